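hill <- function(x, kn) {
  r <- (x / kn[["K"]])^kn[["n"]]
  r / (1 + r)
}

# Steady-state model evaluated at arbitrary positions, with the boundary
# shifted to `boundary` (used to impose per-disc positional jitter exactly
# rather than by interpolation). Returns one row per position with the
# noise-free channel intensities and all ground-truth component curves.
eval_model <- function(x, params, genotype, boundary = params$x_boundary) {
  p <- params; g <- genotype
  anterior <- x <= boundary
  H <- ifelse(anterior, exp((x - boundary) / p$lambda_hh), 0)
  A <- g$fu_responsive * hill(H, p$hill_act)
  A_bdry <- g$fu_responsive * hill(1, p$hill_act)

  k_basal <- p$k_basal * g$basal_turnover_mult
  k_proc <- g$proc_mult * p$k_proc0 * (1 - hill(H, p$hill_proc_inh))
  k_deg <- g$deg_mult * p$k_deg0 * hill(A, p$hill_deg)

  if (p$mode == "kinetic") {
    ci <- p$s_syn / (k_basal + k_proc + k_deg)
    c_proc_only <- p$s_syn / (k_basal + k_proc)
    r_true <- c_proc_only - ci
  } else {
    c_hi <- p$s_syn / k_basal
    c_lo <- p$s_syn / (k_basal + g$proc_mult * p$k_proc0)
    r_max <- g$deg_mult * (c_hi - p$s_syn / (k_basal + p$k_deg0))
    c_proc_only <- c_lo + (c_hi - c_lo) * hill(H, p$hill_proc_inh)
    r_true <- r_max * hill(A, p$hill_deg)
    ci <- c_proc_only - r_true
    if (any(ci[anterior] < 0)) {
      bad <- x[anterior][which(ci[anterior] < 0)[1]]
      abort(sprintf(
        "additive-mode Ci-155 becomes negative at x = %.3g: R_max too large",
        bad), class = "cidecomp_param_error")
    }
  }
  ptc <- p$ptc_base + p$ptc_gain * A

  # posterior compartment: Ci not expressed (constant background); the
  # posterior ptc-lacZ tail is an imaging artifact modelled as a decay
  ci[!anterior] <- p$ci_post_bg
  c_proc_only[!anterior] <- p$ci_post_bg
  r_true[!anterior] <- 0
  post <- !anterior
  ptc[post] <- p$ptc_base +
    p$ptc_gain * A_bdry * exp(-(x[post] - boundary) / p$ptc_post_decay)

  tibble(x = x, hh = H, activity = A, k_proc = k_proc, k_deg = k_deg,
         ci = ci, ptc = ptc, c_proc_only = c_proc_only, r_true = r_true)
}

model_grid <- function(params) {
  seq(params$x_min, params$x_max, by = params$grid_step)
}

truth_to_long <- function(truth, disc_id, genotype_name) {
  tibble(
    disc_id = disc_id, genotype = genotype_name,
    x = rep(truth$x, 2L),
    channel = rep(c("Ci-155", "ptc-lacZ"), each = nrow(truth)),
    intensity = c(truth$ci, truth$ptc)
  )
}

#' Simulate one noise-free AP intensity profile
#'
#' Evaluates the steady-state model on the parameter grid for one genotype
#' and returns a tidy profile: one row per position and channel
#' (`"Ci-155"`, `"ptc-lacZ"`). Ground-truth component curves (Hh level,
#' pathway activity, position-dependent processing and degradation rates,
#' the processing-only Ci-155 curve and the true reduction profile) are
#' attached as the `"truth"` attribute for parameter-recovery tests.
#'
#' @param params A [sim_params()] object.
#' @param genotype A [genotype_spec()] (e.g. from [genotype_preset()]).
#' @param disc_id Identifier recorded in the `disc_id` column.
#' @return A tibble of class `ap_profile` with columns `disc_id`, `genotype`,
#'   `x` (µm, boundary at 0), `channel`, `intensity`; attributes `truth`
#'   (tibble), `params`, `genotype_spec`, and `unit = "um"`.
#' @export
#' @examples
#' p <- sim_params()
#' wt <- simulate_profile(p, genotype_preset("WT"))
#' dplyr::count(wt, channel)
simulate_profile <- function(params, genotype, disc_id = "disc1") {
  stopifnot(inherits(params, "sim_params"), inherits(genotype, "genotype_spec"))
  truth <- eval_model(model_grid(params), params, genotype)
  out <- truth_to_long(truth, disc_id, genotype$name)
  structure(out, truth = truth, params = params, genotype_spec = genotype,
            unit = "um", class = c("ap_profile", class(out)))
}

#' Simulate a replicate set of noisy discs
#'
#' Each disc is the noise-free genotype profile with (i) a positional offset
#' drawn from `Normal(0, offset_sd)` applied by re-evaluating the model with
#' a shifted boundary (so the jitter is exact, not interpolated), (ii) a
#' per-channel intensity scale factor `exp(Normal(0, scale_sd_frac))`, and
#' (iii) independent per-position multiplicative lognormal noise of SD
#' fraction `noise_sd_frac`. Multiplicative noise keeps intensities positive
#' and scales with the signal, as fluorescence noise does. True offsets and
#' scales are retained in the `"disc_effects"` attribute.
#'
#' @inheritParams simulate_profile
#' @param n_discs Number of replicate discs (>= 1).
#' @param seed Optional seed overriding `params$seed`.
#' @return A tibble of class `ap_profile` stacking all discs, with attributes
#'   `truth` (noise-free curves), `disc_effects` (disc_id, offset, per-channel
#'   scale), `params`, `genotype_spec`.
#' @export
simulate_disc_set <- function(params, genotype, n_discs = 3, seed = NULL) {
  stopifnot(inherits(params, "sim_params"), inherits(genotype, "genotype_spec"))
  if (!is.numeric(n_discs) || length(n_discs) != 1 || n_discs < 1) {
    abort("`n_discs` must be >= 1", class = "cidecomp_argument_error")
  }
  n_discs <- as.integer(n_discs)
  seed <- seed %||% params$seed
  if (!is.null(seed)) withr::local_seed(seed)

  x <- model_grid(params)
  truth <- eval_model(x, params, genotype)
  channels <- c("Ci-155", "ptc-lacZ")

  discs <- vector("list", n_discs)
  eff <- vector("list", n_discs)
  for (d in seq_len(n_discs)) {
    offset <- if (params$offset_sd > 0) rnorm(1, 0, params$offset_sd) else 0
    scales <- if (params$scale_sd_frac > 0) {
      exp(rnorm(2, 0, params$scale_sd_frac))
    } else c(1, 1)
    names(scales) <- channels
    m <- eval_model(x, params, genotype,
                    boundary = params$x_boundary + offset)
    id <- sprintf("%s_disc%d", genotype$name, d)
    long <- truth_to_long(m, id, genotype$name)
    long$intensity <- long$intensity * scales[long$channel]
    if (params$noise_sd_frac > 0) {
      long$intensity <- long$intensity *
        exp(rnorm(nrow(long), 0, params$noise_sd_frac))
    }
    discs[[d]] <- long
    eff[[d]] <- tibble(disc_id = id, offset = offset,
                       scale_ci = scales[["Ci-155"]],
                       scale_ptc = scales[["ptc-lacZ"]])
  }
  out <- bind_rows(discs)
  structure(out, truth = truth, disc_effects = bind_rows(eff),
            params = params, genotype_spec = genotype, unit = "um",
            class = c("ap_profile", class(out)))
}

#' Render a profile as a synthetic 2D image
#'
#' Produces a `height x length(x)` matrix whose column `j` holds the profile
#' intensity at the j-th position, with independent multiplicative lognormal
#' noise per pixel. This is the inverse of [extract_profile()]: with zero
#' noise, extracting the full-image ROI reproduces the profile exactly.
#'
#' @param profile An `ap_profile` tibble (one disc).
#' @param channel Channel to render.
#' @param height Image height in pixels (>= 1).
#' @param noise_sd_frac Per-pixel multiplicative noise SD fraction.
#' @param seed Optional RNG seed.
#' @return A numeric matrix (rows = pixels, columns = positions) with the
#'   position vector as attribute `"x"`.
#' @export
render_image <- function(profile, channel = "Ci-155", height = 50,
                         noise_sd_frac = 0, seed = NULL) {
  if (!is.numeric(height) || length(height) != 1 || height < 1) {
    abort("`height` must be >= 1", class = "cidecomp_argument_error")
  }
  height <- as.integer(height)
  pr <- dplyr::filter(profile, .data$channel == !!channel)
  if (nrow(pr) == 0) {
    abort(sprintf("channel '%s' not present in profile", channel),
          class = "cidecomp_argument_error")
  }
  if (dplyr::n_distinct(pr$disc_id) != 1) {
    abort("`profile` must contain a single disc", class = "cidecomp_argument_error")
  }
  pr <- dplyr::arrange(pr, .data$x)
  img <- matrix(rep(pr$intensity, each = height), nrow = height)
  if (noise_sd_frac > 0) {
    if (!is.null(seed)) withr::local_seed(seed)
    img <- img * exp(matrix(rnorm(length(img), 0, noise_sd_frac),
                            nrow = height))
  }
  attr(img, "x") <- pr$x
  img
}

apply_clone_overrides <- function(params, genotype, overrides) {
  p <- params
  for (nm in intersect(names(overrides), c("k_proc0", "k_deg0", "k_basal",
                                           "s_syn"))) {
    p[[nm]] <- overrides[[nm]]
  }
  pos <- c("k_basal", "s_syn")
  for (f in pos) {
    if (p[[f]] <= 0) {
      abort(sprintf("clone override leaves `%s` non-positive", f),
            class = "cidecomp_param_error")
    }
  }
  p
}

# Noise-free region means for one genotype under `params`, with the clone
# carrying `scenario` overrides in far-anterior territory.
clone_clean_means <- function(params, genotype, scenario) {
  p <- params; g <- genotype
  grid <- model_grid(p)
  m <- eval_model(grid, p, g)

  ant_idx <- grid <= (p$x_boundary - 4 * p$lambda_hh)
  border_idx <- grid > (p$x_boundary - p$lambda_hh) & grid <= p$x_boundary
  post_idx <- grid > p$x_boundary + 2 & grid <= p$x_boundary + 12

  ov <- scenario$local_overrides
  pc <- apply_clone_overrides(p, g, ov)
  a_clone <- if ("activity" %in% names(ov)) {
    ov$activity * g$fu_responsive
  } else {
    mean(m$activity[ant_idx])
  }
  k_basal_c <- pc$k_basal * g$basal_turnover_mult
  k_proc_c <- g$proc_mult * pc$k_proc0   # clone sits in Hh-free territory
  k_deg_c <- g$deg_mult * pc$k_deg0 * hill(a_clone, p$hill_deg)
  ci_clone <- pc$s_syn / (k_basal_c + k_proc_c + k_deg_c)
  ptc_clone <- p$ptc_base + p$ptc_gain * a_clone

  tibble(
    channel = rep(c("Ci-155", "ptc-lacZ"), each = 4),
    region = rep(c("clone", "anterior", "ap_border", "posterior"), 2),
    clean_mean = c(ci_clone, mean(m$ci[ant_idx]), mean(m$ci[border_idx]),
                   mean(m$ci[post_idx]),
                   ptc_clone, mean(m$ptc[ant_idx]), mean(m$ptc[border_idx]),
                   mean(m$ptc[post_idx]))
  )
}

clone_truth_relative <- function(clean) {
  wide <- tidyr::pivot_wider(clean, names_from = "region",
                             values_from = "clean_mean")
  purrr::map_dfr(c("ptc_subtracted", "ptc_ratio_clone", "ptc_ratio_anterior",
                   "ci155_subtracted_clone", "ci155_subtracted_anterior"),
                 function(f) {
    ch <- if (grepl("^ptc", f)) "ptc-lacZ" else "Ci-155"
    w <- wide[wide$channel == ch, ]
    v <- switch(f,
      ptc_subtracted = (w$clone - w$anterior) / (w$ap_border - w$anterior),
      ptc_ratio_clone = w$clone / w$ap_border,
      ptc_ratio_anterior = w$anterior / w$ap_border,
      ci155_subtracted_clone = (w$clone - w$posterior) /
        (w$ap_border - w$posterior),
      ci155_subtracted_anterior = (w$anterior - w$posterior) /
        (w$ap_border - w$posterior)
    )
    tibble(channel = ch, formula = f, value = v)
  })
}

#' Simulate a mosaic-clone region-mean dataset
#'
#' Generates per-disc region means (clone, anterior, AP border, posterior;
#' `n_regions` replicate regions each, as in a manual ROI workflow) for both
#' channels, from the kinetic model with the scenario's `local_overrides`
#' applied inside the clone only. Region means carry per-disc scale jitter
#' and per-region multiplicative noise. Noise-free ground truth for every
#' normalization formula is attached as attribute `"ground_truth_relative"`.
#'
#' @inheritParams simulate_disc_set
#' @param scenario A [clone_scenario()] (e.g. from [clone_preset()]).
#' @param n_regions Replicate regions sampled per territory per disc.
#' @return A tibble with columns `disc_id`, `genotype`, `scenario`,
#'   `channel`, `region`, `replicate_idx`, `mean_intensity`; attributes
#'   `ground_truth_relative` and `clean_means`.
#' @export
simulate_clone_dataset <- function(params, genotype, scenario, n_discs = 5,
                                   n_regions = 3, seed = NULL) {
  stopifnot(inherits(params, "sim_params"),
            inherits(genotype, "genotype_spec"),
            inherits(scenario, "clone_scenario"))
  if (n_discs < 1) abort("`n_discs` must be >= 1",
                         class = "cidecomp_argument_error")
  seed <- seed %||% params$seed
  if (!is.null(seed)) withr::local_seed(seed)

  clean <- clone_clean_means(params, genotype, scenario)
  truth <- clone_truth_relative(clean)

  rows <- vector("list", n_discs)
  for (d in seq_len(n_discs)) {
    scale <- if (params$scale_sd_frac > 0) {
      exp(rnorm(1, 0, params$scale_sd_frac))
    } else 1
    reg <- clean[rep(seq_len(nrow(clean)), each = n_regions), ]
    reg$replicate_idx <- rep(seq_len(n_regions), times = nrow(clean))
    noise <- if (params$noise_sd_frac > 0) {
      exp(rnorm(nrow(reg), 0, params$noise_sd_frac))
    } else 1
    rows[[d]] <- tibble(
      disc_id = sprintf("%s_%s_disc%d", genotype$name, scenario$name, d),
      genotype = genotype$name, scenario = scenario$name,
      channel = reg$channel, region = reg$region,
      replicate_idx = reg$replicate_idx,
      mean_intensity = reg$clean_mean * scale * noise
    )
  }
  out <- bind_rows(rows)
  structure(out, ground_truth_relative = truth, clean_means = clean,
            params = params, genotype_spec = genotype, scenario = scenario)
}
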