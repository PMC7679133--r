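# Coerce an aligned set / summary tibble / plain tibble(x, mean) to the
# Ci-155 mean trace: tibble(x, mean, sem).
as_mean_trace <- function(obj, channel = "Ci-155") {
  if (inherits(obj, "aligned_profiles")) obj <- obj$summary
  if (!is.data.frame(obj)) {
    abort("expected an aligned_profiles object or a data frame",
          class = "cidecomp_argument_error")
  }
  tr <- obj
  if ("channel" %in% names(tr)) tr <- filter(tr, .data$channel == !!channel)
  if (!"mean" %in% names(tr) && "intensity" %in% names(tr)) {
    tr$mean <- tr$intensity
  }
  if (!all(c("x", "mean") %in% names(tr)) || nrow(tr) == 0) {
    abort(sprintf("no usable '%s' trace (need x and mean columns)", channel),
          class = "cidecomp_argument_error")
  }
  if (!"sem" %in% names(tr)) tr$sem <- NA_real_
  arrange(tr[c("x", "mean", "sem")], x)
}

#' Hh-stimulated Ci-155 reduction profile from processing-resistant variants
#'
#' Averages the mean Ci-155 traces of one or more processing-resistant
#' genotypes (unweighted mean across genotype means), takes the maximum of
#' that average over an anterior window (territory anterior of the pathway
#' response, where no Hh-stimulated reduction occurs), and defines the
#' reduction profile as
#' `reduction(x) = c_max_anterior - c_resistant_avg(x)`.
#' Negative values arising from noise are retained, not clipped, so the
#' identity holds exactly; their count is reported.
#'
#' @param resistant_sets One `aligned_profiles` object (or tibble with
#'   `x`/`mean` columns), or a list of them, one per resistant genotype;
#'   traces are re-interpolated onto their common overlapping grid.
#' @param anterior_window `c(lo, hi)` positions defining anterior,
#'   pre-response territory.
#' @param channel Intensity channel to decompose.
#' @return A list: `grid`, `c_resistant_avg`, `c_max_anterior`, `reduction`,
#'   `n_negative` (positions where noise drives the reduction negative).
#' @export
reduction_profile <- function(resistant_sets, anterior_window,
                              channel = "Ci-155") {
  if (inherits(resistant_sets, "aligned_profiles") ||
      is.data.frame(resistant_sets)) {
    resistant_sets <- list(resistant_sets)
  }
  traces <- purrr::map(resistant_sets, as_mean_trace, channel = channel)
  lo <- max(purrr::map_dbl(traces, function(t) min(t$x)))
  hi <- min(purrr::map_dbl(traces, function(t) max(t$x)))
  if (lo > hi) {
    abort("resistant-set grids do not overlap", class = "cidecomp_grid_error")
  }
  grid <- traces[[1]]$x[traces[[1]]$x >= lo & traces[[1]]$x <= hi]
  mat <- vapply(traces, function(t) {
    if (identical(t$x, grid)) t$mean else approx(t$x, t$mean, xout = grid)$y
  }, numeric(length(grid)))
  c_avg <- rowMeans(mat)

  idx <- grid >= anterior_window[1] & grid <= anterior_window[2]
  if (!any(idx)) {
    abort("anterior window is empty on the common grid",
          class = "cidecomp_argument_error")
  }
  c_max <- max(c_avg[idx])
  reduction <- c_max - c_avg
  list(grid = grid, c_resistant_avg = c_avg, c_max_anterior = c_max,
       reduction = reduction, n_negative = sum(reduction < 0))
}

#' Add the reduction profile back to the wild-type trace
#'
#' Produces the "no-reduction" curve: the Ci-155 profile that processing
#' inhibition alone would generate, obtained by adding the reduction
#' inferred from processing-resistant variants to the wild-type profile at
#' each position. The wild-type SEM is carried through unchanged (the
#' reduction is treated as a fixed curve).
#'
#' @param wt_set `aligned_profiles` (or tibble with `x`/`mean`) for the
#'   wild-type genotype.
#' @param reduction Either the list returned by [reduction_profile()] or a
#'   numeric vector on `grid`.
#' @param grid Positions for a bare numeric `reduction`.
#' @param channel Intensity channel.
#' @return A tibble: `x`, `c_wt`, `reduction`, `c_nored`, `sem_wt`.
#' @export
no_reduction_curve <- function(wt_set, reduction, grid = NULL,
                               channel = "Ci-155") {
  if (is.list(reduction) && !is.null(reduction$grid)) {
    grid <- reduction$grid
    red <- reduction$reduction
  } else {
    red <- reduction
    if (is.null(grid)) {
      abort("`grid` is required when `reduction` is a bare vector",
            class = "cidecomp_argument_error")
    }
  }
  if (length(red) != length(grid)) {
    abort("reduction and grid lengths differ", class = "cidecomp_grid_error")
  }
  wt <- as_mean_trace(wt_set, channel = channel)
  if (min(grid) < min(wt$x) - 1e-9 || max(grid) > max(wt$x) + 1e-9) {
    abort("wild-type trace does not cover the reduction grid",
          class = "cidecomp_grid_error")
  }
  c_wt <- if (identical(wt$x, grid)) wt$mean else
    approx(wt$x, wt$mean, xout = grid)$y
  sem <- if (identical(wt$x, grid)) wt$sem else
    suppressWarnings(approx(wt$x, wt$sem, xout = grid)$y)
  tibble(x = grid, c_wt = c_wt, reduction = red,
         c_nored = c_wt + red, sem_wt = sem)
}

#' Processing-inhibition fraction and landmarks from the no-reduction curve
#'
#' Rescales the no-reduction curve between its anterior plateau mean
#' (`C_ant`, processing fully active) and its maximum (`C_top`, processing
#' fully inhibited) to an inhibition fraction
#' `phi(x) = (c_nored(x) - C_ant) / (C_top - C_ant)`, and locates where
#' processing is first inhibited (`phi > eps` sustained for `run` samples),
#' 50% inhibited (first `phi >= 0.5`), and fully inhibited
#' (first `phi >= 1 - eps`).
#'
#' @param c_nored Numeric no-reduction curve, or the tibble returned by
#'   [no_reduction_curve()].
#' @param x Positions (taken from the tibble if supplied there).
#' @param anterior_window `c(lo, hi)` anterior plateau window.
#' @param eps Fractional threshold for "first" and "fully" inhibited.
#' @param run Run length (samples) required for the first-inhibited call.
#' @return A list: `inhibition_fraction` tibble (`x`, `phi`), `C_ant`,
#'   `C_top`, `x_first_inh`, `x_half_inh`, `x_full_inh`.
#' @export
inhibition_landmarks <- function(c_nored, x = NULL, anterior_window,
                                 eps = 0.05, run = 3) {
  if (is.data.frame(c_nored)) {
    x <- c_nored$x
    c_nored <- c_nored$c_nored
  }
  if (is.null(x)) x <- seq_along(c_nored)
  idx <- x >= anterior_window[1] & x <= anterior_window[2]
  if (!any(idx)) {
    abort("anterior window is empty", class = "cidecomp_argument_error")
  }
  c_ant <- mean(c_nored[idx])
  c_top <- max(c_nored)
  if (c_top <= c_ant) {
    abort("no inferred inhibition: curve has no rise above its anterior plateau",
          class = "cidecomp_no_response")
  }
  phi <- (c_nored - c_ant) / (c_top - c_ant)
  i_first <- first_sustained(phi > eps, run)
  i_half <- which(phi >= 0.5)[1]
  i_full <- which(phi >= 1 - eps)[1]
  list(
    inhibition_fraction = tibble(x = x, phi = phi),
    C_ant = c_ant, C_top = c_top,
    x_first_inh = if (is.na(i_first)) NA_real_ else x[i_first],
    x_half_inh = if (is.na(i_half)) NA_real_ else x[i_half],
    x_full_inh = if (is.na(i_full)) NA_real_ else x[i_full]
  )
}

#' Fold changes implied by a decomposition
#'
#' `fold_reduction_at_boundary` is the anterior maximum of the averaged
#' resistant-variant Ci-155 divided by its value at the compartment boundary
#' (grid position 0): how far Hh-stimulated degradation lowers Ci-155 by the
#' boundary. `fold_span_processing` is `C_top / C_ant` of the no-reduction
#' curve: the span that graded processing inhibition alone would produce.
#'
#' @param result A `ci_decomposition` object from [decompose_ci_profiles()].
#' @return A one-row tibble with both fold changes.
#' @export
fold_changes <- function(result) {
  stopifnot(inherits(result, "ci_decomposition"))
  i0 <- which.min(abs(result$grid))
  c0 <- result$c_resistant_avg[i0]
  if (!is.finite(c0) || c0 <= 0) {
    abort(sprintf("resistant Ci-155 at the boundary (x = %.3g) is not positive",
                  result$grid[i0]), class = "cidecomp_argument_error")
  }
  if (result$inhibition$C_ant <= 0) {
    abort("anterior plateau of the no-reduction curve is not positive",
          class = "cidecomp_argument_error")
  }
  tibble(
    fold_reduction_at_boundary = result$c_max_anterior / c0,
    fold_span_processing = result$inhibition$C_top / result$inhibition$C_ant
  )
}

#' Decompose Ci-155 profiles into degradation and processing components
#'
#' End-to-end inference from a tidy multi-genotype profile table: aligns the
#' replicate discs of the wild-type and of each processing-resistant
#' genotype on their ptc-lacZ reference landmark (optionally smoothing each
#' trace first), restricts to territory anterior of the boundary (the
#' posterior tail carries no usable information), computes the reduction
#' profile from the resistant genotypes, adds it to the wild-type trace to
#' obtain the no-reduction curve, and extracts inhibition landmarks and fold
#' changes.
#'
#' The default anterior window runs from the anterior end of the common grid
#' to two grid steps anterior of the wild-type ptc-lacZ initial rise.
#'
#' @param profiles Tidy profile table (`disc_id`, `genotype`, `x`, `channel`,
#'   `intensity`).
#' @param wt Wild-type genotype label.
#' @param resistant Character vector of processing-resistant genotype labels.
#' @param channel Channel to decompose.
#' @param smooth Smooth each disc trace before alignment?
#' @param smooth_window Window for [smooth_profile()].
#' @param reference,min_discs Passed to [align_profiles()].
#' @param anterior_window Override for the anterior window `c(lo, hi)`.
#' @param trim_posterior Drop grid positions posterior of the boundary
#'   (x > 0) before decomposing (recommended).
#' @param eps,run Passed to [inhibition_landmarks()].
#' @return An object of class `ci_decomposition`; see [tidy.ci_decomposition()]
#'   and [glance.ci_decomposition()].
#' @export
decompose_ci_profiles <- function(profiles, wt = "WT",
                                  resistant = c("S849A", "P13A"),
                                  channel = "Ci-155", smooth = TRUE,
                                  smooth_window = 5,
                                  reference = "ptc_peak", min_discs = 3,
                                  anterior_window = NULL,
                                  trim_posterior = TRUE,
                                  eps = 0.05, run = 3) {
  have <- unique(profiles$genotype)
  missing <- setdiff(c(wt, resistant), have)
  if (length(missing)) {
    abort(sprintf("Ci-WT profile and all resistant genotypes are required; missing: %s",
                  paste(missing, collapse = ", ")),
          class = "cidecomp_argument_error")
  }
  if (smooth) profiles <- smooth_channels(profiles, window = smooth_window)

  align_one <- function(g) {
    align_profiles(filter(profiles, .data$genotype == g),
                   reference = reference, min_discs = min_discs)
  }
  wt_set <- align_one(wt)
  res_sets <- purrr::map(setNames(resistant, resistant), align_one)

  # restrict every set to the common overlap (grids share step and phase but
  # can differ in extent after per-disc jitter), and drop the posterior tail
  all_sets <- c(list(wt_set), res_sets)
  lo <- max(purrr::map_dbl(all_sets, function(s) min(s$grid)))
  hi <- min(purrr::map_dbl(all_sets, function(s) max(s$grid)))
  if (trim_posterior) hi <- min(hi, 0)
  if (lo > hi) {
    abort("aligned genotype grids do not overlap", class = "cidecomp_grid_error")
  }
  trim <- function(set) {
    set$summary <- filter(set$summary, .data$x >= lo, .data$x <= hi)
    set$grid <- set$grid[set$grid >= lo & set$grid <= hi]
    set
  }
  wt_set <- trim(wt_set); res_sets <- purrr::map(res_sets, trim)

  if (is.null(anterior_window)) {
    wt_lm <- find_landmarks(
      wt_set$summary |>
        dplyr::rename(intensity = "mean") |>
        mutate(disc_id = "wt_mean"),
      channel = "ptc-lacZ")
    step <- min(diff(wt_set$grid))
    anterior_window <- c(min(wt_set$grid), wt_lm$x_rise - 2 * step)
  }

  red <- reduction_profile(res_sets, anterior_window, channel = channel)
  nored <- no_reduction_curve(wt_set, red, channel = channel)
  inh <- inhibition_landmarks(nored, anterior_window = anterior_window,
                              eps = eps, run = run)

  result <- structure(list(
    grid = red$grid,
    c_resistant_avg = red$c_resistant_avg,
    c_max_anterior = red$c_max_anterior,
    reduction = red$reduction,
    n_negative = red$n_negative,
    c_wt = nored$c_wt, sem_wt = nored$sem_wt,
    c_nored = nored$c_nored,
    inhibition = inh,
    anterior_window = anterior_window,
    wt_set = wt_set, resistant_sets = res_sets,
    provenance = list(wt = wt, resistant = resistant, channel = channel,
                      smooth = smooth,
                      smooth_window = if (smooth) smooth_window else NA,
                      reference = reference, eps = eps, run = run,
                      trim_posterior = trim_posterior,
                      n_discs = c(setNames(length(unique(wt_set$per_disc$disc_id)), wt),
                                  purrr::map_int(res_sets, function(s)
                                    length(unique(s$per_disc$disc_id)))))
  ), class = "ci_decomposition")
  result
}

#' @export
print.ci_decomposition <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    paste0("<ci_decomposition> genotypes: WT = %s; resistant = %s\n",
           "  grid: [%.4g, %.4g] um, %d positions\n",
           "  fold reduction at boundary: %.3g; processing span: %.3g-fold\n",
           "  inhibition landmarks (um): first %.3g, half %.3g, full %.3g\n"),
    x$provenance$wt, paste(x$provenance$resistant, collapse = ", "),
    min(x$grid), max(x$grid), length(x$grid),
    g$fold_reduction_at_boundary, g$fold_span_processing,
    g$x_first_inh, g$x_half_inh, g$x_full_inh))
  invisible(x)
}

#' Tidy a Ci-155 decomposition
#'
#' @param x A `ci_decomposition` object.
#' @param ... Unused.
#' @return One row per grid position: `x`, `c_resistant_avg`, `reduction`,
#'   `c_wt`, `sem_wt`, `c_nored`, `inhibition_fraction`.
#' @method tidy ci_decomposition
#' @export
tidy.ci_decomposition <- function(x, ...) {
  obj <- x
  tibble(x = obj$grid,
         c_resistant_avg = obj$c_resistant_avg,
         reduction = obj$reduction,
         c_wt = obj$c_wt, sem_wt = obj$sem_wt,
         c_nored = obj$c_nored,
         inhibition_fraction = obj$inhibition$inhibition_fraction$phi)
}

#' One-row summary of a Ci-155 decomposition
#'
#' @param x A `ci_decomposition` object.
#' @param ... Unused.
#' @return A one-row tibble with the anterior maximum, plateau and top of
#'   the no-reduction curve, the inhibition landmarks, fold changes, and the
#'   fraction of noise-negative reduction positions.
#' @method glance ci_decomposition
#' @export
glance.ci_decomposition <- function(x, ...) {
  fc <- fold_changes(x)
  tibble(
    c_max_anterior = x$c_max_anterior,
    C_ant = x$inhibition$C_ant, C_top = x$inhibition$C_top,
    x_first_inh = x$inhibition$x_first_inh,
    x_half_inh = x$inhibition$x_half_inh,
    x_full_inh = x$inhibition$x_full_inh,
    fold_reduction_at_boundary = fc$fold_reduction_at_boundary,
    fold_span_processing = fc$fold_span_processing,
    frac_negative_reduction = x$n_negative / length(x$grid)
  )
}
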