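#' Build a fully resolved run configuration
#'
#' All tunable knobs of the pipeline in one nested list that round-trips
#' losslessly through YAML. Every run writes the resolved configuration it
#' used next to its outputs, so results are reproducible from the output
#' directory alone. A single top-level `seed` drives all stages through
#' fixed per-stage offsets, so stages can be re-run independently.
#'
#' @param seed Integer master seed.
#' @param outdir Output directory.
#' @param params Named list of overrides for [sim_params()].
#' @param simulate,decompose,clones Named lists of per-stage settings;
#'   unspecified entries take the documented defaults.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, outdir = tempfile("cidecomp_run_"),
                       params = list(), simulate = list(),
                       decompose = list(), clones = list()) {
  cfg <- list(
    seed = as.integer(seed),
    outdir = outdir,
    params = params,
    simulate = utils::modifyList(list(
      genotypes = c("WT", "S849A", "P13A", "D1270_1370", "SufuNull"),
      n_discs = 3,
      images = FALSE,
      image_height = 50
    ), simulate),
    decompose = utils::modifyList(list(
      wt = "WT",
      resistant = c("S849A", "P13A"),
      channel = "Ci-155",
      smooth = TRUE,
      smooth_window = 5,
      reference = "ptc_peak",
      eps = 0.05,
      run = 3,
      trim_posterior = TRUE,
      anterior_window = NA,
      plot = TRUE
    ), decompose),
    clones = utils::modifyList(list(
      scenarios = c("pka_loss", "cos2_loss"),
      genotypes = c("WT", "S849A"),
      n_discs = 5,
      formula = "ptc_subtracted",
      test = "two_sample",
      aggregate = "before"
    ), clones)
  )
  structure(cfg, class = c("run_config", "list"))
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw[intersect(names(raw),
                                    names(formals(run_config)))])
}

#' @rdname run_config
#' @param config A `run_config` object.
#' @export
write_run_config <- function(config, path) {
  # named vectors (e.g. Hill K/n pairs) must become YAML maps, not bare
  # sequences, or their names are lost on the round trip
  as_mappable <- function(x) {
    if (is.list(x)) return(lapply(x, as_mappable))
    if (is.atomic(x) && length(x) > 1 && !is.null(names(x))) {
      return(as.list(x))
    }
    x
  }
  yaml::write_yaml(as_mappable(unclass(config)), path)
  invisible(config)
}

stage_seed <- function(config, stage) {
  # per-stage substreams from one master seed; offsets keep seeds < 2^31
  offsets <- c(simulate = 101L, clones = 211L, decompose = 307L)
  (config$seed + offsets[[stage]]) %% .Machine$integer.max
}

resolve_params <- function(config, extra = list()) {
  p <- utils::modifyList(config$params, extra)
  # YAML round-trips named vectors (Hill K/n pairs) as named lists
  for (nm in grep("^hill_", names(p), value = TRUE)) {
    p[[nm]] <- unlist(p[[nm]])
  }
  do.call(sim_params, p)
}

#' Run the simulation stage of a configured pipeline
#'
#' Writes per-disc genotype profiles (`profiles.csv`), ground-truth sidecar
#' (`truth.json`), the resolved configuration (`config.yml`), and optional
#' per-disc TIFF renderings into `config$outdir`. Deterministic for a fixed
#' configuration.
#'
#' @param config A [run_config()].
#' @return The tidy profile tibble, invisibly; files as a side effect.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- config$simulate
  if (sim$n_discs < 1) {
    abort("simulate: `n_discs` must be >= 1", class = "cidecomp_argument_error")
  }
  params <- resolve_params(config)
  seed0 <- stage_seed(config, "simulate")

  sets <- purrr::imap(setNames(sim$genotypes, sim$genotypes), function(g, nm) {
    simulate_disc_set(params, genotype_preset(g), n_discs = sim$n_discs,
                      seed = seed0 + match(g, sim$genotypes))
  })
  profiles <- bind_rows(sets)
  write_profiles(profiles, file.path(config$outdir, "profiles.csv"))

  truth <- purrr::map(sets, function(s) {
    list(truth = attr(s, "truth"), disc_effects = attr(s, "disc_effects"))
  })
  jsonlite::write_json(truth, file.path(config$outdir, "truth.json"),
                       dataframe = "columns", digits = NA)
  write_run_config(config, file.path(config$outdir, "config.yml"))

  if (isTRUE(sim$images)) {
    for (id in unique(profiles$disc_id)) {
      img <- render_image(filter(profiles, .data$disc_id == id),
                          height = sim$image_height)
      write_image_tiff(img, file.path(config$outdir,
                                      sprintf("%s_Ci155.tiff", id)))
    }
  }
  invisible(profiles)
}

#' Run the decomposition stage of a configured pipeline
#'
#' Reads `profiles.csv` from `config$outdir` (or takes a profile tibble
#' directly), aligns and decomposes, and writes `aligned_<genotype>.csv`,
#' `decomposition_curves.csv`, `decomposition.json` and an overlay plot.
#'
#' @param config A [run_config()].
#' @param profiles Optional in-memory profile tibble (skips the CSV read).
#' @return The `ci_decomposition` object, invisibly.
#' @export
run_decompose <- function(config, profiles = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(profiles)) {
    path <- file.path(config$outdir, "profiles.csv")
    if (!file.exists(path)) {
      abort(sprintf("no profiles at '%s'; run the simulate stage or supply `profiles`",
                    path), class = "cidecomp_io_error")
    }
    profiles <- read_profiles(path)
  }
  dc <- config$decompose
  awin <- dc$anterior_window
  if (is.null(awin) || all(is.na(awin))) awin <- NULL  # NA means "auto"
  result <- decompose_ci_profiles(
    profiles, wt = dc$wt, resistant = dc$resistant, channel = dc$channel,
    smooth = dc$smooth, smooth_window = dc$smooth_window,
    reference = dc$reference, eps = dc$eps, run = dc$run,
    trim_posterior = dc$trim_posterior,
    anterior_window = awin)

  write_aligned(result$wt_set,
                file.path(config$outdir,
                          sprintf("aligned_%s.csv", dc$wt)))
  purrr::iwalk(result$resistant_sets, function(s, g) {
    write_aligned(s, file.path(config$outdir, sprintf("aligned_%s.csv", g)))
  })
  write_decomposition(result,
                      file.path(config$outdir, "decomposition_curves.csv"),
                      file.path(config$outdir, "decomposition.json"))
  if (isTRUE(dc$plot)) {
    ggplot2::ggsave(file.path(config$outdir, "decomposition_overlay.pdf"),
                    autoplot(result), width = 7, height = 4.5)
  }
  write_run_config(config, file.path(config$outdir, "config.yml"))
  invisible(result)
}

#' Run the clone-metrics stage of a configured pipeline
#'
#' Reads `regions.csv` from `config$outdir` (or simulates region tables for
#' the configured scenarios and genotypes when none exists), computes
#' relative expression under the configured formula, genotype summaries,
#' and pairwise group comparisons with significance marks, writing
#' `relative_expression.csv`, `group_comparisons.csv` and
#' `group_comparisons.json`.
#'
#' @param config A [run_config()].
#' @param regions Optional in-memory region tibble.
#' @return A list with `values`, `summaries`, `comparisons`, invisibly.
#' @export
run_clones <- function(config, regions = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  cl <- config$clones
  if (is.null(regions)) {
    path <- file.path(config$outdir, "regions.csv")
    if (file.exists(path)) {
      regions <- read_regions(path)
    } else {
      params <- resolve_params(config)
      seed0 <- stage_seed(config, "clones")
      k <- 0
      regions <- purrr::map(cl$scenarios, function(sc) {
        purrr::map(cl$genotypes, function(g) {
          k <<- k + 1
          simulate_clone_dataset(params, genotype_preset(g),
                                 clone_preset(sc), n_discs = cl$n_discs,
                                 seed = seed0 + k)
        }) |> bind_rows()
      }) |> bind_rows()
      write_regions(regions, path)
    }
  }
  if (nrow(regions) == 0) {
    abort("no measurements in the region table", class = "cidecomp_io_error")
  }
  values <- relative_expression(regions, cl$formula,
                                aggregate = cl$aggregate)
  summaries <- values |>
    group_by(.data$genotype) |>
    group_split() |>
    purrr::map(function(v) {
      dplyr::bind_cols(tibble(genotype = v$genotype[1],
                              formula = cl$formula),
                       summarize_relative(v))
    }) |> bind_rows()

  gts <- unique(values$genotype)
  comparisons <- NULL
  if (length(gts) >= 2) {
    pairs <- utils::combn(gts, 2, simplify = FALSE)
    comparisons <- purrr::map(pairs, function(p) {
      va <- filter(values, .data$genotype == p[1])
      vb <- filter(values, .data$genotype == p[2])
      cmp <- tryCatch(
        if (cl$test == "paired") {
          # genotypes come from different discs; "paired" pairs replicate
          # indices in acquisition order, and is only meaningful when the
          # design pairs them deliberately
          compare_groups(va$value, vb$value, test = "paired",
                         pairing_a = seq_len(nrow(va)),
                         pairing_b = seq_len(nrow(vb)), labels = p)
        } else {
          compare_groups(va, vb, test = "two_sample", labels = p)
        },
        cidecomp_degenerate_error = function(e) {
          warn(sprintf("comparison %s vs %s is degenerate: %s",
                       p[1], p[2], conditionMessage(e)))
          sa <- summarize_relative(va); sb <- summarize_relative(vb)
          tibble(group_a = p[1], group_b = p[2], n_a = sa$n, n_b = sb$n,
                 mean_a = sa$mean, mean_b = sb$mean,
                 sem_a = sa$sem, sem_b = sb$sem, test = cl$test,
                 t_stat = NA_real_, df = NA_real_, p_value = NA_real_,
                 significance_mark = "")
        })
      cmp
    }) |> bind_rows()
  }

  readr::write_csv(values,
                   file.path(config$outdir, "relative_expression.csv"))
  readr::write_csv(summaries,
                   file.path(config$outdir, "relative_summaries.csv"))
  if (!is.null(comparisons)) {
    readr::write_csv(comparisons,
                     file.path(config$outdir, "group_comparisons.csv"))
    jsonlite::write_json(comparisons,
                         file.path(config$outdir, "group_comparisons.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  write_run_config(config, file.path(config$outdir, "config.yml"))
  invisible(list(values = values, summaries = summaries,
                 comparisons = comparisons))
}
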