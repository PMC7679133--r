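#' Extract an AP intensity profile from a 2D image
#'
#' Averages pixel intensity over the rows of a rectangular ROI at each
#' column, mimicking the classic elongated-rectangle measurement on a wing
#' pouch: the profile value at a position is the mean over the rectangle's
#' height there.
#'
#' @param image Numeric matrix (rows = pixels along the rectangle height,
#'   columns = positions along the AP axis).
#' @param roi Rectangle `c(x0, y0, width, height)` in 0-based pixel
#'   coordinates, half-open (so `x0 = 0, width = ncol(image)` spans all
#'   columns). Defaults to the full image.
#' @param disc_id,genotype Labels recorded in the output.
#' @return A tibble of class `ap_profile` with columns `disc_id`, `genotype`,
#'   `x` (column index within the ROI, pixel units), `channel`, `intensity`.
#' @export
extract_profile <- function(image, roi = NULL, disc_id = "disc1",
                            genotype = NA_character_) {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort("`image` must be a numeric matrix", class = "cidecomp_argument_error")
  }
  if (is.null(roi)) roi <- c(0, 0, ncol(image), nrow(image))
  if (length(roi) != 4) {
    abort("`roi` must be c(x0, y0, width, height)",
          class = "cidecomp_argument_error")
  }
  x0 <- roi[1]; y0 <- roi[2]; w <- roi[3]; h <- roi[4]
  if (w < 1 || h < 1) {
    abort("empty ROI", class = "cidecomp_argument_error")
  }
  if (x0 < 0 || y0 < 0 || x0 + w > ncol(image) || y0 + h > nrow(image)) {
    abort("ROI exceeds image bounds", class = "cidecomp_bounds_error")
  }
  sub <- image[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w), drop = FALSE]
  xs <- attr(image, "x")
  x <- if (!is.null(xs)) xs[(x0 + 1):(x0 + w)] else seq(x0, x0 + w - 1)
  out <- tibble(disc_id = disc_id, genotype = genotype, x = x,
                channel = "Ci-155", intensity = colMeans(sub))
  structure(out, unit = if (is.null(xs)) "px" else "um",
            class = c("ap_profile", class(out)))
}

#' Centered moving-average smoothing
#'
#' Five-point (by default) centered moving average with a shrinking window
#' at the edges: `out[i]` is the mean of the input over indices
#' `[i - w, i + w]` intersected with the valid range, so the output has the
#' same length as the input and lies within its extrema.
#'
#' @param y Numeric vector.
#' @param window Odd window size, `1 <= window <= length(y)`.
#' @return Numeric vector, same length as `y`.
#' @export
#' @examples
#' smooth_profile(c(0, 0, 0, 5, 0, 0, 0), window = 5)
smooth_profile <- function(y, window = 5) {
  if (!is.numeric(window) || length(window) != 1 || window < 1 ||
      window %% 2 == 0) {
    abort("`window` must be a positive odd integer",
          class = "cidecomp_argument_error")
  }
  n <- length(y)
  if (window > n) {
    abort("`window` must not exceed the profile length",
          class = "cidecomp_argument_error")
  }
  w <- (window - 1) / 2
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - w, 1)
  hi <- pmin(seq_len(n) + w, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Apply smooth_profile to every disc x channel trace of a tidy profile table.
smooth_channels <- function(profiles, window = 5) {
  profiles |>
    group_by(.data$disc_id, .data$channel) |>
    arrange(.data$x, .by_group = TRUE) |>
    mutate(intensity = smooth_profile(.data$intensity, window = window)) |>
    ungroup()
}

#' Detect ptc-lacZ landmarks on a profile
#'
#' Finds the anterior baseline, the peak, and the initial-rise and 50%-rise
#' positions of a reporter trace. The baseline is the mean over
#' `baseline_window`; the peak is the global maximum (most anterior position
#' on ties). The initial rise is the first position, scanning
#' anterior-to-posterior, where intensity exceeds
#' `baseline + max(rise_k * SD_baseline, rise_floor_frac * (peak - baseline))`
#' and stays above it for at least `rise_run` consecutive samples (the
#' floor term keeps the rule meaningful on noise-free traces, whose baseline
#' SD can be 0). The 50%-rise position is the first where intensity reaches
#' `baseline + 0.5 * (peak - baseline)`.
#'
#' @param profile An `ap_profile` tibble (single disc), or any data frame
#'   with `x`, `channel`, `intensity` columns.
#' @param channel Channel to landmark (default the `ptc-lacZ` reporter).
#' @param baseline_window `c(lo, hi)` position range for the anterior
#'   baseline; defaults to the most anterior 25% of the trace. Must lie
#'   anterior of the profile maximum.
#' @param rise_k Baseline-SD multiplier of the initial-rise threshold.
#' @param rise_run Required run length (samples) above threshold.
#' @param rise_floor_frac Minimum threshold as a fraction of the
#'   baseline-to-peak span.
#' @return A one-row tibble of class `ptc_landmarks`: `baseline`,
#'   `baseline_sd`, `peak_value`, `x_peak`, `x_rise`, `x_half`,
#'   `x_post_half` (posterior half-max edge, `NA` if the trace ends first).
#' @export
find_landmarks <- function(profile, channel = "ptc-lacZ",
                           baseline_window = NULL, rise_k = 2,
                           rise_run = 3, rise_floor_frac = 0.02) {
  tr <- profile |>
    filter(.data$channel == !!channel) |>
    arrange(.data$x)
  if (nrow(tr) < rise_run + 1) {
    abort("profile too short for landmark detection",
          class = "cidecomp_argument_error")
  }
  x <- tr$x; y <- tr$intensity
  if (is.null(baseline_window)) {
    baseline_window <- c(min(x), min(x) + 0.25 * diff(range(x)))
  }
  in_base <- x >= baseline_window[1] & x <= baseline_window[2]
  if (!any(in_base)) {
    abort("empty baseline window", class = "cidecomp_argument_error")
  }
  i_peak <- which.max(y)            # which.max takes the first (most anterior) tie
  baseline <- mean(y[in_base])
  bsd <- if (sum(in_base) > 1) sd(y[in_base]) else 0
  peak_value <- y[i_peak]
  thr <- baseline + max(rise_k * bsd, rise_floor_frac * (peak_value - baseline))
  if (peak_value <= thr) {
    abort("no response: peak not distinguishable from baseline",
          class = "cidecomp_no_response")
  }
  if (baseline_window[2] >= x[i_peak]) {
    abort("baseline window must lie anterior of the profile maximum",
          class = "cidecomp_argument_error")
  }
  above <- y > thr
  i_rise <- first_sustained(above, rise_run)
  if (is.na(i_rise)) {
    abort("no sustained rise above threshold",
          class = "cidecomp_no_response")
  }
  half_level <- baseline + 0.5 * (peak_value - baseline)
  i_half <- which(y >= half_level)[1]
  x_rise <- x[i_rise]; x_half <- x[i_half]; x_peak <- x[i_peak]
  if (!(x_rise <= x_half && x_half <= x_peak)) {
    abort(sprintf(
      "landmark ordering violated (rise %.3g, half %.3g, peak %.3g)",
      x_rise, x_half, x_peak), class = "cidecomp_landmark_error")
  }
  post <- which(x > x_peak & y <= half_level)
  x_post_half <- if (length(post)) x[post[1]] else NA_real_
  structure(
    tibble(baseline = baseline, baseline_sd = bsd, peak_value = peak_value,
           x_peak = x_peak, x_rise = x_rise, x_half = x_half,
           x_post_half = x_post_half),
    class = c("ptc_landmarks", "tbl_df", "tbl", "data.frame"))
}

# Positions must be strictly increasing and uniformly spaced (1e-6 relative
# tolerance) for interpolation and windowed smoothing to be meaningful.
check_profile_grid <- function(x, disc_id = "?") {
  d <- diff(x)
  if (any(d <= 0)) {
    abort(sprintf("disc '%s': positions are not strictly increasing", disc_id),
          class = "cidecomp_grid_error")
  }
  if ((max(d) - min(d)) > 1e-6 * stats::median(d)) {
    abort(sprintf("disc '%s': positions are not uniformly spaced", disc_id),
          class = "cidecomp_grid_error")
  }
  invisible(x)
}

first_sustained <- function(flag, run) {
  if (run <= 1) return(which(flag)[1] %||% NA_integer_)
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  ok <- which(r$values & r$lengths >= run)
  if (!length(ok)) return(NA_integer_)
  ends[ok[1]] - r$lengths[ok[1]] + 1L
}

#' Align replicate discs on a ptc-lacZ reference landmark and average
#'
#' Shifts each disc so that its reference landmark (the ptc-lacZ peak by
#' default, which effectively marks the AP compartment boundary; optionally
#' the posterior half-maximum edge) sits at position 0, interpolates every
#' channel linearly onto a common grid (step = the smallest input step), and
#' computes the per-position mean and SEM over the discs contributing at
#' each position. Positions outside a disc's support are missing for that
#' disc; `n` tracks contributors, and SEM is `NA` where `n < 2`.
#'
#' @param profiles A tidy profile table (rows from one or more discs:
#'   columns `disc_id`, `x`, `channel`, `intensity`, optionally `genotype`).
#' @param reference `"ptc_peak"` or `"ptc_posterior_half"`.
#' @param ref_channel Channel carrying the reference landmark.
#' @param min_discs Fewer usable discs than this triggers a warning
#'   (replicate sets of three are customary; two occur in practice).
#' @param landmark_args Extra arguments passed to [find_landmarks()].
#' @return An object of class `aligned_profiles`: list with `grid`,
#'   `per_disc` (aligned interpolated long tibble), `summary` (tibble `x`,
#'   `channel`, `mean`, `sem`, `n`), `shifts` (per-disc applied shift),
#'   `landmarks`, `reference`, `genotype`.
#' @export
align_profiles <- function(profiles, reference = c("ptc_peak",
                                                   "ptc_posterior_half"),
                           ref_channel = "ptc-lacZ", min_discs = 3,
                           landmark_args = list()) {
  reference <- match.arg(reference)
  ids <- unique(profiles$disc_id)
  if (!length(ids)) abort("no profiles supplied",
                          class = "cidecomp_argument_error")

  shifts <- list(); lms <- list(); kept <- list(); failed <- character()
  for (id in ids) {
    pr <- filter(profiles, .data$disc_id == id)
    for (ch in unique(pr$channel)) {
      check_profile_grid(sort(pr$x[pr$channel == ch]), disc_id = id)
    }
    lm <- tryCatch(
      do.call(find_landmarks, c(list(pr, channel = ref_channel),
                                landmark_args)),
      error = function(e) e)
    if (inherits(lm, "error")) { failed <- c(failed, id); next }
    ref_x <- switch(reference, ptc_peak = lm$x_peak,
                    ptc_posterior_half = lm$x_post_half)
    if (is.na(ref_x)) { failed <- c(failed, id); next }
    shifts[[id]] <- ref_x
    lms[[id]] <- lm
    kept[[id]] <- mutate(pr, x = .data$x - ref_x)
  }
  if (length(failed)) {
    warn(sprintf("excluded disc(s) without usable landmarks: %s",
                 paste(failed, collapse = ", ")))
  }
  if (!length(kept)) {
    abort("no profile yielded a usable reference landmark",
          class = "cidecomp_landmark_error")
  }
  if (length(kept) < min_discs) {
    warn(sprintf("only %d usable disc(s); %d or more are customary",
                 length(kept), min_discs))
  }

  step <- min(purrr::map_dbl(kept, function(p) {
    min(diff(sort(unique(p$x))))
  }))
  lo <- min(purrr::map_dbl(kept, function(p) min(p$x)))
  hi <- max(purrr::map_dbl(kept, function(p) max(p$x)))
  grid <- seq(ceiling(lo / step), floor(hi / step)) * step

  per_disc <- purrr::imap(kept, function(p, id) {
    p |>
      group_by(.data$channel) |>
      group_split() |>
      purrr::map(function(tr) {
        tr <- arrange(tr, .data$x)
        tibble(disc_id = id,
               genotype = if ("genotype" %in% names(tr))
                 tr$genotype[1] else NA_character_,
               x = grid, channel = tr$channel[1],
               intensity = approx(tr$x, tr$intensity, xout = grid,
                                  rule = 1)$y)
      }) |>
      bind_rows()
  }) |> bind_rows()

  summary <- per_disc |>
    group_by(.data$x, .data$channel) |>
    summarise(
      n = sum(!is.na(.data$intensity)),
      mean = if (n[1] > 0) mean(.data$intensity, na.rm = TRUE) else NA_real_,
      sem = if (sum(!is.na(.data$intensity)) >= 2)
        sd(.data$intensity, na.rm = TRUE) / sqrt(sum(!is.na(.data$intensity)))
      else NA_real_,
      .groups = "drop") |>
    select("x", "channel", "mean", "sem", "n") |>
    arrange(.data$channel, .data$x)

  genotype <- if ("genotype" %in% names(profiles)) {
    g <- unique(profiles$genotype); if (length(g) == 1) g else NA_character_
  } else NA_character_

  structure(list(
    grid = grid,
    per_disc = per_disc,
    summary = summary,
    shifts = tibble(disc_id = names(shifts),
                    shift = -unlist(shifts, use.names = FALSE),
                    x_ref = unlist(shifts, use.names = FALSE)),
    landmarks = bind_rows(lms, .id = "disc_id"),
    excluded = failed,
    reference = reference,
    genotype = genotype
  ), class = "aligned_profiles")
}

#' @export
print.aligned_profiles <- function(x, ...) {
  cat(sprintf("<aligned_profiles> %d disc(s), reference = %s, grid [%.4g, %.4g]\n",
              nrow(x$shifts), x$reference, min(x$grid), max(x$grid)))
  print(x$summary, n = 6)
  invisible(x)
}

#' @rdname align_profiles
#' @param x An `aligned_profiles` object.
#' @param ... Unused.
#' @method tidy aligned_profiles
#' @export
tidy.aligned_profiles <- function(x, ...) x$summary

#' Normalize an intensity profile
#'
#' `mode = "max"` divides by the global maximum so the output peaks at 1;
#' `mode = "anterior_plateau"` divides by the mean over an anterior window,
#' expressing intensities relative to the Hh-free plateau.
#'
#' @param y Numeric intensity vector.
#' @param mode Normalization mode.
#' @param x Positions (required for `"anterior_plateau"`).
#' @param anterior_window `c(lo, hi)` window for the plateau mean.
#' @return Normalized numeric vector.
#' @export
normalize_profile <- function(y, mode = c("max", "anterior_plateau"),
                              x = NULL, anterior_window = NULL) {
  mode <- match.arg(mode)
  norm <- if (mode == "max") {
    max(y)
  } else {
    if (is.null(x) || is.null(anterior_window)) {
      abort("anterior_plateau mode needs `x` and `anterior_window`",
            class = "cidecomp_argument_error")
    }
    idx <- x >= anterior_window[1] & x <= anterior_window[2]
    if (!any(idx)) abort("empty anterior window",
                         class = "cidecomp_argument_error")
    mean(y[idx])
  }
  if (!is.finite(norm) || norm <= 0) {
    abort("normalizing constant must be positive",
          class = "cidecomp_argument_error")
  }
  y / norm
}
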