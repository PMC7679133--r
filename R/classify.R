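#' Classify the qualitative shape of a Ci-155 profile
#'
#' Automated shape classifier for the genotype signatures seen at the AP
#' border. Using the ptc-lacZ landmarks of the same disc set, it computes,
#' on territory anterior of the boundary:
#' \itemize{
#'   \item `ci_ant`: mean Ci-155 over the anterior plateau window;
#'   \item `ci_border_max` and its position, over territory posterior of the
#'     ptc-lacZ initial rise;
#'   \item `ci_boundary`: Ci-155 at the boundary (x = 0);
#'   \item `ptc_induction`: `(peak - baseline) / baseline` of ptc-lacZ.
#' }
#' and assigns one of three shape classes:
#' \describe{
#'   \item{interior_peak}{Ci-155 rises above the anterior plateau
#'     (`ci_border_max > rise_thresh * ci_ant`), peaks strictly between the
#'     ptc-lacZ initial rise and the boundary, and declines again toward the
#'     boundary — the wild-type signature.}
#'   \item{flat_decline}{no interior rise, but a marked decline at the
#'     boundary (`ci_boundary < decline_thresh * ci_ant`) — the signature of
#'     processing-resistant, activatable variants, where only Hh-stimulated
#'     degradation shapes the profile.}
#'   \item{flat_no_decline}{neither rise nor decline. Combined with
#'     `weak_ptc` this separates weakly activatable variants (flat, high,
#'     weak ptc) from destabilized backgrounds (flat, low, normal ptc) when
#'     a `reference_level` (e.g. the wild-type anterior plateau) is given.}
#' }
#'
#' @param aligned An `aligned_profiles` object (or its summary tibble) with
#'   both channels.
#' @param reference_level Optional anterior-plateau Ci-155 level of a
#'   reference genotype; enables the `level` call (`"low"`, `"normal"`,
#'   `"high"`).
#' @param rise_thresh Interior-peak threshold on `ci_border_max / ci_ant`.
#' @param decline_thresh Boundary-decline threshold on
#'   `ci_boundary / ci_ant`.
#' @param weak_ptc_thresh `ptc_induction` below this is called weak.
#' @param level_thresh Relative deviation from `reference_level` beyond
#'   which the level is called `"low"`/`"high"`.
#' @return A one-row tibble: `class`, `weak_ptc`, `level`, and the numeric
#'   features.
#' @export
classify_ci_shape <- function(aligned, reference_level = NULL,
                              rise_thresh = 1.3, decline_thresh = 0.6,
                              weak_ptc_thresh = 4, level_thresh = 0.4) {
  summ <- if (inherits(aligned, "aligned_profiles")) aligned$summary
          else aligned
  summ <- filter(summ, .data$x <= 0)
  lm <- find_landmarks(
    summ |> dplyr::rename(intensity = "mean") |> mutate(disc_id = "mean"),
    channel = "ptc-lacZ")
  ci <- summ |> filter(.data$channel == "Ci-155") |> arrange(.data$x)

  ant_hi <- min(ci$x) + 0.2 * diff(range(ci$x))
  ci_ant <- mean(ci$mean[ci$x <= ant_hi])
  border <- ci |> filter(.data$x > lm$x_rise)
  i_max <- which.max(border$mean)
  ci_border_max <- border$mean[i_max]
  x_ci_max <- border$x[i_max]
  ci_boundary <- ci$mean[which.min(abs(ci$x))]
  ptc_induction <- (lm$peak_value - lm$baseline) / lm$baseline

  interior <- x_ci_max > lm$x_rise && x_ci_max < 0
  cls <- if (ci_border_max > rise_thresh * ci_ant && interior &&
             ci_boundary < 0.9 * ci_border_max) {
    "interior_peak"
  } else if (ci_boundary < decline_thresh * ci_ant) {
    "flat_decline"
  } else {
    "flat_no_decline"
  }
  weak_ptc <- ptc_induction < weak_ptc_thresh
  level <- if (is.null(reference_level)) {
    NA_character_
  } else if (ci_ant < (1 - level_thresh) * reference_level) {
    "low"
  } else if (ci_ant > (1 + level_thresh) * reference_level) {
    "high"
  } else "normal"

  tibble(class = cls, weak_ptc = weak_ptc, level = level,
         ci_ant = ci_ant, ci_border_max = ci_border_max,
         x_ci_max = x_ci_max, ci_boundary = ci_boundary,
         ptc_induction = ptc_induction)
}
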