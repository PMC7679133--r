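#' Plot an aligned profile set
#'
#' Mean intensity per channel with a mean +/- SEM ribbon, anterior to the
#' left, and a dashed line at the reference landmark (x = 0).
#'
#' @param object An `aligned_profiles` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot aligned_profiles
#' @export
autoplot.aligned_profiles <- function(object, ...) {
  d <- object$summary
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$mean,
                                  colour = .data$channel,
                                  fill = .data$channel)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25, colour = NA, na.rm = TRUE) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "position along AP axis (µm, boundary at 0)",
                  y = "intensity (a.u.)",
                  title = object$genotype %||% NULL) +
    ggplot2::theme_minimal()
}

#' Overlay plot of a Ci-155 decomposition
#'
#' Wild-type and averaged resistant Ci-155 traces, the inferred
#' no-reduction curve, and vertical guide lines at the inhibition landmarks
#' (first, 50%, fully inhibited).
#'
#' @param object A `ci_decomposition` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ci_decomposition
#' @export
autoplot.ci_decomposition <- function(object, ...) {
  td <- tidy(object)
  long <- tidyr::pivot_longer(
    td[c("x", "c_wt", "c_resistant_avg", "c_nored")],
    cols = -"x", names_to = "curve", values_to = "intensity")
  long$curve <- factor(long$curve,
                       levels = c("c_wt", "c_resistant_avg", "c_nored"),
                       labels = c("Ci-WT", "resistant average",
                                  "no-reduction (inferred)"))
  inh <- object$inhibition
  guides <- tibble(
    x = c(inh$x_first_inh, inh$x_half_inh, inh$x_full_inh),
    what = c("first", "50%", "full"))
  guides <- guides[!is.na(guides$x), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$intensity,
                                     colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = guides,
                        ggplot2::aes(xintercept = .data$x),
                        linetype = "dotted", colour = "blue") +
    ggplot2::scale_colour_manual(values = c("black", "grey50", "blue")) +
    ggplot2::labs(x = "position along AP axis (µm, boundary at 0)",
                  y = "Ci-155 intensity (a.u.)", colour = NULL,
                  subtitle = "dotted lines: processing first/50%/fully inhibited") +
    ggplot2::theme_minimal()
}

#' Genotype summary bar plot of relative expression
#'
#' Mean with SEM error bars per genotype for one normalization formula,
#' as in mosaic-clone quantification figures.
#'
#' @param values Tibble from [relative_expression()] (may pool genotypes).
#' @return A ggplot object.
#' @export
plot_relative_expression <- function(values) {
  summ <- values |>
    group_by(.data$genotype, .data$formula) |>
    summarise(sem = sd(.data$value) / sqrt(dplyr::n()),
              mean = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$genotype, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.3, na.rm = TRUE) +
    ggplot2::facet_wrap(~formula) +
    ggplot2::labs(y = "expression relative to AP border") +
    ggplot2::theme_minimal()
}
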