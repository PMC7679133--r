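rel_formulas <- c("ptc_subtracted", "ptc_ratio_clone", "ptc_ratio_anterior",
                  "ci155_subtracted_clone", "ci155_subtracted_anterior")

formula_channel <- function(formula) {
  if (grepl("^ptc", formula)) "ptc-lacZ" else "Ci-155"
}

# One relative-expression value from the four region means.
rel_expr_value <- function(clone, anterior, ap_border, posterior, formula,
                           disc_id = "?") {
  den_err <- function(what) {
    abort(sprintf("disc '%s': %s denominator is zero", disc_id, what),
          class = "cidecomp_degenerate_error")
  }
  switch(formula,
    ptc_subtracted = {
      d <- ap_border - anterior
      if (d == 0) den_err("AP border - anterior")
      (clone - anterior) / d
    },
    ptc_ratio_clone = {
      if (ap_border == 0) den_err("AP border")
      clone / ap_border
    },
    ptc_ratio_anterior = {
      if (ap_border == 0) den_err("AP border")
      anterior / ap_border
    },
    ci155_subtracted_clone = {
      d <- ap_border - posterior
      if (d == 0) den_err("AP border - posterior")
      (clone - posterior) / d
    },
    ci155_subtracted_anterior = {
      d <- ap_border - posterior
      if (d == 0) den_err("AP border - posterior")
      (anterior - posterior) / d
    },
    abort(sprintf("unknown formula '%s'", formula),
          class = "cidecomp_argument_error")
  )
}

#' Relative expression of clone regions against AP-border reference
#'
#' Applies the region-normalization formulas used for mosaic-clone
#' quantification to a tidy region-mean table. Each disc contributes one
#' value per formula. The formulas are:
#' \describe{
#'   \item{ptc_subtracted}{`(clone - anterior) / (AP border - anterior)`,
#'     with the anterior level subtracted from both because ptc-lacZ can be
#'     expressed artifactually in posterior cells.}
#'   \item{ptc_ratio_clone / ptc_ratio_anterior}{clone (or anterior)
#'     intensity divided by AP-border intensity, without subtraction.}
#'   \item{ci155_subtracted_clone / ci155_subtracted_anterior}{clone (or
#'     anterior) Ci-155 relative to the AP border after subtracting the
#'     posterior background from both:
#'     `(region - posterior) / (AP border - posterior)`.}
#' }
#' Values of 1 mean "equal to the AP-border reference"; values below 0 or
#' above 1 are valid (clone Ci-155 can exceed AP-border levels).
#'
#' @param regions Tidy table with columns `disc_id`, `channel`, `region`
#'   (`clone`, `anterior`, `ap_border`, `posterior`), `mean_intensity`, and
#'   optionally `genotype`/`scenario`/`replicate_idx`.
#' @param formula One of the formula tags above.
#' @param aggregate `"before"` (default) averages a disc's replicate regions
#'   before applying the formula; `"after"` applies the formula per
#'   `replicate_idx` (which must match across regions) and averages the
#'   resulting values.
#' @return A tibble with one row per disc: `disc_id`, `genotype`, `channel`,
#'   `formula`, `value`.
#' @export
#' @examples
#' regions <- tibble::tibble(
#'   disc_id = "d1", genotype = "WT", channel = "ptc-lacZ",
#'   region = c("clone", "anterior", "ap_border", "posterior"),
#'   mean_intensity = c(5, 2, 8, 1))
#' relative_expression(regions, "ptc_subtracted")   # (5-2)/(8-2) = 0.5
relative_expression <- function(regions, formula,
                                aggregate = c("before", "after")) {
  aggregate <- match.arg(aggregate)
  if (!formula %in% rel_formulas) {
    abort(sprintf("unknown formula '%s' (have: %s)", formula,
                  paste(rel_formulas, collapse = ", ")),
          class = "cidecomp_argument_error")
  }
  ch <- formula_channel(formula)
  d <- filter(regions, .data$channel == ch)
  if (nrow(d) == 0) {
    abort("no measurements for the formula's channel",
          class = "cidecomp_argument_error")
  }
  if (any(!is.finite(d$mean_intensity)) || any(d$mean_intensity < 0)) {
    abort("region means must be finite and >= 0",
          class = "cidecomp_argument_error")
  }
  needs <- switch(formula,
    ptc_subtracted = c("clone", "anterior", "ap_border"),
    ptc_ratio_clone = c("clone", "ap_border"),
    ptc_ratio_anterior = c("anterior", "ap_border"),
    c("ap_border", "posterior",
      if (grepl("clone$", formula)) "clone" else "anterior"))

  one_disc <- function(dd) {
    id <- dd$disc_id[1]
    missing <- setdiff(needs, unique(dd$region))
    if (length(missing)) {
      abort(sprintf("disc '%s' lacks region(s): %s", id,
                    paste(missing, collapse = ", ")),
            class = "cidecomp_argument_error")
    }
    gmean <- function(sub) {
      m <- setNames(rep(NA_real_, 4),
                    c("clone", "anterior", "ap_border", "posterior"))
      agg <- sub |> group_by(.data$region) |>
        summarise(v = mean(.data$mean_intensity), .groups = "drop")
      m[agg$region] <- agg$v
      m
    }
    value <- if (aggregate == "before" || !"replicate_idx" %in% names(dd)) {
      m <- gmean(dd)
      rel_expr_value(m[["clone"]], m[["anterior"]], m[["ap_border"]],
                     m[["posterior"]], formula, disc_id = id)
    } else {
      reps <- sort(unique(dd$replicate_idx))
      vals <- purrr::map_dbl(reps, function(r) {
        m <- gmean(filter(dd, .data$replicate_idx == r))
        if (any(is.na(m[needs]))) {
          abort(sprintf(
            "disc '%s': replicate %s does not cover all regions needed for aggregate = 'after'",
            id, r), class = "cidecomp_argument_error")
        }
        rel_expr_value(m[["clone"]], m[["anterior"]], m[["ap_border"]],
                       m[["posterior"]], formula, disc_id = id)
      })
      mean(vals)
    }
    tibble(disc_id = id,
           genotype = if ("genotype" %in% names(dd)) dd$genotype[1]
                      else NA_character_,
           channel = ch, formula = formula, value = value)
  }

  d |> group_by(.data$disc_id) |> group_split() |>
    purrr::map(one_disc) |> bind_rows()
}

#' Mean, SEM and n of relative-expression values
#'
#' @param values Numeric vector, or a tibble from [relative_expression()]
#'   (its `value` column is used).
#' @return One-row tibble: `mean`, `sem` (sample SD / sqrt(n); `NA` and
#'   flagged when n = 1), `n`, `sem_defined`.
#' @export
summarize_relative <- function(values) {
  if (is.data.frame(values)) values <- values$value
  if (!length(values)) {
    abort("no values to summarize", class = "cidecomp_argument_error")
  }
  n <- length(values)
  tibble(mean = mean(values),
         sem = if (n >= 2) sd(values) / sqrt(n) else NA_real_,
         n = n, sem_defined = n >= 2)
}

significance_mark <- function(p) {
  dplyr::case_when(p < 0.001 ~ "*", p < 0.05 ~ "#", .default = "")
}

#' Compare two groups of relative-expression values
#'
#' Two-sided t-test between groups with the figure-legend significance
#' convention: `"*"` for p < 0.001, `"#"` for p < 0.05. `test = "paired"`
#' performs a one-sample t-test on within-pair differences and requires a
#' pairing key (values are matched on it); `test = "two_sample"` performs
#' Welch's unequal-variance t-test, appropriate when the two groups come
#' from different discs and cannot be paired.
#'
#' @param a,b Numeric vectors, or tibbles from [relative_expression()].
#' @param test `"two_sample"` (default) or `"paired"`.
#' @param pairing_a,pairing_b Keys matching paired observations (e.g.
#'   disc ids); required for the paired test unless both inputs are
#'   tibbles carrying `disc_id`.
#' @param labels Length-2 group labels for the report.
#' @return A one-row tibble: group labels, `n`, `mean`, `sem` per group,
#'   `test`, `t_stat`, `df`, `p_value`, `significance_mark`.
#' @export
compare_groups <- function(a, b, test = c("two_sample", "paired"),
                           pairing_a = NULL, pairing_b = NULL,
                           labels = c("A", "B")) {
  test <- match.arg(test)
  if (is.data.frame(a)) {
    if (is.null(pairing_a) && "disc_id" %in% names(a)) pairing_a <- a$disc_id
    if (length(labels) == 2 && identical(labels, c("A", "B")) &&
        "genotype" %in% names(a)) labels[1] <- a$genotype[1]
    a <- a$value
  }
  if (is.data.frame(b)) {
    if (is.null(pairing_b) && "disc_id" %in% names(b)) pairing_b <- b$disc_id
    if (length(labels) == 2 && "genotype" %in% names(b) &&
        labels[2] == "B") labels[2] <- b$genotype[1]
    b <- b$value
  }
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs at least 2 values",
          class = "cidecomp_argument_error")
  }
  if (test == "paired") {
    if (length(a) != length(b)) {
      abort("paired test requires equal group sizes",
            class = "cidecomp_argument_error")
    }
    if (!is.null(pairing_a) || !is.null(pairing_b)) {
      if (is.null(pairing_a) || is.null(pairing_b) ||
          !setequal(pairing_a, pairing_b)) {
        abort("paired test requires matching pairing keys",
              class = "cidecomp_argument_error")
      }
      b <- b[match(pairing_a, pairing_b)]
    } else {
      warn("paired test without pairing keys: pairing by position")
    }
    diffs <- a - b
    if (sd(diffs) == 0) {
      abort("degenerate paired test: all within-pair differences are equal",
            class = "cidecomp_degenerate_error")
    }
    ht <- stats::t.test(diffs)
  } else {
    if (sd(a) == 0 && sd(b) == 0) {
      abort("degenerate two-sample test: both groups have zero variance",
            class = "cidecomp_degenerate_error")
    }
    ht <- stats::t.test(a, b, var.equal = FALSE)
  }
  sa <- summarize_relative(a); sb <- summarize_relative(b)
  tibble(
    group_a = labels[1], group_b = labels[2],
    n_a = sa$n, n_b = sb$n,
    mean_a = sa$mean, mean_b = sb$mean,
    sem_a = sa$sem, sem_b = sb$sem,
    test = test,
    t_stat = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    significance_mark = significance_mark(ht$p.value)
  )
}
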