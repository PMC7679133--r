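test_that("normalization formulas match hand arithmetic", {
  r <- fx_regions(clone = 5, anterior = 2, ap_border = 8, posterior = 1)
  expect_equal(relative_expression(r, "ptc_subtracted")$value, 0.5,
               tolerance = 1e-12)
  expect_equal(relative_expression(fx_regions(8, 2, 8, 1),
                                   "ptc_subtracted")$value, 1)
  expect_equal(relative_expression(fx_regions(2, 2, 8, 1),
                                   "ptc_subtracted")$value, 0)
  expect_equal(relative_expression(fx_regions(6, 2, 8, 1),
                                   "ptc_ratio_clone")$value, 0.75)
  expect_equal(relative_expression(fx_regions(6, 0, 8, 1),
                                   "ptc_ratio_anterior")$value, 0)

  ci <- fx_regions(9, 3, 5, 1, channel = "Ci-155")
  expect_equal(relative_expression(ci, "ci155_subtracted_clone")$value, 2.0,
               tolerance = 1e-12)   # clone Ci-155 may exceed AP-border levels
  expect_equal(relative_expression(fx_regions(9, 1, 5, 1, channel = "Ci-155"),
                                   "ci155_subtracted_clone")$value, 2.0)
  expect_equal(relative_expression(ci, "ci155_subtracted_anterior")$value,
               0.5, tolerance = 1e-12)

  expect_error(relative_expression(fx_regions(5, 8, 8, 1), "ptc_subtracted"),
               class = "cidecomp_degenerate_error")
  expect_error(relative_expression(r, "not_a_formula"),
               class = "cidecomp_argument_error")
})

test_that("subtracted formulas are affine invariant; ratios scale invariant", {
  withr::local_seed(101)
  for (rep in 1:1000) {
    v <- rexp(4) + 0.1
    a <- rexp(1) + 0.1; b <- rexp(1)
    r0 <- fx_regions(v[1], v[2], v[3], v[4])
    r1 <- fx_regions(a * v[1] + b, a * v[2] + b, a * v[3] + b, a * v[4] + b)
    expect_equal(relative_expression(r1, "ptc_subtracted")$value,
                 relative_expression(r0, "ptc_subtracted")$value,
                 tolerance = 1e-9)
    c0 <- fx_regions(v[1], v[2], v[3], v[4], channel = "Ci-155")
    c1 <- fx_regions(a * v[1] + b, a * v[2] + b, a * v[3] + b, a * v[4] + b,
                     channel = "Ci-155")
    expect_equal(relative_expression(c1, "ci155_subtracted_clone")$value,
                 relative_expression(c0, "ci155_subtracted_clone")$value,
                 tolerance = 1e-9)
    # pure rescaling leaves the ratio unchanged; an offset does not
    r2 <- fx_regions(a * v[1], a * v[2], a * v[3], a * v[4])
    expect_equal(relative_expression(r2, "ptc_ratio_clone")$value,
                 relative_expression(r0, "ptc_ratio_clone")$value,
                 tolerance = 1e-9)
  }
})

test_that("replicate regions can be averaged before or after normalization", {
  reg <- tibble::tibble(
    disc_id = "d1", genotype = "g", channel = "ptc-lacZ",
    region = rep(c("clone", "anterior", "ap_border"), each = 2),
    replicate_idx = rep(1:2, 3),
    mean_intensity = c(5, 7, 2, 2, 8, 10))
  before <- relative_expression(reg, "ptc_subtracted", aggregate = "before")
  expect_equal(before$value, (6 - 2) / (9 - 2), tolerance = 1e-12)
  after <- relative_expression(reg, "ptc_subtracted", aggregate = "after")
  expect_equal(after$value, mean(c((5 - 2) / (8 - 2), (7 - 2) / (10 - 2))),
               tolerance = 1e-12)
})

test_that("summaries report mean and sample SEM, flagged for n = 1", {
  s <- summarize_relative(c(2, 4, 6))
  expect_equal(s$mean, 4)
  expect_equal(s$sem, 2 / sqrt(3), tolerance = 1e-12)
  s1 <- summarize_relative(5)
  expect_equal(s1$mean, 5)
  expect_true(is.na(s1$sem) && !s1$sem_defined)
  expect_error(summarize_relative(numeric(0)),
               class = "cidecomp_argument_error")

  withr::local_seed(5)
  v <- rnorm(1000)
  s2 <- summarize_relative(v)
  expect_equal(s2$sem, sqrt(sum((v - mean(v))^2) / 999) / sqrt(1000),
               tolerance = 1e-12)
})

test_that("t-tests match closed forms and flag significance correctly", {
  got <- compare_groups(c(1, 2, 3), c(2, 3, 4), test = "two_sample")
  expect_equal(got$t_stat, -1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(got$p_value,
               2 * pt(-abs(-1 / sqrt(2 / 3)), df = 4), tolerance = 1e-12)
  expect_equal(got$significance_mark, "")

  paired <- compare_groups(c(1, 2, 4), c(0, 1, 1), test = "paired",
                           pairing_a = c("a", "b", "c"),
                           pairing_b = c("a", "b", "c"))
  expect_equal(paired$t_stat, 2.5, tolerance = 1e-12)

  expect_error(compare_groups(c(1, 2, 3), c(1, 2, 3), test = "paired",
                              pairing_a = 1:3, pairing_b = 1:3),
               class = "cidecomp_degenerate_error")
  expect_error(compare_groups(1, c(1, 2), test = "two_sample"),
               class = "cidecomp_argument_error")

  expect_equal(cidecomp:::significance_mark(c(0.0005, 0.01, 0.2)),
               c("*", "#", ""))
})

test_that("paired tests respect the pairing key order", {
  a <- c(1, 2, 3); ka <- c("d1", "d2", "d3")
  b <- c(30, 10, 20); kb <- c("d3", "d1", "d2")
  got <- compare_groups(a, b, test = "paired", pairing_a = ka, pairing_b = kb)
  want <- stats::t.test(a - c(10, 20, 30))
  expect_equal(got$t_stat, unname(want$statistic), tolerance = 1e-12)
})

test_that("group means converge to clone ground truth with many discs", {
  p <- sim_params(scale_sd_frac = 0.05, noise_sd_frac = 0.05)
  ds <- simulate_clone_dataset(p, genotype_preset("WT"),
                               clone_preset("pka_loss"),
                               n_discs = 200, seed = 77)
  truth <- attr(ds, "ground_truth_relative")
  vals <- relative_expression(ds, "ptc_subtracted")
  s <- summarize_relative(vals)
  want <- truth$value[truth$formula == "ptc_subtracted"]
  expect_lt(abs(s$mean - want), 3 * s$sem + 0.01 * abs(want))
})
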