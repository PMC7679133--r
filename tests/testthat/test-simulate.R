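test_that("with only basal turnover the Ci-155 profile is flat at s_syn/k_basal", {
  p <- fx_params0(ci_post_bg = 1 / 0.05)
  g <- genotype_spec("inert", processing_competent = FALSE,
                     degradation_competent = FALSE)
  prof <- simulate_profile(p, g)
  ci <- dplyr::filter(prof, channel == "Ci-155")
  expect_equal(ci$intensity, rep(p$s_syn / p$k_basal, nrow(ci)),
               tolerance = 1e-12)
})

test_that("when Hh is confined to the boundary, anterior WT Ci-155 is uniform", {
  p <- fx_params0(lambda_hh = 0.01)
  prof <- simulate_profile(p, genotype_preset("WT"))
  ci <- dplyr::filter(prof, channel == "Ci-155", x < 0)
  expect_equal(ci$intensity,
               rep(p$s_syn / (p$k_basal + p$k_proc0), nrow(ci)),
               tolerance = 1e-9)
})

test_that("parameter validation rejects non-positive rates and lengths", {
  expect_error(sim_params(k_basal = 0), class = "cidecomp_param_error")
  expect_error(sim_params(lambda_hh = -1), class = "cidecomp_param_error")
  expect_error(sim_params(hill_act = c(K = 0, n = 4)),
               class = "cidecomp_param_error")
  expect_error(sim_params(noise_sd_frac = -0.1),
               class = "cidecomp_param_error")
  # anterior plateau requirement
  expect_error(sim_params(x_min = -30), class = "cidecomp_param_error")
})

test_that("additive mode with an overwhelming reduction errors with position", {
  # making degradation respond to lower Hh than processing inhibition lets
  # the reduction exceed the still-low processing-only curve mid-gradient
  expect_error(
    simulate_profile(fx_params0("additive",
                                hill_proc_inh = c(K = 0.9, n = 8),
                                hill_deg = c(K = 0.05, n = 2)),
                     genotype_preset("WT")),
    regexp = "negative at x", class = "cidecomp_param_error")
})

test_that("zero-noise replicate discs are identical and seeded runs reproduce", {
  p <- fx_params0()
  set1 <- simulate_disc_set(p, genotype_preset("WT"), n_discs = 3, seed = 7)
  wide <- tidyr::pivot_wider(set1, names_from = disc_id,
                             values_from = intensity)
  expect_equal(wide$WT_disc1, wide$WT_disc2)
  expect_equal(wide$WT_disc1, wide$WT_disc3)

  pn <- sim_params(seed = 11)
  a <- simulate_disc_set(pn, genotype_preset("WT"), n_discs = 3)
  b <- simulate_disc_set(pn, genotype_preset("WT"), n_discs = 3)
  expect_identical(a$intensity, b$intensity)
  expect_error(simulate_disc_set(pn, genotype_preset("WT"), n_discs = 0),
               class = "cidecomp_argument_error")
})

test_that("multiplicative noise has the configured relative SD", {
  p <- sim_params(noise_sd_frac = 0.05, offset_sd = 0, scale_sd_frac = 0)
  set <- simulate_disc_set(p, genotype_preset("WT"), n_discs = 100, seed = 3)
  rel <- set |>
    dplyr::filter(channel == "Ci-155", x <= 0) |>
    dplyr::group_by(x) |>
    dplyr::summarise(rel_sd = sd(intensity) / mean(intensity))
  expect_gt(nrow(rel), 200)
  # lognormal with sigma = 0.05 has relative SD sqrt(exp(sigma^2) - 1)
  expect_equal(mean(rel$rel_sd), sqrt(exp(0.05^2) - 1), tolerance = 0.1)
})

test_that("kinetic-mode traces are positive with monotone component rates", {
  for (g in c("WT", "S849A", "D1270_1370", "SufuNull")) {
    tr <- fx_truth(g)
    ant <- tr[tr$x <= 0, ]
    expect_true(all(ant$ci > 0))
    expect_true(all(diff(ant$k_proc) <= 1e-12))  # non-increasing toward boundary
    expect_true(all(diff(ant$k_deg) >= -1e-12))  # non-decreasing toward boundary
  }
})

test_that("WT peaks interior to the border; resistant peaks on the anterior plateau", {
  p <- fx_params0()
  wt <- simulate_profile(p, genotype_preset("WT"))
  lm <- find_landmarks(wt)
  tr <- attr(wt, "truth")
  ant <- tr[tr$x <= 0, ]
  x_peak_ci <- ant$x[which.max(ant$ci)]
  expect_gt(x_peak_ci, lm$x_rise)
  expect_lt(x_peak_ci, 0)

  res <- attr(simulate_profile(p, genotype_preset("S849A")), "truth")
  res_ant <- res[res$x <= 0, ]
  expect_lt(res_ant$x[which.max(res_ant$ci)], lm$x_rise)
})

test_that("additive-mode output satisfies C + R = processing-only curve exactly", {
  for (g in c("WT", "S849A")) {
    tr <- fx_truth(g, mode = "additive")
    ant <- tr[tr$x <= 0, ]
    expect_equal(ant$ci + ant$r_true, ant$c_proc_only, tolerance = 1e-15)
  }
})

test_that("rendered images round-trip through profile extraction", {
  p <- fx_params0()
  prof <- simulate_profile(p, genotype_preset("WT"))
  img <- render_image(prof, height = 20, noise_sd_frac = 0)
  back <- extract_profile(img)
  ci <- dplyr::filter(prof, channel == "Ci-155") |> dplyr::arrange(x)
  expect_equal(back$intensity, ci$intensity, tolerance = 1e-12)
  expect_equal(back$x, ci$x)

  flat <- prof |> dplyr::mutate(intensity = 7)
  img2 <- render_image(flat, height = 5, noise_sd_frac = 0)
  expect_true(all(img2 == 7))
})

test_that("noisy image column means satisfy the CLT bound", {
  p <- fx_params0()
  prof <- simulate_profile(p, genotype_preset("WT"))
  v <- dplyr::filter(prof, channel == "ptc-lacZ") |>
    dplyr::arrange(x) |> dplyr::pull(intensity)
  h <- 200; s <- 0.1
  img <- render_image(prof, channel = "ptc-lacZ", height = h,
                      noise_sd_frac = s, seed = 5)
  mu <- v * exp(s^2 / 2)              # lognormal mean of the noise factor
  within <- abs(colMeans(img) - mu) <= 3 * (s * v / sqrt(h))
  expect_gte(mean(within), 0.99)
})

test_that("clone dataset with empty overrides gives clone == anterior", {
  p <- fx_params0()
  ds <- simulate_clone_dataset(p, genotype_preset("WT"),
                               clone_scenario("none"), n_discs = 2)
  vals <- relative_expression(ds, "ptc_subtracted")
  expect_equal(vals$value, rep(0, 2), tolerance = 1e-12)
})

test_that("a clone engineered to match the AP border scores exactly 1", {
  p <- fx_params0()
  clean <- attr(simulate_clone_dataset(p, genotype_preset("WT"),
                                       clone_scenario("none"), n_discs = 1),
                "clean_means")
  ap_ptc <- clean$clean_mean[clean$channel == "ptc-lacZ" &
                             clean$region == "ap_border"]
  a <- (ap_ptc - p$ptc_base) / p$ptc_gain  # activity that reproduces it
  ds <- simulate_clone_dataset(p, genotype_preset("WT"),
                               clone_scenario("match", list(activity = a)),
                               n_discs = 1)
  vals <- relative_expression(ds, "ptc_subtracted")
  expect_equal(vals$value, 1, tolerance = 1e-12)
})

test_that("pka-loss clone values round-trip against generator ground truth", {
  p <- fx_params0()
  ds <- simulate_clone_dataset(p, genotype_preset("WT"), clone_preset("pka_loss"),
                               n_discs = 3)
  truth <- attr(ds, "ground_truth_relative")
  for (f in unique(truth$formula)) {
    vals <- relative_expression(ds, f)
    expect_equal(vals$value, rep(truth$value[truth$formula == f], 3),
                 tolerance = 1e-12, label = f)
  }
})
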