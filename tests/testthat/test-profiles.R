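test_that("ROI extraction is the per-column mean over rows", {
  img <- matrix(7, nrow = 10, ncol = 8)
  expect_equal(extract_profile(img)$intensity, rep(7, 8))

  img2 <- rbind(c(1, 2, 3), c(3, 4, 5))
  expect_equal(extract_profile(img2)$intensity, c(2, 3, 4))

  expect_error(extract_profile(img, roi = c(0, 0, 9, 10)),
               class = "cidecomp_bounds_error")
  expect_error(extract_profile(img, roi = c(0, 0, 0, 5)),
               class = "cidecomp_argument_error")
})

test_that("ROI extraction matches a brute-force column loop on random images", {
  withr::local_seed(42)
  for (rep in 1:100) {
    nr <- sample(5:60, 1); nc <- sample(5:200, 1)
    img <- matrix(rexp(nr * nc), nr, nc)
    h <- sample(seq_len(nr), 1); w <- sample(seq_len(nc), 1)
    y0 <- sample(0:(nr - h), 1); x0 <- sample(0:(nc - w), 1)
    got <- extract_profile(img, roi = c(x0, y0, w, h))$intensity
    want <- vapply(seq_len(w), function(j) {
      s <- 0
      for (i in seq_len(h)) s <- s + img[y0 + i, x0 + j]
      s / h
    }, numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("moving-average smoothing matches its definition", {
  expect_equal(smooth_profile(rep(3, 10)), rep(3, 10))
  expect_equal(smooth_profile(c(0, 0, 0, 5, 0, 0, 0), window = 5)[4], 1.0)
  expect_error(smooth_profile(1:10, window = 4),
               class = "cidecomp_argument_error")
  expect_error(smooth_profile(1:3, window = 5),
               class = "cidecomp_argument_error")
})

test_that("smoothing matches a brute-force windowed mean with edge shrinkage", {
  brute <- function(y, window) {
    w <- (window - 1) / 2
    n <- length(y)
    out <- numeric(n)
    for (i in seq_len(n)) {
      acc <- 0; k <- 0
      for (j in max(1, i - w):min(n, i + w)) {
        acc <- acc + y[j]; k <- k + 1
      }
      out[i] <- acc / k
    }
    out
  }
  withr::local_seed(7)
  for (rep in 1:100) {
    n <- sample(5:120, 1)
    y <- rnorm(n)
    window <- sample(c(1, 3, 5, 7), 1)
    if (window > n) window <- 1
    got <- smooth_profile(y, window)
    expect_equal(got, brute(y, window), tolerance = 1e-12)
    expect_true(all(got >= min(y) - 1e-12 & got <= max(y) + 1e-12))
  }
})

test_that("landmark detection finds baseline, rise, half-rise and peak", {
  # baseline 1 up to x = 4, linear ramp to 9 at x = 8: half level 5 at x = 6
  x <- 0:8
  y <- c(rep(1, 5), 3, 5, 7, 9)
  pr <- tibble::tibble(disc_id = "d", x = x, channel = "ptc-lacZ",
                       intensity = y)
  lm <- find_landmarks(pr, baseline_window = c(0, 3))
  expect_equal(lm$baseline, 1)
  expect_equal(lm$x_half, 6)
  expect_equal(lm$x_peak, 8)
  expect_lte(lm$x_rise, lm$x_half)

  flat <- dplyr::mutate(pr, intensity = 2)
  expect_error(find_landmarks(flat, baseline_window = c(0, 3)),
               class = "cidecomp_no_response")
})

test_that("simulated ptc half-rise matches the closed-form Hill inversion", {
  p <- fx_params0()
  prof <- simulate_profile(p, genotype_preset("WT"))
  lm <- find_landmarks(prof)
  K <- p$hill_act[["K"]]; n <- p$hill_act[["n"]]
  a_top <- 1 / (1 + K^n)          # activity at the boundary (H = 1)
  a_base <- mean((dplyr::filter(prof, channel == "ptc-lacZ",
                                x <= p$x_min + 0.25 * (p$x_max - p$x_min)) |>
                    dplyr::pull(intensity) - p$ptc_base) / p$ptc_gain)
  a_half <- a_base + 0.5 * (a_top - a_base)
  h_half <- K * (a_half / (1 - a_half))^(1 / n)
  x_analytic <- p$lambda_hh * log(h_half)
  expect_lte(abs(lm$x_half - x_analytic), p$grid_step)
})

test_that("alignment undoes known shifts and averages on the overlap", {
  p <- fx_params0()
  base <- simulate_profile(p, genotype_preset("WT"), disc_id = "a")
  shifted <- base |>
    dplyr::mutate(disc_id = "b", x = x + 3 * p$grid_step)
  aligned <- align_profiles(dplyr::bind_rows(base, shifted), min_discs = 2)
  # both discs land on the same curve: per-disc deviation from the mean is 0
  dev <- aligned$per_disc |>
    dplyr::left_join(aligned$summary, by = c("x", "channel")) |>
    dplyr::filter(n == 2)
  expect_lt(max(abs(dev$intensity - dev$mean)), 1e-9)
  # the aligned mean reproduces the unshifted profile (whose peak is at 0)
  chk <- aligned$summary |>
    dplyr::filter(channel == "Ci-155", n == 2) |>
    dplyr::inner_join(dplyr::filter(base, channel == "Ci-155"), by = "x")
  expect_lt(max(abs(chk$mean - chk$intensity)), 1e-9)
})

test_that("a single profile aligns to itself with undefined SEM", {
  p <- fx_params0()
  base <- simulate_profile(p, genotype_preset("WT"))
  expect_warning(aligned <- align_profiles(base), "usable disc")
  chk <- aligned$summary |>
    dplyr::filter(channel == "Ci-155") |>
    dplyr::inner_join(dplyr::filter(base, channel == "Ci-155"), by = "x")
  expect_equal(chk$mean, chk$intensity, tolerance = 1e-12)
  expect_true(all(is.na(aligned$summary$sem)))
  expect_true(all(aligned$summary$n == 1))
})

test_that("alignment recovers simulated disc offsets within one grid step", {
  p <- sim_params(noise_sd_frac = 0, scale_sd_frac = 0, offset_sd = 5)
  set <- simulate_disc_set(p, genotype_preset("WT"), n_discs = 3, seed = 21)
  aligned <- align_profiles(set)
  eff <- attr(set, "disc_effects")
  chk <- dplyr::left_join(aligned$shifts, eff, by = "disc_id")
  expect_lte(max(abs(chk$x_ref - chk$offset)), p$grid_step)
})

test_that("alignment is equivariant under a common translation", {
  p <- sim_params(noise_sd_frac = 0.02, scale_sd_frac = 0, offset_sd = 2,
                  seed = 9)
  set <- simulate_disc_set(p, genotype_preset("WT"), n_discs = 3)
  a1 <- align_profiles(set)
  a2 <- align_profiles(dplyr::mutate(set, x = x + 12.5))
  common <- intersect(a1$grid, a2$grid)
  s1 <- dplyr::filter(a1$summary, x %in% common)
  s2 <- dplyr::filter(a2$summary, x %in% common)
  expect_equal(s1$mean, s2$mean, tolerance = 1e-9)
})

test_that("per-position SEM equals the brute-force sample formula", {
  p <- sim_params(noise_sd_frac = 0.1, scale_sd_frac = 0, offset_sd = 0,
                  seed = 13)
  set <- simulate_disc_set(p, genotype_preset("WT"), n_discs = 4)
  aligned <- align_profiles(set, min_discs = 3)
  wide <- aligned$per_disc |>
    dplyr::filter(channel == "Ci-155") |>
    tidyr::pivot_wider(id_cols = x, names_from = disc_id,
                       values_from = intensity)
  mat <- as.matrix(wide[, -1])
  brute_sem <- apply(mat, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    sqrt(sum((v - mean(v))^2) / (length(v) - 1)) / sqrt(length(v))
  })
  got <- dplyr::filter(aligned$summary, channel == "Ci-155")$sem
  expect_equal(got, unname(brute_sem), tolerance = 1e-12)
})

test_that("landmark ordering holds on every accepted noisy profile", {
  p <- sim_params(seed = 17)
  set <- simulate_disc_set(p, genotype_preset("WT"), n_discs = 20)
  for (id in unique(set$disc_id)) {
    lm <- find_landmarks(dplyr::filter(set, disc_id == id))
    expect_true(lm$x_rise <= lm$x_half && lm$x_half <= lm$x_peak)
  }
})

test_that("non-uniform or disordered position grids are rejected", {
  pr <- tibble::tibble(disc_id = "d", x = c(0, 1, 2, 4, 8),
                       channel = "ptc-lacZ", intensity = c(1, 1, 2, 5, 9))
  expect_error(align_profiles(pr), class = "cidecomp_grid_error")
})

test_that("normalization modes behave and reject degenerate input", {
  expect_equal(normalize_profile(c(2, 4, 8)), c(0.25, 0.5, 1))
  expect_equal(normalize_profile(c(0.25, 0.5, 1)), c(0.25, 0.5, 1))
  y <- rexp(20) + 0.1
  expect_equal(normalize_profile(5.3 * y), normalize_profile(y),
               tolerance = 1e-12)
  expect_equal(normalize_profile(y, mode = "anterior_plateau", x = 1:20,
                                 anterior_window = c(1, 5)),
               y / mean(y[1:5]), tolerance = 1e-12)
  expect_error(normalize_profile(c(0, 0)), class = "cidecomp_argument_error")
})
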