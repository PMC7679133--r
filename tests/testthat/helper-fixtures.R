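# Shared fixtures, built once per test run and cached.
.fx <- new.env(parent = emptyenv())

fx_cached <- function(key, builder) {
  if (!exists(key, envir = .fx)) assign(key, builder(), envir = .fx)
  get(key, envir = .fx)
}

# Noise-free parameter set (jitter and noise off), kinetic or additive.
fx_params0 <- function(mode = "kinetic", ...) {
  sim_params(noise_sd_frac = 0, offset_sd = 0, scale_sd_frac = 0,
             mode = mode, ...)
}

# Noise-free three-disc profile table for the decomposition genotypes.
fx_profiles0 <- function(mode = "kinetic") {
  fx_cached(paste0("profiles0_", mode), function() {
    p <- fx_params0(mode)
    dplyr::bind_rows(lapply(c("WT", "S849A", "P13A"), function(g) {
      simulate_disc_set(p, genotype_preset(g), n_discs = 3, seed = 1)
    }))
  })
}

fx_decomp0 <- function(mode = "kinetic") {
  fx_cached(paste0("decomp0_", mode), function() {
    decompose_ci_profiles(fx_profiles0(mode), smooth = FALSE)
  })
}

# Ground-truth curves of the noise-free simulation for one genotype.
fx_truth <- function(genotype = "WT", mode = "kinetic") {
  attr(simulate_profile(fx_params0(mode), genotype_preset(genotype)), "truth")
}

# Minimal hand-made region table: one disc, one channel, one value/region.
fx_regions <- function(clone, anterior, ap_border, posterior,
                       channel = "ptc-lacZ", disc_id = "d1",
                       genotype = "g") {
  tibble::tibble(
    disc_id = disc_id, genotype = genotype, channel = channel,
    region = c("clone", "anterior", "ap_border", "posterior"),
    mean_intensity = c(clone, anterior, ap_border, posterior))
}
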