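#' Parameters of the steady-state wing-disc simulator
#'
#' Constructs the parameter set of the generative model used by
#' [simulate_profile()] and friends. The model places the anterior-posterior
#' (AP) compartment boundary at `x = 0` with anterior positions negative, in
#' micrometres, matching the usual "anterior is left" display convention. Hh
#' spreading from the posterior compartment decays exponentially with length
#' `lambda_hh` anterior of the boundary; pathway activity, inhibition of
#' Ci-155 processing, and Hh-stimulated Ci-155 degradation are Hill-function
#' readouts of the local Hh level (or of activity, for degradation).
#'
#' At steady state in `"kinetic"` mode the full-length Ci level is
#' \deqn{C(x) = s_{syn} / (k_{basal} + k_{proc}(x) + k_{deg}(x))}
#' with \eqn{k_{proc}(x) = k_{proc0} (1 - Hill_{pi}(H(x)))} and
#' \eqn{k_{deg}(x) = k_{deg0} Hill_{deg}(A(x))}, where
#' \eqn{A(x) = f \cdot Hill_{act}(H(x))} is pathway activity and
#' `ptc-lacZ` intensity is the affine readout `ptc_base + ptc_gain * A(x)`.
#'
#' `"additive"` mode generates profiles for which the genotype-subtraction
#' decomposition is exactly invertible: the processing-only curve is
#' \eqn{C_{proc}(x) = C_{lo} + (C_{hi} - C_{lo}) Hill_{pi}(H(x))} and an
#' additive reduction \eqn{R(x) = R_{max} Hill_{deg}(A(x))} is subtracted,
#' with \eqn{C_{lo}, C_{hi}, R_{max}} derived from the same rate constants.
#'
#' Defaults are calibration choices, not measured rates: they are set so that
#' Hh-stimulated degradation lowers processing-resistant Ci-155 more than
#' two-fold at the boundary and the processing span exceeds two-fold, and so
#' that processing inhibition responds to lower Hh levels than `ptc`
#' induction (`hill_proc_inh` K below `hill_act` K).
#'
#' @param x_min,x_max Grid extent (µm); the anterior extent must leave a
#'   plateau of at least `3 * lambda_hh` anterior of the Hh response.
#' @param grid_step Sampling interval (µm).
#' @param x_boundary Position of the AP compartment boundary (µm); kept at 0.
#' @param lambda_hh Hh decay length anterior of the boundary (µm).
#' @param hill_act Named vector `c(K=, n=)`: pathway activity vs Hh.
#' @param hill_proc_inh Named vector `c(K=, n=)`: processing inhibition vs Hh.
#' @param hill_deg Named vector `c(K=, n=)`: degradation vs pathway activity.
#' @param s_syn Ci-155 synthesis rate (a.u./time).
#' @param k_basal Basal Ci-155 turnover rate (1/time).
#' @param k_proc0 Maximal processing rate (1/time).
#' @param k_deg0 Maximal Hh-stimulated degradation rate (1/time).
#' @param ptc_base,ptc_gain Affine map from activity to ptc-lacZ intensity.
#' @param ci_post_bg Constant posterior-compartment Ci-155 background (a.u.).
#' @param ptc_post_decay Decay length (µm) of the posterior ptc-lacZ signal;
#'   the posterior tail is a measurement artifact, not a modelled response.
#' @param noise_sd_frac Per-position multiplicative (lognormal) noise SD,
#'   as a fraction of signal.
#' @param offset_sd Disc-to-disc positional jitter SD (µm).
#' @param scale_sd_frac Disc-to-disc per-channel intensity scale jitter SD
#'   (fraction; scales are `exp(rnorm(1, 0, scale_sd_frac))`).
#' @param seed Optional RNG seed used by the stochastic generators.
#' @param mode `"kinetic"` or `"additive"` (see Details).
#'
#' @return A list of class `sim_params`.
#' @seealso [genotype_spec()], [simulate_profile()], [simulate_disc_set()]
#' @export
#' @examples
#' p <- sim_params(noise_sd_frac = 0, offset_sd = 0, scale_sd_frac = 0)
#' prof <- simulate_profile(p, genotype_preset("WT"))
#' head(prof)
sim_params <- function(x_min = -100, x_max = 25, grid_step = 0.5,
                       x_boundary = 0, lambda_hh = 10,
                       hill_act = c(K = 0.3, n = 4),
                       hill_proc_inh = c(K = 0.08, n = 2),
                       hill_deg = c(K = 0.5, n = 4),
                       s_syn = 1, k_basal = 0.05, k_proc0 = 0.15,
                       k_deg0 = 0.3, ptc_base = 1, ptc_gain = 10,
                       ci_post_bg = 0, ptc_post_decay = 5,
                       noise_sd_frac = 0.05, offset_sd = 3,
                       scale_sd_frac = 0.05, seed = NULL,
                       mode = c("kinetic", "additive")) {
  mode <- match.arg(mode)
  p <- list(
    x_min = x_min, x_max = x_max, grid_step = grid_step,
    x_boundary = x_boundary, lambda_hh = lambda_hh,
    hill_act = check_hill(hill_act, "hill_act"),
    hill_proc_inh = check_hill(hill_proc_inh, "hill_proc_inh"),
    hill_deg = check_hill(hill_deg, "hill_deg"),
    s_syn = s_syn, k_basal = k_basal, k_proc0 = k_proc0, k_deg0 = k_deg0,
    ptc_base = ptc_base, ptc_gain = ptc_gain,
    ci_post_bg = ci_post_bg, ptc_post_decay = ptc_post_decay,
    noise_sd_frac = noise_sd_frac, offset_sd = offset_sd,
    scale_sd_frac = scale_sd_frac, seed = seed, mode = mode
  )
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

check_hill <- function(h, what) {
  if (length(h) != 2 || !all(c("K", "n") %in% names(h))) {
    abort(sprintf("`%s` must be a named vector c(K=, n=)", what),
          class = "cidecomp_param_error")
  }
  h[c("K", "n")]
}

validate_sim_params <- function(p) {
  pos <- c("grid_step", "lambda_hh", "s_syn", "k_basal", "k_proc0",
           "k_deg0", "ptc_post_decay")
  for (f in pos) {
    if (!is.finite(p[[f]]) || p[[f]] <= 0) {
      abort(sprintf("`%s` must be strictly positive", f),
            class = "cidecomp_param_error")
    }
  }
  for (h in c("hill_act", "hill_proc_inh", "hill_deg")) {
    if (any(!is.finite(p[[h]])) || any(p[[h]] <= 0)) {
      abort(sprintf("`%s` K and n must be strictly positive", h),
            class = "cidecomp_param_error")
    }
  }
  nonneg <- c("noise_sd_frac", "offset_sd", "scale_sd_frac", "ptc_base",
              "ptc_gain", "ci_post_bg")
  for (f in nonneg) {
    if (!is.finite(p[[f]]) || p[[f]] < 0) {
      abort(sprintf("`%s` must be >= 0", f), class = "cidecomp_param_error")
    }
  }
  if (p$x_min >= p$x_boundary || p$x_max < p$x_boundary) {
    abort("grid must straddle the compartment boundary",
          class = "cidecomp_param_error")
  }
  # the anterior plateau must be wide enough that the far-anterior profile is
  # effectively Hh-free (>= 3 lambda anterior of appreciable Hh response)
  if ((p$x_boundary - p$x_min) < 6 * p$lambda_hh) {
    abort("grid must extend at least 6*lambda_hh anterior of the boundary",
          class = "cidecomp_param_error")
  }
  invisible(p)
}

#' Genotype capability flags for the simulator
#'
#' A genotype is described phenomenologically by how its Ci variant couples to
#' the three regulatory arms of the model: whether it can be processed to the
#' Ci-75 repressor (`processing_competent`), how strongly Fu kinase can
#' activate it (`fu_responsive`, a fraction of the wild-type activity
#' ceiling), whether it is subject to Hh-stimulated degradation
#' (`degradation_competent`), and a multiplier on basal turnover
#' (`basal_turnover_mult`, used for the Su(fu)-null-like preset in which
#' Ci-155 is destabilized everywhere).
#'
#' @param name Genotype label.
#' @param processing_competent Logical or multiplier in `[0, 1]` on `k_proc0`.
#' @param fu_responsive Fraction in `[0, 1]` scaling the activity ceiling.
#' @param degradation_competent Logical or multiplier in `[0, 1]` on `k_deg0`.
#' @param basal_turnover_mult Multiplier (> 0) on `k_basal`.
#' @return A list of class `genotype_spec`.
#' @export
genotype_spec <- function(name, processing_competent = TRUE,
                          fu_responsive = 1, degradation_competent = TRUE,
                          basal_turnover_mult = 1) {
  g <- list(
    name = name,
    proc_mult = as.numeric(processing_competent),
    fu_responsive = fu_responsive,
    deg_mult = as.numeric(degradation_competent),
    basal_turnover_mult = basal_turnover_mult
  )
  if (g$proc_mult < 0 || g$proc_mult > 1 || g$deg_mult < 0 || g$deg_mult > 1) {
    abort("processing/degradation competence must lie in [0, 1]",
          class = "cidecomp_param_error")
  }
  if (g$fu_responsive < 0 || g$fu_responsive > 1) {
    abort("`fu_responsive` must lie in [0, 1]", class = "cidecomp_param_error")
  }
  if (!is.finite(g$basal_turnover_mult) || g$basal_turnover_mult <= 0) {
    abort("`basal_turnover_mult` must be > 0", class = "cidecomp_param_error")
  }
  structure(g, class = "genotype_spec")
}

#' Built-in genotype presets
#'
#' Presets reproduce the qualitative Ci-155 profile signatures of the
#' commonly studied Ci variants:
#' \describe{
#'   \item{WT, S3_5}{processing-competent and fully activatable: low anterior
#'     Ci-155 with a stripe at the AP border that peaks interiorly and
#'     declines toward the boundary.}
#'   \item{S849A, P13A}{processing-resistant but fully activatable: uniformly
#'     high anterior Ci-155 with a sharp decline near the boundary caused by
#'     Hh-stimulated degradation; normal ptc-lacZ.}
#'   \item{D1270_1370}{processing-resistant and only weakly activatable
#'     (activity ceiling 0.2): uniformly high, essentially flat Ci-155 and
#'     weak ptc-lacZ induction.}
#'   \item{SufuNull}{Ci-155 destabilized everywhere (basal turnover x10),
#'     with neither processing nor Hh-stimulated degradation contributing:
#'     uniformly low, flat Ci-155.}
#' }
#'
#' @param name Preset name; see Details. `genotype_presets()` returns all of
#'   them as a named list.
#' @return A `genotype_spec` (or named list of them).
#' @export
genotype_preset <- function(name) {
  presets <- genotype_presets()
  if (!name %in% names(presets)) {
    abort(sprintf("unknown genotype preset '%s' (have: %s)", name,
                  paste(names(presets), collapse = ", ")),
          class = "cidecomp_param_error")
  }
  presets[[name]]
}

#' @rdname genotype_preset
#' @export
genotype_presets <- function() {
  list(
    WT = genotype_spec("WT"),
    S3_5 = genotype_spec("S3_5"),
    S849A = genotype_spec("S849A", processing_competent = FALSE),
    P13A = genotype_spec("P13A", processing_competent = FALSE),
    D1270_1370 = genotype_spec("D1270_1370", processing_competent = FALSE,
                               fu_responsive = 0.2),
    SufuNull = genotype_spec("SufuNull", processing_competent = FALSE,
                             degradation_competent = FALSE,
                             basal_turnover_mult = 10)
  )
}

#' Clone scenarios for the mosaic-clone generator
#'
#' A clone scenario describes parameter overrides that apply only inside a
#' marked clone of mutant cells sitting in far-anterior (Hh-free) territory.
#' Overrides may replace `k_proc0`, `k_deg0`, `k_basal`, `s_syn`, or pin the
#' local pathway activity `activity` (normally ~0 in the far anterior).
#' Presets mirror classic mosaic experiments: `pka_loss` and `cos2_loss`
#' block processing cell-autonomously and partially activate the pathway;
#' `gap_fu` activates Fu without Hh; `gap_fu_smo` is the weaker
#' smo-independent variant; `ci_dose_change` lowers Ci synthesis.
#'
#' @param name Scenario label.
#' @param local_overrides Named list of parameter overrides applied inside
#'   the clone only.
#' @return A list of class `clone_scenario`.
#' @export
clone_scenario <- function(name, local_overrides = list()) {
  allowed <- c("k_proc0", "k_deg0", "k_basal", "s_syn", "activity")
  bad <- setdiff(names(local_overrides), allowed)
  if (length(bad)) {
    abort(sprintf("unknown clone override(s): %s", paste(bad, collapse = ", ")),
          class = "cidecomp_param_error")
  }
  for (nm in names(local_overrides)) {
    v <- local_overrides[[nm]]
    if (!is.finite(v) || v < 0) {
      abort(sprintf("clone override `%s` must be a finite value >= 0", nm),
            class = "cidecomp_param_error")
    }
    if (nm == "activity" && v > 1) {
      abort("clone `activity` override must lie in [0, 1]",
            class = "cidecomp_param_error")
    }
  }
  structure(list(name = name, local_overrides = local_overrides),
            class = "clone_scenario")
}

#' @rdname clone_scenario
#' @param name Preset name for `clone_preset()`.
#' @export
clone_preset <- function(name) {
  presets <- list(
    pka_loss = clone_scenario("pka_loss",
                              list(k_proc0 = 0, activity = 0.6)),
    cos2_loss = clone_scenario("cos2_loss",
                               list(k_proc0 = 0, activity = 0.35)),
    gap_fu = clone_scenario("gap_fu", list(activity = 0.5)),
    gap_fu_smo = clone_scenario("gap_fu_smo", list(activity = 0.25)),
    ci_dose_change = clone_scenario("ci_dose_change", list(s_syn = 0.7))
  )
  if (!name %in% names(presets)) {
    abort(sprintf("unknown clone preset '%s' (have: %s)", name,
                  paste(names(presets), collapse = ", ")),
          class = "cidecomp_param_error")
  }
  presets[[name]]
}
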