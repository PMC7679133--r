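---
title: "Decomposing Ci-155 gradients: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing Ci-155 gradients: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(cidecomp)
library(dplyr)
```

## The inference

At the wing-disc AP border, Hh both inhibits Ci-155 processing (to the
Ci-75 repressor) and, at high pathway activity, stimulates outright Ci-155
degradation. A single wild-type Ci-155 profile cannot separate the two.
`cidecomp` performs the separation using processing-resistant Ci variants,
whose profiles are shaped by degradation alone:

* **Reduction profile.** Replicate discs per genotype are aligned on the
  *ptc-lacZ* peak and averaged. The resistant-genotype means are averaged
  (unweighted across genotypes, not pooled across discs — each genotype's
  disc set is its own estimate of the same underlying curve, and pooling
  would weight genotypes by disc count), and the reduction is
  `R(x) = max_anterior(C_res) − C_res(x)`, the drop below the Hh-free
  anterior maximum.
* **No-reduction curve.** `C_nored(x) = C_WT(x) + R(x)` transfers the
  reduction measured in resistant variants onto the wild-type profile.
  This is valid insofar as wild-type and resistant variants share the same
  pathway-activity profile, which holds for the activatable resistant
  presets (their *ptc-lacZ* output is identical to wild type).
* **Inhibition landmarks.** `φ(x) = (C_nored − C_ant)/(C_top − C_ant)`
  is read as the local fraction of processing inhibited; we report the
  first position where `φ` exceeds `eps` for at least `run` consecutive
  samples, the first position with `φ ≥ 0.5`, and the first with
  `φ ≥ 1 − eps`.

The subtraction assumes the two genotype groups are recorded in comparable
arbitrary units (identical staining and imaging). We default to no
cross-genotype rescaling, mirroring the manual workflow the pipeline
formalizes; intensities are carried through unnormalized and the
provenance records every knob used.

## The synthetic wing disc

No imaging data accompany the analysis, so all validation rests on a
generative model whose ground truth is retained. The model is deliberately
minimal — steady-state, one-dimensional, phenomenological:

* Hh level `H(x) = exp(x / λ)` for `x ≤ 0` (boundary at 0, anterior
  negative, µm); the posterior compartment is not modelled beyond a
  constant Ci-155 background and a decaying *ptc-lacZ* tail that stands in
  for the known posterior measurement artifact.
* Pathway activity `A = f · Hill(H; K_act, n_act)` with `f` the genotype's
  activability ceiling; `ptc(x) = ptc_base + ptc_gain · A(x)`.
* Position-dependent rates
  `k_proc(x) = k_proc0 (1 − Hill(H; K_pi, n_pi))` and
  `k_deg(x) = k_deg0 · Hill(A; K_deg, n_deg)`, and the steady state
  `C(x) = s_syn / (k_basal + k_proc(x) + k_deg(x))`.

Genotypes are capability flags, not mechanisms: processing competence,
activability fraction, degradation competence, and a basal-turnover
multiplier. The presets reproduce the qualitative phenotype table (wild
type: low anterior with an interior border peak; S849A/P(1-3)A: flat high
anterior with a sharp boundary decline; Δ1270–1370-like: flat high with
weak *ptc*; Su(fu)-null-like: flat low). The Su(fu)-null preset raises
basal turnover 10-fold and disables both Hh-dependent arms — a
phenomenological route to "uniformly low, no decline", chosen because the
pipeline only consumes profile shapes.

**Calibration.** No kinetic rates are published for this system; the
defaults are calibration choices, recorded in the configuration of every
run. They were set once so that (i) degradation lowers resistant-variant
Ci-155 more than two-fold by the boundary (defaults give ≈ 6.6-fold),
(ii) the processing span exceeds two-fold (≈ 3.7-fold), and (iii)
processing inhibition responds to lower Hh than *ptc* induction
(`K_pi = 0.08` vs `K_act = 0.3` in units of the boundary Hh level), which
places the inhibition half-point ≈ 6 µm anterior of the *ptc-lacZ*
half-rise. Noise defaults (5% multiplicative intensity noise, ± 3 µm
positional jitter, 5% per-channel scale jitter, three discs per genotype)
emulate a typical confocal quantification of a small replicate set.

Noise is multiplicative lognormal because fluorescence noise scales with
signal and intensities must stay positive. Positional jitter is imposed by
re-evaluating the model with a shifted boundary, not by interpolating, so
recovered alignments can be compared to exact truth.

The **additive mode** exists for exactness testing: it generates
`C(x) = C_proc_only(x) − R_true(x)` from the same parameters, so the
genotype-subtraction decomposition is exactly invertible and any recovered
deviation beyond floating-point error is a pipeline defect. In kinetic
mode the additivity assumption is only approximate — `1/(a+b)` kinetics do
not decompose additively — so there the suite characterizes the bias
instead: it is confined to the region where `k_deg > 0`, and the
half-inhibition landmark survives it (recovered within half a decay length
of the value derived from the true processing-only curve).

**What passing tests do not show.** The generator emulates smooth
gradients, independent lognormal noise, and rigid positional offsets. Real
discs add curvature of the border, fold artifacts, staining gradients,
cross-channel bleed-through and segmentation error, none of which are
modelled; parameter recovery here validates the inference arithmetic and
its noise robustness, not performance on degraded imagery.

## Numerical and procedural choices

* **Alignment reference.** The "posterior edge of *ptc-lacZ* expression"
  is operationalized as the *ptc-lacZ* peak position, which effectively
  marks the compartment boundary and is robust to noise; a posterior
  half-maximum edge (`reference = "ptc_posterior_half"`) is available.
  Ties at the maximum resolve to the most anterior position.
* **Initial rise.** Defined as intensity exceeding
  `baseline + max(rise_k·SD_baseline, rise_floor_frac·span)` for at least
  `rise_run = 3` samples. The SD term is the operative one on noisy data
  (`rise_k = 2`); the 2% floor keeps the rule meaningful on noise-free
  traces, whose baseline SD vanishes. All three are configuration keys;
  there is no canonical definition to defer to.
* **Smoothing.** 5-point centered moving average with a shrinking window
  at the edges, so output length equals input length. The pipeline smooths
  each disc trace before alignment by default (`smooth = TRUE`); the
  exactness tests run unsmoothed, since smoothing biases curved profiles
  by design. Both orders of smoothing vs decomposition are available.
* **Alignment interpolation.** Linear, onto a common grid at the smallest
  input step; positions outside a disc's support are missing, and the mean
  and SEM at each position use only contributing discs (`n` is tracked;
  SEM is `NA` where `n < 2`). Three discs per condition are customary and
  fewer triggers a warning, not an error.
* **Posterior trimming.** The decomposition drops grid positions posterior
  of the boundary: Ci is not expressed there and the *ptc-lacZ* tail is an
  artifact, so the territory carries no usable information.
* **Anterior window.** Defaults to everything from the anterior end of the
  common grid to two grid steps anterior of the wild-type *ptc-lacZ*
  initial rise — i.e. territory with no detectable pathway response.
* **Negative reductions.** Noise can push `R(x)` below zero anterior of
  the response; values are retained unclipped so the defining identity
  holds exactly, and the fraction of negative positions is reported.
* **Inhibition thresholds.** `eps = 0.05` for "first" and "fully"
  inhibited; the guide-line definitions have no numeric precedent, so both
  are configuration keys. The 50% landmark is the first grid position with
  `φ ≥ 0.5` (no sub-grid interpolation), consistent with the other two.
* **Clone statistics.** Each disc contributes one value per formula (its
  replicate regions averaged before normalization by default; the
  per-replicate alternative is available), and `n` counts discs — the disc
  is the independent unit. Between-genotype comparisons default to Welch's
  two-sample t-test because genotypes come from different animals; a
  paired mode exists for designs with a genuine pairing key and the output
  records which test was used. Significance marks follow the `*`
  (p < 0.001) / `#` (p < 0.05) convention.
* **Degenerate inputs** raise classed errors rather than propagating NaN:
  flat reporter traces ("no response"), zero normalization constants, zero
  denominators in clone formulas (named per disc), zero-variance t-tests,
  non-uniform position grids.

## Problem sizes

The validation suite runs at desk scale, chosen to exercise every code
path with comfortable statistical margins: 251-point profiles
(0.5 µm step over [−100, 25] µm), three discs per genotype, 50 replicate
pipelines for the noise-recovery study, 100-case property sweeps per
primitive, 1,000 random fixtures for the invariance checks, and 10,000
null replicates for the type-I-error check.

## Known limitations

* The kinetic model is steady-state and one-dimensional; no transport,
  no transcriptional delay, no cell-size or folding geometry.
* Genotype presets are parameter bundles, not mechanistic models of the
  underlying mutations; conclusions about mechanism are out of scope.
* Cross-genotype comparability of intensities is assumed, not estimated;
  if staining batches differ systematically the reduction profile
  inherits that bias.
* The inhibition fraction reads the no-reduction curve as if steady-state
  Ci-155 were linear in the processing rate; under saturating kinetics the
  mapping is monotone but not proportional, so `φ` is a calibrated
  landmark scale rather than a literal fraction of molecules spared.
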