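# cidecomp

Quantitative decomposition of Ci-155 gradients at the anterior–posterior
(AP) border of the *Drosophila* wing imaginal disc.

## The problem

Hedgehog (Hh) spreading anterior from the compartment boundary regulates the
transcription factor Cubitus interruptus in two opposing ways: it inhibits
the partial proteolytic **processing** of full-length Ci-155 to the Ci-75
repressor, and at high pathway activity it stimulates **degradation** of
Ci-155 outright. The steady-state Ci-155 immunofluorescence profile
therefore confounds the two: instead of rising monotonically toward the
boundary, wild-type Ci-155 peaks mid-border and declines where target-gene
activation (read out by the *ptc-lacZ* reporter) is strongest.

`cidecomp` implements the inference that untangles these components, for
workers quantifying morphogen-graded immunofluorescence in fixed discs:

1. Ci variants that cannot be processed (e.g. S849A, P(1-3)A) expose the
   degradation component directly. With profiles aligned on the *ptc-lacZ*
   reference landmark, the **reduction profile** is
   `R(x) = max_anterior(C_res) − C_res(x)`,
   where `C_res` is the unweighted mean of the resistant-variant Ci-155
   profiles and the maximum is taken over Hh-free anterior territory.
2. Adding `R(x)` back to the wild-type profile gives the **no-reduction
   curve** `C_nored(x) = C_WT(x) + R(x)` — the Ci-155 profile that graded
   processing inhibition alone would produce.
3. Rescaling `C_nored` between its anterior plateau `C_ant` and maximum
   `C_top` yields the processing-inhibition fraction
   `φ(x) = (C_nored(x) − C_ant) / (C_top − C_ant)` and the positions where
   processing is first, 50%, and fully inhibited.

The package also provides the surrounding workflow: ROI profile extraction
from images (column means over an elongated rectangle), 5-point moving
average smoothing, *ptc-lacZ* landmark detection (baseline, initial rise,
50% rise, peak), replicate-disc alignment and SEM, mosaic-clone
normalization formulas (e.g. `(clone − anterior)/(AP border − anterior)`)
with paired/Welch t-tests and the `*` (p < 0.001) / `#` (p < 0.05)
significance convention, and a synthetic wing-disc generator — a
steady-state kinetic model `C(x) = s_syn / (k_basal + k_proc(x) + k_deg(x))`
with Hill-function couplings to an exponential Hh gradient — that supplies
ground truth for every stage.

## Worked example

```r
library(cidecomp)

p <- sim_params()                      # defaults: 5% noise, ±3 µm jitter
profiles <- dplyr::bind_rows(lapply(c("WT", "S849A", "P13A"), function(g)
  simulate_disc_set(p, genotype_preset(g), n_discs = 3,
                    seed = match(g, c("WT", "S849A", "P13A")))))

dec <- decompose_ci_profiles(profiles)
dec
#> <ci_decomposition> genotypes: WT = WT; resistant = S849A, P13A
#>   grid: [-99.5, 0] um, 200 positions
#>   fold reduction at boundary: 6.76; processing span: 3.7-fold
#>   inhibition landmarks (um): first -28.5, half -15.5, full -10.5
```

Read: by the compartment boundary, Hh-stimulated degradation lowers
resistant-variant Ci-155 about 6.8-fold below its anterior maximum; graded
processing inhibition alone would span ~3.7-fold; and the inferred
inhibition half-point (−15.5 µm) lies anterior of the *ptc-lacZ* half-rise
(≈ −12 µm), i.e. processing inhibition responds to lower Hh levels than
*ptc* induction. `tidy(dec)` returns the per-position curves, `glance(dec)` the
scalars, and `autoplot(dec)` the overlay figure with inhibition guide
lines.

Clone quantification works from tidy region tables:

```r
regions <- simulate_clone_dataset(p, genotype_preset("WT"),
                                  clone_preset("pka_loss"),
                                  n_discs = 5, seed = 4)
vals <- relative_expression(regions, "ptc_subtracted")
summarize_relative(vals)
#> # A tibble: 1 × 4
#>    mean    sem     n sem_defined
#>   <dbl>  <dbl> <int> <lgl>
#> 1 0.658 0.0159     5 TRUE
```

A configured end-to-end run (`run_config()`, `run_simulate()`,
`run_decompose()`, `run_clones()`) writes CSV/JSON outputs plus the fully
resolved YAML configuration; `inst/scripts/cidecomp-run.R` wraps the same
functions for shell use.

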