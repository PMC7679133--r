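Package: cidecomp
Title: Decomposition of Ci-155 Gradients at the Wing Disc AP Border
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification and decomposition of steady-state Cubitus
    interruptus (Ci-155) fluorescence profiles along the anterior-posterior
    axis of the Drosophila wing imaginal disc. Provides a synthetic wing-disc
    generator built on a steady-state kinetic model of Hedgehog-regulated Ci
    synthesis, processing and degradation; intensity-profile extraction,
    smoothing, landmark detection, alignment on ptc-lacZ reference points and
    averaging across replicate discs; decomposition of Ci-155 profiles into a
    Hh-stimulated degradation component and the inferred processing-only
    ("no-reduction") profile with graded processing-inhibition landmarks;
    and mosaic-clone region normalization formulas with paired and two-sample
    statistics. All stages are exercised by parameter recovery against the
    generator's ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
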