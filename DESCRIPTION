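Package: nbsdual
Title: Dual-Platform Newborn Screening Analysis for Inborn Errors of
    Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Evaluates newborn screening for inborn errors of metabolism
    when gene-panel sequencing (NGS) and tandem mass spectrometry (MS/MS)
    are run in parallel on the same dried blood spots. Provides a
    genotype-based screen-positivity classifier (pathogenic/likely
    pathogenic alleles matched to the gene's inheritance pattern), a
    direction-aware analyte-cutoff classifier including ratio markers,
    a combined referral/recall workflow with per-modality outcome
    labelling, screening performance metrics (PPV, sensitivity, recall
    rate, incidence), carrier-frequency estimation with Hardy-Weinberg
    incidence projection, and a synthetic newborn-cohort simulator with
    incomplete biochemical penetrance for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
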