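Package: evtwin
Title: Discovery of Equivalently Variable CpGs from Monozygotic Twin
    DNA Methylation Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Isolates stochastic inter-individual DNA methylation variation
    from array-style beta-value matrices of monozygotic twin cohorts.
    Implements equivalence testing (two one-sided tests based on the Yuen
    trimmed-mean t test) of co-twin versus unrelated-pair absolute
    methylation differences to discover equivalently variable CpGs
    (evCpGs), together with the supporting analyses: probe variability
    gating (IQR/ICC) with a measurement-error beta-distribution reference,
    cross-sectional epigenetic clock and drift (White heteroscedasticity)
    testing, replicate-resolution evaluation by hierarchical clustering,
    coverage-aware whole-genome bisulfite sequencing twin-discordance
    thresholds with regional Fisher enrichment, genomic annotation and
    positional enrichment, and a synthetic twin-cohort generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    mclust
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
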