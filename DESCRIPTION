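Package: ripesync
Title: Ripening Synchronization Analysis for Grape Berry Transcriptomes and
    Physiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to study how grape berries that enter ripening
    asynchronously converge to a common state at maturity. Implements the
    reduction-in-variance (RV) score for prioritising synchronizing genes,
    with a one-sided F-test and Benjamini-Hochberg FDR control; moderated
    paired t-tests with empirical-Bayes variance shrinkage for
    between-class differential expression; an additive
    transcriptional-distance decomposition with an observed-versus-calculated
    linearity assessment; expression-trend classification between veraison
    and maturity; and physiological ripening kinetics (colour index,
    ripening-curve regression, reference stages, time-to-reference curve
    inversion, lag and accumulation-rate tables with Tukey HSD letters).
    A synthetic-data generator emulating the multi-class, two-timepoint
    berry design supports calibration and parameter-recovery testing, and
    a pipeline driver runs all stages end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
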