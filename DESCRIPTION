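Package: genomescars
Title: Copy-Number Scars, Breakage-Fusion-Bridge Testing and Expression
    Subgroups from Tumour Whole-Genome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for somatic genome instability in tumour
    whole-genome sequencing data. Models binned read depth as a mixture of
    tumour and normal DNA, corrects GC bias with an empirical per-stratum
    model, estimates normal contamination and tumour mean ploidy by fitting
    an evenly spaced Gaussian comb to the relative read-count distribution,
    and segments copy number with a Gaussian hidden Markov model. On top of
    the segmentation it computes arm-level instability scores (firestorms,
    large-scale state transitions, fraction of genome altered), refines
    minimal common amplicons across samples, calls structural variants from
    discordant read pairs and soft-clipped reads with matched-normal
    subtraction, and tests whether amplified copy-number sequences are
    compatible with a breakage-fusion-bridge history, verifying the implied
    folding pattern against clipped-read orientations. An expression module
    discovers and validates sample subgroups with variance-filtered
    hierarchical clustering, single-sample centroid classification and
    single-sample gene-set enrichment. Synthetic-data generators provide
    every input the pipeline consumes so the whole analysis is testable
    without access to protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
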