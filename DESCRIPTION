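Package: credyn
Title: Dynamics of Cis-Regulatory Elements Across DNA-Damage Timepoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for analysing enhancer and promoter dynamics across
    three DNA-damage timepoints (0 h, 8 h, 16 h) from processed multi-omics
    inputs. Curates candidate cis-regulatory elements (coding-region and
    blacklist exclusion, distal/proximal classification), quantifies
    per-element RNA/ATAC/H3K27ac signal as reads per million, classifies
    per-timepoint binary accessibility, activity and expression states into
    three-timepoint trajectories, assigns enhancers to target genes through
    basal-plus-extension regulatory domains and chromatin-loop anchors,
    detects direction-coordinated enhancer-gene pairs, ranks transcription
    factor footprints by cross-timepoint binding-activity variability,
    partitions elements by p53 binding, and provides a paired Friedman test
    and an unpaired two-sample Kolmogorov-Smirnov test with exact small-sample
    p-values. A seeded synthetic-data generator emits a complete input bundle
    with planted temporal structure so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
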