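Package: lipscreen
Title: In Silico Screening of Triacylglycerol Lipase Candidates in a Proteome
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A multi-stage screening pipeline for putative triacylglycerol
    lipases (EC 3.1.1.3) in an annotated proteome: keyword and
    annotation-significance filtering, catalytic-motif requirements
    (GXSXG pentapeptide, GDSL N-terminal motif), family assignment,
    ProtParam-style physico-chemical profiling (molecular weight, pI,
    instability/aliphatic index, GRAVY), rule-based subcellular
    localization from external predictor tables and targeting-signal
    motifs, transcript-regulation ranking across stress time-course
    datasets, and predicted-structure quality control (backbone
    dihedrals, Ramachandran region fractions, pLDDT summaries).
    Includes a synthetic-data generator that emits every input format
    the pipeline consumes, with planted ground truth for end-to-end
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
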