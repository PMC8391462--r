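Package: ppreAlu
Title: Discovery of Alu-Embedded PPAR-Responsive Elements in Gene Promoters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scans gene promoters for PPAR-responsive elements (PPREs)
    embedded in a distinctive ordered repeat configuration
    (Alu-Alu-Low complexity-LINE/L1), annotates each motif hit's position
    inside the Alu dimeric structure (left arm, A-/B-box proximity) by
    global alignment to subfamily consensus sequences, and provides the
    downstream cancer statistics used to characterise such loci:
    per-cohort Pearson co-expression with significance, two-sample
    Kolmogorov-Smirnov comparison of evolutionary-action variant scores
    against an all-missense null, and median-split Kaplan-Meier survival
    with chromosome-3 subgroups for uveal-melanoma style cohorts. A
    synthetic-data module generates genomes, repeat annotations,
    expression matrices, mutation sets and survival cohorts with planted
    ground truth so every stage is verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    ape,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
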