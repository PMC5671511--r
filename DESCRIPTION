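Package: codonexpress
Title: Codon Usage Bias Detection, Expression-Guided Recoding, and
    Dual-Reporter Fluorescence Normalization
Version: 0.1.0
Authors@R:
    person("codonexpress", "maintainers", email = "maintainers@codonexpress.dev",
           role = c("aut", "cre"))
Description: Detects synonymous codon usage bias in highly expressed genes by
    per-codon exact tests with Benjamini-Hochberg false discovery rate
    control, computes per-gene GC, GC3 and effective number of codons (ENC)
    statistics, deterministically recodes coding sequences toward or away
    from the preferred-codon profile of a highly expressed gene set while
    preserving the protein sequence, and normalizes dual-reporter (GFP and
    mCherry) plate-reader fluorescence for per-well transfection efficiency.
    Seeded synthetic generators for coding-sequence sets, expression tables
    and two-channel plates make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
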