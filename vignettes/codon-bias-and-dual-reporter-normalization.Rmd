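---
title: "Methods: codon usage bias detection, recoding, and dual-reporter normalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon usage bias detection, recoding, and dual-reporter normalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonexpress)
```

## The problem

Two "inside factors" dominate how much protein a transfected construct
produces: the promoter and the codon usage of the coding sequence. This
package implements the computational side of a workflow built around that
observation in a moss expression system: (i) detect which synonymous codons
are preferred by highly expressed genes, (ii) recode a reporter toward or
away from that preference without touching the protein, and (iii) quantify
the resulting expression differences from two-channel plate-reader
fluorescence, normalized for transfection efficiency. Every stage runs on
seeded synthetic data with planted truth, so the statistical machinery is
testable without genome-scale downloads.

## Codon bias model

For a group of genes (e.g. all genes with normalized microarray intensity at
or above a cutoff) and an inclusive background (all genes), the pooled codon
counts are compared one codon at a time. In the default `within_family` mode
the 2x2 table for codon $c$ of amino acid $a$ is

$$\begin{pmatrix} n_{g}(c) & n_{g}(a) - n_{g}(c) \\
                  n_{b}(c) & n_{b}(a) - n_{b}(c) \end{pmatrix}$$

where $n(a)$ is the synonymous-family total. Conditioning on the family
removes amino-acid composition as a confounder; the `vs_all` mode (codon vs
all other sense codons) is also exposed because the original description
("each of the 64 codons") does not pin the construction down, but it is not
the default precisely because of that confounding. The p-value is the exact
two-sided hypergeometric tail: the total probability of all tables with the
observed margins whose point probability does not exceed the observed one
(with the conventional $1+10^{-7}$ relative slack for floating-point ties).

Stop codons never enter (they encode no amino acid and recoding never
touches them) and neither do the single-codon families Met and Trp, in
either mode, so the multiplicity $m$ counts testable codons only —
untestable cells would dilute the FDR. The joint p-vector is adjusted by
Benjamini–Hochberg step-up ($q_{(i)} = \min_{j \ge i} p_{(j)} m / j$, capped
at 1). BH is the default because the downstream semantics are explicitly
FDR-based; Holm (the `p.adjust` default in R) is available via
`method = "holm"`. Direction (over/under) is assigned post hoc from the
within-table proportions and only kept where $q < \alpha$ (default 0.05);
an exact proportion tie is reported as no direction, with a warning, even
when significant.

`rank_scan()` repeats the comparison for the top-$n$ genes over an
increasing grid of $n$, against the pooled background of all genes
(inclusive by default — the group is part of "all genes"; an exclusive
background is a flag), reporting how deep into the expression ranking the
bias remains detectable.

## ENC and GC statistics

The effective number of codons follows Wright's estimator. Per family with
total $n \ge 2$, the homozygosity is $F = (n\sum_i p_i^2 - 1)/(n-1)$;
families are averaged within degeneracy classes and

$$N_c = 2 + \frac{9}{\bar F_2} + \frac{1}{\bar F_3} + \frac{5}{\bar F_4} + \frac{3}{\bar F_6}.$$

Design choices where the method description is open:

* The six-fold families (Leu, Ser, Arg) are kept as whole families in their
  own class with weight 3 — standard ENC practice.
* Families with $n < 2$ or $F \le 0$ are excluded from their class mean; a
  class with no defined family substitutes the mean of the defined class
  means (Wright's own fallback), so short sequences still get a value
  instead of being dropped.
* $N_c$ is clamped at 61 (finite-sample $F$ slightly undershoots $1/k$
  under uniform usage, which would push the estimate above the theoretical
  maximum); the lower bound 20 needs no clamp, since $F \le 1$.

`gc_content()` reports overall GC or a single codon position; GC3 carries
most synonymous signal. `gene_stats()` bundles `n_codons`, `gc`, `gc3`,
`enc` per gene for the TSV report.

## Recoding

`build_recoding_map()` turns a bias result plus the within-family frequency
table of the high-expression group into a deterministic map: per amino acid
in scope, `high` mode targets the family's most frequent codon in the
high-expression group, `low` its least frequent. The scope defaults to the
significantly biased amino acids only, not all 20: recoding only the biased
families is what keeps the change count on a GFP-sized CDS in the tens
rather than the hundreds, and the resulting GC shift arithmetic (each
two-fold family swap moves exactly one third-position nucleotide) is
consistent with that. `scope = "all"` recodes every degenerate family. Ties
break alphabetically with a logged warning, so map construction is
reproducible. Low mode targets the strict within-family minimum rather than
"the codon flagged under-represented", because under-representation flags
do not identify a unique codon in 3/4/6-fold families.

`recode_cds()` replaces every in-scope codon differing from its target and
records each substitution in a 1-based ledger (`codon_index`, `from_codon`,
`to_codon`); stop codons and out-of-scope families are untouched, so
`translate_cds()` is invariant by construction. `apply_ledger()` replays a
ledger (verifying `from_codon` against the sequence) and `diff_codons()`
independently audits the change count. Coordinates are 1-based throughout,
matching molecular-biology convention.

## Plate normalization

The measurement model behind the dual-reporter design: each well's
transfection efficiency multiplies both channels, because GFP (under the
promoter of interest) and mCherry (under a constant medium-strength
promoter) sit on the same plasmid. The per-well ratio GFP/mCherry therefore
cancels efficiency exactly; with zero channel noise the ratio is constant
per construct regardless of the efficiency distribution (a tested
invariant).

Processing order and choices:

1. `blank_correct()` subtracts the per-channel blank aggregate (mean by
   default — the simplest unbiased choice, unstated in the original
   protocol; median available). Negative corrected values are kept but
   flagged.
2. `normalized_ratios()` forms per-well ratios and excludes wells whose
   corrected mCherry does not exceed the mean corrected mCherry of the
   background (non-transfected) wells — such wells show no evidence of
   transfection. This exclusion is the package's expression of the
   "minimum number of protoplasts for signal above background" rule; a cell
   count is not an input.
3. `summarize_constructs()` aggregates with the transfection (biological
   replicate) as the replication unit: wells of one transfection are
   averaged first, because replicate counts in this design refer to
   independent transfections, not wells. Per construct it reports n, mean,
   sd, cv = sd/mean, the reference-scaled relative value (the reference is
   exactly the scale constant, conventionally 1 or 100), and a two-sided
   equal-variance Student's t-test against the reference replicates —
   equal-variance because that is the named test in this setting. Zero
   pooled variance is special-cased (p = 1 for equal means, 0 otherwise),
   since the generic routine rejects constant data while the contract
   requires p = 1 for a construct identical to the reference. Constructs
   with fewer than two replicates get NA with a flag.
4. `median_cv()` gives the across-construct variability summary used to
   compare normalization schemes (ratio vs raw GFP).

## Synthetic data: the stated world

The generators are pure functions of (configuration, seed); identical
configurations give byte-identical outputs.

`simulate_cds_set()` draws each gene's codons per amino-acid position from
within-family multinomials. Background usage is uniform within each family:
amino-acid composition and background codon preference do not enter the
within-family tests, so a flat background isolates exactly the signal the
detector is meant to find. The biased subset (default 20 of 220 genes, the
planted-recovery setting used throughout the tests) multiplies the preferred
codon's probability by `bias_strength` (default 5) in the planted families
(default Glu, Phe, His, Lys, Tyr — five two-fold families from the
empirically biased set) and renormalizes; `bias_strength = 1` is therefore
an exact null generator. Gene body lengths are uniform over 100–300 codons,
an ATG start is forced and one terminal stop appended.

`simulate_expression()` draws lognormal intensities on the normalized
microarray fluorescence scale: background `lnorm(log 2e4, 1)`, biased subset
`lnorm(log 5e5, 0.4)`. These place roughly the top 1–3% of a large gene set
above the 200,000 cutoff and the biased genes around 450,000 and above, so
both threshold stratification and rank scanning behave the way the real
intensity distribution makes them behave.

`simulate_plate()` uses the well model
`GFP = strength x base_GFP x efficiency x noise + blank`,
`mCherry = base_mCherry x efficiency x noise + blank`. The efficiency
factor is drawn once per (construct, transfection) with lognormal c.v. 0.5 —
transformations, not wells, are the dominant variance source — and shared
by that transfection's wells; channel noise is per-well-per-channel
lognormal with c.v. 0.1 (fluorescence is positive and heteroscedastic; no
noise model is stated in the original protocol, so multiplicative lognormal
is the package's choice). Default construct strengths (1, 1.8, 0.4, 1.7,
5.7, 0.9) are the relative expression levels of the six promoter x
codon-variant combinations the readout system was designed to compare.

What the generators do **not** emulate: microarray probe effects and
normalization, spectral bleed-through between channels, plate position
effects, the time course of fluorescence development, and sequence-level
realism beyond codon usage (no introns, UTRs, or composition gradients). A
green test therefore establishes that the statistics are implemented
correctly and recover planted structure under the assumed model — not that
the model captures every property of real plates or real genomes.

## Numerical choices and degenerate inputs

* Exact-test ties use the standard $1+10^{-7}$ relative slack; a 2x2 table
  with an empty margin returns p = 1.
* Intensity ties in stratification break by gene id, so top-n sets are
  deterministic.
* Strict CDS validation (internal stop = error naming the codon index) is
  the default; permissive mode warns and counts through.
* Genes missing from either the expression table or the sequence set are
  dropped from pooling with a logged count.
* Frequency tables report empty families as NA, never 0/0.

## Reproducing the external-data targets

The derived sequence statistics of the original study (smGFP GC 43.7%,
GFPhigh 49.1%, GFPlow 35.6%; 39 and 58 codon changes; nine biased amino
acids) are exactly recomputable with this package once the external inputs
are supplied — the smGFP coding sequence as FASTA plus the genome-scale CDS
and intensity tables:

```r
smgfp <- read_cds_fasta("smGFP.fa")
gc_content(smgfp[[1]])                                   # 0.437
bias <- detect_bias(group_counts, background_counts)      # nine amino acids
map <- build_recoding_map(bias, codon_frequencies(group_counts), "high")
recode_cds(smgfp[[1]], map)$n_changes                     # 39
```

The package ships no stand-in for these sequences; fabricated inputs would
make the comparison meaningless.

## Known limitations

* Only the standard genetic code is bundled; alternative codes plug in via
  `genetic_code(table)`, but no intron-aware CDS extraction is provided.
* `vs_all` mode tests amino-acid-composition and codon-preference signal
  jointly; interpret its directions with care.
* The t-test assumes approximately normal replicate means with equal
  variances; with 3–6 replicates per construct this is an approximation the
  original design also accepts.
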