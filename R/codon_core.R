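# Codon counting, frequency tables, GC/GC3, and Wright's effective number
# of codons (ENC).

new_codon_counts <- function(x, code = genetic_code()) {
  # internal fast path: x is a numeric vector named by all 64 codons (sorted)
  structure(as.integer(x), names = names(code$table),
            n_total = sum(as.integer(x)), class = "codon_counts")
}

#' Construct a codon count vector
#'
#' Builds a full 64-cell count vector from a (possibly sparse) named count
#' set; missing codons get zero. Used for hand-built examples; sequence
#' counting goes through [count_codons()].
#'
#' @param x Named non-negative integer vector, names are codons.
#' @param code A [genetic_code()].
#' @return A `codon_counts` object: integer vector over all 64 codons with an
#'   `n_total` attribute equal to its sum.
#' @examples
#' codon_counts(c(AAA = 3, AAG = 1))
#' @export
codon_counts <- function(x, code = genetic_code()) {
  if (is.null(names(x)) || !all(names(x) %in% names(code$table))) {
    stop("'x' must be named by valid codons")
  }
  if (anyDuplicated(names(x))) stop("duplicate codon names in 'x'")
  if (any(x < 0) || any(x != floor(x))) {
    stop("counts must be non-negative integers")
  }
  full <- stats::setNames(integer(64L), names(code$table))
  full[names(x)] <- as.integer(x)
  new_codon_counts(full, code)
}

#' @export
print.codon_counts <- function(x, ...) {
  nz <- x[x > 0]
  cat(sprintf("<codon_counts> %d codons total, %d distinct\n",
              attr(x, "n_total"), length(nz)))
  print(unclass(nz)[order(names(nz))])
  invisible(x)
}

#' Count frame-0 codons of a coding sequence
#'
#' @inheritParams validate_cds
#' @return A `codon_counts` vector; `n_total` equals `nchar(seq)/3`.
#' @examples
#' count_codons("ATGAAAAAGTAA")
#' @export
count_codons <- function(seq, id = "<cds>", strict = TRUE,
                         code = genetic_code()) {
  seq <- validate_cds(seq, id = id, strict = strict, code = code)
  tab <- tabulate(factor(split_codons(seq), levels = names(code$table)),
                  nbins = 64L)
  new_codon_counts(stats::setNames(tab, names(code$table)), code)
}

#' Pool codon counts over a gene group
#'
#' Cell-wise sum over a non-empty list of `codon_counts`; `n_total` is
#' additive, so order never matters.
#'
#' @param counts_list Non-empty list of `codon_counts`.
#' @param code A [genetic_code()].
#' @return Pooled `codon_counts`.
#' @export
pool_counts <- function(counts_list, code = genetic_code()) {
  if (!is.list(counts_list) || length(counts_list) == 0L) {
    stop("'counts_list' must be a non-empty list of codon_counts")
  }
  ok <- vapply(counts_list, inherits, logical(1L), what = "codon_counts")
  if (!all(ok)) stop("all elements must be codon_counts objects")
  pooled <- Reduce(`+`, lapply(counts_list, unclass))
  new_codon_counts(pooled, code)
}

#' Codon frequency table
#'
#' Within-family scope divides each codon's count by its synonymous-family
#' total (the quantity the exact bias tests and the recoding maps consume);
#' families with zero total are reported as `NA`, not 0/0. Global scope
#' divides by the total sense-codon count. Stop codons are excluded by
#' default: they encode no amino acid and recoding never touches them.
#'
#' @param counts A `codon_counts` object with positive total.
#' @param scope `"within_family"` (default) or `"global"`.
#' @param code A [genetic_code()].
#' @return A data frame of class `freq_table` with columns `codon`,
#'   `amino_acid`, `count`, `family_total`, `freq`, plus a `scope` attribute.
#' @examples
#' codon_frequencies(codon_counts(c(AAA = 3, AAG = 1)))
#' @export
codon_frequencies <- function(counts, scope = c("within_family", "global"),
                              code = genetic_code()) {
  scope <- match.arg(scope)
  stopifnot(inherits(counts, "codon_counts"))
  if (attr(counts, "n_total") <= 0L) {
    stop("cannot compute frequencies from an empty count vector")
  }
  sense <- code$sense_codons
  cnt <- unclass(counts)[sense]
  aa <- unname(code$table[sense])
  fam_tot <- tapply(cnt, aa, sum)
  family_total <- as.integer(fam_tot[aa])
  if (scope == "within_family") {
    freq <- ifelse(family_total > 0L, cnt / family_total, NA_real_)
  } else {
    tot <- sum(cnt)
    if (tot == 0L) stop("no sense codons present")
    freq <- cnt / tot
  }
  out <- data.frame(codon = sense, amino_acid = aa, count = as.integer(cnt),
                    family_total = family_total, freq = freq,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, scope = scope, class = c("freq_table", "data.frame"))
}

#' GC content of a nucleotide sequence
#'
#' @param seq Nucleotide string over A/C/G/T.
#' @param positions `"all"` (default) or one of `"first"`, `"second"`,
#'   `"third"` to restrict to a codon position (sequence length must then be
#'   divisible by 3). `"third"` gives GC3, where most synonymous variation
#'   resides.
#' @return Fraction of G or C in \[0, 1\].
#' @examples
#' gc_content("GGCC")               # 1
#' gc_content("ATGAAG", "third")    # 1
#' @export
gc_content <- function(seq, positions = c("all", "first", "second", "third")) {
  positions <- match.arg(positions)
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop("'seq' must be a single nucleotide string")
  }
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) stop("sequence contains characters outside A/C/G/T")
  n <- nchar(seq)
  if (n == 0L) stop("empty sequence")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (positions != "all") {
    if (n %% 3L != 0L) {
      stop("codon-position GC requires length divisible by 3")
    }
    off <- match(positions, c("first", "second", "third"))
    chars <- chars[seq.int(off, n, 3L)]
  }
  mean(chars == "G" | chars == "C")
}

#' Effective number of codons (ENC)
#'
#' Wright's Nc statistic: 61 means uniform synonymous usage, 20 means one
#' codon per amino acid. Per family with total n >= 2, the homozygosity is
#' F = (n * sum(p_i^2) - 1) / (n - 1); families are averaged within their
#' degeneracy class and Nc = N1 + sum_k N_k / Fbar_k, where N1 counts the
#' single-codon families (Met, Trp: the constant 2 in the standard code) and
#' N_k the k-fold families (9, 1, 5, 3 for k = 2, 3, 4, 6). Six-fold
#' families (Leu, Ser, Arg) form their own class. Families with n < 2 or
#' F <= 0 are excluded from their class mean; a class with no defined family
#' falls back to the mean of the defined class means, so short sequences are
#' not dropped. The result is clamped at the sense-codon count (61).
#'
#' @param counts A `codon_counts` object.
#' @param code A [genetic_code()].
#' @return Nc in \[20, 61\] for the standard code.
#' @export
effective_number_of_codons <- function(counts, code = genetic_code()) {
  stopifnot(inherits(counts, "codon_counts"))
  cnt <- unclass(counts)
  deg <- code$degeneracy
  multi <- names(deg)[deg >= 2L]
  f_vals <- vapply(multi, function(a) {
    x <- cnt[code$families[[a]]]
    n <- sum(x)
    if (n < 2) return(NA_real_)
    p <- x / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    if (!is.finite(f) || f <= 0) NA_real_ else f
  }, numeric(1L))
  sizes <- deg[multi]
  classes <- sort(unique(sizes))
  class_mean <- vapply(classes, function(k) {
    v <- f_vals[sizes == k]
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1L))
  if (all(is.na(class_mean))) {
    stop("insufficient counts: no synonymous family has a defined homozygosity")
  }
  fallback <- mean(class_mean, na.rm = TRUE)
  class_mean[is.na(class_mean)] <- fallback
  n_single <- sum(deg == 1L)
  n_per_class <- vapply(classes, function(k) sum(sizes == k), numeric(1L))
  nc <- n_single + sum(n_per_class / class_mean)
  min(nc, length(code$sense_codons))
}

#' Per-gene sequence statistics
#'
#' Convenience wrapper producing the gene-level report: codon count, GC,
#' GC3, and ENC for each sequence. ENC is `NA` where counts are insufficient.
#'
#' @param seqs Named character vector of coding sequences.
#' @param strict Passed to [validate_cds()].
#' @param code A [genetic_code()].
#' @return Data frame with columns `gene_id`, `n_codons`, `gc`, `gc3`, `enc`.
#' @export
gene_stats <- function(seqs, strict = TRUE, code = genetic_code()) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("'seqs' must be uniquely named")
  }
  rows <- lapply(names(seqs), function(id) {
    s <- validate_cds(seqs[[id]], id = id, strict = strict, code = code)
    cc <- count_codons(s, id = id, strict = FALSE, code = code)
    enc <- tryCatch(effective_number_of_codons(cc, code = code),
                    error = function(e) NA_real_)
    data.frame(gene_id = id, n_codons = nchar(s) %/% 3L,
               gc = gc_content(s), gc3 = gc_content(s, "third"), enc = enc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
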