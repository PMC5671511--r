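# Expression stratification, per-codon exact tests, FDR control, and the
# detection-depth scan over expression rank.

#' Two-sided exact test for a 2x2 table
#'
#' Exact hypergeometric tail enumeration with fixed margins: the two-sided p
#' is the total probability of all tables whose point probability does not
#' exceed the observed one (with the conventional 1 + 1e-7 relative slack
#' for floating-point ties). A table with a zero margin carries no
#' information and returns p = 1.
#'
#' @param m 2x2 matrix of non-negative integer counts,
#'   `rbind(c(a, b), c(c, d))` with rows = groups, columns = codon vs rest.
#' @return Two-sided p-value in \[0, 1\].
#' @examples
#' exact_test_2x2(rbind(c(8, 2), c(50, 50)))
#' @export
exact_test_2x2 <- function(m) {
  if (!is.matrix(m) || !all(dim(m) == 2L) || any(m < 0) ||
      any(m != floor(m))) {
    stop("'m' must be a 2x2 matrix of non-negative integers")
  }
  a <- m[1L, 1L]
  r1 <- a + m[1L, 2L]
  r2 <- m[2L, 1L] + m[2L, 2L]
  c1 <- a + m[2L, 1L]
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) {
    return(1)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  dens <- stats::dhyper(support, r1, r2, c1)
  p0 <- dens[match(a, support)]
  min(1, sum(dens[dens <= p0 * (1 + 1e-7)]))
}

#' Per-codon usage bias test between a gene group and background
#'
#' Tests one codon's usage in a group against a background via the exact
#' 2x2 test on `[[group codon, group rest], [background codon, background
#' rest]]`. In `within_family` mode (default) "rest" is the other synonymous
#' codons of the same amino acid, so the test is unconfounded by amino-acid
#' composition; in `vs_all` mode "rest" is all other sense codons. Stop
#' codons and single-codon families (Met, Trp) are untestable in either
#' mode. Direction is assigned post hoc from the within-table proportions;
#' an exact proportion tie yields direction `"none"`.
#'
#' @param group,background `codon_counts` objects.
#' @param codon 3-mer to test.
#' @param mode `"within_family"` or `"vs_all"`.
#' @param code A [genetic_code()].
#' @return List with elements `codon`, `amino_acid`, `testable`, `p_value`,
#'   `direction` (`"over"`, `"under"` or `"none"`), `group_count`,
#'   `group_family_total`, `background_count`, `background_family_total`.
#' @export
codon_bias_test <- function(group, background, codon,
                            mode = c("within_family", "vs_all"),
                            code = genetic_code()) {
  mode <- match.arg(mode)
  stopifnot(inherits(group, "codon_counts"),
            inherits(background, "codon_counts"))
  if (!codon %in% names(code$table)) stop(sprintf("invalid codon '%s'", codon))
  aa <- unname(code$table[codon])
  untestable <- function() {
    list(codon = codon, amino_acid = aa, testable = FALSE,
         p_value = NA_real_, direction = "none",
         group_count = NA_integer_, group_family_total = NA_integer_,
         background_count = NA_integer_,
         background_family_total = NA_integer_)
  }
  if (aa == "*") return(untestable())
  if (length(code$families[[aa]]) < 2L) return(untestable())
  if (mode == "within_family") {
    fam <- code$families[[aa]]
    gf <- sum(unclass(group)[fam])
    bf <- sum(unclass(background)[fam])
  } else {
    gf <- sum(unclass(group)[code$sense_codons])
    bf <- sum(unclass(background)[code$sense_codons])
  }
  if (gf == 0L || bf == 0L) return(untestable())
  gc_ <- unclass(group)[[codon]]
  bc_ <- unclass(background)[[codon]]
  p <- exact_test_2x2(rbind(c(gc_, gf - gc_), c(bc_, bf - bc_)))
  pg <- gc_ / gf
  pb <- bc_ / bf
  direction <- if (pg > pb) "over" else if (pg < pb) "under" else "none"
  list(codon = codon, amino_acid = aa, testable = TRUE, p_value = p,
       direction = direction, group_count = as.integer(gc_),
       group_family_total = as.integer(gf),
       background_count = as.integer(bc_),
       background_family_total = as.integer(bf))
}

#' Multiple-testing adjustment (Benjamini-Hochberg or Holm)
#'
#' Benjamini-Hochberg step-up (the default, matching FDR semantics):
#' q_(i) = min over j >= i of p_(j) * m / j, capped at 1, returned in input
#' order. `"holm"` gives the step-down family-wise bound.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method `"BH"` (default) or `"holm"`.
#' @return Adjusted values in input order.
#' @examples
#' adjust_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
adjust_fdr <- function(p, method = c("BH", "holm")) {
  method <- match.arg(method)
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("all p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m == 0L) return(numeric(0L))
  if (method == "BH") {
    o <- order(p, decreasing = TRUE)
    q <- pmin(1, cummin(p[o] * m / seq.int(m, 1L)))
    q[order(o)]
  } else {
    o <- order(p)
    q <- pmin(1, cummax(p[o] * seq.int(m, 1L)))
    q[order(o)]
  }
}

#' Detect codon usage bias between a gene group and background
#'
#' Runs [codon_bias_test()] on every testable codon, adjusts the full
#' p-vector jointly with [adjust_fdr()] (so m counts testable codons only),
#' and keeps a direction only where q < alpha. A proportion tie on a
#' significant codon is demoted to `"none"` with a warning.
#'
#' @param group,background Pooled `codon_counts` for the group and the
#'   (conventionally inclusive) background.
#' @param alpha Significance level on the adjusted scale (default 0.05).
#' @param mode,code Passed to [codon_bias_test()].
#' @param method FDR method for [adjust_fdr()].
#' @return A `bias_result_set`: data frame with one row per testable codon
#'   (columns `codon`, `amino_acid`, `group_count`, `group_family_total`,
#'   `background_count`, `background_family_total`, `p_value`, `q_value`,
#'   `direction`), with attributes `alpha`, `mode`, and
#'   `biased_amino_acids` (amino acids owning at least one directional codon).
#' @export
detect_bias <- function(group, background, alpha = 0.05,
                        mode = c("within_family", "vs_all"),
                        method = c("BH", "holm"), code = genetic_code()) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 1)
  res <- lapply(code$sense_codons, function(cd) {
    codon_bias_test(group, background, cd, mode = mode, code = code)
  })
  res <- res[vapply(res, `[[`, logical(1L), "testable")]
  if (length(res) == 0L) stop("no testable codons")
  out <- data.frame(
    codon = vapply(res, `[[`, character(1L), "codon"),
    amino_acid = vapply(res, `[[`, character(1L), "amino_acid"),
    group_count = vapply(res, `[[`, integer(1L), "group_count"),
    group_family_total = vapply(res, `[[`, integer(1L), "group_family_total"),
    background_count = vapply(res, `[[`, integer(1L), "background_count"),
    background_family_total = vapply(res, `[[`, integer(1L),
                                     "background_family_total"),
    p_value = vapply(res, `[[`, numeric(1L), "p_value"),
    stringsAsFactors = FALSE)
  out$q_value <- adjust_fdr(out$p_value, method = method)
  raw_dir <- vapply(res, `[[`, character(1L), "direction")
  sig <- out$q_value < alpha
  tied_sig <- sig & raw_dir == "none"
  if (any(tied_sig)) {
    warning(sprintf("proportion tie on significant codon(s) %s: direction set to 'none'",
                    paste(out$codon[tied_sig], collapse = ", ")),
            call. = FALSE)
  }
  out$direction <- ifelse(sig, raw_dir, "none")
  structure(out,
            alpha = alpha, mode = mode,
            biased_amino_acids =
              sort(unique(out$amino_acid[out$direction != "none"])),
            class = c("bias_result_set", "data.frame"))
}

#' @export
print.bias_result_set <- function(x, ...) {
  baa <- attr(x, "biased_amino_acids")
  cat(sprintf("<bias_result_set> %d testable codons, alpha = %g, mode = %s\n",
              nrow(x), attr(x, "alpha"), attr(x, "mode")))
  cat(sprintf("biased amino acids (%d): %s\n", length(baa),
              if (length(baa)) paste(baa, collapse = ", ") else "none"))
  sig <- x[x$direction != "none", , drop = FALSE]
  if (nrow(sig)) print.data.frame(sig[order(sig$q_value, sig$codon), ])
  invisible(x)
}

#' Stratify genes by expression level
#'
#' Threshold mode reproduces the two-cutoff design used for microarray
#' intensities: genes at or above `strong_cutoff` (default 200,000
#' normalized fluorescence) are "strong", at or above `high_cutoff` (default
#' 450,000) "high". `top_n` mode takes the n highest-intensity genes (ties
#' broken by intensity, then gene id, for determinism). The background
#' stratum `"all"` always contains every gene, so group membership is
#' inclusive.
#'
#' @param expr Data frame with columns `gene_id` (unique) and `intensity`
#'   (finite, non-negative).
#' @param mode `"threshold"` or `"top_n"`.
#' @param strong_cutoff,high_cutoff Intensity cutoffs, `high_cutoff >=
#'   strong_cutoff`.
#' @param n Group size for `top_n` mode.
#' @return Named list of gene-id character vectors: `strong`, `high`, `all`
#'   (threshold mode) or `top`, `all` (top_n mode).
#' @export
stratify_by_expression <- function(expr, mode = c("threshold", "top_n"),
                                   strong_cutoff = 2e5, high_cutoff = 4.5e5,
                                   n = NULL) {
  mode <- match.arg(mode)
  check_expression_table(expr)
  if (mode == "threshold") {
    if (high_cutoff < strong_cutoff) {
      stop("'high_cutoff' must be >= 'strong_cutoff'")
    }
    list(strong = expr$gene_id[expr$intensity >= strong_cutoff],
         high = expr$gene_id[expr$intensity >= high_cutoff],
         all = expr$gene_id)
  } else {
    if (is.null(n) || n < 1L) stop("'n' must be a positive integer")
    if (n > nrow(expr)) {
      stop(sprintf("'n' (%d) exceeds the number of genes (%d)", n, nrow(expr)))
    }
    o <- order(-expr$intensity, expr$gene_id)
    list(top = expr$gene_id[o[seq_len(n)]], all = expr$gene_id)
  }
}

check_expression_table <- function(expr) {
  if (!is.data.frame(expr) || !all(c("gene_id", "intensity") %in% names(expr))) {
    stop("expression table needs columns 'gene_id' and 'intensity'")
  }
  if (nrow(expr) == 0L) stop("expression table is empty")
  if (anyDuplicated(expr$gene_id)) stop("duplicate gene ids in expression table")
  if (!all(is.finite(expr$intensity)) || any(expr$intensity < 0)) {
    stop("intensities must be finite and non-negative")
  }
  invisible(expr)
}

#' Scan bias detection depth over expression rank
#'
#' For each n in an increasing grid, pools the codon counts of the top-n
#' expressed genes and runs [detect_bias()] against the pooled background of
#' all genes (inclusive by default), reporting which codons and how many
#' amino acids reach significance. This answers "how deep into the
#' expression ranking can the codon bias be detected".
#'
#' @param expr Expression table (`gene_id`, `intensity`).
#' @param counts Named list of per-gene `codon_counts`; genes missing from
#'   either input are dropped with a message.
#' @param n_grid Strictly increasing positive integers, all at most the
#'   number of usable genes.
#' @param alpha,mode,method,code Passed to [detect_bias()].
#' @param inclusive_background Keep the group inside the background
#'   (default `TRUE`, the convention of comparing a top stratum against all
#'   genes).
#' @return A `scan_table` data frame: `n_top`, `n_significant_codons`,
#'   `n_significant_amino_acids`, `significant_codons` (comma-joined), with
#'   the per-row codon sets in attribute `codon_sets`.
#' @export
rank_scan <- function(expr, counts, n_grid, alpha = 0.05,
                      mode = c("within_family", "vs_all"),
                      method = c("BH", "holm"),
                      inclusive_background = TRUE, code = genetic_code()) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  check_expression_table(expr)
  if (is.null(names(counts))) stop("'counts' must be a named list")
  usable <- intersect(expr$gene_id, names(counts))
  dropped <- nrow(expr) - length(usable)
  if (dropped > 0L) {
    message(sprintf("rank_scan: dropping %d gene(s) without codon counts",
                    dropped))
  }
  if (length(usable) == 0L) stop("no genes shared between 'expr' and 'counts'")
  n_grid <- as.integer(n_grid)
  if (length(n_grid) == 0L || any(n_grid < 1L) ||
      any(diff(n_grid) <= 0L)) {
    stop("'n_grid' must be strictly increasing positive integers")
  }
  if (max(n_grid) > length(usable)) {
    stop(sprintf("grid value %d exceeds the %d usable genes",
                 max(n_grid), length(usable)))
  }
  expr <- expr[expr$gene_id %in% usable, , drop = FALSE]
  o <- order(-expr$intensity, expr$gene_id)
  ids <- expr$gene_id[o]
  mat <- do.call(rbind, lapply(counts[ids], unclass))
  cum <- apply(mat, 2L, cumsum)
  if (length(ids) == 1L) cum <- matrix(cum, nrow = 1L, dimnames = list(NULL, names(counts[[1L]])))
  total <- cum[nrow(cum), ]
  rows <- lapply(n_grid, function(n) {
    grp <- new_codon_counts(cum[n, ], code)
    bg <- if (inclusive_background) total else total - cum[n, ]
    rs <- detect_bias(grp, new_codon_counts(bg, code), alpha = alpha,
                      mode = mode, method = method, code = code)
    sig <- sort(rs$codon[rs$direction != "none"])
    list(n_top = n, codons = sig,
         n_aa = length(attr(rs, "biased_amino_acids")))
  })
  out <- data.frame(
    n_top = vapply(rows, `[[`, integer(1L), "n_top"),
    n_significant_codons = vapply(rows, function(r) length(r$codons),
                                  integer(1L)),
    n_significant_amino_acids = vapply(rows, `[[`, integer(1L), "n_aa"),
    significant_codons = vapply(rows, function(r)
      paste(r$codons, collapse = ","), character(1L)),
    stringsAsFactors = FALSE)
  structure(out, codon_sets = lapply(rows, `[[`, "codons"),
            class = c("scan_table", "data.frame"))
}
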