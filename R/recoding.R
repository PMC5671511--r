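# Deterministic codon recoding: build a preferred/avoided target-codon map
# from bias results + group frequencies, apply it with an auditable ledger.

#' Build a recoding map from bias results
#'
#' For each amino acid in scope, the `"high"` mode targets the codon with
#' the maximal within-family frequency in the high-expression group and
#' `"low"` the minimal one, so a sequence can be pushed toward or away from
#' the preferred-codon profile. Scope defaults to the significantly biased
#' amino acids of `bias`; pass `scope = "all"` to recode every degenerate
#' family. Frequency ties are broken alphabetically (first codon wins) with
#' a warning, so map construction is deterministic.
#'
#' @param bias A `bias_result_set` from [detect_bias()] (used for the
#'   default scope).
#' @param group_freq A within-family [codon_frequencies()] table of the
#'   high-expression group.
#' @param mode `"high"` or `"low"`.
#' @param scope Character vector of amino acids to recode, `NULL` for the
#'   biased set, or `"all"` for every amino acid with >= 2 codons.
#' @param code A [genetic_code()].
#' @return A `recoding_map`: list with `mode`, `targets` (named amino acid ->
#'   codon), `scope`.
#' @export
build_recoding_map <- function(bias, group_freq, mode = c("high", "low"),
                               scope = NULL, code = genetic_code()) {
  mode <- match.arg(mode)
  if (!inherits(group_freq, "freq_table") ||
      !identical(attr(group_freq, "scope"), "within_family")) {
    stop("'group_freq' must be a within-family frequency table")
  }
  multi <- names(code$degeneracy)[code$degeneracy >= 2L]
  if (is.null(scope)) {
    if (!inherits(bias, "bias_result_set")) {
      stop("'bias' must be a bias_result_set (or supply 'scope' explicitly)")
    }
    scope <- attr(bias, "biased_amino_acids")
  } else if (identical(scope, "all")) {
    scope <- multi
  }
  scope <- sort(unique(scope))
  if (length(scope) == 0L) stop("recoding scope is empty")
  if (!all(scope %in% multi)) {
    stop(sprintf("scope contains amino acids without >= 2 codons: %s",
                 paste(setdiff(scope, multi), collapse = ", ")))
  }
  targets <- vapply(scope, function(a) {
    sub <- group_freq[group_freq$amino_acid == a, , drop = FALSE]
    if (nrow(sub) == 0L || anyNA(sub$freq)) {
      stop(sprintf("family frequencies undefined for amino acid '%s'", a))
    }
    want <- if (mode == "high") max(sub$freq) else min(sub$freq)
    hits <- sort(sub$codon[sub$freq == want])
    if (length(hits) > 1L) {
      warning(sprintf("frequency tie for amino acid '%s' (%s): taking %s",
                      a, paste(hits, collapse = "/"), hits[1L]),
              call. = FALSE)
    }
    hits[1L]
  }, character(1L))
  structure(list(mode = mode, targets = targets, scope = scope),
            class = "recoding_map")
}

#' @export
print.recoding_map <- function(x, ...) {
  cat(sprintf("<recoding_map> mode = %s, %d amino acids\n", x$mode,
              length(x$targets)))
  print(x$targets)
  invisible(x)
}

validate_recoding_map <- function(map, code = genetic_code()) {
  if (!inherits(map, "recoding_map")) stop("'map' must be a recoding_map")
  aa <- names(map$targets)
  if ("*" %in% aa) stop("stop codons cannot be recoded")
  ok <- unname(code$table[map$targets]) == aa
  if (!all(ok)) {
    stop(sprintf("target codon does not encode its amino acid: %s",
                 paste(map$targets[!ok], collapse = ", ")))
  }
  invisible(map)
}

#' Recode a coding sequence toward a target-codon map
#'
#' Every codon whose amino acid is in the map's scope and that differs from
#' the target codon is replaced; stop codons and out-of-scope amino acids
#' are never touched, so the protein sequence is invariant by construction.
#' Each substitution is recorded in a 1-based change ledger.
#'
#' @param seq Coding sequence (validated strictly).
#' @param map A `recoding_map`.
#' @param id Sequence id carried into the result.
#' @param code A [genetic_code()].
#' @return A `recoded_cds`: list with `original_id`, `seq`, `changes` (data
#'   frame `codon_index`, `from_codon`, `to_codon`), `n_changes`,
#'   `gc_before`, `gc_after`.
#' @examples
#' m <- structure(list(mode = "high", targets = c(K = "AAG", F = "TTC"),
#'                     scope = c("F", "K")), class = "recoding_map")
#' recode_cds("AAAAAGTTT", m)$seq  # "AAGAAGTTC"
#' @export
recode_cds <- function(seq, map, id = "<cds>", code = genetic_code()) {
  seq <- validate_cds(seq, id = id, strict = TRUE, code = code)
  validate_recoding_map(map, code)
  codons <- split_codons(seq)
  aa <- unname(code$table[codons])
  target <- map$targets[aa]  # NA where aa (or stop) has no target
  change <- !is.na(target) & codons != target
  changes <- data.frame(codon_index = which(change),
                        from_codon = codons[change],
                        to_codon = unname(target[change]),
                        stringsAsFactors = FALSE)
  codons[change] <- target[change]
  out <- paste0(codons, collapse = "")
  structure(list(original_id = id, seq = out, changes = changes,
                 n_changes = nrow(changes),
                 gc_before = gc_content(seq), gc_after = gc_content(out)),
            class = "recoded_cds")
}

#' @export
print.recoded_cds <- function(x, ...) {
  cat(sprintf("<recoded_cds> %s: %d change(s), GC %.3f -> %.3f\n",
              x$original_id, x$n_changes, x$gc_before, x$gc_after))
  invisible(x)
}

#' Codon-level diff of two equal-length sequences
#'
#' @param a,b Nucleotide strings of equal length divisible by 3.
#' @return Data frame `codon_index` (1-based), `codon_a`, `codon_b`, one row
#'   per differing frame-0 triplet.
#' @export
diff_codons <- function(a, b) {
  if (!is.character(a) || !is.character(b) || length(a) != 1L ||
      length(b) != 1L) {
    stop("'a' and 'b' must be single strings")
  }
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  if (nchar(a) %% 3L != 0L) stop("length not divisible by 3")
  ca <- split_codons(toupper(a))
  cb <- split_codons(toupper(b))
  d <- which(ca != cb)
  data.frame(codon_index = d, codon_a = ca[d], codon_b = cb[d],
             stringsAsFactors = FALSE)
}

#' Replay a change ledger onto a sequence
#'
#' Applies a recoding ledger (as produced by [recode_cds()]) to the original
#' sequence; each `from_codon` is checked against the sequence before the
#' swap, so a stale or misaligned ledger errors instead of corrupting.
#'
#' @param seq Original coding sequence.
#' @param changes Data frame with columns `codon_index`, `from_codon`,
#'   `to_codon`.
#' @return The recoded sequence string.
#' @export
apply_ledger <- function(seq, changes) {
  codons <- split_codons(toupper(seq))
  if (nrow(changes) == 0L) return(paste0(codons, collapse = ""))
  idx <- changes$codon_index
  if (any(idx < 1L) || any(idx > length(codons))) {
    stop("ledger index out of range")
  }
  if (!all(codons[idx] == changes$from_codon)) {
    stop("ledger 'from_codon' does not match the sequence")
  }
  codons[idx] <- changes$to_codon
  paste0(codons, collapse = "")
}
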