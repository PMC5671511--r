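# Genetic-code bookkeeping: the 64-codon universe, synonymous families,
# degeneracy classes. Everything downstream (counting, ENC, bias tests,
# recoding) takes a `code` argument so non-standard tables stay pluggable.

.code_cache <- new.env(parent = emptyenv())

#' Genetic code table with synonymous-family structure
#'
#' Builds the bookkeeping object used throughout the package: the codon to
#' amino-acid map, the synonymous families (amino acid to ordered codon list),
#' and the degeneracy classes needed for Wright's effective number of codons.
#'
#' @param table Named character vector mapping all 64 DNA codons (3-mers over
#'   A/C/G/T) to one-letter amino-acid codes, with `"*"` marking stop codons.
#'   `NULL` (default) uses the standard genetic code
#'   ([Biostrings::GENETIC_CODE]): 61 sense codons, 3 stops, 20 amino acids.
#' @return An object of class `genetic_code`: a list with elements
#'   `table` (codon -> amino acid, codons sorted), `families` (amino acid ->
#'   alphabetically sorted synonymous codons), `sense_codons`, `stop_codons`,
#'   and `degeneracy` (amino acid -> family size).
#' @examples
#' code <- genetic_code()
#' code$families[["K"]]   # Lys: AAA, AAG
#' @export
genetic_code <- function(table = NULL) {
  if (is.null(table)) {
    if (!is.null(.code_cache$standard)) {
      return(.code_cache$standard)
    }
    table <- Biostrings::GENETIC_CODE
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  codons <- names(table)
  if (length(table) != 64L || is.null(codons) || anyDuplicated(codons) ||
      !all(grepl("^[ACGT]{3}$", codons))) {
    stop("genetic code table must cover all 64 ACGT codons exactly once")
  }
  table <- table[order(codons)]
  aa <- unname(table)
  sense <- names(table)[aa != "*"]
  stops <- names(table)[aa == "*"]
  families <- lapply(split(sense, unname(table[sense])), sort)
  code <- structure(
    list(table = table,
         families = families,
         sense_codons = sense,
         stop_codons = stops,
         degeneracy = lengths(families)),
    class = "genetic_code")
  if (cache) .code_cache$standard <- code
  code
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf("<genetic_code> %d sense codons, %d stops, %d amino acids\n",
              length(x$sense_codons), length(x$stop_codons),
              length(x$families)))
  invisible(x)
}

# frame-0 triplet view of a nucleotide string
split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq.int(1L, n, 3L), seq.int(3L, n, 3L))
}

#' Validate a coding sequence
#'
#' Checks alphabet (strict A/C/G/T; ambiguity codes rejected), length
#' (at least one codon, divisible by 3), and internal stop codons. Strict
#' mode (the default) turns an internal stop into an error naming the codon
#' index; permissive mode downgrades it to a warning so exploratory counting
#' can proceed.
#'
#' @param seq Nucleotide string.
#' @param id Identifier used in error messages.
#' @param strict Logical; error (`TRUE`) or warn (`FALSE`) on internal stops.
#' @param code A [genetic_code()].
#' @return The validated (upper-cased) sequence, invisibly usable downstream.
#' @export
validate_cds <- function(seq, id = "<cds>", strict = TRUE,
                         code = genetic_code()) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop("'seq' must be a single nucleotide string")
  }
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) {
    stop(sprintf("sequence '%s' contains characters outside A/C/G/T (ambiguity codes are rejected)",
                 id))
  }
  n <- nchar(seq)
  if (n < 3L) stop(sprintf("sequence '%s' is shorter than one codon", id))
  if (n %% 3L != 0L) {
    stop(sprintf("length of '%s' (%d nt) is not divisible by 3", id, n))
  }
  aa <- unname(code$table[split_codons(seq)])
  internal <- which(aa[-length(aa)] == "*")
  if (length(internal)) {
    msg <- sprintf("internal stop codon %s at codon %d in '%s'",
                   split_codons(seq)[internal[1L]], internal[1L], id)
    if (strict) stop(msg) else warning(msg, call. = FALSE)
  }
  seq
}

#' Translate a coding sequence
#'
#' One amino-acid letter per codon; a terminal stop codon, if present, is
#' omitted from the protein string.
#'
#' @inheritParams validate_cds
#' @return Protein string (one-letter code).
#' @examples
#' translate_cds("ATGTTTTAA")  # "MF"
#' @export
translate_cds <- function(seq, id = "<cds>", strict = TRUE,
                          code = genetic_code()) {
  seq <- validate_cds(seq, id = id, strict = strict, code = code)
  aa <- unname(code$table[split_codons(seq)])
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste0(aa, collapse = "")
}
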