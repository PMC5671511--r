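# Format readers/writers shared by all modules: FASTA via Biostrings,
# TSV with headers for every tabular artifact, CSV for plates. All writers
# use UTF-8, "." decimals, and enough digits that write-then-read
# round-trips reproduce the in-memory structure.

#' Read a coding-sequence FASTA
#'
#' Ids are truncated at the first whitespace; duplicate ids are rejected.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate FASTA ids in '%s': %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  stats::setNames(as.character(x), ids)
}

#' Write a coding-sequence FASTA (60-column wrap)
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_cds_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("'seqs' must be uniquely named")
  }
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA, format(x, digits = 17, scientific = FALSE,
                                trim = TRUE))
  })
  utf8 <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(utf8))
  utils::write.table(df, utf8, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_tsv <- function(path, required = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!is.null(required) && !all(required %in% names(df))) {
    stop(sprintf("'%s' lacks required column(s): %s", path,
                 paste(setdiff(required, names(df)), collapse = ", ")))
  }
  df
}

#' Read / write an expression table (TSV: gene_id, intensity)
#' @param path TSV file with header.
#' @return Data frame `gene_id`, `intensity`.
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv(path, c("gene_id", "intensity"))
  df$gene_id <- as.character(df$gene_id)
  df$intensity <- as.numeric(df$intensity)
  check_expression_table(df[, c("gene_id", "intensity")])
}

#' @rdname read_expression_tsv
#' @param expr Expression data frame.
#' @export
write_expression_tsv <- function(expr, path) {
  check_expression_table(expr)
  write_tsv(expr[, c("gene_id", "intensity")], path)
}

#' Write a bias report (TSV, sorted by q then codon)
#' @param bias A `bias_result_set`.
#' @param path Output TSV.
#' @export
write_bias_tsv <- function(bias, path) {
  stopifnot(inherits(bias, "bias_result_set"))
  df <- as.data.frame(bias)[, c("codon", "amino_acid", "group_count",
                                "group_family_total", "background_count",
                                "background_family_total", "p_value",
                                "q_value", "direction")]
  names(df)[names(df) == "p_value"] <- "p"
  names(df)[names(df) == "q_value"] <- "q"
  write_tsv(df[order(df$q, df$codon), ], path)
}

#' Write a rank-scan report (TSV)
#' @param scan A `scan_table` from [rank_scan()].
#' @param path Output TSV.
#' @export
write_scan_tsv <- function(scan, path) {
  stopifnot(inherits(scan, "scan_table"))
  write_tsv(as.data.frame(scan), path)
}

#' Write the per-gene statistics report (TSV: gene_id, n_codons, gc, gc3, enc)
#' @param stats_df Output of [gene_stats()].
#' @param path Output TSV.
#' @export
write_gene_stats_tsv <- function(stats_df, path) {
  need <- c("gene_id", "n_codons", "gc", "gc3", "enc")
  stopifnot(all(need %in% names(stats_df)))
  write_tsv(stats_df[, need], path)
}

#' Read / write a recoding map (TSV: amino_acid, target_codon)
#' @param path TSV file.
#' @param mode Recoding mode recorded in the object (`"high"`/`"low"`).
#' @param code A [genetic_code()].
#' @return A `recoding_map`.
#' @export
read_recoding_map_tsv <- function(path, mode = "high",
                                  code = genetic_code()) {
  df <- read_tsv(path, c("amino_acid", "target_codon"))
  if (anyDuplicated(df$amino_acid)) stop("duplicate amino acids in map")
  map <- structure(list(mode = mode,
                        targets = stats::setNames(df$target_codon,
                                                  df$amino_acid),
                        scope = sort(df$amino_acid)),
                   class = "recoding_map")
  validate_recoding_map(map, code)
  map
}

#' @rdname read_recoding_map_tsv
#' @param map A `recoding_map`.
#' @export
write_recoding_map_tsv <- function(map, path) {
  validate_recoding_map(map)
  write_tsv(data.frame(amino_acid = names(map$targets),
                       target_codon = unname(map$targets),
                       stringsAsFactors = FALSE), path)
}

#' Write a recoding change ledger (TSV: codon_index, from_codon, to_codon)
#' @param recoded A `recoded_cds` (or its `changes` data frame).
#' @param path Output TSV.
#' @export
write_ledger_tsv <- function(recoded, path) {
  df <- if (inherits(recoded, "recoded_cds")) recoded$changes else recoded
  stopifnot(all(c("codon_index", "from_codon", "to_codon") %in% names(df)))
  write_tsv(df, path)
}

#' Read / write a plate CSV
#'
#' Columns `well`, `construct`, `role`, `channel`, `value` and optionally
#' `transfection` (one row per well x channel).
#'
#' @param path CSV file.
#' @return A validated plate data frame.
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "construct", "role", "channel", "value")
  if (!all(need %in% names(df))) {
    stop(sprintf("'%s' lacks required column(s): %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")))
  }
  df$construct <- as.character(df$construct)
  df$construct[df$construct == ""] <- NA_character_
  if ("transfection" %in% names(df)) {
    df$transfection <- as.character(df$transfection)
    df$transfection[df$transfection == ""] <- NA_character_
  }
  as_plate(df)
}

#' @rdname read_plate_csv
#' @param plate Plate data frame.
#' @export
write_plate_csv <- function(plate, path) {
  plate <- as_plate(plate)
  keep <- intersect(c("well", "construct", "role", "channel", "value",
                      "transfection"), names(plate))
  df <- as.data.frame(plate)[, keep]
  if (is.numeric(df$value)) {
    df$value <- format(df$value, digits = 17, scientific = FALSE,
                       trim = TRUE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a construct summary (TSV: construct, n, mean_ratio, sd, cv,
#' relative, p_vs_reference)
#' @param summary A `construct_summary`.
#' @param path Output TSV.
#' @export
write_summary_tsv <- function(summary, path) {
  stopifnot(inherits(summary, "construct_summary"))
  df <- as.data.frame(summary)[, c("construct", "n", "mean_ratio",
                                   "sd_ratio", "cv", "relative",
                                   "p_vs_reference")]
  names(df)[names(df) == "sd_ratio"] <- "sd"
  write_tsv(df, path)
}
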