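# Seeded synthetic generators: coding-sequence sets with planted codon
# preference shifts, log-scale expression tables, and two-channel plates
# with shared per-well transfection-efficiency factors. All are pure
# functions of (config, seed), so every downstream stage is testable
# against planted truth without external data.

lognormal_pars <- function(cv) {
  # meanlog/sdlog giving mean 1 and the requested coefficient of variation
  s2 <- log(1 + cv^2)
  c(meanlog = -s2 / 2, sdlog = sqrt(s2))
}

uniform_family_usage <- function(code = genetic_code()) {
  lapply(code$families, function(f) {
    stats::setNames(rep(1 / length(f), length(f)), f)
  })
}

#' Simulate a coding-sequence set with planted codon bias
#'
#' Generates genes whose codons are drawn per amino-acid position from
#' within-family multinomials. A "biased" subset emulates highly expressed
#' genes: in the planted families, the preferred codon's probability is
#' boosted by `bias_strength` and renormalized, so `bias_strength = 1` is an
#' exact null generator. Amino acids are drawn uniformly (amino-acid
#' composition does not enter the within-family tests), an ATG start is
#' forced and one terminal stop appended. Deterministic given `seed`.
#'
#' @param n_genes Total genes (default 220).
#' @param biased_subset_size Genes carrying the planted shift (default 20);
#'   they are the first genes and the truth table records the group.
#' @param biased_families Amino acids with a planted preference (default
#'   `c("E","F","H","K","Y")`, five two-fold families).
#' @param bias_strength Multiplier >= 1 on the preferred codon (default 5).
#' @param length_range Codon-count interval for gene bodies (default
#'   100-300, excluding start/stop).
#' @param base_usage Within-family usage of the background: named list
#'   amino acid -> named probability vector. Default uniform in each family.
#' @param seed Integer seed (required).
#' @param code A [genetic_code()].
#' @return List with `sequences` (named character vector), `truth` (data
#'   frame `gene_id`, `group` in `biased`/`background`), `planted_map`
#'   (named amino acid -> preferred codon), and `config`.
#' @export
simulate_cds_set <- function(n_genes = 220L, biased_subset_size = 20L,
                             biased_families = c("E", "F", "H", "K", "Y"),
                             bias_strength = 5, length_range = c(100L, 300L),
                             base_usage = NULL, seed,
                             code = genetic_code()) {
  stopifnot(n_genes >= 1L, biased_subset_size <= n_genes,
            bias_strength >= 1, length(length_range) == 2L,
            length_range[1L] >= 1L, length_range[1L] <= length_range[2L])
  if (missing(seed)) stop("'seed' is required")
  if (is.null(base_usage)) base_usage <- uniform_family_usage(code)
  aa_all <- names(code$families)
  if (!all(biased_families %in% aa_all)) stop("unknown amino acid in 'biased_families'")
  if (any(code$degeneracy[biased_families] < 2L)) {
    stop("biased families must have >= 2 codons")
  }
  for (a in aa_all) {
    u <- base_usage[[a]]
    if (is.null(u) || !setequal(names(u), code$families[[a]]) ||
        any(u < 0) || abs(sum(u) - 1) > 1e-9) {
      stop(sprintf("invalid base usage for amino acid '%s'", a))
    }
  }
  # planted map: preferred codon = alphabetically first codon of the family
  planted <- vapply(sort(biased_families),
                    function(a) code$families[[a]][1L], character(1L))
  biased_usage <- base_usage
  for (a in names(planted)) {
    u <- biased_usage[[a]]
    u[planted[[a]]] <- u[planted[[a]]] * bias_strength
    biased_usage[[a]] <- u / sum(u)
  }
  set.seed(seed)
  ids <- sprintf("gene%04d", seq_len(n_genes))
  group <- rep(c("biased", "background"),
               c(biased_subset_size, n_genes - biased_subset_size))
  lens <- sample.int(length_range[2L] - length_range[1L] + 1L, n_genes,
                     replace = TRUE) + length_range[1L] - 1L
  seqs <- vapply(seq_len(n_genes), function(i) {
    usage <- if (group[i] == "biased") biased_usage else base_usage
    aa <- sample(aa_all, lens[i], replace = TRUE)
    codons <- character(lens[i])
    for (a in unique(aa)) {
      idx <- which(aa == a)
      fam <- code$families[[a]]
      codons[idx] <- if (length(fam) == 1L) fam else
        sample(fam, length(idx), replace = TRUE, prob = usage[[a]])
    }
    stop_codon <- sample(code$stop_codons, 1L)
    paste0(c("ATG", codons, stop_codon), collapse = "")
  }, character(1L))
  list(sequences = stats::setNames(seqs, ids),
       truth = data.frame(gene_id = ids, group = group,
                          stringsAsFactors = FALSE),
       planted_map = planted,
       config = list(n_genes = n_genes,
                     biased_subset_size = biased_subset_size,
                     biased_families = sort(biased_families),
                     bias_strength = bias_strength,
                     length_range = length_range, seed = seed))
}

#' Simulate a log-scale expression table
#'
#' Intensities are lognormal on the scale of normalized microarray
#' fluorescence; the biased subset is drawn from a higher-location
#' lognormal so expression rank correlates with the planted codon bias and
#' threshold/top-n stratification is exercisable. Defaults place the
#' background so that roughly the top couple of percent of a large gene set
#' exceed the 200,000 cutoff while the biased genes sit near 450,000 and
#' above.
#'
#' @param gene_ids Character vector of gene ids.
#' @param biased_ids Subset of `gene_ids` to draw from the high component.
#' @param meanlog_background,sdlog_background Background lognormal
#'   parameters (default `log(2e4)`, 1).
#' @param meanlog_biased,sdlog_biased High-component parameters (default
#'   `log(5e5)`, 0.4).
#' @param seed Integer seed (required).
#' @return Data frame `gene_id`, `intensity`.
#' @export
simulate_expression <- function(gene_ids, biased_ids = character(0L),
                                meanlog_background = log(2e4),
                                sdlog_background = 1,
                                meanlog_biased = log(5e5),
                                sdlog_biased = 0.4, seed) {
  if (missing(seed)) stop("'seed' is required")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (!all(biased_ids %in% gene_ids)) stop("'biased_ids' must be a subset of 'gene_ids'")
  set.seed(seed)
  hi <- gene_ids %in% biased_ids
  n <- length(gene_ids)
  intensity <- numeric(n)
  intensity[!hi] <- stats::rlnorm(sum(!hi), meanlog_background,
                                  sdlog_background)
  intensity[hi] <- stats::rlnorm(sum(hi), meanlog_biased, sdlog_biased)
  data.frame(gene_id = gene_ids, intensity = intensity,
             stringsAsFactors = FALSE)
}

default_constructs <- function() {
  # relative strengths of the seven-construct comparison the dual-reporter
  # design was built for: reference promoter x three GFP codon variants,
  # plus the strong endogenous promoter series
  data.frame(
    construct = c("2xp35S:smGFP", "2xp35S:GFPhigh", "2xp35S:GFPlow",
                  "plhcsr1:smGFP", "plhcsr1:GFPhigh", "plhcsr1:GFPlow"),
    strength = c(1, 1.8, 0.4, 1.7, 5.7, 0.9),
    stringsAsFactors = FALSE)
}

#' Simulate a two-channel reporter plate
#'
#' Emulates the dual-cassette design: each well carries one multiplicative
#' transfection-efficiency factor that scales both channels, so the
#' GFP/mCherry ratio cancels it. The efficiency factor is drawn once per
#' (construct, transfection) - transformations, not wells, are the
#' dominant variance source - and shared by that transfection's wells.
#' Channel noise is multiplicative lognormal (fluorescence is positive and
#' heteroscedastic); a per-channel blank offset is added everywhere. Blank
#' wells read the blank level with noise; background wells add a small
#' autofluorescence term.
#'
#' Well model (sample wells):
#' `GFP = strength * base_GFP * efficiency * noise + blank_GFP`,
#' `mCherry = base_mCherry * efficiency * noise + blank_mCherry`.
#'
#' @param constructs Data frame `construct`, `strength` (> 0). Default: six
#'   promoter x codon-variant combinations with strengths 1, 1.8, 0.4,
#'   1.7, 5.7, 0.9 relative to the reference.
#' @param n_transfections Biological replicates per construct (default 4).
#' @param wells_per_transfection Wells per transfection (default 3).
#' @param efficiency_cv C.v. of the transfection-efficiency factor
#'   (default 0.5: transformation efficiencies vary a lot).
#' @param channel_noise_cv C.v. of per-well-per-channel measurement noise
#'   (default 0.1).
#' @param base_signal Named per-channel signal scale at strength 1 and
#'   efficiency 1.
#' @param blank_level Named per-channel blank offset.
#' @param background_level Named per-channel autofluorescence of
#'   non-transfected wells.
#' @param n_blank_wells,n_background_wells Control wells (default 3 each).
#' @param seed Integer seed (required).
#' @return List with `plate` (data frame `well`, `construct`, `role`,
#'   `channel`, `value`, `transfection`) and `truth` (per sample well:
#'   `well`, `construct`, `transfection`, `strength`, `efficiency`).
#' @export
simulate_plate <- function(constructs = default_constructs(),
                           n_transfections = 4L,
                           wells_per_transfection = 3L,
                           efficiency_cv = 0.5, channel_noise_cv = 0.1,
                           base_signal = c(GFP = 20000, mCherry = 10000),
                           blank_level = c(GFP = 300, mCherry = 300),
                           background_level = c(GFP = 80, mCherry = 40),
                           n_blank_wells = 3L, n_background_wells = 3L,
                           seed) {
  if (missing(seed)) stop("'seed' is required")
  stopifnot(is.data.frame(constructs),
            all(c("construct", "strength") %in% names(constructs)),
            all(constructs$strength > 0), efficiency_cv >= 0,
            channel_noise_cv >= 0, n_transfections >= 1L,
            wells_per_transfection >= 1L, n_blank_wells >= 1L)
  set.seed(seed)
  grid <- expand.grid(t = seq_len(n_transfections),
                      ci = seq_len(nrow(constructs)))
  eff_t <- stats::setNames(
    stats::rlnorm(nrow(grid), lognormal_pars(efficiency_cv)["meanlog"],
                  lognormal_pars(efficiency_cv)["sdlog"]),
    paste(grid$ci, grid$t, sep = "."))
  noise <- function(n) {
    if (channel_noise_cv == 0) rep(1, n) else
      stats::rlnorm(n, lognormal_pars(channel_noise_cv)["meanlog"],
                    lognormal_pars(channel_noise_cv)["sdlog"])
  }
  rows <- list()
  truth <- list()
  w <- 0L
  for (k in seq_len(nrow(grid))) {
    ci <- grid$ci[k]
    cid <- constructs$construct[ci]
    strength <- constructs$strength[ci]
    tf <- sprintf("%s_t%d", cid, grid$t[k])
    eff <- eff_t[[paste(ci, grid$t[k], sep = ".")]]
    for (j in seq_len(wells_per_transfection)) {
      w <- w + 1L
      well <- sprintf("W%03d", w)
      gfp <- strength * base_signal[["GFP"]] * eff * noise(1L) +
        blank_level[["GFP"]]
      mch <- base_signal[["mCherry"]] * eff * noise(1L) +
        blank_level[["mCherry"]]
      rows[[length(rows) + 1L]] <- data.frame(
        well = well, construct = cid, role = "sample",
        channel = PLATE_CHANNELS, value = c(gfp, mch), transfection = tf,
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        well = well, construct = cid, transfection = tf,
        strength = strength, efficiency = eff, stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(n_blank_wells)) {
    w <- w + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      well = sprintf("W%03d", w), construct = NA_character_, role = "blank",
      channel = PLATE_CHANNELS,
      value = c(blank_level[["GFP"]] * noise(1L),
                blank_level[["mCherry"]] * noise(1L)),
      transfection = NA_character_, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_background_wells)) {
    w <- w + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      well = sprintf("W%03d", w), construct = NA_character_,
      role = "background", channel = PLATE_CHANNELS,
      value = c(background_level[["GFP"]] * noise(1L) + blank_level[["GFP"]],
                background_level[["mCherry"]] * noise(1L) +
                  blank_level[["mCherry"]]),
      transfection = NA_character_, stringsAsFactors = FALSE)
  }
  list(plate = do.call(rbind, rows), truth = do.call(rbind, truth))
}
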