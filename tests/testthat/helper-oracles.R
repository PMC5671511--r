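# Independent oracles and small fixture builders used across the suite.

# Brute-force two-sided Fisher p: enumerate every table with the observed
# margins, probabilities from binomial coefficients directly (independent of
# the dhyper-based implementation path).
oracle_fisher_p <- function(m) {
  a <- m[1, 1]
  r1 <- a + m[1, 2]
  r2 <- m[2, 1] + m[2, 2]
  c1 <- a + m[2, 1]
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) {
    return(1)
  }
  ks <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  p0 <- pr[ks == a]
  min(1, sum(pr[pr <= p0 * (1 + 1e-7)]))
}

# all two-sided p-values for one margin setting at once (vectorized over the
# support), same tie convention
oracle_fisher_all <- function(r1, r2, c1) {
  ks <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n <- r1 + r2, c1)
  vapply(pr, function(p0) min(1, sum(pr[pr <= p0 * (1 + 1e-7)])),
         numeric(1))
}

# random CDS: ATG start, random sense codons, one stop; no internal stops
random_cds <- function(n_codons, code = genetic_code()) {
  body <- sample(code$sense_codons, n_codons, replace = TRUE)
  paste0(c("ATG", body, sample(code$stop_codons, 1)), collapse = "")
}

# random valid recoding map over a random subset of degenerate families
random_map <- function(code = genetic_code()) {
  multi <- names(code$degeneracy)[code$degeneracy >= 2]
  scope <- sort(sample(multi, sample(2:length(multi), 1)))
  targets <- vapply(scope, function(a) sample(code$families[[a]], 1),
                    character(1))
  structure(list(mode = "high", targets = targets, scope = scope),
            class = "recoding_map")
}

# random codon count set with enough mass that ENC is defined
random_counts <- function(code = genetic_code()) {
  codon_counts(stats::setNames(
    stats::rpois(61, lambda = stats::runif(61, 1, 20)),
    code$sense_codons))
}

sense_counts_from_table <- function(a, b, cc, d) {
  # embed a 2x2 table into Lys (AAA/AAG) group/background counts
  list(group = codon_counts(c(AAA = a, AAG = b)),
       background = codon_counts(c(AAA = cc, AAG = d)))
}
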