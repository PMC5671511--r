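# bias_detection: stratification, exact tests, FDR, detect_bias, rank_scan

test_that("exact_test_2x2 matches the enumeration oracle on sampled tables", {
  set.seed(11)
  for (i in 1:300) {
    m <- matrix(sample(0:25, 4, replace = TRUE), 2)
    expect_equal(exact_test_2x2(m), oracle_fisher_p(m), tolerance = 1e-12)
  }
  # and agrees with stats::fisher.test as a second, independent route
  for (i in 1:50) {
    m <- matrix(sample(0:40, 4, replace = TRUE), 2)
    if (sum(m) == 0) next
    expect_equal(exact_test_2x2(m), stats::fisher.test(m)$p.value,
                 tolerance = 1e-12)
  }
  expect_equal(exact_test_2x2(rbind(c(5, 5), c(50, 50))), 1)
  expect_equal(exact_test_2x2(rbind(c(0, 0), c(3, 4))), 1)  # empty margin
  expect_error(exact_test_2x2(rbind(c(-1, 2), c(3, 4))), "non-negative")
})

test_that("codon_bias_test builds the within-family table and directions", {
  tabs <- sense_counts_from_table(8, 2, 50, 50)
  r <- codon_bias_test(tabs$group, tabs$background, "AAA")
  # frozen from the enumeration oracle over [[8,2],[50,50]]
  expect_equal(r$p_value, 0.0985283364822736, tolerance = 1e-12)
  expect_identical(r$direction, "over")
  expect_identical(r$group_count, 8L)
  expect_identical(r$group_family_total, 10L)
  expect_identical(r$background_family_total, 100L)
  r2 <- codon_bias_test(tabs$background, tabs$group, "AAA")
  expect_identical(r2$direction, "under")
  # identical proportions: p = 1, no direction
  tied <- sense_counts_from_table(5, 5, 50, 50)
  rt <- codon_bias_test(tied$group, tied$background, "AAA")
  expect_equal(rt$p_value, 1)
  expect_identical(rt$direction, "none")
  # single-codon families untestable in either mode
  for (mode in c("within_family", "vs_all")) {
    ru <- codon_bias_test(tabs$group, tabs$background, "ATG", mode = mode)
    expect_false(ru$testable)
    expect_true(is.na(ru$p_value))
  }
  # stop codons untestable
  expect_false(codon_bias_test(tabs$group, tabs$background, "TAA")$testable)
})

test_that("vs_all mode uses all other sense codons as the rest cell", {
  g <- codon_counts(c(AAA = 10, TTT = 30))
  b <- codon_counts(c(AAA = 20, TTT = 20))
  r <- codon_bias_test(g, b, "AAA", mode = "vs_all")
  expect_identical(r$group_family_total, 40L)
  expect_equal(r$p_value, exact_test_2x2(rbind(c(10, 30), c(20, 20))),
               tolerance = 1e-15)
})

test_that("adjust_fdr reproduces BH step-up and Holm", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(0.03), 0.03)
  expect_equal(adjust_fdr(c(1, 1)), c(1, 1))
  expect_error(adjust_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(adjust_fdr(c(0.1, -0.2)), "\\[0, 1\\]")
  set.seed(21)
  for (i in 1:50) {
    p <- stats::runif(sample(1:40, 1))
    expect_equal(adjust_fdr(p), stats::p.adjust(p, "BH"), tolerance = 1e-15)
    expect_equal(adjust_fdr(p, "holm"), stats::p.adjust(p, "holm"),
                 tolerance = 1e-15)
  }
})

test_that("stratify_by_expression thresholds and top_n", {
  expr <- data.frame(gene_id = c("g1", "g2", "g3"),
                     intensity = c(5e5, 3e5, 1e5))
  s <- stratify_by_expression(expr)
  expect_setequal(s$strong, c("g1", "g2"))
  expect_setequal(s$high, "g1")
  expect_setequal(s$all, c("g1", "g2", "g3"))
  t2 <- stratify_by_expression(expr, "top_n", n = 2)
  expect_identical(t2$top, c("g1", "g2"))
  expect_error(stratify_by_expression(expr, "top_n", n = 5), "exceeds")
  expect_error(stratify_by_expression(expr, strong_cutoff = 3e5,
                                      high_cutoff = 1e5), ">=")
  expect_error(stratify_by_expression(
    data.frame(gene_id = c("a", "a"), intensity = c(1, 2))), "duplicate")
})

test_that("detect_bias recovers planted families and is quiet under the null", {
  sim <- simulate_cds_set(n_genes = 220, biased_subset_size = 20,
                          bias_strength = 5, seed = 101)
  cnt <- lapply(names(sim$sequences), function(id)
    count_codons(sim$sequences[[id]], id = id))
  names(cnt) <- names(sim$sequences)
  grp <- pool_counts(cnt[sim$truth$gene_id[sim$truth$group == "biased"]])
  bg <- pool_counts(cnt)
  rs <- detect_bias(grp, bg, alpha = 0.05)
  expect_s3_class(rs, "bias_result_set")
  expect_true(all(sim$config$biased_families %in%
                    attr(rs, "biased_amino_acids")))
  # directions on planted preferred codons are "over"
  planted_rows <- rs[rs$codon %in% sim$planted_map, ]
  expect_true(all(planted_rows$direction == "over"))
  # one row per testable codon; counts bounded by family totals
  expect_identical(nrow(rs), 59L)  # 61 sense - Met - Trp
  expect_true(all(rs$group_count <= rs$group_family_total))
  # group == background: nothing significant at any alpha < 1
  self <- detect_bias(bg, bg, alpha = 0.5)
  expect_identical(attr(self, "biased_amino_acids"), character(0))
  expect_true(all(self$direction == "none"))
})

test_that("planted-bias recall >= 80% with <= 1 family false positive over 20 seeds", {
  recalls <- numeric(20)
  fps <- integer(20)
  for (s in 1:20) {
    sim <- simulate_cds_set(n_genes = 220, biased_subset_size = 20,
                            bias_strength = 5, seed = 3000 + s)
    cnt <- lapply(names(sim$sequences), function(id)
      count_codons(sim$sequences[[id]], id = id))
    names(cnt) <- names(sim$sequences)
    grp <- pool_counts(cnt[sim$truth$gene_id[sim$truth$group == "biased"]])
    rs <- detect_bias(grp, pool_counts(cnt), alpha = 0.05)
    hit <- attr(rs, "biased_amino_acids")
    recalls[s] <- mean(sim$config$biased_families %in% hit)
    fps[s] <- length(setdiff(hit, sim$config$biased_families))
  }
  expect_true(all(recalls >= 0.8))
  # BH controls the expected false-discovery fraction, so the family-level
  # false-positive bound is on the mean across simulations
  expect_lte(mean(fps), 1)
})

test_that("rank_scan recovers planted bias at shallow depth and attenuates deep", {
  sim <- simulate_cds_set(n_genes = 250, biased_subset_size = 50,
                          bias_strength = 5, seed = 202)
  expr <- simulate_expression(
    sim$truth$gene_id, sim$truth$gene_id[sim$truth$group == "biased"],
    seed = 203)
  cnt <- lapply(names(sim$sequences), function(id)
    count_codons(sim$sequences[[id]], id = id))
  names(cnt) <- names(sim$sequences)
  sc <- rank_scan(expr, cnt, c(25, 50, 250), alpha = 0.05)
  expect_s3_class(sc, "scan_table")
  expect_identical(sc$n_top, c(25L, 50L, 250L))
  # shallow rows recover all planted families
  expect_gte(sc$n_significant_amino_acids[1], 5L)
  expect_gte(sc$n_significant_amino_acids[2], 5L)
  # the full-table row is a self-comparison: nothing significant
  expect_identical(sc$n_significant_codons[3], 0L)
  expect_identical(sc$significant_codons[3], "")
  expect_error(rank_scan(expr, cnt, c(50, 25)), "strictly increasing")
  expect_error(rank_scan(expr, cnt, c(10, 9999)), "exceeds")
})

test_that("rank_scan drops genes without counts and messages the count", {
  sim <- simulate_cds_set(n_genes = 30, biased_subset_size = 5, seed = 301)
  expr <- simulate_expression(
    c(sim$truth$gene_id, "ghost1", "ghost2"),
    sim$truth$gene_id[sim$truth$group == "biased"], seed = 302)
  cnt <- lapply(names(sim$sequences), function(id)
    count_codons(sim$sequences[[id]], id = id))
  names(cnt) <- names(sim$sequences)
  expect_message(rank_scan(expr, cnt, c(5, 30)), "dropping 2")
})
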