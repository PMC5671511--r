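# fluor_norm: blank subtraction, ratios, construct summaries, median cv

toy_plate <- function() {
  data.frame(
    well = rep(c("A1", "A2", "B1", "B2", "C1"), each = 2),
    construct = rep(c("x", "x", "ref", "ref", NA), each = 2),
    role = rep(c("sample", "sample", "sample", "sample", "blank"), each = 2),
    channel = rep(c("GFP", "mCherry"), 5),
    value = c(1500, 900, 1700, 1100, 1400, 800, 1600, 1000, 300, 300),
    transfection = rep(c("x_t1", "x_t2", "ref_t1", "ref_t2", NA), each = 2),
    stringsAsFactors = FALSE)
}

test_that("as_plate validates structure", {
  expect_silent(p <- as_plate(toy_plate()))
  bad <- toy_plate()[-1, ]                       # sample well with one channel
  expect_error(as_plate(bad), "both|exactly one")
  noblank <- toy_plate()[toy_plate()$role != "blank", ]
  expect_error(as_plate(noblank), "no blank well")
  badrole <- toy_plate()
  badrole$role[1] <- "mystery"
  expect_error(as_plate(badrole), "unknown role")
})

test_that("blank_correct subtracts channel means and flags negatives", {
  p <- toy_plate()
  p$value[p$well == "A2" & p$channel == "mCherry"] <- 250
  bc <- blank_correct(p)
  expect_equal(bc$value[bc$well == "A1" & bc$channel == "GFP"], 1200)
  expect_equal(bc$value[bc$well == "A2" & bc$channel == "mCherry"], -50)
  expect_true(bc$negative[bc$well == "A2" & bc$channel == "mCherry"])
  # blank wells read ~0 after correction
  expect_equal(bc$value[bc$role == "blank"], c(0, 0))
  # median aggregation option
  expect_silent(blank_correct(p, "median"))
})

test_that("normalized_ratios forms per-well ratios and excludes at-background wells", {
  p <- toy_plate()
  # add background wells and a sample well whose mCherry sits below them
  extra <- data.frame(
    well = rep(c("D1", "E1"), each = 2),
    construct = rep(c(NA, "x"), each = 2),
    role = rep(c("background", "sample"), each = 2),
    channel = rep(c("GFP", "mCherry"), 2),
    value = c(350, 350, 700, 310),
    transfection = rep(c(NA, "x_t3"), each = 2), stringsAsFactors = FALSE)
  rt <- normalized_ratios(blank_correct(rbind(p, extra)))
  expect_s3_class(rt, "ratio_table")
  expect_equal(rt$ratio[rt$well == "A1"], 1200 / 600)
  e1 <- rt[rt$well == "E1", ]
  expect_true(e1$excluded)           # corrected mCherry 10 <= background 50
  expect_identical(e1$reason, "mCherry at background")
  expect_true(is.na(e1$ratio))
  # uncorrected plate rejected; missing background wells rejected
  expect_error(normalized_ratios(as_plate(p)), "blank-corrected")
  expect_error(normalized_ratios(blank_correct(p)), "background wells")
  expect_silent(normalized_ratios(blank_correct(p), "none"))
})

test_that("ratios are invariant to a per-well efficiency factor", {
  p <- toy_plate()
  k <- c(A1 = 3.7, A2 = 0.2, B1 = 1.9, B2 = 11)
  scaled <- p
  smp <- scaled$role == "sample"
  scaled$value[smp] <- (scaled$value[smp] - 300) * k[scaled$well[smp]] + 300
  r0 <- normalized_ratios(blank_correct(p), "none")
  r1 <- normalized_ratios(blank_correct(scaled), "none")
  expect_equal(r1$ratio, r0$ratio, tolerance = 1e-12)
})

test_that("summarize_constructs aggregates per transfection and scales to the reference", {
  p <- toy_plate()
  rt <- normalized_ratios(blank_correct(p), "none")
  s <- summarize_constructs(rt, reference = "ref", scale = 1)
  expect_s3_class(s, "construct_summary")
  # replicate values computed by hand: ref {1100/500, 1300/700}, x {1200/600, 1400/800}
  ref_reps <- c(1100 / 500, 1300 / 700)
  x_reps <- c(2, 1.75)
  expect_equal(s$mean_ratio[s$construct == "ref"], mean(ref_reps))
  expect_equal(s$relative[s$construct == "ref"], 1)      # exact by contract
  expect_equal(s$relative[s$construct == "x"],
               mean(x_reps) / mean(ref_reps))
  expect_equal(s$p_vs_reference[s$construct == "x"],
               stats::t.test(x_reps, ref_reps, var.equal = TRUE)$p.value)
  expect_true(is.na(s$p_vs_reference[s$construct == "ref"]))
  # scale = 100 variant
  s100 <- summarize_constructs(rt, reference = "ref", scale = 100)
  expect_equal(s100$relative[s100$construct == "ref"], 100)
  expect_error(summarize_constructs(rt, reference = "nope"), "not present")
})

test_that("cv arithmetic and degenerate t-tests behave per contract", {
  rt <- structure(data.frame(
    well = sprintf("W%d", 1:6),
    construct = rep(c("a", "ref"), each = 3),
    transfection = sprintf("t%d", 1:6),
    gfp_corrected = c(1, 2, 3, 1, 2, 3),
    mcherry_corrected = 1,
    ratio = c(1, 2, 3, 1, 2, 3),
    excluded = FALSE, reason = "", stringsAsFactors = FALSE),
    class = c("ratio_table", "data.frame"))
  s <- summarize_constructs(rt, "ref")
  expect_equal(s$cv[s$construct == "a"], 0.5)    # replicates {1,2,3}
  # identical replicate sets: relative 1, p = 1 (zero t statistic)
  expect_equal(s$relative[s$construct == "a"], 1)
  expect_equal(s$p_vs_reference[s$construct == "a"], 1)
  # constant but different replicate sets: p -> 0
  rt2 <- rt
  rt2$ratio[rt2$construct == "a"] <- 5
  s2 <- summarize_constructs(rt2, "ref")
  expect_equal(s2$p_vs_reference[s2$construct == "a"],
               stats::t.test(c(5, 5, 5), c(1, 2, 3),
                             var.equal = TRUE)$p.value)
  # single-replicate construct is flagged with NA p
  rt3 <- rt[rt$well != "W1", ]
  rt3$transfection[rt3$construct == "a"] <- "t_only"
  s3 <- summarize_constructs(rt3, "ref")
  expect_identical(s3$n[s3$construct == "a"], 1L)
  expect_true(is.na(s3$p_vs_reference[s3$construct == "a"]))
  expect_match(s3$flag[s3$construct == "a"], "fewer than 2")
})

test_that("raising one construct's GFP by a factor scales its relative value", {
  sim <- simulate_plate(seed = 61)
  k <- 2.5
  boosted <- sim$plate
  # scale the blank-corrected GFP readings by k, using the plate's own
  # blank aggregate so the correction cancels exactly
  bl <- mean(boosted$value[boosted$role == "blank" &
                             boosted$channel == "GFP"])
  pick <- boosted$role == "sample" & boosted$channel == "GFP" &
    boosted$construct == "2xp35S:GFPhigh"
  boosted$value[pick] <- (boosted$value[pick] - bl) * k + bl
  s0 <- summarize_constructs(
    normalized_ratios(blank_correct(sim$plate)), "2xp35S:smGFP")
  s1 <- summarize_constructs(
    normalized_ratios(blank_correct(boosted)), "2xp35S:smGFP")
  expect_equal(s1$relative[s1$construct == "2xp35S:GFPhigh"],
               k * s0$relative[s0$construct == "2xp35S:GFPhigh"],
               tolerance = 1e-9)
})

test_that("median_cv summarizes construct variability", {
  df <- data.frame(cv = c(0.1, 0.2, 0.3))
  expect_equal(median_cv(df), 0.2)
  expect_equal(median_cv(data.frame(cv = 0.4)), 0.4)
  expect_error(median_cv(data.frame(x = 1)), "cv")
})
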