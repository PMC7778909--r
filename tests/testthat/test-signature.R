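# Two-set sequence signature: selection, tie-breaking, cutoff, z statistics,
# and signature matching.

sig_columns <- function(n) {
  tibble::tibble(position = sprintf("3x%02d", seq_len(n) + 29),
                 segment = "TM3")
}

make_pair <- function(set1, set2) {
  n <- nchar(set1[1])
  list(
    aln1 = gpcr_alignment(stats::setNames(set1,
                                          sprintf("a%d", seq_along(set1))),
                          sig_columns(n)),
    aln2 = gpcr_alignment(stats::setNames(set2,
                                          sprintf("b%d", seq_along(set2))),
                          sig_columns(n))
  )
}

test_that("fully separated columns yield a 100% difference entry", {
  p <- make_pair(c("D", "D", "D"), c("K", "K", "K"))
  sig <- compute_signature(p$aln1, p$aln2, cutoff = 50)
  expect_identical(nrow(sig), 1L)
  expect_identical(sig$group, "charge_negative@3")
  expect_identical(sig$polarity, "enriched_in_set1")
  expect_equal(sig$difference, 100)
  expect_equal(sig$cons_set1, 100)
  expect_equal(sig$cons_set2, 0)
})

test_that("identical sets produce no entry at any positive cutoff", {
  p <- make_pair(c("D", "D", "D"), c("D", "D", "D"))
  for (cutoff in c(0, 1, 50)) {
    expect_identical(nrow(compute_signature(p$aln1, p$aln2,
                                            cutoff = cutoff)), 0L)
  }
})

test_that("ties break toward the fewest distinct amino acids", {
  # all-D column: charge_negative@3 (1 member) beats @any (2) and charge_any
  p <- make_pair(c("D", "D", "D"), c("L", "L", "L"))
  expect_identical(compute_signature(p$aln1, p$aln2)$group,
                   "charge_negative@3")
  # D/E mix: @3 no longer reaches 100, @any (2 members) wins over
  # charge_any@any (5) and the hydrogen-bond supersets
  p <- make_pair(c("D", "E", "D"), c("L", "L", "L"))
  sig <- compute_signature(p$aln1, p$aln2)
  expect_identical(sig$group, "charge_negative@any")
  expect_equal(sig$difference, 100)
})

test_that("entries enriched in set 2 carry negative differences", {
  p <- make_pair(c("L", "L", "L"), c("D", "D", "D"))
  sig <- compute_signature(p$aln1, p$aln2)
  expect_identical(sig$polarity, "enriched_in_set2")
  expect_equal(sig$difference, -100)
})

test_that("swapping the sets negates differences and keeps the groups", {
  set.seed(21)
  for (rep in 1:10) {
    fx <- generate_contrast_alignments(
      n_set1 = 6, n_set2 = 6, n_columns = 12,
      planted = tibble::tibble(column = c(2, 7),
                               group_set1 = c("charge_negative@any",
                                              "aromatic@5"),
                               group_set2 = c("charge_positive@any",
                                              "aliphatic@any")),
      seed = rep)
    s12 <- compute_signature(fx$aln1, fx$aln2, cutoff = 0)
    s21 <- compute_signature(fx$aln2, fx$aln1, cutoff = 0)
    expect_identical(s12$position, s21$position)
    expect_identical(s12$group, s21$group)
    expect_equal(s12$difference, -s21$difference)
    expect_true(all(s12$polarity != s21$polarity))
  }
})

test_that("raising the cutoff never adds entries", {
  set.seed(22)
  fx <- generate_contrast_alignments(
    n_set1 = 5, n_set2 = 7, n_columns = 30,
    planted = tibble::tibble(column = 4,
                             group_set1 = "charge_negative@any",
                             group_set2 = "charge_positive@any"),
    seed = 5)
  prev <- NULL
  for (cutoff in c(0, 10, 25, 50, 75, 100)) {
    sig <- compute_signature(fx$aln1, fx$aln2, cutoff = cutoff)
    if (!is.null(prev)) expect_true(all(sig$position %in% prev))
    prev <- sig$position
  }
})

test_that("the Welch t-test matches an independent formula implementation", {
  res <- zscale_ttest(c(1, 2, 3, 4), c(3, 4, 5, 6))
  oracle <- welch_oracle(c(1, 2, 3, 4), c(3, 4, 5, 6))
  expect_equal(res$p_value, oracle$p_value, tolerance = 1e-9)
  expect_equal(res$mean_difference, -2)
  set.seed(23)
  for (rep in 1:200) {
    x <- stats::rnorm(sample(2:12, 1), sd = stats::runif(1, 0.5, 3))
    y <- stats::rnorm(sample(2:12, 1), mean = stats::runif(1, -2, 2))
    res <- zscale_ttest(x, y)
    oracle <- welch_oracle(x, y)
    expect_equal(res$p_value, oracle$p_value, tolerance = 1e-9)
    expect_equal(res$mean_difference, oracle$mean_difference,
                 tolerance = 1e-12)
  }
})

test_that("degenerate t-test inputs follow the stated conventions", {
  expect_equal(zscale_ttest(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  zero_var <- zscale_ttest(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_equal(zero_var$p_value, 0)
  expect_equal(zero_var$mean_difference, -1)
  expect_equal(zscale_ttest(c(2, 2, 2), c(2, 2, 2))$p_value, 1)
  short <- zscale_ttest(1, c(1, 2, 3))
  expect_false(short$computable)
  expect_true(is.na(short$p_value))
})

test_that("significance flags flip exactly at p = 0.05", {
  # n = 2 per set with equal variances: Welch df = 2; choose the mean shift
  # whose p-value sits exactly at the 5% critical point, then nudge it
  d_crit <- stats::qt(0.975, df = 2) * sqrt(0.5)
  p_above <- zscale_ttest(c(0, 1), c(0, 1) + d_crit * (1 - 1e-6))$p_value
  p_below <- zscale_ttest(c(0, 1), c(0, 1) + d_crit * (1 + 1e-6))$p_value
  expect_gt(p_above, 0.05)
  expect_lte(p_below, 0.05)
  # and the flag recorded in signature entries obeys p <= 0.05 exactly
  set.seed(24)
  fx <- generate_contrast_alignments(
    n_set1 = 8, n_set2 = 8, n_columns = 20,
    planted = tibble::tibble(column = 1:5,
                             group_set1 = "hbond_donor@2",
                             group_set2 = "aliphatic@3"),
    seed = 3)
  sig <- compute_signature(fx$aln1, fx$aln2, cutoff = 50)
  for (k in 1:5) {
    expect_identical(sig[[paste0("z", k, "_significant")]],
                     sig[[paste0("z", k, "_p")]] <= 0.05)
  }
})

test_that("a set with fewer than two residues leaves tests not computable", {
  p <- make_pair(c("D", "-", "-"), c("K", "K", "K"))
  sig <- compute_signature(p$aln1, p$aln2, cutoff = 10)
  expect_identical(nrow(sig), 1L)
  expect_false(sig$ttest_computable)
  expect_true(all(is.na(unlist(sig[, paste0("z", 1:5, "_p")]))))
})

test_that("the ergotamine-style fixture recovers exactly five positions", {
  fx <- ergotamine_fixture(seed = 101)
  sig <- compute_signature(fx$aln1, fx$aln2, cutoff = 50)
  expect_identical(sort(sig$position),
                   sort(c("3x33", "3x36", "5x43", "6x51", "6x52")))
  expect_true(all(abs(sig$difference) == 100))
})

test_that("planted determinants are recovered with perfect precision/recall", {
  for (seed in 1:25) {
    fx <- generate_contrast_alignments(
      n_set1 = 8, n_set2 = 8, n_columns = 50,
      planted = tibble::tibble(column = c(3, 11, 24, 37, 48),
                               group_set1 = c("charge_negative@any",
                                              "aromatic@5",
                                              "hbond_donor@2",
                                              "aliphatic@any",
                                              "charge_positive@any"),
                               group_set2 = c("charge_positive@any",
                                              "aliphatic@3",
                                              "aliphatic@3",
                                              "aromatic@5",
                                              "charge_negative@any")),
      seed = seed)
    sig <- compute_signature(fx$aln1, fx$aln2, cutoff = 50)
    expect_identical(sort(sig$position), sort(fx$truth$position))
  }
})

test_that("the conservation-contrast t-test variant is available", {
  p <- make_pair(c("D", "D", "E"), c("K", "K", "R"))
  sig <- compute_signature(p$aln1, p$aln2, cutoff = 50,
                           ttest = "conservation")
  expect_identical(nrow(sig), 1L)
  expect_true(is.finite(sig$z1_p) || is.na(sig$z1_p))
})

test_that("signature matching scores receptors by group membership", {
  p <- make_pair(c("DFS", "DYS", "EFT"), c("KLL", "RLI", "KIV"))
  sig <- compute_signature(p$aln1, p$aln2, cutoff = 50)
  m <- match_signature(sig, p$aln1)
  expect_equal(m$score[m$receptor_id == "a1"], 100)
  # gaps never match
  gappy <- gpcr_alignment(c(g = strrep("-", 3)), sig_columns(3))
  expect_equal(match_signature(sig, gappy)$score, 0)
  # missing positions are an error
  expect_error(match_signature(sig, gpcr_alignment(c(h = "DD"),
                                                   sig_columns(2))),
               "absent from alignment")
})

test_that("matching respects polarity for set-2 enriched entries", {
  sig <- tibble::tibble(position = "3x30", group = "charge_negative@any",
                        polarity = "enriched_in_set2")
  aln <- gpcr_alignment(c(neg = "D", pos = "K"), sig_columns(1))
  m <- match_signature(sig, aln)
  expect_equal(m$score[m$receptor_id == "pos"], 100)
  expect_equal(m$score[m$receptor_id == "neg"], 0)
})

test_that("random receptors match singleton-group signatures at chance", {
  sig <- tibble::tibble(position = sprintf("3x%02d", 30:34),
                        group = c("charge_negative@3", "charge_negative@4",
                                  "charge_positive@5", "charge_positive@6",
                                  "aliphatic@1"),
                        polarity = "enriched_in_set1")
  set.seed(25)
  n <- 2000
  seqs <- stats::setNames(
    replicate(n, paste(sample(gpcrsig:::AA_CODES, 5, replace = TRUE),
                       collapse = "")),
    sprintf("r%04d", seq_len(n)))
  aln <- gpcr_alignment(seqs, sig_columns(5))
  m <- match_signature(sig, aln)
  expect_equal(mean(m$score), 5, tolerance = 0.2)  # 1/20 per position
})

test_that("signatures round-trip through TSV and JSON", {
  fx <- ergotamine_fixture(seed = 5)
  sig <- compute_signature(fx$aln1, fx$aln2, cutoff = 50)
  tsv <- tempfile(fileext = ".tsv")
  js <- tempfile(fileext = ".json")
  write_signature(sig, tsv)
  write_signature(sig, js)
  back_tsv <- read_signature(tsv)
  back_js <- read_signature(js)
  expect_identical(back_tsv$position, sig$position)
  expect_equal(back_js$difference, sig$difference)
  expect_equal(attr(back_js, "cutoff"), 50)
})

test_that("glance and tidy summarise signatures", {
  fx <- ergotamine_fixture(seed = 6)
  sig <- compute_signature(fx$aln1, fx$aln2, cutoff = 50)
  g <- glance(sig)
  expect_identical(g$n_positions, 5L)
  expect_equal(g$max_abs_difference, 100)
  td <- tidy(sig)
  expect_identical(nrow(td), 25L)  # 5 positions x 5 z-scales
  expect_true(all(c("zscale", "z_diff", "z_p") %in% names(td)))
})

test_that("autoplot returns a ggplot for signatures and alignments", {
  fx <- ergotamine_fixture(seed = 7)
  sig <- compute_signature(fx$aln1, fx$aln2, cutoff = 50)
  expect_s3_class(autoplot(sig), "ggplot")
  expect_s3_class(autoplot(fx$aln1), "ggplot")
})
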