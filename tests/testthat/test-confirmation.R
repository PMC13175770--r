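mk_assay <- function(len = 200L, cut = 100L) {
  set.seed(2)
  data.frame(site_id = "s1", seq = rand_seq(len), cut = cut,
             tract_overlap = FALSE, stringsAsFactors = FALSE)
}

test_that("indel calls respect the quantification window and indel definition", {
  assay <- mk_assay()
  ref <- assay$seq
  del_at_cut <- paste0(substr(ref, 1, 100), substr(ref, 102, 200))
  ins_far <- paste0(substr(ref, 1, 130), "A", substr(ref, 131, 200))
  sub_at_cut <- ref
  substr(sub_at_cut, 101, 101) <- if (substr(ref, 101, 101) == "A") "C"
    else "A"
  reads <- c(rep(ref, 7), rep(del_at_cut, 3))
  q <- quantify_amplicon_indels(reads, assay, window_halfwidth = 2L)
  expect_equal(q$frequency, 0.30)
  # insertion 30 bp from the cut does not count at w = 2
  q2 <- quantify_amplicon_indels(c(ref, ins_far), assay, 2L)
  expect_equal(q2$indel, 0L)
  # substitutions never count
  q3 <- quantify_amplicon_indels(rep(sub_at_cut, 5), assay, 2L)
  expect_equal(q3$indel, 0L)
  # zero reads -> sentinel
  q4 <- quantify_amplicon_indels(character(0), assay)
  expect_true(q4$flagged)
  expect_true(is.na(q4$frequency))
})

test_that("an indel counts if any base overlaps the window boundary", {
  assay <- mk_assay()
  ref <- assay$seq
  # 3-bp deletion covering ref positions 97-99 (0-based), window [98, 102]
  del_edge <- paste0(substr(ref, 1, 97), substr(ref, 101, 200))
  q <- quantify_amplicon_indels(del_edge, assay, window_halfwidth = 2L)
  expect_equal(q$indel, 1L)
})

test_that("coverage classes and fractions follow the thresholds", {
  quants <- data.frame(
    site_id = rep(c("a", "b", "c"), each = 2),
    sample = rep(c("t", "c"), 3),
    total = c(150000L, 120000L, 5000L, 5000L, 50L, 60L))
  cov <- summarize_coverage(quants)
  expect_equal(cov$per_site$class,
               c(">10000", ">1000", "<=100"))
  expect_equal(cov$per_site$tested, c(TRUE, TRUE, FALSE))
  expect_equal(cov$fractions$fraction[cov$fractions$threshold == 10000],
               1 / 3)
  expect_equal(cov$fractions$fraction[cov$fractions$threshold == 100],
               2 / 3)
  # min depth 800 -> excluded from testing
  q2 <- data.frame(site_id = "x", sample = c("t", "c"),
                   total = c(800L, 100000L))
  expect_false(summarize_coverage(q2)$per_site$tested)
})

test_that("background summary reports median/IQR and homopolymer flags", {
  cq <- data.frame(site_id = c("a", "b", "c"), sample = "ctrl",
                   frequency = c(0.0007, 0.0012, 0.0029))
  bs <- background_stats(cq)
  expect_equal(bs$median, 0.0012)
  expect_equal(bs$q1, 0.00095)
  bs1 <- background_stats(cq[1, ])
  expect_equal(bs1$median, 0.0007)
  expect_equal(bs1$iqr, 0)
  bs2 <- background_stats(cq, tract_overlap = c(a = TRUE, b = FALSE,
                                                c = FALSE))
  expect_equal(bs2$per_site$homopolymer, c(TRUE, FALSE, FALSE))
})

test_that("homopolymer-flagged sites show elevated simulated background", {
  em <- error_model(base_indel_error_rate = 0.001,
                    homopolymer_multiplier = 5)
  assays <- data.frame(site_id = sprintf("s%03d", 1:400),
                       tract_overlap = rep(c(TRUE, FALSE), each = 200))
  counts <- simulate_amplicon_assay(assays, matrix(0, 400, 1),
                                    depths = 5000L, em = em,
                                    mode = "counts", seed = 3L)
  counts$frequency <- counts$indel / counts$total
  bs <- background_stats(counts,
                         stats::setNames(assays$tract_overlap,
                                         assays$site_id))
  flagged <- bs$per_site$control_frequency[bs$per_site$homopolymer]
  plain <- bs$per_site$control_frequency[!bs$per_site$homopolymer]
  expect_gt(mean(flagged), mean(plain) * 3)
})

test_that("confirmation test agrees with a one-sided Fisher oracle", {
  quants <- data.frame(
    site_id = "s1",
    sample = c("d1", "d2", "d3", "c1"),
    role = c("treatment", "treatment", "treatment", "control"),
    total = 200000L,
    indel = c(40L, 35L, 25L, 10L))
  quants$frequency <- quants$indel / quants$total
  out <- test_confirmation(quants, fdr = 0.05)
  fisher_p <- fisher.test(matrix(c(100L, 200000L * 3 - 100L,
                                   10L, 200000L - 10L), 2,
                                 byrow = TRUE),
                          alternative = "greater")$p.value
  expect_equal(out$p_value, fisher_p, tolerance = 1e-9)
  expect_true(out$significant)

  # equal counts: not significant
  q2 <- quants
  q2$indel <- c(24L, 24L, 24L, 24L * 3L)
  q2$total[4] <- 600000L
  q2$frequency <- q2$indel / q2$total
  expect_false(test_confirmation(q2)$significant)
})

test_that("the donor-independence guard blocks single-donor signals", {
  quants <- data.frame(
    site_id = "s1",
    sample = c("d1", "d2", "d3", "c1"),
    role = c("treatment", "treatment", "treatment", "control"),
    total = 200000L,
    indel = c(1000L, 1000L, 10L, 200L))
  quants$frequency <- quants$indel / quants$total
  out <- test_confirmation(quants)
  expect_false(out$donor_guard)      # donor 3 below pooled control 0.1%
  expect_false(out$significant)
})

test_that("sites below the coverage filter are never significant", {
  quants <- data.frame(
    site_id = rep(c("lo", "hi"), each = 2),
    sample = rep(c("d1", "c1"), 2),
    role = rep(c("treatment", "control"), 2),
    total = c(500L, 500L, 200000L, 200000L),
    indel = c(200L, 2L, 800L, 200L))
  quants$frequency <- quants$indel / quants$total
  out <- test_confirmation(quants)
  lo <- out[out$site_id == "lo", ]
  expect_false(lo$tested)
  expect_false(lo$significant)
  expect_true(out$significant[out$site_id == "hi"])
  # missing controls error
  qq <- quants[quants$role == "treatment", ]
  expect_error(test_confirmation(qq), "no control data")
})

test_that("count-level estimator is calibrated at high depth", {
  em <- error_model(base_indel_error_rate = 0)
  assays <- data.frame(site_id = sprintf("s%03d", 1:500),
                       tract_overlap = FALSE)
  f0 <- 0.004
  counts <- simulate_amplicon_assay(assays, matrix(f0, 500, 1),
                                    depths = 200000L, em = em,
                                    mode = "counts", seed = 12L)
  est <- counts$indel / counts$total
  se <- sqrt(f0 * (1 - f0) / 200000 / 500)
  expect_lt(abs(mean(est) - f0), 2 * se)
})
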