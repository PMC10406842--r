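test_that("poisson_peak_call finds planted enrichment and nothing else", {
  binning <- genomic_binning("chr", 2000 * 25, 25)

  # constant track: no bin exceeds its own background
  expect_equal(nrow(poisson_peak_call(rep(asinh(3), 2000), binning)), 0L)
  # all-zero track: empty peak set, not an error
  expect_equal(nrow(poisson_peak_call(rep(0, 2000), binning)), 0L)

  # flat lambda = 2 with one bin at 100: exactly one single-bin peak, and
  # the expected call verified through an explicitly summed Poisson tail
  x <- rep(2, 2000)
  x[500] <- 100
  ps <- poisson_peak_call(x, binning, scale = "measurement")
  expect_equal(nrow(ps), 1L)
  expect_equal(ps$start, 499 * 25)
  expect_equal(ps$end, 500 * 25)
  lambda <- mean(x)
  p_tail <- 1 - sum(exp(-lambda) * lambda^(0:99) / factorial(0:99))
  expect_lt(p_tail * 2000, 0.01)  # even Bonferroni-sized adjustment passes

  # two adjacent significant bins merge into one 50 bp interval
  x2 <- rep(2, 2000)
  x2[c(700, 701)] <- 100
  ps2 <- poisson_peak_call(x2, binning, scale = "measurement")
  expect_equal(nrow(ps2), 1L)
  expect_equal(c(ps2$start, ps2$end), c(699 * 25, 701 * 25))

  # threshold monotonicity: stricter alpha yields a subset of enriched bins
  set.seed(44)
  x3 <- rpois(2000, 2) + ifelse(seq_len(2000) %in% sample(2000, 30), 60, 0)
  loose <- peak_bins(poisson_peak_call(x3, binning, alpha = 0.01,
                                       scale = "measurement"), binning)
  strict <- peak_bins(poisson_peak_call(x3, binning, alpha = 1e-6,
                                        scale = "measurement"), binning)
  expect_true(all(!strict | loose))

  # local-lambda mode suppresses calls inside broad elevated regions
  x4 <- rep(1, 2000)
  x4[800:1200] <- 20
  n_global <- nrow(poisson_peak_call(x4, binning, scale = "measurement"))
  n_local <- nrow(poisson_peak_call(x4, binning, lambda_mode = "local",
                                    scale = "measurement"))
  expect_lte(n_local, n_global)
})

test_that("BH adjustment preserves p-value order", {
  set.seed(10)
  for (k in 1:25) {
    p <- runif(100)
    padj <- stats::p.adjust(p, "BH")
    expect_true(all(diff(padj[order(p)]) >= -1e-12))
  }
})

test_that("stratified_mse_pearson matches direct formulas", {
  obs <- c(1, 2, 3)
  expect_equal(stratified_mse_pearson(obs, obs, c(TRUE, FALSE, TRUE))$mse[["global"]], 0)
  expect_equal(stratified_mse_pearson(obs, obs, c(TRUE, FALSE, TRUE))$pearson[["global"]], 1)

  r <- stratified_mse_pearson(c(3, 2, 1), obs, rep(FALSE, 3))
  expect_equal(r$mse[["global"]], 8 / 3)
  expect_equal(r$pearson[["global"]], -1)
  expect_true(is.na(r$pearson[["fg"]]))  # empty stratum

  set.seed(6)
  a <- rnorm(100)^2
  b <- rnorm(100)^2
  fg <- runif(100) < 0.3
  r2 <- stratified_mse_pearson(a, b, fg)
  expect_equal(r2$mse[["fg"]], sum((a[fg] - b[fg])^2) / sum(fg), tolerance = 1e-12)
  expect_equal(r2$pearson[["bg"]],
               sum(scale(a[!fg]) * scale(b[!fg])) / (sum(!fg) - 1),
               tolerance = 1e-12)

  # zero-variance stratum reported missing
  r3 <- stratified_mse_pearson(rep(1, 4), c(1, 2, 3, 4), rep(FALSE, 4))
  expect_true(is.na(r3$pearson[["global"]]))
})

test_that("auprc matches brute-force threshold enumeration", {
  expect_equal(auprc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_error(auprc(1:3, c(1, 1, 1)), "positive and one negative")

  # constant scores: one operating point at the positive fraction
  expect_equal(auprc(rep(0.5, 10), c(rep(1, 3), rep(0, 7))), 0.3)

  # the 6-point hand case
  labels <- c(1, 0, 1, 1, 0, 0)
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  expect_equal(auprc(scores, labels), oracle_auprc(scores, labels))
  expect_equal(auprc(scores, labels), 1 / 3 * (1 + 2 / 3 + 3 / 4))

  # random instances incl. ties
  set.seed(23)
  for (k in 1:30) {
    n <- sample(5:40, 1)
    sc <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    lb <- runif(n) < 0.4
    if (!any(lb) || all(lb)) next
    expect_equal(auprc(sc, lb), oracle_auprc(sc, lb), tolerance = 1e-12)
  }
})

test_that("peakset precision/recall is a bin-level set comparison", {
  binning <- genomic_binning("chr", 100 * 25, 25)
  a <- peak_set(c(100, 500), c(200, 700), c(1, 2), "chr")
  expect_equal(peakset_precision_recall(a, a, binning),
               c(precision = 1, recall = 1))

  # predicted covers half the reference bins
  ref <- peak_set(0, 200, 1, "chr")     # bins 1..8
  pred <- peak_set(0, 100, 1, "chr")    # bins 1..4
  expect_equal(peakset_precision_recall(pred, ref, binning),
               c(precision = 1, recall = 0.5))

  empty <- peak_set(chrom = "chr")
  pr <- peakset_precision_recall(empty, ref, binning)
  expect_true(is.na(pr[["precision"]]))
  expect_equal(pr[["recall"]], 0)

  # random pair against explicit per-bin set intersection
  set.seed(17)
  for (k in 1:10) {
    s1 <- sort(sample(seq(0, 2400, by = 50), 4))
    s2 <- sort(sample(seq(0, 2400, by = 50), 4))
    p1 <- peak_set(s1[c(1, 3)], s1[c(1, 3)] + c(50, 75), c(0, 0), "chr")
    p2 <- peak_set(s2[c(1, 3)], s2[c(1, 3)] + c(60, 30), c(0, 0), "chr")
    bins1 <- which(peak_bins(p1, binning))
    bins2 <- which(peak_bins(p2, binning))
    got <- peakset_precision_recall(p1, p2, binning)
    expect_equal(got[["precision"]], length(intersect(bins1, bins2)) / length(bins1))
    expect_equal(got[["recall"]], length(intersect(bins1, bins2)) / length(bins2))
  }
})

test_that("individual_specific_regions applies exclusion and length rules", {
  binning <- genomic_binning("chr", 400 * 25, 25)
  target <- peak_set(c(1000, 3000, 5000), c(1400, 3100, 5400),
                     c(1, 1, 1), "chr")
  training <- peak_set(1100, 1300, 1, "chr")
  reg <- individual_specific_regions(target, training, binning)

  # conserved peak (overlaps training) excluded
  expect_true(all(!reg$eval_mask[peak_bins(peak_set(1000, 1400, 1, "chr"), binning)]))
  # 100 bp target-only peak excluded as spurious
  expect_true(all(!reg$eval_mask[peak_bins(peak_set(3000, 3100, 1, "chr"), binning)]))
  # 400 bp target-only peak: positives at 25 bp resolution
  pos_bins <- peak_bins(peak_set(5000, 5400, 1, "chr"), binning)
  expect_true(all(reg$labels[pos_bins]))
  expect_equal(sum(reg$labels), 16L)

  # exactly 200 bp peak -> 8 positive bins
  t200 <- peak_set(2000, 2200, 1, "chr")
  r200 <- individual_specific_regions(t200, peak_set(chrom = "chr"), binning)
  expect_equal(sum(r200$labels), 8L)
})

test_that("individual_specific_auprc scores imputations against regions", {
  binning <- genomic_binning("chr", 1000 * 25, 25)
  target <- peak_set(c(5000, 15000), c(5500, 15400), c(1, 1), "chr")
  reg <- individual_specific_regions(target, peak_set(chrom = "chr"), binning)

  truth_track <- as.numeric(reg$labels) * 3
  got <- individual_specific_auprc(truth_track + 0.001 * seq_len(1000) / 1e6, reg)
  expect_equal(got[["auprc"]], 1)
  expect_equal(got[["pos_fraction"]], mean(reg$labels))

  # an imputation that copies the training individual (which lacks the
  # peaks entirely) ranks positives at background level
  set.seed(33)
  train_like <- abs(rnorm(1000, sd = 0.1))
  adv <- individual_specific_auprc(train_like, reg)
  expect_lt(adv[["auprc"]], 0.15)

  # no positives after filtering: metric missing
  reg0 <- individual_specific_regions(peak_set(chrom = "chr"),
                                      peak_set(chrom = "chr"), binning)
  r0 <- individual_specific_auprc(train_like, reg0)
  expect_true(is.na(r0[["auprc"]]))

  # invariance to prepending excluded bins
  reg_pad <- list(eval_mask = c(rep(FALSE, 50), reg$eval_mask),
                  labels = c(rep(FALSE, 50), reg$labels))
  got_pad <- individual_specific_auprc(c(runif(50), truth_track + 0.001 * seq_len(1000) / 1e6),
                                       reg_pad)
  expect_equal(got_pad[["auprc"]], got[["auprc"]])
})

test_that("peak sets survive a BED round trip", {
  ps <- peak_set(c(100, 500), c(250, 900), c(3.5, 7.1), "chr21")
  path <- withr::local_tempfile(fileext = ".bed")
  write_peaks(ps, path)
  back <- read_peaks(path)
  expect_equal(back$start, ps$start)
  expect_equal(back$end, ps$end)
  expect_equal(attr(back, "chrom"), "chr21")
  expect_error(peak_set(10, 10), "end > start")
  expect_error(peak_set(c(0, 5), c(10, 20)), "non-overlapping")
})
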