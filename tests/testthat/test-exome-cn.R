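# Exome-coverage copy-number path: locus selection, log ratios, GC LOESS.

cov_track <- function(sample, chrom, pos, depth) {
  coverage_track(sample, data.frame(chrom = chrom, pos = pos, depth = depth))
}

test_that("locus selection scans greedily with 250-bp spacing", {
  norm <- cov_track("N1", "1", 1:1000, 30)
  targets <- data.frame(chrom = "1", start = 1, end = 1000)
  loci <- select_loci(targets, list(norm))
  expect_equal(loci$pos, c(1, 251, 501, 751))
  # spacing invariant holds exactly
  expect_true(all(diff(loci$pos) >= 250))
})

test_that("locus selection enforces min depth in every normal", {
  # depth 24 < 25 everywhere -> no loci -> error
  norm24 <- cov_track("N1", "1", 1:1000, 24)
  targets <- data.frame(chrom = "1", start = 1, end = 1000)
  expect_error(select_loci(targets, list(norm24)), "no loci")
  # the minimum across normals governs
  normA <- cov_track("N1", "1", 1:1000, 30)
  normB <- cov_track("N2", "1", 1:1000, c(rep(30, 500), rep(10, 500)))
  loci <- select_loci(targets, list(normA, normB))
  expect_true(all(loci$pos <= 500))
})

test_that("spacing resets at region boundaries", {
  norm <- cov_track("N1", "1", 1:2000, 30)
  targets <- data.frame(chrom = "1", start = c(1, 1101), end = c(100, 1200))
  loci <- select_loci(targets, list(norm))
  expect_equal(loci$pos, c(1, 1101))  # one locus per 100-bp region
})

test_that("BED targets convert from 0-based half-open coordinates", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("1\t0\t1000", "2\t500\t600"), f)
  tg <- read_bed_targets(f)
  expect_equal(tg$start, c(1, 501))
  expect_equal(tg$end, c(1000, 600))
})

test_that("coverage log ratio is library-size scaled", {
  loci <- data.frame(chrom = "1", pos = seq(1, 1000, by = 250))
  norm <- cov_track("N", "1", loci$pos, 40)
  # identical tracks -> r = 0 everywhere
  r0 <- coverage_log_ratio(cov_track("T", "1", loci$pos, 40), norm, loci)
  expect_equal(r0$logratio, rep(0, 4))
  # uniformly doubled tumor depth -> still 0 after scaling
  r2 <- coverage_log_ratio(cov_track("T", "1", loci$pos, 80), norm, loci)
  expect_equal(r2$logratio, rep(0, 4))
  # doubling on one chromosome only: ~ +1 there, slightly negative elsewhere
  loci2 <- data.frame(chrom = rep(c("1", "2"), each = 4),
                      pos = rep(seq(1, 1000, by = 250), 2))
  normal2 <- cov_track("N", loci2$chrom, loci2$pos, 40)
  tum <- cov_track("T", loci2$chrom, loci2$pos,
                   ifelse(loci2$chrom == "1", 80, 40))
  r3 <- coverage_log_ratio(tum, normal2, loci2)
  on1 <- r3$logratio[r3$chrom == "1"]
  off <- r3$logratio[r3$chrom == "2"]
  expect_equal(unique(round(on1 - off, 10)), 1)  # relative doubling
  expect_true(all(off < 0))
  expect_equal(mean(on1), 1 + mean(off))
})

test_that("zero depths are handled by dropping or pseudo-counting", {
  loci <- data.frame(chrom = "1", pos = c(1, 300, 600))
  norm <- cov_track("N", "1", loci$pos, c(40, 0, 40))
  tum <- cov_track("T", "1", loci$pos, c(40, 40, 0))
  expect_warning(
    expect_message(r <- coverage_log_ratio(tum, norm, loci), "pseudo-count"),
    "zero normal depth")
  expect_equal(nrow(r), 2)
})

test_that("GC LOESS removes a planted GC effect", {
  set.seed(21)
  n <- 1500
  gc <- runif(n, 0.3, 0.7)
  series <- data.frame(chrom = "1", pos = seq_len(n) * 250,
                       logratio = 2 * (gc - 0.5) + rnorm(n, 0, 0.1))
  out <- gc_normalize(series, gc)
  slope <- stats::coef(stats::lm(out$logratio ~ gc))[2]
  expect_lt(abs(slope), 0.05)
  # residual GC dependence < 10% of the planted 0.8-magnitude effect
  sm <- stats::loess(out$logratio ~ gc)
  expect_lt(diff(range(stats::predict(sm))), 0.08)
})

test_that("GC normalization degenerates gracefully", {
  set.seed(22)
  n <- 1500
  gc <- runif(n, 0.3, 0.7)
  series <- data.frame(chrom = "1", pos = seq_len(n) * 250,
                       logratio = rnorm(n, 0.5, 0.1))
  # GC-independent input: output tracks the centered input
  out <- gc_normalize(series, gc)
  expect_gt(stats::cor(out$logratio,
                       series$logratio - mean(series$logratio)), 0.99)
  # constant GC: centering only, with a warning
  expect_warning(out2 <- gc_normalize(series, rep(0.5, n)), "constant GC")
  expect_equal(out2$logratio,
               series$logratio - stats::median(series$logratio))
  # too few loci: skipped with a warning
  expect_warning(out3 <- gc_normalize(series[1:10, ], gc[1:10]), "skipped")
  expect_equal(out3$logratio, series$logratio[1:10])
})

test_that("exome series feed the marker/segmentation path unchanged", {
  series <- data.frame(chrom = "1", pos = seq_len(24) * 250, logratio = 0.3)
  mk <- suppressWarnings(exome_marker_profile(series, toy_gp, "E1", "P1", "LCIS"))
  expect_s3_class(mk, "marker_profile")
  expect_equal(nrow(mk$markers), 2)
  acs <- one_step_arm_calls(mk, n_perm = 50, seed = 1)
  expect_s3_class(acs, "arm_call_set")
})

test_that("a planted whole-arm doubling is recovered through the exome path", {
  set.seed(23)
  cfg <- simulation_config(depth_mean = 100, seed = 23)
  hits <- 0
  for (r in 1:5) {
    events <- data.frame(arm = "1q", event = "gain", start_probe = 1,
                         end_probe = 100, amp = 1)
    sim <- simulate_exome_coverage(events, toy_gp, cfg)
    loci <- select_loci(sim$targets, list(sim$normal))
    lr <- coverage_log_ratio(sim$tumor, sim$normal, loci)
    gc <- sim$gc$gc[match(paste(lr$chrom, lr$pos),
                          paste(sim$gc$chrom, sim$gc$pos))]
    lr <- gc_normalize(lr, gc)
    mk <- exome_marker_profile(lr, toy_gp, "E", "P", "LCIS")
    acs <- one_step_arm_calls(mk, n_perm = 100)
    if (acs$calls$call[acs$calls$arm == "1q"] == "gain") hits <- hits + 1
    expect_true(all(acs$calls$call[acs$calls$arm != "1q"] == "none"))
  }
  expect_gte(hits, 4)
})
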