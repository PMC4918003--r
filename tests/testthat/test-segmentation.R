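# Marker averaging, recursive segmentation, one-step calls, MAD calling,
# QC gate.

test_that("adjacent averaging follows the remainder-group policy", {
  gp <- toy_gp
  mk_of <- function(n) {
    probes <- data.frame(chrom = "1", pos = seq_len(n) * 100, logratio = 1)
    pp <- suppressWarnings(probe_profile("L", "P", "LCIS", probes, gp))
    suppressWarnings(average_adjacent(pp, group_size = 12))
  }
  # 24 probes, constant value -> 2 markers of 12, both equal to the value
  m24 <- mk_of(24)
  expect_equal(nrow(m24$markers), 2)
  expect_equal(m24$markers$n_probes, c(12L, 12L))
  expect_equal(m24$markers$logratio, c(1, 1))
  # 30 probes: remainder 6 >= ceiling(12/2) kept -> sizes 12, 12, 6
  expect_equal(mk_of(30)$markers$n_probes, c(12L, 12L, 6L))
  # 29 probes: remainder 5 < 6 merged into the previous group -> 12, 17
  expect_equal(mk_of(29)$markers$n_probes, c(12L, 17L))
  # marker position is the median probe position of its group
  expect_equal(m24$markers$pos, c(stats::median(1:12 * 100),
                                  stats::median(13:24 * 100)))
})

test_that("group size 1 maps probes to markers unchanged", {
  set.seed(2)
  pp <- flat_probe_profile(n_per_arm = 15)
  mk <- average_adjacent(pp, group_size = 1)
  expect_equal(nrow(mk$markers), nrow(pp$probes))
  expect_equal(mk$markers$logratio, pp$probes$logratio)
  expect_equal(mk$markers$pos, pp$probes$pos)
})

test_that("arms with no probes are omitted with a warning", {
  probes <- data.frame(chrom = "1", pos = seq_len(24) * 100, logratio = 0)
  pp <- probe_profile("L", "P", "LCIS", probes, toy_gp)
  expect_warning(mk <- average_adjacent(pp), "no probes")
  expect_equal(unique(mk$markers$arm), "1p")
})

test_that("multi-step segmentation recovers planted change points", {
  set.seed(4)
  ev <- data.frame(arm = "1p", start = 40, end = 60, amp = 0.5)  # 5 SD of 0.1
  pp <- flat_probe_profile(n_per_arm = 100, sd = 0.1, events = ev)
  mk <- average_adjacent(pp, group_size = 1)
  seg <- segment_genome(mk, n_perm = 300, seed = 1)
  called <- seg$segments[seg$segments$arm == "1p" &
                           seg$segments$call != "none", ]
  expect_equal(nrow(called), 1)
  expect_lte(abs(called$start - 40), 2)
  expect_lte(abs(called$end - 60), 2)
  expect_equal(called$call, "gain")
  # segments tile each arm
  for (a in unique(seg$segments$arm)) {
    s <- seg$segments[seg$segments$arm == a, ]
    expect_equal(min(s$start), 1)
    expect_equal(sum(s$n_markers), max(s$end))
  }
})

test_that("constant and whole-arm-shifted arms give one segment each", {
  set.seed(5)
  ev <- data.frame(arm = "2q", start = 1, end = 120, amp = 0.6)
  pp <- flat_probe_profile(n_per_arm = 120, sd = 0.1, events = ev)
  mk <- average_adjacent(pp)
  seg <- segment_genome(mk, n_perm = 200, seed = 2)
  expect_equal(sum(seg$segments$arm == "1p"), 1)
  expect_equal(sum(seg$segments$arm == "2q"), 1)
  expect_equal(seg$segments$call[seg$segments$arm == "2q"], "gain")
})

test_that("gain/loss calling is strict at 1 MAD and handles zero MAD", {
  prof <- make_segmented(heights = c(0, 0.05, 0.15, -0.15),
                         n_markers = c(45, 9, 9, 9), resid_mad = 0.05)
  prof <- call_segments(prof)
  expect_equal(prof$median, 0)
  expect_equal(prof$mad, 0.05)
  # exactly median + 1 MAD is NOT called ("exceeds" is strict)
  expect_equal(prof$segments$call, c("none", "none", "gain", "loss"))

  # noiseless profile: MAD 0 falls back to any-offset calling
  prof0 <- make_segmented(heights = c(0, 0.2), n_markers = c(30, 10),
                          resid_mad = 0)
  expect_message(prof0 <- call_segments(prof0), "MAD is 0")
  expect_equal(prof0$segments$call, c("none", "gain"))
})

test_that("calls are invariant under a constant shift of all log ratios", {
  prof <- make_segmented(heights = c(0, 0.15, -0.2), n_markers = c(40, 12, 10))
  calls1 <- call_segments(prof)$segments$call
  shifted <- prof
  shifted$markers$logratio <- shifted$markers$logratio + 3
  shifted$segments$height <- shifted$segments$height + 3
  calls2 <- call_segments(shifted)$segments$call
  expect_equal(calls1, calls2)
  # and the QC gate sees identical metrics
  q1 <- qc_gate(call_segments(prof))
  q2 <- qc_gate(call_segments(shifted))
  expect_equal(q1$percent_aberrant, q2$percent_aberrant)
  expect_equal(q1$height_ratio, q2$height_ratio)
})

test_that("one-step calls match construction on flat, whole-arm and focal arms", {
  set.seed(6)
  ev <- data.frame(arm = c("1q", "2q"), start = c(1, 41), end = c(120, 80),
                   amp = c(0.5, 0.5))
  pp <- flat_probe_profile(n_per_arm = 120, sd = 0.1, events = ev)
  mk <- average_adjacent(pp)  # 10 markers per 120 probes? no: 120/12 = 10
  acs <- one_step_arm_calls(mk, n_perm = 300, seed = 3)
  calls <- acs$calls
  expect_equal(calls$call[calls$arm == "1q"], "gain")
  expect_equal(calls$start[calls$arm == "1q"], 1)
  expect_equal(calls$end[calls$arm == "1q"],
               calls$n_markers[calls$arm == "1q"])
  expect_equal(calls$call[calls$arm == "2q"], "gain")
  expect_equal(sum(calls$call != "none"), 2)

  # flat genome: every arm none
  set.seed(7)
  flat <- average_adjacent(flat_probe_profile(n_per_arm = 120, sd = 0.1))
  acs_flat <- one_step_arm_calls(flat, n_perm = 300, seed = 4)
  expect_true(all(acs_flat$calls$call == "none"))
})

test_that("focal one-step bounds equal the brute-force max-T oracle", {
  set.seed(8)
  for (r in 1:5) {
    n <- sample(25:50, 1)
    x <- rnorm(n, 0, 0.1)
    s0 <- sample(3:(n - 10), 1)
    e0 <- min(n - 2, s0 + sample(5:12, 1))
    x[s0:e0] <- x[s0:e0] + 0.6
    sc <- clonalpair:::max_t_scan(x)
    br <- brute_max_t(x)
    expect_equal(sc$s, br$s)
    expect_equal(sc$e, br$e)
    expect_equal(sc$t, br$t, tolerance = 1e-10)
  }
})

test_that("QC gate applies the 10% / 1.75 rules", {
  # no called segments -> percent 0, ratio 0, fail
  none <- call_segments(make_segmented(heights = c(0, 0.02),
                                       n_markers = c(40, 12)))
  q <- qc_gate(none)
  expect_equal(q$percent_aberrant, 0)
  expect_equal(q$height_ratio, 0)
  expect_false(q$pass)

  # >10% of markers in called segments passes on the percent rule
  pct <- call_segments(make_segmented(heights = c(0, 0.15, -0.15),
                                      n_markers = c(45, 9, 9)))
  qp <- qc_gate(pct)
  expect_gt(qp$percent_aberrant, 10)
  expect_true(qp$pass)

  # percent < 10 but a >=10-marker segment at 2 MAD passes on the ratio rule
  rat <- call_segments(make_segmented(heights = c(0, 0.10),
                                      n_markers = c(200, 12)))
  qr <- qc_gate(rat)
  expect_lt(qr$percent_aberrant, 10)
  expect_equal(qr$height_ratio, 2, tolerance = 1e-9)
  expect_true(qr$pass)

  # same height on a short (<10 marker) segment does not qualify
  short <- call_segments(make_segmented(heights = c(0, 0.10),
                                        n_markers = c(200, 8)))
  qs <- qc_gate(short)
  expect_equal(qs$height_ratio, 0)
  expect_false(qs$pass)
})

test_that("running-median detrend removes slow waves, preserves signal scale", {
  set.seed(9)
  pp <- flat_probe_profile(n_per_arm = 200, sd = 0.05)
  wave <- sin(seq_len(nrow(pp$probes)) / 15) * 0.3
  pp$probes$logratio <- pp$probes$logratio + wave
  dt <- detrend_running_median(pp, window = 51)
  expect_lt(stats::sd(dt$probes$logratio), stats::sd(pp$probes$logratio))
  expect_equal(dim(dt$probes), dim(pp$probes))
})
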