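# Frequency-weighted concordance statistic and cross-patient benchmark.

test_that("arm-event frequency estimator uses the +0.5/+1 shrinkage", {
  # 10 lesions, 8 carrying a loss on 2q (the 16q-loss stand-in)
  sets <- c(
    lapply(1:8, function(i) make_call_set(
      paste0("L", i), list(`2q` = list(event = "loss", start = 1, end = 30)))),
    lapply(9:10, function(i) make_call_set(paste0("L", i)))
  )
  fr <- estimate_arm_frequencies(sets)
  expect_equal(fr$freq[fr$arm == "2q" & fr$event == "loss"], 8.5 / 11)
  # never-observed event gets the pseudo-count floor
  expect_equal(fr$freq[fr$arm == "3p" & fr$event == "gain"], 0.5 / 11)
  # ubiquitous event stays strictly below 1
  sets_all <- lapply(1:10, function(i) make_call_set(
    paste0("L", i), list(`1q` = list(event = "gain", start = 1, end = 30))))
  fr_all <- estimate_arm_frequencies(sets_all)
  expect_equal(fr_all$freq[fr_all$arm == "1q" & fr_all$event == "gain"],
               10.5 / 11)
  expect_lt(max(fr_all$freq), 1)
  expect_error(estimate_arm_frequencies(sets[1]), "length")
})

test_that("concordance statistic weights closeness by event rarity", {
  fr <- data.frame(arm = rep(c("1q", "2q", "3p"), each = 2),
                   event = rep(c("gain", "loss"), 3),
                   freq = c(0.05, 0.05, 0.8, 0.8, 0.8, 0.8))
  # identical rare event, identical markers -> S = -log(0.05)
  a <- make_call_set("A", list(`1q` = list(event = "gain", start = 5, end = 20)))
  b <- make_call_set("B", list(`1q` = list(event = "gain", start = 5, end = 20)))
  s1 <- concordance_statistic(a, b, fr)
  expect_equal(s1$S, -log(0.05), tolerance = 1e-12)
  expect_equal(s1$records$closeness, 1)

  # two shared common events -> S = 2 * (-log 0.8), small
  a2 <- make_call_set("A", list(`2q` = list(event = "loss", start = 1, end = 30),
                                `3p` = list(event = "gain", start = 1, end = 30)))
  b2 <- make_call_set("B", list(`2q` = list(event = "loss", start = 1, end = 30),
                                `3p` = list(event = "gain", start = 1, end = 30)))
  s2 <- concordance_statistic(a2, b2, fr)
  expect_equal(s2$S, 2 * -log(0.8), tolerance = 1e-12)
  expect_lt(s2$S, s1$S)

  # empty call sets -> S = 0
  expect_equal(concordance_statistic(make_call_set("A"), make_call_set("B"),
                                     fr)$S, 0)

  # partial overlap: Jaccard closeness in markers
  a3 <- make_call_set("A", list(`1q` = list(event = "gain", start = 1, end = 20)))
  b3 <- make_call_set("B", list(`1q` = list(event = "gain", start = 11, end = 30)))
  s3 <- concordance_statistic(a3, b3, fr)
  expect_equal(s3$records$closeness, 10 / 30)

  # discordant arms contribute nothing (gain vs loss, call vs none)
  a4 <- make_call_set("A", list(`1q` = list(event = "gain", start = 1, end = 30),
                                `2q` = list(event = "loss", start = 1, end = 30)))
  b4 <- make_call_set("B", list(`1q` = list(event = "loss", start = 1, end = 30)))
  expect_equal(concordance_statistic(a4, b4, fr)$S, 0)
})

test_that("concordance statistic is symmetric and monotone in rarity", {
  fr <- function(f) data.frame(arm = "1q", event = "gain", freq = f)
  a <- make_call_set("A", list(`1q` = list(event = "gain", start = 3, end = 25)))
  b <- make_call_set("B", list(`1q` = list(event = "gain", start = 6, end = 28)))
  expect_equal(concordance_statistic(a, b, fr(0.3))$S,
               concordance_statistic(b, a, fr(0.3))$S)
  # lower frequency, same closeness -> strictly larger contribution
  expect_gt(concordance_statistic(a, b, fr(0.1))$S,
            concordance_statistic(a, b, fr(0.3))$S)
})

test_that("mismatched marker grids are an error", {
  a <- make_call_set("A", n_markers = 30)
  b <- make_call_set("B", n_markers = 25)
  expect_error(concordance_statistic(a, b,
                                     data.frame(arm = "1q", event = "gain",
                                                freq = 0.5)),
               "mismatched marker grids")
})

test_that("empirical p-value follows the +1-corrected rank formula", {
  ref <- structure(list(S = rep(0.5, 99), N_ref = 99),
                   class = "reference_distribution")
  # S = 0: every reference value >= 0 -> p = 1
  expect_equal(cn_clonality_pvalue(0, rep(0.2, 10)), 1)
  # above all 99 reference values -> p = 1/100
  expect_equal(cn_clonality_pvalue(1.0, ref), 0.01)
  # p never 0, always <= 1
  expect_gt(cn_clonality_pvalue(100, ref), 0)
})

test_that("reference distribution uses cross-patient pairs only", {
  mk <- function(id) make_call_set(id, list(
    `1q` = list(event = "gain", start = 1, end = 30)))
  # 3 patients, 1 lesion each -> 3 cross-patient pairs
  r3 <- build_reference(lapply(c("A", "B", "C"), mk), c("p1", "p2", "p3"))
  expect_equal(r3$N_ref, 3)
  # 2 patients with 2 lesions each -> 4 cross-patient pairs
  r4 <- build_reference(lapply(c("A1", "A2", "B1", "B2"), mk),
                        c("p1", "p1", "p2", "p2"))
  expect_equal(r4$N_ref, 4)
  expect_true(all(r4$S >= 0))
  # all lesions from one patient -> error
  expect_error(build_reference(lapply(c("A1", "A2"), mk), c("p1", "p1")),
               ">= 2 patients")
})
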