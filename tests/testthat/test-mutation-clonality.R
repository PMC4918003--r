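# Marginal probabilities, the LR clonality test, and the clonal/private
# spectrum bookkeeping.

test_that("marginal probabilities follow the shrinkage estimator", {
  ref <- frequency_reference(
    N = 1000,
    locus_counts = data.frame(chrom = "1", pos = c(100, 200),
                              ref = "A", alt = "T", count = c(0, 300)),
    gene_counts = data.frame(gene = "BIGGENE", count = 200))
  # floor: x = 0 -> 0.5/1001
  expect_equal(marginal_probability("1", 100, "A", "T", "G", ref), 0.5 / 1001)
  # hotspot: x = 300 -> 300.5/1001
  expect_equal(marginal_probability("1", 200, "A", "T", "G", ref), 300.5 / 1001)
  # unlisted locus in a counted gene: gene count apportioned over 100 sites
  expect_equal(marginal_probability("1", 999, "A", "T", "BIGGENE", ref),
               (200 / 100 + 0.5) / 1001)
  # unlisted locus, unlisted gene: pseudo-count floor
  expect_equal(marginal_probability("1", 999, "A", "T", "NOGENE", ref),
               0.5 / 1001)
  # x = N stays strictly below 1
  ref2 <- frequency_reference(N = 10, locus_counts = data.frame(
    chrom = "1", pos = 1, ref = "A", alt = "T", count = 10))
  expect_lt(marginal_probability("1", 1, "A", "T", "G", ref2), 1)
})

test_that("zero shared mutations give p = 1 exactly on both paths", {
  # exact path
  r <- lr_match_test(runif(10, 0.001, 0.3), rep(FALSE, 10))
  expect_identical(r$p_value, 1)
  expect_identical(r$lambda, 1)
  expect_identical(r$xi_hat, 0)
  # forced Monte Carlo path
  r2 <- lr_match_test(runif(25, 0.001, 0.3), rep(FALSE, 25),
                      n_mc = 200, seed = 1)
  expect_identical(r2$p_value, 1)
  # profile-level: totals 29 and 32, disjoint
  ref <- frequency_reference(N = 1000)
  a <- make_mut_profile("A", pos = 1:29)
  b <- make_mut_profile("B", pos = 101:132)
  res <- lr_clonality_test(a, b, ref)
  expect_identical(res$p_value, 1)
  expect_equal(res$m, 0L)
})

test_that("a ubiquitous match carries no evidence", {
  p <- c(1 - 1e-9, runif(7, 0.001, 0.01))
  r <- lr_match_test(p, c(TRUE, rep(FALSE, 7)))
  expect_equal(r$lambda, 1)
  expect_equal(r$p_value, 1)
  expect_equal(r$xi_hat, 0)
})

test_that("the empty conditioning set warns and returns p = 1", {
  expect_warning(r <- lr_match_test(numeric(0), logical(0)), "empty")
  expect_equal(r$p_value, 1)
})

test_that("exact path equals the full-enumeration oracle", {
  set.seed(11)
  for (rep in 1:6) {
    n <- sample(5:10, 1)
    p <- runif(n, 0.02, 0.5)
    matched <- runif(n) < pmax(p, 0.25)
    r <- lr_match_test(p, matched)
    expect_equal(r$method, "exact")
    expect_equal(r$p_value, oracle_lr_pvalue(p, matched), tolerance = 1e-9)
  }
})

test_that("Monte Carlo path agrees with exact enumeration within 2 SE", {
  set.seed(12)
  n <- 8
  p <- c(0.001, runif(n - 1, 0.05, 0.3))
  matched <- c(TRUE, rep(FALSE, n - 1))  # one shared rare mutation
  exact <- lr_match_test(p, matched)$p_value
  mc <- lr_match_test(p, matched, n_mc = 5000, seed = 99, exact_limit = 0)
  expect_equal(mc$method, "monte_carlo")
  se <- sqrt(exact * (1 - exact) / 5000)
  expect_lt(abs(mc$p_value - exact), 2 * se + 1 / 5000)
})

test_that("adding a shared rare mutation never increases the exact p-value", {
  set.seed(13)
  for (rep in 1:5) {
    n <- sample(6:9, 1)
    p <- runif(n, 0.02, 0.45)
    matched <- runif(n) < 0.3
    base <- lr_match_test(p, matched)$p_value
    ext <- lr_match_test(c(p, 0.01), c(matched, TRUE))$p_value
    expect_lte(ext, base + 1e-12)
  }
})

test_that("conditioning is on the smaller profile, ties by lesion id", {
  ref <- frequency_reference(N = 1000)
  small <- make_mut_profile("B_small", pos = 1:5)
  big <- make_mut_profile("A_big", pos = c(1:3, 50:70))
  res <- lr_clonality_test(small, big, ref)
  expect_equal(res$n_cond, 5)
  expect_equal(res$cond_lesion, "B_small")
  # tie on size: lexicographically first lesion id conditions
  t1 <- make_mut_profile("AAA", pos = 1:4)
  t2 <- make_mut_profile("BBB", pos = c(1, 2, 90, 91))
  expect_equal(lr_clonality_test(t1, t2, ref)$cond_lesion, "AAA")
})

test_that("clonal/private designation counts tumors per mutation", {
  p1 <- make_mut_profile("T1", pos = c(1, 2, 3))
  p2 <- make_mut_profile("T2", pos = c(1, 4))
  p3 <- make_mut_profile("T3", pos = c(5))
  lab <- designate_clonal_private(list(p1, p2, p3))
  expect_equal(lab$label[lab$key == mutation_key("1", 1, "A", "T")], "clonal")
  expect_equal(sum(lab$label == "clonal"), 1)
  expect_equal(sum(lab$label == "private"), 4)

  # hypermutated tumor excluded before labeling
  hyper <- make_mut_profile("T4", pos = 1:250)
  lab2 <- designate_clonal_private(list(p2, hyper))
  expect_equal(attr(lab2, "excluded_lesions"), "T4")
  expect_true(all(lab2$label == "private"))

  # single-tumor patient: everything private
  lab3 <- designate_clonal_private(list(p1))
  expect_true(all(lab3$label == "private"))

  expect_warning(designate_clonal_private(list(hyper)), "hypermutated")
})

test_that("spectrum table aggregates genes with exclusions and ranking", {
  mk <- function(lesion, patient, pos, gene, func = "missense") {
    mutation_profile(lesion, patient, "LCIS", data.frame(
      chrom = "1", pos = pos, ref = "A", alt = "T", gene = gene,
      func_class = func, stringsAsFactors = FALSE))
  }
  # gene X: 3 clonal + 1 private; gene Y: all synonymous private;
  # FSIP2 excluded
  cohort <- list(
    list(mk("P1T1", "P1", c(1, 2, 3, 10), c("X", "X", "X", "FSIP2")),
         mk("P1T2", "P1", c(1, 2, 3), c("X", "X", "X"))),
    list(mk("P2T1", "P2", c(4, 20), c("X", "Y"), func = c("missense", "silent")),
         mk("P2T2", "P2", 21, "Y", func = "silent"))
  )
  tab <- suppressMessages(spectrum_table(cohort))
  x <- tab[tab$gene == "X", ]
  expect_equal(x$total, 4)
  expect_equal(x$clonal, 3)
  expect_equal(x$private, 1)
  expect_equal(x$percent_clonal, 75)
  expect_equal(x$cases, 2)
  expect_false("FSIP2" %in% tab$gene)
  y <- tab[tab$gene == "Y", ]
  expect_equal(y$functional_private, 0)
  expect_true(is.na(y$functional_clonal))
  # ranked by total desc, ties alphabetical
  expect_equal(tab$gene, c("X", "Y"))
  # totals conserve
  expect_true(all(tab$clonal + tab$private == tab$total))
})

test_that("burden summary reports per-histology medians", {
  profs <- list(make_mut_profile("A", pos = 1:10),
                make_mut_profile("B", pos = 1:20),
                make_mut_profile("C", pos = 1:30),
                make_mut_profile("D", pos = 1:7, histology = "ILC"))
  s <- mutation_burden_summary(profs)
  expect_equal(s$median_mutations[s$histology == "LCIS"], 20)
  expect_equal(s$n_lesions[s$histology == "LCIS"], 3)
  expect_equal(s$median_mutations[s$histology == "ILC"], 7)
})
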