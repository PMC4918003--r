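# Likelihood-ratio test for clonal relatedness from shared somatic
# mutations. Conditional on the mutations of one tumor (the smaller
# profile), each is matched in the other tumor with probability p_i under
# independence and xi + (1 - xi) p_i under clonality with clonality
# fraction xi. The LR is profiled over xi and the null distribution of
# the maximized LR is obtained by exact enumeration over match
# configurations (small conditioning sets) or Monte Carlo.

# xi grid shared by the observed statistic and every enumeration /
# Monte Carlo replicate, so that p-value comparisons are internally
# consistent; extra resolution near 1 where log(1 - xi) is steep.
XI_MAX <- 1 - 1e-6
xi_grid <- function() {
  sort(unique(c(seq(0, 0.995, by = 0.005), 1 - 10^(-seq(2.4, 6, by = 0.15)),
                XI_MAX)))
}

# log LR(xi) for one match configuration:
#   sum_{i matched} log((xi + (1-xi) p_i) / p_i) + (n - m) log(1 - xi)
loglr_fun <- function(p, matched) {
  n <- length(p)
  m <- sum(matched)
  ps <- p[matched]
  function(xi) {
    sum(log((xi + (1 - xi) * ps) / ps)) + (n - m) * log1p(-xi)
  }
}

# Per-mutation grid contribution c_i(xi) = log((xi+(1-xi)p_i)/p_i) - log(1-xi),
# so that logLR(z, xi) = sum_i z_i c_i(xi) + n log(1-xi).
grid_contributions <- function(p, xi) {
  n <- length(p)
  C <- matrix(0, n, length(xi))
  for (i in seq_len(n)) {
    C[i, ] <- log(xi + (1 - xi) * p[i]) - log(p[i]) - log1p(-xi)
  }
  C
}

# Grid-maximized log LR for a 0/1 configuration matrix (rows = configs).
grid_gmax <- function(Z, C, base) {
  A <- Z %*% C
  g <- A[, 1] + base[1]
  for (j in 2:ncol(A)) g <- pmax(g, A[, j] + base[j])
  g
}

bit_matrix <- function(ints, n) {
  Z <- matrix(0, length(ints), n)
  for (b in seq_len(n)) {
    Z[, b] <- bitwAnd(ints, bitwShiftL(1L, b - 1L)) != 0L
  }
  Z
}

#' Core LR clonality test on marginals and a match indicator
#'
#' Computational engine behind [lr_clonality_test()]: takes the marginal
#' match probabilities `p` of the conditioning tumor's mutations and the
#' observed 0/1 match indicator, maximizes the likelihood ratio over the
#' clonality fraction xi in \[0, 1), and computes the null probability
#' that the maximized LR is at least as large under independent matching.
#' Exact enumeration over all `2^n` configurations when
#' `n <= exact_limit`; Monte Carlo otherwise.
#'
#' @param p numeric vector of marginal probabilities in (0,1).
#' @param matched logical vector, same length: which conditioning
#'   mutations are present in the other tumor.
#' @param n_mc Monte Carlo replicates for the sampling path.
#' @param seed optional RNG seed (Monte Carlo path only).
#' @param exact_limit largest conditioning-set size enumerated exactly.
#' @return Object of class `lr_test_result`: `m`, `n_cond`, `xi_hat`,
#'   `lambda`, `p_value`, `method` (`"exact"` or `"monte_carlo"`),
#'   `n_reps`, `seed`.
#' @export
lr_match_test <- function(p, matched, n_mc = 10000, seed = NULL,
                          exact_limit = 20) {
  stopifnot(length(p) == length(matched))
  n <- length(p)
  if (n == 0) {
    warning("empty conditioning set: p = 1", call. = FALSE)
    return(structure(list(m = 0L, n_cond = 0L, xi_hat = 0, lambda = 1,
                          p_value = 1, method = "exact", n_reps = NA_integer_,
                          seed = seed),
                     class = "lr_test_result"))
  }
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  matched <- as.logical(matched)
  m <- sum(matched)
  xi <- xi_grid()
  C <- grid_contributions(p, xi)
  base <- n * log1p(-xi)
  tol <- 1e-9

  # observed statistic: grid value (for null comparisons) + refined report
  g_obs <- as.numeric(grid_gmax(matrix(as.numeric(matched), 1), C, base))
  if (m == 0) {
    xi_hat <- 0
    lambda <- 1
  } else {
    f <- loglr_fun(p, matched)
    k <- which.max(vapply(xi, f, 0))
    lo <- xi[max(1, k - 1)]
    hi <- xi[min(length(xi), k + 1)]
    opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-8)
    if (opt$objective <= 0 || f(0) >= opt$objective) {
      xi_hat <- 0
      lambda <- 1
    } else {
      xi_hat <- opt$maximum
      lambda <- exp(opt$objective)
    }
  }

  if (m == 0) {
    # no match carries no evidence for clonality: p = 1 exactly
    return(structure(list(m = 0L, n_cond = n, xi_hat = 0, lambda = 1,
                          p_value = 1, method = "exact", n_reps = NA_integer_,
                          seed = seed),
                     class = "lr_test_result"))
  }

  if (n <= exact_limit) {
    total <- 2^n
    chunk <- 2^min(n, 16)
    lp <- log(p)
    lq <- log1p(-p)
    psum <- 0
    start <- 0
    while (start < total) {
      ints <- as.integer(seq.int(start, min(start + chunk, total) - 1))
      Z <- bit_matrix(ints, n)
      g <- grid_gmax(Z, C, base)
      logprob <- Z %*% lp + (1 - Z) %*% lq
      psum <- psum + sum(exp(logprob[g >= g_obs - tol]))
      start <- start + chunk
    }
    p_value <- min(1, psum)
    method <- "exact"
    n_reps <- NA_integer_
  } else {
    if (!is.null(seed)) set.seed(seed)
    exceed <- 0L
    left <- n_mc
    chunk <- 20000L
    while (left > 0) {
      nb <- min(chunk, left)
      Z <- matrix(stats::runif(nb * n) < rep(p, each = nb), nb, n) * 1
      g <- grid_gmax(Z, C, base)
      exceed <- exceed + sum(g >= g_obs - tol)
      left <- left - nb
    }
    p_value <- (1 + exceed) / (1 + n_mc)
    method <- "monte_carlo"
    n_reps <- n_mc
  }
  structure(list(m = as.integer(m), n_cond = n, xi_hat = xi_hat,
                 lambda = lambda, p_value = p_value, method = method,
                 n_reps = n_reps, seed = seed),
            class = "lr_test_result")
}

#' Exact null distribution of the LR-test p-value for one catalog
#'
#' For a conditioning set with marginal probabilities `p`, enumerates all
#' `2^n` match configurations, assigns each its p-value (the tail
#' probability of its maximized LR, ties sharing the tail), and returns
#' the exact null probability of rejecting at each `alpha` together with
#' the full discrete p-value distribution. This is the
#' conditional-on-catalog type-I error of the exact path; averaging it
#' over simulated catalogs estimates the test's operating level with no
#' binomial noise from a single match draw per catalog.
#'
#' @param p marginal probabilities of the conditioning mutations
#'   (length <= 20).
#' @param alphas rejection levels to evaluate.
#' @return List: `rates` (named by alpha), `pvalues`, `probs` (per
#'   configuration).
#' @export
lr_exact_null <- function(p, alphas = c(0.01, 0.05)) {
  n <- length(p)
  stopifnot(n >= 1, n <= 20)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  xi <- xi_grid()
  C <- grid_contributions(p, xi)
  base <- n * log1p(-xi)
  lp <- log(p)
  lq <- log1p(-p)
  total <- 2^n
  chunk <- 2^min(n, 16)
  g <- numeric(total)
  probs <- numeric(total)
  start <- 0
  while (start < total) {
    ints <- as.integer(seq.int(start, min(start + chunk, total) - 1))
    Z <- bit_matrix(ints, n)
    g[ints + 1] <- grid_gmax(Z, C, base)
    probs[ints + 1] <- exp(Z %*% lp + (1 - Z) %*% lq)
    start <- start + chunk
  }
  ord <- order(-g)
  cum <- cumsum(probs[ord])
  # ties (equal maximized LR) share the full tail probability
  gs <- g[ord]
  pv_sorted <- cum
  i <- 1
  while (i <= total) {
    j <- i
    while (j < total && gs[j + 1] >= gs[i] - 1e-9) j <- j + 1
    pv_sorted[i:j] <- cum[j]
    i <- j + 1
  }
  pvalues <- numeric(total)
  pvalues[ord] <- pv_sorted
  rates <- vapply(alphas, function(a) sum(probs[pvalues <= a]), 0)
  names(rates) <- as.character(alphas)
  list(rates = rates, pvalues = pvalues, probs = probs)
}

#' Likelihood-ratio clonality test for two mutation profiles
#'
#' Tests the hypothesis that two (germline-filtered) tumors are
#' independent against the alternative that a fraction xi of the
#' conditioning tumor's mutations are clonal (inherited from a common
#' ancestor clone). Conditioning is on the smaller profile (ties broken
#' by lexicographically first lesion id). Mutation matching is exact on
#' (chrom, pos, ref, alt); marginal match probabilities come from the
#' reference cohort (see [marginal_probability()]), so matches at common
#' hotspots are discounted. Small p-values indicate clonal relatedness;
#' zero matches give p = 1 exactly.
#'
#' @param a,b [mutation_profile()] objects from one patient.
#' @param ref_freq a [frequency_reference()].
#' @inheritParams lr_match_test
#' @return An `lr_test_result` (see [lr_match_test()]) with the
#'   conditioning lesion id and profile sizes `n_a`, `n_b` attached.
#' @export
lr_clonality_test <- function(a, b, ref_freq, n_mc = 10000, seed = NULL,
                              exact_limit = 20) {
  stopifnot(inherits(a, "mutation_profile"), inherits(b, "mutation_profile"))
  na <- n_mutations(a)
  nb <- n_mutations(b)
  swap <- (nb < na) || (nb == na && b$lesion < a$lesion)
  cond <- if (swap) b else a
  other <- if (swap) a else b
  p <- profile_marginals(cond, ref_freq)
  matched <- cond$mutations$key %in% other$mutations$key
  res <- lr_match_test(p, matched, n_mc = n_mc, seed = seed,
                       exact_limit = exact_limit)
  res$cond_lesion <- cond$lesion
  res$n_a <- na
  res$n_b <- nb
  res
}

#' @export
print.lr_test_result <- function(x, ...) {
  cat(sprintf(
    "<lr_test_result> m = %d of %d; xi_hat = %.3f, Lambda = %.3g, p = %.4g (%s%s)\n",
    x$m, x$n_cond, x$xi_hat, x$lambda, x$p_value, x$method,
    if (x$method == "monte_carlo") sprintf(", %d reps", x$n_reps) else ""))
  invisible(x)
}
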