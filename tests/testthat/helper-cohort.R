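# Shared builders for small in-code fixtures.

toy_gp <- toy_genome()

# Probe profile with optional planted events (probe-index bounds per arm).
flat_probe_profile <- function(lesion = "L1", patient = "P1",
                               histology = "LCIS", n_per_arm = 120,
                               sd = 0.1, events = NULL, genome = toy_gp) {
  probes <- do.call(rbind, lapply(seq_len(nrow(genome$arms)), function(i) {
    a <- genome$arms$arm[i]
    pos <- sort(sample(genome$arms$start[i]:genome$arms$end[i], n_per_arm))
    x <- stats::rnorm(n_per_arm, 0, sd)
    if (!is.null(events)) {
      ev <- events[events$arm == a, , drop = FALSE]
      for (k in seq_len(nrow(ev))) {
        x[ev$start[k]:ev$end[k]] <- x[ev$start[k]:ev$end[k]] + ev$amp[k]
      }
    }
    data.frame(chrom = genome$arms$chrom[i], pos = pos, logratio = x,
               stringsAsFactors = FALSE)
  }))
  probe_profile(lesion, patient, histology, probes, genome)
}

# Arm call set built directly (for concordance tests).
# calls: list(arm = list(event, start, end)), on a uniform marker grid.
make_call_set <- function(lesion, calls = list(), n_markers = 30,
                          genome = toy_gp) {
  df <- data.frame(arm = genome$arms$arm, n_markers = n_markers,
                   start = NA_integer_, end = NA_integer_,
                   height = NA_real_, call = "none",
                   stringsAsFactors = FALSE)
  for (a in names(calls)) {
    i <- which(df$arm == a)
    df$call[i] <- calls[[a]]$event
    df$start[i] <- calls[[a]]$start
    df$end[i] <- calls[[a]]$end
    df$height[i] <- if (calls[[a]]$event == "gain") 0.5 else -0.5
  }
  structure(list(lesion = lesion, calls = df, median = 0, mad = 0.05),
            class = "arm_call_set")
}

# Mutation profile from position vectors (chrom "1", A>T, gene G1 default).
make_mut_profile <- function(lesion, pos, patient = "P1",
                             histology = "LCIS", chrom = "1", gene = "G1",
                             func_class = "missense", pop_af = NA_real_) {
  mutation_profile(lesion, patient, histology, data.frame(
    chrom = chrom, pos = pos, ref = "A", alt = "T", gene = gene,
    func_class = func_class, pop_af = pop_af, stringsAsFactors = FALSE))
}

# Segmented profile with analytically known median (0) and residual MAD
# (resid_mad): residuals cycle (-d, 0, +d) within each segment.
make_segmented <- function(heights, n_markers, resid_mad = 0.05,
                           lesion = "L1", genome = toy_gp) {
  stopifnot(length(heights) == length(n_markers))
  resid <- function(n) rep_len(c(-resid_mad, 0, resid_mad), n)
  segs <- list()
  mk <- list()
  start <- 1L
  for (i in seq_along(heights)) {
    n <- n_markers[i]
    segs[[i]] <- data.frame(arm = "1p", start = start, end = start + n - 1L,
                            n_markers = n, height = heights[i], call = "none",
                            stringsAsFactors = FALSE)
    mk[[i]] <- data.frame(arm = "1p", marker = seq(start, start + n - 1L),
                          pos = seq(start, start + n - 1L) * 1000,
                          logratio = heights[i] + resid(n), n_probes = 12L,
                          stringsAsFactors = FALSE)
    start <- start + n
  }
  structure(list(lesion = lesion, markers = do.call(rbind, mk),
                 segments = do.call(rbind, segs), group_size = 12,
                 genome = genome, median = NA_real_, mad = NA_real_),
            class = "segmented_profile")
}

# Brute-force max-T oracle: exhaustive double loop, shorter-then-leftmost
# tie break (independent of the package's vectorized scan).
brute_max_t <- function(x) {
  n <- length(x)
  best <- list(s = NA, e = NA, t = -1)
  best_len <- Inf
  for (s in 1:n) {
    for (e in s:n) {
      if (s == 1 && e == n) next
      nin <- e - s + 1
      nout <- n - nin
      m_in <- mean(x[s:e])
      m_out <- mean(x[-(s:e)])
      ss <- sum((x[s:e] - m_in)^2) + sum((x[-(s:e)] - m_out)^2)
      sp2 <- if (n > 2) ss / (n - 2) else 0
      den <- sqrt(sp2 * (1 / nin + 1 / nout))
      tv <- if (den > 0) abs(m_in - m_out) / den else
        if (abs(m_in - m_out) > 0) Inf else 0
      if (tv > best$t + 1e-12 ||
          (tv > best$t - 1e-12 && nin < best_len)) {
        best <- list(s = s, e = e, t = tv)
        best_len <- nin
      }
    }
  }
  best
}

# Full-enumeration LR-test oracle using per-subset stats::optimize
# (independent of the package's xi-grid path).
oracle_lr_pvalue <- function(p, matched) {
  n <- length(p)
  gmax <- function(z) {
    if (sum(z) == 0) return(0)
    f <- function(xi) {
      sum(log((xi + (1 - xi) * p[z]) / p[z])) + (n - sum(z)) * log1p(-xi)
    }
    max(0, stats::optimize(f, c(0, 1 - 1e-6), maximum = TRUE,
                           tol = 1e-10)$objective)
  }
  g_obs <- gmax(as.logical(matched))
  total <- 0
  for (i in 0:(2^n - 1)) {
    z <- as.logical(bitwAnd(i, 2^(0:(n - 1))))
    lp <- sum(log(p[z])) + sum(log1p(-p[!z]))
    if (gmax(z) >= g_obs - 1e-7) total <- total + exp(lp)
  }
  min(1, total)
}
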