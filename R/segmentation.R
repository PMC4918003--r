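# Copy-number segmentation: probe -> marker averaging, recursive
# (CBS-style) segmentation with a permutation acceptance rule, one-step
# per-arm calls for the clonality comparison, MAD-threshold gain/loss
# calling, and the array quality gate.

#' Average adjacent probes into markers
#'
#' Within each chromosome arm, consecutive non-overlapping groups of
#' `group_size` probes are averaged to reduce noise (default 12, the
#' conventional reduction for 180K-feature arrays). A trailing remainder
#' group is kept as its own marker when it has at least
#' `ceiling(group_size / 2)` probes and is otherwise merged into the
#' previous group. Marker position is the median probe position of its
#' group. Grouping is per arm, so no marker straddles a centromere.
#'
#' @param profile a [probe_profile()].
#' @param group_size probes per marker (>= 1).
#' @return An object of class `marker_profile`: `lesion`, `markers`
#'   (data frame `arm`, `marker` (1-based index within arm), `pos`,
#'   `logratio`, `n_probes`), `group_size`, `genome`.
#' @export
average_adjacent <- function(profile, group_size = 12) {
  stopifnot(inherits(profile, "probe_profile"), group_size >= 1)
  genome <- profile$genome
  out <- list()
  present <- unique(profile$probes$arm)
  absent <- setdiff(genome$arms$arm, present)
  if (length(absent) > 0) {
    warning(sprintf("average_adjacent[%s]: arm(s) with no probes omitted: %s",
                    profile$lesion, paste(absent, collapse = ", ")),
            call. = FALSE)
  }
  for (a in genome$arms$arm[genome$arms$arm %in% present]) {
    p <- profile$probes[profile$probes$arm == a, , drop = FALSE]
    n <- nrow(p)
    g <- group_size
    k <- n %/% g
    r <- n %% g
    if (k == 0) {
      sizes <- r
    } else if (r == 0) {
      sizes <- rep(g, k)
    } else if (r >= ceiling(g / 2)) {
      sizes <- c(rep(g, k), r)
    } else {
      sizes <- c(rep(g, k - 1), g + r)
    }
    grp <- rep(seq_along(sizes), sizes)
    out[[a]] <- data.frame(
      arm = a,
      marker = seq_along(sizes),
      pos = as.numeric(tapply(p$pos, grp, stats::median)),
      logratio = as.numeric(tapply(p$logratio, grp, mean)),
      n_probes = as.integer(sizes),
      stringsAsFactors = FALSE
    )
  }
  markers <- do.call(rbind, out)
  rownames(markers) <- NULL
  structure(list(lesion = profile$lesion, markers = markers,
                 group_size = group_size, genome = genome),
            class = "marker_profile")
}

#' @export
print.marker_profile <- function(x, ...) {
  cat(sprintf("<marker_profile> lesion %s: %d markers (group size %d) on %d arms\n",
              x$lesion, nrow(x$markers), x$group_size,
              length(unique(x$markers$arm))))
  invisible(x)
}

#' Optional running-median detrend of a probe profile
#'
#' Removes slow wave artifacts by subtracting a running median
#' (odd window, default 51 probes, applied per arm). Off by default in the
#' pipeline; a simple alternative to model-based wave correction.
#'
#' @param profile a [probe_profile()].
#' @param window odd window width in probes.
#' @return The detrended [probe_profile()].
#' @export
detrend_running_median <- function(profile, window = 51) {
  stopifnot(inherits(profile, "probe_profile"), window %% 2 == 1)
  for (a in unique(profile$probes$arm)) {
    idx <- which(profile$probes$arm == a)
    x <- profile$probes$logratio[idx]
    if (length(x) >= window) {
      trend <- stats::runmed(x, window, endrule = "median")
      profile$probes$logratio[idx] <- x - (trend - stats::median(trend))
    }
  }
  profile
}

# Two-sample t-like statistic for splitting marker series x at the
# sub-interval [s, e]:
#   T(s,e) = |mean(in) - mean(out)| / (s_p * sqrt(1/n_in + 1/n_out)),
# with s_p the pooled within-group SD. Returns the best candidate over all
# sub-intervals with a non-empty outside; ties broken toward the shorter
# segment, then the leftmost start (determinism).
max_t_scan <- function(x, tol = 1e-12) {
  n <- length(x)
  if (n < 2) return(list(s = NA, e = NA, t = 0))
  S <- cumsum(x)
  Q <- cumsum(x^2)
  tot <- S[n]
  qtot <- Q[n]
  best_t <- 0
  best_s <- NA_integer_
  best_e <- NA_integer_
  best_len <- Inf
  for (s in 1:n) {
    e_max <- if (s == 1) n - 1 else n
    if (e_max < s) next
    e <- s:e_max
    n_in <- e - s + 1
    n_out <- n - n_in
    sum_in <- S[e] - if (s > 1) S[s - 1] else 0
    q_in <- Q[e] - if (s > 1) Q[s - 1] else 0
    mean_in <- sum_in / n_in
    mean_out <- (tot - sum_in) / n_out
    ss_in <- pmax(q_in - n_in * mean_in^2, 0)
    ss_out <- pmax((qtot - q_in) - n_out * mean_out^2, 0)
    sp2 <- if (n > 2) (ss_in + ss_out) / (n - 2) else 0
    denom <- sqrt(sp2 * (1 / n_in + 1 / n_out))
    diff <- abs(mean_in - mean_out)
    tval <- ifelse(denom > 0, diff / denom, ifelse(diff > 0, Inf, 0))
    # local best for this s: highest T, then shortest interval
    tb <- max(tval)
    if (tb <= 0) next
    sel <- if (is.finite(tb)) which(tval > tb - tol) else which(is.infinite(tval))
    j <- sel[which.min(n_in[sel])]
    improved <- tval[j] > best_t + tol ||
      (is.infinite(tval[j]) && is.infinite(best_t) && n_in[j] < best_len) ||
      (is.finite(tval[j]) && tval[j] > best_t - tol && n_in[j] < best_len)
    if (is.na(best_s) || improved) {
      best_t <- tval[j]
      best_s <- s
      best_e <- e[j]
      best_len <- n_in[j]
    }
  }
  list(s = best_s, e = best_e, t = best_t)
}

# Max T only (for permutation replicates).
max_t_value <- function(x) max_t_scan(x)$t

# Row-wise max T for a matrix of series (rows = permutation replicates).
# Same statistic as max_t_scan, vectorized across replicates.
max_t_values_batch <- function(X) {
  B <- nrow(X)
  n <- ncol(X)
  if (n < 2) return(rep(0, B))
  S <- t(apply(X, 1, cumsum))
  Q <- t(apply(X^2, 1, cumsum))
  tot <- S[, n]
  qtot <- Q[, n]
  best <- rep(0, B)
  for (s in 1:n) {
    e_max <- if (s == 1) n - 1 else n
    if (e_max < s) next
    cols <- s:e_max
    k <- length(cols)
    n_in <- matrix(cols - s + 1, B, k, byrow = TRUE)
    n_out <- n - n_in
    Sin <- S[, cols, drop = FALSE] - if (s > 1) S[, s - 1] else 0
    Qin <- Q[, cols, drop = FALSE] - if (s > 1) Q[, s - 1] else 0
    mean_in <- Sin / n_in
    mean_out <- (tot - Sin) / n_out
    ss <- pmax(Qin - n_in * mean_in^2, 0) +
      pmax((qtot - Qin) - n_out * mean_out^2, 0)
    sp2 <- if (n > 2) ss / (n - 2) else 0
    denom <- sqrt(sp2 * (1 / n_in + 1 / n_out))
    diff <- abs(mean_in - mean_out)
    tval <- ifelse(denom > 0, diff / denom, ifelse(diff > 0, Inf, 0))
    for (j in seq_len(k)) best <- pmax(best, tval[, j])
  }
  best
}

# Permutation acceptance of the best split in x: within-region shuffles.
split_pvalue <- function(x, t_obs, n_perm) {
  if (!is.finite(t_obs)) {
    # ties between Inf statistics are resolved by the permutation count
    t_obs <- .Machine$double.xmax
  }
  P <- matrix(0, n_perm, length(x))
  for (b in seq_len(n_perm)) P[b, ] <- sample(x)
  tb <- max_t_values_batch(P)
  (1 + sum(!is.finite(tb) | tb >= t_obs - 1e-12)) / (1 + n_perm)
}

# Recursive binary segmentation of one arm. Returns integer vector of
# segment ids along the arm.
segment_arm_recursive <- function(x, alpha, n_perm) {
  n <- length(x)
  seg_bounds <- list()
  recurse <- function(lo, hi) {
    len <- hi - lo + 1
    if (len < 2) {
      seg_bounds[[length(seg_bounds) + 1]] <<- c(lo, hi)
      return(invisible())
    }
    xs <- x[lo:hi]
    cand <- max_t_scan(xs)
    accept <- FALSE
    if (!is.na(cand$s) && cand$t > 0) {
      p <- split_pvalue(xs, cand$t, n_perm)
      accept <- p < alpha
    }
    if (!accept) {
      seg_bounds[[length(seg_bounds) + 1]] <<- c(lo, hi)
      return(invisible())
    }
    s <- lo + cand$s - 1
    e <- lo + cand$e - 1
    if (s > lo) recurse(lo, s - 1)
    recurse(s, e)
    if (e < hi) recurse(e + 1, hi)
  }
  recurse(1, n)
  bounds <- do.call(rbind, seg_bounds)
  bounds <- bounds[order(bounds[, 1]), , drop = FALSE]
  seg <- integer(n)
  for (i in seq_len(nrow(bounds))) seg[bounds[i, 1]:bounds[i, 2]] <- i
  # merge adjacent segments whose means coincide (keeps means distinct)
  means <- tapply(x, seg, mean)
  keep <- c(TRUE, abs(diff(means)) > 1e-12)
  relabel <- cumsum(keep)
  as.integer(relabel[seg])
}

#' Multi-step segmentation of a marker profile
#'
#' Recursive binary segmentation per arm: at each step the sub-interval
#' maximizing the two-sample T statistic is found; the split is accepted
#' when its within-region permutation p-value is below `alpha`, and the
#' algorithm recurses on the resulting pieces. Segments tile each arm.
#' Calls are filled in by [call_segments()].
#'
#' @param markers a [marker_profile()].
#' @param alpha split acceptance level (default 0.01).
#' @param n_perm permutation replicates per tested split (default 1000).
#' @param seed optional RNG seed for the permutations.
#' @return An object of class `segmented_profile`: `lesion`, `markers`,
#'   `segments` (data frame `arm`, `start`, `end`, `n_markers`, `height`,
#'   `call`), `median`, `mad`, and the calling metadata once
#'   [call_segments()] has run.
#' @export
segment_genome <- function(markers, alpha = 0.01, n_perm = 1000, seed = NULL) {
  stopifnot(inherits(markers, "marker_profile"))
  if (!is.null(seed)) set.seed(seed)
  segs <- list()
  mk <- markers$markers
  seg_of_marker <- integer(nrow(mk))
  for (a in unique(mk$arm)) {
    idx <- which(mk$arm == a)
    x <- mk$logratio[idx]
    ids <- if (length(x) >= 2) {
      segment_arm_recursive(x, alpha, n_perm)
    } else rep(1L, length(x))
    for (k in unique(ids)) {
      w <- which(ids == k)
      segs[[length(segs) + 1]] <- data.frame(
        arm = a, start = min(w), end = max(w), n_markers = length(w),
        height = mean(x[w]), call = "none", stringsAsFactors = FALSE)
    }
    seg_of_marker[idx] <- ids + max(c(0L, seg_of_marker))
  }
  segments <- do.call(rbind, segs)
  rownames(segments) <- NULL
  prof <- structure(list(lesion = markers$lesion, markers = mk,
                         segments = segments, group_size = markers$group_size,
                         genome = markers$genome,
                         median = NA_real_, mad = NA_real_),
                    class = "segmented_profile")
  call_segments(prof)
}

#' @export
print.segmented_profile <- function(x, ...) {
  cat(sprintf("<segmented_profile> lesion %s: %d segments (%d gain, %d loss); median %.3f, MAD %.4f\n",
              x$lesion, nrow(x$segments), sum(x$segments$call == "gain"),
              sum(x$segments$call == "loss"), x$median, x$mad))
  invisible(x)
}

# Piecewise fitted mean per marker given a segment table.
fitted_heights <- function(markers, segments) {
  fit <- numeric(nrow(markers))
  for (i in seq_len(nrow(segments))) {
    idx <- which(markers$arm == segments$arm[i] &
                   markers$marker >= segments$start[i] &
                   markers$marker <= segments$end[i])
    fit[idx] <- segments$height[i]
  }
  fit
}

#' Call gains and losses against the 1-MAD rule
#'
#' Residuals are marker log ratios minus their segment mean; the noise
#' scale is the unscaled median absolute deviation of those residuals.
#' A segment is called a gain when its height strictly exceeds the
#' genome-wide median plus 1 MAD, a loss when strictly below median minus
#' 1 MAD, otherwise none ("exceeds" is strict, so a height exactly at
#' median + MAD is not called). A MAD of exactly 0 (noiseless input) falls
#' back to calling any segment whose height differs from the median.
#'
#' @param profile a `segmented_profile`.
#' @return The profile with `call` filled in and `median`/`mad` set.
#' @export
call_segments <- function(profile) {
  stopifnot(inherits(profile, "segmented_profile"))
  mk <- profile$markers
  med <- stats::median(mk$logratio)
  resid <- mk$logratio - fitted_heights(mk, profile$segments)
  mad <- mad_unscaled(resid)
  if (mad == 0) {
    message("call_segments: residual MAD is 0; calling any segment off the median")
  }
  h <- profile$segments$height
  profile$segments$call <- ifelse(h > med + mad, "gain",
                                  ifelse(h < med - mad, "loss", "none"))
  profile$median <- med
  profile$mad <- mad
  profile
}

#' One-step per-arm segmentation and calling
#'
#' The clonality comparison works on at most one gain or loss region per
#' chromosome arm. Per arm, the single best candidate is the sub-interval
#' maximizing the two-sample T statistic, retained only when its split
#' passes the within-arm permutation test (without this gate the
#' maximization would hand every flat arm a selection-biased noise
#' interval); the whole arm is also a candidate, scored by a one-sample
#' statistic of the arm mean against the genome-wide median (a whole-arm
#' segment has no "outside" on its own arm). The winning candidate is
#' called gain or loss under the same 1-MAD rule used by
#' [call_segments()]; otherwise the arm's call is none.
#'
#' @param markers a [marker_profile()].
#' @param alpha split acceptance level for the interior candidate.
#' @param n_perm permutation replicates per arm.
#' @param seed optional RNG seed for the permutations.
#' @return An object of class `arm_call_set`: `lesion`, `calls` (data
#'   frame `arm`, `n_markers`, `start`, `end`, `height`, `call`; bounds are
#'   marker indices within the arm, `NA` when the call is none), `median`,
#'   `mad`.
#' @export
one_step_arm_calls <- function(markers, alpha = 0.01, n_perm = 300,
                               seed = NULL) {
  stopifnot(inherits(markers, "marker_profile"))
  if (!is.null(seed)) set.seed(seed)
  mk <- markers$markers
  med <- stats::median(mk$logratio)
  arms <- unique(mk$arm)
  rows <- list()
  resid <- numeric(nrow(mk))
  for (a in arms) {
    idx <- which(mk$arm == a)
    x <- mk$logratio[idx]
    n <- length(x)
    cand <- if (n >= 2) max_t_scan(x) else list(s = NA, e = NA, t = 0)
    use_interior <- FALSE
    if (!is.na(cand$s) && cand$t > 0 &&
        !(cand$s == 1 && cand$e == n)) {
      use_interior <- split_pvalue(x, cand$t, n_perm) < alpha
    }
    if (use_interior) {
      s <- cand$s; e <- cand$e
      if (s == 1 || e == n) {
        # boundary split: two contiguous pieces share the same T; the
        # aberrant region is the piece deviating more from the median
        out_rng <- if (s == 1) (e + 1):n else 1:(s - 1)
        if (abs(mean(x[out_rng]) - med) > abs(mean(x[s:e]) - med)) {
          s <- min(out_rng); e <- max(out_rng)
        }
      }
      inside <- idx[s:e]
      h <- mean(mk$logratio[inside])
      out_mean <- mean(mk$logratio[setdiff(idx, inside)])
      resid[inside] <- mk$logratio[inside] - h
      resid[setdiff(idx, inside)] <- mk$logratio[setdiff(idx, inside)] - out_mean
    } else {
      s <- 1L; e <- n
      h <- mean(x)
      resid[idx] <- x - h
    }
    rows[[a]] <- data.frame(arm = a, n_markers = n, start = s, end = e,
                            height = h, call = "none", stringsAsFactors = FALSE)
  }
  mad <- mad_unscaled(resid)
  calls <- do.call(rbind, rows)
  thr_hit <- if (mad > 0) {
    ifelse(calls$height > med + mad, "gain",
           ifelse(calls$height < med - mad, "loss", "none"))
  } else {
    ifelse(calls$height > med, "gain", ifelse(calls$height < med, "loss", "none"))
  }
  calls$call <- thr_hit
  calls$start[calls$call == "none"] <- NA_integer_
  calls$end[calls$call == "none"] <- NA_integer_
  calls$height[calls$call == "none"] <- NA_real_
  rownames(calls) <- NULL
  structure(list(lesion = markers$lesion, calls = calls,
                 median = med, mad = mad),
            class = "arm_call_set")
}

#' @export
print.arm_call_set <- function(x, ...) {
  called <- x$calls[x$calls$call != "none", , drop = FALSE]
  cat(sprintf("<arm_call_set> lesion %s: %d/%d arms called (%s)\n",
              x$lesion, nrow(called), nrow(x$calls),
              if (nrow(called)) paste(called$arm, called$call, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Array quality gate
#'
#' Two metrics decide whether a profile shows interpretable copy-number
#' signal: (1) the percentage of markers lying in called gain/loss
#' segments, and (2) the 75th percentile of called-segment heights (at
#' least 10 markers long, measured as |height - median| so the gate is
#' shift-invariant) divided by the MAD. A profile passes when metric (1)
#' exceeds 10% or metric (2) exceeds 1.75; profiles with no clear gains or
#' losses, or high noise relative to few called changes, fail and are
#' excluded from copy-number comparisons.
#'
#' @param profile a called `segmented_profile`.
#' @param min_markers minimum called-segment length entering metric (2).
#' @return A list of class `qc_result`: `percent_aberrant`,
#'   `height_ratio`, `pass`.
#' @export
qc_gate <- function(profile, min_markers = 10) {
  stopifnot(inherits(profile, "segmented_profile"))
  segs <- profile$segments
  called <- segs[segs$call != "none", , drop = FALSE]
  total <- sum(segs$n_markers)
  percent <- 100 * sum(called$n_markers) / total
  qual <- called[called$n_markers >= min_markers, , drop = FALSE]
  height_ratio <- if (nrow(qual) == 0 || profile$mad == 0) 0 else {
    as.numeric(stats::quantile(abs(qual$height - profile$median), 0.75)) /
      profile$mad
  }
  structure(list(percent_aberrant = percent, height_ratio = height_ratio,
                 pass = percent > 10 || height_ratio > 1.75),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> %.1f%% aberrant, height ratio %.2f -> %s\n",
              x$percent_aberrant, x$height_ratio,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
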