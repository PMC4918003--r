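# Copy-number clonality: a frequency-weighted concordance statistic over
# chromosome-arm gain/loss calls, benchmarked against the distribution of
# the statistic in cross-patient lesion pairs.

#' Estimate arm-event frequencies from a cohort of call sets
#'
#' The weight of a concordant event depends on how common the event is:
#' a shared 1q-gain-like change seen in most lesions carries little
#' evidence, a shared rare change carries much. Frequencies use the
#' shrunken estimator `(count + 0.5) / (n_lesions + 1)`, so events never
#' observed get the pseudo-count floor and nothing reaches 0 or 1.
#'
#' @param call_sets list of [one_step_arm_calls()] results.
#' @param exclude_patients optional patient ids whose lesions are excluded
#'   (leave-out estimation for an index pair); requires `patients`.
#' @param patients character vector of patient ids parallel to
#'   `call_sets` (needed only with `exclude_patients`).
#' @return Data frame `arm`, `event`, `freq` covering every arm seen in
#'   the cohort for both gain and loss.
#' @export
estimate_arm_frequencies <- function(call_sets, patients = NULL,
                                     exclude_patients = NULL) {
  stopifnot(length(call_sets) >= 2)
  if (!is.null(exclude_patients)) {
    stopifnot(!is.null(patients), length(patients) == length(call_sets))
    keep <- !(patients %in% exclude_patients)
    # leave-out is a bias guard, not a hard requirement: with too few
    # patients the full cohort is the only available estimate
    if (any(keep)) call_sets <- call_sets[keep]
  }
  arms <- unique(unlist(lapply(call_sets, function(cs) cs$calls$arm)))
  grid <- expand.grid(arm = arms, event = c("gain", "loss"),
                      stringsAsFactors = FALSE)
  n <- length(call_sets)
  counts <- mapply(function(a, ev) {
    sum(vapply(call_sets, function(cs) {
      any(cs$calls$arm == a & cs$calls$call == ev)
    }, logical(1)))
  }, grid$arm, grid$event)
  grid$freq <- (counts + 0.5) / (n + 1)
  rownames(grid) <- NULL
  grid
}

arm_event_freq <- function(arm_freqs, arm, event) {
  i <- which(arm_freqs$arm == arm & arm_freqs$event == event)
  if (length(i) == 0) min(arm_freqs$freq) else arm_freqs$freq[i[1]]
}

#' Frequency-weighted copy-number concordance statistic
#'
#' For each chromosome arm where both lesions carry the same event type
#' (gain-gain or loss-loss), the closeness of the two called regions is
#' the Jaccard overlap of their marker intervals, and the arm contributes
#' `closeness * (-log freq)` with `freq` the cohort frequency of that
#' arm event. Discordant arms (gain vs loss, or call vs none) contribute
#' 0. The statistic is the sum of contributions: 0 iff no concordant
#' aberrant arm, large when the pair shares rare, tightly matching
#' changes.
#'
#' @param a,b [one_step_arm_calls()] results on the same marker grid.
#' @param arm_freqs data frame `arm`, `event`, `freq` (from
#'   [estimate_arm_frequencies()]) or a [frequency_reference()] carrying
#'   one.
#' @return An object of class `concordance_score`: `records` (per
#'   concordant arm: arm, event, closeness, freq, contribution) and
#'   total statistic `S`.
#' @export
concordance_statistic <- function(a, b, arm_freqs) {
  stopifnot(inherits(a, "arm_call_set"), inherits(b, "arm_call_set"))
  if (inherits(arm_freqs, "frequency_reference")) arm_freqs <- arm_freqs$arm_freqs
  stopifnot(is.data.frame(arm_freqs))
  arms <- a$calls$arm
  if (!setequal(arms, b$calls$arm)) stop_format("call sets cover different arms")
  recs <- list()
  for (arm in arms) {
    ra <- a$calls[a$calls$arm == arm, ]
    rb <- b$calls[b$calls$arm == arm, ]
    if (ra$n_markers != rb$n_markers) {
      stop_format("mismatched marker grids on arm %s (%d vs %d markers)",
                  arm, ra$n_markers, rb$n_markers)
    }
    if (ra$call == "none" || ra$call != rb$call) next
    inter <- max(0, min(ra$end, rb$end) - max(ra$start, rb$start) + 1)
    union <- (ra$end - ra$start + 1) + (rb$end - rb$start + 1) - inter
    closeness <- inter / union
    freq <- arm_event_freq(arm_freqs, arm, ra$call)
    recs[[arm]] <- data.frame(arm = arm, event = ra$call,
                              closeness = closeness, freq = freq,
                              contribution = closeness * (-log(freq)),
                              stringsAsFactors = FALSE)
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(arm = character(), event = character(), closeness = numeric(),
               freq = numeric(), contribution = numeric())
  rownames(records) <- NULL
  structure(list(records = records, S = sum(records$contribution)),
            class = "concordance_score")
}

#' @export
print.concordance_score <- function(x, ...) {
  cat(sprintf("<concordance_score> S = %.4f over %d concordant arm(s)\n",
              x$S, nrow(x$records)))
  if (nrow(x$records)) print(x$records, ...)
  invisible(x)
}

#' Cross-patient reference distribution of the concordance statistic
#'
#' Computes the statistic for every unordered pair of lesions from
#' different patients (within-patient pairs are excluded: they are the
#' pairs under test). Arm-event frequencies are re-estimated for each
#' pair leaving out both patients involved, so no pair influences its own
#' weights.
#'
#' @param call_sets list of [one_step_arm_calls()] results (QC-passing
#'   lesions only).
#' @param patients character vector of patient ids parallel to `call_sets`.
#' @return An object of class `reference_distribution`: `S` (numeric
#'   vector), `pairs` (data frame of lesion index pairs), `N_ref`.
#' @export
build_reference <- function(call_sets, patients) {
  stopifnot(length(call_sets) == length(patients))
  if (length(unique(patients)) < 2) {
    stop_format("reference distribution needs lesions from >= 2 patients")
  }
  n <- length(call_sets)
  idx <- utils::combn(n, 2)
  cross <- patients[idx[1, ]] != patients[idx[2, ]]
  idx <- idx[, cross, drop = FALSE]
  S <- numeric(ncol(idx))
  pairs <- data.frame(i = idx[1, ], j = idx[2, ],
                      lesion_i = vapply(call_sets[idx[1, ]], `[[`, "", "lesion"),
                      lesion_j = vapply(call_sets[idx[2, ]], `[[`, "", "lesion"))
  for (k in seq_len(ncol(idx))) {
    i <- idx[1, k]; j <- idx[2, k]
    fr <- estimate_arm_frequencies(call_sets, patients,
                                   exclude_patients = unique(c(patients[i], patients[j])))
    S[k] <- concordance_statistic(call_sets[[i]], call_sets[[j]], fr)$S
  }
  structure(list(S = S, pairs = pairs, N_ref = length(S)),
            class = "reference_distribution")
}

#' @export
print.reference_distribution <- function(x, ...) {
  cat(sprintf("<reference_distribution> %d cross-patient pairs; S median %.3f, max %.3f\n",
              x$N_ref, stats::median(x$S), max(x$S)))
  invisible(x)
}

#' Empirical p-value of a concordance score
#'
#' Rank of the observed statistic in the cross-patient reference, with
#' the +1 correction so p is never 0:
#' `p = (1 + #\{S_ref >= S_obs\}) / (1 + N_ref)`.
#'
#' @param score a [concordance_statistic()] result or a bare numeric S.
#' @param reference a [build_reference()] result or numeric vector of
#'   reference S values.
#' @return p-value in (0, 1].
#' @export
cn_clonality_pvalue <- function(score, reference) {
  S_obs <- if (inherits(score, "concordance_score")) score$S else score
  S_ref <- if (inherits(reference, "reference_distribution")) reference$S else reference
  stopifnot(length(S_ref) >= 1)
  (1 + sum(S_ref >= S_obs)) / (1 + length(S_ref))
}

#' Copy-number clonality test for one within-patient lesion pair
#'
#' Convenience wrapper: leave-one-patient-out arm frequencies, the
#' concordance statistic for the index pair, and its empirical p-value
#' against a cross-patient reference distribution.
#'
#' @param a,b [one_step_arm_calls()] for the two lesions (same patient).
#' @param call_sets,patients the QC-passing cohort (see
#'   [build_reference()]); used for frequency estimation.
#' @param reference a [build_reference()] result (computed from
#'   `call_sets`/`patients` if omitted).
#' @param patient patient id of the index pair (excluded from frequency
#'   estimation).
#' @return List with `S`, `score`, `p_cn`, `N_ref`.
#' @export
cn_clonality_test <- function(a, b, call_sets, patients, patient,
                              reference = NULL) {
  fr <- estimate_arm_frequencies(call_sets, patients,
                                 exclude_patients = patient)
  score <- concordance_statistic(a, b, fr)
  if (is.null(reference)) reference <- build_reference(call_sets, patients)
  p <- cn_clonality_pvalue(score, reference)
  list(S = score$S, score = score, p_cn = p, N_ref = reference$N_ref)
}
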