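# Believe-the-positive combination of the two clonality tests into a
# clonal / equivocal / independent verdict, and cohort-level summaries.

#' Classify a lesion pair from its clonality test p-values
#'
#' Believe-the-positive rule with a strict significance level: the pair
#' is *clonal* when either test rejects independence with p < 0.01.
#' Otherwise, if mutation data are available and the tumors share zero
#' mutations, the pair is *independent* — the absence of any exact
#' mutational match overrides a merely suggestive copy-number p-value.
#' Otherwise the pair is *equivocal* when the smaller available p-value
#' lies in \[0.01, 0.05), and *independent* when it is 0.05 or larger.
#' With no test available the verdict is *untested*.
#'
#' @param p_mut mutation-test p-value (`NA` when not available).
#' @param m shared-mutation count (required whenever `p_mut` is given).
#' @param p_cn copy-number-test p-value (`NA` when not available).
#' @return One of `"clonal"`, `"equivocal"`, `"independent"`,
#'   `"untested"`. Vectorized over its arguments.
#' @export
#' @examples
#' classify_pair(p_mut = 0.0005, m = 16, p_cn = 0.002)  # clonal
#' classify_pair(p_mut = 1, m = 0, p_cn = 0.02)         # independent
#' classify_pair(p_mut = 0.03, m = 1, p_cn = 0.10)      # equivocal
#' classify_pair(p_cn = 0.05)                           # independent
classify_pair <- function(p_mut = NA_real_, m = NA_integer_, p_cn = NA_real_) {
  k <- max(length(p_mut), length(m), length(p_cn))
  p_mut <- rep_len(as.numeric(p_mut), k)
  m <- rep_len(as.numeric(m), k)
  p_cn <- rep_len(as.numeric(p_cn), k)
  if (any(!is.na(p_mut) & is.na(m))) {
    stop_format("shared count m is required whenever p_mut is given")
  }
  vapply(seq_len(k), function(i) {
    ps <- c(p_mut[i], p_cn[i])
    ps <- ps[!is.na(ps)]
    if (length(ps) == 0) return("untested")
    minp <- min(ps)
    if (minp < 0.01) return("clonal")
    if (!is.na(p_mut[i]) && m[i] == 0) return("independent")
    if (minp < 0.05) return("equivocal")
    "independent"
  }, character(1))
}

#' Summarize pair decisions by category
#'
#' @param decisions data frame with columns `case` (patient id),
#'   `category` (e.g. `"LCIS-ILC"`), `verdict`, and optionally `m`
#'   (shared-mutation count, for the zero-match tally).
#' @return Data frame per category: pairings, clonal / equivocal /
#'   independent / untested counts, distinct cases, distinct cases with
#'   at least one clonal pairing, and zero-match pair count.
#' @export
summarize_cohort <- function(decisions) {
  if (nrow(decisions) == 0) {
    return(data.frame(category = character(), pairings = integer(),
                      clonal = integer(), equivocal = integer(),
                      independent = integer(), untested = integer(),
                      cases = integer(), cases_clonal = integer(),
                      zero_match = integer()))
  }
  out <- do.call(rbind, lapply(unique(decisions$category), function(cat) {
    d <- decisions[decisions$category == cat, , drop = FALSE]
    zero <- if ("m" %in% names(d)) sum(!is.na(d$m) & d$m == 0) else NA_integer_
    data.frame(
      category = cat,
      pairings = nrow(d),
      clonal = sum(d$verdict == "clonal"),
      equivocal = sum(d$verdict == "equivocal"),
      independent = sum(d$verdict == "independent"),
      untested = sum(d$verdict == "untested"),
      cases = length(unique(d$case)),
      cases_clonal = length(unique(d$case[d$verdict == "clonal"])),
      zero_match = zero,
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pair category from two histology labels
#'
#' LCIS is listed first by convention (`"LCIS-ILC"`, `"LCIS-DCIS"`, ...);
#' pairs without an LCIS member fall into `"other"`.
#'
#' @param hist_a,hist_b histology labels.
#' @return Character vector of categories.
#' @export
pair_category <- function(hist_a, hist_b) {
  mapply(function(a, b) {
    if (a == "LCIS" && b == "LCIS") return("LCIS-LCIS")
    if (a == "LCIS") return(paste0("LCIS-", b))
    if (b == "LCIS") return(paste0("LCIS-", a))
    "other"
  }, hist_a, hist_b, USE.NAMES = FALSE)
}
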