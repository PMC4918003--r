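# Clonal vs private mutation designation and the per-gene mutation
# spectrum across a cohort of multi-lesion patients.

#' Designate each mutation of a patient as clonal or private
#'
#' A mutation observed in two or more tumors of the patient is "clonal"
#' (it must have been present in the common ancestral clone); a mutation
#' seen in exactly one tumor is "private". Hypermutated tumors (total
#' mutations above `hypermutation_cutoff`, default 200) are excluded
#' before labeling so a single unstable genome does not distort the
#' spectrum.
#'
#' @param patient_profiles list of [mutation_profile()] objects from one
#'   patient.
#' @param hypermutation_cutoff tumors with more mutations than this are
#'   dropped.
#' @return Data frame with one row per distinct mutation key among the
#'   retained tumors: `key`, `gene`, `func_class`, `n_tumors`, `label`
#'   (`"clonal"`/`"private"`); attribute `excluded_lesions` lists dropped
#'   tumors.
#' @export
designate_clonal_private <- function(patient_profiles,
                                     hypermutation_cutoff = 200) {
  stopifnot(length(patient_profiles) >= 1, hypermutation_cutoff > 0)
  totals <- vapply(patient_profiles, n_mutations, 0L)
  hyper <- totals > hypermutation_cutoff
  excluded <- vapply(patient_profiles[hyper], `[[`, "", "lesion")
  kept <- patient_profiles[!hyper]
  if (length(kept) == 0) {
    warning("all tumors of the patient are hypermutated; empty labeling",
            call. = FALSE)
    out <- data.frame(key = character(), gene = character(),
                      func_class = character(), n_tumors = integer(),
                      label = character())
    attr(out, "excluded_lesions") <- excluded
    return(out)
  }
  all_mut <- do.call(rbind, lapply(kept, function(pr) {
    pr$mutations[c("key", "gene", "func_class")]
  }))
  counts <- table(all_mut$key)
  uniq <- all_mut[!duplicated(all_mut$key), , drop = FALSE]
  uniq$n_tumors <- as.integer(counts[uniq$key])
  uniq$label <- ifelse(uniq$n_tumors >= 2, "clonal", "private")
  rownames(uniq) <- NULL
  attr(uniq, "excluded_lesions") <- excluded
  uniq
}

#' Per-gene clonal/private mutation spectrum for a cohort
#'
#' Aggregates [designate_clonal_private()] over all patients: per gene,
#' the number of distinct (patient, mutation) events, how many patients
#' have at least one mutated tumor in the gene, clonal and private
#' counts, percent clonal, and the fraction of functional (any class
#' except synonymous) mutations among clonal and among private events.
#' Outlier genes can be excluded (default `FSIP2`, an artifact-prone
#' gene); hypermutated tumors are excluded per patient. Genes are ranked
#' by total mutations descending, ties broken alphabetically.
#'
#' @param cohort list of patients, each a list of [mutation_profile()]
#'   objects.
#' @param excluded_genes genes dropped from the table.
#' @param hypermutation_cutoff see [designate_clonal_private()].
#' @return Data frame `gene`, `total`, `cases`, `clonal`, `private`,
#'   `percent_clonal`, `functional_clonal`, `functional_private` (the
#'   last two are fractions in \[0,1\], `NA` when no events of the label).
#' @export
spectrum_table <- function(cohort, excluded_genes = "FSIP2",
                           hypermutation_cutoff = 200) {
  labeled <- do.call(rbind, lapply(seq_along(cohort), function(i) {
    d <- designate_clonal_private(cohort[[i]], hypermutation_cutoff)
    if (nrow(d) > 0) d$patient <- cohort[[i]][[1]]$patient
    d
  }))
  if (is.null(labeled) || nrow(labeled) == 0) {
    return(data.frame(gene = character(), total = integer(),
                      cases = integer(), clonal = integer(),
                      private = integer(), percent_clonal = numeric(),
                      functional_clonal = numeric(),
                      functional_private = numeric()))
  }
  drop <- labeled$gene %in% excluded_genes
  if (any(drop)) {
    message(sprintf("spectrum_table: excluded %d mutation(s) in gene(s) %s",
                    sum(drop), paste(unique(labeled$gene[drop]), collapse = ", ")))
    labeled <- labeled[!drop, , drop = FALSE]
  }
  labeled$functional <- is.na(labeled$func_class) |
    labeled$func_class != "synonymous"
  genes <- sort(unique(labeled$gene))
  tab <- do.call(rbind, lapply(genes, function(g) {
    d <- labeled[labeled$gene == g, , drop = FALSE]
    cl <- d$label == "clonal"
    data.frame(
      gene = g,
      total = nrow(d),
      cases = length(unique(d$patient)),
      clonal = sum(cl),
      private = sum(!cl),
      percent_clonal = 100 * mean(cl),
      functional_clonal = if (any(cl)) mean(d$functional[cl]) else NA_real_,
      functional_private = if (any(!cl)) mean(d$functional[!cl]) else NA_real_,
      stringsAsFactors = FALSE)
  }))
  tab <- tab[order(-tab$total, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Median mutation burden by histology
#'
#' @param profiles list of [mutation_profile()] objects (one per lesion).
#' @return Data frame `histology`, `n_lesions`, `median_mutations`.
#' @export
mutation_burden_summary <- function(profiles) {
  hist <- vapply(profiles, `[[`, "", "histology")
  totals <- vapply(profiles, n_mutations, 0L)
  out <- do.call(rbind, lapply(unique(hist), function(h) {
    data.frame(histology = h, n_lesions = sum(hist == h),
               median_mutations = stats::median(totals[hist == h]),
               stringsAsFactors = FALSE)
  }))
  out[order(out$histology), , drop = FALSE]
}
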