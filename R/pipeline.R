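# End-to-end orchestration: QC -> segmentation -> both clonality tests
# where the data permit -> pair classification -> reports.

#' Read a cohort from a manifest directory
#'
#' `manifest.yaml` lists lesions (`lesion`, `patient`, `histology`,
#' optional `probe_file`, `mutation_file`, paths relative to the
#' directory); a `reference/` subdirectory holds the frequency
#' reference (see [write_frequency_reference()]).
#'
#' @param dir cohort directory (as written by [write_cohort()]).
#' @param genome a [genome_partition()]; defaults to [toy_genome()].
#' @return A `synthetic_cohort`-shaped list usable by [run_pipeline()].
#' @export
read_cohort <- function(dir, genome = toy_genome()) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  lesions <- list()
  for (entry in man$lesions) {
    pp <- if (!is.null(entry$probe_file)) {
      read_probe_profile(file.path(dir, entry$probe_file), genome)
    } else NULL
    mp <- if (!is.null(entry$mutation_file)) {
      read_mutation_table(file.path(dir, entry$mutation_file))
    } else NULL
    lesions[[entry$lesion]] <- list(lesion = entry$lesion,
                                    patient = entry$patient,
                                    histology = entry$histology,
                                    probe_profile = pp, mutation_profile = mp)
  }
  ref_dir <- file.path(dir, "reference")
  ref_freq <- if (dir.exists(ref_dir)) read_frequency_reference(ref_dir) else NULL
  structure(list(genome = genome, config = NULL, lesions = lesions,
                 ref_freq = ref_freq, truth = NULL),
            class = "synthetic_cohort")
}

#' Run the full clonality pipeline on a cohort
#'
#' Per lesion with array (or exome-derived) data: marker averaging,
#' multi-step segmentation with gain/loss calling, and the QC gate. The
#' copy-number comparison runs for within-patient pairs where both
#' lesions pass QC and a cross-patient reference (>= 2 patients with
#' QC-passing lesions) exists; the mutation LR test runs for pairs with
#' mutation data (germline-filtered first). Verdicts combine the two
#' tests under the believe-the-positive rule. Deterministic given
#' `seed`.
#'
#' @param cohort a [simulate_cohort()] or [read_cohort()] result.
#' @param group_size probes per marker.
#' @param seg_alpha,seg_perm segmentation split level and permutation
#'   count (see [segment_genome()]).
#' @param maf_threshold germline filter threshold.
#' @param n_mc,exact_limit LR-test settings (see [lr_match_test()]).
#' @param seed master seed; per-stage seeds are derived from it.
#' @return List of class `pipeline_result`: `decisions` (one row per
#'   within-patient pair), `summary` (per category), `qc` (per lesion),
#'   `call_sets`, `reference`.
#' @export
run_pipeline <- function(cohort, group_size = 12, seg_alpha = 0.01,
                         seg_perm = 300, maf_threshold = 0.05,
                         n_mc = 10000, exact_limit = 20, seed = 1L) {
  lesions <- cohort$lesions
  ids <- names(lesions)
  patients <- vapply(lesions, `[[`, "", "patient")

  # --- copy-number stage ---------------------------------------------
  call_sets <- list()
  qc <- list()
  for (id in ids) {
    pp <- lesions[[id]]$probe_profile
    if (is.null(pp)) next
    mk <- average_adjacent(pp, group_size = group_size)
    seg <- segment_genome(mk, alpha = seg_alpha, n_perm = seg_perm,
                          seed = seed + match(id, ids))
    q <- qc_gate(seg)
    qc[[id]] <- data.frame(lesion = id, patient = lesions[[id]]$patient,
                           percent_aberrant = q$percent_aberrant,
                           height_ratio = q$height_ratio, pass = q$pass,
                           stringsAsFactors = FALSE)
    if (q$pass) {
      call_sets[[id]] <- one_step_arm_calls(mk, alpha = seg_alpha,
                                            n_perm = seg_perm,
                                            seed = seed + 5000L + match(id, ids))
    }
  }
  qc <- if (length(qc)) do.call(rbind, qc) else NULL
  if (!is.null(qc)) rownames(qc) <- NULL

  cs_ids <- names(call_sets)
  cs_patients <- patients[cs_ids]
  reference <- NULL
  if (length(unique(cs_patients)) >= 2) {
    reference <- build_reference(unname(call_sets), unname(cs_patients))
  }

  # --- per within-patient pair ---------------------------------------
  rows <- list()
  pair_no <- 0L
  for (pat in unique(patients)) {
    les <- ids[patients == pat]
    if (length(les) < 2) next
    combos <- utils::combn(les, 2)
    for (k in seq_len(ncol(combos))) {
      a_id <- combos[1, k]; b_id <- combos[2, k]
      pair_no <- pair_no + 1L
      p_cn <- NA_real_; S <- NA_real_
      if (!is.null(reference) && a_id %in% cs_ids && b_id %in% cs_ids) {
        res_cn <- try(cn_clonality_test(call_sets[[a_id]], call_sets[[b_id]],
                                        unname(call_sets), unname(cs_patients),
                                        patient = pat, reference = reference),
                      silent = TRUE)
        if (!inherits(res_cn, "try-error")) {
          p_cn <- res_cn$p_cn; S <- res_cn$S
        }
      }
      p_mut <- NA_real_; m <- NA_integer_
      n_a <- NA_integer_; n_b <- NA_integer_
      xi_hat <- NA_real_
      ma <- lesions[[a_id]]$mutation_profile
      mb <- lesions[[b_id]]$mutation_profile
      if (!is.null(ma) && !is.null(mb) && !is.null(cohort$ref_freq)) {
        ma <- filter_germline_suspects(ma, maf_threshold)
        mb <- filter_germline_suspects(mb, maf_threshold)
        res_mut <- try(lr_clonality_test(ma, mb, cohort$ref_freq, n_mc = n_mc,
                                         seed = seed + 10000L + pair_no,
                                         exact_limit = exact_limit),
                       silent = TRUE)
        if (!inherits(res_mut, "try-error")) {
          p_mut <- res_mut$p_value
          m <- res_mut$m
          xi_hat <- res_mut$xi_hat
          n_a <- n_mutations(ma); n_b <- n_mutations(mb)
        }
      }
      rows[[pair_no]] <- data.frame(
        case = pat, lesion_1 = a_id, lesion_2 = b_id,
        category = pair_category(lesions[[a_id]]$histology,
                                 lesions[[b_id]]$histology),
        m = m, n_1 = n_a, n_2 = n_b, xi_hat = xi_hat,
        p_mut = p_mut, S = S, p_cn = p_cn,
        verdict = classify_pair(p_mut, m, p_cn),
        stringsAsFactors = FALSE)
    }
  }
  decisions <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case = character(), lesion_1 = character(),
               lesion_2 = character(), category = character(),
               m = integer(), n_1 = integer(), n_2 = integer(),
               xi_hat = numeric(), p_mut = numeric(), S = numeric(),
               p_cn = numeric(), verdict = character())
  rownames(decisions) <- NULL
  structure(list(decisions = decisions, summary = summarize_cohort(decisions),
                 qc = qc, call_sets = call_sets, reference = reference),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d pair decision(s):\n", nrow(x$decisions)))
  print(table(x$decisions$verdict))
  invisible(x)
}

#' Write pipeline reports
#'
#' Decisions TSV (one row per pair), per-category summary JSON, and the
#' QC table TSV.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_reports <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(result$decisions, file.path(dir, "decisions.tsv"))
  jsonlite::write_json(result$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(result$qc)) write_tsv(result$qc, file.path(dir, "qc.tsv"))
  invisible(dir)
}

#' Operating characteristics of the pipeline on simulated cohorts
#'
#' Runs the full pipeline on `n_reps` simulated cohorts and compares
#' verdicts with the planted truth: type-I error (independent pairs
#' called clonal), power (related pairs called clonal), bias and RMSE of
#' the clonality-fraction estimate, and the verdict confusion matrix.
#'
#' @param config a [simulation_config()] (its `seed` seeds replicate 1;
#'   replicate r uses `seed + r - 1`).
#' @param n_reps number of replicate cohorts.
#' @param ... passed to [run_pipeline()].
#' @return List: `confusion` (related x verdict table), `type1`, `power`,
#'   `xi_bias`, `xi_rmse`, `decisions` (all replicates, with `related`).
#' @export
recovery_experiment <- function(config = simulation_config(), n_reps = 5, ...) {
  all_dec <- list()
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    cohort <- simulate_cohort(cfg)
    res <- run_pipeline(cohort, seed = cfg$seed, ...)
    dec <- res$decisions
    if (nrow(dec) == 0) next
    dec$related <- vapply(dec$case, function(p) cohort$truth[[p]]$related, TRUE)
    dec$xi_true <- vapply(dec$case, function(p) cohort$truth[[p]]$xi, 0)
    dec$rep <- r
    all_dec[[r]] <- dec
  }
  dec <- do.call(rbind, all_dec)
  ind <- dec[!dec$related, , drop = FALSE]
  rel <- dec[dec$related, , drop = FALSE]
  xi_err <- rel$xi_hat - rel$xi_true
  xi_err <- xi_err[!is.na(xi_err)]
  list(confusion = table(related = dec$related, verdict = dec$verdict),
       type1 = if (nrow(ind)) mean(ind$verdict == "clonal") else NA_real_,
       power = if (nrow(rel)) mean(rel$verdict == "clonal") else NA_real_,
       xi_bias = if (length(xi_err)) mean(xi_err) else NA_real_,
       xi_rmse = if (length(xi_err)) sqrt(mean(xi_err^2)) else NA_real_,
       decisions = dec)
}
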