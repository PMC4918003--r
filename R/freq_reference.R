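#' Reference cohort mutation / arm-event frequencies
#'
#' Marginal occurrence frequencies of somatic events in a reference tumor
#' cohort (TCGA-style), used to weight the evidential value of a match:
#' sharing a rare event is strong evidence of common clonal origin, sharing
#' a ubiquitous one is not. Carries locus-level counts, gene-level fallback
#' counts, and arm-level gain/loss frequencies.
#'
#' Marginal probabilities use the shrunken estimator
#' `p_i = (x_i + alpha) / (N + 2 alpha)`, which is strictly inside (0,1)
#' for any count `0 <= x_i <= N`.
#'
#' @param N reference cohort size (number of tumors).
#' @param locus_counts data frame `chrom`, `pos`, `ref`, `alt`, `count`
#'   (tumors in the reference carrying that exact mutation); may be `NULL`.
#' @param gene_counts data frame `gene`, `count` (tumors with any mutation
#'   in the gene); may be `NULL`.
#' @param arm_freqs data frame `arm`, `event` (`"gain"`/`"loss"`), `freq`
#'   in \[0,1\]; may be `NULL`.
#' @param alpha pseudo-count, default 0.5.
#' @param sites_per_gene nominal number of distinct mutable sites per gene
#'   used to apportion a gene-level count to an unlisted locus; default 100.
#' @return An object of class `frequency_reference`.
#' @export
frequency_reference <- function(N, locus_counts = NULL, gene_counts = NULL,
                                arm_freqs = NULL, alpha = 0.5,
                                sites_per_gene = 100) {
  stopifnot(N >= 1, alpha > 0, sites_per_gene >= 1)
  if (!is.null(locus_counts)) {
    req <- c("chrom", "pos", "ref", "alt", "count")
    stopifnot(all(req %in% names(locus_counts)))
    if (any(locus_counts$count < 0 | locus_counts$count > N)) {
      stop_format("locus counts must lie in [0, N]")
    }
    locus_counts$key <- mutation_key(locus_counts$chrom, locus_counts$pos,
                                     locus_counts$ref, locus_counts$alt)
  }
  if (!is.null(gene_counts)) {
    stopifnot(all(c("gene", "count") %in% names(gene_counts)))
    if (any(gene_counts$count < 0 | gene_counts$count > N)) {
      stop_format("gene counts must lie in [0, N]")
    }
  }
  if (!is.null(arm_freqs)) {
    stopifnot(all(c("arm", "event", "freq") %in% names(arm_freqs)))
    if (any(arm_freqs$freq < 0 | arm_freqs$freq > 1)) {
      stop_format("arm-event frequencies must lie in [0,1]")
    }
  }
  structure(list(N = N, alpha = alpha, sites_per_gene = sites_per_gene,
                 locus_counts = locus_counts, gene_counts = gene_counts,
                 arm_freqs = arm_freqs),
            class = "frequency_reference")
}

#' @export
print.frequency_reference <- function(x, ...) {
  cat(sprintf(
    "<frequency_reference> N = %d, alpha = %g; %d locus counts, %d gene counts, %d arm-event rows\n",
    x$N, x$alpha,
    if (is.null(x$locus_counts)) 0L else nrow(x$locus_counts),
    if (is.null(x$gene_counts)) 0L else nrow(x$gene_counts),
    if (is.null(x$arm_freqs)) 0L else nrow(x$arm_freqs)))
  invisible(x)
}

#' Marginal probability of a specific somatic mutation
#'
#' Locus-level reference count if present; otherwise the gene-level count
#' apportioned over a nominal `sites_per_gene` distinct sites; otherwise
#' the pseudo-count floor `alpha / (N + 2 alpha)`. Always strictly in
#' (0,1).
#'
#' @param chrom,pos,ref,alt mutation key (vectors recycle together).
#' @param gene gene symbol(s) for the gene-level fallback (`NA` to skip).
#' @param ref_freq a [frequency_reference()].
#' @return Numeric vector of marginal probabilities.
#' @export
marginal_probability <- function(chrom, pos, ref, alt, gene, ref_freq) {
  stopifnot(inherits(ref_freq, "frequency_reference"))
  n <- length(pos)
  key <- mutation_key(chrom, pos, ref, alt)
  x <- rep(0, n)
  resolved <- rep(FALSE, n)
  if (!is.null(ref_freq$locus_counts)) {
    idx <- match(key, ref_freq$locus_counts$key)
    hit <- !is.na(idx)
    x[hit] <- ref_freq$locus_counts$count[idx[hit]]
    resolved[hit] <- TRUE
  }
  if (!is.null(ref_freq$gene_counts)) {
    idx <- match(gene, ref_freq$gene_counts$gene)
    hit <- !resolved & !is.na(idx)
    x[hit] <- ref_freq$gene_counts$count[idx[hit]] / ref_freq$sites_per_gene
  }
  (x + ref_freq$alpha) / (ref_freq$N + 2 * ref_freq$alpha)
}

# Marginal probabilities for every mutation of a profile.
profile_marginals <- function(profile, ref_freq) {
  m <- profile$mutations
  marginal_probability(m$chrom, m$pos, m$ref, m$alt, m$gene, ref_freq)
}

#' Read / write a frequency reference
#'
#' The reference is persisted as a directory of up to three tab-delimited
#' tables (`locus_counts.tsv`, `gene_counts.tsv`, `arm_freqs.tsv`) plus a
#' `meta.tsv` holding `N`, `alpha` and `sites_per_gene`.
#'
#' @param dir directory path.
#' @param ref_freq a [frequency_reference()] (for writing).
#' @return `read_frequency_reference` returns a [frequency_reference()];
#'   `write_frequency_reference` returns `dir` invisibly.
#' @export
read_frequency_reference <- function(dir) {
  meta <- read_tsv_strict(file.path(dir, "meta.tsv"),
                          c("N", "alpha", "sites_per_gene"), "reference meta")
  rd <- function(f, req) {
    p <- file.path(dir, f)
    if (file.exists(p)) read_tsv_strict(p, req, f) else NULL
  }
  frequency_reference(
    N = meta$N[1], alpha = meta$alpha[1], sites_per_gene = meta$sites_per_gene[1],
    locus_counts = rd("locus_counts.tsv", c("chrom", "pos", "ref", "alt", "count")),
    gene_counts = rd("gene_counts.tsv", c("gene", "count")),
    arm_freqs = rd("arm_freqs.tsv", c("arm", "event", "freq"))
  )
}

#' @rdname read_frequency_reference
#' @export
write_frequency_reference <- function(ref_freq, dir) {
  stopifnot(inherits(ref_freq, "frequency_reference"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(data.frame(N = ref_freq$N, alpha = ref_freq$alpha,
                       sites_per_gene = ref_freq$sites_per_gene),
            file.path(dir, "meta.tsv"))
  if (!is.null(ref_freq$locus_counts)) {
    write_tsv(ref_freq$locus_counts[c("chrom", "pos", "ref", "alt", "count")],
              file.path(dir, "locus_counts.tsv"))
  }
  if (!is.null(ref_freq$gene_counts)) {
    write_tsv(ref_freq$gene_counts[c("gene", "count")],
              file.path(dir, "gene_counts.tsv"))
  }
  if (!is.null(ref_freq$arm_freqs)) {
    write_tsv(ref_freq$arm_freqs[c("arm", "event", "freq")],
              file.path(dir, "arm_freqs.tsv"))
  }
  invisible(dir)
}
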