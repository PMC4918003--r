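#' Probe-level copy-number profile for one lesion
#'
#' Ordered per-probe log2 ratios with genomic coordinates. This is the raw
#' input of the array copy-number path; the exome path produces the same
#' structure from coverage depth.
#'
#' @param lesion lesion id.
#' @param patient patient id.
#' @param histology one of `"LCIS"`, `"ILC"`, `"DCIS"`, `"IDC"`.
#' @param probes data frame with columns `chrom`, `pos` (1-based bp),
#'   `logratio` (log2, dimensionless).
#' @param genome a [genome_partition()]; probes outside every arm are
#'   dropped (with a message reporting the count).
#'
#' @return An object of class `probe_profile` with elements `lesion`,
#'   `patient`, `histology`, `probes` (sorted, with an `arm` column).
#' @export
probe_profile <- function(lesion, patient, histology, probes, genome) {
  req <- c("chrom", "pos", "logratio")
  if (!all(req %in% names(probes))) {
    stop_format("probes must have columns %s", paste(req, collapse = ", "))
  }
  histology <- match.arg(toupper(histology), HISTOLOGIES)
  probes <- probes[req]
  probes$chrom <- as.character(probes$chrom)
  probes$pos <- as.numeric(probes$pos)
  probes$logratio <- as.numeric(probes$logratio)
  if (any(!is.finite(probes$logratio))) stop_format("log ratios must be finite")
  probes$arm <- assign_arm(probes$chrom, probes$pos, genome)
  n_drop <- sum(is.na(probes$arm))
  if (n_drop > 0) {
    message(sprintf("probe_profile[%s]: dropped %d probe(s) outside all arms",
                    lesion, n_drop))
    probes <- probes[!is.na(probes$arm), , drop = FALSE]
  }
  probes <- probes[genome_order(probes$chrom, probes$pos, genome), , drop = FALSE]
  for (ch in unique(probes$chrom)) {
    p <- probes$pos[probes$chrom == ch]
    if (anyDuplicated(p)) stop_format("duplicate probe positions on chromosome %s", ch)
  }
  rownames(probes) <- NULL
  structure(list(lesion = lesion, patient = patient, histology = histology,
                 probes = probes, genome = genome),
            class = "probe_profile")
}

#' @export
print.probe_profile <- function(x, ...) {
  cat(sprintf("<probe_profile> lesion %s (patient %s, %s): %d probes on %d arms\n",
              x$lesion, x$patient, x$histology, nrow(x$probes),
              length(unique(x$probes$arm))))
  invisible(x)
}

#' Read a probe-level log-ratio table
#'
#' Tab-delimited with header columns `probe`, `chrom`, `pos`, `logratio`.
#' Lesion metadata comes from sidecar comment lines at the top of the file
#' (`# lesion: X`, `# patient: P`, `# histology: LCIS`) or from the
#' `lesion`/`patient`/`histology` arguments, which take precedence.
#'
#' @param path file path.
#' @param genome a [genome_partition()].
#' @param lesion,patient,histology optional metadata overriding the sidecar.
#' @return A [probe_profile()].
#' @export
read_probe_profile <- function(path, genome, lesion = NULL, patient = NULL,
                               histology = NULL) {
  meta <- read_sidecar_meta(path)
  df <- read_tsv_strict(path, c("probe", "chrom", "pos", "logratio"),
                        "probe table")
  lr <- suppressWarnings(as.numeric(df$logratio))
  if (any(is.na(lr))) {
    bad <- which(is.na(lr))[1]
    stop_format("non-numeric log ratio in %s at data line %d", path, bad)
  }
  df$logratio <- lr
  probe_profile(
    lesion = lesion %||% meta$lesion %||% stop_format("no lesion id for %s", path),
    patient = patient %||% meta$patient %||% stop_format("no patient id for %s", path),
    histology = histology %||% meta$histology %||% stop_format("no histology for %s", path),
    probes = df[c("chrom", "pos", "logratio")],
    genome = genome
  )
}

#' Write a probe profile (round-trips through [read_probe_profile()])
#'
#' @param profile a [probe_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probe_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# lesion: %s", profile$lesion),
               sprintf("# patient: %s", profile$patient),
               sprintf("# histology: %s", profile$histology)), con)
  df <- profile$probes
  df <- data.frame(probe = sprintf("P%06d", seq_len(nrow(df))),
                   chrom = df$chrom, pos = df$pos, logratio = df$logratio)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
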