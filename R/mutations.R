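# Somatic mutation profiles: construction, IO, the germline-frequency
# filter, and the shared-mutation intersection that feeds the LR test.

# Closed functional-class vocabulary plus MAF-style synonyms.
FUNCTIONAL_CLASSES <- c("missense", "nonsense", "frameshift", "splice", "synonymous")

FUNCTIONAL_SYNONYMS <- c(
  missense = "missense", missense_mutation = "missense",
  nonsense = "nonsense", nonsense_mutation = "nonsense",
  frameshift = "frameshift", truncating = "frameshift",
  frame_shift_del = "frameshift", frame_shift_ins = "frameshift",
  in_frame_del = "missense", in_frame_ins = "missense",
  splice = "splice", splice_site = "splice",
  synonymous = "synonymous", silent = "synonymous"
)

normalize_functional_class <- function(x) {
  key <- tolower(gsub("[ -]", "_", trimws(x)))
  out <- unname(FUNCTIONAL_SYNONYMS[key])
  if (any(is.na(out))) {
    stop_format("unknown functional class(es): %s",
                paste(unique(x[is.na(out)]), collapse = ", "))
  }
  out
}

#' Somatic mutation profile for one lesion
#'
#' The set of somatic mutations of one lesion, keyed by exact
#' (chrom, pos, ref, alt). Protein-level matching is deliberately not used:
#' precise mutational matches are the evidential basis of the clonality
#' test.
#'
#' @param lesion,patient,histology lesion metadata (histology one of
#'   LCIS/ILC/DCIS/IDC).
#' @param mutations data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `gene`, and optionally `protein_change`, `func_class`, `pop_af`
#'   (population minor-allele frequency in \[0,1\]; `NA` means "not seen in
#'   population databases" and is treated as 0 by the germline filter).
#'   Duplicate keys are collapsed with a warning.
#' @return An object of class `mutation_profile` with a `key` column added.
#' @export
mutation_profile <- function(lesion, patient, histology, mutations) {
  req <- c("chrom", "pos", "ref", "alt", "gene")
  if (!all(req %in% names(mutations))) {
    stop_format("mutations must have columns %s", paste(req, collapse = ", "))
  }
  histology <- match.arg(toupper(histology), HISTOLOGIES)
  m <- mutations
  m$chrom <- as.character(m$chrom)
  m$pos <- as.numeric(m$pos)
  m$ref <- as.character(m$ref)
  m$alt <- as.character(m$alt)
  if (any(m$ref == m$alt)) stop_format("ref and alt alleles must differ")
  m$protein_change <- if (is.null(m$protein_change)) NA_character_ else
    as.character(m$protein_change)
  m$func_class <- if (is.null(m$func_class)) NA_character_ else
    normalize_functional_class(m$func_class)
  m$pop_af <- if (is.null(m$pop_af)) NA_real_ else as.numeric(m$pop_af)
  if (any(!is.na(m$pop_af) & (m$pop_af < 0 | m$pop_af > 1))) {
    stop_format("pop_af must lie in [0,1]")
  }
  m$key <- mutation_key(m$chrom, m$pos, m$ref, m$alt)
  if (anyDuplicated(m$key)) {
    warning(sprintf("mutation_profile[%s]: collapsed %d duplicate mutation key(s)",
                    lesion, sum(duplicated(m$key))), call. = FALSE)
    m <- m[!duplicated(m$key), , drop = FALSE]
  }
  m <- m[order(m$chrom, m$pos, m$ref, m$alt),
         c("chrom", "pos", "ref", "alt", "gene", "protein_change",
           "func_class", "pop_af", "key"), drop = FALSE]
  rownames(m) <- NULL
  structure(list(lesion = lesion, patient = patient, histology = histology,
                 mutations = m),
            class = "mutation_profile")
}

#' @export
print.mutation_profile <- function(x, ...) {
  cat(sprintf("<mutation_profile> lesion %s (patient %s, %s): %d mutations\n",
              x$lesion, x$patient, x$histology, nrow(x$mutations)))
  invisible(x)
}

#' Number of mutations in a profile
#' @param profile a [mutation_profile()].
#' @return Integer count.
#' @export
n_mutations <- function(profile) nrow(profile$mutations)

#' Read a MAF-like somatic mutation table
#'
#' Tab-delimited with header columns `chrom`, `pos`, `ref`, `alt`, `gene`
#' and optional `protein_change`, `func_class`, `pop_af`. Metadata comes
#' from sidecar `#` lines or the explicit arguments.
#'
#' @inheritParams read_probe_profile
#' @return A [mutation_profile()].
#' @export
read_mutation_table <- function(path, lesion = NULL, patient = NULL,
                                histology = NULL) {
  meta <- read_sidecar_meta(path)
  df <- read_tsv_strict(path, c("chrom", "pos", "ref", "alt", "gene"),
                        "mutation table",
                        col_classes = c(chrom = "character", ref = "character",
                                        alt = "character", gene = "character",
                                        protein_change = "character",
                                        func_class = "character"))
  mutation_profile(
    lesion = lesion %||% meta$lesion %||% stop_format("no lesion id for %s", path),
    patient = patient %||% meta$patient %||% stop_format("no patient id for %s", path),
    histology = histology %||% meta$histology %||% stop_format("no histology for %s", path),
    mutations = df
  )
}

#' Write a mutation profile (round-trips through [read_mutation_table()])
#' @param profile a [mutation_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# lesion: %s", profile$lesion),
               sprintf("# patient: %s", profile$patient),
               sprintf("# histology: %s", profile$histology)), con)
  cols <- c("chrom", "pos", "ref", "alt", "gene", "protein_change",
            "func_class", "pop_af")
  utils::write.table(profile$mutations[cols], con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Drop likely-germline variants by population allele frequency
#'
#' Variants whose population minor-allele frequency exceeds the threshold
#' are disregarded as probable germline polymorphisms; the convention
#' follows the ">5 % is germline" reading, so a frequency exactly at the
#' threshold is kept. Mutations lacking a population frequency are treated
#' as frequency 0 (rare). Idempotent.
#'
#' @param profile a [mutation_profile()].
#' @param maf_threshold frequency cutoff in \[0,1\]; default 0.05.
#' @return The filtered [mutation_profile()].
#' @export
filter_germline_suspects <- function(profile, maf_threshold = 0.05) {
  stopifnot(inherits(profile, "mutation_profile"),
            maf_threshold >= 0, maf_threshold <= 1)
  af <- profile$mutations$pop_af
  af[is.na(af)] <- 0
  keep <- af <= maf_threshold
  profile$mutations <- profile$mutations[keep, , drop = FALSE]
  rownames(profile$mutations) <- NULL
  profile
}

#' Shared somatic mutations between two lesions
#'
#' Exact-key intersection of two mutation profiles. Profiles from different
#' patients are allowed (needed to build cross-patient null comparisons)
#' but trigger a warning unless `quiet = TRUE`.
#'
#' @param a,b [mutation_profile()] objects.
#' @param quiet suppress the cross-patient warning.
#' @return A list with `shared` (data frame of shared mutations, from `a`),
#'   `m` (shared count), `n_a`, `n_b` (profile sizes).
#' @export
shared_mutations <- function(a, b, quiet = FALSE) {
  stopifnot(inherits(a, "mutation_profile"), inherits(b, "mutation_profile"))
  if (!quiet && !identical(a$patient, b$patient)) {
    warning("shared_mutations: profiles come from different patients",
            call. = FALSE)
  }
  keys <- intersect(a$mutations$key, b$mutations$key)
  list(shared = a$mutations[a$mutations$key %in% keys, , drop = FALSE],
       m = length(keys), n_a = n_mutations(a), n_b = n_mutations(b))
}
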