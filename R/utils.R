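#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_format <- function(...) stop(sprintf(...), call. = FALSE)

# Unscaled median absolute deviation: median(|x - median(x)|).
# No 1.4826 consistency factor anywhere in the package.
mad_unscaled <- function(x) {
  x <- x[is.finite(x)]
  stats::median(abs(x - stats::median(x)))
}

# Canonical string key for a somatic mutation, used for set operations.
mutation_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

read_tsv_strict <- function(path, required, what = "table",
                            col_classes = NA) {
  if (!file.exists(path)) stop_format("%s file not found: %s", what, path)
  if (!is.null(names(col_classes))) {
    hdr <- names(utils::read.delim(path, nrows = 1, sep = "\t",
                                   comment.char = "#", check.names = FALSE))
    col_classes <- col_classes[names(col_classes) %in% hdr]
    if (length(col_classes) == 0) col_classes <- NA
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE, colClasses = col_classes)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_format("%s file %s is missing required column(s): %s",
                what, path, paste(missing, collapse = ", "))
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Parse "# key: value" sidecar lines at the top of a profile file.
read_sidecar_meta <- function(path) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  lines <- lines[startsWith(lines, "#")]
  meta <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*[:=]\\s*(.+?)\\s*$", ln))[[1]]
    if (length(m) == 3) meta[[tolower(m[2])]] <- m[3]
  }
  meta
}

HISTOLOGIES <- c("LCIS", "ILC", "DCIS", "IDC")

# Uniform integer draw(s) on [lo, hi]; safe when lo == hi (base sample()
# would treat a length-1 vector as 1:n).
sample_range <- function(lo, hi, n = 1) {
  if (lo >= hi) rep(lo, n) else sample(seq(lo, hi), n, replace = TRUE)
}
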