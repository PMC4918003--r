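# Copy-number profiles derived from tumor/normal exome coverage:
# locus selection on the capture targets, library-size-scaled log2
# coverage ratios, LOESS correction of GC bias, then the same marker
# averaging and segmentation machinery as the array path.

#' Read a per-locus coverage depth track
#'
#' Tab-delimited `chrom`, `pos` (1-based), `depth` (integer >= 0), with
#' optional sidecar `# sample:` line.
#'
#' @param path file path.
#' @param sample sample id (overrides the sidecar line).
#' @return Object of class `coverage_track`: `sample`, `loci` (sorted
#'   data frame), `total_depth`.
#' @export
read_coverage_track <- function(path, sample = NULL) {
  meta <- read_sidecar_meta(path)
  df <- read_tsv_strict(path, c("chrom", "pos", "depth"), "coverage")
  coverage_track(sample %||% meta$sample %||% basename(path), df)
}

#' @rdname read_coverage_track
#' @param loci data frame `chrom`, `pos`, `depth`.
#' @export
coverage_track <- function(sample, loci) {
  stopifnot(all(c("chrom", "pos", "depth") %in% names(loci)))
  loci <- loci[c("chrom", "pos", "depth")]
  loci$chrom <- as.character(loci$chrom)
  if (any(loci$depth < 0)) stop_format("coverage depths must be >= 0")
  loci <- loci[order(loci$chrom, loci$pos), , drop = FALSE]
  if (anyDuplicated(paste(loci$chrom, loci$pos))) {
    stop_format("duplicate positions in coverage track %s", sample)
  }
  rownames(loci) <- NULL
  structure(list(sample = sample, loci = loci,
                 total_depth = sum(loci$depth)),
            class = "coverage_track")
}

#' Read a BED file of capture target regions
#'
#' Minimal 3-column BED (chrom, start, end), 0-based half-open; converted
#' to 1-based inclusive coordinates at this boundary.
#'
#' @param path BED file path.
#' @return Data frame `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_bed_targets <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 3) stop_format("BED file %s needs >= 3 columns", path)
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.numeric(df[[2]]) + 1,  # 0-based -> 1-based
                    end = as.numeric(df[[3]]),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Select analysis loci on the capture targets
#'
#' Greedy left-to-right scan within each target region: a candidate
#' position (a position present in the normal coverage tracks) is
#' accepted when it lies at least `spacing` bases after the last accepted
#' position (the spacing counter resets at each region and chromosome
#' boundary) and every normal sample covers it with at least `min_depth`
#' reads. Enforcing depth in all normals keeps the denominator of the
#' log ratio stable.
#'
#' @param targets data frame from [read_bed_targets()] (1-based
#'   inclusive).
#' @param normals list of [coverage_track()] objects.
#' @param spacing minimum distance between consecutive loci (bp).
#' @param min_depth minimum depth in every normal.
#' @return Data frame `chrom`, `pos` of accepted loci.
#' @export
select_loci <- function(targets, normals, spacing = 250, min_depth = 25) {
  stopifnot(nrow(targets) > 0, length(normals) >= 1)
  # minimum depth across normals at each position covered by all normals
  key0 <- paste(normals[[1]]$loci$chrom, normals[[1]]$loci$pos)
  min_depth_vec <- normals[[1]]$loci$depth
  for (tr in normals[-1]) {
    key1 <- paste(tr$loci$chrom, tr$loci$pos)
    idx <- match(key0, key1)
    min_depth_vec <- pmin(min_depth_vec,
                          ifelse(is.na(idx), -1, tr$loci$depth[idx]))
  }
  cand <- normals[[1]]$loci[min_depth_vec >= min_depth, c("chrom", "pos")]
  out <- list()
  for (i in seq_len(nrow(targets))) {
    pos <- cand$pos[cand$chrom == targets$chrom[i] &
                      cand$pos >= targets$start[i] &
                      cand$pos <= targets$end[i]]
    pos <- sort(pos)
    last <- -Inf
    acc <- logical(length(pos))
    for (k in seq_along(pos)) {
      if (pos[k] - last >= spacing || !is.finite(last)) {
        acc[k] <- TRUE
        last <- pos[k]
      }
    }
    if (any(acc)) {
      out[[i]] <- data.frame(chrom = targets$chrom[i], pos = pos[acc],
                             stringsAsFactors = FALSE)
    }
  }
  loci <- do.call(rbind, out)
  if (is.null(loci) || nrow(loci) == 0) {
    stop_format("no loci satisfy the spacing/depth criteria")
  }
  rownames(loci) <- NULL
  loci
}

#' Library-size-scaled tumor/normal coverage log ratio
#'
#' `r = log2((t_d / T) / (n_d / N))` per locus, with `T`/`N` the total
#' tumor/normal depth over the selected loci, so a uniform change in
#' sequencing yield cancels. Loci with zero normal depth are dropped with
#' a warning; zero tumor depth enters through a 0.5 pseudo-count.
#'
#' @param tumor,normal [coverage_track()] objects.
#' @param loci data frame `chrom`, `pos` from [select_loci()].
#' @return Data frame `chrom`, `pos`, `logratio`.
#' @export
coverage_log_ratio <- function(tumor, normal, loci) {
  key <- paste(loci$chrom, loci$pos)
  ti <- match(key, paste(tumor$loci$chrom, tumor$loci$pos))
  ni <- match(key, paste(normal$loci$chrom, normal$loci$pos))
  if (any(is.na(ti)) || any(is.na(ni))) {
    stop_format("tumor/normal tracks do not cover all selected loci")
  }
  td <- tumor$loci$depth[ti]
  nd <- normal$loci$depth[ni]
  drop <- nd == 0
  if (any(drop)) {
    warning(sprintf("coverage_log_ratio: dropped %d locus/loci with zero normal depth",
                    sum(drop)), call. = FALSE)
    td <- td[!drop]; nd <- nd[!drop]; loci <- loci[!drop, , drop = FALSE]
  }
  if (any(td == 0)) {
    message(sprintf("coverage_log_ratio: %d locus/loci with zero tumor depth use a 0.5 pseudo-count",
                    sum(td == 0)))
    td[td == 0] <- 0.5
  }
  Tt <- sum(td)
  Nn <- sum(nd)
  data.frame(chrom = loci$chrom, pos = loci$pos,
             logratio = log2((td / Tt) / (nd / Nn)),
             stringsAsFactors = FALSE)
}

#' LOESS correction of GC bias in coverage log ratios
#'
#' Regresses the log ratio on the GC fraction of a window centered at
#' each locus and returns the residuals, removing the smooth dependence
#' of coverage on local base composition. With fewer than `min_loci`
#' points the fit is unstable and normalization is skipped (with a
#' warning); constant GC degenerates to median-centering.
#'
#' @param series data frame `chrom`, `pos`, `logratio`.
#' @param gc numeric vector of GC fractions in \[0,1\], parallel to
#'   `series` rows (1-kb window centered at each locus by convention).
#' @param span LOESS span (default 0.3).
#' @param min_loci minimum points for a stable fit.
#' @return `series` with `logratio` replaced by the GC-corrected values.
#' @export
gc_normalize <- function(series, gc, span = 0.3, min_loci = 30) {
  stopifnot(length(gc) == nrow(series))
  if (any(gc < 0 | gc > 1)) stop_format("GC fractions must lie in [0,1]")
  if (nrow(series) < min_loci) {
    warning(sprintf("gc_normalize: only %d loci (< %d); normalization skipped",
                    nrow(series), min_loci), call. = FALSE)
    return(series)
  }
  if (stats::sd(gc) == 0) {
    warning("gc_normalize: constant GC; centering only", call. = FALSE)
    series$logratio <- series$logratio - stats::median(series$logratio)
    return(series)
  }
  fit <- stats::loess(series$logratio ~ gc, span = span, degree = 2,
                      family = "symmetric",
                      control = stats::loess.control(surface = "direct"))
  series$logratio <- stats::residuals(fit)
  series
}

#' Marker profile from a GC-corrected coverage log-ratio series
#'
#' Wraps the series into a [probe_profile()] and delegates to
#' [average_adjacent()], so the exome-derived profile feeds the same
#' segmentation and clonality machinery as the array path.
#'
#' @param series data frame `chrom`, `pos`, `logratio`.
#' @param genome a [genome_partition()].
#' @param lesion,patient,histology lesion metadata.
#' @param group_size loci per marker (default 12).
#' @return A [average_adjacent()] marker profile.
#' @export
exome_marker_profile <- function(series, genome, lesion, patient, histology,
                                 group_size = 12) {
  pr <- probe_profile(lesion, patient, histology,
                      series[c("chrom", "pos", "logratio")], genome)
  average_adjacent(pr, group_size = group_size)
}
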