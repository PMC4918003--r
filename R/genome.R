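#' Chromosome-arm partition of a genome
#'
#' A `genome_partition` is the coordinate frame for every copy-number
#' operation in the package: an ordered table of chromosome arms, each a
#' half-chromosome interval in 1-based inclusive base-pair coordinates.
#' Arm-level gain/loss calls (the unit compared between lesions) are always
#' made with respect to such a partition.
#'
#' @param arms data frame with columns `arm` (e.g. `"1p"`), `chrom`,
#'   `start`, `end` (1-based inclusive bp).
#' @param chrom_order character vector giving chromosome display order;
#'   defaults to order of first appearance.
#'
#' @return An object of class `genome_partition`: the validated arm table,
#'   sorted by (chromosome order, start), with a `chrom_order` attribute.
#' @export
#' @examples
#' gp <- toy_genome()
#' gp$arms
genome_partition <- function(arms, chrom_order = NULL) {
  req <- c("arm", "chrom", "start", "end")
  if (!is.data.frame(arms) || !all(req %in% names(arms))) {
    stop_format("arms must be a data frame with columns %s",
                paste(req, collapse = ", "))
  }
  arms <- arms[req]
  arms$chrom <- as.character(arms$chrom)
  arms$arm <- as.character(arms$arm)
  if (anyDuplicated(arms$arm)) stop_format("duplicate arm ids")
  if (any(arms$end <= arms$start)) stop_format("every arm must have end > start")
  chrom_order <- chrom_order %||% unique(arms$chrom)
  if (!all(arms$chrom %in% chrom_order)) stop_format("chrom_order does not cover all chromosomes")
  tab <- table(arms$chrom)
  if (any(tab > 2)) stop_format("a chromosome may contribute at most two arms")
  arms <- arms[order(match(arms$chrom, chrom_order), arms$start), , drop = FALSE]
  # non-overlap within chromosome
  for (ch in unique(arms$chrom)) {
    a <- arms[arms$chrom == ch, ]
    if (nrow(a) == 2 && a$start[2] <= a$end[1]) {
      stop_format("arms overlap on chromosome %s", ch)
    }
  }
  rownames(arms) <- NULL
  structure(list(arms = arms, chrom_order = chrom_order),
            class = "genome_partition")
}

#' @export
print.genome_partition <- function(x, ...) {
  cat(sprintf("<genome_partition> %d arms on %d chromosomes\n",
              nrow(x$arms), length(x$chrom_order)))
  print(x$arms, ...)
  invisible(x)
}

#' Built-in toy genome for testing and simulation
#'
#' Four chromosomes split into eight arms. Small enough that every
#' segmentation and clonality operation runs in milliseconds, while
#' retaining the arm structure (p/q per chromosome) the statistics assume.
#'
#' @param arm_length_bp length of each arm in bp.
#' @return A [genome_partition()] with arms 1p,1q,...,4q.
#' @export
toy_genome <- function(arm_length_bp = 5e6) {
  chroms <- as.character(1:4)
  arms <- do.call(rbind, lapply(chroms, function(ch) {
    data.frame(
      arm = paste0(ch, c("p", "q")),
      chrom = ch,
      start = c(1, arm_length_bp + 1),
      end = c(arm_length_bp, 2 * arm_length_bp),
      stringsAsFactors = FALSE
    )
  }))
  genome_partition(arms, chrom_order = chroms)
}

#' Build a genome partition from a cytoband table
#'
#' Reads a cytoband-like tab-delimited file (columns `chrom`, `start`,
#' `end`, `band`; `start` 0-based as in UCSC cytoband files) and collapses
#' bands into p/q arms. Chromosomes whose bands carry no p/q prefix are
#' treated as single-arm ("q").
#'
#' @param path path to the cytoband file.
#' @return A [genome_partition()].
#' @export
read_cytoband_arms <- function(path) {
  df <- read_tsv_strict(path, c("chrom", "start", "end", "band"), "cytoband")
  df$chrom <- sub("^chr", "", as.character(df$chrom))
  df$armtag <- ifelse(grepl("^p", df$band), "p",
                      ifelse(grepl("^q", df$band), "q", "q"))
  agg_start <- stats::aggregate(start ~ chrom + armtag, df, min)
  agg_end <- stats::aggregate(end ~ chrom + armtag, df, max)
  arms <- merge(agg_start, agg_end, by = c("chrom", "armtag"))
  arms$arm <- paste0(arms$chrom, arms$armtag)
  arms$start <- arms$start + 1L  # 0-based cytoband starts -> 1-based inclusive
  genome_partition(arms[c("arm", "chrom", "start", "end")],
                   chrom_order = unique(df$chrom))
}

# Map (chrom, pos) to arm id; NA when the position falls outside all arms.
assign_arm <- function(chrom, pos, genome) {
  stopifnot(inherits(genome, "genome_partition"))
  arms <- genome$arms
  out <- rep(NA_character_, length(pos))
  for (i in seq_len(nrow(arms))) {
    hit <- chrom == arms$chrom[i] & pos >= arms$start[i] & pos <= arms$end[i]
    out[hit] <- arms$arm[i]
  }
  out
}

# Sort order of (chrom, pos) under the partition's chromosome order.
genome_order <- function(chrom, pos, genome) {
  order(match(chrom, genome$chrom_order), pos)
}
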