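## Capture-performance QC: per-base depth summaries and on-target rate.

#' Summarize per-base depth over capture targets
#'
#' Computes the median per-base depth and the fractions of bases covered by
#' more than 10 and more than 30 reads (strict inequalities: a base at depth
#' exactly 10 does not count as ">10").
#'
#' @param depth Numeric vector of per-base depths, or a data frame with a
#'   `depth` column (e.g. from [read_depth_tsv()] or [simulate_depth()]).
#' @return A `coverage_stats` list: `median_depth`, `frac_gt10`,
#'   `frac_gt30`, `n_bases`.
#' @examples
#' coverage_stats(c(5, 10, 11, 31, 31))
#' @export
coverage_stats <- function(depth) {
  if (is.data.frame(depth)) depth <- depth$depth
  depth <- as.numeric(depth)
  if (length(depth) == 0L)
    stop("no target bases: depth vector is empty", call. = FALSE)
  if (any(is.na(depth)) || any(depth < 0))
    stop("depths must be non-negative and non-missing", call. = FALSE)
  out <- list(median_depth = stats::median(depth),
              frac_gt10 = mean(depth > 10),
              frac_gt30 = mean(depth > 30),
              n_bases = length(depth))
  class(out) <- "coverage_stats"
  out
}

#' @export
print.coverage_stats <- function(x, ...) {
  cat(sprintf("Coverage over %d target bases\n", x$n_bases))
  cat(sprintf("  median depth : %.0fx\n", x$median_depth))
  cat(sprintf("  bases > 10x  : %.1f%%\n", 100 * x$frac_gt10))
  cat(sprintf("  bases > 30x  : %.1f%%\n", 100 * x$frac_gt30))
  invisible(x)
}

#' On-target capture efficiency
#'
#' Fraction of reads overlapping any target base by at least one base.
#' The target set here is the bait-covered (capture) region, matching the
#' practice of aligning reads against the BED of capture targets and
#' discarding off-target reads.
#'
#' @param reads `GRanges` of read placements.
#' @param targets `GRanges` of capture targets.
#' @return Proportion in \[0, 1\]; 0 when there are no targets.
#' @export
on_target_rate <- function(reads, targets) {
  validate_intervals(reads, "reads")
  if (length(reads) == 0L) return(0)
  if (is.null(targets) || length(targets) == 0L) return(0)
  validate_intervals(targets, "targets")
  mean(GenomicRanges::countOverlaps(reads, targets, minoverlap = 1L) > 0L)
}

#' Read a per-base depth table
#'
#' Expects a TSV with columns `chrom`, `pos` (1-based) and `depth`.
#'
#' @param path Path to the TSV.
#' @return Data frame with those columns.
#' @export
read_depth_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "depth")
  if (!all(need %in% names(df)))
    stop("depth table must have columns chrom, pos, depth", call. = FALSE)
  df
}

#' Write coverage statistics to JSON
#'
#' @param stats A `coverage_stats` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_stats <- function(stats, path) {
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
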