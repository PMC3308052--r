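## Capture design: exon expansion, centered 3x bait tiling with a per-bait
## repeat-overlap budget, and design summary statistics.

#' Expand exons into capture targets
#'
#' Grows each exon by `flank` bases on both sides (clipped at the chromosome
#' origin), then merges overlapping or book-ended intervals per chromosome.
#' This reproduces the usual panel-design step of capturing each exon plus
#' its flanking intronic bases (40 bp by default) so that splice junctions
#' fall inside the captured sequence.
#'
#' @param exons `GRanges` of exons (coding and UTR).
#' @param flank Non-negative integer, bases added on each side.
#' @return Sorted, disjoint `GRanges` of capture targets.
#' @examples
#' expand_targets(interval0("chr1", 100, 200), flank = 40)
#' @export
expand_targets <- function(exons, flank = 40L) {
  validate_intervals(exons, "exons")
  stopifnot(length(flank) == 1L, flank >= 0)
  if (length(exons) == 0L) return(GenomicRanges::GRanges())
  grown <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(exons),
    IRanges::IRanges(pmax(GenomicRanges::start(exons) - as.integer(flank), 1L),
                     GenomicRanges::end(exons) + as.integer(flank)))
  GenomicRanges::sort(GenomicRanges::reduce(grown))
}

## Candidate bait starts (0-based) for one target under centered tiling:
## a bait grid anchored so one candidate is centered on the target midpoint,
## step = bait_length / tiling_factor, keeping every grid bait that overlaps
## the target by >= 1 bp. Before repeat rejection this covers every target
## base by exactly `tiling_factor` baits.
candidate_starts0 <- function(t0, t1, bait_length, step) {
  m <- (t0 + t1) %/% 2L
  c0 <- m - bait_length %/% 2L
  ## overlap requires start > t0 - bait_length and start < t1
  kmin <- ceiling((t0 - bait_length + 1L - c0) / step)
  kmax <- floor((t1 - 1L - c0) / step)
  if (kmax < kmin) return(integer(0))
  starts <- c0 + seq.int(kmin, kmax) * step
  starts[starts >= 0L]
}

#' Tile a capture target with fixed-length baits
#'
#' Lays candidate baits under a centered k-fold tiling design: baits are
#' placed on a grid of step `bait_length / tiling_factor` anchored so one
#' candidate is centered on the target midpoint, and every grid bait
#' overlapping the target is a candidate. Interior target bases are thus
#' covered by exactly `tiling_factor` candidates. A candidate is rejected
#' when its total overlap with repeat bases exceeds `max_repeat_overlap`
#' (a per-bait budget summed over all repeat elements it touches).
#'
#' Targets shorter than a bait still receive `tiling_factor` overhanging
#' candidates, so small exons closely flanked by interspersed repeats can
#' be captured.
#'
#' @param targets `GRanges` of capture targets (one or more).
#' @param bait_length Bait length in bp (120 for typical cRNA baits).
#' @param tiling_factor Fold-coverage of the tiling design.
#' @param repeats `GRanges` of repeat-masked intervals, or `NULL`.
#' @param max_repeat_overlap Maximum tolerated repeat overlap per bait, bp.
#' @return `GRanges` of accepted baits, sorted, with a `target_id` metadata
#'   column indexing the target each bait was laid for.
#' @examples
#' tile_baits(interval0("chr1", 1000, 1120))
#' @export
tile_baits <- function(targets, bait_length = 120L, tiling_factor = 3L,
                       repeats = NULL, max_repeat_overlap = 20L) {
  validate_intervals(targets, "targets")
  if (length(targets) == 0L) return(GenomicRanges::GRanges())
  stopifnot(bait_length >= 1, tiling_factor >= 1)
  if (bait_length %% tiling_factor != 0)
    warning("bait_length not divisible by tiling_factor; ",
            "using step = floor(bait_length / tiling_factor)")
  step <- bait_length %/% tiling_factor
  if (is.null(repeats)) repeats <- GenomicRanges::GRanges()
  validate_intervals(repeats, "repeats")
  repeats <- GenomicRanges::reduce(GenomicRanges::sort(repeats))

  chrom <- as.character(GenomicRanges::seqnames(targets))
  t0 <- GenomicRanges::start(targets) - 1L   # 0-based
  t1 <- GenomicRanges::end(targets)
  per_target <- lapply(seq_along(targets), function(i) {
    starts <- candidate_starts0(t0[i], t1[i], as.integer(bait_length),
                                as.integer(step))
    if (!length(starts)) return(GenomicRanges::GRanges())
    cand <- GenomicRanges::GRanges(
      chrom[i], IRanges::IRanges(starts + 1L, starts + as.integer(bait_length)),
      target_id = i)
    ov <- repeat_overlap(cand, repeats)
    cand[ov <= max_repeat_overlap]
  })
  baits <- suppressWarnings(do.call(c, per_target))
  GenomicRanges::sort(baits)
}

## Total repeat-base overlap per query interval.
repeat_overlap <- function(x, repeats) {
  ov <- rep(0L, length(x))
  if (length(repeats) == 0L || length(x) == 0L) return(ov)
  hits <- GenomicRanges::findOverlaps(x, repeats)
  if (length(hits) == 0L) return(ov)
  w <- BiocGenerics::width(IRanges::pintersect(
    x[S4Vectors::queryHits(hits)], repeats[S4Vectors::subjectHits(hits)]))
  agg <- tapply(w, S4Vectors::queryHits(hits), sum)
  ov[as.integer(names(agg))] <- as.integer(agg)
  ov
}

#' Summarize a capture design
#'
#' Computes the capture size (bases of target covered by at least one
#' accepted bait), the number of accepted baits, the number of target
#' regions with at least one bait, and the failed fraction both by base
#' (target bases with zero accepted baits over total target bases) and by
#' region (targets with no accepted bait).
#'
#' @param targets `GRanges` of capture targets.
#' @param baits `GRanges` of accepted baits, as returned by [tile_baits()].
#' @return A `design_report` list with elements `capture_size_bp`,
#'   `n_baits`, `n_regions`, `failed_fraction` (by base) and
#'   `failed_fraction_regions`.
#' @export
summarize_design <- function(targets, baits) {
  validate_intervals(targets, "targets")
  total_bp <- sum(BiocGenerics::width(targets))
  if (length(baits)) {
    covered <- GenomicRanges::intersect(GenomicRanges::reduce(baits),
                                        GenomicRanges::reduce(targets))
    covered_bp <- sum(BiocGenerics::width(covered))
    hit <- GenomicRanges::countOverlaps(targets, baits) > 0L
  } else {
    covered_bp <- 0L
    hit <- rep(FALSE, length(targets))
  }
  rep_ <- list(
    capture_size_bp = as.integer(covered_bp),
    n_baits = length(baits),
    n_regions = sum(hit),
    failed_fraction = if (total_bp > 0) 1 - covered_bp / total_bp else 0,
    failed_fraction_regions =
      if (length(targets)) 1 - mean(hit) else 0)
  class(rep_) <- "design_report"
  rep_
}

#' @export
print.design_report <- function(x, ...) {
  cat("Capture design report\n")
  cat(sprintf("  capture size        : %d bp\n", x$capture_size_bp))
  cat(sprintf("  baits               : %d\n", x$n_baits))
  cat(sprintf("  regions with baits  : %d\n", x$n_regions))
  cat(sprintf("  failed fraction     : %.3f (by base), %.3f (by region)\n",
              x$failed_fraction, x$failed_fraction_regions))
  invisible(x)
}

#' Design a capture panel in one step
#'
#' Expands exons into targets, tiles them with baits, and summarizes the
#' design.
#'
#' @inheritParams expand_targets
#' @inheritParams tile_baits
#' @return List with `targets`, `baits` and `report`.
#' @export
design_panel <- function(exons, repeats = NULL, flank = 40L,
                         bait_length = 120L, tiling_factor = 3L,
                         max_repeat_overlap = 20L) {
  targets <- expand_targets(exons, flank)
  baits <- tile_baits(targets, bait_length, tiling_factor, repeats,
                      max_repeat_overlap)
  list(targets = targets, baits = baits,
       report = summarize_design(targets, baits))
}

#' Write a design report to TSV and JSON
#'
#' @param report A `design_report`.
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return Paths written, invisibly.
#' @export
write_design_report <- function(report, prefix) {
  df <- as.data.frame(unclass(report))
  tsv <- paste0(prefix, ".tsv"); json <- paste0(prefix, ".json")
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(report), json, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, json))
}
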