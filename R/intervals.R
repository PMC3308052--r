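#' panelseeker: targeted gene-panel design and rare-variant analysis
#'
#' Capture-panel bait tiling, coverage QC, zygosity calling, cryptic-indel
#' detection, a rare-variant filter cascade, pedigree co-segregation checks
#' and founder-allele cohort statistics, plus a synthetic-data generator that
#' emulates a multi-gene deafness panel end to end.
#'
#' @keywords internal
#' @import GenomicRanges IRanges S4Vectors BiocGenerics methods
#' @importFrom Biostrings DNAString DNAStringSet subseq replaceAt GENETIC_CODE
#'   writeXStringSet readDNAStringSet
#' @importFrom stats rbinom rnorm rpois runif fisher.test chisq.test
#'   binom.test setNames
#' @importFrom utils read.delim write.table
"_PACKAGE"

## Interval utilities shared across modules. Genomic intervals are held as
## GRanges (1-based, closed); BED I/O through rtracklayer keeps the usual
## 0-based half-open convention on disk.

#' Validate a set of genomic intervals
#'
#' Checks that `x` is a `GRanges` with strictly positive widths. Used at the
#' entry points of the design functions so malformed BED rows fail loudly.
#'
#' @param x A `GRanges`.
#' @param what Label used in error messages.
#' @return `x`, invisibly.
#' @keywords internal
validate_intervals <- function(x, what = "intervals") {
  if (!methods::is(x, "GRanges"))
    stop(what, " must be a GRanges object", call. = FALSE)
  if (length(x) && any(BiocGenerics::width(x) < 1L))
    stop(what, " contains empty or inverted intervals (end <= start)",
         call. = FALSE)
  invisible(x)
}

#' Build a GRanges from 0-based half-open coordinates
#'
#' Convenience constructor mirroring BED arithmetic: `interval0("chr1", 100,
#' 200)` is the 100 bases `[100, 200)` in 0-based coordinates, i.e. 101..200
#' in the 1-based closed representation used in memory.
#'
#' @param chrom Chromosome names.
#' @param start0 0-based inclusive starts.
#' @param end0 0-based exclusive ends.
#' @param ... Passed to [GenomicRanges::GRanges()] metadata columns.
#' @return A `GRanges`.
#' @examples
#' interval0("chr1", 100, 200)
#' @export
interval0 <- function(chrom, start0, end0, ...) {
  if (any(end0 <= start0))
    stop("end must be greater than start", call. = FALSE)
  if (any(start0 < 0))
    stop("negative start coordinate", call. = FALSE)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0), ...)
}

#' Read intervals from a BED file
#'
#' Thin wrapper over [rtracklayer::import()]; only the first three columns
#' are required.
#'
#' @param path Path to a BED file.
#' @return A `GRanges`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  validate_intervals(gr, basename(path))
  gr
}

#' Write intervals to a BED file
#'
#' @param x A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  rtracklayer::export(x, path, format = "BED")
  invisible(path)
}
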