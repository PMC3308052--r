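## Variant observations: zygosity from allele fractions, cryptic-indel
## detection (adjacent weakly supported substitutions hiding an indel), and
## resolution of indel candidates against a truth source.
##
## Variant tables are plain data frames with columns
##   chrom, pos (1-based), ref, alt, ref_reads, var_reads, proband
## Deletions/insertions use the simple non-anchored representation: a 2-bp
## deletion has ref = "CG", alt = "" (or "-"), pos = first deleted base.

#' Read / write a variant observation table
#'
#' @param path Path to a TSV with header columns `chrom`, `pos`, `ref`,
#'   `alt`, `ref_reads`, `var_reads` and optionally `proband`.
#' @return Data frame.
#' @export
read_variants <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(alt = "character", ref = "character"))
  need <- c("chrom", "pos", "ref", "alt", "ref_reads", "var_reads")
  if (!all(need %in% names(df)))
    stop("variant table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df$alt[is.na(df$alt)] <- ""
  df
}

#' @rdname read_variants
#' @param variants Variant data frame.
#' @export
write_variants <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Call zygosity from reference and variant read counts
#'
#' The variant allele fraction (VAF) is `var_reads / (ref_reads +
#' var_reads)`. A site is called homozygous when VAF >= `hom_min`,
#' heterozygous when `het_min` <= VAF < `hom_min`, weakly supported when
#' 0 < VAF < `het_min`, and reference when no variant reads are present.
#' Defaults reflect the empirical pattern that true heterozygotes show
#' roughly half the reads supporting the variant and true homozygotes close
#' to all of them, while sites near 25% support are anomalous and may hide
#' an indel (see [detect_cryptic_indels()]). `depth_ok` marks whether total
#' depth meets the detection cutoff (10 by default; 30 is the stricter
#' option).
#'
#' @param ref_reads,var_reads Non-negative integer vectors.
#' @param min_depth Depth cutoff for `depth_ok`.
#' @param het_min Minimum VAF to call a heterozygote.
#' @param hom_min Minimum VAF to call a homozygote.
#' @return Data frame with columns `state` (factor: reference, weak_support,
#'   heterozygous, homozygous), `vaf`, `depth_ok`.
#' @examples
#' call_zygosity(643, 666)   # ~51% of reads: heterozygous
#' call_zygosity(0, 425)     # 100% of reads: homozygous
#' @export
call_zygosity <- function(ref_reads, var_reads, min_depth = 10L,
                          het_min = 0.30, hom_min = 0.80) {
  stopifnot(length(ref_reads) == length(var_reads))
  if (any(ref_reads < 0) || any(var_reads < 0))
    stop("read counts must be non-negative", call. = FALSE)
  total <- ref_reads + var_reads
  if (any(total == 0))
    stop("site with zero total reads", call. = FALSE)
  vaf <- var_reads / total
  state <- ifelse(var_reads == 0, "reference",
           ifelse(vaf >= hom_min, "homozygous",
           ifelse(vaf >= het_min, "heterozygous", "weak_support")))
  data.frame(
    state = factor(state, levels = c("reference", "weak_support",
                                     "heterozygous", "homozygous")),
    vaf = vaf,
    depth_ok = total >= min_depth)
}

#' Annotate a variant table with zygosity calls
#'
#' @param variants Variant data frame (see [read_variants()]).
#' @inheritParams call_zygosity
#' @return The table with `state`, `vaf` and `depth_ok` columns appended.
#' @export
call_variants <- function(variants, min_depth = 10L, het_min = 0.30,
                          hom_min = 0.80) {
  cbind(variants,
        call_zygosity(variants$ref_reads, variants$var_reads,
                      min_depth, het_min, hom_min))
}

is_snv <- function(ref, alt) {
  alt <- ifelse(alt == "-", "", alt)
  nchar(ref) == 1L & nchar(alt) == 1L
}

#' Detect cryptic indels presenting as adjacent weak substitutions
#'
#' Two (or more) apparently adjacent or nearly adjacent single-base
#' substitutions, each supported by a similar, sub-heterozygous fraction of
#' reads (e.g. ~25% each), may reflect a single underlying insertion or
#' deletion misread by the aligner. This groups every maximal run of >= 2
#' weakly supported SNVs on one chromosome with successive position gaps
#' <= `max_gap` and pairwise variant-read ratios <= `ratio_tol` into one
#' indel candidate, removing the member sites from the SNV stream.
#'
#' @param variants Variant data frame for one proband, sorted by position
#'   (sorted internally if not).
#' @param max_gap Maximum distance (bp) between successive member sites.
#' @param ratio_tol Maximum ratio between the largest and smallest
#'   variant-read counts within a candidate.
#' @inheritParams call_zygosity
#' @return List with `candidates` (list of `indel_candidate` objects, each
#'   with `chrom`, `span` = c(start, end) 1-based inclusive, `member_sites`,
#'   `status` = "candidate", `resolved_allele` = NA) and `variants` (the
#'   input table with member sites removed).
#' @export
detect_cryptic_indels <- function(variants, max_gap = 3L, ratio_tol = 1.5,
                                  het_min = 0.30, hom_min = 0.80,
                                  min_depth = 10L) {
  if (nrow(variants) == 0L)
    return(list(candidates = list(), variants = variants))
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  z <- call_zygosity(variants$ref_reads, variants$var_reads,
                     min_depth, het_min, hom_min)
  weak <- which(z$state == "weak_support" &
                is_snv(variants$ref, variants$alt))
  candidates <- list()
  consumed <- integer(0)
  run <- integer(0)
  close_run <- function(run) {
    if (length(run) >= 2L) {
      sites <- variants[run, , drop = FALSE]
      cand <- structure(list(
        chrom = sites$chrom[1L],
        span = c(min(sites$pos), max(sites$pos)),
        member_sites = sites,
        status = "candidate",
        resolved_allele = NA_character_), class = "indel_candidate")
      candidates[[length(candidates) + 1L]] <<- cand
      consumed <<- c(consumed, run)
    }
  }
  for (i in weak) {
    if (length(run) == 0L) { run <- i; next }
    prev <- run[length(run)]
    same_chrom <- variants$chrom[i] == variants$chrom[prev]
    gap_ok <- same_chrom &&
      (variants$pos[i] - variants$pos[prev]) <= max_gap
    vr <- variants$var_reads[c(run, i)]
    ratio_ok <- max(vr) / max(min(vr), 1L) <= ratio_tol
    if (gap_ok && ratio_ok) {
      run <- c(run, i)
    } else {
      close_run(run)
      run <- i
    }
  }
  close_run(run)
  keep <- setdiff(seq_len(nrow(variants)), consumed)
  list(candidates = candidates,
       variants = variants[keep, , drop = FALSE])
}

#' @export
print.indel_candidate <- function(x, ...) {
  cat(sprintf("Indel candidate %s:%d-%d (%d member sites, %s%s)\n",
              x$chrom, x$span[1], x$span[2], nrow(x$member_sites), x$status,
              if (!is.na(x$resolved_allele))
                paste0(": ", x$resolved_allele) else ""))
  invisible(x)
}

#' Resolve an indel candidate against a reference window and truth source
#'
#' In synthetic runs a truth table of planted indels is available; a
#' candidate whose span overlaps a planted indel is marked resolved with the
#' planted allele (e.g. a 2-bp deletion). Without a truth source the
#' candidate is returned unchanged, flagged for external (Sanger-style)
#' confirmation. When a reference sequence set is supplied it must cover
#' the candidate span.
#'
#' @param candidate An `indel_candidate` from [detect_cryptic_indels()].
#' @param reference Optional named `DNAStringSet` (or named character) of
#'   chromosome sequences; must include the candidate's chromosome and cover
#'   its span.
#' @param truth Optional data frame of planted indels with columns `chrom`,
#'   `pos`, `ref`, `alt`.
#' @return The candidate, with `status = "resolved"` and `resolved_allele`
#'   set when a matching planted indel is found.
#' @export
resolve_indel <- function(candidate, reference = NULL, truth = NULL) {
  stopifnot(inherits(candidate, "indel_candidate"))
  if (candidate$status != "candidate") return(candidate)
  if (!is.null(reference)) {
    seqs <- if (is.character(reference)) Biostrings::DNAStringSet(reference)
            else reference
    if (!candidate$chrom %in% names(seqs))
      stop("reference does not include chromosome ", candidate$chrom,
           call. = FALSE)
    if (candidate$span[2] > length(seqs[[candidate$chrom]]))
      stop("reference window does not cover the candidate span",
           call. = FALSE)
  }
  if (is.null(truth)) return(candidate)
  truth$alt[is.na(truth$alt)] <- ""
  tr <- truth[!is_snv(truth$ref, truth$alt) &
              truth$chrom == candidate$chrom, , drop = FALSE]
  if (nrow(tr) == 0L) return(candidate)
  t_start <- tr$pos
  t_end <- tr$pos + pmax(nchar(tr$ref), 1L) - 1L
  hit <- which(t_start <= candidate$span[2] + 1L &
               t_end >= candidate$span[1] - 1L)
  if (length(hit) == 0L) return(candidate)
  hit <- hit[1L]
  alt <- tr$alt[hit]; ref <- tr$ref[hit]
  candidate$status <- "resolved"
  candidate$resolved_allele <-
    if (nchar(alt) < nchar(ref)) paste0("del", substr(ref, nchar(alt) + 1L,
                                                      nchar(ref)))
    else if (nchar(alt) > nchar(ref)) paste0("ins", substr(alt,
                                                           nchar(ref) + 1L,
                                                           nchar(alt)))
    else paste0(ref, ">", alt)
  candidate
}
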