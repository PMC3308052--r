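## Rare-variant filter cascade: dbSNP (clinical-flag rescue), PhyloP
## conservation, cohort recurrence, 1000 Genomes / hearing-genomes
## membership, followed by codon-level effect classification and
## per-proband summary counts.

variant_key <- function(chrom, pos, ref, alt) {
  alt <- ifelse(is.na(alt) | alt == "-", "", alt)
  paste(chrom, pos, ref, alt, sep = ":")
}

#' dbSNP filter with clinical-association rescue
#'
#' Known database variants are removed unless flagged as clinically
#' associated: a database that mixes disease-associated and benign alleles
#' cannot be used as a plain exclusion list.
#'
#' @param variants Variant data frame.
#' @param dbsnp Stub data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `id`, `clinical` (logical).
#' @return Logical vector: `TRUE` = variant passes (is retained).
#' @export
filter_dbsnp <- function(variants, dbsnp) {
  if (is.null(dbsnp) || nrow(dbsnp) == 0L)
    return(rep(TRUE, nrow(variants)))
  key <- variant_key(variants$chrom, variants$pos, variants$ref,
                     variants$alt)
  dkey <- variant_key(dbsnp$chrom, dbsnp$pos, dbsnp$ref, dbsnp$alt)
  idx <- match(key, dkey)
  in_db <- !is.na(idx)
  clinical <- rep(FALSE, nrow(variants))
  clinical[in_db] <- dbsnp$clinical[idx[in_db]]
  !(in_db & !clinical)
}

#' Conservation filter (PhyloP)
#'
#' Substitutions at sites with placental-mammal PhyloP below `threshold`
#' (0.9 by default) are considered non-conserved and removed. Indels are
#' exempt: the score applies to the consensus nucleotide of a substitution
#' site. Missing scores pass by default (with a message) or fail when
#' `missing_action = "fail"`.
#'
#' @param variants Variant data frame.
#' @param phylop Stub data frame with columns `chrom`, `pos`, `score`.
#' @param threshold Minimum score for a substitution to be retained.
#' @param missing_action "pass" or "fail" for SNVs with no score.
#' @return Logical pass vector.
#' @export
filter_conservation <- function(variants, phylop, threshold = 0.9,
                                missing_action = c("pass", "fail")) {
  missing_action <- match.arg(missing_action)
  snv <- is_snv(variants$ref, variants$alt)
  pass <- rep(TRUE, nrow(variants))
  if (!any(snv)) return(pass)
  pkey <- paste(phylop$chrom, phylop$pos)
  idx <- match(paste(variants$chrom, variants$pos)[snv], pkey)
  score <- phylop$score[idx]
  miss <- is.na(score)
  if (any(miss)) {
    message(sum(miss), " substitution(s) without a conservation score (",
            missing_action, ")")
    score[miss] <- if (missing_action == "pass") Inf else -Inf
  }
  pass[snv] <- score >= threshold
  pass
}

#' Count cohort recurrence of each variant
#'
#' Number of distinct probands in the cohort carrying each variant (any
#' zygosity).
#'
#' @param variants Variant data frame (rows to annotate).
#' @param cohort Variant data frame across all cohort probands (must have a
#'   `proband` column); defaults to `variants`.
#' @return Integer vector of proband counts.
#' @export
compute_recurrence <- function(variants, cohort = variants) {
  if (is.null(cohort$proband))
    stop("cohort table needs a proband column", call. = FALSE)
  ckey <- variant_key(cohort$chrom, cohort$pos, cohort$ref, cohort$alt)
  counts <- tapply(cohort$proband, ckey,
                   function(p) length(unique(p)))
  key <- variant_key(variants$chrom, variants$pos, variants$ref,
                     variants$alt)
  n <- counts[key]
  n[is.na(n)] <- 0L
  as.integer(n)
}

#' Cohort-recurrence filter
#'
#' Novel variants carried by many probands of the same cohort are almost
#' certainly population-specific polymorphisms rather than private
#' mutations; variants present in more than `max_probands` probands are
#' removed.
#'
#' @param variants Variant data frame.
#' @param recurrence Integer vector from [compute_recurrence()].
#' @param max_probands Maximum number of carriers to retain a variant.
#' @return Logical pass vector.
#' @export
filter_recurrence <- function(variants, recurrence, max_probands = 3L) {
  stopifnot(length(recurrence) == nrow(variants))
  recurrence <= max_probands
}

#' Population-membership filter (1000 Genomes and hearing genomes)
#'
#' Removes variants already reported in the 1000 Genomes project or in
#' other published genomes of hearing individuals. Applied after the
#' recurrence filter (only low-recurrence variants are checked).
#'
#' @param variants Variant data frame.
#' @param kg Membership stub with columns `chrom`, `pos`, `ref`, `alt`.
#' @param hearing Optional second membership stub, same columns.
#' @return Logical pass vector.
#' @export
filter_1000g <- function(variants, kg, hearing = NULL) {
  key <- variant_key(variants$chrom, variants$pos, variants$ref,
                     variants$alt)
  in_any <- rep(FALSE, nrow(variants))
  for (stub in list(kg, hearing)) {
    if (is.null(stub) || nrow(stub) == 0L) next
    skey <- variant_key(stub$chrom, stub$pos, stub$ref, stub$alt)
    in_any <- in_any | key %in% skey
  }
  !in_any
}

#' Construct a toy gene model
#'
#' A minimal plus-strand transcript model: exon boundaries, a CDS interval
#' with the reading frame starting at `cds_start`, and the gene name. Used
#' for codon-level effect classification on synthetic panels.
#'
#' @param gene Gene name.
#' @param chrom Chromosome name.
#' @param exons Data frame with 1-based inclusive `start`, `end` columns,
#'   sorted, non-overlapping.
#' @param cds_start,cds_end 1-based genomic CDS bounds (inclusive); the
#'   first CDS base is the first base of codon 1.
#' @return A `gene_model` list.
#' @export
gene_model <- function(gene, chrom, exons, cds_start, cds_end) {
  stopifnot(all(exons$end >= exons$start), cds_end >= cds_start)
  if (is.unsorted(exons$start))
    exons <- exons[order(exons$start), , drop = FALSE]
  structure(list(gene = gene, chrom = chrom, strand = "+",
                 exons = exons, cds_start = cds_start, cds_end = cds_end),
            class = "gene_model")
}

## Ordered genomic positions of the CDS (spliced).
cds_positions <- function(model) {
  pos <- unlist(lapply(seq_len(nrow(model$exons)), function(i)
    seq.int(model$exons$start[i], model$exons$end[i])))
  pos[pos >= model$cds_start & pos <= model$cds_end]
}

in_exon <- function(model, pos)
  any(pos >= model$exons$start & pos <= model$exons$end)

near_splice <- function(model, pos, splice_window) {
  any((model$exons$start - pos) >= 1L &
      (model$exons$start - pos) <= splice_window) ||
  any((pos - model$exons$end) >= 1L &
      (pos - model$exons$end) <= splice_window)
}

classify_one <- function(chrom, pos, ref, alt, models, reference,
                         splice_window) {
  model <- NULL
  for (m in models) {
    span <- range(c(m$exons$start, m$exons$end))
    if (m$chrom == chrom && pos >= span[1] - 10000L && pos <= span[2] +
        10000L) { model <- m; break }
  }
  if (is.null(model)) return(c("intronic", NA_character_))
  alt <- if (is.na(alt) || alt == "-") "" else alt
  site <- seq.int(pos, pos + max(nchar(ref), 1L) - 1L)
  if (nchar(ref) != nchar(alt)) {               # indel
    cpos <- cds_positions(model)
    eff <- if (any(site %in% cpos)) {
      if (abs(nchar(alt) - nchar(ref)) %% 3L == 0L) "inframe_indel"
      else "frameshift"
    } else if (any(vapply(site, function(p)
               near_splice(model, p, splice_window), NA))) {
      "splice_junction"
    } else if (any(vapply(site, function(p) in_exon(model, p), NA))) {
      "utr"
    } else "intronic"
    return(c(eff, model$gene))
  }
  if (!in_exon(model, pos)) {
    eff <- if (near_splice(model, pos, splice_window)) "splice_junction"
           else "intronic"
    return(c(eff, model$gene))
  }
  if (pos < model$cds_start || pos > model$cds_end)
    return(c("utr", model$gene))
  cpos <- cds_positions(model)
  k <- match(pos, cpos)
  if (is.na(k)) return(c("utr", model$gene))   # CDS bounds inside intron
  codon_idx <- (k - 1L) %/% 3L
  cod_pos <- cpos[(codon_idx * 3L + 1L):(codon_idx * 3L + 3L)]
  if (any(is.na(cod_pos))) return(c("utr", model$gene))  # trailing partial
  seq <- reference[[chrom]]
  ref_codon <- vapply(cod_pos, function(p)
    as.character(Biostrings::subseq(seq, p, p)), "")
  if (ref_codon[k - codon_idx * 3L] != ref)
    warning("reference allele mismatch at ", chrom, ":", pos)
  alt_codon <- ref_codon
  alt_codon[k - codon_idx * 3L] <- alt
  aa_ref <- Biostrings::GENETIC_CODE[[paste(ref_codon, collapse = "")]]
  aa_alt <- Biostrings::GENETIC_CODE[[paste(alt_codon, collapse = "")]]
  eff <- if (aa_ref == aa_alt) "synonymous"
         else if (aa_alt == "*") "nonsense"
         else "missense"
  c(eff, model$gene)
}

#' Classify the predicted effect of variants on a gene model
#'
#' Substitutions inside the coding sequence are translated codon-by-codon
#' (synonymous / missense / nonsense); indels touching coding bases are
#' frameshift or in-frame by length modulo 3; intronic sites within
#' `splice_window` bases of an exon boundary are splice-junction; exonic
#' non-coding sites are UTR; everything else (including sites outside all
#' transcripts) is intronic.
#'
#' @param variants Variant data frame.
#' @param gene_models List of [gene_model()] objects.
#' @param reference Named `DNAStringSet` of chromosome sequences.
#' @param splice_window Intronic bases from an exon boundary treated as
#'   splice site (2 = canonical donor/acceptor; up to the 40-base captured
#'   flank is meaningful).
#' @return Data frame with columns `effect` and `gene`.
#' @export
classify_effect <- function(variants, gene_models, reference,
                            splice_window = 2L) {
  if (inherits(gene_models, "gene_model")) gene_models <- list(gene_models)
  out <- t(vapply(seq_len(nrow(variants)), function(i)
    classify_one(variants$chrom[i], variants$pos[i], variants$ref[i],
                 variants$alt[i], gene_models, reference, splice_window),
    c("", "")))
  data.frame(effect = factor(out[, 1], levels = effect_levels()),
             gene = out[, 2], stringsAsFactors = FALSE)
}

effect_levels <- function()
  c("nonsense", "missense", "synonymous", "splice_junction", "frameshift",
    "inframe_indel", "utr", "intronic")

functional_effects <- function()
  c("nonsense", "missense", "splice_junction", "frameshift")

#' Run the full rare-variant filter cascade for one proband
#'
#' Applies, in order, the dbSNP clinical-flag filter, the PhyloP
#' conservation filter, the cohort-recurrence filter and the 1000
#' Genomes / hearing-genomes membership filter; a variant stops at its
#' first failure, and later filters are not applied to it (their verdict is
#' `NA` in the trail). Survivors are classified by predicted effect and
#' annotated with PolyPhen-2 HumVar and SIFT scores where available; the
#' scores are annotations only, never filters.
#'
#' @param variants Variant table for one proband.
#' @param annotations List of stubs: `dbsnp`, `phylop`, `kg`, optionally
#'   `hearing` and `scores` (columns `chrom`, `pos`, `ref`, `alt`,
#'   `polyphen2_humvar`, `sift`).
#' @param gene_models List of [gene_model()] objects.
#' @param reference Named `DNAStringSet`.
#' @param cohort Variant table across all cohort probands (for recurrence);
#'   defaults to `variants`.
#' @param max_probands Recurrence cutoff (retain if carried by at most this
#'   many probands).
#' @param phylop_min Conservation threshold.
#' @param splice_window See [classify_effect()].
#' @param order Filter order; the default places recurrence before the
#'   membership check, which is only applied to low-recurrence variants.
#' @return Data frame of annotated variants: the input columns plus
#'   `recurrence`, per-filter verdicts `pass_dbsnp`, `pass_conservation`,
#'   `pass_recurrence`, `pass_1000g` (`NA` = not applied), `rare` (all
#'   pass), and for rare variants `effect`, `gene`, `polyphen2_humvar`,
#'   `sift`.
#' @export
run_cascade <- function(variants, annotations, gene_models, reference,
                        cohort = variants, max_probands = 3L,
                        phylop_min = 0.9, splice_window = 2L,
                        order = c("dbsnp", "conservation", "recurrence",
                                  "1000g")) {
  stopifnot(all(order %in% c("dbsnp", "conservation", "recurrence",
                             "1000g")), !anyDuplicated(order))
  n <- nrow(variants)
  out <- variants
  out$recurrence <- compute_recurrence(variants, cohort)
  verdicts <- list(dbsnp = rep(NA, n), conservation = rep(NA, n),
                   recurrence = rep(NA, n), `1000g` = rep(NA, n))
  alive <- rep(TRUE, n)
  for (f in order) {
    if (!any(alive)) break
    pass <- switch(f,
      dbsnp = filter_dbsnp(variants, annotations$dbsnp),
      conservation = filter_conservation(variants, annotations$phylop,
                                         threshold = phylop_min),
      recurrence = filter_recurrence(variants, out$recurrence,
                                     max_probands),
      `1000g` = filter_1000g(variants, annotations$kg,
                             annotations$hearing))
    verdicts[[f]][alive] <- pass[alive]
    alive <- alive & pass
  }
  out$pass_dbsnp <- verdicts$dbsnp
  out$pass_conservation <- verdicts$conservation
  out$pass_recurrence <- verdicts$recurrence
  out$pass_1000g <- verdicts$`1000g`
  out$rare <- alive
  out$effect <- factor(NA_character_, levels = effect_levels())[rep(1L, n)]
  out$gene <- rep(NA_character_, n)
  out$polyphen2_humvar <- rep(NA_real_, n)
  out$sift <- rep(NA_real_, n)
  if (any(alive)) {
    cls <- classify_effect(variants[alive, , drop = FALSE], gene_models,
                           reference, splice_window)
    out$effect[alive] <- cls$effect
    out$gene[alive] <- cls$gene
    sc <- annotations$scores
    if (!is.null(sc) && nrow(sc)) {
      key <- variant_key(out$chrom, out$pos, out$ref, out$alt)
      skey <- variant_key(sc$chrom, sc$pos, sc$ref, sc$alt)
      idx <- match(key, skey)
      hit <- alive & !is.na(idx)
      out$polyphen2_humvar[hit] <- sc$polyphen2_humvar[idx[hit]]
      out$sift[hit] <- sc$sift[idx[hit]]
    }
  }
  out
}

#' Tabulate per-proband rare and potentially functional variant counts
#'
#' Summarizes a cascade output in the layout of a per-proband results
#' table: rare substitutions, private indels, their total, counts of the
#' four potentially functional effect classes (nonsense, missense, splice
#' junction, frameshift) and their total. Synonymous, UTR, intronic and
#' in-frame indel survivors are counted as rare but not as potentially
#' functional.
#'
#' @param annotated Output of [run_cascade()] (one or more probands).
#' @return Data frame, one row per proband.
#' @export
proband_summary <- function(annotated) {
  if (is.null(annotated$proband)) annotated$proband <- "proband"
  rare <- annotated[annotated$rare, , drop = FALSE]
  probands <- unique(annotated$proband)
  rows <- lapply(probands, function(p) {
    r <- rare[rare$proband == p, , drop = FALSE]
    snv <- is_snv(r$ref, r$alt)
    data.frame(
      proband = p,
      n_rare_snv = sum(snv),
      n_private_indel = sum(!snv),
      n_rare_total = nrow(r),
      n_nonsense = sum(r$effect == "nonsense", na.rm = TRUE),
      n_missense = sum(r$effect == "missense", na.rm = TRUE),
      n_splice = sum(r$effect == "splice_junction", na.rm = TRUE),
      n_frameshift = sum(r$effect == "frameshift", na.rm = TRUE),
      stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    rows <- list(data.frame(proband = character(), n_rare_snv = integer(),
                            n_private_indel = integer(),
                            n_rare_total = integer(),
                            n_nonsense = integer(), n_missense = integer(),
                            n_splice = integer(),
                            n_frameshift = integer()))
  out <- do.call(rbind, rows)
  out$n_functional_total <- out$n_nonsense + out$n_missense +
    out$n_splice + out$n_frameshift
  out
}
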