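## Synthetic-data generator: toy multi-gene panels with repeats and coding
## sequence, per-base depth with GC-dropout-like blocks, per-proband variant
## tables (population-common alleles, database alleles, private benigns and
## one planted causal allele with binomial read support), nuclear pedigrees
## segregating the causal allele, and case/control cohorts carrying a
## founder allele at distinct frequencies. Everything is deterministic under
## a fixed seed so the downstream modules are testable without any raw data.

BASES <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Parameter defaults emulate the study conditions of a deafness gene-panel
#' screen: 11 probands, median per-base coverage near 937x (the average for
#' two multiplexed samples per lane), ~5% of target bases in contiguous
#' poorly covered (GC-rich-like) blocks, ~8% of panel bases inside repeat
#' elements, and a founder allele at frequency 0.337 in cases versus 0.028
#' in controls (52 cases, 282 controls). The panel itself is scaled down to
#' `n_genes` toy genes so simulations run in seconds.
#'
#' @param seed Integer seed; fixed seed gives identical output.
#' @param n_genes Number of toy genes (each on its own toy chromosome).
#' @param exons_per_gene Integer range `c(min, max)`.
#' @param exon_length Integer range `c(min, max)` in bp.
#' @param intron_length Integer range `c(min, max)` in bp.
#' @param flank Intronic bases captured on each side of an exon.
#' @param repeat_fraction Fraction of target bases inside repeat intervals.
#' @param median_depth Median per-base depth.
#' @param depth_sigma Log-scale spread of the depth distribution.
#' @param dropout_fraction Fraction of target bases forced below 10 reads,
#'   in contiguous blocks.
#' @param n_probands Number of sequenced probands.
#' @param common_poly_rate Population-common polymorphisms per kb of panel
#'   (shared by four or more probands).
#' @param dbsnp_overlap Probability that a private background variant is
#'   present in the dbSNP stub (without a clinical flag).
#' @param rare_benign_per_proband Expected count of private, conserved,
#'   database-absent benign variants per proband (these survive the filter
#'   cascade and are only removed by co-segregation).
#' @param causal_model "recessive_hom", "recessive_compound_het" or
#'   "dominant_het".
#' @param case_allele_freq,control_allele_freq Founder-allele frequencies.
#' @param second_allele_freq Frequency of the second pathogenic allele
#'   among case chromosomes (compound heterozygotes).
#' @param n_cases,n_controls Cohort sizes.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 8L,
                       exons_per_gene = c(3L, 8L),
                       exon_length = c(90L, 240L),
                       intron_length = c(300L, 1200L),
                       flank = 40L,
                       repeat_fraction = 0.08,
                       median_depth = 937,
                       depth_sigma = 0.35,
                       dropout_fraction = 0.05,
                       n_probands = 11L,
                       common_poly_rate = 0.5,
                       dbsnp_overlap = 0.9,
                       rare_benign_per_proband = 2,
                       causal_model = c("recessive_hom",
                                        "recessive_compound_het",
                                        "dominant_het"),
                       case_allele_freq = 0.337,
                       control_allele_freq = 0.028,
                       second_allele_freq = 0.058,
                       n_cases = 52L,
                       n_controls = 282L) {
  causal_model <- match.arg(causal_model)
  props <- c(repeat_fraction = repeat_fraction,
             dropout_fraction = dropout_fraction,
             dbsnp_overlap = dbsnp_overlap,
             case_allele_freq = case_allele_freq,
             control_allele_freq = control_allele_freq,
             second_allele_freq = second_allele_freq)
  if (any(props < 0 | props > 1))
    stop("proportions must lie in [0, 1]: ",
         paste(names(props)[props < 0 | props > 1], collapse = ", "),
         call. = FALSE)
  for (rng in list(exons_per_gene, exon_length, intron_length))
    if (length(rng) != 2L || rng[2] < rng[1] || rng[1] < 1)
      stop("ranges must be c(min, max) with 1 <= min <= max", call. = FALSE)
  if (exon_length[1] < 70L)
    stop("exon_length minimum below 70 bp cannot hold UTRs plus coding ",
         "sequence in single-exon genes", call. = FALSE)
  if (case_allele_freq + second_allele_freq > 1)
    stop("case_allele_freq + second_allele_freq exceeds 1", call. = FALSE)
  stopifnot(n_genes >= 1, n_probands >= 1, median_depth > 0,
            n_cases >= 1, n_controls >= 1, common_poly_rate >= 0)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 exon_length = as.integer(exon_length),
                 intron_length = as.integer(intron_length),
                 flank = as.integer(flank),
                 repeat_fraction = repeat_fraction,
                 median_depth = median_depth, depth_sigma = depth_sigma,
                 dropout_fraction = dropout_fraction,
                 n_probands = as.integer(n_probands),
                 common_poly_rate = common_poly_rate,
                 dbsnp_overlap = dbsnp_overlap,
                 rare_benign_per_proband = rare_benign_per_proband,
                 causal_model = causal_model,
                 case_allele_freq = case_allele_freq,
                 control_allele_freq = control_allele_freq,
                 second_allele_freq = second_allele_freq,
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls)),
            class = "sim_config")
}

rand_in <- function(rng, n = 1L) sample(seq.int(rng[1], rng[2]), n,
                                        replace = TRUE)

NON_STOP_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                           c("TAA", "TAG", "TGA"))

#' Simulate a capture panel with reference sequence and gene models
#'
#' Builds `n_genes` toy genes, each on its own toy chromosome, with
#' plausible exon/intron structure, 30-bp UTRs on the terminal exons, a
#' coding sequence in frame (ATG start, internal codons free of stops,
#' terminal stop codon), capture targets (exons expanded by `flank`), and
#' repeat intervals covering `repeat_fraction` of target bases.
#'
#' @param cfg A [sim_config()].
#' @param seed Seed; defaults to `cfg$seed`.
#' @return A `sim_panel` list: `exons`, `targets`, `repeats` (`GRanges`),
#'   `reference` (named `DNAStringSet`), `gene_models`, `cfg`.
#' @export
simulate_panel <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  exon_list <- list()
  seqs <- character(cfg$n_genes)
  models <- vector("list", cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    chrom <- sprintf("gene%02d", g)
    n_ex <- rand_in(cfg$exons_per_gene)
    lens <- rand_in(cfg$exon_length, n_ex)
    gaps <- if (n_ex > 1) rand_in(cfg$intron_length, n_ex - 1L) else integer(0)
    starts <- 201L + cumsum(c(0L, lens[-n_ex] + gaps))
    ends <- starts + lens - 1L
    cds_start <- starts[1] + 30L
    cds_end <- ends[n_ex] - 30L
    cds_len <- sum(pmin(ends, cds_end) - pmax(starts, cds_start) + 1L)
    cds_end <- cds_end - cds_len %% 3L       # keep the frame whole
    model <- gene_model(chrom, chrom,
                        data.frame(start = starts, end = ends),
                        cds_start, cds_end)
    chrom_len <- ends[n_ex] + 400L
    seq <- sample(BASES, chrom_len, replace = TRUE)
    cpos <- cds_positions(model)
    codons <- c("ATG",
                sample(NON_STOP_CODONS, length(cpos) / 3L - 2L,
                       replace = TRUE),
                "TAA")
    seq[cpos] <- unlist(strsplit(codons, ""))
    seqs[g] <- paste(seq, collapse = "")
    names(seqs)[g] <- chrom
    exon_list[[g]] <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(starts, ends), gene = chrom)
    models[[g]] <- model
  }
  exons <- suppressWarnings(do.call(c, exon_list))
  targets <- expand_targets(exons, cfg$flank)
  repeats <- place_repeats(targets, cfg$repeat_fraction)
  structure(list(exons = exons, targets = targets, repeats = repeats,
                 reference = Biostrings::DNAStringSet(seqs),
                 gene_models = models, cfg = cfg),
            class = "sim_panel")
}

## Carve repeat chunks inside targets until `fraction` of target bases is
## covered (exact up to the final chunk trim).
place_repeats <- function(targets, fraction) {
  budget <- round(fraction * sum(BiocGenerics::width(targets)))
  if (budget <= 0) return(GenomicRanges::GRanges())
  chunks <- list()
  for (pass in 1:3) {
    if (budget <= 0) break
    for (t in sample(seq_along(targets))) {
      if (budget <= 0) break
      w <- BiocGenerics::width(targets)[t]
      t_start <- GenomicRanges::start(targets)[t]
      off <- if (pass == 1) 0L else sample(0:60, 1)
      while (off < w && budget > 0) {
        gap <- sample(60:250, 1)
        len <- sample(40:200, 1)
        s <- off + gap
        if (s + 1 > w) break
        len <- min(len, w - s, budget)
        chunks[[length(chunks) + 1L]] <- GenomicRanges::GRanges(
          GenomicRanges::seqnames(targets)[t],
          IRanges::IRanges(t_start + s, t_start + s + len - 1L))
        budget <- budget - len
        off <- s + len
      }
    }
  }
  before <- suppressWarnings(do.call(c, chunks))
  GenomicRanges::sort(GenomicRanges::reduce(before))
}

#' Simulate per-base depth over capture targets
#'
#' Depth follows a lognormal distribution around `median_depth` with
#' short-range autocorrelation (AR(1) on the log scale), and
#' `dropout_fraction` of target bases are forced below 10 reads in
#' contiguous blocks, mimicking coverage loss in GC-rich regions.
#'
#' @param targets `GRanges` of capture targets.
#' @param cfg A [sim_config()].
#' @param seed Seed.
#' @return Data frame with columns `chrom`, `pos` (1-based), `depth`.
#' @export
simulate_depth <- function(targets, cfg, seed = cfg$seed) {
  validate_intervals(targets, "targets")
  if (length(targets) == 0L) stop("no targets", call. = FALSE)
  set.seed(seed)
  phi <- 0.9
  per_target <- lapply(seq_along(targets), function(t) {
    n <- BiocGenerics::width(targets)[t]
    z <- numeric(n)
    z[1] <- stats::rnorm(1)
    if (n > 1)
      for (i in 2:n)
        z[i] <- phi * z[i - 1] + sqrt(1 - phi^2) * stats::rnorm(1)
    depth <- pmax(0, round(exp(log(cfg$median_depth) +
                               cfg$depth_sigma * z)))
    data.frame(chrom = as.character(GenomicRanges::seqnames(targets))[t],
               pos = seq.int(GenomicRanges::start(targets)[t],
                             GenomicRanges::end(targets)[t]),
               depth = depth, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_target)
  n_total <- nrow(out)
  n_drop <- round(cfg$dropout_fraction * n_total)
  if (n_drop > 0) {
    mask <- rep(FALSE, n_total)
    added_last <- integer(0)
    while (sum(mask) < n_drop) {
      s <- sample.int(n_total, 1)
      len <- sample(50:200, 1)
      block <- s:min(s + len - 1L, n_total)
      added_last <- block[!mask[block]]
      mask[block] <- TRUE
    }
    excess <- sum(mask) - n_drop
    if (excess > 0)
      mask[utils::tail(added_last, excess)] <- FALSE
    out$depth[mask] <- sample(0:9, n_drop, replace = TRUE)
  }
  out
}

#' Simulate read placements with a given on-target rate
#'
#' Draws `n_reads` read intervals of length `read_length`; each read is
#' on-target (overlaps a target by at least one base) with probability
#' `on_target_prob` and otherwise falls entirely outside the targets.
#'
#' @param targets `GRanges` of capture targets.
#' @param n_reads Number of reads.
#' @param on_target_prob Probability a read touches a target.
#' @param read_length Read length, bp.
#' @param seed Seed.
#' @return `GRanges` of reads.
#' @export
simulate_reads <- function(targets, n_reads = 10000L, on_target_prob = 0.66,
                           read_length = 72L, seed = 1L) {
  validate_intervals(targets, "targets")
  set.seed(seed)
  chroms <- unique(as.character(GenomicRanges::seqnames(targets)))
  chrom_len <- vapply(chroms, function(ch)
    max(GenomicRanges::end(targets[
      GenomicRanges::seqnames(targets) == ch])) + 5000L, 0)
  genome <- GenomicRanges::GRanges(chroms, IRanges::IRanges(1L, chrom_len))
  ## off-target space: bases where a read start cannot reach a target
  buffered <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(targets),
    IRanges::IRanges(pmax(GenomicRanges::start(targets) - read_length + 1L,
                          1L),
                     GenomicRanges::end(targets)))
  off_space <- GenomicRanges::setdiff(genome,
                                      GenomicRanges::reduce(buffered))
  off_space <- off_space[BiocGenerics::width(off_space) >= read_length]
  on <- stats::runif(n_reads) < on_target_prob
  ## on-target: start anywhere a read would still touch the target
  on_space <- GenomicRanges::reduce(buffered)
  mk <- function(space, n) {
    if (n == 0L) return(GenomicRanges::GRanges())
    w <- BiocGenerics::width(space)
    i <- sample.int(length(space), n, replace = TRUE, prob = w)
    offs <- vapply(w[i], function(wi) sample.int(wi, 1) - 1L, 0L)
    GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(space))[i],
      IRanges::IRanges(GenomicRanges::start(space)[i] + offs,
                       width = read_length))
  }
  out <- suppressWarnings(c(mk(on_space, sum(on)),
                            mk(off_space, sum(!on))))
  GenomicRanges::sort(out)
}

ref_base_at <- function(reference, chrom, pos, len = 1L)
  as.character(Biostrings::subseq(reference[[chrom]], pos, pos + len - 1L))

sample_target_pos <- function(targets, n) {
  w <- BiocGenerics::width(targets)
  cw <- cumsum(w)
  idx <- sample.int(cw[length(cw)], n, replace = TRUE)
  t <- findInterval(idx - 1L, c(0L, cw), rightmost.closed = FALSE)
  off <- idx - c(0L, cw)[t]
  data.frame(chrom = as.character(GenomicRanges::seqnames(targets))[t],
             pos = GenomicRanges::start(targets)[t] + off - 1L,
             stringsAsFactors = FALSE)
}

draw_depth <- function(n, cfg)
  pmax(20L, round(exp(log(cfg$median_depth) +
                      cfg$depth_sigma * stats::rnorm(n))))

## Read counts for one site given zygosity ("het", "hom" or "weak").
read_counts <- function(zygosity, depth) {
  p <- switch(zygosity, het = 0.5, hom = 0.995, weak = 0.25)
  v <- stats::rbinom(length(depth), depth, p)
  data.frame(ref_reads = depth - v, var_reads = v)
}

#' Choose and plant a causal allele in a simulated panel
#'
#' Picks coding positions in the first toy gene whose substitution yields a
#' potentially functional effect (missense, or nonsense for the second
#' allele of a compound pair), matching the configured causal model.
#'
#' @param panel A `sim_panel`.
#' @param cfg A [sim_config()].
#' @return Data frame of planted alleles: `chrom`, `pos`, `ref`, `alt`,
#'   `zygosity`, `allele_id`.
#' @export
plant_causal <- function(panel, cfg) {
  model <- panel$gene_models[[1L]]
  want <- switch(cfg$causal_model,
                 recessive_hom = list(c("missense", "hom")),
                 dominant_het = list(c("missense", "het")),
                 recessive_compound_het = list(c("missense", "het"),
                                               c("nonsense", "het")))
  cpos <- cds_positions(model)
  cpos <- cpos[seq(4L, length(cpos) - 3L)]    # avoid start/stop codons
  picked <- list()
  for (spec_i in want) {
    eff_want <- spec_i[1]; zyg <- spec_i[2]
    found <- FALSE
    for (pos in sample(cpos)) {
      ref <- ref_base_at(panel$reference, model$chrom, pos)
      for (alt in sample(setdiff(BASES, ref))) {
        cand <- data.frame(chrom = model$chrom, pos = pos, ref = ref,
                           alt = alt, stringsAsFactors = FALSE)
        eff <- as.character(classify_effect(cand, panel$gene_models,
                                            panel$reference)$effect)
        if (eff == eff_want &&
            !pos %in% vapply(picked, `[[`, 0, "pos")) {
          cand$zygosity <- zyg
          cand$allele_id <- variant_key(cand$chrom, cand$pos, cand$ref,
                                        cand$alt)
          picked[[length(picked) + 1L]] <- cand
          found <- TRUE
        }
        if (found) break
      }
      if (found) break
    }
    if (!found) stop("could not place a ", eff_want,
                     " causal allele; enlarge the panel", call. = FALSE)
  }
  do.call(rbind, picked)
}

#' Simulate per-proband variant tables with annotation stubs
#'
#' Generates, per proband: population-common polymorphisms (shared by four
#' or more probands; absent from the dbSNP stub, as population-specific
#' alleles often are), private background variants (each carrying a benign
#' signature: dbSNP membership without a clinical flag, a low conservation
#' score, or 1000 Genomes membership), a small number of private conserved
#' benign variants that survive every filter and must be removed by
#' co-segregation, and the planted causal allele(s) in the focal proband
#' with variant reads drawn Binomial(depth, 0.5) for heterozygous or
#' Binomial(depth, 0.995) for homozygous carriers. Optionally a cryptic
#' indel fixture: a 2-bp deletion emitted as two nearby substitutions each
#' with ~25% variant allele fraction.
#'
#' @param panel A `sim_panel`.
#' @param cfg A [sim_config()].
#' @param planted Data frame of planted causal alleles (see
#'   [plant_causal()]); `NULL` plants automatically per `cfg$causal_model`.
#'   Planted sites must lie inside the panel targets.
#' @param cryptic_indel If `TRUE`, also plant a 2-bp deletion read as two
#'   weakly supported adjacent substitutions in the focal proband.
#' @param seed Seed.
#' @return A `sim_variants` list: `variants` (all probands), `annotations`
#'   (stubs: `dbsnp`, `phylop`, `kg`, `scores`), `truth` (planted causal
#'   rows incl. any cryptic deletion), `focal_proband`, `cfg`.
#' @export
simulate_proband_variants <- function(panel, cfg, planted = NULL,
                                      cryptic_indel = FALSE,
                                      seed = cfg$seed) {
  stopifnot(inherits(panel, "sim_panel"))
  set.seed(seed)
  if (is.null(planted)) planted <- plant_causal(panel, cfg)
  inside <- GenomicRanges::countOverlaps(
    GenomicRanges::GRanges(planted$chrom,
                           IRanges::IRanges(planted$pos, planted$pos)),
    panel$targets) > 0L
  if (!all(inside))
    stop("planted site outside the capture panel", call. = FALSE)
  probands <- sprintf("P%02d", seq_len(cfg$n_probands))
  focal <- probands[1L]
  rows <- list()
  dbsnp <- list(); phylop <- list(); kg <- list(); scores <- list()
  add_phylop <- function(chrom, pos, score)
    phylop[[length(phylop) + 1L]] <<- data.frame(chrom = chrom, pos = pos,
                                                 score = score)
  emit <- function(proband, chrom, pos, ref, alt, zygosity) {
    rc <- read_counts(zygosity, draw_depth(1L, cfg))
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = alt,
      ref_reads = rc$ref_reads, var_reads = rc$var_reads,
      proband = proband, stringsAsFactors = FALSE)
  }
  rand_site <- function() {
    repeat {
      s <- sample_target_pos(panel$targets, 1L)
      ref <- ref_base_at(panel$reference, s$chrom, s$pos)
      key <- paste(s$chrom, s$pos)
      if (!key %in% used_sites) {
        used_sites <<- c(used_sites, key)
        return(cbind(s, ref = ref, stringsAsFactors = FALSE))
      }
    }
  }
  used_sites <- paste(planted$chrom, planted$pos)

  ## population-common polymorphisms, shared by >= 4 probands
  panel_kb <- sum(BiocGenerics::width(panel$targets)) / 1000
  n_common <- round(cfg$common_poly_rate * panel_kb)
  for (i in seq_len(n_common)) {
    s <- rand_site()
    alt <- sample(setdiff(BASES, s$ref), 1L)
    carriers <- sample(probands, sample(min(4L, cfg$n_probands):
                                        cfg$n_probands, 1L))
    add_phylop(s$chrom, s$pos, round(stats::runif(1, -2, 3), 3))
    for (p in carriers)
      emit(p, s$chrom, s$pos, s$ref, alt,
           if (stats::runif(1) < 0.8) "het" else "hom")
  }

  ## private background variants with a benign signature
  for (p in probands) {
    n_priv <- stats::rpois(1, 4)
    for (i in seq_len(n_priv)) {
      s <- rand_site()
      is_indel <- stats::runif(1) < 0.25
      if (is_indel) {
        len <- sample(1:3, 1)
        ref <- ref_base_at(panel$reference, s$chrom, s$pos, len)
        alt <- ""
      } else {
        ref <- s$ref
        alt <- sample(setdiff(BASES, ref), 1L)
      }
      in_db <- stats::runif(1) < cfg$dbsnp_overlap
      if (in_db) {
        dbsnp[[length(dbsnp) + 1L]] <- data.frame(
          chrom = s$chrom, pos = s$pos, ref = ref, alt = alt,
          id = sprintf("rs%06d", length(dbsnp) + 1L), clinical = FALSE)
        if (!is_indel) add_phylop(s$chrom, s$pos,
                                  round(stats::runif(1, 0.9, 6), 3))
      } else if (!is_indel && stats::runif(1) < 0.6) {
        add_phylop(s$chrom, s$pos, round(stats::runif(1, -2, 0.89), 3))
      } else {
        kg[[length(kg) + 1L]] <- data.frame(chrom = s$chrom, pos = s$pos,
                                            ref = ref, alt = alt)
        if (!is_indel) add_phylop(s$chrom, s$pos,
                                  round(stats::runif(1, 0.9, 6), 3))
      }
      emit(p, s$chrom, s$pos, ref, alt,
           if (stats::runif(1) < 0.95) "het" else "hom")
    }
  }

  ## private conserved benigns that survive the cascade
  for (p in probands) {
    n_rb <- stats::rpois(1, cfg$rare_benign_per_proband)
    for (i in seq_len(n_rb)) {
      s <- rand_site()
      alt <- sample(setdiff(BASES, s$ref), 1L)
      add_phylop(s$chrom, s$pos, round(stats::runif(1, 0.9, 6), 3))
      scores[[length(scores) + 1L]] <- data.frame(
        chrom = s$chrom, pos = s$pos, ref = s$ref, alt = alt,
        polyphen2_humvar = round(stats::runif(1), 3),
        sift = round(stats::runif(1), 3))
      emit(p, s$chrom, s$pos, s$ref, alt,
           if (stats::runif(1) < 0.95) "het" else "hom")
    }
  }

  ## planted causal allele(s) in the focal proband
  truth <- planted
  for (i in seq_len(nrow(planted))) {
    add_phylop(planted$chrom[i], planted$pos[i],
               round(stats::runif(1, 2, 6), 3))
    scores[[length(scores) + 1L]] <- data.frame(
      chrom = planted$chrom[i], pos = planted$pos[i],
      ref = planted$ref[i], alt = planted$alt[i],
      polyphen2_humvar = round(stats::runif(1, 0.9, 1), 3),
      sift = round(stats::runif(1, 0, 0.05), 3))
    emit(focal, planted$chrom[i], planted$pos[i], planted$ref[i],
         planted$alt[i], planted$zygosity[i])
  }

  ## cryptic indel fixture: 2-bp deletion read as two weak substitutions
  if (cryptic_indel) {
    model <- panel$gene_models[[min(2L, length(panel$gene_models))]]
    cpos <- cds_positions(model)
    del_pos <- cpos[length(cpos) %/% 2L]
    del_ref <- ref_base_at(panel$reference, model$chrom, del_pos, 2L)
    truth <- rbind(truth, data.frame(
      chrom = model$chrom, pos = del_pos, ref = del_ref, alt = "",
      zygosity = "het",
      allele_id = variant_key(model$chrom, del_pos, del_ref, ""),
      stringsAsFactors = FALSE))
    d <- draw_depth(1L, cfg)
    for (off in c(0L, 2L)) {
      p <- del_pos + off
      ref <- ref_base_at(panel$reference, model$chrom, p)
      alt <- sample(setdiff(BASES, ref), 1L)
      v <- stats::rbinom(1, d, 0.25)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = model$chrom, pos = p, ref = ref, alt = alt,
        ref_reads = d - v, var_reads = v, proband = focal,
        stringsAsFactors = FALSE)
      add_phylop(model$chrom, p, round(stats::runif(1, 0.9, 6), 3))
    }
  }

  variants <- do.call(rbind, rows)
  variants <- variants[order(variants$proband, variants$chrom,
                             variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  bind <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  annotations <- list(
    dbsnp = bind(dbsnp, data.frame(chrom = character(), pos = integer(),
                                   ref = character(), alt = character(),
                                   id = character(), clinical = logical())),
    phylop = bind(phylop, data.frame(chrom = character(), pos = integer(),
                                     score = numeric())),
    kg = bind(kg, data.frame(chrom = character(), pos = integer(),
                             ref = character(), alt = character())),
    scores = bind(scores, data.frame(chrom = character(), pos = integer(),
                                     ref = character(), alt = character(),
                                     polyphen2_humvar = numeric(),
                                     sift = numeric())))
  structure(list(variants = variants, annotations = annotations,
                 truth = truth, focal_proband = focal, cfg = cfg),
            class = "sim_variants")
}

## Mendelian transmission helpers for pedigree simulation. Genotypes are
## copy counts 0/1/2 of one allele.
gt_code <- function(n) c("ref", "het", "hom")[n + 1L]
transmit <- function(parent_copies) {
  if (parent_copies == 0L) 0L
  else if (parent_copies == 2L) 1L
  else stats::rbinom(1, 1, 0.5)
}

#' Simulate a nuclear pedigree segregating planted and background alleles
#'
#' Parents plus `n_children` children. The causal allele(s) segregate per
#' the configured model (both parents heterozygous carriers for recessive
#' models, one affected heterozygous parent for dominant); the first child
#' (the proband) is forced to the causal genotype; other members follow
#' Mendelian transmission. Affection status is fully penetrant with no
#' phenocopies. Background alleles (e.g. cascade survivors in the proband)
#' are transmitted Mendelianly from randomly assigned carrier parents
#' consistent with the proband's observed zygosity.
#'
#' @param cfg A [sim_config()].
#' @param causal Data frame of planted alleles (`allele_id`, `zygosity`).
#' @param background Optional data frame of background alleles carried by
#'   the proband, with `allele_id` and `zygosity` columns.
#' @param n_children Number of children.
#' @param seed Seed.
#' @return List: `ped` (a [pedigree()]), `proband` (member id).
#' @export
simulate_pedigree <- function(cfg, causal, background = NULL,
                              n_children = 4L, seed = cfg$seed) {
  set.seed(seed)
  ids <- c("F1", "M1", sprintf("C%d", seq_len(n_children)))
  proband <- "C1"
  geno <- list()  # geno[[allele]][member] = copies
  model <- cfg$causal_model
  a <- causal$allele_id[1L]
  b <- if (nrow(causal) > 1L) causal$allele_id[2L] else a
  g <- stats::setNames(integer(length(ids)), ids)
  if (model == "recessive_hom") {
    ga <- g; ga["F1"] <- 1L; ga["M1"] <- 1L; ga[proband] <- 2L
    for (ch in ids[-(1:3)])
      ga[ch] <- transmit(ga["F1"]) + transmit(ga["M1"])
    geno[[a]] <- ga
  } else if (model == "dominant_het") {
    ga <- g; ga["F1"] <- 1L; ga["M1"] <- 0L; ga[proband] <- 1L
    for (ch in ids[-(1:3)])
      ga[ch] <- transmit(ga["F1"]) + transmit(ga["M1"])
    geno[[a]] <- ga
  } else {                                   # recessive_compound_het
    ga <- g; gb <- g
    ga["F1"] <- 1L; gb["M1"] <- 1L
    ga[proband] <- 1L; gb[proband] <- 1L
    for (ch in ids[-(1:3)]) {
      ga[ch] <- transmit(ga["F1"]) + transmit(ga["M1"])
      gb[ch] <- transmit(gb["F1"]) + transmit(gb["M1"])
    }
    geno[[a]] <- ga; geno[[b]] <- gb
  }
  affected_of <- function(i) {
    if (model == "dominant_het") geno[[a]][i] >= 1L
    else if (model == "recessive_hom") geno[[a]][i] == 2L
    else (geno[[a]][i] >= 1L && geno[[b]][i] >= 1L) ||
      geno[[a]][i] == 2L || geno[[b]][i] == 2L
  }
  if (!is.null(background) && nrow(background)) {
    for (i in seq_len(nrow(background))) {
      al <- background$allele_id[i]
      if (al %in% names(geno)) next
      gb_ <- stats::setNames(integer(length(ids)), ids)
      if (background$zygosity[i] %in% c("hom", "homozygous")) {
        gb_["F1"] <- 1L; gb_["M1"] <- 1L; gb_[proband] <- 2L
      } else {
        carrier <- sample(c("F1", "M1"), 1L)
        gb_[carrier] <- 1L; gb_[proband] <- 1L
      }
      for (ch in ids[-(1:3)])
        gb_[ch] <- transmit(gb_["F1"]) + transmit(gb_["M1"])
      geno[[al]] <- gb_
    }
  }
  members <- data.frame(
    id = ids,
    father = c(NA, NA, rep("F1", n_children)),
    mother = c(NA, NA, rep("M1", n_children)),
    sex = c(1L, 2L, sample(1:2, n_children, replace = TRUE)),
    affected = vapply(ids, affected_of, NA),
    stringsAsFactors = FALSE)
  genotypes <- do.call(rbind, lapply(names(geno), function(al)
    data.frame(member_id = ids, allele_id = al,
               genotype = gt_code(geno[[al]]), stringsAsFactors = FALSE)))
  list(ped = pedigree(members, genotypes), proband = proband)
}

#' Simulate case/control cohorts carrying a founder allele
#'
#' Genotypes are drawn per chromosome under Hardy-Weinberg: each case
#' chromosome carries the focal allele with probability
#' `case_allele_freq` and (for compound-heterozygote structure) a second
#' pathogenic allele with probability `second_allele_freq`; control
#' chromosomes carry the focal allele with probability
#' `control_allele_freq`. Also returns a pedigree segregating the planted
#' allele(s) under the configured causal model.
#'
#' @param cfg A [sim_config()].
#' @param seed Seed.
#' @return List: `cases`, `controls` ([cohort_counts()]),
#'   `case_genotypes`, `control_genotypes` (per-individual class labels),
#'   `pedigree` (from [simulate_pedigree()]).
#' @export
simulate_cohort <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  draw <- function(n, p_focal, p_second) {
    chrom1 <- sample(c("focal", "second", "wt"), n, replace = TRUE,
                     prob = c(p_focal, p_second, 1 - p_focal - p_second))
    chrom2 <- sample(c("focal", "second", "wt"), n, replace = TRUE,
                     prob = c(p_focal, p_second, 1 - p_focal - p_second))
    cls <- ifelse(chrom1 == "focal" & chrom2 == "focal", "hom",
           ifelse((chrom1 == "focal" & chrom2 == "second") |
                  (chrom1 == "second" & chrom2 == "focal"), "compound_het",
           ifelse(chrom1 == "focal" | chrom2 == "focal", "het", "other")))
    cls
  }
  case_cls <- draw(cfg$n_cases, cfg$case_allele_freq,
                   cfg$second_allele_freq)
  ctrl_cls <- draw(cfg$n_controls, cfg$control_allele_freq, 0)
  cases <- cohort_counts(cfg$n_cases,
                         sum(case_cls == "hom"),
                         sum(case_cls == "compound_het"),
                         sum(case_cls == "het"), "cases")
  controls <- cohort_counts(cfg$n_controls,
                            sum(ctrl_cls == "hom"),
                            sum(ctrl_cls == "compound_het"),
                            sum(ctrl_cls == "het"), "controls")
  causal <- data.frame(
    allele_id = c("allele_a",
                  if (cfg$causal_model == "recessive_compound_het")
                    "allele_b"),
    zygosity = if (cfg$causal_model == "recessive_hom") "hom" else "het",
    stringsAsFactors = FALSE)
  ped <- simulate_pedigree(cfg, causal, seed = seed + 1L)
  list(cases = cases, controls = controls,
       case_genotypes = data.frame(individual = seq_len(cfg$n_cases),
                                   class = case_cls),
       control_genotypes = data.frame(individual = seq_len(cfg$n_controls),
                                      class = ctrl_cls),
       pedigree = ped)
}

#' Run the full pipeline on one simulated study and score recovery
#'
#' Simulates a panel and proband variant tables with one planted causal
#' allele (or compound pair), runs cryptic-indel detection and the filter
#' cascade on the focal proband, simulates the proband's pedigree, tests
#' co-segregation of every cascade survivor under the configured model, and
#' reports whether the planted allele(s) are recovered as the sole
#' co-segregating survivors.
#'
#' @param cfg A [sim_config()].
#' @param seed Seed for the replicate.
#' @return List: `survivors` (annotated cascade survivors for the focal
#'   proband), `cosegregating` (allele keys consistent with the model),
#'   `truth_alleles`, `recovered` (logical).
#' @export
run_pipeline <- function(cfg, seed = cfg$seed) {
  panel <- simulate_panel(cfg, seed = seed)
  sim <- simulate_proband_variants(panel, cfg, seed = seed + 1L)
  foc <- sim$variants[sim$variants$proband == sim$focal_proband, ,
                      drop = FALSE]
  det <- detect_cryptic_indels(foc)
  ann <- run_cascade(det$variants, sim$annotations, panel$gene_models,
                     panel$reference, cohort = sim$variants)
  surv <- ann[ann$rare, , drop = FALSE]
  surv_keys <- variant_key(surv$chrom, surv$pos, surv$ref, surv$alt)
  zyg <- call_zygosity(surv$ref_reads, surv$var_reads)
  background <- data.frame(allele_id = surv_keys,
                           zygosity = as.character(zyg$state),
                           stringsAsFactors = FALSE)
  causal <- sim$truth
  fam <- simulate_pedigree(cfg, causal, background, seed = seed + 2L)
  ped <- fam$ped
  coseg <- character(0)
  if (cfg$causal_model == "recessive_compound_het") {
    if (length(surv_keys) >= 2L) {
      prs <- utils::combn(surv_keys, 2L)
      for (j in seq_len(ncol(prs))) {
        res <- check_recessive(ped, prs[1, j], prs[2, j])
        if (res$consistent && length(res$warnings) == 0L)
          coseg <- union(coseg, prs[, j])
      }
    }
  } else {
    for (k in surv_keys) {
      res <- if (cfg$causal_model == "dominant_het")
        check_dominant(ped, k) else check_recessive(ped, k)
      if (res$consistent) coseg <- union(coseg, k)
    }
  }
  truth_alleles <- sim$truth$allele_id
  list(survivors = surv, cosegregating = coseg,
       truth_alleles = truth_alleles,
       recovered = setequal(coseg, truth_alleles))
}

#' Write a simulated data set to plain-text files
#'
#' Emits exon, repeat and target BED files, the toy reference FASTA, the
#' variant table and annotation stubs as TSV, and a JSON echo of the
#' configuration.
#'
#' @param panel A `sim_panel`.
#' @param sim A `sim_variants` (optional).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_data <- function(panel, sim = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bed(panel$exons, file.path(dir, "exons.bed"))
  write_bed(panel$targets, file.path(dir, "targets.bed"))
  if (length(panel$repeats))
    write_bed(panel$repeats, file.path(dir, "repeats.bed"))
  Biostrings::writeXStringSet(panel$reference,
                              file.path(dir, "reference.fa"))
  jsonlite::write_json(unclass(panel$cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(sim)) {
    write_variants(sim$variants, file.path(dir, "variants.tsv"))
    for (nm in names(sim$annotations))
      utils::write.table(sim$annotations[[nm]],
                         file.path(dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    write_variants(sim$truth, file.path(dir, "truth.tsv"))
  }
  invisible(dir)
}
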