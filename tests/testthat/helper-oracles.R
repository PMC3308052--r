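## Independent brute-force oracles used across the suite. These deliberately
## work on explicit base sets and loops, not on the package's interval code.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

## All bases (0-based) covered by a set of 0-based half-open intervals.
bases0 <- function(starts, ends) {
  if (length(starts) == 0L) return(integer(0))
  unique(unlist(mapply(function(s, e) seq.int(s, e - 1L), starts, ends,
                       SIMPLIFY = FALSE)))
}

## Brute-force centered tiling: enumerate grid candidates over a generous k
## range, keep those sharing >= 1 base with the target, reject on total
## repeat overlap, and return accepted 0-based starts plus the per-base
## covering count over the target.
oracle_tile <- function(t0, t1, bait_length = 120L, tiling_factor = 3L,
                        rep_starts = integer(0), rep_ends = integer(0),
                        max_overlap = 20L) {
  s <- bait_length %/% tiling_factor
  m <- (t0 + t1) %/% 2L
  c0 <- m - bait_length %/% 2L
  rep_bases <- bases0(rep_starts, rep_ends)
  target_bases <- seq.int(t0, t1 - 1L)
  accepted <- integer(0)
  for (k in -200:200) {
    st <- c0 + k * s
    if (st < 0L) next
    bait_bases <- seq.int(st, st + bait_length - 1L)
    if (!any(bait_bases %in% target_bases)) next
    if (length(intersect(bait_bases, rep_bases)) > max_overlap) next
    accepted <- c(accepted, st)
  }
  cover <- vapply(target_bases, function(b)
    sum(accepted <= b & b <= accepted + bait_length - 1L), 0L)
  list(starts = sort(accepted), cover = cover)
}

## Per-base covering counts of target bases by a GRanges of baits.
bait_cover_counts <- function(target_gr, baits) {
  pos <- seq.int(GenomicRanges::start(target_gr),
                 GenomicRanges::end(target_gr))
  ch <- as.character(GenomicRanges::seqnames(target_gr))
  b <- baits[as.character(GenomicRanges::seqnames(baits)) == ch]
  vapply(pos, function(p)
    sum(GenomicRanges::start(b) <= p & p <= GenomicRanges::end(b)), 0L)
}

## Exhaustive two-sided Fisher p by enumerating all tables with the
## observed margins (hypergeometric probabilities via log-binomials).
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0L, k - n):min(m, k)
  logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  p_obs <- lchoose(m, a) + lchoose(n, c) - lchoose(m + n, k)
  sum(exp(logp)[logp <= p_obs + 1e-7])
}

## Gamete-enumeration oracle for compound-het phase: enumerate parental
## haplotype configurations consistent with per-allele copy counts and all
## transmissions producing a child heterozygous for both alleles; classify
## the child's placement of the two alleles.
oracle_phase <- function(fa_a, fa_b, mo_a, mo_b) {
  hap_configs <- function(na, nb) {
    ## distribute copy counts of alleles a and b onto two chromosomes
    out <- list()
    for (a1 in 0:1) for (b1 in 0:1) {
      a2 <- na - a1; b2 <- nb - b1
      if (a2 %in% 0:1 && b2 %in% 0:1)
        out[[length(out) + 1L]] <- rbind(c(a1, b1), c(a2, b2))
    }
    unique(out)
  }
  placements <- character(0)
  for (fh in hap_configs(fa_a, fa_b)) for (mh in hap_configs(mo_a, mo_b)) {
    for (fi in 1:2) for (mi in 1:2) {
      child <- rbind(fh[fi, ], mh[mi, ])
      if (sum(child[, 1]) == 1L && sum(child[, 2]) == 1L) {
        same <- any(child[, 1] == 1L & child[, 2] == 1L)
        placements <- c(placements, if (same) "cis" else "trans")
      }
    }
  }
  placements <- unique(placements)
  if (length(placements) == 1L) placements else "unknown"
}

## Naive re-derivations of the segregation rules, written as plain loops.
oracle_recessive <- function(members, geno, allele_a, allele_b = allele_a) {
  bad <- character(0)
  for (i in seq_len(nrow(members))) {
    id <- members$id[i]; aff <- members$affected[i]
    if (is.na(aff)) next
    ga <- geno[[paste(id, allele_a)]]
    two <- NA
    if (allele_a == allele_b) {
      if (!is.null(ga) && !is.na(ga)) two <- ga == 2L
    } else {
      gb <- geno[[paste(id, allele_b)]]
      ga_known <- !is.null(ga) && !is.na(ga)
      gb_known <- !is.null(gb) && !is.na(gb)
      if (ga_known && ga == 2L) two <- TRUE
      else if (gb_known && gb == 2L) two <- TRUE
      else if (ga_known && gb_known) {
        if (ga == 1L && gb == 1L) {
          fid <- members$father[i]; mid <- members$mother[i]
          ph <- "unknown"
          if (!is.na(fid) && !is.na(mid)) {
            fa <- geno[[paste(fid, allele_a)]]; fb <- geno[[paste(fid, allele_b)]]
            ma <- geno[[paste(mid, allele_a)]]; mb <- geno[[paste(mid, allele_b)]]
            known <- function(x) !is.null(x) && !is.na(x)
            if (known(fa) && known(fb) && known(ma) && known(mb)) {
              f1 <- (fa >= 1L) + (fb >= 1L); m1 <- (ma >= 1L) + (mb >= 1L)
              if (f1 == 1L && m1 == 1L && (fa >= 1L) != (ma >= 1L)) ph <- "trans"
              else if ((f1 == 2L && m1 == 0L) || (f1 == 0L && m1 == 2L)) ph <- "cis"
            }
          }
          two <- if (ph == "trans") TRUE else if (ph == "cis") FALSE else NA
        } else two <- FALSE
      }
    }
    if (is.na(two)) next
    if (aff && !two) bad <- c(bad, id)
    if (!aff && two) bad <- c(bad, id)
  }
  length(bad) == 0L
}

oracle_dominant <- function(members, geno, allele) {
  for (i in seq_len(nrow(members))) {
    id <- members$id[i]; aff <- members$affected[i]
    if (is.na(aff)) next
    g <- geno[[paste(id, allele)]]
    if (is.null(g) || is.na(g)) next
    if (aff && g == 0L) return(FALSE)
    if (!aff && g >= 1L) return(FALSE)
  }
  TRUE
}

## Build a pedigree object from copy-count maps (list keyed "id allele").
ped_from_counts <- function(members, geno) {
  rows <- lapply(names(geno), function(key) {
    parts <- strsplit(key, " ")[[1]]
    g <- geno[[key]]
    if (is.na(g)) return(NULL)
    data.frame(member_id = parts[1], allele_id = parts[2],
               genotype = c("ref", "het", "hom")[g + 1L],
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  gt <- if (length(rows)) do.call(rbind, rows) else NULL
  pedigree(members, gt)
}

## A hand-built toy gene on chromosome "chrT" for effect classification:
## exon1 11-40 (UTR5 11-16, CDS 17-40), exon2 61-96 coding, UTR3 97-100
## within exon2 61-100. CDS is 60 bases = 20 codons; codon 1 = ATG at
## 17-19, codon 2 = CGA at 20-22, codon 3 = CCT at 23-25, codon 20 = TAA.
toy_gene <- function() {
  codons <- c("ATG", "CGA", "CCT", "GAA", "TTC", "AAG", "GAT", "TGG",
              "CAT", "GTC", "ATC", "CTG", "AAA", "GGC", "TAC", "CAG",
              "GTG", "TTT", "GCA", "TAA")
  cds_pos <- c(17:40, 61:96)
  seqv <- rep("T", 140)
  seqv[11:16] <- c("G", "C", "A", "A", "G", "C")     # 5' UTR
  seqv[97:100] <- c("A", "G", "C", "A")              # 3' UTR
  seqv[41:60] <- rep(c("G", "A"), 10)                # intron
  seqv[cds_pos] <- unlist(strsplit(codons, ""))
  model <- gene_model("TOY1", "chrT",
                      data.frame(start = c(11L, 61L), end = c(40L, 100L)),
                      cds_start = 17L, cds_end = 96L)
  list(model = model,
       reference = Biostrings::DNAStringSet(
         c(chrT = paste(seqv, collapse = ""))),
       cds_pos = cds_pos, codons = codons, seq = seqv)
}

## Codon-arithmetic helper independent of classify_effect: predicted amino
## acid change for a substitution at CDS index k (1-based within CDS).
toy_aa_change <- function(tg, k, alt) {
  ci <- (k - 1L) %/% 3L + 1L
  codon <- strsplit(tg$codons[ci], "")[[1]]
  within <- k - (ci - 1L) * 3L
  ref_aa <- Biostrings::GENETIC_CODE[[paste(codon, collapse = "")]]
  codon[within] <- alt
  alt_aa <- Biostrings::GENETIC_CODE[[paste(codon, collapse = "")]]
  c(ref_aa, alt_aa)
}

empty_stubs <- function() {
  list(dbsnp = data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          id = character(), clinical = logical()),
       phylop = data.frame(chrom = character(), pos = integer(),
                           score = numeric()),
       kg = data.frame(chrom = character(), pos = integer(),
                       ref = character(), alt = character()),
       scores = NULL)
}

## Nuclear-family scaffolding shared by the segregation tests.
nuclear <- function(n_children, affected) {
  data.frame(
    id = c("F1", "M1", paste0("C", seq_len(n_children))),
    father = c(NA, NA, rep("F1", n_children)),
    mother = c(NA, NA, rep("M1", n_children)),
    sex = c(1, 2, rep(1, n_children)),
    affected = affected,
    stringsAsFactors = FALSE)
}

geno_map <- function(ids, allele, copies) {
  g <- list()
  for (i in seq_along(ids)) g[[paste(ids[i], allele)]] <- copies[i]
  g
}

variant_row <- function(chrom, pos, ref, alt, ref_reads = 500L,
                        var_reads = 480L, proband = "D28C") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             ref_reads = ref_reads, var_reads = var_reads,
             proband = proband, stringsAsFactors = FALSE)
}
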