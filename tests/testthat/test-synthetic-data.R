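test_that("configuration validation rejects infeasible parameters", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(repeat_fraction = 1.2), "proportions")
  expect_error(sim_config(exon_length = c(200, 100)), "ranges")
  expect_error(sim_config(exon_length = c(40, 100)), "UTR")
  expect_error(sim_config(case_allele_freq = 0.7, second_allele_freq = 0.5),
               "exceeds 1")
})

test_that("panel simulation is deterministic and honors repeat_fraction", {
  cfg <- sim_config(seed = 1, n_genes = 5)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(as.character(p1$exons), as.character(p2$exons))
  expect_identical(as.character(p1$reference), as.character(p2$reference))
  p3 <- simulate_panel(cfg, seed = 2)
  expect_false(identical(as.character(p1$exons), as.character(p3$exons)))

  # repeat fraction recovered by base counting on the output
  tw <- sum(width(p1$targets))
  rb <- sum(width(GenomicRanges::intersect(p1$repeats, p1$targets)))
  expect_equal(rb / tw, cfg$repeat_fraction, tolerance = 0.02)
  cfg30 <- sim_config(seed = 1, n_genes = 5, repeat_fraction = 0.3)
  p30 <- simulate_panel(cfg30)
  rb30 <- sum(width(GenomicRanges::intersect(p30$repeats, p30$targets)))
  expect_equal(rb30 / sum(width(p30$targets)), 0.30, tolerance = 0.02)
  expect_length(simulate_panel(sim_config(seed = 1, n_genes = 3,
                                          repeat_fraction = 0))$repeats, 0L)
})

test_that("simulated coding sequence translates without internal stops", {
  p <- simulate_panel(sim_config(seed = 6, n_genes = 3))
  for (m in p$gene_models) {
    cpos <- panelseeker:::cds_positions(m)
    cds <- paste(vapply(cpos, function(i)
      as.character(Biostrings::subseq(p$reference[[m$chrom]], i, i)), ""),
      collapse = "")
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_equal(substr(aa, 1, 1), "M")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
})

test_that("depth simulation is deterministic with exact dropout blocks", {
  cfg <- sim_config(seed = 3, n_genes = 3)
  p <- simulate_panel(cfg)
  d1 <- simulate_depth(p$targets, cfg)
  d2 <- simulate_depth(p$targets, cfg)
  expect_identical(d1, d2)
  expect_equal(sum(d1$depth < 10) / nrow(d1), 0.05, tolerance = 0.003)
  expect_error(simulate_depth(GRanges(), cfg), "no targets")
})

test_that("proband tables carry the planted allele at the right VAF", {
  cfg <- sim_config(seed = 21, n_genes = 4)
  p <- simulate_panel(cfg)
  sim <- simulate_proband_variants(p, cfg)
  v <- sim$variants
  expect_identical(v, simulate_proband_variants(p, cfg)$variants)

  causal <- v[variant_key(v$chrom, v$pos, v$ref, v$alt) %in%
              sim$truth$allele_id, ]
  expect_equal(nrow(causal), 1L)
  expect_equal(causal$proband, sim$focal_proband)
  # recessive_hom default: variant reads swamp reference reads
  expect_gt(causal$var_reads / (causal$var_reads + causal$ref_reads), 0.97)

  # a planted heterozygote sits near 50% support
  cfg_d <- sim_config(seed = 21, n_genes = 4, causal_model = "dominant_het")
  sim_d <- simulate_proband_variants(p, cfg_d)
  het <- sim_d$variants[variant_key(sim_d$variants$chrom, sim_d$variants$pos,
                                    sim_d$variants$ref, sim_d$variants$alt)
                        %in% sim_d$truth$allele_id, ]
  expect_equal(het$var_reads / (het$var_reads + het$ref_reads), 0.5,
               tolerance = 0.1)

  # common polymorphisms are shared by four or more probands
  rec <- compute_recurrence(v, v)
  common <- v[rec >= 4, ]
  expect_gt(nrow(unique(common[, c("chrom", "pos")])), 0L)

  # planting outside the panel is rejected
  bad <- data.frame(chrom = "gene01", pos = 1L, ref = "A", alt = "T",
                    zygosity = "hom", allele_id = "x")
  expect_error(simulate_proband_variants(p, cfg, planted = bad), "outside")
})

test_that("background-free configurations yield empty rare tables", {
  cfg <- sim_config(seed = 9, n_genes = 3, common_poly_rate = 0,
                    dbsnp_overlap = 0, rare_benign_per_proband = 0,
                    n_probands = 3)
  p <- simulate_panel(cfg)
  sim <- simulate_proband_variants(p, cfg)
  other <- sim$variants[sim$variants$proband != sim$focal_proband, ]
  ann <- suppressMessages(
    run_cascade(other, sim$annotations, p$gene_models, p$reference,
                cohort = sim$variants))
  # everything except the planted causal carries a benign signature here,
  # so non-focal probands have nothing rare
  expect_equal(sum(ann$rare), 0L)
})

test_that("cohort simulation recovers the configured founder frequencies", {
  cfg <- sim_config(seed = 1)
  co <- simulate_cohort(cfg)
  expect_identical(co$cases, simulate_cohort(cfg)$cases)
  expect_equal(2 * co$cases$n_individuals, 104L)

  # 1000 replicates: enough Monte Carlo resolution that the ~96% exact-CI
  # coverage is distinguishable from the 93% bound being tested
  n_rep <- 1000
  hits_case <- 0; hits_ctrl <- 0; hw_reject <- 0; hw_n <- 0
  for (s in seq_len(n_rep)) {
    co <- simulate_cohort(cfg, seed = s)
    x <- 2 * co$cases$n_hom + co$cases$n_compound_het + co$cases$n_het
    ci <- binom.test(x, 104)$conf.int
    if (ci[1] <= 0.337 && 0.337 <= ci[2]) hits_case <- hits_case + 1
    y <- 2 * co$controls$n_hom + co$controls$n_compound_het +
      co$controls$n_het
    ci2 <- binom.test(y, 564)$conf.int
    if (ci2[1] <= 0.028 && 0.028 <= ci2[2]) hits_ctrl <- hits_ctrl + 1
    # Hardy-Weinberg goodness of fit on focal-copy classes in cases
    n <- co$cases$n_individuals
    n2 <- co$cases$n_hom
    n1 <- co$cases$n_compound_het + co$cases$n_het
    n0 <- n - n2 - n1
    ph <- (2 * n2 + n1) / (2 * n)
    expd <- n * c((1 - ph)^2, 2 * ph * (1 - ph), ph^2)
    if (all(expd > 1)) {
      hw_n <- hw_n + 1
      x2 <- sum((c(n0, n1, n2) - expd)^2 / expd)
      if (stats::pchisq(x2, df = 1, lower.tail = FALSE) < 0.01)
        hw_reject <- hw_reject + 1
    }
  }
  expect_gte(hits_case / n_rep, 0.93)
  expect_gte(hits_ctrl / n_rep, 0.93)
  expect_lte(hw_reject / hw_n, 0.05)

  # degenerate control frequency: all wild type
  co0 <- simulate_cohort(sim_config(seed = 2, control_allele_freq = 0))
  expect_equal(allele_frequency(co0$controls), 0)
})

test_that("compound-het cohorts put two alleles in trans in affecteds", {
  cfg <- sim_config(seed = 4, causal_model = "recessive_compound_het")
  co <- simulate_cohort(cfg)
  ped <- co$pedigree$ped
  aff <- ped$members$id[which(ped$members$affected)]
  expect_gt(length(aff), 0L)
  for (id in aff) {
    ga <- panelseeker:::genotype_of(ped, id, "allele_a")
    gb <- panelseeker:::genotype_of(ped, id, "allele_b")
    carries_two <- (ga == "het" && gb == "het") || ga == "hom" ||
      gb == "hom"
    expect_true(carries_two)
    if (ga == "het" && gb == "het" &&
        !id %in% c("F1", "M1"))
      expect_equal(phase_compound_het(ped, id, "allele_a", "allele_b"),
                   "trans")
  }
  expect_true(check_recessive(ped, "allele_a", "allele_b")$consistent)
})

test_that("simulated data sets serialize to plain-text files", {
  cfg <- sim_config(seed = 13, n_genes = 2, n_probands = 3)
  p <- simulate_panel(cfg)
  sim <- simulate_proband_variants(p, cfg)
  dir <- file.path(tempdir(), "simout")
  write_sim_data(p, sim, dir)
  expect_true(file.exists(file.path(dir, "exons.bed")))
  back <- read_bed(file.path(dir, "targets.bed"))
  expect_equal(length(back), length(p$targets))
  expect_equal(start(back), start(p$targets))
  fa <- Biostrings::readDNAStringSet(file.path(dir, "reference.fa"))
  expect_equal(as.character(fa[["gene01"]]),
               as.character(p$reference[["gene01"]]))
  vt <- read_variants(file.path(dir, "variants.tsv"))
  expect_equal(nrow(vt), nrow(sim$variants))
})
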