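test_that("dbSNP filter removes known variants unless clinically flagged", {
  v <- rbind(variant_row("c", 10, "A", "G"),
             variant_row("c", 20, "C", "T"),
             variant_row("c", 30, "G", "A"))
  db <- data.frame(chrom = "c", pos = c(20, 30), ref = c("C", "G"),
                   alt = c("T", "A"), id = c("rs1", "rs2"),
                   clinical = c(FALSE, TRUE))
  expect_equal(filter_dbsnp(v, db), c(TRUE, FALSE, TRUE))
  expect_equal(filter_dbsnp(v, NULL), rep(TRUE, 3))
})

test_that("conservation filter discards substitutions below 0.9 only", {
  v <- rbind(variant_row("c", 10, "A", "G"),   # 0.89 -> fail
             variant_row("c", 20, "C", "T"),   # 0.90 -> pass (strict <0.9)
             variant_row("c", 30, "CG", ""),   # indel -> exempt
             variant_row("c", 40, "G", "A"))   # no score
  ph <- data.frame(chrom = "c", pos = c(10, 20), score = c(0.89, 0.90))
  expect_message(pass <- filter_conservation(v, ph), "without a conservation")
  expect_equal(pass, c(FALSE, TRUE, TRUE, TRUE))
  expect_message(
    pass_strict <- filter_conservation(v, ph, missing_action = "fail"))
  expect_equal(pass_strict[4], FALSE)
})

test_that("recurrence filter keeps variants in at most three probands", {
  cohort <- do.call(rbind, lapply(1:11, function(i)
    variant_row("c", 100, "A", "G", proband = sprintf("P%02d", i))))
  cohort <- rbind(cohort,
                  do.call(rbind, lapply(1:3, function(i)
                    variant_row("c", 200, "C", "T",
                                proband = sprintf("P%02d", i)))),
                  variant_row("c", 300, "G", "A", proband = "P01"))
  v <- cohort[!duplicated(variant_key(cohort$chrom, cohort$pos,
                                      cohort$ref, cohort$alt)), ]
  rec <- compute_recurrence(v, cohort)
  expect_equal(rec, c(11L, 3L, 1L))
  expect_equal(filter_recurrence(v, rec), c(FALSE, TRUE, TRUE))
  # the same proband counted once even with duplicate rows
  dup <- rbind(cohort, variant_row("c", 300, "G", "A", proband = "P01"))
  expect_equal(compute_recurrence(v, dup)[3], 1L)
})

test_that("membership filter covers 1000 Genomes and hearing genomes", {
  v <- rbind(variant_row("c", 10, "A", "G"),
             variant_row("c", 20, "C", "T"),
             variant_row("c", 30, "G", "A"))
  kg <- data.frame(chrom = "c", pos = 10, ref = "A", alt = "G")
  hearing <- data.frame(chrom = "c", pos = 30, ref = "G", alt = "A")
  expect_equal(filter_1000g(v, kg), c(FALSE, TRUE, TRUE))
  expect_equal(filter_1000g(v, kg, hearing), c(FALSE, TRUE, FALSE))
})

test_that("effect classification translates codons and windows correctly", {
  tg <- toy_gene()
  cases <- rbind(
    # codon 2 CGA: C>T at 20 gives TGA stop (nonsense)
    data.frame(pos = 20, ref = "C", alt = "T", want = "nonsense"),
    # codon 2 CGA: G>A at 21 gives CAA Arg->Gln (missense)
    data.frame(pos = 21, ref = "G", alt = "A", want = "missense"),
    # codon 3 CCT: third position T>C silent (CCT/CCC both Pro)
    data.frame(pos = 25, ref = "T", alt = "C", want = "synonymous"),
    # intronic, 2 bp from exon 2 acceptor
    data.frame(pos = 59, ref = "A", alt = "C", want = "splice_junction"),
    # donor side: 1 bp past exon 1 end
    data.frame(pos = 41, ref = "G", alt = "C", want = "splice_junction"),
    # deep intron
    data.frame(pos = 50, ref = "A", alt = "C", want = "intronic"),
    # UTRs
    data.frame(pos = 14, ref = "A", alt = "C", want = "utr"),
    data.frame(pos = 98, ref = "G", alt = "C", want = "utr"),
    # outside any transcript
    data.frame(pos = 130, ref = "T", alt = "C", want = "intronic"))
  v <- variant_row("chrT", cases$pos, cases$ref, cases$alt)
  cls <- classify_effect(v, tg$model, tg$reference)
  expect_equal(as.character(cls$effect), cases$want)
  # agreement with independent codon arithmetic for the coding cases
  expect_equal(toy_aa_change(tg, 4, "T"), c("R", "*"))
  expect_equal(toy_aa_change(tg, 5, "A")[1] ==
               toy_aa_change(tg, 5, "A")[2], FALSE)
  expect_equal(toy_aa_change(tg, 9, "C"), c("P", "P"))

  # indels: 2-bp CDS deletion frameshift, 3-bp in-frame, intronic indel
  ind <- rbind(variant_row("chrT", 30, "TG", ""),
               variant_row("chrT", 30, "TGG", ""),
               variant_row("chrT", 50, "AG", ""))
  cls <- classify_effect(ind, tg$model, tg$reference)
  expect_equal(as.character(cls$effect),
               c("frameshift", "inframe_indel", "intronic"))

  # widened splice window reclassifies deeper intronic sites
  deep <- variant_row("chrT", 55, "A", "C")
  expect_equal(as.character(
    classify_effect(deep, tg$model, tg$reference, splice_window = 10)$effect),
    "splice_junction")
})

cascade_fixture <- function() {
  tg <- toy_gene()
  ## survivors: 9 missense, 5 synonymous, 5 UTR, 5 intronic SNVs (24 rare
  ## substitutions), 7 in-frame CDS deletions + 7 intronic indels (14
  ## private indels); plus filtered rows: 5 dbSNP-benign, 3 non-conserved,
  ## 2 in 1000 Genomes, 1 population-common variant in 4 probands.
  aa_at <- function(k, alt) toy_aa_change(tg, k, alt)
  mis <- list(); syn <- list()
  for (k in seq(4, 60)) {
    pos <- tg$cds_pos[k]
    ref <- tg$seq[pos]
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      ch <- aa_at(k, alt)
      if (ch[1] != ch[2] && ch[2] != "*" && length(mis) < 9 &&
          !pos %in% vapply(mis, `[[`, 0, "pos"))
        mis[[length(mis) + 1]] <- list(pos = pos, ref = ref, alt = alt)
      if (ch[1] == ch[2] && length(syn) < 5 &&
          !pos %in% c(vapply(mis, `[[`, 0, "pos"),
                      vapply(syn, `[[`, 0, "pos")))
        syn[[length(syn) + 1]] <- list(pos = pos, ref = ref, alt = alt)
    }
  }
  stopifnot(length(mis) == 9, length(syn) == 5)
  snv <- function(lst) do.call(rbind, lapply(lst, function(x)
    variant_row("chrT", x$pos, x$ref, x$alt)))
  utr_pos <- c(11, 12, 13, 97, 99)
  intr_pos <- c(44, 46, 48, 52, 54)
  surv_snv <- rbind(
    snv(mis), snv(syn),
    variant_row("chrT", utr_pos, tg$seq[utr_pos], "C"),
    variant_row("chrT", intr_pos, tg$seq[intr_pos], "C"))
  del3 <- tg$cds_pos[seq(10, 46, by = 6)][1:7]
  surv_ind <- rbind(
    do.call(rbind, lapply(del3, function(p)
      variant_row("chrT", p, ref_sub <- paste(tg$seq[p:(p + 2)],
                                              collapse = ""), ""))),
    do.call(rbind, lapply(43 + (0:6), function(p)
      variant_row("chrT", p, paste(tg$seq[p:(p + 1)], collapse = ""), ""))))
  filtered <- rbind(
    variant_row("chrQ", 1:5 * 10, "A", "G"),          # dbSNP benign
    variant_row("chrQ", 100 + 1:3 * 10, "C", "T"),    # non-conserved
    variant_row("chrQ", 200 + 1:2 * 10, "G", "A"),    # in 1000 Genomes
    variant_row("chrQ", 300, "T", "A"))               # common, 4 probands
  tbl <- rbind(surv_snv, surv_ind, filtered)
  cohort <- rbind(tbl, do.call(rbind, lapply(2:4, function(i)
    variant_row("chrQ", 300, "T", "A", proband = paste0("X", i)))))
  snv_rows <- is_snv <- nchar(tbl$ref) == 1 & nchar(tbl$alt) == 1
  stubs <- list(
    dbsnp = data.frame(chrom = "chrQ", pos = 1:5 * 10, ref = "A",
                       alt = "G", id = paste0("rs", 1:5), clinical = FALSE),
    phylop = rbind(
      data.frame(chrom = "chrT", pos = tbl$pos[tbl$chrom == "chrT" &
                                               is_snv],
                 score = 2.5),
      data.frame(chrom = "chrQ", pos = 100 + 1:3 * 10, score = 0.2),
      data.frame(chrom = "chrQ", pos = c(1:5 * 10, 200 + 1:2 * 10, 300),
                 score = 3)),
    kg = data.frame(chrom = "chrQ", pos = 200 + 1:2 * 10, ref = "G",
                    alt = "A"),
    scores = data.frame(chrom = "chrT",
                        pos = vapply(mis, `[[`, 0, "pos"),
                        ref = vapply(mis, `[[`, "", "ref"),
                        alt = vapply(mis, `[[`, "", "alt"),
                        polyphen2_humvar = 0.97, sift = 0.02))
  list(tbl = tbl, cohort = cohort, stubs = stubs, tg = tg)
}

test_that("the cascade reproduces a 24 SNV / 14 indel / 9 missense proband", {
  fx <- cascade_fixture()
  ann <- suppressMessages(
    run_cascade(fx$tbl, fx$stubs, fx$tg$model, fx$tg$reference,
                cohort = fx$cohort))
  smry <- proband_summary(ann)
  expect_equal(smry$n_rare_snv, 24L)
  expect_equal(smry$n_private_indel, 14L)
  expect_equal(smry$n_rare_total, 38L)
  expect_equal(smry$n_nonsense, 0L)
  expect_equal(smry$n_missense, 9L)
  expect_equal(smry$n_splice, 0L)
  expect_equal(smry$n_frameshift, 0L)
  expect_equal(smry$n_functional_total, 9L)
  expect_equal(smry$n_rare_total, smry$n_rare_snv + smry$n_private_indel)
  # survivors carry scores where provided, and full all-pass trails
  surv <- ann[ann$rare, ]
  expect_true(all(surv$pass_dbsnp & surv$pass_conservation &
                  surv$pass_recurrence & surv$pass_1000g))
  expect_equal(sum(surv$polyphen2_humvar == 0.97, na.rm = TRUE), 9L)
})

test_that("cascade is a subset, idempotent, and order-insensitive where due", {
  fx <- cascade_fixture()
  base_orders <- list(
    c("dbsnp", "conservation", "recurrence", "1000g"),
    c("conservation", "dbsnp", "recurrence", "1000g"),
    c("dbsnp", "recurrence", "1000g", "conservation"))
  keys <- lapply(base_orders, function(o) {
    ann <- suppressMessages(
      run_cascade(fx$tbl, fx$stubs, fx$tg$model, fx$tg$reference,
                  cohort = fx$cohort, order = o))
    sort(variant_key(ann$chrom[ann$rare], ann$pos[ann$rare],
                     ann$ref[ann$rare], ann$alt[ann$rare]))
  })
  expect_equal(keys[[2]], keys[[1]])
  expect_equal(keys[[3]], keys[[1]])

  ann <- suppressMessages(
    run_cascade(fx$tbl, fx$stubs, fx$tg$model, fx$tg$reference,
                cohort = fx$cohort))
  # output is a subset of input, and re-running on survivors keeps them all
  surv <- ann[ann$rare, names(fx$tbl)]
  expect_true(all(variant_key(surv$chrom, surv$pos, surv$ref, surv$alt) %in%
                  variant_key(fx$tbl$chrom, fx$tbl$pos, fx$tbl$ref,
                              fx$tbl$alt)))
  again <- suppressMessages(
    run_cascade(surv, fx$stubs, fx$tg$model, fx$tg$reference,
                cohort = fx$cohort))
  expect_true(all(again$rare))
  # the membership check is conditioned on low recurrence: a variant that
  # fails recurrence is never tested against 1000 Genomes
  common <- ann[ann$pos == 300 & ann$chrom == "chrQ", ]
  expect_false(common$pass_recurrence)
  expect_true(is.na(common$pass_1000g))
})

test_that("a planted causal variant survives the simulated cascade", {
  cfg <- sim_config(seed = 31, n_genes = 4)
  panel <- simulate_panel(cfg)
  sim <- simulate_proband_variants(panel, cfg)
  foc <- sim$variants[sim$variants$proband == sim$focal_proband, ]
  ann <- suppressMessages(
    run_cascade(foc, sim$annotations, panel$gene_models, panel$reference,
                cohort = sim$variants))
  key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  expect_true(all(sim$truth$allele_id %in% key[ann$rare]))
  expect_equal(as.character(ann$effect[key == sim$truth$allele_id[1]]),
               "missense")
  # empty input gives empty output
  ann0 <- run_cascade(foc[0, ], sim$annotations, panel$gene_models,
                      panel$reference, cohort = sim$variants)
  expect_equal(nrow(ann0), 0L)
  expect_equal(nrow(proband_summary(cbind(ann0))), 0L)
})
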