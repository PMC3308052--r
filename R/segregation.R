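## Pedigree co-segregation of candidate alleles under recessive or dominant
## models with full penetrance. Pedigrees are standard 6-column PED tables;
## per-variant genotypes live in a sidecar table (member_id, allele_id,
## genotype in {ref, het, hom}); missing entries are unknown and never
## create violations.

#' Construct a pedigree
#'
#' @param members Data frame with columns `id`, `father`, `mother` (`NA` or
#'   "0" for founders), `sex` (1 male, 2 female, 0 unknown) and `affected`
#'   (logical, `NA` for unknown phenotype).
#' @param genotypes Data frame with columns `member_id`, `allele_id`,
#'   `genotype` ("ref", "het" or "hom"). Members or alleles absent from the
#'   table have unknown genotype.
#' @return A `pedigree` list.
#' @export
pedigree <- function(members, genotypes = NULL) {
  need <- c("id", "father", "mother", "sex", "affected")
  if (!all(need %in% names(members)))
    stop("members must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  members$id <- as.character(members$id)
  for (col in c("father", "mother")) {
    members[[col]] <- as.character(members[[col]])
    members[[col]][members[[col]] %in% c("0", "", NA)] <- NA_character_
    bad <- !is.na(members[[col]]) & !(members[[col]] %in% members$id)
    if (any(bad))
      stop("unresolved ", col, " reference: ",
           paste(members[[col]][bad], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(members$id))
    stop("duplicate member ids", call. = FALSE)
  if (is.null(genotypes))
    genotypes <- data.frame(member_id = character(), allele_id = character(),
                            genotype = character())
  if (nrow(genotypes) &&
      !all(genotypes$genotype %in% c("ref", "het", "hom")))
    stop("genotypes must be ref, het or hom", call. = FALSE)
  structure(list(members = members, genotypes = genotypes),
            class = "pedigree")
}

#' Read a 6-column PED file and genotype sidecar
#'
#' PED columns: family, id, father, mother, sex, phenotype (1 unaffected,
#' 2 affected, 0/-9 unknown).
#'
#' @param ped_path Path to the PED file (whitespace-separated, no header).
#' @param genotype_path Optional path to the sidecar TSV with header
#'   `member_id`, `allele_id`, `genotype`.
#' @return A `pedigree`.
#' @export
read_ped <- function(ped_path, genotype_path = NULL) {
  raw <- utils::read.table(ped_path, header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("family", "id", "father", "mother",
                                         "sex", "phenotype"))
  members <- data.frame(
    id = as.character(raw$id),
    father = as.character(raw$father),
    mother = as.character(raw$mother),
    sex = raw$sex,
    affected = ifelse(raw$phenotype == 2, TRUE,
               ifelse(raw$phenotype == 1, FALSE, NA)),
    stringsAsFactors = FALSE)
  genotypes <- if (!is.null(genotype_path))
    utils::read.delim(genotype_path, stringsAsFactors = FALSE) else NULL
  pedigree(members, genotypes)
}

#' Write a pedigree as PED plus genotype sidecar
#'
#' @param ped A `pedigree`.
#' @param ped_path,genotype_path Output paths.
#' @param family Family id written in column 1.
#' @return Paths, invisibly.
#' @export
write_ped <- function(ped, ped_path, genotype_path = NULL,
                      family = "FAM1") {
  m <- ped$members
  out <- data.frame(family = family, id = m$id,
                    father = ifelse(is.na(m$father), "0", m$father),
                    mother = ifelse(is.na(m$mother), "0", m$mother),
                    sex = m$sex,
                    phenotype = ifelse(is.na(m$affected), 0,
                                       ifelse(m$affected, 2, 1)))
  utils::write.table(out, ped_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(genotype_path))
    utils::write.table(ped$genotypes, genotype_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(c(ped_path, genotype_path))
}

## Genotype of `member` for `allele`: "ref"/"het"/"hom" or NA (unknown).
genotype_of <- function(ped, member, allele) {
  g <- ped$genotypes
  hit <- g$member_id == member & g$allele_id == allele
  if (!any(hit)) return(NA_character_)
  g$genotype[which(hit)[1L]]
}

carries <- function(g) if (is.na(g)) NA else g %in% c("het", "hom")

assert_allele_known <- function(ped, allele) {
  if (!allele %in% ped$genotypes$allele_id)
    stop("allele '", allele, "' absent from all genotype maps",
         call. = FALSE)
}

#' Phase two heterozygous alleles in a pedigree member
#'
#' Infers whether two alleles carried heterozygously by one member lie on
#' opposite chromosomes (trans, a true compound heterozygote) or on the same
#' chromosome (cis), from the parental genotypes: trans when each parent
#' carries exactly one of the two alleles (a different one each); cis when
#' one parent carries both and the other neither; unknown otherwise,
#' including when parents are missing or ungenotyped.
#'
#' @param ped A `pedigree`.
#' @param member Member id, heterozygous for both alleles.
#' @param allele_a,allele_b Allele ids.
#' @return "trans", "cis" or "unknown".
#' @export
phase_compound_het <- function(ped, member, allele_a, allele_b) {
  m <- ped$members[ped$members$id == member, , drop = FALSE]
  if (nrow(m) == 0L) stop("unknown member ", member, call. = FALSE)
  parents <- c(m$father, m$mother)
  if (any(is.na(parents))) return("unknown")
  pa <- vapply(parents, function(p)
    carries(genotype_of(ped, p, allele_a)), NA)
  pb <- vapply(parents, function(p)
    carries(genotype_of(ped, p, allele_b)), NA)
  if (any(is.na(pa)) || any(is.na(pb))) return("unknown")
  n_alleles <- pa + pb                      # alleles of the pair per parent
  if (all(n_alleles == 1L) && sum(pa) == 1L && sum(pb) == 1L)
    return("trans")
  if (any(n_alleles == 2L) && any(n_alleles == 0L))
    return("cis")
  "unknown"
}

## Does `member` carry two pathogenic alleles of the candidate (pair)?
## Returns TRUE/FALSE/NA (unknown), plus attribute "warning" when a
## compound het has uninferable phase.
two_pathogenic <- function(ped, member, allele_a, allele_b) {
  ga <- genotype_of(ped, member, allele_a)
  if (allele_a == allele_b) {
    if (is.na(ga)) return(NA)
    return(ga == "hom")
  }
  gb <- genotype_of(ped, member, allele_b)
  if (!is.na(ga) && ga == "hom") return(TRUE)
  if (!is.na(gb) && gb == "hom") return(TRUE)
  if (is.na(ga) || is.na(gb)) return(NA)
  if (ga == "het" && gb == "het") {
    ph <- phase_compound_het(ped, member, allele_a, allele_b)
    if (ph == "trans") return(TRUE)
    if (ph == "cis") return(FALSE)
    return(structure(NA, warning = "phase_unknown"))
  }
  FALSE
}

seg_result <- function(model, violations, warnings) {
  structure(list(consistent = nrow(violations) == 0L,
                 violations = violations,
                 warnings = warnings,
                 model = model),
            class = "segregation_result")
}

no_violations <- function()
  data.frame(member = character(), rule = character(),
             stringsAsFactors = FALSE)

#' Test co-segregation under an autosomal recessive model
#'
#' Under full penetrance with no phenocopies, every affected member must
#' carry two pathogenic alleles (homozygous for the candidate, or
#' heterozygous for both alleles of a compound pair in trans where phase is
#' inferable from the parents) and no unaffected member may. Unknown
#' genotypes, phenotypes or phases never create violations; an affected
#' compound heterozygote whose phase cannot be inferred is recorded as a
#' warning (consistent-with-warning), since a lone pair of heterozygous
#' calls is insufficient evidence on its own.
#'
#' @param ped A `pedigree`.
#' @param allele_a Candidate allele id.
#' @param allele_b Second allele of a compound pair; defaults to
#'   `allele_a` (simple homozygous model).
#' @return A `segregation_result`: `consistent`, `violations` (data frame
#'   of member/rule), `warnings`, `model`.
#' @export
check_recessive <- function(ped, allele_a, allele_b = allele_a) {
  stopifnot(inherits(ped, "pedigree"))
  assert_allele_known(ped, allele_a)
  if (allele_b != allele_a) assert_allele_known(ped, allele_b)
  violations <- no_violations()
  warnings <- character(0)
  for (i in seq_len(nrow(ped$members))) {
    id <- ped$members$id[i]
    aff <- ped$members$affected[i]
    if (is.na(aff)) next
    tp <- two_pathogenic(ped, id, allele_a, allele_b)
    if (!is.null(attr(tp, "warning")))
      warnings <- c(warnings, paste0(id, ": ", attr(tp, "warning")))
    if (is.na(tp)) next
    if (aff && !tp)
      violations <- rbind(violations, data.frame(
        member = id, rule = "affected_without_two_pathogenic_alleles"))
    if (!aff && tp)
      violations <- rbind(violations, data.frame(
        member = id, rule = "unaffected_with_two_pathogenic_alleles"))
  }
  seg_result("recessive", violations, warnings)
}

#' Test co-segregation under an autosomal dominant model
#'
#' Under full penetrance, every affected member must carry at least one
#' copy of the allele and no unaffected member may carry any. Unknown
#' genotypes or phenotypes abstain.
#'
#' @param ped A `pedigree`.
#' @param allele Candidate allele id.
#' @return A `segregation_result`.
#' @export
check_dominant <- function(ped, allele) {
  stopifnot(inherits(ped, "pedigree"))
  assert_allele_known(ped, allele)
  violations <- no_violations()
  for (i in seq_len(nrow(ped$members))) {
    id <- ped$members$id[i]
    aff <- ped$members$affected[i]
    if (is.na(aff)) next
    carrier <- carries(genotype_of(ped, id, allele))
    if (is.na(carrier)) next
    if (aff && !carrier)
      violations <- rbind(violations, data.frame(
        member = id, rule = "affected_non_carrier"))
    if (!aff && carrier)
      violations <- rbind(violations, data.frame(
        member = id, rule = "unaffected_carrier"))
  }
  seg_result("dominant", violations, character(0))
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf("Co-segregation (%s model): %s\n", x$model,
              if (x$consistent) "consistent" else "inconsistent"))
  if (nrow(x$violations)) {
    for (i in seq_len(nrow(x$violations)))
      cat(sprintf("  violation: %s (%s)\n", x$violations$member[i],
                  x$violations$rule[i]))
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
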