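## Founder-allele population statistics from cohort genotype counts:
## allele and carrier frequencies, exact case-control comparison on
## chromosome counts, and the attributable fraction with an exact lower
## bound.

#' Cohort genotype counts for one focal allele
#'
#' Counts of genotype classes with respect to one focal pathogenic allele in
#' a cohort of `n_individuals`: homozygotes (two focal copies), compound
#' heterozygotes (one focal copy plus one copy of a distinct pathogenic
#' allele of the same gene), and simple heterozygotes (one focal copy).
#'
#' @param n_individuals Cohort size.
#' @param n_hom,n_compound_het,n_het Genotype-class counts.
#' @param label "cases" or "controls".
#' @return A `cohort_counts` list.
#' @examples
#' # 52 deaf probands: 10 hom, 6 compound het, 9 het for the focal allele
#' cohort_counts(52, n_hom = 10, n_compound_het = 6, n_het = 9, "cases")
#' @export
cohort_counts <- function(n_individuals, n_hom = 0L, n_compound_het = 0L,
                          n_het = 0L, label = c("cases", "controls")) {
  label <- match.arg(label)
  stopifnot(n_individuals >= 1, n_hom >= 0, n_compound_het >= 0, n_het >= 0)
  if (n_hom + n_compound_het + n_het > n_individuals)
    stop("genotype-class counts exceed the number of individuals",
         call. = FALSE)
  structure(list(n_individuals = as.integer(n_individuals),
                 n_hom = as.integer(n_hom),
                 n_compound_het = as.integer(n_compound_het),
                 n_het = as.integer(n_het),
                 label = label),
            class = "cohort_counts")
}

focal_chromosomes <- function(c) 2L * c$n_hom + c$n_compound_het + c$n_het

#' Allele frequency of the focal allele
#'
#' Each homozygote contributes two focal chromosomes; compound and simple
#' heterozygotes contribute one each; the denominator is the total
#' chromosome count `2 * n_individuals`.
#'
#' @param c A `cohort_counts` object.
#' @return Proportion in \[0, 1\].
#' @examples
#' allele_frequency(cohort_counts(52, 10, 6, 9, "cases"))  # 35/104 = 0.337
#' @export
allele_frequency <- function(c) {
  stopifnot(inherits(c, "cohort_counts"))
  focal_chromosomes(c) / (2 * c$n_individuals)
}

#' Carrier frequency of the focal allele
#'
#' Fraction of individuals carrying at least one focal copy.
#'
#' @inheritParams allele_frequency
#' @return Proportion in \[0, 1\].
#' @export
carrier_frequency <- function(c) {
  stopifnot(inherits(c, "cohort_counts"))
  (c$n_hom + c$n_compound_het + c$n_het) / c$n_individuals
}

#' Case-control comparison of focal-allele frequency
#'
#' Builds the 2x2 table of focal versus other chromosomes in cases and
#' controls and tests for a frequency difference. The default is the
#' two-sided Fisher exact test, appropriate for founder alleles in small
#' cohorts; Pearson's chi-square on the same table (without continuity
#' correction) is available as an option. The odds ratio is the sample odds
#' ratio with the Haldane-Anscombe 0.5 correction applied when any cell is
#' zero.
#'
#' @param cases,controls `cohort_counts` objects.
#' @param method "fisher" or "chisq".
#' @return A `case_control_result` list: `case_freq`, `control_freq`,
#'   `odds_ratio`, `p_value`, `table` (2x2 chromosome counts), `method`.
#' @export
case_control_test <- function(cases, controls,
                              method = c("fisher", "chisq")) {
  method <- match.arg(method)
  stopifnot(inherits(cases, "cohort_counts"),
            inherits(controls, "cohort_counts"))
  a <- focal_chromosomes(cases);    n1 <- 2L * cases$n_individuals
  c_ <- focal_chromosomes(controls); n2 <- 2L * controls$n_individuals
  tab <- matrix(c(a, n1 - a, c_, n2 - c_), nrow = 2, byrow = TRUE,
                dimnames = list(c("cases", "controls"),
                                c("focal", "other")))
  p <- switch(method,
    fisher = stats::fisher.test(tab)$p.value,
    chisq = stats::chisq.test(tab, correct = FALSE)$p.value)
  ha <- if (any(tab == 0)) 0.5 else 0
  or <- ((tab[1, 1] + ha) * (tab[2, 2] + ha)) /
        ((tab[1, 2] + ha) * (tab[2, 1] + ha))
  structure(list(case_freq = a / n1,
                 control_freq = c_ / n2,
                 odds_ratio = or,
                 p_value = p,
                 table = tab,
                 method = method),
            class = "case_control_result")
}

#' @export
print.case_control_result <- function(x, ...) {
  cat(sprintf("Case-control allele comparison (%s)\n", x$method))
  cat(sprintf("  case freq %.3f (%d/%d), control freq %.3f (%d/%d)\n",
              x$case_freq, x$table[1, 1], sum(x$table[1, ]),
              x$control_freq, x$table[2, 1], sum(x$table[2, ])))
  cat(sprintf("  OR = %.1f, p = %.3g\n", x$odds_ratio, x$p_value))
  invisible(x)
}

#' Attributable fraction of solved cases
#'
#' Share of a cohort explained by pathogenic genotypes in one gene, with a
#' one-sided exact binomial lower confidence bound supporting "at least x%"
#' statements.
#'
#' @param n_solved Number of cohort members with a causal genotype.
#' @param n_total Cohort size.
#' @param conf_level Confidence level for the one-sided lower bound.
#' @return List with `estimate`, `lower_bound`, `n_solved`, `n_total`,
#'   `conf_level`.
#' @examples
#' attributable_fraction(20, 52)  # 38.5% of cases explained
#' @export
attributable_fraction <- function(n_solved, n_total, conf_level = 0.95) {
  stopifnot(n_total >= 1, n_solved >= 0, n_solved <= n_total)
  bt <- stats::binom.test(n_solved, n_total, alternative = "greater",
                          conf.level = conf_level)
  list(estimate = n_solved / n_total,
       lower_bound = bt$conf.int[1],
       n_solved = as.integer(n_solved),
       n_total = as.integer(n_total),
       conf_level = conf_level)
}

#' Read cohort counts from a TSV
#'
#' Expects columns `label`, `n_individuals`, `n_hom`, `n_compound_het`,
#' `n_het`; one row per cohort.
#'
#' @param path Path to the TSV.
#' @return List of `cohort_counts`, named by label.
#' @export
read_cohort_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    cohort_counts(df$n_individuals[i], df$n_hom[i], df$n_compound_het[i],
                  df$n_het[i], df$label[i]))
  stats::setNames(out, df$label)
}
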