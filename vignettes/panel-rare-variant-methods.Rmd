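---
title: "Methods: capture design, rare-variant filtering and founder-allele statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: capture design, rare-variant filtering and founder-allele statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelseeker)
```

# The problem

In genetically heterogeneous Mendelian conditions such as inherited hearing
loss, dozens to hundreds of genes can each explain a small share of cases.
A practical diagnostic workflow captures all exons of a candidate-gene
panel, sequences each proband to very high depth, and then faces two
statistical problems: separating the one causal allele from thousands of
benign variants, and quantifying founder alleles once a mutation recurs in
a population. panelseeker implements that workflow as composable pieces —
capture design, coverage QC, zygosity calling, a filter cascade, pedigree
co-segregation and cohort statistics — plus a synthetic-data generator that
makes every piece testable without raw reads.

# Capture design

Exons (coding and UTR) are expanded by a symmetric intronic flank (default
40 bp, so canonical splice sites are always captured) and merged into
disjoint targets. Baits of fixed length $L$ (default 120) are laid under a
centered $k$-fold tiling: the bait grid has step $s = L/k$ (default
$120/3 = 40$) and is anchored so one bait is centered on the target
midpoint $m = \lfloor (start + end)/2 \rfloor$; every grid bait overlapping
the target by at least one base is a candidate. This makes the candidate
set deterministic and symmetric, and it covers *every* target base with
exactly $k$ candidates (a grid of step $s$ has exactly $L/s = k$ starts in
any half-open window of length $L$). Targets shorter than a bait still
receive $k$ overhanging candidates, which is what allows small exons hemmed
in by interspersed repeats to be captured at all.

A candidate is rejected when its total overlap with repeat-masked bases —
summed over all repeat elements it touches — exceeds a per-bait budget
(default 20 bp). The budget is per bait, not per repeat element: it is a
bound on how much repeat sequence a single capture probe may drag in.
Segmental duplications are deliberately *not* excluded; only the
repeat-overlap rule applies.

`summarize_design()` reports the capture size (target bases under at least
one accepted bait) and the failed fraction both by base and by region,
since "x% of regions failed" and "x% of bases failed" can differ wildly
when repeats blanket a few whole targets. If `bait_length` is not divisible
by `tiling_factor` the step is floored and a warning is emitted; the
defaults never hit this.

# Coverage QC

`coverage_stats()` reports the median per-base depth and the fractions of
target bases covered by **more than** 10 and more than 30 reads — strict
inequalities, because those are the two depth cutoffs used for variant
detection (10 is the default `min_depth`; 30 is exposed as the stricter
option). `on_target_rate()` counts a read as on-target when it overlaps the
bait-covered capture region by at least one base, matching the practice of
aligning against the capture-target BED and discarding everything else.

# Zygosity and cryptic indels

For a site with $r$ reference and $v$ variant reads, the variant allele
fraction is $\mathrm{VAF} = v/(r+v)$. The classification is a step
function with two thresholds:

* homozygous if VAF $\ge$ `hom_min` (default 0.80),
* heterozygous if `het_min` $\le$ VAF $<$ `hom_min` (default `het_min` = 0.30),
* weakly supported if $0 <$ VAF $<$ `het_min`,
* reference if $v = 0$.

The defaults are set from observed behaviour of true genotypes at high
depth: genuine heterozygotes sit near 48–51% support, genuine homozygotes
near 100%, and sites near 25% are anomalous. Both boundaries are closed on
the upper class and are tested exactly at the threshold. At depth
$\ge 100$ the binomial spread of the VAF makes misclassification of a true
heterozygote or homozygote vanishingly rare (the suite checks $\ge 99.9\%$
over $10^4$ draws).

Anomalous sites matter because alignment can misread a short
insertion/deletion as two nearby substitutions, each supported by a
similar, sub-heterozygous fraction of reads (about 25% each for a
heterozygous 2-bp deletion). `detect_cryptic_indels()` merges every maximal
run of $\ge 2$ weakly supported substitutions with successive gaps
$\le$ `max_gap` (default 3 bp, covering the printed 2-bp case with margin)
and pairwise variant-read ratios $\le$ `ratio_tol` (default 1.5, "similar
numbers of reads") into one indel candidate, removing the member sites
from the substitution stream. A candidate is resolved when a truth source
(in synthetic runs, the planted indel table) overlaps its span; otherwise
it stays a candidate for external confirmation, which is exactly the status
such sites have in practice before Sanger sequencing.

# The filter cascade

Filters are applied per proband in the order dbSNP → conservation →
recurrence → population membership; a variant stops at its first failure
and the per-filter verdicts (`pass_*`, with `NA` for filters never reached)
form its audit trail.

1. **dbSNP with clinical rescue.** Database membership alone is not
   grounds for exclusion, because the database mixes benign and
   disease-associated alleles; known variants are removed only when not
   clinically flagged.
2. **Conservation.** Substitutions at sites with PhyloP score below 0.9
   are discarded as non-conserved; the threshold is strict (0.90 passes,
   0.89 fails). Indels are exempt — the score is defined for the consensus
   nucleotide of a substitution site. Missing scores pass by default (with
   a message) and can be made failing.
3. **Recurrence.** Sequencing several probands from the same ethnic groups
   is itself a powerful filter: a "novel" variant carried by more than 3
   probands (any zygosity) is almost certainly a population-specific
   polymorphism, not a private mutation, and is removed.
4. **Population membership.** Variants passing the recurrence filter are
   checked against 1000 Genomes membership and, optionally, a list of
   other published genomes from hearing individuals.

The dbSNP, conservation and membership filters commute (the suite asserts
identical survivor sets under permuted orders); recurrence is kept ahead of
the membership check because only low-recurrence variants are conditioned
on it. PolyPhen-2 HumVar and SIFT scores are attached to survivors as
annotations but are **never** used as filters — validation is by
segregation, not by score cutoff.

Survivors are classified at codon level against plus-strand toy gene
models (exon boundaries, a CDS interval in frame, the chromosome sequence):
substitutions translate the affected codon (synonymous / missense /
nonsense), indels touching coding bases are frameshift or in-frame by
length mod 3, intronic sites within `splice_window` of an exon boundary
(default 2 bp, the canonical donor/acceptor; configurable up to the 40-bp
captured flank) are splice-junction, exonic non-coding sites are UTR, and
everything else — including sites outside any transcript — is intronic.
"Potentially functional" means nonsense, missense, splice junction or
frameshift; synonymous, UTR, intronic and in-frame changes are counted as
rare but not as functional.

# Co-segregation

Pedigrees are standard 6-column PED plus a genotype sidecar
(member, allele, ref/het/hom); absent entries are unknown. Both checkers
assume full penetrance, no phenocopies and no de novo events — the same
qualitative standard used when a family is read by eye — and unknown
genotypes or phenotypes never create violations (so adding an ungenotyped
relative can never flip a consistent family to inconsistent; the suite
checks this monotonicity).

* **Recessive:** every affected member must carry two pathogenic alleles —
  homozygous for the candidate, or heterozygous for both members of a
  compound pair *in trans*; no unaffected member may. Phase is inferred
  from the parents: trans when each parent carries exactly one (different)
  allele of the pair, cis when one parent carries both and the other
  neither, unknown otherwise. An affected compound heterozygote with
  uninferable phase is consistent-with-warning: a lone pair of
  heterozygous calls is insufficient evidence, as a heterozygous carrier's
  condition may be due to another gene entirely.
* **Dominant:** affected if and only if carrier.

X-linkage is out of scope; all models are autosomal. The checkers are
verified against independently written rule enumerations and a
gamete-enumeration phasing oracle over exhaustive small-pedigree genotype
grids and random 8-member families.

# Founder-allele statistics

From genotype-class counts over $N$ individuals ($2N$ chromosomes), the
focal allele frequency is $(2\,hom + compound + het)/2N$ — a compound
heterozygote contributes one focal chromosome, with the second pathogenic
allele counted toward its own tally — and the carrier frequency is
$(hom + compound + het)/N$.

The case-control comparison builds the 2×2 table of focal versus other
chromosomes. The default test is the two-sided Fisher exact test, the
appropriate exact choice for founder-allele tables with small or empty
cells; Pearson's chi-square without continuity correction is available via
`method = "chisq"`. On extremely unbalanced tables the two differ by many
orders of magnitude — for the 35/104 versus 16/564 founder table the exact
test gives $p \approx 2.4\times10^{-19}$ while the chi-square gives
$p \approx 1.5\times10^{-27}$ — so the method is always reported alongside
the p-value. The odds ratio uses the Haldane–Anscombe 0.5 correction when
a cell is zero. Chromosomes are treated as independent (Hardy–Weinberg,
unrelated individuals); kinship correction is out of scope.

`attributable_fraction()` supports "this gene explains at least x% of
cases" statements with an exact one-sided lower binomial bound rather than
a bare point estimate.

# The synthetic-data generator

The generator's defaults are the study conditions the pipeline is meant to
operate under: 11 probands; median per-base depth 937 (the average for two
multiplexed samples per lane) with a lognormal spread (`depth_sigma` 0.35)
and AR(1) short-range autocorrelation on the log scale; 5% of target bases
forced below 10 reads in contiguous blocks, mimicking coverage loss
concentrated in GC-rich regions; 8% of target bases inside repeat
intervals; a founder allele at frequency 0.337 in 52 cases versus 0.028 in
282 controls, with a second pathogenic allele at 0.058 among case
chromosomes for the compound-heterozygote structure. The panel itself is
scaled down to `n_genes` toy genes (default 8; 5 in the replicated
recovery runs) with 3–8 exons of 90–240 bp so that a full simulated study
runs in well under a second; gene count affects only runtime, not the
statistical structure of any downstream test.

Each toy gene lives on its own toy chromosome with 30-bp UTRs and a coding
sequence in frame (ATG start, no internal stops, terminal stop), so codon
level effect classification is exercised for real. Per-proband variant
tables mix: population-common polymorphisms shared by $\ge 4$ probands
(never placed in the dbSNP stub — the recurrence filter, not the database,
is what removes population-specific alleles); private background variants
each carrying one benign signature (dbSNP membership with probability
`dbsnp_overlap`, otherwise a low conservation score or 1000 Genomes
membership); a small number of private, conserved, database-absent benign
variants that survive every filter and can only be removed by
co-segregation (heterozygous with probability 0.95 — rare alleles are
almost always carried heterozygously); and one planted causal allele with
read support Binomial(depth, 0.5) for heterozygotes or Binomial(depth,
0.995) for homozygotes. The homozygous support probability is 0.995 rather
than 1.0 so the homozygosity threshold is actually exercised; a true
0-reference-reads fixture also appears in the tests. Cryptic-indel
fixtures emit a 2-bp deletion as two substitutions 2 bp apart, each
Binomial(depth, 0.25).

Pedigrees are nuclear families (2 parents, 4 children) with the causal
allele segregating per the configured model and the proband forced to the
causal genotype; background alleles enter through randomly assigned carrier
parents and Mendelian transmission. Cohort genotypes are drawn per
chromosome, so Hardy–Weinberg consistency holds by construction and is
verified by goodness-of-fit across seeds.

What passing tests on this generator do show: the filter logic, the
zygosity thresholds, the tiling arithmetic, the segregation rules and the
founder statistics behave correctly on data with the assumed statistical
structure, and the full pipeline recovers a planted causal allele as the
sole co-segregating survivor in $\ge 95\%$ of replicate studies. What they
do not show: robustness to alignment artifacts other than the modeled
cryptic-indel signature, base-quality effects, population stratification,
relatedness among "unrelated" cohort members, or real repeat/GC sequence
composition — the generator places repeats and dropout blocks by position,
not by sequence content, and simulates no reads.

# Numerical and design choices

* Intervals are held as `GRanges` (1-based, closed) in memory; BED I/O via
  rtracklayer keeps the on-disk 0-based half-open convention; variant
  tables are 1-based. Tiling arithmetic is done 0-based internally.
* Indels use the simple non-anchored representation (a 2-bp deletion is
  `ref = "CG"`, `alt = ""`, `pos` = first deleted base).
* Multi-allelic sites are separate observations sharing reference reads,
  keeping the VAF well defined per alternate allele.
* `min_depth` defaults to 10, the looser of the two detection cutoffs,
  with 30 available by argument.
* Zygosity thresholds `het_min = 0.30` / `hom_min = 0.80` are closed on
  the upper class; boundary behaviour is pinned by tests.
* Replicated statistical tests in the suite run at sample sizes where
  Monte Carlo noise cannot mask the tested property (e.g. 1000 cohort
  replicates against a 93% coverage bound whose true rate is ~96%), with
  all seeds fixed.
* Degenerate inputs fail loudly: empty depth vectors, zero-read sites,
  zero-size cohorts, unresolved parent references, planted sites outside
  the panel, and reference windows not covering an indel-candidate span
  are all rejected with errors rather than propagated.

# Limitations

The gene models are plus-strand toys; HGVS-style naming, strand-aware
annotation and transcript isoforms are out of scope, as are genotype
likelihoods, linkage LOD scores, haplotype inference beyond trio phasing,
CNV detection and kinship-aware association. The capture-design module
reproduces the tiling *rules*, not any vendor's proprietary bait placement,
so published bait counts for real panels are not expected to be reproduced
from coordinates alone.
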