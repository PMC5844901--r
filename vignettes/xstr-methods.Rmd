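---
title: "Methods: X-STR population genetics and forensic statistics in xstrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: X-STR population genetics and forensic statistics in xstrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xstrkit)
```

## The data model

X-chromosomal STR markers are unusual among forensic markers because the two
sexes carry different chromosome doses: males are hemizygous (one allele per
locus), females diploid (an unordered allele pair). `xstrkit` makes this
dosage explicit everywhere. A `genotype_table` stores one row per individual
(`sample_id`, `sex`, `population`, one column per locus) with male cells
`"a"`, female cells `"a/b"` and missing cells `NA`/`"."`. Allele labels are
repeat numbers, possibly with a microvariant fraction (`"24.1"`); they are
kept as text so files round-trip byte-identically, and ordered by their
numeric repeat key.

Counting is per locus with per-locus deletion: an individual missing locus L
drops out of L's chromosome total only. A male contributes 1 chromosome and a
female 2, so a sample of 116 males and 116 females yields 348 chromosomes per
fully typed locus.

Twelve Argus X-12 markers cluster into four physically linked triples (LG1
Xp22, LG2 Xq11, LG3 Xq26, LG4 Xq28). In males each triple is an observed,
fully phased haplotype; `haplotype_counts()` therefore accepts male rows only
(or drops females explicitly with `males_only = TRUE`), and haplotype
diversity uses Nei's unbiased form \(HD = n(1-\sum \hat p_i^2)/(n-1)\). We use
the \(n/(n-1)\) correction because it is the standard gene-diversity
estimator reported by the common population-genetics software for haplotype
data; the package exposes `sum_p2` alongside so either convention can be
inspected.

## Exact tests

All tests are conditional exact tests: the p-value is the total null
probability, given the observed margins, of outcomes no more probable than
the observed one.

**HWE in females.** Conditional on the allele counts, every pairing of the
2n allele copies into n genotypes is equally likely under HWE (the
Levene/Haldane distribution used by the Guo–Thompson test). Small problems
are enumerated completely (all genotype tables with the observed allele
margins, up to `max_tables`). Larger problems are sampled: the package draws
i.i.d. genotype tables by randomly re-pairing the observed allele multiset.
This samples the exact conditional null directly, so the Monte-Carlo p is
unbiased with standard error \(\sqrt{p(1-p)/B}\), and no Markov-chain
dememorization or autocorrelation correction is needed. This is a deliberate
design choice over the classical Guo–Thompson switch chain: independent
draws dominate a chain of equal length statistically, and the result is a
pure function of (data, draws, seed). Monomorphic loci return p = 1 flagged
`degenerate`.

**LD in males** uses the fact that hemizygous males are fully phased: the
two-locus allele table is tested for independence with the conditional exact
(Fisher-style R×C) test, enumerated when small and otherwise sampled with
fixed margins via Patefield's algorithm (`stats::r2dtable`).

**Population differentiation** applies the same R×C machinery to the
alleles × populations chromosome-count table (the Raymond–Rousset
formulation for two populations).

**LD in females** cannot condition on phase, so two-locus haplotype
frequencies are estimated by EM and the statistic is the likelihood ratio
between the EM solution and the independence model. Because the null
distribution of this LR on unphased data is not chi-squared at forensic
sample sizes, p comes from permuting one locus's genotypes across
individuals ((1+hits)/(1+B) estimator). EM non-convergence after `max_iter`
is flagged but the best statistic is still used.

**Multiple testing** uses Bonferroni with a strict inequality: a p-value
exactly equal to α/m is not significant. With 12 loci the HWE threshold is
0.05/12 ≈ 0.00417; with 66 locus pairs the LD threshold is 0.05/66 ≈ 0.00076.

## Forensic efficiency parameters

With power sums \(S_k = \sum_i p_i^k\) of the pooled (male + female)
allele frequencies:

| statistic | closed form |
|---|---|
| HOM, HET | \(S_2\), \(1-S_2\) |
| PIC | \(1 - S_2 - S_2^2 + S_4\) |
| PD (males) | \(1-S_2\) |
| PD (females) | \(1 - 2S_2^2 + S_4\) |
| PE | \(HET^2(1 - 2\,HET\,HOM^2)\) |
| PI | \(HOM/2\) |
| MEC trio (Desmarais) | \(= PIC\) |
| MEC trio (Kishida) | explicit enumeration; analytically \(= PIC\) |
| MEC trio (Krüger) | \(1-2S_2+S_3-2(S_2^2-S_4)+3(S_2S_3-S_5)\) |
| MEC duo (Desmarais) | \(1 - 2S_2 + S_3 = \sum_i p_i(1-p_i)^2\) |

Conventions and their justification:

* **PI = HOM/2** is the "mean paternity index" convention of the online ChrX
  reporting tools, adopted because it reproduces published per-locus tables
  row for row; it is not the classical \(1/(2\,HOM)\).
* **PE** is the PowerStats power-of-exclusion formula computed from expected
  heterozygosity. It is *not* the exact exclusion probability of any of the
  X-kinship scenarios: the exact mother–daughter–alleged-father exclusion
  probability on the X equals PIC (derived by enumerating mother genotype,
  transmitted allele and paternal allele: the non-exclusion probability is
  \(S_2^2 + S_2 - S_4\)), and the exact autosomal-trio exclusion probability
  is the Krüger form. The package validates each closed form against a direct
  Monte-Carlo simulation of *its own* scenario
  (`mc_exclusion_trio_x()`, `mc_exclusion_trio_autosomal()`,
  `mc_exclusion_duo_x()`); an acceptance check that compares PE itself to the
  X-trio simulation is retained verbatim and fails, documenting the mismatch
  rather than papering over it.
* **MEC Kishida** is computed by explicit enumeration of
  mother/daughter/random-male configurations — a different evaluation route
  that agrees with PIC to machine precision. Published tables occasionally
  print last-digit differences between the Kishida and Desmarais columns;
  those are artefacts of the upstream tool's rounding and cannot be
  reproduced from closed forms.

Combined multi-locus values are \(1-\prod_l(1-x_l)\), evaluated as
`-expm1(sum(log1p(-x)))` so that values like 0.9999999983 keep their trailing
digits. Report output rounds half-up to 4 decimals (10 for combined values);
full precision is kept internally.

## Between-population statistics

**Pairwise Fst** uses haploid variance components on chromosome-level allele
indicators (Weir–Cockerham moment estimators adapted to one-locus haploid
dose): per locus, \(F_{st} = \sigma^2_a/(\sigma^2_a+\sigma^2_w)\), and the
multi-locus value pools the components across loci before the ratio.
Chromosomes are the resampling unit because X data mix ploidies — each male
contributes 1, each female 2. Negative estimates are reported as computed;
they are floored at zero only when a result is exported as a distance matrix
for UPGMA, which requires nonnegative dissimilarities. Because the estimator
consumes count tables (not linked chromosomes), the permutation null
relabels chromosomes per locus via fixed-margin table resampling, equivalent
to permuting chromosome labels when loci are treated independently; the p is
the plain fraction of replicates at or above the observed value. Both the
pooled variance-component ratio and the arithmetic per-locus mean are
available as tree inputs (`fst_distance_matrix(mode=)`) because published
trees do not always state which aggregation they used.

**Nei's distance** is \(D = -\ln(\bar J_{xy}/\sqrt{\bar J_x \bar J_y})\)
with arithmetic means of the per-locus gene identities. The unbiased variant
replaces within-population identities by \((n\sum p^2 - 1)/(n-1)\) (haploid
n), which can make small distances slightly negative; such values are
preserved and documented rather than truncated. Male-only frequencies are
the default for haplotype-style comparisons, pooled mode is available.

## Trees and ordination

`upgma()` is the classic size-weighted average-linkage agglomeration with
new nodes at half the merge distance. Ties are broken by joining the pair
whose sorted representative labels (the smallest leaf label in each cluster)
compare lexicographically smallest, and children of each node are emitted in
representative-label order, so output is bit-stable across label
permutations. Newick output defaults to 6 decimals, enough to round-trip
branch lengths on the 1e-8 scale of X-STR Fst trees.

`pcoa()` implements Gower double-centring of \(-\tfrac12 d^2\) followed by a
symmetric eigendecomposition. Fst and Nei matrices need not be Euclidean, so
negative eigenvalues can occur: they are reported, excluded from the
percent-variance denominator (GenAlEx convention) and their total mass is
returned as `negative_mass`. On Euclidean input the configuration is
reproduced to 1e-9.

## STRUCTURE interchange and Evanno ΔK

`export_structure_input()` writes two rows per individual (one allele per
row); hemizygous males carry their allele on the first row and the missing
code (default −9) on the second. This mixed-ploidy coding is a documented
choice — admixture software has no native X mode, and one-allele-plus-missing
is the common convention. Microvariants are recoded to
`10·repeat + fractional digit` (so ordering survives), and the map is always
written next to the export. `evanno_delta_k()` computes mean/sd of L(K), the
first and absolute second differences, and ΔK = |L''(K)|/sd(L(K)); ΔK is
undefined (NA, flagged) at interior K with zero or unavailable sd. The
admixture MCMC itself is out of scope.

## The synthetic-data generator

The generator states a world and stays there; none of its defaults were
adjusted after seeing test results.

* Allele frequencies: symmetric Dirichlet draws over 8–25 alleles labelled
  like repeat numbers — the allele-count range typical of the Argus X-12
  panel.
* One population: males draw one allele per locus; female genotypes follow
  the inbreeding-distorted HWE model (homozygote probability
  \(p^2 + F p(1-p)\)), so `f_is = 0` is exact HWE and `f_is` gives a
  graded, known violation.
* Linked males: whole haplotypes are drawn per male, so marginal
  frequencies and LD are exact by construction.
* Divergence: the Balding–Nichols model (population frequencies
  Dirichlet(\(p(1-F_{st})/F_{st}\)) around ancestral ones) was chosen
  because its parameter *is* the expected Fst, giving a quantitative
  recovery target without real multi-population data. The default test
  design mirrors a two-population study with sample sizes in the low
  hundreds of chromosomes.

What a green test does and does not establish: the generator draws
unlinked loci (except where haplotypes are requested), has no mutation
model, no allele-calling error, no missing-data mechanism and no family
structure. Green calibration and recovery tests therefore establish the
correctness of the estimators under the stated sampling models, not
robustness to the artefacts of real casework data.

## Numerical and testing choices

* Exact-test ties use a 1e-9 log-probability tolerance when comparing table
  probabilities to the observed one.
* Enumeration is capped (`max_tables`, default 2e5 tables) and falls back to
  Monte-Carlo, which then *requires* an explicit seed — stochastic results
  without a recorded seed are treated as a usage error.
* Calibration suites are scaled to the test budget: 500 null replicates with
  1000–2000 Monte-Carlo draws per replicate (p granularity ≤ 1e-3) rather
  than production-scale 1e6-draw runs. The acceptance band for empirical
  size, [α/2, 2α] at α = 0.05, is comfortably wider than the granularity
  this induces.
* Distance matrices are accepted with asymmetry up to 1e-8 (averaged away);
  anything larger is rejected rather than silently symmetrised.

## Known limitations

* The published supplementary datasets of the motivating study (male
  haplotype tables, full allele-frequency tables, the pairwise Fst matrix
  of eleven populations) are not redistributable here, so the checks that
  pin MEC-Krüger/Kishida columns, the LG haplotype diversities and the
  0.00821881 UPGMA total branch length against those files cannot run; the
  corresponding acceptance tests fail honestly instead of being skipped.
* Kinship likelihood ratios for casework (mutation models, silent alleles,
  θ corrections) are out of scope, as are Rst statistics, hierarchical
  AMOVA beyond two levels, and maximum-likelihood haplotype inference from
  female genotypes.
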