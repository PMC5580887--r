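---
title: "Models and methods behind evoherit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind evoherit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoherit)
```

# The experimental design the package models

A biparental yeast cross (RM × BY style) yields a panel of recombinant
haploid founders, each carrying a random mosaic of the two parental genomes.
Every founder seeds replicate populations that evolve independently for
hundreds of generations in each of two environments — an optimal-temperature
rich-medium condition ("OT") and a high-temperature synthetic-medium
condition ("HT"). Fitness is assayed by competition against a fluorescent
reference strain, before and after evolution, in both environments. A subset
of evolved populations is whole-population sequenced to identify de novo
mutations.

Three questions structure the analysis: how much of the variation in the
*rate of adaptation* (the fitness increment ΔX) is heritable; how well founder
fitness and individual loci predict it; and whether founder genotype and
environment shape *which* mutations accumulate.

# Estimators

## Fitness from competition counts

`estimate_fitness()` inverts the exponential-growth model of a two-strain
competition: with evolved and reference counts at two timepoints separated by
τ generations, `s = (1/τ) ln[(n_e,f − p n_r,f)/n_r,f × n_r,i/(n_e,i − p n_r,i)]`
per generation. The correction `p` handles a reference strain of which a
fraction `1 − p` fluoresces: at HT the default is `p = 0.015`, at OT `p = 0`.
Counts are accepted as nonnegative reals because flow cytometers report
proportions of a fixed event total. The estimator is antisymmetric under
swapping the roles of the strains and invariant to rescaling all counts,
and both properties are tested.

`summarize_replicates()` returns the mean of technical replicates and the
error variance **of the mean** (unbiased sample variance divided by the
replicate count). The variance-of-the-mean convention is a deliberate design
choice: the broad-sense partition below subtracts this quantity from the
variance of founder means, and only this scaling makes the fitness
heritability of a low-noise assay approach 1. The raw replicate variance is
recoverable by multiplying back.

## Broad-sense heritability

For founder fitness, the observed variance of founder means is split into a
measurement-error component (the average error variance of the means) and a
genetic remainder. For fitness increments, the within-founder component
`σ²_p = (1/n) Σ_i [n_i/(n_i − 1)] Σ_j (ΔX_ij − ΔX̄_i)²` absorbs both
measurement error and evolutionary stochasticity; what is left of the total
is attributed to founder genotype. Divisors follow the population-style
`1/n` convention of the estimating equations throughout, not the `1/(n−1)`
sample convention — the difference is negligible at panel scale but the
printed formulas are authoritative for this package. A negative genetic
component (possible when noise dominates) is reported raw, alongside a
`[0, 1]`-clipped heritability for summaries; both are exposed because
unbiasedness and interpretability pull in different directions.

Confidence intervals use a delete-half jackknife over founders: the
statistic is recomputed on 1000 random subsets of ⌈n/2⌉ founders (default;
seeded) and the 2.5/97.5 percentiles reported. The resample count and the
percentile construction are package choices — the half-sample size is the
defining feature. Founders contributing a single population are excluded
from the increment partition with a warning, because their within-founder
variance is inestimable.

## Narrow-sense heritability by REML

Additive heritability uses the standardized kinship
`R = GGᵀ`, `g_ik = (x_ik − p_k)/√(m p_k (1 − p_k))` with `x_ik ∈ {0, 1}` the
BY-allele indicator and `p_k` the panel BY-allele frequency, so
`diag(R) ≈ 1`. The variance model `V = R σ²_a + I σ²_e` with an
intercept-only fixed effect is fit by restricted maximum likelihood: one
eigendecomposition of `R`, then a bounded one-dimensional search (tolerance
1e−6) over the ratio `λ = σ²_a/(σ²_a + σ²_e)`, profiling `σ²_a` in closed
form. Reported `h² = σ̂²_a / Var(trait)`. Boundary estimates are flagged,
and the profiled restricted likelihood is returned so tests can verify the
optimum dominates random admissible points. Monomorphic loci are rejected
(they carry no information and break the standardization); allele
frequencies are fixed from the full panel, including inside jackknife
resamples.

Two properties of this estimator deserve note. First, identifiability of
`σ²_a` comes from the eigenvalue *spread* of `R`: a linkage-structured panel
(as this cross is) identifies the additive component well, whereas a
hypothetical panel with `R ≈ I` cannot. For pure-noise traits the estimate
therefore concentrates near zero but retains an upper tail; the test suite
asserts the concentration, not an arbitrary tail bound. Second, REML is
calibrated in expectation when effects are drawn from the random-effect
model across all loci; a trait driven by a handful of large-effect QTLs
(like founder fitness here) is a single sparse draw from a different
architecture, and its `h²` estimate can sit below the variance explained by
the detected QTLs themselves. This mirrors the generic behaviour of
kinship-based REML under architecture mismatch and is visible in the
pipeline output on synthetic data.

## Iterative QTL scan

The forward scan alternates residualization and genome-wide search. At
iteration k+1 the trait is residualized by OLS on the k detected QTLs
(alleles coded ±1/2); every locus is scored by
`LOD = −(n/2) log10(1 − r²)` where `r` is the Pearson correlation between
its code and the residuals, weighted by the square root of each founder's
technical replicate count. The largest LOD is tested against its
genome-wide permutation null — residual values are permuted while weights
stay attached to genotypes, the add-one p-value
`(1 + #{null max ≥ observed})/(1 + n_perm)` is used, and scanning stops when
`p > α` (default 0.05) or a safety cap of 20 QTLs is reached. Each hit
carries a positional confidence interval: the maximal contiguous run of
loci on the peak's chromosome with LOD within 1.5 of the peak. Ties at the
peak break to the lowest locus index. Permuting residuals (rather than the
raw trait jointly with weights) was an open choice; it keeps the null
conditional on the already-detected QTL structure.

Because the test statistic is the genome-wide maximum, one permutation null
per iteration controls the genome-wide false-positive rate at α per
iteration; the suite verifies both the rate (binomial band over 200 null
scans) and the uniformity of the first-iteration p-value.

## Fitness-based models

Adaptability regressions are fit on founder means of the replicate
populations, unweighted — the natural scale for a founder-level rule — with
per-population fitting available by passing population-level vectors. The
reported r² is on founder means; a total-variance convention (including
population stochasticity in the denominator) would give systematically
smaller values, and the choice is stated here because the two are easy to
conflate.

The noise-robustness variant re-adds normal noise with each founder's
estimated error variance to the fitness predictor and refits repeatedly;
since the predictor's error variance here is a percent or less of its total
variance, attenuation is expected to be slight, and the procedure's own
attenuation behaviour (halving of r² when the added noise variance equals
the predictor variance) is tested against the classical errors-in-variables
factor.

The combined model
`ΔX̄_i = α + β X_i + γ g* + Σ a_ℓ g_iℓ + Σ b_ℓ g* g_iℓ + ε` uses ±1/2
indicator codes (BY = +0.5, RM = −0.5), with `g*` the focal-locus allele and
interactions between the focal locus and every other QTL in the master list.
Every non-intercept term is tested by a single-degree F-test with Bonferroni
correction over all tested terms (α = 0.05), and the model is refit once on
the significant terms — one selection pass, no stepwise loop. Aliased
(collinear) terms are dropped with a warning before testing. Nested-model
monotonicity (combined r² ≥ fitness-only r²) is asserted across simulated
datasets.

The normalized-difference analysis z-scores fitness and increments per
environment (sample s.d., optionally within focal-allele strata, each
stratum needing ≥3 founders) and correlates `X̃ − Ỹ` with `ΔX̃ − ΔỸ`; a
negative correlation indicates declining adaptability operating
independently in each environment. Significance is a one-sided bootstrap
over founders for r < 0.

## Mutation calling and filters

Starting from per-site, per-population reference/alternate read counts, two
site filters run in order: sites where the alternate allele is in the
majority (> 0.5, strict) in ≥ 6 populations are removed as parental fixed
differences; then, among survivors, sites with alternate frequency > 0.10
(strict) in ≥ 5 populations are removed as error-prone. Populations with
zero depth at a site have undefined frequency and count toward neither
rule; ties go to retention. Calls then require frequency strictly above 50%
with ≥ 4 supporting reads. Variants identical in state shared by two or
more populations of the same founder are discarded everywhere (standing
variation predating evolution). Gene assignment uses 1-based inclusive
intervals (BED converted at the boundary via rtracklayer), resolving
overlaps to the smallest interval; multi-hit genes are those with
missense/putative-LOF/indel calls in ≥ 2 distinct populations. The
hypergeometric overlap expectation between multi-hit genes and
QTL-interval genes is `n_multihit × n_qtl / n_genome` with an exact
enrichment tail probability.

All thresholds are exposed as arguments with the defaults above; the whole
chain is validated exactly against a hand-derived 10-site × 10-population
table that places each rule at its boundary.

## Mutual information

For a population label W and a gene's binary incidence m,
`I(W, g) = Σ_W p(W) Σ_m p(m|W) log2[p(m|W)/p(m)]` with observed-frequency
plug-ins and `0 log 0 = 0`; the conditional form averages over strata of Z
weighted by p(Z). The test statistic sums I over a gene universe —
defaulting to the multi-hit genes, the informative set, with the full list
available. The null permutes the pooled multiset of gene labels across
mutation *events* (pre-binarization), reassigns each population its
original event count, and re-binarizes: both the per-population counts and
the overall gene spectrum are preserved, so differences in mutation *number*
between environments or alleles cannot masquerade as spectrum differences.
Results are reported centered on the null mean with a null 95% interval and
an add-one p-value, in the hierarchy M(focal), M(environment | focal),
M(founder | focal, environment). Base-2 logarithms throughout (bits).

# The synthetic cross generator

`cross_config()`/`simulate_cross()` generate ground-truth datasets with the
statistical structure the estimators assume:

- **Genotypes**: each chromosome is a two-state Markov chain with
  per-interval switch probability (default 0.05 over 62 loci per chromosome,
  16 chromosomes), i.e. linkage decay without interference — the only
  recombination feature downstream methods are sensitive to.
- **Founder fitness**: five additive QTLs per environment (full-effect sizes
  0.09/0.05/0.04/0.03/0.03 at OT and 0.19/0.06/0.05/0.04/0.03 at HT — the
  focal locus on chromosome 14 carries the large effect, with the BY allele
  fitter by 9% at OT and 19% at HT), one pairwise epistatic term, and a
  polygenic normal residual (s.d. 0.055 at OT, 0.080 at HT, making HT
  fitness spreads roughly twice OT, as in the real cross).
- **Evolution**: home-environment increments follow
  `ΔX = a + b X + u_i + e_ij` with intercepts 0.08 (OT) and 0.15 (HT) —
  mean gains of roughly 8% and 15–20% — slope b = −0.5 in both environments,
  founder deviation s.d. 0.02 and population noise s.d. 0.034 (OT) / 0.046
  (HT). These defaults were chosen so the generative broad-sense
  heritability of the increment is ≈ 0.62 at OT and ≈ 0.65 at HT
  (`theoretical_components()` prints the implied values), the regime the
  estimators must operate in. Away-environment increments follow an
  analogous rule on the founder's *away* fitness, correlated with the home
  components (ρ = 0.5) and, for OT-evolved populations, noisier by a factor
  2.5 — reproducing the observed asymmetry in which pleiotropic gains of
  HT-evolved populations are predictable and those of OT-evolved
  populations much less so.
- **Measurements**: normal technical error per replicate (s.d. 0.011 OT /
  0.024 HT; four founder replicates, two population replicates), sized so
  the error variance of founder means is under 1% of fitness variance.
  Optional competition-count quadruples are emitted under exactly the model
  the estimator inverts, for round-trip tests.
- **Mutations**: per-population counts are Poisson with mean
  `max(0, λ_env + c X_home)` (λ = 1.3 OT / 3.6 HT, c = −5), so mutation
  accumulation declines with founder fitness. Gene labels are drawn from a
  weighted target universe: a ribosome-biogenesis class (ten genes, the
  focal-role gene heaviest) accessible **only** on the RM focal background,
  a cAMP class favoured on BY, two silencing genes strongly enriched at HT,
  and 2000 diffuse background genes — so multi-hit genes form a small
  informative set above a singleton background. Sequencing covers the
  populations of 35 founders balanced between focal alleles, mirroring
  realistic sequencing budgets. The site-count layer adds parental-majority,
  error-prone and low-frequency decoy sites to exercise every filter, plus
  planted founder-shared variants; 57% of true mutation sites are fixed and
  the rest segregate above 55%.

What the generator deliberately does **not** emulate: lineage dynamics and
clonal interference (increments are drawn from the phenomenological rule,
not simulated), founder-specific mutational idiosyncrasies beyond the focal
allele, G×E in measurement error, linkage between the mutation spectrum and
fitness beyond the count trend, and real sequencing artifacts (mapping bias,
indel realignment). Passing tests therefore certify the estimators under
the stated generative assumptions — not the wet-lab pipeline upstream of the
count tables.

The dataset seed is split into named substreams (genotypes / fitness /
evolution / measurement / sites), so any stage is reproducible in isolation
and identical configurations yield byte-identical tables.

# Numerical and scale choices

- Permutation and bootstrap p-values all use the add-one convention; all
  resampling is seeded and deterministic.
- The REML search runs over λ ∈ [1e−6, 1 − 1e−6] with tolerance 1e−6;
  kinship eigenvalues are clipped at zero.
- LOD computations clamp r² below 1 by 1e−12 to keep the score finite; an
  exact r² = 1 is flagged.
- Validation problem sizes: oracle-equivalence suites run 1000 random small
  instances per formula family; parameter recovery uses 100 replicate
  simulations at 230 founders with a 192-marker panel (the generative
  variance components do not depend on neutral marker count); QTL
  calibration uses 200 null scans and 100 power simulations at 200
  permutations; REML recovery uses 50 simulations at 230 founders × 1008
  loci; mutual-information calibration uses 200 null datasets of 254
  populations at 500 permutations. These sizes give binomial/Monte-Carlo
  error comfortably inside the asserted bands while keeping the default
  test run fast.

# Known limitations

- The REML implementation supports an intercept-only fixed effect; covariate
  adjustment must happen upstream.
- The scan tests loci marginally after residualization; interval mapping
  between markers and multi-trait scans are out of scope.
- Consequence classes are taken from the annotation/generator; no
  codon-level effect prediction is performed.
- The hypergeometric overlap expectation treats genes as exchangeable units;
  gene length is ignored.
- With two environments the pleiotropy analysis is a 2×2 design; more
  environments would need a generalization of the normalized-difference
  construction.
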