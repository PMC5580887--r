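# evoherit

Quantitative genetics of **adaptability** and **pleiotropy** in experimental
evolution.

When hundreds of recombinant haploid founders from a cross between two
diverged yeast strains (an RM × BY style segregant panel) each seed replicate
populations that evolve for hundreds of generations in two environments, the
rate of adaptation itself becomes a measurable, heritable trait. This package
implements the full analysis chain for such an experiment:

- **Fitness estimation** from competition flow-cytometry counts,
  `s = (1/τ) ln[ ((n_e,f − p·n_r,f)/n_r,f) · (n_r,i/(n_e,i − p·n_r,i)) ]`,
  with the non-fluorescent reference correction `p` and replicate summaries.
- **Broad-sense heritability** by variance partitioning: for founder fitness,
  `σ²_t = (1/n)Σ(X_i − X̄)²`, `σ²_ε = (1/n)Σσ²_{X,ε,i}`,
  `H² = (σ²_t − σ²_ε)/σ²_t`; for the fitness increment ΔX of evolved
  populations, the within-founder component
  `σ²_p = (1/n)Σ_i [n_i/(n_i−1)] Σ_j (ΔX_ij − ΔX̄_i)²` absorbs measurement
  error *and* evolutionary stochasticity. Confidence intervals come from a
  delete-half jackknife over founders.
- **Narrow-sense heritability** by REML on a standardized kinship matrix
  `R = GGᵀ` with `g_ik = (allele − p_k)/√(m p_k (1−p_k))`, fit by
  eigendecomposition and a 1-D search over the heritability ratio.
- **QTL mapping** by an iterative forward scan: residualize on detected QTLs
  (alleles coded ±1/2), score every locus by
  `LOD = −(n/2) log10(1 − r²)` with replicate-weighted correlations, test the
  genome-wide maximum against a permutation null, and report 1.5-LOD
  positional confidence intervals.
- **Declining adaptability and pleiotropy models**: `ΔX̄_i = α + βX_i + ε`,
  the two-environment pleiotropy regression, a combined fitness + QTL +
  focal-allele-interaction model with Bonferroni F-test term selection, and
  the normalized-difference test of whether adaptability declines
  independently in each environment.
- **Mutation calling from pooled sequencing**: parental-majority and
  error-prone site filters, strict >50% frequency / ≥4 read calling,
  founder-shared variant removal, multi-hit gene tallies, hypergeometric
  QTL-overlap expectations, and the mutation-count-versus-fitness trend.
- **Mutual-information association tests**: `M(W|Z) = Σ_genes I(W, g | Z)`
  in bits against a count-preserving permutation null, in the hierarchy
  M(focal allele), M(environment | focal), M(founder | focal, environment).
- A **synthetic cross generator** with known ground truth for every stage —
  recombinant genotypes, correlated founder fitnesses, increments following a
  declining-adaptability rule, technical replicates, and de novo mutation
  spectra gated by the focal-locus allele and environment — so that every
  estimator can be validated by parameter recovery.

## Worked example

```r
library(evoherit)
cfg <- cross_config(seed = 1)              # 230 founders, 2 environments
cross <- simulate_cross(cfg, site_counts = FALSE)

sm <- summarize_fitness_table(cross$fitness_table,
                              environment = "OT", type = "founder")
broad_sense_fitness(sm$mean, sm$error_var)
#> Broad-sense variance partition (fitness; n = 230)
#>   total 0.006092 | noise 3.141e-05 | founder 0.00606
#>   H2 = 0.9948 (clipped 0.9948)

pops <- subset(cross$populations, home_env == "OT")
broad_sense_increment(pops$d_OT, pops$founder_id)
#> Broad-sense variance partition (increment; n = 920)
#>   total 0.003047 | noise 0.001202 | founder 0.001845
#>   H2 = 0.6056 (clipped 0.6056)

forward_scan(cross$genotypes, sm$mean, weights = sqrt(sm$n_reps),
             n_perm = 1000, seed = 2)
#> Forward QTL scan: 230 founders, 992 loci, alpha 0.05, 1000 permutations
#>  chrom peak_pos       lod           p ci_start ci_end     effect
#>  chr14    31000 18.077367 0.000999001    31000  31000 0.08071968
#>  chr05    31000  4.183528 0.010989011    31000  35000 0.03848178
#>  chr03    31000  4.726552 0.004995005    30000  31000 0.04495010
#>  chr01    32000  5.989565 0.000999001    31000  33000 0.04679587
#>  chr08    33000  4.282720 0.007992008    30000  33000 0.03324924

dbar <- tapply(pops$d_OT, pops$founder_id, mean)
X <- sm$mean[match(names(dbar), sm$strain_id)]
fit_adaptability_vs_fitness(as.numeric(dbar), X)
#> Linear model fit (n = 230, r2 = 0.6939)
#>             estimate       se          p
#> (Intercept)   0.0805 0.001699 5.290e-120
#> fitness      -0.4944 0.021750  1.545e-60
```

Reading the output: measurement error is a tiny fraction of fitness variance
(H² ≈ 0.99), about 61% of the variance in fitness gains is attributable to
founder genotype rather than evolutionary stochasticity, the scan recovers
all five planted QTLs (the chr14 peak is the large-effect focal locus), and
fitter founders adapt more slowly — the fitted slope −0.49 recovers the
generative declining-adaptability slope of −0.5.

`run_full_analysis()` chains every stage (heritability tables, QTL scans,
models, group means, mutation calling, mutual information) and writes a
results bundle with a YAML manifest.

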