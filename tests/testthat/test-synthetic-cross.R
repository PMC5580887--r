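test_that("recombination model produces single-parent chromosomes at zero crossover", {
  cfg <- cross_config(n_founders = 50, chromosome_lengths = 20L,
                      crossover_prob = 0,
                      qtl_spec = data.frame(locus = 5L, effect_OT = 0.1,
                                            effect_HT = 0.1),
                      epistasis_spec = data.frame(locus1 = integer(0),
                                                  locus2 = integer(0),
                                                  effect_OT = numeric(0),
                                                  effect_HT = numeric(0)),
                      focal_locus = 5L, seed = 4)
  g <- simulate_genotypes(cfg)
  per_founder <- apply(g$alleles, 1, function(r) length(unique(r)))
  expect_true(all(per_founder == 1))
})

test_that("genotype simulation is deterministic given the seed", {
  cfg <- tiny_config(seed = 9)
  expect_identical(simulate_genotypes(cfg)$alleles,
                   simulate_genotypes(cfg)$alleles)
  expect_identical(simulate_cross(cfg), simulate_cross(cfg))
})

test_that("free recombination decorrelates adjacent loci", {
  cfg <- cross_config(n_founders = 230, chromosome_lengths = 200L,
                      crossover_prob = 0.5,
                      qtl_spec = data.frame(locus = 1L, effect_OT = 0,
                                            effect_HT = 0),
                      epistasis_spec = data.frame(locus1 = integer(0),
                                                  locus2 = integer(0),
                                                  effect_OT = numeric(0),
                                                  effect_HT = numeric(0)),
                      focal_locus = 1L, seed = 2)
  g <- simulate_genotypes(cfg)
  num <- (g$alleles == "BY") * 1
  r_adj <- sapply(seq_len(199), function(j) cor(num[, j], num[, j + 1]))
  ## no systematic linkage: signed correlations average to ~0 and their
  ## spread matches the null sampling scale 1/sqrt(n)
  expect_lt(abs(mean(r_adj)), 0.02)
  expect_lt(mean(abs(r_adj)), 1.3 * sqrt(2 / pi) / sqrt(230))
})

test_that("allele frequencies are near 1/2 across the panel", {
  g <- simulate_genotypes(cross_config(seed = 5))
  p <- colMeans(g$alleles == "BY")
  se4 <- 4 * sqrt(0.25 / 230)
  expect_true(all(abs(p - 0.5) <= se4))
})

test_that("additive effects follow the +/- 1/2 allele code exactly", {
  cfg <- cross_config(n_founders = 30, chromosome_lengths = 10L,
                      crossover_prob = 0.3,
                      qtl_spec = data.frame(locus = 4L, effect_OT = 0.1,
                                            effect_HT = 0.2),
                      epistasis_spec = data.frame(locus1 = integer(0),
                                                  locus2 = integer(0),
                                                  effect_OT = numeric(0),
                                                  effect_HT = numeric(0)),
                      focal_locus = 4L,
                      fitness_residual_sd = c(OT = 0, HT = 0), seed = 3)
  g <- simulate_genotypes(cfg)
  f <- simulate_founder_fitness(g, cfg)
  by <- g$alleles[, 4] == "BY"
  expect_equal(unique(f$OT[by]) - unique(f$OT[!by]), 0.1)
  expect_equal(unique(f$HT[by]) - unique(f$HT[!by]), 0.2)
  ## and with no QTL effects and zero residual, all fitnesses are 0
  cfg0 <- cross_config(n_founders = 20, chromosome_lengths = 10L,
                       qtl_spec = data.frame(locus = 4L, effect_OT = 0,
                                             effect_HT = 0),
                       epistasis_spec = cfg$epistasis_spec, focal_locus = 4L,
                       fitness_residual_sd = c(OT = 0, HT = 0), seed = 3)
  f0 <- simulate_founder_fitness(simulate_genotypes(cfg0), cfg0)
  expect_true(all(f0$OT == 0) && all(f0$HT == 0))
})

test_that("shared large-effect QTLs induce cross-environment fitness correlation", {
  cfg <- cross_config(
    n_founders = 230, chromosome_lengths = rep(20L, 5),
    qtl_spec = data.frame(locus = c(10L, 30L, 50L),
                          effect_OT = c(0.2, 0.15, 0.1),
                          effect_HT = c(0.2, 0.15, 0.1)),
    epistasis_spec = data.frame(locus1 = integer(0), locus2 = integer(0),
                                effect_OT = numeric(0), effect_HT = numeric(0)),
    focal_locus = 10L, fitness_residual_sd = c(OT = 0.02, HT = 0.02),
    seed = 6)
  f <- simulate_founder_fitness(simulate_genotypes(cfg), cfg)
  expect_gt(cor(f$OT, f$HT), 0.8)
})

test_that("declining-adaptability slope is recovered by regression at panel scale", {
  cfg <- recovery_config(seed = 21)
  cross <- simulate_cross(cfg, site_counts = FALSE)
  pops <- cross$populations
  k <- pops$home_env == "OT"
  dbar <- tapply(pops$d_OT[k], pops$founder_id[k], mean)
  X <- cross$founder_fitness$OT[match(names(dbar),
                                      cross$founder_fitness$founder_id)]
  slope <- unname(coef(lm(as.numeric(dbar) ~ X))[2])
  expect_equal(slope, -0.5, tolerance = 0.05 / 0.5)
  expect_lt(abs(slope + 0.5), 0.05)
})

test_that("increments are i.i.d. when the rule and founder deviations are flat", {
  cfg <- recovery_config(seed = 22,
                         adaptability_rule = list(OT = c(a = 0.05, b = 0),
                                                  HT = c(a = 0.05, b = 0)),
                         founder_effect_sd = 0)
  cross <- simulate_cross(cfg, site_counts = FALSE)
  pops <- cross$populations
  k <- pops$home_env == "OT"
  vc <- broad_sense_increment(pops$d_OT[k], pops$founder_id[k])
  expect_lt(abs(vc$H2), 0.1)
})

test_that("focal-allele-restricted gene classes never mutate on the other background", {
  cfg <- recovery_config(seed = 23)
  cross <- simulate_cross(cfg, site_counts = FALSE)
  gt <- cfg$gene_targets
  rm_only <- gt$gene[gt$w_BY_OT == 0 & gt$w_BY_HT == 0]
  muts <- cross$mutations
  by_pops <- cross$populations$population_id[
    cross$populations$focal_allele == "BY"]
  expect_true(length(rm_only) > 0)
  expect_false(any(muts$gene[muts$population_id %in% by_pops] %in% rm_only))
})

test_that("measurement layer adds the configured technical error", {
  cfg <- tiny_config(seed = 11, meas_error_sd = c(OT = 0, HT = 0))
  cross <- simulate_cross(cfg, site_counts = FALSE)
  s <- summarize_fitness_table(cross$fitness_table, environment = "OT",
                               type = "founder")
  expect_true(all(s$error_var == 0))
  expect_equal(sort(unique(s$mean)), sort(unique(cross$founder_fitness$OT)))

  ## with error: mean per-founder error variance of the mean ~ sd^2 / reps
  cfg2 <- cross_config(n_founders = 400, chromosome_lengths = 10L,
                       qtl_spec = data.frame(locus = 4L, effect_OT = 0,
                                             effect_HT = 0),
                       epistasis_spec = data.frame(locus1 = integer(0),
                                                   locus2 = integer(0),
                                                   effect_OT = numeric(0),
                                                   effect_HT = numeric(0)),
                       focal_locus = 4L,
                       meas_error_sd = c(OT = 0.01, HT = 0.01),
                       n_tech_reps = 4L, seed = 12)
  cross2 <- simulate_cross(cfg2, site_counts = FALSE)
  s2 <- summarize_fitness_table(cross2$fitness_table, environment = "OT",
                                type = "founder")
  expect_equal(mean(s2$error_var), 0.01^2 / 4, tolerance = 0.15)
})

test_that("competition counts round-trip through the fitness estimator", {
  cfg <- tiny_config(seed = 13)
  cross <- simulate_cross(cfg, site_counts = FALSE)
  evo <- list(populations = cross$populations)
  meas <- simulate_measurements(evo, cross$founder_fitness, cfg,
                                competition_counts = TRUE)
  cnt <- attr(meas, "counts")
  s_hat <- estimate_fitness(cnt$ne_i, cnt$nr_i, cnt$ne_f, cnt$nr_f,
                            tau = cnt$tau, p = cnt$p_nonfluor)
  expect_equal(s_hat, meas$fitness, tolerance = 1e-10)
})

test_that("simulated founder-mean variance matches its generative decomposition", {
  ## var of measured founder means ~ var(true fitness) + meas_sd^2 / n_reps
  lens <- 10L
  qs <- data.frame(locus = 4L, effect_OT = 0.1, effect_HT = 0.1)
  es <- data.frame(locus1 = integer(0), locus2 = integer(0),
                   effect_OT = numeric(0), effect_HT = numeric(0))
  vars <- sapply(1:100, function(s) {
    cfg <- cross_config(n_founders = 60, chromosome_lengths = lens,
                        qtl_spec = qs, epistasis_spec = es, focal_locus = 4L,
                        fitness_residual_sd = c(OT = 0.05, HT = 0.05),
                        meas_error_sd = c(OT = 0.02, HT = 0.02),
                        n_tech_reps = 4L, seed = 1000 + s)
    g <- simulate_genotypes(cfg)
    f <- simulate_founder_fitness(g, cfg)
    evo <- simulate_evolution(f, g, cfg)
    m <- simulate_measurements(evo, f, cfg)
    sm <- summarize_fitness_table(m, environment = "OT", type = "founder")
    var(sm$mean)
  })
  th <- 0.1^2 / 4 + 0.05^2 + 0.02^2 / 4
  mc_se <- sd(vars) / sqrt(length(vars))
  expect_lt(abs(mean(vars) - th), 3 * mc_se)
})

test_that("dataset tables round-trip through the TSV writers", {
  cfg <- tiny_config(seed = 31)
  cross <- simulate_cross(cfg)
  dir <- tempfile("crossdat")
  write_cross_tables(cross, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "genotypes.tsv", "fitness.tsv", "populations.tsv", "mutations.tsv",
    "truth.tsv", "site_counts.tsv", "genes.bed")))))
  g2 <- read_genotypes(file.path(dir, "genotypes.tsv"))
  expect_identical(unname(g2$alleles), unname(cross$genotypes$alleles))
  sc2 <- read_site_counts(file.path(dir, "site_counts.tsv"))
  expect_equal(unname(sc2$alt), unname(cross$site_data$site_counts$alt))
  expect_equal(sc2$sites$pos, cross$site_data$site_counts$sites$pos)
})
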