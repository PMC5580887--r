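#' Configuration for a synthetic biparental cross and evolution experiment
#'
#' Builds the parameter set from which [simulate_cross()] generates a complete
#' synthetic dataset: recombinant haploid founder genotypes, founder fitnesses
#' in two environments, evolved-population fitness increments under a
#' declining-adaptability rule, replicated fitness measurements, and de novo
#' mutation spectra whose gene-level targets depend on the allele at a focal
#' locus and on the evolution environment.
#'
#' The defaults emulate the study conditions the package is designed for:
#' 230 founders from an RM x BY style cross, four replicate populations per
#' founder per environment (eight in total), an optimal-temperature ("OT") and
#' a high-temperature ("HT") environment, a large-effect focal locus on
#' chromosome 14 whose less-fit RM allele opens a ribosome-biogenesis
#' mutational pathway, adaptability declining with founder fitness with slope
#' -0.5 in both environments, and noise levels calibrated so that the
#' generative broad-sense heritability of the home-environment fitness
#' increment is close to 0.62 at OT (see [theoretical_components()]).
#'
#' @param n_founders number of recombinant founders.
#' @param chromosome_lengths integer vector, loci per chromosome.
#' @param crossover_prob per-interval switch probability of the recombination
#'   Markov chain (no interference), in `[0, 0.5]`.
#' @param qtl_spec data frame with columns `locus`, `effect_OT`, `effect_HT`:
#'   additive effect sizes (full allele-substitution effect; alleles are coded
#'   +/- 1/2 so the fitness gap between BY and RM homozygous classes equals the
#'   effect). Must contain `focal_locus` exactly once.
#' @param epistasis_spec data frame with columns `locus1`, `locus2`,
#'   `effect_OT`, `effect_HT`; interaction term is the product of the two
#'   +/- 1/2 codes times the effect.
#' @param focal_locus locus index of the large-effect locus that also gates
#'   mutational targets (the "KRE33 role").
#' @param fitness_residual_sd named per-environment s.d. of the non-QTL
#'   (polygenic/epistatic) residual of true founder fitness.
#' @param adaptability_rule list per environment with entries `a` (intercept)
#'   and `b` (slope, default negative) of expected home-environment fitness
#'   gain versus true founder fitness.
#' @param away_rule list keyed by the *home* environment giving `a` and `b`
#'   for the expected fitness change measured in the away environment; the
#'   slope multiplies the founder's true fitness in the away environment.
#' @param founder_effect_sd s.d. of the founder-level random adaptability
#'   deviation shared by all populations of a founder within a home
#'   environment.
#' @param pop_noise_sd named per-environment s.d. of per-population
#'   evolutionary stochasticity of the home-environment increment.
#' @param away_noise_factor multiplier (keyed by home environment) applied to
#'   the away-environment population noise; values above 1 make pleiotropic
#'   outcomes less predictable for that direction.
#' @param home_away_cor correlation between home and away components of the
#'   founder deviation and of the population noise.
#' @param meas_error_sd named per-environment technical s.d. of a single
#'   fitness measurement.
#' @param n_tech_reps technical replicates per founder fitness measurement
#'   (must be at least 2 so error variance is estimable).
#' @param n_tech_reps_pop technical replicates per evolved-population fitness
#'   measurement.
#' @param n_pops_per_env replicate populations per founder per environment.
#' @param mut_rate named per-environment mean de novo mutation count per
#'   population at founder fitness 0.
#' @param mut_fitness_coef linear dependence of the Poisson mean on true
#'   founder fitness in the home environment; the mean is floored at 0.
#' @param n_seq_founders number of founders whose descendant populations get
#'   a pooled-sequencing site-count table, chosen to balance the two focal
#'   alleles (whole-panel sequencing is rarely affordable; the mutation
#'   analyses run on this subset).
#' @param consequence_probs sampling probabilities of the consequence class of
#'   each mutation event.
#' @param gene_targets data frame describing the mutational target genes and
#'   their sampling weights per focal allele and environment; see
#'   [default_gene_targets()].
#' @param environments character vector of length 2 naming the environments.
#' @param seed integer RNG seed for the dataset.
#'
#' @return an object of class `cross_config` (a validated list).
#' @seealso [simulate_cross()], [theoretical_components()]
#' @export
cross_config <- function(n_founders = 230L,
                         chromosome_lengths = rep(62L, 16),
                         crossover_prob = 0.05,
                         qtl_spec = NULL,
                         epistasis_spec = NULL,
                         focal_locus = NULL,
                         fitness_residual_sd = c(OT = 0.055, HT = 0.080),
                         adaptability_rule = list(OT = c(a = 0.08, b = -0.5),
                                                  HT = c(a = 0.15, b = -0.5)),
                         away_rule = list(OT = c(a = 0.10, b = -0.5),
                                          HT = c(a = 0.08, b = -0.5)),
                         founder_effect_sd = 0.02,
                         pop_noise_sd = c(OT = 0.034, HT = 0.046),
                         away_noise_factor = c(OT = 2.5, HT = 1),
                         home_away_cor = 0.5,
                         meas_error_sd = c(OT = 0.011, HT = 0.024),
                         n_tech_reps = 4L,
                         n_tech_reps_pop = 2L,
                         n_pops_per_env = 4L,
                         mut_rate = c(OT = 1.3, HT = 3.6),
                         mut_fitness_coef = -5,
                         n_seq_founders = 35L,
                         consequence_probs = c(missense = 0.60,
                                               putative_LOF = 0.14,
                                               synonymous = 0.13,
                                               noncoding = 0.13),
                         gene_targets = default_gene_targets(),
                         environments = c("OT", "HT"),
                         seed = 1L) {
  if (length(chromosome_lengths) < 1 || any(chromosome_lengths < 1))
    stop("'chromosome_lengths' must be a nonempty vector of positive counts")
  check_prob(crossover_prob, "crossover_prob", upper = 0.5)
  check_sd(fitness_residual_sd, "fitness_residual_sd")
  check_sd(founder_effect_sd, "founder_effect_sd")
  check_sd(pop_noise_sd, "pop_noise_sd")
  check_sd(meas_error_sd, "meas_error_sd")
  if (n_tech_reps < 2)
    stop("'n_tech_reps' must be >= 2: founder error variance is inestimable otherwise")
  if (abs(home_away_cor) > 1) stop("'home_away_cor' must be in [-1, 1]")

  n_loci <- sum(chromosome_lengths)
  if (is.null(focal_locus)) focal_locus <- default_focal_locus(chromosome_lengths)
  if (is.null(qtl_spec)) qtl_spec <- default_qtl_spec(chromosome_lengths)
  if (is.null(epistasis_spec)) epistasis_spec <- default_epistasis_spec(chromosome_lengths)

  stopifnot(is.data.frame(qtl_spec),
            all(c("locus", "effect_OT", "effect_HT") %in% names(qtl_spec)))
  if (any(qtl_spec$locus < 1 | qtl_spec$locus > n_loci))
    stop("qtl_spec locus index out of range")
  if (sum(qtl_spec$locus == focal_locus) != 1L)
    stop("'focal_locus' must appear exactly once in qtl_spec")
  if (nrow(epistasis_spec) &&
      any(unlist(epistasis_spec[c("locus1", "locus2")]) > n_loci))
    stop("epistasis_spec locus index out of range")

  names(fitness_residual_sd) <- names(meas_error_sd) <- environments
  names(pop_noise_sd) <- names(mut_rate) <- environments
  names(adaptability_rule) <- names(away_rule) <- environments
  names(away_noise_factor) <- environments

  structure(list(
    n_founders = as.integer(n_founders),
    chromosome_lengths = as.integer(chromosome_lengths),
    crossover_prob = crossover_prob,
    qtl_spec = qtl_spec,
    epistasis_spec = epistasis_spec,
    focal_locus = as.integer(focal_locus),
    fitness_residual_sd = fitness_residual_sd,
    adaptability_rule = adaptability_rule,
    away_rule = away_rule,
    founder_effect_sd = founder_effect_sd,
    pop_noise_sd = pop_noise_sd,
    away_noise_factor = away_noise_factor,
    home_away_cor = home_away_cor,
    meas_error_sd = meas_error_sd,
    n_tech_reps = as.integer(n_tech_reps),
    n_tech_reps_pop = as.integer(n_tech_reps_pop),
    n_pops_per_env = as.integer(n_pops_per_env),
    mut_rate = mut_rate,
    mut_fitness_coef = mut_fitness_coef,
    n_seq_founders = as.integer(n_seq_founders),
    consequence_probs = consequence_probs,
    gene_targets = gene_targets,
    environments = environments,
    seed = as.integer(seed)
  ), class = "cross_config")
}

## global locus index of position `pos` on chromosome `chrom`
locus_index <- function(chromosome_lengths, chrom, pos) {
  offs <- c(0L, cumsum(chromosome_lengths))
  offs[chrom] + pos
}

default_focal_locus <- function(chromosome_lengths) {
  ## middle of chromosome 14 (or of the last chromosome on short genomes)
  chrom <- min(14L, length(chromosome_lengths))
  locus_index(chromosome_lengths, chrom,
              max(1L, chromosome_lengths[chrom] %/% 2L))
}

#' @rdname cross_config
#' @export
default_qtl_spec <- function(chromosome_lengths = rep(62L, 16)) {
  nc <- length(chromosome_lengths)
  at <- function(chrom, frac) {
    chrom <- min(chrom, nc)
    locus_index(chromosome_lengths, chrom,
                max(1L, round(chromosome_lengths[chrom] * frac)))
  }
  data.frame(
    locus = c(default_focal_locus(chromosome_lengths),
              at(1, 0.5), at(3, 0.5), at(5, 0.5), at(8, 0.5)),
    effect_OT = c(0.09, 0.05, 0.04, 0.03, 0.03),
    effect_HT = c(0.19, 0.06, 0.05, 0.04, 0.03)
  )
}

#' @rdname cross_config
#' @export
default_epistasis_spec <- function(chromosome_lengths = rep(62L, 16)) {
  nc <- length(chromosome_lengths)
  data.frame(
    locus1 = default_focal_locus(chromosome_lengths),
    locus2 = locus_index(chromosome_lengths, min(3L, nc),
                         max(1L, chromosome_lengths[min(3L, nc)] %/% 2L)),
    effect_OT = 0.02,
    effect_HT = 0.03
  )
}

#' Default mutational target genes of the synthetic cross
#'
#' The gene universe emulates the qualitative structure of adaptive targets in
#' the yeast cross: a ribosome-biogenesis class accessible only to founders
#' carrying the RM allele at the focal locus, a cAMP-pathway class strongly
#' favoured on the BY background, a pair of silencing genes enriched in the
#' high-temperature environment, and a background of generic targets. Weights
#' are relative sampling rates of mutation events per (focal allele,
#' environment) combination; a weight of zero makes a class inaccessible.
#'
#' @return data frame with columns `gene`, `class`, `w_RM_OT`, `w_RM_HT`,
#'   `w_BY_OT`, `w_BY_HT`.
#' @export
default_gene_targets <- function() {
  ribo <- c("KRE33", "UTP20", "RRP12", "BMS1", "ROK1",
            "KRR1", "UTP10", "NOP14", "DIP2", "ENP1")
  camp <- c("GPB1", "GPB2", "PDE2", "IRA1", "IRA2", "RAS2")
  sir  <- c("SIR3", "SIR4")
  gen  <- sprintf("GEN%04d", 1:2000)
  rbind(
    data.frame(gene = ribo, class = "ribosome_biogenesis",
               w_RM_OT = c(40, rep(12, 9)), w_RM_HT = c(40, rep(12, 9)),
               w_BY_OT = 0, w_BY_HT = 0),
    data.frame(gene = camp, class = "cAMP",
               w_RM_OT = 0.5, w_RM_HT = 0.5, w_BY_OT = 8, w_BY_HT = 8),
    data.frame(gene = sir, class = "silencing",
               w_RM_OT = 1, w_RM_HT = 25, w_BY_OT = 1, w_BY_HT = 25),
    data.frame(gene = gen, class = "general",
               w_RM_OT = 0.2, w_RM_HT = 0.2, w_BY_OT = 0.2, w_BY_HT = 0.2)
  )
}

#' Generative variance components implied by a cross configuration
#'
#' Computes, from the configuration alone, the expected variance of true
#' founder fitness per environment and the implied broad-sense heritabilities
#' of fitness and of the home-environment fitness increment under the
#' generative model (QTL loci on distinct chromosomes segregate independently
#' at allele frequency 1/2; the additive variance of a locus with full effect
#' `e` is `e^2/4` and of an interaction `e^2/16`).  These are the ground-truth
#' values parameter-recovery checks compare estimates against.
#'
#' @param config a [cross_config()].
#' @return list with per-environment `var_fitness`, `H2_fitness`,
#'   `H2_increment`, and `slope` of the adaptability rule.
#' @export
theoretical_components <- function(config) {
  envs <- config$environments
  out <- list(var_fitness = numeric(0), H2_fitness = numeric(0),
              H2_increment = numeric(0), slope = numeric(0))
  for (env in envs) {
    eff <- config$qtl_spec[[paste0("effect_", env)]]
    epi <- if (nrow(config$epistasis_spec))
      config$epistasis_spec[[paste0("effect_", env)]] else numeric(0)
    v_x <- sum(eff^2) / 4 + sum(epi^2) / 16 + config$fitness_residual_sd[[env]]^2
    se2_mean <- config$meas_error_sd[[env]]^2 / config$n_tech_reps
    b <- config$adaptability_rule[[env]][["b"]]
    s_f2 <- b^2 * v_x + config$founder_effect_sd^2
    s_p2 <- config$pop_noise_sd[[env]]^2 +
      config$meas_error_sd[[env]]^2 / config$n_tech_reps_pop + se2_mean
    out$var_fitness[env] <- v_x
    out$H2_fitness[env] <- v_x / (v_x + se2_mean)
    out$H2_increment[env] <- s_f2 / (s_f2 + s_p2)
    out$slope[env] <- b
  }
  out
}

#' @export
print.cross_config <- function(x, ...) {
  cat("Synthetic cross configuration\n")
  cat(sprintf("  founders: %d, loci: %d on %d chromosomes, crossover prob %.3g\n",
              x$n_founders, sum(x$chromosome_lengths),
              length(x$chromosome_lengths), x$crossover_prob))
  cat(sprintf("  environments: %s; %d populations per founder per environment\n",
              paste(x$environments, collapse = ", "), x$n_pops_per_env))
  cat(sprintf("  QTLs: %d (focal locus %d); adaptability slopes: %s\n",
              nrow(x$qtl_spec), x$focal_locus,
              paste(sprintf("%s %.2f", x$environments,
                            vapply(x$adaptability_rule, `[[`, 0, "b")),
                    collapse = ", ")))
  th <- theoretical_components(x)
  cat(sprintf("  generative H2 of increment: %s\n",
              paste(sprintf("%s %.3f", x$environments, th$H2_increment),
                    collapse = ", ")))
  invisible(x)
}
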