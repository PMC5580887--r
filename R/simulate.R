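#' Simulate recombinant founder genotypes
#'
#' Each founder's chromosome is an independent two-state Markov chain: the
#' first locus is RM or BY with probability 1/2 and each subsequent locus
#' switches parental origin with probability `crossover_prob` (per-interval
#' switch model, no interference -- only linkage decay matters downstream).
#'
#' @param config a [cross_config()].
#' @param seed optional seed; defaults to the genotype substream of the
#'   configuration seed, so the stage is reproducible on its own.
#' @return an object of class `genotype_matrix`: list with `alleles`
#'   (founders x loci character matrix of `"RM"`/`"BY"`), `loci` (data frame
#'   of `chrom` and 1-based `pos`) and `founders`.
#' @export
simulate_genotypes <- function(config, seed = NULL) {
  check_prob(config$crossover_prob, "crossover_prob", upper = 0.5)
  set.seed(seed %||% stage_seed(config$seed, "genotypes"))
  n <- config$n_founders
  lens <- config$chromosome_lengths
  blocks <- vector("list", length(lens))
  for (ch in seq_along(lens)) {
    L <- lens[ch]
    start <- stats::rbinom(n, 1L, 0.5)
    if (L > 1L) {
      sw <- matrix(stats::rbinom(n * (L - 1L), 1L, config$crossover_prob),
                   n, L - 1L)
      cum <- sw
      for (j in seq_len(L - 1L)[-1]) cum[, j] <- cum[, j - 1L] + cum[, j]
      blocks[[ch]] <- (start + cbind(0L, cum)) %% 2L
    } else {
      blocks[[ch]] <- matrix(start, n, 1L)
    }
  }
  num <- do.call(cbind, blocks)          # 1 = BY, 0 = RM
  loci <- data.frame(
    chrom = rep(sprintf("chr%02d", seq_along(lens)), lens),
    pos = unlist(lapply(lens, function(L) seq_len(L) * 1000L))
  )
  founders <- sprintf("F%03d", seq_len(n))
  alleles <- matrix(ifelse(num == 1L, "BY", "RM"), n, ncol(num),
                    dimnames = list(founders,
                                    paste(loci$chrom, loci$pos, sep = ":")))
  structure(list(alleles = alleles, loci = loci, founders = founders),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d founders x %d loci on %d chromosomes\n",
              nrow(x$alleles), ncol(x$alleles), length(unique(x$loci$chrom))))
  mono <- monomorphic_loci(x)
  if (any(mono)) cat(sprintf("  %d monomorphic loci\n", sum(mono)))
  invisible(x)
}

#' Loci at which the founder panel carries a single allele
#'
#' Monomorphic loci carry no mapping information and are excluded from
#' kinship construction and QTL predictors.
#'
#' @param geno a `genotype_matrix` or character allele matrix.
#' @return logical vector over loci.
#' @export
monomorphic_loci <- function(geno) {
  m <- genotype_alleles(geno)
  p <- colMeans(m == "BY")
  p <= 0 | p >= 1
}

#' Simulate true founder fitnesses in both environments
#'
#' True fitness is the sum of additive QTL contributions (BY allele coded
#' +1/2, RM coded -1/2, times the full effect), pairwise epistatic terms
#' (product of the two codes times the interaction effect) and a normal
#' polygenic residual with per-environment standard deviation.
#'
#' @param geno a `genotype_matrix` from [simulate_genotypes()].
#' @inheritParams simulate_genotypes
#' @return data frame with `founder_id` and one column of true fitness per
#'   environment.
#' @export
simulate_founder_fitness <- function(geno, config, seed = NULL) {
  set.seed(seed %||% stage_seed(config$seed, "fitness"))
  code <- allele_code(geno)
  n <- nrow(code)
  if (any(config$qtl_spec$locus > ncol(code)))
    stop("qtl_spec locus out of range for this genotype matrix")
  out <- data.frame(founder_id = rownames(code) %||% seq_len(n))
  for (env in config$environments) {
    eff <- config$qtl_spec[[paste0("effect_", env)]]
    x <- as.vector(code[, config$qtl_spec$locus, drop = FALSE] %*% eff)
    if (nrow(config$epistasis_spec)) {
      ee <- config$epistasis_spec
      for (i in seq_len(nrow(ee)))
        x <- x + code[, ee$locus1[i]] * code[, ee$locus2[i]] *
          ee[[paste0("effect_", env)]][i]
    }
    out[[env]] <- x + stats::rnorm(n, 0, config$fitness_residual_sd[[env]])
  }
  out
}

#' Simulate evolution: fitness increments and de novo mutations
#'
#' For every founder x home environment x replicate population the
#' home-environment fitness increment is drawn from the phenomenological
#' declining-adaptability rule
#' `dX = a + b * X_home + u_i + e_ij`,
#' where `u_i` is a founder-level deviation (s.d. `founder_effect_sd`) and
#' `e_ij` per-population evolutionary stochasticity (s.d. `pop_noise_sd`).
#' The increment measured in the away environment follows the away rule with
#' slope on the founder's fitness in the *away* environment; its founder
#' deviation and population noise are correlated with the home components
#' with correlation `home_away_cor`, and its noise is scaled by
#' `away_noise_factor`.  De novo mutation counts are Poisson with mean
#' `max(0, mut_rate + mut_fitness_coef * X_home)`; gene labels are drawn from
#' the target-gene weights conditioned on the founder's focal-locus allele and
#' the home environment (classes with weight zero are inaccessible on that
#' background).
#'
#' @param fitness data frame of true founder fitness from
#'   [simulate_founder_fitness()].
#' @inheritParams simulate_founder_fitness
#' @return list with `populations` (one row per evolved population:
#'   `population_id`, `founder_id`, `focal_allele`, `home_env`, `replicate`,
#'   true increments `d_<env>` and true final fitnesses `final_<env>`),
#'   `mutations` (one row per mutation event), and `truth` (founder-level
#'   deviations and the inputs, kept as generative ground truth).
#' @export
simulate_evolution <- function(fitness, geno, config, seed = NULL) {
  set.seed(seed %||% stage_seed(config$seed, "evolution"))
  envs <- config$environments
  stopifnot(all(envs %in% names(fitness)))
  n <- nrow(fitness)
  focal <- genotype_alleles(geno)[, config$focal_locus]
  rho <- config$home_away_cor
  npop <- config$n_pops_per_env

  pops <- list(); devs <- list(); muts <- list()
  for (home in envs) {
    away <- setdiff(envs, home)
    x_home <- fitness[[home]]; x_away <- fitness[[away]]
    ar <- config$adaptability_rule[[home]]
    wr <- config$away_rule[[home]]
    sd_u <- config$founder_effect_sd
    u_home <- stats::rnorm(n, 0, sd_u)
    u_away <- rho * u_home + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n, 0, sd_u)
    sd_eh <- config$pop_noise_sd[[home]]
    sd_ea <- config$pop_noise_sd[[away]] * config$away_noise_factor[[home]]
    devs[[home]] <- data.frame(founder_id = fitness$founder_id,
                               home_env = home, u_home = u_home,
                               u_away = u_away)
    idx <- rep(seq_len(n), each = npop)
    e_home <- stats::rnorm(n * npop, 0, sd_eh)
    e_away <- rho * (sd_ea / max(sd_eh, .Machine$double.eps)) * e_home +
      sqrt(max(0, 1 - rho^2)) * stats::rnorm(n * npop, 0, sd_ea)
    d_home <- ar[["a"]] + ar[["b"]] * x_home[idx] + u_home[idx] + e_home
    d_away <- wr[["a"]] + wr[["b"]] * x_away[idx] + u_away[idx] + e_away
    df <- data.frame(
      population_id = sprintf("%s_%s_r%d", fitness$founder_id[idx], home,
                              rep(seq_len(npop), times = n)),
      founder_id = fitness$founder_id[idx],
      focal_allele = focal[idx],
      home_env = home,
      replicate = rep(seq_len(npop), times = n)
    )
    df[[paste0("d_", home)]] <- d_home
    df[[paste0("d_", away)]] <- d_away
    df[[paste0("final_", home)]] <- x_home[idx] + d_home
    df[[paste0("final_", away)]] <- x_away[idx] + d_away
    pops[[home]] <- df

    lambda <- pmax(0, config$mut_rate[[home]] +
                        config$mut_fitness_coef * x_home[idx])
    counts <- stats::rpois(length(lambda), lambda)
    if (sum(counts) > 0) {
      gt <- config$gene_targets
      ev_pop <- rep(seq_len(nrow(df)), counts)
      genes <- character(sum(counts))
      for (al in unique(focal)) {
        wcol <- paste0("w_", al, "_", home)
        sel <- df$focal_allele[ev_pop] == al
        if (any(sel))
          genes[sel] <- sample(gt$gene, sum(sel), replace = TRUE,
                               prob = gt[[wcol]])
      }
      muts[[home]] <- data.frame(
        population_id = df$population_id[ev_pop],
        founder_id = df$founder_id[ev_pop],
        home_env = home,
        gene = genes,
        gene_class = gt$class[match(genes, gt$gene)],
        consequence = sample(names(config$consequence_probs), sum(counts),
                             replace = TRUE, prob = config$consequence_probs)
      )
    }
  }
  populations <- do.call(rbind, unname(pops))
  ## harmonise column order across the two home environments
  cols <- c("population_id", "founder_id", "focal_allele", "home_env",
            "replicate", paste0("d_", envs), paste0("final_", envs))
  populations <- populations[, cols]
  rownames(populations) <- NULL
  mutations <- if (length(muts)) do.call(rbind, unname(muts)) else
    data.frame(population_id = character(0), founder_id = character(0),
               home_env = character(0), gene = character(0),
               gene_class = character(0), consequence = character(0))
  rownames(mutations) <- NULL
  list(populations = populations, mutations = mutations,
       truth = list(founder_fitness = fitness,
                    founder_deviation = do.call(rbind, unname(devs)),
                    focal_allele = focal))
}

#' Simulate replicated fitness measurements
#'
#' Adds independent normal technical error (per-environment s.d.
#' `meas_error_sd`) to the true founder fitnesses (`n_tech_reps` replicates
#' per founder per environment) and to the true final fitnesses of every
#' evolved population in both environments (`n_tech_reps_pop` replicates).
#'
#' @param evolution result of [simulate_evolution()].
#' @param fitness true founder fitness data frame.
#' @inheritParams simulate_founder_fitness
#' @param competition_counts if `TRUE`, also emit synthetic flow-cytometry
#'   competition count quadruples consistent with each measured fitness under
#'   the model [estimate_fitness()] inverts (reference count known, evolved
#'   count contaminated by the non-fluorescent reference fraction `p`), for
#'   round-trip testing.
#' @param tau named per-environment assay length in generations used when
#'   emitting counts.
#' @param p_nonfluor named per-environment non-fluorescent reference fraction
#'   used when emitting counts (defaults: 0 at OT, 0.015 at HT).
#' @return data frame with columns `strain_id`, `type` (founder/population),
#'   `environment`, `replicate`, `fitness`; when `competition_counts` is
#'   requested, an additional data frame of counts as attribute `"counts"`.
#' @export
simulate_measurements <- function(evolution, fitness, config, seed = NULL,
                                  competition_counts = FALSE,
                                  tau = c(OT = 10, HT = 9),
                                  p_nonfluor = c(OT = 0, HT = 0.015)) {
  if (config$n_tech_reps < 2)
    stop("founders need >= 2 technical replicates for the error variance")
  set.seed(seed %||% stage_seed(config$seed, "measurement"))
  envs <- config$environments
  pops <- evolution$populations
  rows <- list()
  for (env in envs) {
    sd_m <- config$meas_error_sd[[env]]
    nf <- nrow(fitness); rf <- config$n_tech_reps
    rows[[paste0("f", env)]] <- data.frame(
      strain_id = rep(fitness$founder_id, each = rf),
      type = "founder", environment = env,
      replicate = rep(seq_len(rf), times = nf),
      fitness = rep(fitness[[env]], each = rf) +
        stats::rnorm(nf * rf, 0, sd_m)
    )
    np <- nrow(pops); rp <- config$n_tech_reps_pop
    rows[[paste0("p", env)]] <- data.frame(
      strain_id = rep(pops$population_id, each = rp),
      type = "population", environment = env,
      replicate = rep(seq_len(rp), times = np),
      fitness = rep(pops[[paste0("final_", env)]], each = rp) +
        stats::rnorm(np * rp, 0, sd_m)
    )
  }
  out <- do.call(rbind, unname(rows))
  rownames(out) <- NULL
  if (competition_counts) {
    n0 <- 15000
    p <- p_nonfluor[out$environment]
    tt <- tau[out$environment]
    ne_f <- p * n0 + n0 * exp(out$fitness * tt) * (n0 - p * n0) / n0
    attr(out, "counts") <- data.frame(
      strain_id = out$strain_id, environment = out$environment,
      replicate = out$replicate, tau = as.numeric(tt),
      p_nonfluor = as.numeric(p),
      ne_i = n0, nr_i = n0, ne_f = ne_f, nr_f = n0
    )
  }
  out
}

#' Gene annotation of the synthetic genome
#'
#' Places the mutational target genes of a configuration on the synthetic
#' genome as non-overlapping 1-based inclusive intervals (1.5 kb each),
#' cycling over chromosomes.
#'
#' @inheritParams simulate_genotypes
#' @return data frame with `gene`, `chrom`, `start`, `end`, `class`.
#' @export
gene_annotation <- function(config) {
  gt <- config$gene_targets
  nc <- length(config$chromosome_lengths)
  g <- seq_len(nrow(gt))
  chrom_i <- ((g - 1L) %% nc) + 1L
  slot <- (g - 1L) %/% nc
  ## 1.5 kb genes on a 2 kb grid interleaved with the marker space, so QTL
  ## confidence intervals contain genes
  start <- 1000L + slot * 2000L
  anno <- data.frame(gene = gt$gene,
                     chrom = sprintf("chr%02d", chrom_i),
                     start = start, end = start + 1499L,
                     class = gt$class)
  ## the first target gene plays the focal-QTL role: swap it into the grid
  ## slot containing the focal locus position
  offs <- c(0L, cumsum(config$chromosome_lengths))
  fch <- findInterval(config$focal_locus - 1L, offs)
  fpos <- (config$focal_locus - offs[fch]) * 1000L
  fslot <- which(anno$chrom == sprintf("chr%02d", fch) &
                   anno$start <= fpos & anno$end >= fpos)
  if (length(fslot) == 1L && fslot != 1L) {
    tmp <- anno[1L, c("chrom", "start", "end")]
    anno[1L, c("chrom", "start", "end")] <- anno[fslot, c("chrom", "start", "end")]
    anno[fslot, c("chrom", "start", "end")] <- tmp
  }
  anno
}

#' Simulate a pooled-sequencing per-site read-count table
#'
#' Converts the mutation events of a simulated experiment into the per-site,
#' per-population reference/alternate read-count table that the mutation
#' calling module consumes, together with decoy sites that exercise the site
#' filters: parental fixed differences (alternate allele in the majority in
#' many lines), error-prone sites (alternate allele at 10--30% frequency in
#' five or more populations), low-frequency background sites, and a small
#' number of variants shared among sibling populations of the same founder
#' (pre-existing variation that must be discarded).
#'
#' True mutation sites are given read support that passes the calling
#' thresholds; 57% of them are fixed (alternate frequency 1) and the rest
#' segregate above 55%, mirroring pooled-sequencing behaviour.
#'
#' @param evolution result of [simulate_evolution()].
#' @inheritParams simulate_genotypes
#' @param mean_depth mean sequencing depth per site per population.
#' @param n_parental,n_error_sites,n_background numbers of decoy sites.
#' @param n_shared_founder number of planted founder-shared variants.
#' @return list with `site_counts` (a [site_count_table()]), `annotation`
#'   (gene intervals), and `pop_founder` (named founder map over populations).
#' @export
simulate_site_counts <- function(evolution, config, seed = NULL,
                                 mean_depth = 23,
                                 n_parental = 30, n_error_sites = 20,
                                 n_background = 50, n_shared_founder = 2) {
  set.seed(seed %||% stage_seed(config$seed, "sites"))
  anno <- gene_annotation(config)
  allpops <- evolution$populations

  ## sequence populations of a founder subset balanced by focal allele
  focal <- evolution$truth$focal_allele
  fid <- evolution$truth$founder_fitness$founder_id
  nseq <- min(config$n_seq_founders %||% length(fid), length(fid))
  by_al <- split(fid, focal)
  want <- ceiling(nseq / length(by_al))
  chosen <- unlist(lapply(by_al, function(f) sample(f, min(want, length(f)))))
  chosen <- chosen[seq_len(min(nseq, length(chosen)))]
  seq_rows <- allpops$founder_id %in% chosen
  pops <- allpops$population_id[seq_rows]
  np <- length(pops)
  muts <- evolution$mutations
  muts <- muts[muts$population_id %in% pops, , drop = FALSE]
  bases <- c("A", "C", "G", "T")

  ## one distinct genomic site per mutation event
  ev_sites <- NULL
  if (nrow(muts)) {
    gi <- match(muts$gene, anno$gene)
    pos <- integer(nrow(muts))
    for (g in unique(gi)) {
      k <- which(gi == g)
      pos[k] <- sample(anno$start[g]:anno$end[g], length(k))
    }
    ref <- sample(bases, nrow(muts), replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
    ev_sites <- data.frame(chrom = anno$chrom[gi], pos = pos,
                           ref = ref, alt = alt,
                           consequence = muts$consequence,
                           population_id = muts$population_id)
  }

  ## planted founder-shared variants (standing variation artifacts)
  shared <- NULL
  fcount <- table(allpops$founder_id[seq_rows])
  cand <- names(fcount)[fcount >= 2]
  n_shared_founder <- min(n_shared_founder, length(cand))
  if (n_shared_founder > 0) {
    for (f in sample(cand, n_shared_founder)) {
      sibs <- sample(pops[allpops$founder_id[seq_rows] == f], 2)
      g <- sample(nrow(anno), 1)
      b <- sample(bases, 2)
      shared <- rbind(shared, data.frame(
        chrom = anno$chrom[g], pos = sample(anno$start[g]:anno$end[g], 1),
        ref = b[1], alt = b[2], consequence = "missense",
        population_id = sibs))
    }
  }

  ## decoy sites on intergenic positions
  decoy_pos <- function(k) {
    ch <- sample(seq_along(config$chromosome_lengths), k, replace = TRUE)
    data.frame(chrom = sprintf("chr%02d", ch),
               pos = 50000L + sample.int(10000L, k, replace = TRUE))
  }
  par_sites <- cbind(decoy_pos(n_parental), ref = sample(bases, n_parental, replace = TRUE))
  err_sites <- cbind(decoy_pos(n_error_sites), ref = sample(bases, n_error_sites, replace = TRUE))
  bg_sites <- cbind(decoy_pos(n_background), ref = sample(bases, n_background, replace = TRUE))

  all_present <- rbind(ev_sites, shared)
  site_key <- unique(all_present[c("chrom", "pos", "ref", "alt", "consequence")])
  decoy_df <- function(d, kind) {
    data.frame(chrom = d$chrom, pos = d$pos, ref = d$ref,
               alt = vapply(d$ref, function(b) sample(setdiff(bases, b), 1), ""),
               consequence = "noncoding", kind = kind)
  }
  site_key$kind <- "mutation"
  sites <- rbind(site_key,
                 decoy_df(par_sites, "parental"),
                 decoy_df(err_sites, "error"),
                 decoy_df(bg_sites, "background"))
  sites <- sites[!duplicated(sites[c("chrom", "pos")]), ]
  kind <- sites$kind
  sites$kind <- NULL
  ns <- nrow(sites)

  depth <- function(k) pmax(8L, stats::rpois(k, mean_depth))
  ref_m <- matrix(0L, ns, np, dimnames = list(NULL, pops))
  alt_m <- matrix(0L, ns, np, dimnames = list(NULL, pops))
  ## background sequencing depth with rare errors everywhere
  d0 <- matrix(depth(ns * np), ns, np)
  e0 <- matrix(stats::rbinom(ns * np, d0, 0.004), ns, np)
  ref_m[] <- d0 - e0
  alt_m[] <- e0

  put_alt <- function(i, j, freq) {
    d <- depth(length(i))
    a <- pmin(d, pmax(4L, round(d * freq), floor(d / 2) + 1L))
    a[freq <= 0.5] <- round(d[freq <= 0.5] * freq[freq <= 0.5])
    alt_m[cbind(i, j)] <<- a
    ref_m[cbind(i, j)] <<- d - a
  }

  skey <- paste(sites$chrom, sites$pos)
  if (!is.null(all_present) && nrow(all_present)) {
    i <- match(paste(all_present$chrom, all_present$pos), skey)
    j <- match(all_present$population_id, pops)
    fixed <- stats::runif(length(i)) < 0.57
    put_alt(i, j, ifelse(fixed, 1, stats::runif(length(i), 0.55, 0.98)))
  }
  idx_par <- which(kind == "parental")
  for (i in idx_par) put_alt(rep(i, np), seq_len(np),
                             stats::runif(np, 0.9, 1))
  idx_err <- which(kind == "error")
  for (i in idx_err) {
    j <- sample(np, sample(5:8, 1))
    put_alt(rep(i, length(j)), j, stats::runif(length(j), 0.12, 0.30))
  }
  idx_bg <- which(kind == "background")
  for (i in idx_bg) {
    j <- sample(np, sample(1:4, 1))
    put_alt(rep(i, length(j)), j, stats::runif(length(j), 0.12, 0.45))
  }

  ord <- order(sites$chrom, sites$pos)
  sc <- site_count_table(sites[ord, , drop = FALSE],
                         ref_m[ord, , drop = FALSE],
                         alt_m[ord, , drop = FALSE])
  pf <- allpops$founder_id
  names(pf) <- allpops$population_id
  list(site_counts = sc, annotation = anno, pop_founder = pf,
       sequenced_founders = sort(chosen), shared_planted = shared)
}

#' Simulate a complete synthetic cross dataset
#'
#' Runs all simulation stages -- genotypes, founder fitness, evolution,
#' measurements, and the pooled-sequencing site-count table -- from one
#' configuration.  Stages draw from named substreams of the configuration
#' seed, so identical configurations yield byte-identical datasets and each
#' stage is independently reproducible.
#'
#' @inheritParams simulate_genotypes
#' @param site_counts generate the pooled-sequencing layer (slowest stage).
#' @return object of class `cross_data`.
#' @export
simulate_cross <- function(config, site_counts = TRUE) {
  geno <- simulate_genotypes(config)
  fit <- simulate_founder_fitness(geno, config)
  evo <- simulate_evolution(fit, geno, config)
  meas <- simulate_measurements(evo, fit, config)
  sc <- if (site_counts) simulate_site_counts(evo, config) else NULL
  structure(list(config = config, genotypes = geno, founder_fitness = fit,
                 populations = evo$populations, mutations = evo$mutations,
                 truth = evo$truth, fitness_table = meas,
                 site_data = sc),
            class = "cross_data")
}

#' @export
print.cross_data <- function(x, ...) {
  cat(sprintf("Synthetic cross dataset: %d founders, %d evolved populations\n",
              nrow(x$founder_fitness), nrow(x$populations)))
  cat(sprintf("  %d loci; %d fitness measurements; %d mutation events\n",
              ncol(x$genotypes$alleles), nrow(x$fitness_table),
              nrow(x$mutations)))
  if (!is.null(x$site_data))
    cat(sprintf("  site-count table: %d sites x %d populations\n",
                nrow(x$site_data$site_counts$sites),
                ncol(x$site_data$site_counts$alt)))
  invisible(x)
}
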