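#' Read a cross dataset back from a directory of TSV tables
#'
#' Inverse of [write_cross_tables()]; the site-count layer and annotation are
#' optional.
#'
#' @param dir directory containing `genotypes.tsv`, `fitness.tsv`,
#'   `populations.tsv`, `mutations.tsv` (and optionally `site_counts.tsv`,
#'   `genes.bed`).
#' @return a `cross_data` object (without a configuration).
#' @export
cross_data_from_dir <- function(dir) {
  need <- c("genotypes.tsv", "fitness.tsv", "populations.tsv")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss))
    stop("missing input table(s): ", paste(miss, collapse = ", "))
  geno <- read_genotypes(file.path(dir, "genotypes.tsv"))
  sd_path <- file.path(dir, "site_counts.tsv")
  site_data <- NULL
  if (file.exists(sd_path)) {
    sc <- read_site_counts(sd_path)
    bed <- file.path(dir, "genes.bed")
    anno <- if (file.exists(bed)) {
      b <- utils::read.delim(bed, header = FALSE,
                             col.names = c("chrom", "start", "end", "name"))
      data.frame(gene = b$name, chrom = b$chrom,
                 start = b$start + 1L, end = b$end)
    } else NULL
    pops <- read_tsv(file.path(dir, "populations.tsv"))
    pf <- pops$founder_id; names(pf) <- pops$population_id
    site_data <- list(site_counts = sc, annotation = anno, pop_founder = pf)
  }
  mut_path <- file.path(dir, "mutations.tsv")
  structure(list(
    config = NULL,
    genotypes = geno,
    founder_fitness = if (file.exists(file.path(dir, "truth.tsv")))
      read_tsv(file.path(dir, "truth.tsv")) else NULL,
    populations = read_tsv(file.path(dir, "populations.tsv")),
    mutations = if (file.exists(mut_path)) read_tsv(mut_path) else NULL,
    truth = NULL,
    fitness_table = read_tsv(file.path(dir, "fitness.tsv")),
    site_data = site_data
  ), class = "cross_data")
}

## genotype matrix restricted to polymorphic loci
drop_monomorphic <- function(geno) {
  mono <- monomorphic_loci(geno)
  if (!any(mono)) return(geno)
  structure(list(alleles = geno$alleles[, !mono, drop = FALSE],
                 loci = geno$loci[!mono, , drop = FALSE],
                 founders = geno$founders),
            class = "genotype_matrix")
}

#' Run the full adaptability / pleiotropy analysis
#'
#' Orchestrates the whole pipeline on a dataset: per-strain fitness
#' summaries; broad-sense variance partitioning of founder fitness,
#' home-environment adaptability, and away-environment (pleiotropic) gains,
#' each with a delete-half jackknife confidence interval; narrow-sense REML
#' heritabilities on the kinship matrix; iterative QTL scans for fitness and
#' adaptability; the declining-adaptability, pleiotropy, combined
#' fitness + QTL, and normalized-difference models; the group-mean increment
#' table; and, when a site-count layer is present, mutation filtering and
#' calling, multi-hit genes, the QTL-overlap expectation, the mutation-count
#' trend, and the hierarchical mutual-information analysis.
#'
#' @param data a [cross_config()] (the dataset is simulated), a `cross_data`
#'   object, or a directory path of TSV tables (see [cross_data_from_dir()]).
#' @param output_dir optional directory; when given, result tables are
#'   written (`heritability.tsv`, `qtl_hits.tsv`, `model_fit.tsv`,
#'   `group_means.tsv`, `mi_results.tsv`, `calls.vcf`) together with a
#'   `manifest.yaml` recording seeds, parameters and per-stage record
#'   counts.
#' @param alpha significance level used by the QTL scans and model
#'   selection.
#' @param n_perm_qtl permutations per QTL-scan iteration.
#' @param n_jackknife delete-half jackknife resamples for broad-sense
#'   confidence intervals.
#' @param n_jackknife_reml jackknife resamples for REML confidence intervals
#'   (0 skips them; they dominate runtime).
#' @param n_perm_mi permutations of the mutual-information null.
#' @param n_boot bootstrap resamples (group means, trend, difference
#'   correlation).
#' @param seed seed for the analysis-stage resampling (simulation stages use
#'   the configuration seed).
#' @param focal_locus locus index of the focal allele; defaults to the
#'   configuration's focal locus or, failing that, the top fitness QTL.
#' @return object of class `evoherit_results`.
#' @export
run_full_analysis <- function(data, output_dir = NULL, alpha = 0.05,
                              n_perm_qtl = 1000, n_jackknife = 1000,
                              n_jackknife_reml = 0, n_perm_mi = 2000,
                              n_boot = 1000, seed = 1, focal_locus = NULL) {
  t0 <- proc.time()[["elapsed"]]
  stages <- character(0)
  timings <- numeric(0)
  run_stage <- function(name, expr) {
    ts <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    stages <<- c(stages, name)
    timings <<- c(timings, proc.time()[["elapsed"]] - ts)
    names(timings)[length(timings)] <<- name
    out
  }

  cross <- run_stage("input", {
    if (inherits(data, "cross_config")) simulate_cross(data)
    else if (inherits(data, "cross_data")) data
    else if (is.character(data) && length(data) == 1) cross_data_from_dir(data)
    else stop("expected a cross_config, cross_data, or directory path")
  })
  config <- cross$config
  envs <- config$environments %||% sort(unique(cross$fitness_table$environment))
  ## locus indices throughout refer to the full marker table; monomorphic
  ## loci are pruned only where the method requires it (kinship)
  geno <- cross$genotypes
  founders <- geno$founders
  focal_locus <- focal_locus %||% config$focal_locus

  ## -- fitness summaries ---------------------------------------------------
  summaries <- run_stage("fitness_summaries", {
    s <- summarize_fitness_table(cross$fitness_table)
    s$strain_id <- as.character(s$strain_id)
    s
  })
  fsum <- function(env) {
    s <- summaries[summaries$environment == env &
                     summaries$strain_id %in% founders, ]
    s[match(founders, s$strain_id), ]
  }
  psum <- function(env) {
    s <- summaries[summaries$environment == env &
                     summaries$strain_id %in% cross$populations$population_id, ]
    s[match(cross$populations$population_id, s$strain_id), ]
  }

  ## measured increments per population per measured environment
  pops <- cross$populations
  d_meas <- list()
  for (env in envs) {
    fm <- fsum(env); pm <- psum(env)
    d_meas[[env]] <- pm$mean - fm$mean[match(pops$founder_id, founders)]
  }

  ## -- broad-sense heritability --------------------------------------------
  herit <- run_stage("broad_sense", {
    out <- list()
    for (env in envs) {
      fm <- fsum(env)
      vc <- broad_sense_fitness(fm$mean, fm$error_var)
      jk <- delete_half_jackknife(function(sub) {
        k <- match(sub, founders)
        broad_sense_fitness(fm$mean[k], fm$error_var[k])$H2
      }, founders, n_resamples = n_jackknife, seed = seed)
      vc$ci <- jk$ci
      out[[paste0("fitness_", env)]] <- vc

      home <- pops$home_env == env
      vc <- broad_sense_increment(d_meas[[env]][home], pops$founder_id[home])
      jk <- delete_half_jackknife(function(sub) {
        k <- home & pops$founder_id %in% sub
        broad_sense_increment(d_meas[[env]][k], pops$founder_id[k])$H2
      }, founders, n_resamples = n_jackknife, seed = seed + 1)
      vc$ci <- jk$ci
      out[[paste0("adaptability_", env)]] <- vc

      away <- setdiff(envs, env)
      vc <- broad_sense_increment(d_meas[[away]][home], pops$founder_id[home])
      jk <- delete_half_jackknife(function(sub) {
        k <- home & pops$founder_id %in% sub
        broad_sense_increment(d_meas[[away]][k], pops$founder_id[k])$H2
      }, founders, n_resamples = n_jackknife, seed = seed + 2)
      vc$ci <- jk$ci
      out[[paste0("pleiotropy_", env, "_pops_at_", away)]] <- vc
    }
    out
  })

  ## founder means of increments per (home env, measured env)
  inc_mean <- function(home_env, meas_env) {
    k <- pops$home_env == home_env
    m <- tapply(d_meas[[meas_env]][k], pops$founder_id[k], mean)
    as.numeric(m[founders])
  }

  ## -- narrow-sense REML ----------------------------------------------------
  reml <- run_stage("reml", {
    K <- kinship_matrix(drop_monomorphic(geno))
    out <- list(kinship = K)
    for (env in envs) {
      out[[paste0("fitness_", env)]] <-
        narrow_sense_reml(fsum(env)$mean, K,
                          n_jackknife = n_jackknife_reml, seed = seed)
      out[[paste0("adaptability_", env)]] <-
        narrow_sense_reml(inc_mean(env, env), K,
                          n_jackknife = n_jackknife_reml, seed = seed)
      away <- setdiff(envs, env)
      out[[paste0("pleiotropy_", env, "_pops_at_", away)]] <-
        narrow_sense_reml(inc_mean(env, away), K,
                          n_jackknife = n_jackknife_reml, seed = seed)
    }
    out
  })

  ## -- QTL scans ------------------------------------------------------------
  scans <- run_stage("qtl_scan", {
    out <- list()
    for (env in envs) {
      fm <- fsum(env)
      out[[paste0("fitness_", env)]] <-
        forward_scan(geno, fm$mean, weights = sqrt(fm$n_reps),
                     alpha = alpha, n_perm = n_perm_qtl, seed = seed)
      out[[paste0("adaptability_", env)]] <-
        forward_scan(geno, inc_mean(env, env), weights = sqrt(fm$n_reps),
                     alpha = alpha, n_perm = n_perm_qtl, seed = seed + 1)
    }
    out
  })
  ## focal locus fallback for datasets without a configuration: the
  ## largest-effect fitness QTL plays the focal role
  if (is.null(focal_locus)) {
    h <- scans[[paste0("fitness_", envs[1])]]$hits
    if (!nrow(h)) stop("no focal locus available: supply 'focal_locus'")
    focal_locus <- h$locus[1]
  }
  qtl_r2 <- list()
  for (nm in names(scans)) {
    s <- scans[[nm]]
    if (!nrow(s$hits)) { qtl_r2[[nm]] <- NA_real_; next }
    env <- sub(".*_", "", nm)
    trait <- if (startsWith(nm, "fitness")) fsum(env)$mean else
      inc_mean(env, env)
    qtl_r2[[nm]] <- additive_model_r2(geno, s$hits$locus, trait,
                                      weights = sqrt(fsum(env)$n_reps))
  }

  ## -- fitness-based models -------------------------------------------------
  models <- run_stage("models", {
    out <- list()
    for (env in envs) {
      X <- fsum(env)$mean
      dX <- inc_mean(env, env)
      out[[paste0("adaptability_", env)]] <- fit_adaptability_vs_fitness(dX, X)
      out[[paste0("adaptability_noise_", env)]] <-
        noise_robustness_fit(dX, X, fsum(env)$error_var, seed = seed)

      ## combined fitness + QTL model
      master <- unique(c(scans[[paste0("fitness_", env)]]$hits$locus,
                         scans[[paste0("adaptability_", env)]]$hits$locus))
      code <- allele_code(geno)
      gstar <- if (!is.null(focal_locus) && focal_locus <= ncol(code))
        code[, focal_locus] else code[, master[1]]
      other <- setdiff(master, focal_locus)
      qcodes <- code[, other, drop = FALSE]
      out[[paste0("combined_", env)]] <-
        fit_combined_model(dX, X, qcodes, gstar, alpha = alpha)

      away <- setdiff(envs, env)
      out[[paste0("pleiotropy_", env, "_pops_at_", away)]] <-
        fit_pleiotropy_model(inc_mean(env, away), fsum(away)$mean, X)
    }
    ## normalized-difference (home-environment effect) analysis
    nt <- normalize_traits(fsum(envs[1])$mean, fsum(envs[2])$mean,
                           inc_mean(envs[1], envs[1]),
                           inc_mean(envs[2], envs[2]))
    out$difference <- difference_correlation(nt$X - nt$Y, nt$dX - nt$dY,
                                             n_boot = n_boot, seed = seed)
    out
  })

  ## -- group means -----------------------------------------------------------
  group_means <- run_stage("group_means", {
    gp <- pops
    for (env in envs) gp[[paste0("d_", env)]] <- d_meas[[env]]
    if (is.null(gp$focal_allele))
      gp$focal_allele <- genotype_alleles(geno)[match(gp$founder_id, founders),
                                                focal_locus]
    group_mean_increments(gp, environments = envs, n_boot = n_boot,
                          seed = seed, scale = 100)
  })

  ## -- mutation analyses -----------------------------------------------------
  mutations <- NULL
  if (!is.null(cross$site_data)) {
    mutations <- run_stage("mutations", {
      sd <- cross$site_data
      filt <- apply_site_filters(sd$site_counts)
      calls <- call_mutations(filt$filtered)
      shared <- remove_shared_founder_snvs(calls, sd$pop_founder)
      ann <- assign_genes_and_multihit(shared$calls, sd$annotation)
      func <- ann$calls[!is.na(ann$calls$gene) &
                          ann$calls$consequence %in%
                          c("missense", "putative_LOF", "indel"), ]
      ## mutation analyses run on the sequenced population subset
      pop_ids <- colnames(sd$site_counts$alt)
      sp <- pops[match(pop_ids, pops$population_id), ]
      mm <- mutation_matrix(func, pop_ids, genes = ann$multihit)
      labels <- data.frame(
        focal_allele = genotype_alleles(geno)[match(sp$founder_id,
                                                    founders), focal_locus],
        environment = sp$home_env,
        founder = sp$founder_id)
      mi <- mi_hierarchy(mm, labels, n_perm = n_perm_mi, seed = seed)

      counts <- as.vector(table(factor(func$population_id,
                                       levels = pop_ids)))
      ffit <- numeric(length(pop_ids))
      for (env in envs) {
        k <- sp$home_env == env
        ffit[k] <- fsum(env)$mean[match(sp$founder_id[k], founders)]
      }
      trend <- mutation_count_trend(counts, ffit, sp$founder_id,
                                    n_boot = n_boot, seed = seed)

      ## genes inside QTL confidence intervals, across all scans
      qtl_genes <- character(0)
      if (!is.null(sd$annotation)) {
        for (s in scans) if (nrow(s$hits)) {
          for (i in seq_len(nrow(s$hits))) {
            h <- s$hits[i, ]
            a <- sd$annotation
            inside <- a$chrom == h$chrom & a$end >= h$ci_start &
              a$start <= h$ci_end
            qtl_genes <- union(qtl_genes, a$gene[inside])
          }
        }
      }
      overlap <- expected_overlap(length(ann$multihit), length(qtl_genes),
                                  nrow(sd$annotation),
                                  observed = length(intersect(ann$multihit,
                                                              qtl_genes)))
      list(filter_log = filt$removed, calls = ann$calls,
           removed_shared = shared$removed, multihit = ann$multihit,
           gene_populations = ann$gene_populations, matrix = mm, mi = mi,
           trend = trend, qtl_genes = qtl_genes, overlap = overlap)
    })
  }

  res <- structure(list(
    cross = cross, environments = envs, herit = herit, reml = reml,
    scans = scans, qtl_r2 = qtl_r2, models = models,
    group_means = group_means, mutations = mutations,
    heritability_table = NULL,
    params = list(alpha = alpha, n_perm_qtl = n_perm_qtl,
                  n_jackknife = n_jackknife, n_perm_mi = n_perm_mi,
                  n_boot = n_boot, seed = seed,
                  config_seed = config$seed %||% NA,
                  focal_locus = focal_locus),
    timings = timings
  ), class = "evoherit_results")
  res$heritability_table <- heritability_table(res)

  if (!is.null(output_dir)) run_stage("write_outputs", {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(res$heritability_table, file.path(output_dir, "heritability.tsv"))
    hits <- do.call(rbind, lapply(names(scans), function(nm) {
      h <- scans[[nm]]$hits
      if (nrow(h)) cbind(trait = nm, h) else NULL
    }))
    write_tsv(hits %||% data.frame(), file.path(output_dir, "qtl_hits.tsv"))
    fitrows <- do.call(rbind, lapply(names(models), function(nm) {
      m <- models[[nm]]
      if (inherits(m, "combined_fit")) m <- m$full
      if (!inherits(m, "evo_fit")) return(NULL)
      data.frame(model = nm, term = m$terms, estimate = m$coefficients,
                 se = m$se, p = m$p,
                 p_adj = if (!is.null(m$p_adj)) m$p_adj else NA_real_)
    }))
    write_tsv(fitrows, file.path(output_dir, "model_fit.tsv"))
    write_tsv(group_means, file.path(output_dir, "group_means.tsv"))
    if (!is.null(mutations)) {
      write_calls_vcf(mutations$calls, file.path(output_dir, "calls.vcf"))
      mi_tab <- do.call(rbind, lapply(names(mutations$mi), function(nm) {
        m <- mutations$mi[[nm]]
        data.frame(analysis = nm, statistic = m$statistic,
                   null_mean = m$null_mean, centered = m$centered,
                   null_lo = m$null_ci[1], null_hi = m$null_ci[2], p = m$p)
      }))
      write_tsv(mi_tab, file.path(output_dir, "mi_results.tsv"))
    }
    manifest <- list(
      package = "evoherit",
      seed = seed, config_seed = config$seed %||% NA,
      alpha = alpha, n_perm_qtl = n_perm_qtl, n_jackknife = n_jackknife,
      n_perm_mi = n_perm_mi, n_boot = n_boot,
      thresholds = list(call_frequency = 0.5, call_support = 4,
                        parental_majority_lines = 6,
                        error_site_frequency = 0.10, error_site_pops = 5,
                        lod_decline = 1.5, allele_code = 0.5),
      stages = stages,
      timings_s = as.list(round(timings, 3)),
      records = list(founders = length(founders),
                     populations = nrow(pops),
                     loci = ncol(genotype_alleles(geno)),
                     mutation_calls = if (!is.null(mutations))
                       nrow(mutations$calls) else 0)
    )
    yaml::write_yaml(manifest, file.path(output_dir, "manifest.yaml"))
  })
  res
}

## Table-1-style summary: one row per trait, heritabilities and model r2
heritability_table <- function(res) {
  envs <- res$environments
  rows <- list()
  for (env in envs) {
    away <- setdiff(envs, env)
    for (nm in c(paste0("fitness_", env), paste0("adaptability_", env),
                 paste0("pleiotropy_", env, "_pops_at_", away))) {
      vc <- res$herit[[nm]]
      if (is.null(vc)) next
      r2f <- if (startsWith(nm, "adaptability"))
        res$models[[paste0("adaptability_", env)]]$r2
      else if (startsWith(nm, "pleiotropy")) res$models[[nm]]$r2
      else NA_real_
      r2c <- if (startsWith(nm, "adaptability"))
        res$models[[paste0("combined_", env)]]$full$r2 else NA_real_
      rows[[nm]] <- data.frame(
        trait = nm, H2 = vc$H2, H2_lo = vc$ci[1], H2_hi = vc$ci[2],
        h2 = res$reml[[nm]]$h2,
        r2_qtl = res$qtl_r2[[nm]] %||% NA_real_,
        r2_fitness = r2f, r2_combined = r2c)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.evoherit_results <- function(x, ...) {
  cat("evoherit full analysis\n")
  cat(sprintf("  %d founders, %d populations, environments: %s\n",
              length(x$cross$genotypes$founders), nrow(x$cross$populations),
              paste(x$environments, collapse = ", ")))
  cat("\nHeritability summary:\n")
  tab <- x$heritability_table
  tab[-1] <- lapply(tab[-1], function(v) round(v, 3))
  print(tab, row.names = FALSE)
  for (env in x$environments) {
    m <- x$models[[paste0("adaptability_", env)]]
    cat(sprintf("\nAdaptability at %s: slope %.3f (r2 = %.3f)\n",
                env, m$coefficients[["fitness"]], m$r2))
  }
  if (!is.null(x$mutations)) {
    cat(sprintf("\nMutations: %d calls, %d multi-hit genes; count-trend slope %.3f (p = %.3g)\n",
                nrow(x$mutations$calls), length(x$mutations$multihit),
                x$mutations$trend$slope, x$mutations$trend$p))
    mi <- x$mutations$mi
    cat(sprintf("  MI: focal %.3f bits (p %.3g); env|focal %.3f (p %.3g); founder|focal,env %.3f (p %.3g)\n",
                mi$focal$centered, mi$focal$p,
                mi$environment_given_focal$centered,
                mi$environment_given_focal$p,
                mi$founder_given_focal_env$centered,
                mi$founder_given_focal_env$p))
  }
  invisible(x)
}
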