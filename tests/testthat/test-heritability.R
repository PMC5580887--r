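test_that("fitness variance partition matches hand computations", {
  vc <- broad_sense_fitness(c(1, 3), c(0, 0))
  expect_equal(vc$sigma_t2, 1)
  expect_equal(vc$sigma_noise2, 0)
  expect_equal(vc$H2, 1)

  ## zero total variance: undefined, flagged, clipped to 0
  vc <- broad_sense_fitness(c(1, 1), c(1, 1))
  expect_equal(vc$sigma_t2, 0)
  expect_equal(vc$sigma_f2, -1)
  expect_true(vc$flagged)
  expect_true(is.na(vc$H2))
  expect_equal(vc$H2_clipped, 0)

  vc <- broad_sense_fitness(c(0, 2, 4), c(0.5, 0.5, 0.5))
  expect_equal(vc$sigma_t2, 8 / 3)
  expect_equal(vc$sigma_noise2, 0.5)
  expect_equal(vc$H2, (8 / 3 - 0.5) / (8 / 3))
})

test_that("increment variance partition matches hand computations", {
  vc <- broad_sense_increment(c(1, 1, 3, 3), c("A", "A", "B", "B"))
  expect_equal(vc$sigma_noise2, 0)
  expect_equal(vc$sigma_t2, 1)
  expect_equal(vc$H2, 1)

  ## one founder, two populations: negative founder component, clipped
  vc <- broad_sense_increment(c(1, 3), c("A", "A"))
  expect_equal(vc$sigma_noise2, 2)
  expect_equal(vc$sigma_t2, 1)
  expect_equal(vc$sigma_f2, -1)
  expect_equal(vc$H2_clipped, 0)

  expect_error(broad_sense_increment(c(1, 2), c("A", "B")), "single")
  expect_warning(broad_sense_increment(c(1, 2, 3), c("A", "A", "B")),
                 "excluding")
})

test_that("both partitions agree with the brute-force oracle", {
  set.seed(42)
  for (i in 1:300) {
    n <- sample(3:12, 1)
    means <- rnorm(n)
    evars <- runif(n, 0, 0.5)
    vc <- broad_sense_fitness(means, evars)
    or <- oracle_broad_fitness(means, evars)
    expect_equal(vc$sigma_t2, or$sigma_t2, tolerance = 1e-12)
    expect_equal(vc$H2, or$H2, tolerance = 1e-12)

    nf <- sample(2:6, 1)
    founder <- rep(sprintf("f%d", seq_len(nf)), each = sample(2:5, 1))
    dx <- rnorm(length(founder))
    vc <- broad_sense_increment(dx, founder)
    or <- oracle_broad_increment(dx, founder)
    expect_equal(vc$sigma_noise2, or$sigma_p2, tolerance = 1e-12)
    expect_equal(vc$H2, or$H2, tolerance = 1e-12)
  }
})

test_that("measurement noise does not inflate expected increment heritability", {
  set.seed(7)
  h_clean <- h_noisy <- numeric(30)
  for (i in 1:30) {
    founder <- rep(sprintf("f%d", 1:40), each = 4)
    mu <- rnorm(40, 0, 1)[rep(1:40, each = 4)]
    dx <- mu + rnorm(length(founder), 0, 1)
    h_clean[i] <- broad_sense_increment(dx, founder)$H2
    h_noisy[i] <- broad_sense_increment(dx + rnorm(length(dx), 0, 1),
                                        founder)$H2
  }
  expect_lt(mean(h_noisy), mean(h_clean))
})

test_that("delete-half jackknife is deterministic and degenerate on constants", {
  jk <- delete_half_jackknife(function(ids) 1.5, 1:20, n_resamples = 50,
                              seed = 3)
  expect_equal(unname(jk$ci), c(1.5, 1.5))
  x <- rnorm(30)
  st <- function(ids) mean(x[ids])
  jk1 <- delete_half_jackknife(st, 1:30, n_resamples = 2, seed = 5)
  jk2 <- delete_half_jackknife(st, 1:30, n_resamples = 2, seed = 5)
  expect_identical(jk1$ci, jk2$ci)
  ## failure accounting
  bad <- function(ids) if (runif(1) < 0.5) stop("no") else 1
  expect_error(delete_half_jackknife(bad, 1:20, n_resamples = 100, seed = 1),
               "failed")
})

test_that("jackknife CI covers the generative increment heritability", {
  ## H2 ~ 0.62 by construction; the CI should cover it in most replicates
  hits <- 0
  for (s in 1:10) {
    cfg <- recovery_config(seed = 300 + s)
    cross <- simulate_cross(cfg, site_counts = FALSE)
    pops <- cross$populations
    k <- pops$home_env == "OT"
    sm <- summarize_fitness_table(cross$fitness_table, "OT", "founder")
    sm <- sm[match(cross$genotypes$founders, sm$strain_id), ]
    d <- cross$fitness_table  # measured increments
    ps <- summarize_fitness_table(cross$fitness_table, "OT", "population")
    ps <- ps[match(pops$population_id, ps$strain_id), ]
    dX <- ps$mean - sm$mean[match(pops$founder_id, cross$genotypes$founders)]
    jk <- delete_half_jackknife(function(sub) {
      kk <- k & pops$founder_id %in% sub
      broad_sense_increment(dX[kk], pops$founder_id[kk])$H2
    }, cross$genotypes$founders, n_resamples = 100, seed = s)
    tr <- theoretical_components(cfg)$H2_increment[["OT"]]
    if (jk$ci[1] <= tr && tr <= jk$ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("kinship matrix has the closed-form structure", {
  ## identical founders: off-diagonal equals the diagonal
  alle <- rbind(c("BY", "RM", "BY"), c("BY", "RM", "BY"),
                c("RM", "BY", "RM"))
  rownames(alle) <- c("a", "b", "c")
  colnames(alle) <- paste0("chr01:", 1:3 * 1000)
  K <- kinship_matrix(alle)
  expect_equal(K["a", "b"], K["a", "a"])
  ## two founders opposite at every locus, p = 1/2: R_12 = -1, R_ii = +1
  opp <- rbind(rep("BY", 10), rep("RM", 10))
  rownames(opp) <- c("x", "y")
  K2 <- kinship_matrix(opp)
  expect_equal(unname(K2["x", "y"]), -1)
  expect_equal(unname(diag(K2)), c(1, 1))
  ## concentration: random panel has small relatedness off the diagonal
  g <- random_geno(230, 1000, seed = 8)
  K3 <- kinship_matrix(g)
  expect_lt(mean(abs(K3[upper.tri(K3)])), 0.1)
  ## monomorphic loci are rejected by name
  mono <- rbind(c("BY", "BY"), c("BY", "RM"))
  colnames(mono) <- c("chr01:1000", "chr01:2000")
  rownames(mono) <- c("x", "y")
  expect_error(kinship_matrix(mono), "chr01:1000")
})

test_that("REML recovers the noiseless additive limit", {
  g <- random_geno(60, 300, seed = 10)
  K <- kinship_matrix(g)
  set.seed(10)
  ev <- eigen(K, symmetric = TRUE)
  y <- as.vector(ev$vectors %*% (sqrt(pmax(ev$values, 0)) * rnorm(60)))
  fit <- narrow_sense_reml(y, K)
  expect_gte(fit$h2, 0.99)
})

test_that("REML concentrates near zero for pure-noise traits", {
  ## a linkage-structured panel gives the kinship the eigenvalue spread
  ## needed to identify the additive component
  g <- simulate_genotypes(cross_config(seed = 2))
  K <- kinship_matrix(g)
  set.seed(11)
  h2s <- replicate(30, narrow_sense_reml(rnorm(230), K)$h2)
  expect_lt(mean(h2s), 0.1)
  expect_gte(mean(h2s < 0.1), 0.7)
})

test_that("REML optimum dominates random admissible points", {
  g <- random_geno(80, 200, seed = 12)
  K <- kinship_matrix(g)
  set.seed(12)
  ev <- eigen(K, symmetric = TRUE)
  y <- as.vector(ev$vectors %*% (sqrt(pmax(ev$values, 0)) * rnorm(80))) +
    rnorm(80)
  fit <- narrow_sense_reml(y, K)
  lambdas <- runif(50, 1e-6, 1 - 1e-6)
  lls <- vapply(lambdas, fit$profile, 0)
  expect_true(all(fit$loglik >= lls - 1e-8))
})
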