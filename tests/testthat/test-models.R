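test_that("adaptability regression handles degenerate and exact inputs", {
  X <- c(1, 2, 3, 4, 5)
  fit <- fit_adaptability_vs_fitness(rep(2, 5), X)
  expect_equal(unname(coef(fit)[2]), 0)
  expect_equal(fit$r2, 0)
  fit <- fit_adaptability_vs_fitness(3 - 0.5 * X, X)
  expect_equal(fit$r2, 1)
  expect_equal(unname(coef(fit)[2]), -0.5)
  expect_error(fit_adaptability_vs_fitness(1:3, rep(1, 3)), "zero variance")
})

test_that("all regression fits match the normal-equations oracle", {
  set.seed(5)
  for (i in 1:200) {
    n <- sample(10:30, 1)
    X <- rnorm(n); Y <- rnorm(n)
    d <- 0.3 - 0.4 * X + 0.2 * Y + rnorm(n, 0, 0.5)
    f1 <- fit_adaptability_vs_fitness(d, X)
    o1 <- oracle_ols(cbind(1, X), d)
    expect_equal(unname(coef(f1)), o1$beta, tolerance = 1e-10)
    expect_equal(f1$r2, o1$r2, tolerance = 1e-10)
    f2 <- fit_pleiotropy_model(d, X, Y)
    o2 <- oracle_ols(cbind(1, X, Y), d)
    expect_equal(unname(coef(f2)), o2$beta, tolerance = 1e-10)
    expect_equal(f2$r2, o2$r2, tolerance = 1e-10)
  }
})

test_that("noise-added refits attenuate but never flatter the correlation", {
  set.seed(9)
  n <- 2000
  X <- rnorm(n)
  d <- -0.5 * X + rnorm(n, 0, 0.5)
  base <- noise_robustness_fit(d, X, rep(0, n), n_draws = 5, seed = 1)
  expect_equal(base$mean_r2, base$fit$r2, tolerance = 1e-12)
  ## error variance equal to Var(X): attenuation factor ~ 1/2
  nr <- noise_robustness_fit(d, X, rep(var(X), n), n_draws = 50, seed = 2)
  expect_equal(nr$mean_r2, base$fit$r2 / 2, tolerance = 0.05 / (base$fit$r2 / 2))
  expect_lt(nr$mean_r2, base$fit$r2)
  ## deterministic given seed
  nr2 <- noise_robustness_fit(d, X, rep(var(X), n), n_draws = 50, seed = 2)
  expect_identical(nr$mean_r2, nr2$mean_r2)
})

test_that("pleiotropy model attributes significance to the generative predictor", {
  set.seed(11)
  b_sig <- g_sig <- logical(10)
  for (i in 1:10) {
    n <- 230
    X <- rnorm(n); Y <- 0.6 * X + rnorm(n, 0, 0.8)
    d <- -0.5 * X + rnorm(n, 0, 0.3)
    fit <- fit_pleiotropy_model(d, X, Y)
    b_sig[i] <- fit$p[["X"]] < 0.05
    g_sig[i] <- fit$p[["Y"]] < 0.05
  }
  expect_true(all(b_sig))
  expect_lte(sum(g_sig), 3)
  ## duplicated predictor flags collinearity
  X <- rnorm(30)
  fit <- fit_pleiotropy_model(rnorm(30), X, X + 1e-9 * rnorm(30))
  expect_match(fit$note, "collinear")
})

test_that("combined model selects a true interaction and prunes null terms", {
  set.seed(13)
  retained <- 0
  for (i in 1:10) {
    n <- 230
    gstar <- sample(c(-0.5, 0.5), n, replace = TRUE)
    q1 <- sample(c(-0.5, 0.5), n, replace = TRUE)
    q2 <- sample(c(-0.5, 0.5), n, replace = TRUE)
    X <- rnorm(n, 0, 0.08)
    d <- -0.5 * X + 0.35 * gstar + 0.45 * gstar * q1 + rnorm(n, 0, 0.1)
    cm <- fit_combined_model(d, X, cbind(Q1 = q1, Q2 = q2), gstar)
    if ("gstar_x_Q1" %in% cm$selected) retained <- retained + 1
    ## refit never keeps a term that was not significant in the full model
    expect_true(all(cm$full$p_adj[cm$selected] <= cm$alpha))
  }
  expect_gte(retained, 9)

  ## pure-noise response: interactions essentially never retained
  set.seed(14)
  false_terms <- 0
  for (i in 1:10) {
    n <- 230
    gstar <- sample(c(-0.5, 0.5), n, replace = TRUE)
    q1 <- sample(c(-0.5, 0.5), n, replace = TRUE)
    d <- rnorm(n)
    cm <- fit_combined_model(d, rnorm(n, 0, 0.08), cbind(Q1 = q1), gstar)
    false_terms <- false_terms + length(cm$selected)
  }
  expect_lte(false_terms, 3)
})

test_that("combined model r-squared dominates the fitness-only model", {
  set.seed(15)
  for (i in 1:10) {
    n <- 100
    gstar <- sample(c(-0.5, 0.5), n, replace = TRUE)
    q1 <- sample(c(-0.5, 0.5), n, replace = TRUE)
    X <- rnorm(n)
    d <- -0.4 * X + 0.1 * gstar + rnorm(n, 0, 0.5)
    f_only <- fit_adaptability_vs_fitness(d, X)
    cm <- fit_combined_model(d, X, cbind(Q1 = q1), gstar)
    expect_gte(cm$full$r2, f_only$r2 - 1e-12)
  }
})

test_that("normalization yields unit-scale traits, also within strata", {
  set.seed(17)
  X <- rnorm(50, 2, 3); Y <- rnorm(50); dX <- rnorm(50); dY <- rnorm(50)
  nt <- normalize_traits(X, Y, dX, dY)
  for (v in nt) {
    expect_equal(mean(v), 0, tolerance = 1e-12)
    expect_equal(sd(v), 1, tolerance = 1e-12)
  }
  ## a value one sd above the mean maps to 1
  v <- c(1, 2, 3)   # mean 2, sd 1
  nt1 <- normalize_traits(v, v, v, v)
  expect_equal(nt1$X[3], 1)
  strata <- rep(c("RM", "BY"), each = 25)
  nts <- normalize_traits(X, Y, dX, dY, strata = strata)
  for (g in c("RM", "BY")) {
    expect_equal(mean(nts$X[strata == g]), 0, tolerance = 1e-12)
    expect_equal(sd(nts$dY[strata == g]), 1, tolerance = 1e-12)
  }
  expect_error(normalize_traits(rep(1, 5), Y[1:5], dX[1:5], dY[1:5]),
               "zero standard deviation")
})

test_that("difference correlation detects exact opposition and independence", {
  set.seed(19)
  u <- rnorm(40)
  dc <- difference_correlation(u, -u, n_boot = 500, seed = 1)
  expect_equal(dc$r, -1)
  expect_equal(dc$r2, 1)
  expect_lt(dc$p, 0.01)
  dc1 <- difference_correlation(u, -u, n_boot = 500, seed = 1)
  expect_identical(dc$p, dc1$p)
  ## independent inputs: p is typically non-significant
  ps <- replicate(20, {
    difference_correlation(rnorm(40), rnorm(40), n_boot = 300,
                           seed = sample.int(1e6, 1))$p
  })
  expect_gte(sum(ps > 0.05), 14)
})

test_that("independent declining-adaptability rules produce a negative difference correlation", {
  set.seed(21)
  n <- 230
  X <- rnorm(n); Y <- 0.6 * X + rnorm(n, 0, 0.8)
  dX <- -0.5 * X + rnorm(n, 0, 0.6)
  dY <- -0.5 * Y + rnorm(n, 0, 0.6)
  nt <- normalize_traits(X, Y, dX, dY)
  dc <- difference_correlation(nt$X - nt$Y, nt$dX - nt$dY,
                               n_boot = 2000, seed = 2)
  expect_lt(dc$r, 0)
  expect_lt(dc$p, 0.05)
})

test_that("group-mean increment table is exact on degenerate data and reproducible", {
  pops <- data.frame(
    focal_allele = rep(c("RM", "BY"), each = 8),
    home_env = rep(rep(c("OT", "HT"), each = 4), 2),
    d_OT = 3, d_HT = 3)
  gm <- group_mean_increments(pops, n_boot = 100, seed = 1)
  expect_true(all(gm$mean == 3))
  expect_true(all(gm$lo == 3 & gm$hi == 3))
  ## home gain much larger than away gain is preserved in the cell means
  pops$d_HT <- ifelse(pops$home_env == "HT", 20, 9) + rnorm(16, 0, 0.1)
  gm2 <- group_mean_increments(pops, n_boot = 100, seed = 2)
  home_ht <- gm2$mean[gm2$evolved_in == "HT" & gm2$measured_in == "HT"]
  away_ht <- gm2$mean[gm2$evolved_in == "OT" & gm2$measured_in == "HT"]
  expect_true(all(home_ht > away_ht))
  gm3 <- group_mean_increments(pops, n_boot = 100, seed = 2)
  expect_identical(gm2, gm3)
})
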