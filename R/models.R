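## Fitness-based models of adaptability and pleiotropy.
##
## All fits are ordinary least squares on founder means (matching the
## convention of averaging the replicate populations of a founder);
## per-population fitting is available via the `per_population` data the
## caller passes in.

## wrap an lm into the light-weight fit container used throughout
wrap_fit <- function(fit, n, note = NULL) {
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  y <- stats::fitted(fit) + stats::residuals(fit)
  sst <- sum((y - mean(y))^2)
  ## with an intercept, rss <= sst holds exactly; clamping only absorbs
  ## floating-point noise when the response is (near-)constant
  r2 <- if (sst > 0) min(1, max(0, 1 - sum(stats::residuals(fit)^2) / sst))
        else 0
  structure(list(
    terms = rownames(co),
    coefficients = co[, "Estimate"],
    se = co[, "Std. Error"],
    p = co[, "Pr(>|t|)"],       # single-df F-test == squared-t test
    r2 = r2,
    n = n,
    residuals = stats::residuals(fit),
    fitted = stats::fitted(fit),
    lm = fit,
    note = note
  ), class = "evo_fit")
}

#' @export
print.evo_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Linear model fit (n = %d, r2 = %.*g)\n", x$n, digits, x$r2))
  tab <- data.frame(estimate = x$coefficients, se = x$se, p = x$p)
  if (!is.null(x$p_adj)) tab$p_adj <- x$p_adj
  print(signif(as.matrix(tab), digits))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' @export
coef.evo_fit <- function(object, ...) object$coefficients

#' @export
predict.evo_fit <- function(object, newdata = NULL, ...) {
  stats::predict(object$lm, newdata = newdata, ...)
}

#' @export
residuals.evo_fit <- function(object, ...) object$residuals

#' Declining-adaptability regression
#'
#' Ordinary least squares of the mean fitness increment of each founder on
#' its fitness, `dX_i = alpha + beta * X_i + eps_i`.  A negative fitted
#' slope is the rule of declining adaptability; the sign is unconstrained.
#'
#' @param increments per-founder mean fitness increments.
#' @param fitness per-founder fitness (same order).
#' @return an `evo_fit`.
#' @export
fit_adaptability_vs_fitness <- function(increments, fitness) {
  if (length(increments) != length(fitness)) stop("length mismatch")
  if (length(fitness) < 3) stop("need >= 3 founders")
  if (stats::var(fitness) == 0) stop("zero variance in fitness")
  wrap_fit(stats::lm(increments ~ fitness,
                     data = data.frame(increments, fitness)),
           length(fitness))
}

#' Robustness of the adaptability fit to measurement noise in the predictor
#'
#' Measurement errors in founder fitness enter both the predictor and (with
#' opposite sign) the increment, and could create spurious correlation.  To
#' bound the effect, normal noise with the per-founder error variance is
#' added to the fitness predictor and the regression refitted `n_draws`
#' times; the attenuated mean correlation is compared with the noiseless fit.
#'
#' @inheritParams fit_adaptability_vs_fitness
#' @param error_vars per-founder error variances of the fitness means.
#' @param n_draws number of noise draws.
#' @param seed RNG seed (deterministic given seed).
#' @return list with the noiseless `fit`, `mean_r`, `mean_r2`, `sd_r2`, and
#'   the per-draw values.
#' @export
noise_robustness_fit <- function(increments, fitness, error_vars,
                                 n_draws = 100, seed = 1) {
  if (any(error_vars < 0)) stop("error variances must be nonnegative")
  base <- fit_adaptability_vs_fitness(increments, fitness)
  set.seed(seed)
  n <- length(fitness)
  r <- r2 <- numeric(n_draws)
  sds <- sqrt(error_vars)
  for (b in seq_len(n_draws)) {
    xt <- fitness + stats::rnorm(n, 0, sds)
    r[b] <- stats::cor(increments, xt)
    r2[b] <- r[b]^2
  }
  list(fit = base, mean_r = mean(r), mean_r2 = mean(r2), sd_r2 = stats::sd(r2),
       draws = data.frame(r = r, r2 = r2))
}

#' Pleiotropy model: away-environment gains versus both founder fitnesses
#'
#' Two-predictor ordinary least squares
#' `dX_away = alpha + beta * X_away + gamma * Y_home + eps`, used to ask
#' whether fitness in the home or the away environment predicts the fitness
#' change realized in the away environment.
#'
#' @param away_increments per-founder mean fitness increments measured in the
#'   away environment.
#' @param away_fitness founder fitness in the away environment.
#' @param home_fitness founder fitness in the home environment.
#' @return an `evo_fit`; a collinearity note is attached when the two fitness
#'   predictors correlate above 0.999 in absolute value.
#' @export
fit_pleiotropy_model <- function(away_increments, away_fitness, home_fitness) {
  stopifnot(length(away_increments) == length(away_fitness),
            length(away_fitness) == length(home_fitness))
  note <- NULL
  if (abs(stats::cor(away_fitness, home_fitness)) > 0.999)
    note <- "predictors nearly collinear (|cor| > 0.999)"
  df <- data.frame(d = away_increments, X = away_fitness, Y = home_fitness)
  wrap_fit(stats::lm(d ~ X + Y, data = df), nrow(df), note = note)
}

#' Combined fitness + QTL model of adaptability
#'
#' Fits
#' `dX_i = alpha + beta * X_i + gamma * g* + sum_l a_l g_il + sum_l b_l g* g_il + eps_i`,
#' where `g*` is the +/- 1/2 indicator of the focal-locus allele (BY = +0.5,
#' RM = -0.5), the `g_il` are +/- 1/2 indicators of the other QTLs in the
#' master list, and the last sum holds pairwise interactions between the
#' focal locus and each other QTL.  Every non-intercept term is tested with a
#' Bonferroni-corrected F-test (family = all tested terms) and the model is
#' refitted once including only the significant terms.
#'
#' @param increments per-founder mean fitness increments.
#' @param fitness per-founder fitness.
#' @param qtl_codes founders x QTLs matrix of +/- 1/2 codes for the master
#'   QTL list, excluding the focal locus (named columns recommended).
#' @param focal_code +/- 1/2 indicator of the focal-locus allele per founder.
#' @param alpha significance level for term retention.
#' @return list of class `combined_fit` with the `full` and `refit`
#'   `evo_fit`s, the retained `selected` terms, and the Bonferroni family
#'   size `m`.
#' @export
fit_combined_model <- function(increments, fitness, qtl_codes, focal_code,
                               alpha = 0.05) {
  qtl_codes <- as.matrix(qtl_codes)
  df <- data.frame(d = increments, fitness = fitness, gstar = focal_code)
  if (ncol(qtl_codes) > 0) {
    if (is.null(colnames(qtl_codes)))
      colnames(qtl_codes) <- paste0("Q", seq_len(ncol(qtl_codes)))
    colnames(qtl_codes) <- make.names(colnames(qtl_codes))
    inter <- qtl_codes * focal_code
    colnames(inter) <- paste0("gstar_x_", colnames(qtl_codes))
    df <- cbind(df, as.data.frame(qtl_codes), as.data.frame(inter))
  }
  full_lm <- stats::lm(d ~ ., data = df)
  aliased <- names(which(is.na(stats::coef(full_lm))))
  if (length(aliased)) {
    warning(sprintf("dropping aliased term(s): %s",
                    paste(aliased, collapse = ", ")))
    df <- df[, setdiff(names(df), aliased)]
    full_lm <- stats::lm(d ~ ., data = df)
  }
  full <- wrap_fit(full_lm, nrow(df))
  tested <- setdiff(full$terms, "(Intercept)")
  m <- length(tested)
  p_adj <- pmin(1, full$p * m)
  names(p_adj) <- full$terms
  p_adj["(Intercept)"] <- NA_real_
  full$p_adj <- p_adj
  selected <- tested[p_adj[tested] <= alpha]

  refit <- if (length(selected)) {
    sub <- df[, c("d", selected), drop = FALSE]
    wrap_fit(stats::lm(d ~ ., data = sub), nrow(sub))
  } else {
    wrap_fit(stats::lm(d ~ 1, data = df), nrow(df))
  }
  structure(list(full = full, refit = refit, selected = selected,
                 alpha = alpha, m = m),
            class = "combined_fit")
}

#' @export
print.combined_fit <- function(x, ...) {
  cat(sprintf("Combined fitness + QTL model (Bonferroni family m = %d, alpha %.3g)\n",
              x$m, x$alpha))
  cat("Full model:\n"); print(x$full)
  cat(sprintf("Retained terms: %s\n",
              if (length(x$selected)) paste(x$selected, collapse = ", ")
              else "(intercept only)"))
  cat("Refit:\n"); print(x$refit)
  invisible(x)
}

#' Normalize fitnesses and increments to a common scale
#'
#' Centers each vector by its mean and scales by its sample standard
#' deviation (n - 1 divisor), optionally within strata (e.g. the two
#' focal-locus allele groups), so that quantities measured in environments
#' with different fitness scales can be subtracted.
#'
#' @param X,Y founder fitness in the two environments.
#' @param dX,dY founder mean fitness increments in the two environments.
#' @param strata optional factor of strata; each vector is normalized within
#'   each stratum separately (>= 3 founders per stratum required).
#' @return list with normalized `X`, `Y`, `dX`, `dY`.
#' @export
normalize_traits <- function(X, Y, dX, dY, strata = NULL) {
  zs <- function(v) {
    if (is.null(strata)) {
      s <- stats::sd(v)
      if (s == 0) stop("zero standard deviation; cannot normalize")
      return((v - mean(v)) / s)
    }
    out <- v
    for (g in unique(strata)) {
      k <- strata == g
      if (sum(k) < 3) stop("need >= 3 founders per stratum")
      s <- stats::sd(v[k])
      if (s == 0) stop("zero standard deviation in a stratum")
      out[k] <- (v[k] - mean(v[k])) / s
    }
    out
  }
  list(X = zs(X), Y = zs(Y), dX = zs(dX), dY = zs(dY))
}

#' Correlation between fitness differences and adaptability differences
#'
#' Pearson correlation of `X~ - Y~` (difference in normalized founder
#' fitness between environments) against `dX~ - dY~` (difference in
#' normalized fitness increments), with a bootstrap over founders for a
#' one-sided p-value of a negative correlation and a percentile confidence
#' interval.  A significantly negative correlation indicates that declining
#' adaptability operates independently in each environment rather than
#' through a single shared factor.
#'
#' @param fitness_diff vector `X~ - Y~` per founder.
#' @param increment_diff vector `dX~ - dY~` per founder.
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed.
#' @return object of class `diff_cor` with `r`, `r2`, `p` (one-sided, r < 0),
#'   `ci` on `r`, and the bootstrap draws.
#' @export
difference_correlation <- function(fitness_diff, increment_diff,
                                   n_boot = 10000, seed = 1) {
  n <- length(fitness_diff)
  if (n < 10) stop("need >= 10 founders")
  if (length(increment_diff) != n) stop("length mismatch")
  r <- stats::cor(fitness_diff, increment_diff)
  set.seed(seed)
  rb <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    k <- sample.int(n, replace = TRUE)
    rb[b] <- suppressWarnings(stats::cor(fitness_diff[k], increment_diff[k]))
  }
  rb <- rb[is.finite(rb)]
  p <- (1 + sum(rb >= 0)) / (1 + length(rb))
  structure(list(r = r, r2 = r^2, p = p, ci = pct_ci(rb), n = n,
                 boot = rb), class = "diff_cor")
}

#' @export
print.diff_cor <- function(x, digits = 4, ...) {
  cat(sprintf("Fitness-difference vs adaptability-difference correlation (n = %d)\n",
              x$n))
  cat(sprintf("  r = %.*g (r2 = %.*g), bootstrap p[r < 0] = %.3g, 95%% CI (%.*g, %.*g)\n",
              digits, x$r, digits, x$r2, x$p, digits, x$ci[1],
              digits, x$ci[2]))
  invisible(x)
}

#' Mean fitness increments by focal allele, evolution and assay environment
#'
#' Means over populations per (focal allele x home environment x measured
#' environment) cell with percentile bootstrap confidence intervals over
#' populations, in the layout of the home/away increment summary table.
#'
#' @param populations data frame with columns `focal_allele`, `home_env`,
#'   and one increment column per measured environment named `d_<env>`.
#' @param environments the measured environments (defaults to those present).
#' @param n_boot bootstrap resamples per cell.
#' @param seed RNG seed.
#' @param scale multiply increments by this factor (100 reports percent).
#' @return data frame with `focal_allele`, `evolved_in`, `measured_in`,
#'   `mean`, `lo`, `hi`, `n`; empty cells are flagged with `NA` means.
#' @export
group_mean_increments <- function(populations, environments = NULL,
                                  n_boot = 1000, seed = 1, scale = 1) {
  envs <- environments %||%
    sub("^d_", "", grep("^d_", names(populations), value = TRUE))
  set.seed(seed)
  out <- list()
  for (al in sort(unique(populations$focal_allele)))
    for (he in sort(unique(populations$home_env)))
      for (me in envs) {
        rows <- populations$focal_allele == al & populations$home_env == he
        v <- populations[[paste0("d_", me)]][rows] * scale
        if (!length(v)) {
          out[[length(out) + 1]] <- data.frame(
            focal_allele = al, evolved_in = he, measured_in = me,
            mean = NA_real_, lo = NA_real_, hi = NA_real_, n = 0L)
          next
        }
        mb <- numeric(n_boot)
        for (b in seq_len(n_boot))
          mb[b] <- mean(v[sample.int(length(v), replace = TRUE)])
        ci <- pct_ci(mb)
        out[[length(out) + 1]] <- data.frame(
          focal_allele = al, evolved_in = he, measured_in = me,
          mean = mean(v), lo = ci[1], hi = ci[2], n = length(v))
      }
  res <- do.call(rbind, out)
  if (any(res$n == 0)) warning("empty cell(s) in the group-mean table")
  res
}
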