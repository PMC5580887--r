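#' Narrow-sense heritability by REML on a kinship matrix
#'
#' Fits the variance-component model `V = R * sigma_a^2 + I * sigma_e^2`
#' with an intercept-only fixed effect by restricted maximum likelihood,
#' using a single eigendecomposition of the kinship matrix and a bounded
#' one-dimensional search over the heritability ratio
#' `lambda = sigma_a^2 / (sigma_a^2 + sigma_e^2)` (tolerance 1e-6).
#' The narrow-sense heritability is reported as the fitted additive variance
#' divided by the sample variance of the trait.
#'
#' @param trait numeric vector of per-founder trait values (fitness or mean
#'   fitness increment), in kinship row order.
#' @param kinship matrix from [kinship_matrix()], founders in the same order.
#' @param n_jackknife if positive, number of delete-half jackknife resamples
#'   for a 95% confidence interval on `h2` (the kinship is subset; locus
#'   allele frequencies stay fixed from the full panel).
#' @param seed seed for the jackknife resampling.
#' @param tol convergence tolerance of the 1-D search.
#' @return object of class `reml_fit` with elements `h2`, `sigma_a2`,
#'   `sigma_e2`, `lambda`, `loglik`, `boundary` (logical flag for estimates
#'   at the admissible boundary), `ci`, and `profile` (the profiled
#'   restricted log-likelihood as a function of `lambda`, for diagnostics).
#' @export
narrow_sense_reml <- function(trait, kinship, n_jackknife = 0, seed = 1,
                              tol = 1e-6) {
  n <- length(trait)
  if (n < 20) stop("need >= 20 founders for REML")
  if (nrow(kinship) != n || ncol(kinship) != n)
    stop("kinship and trait must share founder order and length")
  fit <- reml_core(trait, kinship, tol)
  ci <- NULL
  if (n_jackknife > 0) {
    ids <- seq_len(n)
    stat <- function(sub) {
      sub <- sort(sub)
      reml_core(trait[sub], kinship[sub, sub, drop = FALSE], tol)$h2
    }
    jk <- delete_half_jackknife(stat, ids, n_resamples = n_jackknife,
                                seed = seed)
    ci <- jk$ci
  }
  fit$ci <- ci
  class(fit) <- "reml_fit"
  fit
}

## eigendecomposition-based profiled REML over lambda in (0, 1)
reml_core <- function(y, R, tol = 1e-6) {
  n <- length(y)
  ev <- eigen(R, symmetric = TRUE)
  d <- pmax(ev$values, 0)
  U <- ev$vectors
  ys <- as.vector(crossprod(U, y))
  xs <- as.vector(crossprod(U, rep(1, n)))
  q <- 1L

  ## restricted log-likelihood profiled over sigma_a^2, at
  ## delta = sigma_e^2 / sigma_a^2 = (1 - lambda) / lambda
  rll <- function(lambda) {
    delta <- (1 - lambda) / lambda
    w <- 1 / (d + delta)
    xwx <- sum(xs^2 * w)
    beta <- sum(xs * w * ys) / xwx
    r <- ys - xs * beta
    rss <- sum(r^2 * w)
    s_a2 <- rss / (n - q)
    -0.5 * ((n - q) * log(s_a2) + sum(log(d + delta)) + log(xwx) + (n - q))
  }
  lo <- 1e-6; hi <- 1 - 1e-6
  opt <- stats::optimize(rll, interval = c(lo, hi), maximum = TRUE, tol = tol)
  if (!is.finite(opt$objective))
    stop("REML optimization failed to converge; non-finite likelihood")
  lambda <- opt$maximum
  ## recover the variance components at the optimum
  delta <- (1 - lambda) / lambda
  w <- 1 / (d + delta)
  xwx <- sum(xs^2 * w)
  beta <- sum(xs * w * ys) / xwx
  rss <- sum((ys - xs * beta)^2 * w)
  s_a2 <- rss / (n - q)
  s_e2 <- delta * s_a2
  boundary <- lambda < lo * 10 || lambda > 1 - 10 * (1 - hi)
  list(h2 = s_a2 / stats::var(y), sigma_a2 = s_a2, sigma_e2 = s_e2,
       lambda = lambda, beta = beta, loglik = opt$objective,
       boundary = boundary, n = n, profile = rll)
}

#' @export
print.reml_fit <- function(x, digits = 4, ...) {
  cat(sprintf("REML narrow-sense heritability (n = %d)\n", x$n))
  cat(sprintf("  h2 = %.*g  (sigma_a2 = %.*g, sigma_e2 = %.*g)\n",
              digits, x$h2, digits, x$sigma_a2, digits, x$sigma_e2))
  if (x$boundary) cat("  note: estimate at the admissible boundary\n")
  if (!is.null(x$ci))
    cat(sprintf("  95%% jackknife CI: (%.*g, %.*g)\n",
                digits, x$ci[1], digits, x$ci[2]))
  invisible(x)
}

#' @export
coef.reml_fit <- function(object, ...) {
  c(h2 = object$h2, sigma_a2 = object$sigma_a2, sigma_e2 = object$sigma_e2)
}
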