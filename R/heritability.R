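## Broad-sense variance partitioning and jackknife confidence intervals.
##
## Divisors follow the population-style convention (1/n) of the estimating
## equations, not the sample-variance convention; the negative-component
## policy is to report the raw difference and additionally a [0,1]-clipped
## heritability.

new_varcomp <- function(sigma_t2, sigma_noise2, n, type, extra = list()) {
  sigma_f2 <- sigma_t2 - sigma_noise2
  H2 <- if (sigma_t2 > 0) sigma_f2 / sigma_t2 else NA_real_
  structure(c(list(sigma_t2 = sigma_t2, sigma_noise2 = sigma_noise2,
                   sigma_f2 = sigma_f2, H2 = H2,
                   H2_clipped = if (is.finite(H2)) min(1, max(0, H2)) else 0,
                   flagged = !is.finite(H2),
                   n = n, type = type, ci = NULL), extra),
            class = "varcomp")
}

#' Broad-sense heritability of founder fitness
#'
#' Partitions the variance of founder mean fitnesses into a measurement-error
#' component and a founder-genotype component:
#' `sigma_t2 = mean((X_i - mean(X))^2)`, `sigma_noise2 = mean(error_vars)`,
#' `sigma_f2 = sigma_t2 - sigma_noise2`, and `H2 = sigma_f2 / sigma_t2`.
#' `error_vars` are the per-founder error variances of the mean from
#' [summarize_replicates()].
#'
#' @param founder_means numeric vector of per-founder mean fitnesses.
#' @param founder_error_vars matching vector of error variances of the means.
#' @return a `varcomp` object.  If the total variance is zero, `H2` is `NA`
#'   and the result is flagged.
#' @export
broad_sense_fitness <- function(founder_means, founder_error_vars) {
  stopifnot(length(founder_means) == length(founder_error_vars))
  if (length(founder_means) < 2) stop("need >= 2 founders")
  if (any(founder_error_vars < 0)) stop("error variances must be nonnegative")
  n <- length(founder_means)
  s_t2 <- mean((founder_means - mean(founder_means))^2)
  s_e2 <- mean(founder_error_vars)
  new_varcomp(s_t2, s_e2, n, "fitness")
}

#' Broad-sense heritability of the fitness increment
#'
#' Partitions the total variance of per-population fitness increments into a
#' within-founder component (measurement error plus evolutionary
#' stochasticity) and a between-founder component:
#' \deqn{\sigma^2_p = \frac{1}{n}\sum_i \frac{n_{p,i}}{n_{p,i}-1}
#'       \sum_j (\Delta X_{ij} - \overline{\Delta X}_{i\cdot})^2, \qquad
#'       \sigma^2_t = \frac{1}{n}\sum_{ij}
#'       (\Delta X_{ij} - \overline{\Delta X}_{\cdot\cdot})^2,}
#' with `n` the total number of populations, and
#' `H2 = (sigma_t2 - sigma_p2) / sigma_t2`.  Founders contributing a single
#' population are excluded with a warning (their within-founder variance is
#' inestimable).
#'
#' @param increments numeric vector of per-population fitness increments.
#' @param founder factor or character vector grouping populations by founder.
#' @return a `varcomp` object.
#' @export
broad_sense_increment <- function(increments, founder) {
  stopifnot(length(increments) == length(founder))
  founder <- as.character(founder)
  cnt <- table(founder)
  single <- names(cnt)[cnt < 2]
  if (length(single) == length(cnt))
    stop("all founders contribute a single population; variance inestimable")
  if (length(single)) {
    warning(sprintf("excluding %d founder(s) with a single population",
                    length(single)))
    keep <- !(founder %in% single)
    increments <- increments[keep]; founder <- founder[keep]
  }
  n <- length(increments)
  grand <- mean(increments)
  s_t2 <- mean((increments - grand)^2)
  gm <- tapply(increments, founder, mean)
  gn <- tapply(increments, founder, length)
  ss <- tapply(seq_along(increments), founder, function(k)
    sum((increments[k] - mean(increments[k]))^2))
  s_p2 <- sum(gn / (gn - 1) * ss) / n
  new_varcomp(s_t2, s_p2, n, "increment",
              extra = list(n_founders = length(gn)))
}

#' @export
print.varcomp <- function(x, digits = 4, ...) {
  cat(sprintf("Broad-sense variance partition (%s; n = %d)\n", x$type, x$n))
  cat(sprintf("  total %.*g | noise %.*g | founder %.*g\n",
              digits, x$sigma_t2, digits, x$sigma_noise2, digits, x$sigma_f2))
  if (x$flagged) cat("  H2 undefined (zero total variance)\n")
  else cat(sprintf("  H2 = %.*g (clipped %.*g)\n", digits, x$H2,
                   digits, x$H2_clipped))
  if (!is.null(x$ci))
    cat(sprintf("  95%% jackknife CI: (%.*g, %.*g)\n",
                digits, x$ci[1], digits, x$ci[2]))
  invisible(x)
}

#' Delete-half jackknife confidence interval over founders
#'
#' Recomputes a statistic on random founder subsets of size `ceiling(n/2)`
#' and forms a percentile interval from the resample distribution
#' (leave-n/2-out jackknife on genotypes).  Subsets on which the statistic
#' fails are dropped and counted; more than 20% failures is an error.
#'
#' @param statistic function taking a vector of founder ids and returning a
#'   scalar.
#' @param founder_ids vector of founder ids (>= 4).
#' @param n_resamples number of random half-subsets.
#' @param seed RNG seed; resampling is deterministic given the seed.
#' @param level confidence level.
#' @return list with `ci` (lower, upper), `values` (resample statistics) and
#'   `n_failed`.
#' @export
delete_half_jackknife <- function(statistic, founder_ids, n_resamples = 1000,
                                  seed = 1, level = 0.95) {
  n <- length(founder_ids)
  if (n < 4) stop("need >= 4 founders for the delete-half jackknife")
  set.seed(seed)
  half <- ceiling(n / 2)
  vals <- rep(NA_real_, n_resamples)
  for (b in seq_len(n_resamples)) {
    sub <- sample(founder_ids, half)
    vals[b] <- tryCatch(statistic(sub), error = function(e) NA_real_)
  }
  n_failed <- sum(is.na(vals))
  if (n_failed > 0.2 * n_resamples)
    stop(sprintf("statistic failed on %d/%d jackknife subsets",
                 n_failed, n_resamples))
  list(ci = pct_ci(vals, level), values = vals, n_failed = n_failed)
}

#' Standardized kinship (relatedness) matrix of a founder panel
#'
#' Encodes each biallelic locus as
#' \eqn{g_{ik} = -p_k/\sqrt{m\,p_k(1-p_k)}} for the RM allele and
#' \eqn{(1-p_k)/\sqrt{m\,p_k(1-p_k)}} for the BY allele, where `p_k` is the
#' BY-allele frequency in the supplied panel and `m` the number of loci; the
#' relatedness between founders is \eqn{R_{ij} = \sum_k g_{ik} g_{jk}}.
#'
#' @param geno a `genotype_matrix` or character allele matrix.
#' @return symmetric kinship matrix (class `kinship`) with founder dimnames
#'   and unit-scale diagonal.
#' @export
kinship_matrix <- function(geno) {
  m <- genotype_alleles(geno)
  p <- colMeans(m == "BY")
  mono <- which(p <= 0 | p >= 1)
  if (length(mono))
    stop(sprintf("monomorphic locus present: %s",
                 paste(colnames(m)[utils::head(mono, 5)] %||%
                         utils::head(mono, 5), collapse = ", ")))
  nloc <- ncol(m)
  g <- (m == "BY") - matrix(p, nrow(m), nloc, byrow = TRUE)
  g <- g / matrix(sqrt(nloc * p * (1 - p)), nrow(m), nloc, byrow = TRUE)
  R <- tcrossprod(g)
  dimnames(R) <- list(rownames(m), rownames(m))
  class(R) <- c("kinship", class(R))
  R
}
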