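#' Weighted Pearson correlation
#'
#' Pearson correlation computed from weight-normalized means, variances and
#' covariance.  In the QTL scan, observations are weighted by the square root
#' of the number of technical replicate measurements.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @param w positive weights.
#' @return correlation in `[-1, 1]`; `NA` (with a warning) if either variable
#'   has zero weighted variance.
#' @export
weighted_pearson <- function(x, y, w = rep(1, length(x))) {
  n <- length(x)
  if (length(y) != n || length(w) != n) stop("x, y, w must have equal length")
  if (n < 3) stop("need >= 3 observations")
  if (any(w <= 0)) stop("weights must be positive")
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * x^2) - mx^2
  vy <- sum(w * y^2) - my^2
  if (vx <= 0 || vy <= 0) {
    warning("zero weighted variance; correlation undefined")
    return(NA_real_)
  }
  cxy <- sum(w * x * y) - mx * my
  max(-1, min(1, cxy / sqrt(vx * vy)))
}

#' LOD score from a squared locus-trait correlation
#'
#' `LOD = -(n_g / 2) * log10(1 - r^2)`, increasing in both arguments.
#'
#' @param r2 squared correlation in `[0, 1)`.
#' @param n_g number of founders (>= 2).
#' @return nonnegative LOD score; `Inf` (with a warning) at `r2 = 1`.
#' @export
lod_score <- function(r2, n_g) {
  if (any(r2 < 0 | r2 > 1)) stop("r2 must be in [0, 1]")
  if (n_g < 2) stop("n_g must be >= 2")
  if (any(r2 == 1)) warning("r2 = 1: infinite LOD score")
  -(n_g / 2) * log10(1 - r2)
}

## Weighted correlations of each column of a code matrix with each column of
## a response matrix; w is normalized to sum 1.  Returns |loci| x |responses|.
wcor_matrix <- function(G, Y, w) {
  w <- w / sum(w)
  Y <- as.matrix(Y)
  mg <- as.vector(crossprod(G, w))          # weighted locus means
  vg <- as.vector(crossprod(G^2, w)) - mg^2
  WY <- Y * w
  s1 <- colSums(WY)                          # weighted response means
  vy <- colSums(Y^2 * w) - s1^2
  num <- crossprod(G, WY) - outer(mg, s1)
  den <- outer(sqrt(pmax(vg, 0)), sqrt(pmax(vy, 0)))
  r <- num / den
  r[!is.finite(r)] <- 0
  r[r > 1] <- 1
  r[r < -1] <- -1
  r
}

#' Iterative forward QTL scan with permutation significance
#'
#' At each iteration the trait is residualized by an ordinary least-squares
#' fit on the already-detected QTLs (alleles coded +/- 1/2), every locus is
#' scored by the LOD of its weighted Pearson correlation with the residuals,
#' and the top locus is tested against the genome-wide permutation null of
#' the maximum LOD (residual values are permuted; weights stay attached to
#' genotypes).  Scanning stops when the top locus is no longer significant at
#' `alpha` or `max_qtls` is reached.  Each hit carries a positional
#' confidence interval: the maximal contiguous run of loci on the peak's
#' chromosome whose LOD is within 1.5 of the peak.
#'
#' @param geno `genotype_matrix` (or character allele matrix) over founders.
#' @param trait per-founder trait values.
#' @param weights observation weights; defaults to all ones.  For replicated
#'   measurements use the square root of the replicate count.
#' @param alpha genome-wide significance level per iteration.
#' @param n_perm number of permutations (>= 100); the permutation p-value
#'   uses the add-one correction `(1 + #exceedances) / (1 + n_perm)`.
#' @param seed RNG seed (scan is deterministic given seed and data).
#' @param max_qtls safety cap on the number of detected QTLs.
#' @return object of class `qtl_scan`; `$hits` is a data frame with one row
#'   per detected QTL (`locus`, `chrom`, `peak_pos`, `lod`, `p`, `ci_lo`,
#'   `ci_hi` as 1-based inclusive locus indices, `ci_start`, `ci_end` as
#'   genomic positions, `effect` from the joint OLS fit).
#' @export
forward_scan <- function(geno, trait, weights = NULL, alpha = 0.05,
                         n_perm = 1000, seed = 1, max_qtls = 20) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  set.seed(seed)
  code <- allele_code(geno)
  loci <- genotype_loci(geno)
  n <- nrow(code)
  if (length(trait) != n) stop("trait and genotypes are not aligned")
  keep <- !monomorphic_loci(geno)
  if (!any(keep)) stop("no polymorphic loci to scan")
  w <- weights %||% rep(1, n)
  G <- code[, keep, drop = FALSE]
  loc_idx <- which(keep)

  hits <- list()
  y <- trait
  repeat {
    r <- wcor_matrix(G, y, w)[, 1]
    lod <- lod_score(pmin(r^2, 1 - 1e-12), n)
    peak <- which.max(lod)                      # ties -> lowest index
    obs <- lod[peak]
    ## genome-wide null of the max LOD: permute residual values
    P <- matrix(0, n, n_perm)
    for (b in seq_len(n_perm)) P[, b] <- y[sample.int(n)]
    rp <- wcor_matrix(G, P, w)
    maxlod <- apply(lod_score(pmin(rp^2, 1 - 1e-12), n), 2, max)
    p <- (1 + sum(maxlod >= obs)) / (1 + n_perm)
    if (p > alpha || length(hits) >= max_qtls) break

    gidx <- loc_idx[peak]
    chrom <- loci$chrom[gidx]
    on_chr <- which(loci$chrom[loc_idx] == chrom)
    ok <- lod[on_chr] >= obs - 1.5
    ## maximal contiguous run (in locus order) containing the peak
    pk <- match(peak, on_chr)
    lo <- pk; while (lo > 1 && ok[lo - 1]) lo <- lo - 1
    hi <- pk; while (hi < length(ok) && ok[hi + 1]) hi <- hi + 1
    hits[[length(hits) + 1]] <- data.frame(
      locus = gidx, chrom = chrom, peak_pos = loci$pos[gidx],
      lod = obs, p = p, r2 = r[peak]^2,
      ci_lo = loc_idx[on_chr[lo]], ci_hi = loc_idx[on_chr[hi]],
      ci_start = loci$pos[loc_idx[on_chr[lo]]],
      ci_end = loci$pos[loc_idx[on_chr[hi]]],
      effect = NA_real_
    )
    ## residualize on all detected QTLs (ordinary least squares)
    X <- cbind(1, code[, vapply(hits, `[[`, 0L, "locus"), drop = FALSE])
    fit <- stats::lm.fit(X, trait)
    y <- fit$residuals
    if (length(hits) >= max_qtls) break
  }

  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(locus = integer(0), chrom = character(0),
               peak_pos = integer(0), lod = numeric(0), p = numeric(0),
               r2 = numeric(0), ci_lo = integer(0), ci_hi = integer(0),
               ci_start = integer(0), ci_end = integer(0),
               effect = numeric(0))
  if (nrow(hits)) {
    X <- cbind(1, code[, hits$locus, drop = FALSE])
    hits$effect <- stats::lm.fit(X, trait)$coefficients[-1]
  }
  rownames(hits) <- NULL
  structure(list(hits = hits, n_founders = n, n_loci = sum(keep),
                 alpha = alpha, n_perm = n_perm, seed = seed),
            class = "qtl_scan")
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat(sprintf("Forward QTL scan: %d founders, %d loci, alpha %.3g, %d permutations\n",
              x$n_founders, x$n_loci, x$alpha, x$n_perm))
  if (!nrow(x$hits)) cat("  no significant QTLs\n")
  else print(x$hits[c("chrom", "peak_pos", "lod", "p", "ci_start",
                      "ci_end", "effect")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.qtl_scan <- function(object, ...) object$hits

#' Variance explained by a set of QTLs
#'
#' Coefficient of determination of the weighted least-squares fit of the
#' trait on the +/- 1/2 allele codes of the given loci.  Collinear
#' predictors are dropped with a warning.
#'
#' @inheritParams forward_scan
#' @param qtl_loci locus indices (nonempty).
#' @return r-squared of the fit.
#' @export
additive_model_r2 <- function(geno, qtl_loci, trait, weights = NULL) {
  if (!length(qtl_loci)) stop("QTL set must be nonempty")
  code <- allele_code(geno)[, qtl_loci, drop = FALSE]
  colnames(code) <- paste0("q", seq_len(ncol(code)))
  df <- data.frame(trait = trait, code)
  w <- weights %||% rep(1, length(trait))
  fit <- stats::lm(trait ~ ., data = df, weights = w)
  if (any(is.na(stats::coef(fit))))
    warning("collinear QTL predictors dropped")
  summary(fit)$r.squared
}

#' Export QTL confidence intervals as BED intervals
#'
#' Converts the 1-based inclusive genomic confidence intervals of a scan to
#' 0-based half-open BED records.
#'
#' @param scan a `qtl_scan`.
#' @param file optional path to write a BED file to.
#' @return data frame with `chrom`, `start` (0-based), `end`, `name`,
#'   `score` (LOD), invisibly when writing.
#' @export
qtl_ci_bed <- function(scan, file = NULL) {
  h <- scan$hits
  bed <- data.frame(chrom = h$chrom, start = h$ci_start - 1L, end = h$ci_end,
                    name = paste0("QTL_", seq_len(nrow(h))), score = h$lod)
  if (!is.null(file)) {
    utils::write.table(bed, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(bed))
  }
  bed
}
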