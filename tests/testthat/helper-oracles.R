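## Independent brute-force oracles used to validate the package's
## estimators.  These deliberately use naive loops and definitional formulas
## (entropy differences, explicit weighted moments, normal equations) rather
## than any code path under test.

oracle_broad_fitness <- function(means, evars) {
  n <- length(means)
  st <- 0
  for (i in seq_len(n)) st <- st + (means[i] - mean(means))^2
  st <- st / n
  se <- sum(evars) / n
  list(sigma_t2 = st, sigma_noise2 = se, H2 = (st - se) / st)
}

oracle_broad_increment <- function(dx, founder) {
  founder <- as.character(founder)
  ids <- unique(founder)
  n <- length(dx)
  grand <- mean(dx)
  st <- sum((dx - grand)^2) / n
  sp <- 0
  for (f in ids) {
    v <- dx[founder == f]
    np <- length(v)
    sp <- sp + np / (np - 1) * sum((v - mean(v))^2)
  }
  sp <- sp / n
  list(sigma_t2 = st, sigma_p2 = sp, H2 = (st - sp) / st)
}

oracle_wpearson <- function(x, y, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  cxy <- sum(w * (x - mx) * (y - my)) / sw
  vx <- sum(w * (x - mx)^2) / sw
  vy <- sum(w * (y - my)^2) / sw
  cxy / sqrt(vx * vy)
}

## entropy-difference formulation of (conditional) mutual information,
## independent of the frequency-ratio formulation in the package
oracle_mi <- function(W, m, Z = NULL) {
  H <- function(v) {
    p <- table(v) / length(v)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  if (is.null(Z)) Z <- rep(1, length(W))
  z_lev <- unique(Z)
  I <- 0
  for (z in z_lev) {
    kz <- which(Z == z)
    pz <- length(kz) / length(W)
    h_mz <- H(m[kz])
    h_mwz <- 0
    for (w in unique(W[kz])) {
      kw <- kz[W[kz] == w]
      h_mwz <- h_mwz + length(kw) / length(kz) * H(m[kw])
    }
    I <- I + pz * (h_mz - h_mwz)
  }
  I
}

## least squares via the normal equations
oracle_ols <- function(X, y) {
  beta <- solve(crossprod(X), crossprod(X, y))
  res <- y - X %*% beta
  sst <- sum((y - mean(y))^2)
  list(beta = as.vector(beta), r2 = 1 - sum(res^2) / sst)
}

## small, fast cross configuration for end-to-end tests
tiny_config <- function(seed = 1, n_founders = 40L, ...) {
  lens <- rep(10L, 4)
  cross_config(
    n_founders = n_founders,
    chromosome_lengths = lens,
    qtl_spec = data.frame(locus = c(5L, 15L, 25L),
                          effect_OT = c(0.08, 0.05, 0.04),
                          effect_HT = c(0.16, 0.06, 0.05)),
    epistasis_spec = data.frame(locus1 = integer(0), locus2 = integer(0),
                                effect_OT = numeric(0),
                                effect_HT = numeric(0)),
    focal_locus = 5L,
    n_seq_founders = 10L,
    seed = seed, ...)
}

## paper-scale configuration with a reduced marker panel (the generative
## variance components do not depend on the number of neutral markers)
recovery_config <- function(seed = 1, ...) {
  lens <- rep(12L, 16)
  cross_config(
    chromosome_lengths = lens,
    qtl_spec = data.frame(
      locus = c(evoherit:::locus_index(lens, 14, 6),
                evoherit:::locus_index(lens, 1, 6),
                evoherit:::locus_index(lens, 3, 6),
                evoherit:::locus_index(lens, 5, 6),
                evoherit:::locus_index(lens, 8, 6)),
      effect_OT = c(0.09, 0.05, 0.04, 0.03, 0.03),
      effect_HT = c(0.19, 0.06, 0.05, 0.04, 0.03)),
    epistasis_spec = data.frame(
      locus1 = evoherit:::locus_index(lens, 14, 6),
      locus2 = evoherit:::locus_index(lens, 3, 6),
      effect_OT = 0.02, effect_HT = 0.03),
    focal_locus = evoherit:::locus_index(lens, 14, 6),
    seed = seed, ...)
}

## random character allele matrix wrapped as a genotype_matrix
random_geno <- function(n, m, seed = 1, p = 0.5) {
  set.seed(seed)
  alle <- matrix(ifelse(stats::runif(n * m) < p, "BY", "RM"), n, m)
  rownames(alle) <- sprintf("F%03d", seq_len(n))
  colnames(alle) <- sprintf("chr01:%d", seq_len(m) * 1000L)
  structure(list(alleles = alle,
                 loci = data.frame(chrom = rep("chr01", m),
                                   pos = seq_len(m) * 1000L),
                 founders = rownames(alle)),
            class = "genotype_matrix")
}
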