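## internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic per-stage seed derived from the dataset seed, so that
## individual simulation stages are reproducible when called on their own.
## Must stay below 2^31 - 1 (R integers are 32-bit).
stage_seed <- function(seed, stage) {
  stages <- c(genotypes = 1L, fitness = 2L, evolution = 3L,
              measurement = 4L, sites = 5L)
  k <- stages[[stage]]
  s <- (as.double(seed) %% 1048573) + 1
  as.integer((s * 2654435 + k * 40503) %% 2147483629)
}

## Convert a genotype representation to the +/- 1/2 additive code
## (BY -> +0.5, RM -> -0.5), as a founders x loci numeric matrix.
allele_code <- function(geno) {
  m <- genotype_alleles(geno)
  code <- matrix(-0.5, nrow(m), ncol(m), dimnames = dimnames(m))
  code[m == "BY"] <- 0.5
  code
}

## Extract the founders x loci character allele matrix from a
## genotype_matrix object or a plain matrix.
genotype_alleles <- function(geno) {
  if (inherits(geno, "genotype_matrix")) return(geno$alleles)
  if (is.matrix(geno) && is.character(geno)) return(geno)
  stop("expected a genotype_matrix or a character allele matrix")
}

genotype_loci <- function(geno) {
  if (inherits(geno, "genotype_matrix")) return(geno$loci)
  data.frame(chrom = rep("chr01", ncol(geno)), pos = seq_len(ncol(geno)))
}

check_prob <- function(x, name, upper = 1) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > upper))
    stop(sprintf("'%s' must be a probability in [0, %g]", name, upper),
         call. = FALSE)
  invisible(x)
}

check_sd <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0))
    stop(sprintf("'%s' must be a nonnegative standard deviation", name),
         call. = FALSE)
  invisible(x)
}

## quantile-based 95% interval used by the resampling routines
pct_ci <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  stats::quantile(x, c(a, 1 - a), names = FALSE, na.rm = TRUE)
}
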