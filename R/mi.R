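#' Mutual information between a population label and mutation incidence
#'
#' Computes, in bits,
#' \deqn{I(W, g) = \sum_W p(W) \sum_{m \in \{0,1\}} p(m\mid W)
#'       \log_2 \frac{p(m\mid W)}{p(m)},}
#' with probabilities estimated as observed frequencies and the convention
#' `0 log 0 = 0`; when a conditioning label `Z` is supplied the conditional
#' form averages the within-stratum information over strata of `Z` weighted
#' by `p(Z)` (empty strata carry weight zero).
#'
#' @param W categorical label per population (factor or vector).
#' @param m binary incidence per population (1 = at least one called
#'   putatively functional mutation in the gene).
#' @param Z optional conditioning label(s); a vector or a data frame /
#'   list of vectors combined into joint strata.
#' @return mutual information in bits (nonnegative).
#' @export
mutual_information <- function(W, m, Z = NULL) {
  drop(mi_columns(as.matrix(as.numeric(m)), W, Z))
}

## vectorized per-gene mutual information over the columns of a binary
## incidence matrix; returns a named vector of bits
mi_columns <- function(mat, W, Z = NULL) {
  n <- nrow(mat)
  W <- as.factor(W)
  if (length(W) != n) stop("label length does not match populations")
  z <- if (is.null(Z)) factor(rep("all", n)) else
    interaction(as.data.frame(Z), drop = TRUE)
  plogq <- function(p, q) ifelse(p > 0, p * log2(p / q), 0)
  I <- numeric(ncol(mat))
  for (zl in levels(z)) {
    kz <- which(z == zl)
    pz <- length(kz) / n
    if (pz == 0) next
    fz <- colMeans(mat[kz, , drop = FALSE])     # p(m = 1 | z)
    for (wl in levels(W)) {
      kw <- kz[W[kz] == wl]
      pw <- length(kw) / length(kz)             # p(w | z)
      if (pw == 0) next
      f <- colMeans(mat[kw, , drop = FALSE])    # p(m = 1 | w, z)
      I <- I + pz * pw * (plogq(f, fz) + plogq(1 - f, 1 - fz))
    }
  }
  I[!is.finite(I)] <- 0
  names(I) <- colnames(mat)
  pmax(I, 0)
}

#' Populations x genes mutation incidence matrix
#'
#' Builds the binary incidence container used by the mutual-information
#' test from a table of mutation events, retaining the event list so the
#' count-preserving permutation null can reshuffle gene labels among events.
#' Events in genes outside the chosen universe still count toward the
#' per-population event totals (and participate in permutations).
#'
#' @param events data frame with columns `population_id` and `gene`, one row
#'   per called putatively functional mutation event.
#' @param populations character vector of all population ids (including
#'   populations without any event).
#' @param genes gene universe for the incidence columns; defaults to the
#'   multi-hit genes (genes with events in two or more distinct
#'   populations).
#' @return object of class `mutation_matrix`: `incidence` (binary matrix),
#'   `events`, `counts` (events per population), `genes`.
#' @export
mutation_matrix <- function(events, populations, genes = NULL) {
  stopifnot(all(c("population_id", "gene") %in% names(events)))
  events <- events[!is.na(events$gene), , drop = FALSE]
  if (any(!events$population_id %in% populations))
    stop("event in a population not listed in 'populations'")
  if (is.null(genes)) {
    gp <- tapply(events$population_id, events$gene,
                 function(p) length(unique(p)))
    genes <- sort(names(gp)[gp >= 2])
  }
  inc <- matrix(0L, length(populations), length(genes),
                dimnames = list(populations, genes))
  keep <- events$gene %in% genes
  if (any(keep))
    inc[cbind(match(events$population_id[keep], populations),
              match(events$gene[keep], genes))] <- 1L
  counts <- table(factor(events$population_id, levels = populations))
  structure(list(incidence = inc,
                 events = events[c("population_id", "gene")],
                 counts = as.vector(counts), genes = genes,
                 populations = populations),
            class = "mutation_matrix")
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat(sprintf("Mutation incidence: %d populations x %d genes (%d events)\n",
              nrow(x$incidence), ncol(x$incidence), nrow(x$events)))
  invisible(x)
}

#' Summed mutual-information statistic over genes
#'
#' `M(W | Z) = sum over genes of I(W, g | Z)`, the test statistic of the
#' mutation-spectrum association analysis.
#'
#' @param W label per population (aligned with the matrix rows).
#' @param matrix a `mutation_matrix` (or a plain binary matrix).
#' @param Z optional conditioning label(s).
#' @return scalar `M` in bits, with the per-gene contributions as attribute
#'   `"per_gene"`.
#' @export
mi_statistic <- function(W, matrix, Z = NULL) {
  inc <- if (inherits(matrix, "mutation_matrix")) matrix$incidence else matrix
  per <- mi_columns(inc, W, Z)
  structure(sum(per), per_gene = per)
}

#' Permutation null for the mutual-information statistic
#'
#' Tests `M(W | Z)` against a null in which mutation events carry no
#' information about the labels: the pooled multiset of gene labels across
#' all events is permuted, each population is reassigned its original
#' number of events, incidence is re-binarized, and `M` recomputed.  This
#' holds both the per-population event counts and the overall gene spectrum
#' fixed.  The statistic is reported centered on the null mean,
#' `M - mean(M_perm)`, with a null 95% interval and the add-one permutation
#' p-value.
#'
#' @inheritParams mi_statistic
#' @param n_perm number of permutations (>= 200).
#' @param seed RNG seed (deterministic given seed).
#' @return object of class `mi_test`: `statistic` (M), `null_mean`,
#'   `centered`, `null_ci`, `p`, `per_gene`, `n_perm`.
#' @export
permutation_null <- function(W, matrix, Z = NULL, n_perm = 10000, seed = 1) {
  stopifnot(inherits(matrix, "mutation_matrix"))
  if (n_perm < 200) stop("n_perm must be >= 200")
  if (nrow(matrix$events) == 0) stop("no mutation events to permute")
  set.seed(seed)
  obs <- mi_statistic(W, matrix, Z)
  inc0 <- matrix$incidence
  pops <- matrix$populations
  genes <- matrix$genes
  ev_pop <- match(matrix$events$population_id, pops)
  ev_gene <- matrix$events$gene
  null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    g <- ev_gene[sample.int(length(ev_gene))]
    keep <- g %in% genes
    inc <- inc0; inc[] <- 0L
    if (any(keep))
      inc[cbind(ev_pop[keep], match(g[keep], genes))] <- 1L
    null[b] <- sum(mi_columns(inc, W, Z))
  }
  p <- (1 + sum(null >= as.numeric(obs))) / (1 + n_perm)
  structure(list(statistic = as.numeric(obs), null_mean = mean(null),
                 centered = as.numeric(obs) - mean(null),
                 null_ci = pct_ci(null), p = p,
                 per_gene = attr(obs, "per_gene"),
                 null = null, n_perm = n_perm),
            class = "mi_test")
}

#' @export
print.mi_test <- function(x, digits = 4, ...) {
  cat("Mutual-information permutation test\n")
  cat(sprintf("  M = %.*g bits; null mean %.*g; centered %.*g\n",
              digits, x$statistic, digits, x$null_mean, digits, x$centered))
  cat(sprintf("  null 95%% interval (%.*g, %.*g); p = %.4g (%d permutations)\n",
              digits, x$null_ci[1], digits, x$null_ci[2], x$p, x$n_perm))
  invisible(x)
}

#' Hierarchical mutation-spectrum association analysis
#'
#' Runs the permutation test for the standard label hierarchy: the focal
#' (KRE33-type) allele, then the evolution environment conditional on the
#' allele, then the founder conditional on allele and environment --
#' M(Kre), M(E | Kre), M(F | Kre, E).
#'
#' @param matrix a `mutation_matrix`.
#' @param labels data frame aligned with the matrix rows, with columns
#'   `focal_allele`, `environment`, `founder`.
#' @param n_perm permutations per level.
#' @param seed RNG seed.
#' @return named list of `mi_test` objects.
#' @export
mi_hierarchy <- function(matrix, labels, n_perm = 10000, seed = 1) {
  stopifnot(all(c("focal_allele", "environment", "founder") %in%
                  names(labels)))
  list(
    focal = permutation_null(labels$focal_allele, matrix,
                             n_perm = n_perm, seed = seed),
    environment_given_focal = permutation_null(
      labels$environment, matrix, Z = labels$focal_allele,
      n_perm = n_perm, seed = seed + 1),
    founder_given_focal_env = permutation_null(
      labels$founder, matrix,
      Z = data.frame(labels$focal_allele, labels$environment),
      n_perm = n_perm, seed = seed + 2)
  )
}
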