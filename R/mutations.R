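#' Per-site, per-population read-count table
#'
#' Container for pooled-sequencing counts: a sites data frame (`chrom`,
#' 1-based `pos`, `ref`, `alt`, optional `consequence`) and matching
#' sites x populations matrices of reference and alternate read counts.
#'
#' @param sites data frame of site descriptors.
#' @param ref_counts,alt_counts integer matrices, one column per population
#'   (column names are population ids).
#' @return object of class `site_counts`.
#' @export
site_count_table <- function(sites, ref_counts, alt_counts) {
  stopifnot(nrow(sites) == nrow(ref_counts),
            all(dim(ref_counts) == dim(alt_counts)),
            !is.null(colnames(alt_counts)))
  if (any(ref_counts < 0) || any(alt_counts < 0))
    stop("read counts must be nonnegative")
  rownames(sites) <- NULL
  structure(list(sites = sites, ref = ref_counts, alt = alt_counts),
            class = "site_counts")
}

#' @export
print.site_counts <- function(x, ...) {
  cat(sprintf("Site count table: %d sites x %d populations\n",
              nrow(x$sites), ncol(x$alt)))
  invisible(x)
}

## alternate-allele frequency matrix; NA where depth is zero
alt_frequency <- function(x) {
  depth <- x$ref + x$alt
  f <- x$alt / depth
  f[depth == 0] <- NA_real_
  f
}

#' Pooled-sequencing site filters
#'
#' Applies, in order, the two site-level filters used before mutation
#' calling: (1) remove sites where the alternate allele is in the majority
#' (frequency strictly above 0.5) in at least `majority_lines` populations
#' -- these are fixed differences between the parental strains; then
#' (2) remove sites (among stage-1 survivors) where the alternate allele is
#' strictly above `freq_thresh` frequency in `freq_pops` or more populations
#' -- typically alignment artifacts.  Populations with zero depth at a site
#' have undefined frequency and do not count toward either rule.  Ties go to
#' retention (thresholds are strict).
#'
#' @param x a `site_counts` table.
#' @param majority_lines stage-1 line count threshold (default 6).
#' @param freq_thresh stage-2 frequency threshold (default 0.10).
#' @param freq_pops stage-2 population count threshold (default 5).
#' @return list with `filtered` (a `site_counts` of surviving sites) and
#'   `removed` (data frame logging which rule fired per removed site).
#' @export
apply_site_filters <- function(x, majority_lines = 6, freq_thresh = 0.10,
                               freq_pops = 5) {
  stopifnot(inherits(x, "site_counts"))
  if (ncol(x$alt) < 1) stop("need >= 1 population")
  f <- alt_frequency(x)
  stage1 <- rowSums(f > 0.5, na.rm = TRUE) >= majority_lines
  keep1 <- which(!stage1)
  f2 <- f[keep1, , drop = FALSE]
  stage2 <- rowSums(f2 > freq_thresh, na.rm = TRUE) >= freq_pops
  removed <- data.frame(
    index = c(which(stage1), keep1[stage2]),
    rule = c(rep("parental_majority", sum(stage1)),
             rep("error_prone", sum(stage2))))
  removed <- removed[order(removed$index), , drop = FALSE]
  removed$chrom <- x$sites$chrom[removed$index]
  removed$pos <- x$sites$pos[removed$index]
  rownames(removed) <- NULL
  keep <- setdiff(seq_len(nrow(x$sites)), removed$index)
  list(filtered = site_count_table(x$sites[keep, , drop = FALSE],
                                   x$ref[keep, , drop = FALSE],
                                   x$alt[keep, , drop = FALSE]),
       removed = removed)
}

#' Call de novo mutations from a filtered count table
#'
#' A mutation is called in a population when the alternate allele is
#' strictly above 50% of the reads and supported by at least 4 reads.
#'
#' @param x a `site_counts` table (already filtered with
#'   [apply_site_filters()]).
#' @param min_support minimum alternate read support.
#' @return data frame of calls: `population_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `frequency`, `alt_reads`, `depth`, and `consequence` when the
#'   site table carries one.
#' @export
call_mutations <- function(x, min_support = 4) {
  stopifnot(inherits(x, "site_counts"))
  f <- alt_frequency(x)
  hit <- which(f > 0.5 & x$alt >= min_support, arr.ind = TRUE)
  calls <- data.frame(
    population_id = colnames(x$alt)[hit[, 2]],
    chrom = x$sites$chrom[hit[, 1]],
    pos = x$sites$pos[hit[, 1]],
    ref = x$sites$ref[hit[, 1]],
    alt = x$sites$alt[hit[, 1]],
    frequency = f[hit],
    alt_reads = x$alt[hit],
    depth = x$alt[hit] + x$ref[hit]
  )
  if (!is.null(x$sites$consequence))
    calls$consequence <- x$sites$consequence[hit[, 1]]
  calls[order(calls$chrom, calls$pos, calls$population_id), , drop = FALSE]
}

#' Remove variants shared among sibling populations
#'
#' An identical variant (same chromosome, position, reference and alternate
#' allele) present in two or more populations descended from the same
#' founder almost certainly predates the evolution experiment (standing
#' variation picked up when founding the populations) and is removed from
#' all carriers.
#'
#' @param calls a calls data frame from [call_mutations()].
#' @param pop_founder named vector mapping population id to founder id; must
#'   cover every population in `calls`.
#' @return list with `calls` (retained) and `removed`.
#' @export
remove_shared_founder_snvs <- function(calls, pop_founder) {
  if (!nrow(calls)) return(list(calls = calls, removed = calls))
  if (any(!calls$population_id %in% names(pop_founder)))
    stop("unmapped population in calls")
  founder <- pop_founder[calls$population_id]
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, founder)
  shared <- key %in% names(which(table(key) >= 2))
  list(calls = calls[!shared, , drop = FALSE],
       removed = calls[shared, , drop = FALSE])
}

## coerce annotation input to a GRanges of 1-based inclusive gene intervals
as_gene_ranges <- function(annotation) {
  if (inherits(annotation, "GRanges")) {
    gr <- annotation
    if (is.null(gr$gene)) {
      nm <- gr$Name %||% gr$gene_id %||% names(gr)
      gr$gene <- as.character(nm)
    }
    return(gr)
  }
  if (is.character(annotation) && length(annotation) == 1) {
    ## BED (0-based half-open) or GFF3 (1-based inclusive); rtracklayer
    ## converts both to 1-based GRanges at the boundary
    gr <- rtracklayer::import(annotation)
    nm <- gr$name %||% gr$Name %||% gr$ID
    gr$gene <- as.character(nm)
    return(gr)
  }
  stopifnot(is.data.frame(annotation),
            all(c("gene", "chrom", "start", "end") %in% names(annotation)))
  GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start, end = annotation$end),
    gene = annotation$gene)
}

#' Assign calls to genes and list multi-hit genes
#'
#' Maps each call to the gene whose interval contains its position (1-based
#' inclusive; BED input is converted at the boundary; overlapping intervals
#' are resolved in favour of the smallest, with a warning).  Calls outside
#' every interval are classed intergenic.  Multi-hit genes are genes with
#' putatively functional calls (missense, putative loss-of-function, or an
#' indel in the gene) in at least two distinct populations; such genes are
#' enriched for targets of selection.
#'
#' @param calls calls data frame (from [call_mutations()], possibly after
#'   [remove_shared_founder_snvs()]).
#' @param annotation gene intervals: a data frame (`gene`, `chrom`, `start`,
#'   `end`), a `GRanges`, or a path to a BED/GFF3 file.
#' @param functional_classes consequence classes counted as putatively
#'   functional.
#' @return list with `calls` (gene column added), `multihit` (character
#'   vector of multi-hit genes), and `gene_populations` (per-gene number of
#'   distinct populations with functional calls).
#' @export
assign_genes_and_multihit <- function(calls, annotation,
                                      functional_classes = c("missense",
                                                             "putative_LOF",
                                                             "indel")) {
  genes <- as_gene_ranges(annotation)
  calls$gene <- NA_character_
  if (nrow(calls)) {
    q <- GenomicRanges::GRanges(calls$chrom,
                                IRanges::IRanges(calls$pos, calls$pos))
    ov <- GenomicRanges::findOverlaps(q, genes)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    if (anyDuplicated(qh)) {
      warning("overlapping gene intervals; resolving by smallest interval")
      w <- GenomicRanges::width(genes)[sh]
      ord <- order(qh, w)
      keep <- !duplicated(qh[ord])
      qh <- qh[ord][keep]; sh <- sh[ord][keep]
    }
    calls$gene[qh] <- genes$gene[sh]
  }
  if (is.null(calls$consequence)) calls$consequence <- "missense"
  calls$consequence[is.na(calls$gene)] <- "noncoding"
  func <- !is.na(calls$gene) & calls$consequence %in% functional_classes
  gp <- tapply(calls$population_id[func], calls$gene[func],
               function(p) length(unique(p)))
  gp <- gp[order(-gp, names(gp))]
  multihit <- names(gp)[gp >= 2]
  list(calls = calls, multihit = multihit,
       gene_populations = gp)
}

#' Expected overlap between multi-hit genes and QTL-interval genes
#'
#' Under random draws from a genome of `n_genome` genes, the expected number
#' of genes common to a set of `n_multihit` and a set of `n_qtl_genes` genes
#' is hypergeometric: `n_multihit * n_qtl_genes / n_genome`.  When the
#' observed overlap is supplied, the hypergeometric enrichment probability
#' `P(overlap >= observed)` is also returned.
#'
#' @param n_multihit,n_qtl_genes,n_genome set sizes (both sets within the
#'   genome).
#' @param observed optional observed overlap.
#' @return list with `expected` and (if `observed` given) `p_value` and
#'   `observed`.
#' @export
expected_overlap <- function(n_multihit, n_qtl_genes, n_genome,
                             observed = NULL) {
  if (n_multihit > n_genome || n_qtl_genes > n_genome)
    stop("set sizes cannot exceed the genome size")
  out <- list(expected = n_multihit * n_qtl_genes / n_genome)
  if (!is.null(observed)) {
    out$observed <- observed
    out$p_value <- stats::phyper(observed - 1, n_qtl_genes,
                                 n_genome - n_qtl_genes, n_multihit,
                                 lower.tail = FALSE)
  }
  out
}

#' Trend of mutation counts with founder fitness
#'
#' Ordinary least-squares slope of per-population mutation counts on the
#' founder's fitness, with a cluster bootstrap over founders (populations of
#' a founder are resampled together) for the p-value, since counts of
#' sibling populations are not independent.
#'
#' @param counts per-population nonsynonymous mutation counts.
#' @param fitness per-population founder fitness (home environment).
#' @param founder founder id per population (bootstrap cluster).
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed.
#' @return list with `slope`, `intercept`, `p` (two-sided bootstrap),
#'   `p_negative` (one-sided for a declining trend), `ci` on the slope.
#' @export
mutation_count_trend <- function(counts, fitness, founder, n_boot = 1000,
                                 seed = 1) {
  stopifnot(length(counts) == length(fitness),
            length(fitness) == length(founder))
  if (any(counts < 0)) stop("counts must be nonnegative")
  fit <- stats::lm(counts ~ fitness)
  slope <- unname(stats::coef(fit)[2])
  set.seed(seed)
  fs <- unique(founder)
  idx_by_f <- split(seq_along(founder), founder)[fs]
  sb <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    k <- unlist(idx_by_f[sample.int(length(fs), replace = TRUE)],
                use.names = FALSE)
    if (stats::var(fitness[k]) == 0) { sb[b] <- NA; next }
    sb[b] <- unname(stats::coef(stats::lm.fit(cbind(1, fitness[k]),
                                              counts[k]))[2])
  }
  sb <- sb[is.finite(sb)]
  p_neg <- (1 + sum(sb >= 0)) / (1 + length(sb))
  p_pos <- (1 + sum(sb <= 0)) / (1 + length(sb))
  list(slope = slope, intercept = unname(stats::coef(fit)[1]),
       p = min(1, 2 * min(p_neg, p_pos)), p_negative = p_neg,
       ci = pct_ci(sb), n = length(counts))
}
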