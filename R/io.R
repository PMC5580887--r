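## Readers and writers for the package's tab-separated interchange formats.
## All tables are TSV with a header line; genomic positions are 1-based.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write a simulated cross dataset to a directory of TSV tables
#'
#' Emits `genotypes.tsv` (founder_id then one RM/BY column per locus labeled
#' `chrom:pos`), `fitness.tsv` (strain_id, type, environment, replicate,
#' fitness), `populations.tsv`, `mutations.tsv`, `truth.tsv` (true founder
#' fitness), and when present `site_counts.tsv` plus `genes.bed`
#' (0-based half-open, converted at the boundary).
#'
#' @param cross a `cross_data` from [simulate_cross()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_cross_tables <- function(cross, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- cross$genotypes
  gdf <- data.frame(founder_id = g$founders, g$alleles, check.names = FALSE)
  write_tsv(gdf, file.path(dir, "genotypes.tsv"))
  write_tsv(cross$fitness_table, file.path(dir, "fitness.tsv"))
  write_tsv(cross$populations, file.path(dir, "populations.tsv"))
  write_tsv(cross$mutations, file.path(dir, "mutations.tsv"))
  write_tsv(cross$founder_fitness, file.path(dir, "truth.tsv"))
  if (!is.null(cross$site_data)) {
    write_site_counts(cross$site_data$site_counts,
                      file.path(dir, "site_counts.tsv"))
    anno <- cross$site_data$annotation
    bed <- data.frame(chrom = anno$chrom, start = anno$start - 1L,
                      end = anno$end, name = anno$gene)
    utils::write.table(bed[order(bed$chrom, bed$start), ],
                       file.path(dir, "genes.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Read a founder genotype table
#'
#' Inverse of the `genotypes.tsv` layout written by [write_cross_tables()]:
#' first column `founder_id`, then one RM/BY column per locus labeled
#' `chrom:pos`.
#'
#' @param path TSV path.
#' @return a `genotype_matrix`.
#' @export
read_genotypes <- function(path) {
  df <- read_tsv(path)
  founders <- df[[1]]
  alleles <- as.matrix(df[, -1, drop = FALSE])
  rownames(alleles) <- founders
  parts <- strsplit(colnames(alleles), ":", fixed = TRUE)
  loci <- data.frame(chrom = vapply(parts, `[`, "", 1),
                     pos = as.integer(vapply(parts, `[`, "", 2)))
  structure(list(alleles = alleles, loci = loci, founders = founders),
            class = "genotype_matrix")
}

#' Write / read a per-site read-count table
#'
#' Wide TSV layout: `chrom`, `pos`, `ref`, `alt` (and `consequence` when
#' known), then paired columns `<pop>_ref`, `<pop>_alt` per population.
#'
#' @param x a `site_counts` table.
#' @param path TSV path.
#' @return `write_site_counts` returns the path invisibly;
#'   `read_site_counts` returns a `site_counts`.
#' @export
write_site_counts <- function(x, path) {
  stopifnot(inherits(x, "site_counts"))
  pops <- colnames(x$alt)
  wide <- x$sites
  for (p in pops) {
    wide[[paste0(p, "_ref")]] <- x$ref[, p]
    wide[[paste0(p, "_alt")]] <- x$alt[, p]
  }
  write_tsv(wide, path)
  invisible(path)
}

#' @rdname write_site_counts
#' @export
read_site_counts <- function(path) {
  df <- read_tsv(path)
  refcols <- grep("_ref$", names(df), value = TRUE)
  pops <- sub("_ref$", "", refcols)
  meta <- df[, setdiff(names(df), c(refcols, paste0(pops, "_alt"))),
             drop = FALSE]
  ref <- as.matrix(df[, refcols, drop = FALSE])
  alt <- as.matrix(df[, paste0(pops, "_alt"), drop = FALSE])
  colnames(ref) <- colnames(alt) <- pops
  site_count_table(meta, ref, alt)
}

#' Write mutation calls as a minimal VCF 4.2 file
#'
#' One record per (site, population) call with `INFO` fields `POP`
#' (population id), `AF` (alternate frequency) and `AD` (alternate read
#' depth); `QUAL` is `.` and `FILTER` is `PASS`, since records are written
#' after the site filters.
#'
#' @param calls calls data frame from [call_mutations()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_calls_vcf <- function(calls, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=evoherit",
    "##INFO=<ID=POP,Number=1,Type=String,Description=\"Population id\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele frequency\">",
    "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Alternate read depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- if (nrow(calls)) sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\tPOP=%s;AF=%.4g;AD=%d",
    calls$chrom, as.integer(calls$pos), calls$ref, calls$alt,
    calls$population_id, calls$frequency, as.integer(calls$alt_reads)
  ) else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}
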