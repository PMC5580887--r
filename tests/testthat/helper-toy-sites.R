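## Hand-constructed 10-site x 10-population count table whose filtering and
## calling outcome was derived by hand from the filter definitions:
##   s1  alt 12/20 in pops 1-6            -> removed, parental majority (6 lines)
##   s2  alt 12/20 in pops 1-5            -> survives stage 1 (5 < 6) but is
##                                           removed at stage 2 (5 pops > 10%)
##   s3  alt 3/20 in pops 1-5             -> removed, error-prone (5 pops > 10%)
##   s4  alt 3/20 in pops 1-4             -> retained (4 < 5), never called
##   s5  alt 20/20 in pops 1,3,5,7; pops 9,10 zero depth -> retained, 4 calls
##   s6  alt 3/5 in pop 7 (60%)           -> retained, support 3 < 4: no call
##   s7  alt 4/6 in pop 8 (66.7%)         -> retained, called
##   s8  alt 4/8 in pop 9 (50%)           -> retained, not > 50%: no call
##   s9  alt 20/20 in pops 1,2 (same founder) -> called twice, then discarded
##                                           as a shared founder variant
##   s10 alt 18/20 in pop 3               -> retained, called
## Gene GA [450,550] contains s5 (multi-hit: 4 distinct populations);
## gene GB [950,1050] contains s10 (one population: not multi-hit).
toy_sites <- function() {
  pops <- sprintf("pop%02d", 1:10)
  founders <- rep(sprintf("f%d", 1:5), each = 2)
  names(founders) <- pops
  sites <- data.frame(
    chrom = "chr01", pos = (1:10) * 100L, ref = "A", alt = "T",
    consequence = c("noncoding", "noncoding", "noncoding", "noncoding",
                    "missense", "missense", "missense", "missense",
                    "missense", "missense"))
  ref <- matrix(20L, 10, 10, dimnames = list(NULL, pops))
  alt <- matrix(0L, 10, 10, dimnames = list(NULL, pops))
  put <- function(site, pop, a, r) {
    alt[site, pop] <<- a
    ref[site, pop] <<- r
  }
  for (j in 1:6) put(1, j, 12L, 8L)
  for (j in 1:5) put(2, j, 12L, 8L)
  for (j in 1:5) put(3, j, 3L, 17L)
  for (j in 1:4) put(4, j, 3L, 17L)
  for (j in c(1, 3, 5, 7)) put(5, j, 20L, 0L)
  put(5, 9, 0L, 0L); put(5, 10, 0L, 0L)
  put(6, 7, 3L, 2L)
  put(7, 8, 4L, 2L)
  put(8, 9, 4L, 4L)
  put(9, 1, 20L, 0L); put(9, 2, 20L, 0L)
  put(10, 3, 18L, 2L)
  list(table = site_count_table(sites, ref, alt),
       pop_founder = founders,
       annotation = data.frame(gene = c("GA", "GB"), chrom = "chr01",
                               start = c(450L, 950L), end = c(550L, 1050L)),
       expected_surviving_pos = c(400L, 500L, 600L, 700L, 800L, 900L, 1000L),
       expected_removed = data.frame(pos = c(100L, 200L, 300L),
                                     rule = c("parental_majority",
                                              "error_prone", "error_prone")),
       expected_calls = data.frame(
         population_id = c("pop01", "pop03", "pop05", "pop07", "pop08",
                           "pop01", "pop02", "pop03"),
         pos = c(500L, 500L, 500L, 500L, 700L, 900L, 900L, 1000L)),
       expected_calls_after_shared = data.frame(
         population_id = c("pop01", "pop03", "pop05", "pop07", "pop08",
                           "pop03"),
         pos = c(500L, 500L, 500L, 500L, 700L, 1000L)),
       expected_multihit = "GA")
}
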