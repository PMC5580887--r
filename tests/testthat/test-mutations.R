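test_that("site filters fire the documented rules at their boundaries", {
  toy <- toy_sites()
  res <- apply_site_filters(toy$table)
  expect_equal(res$filtered$sites$pos, toy$expected_surviving_pos)
  expect_equal(res$removed$pos, toy$expected_removed$pos)
  expect_equal(res$removed$rule, toy$expected_removed$rule)
})

test_that("site filtering is idempotent and stage-ordered", {
  toy <- toy_sites()
  once <- apply_site_filters(toy$table)
  twice <- apply_site_filters(once$filtered)
  expect_equal(twice$filtered$sites, once$filtered$sites)
  expect_equal(nrow(twice$removed), 0)
  ## s2 is majority in only 5 lines (stage 1 keeps it) but above 10% in 5
  ## populations, so stage 2 -- computed on stage-1 survivors -- removes it
  s2 <- once$removed[once$removed$pos == 200L, ]
  expect_equal(s2$rule, "error_prone")
})

test_that("mutation calling applies strict frequency and support thresholds", {
  toy <- toy_sites()
  filt <- apply_site_filters(toy$table)$filtered
  calls <- call_mutations(filt)
  got <- calls[order(calls$pos, calls$population_id),
               c("population_id", "pos")]
  want <- toy$expected_calls[order(toy$expected_calls$pos,
                                   toy$expected_calls$population_id), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
  ## boundary cases: 3/5 lacks support, 4/8 is not > 50%
  expect_false(any(calls$pos == 600L))
  expect_false(any(calls$pos == 800L))
  expect_true(any(calls$pos == 700L))
})

test_that("variants shared among sibling populations are discarded", {
  toy <- toy_sites()
  calls <- call_mutations(apply_site_filters(toy$table)$filtered)
  res <- remove_shared_founder_snvs(calls, toy$pop_founder)
  expect_equal(sort(res$removed$population_id), c("pop01", "pop02"))
  expect_equal(nrow(res$calls), 6)
  ## the same variant in populations of different founders is retained
  expect_true(all(res$calls$pos[res$calls$population_id == "pop05"] == 500))
  expect_error(remove_shared_founder_snvs(calls, toy$pop_founder[-1]),
               "unmapped")
})

test_that("gene assignment and the multi-hit rule count distinct populations", {
  toy <- toy_sites()
  calls <- remove_shared_founder_snvs(
    call_mutations(apply_site_filters(toy$table)$filtered),
    toy$pop_founder)$calls
  ann <- assign_genes_and_multihit(calls, toy$annotation)
  expect_equal(ann$multihit, toy$expected_multihit)
  expect_equal(unname(ann$gene_populations[["GA"]]), 4)
  ## intergenic calls are classed noncoding
  expect_equal(unique(ann$calls$consequence[is.na(ann$calls$gene)]),
               "noncoding")
  ## a gene hit twice in one population only is not multi-hit
  calls2 <- data.frame(population_id = c("p1", "p1"), chrom = "chr01",
                       pos = c(460L, 470L), ref = "A", alt = "T",
                       frequency = 1, alt_reads = 10L, depth = 10L,
                       consequence = "missense")
  ann2 <- assign_genes_and_multihit(calls2, toy$annotation)
  expect_equal(length(ann2$multihit), 0)
})

test_that("annotation can be supplied as a BED file", {
  toy <- toy_sites()
  bed <- tempfile(fileext = ".bed")
  a <- toy$annotation
  writeLines(sprintf("%s\t%d\t%d\t%s", a$chrom, a$start - 1L, a$end, a$gene),
             bed)
  calls <- remove_shared_founder_snvs(
    call_mutations(apply_site_filters(toy$table)$filtered),
    toy$pop_founder)$calls
  ann <- assign_genes_and_multihit(calls, bed)
  expect_equal(ann$multihit, toy$expected_multihit)
})

test_that("calls export as parseable minimal VCF", {
  toy <- toy_sites()
  calls <- call_mutations(apply_site_filters(toy$table)$filtered)
  f <- tempfile(fileext = ".vcf")
  write_calls_vcf(calls, f)
  lines <- readLines(f)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), nrow(calls))
  fields <- strsplit(body[1], "\t")[[1]]
  expect_equal(length(fields), 8)
  expect_equal(fields[7], "PASS")
})

test_that("hypergeometric overlap expectation follows nK/N", {
  expect_equal(expected_overlap(0, 99, 5858)$expected, 0)
  expect_equal(expected_overlap(27, 99, 5858)$expected, 2673 / 5858)
  expect_equal(expected_overlap(40, 40, 40)$expected, 40)
  ov <- expected_overlap(27, 99, 5858, observed = 3)
  expect_equal(ov$p_value,
               phyper(2, 99, 5858 - 99, 27, lower.tail = FALSE))
  expect_error(expected_overlap(10, 20, 15))
})

test_that("mutation-count trend recovers a planted decline", {
  set.seed(23)
  founder <- rep(sprintf("f%d", 1:60), each = 4)
  X <- rnorm(60, 0, 0.1)[rep(1:60, each = 4)]
  counts <- pmax(0, round(10 - 5 * X + rnorm(length(X), 0, 1)))
  tr <- mutation_count_trend(counts, X, founder, n_boot = 500, seed = 1)
  expect_lt(tr$slope, 0)
  expect_lt(tr$p_negative, 0.05)
  ## constant counts: slope exactly zero
  tr0 <- mutation_count_trend(rep(3, length(X)), X, founder,
                              n_boot = 200, seed = 1)
  expect_equal(tr0$slope, 0)
})
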