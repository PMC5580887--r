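Package: evoherit
Title: Heritability of Adaptability and Pleiotropy in Experimental Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-genetic analysis of adaptability and pleiotropy in
    experimentally evolved populations founded from a biparental yeast cross.
    Provides competitive-fitness estimation from flow-cytometry counts,
    broad-sense variance partitioning of fitness and fitness increments with
    delete-half jackknife confidence intervals, narrow-sense heritability by
    REML on a standardized kinship matrix, iterative QTL scanning with
    permutation LOD thresholds and 1.5-LOD confidence intervals,
    declining-adaptability and pleiotropy regressions, pooled-sequencing
    mutation-call filtering, a mutual-information permutation test for
    associations between founder genotype, environment and de novo mutation
    spectra, and a synthetic-cross generator with known ground truth for
    validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
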