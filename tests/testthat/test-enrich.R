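test_that("gene regions extend 2 kb upstream strand-awarely with truncation", {
  ann <- tinyAnnotation(
    data.frame(gene_id = c("gPlus", "gMinus", "gEdge"), chr = "chr1",
               start = c(10001, 10001, 500), end = c(12000, 12000, 900),
               strand = c("+", "-", "+")),
    data.frame(te_id = character(), chr = character(), start = integer(),
               end = integer(), superfamily = character()))
  r <- geneRegions(ann, upstream = 2000)
  expect_equal(GenomicRanges::start(r["gPlus"]), 8001)
  expect_equal(GenomicRanges::end(r["gPlus"]), 12000)
  expect_equal(GenomicRanges::start(r["gMinus"]), 10001)
  expect_equal(GenomicRanges::end(r["gMinus"]), 14000)
  expect_equal(GenomicRanges::start(r["gEdge"]), 1)   # truncated at 1
  ## minus-strand extension truncated at the chromosome end
  ann2 <- tinyAnnotation(
    data.frame(gene_id = "gM", chr = "chr1", start = 19000, end = 19500,
               strand = "-"),
    data.frame(te_id = character(), chr = character(), start = integer(),
               end = integer(), superfamily = character()))
  expect_equal(GenomicRanges::end(geneRegions(ann2)["gM"]), 20000)
})

test_that("overlap counting uses closed intervals and counts per gene", {
  ann <- tinyAnnotation(
    data.frame(gene_id = c("g1", "g2"), chr = "chr1",
               start = c(5001, 5501), end = c(6000, 6400),
               strand = c("+", "+")),
    data.frame(te_id = c("t1", "t2", "t3"), chr = "chr1",
               start = c(6000, 6401, 3100), end = c(6200, 6500, 3200),
               superfamily = c("Gypsy", "Gypsy", "MuDR")))
  r <- geneRegions(ann, upstream = 2000)
  oc <- teOverlapCounts(r, ann, "Gypsy")
  ## t1 abuts g1 region end (te.start == region.end): counted; and it
  ## overlaps g2 as well, so it contributes to both genes
  expect_identical(oc$per_gene, c(g1 = 1L, g2 = 1L))
  expect_identical(oc$total, 2L)
  expect_identical(teOverlapCounts(r, ann, "MuDR")$total, 1L)  # upstream g1
  expect_error(teOverlapCounts(r, ann, "NotAFamily"), "superfamily")
})

test_that("no TEs means all overlap counts are zero", {
  ann <- simulateAnnotation(n_genes = 20, n_tes = 0, seed = 1)
  r <- geneRegions(ann)
  expect_identical(teOverlapCounts(r, ann)$total, 0L)
})

test_that("overlap totals match a brute-force all-pairs oracle", {
  set.seed(14)
  for (rep in 1:3) {
    ann <- simulateAnnotation(n_genes = 60, n_tes = 200, seed = rep)
    r <- geneRegions(ann)
    got <- teOverlapCounts(r, ann, "Gypsy")
    te <- transposons(ann)
    te <- te[S4Vectors::mcols(te)$superfamily == "Gypsy"]
    brute <- vapply(seq_along(r), function(i) {
      sum(as.character(GenomicRanges::seqnames(te)) ==
            as.character(GenomicRanges::seqnames(r[i])) &
            GenomicRanges::start(te) <= GenomicRanges::end(r[i]) &
            GenomicRanges::end(te) >= GenomicRanges::start(r[i]))
    }, numeric(1))
    expect_identical(unname(got$per_gene), as.integer(brute))
    expect_identical(got$total, as.integer(sum(brute)))
  }
})

test_that("the permutation test is seeded, monotone and formula-exact", {
  ann <- simulateAnnotation(n_genes = 100, n_tes = 400,
                            enrichment_factor = 6,
                            susceptible = sprintf("gene%05d", 1:20),
                            seed = 3)
  bg <- sprintf("gene%05d", 1:100)
  gs <- sprintf("gene%05d", 1:20)
  r1 <- tePermutationTest(gs, bg, ann, n_permutations = 500, seed = 9)
  r2 <- tePermutationTest(gs, bg, ann, n_permutations = 500, seed = 9)
  expect_identical(r1$null_samples, r2$null_samples)
  expect_identical(r1$p_empirical, r2$p_empirical)
  ## exact estimator definition, including p = 0 when observed tops all
  expect_equal(r1$p_empirical,
               sum(r1$null_samples > r1$observed) / 500)
  expect_equal(r1$p_empirical, 0)
  ## reordering the null draws cannot change p
  expect_equal(sum(sample(r1$null_samples) > r1$observed) / 500,
               r1$p_empirical)
  ## add-one estimator never returns zero
  r3 <- tePermutationTest(gs, bg, ann, n_permutations = 500, seed = 9,
                          estimator = "add_one")
  expect_gt(r3$p_empirical, 0)
  expect_error(tePermutationTest(gs, bg, ann, n_permutations = 0),
               "n_permutations")
  expect_error(tePermutationTest(bg, gs, ann), "larger than background")
})

test_that("adding a TE inside a set region cannot increase p", {
  ann <- simulateAnnotation(n_genes = 40, n_tes = 120, seed = 4)
  bg <- sprintf("gene%05d", 1:40)
  gs <- sprintf("gene%05d", 1:10)
  r1 <- tePermutationTest(gs, bg, ann, n_permutations = 400, seed = 5)
  ## drop one TE into the middle of the first set gene
  g <- annotGenes(ann)[gs[1]]
  extra <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(g),
    IRanges::IRanges(GenomicRanges::start(g) + 10,
                     GenomicRanges::start(g) + 200),
    strand = "*",
    seqlengths = GenomeInfoDb::seqlengths(g))
  S4Vectors::mcols(extra)$te_id <- "teX"
  S4Vectors::mcols(extra)$superfamily <-
    S4Vectors::mcols(transposons(ann))$superfamily[1]
  ann2 <- GenomeAnnotation(annotGenes(ann),
                           c(transposons(ann), extra))
  r2 <- tePermutationTest(gs, bg, ann2, n_permutations = 400, seed = 5)
  expect_gte(r2$observed, r1$observed + 1)
  expect_lte(r2$p_empirical, r1$p_empirical)
})

test_that("p is invariant under consistent gene relabeling", {
  ann <- simulateAnnotation(n_genes = 50, n_tes = 150, seed = 6)
  bg <- sprintf("gene%05d", 1:50)
  gs <- sprintf("gene%05d", 11:25)
  r1 <- tePermutationTest(gs, bg, ann, n_permutations = 300, seed = 2)
  g2 <- annotGenes(ann)
  relabel <- setNames(sprintf("X%03d", seq_along(bg)), bg)
  names(g2) <- unname(relabel[names(g2)])
  S4Vectors::mcols(g2)$gene_id <- names(g2)
  ann2 <- GenomeAnnotation(g2, transposons(ann))
  r2 <- tePermutationTest(unname(relabel[gs]), unname(relabel[bg]), ann2,
                          n_permutations = 300, seed = 2)
  expect_identical(r1$p_empirical, r2$p_empirical)
})

test_that("strong planted enrichment is detected with high power", {
  hits <- vapply(1:25, function(s) {
    ann <- simulateAnnotation(n_genes = 400, n_tes = 1600,
                              enrichment_factor = 5,
                              susceptible = sprintf("gene%05d", 1:200),
                              seed = s)
    bg <- sprintf("gene%05d", 1:400)
    tePermutationTest(sprintf("gene%05d", 1:200), bg, ann,
                      n_permutations = 400,
                      seed = s + 500)$p_empirical < 0.05
  }, logical(1))
  expect_gte(sum(hits), 23)
})

test_that("base-pair overlap mode sums intersection widths", {
  ann <- tinyAnnotation(
    data.frame(gene_id = "g1", chr = "chr1", start = 5001, end = 6000,
               strand = "+"),
    data.frame(te_id = c("t1", "t2"), chr = "chr1",
               start = c(5901, 100), end = c(6100, 200),
               superfamily = c("Gypsy", "Gypsy")))
  r <- tePermutationTest("g1", "g1", ann, superfamily = "Gypsy",
                         n_permutations = 10, seed = 1, unit = "bases")
  expect_equal(r$observed, 100)   # overlap 5901..6000 inclusive
})
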