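test_that("CPM normalizes every sample to one million", {
  m <- matrix(c(1, 1, 2), 3, 1, dimnames = list(paste0("g", 1:3), "s1"))
  expect_equal(drop(countsPerMillion(m)),
               c(g1 = 250000, g2 = 250000, g3 = 500000))
  set.seed(1)
  r <- matrix(rpois(600, 20), 60, 10)
  colnames(r) <- paste0("s", 1:10)
  expect_equal(unname(colSums(countsPerMillion(r))), rep(1e6, 10),
               tolerance = 1e-9)
  r[, 3] <- 0
  expect_error(countsPerMillion(r), "s3")
})

test_that("the expression filter applies a strict sum-CPM cutoff", {
  ## 4 samples, library size 4e6 each; gene2 sums to CPM exactly 1
  m <- rbind(big = c(4e6 - 1, 4e6 - 1), g2 = c(1, 1), g3 = c(0, 0))
  m <- cbind(m, m)    # 2 control + 2 treatment samples
  colnames(m) <- paste0("s", 1:4)
  x <- tinyCounts(m)
  kept <- filterGenes(x, "gtA", "drought")
  expect_true("big" %in% kept)
  expect_false("g2" %in% kept)   # exactly 1 is removed (strict >)
  expect_false("g3" %in% kept)   # all-zero gene removed
})

test_that("median-of-ratios matches its definition and a brute-force oracle", {
  set.seed(2)
  m <- matrix(rpois(300, 50) + 1, 50, 6)
  colnames(m) <- paste0("s", 1:6)
  m2 <- m
  m2[, 2] <- 2 * m2[, 1]
  sf <- medianOfRatios(m2)
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)
  expect_equal(medianOfRatios(m[, 1, drop = FALSE]), c(s1 = 1))
  ## brute-force oracle
  brute <- function(mm) {
    keep <- apply(mm > 0, 1, all)
    gm <- exp(rowMeans(log(mm[keep, ])))
    f <- apply(mm[keep, ] / gm, 2, median)
    f / exp(mean(log(f)))
  }
  for (s in 1:5) {
    set.seed(s)
    r <- matrix(rnbinom(300, mu = 40, size = 5), 50, 6,
                dimnames = list(NULL, paste0("s", 1:6)))
    expect_equal(medianOfRatios(r), brute(r), tolerance = 1e-12)
  }
  ## all-zero-containing genes only: error unless fallback
  z <- matrix(c(0, 5, 5, 0), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(medianOfRatios(z), "fallback")
  expect_silent(medianOfRatios(z, fallback = TRUE))
})

test_that("BH adjustment within a DE family matches the step-up oracle", {
  samples <- transcriptomeSamples("full", genotypes = "gtA",
                                  treatments = "drought")
  x <- simulateCounts(samples[samples$generation == "F1", ],
                      countScenario(n_genes = 300, seed = 3))
  de <- nbWaldTest(x, "gtA", "drought", "F1")
  ok <- !is.na(de$wald_p)
  expect_equal(de$padj[ok], bruteBH(de$wald_p[ok]), tolerance = 1e-12)
  expect_true(all(de$is_deg[ok] ==
                    (abs(de$log2fc[ok]) > 1.5 & de$padj[ok] < 0.05)))
})

test_that("log2 fold change flips sign when arms are swapped", {
  samples <- transcriptomeSamples("full", genotypes = "gtA",
                                  treatments = "drought")
  samples <- samples[samples$generation == "F1", ]
  x <- simulateCounts(samples, countScenario(
    n_genes = 100, planted_degs = data.frame(
      genotype = "gtA", treatment = "drought", gene = "gene00001",
      log2fc = 2, generations = "F1"), seed = 4))
  de1 <- nbWaldTest(x, "gtA", "drought", "F1")
  swapped <- sampleSheet(x)
  swapped$treatment <- ifelse(swapped$treatment == "control", "drought",
                              "control")
  x2 <- TransgenCounts(countMatrix(x), swapped)
  de2 <- nbWaldTest(x2, "gtA", "drought", "F1",
                    genes = de1$gene)
  m <- match(de1$gene, de2$gene)
  expect_equal(de1$log2fc, -de2$log2fc[m], tolerance = 1e-6)
})

test_that("identical arms yield no DEG calls", {
  set.seed(6)
  half <- matrix(rnbinom(200 * 3, mu = 60, size = 10), 200, 3)
  m <- cbind(half, half)
  colnames(m) <- paste0("s", 1:6)
  de <- nbWaldTest(tinyCounts(m), "gtA", "drought", "F1")
  expect_true(all(de$is_deg[!is.na(de$is_deg)] == 0))
  expect_true(all(abs(de$log2fc) < 1e-6, na.rm = TRUE))
})

test_that("significant but small fold changes are not DEGs", {
  ## planted log2fc = 1.2 < 1.5 with high counts: tiny P, still no call
  samples <- transcriptomeSamples("full", genotypes = "gtA",
                                  treatments = "drought")
  samples <- samples[samples$generation == "F1", ]
  x <- simulateCounts(samples, countScenario(
    n_genes = 500, baseline_meanlog = log(5000), baseline_sdlog = 0.2,
    dispersion = 0.002,
    planted_degs = data.frame(genotype = "gtA", treatment = "drought",
                              gene = sprintf("gene%05d", 1:25),
                              log2fc = 1.2, generations = "F1"),
    seed = 7))
  de <- nbWaldTest(x, "gtA", "drought", "F1")
  planted <- de[de$gene %in% sprintf("gene%05d", 1:25), ]
  expect_true(any(planted$padj < 0.05))
  expect_true(all(planted$is_deg == 0))
  ## the call column always equals the rule applied to its own columns
  ok <- !is.na(de$padj)
  expect_identical(de$is_deg[ok],
                   as.integer(abs(de$log2fc[ok]) > 1.5 & de$padj[ok] < 0.05))
})

test_that("the heritable-DEG rule needs at least two generations", {
  de <- expand.grid(gene = c("gA", "gB", "gC"),
                    generation = paste0("F", 1:4),
                    stringsAsFactors = FALSE)
  de$genotype <- "g1"; de$treatment <- "t"
  de$is_deg <- 0L
  de$is_deg[de$gene == "gA" & de$generation %in% c("F1", "F3")] <- 1L
  de$is_deg[de$gene == "gB" & de$generation == "F2"] <- 1L
  hd <- callHeritableDEGs(de)
  expect_true(hd$heritable[hd$gene == "gA"])
  expect_false(hd$heritable[hd$gene == "gB"])
  expect_false("gC" %in% hd$gene)
  expect_identical(hd$n_deg_generations[hd$gene == "gA"], 2L)
})

test_that("DEG-count model F statistics match a sums-of-squares oracle", {
  set.seed(8)
  de <- expand.grid(gene = "x", genotype = paste0("g", 1:4),
                    treatment = c("a", "b", "c"),
                    generation = paste0("F", 1:4),
                    stringsAsFactors = FALSE)
  de$is_deg <- rpois(nrow(de), 4)
  dm <- degCountModel(de)
  agg <- dm$counts
  ## brute force: type-II F via residual sums of squares of nested fits
  rss <- function(fml) sum(lm(fml, agg)$residuals^2)
  full <- rss(n_degs ~ genotype + treatment + generation)
  df_res <- nrow(agg) - (1 + 3 + 2 + 3)
  for (tm in c("genotype", "treatment", "generation")) {
    others <- setdiff(c("genotype", "treatment", "generation"), tm)
    red <- rss(as.formula(paste("n_degs ~", paste(others, collapse = "+"))))
    dfk <- length(unique(agg[[tm]])) - 1
    f_oracle <- ((red - full) / dfk) / (full / df_res)
    expect_equal(dm$anova$f[dm$anova$term == tm], f_oracle,
                 tolerance = 1e-8)
  }
  ## constant counts: nothing significant
  de$is_deg <- 3L
  dm2 <- degCountModel(de)
  expect_true(all(is.na(dm2$anova$p) | dm2$anova$p > 0.99))
})

test_that("overlap regions partition the union", {
  r <- overlapSummary(list(A = "a", B = "b"))
  expect_identical(sum(r$count[r$A & r$B]), 0L)
  r2 <- overlapSummary(list(A = c("x", "y"), B = c("x", "y")))
  expect_identical(r2$count[r2$A & r2$B], 2L)
  set.seed(9)
  sets <- lapply(1:3, function(i) sample(letters, 12))
  names(sets) <- c("s1", "s2", "s3")
  r3 <- overlapSummary(sets)
  expect_identical(sum(r3$count), length(unique(unlist(sets))))
  ## each region count agrees with direct set algebra
  for (i in seq_len(nrow(r3))) {
    inset <- unlist(r3[i, c("s1", "s2", "s3")])
    members <- Reduce(intersect, sets[inset])
    for (s in names(sets)[!inset]) members <- setdiff(members, sets[[s]])
    expect_identical(r3$count[i], length(members))
  }
})

test_that("gene-list cross-referencing flags DEG and heritable status", {
  de <- expand.grid(gene = c("gA", "gB"), generation = paste0("F", 1:4),
                    stringsAsFactors = FALSE)
  de$genotype <- "g1"; de$treatment <- "t"
  de$is_deg <- ifelse(de$gene == "gA" & de$generation %in% c("F1", "F2"),
                      1L, 0L)
  hd <- callHeritableDEGs(de)
  expect_identical(nrow(crossrefGeneList(de, hd, character())), 0L)
  tab <- crossrefGeneList(de, hd, c("gA", "gB", "gZ"))
  expect_identical(tab$measured, c(TRUE, TRUE, FALSE))
  expect_identical(tab$deg_anywhere, c(TRUE, FALSE, FALSE))
  expect_identical(tab$heritable, c(TRUE, FALSE, FALSE))
  expect_match(tab$hits[1], "g1:t:F1")
})

test_that("pooled control pairing uses every control sample", {
  samples <- transcriptomeSamples("full", genotypes = "gtA",
                                  treatments = "drought")
  x <- simulateCounts(samples, countScenario(n_genes = 120, seed = 11))
  de_m <- nbWaldTest(x, "gtA", "drought", "F1", control_pairing = "matched")
  de_p <- nbWaldTest(x, "gtA", "drought", "F1", control_pairing = "pooled")
  expect_identical(nrow(de_m), nrow(de_p))
  expect_false(identical(de_m$log2fc, de_p$log2fc))
  ## compact layout: the shared control arm serves matched contrasts
  cs <- transcriptomeSamples("compact", genotypes = "gtA",
                             treatments = "drought")
  xc <- simulateCounts(cs, countScenario(n_genes = 120, seed = 12))
  de_c <- nbWaldTest(xc, "gtA", "drought", "F2")
  expect_gt(nrow(de_c), 0)
})

test_that("fold changes track an established NB implementation", {
  samples <- transcriptomeSamples("full", genotypes = "gtA",
                                  treatments = "drought")
  samples <- samples[samples$generation == "F1", ]
  x <- simulateCounts(samples, countScenario(
    n_genes = 400, planted_degs = data.frame(
      genotype = "gtA", treatment = "drought",
      gene = sprintf("gene%05d", 1:30), log2fc = rep(c(-2, 2, 3), 10),
      generations = "F1"), seed = 13))
  de <- nbWaldTest(x, "gtA", "drought", "F1")
  suppressMessages({
    ss <- sampleSheet(x)
    ss$condition <- factor(ss$treatment, levels = c("control", "drought"))
    dds <- DESeq2::DESeqDataSetFromMatrix(countMatrix(x)[de$gene, ],
                                          S4Vectors::DataFrame(ss),
                                          ~ condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- as.data.frame(DESeq2::results(dds))
  })
  ok <- is.finite(de$log2fc) & is.finite(ref$log2FoldChange)
  expect_gt(cor(de$log2fc[ok], ref$log2FoldChange[ok]), 0.98)
  ## the strongly induced genes agree in sign and rough magnitude
  planted <- de$gene %in% sprintf("gene%05d", 1:30)
  expect_equal(de$log2fc[planted], ref$log2FoldChange[planted],
               tolerance = 0.35)
})
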