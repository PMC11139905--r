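test_that("single-step adjustment honours its closed-form anchors", {
  ## one contrast: adjusted equals unadjusted exactly
  r1 <- singleStepAdjust(2.1, matrix(4), seed = 1)
  expect_identical(r1$p_adjusted, r1$p_unadjusted)
  ## two independent contrasts at z = 1.96: Sidak 1 - 0.95^2
  r2 <- singleStepAdjust(c(1.96, 1.96), diag(2), n_draws = 2e5, seed = 1)
  expect_lt(abs(r2$p_adjusted[1] - (1 - (1 - 0.05)^2)), 0.004)
  ## perfectly correlated contrasts: max is the same variable
  S <- matrix(1, 2, 2)
  r3 <- singleStepAdjust(c(1.5, 1.5), S, n_draws = 2e5, seed = 1)
  expect_equal(r3$p_adjusted, r3$p_unadjusted, tolerance = 0.01)
  expect_true(all(r3$p_adjusted >= r3$p_unadjusted))
})

test_that("single-step adjustment is monotone and order-invariant", {
  set.seed(5)
  z <- c(0.5, 1.2, 2.4, 3.1)
  S <- crossprod(matrix(rnorm(16), 4))
  r <- singleStepAdjust(z * sqrt(diag(S)), S, n_draws = 5e4, seed = 2)
  expect_true(all(diff(r$p_adjusted[order(abs(r$z))]) <= 0))
  perm <- c(3, 1, 4, 2)
  r2 <- singleStepAdjust((z * sqrt(diag(S)))[perm], S[perm, perm],
                         n_draws = 5e4, seed = 2)
  expect_equal(r2$p_adjusted, r$p_adjusted[perm], tolerance = 0.01)
  expect_error(singleStepAdjust(c(1, 1), matrix(c(1, 2, 2, 1), 2)),
               "positive semi-definite")
})

test_that("the occurrence GLMM detects a planted genotype spread", {
  simOcc <- function(spread, seed) {
    set.seed(seed)
    occ <- expand.grid(genotype = paste0("g", 1:8),
                       treatment = c("t1", "t2", "t3"),
                       generation = paste0("F", 1:4),
                       phenotype = paste0("p", 1:5),
                       stringsAsFactors = FALSE)
    occ$test <- "I"
    lo <- seq(-spread / 2, spread / 2, length.out = 8)
    eta <- qlogis(0.25) + lo[match(occ$genotype, paste0("g", 1:8))]
    occ$group_id <- paste(occ$genotype, occ$treatment, occ$generation)
    gre <- rnorm(length(unique(occ$group_id)), 0, 0.3)
    eta <- eta + gre[match(occ$group_id, unique(occ$group_id))]
    occ$occurred <- rbinom(nrow(occ), 1, plogis(eta))
    occ
  }
  hits <- vapply(1:20, function(s) {
    fm <- fitOccurrenceGLMM(simOcc(2, s))
    fm$anova$p[fm$anova$term == "G"] < 0.05
  }, logical(1))
  expect_gte(sum(hits), 17)
})

test_that("separation triggers the penalized-logistic downgrade", {
  occ <- expand.grid(genotype = paste0("g", 1:4), treatment = c("a", "b"),
                     generation = paste0("F", 1:4),
                     phenotype = c("p1", "p2"), stringsAsFactors = FALSE)
  occ$test <- "I"
  set.seed(2)
  occ$occurred <- rbinom(nrow(occ), 1, 0.4)
  occ$occurred[occ$phenotype == "p2"] <- 0L    # complete separation
  occ$group_id <- paste(occ$genotype, occ$treatment, occ$generation)
  expect_message(fm <- fitOccurrenceGLMM(occ), "separation")
  expect_identical(fm$method, "firth")
  expect_true(all(is.finite(fm$coefficients)))
  expect_true(all(fm$anova$p >= 0 & fm$anova$p <= 1))
})

test_that("zero planted group variance is estimated near zero", {
  set.seed(8)
  occ <- expand.grid(genotype = paste0("g", 1:6), treatment = c("a", "b"),
                     generation = paste0("F", 1:4),
                     phenotype = paste0("p", 1:5), stringsAsFactors = FALSE)
  occ$test <- "I"
  occ$occurred <- rbinom(nrow(occ), 1, 0.3)
  occ$group_id <- paste(occ$genotype, occ$treatment, occ$generation)
  fm <- fitOccurrenceGLMM(occ)
  expect_identical(fm$method, "glmm")
  expect_lt(fm$group_variance, 0.5)
})

test_that("frequency regression applies the documented transforms", {
  freq <- data.frame(genotype = paste0("g", 1:8),
                     frequency = seq(0.05, 0.6, length.out = 8))
  met <- simulateMetadata(paste0("g", 1:8),
                          propensity = setNames(freq$frequency,
                                                freq$genotype),
                          link_superfamily = "MuDR", link_slope = 1,
                          link_sd = 0, seed = 2)
  r <- frequencyRegression(freq, met, "te_MuDR")
  expect_identical(r$transform, "log")
  expect_equal(abs(r$r), 1, tolerance = 1e-9)
  ## log transform: invariant to multiplicative predictor rescaling
  met2 <- met
  met2$te_MuDR <- met2$te_MuDR * 37
  expect_equal(frequencyRegression(freq, met2, "te_MuDR")$r, r$r,
               tolerance = 1e-9)
  ## identity transform: invariant to affine predictor rescaling
  rb <- frequencyRegression(freq, met, "Bio1")
  met3 <- met
  met3$Bio1 <- 3 * met3$Bio1 + 11
  expect_equal(frequencyRegression(freq, met3, "Bio1")$r, rb$r,
               tolerance = 1e-9)
  ## arcsine endpoints
  expect_equal(asin(sqrt(0)), 0)
  expect_equal(asin(sqrt(1)), pi / 2)
  ## zero-variance predictor is an explicit error
  met$te_Copia <- 5
  expect_error(frequencyRegression(freq, met, "te_Copia"), "variance")
})

test_that("a null susceptibility link yields mostly non-significant r", {
  freq <- data.frame(genotype = paste0("g", 1:10),
                     frequency = seq(0.1, 0.5, length.out = 10))
  hits <- vapply(1:40, function(s) {
    met <- simulateMetadata(paste0("g", 1:10), seed = s)  # no link planted
    frequencyRegression(freq, met, "te_MuDR")$p < 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.2)
})

test_that("effect-size correlations honour subsets and degeneracy", {
  set.seed(4)
  base <- expand.grid(genotype = paste0("g", 1:30), treatment = "t",
                      phenotype = c("p1", "p2"), stringsAsFactors = FALSE)
  eff <- do.call(rbind, lapply(c("F1", "F2"), function(g) {
    d <- base
    d$generation <- g
    d
  }))
  eff$test <- "I"
  eff$estimate <- rep(rnorm(nrow(base)), 2)   # duplicated across F1/F2
  eff$se <- 0.3
  eff$p <- 2 * pnorm(-abs(eff$estimate / eff$se))
  cc <- effectSizeCorrelations(eff, "generations", "all")
  expect_equal(cc$r, 1)
  ## subsets partition the points
  n_all <- effectSizeCorrelations(eff, "generations", "all")$n_points
  n_sig <- effectSizeCorrelations(eff, "generations",
                                  "significant")$n_points
  n_non <- effectSizeCorrelations(eff, "generations",
                                  "nonsignificant")$n_points
  expect_identical(n_all, n_sig + n_non)
  ## independent vectors stay near zero
  low <- vapply(1:20, function(s) {
    set.seed(s)
    e2 <- eff
    e2$estimate <- rnorm(nrow(e2))
    e2$p <- runif(nrow(e2))
    abs(effectSizeCorrelations(e2, "generations", "all")$r) < 0.3
  }, logical(1))
  expect_gte(sum(low), 18)
  ## fewer than 3 pairs -> undefined cell
  small <- eff[eff$genotype %in% c("g1", "g2") & eff$phenotype == "p1", ]
  cc2 <- effectSizeCorrelations(small, "generations", "all")
  expect_true(is.na(cc2$r))
})

test_that("matched-test correlations pair effects across tests", {
  set.seed(9)
  key <- expand.grid(genotype = paste0("g", 1:20), treatment = "t",
                     phenotype = "p1", generation = c("F1", "F2"),
                     stringsAsFactors = FALSE)
  e1 <- key; e1$test <- "I"; e1$estimate <- rnorm(nrow(key))
  e2 <- key; e2$test <- "II"; e2$estimate <- e1$estimate + rnorm(nrow(key),
                                                                 0, 0.1)
  e1$se <- e2$se <- 0.3
  e1$p <- e2$p <- 0.5
  cc <- effectSizeCorrelations(rbind(e1, e2), "tests", "all")
  expect_gt(cc$r, 0.9)
  expect_identical(cc$n_points, nrow(key))
})

test_that("scale-down analysis reduces the chance of significant correlations", {
  gt <- paste0("g", 1:6)
  sp <- designSpec(gt, c(t1 = 6L, t2 = 6L), 6L, n_layers = 8, n_rows = 6,
                   n_columns = 10)
  set.seed(31)
  keys <- expand.grid(genotype = gt, treatment = c("t1", "t2"),
                      phenotype = c("flowering_time", "plant_height"),
                      stringsAsFactors = FALSE)
  keys$effect <- ifelse(runif(nrow(keys)) < 0.5, 0, rnorm(nrow(keys), 0, 1.5))
  sc <- effectScenario(planted_effects = keys, seed = 31)
  ph <- simulatePhenotypes(buildDesign(sp, seed = 31), sc, test = "I")
  eff <- suppressWarnings(estimateAllEffects(
    ph, phenotypes = c("flowering_time", "plant_height"),
    treatments = c("t1", "t2")))
  full <- effectSizeCorrelations(eff, "generations", "all")
  full_share <- mean(full$p < 0.05, na.rm = TRUE)
  sd1 <- scaleDownAnalysis(eff, "one_genotype")
  expect_gte(full_share, mean(sd1$share_significant, na.rm = TRUE))
  ## degenerate restricted subsets are excluded, not errors
  tinyeff <- eff[eff$genotype == "g1" & eff$phenotype == "flowering_time" &
                   eff$treatment == "t1", ]
  sd2 <- scaleDownAnalysis(tinyeff, "one_treatment")
  expect_identical(sd2$n_pairs_defined, 0L)
  expect_true(is.na(sd2$share_significant))
})
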