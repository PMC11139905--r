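## Firth-penalized logistic regression (bias-reduced Newton iterations).
## Used as the fallback when the occurrence GLMM meets complete separation;
## the penalty keeps all coefficients finite.
.firthLogistic <- function(X, y, maxit = 100L, tol = 1e-8) {
  b <- numeric(ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% b)
    mu <- plogis(eta)
    W <- mu * (1 - mu)
    XtWX <- crossprod(X * W, X)
    Vi <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(Vi)) stop("Firth fit failed: singular information matrix",
                          call. = FALSE)
    h <- rowSums((X %*% Vi) * X) * W          # hat diagonal
    U <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    step <- drop(Vi %*% U)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% b); mu <- plogis(eta); W <- mu * (1 - mu)
  V <- solve(crossprod(X * W, X))
  list(coef = setNames(b, colnames(X)), vcov = V, converged = it < maxit)
}

## joint Wald chi-square per model term from coefficients + covariance
.waldTermTable <- function(b, V, assign, term_labels) {
  out <- lapply(seq_along(term_labels), function(k) {
    idx <- which(assign == k)
    idx <- idx[names(b)[idx] %in% names(b)[!is.na(b[idx])]]
    if (!length(idx)) return(NULL)
    bb <- b[idx]
    stat <- drop(t(bb) %*% solve(V[idx, idx, drop = FALSE]) %*% bb)
    data.frame(term = term_labels[k], chisq = stat, df = length(idx),
               p = pchisq(stat, length(idx), lower.tail = FALSE))
  })
  do.call(rbind, out)
}

#' Model the determinants of occurrence with a binomial GLMM
#'
#' Logistic mixed model of the 0/1 occurrence on genotype, ancestral
#' environment, generation and trait, with a random intercept per
#' six-replicate group, fit by Laplace approximation; fixed terms are tested
#' with Type-II Wald chi-square statistics. If a fixed-factor level shows
#' complete separation (all-0 or all-1 outcomes) the model is downgraded to
#' a Firth-penalized fixed-effects logistic regression, recorded in
#' `method`.
#'
#' @param occurrence table from [effectsToOccurrence()].
#' @param value_col `"occurred"` or `"marginal"`.
#' @return List with `anova` (term tests), `coefficients`, `vcov`,
#'   `group_variance`, `method` (`"glmm"` or `"firth"`), and the underlying
#'   `model` when a GLMM was fit.
#' @export
fitOccurrenceGLMM <- function(occurrence, value_col = "occurred") {
  df <- data.frame(y = occurrence[[value_col]],
                   G = factor(occurrence$genotype),
                   A.E = factor(occurrence$treatment),
                   F = factor(occurrence$generation),
                   Trait = factor(occurrence$phenotype),
                   group = factor(occurrence$group_id))
  terms_fixed <- c("G", "A.E", "F", "Trait")
  terms_fixed <- terms_fixed[vapply(terms_fixed, function(v)
    nlevels(droplevels(df[[v]])) >= 2L, logical(1))]
  separated <- any(vapply(terms_fixed, function(v) {
    tab <- tapply(df$y, df[[v]], mean)
    any(tab %in% c(0, 1))
  }, logical(1)))
  rhs <- paste(terms_fixed, collapse = " + ")
  if (!separated) {
    fml <- as.formula(paste("y ~", rhs, "+ (1 | group)"))
    fit <- suppressWarnings(suppressMessages(
      lme4::glmer(fml, data = df, family = "binomial")))
    an <- as.data.frame(suppressWarnings(car::Anova(fit, type = 2)))
    vc <- as.data.frame(lme4::VarCorr(fit))
    b <- lme4::fixef(fit)
    return(list(anova = data.frame(term = rownames(an),
                                   chisq = an$Chisq, df = an$Df,
                                   p = an[["Pr(>Chisq)"]]),
                coefficients = b, vcov = as.matrix(vcov(fit)),
                group_variance = vc$vcov[vc$grp == "group"],
                method = "glmm", model = fit))
  }
  message("complete separation detected; falling back to Firth-penalized ",
          "fixed-effects logistic regression")
  mm <- model.matrix(as.formula(paste("~", rhs)), df)
  ff <- .firthLogistic(mm, df$y)
  an <- .waldTermTable(ff$coef, ff$vcov, attr(mm, "assign"), terms_fixed)
  list(anova = an, coefficients = ff$coef, vcov = ff$vcov,
       group_variance = NA_real_, method = "firth", model = NULL)
}

#' Single-step (max-|z|) multiple-comparison adjustment
#'
#' Adjusts each contrast's two-sided P for the family by referring its
#' standardized statistic to the distribution of the maximum absolute
#' component of the joint normal implied by the contrast covariance,
#' evaluated by seeded Monte Carlo.
#'
#' @param estimates numeric vector of contrast estimates.
#' @param covariance their covariance matrix (positive semi-definite).
#' @param n_draws Monte-Carlo sample size (default 1e5).
#' @param seed integer seed for the draws.
#' @return data.frame with `estimate`, `se`, `z`, `p_unadjusted`,
#'   `p_adjusted` and the Monte-Carlo standard error `mc_se`.
#' @export
singleStepAdjust <- function(estimates, covariance, n_draws = 1e5,
                             seed = 1L) {
  k <- length(estimates)
  covariance <- as.matrix(covariance)
  stopifnot(nrow(covariance) == k, ncol(covariance) == k)
  ev <- eigen(covariance, symmetric = TRUE)
  if (any(ev$values < -1e-8 * max(abs(ev$values), 1)))
    stop("covariance matrix is not positive semi-definite", call. = FALSE)
  se <- sqrt(diag(covariance))
  z <- estimates / se
  p_un <- 2 * pnorm(-abs(z))
  if (k == 1L)
    return(data.frame(estimate = estimates, se = se, z = z,
                      p_unadjusted = p_un, p_adjusted = p_un, mc_se = 0))
  R <- covariance / tcrossprod(se)
  evR <- eigen(R, symmetric = TRUE)
  L <- evR$vectors %*% diag(sqrt(pmax(evR$values, 0)), k)
  set.seed(as.integer(seed))
  Z <- matrix(rnorm(n_draws * k), n_draws, k) %*% t(L)
  maxabs <- do.call(pmax, as.data.frame(abs(Z)))
  p_adj <- vapply(abs(z), function(zz) mean(maxabs >= zz), numeric(1))
  mc_se <- sqrt(p_adj * (1 - p_adj) / n_draws)
  p_adj <- pmax(p_adj, p_un)   # adjusted P can never undercut unadjusted
  data.frame(estimate = estimates, se = se, z = z, p_unadjusted = p_un,
             p_adjusted = p_adj, mc_se = mc_se)
}

#' All pairwise level comparisons of one occurrence-model factor
#'
#' Builds every pairwise difference between the levels of a fixed factor
#' from the fitted occurrence model and adjusts the family with
#' [singleStepAdjust()].
#'
#' @param fit result of [fitOccurrenceGLMM()].
#' @param term factor name (`"A.E"`, `"F"`, `"Trait"`, `"G"`).
#' @param n_draws,seed passed to [singleStepAdjust()].
#' @return data.frame with one row per level pair.
#' @export
pairwiseOccurrence <- function(fit, term, n_draws = 1e5, seed = 1L) {
  b <- fit$coefficients
  V <- fit$vcov
  idx <- grep(paste0("^", term), names(b))
  if (!length(idx)) stop("term not found in the fitted model", call. = FALSE)
  levs <- c("(ref)", sub(paste0("^", term), "", names(b)[idx]))
  k <- length(levs)
  Cm <- NULL; labels <- character()
  for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
    cv <- numeric(length(b))
    if (i > 1L) cv[idx[i - 1L]] <- -1
    cv[idx[j - 1L]] <- 1
    Cm <- rbind(Cm, cv)
    labels <- c(labels, paste(levs[j], "-", levs[i]))
  }
  est <- drop(Cm %*% b)
  cv <- Cm %*% V %*% t(Cm)
  out <- singleStepAdjust(est, cv, n_draws = n_draws, seed = seed)
  cbind(data.frame(comparison = labels), out)
}

#' Regress occurrence frequency on a genotype-level predictor
#'
#' The occurrence frequency is arcsine-square-root transformed; transposon
#' counts are log transformed; climate and methylation predictors enter
#' untransformed. The Pearson correlation coefficient and its two-sided P
#' are extracted from the simple linear regression.
#'
#' @param freqs data.frame with `genotype` and `frequency` (in `[0, 1]`).
#' @param metadata genotype metadata table (see [simulateMetadata()] /
#'   [readMetadata()]).
#' @param predictor metadata column name (e.g. `"Bio1"`, `"mCG"`,
#'   `"te_Gypsy"`).
#' @param transform `"identity"` or `"log"`; default chosen by predictor
#'   type (log for `te_*` counts).
#' @return One-row data.frame: `predictor`, `transform`, `r`, `p`, `n`.
#' @export
frequencyRegression <- function(freqs, metadata, predictor,
                                transform = NULL) {
  transform <- transform %||%
    (if (grepl("^te_", predictor)) "log" else "identity")
  assertChoice(transform, c("identity", "log"), "transform")
  m <- merge(freqs, metadata, by = "genotype")
  x <- m[[predictor]]
  if (transform == "log") x <- log(x)
  y <- asin(sqrt(pmin(pmax(m$frequency, 0), 1)))
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L)
    stop("fewer than 3 genotypes with both values", call. = FALSE)
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in predictor or transformed frequency; r undefined",
         call. = FALSE)
  ct <- cor.test(x, y)
  data.frame(predictor = predictor, transform = transform,
             r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Regress occurrence frequency on every available predictor
#'
#' One regression per climate variable, methylation context and TE
#' superfamily (no cross-predictor adjustment, matching per-predictor
#' reporting; a BH column is appended for reference). Predictors with zero
#' variance across genotypes are skipped with a warning.
#'
#' @inheritParams frequencyRegression
#' @return data.frame of [frequencyRegression()] rows plus `p_bh`.
#' @export
frequencyRegressionAll <- function(freqs, metadata) {
  preds <- setdiff(names(metadata), "genotype")
  preds <- preds[vapply(metadata[preds], is.numeric, logical(1))]
  rows <- lapply(preds, function(p) {
    tryCatch(frequencyRegression(freqs, metadata, p),
             error = function(e) {
               warning("skipping predictor ", p, ": ", conditionMessage(e),
                       call. = FALSE)
               NULL
             })
  })
  out <- do.call(rbind, rows)
  if (!is.null(out)) out$p_bh <- p.adjust(out$p, method = "BH")
  out
}

## wide matrices of estimates and P values: key x generation
.effectWide <- function(effects, value, test = NULL) {
  e <- effects[!is.na(effects$estimate), , drop = FALSE]
  if (!is.null(test)) e <- e[e$test %in% test, , drop = FALSE]
  key <- paste(e$genotype, e$treatment, e$phenotype, sep = "\r")
  gens <- intersect(c("Anc", OFFSPRING_GENERATIONS), unique(e$generation))
  m <- matrix(NA_real_, length(unique(key)), length(gens),
              dimnames = list(unique(key), gens))
  m[cbind(match(key, rownames(m)), match(e$generation, gens))] <- e[[value]]
  m
}

#' Pairwise reproducibility of effect sizes
#'
#' Pearson correlations of matched effect sizes between offspring
#' generations (or between the ancestral response and each offspring
#' generation, or between two tests), optionally restricted to pairs
#' significant in either member (`"significant"`) or to the complement
#' (`"nonsignificant"`).
#'
#' @param effects an `effect_sizes` table (may combine tests).
#' @param pairing `"generations"`, `"ancestral"` or `"tests"`.
#' @param subset `"all"`, `"significant"` or `"nonsignificant"`.
#' @param alpha significance cutoff defining the subsets.
#' @param test,test2 test labels used for `"generations"` (one test) and
#'   `"tests"` (the two tests to match).
#' @return data.frame with one row per pair: `pair`, `subset`, `r`, `p`,
#'   `n_points` (`r` is NA when fewer than 3 points remain).
#' @export
effectSizeCorrelations <- function(effects,
                                   pairing = c("generations", "ancestral",
                                               "tests"),
                                   subset = c("all", "significant",
                                              "nonsignificant"),
                                   alpha = 0.05, test = "I", test2 = "II") {
  pairing <- match.arg(pairing)
  subset <- match.arg(subset)
  cell <- function(x, y, px, py, label) {
    ok <- is.finite(x) & is.finite(y)
    if (subset == "significant") ok <- ok & (px < alpha | py < alpha)
    if (subset == "nonsignificant") ok <- ok & !(px < alpha | py < alpha)
    n <- sum(ok, na.rm = TRUE)
    if (n < 3L)
      return(data.frame(pair = label, subset = subset, r = NA_real_,
                        p = NA_real_, n_points = n))
    ct <- cor.test(x[ok], y[ok])
    data.frame(pair = label, subset = subset, r = unname(ct$estimate),
               p = ct$p.value, n_points = n)
  }
  if (pairing == "tests") {
    keyfun <- function(e) paste(e$genotype, e$treatment, e$phenotype,
                                e$generation, sep = "\r")
    e1 <- effects[effects$test == test & !is.na(effects$estimate), ]
    e2 <- effects[effects$test == test2 & !is.na(effects$estimate), ]
    m <- match(keyfun(e1), keyfun(e2))
    ok <- !is.na(m)
    return(cell(e1$estimate[ok], e2$estimate[m[ok]], e1$p[ok],
                e2$p[m[ok]], paste(test, "vs", test2)))
  }
  est <- .effectWide(effects, "estimate",
                     test = if (pairing == "ancestral")
                       c("ancestral", test) else test)
  pv <- .effectWide(effects, "p",
                    test = if (pairing == "ancestral")
                      c("ancestral", test) else test)
  gens <- colnames(est)
  pairs <- if (pairing == "ancestral") {
    if (!"Anc" %in% gens) stop("no ancestral effects present", call. = FALSE)
    lapply(setdiff(gens, "Anc"), function(g) c("Anc", g))
  } else {
    gens <- setdiff(gens, "Anc")
    if (length(gens) < 2L) stop("need at least two generations",
                                call. = FALSE)
    combn(gens, 2L, simplify = FALSE)
  }
  do.call(rbind, lapply(pairs, function(pr)
    cell(est[, pr[1]], est[, pr[2]], pv[, pr[1]], pv[, pr[2]],
         paste(pr[1], "vs", pr[2]))))
}

#' Effect-size reproducibility after scaling the experiment down
#'
#' Recomputes the generation-pair correlations using only one genotype (or
#' only one treatment) at a time and reports, per restricted subset, the
#' share of defined generation pairs whose correlation is significant at
#' `alpha`. Degenerate subsets (fewer than 3 matched pairs) are excluded
#' from the share.
#'
#' @param effects an `effect_sizes` table for one test.
#' @param mode `"one_genotype"` or `"one_treatment"`.
#' @param alpha significance level for the pair correlations.
#' @param test test label.
#' @return data.frame with one row per restricted level: `level`,
#'   `n_pairs_defined`, `share_significant`.
#' @export
scaleDownAnalysis <- function(effects, mode = c("one_genotype",
                                                "one_treatment"),
                              alpha = 0.05, test = "I") {
  mode <- match.arg(mode)
  col <- if (mode == "one_genotype") "genotype" else "treatment"
  levels <- unique(effects[[col]])
  rows <- lapply(levels, function(lv) {
    sub <- effects[effects[[col]] == lv, , drop = FALSE]
    cc <- tryCatch(effectSizeCorrelations(sub, "generations", "all",
                                          alpha = alpha, test = test),
                   error = function(e) NULL)
    if (is.null(cc)) return(data.frame(level = lv, n_pairs_defined = 0L,
                                       share_significant = NA_real_))
    def <- !is.na(cc$r)
    data.frame(level = lv, n_pairs_defined = sum(def),
               share_significant = if (any(def)) mean(cc$p[def] < alpha)
                                   else NA_real_)
  })
  do.call(rbind, rows)
}
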