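## Map the phenotype-table schema onto the model variables used throughout:
## G = genotype, E / A.E = ancestral environment, F = offspring generation,
## O.Layer = the plant's own layer, A.Layer / A.Row = the ancestral position
## of its line, Line = line identity (single-seed descent).
.modelFrame <- function(data, response) {
  mf <- data.frame(
    y = data[[response]],
    G = factor(data$genotype),
    E = factor(data$ancestral_env),
    A.E = factor(data$ancestral_env),
    O.Layer = factor(data$layer),
    A.Layer = factor(data$anc_layer),
    A.Row = factor(data$anc_row),
    Line = factor(data$line_id))
  if ("generation" %in% names(data))
    mf$F <- factor(data$generation,
                   levels = intersect(c("Anc", OFFSPRING_GENERATIONS),
                                      unique(data$generation)))
  mf[!is.na(mf$y), , drop = FALSE]
}

## Gaussian mixed fit with REML random intercepts; random terms whose
## variance estimate collapses to zero are dropped and reported as 0.
## Falls back to OLS when no random term survives (then identical to the
## normal-equations solution).
.fitMixed <- function(mf, fixed_rhs, random_terms = character(),
                      force_lm = FALSE) {
  keep <- if (force_lm) character() else random_terms
  repeat {
    if (!length(keep)) {
      fit <- lm(as.formula(paste("y ~", fixed_rhs)), data = mf)
      b <- coef(fit)
      est <- b[!is.na(b)]
      V <- vcov(fit)
      vc <- setNames(rep(0, length(random_terms)), random_terms)
      return(list(fit = fit, is_lm = TRUE, coef = est, vcov = V,
                  varcomp = c(vc, residual = summary(fit)$sigma^2),
                  dropped = random_terms, converged = TRUE))
    }
    fml <- as.formula(paste("y ~", fixed_rhs, "+",
                            paste(sprintf("(1 | %s)", keep),
                                  collapse = " + ")))
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(fml, data = mf, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore"))))
    vc_df <- as.data.frame(lme4::VarCorr(fit))
    vars <- setNames(vc_df$vcov[vc_df$grp != "Residual"],
                     vc_df$grp[vc_df$grp != "Residual"])
    zero <- names(vars)[vars < 1e-8]
    if (!length(zero)) {
      b <- lme4::fixef(fit)
      vc <- setNames(rep(0, length(random_terms)), random_terms)
      vc[names(vars)] <- vars
      return(list(fit = fit, is_lm = FALSE, coef = b,
                  vcov = as.matrix(vcov(fit)),
                  varcomp = c(vc,
                              residual = vc_df$vcov[vc_df$grp == "Residual"]),
                  dropped = setdiff(random_terms, keep),
                  converged = length(fit@optinfo$conv$lme4$messages %||%
                                       character()) == 0))
    }
    keep <- setdiff(keep, zero)
  }
}

#' Fit a phenotype linear mixed model
#'
#' Gaussian linear mixed model (REML, random intercepts) of one phenotype on
#' the design factors, with Type-II Wald chi-square tests per fixed term and
#' REML variance components. A random term whose variance estimate hits zero
#' is dropped from the fit and reported as exactly 0; with no random term
#' left the fit is ordinary least squares.
#'
#' @param data a phenotype table (see [simulatePhenotypes()] /
#'   [readPhenotypes()]).
#' @param response phenotype column name.
#' @param fixed character vector of fixed terms among `O.Layer`, `G`, `E`,
#'   `A.E`, `F` and `:` interactions of them.
#' @param random character vector among `A.Layer`, `A.Row`, `Line`.
#' @return An object of class `phenoFit`: list with `coefficients`
#'   (estimate, se), `vcov`, `varcomp` (named, includes `residual`),
#'   `anova` (Type-II tests), `converged`, `dropped_random`.
#' @export
fitPhenoLMM <- function(data, response, fixed = c("G", "E", "G:E"),
                        random = c("A.Layer", "A.Row")) {
  mf <- .modelFrame(data, response)
  if (!nrow(mf)) stop("no data left after filtering", call. = FALSE)
  ## terms with a single observed level cannot be estimated; drop them
  mains <- unique(unlist(strsplit(fixed, ":", fixed = TRUE)))
  degenerate <- mains[vapply(mains, function(v) nlevels(droplevels(mf[[v]])),
                             1L) < 2L]
  if (length(degenerate))
    fixed <- fixed[!vapply(strsplit(fixed, ":", fixed = TRUE),
                           function(p) any(p %in% degenerate), logical(1))]
  random <- random[vapply(random, function(v)
    nlevels(droplevels(mf[[v]])), 1L) >= 2L]
  if (!length(fixed)) fixed <- "1"
  constant <- var(mf$y) == 0
  res <- .fitMixed(mf, paste(fixed, collapse = " + "), random,
                   force_lm = constant)
  an <- tryCatch(
    suppressWarnings(car::Anova(res$fit, type = 2,
                                test.statistic = if (res$is_lm) "F"
                                                 else "Chisq")),
    error = function(e) NULL)
  co <- data.frame(term = names(res$coef), estimate = unname(res$coef),
                   se = sqrt(diag(res$vcov))[names(res$coef)])
  structure(list(coefficients = co, vcov = res$vcov, varcomp = res$varcomp,
                 anova = if (is.null(an)) NULL else as.data.frame(an),
                 converged = res$converged, dropped_random = res$dropped,
                 is_lm = res$is_lm, model = res$fit,
                 formula_fixed = paste(fixed, collapse = " + ")),
            class = "phenoFit")
}

#' @export
print.phenoFit <- function(x, ...) {
  cat("phenoFit: y ~", x$formula_fixed, "\n")
  cat("  variance components:",
      paste(names(x$varcomp), signif(x$varcomp, 3), sep = "=",
            collapse = ", "), "\n")
  if (length(x$dropped_random))
    cat("  dropped (zero-variance):",
        paste(x$dropped_random, collapse = ", "), "\n")
  invisible(x)
}

## reference environment for a treatment: JA is contrasted against its own
## solvent control, everything else against the global control
.referenceEnv <- function(treatment, control_label = "control") {
  if (identical(treatment, "JA")) "JA_control" else control_label
}

#' Estimate genotype-specific induced effect sizes
#'
#' For one phenotype, treatment and generation, subsets the data to the
#' treatment arm plus its reference arm (the control, or the solvent control
#' for JA), standardizes the phenotype to unit SD within that (test,
#' generation) subset, fits the mixed model (`~ G + E + G:E` with ancestral
#' layer/row random intercepts; offspring fits add the plant's own layer as
#' a fixed term), and extracts per genotype the treatment-vs-reference
#' contrast (treatment main effect plus the genotype's interaction
#' deviation) with its SE and two-sided Wald P.
#'
#' @param data phenotype table.
#' @param phenotype phenotype column name.
#' @param treatment treatment label.
#' @param generation `"Anc"` or one of `F1..F4`.
#' @param test which offspring test to use (`"I"` or `"II"`); ignored for
#'   `"Anc"`.
#' @param control reference environment label; defaults to the JA rule above.
#' @param min_replicates genotypes with fewer surviving replicates than this
#'   in either arm are flagged inestimable rather than failing the fit.
#' @return data.frame of class `effect_sizes` with one row per genotype:
#'   standardized `estimate`, `se`, two-sided `p`, raw-scale `estimate_raw`,
#'   `se_raw`, and an `inestimable` flag.
#' @export
estimateEffectSizes <- function(data, phenotype, treatment, generation,
                                test = "I", control = NULL,
                                min_replicates = 2L) {
  control <- control %||% .referenceEnv(treatment)
  if (generation == "Anc") {
    sub <- data[data$generation == "Anc", , drop = FALSE]
    test_label <- "ancestral"
  } else {
    sub <- data[data$generation == generation & data$test == test, ,
                drop = FALSE]
    test_label <- test
  }
  sub <- sub[sub$ancestral_env %in% c(control, treatment), , drop = FALSE]
  sub <- sub[!is.na(sub[[phenotype]]), , drop = FALSE]
  if (!nrow(sub)) stop("no observations for this contrast", call. = FALSE)

  genotypes <- sort(unique(data$genotype))
  tab <- table(sub$genotype, sub$ancestral_env == treatment)
  ok <- rownames(tab)[tab[, "TRUE"] >= min_replicates &
                        tab[, "FALSE"] >= min_replicates]
  bad <- setdiff(genotypes, ok)
  if (length(bad))
    warning("genotype(s) flagged inestimable (too few replicates in an arm): ",
            paste(bad, collapse = ", "), call. = FALSE)
  sub <- sub[sub$genotype %in% ok, , drop = FALSE]

  z <- zStandardize(sub[[phenotype]])
  sdy <- attr(z, "scale")
  sub$.z <- as.numeric(z)
  mf <- .modelFrame(sub, ".z")
  mf$E <- factor(as.character(mf$E), levels = c(control, treatment))
  mf$G <- droplevels(mf$G)
  fixed <- if (generation == "Anc") "G + E + G:E" else {
    if (nlevels(droplevels(mf$O.Layer)) >= 2L) "O.Layer + G + E + G:E"
    else "G + E + G:E"
  }
  random <- c("A.Layer", "A.Row")
  random <- random[vapply(random, function(v)
    nlevels(droplevels(mf[[v]])), 1L) >= 2L]
  res <- .fitMixed(mf, fixed, random, force_lm = var(mf$y) == 0)
  b <- res$coef
  V <- res$vcov

  trt_coef <- paste0("E", treatment)
  out <- lapply(genotypes, function(g) {
    row <- data.frame(genotype = g, treatment = treatment,
                      phenotype = phenotype, generation = generation,
                      test = test_label, estimate = NA_real_, se = NA_real_,
                      p = NA_real_, estimate_raw = NA_real_,
                      se_raw = NA_real_, inestimable = TRUE)
    if (!g %in% ok || !trt_coef %in% names(b)) return(row)
    idx <- trt_coef
    if (g != levels(mf$G)[1]) {
      int <- paste0("G", g, ":", trt_coef)
      if (!int %in% names(b)) return(row)
      idx <- c(idx, int)
    }
    cvec <- setNames(numeric(length(b)), names(b))
    cvec[idx] <- 1
    est <- sum(b[idx])
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    if (var(mf$y) == 0) { est <- 0; se <- 0 }
    p <- if (is.finite(se) && se > 0) 2 * pnorm(-abs(est / se)) else 1
    row$estimate <- est; row$se <- se; row$p <- p
    row$estimate_raw <- est * sdy; row$se_raw <- se * sdy
    row$inestimable <- FALSE
    row
  })
  out <- do.call(rbind, out)
  class(out) <- c("effect_sizes", "data.frame")
  out
}

#' Estimate effect sizes over a grid of contrasts
#'
#' Convenience wrapper looping [estimateEffectSizes()] over phenotypes,
#' treatments and generations; fit failures for a single contrast yield NA
#' rows rather than aborting the sweep.
#'
#' @inheritParams estimateEffectSizes
#' @param phenotypes,treatments,generations vectors defining the sweep;
#'   defaults cover everything present in the data.
#' @return Combined `effect_sizes` data.frame.
#' @export
estimateAllEffects <- function(data, phenotypes = NULL, treatments = NULL,
                               generations = NULL, test = "I") {
  phenotypes <- phenotypes %||% intersect(PHENOTYPES, names(data))
  envs <- unique(data$ancestral_env)
  treatments <- treatments %||%
    setdiff(envs, c("control", if ("JA" %in% envs) "JA_control"))
  generations <- generations %||%
    intersect(OFFSPRING_GENERATIONS, unique(data$generation))
  grid <- expand.grid(phenotype = phenotypes, treatment = treatments,
                      generation = generations, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    tryCatch(suppressWarnings(
      estimateEffectSizes(data, grid$phenotype[i], grid$treatment[i],
                          grid$generation[i], test = test)),
      error = function(e) NULL)
  })
  out <- do.call(rbind, res)
  class(out) <- c("effect_sizes", "data.frame")
  out
}

#' Convert effect sizes to qualitative occurrence records
#'
#' A change "occurs" when its two-sided P is strictly below `alpha`; a
#' marginal occurrence uses `alpha_marginal`. All phenotypes estimated from
#' the same six-replicate group (genotype x treatment x generation) share a
#' `group_id`.
#'
#' @param effects an `effect_sizes` table.
#' @param alpha,alpha_marginal strict significance cutoffs,
#'   `alpha < alpha_marginal`.
#' @return data.frame with `occurred` and `marginal` in \{0, 1\} plus the key
#'   columns and `group_id`; inestimable effects are excluded.
#' @export
effectsToOccurrence <- function(effects, alpha = 0.05, alpha_marginal = 0.1) {
  if (!(alpha < alpha_marginal))
    stop("alpha must be < alpha_marginal", call. = FALSE)
  keep <- !is.na(effects$p)
  e <- effects[keep, , drop = FALSE]
  data.frame(genotype = e$genotype, treatment = e$treatment,
             generation = e$generation, phenotype = e$phenotype,
             test = e$test,
             occurred = as.integer(e$p < alpha),
             marginal = as.integer(e$p < alpha_marginal),
             group_id = paste(e$genotype, e$treatment, e$generation,
                              sep = "|"))
}

#' Partition phenotypic variance with a full random-effect model
#'
#' Re-declares the design factors as random intercepts (the plant's own
#' layer stays fixed in offspring fits) and reports the proportion of total
#' variance attributed to genotype, environment, their interaction, the
#' ancestral layer and row, and the residual. Proportions sum to one.
#'
#' @param data phenotype table, restricted to the generations of interest.
#' @param response phenotype column.
#' @param model `"ancestral"` (G, E) or `"offspring"` (G, A.E, plus a fixed
#'   own-layer term).
#' @return Named numeric vector of variance proportions.
#' @export
variancePartition <- function(data, response,
                              model = c("ancestral", "offspring")) {
  model <- match.arg(model)
  mf <- .modelFrame(data, response)
  mf$GxE <- interaction(mf$G, mf$E, drop = TRUE)
  rand <- c(G = "G", E = if (model == "ancestral") "E" else "A.E",
            `G:E` = "GxE", A.Layer = "A.Layer", A.Row = "A.Row")
  rand <- rand[vapply(rand, function(v) nlevels(droplevels(mf[[v]])),
                      1L) >= 2L]
  fixed <- if (model == "offspring" &&
               nlevels(droplevels(mf$O.Layer)) >= 2L) "O.Layer" else "1"
  fml <- as.formula(paste("y ~", fixed, "+",
                          paste(sprintf("(1 | %s)", rand), collapse = " + ")))
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(fml, data = mf, REML = TRUE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore"))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  v <- setNames(vc$vcov, vc$grp)
  out <- setNames(numeric(length(rand) + 1L), c(names(rand), "residual"))
  for (i in seq_along(rand)) out[names(rand)[i]] <- v[[rand[[i]]]] %||% 0
  out["residual"] <- v[["Residual"]]
  out / sum(out)
}
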