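#' Counts per million
#'
#' Scales each sample's counts by its library size times one million, so
#' every column of the result sums to 1e6.
#'
#' @param x a [TransgenCounts-class] object or a counts matrix.
#' @return Numeric matrix of CPM values.
#' @export
countsPerMillion <- function(x) {
  m <- if (is(x, "TransgenCounts")) countMatrix(x) else as.matrix(x)
  tot <- colSums(m)
  if (any(tot == 0))
    stop("sample(s) with zero total counts: ",
         paste(colnames(m)[tot == 0], collapse = ", "), call. = FALSE)
  t(t(m) / tot) * 1e6
}

#' Expression filter: genes with sum CPM above one
#'
#' A gene is retained for a genotype's treatment-vs-control analyses when
#' the sum of its CPM values over all of that genotype's treatment and
#' control samples is strictly greater than one.
#'
#' @param x a [TransgenCounts-class] object.
#' @param genotype,treatment the contrast cell.
#' @param control_label control environment label.
#' @param threshold strict lower bound on the summed CPM (default 1).
#' @return Character vector of retained gene ids.
#' @export
filterGenes <- function(x, genotype, treatment, control_label = "control",
                        threshold = 1) {
  ss <- sampleSheet(x)
  sel <- ss$genotype == genotype & ss$treatment %in% c(treatment,
                                                       control_label)
  if (!any(sel)) stop("no samples for this genotype/treatment",
                      call. = FALSE)
  cpm <- countsPerMillion(countMatrix(x)[, sel, drop = FALSE])
  rownames(cpm)[rowSums(cpm) > threshold]
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling factor: the median, over genes expressed in every
#' sample, of the sample count divided by the gene's geometric mean across
#' samples; factors are normalized to geometric mean 1. With
#' `fallback = TRUE`, when no gene is expressed everywhere the geometric
#' means are computed over positive counts only (pseudo-reference).
#'
#' @param counts integer matrix, genes x samples.
#' @param fallback allow the positive-count pseudo-reference when no gene
#'   is nonzero in all samples.
#' @return Named numeric vector of size factors.
#' @export
medianOfRatios <- function(counts, fallback = FALSE) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 1L)
    return(setNames(1, colnames(counts)))
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    if (!fallback)
      stop("no gene with nonzero counts in every sample; consider the ",
           "pseudo-reference fallback (fallback = TRUE)", call. = FALSE)
    some <- rowSums(counts > 0) > 0
    sub <- pmax(counts[some, , drop = FALSE], 1)
    gm <- exp(rowSums(log(sub)) / ncol(counts))
    f <- apply(sub / gm, 2L, median)
  } else {
    sub <- counts[all_pos, , drop = FALSE]
    gm <- exp(rowMeans(log(sub)))
    f <- apply(sub / gm, 2L, median)
  }
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

## Vectorized NB IRLS for the two-group model log mu = b0 + b1*group + log sf.
## One row per gene; returns b1 (natural log fold change) and its Wald SE.
.nbTwoGroupFit <- function(y, group, sf, alpha, maxit = 25L, tol = 1e-8) {
  G <- nrow(y); n <- ncol(y)
  x <- as.numeric(group)                    # 0 = control, 1 = treatment
  off <- matrix(log(sf), G, n, byrow = TRUE)
  ybar0 <- rowMeans((y / matrix(sf, G, n, byrow = TRUE))[, x == 0,
                                                         drop = FALSE])
  ybar1 <- rowMeans((y / matrix(sf, G, n, byrow = TRUE))[, x == 1,
                                                         drop = FALSE])
  b0 <- log(ybar0 + 0.125)
  b1 <- log(ybar1 + 0.125) - b0
  xm <- matrix(x, G, n, byrow = TRUE)
  for (it in seq_len(maxit)) {
    eta <- b0 + b1 * xm + off
    mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
    w <- mu / (1 + alpha * mu)
    z <- (eta - off) + (y - mu) / mu
    A11 <- rowSums(w); A12 <- rowSums(w * xm); A22 <- rowSums(w * xm^2)
    c1 <- rowSums(w * z); c2 <- rowSums(w * z * xm)
    det <- A11 * A22 - A12^2
    nb0 <- (A22 * c1 - A12 * c2) / det
    nb1 <- (A11 * c2 - A12 * c1) / det
    nb0 <- pmin(pmax(nb0, -50), 50); nb1 <- pmin(pmax(nb1, -50), 50)
    delta <- pmax(abs(nb0 - b0), abs(nb1 - b1))
    b0 <- nb0; b1 <- nb1
    if (all(is.na(delta) | delta < tol)) break
  }
  eta <- b0 + b1 * xm + off
  mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
  w <- mu / (1 + alpha * mu)
  A11 <- rowSums(w); A12 <- rowSums(w * xm); A22 <- rowSums(w * xm^2)
  det <- A11 * A22 - A12^2
  se1 <- sqrt(A11 / det)
  list(beta = b1, se = se1)
}

## method-of-moments dispersions shrunk toward a 1/mean trend
.dispersionEstimates <- function(norm, group, weight = 0.5) {
  x <- as.numeric(group)
  v_pool <- m_all <- numeric(nrow(norm))
  ns <- table(factor(x, levels = c(0, 1)))
  ss <- 0
  for (g in c(0, 1)) {
    sub <- norm[, x == g, drop = FALSE]
    mg <- rowMeans(sub)
    ss <- ss + rowSums((sub - mg)^2)
  }
  s2 <- ss / (ncol(norm) - 2L)
  m <- rowMeans(norm)
  raw <- pmax(0, (s2 - m) / m^2)
  use <- raw > 0 & m > 1
  if (sum(use) >= 10) {
    fit <- lm(raw[use] ~ I(1 / m[use]))
    a0 <- max(coef(fit)[1], 1e-4); a1 <- max(coef(fit)[2], 0)
  } else {
    a0 <- max(mean(raw[m > 1]), 1e-4); a1 <- 0
  }
  trend <- a0 + a1 / pmax(m, 1e-8)
  pmax((1 - weight) * raw + weight * trend, 1e-8)
}

#' Negative-binomial Wald test for one treatment-vs-control contrast
#'
#' For one genotype, treatment and offspring generation, fits per gene a
#' negative-binomial GLM with log link on the treatment indicator with the
#' log size factor as offset. Size factors are median-of-ratios over the
#' contrast's samples; per-gene dispersions are method-of-moments estimates
#' shrunk toward a smooth mean-dispersion trend; the treatment coefficient
#' is tested with a two-sided Wald test and BH-adjusted within the
#' (genotype, treatment, generation) family. A gene is a DEG when
#' `|log2fc| > lfc_cutoff` (strict) and `padj < padj_cutoff`.
#'
#' @param x a [TransgenCounts-class] object.
#' @param genotype,treatment,generation the contrast.
#' @param genes genes to test; defaults to [filterGenes()] output.
#' @param control_label control environment label.
#' @param control_pairing `"matched"` uses control samples of the same
#'   generation; `"pooled"` uses all of the genotype's control samples
#'   (covers designs whose control arm is shared across generations).
#' @param shrink_weight weight of the trend in the dispersion shrinkage.
#' @param lfc_cutoff,padj_cutoff DEG thresholds (strict |log2FC| bound).
#' @param size_factor_fallback passed to [medianOfRatios()].
#' @return data.frame with one row per tested gene: `gene`, `genotype`,
#'   `treatment`, `generation`, `log2fc`, `se`, `wald_p`, `padj`, `is_deg`.
#' @export
nbWaldTest <- function(x, genotype, treatment, generation, genes = NULL,
                       control_label = "control",
                       control_pairing = c("matched", "pooled"),
                       shrink_weight = 0.5, lfc_cutoff = 1.5,
                       padj_cutoff = 0.05, size_factor_fallback = TRUE) {
  control_pairing <- match.arg(control_pairing)
  ss <- sampleSheet(x)
  trt <- ss$genotype == genotype & ss$treatment == treatment &
    ss$generation == generation
  ctl <- ss$genotype == genotype & ss$treatment == control_label
  if (control_pairing == "matched") {
    ctl_gen <- ctl & ss$generation == generation
    ## a control arm recorded as "shared" serves every generation
    if (!any(ctl_gen)) ctl_gen <- ctl & ss$generation == "shared"
    ctl <- ctl_gen
  }
  if (sum(trt) < 2L || sum(ctl) < 2L)
    stop("need >= 2 replicates in each arm", call. = FALSE)
  genes <- genes %||% filterGenes(x, genotype, treatment, control_label)
  sel <- trt | ctl
  y <- countMatrix(x)[genes, sel, drop = FALSE]
  group <- as.integer(trt[sel])
  sf <- medianOfRatios(y, fallback = size_factor_fallback)
  norm <- t(t(y) / sf)
  alpha <- .dispersionEstimates(norm, group, weight = shrink_weight)
  fit <- .nbTwoGroupFit(y, group, sf, alpha)
  log2fc <- fit$beta / log(2)
  se <- fit$se / log(2)
  wald_p <- 2 * pnorm(-abs(fit$beta / fit$se))
  bad <- !is.finite(log2fc) | !is.finite(se) | rowSums(y) == 0
  log2fc[bad] <- NA; se[bad] <- NA; wald_p[bad] <- NA
  padj <- rep(NA_real_, length(genes))
  padj[!bad] <- p.adjust(wald_p[!bad], method = "BH")
  is_deg <- as.integer(!is.na(padj) & abs(log2fc) > lfc_cutoff &
                         padj < padj_cutoff)
  data.frame(gene = genes, genotype = genotype, treatment = treatment,
             generation = generation, log2fc = log2fc, se = se,
             wald_p = wald_p, padj = padj, is_deg = is_deg,
             row.names = NULL)
}

#' Run the NB Wald test across all generations of one or more contrasts
#'
#' @inheritParams nbWaldTest
#' @param contrasts data.frame with `genotype`, `treatment` (default: all
#'   non-control cells in the sample sheet).
#' @param generations generations to test.
#' @param ... passed to [nbWaldTest()].
#' @return Combined DE table over all contrasts and generations.
#' @export
runDE <- function(x, contrasts = NULL, generations = OFFSPRING_GENERATIONS,
                  control_label = "control", ...) {
  contrasts <- contrasts %||% contrastSets(sampleSheet(x), control_label)
  out <- list()
  for (i in seq_len(nrow(contrasts))) {
    genes <- filterGenes(x, contrasts$genotype[i], contrasts$treatment[i],
                         control_label)
    for (gen in generations)
      out[[length(out) + 1L]] <-
        nbWaldTest(x, contrasts$genotype[i], contrasts$treatment[i], gen,
                   genes = genes, control_label = control_label, ...)
  }
  do.call(rbind, out)
}

#' Call heritable DEGs
#'
#' A gene is a heritable DEG for a genotype x treatment when it is a DEG in
#' at least `min_generations` offspring generations; the per-gene count of
#' DEG generations is retained for the 2/3/4-generation breakdown.
#'
#' @param de combined DE table from [runDE()].
#' @param min_generations minimum DEG generations (default 2).
#' @return data.frame with `genotype`, `treatment`, `gene`,
#'   `n_deg_generations`, `heritable`.
#' @export
callHeritableDEGs <- function(de, min_generations = 2L) {
  key <- paste(de$genotype, de$treatment, de$gene, sep = "\r")
  n <- tapply(de$is_deg, key, sum, na.rm = TRUE)
  n <- n[n > 0]
  parts <- do.call(rbind, strsplit(names(n), "\r", fixed = TRUE))
  out <- data.frame(genotype = parts[, 1], treatment = parts[, 2],
                    gene = parts[, 3], n_deg_generations = as.integer(n),
                    heritable = as.integer(n) >= min_generations,
                    row.names = NULL)
  out[order(out$genotype, out$treatment, out$gene), ]
}

#' Linear model of DEG counts on design factors
#'
#' Tests whether the number of DEGs varies between genotypes, treatments
#' and generations with Type-II two-sided F statistics.
#'
#' @param de combined DE table from [runDE()].
#' @return list with `counts` (one row per genotype x treatment x
#'   generation) and `anova` (term F table).
#' @export
degCountModel <- function(de) {
  agg <- aggregate(is_deg ~ genotype + treatment + generation, de, sum,
                   na.rm = TRUE)
  names(agg)[4] <- "n_degs"
  terms_fixed <- c("genotype", "treatment", "generation")
  terms_fixed <- terms_fixed[vapply(terms_fixed, function(v)
    length(unique(agg[[v]])) >= 2L, logical(1))]
  fml <- as.formula(paste("n_degs ~", paste(terms_fixed, collapse = " + ")))
  fit <- lm(fml, data = agg)
  an <- tryCatch(as.data.frame(car::Anova(fit, type = 2)),
                 error = function(e) NULL)   # e.g. zero residual variance
  tab <- if (is.null(an))
    data.frame(term = terms_fixed, sum_sq = NA_real_, df = NA_integer_,
               f = NA_real_, p = NA_real_)
  else data.frame(term = rownames(an), sum_sq = an[["Sum Sq"]],
                  df = an$Df, f = an[["F value"]], p = an[["Pr(>F)"]])
  list(counts = agg, anova = tab, model = fit)
}

#' Venn-style overlap counts of gene (or term) sets
#'
#' Counts the members of every intersection region of the given sets; the
#' regions partition the union.
#'
#' @param sets named list of character vectors (>= 2 sets).
#' @return data.frame with one row per non-empty region membership pattern:
#'   one logical column per set plus `count`.
#' @export
overlapSummary <- function(sets) {
  if (length(sets) < 2L) stop("need at least 2 sets", call. = FALSE)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  universe <- unique(unlist(sets))
  memb <- vapply(sets, function(s) universe %in% s,
                 logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, nrow = 1L,
                                             dimnames = list(NULL,
                                                             names(sets)))
  pat <- apply(memb, 1L, function(r) paste(as.integer(r), collapse = ""))
  pats <- sort(unique(pat))
  out <- do.call(rbind, lapply(pats, function(p) {
    flags <- strsplit(p, "", fixed = TRUE)[[1]] == "1"
    df <- as.data.frame(as.list(setNames(flags, names(sets))))
    df$count <- sum(pat == p)
    df
  }))
  rownames(out) <- NULL
  out
}

#' Cross-reference heritable DEGs against a curated gene list
#'
#' For each curated gene: whether it was measured at all, whether it was a
#' DEG in any (genotype, treatment, generation), whether it is a heritable
#' DEG, and the hits.
#'
#' @param de combined DE table from [runDE()].
#' @param heritable table from [callHeritableDEGs()].
#' @param gene_list character vector of curated gene ids.
#' @return data.frame with one row per curated gene: `gene`, `measured`,
#'   `deg_anywhere`, `heritable`, `hits` (semicolon-separated
#'   genotype:treatment:generation labels).
#' @export
crossrefGeneList <- function(de, heritable, gene_list) {
  if (!length(gene_list))
    return(data.frame(gene = character(), measured = logical(),
                      deg_anywhere = logical(), heritable = logical(),
                      hits = character()))
  out <- lapply(gene_list, function(g) {
    rows <- de[de$gene == g & !is.na(de$is_deg) & de$is_deg == 1L, ,
               drop = FALSE]
    data.frame(gene = g, measured = g %in% de$gene,
               deg_anywhere = nrow(rows) > 0,
               heritable = g %in% heritable$gene[heritable$heritable],
               hits = paste(paste(rows$genotype, rows$treatment,
                                  rows$generation, sep = ":"),
                            collapse = ";"))
  })
  do.call(rbind, out)
}
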