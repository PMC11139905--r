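## strand-aware upstream extension, truncated at chromosome bounds
.extendUpstream <- function(genes, upstream = 2000L) {
  st <- GenomicRanges::start(genes)
  en <- GenomicRanges::end(genes)
  plus <- as.character(GenomicRanges::strand(genes)) != "-"
  new_st <- ifelse(plus, pmax(1L, st - upstream), st)
  sl <- GenomeInfoDb::seqlengths(genes)
  lim <- if (anyNA(sl)) rep(Inf, length(genes))
         else sl[as.character(GenomeInfoDb::seqnames(genes))]
  new_en <- ifelse(plus, en, pmin(lim, en + upstream))
  out <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(genes),
                                IRanges::IRanges(new_st, new_en),
                                strand = GenomicRanges::strand(genes),
                                seqlengths = sl)
  names(out) <- names(genes)
  out
}

#' Promoter-plus-gene-body regions
#'
#' Extends each gene body 2 kb upstream of its transcription start
#' (strand-aware), truncated at the chromosome bounds. Coordinates are
#' 1-based closed.
#'
#' @param annotation a [GenomeAnnotation-class] object (or a genes GRanges).
#' @param upstream upstream width in bases.
#' @param genes optional character vector restricting to a gene set.
#' @return GRanges of regions named by gene id.
#' @export
geneRegions <- function(annotation, upstream = 2000L, genes = NULL) {
  g <- if (is(annotation, "GenomeAnnotation")) annotGenes(annotation)
       else annotation
  if (!is.null(genes)) {
    miss <- setdiff(genes, names(g))
    if (length(miss))
      stop("unknown gene id(s): ", paste(head(miss), collapse = ", "),
           call. = FALSE)
    g <- g[genes]
  }
  .extendUpstream(g, upstream)
}

#' Count transposons overlapping gene regions
#'
#' A TE counts for a gene when its interval shares at least one base with
#' the gene's 2 kb-upstream-plus-body region (closed intervals); a TE
#' overlapping several regions contributes to each. The set total is the
#' sum over genes.
#'
#' @param regions GRanges from [geneRegions()].
#' @param annotation a [GenomeAnnotation-class] object.
#' @param superfamily TE superfamily label, or NULL for all TEs.
#' @return list with `per_gene` (named integer vector) and `total`.
#' @export
teOverlapCounts <- function(regions, annotation, superfamily = NULL) {
  tes <- transposons(annotation)
  if (!is.null(superfamily)) {
    vocab <- unique(S4Vectors::mcols(tes)$superfamily)
    if (!superfamily %in% vocab)
      stop("unknown superfamily '", superfamily, "'; known: ",
           paste(vocab, collapse = ", "), call. = FALSE)
    tes <- tes[S4Vectors::mcols(tes)$superfamily == superfamily]
  }
  cnt <- GenomicRanges::countOverlaps(regions, tes, ignore.strand = TRUE)
  list(per_gene = setNames(as.integer(cnt), names(regions)),
       total = sum(cnt))
}

#' Resampling test for transposon enrichment near a gene set
#'
#' Compares the summed TE overlap count of the gene set's
#' 2 kb-upstream-plus-body regions against a null distribution obtained by
#' repeatedly sampling equally many genes (without replacement) from the
#' background universe. The empirical P is the proportion of null samples
#' strictly greater than the observed total (ties favour enrichment);
#' `estimator = "add_one"` uses (k+1)/(N+1) instead, which cannot return 0.
#'
#' @param gene_set character vector of gene ids (the susceptible genes).
#' @param background character vector of background gene ids (the universe
#'   actually subjected to differential expression analysis); the gene set
#'   may be part of it.
#' @param annotation a [GenomeAnnotation-class] object.
#' @param superfamily TE superfamily, or NULL for all TEs.
#' @param n_permutations number of null draws (default 10000).
#' @param seed integer seed; results are reproducible given the seed.
#' @param upstream upstream window width.
#' @param estimator `"proportion_greater"` or `"add_one"`.
#' @param unit `"copies"` counts TE copies; `"bases"` sums overlap widths.
#' @return list of class `te_enrichment`: `superfamily`, `observed`,
#'   `null_samples`, `p_empirical`, `n_permutations`, set sizes.
#' @export
tePermutationTest <- function(gene_set, background, annotation,
                              superfamily = NULL, n_permutations = 10000L,
                              seed = 1L, upstream = 2000L,
                              estimator = c("proportion_greater",
                                            "add_one"),
                              unit = c("copies", "bases")) {
  estimator <- match.arg(estimator)
  unit <- match.arg(unit)
  if (n_permutations < 1L) stop("n_permutations must be >= 1",
                                call. = FALSE)
  background <- unique(background)
  gene_set <- unique(gene_set)
  if (!length(background)) stop("empty background", call. = FALSE)
  if (length(gene_set) > length(background))
    stop("gene set larger than background", call. = FALSE)
  regions <- geneRegions(annotation, upstream, genes = background)
  if (unit == "copies") {
    per_gene <- teOverlapCounts(regions, annotation, superfamily)$per_gene
  } else {
    tes <- transposons(annotation)
    if (!is.null(superfamily))
      tes <- tes[S4Vectors::mcols(tes)$superfamily == superfamily]
    hits <- GenomicRanges::findOverlaps(regions, tes, ignore.strand = TRUE)
    w <- GenomicRanges::width(IRanges::pintersect(
      regions[S4Vectors::queryHits(hits)],
      tes[S4Vectors::subjectHits(hits)], ignore.strand = TRUE))
    per_gene <- setNames(numeric(length(regions)), names(regions))
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    per_gene[as.integer(names(agg))] <- agg
  }
  observed <- sum(per_gene[gene_set])
  k <- length(gene_set)
  set.seed(as.integer(seed))
  idx <- replicate(n_permutations, sample.int(length(background), k))
  null_samples <- colSums(matrix(per_gene[background][idx], nrow = k))
  p <- if (estimator == "proportion_greater")
    sum(null_samples > observed) / n_permutations
  else (sum(null_samples > observed) + 1) / (n_permutations + 1)
  structure(list(superfamily = superfamily %||% "all",
                 observed = observed, null_samples = null_samples,
                 p_empirical = p, n_permutations = n_permutations,
                 set_size = k, background_size = length(background),
                 estimator = estimator, unit = unit),
            class = "te_enrichment")
}

#' @export
print.te_enrichment <- function(x, ...) {
  cat("TE enrichment (", x$superfamily, "): observed ", x$observed,
      ", null mean ", signif(mean(x$null_samples), 4),
      ", empirical P = ", x$p_empirical, " (", x$n_permutations,
      " draws)\n", sep = "")
  invisible(x)
}

#' Enrichment tests across all superfamilies
#'
#' @inheritParams tePermutationTest
#' @return data.frame with one row per superfamily: `superfamily`,
#'   `observed`, `null_mean`, `p_empirical`.
#' @export
teEnrichmentTable <- function(gene_set, background, annotation,
                              n_permutations = 10000L, seed = 1L,
                              upstream = 2000L) {
  sfs <- sort(unique(S4Vectors::mcols(transposons(annotation))$superfamily))
  rows <- lapply(seq_along(sfs), function(i) {
    r <- tePermutationTest(gene_set, background, annotation, sfs[i],
                           n_permutations, seed = subSeed(seed, i),
                           upstream = upstream)
    data.frame(superfamily = sfs[i], observed = r$observed,
               null_mean = mean(r$null_samples),
               p_empirical = r$p_empirical)
  })
  do.call(rbind, rows)
}
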