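#' Simulate a gene + transposon annotation with optional planted enrichment
#'
#' Genes are laid out with random strand on two chromosomes; TE copies are
#' placed uniformly at random except for an `enrichment_factor`-fold higher
#' placement intensity inside the 2 kb-upstream-plus-gene-body windows of
#' the `susceptible` genes, the alternative hypothesis of the enrichment
#' test. All intervals are 1-based closed and respect chromosome bounds.
#'
#' @param n_genes,n_tes numbers of genes and TE copies.
#' @param enrichment_factor intensity multiplier (>= 1) inside susceptible
#'   windows; 1 gives the uniform null.
#' @param susceptible character vector of susceptible gene ids (e.g.
#'   `"gene00001"`).
#' @param gene_length,gene_spacing mean gene body length and inter-gene
#'   spacing (bp).
#' @param te_length_range TE length range (bp).
#' @param upstream upstream window width used for the susceptible regions.
#' @param superfamilies TE superfamily vocabulary to draw from.
#' @param seed integer seed.
#' @return A [GenomeAnnotation-class] object.
#' @export
simulateAnnotation <- function(n_genes = 1000L, n_tes = 2000L,
                               enrichment_factor = 1,
                               susceptible = character(),
                               gene_length = 2000L, gene_spacing = 3000L,
                               te_length_range = c(300L, 3000L),
                               upstream = 2000L,
                               superfamilies = TE_SUPERFAMILIES,
                               seed = 1L) {
  assertScalarNumber(enrichment_factor, "enrichment_factor", lower = 1)
  set.seed(subSeed(seed, 1L))
  per_chr <- ceiling(n_genes / 2)
  slot_w <- gene_length + gene_spacing
  chr_len <- per_chr * slot_w + upstream + 10000L
  chrom <- setNames(rep(chr_len, 2L), c("chr1", "chr2"))
  if (chr_len < gene_length + upstream)
    stop("chromosome too short for the requested features", call. = FALSE)

  idx <- seq_len(n_genes)
  chr <- ifelse(idx <= per_chr, "chr1", "chr2")
  slot <- ifelse(idx <= per_chr, idx, idx - per_chr) - 1L
  start <- slot * slot_w + upstream + 1L +
    sample.int(gene_spacing, n_genes, replace = TRUE) - 1L
  len <- pmax(200L, round(rnorm(n_genes, gene_length, gene_length / 4)))
  end <- pmin(start + len - 1L, chr_len)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  genes <- GenomicRanges::GRanges(chr, IRanges::IRanges(start, end),
                                  strand = strand,
                                  seqlengths = chrom)
  names(genes) <- sprintf("gene%05d", idx)
  S4Vectors::mcols(genes)$gene_id <- names(genes)

  ## susceptible windows (2 kb upstream + gene body), merged
  win <- GenomicRanges::GRanges()
  if (length(susceptible)) {
    miss <- setdiff(susceptible, names(genes))
    if (length(miss)) stop("unknown susceptible gene id(s)", call. = FALSE)
    win <- GenomicRanges::reduce(.extendUpstream(genes[susceptible],
                                                 upstream))
  }
  W <- sum(as.numeric(GenomicRanges::width(win)))
  L <- sum(as.numeric(chrom))
  p_win <- if (W > 0) enrichment_factor * W /
    (enrichment_factor * W + (L - W)) else 0

  set.seed(subSeed(seed, 2L))
  in_win <- runif(n_tes) < p_win
  te_start <- integer(n_tes); te_chr <- character(n_tes)
  if (any(in_win)) {
    w <- as.numeric(GenomicRanges::width(win))
    pick <- sample.int(length(win), sum(in_win), replace = TRUE,
                       prob = w / sum(w))
    off <- floor(runif(sum(in_win)) * w[pick])
    te_start[in_win] <- GenomicRanges::start(win)[pick] + off
    te_chr[in_win] <- as.character(GenomicRanges::seqnames(win))[pick]
  }
  if (any(!in_win)) {
    ## complement of the windows, sampled by width
    all_gr <- GenomicRanges::GRanges(names(chrom),
                                     IRanges::IRanges(1L, chrom),
                                     seqlengths = chrom)
    comp <- if (length(win)) GenomicRanges::setdiff(all_gr, win) else all_gr
    w <- as.numeric(GenomicRanges::width(comp))
    pick <- sample.int(length(comp), sum(!in_win), replace = TRUE,
                       prob = w / sum(w))
    off <- floor(runif(sum(!in_win)) * w[pick])
    te_start[!in_win] <- GenomicRanges::start(comp)[pick] + off
    te_chr[!in_win] <- as.character(GenomicRanges::seqnames(comp))[pick]
  }
  te_len <- sample(seq(te_length_range[1], te_length_range[2]), n_tes,
                   replace = TRUE)
  te_end <- pmin(te_start + te_len - 1L, chrom[te_chr])
  tes <- if (n_tes > 0)
    GenomicRanges::GRanges(te_chr, IRanges::IRanges(te_start, te_end),
                           strand = "*", seqlengths = chrom)
  else GenomicRanges::GRanges(seqlengths = chrom)
  S4Vectors::mcols(tes)$te_id <- sprintf("te%05d", seq_len(n_tes))
  S4Vectors::mcols(tes)$superfamily <-
    sample(superfamilies, n_tes, replace = TRUE)
  GenomeAnnotation(genes, tes)
}

#' Simulate genotype metadata (climate, methylation, TE abundance)
#'
#' Climate variables Bio1..Bio19 and context-wise methylation means are
#' independent noise around realistic values; TE counts per superfamily are
#' log-normal. If a `propensity` (per-genotype susceptibility score in
#' `[0, 1]`) is supplied, the log TE count of `link_superfamily` is made
#' linear in the arcsine-square-root of the propensity with slope
#' `link_slope` and residual SD `link_sd`, planting the relationship the
#' frequency regressions are meant to recover.
#'
#' @param genotypes character vector of genotype labels.
#' @param propensity optional named numeric vector over `genotypes`.
#' @param link_superfamily,link_slope,link_sd the planted link.
#' @param superfamilies TE superfamily vocabulary.
#' @param seed integer seed.
#' @return data.frame with `genotype`, `Bio1..Bio19`, `mCG`, `mCHG`,
#'   `mCHH`, and one `te_<superfamily>` count column per superfamily.
#' @export
simulateMetadata <- function(genotypes, propensity = NULL,
                             link_superfamily = "MuDR", link_slope = 1,
                             link_sd = 0.2,
                             superfamilies = TE_SUPERFAMILIES, seed = 1L) {
  assertScalarNumber(link_slope, "link_slope")
  n <- length(genotypes)
  set.seed(subSeed(seed, 1L))
  out <- data.frame(genotype = genotypes)
  bio_mean <- c(9, 11, 33, 640, 26, -5, 31, 15, 3, 20, 0, 650, 80, 30, 35,
                220, 110, 190, 160)
  bio_sd <- abs(bio_mean) * 0.25 + 1
  for (k in 1:19)
    out[[paste0("Bio", k)]] <- rnorm(n, bio_mean[k], bio_sd[k])
  out$mCG <- pmin(pmax(rnorm(n, 0.24, 0.02), 0), 1)
  out$mCHG <- pmin(pmax(rnorm(n, 0.10, 0.015), 0), 1)
  out$mCHH <- pmin(pmax(rnorm(n, 0.04, 0.008), 0), 1)
  for (sf in superfamilies)
    out[[paste0("te_", sf)]] <- rlnorm(n, log(1500), 0.3)
  if (!is.null(propensity)) {
    if (!all(genotypes %in% names(propensity)))
      stop("propensity must be named over all genotypes", call. = FALSE)
    x <- asin(sqrt(pmin(pmax(propensity[genotypes], 0), 1)))
    xs <- x - mean(x)
    if (sd(x) > 0) xs <- xs / sd(x)
    set.seed(subSeed(seed, 2L))
    out[[paste0("te_", link_superfamily)]] <-
      exp(log(1500) + link_slope * xs + rnorm(n, 0, link_sd))
  }
  out
}
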