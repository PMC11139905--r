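#' Ground-truth scenario for count simulation
#'
#' Negative-binomial counts with per-gene baseline means drawn from a
#' log-normal distribution, a common (or per-gene) overdispersion, sample
#' library-size factors, and planted differentially expressed genes whose
#' fold change applies only in the listed generations of the listed
#' genotype x treatment arm.
#'
#' @param n_genes number of genes.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-gene baseline mean.
#' @param dispersion NB overdispersion alpha (variance = mu + alpha mu^2);
#'   scalar or per-gene vector; 0 gives Poisson counts.
#' @param planted_degs data.frame with columns `genotype`, `treatment`,
#'   `gene` (gene id), `log2fc`, `generations` (comma-separated subset of
#'   F1..F4), or NULL for a global null.
#' @param libsize_range range of the uniform sample library-size factors.
#' @param seed master seed for the count stream.
#' @return A list of class `count_scenario`.
#' @export
countScenario <- function(n_genes = 2000L, baseline_meanlog = log(100),
                          baseline_sdlog = 1, dispersion = 0.05,
                          planted_degs = NULL, libsize_range = c(0.7, 1.3),
                          seed = 1L) {
  assertScalarNumber(n_genes, "n_genes", lower = 1)
  if (any(dispersion < 0)) stop("dispersion must be >= 0", call. = FALSE)
  if (!is.null(planted_degs)) {
    need <- c("genotype", "treatment", "gene", "log2fc", "generations")
    if (!all(need %in% names(planted_degs)))
      stop("planted_degs needs columns ", paste(need, collapse = ", "))
    if (any(!is.finite(planted_degs$log2fc)))
      stop("planted log2fc must be finite")
    gens <- unlist(strsplit(planted_degs$generations, ",", fixed = TRUE))
    if (!all(trimws(gens) %in% OFFSPRING_GENERATIONS))
      stop("planted generations must be a subset of F1..F4")
  }
  structure(list(n_genes = as.integer(n_genes),
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog, dispersion = dispersion,
                 planted_degs = planted_degs,
                 libsize_range = libsize_range, seed = as.integer(seed)),
            class = c("count_scenario", "list"))
}

#' Simulate a gene x sample count matrix with planted DEGs
#'
#' Counts are drawn NB with mean `baseline x library factor x 2^log2fc`
#' where the fold change applies when the sample's genotype, treatment and
#' generation match a planted DEG. The same seed reproduces the matrix
#' exactly.
#'
#' @param samples sample sheet (see [transcriptomeSamples()]).
#' @param scenario a [countScenario()].
#' @return A [TransgenCounts-class] object; the scenario's ground truth is
#'   attached as `metadata(x)$scenario`.
#' @export
simulateCounts <- function(samples, scenario) {
  stopifnot(inherits(scenario, "count_scenario"))
  G <- scenario$n_genes
  n <- nrow(samples)
  gene_ids <- sprintf("gene%05d", seq_len(G))
  set.seed(subSeed(scenario$seed, 1L))
  baseline <- rlnorm(G, scenario$baseline_meanlog, scenario$baseline_sdlog)
  alpha <- rep_len(scenario$dispersion, G)
  set.seed(subSeed(scenario$seed, 2L))
  libfac <- runif(n, scenario$libsize_range[1], scenario$libsize_range[2])

  lfc <- matrix(0, G, n)
  pd <- scenario$planted_degs
  if (!is.null(pd)) {
    bad <- setdiff(pd$gene, gene_ids)
    if (length(bad)) stop("planted gene id(s) not in 1..n_genes: ",
                          paste(head(bad), collapse = ", "), call. = FALSE)
    for (i in seq_len(nrow(pd))) {
      gens <- trimws(strsplit(pd$generations[i], ",", fixed = TRUE)[[1]])
      hit <- samples$genotype == pd$genotype[i] &
        samples$treatment == pd$treatment[i] &
        samples$generation %in% gens
      lfc[match(pd$gene[i], gene_ids), hit] <- pd$log2fc[i]
    }
  }
  mu <- baseline * outer(rep(1, G), libfac) * 2^lfc
  set.seed(subSeed(scenario$seed, 3L))
  counts <- matrix(0L, G, n, dimnames = list(gene_ids, samples$sample_id))
  pois <- alpha == 0
  if (any(pois))
    counts[pois, ] <- rpois(sum(pois) * n, mu[pois, , drop = FALSE])
  if (any(!pois))
    counts[!pois, ] <- rnbinom(sum(!pois) * n,
                               size = 1 / alpha[!pois],
                               mu = mu[!pois, , drop = FALSE])
  obj <- TransgenCounts(counts, samples)
  S4Vectors::metadata(obj)$scenario <- scenario
  obj
}
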