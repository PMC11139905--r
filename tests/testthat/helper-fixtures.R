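## Small in-code fixtures shared across test files.

tinySpec <- function(genotypes = c("gtA", "gtB", "gtC", "gtD"),
                     treatments = c(drought = 6L), control = 6L,
                     n_layers = 4L, n_rows = 6L, n_columns = 6L, ...) {
  designSpec(genotypes, treatments, control, n_layers = n_layers,
             n_rows = n_rows, n_columns = n_columns, ...)
}

## a phenotype table with the full schema, built directly (bypasses the
## simulator) for model-level tests
syntheticPheno <- function(n_geno = 2, n_rep = 6, treatments = "drought",
                           gen = "F1", effect = 0, sd_resid = 1,
                           seed = 1) {
  set.seed(seed)
  gt <- paste0("g", seq_len(n_geno))
  rows <- expand.grid(genotype = gt,
                      ancestral_env = c("control", treatments),
                      replicate = seq_len(n_rep),
                      stringsAsFactors = FALSE)
  n <- nrow(rows)
  rows$line_id <- sprintf("L%03d", seq_len(n))
  rows$test <- "I"
  rows$generation <- gen
  rows$layer <- sample(1:4, n, TRUE)
  rows$row <- sample(1:12, n, TRUE)
  rows$column <- sample(1:8, n, TRUE)
  rows$anc_layer <- sample(1:4, n, TRUE)
  rows$anc_row <- sample(1:12, n, TRUE)
  rows$replaced <- FALSE
  delta <- ifelse(rows$genotype == gt[1] & rows$ancestral_env != "control",
                  effect, 0)
  for (ph in c("flowering_time", "plant_height", "aboveground_biomass",
               "rosette_diameter", "fruit_number"))
    rows[[ph]] <- 30 + 3 * (delta + rnorm(n, 0, sd_resid))
  rows
}

## minimal TransgenCounts from a raw matrix (one genotype, 3 vs 3)
tinyCounts <- function(m, treatment = "drought", generation = "F1") {
  n <- ncol(m)
  stopifnot(n %% 2 == 0)
  samples <- data.frame(
    sample_id = colnames(m) %||% sprintf("S%02d", seq_len(n)),
    genotype = "gtA",
    treatment = rep(c("control", treatment), each = n / 2),
    generation = generation, replicate = rep(seq_len(n / 2), 2))
  if (is.null(colnames(m))) colnames(m) <- samples$sample_id
  if (is.null(rownames(m))) rownames(m) <- sprintf("gene%05d",
                                                   seq_len(nrow(m)))
  TransgenCounts(m, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## hand-built two-chromosome annotation for interval tests
tinyAnnotation <- function(gene_df, te_df, chrom = c(chr1 = 20000L)) {
  g <- GenomicRanges::GRanges(gene_df$chr,
                              IRanges::IRanges(gene_df$start, gene_df$end),
                              strand = gene_df$strand, seqlengths = chrom)
  names(g) <- gene_df$gene_id
  S4Vectors::mcols(g)$gene_id <- gene_df$gene_id
  te <- if (nrow(te_df))
    GenomicRanges::GRanges(te_df$chr,
                           IRanges::IRanges(te_df$start, te_df$end),
                           strand = "*", seqlengths = chrom)
  else GenomicRanges::GRanges(seqlengths = chrom)
  S4Vectors::mcols(te)$te_id <- if (nrow(te_df)) te_df$te_id else character()
  S4Vectors::mcols(te)$superfamily <-
    if (nrow(te_df)) te_df$superfamily else character()
  GenomeAnnotation(g, te)
}

## brute-force Benjamini-Hochberg step-up (independent of p.adjust)
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- prev
  }
  adj
}
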