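#' Configuration of the end-to-end pipeline
#'
#' One validated configuration object drives [runPipeline()]. Thresholds
#' are checked up front (before any computation); mode switches come from
#' closed vocabularies.
#'
#' @param seed master seed; every stage's randomness derives from it.
#' @param out_dir output directory for tables and the manifest, or NULL to
#'   return results in memory only.
#' @param genotypes,treatments design cells of the demonstration-scale
#'   experiment (treatments is a named replicate-count vector).
#' @param control_replicates control lines per genotype.
#' @param n_layers,n_rows,n_columns growth-room grid.
#' @param n_genes genes in the expression stage.
#' @param alpha,alpha_marginal occurrence cutoffs (`alpha <
#'   alpha_marginal`).
#' @param lfc_cutoff,padj_cutoff,cpm_threshold DE thresholds.
#' @param upstream,n_permutations enrichment parameters.
#' @param te_enrichment_factor planted enrichment of the simulated
#'   annotation.
#' @param persistent_rule,p_estimator,control_pairing mode switches (see
#'   [classifyHeritability()], [tePermutationTest()], [nbWaldTest()]).
#' @param scenario,count_scenario optional ground-truth overrides.
#' @return A list of class `pipeline_config`.
#' @export
pipelineConfig <- function(seed = 1L, out_dir = NULL,
                           genotypes = c("gtA", "gtB"),
                           treatments = c(drought = 6L, high_salinity = 6L),
                           control_replicates = 6L,
                           n_layers = 6L, n_rows = 6L, n_columns = 8L,
                           n_genes = 200L,
                           alpha = 0.05, alpha_marginal = 0.1,
                           lfc_cutoff = 1.5, padj_cutoff = 0.05,
                           cpm_threshold = 1, upstream = 2000L,
                           n_permutations = 1000L,
                           te_enrichment_factor = 3,
                           persistent_rule = "three_plus_final",
                           p_estimator = "proportion_greater",
                           control_pairing = "matched",
                           scenario = NULL, count_scenario = NULL) {
  for (nm in c("alpha", "alpha_marginal", "lfc_cutoff", "padj_cutoff",
               "cpm_threshold", "upstream", "n_permutations"))
    assertScalarNumber(get(nm), nm, lower = 1e-12)
  if (!(alpha < alpha_marginal))
    stop("alpha must be < alpha_marginal", call. = FALSE)
  assertChoice(persistent_rule, c("three_plus_final", "all_four"),
               "persistent_rule")
  assertChoice(p_estimator, c("proportion_greater", "add_one"),
               "p_estimator")
  assertChoice(control_pairing, c("matched", "pooled"), "control_pairing")
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              genotypes = genotypes, treatments = treatments,
              control_replicates = control_replicates,
              n_layers = n_layers, n_rows = n_rows, n_columns = n_columns,
              n_genes = as.integer(n_genes), alpha = alpha,
              alpha_marginal = alpha_marginal, lfc_cutoff = lfc_cutoff,
              padj_cutoff = padj_cutoff, cpm_threshold = cpm_threshold,
              upstream = as.integer(upstream),
              n_permutations = as.integer(n_permutations),
              te_enrichment_factor = te_enrichment_factor,
              persistent_rule = persistent_rule,
              p_estimator = p_estimator,
              control_pairing = control_pairing,
              scenario = scenario, count_scenario = count_scenario)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

.stage <- function(name, partial, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    cond <- simpleError(sprintf("pipeline stage '%s' failed: %s", name,
                                conditionMessage(e)))
    cond$stage <- name
    cond$partial <- as.list(partial)
    class(cond) <- c("pipeline_error", class(cond))
    stop(cond)
  })
  message(sprintf("[%s] done in %.1fs", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full analysis pipeline on simulated inputs
#'
#' Executes design + phenotype simulation, effect-size estimation,
#' occurrence conversion and heritability classification, occurrence
#' modelling and reproducibility analysis, count simulation and
#' differential expression with heritable-DEG calling, and the TE
#' enrichment test, stage by stage. Rerunning with an identical config and
#' seed reproduces every result bit-identically; a stage failure aborts
#' with the stage name while preserving the finished stages in the error's
#' `partial` field.
#'
#' @param config a [pipelineConfig()].
#' @return list of class `pipeline_result` with one element per stage and
#'   a `manifest` (seed, config hash, result hash, record counts).
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- new.env(parent = emptyenv())
  cfg_for_hash <- config[setdiff(names(config), "out_dir")]
  config_hash <- objectHash(cfg_for_hash)

  spec <- designSpec(config$genotypes, config$treatments,
                     config$control_replicates, n_generations = 4L,
                     n_layers = config$n_layers, n_rows = config$n_rows,
                     n_columns = config$n_columns)
  res$design <- .stage("design", res,
                       buildDesign(spec, seed = subSeed(config$seed, 1L)))

  scenario <- config$scenario %||% effectScenario(
    planted_effects = data.frame(
      genotype = config$genotypes[1],
      treatment = rep(names(config$treatments)[1], 2),
      phenotype = c("flowering_time", "plant_height"),
      effect = c(1.2, 1.0)),
    seed = subSeed(config$seed, 2L))
  res$phenotypes <- .stage("phenotypes", res,
                           simulatePhenotypes(res$design, scenario,
                                              test = "I"))

  res$effects <- .stage("effects", res,
                        estimateAllEffects(res$phenotypes, test = "I"))
  res$occurrence <- .stage("occurrence", res,
                           effectsToOccurrence(res$effects, config$alpha,
                                               config$alpha_marginal))
  res$classification <- .stage("classify", res, {
    prof <- generationProfiles(res$occurrence)
    classifyHeritability(prof, persistent = config$persistent_rule)
  })
  res$proportions <- .stage("proportions", res, {
    if (any(res$classification$n_significant >= 1))
      proportionSummary(res$classification)
    else c(two = NA_real_, three = NA_real_, four = NA_real_)
  })
  res$frequency <- .stage("frequency", res,
                          occurrenceFrequency(res$occurrence, "genotype"))

  res$occurrence_model <- .stage("occurrence_model", res,
                                 fitOccurrenceGLMM(res$occurrence))
  res$metadata <- .stage("metadata", res, {
    prop <- setNames(res$frequency$frequency, res$frequency$genotype)
    prop <- prop[config$genotypes]
    prop[is.na(prop)] <- 0
    names(prop) <- config$genotypes
    simulateMetadata(config$genotypes, propensity = prop,
                     seed = subSeed(config$seed, 3L))
  })
  res$regressions <- .stage("regressions", res, {
    if (length(config$genotypes) >= 3)
      suppressWarnings(frequencyRegressionAll(res$frequency, res$metadata))
    else NULL   # r undefined below 3 genotypes
  })
  res$reproducibility <- .stage("reproducibility", res, {
    do.call(rbind, lapply(c("all", "significant", "nonsignificant"),
                          function(s) tryCatch(
                            effectSizeCorrelations(res$effects,
                                                   "generations", s,
                                                   alpha = config$alpha),
                            error = function(e) NULL)))
  })

  samples <- transcriptomeSamples(
    layout = "full", genotypes = config$genotypes,
    treatments = names(config$treatments), n_replicates = 3L)
  cscen <- config$count_scenario %||% countScenario(
    n_genes = config$n_genes,
    planted_degs = data.frame(
      genotype = config$genotypes[1],
      treatment = names(config$treatments)[1],
      gene = sprintf("gene%05d", seq_len(max(2L, config$n_genes %/% 20))),
      log2fc = 3,
      generations = "F1,F2,F3"),
    seed = subSeed(config$seed, 4L))
  res$counts <- .stage("counts", res, simulateCounts(samples, cscen))
  res$de <- .stage("de", res,
                   runDE(res$counts, lfc_cutoff = config$lfc_cutoff,
                         padj_cutoff = config$padj_cutoff,
                         control_pairing = config$control_pairing))
  res$heritable_degs <- .stage("heritable_degs", res,
                               callHeritableDEGs(res$de))
  res$deg_counts <- .stage("deg_counts", res, degCountModel(res$de))

  res$annotation <- .stage("annotation", res, {
    herit <- res$heritable_degs$gene[res$heritable_degs$heritable]
    simulateAnnotation(n_genes = config$n_genes,
                       n_tes = max(500L, config$n_genes * 3L),
                       enrichment_factor = config$te_enrichment_factor,
                       susceptible = unique(herit),
                       upstream = config$upstream,
                       seed = subSeed(config$seed, 5L))
  })
  res$enrichment <- .stage("enrichment", res, {
    herit <- unique(res$heritable_degs$gene[res$heritable_degs$heritable])
    background <- unique(res$de$gene)
    if (length(herit) >= 2 && length(background) > length(herit))
      teEnrichmentTable(herit, background, res$annotation,
                        n_permutations = config$n_permutations,
                        seed = subSeed(config$seed, 6L),
                        upstream = config$upstream)
    else NULL
  })

  out <- as.list(res)
  out <- out[c("design", "phenotypes", "effects", "occurrence",
               "classification", "proportions", "frequency",
               "occurrence_model", "metadata", "regressions",
               "reproducibility", "counts", "de", "heritable_degs",
               "deg_counts", "annotation", "enrichment")]
  hashable <- out[setdiff(names(out), c("occurrence_model", "deg_counts"))]
  manifest <- list(package_version =
                     as.character(packageVersion("heritvar")),
                   seed = config$seed, config_hash = config_hash,
                   result_hash = objectHash(hashable),
                   n_lines = nrow(designLines(out$design)),
                   n_effect_tests = sum(!is.na(out$effects$p)),
                   n_degs = sum(out$de$is_deg, na.rm = TRUE),
                   n_heritable_degs =
                     sum(out$heritable_degs$heritable %||% 0))
  out$manifest <- manifest

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wp <- function(df, f) if (!is.null(df))
      .writeTSV(df, file.path(config$out_dir, f), config$seed, config_hash)
    wp(out$effects, "effects.tsv")
    wp(out$occurrence, "occurrence.tsv")
    wp(out$classification, "classification.tsv")
    wp(out$frequency, "occurrence_frequency.tsv")
    wp(out$regressions, "frequency_regressions.tsv")
    wp(out$reproducibility, "reproducibility.tsv")
    wp(out$de, "de.tsv")
    wp(out$heritable_degs, "heritable_degs.tsv")
    wp(out$enrichment, "te_enrichment.tsv")
    writePhenotypes(out$phenotypes,
                    file.path(config$out_dir, "phenotypes.tsv"),
                    config$seed, config_hash)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  class(out) <- c("pipeline_result", "list")
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat("heritvar pipeline result (seed ", m$seed, ", config ",
      substr(m$config_hash, 1, 8), ")\n", sep = "")
  cat("  lines:", m$n_lines, "| effect tests:", m$n_effect_tests,
      "| DEGs:", m$n_degs, "| heritable DEGs:", m$n_heritable_degs, "\n")
  invisible(x)
}
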