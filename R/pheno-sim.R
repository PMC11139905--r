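#' Natural measurement scales of the five phenotypes
#'
#' Phenotypes are simulated on a standardized latent scale (residual SD 1)
#' and mapped to natural units by these means and SDs; `fruit_number` is
#' rounded and floored at zero, all phenotypes are non-negative.
#'
#' @return data.frame with columns `phenotype`, `mean`, `sd`, `integer`.
#' @export
phenotypeScales <- function() {
  data.frame(
    phenotype = PHENOTYPES,
    mean = c(32, 30, 0.8, 9, 120),      # d, cm, g, cm, siliques
    sd = c(3, 4, 0.15, 1.2, 25),
    integer = c(FALSE, FALSE, FALSE, FALSE, TRUE))
}

#' Ground-truth scenario for phenotype simulation
#'
#' Defines the planted genotype-specific induced effects (in within-phenotype
#' SD units), how they are transmitted across generations, and the variance
#' structure of the growth room.
#'
#' @param planted_effects data.frame with columns `genotype`, `treatment`,
#'   `phenotype`, `effect` (SD units). Cells not listed are taken as zero;
#'   rows referring to cells absent from the design are a configuration
#'   error at simulation time.
#' @param transmission named numeric vector of multipliers on the planted
#'   effect per generation, e.g. `c(Anc = 1, F1 = 1, F2 = 1, F3 = 1, F4 = 1)`
#'   for stable transmission or `c(Anc = 1, F1 = 1, F2 = .5, F3 = .25,
#'   F4 = 0)` for decay. Must cover every simulated generation.
#' @param genotype_means,treatment_means optional named vectors of latent
#'   mean shifts (SD units); treatment means act in the ancestral generation
#'   only (the direct environmental response).
#' @param sd_layer,sd_row,sd_line,sd_residual standard deviations of the
#'   layer, row, line and residual effects on the latent scale.
#' @param death_rate probability that an ancestral line dies before seed
#'   production; its descendants are replaced by a random surviving
#'   replicate of the same genotype and treatment and flagged `replaced`.
#' @param phenotype_scales see [phenotypeScales()].
#' @param seed master seed for the phenotype stream.
#' @return A list of class `effect_scenario`.
#' @export
effectScenario <- function(planted_effects = NULL,
                           transmission = c(Anc = 1, F1 = 1, F2 = 1,
                                            F3 = 1, F4 = 1),
                           genotype_means = NULL, treatment_means = NULL,
                           sd_layer = 0.15, sd_row = 0.1, sd_line = 0.25,
                           sd_residual = 1, death_rate = 0.0258,
                           phenotype_scales = phenotypeScales(), seed = 1L) {
  for (s in c(sd_layer, sd_row, sd_line, sd_residual))
    assertScalarNumber(s, "sd", lower = 0)
  assertScalarNumber(death_rate, "death_rate", lower = 0, upper = 1)
  if (!is.null(planted_effects)) {
    need <- c("genotype", "treatment", "phenotype", "effect")
    if (!all(need %in% names(planted_effects)))
      stop("planted_effects needs columns genotype, treatment, phenotype, effect")
    if (any(!is.finite(planted_effects$effect)))
      stop("planted effects must be finite")
  }
  structure(list(planted_effects = planted_effects,
                 transmission = transmission,
                 genotype_means = genotype_means,
                 treatment_means = treatment_means,
                 sd_layer = sd_layer, sd_row = sd_row, sd_line = sd_line,
                 sd_residual = sd_residual, death_rate = death_rate,
                 phenotype_scales = phenotype_scales,
                 seed = as.integer(seed)),
            class = c("effect_scenario", "list"))
}

## planted effect lookup table -> full matrix over (line cells x phenotype)
.plantedLookup <- function(scenario, lines, phenotype) {
  eff <- setNames(numeric(nrow(lines)), lines$line_id)
  pe <- scenario$planted_effects
  if (is.null(pe)) return(eff)
  pe <- pe[pe$phenotype == phenotype, , drop = FALSE]
  if (!nrow(pe)) return(eff)
  bad <- !(pe$genotype %in% lines$genotype) |
    !(pe$treatment %in% lines$ancestral_env)
  if (any(bad))
    stop("planted_effects refer to genotype/treatment cells absent from the design",
         call. = FALSE)
  key <- paste(lines$genotype, lines$ancestral_env)
  m <- match(key, paste(pe$genotype, pe$treatment))
  eff[!is.na(m)] <- pe$effect[m[!is.na(m)]]
  eff
}

#' Simulate multigenerational phenotypes with known ground truth
#'
#' Generates one record per plant per generation. On the latent scale,
#' `Y = genotype mean + direct treatment response (ancestral generation) +
#' planted effect x transmission(generation) + layer + row + line +
#' residual`; latent values are then mapped to natural units
#' (see [phenotypeScales()]). The same seed reproduces the table exactly.
#'
#' @param design a [HeritDesign-class] object.
#' @param scenario an [effectScenario()].
#' @param test label recorded for offspring rows (`"I"` or `"II"`);
#'   ancestral rows are labelled `"ancestral"`.
#' @param generations generations to simulate; default all in the design.
#' @return data.frame with design columns (`line_id`, `genotype`,
#'   `ancestral_env`, `test`, `generation`, `layer`, `row`, `column`,
#'   `anc_layer`, `anc_row`, `replaced`) and the five phenotype columns.
#' @export
simulatePhenotypes <- function(design, scenario, test = "I",
                               generations = NULL) {
  stopifnot(is(design, "HeritDesign"), inherits(scenario, "effect_scenario"))
  lines <- designLines(design)
  pos <- designPositions(design)
  generations <- generations %||% unique(pos$generation)
  miss <- setdiff(generations, names(scenario$transmission))
  if (length(miss))
    stop("transmission multiplier missing for generation(s): ",
         paste(miss, collapse = ", "), call. = FALSE)

  pos <- pos[pos$generation %in% generations, , drop = FALSE]
  pos <- pos[order(match(pos$generation, c("Anc", OFFSPRING_GENERATIONS)),
                   pos$line_id), , drop = FALSE]
  df <- merge(pos, lines, by = "line_id", sort = FALSE)
  anc <- designPositions(design)
  anc <- anc[anc$generation == "Anc", c("line_id", "layer", "row")]
  names(anc) <- c("line_id", "anc_layer", "anc_row")
  df <- merge(df, anc, by = "line_id", sort = FALSE)
  df <- df[order(match(df$generation, c("Anc", OFFSPRING_GENERATIONS)),
                 df$line_id), , drop = FALSE]
  rownames(df) <- NULL
  df$test <- ifelse(df$generation == "Anc", "ancestral", test)

  ## ancestral deaths and single-seed replacement
  set.seed(subSeed(scenario$seed, 40L))
  dead <- lines$line_id[runif(nrow(lines)) < scenario$death_rate]
  donor <- setNames(lines$line_id, lines$line_id)
  for (id in dead) {
    i <- match(id, lines$line_id)
    cand <- lines$line_id[lines$genotype == lines$genotype[i] &
                            lines$ancestral_env == lines$ancestral_env[i] &
                            !(lines$line_id %in% dead)]
    if (length(cand)) donor[id] <- cand[sample.int(length(cand), 1L)]
  }
  df$replaced <- df$generation != "Anc" & donor[df$line_id] != df$line_id

  gm <- setNames(numeric(length(unique(lines$genotype))),
                 unique(lines$genotype))
  if (!is.null(scenario$genotype_means))
    gm[names(scenario$genotype_means)] <- scenario$genotype_means
  tm <- setNames(numeric(length(unique(lines$ancestral_env))),
                 unique(lines$ancestral_env))
  if (!is.null(scenario$treatment_means))
    tm[names(scenario$treatment_means)] <- scenario$treatment_means

  scales <- scenario$phenotype_scales
  eff_line <- donor[df$line_id]  # effective line (replacement duplicates)
  for (k in seq_len(nrow(scales))) {
    ph <- scales$phenotype[k]
    set.seed(subSeed(scenario$seed, 100L + k))
    planted <- .plantedLookup(scenario, lines, ph)
    lay_key <- unique(df[, c("generation", "layer")])
    lay_eff <- setNames(rnorm(nrow(lay_key), 0, scenario$sd_layer),
                        paste(lay_key$generation, lay_key$layer))
    row_key <- unique(df[, c("generation", "row")])
    row_eff <- setNames(rnorm(nrow(row_key), 0, scenario$sd_row),
                        paste(row_key$generation, row_key$row))
    line_eff <- setNames(rnorm(nrow(lines), 0, scenario$sd_line),
                         lines$line_id)
    trans <- scenario$transmission[df$generation]
    direct <- ifelse(df$generation == "Anc", tm[df$ancestral_env], 0)
    z <- gm[df$genotype] + direct +
      planted[eff_line] * trans +
      lay_eff[paste(df$generation, df$layer)] +
      row_eff[paste(df$generation, df$row)] +
      line_eff[eff_line] +
      rnorm(nrow(df), 0, scenario$sd_residual)
    y <- scales$mean[k] + scales$sd[k] * z
    y <- pmax(y, 0)
    if (scales$integer[k]) y <- round(y)
    y[df$generation == "Anc" & df$line_id %in% dead] <- NA_real_
    df[[ph]] <- unname(y)
  }
  df[, c("line_id", "genotype", "ancestral_env", "test", "generation",
         "layer", "row", "column", "anc_layer", "anc_row", "replaced",
         scales$phenotype)]
}
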