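#' Specify a multigenerational common-garden design
#'
#' Describes one test of the experiment: which genotypes are grown, which
#' ancestral environments are applied with how many replicate lines, how many
#' offspring generations are followed by single-seed descent, and the
#' growth-room grid (layers x rows x columns; row numbers are unique across
#' layers).
#'
#' @param genotypes character vector of genotype labels.
#' @param treatments named integer vector: treatment label -> replicate lines
#'   per genotype.
#' @param control_replicates replicate lines per genotype in the control.
#' @param n_generations number of offspring generations (F1, F2, ...).
#' @param n_layers,n_rows,n_columns growth-room grid dimensions (`n_rows`
#'   rows per layer).
#' @param plant_together logical; if `TRUE` all offspring generations are
#'   planted simultaneously in one grid (as when reproducibility across
#'   generations is tested under uniform conditions), otherwise each
#'   generation occupies the grid in turn.
#' @param control_label label used for the control environment.
#' @return A list of class `design_spec`.
#' @seealso [buildDesign()], [testISpec()], [testIISpec()]
#' @export
designSpec <- function(genotypes, treatments, control_replicates,
                       n_generations = 4L, n_layers = 16L, n_rows = 6L,
                       n_columns = 14L, plant_together = FALSE,
                       control_label = "control") {
  stopifnot(length(genotypes) >= 1, !anyDuplicated(genotypes))
  if (is.null(names(treatments)) || any(!nzchar(names(treatments))))
    stop("'treatments' must be a named vector of replicate counts")
  if (any(treatments < 1) || control_replicates < 1)
    stop("replicate counts must be >= 1")
  assertScalarNumber(n_generations, "n_generations", lower = 1)
  for (d in c(n_layers, n_rows, n_columns))
    assertScalarNumber(d, "grid dimension", lower = 1)
  spec <- list(genotypes = as.character(genotypes),
               treatments = setNames(as.integer(treatments),
                                     names(treatments)),
               control_replicates = as.integer(control_replicates),
               n_generations = as.integer(n_generations),
               n_layers = as.integer(n_layers), n_rows = as.integer(n_rows),
               n_columns = as.integer(n_columns),
               plant_together = isTRUE(plant_together),
               control_label = control_label)
  class(spec) <- c("design_spec", "list")
  spec
}

#' The main multigenerational test: 14 genotypes, 10 treatments
#'
#' Control with 12 replicate lines per genotype plus ten ancestral
#' environments with six replicates each, giving 14 x (12 + 10 x 6) = 1008
#' lines, each followed for four offspring generations by single-seed
#' descent (4032 offspring plants).
#'
#' @return A `design_spec`.
#' @export
testISpec <- function() {
  genotypes <- c("Abd-0", "Ang-0", "Col-0", "Dja-1", "En-1", "Fei-0",
                 "Kar-1", "Ler-0", "Olympia-2", "Sap-0", "Tol-0", "TRE-1",
                 "Tri-0", "Ws-2")
  treatments <- setNames(rep(6L, 10),
                         c("JA", "JA_control", "nutrient_addition",
                           "nutrient_depletion", "leaf_removal", "drought",
                           "low_cadmium", "high_cadmium", "low_salinity",
                           "high_salinity"))
  designSpec(genotypes, treatments, control_replicates = 12L,
             n_generations = 4L, n_layers = 16L, n_rows = 6L,
             n_columns = 14L)
}

#' The uniform-conditions reproducibility test: 10 genotypes, 6 environments
#'
#' Ten genotypes by six environments (control plus five stress treatments)
#' with six replicates each, 360 lines; all four offspring generations are
#' planted together (1440 plants) in a 16-layer, 6 x 15 grid.
#'
#' @return A `design_spec`.
#' @export
testIISpec <- function() {
  genotypes <- c("Abd-0", "Col-0", "Ang-0", "Dja-1", "Fei-0", "Ler-0",
                 "Sap-0", "Tol-0", "TRE-1", "Tri-0")
  treatments <- setNames(rep(6L, 5),
                         c("drought", "low_cadmium", "high_cadmium",
                           "low_salinity", "high_salinity"))
  designSpec(genotypes, treatments, control_replicates = 6L,
             n_generations = 4L, n_layers = 16L, n_rows = 6L,
             n_columns = 15L, plant_together = TRUE)
}

#' Build the experimental lines and randomized grid positions
#'
#' Creates one line per genotype x treatment x replicate (plus the control
#' replicates) and assigns every plant of every generation a random
#' (layer, row, column) cell, without collisions, by seeded randomization.
#'
#' @param spec a `design_spec` from [designSpec()].
#' @param seed integer seed; the same seed reproduces the design exactly.
#' @return A [HeritDesign-class] object.
#' @export
buildDesign <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "design_spec"))
  envs <- c(setNames(spec$control_replicates, spec$control_label),
            spec$treatments)
  lines <- do.call(rbind, lapply(spec$genotypes, function(g) {
    do.call(rbind, lapply(names(envs), function(e) {
      data.frame(genotype = g, ancestral_env = e,
                 replicate = seq_len(envs[[e]]))
    }))
  }))
  lines$line_id <- sprintf("L%04d", seq_len(nrow(lines)))
  lines <- lines[, c("line_id", "genotype", "ancestral_env", "replicate")]

  n_cells <- spec$n_layers * spec$n_rows * spec$n_columns
  gens <- c("Anc", paste0("F", seq_len(spec$n_generations)))
  cells <- expand.grid(layer = seq_len(spec$n_layers),
                       row_in_layer = seq_len(spec$n_rows),
                       column = seq_len(spec$n_columns))
  ## row numbers are unique across layers
  cells$row <- (cells$layer - 1L) * spec$n_rows + cells$row_in_layer

  assign_gen <- function(gen_labels, rng_seed) {
    n_plants <- nrow(lines) * length(gen_labels)
    if (n_plants > n_cells)
      stop(sprintf("grid capacity %d is too small for %d plants",
                   n_cells, n_plants), call. = FALSE)
    set.seed(rng_seed)
    idx <- sample.int(n_cells, n_plants)
    data.frame(generation = rep(gen_labels, each = nrow(lines)),
               line_id = rep(lines$line_id, length(gen_labels)),
               layer = cells$layer[idx], row = cells$row[idx],
               column = cells$column[idx])
  }

  seed <- as.integer(seed)
  pos <- assign_gen("Anc", subSeed(seed, 0L))
  off <- gens[-1]
  if (spec$plant_together) {
    pos <- rbind(pos, assign_gen(off, subSeed(seed, 1L)))
  } else {
    for (i in seq_along(off))
      pos <- rbind(pos, assign_gen(off[i], subSeed(seed, i)))
  }
  new("HeritDesign", spec = unclass(spec), lines = lines, positions = pos,
      seed = seed)
}

#' Sample sheet for the transcriptomic sub-design
#'
#' Four genotypes spanning high and low susceptibility, the control plus
#' three stress environments, four offspring generations, three replicates.
#' Two layouts are provided: `"full"` gives every genotype x environment
#' (control included) x generation its own three replicates (192 samples);
#' `"compact"` enumerates only the three treatment arms per generation (144
#' samples), with the control arm shared across generations within a
#' genotype (12 additional control samples per genotype appended with
#' generation `"shared"`).
#'
#' @param layout `"full"` or `"compact"`.
#' @param genotypes,treatments,n_replicates design cells; defaults follow
#'   the standard sub-design.
#' @param control_label control environment label.
#' @return data.frame with columns `sample_id`, `genotype`, `treatment`,
#'   `generation`, `replicate`.
#' @export
transcriptomeSamples <- function(layout = c("full", "compact"),
                                 genotypes = c("Abd-0", "Ang-0", "Tol-0",
                                               "TRE-1"),
                                 treatments = c("drought", "low_cadmium",
                                                "high_cadmium"),
                                 n_replicates = 3L,
                                 control_label = "control") {
  layout <- match.arg(layout)
  gens <- OFFSPRING_GENERATIONS
  envs <- c(control_label, treatments)
  grid <- expand.grid(replicate = seq_len(n_replicates), generation = gens,
                      treatment = envs, genotype = genotypes,
                      stringsAsFactors = FALSE)
  if (layout == "compact") {
    trt <- grid[grid$treatment != control_label, ]
    ctl <- expand.grid(replicate = seq_len(n_replicates),
                       generation = "shared", treatment = control_label,
                       genotype = genotypes, stringsAsFactors = FALSE)
    grid <- rbind(trt, ctl)
  }
  grid <- grid[, c("genotype", "treatment", "generation", "replicate")]
  grid$sample_id <- sprintf("S%03d", seq_len(nrow(grid)))
  grid[, c("sample_id", "genotype", "treatment", "generation", "replicate")]
}

#' Enumerate the differential-expression contrast sets of a sample sheet
#'
#' One set per genotype x (non-control) treatment; each is later tested
#' against its control arm in every generation.
#'
#' @param samples a transcriptome sample sheet.
#' @param control_label control environment label.
#' @return data.frame with columns `genotype`, `treatment`.
#' @export
contrastSets <- function(samples, control_label = "control") {
  u <- unique(samples[samples$treatment != control_label,
                      c("genotype", "treatment")])
  rownames(u) <- NULL
  u[order(u$genotype, u$treatment), , drop = FALSE]
}
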