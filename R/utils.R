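#' @importFrom stats aggregate anova as.formula coef complete.cases cor cor.test
#'   lm median model.matrix na.omit p.adjust pchisq plogis pnorm quantile
#'   rbinom rlnorm rnbinom rnorm rpois runif sd setNames var vcov
#' @importFrom utils combn head read.delim write.table packageVersion
NULL

OFFSPRING_GENERATIONS <- c("F1", "F2", "F3", "F4")
PHENOTYPES <- c("flowering_time", "plant_height", "aboveground_biomass",
                "rosette_diameter", "fruit_number")
TE_SUPERFAMILIES <- c("Gypsy", "Copia", "MuDR", "HAT", "Mariner", "Helitron")

#' Derive a reproducible sub-seed from a master seed
#'
#' Module-level random streams (design, phenotypes, counts, annotation,
#' metadata) are split from one master seed so regenerating any single
#' artifact is independent of the others.
#'
#' @param seed master integer seed.
#' @param offset integer stream index (0, 1, 2, ...).
#' @return An integer seed in `[1, 2^31 - 20]`.
#' @export
subSeed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 7919 + as.numeric(offset) * 104729) %%
               2147483629) + 1L
}

## z-standardize, guarding constant vectors (returns zeros, sd attribute 1)
zStandardize <- function(x) {
  m <- mean(x, na.rm = TRUE)
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s <= 0) {
    z <- x - m
    attr(z, "scale") <- 1
    return(z)
  }
  z <- (x - m) / s
  attr(z, "scale") <- s
  z
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower ||
      x > upper)
    stop(sprintf("'%s' must be a single finite number in [%s, %s]",
                 name, lower, upper), call. = FALSE)
  invisible(x)
}

assertChoice <- function(x, choices, name) {
  if (!is.character(x) || length(x) != 1L || !x %in% choices)
    stop(sprintf("'%s' must be one of: %s", name,
                 paste(choices, collapse = ", ")), call. = FALSE)
  invisible(x)
}

## md5 hash of an arbitrary R object via a serialized temp file (used in the
## provenance manifest)
objectHash <- function(x) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
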