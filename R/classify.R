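#' Build per-key occurrence profiles across offspring generations
#'
#' Collapses an occurrence table to one row per (genotype, treatment,
#' phenotype, test) key with an ordered 0/1 vector over F1..F4. Generations
#' with no record are imputed as 0 and the key flagged `incomplete`.
#'
#' @param occurrence table from [effectsToOccurrence()].
#' @param value_col `"occurred"` (strict significance) or `"marginal"`.
#' @param generations ordered offspring generations expected.
#' @return data.frame with columns `genotype`, `treatment`, `phenotype`,
#'   `test`, one 0/1 column per generation, `n_significant`, `incomplete`.
#' @export
generationProfiles <- function(occurrence, value_col = "occurred",
                               generations = OFFSPRING_GENERATIONS) {
  assertChoice(value_col, c("occurred", "marginal"), "value_col")
  occ <- occurrence[occurrence$generation %in% generations, , drop = FALSE]
  key <- unique(occ[, c("genotype", "treatment", "phenotype", "test")])
  rownames(key) <- NULL
  m <- matrix(NA_integer_, nrow(key), length(generations),
              dimnames = list(NULL, generations))
  kid <- paste(occ$genotype, occ$treatment, occ$phenotype, occ$test,
               sep = "\r")
  kid_key <- paste(key$genotype, key$treatment, key$phenotype, key$test,
                   sep = "\r")
  for (j in seq_along(generations)) {
    rows <- occ[occ$generation == generations[j], , drop = FALSE]
    idx <- match(paste(rows$genotype, rows$treatment, rows$phenotype,
                       rows$test, sep = "\r"), kid_key)
    m[idx, j] <- rows[[value_col]]
  }
  key$incomplete <- apply(m, 1L, anyNA)
  m[is.na(m)] <- 0L
  out <- cbind(key[, c("genotype", "treatment", "phenotype", "test")],
               as.data.frame(m), key["incomplete"])
  out$n_significant <- rowSums(m)
  out
}

#' Classify induced changes by their cross-generation occurrence
#'
#' A change occurring in no generation is `none`; in exactly one,
#' `transient`; in at least two, `heritable`; `persistent` additionally
#' requires at least three significant generations with the final generation
#' among them (or, with `persistent = "all_four"`, significance in every
#' generation); `four_generation` means significant throughout. Categories
#' nest: four_generation implies persistent implies heritable.
#'
#' @param profiles table from [generationProfiles()].
#' @param persistent `"three_plus_final"` (default) or `"all_four"`.
#' @param generations ordered generation columns.
#' @return `profiles` with a `category` factor added (the most specific
#'   label) and logical columns `heritable`, `persistent`, `four_generation`.
#' @export
classifyHeritability <- function(profiles,
                                 persistent = c("three_plus_final",
                                                "all_four"),
                                 generations = OFFSPRING_GENERATIONS) {
  persistent <- match.arg(persistent)
  m <- as.matrix(profiles[, generations, drop = FALSE])
  n_sig <- rowSums(m)
  final <- m[, length(generations)]
  four <- n_sig == length(generations)
  pers <- if (persistent == "all_four") four
          else n_sig >= 3L & final == 1L
  herit <- n_sig >= 2L
  cat <- rep("none", nrow(profiles))
  cat[n_sig == 1L] <- "transient"
  cat[herit] <- "heritable"
  cat[pers] <- "persistent"
  cat[four] <- "four_generation"
  profiles$category <- factor(cat, levels = c("none", "transient",
                                              "heritable", "persistent",
                                              "four_generation"))
  profiles$heritable <- herit
  profiles$persistent <- pers
  profiles$four_generation <- four
  profiles
}

#' Fractions of induced changes occurring in 2, 3 and 4 generations
#'
#' Denominator: keys with at least one significant generation.
#'
#' @param profiles table from [generationProfiles()].
#' @param generations ordered generation columns.
#' @return Named numeric vector `two`, `three`, `four`.
#' @export
proportionSummary <- function(profiles,
                              generations = OFFSPRING_GENERATIONS) {
  n_sig <- rowSums(as.matrix(profiles[, generations, drop = FALSE]))
  denom <- sum(n_sig >= 1L)
  if (denom == 0L)
    stop("no key has any significant generation; proportions undefined",
         call. = FALSE)
  c(two = sum(n_sig == 2L), three = sum(n_sig == 3L),
    four = sum(n_sig == 4L)) / denom
}

#' Occurrence frequency (mean and SE) within groups
#'
#' Mean of the 0/1 occurrence per group with the SE computed from the
#' between-unit variation within the group.
#'
#' @param occurrence table from [effectsToOccurrence()].
#' @param by grouping column(s): any of `genotype`, `treatment`,
#'   `generation`, `phenotype`, `test`.
#' @param value_col `"occurred"` or `"marginal"`.
#' @return data.frame with the grouping columns, `frequency`, `se`, `n`.
#' @export
occurrenceFrequency <- function(occurrence, by = "genotype",
                                value_col = "occurred") {
  stopifnot(all(by %in% names(occurrence)))
  x <- occurrence[[value_col]]
  g <- interaction(occurrence[by], drop = TRUE, sep = "\r")
  freq <- tapply(x, g, mean)
  n <- tapply(x, g, length)
  se <- tapply(x, g, function(v)
    if (length(v) > 1L) sd(v) / sqrt(length(v)) else 0)
  keys <- do.call(rbind, strsplit(names(freq), "\r", fixed = TRUE))
  out <- as.data.frame(keys, stringsAsFactors = FALSE)
  names(out) <- by
  out$frequency <- as.numeric(freq)
  out$se <- as.numeric(se)
  out$n <- as.integer(n)
  rownames(out) <- NULL
  out
}
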