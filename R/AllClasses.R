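#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom GenomicRanges GRanges
NULL

#' HeritDesign: a multigenerational single-seed-descent design
#'
#' Holds the experimental lines (one per genotype x ancestral environment x
#' replicate) together with the randomized growth-room position of every
#' plant in every generation.
#'
#' @slot spec list; the design specification (see [designSpec()]).
#' @slot lines data.frame with columns `line_id`, `genotype`,
#'   `ancestral_env`, `replicate`.
#' @slot positions data.frame with columns `generation`, `line_id`, `layer`,
#'   `row`, `column`. Row numbers are unique across layers.
#' @slot seed integer seed used for the randomization.
#' @export
setClass("HeritDesign",
         representation(spec = "list", lines = "data.frame",
                        positions = "data.frame", seed = "integer"))

setValidity("HeritDesign", function(object) {
  msg <- character()
  ln <- object@lines
  if (!all(c("line_id", "genotype", "ancestral_env", "replicate") %in%
           names(ln)))
    msg <- c(msg, "lines must have line_id, genotype, ancestral_env, replicate")
  else if (anyDuplicated(ln$line_id))
    msg <- c(msg, "line_id values must be unique")
  pos <- object@positions
  if (!all(c("generation", "line_id", "layer", "row", "column") %in%
           names(pos)))
    msg <- c(msg, "positions must have generation, line_id, layer, row, column")
  else {
    dup <- duplicated(pos[, c("generation", "layer", "row", "column")])
    if (any(dup))
      msg <- c(msg, "two plants assigned to the same grid cell in a generation")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn HeritDesign lines table accessor.
#' @param object,x a `HeritDesign`.
#' @export
setGeneric("designLines", function(object) standardGeneric("designLines"))

#' @rdname HeritDesign
#' @export
setMethod("designLines", "HeritDesign", function(object) object@lines)

#' @describeIn HeritDesign per-generation position assignments.
#' @export
setGeneric("designPositions",
           function(object) standardGeneric("designPositions"))

#' @rdname HeritDesign
#' @export
setMethod("designPositions", "HeritDesign", function(object) object@positions)

setMethod("show", "HeritDesign", function(object) {
  ln <- object@lines
  cat("HeritDesign:", nrow(ln), "lines,",
      length(unique(ln$genotype)), "genotypes,",
      length(setdiff(unique(ln$ancestral_env), object@spec$control_label)),
      "treatments\n")
  cat("  generations:",
      paste(unique(object@positions$generation), collapse = ", "), "\n")
  cat("  grid:", object@spec$n_layers, "layers x", object@spec$n_rows,
      "rows x", object@spec$n_columns, "columns\n")
})

#' GenomeAnnotation: gene and transposon intervals on shared chromosomes
#'
#' A light container for a strand-aware gene annotation plus a transposable
#' element (TE) annotation labelled by superfamily, both as
#' [GenomicRanges::GRanges] on the same seqinfo. Coordinates follow the GFF3
#' convention (1-based, closed).
#'
#' @slot genes GRanges named by `gene_id`.
#' @slot transposons GRanges with a `superfamily` metadata column.
#' @export
setClass("GenomeAnnotation",
         representation(genes = "GRanges", transposons = "GRanges"))

setValidity("GenomeAnnotation", function(object) {
  msg <- character()
  g <- object@genes; te <- object@transposons
  if (is.null(names(g)) || anyDuplicated(names(g)))
    msg <- c(msg, "genes must carry unique gene_id names")
  if (length(g) &&
      !all(as.character(GenomicRanges::strand(g)) %in% c("+", "-")))
    msg <- c(msg, "gene strand must be + or -")
  if (!"superfamily" %in% names(S4Vectors::mcols(te)))
    msg <- c(msg, "transposons must have a 'superfamily' metadata column")
  for (gr in list(g, te)) {
    sl <- GenomeInfoDb::seqlengths(gr)
    if (length(gr) && any(GenomicRanges::start(gr) < 1))
      msg <- c(msg, "intervals must be 1-based (start >= 1)")
    if (length(gr) && !anyNA(sl)) {
      lim <- sl[as.character(GenomeInfoDb::seqnames(gr))]
      if (any(GenomicRanges::end(gr) > lim))
        msg <- c(msg, "interval end beyond chromosome length")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeAnnotation
#'
#' @param genes `GRanges` of gene bodies, named by gene id (or carrying a
#'   `gene_id` metadata column).
#' @param transposons `GRanges` of TE copies with a `superfamily` column.
#' @return A [GenomeAnnotation-class] object.
#' @export
GenomeAnnotation <- function(genes, transposons) {
  if (is.null(names(genes)) && "gene_id" %in% names(S4Vectors::mcols(genes)))
    names(genes) <- S4Vectors::mcols(genes)$gene_id
  new("GenomeAnnotation", genes = genes, transposons = transposons)
}

#' @describeIn GenomeAnnotation gene intervals.
#' @param object,x a `GenomeAnnotation`.
#' @export
setGeneric("annotGenes", function(object) standardGeneric("annotGenes"))

#' @rdname GenomeAnnotation
#' @export
setMethod("annotGenes", "GenomeAnnotation", function(object) object@genes)

#' @describeIn GenomeAnnotation TE intervals.
#' @export
setGeneric("transposons", function(object) standardGeneric("transposons"))

#' @rdname GenomeAnnotation
#' @export
setMethod("transposons", "GenomeAnnotation", function(object)
  object@transposons)

setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation:", length(object@genes), "genes,",
      length(object@transposons), "TEs on",
      length(GenomeInfoDb::seqlevels(object@genes)), "chromosome(s)\n")
  sf <- table(S4Vectors::mcols(object@transposons)$superfamily)
  if (length(sf))
    cat("  superfamilies:",
        paste(names(sf), sf, sep = "=", collapse = ", "), "\n")
})

#' TransgenCounts: gene expression counts over a transgenerational design
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass whose `counts`
#' assay holds non-negative integer counts and whose column data identify
#' each sample's genotype, ancestral treatment, offspring generation and
#' replicate.
#'
#' @export
setClass("TransgenCounts", contains = "SummarizedExperiment")

setValidity("TransgenCounts", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  m <- SummarizedExperiment::assay(object, "counts")
  if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
  if (any(m != round(m))) msg <- c(msg, "counts must be integers")
  need <- c("genotype", "treatment", "generation", "replicate")
  cd <- SummarizedExperiment::colData(object)
  miss <- setdiff(need, names(cd))
  if (length(miss))
    msg <- c(msg, paste("missing sample annotation column(s):",
                        paste(miss, collapse = ", ")))
  else if (any(vapply(need, function(k) anyNA(cd[[k]]), logical(1))))
    msg <- c(msg, "sample annotations must be complete (no NA)")
  if (length(msg)) msg else TRUE
})

#' Construct a TransgenCounts object
#'
#' @param counts integer matrix, genes x samples; rownames are gene ids and
#'   colnames sample ids.
#' @param samples data.frame of sample annotations (one row per column of
#'   `counts`) with at least `genotype`, `treatment`, `generation`,
#'   `replicate`.
#' @return A [TransgenCounts-class] object.
#' @export
TransgenCounts <- function(counts, samples) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (!is.null(samples$sample_id)) rownames(samples) <- samples$sample_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(samples))
  new("TransgenCounts", se)
}

#' @describeIn TransgenCounts the raw count matrix.
#' @param object a `TransgenCounts`.
#' @export
setGeneric("countMatrix", function(object) standardGeneric("countMatrix"))

#' @rdname TransgenCounts
#' @export
setMethod("countMatrix", "TransgenCounts", function(object)
  SummarizedExperiment::assay(object, "counts"))

#' @describeIn TransgenCounts the sample sheet as a plain data.frame.
#' @export
setGeneric("sampleSheet", function(object) standardGeneric("sampleSheet"))

#' @rdname TransgenCounts
#' @export
setMethod("sampleSheet", "TransgenCounts", function(object) {
  df <- as.data.frame(SummarizedExperiment::colData(object))
  df$sample_id <- colnames(object)
  df
})
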