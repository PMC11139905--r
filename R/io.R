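## TSV writers stamp the provenance (package version, seed, config hash)
## into comment lines; readers skip comments.
.writeTSV <- function(df, path, seed = NULL, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# heritvar %s", as.character(packageVersion("heritvar"))),
             con)
  if (!is.null(seed) || !is.null(config_hash))
    writeLines(sprintf("# seed=%s config=%s",
                       seed %||% "NA", config_hash %||% "NA"), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readTSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Read and validate a long-format phenotype table
#'
#' Expects the schema written by [writePhenotypes()] (header matching is
#' case-insensitive): `line_id`, `genotype`, `ancestral_env`, `test`,
#' `generation`, `layer`, `row`, `column`, `anc_layer`, `anc_row` and the
#' five phenotype columns. Non-numeric phenotype entries and negative fruit
#' numbers are schema errors naming the offending rows.
#'
#' @param path TSV file.
#' @return Validated phenotype data.frame.
#' @export
readPhenotypes <- function(path) {
  df <- .readTSV(path)
  names(df) <- tolower(names(df))
  need <- c("line_id", "genotype", "ancestral_env", "test", "generation",
            "layer", "row", "column", "anc_layer", "anc_row", PHENOTYPES)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phenotype table missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (ph in PHENOTYPES) {
    v <- suppressWarnings(as.numeric(df[[ph]]))
    bad <- which(!is.na(df[[ph]]) & df[[ph]] != "" & is.na(v))
    if (length(bad))
      stop("non-numeric '", ph, "' at data row(s): ",
           paste(head(bad), collapse = ", "), call. = FALSE)
    df[[ph]] <- v
  }
  neg <- which(!is.na(df$fruit_number) & df$fruit_number < 0)
  if (length(neg))
    stop("negative fruit_number at data row(s): ",
         paste(head(neg), collapse = ", "), call. = FALSE)
  if (!"replaced" %in% names(df)) df$replaced <- FALSE
  message("read ", nrow(df), " phenotype records from ", path)
  df
}

#' Write a phenotype table
#' @param pheno phenotype data.frame.
#' @param path output TSV.
#' @param seed,config_hash optional provenance stamped into the header.
#' @return The path, invisibly.
#' @export
writePhenotypes <- function(pheno, path, seed = NULL, config_hash = NULL) {
  invisible(.writeTSV(pheno, path, seed, config_hash))
}

#' Read a count matrix and sample sheet
#'
#' The count TSV has gene ids in the first column (`gene_id`) and one
#' integer column per sample; the sample sheet TSV has `sample_id`,
#' `genotype`, `treatment`, `generation`, `replicate`. Non-integer or
#' negative entries are schema errors.
#'
#' @param counts_path,samples_path TSV files.
#' @return A [TransgenCounts-class] object.
#' @export
readCounts <- function(counts_path, samples_path) {
  cm <- .readTSV(counts_path)
  ss <- .readTSV(samples_path)
  gene_ids <- cm[[1]]
  m <- as.matrix(cm[, -1, drop = FALSE])
  if (!is.numeric(m) || any(is.na(m)))
    stop("count matrix contains non-numeric entries", call. = FALSE)
  if (any(m != round(m)))
    stop("count matrix contains non-integer entries", call. = FALSE)
  if (any(m < 0))
    stop("count matrix contains negative entries", call. = FALSE)
  rownames(m) <- gene_ids
  need <- c("sample_id", "genotype", "treatment", "generation", "replicate")
  miss <- setdiff(need, names(ss))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  absent <- setdiff(colnames(m), ss$sample_id)
  if (length(absent))
    stop("samples without annotation: ", paste(absent, collapse = ", "),
         call. = FALSE)
  ss <- ss[match(colnames(m), ss$sample_id), ]
  message("read ", nrow(m), " genes x ", ncol(m), " samples")
  TransgenCounts(m, ss)
}

#' Write a count matrix and its sample sheet
#' @param x a [TransgenCounts-class] object.
#' @param counts_path,samples_path output TSVs.
#' @param seed,config_hash optional provenance.
#' @return The count path, invisibly.
#' @export
writeCounts <- function(x, counts_path, samples_path, seed = NULL,
                        config_hash = NULL) {
  m <- countMatrix(x)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  .writeTSV(df, counts_path, seed, config_hash)
  .writeTSV(sampleSheet(x), samples_path, seed, config_hash)
  invisible(counts_path)
}

#' Write a GenomeAnnotation as GFF3 (and optionally BED6)
#'
#' Genes are written as `type=gene` features with `ID`; TEs as
#' `type=transposable_element` with `ID` and a `superfamily` attribute.
#'
#' @param annotation a [GenomeAnnotation-class] object.
#' @param gff_path output GFF3 file.
#' @param bed_prefix if given, also writes `<prefix>_genes.bed` and
#'   `<prefix>_tes.bed` (BED6; TE names are `te_id|superfamily`).
#' @return The GFF3 path, invisibly.
#' @export
writeAnnotation <- function(annotation, gff_path, bed_prefix = NULL) {
  g <- annotGenes(annotation)
  S4Vectors::mcols(g) <- S4Vectors::DataFrame(type = "gene", ID = names(g))
  te <- transposons(annotation)
  sf <- S4Vectors::mcols(te)$superfamily
  ids <- S4Vectors::mcols(te)$te_id %||% sprintf("te%05d", seq_along(te))
  S4Vectors::mcols(te) <- S4Vectors::DataFrame(type = "transposable_element",
                                               ID = ids, superfamily = sf)
  rtracklayer::export(c(g, te), gff_path, format = "gff3")
  if (!is.null(bed_prefix)) {
    gb <- g; S4Vectors::mcols(gb) <- S4Vectors::DataFrame(name = names(g))
    teb <- te
    S4Vectors::mcols(teb) <- S4Vectors::DataFrame(name = paste(ids, sf,
                                                               sep = "|"))
    rtracklayer::export(gb, paste0(bed_prefix, "_genes.bed"),
                        format = "bed")
    rtracklayer::export(teb, paste0(bed_prefix, "_tes.bed"), format = "bed")
  }
  invisible(gff_path)
}

#' Read a GenomeAnnotation from GFF3
#'
#' Accepts `gene` and `transposable_element` features; the TE superfamily
#' is taken from the `superfamily` attribute. Zero or negative start
#' coordinates are rejected (GFF3 is 1-based).
#'
#' @param path GFF3 file.
#' @return A [GenomeAnnotation-class] object.
#' @export
readAnnotation <- function(path) {
  ## reject 0-based coordinates before import (GFF3 is 1-based)
  raw <- readLines(path)
  body <- raw[!startsWith(raw, "#") & nzchar(raw)]
  starts <- suppressWarnings(as.numeric(vapply(strsplit(body, "\t"),
                                               `[`, "", 4L)))
  if (any(!is.na(starts) & starts < 1))
    stop("GFF3 start coordinates must be >= 1 (1-based convention)",
         call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  g <- gr[type == "gene"]
  names(g) <- g$ID
  S4Vectors::mcols(g) <- S4Vectors::DataFrame(gene_id = g$ID %||% names(g))
  te <- gr[type == "transposable_element"]
  S4Vectors::mcols(te) <- S4Vectors::DataFrame(
    te_id = te$ID, superfamily = te$superfamily)
  message("read ", length(g), " genes and ", length(te), " TEs from ", path)
  GenomeAnnotation(g, te)
}

#' Read / write genotype metadata tables
#' @param path TSV file with `genotype` plus numeric predictor columns.
#' @return data.frame.
#' @export
readMetadata <- function(path) {
  df <- .readTSV(path)
  if (!"genotype" %in% names(df))
    stop("metadata table must have a 'genotype' column", call. = FALSE)
  df
}

#' @rdname readMetadata
#' @param metadata data.frame.
#' @param seed,config_hash optional provenance.
#' @export
writeMetadata <- function(metadata, path, seed = NULL, config_hash = NULL) {
  invisible(.writeTSV(metadata, path, seed, config_hash))
}

#' Read a curated gene list (one id per line)
#' @param path text file; blank lines and `#` comments are ignored.
#' @return Character vector of gene ids.
#' @export
readGeneList <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
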