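#' Read a genotype matrix from a plain-text file
#'
#' Two dialects are supported:
#' * `"matrix"`: a headerless whitespace- or comma-separated matrix of
#'   0/1/2 codes with `NA` for missing; optional sidecar files (same path
#'   plus `.animals` / `.snps`) supply identifiers, one per line.
#' * `"raw"`: the PLINK `.raw` dialect — a header row, six leading metadata
#'   columns (`FID IID PAT MAT SEX PHENOTYPE`), then one column per SNP.
#'
#' @param path File path.
#' @param format `"matrix"` or `"raw"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("matrix", "raw")) {
  format <- match.arg(format)
  if (format == "raw") {
    df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 7L) stop("PLINK .raw file needs 6 metadata columns plus SNPs")
    codes <- as.matrix(df[, -(1:6), drop = FALSE])
    storage.mode(codes) <- "double"
    return(genotype_matrix(codes, animal_ids = as.character(df[[2L]]),
                           snp_ids = colnames(df)[-(1:6)]))
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  codes <- as.matrix(utils::read.table(path, header = FALSE, sep = sep,
                                       na.strings = c("NA", "na")))
  storage.mode(codes) <- "double"
  animal_ids <- snp_ids <- NULL
  af <- paste0(path, ".animals")
  sf <- paste0(path, ".snps")
  if (file.exists(af)) animal_ids <- readLines(af)
  if (file.exists(sf)) snp_ids <- readLines(sf)
  genotype_matrix(codes, animal_ids = animal_ids, snp_ids = snp_ids)
}

#' Write a genotype matrix in the headerless matrix dialect
#'
#' Writes the 0/1/2 code matrix as comma-separated values with `NA` for
#' missing calls, plus `.animals` and `.snps` sidecar identifier files.
#'
#' @param g A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  utils::write.table(unclass(g), path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "NA")
  writeLines(rownames(g), paste0(path, ".animals"))
  writeLines(colnames(g), paste0(path, ".snps"))
  invisible(path)
}

#' Write a genomic relationship matrix as dense CSV
#'
#' Animal identifiers form both the header row and the first column.
#'
#' @param grm A `relationship_matrix` (from [compute_grm()]) or a plain
#'   symmetric matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grm <- function(grm, path) {
  A <- if (inherits(grm, "relationship_matrix")) grm$A else as.matrix(grm)
  df <- data.frame(animal_id = rownames(A), A, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a genomic relationship matrix written by [write_grm()]
#'
#' @param path File path.
#' @return A numeric matrix with animal identifiers as dimnames.
#' @export
read_grm <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  A <- as.matrix(df[, -1L, drop = FALSE])
  rownames(A) <- as.character(df[[1L]])
  A
}

#' Write a phenotype table
#'
#' Columns: `animal_id`, then one column per trait.
#'
#' @param y n x t phenotype matrix with animal row names and trait column
#'   names.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(y, path) {
  y <- as.matrix(y)
  if (is.null(rownames(y))) rownames(y) <- paste0("A", seq_len(nrow(y)))
  if (is.null(colnames(y))) colnames(y) <- paste0("trait_", seq_len(ncol(y)))
  df <- data.frame(animal_id = rownames(y), y, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table written by [write_phenotypes()]
#'
#' @param path File path.
#' @return A numeric matrix, animals in rows, traits in columns.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  y <- as.matrix(df[, -1L, drop = FALSE])
  rownames(y) <- as.character(df[[1L]])
  y
}
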