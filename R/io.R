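# Readers and writers for the plain-text interchange formats: IV tables,
# LD matrices, single-nucleus references (MatrixMarket + metadata TSVs),
# expression sets and cohort tables.

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read an IV summary-statistic table
#'
#' Tab-separated with columns `variant_id`, `beta_exp`, `se_exp`, `p_exp`,
#' `beta_out`, `se_out` and any `p_<confounder>` columns.
#'
#' @param ivs IV table.
#' @param path file path.
#' @return `write_iv_table` the path, invisibly; `read_iv_table` the table.
#' @export
write_iv_table <- function(ivs, path) {
  validate_iv_table(ivs, min_n = 0L)
  write_tsv(ivs, path)
}

#' @rdname write_iv_table
#' @export
read_iv_table <- function(path) {
  ivs <- read_tsv(path)
  validate_iv_table(ivs, min_n = 0L)
  ivs
}

#' Write / read an LD matrix as TSV
#'
#' @param ld an `ld_matrix`.
#' @param path file path.
#' @export
write_ld_matrix <- function(ld, path) {
  m <- as.data.frame(ld$r2)
  m <- cbind(variant_id = ld$variant_ids, m)
  write_tsv(m, path)
}

#' @rdname write_ld_matrix
#' @export
read_ld_matrix <- function(path) {
  d <- read_tsv(path)
  ids <- d$variant_id
  r2 <- as.matrix(d[, -1, drop = FALSE])
  dimnames(r2) <- list(ids, ids)
  structure(list(variant_ids = ids, r2 = r2), class = "ld_matrix")
}

#' Write / read a single-nucleus reference (MatrixMarket + metadata)
#'
#' Writes `matrix.mtx` (cells x genes), `cells.tsv` (barcode, subject,
#' cluster) and `genes.tsv` (gene annotation) into `dir`.
#'
#' @param ref an `sc_reference`.
#' @param dir output directory (created if needed).
#' @export
write_sc_reference <- function(ref, dir) {
  stopifnot(inherits(ref, "sc_reference"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(ref$counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  write_tsv(ref$cell_meta, file.path(dir, "cells.tsv"))
  if (!is.null(ref$genes)) write_tsv(ref$genes, file.path(dir, "genes.tsv"))
  invisible(dir)
}

#' @rdname write_sc_reference
#' @export
read_sc_reference <- function(dir) {
  counts <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  cell_meta <- read_tsv(file.path(dir, "cells.tsv"))
  genes_path <- file.path(dir, "genes.tsv")
  genes <- if (file.exists(genes_path)) read_tsv(genes_path) else NULL
  counts <- methods::as(counts, "CsparseMatrix")
  dimnames(counts) <- list(cell_meta$barcode,
                           if (!is.null(genes)) genes$gene_id else NULL)
  structure(list(counts = counts, cell_meta = cell_meta, genes = genes),
            class = "sc_reference")
}

#' Write / read an expression set as gene x sample TSV
#'
#' The counts table is written with the gene annotation columns first, then
#' one column per sample.
#'
#' @param es an `expression_set`.
#' @param path file path.
#' @export
write_expression_set <- function(es, path) {
  stopifnot(inherits(es, "expression_set"))
  write_tsv(cbind(es$genes, as.data.frame(es$counts)), path)
}

#' @rdname write_expression_set
#' @export
read_expression_set <- function(path) {
  d <- read_tsv(path)
  anno_cols <- intersect(c("gene_id", "name", "length", "is_MT",
                           "is_discordant"), names(d))
  genes <- d[, anno_cols, drop = FALSE]
  counts <- as.matrix(d[, setdiff(names(d), anno_cols), drop = FALSE])
  rownames(counts) <- genes$gene_id
  expression_set(counts, genes)
}

#' Write / read a cohort phenotype table
#'
#' @param cohort cohort data frame.
#' @param path file path.
#' @export
write_cohort_table <- function(cohort, path) {
  write_tsv(cohort, path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  read_tsv(path)
}
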