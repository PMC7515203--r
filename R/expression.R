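# Bulk expression handling: TPM, mitochondrial expression, bias-aware
# technical metrics, rank-based inverse normal transform, residualization
# and group comparisons.

#' Construct a gene-by-sample expression set
#'
#' A light container tying a count matrix to its gene annotation (lengths in
#' bp and a mitochondrial flag) with TPM derived on construction.
#'
#' @param counts gene x sample matrix of nonnegative counts, rownames = gene
#'   ids.
#' @param genes data frame with `gene_id`, `length` (bp) and logical `is_MT`
#'   (extra columns such as `is_discordant` are carried along).
#' @return A list of class `expression_set` with `counts`, `tpm`, `genes`
#'   and `samples`.
#' @export
expression_set <- function(counts, genes) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_bad("counts must be nonnegative")
  if (!all(c("gene_id", "length") %in% names(genes))) {
    stop_bad("`genes` needs `gene_id` and `length` columns")
  }
  if (!"is_MT" %in% names(genes)) genes$is_MT <- FALSE
  idx <- match(rownames(counts), genes$gene_id)
  if (anyNA(idx)) stop_bad("count rownames must all appear in `genes`")
  genes <- genes[idx, , drop = FALSE]
  rownames(genes) <- NULL
  structure(
    list(
      counts = counts,
      tpm = compute_tpm(counts, genes$length),
      genes = genes,
      samples = colnames(counts)
    ),
    class = "expression_set"
  )
}

#' Transcripts per million from counts and gene lengths
#'
#' `tpm[g, s] = (counts[g, s] / length_kb[g]) / sum_g(counts / length_kb) *
#' 1e6`; every column sums to one million, so TPM is invariant to uniform
#' scaling of a sample's counts.
#'
#' @param counts gene x sample count matrix.
#' @param gene_lengths per-gene lengths in bp (> 0).
#' @return TPM matrix with the same dimnames.
#' @export
compute_tpm <- function(counts, gene_lengths) {
  counts <- as.matrix(counts)
  if (length(gene_lengths) != nrow(counts)) {
    stop_bad("`gene_lengths` must have one entry per gene")
  }
  if (any(gene_lengths <= 0)) stop_bad("gene lengths must be positive")
  rate <- counts / (gene_lengths / 1000)
  depth <- colSums(rate)
  bad <- which(depth == 0)
  if (length(bad)) {
    nm <- if (!is.null(colnames(counts))) colnames(counts)[bad] else bad
    stop_bad("zero-depth sample(s): %s", paste(nm, collapse = ", "))
  }
  sweep(rate, 2, depth, "/") * 1e6
}

#' Mitochondrial gene expression per sample
#'
#' Defined as the sum of TPM over all mitochondrially encoded genes.
#'
#' @param tpm gene x sample TPM matrix (or an `expression_set`).
#' @param is_MT logical flag per gene (ignored for an `expression_set`).
#' @return Named numeric vector, one value per sample.
#' @export
mt_expression <- function(tpm, is_MT = NULL) {
  if (inherits(tpm, "expression_set")) {
    is_MT <- tpm$genes$is_MT
    tpm <- tpm$tpm
  }
  if (is.null(is_MT) || length(is_MT) != nrow(tpm)) {
    stop_bad("`is_MT` must flag every gene")
  }
  if (!any(is_MT)) stop_bad("no mitochondrial genes are flagged")
  colSums(tpm[is_MT, , drop = FALSE])
}

#' Read-category metrics with and without mitochondrial reads
#'
#' Mitochondrial transcripts can dominate a bulk library, so alignment
#' metrics computed over all reads are confounded with MT expression (a high
#' MT fraction deflates every nuclear category's percentage). The unbiased
#' versions remove MT reads from the denominator: each nuclear category is
#' expressed as a fraction of nuclear (non-MT) aligned reads. Both versions
#' are returned, alongside the MT read percentage itself.
#'
#' @param rc data frame with per-sample columns `exonic`, `intronic`,
#'   `intergenic`, `mt_aligned`, `total_aligned` (and optionally an id
#'   column, carried through).
#' @return Data frame with `<cat>_pct_biased`, `<cat>_pct` (MT-excluded) for
#'   each nuclear category and `mt_read_pct`.
#' @export
rna_metrics_excluding_mt <- function(rc) {
  cats <- c("exonic", "intronic", "intergenic")
  need <- c(cats, "mt_aligned", "total_aligned")
  missing <- setdiff(need, names(rc))
  if (length(missing)) {
    stop_bad("read-category table is missing: %s",
             paste(missing, collapse = ", "))
  }
  if (any(rc$mt_aligned > rc$total_aligned)) {
    stop_bad("mt_aligned exceeds total_aligned")
  }
  nuclear <- rc$total_aligned - rc$mt_aligned
  if (any(nuclear == 0)) stop_bad("sample(s) with no nuclear reads")
  out <- data.frame(row.names = seq_len(nrow(rc)))
  if ("id" %in% names(rc)) out$id <- rc$id
  for (cat in cats) {
    out[[paste0(cat, "_pct_biased")]] <- 100 * rc[[cat]] / rc$total_aligned
    out[[paste0(cat, "_pct")]] <- 100 * rc[[cat]] / nuclear
  }
  out$mt_read_pct <- 100 * rc$mt_aligned / rc$total_aligned
  out
}

#' Rank-based inverse normal transform
#'
#' Maps values to standard-normal quantiles via
#' `qnorm((rank - c) / (n - 2c + 1))` with the Blom constant `c = 3/8`; ties
#' receive their average rank.
#'
#' @param values numeric vector (n >= 2, not all identical).
#' @return Transformed vector, strictly monotone in the input up to ties.
#' @export
inverse_normal_transform <- function(values) {
  if (length(values) < 2L) stop_bad("need at least 2 values")
  if (anyNA(values)) stop_bad("missing values are not allowed")
  if (diff(range(values)) == 0) {
    stop_bad("all values identical: ranks are degenerate")
  }
  n <- length(values)
  r <- rank(values, ties.method = "average")
  qnorm((r - 3 / 8) / (n + 0.25))
}

#' Residualize a variable on covariates by ordinary least squares
#'
#' Fits `y ~ 1 + covariates` and returns the residuals; these are orthogonal
#' to every covariate column. Rank-deficient designs are rejected with the
#' offending columns named.
#'
#' @param y numeric response.
#' @param covariates matrix or data frame of covariates (may be `NULL` /
#'   zero columns, in which case `y - mean(y)` is returned).
#' @return Residual vector of the same length as `y`.
#' @export
residualize <- function(y, covariates = NULL) {
  y <- as.numeric(y)
  if (is.null(covariates) || NCOL(covariates) == 0L) return(y - mean(y))
  X <- as.matrix(covariates)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(y)) stop_bad("`covariates` rows must match `y`")
  Xi <- cbind(`(Intercept)` = 1, X)
  qr_x <- qr(Xi)
  if (qr_x$rank < ncol(Xi)) {
    dropped <- colnames(Xi)[qr_x$pivot[(qr_x$rank + 1):ncol(Xi)]]
    stop_bad("rank-deficient covariates; collinear column(s): %s",
             paste(dropped, collapse = ", "))
  }
  as.numeric(qr.resid(qr_x, y))
}

#' Welch two-sample comparison of a quantitative value between groups
#'
#' @param values numeric vector.
#' @param group_labels factor-like with exactly two levels, each with at
#'   least 2 observations.
#' @return A list with `t`, `p` and the per-group means.
#' @export
group_difference_test <- function(values, group_labels) {
  g <- factor(group_labels)
  if (nlevels(g) != 2L) stop_bad("need exactly two groups")
  if (any(table(g) < 2L)) stop_bad("each group needs at least 2 values")
  vs <- tapply(values, g, var)
  ms <- tapply(values, g, mean)
  if (all(vs == 0)) {
    # degenerate: no within-group variation
    return(list(t = if (ms[1] == ms[2]) 0 else Inf,
                p = if (ms[1] == ms[2]) 1 else 0,
                means = setNames(as.numeric(ms), levels(g))))
  }
  fit <- t.test(values ~ g)
  list(
    t = unname(fit$statistic),
    p = fit$p.value,
    means = setNames(as.numeric(tapply(values, g, mean)), levels(g))
  )
}
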