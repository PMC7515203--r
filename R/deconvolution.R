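# Cell-type deconvolution of bulk RNA-seq against a single-nucleus
# reference: QC, signature genes, pseudo-bulk profiles, a bulk/pseudo-bulk
# concordance filter for pre-mRNA-discordant genes, cross-subject-variance
# weighted NNLS, and leave-one-out validation.

#' Quality-control a single-nucleus reference
#'
#' Applies the thresholds in order: first cells with fewer than `min_genes`
#' expressed genes are removed, then genes expressed in fewer than
#' `min_cells` of the remaining cells.
#'
#' @param x an `sc_reference` (from [simulate_sc_reference()]) or a cell x
#'   gene count matrix.
#' @param cell_meta data frame with `barcode`, `subject`, `cluster` rows
#'   aligned to the counts (taken from `x` when it is an `sc_reference`).
#' @param min_genes minimum expressed genes per retained cell.
#' @param min_cells minimum expressing cells per retained gene.
#' @return An `sc_reference` list with filtered `counts`, `cell_meta`,
#'   `genes` (if present) and a `qc` report of removed counts.
#' @export
qc_reference <- function(x, cell_meta = NULL, min_genes = 300L,
                         min_cells = 3L) {
  if (inherits(x, "sc_reference")) {
    counts <- x$counts
    cell_meta <- x$cell_meta
    genes <- x$genes
    truth <- x$truth
  } else {
    counts <- x
    genes <- NULL
    truth <- NULL
  }
  if (is.null(cell_meta) || nrow(cell_meta) != nrow(counts)) {
    stop_bad("`cell_meta` must have one row per cell")
  }
  expressed <- Matrix::rowSums(counts > 0)
  keep_cells <- expressed >= min_genes
  counts <- counts[keep_cells, , drop = FALSE]
  cell_meta <- cell_meta[keep_cells, , drop = FALSE]
  n_expr_cells <- Matrix::colSums(counts > 0)
  keep_genes <- n_expr_cells >= min_cells
  counts <- counts[, keep_genes, drop = FALSE]
  if (!is.null(genes)) genes <- genes[keep_genes, , drop = FALSE]
  if (nrow(counts) == 0L || ncol(counts) == 0L) {
    stop_bad("QC removed every cell or gene")
  }
  structure(
    list(counts = counts, cell_meta = cell_meta, genes = genes,
         truth = truth,
         qc = list(cells_removed = sum(!keep_cells),
                   genes_removed = sum(!keep_genes),
                   min_genes = min_genes, min_cells = min_cells)),
    class = "sc_reference"
  )
}

#' True cell-type proportions from cell labels
#'
#' @param cell_meta data frame with `subject` and `cluster` columns (or an
#'   `sc_reference`).
#' @return Subject x cell-type matrix of label frequencies (rows sum to 1).
#' @export
true_proportions <- function(cell_meta) {
  if (inherits(cell_meta, "sc_reference")) cell_meta <- cell_meta$cell_meta
  tab <- table(cell_meta$subject, cell_meta$cluster)
  p <- sweep(unclass(tab), 1, rowSums(tab), "/")
  dimnames(p) <- dimnames(tab)
  p
}

# log2(count / libsize * 1e4 + 1) applied to the nonzero entries of a
# column-sparse matrix (zeros map to zero, preserving sparsity)
normalize_log_sparse <- function(counts, scale = 1e4) {
  X <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  libs <- Matrix::rowSums(X)
  libs[libs == 0] <- 1
  row_of <- X@i + 1L
  X@x <- log2(X@x / libs[row_of] * scale + 1)
  X
}

#' Select cell-type signature genes by one-vs-rest rank-sum tests
#'
#' For each cluster, every gene is tested for higher library-normalized log
#' expression in the cluster versus all other cells using a tie-corrected
#' normal approximation to the Wilcoxon rank-sum statistic. Genes with
#' Benjamini-Hochberg q below `max_p` and log2 fold-change above `min_logfc`
#' are selected and attributed to the cluster where their fold-change is
#' largest. Clusters with fewer than 3 cells are excluded with a warning.
#'
#' @param ref an `sc_reference` (post-QC).
#' @param min_logfc minimum log2 fold-change (cluster mean minus rest mean).
#' @param max_p BH-adjusted p-value threshold.
#' @return Data frame with `gene_id`, `cluster`, `logfc`, `p`, `q`, one row
#'   per selected gene.
#' @export
select_signature_genes <- function(ref, min_logfc = 1, max_p = 0.05) {
  stopifnot(inherits(ref, "sc_reference"))
  clusters <- sort(unique(ref$cell_meta$cluster))
  sizes <- table(ref$cell_meta$cluster)
  small <- names(sizes)[sizes < 3L]
  if (length(small)) {
    warning(sprintf("cluster(s) with < 3 cells excluded: %s",
                    paste(small, collapse = ", ")))
    clusters <- setdiff(clusters, small)
  }
  if (length(clusters) < 2L) stop_bad("need at least 2 usable clusters")

  use_cell <- ref$cell_meta$cluster %in% clusters
  X <- normalize_log_sparse(ref$counts[use_cell, , drop = FALSE])
  labels <- ref$cell_meta$cluster[use_cell]
  n <- nrow(X)
  gene_ids <- colnames(X)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%d", seq_len(ncol(X)))

  code <- match(labels, clusters) - 1L
  st <- ranksum_stats(X@i, X@p, X@x, n, ncol(X), code, length(clusters))
  total_sum <- colSums(st$mean_sum)

  res <- vector("list", length(clusters))
  for (ci in seq_along(clusters)) {
    n1 <- st$cluster_size[ci]
    n2 <- n - n1
    W <- st$W[ci, ]
    mu <- n1 * (n + 1) / 2
    sig2 <- n1 * n2 / 12 * ((n + 1) - st$tie / (n * (n - 1)))
    z <- (W - mu) / sqrt(pmax(sig2, .Machine$double.eps))
    # one-sided (higher in cluster): one-vs-rest enrichment
    p <- pnorm(z, lower.tail = FALSE)
    lfc <- st$mean_sum[ci, ] / n1 - (total_sum - st$mean_sum[ci, ]) / n2
    res[[ci]] <- data.frame(
      gene_id = gene_ids, cluster = clusters[ci], logfc = lfc, p = p,
      q = p.adjust(p, method = "BH"), stringsAsFactors = FALSE,
      row.names = NULL
    )
  }
  all <- do.call(rbind, res)
  hits <- all[all$q < max_p & all$logfc > min_logfc, , drop = FALSE]
  if (!nrow(hits)) return(hits)
  # attribute multi-cluster hits to the cluster with the largest fold-change
  hits <- hits[order(hits$gene_id, -hits$logfc), , drop = FALSE]
  hits <- hits[!duplicated(hits$gene_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Pseudo-bulk expression and cell-type reference profiles
#'
#' Pseudo-bulk sums each subject's counts and rescales to relative
#' expression (parts per million, matching the aggregate-read semantics of a
#' bulk library). Reference profiles hold, per cell type: the mean relative
#' expression across subjects, the cross-subject variance of relative
#' expression, and the mean library size per cell (the cell-size factor used
#' to convert RNA-proportion coefficients into cell-count proportions).
#'
#' @param ref an `sc_reference` (post-QC).
#' @return A list with `pseudobulk` (gene x subject matrix, columns sum to
#'   1e6) and `profiles` (class `reference_profiles`: `theta` K x G mean
#'   relative expression, `sigma2` K x G cross-subject variance, `S` mean
#'   library size per cell type, `celltypes`, `gene_ids`).
#' @export
build_pseudobulk <- function(ref) {
  stopifnot(inherits(ref, "sc_reference"))
  counts <- Matrix::Matrix(ref$counts, sparse = TRUE)
  meta <- ref$cell_meta
  subjects <- sort(unique(meta$subject))
  celltypes <- sort(unique(meta$cluster))
  G <- ncol(counts)
  gene_ids <- colnames(counts)

  # aggregate counts over (subject, cell type) groups in one cross-product
  K <- length(celltypes)
  grp <- (match(meta$subject, subjects) - 1L) * K +
    match(meta$cluster, celltypes)
  ind <- Matrix::sparseMatrix(i = seq_len(nrow(counts)), j = grp, x = 1,
                              dims = c(nrow(counts), length(subjects) * K))
  sums <- as.matrix(Matrix::crossprod(counts, ind))  # G x (J*K)
  n_cells_grp <- Matrix::colSums(ind)

  pb <- sapply(seq_along(subjects), function(j) {
    rowSums(sums[, (j - 1L) * K + seq_len(K), drop = FALSE])
  })
  pb <- sweep(pb, 2, colSums(pb), "/") * 1e6
  dimnames(pb) <- list(gene_ids, subjects)

  theta_js <- array(NA_real_, dim = c(length(subjects), K, G))
  S_js <- matrix(NA_real_, length(subjects), K)
  for (j in seq_along(subjects)) {
    for (k in seq_len(K)) {
      g <- (j - 1L) * K + k
      tot <- sum(sums[, g])
      if (n_cells_grp[g] == 0 || tot == 0) next
      theta_js[j, k, ] <- sums[, g] / tot
      S_js[j, k] <- tot / n_cells_grp[g]
    }
  }
  theta <- apply(theta_js, c(2, 3), mean, na.rm = TRUE)
  sigma2 <- apply(theta_js, c(2, 3), function(v) {
    v <- v[!is.na(v)]
    if (length(v) >= 2) var(v) else 0
  })
  theta[is.nan(theta)] <- 0
  S <- colMeans(S_js, na.rm = TRUE)
  dimnames(theta) <- dimnames(sigma2) <- list(celltypes, gene_ids)
  profiles <- structure(
    list(theta = theta, sigma2 = sigma2, S = setNames(S, celltypes),
         celltypes = celltypes, gene_ids = gene_ids,
         n_subjects = length(subjects)),
    class = "reference_profiles"
  )
  list(pseudobulk = pb, profiles = profiles)
}

#' Bulk / pseudo-bulk concordance filter
#'
#' Computes, per gene, the difference of mean log expression (natural log,
#' +1 offset) between the target bulk samples and the pseudo-bulk samples,
#' standardizes the differences to z-scores, and keeps genes whose squared
#' z (a 1-df chi-square statistic) is at most `threshold`. Genes whose
#' nuclear abundance disagrees with bulk tissue (pre-mRNA rich transcripts
#' such as MALAT1) land far in either tail and are removed.
#'
#' @param bulk_expr gene x sample bulk expression (TPM) with rownames.
#' @param pseudobulk_expr gene x subject pseudo-bulk expression (TPM-like).
#' @param threshold chi-square cutoff (default 1).
#' @return A list with `genes` (kept gene ids) and `stats` (per-gene `d`,
#'   `z`, `chi_sq`, `kept`). If the differences are all identical the filter
#'   is degenerate: every gene is kept with a warning.
#' @export
concordance_filter <- function(bulk_expr, pseudobulk_expr, threshold = 1) {
  shared <- intersect(rownames(bulk_expr), rownames(pseudobulk_expr))
  if (!length(shared)) stop_bad("no shared genes between bulk and pseudo-bulk")
  d <- rowMeans(log(as.matrix(bulk_expr)[shared, , drop = FALSE] + 1)) -
    rowMeans(log(as.matrix(pseudobulk_expr)[shared, , drop = FALSE] + 1))
  s <- sd(d)
  if (s == 0) {
    warning("degenerate concordance filter (all differences equal); ",
            "keeping every gene")
    z <- rep(0, length(d))
  } else {
    z <- (d - mean(d)) / s
  }
  stats <- data.frame(gene_id = shared, d = d, z = z, chi_sq = z^2,
                      kept = z^2 <= threshold, row.names = NULL,
                      stringsAsFactors = FALSE)
  list(genes = shared[stats$kept], stats = stats)
}

# brute NNLS wrapper: weighted columns/response, Lawson-Hanson active set
nnls_solve <- function(A, b, w = NULL) {
  if (!is.null(w)) {
    sw <- sqrt(w)
    A <- A * sw
    b <- b * sw
  }
  fit <- pracma::lsqnonneg(A, b)
  fit$x
}

#' Weighted non-negative least squares deconvolution of one bulk sample
#'
#' Iteratively re-weighted NNLS of the bulk sample's relative expression on
#' the cell-type mean profiles. Genes are down-weighted when their residual
#' is large or their profiles vary strongly across reference subjects
#' (weight `1/(nu + r_g^2 + sum_k b_k^2 sigma2_kg)`), with a cap limiting
#' the leverage of any single gene. The non-negative coefficients estimate
#' each cell type's share of the RNA pool; dividing by the per-cell-type
#' library size converts them to cell-count proportions, which are
#' renormalized to sum to 1.
#'
#' @param bulk_sample named vector of bulk expression (any scale; the
#'   estimate is invariant to the sample's library size).
#' @param profiles a `reference_profiles` object from [build_pseudobulk()].
#' @param genes genes to use (default: all shared genes with nonzero
#'   reference expression).
#' @param nu relative variance floor in the weights.
#' @param tol convergence tolerance on the max absolute change in
#'   proportions.
#' @param max_iter maximum re-weighting iterations.
#' @param weight_cap cap on weights, as a multiple of the median weight.
#' @param cond_limit condition number above which the reference is flagged
#'   non-identifiable (duplicated or collinear profiles).
#' @return A list with `proportions` (named, in `[0,1]`, summing to 1),
#'   `coefficients` (RNA-share scale), `iterations`, `converged` and
#'   `identifiable`.
#' @export
wnnls_deconvolve <- function(bulk_sample, profiles, genes = NULL, nu = 1e-4,
                             tol = 1e-6, max_iter = 100L, weight_cap = 100,
                             cond_limit = 1e8) {
  stopifnot(inherits(profiles, "reference_profiles"))
  if (is.null(names(bulk_sample))) {
    if (length(bulk_sample) != length(profiles$gene_ids)) {
      stop_bad("unnamed bulk sample must match the profile gene order")
    }
    names(bulk_sample) <- profiles$gene_ids
  }
  if (is.null(genes)) genes <- profiles$gene_ids
  genes <- intersect(genes, intersect(profiles$gene_ids,
                                      names(bulk_sample)))
  genes <- genes[colSums(profiles$theta[, genes, drop = FALSE]) > 0]
  if (!length(genes)) stop_bad("no usable genes for deconvolution")
  y <- as.numeric(bulk_sample[genes])
  if (sum(y) <= 0) stop_bad("bulk sample is all zero on the selected genes")
  y <- y / sum(y)

  # renormalize each cell type's relative abundance over the selected
  # genes, and scale the cell-size factors by the fraction of that cell
  # type's transcripts falling on them; otherwise genes excluded from the
  # fit (e.g. nuclear-inflated ones) would still distort every coefficient
  # through the profile normalization
  fsel <- rowSums(profiles$theta[, genes, drop = FALSE])
  if (any(fsel <= 0)) {
    stop_bad("cell type(s) with no expression on the selected genes: %s",
             paste(profiles$celltypes[fsel <= 0], collapse = ", "))
  }
  M <- t(profiles$theta[, genes, drop = FALSE] / fsel)       # G x K
  V <- t(profiles$sigma2[, genes, drop = FALSE] / fsel^2)    # G x K
  S_eff <- profiles$S * fsel
  K <- ncol(M)

  cn <- tryCatch({
    sv <- svd(scale(M, center = FALSE,
                    scale = sqrt(colSums(M^2)) + 1e-300))$d
    sv[1] / max(sv[length(sv)], 1e-300)
  }, error = function(e) Inf)
  identifiable <- is.finite(cn) && cn < cond_limit
  if (!identifiable) {
    warning("reference profiles are (near-)collinear; ",
            "proportions are not identifiable")
  }

  nu_eff <- nu * mean(y^2)
  b <- nnls_solve(M, y)
  p_old <- rep(1 / K, K)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    r <- y - drop(M %*% b)
    w <- 1 / (nu_eff + r^2 + drop(V %*% b^2))
    w <- pmin(w, weight_cap * stats::median(w))
    b <- nnls_solve(M, y, w)
    p_raw <- b / S_eff
    p <- if (sum(p_raw) > 0) p_raw / sum(p_raw) else rep(1 / K, K)
    if (max(abs(p - p_old)) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    p_old <- p
  }
  list(
    proportions = setNames(p, profiles$celltypes),
    coefficients = setNames(b, profiles$celltypes),
    iterations = iter,
    converged = converged,
    identifiable = identifiable
  )
}

#' Deconvolve every sample of a bulk expression matrix
#'
#' @param bulk gene x sample expression matrix (or an `expression_set`, in
#'   which case its TPM slot is used).
#' @param profiles a `reference_profiles` object.
#' @param genes gene subset passed to [wnnls_deconvolve()].
#' @param ... further arguments for [wnnls_deconvolve()].
#' @return Sample x cell-type proportion matrix (rows sum to 1).
#' @export
deconvolve_proportions <- function(bulk, profiles, genes = NULL, ...) {
  if (inherits(bulk, "expression_set")) bulk <- bulk$tpm
  bulk <- as.matrix(bulk)
  out <- t(vapply(seq_len(ncol(bulk)), function(s) {
    wnnls_deconvolve(setNames(bulk[, s], rownames(bulk)), profiles,
                     genes = genes, ...)$proportions
  }, numeric(length(profiles$celltypes))))
  dimnames(out) <- list(colnames(bulk), profiles$celltypes)
  out
}

#' Leave-one-out validation of the deconvolution pipeline
#'
#' For each subject with paired single-nucleus and bulk data, the reference
#' (signature genes, pseudo-bulk, concordance filter, profiles) is rebuilt
#' from the other subjects only; the held-out subject's bulk sample is then
#' deconvolved and compared to that subject's true cell-type label
#' frequencies. Nothing from the held-out subject's nuclei enters the fold.
#'
#' @param ref an `sc_reference` (post-QC) covering at least 3 subjects.
#' @param bulk gene x sample bulk expression with one column per subject
#'   (colnames matching subject ids), or an `expression_set`.
#' @param use_concordance_filter apply the bulk/pseudo-bulk concordance
#'   filter inside each fold (default TRUE).
#' @param gene_set genes handed to the solver: `"concordant"` (default; all
#'   genes surviving the concordance filter, the full reference that the
#'   weighted solver is designed for), `"signature"` (in-fold marker genes
#'   only) or `"both"` (their intersection). Signature selection is re-run
#'   inside every fold either way and its size reported.
#' @param min_logfc,max_p signature-gene thresholds per fold.
#' @param ... further arguments for [wnnls_deconvolve()].
#' @return A list with `estimated` and `truth` (subject x cell-type
#'   matrices), `per_celltype` (Pearson r and RMSE per cell type),
#'   `overall_r`, `overall_rmse` and `n_signature` per fold.
#' @export
loo_validate <- function(ref, bulk, use_concordance_filter = TRUE,
                         gene_set = c("concordant", "signature", "both"),
                         min_logfc = 1, max_p = 0.05, ...) {
  gene_set <- match.arg(gene_set)
  stopifnot(inherits(ref, "sc_reference"))
  if (inherits(bulk, "expression_set")) bulk <- bulk$tpm
  bulk <- as.matrix(bulk)
  subjects <- intersect(unique(ref$cell_meta$subject), colnames(bulk))
  if (length(subjects) < 3L) stop_bad("need paired data for >= 3 subjects")
  celltypes <- sort(unique(ref$cell_meta$cluster))
  truth <- true_proportions(ref)[subjects, celltypes, drop = FALSE]

  est <- matrix(NA_real_, length(subjects), length(celltypes),
                dimnames = list(subjects, celltypes))
  n_signature <- setNames(integer(length(subjects)), subjects)
  for (s in subjects) {
    in_fold <- ref$cell_meta$subject != s
    fold_ref <- structure(
      list(counts = ref$counts[in_fold, , drop = FALSE],
           cell_meta = ref$cell_meta[in_fold, , drop = FALSE],
           genes = ref$genes),
      class = "sc_reference"
    )
    sig <- select_signature_genes(fold_ref, min_logfc = min_logfc,
                                  max_p = max_p)
    n_signature[s] <- nrow(sig)
    pb <- build_pseudobulk(fold_ref)
    genes_use <- switch(gene_set,
      concordant = pb$profiles$gene_ids,
      signature = sig$gene_id,
      both = sig$gene_id
    )
    if (use_concordance_filter) {
      filt <- concordance_filter(bulk, pb$pseudobulk)
      if (gene_set == "signature") {
        # signature-only requests skip the filter intersection
      } else {
        genes_use <- intersect(genes_use, filt$genes)
      }
    }
    if (!length(genes_use)) {
      stop_bad("fold for subject %s: no genes survive signature selection %s",
               s, if (use_concordance_filter) "and concordance filtering"
                  else "")
    }
    fit <- wnnls_deconvolve(setNames(bulk[, s], rownames(bulk)),
                            pb$profiles, genes = genes_use, ...)
    est[s, names(fit$proportions)] <- fit$proportions
  }

  per_ct <- data.frame(
    celltype = celltypes,
    r = vapply(celltypes, function(k) {
      if (sd(truth[, k]) == 0 || sd(est[, k]) == 0) NA_real_ else
        cor(est[, k], truth[, k])
    }, numeric(1)),
    rmse = vapply(celltypes, function(k) {
      sqrt(mean((est[, k] - truth[, k])^2))
    }, numeric(1)),
    row.names = NULL
  )
  list(
    estimated = est,
    truth = truth,
    per_celltype = per_ct,
    overall_r = cor(as.numeric(est), as.numeric(truth)),
    overall_rmse = sqrt(mean((est - truth)^2)),
    n_signature = n_signature
  )
}

#' Adjust cell-type proportions for technical factors
#'
#' Residualizes each cell-type proportion column on the technical factor
#' matrix and re-centres at the original mean. Adjusted values may leave
#' `[0, 1]`; they are intended for association testing, not as proportions.
#'
#' @param props sample x cell-type proportion matrix.
#' @param tech sample x factor matrix of technical covariates (row-aligned).
#' @return Adjusted matrix with the same dimnames.
#' @export
adjust_proportions <- function(props, tech) {
  props <- as.matrix(props)
  tech <- as.matrix(tech)
  if (nrow(props) != nrow(tech)) stop_bad("`props` and `tech` must align")
  out <- apply(props, 2, function(p) residualize(p, tech) + mean(p))
  dimnames(out) <- dimnames(props)
  out
}
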