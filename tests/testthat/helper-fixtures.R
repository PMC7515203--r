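# Shared fixture builders; everything is generated in code at test time.

# hand-written IV table used by the regression oracles
fixture_ivs <- function(n = 8, seed = 101, se_out = 0.05) {
  set.seed(seed)
  bx <- abs(rnorm(n, 0.05, 0.02))
  by <- 0.02 + 0.4 * bx + rnorm(n, 0, se_out)
  data.frame(
    variant_id = sprintf("rs%03d", seq_len(n)),
    beta_exp = bx, se_exp = 0.004,
    p_exp = 2 * pnorm(-abs(bx) / 0.004),
    beta_out = by, se_out = se_out,
    stringsAsFactors = FALSE
  )
}

# small post-QC single-nucleus reference for unit tests
fixture_sc <- function(seed = 7, n_genes = 400, cells = 200, ...) {
  ref <- simulate_sc_reference(cell_sim_config(
    n_genes = n_genes, cells_per_subject = cells, seed = seed, ...
  ))
  qc_reference(ref, min_genes = 10, min_cells = 3)
}

# tiny reference_profiles object built by hand (K cell types, G genes)
fixture_profiles <- function(theta, sigma2 = NULL, S = NULL) {
  K <- nrow(theta)
  G <- ncol(theta)
  if (is.null(rownames(theta))) rownames(theta) <- paste0("ct", seq_len(K))
  if (is.null(colnames(theta))) colnames(theta) <- paste0("g", seq_len(G))
  if (is.null(sigma2)) {
    sigma2 <- matrix(0, K, G, dimnames = dimnames(theta))
  }
  if (is.null(S)) S <- setNames(rep(1, K), rownames(theta))
  structure(
    list(theta = theta, sigma2 = sigma2, S = S,
         celltypes = rownames(theta), gene_ids = colnames(theta),
         n_subjects = 1L),
    class = "reference_profiles"
  )
}

# brute-force NNLS by enumerating active sets (independent oracle)
oracle_nnls <- function(A, b) {
  p <- ncol(A)
  best <- NULL
  best_rss <- Inf
  for (mask in 0:(2^p - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    x <- rep(0, p)
    if (length(S)) {
      xs <- tryCatch(qr.solve(A[, S, drop = FALSE], b),
                     error = function(e) NULL)
      if (is.null(xs) || any(xs < 0)) next
      x[S] <- xs
    }
    r <- b - A %*% x
    # KKT: gradient of excluded coordinates must be nonnegative
    grad <- -drop(crossprod(A, r))
    if (any(grad[setdiff(seq_len(p), S)] < -1e-9)) next
    rss <- sum(r^2)
    if (rss < best_rss) {
      best_rss <- rss
      best <- x
    }
  }
  best
}
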