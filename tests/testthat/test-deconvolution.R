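test_that("reference QC applies cell and gene thresholds in order", {
  # 5 cells x 6 genes; cell 5 expresses only 2 genes; gene 6 is expressed
  # in 2 cells only after cell filtering
  counts <- rbind(
    c(5, 3, 2, 1, 4, 0),
    c(4, 2, 1, 2, 0, 1),
    c(3, 1, 2, 4, 5, 1),
    c(2, 2, 3, 1, 2, 0),
    c(7, 9, 0, 0, 0, 0)
  )
  rownames(counts) <- paste0("c", 1:5)
  colnames(counts) <- paste0("g", 1:6)
  meta <- data.frame(barcode = paste0("c", 1:5), subject = "S1",
                     cluster = rep(c("a", "b"), c(3, 2)))
  qc <- qc_reference(counts, meta, min_genes = 3, min_cells = 3)
  expect_equal(rownames(qc$counts), paste0("c", 1:4))
  # g6 is expressed in 2 of the surviving cells only (cells filtered first)
  expect_equal(colnames(qc$counts), paste0("g", 1:5))
  expect_equal(qc$qc$cells_removed, 1)
  expect_equal(qc$qc$genes_removed, 1)

  # boundary: exactly at threshold is kept
  qc2 <- qc_reference(counts, meta, min_genes = 2, min_cells = 2)
  expect_true("c5" %in% rownames(qc2$counts))
  expect_error(qc_reference(counts, meta, min_genes = 100), "every cell")
})

test_that("true proportions are exact label frequencies", {
  meta <- data.frame(barcode = paste0("c", 1:10), subject = "S1",
                     cluster = rep(c("a", "b", "c"), c(7, 2, 1)))
  p <- true_proportions(meta)
  expect_equal(unname(p["S1", ]), c(0.7, 0.2, 0.1))

  solo <- true_proportions(data.frame(subject = "S1", cluster = "a"))
  expect_equal(unname(solo[1, 1]), 1)
})

test_that("signature selection recovers planted markers and ignores flat genes", {
  ref <- fixture_sc(seed = 13, n_genes = 500, cells = 250,
                    n_celltypes = 4, marker_frac = 0.1, marker_fold = 8,
                    celltype_sd = 0)
  sig <- select_signature_genes(ref)
  truth <- ref$truth$marker_of[colnames(ref$counts)]
  planted <- names(truth)[!is.na(truth)]
  recovered <- intersect(sig$gene_id, planted)
  expect_gt(length(recovered) / length(planted), 0.9)
  # attribution correct for the recovered markers
  attributed <- sig$cluster[match(recovered, sig$gene_id)]
  expect_gt(mean(attributed == truth[recovered]), 0.95)
  # essentially nothing selected outside the planted markers
  expect_lt(sum(!sig$gene_id %in% planted), 0.02 * 500)
})

test_that("no-signal references yield at most a false-positive floor", {
  ref <- fixture_sc(seed = 17, n_genes = 400, cells = 200,
                    marker_fold = 1, celltype_sd = 0)
  sig <- select_signature_genes(ref)
  expect_lt(nrow(sig), 0.05 * 400)
})

test_that("pseudo-bulk and profiles match a hand-summed fixture", {
  counts <- rbind(c(10, 0, 5), c(2, 3, 0), c(4, 4, 4))
  rownames(counts) <- paste0("c", 1:3)
  colnames(counts) <- paste0("g", 1:3)
  meta <- data.frame(barcode = paste0("c", 1:3),
                     subject = c("S1", "S1", "S2"),
                     cluster = c("a", "b", "a"))
  ref <- structure(list(counts = counts, cell_meta = meta),
                   class = "sc_reference")
  pb <- build_pseudobulk(ref)
  expect_equal(unname(pb$pseudobulk[, "S1"]),
               c(12, 3, 5) / 20 * 1e6)
  expect_equal(unname(pb$pseudobulk[, "S2"]), c(4, 4, 4) / 12 * 1e6)
  # profile of type a: mean over the two subjects' relative profiles
  expect_equal(unname(pb$profiles$theta["a", ]),
               unname(colMeans(rbind(c(10, 0, 5) / 15, c(4, 4, 4) / 12))))
  # library sizes per cell type
  expect_equal(unname(pb$profiles$S["a"]), mean(c(15, 12)))
  expect_equal(unname(pb$profiles$S["b"]), 5)
  # single subject, single cell: pseudo-bulk proportional to that cell
  solo <- structure(list(
    counts = counts[1, , drop = FALSE], cell_meta = meta[1, ]
  ), class = "sc_reference")
  pbs <- build_pseudobulk(solo)
  expect_equal(unname(pbs$pseudobulk[, 1]), c(10, 0, 5) / 15 * 1e6)

  # identical subjects have zero cross-subject variance
  meta2 <- meta
  meta2$subject <- c("S1", "S1", "S2")
  counts2 <- rbind(c(10, 0, 5), c(2, 3, 0), c(10, 0, 5))
  dimnames(counts2) <- dimnames(counts)
  ref2 <- structure(list(counts = counts2, cell_meta = meta2),
                    class = "sc_reference")
  pb2 <- build_pseudobulk(ref2)
  expect_equal(unname(pb2$profiles$sigma2["a", ]), rep(0, 3))
})

test_that("concordance filter excludes a MALAT1-like gene and keeps ~68%", {
  # 50 concordant genes plus one gene wildly inflated in the nuclei
  set.seed(8)
  base <- exp(rnorm(50, 4, 1))
  bulk <- cbind(s1 = c(base * exp(rnorm(50, 0, 0.05)), malat1 = 254))
  pseudo <- cbind(p1 = c(base * exp(rnorm(50, 0, 0.05)), malat1 = 391375))
  rownames(bulk) <- rownames(pseudo) <- c(sprintf("g%02d", 1:50), "MALAT1")
  filt <- concordance_filter(bulk, pseudo)
  expect_false("MALAT1" %in% filt$genes)
  expect_gt(filt$stats$chi_sq[filt$stats$gene_id == "MALAT1"], 1)

  # exactly equal inputs: degenerate branch keeps everything, warns
  expect_warning(all_kept <- concordance_filter(bulk, bulk), "degenerate")
  expect_length(all_kept$genes, 51)

  # standard-normal differences keep about 68% of genes; the construction
  # makes log(bulk + 1) - log(pseudo + 1) exactly the normal draw
  set.seed(9)
  d <- rnorm(20000)
  b2 <- cbind(s = exp(d) - 1)
  p2 <- cbind(p = rep(0, 20000))
  rownames(b2) <- rownames(p2) <- sprintf("g%05d", 1:20000)
  frac <- length(concordance_filter(b2, p2)$genes) / 20000
  expect_equal(frac, 2 * pnorm(1) - 1, tolerance = 0.02)
})

test_that("weighted NNLS recovers pure and mixed profiles exactly", {
  set.seed(10)
  theta <- matrix(rgamma(3 * 60, 1), 3, 60)
  theta <- theta / rowSums(theta)
  prof <- fixture_profiles(theta, S = c(ct1 = 10, ct2 = 20, ct3 = 5))

  # pure type 2 (in cell counts): bulk = S2-weighted type-2 profile
  y <- setNames(theta[2, ], colnames(theta))
  fit <- wnnls_deconvolve(y, prof)
  expect_gte(fit$proportions[["ct2"]], 0.99)

  # known mixture of cell counts maps through the RNA-content scaling
  p_true <- c(0.5, 0.3, 0.2)
  y2 <- drop((p_true * prof$S) %*% theta)
  fit2 <- wnnls_deconvolve(setNames(y2, colnames(theta)), prof)
  expect_equal(unname(fit2$proportions), p_true, tolerance = 1e-6)

  # scale invariance in the bulk library size
  fit3 <- wnnls_deconvolve(setNames(y2 * 5000, colnames(theta)), prof)
  expect_equal(fit3$proportions, fit2$proportions, tolerance = 1e-10)

  # duplicated profiles are flagged as non-identifiable
  dup <- fixture_profiles(rbind(theta[1, ], theta[1, ], theta[3, ]))
  expect_warning(fd <- wnnls_deconvolve(y, dup), "identifiable")
  expect_false(fd$identifiable)

  expect_error(wnnls_deconvolve(setNames(rep(0, 60), colnames(theta)), prof),
               "all zero")
})

test_that("NNLS inner solves match a brute-force active-set oracle", {
  set.seed(11)
  for (rep in 1:5) {
    A <- matrix(rexp(10 * 4), 10, 4)
    b <- drop(A %*% c(2, 0, 1, 0)) + rnorm(10, 0, 0.3)
    theta <- t(A) / rowSums(t(A))
    prof <- fixture_profiles(theta)
    # single unweighted solve (huge variance floor flattens the weights)
    fit <- wnnls_deconvolve(setNames(b, colnames(prof$theta)), prof,
                            nu = 1e12, max_iter = 1)
    x_o <- oracle_nnls(t(prof$theta), b / sum(b))
    expect_equal(unname(fit$coefficients), x_o, tolerance = 1e-8)
  }
})

test_that("leave-one-out validation is leak-free and accurate when easy", {
  ref <- fixture_sc(seed = 19, n_genes = 400, cells = 250, n_celltypes = 4,
                    subject_sd = 0.05, discordant_frac = 0)
  bulk <- simulate_bulk_mixtures(ref, libsize = 2e6, noise_cv = 0, seed = 20)
  loo <- loo_validate(ref, bulk$tpm)
  expect_lt(loo$overall_rmse, 0.02)

  # leakage guard: corrupting the held-out subject's nuclei does not move
  # that subject's estimate
  ref2 <- ref
  s1 <- ref2$cell_meta$subject == "S1"
  ref2$counts[s1, ] <- 0
  ref2$counts[s1, 1] <- 1000
  loo2 <- loo_validate(ref2, bulk$tpm)
  expect_equal(loo2$estimated["S1", ], loo$estimated["S1", ],
               tolerance = 1e-12)

  expect_error(loo_validate(ref, bulk$tpm[, 1:2]), ">= 3 subjects")
})

test_that("proportion adjustment is residualization re-centred at the mean", {
  set.seed(12)
  g <- matrix(rgamma(40 * 3, shape = c(4, 3, 2)), 40, 3, byrow = TRUE)
  props <- g / rowSums(g)
  colnames(props) <- paste0("ct", 1:3)
  tech <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("t1", "t2")))
  adj <- adjust_proportions(props, tech)
  for (k in 1:3) {
    expect_equal(adj[, k], residualize(props[, k], tech) + mean(props[, k]))
    expect_lt(max(abs(crossprod(scale(tech, scale = FALSE), adj[, k]))),
              1e-8)
  }
  # zero technical effect leaves proportions essentially unchanged: the
  # adjustment only removes the (noise-level) sample association
  expect_equal(colMeans(adj), colMeans(props))
})
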