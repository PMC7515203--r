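# Generators for every input of the analysis pipeline: two-sample MR summary
# statistics, block LD matrices, single-nucleus references, bulk mixtures and
# phenotype cohorts. Each generator returns the dataset together with a
# `truth` record of the parameters that produced it, so downstream recovery
# tests never have to peek at internal state.

#' Configuration for the MR summary-statistic generator
#'
#' @param n_variants number of instrument variants (>= 2).
#' @param causal_effect true causal slope of the exposure on the outcome.
#' @param exposure_beta_sd SD of per-variant true exposure effects.
#' @param exposure_se reported per-variant SE of the exposure effect.
#' @param outcome_se per-variant sampling SD (and reported SE) of the outcome
#'   effect.
#' @param pleiotropy_frac fraction of variants with a direct (horizontal
#'   pleiotropy) path to the outcome.
#' @param pleiotropy_sd scale of the pleiotropic effects.
#' @param pleiotropy_mode `"balanced"` (mean-zero pleiotropy) or
#'   `"directional"` (mean `pleiotropy_sd`).
#' @param seed integer RNG seed.
#' @return An object of class `mr_sim_config`.
#' @export
mr_sim_config <- function(n_variants = 100L, causal_effect = 0,
                          exposure_beta_sd = 0.03, exposure_se = 0.003,
                          outcome_se = 0.02, pleiotropy_frac = 0,
                          pleiotropy_sd = 0.05,
                          pleiotropy_mode = c("balanced", "directional"),
                          seed = NULL) {
  cfg <- list(
    n_variants = check_count(n_variants, "n_variants", min = 2L),
    causal_effect = as.numeric(causal_effect),
    exposure_beta_sd = check_nonneg(exposure_beta_sd, "exposure_beta_sd"),
    exposure_se = check_nonneg(exposure_se, "exposure_se"),
    outcome_se = check_nonneg(outcome_se, "outcome_se"),
    pleiotropy_frac = check_fraction(pleiotropy_frac, "pleiotropy_frac"),
    pleiotropy_sd = check_nonneg(pleiotropy_sd, "pleiotropy_sd"),
    pleiotropy_mode = match.arg(pleiotropy_mode),
    seed = seed
  )
  structure(cfg, class = "mr_sim_config")
}

#' Simulate two-sample MR summary statistics
#'
#' Draws per-variant exposure effects from `Normal(0, exposure_beta_sd^2)`
#' and builds outcome effects as `causal_effect * beta_exp` plus an optional
#' horizontal-pleiotropy term for a random subset of variants, plus
#' `Normal(0, outcome_se^2)` sampling noise. Reported SEs equal the
#' generating SDs (the no-measurement-error convention on the exposure side
#' of a two-sample design).
#'
#' @param cfg an [mr_sim_config()].
#' @return A list with `ivs` (a data frame with columns `variant_id`,
#'   `beta_exp`, `se_exp`, `p_exp`, `beta_out`, `se_out`) and `truth`
#'   (causal effect, pleiotropic variant indices and their direct effects).
#' @export
simulate_mr_summary <- function(cfg) {
  stopifnot(inherits(cfg, "mr_sim_config"))
  n <- cfg$n_variants
  with_seed(cfg$seed, {
    beta_exp <- rnorm(n, 0, cfg$exposure_beta_sd)
    n_pleio <- floor(cfg$pleiotropy_frac * n)
    pleio_idx <- if (n_pleio > 0) sort(sample.int(n, n_pleio)) else integer(0)
    alpha <- numeric(n)
    if (n_pleio > 0) {
      alpha[pleio_idx] <- switch(cfg$pleiotropy_mode,
        balanced = rnorm(n_pleio, 0, cfg$pleiotropy_sd),
        directional = rnorm(n_pleio, cfg$pleiotropy_sd, cfg$pleiotropy_sd / 2)
      )
    }
    beta_out <- cfg$causal_effect * beta_exp + alpha +
      rnorm(n, 0, cfg$outcome_se)
    se_exp <- rep(max(cfg$exposure_se, 1e-12), n)
    p_exp <- 2 * pnorm(-abs(beta_exp) / se_exp)
    p_exp <- pmax(p_exp, .Machine$double.xmin)
    ivs <- data.frame(
      variant_id = sprintf("rs%05d", seq_len(n)),
      beta_exp = beta_exp,
      se_exp = se_exp,
      p_exp = p_exp,
      beta_out = beta_out,
      se_out = rep(max(cfg$outcome_se, 1e-12), n),
      stringsAsFactors = FALSE
    )
    list(
      ivs = ivs,
      truth = list(
        causal_effect = cfg$causal_effect,
        pleiotropy_idx = pleio_idx,
        pleiotropy_effects = alpha[pleio_idx],
        config = cfg
      )
    )
  })
}

#' Simulate a block-diagonal LD matrix
#'
#' Variants are grouped into consecutive blocks; every pair within a block
#' shares squared correlation `within_r2` and pairs across blocks are
#' uncorrelated. The construction (elementwise square of an equicorrelation
#' matrix) is symmetric positive semi-definite by the Schur product theorem.
#'
#' @param n_variants number of variants.
#' @param block_size block width; the last block is truncated if needed.
#' @param within_r2 within-block squared correlation, in `[0, 1)`.
#' @param variant_ids optional ids (default `rs00001`...).
#' @return A list with `variant_ids` and the `r2` matrix (class `ld_matrix`).
#' @export
simulate_ld_blocks <- function(n_variants, block_size, within_r2,
                               variant_ids = NULL) {
  n <- check_count(n_variants, "n_variants")
  bs <- check_count(block_size, "block_size")
  if (!is.numeric(within_r2) || within_r2 < 0 || within_r2 >= 1) {
    stop_bad("`within_r2` must lie in [0, 1)")
  }
  if (is.null(variant_ids)) variant_ids <- sprintf("rs%05d", seq_len(n))
  block <- (seq_len(n) - 1L) %/% bs
  r2 <- outer(block, block, "==") * within_r2
  diag(r2) <- 1
  dimnames(r2) <- list(variant_ids, variant_ids)
  structure(list(variant_ids = variant_ids, r2 = r2), class = "ld_matrix")
}

#' Configuration for the single-nucleus reference generator
#'
#' @param n_subjects,n_celltypes,n_genes,cells_per_subject dataset dimensions.
#' @param dirichlet_alpha positive concentration vector (length
#'   `n_celltypes`) for per-subject cell-type proportions; the default is
#'   adipose-like, with the first (adipocyte-like) type near 44% of cells.
#' @param marker_frac fraction of genes acting as cell-type markers.
#' @param marker_fold fold upregulation of a marker in its cell type (>= 1).
#' @param celltype_sd SD (log scale) of cell-type-specific expression
#'   deviations around the shared base rate. The default (1.0) makes
#'   between-cell-type differences dominate between-subject differences,
#'   the regime in which clustering reflects cell identity rather than
#'   donor.
#' @param discordant_frac fraction of genes whose nuclear expression is
#'   inflated relative to bulk (pre-mRNA rich, MALAT1-like).
#' @param discordant_fold median nuclear inflation factor for discordant
#'   genes. Per-gene folds are lognormal around it (see `discordant_sdlog`),
#'   so most discordant genes are modestly pre-mRNA inflated while the tail
#'   reaches the MALAT1 regime, where nuclear abundance exceeds bulk tissue
#'   by roughly three orders of magnitude.
#' @param discordant_sdlog log-scale SD of the per-gene inflation folds
#'   (0 makes every discordant gene exactly `discordant_fold`).
#' @param libsize_mean mean UMIs per nucleus.
#' @param subject_sd SD (log scale) of subject-level expression jitter.
#' @param rna_content per-cell-type total-RNA content multipliers (default:
#'   equal RNA per cell).
#' @param n_mt_genes number of genes flagged as mitochondrially encoded
#'   (capped at `n_genes %/% 4`); they receive an elevated base rate.
#' @param seed integer RNG seed.
#' @return An object of class `cell_sim_config`.
#' @export
cell_sim_config <- function(n_subjects = 6L, n_celltypes = 8L,
                            n_genes = 2000L, cells_per_subject = 2600L,
                            dirichlet_alpha = NULL, marker_frac = 0.05,
                            marker_fold = 8, celltype_sd = 1,
                            discordant_frac = 0.05, discordant_fold = 20,
                            discordant_sdlog = 1.5,
                            libsize_mean = 2000, subject_sd = 0.3,
                            rna_content = NULL, n_mt_genes = 37L,
                            seed = NULL) {
  n_celltypes <- check_count(n_celltypes, "n_celltypes")
  if (is.null(dirichlet_alpha)) {
    # adipose-like skew: dominant adipocyte fraction, small immune tail
    base <- c(8.8, 3, 2.4, 2, 1.6, 1.2, 0.6, 0.4)
    dirichlet_alpha <- if (n_celltypes <= 8L) base[seq_len(n_celltypes)] else
      c(base, rep(0.4, n_celltypes - 8L))
  }
  if (length(dirichlet_alpha) != n_celltypes || any(dirichlet_alpha <= 0)) {
    stop_bad("`dirichlet_alpha` must be strictly positive, length n_celltypes")
  }
  if (is.null(rna_content)) rna_content <- rep(1, n_celltypes)
  if (length(rna_content) != n_celltypes || any(rna_content <= 0)) {
    stop_bad("`rna_content` must be strictly positive, length n_celltypes")
  }
  if (marker_fold < 1) stop_bad("`marker_fold` must be >= 1")
  cfg <- list(
    n_subjects = check_count(n_subjects, "n_subjects"),
    n_celltypes = n_celltypes,
    n_genes = check_count(n_genes, "n_genes", min = 2L),
    cells_per_subject = check_count(cells_per_subject, "cells_per_subject"),
    dirichlet_alpha = as.numeric(dirichlet_alpha),
    marker_frac = check_fraction(marker_frac, "marker_frac"),
    marker_fold = as.numeric(marker_fold),
    celltype_sd = check_nonneg(celltype_sd, "celltype_sd"),
    discordant_frac = check_fraction(discordant_frac, "discordant_frac"),
    discordant_fold = check_nonneg(discordant_fold, "discordant_fold"),
    discordant_sdlog = check_nonneg(discordant_sdlog, "discordant_sdlog"),
    libsize_mean = check_nonneg(libsize_mean, "libsize_mean"),
    subject_sd = check_nonneg(subject_sd, "subject_sd"),
    rna_content = as.numeric(rna_content),
    n_mt_genes = check_count(n_mt_genes, "n_mt_genes", min = 0L),
    seed = seed
  )
  structure(cfg, class = "cell_sim_config")
}

rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  x / rowSums(x)
}

#' Simulate a single-nucleus RNA-seq reference with known cell proportions
#'
#' Per-subject cell-type proportions are Dirichlet; per-gene base rates are
#' gamma-distributed with lognormal subject jitter; marker genes are
#' upregulated `marker_fold` in one cell type; UMI counts are Poisson at the
#' per-cell library size. A `discordant_frac` subset of genes is inflated by
#' `discordant_fold` in the nuclei only, emulating pre-mRNA-rich transcripts
#' whose nuclear abundance does not match bulk tissue.
#'
#' @param cfg a [cell_sim_config()].
#' @return A list of class `sc_reference` with `counts` (sparse cell x gene),
#'   `cell_meta` (barcode, subject, cluster), `genes` (id, name, is_MT,
#'   is_discordant) and `truth` (realized per-subject label frequencies,
#'   bulk-side relative expression profiles per subject and cell type,
#'   marker/discordant assignments, RNA content).
#' @export
simulate_sc_reference <- function(cfg) {
  stopifnot(inherits(cfg, "cell_sim_config"))
  J <- cfg$n_subjects; K <- cfg$n_celltypes; G <- cfg$n_genes
  with_seed(cfg$seed, {
    celltypes <- sprintf("ct%d", seq_len(K))
    subjects <- sprintf("S%d", seq_len(J))
    gene_id <- sprintf("G%04d", seq_len(G))

    props <- rdirichlet(J, cfg$dirichlet_alpha)
    dimnames(props) <- list(subjects, celltypes)

    base <- rgamma(G, shape = 0.4, rate = 0.4)
    base <- pmax(base, 1e-4)

    n_mt <- min(cfg$n_mt_genes, G %/% 4L)
    is_mt <- rep(FALSE, G)
    if (n_mt > 0) {
      mt_idx <- sample.int(G, n_mt)
      is_mt[mt_idx] <- TRUE
      base[mt_idx] <- base[mt_idx] * 20  # MT transcripts are highly expressed
    }

    n_mark <- floor(cfg$marker_frac * G)
    marker_of <- rep(NA_integer_, G)
    if (n_mark > 0) {
      # markers are drawn among the better-expressed genes: a cell-type
      # marker that nobody can detect is not a marker
      cand <- which(!is_mt & base > quantile(base, 0.5))
      mark_idx <- sample(cand, min(n_mark, length(cand)))
      marker_of[mark_idx] <- rep_len(seq_len(K), length(mark_idx))
    }

    n_disc <- floor(cfg$discordant_frac * G)
    is_disc <- rep(FALSE, G)
    disc_fold <- rep(1, G)
    malat1_like <- NA_character_
    if (n_disc > 0) {
      cand <- which(is.na(marker_of) & !is_mt)
      sel <- sample(cand, min(n_disc, length(cand)))
      is_disc[sel] <- TRUE
      disc_fold[sel] <- pmax(
        exp(rnorm(length(sel), log(cfg$discordant_fold),
                  cfg$discordant_sdlog)), 1)
      # one constitutive MALAT1-like transcript in the bulk-TPM-254 vs
      # nuclear-TPM-391,375 regime: base expression solved so that after
      # its ~1540-fold nuclear inflation it takes ~39% of nuclear reads,
      # the share the real transcript occupies
      m_idx <- sel[which.max(base[sel])]
      fold_m <- max(disc_fold[m_idx], 1541)
      nuc_share <- 0.39
      base[m_idx] <- nuc_share * sum(base[-m_idx]) /
        (fold_m * (1 - nuc_share))
      disc_fold[m_idx] <- fold_m
      malat1_like <- gene_id[m_idx]
    }

    # cell-type rate profiles: shared base rate, lognormal cell-identity
    # deviations, and marker upregulation on top
    rate_kg <- matrix(base, nrow = K, ncol = G, byrow = TRUE) *
      exp(matrix(rnorm(K * G, 0, cfg$celltype_sd), nrow = K))
    for (k in seq_len(K)) {
      sel <- which(marker_of == k)
      rate_kg[k, sel] <- rate_kg[k, sel] * cfg$marker_fold
    }

    # subject-level multiplicative jitter, shared across cell types
    jitter <- matrix(exp(rnorm(J * G, 0, cfg$subject_sd)), nrow = J)

    theta_bulk <- array(0, dim = c(J, K, G),
                        dimnames = list(subjects, celltypes, gene_id))
    theta_nuc <- theta_bulk
    disc_mult <- disc_fold
    for (j in seq_len(J)) {
      for (k in seq_len(K)) {
        r <- rate_kg[k, ] * jitter[j, ]
        theta_bulk[j, k, ] <- r / sum(r)
        rn <- r * disc_mult
        theta_nuc[j, k, ] <- rn / sum(rn)
      }
    }

    n_cells <- J * cfg$cells_per_subject
    cell_subject <- rep(subjects, each = cfg$cells_per_subject)
    cell_type <- character(n_cells)
    for (j in seq_len(J)) {
      idx <- which(cell_subject == subjects[j])
      cell_type[idx] <- sample(celltypes, length(idx), replace = TRUE,
                               prob = props[j, ])
    }

    libsize <- cfg$libsize_mean * cfg$rna_content[match(cell_type, celltypes)]
    counts <- matrix(0L, nrow = n_cells, ncol = G)
    for (j in seq_len(J)) {
      for (k in seq_len(K)) {
        idx <- which(cell_subject == subjects[j] & cell_type == celltypes[k])
        if (!length(idx)) next
        lam <- outer(libsize[idx], theta_nuc[j, k, ])
        counts[idx, ] <- matrix(rpois(length(lam), lam), nrow = length(idx))
      }
    }

    realized <- true_label_frequencies(cell_subject, cell_type,
                                       subjects, celltypes)
    cell_meta <- data.frame(
      barcode = sprintf("cell%05d", seq_len(n_cells)),
      subject = cell_subject,
      cluster = cell_type,
      stringsAsFactors = FALSE
    )
    genes <- data.frame(
      gene_id = gene_id,
      name = gene_id,
      length = rep(1000L, G),
      is_MT = is_mt,
      is_discordant = is_disc,
      stringsAsFactors = FALSE
    )
    counts <- Matrix::Matrix(counts, sparse = TRUE)
    dimnames(counts) <- list(cell_meta$barcode, gene_id)
    structure(
      list(
        counts = counts,
        cell_meta = cell_meta,
        genes = genes,
        truth = list(
          proportions = realized,
          genes = genes,  # full annotation (survives downstream QC subsetting)
          dirichlet_draw = props,
          theta_bulk = theta_bulk,
          theta_nuc = theta_nuc,
          rna_content = setNames(cfg$rna_content, celltypes),
          marker_of = setNames(ifelse(is.na(marker_of), NA_character_,
                                      celltypes[marker_of]), gene_id),
          is_discordant = setNames(is_disc, gene_id),
          discordant_fold = setNames(disc_fold, gene_id),
          malat1_like = malat1_like,
          config = cfg
        )
      ),
      class = "sc_reference"
    )
  })
}

true_label_frequencies <- function(cell_subject, cell_type, subjects,
                                   celltypes) {
  tab <- table(factor(cell_subject, levels = subjects),
               factor(cell_type, levels = celltypes))
  freq <- sweep(unclass(tab), 1, rowSums(tab), "/")
  dimnames(freq) <- list(subjects, celltypes)
  freq
}

#' Simulate bulk RNA-seq mixtures from a single-nucleus reference
#'
#' Expected bulk expression of a sample is the proportion-weighted,
#' RNA-content-scaled sum of the subject's cell-type profiles (the bulk-side
#' profiles, i.e. without nuclear inflation of discordant genes), perturbed
#' by multiplicative lognormal noise of coefficient of variation `noise_cv`;
#' counts are Poisson at `libsize` reads.
#'
#' @param reference an `sc_reference` from [simulate_sc_reference()].
#' @param proportions sample x cell-type mixing weights (rows sum to 1); rows
#'   map to reference subjects by rowname or index. Defaults to the
#'   reference's true label frequencies.
#' @param libsize expected total counts per bulk sample.
#' @param noise_cv lognormal noise CV (0 for noiseless mixtures).
#' @param seed integer RNG seed.
#' @return An [expression_set()] with gene lengths of 1 kb and the reference
#'   gene annotation (MT and discordant flags carried over).
#' @export
simulate_bulk_mixtures <- function(reference, proportions = NULL,
                                   libsize = 1e6, noise_cv = 0.1,
                                   seed = NULL) {
  stopifnot(inherits(reference, "sc_reference"))
  if (libsize < 0) stop_bad("`libsize` must be nonnegative")
  if (is.null(proportions)) proportions <- reference$truth$proportions
  proportions <- as.matrix(proportions)
  if (any(abs(rowSums(proportions) - 1) > 1e-8)) {
    stop_bad("`proportions` rows must sum to 1")
  }
  theta <- reference$truth$theta_bulk
  J <- dim(theta)[1]
  subj_of_row <- if (!is.null(rownames(proportions)) &&
                     all(rownames(proportions) %in% dimnames(theta)[[1]])) {
    match(rownames(proportions), dimnames(theta)[[1]])
  } else {
    rep_len(seq_len(J), nrow(proportions))
  }
  S <- reference$truth$rna_content
  G <- dim(theta)[3]
  with_seed(seed, {
    n_s <- nrow(proportions)
    expr <- matrix(0, nrow = G, ncol = n_s)
    for (s in seq_len(n_s)) {
      j <- subj_of_row[s]
      w <- proportions[s, ] * S
      e <- colSums(theta[j, , ] * w)  # K x G profile weighted by p_k * S_k
      if (noise_cv > 0) {
        sig <- sqrt(log(1 + noise_cv^2))
        e <- e * exp(rnorm(G, -sig^2 / 2, sig))
      }
      expr[, s] <- e / sum(e)
    }
    counts <- matrix(rpois(length(expr), libsize * expr), nrow = G)
    sample_ids <- if (!is.null(rownames(proportions))) {
      rownames(proportions)
    } else {
      sprintf("bulk%02d", seq_len(n_s))
    }
    dimnames(counts) <- list(dimnames(theta)[[3]], sample_ids)
    gene_anno <- if (!is.null(reference$truth$genes)) reference$truth$genes
      else reference$genes
    expression_set(counts, gene_anno)
  })
}

#' Configuration for the phenotype cohort generator
#'
#' Effects are specified on z-score (unit-SD) scale so that squared betas
#' control relative variance contributions directly; the `truth` record also
#' reports them on the raw predictor scale. The noise SD is calibrated
#' analytically so the realized coefficient of determination of the linear
#' predictor matches `target_r2_total` (unless `noise_sd` is given).
#'
#' @param n_individuals cohort size.
#' @param beta_bodyfat,beta_mt standardized effects of body fat % and of MT
#'   expression on the latent Matsuda index. Defaults reflect a cohort where
#'   adiposity dominates and low MT expression accompanies insulin
#'   resistance.
#' @param beta_celltypes standardized cell-type effects; the last type is the
#'   reference category with effect 0 (mirroring the exclusion of one
#'   cell-type proportion from the linear model). `NULL` uses a default
#'   pattern recycled to the number of cell types.
#' @param noise_sd residual SD; `NULL` (default) calibrates it from
#'   `target_r2_total` by variance matching.
#' @param target_r2_total fraction of Matsuda variance explained by the
#'   linear predictor (default 0.44).
#' @param hba1c_prediabetes_band HbA1c band (%) defining prediabetes.
#' @param t2d_frac fraction of individuals given a type 2 diabetes flag
#'   (their HbA1c is pushed above the band).
#' @param mt_confounding_strength strength of the link between MT expression
#'   and the per-sample MT read fraction (and thereby the biased technical
#'   metrics).
#' @param seed integer RNG seed.
#' @return An object of class `pheno_sim_config`.
#' @export
pheno_sim_config <- function(n_individuals = 324L, beta_bodyfat = -0.56,
                             beta_mt = 0.39, beta_celltypes = NULL,
                             noise_sd = NULL, target_r2_total = 0.44,
                             hba1c_prediabetes_band = c(5.7, 6.4),
                             t2d_frac = 0.034,
                             mt_confounding_strength = 0.8, seed = NULL) {
  if (!is.null(noise_sd)) noise_sd <- check_nonneg(noise_sd, "noise_sd")
  target_r2_total <- check_fraction(target_r2_total, "target_r2_total")
  if (target_r2_total <= 0 || target_r2_total >= 1) {
    stop_bad("`target_r2_total` must lie in (0, 1)")
  }
  if (length(hba1c_prediabetes_band) != 2L ||
      hba1c_prediabetes_band[1] >= hba1c_prediabetes_band[2]) {
    stop_bad("`hba1c_prediabetes_band` must be (lower, upper), lower < upper")
  }
  cfg <- list(
    n_individuals = check_count(n_individuals, "n_individuals", min = 2L),
    beta_bodyfat = as.numeric(beta_bodyfat),
    beta_mt = as.numeric(beta_mt),
    beta_celltypes = beta_celltypes,
    noise_sd = noise_sd,
    target_r2_total = target_r2_total,
    hba1c_prediabetes_band = as.numeric(hba1c_prediabetes_band),
    t2d_frac = check_fraction(t2d_frac, "t2d_frac"),
    mt_confounding_strength = check_nonneg(mt_confounding_strength,
                                           "mt_confounding_strength"),
    seed = seed
  )
  structure(cfg, class = "pheno_sim_config")
}

default_celltype_betas <- function(K) {
  # alternating moderate effects on the non-reference types; immune-like
  # types (later columns) pull the Matsuda index down
  pattern <- c(-0.25, 0.2, -0.3, 0.25, 0.15, -0.2, 0.1)
  b <- rep_len(pattern, max(K - 1L, 0L))
  c(b, 0)  # last type is the reference category
}

#' Simulate a phenotype cohort with a known Matsuda-index model
#'
#' The latent Matsuda index is a linear function of body fat percent, MT
#' expression and cell-type proportions (all standardized internally) plus
#' Gaussian noise scaled so the realized R^2 matches the configured target.
#' HbA1c depends weakly on body fat; the prediabetes flag marks HbA1c inside
#' the configured band and a random `t2d_frac` subset is pushed above it and
#' flagged as T2D. Per-sample read-category counts are generated with the MT
#' read fraction tied to MT expression at strength
#' `mt_confounding_strength`, so technical metrics computed without removing
#' MT reads are confounded with MT expression.
#'
#' @param cfg a [pheno_sim_config()].
#' @param proportions optional n x K cell-type proportion matrix (rows sum to
#'   1); drawn from an adipose-like Dirichlet when `NULL`.
#' @param mt_expression optional per-individual MT expression (TPM-like);
#'   lognormal draws when `NULL`.
#' @return A list with `cohort` (a data frame: phenotypes, flags, cell-type
#'   proportion columns, MT expression, read-category counts and eight extra
#'   technical factor columns `tf_1..tf_8`) and `truth` (raw- and
#'   standardized-scale betas, the noise SD used, and the latent linear
#'   predictor).
#' @export
simulate_cohort <- function(cfg, proportions = NULL, mt_expression = NULL) {
  stopifnot(inherits(cfg, "pheno_sim_config"))
  n <- cfg$n_individuals
  with_seed(cfg$seed, {
    if (is.null(proportions)) {
      alpha <- c(8.8, 3, 2.4, 2, 1.6, 1.2, 0.6, 0.4)
      proportions <- rdirichlet(n, alpha)
      colnames(proportions) <- sprintf("ct%d", seq_len(ncol(proportions)))
    }
    proportions <- as.matrix(proportions)
    if (nrow(proportions) != n) stop_bad("`proportions` rows must match n")
    if (is.null(colnames(proportions))) {
      colnames(proportions) <- sprintf("ct%d", seq_len(ncol(proportions)))
    }
    K <- ncol(proportions)
    if (is.null(mt_expression)) {
      mt_expression <- exp(rnorm(n, log(2e5), 0.35))
    }
    if (length(mt_expression) != n) {
      stop_bad("`mt_expression` length must match n")
    }

    beta_ct <- cfg$beta_celltypes
    if (is.null(beta_ct)) beta_ct <- default_celltype_betas(K)
    if (length(beta_ct) != K) {
      stop_bad("`beta_celltypes` must have one entry per cell type")
    }

    age <- round(rnorm(n, 55, 6))
    bodyfat <- pmin(pmax(rnorm(n, 27, 7), 8), 55)
    bmi <- 18 + 0.32 * bodyfat + rnorm(n, 0, 1.5)

    zs <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
    z_bf <- zs(bodyfat)
    z_mt <- zs(mt_expression)
    z_ct <- apply(proportions, 2, zs)

    lp <- cfg$beta_bodyfat * z_bf + cfg$beta_mt * z_mt +
      drop(z_ct %*% beta_ct)
    noise_sd <- cfg$noise_sd
    if (is.null(noise_sd)) {
      # analytic variance matching: Var(noise) = Var(lp) (1 - R2) / R2
      noise_sd <- sqrt(var(lp) * (1 - cfg$target_r2_total) /
                         cfg$target_r2_total)
    }
    matsuda <- 6 + lp + rnorm(n, 0, noise_sd)

    # intercept chosen so the default body-fat distribution yields ~14%
    # prediabetes, the population fraction observed in large biobank data
    hba1c <- pmax(4.8 + 0.02 * bodyfat + rnorm(n, 0, 0.3), 4.5)
    band <- cfg$hba1c_prediabetes_band
    n_t2d <- floor(cfg$t2d_frac * n)
    t2d <- rep(FALSE, n)
    if (n_t2d > 0) {
      idx <- sample.int(n, n_t2d)
      t2d[idx] <- TRUE
      hba1c[idx] <- band[2] + 0.1 + abs(rnorm(n_t2d, 0, 0.5))
    }
    prediab <- !t2d & hba1c >= band[1] & hba1c <= band[2]

    # read categories: MT read fraction tracks MT expression; nuclear
    # category fractions are independent of it
    mt_frac <- plogis(qlogis(0.15) +
                        cfg$mt_confounding_strength * z_mt +
                        rnorm(n, 0, 0.15))
    total <- round(rnorm(n, 3e7, 2e6))
    mt_reads <- round(total * mt_frac)
    nuclear <- total - mt_reads
    # exonic/intronic/intergenic/other nuclear fractions; concentration set
    # so the MT-included metrics show the strong MT-percent confounding seen
    # in real libraries (correlations near 0.8)
    fr <- rdirichlet(n, c(220, 108, 32, 40))
    exonic <- round(nuclear * fr[, 1])
    intronic <- round(nuclear * fr[, 2])
    intergenic <- round(nuclear * fr[, 3])

    tf <- matrix(rnorm(n * 8), nrow = n,
                 dimnames = list(NULL, sprintf("tf_%d", seq_len(8))))

    cohort <- data.frame(
      id = sprintf("ind%05d", seq_len(n)),
      age = age,
      bodyfat_pct = bodyfat,
      bmi = bmi,
      matsuda = matsuda,
      hba1c = hba1c,
      prediabetes_flag = prediab,
      t2d_flag = t2d,
      mt_expression = mt_expression,
      exonic = exonic,
      intronic = intronic,
      intergenic = intergenic,
      mt_aligned = mt_reads,
      total_aligned = total,
      stringsAsFactors = FALSE
    )
    cohort <- cbind(cohort, as.data.frame(proportions), as.data.frame(tf))

    beta_std <- c(bodyfat_pct = cfg$beta_bodyfat,
                  mt_expression = cfg$beta_mt,
                  setNames(beta_ct, colnames(proportions)))
    sds <- c(bodyfat_pct = sd(bodyfat), mt_expression = sd(mt_expression),
             setNames(apply(proportions, 2, sd), colnames(proportions)))
    list(
      cohort = cohort,
      truth = list(
        beta_std = beta_std,
        beta_raw = beta_std / sds,
        noise_sd = noise_sd,
        linear_predictor = lp,
        celltypes = colnames(proportions),
        reference_celltype = colnames(proportions)[K],
        config = cfg
      )
    )
  })
}
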