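# Modelling the Matsuda insulin-sensitivity index from adipose features:
# cohort preparation, the multi-variable linear model, variance
# partitioning, per-cell-type association scans, and an elastic-net
# predictor with out-of-fold evaluation.

cohort_celltypes <- function(cohort, celltypes = NULL) {
  if (!is.null(celltypes)) return(celltypes)
  ct <- attr(cohort, "celltypes")
  if (is.null(ct)) ct <- grep("^ct", names(cohort), value = TRUE)
  if (!length(ct)) stop_bad("no cell-type proportion columns found")
  ct
}

#' Prepare a cohort table for Matsuda-index modelling
#'
#' Individuals flagged with type 2 diabetes are removed (they are excluded
#' from every analysis involving the Matsuda index), the Matsuda index and
#' MT expression are inverse-normal transformed, and the Matsuda index is
#' residualized on age and age squared.
#'
#' @param raw data frame with at least `id`, `matsuda`, `age`, `t2d_flag`
#'   and an `mt_expression` column (e.g. from [simulate_cohort()]).
#' @param proportions optional sample x cell-type matrix to attach (rows
#'   aligned with `raw`, or rownames matching `raw$id`); otherwise columns
#'   named `ct*` already in `raw` are used.
#' @param mt_adjusted optional per-individual technically corrected MT
#'   expression replacing the `mt_expression` column before transformation.
#' @return The filtered, transformed cohort data frame with a `celltypes`
#'   attribute naming the proportion columns.
#' @export
prepare_cohort <- function(raw, proportions = NULL, mt_adjusted = NULL) {
  if (anyDuplicated(raw$id)) stop_bad("duplicate individual ids")
  if (!is.null(proportions)) {
    proportions <- as.matrix(proportions)
    if (!is.null(rownames(proportions)) && all(raw$id %in%
                                               rownames(proportions))) {
      proportions <- proportions[raw$id, , drop = FALSE]
    } else if (nrow(proportions) != nrow(raw)) {
      stop_bad("`proportions` rows do not align with the cohort")
    }
    if (is.null(colnames(proportions))) {
      colnames(proportions) <- sprintf("ct%d", seq_len(ncol(proportions)))
    }
    raw[colnames(proportions)] <- as.data.frame(proportions)
    celltypes <- colnames(proportions)
  } else {
    celltypes <- grep("^ct", names(raw), value = TRUE)
  }
  if (!is.null(mt_adjusted)) {
    if (length(mt_adjusted) != nrow(raw)) {
      stop_bad("`mt_adjusted` does not align with the cohort")
    }
    raw$mt_expression <- as.numeric(mt_adjusted)
  }
  out <- raw[!raw$t2d_flag, , drop = FALSE]
  rownames(out) <- NULL
  out$matsuda <- inverse_normal_transform(out$matsuda)
  out$matsuda <- residualize(out$matsuda,
                             cbind(age = out$age, age2 = out$age^2))
  out$mt_expression <- inverse_normal_transform(out$mt_expression)
  attr(out, "celltypes") <- celltypes
  out
}

#' Per-cell-type association scan against the Matsuda index
#'
#' Fits, for each cell type, a linear model of the (transformed) Matsuda
#' index on that cell type's proportion with age as a covariate, and
#' Bonferroni-adjusts the proportion p-values over the number of cell types.
#'
#' @param cohort a prepared cohort (see [prepare_cohort()]).
#' @param celltypes proportion column names (default: the cohort attribute).
#' @return Data frame with `celltype`, `beta`, `se`, `p`, `p_bonferroni`.
#' @export
celltype_association_scan <- function(cohort, celltypes = NULL) {
  celltypes <- cohort_celltypes(cohort, celltypes)
  if (nrow(cohort) < length(celltypes) + 2L) stop_bad("cohort too small")
  rows <- lapply(celltypes, function(ct) {
    x <- cohort[[ct]]
    if (sd(x) == 0) stop_bad("constant proportion column: %s", ct)
    fit <- lm(cohort$matsuda ~ x + cohort$age)
    sm <- summary(fit)$coefficients
    data.frame(celltype = ct, beta = sm["x", 1], se = sm["x", 2],
               p = sm["x", 4], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- bonferroni_adjust(out$p, m = length(celltypes))
  rownames(out) <- NULL
  out
}

#' Fit the multi-variable Matsuda model (body fat + cell types + MT)
#'
#' Ordinary least squares of the (transformed) Matsuda index on body fat
#' percent, the corrected MT expression, and the cell-type proportions with
#' one cell type excluded: because the proportions sum to 1 they carry only
#' `K - 1` degrees of freedom, and including all of them alongside an
#' intercept is a singular design.
#'
#' @param cohort a prepared cohort.
#' @param exclude_celltype proportion column left out (default: the last
#'   one; in the adipose application this is the least reliably estimated,
#'   endothelial-like type). Use `NULL` to attempt the full design, which
#'   errors if singular.
#' @param obesity_col obesity predictor column (default `bodyfat_pct`).
#' @param celltypes proportion column names.
#' @return A list of class `model1_fit` with `coefficients` (term, beta,
#'   se, p), `r_squared`, `n`, `excluded_celltype` and the residuals.
#' @export
fit_model1 <- function(cohort, exclude_celltype = "last",
                       obesity_col = "bodyfat_pct", celltypes = NULL) {
  celltypes <- cohort_celltypes(cohort, celltypes)
  if (identical(exclude_celltype, "last")) {
    exclude_celltype <- celltypes[length(celltypes)]
  }
  use_ct <- setdiff(celltypes, exclude_celltype)
  terms <- c(obesity_col, "mt_expression", use_ct)
  X <- as.matrix(cohort[, terms, drop = FALSE])
  y <- cohort$matsuda
  if (nrow(X) <= ncol(X) + 2L) stop_bad("too few individuals for the model")
  qr_x <- qr(cbind(1, X))
  if (qr_x$rank < ncol(X) + 1L) {
    stop_bad(paste("singular design: the cell-type proportions sum to 1;",
                   "exclude one cell type from the model"))
  }
  fit <- lm(y ~ X)
  sm <- summary(fit)
  co <- sm$coefficients
  rownames(co) <- sub("^X", "", rownames(co))
  structure(
    list(
      coefficients = data.frame(
        term = rownames(co), beta = co[, 1], se = co[, 2], p = co[, 4],
        row.names = NULL, stringsAsFactors = FALSE
      ),
      r_squared = sm$r.squared,
      n = nrow(X),
      excluded_celltype = exclude_celltype,
      df_note = sprintf("%d cell types enter with %d df (one excluded)",
                        length(celltypes), length(use_ct)),
      residuals = residuals(fit)
    ),
    class = "model1_fit"
  )
}

#' Variance in the Matsuda index explained by predictor subsets
#'
#' @param cohort a prepared cohort.
#' @param predictor_sets named list of character vectors of cohort columns.
#' @return Named numeric vector of OLS R-squared values, one per set plus
#'   `full` (the union of all sets).
#' @export
variance_explained <- function(cohort, predictor_sets) {
  if (!length(predictor_sets)) stop_bad("no predictor sets given")
  r2 <- function(cols) {
    if (!length(cols)) stop_bad("empty predictor set")
    missing <- setdiff(cols, names(cohort))
    if (length(missing)) {
      stop_bad("unknown predictors: %s", paste(missing, collapse = ", "))
    }
    X <- as.matrix(cohort[, cols, drop = FALSE])
    summary(lm(cohort$matsuda ~ X))$r.squared
  }
  out <- vapply(predictor_sets, r2, numeric(1))
  c(out, full = r2(unique(unlist(predictor_sets))))
}

standardize_cols <- function(X) {
  m <- colMeans(X)
  s <- sqrt(colMeans(sweep(X, 2, m)^2))  # 1/n variance, glmnet convention
  if (any(s == 0)) {
    stop_bad("constant predictor column(s): %s",
             paste(colnames(X)[s == 0], collapse = ", "))
  }
  list(X = sweep(sweep(X, 2, m), 2, s, "/"), mean = m, sd = s)
}

default_lambda_grid <- function(Xs, yc, alpha_mix, n_lambda = 100L,
                                ratio = 1e-4) {
  n <- nrow(Xs)
  lmax <- max(abs(crossprod(Xs, yc))) / (n * max(alpha_mix, 1e-3))
  exp(seq(log(lmax), log(lmax * ratio), length.out = n_lambda))
}

#' Fit an elastic-net model for the Matsuda index
#'
#' Cyclic coordinate descent on standardized predictors minimizing
#' `(1/2n)||y - Xb||^2 + lambda (alpha ||b||_1 + (1-alpha)/2 ||b||_2^2)`,
#' over a decreasing lambda path with warm starts; the intercept is
#' unpenalized. The penalty weight is chosen at the minimum mean k-fold
#' cross-validated squared error (standardization recomputed inside each
#' training split). Coefficients are returned on the original scale.
#'
#' @param X predictor matrix with column names.
#' @param y numeric response (not constant).
#' @param alpha_mix L1 share of the penalty in `[0, 1]` (default 0.5: one
#'   common weight on both norms).
#' @param lambda_grid decreasing penalty path; `NULL` builds 100 log-spaced
#'   values spanning 4 decades below the smallest all-zero lambda.
#' @param n_folds folds for the internal CV (default 10); ignored when
#'   `lambda` is given.
#' @param lambda optional fixed penalty, skipping CV (0 gives OLS).
#' @param seed RNG seed for the CV fold assignment.
#' @param tol,max_iter coordinate-descent convergence controls.
#' @return An object of class `elastic_net_model`: `intercept`, `betas`
#'   (original scale), `betas_std`, `lambda`, `alpha_mix`, `lambda_grid`,
#'   `cv_mse` (if CV ran) and the `standardization` means/SDs.
#' @export
elastic_net_fit <- function(X, y, alpha_mix = 0.5, lambda_grid = NULL,
                            n_folds = 10L, lambda = NULL, seed = NULL,
                            tol = 1e-9, max_iter = 100000L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(y)) stop_bad("`X` rows must match `y`")
  if (sd(y) == 0) stop_bad("`y` is constant")
  alpha_mix <- check_fraction(alpha_mix, "alpha_mix")
  n <- nrow(X)

  std <- standardize_cols(X)
  ym <- mean(y)
  yc <- y - ym

  if (!is.null(lambda_grid) && !length(lambda_grid)) {
    stop_bad("`lambda_grid` is empty")
  }
  if (is.null(lambda_grid)) {
    lambda_grid <- default_lambda_grid(std$X, yc, alpha_mix)
  }
  lambda_grid <- sort(as.numeric(lambda_grid), decreasing = TRUE)

  cv_mse <- NULL
  if (is.null(lambda)) {
    if (length(lambda_grid) == 1L) {
      lambda <- lambda_grid
    } else {
      n_folds <- check_count(n_folds, "n_folds", min = 2L)
      if (n < n_folds) stop_bad("fewer observations than folds")
      folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
      se_mat <- matrix(NA_real_, n, length(lambda_grid))
      for (f in seq_len(n_folds)) {
        tr <- folds != f
        std_f <- standardize_cols(X[tr, , drop = FALSE])
        ym_f <- mean(y[tr])
        b_f <- en_path_cd(std_f$X, y[tr] - ym_f, lambda_grid, alpha_mix,
                          tol, max_iter)
        Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, std_f$mean), 2,
                     std_f$sd, "/")
        pred <- Xte %*% b_f + ym_f
        se_mat[!tr, ] <- (y[!tr] - pred)^2
      }
      cv_mse <- colMeans(se_mat)
      lambda <- lambda_grid[which.min(cv_mse)]
    }
  }

  path <- sort(unique(c(lambda_grid[lambda_grid >= lambda], lambda)),
               decreasing = TRUE)
  b_path <- en_path_cd(std$X, yc, path, alpha_mix, tol, max_iter)
  b_std <- b_path[, length(path)]
  betas <- b_std / std$sd
  structure(
    list(
      predictor_names = colnames(X),
      intercept = ym - sum(betas * std$mean),
      betas = setNames(betas, colnames(X)),
      betas_std = setNames(b_std, colnames(X)),
      lambda = lambda,
      alpha_mix = alpha_mix,
      lambda_grid = lambda_grid,
      cv_mse = cv_mse,
      standardization = list(mean = std$mean, sd = std$sd, y_mean = ym)
    ),
    class = "elastic_net_model"
  )
}

#' Fit the elastic net along a full lambda path (no CV)
#'
#' @inheritParams elastic_net_fit
#' @return Matrix of original-scale coefficients, one column per lambda,
#'   with the intercepts as an attribute.
#' @export
elastic_net_path <- function(X, y, alpha_mix = 0.5, lambda_grid,
                             tol = 1e-9, max_iter = 100000L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  std <- standardize_cols(X)
  ym <- mean(y)
  lambda_grid <- sort(as.numeric(lambda_grid), decreasing = TRUE)
  b <- en_path_cd(std$X, y - ym, lambda_grid, alpha_mix, tol, max_iter)
  betas <- sweep(b, 1, std$sd, "/")
  dimnames(betas) <- list(colnames(X), signif(lambda_grid, 6))
  attr(betas, "intercepts") <- ym - drop(crossprod(betas, std$mean))
  betas
}

#' Karush-Kuhn-Tucker residual of an elastic-net solution
#'
#' On the standardized scale the stationarity conditions are
#' `|g_j + lambda alpha sign(b_j)| = 0` for active coefficients and
#' `|g_j| <= lambda alpha` for zero coefficients, where
#' `g_j = -(1/n) x_j'(y - Xb) + lambda (1-alpha) b_j`. Returns the largest
#' violation.
#'
#' @param model an `elastic_net_model`.
#' @param X,y the training data the model was fitted on.
#' @return Maximum KKT violation (a converged solution is ~1e-9).
#' @export
elastic_net_kkt <- function(model, X, y) {
  X <- as.matrix(X)
  st <- model$standardization
  Xs <- sweep(sweep(X, 2, st$mean), 2, st$sd, "/")
  yc <- y - st$y_mean
  b <- model$betas_std
  n <- nrow(Xs)
  r <- yc - drop(Xs %*% b)
  g <- -drop(crossprod(Xs, r)) / n + model$lambda * (1 - model$alpha_mix) * b
  l1 <- model$lambda * model$alpha_mix
  viol <- ifelse(b != 0, abs(g + l1 * sign(b)), pmax(abs(g) - l1, 0))
  max(viol)
}

#' Predict the Matsuda index with a fitted elastic-net model
#'
#' @param model an `elastic_net_model`.
#' @param new_table data frame or matrix containing every predictor column.
#' @return Numeric predictions.
#' @export
predict_matsuda <- function(model, new_table) {
  missing <- setdiff(model$predictor_names, colnames(new_table))
  if (length(missing)) {
    stop_bad("missing predictor(s): %s", paste(missing, collapse = ", "))
  }
  X <- as.matrix(as.data.frame(new_table)[, model$predictor_names,
                                          drop = FALSE])
  drop(model$intercept + X %*% model$betas)
}

#' @export
predict.elastic_net_model <- function(object, newdata, ...) {
  predict_matsuda(object, newdata)
}

model_design <- function(cohort, preset, celltypes, exclude_celltype) {
  obesity <- switch(preset, bmi = "bmi", bodyfat = "bodyfat_pct",
                    stop_bad("unknown preset: %s", preset))
  use_ct <- setdiff(celltypes, exclude_celltype)
  cols <- c(obesity, "mt_expression", "age", use_ct)
  missing <- setdiff(cols, names(cohort))
  if (length(missing)) {
    stop_bad("cohort lacks predictor(s): %s", paste(missing, collapse = ", "))
  }
  as.matrix(cohort[, cols, drop = FALSE])
}

#' Out-of-fold Matsuda prediction with 100-group cross-validation
#'
#' Randomly partitions the cohort into `n_groups` disjoint groups; each
#' group's Matsuda index is predicted from an elastic-net model trained on
#' the other groups (with the penalty re-selected by internal CV inside
#' every training set). Returns the out-of-fold predictions and their
#' Pearson correlation with the observed values.
#'
#' @param cohort a prepared cohort.
#' @param preset `"bmi"` (default) or `"bodyfat"`: which obesity measure
#'   enters the predictor set alongside MT expression, age and the
#'   cell-type proportions (one excluded).
#' @param n_groups number of groups (default 100; reduced to `n` with a
#'   warning when the cohort is smaller).
#' @param seed RNG seed for the partition and inner CV.
#' @param alpha_mix,inner_folds elastic-net settings per training fit.
#' @param exclude_celltype cell type left out of the design (default: last).
#' @param celltypes proportion column names.
#' @return A list with `predictions`, `truth`, `groups`, `r` and `p`.
#' @export
cross_validate_100fold <- function(cohort, preset = "bmi", n_groups = 100L,
                                   seed = NULL, alpha_mix = 0.5,
                                   inner_folds = 10L,
                                   exclude_celltype = "last",
                                   celltypes = NULL) {
  celltypes <- cohort_celltypes(cohort, celltypes)
  if (identical(exclude_celltype, "last")) {
    exclude_celltype <- celltypes[length(celltypes)]
  }
  X <- model_design(cohort, preset, celltypes, exclude_celltype)
  y <- cohort$matsuda
  n <- nrow(X)
  if (n < n_groups) {
    warning(sprintf("cohort smaller than %d: falling back to %d-fold",
                    n_groups, n))
    n_groups <- n
  }
  with_seed(seed, {
    groups <- sample(rep_len(seq_len(n_groups), n))
    pred <- rep(NA_real_, n)
    for (g in seq_len(n_groups)) {
      te <- groups == g
      fit <- elastic_net_fit(X[!te, , drop = FALSE], y[!te],
                             alpha_mix = alpha_mix, n_folds = inner_folds,
                             seed = sample.int(.Machine$integer.max, 1))
      pred[te] <- predict_matsuda(fit, X[te, , drop = FALSE])
    }
    ct <- cor.test(pred, y)
    list(predictions = pred, truth = y, groups = groups,
         r = unname(ct$estimate), p = ct$p.value)
  })
}

#' Correlation of predictions and truth on one individual per twin pair
#'
#' @param predictions,truth numeric vectors (row-aligned).
#' @param pair_ids pair membership covering every row.
#' @param seed RNG seed for the one-per-pair draw.
#' @return A list with `r`, `p`, and the selected row indices.
#' @export
evaluate_unrelated_subset <- function(predictions, truth, pair_ids,
                                      seed = NULL) {
  if (length(predictions) != length(truth) ||
      length(predictions) != length(pair_ids)) {
    stop_bad("inputs must be row-aligned")
  }
  with_seed(seed, {
    idx <- vapply(split(seq_along(pair_ids), pair_ids), function(i) {
      if (length(i) == 1L) i else sample(i, 1L)
    }, integer(1))
    ct <- cor.test(predictions[idx], truth[idx])
    list(r = unname(ct$estimate), p = ct$p.value, indices = unname(idx))
  })
}
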