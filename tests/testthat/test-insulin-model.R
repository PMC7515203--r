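make_cohort <- function(n = 335, seed = 15, t2d_frac = 11 / 335, ...) {
  simulate_cohort(pheno_sim_config(n_individuals = n, t2d_frac = t2d_frac,
                                   seed = seed, ...))
}

test_that("cohort preparation drops T2D and de-correlates age", {
  sim <- make_cohort()
  expect_equal(sum(sim$cohort$t2d_flag), 11)
  coh <- prepare_cohort(sim$cohort)
  expect_equal(nrow(coh), 324)
  expect_lt(abs(cor(coh$matsuda, coh$age)), 1e-8)
  expect_lt(abs(cor(coh$matsuda, coh$age^2)), 1e-8)
  expect_equal(attr(coh, "celltypes"), sprintf("ct%d", 1:8))

  no_t2d <- make_cohort(t2d_frac = 0)
  expect_equal(nrow(prepare_cohort(no_t2d$cohort)), 335)

  dup <- sim$cohort
  dup$id[2] <- dup$id[1]
  expect_error(prepare_cohort(dup), "duplicate")
})

test_that("cell-type association scan uses a Bonferroni factor of 8", {
  sim <- make_cohort(n = 400, seed = 16)
  coh <- prepare_cohort(sim$cohort)
  scan <- celltype_association_scan(coh)
  expect_equal(nrow(scan), 8)
  expect_equal(scan$p_bonferroni, pmin(1, 8 * scan$p))
  expect_error(celltype_association_scan(coh[1:5, ]), "too small")
})

test_that("the scan is calibrated under the null and powered under signal", {
  # null: proportions unrelated to the response
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 150
    g <- matrix(rgamma(n * 8, shape = 2), n, 8)
    props <- g / rowSums(g)
    colnames(props) <- sprintf("ct%d", 1:8)
    coh <- data.frame(matsuda = rnorm(n), age = rnorm(n, 55, 6), props)
    attr(coh, "celltypes") <- colnames(props)
    sum(celltype_association_scan(coh)$p < 0.05)
  }, numeric(1))
  expect_gt(mean(hits) / 8, 0.02)
  expect_lt(mean(hits) / 8, 0.09)

  # power: a strong immune-type effect is flagged after Bonferroni
  found <- vapply(1:20, function(s) {
    sim <- simulate_cohort(pheno_sim_config(
      n_individuals = 300,
      beta_celltypes = c(0, 0, 0, 0, 0, -0.6, 0, 0), seed = s
    ))
    coh <- prepare_cohort(sim$cohort)
    scan <- celltype_association_scan(coh)
    scan$p_bonferroni[scan$celltype == "ct6"] < 0.05
  }, logical(1))
  expect_gt(mean(found), 0.9)
})

test_that("the multi-variable model matches a normal-equations oracle", {
  sim <- make_cohort(n = 50, seed = 17, t2d_frac = 0)
  coh <- prepare_cohort(sim$cohort)
  fit <- fit_model1(coh)
  ct <- attr(coh, "celltypes")
  X <- cbind(1, as.matrix(coh[, c("bodyfat_pct", "mt_expression",
                                  head(ct, -1))]))
  beta_o <- solve(crossprod(X), crossprod(X, coh$matsuda))
  expect_equal(fit$coefficients$beta, unname(drop(beta_o)),
               tolerance = 1e-8)
  expect_equal(fit$excluded_celltype, "ct8")

  # including all 8 proportions alongside an intercept is singular
  expect_error(fit_model1(coh, exclude_celltype = NULL), "exclude one")
})

test_that("variance partitioning is monotone and additive when orthogonal", {
  sim <- make_cohort(n = 300, seed = 18)
  coh <- prepare_cohort(sim$cohort)
  ct <- attr(coh, "celltypes")
  ve <- variance_explained(coh, list(
    bodyfat = "bodyfat_pct", mt = "mt_expression",
    celltypes = head(ct, -1)
  ))
  expect_true(all(ve["full"] >= ve[c("bodyfat", "mt", "celltypes")] - 1e-12))
  # single predictor R^2 equals the squared Pearson correlation
  expect_equal(unname(ve["bodyfat"]),
               cor(coh$matsuda, coh$bodyfat_pct)^2, tolerance = 1e-10)
  expect_error(variance_explained(coh, list(a = character(0))), "empty")

  # orthogonal, mean-centred predictors: subset R-squareds add up
  set.seed(19)
  Q <- qr.Q(qr(scale(matrix(rnorm(200 * 3), 200, 3), scale = FALSE)))
  colnames(Q) <- c("u1", "u2", "u3")
  orth <- data.frame(matsuda = drop(Q %*% c(1, 2, 3)) + rnorm(200, 0, 0.5),
                     Q)
  vo <- variance_explained(orth, list(a = "u1", b = "u2", c = "u3"))
  expect_equal(unname(vo["a"] + vo["b"] + vo["c"]), unname(vo["full"]),
               tolerance = 1e-10)
})

test_that("elastic net reduces to OLS and closed-form ridge", {
  set.seed(20)
  n <- 120; p <- 8
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  y <- drop(X %*% c(1.5, -1, 0.5, rep(0, 5))) + rnorm(n)

  f0 <- elastic_net_fit(X, y, lambda = 0)
  ols <- coef(lm(y ~ X))
  expect_equal(unname(c(f0$intercept, f0$betas)), unname(ols),
               tolerance = 1e-6)

  lam <- 0.4
  fr <- elastic_net_fit(X, y, alpha_mix = 0, lambda = lam)
  s <- sqrt(colMeans(sweep(X, 2, colMeans(X))^2))
  Xs <- sweep(sweep(X, 2, colMeans(X)), 2, s, "/")
  ridge <- solve(crossprod(Xs) / n + lam * diag(p),
                 crossprod(Xs, y - mean(y)) / n)
  expect_equal(unname(fr$betas_std), unname(drop(ridge)), tolerance = 1e-6)

  expect_error(elastic_net_fit(X, rep(1, n)), "constant")
  expect_error(elastic_net_fit(X, y, lambda_grid = numeric(0)), "empty")
})

test_that("elastic net satisfies its KKT conditions at convergence", {
  set.seed(21)
  X <- matrix(rnorm(150 * 10), 150, 10)
  y <- drop(X %*% c(2, -1, rep(0, 8))) + rnorm(150)
  fit <- elastic_net_fit(X, y, seed = 2)
  expect_lt(elastic_net_kkt(fit, X, y), 1e-6)
  # sparse solution has exactly zero dropped coefficients
  expect_true(any(fit$betas == 0))
})

test_that("elastic net matches the reference solver along a lambda path", {
  skip_if_not_installed("glmnet")
  set.seed(22)
  n <- 100; p <- 10
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  y <- drop(X %*% c(2, -1, 0.5, rep(0, 7))) + rnorm(n)
  # unit-variance response aligns the reference solver's internal response
  # scaling with the stated objective
  ys <- y / sqrt(mean((y - mean(y))^2))
  g <- glmnet::glmnet(X, ys, alpha = 0.5, standardize = TRUE, thresh = 1e-14)
  mine <- elastic_net_path(X, ys, alpha_mix = 0.5, lambda_grid = g$lambda)
  expect_lt(max(abs(as.matrix(g$beta) - mine)), 1e-4)
  expect_lt(max(abs(g$a0 - attr(mine, "intercepts"))), 1e-4)

  # pure lasso agrees on the raw response scale too
  g1 <- glmnet::glmnet(X, y, alpha = 1, standardize = TRUE, thresh = 1e-14)
  m1 <- elastic_net_path(X, y, alpha_mix = 1, lambda_grid = g1$lambda)
  expect_lt(max(abs(as.matrix(g1$beta) - m1)), 1e-4)
})

test_that("prediction applies the stored linear score deterministically", {
  set.seed(23)
  X <- matrix(rnorm(90 * 5), 90, 5, dimnames = list(NULL, paste0("v", 1:5)))
  y <- drop(X %*% c(1, 2, 0, 0, -1)) + rnorm(90)
  fit <- elastic_net_fit(X, y, seed = 3)
  # training-set predictions reproduce the in-sample fitted values
  pred <- predict_matsuda(fit, X)
  expect_equal(pred, drop(fit$intercept + X %*% fit$betas))
  # duplicated rows give identical predictions; manual dot product matches
  nt <- X[c(1, 1, 2), ]
  p2 <- predict_matsuda(fit, nt)
  expect_equal(p2[1], p2[2])
  expect_equal(p2[3], fit$intercept + sum(X[2, ] * fit$betas))
  expect_equal(predict(fit, nt), p2)
  expect_error(predict_matsuda(fit, X[, 1:3]), "v4")
})

test_that("out-of-fold prediction is partition-sound with no predictive leak", {
  # cohorts smaller than the group count fall back to n groups of one
  small <- make_cohort(n = 80, seed = 24, t2d_frac = 0)
  cohs <- prepare_cohort(small$cohort)
  expect_warning(cvs <- cross_validate_100fold(cohs, preset = "bodyfat",
                                               n_groups = 100, seed = 4),
                 "falling back")
  expect_equal(sort(unique(cvs$groups)), 1:80)

  sim <- make_cohort(n = 150, seed = 24, t2d_frac = 0)
  coh <- prepare_cohort(sim$cohort)
  cv <- cross_validate_100fold(coh, preset = "bodyfat", seed = 4)
  expect_equal(sort(unique(cv$groups)), 1:100)
  expect_false(anyNA(cv$predictions))

  # permuted response: no out-of-fold skill (MSE at the variance floor);
  # the raw correlation is not used because hold-out predictions of a
  # no-signal model are near-constant and mechanically anticorrelated with
  # the held-out values
  coh2 <- coh
  set.seed(25)
  coh2$matsuda <- sample(coh2$matsuda)
  cv2 <- cross_validate_100fold(coh2, preset = "bodyfat", seed = 5)
  mse <- mean((cv2$predictions - cv2$truth)^2)
  expect_gt(mse, 0.85 * var(cv2$truth))

  # near-noiseless generator: out-of-fold r close to 1
  easy <- simulate_cohort(pheno_sim_config(n_individuals = 200,
                                           target_r2_total = 0.995,
                                           t2d_frac = 0, seed = 26))
  cohe <- prepare_cohort(easy$cohort)
  cve <- cross_validate_100fold(cohe, preset = "bodyfat", seed = 6)
  expect_gt(cve$r, 0.97)
})

test_that("one-per-pair evaluation subsets reproducibly", {
  set.seed(27)
  truth <- rnorm(60)
  pred <- truth + rnorm(60, 0, 0.5)
  pairs <- rep(1:30, each = 2)
  a <- evaluate_unrelated_subset(pred, truth, pairs, seed = 7)
  b <- evaluate_unrelated_subset(pred, truth, pairs, seed = 7)
  expect_identical(a, b)
  expect_length(a$indices, 30)
  expect_equal(length(unique(pairs[a$indices])), 30)

  # duplicated pairs: the subset correlation equals the full correlation
  pred2 <- rep(pred[1:30], each = 2)
  truth2 <- rep(truth[1:30], each = 2)
  c <- evaluate_unrelated_subset(pred2, truth2, pairs, seed = 8)
  expect_equal(c$r, cor(pred[1:30], truth[1:30]), tolerance = 1e-12)
})
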