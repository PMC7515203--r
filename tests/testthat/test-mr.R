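test_that("instrument selection prunes by LD in ascending p order", {
  sim <- simulate_mr_summary(mr_sim_config(n_variants = 10, seed = 1))
  ivs <- sim$ivs
  ivs$p_exp <- rep(1e-10, 10)

  # identity LD keeps everything significant
  ld <- simulate_ld_blocks(10, 1, 0, variant_ids = ivs$variant_id)
  expect_equal(nrow(select_ivs(ivs, ld)), 10)

  # correlated pair: only the more significant survives
  ivs2 <- ivs[1:2, ]
  ivs2$p_exp <- c(1e-9, 1e-10)
  ld2 <- simulate_ld_blocks(2, 2, 0.9, variant_ids = ivs2$variant_id)
  kept <- select_ivs(ivs2, ld2)
  expect_equal(kept$variant_id, ivs2$variant_id[2])

  # nothing significant: empty result with a warning
  ivs3 <- ivs
  ivs3$p_exp <- rep(0.5, 10)
  expect_warning(out <- select_ivs(ivs3, ld), "threshold")
  expect_equal(nrow(out), 0)

  # missing variants are a hard error naming the ids
  ld_small <- simulate_ld_blocks(5, 1, 0, variant_ids = ivs$variant_id[1:5])
  expect_error(select_ivs(ivs, ld_small), "rs00006")
})

test_that("pruning is invariant to input row order", {
  sim <- simulate_mr_summary(mr_sim_config(n_variants = 40, seed = 5))
  ivs <- sim$ivs
  ivs$p_exp <- pmin(ivs$p_exp, 1e-9)
  ld <- simulate_ld_blocks(40, 4, 0.5, variant_ids = ivs$variant_id)
  a <- select_ivs(ivs, ld)
  b <- select_ivs(ivs[rev(seq_len(40)), ], ld)
  expect_equal(sort(a$variant_id), sort(b$variant_id))
})

test_that("confounder exclusion drops exactly the flagged variants", {
  sim <- simulate_mr_summary(mr_sim_config(n_variants = 100, seed = 2))
  ivs <- sim$ivs
  ivs$p_sbp <- runif(100, 0.1, 1)
  ivs$p_tg <- runif(100, 0.1, 1)
  flagged <- c(3, 20, 55, 90)
  ivs$p_sbp[flagged[1:2]] <- 1e-10
  ivs$p_tg[flagged[3:4]] <- 1e-10

  res <- exclude_confounded_ivs(ivs, c("sbp", "tg"))
  expect_equal(nrow(res$ivs), 96)
  expect_setequal(res$dropped, ivs$variant_id[flagged])
  expect_named(res$report, ivs$variant_id[flagged])

  none <- exclude_confounded_ivs(ivs[-flagged, ], c("sbp", "tg"))
  expect_equal(none$ivs, ivs[-flagged, ])
  expect_error(exclude_confounded_ivs(ivs, "unknown"), "unknown")
})

test_that("exclusion leaves estimates unchanged without a confounding channel", {
  deltas <- vapply(1:30, function(s) {
    sim <- simulate_mr_summary(mr_sim_config(n_variants = 80,
                                             causal_effect = 0.4, seed = s))
    ivs <- sim$ivs
    set.seed(s)
    ivs$p_conf <- runif(80)  # independent of the outcome path
    ivs$p_conf[sample(80, 4)] <- 1e-10
    before <- ivw_estimate(ivs)$estimate
    after <- ivw_estimate(exclude_confounded_ivs(ivs, "conf")$ivs)$estimate
    after - before
  }, numeric(1))
  expect_lt(abs(mean(deltas)), 0.01)
})

test_that("IVW matches a weighted-least-squares oracle", {
  ivs <- fixture_ivs(5, seed = 33)
  fit <- ivw_estimate(ivs)
  oracle <- lm(beta_out ~ 0 + beta_exp, data = ivs,
               weights = 1 / ivs$se_out^2)
  expect_equal(fit$estimate, unname(coef(oracle)), tolerance = 1e-10)
  # overdispersed fixture: multiplicative random-effects SE equals the
  # weighted-regression SE
  if (fit$Q / (nrow(ivs) - 1) > 1) {
    expect_equal(fit$se, unname(summary(oracle)$coefficients[1, 2]),
                 tolerance = 1e-10)
  }

  # exact proportional data: slope recovered, Q = 0
  exact <- data.frame(
    variant_id = paste0("v", 1:4),
    beta_exp = c(0.02, 0.04, 0.05, 0.08), se_exp = 0.001,
    p_exp = 1e-12, beta_out = 0.5 * c(0.02, 0.04, 0.05, 0.08),
    se_out = 1e-6
  )
  f2 <- ivw_estimate(exact)
  expect_equal(f2$estimate, 0.5, tolerance = 1e-12)
  expect_lt(f2$Q, 1e-12)
  expect_equal(f2$Q_p, 1)

  expect_error(ivw_estimate(exact[1, ]), "at least 2")
})

test_that("Egger regression matches a weighted-OLS oracle and finds exact fits", {
  ivs <- fixture_ivs(8, seed = 44)
  fit <- egger_regression(ivs)
  oracle <- lm(beta_out ~ beta_exp, data = ivs, weights = 1 / ivs$se_out^2)
  expect_equal(fit$estimate, unname(coef(oracle)[2]), tolerance = 1e-10)
  expect_equal(fit$egger_intercept, unname(coef(oracle)[1]),
               tolerance = 1e-10)
  sm <- summary(oracle)$coefficients
  if (sum(1 / ivs$se_out^2 * residuals(oracle)^2) / (nrow(ivs) - 2) > 1) {
    expect_equal(fit$se, unname(sm[2, 2]), tolerance = 1e-10)
    expect_equal(fit$intercept_p, unname(sm[1, 4]), tolerance = 1e-10)
  }

  # exact line: intercept 0.3, slope 0.5
  exact <- data.frame(
    variant_id = paste0("v", 1:5),
    beta_exp = c(0.01, 0.03, 0.05, 0.07, 0.1), se_exp = 0.001, p_exp = 1e-12,
    beta_out = 0.3 + 0.5 * c(0.01, 0.03, 0.05, 0.07, 0.1), se_out = 0.01
  )
  f2 <- egger_regression(exact)
  expect_equal(f2$estimate, 0.5, tolerance = 1e-10)
  expect_equal(f2$egger_intercept, 0.3, tolerance = 1e-10)
  expect_error(egger_regression(exact[1:2, ]), "at least 3")
})

test_that("Egger pleiotropy test is calibrated under the null", {
  ps <- vapply(1:500, function(s) {
    sim <- simulate_mr_summary(mr_sim_config(n_variants = 40,
                                             causal_effect = 0.3, seed = s))
    egger_regression(sim$ivs)$intercept_p
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0.02)
  expect_lt(mean(ps < 0.05), 0.09)
  expect_equal(mean(ps), 0.5, tolerance = 0.05)
})

test_that("Cochran's Q follows its reference chi-square under the null", {
  n_iv <- 30
  qs <- vapply(1:1000, function(s) {
    sim <- simulate_mr_summary(mr_sim_config(n_variants = n_iv,
                                             causal_effect = 0.2, seed = s))
    w <- 1 / sim$ivs$se_out^2
    slope <- sum(w * sim$ivs$beta_exp * sim$ivs$beta_out) /
      sum(w * sim$ivs$beta_exp^2)
    cochran_q(sim$ivs, slope)$Q
  }, numeric(1))
  expect_gt(stats::ks.test(qs, stats::pchisq, df = n_iv - 1)$p.value, 0.01)
})

test_that("Cochran's Q detects an injected outlier with high power", {
  hits <- vapply(1:50, function(s) {
    sim <- simulate_mr_summary(mr_sim_config(n_variants = 50,
                                             causal_effect = 0.3, seed = s))
    ivs <- sim$ivs
    ivs$beta_out[1] <- ivs$beta_out[1] + 10 * ivs$se_out[1]
    fit <- ivw_estimate(ivs)
    cochran_q(ivs, fit$estimate)$Q_p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})

test_that("MR-PRESSO is consistent with IVW when no pleiotropy exists", {
  sim <- simulate_mr_summary(mr_sim_config(n_variants = 50,
                                           causal_effect = 0.3, seed = 12))
  pr <- mr_presso(sim$ivs, n_sim = 1000, seed = 1)
  expect_length(pr$outlier_ids, 0)
  expect_equal(pr$estimate, ivw_estimate(sim$ivs)$estimate)
  expect_equal(pr$n_iv_used, 50)
  expect_error(mr_presso(sim$ivs, n_sim = 10), "n_sim")
  expect_error(mr_presso(sim$ivs[1:3, ], n_sim = 1000), "at least 4")
})

test_that("MR-PRESSO flags an injected extreme pleiotropic variant", {
  found <- vapply(1:20, function(s) {
    sim <- simulate_mr_summary(mr_sim_config(n_variants = 50,
                                             causal_effect = 0.3, seed = s))
    ivs <- sim$ivs
    ivs$beta_out[7] <- ivs$beta_out[7] + 12 * ivs$se_out[7]
    pr <- mr_presso(ivs, n_sim = 1000, seed = s + 1)
    "rs00007" %in% pr$outlier_ids
  }, logical(1))
  expect_gt(mean(found), 0.95)
})

test_that("MR-PRESSO simulations are reproducible under a fixed seed", {
  sim <- simulate_mr_summary(mr_sim_config(n_variants = 40,
                                           causal_effect = 0.2, seed = 3))
  a <- mr_presso(sim$ivs, n_sim = 1000, seed = 42)
  b <- mr_presso(sim$ivs, n_sim = 1000, seed = 42)
  expect_identical(a, b)
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(4e-4, 3), 1.2e-3)
  expect_equal(bonferroni_adjust(0.5, 3), 1)
  expect_equal(bonferroni_adjust(c(0.01, 0.2), 1), c(0.01, 0.2))
  expect_error(bonferroni_adjust(0), "0, 1")
})

test_that("the MR battery gates unusable directions and agrees across estimators", {
  # no instruments: direction is not assessable
  empty <- fixture_ivs(8)[0, ]
  rep0 <- run_mr_battery(empty, direction = "reverse")
  expect_equal(rep0$status, "not assessable")

  sim <- simulate_mr_summary(mr_sim_config(n_variants = 60,
                                           causal_effect = 0.5, seed = 21))
  rep1 <- run_mr_battery(sim$ivs, n_sim = 1000, seed = 2)
  expect_equal(rep1$status, "ok")
  # all slope estimators agree within their joint uncertainty
  expect_lt(abs(rep1$presso$estimate - rep1$egger$estimate),
            3 * sqrt(rep1$presso$se^2 + rep1$egger$se^2))
  expect_equal(rep1$presso$p_adjusted,
               min(1, 3 * rep1$presso$p))

  # null simulation: adjusted p-values are non-significant
  sim0 <- simulate_mr_summary(mr_sim_config(n_variants = 60,
                                            causal_effect = 0, seed = 31))
  rep2 <- run_mr_battery(sim0$ivs, n_sim = 1000, seed = 3)
  expect_gt(rep2$presso$p_adjusted, 0.05)
})
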