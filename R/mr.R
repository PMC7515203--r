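# Two-sample Mendelian randomization: instrument selection, confounder
# screening, IVW / Egger estimation, Cochran's Q heterogeneity, and an
# MR-PRESSO style resampling test for horizontal pleiotropy.

validate_iv_table <- function(ivs, min_n = 2L) {
  required <- c("variant_id", "beta_exp", "se_exp", "beta_out", "se_out")
  missing <- setdiff(required, names(ivs))
  if (length(missing)) {
    stop_bad("IV table is missing columns: %s", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(ivs$variant_id)) stop_bad("variant ids must be unique")
  if (any(ivs$se_exp <= 0) || any(ivs$se_out <= 0)) {
    stop_bad("all standard errors must be strictly positive")
  }
  if (nrow(ivs) < min_n) {
    stop_bad("need at least %d instruments, got %d", min_n, nrow(ivs))
  }
  invisible(ivs)
}

mr_result <- function(method, estimate, se, p, n_iv_used, p_adjusted = NA_real_,
                      egger_intercept = NA_real_, intercept_p = NA_real_,
                      Q = NA_real_, Q_p = NA_real_,
                      presso_global_p = NA_real_,
                      outlier_ids = character(0), converged = TRUE) {
  structure(
    list(method = method, estimate = estimate, se = se, p = p,
         p_adjusted = p_adjusted, egger_intercept = egger_intercept,
         intercept_p = intercept_p, Q = Q, Q_p = Q_p,
         presso_global_p = presso_global_p, outlier_ids = outlier_ids,
         n_iv_used = n_iv_used, converged = converged),
    class = "mr_result"
  )
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR estimate (%s): %.4g (se %.3g, p %.3g, n_iv %d)\n",
              x$method, x$estimate, x$se, x$p, x$n_iv_used))
  if (!is.na(x$egger_intercept)) {
    cat(sprintf("  Egger intercept %.3g (p %.3g)\n",
                x$egger_intercept, x$intercept_p))
  }
  if (!is.na(x$Q)) cat(sprintf("  Cochran's Q %.3g (p %.3g)\n", x$Q, x$Q_p))
  if (!is.na(x$presso_global_p)) {
    cat(sprintf("  PRESSO global p %.3g; outliers: %s\n", x$presso_global_p,
                if (length(x$outlier_ids)) {
                  paste(x$outlier_ids, collapse = ", ")
                } else "none"))
  }
  invisible(x)
}

#' Select independent genome-wide-significant instruments
#'
#' Keeps variants with exposure p-value below `p_threshold` and greedily
#' prunes them against the LD matrix in ascending `p_exp` order: the most
#' significant variant is kept and every remaining variant with squared
#' correlation at or above `r2_threshold` to it is dropped, recursively.
#' Ties in `p_exp` are broken by lexicographic `variant_id`, making the
#' output invariant to input row order.
#'
#' @param gwas an IV table (see [simulate_mr_summary()] for the columns).
#' @param ld an `ld_matrix` (or a bare symmetric r-squared matrix with
#'   dimnames) covering every GWAS variant.
#' @param p_threshold genome-wide significance threshold on `p_exp`.
#' @param r2_threshold LD pruning threshold; retained pairs satisfy
#'   `r2 < r2_threshold`.
#' @return The pruned IV table (possibly empty, with a warning).
#' @export
select_ivs <- function(gwas, ld, p_threshold = 5e-8, r2_threshold = 0.01) {
  validate_iv_table(gwas, min_n = 0L)
  r2 <- if (inherits(ld, "ld_matrix")) ld$r2 else as.matrix(ld)
  missing <- setdiff(gwas$variant_id, rownames(r2))
  if (length(missing)) {
    stop_bad("variants missing from the LD matrix: %s",
             paste(missing, collapse = ", "))
  }
  sig <- gwas[gwas$p_exp < p_threshold, , drop = FALSE]
  if (!nrow(sig)) {
    warning("no variant passes the exposure p-value threshold")
    return(sig)
  }
  ord <- order(sig$p_exp, sig$variant_id)
  queue <- sig$variant_id[ord]
  keep <- character(0)
  while (length(queue)) {
    v <- queue[1]
    keep <- c(keep, v)
    queue <- queue[-1]
    if (length(queue)) {
      queue <- queue[r2[v, queue] < r2_threshold]
    }
  }
  out <- sig[match(keep, sig$variant_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclude instruments associated with measured confounders
#'
#' Drops variants whose association p-value with any named confounder
#' (columns `p_<confounder>`) falls below `p_threshold`, the screen used to
#' guard the MR exclusion-restriction assumption against known pleiotropic
#' paths (blood pressure, lipids, lifestyle traits).
#'
#' @param ivs IV table with `p_<confounder>` columns.
#' @param confounders character vector of confounder names.
#' @param p_threshold exclusion threshold (default genome-wide 5e-8).
#' @return A list: `ivs` (retained rows), `dropped` (excluded variant ids)
#'   and `report` (per-dropped-variant offending confounders).
#' @export
exclude_confounded_ivs <- function(ivs, confounders, p_threshold = 5e-8) {
  validate_iv_table(ivs, min_n = 0L)
  cols <- paste0("p_", confounders)
  missing <- setdiff(cols, names(ivs))
  if (length(missing)) {
    stop_bad("unknown confounder columns: %s", paste(missing, collapse = ", "))
  }
  pm <- as.matrix(ivs[, cols, drop = FALSE])
  flagged <- rowSums(pm < p_threshold, na.rm = TRUE) > 0
  report <- lapply(which(flagged), function(i) {
    confounders[which(pm[i, ] < p_threshold)]
  })
  names(report) <- ivs$variant_id[flagged]
  list(
    ivs = ivs[!flagged, , drop = FALSE],
    dropped = ivs$variant_id[flagged],
    report = report
  )
}

# closed-form weighted regression through the origin (IVW workhorse)
ivw_core <- function(bx, by, w) {
  est <- sum(w * bx * by) / sum(w * bx^2)
  list(estimate = est, se_fixed = sqrt(1 / sum(w * bx^2)))
}

#' Inverse-variance-weighted MR estimate
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights `1/se_out^2`; the slope is the causal-effect
#' estimate. The SE is inflated multiplicatively by `sqrt(Q/(n-1))` when the
#' heterogeneity statistic exceeds its degrees of freedom (multiplicative
#' random-effects model).
#'
#' @param ivs IV table with at least 2 variants.
#' @param random_effects apply the multiplicative SE inflation (default TRUE).
#' @return An `mr_result` with estimate, SE, two-sided normal p-value, and
#'   Cochran's Q against the IVW slope.
#' @export
ivw_estimate <- function(ivs, random_effects = TRUE) {
  validate_iv_table(ivs, min_n = 2L)
  w <- 1 / ivs$se_out^2
  fit <- ivw_core(ivs$beta_exp, ivs$beta_out, w)
  n <- nrow(ivs)
  q <- cochran_q(ivs, fit$estimate, df = n - 1L)
  se <- fit$se_fixed
  if (random_effects && q$Q / (n - 1) > 1) se <- se * sqrt(q$Q / (n - 1))
  p <- 2 * pnorm(-abs(fit$estimate / se))
  mr_result("IVW", fit$estimate, se, p, n, Q = q$Q, Q_p = q$Q_p)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with a free
#' intercept (weights `1/se_out^2`), after re-signing each variant so its
#' exposure effect is positive. A nonzero intercept indicates directional
#' pleiotropy; `intercept_p` is the pleiotropy test. P-values use the t
#' distribution with `n - 2` degrees of freedom and the residual-variance
#' estimate is floored at 1 (multiplicative random effects, never deflating
#' the SE below the fixed-effect value).
#'
#' @param ivs IV table with at least 3 variants.
#' @return An `mr_result` with slope, `egger_intercept` and `intercept_p`.
#' @export
egger_regression <- function(ivs) {
  validate_iv_table(ivs, min_n = 3L)
  flip <- sign(ivs$beta_exp)
  flip[flip == 0] <- 1
  bx <- ivs$beta_exp * flip
  by <- ivs$beta_out * flip
  w <- 1 / ivs$se_out^2
  n <- length(bx)

  # closed-form weighted simple regression with intercept
  sw <- sum(w)
  mx <- sum(w * bx) / sw
  my <- sum(w * by) / sw
  sxx <- sum(w * (bx - mx)^2)
  slope <- sum(w * (bx - mx) * (by - my)) / sxx
  intercept <- my - slope * mx
  resid <- by - intercept - slope * bx
  sigma2 <- max(sum(w * resid^2) / (n - 2), 1)
  se_slope <- sqrt(sigma2 / sxx)
  se_int <- sqrt(sigma2 * (1 / sw + mx^2 / sxx))
  p_slope <- 2 * pt(-abs(slope / se_slope), df = n - 2)
  p_int <- 2 * pt(-abs(intercept / se_int), df = n - 2)
  q <- cochran_q(ivs, slope, df = n - 2L, intercept = intercept,
                 oriented_sign = flip)
  mr_result("Egger", slope, se_slope, p_slope, n,
            egger_intercept = intercept, intercept_p = p_int,
            Q = q$Q, Q_p = q$Q_p)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_i (beta_out_i - slope * beta_exp_i - intercept)^2` with
#' `w = 1/se_out^2`, compared to a chi-square with `df` degrees of freedom
#' (`n - 1` for the IVW slope, `n - 2` for the Egger fit).
#'
#' @param ivs IV table.
#' @param slope fitted causal slope.
#' @param df reference degrees of freedom (default `n - 1`).
#' @param intercept optional fitted intercept (Egger); 0 by default.
#' @param oriented_sign optional per-variant sign used when the slope was
#'   fitted on re-signed effects.
#' @return A list with `Q` and `Q_p`.
#' @export
cochran_q <- function(ivs, slope, df = nrow(ivs) - 1L, intercept = 0,
                      oriented_sign = NULL) {
  validate_iv_table(ivs, min_n = 2L)
  bx <- ivs$beta_exp
  by <- ivs$beta_out
  if (!is.null(oriented_sign)) {
    bx <- bx * oriented_sign
    by <- by * oriented_sign
  }
  w <- 1 / ivs$se_out^2
  Q <- sum(w * (by - intercept - slope * bx)^2)
  list(Q = Q, Q_p = pchisq(Q, df = max(df, 1L), lower.tail = FALSE))
}

# leave-one-out IVW slopes for every variant, via sufficient statistics
loo_slopes <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO global pleiotropy test and outlier-corrected estimate
#'
#' The observed residual sum of squares (RSS) uses leave-one-out IVW fits:
#' each variant's residual is taken against the slope estimated from all
#' other variants. A parametric null distribution is built by redrawing
#' outcome effects from `Normal(loo_slope_i * beta_exp_i, se_out_i)` in
#' `n_sim` simulations, recomputing the RSS (with leave-one-out slopes
#' inside each simulation); the global p-value is the fraction of simulated
#' RSS values at or above the observed one. Per-variant outliers are called
#' by comparing each observed squared residual to its simulated null with a
#' Bonferroni-corrected threshold `outlier_alpha / n`. The corrected
#' estimate is IVW on the non-outlier set (identical to plain IVW when no
#' outlier is found).
#'
#' @param ivs IV table with at least 4 variants.
#' @param n_sim number of null simulations (>= 1000).
#' @param outlier_alpha family-wise outlier significance level.
#' @param seed integer RNG seed for the simulations.
#' @return An `mr_result` (method `"PRESSO-corrected"`) with
#'   `presso_global_p`, `outlier_ids`, and IVW fields computed on the
#'   retained instruments.
#' @export
mr_presso <- function(ivs, n_sim = 5000L, outlier_alpha = 0.05, seed = NULL) {
  validate_iv_table(ivs, min_n = 4L)
  n_sim <- check_count(n_sim, "n_sim", min = 1000L)
  bx <- ivs$beta_exp
  by <- ivs$beta_out
  se <- ivs$se_out
  w <- 1 / se^2
  n <- length(bx)

  slopes_loo <- loo_slopes(bx, by, w)
  res_obs <- w * (by - slopes_loo * bx)^2
  rss_obs <- sum(res_obs)

  with_seed(seed, {
    mu <- slopes_loo * bx
    by_sim <- matrix(rnorm(n * n_sim, mean = mu, sd = se), nrow = n)
    # leave-one-out slopes inside each simulation, vectorized over sims
    wbx <- w * bx
    sxx <- sum(w * bx^2)
    sxy_sim <- colSums(wbx * by_sim)
    slope_sim <- (matrix(sxy_sim, n, n_sim, byrow = TRUE) - wbx * by_sim) /
      (sxx - w * bx^2)
    res_sim <- w * (by_sim - slope_sim * bx)^2
    rss_sim <- colSums(res_sim)
    global_p <- mean(rss_sim >= rss_obs)

    p_var <- rowMeans(res_sim >= res_obs)
    outliers <- which(p_var < outlier_alpha / n)
  })

  outlier_ids <- ivs$variant_id[outliers]
  keep <- setdiff(seq_len(n), outliers)
  if (length(keep) < 2L) {
    stop_bad("no instruments remain after outlier removal")
  }
  fit <- ivw_estimate(ivs[keep, , drop = FALSE])
  mr_result("PRESSO-corrected", fit$estimate, fit$se, fit$p,
            n_iv_used = length(keep), Q = fit$Q, Q_p = fit$Q_p,
            presso_global_p = global_p, outlier_ids = outlier_ids)
}

#' Bonferroni adjustment
#'
#' @param p_values p-values in (0, 1].
#' @param m number of tests (default 3, the number of causal-effect tests in
#'   a bidirectional obesity/prediabetes/insulin-sensitivity design).
#' @return `pmin(1, m * p)`.
#' @export
bonferroni_adjust <- function(p_values, m = 3L) {
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE)) {
    stop_bad("p-values must lie in (0, 1]")
  }
  pmin(1, m * p_values)
}

#' Run the full MR estimator battery on a set of instruments
#'
#' Applies MR-PRESSO (global test, outlier removal, corrected IVW), then
#' Egger regression and Cochran's Q on the PRESSO-retained instruments, and
#' Bonferroni-adjusts the causal-effect p-values (PRESSO-corrected and
#' Egger slopes) over `n_tests`; heterogeneity and pleiotropy-intercept
#' p-values are reported unadjusted. When fewer than `min_instruments`
#' instruments are supplied the direction is marked not assessable (the
#' relevance assumption cannot be fulfilled).
#'
#' @param ivs IV table (may be empty).
#' @param n_sim,outlier_alpha,seed passed to [mr_presso()].
#' @param n_tests Bonferroni factor for the causal-effect p-values.
#' @param min_instruments minimum usable instruments (default 4, the PRESSO
#'   requirement).
#' @param direction label stored in the report.
#' @return A list of class `mr_report` with `status`, `presso`, `egger`,
#'   `q`, and adjusted p-values.
#' @export
run_mr_battery <- function(ivs, n_sim = 5000L, outlier_alpha = 0.05,
                           seed = NULL, n_tests = 3L, min_instruments = 4L,
                           direction = "exposure->outcome") {
  if (is.null(ivs) || nrow(ivs) < min_instruments) {
    return(structure(list(direction = direction, status = "not assessable",
                          n_iv = if (is.null(ivs)) 0L else nrow(ivs)),
                     class = "mr_report"))
  }
  presso <- mr_presso(ivs, n_sim = n_sim, outlier_alpha = outlier_alpha,
                      seed = seed)
  kept <- ivs[!ivs$variant_id %in% presso$outlier_ids, , drop = FALSE]
  egger <- if (nrow(kept) >= 3L) egger_regression(kept) else NULL
  presso$p_adjusted <- bonferroni_adjust(presso$p, n_tests)
  if (!is.null(egger)) egger$p_adjusted <- bonferroni_adjust(egger$p, n_tests)
  structure(
    list(direction = direction, status = "ok", n_iv = nrow(ivs),
         presso = presso, egger = egger,
         q = list(Q = presso$Q, Q_p = presso$Q_p)),
    class = "mr_report"
  )
}
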