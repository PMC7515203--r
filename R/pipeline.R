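# Configuration-driven orchestration: simulate inputs, run the MR battery,
# MT expression correction, deconvolution with leave-one-out validation,
# and the Matsuda prediction model, writing per-stage outputs, a JSON
# summary and a provenance record into one run directory.

#' Default pipeline configuration
#'
#' A small all-synthetic demo configuration; any element can be overridden
#' by the YAML file or list passed to [run_pipeline()].
#'
#' @return A nested list of stage toggles and module options.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    stages = list(simulate = TRUE, mr = TRUE, expression = TRUE,
                  deconvolution = TRUE, model = TRUE),
    mr = list(n_variants = 100L, causal_effect = -0.67,
              pleiotropy_frac = 0.05, pleiotropy_mode = "directional",
              n_sim = 2000L, p_threshold = 5e-8, r2_threshold = 0.01,
              ld_block_size = 4L, ld_within_r2 = 0.5),
    cells = list(n_subjects = 6L, n_celltypes = 8L, n_genes = 800L,
                 cells_per_subject = 150L, qc_min_genes = 25L,
                 qc_min_cells = 3L),
    bulk = list(libsize = 1e6, noise_cv = 0.1),
    cohort = list(n_individuals = 324L, target_r2_total = 0.44),
    model = list(preset = "bmi", n_groups = 20L)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

log_line <- function(log_path, fmt, ...) {
  cat(sprintf(paste0(fmt, "\n"), ...), file = log_path, append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order (simulate, mr, expression, deconvolution,
#' model); disabled stages are marked `"skipped"` in the summary. Every
#' output lands in `out_dir` together with `provenance.json` (config hash,
#' seed, package version) and `summary.json`. With identical configuration
#' the deterministic stage outputs are byte-identical across runs.
#'
#' @param config a YAML file path or a nested list overriding
#'   [default_pipeline_config()].
#' @param out_dir run directory; default is a `run_<hash>` directory under
#'   the current working directory.
#' @return The summary list, invisibly, with `out_dir` attached.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_pipeline_config(), config)
  cfg_path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  if (is.null(out_dir)) {
    out_dir <- file.path(getwd(), paste0("run_", substr(cfg_hash, 1, 8)))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  file.copy(cfg_path, file.path(out_dir, "config.yaml"), overwrite = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  cat(sprintf("pipeline started %s\n", format(Sys.time())), file = log_path)

  seed <- as.integer(cfg$seed)
  summary <- list(config_hash = cfg_hash, seed = seed,
                  package_version = as.character(utils::packageVersion("adipomr")))
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!isTRUE(cfg$stages[[name]])) {
      log_line(log_path, "stage %s: skipped", name)
      summary[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      summary[[name]] <<- list(status = "failed",
                               error = conditionMessage(res))
      jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stop_bad("stage %s failed: %s (partial results in %s)", name,
               conditionMessage(res), out_dir)
    }
    log_line(log_path, "stage %s: ok (%.1fs)", name,
             proc.time()[["elapsed"]] - t0)
    summary[[name]] <<- c(list(status = "ok"), res)
  }

  run_stage("simulate", function() {
    m <- cfg$mr
    sim <- simulate_mr_summary(mr_sim_config(
      n_variants = m$n_variants, causal_effect = m$causal_effect,
      pleiotropy_frac = m$pleiotropy_frac,
      pleiotropy_mode = m$pleiotropy_mode, seed = seed
    ))
    ld <- simulate_ld_blocks(m$n_variants, m$ld_block_size, m$ld_within_r2)
    write_iv_table(sim$ivs, file.path(out_dir, "ivs.tsv"))
    write_ld_matrix(ld, file.path(out_dir, "ld.tsv"))
    state$mr_sim <- sim
    state$ld <- ld

    cc <- cfg$cells
    ref <- simulate_sc_reference(cell_sim_config(
      n_subjects = cc$n_subjects, n_celltypes = cc$n_celltypes,
      n_genes = cc$n_genes, cells_per_subject = cc$cells_per_subject,
      seed = seed + 1L
    ))
    write_sc_reference(ref, file.path(out_dir, "sc_reference"))
    bulk <- simulate_bulk_mixtures(ref, libsize = cfg$bulk$libsize,
                                   noise_cv = cfg$bulk$noise_cv,
                                   seed = seed + 2L)
    write_expression_set(bulk, file.path(out_dir, "bulk.tsv"))
    state$ref <- ref
    state$bulk <- bulk

    co <- simulate_cohort(pheno_sim_config(
      n_individuals = cfg$cohort$n_individuals,
      target_r2_total = cfg$cohort$target_r2_total, seed = seed + 3L
    ))
    write_cohort_table(co$cohort, file.path(out_dir, "cohort.tsv"))
    state$cohort_sim <- co
    log_line(log_path,
             "thresholds in effect: p<%g, r2<%g, chi-square<=1, >=%d genes/cell, >=%d cells/gene, HbA1c band %.1f-%.1f",
             cfg$mr$p_threshold, cfg$mr$r2_threshold, cfg$cells$qc_min_genes,
             cfg$cells$qc_min_cells, 5.7, 6.4)
    list(n_variants = m$n_variants, n_cells = nrow(ref$counts),
         n_individuals = nrow(co$cohort))
  })

  run_stage("mr", function() {
    ivs <- if (!is.null(state$mr_sim)) state$mr_sim$ivs else
      read_iv_table(file.path(out_dir, "ivs.tsv"))
    ld <- if (!is.null(state$ld)) state$ld else
      read_ld_matrix(file.path(out_dir, "ld.tsv"))
    sel <- select_ivs(ivs, ld, p_threshold = cfg$mr$p_threshold,
                      r2_threshold = cfg$mr$r2_threshold)
    fwd <- run_mr_battery(sel, n_sim = cfg$mr$n_sim, seed = seed + 10L,
                          direction = "exposure->outcome")
    rev <- run_mr_battery(sel[0, ], direction = "outcome->exposure")
    report <- list(forward = unclass_report(fwd), reverse = unclass_report(rev))
    jsonlite::write_json(report, file.path(out_dir, "mr_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    scatter <- sel[, c("variant_id", "beta_exp", "se_exp", "beta_out",
                       "se_out")]
    write_tsv(scatter, file.path(out_dir, "mr_scatter.tsv"))
    list(n_selected = nrow(sel),
         estimate = if (fwd$status == "ok") fwd$presso$estimate else NA,
         p_adjusted = if (fwd$status == "ok") fwd$presso$p_adjusted else NA,
         global_p = if (fwd$status == "ok") fwd$presso$presso_global_p
                    else NA,
         reverse_status = rev$status)
  })

  run_stage("expression", function() {
    cohort <- if (!is.null(state$cohort_sim)) state$cohort_sim$cohort else
      read_cohort_table(file.path(out_dir, "cohort.tsv"))
    metrics <- rna_metrics_excluding_mt(cohort)
    tech <- cbind(metrics[, c("exonic_pct", "intronic_pct",
                              "intergenic_pct")],
                  cohort[, grep("^tf_", names(cohort)), drop = FALSE])
    mt_int <- inverse_normal_transform(cohort$mt_expression)
    mt_adj <- residualize(mt_int, as.matrix(tech))
    out <- data.frame(id = cohort$id, mt_expression = cohort$mt_expression,
                      mt_adjusted = mt_adj)
    write_tsv(out, file.path(out_dir, "mt_adjusted.tsv"))
    state$mt_adjusted <- mt_adj
    list(n_samples = nrow(out),
         n_technical_factors = ncol(tech))
  })

  run_stage("deconvolution", function() {
    ref <- if (!is.null(state$ref)) state$ref else
      read_sc_reference(file.path(out_dir, "sc_reference"))
    bulk <- if (!is.null(state$bulk)) state$bulk else
      read_expression_set(file.path(out_dir, "bulk.tsv"))
    qc <- qc_reference(ref, min_genes = cfg$cells$qc_min_genes,
                       min_cells = cfg$cells$qc_min_cells)
    loo <- loo_validate(qc, bulk)
    sig <- select_signature_genes(qc)
    pb <- build_pseudobulk(qc)
    filt <- concordance_filter(bulk$tpm, pb$pseudobulk)
    genes_use <- intersect(sig$gene_id, filt$genes)
    props <- deconvolve_proportions(bulk, pb$profiles, genes = genes_use)
    write_tsv(cbind(sample = rownames(props), as.data.frame(props)),
              file.path(out_dir, "proportions.tsv"))
    write_tsv(filt$stats, file.path(out_dir, "concordance_filter.tsv"))
    loo_tab <- data.frame(
      subject = rep(rownames(loo$estimated), ncol(loo$estimated)),
      celltype = rep(colnames(loo$estimated), each = nrow(loo$estimated)),
      estimated = as.numeric(loo$estimated),
      truth = as.numeric(loo$truth)
    )
    write_tsv(loo_tab, file.path(out_dir, "loo_scatter.tsv"))
    jsonlite::write_json(
      list(per_celltype = loo$per_celltype, overall_r = loo$overall_r,
           overall_rmse = loo$overall_rmse, n_signature = nrow(sig),
           n_genes_used = length(genes_use)),
      file.path(out_dir, "loo_summary.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE, dataframe = "rows"
    )
    list(n_signature_genes = nrow(sig), n_genes_used = length(genes_use),
         loo_overall_r = loo$overall_r, loo_rmse = loo$overall_rmse)
  })

  run_stage("model", function() {
    cohort_raw <- if (!is.null(state$cohort_sim)) state$cohort_sim$cohort
      else read_cohort_table(file.path(out_dir, "cohort.tsv"))
    cohort <- prepare_cohort(cohort_raw, mt_adjusted = state$mt_adjusted)
    ct <- attr(cohort, "celltypes")
    m1 <- fit_model1(cohort)
    ve <- variance_explained(cohort, list(
      bodyfat = "bodyfat_pct", mt = "mt_expression",
      celltypes = setdiff(ct, ct[length(ct)])
    ))
    scan <- celltype_association_scan(cohort)
    cv <- cross_validate_100fold(cohort, preset = cfg$model$preset,
                                 n_groups = cfg$model$n_groups,
                                 seed = seed + 20L)
    jsonlite::write_json(
      list(model1 = list(coefficients = m1$coefficients,
                         r_squared = m1$r_squared, n = m1$n,
                         excluded_celltype = m1$excluded_celltype),
           variance_explained = as.list(ve),
           celltype_scan = scan,
           cv = list(r = cv$r, p = cv$p, n_groups = cfg$model$n_groups)),
      file.path(out_dir, "model_report.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE, dataframe = "rows"
    )
    list(model1_r2 = m1$r_squared, n = m1$n, oof_r = cv$r)
  })

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(config_hash = cfg_hash, seed = seed,
         package_version = summary$package_version),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  summary$out_dir <- out_dir
  invisible(summary)
}

unclass_report <- function(x) {
  if (x$status != "ok") return(list(status = x$status, n_iv = x$n_iv))
  list(status = x$status, n_iv = x$n_iv,
       presso = unclass(x$presso),
       egger = if (!is.null(x$egger)) unclass(x$egger) else NULL)
}

#' Render a human-readable report for a pipeline run
#'
#' @param run_dir a directory produced by [run_pipeline()].
#' @return The markdown report as a character string (also written to
#'   `report.md` in the run directory), invisibly.
#' @export
make_report <- function(run_dir) {
  summary_path <- file.path(run_dir, "summary.json")
  if (!file.exists(summary_path)) {
    stop_bad("no summary.json in %s: not a completed run directory", run_dir)
  }
  s <- jsonlite::read_json(summary_path)
  lines <- c("# Pipeline run report", "",
             sprintf("- config hash: %s", s$config_hash),
             sprintf("- seed: %s", s$seed), "")
  mr_path <- file.path(run_dir, "mr_report.json")
  if (!is.null(s$mr) && s$mr$status == "ok" && file.exists(mr_path)) {
    m <- jsonlite::read_json(mr_path)
    lines <- c(lines, "## Mendelian randomization", "")
    for (dir_name in names(m)) {
      d <- m[[dir_name]]
      if (d$status != "ok") {
        lines <- c(lines, sprintf("- %s: %s (n_iv = %s)", dir_name,
                                  d$status, d$n_iv))
      } else {
        lines <- c(lines, sprintf(
          "- %s: estimate %.4g, adjusted p %.3g, global pleiotropy p %.3g",
          dir_name, d$presso$estimate, d$presso$p_adjusted,
          d$presso$presso_global_p))
      }
    }
    lines <- c(lines, "")
  } else if (!is.null(s$mr)) {
    lines <- c(lines, "## Mendelian randomization", "",
               sprintf("- %s", s$mr$status), "")
  }
  loo_path <- file.path(run_dir, "loo_summary.json")
  if (!is.null(s$deconvolution) && s$deconvolution$status == "ok" &&
      file.exists(loo_path)) {
    l <- jsonlite::read_json(loo_path)
    lines <- c(lines, "## Deconvolution leave-one-out validation", "",
               sprintf("- overall r = %.3f, RMSE = %.4f", l$overall_r,
                       l$overall_rmse))
    for (row in l$per_celltype) {
      lines <- c(lines, sprintf("- %s: r = %s, RMSE = %.4f", row$celltype,
                                if (is.null(row$r) || is.na(row$r)) "NA"
                                else sprintf("%.3f", as.numeric(row$r)),
                                row$rmse))
    }
    lines <- c(lines, "")
  }
  model_path <- file.path(run_dir, "model_report.json")
  if (!is.null(s$model) && s$model$status == "ok" &&
      file.exists(model_path)) {
    mo <- jsonlite::read_json(model_path)
    lines <- c(lines, "## Matsuda index model", "",
               sprintf("- linear model R^2 = %.4f (n = %s, excluded: %s)",
                       mo$model1$r_squared, mo$model1$n,
                       mo$model1$excluded_celltype),
               sprintf("- out-of-fold prediction r = %.3f (p = %.3g)",
                       mo$cv$r, mo$cv$p), "",
               "| term | beta | p |", "|---|---|---|")
    for (row in mo$model1$coefficients) {
      lines <- c(lines, sprintf("| %s | %.4g | %.3g |", row$term, row$beta,
                                row$p))
    }
    lines <- c(lines, "")
  }
  txt <- paste(lines, collapse = "\n")
  writeLines(txt, file.path(run_dir, "report.md"))
  invisible(txt)
}
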