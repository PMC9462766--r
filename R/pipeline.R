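#' Derive a reproducible sub-seed from a master seed
#'
#' Counter-based splitting: every (stage, index) pair maps to its own
#' 31-bit seed, so e.g. changing how many optimizer runs are made never
#' perturbs the training seeds.
#'
#' @param master master integer seed.
#' @param stage stage label (any string).
#' @param index run counter within the stage.
#' @return positive integer seed below 2^31.
#' @export
derive_seed <- function(master, stage, index = 1L) {
  stage_code <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  v <- (as.double(master) * 48271 + stage_code * 10007 + index * 101) %%
    2147483629
  as.integer(v + 1)
}

#' Run the full modeling-and-optimization pipeline
#'
#' Orchestrates the analysis end to end on a factorial experiment table:
#' PCA outlier screen, repeated scale / split / fit of the three response
#' perceptrons under independent derived seeds, NSGA-II optimization over
#' each fitted surrogate triple with ideal-point selection, and
#' variable-sensitivity ranking — aggregated by medians across seeds.
#'
#' @param table a [pgr_table]; default the packaged wallflower factorial.
#' @param n_seeds number of (training, optimizer) seed pairs; default 10.
#' @param master_seed master seed all stage seeds are derived from.
#' @param mlp an [mlp_config()] (its seed is overridden per run).
#' @param n_hidden per-response hidden-layer sizes. The default is the
#'   architecture chosen by [select_hidden_size()] (grid 1-12, 5 seeds,
#'   minimum median test RMSE) on the packaged wallflower factorial; pass
#'   `NULL` to use `mlp$n_hidden` for every response, or your own named
#'   vector for other datasets.
#' @param ga a [ga_config()] (its seed is overridden per run).
#' @param alpha significance level of the outlier screen.
#' @param sensitivity_policy ablation policy for [vsr_table()].
#' @param optimize whether to run the optimization stage (skipping it gives
#'   a fit-and-sensitivity-only report).
#' @param out_dir optional directory; when given, writes `fit_reports.csv`,
#'   `pareto_front.csv`, `vsr_table.csv`, `recommendation.json` and
#'   `run_report.json`.
#' @return list of class `run_report`: `fit` (per-seed data.frame and
#'   `median` row block in the layout R2/RMSE/MBE by response and
#'   partition), `recommendation` (per-seed data.frame, componentwise
#'   `median`, and the median-distance solution), `sensitivity` (median
#'   VSE/VSR report), `outliers`, `seeds`, `config`.
#' @export
run_pipeline <- function(table = wallflower_data(), n_seeds = 10L,
                         master_seed = 1L, mlp = mlp_config(),
                         n_hidden = c(SN = 7L, SL = 3L, CW = 2L),
                         ga = ga_config(), alpha = 0.05,
                         sensitivity_policy = "mean", optimize = TRUE,
                         out_dir = NULL) {
  stopifnot(inherits(table, "pgr_table"), n_seeds >= 1)
  inputs <- table_inputs(table)
  outputs <- table_outputs(table)

  flags <- pca_outlier_screen(table, alpha = alpha)

  train_seeds <- vapply(seq_len(n_seeds), function(i) {
    derive_seed(master_seed, "train", i)
  }, integer(1))
  ga_seeds <- vapply(seq_len(n_seeds), function(i) {
    derive_seed(master_seed, "optimize", i)
  }, integer(1))

  fit_rows <- list()
  rec_rows <- list()
  sens_reports <- list()
  for (i in seq_len(n_seeds)) {
    cfg <- mlp; cfg$seed <- train_seeds[i]
    fit <- fit_response_models(table, cfg, n_hidden = n_hidden)
    fit_rows[[i]] <- cbind(seed = train_seeds[i], fit$reports)
    sens_reports[[i]] <- vsr_table(fit$models, table, sensitivity_policy)
    if (optimize) {
      gcfg <- ga; gcfg$seed <- ga_seeds[i]
      rec <- optimize_media(fit$models, table, gcfg)
      rec_rows[[i]] <- data.frame(
        train_seed = train_seeds[i], ga_seed = ga_seeds[i],
        as.list(rec$solution$genes), as.list(rec$solution$objectives),
        E = rec$solution$distance, front_size = nrow(rec$front))
    }
  }

  fit_all <- do.call(rbind, c(fit_rows, make.row.names = FALSE))
  metric_cols <- c("r2_train", "r2_test", "rmse_train", "rmse_test",
                   "mbe_train", "mbe_test")
  fit_median <- do.call(rbind, lapply(outputs, function(out) {
    sub <- fit_all[fit_all$response == out, metric_cols]
    data.frame(response = out, t(vapply(sub, median, numeric(1))))
  }))

  recommendation <- NULL
  if (optimize) {
    rec_all <- do.call(rbind, c(rec_rows, make.row.names = FALSE))
    comp_cols <- c(inputs, outputs, "E")
    rec_median <- vapply(rec_all[comp_cols], median, numeric(1))
    recommendation <- list(per_seed = rec_all, median = rec_median)
  }

  sens_combined <- do.call(rbind, sens_reports)
  sens_agg <- stats::aggregate(cbind(VSE, VSR, baseline_rmse) ~ output + input,
                               data = sens_combined, FUN = median)
  sens_agg <- sens_agg[order(match(sens_agg$output, outputs),
                             match(sens_agg$input, inputs)), ]
  sens_agg$rank <- stats::ave(-sens_agg$VSR, sens_agg$output,
                              FUN = function(v) rank(v, ties.method = "first"))
  rownames(sens_agg) <- NULL
  sensitivity <- structure(
    sens_agg[, c("output", "input", "VSE", "VSR", "rank", "baseline_rmse")],
    policy = "mean-substitution", per_seed = sens_reports,
    class = c("sensitivity_report", "data.frame"))

  report <- structure(list(
    fit = list(per_seed = fit_all, median = fit_median),
    recommendation = recommendation,
    sensitivity = sensitivity,
    outliers = flags,
    seeds = list(master = master_seed, train = train_seeds, ga = ga_seeds),
    config = list(n_seeds = n_seeds, mlp = mlp, n_hidden = n_hidden, ga = ga,
                  alpha = alpha, sensitivity_policy = sensitivity_policy)),
    class = "run_report")

  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report over", x$config$n_seeds, "seed(s)\n\nFit (medians):\n")
  print(x$fit$median, digits = 3, row.names = FALSE)
  if (!is.null(x$recommendation)) {
    cat("\nRecommended medium (componentwise median):\n")
    print(round(x$recommendation$median, 4))
  }
  cat("\nSensitivity (median VSR):\n")
  print.data.frame(x$sensitivity, digits = 4, row.names = FALSE)
  cat("\nOutlier flags:", sum(x$outliers), "of", length(x$outliers), "records\n")
  invisible(x)
}

#' Write the machine-readable artifacts of a pipeline run
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param out_dir destination directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$fit$per_seed, file.path(out_dir, "fit_reports.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(report$sensitivity),
            file.path(out_dir, "vsr_table.csv"), row.names = FALSE)
  if (!is.null(report$recommendation)) {
    write.csv(report$recommendation$per_seed,
              file.path(out_dir, "pareto_recommendations.csv"),
              row.names = FALSE)
    jsonlite::write_json(as.list(report$recommendation$median),
                         file.path(out_dir, "recommendation.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  doc <- list(fit_median = report$fit$median,
              recommendation_median = if (!is.null(report$recommendation))
                as.list(report$recommendation$median) else NULL,
              sensitivity = as.data.frame(report$sensitivity),
              n_outlier_flags = sum(report$outliers),
              seeds = report$seeds)
  jsonlite::write_json(doc, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

#' Tabulate discrepancies against the published reference values
#'
#' Compares a pipeline run on the packaged wallflower dataset with the
#' published reference results: test-partition R-squared per response, the
#' recommended medium and its predicted responses, and the sensitivity
#' importance orders.
#'
#' @param report a `run_report` from [run_pipeline()].
#' @return data.frame with columns `quantity`, `ours`, `reference`,
#'   `abs_diff`; rank agreement rows count discordant input ranks.
#' @export
compare_to_reference <- function(report) {
  ref <- reference_values()
  rows <- list()
  for (out in ref$fit$response) {
    ours <- report$fit$median$r2_test[report$fit$median$response == out]
    refv <- ref$fit$r2_test[ref$fit$response == out]
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = paste0("r2_test_", out), ours = ours, reference = refv,
      abs_diff = abs(ours - refv))
  }
  if (!is.null(report$recommendation)) {
    med <- report$recommendation$median
    for (nm in names(ref$recommendation)) {
      rows[[length(rows) + 1L]] <- data.frame(
        quantity = paste0("recommendation_", nm), ours = unname(med[[nm]]),
        reference = unname(ref$recommendation[[nm]]),
        abs_diff = abs(med[[nm]] - ref$recommendation[[nm]]))
    }
  }
  sens <- as.data.frame(report$sensitivity)
  for (out in unique(ref$vsr$output)) {
    ours_rank <- sens$rank[sens$output == out][
      match(ref$vsr$input[ref$vsr$output == out],
            sens$input[sens$output == out])]
    ref_rank <- ref$vsr$rank[ref$vsr$output == out]
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = paste0("rank_mismatches_", out),
      ours = sum(ours_rank != ref_rank), reference = 0,
      abs_diff = sum(ours_rank != ref_rank))
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
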