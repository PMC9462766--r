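#' Model error with one input made unavailable
#'
#' The Variable Sensitivity Error (VSE) of an input is the model RMSE on
#' `(X, y)` after that input column is replaced according to the ablation
#' policy — by default mean substitution, i.e. every value of the column is
#' replaced by its mean so the network can no longer draw information from
#' it. A large increase over the baseline RMSE marks an informative input.
#'
#' @param model a trained `mlp_model` with scalers.
#' @param X inputs in original units (matrix or data.frame).
#' @param y observed responses in original units.
#' @param which input index or name to ablate.
#' @param policy `"mean"` (substitute the column mean; default) or a single
#'   numeric value to substitute.
#' @return VSE (RMSE in response units).
#' @export
variable_sensitivity_error <- function(model, X, y, which, policy = "mean") {
  if (is.data.frame(X)) X <- as.matrix(X[model$input_scaler$columns])
  if (is.character(which)) which <- match(which, model$input_scaler$columns)
  if (is.na(which) || which < 1 || which > ncol(X)) {
    stop("invalid input index for ablation", call. = FALSE)
  }
  Xa <- X
  Xa[, which] <- if (identical(policy, "mean")) mean(X[, which])
                 else as.numeric(policy)
  yhat <- mlp_forward(model, Xa)
  sqrt(mean((as.numeric(y) - yhat)^2))
}

#' Variable sensitivity ratios and importance ranks
#'
#' For every (input, output) pair computes VSE (model RMSE with the input
#' mean-ablated) and VSR = VSE / baseline RMSE (the error with all inputs
#' available), then ranks inputs per output by descending VSR (rank 1 = most
#' important). A VSR of 1 means the model does not use the input; values
#' above 1 mark informative inputs.
#'
#' @param models named list of trained `mlp_model`s (one per response).
#' @param table the [pgr_table] to evaluate on (default: full dataset).
#' @param policy ablation policy passed to [variable_sensitivity_error()].
#' @return data.frame of class `sensitivity_report` with columns `output`,
#'   `input`, `VSE`, `VSR`, `rank`, `baseline_rmse`; attribute `policy`.
#' @export
vsr_table <- function(models, table, policy = "mean") {
  inputs <- table_inputs(table)
  outputs <- intersect(table_outputs(table), names(models))
  stopifnot(length(outputs) >= 1)
  df <- as.data.frame(table)
  X <- as.matrix(df[inputs])
  rows <- list()
  for (out in outputs) {
    model <- models[[out]]
    y <- df[[out]]
    baseline <- sqrt(mean((y - mlp_forward(model, X))^2))
    if (baseline == 0) {
      stop("baseline RMSE is zero for '", out,
           "': VSR undefined (perfect model)", call. = FALSE)
    }
    vse <- vapply(seq_along(inputs), function(i) {
      variable_sensitivity_error(model, X, y, i, policy)
    }, numeric(1))
    vsr <- vse / baseline
    rows[[out]] <- data.frame(output = out, input = inputs, VSE = vse,
                              VSR = vsr, rank = rank(-vsr, ties.method = "first"),
                              baseline_rmse = baseline)
  }
  structure(do.call(rbind, c(rows, make.row.names = FALSE)),
            policy = if (identical(policy, "mean")) "mean-substitution"
                     else "constant-substitution",
            class = c("sensitivity_report", "data.frame"))
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("sensitivity_report (", attr(x, "policy"), " ablation)\n", sep = "")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Median importance ranking over repeated fits
#'
#' Refits the response models under several seeds and aggregates VSR by the
#' median per (input, output), then re-ranks; smooths out the seed-to-seed
#' variability of single trained networks.
#'
#' @param table a [pgr_table].
#' @param seeds training/split seeds.
#' @param config base [mlp_config()] (seed overridden per run).
#' @param policy ablation policy.
#' @return `sensitivity_report` with median VSE/VSR and consensus ranks,
#'   plus attribute `per_seed` (list of per-seed reports).
#' @export
vsr_median <- function(table, seeds = 1:10, config = mlp_config(),
                       policy = "mean") {
  per_seed <- lapply(seeds, function(s) {
    cfg <- config; cfg$seed <- as.integer(s)
    fit <- fit_response_models(table, cfg)
    vsr_table(fit$models, table, policy)
  })
  combined <- do.call(rbind, per_seed)
  agg <- stats::aggregate(cbind(VSE, VSR, baseline_rmse) ~ output + input,
                          data = combined, FUN = median)
  out_order <- table_outputs(table)
  in_order <- table_inputs(table)
  agg <- agg[order(match(agg$output, out_order), match(agg$input, in_order)), ]
  agg$rank <- stats::ave(-agg$VSR, agg$output,
                         FUN = function(v) rank(v, ties.method = "first"))
  rownames(agg) <- NULL
  structure(agg[, c("output", "input", "VSE", "VSR", "rank", "baseline_rmse")],
            policy = "mean-substitution", per_seed = per_seed,
            class = c("sensitivity_report", "data.frame"))
}
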