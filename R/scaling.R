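#' Fit a [-1, 1] range scaler (mapminmax)
#'
#' Per-column affine map \eqn{x' = 2 (x - min) / (max - min) - 1}: the
#' observed column minimum maps to -1 and the maximum to +1, mirroring the
#' conventional min-max normalization used before perceptron training.
#'
#' @param x a data.frame / matrix or [pgr_table].
#' @param columns columns to fit; default all numeric columns of `x`.
#' @return object of class `range_scaler` holding per-column `min` and `max`.
#' @export
fit_scaler <- function(x, columns = NULL) {
  df <- as.data.frame(x)
  if (is.null(columns)) columns <- names(df)[vapply(df, is.numeric, logical(1))]
  missing_cols <- setdiff(columns, names(df))
  if (length(missing_cols) > 0) {
    stop("fit_scaler: unknown column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  lo <- vapply(columns, function(cn) min(df[[cn]]), numeric(1))
  hi <- vapply(columns, function(cn) max(df[[cn]]), numeric(1))
  degen <- hi <= lo
  if (any(degen)) {
    stop("fit_scaler: constant column(s) cannot be mapped to [-1, 1]: ",
         paste(columns[degen], collapse = ", "), call. = FALSE)
  }
  structure(list(columns = columns, min = lo, max = hi), class = "range_scaler")
}

#' @export
print.range_scaler <- function(x, ...) {
  cat("range_scaler -> [-1, 1]\n")
  print(data.frame(column = x$columns, min = x$min, max = x$max,
                   row.names = NULL))
  invisible(x)
}

.scaler_cols <- function(scaler, x) {
  df <- as.data.frame(x)
  missing_cols <- setdiff(scaler$columns, names(df))
  if (length(missing_cols) > 0) {
    stop("scaler column(s) absent from data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

#' Apply a fitted range scaler
#'
#' @param scaler a `range_scaler` from [fit_scaler()].
#' @param x data containing the scaler's columns (others pass through).
#' @return `x` with scaled columns.
#' @export
scaler_transform <- function(scaler, x) {
  df <- .scaler_cols(scaler, x)
  for (cn in scaler$columns) {
    df[[cn]] <- 2 * (df[[cn]] - scaler$min[[cn]]) /
      (scaler$max[[cn]] - scaler$min[[cn]]) - 1
  }
  df
}

#' Invert a fitted range scaler
#'
#' @inheritParams scaler_transform
#' @return `x` with the scaler's columns mapped back to original units.
#' @export
scaler_inverse <- function(scaler, x) {
  df <- .scaler_cols(scaler, x)
  for (cn in scaler$columns) {
    df[[cn]] <- (df[[cn]] + 1) / 2 *
      (scaler$max[[cn]] - scaler$min[[cn]]) + scaler$min[[cn]]
  }
  df
}

# vector forms used in the hot paths (columns in scaler order)
.scale_mat <- function(scaler, m) {
  sweep(sweep(m, 2, scaler$min, "-"), 2, (scaler$max - scaler$min) / 2, "/") - 1
}
.unscale_vec <- function(scaler, v, column) {
  (v + 1) / 2 * (scaler$max[[column]] - scaler$min[[column]]) + scaler$min[[column]]
}
.scale_vec <- function(scaler, v, column) {
  2 * (v - scaler$min[[column]]) / (scaler$max[[column]] - scaler$min[[column]]) - 1
}
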