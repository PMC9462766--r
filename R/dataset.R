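#' @importFrom stats median prcomp qbeta quantile rnorm runif sd var
#' @importFrom utils read.csv write.csv
NULL

.default_inputs <- c("BA", "Kin", "NAA", "GA3")
.default_outputs <- c("SN", "SL", "CW")

#' Construct a factorial growth-regulator experiment table
#'
#' A `pgr_table` is a plain `data.frame` carrying four plant-growth-regulator
#' dose columns (inputs, mg/L) and three measured shoot-proliferation
#' responses (outputs: shoot number, shoot length in cm, callus weight in g),
#' optionally with per-treatment standard errors (`SE_*`) and a replicate
#' count (`NREP`). The class records which columns are inputs and outputs so
#' downstream fitting, optimization and sensitivity steps need no further
#' configuration.
#'
#' @param df data.frame holding at least the input and output columns.
#' @param inputs character vector of 4 input column names.
#' @param outputs character vector of 3 output column names.
#' @return `df` with class `pgr_table` and attributes `inputs`, `outputs`.
#' @export
pgr_table <- function(df, inputs = .default_inputs, outputs = .default_outputs) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(c(inputs, outputs), names(df))
  if (length(missing_cols) > 0) {
    stop("pgr_table: missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (cn in c(inputs, outputs)) {
    v <- df[[cn]]
    if (!is.numeric(v)) stop("pgr_table: column '", cn, "' is not numeric", call. = FALSE)
    if (anyNA(v)) stop("pgr_table: column '", cn, "' contains NA", call. = FALSE)
    if (any(v < 0)) stop("pgr_table: column '", cn, "' has negative values", call. = FALSE)
  }
  se_cols <- intersect(paste0("SE_", outputs), names(df))
  for (cn in se_cols) {
    if (any(df[[cn]] < 0, na.rm = TRUE)) {
      stop("pgr_table: standard errors in '", cn, "' must be >= 0", call. = FALSE)
    }
  }
  key <- do.call(paste, c(df[inputs], sep = "\r"))
  if (anyDuplicated(key)) stop("pgr_table: duplicate input combinations", call. = FALSE)
  structure(df, inputs = inputs, outputs = outputs,
            class = c("pgr_table", "data.frame"))
}

#' @export
print.pgr_table <- function(x, ...) {
  cat(sprintf("pgr_table: %d treatments, inputs [%s], outputs [%s]\n",
              nrow(x), paste(attr(x, "inputs"), collapse = ", "),
              paste(attr(x, "outputs"), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}

#' Input / output column names of a table
#' @param x a [pgr_table].
#' @return character vector of column names.
#' @export
table_inputs <- function(x) attr(x, "inputs")

#' @rdname table_inputs
#' @export
table_outputs <- function(x) attr(x, "outputs")

# Parse a "6.50 +/- 0.129"-style cell into c(mean, se); plain numerics get NA se.
.parse_pm <- function(cell, row, col) {
  txt <- gsub("±", "+/-", trimws(as.character(cell)))
  parts <- strsplit(txt, "+/-", fixed = TRUE)[[1]]
  # typeset tables sometimes break "0. 000" across the decimal point
  parts <- gsub("[[:space:]]", "", parts)
  vals <- suppressWarnings(as.numeric(parts))
  if (length(vals) < 1 || length(vals) > 2 || anyNA(vals)) {
    stop(sprintf("non-numeric cell '%s' at row %d, column '%s'", cell, row, col),
         call. = FALSE)
  }
  if (length(vals) == 1) c(vals, NA_real_) else vals
}

#' Read a factorial experiment table from CSV
#'
#' Expects a header row with four input and three output columns; the default
#' dialect is `BA,Kin,NAA,GA3,SN,SL,CW` with optional `SE_SN,SE_SL,SE_CW,NREP`.
#' Output cells may be written as `mean ± SE` (or `mean +/- SE`); the SE part
#' is split into the corresponding `SE_*` column.
#'
#' @param path CSV file path.
#' @param inputs,outputs column names for doses and responses.
#' @return a [pgr_table].
#' @export
read_pgr_table <- function(path, inputs = .default_inputs,
                           outputs = .default_outputs) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, check.names = FALSE, colClasses = "character",
                  strip.white = TRUE)
  if (nrow(raw) == 0) stop("empty table: ", path, call. = FALSE)
  missing_cols <- setdiff(c(inputs, outputs), names(raw))
  if (length(missing_cols) > 0) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (cn in inputs) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(sprintf("non-numeric cell '%s' at row %d, column '%s'",
                   raw[[cn]][bad], bad, cn), call. = FALSE)
    }
    out[[cn]] <- v
  }
  for (cn in outputs) {
    parsed <- vapply(seq_len(nrow(raw)),
                     function(i) .parse_pm(raw[[cn]][i], i, cn), numeric(2))
    out[[cn]] <- parsed[1, ]
    se_name <- paste0("SE_", cn)
    if (se_name %in% names(raw)) {
      se <- suppressWarnings(as.numeric(raw[[se_name]]))
      out[[se_name]] <- se
    } else if (any(!is.na(parsed[2, ]))) {
      out[[se_name]] <- parsed[2, ]
    }
  }
  if ("NREP" %in% names(raw)) {
    out[["NREP"]] <- suppressWarnings(as.integer(raw[["NREP"]]))
  }
  pgr_table(out, inputs = inputs, outputs = outputs)
}

#' Write a factorial experiment table to CSV
#'
#' Full-precision round-trip companion of [read_pgr_table()].
#'
#' @param x a [pgr_table].
#' @param path destination CSV path.
#' @export
write_pgr_table <- function(x, path) {
  stopifnot(inherits(x, "pgr_table"))
  df <- as.data.frame(x)
  for (cn in names(df)) {
    if (is.double(df[[cn]])) df[[cn]] <- format(df[[cn]], digits = 17, trim = TRUE)
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load the packaged wallflower factorial dataset
#'
#' The packaged fixture holds the 4 x 4 x 2 x 2 factorial of BA, Kin, NAA and
#' GA3 doses (64 treatment means with standard errors over 4 replicates) for
#' in vitro shoot proliferation of wallflower (*Erysimum cheiri*): shoot
#' number, shoot length (cm) and callus weight (g) scored after 8 weeks.
#'
#' @return a [pgr_table] with 64 records.
#' @export
wallflower_data <- function() {
  path <- system.file("extdata", "wallflower_table1.csv", package = "shootopt",
                      mustWork = TRUE)
  read_pgr_table(path)
}

#' Split a table into training and testing partitions
#'
#' Draws a uniformly random permutation under `seed`. The test partition
#' receives `ceiling((1 - fraction) * N)` records and training the rest, so
#' the held-out set is never rounded away (for the 64-cell factorial at the
#' default 0.8 this gives 51 training / 13 testing records).
#'
#' @param x a [pgr_table] (or anything with rows).
#' @param fraction training fraction in (0, 1); default 0.8.
#' @param seed integer seed making the split reproducible.
#' @return list with integer vectors `train`, `test` plus `fraction`, `seed`;
#'   class `split_index`.
#' @export
split_table <- function(x, fraction = 0.8, seed = 1L) {
  n <- nrow(x)
  if (is.null(n) || n < 1) stop("cannot split an empty table", call. = FALSE)
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)", call. = FALSE)
  n_train <- n - as.integer(ceiling((1 - fraction) * n))
  if (n_train == 0 || n_train == n) {
    stop(sprintf("invalid split: %d train / %d test from %d records",
                 n_train, n - n_train, n), call. = FALSE)
  }
  perm <- local({
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    sample.int(n)
  })
  structure(list(train = sort(perm[seq_len(n_train)]),
                 test = sort(perm[(n_train + 1L):n]),
                 fraction = fraction, seed = as.integer(seed)),
            class = "split_index")
}

# Save/restore the global RNG state so seeded helpers do not perturb callers.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Screen for multivariate outliers by principal component analysis
#'
#' Runs correlation-matrix PCA over the numeric input and output columns,
#' retains the leading components reaching at least `var_explained`
#' cumulative variance, and flags records whose in-sample Hotelling T-squared
#' exceeds the exact Beta-distribution control limit. Because every record is
#' tested, the level is Bonferroni-corrected (`alpha / N` per record) so that
#' `alpha` is the familywise probability of flagging anything in clean data —
#' without the correction a 64-record table would flag about 3 perfectly
#' ordinary records at `alpha = 0.05`. This is a screen only: flags are
#' reported, records are never removed.
#'
#' @param x a [pgr_table].
#' @param alpha familywise significance level (default 0.05).
#' @param var_explained cumulative variance ratio for component retention.
#' @return logical vector of per-record flags with attributes `t2`
#'   (the statistic), `limit`, and `n_components`.
#' @export
pca_outlier_screen <- function(x, alpha = 0.05, var_explained = 0.95) {
  stopifnot(inherits(x, "pgr_table"))
  cols <- c(table_inputs(x), table_outputs(x))
  m <- as.matrix(as.data.frame(x)[cols])
  n <- nrow(m)
  if (n < 3) stop("need at least 3 records to screen", call. = FALSE)
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    warning("constant column(s) dropped from PCA screen: ",
            paste(cols[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  if (ncol(m) < 2 || all(apply(m, 2, sd) == 0)) {
    warning("degenerate covariance; no outliers flagged")
    return(structure(rep(FALSE, n), t2 = rep(0, n), limit = Inf, n_components = 0L))
  }
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  ev <- ev[ev > 1e-12]
  k <- which(cumsum(ev) / sum(pc$sdev^2) >= var_explained)[1]
  if (is.na(k)) k <- length(ev)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  t2 <- rowSums(sweep(scores^2, 2, ev[seq_len(k)], "/"))
  # exact in-sample limit: T2/( (n-1)^2/n ) ~ Beta(k/2, (n-k-1)/2);
  # Bonferroni over the n tested records
  limit <- (n - 1)^2 / n * qbeta(1 - alpha / n, k / 2, (n - k - 1) / 2)
  structure(t2 > limit, t2 = t2, limit = limit, n_components = as.integer(k))
}
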