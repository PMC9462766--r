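#' Specification of a synthetic dose-response surface family
#'
#' Describes a full-factorial growth-regulator experiment with known ground
#' truth. Each response follows a saturating quadratic-with-interactions
#' surface on dose fractions \eqn{u_i = x_i / \max(x_i)}:
#' \deqn{y(x) = \max\{0,\; c \,[\sigma(\eta(u)) - \sigma(\eta(0))]\},\quad
#'       \eta(u) = b_0 + \sum_i b_i u_i + \sum_i q_i u_i^2 +
#'                 \sum_{i<j} I_{ij} u_i u_j}
#' with \eqn{\sigma} the logistic link and \eqn{c} a saturation ceiling.
#' Negative quadratic terms in the cytokinins give the interior optimum seen
#' in real proliferation data (shoot formation declines again at high
#' cytokinin doses) while the callus response stays monotone. Observed cell
#' values are the true mean plus Gaussian replicate noise
#' \eqn{N(0, sd/\sqrt{n_{reps}})}, clipped at zero.
#'
#' The defaults emulate the packaged wallflower factorial: the same factor
#' grid (BA, Kin in \{0, 0.5, 1, 2\}; NAA in \{0, 0.1\}; GA3 in \{0, 0.2\}
#' mg/L), response ranges close to the observed ones (shoot number 0-6.5,
#' shoot length 0-4 cm, callus weight 0-0.3 g), a planted interior optimum
#' in the cytokinin plane, and per-output noise at the magnitude of the
#' observed standard errors.
#'
#' @param levels named list of factor levels per input (mg/L).
#' @param surfaces named list per output with elements `intercept`, `linear`
#'   (named by input), `quadratic`, `interactions` (named `"A:B"`),
#'   `ceiling`.
#' @param noise_sd named per-output replicate standard deviation (original
#'   response units, per single observation).
#' @param n_reps replicates per treatment cell.
#' @param seed integer seed for noise generation.
#' @return list of class `surface_spec`.
#' @export
surface_spec <- function(levels = list(BA = c(0, 0.5, 1, 2),
                                       Kin = c(0, 0.5, 1, 2),
                                       NAA = c(0, 0.1),
                                       GA3 = c(0, 0.2)),
                         surfaces = NULL,
                         noise_sd = c(SN = 0.32, SL = 0.012, CW = 0.005),
                         n_reps = 4L, seed = 1L) {
  if (is.null(surfaces)) {
    surfaces <- list(
      SN = list(intercept = -2,
                linear = c(BA = 4, Kin = 3.5, NAA = 0.8, GA3 = 0.6),
                quadratic = c(BA = -2.2, Kin = -1.5, NAA = 0, GA3 = 0),
                interactions = c("BA:Kin" = -1.5),
                ceiling = 8.5),
      SL = list(intercept = -1.5,
                linear = c(BA = 5, Kin = 4.5, NAA = 0.5, GA3 = 0.9),
                quadratic = c(BA = -2, Kin = -1.8, NAA = 0, GA3 = 0),
                interactions = c("BA:Kin" = -1),
                ceiling = 5.05),
      CW = list(intercept = -3,
                linear = c(BA = 2.8, Kin = 2.4, NAA = 0.7, GA3 = 0.4),
                quadratic = c(BA = 0, Kin = 0, NAA = 0, GA3 = 0),
                interactions = c("BA:Kin" = 1.2),
                ceiling = 0.32))
  }
  stopifnot(length(levels) >= 1, all(vapply(levels, min, numeric(1)) >= 0),
            n_reps >= 1)
  structure(list(levels = levels, surfaces = surfaces, noise_sd = noise_sd,
                 n_reps = as.integer(n_reps), seed = as.integer(seed)),
            class = "surface_spec")
}

# true mean responses at dose matrix X (columns = names(spec$levels))
.surface_eval <- function(spec, X) {
  inputs <- names(spec$levels)
  X <- as.matrix(as.data.frame(X)[, inputs, drop = FALSE])
  upper <- vapply(spec$levels, max, numeric(1))
  U <- sweep(X, 2, upper, "/")
  sigma <- function(t) 1 / (1 + exp(-t))
  out <- vapply(names(spec$surfaces), function(resp) {
    s <- spec$surfaces[[resp]]
    eta <- rep(s$intercept, nrow(U))
    for (cn in inputs) {
      eta <- eta + s$linear[[cn]] * U[, cn] + s$quadratic[[cn]] * U[, cn]^2
    }
    for (nm in names(s$interactions)) {
      pair <- strsplit(nm, ":", fixed = TRUE)[[1]]
      eta <- eta + s$interactions[[nm]] * U[, pair[1]] * U[, pair[2]]
    }
    pmax(0, s$ceiling * (sigma(eta) - sigma(s$intercept)))
  }, numeric(nrow(U)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, names(spec$surfaces)))
  out
}

# Planted optimum of the true surfaces, mirroring the pipeline's default
# recommendation rule: per-objective optima over the dose box define the true
# utopia point, and the optimum is the dose vector minimizing the Euclidean
# distance to it on original response units. Deterministic: dense grid search
# followed by bounded local refinement.
.planted_optimum <- function(spec) {
  inputs <- names(spec$levels)
  lower <- vapply(spec$levels, min, numeric(1))
  upper <- vapply(spec$levels, max, numeric(1))
  outputs <- names(spec$surfaces)
  directions <- c(SN = "max", SL = "max", CW = "min")[outputs]
  grid <- as.matrix(expand.grid(lapply(inputs, function(cn) {
    seq(lower[[cn]], upper[[cn]], length.out = 13)
  })))
  colnames(grid) <- inputs
  truth_grid <- .surface_eval(spec, grid)
  refine <- function(start, f) {
    stats::optim(start, function(x) {
      f(matrix(pmin(pmax(x, lower), upper), nrow = 1,
               dimnames = list(NULL, inputs)))
    }, method = "L-BFGS-B", lower = lower, upper = upper)
  }
  utopia <- vapply(seq_along(outputs), function(k) {
    s <- if (directions[k] == "max") -1 else 1
    start <- grid[which.min(s * truth_grid[, k]), ]
    # refine minimizes s*y, so the optimal y is s times the attained value
    s * refine(start, function(X) s * .surface_eval(spec, X)[, k])$value
  }, numeric(1))
  names(utopia) <- outputs
  dist_fn <- function(X) {
    v <- .surface_eval(spec, X)
    sqrt(rowSums(sweep(v, 2, utopia)^2))
  }
  opt <- refine(grid[which.min(dist_fn(grid)), ], dist_fn)
  genes <- stats::setNames(opt$par, inputs)
  list(genes = genes,
       responses = drop(.surface_eval(spec, matrix(genes, nrow = 1,
                                                   dimnames = list(NULL, inputs)))),
       utopia = utopia, distance = opt$value)
}

#' Generate a synthetic factorial experiment with known ground truth
#'
#' Builds the full factorial over the spec's factor levels, evaluates the
#' true surfaces at every cell, adds replicate-mean noise, and returns both
#' the observation table and a ground-truth record for scoring recovery.
#'
#' @param spec a [surface_spec()].
#' @return list with `table` (a [pgr_table] including `SE_*` and `NREP`
#'   columns) and `truth`: the true cell means (`cell_means`), the planted
#'   continuous optimum (`optimum`: genes, responses, ideal-point distance)
#'   and the per-output importance order implied by the linear coefficient
#'   magnitudes (`importance`).
#' @export
generate_pgr_data <- function(spec = surface_spec()) {
  stopifnot(inherits(spec, "surface_spec"))
  inputs <- names(spec$levels)
  outputs <- names(spec$surfaces)
  cells <- expand.grid(spec$levels)
  truth <- .surface_eval(spec, cells)
  df <- as.data.frame(cells)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed)
  for (k in seq_along(outputs)) {
    out <- outputs[k]
    sd_mean <- spec$noise_sd[[out]] / sqrt(spec$n_reps)
    df[[out]] <- pmax(0, truth[, k] + rnorm(nrow(df), 0, sd_mean))
    df[[paste0("SE_", out)]] <- rep(sd_mean, nrow(df))
  }
  df$NREP <- spec$n_reps
  importance <- lapply(outputs, function(out) {
    lin <- abs(spec$surfaces[[out]]$linear)
    names(sort(lin, decreasing = TRUE))
  })
  names(importance) <- outputs
  list(table = pgr_table(df, inputs = inputs, outputs = outputs),
       truth = list(spec = spec, cell_means = truth,
                    optimum = .planted_optimum(spec),
                    importance = importance))
}

#' Expand treatment means into pseudo-replicates
#'
#' Emits `NREP` pseudo-replicates per treatment cell, drawn as
#' \eqn{N(mean, SE \sqrt{n_{reps}})} and clipped at zero (the standard error
#' of a mean of n replicates corresponds to a per-observation standard
#' deviation of \eqn{SE \sqrt{n}}). The result is replicate-level data: the
#' input combinations repeat, with a `REP` column indexing replicates.
#'
#' @param table a [pgr_table] with `SE_*` and `NREP` columns.
#' @param seed integer seed.
#' @return data.frame with the table's columns plus `REP`, one row per
#'   pseudo-replicate.
#' @export
replicate_expand <- function(table, seed = 1L) {
  stopifnot(inherits(table, "pgr_table"))
  outputs <- table_outputs(table)
  df <- as.data.frame(table)
  se_cols <- paste0("SE_", outputs)
  if (!all(se_cols %in% names(df))) {
    stop("replicate_expand needs SE_ columns for every output", call. = FALSE)
  }
  if (!"NREP" %in% names(df)) stop("replicate_expand needs an NREP column",
                                   call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  reps <- lapply(seq_len(nrow(df)), function(i) {
    n <- df$NREP[i]
    block <- df[rep(i, n), c(table_inputs(table), outputs)]
    for (out in outputs) {
      sd_obs <- df[[paste0("SE_", out)]][i] * sqrt(n)
      block[[out]] <- pmax(0, df[[out]][i] + rnorm(n, 0, sd_obs))
    }
    block$REP <- seq_len(n)
    block
  })
  res <- do.call(rbind, c(reps, make.row.names = FALSE))
  rownames(res) <- NULL
  res
}

#' Score recovery of a planted optimum
#'
#' Compares a recommendation against the ground truth of the generating
#' [surface_spec()]: per-gene absolute error normalized by the factor bound
#' width, their mean as the aggregate score, and the gap between the
#' predicted responses and the true surface responses at the recommended
#' doses.
#'
#' @param solution an `ideal_point_solution` (or anything with `genes` and
#'   `objectives`).
#' @param spec the [surface_spec()] that generated the data.
#' @return list: `per_gene` (normalized absolute errors), `aggregate` (their
#'   mean), `response_gap` (|predicted - true| per output), `true_at_genes`.
#' @export
score_recovery <- function(solution, spec) {
  inputs <- names(spec$levels)
  genes <- solution$genes[inputs]
  opt <- .planted_optimum(spec)
  width <- vapply(spec$levels, function(v) max(v) - min(v), numeric(1))
  per_gene <- abs(genes - opt$genes) / width
  true_here <- drop(.surface_eval(spec, matrix(genes, nrow = 1,
                                               dimnames = list(NULL, inputs))))
  gap <- abs(solution$objectives[names(spec$surfaces)] - true_here)
  list(per_gene = per_gene, aggregate = mean(per_gene),
       response_gap = gap, true_at_genes = true_here,
       planted = opt)
}
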