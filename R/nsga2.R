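#' Genetic-algorithm configuration for media optimization
#'
#' Defaults are the settings used for the wallflower study: population 50,
#' 800 generations, crossover rate 0.8 and per-gene mutation rate 0.01, with
#' the canonical real-coded operator pair (simulated binary crossover,
#' distribution index `eta_c` = 15; polynomial mutation, `eta_m` = 20).
#'
#' @param pop_size even population size >= 4.
#' @param generations number of generations (fixed-count termination).
#' @param p_crossover per-pair SBX probability.
#' @param p_mutation per-gene polynomial-mutation probability.
#' @param eta_c,eta_m SBX and mutation distribution indices.
#' @param mutation_mode `"per_gene"` (default: `p_mutation` is the per-gene
#'   probability) or `"per_individual"` (`p_mutation` selects individuals,
#'   whose genes then mutate with probability 1 / n_genes).
#' @param seed integer seed; the whole run is deterministic given it.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(pop_size = 50L, generations = 800L, p_crossover = 0.8,
                      p_mutation = 0.01, eta_c = 15, eta_m = 20,
                      mutation_mode = c("per_gene", "per_individual"),
                      seed = 1L) {
  stopifnot(pop_size >= 4, pop_size %% 2 == 0, generations >= 1,
            p_crossover >= 0, p_crossover <= 1,
            p_mutation >= 0, p_mutation <= 1)
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 eta_c = eta_c, eta_m = eta_m,
                 mutation_mode = match.arg(mutation_mode),
                 seed = as.integer(seed)),
            class = "ga_config")
}

.dir_sign <- function(directions) {
  stopifnot(all(directions %in% c("max", "min")))
  ifelse(directions == "max", -1, 1)
}

#' Pareto dominance between two objective vectors
#'
#' `a` dominates `b` iff it is no worse in every objective (according to the
#' per-objective direction) and strictly better in at least one.
#'
#' @param a,b numeric objective vectors of equal length.
#' @param directions character vector of `"max"`/`"min"` per objective;
#'   default all `"min"`.
#' @return logical scalar.
#' @export
dominates <- function(a, b, directions = rep("min", length(a))) {
  stopifnot(length(a) == length(b), length(a) == length(directions),
            all(is.finite(a)), all(is.finite(b)))
  s <- .dir_sign(directions)
  fa <- s * a; fb <- s * b
  all(fa <= fb) && any(fa < fb)
}

# domination matrix for a minimization objective matrix (N x M):
# D[i, j] TRUE iff i dominates j
.domination_matrix <- function(f) {
  n <- nrow(f)
  leq <- matrix(TRUE, n, n)
  lt <- matrix(FALSE, n, n)
  for (k in seq_len(ncol(f))) {
    o <- outer(f[, k], f[, k], "<=")
    leq <- leq & o
    lt <- lt | outer(f[, k], f[, k], "<")
  }
  leq & lt
}

#' Fast non-dominated sorting
#'
#' Partitions a population into Pareto fronts: front 1 is the maximal
#' non-dominated set, front k the non-dominated set once fronts < k are
#' removed.
#'
#' @param objectives numeric matrix, one row per individual.
#' @param directions `"max"`/`"min"` per objective column; default all min.
#' @return list with `fronts` (list of index vectors) and `rank` (integer
#'   vector, 1-based front index per individual).
#' @export
nds_sort <- function(objectives, directions = rep("min", ncol(objectives))) {
  f <- as.matrix(objectives)
  stopifnot(nrow(f) >= 1, all(is.finite(f)))
  f <- sweep(f, 2, .dir_sign(directions), "*")
  D <- .domination_matrix(f)
  n_dominators <- colSums(D)
  rank <- integer(nrow(f))
  fronts <- list()
  remaining <- rep(TRUE, nrow(f))
  k <- 0L
  while (any(remaining)) {
    k <- k + 1L
    front <- which(remaining & n_dominators == 0L)
    if (length(front) == 0L) stop("non-dominated sort failed to progress")
    rank[front] <- k
    fronts[[k]] <- front
    remaining[front] <- FALSE
    n_dominators <- n_dominators - colSums(D[front, , drop = FALSE])
  }
  list(fronts = fronts, rank = rank)
}

#' Crowding distance within one Pareto front
#'
#' Per objective the front is sorted, the two boundary individuals receive
#' infinite distance and interior ones the normalized gap between their
#' neighbours; distances are summed over objectives. Fronts of size <= 2 are
#' all infinite. Direction is immaterial (the measure is symmetric).
#'
#' @param objectives numeric matrix for the members of a single front.
#' @return numeric vector of crowding distances.
#' @export
crowding_distance <- function(objectives) {
  f <- as.matrix(objectives)
  n <- nrow(f)
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (k in seq_len(ncol(f))) {
    ord <- order(f[, k])
    rng <- f[ord[n], k] - f[ord[1], k]
    d[ord[c(1, n)]] <- Inf
    if (rng > 0) {
      gaps <- (f[ord[3:n], k] - f[ord[1:(n - 2)], k]) / rng
      d[ord[2:(n - 1)]] <- d[ord[2:(n - 1)]] + gaps
    }
  }
  d
}

# binary tournament on (rank, crowding): lower rank wins, ties by larger
# crowding, remaining ties by the first contender (stable)
.tournament <- function(rank, crowd, n_picks) {
  i <- sample.int(length(rank), n_picks, replace = TRUE)
  j <- sample.int(length(rank), n_picks, replace = TRUE)
  pick_j <- (rank[j] < rank[i]) |
    (rank[j] == rank[i] & crowd[j] > crowd[i])
  ifelse(pick_j, j, i)
}

# bounded simulated binary crossover on two parent gene vectors
.sbx_pair <- function(p1, p2, lower, upper, eta) {
  c1 <- p1; c2 <- p2
  for (g in seq_along(p1)) {
    if (runif(1) > 0.5) next
    y1 <- min(p1[g], p2[g]); y2 <- max(p1[g], p2[g])
    if (y2 - y1 < 1e-14) next
    u <- runif(1)
    make_child <- function(beta) {
      a <- 2 - beta^-(eta + 1)
      if (u <= 1 / a) (u * a)^(1 / (eta + 1)) else (1 / (2 - u * a))^(1 / (eta + 1))
    }
    bq1 <- make_child(1 + 2 * (y1 - lower[g]) / (y2 - y1))
    bq2 <- make_child(1 + 2 * (upper[g] - y2) / (y2 - y1))
    ch1 <- 0.5 * ((y1 + y2) - bq1 * (y2 - y1))
    ch2 <- 0.5 * ((y1 + y2) + bq2 * (y2 - y1))
    if (runif(1) > 0.5) { tmp <- ch1; ch1 <- ch2; ch2 <- tmp }
    c1[g] <- min(max(ch1, lower[g]), upper[g])
    c2[g] <- min(max(ch2, lower[g]), upper[g])
  }
  list(c1, c2)
}

# bounded polynomial mutation applied gene-wise with probability p
.poly_mutate <- function(x, lower, upper, eta, p) {
  for (g in seq_along(x)) {
    if (runif(1) >= p) next
    rng <- upper[g] - lower[g]
    if (rng <= 0) next
    u <- runif(1)
    if (u < 0.5) {
      xy <- 1 - (x[g] - lower[g]) / rng
      dq <- (2 * u + (1 - 2 * u) * xy^(eta + 1))^(1 / (eta + 1)) - 1
    } else {
      xy <- 1 - (upper[g] - x[g]) / rng
      dq <- 1 - (2 * (1 - u) + 2 * (u - 0.5) * xy^(eta + 1))^(1 / (eta + 1))
    }
    x[g] <- min(max(x[g] + dq * rng, lower[g]), upper[g])
  }
  x
}

#' Elitist multi-objective search (NSGA-II)
#'
#' Real-coded NSGA-II over box-bounded genes: binary tournament selection on
#' (front rank, crowding distance), simulated binary crossover, polynomial
#' mutation, and (mu + lambda) environmental selection filling whole fronts
#' and truncating the last one by descending crowding distance (stable order
#' on ties). Termination is a fixed generation count.
#'
#' @param fn vectorized objective function: takes an `N x n_genes` matrix,
#'   returns an `N x n_obj` numeric matrix (original objective units).
#' @param lower,upper numeric bounds per gene.
#' @param directions `"max"`/`"min"` per objective.
#' @param config a [ga_config()].
#' @param snapshot_every if > 0, store the front-1 objective matrix every
#'   that many generations (for convergence diagnostics).
#' @return list of class `nsga2_result`: `genes`, `objectives` (final
#'   population), `rank`, `crowding`, `front` (indices of front 1), `log`
#'   (per-generation best value of each objective), `snapshots`.
#' @export
nsga2 <- function(fn, lower, upper, directions, config = ga_config(),
                  snapshot_every = 0L) {
  stopifnot(length(lower) == length(upper), all(lower < upper))
  n_genes <- length(lower)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)

  evaluate <- function(X) {
    F <- fn(X)
    if (is.null(dim(F))) F <- matrix(F, nrow = nrow(X))
    bad <- !apply(F, 1, function(r) all(is.finite(r)))
    if (any(bad)) {
      stop("objective evaluation returned non-finite values for genes [",
           paste(signif(X[which(bad)[1], ], 6), collapse = ", "), "]",
           call. = FALSE)
    }
    F
  }

  N <- config$pop_size
  X <- sweep(sweep(matrix(runif(N * n_genes), N, n_genes), 2,
                   upper - lower, "*"), 2, lower, "+")
  F <- evaluate(X)
  srt <- nds_sort(F, directions)
  crowd <- .crowding_by_front(F, srt$fronts)
  log <- matrix(NA_real_, config$generations, ncol(F))
  snapshots <- list()

  for (gen in seq_len(config$generations)) {
    parents <- .tournament(srt$rank, crowd, N)
    Xoff <- X[parents, , drop = FALSE]
    for (p in seq(1, N - 1, by = 2)) {
      if (runif(1) < config$p_crossover) {
        ch <- .sbx_pair(Xoff[p, ], Xoff[p + 1, ], lower, upper, config$eta_c)
        Xoff[p, ] <- ch[[1]]; Xoff[p + 1, ] <- ch[[2]]
      }
    }
    for (p in seq_len(N)) {
      if (identical(config$mutation_mode, "per_individual")) {
        if (runif(1) < config$p_mutation) {
          Xoff[p, ] <- .poly_mutate(Xoff[p, ], lower, upper, config$eta_m,
                                    1 / n_genes)
        }
      } else {
        Xoff[p, ] <- .poly_mutate(Xoff[p, ], lower, upper, config$eta_m,
                                  config$p_mutation)
      }
    }
    Foff <- evaluate(Xoff)
    Xall <- rbind(X, Xoff); Fall <- rbind(F, Foff)
    sel <- .environmental_selection(Fall, directions, N)
    X <- Xall[sel$keep, , drop = FALSE]
    F <- Fall[sel$keep, , drop = FALSE]
    srt <- list(fronts = sel$fronts, rank = sel$rank)
    crowd <- sel$crowding
    s <- .dir_sign(directions)
    log[gen, ] <- vapply(seq_len(ncol(F)),
                         function(k) s[k] * min(s[k] * F[, k]), numeric(1))
    if (snapshot_every > 0 && gen %% snapshot_every == 0) {
      snapshots[[length(snapshots) + 1L]] <-
        F[srt$fronts[[1]], , drop = FALSE]
    }
  }
  structure(list(genes = X, objectives = F, rank = srt$rank, crowding = crowd,
                 front = srt$fronts[[1]], log = log, snapshots = snapshots,
                 directions = directions, lower = lower, upper = upper,
                 config = config),
            class = "nsga2_result")
}

.crowding_by_front <- function(F, fronts) {
  crowd <- numeric(nrow(F))
  for (fr in fronts) crowd[fr] <- crowding_distance(F[fr, , drop = FALSE])
  crowd
}

# (mu + lambda) truncation: whole fronts first, partial front by descending
# crowding with stable input order on ties
.environmental_selection <- function(Fall, directions, N) {
  srt <- nds_sort(Fall, directions)
  crowd_all <- .crowding_by_front(Fall, srt$fronts)
  keep <- integer(0)
  for (fr in srt$fronts) {
    if (length(keep) + length(fr) <= N) {
      keep <- c(keep, fr)
    } else {
      need <- N - length(keep)
      ord <- fr[order(-crowd_all[fr])]   # radix-stable on ties
      keep <- c(keep, ord[seq_len(need)])
      break
    }
  }
  keep <- sort(keep)
  Fk <- Fall[keep, , drop = FALSE]
  srt_k <- nds_sort(Fk, directions)
  list(keep = keep, fronts = srt_k$fronts, rank = srt_k$rank,
       crowding = .crowding_by_front(Fk, srt_k$fronts))
}

#' @export
print.nsga2_result <- function(x, ...) {
  cat(sprintf("nsga2_result: pop %d, %d generations, front-1 size %d\n",
              nrow(x$genes), nrow(x$log), length(x$front)))
  invisible(x)
}

#' Scale objective values by the observed response ranges
#'
#' Maps each response to \eqn{(v - min_{obs}) / (max_{obs} - min_{obs})}
#' using the table's observed extremes. Values are not clipped: a surrogate
#' prediction beyond the observed best legitimately exceeds 1.
#'
#' @param values numeric matrix / data.frame with one column per response.
#' @param table the [pgr_table] supplying observed ranges.
#' @param outputs response names; default the table's outputs.
#' @return matrix of scaled values.
#' @export
scale_objectives <- function(values, table, outputs = table_outputs(table)) {
  v <- as.matrix(as.data.frame(values)[, outputs, drop = FALSE])
  df <- as.data.frame(table)
  for (k in seq_along(outputs)) {
    lo <- min(df[[outputs[k]]]); hi <- max(df[[outputs[k]]])
    if (hi <= lo) stop("zero observed range for ", outputs[k], call. = FALSE)
    v[, k] <- (v[, k] - lo) / (hi - lo)
  }
  v
}

#' Select the recommendation closest to the ideal point
#'
#' The ideal point assembles the best value of each objective (for the
#' proliferation problem: maximum shoot number, maximum shoot length,
#' minimum callus weight) and the front member minimizing the Euclidean
#' distance
#' \deqn{E = \sqrt{(SN - n)^2 + (SL - l)^2 + (CW - c)^2}}
#' to it is returned. Ties go to the smaller callus weight, then to
#' lexicographically smaller gene vectors.
#'
#' Two axes of the construction are selectable. `ideal_from = "observed"`
#' (default) takes the per-objective best over the experiment table;
#' `"front"` takes the attainable per-objective best over the candidate set
#' itself (the utopia point of the front). `scale = "observed"` (default)
#' computes E after range-scaling objectives to \[0, 1\] with
#' [scale_objectives()], which weights all three responses equally;
#' `"none"` computes E on original response units, which — because callus
#' weights are an order of magnitude smaller than shoot counts — effectively
#' prioritizes the shoot objectives. See [optimize_media()] for why the
#' end-to-end wrapper defaults to the `"front"`/`"none"` combination.
#'
#' @param genes matrix of candidate gene vectors (one row each).
#' @param objectives matrix of their predicted responses in original units,
#'   columns ordered as the table's outputs.
#' @param table the [pgr_table] defining observed extremes.
#' @param directions `"max"`/`"min"` per objective (defines "best").
#' @param ideal_from `"observed"` (table extremes) or `"front"` (attainable
#'   extremes of the candidate set).
#' @param scale `"observed"` (E on 0-1 range-scaled objectives) or `"none"`
#'   (E on original units).
#' @return list of class `ideal_point_solution`: `genes`, `objectives`,
#'   `distance` (E), `ideal` (original units), `index` of the selected row.
#' @export
ideal_point_select <- function(genes, objectives, table,
                               directions = c("max", "max", "min"),
                               ideal_from = c("observed", "front"),
                               scale = c("observed", "none")) {
  ideal_from <- match.arg(ideal_from)
  scale <- match.arg(scale)
  genes <- as.matrix(genes)
  obj <- as.matrix(objectives)
  stopifnot(nrow(genes) == nrow(obj), nrow(obj) >= 1)
  outputs <- table_outputs(table)
  df <- as.data.frame(table)
  ideal <- vapply(seq_along(outputs), function(k) {
    pool <- if (ideal_from == "observed") df[[outputs[k]]] else obj[, k]
    if (directions[k] == "max") max(pool) else min(pool)
  }, numeric(1))
  colnames(obj) <- outputs
  if (scale == "observed") {
    v <- scale_objectives(obj, table)
    vi <- drop(scale_objectives(matrix(ideal, nrow = 1,
                                       dimnames = list(NULL, outputs)), table))
  } else {
    v <- obj
    vi <- ideal
  }
  E <- sqrt(rowSums(sweep(v, 2, vi)^2))
  cw <- obj[, which(directions == "min")[1]]
  ord <- do.call(order, c(list(E, cw), as.data.frame(genes)))
  i <- ord[1]
  structure(list(genes = genes[i, ], objectives = obj[i, ], distance = E[i],
                 ideal = stats::setNames(ideal, outputs), index = i,
                 ideal_from = ideal_from, scale = scale),
            class = "ideal_point_solution")
}

#' @export
print.ideal_point_solution <- function(x, ...) {
  cat("ideal-point recommendation:\n")
  print(round(c(x$genes, x$objectives), 4))
  cat(sprintf("  distance to ideal point E = %.4f\n", x$distance))
  invisible(x)
}

#' Optimize the culture medium over trained surrogate models
#'
#' End-to-end optimization step: runs NSGA-II over the dose space bounded by
#' the observed factor ranges, maximizing predicted shoot number and length
#' and minimizing predicted callus weight as given by the three trained
#' perceptrons, then picks the single recommended medium by ideal-point
#' distance on the final Pareto front.
#'
#' The default selection (`selection = "utopia"`) measures the distance E on
#' original response units against the attainable per-objective optima of
#' the front: the recommendation is the medium that comes closest to jointly
#' attaining the front's best shoot number and best shoot length, with
#' callus weight entering only through its (small) natural magnitude. This
#' is the construction under which the published wallflower recommendation
#' (high shoot number with moderate callus) is the minimizer; the
#' equal-weight alternative (`selection = "scaled_observed"`: observed-data
#' ideal, E on 0-1 scaled objectives) instead returns a strongly
#' callus-averse compromise and is available for sensitivity checks.
#'
#' @param models named list of three `mlp_model` (one per response, as from
#'   [fit_response_models()]`$models`).
#' @param table the [pgr_table] the models were trained on (supplies bounds
#'   and observed extremes).
#' @param config a [ga_config()].
#' @param directions objective directions; default max SN, max SL, min CW.
#' @param bounds optional 2-row matrix (lower; upper) per input overriding
#'   the observed factor ranges.
#' @param selection `"utopia"` (attainable ideal, original units; default)
#'   or `"scaled_observed"` (observed ideal, range-scaled E).
#' @return list of class `media_recommendation`: `solution` (the
#'   [ideal_point_select()] result), `front` (data.frame of genes,
#'   objectives, rank and crowding for the final front), `result` (full
#'   `nsga2_result`).
#' @export
optimize_media <- function(models, table, config = ga_config(),
                           directions = c("max", "max", "min"),
                           bounds = NULL,
                           selection = c("utopia", "scaled_observed")) {
  selection <- match.arg(selection)
  inputs <- table_inputs(table)
  outputs <- table_outputs(table)
  stopifnot(all(outputs %in% names(models)))
  df <- as.data.frame(table)
  if (is.null(bounds)) {
    bounds <- rbind(vapply(inputs, function(cn) min(df[[cn]]), numeric(1)),
                    vapply(inputs, function(cn) max(df[[cn]]), numeric(1)))
  }
  fn <- function(X) {
    colnames(X) <- inputs
    vapply(outputs, function(out) mlp_forward(models[[out]], X), numeric(nrow(X)))
  }
  res <- nsga2(fn, bounds[1, ], bounds[2, ], directions, config)
  fr <- res$front
  sol <- ideal_point_select(res$genes[fr, , drop = FALSE],
                            res$objectives[fr, , drop = FALSE],
                            table, directions,
                            ideal_from = if (selection == "utopia") "front"
                                         else "observed",
                            scale = if (selection == "utopia") "none"
                                    else "observed")
  front_df <- data.frame(res$genes[fr, , drop = FALSE],
                         res$objectives[fr, , drop = FALSE])
  names(front_df) <- c(inputs, outputs)
  front_df$rank <- res$rank[fr]
  front_df$crowding <- res$crowding[fr]
  names(sol$genes) <- inputs
  names(sol$objectives) <- outputs
  structure(list(solution = sol, front = front_df, result = res),
            class = "media_recommendation")
}

#' @export
print.media_recommendation <- function(x, ...) {
  cat("media_recommendation (front size ", nrow(x$front), "):\n", sep = "")
  print(x$solution)
  invisible(x)
}
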