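#' Training configuration for the single-hidden-layer perceptron
#'
#' Defaults follow the classical Levenberg-Marquardt trainer with MacKay /
#' Foresee-Hagan evidence re-estimation of the regularization
#' hyperparameters: the objective is \eqn{F = \beta E_D + \alpha E_W} with
#' \eqn{E_D} the sum of squared errors and \eqn{E_W} the sum of squared
#' weights, and \eqn{\alpha, \beta} updated each epoch from the effective
#' number of parameters \eqn{\gamma}.
#'
#' @param n_hidden hidden-layer size (tansig units); default 5.
#' @param max_epochs maximum training epochs; default 1000.
#' @param grad_tol stop when the gradient infinity-norm falls below this.
#' @param e_tol stop when the mean squared training error falls below this.
#' @param mu0,mu_inc,mu_dec,mu_max Levenberg-Marquardt damping schedule.
#' @param alpha0,beta0 initial weight-penalty and error-precision
#'   hyperparameters.
#' @param regularization `"bayesian"` (evidence re-estimation, the default)
#'   or `"fixed"` (constant `alpha0`, `beta0`; debugging aid).
#' @param seed integer seed for the uniform \[-0.5, 0.5\] weight
#'   initialization.
#' @return list of class `mlp_config`.
#' @export
mlp_config <- function(n_hidden = 5L, max_epochs = 1000L, grad_tol = 1e-7,
                       e_tol = 1e-10, mu0 = 0.005, mu_inc = 10, mu_dec = 0.1,
                       mu_max = 1e10, alpha0 = 0.01, beta0 = 1,
                       regularization = c("bayesian", "fixed"), seed = 1L) {
  stopifnot(n_hidden >= 1, max_epochs >= 1, grad_tol > 0, e_tol > 0)
  structure(list(n_hidden = as.integer(n_hidden),
                 max_epochs = as.integer(max_epochs),
                 grad_tol = grad_tol, e_tol = e_tol, mu0 = mu0,
                 mu_inc = mu_inc, mu_dec = mu_dec, mu_max = mu_max,
                 alpha0 = alpha0, beta0 = beta0,
                 regularization = match.arg(regularization),
                 seed = as.integer(seed)),
            class = "mlp_config")
}

# ---- weight vector packing -------------------------------------------------

.n_weights <- function(m, n) m * n + m + m + 1L

.unpack_weights <- function(w, m, n) {
  list(w1 = matrix(w[seq_len(m * n)], nrow = m, ncol = n, byrow = TRUE),
       b1 = w[m * n + seq_len(m)],
       w2 = w[m * n + m + seq_len(m)],
       b0 = w[m * n + 2L * m + 1L])
}

.pack_weights <- function(w1, b1, w2, b0) c(as.vector(t(w1)), b1, w2, b0)

# forward pass on the scaled domain; X is K x n
.mlp_forward_scaled <- function(wts, X) {
  Z <- tanh(X %*% t(wts$w1) + rep(wts$b1, each = nrow(X)))
  drop(Z %*% wts$w2 + wts$b0)
}

# Jacobian of predictions wrt the packed weight vector (K x Nw), plus the
# hidden activations (reused by callers)
.mlp_jacobian <- function(wts, X) {
  K <- nrow(X); m <- length(wts$b1); n <- ncol(X)
  A <- X %*% t(wts$w1) + rep(wts$b1, each = K)
  Z <- tanh(A)
  D <- (1 - Z^2) * rep(wts$w2, each = K)      # K x m: dyhat/d(preact_j)
  J <- matrix(0, K, .n_weights(m, n))
  for (j in seq_len(m)) {
    J[, (j - 1L) * n + seq_len(n)] <- D[, j] * X
  }
  J[, m * n + seq_len(m)] <- D
  J[, m * n + m + seq_len(m)] <- Z
  J[, m * n + 2L * m + 1L] <- 1
  list(J = J, Z = Z)
}

# gradient of F = beta*sum(e^2) + alpha*sum(w^2) wrt packed weights
.mlp_grad <- function(w, m, X, y, alpha, beta) {
  wts <- .unpack_weights(w, m, ncol(X))
  jac <- .mlp_jacobian(wts, X)
  e <- drop(jac$Z %*% wts$w2 + wts$b0) - y
  drop(2 * beta * crossprod(jac$J, e) + 2 * alpha * w)
}

.mlp_objective <- function(w, m, X, y, alpha, beta) {
  wts <- .unpack_weights(w, m, ncol(X))
  e <- .mlp_forward_scaled(wts, X) - y
  beta * sum(e^2) + alpha * sum(w^2)
}

# ---- training --------------------------------------------------------------

#' Train a single-hidden-layer perceptron on scaled data
#'
#' Fits a tansig-hidden / linear-output network by Levenberg-Marquardt with
#' Bayesian regularization: each epoch takes a damped Gauss-Newton step on
#' \eqn{F = \beta E_D + \alpha E_W}, then re-estimates \eqn{\alpha =
#' \gamma / (2 E_W)} and \eqn{\beta = (K - \gamma) / (2 E_D)} with
#' \eqn{\gamma = N_w - 2 \alpha\, \mathrm{tr}(H^{-1})} the effective number
#' of parameters. Inputs and targets are expected on the \[-1, 1\] training
#' scale (see [fit_scaler()]).
#'
#' @param X numeric matrix (K observations x n inputs), scaled.
#' @param y numeric target vector of length K, scaled.
#' @param config an [mlp_config()].
#' @return object of class `mlp_model`: weight arrays `w1`, `b1`, `w2`, `b0`,
#'   transfer identifiers, training diagnostics (`epochs`, `alpha`, `beta`,
#'   `gamma`, `trace`), and empty scaler slots filled by the higher-level
#'   fitting wrappers.
#' @export
mlp_train <- function(X, y, config = mlp_config()) {
  X <- as.matrix(X); y <- as.numeric(y)
  K <- nrow(X); n <- ncol(X); m <- config$n_hidden
  if (K < 1 || length(y) != K) stop("X and y sizes disagree", call. = FALSE)
  if (K < m + 2) {
    warning(sprintf("only %d training pairs for %d hidden units: underdetermined",
                    K, m))
  }
  Nw <- .n_weights(m, n)
  w <- local({
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(config$seed)
    runif(Nw, -0.5, 0.5)
  })
  alpha <- config$alpha0; beta <- config$beta0
  bayes <- config$regularization == "bayesian"
  mu <- config$mu0
  gamma <- Nw
  trace <- matrix(NA_real_, config$max_epochs, 6,
                  dimnames = list(NULL, c("F_before", "F_after", "E", "alpha",
                                          "beta", "gamma")))
  epoch <- 0L
  stop_reason <- "max_epochs"
  repeat {
    if (epoch >= config$max_epochs) break
    epoch <- epoch + 1L
    wts <- .unpack_weights(w, m, n)
    jac <- .mlp_jacobian(wts, X)
    e <- drop(jac$Z %*% wts$w2 + wts$b0) - y
    ED <- sum(e^2); EW <- sum(w^2)
    Fcur <- beta * ED + alpha * EW
    if (!is.finite(Fcur)) {
      stop("training diverged (non-finite objective) at epoch ", epoch,
           call. = FALSE)
    }
    g <- drop(2 * beta * crossprod(jac$J, e) + 2 * alpha * w)
    if (max(abs(g)) < config$grad_tol) { stop_reason <- "grad_tol"; epoch <- epoch - 1L; break }
    if (ED / K < config$e_tol) { stop_reason <- "e_tol"; epoch <- epoch - 1L; break }
    H <- 2 * beta * crossprod(jac$J) + diag(2 * alpha, Nw)
    accepted <- FALSE
    while (mu <= config$mu_max) {
      delta <- tryCatch(solve(H + diag(mu, Nw), -g), error = function(err) NULL)
      if (!is.null(delta)) {
        w_new <- w + delta
        Fnew <- .mlp_objective(w_new, m, X, y, alpha, beta)
        if (is.finite(Fnew) && Fnew < Fcur) {
          w <- w_new
          mu <- max(mu * config$mu_dec, 1e-20)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * config$mu_inc
    }
    if (!accepted) { stop_reason <- "mu_max"; epoch <- epoch - 1L; break }
    # evidence re-estimation at the accepted weights
    wts <- .unpack_weights(w, m, n)
    jac <- .mlp_jacobian(wts, X)
    e <- drop(jac$Z %*% wts$w2 + wts$b0) - y
    ED <- sum(e^2); EW <- sum(w^2)
    # objective after the accepted step, under the epoch's (alpha, beta)
    F_accepted <- beta * ED + alpha * EW
    if (bayes) {
      H <- 2 * beta * crossprod(jac$J) + diag(2 * alpha, Nw)
      trH_inv <- tryCatch(sum(diag(solve(H))), error = function(err) NA_real_)
      if (is.finite(trH_inv)) {
        gamma <- Nw - 2 * alpha * trH_inv
        gamma <- min(max(gamma, 1e-6), Nw)
        alpha <- gamma / (2 * max(EW, 1e-12))
        beta <- max(K - gamma, 1e-3) / (2 * max(ED, 1e-12))
      }
    }
    trace[epoch, ] <- c(Fcur, F_accepted, ED / K, alpha, beta, gamma)
  }
  structure(list(n_inputs = n, n_hidden = m,
                 w1 = .unpack_weights(w, m, n)$w1,
                 b1 = .unpack_weights(w, m, n)$b1,
                 w2 = .unpack_weights(w, m, n)$w2,
                 b0 = .unpack_weights(w, m, n)$b0,
                 hidden_transfer = "tansig", output_transfer = "purelin",
                 input_scaler = NULL, target_scaler = NULL, target = NULL,
                 alpha = alpha, beta = beta, gamma = gamma,
                 epochs = epoch, stop_reason = stop_reason,
                 trace = trace[seq_len(epoch), , drop = FALSE],
                 config = config),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("mlp_model: %d-%d-1 (tansig/purelin)%s\n", x$n_inputs, x$n_hidden,
              if (!is.null(x$target)) paste0(", target ", x$target) else ""))
  cat(sprintf("  trained %d epochs (%s); alpha=%.4g beta=%.4g gamma=%.3g\n",
              x$epochs, x$stop_reason, x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Evaluate the perceptron forward equation
#'
#' Computes \eqn{\hat y = w_0 + \sum_j w_j \tanh(\sum_i w_{ji} x_i + w_{j0})}.
#' With `scaled = FALSE` (the default for models produced by
#' [fit_response_models()]) the inputs are passed through the model's input
#' scaler first and the prediction is mapped back to original response units.
#'
#' @param model an `mlp_model`.
#' @param x numeric vector of length `n_inputs`, or a matrix / data.frame
#'   with one row per prediction.
#' @param scaled if `TRUE`, `x` is already on the \[-1, 1\] domain and the
#'   raw network output is returned.
#' @return numeric vector of predictions.
#' @export
mlp_forward <- function(model, x, scaled = FALSE) {
  stopifnot(inherits(model, "mlp_model"))
  if (is.data.frame(x)) {
    cols <- if (!is.null(model$input_scaler)) model$input_scaler$columns
            else names(x)[seq_len(model$n_inputs)]
    x <- as.matrix(x[cols])
  }
  if (is.null(dim(x))) {
    # for a single-input model a bare vector is a batch of observations;
    # otherwise it is one observation
    x <- if (model$n_inputs == 1L) matrix(x, ncol = 1) else matrix(x, nrow = 1)
  }
  if (ncol(x) != model$n_inputs) {
    stop(sprintf("expected %d input columns, got %d", model$n_inputs, ncol(x)),
         call. = FALSE)
  }
  if (!scaled) {
    if (is.null(model$input_scaler)) {
      stop("model has no input scaler; pass scaled inputs", call. = FALSE)
    }
    x <- .scale_mat(model$input_scaler, x)
  }
  yhat <- .mlp_forward_scaled(model, x)
  if (!scaled) {
    if (is.null(model$target_scaler)) {
      stop("model has no target scaler; use scaled = TRUE", call. = FALSE)
    }
    yhat <- .unscale_vec(model$target_scaler, yhat, model$target)
  }
  yhat
}

#' Mean squared training error
#'
#' \eqn{E = (1/K) \sum_k (y_k - \hat y_k)^2} on the scaled domain used for
#' training.
#'
#' @param model an `mlp_model`.
#' @param X scaled input matrix.
#' @param y scaled target vector.
#' @return scalar E.
#' @export
training_error <- function(model, X, y) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (nrow(X) < 1) stop("empty data", call. = FALSE)
  mean((y - .mlp_forward_scaled(model, X))^2)
}

#' Regression performance measures
#'
#' Returns the three goodness-of-fit criteria used throughout the package:
#' \deqn{R^2 = 1 - \sum (y_i - \hat y_i)^2 / \sum (y_i - \bar y)^2}
#' \deqn{RMSE = \sqrt{\sum (\hat y_i - y_i)^2 / n}}
#' \deqn{MBE = (1/n) \sum (y_i - \hat y_i)}
#'
#' @param model an `mlp_model` (with scalers for original-unit evaluation).
#' @param X inputs in original units (or scaled, with `scaled = TRUE`).
#' @param y observed responses on the same scale as the predictions.
#' @param scaled evaluate on the scaled domain instead of original units.
#' @return named list `r2`, `rmse`, `mbe`. `r2` is `NA` with a warning when
#'   the targets have zero variance.
#' @export
mlp_evaluate <- function(model, X, y, scaled = FALSE) {
  y <- as.numeric(y)
  yhat <- mlp_forward(model, X, scaled = scaled)
  n <- length(y)
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else {
    warning("zero target variance: R^2 undefined")
    NA_real_
  }
  list(r2 = r2, rmse = sqrt(ss_res / n), mbe = mean(y - yhat))
}

# ---- per-response fitting over the factorial table -------------------------

#' Fit one perceptron per response column
#'
#' The standard modeling path for a factorial table: fit \[-1, 1\] range
#' scalers on the full table (inputs and responses), split 80/20 under
#' `seed` (unless a `split_index` is supplied), train one independent
#' single-output network per response by Bayesian-regularized
#' Levenberg-Marquardt, and report R-squared / RMSE / MBE on both partitions
#' in original response units.
#'
#' @param table a [pgr_table].
#' @param config an [mlp_config()]; its `seed` drives weight initialization.
#' @param split optional [split_table()] result; by default derived from
#'   `config$seed`.
#' @param outputs responses to fit; default all outputs of the table.
#' @param n_hidden optional named vector of per-response hidden sizes
#'   overriding `config$n_hidden` (as chosen by [select_hidden_size()]).
#' @return object of class `mlp_fit_set`: `models` (named list of
#'   `mlp_model`), `reports` (data.frame, one row per response with train and
#'   test metrics), `split`, `config`.
#' @export
fit_response_models <- function(table, config = mlp_config(), split = NULL,
                                outputs = NULL, n_hidden = NULL) {
  stopifnot(inherits(table, "pgr_table"))
  inputs <- table_inputs(table)
  if (is.null(outputs)) outputs <- table_outputs(table)
  if (!is.null(n_hidden)) stopifnot(all(outputs %in% names(n_hidden)))
  if (is.null(split)) split <- split_table(table, 0.8, seed = config$seed)
  df <- as.data.frame(table)
  in_scaler <- fit_scaler(df, inputs)
  Xs <- .scale_mat(in_scaler, as.matrix(df[inputs]))
  models <- list()
  reports <- list()
  for (out in outputs) {
    if (max(df[[out]]) <= min(df[[out]])) {
      stop("response '", out, "': zero variance, R^2 and scaling undefined",
           call. = FALSE)
    }
    t_scaler <- fit_scaler(df, out)
    ys <- .scale_vec(t_scaler, df[[out]], out)
    cfg <- config
    if (!is.null(n_hidden)) cfg$n_hidden <- as.integer(n_hidden[[out]])
    model <- mlp_train(Xs[split$train, , drop = FALSE], ys[split$train], cfg)
    model$input_scaler <- in_scaler
    model$target_scaler <- t_scaler
    model$target <- out
    ev_train <- mlp_evaluate(model, as.matrix(df[inputs])[split$train, , drop = FALSE],
                             df[[out]][split$train])
    ev_test <- mlp_evaluate(model, as.matrix(df[inputs])[split$test, , drop = FALSE],
                            df[[out]][split$test])
    models[[out]] <- model
    reports[[out]] <- data.frame(
      response = out, n_hidden = cfg$n_hidden, epochs = model$epochs,
      r2_train = ev_train$r2, r2_test = ev_test$r2,
      rmse_train = ev_train$rmse, rmse_test = ev_test$rmse,
      mbe_train = ev_train$mbe, mbe_test = ev_test$mbe,
      alpha = model$alpha, beta = model$beta, gamma = model$gamma)
  }
  structure(list(models = models,
                 reports = do.call(rbind, c(reports, make.row.names = FALSE)),
                 split = split, config = config),
            class = "mlp_fit_set")
}

#' @export
print.mlp_fit_set <- function(x, ...) {
  cat("mlp_fit_set:", length(x$models), "response model(s)\n")
  print(x$reports, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Choose the hidden-layer size by trial and error
#'
#' Trains over a grid of candidate sizes and several seeds for each response
#' and picks the size minimizing the median test RMSE; ties go to the
#' smaller (more parsimonious) network.
#'
#' @param table a [pgr_table].
#' @param grid candidate hidden sizes; default 1:12.
#' @param seeds training/split seeds; default 5 seeds.
#' @param config base [mlp_config()] (its `n_hidden`/`seed` are overridden).
#' @param outputs responses to tune; default all.
#' @return list: `chosen` (named integer vector per response) and `scores`
#'   (data.frame of response, n_hidden, median test RMSE).
#' @export
select_hidden_size <- function(table, grid = 1:12, seeds = 1:5,
                               config = mlp_config(), outputs = NULL) {
  stopifnot(length(grid) >= 1)
  if (is.null(outputs)) outputs <- table_outputs(table)
  scores <- list()
  for (m in grid) {
    rmse <- matrix(NA_real_, length(seeds), length(outputs),
                   dimnames = list(NULL, outputs))
    for (si in seq_along(seeds)) {
      cfg <- config
      cfg$n_hidden <- as.integer(m)
      cfg$seed <- as.integer(seeds[si])
      fit <- fit_response_models(table, cfg, outputs = outputs)
      rmse[si, ] <- fit$reports$rmse_test[match(outputs, fit$reports$response)]
    }
    scores[[length(scores) + 1L]] <- data.frame(
      response = outputs, n_hidden = as.integer(m),
      rmse_test_median = apply(rmse, 2, median))
  }
  scores <- do.call(rbind, c(scores, make.row.names = FALSE))
  chosen <- vapply(outputs, function(out) {
    s <- scores[scores$response == out, ]
    s <- s[order(s$rmse_test_median, s$n_hidden), ]
    s$n_hidden[1]
  }, integer(1))
  list(chosen = chosen, scores = scores)
}

# ---- serialization ---------------------------------------------------------

#' Save / load a trained perceptron as JSON
#'
#' Stores dimensions, weight arrays, transfer identifiers, scaler parameters
#' and training metadata; `mlp_from_json()` reverses the mapping exactly.
#'
#' @param model an `mlp_model`.
#' @param path JSON file path.
#' @return `mlp_to_json` returns `path` invisibly; `mlp_from_json` the model.
#' @export
mlp_to_json <- function(model, path) {
  stopifnot(inherits(model, "mlp_model"))
  ser_scaler <- function(s) {
    if (is.null(s)) NULL
    else list(columns = s$columns, min = unname(s$min), max = unname(s$max))
  }
  doc <- list(
    n_inputs = model$n_inputs, n_hidden = model$n_hidden,
    hidden_transfer = model$hidden_transfer,
    output_transfer = model$output_transfer,
    w1 = model$w1, b1 = model$b1, w2 = model$w2, b0 = model$b0,
    input_scaler = ser_scaler(model$input_scaler),
    target_scaler = ser_scaler(model$target_scaler),
    target = model$target,
    alpha = model$alpha, beta = model$beta, gamma = model$gamma,
    epochs = model$epochs, stop_reason = model$stop_reason)
  # 17 significant digits guarantee exact double-precision round-trip
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname mlp_to_json
#' @export
mlp_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  de_scaler <- function(s) {
    if (is.null(s)) NULL
    else structure(list(columns = s$columns,
                        min = stats::setNames(s$min, s$columns),
                        max = stats::setNames(s$max, s$columns)),
                   class = "range_scaler")
  }
  structure(list(n_inputs = as.integer(doc$n_inputs),
                 n_hidden = as.integer(doc$n_hidden),
                 w1 = matrix(doc$w1, nrow = doc$n_hidden),
                 b1 = as.numeric(doc$b1), w2 = as.numeric(doc$w2),
                 b0 = as.numeric(doc$b0),
                 hidden_transfer = doc$hidden_transfer,
                 output_transfer = doc$output_transfer,
                 input_scaler = de_scaler(doc$input_scaler),
                 target_scaler = de_scaler(doc$target_scaler),
                 target = doc$target,
                 alpha = doc$alpha, beta = doc$beta, gamma = doc$gamma,
                 epochs = doc$epochs, stop_reason = doc$stop_reason,
                 trace = NULL, config = NULL),
            class = "mlp_model")
}
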