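# Shared fixtures and independent oracles for the test suite.

# small factorial table with non-trivial responses, built in code
toy_table <- function() {
  grid <- expand.grid(BA = c(0, 1, 2), Kin = c(0, 1, 2),
                      NAA = c(0, 0.1), GA3 = c(0, 0.2))
  grid$SN <- with(grid, 2 * BA + Kin + 4 * NAA + GA3)
  grid$SL <- with(grid, 1 + BA + 0.5 * Kin)
  grid$CW <- with(grid, 0.05 * BA * Kin + 0.01)
  pgr_table(grid)
}

# hand-assembled 1-input / 1-hidden-unit model with explicit weights
toy_mlp <- function(w11 = 1, w10 = 0, w1 = 2, w0 = 0) {
  structure(list(n_inputs = 1L, n_hidden = 1L,
                 w1 = matrix(w11, 1, 1), b1 = w10, w2 = w1, b0 = w0,
                 hidden_transfer = "tansig", output_transfer = "purelin",
                 input_scaler = NULL, target_scaler = NULL, target = NULL,
                 alpha = 0, beta = 1, gamma = 0, epochs = 0L,
                 stop_reason = "manual", trace = NULL, config = NULL),
            class = "mlp_model")
}

# identity scaler over given columns (min -1, max 1 leaves values unchanged)
identity_scaler <- function(columns) {
  structure(list(columns = columns,
                 min = stats::setNames(rep(-1, length(columns)), columns),
                 max = stats::setNames(rep(1, length(columns)), columns)),
            class = "range_scaler")
}

# brute-force Pareto front peeling: repeatedly remove the set of individuals
# not dominated by any remaining individual (O(N^2 * fronts) oracle)
peel_fronts_oracle <- function(f, directions) {
  s <- ifelse(directions == "max", -1, 1)
  f <- sweep(as.matrix(f), 2, s, "*")
  n <- nrow(f)
  remaining <- seq_len(n)
  rank <- integer(n)
  k <- 0L
  dom <- function(i, j) all(f[i, ] <= f[j, ]) && any(f[i, ] < f[j, ])
  while (length(remaining) > 0) {
    k <- k + 1L
    nd <- remaining[vapply(remaining, function(j) {
      !any(vapply(remaining, function(i) i != j && dom(i, j), logical(1)))
    }, logical(1))]
    rank[nd] <- k
    remaining <- setdiff(remaining, nd)
  }
  rank
}

# Monte-Carlo hypervolume of a front (minimization orientation) against a
# fixed reference point, using a frozen quasi-random point cloud
mc_hypervolume <- function(front_min, ref, samples) {
  dominated <- vapply(seq_len(nrow(samples)), function(i) {
    any(apply(front_min, 1, function(p) all(p <= samples[i, ])))
  }, logical(1))
  mean(dominated) * prod(ref)
}

# finite-difference gradient of the regularized training objective
fd_grad <- function(w, m, X, y, alpha, beta, eps = 1e-6) {
  obj <- function(wv) shootopt:::.mlp_objective(wv, m, X, y, alpha, beta)
  vapply(seq_along(w), function(i) {
    e <- numeric(length(w)); e[i] <- eps
    (obj(w + e) - obj(w - e)) / (2 * eps)
  }, numeric(1))
}
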