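test_that("pairwise dominance follows the per-objective directions", {
  dirs <- c("max", "max", "min")
  expect_true(dominates(c(7, 4, 0.1), c(6, 3, 0.2), dirs))
  expect_false(dominates(c(7, 4, 0.1), c(7, 4, 0.1), dirs))
  expect_false(dominates(c(7, 3, 0.1), c(6, 4, 0.2), dirs))
  expect_false(dominates(c(6, 4, 0.2), c(7, 3, 0.1), dirs))
})

test_that("fast non-dominated sort agrees with the brute-force peeling oracle", {
  set.seed(13)
  for (rep in 1:200) {
    n <- sample(3:40, 1)
    n_obj <- sample(2:4, 1)
    dirs <- sample(c("max", "min"), n_obj, replace = TRUE)
    f <- matrix(sample(seq(0, 1, 0.05), n * n_obj, replace = TRUE), n, n_obj)
    srt <- nds_sort(f, dirs)
    expect_identical(srt$rank, peel_fronts_oracle(f, dirs))
  }
})

test_that("degenerate populations sort as expected", {
  # one individual dominating everything forms front 1 alone
  f <- rbind(c(0, 0), matrix(runif(20, 1, 2), 10, 2))
  srt <- nds_sort(f)
  expect_identical(srt$fronts[[1]], 1L)
  # a pure antichain is a single front
  g <- cbind(1:8, 8:1)
  expect_length(nds_sort(g)$fronts, 1)
})

test_that("crowding distance matches hand computation and boundary rules", {
  # three equally spaced collinear points: boundaries infinite, middle gets
  # gap/range summed over both objectives = 1 + 1
  f <- rbind(c(0, 0), c(1, 2), c(2, 4))
  expect_equal(crowding_distance(f), c(Inf, 2, Inf))
  expect_equal(crowding_distance(f[1:2, ]), c(Inf, Inf))
  # an interior duplicate triple has zero gaps on both sides
  f2 <- rbind(c(0, 0), c(1, 1), c(1, 1), c(1, 1), c(2, 2))
  expect_equal(crowding_distance(f2)[3], 0)
})

test_that("the optimizer solves a constructed problem with a known optimum", {
  a <- 0.7; b <- -0.3
  fn <- function(X) cbind(-(X[, 1] - a)^2, -(X[, 2] - b)^2,
                          (X[, 1] + X[, 2] - a - b)^2)
  res <- nsga2(fn, lower = c(-2, -2), upper = c(2, 2),
               directions = c("max", "max", "min"),
               config = ga_config(pop_size = 40L, generations = 200L,
                                  seed = 17))
  best <- res$genes[which.max(res$objectives[, 1] + res$objectives[, 2]), ]
  expect_lt(abs(best[1] - a), 1e-2)
  expect_lt(abs(best[2] - b), 1e-2)
})

test_that("switching off variation operators freezes the gene pool", {
  fn <- function(X) cbind(X[, 1], X[, 2])
  cfg <- ga_config(pop_size = 20L, generations = 30L, p_crossover = 0,
                   p_mutation = 0, seed = 5)
  res <- nsga2(fn, c(0, 0), c(1, 1), c("min", "min"), cfg)
  set.seed(5)
  init <- matrix(runif(40), 20, 2)
  init <- sweep(sweep(init, 2, c(1, 1), "*"), 2, c(0, 0), "+")
  key <- function(m) apply(round(m, 12), 1, paste, collapse = ",")
  expect_true(all(key(res$genes) %in% key(init)))
})

test_that("elitism keeps per-objective bests and grows dominated hypervolume", {
  fn <- function(X) cbind((X[, 1] - 0.3)^2 + X[, 2]^2,
                          (X[, 1] - 0.7)^2 + (X[, 2] - 0.5)^2)
  res <- nsga2(fn, c(0, 0), c(1, 1), c("min", "min"),
               ga_config(pop_size = 24L, generations = 200L, seed = 23),
               snapshot_every = 50L)
  # best-so-far of each objective never worsens
  for (k in 1:2) expect_true(all(diff(res$log[, k]) <= 1e-12))
  # Monte-Carlo hypervolume of the front snapshots is non-decreasing
  set.seed(99)
  ref <- c(1.2, 1.2)
  samples <- cbind(runif(4000, 0, ref[1]), runif(4000, 0, ref[2]))
  hv <- vapply(res$snapshots, mc_hypervolume, numeric(1), ref = ref,
               samples = samples)
  # crowding-based truncation of a full front can shed interior points, so
  # the dominated volume may wobble by a fraction of a percent; it must
  # never genuinely shrink
  expect_true(all(diff(hv) >= -0.01 * max(hv)))
  expect_gte(hv[length(hv)], hv[1] - 0.01 * max(hv))
})

test_that("genes stay within bounds and runs are seed-deterministic", {
  fn <- function(X) cbind(sin(5 * X[, 1]) + X[, 2], cos(3 * X[, 2]) - X[, 1])
  cfg <- ga_config(pop_size = 20L, generations = 60L, seed = 31)
  res1 <- nsga2(fn, c(-1, 0), c(1, 2), c("min", "min"), cfg)
  expect_true(all(res1$genes[, 1] >= -1 & res1$genes[, 1] <= 1))
  expect_true(all(res1$genes[, 2] >= 0 & res1$genes[, 2] <= 2))
  res2 <- nsga2(fn, c(-1, 0), c(1, 2), c("min", "min"), cfg)
  expect_identical(res1$genes, res2$genes)
  expect_identical(res1$objectives, res2$objectives)
})

test_that("objective scaling uses observed ranges and permits extrapolation", {
  tab <- wallflower_data()
  v <- matrix(c(6.50, 3.99, 0.30,
                0.00, 0.00, 0.00,
                3.25, 2.00, 0.15,
                7.12, 3.99, 0.21), ncol = 3, byrow = TRUE,
              dimnames = list(NULL, c("SN", "SL", "CW")))
  sc <- scale_objectives(v, tab)
  expect_equal(sc[1, ], c(SN = 1, SL = 1, CW = 1))
  expect_equal(sc[2, ], c(SN = 0, SL = 0, CW = 0))
  expect_equal(sc[3, "SN"], c(SN = 0.5))
  expect_equal(sc[4, "SN"], c(SN = 7.12 / 6.5))  # ~1.095, beyond 1 permitted
  df <- as.data.frame(tab); df$CW <- 0.1
  expect_error(scale_objectives(v, pgr_table(df)), "zero observed range")
})

test_that("ideal-point selection picks the closest member with sane tie-breaks", {
  tab <- wallflower_data()
  genes <- rbind(c(1, 2, 0.1, 0.2), c(0.5, 1, 0, 0))
  # the first member sits exactly at the observed-extreme ideal point
  obj <- rbind(c(6.50, 3.99, 0.00), c(4.00, 3.00, 0.10))
  sol <- ideal_point_select(genes, obj, tab)
  expect_identical(sol$index, 1L)
  expect_equal(sol$distance, 0)
  expect_equal(unname(sol$ideal), c(6.50, 3.99, 0.00))

  # hand-computed scaled distances: member 1 at 0.3, member 2 at 0.5
  obj2 <- rbind(c(6.50 * (1 - 0.3), 3.99, 0.00),
                c(6.50 * (1 - 0.5), 3.99, 0.00))
  sol2 <- ideal_point_select(genes, obj2, tab)
  expect_identical(sol2$index, 1L)
  expect_equal(sol2$distance, 0.3)

  # exact ties resolve toward the smaller callus weight
  obj3 <- rbind(c(5.0, 3.5, 0.20), c(5.0, 3.5, 0.05))
  sol3 <- ideal_point_select(genes, obj3, tab)
  expect_identical(sol3$index, 2L)

  # utopia mode measures distance to the front's own attainable best
  sol4 <- ideal_point_select(genes, obj2, tab, ideal_from = "front",
                             scale = "none")
  expect_identical(sol4$index, 1L)
  expect_equal(sol4$distance, 0)
})

test_that("media optimization returns an in-bounds front-1 recommendation", {
  tab <- wallflower_data()
  fit <- fit_response_models(tab, mlp_config(seed = 2),
                             n_hidden = c(SN = 7L, SL = 3L, CW = 2L))
  rec <- optimize_media(fit$models, tab,
                        ga_config(pop_size = 24L, generations = 120L, seed = 6))
  g <- rec$solution$genes
  expect_true(g[["BA"]] >= 0 && g[["BA"]] <= 2)
  expect_true(g[["NAA"]] >= 0 && g[["NAA"]] <= 0.1)
  expect_true(all(rec$front$rank == 1))
  # the recommendation is a member of the returned front
  hit <- apply(rec$front[, 1:4], 1, function(r) all(abs(r - g) < 1e-12))
  expect_true(any(hit))
  # collapsed bounds pin the recommendation to the admissible point
  eps <- 1e-6
  b <- rbind(c(1, 2, 0.1, 0.2) - eps, c(1, 2, 0.1, 0.2) + eps)
  rec2 <- optimize_media(fit$models, tab,
                         ga_config(pop_size = 8L, generations = 20L, seed = 1),
                         bounds = b)
  expect_equal(unname(rec2$solution$genes), c(1, 2, 0.1, 0.2),
               tolerance = 1e-4)
})

test_that("non-finite surrogate output is reported with the offending genes", {
  fn <- function(X) cbind(X[, 1], ifelse(X[, 2] > 0.5, NaN, X[, 2]))
  expect_error(nsga2(fn, c(0, 0), c(1, 1), c("min", "min"),
                     ga_config(pop_size = 8L, generations = 5L, seed = 2)),
               "non-finite")
})
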