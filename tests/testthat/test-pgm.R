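test_that("factor initialization is seeded, positive and leaves the RNG alone", {
  a <- init_factors(10, 4, seed = 99)
  b <- init_factors(10, 4, seed = 99)
  expect_identical(a, b)
  expect_false(identical(a, init_factors(10, 4, seed = 100)))
  expect_true(all(a > 0.01 & a < 1))

  set.seed(1)
  before <- stats::runif(1)
  set.seed(1)
  invisible(init_factors(5, 2, seed = 123))
  expect_identical(stats::runif(1), before)
})

test_that("the vectorized objective matches the straight-loop oracle", {
  inst <- make_instance(3, 2, seed = 1)
  beta <- c(0.4, 1.3)
  expect_equal(
    pgm_objective(inst$w, inst$h, beta, inst$g, alpha = 50),
    oracle_objective(inst$w, inst$h, beta, inst$g$adjacency, alpha = 50),
    tolerance = 1e-12)
})

test_that("objective is exactly linear in the regularization strength", {
  inst <- make_instance(12, 3, seed = 5)
  beta <- rep(0.5, 3)
  r1 <- graph_penalty(inst$h, inst$g)
  f0 <- pgm_objective(inst$w, inst$h, beta, inst$g, alpha = 0)
  f1 <- pgm_objective(inst$w, inst$h, beta, inst$g, alpha = 80)
  f2 <- pgm_objective(inst$w, inst$h, beta, inst$g, alpha = 160)
  expect_equal(f2 - f1, 80 * r1, tolerance = 1e-9)
  expect_equal(f1 - f0, 80 * r1, tolerance = 1e-9)
})

test_that("H updates preserve nonnegativity and exact zeros", {
  set.seed(14)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    q <- sample(2:6, 1)
    inst <- make_instance(n, q, seed = rep)
    h <- inst$h
    h[sample(length(h), 5)] <- 0
    zero_idx <- h == 0
    beta <- update_beta(h)
    for (it in 1:30) {
      h <- update_h(inst$w, h, beta, inst$g, alpha = 10)
      beta <- update_beta(h)
    }
    expect_true(all(h >= 0))
    expect_true(all(is.finite(h)))
    expect_true(all(h[zero_idx] == 0))
  }
})

test_that("a single positive pair drives its co-membership strength upward", {
  w <- matrix(1, 2, 2)
  beta <- 1e6          # effectively flat prior
  h <- matrix(c(0.1, 0.1), 2, 1)
  s_old <- h[1] * h[2]
  for (it in 1:200) h <- update_h(w, h, beta)
  expect_gt(h[1] * h[2], s_old)
  # likelihood saturates: P(w = 1) = 1 - exp(-s) approaches 1
  expect_gt(1 - exp(-h[1] * h[2]), 0.99)
})

test_that("beta update reproduces its closed form", {
  expect_equal(update_beta(matrix(0, 3, 1), 1, 0.3)[1], 0.6 / 7)
  h <- matrix(c(1, 0), 2, 1)
  expect_equal(update_beta(h, 1, 0.5)[1], 2 / 6)
  # per-column straight-loop recomputation on a random matrix
  set.seed(6)
  hr <- matrix(stats::runif(40), 10, 4)
  a <- 2; b <- 0.25
  manual <- vapply(1:4, function(z) {
    ss <- 0
    for (i in 1:10) ss <- ss + hr[i, z]^2
    (2 * b + ss) / (10 + 2 * a + 2)
  }, numeric(1))
  expect_equal(update_beta(hr, a, b), manual, tolerance = 1e-12)
  # quadratic scaling of the data-dependent part
  base <- update_beta(hr, a, b) - 2 * b / (10 + 2 * a + 2)
  scaled <- update_beta(3 * hr, a, b) - 2 * b / (10 + 2 * a + 2)
  expect_equal(scaled, 9 * base, tolerance = 1e-12)
})

test_that("fitting is deterministic given a seed", {
  inst <- make_instance(15, 3, seed = 2)
  ctrl <- pgm_control(q_max = 3, n_restarts = 2, seed = 7, max_iter = 40)
  f1 <- pgm_fit(inst$w, inst$g, ctrl)
  f2 <- pgm_fit(inst$w, inst$g, ctrl)
  expect_identical(f1$h_star, f2$h_star)
  expect_identical(f1$objective_trace, f2$objective_trace)
})

test_that("a perfect two-block consensus is recovered exactly", {
  lab <- rep(c("a", "b"), each = 5)
  w <- outer(lab, lab, "==") * 1
  for (seed in 1:5) {
    fit <- pgm_fit(w, control = pgm_control(q_max = 6, alpha = 0,
                                            n_restarts = 1, seed = seed))
    got <- assign_clusters(fit)
    expect_equal(got$n_clusters, 2)
    expect_equal(adjusted_rand_index(got$label, lab), 1)
  }
})

test_that("a huge convergence threshold stops after one iteration", {
  inst <- make_instance(10, 2, seed = 3)
  fit <- pgm_fit(inst$w, inst$g,
                 pgm_control(q_max = 2, rho = 10, n_restarts = 1, seed = 1))
  expect_equal(fit$n_iterations, 1L)
  expect_true(fit$converged)
})

test_that("stored objective equals its recomputation at the optimum", {
  inst <- make_instance(12, 3, seed = 10)
  ctrl <- pgm_control(q_max = 3, n_restarts = 2, seed = 4, max_iter = 60)
  fit <- pgm_fit(inst$w, inst$g, ctrl)
  expect_equal(fit$objective,
               pgm_objective(inst$w, fit$h_star, fit$beta, inst$g,
                             ctrl$alpha, ctrl$hyper_a, ctrl$hyper_b),
               tolerance = 1e-12)
})

test_that("objective traces are non-increasing on nearly all random instances", {
  ok <- 0
  n_inst <- 20
  for (seed in seq_len(n_inst)) {
    inst <- make_instance(25, 4, seed = 100 + seed)
    alpha <- if (seed %% 2) 0 else 20
    fit <- pgm_fit(inst$w, inst$g,
                   pgm_control(q_max = 4, alpha = alpha, n_restarts = 1,
                               seed = seed, max_iter = 80))
    tr <- fit$objective_trace
    viol <- diff(tr) > 1e-6 * abs(tr[-length(tr)])
    if (!any(viol)) ok <- ok + 1
  }
  # the damped multiplicative rule is a heuristic descent, monitored not proven
  expect_gte(ok / n_inst, 0.95)
})

test_that("ARD prunes a 25-column model down to the true block count", {
  lab <- rep(1:5, each = 40)
  w <- outer(lab, lab, "==") * 1
  hits <- 0
  for (seed in 1:10) {
    fit <- pgm_fit(w, control = pgm_control(q_max = 25, alpha = 0,
                                            n_restarts = 1, seed = seed))
    alive <- sum(apply(fit$h_star, 2, max) > fit$control$prune_tol)
    if (abs(alive - 5) <= 1) hits <- hits + 1
  }
  expect_gte(hits, 8)
})
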