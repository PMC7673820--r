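test_that("co-membership matrices follow the partition block structure", {
  p <- partition(c("A", "A", "B"), c("c1", "c2", "c3"))
  expect_equal(unname(comembership(p)),
               matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3, 3),
               ignore_attr = TRUE)
  all_same <- comembership(partition(rep("x", 4), paste0("c", 1:4)))
  expect_true(all(all_same == 1))
  all_diff <- comembership(partition(letters[1:4], paste0("c", 1:4)))
  expect_equal(unname(all_diff), diag(4), ignore_attr = TRUE)
})

test_that("Calinski-Harabasz matches the hand-computed 1-D example", {
  x <- matrix(c(0, 1, 10, 11), 4, 1)
  p <- partition(c(1, 1, 2, 2), paste0("c", 1:4))
  # between = 2*25 + 2*25 = 100, within = 4*0.25 = 1, times (N-K)/(K-1) = 2
  expect_equal(calinski_harabasz(x, p), 200)
  expect_error(calinski_harabasz(x, partition(1:4, paste0("c", 1:4))),
               "N - K")
  expect_error(
    calinski_harabasz(x, partition(rep(1, 4), paste0("c", 1:4))),
    "2 clusters")
})

test_that("CH ranks a true two-blob labelling above a shuffled one", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- rbind(matrix(stats::rnorm(40, 0), 20, 2),
               matrix(stats::rnorm(40, 6), 20, 2))
    ids <- paste0("c", 1:40)
    truth <- partition(rep(c("a", "b"), each = 20), ids)
    shuffled <- partition(sample(truth$label), ids)
    expect_gt(calinski_harabasz(x, truth),
              calinski_harabasz(x, shuffled))
  }
})

test_that("the printed CH variant differs from the standard one as documented", {
  set.seed(2)
  x <- matrix(stats::rnorm(60), 30, 2)
  p <- partition(rep(1:3, each = 10), paste0("c", 1:30))
  std <- calinski_harabasz(x, p)
  printed <- calinski_harabasz(x, p, variant = "printed")
  # equal cluster sizes: variants differ exactly by size * ((N-K)/(K-1))^2
  expect_equal(std / printed, 10 * ((30 - 3) / (3 - 1))^2)
})

test_that("weight normalization is exact, scale-invariant and positive", {
  w <- normalize_weights(c(2, 3, 5))
  expect_equal(w$weights, c(0.2, 0.3, 0.5))
  expect_equal(normalize_weights(7)$weights, 1)
  expect_equal(normalize_weights(c(4, 4, 4, 4))$weights, rep(0.25, 4))
  expect_equal(normalize_weights(c(2, 3, 5) * 17.3)$weights,
               normalize_weights(c(2, 3, 5))$weights)
  expect_error(normalize_weights(c(1, 0)), "positive")
  set.seed(5)
  for (i in 1:10) {
    s <- stats::runif(4, 0.01, 100)
    u <- normalize_weights(s)$weights
    expect_equal(sum(u), 1, tolerance = 1e-12)
    expect_true(all(u > 0 & u < 1))
  }
})

test_that("consensus assembly is the weighted sum of co-memberships", {
  ids <- paste0("c", 1:3)
  p1 <- partition(c("a", "a", "a"), ids, method = "m1")
  p2 <- partition(c("x", "y", "z"), ids, method = "m2")
  w <- consensus_matrix(list(p1, p2), normalize_weights(c(0.6, 0.4)))
  expect_equal(unname(diag(w)), rep(1, 3))
  expect_equal(w[1, 2], 0.6)

  same <- consensus_matrix(list(p1, p1), normalize_weights(c(1, 1)))
  expect_equal(unname(same), unname(comembership(p1)), ignore_attr = TRUE)

  # an edge present in 3 of 4 equally-weighted partitions scores 0.75
  p3 <- partition(c("a", "a", "b"), ids)
  w4 <- consensus_matrix(list(p1, p3, p3, p2), rep(1, 4))
  expect_equal(w4[1, 2], 0.75)
})

test_that("binarization is strict: ties at the threshold drop to zero", {
  ids <- paste0("c", 1:3)
  w <- consensus_matrix(
    list(partition(c("a", "a", "b"), ids), partition(c("a", "b", "b"), ids)),
    rep(1, 2))
  expect_equal(w[1, 2], 0.5)
  b <- binarize_consensus(w, 0.5)
  expect_equal(b[1, 2], 0)         # exactly at threshold -> 0
  expect_equal(unname(diag(b)), rep(1, 3))
  expect_error(binarize_consensus(b, 0.5), "already")
  expect_error(binarize_consensus(w, 1.2), "between 0 and 1")

  w2 <- consensus_matrix(list(partition(c("a", "a", "b"), ids),
                              partition(c("a", "a", "b"), ids)),
                         c(0.6, 0.4))
  b2 <- binarize_consensus(w2, 0.5)
  expect_equal(b2[1, 2], 1)        # 1.0 > 0.5
  expect_equal(b2[1, 3], 0)        # 0.0
})

test_that("consensus invariants hold on random ensembles", {
  set.seed(9)
  for (rep in 1:8) {
    n <- sample(10:30, 1)
    ids <- paste0("c", seq_len(n))
    parts <- lapply(1:4, function(m)
      partition(sample(letters[1:4], n, replace = TRUE), ids))
    w <- consensus_matrix(parts, stats::runif(4, 0.1, 10))
    expect_true(isSymmetric(unname(w)))
    expect_equal(unname(diag(w)), rep(1, n))
    expect_true(all(w >= 0 & w <= 1 + 1e-12))
  }
})

test_that("identical base partitions reproduce their own co-membership", {
  set.seed(3)
  ids <- paste0("c", 1:25)
  p <- partition(sample(letters[1:3], 25, replace = TRUE), ids)
  for (wt in c(0.2, 0.5, 0.8)) {
    b <- binarize_consensus(
      consensus_matrix(list(p, p, p), rep(1, 3)), wt)
    expect_equal(unname(b), unname(comembership(p)), ignore_attr = TRUE)
  }
})
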