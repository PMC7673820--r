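# Independent brute-force oracles and fixture builders. Everything here is
# deliberately written with straight loops / first-principles counting so it
# shares no code path with the package implementation it checks.

# Straight-loop evaluation of the negative log joint: Bernoulli likelihood
# over unordered pairs, half-normal column priors, inverse-Gamma hyperprior,
# and the half-double-sum graph penalty.
oracle_objective <- function(w, h, beta, v = NULL, alpha = 0,
                             a = 1, b = 0.3, eps = 1e-12) {
  n <- nrow(h)
  q <- ncol(h)
  f <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- 0
    for (z in seq_len(q)) s <- s + h[i, z] * h[j, z]
    f <- f + (1 - w[i, j]) * s - w[i, j] * log(max(1 - exp(-s), eps))
  }
  for (z in seq_len(q)) {
    ss <- 0
    for (i in seq_len(n)) ss <- ss + h[i, z]^2
    f <- f + ss / (2 * beta[z]) + (n / 2) * log(beta[z]) +
      (a + 1) * log(beta[z]) + b / beta[z]
  }
  if (alpha > 0) {
    r1 <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) for (z in seq_len(q))
      r1 <- r1 + 0.5 * (h[i, z] - h[j, z])^2 * v[i, j]
    f <- f + alpha * r1
  }
  f
}

# Pair-counting adjusted Rand index: classify every unordered pair of cells
# by agreement in the two labellings, then apply the pair-count closed form.
oracle_ari <- function(l1, l2) {
  n <- length(l1)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s1 <- l1[i] == l1[j]
    s2 <- l2[i] == l2[j]
    if (s1 && s2) n11 <- n11 + 1
    else if (!s1 && !s2) n00 <- n00 + 1
    else if (s1) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / den
}

# Entropy-normalized mutual information computed in log base 2 (the base
# cancels in the ratio, so agreement with the natural-log implementation
# also checks base invariance).
oracle_nmi <- function(l1, l2) {
  n <- length(l1)
  u1 <- unique(l1)
  u2 <- unique(l2)
  mi <- 0
  for (a in u1) for (b in u2) {
    pab <- sum(l1 == a & l2 == b) / n
    if (pab > 0) mi <- mi + pab * log2(pab / (sum(l1 == a) / n *
                                              sum(l2 == b) / n))
  }
  h1 <- -sum(vapply(u1, function(a) {
    p <- sum(l1 == a) / n; p * log2(p)
  }, numeric(1)))
  h2 <- -sum(vapply(u2, function(b) {
    p <- sum(l2 == b) / n; p * log2(p)
  }, numeric(1)))
  if (h1 + h2 == 0) return(1)
  2 * mi / (h1 + h2)
}

# All set partitions of n elements into at most `max_blocks` blocks, as
# canonical restricted-growth label vectors.
enumerate_partitions <- function(n, max_blocks = 3) {
  out <- list()
  rec <- function(prefix, used) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(min(used + 1L, max_blocks)))
      rec(c(prefix, v), max(used, v))
  }
  rec(integer(0), 0L)
  out
}

# Random symmetric binary "consensus" plus a KNN graph on random points —
# the generic small instance used by the model-level tests.
make_instance <- function(n, q, seed, edge_prob = 0.3, knn_k = 3) {
  set.seed(seed)
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- as.numeric(stats::runif(n * (n - 1) / 2) < edge_prob)
  w <- w + t(w)
  diag(w) <- 1
  pts <- matrix(stats::rnorm(n * 3), n, 3)
  list(w = w, g = knn_graph(pts, min(knn_k, n - 1L)),
       h = init_factors(n, q, seed), q = q, n = n)
}

# Alternate H/beta updates until the objective change is negligible; used
# where a test needs a genuinely converged fixed point rather than the
# 100-iteration production default.
run_to_fixed_point <- function(w, g, alpha, h, max_iter = 6000,
                               tol = 1e-13) {
  beta <- update_beta(h)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    h <- update_h(w, h, beta, g, alpha)
    beta <- update_beta(h)
    obj <- pgm_objective(w, h, beta, g, alpha)
    if (is.finite(prev) && abs(prev - obj) < tol) break
    prev <- obj
  }
  list(h = h, beta = beta, objective = obj, iterations = it)
}

# Central finite-difference gradient of the objective at the given entries.
fd_gradient_max <- function(w, h, beta, g, alpha, active, step = 1e-6) {
  mx <- 0
  for (i in seq_len(nrow(h))) for (z in seq_len(ncol(h))) {
    if (!active[i, z]) next
    hp <- h; hp[i, z] <- h[i, z] + step
    hm <- h; hm[i, z] <- h[i, z] - step
    gr <- (pgm_objective(w, hp, beta, g, alpha) -
           pgm_objective(w, hm, beta, g, alpha)) / (2 * step)
    mx <- max(mx, abs(gr))
  }
  mx
}

# Connected components of a binary adjacency matrix by breadth-first
# traversal (independent of any eigen computation).
count_components <- function(v) {
  n <- nrow(v)
  seen <- rep(FALSE, n)
  comps <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      cur <- queue[1L]
      queue <- queue[-1L]
      nb <- which(v[cur, ] > 0 & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  comps
}
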