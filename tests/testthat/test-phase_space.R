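test_that("delay embedding reproduces hand-computed trajectories", {
  tr <- delay_embed(c(1, 2, 3, 4, 5), dimension = 2, delay = 1)
  expect_equal(unclass(tr)[, ], matrix(c(1:4, 2:5), ncol = 2),
               ignore_attr = TRUE)
  tr2 <- delay_embed(c(1, 2, 3, 4, 5, 6), dimension = 3, delay = 2)
  expect_equal(nrow(tr2), 2)
  expect_equal(unclass(tr2)[, ], matrix(c(1, 2, 3, 4, 5, 6), ncol = 3),
               ignore_attr = TRUE)
})

test_that("dimension-1 embedding is the identity and row counts conserve", {
  set.seed(1)
  for (rep in 1:20) {
    i <- sample(20:200, 1)
    x <- rnorm(i)
    n <- sample(1:5, 1)
    t <- sample(1:8, 1)
    if ((n - 1) * t >= i) next
    tr <- delay_embed(x, dimension = n, delay = t)
    expect_equal(nrow(tr) + (n - 1) * t, i)
    if (n == 1) expect_equal(as.numeric(tr), x)
  }
})

test_that("infeasible embedding parameters raise an informative error", {
  expect_error(delay_embed(1:10, dimension = 4, delay = 4), "maximal feasible")
  expect_error(embedding_params(0, 1), "dimension")
  expect_error(embedding_params(2, 0), "delay")
})

test_that("best-match rule keeps max dimension, min delay; commutative and idempotent", {
  a <- embedding_params(6, 9)
  b <- embedding_params(8, 28)
  expect_equal(format(resolve_best_match(a, b)), "8/9")
  c <- embedding_params(17, 24)
  expect_equal(format(resolve_best_match(a, c)), "17/9")
  set.seed(2)
  for (rep in 1:25) {
    p <- embedding_params(sample(1:20, 1), sample(1:40, 1))
    q <- embedding_params(sample(1:20, 1), sample(1:40, 1))
    pq <- resolve_best_match(p, q)
    qp <- resolve_best_match(q, p)
    expect_equal(pq, qp)
    expect_equal(resolve_best_match(pq, pq), pq)
    expect_equal(resolve_best_match(pq, p), pq)
  }
})

test_that("AMI delay finds the quarter period of a sine and ignores amplitude", {
  x <- sin(2 * pi * seq_len(4000) / 100)
  d <- ami_delay(x, max_delay = 60)
  expect_gte(d, 22)
  expect_lte(d, 28)
  expect_identical(ami_delay(3.7 * x + 12, max_delay = 60), d)
  expect_identical(ami_delay(-x, max_delay = 60), d)
})

test_that("AMI errors on constant or too-short input", {
  expect_error(ami_delay(rep(1, 500), 20), "degenerate|constant")
  expect_error(ami_delay(rnorm(50), 40), "length")
})

test_that("AMI profile matches a literal per-lag histogram computation", {
  set.seed(3)
  x <- cumsum(rnorm(300))
  prof <- ami_profile(x, max_delay = 10, n_bins = 6)
  rng <- range(x)
  bi <- pmin(floor((x - rng[1]) / diff(rng) * 6), 5) + 1
  for (tau in c(1, 4, 10)) {
    a <- bi[seq_len(300 - tau)]
    b <- bi[seq_len(300 - tau) + tau]
    tab <- table(factor(a, 1:6), factor(b, 1:6))
    p <- tab / sum(tab)
    px <- rowSums(p); py <- colSums(p)
    mi <- 0
    for (i in 1:6) for (j in 1:6)
      if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (px[i] * py[j]))
    expect_equal(prof[tau], as.numeric(mi), tolerance = 1e-12)
  }
})

test_that("FNN recovers dimension 2 for the Henon map and flags white noise", {
  n <- 2000
  xs <- numeric(n); ys <- numeric(n); xs[1] <- 0.1
  for (i in 2:n) {
    xs[i] <- 1 - 1.4 * xs[i - 1]^2 + ys[i - 1]
    ys[i] <- 0.3 * xs[i - 1]
  }
  expect_equal(fnn_dimension(xs, delay = 1), 2L)
  set.seed(4)
  expect_warning(d <- fnn_dimension(rnorm(1200), delay = 1, max_dim = 6),
                 "never dropped")
  expect_equal(d, 6L)
})

test_that("FNN on a deterministic monotone ramp needs one dimension", {
  x <- seq(0, 1, length.out = 500)
  expect_equal(fnn_dimension(x, delay = 1, max_dim = 4), 1L)
})

test_that("constant series are rejected by parameter selection", {
  expect_error(fnn_dimension(rep(2, 300), delay = 1), "degenerate|constant")
  expect_error(select_embedding(rep(0, 300)), "degenerate|constant")
})
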