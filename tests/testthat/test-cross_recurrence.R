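make_traj <- function(m) {
  structure(as.matrix(m), class = c("trajectory", "matrix", "array"))
}

test_that("phase-space diameter matches hand and brute-force values", {
  a <- make_traj(matrix(c(0, 0), 1))
  b <- make_traj(matrix(c(3, 4), 1))
  expect_equal(phase_space_diameter(a, b), 5)
  expect_equal(phase_space_diameter(a, a), 0)
  expect_equal(phase_space_diameter(a, b, norm = "maximum"), 4)
  set.seed(5)
  for (rep in 1:10) {
    p <- make_traj(matrix(rnorm(20), ncol = 2))
    q <- make_traj(matrix(rnorm(16), ncol = 2))
    u <- rbind(unclass(p), unclass(q))
    expect_equal(phase_space_diameter(p, q), naive_diameter(u))
    expect_equal(phase_space_diameter(p, q, "maximum"), naive_diameter(u, TRUE))
  }
  expect_error(phase_space_diameter(p, make_traj(matrix(1:9, 3))), "dimension")
})

test_that("identical trajectories give an all-one main diagonal", {
  set.seed(6)
  a <- make_traj(matrix(rnorm(60), ncol = 3))
  m <- cross_recurrence(a, a, epsilon_fraction = 0.05)
  expect_true(all(diag(unclass(m)) == 1L))
  expect_true(isSymmetric(unname(unclass(m))))
})

test_that("separated clouds give an all-zero matrix; epsilon tie counts as recurrent", {
  a <- make_traj(matrix(0, nrow = 4, ncol = 2))
  b <- make_traj(matrix(10, nrow = 3, ncol = 2))
  # diameter is the 0-to-10 corner distance; 10% of it is far below the gap
  m <- cross_recurrence(a, b, epsilon_fraction = 0.1)
  expect_equal(sum(m == 1L), 0)
  # two unit-separated points: epsilon equals the full diameter minus nothing
  # is not allowed (fraction < 1), so check the boundary inside the matrix:
  # distance exactly epsilon must be recurrent (Heaviside at zero is 1)
  a2 <- make_traj(matrix(c(0, 2), ncol = 1))
  b2 <- make_traj(matrix(c(1), ncol = 1))
  m2 <- cross_recurrence(a2, b2, epsilon_fraction = 0.5)
  expect_equal(attr(m2, "epsilon"), 1)   # diameter 2, fraction 0.5
  expect_equal(as.vector(unclass(m2)), c(1L, 1L))
})

test_that("a 5x5 hand-enumerated example has exactly the constructed recurrences", {
  # 1-D trajectories: a = (0, 10, 20, 30, 40), b = (1, 12, 23, 34, 45)
  # pairwise |a_i - b_j| has smallest distances 1 (a1,b1) and 2 (a2,b2);
  # third smallest is 3 (a3,b3). epsilon between 2 and 3 keeps exactly 2.
  a <- make_traj(matrix(c(0, 10, 20, 30, 40), ncol = 1))
  b <- make_traj(matrix(c(1, 12, 23, 34, 45), ncol = 1))
  diam <- phase_space_diameter(a, b)  # 45 - 0
  expect_equal(diam, 45)
  m <- cross_recurrence(a, b, epsilon_fraction = 2.5 / 45)
  expect_equal(sum(m == 1L), 2)
  expect_equal(unclass(m)[1, 1], 1L)
  expect_equal(unclass(m)[2, 2], 1L)
})

test_that("cross recurrence is transpose-symmetric and monotone in epsilon", {
  set.seed(7)
  a <- make_traj(matrix(rnorm(40), ncol = 2))
  b <- make_traj(matrix(rnorm(30), ncol = 2))
  m_ab <- cross_recurrence(a, b, 0.3)
  m_ba <- cross_recurrence(b, a, 0.3)
  expect_equal(unname(unclass(m_ab)), unname(t(unclass(m_ba))))
  for (rep in 1:5) {
    f1 <- runif(1, 0.05, 0.5)
    f2 <- runif(1, f1, 0.9)
    m1 <- cross_recurrence(a, b, f1)
    m2 <- cross_recurrence(a, b, f2)
    expect_true(all(unclass(m2)[unclass(m1) == 1L] == 1L))
  }
})

test_that("degenerate zero-diameter clouds are rejected", {
  a <- make_traj(matrix(1, 3, 2))
  expect_error(cross_recurrence(a, a, 0.1), "zero diameter")
  expect_error(cross_recurrence(a, a, 1.2), "epsilon_fraction")
})

test_that("CRP image is written and its black pixels equal the matrix sum", {
  set.seed(8)
  a <- make_traj(matrix(rnorm(50), ncol = 2))
  b <- make_traj(matrix(rnorm(50), ncol = 2))
  m <- cross_recurrence(a, b, 0.4)
  path <- tempfile(fileext = ".png")
  render_crp(m, path)
  expect_true(file.exists(path))
  expect_gt(file.info(path)$size, 0)
  unlink(path)
})
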