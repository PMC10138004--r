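# Independent naive oracles used to cross-check the package's compiled
# implementations. These deliberately use the slowest, most literal
# formulation available.

# histogram of maximal runs of 1s along every (i+1, j+1) diagonal,
# scanning each diagonal cell by cell
naive_diagonal_hist <- function(m) {
  n <- nrow(m); mm <- ncol(m)
  counts <- integer(min(n, mm))
  for (s in (-(n - 1)):(mm - 1)) {
    i <- if (s < 0) -s + 1 else 1
    j <- if (s < 0) 1 else s + 1
    run <- 0
    while (i <= n && j <= mm) {
      if (m[i, j] == 1) run <- run + 1
      else if (run > 0) { counts[run] <- counts[run] + 1L; run <- 0 }
      i <- i + 1; j <- j + 1
    }
    if (run > 0) counts[run] <- counts[run] + 1L
  }
  counts
}

naive_vertical_hist <- function(m) {
  n <- nrow(m); mm <- ncol(m)
  counts <- integer(n)
  for (j in seq_len(mm)) {
    run <- 0
    for (i in seq_len(n)) {
      if (m[i, j] == 1) run <- run + 1
      else if (run > 0) { counts[run] <- counts[run] + 1L; run <- 0 }
    }
    if (run > 0) counts[run] <- counts[run] + 1L
  }
  counts
}

naive_det <- function(m, lmin = 2) {
  h <- naive_diagonal_hist(m)
  tot <- sum(seq_along(h) * h)
  if (tot == 0) return(0)
  keep <- seq_along(h) >= lmin
  sum(seq_along(h)[keep] * h[keep]) / tot
}

naive_lam <- function(m, vmin = 2) {
  h <- naive_vertical_hist(m)
  tot <- sum(seq_along(h) * h)
  if (tot == 0) return(0)
  keep <- seq_along(h) >= vmin
  sum(seq_along(h)[keep] * h[keep]) / tot
}

naive_mdl <- function(m, lmin = 2) {
  h <- naive_diagonal_hist(m)
  keep <- seq_along(h) >= lmin
  if (sum(h[keep]) == 0) return(0)
  sum(seq_along(h)[keep] * h[keep]) / sum(h[keep])
}

# exhaustive double loop over the union point set
naive_diameter <- function(pts, maxnorm = FALSE) {
  best <- 0
  n <- nrow(pts)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- if (maxnorm) max(abs(pts[i, ] - pts[j, ]))
         else sqrt(sum((pts[i, ] - pts[j, ])^2))
    if (d > best) best <- d
  }
  best
}

# joint entropy by explicit contingency-table double loop (bits)
naive_joint_entropy <- function(sx, sy) {
  tab <- table(sx, sy)
  p <- tab / sum(tab)
  h <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    if (p[i, j] > 0) h <- h - p[i, j] * log2(p[i, j])
  h
}

# checkerboard with 1s on even (i + j) cells: every recurrent diagonal is
# a full run, every vertical run has length 1
checkerboard <- function(n) {
  outer(seq_len(n), seq_len(n), function(i, j) as.integer((i + j) %% 2 == 0))
}

random_binary_matrix <- function(n, m, p = 0.4) {
  matrix(rbinom(n * m, 1, p), n, m)
}

small_test_dataset <- function(seed = 7, n = 400, factors = c("pH", "Temp", "Chl"),
                               n_stations = 2) {
  simulate_stations(sim_config(n_stations = n_stations, factors = factors,
                               n_samples = n, seed = seed))
}

fast_config <- function(...) {
  pipeline_config(epsilon_fraction = 0.15, fnn_threshold = 0.05,
                  max_dim = 8, max_delay = 30, ...)
}
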