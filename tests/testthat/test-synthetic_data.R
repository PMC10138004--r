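test_that("generation is a pure function of the config", {
  cfg <- sim_config(n_stations = 2, factors = c("pH", "Temp", "Chl"),
                    n_samples = 200, seed = 31)
  d1 <- simulate_stations(cfg)
  d2 <- simulate_stations(cfg)
  expect_identical(lapply(d1$series, as.numeric), lapply(d2$series, as.numeric))
  d3 <- simulate_stations(sim_config(n_stations = 2,
                                     factors = c("pH", "Temp", "Chl"),
                                     n_samples = 200, seed = 32))
  expect_false(identical(as.numeric(d1$series[[1]]), as.numeric(d3$series[[1]])))
})

test_that("dataset shape follows the config", {
  ds <- small_test_dataset(seed = 1, n = 150)
  expect_length(ds$series, 2 * 3)
  expect_true(all(vapply(ds$series, length, integer(1)) == 150))
  expect_setequal(unique(vapply(ds$series, function(s) attr(s, "station"),
                                character(1))), c("ST1", "ST2"))
})

test_that("perfect coupling without noise duplicates the pair exactly", {
  f <- c("A", "B")
  cp <- matrix(c(0, 1, 1, 0), 2, dimnames = list(f, f))
  cfg <- sim_config(n_stations = 1, factors = f, n_samples = 300,
                    coupling = cp, noise_sd = 0, seed = 5)
  ds <- simulate_stations(cfg)
  expect_equal(as.numeric(ds$series[["ST1:A"]]),
               as.numeric(ds$series[["ST1:B"]]), tolerance = 1e-12)
  # downstream: the CRP main diagonal is fully recurrent
  tr <- delay_embed(standardize_series(ds$series[["ST1:A"]]),
                    dimension = 3, delay = 10)
  m <- cross_recurrence(tr, tr, 0.05)
  expect_true(all(diag(unclass(m)) == 1L))
})

test_that("uncoupled cross-factor MI sits at the permutation null", {
  # noise-only config: no diurnal, trend or coupling
  f <- c("A", "B")
  cp <- matrix(0, 2, 2, dimnames = list(f, f))
  excess <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(n_stations = 1, factors = f, n_samples = 600,
                      coupling = cp, diurnal_amp = 0, trend_amp = 0,
                      signal_amp = 0, noise_sd = 0.35, seed = 100 + s)
    ds <- simulate_stations(cfg)
    x <- as.numeric(ds$series[["ST1:A"]])
    y <- as.numeric(ds$series[["ST1:B"]])
    mi <- mutual_information(x, y)
    set.seed(s)
    null_mi <- replicate(30, mutual_information(x, sample(y)))
    if (mi > quantile(null_mi, 0.95)) excess <- excess + 1
  }
  # ~5% of seeds may exceed the null's 95th percentile by construction
  expect_lte(excess, 4)
})

test_that("pairwise mutual information rises with coupling strength", {
  f <- c("A", "B")
  score_at <- function(beta, s) {
    cp <- matrix(c(0, beta, beta, 0), 2, dimnames = list(f, f))
    cfg <- sim_config(n_stations = 1, factors = f, n_samples = 700,
                      coupling = cp, seed = 400 + s)
    ds <- simulate_stations(cfg)
    mutual_information(as.numeric(ds$series[["ST1:A"]]),
                       as.numeric(ds$series[["ST1:B"]]))
  }
  mis <- sapply(1:8, function(s) sapply(c(0, 0.5, 1), score_at, s = s))
  means <- rowMeans(mis)
  expect_lt(means[1], means[2])
  expect_lt(means[2], means[3])
})

test_that("generated series carry the diurnal AMI signature", {
  # no coupling, weak noise: the first AMI minimum sits near a quarter of
  # the 48-sample diurnal period
  f <- c("A", "B")
  cp <- matrix(0, 2, 2, dimnames = list(f, f))
  hits <- 0
  for (s in 1:5) {
    cfg <- sim_config(n_stations = 1, factors = f, n_samples = 1500,
                      coupling = cp, signal_amp = 0, noise_sd = 0.1,
                      seed = 200 + s)
    ds <- simulate_stations(cfg)
    d <- ami_delay(standardize_series(ds$series[["ST1:A"]]), 40)
    if (d >= 9 && d <= 16) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("invalid configs are rejected", {
  f <- c("A", "B")
  bad <- matrix(c(0, 2, 2, 0), 2, dimnames = list(f, f))
  expect_error(sim_config(factors = f, coupling = bad), "\\[0, 1\\]")
  asym <- matrix(c(0, 0.5, 0.1, 0), 2, dimnames = list(f, f))
  expect_error(sim_config(factors = f, coupling = asym), "symmetric")
  diag1 <- matrix(c(0.5, 0, 0, 0), 2, dimnames = list(f, f))
  expect_error(sim_config(factors = f, coupling = diag1), "diagonal")
  expect_error(sim_config(factors = f, coupling = matrix(0, 3, 3)), "matrix")
})
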