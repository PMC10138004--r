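test_that("min-max normalization maps columns to [0,1] with the stated conventions", {
  rows <- data.frame(station = "ST1", factor = c("a", "b", "c"),
                     rr = c(2, 4, 6), det = c(0.5, 0.5, 0.5),
                     lam = c(0, 1, 0.25), mdl = c(3, 2, 7), mi = c(1, 2, 3))
  nm <- min_max_normalize(rows)
  expect_equal(nm$rr, c(0, 0.5, 1))
  expect_equal(nm$det, c(1, 1, 1))      # constant column convention
  expect_equal(nm$lam, c(0, 1, 0.25))
  set.seed(20)
  r2 <- rows
  for (cn in c("rr", "det", "lam", "mdl", "mi")) r2[[cn]] <- rnorm(3)
  n2 <- min_max_normalize(r2)
  for (cn in c("rr", "det", "lam", "mdl", "mi")) {
    expect_equal(min(n2[[cn]]), 0)
    expect_equal(max(n2[[cn]]), 1)
  }
})

test_that("normalized scores ignore affine rescaling of a raw index column", {
  set.seed(21)
  rows <- data.frame(station = "ST1", factor = letters[1:5],
                     rr = runif(5), det = runif(5), lam = runif(5),
                     mdl = runif(5), mi = runif(5))
  n1 <- min_max_normalize(rows)
  rows2 <- rows
  rows2$mi <- 100 * rows$mi + 7   # e.g. a different MI log base plus offset
  n2 <- min_max_normalize(rows2)
  expect_equal(n1$mi, n2$mi, tolerance = 1e-12)
})

test_that("geometric mean score has the documented fixed points", {
  expect_equal(geometric_mean_score(rep(1, 5)), 1)
  expect_equal(geometric_mean_score(c(1, 0.5, 0, 1, 1)), 0)
  expect_equal(geometric_mean_score(rep(0.37, 5)), 0.37, tolerance = 1e-12)
  set.seed(22)
  x <- runif(5)
  expect_equal(geometric_mean_score(x), prod(x)^(1 / 5), tolerance = 1e-12)
})

test_that("a coupling panel computes one row per candidate with valid scores", {
  ds <- small_test_dataset(seed = 23, n = 500)
  p <- coupling_panel(ds, "ST1:pH", config = fast_config())
  # candidates: all series of a different factor, both stations
  expect_equal(nrow(p$scores), 4)
  expect_true(all(p$scores$score >= 0 & p$scores$score <= 1))
  expect_true(all(diff(p$scores$score) <= 0))   # sorted descending
  expect_setequal(p$raw$factor[p$raw$station == "ST1"], c("Temp", "Chl"))
})

test_that("self-comparison dominates a noiseless panel", {
  f <- c("pH", "Temp", "Chl")
  cfg <- sim_config(n_stations = 1, factors = f, n_samples = 600,
                    coupling = default_coupling(f), noise_sd = 0, seed = 24)
  ds <- simulate_stations(cfg)
  # include the target itself as one of the candidates
  p <- coupling_panel(ds, "ST1:pH",
                      candidates = c("ST1:pH", "ST1:Temp", "ST1:Chl"),
                      config = fast_config())
  top <- p$scores[1, ]
  expect_equal(top$factor, "pH")
  raw_ph <- p$raw[p$raw$factor == "pH", ]
  for (cn in c("rr", "det", "lam", "mi"))
    expect_equal(max(p$raw[[cn]]), raw_ph[[cn]])
})

test_that("degenerate candidates are excluded with a warning", {
  ds <- small_test_dataset(seed = 25, n = 400, factors = c("pH", "Temp"),
                           n_stations = 1)
  flat <- water_ts(rep(3, 400), "ST1", "Flat")
  ds$series[["ST1:Flat"]] <- flat
  expect_warning(
    p <- coupling_panel(ds, "ST1:pH", config = fast_config()),
    "excluded")
  expect_false("Flat" %in% p$scores$factor)
})

test_that("length sensitivity reports unit rank correlation for identical lengths", {
  ds <- small_test_dataset(seed = 26, n = 700)
  cc <- fast_config()
  sens <- length_sensitivity(ds, "ST1:pH", config = cc, lengths = c(700, 350))
  expect_named(sens$panels, c("350", "700"))
  expect_equal(unname(sens$spearman["350"]) <= 1, TRUE)
  full_again <- length_sensitivity(ds, "ST1:pH", config = cc, lengths = 700)
  expect_length(full_again$spearman, 0)
  # truncations below the embeddable minimum are refused
  expect_error(length_sensitivity(ds, "ST1:pH", config = cc, lengths = 30),
               "minimum embeddable")
})

test_that("score heatmaps are rendered to file", {
  ds <- small_test_dataset(seed = 27, n = 500)
  p <- coupling_panel(ds, "ST1:pH", config = fast_config())
  path <- tempfile(fileext = ".png")
  render_heatmap(list(ST = p), path)
  expect_true(file.exists(path) && file.info(path)$size > 0)
  unlink(path)
})
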