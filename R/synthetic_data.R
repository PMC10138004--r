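#' Configuration for the coupled multi-station generator
#'
#' The generator emulates the shape of a coastal buoy campaign: several
#' stations each recording the same set of water-quality factors at a fixed
#' cadence (defaults: 3 stations x 8 factors x 4320 samples at 30 min, i.e.
#' 90 days). Each series is the sum of
#' \itemize{
#'   \item a diurnal sinusoid (period 48 samples at 30-min sampling), common
#'     to all series — the sun forces every factor in phase;
#'   \item a slow common trend (half sine over the record, amplitude
#'     `trend_amp`) standing in for seasonal drift;
#'   \item a stochastic signal of unit variance built from latent
#'     drivers. Every driver is a mix of an AR(1) component (coefficient
#'     `driver_ar`, variance share `1 - driver_osc_weight`) and an
#'     oscillation with random phase and a period taken from a log-spaced
#'     grid over `driver_period_range` samples (default 24-96, the 12-48 h
#'     tidal/weather band; variance share `driver_osc_weight`), scaled to
#'     unit sd. The grid slots are randomly assigned but all distinct, so
#'     no two drivers share a spectral band.
#'     The oscillation gives each driver a distinct spectral signature, so
#'     sharing a driver reshapes a pair's joint phase-space geometry —
#'     the feature recurrence statistics respond to. Factor f's signal is sum(beta_fg * d_fg) + w_f * d_f: one
#'     driver d_fg shared with every coupled partner g (weight beta_fg)
#'     plus the factor's own private driver d_f, whose weight
#'     w_f = sqrt(1 - sum(beta_fg^2)) tops the variance up to 1 (if the
#'     declared couplings exceed unit variance the sum is rescaled to unit
#'     variance instead). Every factor therefore has the same marginal
#'     law and comparable embedding parameters; beta only moves the
#'     fraction of variance shared with the partner. Stations other than
#'     the first see all drivers lagged by `station_lag` samples per
#'     distance rank and attenuated by `station_decay` per rank, so the
#'     same factor at neighbouring stations co-varies with a distance
#'     decay;
#'   \item independent AR(1) observation noise (coefficient `ar_coeff`,
#'     innovation sd `noise_sd`).
#' }
#' Ground-truth coupling is known exactly: the shared variance fraction of
#' a coupled pair grows with beta, which downstream ranking should
#' recover.
#'
#' @param n_stations Number of stations (default 3).
#' @param factors Character vector of factor names (default the 8 standard
#'   water-quality factors).
#' @param n_samples Samples per series (default 4320).
#' @param interval_min Sampling interval in minutes (default 30).
#' @param coupling Symmetric factors x factors matrix of coupling strengths
#'   beta in \[0, 1\], zero diagonal. Default [default_coupling()].
#' @param station_lag Driver lag in samples per station distance rank
#'   (default 6, i.e. 3 h).
#' @param station_decay Multiplicative driver attenuation per distance rank
#'   (default 0.7).
#' @param ar_coeff AR(1) coefficient of the observation noise (default 0.6).
#' @param noise_sd Innovation sd of the observation noise (default 0.22).
#' @param diurnal_amp Amplitude of the diurnal sinusoid (default 1).
#' @param diurnal_period Diurnal period in samples (default 48).
#' @param trend_amp Amplitude of the slow common trend (default 0.5).
#' @param driver_ar AR(1) coefficient of the AR component of the latent
#'   coupling drivers (default 0.9).
#' @param driver_period_range Range (samples) the pair-specific driver
#'   oscillation period is drawn from (default c(24, 96)).
#' @param driver_osc_weight Variance share of the oscillation within each
#'   driver, in \[0, 1\].
#' @param signal_amp Overall amplitude of the stochastic (driver) signal;
#'   0 leaves diurnal + trend + noise only.
#' @param hub Optional factor name acting as a regional forcing: every
#'   declared coupling involving this factor shares the hub factor's own
#'   driver instead of a pair-specific one, so partners respond directly
#'   to the hub's dynamics (the natural model when one factor, e.g. pH or
#'   Temp, is the field's key indicator). `NULL` (default) keeps all
#'   couplings pairwise.
#' @param seed Integer seed; the dataset is a pure function of the config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_stations = 3,
                       factors = c("Do", "Chl", "Turb", "Bga",
                                   "Tds", "DoP", "Temp", "pH"),
                       n_samples = 4320, interval_min = 30,
                       coupling = default_coupling(factors),
                       station_lag = 6, station_decay = 0.7,
                       ar_coeff = 0.6, noise_sd = 0.22,
                       diurnal_amp = 1, diurnal_period = 48,
                       trend_amp = 0.5, driver_ar = 0.9,
                       driver_period_range = c(24, 96),
                       driver_osc_weight = 0.92, signal_amp = 1,
                       hub = if ("pH" %in% factors) "pH" else NULL,
                       seed = 1) {
  f <- length(factors)
  if (f < 1L || n_stations < 1L) stop("need >= 1 station and factor")
  coupling <- as.matrix(coupling)
  if (!all(dim(coupling) == c(f, f)))
    stop("coupling must be a ", f, " x ", f, " matrix matching factors")
  if (!isTRUE(all.equal(coupling, t(coupling))))
    stop("coupling matrix must be symmetric")
  if (any(coupling < 0 | coupling > 1))
    stop("coupling strengths must lie in [0, 1]")
  if (any(diag(coupling) != 0)) stop("coupling diagonal must be zero")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (ar_coeff < 0 || ar_coeff >= 1) stop("ar_coeff must be in [0, 1)")
  if (driver_ar < 0 || driver_ar >= 1) stop("driver_ar must be in [0, 1)")
  if (length(driver_period_range) != 2L || any(driver_period_range < 2))
    stop("driver_period_range must be two periods >= 2 samples")
  if (driver_osc_weight < 0 || driver_osc_weight > 1)
    stop("driver_osc_weight must lie in [0, 1]")
  if (signal_amp < 0) stop("signal_amp must be >= 0")
  if (!is.null(hub) && !hub %in% factors)
    stop("hub must be one of the factors")
  dimnames(coupling) <- list(factors, factors)
  structure(list(n_stations = as.integer(n_stations), factors = factors,
                 n_samples = as.integer(n_samples),
                 interval_min = interval_min, coupling = coupling,
                 station_lag = as.integer(station_lag),
                 station_decay = station_decay, ar_coeff = ar_coeff,
                 noise_sd = noise_sd, diurnal_amp = diurnal_amp,
                 diurnal_period = diurnal_period, trend_amp = trend_amp,
                 driver_ar = driver_ar,
                 driver_period_range = driver_period_range,
                 driver_osc_weight = driver_osc_weight,
                 signal_amp = signal_amp, hub = hub,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default factor-coupling matrix
#'
#' For the standard 8-factor set, couples pH to the other factors with a
#' graded spread (Temp 0.9, Tds 0.75, DoP 0.6, Do 0.45, Turb 0.3, Bga 0.15,
#' Chl 0) mirroring the usual field observation that temperature and total
#' dissolved solids co-vary most strongly with pH while chlorophyll barely
#' does, plus two physically motivated pairs (Do-DoP 0.8, Temp-Tds 0.4).
#' Unknown factor names get a zero matrix.
#'
#' @param factors Character vector of factor names.
#' @return Symmetric matrix of coupling strengths.
#' @export
default_coupling <- function(factors) {
  f <- length(factors)
  m <- matrix(0, f, f, dimnames = list(factors, factors))
  set_beta <- function(a, b, beta) {
    if (a %in% factors && b %in% factors) {
      m[a, b] <<- beta
      m[b, a] <<- beta
    }
  }
  set_beta("pH", "Temp", 0.9)
  set_beta("pH", "Tds", 0.75)
  set_beta("pH", "DoP", 0.6)
  set_beta("pH", "Do", 0.45)
  set_beta("pH", "Turb", 0.3)
  set_beta("pH", "Bga", 0.15)
  set_beta("Do", "DoP", 0.8)
  set_beta("Temp", "Tds", 0.4)
  m
}

# stationary AR(1) path of length n with innovation sd s
ar1_path <- function(n, phi, s) {
  if (s == 0) return(numeric(n))
  e <- stats::rnorm(n, 0, s)
  x0 <- stats::rnorm(1, 0, s / sqrt(1 - phi^2))
  as.numeric(stats::filter(e, phi, method = "recursive", init = x0))
}

#' Generate a coupled multi-station dataset
#'
#' Fully deterministic given the config (including its seed): the same
#' config yields a byte-identical dataset. See [sim_config()] for the
#' generative model.
#'
#' @param config A `sim_config`.
#' @return A `station_dataset` with the config stored as `truth`.
#' @examples
#' cfg <- sim_config(n_stations = 2, factors = c("pH", "Temp", "Chl"),
#'                   n_samples = 300, seed = 42)
#' ds <- simulate_stations(cfg)
#' ds
#' @export
simulate_stations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  f <- length(config$factors)
  n <- config$n_samples
  maxlag <- (config$n_stations - 1L) * config$station_lag
  L <- n + maxlag
  tt <- seq_len(n)

  diurnal <- config$diurnal_amp * sin(2 * pi * tt / config$diurnal_period)
  trend <- config$trend_amp * sin(pi * tt / n)

  # one shared driver per coupled pair plus one private driver per factor.
  # Oscillation periods come from a log-spaced grid over the configured
  # range, randomly assigned, so no two drivers collide on the same
  # spectral band; phases are random. Drivers are generated in fixed order
  # so the dataset is a pure function of the seed.
  hub_i <- if (is.null(config$hub)) 0L else match(config$hub, config$factors)
  pair_needs_driver <- function(i, j) i != hub_i && j != hub_i
  n_pairs <- 0L
  for (i in seq_len(f)) for (j in seq_len(f))
    if (j > i && config$coupling[i, j] > 0 && pair_needs_driver(i, j))
      n_pairs <- n_pairs + 1L
  n_drv <- n_pairs + f
  periods <- exp(seq(log(config$driver_period_range[1]),
                     log(config$driver_period_range[2]),
                     length.out = max(n_drv, 2)))[seq_len(n_drv)]
  periods <- sample(periods)
  drv_k <- 0
  new_driver <- function() {
    drv_k <<- drv_k + 1
    a <- ar1_path(L, config$driver_ar, 1)
    phase <- stats::runif(1, 0, 2 * pi)
    osc <- sin(2 * pi * seq_len(L) / periods[drv_k] + phase)
    w <- config$driver_osc_weight
    d <- sqrt(1 - w) * a / stats::sd(a) + sqrt(w) * osc / stats::sd(osc)
    d / stats::sd(d)
  }
  shared <- list()
  for (i in seq_len(f)) for (j in seq_len(f)) {
    if (j > i && config$coupling[i, j] > 0 && pair_needs_driver(i, j))
      shared[[paste(i, j)]] <- new_driver()
  }
  private <- lapply(seq_len(f), function(i) new_driver())
  # hub couplings share the hub's private driver
  if (hub_i > 0L) {
    for (i in seq_len(f)) for (j in seq_len(f)) {
      if (j > i && config$coupling[i, j] > 0 && !pair_needs_driver(i, j))
        shared[[paste(i, j)]] <- private[[hub_i]]
    }
  }

  series <- list()
  for (s in seq_len(config$n_stations)) {
    rank <- s - 1L
    shift <- maxlag - rank * config$station_lag
    scale <- config$station_decay^rank
    st <- sprintf("ST%d", s)
    for (i in seq_len(f)) {
      coupled <- numeric(n)
      beta2 <- 0
      for (j in seq_len(f)) {
        beta <- config$coupling[i, j]
        if (beta > 0 && i != hub_i) {
          key <- if (i < j) paste(i, j) else paste(j, i)
          coupled <- coupled + beta * shared[[key]][tt + shift]
          beta2 <- beta2 + beta^2
        }
      }
      signal <- if (beta2 > 1) {
        coupled / sqrt(beta2)
      } else {
        coupled + sqrt(1 - beta2) * private[[i]][tt + shift]
      }
      noise <- ar1_path(n, config$ar_coeff, config$noise_sd)
      v <- diurnal + trend + config$signal_amp * scale * signal + noise
      id <- paste0(st, ":", config$factors[i])
      series[[id]] <- water_ts(v, st, config$factors[i], config$interval_min)
    }
  }
  station_dataset(series, truth = config)
}
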