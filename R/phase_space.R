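#' Embedding parameters
#'
#' @param dimension Embedding dimension n (integer >= 1).
#' @param delay Delay time t in samples (integer >= 1).
#' @return An `embedding_params` object.
#' @export
embedding_params <- function(dimension, delay) {
  dimension <- as.integer(dimension)
  delay <- as.integer(delay)
  if (is.na(dimension) || dimension < 1L) stop("dimension must be >= 1")
  if (is.na(delay) || delay < 1L) stop("delay must be >= 1")
  structure(list(dimension = dimension, delay = delay),
            class = "embedding_params")
}

#' @export
print.embedding_params <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
#' @method format embedding_params
format.embedding_params <- function(x, ...) {
  # "n/t" notation: dimension slash delay
  paste0(x$dimension, "/", x$delay)
}

#' Average mutual information profile of a series
#'
#' Mutual information (in nats) between the series and its lagged copy for
#' lags 1..max_delay, estimated with an equal-width 2-D histogram. The
#' location of the first minimum, which is all the delay selection uses, is
#' invariant to the log base and to affine rescaling of the series.
#'
#' @param x A `water_ts` or numeric vector.
#' @param max_delay Largest lag evaluated; must be below half the length.
#' @param n_bins Number of equal-width marginal bins (default 16).
#' @return Numeric vector of AMI values, one per lag.
#' @export
ami_profile <- function(x, max_delay, n_bins = 16) {
  x <- as.numeric(x)
  n <- length(x)
  if (max_delay >= n / 2)
    stop("max_delay = ", max_delay, " requires a series of length > ",
         2 * max_delay, " (got ", n, ")")
  if (n_bins < 2) stop("n_bins must be >= 2")
  rng <- range(x)
  if (rng[1] == rng[2])
    stop("degenerate input: constant series has zero entropy at all lags")
  # bin index in 1..n_bins, top edge closed
  bi <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins), n_bins - 1) + 1
  vapply(seq_len(max_delay), function(tau) {
    a <- bi[seq_len(n - tau)]
    b <- bi[seq_len(n - tau) + tau]
    joint <- tabulate((a - 1L) * n_bins + b, nbins = n_bins * n_bins)
    p <- joint / sum(joint)
    px <- tabulate(a, nbins = n_bins) / length(a)
    py <- tabulate(b, nbins = n_bins) / length(b)
    # joint index (a-1)*n_bins + b runs fastest in b, so the matching
    # product-of-marginals vector is outer(py, px) flattened column-major
    pp <- as.vector(outer(py, px))
    keep <- p > 0
    sum(p[keep] * log(p[keep] / pp[keep]))
  }, numeric(1))
}

#' Select the embedding delay by the first AMI minimum
#'
#' Returns the lag of the first local minimum of the average mutual
#' information profile. The raw histogram profile of strongly periodic
#' signals carries binning-resonance wiggles that create spurious early
#' minima, so by default the profile is smoothed with a quadratic loess fit
#' (span 0.35) before the minimum is picked; set `smooth = FALSE` to use
#' the raw profile (preferable for series that decorrelate within a couple
#' of samples, e.g. strongly chaotic maps). If no local minimum exists in
#' the search range, `max_delay` is returned with a warning.
#'
#' @inheritParams ami_profile
#' @param smooth Smooth the profile before minimum-picking (default TRUE;
#'   requires `max_delay >= 8`, otherwise the raw profile is used).
#' @param span loess span for the smoother.
#' @return Integer delay in samples.
#' @examples
#' x <- sin(2 * pi * seq_len(2000) / 100)
#' ami_delay(x, max_delay = 60)  # near a quarter period
#' @export
ami_delay <- function(x, max_delay, n_bins = 16, smooth = TRUE,
                      span = 0.35) {
  prof <- ami_profile(x, max_delay, n_bins)
  if (isTRUE(smooth) && max_delay >= 8) {
    lag <- seq_along(prof)
    prof <- as.numeric(stats::predict(stats::loess(prof ~ lag, span = span,
                                                   degree = 2)))
  }
  if (max_delay >= 2) {
    for (tau in seq_len(max_delay - 1)) {
      falls_into <- if (tau == 1) TRUE else prof[tau] < prof[tau - 1]
      rises_out <- prof[tau] < prof[tau + 1]
      if (falls_into && rises_out && (tau > 1 || prof[1] < prof[2]))
        return(as.integer(tau))
    }
  }
  warning("no local AMI minimum up to lag ", max_delay,
          "; falling back to max_delay")
  as.integer(max_delay)
}

#' Select the embedding dimension by false nearest neighbours
#'
#' Kennel-style criterion: for each trial dimension the nearest neighbour of
#' every embedded point is found and flagged false when adding the next
#' delay coordinate stretches the pair by more than `rtol` relative to their
#' distance, or beyond `atol` attractor sizes. The smallest dimension whose
#' false-neighbour fraction drops below `threshold` is returned; if none
#' does, `max_dim` with a warning.
#'
#' @param x A `water_ts` or numeric vector.
#' @param delay Embedding delay in samples.
#' @param max_dim Largest dimension tried (default 12).
#' @param rtol Relative stretch tolerance (default 15).
#' @param atol Absolute stretch tolerance in attractor sizes (default 2).
#' @param threshold False-neighbour fraction below which the dimension is
#'   accepted (default 0.01).
#' @param n_ref Number of evenly spaced reference points whose neighbours
#'   are tested per dimension (default 600; neighbours are searched over
#'   all embedded points). Long series are subsampled this way to keep
#'   the search quadratic cost bounded; 0 tests every point.
#' @return Integer dimension.
#' @examples
#' # deterministic quadratic map needs only 2 dimensions
#' x <- numeric(1500); y <- numeric(1500); x[1] <- 0.1
#' for (i in 2:1500) { x[i] <- 1 - 1.4 * x[i-1]^2 + y[i-1]; y[i] <- 0.3 * x[i-1] }
#' fnn_dimension(x, delay = 1)
#' @export
fnn_dimension <- function(x, delay, max_dim = 12, rtol = 15, atol = 2,
                          threshold = 0.01, n_ref = 600) {
  x <- as.numeric(x)
  if (delay < 1) stop("delay must be >= 1")
  if (max_dim < 2) stop("max_dim must be >= 2")
  if (length(x) - max_dim * delay < 2)
    stop("series too short to test dimension ", max_dim, " at delay ", delay,
         ": need length > ", max_dim * delay + 1)
  if (stats::sd(x) == 0)
    stop("degenerate input: constant series has no attractor")
  frac <- .cpp_fnn_fractions(x, as.integer(delay), as.integer(max_dim),
                             rtol, atol, threshold, as.integer(n_ref))
  ok <- which(!is.na(frac) & frac < threshold)
  if (length(ok) > 0) return(ok[1])
  warning("false-neighbour fraction never dropped below ", threshold,
          " up to dimension ", max_dim, "; returning max_dim")
  as.integer(max_dim)
}

#' Select both embedding parameters for one series
#'
#' Convenience wrapper: delay by first AMI minimum, then dimension by false
#' nearest neighbours at that delay.
#'
#' @inheritParams fnn_dimension
#' @param max_delay Largest lag scanned for the AMI minimum (default 60).
#' @param n_bins AMI histogram bins.
#' @return An `embedding_params`.
#' @export
select_embedding <- function(x, max_delay = 60, max_dim = 12, n_bins = 16,
                             rtol = 15, atol = 2, threshold = 0.01,
                             n_ref = 600) {
  t <- ami_delay(x, max_delay, n_bins)
  n <- fnn_dimension(x, t, max_dim, rtol, atol, threshold, n_ref)
  embedding_params(n, t)
}

#' Best-match parameters for a series pair
#'
#' Two series compared by cross recurrence must share one phase space, so a
#' single (dimension, delay) pair has to serve both. The rule keeps the
#' higher dimension (never under-embed either series) and the smaller delay:
#' `(max(n_a, n_b), min(t_a, t_b))`. Commutative and idempotent.
#'
#' @param a,b `embedding_params` for the two series.
#' @return The shared `embedding_params`.
#' @examples
#' resolve_best_match(embedding_params(6, 9), embedding_params(8, 28))  # 8/9
#' @export
resolve_best_match <- function(a, b) {
  stopifnot(inherits(a, "embedding_params"), inherits(b, "embedding_params"))
  embedding_params(max(a$dimension, b$dimension), min(a$delay, b$delay))
}

#' Time-delay embedding
#'
#' Reconstructs the phase-space trajectory of a scalar series: row k of the
#' result is (w_k, w_{k+t}, ..., w_{k+(n-1)t}), giving N = i - (n-1) t
#' embedded states from i samples.
#'
#' @param x A `water_ts` or numeric vector.
#' @param params An `embedding_params`, or `NULL` to pass `dimension` and
#'   `delay` directly.
#' @param dimension,delay Scalars used when `params` is `NULL`.
#' @return An N x n numeric matrix of class `trajectory` with the params
#'   attached as attribute `"params"`.
#' @examples
#' delay_embed(c(1, 2, 3, 4, 5), dimension = 2, delay = 1)
#' @export
delay_embed <- function(x, params = NULL, dimension = NULL, delay = NULL) {
  if (is.null(params)) params <- embedding_params(dimension, delay)
  xv <- as.numeric(x)
  i <- length(xv)
  n <- params$dimension
  t <- params$delay
  if ((n - 1) * t >= i) {
    nmax <- (i - 1) %/% t + 1
    stop("cannot embed ", i, " samples at dimension ", n, ", delay ", t,
         "; maximal feasible dimension at this delay is ", nmax - 1)
  }
  N <- i - (n - 1) * t
  traj <- matrix(0, nrow = N, ncol = n)
  for (m in seq_len(n)) traj[, m] <- xv[seq_len(N) + (m - 1) * t]
  structure(traj, params = params, source_label = series_label(as_water_ts(x)),
            class = c("trajectory", "matrix", "array"))
}
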