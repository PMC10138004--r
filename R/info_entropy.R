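#' Discretize a series into equal-width bins
#'
#' Bins span \[min, max\] of the series; the maximum falls in the top bin.
#' Symbols are integers in 0..n_bins-1.
#'
#' @param x A `water_ts` or numeric vector, non-constant.
#' @param n_bins Number of bins (default 16).
#' @return A `discretized_series`: list with `symbols`, `n_bins`,
#'   `bin_edges`.
#' @export
discretize <- function(x, n_bins = 16) {
  x <- as.numeric(x)
  if (n_bins < 2) stop("n_bins must be >= 2")
  rng <- range(x)
  if (rng[1] == rng[2])
    stop("cannot discretize a constant series")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  sym <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins), n_bins - 1)
  structure(list(symbols = as.integer(sym), n_bins = as.integer(n_bins),
                 bin_edges = edges),
            class = "discretized_series")
}

as_discretized <- function(x, n_bins) {
  if (inherits(x, "discretized_series")) x else discretize(x, n_bins)
}

#' Shannon entropy of a discretized series
#'
#' Plug-in estimate −sum(p log2 p) over empirical symbol frequencies, in
#' bits; 0 log 0 taken as 0.
#'
#' @param d A `discretized_series` (or numeric vector, binned with
#'   `n_bins`).
#' @param n_bins Bins used when `d` is raw.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(d, n_bins = 16) {
  d <- as_discretized(d, n_bins)
  p <- tabulate(d$symbols + 1L, nbins = d$n_bins)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Joint entropy of two discretized series
#'
#' −sum(p(x, y) log2 p(x, y)) over the empirical joint distribution of the
#' aligned symbol pairs, in bits.
#'
#' @param dx,dy `discretized_series` of equal length (or raw vectors).
#' @param n_bins Bins used for raw inputs.
#' @return Joint entropy in bits.
#' @export
joint_entropy <- function(dx, dy, n_bins = 16) {
  dx <- as_discretized(dx, n_bins)
  dy <- as_discretized(dy, n_bins)
  if (length(dx$symbols) != length(dy$symbols))
    stop("series must have equal length")
  joint <- tabulate(dx$symbols * dy$n_bins + dy$symbols + 1L,
                    nbins = dx$n_bins * dy$n_bins)
  p <- joint / sum(joint)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information between two series
#'
#' I(X;Y) = H(X) + H(Y) − H(X,Y) in bits, from the equal-width histogram
#' discretization; clipped at zero against negative rounding. Symmetric in
#' its arguments.
#'
#' @param x,y Series (raw `water_ts`/numeric, or `discretized_series`) of
#'   equal length.
#' @param n_bins Bins used for raw inputs (default 16).
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, y, n_bins = 16) {
  dx <- as_discretized(x, n_bins)
  dy <- as_discretized(y, n_bins)
  mi <- shannon_entropy(dx) + shannon_entropy(dy) - joint_entropy(dx, dy)
  max(mi, 0)
}
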