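#' Diagonal and vertical line histograms of a recurrence matrix
#'
#' Counts maximal runs of recurrent cells along diagonals parallel to the
#' main diagonal (i -> i+1, j -> j+1) and down columns. Cells outside the
#' matrix are treated as empty, so runs touching a border are maximal runs.
#' Every recurrent cell belongs to exactly one maximal run per direction,
#' which yields the conservation identity
#' sum(l * P(l)) = sum(v * P(v)) = N * M * RR.
#'
#' @param m A `cross_recurrence` (or any 0/1 matrix).
#' @return List with components `diagonal` and `vertical`: numeric vectors
#'   where element `k` is the number of maximal runs of length `k`.
#' @export
line_histograms <- function(m) {
  m <- unclass(m)
  storage.mode(m) <- "integer"
  if (length(m) == 0L) stop("empty matrix")
  .cpp_line_histograms(m)
}

#' Recurrence rate
#'
#' Density of recurrent cells: the count of 1s over N x M. For a square
#' self-comparison this is the classical RR; the rectangular form covers
#' trajectories of unequal length.
#'
#' @param m A 0/1 recurrence matrix.
#' @return Scalar in \[0, 1\].
#' @export
recurrence_rate <- function(m) {
  sum(m == 1L) / length(m)
}

hist_total <- function(h) sum(seq_along(h) * h)

#' Determinism
#'
#' Fraction of recurrence points lying on diagonal lines of length at least
#' `lmin`: sum(l P(l), l >= lmin) / sum(l P(l), l >= 1). High values mark
#' deterministic co-evolution of the two series; defined as 0 on an empty
#' matrix.
#'
#' @param h Line histograms from [line_histograms()].
#' @param lmin Minimal diagonal length counted as a line (default 2).
#' @return Scalar in \[0, 1\].
#' @export
determinism <- function(h, lmin = 2) {
  d <- h$diagonal
  tot <- hist_total(d)
  if (tot == 0) return(0)
  keep <- seq_along(d) >= lmin
  sum(seq_along(d)[keep] * d[keep]) / tot
}

#' Laminarity
#'
#' Fraction of recurrence points inside vertical lines of length at least
#' `vmin`; marks laminar (stationary) co-states. Defined as 0 on an empty
#' matrix.
#'
#' @param h Line histograms from [line_histograms()].
#' @param vmin Minimal vertical length counted (default 2).
#' @return Scalar in \[0, 1\].
#' @export
laminarity <- function(h, vmin = 2) {
  v <- h$vertical
  tot <- hist_total(v)
  if (tot == 0) return(0)
  keep <- seq_along(v) >= vmin
  sum(seq_along(v)[keep] * v[keep]) / tot
}

#' Mean diagonal line length
#'
#' Average length of diagonal lines of length at least `lmin`:
#' sum(l P(l)) / sum(P(l)) over l >= lmin — the mean duration of episodes in
#' which the two series evolve similarly. Defined as 0 when no diagonal
#' reaches `lmin`.
#'
#' @inheritParams determinism
#' @return Scalar, 0 or >= `lmin`.
#' @export
mean_diagonal_length <- function(h, lmin = 2) {
  d <- h$diagonal
  keep <- seq_along(d) >= lmin
  cnt <- sum(d[keep])
  if (cnt == 0) return(0)
  sum(seq_along(d)[keep] * d[keep]) / cnt
}

#' All four CRQA indices of a cross-recurrence matrix
#'
#' @param m A `cross_recurrence` matrix.
#' @param lmin,vmin Minimal diagonal / vertical line lengths (default 2).
#' @return List with `rr`, `det`, `lam`, `mdl`, the `histograms`, and the
#'   `lmin`/`vmin` used.
#' @export
crqa_metrics <- function(m, lmin = 2, vmin = 2) {
  h <- line_histograms(m)
  list(rr = recurrence_rate(m),
       det = determinism(h, lmin),
       lam = laminarity(h, vmin),
       mdl = mean_diagonal_length(h, lmin),
       histograms = h, lmin = lmin, vmin = vmin)
}
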