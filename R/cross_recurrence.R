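#' Maximum phase-space diameter of two trajectories
#'
#' Largest pairwise distance over the union of both embedded point clouds,
#' under the configured norm. The recurrence threshold is defined as a fixed
#' fraction of this diameter, so both series see a single shared scale.
#'
#' @param a,b `trajectory` matrices of equal dimension (column count).
#' @param norm `"euclidean"` (default) or `"maximum"`.
#' @return Scalar diameter.
#' @export
phase_space_diameter <- function(a, b, norm = c("euclidean", "maximum")) {
  norm <- match.arg(norm)
  if (ncol(a) != ncol(b))
    stop("trajectories have different dimensions: ", ncol(a), " vs ", ncol(b))
  pts <- rbind(unclass(a), unclass(b))
  .cpp_max_pairwise_dist(pts, norm == "maximum")
}

#' Cross-recurrence matrix of two trajectories
#'
#' Binary N x M matrix with cell (i, j) = 1 when the i-th state of `a` lies
#' within epsilon of the j-th state of `b`. Epsilon is `epsilon_fraction`
#' times the joint phase-space diameter; a boundary tie (distance exactly
#' epsilon) counts as recurrent, following the Heaviside convention
#' Theta(0) = 1.
#'
#' @param a,b `trajectory` matrices of equal dimension.
#' @param epsilon_fraction Fraction of the joint diameter used as the
#'   recurrence threshold; default 0.006 (0.6 percent).
#' @param norm Distance norm, `"euclidean"` or `"maximum"`.
#' @return A `cross_recurrence` object: integer 0/1 matrix with attributes
#'   `epsilon`, `epsilon_fraction`, `norm`, `labels`.
#' @export
cross_recurrence <- function(a, b, epsilon_fraction = 0.006,
                             norm = c("euclidean", "maximum")) {
  norm <- match.arg(norm)
  if (ncol(a) != ncol(b))
    stop("trajectories have different dimensions: ", ncol(a), " vs ", ncol(b),
         "; resolve a shared embedding first")
  if (epsilon_fraction <= 0 || epsilon_fraction >= 1)
    stop("epsilon_fraction must lie in (0, 1)")
  diam <- phase_space_diameter(a, b, norm)
  if (diam == 0)
    stop("joint point cloud has zero diameter: epsilon undefined")
  eps <- epsilon_fraction * diam
  cells <- .cpp_cross_recurrence(unclass(a), unclass(b), eps,
                                 norm == "maximum")
  structure(cells,
            epsilon = eps, epsilon_fraction = epsilon_fraction, norm = norm,
            labels = c(attr(a, "source_label") %||% "a",
                       attr(b, "source_label") %||% "b"),
            class = c("cross_recurrence", "matrix", "array"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.cross_recurrence <- function(x, ...) {
  cat(sprintf("<cross_recurrence> %d x %d, eps = %.4g (%.3g%% of diameter), %s norm, RR = %.4f\n",
              nrow(x), ncol(x), attr(x, "epsilon"),
              100 * attr(x, "epsilon_fraction"), attr(x, "norm"),
              mean(x == 1L)))
  invisible(x)
}

#' Render a cross-recurrence plot to PNG
#'
#' Recurrent cells are drawn black on white, x axis indexing the states of
#' the first series and y axis the second, origin at the lower left.
#'
#' @param m A `cross_recurrence` matrix.
#' @param path Output PNG path.
#' @param width,height Image size in pixels.
#' @return `path`, invisibly.
#' @export
render_crp <- function(m, path, width = 600, height = 600) {
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  labs <- attr(m, "labels")
  graphics::image(x = seq_len(nrow(m)), y = seq_len(ncol(m)),
                  z = unclass(m) == 1L,
                  col = c("white", "black"), useRaster = TRUE,
                  xlab = labs[1], ylab = labs[2],
                  main = sprintf("CRP  eps = %.3g  RR = %.3f",
                                 attr(m, "epsilon"), mean(m == 1L)))
  invisible(path)
}
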