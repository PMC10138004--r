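#' Analysis configuration
#'
#' Collects every tunable the coupling analysis uses, validated on
#' construction. One config travels through panel building, the pipeline
#' and the sensitivity analysis so that all reported numbers share one set
#' of parameters.
#'
#' @param epsilon_fraction Recurrence threshold as a fraction of the joint
#'   phase-space diameter (default 0.006).
#' @param norm Distance norm for recurrence, `"euclidean"` or `"maximum"`.
#' @param lmin,vmin Minimal diagonal / vertical line lengths (default 2).
#' @param mi_bins Histogram bins for mutual information (default 16).
#' @param normalization_scope `"panel"` (per station panel, default) or
#'   `"global"` (across all candidate rows of one target).
#' @param lengths Truncation lengths for the sensitivity analysis (default
#'   2000 and 3000; the full length is always added).
#' @param max_delay,ami_bins AMI delay search range and bins.
#' @param max_dim,rtol,atol,fnn_threshold False-nearest-neighbour settings.
#' @param standardize Z-score each series before embedding (default TRUE)
#'   so the shared epsilon is not dominated by unit differences.
#' @param seed Seed for any randomized diagnostics.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(epsilon_fraction = 0.006,
                            norm = c("euclidean", "maximum"),
                            lmin = 2, vmin = 2, mi_bins = 16,
                            normalization_scope = c("panel", "global"),
                            lengths = c(2000, 3000),
                            max_delay = 60, ami_bins = 16,
                            max_dim = 12, rtol = 15, atol = 2,
                            fnn_threshold = 0.01,
                            standardize = TRUE, seed = 1) {
  norm <- match.arg(norm)
  normalization_scope <- match.arg(normalization_scope)
  if (epsilon_fraction <= 0 || epsilon_fraction >= 1)
    stop("epsilon_fraction must lie in (0, 1)")
  if (lmin < 1 || vmin < 1) stop("lmin and vmin must be >= 1")
  if (mi_bins < 2 || ami_bins < 2) stop("histogram bins must be >= 2")
  if (max_delay < 1 || max_dim < 2) stop("invalid embedding search range")
  structure(list(epsilon_fraction = epsilon_fraction, norm = norm,
                 lmin = lmin, vmin = vmin, mi_bins = mi_bins,
                 normalization_scope = normalization_scope,
                 lengths = lengths, max_delay = max_delay,
                 ami_bins = ami_bins, max_dim = max_dim, rtol = rtol,
                 atol = atol, fnn_threshold = fnn_threshold,
                 standardize = standardize, seed = as.integer(seed)),
            class = "pipeline_config")
}

prep_series <- function(x, config) {
  if (config$standardize) standardize_series(x) else x
}

select_embedding_cfg <- function(x, config) {
  select_embedding(x, max_delay = config$max_delay, max_dim = config$max_dim,
                   n_bins = config$ami_bins, rtol = config$rtol,
                   atol = config$atol, threshold = config$fnn_threshold)
}

# raw five-index row for one target/candidate pair; params may be
# pre-computed per series and passed in via the cache environment
pair_indices <- function(tx, ty, px, py, config) {
  best <- resolve_best_match(px, py)
  a <- delay_embed(prep_series(tx, config), best)
  b <- delay_embed(prep_series(ty, config), best)
  m <- cross_recurrence(a, b, config$epsilon_fraction, config$norm)
  q <- crqa_metrics(m, config$lmin, config$vmin)
  mi <- mutual_information(tx, ty, config$mi_bins)
  list(rr = q$rr, det = q$det, lam = q$lam, mdl = q$mdl, mi = mi,
       params = best, epsilon = attr(m, "epsilon"))
}

#' Raw coupling indices between a target and candidate series
#'
#' For each candidate, resolves a shared embedding with the target
#' (best-match rule), builds the cross-recurrence matrix on the
#' standardized series, quantifies it (RR, DET, LAM, MDL), and adds the
#' histogram mutual information of the raw aligned series. Degenerate
#' (constant) candidates are dropped with a warning.
#'
#' @param ds A `station_dataset`.
#' @param target Target id `"ST1:pH"`.
#' @param candidates Character vector of candidate ids; default every other
#'   series whose factor differs from the target's.
#' @param config A `pipeline_config`.
#' @param param_cache Optional environment caching per-series embedding
#'   params across calls.
#' @return Data frame: station, factor, rr, det, lam, mdl, mi, dimension,
#'   delay, epsilon.
#' @export
coupling_indices <- function(ds, target, candidates = NULL,
                             config = pipeline_config(),
                             param_cache = new.env(parent = emptyenv())) {
  tx <- get_series(ds, target)
  if (is.null(candidates)) {
    tf <- attr(tx, "factor_name")
    candidates <- names(ds$series)[vapply(ds$series, function(s)
      attr(s, "factor_name") != tf, logical(1))]
  }
  if (length(candidates) == 0L) stop("no candidate series")
  params_of <- function(id) {
    if (!exists(id, envir = param_cache)) {
      p <- select_embedding_cfg(prep_series(get_series(ds, id), config), config)
      assign(id, p, envir = param_cache)
    }
    get(id, envir = param_cache)
  }
  px <- params_of(target)
  rows <- lapply(candidates, function(id) {
    ty <- get_series(ds, id)
    ok <- tryCatch({
      py <- params_of(id)
      r <- pair_indices(tx, ty, px, py, config)
      data.frame(station = attr(ty, "station"),
                 factor = attr(ty, "factor_name"),
                 rr = r$rr, det = r$det, lam = r$lam, mdl = r$mdl, mi = r$mi,
                 dimension = r$params$dimension, delay = r$params$delay,
                 epsilon = r$epsilon, stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("candidate ", id, " excluded: ", conditionMessage(e))
      NULL
    })
    ok
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("all candidates degenerate")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

index_cols <- c("rr", "det", "lam", "mdl", "mi")

#' Min-max normalize the index columns of a panel
#'
#' Per index column, maps x to (x − min) / (max − min) over the rows in
#' scope; a constant column maps to all 1 (no information to rank on, so no
#' row is penalized).
#'
#' @param rows Data frame with columns rr, det, lam, mdl, mi.
#' @return The data frame with those columns rescaled to \[0, 1\].
#' @export
min_max_normalize <- function(rows) {
  for (cn in index_cols) {
    x <- rows[[cn]]
    r <- range(x)
    rows[[cn]] <- if (r[1] == r[2]) rep(1, length(x)) else (x - r[1]) / (r[2] - r[1])
  }
  rows
}

#' Geometric mean of normalized indices
#'
#' `(prod x)^(1/length(x))`; exactly 0 when any component is 0, so the
#' per-index minimum row of a panel scores 0.
#'
#' @param x Numeric vector in \[0, 1\].
#' @return Scalar in \[0, 1\].
#' @export
geometric_mean_score <- function(x) {
  if (any(x == 0)) return(0)
  exp(mean(log(x)))
}

#' Build a coupling panel for one target
#'
#' Computes the five raw indices per candidate ([coupling_indices()]),
#' min-max normalizes them (per station panel by default, or across all
#' rows with the `"global"` scope), and scores each candidate by the
#' geometric mean of its five normalized indices. Rows are returned sorted
#' by descending score, ties broken by factor name.
#'
#' @inheritParams coupling_indices
#' @return A `coupling_panel`: list with `target`, `raw`, `normalized`,
#'   `scores` (the normalized data frame with a `score` column, sorted).
#' @export
coupling_panel <- function(ds, target, candidates = NULL,
                           config = pipeline_config(),
                           param_cache = new.env(parent = emptyenv())) {
  raw <- coupling_indices(ds, target, candidates, config, param_cache)
  norm <- if (config$normalization_scope == "global") {
    min_max_normalize(raw)
  } else {
    parts <- split(raw, raw$station)
    out <- do.call(rbind, lapply(parts, min_max_normalize))
    out[order(match(paste(out$station, out$factor),
                    paste(raw$station, raw$factor))), ]
  }
  norm$score <- apply(as.matrix(norm[, index_cols]), 1, geometric_mean_score)
  norm <- norm[order(-norm$score, norm$factor), ]
  rownames(norm) <- NULL
  structure(list(target = target, raw = raw, scores = norm,
                 config = config),
            class = "coupling_panel")
}

#' @export
print.coupling_panel <- function(x, ...) {
  cat("<coupling_panel> target", x$target, "\n")
  print(x$scores[, c("station", "factor", index_cols, "score")],
        digits = 3)
  invisible(x)
}

#' Data-length sensitivity of a coupling panel
#'
#' Rebuilds the panel on the first L samples for each requested length plus
#' the full record, and reports the Spearman rank correlation of the
#' composite scores between each truncation and the full run (matched by
#' station and factor).
#'
#' @inheritParams coupling_indices
#' @param lengths Truncation lengths; default from the config. The full
#'   length is always included.
#' @return List with `panels` (one `coupling_panel` per length, named by
#'   length) and `spearman` (named vector, one entry per truncation).
#' @export
length_sensitivity <- function(ds, target, candidates = NULL,
                               config = pipeline_config(),
                               lengths = config$lengths) {
  full <- length(ds$series[[1]])
  min_len <- (config$max_dim - 1) * 2 + config$max_delay * 2 + 2
  lengths <- sort(unique(c(pmin(lengths, full), full)))
  if (any(lengths < min_len))
    stop("truncation length below the minimum embeddable length ", min_len)
  panels <- lapply(lengths, function(L) {
    coupling_panel(truncate_dataset(ds, L), target, candidates, config)
  })
  names(panels) <- as.character(lengths)
  key <- function(p) paste(p$scores$station, p$scores$factor)
  ref <- panels[[as.character(full)]]
  ref_scores <- ref$scores$score[order(key(ref))]
  spearman <- vapply(panels[names(panels) != as.character(full)], function(p) {
    s <- p$scores$score[order(key(p))]
    if (stats::sd(s) == 0 || stats::sd(ref_scores) == 0) return(NA_real_)
    stats::cor(s, ref_scores, method = "spearman")
  }, numeric(1))
  list(panels = panels, spearman = spearman)
}

#' Render a score heatmap to PNG
#'
#' One column per panel, one row per (station, factor) candidate; darker
#' cells mark stronger composite coupling, each cell annotated with its
#' score.
#'
#' @param panels Named list of `coupling_panel`s (e.g. per target or per
#'   length).
#' @param path Output PNG path.
#' @param width,height Image size in pixels.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(panels, path, width = 700, height = 500) {
  if (inherits(panels, "coupling_panel")) panels <- list(panel = panels)
  keys <- sort(unique(unlist(lapply(panels, function(p)
    paste(p$scores$station, p$scores$factor)))))
  z <- sapply(panels, function(p) {
    k <- paste(p$scores$station, p$scores$factor)
    p$scores$score[match(keys, k)]
  })
  z <- matrix(z, nrow = length(keys),
              dimnames = list(keys, names(panels)))
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 8, 2, 1))
  pal <- grDevices::gray(seq(1, 0.2, length.out = 64))
  graphics::image(x = seq_len(ncol(z)), y = seq_len(nrow(z)), z = t(z),
                  zlim = c(0, 1), col = pal, axes = FALSE,
                  xlab = "", ylab = "", main = "composite coupling score")
  graphics::axis(1, at = seq_len(ncol(z)), labels = colnames(z), las = 2)
  graphics::axis(2, at = seq_len(nrow(z)), labels = rownames(z), las = 1)
  for (i in seq_len(nrow(z))) for (j in seq_len(ncol(z)))
    if (!is.na(z[i, j]))
      graphics::text(j, i, sprintf("%.2f", z[i, j]),
                     col = if (z[i, j] > 0.6) "white" else "black")
  invisible(path)
}
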