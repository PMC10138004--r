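#' Run the full coupling analysis
#'
#' End-to-end driver: for every target (by default, each factor at the
#' first station — the "central" station of the campaign), builds the
#' coupling panel against every other factor at every station, writes the
#' CRQA index table (station, factor, MDL, RR, DET, LAM per target), the
#' composite score panels and their heatmaps, optionally the per-pair CRP
#' images and the data-length sensitivity table, plus a parameter log
#' recording every setting used (including the absolute epsilon per pair,
#' for comparison with other recurrence software).
#'
#' Everything is computed before anything is written, so a failing stage
#' leaves no partial output files.
#'
#' @param ds A `station_dataset`, or a path to a long-format CSV readable
#'   by [read_station_csv()].
#' @param out_dir Output directory, created if needed.
#' @param config A `pipeline_config`.
#' @param targets Target ids; default all factors at the first station.
#' @param render_crps Write one CRP PNG per (target, candidate) pair
#'   (default FALSE; heatmaps are always written).
#' @param sensitivity Run the data-length sensitivity analysis for the
#'   first target (default TRUE when the record is long enough).
#' @return Invisibly, a list with `panels`, `crqa_table`, `sensitivity`,
#'   `files`.
#' @export
run_pipeline <- function(ds, out_dir, config = pipeline_config(),
                         targets = NULL, render_crps = FALSE,
                         sensitivity = TRUE) {
  if (is.character(ds)) ds <- read_station_csv(ds)
  if (length(ds$series) < 2L)
    stop("pipeline stage 'input': need >= 2 series (stations x factors)")
  stations <- vapply(ds$series, function(s) attr(s, "station"), character(1))
  if (is.null(targets)) {
    central <- stations[1]
    targets <- names(ds$series)[stations == central]
  }

  cache <- new.env(parent = emptyenv())
  panels <- withCallingHandlers(
    lapply(targets, function(tg)
      coupling_panel(ds, tg, config = config, param_cache = cache)),
    error = function(e) stop("pipeline stage 'panels': ", conditionMessage(e)))
  names(panels) <- targets

  sens <- NULL
  if (isTRUE(sensitivity)) {
    full <- length(ds$series[[1]])
    if (any(config$lengths < full)) {
      sens <- tryCatch(
        length_sensitivity(ds, targets[1], config = config),
        error = function(e) stop("pipeline stage 'sensitivity': ",
                                 conditionMessage(e)))
    }
  }

  # ---- all computed; write the bundle ----
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  safe_name <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)

  crqa_rows <- do.call(rbind, lapply(targets, function(tg) {
    r <- panels[[tg]]$raw
    data.frame(target = tg, station = r$station, factor = r$factor,
               MDL = r$mdl, RR = r$rr, DET = r$det, LAM = r$lam, MI = r$mi,
               dimension = r$dimension, delay = r$delay,
               epsilon = r$epsilon, stringsAsFactors = FALSE)
  }))
  f <- file.path(out_dir, "crqa_indices.csv")
  utils::write.csv(crqa_rows, f, row.names = FALSE)
  files <- c(files, f)

  score_rows <- do.call(rbind, lapply(targets, function(tg) {
    s <- panels[[tg]]$scores
    cbind(data.frame(target = tg, stringsAsFactors = FALSE),
          s[, c("station", "factor", "rr", "det", "lam", "mdl", "mi", "score")])
  }))
  f <- file.path(out_dir, "composite_scores.csv")
  utils::write.csv(score_rows, f, row.names = FALSE)
  files <- c(files, f)

  for (tg in targets) {
    f <- file.path(out_dir, paste0("heatmap_", safe_name(tg), ".png"))
    by_station <- split_panel_by_station(panels[[tg]])
    render_heatmap(by_station, f)
    files <- c(files, f)
  }

  if (render_crps) {
    for (tg in targets) {
      tx <- get_series(ds, tg)
      px <- get(tg, envir = cache)
      r <- panels[[tg]]$raw
      for (k in seq_len(nrow(r))) {
        id <- paste0(r$station[k], ":", r$factor[k])
        py <- get(id, envir = cache)
        best <- resolve_best_match(px, py)
        a <- delay_embed(prep_series(tx, config), best)
        b <- delay_embed(prep_series(get_series(ds, id), config), best)
        m <- cross_recurrence(a, b, config$epsilon_fraction, config$norm)
        f <- file.path(out_dir, paste0("crp_", safe_name(tg), "_",
                                       safe_name(id), ".png"))
        render_crp(m, f)
        files <- c(files, f)
      }
    }
  }

  if (!is.null(sens)) {
    sens_rows <- do.call(rbind, lapply(names(sens$panels), function(L) {
      s <- sens$panels[[L]]$scores
      cbind(data.frame(target = targets[1], length = as.integer(L),
                       stringsAsFactors = FALSE),
            s[, c("station", "factor", "score")])
    }))
    f <- file.path(out_dir, "length_sensitivity.csv")
    utils::write.csv(sens_rows, f, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(out_dir, "length_sensitivity_spearman.csv")
    utils::write.csv(data.frame(length = names(sens$spearman),
                                spearman = as.numeric(sens$spearman)),
                     f, row.names = FALSE)
    files <- c(files, f)
  }

  log_lines <- c(
    "parameters used:",
    sprintf("  epsilon_fraction: %g", config$epsilon_fraction),
    sprintf("  norm: %s", config$norm),
    sprintf("  lmin: %d  vmin: %d", config$lmin, config$vmin),
    sprintf("  mi_bins: %d  ami_bins: %d", config$mi_bins, config$ami_bins),
    sprintf("  max_delay: %d  max_dim: %d", config$max_delay, config$max_dim),
    sprintf("  fnn rtol: %g  atol: %g  threshold: %g",
            config$rtol, config$atol, config$fnn_threshold),
    sprintf("  standardize: %s", config$standardize),
    sprintf("  normalization_scope: %s", config$normalization_scope),
    sprintf("  seed: %d", config$seed),
    "per-pair absolute epsilon values are in crqa_indices.csv")
  f <- file.path(out_dir, "parameters.log")
  writeLines(log_lines, f)
  files <- c(files, f)

  invisible(list(panels = panels, crqa_table = crqa_rows,
                 scores = score_rows, sensitivity = sens, files = files,
                 config = config))
}

split_panel_by_station <- function(panel) {
  parts <- split(seq_len(nrow(panel$scores)), panel$scores$station)
  out <- lapply(parts, function(idx) {
    p <- panel
    p$scores <- panel$scores[idx, ]
    p
  })
  names(out) <- names(parts)
  out
}
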