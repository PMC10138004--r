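#' Published per-series embedding parameters for the reference campaign
#'
#' The package ships, as plain CSV, the per-series embedding dimension and
#' delay reported for the eight water-quality factors at the three coastal
#' monitoring stations whose campaign the synthetic generator emulates (the
#' raw buoy records themselves are not public). These printed parameters
#' are useful as realistic inputs to the best-match rule and as a worked
#' example of the "n/t" notation.
#'
#' @return Data frame with columns `station`, `factor`, `dimension`,
#'   `delay` (24 rows).
#' @examples
#' p <- reference_embedding_params()
#' subset(p, station == "ST1" & factor == "pH")
#' @export
reference_embedding_params <- function() {
  path <- system.file("extdata", "station_embedding_params.csv",
                      package = "stcrqa", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Best-match table for one target series
#'
#' Applies the best-match rule against a fixed target to every (station,
#' factor) row of a parameter table, reproducing the campaign's published
#' shared-embedding table: each cell is `"dimension/delay"` of
#' [resolve_best_match()] between that series and the target.
#'
#' @param params Data frame as returned by [reference_embedding_params()].
#' @param target_station,target_factor Identify the target row.
#' @return Data frame: station, factor, dimension, delay, label ("n/t").
#' @examples
#' best_match_table(reference_embedding_params(), "ST1", "pH")
#' @export
best_match_table <- function(params, target_station, target_factor) {
  trow <- params[params$station == target_station &
                   params$factor == target_factor, ]
  if (nrow(trow) != 1L)
    stop("target ", target_station, ":", target_factor, " not in table")
  tp <- embedding_params(trow$dimension, trow$delay)
  res <- lapply(seq_len(nrow(params)), function(k) {
    bp <- embedding_params(params$dimension[k], params$delay[k])
    resolve_best_match(tp, bp)
  })
  data.frame(station = params$station, factor = params$factor,
             dimension = vapply(res, `[[`, integer(1), "dimension"),
             delay = vapply(res, `[[`, integer(1), "delay"),
             label = vapply(res, format, character(1)),
             stringsAsFactors = FALSE)
}
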