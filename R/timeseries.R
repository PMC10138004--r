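#' Construct a station time series
#'
#' A `water_ts` is one factor's uniformly sampled record at one monitoring
#' station: a numeric vector tagged with station and factor identifiers and
#' the sampling interval. All analysis functions in the package accept these
#' objects (plain numeric vectors are coerced with placeholder identifiers).
#'
#' @param values Numeric vector of measurements, no missing values.
#' @param station Station identifier, e.g. `"ST1"`.
#' @param factor_name Factor identifier, e.g. `"pH"` or `"Tds"`.
#' @param interval_min Sampling interval in minutes (default 30, the typical
#'   buoy telemetry cadence).
#' @return An object of class `water_ts`: the numeric vector with
#'   `station`, `factor_name` and `interval_min` attributes.
#' @examples
#' x <- water_ts(sin(seq_len(200) / 10), "ST1", "Temp")
#' length(x)
#' @export
water_ts <- function(values, station = "S1", factor_name = "x",
                     interval_min = 30) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a water_ts needs at least 2 observations")
  if (anyNA(values))
    stop("water_ts values must not contain NA; interpolate or drop gaps first")
  structure(values,
            station = as.character(station),
            factor_name = as.character(factor_name),
            interval_min = interval_min,
            class = "water_ts")
}

as_water_ts <- function(x) {
  if (inherits(x, "water_ts")) return(x)
  water_ts(x)
}

#' @export
print.water_ts <- function(x, ...) {
  cat(sprintf("<water_ts> %s:%s, %d samples @ %g min\n",
              attr(x, "station"), attr(x, "factor_name"),
              length(x), attr(x, "interval_min")))
  invisible(x)
}

series_label <- function(x) {
  paste0(attr(x, "station"), ":", attr(x, "factor_name"))
}

#' Z-score standardize a series
#'
#' Centers and scales to unit variance. Used before embedding so that the
#' shared recurrence threshold on the joint phase space is not dominated by
#' unit differences between factors (pH versus mg/L-scale factors).
#'
#' @param x A `water_ts` or numeric vector.
#' @return A series of the same class with mean 0 and sd 1.
#' @export
standardize_series <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize a constant series (", series_label(as_water_ts(x)),
         "): zero variance")
  out <- (as.numeric(x) - mean(x)) / s
  attributes(out) <- attributes(x)
  out
}

#' Bundle per-station series into a dataset
#'
#' @param series Named list of `water_ts`, names `"<station>:<factor>"`.
#' @param truth Optional simulation config the data came from (ground truth).
#' @return A `station_dataset` object.
#' @export
station_dataset <- function(series, truth = NULL) {
  if (length(series) == 0L) stop("empty dataset")
  lens <- vapply(series, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("all series in a dataset must have equal length")
  if (is.null(names(series)) || any(!nzchar(names(series))))
    names(series) <- vapply(series, series_label, character(1))
  structure(list(series = series, truth = truth), class = "station_dataset")
}

#' @export
print.station_dataset <- function(x, ...) {
  st <- unique(vapply(x$series, function(s) attr(s, "station"), character(1)))
  fa <- unique(vapply(x$series, function(s) attr(s, "factor_name"), character(1)))
  cat(sprintf("<station_dataset> %d series (%d stations x %d factors), %d samples\n",
              length(x$series), length(st), length(fa),
              length(x$series[[1]])))
  invisible(x)
}

#' Fetch one series from a dataset by "station:factor" id
#'
#' @param ds A `station_dataset`.
#' @param id Identifier string such as `"ST1:pH"`.
#' @return The `water_ts`.
#' @export
get_series <- function(ds, id) {
  if (!id %in% names(ds$series))
    stop("no series '", id, "' in dataset; available: ",
         paste(utils::head(names(ds$series), 8), collapse = ", "), " ...")
  ds$series[[id]]
}

#' Read a long-format station CSV
#'
#' Expects columns `timestamp,station,factor,value`, one row per observation,
#' uniformly sampled within each (station, factor) series. Runs of up to
#' `max_gap` consecutive missing values are filled by linear interpolation;
#' longer gaps raise an error, as do leading/trailing missing values.
#'
#' @param path CSV file path.
#' @param max_gap Longest internal gap (in samples) repaired by linear
#'   interpolation; default 3.
#' @param interval_min Sampling interval recorded on each series.
#' @return A `station_dataset`.
#' @export
read_station_csv <- function(path, max_gap = 3, interval_min = 30) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "station", "factor", "value")
  if (!all(need %in% names(df)))
    stop("CSV must have columns: ", paste(need, collapse = ", "))
  df <- df[order(df$station, df$factor, df$timestamp), ]
  key <- paste0(df$station, ":", df$factor)
  series <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    v <- df$value[idx]
    v <- fill_gaps(v, max_gap, paste0(df$station[idx[1]], ":", df$factor[idx[1]]))
    water_ts(v, df$station[idx[1]], df$factor[idx[1]], interval_min)
  })
  station_dataset(series)
}

fill_gaps <- function(v, max_gap, label) {
  if (!anyNA(v)) return(v)
  na <- is.na(v)
  if (na[1] || na[length(v)])
    stop("series ", label, " starts or ends with missing values")
  r <- rle(na)
  if (any(r$values & r$lengths > max_gap))
    stop("series ", label, " has a gap of ", max(r$lengths[r$values]),
         " samples, longer than max_gap = ", max_gap)
  stats::approx(which(!na), v[!na], xout = seq_along(v))$y
}

#' Write a dataset to long-format CSV
#'
#' Inverse of [read_station_csv()]; round-trips values exactly (values are
#' printed with full precision).
#'
#' @param ds A `station_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_station_csv <- function(ds, path) {
  if (length(ds$series) == 0L) stop("empty dataset")
  rows <- lapply(ds$series, function(s) {
    data.frame(timestamp = seq_along(s),
               station = attr(s, "station"),
               factor = attr(s, "factor_name"),
               value = format(as.numeric(s), digits = 17, trim = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Truncate every series in a dataset to its first `n` samples
#'
#' @param ds A `station_dataset`.
#' @param n Number of leading samples to keep.
#' @return A `station_dataset` of length-`n` series.
#' @export
truncate_dataset <- function(ds, n) {
  full <- length(ds$series[[1]])
  if (n > full) stop("n = ", n, " exceeds series length ", full)
  series <- lapply(ds$series, function(s) {
    out <- as.numeric(s)[seq_len(n)]
    attributes(out) <- attributes(s)
    out
  })
  station_dataset(series, truth = ds$truth)
}
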