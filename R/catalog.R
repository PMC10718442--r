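# Earth radius used for all great-circle distances (miles).
EARTH_RADIUS_MILES <- 3958.8

# One second expressed in days; used to break tied timestamps so event times
# are strictly increasing (required by the likelihood recursion).
TIE_EPS_DAYS <- 1 / 86400

#' Construct an event catalog
#'
#' An event catalog holds event times on a continuous day axis (fractional
#' days since a calendar origin), the observation window \code{[0, T]}, and
#' the source records in the same order. It is the common currency of all
#' model, estimation, declustering and simulation functions.
#'
#' @param times numeric vector of event times in days since \code{origin};
#'   must be nondecreasing and contained in \code{[0, window_end]}. Ties are
#'   broken by adding 1-second increments in input order.
#' @param origin \code{POSIXct} calendar date-time mapped to \code{t = 0}.
#' @param window_end observation-window length \eqn{T} in days.
#' @param records optional \code{data.frame} of source records (one row per
#'   event, same order as \code{times}); free-form attributes such as weather
#'   are carried but never used by the model.
#' @return An object of class \code{event_catalog}: a list with elements
#'   \code{times}, \code{origin}, \code{window_end}, \code{records}, \code{n}.
#' @export
event_catalog <- function(times, origin, window_end, records = NULL) {
  times <- as.numeric(times)
  if (any(is.na(times))) stop("event times contain NA")
  if (is.unsorted(times)) stop("event times must be nondecreasing")
  if (length(times) && (times[1] < 0 || times[length(times)] > window_end)) {
    stop("event times must lie within [0, window_end]")
  }
  if (!inherits(origin, "POSIXct")) {
    origin <- as.POSIXct(origin, tz = "UTC")
  }
  times <- break_ties(times)
  if (!is.null(records)) {
    records <- as.data.frame(records)
    if (nrow(records) != length(times)) {
      stop("records must have one row per event time")
    }
  }
  structure(
    list(times = times, origin = origin, window_end = as.numeric(window_end),
         records = records, n = length(times)),
    class = "event_catalog"
  )
}

# Add +1s increments within runs of tied times so the sequence is strictly
# increasing; input order within a tie is preserved.
break_ties <- function(times) {
  if (length(times) < 2) return(times)
  repeat {
    tied <- which(diff(times) <= 0)
    if (!length(tied)) break
    times[tied + 1] <- times[tied] + TIE_EPS_DAYS
  }
  times
}

#' @export
print.event_catalog <- function(x, ...) {
  cat(sprintf("<event_catalog> %d events over [0, %.3f] days\n", x$n, x$window_end))
  cat(sprintf("  origin: %s UTC\n", format(x$origin, "%Y-%m-%d %H:%M")))
  if (x$n) {
    cat(sprintf("  first/last event: t = %.5f / %.5f days\n",
                x$times[1], x$times[x$n]))
  }
  invisible(x)
}

# Parse "date time" strings in the accepted formats; returns POSIXct with NA
# for unparseable rows.
parse_datetimes <- function(date, time) {
  stamp <- trimws(paste(date, time))
  fmts <- c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M",
            "%m/%d/%Y %H:%M:%S", "%m/%d/%Y %H:%M")
  out <- as.POSIXct(rep(NA_real_, length(stamp)), tz = "UTC",
                    origin = "1970-01-01")
  for (f in fmts) {
    idx <- which(is.na(out))
    if (!length(idx)) break
    parsed <- as.POSIXct(strptime(stamp[idx], format = f, tz = "UTC"))
    out[idx] <- parsed
  }
  out
}

#' Load an event catalog from a CSV export
#'
#' Reads a crash-record CSV (one row per event, with date and time columns in
#' ISO \code{YYYY-MM-DD} or US \code{MM/DD/YYYY} format plus \code{HH:MM} or
#' \code{HH:MM:SS} times), converts timestamps to fractional days since the
#' origin, and returns a sorted \code{\link{event_catalog}}. Coordinate
#' columns are optional and only required by the spatial filters.
#'
#' @param path CSV file with a header row.
#' @param date_column,time_column names of the date and time columns.
#' @param lon_column,lat_column names of the coordinate columns (ignored when
#'   absent from the file).
#' @param origin optional \code{POSIXct} for \code{t = 0}; defaults to
#'   midnight (UTC) of the earliest event's date.
#' @param window_end optional window length in days; defaults to the end of
#'   the last event's day.
#' @return An \code{\link{event_catalog}} whose \code{records} keep all input
#'   columns (reordered chronologically).
#' @export
load_catalog <- function(path, date_column = "crash_date",
                         time_column = "crash_time",
                         lon_column = "longitude", lat_column = "latitude",
                         origin = NULL, window_end = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0) stop("empty catalog: ", path, " contains no events")
  for (col in c(date_column, time_column)) {
    if (!col %in% names(df)) stop("column '", col, "' not found in ", path)
  }
  ts <- parse_datetimes(df[[date_column]], df[[time_column]])
  if (anyNA(ts)) {
    bad <- which(is.na(ts))
    stop("unparseable date/time at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  }
  for (col in c(lon_column, lat_column)) {
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  }
  if (lat_column %in% names(df)) {
    lat <- df[[lat_column]]
    if (any(!is.na(lat) & abs(lat) > 90)) stop("latitude outside [-90, 90]")
  }
  if (lon_column %in% names(df)) {
    lon <- df[[lon_column]]
    if (any(!is.na(lon) & abs(lon) > 180)) stop("longitude outside [-180, 180]")
  }
  ord <- order(ts)
  ts <- ts[ord]
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  if (is.null(origin)) {
    origin <- trunc(ts[1], units = "days")
  } else if (!inherits(origin, "POSIXct")) {
    origin <- as.POSIXct(origin, tz = "UTC")
  }
  times <- as.numeric(difftime(ts, origin, units = "days"))
  if (is.null(window_end)) {
    last_midnight <- trunc(ts[length(ts)], units = "days") + 86400
    window_end <- as.numeric(difftime(last_midnight, origin, units = "days"))
  }
  event_catalog(times, origin, window_end, records = df)
}

#' Write a catalog back to CSV
#'
#' Writes the source records with an added \code{t_days} column (event time
#' on the catalog's day axis).
#'
#' @param catalog an \code{\link{event_catalog}}.
#' @param path output CSV path.
#' @export
write_catalog <- function(catalog, path) {
  df <- catalog$records
  if (is.null(df)) df <- data.frame(row.names = seq_len(catalog$n))
  df$t_days <- catalog$times
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Great-circle (haversine) distance in miles between points and a center;
# points is a 2-column lon/lat matrix.
haversine_miles <- function(points, center) {
  geosphere::distHaversine(points, center, r = EARTH_RADIUS_MILES)
}

# Pull the lon/lat matrix out of a catalog's records, with row-level errors
# for missing coordinates.
catalog_coords <- function(catalog, lon_column = "longitude",
                           lat_column = "latitude") {
  df <- catalog$records
  if (is.null(df) || !all(c(lon_column, lat_column) %in% names(df))) {
    stop("catalog records carry no '", lon_column, "'/'", lat_column,
         "' coordinates")
  }
  lon <- as.numeric(df[[lon_column]])
  lat <- as.numeric(df[[lat_column]])
  bad <- which(is.na(lon) | is.na(lat))
  if (length(bad)) {
    stop("missing coordinates at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  }
  cbind(lon, lat)
}

# Subset a catalog by event index, keeping origin and window.
subset_catalog <- function(catalog, keep) {
  records <- catalog$records
  if (!is.null(records)) {
    records <- records[keep, , drop = FALSE]
    rownames(records) <- NULL
  }
  event_catalog(catalog$times[keep], catalog$origin, catalog$window_end,
                records = records)
}

#' Filter a catalog to a circular corridor window
#'
#' Keeps the events whose great-circle (haversine, spherical Earth of radius
#' 3958.8 miles) distance to \code{center} is at most \code{radius} miles.
#' The time axis, origin and observation window are unchanged, so fitted
#' rates remain per-day rates over the same window.
#'
#' @param catalog an \code{\link{event_catalog}} whose records carry
#'   longitude/latitude columns.
#' @param center numeric \code{c(lon, lat)} of the corridor window center.
#' @param radius inclusion radius in miles (the field's conventional spatial
#'   threshold for secondary-crash analysis is 2 miles).
#' @return The filtered \code{event_catalog}.
#' @export
filter_corridor <- function(catalog, center, radius = 2) {
  pts <- catalog_coords(catalog)
  d <- haversine_miles(pts, center)
  subset_catalog(catalog, which(d <= radius))
}

# Cumulative along-polyline distances (miles) for a lon/lat polyline matrix.
polyline_cumdist <- function(polyline) {
  n <- nrow(polyline)
  if (n < 2) stop("polyline needs at least two vertices")
  seg <- geosphere::distHaversine(polyline[-n, , drop = FALSE],
                                  polyline[-1, , drop = FALSE],
                                  r = EARTH_RADIUS_MILES)
  c(0, cumsum(seg))
}

# Interpolate the lon/lat point a given distance (miles) along a polyline.
point_along_polyline <- function(polyline, dist) {
  cum <- polyline_cumdist(polyline)
  total <- cum[length(cum)]
  if (dist < 0 || dist > total + 1e-9) {
    stop("distance ", dist, " outside polyline extent [0, ", round(total, 3), "]")
  }
  dist <- min(dist, total)
  i <- findInterval(dist, cum, rightmost.closed = TRUE)
  i <- min(i, length(cum) - 1)
  f <- (dist - cum[i]) / max(cum[i + 1] - cum[i], 1e-12)
  polyline[i, ] + f * (polyline[i + 1, ] - polyline[i, ])
}

#' Sliding corridor windows along a highway polyline
#'
#' Generates window centers every \code{step} miles along the corridor
#' polyline, from mile 0 to mile \code{extent}, and applies
#' \code{\link{filter_corridor}} with the stated radius at each center.
#' The default 0.25-mile step over a 20-mile extent yields 81 windows.
#'
#' @param catalog an \code{\link{event_catalog}} with coordinates.
#' @param polyline 2-column lon/lat matrix tracing the corridor centerline.
#' @param radius window radius in miles.
#' @param step distance between consecutive window centers in miles.
#' @param extent total distance covered by window centers in miles; defaults
#'   to the full polyline length. Must not exceed the polyline length.
#' @return A list of \code{event_catalog} windows, with the center offset in
#'   miles attached as attribute \code{"offset"}.
#' @export
sliding_windows <- function(catalog, polyline, radius = 2, step = 0.25,
                            extent = NULL) {
  if (step <= 0) stop("step must be positive")
  polyline <- as.matrix(polyline)
  total <- polyline_cumdist(polyline)[nrow(polyline)]
  if (is.null(extent)) extent <- total
  if (extent > total + 1e-9) {
    stop("extent (", extent, " mi) exceeds polyline length (",
         round(total, 3), " mi)")
  }
  offsets <- seq(0, extent, by = step)
  lapply(offsets, function(off) {
    center <- point_along_polyline(polyline, off)
    w <- filter_corridor(catalog, center, radius)
    attr(w, "offset") <- off
    w
  })
}
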