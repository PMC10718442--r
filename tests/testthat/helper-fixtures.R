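# Shared fixtures and independent oracles, all built in code at test time.

# Independent haversine implementation (oracle for the geosphere-backed
# distance in the package). Spherical Earth, 3958.8 miles.
oracle_haversine <- function(lon1, lat1, lon2, lat2, r = 3958.8) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# Longitude offset (degrees) east of (lon, lat) at which the haversine
# distance equals `miles`, found numerically against the oracle.
lon_offset_for_miles <- function(lon, lat, miles) {
  stats::uniroot(function(d) oracle_haversine(lon, lat, lon + d, lat) - miles,
                 c(1e-8, 5), tol = 1e-12)$root
}

# Write a data.frame as a fixture CSV and return the path.
fixture_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}

# A Monday-midnight origin shared by calendar-sensitive tests.
monday_origin <- function() as.POSIXct("2015-01-05 00:00:00", tz = "UTC")

# The stationary study-condition model used across recovery tests.
recovery_model <- function() {
  hawkes_model(stationary_background(0.4), triggering_params(0.25, 12))
}

# Dense O(N^2) triggering-probability oracle, independent of the package's
# pruned backward scan.
oracle_dense_pairs <- function(model, catalog) {
  times <- catalog$times
  n <- length(times)
  A <- model$trigger$A
  alpha <- model$trigger$alpha
  mu <- background_rate(model$background, times, catalog$origin)
  lam <- mu + vapply(seq_len(n), function(j) {
    if (j == 1) return(0)
    A * alpha * sum(exp(-alpha * (times[j] - times[seq_len(j - 1)])))
  }, numeric(1))
  out <- matrix(0, n, n)
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1)) {
      out[i, j] <- A * alpha * exp(-alpha * (times[j] - times[i])) / lam[j]
    }
  }
  out
}

# Background integral by segment-wise quadrature; cuts_extra carries any
# non-integer discontinuity/kink locations (step edges sit at integer-day
# or hour boundaries already covered; wrapped sinusoids kink where
# (t + offset) mod period = 0).
oracle_piecewise_integral <- function(spec, T, origin, cuts_extra = numeric(0)) {
  cuts <- sort(unique(c(seq(0, ceiling(T), by = 0.125), T, cuts_extra)))
  cuts <- cuts[cuts >= 0 & cuts <= T]
  if (cuts[length(cuts)] < T) cuts <- c(cuts, T)
  total <- 0
  for (k in seq_len(length(cuts) - 1)) {
    total <- total + stats::integrate(
      function(t) background_rate(spec, t, origin),
      cuts[k], cuts[k + 1], rel.tol = 1e-11, subdivisions = 400L)$value
  }
  total
}
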