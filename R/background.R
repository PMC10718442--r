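# Background-rate families for the self-exciting model. Each spec is an S3
# object; background_rate()/background_integral() evaluate mu(t) and its
# exact compensator contribution, and background_design() additionally
# returns the Jacobian of mu with respect to the free rate parameters (used
# by the analytic likelihood gradient).

DAY_NAMES <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
TOD_NAMES <- c("morning_rush", "non_rush", "evening_rush")

#' Stationary background rate
#'
#' @param mu constant background (primary-event) rate in events per day.
#' @return A \code{background_spec} of the stationary family.
#' @export
stationary_background <- function(mu) {
  stopifnot(is.numeric(mu), length(mu) == 1, mu > 0)
  structure(list(mu = mu), class = c("stationary_background", "background_spec"))
}

#' Piecewise-constant periodic background rate
#'
#' A step function over calendar bins: either one rate per day of the week
#' (7 rates, Monday first) or one rate per daily traffic period (morning
#' rush, non-rush, evening rush). Rush-hour edges default to 06:00-09:00 and
#' 16:00-19:00, matching the morning and evening crash-count peaks typical
#' of highway data, and are configurable.
#'
#' @param rates positive per-day rates; length 7 for \code{"day_of_week"},
#'   length 3 (morning rush, non-rush, evening rush) for \code{"time_of_day"}.
#' @param period the calendar period the steps tile.
#' @param morning,evening numeric \code{c(start, end)} hours of the two rush
#'   windows (time-of-day variant only).
#' @return A \code{background_spec} of the piecewise family.
#' @export
piecewise_background <- function(rates,
                                 period = c("day_of_week", "time_of_day"),
                                 morning = c(6, 9), evening = c(16, 19)) {
  period <- match.arg(period)
  rates <- as.numeric(rates)
  if (any(rates <= 0)) stop("all piecewise rates must be positive")
  k <- if (period == "day_of_week") 7L else 3L
  if (length(rates) != k) {
    stop("period '", period, "' needs ", k, " rates, got ", length(rates))
  }
  names(rates) <- if (period == "day_of_week") DAY_NAMES else TOD_NAMES
  if (period == "time_of_day") {
    stopifnot(morning[1] < morning[2], morning[2] <= evening[1],
              evening[1] < evening[2], morning[1] >= 0, evening[2] <= 24)
  }
  structure(list(rates = rates, period = period,
                 morning = morning, evening = evening),
            class = c("piecewise_background", "background_spec"))
}

#' Sinusoidal periodic background rate
#'
#' \deqn{\mu(t) = \mu_0 \{P \cdot wave(Q x + R) + S\}}
#' where \code{wave} is sine (weekly trend) or cosine (daily trend) and
#' \code{x} is the event time in days offset so that the phase is aligned
#' with the calendar (weekly: days since the Monday-midnight preceding the
#' origin; daily: time of day in days). \code{Q} defaults to one full cycle
#' per period. The constraint \code{S > |P|} keeps the rate positive.
#'
#' @param mu0 overall scale in events per day.
#' @param P dimensionless amplitude.
#' @param Q angular frequency in radians per day; default \code{2*pi/period}.
#' @param R phase in radians.
#' @param S dimensionless offset; must exceed \code{|P|}.
#' @param phase which calendar period the waveform tracks.
#' @param waveform sine or cosine; by convention the weekly trend uses sine
#'   and the daily trend cosine.
#' @return A \code{background_spec} of the sinusoidal family.
#' @export
sinusoidal_background <- function(mu0, P, Q = NULL, R = 0, S = 1,
                                  phase = c("weekly", "daily"),
                                  waveform = c("sin", "cos")) {
  phase <- match.arg(phase)
  waveform <- match.arg(waveform)
  period <- if (phase == "weekly") 7 else 1
  if (is.null(Q)) Q <- 2 * pi / period
  stopifnot(mu0 > 0, Q > 0)
  if (S <= abs(P)) stop("S must exceed |P| so mu(t) stays positive")
  structure(list(mu0 = mu0, P = P, Q = Q, R = R, S = S,
                 phase = phase, waveform = waveform, period = period),
            class = c("sinusoidal_background", "background_spec"))
}

# Day axis offsets relative to the calendar. frac0 is the origin's time of
# day in days (0 for a midnight origin); dow0 the 0-based weekday (Mon = 0).
origin_frac <- function(origin) {
  as.numeric(difftime(origin, trunc(origin, units = "days"), units = "days"))
}
origin_weekday <- function(origin) {
  as.integer(format(origin, "%u")) - 1L
}

# Phase position used by the sinusoid: the calendar position within the
# period (weekly: days since Monday midnight, in [0, 7); daily: time of day
# in [0, 1)). Wrapping keeps the background exactly periodic even when the
# fitted Q is not exactly 2*pi/period, so small shape-fit errors cannot
# accumulate into phase drift over long windows.
sin_phase_offset <- function(spec, origin) {
  origin_frac(origin) + if (spec$phase == "weekly") origin_weekday(origin) else 0
}
sin_phase_x <- function(spec, t, origin) {
  (t + sin_phase_offset(spec, origin)) %% spec$period
}

wave_fun <- function(spec) if (spec$waveform == "sin") sin else cos

# -- background_rate -----------------------------------------------------

#' Evaluate the background rate
#'
#' @param spec a \code{background_spec}.
#' @param t event time(s) in days on the catalog axis.
#' @param origin catalog origin (\code{POSIXct}); anchors calendar bins and
#'   sinusoid phase.
#' @return mu(t) in events per day, vectorized over \code{t}.
#' @export
background_rate <- function(spec, t, origin) UseMethod("background_rate")

#' @export
background_rate.stationary_background <- function(spec, t, origin) {
  rep(spec$mu, length(t))
}

# 1-based bin index of each time for a piecewise spec.
piecewise_bin <- function(spec, t, origin) {
  frac0 <- origin_frac(origin)
  if (spec$period == "day_of_week") {
    ((origin_weekday(origin) + floor(t + frac0)) %% 7) + 1L
  } else {
    h <- 24 * ((t + frac0) %% 1)
    ifelse(h >= spec$morning[1] & h < spec$morning[2], 1L,
           ifelse(h >= spec$evening[1] & h < spec$evening[2], 3L, 2L))
  }
}

#' @export
background_rate.piecewise_background <- function(spec, t, origin) {
  unname(spec$rates[piecewise_bin(spec, t, origin)])
}

#' @export
background_rate.sinusoidal_background <- function(spec, t, origin) {
  x <- sin_phase_x(spec, t, origin)
  spec$mu0 * (spec$P * wave_fun(spec)(spec$Q * x + spec$R) + spec$S)
}

# -- exact integral over [0, T] ------------------------------------------

#' Integrated background rate over the observation window
#'
#' Closed-form \eqn{\int_0^T \mu(t) dt} for every family: \code{mu*T}
#' (stationary), sum of rate times bin occupancy (piecewise), and the exact
#' sinusoid antiderivative.
#'
#' @inheritParams background_rate
#' @param T window length in days.
#' @return The integral (expected number of background events in \code{[0,T]}).
#' @export
background_integral <- function(spec, T, origin) UseMethod("background_integral")

#' @export
background_integral.stationary_background <- function(spec, T, origin) {
  spec$mu * T
}

# Total time (days) spent in each piecewise bin over [0, T].
piecewise_durations <- function(spec, T, origin) {
  frac0 <- origin_frac(origin)
  if (spec$period == "day_of_week") {
    # calendar days m (day index relative to origin's midnight) overlapping [0, T]
    m <- floor(-frac0 + 0):floor(T + frac0)
    lo <- pmax(m - frac0, 0)
    hi <- pmin(m + 1 - frac0, T)
    len <- pmax(hi - lo, 0)
    wd <- ((origin_weekday(origin) + m) %% 7) + 1L
    out <- vapply(1:7, function(k) sum(len[wd == k]), numeric(1))
  } else {
    edges <- c(0, spec$morning, spec$evening, 24) / 24
    segbin <- c(2L, 1L, 2L, 3L, 2L)           # non, morning, non, evening, non
    m <- floor(-frac0 + 0):floor(T + frac0)
    out <- numeric(3)
    for (s in seq_along(segbin)) {
      a <- edges[s]; b <- edges[s + 1]
      if (b <= a) next
      lo <- pmax(m + a - frac0, 0)
      hi <- pmin(m + b - frac0, T)
      out[segbin[s]] <- out[segbin[s]] + sum(pmax(hi - lo, 0))
    }
  }
  names(out) <- names(spec$rates)
  out
}

#' @export
background_integral.piecewise_background <- function(spec, T, origin) {
  sum(spec$rates * piecewise_durations(spec, T, origin))
}

# Antiderivative of the dimensionless shape P*wave(Q x + R) + S on the
# unwrapped phase coordinate.
sin_shape_antideriv <- function(spec, u) {
  osc <- if (spec$waveform == "sin") {
    -(spec$P / spec$Q) * cos(spec$Q * u + spec$R)
  } else {
    (spec$P / spec$Q) * sin(spec$Q * u + spec$R)
  }
  osc + spec$S * u
}

#' @export
background_integral.sinusoidal_background <- function(spec, T, origin) {
  # integral of the wrapped shape: whole periods plus partial-period tails,
  # each via the exact antiderivative
  per <- spec$period
  H <- function(u) {
    k <- floor(u / per)
    per_int <- sin_shape_antideriv(spec, per) - sin_shape_antideriv(spec, 0)
    k * per_int + sin_shape_antideriv(spec, u - k * per) -
      sin_shape_antideriv(spec, 0)
  }
  off <- sin_phase_offset(spec, origin)
  spec$mu0 * (H(off + T) - H(off))
}

# -- upper bound on mu(t), used by the thinning simulator ----------------

background_max <- function(spec) UseMethod("background_max")
#' @export
background_max.stationary_background <- function(spec) spec$mu
#' @export
background_max.piecewise_background <- function(spec) max(spec$rates)
#' @export
background_max.sinusoidal_background <- function(spec) {
  spec$mu0 * (abs(spec$P) + spec$S)
}

# -- free parameters and design info for the MLE -------------------------

# Free rate parameters of the family (the sinusoid's shape P,Q,R,S is fixed
# by the histogram fit, only mu0 is free).
background_params <- function(spec) UseMethod("background_params")
#' @export
background_params.stationary_background <- function(spec) c(mu = spec$mu)
#' @export
background_params.piecewise_background <- function(spec) spec$rates
#' @export
background_params.sinusoidal_background <- function(spec) c(mu0 = spec$mu0)

# Return the spec with its free parameters replaced.
background_with_params <- function(spec, p) UseMethod("background_with_params")
#' @export
background_with_params.stationary_background <- function(spec, p) {
  spec$mu <- unname(p[1]); spec
}
#' @export
background_with_params.piecewise_background <- function(spec, p) {
  spec$rates[] <- unname(p); spec
}
#' @export
background_with_params.sinusoidal_background <- function(spec, p) {
  spec$mu0 <- unname(p[1]); spec
}

# values: mu(t_i); integral: int_0^T mu; jac_values: d mu(t_i) / d theta_k
# (N x K); jac_integral: d integral / d theta_k. Everything the analytic
# gradient needs in one pass.
background_design <- function(spec, times, T, origin) {
  UseMethod("background_design")
}
#' @export
background_design.stationary_background <- function(spec, times, T, origin) {
  n <- length(times)
  list(values = rep(spec$mu, n), integral = spec$mu * T,
       jac_values = matrix(1, n, 1), jac_integral = T)
}
#' @export
background_design.piecewise_background <- function(spec, times, T, origin) {
  bins <- piecewise_bin(spec, times, origin)
  k <- length(spec$rates)
  jac <- matrix(0, length(times), k)
  jac[cbind(seq_along(times), bins)] <- 1
  dur <- piecewise_durations(spec, T, origin)
  list(values = unname(spec$rates[bins]), integral = sum(spec$rates * dur),
       jac_values = jac, jac_integral = unname(dur))
}
#' @export
background_design.sinusoidal_background <- function(spec, times, T, origin) {
  x <- sin_phase_x(spec, times, origin)
  shape <- spec$P * wave_fun(spec)(spec$Q * x + spec$R) + spec$S
  integ <- background_integral(spec, T, origin)
  list(values = spec$mu0 * shape, integral = integ,
       jac_values = matrix(shape, ncol = 1), jac_integral = integ / spec$mu0)
}

#' @export
print.background_spec <- function(x, ...) {
  fam <- class(x)[1]
  if (fam == "stationary_background") {
    cat(sprintf("<background: stationary> mu = %.4g /day\n", x$mu))
  } else if (fam == "piecewise_background") {
    cat(sprintf("<background: piecewise %s>\n", x$period))
    print(round(x$rates, 4))
  } else {
    cat(sprintf(
      "<background: sinusoidal %s %s> mu0 = %.4g, P = %.4g, Q = %.4g, R = %.4g, S = %.4g\n",
      x$phase, x$waveform, x$mu0, x$P, x$Q, x$R, x$S))
  }
  invisible(x)
}
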