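# Exact simulators for the self-exciting model: Ogata thinning and the
# cluster (branching) construction. Both return ground-truth parent links,
# which every declustering validation in the package relies on.

# Monday midnight; keeps simulated catalogs aligned with calendar bins.
DEFAULT_SIM_ORIGIN <- "2015-01-05 00:00:00"

new_synthetic_catalog <- function(times, parent, generation, origin, T, seed) {
  ord <- order(times)
  times <- times[ord]
  parent <- parent[ord]
  generation <- generation[ord]
  # remap parent pointers (given in pre-sort indexing) to sorted positions
  pos <- integer(length(ord)); pos[ord] <- seq_along(ord)
  parent <- ifelse(parent < 0, -1L, pos[pmax(parent, 1L)])
  parent[parent == 0] <- -1L
  structure(list(
    catalog = event_catalog(times, origin, T),
    parent = as.integer(parent), generation = as.integer(generation),
    seed = seed
  ), class = "synthetic_catalog")
}

#' @export
print.synthetic_catalog <- function(x, ...) {
  n <- x$catalog$n
  cat(sprintf("<synthetic_catalog> %d events (%d background, %d triggered), seed %d\n",
              n, sum(x$parent == -1L), sum(x$parent != -1L), x$seed))
  print(x$catalog)
  invisible(x)
}

check_subcritical <- function(model, allow_supercritical) {
  if (model$trigger$A >= 1 && !allow_supercritical) {
    stop("A >= 1 is supercritical (explosion risk); ",
         "pass allow_supercritical = TRUE to override")
  }
}

# Sample background (generation-0) events on [0, T] by thinning a
# homogeneous proposal at the analytic background maximum.
sample_background <- function(background, T, origin) {
  bmax <- background_max(background)
  n_prop <- stats::rpois(1, bmax * T)
  if (n_prop == 0) return(numeric(0))
  tt <- sort(stats::runif(n_prop, 0, T))
  keep <- stats::runif(n_prop) * bmax <= background_rate(background, tt, origin)
  tt[keep]
}

#' Simulate a catalog by the cluster (branching) construction
#'
#' Background events arrive as an inhomogeneous Poisson process with rate
#' \eqn{\mu(t)}; every event independently spawns
#' \eqn{Poisson(A)} direct offspring at exponential \eqn{Exp(\alpha)} delays,
#' recursively, with offspring beyond \eqn{T} discarded. Distributionally
#' equivalent to \code{\link{simulate_thinning}} and used as its independent
#' cross-check.
#'
#' @param model a \code{\link{hawkes_model}} with \code{A < 1} (subcritical).
#' @param T window length in days.
#' @param seed RNG seed; identical seeds give identical catalogs. The
#'   caller's RNG stream is left untouched.
#' @param origin calendar origin of the day axis (default: a Monday
#'   midnight).
#' @param allow_supercritical permit \code{A >= 1} (normally an error).
#' @return A \code{synthetic_catalog}: the \code{\link{event_catalog}}, the
#'   ground-truth \code{parent} index per event (\code{-1} for background),
#'   the branching \code{generation} (0 for background), and the seed.
#' @export
simulate_branching <- function(model, T, seed,
                               origin = DEFAULT_SIM_ORIGIN,
                               allow_supercritical = FALSE) {
  check_subcritical(model, allow_supercritical)
  origin <- as.POSIXct(origin, tz = "UTC")
  A <- model$trigger$A
  alpha <- model$trigger$alpha
  with_seed(seed, {
    bg <- sample_background(model$background, T, origin)
    times <- bg
    parent <- rep(-1L, length(bg))
    generation <- rep(0L, length(bg))
    frontier <- seq_along(bg)   # indices whose offspring are still unsampled
    while (length(frontier)) {
      next_frontier <- integer(0)
      for (idx in frontier) {
        n_off <- stats::rpois(1, A)
        if (n_off == 0) next
        delays <- stats::rexp(n_off, alpha)
        tt <- times[idx] + delays
        tt <- tt[tt <= T]
        if (!length(tt)) next
        new_idx <- length(times) + seq_along(tt)
        times <- c(times, tt)
        parent <- c(parent, rep(idx, length(tt)))
        generation <- c(generation, rep(generation[idx] + 1L, length(tt)))
        next_frontier <- c(next_frontier, new_idx)
      }
      frontier <- next_frontier
    }
    new_synthetic_catalog(times, parent, generation, origin, T, seed)
  })
}

#' Simulate a catalog by Ogata thinning
#'
#' Exact sampling of the point process with intensity
#' \eqn{\lambda(t) = \mu(t) + A\sum_{t_i<t}\alpha e^{-\alpha(t-t_i)}}:
#' candidate times are proposed from an upper bound (analytic background
#' maximum plus the excitation evaluated just after the current time, which
#' is nonincreasing until the next event) and accepted with probability
#' \eqn{\lambda/bound}. Each accepted event is attributed to a parent by
#' sampling the intensity components proportionally: the background term
#' yields a primary event (\code{parent = -1}), each prior event's kernel
#' term yields a triggered event.
#'
#' @inheritParams simulate_branching
#' @return A \code{synthetic_catalog} (see \code{\link{simulate_branching}}).
#' @export
simulate_thinning <- function(model, T, seed,
                              origin = DEFAULT_SIM_ORIGIN,
                              allow_supercritical = FALSE) {
  check_subcritical(model, allow_supercritical)
  origin <- as.POSIXct(origin, tz = "UTC")
  A <- model$trigger$A
  alpha <- model$trigger$alpha
  bmax <- background_max(model$background)
  with_seed(seed, {
    times <- numeric(0)
    parent <- integer(0)
    generation <- integer(0)
    t <- 0
    excite <- 0  # sum over prior events of exp(-alpha (t - t_i))
    repeat {
      bound <- bmax + A * alpha * excite
      t_new <- t + stats::rexp(1, bound)
      if (t_new > T) break
      decay <- exp(-alpha * (t_new - t))
      excite_new <- excite * decay
      mu_t <- background_rate(model$background, t_new, origin)
      lam <- mu_t + A * alpha * excite_new
      if (stats::runif(1) * bound <= lam) {
        # parent attribution proportional to intensity components
        if (length(times) == 0 || stats::runif(1) * lam <= mu_t) {
          par_idx <- -1L; gen <- 0L
        } else {
          wts <- exp(-alpha * (t_new - times))
          par_idx <- sample.int(length(times), 1, prob = wts)
          gen <- generation[par_idx] + 1L
        }
        times <- c(times, t_new)
        parent <- c(parent, par_idx)
        generation <- c(generation, gen)
        excite <- excite_new + 1
      } else {
        excite <- excite_new
      }
      t <- t_new
    }
    new_synthetic_catalog(times, parent, generation, origin, T, seed)
  })
}

#' Write a synthetic catalog as an FDOT-style CSV export
#'
#' Emulates the shape of a state-DOT crash export: one row per event with
#' \code{crash_date} (\code{MM/DD/YYYY}), \code{crash_time} (\code{HH:MM},
#' truncated to the minute), \code{longitude}, \code{latitude} and a
#' decorative \code{weather} column. Events are placed along the supplied
#' corridor polyline: background events uniformly, triggered events within
#' 2 miles of their parent (geography is I/O realism only; the model is
#' temporal). A \code{parent} column carries the ground-truth link
#' (\code{-1} = background) so the file round-trips into a labeled catalog.
#'
#' @param syn a \code{synthetic_catalog}.
#' @param path output CSV path.
#' @param corridor 2-column lon/lat polyline matrix.
#' @param seed seed for the spatial placement.
#' @return \code{path}, invisibly.
#' @export
write_fdot_like_csv <- function(syn, path, corridor, seed = syn$seed) {
  corridor <- as.matrix(corridor)
  total <- polyline_cumdist(corridor)[nrow(corridor)]
  cat <- syn$catalog
  n <- cat$n
  with_seed(seed + 104729L, {
    mile <- numeric(n)
    for (i in seq_len(n)) {
      if (syn$parent[i] == -1L) {
        mile[i] <- stats::runif(1, 0, total)
      } else {
        off <- stats::rnorm(1, 0, 0.5)
        off <- max(min(off, 1.9), -1.9)   # keep children within 2 mi of parent
        mile[i] <- min(max(mile[syn$parent[i]] + off, 0), total)
      }
    }
    pts <- t(vapply(mile, function(m) point_along_polyline(corridor, m),
                    numeric(2)))
    weather <- sample(c("clear", "cloudy", "rain"), n, replace = TRUE,
                      prob = c(0.6, 0.25, 0.15))
    ts <- cat$origin + round(cat$times * 86400)
    ts <- trunc(ts, units = "mins")
    df <- data.frame(
      crash_date = format(ts, "%m/%d/%Y", tz = "UTC"),
      crash_time = format(ts, "%H:%M", tz = "UTC"),
      longitude = round(pts[, 1], 6),
      latitude = round(pts[, 2], 6),
      weather = weather,
      parent = syn$parent
    )
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  })
  invisible(path)
}
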