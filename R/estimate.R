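# Maximum-likelihood fitting of the Hawkes model, least-squares fitting of
# the periodic background shape from crash-count histograms, and AIC model
# comparison.

FAMILIES <- c("stationary", "piecewise-weekly", "piecewise-daily",
              "sinusoidal-weekly", "sinusoidal-daily")

# Run code with a temporarily-seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Optimizer configuration for \code{\link{fit_mle}}
#'
#' @param max_iter maximum quasi-Newton iterations.
#' @param grad_tol gradient-norm threshold (log-parameter space) below which
#'   a successful optimizer exit is flagged as converged.
#' @param n_restarts number of additional seeded random restarts around the
#'   default initialization, guarding against local optima.
#' @param min_events smallest catalog the fitter accepts.
#' @param param_scale optimize logarithms of the parameters (default;
#'   enforces positivity) or the natural parameters under box constraints.
#' @param alpha_min lower bound on the decay rate (per day). As
#'   \code{alpha} approaches zero the excitation timescale exceeds the
#'   observation window and the kernel becomes indistinguishable from extra
#'   background, creating a flat likelihood ridge along which \code{A} is
#'   unidentified; a floor well below any plausible triggering rate (the
#'   default caps queue times at 10 days) removes it. Set to 0 to disable.
#' @param seed seed for the restart jitter.
#' @export
fit_options <- function(max_iter = 500, grad_tol = 1e-3, n_restarts = 3,
                        min_events = 10, param_scale = c("log", "natural"),
                        alpha_min = 0.1, seed = 1) {
  list(max_iter = max_iter, grad_tol = grad_tol, n_restarts = n_restarts,
       min_events = min_events, param_scale = match.arg(param_scale),
       alpha_min = alpha_min, seed = seed)
}

#' Weekday or hour-of-day crash-count histogram
#'
#' Tabulates catalog events into the calendar bins used to estimate the
#' periodic background shape (weekday bins for the weekly trend, hourly bins
#' for the daily trend).
#'
#' @param catalog an \code{\link{event_catalog}}.
#' @param by weekday (7 bins, Monday first) or hour (24 bins).
#' @return A \code{histogram_data} object: bin labels, counts, bin-center
#'   positions \code{x} in days, and the period length in days.
#' @export
crash_histogram <- function(catalog, by = c("weekday", "hour")) {
  by <- match.arg(by)
  t <- catalog$times
  frac0 <- origin_frac(catalog$origin)
  if (by == "weekday") {
    bin <- ((origin_weekday(catalog$origin) + floor(t + frac0)) %% 7) + 1L
    counts <- tabulate(bin, nbins = 7)
    histogram_data(counts, period = "weekly", labels = DAY_NAMES)
  } else {
    bin <- floor(24 * ((t + frac0) %% 1)) + 1L
    counts <- tabulate(bin, nbins = 24)
    histogram_data(counts, period = "daily", labels = sprintf("%02d", 0:23))
  }
}

#' Construct histogram data directly from counts
#'
#' @param counts nonnegative event counts, one per bin; bins are assumed to
#'   tile the period uniformly.
#' @param period the calendar period the bins tile.
#' @param labels optional bin labels.
#' @export
histogram_data <- function(counts, period = c("weekly", "daily"),
                           labels = NULL) {
  period <- match.arg(period)
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (length(counts) < 4) stop("need at least 4 bins")
  plen <- if (period == "weekly") 7 else 1
  x <- (seq_along(counts) - 0.5) * plen / length(counts)
  if (is.null(labels)) labels <- as.character(seq_along(counts))
  structure(list(bin_labels = labels, counts = counts, x = x,
                 period = period, period_days = plen),
            class = "histogram_data")
}

#' Fit the sinusoidal background shape to a histogram
#'
#' Least-squares fit of \eqn{P \cdot wave(Q x + R) + S} to bin counts
#' normalized by their mean (the overall level is absorbed into \eqn{\mu_0}
#' during the subsequent MLE). Multiple phase starts guard against the local
#' optima of the phase parameter.
#'
#' @param hist a \code{\link{histogram_data}} object.
#' @param waveform sine (weekly convention) or cosine (daily convention).
#' @return A list with shape parameters \code{P, Q, R, S} (satisfying
#'   \code{S > |P|}), the residual sum of squares \code{sse}, and a
#'   \code{flat} flag set when the histogram carries no periodic signal
#'   (in which case \code{P = 0, S = 1} and \code{Q, R} are fixed defaults).
#' @export
fit_background_shape <- function(hist, waveform = c("sin", "cos")) {
  waveform <- match.arg(waveform)
  y <- hist$counts / mean(hist$counts)
  x <- hist$x
  q0 <- 2 * pi / hist$period_days
  if (stats::sd(y) < 1e-10) {
    return(list(P = 0, Q = q0, R = 0, S = 1, sse = 0, flat = TRUE,
                waveform = waveform))
  }
  wave <- if (waveform == "sin") sin else cos
  # Parameterized as S = P + D with P >= 0 and D > 0 so the positivity
  # constraint S > |P| holds throughout the search, and Q bounded to half
  # through four cycles per period (frequencies outside that band are
  # sampling artifacts on a one-period histogram).
  best <- NULL
  p_start <- min((max(y) - min(y)) / 2, 0.9 * mean(y))
  for (r0 in seq(0, 2 * pi, length.out = 9)[-9]) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ P * wave(Q * x + R) + P + D,
        start = list(P = p_start, Q = q0, R = r0,
                     D = max(mean(y) - p_start, 0.05)),
        lower = c(P = 0, Q = q0 / 2, R = -2 * pi, D = 1e-6),
        upper = c(P = Inf, Q = 4 * q0, R = 2 * pi, D = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                             ptol = 1e-14)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      p <- as.list(stats::coef(fit))
      best <- list(P = p$P, Q = p$Q, R = p$R %% (2 * pi), S = p$P + p$D,
                   sse = sse, flat = FALSE, waveform = waveform)
    }
  }
  if (is.null(best)) stop("sinusoid shape fit failed on all phase starts")
  best
}

# Build the background spec template for a family string, estimating the
# sinusoid shape from the catalog itself when not supplied.
family_template <- function(catalog, family, mu_init, shape = NULL) {
  switch(family,
    "stationary" = stationary_background(mu_init),
    "piecewise-weekly" = piecewise_background(rep(mu_init, 7)),
    "piecewise-daily" = piecewise_background(rep(mu_init, 3),
                                             period = "time_of_day"),
    "sinusoidal-weekly" = ,
    "sinusoidal-daily" = {
      weekly <- family == "sinusoidal-weekly"
      if (is.null(shape)) {
        h <- crash_histogram(catalog, by = if (weekly) "weekday" else "hour")
        shape <- fit_background_shape(h, waveform = if (weekly) "sin" else "cos")
      }
      sinusoidal_background(mu_init / max(shape$S, 1e-8), P = shape$P,
                            Q = shape$Q, R = shape$R, S = shape$S,
                            phase = if (weekly) "weekly" else "daily",
                            waveform = shape$waveform)
    },
    stop("unknown family: ", family)
  )
}

# Assemble the model for a natural-scale parameter vector (bg..., A, alpha).
assemble_model <- function(template, theta) {
  k <- length(background_params(template))
  bg <- background_with_params(template, theta[seq_len(k)])
  hawkes_model(bg, suppressWarnings(
    triggering_params(theta[k + 1], theta[k + 2])))
}

#' Maximum-likelihood fit of a Hawkes model
#'
#' Maximizes the exact log-likelihood over the positive orthant with a
#' quasi-Newton (BFGS) search on the logarithms of the parameters, using
#' analytic gradients. Free parameters: \code{(mu, A, alpha)} for the
#' stationary family, \code{(mu_1..mu_K, A, alpha)} for piecewise, and
#' \code{(mu0, A, alpha)} for sinusoidal, whose shape \code{(P, Q, R, S)} is
#' estimated from the catalog's crash-count histogram first and held fixed
#' (two-stage fit).
#'
#' @param catalog an \code{\link{event_catalog}} with at least
#'   \code{options$min_events} events.
#' @param family background family, one of \code{"stationary"},
#'   \code{"piecewise-weekly"}, \code{"piecewise-daily"},
#'   \code{"sinusoidal-weekly"}, \code{"sinusoidal-daily"}.
#' @param shape optional pre-fitted sinusoid shape (list with P, Q, R, S) as
#'   returned by \code{\link{fit_background_shape}}.
#' @param options optimizer configuration from \code{\link{fit_options}}.
#' @return A \code{fit_result}: the fitted \code{\link{hawkes_model}},
#'   \code{loglik}, \code{n_params} (free MLE parameters), \code{aic},
#'   \code{converged}, \code{n_iter}, \code{gradient_norm}, plus bookkeeping
#'   (\code{family}, \code{n_events}, \code{window_end}).
#' @export
fit_mle <- function(catalog, family = "stationary", shape = NULL,
                    options = fit_options()) {
  family <- match.arg(family, FAMILIES)
  n <- catalog$n
  if (n < options$min_events) {
    stop("catalog too small: ", n, " events < floor of ", options$min_events)
  }
  T <- catalog$window_end
  mu_init <- 0.5 * n / T
  template <- family_template(catalog, family, mu_init, shape)
  k_bg <- length(background_params(template))
  amin <- options$alpha_min
  init <- c(background_params(template), A = 0.5,
            alpha = max(10, 2 * amin))

  # log-space coordinates; alpha is offset by its floor so the bound stays
  # smooth: theta = (exp(p_bg), exp(p_A), amin + exp(p_alpha))
  ia <- k_bg + 2L
  from_par <- function(p) {
    p <- pmin(pmax(p, -30), 30)
    theta <- exp(p)
    theta[ia] <- amin + theta[ia]
    theta
  }
  to_par <- function(theta) {
    p <- theta
    p[ia] <- theta[ia] - amin
    log(pmax(p, 1e-12))
  }
  chain <- function(theta) {
    d <- theta
    d[ia] <- theta[ia] - amin
    d
  }
  neg_fn_log <- function(p) {
    v <- log_likelihood(assemble_model(template, from_par(p)), catalog)
    if (!is.finite(v)) 1e10 else -v
  }
  neg_gr_log <- function(p) {
    theta <- from_par(p)
    lg <- loglik_with_grad(assemble_model(template, theta), catalog)
    if (!all(is.finite(lg$grad))) return(rep(0, length(p)))
    -(lg$grad * chain(theta))
  }
  neg_fn_nat <- function(theta) {
    v <- log_likelihood(assemble_model(template, theta), catalog)
    if (!is.finite(v)) 1e10 else -v
  }
  neg_gr_nat <- function(theta) {
    lg <- loglik_with_grad(assemble_model(template, theta), catalog)
    if (!all(is.finite(lg$grad))) return(rep(0, length(theta)))
    -lg$grad
  }

  starts <- list(init)
  if (options$n_restarts > 0) {
    for (r in seq_len(options$n_restarts)) {
      jit <- with_seed(options$seed + r,
                       stats::runif(length(init), -1, 1))
      starts[[r + 1]] <- init * exp(jit)
    }
  }

  best <- NULL
  for (st in starts) {
    st[ia] <- max(st[ia], amin * 1.5 + 1e-8)
    opt <- tryCatch({
      if (options$param_scale == "log") {
        stats::optim(to_par(st), neg_fn_log, neg_gr_log, method = "BFGS",
                     control = list(maxit = options$max_iter,
                                    reltol = 1e-12))
      } else {
        lower <- rep(1e-10, length(st))
        lower[ia] <- max(amin, 1e-10)
        stats::optim(st, neg_fn_nat, neg_gr_nat, method = "L-BFGS-B",
                     lower = lower,
                     control = list(maxit = options$max_iter,
                                    factr = 1e4))
      }
    }, error = function(e) NULL)
    if (is.null(opt)) next
    # strict improvement beyond numerical noise, so ties keep the first
    # (default-initialized) solution
    if (is.null(best) || opt$value < best$value - 1e-9) best <- opt
  }
  if (is.null(best)) stop("optimization failed for family ", family)

  theta_hat <- if (options$param_scale == "log") from_par(best$par)
               else best$par
  model <- assemble_model(template, theta_hat)
  lg <- loglik_with_grad(model, catalog)
  gnorm <- sqrt(sum((lg$grad * chain(theta_hat))^2))  # log-scale grad norm
  k <- k_bg + 2
  loglik <- lg$value
  structure(list(
    model = model, loglik = loglik, n_params = k, aic = 2 * k - 2 * loglik,
    converged = best$convergence == 0 && is.finite(gnorm) &&
      gnorm < options$grad_tol,
    n_iter = unname(best$counts[1]), gradient_norm = gnorm,
    family = family, n_events = n, window_end = T, origin = catalog$origin
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: %s> N = %d, T = %.1f days\n",
              x$family, x$n_events, x$window_end))
  print(x$model)
  cat(sprintf("  loglik = %.3f, k = %d, AIC = %.2f, converged = %s (|grad| = %.2g, %d evals)\n",
              x$loglik, x$n_params, x$aic, x$converged, x$gradient_norm,
              x$n_iter))
  invisible(x)
}

#' Fit several background families and rank them by AIC
#'
#' Fits each requested family by \code{\link{fit_mle}} and tabulates
#' \eqn{AIC = 2k - 2\ell}. Lower AIC indicates the better fit; ties are
#' broken in favor of fewer parameters (parsimony). Families whose fit
#' errors out are reported with \code{NA} entries rather than aborting the
#' comparison.
#'
#' @param catalog an \code{\link{event_catalog}}.
#' @param families character vector of at least two family names.
#' @param options optimizer configuration shared by all fits.
#' @return A \code{model_comparison}: \code{table} (data.frame sorted
#'   ascending by AIC with columns family, k, loglik, aic, converged) and
#'   \code{fits} (named list of \code{fit_result}s).
#' @export
compare_models <- function(catalog,
                           families = c("stationary", "piecewise-weekly",
                                        "sinusoidal-weekly"),
                           options = fit_options()) {
  if (length(families) < 2) stop("need at least two families to compare")
  fits <- lapply(families, function(f) {
    tryCatch(fit_mle(catalog, family = f, options = options),
             error = function(e) e)
  })
  names(fits) <- families
  rows <- lapply(families, function(f) {
    ft <- fits[[f]]
    if (inherits(ft, "error")) {
      data.frame(family = f, k = NA_integer_, loglik = NA_real_,
                 aic = NA_real_, converged = NA,
                 error = conditionMessage(ft), stringsAsFactors = FALSE)
    } else {
      data.frame(family = f, k = ft$n_params, loglik = ft$loglik,
                 aic = ft$aic, converged = ft$converged, error = "",
                 stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$aic, tab$k, na.last = TRUE), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> (ascending AIC)\n")
  print(x$table, digits = 6)
  invisible(x)
}
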