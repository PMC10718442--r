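# Hawkes model: background spec + exponential triggering kernel
# g(s) = A * alpha * exp(-alpha s), s > 0. A is the branching ratio (expected
# triggered offspring per event), alpha the decay rate per day; 1/alpha is
# the mean parent-to-offspring delay and 1440/alpha the queue time in minutes.

#' Triggering-kernel parameters
#'
#' @param A excitation per parent event (dimensionless branching ratio,
#'   the expected number of directly triggered offspring). \code{A >= 1}
#'   makes the process supercritical and triggers a warning.
#' @param alpha exponential decay rate of the excitation, per day.
#' @return A \code{triggering_params} object.
#' @export
triggering_params <- function(A, alpha) {
  stopifnot(A >= 0, alpha > 0)
  if (A >= 1) warning("A >= 1: the process is non-stationary (supercritical)")
  structure(list(A = A, alpha = alpha), class = "triggering_params")
}

#' Assemble a Hawkes model
#'
#' @param background a \code{background_spec} (see
#'   \code{\link{stationary_background}}, \code{\link{piecewise_background}},
#'   \code{\link{sinusoidal_background}}).
#' @param trigger a \code{\link{triggering_params}} object.
#' @return A \code{hawkes_model}.
#' @export
hawkes_model <- function(background, trigger) {
  stopifnot(inherits(background, "background_spec"),
            inherits(trigger, "triggering_params"))
  structure(list(background = background, trigger = trigger),
            class = "hawkes_model")
}

#' @export
print.hawkes_model <- function(x, ...) {
  cat("<hawkes_model>\n  ")
  print(x$background)
  cat(sprintf("  trigger: A = %.4g, alpha = %.4g /day (queue time %.1f min)\n",
              x$trigger$A, x$trigger$alpha, 1440 / x$trigger$alpha))
  invisible(x)
}

# O(N) recursions for the exponential kernel over strictly increasing times:
#   B_i = sum_{j<i} exp(-alpha (t_i - t_j))
#   C_i = sum_{j<i} (t_i - t_j) exp(-alpha (t_i - t_j))  (for d/dalpha)
# B_i = e^{-a d}(B_{i-1} + 1),  C_i = e^{-a d}(C_{i-1} + d (B_{i-1} + 1)).
hawkes_recursions <- function(times, alpha, with_deriv = FALSE) {
  n <- length(times)
  B <- numeric(n)
  C <- if (with_deriv) numeric(n) else NULL
  if (n >= 2) {
    for (i in 2:n) {
      d <- times[i] - times[i - 1]
      e <- exp(-alpha * d)
      B[i] <- e * (B[i - 1] + 1)
      if (with_deriv) C[i] <- e * (C[i - 1] + d * (B[i - 1] + 1))
    }
  }
  list(B = B, C = C)
}

#' Conditional intensity at arbitrary times
#'
#' Evaluates \eqn{\lambda(t) = \mu(t) + A \sum_{t_i < t} \alpha
#' e^{-\alpha (t - t_i)}} given the catalog history.
#'
#' @param model a \code{\link{hawkes_model}}.
#' @param catalog an \code{\link{event_catalog}} supplying the history.
#' @param t evaluation time(s) in days; events at exactly \code{t} do not
#'   contribute (the sum is over strictly earlier events).
#' @return Intensity in events per day, vectorized over \code{t}.
#' @export
intensity_at <- function(model, catalog, t) {
  A <- model$trigger$A
  alpha <- model$trigger$alpha
  mu <- background_rate(model$background, t, catalog$origin)
  exc <- vapply(t, function(tt) {
    prior <- catalog$times[catalog$times < tt]
    if (!length(prior)) return(0)
    sum(exp(-alpha * (tt - prior)))
  }, numeric(1))
  mu + A * alpha * exc
}

#' Exact log-likelihood of a Hawkes model on a catalog
#'
#' \deqn{\ell = \sum_i \log\lambda(t_i) - \int_0^T \mu(t)\,dt
#'       - A \sum_i (1 - e^{-\alpha (T - t_i)})}
#' The background integral is closed-form for all three families and the
#' event sum uses the standard O(N) exponential-kernel recursion;
#' \code{method = "direct"} evaluates the O(N^2) double sum instead and is
#' kept as a cross-check oracle.
#'
#' @param model a \code{\link{hawkes_model}}.
#' @param catalog an \code{\link{event_catalog}} (may be empty, in which case
#'   the log-likelihood is minus the background integral).
#' @param method recursion (default) or direct double-sum evaluation.
#' @return The log-likelihood; \code{-Inf} if any \eqn{\lambda(t_i) \le 0}.
#' @export
log_likelihood <- function(model, catalog, method = c("recursive", "direct")) {
  method <- match.arg(method)
  times <- catalog$times
  T <- catalog$window_end
  A <- model$trigger$A
  alpha <- model$trigger$alpha
  mu_int <- background_integral(model$background, T, catalog$origin)
  if (!length(times)) return(-mu_int)
  mu_i <- background_rate(model$background, times, catalog$origin)
  B <- if (method == "recursive") {
    hawkes_recursions(times, alpha)$B
  } else {
    vapply(seq_along(times), function(i) {
      if (i == 1) return(0)
      sum(exp(-alpha * (times[i] - times[seq_len(i - 1)])))
    }, numeric(1))
  }
  lam <- mu_i + A * alpha * B
  if (any(lam <= 0)) return(-Inf)
  sum(log(lam)) - mu_int - A * sum(1 - exp(-alpha * (T - times)))
}

# Log-likelihood and its analytic gradient with respect to the natural
# parameters (background rates..., A, alpha). Used by the optimizer; the
# chain rule to log-parameters is applied by the caller.
loglik_with_grad <- function(model, catalog) {
  times <- catalog$times
  T <- catalog$window_end
  A <- model$trigger$A
  alpha <- model$trigger$alpha
  des <- background_design(model$background, times, T, catalog$origin)
  rec <- hawkes_recursions(times, alpha, with_deriv = TRUE)
  B <- rec$B; C <- rec$C
  lam <- des$values + A * alpha * B
  if (!length(times) || any(lam <= 0)) {
    k <- length(background_params(model$background))
    return(list(value = if (length(times)) -Inf else -des$integral,
                grad = rep(NA_real_, k + 2)))
  }
  tail_gap <- T - times
  e_tail <- exp(-alpha * tail_gap)
  value <- sum(log(lam)) - des$integral - A * sum(1 - e_tail)
  inv_lam <- 1 / lam
  g_bg <- as.numeric(crossprod(des$jac_values, inv_lam)) - des$jac_integral
  g_A <- sum(alpha * B * inv_lam) - sum(1 - e_tail)
  g_alpha <- sum(A * (B - alpha * C) * inv_lam) - A * sum(tail_gap * e_tail)
  list(value = value, grad = c(g_bg, g_A, g_alpha))
}

# -- JSON (de)serialization of model specifications ----------------------

background_to_list <- function(spec) {
  fam <- class(spec)[1]
  if (fam == "stationary_background") {
    list(type = "stationary", mu = spec$mu)
  } else if (fam == "piecewise_background") {
    list(type = "piecewise", period = spec$period,
         rates = as.list(spec$rates),
         morning = spec$morning, evening = spec$evening)
  } else {
    list(type = "sinusoidal", mu0 = spec$mu0, P = spec$P, Q = spec$Q,
         R = spec$R, S = spec$S, phase = spec$phase, waveform = spec$waveform)
  }
}

background_from_list <- function(x) {
  switch(x$type,
    stationary = stationary_background(x$mu),
    piecewise = piecewise_background(unlist(x$rates), period = x$period,
                                     morning = unlist(x$morning),
                                     evening = unlist(x$evening)),
    sinusoidal = sinusoidal_background(x$mu0, x$P, Q = x$Q, R = x$R, S = x$S,
                                       phase = x$phase, waveform = x$waveform),
    stop("unknown background type: ", x$type)
  )
}

#' Write a model specification to JSON
#'
#' @param model a \code{\link{hawkes_model}}.
#' @param path output file; when \code{NULL} the JSON string is returned.
#' @export
model_to_json <- function(model, path = NULL) {
  x <- list(background = background_to_list(model$background),
            trigger = list(A = model$trigger$A, alpha = model$trigger$alpha))
  if (is.null(path)) {
    return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model specification from JSON
#'
#' @param path JSON file or literal JSON string as written by
#'   \code{\link{model_to_json}}.
#' @return A \code{\link{hawkes_model}}.
#' @export
model_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  hawkes_model(background_from_list(x$background),
               triggering_params(x$trigger$A, x$trigger$alpha))
}
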