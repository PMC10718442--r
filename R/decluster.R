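# Stochastic declustering: per-pair triggering probabilities, primary /
# secondary classification, queue times, and agreement with external label
# sets.

#' Per-pair triggering probabilities and per-event secondary probabilities
#'
#' For a fitted model, the probability that event \eqn{i} triggered a later
#' event \eqn{j} is \eqn{p_{ij} = A\alpha e^{-\alpha(t_j - t_i)} /
#' \lambda(t_j)}, the probability that \eqn{j} is a secondary (triggered)
#' event is \eqn{p_j = \sum_{i<j} p_{ij}}, and the complementary primary
#' probability is \eqn{1 - p_j = \mu(t_j)/\lambda(t_j)}: the intensity
#' components partition each event's provenance exactly.
#'
#' @param model a fitted \code{\link{hawkes_model}}.
#' @param catalog the \code{\link{event_catalog}} the model was fitted to.
#' @param prune pairs with \eqn{p_{ij}} below this floor are dropped from
#'   the pair table for sparsity (set to 0 for the exact dense set);
#'   \code{p_secondary} is always computed from the full sum via the O(N)
#'   recursion, independent of pruning.
#' @return A \code{decluster_result}: \code{pairs} (data.frame i, j, p),
#'   \code{p_secondary}, \code{p_primary}, \code{lambda} at the event times,
#'   and provisional \code{labels} ("secondary" when \code{p_secondary >=
#'   0.5}); \code{\link{classify_secondary}} applies the queue-time rule.
#' @export
triggering_probabilities <- function(model, catalog, prune = 1e-12) {
  times <- catalog$times
  n <- catalog$n
  A <- model$trigger$A
  alpha <- model$trigger$alpha
  mu_i <- background_rate(model$background, times, catalog$origin)
  B <- hawkes_recursions(times, alpha)$B
  lam <- mu_i + A * alpha * B
  p_sec <- A * alpha * B / lam
  p_pri <- mu_i / lam

  pairs_i <- vector("list", n)
  if (A > 0 && n >= 2) {
    for (j in 2:n) {
      # walk predecessors backwards; contributions decay monotonically in
      # the gap, so stop at the first one below the floor
      i <- j - 1L
      is <- integer(0); ps <- numeric(0)
      while (i >= 1L) {
        p <- A * alpha * exp(-alpha * (times[j] - times[i])) / lam[j]
        if (prune > 0 && p < prune) break
        is <- c(is, i); ps <- c(ps, p)
        i <- i - 1L
      }
      if (length(is)) {
        pairs_i[[j]] <- data.frame(i = rev(is), j = j, p = rev(ps))
      }
    }
  }
  pairs <- do.call(rbind, pairs_i)
  if (is.null(pairs)) pairs <- data.frame(i = integer(0), j = integer(0),
                                          p = numeric(0))
  rownames(pairs) <- NULL
  structure(list(
    pairs = pairs, p_secondary = p_sec, p_primary = p_pri, lambda = lam,
    labels = ifelse(p_sec >= 0.5, "secondary", "primary")
  ), class = "decluster_result")
}

#' @export
print.decluster_result <- function(x, ...) {
  n <- length(x$p_secondary)
  cat(sprintf("<decluster_result> %d events, %d stored pairs\n",
              n, nrow(x$pairs)))
  cat(sprintf("  mean secondary probability: %.4f; %d events with p_j >= 0.5\n",
              mean(x$p_secondary), sum(x$p_secondary >= 0.5)))
  invisible(x)
}

#' Classification thresholds for the secondary-crash rule
#'
#' @param queue_time temporal threshold in minutes; typically
#'   \code{1440/alpha} from the fitted decay rate.
#' @param prob_threshold minimum secondary probability \eqn{p_j}; default
#'   0.5 (triggering more likely than not).
#' @export
classification_config <- function(queue_time, prob_threshold = 0.5) {
  stopifnot(queue_time > 0, prob_threshold >= 0, prob_threshold <= 1)
  list(queue_time = queue_time, prob_threshold = prob_threshold)
}

#' Queue time from a fitted decay rate
#'
#' The reciprocal of the decay rate \eqn{\alpha} is the mean delay between a
#' primary event and the secondary events it triggers, and serves as the
#' temporal threshold ("queue time") of the classification rule:
#' \eqn{1/\alpha} days \eqn{= 1440/\alpha} minutes.
#'
#' @param fit a \code{fit_result}, a \code{\link{hawkes_model}}, or a bare
#'   numeric \eqn{\alpha} in day^-1.
#' @return Queue time in minutes.
#' @export
queue_time <- function(fit) UseMethod("queue_time")

#' @export
queue_time.fit_result <- function(fit) 1440 / fit$model$trigger$alpha

#' @export
queue_time.hawkes_model <- function(fit) 1440 / fit$trigger$alpha

#' @export
queue_time.numeric <- function(fit) {
  stopifnot(all(fit > 0))
  1440 / fit
}

#' Per-period stationary refits and their queue times
#'
#' Refits a stationary model to the events of each calendar period (each
#' weekday, or each rush-hour period) and reports the per-period queue times
#' \eqn{1440/\alpha_k} together with their event-count-weighted average.
#' The window and time axis are unchanged; only the event subset varies, so
#' each \eqn{\alpha_k} reflects the decay of clustering among that period's
#' events.
#'
#' @param catalog an \code{\link{event_catalog}}.
#' @param period calendar split: day of week (7 periods) or rush-hour bins
#'   (3 periods).
#' @param options optimizer configuration; periods with fewer than
#'   \code{options$min_events} events are reported as \code{NA} and excluded
#'   from the weighted average.
#' @return A \code{queue_time_report}: \code{per_period} (minutes),
#'   \code{weights} (event counts), \code{weighted_average} (minutes,
#'   \eqn{\sum w_k q_k / \sum w_k}), and the per-period \code{fits}.
#' @export
fit_by_period <- function(catalog, period = c("day_of_week", "time_of_day"),
                          options = fit_options()) {
  period <- match.arg(period)
  template <- piecewise_background(rep(1, if (period == "day_of_week") 7 else 3),
                                   period = period)
  bins <- piecewise_bin(template, catalog$times, catalog$origin)
  k <- length(template$rates)
  fits <- vector("list", k)
  qt <- rep(NA_real_, k)
  w <- tabulate(bins, nbins = k)
  for (b in seq_len(k)) {
    keep <- which(bins == b)
    if (length(keep) < options$min_events) next
    sub <- subset_catalog(catalog, keep)
    ft <- tryCatch(fit_mle(sub, "stationary", options = options),
                   error = function(e) NULL)
    if (is.null(ft)) next
    fits[[b]] <- ft
    qt[b] <- queue_time(ft)
  }
  names(qt) <- names(w) <- names(template$rates)
  ok <- !is.na(qt)
  structure(list(
    per_period = qt, weights = w,
    weighted_average = sum(qt[ok] * w[ok]) / sum(w[ok]),
    fits = fits, period = period
  ), class = "queue_time_report")
}

#' @export
print.queue_time_report <- function(x, ...) {
  cat(sprintf("<queue_time_report> per-%s queue times (minutes):\n", x$period))
  print(round(x$per_period, 1))
  cat(sprintf("  count-weighted average: %.1f min\n", x$weighted_average))
  invisible(x)
}

#' Count-weighted average of per-period queue times
#'
#' @param minutes per-period queue times in minutes.
#' @param weights per-period event counts.
#' @return \eqn{\sum w_k q_k / \sum w_k} in minutes.
#' @export
weighted_queue_time <- function(minutes, weights) {
  stopifnot(length(minutes) == length(weights))
  ok <- !is.na(minutes)
  sum(minutes[ok] * weights[ok]) / sum(weights[ok])
}

#' Classify events into primary and secondary crashes
#'
#' Applies the post-processing rule: event \eqn{j} is labeled secondary when
#' the gap to the immediately preceding event is shorter than the queue time
#' \emph{and} its secondary probability \eqn{p_j} reaches the probability
#' threshold. The first event is always primary.
#'
#' @param catalog an \code{\link{event_catalog}}.
#' @param decluster the \code{\link{triggering_probabilities}} result for
#'   the same catalog.
#' @param config a \code{\link{classification_config}}.
#' @return A \code{classification}: \code{labels} (character),
#'   \code{secondary} (logical), and \code{summary} with \code{n},
#'   \code{n_secondary}, \code{percentage} (100 x count / N) and
#'   \code{mean_p_secondary} among the secondaries.
#' @export
classify_secondary <- function(catalog, decluster, config) {
  n <- catalog$n
  p <- decluster$p_secondary
  if (length(p) != n) stop("decluster result does not match catalog length")
  if (n == 0) {
    return(structure(list(labels = character(0), secondary = logical(0),
                          summary = list(n = 0L, n_secondary = 0L,
                                         percentage = NaN,
                                         mean_p_secondary = NaN)),
                     class = "classification"))
  }
  gap_min <- c(Inf, diff(catalog$times) * 1440)
  sec <- gap_min < config$queue_time & p >= config$prob_threshold
  structure(list(
    labels = ifelse(sec, "secondary", "primary"),
    secondary = sec,
    summary = list(
      n = n, n_secondary = sum(sec),
      percentage = 100 * sum(sec) / n,
      mean_p_secondary = if (any(sec)) mean(p[sec]) else NaN
    )
  ), class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<classification> %d of %d events secondary (%.2f%%)",
              s$n_secondary, s$n, s$percentage))
  if (is.finite(s$mean_p_secondary)) {
    cat(sprintf(", mean p_j = %.2f", s$mean_p_secondary))
  }
  cat("\n")
  invisible(x)
}

#' Agreement with an external reference labeling
#'
#' Compares this package's secondary labels with those of an external method
#' on the same catalog, reporting the fraction of the reference's
#' secondaries that this method also flags.
#'
#' @param ours,reference logical vectors (TRUE = secondary) of equal length,
#'   aligned to the same catalog.
#' @return A list: \code{matched} (count in both), \code{match_percentage}
#'   (100 x matched / reference count), \code{ours_only},
#'   \code{reference_only}, and the two totals.
#' @export
match_against_reference <- function(ours, reference) {
  ours <- as.logical(ours); reference <- as.logical(reference)
  if (length(ours) != length(reference)) {
    stop("label vectors differ in length (", length(ours), " vs ",
         length(reference), ")")
  }
  matched <- sum(ours & reference)
  n_ref <- sum(reference)
  list(
    matched = matched,
    match_percentage = if (n_ref > 0) 100 * matched / n_ref else NaN,
    ours_only = sum(ours & !reference),
    reference_only = sum(reference & !ours),
    n_ours = sum(ours), n_reference = n_ref
  )
}
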