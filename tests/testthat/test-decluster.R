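test_that("the first event is primary with certainty", {
  m <- hawkes_model(stationary_background(0.4), triggering_params(0.2, 10))
  cat_ <- event_catalog(c(1, 1.5, 4), monday_origin(), 10)
  dec <- triggering_probabilities(m, cat_)
  expect_equal(dec$p_secondary[1], 0)
  expect_equal(dec$p_primary[1], 1)
})

test_that("a two-event pair matches hand arithmetic on the intensity split", {
  mu <- 0.495; A <- 0.114; alpha <- 10.459; dt <- 0.01
  m <- hawkes_model(stationary_background(mu), triggering_params(A, alpha))
  cat_ <- event_catalog(c(2, 2 + dt), monday_origin(), 10)
  dec <- triggering_probabilities(m, cat_)
  g <- A * alpha * exp(-alpha * dt)          # kernel contribution of event 1
  expect_equal(dec$p_secondary[2], g / (mu + g), tolerance = 1e-12)
  expect_equal(dec$p_primary[2], mu / (mu + g), tolerance = 1e-12)
  expect_equal(dec$pairs$p[dec$pairs$i == 1 & dec$pairs$j == 2],
               g / (mu + g), tolerance = 1e-12)
})

test_that("with no excitation every event is primary", {
  m <- hawkes_model(stationary_background(0.4), triggering_params(0, 10))
  cat_ <- event_catalog(c(0.5, 0.51, 0.52, 3), monday_origin(), 10)
  dec <- triggering_probabilities(m, cat_)
  expect_equal(nrow(dec$pairs), 0)
  expect_equal(dec$p_secondary, rep(0, 4))
  expect_equal(dec$labels, rep("primary", 4))
})

test_that("primary and secondary probabilities partition each event", {
  syn <- simulate_branching(recovery_model(), T = 800, seed = 31)
  ft <- fit_mle(syn$catalog, "stationary")
  dec <- triggering_probabilities(ft$model, syn$catalog)
  expect_lt(max(abs(dec$p_secondary + dec$p_primary - 1)), 1e-9)
  # and p_j equals the sum over predecessors of p_ij
  sums <- tapply(dec$pairs$p, dec$pairs$j, sum)
  j <- as.integer(names(sums))
  expect_lt(max(abs(sums - dec$p_secondary[j])), 1e-8)
})

test_that("pruned pair tables agree exactly with the dense computation", {
  m <- hawkes_model(stationary_background(0.4), triggering_params(0.3, 8))
  syn <- simulate_branching(m, T = 300, seed = 14)
  cat_ <- syn$catalog
  expect_lte(cat_$n, 200)
  dense <- oracle_dense_pairs(m, cat_)
  exact <- triggering_probabilities(m, cat_, prune = 0)
  expect_equal(exact$pairs$p,
               dense[cbind(exact$pairs$i, exact$pairs$j)])
  # exact mode stores all predecessor pairs
  expect_equal(nrow(exact$pairs), cat_$n * (cat_$n - 1) / 2)
  # pruning drops only entries below the floor
  pruned <- triggering_probabilities(m, cat_, prune = 1e-12)
  expect_true(all(pruned$pairs$p >= 1e-12))
  expect_equal(sum(dense >= 1e-12), nrow(pruned$pairs))
})

test_that("queue time is the reciprocal decay rate in minutes", {
  expect_equal(queue_time(10.459), 137.7, tolerance = 0.1)
  expect_equal(queue_time(8.676), 166.0, tolerance = 0.1)
  expect_equal(queue_time(1440), 1.0)
  m <- hawkes_model(stationary_background(0.4), triggering_params(0.2, 12))
  expect_equal(queue_time(m), 120)
})

test_that("the successive-gap rule classifies as stated", {
  m <- hawkes_model(stationary_background(0.495),
                    triggering_params(0.114, 10.459))
  # two events 300 minutes apart: gap exceeds the 137.7-minute queue time
  cat2 <- event_catalog(c(1, 1 + 300 / 1440), monday_origin(), 10)
  dec2 <- triggering_probabilities(m, cat2)
  cls2 <- classify_secondary(cat2, dec2, classification_config(137.7))
  expect_equal(cls2$labels, c("primary", "primary"))

  # a lone parent, then a dense cluster: the cluster head is primary (large
  # gap), its four followers secondary (2-minute gaps, high p_j)
  mc <- hawkes_model(stationary_background(0.1), triggering_params(0.6, 100))
  tt <- c(0, c(120, 122, 124, 126, 128) / 1440)
  catc <- event_catalog(tt, monday_origin(), 2)
  decc <- triggering_probabilities(mc, catc)
  clsc <- classify_secondary(catc, decc, classification_config(10, 0.5))
  expect_equal(sum(clsc$secondary), 4)
  expect_equal(clsc$labels[1:3], c("primary", "primary", "secondary"))
  expect_equal(clsc$summary$percentage, 100 * 4 / 6, tolerance = 1e-12)
})

test_that("tightening either threshold never increases the secondary count", {
  syn <- simulate_branching(recovery_model(), T = 600, seed = 23)
  dec <- triggering_probabilities(recovery_model(), syn$catalog)
  counts_p <- vapply(c(0.2, 0.4, 0.6, 0.8), function(p) {
    classify_secondary(syn$catalog, dec,
                       classification_config(120, p))$summary$n_secondary
  }, numeric(1))
  expect_false(is.unsorted(rev(counts_p)))
  counts_q <- vapply(c(30, 60, 120, 240), function(q) {
    classify_secondary(syn$catalog, dec,
                       classification_config(q, 0.5))$summary$n_secondary
  }, numeric(1))
  expect_false(is.unsorted(counts_q))
})

test_that("declustering recovers simulated ground-truth labels", {
  sens <- spec <- numeric(20)
  for (s in 1:20) {
    syn <- simulate_branching(recovery_model(), T = 500, seed = 100 + s)
    dec <- triggering_probabilities(recovery_model(), syn$catalog)
    called <- dec$p_secondary >= 0.5
    truth <- syn$parent != -1L
    sens[s] <- sum(called & truth) / sum(truth)
    spec[s] <- sum(!called & !truth) / sum(!truth)
  }
  expect_gt(mean(sens), 0.70)
  expect_gt(mean(spec), 0.85)
})

test_that("agreement with a reference labeling is scored on its secondaries", {
  ours <- c(rep(TRUE, 48), rep(FALSE, 4), rep(TRUE, 10), rep(FALSE, 825))
  ref <- c(rep(TRUE, 52), rep(FALSE, 835))
  agr <- match_against_reference(ours, ref)
  expect_equal(agr$matched, 48)
  expect_equal(agr$match_percentage, 92.3, tolerance = 0.05)
  expect_equal(agr$ours_only, 10)
  expect_equal(agr$reference_only, 4)

  same <- rep(c(TRUE, FALSE), c(5, 7))
  expect_equal(match_against_reference(same, same)$match_percentage, 100)
  disjoint <- rev(same)
  expect_equal(match_against_reference(same, !same)$match_percentage, 0)
  expect_error(match_against_reference(same, same[-1]), "length")
})

test_that("per-period refits yield a count-weighted average queue time", {
  syn <- simulate_branching(recovery_model(), T = 3000, seed = 77)
  rep_ <- fit_by_period(syn$catalog, "day_of_week",
                        options = fit_options(n_restarts = 0))
  ok <- !is.na(rep_$per_period)
  expect_true(all(rep_$per_period[ok] > 0))
  expect_equal(rep_$weighted_average,
               sum(rep_$per_period[ok] * rep_$weights[ok]) /
                 sum(rep_$weights[ok]))
  expect_equal(rep_$weighted_average,
               weighted_queue_time(rep_$per_period, rep_$weights))
})

test_that("classifying an empty catalog returns empty labels", {
  cat0 <- event_catalog(numeric(0), monday_origin(), 10)
  dec0 <- triggering_probabilities(recovery_model(), cat0)
  cls0 <- classify_secondary(cat0, dec0, classification_config(100))
  expect_length(cls0$labels, 0)
  expect_equal(cls0$summary$n_secondary, 0)
})
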