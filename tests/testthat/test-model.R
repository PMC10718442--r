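test_that("background families evaluate the printed and closed-form rates", {
  origin <- monday_origin()
  # stationary: constant everywhere
  expect_equal(background_rate(stationary_background(0.495), c(0, 3.7, 900),
                               origin),
               rep(0.495, 3))
  # degenerate flat sinusoid
  flat <- sinusoidal_background(0.3, P = 0, S = 1, phase = "weekly")
  tt <- seq(0, 14, by = 0.3)
  expect_equal(background_rate(flat, tt, origin), rep(0.3, length(tt)))
  # weekday step function: Friday at 136% of Sunday
  rates <- c(0.25, 0.25, 0.25, 0.25, 0.34, 0.25, 0.25)
  rates[5] <- 1.36 * rates[7]
  pw <- piecewise_background(rates)
  friday <- background_rate(pw, 4.5, origin)   # origin is a Monday
  sunday <- background_rate(pw, 6.5, origin)
  expect_equal(friday / sunday, 1.36)
  # rush-hour bins pick the right calendar period
  tod <- piecewise_background(c(0.6, 0.2, 0.8), period = "time_of_day")
  expect_equal(background_rate(tod, 7.5 / 24, origin), 0.6)   # 07:30
  expect_equal(background_rate(tod, 12 / 24, origin), 0.2)    # noon
  expect_equal(background_rate(tod, 17 / 24, origin), 0.8)    # 17:00
})

test_that("conditional intensity matches direct arithmetic", {
  origin <- monday_origin()
  m <- hawkes_model(stationary_background(0.5), triggering_params(0.2, 10))
  empty <- event_catalog(numeric(0), origin, 10)
  expect_equal(intensity_at(m, empty, 3), 0.5)

  # one event, evaluated just after: mu + A * alpha
  m2 <- hawkes_model(stationary_background(0.495),
                     triggering_params(0.114, 10.459))
  one <- event_catalog(2, origin, 10)
  expect_equal(intensity_at(m2, one, 2 + 1e-12), 0.495 + 0.114 * 10.459,
               tolerance = 1e-9)
  # closed form of the single-term sum at lag 1/alpha
  m3 <- hawkes_model(stationary_background(1e-12),
                     suppressWarnings(triggering_params(1, 8)))
  one0 <- event_catalog(0, origin, 10)
  expect_equal(intensity_at(m3, one0, 1 / 8), 8 * exp(-1), tolerance = 1e-9)
})

test_that("log-likelihood closed forms hold for degenerate catalogs", {
  origin <- monday_origin()
  m <- hawkes_model(stationary_background(0.3), triggering_params(0.2, 5))
  empty <- event_catalog(numeric(0), origin, 40)
  expect_equal(log_likelihood(m, empty), -0.3 * 40)

  one <- event_catalog(12.5, origin, 40)
  expected <- log(0.3) - 0.3 * 40 - 0.2 * (1 - exp(-5 * (40 - 12.5)))
  expect_equal(log_likelihood(m, one), expected, tolerance = 1e-12)
})

test_that("O(N) likelihood recursion equals the O(N^2) direct sum", {
  for (seed in 1:3) {
    syn <- simulate_branching(recovery_model(), T = 130, seed = seed)
    expect_gt(syn$catalog$n, 30)
    for (bg in list(stationary_background(0.4),
                    piecewise_background(c(0.2, 0.3, 0.5, 0.4, 0.6, 0.3, 0.2)),
                    sinusoidal_background(0.4, P = 0.3, S = 1,
                                          phase = "daily", waveform = "cos"))) {
      m <- hawkes_model(bg, triggering_params(0.3, 9))
      lr <- log_likelihood(m, syn$catalog, method = "recursive")
      ld <- log_likelihood(m, syn$catalog, method = "direct")
      expect_equal(lr, ld, tolerance = 1e-9)
    }
  }
})

test_that("triggering kernel integrates to the branching ratio A", {
  for (p in list(c(0.114, 10.459), c(0.9, 0.5), c(0.25, 12))) {
    got <- stats::integrate(function(s) p[1] * p[2] * exp(-p[2] * s),
                            0, Inf, rel.tol = 1e-12)$value
    expect_equal(got, p[1], tolerance = 1e-8)
  }
})

test_that("compensator is nonnegative and nondecreasing in t", {
  syn <- simulate_branching(recovery_model(), T = 60, seed = 9)
  m <- recovery_model()
  comp <- vapply(seq(0.5, 60, by = 0.5), function(tt) {
    sub <- syn$catalog$times[syn$catalog$times < tt]
    background_integral(m$background, tt, syn$catalog$origin) +
      m$trigger$A * sum(1 - exp(-m$trigger$alpha * (tt - sub)))
  }, numeric(1))
  expect_true(all(comp >= 0))
  expect_true(all(diff(comp) >= 0))
})

test_that("with A = 0 the likelihood reduces to the inhomogeneous Poisson one", {
  syn <- simulate_branching(recovery_model(), T = 200, seed = 4)
  cat_ <- syn$catalog
  for (bg in list(stationary_background(0.37),
                  sinusoidal_background(0.4, P = 0.2, S = 1, phase = "weekly"),
                  piecewise_background(c(0.5, 0.2, 0.7),
                                       period = "time_of_day"))) {
    m0 <- hawkes_model(bg, triggering_params(0, 7))
    poisson_ll <- sum(log(background_rate(bg, cat_$times, cat_$origin))) -
      background_integral(bg, cat_$window_end, cat_$origin)
    expect_equal(log_likelihood(m0, cat_), poisson_ll, tolerance = 1e-12)
  }
})

test_that("closed-form background integrals agree with quadrature", {
  origin <- as.POSIXct("2015-01-08 05:17:00", tz = "UTC")  # awkward origin
  set.seed(77)
  for (rep in 1:8) {
    P <- runif(1, 0, 0.8)
    S <- P + runif(1, 0.1, 1)
    weekly <- runif(1) < 0.5
    spec <- sinusoidal_background(
      mu0 = runif(1, 0.1, 2), P = P,
      Q = 2 * pi / (if (weekly) 7 else 1) * runif(1, 0.8, 1.2),
      R = runif(1, 0, 2 * pi), S = S,
      phase = if (weekly) "weekly" else "daily",
      waveform = sample(c("sin", "cos"), 1))
    T <- runif(1, 5, 40)
    per <- spec$period
    off <- crashdecluster:::sin_phase_offset(spec, origin)
    kinks <- seq(per - off %% per, T, by = per)
    closed <- background_integral(spec, T, origin)
    quad <- oracle_piecewise_integral(spec, T, origin, cuts_extra = kinks)
    expect_equal(closed, quad, tolerance = 1e-8)
  }
  # piecewise families, against segment-wise quadrature
  pw <- piecewise_background(c(0.31, 0.52, 0.18), period = "time_of_day")
  expect_equal(background_integral(pw, 23.3, origin),
               oracle_piecewise_integral(pw, 23.3, origin), tolerance = 1e-8)
  pw7 <- piecewise_background(c(0.2, 0.3, 0.4, 0.5, 0.6, 0.25, 0.15))
  expect_equal(background_integral(pw7, 17.8, origin),
               oracle_piecewise_integral(pw7, 17.8, origin), tolerance = 1e-8)
})

test_that("analytic likelihood gradient matches finite differences", {
  syn <- simulate_branching(recovery_model(), T = 150, seed = 21)
  for (bg in list(stationary_background(0.35),
                  piecewise_background(c(0.3, 0.4, 0.5), period = "time_of_day"),
                  sinusoidal_background(0.4, P = 0.25, S = 1,
                                        phase = "weekly"))) {
    m <- hawkes_model(bg, triggering_params(0.2, 8))
    lg <- crashdecluster:::loglik_with_grad(m, syn$catalog)
    k <- length(crashdecluster:::background_params(bg))
    theta <- c(crashdecluster:::background_params(bg), 0.2, 8)
    h <- 1e-6
    fd <- vapply(seq_along(theta), function(i) {
      up <- dn <- theta
      up[i] <- up[i] + h; dn[i] <- dn[i] - h
      mk <- function(th) crashdecluster:::assemble_model(bg, th)
      (log_likelihood(mk(up), syn$catalog) -
         log_likelihood(mk(dn), syn$catalog)) / (2 * h)
    }, numeric(1))
    expect_equal(lg$grad, fd, tolerance = 1e-5)
    expect_equal(lg$value, log_likelihood(m, syn$catalog))
  }
})

test_that("model JSON serialization round-trips every family", {
  syn <- simulate_branching(recovery_model(), T = 100, seed = 2)
  specs <- list(
    stationary_background(0.41),
    piecewise_background(c(0.2, 0.3, 0.4, 0.5, 0.6, 0.25, 0.15)),
    piecewise_background(c(0.6, 0.2, 0.8), period = "time_of_day"),
    sinusoidal_background(0.5, P = 0.3, R = 1.2, S = 1.1, phase = "daily",
                          waveform = "cos")
  )
  for (bg in specs) {
    m <- hawkes_model(bg, triggering_params(0.17, 11.3))
    path <- tempfile(fileext = ".json")
    model_to_json(m, path)
    m2 <- model_from_json(path)
    expect_equal(m2$trigger, m$trigger)
    expect_equal(log_likelihood(m2, syn$catalog), log_likelihood(m, syn$catalog))
  }
})

test_that("parameter validation rejects degenerate specifications", {
  expect_error(stationary_background(-0.1))
  expect_error(sinusoidal_background(0.5, P = 1.2, S = 1), "S must exceed")
  expect_error(piecewise_background(c(0.1, 0.2)), "7 rates")
  expect_error(triggering_params(0.5, -1))
  expect_warning(triggering_params(1.2, 5), "supercritical")
})
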