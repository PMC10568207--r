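test_that("constant rates give the steady-state periodic solution immediately", {
  g <- phase_grid(200)
  r <- rate_profiles(g, alpha = 10, beta = 12, gamma = 0.5)
  tp <- simulate_total_profiles(r)
  expect_equal(tp$p, rep(10 / 12, g$n), tolerance = 1e-9)
  expect_equal(tp$m, rep(20, g$n), tolerance = 1e-9)
})

test_that("Case I rates reproduce the target and converge in few cycles", {
  g <- phase_grid(500)
  r <- rates_case1(sine_target(20, 8), beta = 12, gamma = 0.5, grid = g)
  tp <- simulate_total_profiles(r, rel_tol = 1e-6)
  expect_lte(attr(tp, "n_cycles"), 10)
  expect_lt(max(abs(tp$m - (20 + 8 * sin(g$phi))) / 20), 1e-3)
})

test_that("non-convergence raises an error naming the residual", {
  g <- phase_grid(100)
  r <- rates_case1(sine_target(20, 8), beta = 12, gamma = 0.5, grid = g)
  expect_error(simulate_total_profiles(r, rel_tol = 1e-12, max_cycles = 2),
               "residual")
})

test_that("zero labeling time means no labeled molecules", {
  g <- phase_grid(100)
  r <- sinusoidal_rates(g)
  tp <- simulate_total_profiles(r)
  prof <- simulate_labeled_profiles(r, tp, t = 0)
  expect_equal(prof$pl, rep(0, g$n))
  expect_equal(prof$ml, rep(0, g$n))
  expect_equal(prof$pu, tp$p)
  expect_equal(prof$mu, tp$m)
  expect_error(simulate_labeled_profiles(r, tp, t = 25), "not supported")
})

test_that("constant-rate labeled profiles match two-exponential closed forms", {
  g <- phase_grid(200)
  a <- 8; b <- 2; gm <- 0.4; t <- 1
  r <- rate_profiles(g, alpha = a, beta = b, gamma = gm)
  tp <- simulate_total_profiles(r)
  prof <- simulate_labeled_profiles(r, tp, t = t)
  P <- a / b; M <- a / gm
  expect_equal(prof$pu, rep(P * exp(-t * b), g$n), tolerance = 1e-6)
  expect_equal(prof$pl, rep(a / b * (1 - exp(-t * b)), g$n), tolerance = 1e-6)
  mu_cf <- b * P / (gm - b) * exp(-t * b) + (M - b * P / (gm - b)) * exp(-t * gm)
  ml_cf <- a / gm - a / (gm - b) * exp(-t * b) +
    a * b / (gm * (gm - b)) * exp(-t * gm)
  expect_equal(prof$mu, rep(mu_cf, g$n), tolerance = 1e-6)
  expect_equal(prof$ml, rep(ml_cf, g$n), tolerance = 1e-6)
})

test_that("labeled profiles conserve totals under dynamic rates", {
  g <- phase_grid(500)
  r <- rates_case1(sine_target(20, 8), beta = 12, gamma = 0.5, grid = g)
  tp <- simulate_total_profiles(r)
  prof <- simulate_labeled_profiles(r, tp, t = 1)
  expect_lt(max(abs(prof$pu + prof$pl - prof$p) / prof$p), 1e-6)
  expect_lt(max(abs(prof$mu + prof$ml - prof$m) / prof$m), 1e-6)
})

test_that("labeled fractions vanish as labeling time shrinks to zero", {
  g <- phase_grid(200)
  r <- sinusoidal_rates(g)
  tp <- simulate_total_profiles(r)
  pl_max <- function(t) max(simulate_labeled_profiles(r, tp, t = t)$pl)
  ml_max <- function(t) max(simulate_labeled_profiles(r, tp, t = t)$ml)
  # halving a short pulse halves pl (first order in t)
  expect_equal(pl_max(0.01) / pl_max(0.02), 0.5, tolerance = 0.07)
  # ml lags one conversion behind and vanishes one order faster
  expect_lt(ml_max(0.01) / ml_max(0.02), 0.35)
  expect_lt(pl_max(0.005), 0.06 * max(tp$p))
})

test_that("full-model estimators are exact at steady state", {
  g <- phase_grid(200)
  t <- 0.25
  a <- 8; b <- 2
  prof <- tibble::tibble(
    phase = g$phi,
    pu = 4 * exp(-0.5), pl = 4 * (1 - exp(-0.5)),
    mu = NA_real_, ml = NA_real_, p = 4, m = 20
  )
  # fill matures from the constant-rate closed forms with gamma = 0.4
  gm <- 0.4
  prof$mu <- b * 4 / (gm - b) * exp(-t * b) + (20 - b * 4 / (gm - b)) * exp(-t * gm)
  prof$ml <- 20 - prof$mu
  attr(prof, "grid") <- g
  attr(prof, "labeling_time") <- t
  est <- estimate_rates_full(prof)
  expect_equal(est$beta, rep(2, g$n), tolerance = 1e-10)
  expect_equal(est$alpha, rep(8, g$n), tolerance = 1e-10)
  expect_equal(est$gamma, rep(0.4, g$n), tolerance = 1e-8)
})

test_that("no precursor loss over the pulse implies zero splicing estimate", {
  g <- phase_grid(100)
  prof <- tibble::tibble(
    phase = g$phi, pu = 4, pl = 1, mu = 10, ml = 2, p = 4, m = 12
  )
  attr(prof, "grid") <- g
  attr(prof, "labeling_time") <- 0.25
  est <- suppressWarnings(estimate_rates_full(prof))
  expect_equal(est$beta, rep(0, g$n))
})

test_that("full-model recovery error shrinks as labeling time shortens", {
  g <- phase_grid(500)
  r <- sinusoidal_rates(g)
  tp <- simulate_total_profiles(r)
  errs <- vapply(c(0.5, 0.25, 0.1), function(t) {
    est <- estimate_rates_full(simulate_labeled_profiles(r, tp, t = t))
    max(stats::median(abs(est$alpha - r$alpha) / r$alpha),
        stats::median(abs(est$beta - r$beta) / r$beta),
        stats::median(abs(est$gamma - r$gamma) / r$gamma))
  }, numeric(1))
  expect_lt(errs[3], 0.05)
  expect_true(all(diff(errs) < 0))
})

test_that("gamma quadratic selects the root inside (0, beta)", {
  g <- phase_grid(100)
  t <- 0.25
  a <- 8; b <- 2; gm <- 0.4
  P <- a / b; M <- a / gm
  prof <- tibble::tibble(
    phase = g$phi,
    pu = P * exp(-t * b), pl = P * (1 - exp(-t * b)),
    mu = b * P / (gm - b) * exp(-t * b) + (M - b * P / (gm - b)) * exp(-t * gm),
    ml = NA_real_, p = P, m = M
  )
  prof$ml <- M - prof$mu
  attr(prof, "grid") <- g
  attr(prof, "labeling_time") <- t
  gamma <- solve_gamma_quadratic(prof, beta = rep(b, g$n), t = t)
  expect_equal(as.numeric(gamma), rep(gm, g$n), tolerance = 1e-10)
  expect_equal(attr(gamma, "n_flagged"), 0L)
})

test_that("inadmissible quadratic points are flagged and interpolated", {
  g <- phase_grid(100)
  prof <- tibble::tibble(
    phase = g$phi,
    pu = 2 * exp(-0.5), pl = 2 * (1 - exp(-0.5)),
    mu = 18, ml = 2, p = 2, m = 20
  )
  # corrupt one grid point so that no root lies inside (0, beta)
  prof$mu[5] <- 21
  attr(prof, "grid") <- g
  attr(prof, "labeling_time") <- 0.25
  expect_warning(
    gamma <- solve_gamma_quadratic(prof, beta = rep(2, g$n), t = 0.25),
    "interpolated"
  )
  expect_gte(attr(gamma, "n_flagged"), 1L)
  expect_true(all(is.finite(gamma)))
})

test_that("simplified estimators are exact at steady state", {
  g <- phase_grid(150)
  obs <- tibble::tibble(
    phase = g$phi,
    mu = 20 * exp(-0.5),
    ml = 20 - 20 * exp(-0.5),
    m = 20
  )
  est <- estimate_rates_simplified(obs, t = 1, grid = g)
  expect_equal(est$gamma, rep(0.5, g$n), tolerance = 1e-12)
  expect_equal(est$alpha, rep(10, g$n), tolerance = 1e-12)
})

test_that("no measurable decay gives the series-guard limit", {
  g <- phase_grid(100)
  obs <- tibble::tibble(phase = g$phi, mu = 20, ml = 3, m = 20)
  est <- estimate_rates_simplified(obs, t = 0.5, grid = g)
  expect_equal(est$gamma, rep(0, g$n))
  expect_equal(est$alpha, rep(3 / 0.5, g$n))
})

test_that("noisy mu above the lagged total is floored and flagged", {
  g <- phase_grid(100)
  obs <- tibble::tibble(phase = g$phi, mu = 20, ml = 1, m = 20)
  obs$mu[3] <- 21
  expect_warning(est <- estimate_rates_simplified(obs, t = 1, grid = g),
                 "floored")
  expect_equal(est$gamma[3], 0)
  expect_equal(attr(est, "n_flagged"), 1L)
})

test_that("simplified estimators recover gently modulated dynamic rates", {
  g <- phase_grid(500)
  r <- sinusoidal_rates(g, beta = 1)
  obs <- simplified_forward(g, t = 1, rates = r)
  est <- estimate_rates_simplified(obs, t = 1, grid = g)
  expect_lt(stats::median(abs(est$alpha - r$alpha) / r$alpha), 0.02)
  expect_lt(stats::median(abs(est$gamma - r$gamma) / r$gamma), 0.02)
})

test_that("constant-rate predictions match the closed forms", {
  g <- phase_grid(200)
  est <- tibble::tibble(phase = g$phi, alpha = rep(10, g$n),
                        gamma = rep(0.5, g$n))
  attr(est, "grid") <- g
  attr(est, "labeling_time") <- 1
  for (method in c("integral", "pointwise")) {
    tol <- if (method == "integral") 1e-4 else 1e-10 # trapezoid vs exact
    pred <- predict_mature_profiles(est, m = rep(20, g$n), t = 1, grid = g,
                                    method = method)
    expect_equal(pred$mu, rep(20 * exp(-0.5), g$n), tolerance = tol)
    expect_equal(pred$ml, rep(10 / 0.5 * (1 - exp(-0.5)), g$n),
                 tolerance = tol)
  }
})

test_that("zero degradation predicts undiminished unlabeled matures", {
  g <- phase_grid(200)
  m <- 20 + 5 * sin(g$phi)
  est <- tibble::tibble(phase = g$phi, alpha = rep(4, g$n),
                        gamma = rep(0, g$n))
  attr(est, "grid") <- g
  attr(est, "labeling_time") <- 1
  pred <- predict_mature_profiles(est, m = m, t = 1, grid = g)
  m_lag <- cyclerates:::shifted_profile(g, m, 1)
  expect_equal(pred$mu, m_lag, tolerance = 1e-9)
})

test_that("predict-after-estimate is the identity in the pointwise pairing", {
  g <- phase_grid(500)
  obs <- simplified_forward(g, t = 0.25)
  est <- estimate_rates_simplified(obs, t = 0.25, grid = g)
  pred <- predict_mature_profiles(est, m = obs$m, t = 0.25, grid = g,
                                  method = "pointwise")
  expect_lt(cyclerates:::max_mature_deviation(pred, obs), 1e-10)
  # the integral predictor deviates only at the short-labeling approximation
  # order, far below the well-predicted cutoff
  pred_int <- predict_mature_profiles(est, m = obs$m, t = 0.25, grid = g)
  expect_lt(cyclerates:::max_mature_deviation(pred_int, obs), 0.01)
})

test_that("holding an already-constant rate fixed changes nothing", {
  g <- phase_grid(200)
  est <- tibble::tibble(phase = g$phi, alpha = rep(10, g$n),
                        gamma = rep(0.5, g$n))
  attr(est, "grid") <- g
  attr(est, "labeling_time") <- 1
  base <- predict_mature_profiles(est, m = rep(20, g$n), t = 1, grid = g)
  for (w in c("transcription", "degradation")) {
    pc <- predict_with_constant_rate(est, t = 1, grid = g, which = w)
    expect_equal(pc$mu, base$mu, tolerance = 1e-6)
    expect_equal(pc$ml, base$ml, tolerance = 1e-6)
  }
})
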