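test_that("CPM normalization scales cells to a million and drops empties", {
  m <- matrix(c(5, 0, 15, 0, 0, 0), nrow = 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
  expect_message(cpm <- normalize_cpm(m), "dropped")
  expect_equal(ncol(cpm), 2)
  expect_equal(as.numeric(Matrix::colSums(cpm)), rep(1e6, 2))
  expect_equal(cpm["g1", "c1"], 1e6)
  # explicit totals: count 5 out of 10000 -> 500 CPM
  cpm2 <- normalize_cpm(m[, 1, drop = FALSE], totals = 10000)
  expect_equal(cpm2["g1", "c1"], 500)
})

test_that("sparse and dense CPM agree", {
  set.seed(5)
  d <- matrix(rpois(300, 4), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("c", 1:30)))
  s <- Matrix::Matrix(d, sparse = TRUE)
  expect_equal(as.matrix(normalize_cpm(s)), normalize_cpm(d),
               ignore_attr = TRUE)
})

test_that("cyclic smoothing is periodic and exact on constant input", {
  set.seed(6)
  ph <- runif(500, 0, 2 * pi)
  sp <- smooth_profile(ph, rep(7, 500))
  expect_lt(max(abs(sp$value(seq(0, 2 * pi, length.out = 100)) - 7)) / 7, 1e-6)
  expect_equal(sp$value(0), sp$value(2 * pi))
  expect_error(smooth_profile(ph[1:10], rep(1, 10)), "distinct phases")
})

test_that("cyclic smoothing recovers a noisy sinusoid", {
  set.seed(7)
  ph <- runif(2000, 0, 2 * pi)
  y <- 10 + 3 * sin(ph) + rnorm(2000, 0, 0.5)
  sp <- smooth_profile(ph, y)
  grid_phi <- seq(0, 2 * pi, length.out = 200)
  expect_lt(sqrt(mean((sp$value(grid_phi) - (10 + 3 * sin(grid_phi)))^2)), 0.1)
})

test_that("peak calling handles flat, single-peak and sub-threshold profiles", {
  flat <- find_peaks(function(phi) rep(5, length(phi)))
  expect_false(flat$is_peaking)
  expect_equal(flat$n_peaks, 0L)
  one <- find_peaks(function(phi) 2 + sin(phi))
  expect_true(one$is_peaking)
  expect_equal(one$fc_global, 3, tolerance = 1e-3)
  expect_equal(one$n_peaks, 1L)
  expect_equal(one$peak_phases, pi / 2, tolerance = 0.01)
  weak <- find_peaks(function(phi) 10 + sin(phi)) # fc = 11/9 < 1.5
  expect_false(weak$is_peaking)
})

test_that("secondary peaks cross at a quarter of the global difference", {
  two_bump <- function(h) {
    function(phi) {
      0.5 + exp(4 * (cos(phi) - 1)) + h * exp(4 * (cos(phi - pi) - 1))
    }
  }
  # locate the crossing height with the brute-force oracle
  dense <- function(h) two_bump(h)(2 * pi * (0:3999) / 4000)
  crossing <- stats::uniroot(function(h) {
    # direct prominence arithmetic on the dense scan
    v <- dense(h)
    n <- length(v)
    i2 <- which.max(v[(n / 4):(3 * n / 4)]) + n / 4 - 1 # secondary bump at pi
    mins <- sort(c(which.min(v[1:(n / 2)]), which.min(v[(n / 2):n]) + n / 2 - 1))
    prom <- v[i2] - max(v[mins])
    prom - (max(v) - min(v)) / 4
  }, c(0.05, 0.9))$root
  lo <- two_bump(crossing * 0.98)
  hi <- two_bump(crossing * 1.02)
  expect_equal(find_peaks(lo, n_grid = 4000)$n_peaks, 1L)
  expect_equal(find_peaks(hi, n_grid = 4000)$n_peaks, 2L)
  # and the package peak caller agrees with the oracle on both sides
  expect_equal(find_peaks(lo, n_grid = 4000)$n_peaks,
               brute_force_peaks(dense(crossing * 0.98)))
  expect_equal(find_peaks(hi, n_grid = 4000)$n_peaks,
               brute_force_peaks(dense(crossing * 1.02)))
})

test_that("cycling requires exactly one peak", {
  expect_true(classify_cycling(find_peaks(function(phi) 2 + sin(phi))))
  expect_false(classify_cycling(
    find_peaks(function(phi) 2 + sin(2 * phi))
  ))
  expect_false(classify_cycling(find_peaks(function(phi) rep(1, length(phi)))))
})

test_that("deviation is a mean relative error, scale-invariant", {
  expect_equal(deviation(1:10, 1:10), 0)
  expect_equal(deviation(1.2 * (1:10), 1:10), 0.2)
  set.seed(8)
  pred <- runif(50, 1, 2)
  obs <- runif(50, 1, 2)
  expect_equal(deviation(pred, obs), sum(abs(pred - obs) / obs) / 50)
  expect_equal(deviation(3 * pred, 3 * obs), deviation(pred, obs))
  expect_message(deviation(c(1, 2), c(1, 0)), "excluded")
})

test_that("kinetic modes follow the dev_c decision table", {
  expect_equal(classify_kinetic_mode(0.5, 0.05), "dynamic transcription")
  expect_equal(classify_kinetic_mode(0.05, 0.5), "dynamic degradation")
  expect_equal(classify_kinetic_mode(0.4, 0.6), "both")
  expect_equal(classify_kinetic_mode(0.05, 0.05), "other")
  # boundary: exactly at threshold counts as small
  expect_equal(classify_kinetic_mode(0.2, 0.2), "other")
})

test_that("half-life is ln 2 over the cycle-mean degradation rate", {
  expect_equal(mean_half_life(rep(log(2), 5)), 1)
  expect_equal(mean_half_life(rep(2 * log(2), 5)), 0.5)
  g <- phase_grid(1000)
  gam <- 0.347 + 0.1 * sin(g$phi)
  expect_equal(mean_half_life(gam), log(2) / mean(gam))
  expect_true(is.na(mean_half_life(rep(-0.1, 5))))
})

test_that("constant-rate deviations separate the three regulation regimes", {
  g <- phase_grid(300)
  cases <- shared_target_cases(g)
  t <- 1
  devs <- lapply(cases, function(r) {
    tot <- simulate_total_profiles(r)
    prof <- simulate_labeled_profiles(r, tot, t = t)
    est <- estimate_rates_simplified(prof, t = t, grid = g)
    c(alpha = constant_rate_deviation(est, m = prof$m, t = t, grid = g,
                                      which = "transcription"),
      gamma = constant_rate_deviation(est, m = prof$m, t = t, grid = g,
                                      which = "degradation"))
  })
  expect_gt(devs$case1[["alpha"]], 0.2)
  expect_lte(devs$case1[["gamma"]], 0.2)
  expect_lte(devs$case2[["alpha"]], 0.2)
  expect_gt(devs$case2[["gamma"]], 0.2)
  expect_gt(devs$case3[["alpha"]], 0.2)
  expect_gt(devs$case3[["gamma"]], 0.2)
})

test_that("gene-level fit classifies a clean cycling gene end to end", {
  g <- phase_grid(200)
  r <- rates_case1(sine_target(20, 8), beta = 12, gamma = 0.5, grid = g)
  tot <- simulate_total_profiles(r)
  prof <- simulate_labeled_profiles(r, tot, t = 1)
  set.seed(12)
  n <- 1500
  ph <- runif(n, 0, 2 * pi)
  fmu <- cyclerates:::periodic_interpolant(g$phi, prof$mu)
  fml <- cyclerates:::periodic_interpolant(g$phi, prof$ml)
  cells <- tibble::tibble(phase = ph,
                          mu = rpois(n, 5 * fmu(ph)) / 5,
                          ml = rpois(n, 5 * fml(ph)) / 5)
  fit <- fit_gene_kinetics(cells, t = 1, grid = g)
  expect_true(fit$cycling)
  expect_true(fit$well_predicted)
  expect_equal(fit$mode, "dynamic transcription")
  expect_equal(fit$half_life, log(2) / mean(fit$estimates$gamma))
  td <- tidy(fit)
  expect_equal(td$n_peaks_expression, 1L)
  expect_true(td$robust_cycling)
  expect_s3_class(glance(fit), "tbl_df")
})

test_that("bootstrap bands are deterministic and collapse on noise-free input", {
  g <- phase_grid(150)
  obs <- simplified_forward(g, t = 1)
  set.seed(14)
  n <- 400
  ph <- runif(n, 0, 2 * pi)
  fmu <- cyclerates:::periodic_interpolant(g$phi, obs$mu)
  fml <- cyclerates:::periodic_interpolant(g$phi, obs$ml)
  noisefree <- tibble::tibble(phase = ph, mu = fmu(ph), ml = fml(ph))
  bb <- bootstrap_rates(noisefree, t = 1, grid = g, B = 30, seed = 2)
  bb2 <- bootstrap_rates(noisefree, t = 1, grid = g, B = 30, seed = 2)
  expect_identical(bb, bb2)
  # functional (noise-free) data: every resample refits the same curve
  expect_lt(max((bb$alpha_hi - bb$alpha_lo) / bb$alpha), 0.02)
  expect_lt(max((bb$gamma_hi - bb$gamma_lo) / pmax(bb$gamma, 0.1)), 0.05)
})

test_that("downsampling yields monotone TPR and no housekeeping false calls", {
  panel <- downsample_panel()
  dv <- downsample_validity(panel$counts, panel$phases, panel$truth,
                            fractions = seq(0.2, 1, by = 0.2), iters = 8,
                            seed = 9, k = 12)
  expect_equal(max(dv$fpr$fpr), 0)
  # TPR non-increasing in dropout rate (dropout falls as fraction grows)
  ord <- order(dv$tpr$dropout_rate)
  tpr_by_dropout <- dv$tpr$tpr[ord]
  # non-increasing within one marker step of sampling tolerance
  expect_true(all(diff(tpr_by_dropout) <= 1 / 3 + 1e-9))
  # identity thinning: fraction 1 keeps the matrix
  expect_equal(
    dv$calls$dropout_rate[dv$calls$fraction == 1 & dv$calls$gene == "hk1"],
    mean(panel$counts["hk1", ] == 0)
  )
  expect_error(downsample_validity(panel$counts, panel$phases, panel$truth,
                                   fractions = c(0, 0.5), iters = 2, seed = 1),
               "fractions")
})

test_that("binomial thinning preserves expected counts proportionally", {
  set.seed(15)
  counts <- matrix(rpois(10000, 20), nrow = 1,
                   dimnames = list("g", NULL))
  thinned <- matrix(rbinom(length(counts), as.integer(counts), 0.3),
                    nrow = 1)
  expect_lt(abs(mean(thinned) - 0.3 * mean(counts)),
            3 * sqrt(0.3 * 20 / 10000))
})

test_that("pseudo-bulk correlation is near one for replicate-like matrices", {
  set.seed(16)
  mu <- rgamma(200, 5, 1) * 20
  a <- matrix(rpois(200 * 40, mu), nrow = 200,
              dimnames = list(paste0("g", 1:200), NULL))
  b <- matrix(rpois(200 * 40, mu), nrow = 200,
              dimnames = list(paste0("g", 1:200), NULL))
  expect_gt(pseudobulk_correlation(a, b), 0.99)
})
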