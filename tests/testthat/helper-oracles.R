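# Independent oracles and shared scenario builders for the test suite.

# Exact pmf arithmetic built from first principles (products over integers),
# independent of dbinom/dpois.
binom_pmf_oracle <- function(k, n, p) {
  if (k < 0 || k > n) return(0)
  choose_nk <- if (k == 0) 1 else prod((n - k + 1):n) / prod(1:k)
  choose_nk * p^k * (1 - p)^(n - k)
}

pois_pmf_oracle <- function(k, lambda) {
  if (k < 0) return(0)
  kf <- if (k == 0) 1 else prod(1:k)
  lambda^k * exp(-lambda) / kf
}

conversion_posterior_oracle <- function(k, n, eps_s, rho) {
  a <- rho * binom_pmf_oracle(k, n, 1 - eps_s)
  b <- (1 - rho) * binom_pmf_oracle(k, n, eps_s)
  if (a + b == 0) return(0)
  a / (a + b)
}

new_posterior_oracle <- function(km, nm, rho_l, eps_c, theta) {
  k <- round(km)
  a <- theta * pois_pmf_oracle(k, nm * rho_l)
  b <- (1 - theta) * binom_pmf_oracle(k, nm, eps_c)
  if (a + b == 0) return(if (theta >= 0.5) 1 else 0)
  a / (a + b)
}

# Brute-force extremum scan on a dense periodic value vector: plain loops,
# direct prominence arithmetic. Returns the peak count under the
# quarter-of-global-difference rule.
brute_force_peaks <- function(values, fc_threshold = 1.5,
                              prominence_frac = 0.25) {
  n <- length(values)
  at <- function(i) values[((i - 1) %% n) + 1]
  maxima <- integer(0)
  minima <- integer(0)
  for (i in seq_len(n)) {
    if (at(i) > at(i - 1) && at(i) >= at(i + 1)) maxima <- c(maxima, i)
    if (at(i) < at(i - 1) && at(i) <= at(i + 1)) minima <- c(minima, i)
  }
  dg <- max(values) - min(values)
  fc <- max(values) / min(values)
  if (fc < fc_threshold || length(maxima) == 0) return(0L)
  global_ix <- maxima[which.max(values[maxima])]
  count <- 0L
  for (ix in maxima) {
    if (ix == global_ix) {
      count <- count + 1L
      next
    }
    prev_min <- minima[minima < ix]
    next_min <- minima[minima > ix]
    pm <- if (length(prev_min)) max(prev_min) else max(minima)
    nm <- if (length(next_min)) min(next_min) else min(minima)
    if (values[ix] - max(values[pm], values[nm]) >= prominence_frac * dg) {
      count <- count + 1L
    }
  }
  count
}

# Canonical gently modulated sinusoidal-rate scenario (10% modulation),
# the regime in which the short-labeling estimators are valid.
sinusoidal_rates <- function(grid, beta = 12) {
  rate_profiles(
    grid,
    alpha = 10 * (1 + 0.1 * sin(grid$phi)),
    beta = beta,
    gamma = 0.5 * (1 + 0.1 * sin(grid$phi + 1))
  )
}

# Exact forward data for the precursor-free (simplified) model.
simplified_forward <- function(grid, t, rates = NULL) {
  if (is.null(rates)) rates <- sinusoidal_rates(grid, beta = 1)
  totals <- simulate_total_profiles(rates, species = "mature")
  simulate_labeled_profiles(rates, totals, t = t)
}

# Small deterministic tagged-read group with known per-position truth,
# for merge oracles.
make_read <- function(cell = "c1", umi = "u1", gene = "g1",
                      start, end, tags = "exonic",
                      t_sites = integer(0), conv_pos = integer(0)) {
  tibble::tibble(
    cell_barcode = cell, umi = umi, gene = gene, contig = gene,
    intervals = list(matrix(c(start, end), ncol = 2,
                            dimnames = list(NULL, c("start", "end")))),
    region_tags = list(tags),
    n_T = length(t_sites),
    t_sites = list(t_sites),
    conversions = list(data.frame(position = conv_pos,
                                  supporting = rep(TRUE, length(conv_pos))))
  )
}

# Marker/housekeeping panel over a flat background gene so that library
# totals are essentially phase-independent (as in transcriptome-wide data).
downsample_panel <- function(n_cells = 400, seed = 21) {
  set.seed(seed)
  phases <- stats::runif(n_cells, 0, 2 * pi)
  amp <- c(mk1 = 3, mk2 = 5, mk3 = 8, hk1 = 0, hk2 = 0, bg = 0)
  base <- c(mk1 = 10, mk2 = 10, mk3 = 10, hk1 = 10, hk2 = 10, bg = 500)
  counts <- t(vapply(names(amp), function(g) {
    stats::rpois(n_cells, base[[g]] + amp[[g]] * sin(phases))
  }, numeric(n_cells)))
  rownames(counts) <- names(amp)
  truth <- tibble::tibble(
    gene = names(amp),
    label = ifelse(amp > 0, "marker", "housekeeping")
  )
  list(counts = counts, phases = phases, truth = truth)
}
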