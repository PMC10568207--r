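#' Built-in periodic target profile: raised sine
#'
#' Convenience constructor for the target mature-expression profile
#' \eqn{m(\Phi) = b + a\,\sin(\Phi + s)} with analytic derivatives, used by
#' the case constructions. The amplitude must keep the profile (and all
#' derived rates) positive.
#'
#' @param base Baseline expression level `b` (> `amplitude`).
#' @param amplitude Sine amplitude `a`.
#' @param shift Phase shift `s` in radians.
#' @return A list of functions `m`, `dm`, `d2m` of phase.
#' @export
sine_target <- function(base = 20, amplitude = 8, shift = 0) {
  stopifnot(base > abs(amplitude))
  list(
    m = function(phi) base + amplitude * sin(phi + shift),
    dm = function(phi) amplitude * cos(phi + shift),
    d2m = function(phi) -amplitude * sin(phi + shift)
  )
}

# Evaluate a target (function list or tabulated vector) on the grid,
# returning m, m', m''. Tabulated targets are differentiated spectrally
# (Fourier), which is exact for band-limited periodic profiles and has no
# boundary artifacts.
target_on_grid <- function(target, grid) {
  if (is.list(target) && is.function(target$m)) {
    dm <- if (is.function(target$dm)) target$dm(grid$phi) else NULL
    d2m <- if (is.function(target$d2m)) target$d2m(grid$phi) else NULL
    m <- target$m(grid$phi)
    if (is.null(dm) || is.null(d2m)) {
      sp <- spectral_derivatives(m)
      if (is.null(dm)) dm <- sp$d1
      if (is.null(d2m)) d2m <- sp$d2
    }
    list(m = m, dm = dm, d2m = d2m)
  } else if (is.numeric(target)) {
    stopifnot(length(target) == grid$n)
    sp <- spectral_derivatives(target)
    list(m = target, dm = sp$d1, d2m = sp$d2)
  } else {
    stop("target must be a function list (m, dm, d2m) or a numeric grid vector")
  }
}

# First and second derivatives of a periodic series on a uniform grid over
# [0, 2pi) via FFT.
spectral_derivatives <- function(y) {
  n <- length(y)
  kk <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)
  if (n %% 2 == 0) kk[n / 2 + 1] <- 0 # drop unpaired Nyquist mode for d1
  ft <- stats::fft(y)
  d1 <- Re(stats::fft(ft * (1i * kk), inverse = TRUE)) / n
  kk2 <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)
  d2 <- Re(stats::fft(ft * -(kk2^2), inverse = TRUE)) / n
  list(d1 = d1, d2 = d2)
}

#' Case I rates: constant degradation, dynamic transcription
#'
#' Given a target mature profile \eqn{m(\Phi)}, constant splicing `beta` and
#' constant degradation `gamma`, the transcription profile that generates the
#' target is
#' \deqn{\alpha(\Phi) = \gamma m + \omega\left(1 + \frac{\gamma}{\beta}\right)m'
#'   + \frac{\omega^2}{\beta} m''.}
#'
#' @param target Target profile: a [sine_target()]-style function list or a
#'   numeric vector on the grid (then differentiated spectrally).
#' @param beta Constant splicing rate (1/h).
#' @param gamma Constant degradation rate (1/h).
#' @param grid A [phase_grid()].
#' @return A [rate_profiles()] tibble.
#' @export
rates_case1 <- function(target, beta, gamma, grid) {
  tg <- target_on_grid(target, grid)
  w <- grid$omega
  alpha <- gamma * tg$m + w * (1 + gamma / beta) * tg$dm +
    w^2 / beta * tg$d2m
  if (any(alpha < 0)) {
    stop("derived transcription rate is negative; reduce the target amplitude")
  }
  rate_profiles(grid, alpha = alpha, beta = beta, gamma = gamma)
}

#' Case II rates: constant transcription, dynamic degradation
#'
#' With constant `alpha` and `beta`, the precursor profile is
#' \eqn{p(\Phi) = \alpha/\beta + (p_0 - \alpha/\beta)e^{-\beta\Phi/\omega}}
#' and the degradation profile generating the target is
#' \deqn{\gamma(\Phi) = \frac{\alpha + (\beta p_0 - \alpha)
#'   e^{-\beta\Phi/\omega}}{m(\Phi)} - \omega\frac{m'(\Phi)}{m(\Phi)}.}
#' The default `p0 = alpha/beta` removes the (extremely fast-decaying)
#' transient and makes the construction exactly periodic.
#'
#' @param target Target mature profile (see [rates_case1()]).
#' @param alpha Constant transcription rate.
#' @param beta Constant splicing rate (1/h).
#' @param grid A [phase_grid()].
#' @param p0 Initial precursor level at phase 0.
#' @return A [rate_profiles()] tibble.
#' @export
rates_case2 <- function(target, alpha, beta, grid, p0 = alpha / beta) {
  tg <- target_on_grid(target, grid)
  if (any(tg$m <= 0)) stop("target profile must be strictly positive")
  w <- grid$omega
  gamma <- (alpha + (beta * p0 - alpha) * exp(-beta * grid$phi / w)) / tg$m -
    w * tg$dm / tg$m
  if (any(gamma <= 0)) {
    stop("derived degradation rate is non-positive; increase alpha or reduce amplitude")
  }
  rate_profiles(grid, alpha = alpha, beta = beta, gamma = gamma)
}

#' Case III rates: prescribed dynamic degradation, dynamic transcription
#'
#' Generalizes Case I to a differentiable degradation profile
#' \eqn{\gamma(\Phi)}:
#' \deqn{\alpha(\Phi) = \left(\gamma + \frac{\omega\gamma'}{\beta}\right)m
#'   + \omega\left(1 + \frac{\gamma}{\beta}\right)m'
#'   + \frac{\omega^2}{\beta}m''.}
#' With constant \eqn{\gamma} this reduces exactly to Case I.
#'
#' @param target Target mature profile (see [rates_case1()]).
#' @param beta Constant splicing rate (1/h).
#' @param gamma_profile Degradation profile: list with functions `g` and
#'   optionally `dg`, or a numeric vector on the grid (spectral derivative).
#' @param grid A [phase_grid()].
#' @return A [rate_profiles()] tibble.
#' @export
rates_case3 <- function(target, beta, gamma_profile, grid) {
  tg <- target_on_grid(target, grid)
  if (is.list(gamma_profile) && is.function(gamma_profile$g)) {
    g <- gamma_profile$g(grid$phi)
    dg <- if (is.function(gamma_profile$dg)) {
      gamma_profile$dg(grid$phi)
    } else {
      spectral_derivatives(g)$d1
    }
  } else {
    stopifnot(is.numeric(gamma_profile), length(gamma_profile) == grid$n)
    g <- gamma_profile
    dg <- spectral_derivatives(g)$d1
  }
  w <- grid$omega
  alpha <- (g + w * dg / beta) * tg$m + w * (1 + g / beta) * tg$dm +
    w^2 / beta * tg$d2m
  if (any(alpha < 0)) {
    stop("derived transcription rate is negative; reduce amplitudes")
  }
  rate_profiles(grid, alpha = alpha, beta = beta, gamma = g)
}

#' The three regulation regimes sharing one expression profile
#'
#' Builds Cases I, II and III on a common target mature profile: the same
#' \eqn{m(\Phi)} arises from dynamic transcription with constant degradation
#' (I), constant transcription with dynamic degradation (II), and both
#' dynamic (III). Defaults give the raised-sine target
#' \eqn{m = 20 + 8\sin\Phi} with \eqn{\beta = 12}/h, Case I
#' \eqn{\gamma = 0.5}/h, Case II \eqn{\alpha = 10}/h and Case III
#' \eqn{\gamma(\Phi) = 0.5 + 0.2\sin(\Phi + 1)}.
#'
#' @param grid A [phase_grid()].
#' @param target Target profile (default `sine_target(20, 8)`).
#' @param beta Constant splicing rate.
#' @param gamma_case1 Constant degradation rate for Case I.
#' @param alpha_case2 Constant transcription rate for Case II.
#' @param gamma_case3 Degradation profile list for Case III.
#' @return Named list of [rate_profiles()] tibbles (`case1`, `case2`,
#'   `case3`).
#' @export
shared_target_cases <- function(grid,
                                target = sine_target(20, 8),
                                beta = 12,
                                gamma_case1 = 0.5,
                                alpha_case2 = 10,
                                gamma_case3 = list(
                                  g = function(phi) 0.5 + 0.2 * sin(phi + 1),
                                  dg = function(phi) 0.2 * cos(phi + 1)
                                )) {
  list(
    case1 = rates_case1(target, beta = beta, gamma = gamma_case1, grid = grid),
    case2 = rates_case2(target, alpha = alpha_case2, beta = beta, grid = grid),
    case3 = rates_case3(target, beta = beta, gamma_profile = gamma_case3,
                        grid = grid)
  )
}

#' Sample single cells from phase-resolved expression profiles
#'
#' Emulates a droplet experiment on an unsynchronized population: cell phases
#' are uniform on \eqn{[0, 2\pi)}, each cell has a lognormal capture factor
#' (mean 1), and each of the four species is sampled Poisson with mean
#' `depth * capture * profile(phase)`. The noise model (Poisson counts times
#' lognormal capture) is this generator's own choice and is configurable.
#'
#' @param profiles A single `expression_profiles` tibble or a named list of
#'   them (one per gene).
#' @param n_cells Number of cells.
#' @param depth Global depth scaling factor.
#' @param capture_sigma Lognormal sigma of the per-cell capture factor
#'   (0 disables capture variation).
#' @param seed Integer seed; same seed, same matrices.
#' @return A `labeled_counts` object; `cells` carries `phase` (radians) and
#'   `labeling_time` (hours, from the profile attribute).
#' @export
sample_cells <- function(profiles, n_cells, depth = 1, capture_sigma = 0.25,
                         seed) {
  stopifnot(n_cells >= 1, depth >= 0)
  if (inherits(profiles, "expression_profiles")) {
    profiles <- list(gene1 = profiles)
  }
  stopifnot(length(profiles) >= 1, !is.null(names(profiles)))
  set.seed(seed)
  t_label <- attr(profiles[[1]], "labeling_time")
  phases <- stats::runif(n_cells, 0, 2 * pi)
  capture <- if (capture_sigma > 0) {
    stats::rlnorm(n_cells, meanlog = -capture_sigma^2 / 2, sdlog = capture_sigma)
  } else {
    rep(1, n_cells)
  }
  genes <- names(profiles)
  species <- c("pl", "ml", "pu", "mu")
  mats <- lapply(species, function(sp) {
    m <- matrix(0, nrow = length(genes), ncol = n_cells,
                dimnames = list(genes, sprintf("cell%05d", seq_len(n_cells))))
    for (g in seq_along(genes)) {
      prof <- profiles[[g]]
      f <- periodic_interpolant(attr(prof, "grid")$phi, prof[[sp]])
      mean_counts <- pmax(depth * capture * f(phases), 0)
      m[g, ] <- stats::rpois(n_cells, mean_counts)
    }
    Matrix::Matrix(m, sparse = TRUE)
  })
  names(mats) <- species
  cells <- tibble::tibble(
    cell_barcode = sprintf("cell%05d", seq_len(n_cells)),
    phase = phases,
    labeling_time = if (is.null(t_label)) NA_real_ else t_label,
    capture = capture
  )
  labeled_counts(pl = mats$pl, ml = mats$ml, pu = mats$pu, mu = mats$mu,
                 cells = cells)
}

#' Simulate a tagged-read table with known labeling truth
#'
#' Generates read-level evidence for a set of molecules with known
#' new/preexisting labels: a labeled molecule with `nm` covered Ts receives
#' `Poisson(nm * rho_l)` conversions (capped at `nm`, placed on distinct T
#' positions); a preexisting molecule receives `Binomial(nm, eps_c)` false
#' positives. Each molecule is emitted as 1-5 overlapping read fragments
#' whose union covers its footprint; with `eps_s > 0` each read additionally
#' flips each covered non-converted T with that probability (sequencing
#' error).
#'
#' @param molecule_truth Tibble with columns `gene`, `new` (logical), `nm`
#'   (T count) and optionally `cell_barcode`, `splice_status`.
#' @param rho_l Conversion rate in labeled molecules.
#' @param eps_c Conversion false-positive rate in preexisting molecules.
#' @param eps_s Per-read per-position sequencing error rate (default 0:
#'   error-free reads, so merged evidence equals the planted truth).
#' @param seed Integer seed.
#' @return A list with `reads` (tagged-read tibble) and `truth`
#'   (`molecule_truth` plus `umi` and planted `n_conversions`).
#' @export
simulate_read_table <- function(molecule_truth, rho_l, eps_c = 0, eps_s = 0,
                                seed) {
  stopifnot(rho_l >= eps_c, eps_c >= 0)
  stopifnot(all(c("gene", "new", "nm") %in% names(molecule_truth)))
  set.seed(seed)
  nmol <- nrow(molecule_truth)
  truth <- tibble::as_tibble(molecule_truth)
  if (!"cell_barcode" %in% names(truth)) truth$cell_barcode <- "cell00001"
  if (!"splice_status" %in% names(truth)) truth$splice_status <- "spliced"
  truth$umi <- sprintf("umi%06d", seq_len(nmol))
  draws <- ifelse(truth$new,
                  stats::rpois(nmol, truth$nm * rho_l),
                  stats::rbinom(nmol, truth$nm, eps_c))
  truth$n_conversions <- pmin(draws, truth$nm)
  reads <- vector("list", nmol)
  for (i in seq_len(nmol)) {
    nm <- truth$nm[i]
    len <- max(40L, 4L * nm)
    start <- sample.int(10000L, 1)
    t_sites <- sort(start - 2L + sample.int(len, nm))
    conv_pos <- if (truth$n_conversions[i] > 0) {
      sort(sample(t_sites, truth$n_conversions[i]))
    } else integer(0)
    n_reads <- sample.int(5L, 1)
    # fragment the footprint into n_reads overlapping chunks covering it
    bounds <- round(seq(start - 1L, start - 1L + len, length.out = n_reads + 1))
    ext <- max(5L, ceiling(len / (4 * n_reads)))
    ivals <- lapply(seq_len(n_reads), function(j) {
      c(max(start - 1L, bounds[j] - ext), min(start - 1L + len, bounds[j + 1] + ext))
    })
    tags <- rep("exonic", n_reads)
    if (truth$splice_status[i] == "unspliced") tags[1] <- "intronic"
    if (truth$splice_status[i] == "ambiguous") tags[] <- "ambiguous"
    rr <- lapply(seq_len(n_reads), function(j) {
      iv <- ivals[[j]]
      ts <- t_sites[t_sites >= iv[1] & t_sites < iv[2]]
      cp <- conv_pos[conv_pos >= iv[1] & conv_pos < iv[2]]
      if (eps_s > 0 && length(ts) > 0) {
        clean <- setdiff(ts, cp)
        flips <- clean[stats::runif(length(clean)) < eps_s]
        cp <- sort(c(cp, flips))
      }
      tibble::tibble(
        cell_barcode = truth$cell_barcode[i],
        umi = truth$umi[i],
        gene = truth$gene[i],
        contig = truth$gene[i],
        intervals = list(matrix(iv, ncol = 2,
                                dimnames = list(NULL, c("start", "end")))),
        region_tags = list(tags[j]),
        n_T = length(ts),
        t_sites = list(ts),
        conversions = list(data.frame(position = cp,
                                      supporting = rep(TRUE, length(cp))))
      )
    })
    reads[[i]] <- dplyr::bind_rows(rr)
  }
  list(reads = dplyr::bind_rows(reads), truth = truth)
}

#' Write a complete synthetic dataset to disk
#'
#' Runs one scenario end to end: builds the case rates, simulates the
#' periodic totals and labeled profiles, samples cells, and writes
#' `truth_rates.tsv`, `profiles.tsv`, the four Matrix Market matrices with
#' `barcodes.tsv`/`features.tsv`, `cells.tsv` and a `provenance.json`
#' recording the configuration and seed.
#'
#' @param dir Output directory (created if needed).
#' @param rates A [rate_profiles()] tibble (e.g. from [rates_case1()]).
#' @param labeling_time Labeling time in hours.
#' @param n_cells Cells to sample.
#' @param depth,capture_sigma Passed to [sample_cells()].
#' @param seed Integer seed (recorded in the provenance file).
#' @return `dir`, invisibly.
#' @export
simulate_dataset <- function(dir, rates, labeling_time = 1, n_cells = 1000,
                             depth = 1, capture_sigma = 0.25, seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- attr(rates, "grid")
  totals <- simulate_total_profiles(rates)
  prof <- simulate_labeled_profiles(rates, totals, t = labeling_time)
  counts <- sample_cells(list(gene1 = prof), n_cells = n_cells, depth = depth,
                         capture_sigma = capture_sigma, seed = seed)
  readr::write_tsv(tibble::as_tibble(rates), file.path(dir, "truth_rates.tsv"))
  readr::write_tsv(tibble::as_tibble(prof), file.path(dir, "profiles.tsv"))
  write_labeled_counts(counts, dir)
  jsonlite::write_json(
    list(seed = seed, labeling_time = labeling_time, n_cells = n_cells,
         depth = depth, capture_sigma = capture_sigma,
         period = grid$period, grid_points = grid$n,
         package_version = as.character(utils::packageVersion("cyclerates"))),
    file.path(dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
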