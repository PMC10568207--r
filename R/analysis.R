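#' Counts-per-million normalization
#'
#' Divides each cell's counts by its total captured molecules and scales to
#' one million. Cells with zero totals are dropped with a message.
#'
#' @param counts Gene-by-cell matrix (dense or sparse).
#' @param totals Per-cell totals; defaults to the matrix's own column sums
#'   (then normalized columns sum to 1e6 exactly).
#' @return Normalized matrix of the same class, possibly with zero-total
#'   columns removed.
#' @export
normalize_cpm <- function(counts, totals = Matrix::colSums(counts)) {
  stopifnot(length(totals) == ncol(counts))
  zero <- totals <= 0
  if (any(zero)) {
    message(sum(zero), " zero-total cell(s) dropped in CPM normalization")
    counts <- counts[, !zero, drop = FALSE]
    totals <- totals[!zero]
  }
  out <- counts %*% Matrix::Diagonal(x = 1e6 / totals, names = FALSE)
  if (is.matrix(counts)) out <- as.matrix(out)
  dimnames(out) <- dimnames(counts)
  out
}

#' Cyclic penalized-spline smoothing of a per-cell profile
#'
#' Fits a generalized additive model with a cyclic cubic spline basis over
#' the cell-cycle phase (`mgcv`, `bs = "cc"`, basis dimension `k = 20`,
#' smoothness-selection inflation `gamma = 1.4`), giving a periodic smooth
#' \eqn{f(0) = f(2\pi)} of noisy single-cell values.
#'
#' @param phase Cell phases in radians.
#' @param values Per-cell values (counts or CPM).
#' @param k Spline basis dimension.
#' @param sp_gamma Smoothness-selection inflation factor passed to
#'   [mgcv::gam()]'s `gamma`.
#' @return An object of class `smooth_profile`: the fitted `gam` plus fast
#'   evaluators for the smooth and its derivative.
#' @export
smooth_profile <- function(phase, values, k = 20, sp_gamma = 1.4) {
  stopifnot(length(phase) == length(values))
  if (length(unique(phase)) < k) {
    stop("need at least k = ", k, " distinct phases to fit the cyclic spline")
  }
  d <- data.frame(phase = phase %% (2 * pi), y = values)
  fit <- mgcv::gam(y ~ s(phase, bs = "cc", k = k), data = d,
                   gamma = sp_gamma, knots = list(phase = c(0, 2 * pi)))
  dense_phi <- 2 * pi * (0:999) / 1000
  dense_val <- as.numeric(mgcv::predict.gam(fit, data.frame(phase = dense_phi)))
  f <- stats::splinefun(c(dense_phi, 2 * pi), c(dense_val, dense_val[1]),
                        method = "periodic")
  structure(
    list(fit = fit,
         value = function(p) f(p %% (2 * pi)),
         deriv = function(p) f(p %% (2 * pi), deriv = 1)),
    class = "smooth_profile"
  )
}

#' @export
print.smooth_profile <- function(x, ...) {
  cat("<smooth_profile> cyclic penalized spline; edf =",
      round(sum(x$fit$edf), 2), "\n")
  invisible(x)
}

#' Evaluate a smooth profile on a phase grid
#'
#' @param sp A `smooth_profile` (or any function of phase).
#' @param grid A [phase_grid()].
#' @return Numeric vector of fitted values at the grid phases.
#' @export
profile_on_grid <- function(sp, grid) {
  f <- if (inherits(sp, "smooth_profile")) sp$value else sp
  f(grid$phi)
}

local_extrema <- function(v) {
  n <- length(v)
  prv <- c(v[n], v[-n])
  nxt <- c(v[-1], v[1])
  list(maxima = which(v > prv & v >= nxt), minima = which(v < prv & v <= nxt))
}

#' Peak calling on a periodic profile
#'
#' A profile is *peaking* when its global fold change
#' \eqn{fc = \max/\min \ge 1.5}. For peaking profiles, the global maximum
#' always counts as a peak; every other local maximum counts only if its
#' prominence over the larger of the two adjacent local minima reaches a
#' quarter of the global difference \eqn{\max - \min}. Extrema are located
#' on a dense grid with periodic wrap-around. Non-positive minima are
#' floored at a small fraction of the maximum before the ratio, with a
#' warning.
#'
#' @param profile A `smooth_profile`, a function of phase, or a numeric
#'   vector interpreted on a uniform grid over \eqn{[0, 2\pi)}.
#' @param n_grid Dense evaluation grid size.
#' @param fc_threshold Peaking fold-change threshold.
#' @param prominence_frac Required secondary-peak prominence as a fraction of
#'   the global difference.
#' @return A list of class `peak_call`: `is_peaking`, `n_peaks`,
#'   `peak_phases`, `fc_global`, `diff_global`.
#' @examples
#' pc <- find_peaks(function(phi) 2 + sin(phi))
#' pc$n_peaks # 1
#' @export
find_peaks <- function(profile, n_grid = 1000, fc_threshold = 1.5,
                       prominence_frac = 0.25) {
  phi <- 2 * pi * (0:(n_grid - 1)) / n_grid
  v <- if (is.numeric(profile)) {
    stats::approx(
      x = c(2 * pi * (seq_along(profile) - 1) / length(profile), 2 * pi),
      y = c(profile, profile[1]), xout = phi
    )$y
  } else {
    profile_on_grid(profile, list(phi = phi))
  }
  vmax <- max(v)
  vmin <- min(v)
  diff_global <- vmax - vmin
  vfloor <- vmin
  if (vmin <= 0) {
    warning("profile minimum <= 0; fold change computed on floored values")
    vfloor <- max(1e-9 * vmax, .Machine$double.xmin)
  }
  fc_global <- vmax / vfloor
  ex <- local_extrema(v)
  if (!(fc_global >= fc_threshold) || length(ex$maxima) == 0) {
    return(structure(list(is_peaking = FALSE, n_peaks = 0L,
                          peak_phases = numeric(0), fc_global = fc_global,
                          diff_global = diff_global),
                     class = "peak_call"))
  }
  # circular alternating sequence of extrema; each max has two flanking minima
  maxima <- ex$maxima
  minima <- ex$minima
  global_ix <- maxima[which.max(v[maxima])]
  keep <- vapply(maxima, function(ix) {
    if (ix == global_ix) return(TRUE)
    if (length(minima) == 0) return(FALSE)
    pos <- sort(minima)
    prev_min <- if (any(pos < ix)) max(pos[pos < ix]) else max(pos)
    next_min <- if (any(pos > ix)) min(pos[pos > ix]) else min(pos)
    prom <- v[ix] - max(v[prev_min], v[next_min])
    prom >= prominence_frac * diff_global
  }, logical(1))
  peaks <- maxima[keep]
  structure(list(is_peaking = TRUE, n_peaks = length(peaks),
                 peak_phases = sort(phi[peaks]), fc_global = fc_global,
                 diff_global = diff_global),
            class = "peak_call")
}

#' @export
print.peak_call <- function(x, ...) {
  cat(sprintf("<peak_call> peaking: %s; %d peak(s); fc = %.3g, diff = %.3g\n",
              x$is_peaking, x$n_peaks, x$fc_global, x$diff_global))
  invisible(x)
}

#' Is a gene cycling?
#'
#' A gene is cycling when its smoothed expression profile is peaking with
#' exactly one peak over the cell cycle.
#'
#' @param peak_call A [find_peaks()] result for the expression profile.
#' @return Logical.
#' @export
classify_cycling <- function(peak_call) {
  isTRUE(peak_call$is_peaking) && peak_call$n_peaks == 1L
}

#' Mean absolute relative deviation between prediction and observation
#'
#' \eqn{dev = \frac{1}{m}\sum_i |pred_i - obs_i| / obs_i}. Points with zero
#' observation are excluded (with a message). Scale-invariant: rescaling
#' both vectors by the same factor leaves `dev` unchanged.
#'
#' @param pred,obs Numeric vectors of equal length.
#' @return A single non-negative number.
#' @examples
#' deviation(1.2 * (1:10), 1:10) # 0.2
#' @export
deviation <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  keep <- obs != 0
  if (!all(keep)) {
    message(sum(!keep), " zero-observation point(s) excluded from deviation")
  }
  mean(abs(pred[keep] - obs[keep]) / obs[keep])
}

# Max deviation over the three mature readouts (labeled, unlabeled, total).
max_mature_deviation <- function(pred, obs) {
  max(deviation(pred$mu, obs$mu),
      deviation(pred$ml, obs$ml),
      deviation(pred$m, obs$m))
}

#' Deviation of constant-rate predictions from dynamic predictions
#'
#' Quantifies how much a rate's time dependence matters: predictions with
#' the chosen rate replaced by its cycle summary are compared to the
#' dynamic-rate predictions, as a mean absolute relative deviation maximized
#' over the three mature readouts (labeled, unlabeled, total).
#'
#' @param estimates A `rate_estimates` tibble.
#' @param m Total mature profile on the grid (baseline for dynamic
#'   predictions).
#' @param t Labeling time (hours).
#' @param grid A [phase_grid()].
#' @param which `"transcription"` or `"degradation"`.
#' @param ... Passed to [predict_with_constant_rate()].
#' @return A single non-negative number (`dev_c`).
#' @export
constant_rate_deviation <- function(estimates, m,
                                    t = attr(estimates, "labeling_time"),
                                    grid = attr(estimates, "grid"),
                                    which = c("transcription", "degradation"),
                                    ...) {
  which <- match.arg(which)
  pred_dyn <- predict_mature_profiles(estimates, m = m, t = t, grid = grid)
  pred_const <- predict_with_constant_rate(estimates, t = t, grid = grid,
                                           which = which, ...)
  max_mature_deviation(pred_const, pred_dyn)
}

#' Kinetic-mode classification from constant-rate deviations
#'
#' A gene whose predictions degrade when transcription is held constant but
#' not when degradation is held constant is driven by dynamic transcription,
#' and vice versa; both large means both rates matter; neither means the
#' profiles are compatible with fully constant kinetics.
#'
#' @param dev_c_alpha Deviation under constant transcription.
#' @param dev_c_gamma Deviation under constant degradation.
#' @param threshold Decision threshold (default 0.2, the well-predicted
#'   cutoff; the separating value is a package choice, configurable).
#' @return Character vector over the inputs: `"dynamic transcription"`,
#'   `"dynamic degradation"`, `"both"` or `"other"`.
#' @examples
#' classify_kinetic_mode(0.5, 0.05) # dynamic transcription
#' @export
classify_kinetic_mode <- function(dev_c_alpha, dev_c_gamma, threshold = 0.2) {
  stopifnot(all(dev_c_alpha >= 0), all(dev_c_gamma >= 0))
  dplyr::case_when(
    dev_c_alpha > threshold & dev_c_gamma <= threshold ~ "dynamic transcription",
    dev_c_alpha <= threshold & dev_c_gamma > threshold ~ "dynamic degradation",
    dev_c_alpha > threshold & dev_c_gamma > threshold ~ "both",
    TRUE ~ "other"
  )
}

#' Mean RNA half-life from a degradation-rate profile
#'
#' \eqn{t_{1/2} = \ln 2 / \bar\gamma} with \eqn{\bar\gamma} the cycle mean of
#' the estimated degradation rate, in hours.
#'
#' @param gamma Degradation-rate profile on the grid (1/h).
#' @return Half-life in hours, or `NA` when the mean rate is non-positive.
#' @examples
#' mean_half_life(rep(log(2), 10)) # 1 hour
#' @export
mean_half_life <- function(gamma) {
  gbar <- mean(gamma)
  if (!is.finite(gbar) || gbar <= 0) return(NA_real_)
  log(2) / gbar
}

#' Simplified-model rates from per-cell observations
#'
#' Smooths the labeled and unlabeled mature values over the cell cycle
#' (cyclic penalized splines), evaluates the smooths on the grid, floors
#' them at a small positive fraction of their maximum, and applies the
#' simplified-model estimators.
#'
#' @param cells Tibble with per-cell columns `phase`, `mu`, `ml`.
#' @param t Labeling time in hours.
#' @param grid A [phase_grid()].
#' @param k,sp_gamma Smoothing parameters, see [smooth_profile()].
#' @return A list with `estimates` (a `rate_estimates` tibble), `smoothed`
#'   (tibble `phase`, `mu`, `ml`, `m` on the grid) and the two
#'   `smooth_profile` fits.
#' @export
estimate_rates_from_cells <- function(cells, t, grid, k = 20, sp_gamma = 1.4) {
  stopifnot(all(c("phase", "mu", "ml") %in% names(cells)))
  sp_mu <- smooth_profile(cells$phase, cells$mu, k = k, sp_gamma = sp_gamma)
  sp_ml <- smooth_profile(cells$phase, cells$ml, k = k, sp_gamma = sp_gamma)
  mu_g <- profile_on_grid(sp_mu, grid)
  ml_g <- profile_on_grid(sp_ml, grid)
  # smoothed values can dip <= 0; floor before ratios and logs
  mu_g <- pmax(mu_g, 1e-9 * max(mu_g))
  ml_g <- pmax(ml_g, 1e-9 * max(ml_g))
  smoothed <- tibble::tibble(phase = grid$phi, mu = mu_g, ml = ml_g,
                             m = mu_g + ml_g)
  est <- estimate_rates_simplified(smoothed, t = t, grid = grid)
  list(estimates = est, smoothed = smoothed, sp_mu = sp_mu, sp_ml = sp_ml)
}

#' Full per-gene kinetic characterization
#'
#' Runs the downstream pipeline for one gene: smoothing, simplified-model
#' rate estimation, dynamic and constant-rate predictions, deviations,
#' peak calls on expression and rate profiles, cycling / well-predicted /
#' robust-cycling classification, kinetic mode and mean half-life.
#'
#' @param cells Tibble with per-cell `phase`, `mu`, `ml`.
#' @param t Labeling time in hours.
#' @param grid A [phase_grid()].
#' @param dev_threshold Well-predicted cutoff on `dev` (default 0.2).
#' @param mode_threshold Kinetic-mode cutoff on `dev_c` (default 0.2).
#' @param ... Passed to [estimate_rates_from_cells()].
#' @return An object of class `gene_kinetics`: estimates, smoothed and
#'   predicted profiles, peak calls and the scalar classification results.
#' @export
fit_gene_kinetics <- function(cells, t, grid, dev_threshold = 0.2,
                              mode_threshold = 0.2, ...) {
  fitted <- estimate_rates_from_cells(cells, t = t, grid = grid, ...)
  est <- fitted$estimates
  obs <- fitted$smoothed
  pred <- predict_mature_profiles(est, m = obs$m, t = t, grid = grid)
  dev <- max_mature_deviation(pred, obs)
  dev_c_alpha <- constant_rate_deviation(est, m = obs$m, t = t, grid = grid,
                                         which = "transcription")
  dev_c_gamma <- constant_rate_deviation(est, m = obs$m, t = t, grid = grid,
                                         which = "degradation")
  peaks_expr <- find_peaks(periodic_interpolant(grid$phi, obs$m))
  peaks_alpha <- find_peaks(periodic_interpolant(grid$phi, est$alpha))
  peaks_gamma <- find_peaks(periodic_interpolant(grid$phi, est$gamma))
  cycling <- classify_cycling(peaks_expr)
  well_predicted <- cycling && dev <= dev_threshold
  robust <- well_predicted && peaks_alpha$n_peaks <= 1 &&
    peaks_gamma$n_peaks <= 1
  structure(
    list(
      estimates = est, smoothed = obs, predicted = pred,
      peaks = list(expression = peaks_expr, alpha = peaks_alpha,
                   gamma = peaks_gamma),
      dev = dev, dev_c_alpha = dev_c_alpha, dev_c_gamma = dev_c_gamma,
      cycling = cycling, well_predicted = well_predicted,
      robust_cycling = robust,
      mode = classify_kinetic_mode(dev_c_alpha, dev_c_gamma, mode_threshold),
      half_life = mean_half_life(est$gamma),
      labeling_time = t, grid = grid
    ),
    class = "gene_kinetics"
  )
}

#' @export
print.gene_kinetics <- function(x, ...) {
  cat(sprintf(
    "<gene_kinetics> cycling: %s; well-predicted: %s (dev = %.3g); mode: %s; t1/2 = %.3g h\n",
    x$cycling, x$well_predicted, x$dev, x$mode, x$half_life
  ))
  invisible(x)
}

#' Robust-cycling filter
#'
#' A gene is robust-cycling when it is well-predicted (hence cycling) and
#' neither its transcription nor its degradation profile has more than one
#' peak.
#'
#' @param gene A `gene_kinetics` object.
#' @return Logical.
#' @export
robust_cycling_filter <- function(gene) {
  stopifnot(inherits(gene, "gene_kinetics"))
  gene$robust_cycling
}

#' @rdname fit_gene_kinetics
#' @param x A `gene_kinetics` object.
#' @param ... Unused.
#' @export
tidy.gene_kinetics <- function(x, ...) {
  tibble::tibble(
    is_cycling = x$cycling,
    well_predicted = x$well_predicted,
    robust_cycling = x$robust_cycling,
    dev = x$dev,
    dev_c_alpha = x$dev_c_alpha,
    dev_c_gamma = x$dev_c_gamma,
    mode = x$mode,
    half_life_hours = x$half_life,
    n_peaks_expression = x$peaks$expression$n_peaks,
    n_peaks_alpha = x$peaks$alpha$n_peaks,
    n_peaks_gamma = x$peaks$gamma$n_peaks,
    fc_global = x$peaks$expression$fc_global
  )
}

#' @rdname fit_gene_kinetics
#' @export
glance.gene_kinetics <- function(x, ...) {
  tibble::tibble(
    dev = x$dev, mode = x$mode, half_life_hours = x$half_life,
    mean_alpha = mean(x$estimates$alpha), mean_gamma = mean(x$estimates$gamma),
    labeling_time = x$labeling_time, grid_points = x$grid$n
  )
}

#' Bootstrap confidence bands for estimated rates
#'
#' Resamples cells with replacement `B` times, redoes smoothing and
#' simplified-model estimation per replicate, and reports pointwise
#' quantile bands (default 5-95%, a 90% interval) for the transcription and
#' degradation profiles. Replicates whose estimation fails are dropped and
#' counted; more than 20% failures is an error. Seed-reproducible: the
#' resampling indices are drawn once up front.
#'
#' @param cells Tibble with per-cell `phase`, `mu`, `ml`.
#' @param t Labeling time (hours).
#' @param grid A [phase_grid()].
#' @param B Number of bootstrap replicates.
#' @param probs Lower and upper quantiles of the band.
#' @param seed Integer seed.
#' @param ... Passed to [estimate_rates_from_cells()].
#' @return Tibble with columns `phase`, `alpha`, `gamma` (point estimates)
#'   and `alpha_lo`, `alpha_hi`, `gamma_lo`, `gamma_hi`; attribute
#'   `n_failed`.
#' @export
bootstrap_rates <- function(cells, t, grid, B = 100, probs = c(0.05, 0.95),
                            seed, ...) {
  stopifnot(B >= 2, length(probs) == 2)
  set.seed(seed)
  idx <- matrix(sample.int(nrow(cells), nrow(cells) * B, replace = TRUE),
                nrow = B)
  point <- estimate_rates_from_cells(cells, t = t, grid = grid, ...)$estimates
  alpha_mat <- matrix(NA_real_, nrow = B, ncol = grid$n)
  gamma_mat <- matrix(NA_real_, nrow = B, ncol = grid$n)
  n_failed <- 0L
  for (b in seq_len(B)) {
    est_b <- tryCatch(
      suppressWarnings(
        estimate_rates_from_cells(cells[idx[b, ], ], t = t, grid = grid,
                                  ...)$estimates
      ),
      error = function(e) NULL
    )
    if (is.null(est_b)) {
      n_failed <- n_failed + 1L
    } else {
      alpha_mat[b, ] <- est_b$alpha
      gamma_mat[b, ] <- est_b$gamma
    }
  }
  if (n_failed > 0.2 * B) {
    stop(sprintf("bootstrap failed in %d of %d replicates", n_failed, B))
  }
  out <- tibble::tibble(
    phase = grid$phi,
    alpha = point$alpha,
    gamma = point$gamma,
    alpha_lo = apply(alpha_mat, 2, stats::quantile, probs = probs[1], na.rm = TRUE),
    alpha_hi = apply(alpha_mat, 2, stats::quantile, probs = probs[2], na.rm = TRUE),
    gamma_lo = apply(gamma_mat, 2, stats::quantile, probs = probs[1], na.rm = TRUE),
    gamma_hi = apply(gamma_mat, 2, stats::quantile, probs = probs[2], na.rm = TRUE)
  )
  attr(out, "n_failed") <- n_failed
  out
}

#' Downsampling analysis of profile validity under dropout
#'
#' Binomially thins the total-mature count matrix to a series of fractions,
#' renormalizes, re-smooths each gene and re-classifies it as marker
#' (global fold change >= `fc_threshold` in at least `marker_prop` of the
#' iterations) or housekeeping. Against the supplied truth labels this
#' yields a true-positive-rate curve over dropout rates, and each gene is
#' declared valid for rate estimation if the TPR at its observed dropout
#' rate is at least `tpr_cutoff`.
#'
#' @param counts Gene-by-cell total mature count matrix (integer-valued).
#' @param phases Per-cell phases (radians), aligned with columns.
#' @param truth Tibble with `gene` and `label` (`"marker"`/`"housekeeping"`).
#' @param fractions Thinning fractions in (0, 1\].
#' @param iters Thinning iterations per fraction.
#' @param fc_threshold Marker fold-change threshold.
#' @param marker_prop Fraction of iterations that must pass.
#' @param tpr_cutoff Required TPR at a gene's dropout rate.
#' @param seed Integer seed.
#' @param k Spline basis dimension for re-smoothing.
#' @return A list of class `downsample_validity`: `calls` (gene x fraction
#'   marker-call proportions and dropout rates), `tpr` (TPR over fraction /
#'   dropout), `validity` (per-gene decision).
#' @export
downsample_validity <- function(counts, phases, truth,
                                fractions = seq(0.1, 1, by = 0.1),
                                iters = 100, fc_threshold = 1.5,
                                marker_prop = 0.95, tpr_cutoff = 0.95,
                                seed, k = 20) {
  if (any(fractions <= 0) || any(fractions > 1)) {
    stop("fractions must lie in (0, 1]")
  }
  stopifnot(!is.null(rownames(counts)), all(rownames(counts) %in% truth$gene))
  set.seed(seed)
  counts <- as.matrix(counts)
  genes <- rownames(counts)
  res <- list()
  for (f in fractions) {
    hits <- matrix(0L, nrow = length(genes), ncol = iters,
                   dimnames = list(genes, NULL))
    dropout <- matrix(0, nrow = length(genes), ncol = iters)
    for (it in seq_len(iters)) {
      thinned <- if (f == 1) counts else {
        matrix(stats::rbinom(length(counts), as.integer(counts), f),
               nrow = nrow(counts), dimnames = dimnames(counts))
      }
      tot <- colSums(thinned)
      keep <- tot > 0
      cpm <- t(t(thinned[, keep, drop = FALSE]) / tot[keep]) * 1e6
      ph <- phases[keep]
      for (g in seq_along(genes)) {
        sp <- smooth_profile(ph, cpm[g, ], k = k)
        v <- sp$value(2 * pi * (0:199) / 200)
        fc <- max(v) / max(min(v), 1e-9 * max(v))
        hits[g, it] <- as.integer(fc >= fc_threshold)
        dropout[g, it] <- mean(thinned[g, ] == 0)
      }
    }
    res[[as.character(f)]] <- tibble::tibble(
      gene = genes,
      fraction = f,
      prop_marker = rowMeans(hits),
      dropout_rate = rowMeans(dropout)
    )
  }
  calls <- dplyr::bind_rows(res) |>
    dplyr::left_join(truth, by = "gene") |>
    dplyr::mutate(called_marker = .data$prop_marker >= marker_prop)
  tpr <- calls |>
    dplyr::filter(.data$label == "marker") |>
    dplyr::group_by(.data$fraction) |>
    dplyr::summarise(
      dropout_rate = mean(.data$dropout_rate),
      tp = sum(.data$called_marker),
      fn = sum(!.data$called_marker),
      tpr = .data$tp / (.data$tp + .data$fn),
      .groups = "drop"
    )
  fpr <- calls |>
    dplyr::filter(.data$label == "housekeeping") |>
    dplyr::group_by(.data$fraction) |>
    dplyr::summarise(fpr = mean(.data$called_marker), .groups = "drop")
  observed <- calls |> dplyr::filter(.data$fraction == max(fractions))
  validity <- observed |>
    dplyr::mutate(
      tpr_at_dropout = vapply(.data$dropout_rate, function(d) {
        i <- which.min(abs(tpr$dropout_rate - d))
        tpr$tpr[i]
      }, numeric(1)),
      valid = .data$tpr_at_dropout >= tpr_cutoff
    ) |>
    dplyr::select("gene", "label", "dropout_rate", "tpr_at_dropout", "valid")
  structure(list(calls = calls, tpr = tpr, fpr = fpr, validity = validity),
            class = "downsample_validity")
}

#' @export
print.downsample_validity <- function(x, ...) {
  cat(sprintf("<downsample_validity> %d genes, %d fractions; %d valid\n",
              length(unique(x$calls$gene)),
              length(unique(x$calls$fraction)),
              sum(x$validity$valid)))
  invisible(x)
}

#' Pseudo-bulk expression correlation between two samples
#'
#' Diagnostic utility: averages CPM over cells per gene in each matrix and
#' reports the Pearson correlation of `log2(CPM + 1)` on shared genes.
#'
#' @param counts_a,counts_b Gene-by-cell count matrices.
#' @return Pearson correlation coefficient.
#' @export
pseudobulk_correlation <- function(counts_a, counts_b) {
  common <- intersect(rownames(counts_a), rownames(counts_b))
  stopifnot(length(common) > 1)
  mean_cpm <- function(m) {
    Matrix::rowMeans(normalize_cpm(m[common, , drop = FALSE]))
  }
  stats::cor(log2(mean_cpm(counts_a) + 1), log2(mean_cpm(counts_b) + 1))
}
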