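#' Uniform grid over one cell-cycle period
#'
#' The cell cycle is modeled as motion on a circle parameterized by the phase
#' \eqn{\Phi \in [0, 2\pi)}. A cell at phase \eqn{\Phi} advances with constant
#' angular velocity \eqn{\omega = 2\pi/T}, where \eqn{T} is the cycle period in
#' hours, so labeling time and phase are interchangeable along a trajectory.
#'
#' @param n Number of uniformly spaced grid points on \eqn{[0, 2\pi)}.
#' @param period Cell-cycle period \eqn{T} in hours.
#'
#' @return An object of class `phase_grid`: a list with elements `phi`
#'   (grid phases), `n`, `period` (hours), `omega` (rad/h) and `dphi`
#'   (grid spacing, rad).
#' @examples
#' g <- phase_grid(8)
#' g$omega * g$period # 2*pi
#' @export
phase_grid <- function(n = 500, period = 19.33) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 4, is.numeric(period), period > 0)
  n <- as.integer(n)
  structure(
    list(
      phi = 2 * pi * (seq_len(n) - 1L) / n,
      n = n,
      period = period,
      omega = 2 * pi / period,
      dphi = 2 * pi / n
    ),
    class = "phase_grid"
  )
}

#' @export
print.phase_grid <- function(x, ...) {
  cat(sprintf(
    "<phase_grid> %d points on [0, 2pi), period %.4g h (omega = %.4g rad/h)\n",
    x$n, x$period, x$omega
  ))
  invisible(x)
}

#' Periodic interpolant of values on a phase grid
#'
#' Builds a periodic cubic-spline interpolant of a profile tabulated on the
#' grid; evaluation wraps modulo \eqn{2\pi}. Used wherever a profile must be
#' read off at shifted phases such as \eqn{\Phi - \omega t}.
#'
#' @param phi Grid phases (uniform, on \eqn{[0, 2\pi)}).
#' @param values Profile values at `phi`.
#' @return A function of phase.
#' @keywords internal
periodic_interpolant <- function(phi, values) {
  stopifnot(length(phi) == length(values), length(phi) >= 4)
  f <- stats::splinefun(c(phi, phi[1] + 2 * pi), c(values, values[1]),
                        method = "periodic")
  function(p) f(p %% (2 * pi))
}

# Linear periodic interpolation (used where monotone, shape-safe reads matter).
periodic_linear <- function(phi, values) {
  x <- c(phi, phi[1] + 2 * pi)
  y <- c(values, values[1])
  function(p) stats::approx(x, y, xout = p %% (2 * pi), rule = 2)$y
}

# Cumulative trapezoid integral C(phi) of a profile on the grid, with
# C(0) = 0 and the full-cycle total attached; supports integrals over
# arbitrary [a, b] windows with modular wrapping via `window_integral`.
cumulative_integral <- function(grid, values) {
  phi_ext <- c(grid$phi, 2 * pi)
  v_ext <- c(values, values[1])
  inc <- diff(phi_ext) * (utils::head(v_ext, -1) + utils::tail(v_ext, -1)) / 2
  list(phi = phi_ext, cum = c(0, cumsum(inc)), total = sum(inc))
}

# Integral of the tabulated profile over [a, b] (b >= a), wrapping periodically.
window_integral <- function(ci, a, b) {
  eval_c <- function(x) {
    k <- floor(x / (2 * pi))
    r <- x - 2 * pi * k
    stats::approx(ci$phi, ci$cum, xout = r, rule = 2)$y + k * ci$total
  }
  eval_c(b) - eval_c(a)
}

# Replace flagged grid points by periodic linear interpolation from the
# nearest valid neighbours. Returns the repaired vector; a fully degenerate
# profile (every point flagged) becomes all-NA with a warning.
interpolate_flagged <- function(phi, values, flagged) {
  if (!any(flagged)) return(values)
  if (all(flagged)) {
    warning("all grid points flagged invalid; returning NA profile")
    return(rep(NA_real_, length(values)))
  }
  good <- which(!flagged)
  x <- c(phi[good] - 2 * pi, phi[good], phi[good] + 2 * pi)
  y <- rep(values[good], 3)
  values[flagged] <- stats::approx(x, y, xout = phi[flagged])$y
  values
}
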