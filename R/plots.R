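#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the four RNA species over the cell cycle
#'
#' @param object An `expression_profiles` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.expression_profiles <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("phase", "pu", "mu", "pl", "ml")],
    -"phase", names_to = "species", values_to = "expression"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$phase, .data$expression,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(
      breaks = c(0, pi / 2, pi, 3 * pi / 2, 2 * pi),
      labels = c("0", "π/2", "π", "3π/2", "2π")
    ) +
    ggplot2::labs(x = "cell-cycle phase", y = "expression",
                  colour = "species") +
    ggplot2::theme_minimal()
}

#' Plot estimated rate profiles
#'
#' @param object A `rate_estimates` or `rate_profiles` tibble.
#' @param ... Unused.
#' @return A ggplot, faceted by rate.
#' @export
autoplot.rate_estimates <- function(object, ...) {
  cols <- intersect(names(object), c("alpha", "beta", "gamma"))
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("phase", cols)],
    -"phase", names_to = "rate", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$phase, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~rate, scales = "free_y") +
    ggplot2::labs(x = "cell-cycle phase", y = "rate (per hour)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rate_profiles <- autoplot.rate_estimates

#' Plot observed versus predicted mature profiles for a fitted gene
#'
#' @param object A `gene_kinetics` object.
#' @param ... Unused.
#' @return A ggplot comparing smoothed observations (solid) with model
#'   predictions (dashed) for labeled, unlabeled and total mature RNA.
#' @export
autoplot.gene_kinetics <- function(object, ...) {
  obs <- tidyr::pivot_longer(object$smoothed, -"phase",
                             names_to = "species", values_to = "value")
  obs$kind <- "observed"
  pred <- tidyr::pivot_longer(object$predicted, -"phase",
                              names_to = "species", values_to = "value")
  pred$kind <- "predicted"
  ggplot2::ggplot(dplyr::bind_rows(obs, pred),
                  ggplot2::aes(.data$phase, .data$value,
                               linetype = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "cell-cycle phase", y = "expression") +
    ggplot2::theme_minimal()
}
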