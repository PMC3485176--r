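#' Plot a trajectory
#'
#' Population sizes (and optionally the molecular species) against time.
#'
#' @param object An `eco_trajectory`.
#' @param species Species to draw (default the two populations).
#' @param log10 Log-scale the y axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eco_trajectory <- function(object, species = c("c1", "c2"),
                                    log10 = TRUE, ...) {
  dat <- dplyr::filter(tidy(object), .data$species %in% !!species)
  gg <- ggplot2::ggplot(dat, ggplot2::aes(.data$time, .data$value,
                                          colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [h]", y = "count",
                  title = sprintf("%s trajectory", attr(object, "mode")))
  if (log10) gg <- gg + ggplot2::scale_y_log10()
  gg
}

#' Plot an ensemble summary
#'
#' Per-time ensemble mean with a mean +/- SD ribbon for the two
#' populations.
#'
#' @param object An [eco_ensemble()].
#' @param species Species to draw (default the two populations).
#' @param log10 Log-scale the y axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eco_ensemble <- function(object, species = c("c1", "c2"),
                                  log10 = TRUE, ...) {
  dat <- dplyr::filter(object$summary, .data$species %in% !!species)
  gg <- ggplot2::ggplot(dat, ggplot2::aes(.data$time, .data$mean,
                                          colour = .data$species,
                                          fill = .data$species)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$mean - .data$sd,
                                                  if (log10) 1e-3 else 0),
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [h]", y = "cells",
                  title = sprintf("ensemble of %d colonies", object$n))
  if (log10) gg <- gg + ggplot2::scale_y_log10()
  gg
}

#' Plot a bifurcation diagram
#'
#' Post-transient amplitude envelope of a population against the
#' bacterial degradation rate, with the Hopf onset marked.
#'
#' @param object An `eco_bifurcation` from [scan_bifurcation()].
#' @param population `"c1"` (yeast, default) or `"c2"` (bacteria).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eco_bifurcation <- function(object, population = c("c1", "c2"),
                                     ...) {
  population <- match.arg(population)
  res <- object$results
  lo <- res[[paste0(population, "_min")]]
  hi <- res[[paste0(population, "_max")]]
  dat <- tibble::tibble(d = res$d, lo = lo, hi = hi,
                        regime = res$regime)
  gg <- ggplot2::ggplot(dat, ggplot2::aes(.data$d)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$lo), colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$hi), colour = "steelblue") +
    ggplot2::labs(x = "E. coli degradation rate d [1/h]",
                  y = sprintf("%s envelope [cells]", population))
  if (!is.na(object$hopf_d))
    gg <- gg + ggplot2::geom_vline(xintercept = object$hopf_d,
                                   linetype = "dashed", colour = "red")
  gg
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
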