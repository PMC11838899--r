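#' Plot a 2Dmito dataset
#'
#' Scatter of log OXPHOS abundance against log mitochondrial mass, controls
#' in grey and the patient in colour.
#'
#' @param object A logged [mito_data] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mito_data <- function(object, ...) {
  stopifnot(isTRUE(attr(object, "logged")))
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(data = df[df$subject_type == "control", ],
                        colour = "grey60", size = 0.8) +
    ggplot2::geom_point(data = df[df$subject_type == "patient", ],
                        colour = "#d95f02", size = 0.9) +
    ggplot2::labs(
      x = paste0("log ", attr(object, "mass_channel")),
      y = paste0("log ", attr(object, "oxphos_channel")),
      title = paste0("2Dmito: patient ", attr(object, "patient_id"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a frequentist classification with its prediction band
#'
#' @param object A [classify_frequentist()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.freq_class <- function(object, ...) {
  fibres <- object$fibres
  grid <- seq(min(fibres$x), max(fibres$x), length.out = 100)
  band <- prediction_interval(object$fit, grid, object$level)
  ggplot2::ggplot(fibres, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_ribbon(data = band,
                         ggplot2::aes(x = .data$x, ymin = .data$lower,
                                      ymax = .data$upper),
                         inherit.aes = FALSE,
                         fill = "darkgreen", alpha = 0.15) +
    ggplot2::geom_line(data = band,
                       ggplot2::aes(x = .data$x, y = .data$fit),
                       inherit.aes = FALSE, colour = "darkgreen") +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$z)), size = 0.9) +
    ggplot2::scale_colour_manual(values = c(`0` = "#2166ac", `1` = "#b2182b"),
                                 name = "not-like-control") +
    ggplot2::labs(x = "log mass", y = "log OXPHOS") +
    ggplot2::theme_minimal()
}

#' Plot Bayesian classifications with the posterior predictive band
#'
#' Patient fibres are coloured on a blue-to-red scale by their posterior
#' deficiency probability; the band is the like-control (component one)
#' posterior predictive interval.
#'
#' @param fit A [fit_mixture()] object.
#' @param result A [classify_bayes()] result for `fit` (computed if
#'   omitted).
#' @param level Band level, default 0.95.
#' @return A ggplot object.
#' @export
plot_classification <- function(fit, result = NULL, level = 0.95) {
  stopifnot(inherits(fit, "mito_fit"))
  if (is.null(result)) result <- classify_bayes(fit)
  fibres <- result$fibres
  ctrl <- tibble::as_tibble(fit$data)
  ctrl <- ctrl[ctrl$subject_type == "control", ]
  grid <- seq(min(fibres$x), max(fibres$x), length.out = 80)
  band <- posterior_predictive_band(fit, grid, level = level)
  ggplot2::ggplot(fibres, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(data = ctrl, colour = "grey70", size = 0.7) +
    ggplot2::geom_ribbon(data = band,
                         ggplot2::aes(x = .data$x, ymin = .data$lower,
                                      ymax = .data$upper),
                         inherit.aes = FALSE,
                         fill = "darkgreen", alpha = 0.15) +
    ggplot2::geom_line(data = band,
                       ggplot2::aes(x = .data$x, y = .data$fitted),
                       inherit.aes = FALSE, colour = "darkgreen") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$prob), size = 0.9) +
    ggplot2::scale_colour_gradient(low = "#2166ac", high = "#b2182b",
                                   limits = c(0, 1),
                                   name = "P(deficient)") +
    ggplot2::labs(x = "log mass", y = "log OXPHOS") +
    ggplot2::theme_minimal()
}

#' Overlay prior and posterior marginal densities
#'
#' @param fit A [fit_mixture()] object.
#' @param n_prior Number of prior draws for the overlay.
#' @param seed Seed for the prior draws.
#' @return A ggplot object faceted by parameter.
#' @export
plot_prior_posterior <- function(fit, n_prior = 5000, seed = 1) {
  stopifnot(inherits(fit, "mito_fit"))
  pars <- c("mu_m", "mu_c", "tau_m", "tau_c", "tau", "pi")
  post <- tibble::as_tibble(fit$draws[[fit$selected_chain]])[pars] |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "parameter") |>
    dplyr::mutate(dist = "posterior")
  pri <- sample_prior(fit$prior, n_prior, seed)[pars] |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "parameter") |>
    dplyr::mutate(dist = "prior")
  ggplot2::ggplot(dplyr::bind_rows(post, pri),
                  ggplot2::aes(x = .data$value, fill = .data$dist)) +
    ggplot2::geom_density(alpha = 0.4, colour = NA) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::scale_fill_manual(values = c(prior = "#e78ac3",
                                          posterior = "#66c2a5"),
                               name = NULL) +
    ggplot2::theme_minimal()
}
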