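#' Highest density interval of a sample
#'
#' The shortest contiguous interval over the sorted sample containing
#' `ceiling(level * n)` points. For skewed posteriors this hugs the mode,
#' unlike the equal-tailed interval.
#'
#' @param samples Numeric vector, at least 10 values.
#' @param level Mass to cover, in (0, 1]; `level = 1` spans the range.
#' @return A length-2 numeric vector `c(lower, upper)`.
#' @export
hdi <- function(samples, level = 0.95) {
  n <- length(samples)
  if (n < 10) stop("need at least 10 samples for an HDI", call. = FALSE)
  if (!is.numeric(level) || level <= 0 || level > 1) {
    stop("level must lie in (0, 1]", call. = FALSE)
  }
  s <- sort(samples)
  m <- ceiling(level * n)
  if (m >= n) return(c(s[1], s[n]))
  starts <- seq_len(n - m + 1)
  widths <- s[starts + m - 1] - s[starts]
  i <- starts[which.min(widths)]
  c(s[i], s[i + m - 1])
}

#' Classify patient fibres from the posterior membership probabilities
#'
#' The posterior mean deficiency probability of each patient fibre is the
#' average of its per-draw membership probabilities over the selected
#' chain. A fibre is labelled not-like-control (`label = 1`) when that mean
#' is at or above `threshold`; below it, like-control (the boundary maps to
#' 1 because like-control is defined strictly as a probability under 50%).
#'
#' @param fit A [fit_mixture()] object.
#' @param threshold Classification threshold on the posterior mean
#'   probability (default 0.5).
#' @param chain Chain index; defaults to the selected chain.
#' @return An object of class `mito_class`: list with `fibres` (tibble
#'   `fibre_id`, `x`, `y`, `prob`, `label`), `pi` (posterior summary of the
#'   deficiency proportion) and `chain`.
#' @export
classify_bayes <- function(fit, threshold = 0.5, chain = NULL) {
  stopifnot(inherits(fit, "mito_fit"))
  ch <- if (is.null(chain)) fit$selected_chain else chain
  P <- fit$membership[[ch]]
  if (is.null(P) || nrow(P) == 0) {
    stop("fit contains no membership draws", call. = FALSE)
  }
  prob <- colMeans(P)
  pi_draws <- fit$draws[[ch]][, "pi"]
  h95 <- hdi(pi_draws, 0.95)
  h99 <- hdi(pi_draws, 0.99)
  fibres <- fit$patient_fibres |>
    dplyr::mutate(prob = prob,
                  label = as.integer(prob >= threshold))
  structure(
    list(fibres = fibres,
         pi = tibble::tibble(median = stats::median(pi_draws),
                             mean = mean(pi_draws),
                             hdi95_lower = h95[1], hdi95_upper = h95[2],
                             hdi99_lower = h99[1], hdi99_upper = h99[2]),
         threshold = threshold, chain = ch),
    class = "mito_class")
}

#' @export
print.mito_class <- function(x, ...) {
  cat(sprintf(
    "Bayesian classification: %d/%d fibres not-like-control (%.1f%%)\n",
    sum(x$fibres$label), nrow(x$fibres), 100 * mean(x$fibres$label)))
  cat(sprintf("  pi posterior median %.3f, 95%% HDI [%.3f, %.3f]\n",
              x$pi$median, x$pi$hdi95_lower, x$pi$hdi95_upper))
  invisible(x)
}

#' @export
tidy.mito_class <- function(x, ...) x$fibres

#' @export
glance.mito_class <- function(x, ...) {
  dplyr::mutate(x$pi,
                n_patient = nrow(x$fibres),
                proportion_flagged = mean(x$fibres$label),
                threshold = x$threshold,
                chain = x$chain)
}

#' Write a classification result to disk
#'
#' The per-fibre table goes to a CSV; the proportion summary to JSON.
#'
#' @param result A [classify_bayes()] object.
#' @param csv_path,json_path Output paths (`NULL` to skip either).
#' @return `result`, invisibly.
#' @export
write_classification <- function(result, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(result, "mito_class"))
  if (!is.null(csv_path)) {
    readr::write_csv(result$fibres, csv_path, progress = FALSE)
  }
  if (!is.null(json_path)) {
    writeLines(jsonlite::toJSON(c(as.list(result$pi),
                                  list(threshold = result$threshold,
                                       chain = result$chain)),
                                auto_unbox = TRUE, digits = NA), json_path)
  }
  invisible(result)
}

#' Posterior predictive band for the healthy patient abundance
#'
#' Equal-tailed predictive quantiles for a new like-control patient fibre
#' at each grid point: the predictive distribution is the mixture over
#' posterior draws of `N(m_k x + c_k, 1/tau)` (component one only), and its
#' quantiles are found by root-finding on the mixture CDF, so a point-mass
#' posterior yields the exact normal band.
#'
#' @param fit A [fit_mixture()] object.
#' @param x_grid Covariate (log mass) grid.
#' @param level Band level, default 0.95.
#' @param chain Chain index; defaults to the selected chain.
#' @return A tibble `x`, `fitted`, `lower`, `upper`.
#' @export
posterior_predictive_band <- function(fit, x_grid, level = 0.95,
                                      chain = NULL) {
  stopifnot(inherits(fit, "mito_fit"))
  ch <- if (is.null(chain)) fit$selected_chain else chain
  d <- fit$draws[[ch]]
  k <- length(fit$subject_ids)
  mk <- d[, paste0("m[", k, "]")]
  ck <- d[, paste0("c[", k, "]")]
  sd_d <- 1 / sqrt(d[, "tau"])
  probs <- c((1 - level) / 2, (1 + level) / 2)
  out <- purrr::map_dfr(x_grid, function(x0) {
    mu_d <- mk * x0 + ck
    cdf <- function(q) mean(stats::pnorm(q, mu_d, sd_d))
    rng <- c(min(mu_d) - 12 * max(sd_d), max(mu_d) + 12 * max(sd_d))
    qs <- vapply(probs, function(p) {
      stats::uniroot(function(q) cdf(q) - p, interval = rng,
                     tol = 1e-10)$root
    }, 0)
    tibble::tibble(x = x0, fitted = mean(mu_d),
                   lower = qs[1], upper = qs[2])
  })
  out
}

#' Compare the posterior deficiency proportion with a reference proportion
#'
#' Summarises the posterior of the mixture weight `pi` (median, 95% and 99%
#' HDIs), the distribution of `pi - reference`, and the one-sided tail
#' probability of observing the reference value or more extreme under the
#' posterior (in the direction of the reference relative to the posterior
#' median). When no draw is as extreme the probability is reported at the
#' Monte-Carlo resolution floor `1/n_draws` with `tail_at_floor = TRUE`.
#'
#' @param pi_draws Posterior draws of the deficiency proportion.
#' @param reference Reference proportion in `[0, 1]` (e.g. the frequentist
#'   or the manual estimate).
#' @return A one-row tibble of class `pi_comparison`.
#' @export
summarize_pi <- function(pi_draws, reference) {
  stopifnot(is.numeric(pi_draws), length(pi_draws) >= 10,
            reference >= 0, reference <= 1)
  n <- length(pi_draws)
  med <- stats::median(pi_draws)
  h95 <- hdi(pi_draws, 0.95)
  h99 <- hdi(pi_draws, 0.99)
  diff <- pi_draws - reference
  dh95 <- hdi(diff, 0.95)
  dh99 <- hdi(diff, 0.99)
  count <- if (reference >= med) sum(pi_draws >= reference)
           else sum(pi_draws <= reference)
  at_floor <- count == 0
  out <- tibble::tibble(
    median = med,
    hdi95_lower = h95[1], hdi95_upper = h95[2],
    hdi99_lower = h99[1], hdi99_upper = h99[2],
    reference = reference,
    diff_median = stats::median(diff),
    diff_hdi95_lower = dh95[1], diff_hdi95_upper = dh95[2],
    diff_hdi99_lower = dh99[1], diff_hdi99_upper = dh99[2],
    tail_prob = if (at_floor) 1 / n else count / n,
    tail_at_floor = at_floor,
    n_draws = n
  )
  class(out) <- c("pi_comparison", class(out))
  out
}
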