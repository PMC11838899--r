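#' Effective sample size of a single chain
#'
#' Geyer's initial monotone positive sequence estimator: autocorrelations
#' are summed in consecutive pairs, truncated at the first non-positive
#' pair, and forced non-increasing; `ESS = n / (2 * sum(pairs) - 1)`.
#' For white noise this is close to `n`; antithetic chains may exceed `n`.
#'
#' @param x Numeric vector of draws.
#' @return The effective sample size.
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 8) return(NA_real_)
  if (stats::var(x) == 0) return(NA_real_)
  lag_max <- min(n - 1, max(100L, floor(10 * sqrt(n))))
  rho <- stats::acf(x, lag.max = lag_max, plot = FALSE)$acf[, 1, 1]
  n_pair <- length(rho) %/% 2
  g <- rho[seq(1, 2 * n_pair, by = 2)] + rho[seq(2, 2 * n_pair, by = 2)]
  pos <- which(g <= 0)
  if (length(pos) > 0) g <- g[seq_len(pos[1] - 1)]
  if (length(g) == 0) return(n)  # immediately negative pair: ~uncorrelated
  g <- cummin(g)
  tau_int <- max(2 * sum(g) - 1, 1e-8)
  n / tau_int
}

#' Split R-hat across one or more chains
#'
#' Each chain is split in half and the standard potential scale reduction
#' factor is computed over the resulting sequences, so that within-chain
#' drift is visible even with a single chain.
#'
#' @param chains A list of equal-length numeric vectors (or one vector).
#' @return The split R-hat statistic.
#' @export
split_rhat <- function(chains) {
  if (is.numeric(chains)) chains <- list(chains)
  n <- min(lengths(chains))
  half <- n %/% 2
  if (half < 2) return(NA_real_)
  seqs <- unlist(lapply(chains, function(ch) {
    list(ch[seq_len(half)], ch[seq(n - half + 1, n)])
  }), recursive = FALSE)
  means <- vapply(seqs, mean, 0)
  vars <- vapply(seqs, stats::var, 0)
  w <- mean(vars)
  if (w == 0) return(1)
  b <- half * stats::var(means)
  sqrt(((half - 1) / half * w + b / half) / w)
}

#' Convergence diagnostics for a fitted mixture model
#'
#' Computes, per parameter, the cross-chain split R-hat and, per chain and
#' parameter, the effective sample size. A chain is flagged as
#' non-convergent when its own split-half R-hat (a drift statistic standing
#' in for visual trace inspection) exceeds `rhat_threshold` for any
#' parameter.
#'
#' @param fit A [fit_mixture()] object, or a list of draw matrices with
#'   common column names.
#' @param rhat_threshold Flagging threshold (default 1.05).
#' @return An object of class `mito_diag`: list with tibbles `rhat`
#'   (parameter, rhat), `ess` (chain, parameter, ess) and `drift` (chain,
#'   drift_rhat, flagged).
#' @export
diagnose_chains <- function(fit, rhat_threshold = 1.05) {
  draws <- if (inherits(fit, "mito_fit")) fit$draws else fit
  stopifnot(is.list(draws), length(draws) >= 1)
  pars <- colnames(draws[[1]])
  rhat <- tibble::tibble(
    parameter = pars,
    rhat = vapply(pars, function(p) {
      split_rhat(lapply(draws, function(d) d[, p]))
    }, 0)
  )
  ess_tbl <- purrr::map_dfr(seq_along(draws), function(ch) {
    tibble::tibble(chain = ch, parameter = pars,
                   ess = vapply(pars, function(p) ess(draws[[ch]][, p]), 0))
  })
  drift <- tibble::tibble(
    chain = seq_along(draws),
    drift_rhat = vapply(seq_along(draws), function(ch) {
      max(vapply(pars, function(p) split_rhat(draws[[ch]][, p]), 0),
          na.rm = TRUE)
    }, 0)
  )
  drift$flagged <- drift$drift_rhat > rhat_threshold
  structure(list(rhat = rhat, ess = ess_tbl, drift = drift,
                 rhat_threshold = rhat_threshold),
            class = "mito_diag")
}

#' @export
print.mito_diag <- function(x, ...) {
  cat("Chain diagnostics (threshold R-hat >", x$rhat_threshold, ")\n")
  cat(sprintf("  max split R-hat: %.4f\n", max(x$rhat$rhat, na.rm = TRUE)))
  ess_min <- x$ess |>
    dplyr::group_by(.data$chain) |>
    dplyr::summarise(min_ess = min(.data$ess, na.rm = TRUE),
                     .groups = "drop")
  for (i in seq_len(nrow(ess_min))) {
    cat(sprintf("  chain %d: min ESS %.0f%s\n", ess_min$chain[i],
                ess_min$min_ess[i],
                if (x$drift$flagged[i]) " [FLAGGED]" else ""))
  }
  invisible(x)
}

#' Select the chain used as the basis for inference
#'
#' Among chains not flagged for drift, returns the index of the chain whose
#' minimum per-parameter effective sample size is largest.
#'
#' @param diag A [diagnose_chains()] object.
#' @return A chain index.
#' @export
select_chain <- function(diag) {
  stopifnot(inherits(diag, "mito_diag"))
  ok <- diag$drift$chain[!diag$drift$flagged]
  if (length(ok) == 0) {
    stop("all chains are flagged as non-convergent", call. = FALSE)
  }
  min_ess <- diag$ess |>
    dplyr::filter(.data$chain %in% ok) |>
    dplyr::group_by(.data$chain) |>
    dplyr::summarise(min_ess = min(.data$ess, na.rm = TRUE),
                     .groups = "drop")
  min_ess$chain[which.max(min_ess$min_ess)]
}
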