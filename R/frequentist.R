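#' Simple least-squares line fit for one subject (or a pooled control set)
#'
#' Fits `y = m x + c` by ordinary least squares and stores everything the
#' downstream classifiers and the prior pipeline need: slope `m`, intercept
#' `c`, residual precision `tau = 1/s^2` (with `s^2` the unbiased residual
#' variance on `n - 2` degrees of freedom), the fibre count `n`, and the
#' design summaries `x_bar` and `s_xx`.
#'
#' @param x,y Numeric vectors of equal length (at least 3 points), typically
#'   log mitochondrial mass and log OXPHOS abundance.
#' @return An object of class `ols_fit`.
#' @export
fit_ols <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  n <- length(x)
  if (n < 3) stop("need at least 3 points to fit a line", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("x and y must be finite", call. = FALSE)
  }
  x_bar <- mean(x)
  s_xx <- sum((x - x_bar)^2)
  if (s_xx <= 0) {
    stop("degenerate design: all x values are equal", call. = FALSE)
  }
  m <- sum((x - x_bar) * (y - mean(y))) / s_xx
  c0 <- mean(y) - m * x_bar
  rss <- sum((y - m * x - c0)^2)
  if (rss <= 0) {
    stop("degenerate fit: zero residual sum of squares (infinite precision)",
         call. = FALSE)
  }
  s2 <- rss / (n - 2)
  structure(
    list(m = m, c = c0, tau = 1 / s2, sigma = sqrt(s2),
         n = n, x_bar = x_bar, s_xx = s_xx),
    class = "ols_fit"
  )
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit: m = %.4f, c = %.4f, tau = %.4f (n = %d)\n",
              x$m, x$c, x$tau, x$n))
  invisible(x)
}

#' @export
tidy.ols_fit <- function(x, ...) {
  tibble::tibble(term = c("m", "c", "tau"),
                 estimate = c(x$m, x$c, x$tau))
}

#' @export
glance.ols_fit <- function(x, ...) {
  tibble::tibble(m = x$m, c = x$c, tau = x$tau, sigma = x$sigma,
                 n = x$n, x_bar = x$x_bar, s_xx = x$s_xx)
}

#' Out-of-sample prediction interval of a fitted line
#'
#' Classical t-based prediction interval for a new observation at `x0`:
#' centred at `m x0 + c` with half-width
#' `t_{n-2,(1+level)/2} * s * sqrt(1 + 1/n + (x0 - x_bar)^2 / s_xx)`.
#'
#' @param fit An [fit_ols()] object.
#' @param x0 Numeric vector of covariate values at which to predict.
#' @param level Interval level in (0, 1); default 0.95.
#' @return A tibble with columns `x`, `fit`, `lower`, `upper`, `level`.
#' @export
prediction_interval <- function(fit, x0, level = 0.95) {
  stopifnot(inherits(fit, "ols_fit"))
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    stop("level must lie strictly between 0 and 1", call. = FALSE)
  }
  centre <- fit$m * x0 + fit$c
  half <- stats::qt((1 + level) / 2, df = fit$n - 2) * fit$sigma *
    sqrt(1 + 1 / fit$n + (x0 - fit$x_bar)^2 / fit$s_xx)
  tibble::tibble(x = x0, fit = centre,
                 lower = centre - half, upper = centre + half,
                 level = level)
}

#' Legacy frequentist prediction-interval classifier
#'
#' The classification pipeline prevalent in the literature: all control
#' fibres are pooled (unweighted) into a single set, one line is fitted by
#' OLS, and each patient fibre is flagged as not-like-control (`z = 1`) iff
#' its log abundance falls outside the `level` prediction interval at its
#' own log mass. A `side` column records whether a flagged fibre lies above
#' or below the band; it does not affect `z`.
#'
#' @param data A logged [mito_data] object (one patient plus controls).
#' @param level Prediction-interval level, default 0.95.
#' @return An object of class `freq_class`: list with `fibres` (tibble
#'   `fibre_id`, `x`, `y`, `lower`, `upper`, `z`, `side`), the pooled
#'   `fit`, and `level`.
#' @export
classify_frequentist <- function(data, level = 0.95) {
  bl <- mito_blocks(data)
  ctrl <- bl$blocks[vapply(bl$blocks, function(b) b$type == "control",
                           logical(1))]
  if (length(ctrl) < 1) stop("no control subjects", call. = FALSE)
  x_pool <- unlist(lapply(ctrl, `[[`, "x"))
  y_pool <- unlist(lapply(ctrl, `[[`, "y"))
  fit <- fit_ols(x_pool, y_pool)
  pat <- bl$patient
  band <- prediction_interval(fit, pat$x, level = level)
  fibres <- tibble::tibble(
    fibre_id = pat$fibre_id, x = pat$x, y = pat$y,
    lower = band$lower, upper = band$upper,
    z = as.integer(pat$y < band$lower | pat$y > band$upper),
    side = dplyr::case_when(pat$y > band$upper ~ "above",
                            pat$y < band$lower ~ "below",
                            TRUE ~ "within")
  )
  structure(list(fibres = fibres, fit = fit, level = level),
            class = "freq_class")
}

#' @export
print.freq_class <- function(x, ...) {
  cat(sprintf(
    "Frequentist classification: %d/%d patient fibres flagged (%.1f%%) at level %.2f\n",
    sum(x$fibres$z), nrow(x$fibres),
    100 * mean(x$fibres$z), x$level))
  invisible(x)
}

#' @export
tidy.freq_class <- function(x, ...) x$fibres

#' @export
glance.freq_class <- function(x, ...) {
  tibble::tibble(n_patient = nrow(x$fibres),
                 n_flagged = sum(x$fibres$z),
                 proportion = mean(x$fibres$z),
                 level = x$level,
                 m = x$fit$m, c = x$fit$c, tau = x$fit$tau)
}

# Internal: per-control-subject OLS fits, used by the prior pipeline and by
# sampler initialization.
control_ols_fits <- function(data) {
  bl <- mito_blocks(data)
  ctrl <- bl$blocks[vapply(bl$blocks, function(b) b$type == "control",
                           logical(1))]
  lapply(ctrl, function(b) fit_ols(b$x, b$y))
}
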