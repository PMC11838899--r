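#' Match a gamma distribution by mode and variance
#'
#' Solves for the shape `g` and rate `h` of a gamma distribution with a
#' given mode `(g - 1) / h` and variance `g / h^2`. The rate is the positive
#' root of `variance * h^2 - mode * h - 1 = 0` and `g = mode * h + 1`.
#' Shape/rate parameterization is used for every gamma distribution in this
#' package.
#'
#' With mode = variance = 50 (the default subject-level precision prior)
#' this yields shape 51.981 and rate 1.020 (3 d.p.).
#'
#' @param mode,variance Positive reals.
#' @return A named numeric vector `c(shape =, rate =)`.
#' @export
solve_gamma_mode_var <- function(mode, variance) {
  if (!is.numeric(mode) || mode <= 0 || !is.numeric(variance) ||
      variance <= 0) {
    stop("mode and variance must be positive", call. = FALSE)
  }
  rate <- (mode + sqrt(mode^2 + 4 * variance)) / (2 * variance)
  shape <- mode * rate + 1
  c(shape = shape, rate = rate)
}

#' Full prior specification of the hierarchical mixture model
#'
#' Collects every hyperparameter of the prior layer. `mu_m ~ N(am, bm)` and
#' `mu_c ~ N(ac, bc)` (with `bm`, `bc` *variances*); `tau ~ Ga(g, h)`;
#' `tau_m ~ Ga(gm, hm)`; `tau_c ~ Ga(gc, hc)` (all shape/rate);
#' `pi ~ Uniform(pi_lower, pi_upper)`. `gamma_fixed` is the fixed precision
#' of the broad second mixture component -- it is never inferred --
#' and `slope_lower` is the left-truncation bound of each subject slope.
#'
#' @param am,bm Prior mean and variance of the population slope mean.
#' @param ac,bc Prior mean and variance of the population intercept mean.
#' @param g,h Shape and rate of the model-precision prior.
#' @param gm,hm,gc,hc Shape and rate of the slope/intercept population
#'   precision priors.
#' @param pi_lower,pi_upper Support of the flat prior on the deficiency
#'   proportion.
#' @param gamma_fixed Fixed second-component precision (default `1e-4`).
#' @param slope_lower Slope truncation bound (default 0.1).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(am, bm = 0.25^2, ac, bc = 0.25^2,
                       g, h, gm, hm, gc, hc,
                       pi_lower = 0, pi_upper = 0.5,
                       gamma_fixed = 1e-4, slope_lower = 0.1) {
  spec <- list(am = am, bm = bm, ac = ac, bc = bc, g = g, h = h,
               gm = gm, hm = hm, gc = gc, hc = hc,
               pi_lower = pi_lower, pi_upper = pi_upper,
               gamma_fixed = gamma_fixed, slope_lower = slope_lower)
  pos <- c("bm", "bc", "g", "h", "gm", "hm", "gc", "hc", "gamma_fixed")
  for (nm in pos) {
    if (!is.numeric(spec[[nm]]) || length(spec[[nm]]) != 1 ||
        !is.finite(spec[[nm]]) || spec[[nm]] <= 0) {
      stop("prior parameter '", nm, "' must be a positive number",
           call. = FALSE)
    }
  }
  if (!(pi_lower < pi_upper && pi_upper <= 1 && pi_lower >= 0)) {
    stop("need 0 <= pi_lower < pi_upper <= 1", call. = FALSE)
  }
  tau_mode <- (g - 1) / h
  if (tau_mode > 0 && gamma_fixed / tau_mode > 1e-2) {
    warning("gamma_fixed is not small relative to the prior mode of tau (",
            "ratio ", signif(gamma_fixed / tau_mode, 3),
            "); the two mixture components may overlap", call. = FALSE)
  }
  structure(spec, class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("Prior specification:\n")
  cat(sprintf("  mu_m ~ N(%.4f, %.4f)   mu_c ~ N(%.4f, %.4f)\n",
              x$am, x$bm, x$ac, x$bc))
  cat(sprintf("  tau   ~ Ga(%.4f, %.4f)\n", x$g, x$h))
  cat(sprintf("  tau_m ~ Ga(%.4f, %.4f)  tau_c ~ Ga(%.4f, %.4f)\n",
              x$gm, x$hm, x$gc, x$hc))
  cat(sprintf("  pi ~ U(%g, %g), gamma_fixed = %g, slope_lower = %g\n",
              x$pi_lower, x$pi_upper, x$gamma_fixed, x$slope_lower))
  invisible(x)
}

#' Build the prior specification from per-control-subject line fits
#'
#' The control-data-driven prior pipeline: a line is fitted independently to
#' each control subject and the resulting sets of slopes, intercepts and
#' residual precisions inform the prior. `am` and `ac` are the means of the
#' control slopes and intercepts; the `tau` prior has its *mode* at the mean
#' of the control precisions with variance `tau_variance`; the subject-level
#' precision priors place mode and variance at `tau_sub_mode`,
#' `tau_sub_variance` (defaults 50 and 50, giving shape 51.981, rate 1.020).
#'
#' @param control_fits A list of [fit_ols()] objects, one per control
#'   subject (a single fit is accepted with a warning).
#' @param bm,bc Prior variances of the population means (default `0.25^2`).
#' @param tau_variance Prior variance of the model precision (default 10).
#' @param tau_sub_mode,tau_sub_variance Mode and variance for the
#'   subject-level precision priors.
#' @inheritParams prior_spec
#' @return A [prior_spec()] object.
#' @export
build_priors <- function(control_fits, bm = 0.25^2, bc = 0.25^2,
                         tau_variance = 10,
                         tau_sub_mode = 50, tau_sub_variance = 50,
                         pi_upper = 0.5, gamma_fixed = 1e-4,
                         slope_lower = 0.1) {
  if (inherits(control_fits, "ols_fit")) control_fits <- list(control_fits)
  if (length(control_fits) == 0) {
    stop("need at least one control fit", call. = FALSE)
  }
  if (length(control_fits) == 1) {
    warning("only one control fit supplied; prior means are taken from a ",
            "single subject", call. = FALSE)
  }
  stopifnot(all(vapply(control_fits, inherits, logical(1), "ols_fit")))
  gh <- solve_gamma_mode_var(mean(vapply(control_fits, `[[`, 0, "tau")),
                             tau_variance)
  gh_sub <- solve_gamma_mode_var(tau_sub_mode, tau_sub_variance)
  prior_spec(
    am = mean(vapply(control_fits, `[[`, 0, "m")), bm = bm,
    ac = mean(vapply(control_fits, `[[`, 0, "c")), bc = bc,
    g = gh[["shape"]], h = gh[["rate"]],
    gm = gh_sub[["shape"]], hm = gh_sub[["rate"]],
    gc = gh_sub[["shape"]], hc = gh_sub[["rate"]],
    pi_upper = pi_upper, gamma_fixed = gamma_fixed,
    slope_lower = slope_lower
  )
}

#' Inflate or deflate prior uncertainty by a common factor
#'
#' Multiplies the prior variances of `mu_m`, `mu_c`, `tau`, `tau_m` and
#' `tau_c` by `factor` while leaving the normal prior means and the gamma
#' prior modes unchanged (the gammas are re-solved by mode/variance
#' matching). Used for the prior-sensitivity analysis, with `factor = 5`
#' and `factor = 1/5`.
#'
#' @param spec A [prior_spec()] object.
#' @param factor Positive variance multiplier.
#' @return A new `prior_spec`.
#' @export
scale_prior <- function(spec, factor) {
  stopifnot(inherits(spec, "prior_spec"), is.numeric(factor), factor > 0)
  rescale <- function(g, h) {
    solve_gamma_mode_var((g - 1) / h, g / h^2 * factor)
  }
  gh <- rescale(spec$g, spec$h)
  ghm <- rescale(spec$gm, spec$hm)
  ghc <- rescale(spec$gc, spec$hc)
  prior_spec(am = spec$am, bm = spec$bm * factor,
             ac = spec$ac, bc = spec$bc * factor,
             g = gh[["shape"]], h = gh[["rate"]],
             gm = ghm[["shape"]], hm = ghm[["rate"]],
             gc = ghc[["shape"]], hc = ghc[["rate"]],
             pi_lower = spec$pi_lower, pi_upper = spec$pi_upper,
             gamma_fixed = spec$gamma_fixed,
             slope_lower = spec$slope_lower)
}

#' Draw from the prior
#'
#' Independent draws of the hyperparameters and one implied subject-level
#' slope/intercept pair per draw (the slope left-truncated at
#' `slope_lower`). Used for prior-vs-posterior density overlays and the
#' prior-sensitivity runs.
#'
#' @param spec A [prior_spec()] object.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return A tibble with columns `mu_m`, `mu_c`, `tau_m`, `tau_c`, `tau`,
#'   `pi`, `m`, `c`.
#' @export
sample_prior <- function(spec, n, seed = 1) {
  stopifnot(inherits(spec, "prior_spec"), n >= 1)
  with_seed(seed, {
    mu_m <- stats::rnorm(n, spec$am, sqrt(spec$bm))
    mu_c <- stats::rnorm(n, spec$ac, sqrt(spec$bc))
    tau_m <- stats::rgamma(n, spec$gm, rate = spec$hm)
    tau_c <- stats::rgamma(n, spec$gc, rate = spec$hc)
    tau <- stats::rgamma(n, spec$g, rate = spec$h)
    pi <- stats::runif(n, spec$pi_lower, spec$pi_upper)
    m <- rtnorm_lower(n, mu_m, 1 / sqrt(tau_m), spec$slope_lower)
    c <- stats::rnorm(n, mu_c, 1 / sqrt(tau_c))
    tibble::tibble(mu_m = mu_m, mu_c = mu_c, tau_m = tau_m, tau_c = tau_c,
                   tau = tau, pi = pi, m = m, c = c)
  })
}

#' Serialize a prior specification to and from JSON
#'
#' @param spec A [prior_spec()] object.
#' @param path Optional file path; when given the JSON is written there.
#' @return `prior_to_json()`: a JSON string (invisibly if written to file);
#'   `prior_from_json()`: a `prior_spec`.
#' @export
prior_to_json <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "prior_spec"))
  js <- jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname prior_to_json
#' @param json A JSON string or path to a JSON file.
#' @export
prior_from_json <- function(json) {
  vals <- jsonlite::fromJSON(json)
  do.call(prior_spec, vals)
}
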