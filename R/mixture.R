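#' MCMC sampler configuration
#'
#' Defaults follow the study design: 3 chains of 22,000 iterations with a
#' 20,000-iteration burn-in and no thinning. Reduced presets (e.g.
#' `mcmc_config(chains = 2, iterations = 3000, burn_in = 1000)`) are
#' appropriate for tests and simulation sweeps; the conjugate Gibbs sampler
#' mixes quickly on this model.
#'
#' @param chains Number of independent chains (>= 1).
#' @param iterations Total iterations per chain.
#' @param burn_in Iterations discarded from the start of each chain.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed; chain `i` uses `seed + i - 1`.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 3, iterations = 22000, burn_in = 20000,
                        thin = 1, seed = 1) {
  stopifnot(chains >= 1, iterations > burn_in, burn_in >= 0, thin >= 1)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

# log-sum-exp of two vectors, tolerant of -Inf entries
lse2 <- function(a, b) {
  hi <- pmax(a, b)
  lo <- pmin(a, b)
  out <- hi + log1p(exp(lo - hi))
  out[is.infinite(hi) & hi < 0] <- -Inf
  out
}

#' Conditional probability that a fibre belongs to the deficient component
#'
#' Bayes' rule for the two-component mixture at a single parameter value:
#' `P(Z = 1 | y) = pi N(y; mu, 1/gamma) / [(1 - pi) N(y; mu, 1/tau) +
#' pi N(y; mu, 1/gamma)]` with `mu = m x + c`. Computed in log space.
#' Vectorized over fibres.
#'
#' @param y,x Log abundance and log mass of the fibre(s).
#' @param m,c,tau Patient slope, intercept and like-control precision.
#' @param gamma Fixed precision of the broad component.
#' @param pi Mixture weight of the deficient component.
#' @return Probabilities in `[0, 1]`.
#' @export
membership_probability <- function(y, x, m, c, tau, gamma, pi) {
  stopifnot(tau > 0, gamma > 0, pi >= 0, pi <= 1)
  mu <- m * x + c
  la <- log(pi) + stats::dnorm(y, mu, 1 / sqrt(gamma), log = TRUE)
  lb <- log1p(-pi) + stats::dnorm(y, mu, 1 / sqrt(tau), log = TRUE)
  stats::plogis(la - lb)
}

#' Log unnormalized posterior density of the hierarchical mixture model
#'
#' Sum of the control log-likelihood, the patient marginal mixture
#' log-likelihood (latent memberships summed out, with log-sum-exp
#' stabilization) and the log prior density of every unknown, including the
#' truncated-normal normalizing constants of the subject slopes. Returns
#' `-Inf` for parameter values off the support. Used by tests and
#' diagnostics; the Gibbs sampler targets the matching augmented posterior.
#'
#' @param params A list with elements `m`, `c` (length-k vectors, patient
#'   last), `tau`, `mu_m`, `mu_c`, `tau_m`, `tau_c`, `pi`.
#' @param data A logged [mito_data] object.
#' @param prior A [prior_spec()] object.
#' @return A single number (possibly `-Inf`).
#' @export
log_posterior <- function(params, data, prior) {
  stopifnot(inherits(prior, "prior_spec"))
  bl <- mito_blocks(data)
  k <- bl$k
  p <- params
  if (length(p$m) != k || length(p$c) != k) {
    stop("params$m and params$c must have one entry per subject (", k, ")",
         call. = FALSE)
  }
  on_support <- all(is.finite(c(p$m, p$c, p$tau, p$mu_m, p$mu_c,
                                p$tau_m, p$tau_c, p$pi))) &&
    p$tau > 0 && p$tau_m > 0 && p$tau_c > 0 &&
    all(p$m >= prior$slope_lower) &&
    p$pi >= prior$pi_lower && p$pi <= prior$pi_upper
  if (!on_support) return(-Inf)

  sd_tau <- 1 / sqrt(p$tau)
  ll <- 0
  for (i in seq_len(k - 1)) {
    b <- bl$blocks[[i]]
    ll <- ll + sum(stats::dnorm(b$y, p$m[i] * b$x + p$c[i], sd_tau,
                                log = TRUE))
  }
  pat <- bl$patient
  mu_p <- p$m[k] * pat$x + p$c[k]
  l0 <- log1p(-p$pi) + stats::dnorm(pat$y, mu_p, sd_tau, log = TRUE)
  l1 <- log(p$pi) +
    stats::dnorm(pat$y, mu_p, 1 / sqrt(prior$gamma_fixed), log = TRUE)
  ll <- ll + sum(lse2(l0, l1))

  lp <- sum(dtnorm_lower_log(p$m, p$mu_m, 1 / sqrt(p$tau_m),
                             prior$slope_lower)) +
    sum(stats::dnorm(p$c, p$mu_c, 1 / sqrt(p$tau_c), log = TRUE)) +
    stats::dgamma(p$tau, prior$g, rate = prior$h, log = TRUE) +
    stats::dnorm(p$mu_m, prior$am, sqrt(prior$bm), log = TRUE) +
    stats::dnorm(p$mu_c, prior$ac, sqrt(prior$bc), log = TRUE) +
    stats::dgamma(p$tau_m, prior$gm, rate = prior$hm, log = TRUE) +
    stats::dgamma(p$tau_c, prior$gc, rate = prior$hc, log = TRUE) +
    stats::dunif(p$pi, prior$pi_lower, prior$pi_upper, log = TRUE)
  ll + lp
}

# One Gibbs chain. Conjugate updates for everything except the population
# slope mean/precision, whose full conditionals carry the truncated-normal
# normalizing constant; those use an independence Metropolis-Hastings step
# proposing from the untruncated conjugate conditional (acceptance is the
# ratio of truncation constants, close to 1 in practice).
run_gibbs_chain <- function(bl, prior, config, init, chain_seed) {
  k <- bl$k
  n_keep <- (config$iterations - config$burn_in) %/% config$thin
  lower <- prior$slope_lower
  gamma <- prior$gamma_fixed

  ctrl <- bl$blocks[seq_len(k - 1)]
  cs <- lapply(ctrl, function(b) {
    list(n = length(b$x), Sx = sum(b$x), Sy = sum(b$y),
         Sxx = sum(b$x^2), Sxy = sum(b$x * b$y), Syy = sum(b$y^2))
  })
  n_ctrl <- sum(vapply(cs, `[[`, 0, "n"))
  xp <- bl$patient$x
  yp <- bl$patient$y
  n_p <- length(xp)

  par_names <- c(paste0("m[", seq_len(k), "]"),
                 paste0("c[", seq_len(k), "]"),
                 "tau", "mu_m", "mu_c", "tau_m", "tau_c", "pi")
  draws <- matrix(NA_real_, n_keep, length(par_names),
                  dimnames = list(NULL, par_names))
  membership <- matrix(NA_real_, n_keep, n_p)

  m <- init$m; c0 <- init$c; tau <- init$tau
  mu_m <- init$mu_m; mu_c <- init$mu_c
  tau_m <- init$tau_m; tau_c <- init$tau_c
  pi <- init$pi
  acc_mu_m <- 0L; acc_tau_m <- 0L

  with_seed(chain_seed, {
    mu_p <- m[k] * xp + c0[k]
    z <- stats::rbinom(n_p, 1L,
                       membership_probability(yp, xp, m[k], c0[k], tau,
                                              gamma, pi))
    keep_i <- 0L
    for (iter in seq_len(config$iterations)) {
      # latent memberships and mixture weight
      mu_p <- m[k] * xp + c0[k]
      pz <- membership_probability(yp, xp, m[k], c0[k], tau, gamma, pi)
      z <- stats::rbinom(n_p, 1L, pz)
      s1 <- sum(z)
      a_b <- 1 + s1
      b_b <- 1 + n_p - s1
      Fl <- stats::pbeta(prior$pi_lower, a_b, b_b)
      Fu <- stats::pbeta(prior$pi_upper, a_b, b_b)
      if (Fu - Fl > 1e-12) {
        pi <- stats::qbeta(stats::runif(1, Fl, Fu), a_b, b_b)
      } else {
        # numerically degenerate truncation window: pin to nearest bound
        pi <- if (stats::pbeta(prior$pi_upper, a_b, b_b) < 0.5)
          prior$pi_upper else prior$pi_lower + 1e-12
      }

      # subject slopes and intercepts: exact joint (block) draw from the
      # bivariate conditional -- slope from its truncated marginal, then
      # intercept given slope. Single-site updates mix poorly here because
      # slope and intercept are strongly correlated when x is uncentred.
      w <- ifelse(z == 1L, gamma, tau)
      for (i in seq_len(k)) {
        if (i < k) {
          s <- cs[[i]]
          a11 <- tau_m + tau * s$Sxx
          a12 <- tau * s$Sx
          a22 <- tau_c + tau * s$n
          b1 <- tau_m * mu_m + tau * s$Sxy
          b2 <- tau_c * mu_c + tau * s$Sy
        } else {
          a11 <- tau_m + sum(w * xp^2)
          a12 <- sum(w * xp)
          a22 <- tau_c + sum(w)
          b1 <- tau_m * mu_m + sum(w * xp * yp)
          b2 <- tau_c * mu_c + sum(w * yp)
        }
        det <- a11 * a22 - a12^2
        mean_m <- (a22 * b1 - a12 * b2) / det
        var_m <- a22 / det
        m[i] <- rtnorm_lower(1, mean_m, sqrt(var_m), lower)
        # c | m: condition the joint Gaussian on the sampled slope
        mean_c <- (b2 - a12 * m[i]) / a22
        c0[i] <- stats::rnorm(1, mean_c, 1 / sqrt(a22))
      }

      # shared like-control precision
      rss <- 0
      for (i in seq_len(k - 1)) {
        s <- cs[[i]]
        rss_i <- s$Syy - 2 * m[i] * s$Sxy - 2 * c0[i] * s$Sy +
          m[i]^2 * s$Sxx + 2 * m[i] * c0[i] * s$Sx + c0[i]^2 * s$n
        rss <- rss + max(rss_i, 0)
      }
      res_p <- yp - m[k] * xp - c0[k]
      n_like <- n_ctrl + sum(z == 0L)
      rss <- rss + sum(res_p[z == 0L]^2)
      tau <- stats::rgamma(1, prior$g + n_like / 2,
                           rate = prior$h + rss / 2)

      # population intercept level (fully conjugate)
      prec <- 1 / prior$bc + k * tau_c
      mu_c <- stats::rnorm(1, (prior$ac / prior$bc + tau_c * sum(c0)) / prec,
                           1 / sqrt(prec))
      tau_c <- stats::rgamma(1, prior$gc + k / 2,
                             rate = prior$hc + sum((c0 - mu_c)^2) / 2)

      # population slope level (MH for the truncation constant)
      prec <- 1 / prior$bm + k * tau_m
      mu_prop <- stats::rnorm(1, (prior$am / prior$bm + tau_m * sum(m)) / prec,
                              1 / sqrt(prec))
      log_acc <- k * (ltnorm_logconst(mu_m, 1 / sqrt(tau_m), lower) -
                        ltnorm_logconst(mu_prop, 1 / sqrt(tau_m), lower))
      if (log(stats::runif(1)) < log_acc) {
        mu_m <- mu_prop
        acc_mu_m <- acc_mu_m + 1L
      }
      tau_prop <- stats::rgamma(1, prior$gm + k / 2,
                                rate = prior$hm + sum((m - mu_m)^2) / 2)
      log_acc <- k * (ltnorm_logconst(mu_m, 1 / sqrt(tau_m), lower) -
                        ltnorm_logconst(mu_m, 1 / sqrt(tau_prop), lower))
      if (log(stats::runif(1)) < log_acc) {
        tau_m <- tau_prop
        acc_tau_m <- acc_tau_m + 1L
      }

      if (iter > config$burn_in &&
          (iter - config$burn_in) %% config$thin == 0L) {
        keep_i <- keep_i + 1L
        draws[keep_i, ] <- c(m, c0, tau, mu_m, mu_c, tau_m, tau_c, pi)
        membership[keep_i, ] <-
          membership_probability(yp, xp, m[k], c0[k], tau, gamma, pi)
      }
    }
  })
  list(draws = draws, membership = membership,
       accept = c(mu_m = acc_mu_m / config$iterations,
                  tau_m = acc_tau_m / config$iterations))
}

#' Fit the Bayesian hierarchical mixture model
#'
#' Samples the joint posterior of the per-subject slopes and intercepts, the
#' shared like-control precision, the population-level slope/intercept means
#' and precisions, and the deficiency proportion, by a Z-augmented Gibbs
#' sampler with conjugate updates (the population slope level uses an exact
#' independence Metropolis correction for the slope truncation). Per-fibre
#' deficiency probabilities are reconstructed at every retained draw by
#' Bayes' rule. Chains are diagnosed with split R-hat and effective sample
#' size, and the chain with the highest minimum per-parameter ESS among
#' unflagged chains is selected as the basis for inference.
#'
#' @param data A logged [mito_data] object.
#' @param prior A [prior_spec()]; when `NULL` it is built from independent
#'   control-subject line fits via [build_priors()].
#' @param config An [mcmc_config()].
#' @return An object of class `mito_fit` with elements `draws` (list of
#'   per-chain draw matrices), `membership` (list of per-chain draw-by-fibre
#'   probability matrices), `diagnostics`, `selected_chain`, `prior`,
#'   `config`, `subject_ids`, `patient_fibres` and `data`.
#' @export
fit_mixture <- function(data, prior = NULL, config = mcmc_config()) {
  stopifnot(inherits(config, "mcmc_config"))
  bl <- mito_blocks(data)
  k <- bl$k
  if (k < 2) stop("need at least one control and one patient", call. = FALSE)
  if (length(bl$patient$x) < 5) {
    warning("patient has fewer than 5 fibres; the hierarchy is identified ",
            "by the controls only", call. = FALSE)
  }
  if (is.null(prior)) prior <- build_priors(control_ols_fits(data))
  stopifnot(inherits(prior, "prior_spec"))

  # Initialization: controls at their per-subject OLS fits; the patient's
  # line at the mean of the control fits and tau at the controls-only
  # pooled precision. The patient's own OLS line is contaminated by the
  # deficient population (it bisects the two clusters when the deficient
  # fraction is large) and initializing there can trap the sampler in a
  # mode where the broad component never activates.
  ctrl_idx <- which(vapply(bl$blocks, function(b) b$type == "control",
                           logical(1)))
  pooled <- fit_ols(unlist(lapply(bl$blocks[ctrl_idx], `[[`, "x")),
                    unlist(lapply(bl$blocks[ctrl_idx], `[[`, "y")))
  sub_fit <- lapply(bl$blocks, function(b) {
    tryCatch(fit_ols(b$x, b$y), error = function(e) pooled)
  })
  m_init <- vapply(sub_fit, `[[`, 0, "m")
  c_init <- vapply(sub_fit, `[[`, 0, "c")
  m_init[k] <- mean(m_init[ctrl_idx])
  c_init[k] <- mean(c_init[ctrl_idx])
  init <- list(
    m = pmax(m_init, prior$slope_lower + 1e-6),
    c = c_init,
    tau = pooled$tau,
    mu_m = prior$am, mu_c = prior$ac,
    tau_m = max((prior$gm - 1) / prior$hm, 1e-3),
    tau_c = max((prior$gc - 1) / prior$hc, 1e-3),
    pi = min(max(0.1, prior$pi_lower + 1e-3), prior$pi_upper - 1e-3)
  )
  lp0 <- log_posterior(c(list(tau = init$tau, mu_m = init$mu_m,
                              mu_c = init$mu_c, tau_m = init$tau_m,
                              tau_c = init$tau_c, pi = init$pi),
                         list(m = init$m, c = init$c)), data, prior)
  if (!is.finite(lp0)) {
    stop("non-finite posterior at initialization; initial values: ",
         paste(sprintf("m=%.3g", init$m), collapse = " "), call. = FALSE)
  }

  chains <- lapply(seq_len(config$chains), function(ch) {
    run_gibbs_chain(bl, prior, config, init, config$seed + ch - 1L)
  })
  fit <- structure(
    list(draws = lapply(chains, `[[`, "draws"),
         membership = lapply(chains, `[[`, "membership"),
         accept = lapply(chains, `[[`, "accept"),
         prior = prior, config = config,
         subject_ids = bl$subject_ids,
         patient_fibres = tibble::tibble(fibre_id = bl$patient$fibre_id,
                                         x = bl$patient$x,
                                         y = bl$patient$y),
         data = data),
    class = "mito_fit")
  fit$diagnostics <- diagnose_chains(fit)
  fit$selected_chain <- select_chain(fit$diagnostics)
  fit
}

#' @export
print.mito_fit <- function(x, ...) {
  n_keep <- nrow(x$draws[[1]])
  cat(sprintf(
    "Hierarchical mixture fit: %d subject(s), %d patient fibres\n",
    length(x$subject_ids), nrow(x$patient_fibres)))
  cat(sprintf("  %d chain(s) x %d retained draws; selected chain %d\n",
              length(x$draws), n_keep, x$selected_chain))
  pi_draws <- x$draws[[x$selected_chain]][, "pi"]
  cat(sprintf("  posterior median deficiency proportion: %.3f\n",
              stats::median(pi_draws)))
  invisible(x)
}

#' Posterior draws as a tidy tibble
#'
#' @param fit A [fit_mixture()] object.
#' @param chain Chain index or `NULL` for all chains.
#' @return A tibble with columns `chain`, `draw` and one column per model
#'   parameter.
#' @export
draws_tibble <- function(fit, chain = NULL) {
  stopifnot(inherits(fit, "mito_fit"))
  idx <- if (is.null(chain)) seq_along(fit$draws) else chain
  purrr::map_dfr(idx, function(ch) {
    d <- tibble::as_tibble(fit$draws[[ch]])
    dplyr::mutate(d, chain = ch, draw = dplyr::row_number(),
                  .before = 1)
  })
}

#' @export
tidy.mito_fit <- function(x, level = 0.95, ...) {
  d <- x$draws[[x$selected_chain]]
  purrr::map_dfr(colnames(d), function(p) {
    s <- d[, p]
    h <- hdi(s, level)
    tibble::tibble(term = p, estimate = stats::median(s),
                   mean = mean(s), sd = stats::sd(s),
                   hdi_lower = h[1], hdi_upper = h[2])
  })
}

#' @export
glance.mito_fit <- function(x, ...) {
  d <- x$draws[[x$selected_chain]][, "pi"]
  h95 <- hdi(d, 0.95)
  tibble::tibble(
    pi_median = stats::median(d),
    pi_hdi95_lower = h95[1], pi_hdi95_upper = h95[2],
    selected_chain = x$selected_chain,
    n_chains = length(x$draws),
    n_draws = nrow(x$draws[[1]]),
    max_rhat = max(x$diagnostics$rhat$rhat, na.rm = TRUE),
    min_ess = min(x$diagnostics$ess$ess, na.rm = TRUE)
  )
}

#' Membership probabilities for arbitrary fibres under a fitted model
#'
#' Evaluates the per-draw deficiency probability for fibres that need not
#' have been part of the fit (used by the train/validation check).
#'
#' @param fit A [fit_mixture()] object.
#' @param x,y Log mass and log abundance vectors.
#' @param chain Chain index; defaults to the selected chain.
#' @return A draws-by-fibres matrix of probabilities.
#' @export
membership_matrix <- function(fit, x, y, chain = NULL) {
  stopifnot(inherits(fit, "mito_fit"))
  ch <- if (is.null(chain)) fit$selected_chain else chain
  d <- fit$draws[[ch]]
  k <- length(fit$subject_ids)
  mk <- d[, paste0("m[", k, "]")]
  ck <- d[, paste0("c[", k, "]")]
  tau <- d[, "tau"]
  pi <- d[, "pi"]
  gamma <- fit$prior$gamma_fixed
  out <- matrix(NA_real_, nrow(d), length(x))
  for (i in seq_len(nrow(d))) {
    out[i, ] <- membership_probability(y, x, mk[i], ck[i], tau[i],
                                       gamma, pi[i])
  }
  out
}
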