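test_that("membership probability collapses correctly in degenerate cases", {
  # identical components: the data carry no information, posterior = pi
  expect_equal(membership_probability(2.3, 1.1, 1, 0, 25, 25, 0.37),
               0.37, tolerance = 1e-12)
  xs <- seq(-3, 3, by = 0.5)
  expect_equal(membership_probability(xs, xs, 1, 0, 25, 25, 0.2),
               rep(0.2, length(xs)), tolerance = 1e-12)
  # degenerate mixture weights dominate the data entirely
  expect_equal(membership_probability(100, 0, 1, 0, 25, 1e-4, 0), 0)
  expect_equal(membership_probability(0.001, 0, 1, 0, 25, 1e-4, 1), 1)
})

test_that("membership probability matches direct density-ratio evaluation", {
  tau <- 25; gamma <- 1e-4; pi <- 0.2
  m <- 1.3; c <- 0.4; x <- 2.1
  y <- m * x + c + 20 / sqrt(tau)
  direct_num <- pi * dnorm(y, m * x + c, 1 / sqrt(gamma))
  direct_den <- (1 - pi) * dnorm(y, m * x + c, 1 / sqrt(tau)) + direct_num
  expect_equal(membership_probability(y, x, m, c, tau, gamma, pi),
               direct_num / direct_den, tolerance = 1e-12)
})

test_that("membership is monotone in the distance from the line when tau > gamma", {
  dist <- seq(0, 5, by = 0.05)
  p <- membership_probability(1 + dist, 1, 1, 0, 25, 1e-4, 0.15)
  expect_true(all(diff(p) >= 0))
  p_dn <- membership_probability(1 - dist, 1, 1, 0, 25, 1e-4, 0.15)
  expect_true(all(diff(p_dn) >= 0))
})

test_that("marginalized posterior equals the exhaustive-membership sum", {
  d <- tiny_instance()
  prior <- prior_spec(am = 1.1, ac = 0.2, g = 20, h = 1, gm = 51.98,
                      hm = 1.02, gc = 51.98, hc = 1.02)
  set.seed(22)
  for (rep in 1:5) {
    p <- list(m = runif(3, 0.5, 1.5), c = rnorm(3, 0.2, 0.3),
              tau = runif(1, 5, 30), mu_m = rnorm(1, 1.1, 0.2),
              mu_c = rnorm(1, 0.2, 0.2), tau_m = runif(1, 20, 80),
              tau_c = runif(1, 20, 80), pi = runif(1, 0.01, 0.49))
    expect_equal(log_posterior(p, d, prior), oracle_log_post(p, d, prior),
                 tolerance = 1e-10)
  }
})

test_that("the log posterior is exchangeable in fibre order and guards support", {
  d <- tiny_instance()
  prior <- prior_spec(am = 1.1, ac = 0.2, g = 20, h = 1, gm = 51.98,
                      hm = 1.02, gc = 51.98, hc = 1.02)
  p <- list(m = c(1, 1.2, 0.9), c = c(0.1, 0.3, 0.2), tau = 10,
            mu_m = 1.1, mu_c = 0.2, tau_m = 50, tau_c = 50, pi = 0.2)
  v1 <- log_posterior(p, d, prior)
  perm <- tibble::as_tibble(d)[c(3, 1, 2, 5, 6, 4, 9, 7, 8), ]
  d2 <- mito_data_from_log(
    perm[, c("subject_id", "subject_type", "fibre_id", "x", "y")],
    patient_id = "P01")
  expect_equal(log_posterior(p, d2, prior), v1, tolerance = 1e-12)
  # off-support values are -Inf, not errors
  expect_identical(log_posterior(modifyList(p, list(pi = 0.6)), d, prior),
                   -Inf)
  expect_identical(log_posterior(modifyList(p, list(tau = -1)), d, prior),
                   -Inf)
  expect_identical(
    log_posterior(modifyList(p, list(m = c(0.05, 1, 1))), d, prior), -Inf)
})

test_that("with identical component precisions the posterior ignores pi", {
  d <- tiny_instance()
  prior <- suppressWarnings(
    prior_spec(am = 1.1, ac = 0.2, g = 20, h = 1, gm = 51.98, hm = 1.02,
               gc = 51.98, hc = 1.02, gamma_fixed = 10))
  p <- list(m = c(1, 1.2, 0.9), c = c(0.1, 0.3, 0.2), tau = 10,
            mu_m = 1.1, mu_c = 0.2, tau_m = 50, tau_c = 50, pi = 0.1)
  v1 <- log_posterior(p, d, prior)
  v2 <- log_posterior(modifyList(p, list(pi = 0.43)), d, prior)
  expect_equal(v1, v2, tolerance = 1e-10)
})

test_that("posterior draws respect the parameter supports", {
  truth <- sample_ground_truth(config = list(k = 3L, pi = 0.2), seed = 31)
  sim <- generate_dataset(truth, n_per_subject = c(60, 60, 80), seed = 32)
  fit <- fit_mixture(sim$data, config = test_config(seed = 33,
                                                    iterations = 1200,
                                                    burn_in = 400))
  d <- fit$draws[[1]]
  expect_true(all(d[, "pi"] >= 0 & d[, "pi"] <= 0.5))
  expect_true(all(d[, paste0("m[", 1:3, "]")] >= 0.1))
  expect_true(all(d[, c("tau", "tau_m", "tau_c")] > 0))
  P <- fit$membership[[1]]
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(dim(P), c(nrow(d), 80))
})

test_that("the sampler recovers known parameters from synthetic data", {
  truth <- sample_ground_truth(config = list(k = 4L, pi = 0.15), seed = 41)
  sim <- generate_dataset(truth, n_per_subject = c(200, 200, 200, 400),
                          seed = 42)
  fit <- fit_mixture(sim$data, config = test_config(seed = 43))
  d <- fit$draws[[fit$selected_chain]]
  h99 <- hdi(d[, "pi"], 0.99)
  expect_gte(0.15, h99[1])
  expect_lte(0.15, h99[2])
  expect_lt(abs(median(d[, "pi"]) - 0.15), 0.05)
  for (i in 1:4) {
    md <- d[, paste0("m[", i, "]")]
    expect_lt(abs(mean(md) - truth$m[i]), 3 * sd(md))
  }
})

test_that("a patient with no deficient fibres yields a near-zero proportion", {
  truth <- sample_ground_truth(config = list(k = 4L, pi = 0), seed = 51)
  sim <- generate_dataset(truth, n_per_subject = c(100, 100, 100, 200),
                          seed = 52)
  fit <- fit_mixture(sim$data, config = test_config(seed = 53,
                                                    iterations = 2000,
                                                    burn_in = 500))
  expect_lt(median(fit$draws[[1]][, "pi"]), 0.05)
})

test_that("posterior ranks of prior-drawn truths are uniform (reduced SBC)", {
  # data generated exactly from the model (deficient component = broad
  # fixed-precision component), truth drawn from the prior
  gh_tau <- solve_gamma_mode_var(25, 10)
  sp <- prior_spec(am = 1, ac = 0, g = gh_tau[["shape"]],
                   h = gh_tau[["rate"]], gm = 51.98, hm = 1.02,
                   gc = 51.98, hc = 1.02)
  n_rep <- 100
  rank_pi <- rank_tau <- integer(n_rep)
  for (r in seq_len(n_rep)) {
    truth <- sample_ground_truth(
      prior = sp,
      config = list(k = 3L, delta = -1e-9, tau_def = 1e-4),
      seed = 1000 + r)
    sim <- generate_dataset(truth, n_per_subject = c(40, 40, 60),
                            seed = 2000 + r)
    fit <- fit_mixture(sim$data, prior = sp,
                       config = mcmc_config(chains = 1, iterations = 1200,
                                            burn_in = 200, thin = 2,
                                            seed = 3000 + r))
    d <- fit$draws[[1]]
    rank_pi[r] <- sum(d[, "pi"] < truth$pi)
    rank_tau[r] <- sum(d[, "tau"] < truth$tau)
  }
  n_draws <- 500
  bins <- seq(-0.5, n_draws + 0.5, length.out = 11)
  p_pi <- chisq.test(table(cut(rank_pi, bins)))$p.value
  p_tau <- chisq.test(table(cut(rank_tau, bins)))$p.value
  expect_gt(p_pi, 0.01)
  expect_gt(p_tau, 0.01)
})

test_that("draws_tibble exposes chains and draws tidily", {
  truth <- sample_ground_truth(config = list(k = 3L), seed = 61)
  sim <- generate_dataset(truth, n_per_subject = c(40, 40, 60), seed = 62)
  fit <- fit_mixture(sim$data,
                     config = mcmc_config(chains = 2, iterations = 600,
                                          burn_in = 200, seed = 63))
  dt <- draws_tibble(fit)
  expect_equal(nrow(dt), 2 * 400)
  expect_true(all(c("chain", "draw", "pi", "tau", "m[3]") %in% names(dt)))
})
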