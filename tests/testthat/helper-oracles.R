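# Independent oracle: evaluate the full unnormalized log posterior on a tiny
# instance by enumerating every patient membership assignment explicitly.
oracle_log_post <- function(p, data, prior) {
  df <- tibble::as_tibble(data)
  ids <- unique(df$subject_id)
  patient <- mito_patient_id(data)
  ids <- c(setdiff(ids, patient), patient)
  k <- length(ids)
  ll <- 0
  for (i in seq_len(k - 1)) {
    s <- df[df$subject_id == ids[i], ]
    ll <- ll + sum(dnorm(s$y, p$m[i] * s$x + p$c[i], 1 / sqrt(p$tau),
                         log = TRUE))
  }
  pat <- df[df$subject_id == patient, ]
  n_p <- nrow(pat)
  zs <- as.matrix(expand.grid(rep(list(0:1), n_p)))
  contrib <- apply(zs, 1, function(z) {
    sd_z <- ifelse(z == 1, 1 / sqrt(prior$gamma_fixed), 1 / sqrt(p$tau))
    sum(z * log(p$pi) + (1 - z) * log(1 - p$pi) +
          dnorm(pat$y, p$m[k] * pat$x + p$c[k], sd_z, log = TRUE))
  })
  ll <- ll + log(sum(exp(contrib)))
  # priors, written independently of the package's helpers
  ltn <- function(v, mu, prec) {
    dnorm(v, mu, 1 / sqrt(prec), log = TRUE) -
      pnorm(0.1, mu, 1 / sqrt(prec), lower.tail = FALSE, log.p = TRUE)
  }
  ll + sum(ltn(p$m, p$mu_m, p$tau_m)) +
    sum(dnorm(p$c, p$mu_c, 1 / sqrt(p$tau_c), log = TRUE)) +
    dgamma(p$tau, prior$g, rate = prior$h, log = TRUE) +
    dnorm(p$mu_m, prior$am, sqrt(prior$bm), log = TRUE) +
    dnorm(p$mu_c, prior$ac, sqrt(prior$bc), log = TRUE) +
    dgamma(p$tau_m, prior$gm, rate = prior$hm, log = TRUE) +
    dgamma(p$tau_c, prior$gc, rate = prior$hc, log = TRUE) +
    dunif(p$pi, prior$pi_lower, prior$pi_upper, log = TRUE)
}

tiny_instance <- function(seed = 21) {
  set.seed(seed)
  df <- tibble::tibble(
    subject_id = rep(c("C01", "C02", "P01"), each = 3),
    subject_type = rep(c("control", "control", "patient"), each = 3),
    fibre_id = paste0("f", 1:9),
    x = runif(9, 1, 3))
  df$y <- 1.1 * df$x + 0.2 + rnorm(9, 0, 0.3)
  df$y[9] <- df$y[9] - 2.5  # one clearly deficient-looking patient fibre
  mito_data_from_log(df, patient_id = "P01")
}
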