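# Shared fixtures, built in code at test time.

# A small long-format record table: 2 subjects x 3 fibres x 2 channels.
tiny_records <- function() {
  tidyr::expand_grid(
    subject_id = c("C01", "P01"),
    fibre_id = c("f1", "f2", "f3"),
    channel = c("VDAC", "NDUFB8")
  ) |>
    dplyr::mutate(
      subject_type = ifelse(subject_id == "P01", "patient", "control"),
      value = seq(1, 2, length.out = dplyr::n())
    ) |>
    dplyr::select(fibre_id, subject_id, subject_type, channel, value)
}

# A small logged dataset with known structure: straight lines plus noise.
tiny_mito <- function(n_ctrl = 30, n_pat = 30, seed = 42) {
  set.seed(seed)
  df <- dplyr::bind_rows(
    tibble::tibble(subject_id = "C01", subject_type = "control",
                   fibre_id = sprintf("c%03d", 1:n_ctrl),
                   x = runif(n_ctrl, 1, 3)),
    tibble::tibble(subject_id = "C02", subject_type = "control",
                   fibre_id = sprintf("d%03d", 1:n_ctrl),
                   x = runif(n_ctrl, 1, 3)),
    tibble::tibble(subject_id = "P01", subject_type = "patient",
                   fibre_id = sprintf("p%03d", 1:n_pat),
                   x = runif(n_pat, 1, 3))
  )
  df$y <- 1.1 * df$x + 0.2 + rnorm(nrow(df), 0, 0.2)
  mito_data_from_log(df, patient_id = "P01")
}

# Default reduced sampler settings for tests.
test_config <- function(seed = 1, chains = 1, iterations = 3000,
                        burn_in = 1000) {
  mcmc_config(chains = chains, iterations = iterations, burn_in = burn_in,
              seed = seed)
}

# A hand-built mito_fit with fully controlled draws, for exercising the
# posterior-analysis operations in isolation.
fake_fit <- function(pi_draws, membership, m = 1, c = 0, tau = 25, k = 2,
                     fibre_x = NULL, fibre_y = NULL) {
  n <- length(pi_draws)
  n_p <- ncol(membership)
  cols <- c(paste0("m[", 1:k, "]"), paste0("c[", 1:k, "]"),
            "tau", "mu_m", "mu_c", "tau_m", "tau_c", "pi")
  d <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  for (i in 1:k) {
    d[, paste0("m[", i, "]")] <- m
    d[, paste0("c[", i, "]")] <- c
  }
  d[, "tau"] <- tau
  d[, "mu_m"] <- m; d[, "mu_c"] <- c
  d[, "tau_m"] <- 50; d[, "tau_c"] <- 50
  d[, "pi"] <- pi_draws
  if (is.null(fibre_x)) fibre_x <- seq_len(n_p)
  if (is.null(fibre_y)) fibre_y <- m * fibre_x + c
  structure(
    list(draws = list(d), membership = list(membership),
         prior = suppressWarnings(
           prior_spec(am = m, ac = c, g = 2, h = 1, gm = 2, hm = 1,
                      gc = 2, hc = 1)),
         subject_ids = paste0("S", 1:k),
         patient_fibres = tibble::tibble(
           fibre_id = sprintf("p%03d", seq_len(n_p)),
           x = fibre_x, y = fibre_y),
         selected_chain = 1L),
    class = "mito_fit")
}
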