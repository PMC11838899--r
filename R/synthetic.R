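#' Ground truth for a synthetic 2Dmito dataset
#'
#' Samples (or takes explicitly) the true parameter values behind a
#' synthetic dataset: the population slope/intercept level, the shared
#' like-control precision, the deficiency proportion, per-subject slopes
#' (left-truncated) and intercepts, the deficient-component offset and
#' precision, and the per-subject covariate distribution. Defaults emulate
#' the IMC regime: 4 controls plus one patient, residual SD 0.2
#' (`tau = 25`), a deficient population shifted `delta = -2` log units
#' below the like-control line with SD about 0.7 (`tau_def = 2`) -- clearly
#' under-expressed yet noisier than the like-control population -- and log
#' mass drawn log-normal.
#'
#' @param prior Optional [prior_spec()]; when supplied the population
#'   parameters are drawn from it instead of the explicit defaults.
#' @param config A named list overriding any field (`k`, `mu_m`, `mu_c`,
#'   `tau_m`, `tau_c`, `tau`, `pi`, `delta`, `tau_def`, `m`, `c`,
#'   `x_meanlog`, `x_sdlog`, `x_shift`, `x_scale`, `slope_lower`).
#' @param seed Integer seed; a fixed seed gives identical truth on repeat
#'   calls.
#' @return An object of class `ground_truth`.
#' @export
sample_ground_truth <- function(prior = NULL, config = list(), seed = 1) {
  tr <- list(k = 5L, mu_m = 1.05, mu_c = 0, tau_m = 50, tau_c = 50,
             tau = 25, pi = 0.1, delta = -2, tau_def = 2,
             x_meanlog = 1.0, x_sdlog = 0.25, x_shift = 0, x_scale = 1,
             slope_lower = 0.1, seed = as.integer(seed))
  with_seed(seed, {
    if (!is.null(prior)) {
      stopifnot(inherits(prior, "prior_spec"))
      tr$mu_m <- stats::rnorm(1, prior$am, sqrt(prior$bm))
      tr$mu_c <- stats::rnorm(1, prior$ac, sqrt(prior$bc))
      tr$tau_m <- stats::rgamma(1, prior$gm, rate = prior$hm)
      tr$tau_c <- stats::rgamma(1, prior$gc, rate = prior$hc)
      tr$tau <- stats::rgamma(1, prior$g, rate = prior$h)
      tr$pi <- stats::runif(1, prior$pi_lower, prior$pi_upper)
      tr$slope_lower <- prior$slope_lower
    }
    fixed <- intersect(names(config), names(tr))
    tr[fixed] <- config[fixed]
    if (!"m" %in% names(config)) {
      tr$m <- rtnorm_lower(tr$k, tr$mu_m, 1 / sqrt(tr$tau_m), tr$slope_lower)
    } else {
      tr$m <- config$m
    }
    if (!"c" %in% names(config)) {
      tr$c <- stats::rnorm(tr$k, tr$mu_c, 1 / sqrt(tr$tau_c))
    } else {
      tr$c <- config$c
    }
  })
  if (tr$pi < 0 || tr$pi > 0.5) {
    stop("true deficiency proportion must lie in [0, 0.5]", call. = FALSE)
  }
  if (tr$delta >= 0) {
    stop("delta must be negative: deficient fibres sit below the ",
         "like-control line", call. = FALSE)
  }
  if (tr$tau_def >= tr$tau) {
    stop("tau_def must be smaller than tau (the deficient component is ",
         "the noisier one)", call. = FALSE)
  }
  stopifnot(length(tr$m) == tr$k, length(tr$c) == tr$k,
            all(tr$m >= tr$slope_lower))
  structure(tr, class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "Ground truth: k = %d subjects, pi = %.3f, tau = %.2f, delta = %.2f\n",
    x$k, x$pi, x$tau, x$delta))
  cat("  slopes:", sprintf("%.3f", x$m), "\n")
  cat("  intercepts:", sprintf("%.3f", x$c), "\n")
  invisible(x)
}

#' Generate a labelled synthetic 2Dmito dataset
#'
#' Per-subject log mass is drawn from the (optionally shifted/scaled)
#' log-normal covariate distribution. Control log abundance follows the
#' subject's line with precision `tau`. Each patient fibre's status is an
#' independent Bernoulli(`pi`) draw; like-control fibres follow component
#' one, deficient fibres a line shifted `delta` below with precision
#' `tau_def`. Output is bitwise reproducible given `(truth, seed)`.
#'
#' @param truth A [sample_ground_truth()] object.
#' @param n_per_subject Integer vector of fibre counts, controls first and
#'   patient last; when `NULL`, control sizes are drawn uniformly from
#'   154--363 and the patient from 151--1199 (the observed per-section
#'   ranges).
#' @param seed Integer seed.
#' @return A list with `data` (a logged [mito_data]), `labels` (tibble
#'   `fibre_id`, `label` for the patient fibres) and `truth`.
#' @export
generate_dataset <- function(truth, n_per_subject = NULL, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  k <- truth$k
  meanlog <- rep_len(truth$x_meanlog, k)
  sdlog <- rep_len(truth$x_sdlog, k)
  with_seed(seed, {
    if (is.null(n_per_subject)) {
      n_per_subject <- c(sample(154:363, k - 1, replace = TRUE),
                         sample(151:1199, 1))
    }
    stopifnot(length(n_per_subject) == k, all(n_per_subject >= 1))
    subject_ids <- c(sprintf("C%02d", seq_len(k - 1)), "P01")
    rows <- vector("list", k)
    labels <- NULL
    for (i in seq_len(k)) {
      n <- n_per_subject[i]
      x <- truth$x_shift + truth$x_scale *
        stats::rlnorm(n, meanlog[i], sdlog[i])
      mu <- truth$m[i] * x + truth$c[i]
      if (i < k) {
        y <- stats::rnorm(n, mu, 1 / sqrt(truth$tau))
        lab <- NULL
      } else {
        z <- stats::rbinom(n, 1L, truth$pi)
        y <- ifelse(z == 1L,
                    stats::rnorm(n, mu + truth$delta,
                                 1 / sqrt(truth$tau_def)),
                    stats::rnorm(n, mu, 1 / sqrt(truth$tau)))
        lab <- z
      }
      fid <- sprintf("%s_f%04d", subject_ids[i], seq_len(n))
      rows[[i]] <- tibble::tibble(
        subject_id = subject_ids[i],
        subject_type = if (i < k) "control" else "patient",
        fibre_id = fid, x = x, y = y)
      if (!is.null(lab)) {
        labels <- tibble::tibble(fibre_id = fid, label = lab)
      }
    }
    data <- mito_data_from_log(dplyr::bind_rows(rows),
                               patient_id = "P01")
    list(data = data, labels = labels, truth = truth)
  })
}

#' Derive an IF-like ("D02") variant of a ground truth
#'
#' Linearly transforms the covariate distribution (`x -> shift + scale * x`,
#' mimicking the larger abundances of immunofluorescence data) and widens
#' the inter-subject spread by dividing the population precisions by
#' `subject_sd_factor^2`, re-drawing the per-subject slopes and intercepts
#' from the widened population. With `scale = 1`, `shift = 0`,
#' `subject_sd_factor = 1` the truth is returned unchanged.
#'
#' @param truth A [sample_ground_truth()] object.
#' @param scale,shift Covariate transform parameters (`scale > 0`).
#' @param subject_sd_factor Inter-subject SD multiplier (>= 1).
#' @param seed Seed for the re-draw of subject parameters; defaults to the
#'   truth's own seed.
#' @return A new `ground_truth`.
#' @export
make_d02_variant <- function(truth, scale = 1, shift = 0,
                             subject_sd_factor = 1, seed = truth$seed) {
  stopifnot(inherits(truth, "ground_truth"), scale > 0,
            subject_sd_factor >= 1)
  out <- unclass(truth)
  out$x_shift <- shift + scale * truth$x_shift
  out$x_scale <- scale * truth$x_scale
  if (subject_sd_factor > 1) {
    out$tau_m <- truth$tau_m / subject_sd_factor^2
    out$tau_c <- truth$tau_c / subject_sd_factor^2
    with_seed(seed, {
      out$m <- rtnorm_lower(out$k, out$mu_m, 1 / sqrt(out$tau_m),
                            out$slope_lower)
      out$c <- stats::rnorm(out$k, out$mu_c, 1 / sqrt(out$tau_c))
    })
  }
  structure(out, class = "ground_truth")
}

#' Write a synthetic dataset to disk
#'
#' Writes the long-format fibre CSV, the patient labels CSV and the ground
#' truth as JSON, mirroring the package's canonical input dialect.
#'
#' @param sim A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @param stem File name stem.
#' @return The directory, invisibly.
#' @export
write_synthetic <- function(sim, dir, stem = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fibre_csv(sim$data, file.path(dir, paste0(stem, "_fibres.csv")))
  readr::write_csv(sim$labels, file.path(dir, paste0(stem, "_labels.csv")),
                   progress = FALSE)
  writeLines(jsonlite::toJSON(unclass(sim$truth), auto_unbox = TRUE,
                              digits = NA),
             file.path(dir, paste0(stem, "_truth.json")))
  invisible(dir)
}
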