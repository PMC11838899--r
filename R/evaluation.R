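#' Confusion matrix between model and reference labels
#'
#' Cross-tabulates binary labels with the model's label as the first index
#' and the reference (ground truth or expert manual classification) as the
#' second; 0 is like-control, 1 not-like-control.
#'
#' @param pred,ref Equal-length vectors of 0/1 labels.
#' @return A 2x2 integer matrix of class `confusion_matrix` with dimnames
#'   `model` and `reference`.
#' @export
confusion_matrix <- function(pred, ref) {
  if (length(pred) != length(ref)) {
    stop("pred and ref must have equal length", call. = FALSE)
  }
  pred <- as.integer(pred)
  ref <- as.integer(ref)
  stopifnot(all(pred %in% 0:1), all(ref %in% 0:1))
  cm <- matrix(c(sum(pred == 0 & ref == 0), sum(pred == 0 & ref == 1),
                 sum(pred == 1 & ref == 0), sum(pred == 1 & ref == 1)),
               nrow = 2, byrow = TRUE,
               dimnames = list(model = c("0", "1"),
                               reference = c("0", "1")))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Percentage of misclassified fibres
#'
#' `100 * (n01 + n10) / n`, the off-diagonal share of a
#' [confusion_matrix()].
#'
#' @param cm A `confusion_matrix`.
#' @return A percentage.
#' @export
misclassification_rate <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  100 * (cm["0", "1"] + cm["1", "0"]) / total
}

#' Mean absolute difference between estimated and reference proportions
#'
#' @param pairs A data frame with columns `estimate` and `reference`, one
#'   row per (sample, protein) pair, all entries in `[0, 1]`.
#' @return The mean of `|estimate - reference|`.
#' @export
mad_proportions <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("estimate", "reference") %in% names(pairs)))
  if (nrow(pairs) == 0) stop("no proportion pairs supplied", call. = FALSE)
  stopifnot(all(pairs$estimate >= 0 & pairs$estimate <= 1),
            all(pairs$reference >= 0 & pairs$reference <= 1))
  mean(abs(pairs$estimate - pairs$reference))
}

#' Expert-consensus reference labels
#'
#' Experts can disagree; a fibre counts as not-like-control only when every
#' annotation column marks it 1.
#'
#' @param annotations A data frame whose columns are 0/1 labels from
#'   individual annotators (one row per fibre).
#' @return An integer vector of consensus labels.
#' @export
consensus_labels <- function(annotations) {
  stopifnot(is.data.frame(annotations), ncol(annotations) >= 1)
  m <- as.matrix(annotations)
  stopifnot(all(m %in% 0:1))
  as.integer(rowSums(m) == ncol(m))
}

#' Sensitivity of the classification to the fixed second-component precision
#'
#' Refits the mixture model for each candidate `gamma`, classifies the
#' patient fibres, and records the absolute difference between the flagged
#' proportion and a reference proportion. All refits reuse the same seed so
#' rows differ only through `gamma`. Per-`gamma` failures are recorded in
#' the table rather than aborting the sweep.
#'
#' @param data A logged [mito_data] object.
#' @param prior A [prior_spec()].
#' @param gammas Positive candidate values for the fixed precision.
#' @param reference Reference not-like-control proportion.
#' @param config An [mcmc_config()].
#' @return A tibble `gamma`, `proportion`, `mad`, `error`, with the
#'   MAD-minimising `gamma` in attribute `"best_gamma"`.
#' @export
gamma_sweep <- function(data, prior, gammas, reference,
                        config = mcmc_config()) {
  stopifnot(all(gammas > 0))
  rows <- purrr::map_dfr(gammas, function(g) {
    res <- tryCatch({
      spec_g <- prior
      spec_g$gamma_fixed <- g
      fit <- fit_mixture(data, spec_g, config)
      cls <- classify_bayes(fit)
      prop <- mean(cls$fibres$label)
      tibble::tibble(gamma = g, proportion = prop,
                     mad = mad_proportions(
                       tibble::tibble(estimate = prop,
                                      reference = reference)),
                     error = NA_character_)
    }, error = function(e) {
      tibble::tibble(gamma = g, proportion = NA_real_, mad = NA_real_,
                     error = conditionMessage(e))
    })
    res
  })
  ok <- !is.na(rows$mad)
  attr(rows, "best_gamma") <- if (any(ok)) {
    rows$gamma[ok][which.min(rows$mad[ok])]
  } else NA_real_
  rows
}

#' Train/validation over-fitting check
#'
#' Randomly splits the patient fibres (controls are never split; they
#' anchor the hierarchy), refits the model on the training split, and
#' compares the posterior mean deficiency probability of *every* patient
#' fibre under the training-only fit with the full-data fit. No evidence of
#' over-fitting corresponds to 0 lying inside the 99% HDI of the per-fibre
#' probability differences.
#'
#' @param data A logged [mito_data] object with >= 10 patient fibres.
#' @param prior A [prior_spec()]; `NULL` builds it from the control data.
#' @param config An [mcmc_config()].
#' @param fraction Training fraction in (0, 1), default 0.8.
#' @param seed Seed for the split.
#' @return An object of class `split_check`: list with `fibres` (tibble
#'   `fibre_id`, `in_training`, `p_train`, `p_full`, `diff`), `hdi99`,
#'   `contains_zero` and the two fits.
#' @export
split_validation <- function(data, prior = NULL, config = mcmc_config(),
                             fraction = 0.8, seed = 1) {
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  bl <- mito_blocks(data)
  n_p <- length(bl$patient$x)
  if (n_p < 10) stop("need at least 10 patient fibres", call. = FALSE)
  n_train <- floor(fraction * n_p)
  idx <- with_seed(seed, sample.int(n_p, n_train))
  patient_id <- mito_patient_id(data)
  keep <- data$subject_type == "control" |
    data$fibre_id %in% bl$patient$fibre_id[idx]
  train_df <- tibble::as_tibble(data[keep, , drop = FALSE])
  train_data <- mito_data_from_log(
    train_df[, c("subject_id", "subject_type", "fibre_id", "x", "y")],
    mass_channel = attr(data, "mass_channel"),
    oxphos_channel = attr(data, "oxphos_channel"),
    patient_id = patient_id)

  if (is.null(prior)) prior <- build_priors(control_ols_fits(data))
  fit_train <- fit_mixture(train_data, prior, config)
  fit_full <- fit_mixture(data, prior, config)

  p_train <- colMeans(membership_matrix(fit_train, bl$patient$x,
                                        bl$patient$y))
  p_full <- colMeans(membership_matrix(fit_full, bl$patient$x,
                                       bl$patient$y))
  diff <- p_train - p_full
  h99 <- hdi(diff, 0.99)
  structure(
    list(fibres = tibble::tibble(fibre_id = bl$patient$fibre_id,
                                 in_training = seq_len(n_p) %in% idx,
                                 p_train = p_train, p_full = p_full,
                                 diff = diff),
         hdi99 = h99,
         contains_zero = h99[1] <= 0 && 0 <= h99[2],
         fit_train = fit_train, fit_full = fit_full,
         fraction = fraction, seed = seed),
    class = "split_check")
}

#' @export
print.split_check <- function(x, ...) {
  cat(sprintf(
    "80/20-style split check (training fraction %.2f):\n", x$fraction))
  cat(sprintf("  probability-difference 99%% HDI [%.4f, %.4f]; %s\n",
              x$hdi99[1], x$hdi99[2],
              if (x$contains_zero) "no evidence of over-fitting"
              else "0 outside the HDI"))
  invisible(x)
}
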