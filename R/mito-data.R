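#' Per-fibre abundance tables and the 2Dmito representation
#'
#' A `mito_data` object holds the content of one 2Dmito plot: per-fibre
#' (log) OXPHOS protein abundance paired with (log) mitochondrial mass for a
#' set of control subjects plus exactly one patient. It is a tibble with one
#' row per fibre and columns `subject_id`, `subject_type` (`"control"` or
#' `"patient"`), `fibre_id`, the raw intensities `mass` and `oxphos`, and --
#' once [log_mito()] has been applied -- their natural logs `x` and `y`.
#' Subjects are kept in a stable order: controls in input order, the patient
#' last.
#'
#' @name mito_data
NULL

mito_cols <- c("fibre_id", "subject_id", "subject_type", "channel", "value")

new_mito_data <- function(df, mass_channel, oxphos_channel, patient_id,
                          logged, report) {
  tibble::new_tibble(
    df,
    mass_channel = mass_channel,
    oxphos_channel = oxphos_channel,
    patient_id = patient_id,
    logged = logged,
    report = report,
    class = "mito_data"
  )
}

#' Read a long-format per-fibre CSV
#'
#' The canonical input dialect is a UTF-8, comma-separated table with a
#' header row and columns `fibre_id`, `subject_id`, `subject_type`,
#' `channel`, `value` -- one row per (fibre, channel), the usual output
#' shape of per-cell mean-intensity quantification after image
#' segmentation.
#'
#' @param path Path to a CSV file.
#' @return A tibble of fibre records.
#' @export
read_fibre_csv <- function(path) {
  records <- readr::read_csv(path, show_col_types = FALSE,
                             progress = FALSE,
                             col_types = readr::cols(
                               .default = readr::col_character()))
  missing <- setdiff(mito_cols, names(records))
  if (length(missing) > 0) {
    stop("fibre CSV is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  records |>
    dplyr::mutate(
      fibre_id = as.character(.data$fibre_id),
      subject_id = as.character(.data$subject_id),
      subject_type = as.character(.data$subject_type),
      channel = as.character(.data$channel),
      value = as.numeric(.data$value)
    ) |>
    dplyr::select(dplyr::all_of(mito_cols))
}

#' Pair two channels of a long fibre table into a 2Dmito dataset
#'
#' Selects the mitochondrial-mass channel (e.g. VDAC) and one OXPHOS channel
#' (e.g. NDUFB8), pairs them by exact `(subject_id, fibre_id)` match, and
#' returns a raw-intensity [mito_data] object. Fibres missing either channel
#' are dropped, never imputed, and counted in the attached load report
#' (`mito_report()`).
#'
#' @param records A long tibble as returned by [read_fibre_csv()].
#' @param mass_channel,oxphos_channel Channel names to pair (x and y axis of
#'   the 2Dmito plot).
#' @param patient_id The `subject_id` of the single patient; every other
#'   subject must be a control.
#' @return A raw (unlogged) `mito_data` tibble.
#' @export
as_mito_data <- function(records, mass_channel, oxphos_channel, patient_id) {
  missing <- setdiff(mito_cols, names(records))
  if (length(missing) > 0) {
    stop("records are missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!patient_id %in% records$subject_id) {
    stop("patient_id '", patient_id, "' not found among subjects",
         call. = FALSE)
  }
  recs <- records |>
    dplyr::filter(.data$channel %in% c(mass_channel, oxphos_channel)) |>
    dplyr::mutate(
      subject_type = ifelse(.data$subject_id == patient_id,
                            "patient", "control")
    )
  dup <- recs |>
    dplyr::count(.data$subject_id, .data$fibre_id, .data$channel) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate (subject_id, fibre_id, channel) records, e.g. subject ",
         dup$subject_id[1], " fibre ", dup$fibre_id[1], call. = FALSE)
  }
  controls <- unique(recs$subject_id[recs$subject_type == "control"])
  if (length(controls) == 0) {
    stop("dataset must contain at least one control subject", call. = FALSE)
  }

  wide <- recs |>
    tidyr::pivot_wider(
      id_cols = c("subject_id", "subject_type", "fibre_id"),
      names_from = "channel", values_from = "value"
    )
  # some fibres may lack one channel entirely -> ensure both columns exist
  for (ch in c(mass_channel, oxphos_channel)) {
    if (!ch %in% names(wide)) wide[[ch]] <- NA_real_
  }
  wide <- wide |>
    dplyr::rename(mass = dplyr::all_of(mass_channel),
                  oxphos = dplyr::all_of(oxphos_channel))
  paired <- wide |>
    dplyr::filter(!is.na(.data$mass) & !is.na(.data$oxphos))
  n_dropped <- nrow(wide) - nrow(paired)

  subject_order <- c(controls, patient_id)
  paired <- paired |>
    dplyr::mutate(subject_id = factor(.data$subject_id,
                                      levels = subject_order)) |>
    dplyr::arrange(.data$subject_id, .data$fibre_id) |>
    dplyr::mutate(subject_id = as.character(.data$subject_id)) |>
    dplyr::select(dplyr::all_of(c("subject_id", "subject_type", "fibre_id",
                                  "mass", "oxphos")))

  new_mito_data(
    paired,
    mass_channel = mass_channel, oxphos_channel = oxphos_channel,
    patient_id = patient_id, logged = FALSE,
    report = list(n_dropped_unpaired = n_dropped, n_dropped_nonpositive = 0L)
  )
}

#' Load a 2Dmito dataset from a CSV in one step
#'
#' @inheritParams as_mito_data
#' @param path Path to a long-format fibre CSV.
#' @return A raw `mito_data` tibble; pipe into [log_mito()] before modelling.
#' @export
load_fibre_data <- function(path, mass_channel, oxphos_channel, patient_id) {
  as_mito_data(read_fibre_csv(path), mass_channel, oxphos_channel, patient_id)
}

#' Natural-log transform a raw 2Dmito dataset
#'
#' Sets `x = ln(mass)` and `y = ln(oxphos)`. Fibres with a non-positive
#' intensity in either channel cannot be log-transformed; they are dropped
#' (not offset) and counted in the load report. Natural log is used
#' throughout; any other base would only rescale slopes and intercepts.
#'
#' @param data A raw `mito_data` object.
#' @return A logged `mito_data` with columns `x` and `y` appended.
#' @export
log_mito <- function(data) {
  stopifnot(inherits(data, "mito_data"))
  if (isTRUE(attr(data, "logged"))) {
    stop("dataset is already on the log scale", call. = FALSE)
  }
  report <- attr(data, "report")
  subjects_before <- unique(data$subject_id)
  keep <- data$mass > 0 & data$oxphos > 0
  dropped <- sum(!keep)
  out <- data[keep, , drop = FALSE]
  lost <- setdiff(subjects_before, unique(out$subject_id))
  if (length(lost) > 0) {
    stop("all fibres of subject(s) ", paste(lost, collapse = ", "),
         " were excluded by the positivity filter", call. = FALSE)
  }
  out <- dplyr::mutate(out, x = log(.data$mass), y = log(.data$oxphos))
  report$n_dropped_nonpositive <- report$n_dropped_nonpositive + dropped
  new_mito_data(out,
                mass_channel = attr(data, "mass_channel"),
                oxphos_channel = attr(data, "oxphos_channel"),
                patient_id = attr(data, "patient_id"),
                logged = TRUE, report = report)
}

#' Build a logged 2Dmito dataset directly from (x, y) pairs
#'
#' Convenience constructor used by the synthetic-data generator and by
#' tests: takes a tibble of already log-scale pairs and fills in the raw
#' intensities as `exp(x)`, `exp(y)`.
#'
#' @param df A data frame with columns `subject_id`, `subject_type`,
#'   `fibre_id`, `x`, `y`.
#' @param mass_channel,oxphos_channel Channel names recorded on the object.
#' @param patient_id The patient's `subject_id`.
#' @return A logged `mito_data` tibble.
#' @export
mito_data_from_log <- function(df, mass_channel = "VDAC",
                               oxphos_channel = "OXPHOS",
                               patient_id) {
  need <- c("subject_id", "subject_type", "fibre_id", "x", "y")
  stopifnot(all(need %in% names(df)))
  if (!patient_id %in% df$subject_id) {
    stop("patient_id '", patient_id, "' not found", call. = FALSE)
  }
  controls <- unique(df$subject_id[df$subject_id != patient_id])
  if (length(controls) == 0) {
    stop("dataset must contain at least one control subject", call. = FALSE)
  }
  df <- df |>
    dplyr::mutate(
      subject_id = as.character(.data$subject_id),
      fibre_id = as.character(.data$fibre_id),
      subject_type = ifelse(.data$subject_id == patient_id,
                            "patient", "control"),
      mass = exp(.data$x), oxphos = exp(.data$y)
    ) |>
    dplyr::mutate(subject_id = factor(.data$subject_id,
                                      levels = c(controls, patient_id))) |>
    dplyr::arrange(.data$subject_id) |>
    dplyr::mutate(subject_id = as.character(.data$subject_id)) |>
    dplyr::select(dplyr::all_of(c("subject_id", "subject_type", "fibre_id",
                                  "mass", "oxphos", "x", "y")))
  new_mito_data(df, mass_channel, oxphos_channel, patient_id,
                logged = TRUE,
                report = list(n_dropped_unpaired = 0L,
                              n_dropped_nonpositive = 0L))
}

#' Write a 2Dmito dataset back to the long CSV dialect
#'
#' Raw intensities are written with 17 significant digits so that
#' write-then-read round-trips bitwise.
#'
#' @param data A `mito_data` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fibre_csv <- function(data, path) {
  stopifnot(inherits(data, "mito_data"))
  long <- dplyr::bind_rows(
    data |>
      dplyr::transmute(.data$fibre_id, .data$subject_id, .data$subject_type,
                       channel = attr(data, "mass_channel"),
                       value = .data$mass),
    data |>
      dplyr::transmute(.data$fibre_id, .data$subject_id, .data$subject_type,
                       channel = attr(data, "oxphos_channel"),
                       value = .data$oxphos)
  ) |>
    dplyr::mutate(value = sprintf("%.17g", .data$value))
  readr::write_csv(long, path, progress = FALSE)
  invisible(path)
}

#' Access the load report or other metadata of a dataset
#'
#' @param data A `mito_data` object.
#' @return `mito_report()`: a list with drop counts
#'   (`n_dropped_unpaired`, `n_dropped_nonpositive`).
#' @export
mito_report <- function(data) {
  stopifnot(inherits(data, "mito_data"))
  attr(data, "report")
}

#' @rdname mito_report
#' @export
mito_patient_id <- function(data) {
  stopifnot(inherits(data, "mito_data"))
  attr(data, "patient_id")
}

# Internal: split a logged mito_data into per-subject blocks, patient last.
mito_blocks <- function(data) {
  stopifnot(inherits(data, "mito_data"))
  if (!isTRUE(attr(data, "logged"))) {
    stop("dataset must be log-transformed first (see log_mito())",
         call. = FALSE)
  }
  ids <- unique(data$subject_id)
  patient <- attr(data, "patient_id")
  ids <- c(setdiff(ids, patient), patient)
  blocks <- lapply(ids, function(id) {
    sub <- data[data$subject_id == id, , drop = FALSE]
    list(subject_id = id,
         type = sub$subject_type[1],
         fibre_id = sub$fibre_id,
         x = sub$x, y = sub$y)
  })
  list(k = length(ids), subject_ids = ids, blocks = blocks,
       patient = blocks[[length(blocks)]])
}

#' Validate a 2Dmito dataset
#'
#' Report-only checks: per-subject fibre counts and value ranges, duplicate
#' fibre identifiers, and non-finite values (named by subject and fibre).
#' The dataset itself is never modified.
#'
#' @param data A `mito_data` object.
#' @return A list of class `mito_validation` with elements `summary` (one
#'   row per subject) and `issues` (one row per problem found, zero rows for
#'   a clean dataset). Serialize with [validation_json()].
#' @export
validate_mito <- function(data) {
  stopifnot(inherits(data, "mito_data"))
  logged <- isTRUE(attr(data, "logged"))
  vx <- if (logged) data$x else data$mass
  vy <- if (logged) data$y else data$oxphos
  df <- tibble::tibble(subject_id = data$subject_id,
                       fibre_id = data$fibre_id, vx = vx, vy = vy)
  summary <- df |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      x_min = suppressWarnings(min(.data$vx, na.rm = TRUE)),
      x_max = suppressWarnings(max(.data$vx, na.rm = TRUE)),
      y_min = suppressWarnings(min(.data$vy, na.rm = TRUE)),
      y_max = suppressWarnings(max(.data$vy, na.rm = TRUE)),
      n_nonfinite = sum(!is.finite(.data$vx) | !is.finite(.data$vy)),
      .groups = "drop"
    )
  bad <- df |>
    dplyr::filter(!is.finite(.data$vx) | !is.finite(.data$vy)) |>
    dplyr::transmute(.data$subject_id, .data$fibre_id,
                     issue = "non-finite value")
  dup <- df |>
    dplyr::count(.data$subject_id, .data$fibre_id) |>
    dplyr::filter(.data$n > 1) |>
    dplyr::transmute(.data$subject_id, .data$fibre_id,
                     issue = "duplicate fibre_id")
  structure(list(summary = summary,
                 issues = dplyr::bind_rows(bad, dup)),
            class = "mito_validation")
}

#' @rdname validate_mito
#' @param report A `mito_validation` object.
#' @param path Optional path; when given the JSON is also written there.
#' @export
validation_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "mito_validation"))
  js <- jsonlite::toJSON(list(summary = report$summary,
                              issues = report$issues),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}

#' @export
print.mito_validation <- function(x, ...) {
  cat("2Dmito validation report\n")
  print(x$summary)
  if (nrow(x$issues) == 0) {
    cat("No issues found.\n")
  } else {
    cat(nrow(x$issues), "issue(s):\n")
    print(x$issues)
  }
  invisible(x)
}
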