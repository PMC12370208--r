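#' @importFrom rlang .data %||%
NULL

dataset_columns <- function() {
  c("study_id", "scenario", "species", "time_h", "value", "unit_kind",
    "normalization_ref_time", "omit_flag", "omit_reason")
}

#' Assemble and validate an experimental-style dataset collection
#'
#' A collection is a long tibble with one row per observed point and columns
#' `study_id`, `scenario` (`constitutive` / `pulse_chase`), `species`
#' (`X` / `I`), `time_h`, `value`, `unit_kind` (`absolute` / `relative`),
#' `normalization_ref_time` (hours; `NA` for absolute data), `omit_flag` and
#' `omit_reason`. A *dataset* is the subset of rows sharing
#' (`study_id`, `scenario`, `species`). Replicate values at the same time
#' point are collapsed to their mean; omitted points are retained with their
#' flag but excluded from fitting and the observation count.
#'
#' @param df A data frame with the columns above (`omit_flag`/`omit_reason`
#'   optional).
#' @return A validated collection tibble of class `sflt_data`.
#' @export
sflt_data <- function(df) {
  df <- tibble::as_tibble(df)
  if (nrow(df) == 0) stop("dataset is empty", call. = FALSE)
  if (!"omit_flag" %in% names(df)) df$omit_flag <- FALSE
  if (!"omit_reason" %in% names(df)) df$omit_reason <- NA_character_
  df$omit_flag <- df$omit_flag %in% c(TRUE, "TRUE", "true", 1)
  missing <- setdiff(setdiff(dataset_columns(), c("omit_flag", "omit_reason")),
                     names(df))
  if (length(missing)) {
    stop("dataset missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_scen <- !df$scenario %in% c("constitutive", "pulse_chase")
  if (any(bad_scen)) {
    stop("row ", which(bad_scen)[1], ": unknown scenario '",
         df$scenario[bad_scen][1], "'", call. = FALSE)
  }
  bad_sp <- !df$species %in% c("X", "I")
  if (any(bad_sp)) {
    stop("row ", which(bad_sp)[1], ": unknown species '",
         df$species[bad_sp][1], "'", call. = FALSE)
  }
  bad_val <- !is.finite(df$value) | df$value < 0
  if (any(bad_val)) {
    stop("row ", which(bad_val)[1], ": value must be a non-negative number",
         call. = FALSE)
  }
  bad_rel <- df$unit_kind == "relative" & !is.finite(df$normalization_ref_time)
  if (any(bad_rel)) {
    stop("row ", which(bad_rel)[1],
         ": relative dataset lacks a normalization reference time",
         call. = FALSE)
  }
  # collapse replicates to their mean within each dataset/time
  df <- df |>
    dplyr::group_by(.data$study_id, .data$scenario, .data$species,
                    .data$unit_kind, .data$normalization_ref_time,
                    .data$time_h) |>
    dplyr::summarise(
      value = mean(.data$value),
      omit_flag = any(.data$omit_flag),
      omit_reason = if (any(!is.na(.data$omit_reason)))
        .data$omit_reason[!is.na(.data$omit_reason)][1] else NA_character_,
      .groups = "drop") |>
    dplyr::arrange(.data$study_id, .data$scenario, .data$species,
                   .data$time_h) |>
    dplyr::relocate(dplyr::all_of(dataset_columns()))
  class(df) <- c("sflt_data", class(df))
  df
}

#' Load a dataset collection from delimited text
#'
#' @param path Path to a tab-separated file with the [sflt_data()] schema.
#' @return A validated `sflt_data` tibble.
#' @examples
#' path <- system.file("extdata", "synthetic-collection.tsv",
#'                     package = "sfltkin")
#' data <- load_dataset(path)
#' n_observations(data)
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- readr::read_tsv(path, col_types = readr::cols(
    study_id = readr::col_character(),
    scenario = readr::col_character(),
    species = readr::col_character(),
    time_h = readr::col_double(),
    value = readr::col_double(),
    unit_kind = readr::col_character(),
    normalization_ref_time = readr::col_double(),
    omit_flag = readr::col_logical(),
    omit_reason = readr::col_character()))
  if (nrow(df) == 0) stop("dataset file is empty: ", path, call. = FALSE)
  sflt_data(df)
}

#' @rdname load_dataset
#' @param data An `sflt_data` collection.
#' @export
write_dataset <- function(data, path) {
  readr::write_tsv(data, path)
  invisible(path)
}

#' Count retained (non-omitted) observations in a collection
#' @param data An `sflt_data` collection.
#' @return Integer count used as `n` in AICc scoring.
#' @export
n_observations <- function(data) sum(!data$omit_flag)

#' Unit conversion map for absolute-unit datasets
#'
#' Maps each absolute-unit `study_id` to the factor converting simulated
#' #/cell into the units of the experimental assay (e.g. concentration in
#' conditioned media). Relative datasets need no entry.
#'
#' @param ... Named positive scale factors, e.g.
#'   `unit_map("synthetic-hornig" = 1e-5)`.
#' @return A named numeric vector of class `sflt_units`.
#' @export
unit_map <- function(...) {
  u <- c(...)
  if (is.null(u)) u <- stats::setNames(numeric(0), character(0))
  if (length(u) && (any(!is.finite(u)) || any(u <= 0))) {
    stop("unit scale factors must be positive", call. = FALSE)
  }
  structure(u, class = "sflt_units")
}

# nearest whole-minute index lookup into a 1-minute reporting grid
grid_lookup <- function(tc_times, times) {
  idx <- match(round(times * 60), round(tc_times * 60))
  if (anyNA(idx)) {
    stop("dataset time ", times[which(is.na(idx))[1]],
         " h is outside the simulated trajectory", call. = FALSE)
  }
  idx
}

#' Map a simulated trajectory onto a dataset's observation scale
#'
#' Reads the simulated species at the dataset's observation times from the
#' 1-minute reporting grid, then converts to the dataset's units: relative
#' datasets are divided by the simulated value at their normalization
#' reference time, absolute datasets are multiplied by the study's
#' [unit_map()] factor.
#'
#' @param tc An `sflt_timecourse` for the dataset's scenario.
#' @param ds Rows of one dataset (single `study_id`, `scenario`, `species`).
#' @param units A [unit_map()] (needed for absolute datasets).
#' @return `ds` with a `predicted` column appended (omitted rows included).
#' @export
predict_on_dataset <- function(tc, ds, units = unit_map()) {
  stopifnot(length(unique(ds$study_id)) == 1,
            length(unique(ds$species)) == 1)
  species <- ds$species[1]
  sim <- if (species == "X") tc$X else tc$I
  pred <- sim[grid_lookup(tc$time_h, ds$time_h)]
  if (ds$unit_kind[1] == "relative") {
    ref_t <- ds$normalization_ref_time[1]
    ref <- sim[grid_lookup(tc$time_h, ref_t)]
    if (!is.finite(ref) || ref == 0) {
      stop("normalization failure: simulated ", species, " at reference time ",
           ref_t, " h is zero", call. = FALSE)
    }
    pred <- pred / ref
  } else {
    scale <- unclass(units)[ds$study_id[1]]
    if (length(scale) == 0 || is.na(scale)) {
      stop("no unit conversion factor for absolute dataset '",
           ds$study_id[1], "'", call. = FALSE)
    }
    pred <- pred * scale
  }
  dplyr::mutate(ds, predicted = pred)
}
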