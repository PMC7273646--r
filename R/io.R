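#' Read symptom frequency tables from CSV
#'
#' The interchange format is wide: columns \code{study_id, symptom_id,
#' psy_0..psy_L, adm_0..adm_L}, where L is the largest \code{max_level} in
#' the scale; rows for items with fewer levels leave the surplus cells empty.
#' The scale definition resolves each row's true level range.
#'
#' @param path CSV file path.
#' @param scale A [symptom_scale()].
#' @return A list of [freq_table()] objects (empty for a header-only file).
#' @export
read_frequency_tables <- function(path, scale) {
  stopifnot(inherits(scale, "symptom_scale"))
  if (!file.exists(path)) validation_error(paste("no such file:", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("study_id", "symptom_id") %in% names(d)))
    validation_error("frequency table CSV needs study_id and symptom_id")
  if (nrow(d) == 0L) return(list())
  lapply(seq_len(nrow(d)), function(r) {
    row <- d[r, ]
    L <- scale_max_level(scale, row$symptom_id)
    cols_psy <- sprintf("psy_%d", 0:L)
    cols_adm <- sprintf("adm_%d", 0:L)
    missing_cols <- setdiff(c(cols_psy, cols_adm), names(d))
    if (length(missing_cols))
      validation_error(sprintf("line %d (%s/%s): missing column(s) %s", r + 1L,
                               row$study_id, row$symptom_id,
                               paste(missing_cols, collapse = ", ")))
    cp <- as.numeric(row[cols_psy]); ca <- as.numeric(row[cols_adm])
    if (anyNA(cp) || anyNA(ca))
      validation_error(sprintf("line %d (%s/%s): malformed or missing count",
                               r + 1L, row$study_id, row$symptom_id))
    extra <- grep("^(psy|adm)_[0-9]+$", names(d), value = TRUE)
    lev <- as.integer(sub("^(psy|adm)_", "", extra))
    over <- extra[lev > L]
    if (length(over)) {
      vals <- suppressWarnings(as.numeric(row[over]))
      if (any(!is.na(vals) & vals != 0))
        validation_error(sprintf(
          "line %d (%s/%s): counts beyond declared max level %d", r + 1L,
          row$study_id, row$symptom_id, L))
    }
    if (any(cp < 0) || any(ca < 0) || any(cp != floor(cp)) ||
        any(ca != floor(ca)))
      validation_error(sprintf("line %d (%s/%s): negative or non-integer count",
                               r + 1L, row$study_id, row$symptom_id))
    freq_table(row$study_id, row$symptom_id, cp, ca)
  })
}

#' Write symptom frequency tables to CSV
#'
#' @param tables List of [freq_table()] objects.
#' @param path Output path.
#' @param scale A [symptom_scale()] fixing the column width.
#' @return \code{path}, invisibly.
#' @export
write_frequency_tables <- function(tables, path, scale) {
  stopifnot(inherits(scale, "symptom_scale"))
  Lmax <- max(scale$items$max_level)
  cols <- c("study_id", "symptom_id",
            sprintf("psy_%d", 0:Lmax), sprintf("adm_%d", 0:Lmax))
  rows <- lapply(tables, function(tb) {
    L <- length(tb$counts_psy) - 1L
    pad <- rep(NA_integer_, Lmax - L)
    as.data.frame(as.list(stats::setNames(
      c(tb$study_id, tb$symptom_id, c(tb$counts_psy, pad),
        c(tb$counts_adm, pad)), cols)), stringsAsFactors = FALSE)
  })
  d <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read per-study summary rows from CSV
#'
#' Columns: \code{study_id, scale_id, n_base_psy, n_base_adm, n_end_psy,
#' n_end_adm, mean_end_psy, sd_end_psy, mean_end_adm, sd_end_adm} (the mean
#' and SD columns may be empty per study). Dropout counts derive as
#' \code{n_base - n_end} per arm.
#'
#' @param path CSV file path.
#' @return A data frame with the above columns, validated (\code{0 <= n_end
#'   <= n_base}; SDs positive when present).
#' @export
read_study_summaries <- function(path) {
  if (!file.exists(path)) validation_error(paste("no such file:", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_id", "scale_id", "n_base_psy", "n_base_adm",
            "n_end_psy", "n_end_adm")
  miss <- setdiff(need, names(d))
  if (length(miss))
    validation_error(paste("missing column(s):", paste(miss, collapse = ", ")))
  if (any(d$n_end_psy > d$n_base_psy | d$n_end_adm > d$n_base_adm |
          d$n_end_psy < 0 | d$n_end_adm < 0, na.rm = TRUE))
    validation_error("need 0 <= n_end <= n_base per arm")
  for (col in c("sd_end_psy", "sd_end_adm"))
    if (col %in% names(d) && any(!is.na(d[[col]]) & d[[col]] <= 0))
      validation_error(paste(col, "must be > 0 when present"))
  d
}

#' Read patient profiles from CSV
#'
#' Columns: \code{patient_id, scale_id, treatment, endpoint_sum}, one column
#' per scale item id, and any further columns as named covariates.
#'
#' @param path CSV file path.
#' @param scale A [symptom_scale()]; item columns must match its item ids.
#' @return A validated patient-profile data frame.
#' @export
read_patient_profiles <- function(path, scale) {
  stopifnot(inherits(scale, "symptom_scale"))
  if (!file.exists(path)) validation_error(paste("no such file:", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(d))
    validation_error("patients CSV needs patient_id")
  if (anyDuplicated(d$patient_id))
    validation_error("duplicate patient_id")
  ids <- scale_item_ids(scale)
  miss <- setdiff(ids, names(d))
  if (length(miss))
    validation_error(paste("missing item column(s):",
                           paste(miss, collapse = ", ")))
  s <- as.matrix(d[, ids, drop = FALSE])
  if (anyNA(s)) validation_error("missing item value (profiles must be complete)")
  maxes <- scale$items$max_level[match(ids, scale$items$item_id)]
  if (any(s < 0) || any(s != floor(s)) || any(sweep(s, 2, maxes, ">")))
    validation_error("item score outside 0..max_level")
  if ("treatment" %in% names(d) &&
      !all(d$treatment %in% c("PSY", "ADM", NA)))
    validation_error("treatment must be PSY or ADM")
  d
}

#' Write an analysis result table to CSV
#'
#' Generic writer for the pipeline's result types (effect estimates, pooled
#' effects, SOrT scores, allocation results, study summaries, patient
#' profiles). Numeric fields survive a write/read round trip to at least 12
#' significant digits.
#'
#' @param x A result data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path CSV file path.
#' @param class Optional class to restore (\code{"effect_estimates"},
#'   \code{"pooled_effects"}, \code{"sort_scores"},
#'   \code{"allocation_result"}).
#' @return The data frame, classed when requested.
#' @export
read_results <- function(path, class = NULL) {
  if (!file.exists(path)) validation_error(paste("no such file:", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(class)) class(d) <- c(class, "data.frame")
  d
}

#' Check a set of pipeline input files against all invariants
#'
#' Validation entry point: reads each supplied file with the matching reader
#' and collects violations instead of stopping at the first.
#'
#' @param scale A [symptom_scale()] (or path to a scale YAML).
#' @param frequency_tables,study_summaries,patients Optional file paths.
#' @return Invisibly, a character vector of violation messages (empty when
#'   everything validates); also printed as messages.
#' @export
validate_inputs <- function(scale, frequency_tables = NULL,
                            study_summaries = NULL, patients = NULL) {
  if (is.character(scale)) scale <- read_scale_yaml(scale)
  problems <- character()
  check <- function(expr) {
    tryCatch({ expr; NULL }, error = function(e) conditionMessage(e))
  }
  if (!is.null(frequency_tables)) {
    p <- check(read_frequency_tables(frequency_tables, scale))
    if (!is.null(p)) problems <- c(problems, paste0(frequency_tables, ": ", p))
  }
  if (!is.null(study_summaries)) {
    p <- check(read_study_summaries(study_summaries))
    if (!is.null(p)) problems <- c(problems, paste0(study_summaries, ": ", p))
  }
  if (!is.null(patients)) {
    p <- check(read_patient_profiles(patients, scale))
    if (!is.null(p)) problems <- c(problems, paste0(patients, ": ", p))
  }
  for (p in problems) message(p)
  if (!length(problems)) message("all inputs valid")
  invisible(problems)
}
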