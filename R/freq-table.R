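#' Two-arm ordinal endpoint frequency table for one symptom in one study
#'
#' The unit of symptom-level evidence: for a single study and a single scale
#' item, the number of completer patients at each endpoint severity level
#' (consecutive integers \code{0..L}) in the psychotherapy and the
#' antidepressant-medication (ADM) arm.
#'
#' @param study_id Study identifier.
#' @param symptom_id Scale item identifier.
#' @param counts_psy,counts_adm Non-negative integer vectors of identical
#'   length \code{L + 1}; element \code{c + 1} is the number of patients at
#'   severity level \code{c}.
#'
#' @return An object of class \code{freq_table}.
#' @export
freq_table <- function(study_id, symptom_id, counts_psy, counts_adm) {
  counts_psy <- as.integer(counts_psy)
  counts_adm <- as.integer(counts_adm)
  if (length(counts_psy) != length(counts_adm))
    validation_error(sprintf("%s/%s: arm count vectors differ in length",
                             study_id, symptom_id))
  if (length(counts_psy) < 2L)
    validation_error(sprintf("%s/%s: need at least two severity levels",
                             study_id, symptom_id))
  if (anyNA(counts_psy) || anyNA(counts_adm) ||
      any(counts_psy < 0L) || any(counts_adm < 0L))
    validation_error(sprintf("%s/%s: counts must be non-negative integers",
                             study_id, symptom_id))
  structure(list(study_id = as.character(study_id),
                 symptom_id = as.character(symptom_id),
                 counts_psy = counts_psy, counts_adm = counts_adm),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("<freq_table %s/%s, levels 0-%d>\n", x$study_id, x$symptom_id,
              length(x$counts_psy) - 1L))
  m <- rbind(psy = x$counts_psy, adm = x$counts_adm)
  colnames(m) <- 0:(length(x$counts_psy) - 1L)
  print(m)
  invisible(x)
}

#' Swap the two arms of a frequency table
#'
#' Utility used by antisymmetry checks: returns the table with psychotherapy
#' and ADM counts exchanged.
#'
#' @param table A [freq_table()].
#' @return A [freq_table()] with the arms exchanged.
#' @export
swap_arms <- function(table) {
  freq_table(table$study_id, table$symptom_id,
             table$counts_adm, table$counts_psy)
}
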