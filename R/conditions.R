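#' @keywords internal
variance_error <- function(message) {
  stop(errorCondition(message,
    class = c("sortmeta_variance_error", "sortmeta_error", "error", "condition")))
}

#' @keywords internal
validation_error <- function(message) {
  stop(errorCondition(message,
    class = c("sortmeta_validation_error", "sortmeta_error", "error", "condition")))
}
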