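#' Compute Symptom-Oriented Therapy (SOrT) scores
#'
#' The SOrT score combines pooled symptom-specific effect sizes with a
#' patient's baseline symptom profile:
#' \deqn{SOrT = \sum_i m_i s_i}
#' where \eqn{m_i} is the meta-analytic effect size for symptom i on the SMD
#' scale (the \code{pooled_smd} column of [pool_symptom_effects()] output)
#' and \eqn{s_i} the patient's baseline score on item i. Positive scores
#' indicate an ADM-favouring symptom profile. The severity-adjusted variant
#' \deqn{SOrT_{adj} = \sum_i m_i s_i / \sum_i s_i}
#' removes the artefactual correlation with overall symptom severity that
#' the raw score carries when most weights share a sign; it is a convex
#' combination of the weights, hence bounded by \code{[min m, max m]}, and is
#' undefined (NA) for an all-zero profile.
#'
#' @param profiles Patient-profile data frame (one row per patient, item
#'   columns named by scale item ids; see [read_patient_profiles()] or
#'   [generate_patient_cohort()]).
#' @param weights Per-symptom weights m: a named numeric vector over item
#'   ids, or a \code{pooled_effects} data frame (its \code{pooled_smd} by
#'   \code{symptom_id} is used). Every scale item must have a weight.
#' @param scale A [symptom_scale()] matching the profiles.
#' @return A data frame of class \code{sort_scores}: \code{patient_id},
#'   \code{scale_id}, \code{value}, \code{value_adjusted}, plus
#'   \code{treatment} and \code{endpoint_sum} carried over when present in
#'   \code{profiles}.
#' @export
compute_sort <- function(profiles, weights, scale) {
  stopifnot(inherits(scale, "symptom_scale"))
  w <- as_weight_vector(weights)
  ids <- scale_item_ids(scale)
  missing_w <- setdiff(ids, names(w))
  if (length(missing_w))
    validation_error(paste("missing weight for item(s):",
                           paste(missing_w, collapse = ", ")))
  p <- as.data.frame(profiles)
  missing_i <- setdiff(ids, names(p))
  if (length(missing_i))
    validation_error(paste("profiles lack item column(s):",
                           paste(missing_i, collapse = ", ")))
  s <- as.matrix(p[, ids, drop = FALSE])
  if (anyNA(s))
    validation_error("missing item scores: complete profiles are required")
  maxes <- scale$items$max_level[match(ids, scale$items$item_id)]
  if (any(s < 0) || any(sweep(s, 2, maxes, ">")))
    validation_error("item scores outside 0..max_level")
  value <- as.vector(s %*% w[ids])
  ssum <- rowSums(s)
  adjusted <- ifelse(ssum > 0, value / ssum, NA_real_)
  out <- data.frame(patient_id = p$patient_id, scale_id = scale$scale_id,
                    value = value, value_adjusted = adjusted,
                    stringsAsFactors = FALSE)
  for (col in c("treatment", "endpoint_sum"))
    if (col %in% names(p)) out[[col]] <- p[[col]]
  class(out) <- c("sort_scores", "data.frame")
  out
}

#' @keywords internal
as_weight_vector <- function(weights) {
  if (inherits(weights, "pooled_effects") ||
      (is.data.frame(weights) && all(c("symptom_id", "pooled_smd") %in%
                                       names(weights))))
    return(stats::setNames(weights$pooled_smd, weights$symptom_id))
  if (is.numeric(weights) && !is.null(names(weights))) return(weights)
  validation_error("weights must be a named numeric vector or pooled_effects")
}

#' Descriptive summary of SOrT scores
#'
#' @param scores A \code{sort_scores} data frame (or numeric vector).
#' @param adjusted Summarise \code{value_adjusted} instead of \code{value}
#'   (NA-adjusted scores are dropped with a message).
#' @return A list: \code{n}, \code{min}, \code{median}, \code{mean},
#'   \code{max}, \code{sd} (sample SD) and \code{frac_positive}, the fraction
#'   of strictly positive scores — the feasibility diagnostic for the valence
#'   split (a one-sided score distribution makes that split degenerate).
#' @export
summarize_scores <- function(scores, adjusted = FALSE) {
  x <- if (is.numeric(scores)) scores
       else if (adjusted) scores$value_adjusted else scores$value
  if (anyNA(x)) {
    message("dropping ", sum(is.na(x)), " undefined score(s)")
    x <- x[!is.na(x)]
  }
  if (length(x) == 0L) validation_error("no scores to summarise")
  list(n = length(x), min = min(x), median = stats::median(x),
       mean = mean(x), max = max(x),
       sd = if (length(x) > 1) stats::sd(x) else 0,
       frac_positive = mean(x > 0))
}

#' Cross-scale correlation of SOrT scores
#'
#' Pearson correlation between two scales' SOrT scores for the same
#' patients, with the usual two-sided t-test. Patients are paired by
#' \code{patient_id}.
#'
#' @param scores_a,scores_b \code{sort_scores} data frames for two scales.
#' @param adjusted Correlate the severity-adjusted scores.
#' @return A list: \code{r}, \code{p}, \code{n}.
#' @export
crossvalidate_scales <- function(scores_a, scores_b, adjusted = FALSE) {
  col <- if (adjusted) "value_adjusted" else "value"
  m <- merge(scores_a[, c("patient_id", col)],
             scores_b[, c("patient_id", col)], by = "patient_id")
  m <- m[stats::complete.cases(m), ]
  if (nrow(m) < 3L) validation_error("need at least 3 paired patients")
  x <- m[[2]]; y <- m[[3]]
  if (stats::var(x) == 0 || stats::var(y) == 0)
    validation_error("zero variance in one scale's scores")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(m))
}

#' Regress SOrT scores on a covariate
#'
#' One ordinary-least-squares model per predictor, as in a covariate table:
#' unadjusted (\code{score ~ x}) and, when a baseline sum-score is supplied,
#' adjusted (\code{score ~ x + baseline}). The intercept is fitted but not
#' reported.
#'
#' @param scores Numeric outcome vector (SOrT scores).
#' @param predictor Numeric or binary covariate vector.
#' @param baseline Optional baseline sum-score for the adjusted model.
#' @return A list with elements \code{unadjusted} and (if baseline given)
#'   \code{adjusted}, each \code{c(beta, se, p)} for the predictor.
#' @export
covariate_regression <- function(scores, predictor, baseline = NULL) {
  if (length(predictor) != length(scores))
    validation_error("predictor length must match scores")
  if (stats::var(predictor) == 0) validation_error("constant predictor")
  pull <- function(fit) {
    sm <- summary(fit)$coefficients
    c(beta = sm[2, "Estimate"], se = sm[2, "Std. Error"],
      p = sm[2, "Pr(>|t|)"])
  }
  out <- list(unadjusted = pull(stats::lm(scores ~ predictor)))
  if (!is.null(baseline))
    out$adjusted <- pull(stats::lm(scores ~ predictor + baseline))
  out
}
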