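#' Leave-one-study-out symptom weights
#'
#' Recomputes pooled per-symptom weights excluding one study, so that scoring
#' a validation cohort drawn from that study stays independent of the
#' meta-analytic training data. Symptoms left with no studies are dropped
#' from the weight set (scoring then errors if a profile needs them).
#'
#' @param all_effects An \code{effect_estimates} data frame across studies
#'   and symptoms.
#' @param exclude_study Study id to leave out; if absent from the data a
#'   warning is issued and full pooling is returned.
#' @inheritParams pool_random_effects
#' @return A \code{pooled_effects} data frame (one row per remaining
#'   symptom); use directly as \code{weights} in [compute_sort()].
#' @export
loso_weights <- function(all_effects, exclude_study,
                         method = c("REML", "DL")) {
  method <- match.arg(method)
  est <- as.data.frame(all_effects)
  if (!exclude_study %in% est$study_id)
    warning("study '", exclude_study, "' not present; using all studies")
  keep <- est[est$study_id != exclude_study, , drop = FALSE]
  class(keep) <- c("effect_estimates", "data.frame")
  pool_symptom_effects(keep, method = method)
}

#' Valence split: optimal vs non-optimal allocation by score sign
#'
#' A patient is optimally allocated when the SOrT score valence matches the
#' received arm: positive score and ADM, or negative score and
#' psychotherapy. Scores exactly zero are excluded (count reported).
#'
#' @param scores A \code{sort_scores} data frame with a \code{treatment}
#'   column (\code{"PSY"}/\code{"ADM"}).
#' @return \code{scores} with added logical column \code{optimal} (NA for
#'   excluded patients); attributes \code{n_excluded} and
#'   \code{frac_positive} (the feasibility diagnostic: a split with 0\% or
#'   100\% positive scores compares treatment arms, not allocation quality).
#' @export
split_valence <- function(scores) {
  stopifnot(!is.null(scores$treatment))
  v <- scores$value
  optimal <- ifelse(v == 0, NA,
                    (v > 0 & scores$treatment == "ADM") |
                      (v < 0 & scores$treatment == "PSY"))
  n_excl <- sum(is.na(optimal))
  if (n_excl > 0) message(n_excl, " patient(s) with zero score excluded")
  out <- scores
  out$optimal <- optimal
  attr(out, "n_excluded") <- n_excl
  attr(out, "frac_positive") <- mean(v > 0)
  out
}

#' Median split: optimal vs non-optimal allocation by score rank
#'
#' Patients above the sample median SOrT score are treated as optimally
#' allocated to ADM, those below to psychotherapy; scores exactly at the
#' median are excluded (count reported).
#'
#' @inheritParams split_valence
#' @return As [split_valence()].
#' @export
split_median <- function(scores) {
  stopifnot(!is.null(scores$treatment))
  if (nrow(scores) < 2L) validation_error("median split needs >= 2 patients")
  v <- scores$value
  med <- stats::median(v)
  optimal <- ifelse(v == med, NA,
                    (v > med & scores$treatment == "ADM") |
                      (v < med & scores$treatment == "PSY"))
  n_excl <- sum(is.na(optimal))
  if (n_excl > 0) message(n_excl, " patient(s) at the median excluded")
  out <- scores
  out$optimal <- optimal
  attr(out, "n_excluded") <- n_excl
  attr(out, "frac_positive") <- mean(v > 0)
  out
}

#' Select the patients with the most extreme SOrT scores
#'
#' Retains the \code{ceiling(fraction * n)} patients whose scores lie
#' farthest from a reference point: zero (the valence threshold) or the
#' sample median. Ties at the cut are retained in \code{patient_id} order
#' until the quota is filled.
#'
#' @param scores A \code{sort_scores} data frame.
#' @param fraction Fraction to retain, in (0, 1\]; default 2/3.
#' @param reference \code{"ZERO"} or \code{"MEDIAN"}.
#' @return The retained subset of \code{scores}.
#' @export
select_extreme <- function(scores, fraction = 2 / 3,
                           reference = c("ZERO", "MEDIAN")) {
  reference <- match.arg(reference)
  if (fraction <= 0 || fraction > 1)
    validation_error("fraction must be in (0, 1]")
  n_keep <- ceiling(fraction * nrow(scores))
  ref <- if (reference == "ZERO") 0 else stats::median(scores$value)
  dist <- abs(scores$value - ref)
  ord <- order(-dist, scores$patient_id)
  scores[sort(ord[seq_len(n_keep)]), , drop = FALSE]
}

#' Compare endpoint outcomes between optimal and non-optimal groups
#'
#' Two-sample t-test of endpoint sum-scores (lower = better) for patients
#' allocated optimally versus non-optimally. Welch's unequal-variance test
#' by default; \code{pooled = TRUE} gives the classical equal-variance test.
#'
#' @param split A data frame from [split_valence()]/[split_median()] (needs
#'   \code{endpoint_sum} and \code{optimal}); excluded patients (NA flag)
#'   are ignored.
#' @param split_method Label recorded in the result.
#' @param pooled Use the pooled-variance t-test.
#' @return A one-row data frame of class \code{allocation_result}:
#'   \code{split_method}, \code{n_opt}, \code{n_nonopt}, \code{mean_opt},
#'   \code{sd_opt}, \code{mean_nonopt}, \code{sd_nonopt}, \code{t},
#'   \code{df}, \code{p}.
#' @export
compare_groups <- function(split, split_method = "VALENCE", pooled = FALSE) {
  if (is.null(split$endpoint_sum) || is.null(split$optimal))
    validation_error("split needs endpoint_sum and optimal columns")
  d <- split[!is.na(split$optimal) & !is.na(split$endpoint_sum), ]
  opt <- d$endpoint_sum[d$optimal]
  non <- d$endpoint_sum[!d$optimal]
  if (length(opt) < 2L || length(non) < 2L)
    validation_error(paste0(split_method,
                            " split: a group has fewer than 2 patients"))
  tt <- stats::t.test(opt, non, var.equal = pooled)
  out <- data.frame(split_method = split_method,
                    n_opt = length(opt), n_nonopt = length(non),
                    mean_opt = mean(opt), sd_opt = stats::sd(opt),
                    mean_nonopt = mean(non), sd_nonopt = stats::sd(non),
                    t = unname(tt$statistic), df = unname(tt$parameter),
                    p = tt$p.value, stringsAsFactors = FALSE)
  class(out) <- c("allocation_result", "data.frame")
  out
}

#' Regression of endpoint outcome on the allocation indicator
#'
#' OLS of the endpoint sum-score on the optimal-allocation indicator,
#' unadjusted and (when a baseline sum-score is given) adjusted for it. The
#' unadjusted coefficient equals \code{mean_opt - mean_nonopt} exactly.
#'
#' @param split As in [compare_groups()].
#' @param baseline Optional baseline sum-score vector aligned with
#'   \code{split}.
#' @return A list of \code{c(beta, se, p)} vectors: \code{unadjusted} and,
#'   if baseline supplied, \code{adjusted}.
#' @export
allocation_regression <- function(split, baseline = NULL) {
  keep <- !is.na(split$optimal) & !is.na(split$endpoint_sum)
  y <- split$endpoint_sum[keep]
  x <- as.numeric(split$optimal[keep])
  covariate_regression(y, x, baseline = baseline[keep])
}

#' Run the full allocation evaluation
#'
#' For each requested split, flags optimal/non-optimal patients and compares
#' endpoint outcomes, assembling one row per split (the standard evaluation
#' table layout). Infeasible splits — e.g. a valence split on a cohort whose
#' scores all share one sign — are reported with \code{feasible = FALSE} and
#' NA statistics instead of aborting the report.
#'
#' @param scores A \code{sort_scores} data frame with \code{treatment} and
#'   \code{endpoint_sum}.
#' @param splits Character subset of \code{c("valence", "median",
#'   "extreme_valence", "extreme_median")}.
#' @param extreme_fraction Fraction retained by the extreme-group splits.
#' @param pooled Use pooled-variance t-tests.
#' @return A data frame, one row per split: the [compare_groups()] columns
#'   plus \code{feasible}, \code{frac_positive} and \code{note}. Valence-based
#'   splits are marked infeasible when all nonzero scores share one sign: the
#'   split would then merely compare the treatment arms, not allocation
#'   quality.
#' @export
run_allocation_pipeline <- function(scores,
                                    splits = c("valence", "median",
                                               "extreme_valence",
                                               "extreme_median"),
                                    extreme_fraction = 2 / 3,
                                    pooled = FALSE) {
  splits <- match.arg(splits, several.ok = TRUE)
  frac_pos <- mean(scores$value > 0)
  one_sign <- all(scores$value >= 0) || all(scores$value <= 0)
  one <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      out <- data.frame(split_method = name, n_opt = NA_integer_,
                        n_nonopt = NA_integer_, mean_opt = NA_real_,
                        sd_opt = NA_real_, mean_nonopt = NA_real_,
                        sd_nonopt = NA_real_, t = NA_real_, df = NA_real_,
                        p = NA_real_, feasible = FALSE,
                        frac_positive = frac_pos, note = res,
                        stringsAsFactors = FALSE)
    } else {
      out <- res
      out$feasible <- TRUE
      out$frac_positive <- frac_pos
      out$note <- ""
    }
    out
  }
  valence_guard <- function(name, expr) {
    if (one_sign)
      one(name, stop("infeasible: all scores share one sign (",
                     round(100 * frac_pos), "% positive)"))
    else one(name, expr)
  }
  rows <- list()
  for (sp in splits) {
    rows[[sp]] <- switch(sp,
      valence = valence_guard("VALENCE",
        compare_groups(split_valence(scores), "VALENCE", pooled)),
      median = one("MEDIAN",
        compare_groups(split_median(scores), "MEDIAN", pooled)),
      extreme_valence = valence_guard("EXTREME_VALENCE",
        compare_groups(split_valence(
          select_extreme(scores, extreme_fraction, "ZERO")),
          "EXTREME_VALENCE", pooled)),
      extreme_median = one("EXTREME_MEDIAN",
        compare_groups(split_median(
          select_extreme(scores, extreme_fraction, "MEDIAN")),
          "EXTREME_MEDIAN", pooled)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
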