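#' @keywords internal
#' rma.uni with a damped-step retry and a DerSimonian-Laird fallback for the
#' rare REML non-convergence on unruly simulated sets.
rma_fit <- function(yi, sei, method, mods = NULL, test = "z") {
  call_rma <- function(method, control) {
    if (is.null(mods))
      metafor::rma.uni(yi = yi, sei = sei, method = method, test = test,
                       control = control)
    else
      metafor::rma.uni(yi = yi, sei = sei, mods = mods, method = method,
                       test = test, control = control)
  }
  fit <- tryCatch(call_rma(method, NULL), error = function(e) NULL)
  if (is.null(fit) && method == "REML")
    fit <- tryCatch(call_rma("REML", list(stepadj = 0.5, maxiter = 1000)),
                    error = function(e) NULL)
  if (is.null(fit)) fit <- call_rma("DL", NULL)
  fit
}

#' Pool per-study effects for one symptom with random-effects meta-analysis
#'
#' Inverse-variance random-effects pooling of one symptom's (or the
#' sum-score's) per-study effect estimates. The between-study variance tau^2
#' is estimated by REML (default) or the DerSimonian-Laird closed form; the
#' pooled effect is \eqn{\sum w_i y_i / \sum w_i} with
#' \eqn{w_i = 1/(se_i^2 + \tau^2)}, its SE is \eqn{(\sum w_i)^{-1/2}}, and CI
#' and p-value use normal theory (no Knapp-Hartung unless requested).
#'
#' @param estimates An \code{effect_estimates} data frame for a single
#'   symptom; all rows must share one metric.
#' @param method \code{"REML"} (default) or \code{"DL"}.
#' @param knha Use the Knapp-Hartung adjustment (default FALSE, matching the
#'   normal-theory default of the underlying software).
#' @return A one-row data frame of class \code{pooled_effects}: columns
#'   \code{symptom_id}, \code{metric}, \code{k}, \code{pooled}, \code{se},
#'   \code{ci_low}, \code{ci_high}, \code{tau2}, \code{Q}, \code{df},
#'   \code{i2}, \code{p}, \code{p_adj} (NA until [adjust_bh()] is applied) and
#'   \code{pooled_smd}, the pooled value on the SMD scale (log-OR metrics are
#'   divided by 1.81; SMDs pass through). \code{pooled_smd} is the
#'   symptom weight m used by [compute_sort()].
#'
#' @details I^2 is computed from Cochran's Q as
#'   \code{max(0, (Q - df)/Q) * 100} (0 when Q = 0), the Q-based definition,
#'   under both estimators. Heterogeneity df is \code{k - 1}.
#' @export
pool_random_effects <- function(estimates, method = c("REML", "DL"),
                                knha = FALSE) {
  method <- match.arg(method)
  est <- as.data.frame(estimates)
  if (nrow(est) == 0L) validation_error("no estimates to pool")
  if (length(unique(est$metric)) != 1L)
    validation_error("mixed effect metrics in one pool")
  if (length(unique(est$symptom_id)) != 1L)
    validation_error("pool_random_effects pools a single symptom")
  fit <- rma_fit(est$value, est$se, method, test = if (knha) "knha" else "z")
  k <- fit$k
  Q <- as.numeric(fit$QE)
  df <- heterogeneity_df(k)
  i2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  metric <- est$metric[1]
  pooled <- as.numeric(fit$beta)
  out <- data.frame(
    symptom_id = est$symptom_id[1], metric = metric, k = k,
    pooled = pooled, se = fit$se, ci_low = fit$ci.lb, ci_high = fit$ci.ub,
    tau2 = fit$tau2, Q = Q, df = df, i2 = i2, p = fit$pval, p_adj = NA_real_,
    pooled_smd = if (metric %in% c("LOG_POR", "LOG_OR_MEDIAN"))
      convert_logor_to_smd(pooled) else pooled,
    stringsAsFactors = FALSE)
  class(out) <- c("pooled_effects", "data.frame")
  out
}

#' Pool every symptom in an effect set and adjust p-values
#'
#' Splits an \code{effect_estimates} data frame by \code{symptom_id}, pools
#' each symptom with [pool_random_effects()], and applies Benjamini-Hochberg
#' adjustment across the pooled symptoms. Call once per scale to keep the
#' adjustment family scale-wise (the default analysis layout); pass the union
#' of scales for a joint family.
#'
#' @inheritParams pool_random_effects
#' @param adjust Apply BH across the returned rows (default TRUE).
#' @return A \code{pooled_effects} data frame, one row per symptom.
#' @export
pool_symptom_effects <- function(estimates, method = c("REML", "DL"),
                                 adjust = TRUE, knha = FALSE) {
  method <- match.arg(method)
  est <- as.data.frame(estimates)
  if (nrow(est) == 0L) validation_error("no estimates to pool")
  parts <- split(est, est$symptom_id)
  out <- do.call(rbind, lapply(parts, function(p) {
    pe <- pool_random_effects(p, method = method, knha = knha)
    pe
  }))
  rownames(out) <- NULL
  if (adjust) out$p_adj <- adjust_bh(out$p)
  class(out) <- c("pooled_effects", "data.frame")
  out
}

#' Heterogeneity degrees of freedom
#'
#' @param k Number of studies pooled (>= 1).
#' @return \code{k - 1}.
#' @export
heterogeneity_df <- function(k) {
  if (length(k) != 1L || is.na(k) || k < 1) validation_error("k must be >= 1")
  as.integer(k) - 1L
}

#' Egger regression test for funnel-plot asymmetry
#'
#' Regresses the standard normal deviate \eqn{y_i / se_i} on precision
#' \eqn{1 / se_i}; the intercept estimates small-study asymmetry and
#' \eqn{z = intercept / SE(intercept)} is referred to the standard normal
#' (two-sided).
#'
#' @param estimates An \code{effect_estimates} data frame with k >= 3 rows.
#' @return A list with \code{z}, \code{p}, \code{intercept}, \code{se} and a
#'   \code{funnel} data frame (\code{study_id}, \code{value}, \code{se}) for
#'   plotting (plot \code{value} against \code{se} with the se axis
#'   inverted).
#' @export
eggers_test <- function(estimates) {
  est <- as.data.frame(estimates)
  if (nrow(est) < 3L) validation_error("Egger's test needs at least 3 studies")
  if (length(unique(est$se)) == 1L)
    validation_error("degenerate design: all standard errors equal")
  snd <- est$value / est$se
  prec <- 1 / est$se
  fit <- stats::lm(snd ~ prec)
  sm <- summary(fit)$coefficients
  z <- sm["(Intercept)", "Estimate"] / sm["(Intercept)", "Std. Error"]
  list(z = z, p = 2 * stats::pnorm(-abs(z)),
       intercept = sm["(Intercept)", "Estimate"],
       se = sm["(Intercept)", "Std. Error"],
       funnel = data.frame(study_id = est$study_id, value = est$value,
                           se = est$se, stringsAsFactors = FALSE))
}

#' Mixed-effects meta-regression on a study-level moderator
#'
#' Regresses per-study effects on a moderator in an inverse-variance weighted
#' mixed-effects model (REML tau^2), e.g. effect on differential dropout
#' (percentage points of greater ADM dropout). The slope is tested with a
#' Wald z test.
#'
#' @param estimates An \code{effect_estimates} data frame (k >= 3).
#' @param moderator Numeric vector, one value per row of \code{estimates}.
#' @return A list: \code{slope}, \code{se}, \code{z}, \code{p},
#'   \code{intercept}, \code{tau2} (residual), \code{QE} (residual
#'   heterogeneity), \code{df} (k - 2), \code{k}.
#' @export
meta_regression <- function(estimates, moderator) {
  est <- as.data.frame(estimates)
  if (nrow(est) < 3L) validation_error("meta-regression needs at least 3 studies")
  if (length(moderator) != nrow(est))
    validation_error("moderator length must match the number of studies")
  if (stats::var(moderator) == 0) validation_error("moderator is constant")
  fit <- rma_fit(est$value, est$se, "REML", mods = cbind(moderator))
  list(slope = as.numeric(fit$beta[2]), se = fit$se[2], z = fit$zval[2],
       p = fit$pval[2], intercept = as.numeric(fit$beta[1]),
       tau2 = fit$tau2, QE = as.numeric(fit$QE), df = nrow(est) - 2L,
       k = nrow(est))
}

#' Meta-analysis of per-arm dropout
#'
#' Builds per-study 2x2 tables (dropout vs completer by arm), pools the log
#' odds ratio of dropout with random effects — oriented so that OR < 1 means
#' fewer psychotherapy dropouts — and reports aggregate dropout rates per arm
#' (total dropouts / total baseline, as percent to one decimal).
#'
#' @param summaries A study-summary data frame (see
#'   [read_study_summaries()]): needs \code{n_base_psy}, \code{n_end_psy},
#'   \code{n_base_adm}, \code{n_end_adm}.
#' @param method tau^2 estimator for the pool, \code{"REML"} or \code{"DL"}.
#' @return A list: \code{pooled} (a \code{pooled_effects} row on the log OR
#'   scale, \code{symptom_id = "DROPOUT"}), \code{rate_psy_pct},
#'   \code{rate_adm_pct} (percent, one decimal), and \code{totals}
#'   (dropouts and baseline n per arm).
#' @export
pool_dropout <- function(summaries, method = c("REML", "DL")) {
  method <- match.arg(method)
  s <- as.data.frame(summaries)
  need <- c("n_base_psy", "n_end_psy", "n_base_adm", "n_end_adm")
  if (!all(need %in% names(s)))
    validation_error("summaries need baseline and endpoint n per arm")
  if (any(s$n_end_psy > s$n_base_psy) || any(s$n_end_adm > s$n_base_adm))
    validation_error("endpoint n exceeds baseline n")
  drop_psy <- s$n_base_psy - s$n_end_psy
  drop_adm <- s$n_base_adm - s$n_end_adm
  rates <- c(psy = round(100 * sum(drop_psy) / sum(s$n_base_psy), 1),
             adm = round(100 * sum(drop_adm) / sum(s$n_base_adm), 1))
  pooled <- NULL
  if (nrow(s) >= 2L) {
    ef <- metafor::escalc(measure = "OR", ai = drop_psy, bi = s$n_end_psy,
                          ci = drop_adm, di = s$n_end_adm)
    est <- effect_estimate(s$study_id, "DROPOUT", "LOG_OR_DROPOUT",
                           as.numeric(ef$yi), sqrt(ef$vi),
                           s$n_base_psy, s$n_base_adm)
    fit <- rma_fit(est$value, est$se, method)
    Q <- as.numeric(fit$QE); df <- heterogeneity_df(fit$k)
    pooled <- data.frame(
      symptom_id = "DROPOUT", metric = "LOG_OR_DROPOUT", k = fit$k,
      pooled = as.numeric(fit$beta), se = fit$se, ci_low = fit$ci.lb,
      ci_high = fit$ci.ub, tau2 = fit$tau2, Q = Q, df = df,
      i2 = if (Q > 0) max(0, (Q - df) / Q) * 100 else 0, p = fit$pval,
      p_adj = NA_real_, pooled_smd = NA_real_, stringsAsFactors = FALSE)
    class(pooled) <- c("pooled_effects", "data.frame")
  } else if (nrow(s) == 1L) {
    # single study: report its log OR directly (equal dropout -> 0)
    a <- drop_psy[1]; b <- s$n_end_psy[1]; cc <- drop_adm[1]; d <- s$n_end_adm[1]
    if (min(a, b, cc, d) == 0) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
    lo <- log((a / b) / (cc / d)); se <- sqrt(1/a + 1/b + 1/cc + 1/d)
    pooled <- data.frame(
      symptom_id = "DROPOUT", metric = "LOG_OR_DROPOUT", k = 1L, pooled = lo,
      se = se, ci_low = lo - stats::qnorm(0.975) * se,
      ci_high = lo + stats::qnorm(0.975) * se, tau2 = 0, Q = 0, df = 0L,
      i2 = 0, p = 2 * stats::pnorm(-abs(lo / se)), p_adj = NA_real_,
      pooled_smd = NA_real_, stringsAsFactors = FALSE)
    class(pooled) <- c("pooled_effects", "data.frame")
  }
  list(pooled = pooled, rate_psy_pct = unname(rates["psy"]),
       rate_adm_pct = unname(rates["adm"]),
       totals = list(drop_psy = sum(drop_psy), base_psy = sum(s$n_base_psy),
                     drop_adm = sum(drop_adm), base_adm = sum(s$n_base_adm)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values (applied
#' scale-wise across a scale's symptom set in the default pipeline).
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Adjusted p-values, capped at 1.
#' @export
adjust_bh <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    validation_error("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
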