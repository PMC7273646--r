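#' @keywords internal
#' Negative log-likelihood of the two-arm cumulative-logit model.
#' th = (z_1..z_L, beta); categories 1..K = levels 0..L; n is a 2 x K count
#' matrix, row 1 = ADM (x = 0), row 2 = psychotherapy (x = 1).
pom_nll <- function(th, n) {
  K <- ncol(n); L <- K - 1L
  z <- th[1:L]; b <- th[K]
  if (L > 1L && is.unsorted(z, strictly = TRUE)) return(Inf)
  v <- 0
  for (a in 1:2) {
    p <- diff(c(0, stats::plogis(z - b * (a - 1)), 1))
    idx <- n[a, ] > 0
    if (any(p[idx] <= 0)) return(Inf)
    v <- v - sum(n[a, idx] * log(p[idx]))
  }
  v
}

#' @keywords internal
pom_score <- function(th, n) {
  K <- ncol(n); L <- K - 1L
  z <- th[1:L]; b <- th[K]
  g <- numeric(K)
  for (a in 1:2) {
    F <- stats::plogis(z - b * (a - 1))
    f <- F * (1 - F)
    p <- diff(c(0, F, 1))
    r <- n[a, ] / p
    d <- f * (r[1:L] - r[2:K])
    g[1:L] <- g[1:L] - d
    g[K] <- g[K] + (a - 1) * sum(d)
  }
  g
}

#' @keywords internal
#' Expected (Fisher) information at th given per-arm totals.
pom_einfo <- function(th, n) {
  K <- ncol(n); L <- K - 1L
  z <- th[1:L]; b <- th[K]
  I <- matrix(0, K, K)
  for (a in 1:2) {
    F <- stats::plogis(z - b * (a - 1))
    f <- F * (1 - F)
    p <- diff(c(0, F, 1))
    D <- matrix(0, K, K)          # D[j, ] = dp_j / d th
    for (j in 1:K) {
      if (j <= L) D[j, j] <- f[j]
      if (j >= 2) D[j, j - 1] <- -f[j - 1]
      fj <- if (j <= L) f[j] else 0
      fj1 <- if (j >= 2) f[j - 1] else 0
      D[j, K] <- -(a - 1) * (fj - fj1)
    }
    I <- I + sum(n[a, ]) * crossprod(D / sqrt(p))
  }
  I
}

#' @keywords internal
#' ML fit of the proportional-odds model by Fisher scoring with step halving;
#' returns beta-hat, its observed-information SE, and the minimised NLL.
fit_pom <- function(counts_psy, counts_adm, tol = 1e-10, maxit = 100L) {
  n <- rbind(counts_adm, counts_psy)
  K <- ncol(n); L <- K - 1L
  cum <- cumsum(colSums(n)); N <- cum[K]
  th <- c(stats::qlogis(cum[1:L] / N), 0)
  v <- pom_nll(th, n)
  for (it in seq_len(maxit)) {
    g <- pom_score(th, n)
    I <- pom_einfo(th, n)
    step <- tryCatch(solve(I, -g), error = function(e) NULL)
    if (is.null(step)) break
    ok <- FALSE
    for (h in 0:30) {
      thn <- th + step / 2^h
      vn <- pom_nll(thn, n)
      if (is.finite(vn) && vn <= v + 1e-12) { ok <- TRUE; break }
    }
    if (!ok) break
    done <- (v - vn) < tol * (abs(v) + 1)
    th <- thn; v <- vn
    if (done && max(abs(pom_score(th, n))) < 1e-6) break
  }
  if (abs(th[K]) > 15)
    variance_error("proportional-odds estimate diverges (separated table)")
  H <- stats::optimHess(th, pom_nll, pom_score, n = n)
  cv <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(cv) || cv[K, K] <= 0)
    variance_error("observed information singular for this table")
  list(beta = th[K], se = sqrt(cv[K, K]), theta = th, nll = v)
}

#' @keywords internal
#' Drop severity levels with zero total count across both arms.
collapse_levels <- function(table) {
  keep <- (table$counts_psy + table$counts_adm) > 0L
  list(counts_psy = table$counts_psy[keep], counts_adm = table$counts_adm[keep])
}

#' Estimate a log proportional odds ratio from a symptom frequency table
#'
#' Fits the cumulative-logit proportional-odds model with a single treatment
#' indicator by maximum likelihood. The proportional odds ratio is the common
#' odds ratio across all cumulative severity dichotomisations of the item
#' ("the average OR over all severity steps"). The returned value is the log
#' pOR oriented so that a positive value favours ADM: it is the log odds of
#' higher endpoint severity in the psychotherapy arm relative to the ADM arm.
#'
#' @param table A [freq_table()].
#' @return A one-row data frame of class \code{effect_estimates} with columns
#'   \code{study_id}, \code{symptom_id}, \code{metric} (\code{"LOG_POR"}),
#'   \code{value}, \code{se}, \code{n_psy}, \code{n_adm}. The standard error
#'   comes from the observed-information matrix.
#'
#' @details Severity levels with zero total count in both arms are collapsed
#'   before fitting (the estimate is invariant to empty levels). Tables left
#'   without variance after collapsing — fewer than two occupied levels, an
#'   empty arm, or a separated configuration — raise a condition of class
#'   \code{sortmeta_variance_error}; meta-analysis callers drop such studies
#'   from the affected symptom's pool.
#'
#'   For a two-level table the model reduces to the ordinary 2x2 log odds
#'   ratio with SE \code{sqrt(1/a + 1/b + 1/c + 1/d)}.
#' @export
estimate_log_por <- function(table) {
  stopifnot(inherits(table, "freq_table"))
  cc <- collapse_levels(table)
  n_psy <- sum(cc$counts_psy); n_adm <- sum(cc$counts_adm)
  if (length(cc$counts_psy) < 2L)
    variance_error(sprintf("%s/%s: no variance after collapsing empty levels",
                           table$study_id, table$symptom_id))
  if (n_psy == 0L || n_adm == 0L)
    variance_error(sprintf("%s/%s: an arm is empty",
                           table$study_id, table$symptom_id))
  fit <- fit_pom(cc$counts_psy, cc$counts_adm)
  effect_estimate(table$study_id, table$symptom_id, "LOG_POR",
                  fit$beta, fit$se, n_psy, n_adm)
}

#' Estimate a median-split log odds ratio from a symptom frequency table
#'
#' Dichotomises the item at the median of the pooled (both-arm) severity
#' distribution — the "high" group is strictly above the pooled median level —
#' and returns the 2x2 log odds ratio of being in the high-severity group for
#' psychotherapy versus ADM (positive favours ADM). If any of the four cells
#' is zero, 0.5 is added to all four cells (Haldane-Anscombe correction) for
#' both the estimate and its SE \code{sqrt(sum of reciprocal cells)}.
#'
#' @param table A [freq_table()].
#' @return A one-row \code{effect_estimates} data frame, metric
#'   \code{"LOG_OR_MEDIAN"}.
#' @export
estimate_log_or_median_split <- function(table) {
  stopifnot(inherits(table, "freq_table"))
  n_psy <- sum(table$counts_psy); n_adm <- sum(table$counts_adm)
  if (n_psy == 0L || n_adm == 0L)
    variance_error(sprintf("%s/%s: an arm is empty",
                           table$study_id, table$symptom_id))
  pooled <- table$counts_psy + table$counts_adm
  cumprop <- cumsum(pooled) / sum(pooled)
  med_level <- which(cumprop >= 0.5)[1]        # 1-based index of median level
  high <- seq_along(pooled) > med_level
  a <- sum(table$counts_psy[high]);  b <- sum(table$counts_psy[!high])
  cc <- sum(table$counts_adm[high]); d <- sum(table$counts_adm[!high])
  if (a + cc == 0 || b + d == 0)
    variance_error(sprintf("%s/%s: median split leaves an empty margin",
                           table$study_id, table$symptom_id))
  if (min(a, b, cc, d) == 0) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
  effect_estimate(table$study_id, table$symptom_id, "LOG_OR_MEDIAN",
                  log((a / b) / (cc / d)), sqrt(1/a + 1/b + 1/cc + 1/d),
                  n_psy, n_adm)
}

#' Standardised mean difference (Hedges' g) from endpoint summary statistics
#'
#' Computes Hedges' g for the endpoint sum-score difference between arms,
#' oriented so that a positive value favours ADM (psychotherapy arm has the
#' higher, i.e. worse, endpoint mean):
#' \deqn{g = J \cdot (\bar x_{psy} - \bar x_{adm}) / s_{pooled}, \quad
#'       J = 1 - 3 / (4(n_1 + n_2 - 2) - 1)}
#' with \eqn{var(g) = J^2 (1/n_1 + 1/n_2 + g_{raw}^2 / (2(n_1+n_2-2)))} where
#' \eqn{g_{raw}} is the corrected g.
#'
#' @param summary A one-row study summary (see [read_study_summaries()]) or any
#'   list with fields \code{study_id}, \code{mean_end_psy}, \code{sd_end_psy},
#'   \code{n_end_psy}, \code{mean_end_adm}, \code{sd_end_adm}, \code{n_end_adm}.
#' @param correct Apply the small-sample correction J (default TRUE); with
#'   \code{FALSE} Cohen's d is returned.
#' @return A one-row \code{effect_estimates} data frame, metric \code{"SMD"},
#'   \code{symptom_id = "SUMSCORE"}.
#' @export
estimate_smd <- function(summary, correct = TRUE) {
  s <- as.list(summary)
  n1 <- s$n_end_psy; n2 <- s$n_end_adm
  if (is.null(n1) || is.null(n2) || n1 < 2 || n2 < 2)
    validation_error("SMD needs at least 2 completers per arm")
  if (anyNA(c(s$mean_end_psy, s$sd_end_psy, s$mean_end_adm, s$sd_end_adm)))
    validation_error("SMD needs endpoint means and SDs for both arms")
  if (s$sd_end_psy <= 0 || s$sd_end_adm <= 0)
    variance_error(paste0(s$study_id, ": zero endpoint SD"))
  df <- n1 + n2 - 2
  s_pooled <- sqrt(((n1 - 1) * s$sd_end_psy^2 + (n2 - 1) * s$sd_end_adm^2) / df)
  if (s_pooled <= 0) variance_error(paste0(s$study_id, ": zero pooled SD"))
  d <- (s$mean_end_psy - s$mean_end_adm) / s_pooled
  J <- if (correct) 1 - 3 / (4 * df - 1) else 1
  g <- J * d
  v <- J^2 * (1 / n1 + 1 / n2 + g^2 / (2 * df))
  effect_estimate(s$study_id, "SUMSCORE", "SMD", g, sqrt(v), n1, n2)
}

#' Convert between the log odds ratio and SMD scales
#'
#' Uses the logistic-scale conversion \code{SMD = ln(OR) / 1.81}. The two
#' functions are exact inverses.
#'
#' @param log_or,smd Numeric vector(s).
#' @return Numeric vector on the other scale.
#' @export
convert_logor_to_smd <- function(log_or) {
  stopifnot(all(is.finite(log_or)))
  log_or / 1.81
}

#' @rdname convert_logor_to_smd
#' @export
convert_smd_to_logor <- function(smd) {
  stopifnot(all(is.finite(smd)))
  smd * 1.81
}

#' @keywords internal
effect_estimate <- function(study_id, symptom_id, metric, value, se,
                            n_psy, n_adm) {
  out <- data.frame(study_id = study_id, symptom_id = symptom_id,
                    metric = metric, value = value, se = se,
                    n_psy = n_psy, n_adm = n_adm, stringsAsFactors = FALSE)
  class(out) <- c("effect_estimates", "data.frame")
  out
}

#' Estimate per-study, per-symptom effects for a set of frequency tables
#'
#' Applies [estimate_log_por()] or [estimate_log_or_median_split()] to each
#' table. Tables raising a variance error (no variance in that symptom for
#' that study) are dropped with a message, mirroring the meta-analytic
#' practice of removing such studies from that symptom's pool; the dropped
#' \code{study_id/symptom_id} pairs are recorded in the \code{"dropped"}
#' attribute of the result.
#'
#' @param tables List of [freq_table()] objects.
#' @param metric \code{"por"} (default) or \code{"or_median"}.
#' @return An \code{effect_estimates} data frame, one row per retained table.
#' @export
estimate_effects <- function(tables, metric = c("por", "or_median")) {
  metric <- match.arg(metric)
  fun <- switch(metric, por = estimate_log_por,
                or_median = estimate_log_or_median_split)
  rows <- list(); dropped <- character()
  for (tb in tables) {
    est <- tryCatch(fun(tb), sortmeta_variance_error = function(e) {
      message("dropping ", tb$study_id, "/", tb$symptom_id, ": ",
              conditionMessage(e))
      NULL
    })
    if (is.null(est)) {
      dropped <- c(dropped, paste0(tb$study_id, "/", tb$symptom_id))
    } else rows[[length(rows) + 1L]] <- est
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    effect_estimate(character(), character(), character(),
                    numeric(), numeric(), integer(), integer())
  rownames(out) <- NULL
  class(out) <- c("effect_estimates", "data.frame")
  attr(out, "dropped") <- dropped
  out
}
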