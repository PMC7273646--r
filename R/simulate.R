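#' Default cumulative-logit cutpoints for a simulated item
#'
#' Cutpoints are chosen so that the control-arm marginal distribution of an
#' item with levels \code{0..max_level} is right-skewed (most mass at low
#' severities), the typical shape of endpoint symptom distributions after
#' active treatment: level probabilities proportional to
#' \code{decay^level}.
#'
#' @param max_level Item maximum severity level (>= 1).
#' @param decay Geometric decay of level mass (default 0.55).
#' @return Numeric vector of \code{max_level} strictly increasing cutpoints
#'   \eqn{\theta_c} with \eqn{P(Y \le c) = logistic(\theta_c)} in the
#'   reference (ADM) arm.
#' @export
default_item_thresholds <- function(max_level, decay = 0.55) {
  stopifnot(max_level >= 1, decay > 0)
  p <- decay^(0:max_level)
  p <- p / sum(p)
  stats::qlogis(cumsum(p)[1:max_level])
}

#' Configuration for simulating a collection of two-arm trials
#'
#' Defines the ground truth for a multi-study RCT simulation: per-symptom
#' true log proportional odds ratios, between-study heterogeneity, arm sizes
#' and per-arm dropout. Defaults emulate the synthesis setting the package
#' targets: around 20 trials with 60-200 randomised patients per arm and
#' per-arm dropout of 21.2\% (psychotherapy) and 26.1\% (ADM), the aggregate
#' completer rates observed across comparable published trials.
#'
#' @param n_studies Number of trials.
#' @param n_per_arm Either a single arm size or a length-2 range sampled
#'   uniformly per study.
#' @param scale A [symptom_scale()].
#' @param beta True log pOR per symptom (positive favours ADM); scalar
#'   recycled or named vector over \code{scale} item ids.
#' @param tau Between-study SD of the study-level effect shift (>= 0).
#' @param thresholds Optional list of cutpoint vectors named by item id;
#'   defaults to [default_item_thresholds()] per item.
#' @param dropout_psy,dropout_adm Per-arm dropout probabilities in \[0, 1).
#' @param level_shift Optional per-symptom departure from proportional odds:
#'   a scalar delta added to the treatment shift above the median cutpoint
#'   (0 = proportional odds holds, the base scenario).
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_studies = 20L, n_per_arm = c(60L, 200L),
                       scale = hamd17_scale(), beta = 0, tau = 0.1,
                       thresholds = NULL, dropout_psy = 0.212,
                       dropout_adm = 0.261, level_shift = 0) {
  stopifnot(n_studies >= 1, tau >= 0,
            dropout_psy >= 0, dropout_psy < 1,
            dropout_adm >= 0, dropout_adm < 1,
            inherits(scale, "symptom_scale"))
  ids <- scale_item_ids(scale)
  if (length(beta) == 1L) beta <- stats::setNames(rep(beta, length(ids)), ids)
  if (!all(ids %in% names(beta)))
    validation_error("beta must cover every scale item")
  if (is.null(thresholds)) {
    thresholds <- lapply(stats::setNames(ids, ids), function(id)
      default_item_thresholds(scale_max_level(scale, id)))
  }
  for (id in ids) {
    th <- thresholds[[id]]
    if (is.null(th) || is.unsorted(th, strictly = TRUE))
      validation_error(paste("thresholds must be strictly increasing for", id))
  }
  if (length(n_per_arm) == 1L) n_per_arm <- rep(n_per_arm, 2L)
  structure(list(n_studies = as.integer(n_studies),
                 n_per_arm = as.integer(n_per_arm), scale = scale,
                 beta = beta[ids], tau = tau, thresholds = thresholds,
                 dropout_psy = dropout_psy, dropout_adm = dropout_adm,
                 level_shift = level_shift),
            class = "sim_config")
}

#' @keywords internal
#' Draw an n x n_items matrix of ordinal item scores for one arm.
draw_item_scores <- function(n, config, shift) {
  ids <- scale_item_ids(config$scale)
  scores <- matrix(0L, n, length(ids), dimnames = list(NULL, ids))
  for (j in seq_along(ids)) {
    th <- config$thresholds[[ids[j]]]
    sh <- rep(shift[j], length(th))
    if (config$level_shift != 0) {
      upper <- seq_along(th) > length(th) / 2
      sh[upper] <- sh[upper] + config$level_shift
    }
    cum <- stats::plogis(th - sh)       # P(Y <= c), non-decreasing in c
    cum <- cummax(pmin(pmax(cum, 0), 1))
    scores[, j] <- findInterval(stats::runif(n), cum)
  }
  scores
}

#' Simulate a collection of two-arm trials with ordinal symptom outcomes
#'
#' For each study j and symptom i, endpoint severities are drawn per patient
#' from the cumulative-logit model
#' \deqn{P(Y \le c \mid arm) = logistic(\theta_{i,c} - (\beta_i + u_j)
#'   \cdot 1[arm = PSY]), \quad u_j \sim N(0, \tau^2)}
#' so that positive \eqn{\beta_i} shifts the psychotherapy arm toward higher
#' severity (favouring ADM). Completers are retained after independent
#' per-arm Bernoulli dropout; frequency tables and sum-score summaries are
#' computed from the same simulated completers.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the output is fully reproducible from it.
#' @return A list with \code{tables} (list of [freq_table()], one per study x
#'   symptom, completers only) and \code{summaries} (study-summary data frame
#'   with baseline/endpoint arm sizes and endpoint sum-score means/SDs).
#' @export
generate_study_collection <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  ids <- scale_item_ids(config$scale)
  tables <- vector("list", config$n_studies * length(ids))
  summaries <- vector("list", config$n_studies)
  ti <- 0L
  for (j in seq_len(config$n_studies)) {
    study_id <- sprintf("S%02d", j)
    rng <- config$n_per_arm
    draw_n <- function() if (rng[1] == rng[2]) rng[1] else
      sample(seq.int(rng[1], rng[2]), 1L)
    n_psy <- draw_n(); n_adm <- draw_n()
    u <- stats::rnorm(1L, 0, config$tau)
    sc_psy <- draw_item_scores(n_psy, config, config$beta + u)
    sc_adm <- draw_item_scores(n_adm, config, rep(0, length(ids)))
    keep_psy <- stats::runif(n_psy) >= config$dropout_psy
    keep_adm <- stats::runif(n_adm) >= config$dropout_adm
    cp <- sc_psy[keep_psy, , drop = FALSE]
    ca <- sc_adm[keep_adm, , drop = FALSE]
    for (i in seq_along(ids)) {
      L <- scale_max_level(config$scale, ids[i])
      ti <- ti + 1L
      tables[[ti]] <- freq_table(
        study_id, ids[i],
        tabulate(cp[, i] + 1L, nbins = L + 1L),
        tabulate(ca[, i] + 1L, nbins = L + 1L))
    }
    sum_psy <- rowSums(cp); sum_adm <- rowSums(ca)
    summaries[[j]] <- data.frame(
      study_id = study_id, scale_id = config$scale$scale_id,
      n_base_psy = n_psy, n_base_adm = n_adm,
      n_end_psy = nrow(cp), n_end_adm = nrow(ca),
      mean_end_psy = if (nrow(cp)) mean(sum_psy) else NA_real_,
      sd_end_psy = if (nrow(cp) > 1) stats::sd(sum_psy) else NA_real_,
      mean_end_adm = if (nrow(ca)) mean(sum_adm) else NA_real_,
      sd_end_adm = if (nrow(ca) > 1) stats::sd(sum_adm) else NA_real_,
      stringsAsFactors = FALSE)
  }
  list(tables = tables, summaries = do.call(rbind, summaries))
}

#' Configuration for simulating a patient cohort
#'
#' Defines a cohort with item-level baseline severities (thresholded
#' exchangeable-correlation latent Gaussian), random treatment assignment and
#' an endpoint sum-score containing an optional symptom-profile x treatment
#' interaction: patients whose assigned arm matches the sign of their
#' weighted symptom profile improve by \code{interaction_delta} sum-score
#' points more. Defaults emulate a mid-sized validation cohort (n = 400,
#' moderate inter-item correlation, endpoint about half of baseline with
#' residual SD 6 sum-score points).
#'
#' @param n_patients Cohort size.
#' @param scale A [symptom_scale()].
#' @param item_severity_means Target marginal mean severity per item; scalar
#'   fraction of \code{max_level} (default 0.35) or named vector of absolute
#'   means over item ids.
#' @param item_correlation Exchangeable latent correlation in \[0, 1).
#' @param response_mean Multiplier mapping baseline sum to expected endpoint
#'   sum (default 0.5).
#' @param response_sd Residual SD of the endpoint sum-score (> 0).
#' @param interaction_delta Endpoint benefit (sum-score points) of receiving
#'   the profile-concordant arm; 0 = no allocation signal.
#' @return A list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_patients = 400L, scale = hamd17_scale(),
                          item_severity_means = 0.35, item_correlation = 0.3,
                          response_mean = 0.5, response_sd = 6,
                          interaction_delta = 0) {
  stopifnot(n_patients > 0, response_sd > 0,
            item_correlation >= 0, item_correlation < 1,
            inherits(scale, "symptom_scale"))
  ids <- scale_item_ids(scale)
  if (length(item_severity_means) == 1L)
    item_severity_means <- stats::setNames(
      item_severity_means * scale$items$max_level, ids)
  if (!all(ids %in% names(item_severity_means)))
    validation_error("item_severity_means must cover every scale item")
  structure(list(n_patients = as.integer(n_patients), scale = scale,
                 item_severity_means = item_severity_means[ids],
                 item_correlation = item_correlation,
                 response_mean = response_mean, response_sd = response_sd,
                 interaction_delta = interaction_delta),
            class = "cohort_config")
}

#' Simulate a patient cohort with baseline profiles and endpoint outcomes
#'
#' Baseline item scores arise from a latent standard Gaussian with
#' exchangeable correlation, thresholded so each item's marginal distribution
#' is Binomial(\code{max_level}, \code{mean/max_level}) with exactly the
#' configured marginal mean. Treatment is Bernoulli(0.5); the endpoint
#' sum-score is
#' \deqn{max(0,\; baseline\_sum \cdot response\_mean + \epsilon -
#'   \delta \cdot 1[arm\ concordant]),\quad \epsilon \sim N(0, response\_sd^2)}
#' where concordance means ADM with a positive weighted profile score
#' \eqn{\sum_i m_i s_i} or psychotherapy with a negative one (a zero score is
#' concordant with neither).
#'
#' @param config A [cohort_config()].
#' @param weights Named numeric vector of per-symptom weights m covering
#'   every scale item (used only for the concordance benefit; pass the truth
#'   or an estimated weight set).
#' @param seed Integer seed.
#' @return A patient-profile data frame: \code{patient_id}, \code{scale_id},
#'   \code{treatment} (\code{"PSY"}/\code{"ADM"}), \code{endpoint_sum}, one
#'   column per item.
#' @export
generate_patient_cohort <- function(config, weights, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  ids <- scale_item_ids(config$scale)
  if (!all(ids %in% names(weights)))
    validation_error("weights must cover every scale item")
  w <- weights[ids]
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_patients
  rho <- config$item_correlation
  g <- stats::rnorm(n)
  scores <- matrix(0L, n, length(ids), dimnames = list(NULL, ids))
  for (j in seq_along(ids)) {
    M <- scale_max_level(config$scale, ids[j])
    mu <- config$item_severity_means[ids[j]]
    if (mu < 0 || mu > M)
      validation_error(paste("item mean out of range for", ids[j]))
    pr <- stats::dbinom(0:M, M, mu / M)
    z <- sqrt(rho) * g + sqrt(1 - rho) * stats::rnorm(n)
    scores[, j] <- findInterval(stats::pnorm(z),
                                cummax(pmin(cumsum(pr), 1)))
  }
  base_sum <- rowSums(scores)
  treatment <- ifelse(stats::rbinom(n, 1L, 0.5) == 1L, "ADM", "PSY")
  profile_score <- as.vector(scores %*% w)
  concordant <- (profile_score > 0 & treatment == "ADM") |
    (profile_score < 0 & treatment == "PSY")
  endpoint <- pmax(0, base_sum * config$response_mean +
                     stats::rnorm(n, 0, config$response_sd) -
                     config$interaction_delta * concordant)
  out <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                    scale_id = config$scale$scale_id, treatment = treatment,
                    endpoint_sum = endpoint, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(scores))
  out
}
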