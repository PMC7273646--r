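#' Confidence-interval coverage study for the pooled symptom effect
#'
#' Monte-Carlo check of the full estimation chain: simulate collections of
#' two-arm trials with a known per-symptom log pOR, estimate each study's
#' effect by maximum likelihood, pool with random effects, and record how
#' often the 95\% CI covers the generating value.
#'
#' @param n_reps Number of simulated meta-analyses.
#' @param beta True log pOR.
#' @param tau Between-study SD.
#' @param n_studies,n_per_arm Collection dimensions (arm size at baseline;
#'   per-arm dropout at the generator defaults applies).
#' @param max_level Severity levels of the single simulated item.
#' @param method tau^2 estimator.
#' @param seed Integer seed.
#' @return A list: \code{coverage} (fraction in \[0, 1\]), \code{mean_pooled},
#'   \code{n_reps}, \code{n_studies}, \code{n_per_arm}.
#' @export
ci_coverage_study <- function(n_reps = 1000, beta = 0.3, tau = 0.1,
                              n_studies = 20, n_per_arm = 60, max_level = 3,
                              method = "REML", seed = 1) {
  set.seed(seed)
  scale <- one_item_scale(max_level)
  covered <- logical(n_reps)
  pooled <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    sim <- generate_study_collection(
      sim_config(n_studies = n_studies, n_per_arm = n_per_arm, scale = scale,
                 beta = beta, tau = tau))
    eff <- suppressMessages(estimate_effects(sim$tables))
    pe <- pool_random_effects(eff, method = method)
    covered[r] <- pe$ci_low <= beta && beta <= pe$ci_high
    pooled[r] <- pe$pooled
  }
  list(coverage = mean(covered), mean_pooled = mean(pooled),
       n_reps = n_reps, n_studies = n_studies, n_per_arm = n_per_arm)
}

#' Type-I error and FDR calibration study under the global null
#'
#' Simulates meta-analyses with all true symptom effects zero and records
#' the rate of raw pooled p-values below the nominal level and the empirical
#' false discovery rate of Benjamini-Hochberg-adjusted discoveries (under a
#' global null every discovery is false, so the per-replicate FDR is 1 when
#' anything is rejected and 0 otherwise).
#'
#' @param n_reps Number of simulated meta-analyses.
#' @param n_symptoms Symptoms per collection (the BH family size).
#' @param tau Between-study SD.
#' @param n_studies,n_per_arm Collection dimensions.
#' @param max_level Severity levels per item.
#' @param alpha Nominal level.
#' @param method tau^2 estimator.
#' @param seed Integer seed.
#' @return A list: \code{raw_rate} (fraction of raw p < alpha over all
#'   replicate x symptom tests), \code{fdr} (mean per-replicate false
#'   discovery proportion after BH), \code{n_tests}, \code{n_reps}.
#' @export
null_calibration_study <- function(n_reps = 2000, n_symptoms = 3, tau = 0.1,
                                   n_studies = 20, n_per_arm = 60,
                                   max_level = 3, alpha = 0.05,
                                   method = "REML", seed = 1) {
  set.seed(seed)
  scale <- symptom_scale("CUSTOM", data.frame(
    item_id = sprintf("it_%d", seq_len(n_symptoms)),
    label = sprintf("item %d", seq_len(n_symptoms)),
    max_level = max_level))
  raw_hits <- 0L; n_tests <- 0L
  fdp <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    sim <- generate_study_collection(
      sim_config(n_studies = n_studies, n_per_arm = n_per_arm, scale = scale,
                 beta = 0, tau = tau))
    eff <- suppressMessages(estimate_effects(sim$tables))
    pooled <- pool_symptom_effects(eff, method = method)
    raw_hits <- raw_hits + sum(pooled$p < alpha)
    n_tests <- n_tests + nrow(pooled)
    fdp[r] <- as.numeric(any(pooled$p_adj < alpha))   # all nulls: V/R is 0/1
  }
  list(raw_rate = raw_hits / n_tests, fdr = mean(fdp),
       n_tests = n_tests, n_reps = n_reps)
}

#' @keywords internal
one_item_scale <- function(max_level) {
  symptom_scale("CUSTOM", data.frame(item_id = "it_1", label = "item 1",
                                     max_level = max_level))
}

#' Type-I error / power study for SOrT-guided allocation
#'
#' Simulates patient cohorts with a known concordance benefit delta, scores
#' them with the generating weights (the well-estimated-weights regime),
#' applies a split and the optimal/non-optimal endpoint comparison, and
#' records the rejection rate of the two-sided t-test and the average group
#' mean difference. With \code{delta = 0} the rejection rate estimates the
#' type-I error; with \code{delta > 0} it estimates power, and
#' \code{mean_diff} (optimal minus non-optimal endpoint) should be negative
#' (lower endpoint severity under concordant allocation).
#'
#' @param n_reps Number of simulated cohorts.
#' @param delta Concordance benefit in endpoint sum-score points.
#' @param n_patients Cohort size.
#' @param response_sd Residual endpoint SD.
#' @param split \code{"valence"} or \code{"median"}.
#' @param scale A [symptom_scale()].
#' @param weights Named weight vector (default: alternating-sign weights of
#'   magnitude 0.12 over the scale items, giving a sign-balanced score
#'   distribution so the valence split is feasible).
#' @param alpha Nominal level.
#' @param seed Integer seed.
#' @return A list: \code{reject_rate}, \code{mean_diff}, \code{n_reps},
#'   \code{n_patients}.
#' @export
allocation_calibration_study <- function(n_reps = 1000, delta = 0,
                                         n_patients = 400, response_sd = 6,
                                         split = c("valence", "median"),
                                         scale = hamd17_scale(),
                                         weights = NULL, alpha = 0.05,
                                         seed = 1) {
  split <- match.arg(split)
  set.seed(seed)
  ids <- scale_item_ids(scale)
  if (is.null(weights))
    weights <- stats::setNames(0.12 * (-1)^(seq_along(ids)), ids)
  cfg <- cohort_config(n_patients = n_patients, scale = scale,
                       response_sd = response_sd, interaction_delta = delta)
  rej <- logical(n_reps); diffs <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    coh <- generate_patient_cohort(cfg, weights)
    scores <- compute_sort(coh, weights, scale)
    sp <- suppressMessages(
      if (split == "valence") split_valence(scores) else split_median(scores))
    cg <- compare_groups(sp, toupper(split))
    rej[r] <- cg$p < alpha
    diffs[r] <- cg$mean_opt - cg$mean_nonopt
  }
  list(reject_rate = mean(rej), mean_diff = mean(diffs), n_reps = n_reps,
       n_patients = n_patients)
}
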