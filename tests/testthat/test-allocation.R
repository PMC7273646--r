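score_df <- function(value, treatment = NULL, endpoint = NULL) {
  d <- data.frame(patient_id = sprintf("P%02d", seq_along(value)),
                  scale_id = "CUSTOM", value = value,
                  value_adjusted = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(treatment)) d$treatment <- treatment
  if (!is.null(endpoint)) d$endpoint_sum <- endpoint
  class(d) <- c("sort_scores", "data.frame")
  d
}

test_that("leave-one-study-out weights drop the excluded study", {
  set.seed(3)
  sim <- generate_study_collection(
    sim_config(n_studies = 2, scale = toy_scale(1), beta = 0.3), seed = 3)
  eff <- quiet_effects(sim$tables)
  w <- loso_weights(eff, "S01")
  expect_equal(w$k, 1)
  expect_equal(w$pooled, eff$value[eff$study_id == "S02"])
  expect_equal(w$pooled_smd, eff$value[eff$study_id == "S02"] / 1.81)
  # excluding an absent study is a warning and a no-op
  expect_warning(w_all <- loso_weights(eff, "NOPE"), "not present")
  full <- pool_symptom_effects(eff)
  expect_equal(w_all$pooled, full$pooled)
})

test_that("LOSO and full weights both recover the simulated truth", {
  cfg <- sim_config(n_studies = 20, n_per_arm = c(100, 200),
                    scale = toy_scale(1), beta = 0.3, tau = 0.05)
  sim <- generate_study_collection(cfg, seed = 17)
  eff <- quiet_effects(sim$tables)
  full <- pool_symptom_effects(eff)
  loso <- loso_weights(eff, "S01")
  expect_false(isTRUE(all.equal(full$pooled, loso$pooled)))
  expect_true(full$ci_low < 0.3 && full$ci_high > 0.3)
  expect_true(loso$ci_low < 0.3 && loso$ci_high > 0.3)
})

test_that("valence split follows the sign/arm concordance rule", {
  s <- split_valence(score_df(c(0.5, -0.5, 0), c("ADM", "ADM", "PSY")))
  expect_equal(s$optimal, c(TRUE, FALSE, NA))
  expect_equal(attr(s, "n_excluded"), 1)
  neg <- split_valence(score_df(c(-0.5), c("PSY")))
  expect_true(neg$optimal)
})

test_that("median split excludes ties at the median", {
  s <- suppressMessages(
    split_median(score_df(c(1, 2, 3), c("PSY", "ADM", "ADM"))))
  expect_equal(s$optimal, c(TRUE, NA, TRUE))
  all_tied <- suppressMessages(
    split_median(score_df(rep(1, 4), rep("ADM", 4), rep(5, 4))))
  expect_true(all(is.na(all_tied$optimal)))
  expect_error(compare_groups(all_tied, "MEDIAN"),
               class = "sortmeta_validation_error")
})

test_that("median split is balanced for symmetric scores and random arms", {
  set.seed(61)
  v <- rnorm(5000)
  s <- split_median(score_df(v, sample(c("PSY", "ADM"), 5000, TRUE)))
  expect_lt(abs(mean(s$optimal, na.rm = TRUE) - 0.5), 0.02)
})

test_that("extreme selection keeps the farthest scores from the reference", {
  sc <- score_df(c(-3, -1, 0, 1, 3))
  kept <- select_extreme(sc, fraction = 2 / 5, reference = "ZERO")
  expect_equal(kept$value, c(-3, 3))
  expect_equal(nrow(select_extreme(sc, fraction = 1)), 5)
  set.seed(71)
  u <- runif(3000, -1, 1)
  kept2 <- select_extreme(score_df(u), fraction = 2 / 3, reference = "ZERO")
  expect_lt(abs(min(abs(kept2$value)) - 1 / 3), 0.02)
  expect_error(select_extreme(sc, fraction = 0),
               class = "sortmeta_validation_error")
})

test_that("group comparison matches the Welch closed form", {
  eq <- compare_groups(score_df(c(1, -1, 1, -1), rep("ADM", 4),
                                c(5, 5, 7, 7)) |> split_valence(), "VALENCE")
  expect_equal(eq$t, 0); expect_equal(eq$p, 1)
  d <- score_df(c(1, 1, 1, -1, -1, -1), rep("ADM", 6), c(1, 2, 3, 2, 3, 4))
  cg <- compare_groups(split_valence(d), "VALENCE")
  expect_equal(cg$t, -1.224745, tolerance = 1e-6)
  expect_equal(cg$df, 4, tolerance = 1e-10)
  expect_equal(cg$mean_opt, 2); expect_equal(cg$mean_nonopt, 3)
  # pooled-variance flag reproduces the classical test
  cg_p <- compare_groups(split_valence(d), "VALENCE", pooled = TRUE)
  expect_equal(cg_p$df, 4)
  expect_equal(cg_p$t, cg$t, tolerance = 1e-6)
})

test_that("allocation regression equals the group mean difference", {
  set.seed(5)
  d <- score_df(rnorm(60), sample(c("PSY", "ADM"), 60, TRUE), rnorm(60, 10))
  s <- split_valence(d)
  cg <- compare_groups(s, "VALENCE")
  ar <- allocation_regression(s)
  expect_equal(unname(ar$unadjusted["beta"]), cg$mean_opt - cg$mean_nonopt,
               tolerance = 1e-10)
  const <- s; const$optimal <- TRUE
  expect_error(allocation_regression(const),
               class = "sortmeta_validation_error")
})

test_that("negating the weights swaps the labels and keeps |t|", {
  set.seed(9)
  sc <- toy_scale(4, 3)
  w <- setNames(c(0.2, -0.15, 0.1, -0.05), sprintf("it_%d", 1:4))
  coh <- generate_patient_cohort(
    cohort_config(n_patients = 300, scale = sc, interaction_delta = 2),
    w, seed = 9)
  s1 <- split_valence(compute_sort(coh, w, sc))
  s2 <- split_valence(compute_sort(coh, -w, sc))
  expect_equal(s2$optimal, !s1$optimal)
  t1 <- compare_groups(s1, "VALENCE"); t2 <- compare_groups(s2, "VALENCE")
  expect_equal(abs(t1$t), abs(t2$t), tolerance = 1e-10)
})

test_that("full-fraction extreme selection is a no-op for the comparison", {
  set.seed(15)
  d <- score_df(rnorm(100), sample(c("PSY", "ADM"), 100, TRUE), rnorm(100, 8))
  full <- compare_groups(split_valence(d), "VALENCE")
  ext <- compare_groups(split_valence(select_extreme(d, 1, "ZERO")),
                        "VALENCE")
  expect_equal(ext, full)
})

test_that("the allocation report flags one-signed valence splits infeasible", {
  set.seed(25)
  d <- score_df(abs(rnorm(80)) + 0.01, sample(c("PSY", "ADM"), 80, TRUE),
                rnorm(80, 8))
  rep <- suppressMessages(run_allocation_pipeline(d))
  expect_false(rep$feasible[rep$split_method == "VALENCE"])
  expect_false(rep$feasible[rep$split_method == "EXTREME_VALENCE"])
  expect_true(rep$feasible[rep$split_method == "MEDIAN"])
  expect_equal(rep$frac_positive[1], 1)
  expect_match(rep$note[rep$split_method == "VALENCE"], "one sign")
})

test_that("a concordance benefit lowers the optimal group's endpoint", {
  sc <- toy_scale(6, 3)
  w <- setNames(c(0.2, -0.2, 0.15, -0.15, 0.1, -0.1), sprintf("it_%d", 1:6))
  coh <- generate_patient_cohort(
    cohort_config(n_patients = 400, scale = sc, interaction_delta = 3),
    w, seed = 33)
  scores <- compute_sort(coh, w, sc)
  rep <- suppressMessages(run_allocation_pipeline(scores))
  val <- rep[rep$split_method == "VALENCE", ]
  expect_true(val$feasible)
  expect_lt(val$mean_opt, val$mean_nonopt)
  # identical inputs give an identical report
  rep2 <- suppressMessages(run_allocation_pipeline(scores))
  expect_identical(rep, rep2)
})
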