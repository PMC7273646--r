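make_estimates <- function(y, se, symptom = "it_1") {
  out <- data.frame(study_id = sprintf("S%02d", seq_along(y)),
                    symptom_id = symptom, metric = "LOG_POR", value = y,
                    se = se, n_psy = 50L, n_adm = 50L,
                    stringsAsFactors = FALSE)
  class(out) <- c("effect_estimates", "data.frame")
  out
}

test_that("a single study pools to itself", {
  pe <- pool_random_effects(make_estimates(0.4, 0.2))
  expect_equal(pe$pooled, 0.4)
  expect_equal(pe$se, 0.2)
  expect_equal(pe$tau2, 0)
  expect_equal(pe$Q, 0)
  expect_equal(pe$df, 0L)
  expect_equal(pe$i2, 0)
  expect_equal(pe$pooled_smd, 0.4 / 1.81)
})

test_that("DerSimonian-Laird reproduces the closed-form hand example", {
  pe <- pool_random_effects(make_estimates(c(0.1, 0.3, 0.5), rep(0.1, 3)),
                            method = "DL")
  expect_equal(pe$Q, 8, tolerance = 1e-10)
  expect_equal(pe$df, 2L)
  expect_equal(pe$i2, 75, tolerance = 1e-10)
  expect_equal(pe$tau2, 0.03, tolerance = 1e-10)
  expect_equal(pe$pooled, 0.3, tolerance = 1e-10)
  expect_equal(pe$se, sqrt(1 / 75), tolerance = 1e-10)
})

test_that("homogeneous estimates give tau2 zero and the common value", {
  est <- make_estimates(rep(0.25, 4), rep(0.15, 4))
  for (m in c("REML", "DL")) {
    pe <- pool_random_effects(est, method = m)
    expect_equal(pe$pooled, 0.25, tolerance = 1e-8)
    expect_equal(pe$tau2, 0, tolerance = 1e-10)
  }
})

test_that("zero estimated tau2 reduces to the fixed-effect mean", {
  est <- make_estimates(c(0.2, 0.21, 0.19, 0.2), c(0.3, 0.2, 0.25, 0.4))
  pe <- pool_random_effects(est, method = "DL")
  expect_equal(pe$tau2, 0)
  w <- 1 / est$se^2
  expect_equal(pe$pooled, sum(w * est$value) / sum(w), tolerance = 1e-10)
  expect_equal(pe$se, 1 / sqrt(sum(w)), tolerance = 1e-10)
})

test_that("pooling validates its inputs", {
  expect_error(pool_random_effects(make_estimates(0.1, 0.1)[0, ]),
               class = "sortmeta_validation_error")
  mixed <- make_estimates(c(0.1, 0.2), c(0.1, 0.1))
  mixed$metric <- c("LOG_POR", "SMD")
  expect_error(pool_random_effects(mixed),
               class = "sortmeta_validation_error")
})

test_that("pooled summaries satisfy the heterogeneity invariants", {
  set.seed(19)
  for (i in 1:20) {
    k <- sample(2:12, 1)
    est <- make_estimates(rnorm(k, 0, 0.4), runif(k, 0.05, 0.4))
    pe <- pool_random_effects(est, method = sample(c("REML", "DL"), 1))
    expect_gte(pe$i2, 0); expect_lte(pe$i2, 100)
    expect_gte(pe$tau2, 0)
    expect_lte(pe$ci_low, pe$pooled); expect_gte(pe$ci_high, pe$pooled)
    expect_equal(pe$df, k - 1L)
  }
})

test_that("heterogeneity df is k minus one", {
  expect_equal(heterogeneity_df(27), 26L)
  expect_equal(heterogeneity_df(19), 18L)
  expect_equal(heterogeneity_df(1), 0L)
  expect_error(heterogeneity_df(0), class = "sortmeta_validation_error")
})

test_that("Egger's test is exactly null on symmetric constructions", {
  # paired +/- offsets around a common mean with equal within-pair SEs
  se <- rep(c(0.1, 0.2, 0.4), each = 2)
  y <- 0.3 + c(0.05, -0.05, 0.12, -0.12, 0.2, -0.2)
  eg <- eggers_test(make_estimates(y, se))
  expect_lt(abs(eg$intercept), 1e-10)
  expect_equal(eg$p, 1, tolerance = 1e-10)
  expect_equal(nrow(eg$funnel), 6)
})

test_that("Egger's test matches an independent OLS oracle", {
  set.seed(7)
  y <- rnorm(10, 0.2, 0.3)
  se <- runif(10, 0.08, 0.5)
  eg <- eggers_test(make_estimates(y, se))
  # normal equations on the transformed variables
  X <- cbind(1, 1 / se)
  z <- y / se
  bhat <- solve(t(X) %*% X, t(X) %*% z)
  res <- z - X %*% bhat
  s2 <- sum(res^2) / (10 - 2)
  se_int <- sqrt(s2 * solve(t(X) %*% X)[1, 1])
  expect_equal(eg$intercept, bhat[1], tolerance = 1e-8)
  expect_equal(eg$z, bhat[1] / se_int, tolerance = 1e-8)
})

test_that("Egger's test rejects degenerate designs", {
  expect_error(eggers_test(make_estimates(c(0.1, 0.2), c(0.1, 0.2))),
               class = "sortmeta_validation_error")
  expect_error(eggers_test(make_estimates(c(0.1, 0.2, 0.3), rep(0.1, 3))),
               class = "sortmeta_validation_error")
})

test_that("Egger's test holds its nominal level on unbiased simulations", {
  set.seed(29)
  rej <- replicate(1000, {
    se <- runif(20, 0.1, 0.5)
    y <- rnorm(20, 0.2, se)         # no small-study effect
    eggers_test(make_estimates(y, se))$p < 0.05
  })
  expect_gte(mean(rej), 0.03); expect_lte(mean(rej), 0.07)
})

test_that("meta-regression recovers an exact linear moderator effect", {
  x <- c(-10, -5, 0, 5, 10, 15)
  est <- make_estimates(0.01 * x, rep(1e-4, 6))
  mr <- meta_regression(est, x)
  expect_equal(mr$slope, 0.01, tolerance = 1e-3)
  expect_lt(mr$p, 1e-6)
})

test_that("meta-regression rejects invalid designs", {
  expect_error(meta_regression(make_estimates(c(0.1, 0.2), c(0.1, 0.1)),
                               c(1, 2)),
               class = "sortmeta_validation_error")
  expect_error(meta_regression(make_estimates(c(0.1, 0.2, 0.3), rep(0.1, 3)),
                               c(2, 2, 2)),
               class = "sortmeta_validation_error")
})

test_that("meta-regression slope test is calibrated under the null", {
  set.seed(37)
  rej <- replicate(1000, {
    k <- 15
    se <- runif(k, 0.1, 0.3)
    y <- rnorm(k, 0, sqrt(se^2 + 0.01))
    x <- rnorm(k)                   # moderator unrelated to effects
    meta_regression(make_estimates(y, se), x)$p < 0.05
  })
  expect_gt(mean(rej), 0.03); expect_lt(mean(rej), 0.07)
})

test_that("dropout pooling reproduces aggregate rates and the null", {
  one <- data.frame(study_id = "S01", n_base_psy = 50, n_end_psy = 40,
                    n_base_adm = 50, n_end_adm = 40)
  pd <- pool_dropout(one)
  expect_equal(pd$pooled$pooled, 0)
  # aggregate-rate arithmetic on arbitrary totals, percent to one decimal
  agg <- data.frame(study_id = c("A", "B"),
                    n_base_psy = c(1000, 1163), n_end_psy = c(780, 925),
                    n_base_adm = c(1000, 1133), n_end_adm = c(730, 846))
  pd2 <- pool_dropout(agg)
  expect_equal(pd2$rate_psy_pct, round(100 * 458 / 2163, 1))
  expect_equal(pd2$rate_adm_pct, round(100 * 557 / 2133, 1))
  bad <- one; bad$n_end_psy <- 60
  expect_error(pool_dropout(bad), class = "sortmeta_validation_error")
})

test_that("dropout log OR is oriented so OR < 1 favours psychotherapy", {
  s <- data.frame(study_id = c("A", "B"),
                  n_base_psy = c(100, 100), n_end_psy = c(90, 85),
                  n_base_adm = c(100, 100), n_end_adm = c(70, 75))
  pd <- pool_dropout(s)          # fewer psychotherapy dropouts
  expect_lt(pd$pooled$pooled, 0)
})

test_that("Benjamini-Hochberg adjustment is the step-up rule", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.5, 1.2)), class = "sortmeta_validation_error")
  # monotone in the input ranks
  set.seed(2)
  p <- runif(20)
  adj <- adjust_bh(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("symptom-wise pooling splits, pools and adjusts per symptom", {
  set.seed(9)
  sim <- generate_study_collection(
    sim_config(n_studies = 6, scale = toy_scale(3), beta = 0.2), seed = 9)
  eff <- quiet_effects(sim$tables)
  pooled <- pool_symptom_effects(eff)
  expect_equal(nrow(pooled), 3)
  expect_equal(sort(pooled$symptom_id), sort(unique(eff$symptom_id)))
  expect_equal(pooled$p_adj, adjust_bh(pooled$p))
  expect_true(all(pooled$k == 6))
})
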