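# Shared fixtures: toy scales, table generators, and the brute-force
# proportional-odds likelihood oracle used to cross-check the ML fit.

toy_scale <- function(n_items = 3L, max_level = 4L) {
  symptom_scale("CUSTOM", data.frame(
    item_id = sprintf("it_%d", seq_len(n_items)),
    label = sprintf("item %d", seq_len(n_items)),
    max_level = rep(max_level, n_items)))
}

make_table <- function(psy, adm, study = "S01", symptom = "it_1") {
  freq_table(study, symptom, psy, adm)
}

# Random small table with occupied extreme levels in the pooled distribution
# (avoids separated configurations for which the pOR MLE does not exist).
random_table <- function(L = 4L, max_total = 30L) {
  repeat {
    p_adm <- as.vector(rmultinom(1, sample(8:max_total, 1),
                                 prob = runif(L + 1, 0.2, 1)))
    p_psy <- as.vector(rmultinom(1, sample(8:max_total, 1),
                                 prob = runif(L + 1, 0.2, 1)))
    tot <- p_adm + p_psy
    occ <- which(tot > 0)
    if (length(occ) < 2) next
    # reject tables where either arm is empty or one arm owns an extreme
    # level alone (quasi-separation -> diverging MLE)
    if (sum(p_psy) == 0 || sum(p_adm) == 0) next
    lo <- occ[1]; hi <- occ[length(occ)]
    if (p_psy[lo] + p_psy[hi] == 0 || p_adm[lo] + p_adm[hi] == 0) next
    return(make_table(p_psy, p_adm))
  }
}

# Brute-force oracle: profile grid search over beta with Nelder-Mead
# maximisation over the cutpoints at each grid value, refined three times.
# Shares only the likelihood definition with the implementation, not the
# optimisation path.
oracle_log_por <- function(table) {
  keep <- (table$counts_psy + table$counts_adm) > 0
  cpsy <- table$counts_psy[keep]; cadm <- table$counts_adm[keep]
  K <- length(cpsy); L <- K - 1L
  n <- rbind(cadm, cpsy)
  nll_z <- function(z, b) {
    if (L > 1 && is.unsorted(z, strictly = TRUE)) return(1e10)
    v <- 0
    for (a in 1:2) {
      p <- diff(c(0, plogis(z - b * (a - 1)), 1))
      idx <- n[a, ] > 0
      if (any(p[idx] <= 0)) return(1e10)
      v <- v - sum(n[a, idx] * log(p[idx]))
    }
    v
  }
  cum <- cumsum(cpsy + cadm)
  z0 <- qlogis(cum[1:L] / cum[K])
  profile_nll <- function(b) {
    if (L == 1L) {
      op <- optimize(function(z) nll_z(z, b), interval = z0 + c(-8, 8),
                     tol = 1e-10)
      op$objective
    } else {
      op <- optim(z0, nll_z, b = b, method = "Nelder-Mead",
                  control = list(maxit = 5000, reltol = 1e-12))
      op$value
    }
  }
  lo <- -6; hi <- 6
  for (step in c(0.2, 0.02, 0.002, 2e-4, 2e-5)) {
    grid <- seq(lo, hi, by = step)
    vals <- vapply(grid, profile_nll, numeric(1))
    b <- grid[which.min(vals)]
    lo <- b - 2 * step; hi <- b + 2 * step
  }
  b
}

# Quietly estimate effects (drop messages about removed tables).
quiet_effects <- function(...) suppressMessages(estimate_effects(...))
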