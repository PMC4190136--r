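# Independent oracles and fixture builders. Nothing here calls the package's
# own estimation code paths: counting, enumeration, grid search, and the
# survival package serve as reference implementations.

# Empirical survivor function by direct counting (valid with no censoring).
empirical_survivor <- function(times, at) {
  vapply(at, function(s) mean(times > s), double(1))
}

# Exhaustive permutation p-value for the two-group log-rank statistic.
# The statistic for every relabelling comes from survival::survdiff, an
# implementation independent of the package's.
permutation_logrank_p <- function(times, events, n_group1) {
  n <- length(times)
  stat_of <- function(idx) {
    g <- rep(2L, n); g[idx] <- 1L
    survival::survdiff(survival::Surv(times, events) ~ g)$chisq
  }
  assignments <- utils::combn(n, n_group1, simplify = FALSE)
  stats <- vapply(assignments, stat_of, double(1))
  obs <- stat_of(seq_len(n_group1))
  mean(stats >= obs - 1e-12)
}

# Hand-coded Breslow partial log-likelihood (naive risk-set loops) for a
# single covariate, plus a grid-search maximiser.
breslow_loglik_naive <- function(beta, times, events, x) {
  ll <- 0
  for (i in which(events)) {
    risk <- which(times >= times[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

grid_search_cox <- function(times, events, x, lo = -5, hi = 5) {
  step <- 0.01
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, breslow_loglik_naive, double(1),
               times = times, events = events, x = x)
  b <- grid[which.max(ll)]
  while (step > 1e-7) {  # zoom: each pass refines the maximiser tenfold
    step <- step / 10
    grid <- seq(b - 11 * step, b + 11 * step, by = step)
    ll <- vapply(grid, breslow_loglik_naive, double(1),
                 times = times, events = events, x = x)
    b <- grid[which.max(ll)]
  }
  b
}

# Random valid cohort for round-trip properties: mixed missingness, extra
# integer / logical / character covariates.
random_cohort <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      id = sprintf("R%04d", sample(10^4, n)),
      time_months = round(rexp(n, 0.1), 3),
      event = sample(c(TRUE, FALSE), n, TRUE),
      kps = sample(c(seq(10L, 100L, 10L), NA), n, TRUE),
      steroids = sample(c(TRUE, FALSE, NA), n, TRUE),
      liver_mets = sample(c(TRUE, FALSE, NA), n, TRUE),
      pleural_effusion = sample(c(TRUE, FALSE), n, TRUE),
      primary_site = sample(c(primary_site_levels(), NA), n, TRUE),
      bone_mets_only = sample(c(TRUE, FALSE, NA), n, TRUE),
      n_metastatic_sites = sample(0:4, n, TRUE),
      opioids = sample(c(TRUE, FALSE, NA), n, TRUE),
      note = sample(c("a", "b", NA), n, TRUE)
    )
  })
}

# Published point-table rates (percent died within horizon), favorable then
# adverse level, for the two score variants.
table_rates_v1 <- function() {
  list(kps = c(2, 15), liver_mets = c(4, 11),
       pleural_effusion = c(4, 33), steroids = c(3, 11))
}
table_rates_v2 <- function() {
  list(kps = c(7, 39), liver_mets = c(8, 49),
       pleural_effusion = c(14, 50), steroids = c(10, 28))
}

# Cohort with the given per-level death rates planted factor by factor:
# records for one factor carry its favorable/adverse level and are missing
# on the other factors, so derive_point_table() sees each factor's own
# planted subcohort.
planted_factor_cohort <- function(rates, horizon, n_per_level, seed) {
  pieces <- lapply(seq_along(rates), function(i) {
    fac <- names(rates)[i]
    pr <- planted_rate_cohort(
      stats::setNames(rates[[fac]], c("favorable", "adverse")),
      n_per_level = n_per_level, horizon = horizon, seed = seed + i)
    adv <- pr$level == "adverse"
    out <- tibble::tibble(
      id = paste0(fac, "_", pr$id),
      time_months = pr$time_months,
      event = pr$event,
      kps = NA_integer_, steroids = NA, liver_mets = NA,
      pleural_effusion = NA
    )
    if (fac == "kps") out$kps <- ifelse(adv, 50L, 90L)
    else out[[fac]] <- adv
    out
  })
  dplyr::bind_rows(pieces)
}

# Two-group exponential cohort with a planted hazard ratio (no censoring).
planted_hr_cohort <- function(n_per_group, hr, baseline_rate = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(
    id = sprintf("H%05d", seq_len(2 * n_per_group)),
    x = rep(c(FALSE, TRUE), each = n_per_group),
    time_months = c(rexp(n_per_group, baseline_rate),
                    rexp(n_per_group, baseline_rate * hr)),
    event = TRUE
  )
}
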