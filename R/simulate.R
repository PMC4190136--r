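#' Configuration for the synthetic reirradiation cohort generator
#'
#' Builds the configuration list consumed by [simulate_cohort()]. The
#' defaults emulate the covariate mix observed on a dedicated palliative
#' radiotherapy service: 30% of patients with KPS <= 60, 34% with KPS 70-80,
#' steroid use in 54% of patients with known status (20% missing), liver
#' metastases in 22%, pleural effusion in 7%, and a primary-site mix led by
#' prostate (29%) and non-small-cell lung cancer (11%). Survival follows a
#' proportional-hazards Weibull model (exponential by default, `shape = 1`)
#' whose baseline median and per-factor log hazard ratios are calibrated from
#' the observed group-wise median survivals (for exponential survival the
#' hazard ratio of two groups is the inverse ratio of their medians):
#' reference pattern (KPS 90-100, no steroids, no liver metastases, no
#' pleural effusion) has median 18.3 months, and the default log hazard
#' ratios are `log(18.3/9.4)` for KPS 70-80, `log(18.3/2.1)` for KPS <= 60,
#' `log(12.2/3.6)` for steroid use, `log(9.7/2.8)` for liver metastases and
#' `log(9.4/1.3)` for pleural effusion. Administrative censoring emulates
#' uniform accrual over a 30-month study window with analysis at its close,
#' so censoring times are uniform on (0, 30) months.
#'
#' @param n Number of reirradiation courses to generate.
#' @param seed Integer seed; the same seed and config reproduce the cohort
#'   bit for bit. `NULL` uses the current RNG state.
#' @param prevalence Named list of covariate prevalences. `kps` is a named
#'   probability vector over the three performance-status bands; the
#'   logical factors are single probabilities of the adverse level;
#'   `primary_site` is a named probability vector over sites.
#' @param missingness Named vector of per-factor missingness probabilities.
#' @param baseline_median Median survival (months) of the reference covariate
#'   pattern.
#' @param log_hr Named list of log hazard ratios. Names `kps_70_80` and
#'   `kps_le60` address the performance-status bands; any other name must be
#'   a logical cohort column (its `TRUE` level carries the hazard ratio).
#' @param shape Weibull shape parameter; 1 gives exponential survival.
#' @param censoring List with `enabled` and `accrual_months`.
#' @param extras Named list of extra covariates to simulate; each element is
#'   `list(prevalence =, missingness =)` for a logical column.
#' @return A config list of class `rerad_config`.
#' @export
cohort_config <- function(n = 87,
                          seed = NULL,
                          prevalence = list(
                            kps = c("90-100" = 0.36, "70-80" = 0.34, "<=60" = 0.30),
                            steroids = 0.54,
                            liver_mets = 0.22,
                            pleural_effusion = 0.07,
                            bone_mets_only = 0.40,
                            primary_site = c(prostate = 0.29, breast = 0.10,
                                             nsclc = 0.11, colorectal = 0.09,
                                             bladder = 0.06, kidney = 0.07,
                                             melanoma = 0.03, other = 0.25)
                          ),
                          missingness = c(kps = 0, steroids = 0.20,
                                          liver_mets = 0, pleural_effusion = 0,
                                          bone_mets_only = 0, primary_site = 0),
                          baseline_median = 18.3,
                          log_hr = list(kps_70_80 = log(18.3 / 9.4),
                                        kps_le60 = log(18.3 / 2.1),
                                        steroids = log(12.2 / 3.6),
                                        liver_mets = log(9.7 / 2.8),
                                        pleural_effusion = log(9.4 / 1.3)),
                          shape = 1,
                          censoring = list(enabled = TRUE, accrual_months = 30),
                          extras = list(
                            opioids = list(prevalence = 0.72, missingness = 0.14),
                            brain_mets = list(prevalence = 0.08, missingness = 0)
                          )) {
  cfg <- list(n = n, seed = seed, prevalence = prevalence,
              missingness = missingness, baseline_median = baseline_median,
              log_hr = log_hr, shape = shape, censoring = censoring,
              extras = extras)
  validate_config(cfg)
  structure(cfg, class = "rerad_config")
}

validate_config <- function(cfg) {
  if (cfg$n < 0) abort("n must be >= 0", class = "reradscore_config_error")
  all_p <- c(unlist(cfg$prevalence), cfg$missingness,
             unlist(lapply(cfg$extras, unlist)))
  if (any(all_p < 0 | all_p > 1)) {
    abort("all probabilities must lie in [0, 1]",
          class = "reradscore_config_error")
  }
  for (fac in c("kps", "primary_site")) {
    s <- sum(cfg$prevalence[[fac]])
    if (s > 1 + 1e-8) {
      abort(sprintf("level probabilities for '%s' sum to %.3f > 1", fac, s),
            class = "reradscore_config_error")
    }
  }
  if (cfg$shape <= 0) abort("Weibull shape must be > 0",
                            class = "reradscore_config_error")
  invisible(cfg)
}

draw_masked <- function(x, miss_p, n) {
  if (miss_p > 0) x[runif(n) < miss_p] <- NA
  x
}

#' Simulate a synthetic reirradiation cohort
#'
#' Draws `n` patient records under the configured covariate prevalences,
#' proportional-hazards survival model, and administrative censoring
#' mechanism (see [cohort_config()] for the model and its defaults).
#' Covariates are drawn independently of one another; survival times depend
#' on the covariates through the configured log hazard ratios. Observed time
#' is the minimum of the death and censoring times and `event` records which
#' came first. A fixed seed reproduces the cohort exactly.
#'
#' @param config A [cohort_config()] object.
#' @param ... Config fields to override, e.g. `simulate_cohort(n = 500, seed = 7)`.
#' @return A cohort tibble (see [cohort_columns()]) with a `true_death_time`
#'   attribute-free layout: only observable columns are returned.
#' @examples
#' co <- simulate_cohort(cohort_config(n = 50, seed = 1))
#' dplyr::count(co, event)
#' @export
simulate_cohort <- function(config = cohort_config(), ...) {
  dots <- list(...)
  if (length(dots)) {
    config <- modifyList(unclass(config), dots)
    validate_config(config)
  }
  local_seed(config$seed)
  n <- config$n
  if (n == 0) {
    return(tibble::tibble(id = character(), time_months = double(),
                          event = logical(), kps = integer(),
                          steroids = logical(), liver_mets = logical(),
                          pleural_effusion = logical(),
                          primary_site = character(),
                          bone_mets_only = logical()))
  }
  prev <- config$prevalence
  kps_band <- sample(names(prev$kps), n, replace = TRUE, prob = prev$kps)
  kps <- integer(n)
  kps[kps_band == "90-100"] <- sample(c(90L, 100L), sum(kps_band == "90-100"), TRUE)
  kps[kps_band == "70-80"] <- sample(c(70L, 80L), sum(kps_band == "70-80"), TRUE)
  kps[kps_band == "<=60"] <- sample(seq(30L, 60L, 10L), sum(kps_band == "<=60"), TRUE)
  co <- tibble::tibble(
    id = sprintf("P%05d", seq_len(n)),
    kps = kps,
    steroids = runif(n) < prev$steroids,
    liver_mets = runif(n) < prev$liver_mets,
    pleural_effusion = runif(n) < prev$pleural_effusion,
    bone_mets_only = runif(n) < prev$bone_mets_only,
    primary_site = sample(names(prev$primary_site), n, TRUE,
                          prob = prev$primary_site)
  )
  for (name in names(config$extras)) {
    spec <- config$extras[[name]]
    co[[name]] <- draw_masked(runif(n) < spec$prevalence, spec$missingness, n)
  }

  # linear predictor from the (pre-masking) covariates
  eta <- rep(0, n)
  for (term in names(config$log_hr)) {
    b <- config$log_hr[[term]]
    ind <- switch(term,
      kps_70_80 = kps_band == "70-80",
      kps_le60 = kps_band == "<=60",
      as.logical(co[[term]])
    )
    eta <- eta + b * as.numeric(ind)
  }
  a <- config$shape
  scale0 <- config$baseline_median / log(2)^(1 / a)
  death_time <- scale0 * (rexp(n) / exp(eta))^(1 / a)
  if (isTRUE(config$censoring$enabled)) {
    censor_time <- runif(n, 0, config$censoring$accrual_months)
    co$time_months <- pmin(death_time, censor_time)
    co$event <- death_time <= censor_time
  } else {
    co$time_months <- death_time
    co$event <- rep(TRUE, n)
  }

  # mask after the survival draw so missingness is non-informative
  miss <- config$missingness
  for (col in names(miss)) {
    if (col %in% names(co)) co[[col]] <- draw_masked(co[[col]], miss[[col]], n)
  }
  co <- co[, c("id", "time_months", "event", "kps", "steroids", "liver_mets",
               "pleural_effusion", "primary_site", "bone_mets_only",
               names(config$extras))]
  validate_cohort(co)
  co
}

#' Simulate a cohort with planted actuarial death rates
#'
#' For each named level, draws exponential survival times whose true
#' cumulative death probability at `horizon` months equals the planted rate
#' (`rate = -log(1 - p) / horizon`), with no censoring. A planted rate of 0
#' yields times far beyond the horizon; a rate of 1 yields immediate deaths.
#' This is the fixture used to test recovery of a point table from known
#' death rates.
#'
#' @param rates Named numeric vector of death probabilities in `[0, 1]`,
#'   one per level.
#' @param n_per_level Patients per level.
#' @param horizon Horizon in months at which the rates are planted.
#' @param seed Integer seed.
#' @return A cohort tibble with an additional `level` column.
#' @export
planted_rate_cohort <- function(rates, n_per_level, horizon, seed = NULL) {
  if (any(rates < 0 | rates > 1)) {
    abort("planted rates must lie in [0, 1]", class = "reradscore_config_error")
  }
  if (horizon <= 0 && any(rates >= 1)) {
    abort("a planted rate of 1 requires a positive horizon",
          class = "reradscore_config_error")
  }
  local_seed(seed)
  far <- 1e6 * max(horizon, 1)
  pieces <- purrr::imap(rates, function(p, lev) {
    t <- if (p <= 0) {
      rep(far, n_per_level)
    } else if (p >= 1) {
      rep(0, n_per_level)
    } else {
      rexp(n_per_level, rate = -log(1 - p) / horizon)
    }
    tibble::tibble(level = lev, time_months = t, event = TRUE)
  })
  out <- dplyr::bind_rows(pieces)
  out$id <- sprintf("L%05d", seq_len(nrow(out)))
  out[, c("id", "time_months", "event", "level")]
}
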