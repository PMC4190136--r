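test_that("the univariate screen applies the strict carry-forward threshold", {
  co <- simulate_cohort(cohort_config(n = 300, seed = 61))
  scr <- univariate_screen(co, factors = c("kps3", "steroids", "liver_mets",
                                           "pleural_effusion", "brain_mets"))
  expect_s3_class(scr, "rerad_screen")
  expect_equal(scr$carried_forward, !is.na(scr$p_value) & scr$p_value < 0.1)

  # threshold 1.0 carries every testable factor forward
  scr_all <- univariate_screen(co, factors = c("steroids", "liver_mets"),
                               threshold = 1.0)
  expect_true(all(scr_all$carried_forward))
})

test_that("screen p-values are pooled log-rank p-values over the factor's levels", {
  co <- simulate_cohort(cohort_config(n = 250, seed = 62))
  scr <- univariate_screen(co, factors = c("kps3", "liver_mets"))
  # kps3 row: 3 bands, df = 2
  expect_equal(scr$df[scr$factor_name == "kps3"], 2L)
  sub <- co[!is.na(co$liver_mets), ]
  ref_liver <- survival::survdiff(
    survival::Surv(time_months, event) ~ liver_mets, data = sub)
  expect_equal(scr$chi_square[scr$factor_name == "liver_mets"],
               ref_liver$chisq, tolerance = 1e-10)
})

test_that("single-level factors are excluded with a warning, not an error", {
  co <- simulate_cohort(cohort_config(n = 80, seed = 63))
  co$flat <- TRUE
  expect_warning(scr <- univariate_screen(co, factors = c("flat", "steroids")),
                 "fewer than two")
  expect_true(is.na(scr$p_value[scr$factor_name == "flat"]))
  expect_false(scr$carried_forward[scr$factor_name == "flat"])
})

test_that("a planted strong factor is almost always carried forward, nulls rarely", {
  n_rep <- 200
  res <- withr::with_seed(71, {
    vapply(seq_len(n_rep), function(i) {
      n <- 200
      strong <- sample(c(TRUE, FALSE), n, TRUE)
      d <- tibble::tibble(
        time_months = rexp(n, 0.1 * ifelse(strong, 3, 1)),
        event = TRUE,
        strong = strong,
        null_factor = sample(c(TRUE, FALSE), n, TRUE))
      scr <- univariate_screen(d, factors = c("strong", "null_factor"))
      scr$carried_forward
    }, logical(2))
  })
  expect_gte(mean(res[1, ]), 0.95)   # power for HR = 3 at n = 200
  expect_lte(mean(res[2, ]), 0.20)   # null factor near the 10% threshold rate
})

test_that("backward elimination keeps a planted factor and discards nulls", {
  n_rep <- 60
  keeps <- withr::with_seed(83, {
    vapply(seq_len(n_rep), function(i) {
      n <- 300
      planted <- sample(c(TRUE, FALSE), n, TRUE)
      d <- tibble::tibble(
        time_months = rexp(n, 0.1 * ifelse(planted, 4, 1)),
        event = TRUE,
        planted = planted,
        n1 = sample(c(TRUE, FALSE), n, TRUE),
        n2 = sample(c(TRUE, FALSE), n, TRUE),
        n3 = sample(c(TRUE, FALSE), n, TRUE))
      fit <- backward_eliminate(d, c("planted", "n1", "n2", "n3"))
      c("planted" %in% fit$retained,
        length(setdiff(fit$retained, "planted")) == 0)
    }, logical(2))
  })
  expect_gte(mean(keeps[1, ]), 0.9)  # planted factor retained
  expect_gte(mean(keeps[2, ]), 0.5)  # all three nulls usually gone
})

test_that("elimination threshold boundaries behave per the removal rule", {
  co <- simulate_cohort(cohort_config(n = 200, seed = 85))
  # removal when p >= threshold: a threshold of 0 removes everything ...
  expect_warning(
    fit0 <- backward_eliminate(co, c("liver_mets", "steroids"), removal_p = 0),
    "removed every covariate")
  expect_length(fit0$retained, 0)
  expect_equal(fit0$loglik, fit0$loglik_null)
  # ... and a threshold of 1 removes nothing (no p-value reaches 1)
  fit1 <- backward_eliminate(co, c("liver_mets", "steroids"), removal_p = 1)
  expect_setequal(fit1$retained, c("liver_mets", "steroids"))
  expect_equal(nrow(fit1$elimination), 0)
})

test_that("multi-column terms are removed jointly and cases stay fixed", {
  co <- simulate_cohort(cohort_config(n = 250, seed = 87))
  fit <- backward_eliminate(co, c("kps3", "brain_mets"), removal_p = 0.10)
  # kps3 either fully present (2 columns) or fully absent
  if ("kps3" %in% fit$retained) {
    expect_true(all(c("kps_70_80", "kps_le60") %in% names(fit$coef)))
  } else {
    expect_false(any(c("kps_70_80", "kps_le60") %in% names(fit$coef)))
  }
  # complete-case set fixed on the full starting covariates
  expect_equal(fit$n, sum(!is.na(co$kps) & !is.na(co$brain_mets)))
})
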