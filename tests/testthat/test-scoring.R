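test_that("point assignment follows the divide-by-ten rule with variant rounding", {
  # half-point grain floors: 15 -> 1.5, 11 -> 1, 33 -> 3, small rates -> 0
  expect_equal(assign_points(c(2, 15, 4, 11, 4, 33, 3, 11), "v1"),
               c(0, 1.5, 0, 1, 0, 3, 0, 1))
  # integer grain rounds half-up: 39 -> 4, 49 -> 5, 50 -> 5, 28 -> 3
  expect_equal(assign_points(c(7, 39, 8, 49, 14, 50, 10, 28), "v2"),
               c(1, 4, 1, 5, 1, 5, 1, 3))
  expect_equal(assign_points(0, "v1"), 0)
  expect_equal(assign_points(0, "v2"), 0)
  expect_equal(assign_points(15, "v1"), 1.5)  # the worked poor-KPS example
  # exact half-grain boundaries stay put, just below them floors down
  expect_equal(assign_points(c(5, 4.999, 25, 24.999), "v1"), c(0.5, 0, 2.5, 2))
  expect_equal(assign_points(c(45, 44.999), "v2"), c(5, 4))
  expect_error(assign_points(101, "v1"), class = "reradscore_validation_error")
})

test_that("both rounding rules are non-decreasing in the rate", {
  rates <- seq(0, 100, by = 0.25)
  expect_true(all(diff(assign_points(rates, "v1")) >= 0))
  expect_true(all(diff(assign_points(rates, "v2")) >= 0))
})

test_that("published rates reproduce the published point tables and sum range", {
  pt1 <- point_table(table_rates_v1(), "v1")
  expect_equal(pt1$points, c(0, 1.5, 0, 1, 0, 3, 0, 1))
  expect_equal(attr(pt1, "min_total"), 0)
  expect_equal(attr(pt1, "max_total"), 6.5)

  pt2 <- point_table(table_rates_v2(), "v2")
  expect_equal(pt2$points, c(1, 4, 1, 5, 1, 5, 1, 3))
  expect_equal(attr(pt2, "min_total"), 4)
  expect_equal(attr(pt2, "max_total"), 17)
  expect_true(all(pt2$points == round(pt2$points)))          # integer grain
  expect_true(all(pt1$points * 2 == round(pt1$points * 2)))  # half grain
})

test_that("derive_point_table recovers planted rates within rounding", {
  co <- planted_factor_cohort(table_rates_v1() |> lapply(`/`, 100),
                              horizon = 1, n_per_level = 20000, seed = 5)
  tab <- derive_point_table(co, variant = "v1")
  expect_equal(tab$points, point_table(table_rates_v1(), "v1")$points)

  # nobody dying before the horizon means zero points everywhere
  quiet <- tibble::tibble(
    id = as.character(1:40), time_months = 10, event = TRUE,
    kps = rep(c(90L, 50L), 20), steroids = rep(c(TRUE, FALSE), 20),
    liver_mets = rep(c(TRUE, FALSE), each = 20),
    pleural_effusion = rep(c(TRUE, FALSE), 20))
  tq <- derive_point_table(quiet, variant = "v1", horizon = 1)
  expect_true(all(tq$points == 0))
})

test_that("an empty factor level is an error naming the level", {
  co <- tibble::tibble(id = as.character(1:10), time_months = rexp(10, 1),
                       event = TRUE, kps = 90L, steroids = FALSE,
                       liver_mets = FALSE, pleural_effusion = FALSE)
  expect_error(derive_point_table(co, variant = "v1"), "kps.*<=60",
               class = "reradscore_validation_error")
})

test_that("total scores reproduce the published extremes and handle missingness", {
  pt2 <- point_table(table_rates_v2(), "v2")
  pts <- tibble::tibble(
    id = c("worst", "best", "missing_steroids"),
    time_months = 1, event = TRUE,
    kps = c(40L, 90L, 90L),
    liver_mets = c(TRUE, FALSE, FALSE),
    pleural_effusion = c(TRUE, FALSE, FALSE),
    steroids = c(TRUE, FALSE, NA))
  sc <- score_cohort(pts, pt2)
  expect_equal(sc$total[sc$id == "worst"], 17)
  expect_equal(sc$total[sc$id == "best"], 4)
  expect_false(sc$assignable[sc$id == "missing_steroids"])
  expect_true(is.na(sc$group[sc$id == "missing_steroids"]))

  pt1 <- point_table(table_rates_v1(), "v1")
  sc1 <- score_cohort(pts, pt1)
  expect_equal(sc1$total[sc1$id == "worst"], 6.5)
  expect_equal(sc1$total[sc1$id == "best"], 0)
})

test_that("total score is monotone in each factor", {
  pt <- point_table(table_rates_v2(), "v2")
  base <- tibble::tibble(id = "b", time_months = 1, event = TRUE, kps = 90L,
                         liver_mets = FALSE, pleural_effusion = FALSE,
                         steroids = FALSE)
  t0 <- score_cohort(base, pt)$total
  for (fac in c("liver_mets", "pleural_effusion", "steroids")) {
    worse <- base
    worse[[fac]] <- TRUE
    expect_gte(score_cohort(worse, pt)$total, t0)
  }
  worse <- base; worse$kps <- 50L
  expect_gte(score_cohort(worse, pt)$total, t0)
})

test_that("risk-group boundaries match the published tiering", {
  expect_equal(assign_risk_group(0, "v1"), 1L)
  expect_equal(assign_risk_group(c(1, 1.5), "v1"), c(2L, 2L))
  expect_equal(assign_risk_group(c(2, 3), "v1"), c(3L, 3L))
  expect_equal(assign_risk_group(3.5, "v1"), 4L)
  expect_equal(assign_risk_group(c(4, 5), "v2"), c(1L, 1L))
  expect_equal(assign_risk_group(7, "v2"), 2L)
  expect_equal(assign_risk_group(c(9, 11), "v2"), c(3L, 3L))
  expect_equal(assign_risk_group(12, "v2"), 4L)
  expect_error(assign_risk_group(20, "v2", range = c(4, 17)),
               "attainable", class = "reradscore_validation_error")
  # custom cutpoints override the defaults
  expect_equal(assign_risk_group(7, "v2", cutpoints = c(7, 10, 12)), 1L)
})

test_that("the SPS comparator counts adverse variables per the published rule", {
  expect_equal(as.character(sps_assign(TRUE, TRUE, TRUE)$group), "poor")
  expect_equal(as.character(sps_assign(TRUE, TRUE, FALSE)$group), "intermediate")
  expect_equal(as.character(sps_assign(TRUE, FALSE, FALSE)$group), "good")
  expect_equal(as.character(sps_assign(FALSE, FALSE, FALSE)$group), "good")
  expect_true(is.na(sps_assign(NA, TRUE, TRUE)$group))

  # all 8 combinations map by count
  grid <- expand.grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE),
                      c = c(TRUE, FALSE))
  res <- sps_assign(grid$a, grid$b, grid$c)
  expect_equal(res$adverse_count, grid$a + grid$b + grid$c)
  expect_equal(as.character(res$group),
               dplyr::case_when(res$adverse_count == 3 ~ "poor",
                                res$adverse_count == 2 ~ "intermediate",
                                TRUE ~ "good"))
})

test_that("sps_cohort derives its inputs from cohort columns", {
  co <- tibble::tibble(
    id = c("a", "b", "c"), time_months = 1, event = TRUE,
    kps = c(50L, 90L, NA), primary_site = c("prostate", "breast", "nsclc"),
    bone_mets_only = c(FALSE, TRUE, FALSE))
  out <- sps_cohort(co)
  expect_equal(as.character(out$sps_group), c("poor", "good", NA))
})

test_that("stratification evaluation summarises groups and pairwise tests", {
  base <- tibble::tibble(time_months = c(1, 2, 4, 8, 16), event = TRUE)
  copies <- dplyr::bind_rows(dplyr::mutate(base, g = "g1"),
                             dplyr::mutate(base, g = "g2"))
  ev <- evaluate_stratification(copies, g)
  expect_equal(ev$by_group$median_months, c(4, 4))
  expect_true(all(ev$pairwise$p_value == 1))

  # a group dying out before 2 months has a 100% 2-month death rate
  mixed <- dplyr::bind_rows(
    tibble::tibble(time_months = c(0.3, 0.9, 1.4), event = TRUE, g = "doomed"),
    tibble::tibble(time_months = c(5, 9, 30), event = c(TRUE, TRUE, FALSE),
                   g = "fine"))
  ev2 <- evaluate_stratification(mixed, g)
  expect_equal(ev2$by_group$death_rate_2mo[ev2$by_group$group == "doomed"], 100)
  expect_error(evaluate_stratification(base |> dplyr::mutate(g = "only"), g),
               class = "reradscore_validation_error")
})

test_that("planted four-tier cohorts recover strictly ordered medians", {
  medians <- c(24, 10, 3, 1)
  n_rep <- 200
  ok <- withr::with_seed(37, {
    vapply(seq_len(n_rep), function(i) {
      d <- dplyr::bind_rows(lapply(1:4, function(k) {
        tibble::tibble(time_months = rexp(100, log(2) / medians[k]),
                       event = TRUE, g = paste0("g", k))
      }))
      ev <- evaluate_stratification(d, g)
      all(diff(ev$by_group$median_months) < 0)
    }, logical(1))
  })
  expect_gte(mean(ok), 0.95)
})
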