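## The point-score constructor: each prognostic factor level contributes
## points equal to its actuarial death rate (percent) at a fixed horizon
## divided by 10. Variant 1 (1-month horizon) keeps half points; variant 2
## (2-month horizon) uses whole points.

score_factor_names <- function() {
  c("kps", "liver_mets", "pleural_effusion", "steroids")
}

score_factor_labels <- function(fac) {
  if (fac == "kps") c(favorable = "70-100", adverse = "<=60")
  else c(favorable = "no", adverse = "yes")
}

# adverse-level indicator for one score factor (NA = missing)
score_factor_adverse <- function(data, fac) {
  if (fac == "kps") data$kps <= 60 else as.logical(data[[fac]])
}

default_horizon <- function(variant) if (variant == "v1") 1 else 2

#' Convert an actuarial death rate to score points
#'
#' Implements the death-rate-divided-by-ten rule with the rounding grain of
#' each score variant: variant 1 (1-month horizon) floors `rate / 10` to the
#' nearest lower multiple of 0.5, so a 15% death rate gives 1.5 points and
#' an 11% rate gives 1 point; variant 2 (2-month horizon) rounds
#' `rate / 10` half-up to the nearest integer, so 39% gives 4 points and
#' 50% gives 5. Both rules are non-decreasing in the rate.
#'
#' @param death_rate_percent Death rate(s) as percentages in `[0, 100]`.
#' @param variant `"v1"` (half-point grain) or `"v2"` (integer grain).
#' @return Numeric points, vectorised over the rates.
#' @examples
#' assign_points(15, "v1")  # 1.5
#' assign_points(39, "v2")  # 4
#' @export
assign_points <- function(death_rate_percent, variant = c("v1", "v2")) {
  variant <- match.arg(variant)
  r <- death_rate_percent
  if (any(is.na(r)) || any(r < 0 | r > 100)) {
    abort("death rates must lie in [0, 100]",
          class = "reradscore_validation_error")
  }
  if (variant == "v1") floor(r / 5 + 1e-9) / 2 else floor(r / 10 + 0.5 + 1e-9)
}

new_point_table <- function(entries, variant, horizon) {
  per_factor <- dplyr::summarise(
    dplyr::group_by(entries, factor_name),
    min_pts = min(points), max_pts = max(points), .groups = "drop")
  structure(entries,
            class = c("point_table", class(entries)),
            variant = variant, horizon = horizon,
            min_total = sum(per_factor$min_pts),
            max_total = sum(per_factor$max_pts))
}

#' Build a point table from known death rates
#'
#' Constructs a score point table directly from per-level actuarial death
#' rates (percentages), e.g. rates taken from a published table, applying
#' the variant's rounding rule via [assign_points()].
#'
#' @param rates Named list, one element per factor (default factors: `kps`,
#'   `liver_mets`, `pleural_effusion`, `steroids`), each a length-2 numeric
#'   vector `c(favorable, adverse)` of death-rate percentages.
#' @param variant `"v1"` or `"v2"`.
#' @param horizon Horizon in months the rates refer to; defaults to 1 for
#'   v1 and 2 for v2.
#' @return A `point_table` tibble: `factor_name`, `level`, `adverse`,
#'   `rate_percent`, `points`, with attributes `variant`, `horizon`,
#'   `min_total`, `max_total` (sums of per-factor minima/maxima).
#' @examples
#' point_table(list(kps = c(2, 15), liver_mets = c(4, 11),
#'                  pleural_effusion = c(4, 33), steroids = c(3, 11)), "v1")
#' @export
point_table <- function(rates, variant = c("v1", "v2"), horizon = NULL) {
  variant <- match.arg(variant)
  horizon <- horizon %||% default_horizon(variant)
  entries <- purrr::imap(rates, function(r, fac) {
    labs <- score_factor_labels(fac)
    tibble::tibble(factor_name = fac,
                   level = unname(labs),
                   adverse = c(FALSE, TRUE),
                   rate_percent = as.numeric(r),
                   points = assign_points(as.numeric(r), variant))
  })
  new_point_table(dplyr::bind_rows(entries), variant, horizon)
}

#' Derive a point table from a cohort
#'
#' For each prognostic factor, estimates the actuarial death rate at the
#' horizon separately for the favorable and adverse level (Kaplan-Meier on
#' the records non-missing for that factor) and converts it to points with
#' the variant's rounding rule. KPS is dichotomised at <= 60 for scoring.
#'
#' @inheritParams cox_fit
#' @param factors Score factors; defaults to KPS (<=60 vs 70-100), liver
#'   metastases, pleural effusion, and steroid use.
#' @param variant `"v1"` (1-month horizon, half-point grain) or `"v2"`
#'   (2-month horizon, integer grain).
#' @param horizon Horizon in months; defaults to the variant's.
#' @return A `point_table` tibble as in [point_table()], with an `n` column
#'   giving the per-level record count.
#' @export
derive_point_table <- function(data, factors = score_factor_names(),
                               variant = c("v1", "v2"), horizon = NULL,
                               time = time_months, event = event) {
  variant <- match.arg(variant)
  horizon <- horizon %||% default_horizon(variant)
  t_all <- dplyr::pull(data, {{ time }})
  d_all <- as.logical(dplyr::pull(data, {{ event }}))
  entries <- purrr::map(factors, function(fac) {
    adverse <- score_factor_adverse(data, fac)
    labs <- score_factor_labels(fac)
    rows <- purrr::map2(c(FALSE, TRUE), unname(labs), function(adv, lab) {
      sel <- !is.na(adverse) & adverse == adv
      if (!any(sel)) {
        abort(sprintf("factor '%s', level '%s' has no records", fac, lab),
              class = "reradscore_validation_error")
      }
      km <- km_estimate(tibble::tibble(.t = t_all[sel], .d = d_all[sel]),
                        .t, .d)
      rate <- as.numeric(death_rate_at(km, horizon))
      tibble::tibble(factor_name = fac, level = lab, adverse = adv,
                     n = sum(sel), rate_percent = rate,
                     points = assign_points(rate, variant))
    })
    dplyr::bind_rows(rows)
  })
  new_point_table(dplyr::bind_rows(entries), variant, horizon)
}

#' @export
print.point_table <- function(x, ...) {
  cat(sprintf("Point table, variant %s (%g-month death rates / 10)\n",
              attr(x, "variant"), attr(x, "horizon")))
  NextMethod()
  cat(sprintf("Attainable totals: %g to %g\n",
              attr(x, "min_total"), attr(x, "max_total")))
  invisible(x)
}

#' Score a cohort against a point table
#'
#' Looks up each patient's level on every score factor, sums the component
#' points, and assigns the four-tier risk group. A patient missing any score
#' factor is unassignable: components present are reported but `total` and
#' `group` are `NA`.
#'
#' @param data A cohort tibble.
#' @param table A `point_table` from [point_table()] or
#'   [derive_point_table()].
#' @param cutpoints Optional risk-group cutpoints passed to
#'   [assign_risk_group()].
#' @return A tibble with one row per patient: `id`, one `points_*` column
#'   per factor, `total`, `assignable`, and `group` (integer 1-4, 1 most
#'   favorable).
#' @export
score_cohort <- function(data, table, cutpoints = NULL) {
  variant <- attr(table, "variant")
  factors <- unique(table$factor_name)
  comp <- purrr::map(factors, function(fac) {
    adverse <- score_factor_adverse(data, fac)
    pts_fav <- table$points[table$factor_name == fac & !table$adverse]
    pts_adv <- table$points[table$factor_name == fac & table$adverse]
    ifelse(is.na(adverse), NA_real_, ifelse(adverse, pts_adv, pts_fav))
  })
  names(comp) <- paste0("points_", factors)
  out <- tibble::tibble(id = data$id, !!!comp)
  mat <- as.matrix(out[, -1, drop = FALSE])
  out$total <- rowSums(mat)
  out$assignable <- !is.na(out$total)
  out$group <- rep(NA_integer_, nrow(out))
  if (any(out$assignable)) {
    out$group[out$assignable] <- assign_risk_group(
      out$total[out$assignable], variant, cutpoints,
      range = c(attr(table, "min_total"), attr(table, "max_total")))
  }
  out
}

#' Assign four-tier risk groups from total scores
#'
#' Maps total points to risk groups 1 (most favorable) through 4. Default
#' boundaries: variant 1 — group 1 at 0 points, group 2 over (0, 1.5],
#' group 3 over (1.5, 3], group 4 above 3; variant 2 — group 1 up to 5
#' points, group 2 over (5, 8], group 3 over (8, 11], group 4 above 11.
#'
#' @param total Numeric total scores.
#' @param variant `"v1"` or `"v2"` (selects the default cutpoints).
#' @param cutpoints Optional numeric vector of three upper boundaries
#'   `c(g1_max, g2_max, g3_max)` replacing the defaults.
#' @param range Optional attainable range `c(min, max)`; totals outside it
#'   raise an error.
#' @return Integer group indices 1-4.
#' @examples
#' assign_risk_group(c(0, 1.5, 3.5), "v1")  # 1 2 4
#' assign_risk_group(7, "v2")               # 2
#' @export
assign_risk_group <- function(total, variant = c("v1", "v2"),
                              cutpoints = NULL, range = NULL) {
  variant <- match.arg(variant)
  cut3 <- cutpoints %||% if (variant == "v1") c(0, 1.5, 3) else c(5, 8, 11)
  if (length(cut3) != 3 || is.unsorted(cut3)) {
    abort("cutpoints must be three non-decreasing upper boundaries",
          class = "reradscore_config_error")
  }
  if (!is.null(range)) {
    bad <- which(!is.na(total) & (total < range[1] - 1e-9 |
                                    total > range[2] + 1e-9))
    if (length(bad)) {
      abort(sprintf("total score %g outside the attainable range [%g, %g]",
                    total[bad[1]], range[1], range[2]),
            class = "reradscore_validation_error")
    }
  }
  as.integer(cut(total, breaks = c(-Inf, cut3, Inf), labels = FALSE))
}

#' Three-variable survival prediction score (SPS)
#'
#' The comparator score counts three adverse variables — nonbreast primary
#' tumor, metastases other than bone, and KPS <= 60 — and maps the count to
#' a prognosis group: `poor` when all three are present, `intermediate` when
#' two are, `good` when zero or one is. Records with any missing input are
#' unassignable (`NA` count and group).
#'
#' @param nonbreast_primary,mets_other_than_bone,kps_le_60 Logical vectors
#'   (recycled to a common length).
#' @return A tibble: `adverse_count` (integer 0-3) and `group` (factor
#'   good < intermediate < poor).
#' @examples
#' sps_assign(TRUE, TRUE, TRUE)$group    # poor
#' sps_assign(TRUE, TRUE, FALSE)$group   # intermediate
#' @export
sps_assign <- function(nonbreast_primary, mets_other_than_bone, kps_le_60) {
  n <- max(length(nonbreast_primary), length(mets_other_than_bone),
           length(kps_le_60))
  a <- rep_len(as.logical(nonbreast_primary), n)
  b <- rep_len(as.logical(mets_other_than_bone), n)
  c_ <- rep_len(as.logical(kps_le_60), n)
  count <- as.integer(a) + as.integer(b) + as.integer(c_)
  group <- factor(dplyr::case_when(
    is.na(count) ~ NA_character_,
    count == 3 ~ "poor",
    count == 2 ~ "intermediate",
    TRUE ~ "good"
  ), levels = c("good", "intermediate", "poor"), ordered = TRUE)
  tibble::tibble(adverse_count = count, group = group)
}

#' @describeIn sps_assign derive the three SPS inputs from cohort columns
#'   (`primary_site`, `bone_mets_only`, `kps`) and return the cohort with
#'   `sps_count` and `sps_group` appended.
#' @param data A cohort tibble.
#' @export
sps_cohort <- function(data) {
  res <- sps_assign(data$primary_site != "breast",
                    !data$bone_mets_only,
                    data$kps <= 60)
  data$sps_count <- res$adverse_count
  data$sps_group <- res$group
  data
}

#' Evaluate a risk-group stratification
#'
#' Summarises survival by risk group: per-group size, Kaplan-Meier median
#' survival, and actuarial death rates at 1 and 2 months, together with the
#' pooled log-rank test over all groups and uncorrected pairwise log-rank
#' comparisons.
#'
#' @param data A data frame with one row per patient.
#' @param group Grouping column (tidy evaluation).
#' @inheritParams km_estimate
#' @param correction Multiplicity correction for the pairwise tests.
#' @return An object of class `rerad_strat`: list with `by_group` (tibble),
#'   `overall` (a `logrank_test`), `pairwise` (tibble), and the per-group
#'   `curves`.
#' @export
evaluate_stratification <- function(data, group, time = time_months,
                                    event = event,
                                    correction = c("none", "bonferroni", "holm")) {
  correction <- match.arg(correction)
  g <- droplevels(factor(dplyr::pull(data, {{ group }})))
  keep <- !is.na(g)
  data <- data[keep, , drop = FALSE]
  g <- g[keep]
  if (nlevels(g) < 2) {
    abort("stratification needs at least two non-empty groups",
          class = "reradscore_validation_error")
  }
  t_all <- dplyr::pull(data, {{ time }})
  d_all <- as.logical(dplyr::pull(data, {{ event }}))
  curves <- purrr::map(levels(g), function(lev) {
    km_estimate(tibble::tibble(.t = t_all[g == lev], .d = d_all[g == lev]),
                .t, .d)
  })
  names(curves) <- levels(g)
  by_group <- purrr::imap(curves, function(km, lev) {
    tibble::tibble(
      group = lev, n = attr(km, "n0"), n_events = sum(km$n_event),
      median_months = median_survival(km),
      death_rate_1mo = suppressWarnings(as.numeric(death_rate_at(km, 1))),
      death_rate_2mo = suppressWarnings(as.numeric(death_rate_at(km, 2))))
  })
  sub <- tibble::tibble(.t = t_all, .d = d_all, .g = g)
  structure(list(
    by_group = dplyr::bind_rows(by_group),
    overall = logrank_test(sub, .g, .t, .d),
    pairwise = pairwise_logrank(sub, .g, .t, .d, correction = correction),
    curves = curves
  ), class = "rerad_strat")
}

#' @export
print.rerad_strat <- function(x, ...) {
  cat("Risk-group stratification\n")
  print(x$by_group)
  print(x$overall)
  cat("Pairwise log-rank comparisons:\n")
  print(x$pairwise)
  invisible(x)
}

#' @describeIn evaluate_stratification per-group summary tibble.
#' @param x A `rerad_strat` object.
#' @param ... Unused.
#' @export
tidy.rerad_strat <- function(x, ...) x$by_group

#' @describeIn evaluate_stratification one-row tibble with the pooled
#'   log-rank test.
#' @export
glance.rerad_strat <- function(x, ...) glance(x$overall)
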