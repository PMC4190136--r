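#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit survival estimate
#' \eqn{S(t) = \prod_{t_i \le t} (1 - d_i / n_i)} over the distinct event
#' times, together with Greenwood standard errors. At a time carrying both
#' deaths and censorings, deaths are processed first: individuals censored at
#' `t` are still at risk at `t`.
#'
#' @param data A data frame with one row per patient.
#' @param time,event Columns holding the follow-up time (months, >= 0) and
#'   the death indicator (`TRUE` = death observed). Tidy evaluation: pass
#'   bare column names.
#' @return A tibble of class `km_curve` with one row per distinct death time:
#'   `time`, `n_risk` (at risk just before the time), `n_event`, `survival`
#'   (the estimate just after the time), and `std_err` (Greenwood). The
#'   initial cohort size, censoring times, and maximum follow-up are carried
#'   as attributes `n0`, `censor_times`, and `max_time`.
#' @examples
#' km <- km_estimate(data.frame(time_months = c(1, 2, 3),
#'                              event = c(TRUE, FALSE, TRUE)))
#' km$survival  # 2/3 at t = 1, 0 at t = 3
#' @export
km_estimate <- function(data, time = time_months, event = event) {
  t <- dplyr::pull(data, {{ time }})
  d <- dplyr::pull(data, {{ event }})
  if (length(t) == 0) {
    abort("cannot estimate a survival curve from an empty cohort",
          class = "reradscore_validation_error")
  }
  if (any(is.na(t)) || any(t < 0)) {
    abort("survival times must be non-negative and non-missing",
          class = "reradscore_validation_error")
  }
  d <- as.logical(d)
  n0 <- length(t)
  ord <- order(t, !d)  # deaths before censorings at tied times
  t <- t[ord]; d <- d[ord]
  event_times <- sort(unique(t[d]))
  if (length(event_times) == 0) {
    out <- tibble::tibble(time = double(), n_risk = integer(),
                          n_event = integer(), survival = double(),
                          std_err = double())
  } else {
    n_risk <- vapply(event_times, function(s) sum(t >= s), integer(1))
    n_event <- vapply(event_times, function(s) sum(t == s & d), integer(1))
    frac <- 1 - n_event / n_risk
    surv <- cumprod(frac)
    # Greenwood: var(S) = S^2 * sum d / (n (n - d)); infinite once S hits 0
    gw <- cumsum(ifelse(n_risk > n_event,
                        n_event / (n_risk * (n_risk - n_event)), Inf))
    se <- ifelse(surv > 0, surv * sqrt(gw), 0)
    out <- tibble::tibble(time = event_times, n_risk = n_risk,
                          n_event = n_event, survival = surv, std_err = se)
  }
  structure(out,
            class = c("km_curve", class(out)),
            n0 = n0,
            censor_times = sort(t[!d]),
            max_time = max(t))
}

km_surv_at <- function(curve, horizon) {
  s <- vapply(horizon, function(h) {
    i <- which(curve$time <= h)
    if (length(i)) curve$survival[max(i)] else 1
  }, double(1))
  s
}

#' Actuarial death rate at a horizon
#'
#' Returns `100 * (1 - S(horizon))` from a Kaplan-Meier curve, with the
#' survival function taken right-continuous so that deaths occurring exactly
#' at the horizon count as dead. When the horizon lies beyond the last
#' observed follow-up time the last available estimate is returned and the
#' result carries an `extrapolated` attribute (with a warning).
#'
#' @param curve A [km_estimate()] result.
#' @param horizon Horizon in months (>= 0); may be a vector.
#' @return Death rate(s) as percentages in `[0, 100]`, with attribute
#'   `extrapolated` flagging horizons beyond follow-up.
#' @export
death_rate_at <- function(curve, horizon) {
  if (any(horizon < 0)) {
    abort("horizon must be >= 0", class = "reradscore_validation_error")
  }
  extrap <- horizon > attr(curve, "max_time")
  if (any(extrap)) {
    warn(sprintf(
      "horizon %g exceeds the last observed time %g; extrapolating the last available estimate",
      horizon[which(extrap)[1]], attr(curve, "max_time")))
  }
  out <- 100 * (1 - km_surv_at(curve, horizon))
  attr(out, "extrapolated") <- extrap
  out
}

#' Median survival from a Kaplan-Meier curve
#'
#' The smallest time at which the survival estimate drops to 0.5 or below.
#'
#' @param curve A [km_estimate()] result.
#' @return The median in months, or `NA` when the curve never reaches 0.5
#'   ("median not reached").
#' @export
median_survival <- function(curve) {
  i <- which(curve$survival <= 0.5)
  if (length(i)) curve$time[i[1]] else NA_real_
}

logrank_components <- function(t, d, g) {
  # g: factor; returns observed, expected, covariance over groups
  k <- nlevels(g)
  event_times <- sort(unique(t[d]))
  obs <- exp <- numeric(k)
  V <- matrix(0, k, k)
  for (s in event_times) {
    at_risk <- t >= s
    n <- sum(at_risk)
    nj <- tabulate(g[at_risk], nbins = k)
    dtot <- sum(t == s & d)
    dj <- tabulate(g[t == s & d], nbins = k)
    obs <- obs + dj
    exp <- exp + dtot * nj / n
    if (n > 1) {
      V <- V + dtot * (n - dtot) / (n - 1) *
        (diag(nj / n, k) - tcrossprod(nj / n))
    }
  }
  list(observed = obs, expected = exp, covariance = V, k = k)
}

#' k-group log-rank test
#'
#' The standard pooled log-rank test over all strata: observed and expected
#' deaths are accumulated across the distinct event times with the
#' hypergeometric covariance, and the chi-square statistic on k - 1 degrees
#' of freedom is referred to the asymptotic chi-square distribution.
#'
#' @param data Data frame with one row per patient.
#' @param group Grouping column (tidy evaluation).
#' @inheritParams km_estimate
#' @return An object of class `logrank_test`: a list with `chi_square`,
#'   `df`, `p_value`, `groups`, per-group `observed`/`expected` deaths, and
#'   `n`. See [glance.logrank_test()].
#' @export
logrank_test <- function(data, group, time = time_months, event = event) {
  t <- dplyr::pull(data, {{ time }})
  d <- as.logical(dplyr::pull(data, {{ event }}))
  g <- dplyr::pull(data, {{ group }})
  g <- factor(g)
  g <- droplevels(g)
  if (nlevels(g) < 2) {
    abort("log-rank test needs at least two non-empty groups",
          class = "reradscore_validation_error")
  }
  if (!any(d)) {
    abort("log-rank statistic is undefined with no events in any group",
          class = "reradscore_validation_error")
  }
  comp <- logrank_components(t, d, g)
  k <- comp$k
  oe <- (comp$observed - comp$expected)[-k]
  Vsub <- comp$covariance[-k, -k, drop = FALSE]
  # drop a redundant group; fall back to a pseudo-inverse if V is singular
  chi <- tryCatch(drop(t(oe) %*% solve(Vsub, oe)), error = function(e) {
    sv <- svd(Vsub)
    pos <- sv$d > max(sv$d) * 1e-10
    drop(t(oe) %*% sv$v[, pos, drop = FALSE] %*%
           ((t(sv$u[, pos, drop = FALSE]) %*% oe) / sv$d[pos]))
  })
  chi <- max(chi, 0)
  df <- k - 1
  structure(list(chi_square = chi, df = df,
                 p_value = pchisq(chi, df, lower.tail = FALSE),
                 groups = levels(g), n = as.integer(table(g)),
                 observed = comp$observed, expected = comp$expected),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test over %d groups (%s)\n", length(x$groups),
              paste(x$groups, collapse = ", ")))
  cat(sprintf("  chi-square = %.4f on %d df, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  invisible(x)
}

#' @describeIn logrank_test one-row tibble with the statistic, df and p-value.
#' @param x A `logrank_test` object.
#' @param ... Unused.
#' @export
glance.logrank_test <- function(x, ...) {
  tibble::tibble(chi_square = x$chi_square, df = x$df, p_value = x$p_value,
                 n_groups = length(x$groups), n = sum(x$n))
}

#' Pairwise two-group log-rank tests
#'
#' One two-group log-rank test per unordered pair of groups. By default the
#' p-values are not corrected for multiple testing (matching common practice
#' in small prognostic-factor studies); Bonferroni or Holm correction can be
#' requested.
#'
#' @inheritParams logrank_test
#' @param correction Multiplicity correction for the pairwise p-values.
#' @return A tibble with one row per pair: `group1`, `group2`, `chi_square`,
#'   `df`, `p_value`, and `p_adjusted` (equal to `p_value` when
#'   `correction = "none"`).
#' @export
pairwise_logrank <- function(data, group, time = time_months, event = event,
                             correction = c("none", "bonferroni", "holm")) {
  correction <- match.arg(correction)
  g <- factor(dplyr::pull(data, {{ group }}))
  g <- droplevels(g)
  levs <- levels(g)
  if (length(levs) < 2) {
    abort("need at least two non-empty groups", class = "reradscore_validation_error")
  }
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(pr) {
    sub <- data[g %in% pr, , drop = FALSE]
    res <- logrank_test(sub, {{ group }}, {{ time }}, {{ event }})
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   chi_square = res$chi_square, df = res$df,
                   p_value = res$p_value)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- if (correction == "none") out$p_value else
    p.adjust(out$p_value, method = correction)
  out
}
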