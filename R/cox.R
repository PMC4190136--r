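## Covariate encoding -------------------------------------------------------

kps_band <- function(kps) {
  factor(dplyr::case_when(
    is.na(kps) ~ NA_character_,
    kps <= 60 ~ "<=60",
    kps <= 80 ~ "70-80",
    TRUE ~ "90-100"
  ), levels = c("90-100", "70-80", "<=60"))
}

# Map a covariate (term) name to its raw columns and indicator matrix.
# "kps3" enters as two indicators (70-80, <=60 vs 90-100) handled jointly;
# "kps2"/"kps_le60" as a single <=60 indicator; logical columns as 0/1;
# character/factor columns as treatment contrasts against the first level.
encode_term <- function(data, term) {
  if (term %in% c("kps3", "kps")) {
    band <- kps_band(data$kps)
    return(list(raw = "kps",
                X = cbind(kps_70_80 = as.numeric(band == "70-80"),
                          kps_le60 = as.numeric(band == "<=60"))))
  }
  if (term %in% c("kps2", "kps_le60")) {
    return(list(raw = "kps",
                X = cbind(kps_le60 = as.numeric(data$kps <= 60))))
  }
  if (!term %in% names(data)) {
    abort(sprintf("covariate '%s' not found in the cohort", term),
          class = "reradscore_schema_error")
  }
  x <- data[[term]]
  if (is.logical(x)) {
    X <- cbind(as.numeric(x)); colnames(X) <- term
  } else if (is.numeric(x)) {
    X <- cbind(x); colnames(X) <- term
  } else {
    f <- factor(x)
    if (nlevels(f) < 2) {
      abort(sprintf("covariate '%s' has fewer than two levels", term),
            class = "reradscore_validation_error")
    }
    # treatment contrasts against the first level, NA rows kept
    X <- vapply(levels(f)[-1], function(l) as.numeric(x == l),
                double(length(x)))
    X <- matrix(X, ncol = nlevels(f) - 1,
                dimnames = list(NULL, paste0(term, "_", levels(f)[-1])))
  }
  list(raw = term, X = X)
}

encode_covariates <- function(data, covariates) {
  encs <- lapply(covariates, function(tm) encode_term(data, tm))
  X <- do.call(cbind, lapply(encs, `[[`, "X"))
  terms <- list()
  at <- 0
  for (i in seq_along(covariates)) {
    k <- ncol(encs[[i]]$X)
    terms[[covariates[i]]] <- colnames(X)[at + seq_len(k)]
    at <- at + k
  }
  list(X = X, terms = terms)
}

## Partial-likelihood engine -------------------------------------------------

# Breslow partial log-likelihood, score and observed information for
# right-censored data; tied event times share one risk set.
cox_lgh <- function(t, d, X, beta) {
  n <- length(t)
  p <- ncol(X)
  eta <- drop(X %*% beta)
  eta <- eta - max(eta)  # additive shift cancels in ll, U, I
  w <- exp(eta)
  first <- match(t, t)   # data sorted by time: first index of each tie block
  S0 <- rev(cumsum(rev(w)))[first]
  Xw <- X * w
  S1 <- matrix(0, n, p)
  for (j in seq_len(p)) S1[, j] <- rev(cumsum(rev(Xw[, j])))[first]
  di <- which(d)
  ll <- sum(eta[di]) - sum(log(S0[di]))
  U <- colSums(X[di, , drop = FALSE]) -
    colSums(S1[di, , drop = FALSE] / S0[di])
  I <- matrix(0, p, p)
  for (j in seq_len(p)) {
    for (k in j:p) {
      s2 <- rev(cumsum(rev(Xw[, j] * X[, k])))[first]
      val <- sum(s2[di] / S0[di] - S1[di, j] * S1[di, k] / S0[di]^2)
      I[j, k] <- val
      I[k, j] <- val
    }
  }
  list(ll = ll, U = U, I = I)
}

cox_newton <- function(t, d, X, max_iter = 50, tol = 1e-8) {
  ord <- order(t)
  t <- t[ord]; d <- d[ord]; X <- X[ord, , drop = FALSE]
  p <- ncol(X)
  beta <- rep(0, p)
  cur <- cox_lgh(t, d, X, beta)
  loglik_null <- cur$ll
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    step <- tryCatch(solve(cur$I, cur$U), error = function(e) NULL)
    if (is.null(step)) break
    nxt <- NULL
    for (h in 0:25) {  # step-halving keeps the likelihood ascending
      cand <- beta + step / 2^h
      trial <- cox_lgh(t, d, X, cand)
      if (is.finite(trial$ll) && trial$ll >= cur$ll - 1e-12) {
        nxt <- trial; beta <- cand; break
      }
    }
    if (is.null(nxt)) break
    delta <- nxt$ll - cur$ll
    cur <- nxt
    if (abs(delta) < tol) { converged <- TRUE; break }
  }
  if (any(abs(beta) > 15)) converged <- FALSE  # monotone likelihood
  covb <- tryCatch(solve(cur$I), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(covb), 0))
  names(beta) <- names(se) <- colnames(X)
  list(coef = beta, se = se, loglik = cur$ll, loglik_null = loglik_null,
       score = cur$U, information = cur$I, iterations = iter,
       converged = converged)
}

## User-facing fits ----------------------------------------------------------

#' Cox proportional-hazards regression
#'
#' Fits a Cox model by maximising the Breslow partial log-likelihood with
#' Newton-Raphson (step-halving, convergence when the log-likelihood change
#' falls below `tol`). Standard errors come from the observed information;
#' per-coefficient p-values are Wald. Analysis is complete-case over the
#' requested covariates. Multi-level covariates (KPS bands via the term name
#' `"kps3"`, or any character column) enter as joint indicator blocks.
#'
#' @param data A cohort tibble.
#' @param covariates Character vector of term names: logical or numeric
#'   cohort columns, a character column (expanded to treatment contrasts),
#'   `"kps3"` (performance-status bands 90-100 / 70-80 / <=60), or
#'   `"kps_le60"` (the dichotomy used by the point score).
#' @inheritParams km_estimate
#' @param max_iter,tol Newton-Raphson controls.
#' @return An object of class `rerad_cox`: coefficients (log hazard ratios),
#'   standard errors, Wald p-values, partial log-likelihoods of the fitted
#'   and null models, the term-to-column mapping, and convergence
#'   information. Use [tidy()] / [glance()] for tibble summaries.
#' @export
cox_fit <- function(data, covariates, time = time_months, event = event,
                    max_iter = 50, tol = 1e-8) {
  t <- dplyr::pull(data, {{ time }})
  d <- as.logical(dplyr::pull(data, {{ event }}))
  enc <- encode_covariates(data, covariates)
  keep <- stats::complete.cases(enc$X) & !is.na(t) & !is.na(d)
  X <- enc$X[keep, , drop = FALSE]
  t <- t[keep]; d <- d[keep]
  if (nrow(X) == 0) {
    abort("no complete cases for the requested covariates",
          class = "reradscore_validation_error")
  }
  const <- colnames(X)[apply(X, 2, function(col) length(unique(col)) < 2)]
  if (length(const)) {
    abort(sprintf("covariate column '%s' is constant among complete cases",
                  const[1]), class = "reradscore_validation_error")
  }
  fit <- cox_newton(t, d, X, max_iter = max_iter, tol = tol)
  z <- fit$coef / fit$se
  structure(list(
    covariates = covariates,
    terms = enc$terms,
    coef = fit$coef, se = fit$se, z = z,
    wald_p = 2 * stats::pnorm(-abs(z)),
    loglik = fit$loglik, loglik_null = fit$loglik_null,
    score = fit$score, information = fit$information,
    iterations = fit$iterations, converged = fit$converged,
    n = length(t), n_events = sum(d),
    retained = covariates,
    elimination = NULL
  ), class = "rerad_cox")
}

#' @export
print.rerad_cox <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit: %d patients, %d events\n",
              x$n, x$n_events))
  if (length(x$coef)) print(tidy(x)) else cat("  (null model)\n")
  cat(sprintf("  partial log-likelihood %.4f (null %.4f), %s in %d iterations\n",
              x$loglik, x$loglik_null,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  if (!is.null(x$elimination)) {
    cat(sprintf("  retained after backward elimination: %s\n",
                if (length(x$retained)) paste(x$retained, collapse = ", ")
                else "(none)"))
  }
  invisible(x)
}

#' Tidy a Cox fit
#'
#' @param x A [cox_fit()] object.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate` (log hazard ratio),
#'   `std.error`, `statistic` (Wald z), `p.value`, and `hazard_ratio`.
#' @export
tidy.rerad_cox <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef),
                 std.error = unname(x$se), statistic = unname(x$z),
                 p.value = unname(x$wald_p),
                 hazard_ratio = exp(unname(x$coef)))
}

#' @describeIn tidy.rerad_cox one-row model summary with log-likelihoods,
#'   the likelihood-ratio test against the null model, and convergence.
#' @export
glance.rerad_cox <- function(x, ...) {
  lr <- 2 * (x$loglik - x$loglik_null)
  df <- length(x$coef)
  tibble::tibble(n = x$n, n_events = x$n_events,
                 loglik = x$loglik, loglik_null = x$loglik_null,
                 lr_statistic = lr, lr_df = df,
                 lr_p = if (df > 0) pchisq(lr, df, lower.tail = FALSE) else NA_real_,
                 iterations = x$iterations, converged = x$converged)
}

## Screening and selection ---------------------------------------------------

screen_grouping <- function(data, factor_name) {
  if (factor_name %in% c("kps3", "kps")) return(kps_band(data$kps))
  if (factor_name %in% c("kps2", "kps_le60")) {
    return(factor(ifelse(data$kps <= 60, "<=60", "70-100"),
                  levels = c("70-100", "<=60")))
  }
  x <- data[[factor_name]]
  if (is.logical(x)) factor(ifelse(x, "yes", "no"), levels = c("no", "yes"))
  else factor(x)
}

#' Univariate log-rank screen of prognostic factors
#'
#' Tests each candidate factor with a log-rank test pooled over its levels
#' (on the records non-missing for that factor) and carries forward those
#' with p strictly below the threshold, the conventional entry rule for a
#' subsequent multivariate Cox model. Factors with fewer than two non-empty
#' levels, or with no events among their non-missing records, are excluded
#' with a warning.
#'
#' @inheritParams cox_fit
#' @param factors Character vector of factor names (see [cox_fit()] for the
#'   special KPS terms). Defaults to `"kps3"` plus every logical or
#'   character column other than `id`.
#' @param threshold Carry-forward threshold on the log-rank p-value
#'   (strict `<`).
#' @return A tibble of class `rerad_screen`, one row per factor:
#'   `factor_name`, `n_used`, `n_levels`, `chi_square`, `df`, `p_value`,
#'   `carried_forward`. The threshold is carried as an attribute.
#' @export
univariate_screen <- function(data, factors = NULL, threshold = 0.1,
                              time = time_months, event = event) {
  if (is.null(factors)) {
    auto <- names(data)[vapply(data, function(x) is.logical(x) ||
                                 is.character(x), logical(1))]
    auto <- setdiff(auto, c("id", "event"))
    factors <- c(if ("kps" %in% names(data)) "kps3", auto)
  }
  t_all <- dplyr::pull(data, {{ time }})
  d_all <- as.logical(dplyr::pull(data, {{ event }}))
  rows <- purrr::map(factors, function(fac) {
    g <- screen_grouping(data, fac)
    ok <- !is.na(g)
    gg <- droplevels(g[ok])
    row <- tibble::tibble(factor_name = fac, n_used = sum(ok),
                          n_levels = nlevels(gg), chi_square = NA_real_,
                          df = NA_integer_, p_value = NA_real_)
    if (nlevels(gg) < 2) {
      warn(sprintf("factor '%s' has fewer than two non-empty levels; excluded",
                   fac))
      return(row)
    }
    if (!any(d_all[ok])) {
      warn(sprintf("factor '%s' has no events among non-missing records; excluded",
                   fac))
      return(row)
    }
    sub <- tibble::tibble(.time = t_all[ok], .event = d_all[ok], .group = gg)
    res <- logrank_test(sub, .group, .time, .event)
    row$chi_square <- res$chi_square
    row$df <- as.integer(res$df)
    row$p_value <- res$p_value
    row
  })
  out <- dplyr::bind_rows(rows)
  out$carried_forward <- !is.na(out$p_value) & out$p_value < threshold
  structure(out, class = c("rerad_screen", class(out)), threshold = threshold)
}

#' Backward elimination for the Cox model
#'
#' Starting from the full model, repeatedly refits and removes the term with
#' the largest likelihood-ratio removal p-value (the p-value of the model
#' without the term against the model with it) as long as that p-value is at
#' or above `removal_p`; elimination stops when every remaining term has
#' removal p below the threshold. Multi-column terms (e.g. KPS bands) are
#' removed or kept jointly. The complete-case set is fixed once, on the full
#' starting covariate set, so all nested comparisons use the same records.
#'
#' @inheritParams cox_fit
#' @param start_covariates Terms in the full model.
#' @param removal_p Removal threshold (term removed while its LR p-value is
#'   `>= removal_p`).
#' @return The final `rerad_cox` fit with `retained` set to the surviving
#'   terms and an `elimination` tibble recording each removal step
#'   (`step`, `removed`, `lr_statistic`, `df`, `p_value`). Removing every
#'   term is allowed and yields a null-model fit with a warning.
#' @export
backward_eliminate <- function(data, start_covariates, removal_p = 0.10,
                               time = time_months, event = event) {
  enc <- encode_covariates(data, start_covariates)
  t_all <- dplyr::pull(data, {{ time }})
  d_all <- as.logical(dplyr::pull(data, {{ event }}))
  keep <- stats::complete.cases(enc$X) & !is.na(t_all) & !is.na(d_all)
  cc <- data[keep, , drop = FALSE]
  current <- start_covariates
  steps <- list()
  fit <- cox_fit(cc, current, {{ time }}, {{ event }})
  while (length(current) > 0) {
    drops <- purrr::map(current, function(tm) {
      reduced_terms <- setdiff(current, tm)
      ll_red <- if (length(reduced_terms)) {
        cox_fit(cc, reduced_terms, {{ time }}, {{ event }})$loglik
      } else {
        fit$loglik_null
      }
      df <- length(fit$terms[[tm]])
      stat <- max(2 * (fit$loglik - ll_red), 0)
      tibble::tibble(removed = tm, lr_statistic = stat, df = df,
                     p_value = pchisq(stat, df, lower.tail = FALSE))
    })
    drops <- dplyr::bind_rows(drops)
    worst <- drops[which.max(drops$p_value), ]
    if (worst$p_value < removal_p) break
    steps[[length(steps) + 1]] <-
      dplyr::mutate(worst, step = length(steps) + 1, .before = 1)
    current <- setdiff(current, worst$removed)
    if (length(current) == 0) {
      warn("backward elimination removed every covariate; returning the null model")
      fit <- structure(list(
        covariates = character(), terms = list(),
        coef = setNames(numeric(0), character(0)),
        se = setNames(numeric(0), character(0)),
        z = numeric(0), wald_p = numeric(0),
        loglik = fit$loglik_null, loglik_null = fit$loglik_null,
        score = numeric(0), information = matrix(0, 0, 0),
        iterations = 0L, converged = TRUE,
        n = nrow(cc), n_events = sum(as.logical(dplyr::pull(cc, {{ event }}))),
        retained = character(), elimination = NULL
      ), class = "rerad_cox")
      break
    }
    fit <- cox_fit(cc, current, {{ time }}, {{ event }})
  }
  fit$retained <- current
  fit$elimination <- if (length(steps)) dplyr::bind_rows(steps) else
    tibble::tibble(step = integer(), removed = character(),
                   lr_statistic = double(), df = integer(), p_value = double())
  fit
}
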