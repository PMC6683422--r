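#' Multiple imputation of missing 12-week outcomes
#'
#' Chained-equation regression imputation with predictive-mean-matching
#' (PMM) draws. Each incomplete 12-week outcome (`phq9_12wk`,
#' `eq5d_12wk`) is imputed from arm, age, sex, both baseline scores, and
#' the current values of the other 12-week outcome: coefficients are
#' drawn from their approximate posterior, predicted means computed for
#' the missing records, and each missing record receives the observed
#' value of one of its `k` nearest donors by predicted mean. The chain is
#' iterated a few cycles and repeated `m` times from independent starts.
#' A fully observed cohort passes through unchanged (all `m` datasets
#' identical to the input).
#'
#' Downstream estimates over the `m` completed datasets are pooled with
#' Rubin's rules via [pool_rubin()].
#'
#' @param cohort A cohort tibble; missingness confined to the 12-week
#'   outcomes.
#' @param m Number of completed datasets (>= 1), default 20.
#' @param seed Integer seed.
#' @param n_cycles Chained-equation cycles per dataset.
#' @param k Donor pool size for PMM.
#' @return An object of class `imputed_set`: list with `datasets` (list of
#'   `m` completed tibbles), `m`, `method`, `seed`.
#' @export
impute_missing <- function(cohort, m = 20, seed = 1L, n_cycles = 5, k = 5) {
  if (m < 1) abort_field("m", "must be >= 1")
  m <- as.integer(m)
  targets <- c("phq9_12wk", "eq5d_12wk")
  base_cols <- c("age", "phq9_baseline", "eq5d_baseline")
  if (anyNA(cohort[, base_cols]) || anyNA(cohort$sex) ||
      anyNA(cohort$arm)) {
    stop("missingness must be confined to 12-week outcomes", call. = FALSE)
  }
  miss <- lapply(targets, function(v) which(is.na(cohort[[v]])))
  names(miss) <- targets
  for (v in targets) {
    if (length(miss[[v]]) == nrow(cohort) && nrow(cohort) > 0) {
      stop(sprintf("'%s' is 100%% missing; cannot impute", v), call. = FALSE)
    }
  }
  if (all(lengths(miss) == 0)) {
    return(new_imputed_set(rep(list(cohort), m), m, seed))
  }
  multi_arm <- length(unique(cohort$arm)) > 1
  multi_sex <- length(unique(cohort$sex)) > 1
  rhs <- c(if (multi_arm) "arm", base_cols, if (multi_sex) "sex")
  datasets <- with_seed(seed, lapply(seq_len(m), function(i) {
    dat <- cohort
    # initial fill: random draws from the observed values
    for (v in targets) {
      if (length(miss[[v]])) {
        obs <- dat[[v]][-miss[[v]]]
        dat[[v]][miss[[v]]] <- sample(obs, length(miss[[v]]),
                                      replace = TRUE)
      }
    }
    for (cycle in seq_len(n_cycles)) {
      for (v in targets) {
        idx <- miss[[v]]
        if (length(idx) == 0) next
        other <- setdiff(targets, v)
        form <- as.formula(paste(v, "~",
                                 paste(c(rhs, other), collapse = " + ")))
        obs_dat <- dat[-idx, ]
        fit <- lm(form, data = obs_dat)
        X_obs <- model.matrix(fit)
        X_mis <- model.matrix(stats::delete.response(stats::terms(fit)),
                              data = dat[idx, ])
        beta <- coef(fit)
        # posterior draw of the coefficients
        V <- vcov(fit)
        dfres <- fit$df.residual
        sig2 <- sum(fit$residuals^2) / dfres
        sig2_star <- sig2 * dfres / rchisq(1, dfres)
        beta_star <- beta + drop(t(chol(V * sig2_star / sig2)) %*%
                                   rnorm(length(beta)))
        pred_obs <- drop(X_obs %*% beta)
        pred_mis <- drop(X_mis %*% beta_star)
        # type-1 PMM: match draws-based predictions for the missing to
        # OLS predictions for the observed, sample one of k donors
        ord <- order(pred_obs)
        pred_sorted <- pred_obs[ord]
        y_sorted <- obs_dat[[v]][ord]
        n_obs <- length(pred_sorted)
        pos <- findInterval(pred_mis, pred_sorted)
        donors <- vapply(seq_along(idx), function(j) {
          lo <- max(1L, pos[j] - k); hi <- min(n_obs, pos[j] + k)
          cand <- lo:hi
          cand <- cand[order(abs(pred_sorted[cand] - pred_mis[j]))]
          cand <- cand[seq_len(min(k, length(cand)))]
          y_sorted[sample(cand, 1L)]
        }, numeric(1))
        dat[[v]][idx] <- if (is.integer(dat[[v]])) as.integer(donors)
        else donors
      }
    }
    dat
  }))
  new_imputed_set(datasets, m, seed)
}

new_imputed_set <- function(datasets, m, seed) {
  structure(list(datasets = datasets, m = m, method = "pmm", seed = seed),
            class = "imputed_set")
}

#' @export
print.imputed_set <- function(x, ...) {
  cat(sprintf("<imputed_set> m = %d completed datasets (%s), %d records\n",
              x$m, x$method, nrow(x$datasets[[1]])))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.imputed_set <- function(x, ...) {
  tibble::tibble(m = x$m, method = x$method,
                 n = nrow(x$datasets[[1]]), seed = x$seed)
}

#' Pool estimates across imputed datasets by Rubin's rules
#'
#' Point estimate: mean of the per-imputation estimates. Total variance:
#' mean within-imputation variance plus `(1 + 1/m)` times the
#' between-imputation variance of the estimates.
#'
#' @param estimates Numeric vector of per-imputation point estimates.
#' @param variances Numeric vector of per-imputation squared standard
#'   errors.
#' @return A one-row tibble with `estimate`, `within`, `between`, `total`,
#'   `se`, `m`.
#' @export
pool_rubin <- function(estimates, variances) {
  stopifnot(length(estimates) == length(variances), length(estimates) >= 1)
  m <- length(estimates)
  est <- mean(estimates)
  within <- mean(variances)
  between <- if (m > 1) var(estimates) else 0
  total <- within + (1 + 1 / m) * between
  tibble::tibble(estimate = est, within = within, between = between,
                 total = total, se = sqrt(total), m = m)
}
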