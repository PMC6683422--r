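# Identity-link gamma GLM fitted by IRLS with step-halving.
#
# Identity link keeps the linear cost-predictor relation but can propose
# non-positive fitted means during iteration; each update is step-halved
# until all fitted means stay above a 1e-6 floor. Convergence is declared
# on relative deviance change below `tol`.
gamma_identity_glm <- function(X, y, tol = 1e-8, maxit = 100) {
  if (any(y <= 0)) {
    stop("non-positive cost in gamma stratum; filter to service users first",
         call. = FALSE)
  }
  n <- length(y); p <- ncol(X)
  beta <- qr.coef(qr(X), y)
  if (anyNA(beta)) stop("rank-deficient design in cost model", call. = FALSE)
  mu <- drop(X %*% beta)
  if (any(mu <= 0)) {
    # shrink toward the intercept-only fit until all means are positive
    beta0 <- c(mean(y), rep(0, p - 1))
    for (s in 1:50) {
      beta <- beta0 + 0.5^s * (beta - beta0)
      mu <- drop(X %*% beta)
      if (all(mu > 1e-6)) break
    }
  }
  dev <- function(mu) 2 * sum((y - mu) / mu - log(y / mu))
  d_old <- dev(mu)
  trace <- numeric(0)
  for (it in seq_len(maxit)) {
    w <- 1 / mu^2
    fit <- stats::lm.wfit(X, y, w)
    beta_new <- fit$coefficients
    step <- 1
    repeat {
      beta_try <- beta + step * (beta_new - beta)
      mu_try <- drop(X %*% beta_try)
      if (all(mu_try > 1e-6) || step < 1e-10) break
      step <- step / 2
    }
    mu_try <- pmax(mu_try, 1e-6)
    d_new <- dev(mu_try)
    trace <- c(trace, d_new)
    beta <- beta_try; mu <- mu_try
    if (abs(d_new - d_old) < tol * (abs(d_new) + 0.1)) {
      phi <- sum(((y - mu) / mu)^2) / (n - p)
      xtwx <- crossprod(X, X / mu^2)
      return(list(coefficients = beta, vcov = phi * solve(xtwx),
                  fitted = mu, deviance = d_new, dispersion = phi,
                  iterations = it, converged = TRUE))
    }
    d_old <- d_new
  }
  stop(sprintf(
    "gamma GLM did not converge in %d iterations; deviance trace: %s",
    maxit, paste(signif(utils::tail(trace, 5), 6), collapse = ", ")),
    call. = FALSE)
}

as_dataset_list <- function(data) {
  if (inherits(data, "imputed_set")) data$datasets else list(data)
}

new_arm_adjusted <- function(estimates, quantity, model, covariates,
                             diagnostics, m) {
  structure(list(estimates = estimates, quantity = quantity, model = model,
                 covariates = covariates, diagnostics = diagnostics, m = m),
            class = "arm_adjusted")
}

#' @export
print.arm_adjusted <- function(x, ...) {
  cat(sprintf("<arm_adjusted> %s via %s (covariates: %s)%s\n", x$quantity,
              x$model, paste(x$covariates, collapse = ", "),
              if (x$m > 1) sprintf(", Rubin-pooled over m = %d", x$m) else ""))
  print(x$estimates)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.arm_adjusted <- function(x, ...) x$estimates

#' @exportS3Method generics::glance
glance.arm_adjusted <- function(x, ...) {
  tibble::tibble(quantity = x$quantity, model = x$model,
                 m = x$m, !!!x$diagnostics)
}

# linear-combination predictions at pooled covariate values, per arm
predict_at_pooled <- function(beta, V, X_template, arms, arm_var = "arm") {
  purrr::map_dfr(arms, function(a) {
    row <- X_template
    acol <- paste0(arm_var, a)
    row[grep(paste0("^", arm_var), names(row))] <- 0
    if (acol %in% names(row)) row[acol] <- 1
    est <- sum(row * beta)
    se <- sqrt(drop(t(row) %*% V %*% row))
    tibble::tibble(arm = a, estimate = est, se = se)
  })
}

#' Covariate-adjusted 12-week outcome means per arm
#'
#' Ordinary least squares of the 12-week score on arm indicators plus the
#' matching baseline score; arm estimates are model predictions at the
#' pooled baseline mean (recycled-population standardization), so arms
#' are compared at identical baseline severity. For an [impute_missing()]
#' result the fit is repeated on every completed dataset and pooled by
#' Rubin's rules.
#'
#' @param data A cohort tibble (complete 12-week outcomes, or rows with
#'   missing outcomes are dropped) or an `imputed_set`.
#' @param outcome `"phq9_12wk"` or `"eq5d_12wk"`.
#' @return An `arm_adjusted` object; `tidy()` gives the per-arm tibble
#'   (`arm`, `estimate`, `se`).
#' @export
fit_outcome_ols <- function(data, outcome = c("phq9_12wk", "eq5d_12wk")) {
  outcome <- match.arg(outcome)
  baseline <- sub("_12wk", "_baseline", outcome)
  datasets <- as_dataset_list(data)
  arms <- if (is.factor(datasets[[1]]$arm)) levels(datasets[[1]]$arm)
  else unique(as.character(datasets[[1]]$arm))
  if (any(table(factor(datasets[[1]]$arm, levels = arms)) == 0)) {
    empty <- arms[table(factor(datasets[[1]]$arm, levels = arms)) == 0]
    stop(sprintf("arm '%s' has no records", empty[1]), call. = FALSE)
  }
  per_fit <- lapply(datasets, function(dat) {
    dat <- dat[!is.na(dat[[outcome]]), ]
    dat$arm <- factor(dat$arm, levels = arms)
    if (any(table(dat$arm) == 0)) {
      stop(sprintf("arm '%s' has no observed %s",
                   arms[table(dat$arm) == 0][1], outcome), call. = FALSE)
    }
    form <- as.formula(paste(outcome, "~ arm +", baseline))
    fit <- lm(form, data = dat)
    template <- c("(Intercept)" = 1,
                  setNames(rep(0, length(arms) - 1),
                           paste0("arm", arms[-1])),
                  setNames(mean(dat[[baseline]]), baseline))
    template <- template[names(coef(fit))]
    preds <- predict_at_pooled(coef(fit), vcov(fit), template, arms)
    list(preds = preds, sigma = summary(fit)$sigma)
  })
  est <- pool_arm_estimates(per_fit, arms)
  new_arm_adjusted(
    est, quantity = outcome, model = "ols",
    covariates = c("arm", baseline),
    diagnostics = list(sigma = mean(vapply(per_fit, `[[`, numeric(1),
                                           "sigma"))),
    m = length(datasets)
  )
}

pool_arm_estimates <- function(per_fit, arms) {
  purrr::map_dfr(arms, function(a) {
    ests <- vapply(per_fit, function(f) {
      f$preds$estimate[f$preds$arm == a]
    }, numeric(1))
    vars <- vapply(per_fit, function(f) {
      f$preds$se[f$preds$arm == a]^2
    }, numeric(1))
    pooled <- pool_rubin(ests, vars)
    tibble::tibble(arm = a, estimate = pooled$estimate, se = pooled$se)
  })
}

#' Covariate-adjusted sector cost means per arm (gamma GLM, identity link)
#'
#' Fits an identity-link gamma GLM of the period cost among service users
#' (positive costs only — non-use is handled by the decision tree, not
#' the GLM) on arm indicators, age, sex, and baseline PHQ-9. Arm
#' estimates are predictions at the pooled covariate means of the
#' stratum. Fitting is IRLS with step-halving and a floor on fitted
#' means; non-convergence after 100 iterations errors with the deviance
#' trace.
#'
#' @param data A cohort tibble or `imputed_set`.
#' @param sector `"physician"`, `"outpatient"`, or `"inpatient"`.
#' @param period `"year"` (post-randomization year, default), `"pre"`,
#'   `"post"`, or `"late"`.
#' @param covariates Adjustment covariates besides arm.
#' @return An `arm_adjusted` object with per-arm `estimate`, `se`,
#'   `n_users`.
#' @export
fit_cost_glm <- function(data, sector, period = "year",
                         covariates = c("age", "sex", "phq9_baseline")) {
  sector <- match.arg(sector, sector_levels())
  datasets <- as_dataset_list(data)
  arms <- levels(droplevels(factor(datasets[[1]]$arm)))
  per_fit <- lapply(datasets, function(dat) {
    cols <- cost_column(sector, period_cols(period))
    y_all <- rowSums(as.matrix(dat[, cols, drop = FALSE]))
    keep <- !is.na(y_all) & y_all > 0
    dat <- dat[keep, ]
    y <- y_all[keep]
    dat$arm <- factor(dat$arm, levels = arms)
    if (any(table(dat$arm) == 0)) {
      stop(sprintf("arm '%s' has no %s users in period '%s'",
                   arms[table(dat$arm) == 0][1], sector, period),
           call. = FALSE)
    }
    # constant covariates in the stratum carry no information and would
    # make the design rank-deficient
    covs <- covariates[vapply(covariates, function(v) {
      length(unique(dat[[v]])) > 1
    }, logical(1))]
    if (length(covs) == 0) covs <- "1"
    form <- as.formula(paste("~ arm +", paste(covs, collapse = " + ")))
    X <- model.matrix(form, data = dat)
    fit <- gamma_identity_glm(X, y)
    template <- colMeans(X)
    names(template) <- colnames(X)
    preds <- predict_at_pooled(fit$coefficients, fit$vcov, template, arms)
    preds$n_users <- as.integer(table(dat$arm)[preds$arm])
    list(preds = preds, deviance = fit$deviance,
         iterations = fit$iterations, dispersion = fit$dispersion)
  })
  est <- pool_arm_estimates(per_fit, arms)
  est$n_users <- per_fit[[1]]$preds$n_users
  new_arm_adjusted(
    est, quantity = paste0("cost_", sector, "_", period), model = "gamma_glm",
    covariates = c("arm", covariates),
    diagnostics = list(
      deviance = mean(vapply(per_fit, `[[`, numeric(1), "deviance")),
      iterations = max(vapply(per_fit, `[[`, numeric(1), "iterations")),
      dispersion = mean(vapply(per_fit, `[[`, numeric(1), "dispersion"))
    ),
    m = length(datasets)
  )
}

#' Adjusted sector user-mean costs per arm and period
#'
#' Composes [fit_cost_glm()] over sectors for one period, with a raw-mean
#' fallback (flagged in `method`) for any arm whose user stratum is too
#' small to adjust (< `min_users`) and a zero placeholder for arms with
#' no users of a sector (their decision-tree branch probability is then
#' zero as well).
#'
#' @inheritParams fit_cost_glm
#' @param min_users Minimum users per arm for the GLM (default 10).
#' @return A tibble with `arm`, `sector`, `estimate`, `se`, `n_users`,
#'   `method` (`"glm"`, `"raw"`, or `"zero"`).
#' @export
adjusted_arm_means <- function(data, period = "year", min_users = 10,
                               covariates = c("age", "sex",
                                              "phq9_baseline")) {
  datasets <- as_dataset_list(data)
  dat1 <- datasets[[1]]
  arms <- levels(droplevels(factor(dat1$arm)))
  cols_of <- function(sector) cost_column(sector, period_cols(period))
  user_counts <- purrr::map_dfr(sector_levels(), function(s) {
    y <- rowSums(as.matrix(dat1[, cols_of(s), drop = FALSE]))
    tibble::tibble(
      sector = s, arm = arms,
      n_users = vapply(arms, function(a) {
        sum(!is.na(y) & y > 0 & dat1$arm == a)
      }, numeric(1))
    )
  })
  any_user <- user_counts |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(total = sum(.data$n_users), .groups = "drop")
  if (any(any_user$total == 0)) {
    stop(sprintf("arm '%s' has no service users in period '%s'",
                 any_user$arm[any_user$total == 0][1], period),
         call. = FALSE)
  }
  purrr::map_dfr(sector_levels(), function(s) {
    counts <- user_counts[user_counts$sector == s, ]
    glm_arms <- counts$arm[counts$n_users >= min_users]
    small_arms <- counts$arm[counts$n_users > 0 & counts$n_users < min_users]
    zero_arms <- counts$arm[counts$n_users == 0]
    out <- list()
    if (length(glm_arms) >= 1) {
      sub <- lapply(datasets, function(d) d[d$arm %in% glm_arms, ])
      sub_data <- if (inherits(data, "imputed_set")) {
        new_imputed_set(sub, length(sub), NA_integer_)
      } else {
        sub[[1]]
      }
      fit <- fit_cost_glm(sub_data, s, period, covariates)
      out$glm <- dplyr::mutate(tidy(fit), sector = s, method = "glm")
    }
    if (length(small_arms) >= 1) {
      out$raw <- purrr::map_dfr(small_arms, function(a) {
        vals <- lapply(datasets, function(d) {
          y <- rowSums(as.matrix(d[d$arm == a, cols_of(s), drop = FALSE]))
          y <- y[!is.na(y) & y > 0]
          c(mean(y), if (length(y) > 1) var(y) / length(y) else 0)
        })
        pooled <- pool_rubin(vapply(vals, `[[`, numeric(1), 1),
                             vapply(vals, `[[`, numeric(1), 2))
        tibble::tibble(arm = a, estimate = pooled$estimate, se = pooled$se,
                       n_users = counts$n_users[counts$arm == a],
                       sector = s, method = "raw")
      })
    }
    if (length(zero_arms) >= 1) {
      out$zero <- tibble::tibble(arm = zero_arms, estimate = 0, se = 0,
                                 n_users = 0L, sector = s, method = "zero")
    }
    dplyr::bind_rows(out)
  }) |>
    dplyr::mutate(arm = factor(.data$arm, levels = arms),
                  sector = factor(.data$sector, levels = sector_levels())) |>
    dplyr::arrange(.data$sector, .data$arm)
}
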