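# run expr under a temporary RNG state so generators are reproducible
# without clobbering the caller's stream
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# latent copula correlation among (phq9_0, phq9_12, eq5d_0, eq5d_12)
copula_chol <- function(cor_stability, cor_cross) {
  s <- cor_stability; cc <- cor_cross; l <- cc * s
  r <- matrix(c(1, s, cc, l,
                s, 1, l, cc,
                cc, l, 1, s,
                l, cc, s, 1), 4, 4)
  ch <- tryCatch(chol(r), error = function(e) NULL)
  if (is.null(ch)) {
    abort_field("cor_cross/cor_stability",
                "implied latent correlation matrix is not positive definite")
  }
  ch
}

generate_arm <- function(profile, config) {
  n <- profile$n
  if (n == 0L) return(empty_cohort())
  z <- matrix(rnorm(4L * n), n, 4L) %*%
    copula_chol(config$cor_stability, config$cor_cross)

  cal_p0 <- calibrate_phq9(profile$phq9_baseline_mean,
                           sd = profile$phq9_baseline_sd,
                           p_gt10 = profile$depressed_fraction,
                           lo = profile$phq9_floor)
  cal_p12 <- calibrate_phq9(profile$phq9_12wk_mean,
                            sd = profile$phq9_12wk_sd)
  cal_e0 <- calibrate_utility(profile$eq5d_baseline_mean,
                              profile$eq5d_baseline_sd)
  cal_e12 <- calibrate_utility(profile$eq5d_12wk_mean,
                               profile$eq5d_12wk_sd)

  phq0 <- z_to_phq9(z[, 1], cal_p0)
  phq12 <- z_to_phq9(z[, 2], cal_p12)
  eq0 <- z_to_utility(z[, 3], cal_e0)
  eq12 <- z_to_utility(z[, 4], cal_e12)

  age <- pmin(pmax(rnorm(n, profile$age_mean, profile$age_sd), 18), 100)
  sex <- ifelse(runif(n) < profile$female, "female", "male")

  mix <- unclass(profile$service_mix)
  combo <- sample(combo_levels(), n, replace = TRUE, prob = mix)
  pre_combo <- sample(combo_levels(), n, replace = TRUE, prob = mix)

  out <- tibble::tibble(
    id = NA_character_,
    arm = profile$arm_label,
    age = age, sex = sex,
    phq9_baseline = phq0, phq9_12wk = phq12,
    eq5d_baseline = eq0, eq5d_12wk = eq12,
    service_combo = factor(combo, levels = combo_levels())
  )

  combo_has <- function(combo, sector) {
    switch(sector,
           physician = combo != "none",
           outpatient = combo %in% c("phys_out", "phys_out_inp"),
           inpatient = combo %in% c("phys_inp", "phys_out_inp"))
  }
  rho <- config$cor_cost_outcome
  zp <- z[, 1]
  for (period in period_levels()) {
    use_combo <- if (period == "pre") pre_combo else combo
    for (sector in sector_levels()) {
      par <- profile$sector_costs[
        profile$sector_costs$sector == sector &
          profile$sector_costs$period == period, ]
      zc <- rho * zp + sqrt(1 - rho^2) * rnorm(n)
      cost <- z_to_gamma(zc, par$mean, par$sd)
      cost[!combo_has(use_combo, sector)] <- 0
      out[[cost_column(sector, period)]] <- cost
    }
  }
  if (profile$missing_rate > 0) {
    miss <- missing_indices(out$phq9_baseline, profile$missing_rate,
                            config$missing_mechanism)
    out$phq9_12wk[miss] <- NA_integer_
    out$eq5d_12wk[miss] <- NA_real_
  }
  out
}

empty_cohort <- function() {
  out <- tibble::tibble(
    id = character(), arm = character(), age = numeric(), sex = character(),
    phq9_baseline = integer(), phq9_12wk = integer(),
    eq5d_baseline = numeric(), eq5d_12wk = numeric(),
    service_combo = factor(character(), levels = combo_levels())
  )
  for (col in cost_columns()) out[[col]] <- numeric()
  out
}

#' Generate a synthetic patient-level cohort
#'
#' Draws a complete trial cohort under a [cohort_config()]: for each arm,
#' PHQ-9 and EQ-5D-5L at baseline and 12 weeks from calibrated
#' censored-normal margins linked by a Gaussian copula (worse depression
#' goes with lower utility), a service-use combination from the arm's
#' [service_mix()], and per-sector per-period costs from gamma
#' distributions parameterized by (mean, s.d.) among users — zero for
#' sectors absent from the drawn combination. High-cost outliers are then
#' injected into physician/outpatient observations at the configured rate,
#' and 12-week outcomes are set missing at each profile's rate under the
#' configured mechanism. Identical config and seed give identical output.
#'
#' @param config A [cohort_config()].
#' @param seed Integer; defaults to `config$seed`.
#' @return A tibble, one row per participant, with arm, demographics,
#'   outcome scores, `service_combo`, and nine `cost_<sector>_<period>`
#'   columns (periods `pre`, `post`, `late`).
#' @examples
#' cfg <- cohort_config(profiles = arm_profiles("all", missing_rate = 0))
#' small <- cfg
#' small$profiles <- lapply(small$profiles, function(p) { p$n <- 50L; p })
#' generate_cohort(small, seed = 1)
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    out <- purrr::map_dfr(config$profiles, generate_arm, config = config)
    if (nrow(out) > 0) {
      out$id <- sprintf("P%05d", seq_len(nrow(out)))
      out$arm <- factor(out$arm, levels = unique(out$arm))
      if (config$outlier_rate > 0) {
        out <- inject_outliers_impl(out, config$outlier_rate,
                                    config$outlier_multiplier)
      }
    }
    out
  })
}

missing_indices <- function(phq0, rate, mechanism) {
  n <- length(phq0)
  if (rate == 0) return(rep(FALSE, n))
  if (mechanism == "MCAR") return(runif(n) < rate)
  # MAR on baseline severity: logistic in PHQ-9, intercept solved so the
  # expected missing fraction equals `rate`
  slope <- 0.15
  ctr <- phq0 - mean(phq0)
  a <- uniroot(function(a) mean(plogis(a + slope * ctr)) - rate,
               c(-30, 30))$root
  runif(n) < plogis(a + slope * ctr)
}

#' Set 12-week outcomes missing
#'
#' Removes `phq9_12wk` and `eq5d_12wk` jointly for a random subset of
#' records (dropout semantics). Under `"MCAR"` every record is equally
#' likely; under `"MAR_on_baseline"` the missingness probability increases
#' logistically with baseline PHQ-9 while keeping the expected overall
#' fraction equal to `rate`. Baseline fields are never removed.
#'
#' @param cohort A cohort tibble.
#' @param rate Expected missing fraction, in \[0,1).
#' @param mechanism `"MCAR"` or `"MAR_on_baseline"`.
#' @param seed Integer seed.
#' @return The cohort with missing 12-week outcomes.
#' @export
inject_missingness <- function(cohort, rate,
                               mechanism = c("MCAR", "MAR_on_baseline"),
                               seed = 1L) {
  mechanism <- match.arg(mechanism)
  check_number(rate, "rate", lower = 0, upper = 1, strict_upper = TRUE)
  if (rate == 0 || nrow(cohort) == 0) return(cohort)
  with_seed(seed, {
    miss <- missing_indices(cohort$phq9_baseline, rate, mechanism)
    cohort$phq9_12wk[miss] <- NA_integer_
    cohort$eq5d_12wk[miss] <- NA_real_
    cohort
  })
}

inject_outliers_impl <- function(cohort, rate, multiplier) {
  cols <- as.vector(outer(c("physician", "outpatient"), period_levels(),
                          cost_column))
  for (col in cols) {
    hit <- runif(nrow(cohort)) < rate
    cohort[[col]][hit] <- cohort[[col]][hit] * multiplier
  }
  cohort
}

#' Inject high-cost outliers
#'
#' Multiplies a random `rate`-fraction of physician and outpatient cost
#' observations (each sector-period cell independently) by `multiplier`,
#' emulating the unusually expensive participants seen in administrative
#' cost data. Inpatient costs are never touched — they are also never
#' trimmed downstream.
#'
#' @inheritParams inject_missingness
#' @param rate Fraction of observations inflated, in \[0,1).
#' @param multiplier Inflation factor (> 1).
#' @return The contaminated cohort.
#' @export
inject_outliers <- function(cohort, rate, multiplier, seed = 1L) {
  check_number(rate, "rate", lower = 0, upper = 1, strict_upper = TRUE)
  check_number(multiplier, "multiplier", lower = 1, strict_lower = TRUE)
  if (rate == 0 || nrow(cohort) == 0) return(cohort)
  with_seed(seed, inject_outliers_impl(cohort, rate, multiplier))
}

#' Read and write the cohort CSV dialect
#'
#' One row per participant, one column per field, cost columns suffixed
#' `_<period>` with periods `pre` (12 weeks pre-randomization), `post`
#' (12 weeks post), `late` (12 weeks to one year). Missing 12-week
#' outcomes are written as empty strings.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `read_cohort()` returns the cohort tibble; `write_cohort()`
#'   returns `cohort` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(cohort)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  spec <- readr::cols(
    id = readr::col_character(),
    arm = readr::col_character(),
    age = readr::col_double(),
    sex = readr::col_character(),
    phq9_baseline = readr::col_integer(),
    phq9_12wk = readr::col_integer(),
    eq5d_baseline = readr::col_double(),
    eq5d_12wk = readr::col_double(),
    service_combo = readr::col_character(),
    .default = readr::col_double()
  )
  out <- readr::read_csv(path, col_types = spec, na = "")
  out$arm <- factor(out$arm, levels = unique(out$arm))
  out$service_combo <- factor(out$service_combo, levels = combo_levels())
  out
}
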