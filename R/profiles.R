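#' Arm generating profile for the synthetic cohort
#'
#' An `arm_profile` collects everything the generator needs for one trial
#' arm: sample size, PHQ-9 and EQ-5D-5L marginal targets at baseline and
#' 12 weeks, the service-mix probabilities over the five service-use
#' combinations, per-sector per-period cost means and s.d. among users
#' (2017 CAD), demographics, the 12-week missingness rate, and optionally
#' a target fraction scoring PHQ-9 > 10 at baseline. When
#' `depressed_fraction` is supplied the PHQ-9 baseline margin is calibrated
#' to match the mean and that tail probability (its s.d. is then emergent);
#' otherwise mean and s.d. are matched.
#'
#' @param arm_label Arm name, e.g. `"SCP"`.
#' @param n Number of participants (>= 0).
#' @param phq9_baseline_mean,phq9_baseline_sd PHQ-9 points.
#' @param phq9_12wk_mean,phq9_12wk_sd PHQ-9 points at 12 weeks.
#' @param eq5d_baseline_mean,eq5d_baseline_sd Utility in \[0,1\].
#' @param eq5d_12wk_mean,eq5d_12wk_sd Utility at 12 weeks.
#' @param service_mix A [service_mix()] over the five combinations.
#' @param sector_costs Tibble with columns `sector`, `period`, `mean`, `sd`:
#'   cost among users of the sector in that period. See
#'   [sector_cost_table()].
#' @param missing_rate Fraction of 12-week outcomes missing, in \[0,1).
#' @param depressed_fraction Optional target fraction with PHQ-9 > 10.
#' @param age_mean,age_sd,female Demographic targets.
#' @param phq9_floor Lower instrument bound used for generation (11 when
#'   emulating a depressed-only cohort, else 0).
#' @return An object of class `arm_profile`.
#' @export
arm_profile <- function(arm_label, n,
                        phq9_baseline_mean, phq9_baseline_sd,
                        phq9_12wk_mean, phq9_12wk_sd,
                        eq5d_baseline_mean, eq5d_baseline_sd,
                        eq5d_12wk_mean, eq5d_12wk_sd,
                        service_mix,
                        sector_costs,
                        missing_rate = 0.15,
                        depressed_fraction = NULL,
                        age_mean = 47, age_sd = 17, female = 0.73,
                        phq9_floor = 0L) {
  if (!is.character(arm_label) || length(arm_label) != 1L) {
    abort_field("arm_label", "must be a single string")
  }
  check_number(n, "n", lower = 0)
  if (n != round(n)) abort_field("n", "must be an integer count")
  for (f in c("phq9_baseline_sd", "phq9_12wk_sd", "eq5d_baseline_sd",
              "eq5d_12wk_sd", "age_sd")) {
    check_number(get(f), f, lower = 0)
  }
  check_number(phq9_baseline_mean, "phq9_baseline_mean", lower = 0, upper = 27)
  check_number(phq9_12wk_mean, "phq9_12wk_mean", lower = 0, upper = 27)
  check_number(eq5d_baseline_mean, "eq5d_baseline_mean", lower = 0, upper = 1)
  check_number(eq5d_12wk_mean, "eq5d_12wk_mean", lower = 0, upper = 1)
  check_number(missing_rate, "missing_rate", lower = 0, upper = 1,
               strict_upper = TRUE)
  check_number(female, "female", lower = 0, upper = 1)
  if (!is.null(depressed_fraction)) {
    check_number(depressed_fraction, "depressed_fraction", lower = 0,
                 upper = 1, strict_upper = TRUE)
  }
  stopifnot(inherits(service_mix, "service_mix"))
  needed <- c("sector", "period", "mean", "sd")
  if (!all(needed %in% names(sector_costs))) {
    abort_field("sector_costs", "needs columns sector, period, mean, sd")
  }
  if (any(!is.finite(sector_costs$mean)) || any(sector_costs$mean < 0) ||
      any(!is.finite(sector_costs$sd)) || any(sector_costs$sd < 0)) {
    abort_field("sector_costs", "means and sds must be finite and >= 0")
  }
  structure(
    list(
      arm_label = arm_label, n = as.integer(n),
      phq9_baseline_mean = phq9_baseline_mean,
      phq9_baseline_sd = phq9_baseline_sd,
      phq9_12wk_mean = phq9_12wk_mean, phq9_12wk_sd = phq9_12wk_sd,
      eq5d_baseline_mean = eq5d_baseline_mean,
      eq5d_baseline_sd = eq5d_baseline_sd,
      eq5d_12wk_mean = eq5d_12wk_mean, eq5d_12wk_sd = eq5d_12wk_sd,
      service_mix = service_mix, sector_costs = sector_costs,
      missing_rate = missing_rate, depressed_fraction = depressed_fraction,
      age_mean = age_mean, age_sd = age_sd, female = female,
      phq9_floor = as.integer(phq9_floor)
    ),
    class = "arm_profile"
  )
}

#' @export
print.arm_profile <- function(x, ...) {
  cat(sprintf("<arm_profile> %s: n = %d, PHQ-9 %.2f -> %.2f, EQ-5D %.2f -> %.2f\n",
              x$arm_label, x$n, x$phq9_baseline_mean, x$phq9_12wk_mean,
              x$eq5d_baseline_mean, x$eq5d_12wk_mean))
  invisible(x)
}

#' Split one-year sector user costs into per-period targets
#'
#' Builds the `sector_costs` table of an [arm_profile()] from one-year
#' (post-randomization) mean/s.d. among users per sector. The year is split
#' across the 12-week post period and the 12-week-to-1-year period
#' proportional to period length (12/52 and 40/52); the 12-week
#' pre-randomization window is assigned the same intensity as an equal
#' post-randomization slice. Coefficients of variation are held constant.
#'
#' @param year_means,year_sds Named numeric vectors with entries
#'   `physician`, `outpatient`, `inpatient` (2017 CAD per user-year).
#' @return Tibble with columns `sector`, `period`, `mean`, `sd`.
#' @export
sector_cost_table <- function(year_means, year_sds) {
  stopifnot(all(sector_levels() %in% names(year_means)),
            all(sector_levels() %in% names(year_sds)))
  frac <- c(pre = 12 / 52, post = 12 / 52, late = 40 / 52)
  tidyr::expand_grid(sector = sector_levels(), period = period_levels()) |>
    dplyr::mutate(
      mean = unname(year_means[.data$sector]) * frac[.data$period],
      sd = unname(year_sds[.data$sector]) * frac[.data$period]
    )
}

profile_from_refs <- function(arm, outcomes, counts, costs, dep_frac,
                              missing_rate, phq9_floor) {
  o <- outcomes[outcomes$arm == arm, ]
  cnt <- counts[counts$arm == arm, ]
  mix_counts <- as.numeric(cnt[1, combo_levels()])
  mix <- service_mix_from_counts(mix_counts)
  cs <- costs[costs$arm == arm, ]
  ym <- setNames(cs$mean, as.character(cs$sector))
  ys <- setNames(cs$sd, as.character(cs$sector))
  arm_profile(
    arm_label = as.character(arm), n = o$n,
    phq9_baseline_mean = o$phq9_0_mean, phq9_baseline_sd = o$phq9_0_sd,
    phq9_12wk_mean = o$phq9_12_mean, phq9_12wk_sd = o$phq9_12_sd,
    eq5d_baseline_mean = o$eq5d_0_mean, eq5d_baseline_sd = o$eq5d_0_sd,
    eq5d_12wk_mean = o$eq5d_12_mean, eq5d_12wk_sd = o$eq5d_12_sd,
    service_mix = mix,
    sector_costs = sector_cost_table(ym, ys),
    missing_rate = missing_rate,
    depressed_fraction = dep_frac,
    age_mean = o$age_mean, age_sd = o$age_sd, female = o$female,
    phq9_floor = phq9_floor
  )
}

#' Default arm profiles calibrated to the reference trial
#'
#' Builds the generator profiles from the bundled reference tables:
#' outcome means/s.d. from the published per-arm summaries, service-mix
#' probabilities from the service-combination counts, sector cost targets
#' from the one-year user means, and (for the `"all"` cohort) per-arm
#' PHQ-9 > 10 fractions from the depressed-subgroup counts. `"pooled"`
#' returns a single profile at the all-arms row, used for marginal
#' calibration checks. `"depressed"` emulates a depressed-only cohort
#' (PHQ-9 floor at 11).
#'
#' @inheritParams reference-parameters
#' @param missing_rate Fraction of 12-week outcomes missing (default 0.15).
#' @return A named list of [arm_profile()] objects.
#' @export
arm_profiles <- function(cohort = c("all", "depressed", "pooled"),
                         missing_rate = 0.15) {
  cohort <- match.arg(cohort)
  if (cohort == "pooled") {
    o <- ref_outcome_summary("pooled")
    counts_all <- ref_service_counts("all")
    pooled_counts <- colSums(counts_all[, combo_levels()])
    costs <- ref_sector_costs("all")
    pooled_costs <- costs |>
      dplyr::group_by(.data$sector) |>
      dplyr::summarise(
        mean = sum(.data$mean * .data$n_users) / sum(.data$n_users),
        sd = sum(.data$sd * .data$n_users) / sum(.data$n_users),
        .groups = "drop"
      )
    ym <- setNames(pooled_costs$mean, as.character(pooled_costs$sector))
    ys <- setNames(pooled_costs$sd, as.character(pooled_costs$sector))
    p <- arm_profile(
      arm_label = "ALL", n = o$n,
      phq9_baseline_mean = o$phq9_0_mean, phq9_baseline_sd = o$phq9_0_sd,
      phq9_12wk_mean = o$phq9_12_mean, phq9_12wk_sd = o$phq9_12_sd,
      eq5d_baseline_mean = o$eq5d_0_mean, eq5d_baseline_sd = o$eq5d_0_sd,
      eq5d_12wk_mean = o$eq5d_12_mean, eq5d_12wk_sd = o$eq5d_12_sd,
      service_mix = service_mix_from_counts(pooled_counts),
      sector_costs = sector_cost_table(ym, ys),
      missing_rate = missing_rate,
      depressed_fraction = 206 / 1407,
      age_mean = o$age_mean, age_sd = o$age_sd, female = o$female
    )
    return(list(ALL = p))
  }
  outcomes <- ref_outcome_summary(cohort)
  counts <- ref_service_counts(cohort)
  costs <- ref_sector_costs(cohort)
  dep <- ref_depressed_counts()
  profs <- lapply(arm_levels(), function(a) {
    dep_frac <- if (cohort == "all") {
      dep$n_depressed[dep$arm == a] / dep$n[dep$arm == a]
    } else {
      NULL
    }
    profile_from_refs(a, outcomes, counts, costs, dep_frac,
                      missing_rate,
                      phq9_floor = if (cohort == "depressed") 11L else 0L)
  })
  setNames(profs, arm_levels())
}

#' Cohort generator configuration
#'
#' Collects the arm profiles and the cohort-level knobs the generator
#' uses: the high-cost outlier contamination (rate and multiplier applied
#' to physician/outpatient observations), the latent-copula correlations
#' linking PHQ-9 and EQ-5D margins, the optional cost–outcome correlation,
#' the missingness mechanism, and the seed.
#'
#' @param profiles Named list of [arm_profile()]s.
#' @param outlier_rate Fraction of physician/outpatient cost observations
#'   inflated, in \[0,1).
#' @param outlier_multiplier Factor (> 1) applied to inflated costs.
#' @param missing_mechanism `"MAR_on_baseline"` (missingness increases with
#'   baseline PHQ-9) or `"MCAR"`.
#' @param cor_cross Latent correlation between PHQ-9 and EQ-5D at the same
#'   visit (negative: worse depression, lower utility).
#' @param cor_stability Latent baseline–12-week correlation within each
#'   instrument.
#' @param cor_cost_outcome Latent correlation between baseline PHQ-9 and
#'   cost draws (0 = none; the reference trial reports no value).
#' @param seed Integer seed; every random stage derives from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(profiles = arm_profiles("all"),
                          outlier_rate = 0.03,
                          outlier_multiplier = 6,
                          missing_mechanism = c("MAR_on_baseline", "MCAR"),
                          cor_cross = -0.5,
                          cor_stability = 0.6,
                          cor_cost_outcome = 0,
                          seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  stopifnot(is.list(profiles), length(profiles) >= 1,
            all(vapply(profiles, inherits, logical(1), "arm_profile")))
  check_number(outlier_rate, "outlier_rate", lower = 0, upper = 1,
               strict_upper = TRUE)
  check_number(outlier_multiplier, "outlier_multiplier", lower = 1,
               strict_lower = TRUE)
  check_number(cor_cross, "cor_cross", lower = -1, upper = 1)
  check_number(cor_stability, "cor_stability", lower = -1, upper = 1)
  check_number(cor_cost_outcome, "cor_cost_outcome", lower = -1, upper = 1)
  check_number(seed, "seed")
  structure(
    list(profiles = profiles, outlier_rate = outlier_rate,
         outlier_multiplier = outlier_multiplier,
         missing_mechanism = missing_mechanism,
         cor_cross = cor_cross, cor_stability = cor_stability,
         cor_cost_outcome = cor_cost_outcome, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> %d arm(s), n = %s; outliers %.1f%% x%.1f; %s missingness\n",
    length(x$profiles),
    paste(vapply(x$profiles, function(p) p$n, integer(1)), collapse = "/"),
    100 * x$outlier_rate, x$outlier_multiplier, x$missing_mechanism))
  invisible(x)
}
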