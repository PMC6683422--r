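#' Bundled reference parameters for the four-arm depression-care trial
#'
#' The package models a randomized primary-care depression screening trial
#' with four strategies: standard care (`SC`), treatment as usual (`TAU`),
#' treatment as usual plus online CBT (`ICBT`), and a stepped-care pathway
#' (`SCP`). The trial's patient-level administrative data are not publicly
#' available; what is available are arm-level summaries — service-use
#' combination counts, outcome means, and sector cost means among users —
#' in 2017 Canadian dollars. These tables are bundled here, both to
#' calibrate the synthetic cohort generator and to drive the
#' table-reproduction mode of the decision-tree and PSA stages.
#'
#' `ref_service_counts()` returns, per arm, the number of participants who
#' in the year after randomization used each of the five service
#' combinations: no services, physician only, physician + outpatient,
#' physician + inpatient, and all three sectors. `ref_sector_costs()`
#' returns mean one-year costs (and s.d.) among users of each sector.
#' `ref_outcome_summary()` returns per-arm PHQ-9 and EQ-5D-5L means/s.d.
#' at baseline and 12 weeks, plus age and sex composition.
#' `ref_ce_summary()` returns the per-arm total annual cost and QALY means
#' and the s.d. used to parameterize probabilistic sensitivity analysis.
#'
#' @param cohort `"all"` for the full trial population, `"depressed"` for
#'   the subgroup scoring above 10 on the PHQ-9 at baseline, or `"pooled"`
#'   (where offered) for the row pooling the four arms.
#' @return A tibble; see Details for the columns of each table.
#' @examples
#' ref_service_counts("all")
#' ref_sector_costs("depressed")
#' @name reference-parameters
NULL

ref_cohorts <- function() c("all", "depressed")

match_cohort <- function(cohort, extra = character()) {
  match.arg(cohort, c(ref_cohorts(), extra))
}

#' @rdname reference-parameters
#' @export
ref_service_counts <- function(cohort = c("all", "depressed")) {
  cohort <- match.arg(cohort)
  all <- tibble::tribble(
    ~arm,   ~none, ~phys_only, ~phys_out, ~phys_inp, ~phys_out_inp,
    "SC",       4,        179,       176,         3,            53,
    "TAU",      8,        160,       160,         2,            69,
    "ICBT",     4,        188,       164,         7,            59,
    "SCP",      3,         75,        88,         0,            17
  )
  dep <- tibble::tribble(
    ~arm,   ~none, ~phys_only, ~phys_out, ~phys_inp, ~phys_out_inp,
    "SC",       0,         21,        28,         0,             7,
    "TAU",      2,         21,        35,         0,             8,
    "ICBT",     0,         22,        23,         0,             5,
    "SCP",      0,         12,        18,         0,             4
  )
  out <- if (cohort == "all") all else dep
  dplyr::mutate(out, arm = factor(.data$arm, levels = arm_levels()))
}

#' @rdname reference-parameters
#' @export
ref_sector_costs <- function(cohort = c("all", "depressed")) {
  cohort <- match.arg(cohort)
  all <- tibble::tribble(
    ~arm,   ~sector,      ~n_users, ~mean,     ~sd,
    "SC",   "inpatient",        56,  8472.98,  4916,
    "TAU",  "inpatient",        70,  8158.80,  5819,
    "ICBT", "inpatient",        66,  8477.81,  5340,
    "SCP",  "inpatient",        17, 10670.27,  3994,
    "SC",   "outpatient",      198,  1036.58,   386,
    "TAU",  "outpatient",      200,  1002.32,   392,
    "ICBT", "outpatient",      193,   945.89,   340,
    "SCP",  "outpatient",       90,  1144.49,   611,
    "SC",   "physician",       395,   683.75,   241,
    "TAU",  "physician",       375,   758.17,   269,
    "ICBT", "physician",       394,   667.49,   214,
    "SCP",  "physician",       172,   559.00,   207
  )
  dep <- tibble::tribble(
    ~arm,   ~sector,      ~n_users, ~mean,     ~sd,
    "SC",   "inpatient",         7, 11953.99,  4257,
    "TAU",  "inpatient",         7, 14771.99,  6465,
    "ICBT", "inpatient",         5,  9357.69,  2698,
    "SCP",  "inpatient",         4, 10820.99,  2660,
    "SC",   "outpatient",       33,  1256.53,   498,
    "TAU",  "outpatient",       38,  1188.60,   428,
    "ICBT", "outpatient",       24,  1101.80,   420,
    "SCP",  "outpatient",       21,  1800.39,   648,
    "SC",   "physician",        52,   802.56,   285,
    "TAU",  "physician",        60,   996.41,   326,
    "ICBT", "physician",        48,   787.08,   216,
    "SCP",  "physician",        31,   633.60,   648
  )
  out <- if (cohort == "all") all else dep
  dplyr::mutate(
    out,
    arm = factor(.data$arm, levels = arm_levels()),
    sector = factor(.data$sector, levels = sector_levels())
  )
}

#' @rdname reference-parameters
#' @export
ref_outcome_summary <- function(cohort = c("all", "depressed", "pooled")) {
  cohort <- match.arg(cohort)
  all <- tibble::tribble(
    ~arm,   ~n,  ~age_mean, ~age_sd, ~female, ~phq9_0_mean, ~phq9_0_sd,
            ~phq9_12_mean, ~phq9_12_sd, ~eq5d_0_mean, ~eq5d_0_sd,
            ~eq5d_12_mean, ~eq5d_12_sd,
    "SC",   412, 46.9, 17.1, 0.75, 4.55, 4.95, 3.85, 2.94, 0.86, 0.11, 0.88, 0.06,
    "TAU",  397, 45.5, 16.3, 0.78, 4.98, 5.19, 4.12, 3.09, 0.84, 0.14, 0.87, 0.08,
    "ICBT", 415, 46.6, 16.8, 0.70, 4.20, 4.61, 3.65, 2.74, 0.86, 0.12, 0.88, 0.07,
    "SCP",  183, 52.3, 17.6, 0.61, 4.86, 5.54, 4.04, 3.29, 0.86, 0.13, 0.88, 0.08
  )
  dep <- tibble::tribble(
    ~arm,   ~n,  ~age_mean, ~age_sd, ~female, ~phq9_0_mean, ~phq9_0_sd,
            ~phq9_12_mean, ~phq9_12_sd, ~eq5d_0_mean, ~eq5d_0_sd,
            ~eq5d_12_mean, ~eq5d_12_sd,
    "SC",   56, 44.7, 16.3, 0.80, 14.73, 4.17,  9.90, 2.48, 0.68, 0.18, 0.78, 0.10,
    "TAU",  66, 44.8, 14.2, 0.70, 14.83, 3.91,  9.94, 2.31, 0.63, 0.20, 0.74, 0.12,
    "ICBT", 50, 42.2, 13.8, 0.70, 14.28, 3.76,  9.64, 2.24, 0.67, 0.22, 0.77, 0.13,
    "SCP",  34, 49.0, 16.4, 0.74, 14.85, 3.84,  9.98, 2.28, 0.68, 0.21, 0.78, 0.12
  )
  pooled <- tibble::tribble(
    ~arm,   ~n,   ~age_mean, ~age_sd, ~female, ~phq9_0_mean, ~phq9_0_sd,
            ~phq9_12_mean, ~phq9_12_sd, ~eq5d_0_mean, ~eq5d_0_sd,
            ~eq5d_12_mean, ~eq5d_12_sd,
    "ALL",  1407, 47.1, 17.0, 0.73, 4.61, 5.01, 3.89, 2.98, 0.86, 0.12, 0.88, 0.07
  )
  switch(cohort, all = all, depressed = dep, pooled = pooled) |>
    dplyr::mutate(arm = factor(.data$arm, levels = unique(.data$arm)))
}

#' @rdname reference-parameters
#' @export
ref_ce_summary <- function(cohort = c("all", "depressed")) {
  cohort <- match.arg(cohort)
  all <- tibble::tribble(
    ~arm,   ~cost_mean, ~cost_sd, ~qaly_mean, ~qaly_sd,
    "SC",         2346,      655,      0.881,    0.003,
    "TAU",        2740,      968,      0.870,    0.004,
    "ICBT",       2353,      767,      0.881,    0.003,
    "SCP",        2191,      539,      0.882,    0.005
  )
  dep <- tibble::tribble(
    ~arm,   ~cost_mean, ~cost_sd, ~qaly_mean, ~qaly_sd,
    "SC",         3078,      677,      0.766,    0.014,
    "TAU",        3516,      890,      0.730,    0.014,
    "ICBT",       2522,      455,      0.758,    0.017,
    "SCP",        3075,      565,      0.767,    0.021
  )
  out <- if (cohort == "all") all else dep
  dplyr::mutate(out, arm = factor(.data$arm, levels = arm_levels()))
}

#' Depressed-subgroup size per arm in the reference trial
#'
#' Counts of participants scoring above 10 on the PHQ-9 at baseline,
#' used as per-arm calibration targets for the synthetic generator.
#' @return A tibble with `arm`, `n_depressed`, `n`.
#' @export
ref_depressed_counts <- function() {
  tibble::tibble(
    arm = factor(arm_levels(), levels = arm_levels()),
    n_depressed = c(56, 66, 50, 34),
    n = c(412, 397, 415, 183)
  )
}
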