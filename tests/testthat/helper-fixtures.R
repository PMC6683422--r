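# tiny in-code fixtures shared across test files

# hand-built cohort with known cost patterns; n records per arm
tiny_cohort <- function(n = 6, arms = c("SC", "SCP")) {
  per_arm <- lapply(arms, function(a) {
    tibble::tibble(
      id = paste0(a, seq_len(n)),
      arm = a,
      age = seq(30, 60, length.out = n),
      sex = rep_len(c("female", "male"), n),
      phq9_baseline = rep_len(c(2L, 5L, 12L), n),
      phq9_12wk = rep_len(c(1L, 4L, 9L), n),
      eq5d_baseline = rep_len(c(0.9, 0.8, 0.6), n),
      eq5d_12wk = rep_len(c(0.92, 0.85, 0.7), n),
      service_combo = factor(rep_len(c("phys_only", "phys_out", "none"), n),
                             levels = c("none", "phys_only", "phys_out",
                                        "phys_inp", "phys_out_inp")),
      cost_physician_pre = rep_len(c(100, 150, 0), n),
      cost_outpatient_pre = rep_len(c(0, 300, 0), n),
      cost_inpatient_pre = 0,
      cost_physician_post = rep_len(c(120, 160, 0), n),
      cost_outpatient_post = rep_len(c(0, 250, 0), n),
      cost_inpatient_post = 0,
      cost_physician_late = rep_len(c(400, 500, 0), n),
      cost_outpatient_late = rep_len(c(0, 800, 0), n),
      cost_inpatient_late = 0
    )
  })
  out <- dplyr::bind_rows(per_arm)
  out$arm <- factor(out$arm, levels = arms)
  out
}

# a small calibrated generator config (defaults scaled down)
small_config <- function(n = 250L, missing_rate = 0, outlier_rate = 0,
                         cohort = "all", ...) {
  cfg <- cohort_config(
    profiles = arm_profiles(cohort, missing_rate = missing_rate),
    outlier_rate = outlier_rate, ...)
  cfg$profiles <- lapply(cfg$profiles, function(p) {
    p$n <- as.integer(n)
    p
  })
  cfg
}

# brute-force IQR trimming oracle: type-7 quartiles, direct filter
trim_oracle <- function(x, factor = 1.5) {
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  fence <- c(q[1] - factor * (q[2] - q[1]), q[2] + factor * (q[2] - q[1]))
  x[x >= fence[1] & x <= fence[2]]
}

# brute-force five-branch expected cost
expected_cost_oracle <- function(p, cp, co, ci) {
  branch <- c(0, cp, cp + co, cp + ci, cp + co + ci)
  sum(p * branch)
}
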