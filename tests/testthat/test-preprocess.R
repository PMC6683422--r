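test_that("service-combination classification matches the five-branch scheme", {
  expect_equal(as.character(classify_service_combination(0, 0, 0)), "none")
  expect_equal(as.character(classify_service_combination(10, 20, 0)),
               "phys_out")
  expect_equal(as.character(classify_service_combination(10, 20, 30)),
               "phys_out_inp")
  expect_equal(as.character(classify_service_combination(10, 0, 0)),
               "phys_only")
  expect_equal(as.character(classify_service_combination(10, 0, 5)),
               "phys_inp")
  expect_error(classify_service_combination(-1, 0, 0), "negative")
  # no-physician patterns map to the nearest branch with their sectors
  expect_warning(
    combos <- classify_service_combination(c(0, 0, 0), c(5, 0, 7),
                                           c(0, 9, 2)),
    "mapped")
  expect_equal(as.character(combos), c("phys_out", "phys_inp",
                                       "phys_out_inp"))
})

test_that("classification partitions every cohort", {
  co <- classify_services(generate_cohort(small_config(n = 300), seed = 2))
  counts <- table(co$service_combo)
  expect_equal(sum(counts), nrow(co))
  expect_false(anyNA(co$service_combo))
})

test_that("IQR trimming keeps exactly the within-fence values", {
  const <- trim_outliers(rep(7, 12))
  expect_equal(const$kept, rep(7, 12))
  expect_equal(const$report$n_removed, 0)

  tr <- trim_outliers(c(1:9, 100))
  expect_equal(tr$kept, 1:9)
  expect_equal(tr$report$n_removed, 1)
  # every removed value sits strictly outside the input-data fences
  expect_true(all(tr$kept >= tr$report$lower_fence &
                    tr$kept <= tr$report$upper_fence))
  expect_gt(100, tr$report$upper_fence)

  # re-application: kept is a sub-multiset, no point outside input fences
  tr2 <- trim_outliers(tr$kept)
  expect_true(all(tr2$kept %in% tr$kept))
  expect_lte(length(tr2$kept), length(tr$kept))

  expect_error(trim_outliers(numeric(0)), "empty")
  expect_error(trim_outliers(1:5, factor = 0), "factor")
  expect_error(trim_outliers(c(1, -2, 3)), "negative")
})

test_that("trimming agrees with a brute-force oracle on small instances", {
  set.seed(11)
  for (i in 1:150) {
    n <- sample(3:20, 1)
    x <- switch(sample(3, 1),
                round(rgamma(n, shape = 1.2, scale = 50)),
                sample(0:5, n, replace = TRUE),       # heavy ties
                c(rgamma(n - 1, 2, 0.01), 1e5))       # planted outlier
    for (f in c(1, 1.5, 3)) {
      got <- trim_outliers(x, factor = f)$kept
      expect_equal(sort(got), sort(trim_oracle(x, f)))
    }
  }
})

test_that("cohort-level trimming is per arm/period/sector and spares inpatient", {
  co <- inject_outliers(generate_cohort(small_config(n = 800), seed = 4),
                        rate = 0.04, multiplier = 12, seed = 9)
  tr <- trim_cohort_costs(co)
  expect_identical(tr$cohort$cost_inpatient_post, co$cost_inpatient_post)
  expect_identical(tr$cohort$cost_inpatient_late, co$cost_inpatient_late)
  expect_true(all(tr$report$sector %in% c("physician", "outpatient")))
  expect_true(all(tr$report$n_removed <= tr$report$n_before))
  # per-arm-and-cell fences: every surviving positive value within fences
  for (i in seq_len(nrow(tr$report))) {
    r <- tr$report[i, ]
    col <- paste0("cost_", r$sector, "_", r$period)
    v <- tr$cohort[[col]][tr$cohort$arm == r$arm]
    v <- v[!is.na(v) & v > 0]
    expect_true(all(v >= r$lower_fence & v <= r$upper_fence))
  }
  # trimmed cells are NA, record itself retained
  expect_equal(nrow(tr$cohort), nrow(co))
})

test_that("depressed subgroup uses the strict PHQ-9 > 10 rule", {
  co <- tiny_cohort(n = 4)
  co$phq9_baseline <- c(10L, 11L, 9L, 27L, 10L, 11L, 0L, 12L)
  sub <- subgroup_depressed(co)
  expect_true(all(sub$phq9_baseline > 10))
  expect_equal(nrow(sub), 4)
  expect_identical(subgroup_depressed(sub), sub)  # idempotent
  # union with complement restores the cohort
  comp <- co[co$phq9_baseline <= 10, ]
  expect_equal(nrow(sub) + nrow(comp), nrow(co))

  none <- co; none$phq9_baseline <- rep(3L, nrow(co))
  expect_equal(nrow(subgroup_depressed(none)), 0)
})

test_that("subgroup size at reference calibration is binomially near 206/1407", {
  cfg <- cohort_config(profiles = arm_profiles("all", missing_rate = 0),
                       outlier_rate = 0)
  # reference arm sizes
  co <- generate_cohort(cfg, seed = 12)
  expect_equal(nrow(co), 412 + 397 + 415 + 183)
  n_dep <- nrow(subgroup_depressed(co))
  p0 <- 206 / 1407
  expect_lt(abs(n_dep - 206), 3 * sqrt(nrow(co) * p0 * (1 - p0)) + 1)
})

test_that("descriptive summary reports correct changes and bootstrap CIs", {
  co <- tiny_cohort(n = 6)
  ds <- descriptive_summary(co, n_boot = 200, seed = 1)
  sc_phq <- ds[ds$arm == "SC" & ds$measure == "phq9", ]
  # improvement positive: baseline minus 12-week for PHQ-9
  expect_equal(sc_phq$change,
               mean(c(2, 5, 12) - c(1, 4, 9)))
  sc_eq <- ds[ds$arm == "SC" & ds$measure == "eq5d", ]
  expect_equal(sc_eq$change, mean(c(0.92, 0.85, 0.7) - c(0.9, 0.8, 0.6)))
  expect_true(all(ds$change_lo <= ds$change & ds$change <= ds$change_hi))

  one <- co[1, ]
  ds1 <- suppressWarnings(descriptive_summary(one, n_boot = 10, seed = 1))
  expect_false(any(ds1$sd_defined))
  expect_equal(ds1$baseline_sd, c(0, 0))

  withArm <- co
  withArm$arm <- factor(withArm$arm, levels = c("SC", "SCP", "GHOST"))
  expect_warning(descriptive_summary(withArm, n_boot = 10), "omitted")
})
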