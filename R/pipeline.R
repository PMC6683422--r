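# delta-method s.e. of the decision-tree total: multinomial uncertainty in
# the mix plus sampling uncertainty in the sector user means
tree_cost_se <- function(mix, n_arm, means, ses) {
  p <- unclass(mix)
  # sector-use probabilities are linear maps of the branch probabilities
  A <- rbind(physician = c(0, 1, 1, 1, 1),
             outpatient = c(0, 0, 1, 0, 1),
             inpatient = c(0, 0, 0, 1, 1))
  q <- drop(A %*% p)
  C <- means[rownames(A)]
  s <- ses[rownames(A)]
  sigma_p <- (diag(p) - tcrossprod(p)) / n_arm
  sigma_q <- A %*% sigma_p %*% t(A)
  var_mix <- drop(t(C) %*% sigma_q %*% C)
  var_means <- sum(q^2 * s^2)
  sqrt(var_mix + var_means)
}

#' Assemble probabilistic-sensitivity-analysis input distributions
#'
#' Combines per-arm decision-tree expected costs (with delta-method
#' s.e. from the multinomial service mix and the sector-mean standard
#' errors) and per-arm QALY estimates into the `(mean, s.d.)` table
#' [simulate_psa()] samples from.
#'
#' @param mixes Named list of [service_mix()] per arm.
#' @param arm_n Named vector of arm sample sizes.
#' @param sector_means Tibble `arm`, `sector`, `estimate`, `se`.
#' @param qalys Tibble `arm`, `qaly`, `se` (from [arm_qaly()]).
#' @return Tibble `arm`, `cost_mean`, `cost_sd`, `qaly_mean`, `qaly_sd`.
#' @export
psa_inputs <- function(mixes, arm_n, sector_means, qalys) {
  arms <- as.character(qalys$arm)
  purrr::map_dfr(arms, function(a) {
    sm <- sector_means[sector_means$arm == a, ]
    means <- setNames(sm$estimate, as.character(sm$sector))
    ses <- setNames(sm$se, as.character(sm$sector))
    ec <- expected_cost(mixes[[a]], means)
    tibble::tibble(
      arm = a,
      cost_mean = ec$total,
      cost_sd = tree_cost_se(mixes[[a]], arm_n[[a]], means, ses),
      qaly_mean = qalys$qaly[qalys$arm == a],
      qaly_sd = qalys$se[qalys$arm == a]
    )
  })
}

#' Run the full cost-effectiveness pipeline
#'
#' Executes the whole analysis end to end on a generated (or supplied)
#' cohort: service-combination classification over the post-randomization
#' year, IQR outlier trimming of physician/outpatient costs, multiple
#' imputation of missing 12-week outcomes, OLS adjustment of 12-week
#' EQ-5D utilities, gamma-GLM adjustment of sector user costs, per-arm
#' QALYs under the chosen persistence scenario, decision-tree expected
#' costs (optionally under the pooled identical-service-mix sensitivity
#' scenario), and Monte Carlo PSA with ICERs, CEACs and the incremental
#' cost-effectiveness scatter. Every stage derives its seed from `seed`,
#' so two runs with identical inputs are identical.
#'
#' @param config A [cohort_config()]; ignored when `cohort` is supplied.
#' @param cohort Optional pre-built cohort tibble (e.g. [read_cohort()]).
#' @param seed Master integer seed.
#' @param subgroup If `TRUE`, restrict to baseline PHQ-9 > 10.
#' @param qaly_scenario See [qaly_auc()].
#' @param pooled_mix If `TRUE`, every arm uses the pooled service mix.
#' @param trim If `TRUE` (default), IQR-trim physician/outpatient costs.
#' @param trim_factor IQR multiplier for trimming.
#' @param m Number of multiple imputations (when 12-week outcomes are
#'   missing).
#' @param n_iter PSA iterations.
#' @param wtp_grid Willingness-to-pay grid for the CEAC.
#' @param scatter_comparator Arm plotted against the reference arm on the
#'   scatter (default `"ICBT"` when present).
#' @param scatter_wtp Willingness-to-pay for the below-line fraction.
#' @param price_factor Multiplicative price-year adjustment applied to
#'   all cost estimates (inputs are 2017 CAD; supply a CPI ratio to
#'   re-express them).
#' @param min_users Minimum per-arm users for the cost GLM.
#' @param reference Reference arm for ICERs (default the last arm).
#' @param out_dir Optional directory; when given, the main tables are
#'   written as CSV files.
#' @return A list of class `depcea_report` with elements `cohort_n`,
#'   `descriptives`, `trim_report`, `mixes`, `sector_means`,
#'   `expected_costs`, `qalys`, `psa_inputs`, `draws`, `icers`, `ceac`,
#'   `scatter`, `scatter_fraction`, and `settings`.
#' @export
run_full_analysis <- function(config = cohort_config(),
                              cohort = NULL,
                              seed = config$seed,
                              subgroup = FALSE,
                              qaly_scenario = c("carry_forward",
                                                "linear_return",
                                                "immediate_return"),
                              pooled_mix = FALSE,
                              trim = TRUE, trim_factor = 1.5,
                              m = 20, n_iter = 10000,
                              wtp_grid = seq(0, 200000, by = 1000),
                              scatter_comparator = NULL,
                              scatter_wtp = 50000,
                              price_factor = 1,
                              min_users = 10,
                              reference = NULL,
                              out_dir = NULL) {
  qaly_scenario <- match.arg(qaly_scenario)
  check_number(price_factor, "price_factor", lower = 0, strict_lower = TRUE)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  cohort <- step("generate",
                 cohort %||% generate_cohort(config, seed = seed))
  if (subgroup) cohort <- step("subgroup", subgroup_depressed(cohort))
  cohort <- step("classify", classify_services(cohort, "year"))
  arms <- levels(droplevels(factor(cohort$arm)))
  arm_n <- table(factor(cohort$arm, levels = arms))
  mixes <- step("service_mix", {
    if (pooled_mix) {
      pm <- pooled_service_mix(cohort)
      setNames(rep(list(pm), length(arms)), arms)
    } else {
      setNames(lapply(arms, estimate_service_mix, cohort = cohort), arms)
    }
  })
  trim_report <- NULL
  analysed <- cohort
  if (trim) {
    tr <- step("trim", trim_cohort_costs(cohort, factor = trim_factor))
    analysed <- tr$cohort
    trim_report <- tr$report
  }
  needs_mi <- anyNA(analysed$phq9_12wk) || anyNA(analysed$eq5d_12wk)
  analysed <- if (needs_mi) {
    step("impute", impute_missing(analysed, m = m, seed = seed + 1L))
  } else analysed
  descriptives <- step("descriptive",
                       descriptive_summary(cohort, seed = seed + 3L))
  u12 <- step("adjust_outcome", tidy(fit_outcome_ols(analysed,
                                                     "eq5d_12wk")))
  base_dat <- as_dataset_list(analysed)[[1]]
  u0 <- base_dat |>
    dplyr::group_by(arm = factor(.data$arm, levels = arms)) |>
    dplyr::summarise(
      u0 = mean(.data$eq5d_baseline),
      se0 = sd(.data$eq5d_baseline) / sqrt(dplyr::n()), .groups = "drop")
  utilities <- dplyr::left_join(
    u0, dplyr::rename(u12, u12 = "estimate", se12 = "se"), by = "arm")
  reference <- reference %||% arms[length(arms)]
  qalys <- step("qaly", arm_qaly(utilities, scenario = qaly_scenario,
                                 reference = reference))
  sector_means <- step("adjust_costs",
                       adjusted_arm_means(analysed, period = "year",
                                          min_users = min_users))
  sector_means$estimate <- sector_means$estimate * price_factor
  sector_means$se <- sector_means$se * price_factor
  expected_costs <- step("cost_tree",
                         arm_expected_costs(mixes, sector_means))
  dists <- step("psa_inputs",
                psa_inputs(mixes, as.list(arm_n), sector_means, qalys))
  draws <- step("psa", simulate_psa(dists, n_iter = n_iter,
                                    seed = seed + 2L))
  icers <- step("icer", purrr::map_dfr(
    setdiff(arms, reference),
    function(a) icer(draws, reference, a)))
  ceac_tbl <- step("ceac", ceac(draws, wtp_grid))
  scatter_comparator <- scatter_comparator %||%
    if ("ICBT" %in% arms && reference != "ICBT") "ICBT"
    else setdiff(arms, reference)[1]
  scatter <- step("scatter",
                  scatter_points(draws, reference, scatter_comparator))
  report <- structure(list(
    cohort_n = as.integer(arm_n),
    arms = arms,
    descriptives = descriptives,
    trim_report = trim_report,
    mixes = mixes,
    sector_means = sector_means,
    expected_costs = expected_costs,
    qalys = qalys,
    psa_inputs = dists,
    draws = draws,
    icers = icers,
    ceac = ceac_tbl,
    scatter = scatter,
    scatter_fraction = fraction_below(scatter, scatter_wtp),
    settings = list(seed = seed, subgroup = subgroup,
                    qaly_scenario = qaly_scenario, pooled_mix = pooled_mix,
                    trim = trim, trim_factor = trim_factor, m = m,
                    n_iter = n_iter, price_factor = price_factor,
                    min_users = min_users, reference = reference,
                    scatter_comparator = scatter_comparator,
                    scatter_wtp = scatter_wtp)
  ), class = "depcea_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.depcea_report <- function(x, ...) {
  cat(sprintf("<depcea_report> arms: %s (n = %s)\n",
              paste(x$arms, collapse = "/"),
              paste(x$cohort_n, collapse = "/")))
  cat(sprintf("  QALY scenario: %s; PSA: %d iterations; reference: %s\n",
              x$settings$qaly_scenario, x$settings$n_iter,
              x$settings$reference))
  tot <- dplyr::select(x$expected_costs, "arm", "total")
  cat("  expected annual cost per participant:\n")
  for (i in seq_len(nrow(tot))) {
    cat(sprintf("    %-5s $%.0f\n", tot$arm[i], tot$total[i]))
  }
  cat(sprintf("  scatter fraction below $%s line (%s vs %s): %.3f\n",
              format(x$settings$scatter_wtp, big.mark = ","),
              x$settings$reference, x$settings$scatter_comparator,
              x$scatter_fraction))
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    readr::write_csv(df, file.path(out_dir, paste0(name, ".csv")))
  }
  w(report$descriptives, "descriptives")
  if (!is.null(report$trim_report)) w(report$trim_report, "trim_report")
  w(report$sector_means, "sector_means")
  w(report$expected_costs, "expected_costs")
  w(report$qalys, "qalys")
  w(report$psa_inputs, "psa_inputs")
  w(report$icers, "icers")
  w(report$ceac, "ceac")
  w(tibble::as_tibble(report$scatter), "scatter")
  settings <- report$settings
  w(tibble::tibble(key = names(settings),
                   value = vapply(settings, function(v)
                     paste(format(v), collapse = " "), character(1))),
    "settings")
  invisible(report)
}

#' Reproduce the reference-trial analysis from the bundled summary tables
#'
#' Table-reproduction mode: instead of patient-level data, the published
#' arm-level inputs drive the model directly — service-combination counts
#' for the mixes, one-year sector user means for the tree, arm utilities
#' for the QALYs, and the published total-cost/QALY means and s.d. for
#' the PSA. Useful as an end-to-end check of the decision-tree, QALY and
#' PSA machinery against the published results.
#'
#' @inheritParams reference-parameters
#' @param n_iter PSA iterations.
#' @param seed Integer seed.
#' @param wtp_grid Willingness-to-pay grid.
#' @param scatter_wtp Threshold for the below-line fraction.
#' @param qaly_scenario See [qaly_auc()].
#' @return A list with `mixes`, `sector_means`, `expected_costs`,
#'   `qalys`, `psa_inputs`, `draws`, `icers`, `ceac`, `scatter`,
#'   `scatter_fraction`.
#' @export
reproduce_reference_analysis <- function(cohort = c("all", "depressed"),
                                         n_iter = 10000, seed = 1L,
                                         wtp_grid = seq(0, 200000,
                                                        by = 1000),
                                         scatter_wtp = 50000,
                                         qaly_scenario = "carry_forward") {
  cohort <- match.arg(cohort)
  counts <- ref_service_counts(cohort)
  arms <- as.character(counts$arm)
  mixes <- setNames(lapply(seq_len(nrow(counts)), function(i) {
    service_mix_from_counts(as.numeric(counts[i, combo_levels()]))
  }), arms)
  costs <- ref_sector_costs(cohort)
  sector_means <- tibble::tibble(
    arm = costs$arm, sector = costs$sector,
    estimate = costs$mean, se = costs$sd / sqrt(costs$n_users)
  )
  expected_costs <- arm_expected_costs(mixes, sector_means)
  outc <- ref_outcome_summary(cohort)
  utilities <- tibble::tibble(
    arm = as.character(outc$arm),
    u0 = outc$eq5d_0_mean, se0 = outc$eq5d_0_sd / sqrt(outc$n),
    u12 = outc$eq5d_12_mean, se12 = outc$eq5d_12_sd / sqrt(outc$n)
  )
  qalys <- arm_qaly(utilities, scenario = qaly_scenario,
                    reference = "SCP")
  dists <- ref_ce_summary(cohort)
  draws <- simulate_psa(dists, n_iter = n_iter, seed = seed)
  icers <- purrr::map_dfr(setdiff(arms, "SCP"),
                          function(a) icer(draws, "SCP", a))
  ceac_tbl <- ceac(draws, wtp_grid)
  scatter <- scatter_points(draws, "SCP", "ICBT")
  list(
    mixes = mixes, sector_means = sector_means,
    expected_costs = expected_costs, qalys = qalys,
    psa_inputs = dists, draws = draws, icers = icers, ceac = ceac_tbl,
    scatter = scatter,
    scatter_fraction = fraction_below(scatter, scatter_wtp)
  )
}
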