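#' Classify sector costs into a service-use combination
#'
#' Returns `none` iff all three sector costs are zero; otherwise the
#' combination of sectors with positive cost. The reference trial's cost
#' model has no branches without a physician component, so the rare
#' patterns lacking physician cost are mapped to the nearest branch
#' containing their sectors (outpatient only to `phys_out`, inpatient only
#' to `phys_inp`, outpatient + inpatient to `phys_out_inp`) and counted in
#' a warning.
#'
#' @param physician,outpatient,inpatient Non-negative cost vectors
#'   (recycled to common length).
#' @return A factor with levels `none`, `phys_only`, `phys_out`,
#'   `phys_inp`, `phys_out_inp`.
#' @examples
#' classify_service_combination(c(0, 10, 5), c(0, 20, 0), c(0, 0, 0))
#' @export
classify_service_combination <- function(physician, outpatient, inpatient) {
  n <- max(length(physician), length(outpatient), length(inpatient))
  physician <- rep_len(physician, n)
  outpatient <- rep_len(outpatient, n)
  inpatient <- rep_len(inpatient, n)
  if (any(physician < 0 | outpatient < 0 | inpatient < 0, na.rm = TRUE)) {
    stop("negative sector cost", call. = FALSE)
  }
  p <- physician > 0; o <- outpatient > 0; i <- inpatient > 0
  out <- rep("none", n)
  out[p & !o & !i] <- "phys_only"
  out[o & !i] <- "phys_out"
  out[!o & i] <- "phys_inp"
  out[o & i] <- "phys_out_inp"
  n_mapped <- sum((o | i) & !p)
  if (n_mapped > 0) {
    warning(sprintf(
      "%d record(s) with service use but no physician cost mapped to the nearest physician-containing combination",
      n_mapped), call. = FALSE)
  }
  factor(out, levels = combo_levels())
}

period_cols <- function(window) {
  switch(window,
         year = c("post", "late"),
         pre = "pre", post = "post", late = "late",
         stop(sprintf("unknown window '%s'", window), call. = FALSE))
}

window_cost <- function(cohort, sector, window) {
  cols <- cost_column(sector, period_cols(window))
  rowSums(as.matrix(cohort[, cols, drop = FALSE]), na.rm = TRUE)
}

#' Classify every record of a cohort
#'
#' Adds/overwrites `service_combo` from the sector costs summed over a
#' period window (default the year after randomization, i.e. the `post`
#' plus `late` periods).
#'
#' @param cohort A cohort tibble.
#' @param window `"year"`, `"pre"`, `"post"`, or `"late"`.
#' @return The cohort with an updated `service_combo` column.
#' @export
classify_services <- function(cohort, window = "year") {
  cohort$service_combo <- classify_service_combination(
    window_cost(cohort, "physician", window),
    window_cost(cohort, "outpatient", window),
    window_cost(cohort, "inpatient", window)
  )
  cohort
}

#' Boxplot (IQR) outlier trimming of a cost vector
#'
#' Keeps the values inside the Tukey fences
#' `[Q1 - factor * IQR, Q3 + factor * IQR]`, with quartiles computed on
#' the input by linear interpolation between order statistics (the type-7
#' quantile convention, recorded in the report so results are auditable).
#' Inpatient costs must not be passed through this operation — hospital
#' admissions are few and their costs are legitimately extreme — and the
#' cohort-level wrapper [trim_cohort_costs()] enforces that.
#'
#' @param costs Non-empty numeric vector of non-negative costs.
#' @param factor IQR multiplier (> 0), default 1.5.
#' @param arm,period,sector Optional labels recorded in the report.
#' @return A list with `kept` (the retained values, in input order) and
#'   `report`, a one-row tibble with `arm`, `period`, `sector`,
#'   `n_before`, `n_removed`, `lower_fence`, `upper_fence`,
#'   `quantile_type`.
#' @examples
#' trim_outliers(c(1:9, 100))
#' @export
trim_outliers <- function(costs, factor = 1.5, arm = NA_character_,
                          period = NA_character_, sector = NA_character_) {
  if (length(costs) == 0) stop("empty cost vector", call. = FALSE)
  if (!is.numeric(costs) || any(!is.finite(costs))) {
    stop("costs must be finite numbers", call. = FALSE)
  }
  if (any(costs < 0)) stop("negative cost", call. = FALSE)
  check_number(factor, "factor", lower = 0, strict_lower = TRUE)
  q <- quantile(costs, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lower <- q[1] - factor * iqr
  upper <- q[2] + factor * iqr
  keep <- costs >= lower & costs <= upper
  list(
    kept = costs[keep],
    report = tibble::tibble(
      arm = arm, period = period, sector = sector,
      n_before = length(costs), n_removed = sum(!keep),
      lower_fence = lower, upper_fence = upper,
      quantile_type = 7L
    )
  )
}

#' Trim cost outliers across a cohort
#'
#' Applies [trim_outliers()] separately per arm, per period, and per
#' sector to the *positive* physician and outpatient cost observations
#' (fences among users; zero costs mean no service use, not cheap use).
#' Trimmed observations are set to `NA` so a record trimmed in one sector
#' stays in the analysis for the others. Inpatient costs are never
#' trimmed.
#'
#' @param cohort A cohort tibble.
#' @param factor IQR multiplier, default 1.5.
#' @param periods Periods to trim (default all three).
#' @return A list with `cohort` (trimmed cells set `NA`) and `report`
#'   (one row per arm x period x sector).
#' @export
trim_cohort_costs <- function(cohort, factor = 1.5,
                              periods = period_levels()) {
  reports <- list()
  for (arm in levels(droplevels(factor(cohort$arm)))) {
    idx_arm <- which(cohort$arm == arm)
    for (period in periods) {
      for (sector in c("physician", "outpatient")) {
        col <- cost_column(sector, period)
        vals <- cohort[[col]][idx_arm]
        pos <- which(!is.na(vals) & vals > 0)
        if (length(pos) == 0) next
        tr <- trim_outliers(vals[pos], factor = factor, arm = arm,
                            period = period, sector = sector)
        drop <- pos[vals[pos] < tr$report$lower_fence |
                      vals[pos] > tr$report$upper_fence]
        cohort[[col]][idx_arm[drop]] <- NA_real_
        reports[[length(reports) + 1L]] <- tr$report
      }
    }
  }
  list(cohort = cohort, report = dplyr::bind_rows(reports))
}

#' Depressed-subgroup extraction
#'
#' Returns exactly the records with baseline PHQ-9 strictly greater
#' than 10 (the moderate-to-severe screening threshold used throughout
#' the analysis).
#'
#' @param cohort A cohort tibble with complete `phq9_baseline`.
#' @return The subset tibble.
#' @export
subgroup_depressed <- function(cohort) {
  if (anyNA(cohort$phq9_baseline)) {
    stop("phq9_baseline must be complete", call. = FALSE)
  }
  cohort[cohort$phq9_baseline > 10, ]
}

#' Per-arm descriptive summary of outcomes
#'
#' Means, s.d. and ranges of PHQ-9 and EQ-5D-5L at baseline and 12 weeks
#' per arm, with within-arm changes — baseline minus 12 weeks for PHQ-9
#' (improvement positive) and 12 weeks minus baseline for EQ-5D — and
#' bootstrap percentile confidence intervals for the changes. Changes use
#' records with observed 12-week outcomes. Empty arms are dropped with a
#' warning; single-record arms report `sd = 0` flagged via `sd_defined`.
#'
#' @param cohort A cohort tibble.
#' @param n_boot Bootstrap replicates for the change CIs.
#' @param conf Confidence level.
#' @param seed Integer seed for the bootstrap.
#' @return A tibble, one row per arm and measure (`phq9`, `eq5d`).
#' @export
descriptive_summary <- function(cohort, n_boot = 500, conf = 0.95,
                                seed = 1L) {
  lv <- if (is.factor(cohort$arm)) levels(cohort$arm)
  else unique(as.character(cohort$arm))
  arms <- lv[lv %in% as.character(cohort$arm)]
  empty <- setdiff(lv, arms)
  if (length(empty)) warning("empty arm(s) omitted: ",
                             paste(empty, collapse = ", "), call. = FALSE)
  alpha <- (1 - conf) / 2
  with_seed(seed, purrr::map_dfr(arms, function(a) {
    sub <- cohort[cohort$arm == a, ]
    purrr::map_dfr(c("phq9", "eq5d"), function(measure) {
      b <- sub[[paste0(measure, "_baseline")]]
      w <- sub[[paste0(measure, "_12wk")]]
      cc <- !is.na(w)
      chg <- if (measure == "phq9") b[cc] - w[cc] else w[cc] - b[cc]
      ci <- if (length(chg) >= 2) {
        boots <- vapply(seq_len(n_boot), function(i) {
          mean(chg[sample.int(length(chg), replace = TRUE)])
        }, numeric(1))
        quantile(boots, c(alpha, 1 - alpha), names = FALSE)
      } else c(NA_real_, NA_real_)
      tibble::tibble(
        arm = a, measure = measure, n = nrow(sub), n_12wk = sum(cc),
        baseline_mean = mean(b),
        baseline_sd = if (length(b) > 1) sd(b) else 0,
        baseline_min = min(b), baseline_max = max(b),
        wk12_mean = mean(w, na.rm = TRUE),
        wk12_sd = if (sum(cc) > 1) sd(w, na.rm = TRUE) else 0,
        change = mean(chg),
        change_lo = ci[1], change_hi = ci[2],
        sd_defined = nrow(sub) > 1
      )
    })
  })) |>
    dplyr::mutate(arm = factor(.data$arm, levels = arms))
}

#' @importFrom stats dnorm
#' @importFrom utils head
NULL
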