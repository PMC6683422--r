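#' Service-mix probabilities over the five service-use combinations
#'
#' The cost model splits an arm's participants into five mutually
#' exclusive service-use combinations for the year after randomization:
#' no services, physician only, physician + outpatient, physician +
#' inpatient, and physician + outpatient + inpatient. A `service_mix`
#' holds the probabilities of these branches; they must be in \[0,1\] and
#' sum to 1 (tolerance 1e-9).
#'
#' @param p_none,p_phys,p_phys_out,p_phys_inp,p_all Branch probabilities.
#' @return A named numeric vector of class `service_mix`.
#' @examples
#' service_mix(0.0164, 0.4098, 0.4809, 0, 0.0929)
#' @export
service_mix <- function(p_none, p_phys, p_phys_out, p_phys_inp, p_all) {
  p <- c(none = p_none, phys_only = p_phys, phys_out = p_phys_out,
         phys_inp = p_phys_inp, phys_out_inp = p_all)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort_field("service_mix", "probabilities must be finite and in [0,1]")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    abort_field("service_mix",
                sprintf("probabilities must sum to 1 (got %.12f)", sum(p)))
  }
  structure(p, class = "service_mix")
}

#' @rdname service_mix
#' @param counts Numeric vector of 5 branch counts (order: none, physician
#'   only, physician + outpatient, physician + inpatient, all three);
#'   normalized by their sum.
#' @export
service_mix_from_counts <- function(counts) {
  stopifnot(length(counts) == 5, all(counts >= 0), sum(counts) > 0)
  p <- counts / sum(counts)
  service_mix(p[1], p[2], p[3], p[4], p[5])
}

#' @export
print.service_mix <- function(x, ...) {
  cat("<service_mix> ",
      paste(sprintf("%s=%.4f", names(unclass(x)), unclass(x)),
            collapse = " "), "\n")
  invisible(x)
}

#' Estimate the service mix of one arm from a classified cohort
#'
#' Branch frequencies are computed from the `service_combo` column
#' (see [classify_services()]): category counts divided by arm size, so
#' they always sum to exactly 1.
#'
#' @param cohort A cohort tibble with `arm` and `service_combo`.
#' @param arm Arm label to estimate; must be present in the cohort.
#' @return A [service_mix()].
#' @export
estimate_service_mix <- function(cohort, arm) {
  sub <- cohort[cohort$arm == arm, ]
  if (nrow(sub) == 0) {
    stop(sprintf("no records for arm '%s'", arm), call. = FALSE)
  }
  combo <- factor(sub$service_combo, levels = combo_levels())
  if (anyNA(combo)) stop("unclassified service_combo values", call. = FALSE)
  service_mix_from_counts(as.numeric(table(combo)))
}

#' @rdname estimate_service_mix
#' @description `pooled_service_mix()` pools the branch frequencies over
#'   all arms — the identical-service-mix sensitivity scenario in which
#'   every arm is assigned the whole-cohort mix.
#' @export
pooled_service_mix <- function(cohort) {
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  combo <- factor(cohort$service_combo, levels = combo_levels())
  if (anyNA(combo)) stop("unclassified service_combo values", call. = FALSE)
  service_mix_from_counts(as.numeric(table(combo)))
}

#' Decision-tree expected one-year cost per participant
#'
#' Combines a [service_mix()] with mean sector costs among users: each
#' branch contributes its probability times the sum of the sector means it
#' involves, and the no-services branch contributes zero. For sector user
#' means `C_p`, `C_o`, `C_i`,
#' `total = p_phys*C_p + p_phys_out*(C_p+C_o) + p_phys_inp*(C_p+C_i) +
#' p_all*(C_p+C_o+C_i)`.
#'
#' @param mix A [service_mix()].
#' @param means Named numeric vector with entries `physician`,
#'   `outpatient`, `inpatient` — mean annual cost among users (2017 CAD).
#' @return A one-row tibble with `total` and the five branch
#'   contributions (`c_none`, `c_phys_only`, `c_phys_out`, `c_phys_inp`,
#'   `c_phys_out_inp`); `total` equals their sum.
#' @examples
#' mix <- service_mix_from_counts(c(3, 75, 88, 0, 17))
#' expected_cost(mix, c(physician = 559, outpatient = 1144.49,
#'                      inpatient = 10670.27))
#' @export
expected_cost <- function(mix, means) {
  if (!inherits(mix, "service_mix")) {
    mix <- do.call(service_mix, as.list(unname(mix)))
  }
  stopifnot(all(sector_levels() %in% names(means)))
  if (any(!is.finite(means[sector_levels()])) ||
      any(means[sector_levels()] < 0)) {
    abort_field("means", "sector means must be finite and >= 0")
  }
  cp <- unname(means["physician"])
  co <- unname(means["outpatient"])
  ci <- unname(means["inpatient"])
  branch_cost <- c(none = 0, phys_only = cp, phys_out = cp + co,
                   phys_inp = cp + ci, phys_out_inp = cp + co + ci)
  contrib <- unclass(mix) * branch_cost
  tibble::tibble(
    total = sum(contrib),
    c_none = contrib[["none"]],
    c_phys_only = contrib[["phys_only"]],
    c_phys_out = contrib[["phys_out"]],
    c_phys_inp = contrib[["phys_inp"]],
    c_phys_out_inp = contrib[["phys_out_inp"]]
  )
}

#' Per-arm decision-tree expected costs
#'
#' Applies [expected_cost()] to every arm of a mix table and a sector-mean
#' table (such as [adjusted_arm_means()] output or the bundled reference
#' user means).
#'
#' @param mixes Named list of [service_mix()] per arm, or a classified
#'   cohort tibble (mixes are then estimated per arm).
#' @param sector_means Tibble with columns `arm`, `sector`, `estimate`
#'   (or `mean`).
#' @param pooled If `TRUE`, every arm uses the pooled mix (sensitivity
#'   scenario); requires `mixes` to be a cohort.
#' @return Tibble with one row per arm: `arm`, `total`, branch
#'   contributions.
#' @export
arm_expected_costs <- function(mixes, sector_means, pooled = FALSE) {
  mean_col <- if ("estimate" %in% names(sector_means)) "estimate" else "mean"
  arms <- unique(as.character(sector_means$arm))
  if (is.data.frame(mixes)) {
    cohort <- mixes
    mixes <- if (pooled) {
      pm <- pooled_service_mix(cohort)
      setNames(rep(list(pm), length(arms)), arms)
    } else {
      setNames(lapply(arms, function(a) estimate_service_mix(cohort, a)), arms)
    }
  }
  purrr::map_dfr(arms, function(a) {
    sm <- sector_means[sector_means$arm == a, ]
    means <- setNames(sm[[mean_col]], as.character(sm$sector))
    dplyr::bind_cols(tibble::tibble(arm = a), expected_cost(mixes[[a]], means))
  }) |>
    dplyr::mutate(arm = factor(.data$arm, levels = arms))
}
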