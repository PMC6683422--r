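qaly_scenarios <- function() {
  c("carry_forward", "linear_return", "immediate_return")
}

# weights on (u0, u12) for each scenario over the 52-week horizon:
# all scenarios share the linear 0-12 week segment, area (12/52)*(u0+u12)/2;
# the 12-52 week segment is u12 held flat (carry_forward), a linear return
# to u0 (linear_return), or u0 held flat (immediate_return)
qaly_weights <- function(scenario) {
  switch(scenario,
         carry_forward = c(u0 = 6 / 52, u12 = 46 / 52),
         linear_return = c(u0 = 26 / 52, u12 = 26 / 52),
         immediate_return = c(u0 = 46 / 52, u12 = 6 / 52))
}

#' One-year QALY from baseline and 12-week utilities
#'
#' Area under the piecewise-linear utility path over a 52-week horizon
#' with the 12-week measurement at 12/52 of the year. The baseline-to-12-
#' week segment is linear interpolation in every scenario. After 12
#' weeks: `carry_forward` (base case) holds the 12-week utility constant
#' to one year; `linear_return` lets the treatment effect decay linearly
#' back to baseline by 52 weeks; `immediate_return` drops back to the
#' baseline utility at 12 weeks. No discounting (one-year horizon).
#'
#' @param u0,u12 Utilities in \[0,1\] (vectorized).
#' @param scenario One of `"carry_forward"`, `"linear_return"`,
#'   `"immediate_return"`.
#' @return Numeric vector of QALYs (in \[0,1\] for utilities in \[0,1\]).
#' @examples
#' qaly_auc(0.86, 0.88)                      # 0.87769...
#' qaly_auc(0.86, 0.88, "immediate_return")
#' @export
qaly_auc <- function(u0, u12, scenario = c("carry_forward", "linear_return",
                                           "immediate_return")) {
  scenario <- match.arg(scenario)
  if (any(!is.finite(u0)) || any(u0 < 0) || any(u0 > 1)) {
    abort_field("u0", "utilities must be in [0, 1]")
  }
  if (any(!is.finite(u12)) || any(u12 < 0) || any(u12 > 1)) {
    abort_field("u12", "utilities must be in [0, 1]")
  }
  w <- qaly_weights(scenario)
  unname(w["u0"] * u0 + w["u12"] * u12)
}

#' Per-arm QALYs with uncertainty and differences versus a reference arm
#'
#' Applies [qaly_auc()] to each arm's baseline and (typically
#' covariate-adjusted) 12-week utilities. Standard errors propagate by
#' the delta method — the QALY is linear in `(u0, u12)`, so
#' `se^2 = w0^2 se0^2 + w12^2 se12^2` — and differences versus the
#' reference arm are reported with independence-based standard errors.
#'
#' @param utilities Tibble with columns `arm`, `u0`, `u12` and optionally
#'   `se0`, `se12`.
#' @param scenario QALY persistence scenario, see [qaly_auc()].
#' @param reference Arm against which differences are reported (default
#'   the last arm, the stepped-care pathway in the reference trial).
#' @return Tibble with `arm`, `qaly`, `se`, `diff_vs_ref`, `diff_se`.
#' @export
arm_qaly <- function(utilities,
                     scenario = c("carry_forward", "linear_return",
                                  "immediate_return"),
                     reference = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(all(c("arm", "u0", "u12") %in% names(utilities)))
  arms <- as.character(utilities$arm)
  reference <- reference %||% arms[length(arms)]
  if (!reference %in% arms) {
    stop(sprintf("reference arm '%s' missing", reference), call. = FALSE)
  }
  w <- qaly_weights(scenario)
  w0 <- unname(w["u0"]); w12 <- unname(w["u12"])
  se0 <- utilities[["se0"]] %||% rep(0, nrow(utilities))
  se12 <- utilities[["se12"]] %||% rep(0, nrow(utilities))
  out <- tibble::tibble(
    arm = utilities$arm,
    qaly = qaly_auc(utilities$u0, utilities$u12, scenario),
    se = sqrt(w0^2 * se0^2 + w12^2 * se12^2)
  )
  ref_row <- which(arms == reference)
  out$diff_vs_ref <- out$qaly - out$qaly[ref_row]
  out$diff_se <- sqrt(out$se^2 + out$se[ref_row]^2)
  out$diff_se[ref_row] <- 0
  out
}
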