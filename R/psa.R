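# inverse-CDF sampler for a normal truncated to [lo, hi]
rtruncnorm <- function(n, mean, sd, lo = 0, hi = 1) {
  if (sd == 0) return(rep(mean, n))
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

#' Monte Carlo draws for probabilistic sensitivity analysis
#'
#' Draws `n_iter` (cost, QALY) pairs per arm from the arm-level sampling
#' distributions: gamma parameterized by (mean, s.d.) for costs and
#' normal truncated to \[0,1\] for QALYs by default. Arms are sampled
#' independently; a zero s.d. collapses the draw to the mean. Draws are
#' reproducible for a fixed seed.
#'
#' @param dists Tibble with columns `arm`, `cost_mean`, `cost_sd`,
#'   `qaly_mean`, `qaly_sd` (e.g. [ref_ce_summary()] or a
#'   [psa_inputs()] result).
#' @param n_iter Number of iterations (default 10,000).
#' @param seed Integer seed.
#' @param cost_family `"gamma"` or `"normal"`.
#' @param qaly_family `"truncnorm"` or `"normal"`.
#' @return A tibble of class `psa_draws` in long format: `iteration`,
#'   `arm`, `cost`, `qaly`.
#' @export
simulate_psa <- function(dists, n_iter = 10000, seed = 1L,
                         cost_family = c("gamma", "normal"),
                         qaly_family = c("truncnorm", "normal")) {
  cost_family <- match.arg(cost_family)
  qaly_family <- match.arg(qaly_family)
  stopifnot(all(c("arm", "cost_mean", "cost_sd", "qaly_mean", "qaly_sd")
                %in% names(dists)))
  if (any(dists$cost_sd < 0) || any(dists$qaly_sd < 0)) {
    abort_field("sd", "sampling s.d. must be >= 0")
  }
  check_number(n_iter, "n_iter", lower = 1)
  arms <- as.character(dists$arm)
  out <- with_seed(seed, purrr::map_dfr(seq_along(arms), function(j) {
    cm <- dists$cost_mean[j]; cs <- dists$cost_sd[j]
    qm <- dists$qaly_mean[j]; qs <- dists$qaly_sd[j]
    cost <- if (cs == 0) rep(cm, n_iter)
    else if (cost_family == "gamma") {
      rgamma(n_iter, shape = gamma_shape(cm, cs),
             scale = gamma_scale(cm, cs))
    } else rnorm(n_iter, cm, cs)
    qaly <- if (qaly_family == "truncnorm") {
      rtruncnorm(n_iter, qm, qs, 0, 1)
    } else if (qs == 0) rep(qm, n_iter) else rnorm(n_iter, qm, qs)
    tibble::tibble(iteration = seq_len(n_iter), arm = arms[j],
                   cost = cost, qaly = qaly)
  }))
  out$arm <- factor(out$arm, levels = arms)
  class(out) <- c("psa_draws", class(out))
  out
}

draws_wide <- function(draws, value) {
  m <- tidyr::pivot_wider(draws[, c("iteration", "arm", value)],
                          names_from = "arm",
                          values_from = dplyr::all_of(value))
  as.matrix(m[order(m$iteration), -1, drop = FALSE])
}

arm_means <- function(x, arm) {
  if (inherits(x, "psa_draws") || all(c("iteration", "cost", "qaly")
                                      %in% names(x))) {
    sub <- x[x$arm == arm, ]
    if (nrow(sub) == 0) stop(sprintf("arm '%s' missing", arm), call. = FALSE)
    c(cost = mean(sub$cost), qaly = mean(sub$qaly))
  } else {
    row <- x[x$arm == arm, ]
    if (nrow(row) == 0) stop(sprintf("arm '%s' missing", arm), call. = FALSE)
    c(cost = row$cost_mean, qaly = row$qaly_mean)
  }
}

#' Incremental cost-effectiveness ratio between two arms
#'
#' Computes the mean cost and QALY differences (`arm_a` minus `arm_b`)
#' and classifies the quadrant: `dominant` (cheaper, more effective —
#' no ratio needed), `dominated` (costlier, less effective), or
#' `trade-off`, in which case the ICER `delta_cost / delta_qaly` is
#' reported. A zero QALY difference is flagged `degenerate` and yields
#' no ratio.
#'
#' @param x A `psa_draws` tibble (means taken over iterations) or a
#'   summary tibble with `arm`, `cost_mean`, `qaly_mean`.
#' @param arm_a,arm_b Arm labels; differences are `arm_a - arm_b`.
#' @return One-row tibble: `arm_a`, `arm_b`, `delta_cost`, `delta_qaly`,
#'   `icer`, `classification`.
#' @export
icer <- function(x, arm_a, arm_b) {
  a <- arm_means(x, arm_a); b <- arm_means(x, arm_b)
  dc <- unname(a["cost"] - b["cost"])
  dq <- unname(a["qaly"] - b["qaly"])
  cls <- if (dc < 0 && dq > 0) "dominant"
  else if (dc > 0 && dq < 0) "dominated"
  else "trade-off"
  degenerate <- cls == "trade-off" && dq == 0
  tibble::tibble(
    arm_a = arm_a, arm_b = arm_b, delta_cost = dc, delta_qaly = dq,
    icer = if (cls == "trade-off" && !degenerate) dc / dq else NA_real_,
    classification = cls, degenerate = degenerate
  )
}

#' Per-iteration incremental net monetary benefit
#'
#' `NMB_i = wtp * (qaly_a,i - qaly_b,i) - (cost_a,i - cost_b,i)`: positive
#' values mean `arm_a` is cost-effective against `arm_b` at
#' willingness-to-pay `wtp` in that iteration.
#'
#' @param draws A `psa_draws` tibble.
#' @param arm_a,arm_b Arm labels.
#' @param wtp Willingness-to-pay per QALY.
#' @return Numeric vector of length `n_iter` in iteration order.
#' @export
incremental_nmb <- function(draws, arm_a, arm_b, wtp) {
  a <- draws[draws$arm == arm_a, ]
  b <- draws[draws$arm == arm_b, ]
  if (nrow(a) == 0 || nrow(b) == 0) stop("arm missing", call. = FALSE)
  if (nrow(a) != nrow(b)) stop("mismatched draw counts", call. = FALSE)
  a <- a[order(a$iteration), ]; b <- b[order(b$iteration), ]
  wtp * (a$qaly - b$qaly) - (a$cost - b$cost)
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the probability an arm is
#' cost-effective is the fraction of Monte Carlo iterations in which it
#' attains the maximum net monetary benefit `wtp * qaly - cost` among
#' all arms; ties split their iteration's credit equally. Probabilities
#' therefore sum to 1 over arms at every grid point.
#'
#' @param draws A `psa_draws` tibble with at least two arms.
#' @param wtp_grid Willingness-to-pay grid (default $0 to $200,000 in
#'   $1,000 steps).
#' @return A tibble of class `depcea_ceac`: `wtp`, `arm`, `probability`.
#' @export
ceac <- function(draws, wtp_grid = seq(0, 200000, by = 1000)) {
  if (length(wtp_grid) == 0) stop("empty willingness-to-pay grid",
                                  call. = FALSE)
  arms <- levels(factor(draws$arm))
  if (length(arms) < 2) stop("need at least two arms", call. = FALSE)
  C <- draws_wide(draws, "cost")
  Q <- draws_wide(draws, "qaly")
  out <- purrr::map_dfr(wtp_grid, function(w) {
    nmb <- w * Q - C
    best <- nmb == matrixStats_rowMaxs(nmb)
    credit <- best / rowSums(best)
    tibble::tibble(wtp = w, arm = colnames(nmb),
                   probability = unname(colMeans(credit)))
  })
  out$arm <- factor(out$arm, levels = arms)
  class(out) <- c("depcea_ceac", class(out))
  out
}

# row maxima without a matrixStats dependency
matrixStats_rowMaxs <- function(m) {
  do.call(pmax, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

#' Incremental cost-effectiveness scatter points
#'
#' Pairs each iteration's QALY and cost differences (`arm_a - arm_b`) for
#' plotting on the incremental cost-effectiveness plane. A point lies
#' below the willingness-to-pay line when
#' `delta_cost < wtp * delta_qaly`, i.e. `arm_a` is cost-effective in
#' that iteration; [fraction_below()] reports that share, which equals
#' the pairwise CEAC value at `wtp` on the same draws.
#'
#' @inheritParams incremental_nmb
#' @return A tibble of class `depcea_scatter`: `iteration`, `delta_qaly`,
#'   `delta_cost`.
#' @export
scatter_points <- function(draws, arm_a, arm_b) {
  a <- draws[draws$arm == arm_a, ]
  b <- draws[draws$arm == arm_b, ]
  if (nrow(a) == 0 || nrow(b) == 0) stop("arm missing", call. = FALSE)
  if (nrow(a) != nrow(b)) stop("mismatched draw counts", call. = FALSE)
  a <- a[order(a$iteration), ]; b <- b[order(b$iteration), ]
  out <- tibble::tibble(
    iteration = a$iteration,
    delta_qaly = a$qaly - b$qaly,
    delta_cost = a$cost - b$cost
  )
  attr(out, "arms") <- c(arm_a, arm_b)
  class(out) <- c("depcea_scatter", class(out))
  out
}

#' @rdname scatter_points
#' @param points A `depcea_scatter` tibble.
#' @param wtp Willingness-to-pay per QALY (default $50,000).
#' @export
fraction_below <- function(points, wtp = 50000) {
  mean(points$delta_cost < wtp * points$delta_qaly)
}
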