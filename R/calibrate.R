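# Latent-normal calibration for instrument-bounded margins.
#
# PHQ-9 scores are integers on 0..27 with a strong floor effect; EQ-5D-5L
# utilities live in [0,1] with a ceiling at full health. Both are modelled
# as a latent normal censored (clamped) at the instrument bounds — rounded
# to integers for PHQ-9 — and the latent (mu, sigma) is solved so the
# *observed* (censored) distribution matches published targets. Censoring
# rather than rejection-truncation is used deliberately: it produces the
# realistic point masses at the bounds and can reproduce the overdispersion
# (s.d. > mean) seen in screening-population PHQ-9 data, which a
# left-truncated normal cannot.

# pmf of round(clamp(N(mu, sigma), lo, hi)) over integers lo..hi
phq9_pmf <- function(mu, sigma, lo = 0L, hi = 27L) {
  k <- lo:hi
  up <- ifelse(k == hi, Inf, k + 0.5)
  dn <- ifelse(k == lo, -Inf, k - 0.5)
  pnorm(up, mu, sigma) - pnorm(dn, mu, sigma)
}

phq9_moments <- function(mu, sigma, lo = 0L, hi = 27L) {
  p <- phq9_pmf(mu, sigma, lo, hi)
  k <- lo:hi
  m <- sum(k * p)
  list(
    mean = m,
    sd = sqrt(sum((k - m)^2 * p)),
    p_gt10 = sum(p[k > 10])
  )
}

# Solve latent (mu, sigma) so the censored-rounded score matches a target
# mean plus either a target sd or a target P(score > 10).
calibrate_phq9 <- function(mean, sd = NULL, p_gt10 = NULL, lo = 0L, hi = 27L) {
  check_number(mean, "mean", lower = lo, upper = hi)
  if (is.null(sd) && is.null(p_gt10)) {
    abort_field("sd", "supply a target sd or a target p_gt10")
  }
  obj <- function(th) {
    m <- phq9_moments(th[1], exp(th[2]), lo, hi)
    if (!is.null(p_gt10)) {
      (m$mean - mean)^2 + 400 * (m$p_gt10 - p_gt10)^2
    } else {
      (m$mean - mean)^2 + (m$sd - sd)^2
    }
  }
  start <- c(mean, log(max(sd %||% (mean / 2), 0.5)))
  o <- stats::optim(start, obj, control = list(reltol = 1e-14, maxit = 5000))
  mu <- o$par[1]; sigma <- exp(o$par[2])
  ach <- phq9_moments(mu, sigma, lo, hi)
  list(mu = mu, sigma = sigma, lo = lo, hi = hi,
       mean = ach$mean, sd = ach$sd, p_gt10 = ach$p_gt10)
}

# Moments of clamp(N(mu, sigma), lo, hi) — closed form via the truncated
# normal moments on (lo, hi) plus the censored point masses.
censnorm_moments <- function(mu, sigma, lo = 0, hi = 1) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  z <- pnorm(b) - pnorm(a)
  if (z < 1e-12) {
    m <- if (mu < lo) lo else hi
    return(list(mean = m, sd = 0))
  }
  et <- mu + sigma * (dnorm(a) - dnorm(b)) / z
  vt <- sigma^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z -
                     ((dnorm(a) - dnorm(b)) / z)^2)
  m1 <- lo * pnorm(a) + hi * (1 - pnorm(b)) + z * et
  m2 <- lo^2 * pnorm(a) + hi^2 * (1 - pnorm(b)) + z * (vt + et^2)
  list(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

calibrate_utility <- function(mean, sd, lo = 0, hi = 1) {
  check_number(mean, "mean", lower = lo, upper = hi)
  check_number(sd, "sd", lower = 0)
  if (sd == 0) return(list(mu = mean, sigma = 0, lo = lo, hi = hi,
                           mean = mean, sd = 0))
  obj <- function(th) {
    m <- censnorm_moments(th[1], exp(th[2]), lo, hi)
    (m$mean - mean)^2 + (m$sd - sd)^2
  }
  o <- stats::optim(c(mean, log(sd)), obj,
                    control = list(reltol = 1e-14, maxit = 5000))
  mu <- o$par[1]; sigma <- exp(o$par[2])
  ach <- censnorm_moments(mu, sigma, lo, hi)
  list(mu = mu, sigma = sigma, lo = lo, hi = hi,
       mean = ach$mean, sd = ach$sd)
}

# Transform standard-normal copula draws into the calibrated margins.
z_to_phq9 <- function(z, cal) {
  as.integer(round(pmin(pmax(cal$mu + cal$sigma * z, cal$lo), cal$hi)))
}

z_to_utility <- function(z, cal) {
  pmin(pmax(cal$mu + cal$sigma * z, cal$lo), cal$hi)
}

# gamma parameterized by mean and sd: shape = mean^2/sd^2, scale = sd^2/mean
gamma_shape <- function(mean, sd) (mean / sd)^2
gamma_scale <- function(mean, sd) sd^2 / mean

z_to_gamma <- function(z, mean, sd) {
  if (mean <= 0) return(rep(0, length(z)))
  if (sd <= 0) return(rep(mean, length(z)))
  qgamma(pnorm(z), shape = gamma_shape(mean, sd),
         scale = gamma_scale(mean, sd))
}

#' @importFrom stats dnorm optim plogis uniroot rchisq
NULL
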