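# builds a two-arm cohort where the 12-week outcome follows a known
# linear generating model: y = a + b * baseline + delta * I(arm B) + noise
ols_cohort <- function(n, a = 0.5, b = 0.4, delta = 0.02, sd = 0.05,
                       seed = 1) {
  withr::local_seed(seed)
  arm <- rep(c("A", "B"), each = n)
  baseline <- runif(2 * n, 0.4, 1)
  y <- a + b * baseline + delta * (arm == "B") + rnorm(2 * n, 0, sd)
  tibble::tibble(
    id = as.character(seq_len(2 * n)), arm = factor(arm),
    age = 50, sex = "female",
    phq9_baseline = 5L, phq9_12wk = 5L,
    eq5d_baseline = baseline, eq5d_12wk = pmin(pmax(y, 0), 1)
  )
}

test_that("OLS adjustment recovers a known arm effect", {
  co <- ols_cohort(10000, delta = 0.02, seed = 2)
  fit <- fit_outcome_ols(co, "eq5d_12wk")
  est <- tidy(fit)
  diff <- est$estimate[est$arm == "B"] - est$estimate[est$arm == "A"]
  se <- sqrt(sum(est$se^2))
  expect_lt(abs(diff - 0.02), 2 * se)

  # symmetric arms give identical adjusted means
  sym <- tiny_cohort(n = 6)
  fs <- tidy(fit_outcome_ols(sym, "eq5d_12wk"))
  expect_equal(fs$estimate[1], fs$estimate[2], tolerance = 1e-10)
})

test_that("with no baseline effect adjusted means equal raw means", {
  co <- ols_cohort(8000, b = 0, delta = 0.03, seed = 3)
  est <- tidy(fit_outcome_ols(co, "eq5d_12wk"))
  raw <- tapply(co$eq5d_12wk, co$arm, mean)
  for (a in c("A", "B")) {
    expect_lt(abs(est$estimate[est$arm == a] - raw[[a]]),
              2 * est$se[est$arm == a])
  }
})

test_that("OLS errors on an empty arm", {
  co <- ols_cohort(50, seed = 4)
  co$arm <- factor(co$arm, levels = c("A", "B", "C"))
  expect_error(fit_outcome_ols(co, "eq5d_12wk"), "'C'")
})

# gamma-cost cohort with linear mean structure among users
gamma_cohort <- function(n, intercept = 500, age_coef = 5, delta = 50,
                         cv = 0.5, seed = 1) {
  withr::local_seed(seed)
  arm <- rep(c("A", "B"), each = n)
  age <- runif(2 * n, 20, 80)
  mu <- intercept + age_coef * age + delta * (arm == "B")
  shape <- 1 / cv^2
  y <- rgamma(2 * n, shape = shape, scale = mu / shape)
  out <- tibble::tibble(
    id = as.character(seq_len(2 * n)), arm = factor(arm),
    age = age, sex = rep_len(c("female", "male"), 2 * n),
    phq9_baseline = sample(0L:15L, 2 * n, replace = TRUE),
    phq9_12wk = 5L, eq5d_baseline = 0.8, eq5d_12wk = 0.8,
    service_combo = factor("phys_only",
                           levels = depcea:::combo_levels())
  )
  for (col in depcea:::cost_columns()) out[[col]] <- 0
  out$cost_physician_post <- y
  out
}

test_that("identity-link gamma GLM recovers known coefficients at n = 20,000", {
  co <- gamma_cohort(10000, age_coef = 5, seed = 5)
  fit <- fit_cost_glm(co, "physician", period = "post",
                      covariates = "age")
  # independent cross-check: stats::glm with the same family and link
  ref <- stats::glm(
    cost_physician_post ~ arm + age, data = co,
    family = stats::Gamma(link = "identity"),
    start = coef(lm(cost_physician_post ~ arm + age, data = co)))
  X <- model.matrix(~ arm + age, data = co)
  mine <- depcea:::gamma_identity_glm(X, co$cost_physician_post)
  expect_equal(unname(mine$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  age_se <- sqrt(mine$vcov[3, 3])
  expect_lt(abs(mine$coefficients[3] - 5), 2 * age_se)

  # constant costs: intercept-only prediction equals the constant
  cc <- gamma_cohort(40, seed = 6)
  cc$cost_physician_post <- 250
  est <- tidy(fit_cost_glm(cc, "physician", period = "post",
                           covariates = "age"))
  expect_equal(est$estimate, c(250, 250), tolerance = 1e-6)
})

test_that("null arm effects are not invented by the cost GLM", {
  co <- gamma_cohort(10000, delta = 0, seed = 7)
  est <- tidy(fit_cost_glm(co, "physician", period = "post",
                           covariates = "age"))
  diff <- diff(est$estimate)
  expect_lt(abs(diff), 2 * sqrt(sum(est$se^2)))
})

test_that("gamma GLM rejects non-positive costs and names missing arms", {
  X <- cbind(1, rnorm(20))
  expect_error(depcea:::gamma_identity_glm(X, c(rep(1, 19), 0)),
               "filter to service users")
  co <- gamma_cohort(30, seed = 8)
  co$cost_physician_post[co$arm == "B"] <- 0
  expect_error(fit_cost_glm(co, "physician", period = "post"),
               "'B'")
})

test_that("Rubin pooling of model fits equals the mean of per-fit estimates", {
  co <- gamma_cohort(300, seed = 9)
  sets <- lapply(1:3, function(i) {
    d <- co
    d$cost_physician_post <- d$cost_physician_post * (1 + 0.01 * i)
    d
  })
  im <- depcea:::new_imputed_set(sets, 3, 1L)
  pooled <- tidy(fit_cost_glm(im, "physician", period = "post",
                              covariates = "age"))
  singles <- vapply(sets, function(d) {
    tidy(fit_cost_glm(d, "physician", period = "post",
                      covariates = "age"))$estimate[1]
  }, numeric(1))
  expect_equal(pooled$estimate[1], mean(singles), tolerance = 1e-12)
})

test_that("adjusted arm means fall back per stratum size and flag methods", {
  co <- generate_cohort(small_config(n = 350), seed = 10)
  am <- adjusted_arm_means(co, period = "year")
  expect_setequal(unique(as.character(am$sector)),
                  c("physician", "outpatient", "inpatient"))
  expect_true(all(am$method %in% c("glm", "raw", "zero")))
  expect_true(all(am$se >= 0))

  # small stratum triggers the raw-mean fallback
  small <- co[co$arm != "SCP" | seq_len(nrow(co)) %% 70 == 0, ]
  am2 <- adjusted_arm_means(small, period = "year", min_users = 10)
  expect_true(any(am2$method == "raw"))

  # degenerate covariates: adjusted equals unadjusted user means
  flat <- co
  flat$sex <- "female"; flat$age <- 50; flat$phq9_baseline <- 4L
  am3 <- adjusted_arm_means(flat, period = "year")
  y <- flat$cost_physician_post + flat$cost_physician_late
  for (a in levels(co$arm)) {
    raw <- mean(y[y > 0 & flat$arm == a])
    got <- am3$estimate[am3$arm == a & am3$sector == "physician"]
    expect_equal(got, raw, tolerance = 1e-6)
  }

  ghost <- co
  ghost[ghost$arm == "SC", grep("^cost_", names(ghost))] <- 0
  expect_error(adjusted_arm_means(ghost, period = "year"), "'SC'")
})
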