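ref_dists <- function() ref_ce_summary("all")

test_that("PSA draws are seeded, degenerate at sd = 0, and converge to inputs", {
  d1 <- simulate_psa(ref_dists(), n_iter = 500, seed = 3)
  d2 <- simulate_psa(ref_dists(), n_iter = 500, seed = 3)
  expect_identical(d1, d2)

  zero <- ref_dists()
  zero$cost_sd <- 0; zero$qaly_sd <- 0
  dz <- simulate_psa(zero, n_iter = 50, seed = 1)
  for (a in zero$arm) {
    expect_true(all(dz$cost[dz$arm == a] ==
                      zero$cost_mean[zero$arm == a]))
    expect_true(all(dz$qaly[dz$arm == a] ==
                      zero$qaly_mean[zero$arm == a]))
  }

  d <- simulate_psa(ref_dists(), n_iter = 10000, seed = 4)
  for (i in seq_len(nrow(ref_dists()))) {
    a <- ref_dists()$arm[i]
    cm <- mean(d$cost[d$arm == a])
    expect_lt(abs(cm - ref_dists()$cost_mean[i]),
              3 * ref_dists()$cost_sd[i] / 100)
    qm <- mean(d$qaly[d$arm == a])
    expect_lt(abs(qm - ref_dists()$qaly_mean[i]),
              3 * ref_dists()$qaly_sd[i] / 100)
    expect_true(all(d$qaly[d$arm == a] >= 0 & d$qaly[d$arm == a] <= 1))
  }
  neg <- ref_dists(); neg$cost_sd[1] <- -1
  expect_error(simulate_psa(neg, 10), "sd")
})

test_that("ICER quadrants match the sign-table oracle", {
  # oracle: dominant iff cheaper & more effective, dominated iff the
  # reverse; everything else is a trade-off, with no ratio when dQALY = 0
  for (dc in c(-100, 0, 100)) {
    for (dq in c(-0.01, 0, 0.01)) {
      x <- tibble::tibble(arm = c("A", "B"),
                          cost_mean = c(1000 + dc, 1000),
                          qaly_mean = c(0.8 + dq, 0.8))
      got <- icer(x, "A", "B")
      want <- if (dc < 0 && dq > 0) "dominant"
      else if (dc > 0 && dq < 0) "dominated"
      else "trade-off"
      expect_equal(got$classification, want)
      expect_equal(got$degenerate, want == "trade-off" && dq == 0)
      if (want == "trade-off" && dq != 0) {
        expect_equal(got$icer, dc / dq, tolerance = 1e-9)
      } else {
        expect_true(is.na(got$icer))
      }
    }
  }
  # published point estimates: stepped care dominates treatment as usual
  expect_equal(icer(ref_dists(), "SCP", "TAU")$classification, "dominant")
  trade <- icer(tibble::tibble(arm = c("A", "B"),
                               cost_mean = c(1500, 1000),
                               qaly_mean = c(0.81, 0.80)), "A", "B")
  expect_equal(trade$icer, 500 / 0.01, tolerance = 1e-9)
})

test_that("incremental NMB matches its closed form", {
  d <- simulate_psa(ref_dists(), n_iter = 4000, seed = 5)
  nmb0 <- incremental_nmb(d, "SCP", "ICBT", wtp = 0)
  sp <- scatter_points(d, "SCP", "ICBT")
  expect_equal(nmb0, -sp$delta_cost, tolerance = 1e-9)

  # normal-theory oracle on independent normal draws
  dists <- tibble::tibble(arm = c("A", "B"),
                          cost_mean = c(2000, 1800), cost_sd = c(300, 200),
                          qaly_mean = c(0.85, 0.84), qaly_sd = c(0.01, 0.02))
  dn <- simulate_psa(dists, n_iter = 20000, seed = 6,
                     cost_family = "normal", qaly_family = "normal")
  w <- 50000
  nmb <- incremental_nmb(dn, "A", "B", w)
  mu <- w * (0.85 - 0.84) - (2000 - 1800)
  sig <- sqrt(w^2 * (0.01^2 + 0.02^2) + 300^2 + 200^2)
  expect_lt(abs(mean(nmb) - mu), 3 * sig / sqrt(20000))
  expect_lt(abs(sd(nmb) - sig) / sig, 0.05)
  # large wtp with positive mean dQALY: the QALY term dominates
  big <- incremental_nmb(dn, "A", "B", 1e7)
  expect_gt(mean(big), 0)
  expect_equal(mean(big > 0),
               mean(dn$qaly[dn$arm == "A"] - dn$qaly[dn$arm == "B"] >
                      (dn$cost[dn$arm == "A"] -
                         dn$cost[dn$arm == "B"]) / 1e7))

  short <- d[!(d$arm == "ICBT" & d$iteration > 100), ]
  expect_error(incremental_nmb(short, "SCP", "ICBT", 0), "mismatched")
})

test_that("CEAC probabilities are coherent and match the normal oracle", {
  d <- simulate_psa(ref_dists(), n_iter = 3000, seed = 7)
  cc <- ceac(d, seq(0, 200000, by = 20000))
  sums <- tapply(cc$probability, cc$wtp, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  expect_error(ceac(d, numeric(0)), "empty")

  # a strictly dominant arm owns the whole curve
  dom <- tibble::tibble(arm = c("A", "B"),
                        cost_mean = c(100, 5000), cost_sd = c(0, 0),
                        qaly_mean = c(0.9, 0.5), qaly_sd = c(0, 0))
  dd <- simulate_psa(dom, n_iter = 20, seed = 8)
  cd <- ceac(dd, c(0, 50000))
  expect_true(all(cd$probability[cd$arm == "A"] == 1))
  expect_true(all(cd$probability[cd$arm == "B"] == 0))

  # two-arm normal case: curve equals Phi((w*dE - dC)/sigma_NMB)
  dists <- tibble::tibble(arm = c("A", "B"),
                          cost_mean = c(2000, 1900), cost_sd = c(250, 250),
                          qaly_mean = c(0.85, 0.845), qaly_sd = c(0.008, 0.008))
  dn <- simulate_psa(dists, n_iter = 10000, seed = 9,
                     cost_family = "normal", qaly_family = "normal")
  cn <- ceac(dn, c(0, 25000, 50000, 100000))
  for (w in unique(cn$wtp)) {
    sig <- sqrt(w^2 * 2 * 0.008^2 + 2 * 250^2)
    p_true <- pnorm((w * 0.005 - 100) / sig)
    got <- cn$probability[cn$arm == "A" & cn$wtp == w]
    expect_lt(abs(got - p_true),
              3 * sqrt(p_true * (1 - p_true) / 10000) + 1e-6)
  }
})

test_that("CEAC endpoints rank by cost at wtp 0 and by QALY at high wtp", {
  dists <- tibble::tibble(
    arm = c("cheap_bad", "dear_good"),
    cost_mean = c(1000, 3000), cost_sd = c(100, 100),
    qaly_mean = c(0.6, 0.9), qaly_sd = c(0.005, 0.005))
  d <- simulate_psa(dists, n_iter = 2000, seed = 10)
  cc <- ceac(d, c(0, 200000))
  expect_gt(cc$probability[cc$arm == "cheap_bad" & cc$wtp == 0], 0.99)
  expect_gt(cc$probability[cc$arm == "dear_good" & cc$wtp == 200000], 0.99)
})

test_that("scatter points mirror the pairwise CEAC and symmetric nulls", {
  d <- simulate_psa(ref_dists(), n_iter = 5000, seed = 11)
  two <- d[d$arm %in% c("SCP", "ICBT"), ]
  sp <- scatter_points(two, "SCP", "ICBT")
  expect_equal(nrow(sp), 5000)
  for (w in c(0, 50000, 100000)) {
    cc <- ceac(two, w)
    expect_equal(fraction_below(sp, w),
                 cc$probability[cc$arm == "SCP"], tolerance = 1e-9)
  }
  # identical arm distributions: fraction near one half
  null <- tibble::tibble(arm = c("A", "B"),
                         cost_mean = 2000, cost_sd = 400,
                         qaly_mean = 0.85, qaly_sd = 0.01)
  dnull <- simulate_psa(null, n_iter = 10000, seed = 12)
  f <- fraction_below(scatter_points(dnull, "A", "B"), 50000)
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / 10000))
  # degenerate identical draws strictly below the line
  sure <- tibble::tibble(arm = c("A", "B"),
                         cost_mean = c(100, 200), cost_sd = c(0, 0),
                         qaly_mean = c(0.9, 0.8), qaly_sd = c(0, 0))
  ds <- simulate_psa(sure, n_iter = 10, seed = 13)
  expect_equal(fraction_below(scatter_points(ds, "A", "B"), 50000), 1)
})
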