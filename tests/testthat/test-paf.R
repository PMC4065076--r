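test_that("RR at the mean dose reproduces the published dose-response RRs", {
  expect_equal(round(rr_at_dose(0.015, 28.53), 2), 1.53)
  expect_equal(round(rr_at_dose(0.024, 28.53), 2), 1.98)
  expect_equal(rr_at_dose(0, 100), 1)
})

test_that("Levin's continuous formula behaves at its anchor points", {
  expect_equal(paf_levin_continuous(0, 0.02, 30), 0)
  expect_equal(paf_levin_continuous(0.5, 0, 30), 0)
  expect_equal(paf_levin_continuous(0.5, 0.02, 0), 0)
  # everyone exposed at RR = 2 removes half the cases
  expect_equal(paf_levin_continuous(1, log(2) / 10, 10), 0.5)
  expect_error(paf_levin_continuous(1.2, 0.01, 10), "proportion")
})

test_that("Levin's formula equals a two-stratum expected-case computation", {
  # 10^6 virtual persons split into drinkers at RR(dose) and non-drinkers;
  # attributable fraction of expected cases vs the closed formula
  n <- 1e6L
  for (p in c(0.25, 0.775, 0.233)) {
    for (rr in c(1.1, 1.53, 2.5)) {
      n_exp <- round(n * p)
      rate0 <- 1e-3
      persons_rr <- c(rep(rr, n_exp), rep(1, n - n_exp))
      expected_cases <- sum(rate0 * persons_rr)
      baseline_cases <- n * rate0
      af_sim <- (expected_cases - baseline_cases) / expected_cases
      beta <- log(rr) / 20
      expect_equal(paf_levin_continuous(n_exp / n, beta, 20), af_sim,
                   tolerance = 1e-9)
    }
  }
})

test_that("prevalence calibration inverts the forward formula exactly", {
  # inversions anchored at the packaged calibration points
  expect_equal(calibrate_prevalence(0.433, 0.024, 28.53), 0.776704,
               tolerance = 1e-4)
  expect_equal(calibrate_prevalence(0.042, 0.027, 6.38), 0.233215,
               tolerance = 1e-4)
  # round trip on a grid of interior points
  for (paf in c(1e-6, 0.01, 0.2, 0.5, 0.9, 1 - 1e-9)) {
    for (bd in list(c(0.005, 10), c(0.024, 28.53), c(0.1, 50))) {
      p <- calibrate_prevalence(paf, bd[1], bd[2])
      if (p <= 1) {
        expect_equal(paf_levin_continuous(p, bd[1], bd[2]), paf,
                     tolerance = 1e-12)
      }
    }
  }
  # and the limit: a vanishing PAF needs a vanishing prevalence
  expect_lt(calibrate_prevalence(1e-12, 0.024, 28.53), 1e-11)
  expect_error(calibrate_prevalence(1, 0.01, 10), "strictly")
  expect_error(calibrate_prevalence(0.5, 0, 10), "positive")
})

test_that("PAF is strictly increasing in p, beta and dose", {
  ps <- seq(0.05, 0.95, by = 0.15)
  betas <- seq(0.001, 0.05, by = 0.007)
  doses <- seq(1, 80, by = 12)
  expect_true(all(diff(paf_levin_continuous(ps, 0.02, 30)) > 0))
  expect_true(all(diff(paf_levin_continuous(0.5, betas, 30)) > 0))
  expect_true(all(diff(paf_levin_continuous(0.5, 0.02, doses)) > 0))
  # and jointly on a grid
  g <- expand.grid(p = ps, beta = betas, dose = doses)
  paf <- paf_levin_continuous(g$p, g$beta, g$dose)
  expect_true(all(paf > 0 & paf < 1))
})

test_that("delta-method CI matches a parametric bootstrap of the slope", {
  set.seed(31)
  # slope uncertainties representative of precisely pooled strata; the
  # delta method is a first-order approximation and is only claimed there
  # (wide-RR strata are handled by sensitivity bounds instead)
  cases <- list(
    c(p = 0.7767, beta = 0.015, se = 0.002, dose = 28.53),
    c(p = 0.2332, beta = 0.027, se = 0.008, dose = 6.38),
    c(p = 0.5, beta = 0.005, se = 0.002, dose = 50)
  )
  for (cs in cases) {
    ci <- paf_ci_delta(cs["p"], cs["beta"], cs["se"], cs["dose"])
    draws <- rnorm(1e5, cs["beta"], cs["se"])
    boot <- quantile(paf_levin_continuous(cs["p"], draws, cs["dose"]),
                     c(0.025, 0.975), names = FALSE)
    expect_lt(abs(ci[["low"]] - boot[1]), 0.005)
    expect_lt(abs(ci[["high"]] - boot[2]), 0.005)
  }
  # zero slope uncertainty collapses the interval onto the point estimate
  ci0 <- paf_ci_delta(0.5, 0.01, 0, 30)
  expect_equal(unname(ci0["low"]), unname(ci0["high"]))
  expect_equal(unname(ci0["low"]), paf_levin_continuous(0.5, 0.01, 30))
  # wider se widens the interval
  w1 <- diff(paf_ci_delta(0.5, 0.01, 0.001, 30))
  w2 <- diff(paf_ci_delta(0.5, 0.01, 0.002, 30))
  expect_gt(w2, w1)
})

test_that("delta-method CI converges to the bootstrap as se shrinks", {
  set.seed(32)
  gaps <- sapply(c(0.002, 0.0005, 0.0001), function(se) {
    ci <- paf_ci_delta(0.7767, 0.015, se, 28.53)
    draws <- rnorm(1e5, 0.015, se)
    boot <- quantile(paf_levin_continuous(0.7767, draws, 28.53),
                     c(0.025, 0.975), names = FALSE)
    max(abs(ci - boot))
  })
  expect_true(all(gaps < 0.005))
  expect_lt(gaps[3], 1e-3) # near-linear regime: the two intervals coincide
})

test_that("sensitivity bounds clip protective lower bounds at zero", {
  b <- sensitivity_bounds(0.233, 0.88, 1.60, 6.38)
  expect_equal(b[["low"]], 0)
  # the upper bound for female colorectal cancer sits close to 12%
  expect_gt(b[["high"]], 0.11)
  expect_lt(b[["high"]], 0.13)
  # degenerate interval returns the point PAF on both sides
  b2 <- sensitivity_bounds(0.5, 1.5, 1.5, 20)
  expect_equal(b2[["low"]], b2[["high"]])
  expect_equal(b2[["low"]], paf_levin_continuous(0.5, log(1.5) / 20, 20))
})

test_that("scenario PAFs replace the dose and keep the prevalence", {
  p <- calibrate_prevalence(0.433, 0.024, 28.53)
  q4 <- scenario_paf(p, 0.015, 56.0, "q4")
  q1 <- scenario_paf(p, 0.015, 2.80, "q1")
  expect_equal(100 * q4$paf, 50.5, tolerance = 0.1)
  expect_equal(100 * q1$paf, 3.2, tolerance = 0.1)
  expect_equal(scenario_paf(p, 0.015, 0)$paf, 0)
})

test_that("dose-reduction impact recomputes the PAF at the reduced dose", {
  same <- dose_reduction_impact(0.7, 0.01, 30, 0)
  expect_equal(same$paf_before, same$paf_after)
  gone <- dose_reduction_impact(0.7, 0.01, 30, 45)
  expect_equal(gone$paf_after, 0)
  expect_equal(gone$relative_change, 1)
  cut <- dose_reduction_impact(0.7, 0.01, 30, 12, count = 1000)
  expect_equal(cut$paf_after, paf_levin_continuous(0.7, 0.01, 18))
  expect_equal(cut$cases_averted, cut$cases_before - cut$cases_after)
})

test_that("paf_table emits baseline, Q1 and Q4 rows with CIs and bounds", {
  pooled <- data.frame(sex = "male", site = "oral_cavity",
                       outcome = "incidence", beta = 0.015, se = 0.002,
                       rr_ci_low = 0.77, rr_ci_high = 2.96)
  prev <- data.frame(sex = "male", p_drinkers = 0.7767,
                     mean_dose_gday = 28.53, q1_median_gday = 2.80,
                     q4_median_gday = 56.0)
  out <- paf_table(pooled, prev)
  expect_equal(nrow(out), 3L)
  expect_setequal(out$scenario_label, c("baseline", "q1", "q4"))
  base <- out[out$scenario_label == "baseline", ]
  expect_true(base$paf_ci_low < base$paf & base$paf < base$paf_ci_high)
  expect_equal(base$paf_sens_low, 0) # rr CI spans 1
  expect_error(paf_table(pooled, prev[prev$sex == "female", ]), "missing")
})
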