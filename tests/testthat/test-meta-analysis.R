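test_that("fixed-effect pooling matches direct summation and metafor", {
  # two identical estimates: mean unchanged, se shrinks by sqrt(2), Q = 0
  r <- pool_fixed(c(0.01, 0.01), c(0.005, 0.005))
  expect_equal(r$beta_pooled, 0.01)
  expect_equal(r$se_pooled, 0.005 / sqrt(2))
  expect_equal(r$q_stat, 0)
  expect_equal(r$i_squared, 0)

  # k = 1 passes through
  r1 <- pool_fixed(0.02, 0.004)
  expect_equal(r1$beta_pooled, 0.02)
  expect_equal(r1$se_pooled, 0.004)
  expect_equal(r1$q_pvalue, 1)

  set.seed(11)
  for (i in 1:5) {
    beta <- rnorm(5, 0.01, 0.005)
    se <- runif(5, 0.001, 0.01)
    r <- pool_fixed(beta, se)
    w <- 1 / se^2
    expect_equal(r$beta_pooled, sum(w * beta) / sum(w), tolerance = 1e-12)
    expect_equal(r$q_stat, sum(w * (beta - sum(w * beta) / sum(w))^2),
                 tolerance = 1e-12)
    m <- metafor::rma(yi = beta, sei = se, method = "FE")
    expect_equal(r$beta_pooled, as.numeric(m$beta), tolerance = 1e-10)
    expect_equal(r$se_pooled, m$se, tolerance = 1e-10)
    expect_equal(r$q_stat, m$QE, tolerance = 1e-10)
    expect_equal(r$q_pvalue, m$QEp, tolerance = 1e-10)
  }
})

test_that("DerSimonian-Laird pooling matches metafor and truncates at zero", {
  # homogeneous inputs: tau^2 truncates to 0 and equals the fixed result
  r <- pool_random(c(0.01, 0.0101), c(0.01, 0.01))
  expect_equal(r$tau_squared, 0)
  expect_equal(r$beta_pooled, pool_fixed(c(0.01, 0.0101),
                                         c(0.01, 0.01))$beta_pooled)

  # symmetric weights: pooled beta is the midpoint, tau^2 > 0
  r2 <- pool_random(c(0, 0.1), c(0.01, 0.01))
  expect_equal(r2$beta_pooled, 0.05)
  expect_gt(r2$tau_squared, 0)

  set.seed(12)
  for (i in 1:5) {
    beta <- rnorm(8, 0.004, 0.003)
    se <- runif(8, 0.001, 0.01)
    r <- pool_random(beta, se)
    m <- metafor::rma(yi = beta, sei = se, method = "DL")
    expect_equal(r$beta_pooled, as.numeric(m$beta), tolerance = 1e-10)
    expect_equal(r$se_pooled, m$se, tolerance = 1e-10)
    expect_equal(r$tau_squared, m$tau2, tolerance = 1e-10)
  }
  expect_error(pool_random(0.01, 0.005), ">=2 studies")
})

test_that("random-effects pooling recovers a heterogeneous true slope", {
  set.seed(13)
  true <- 0.004
  k <- 10
  se <- runif(k, 0.0005, 0.002)
  beta <- rnorm(k, rnorm(k, true, 0.002), se)
  r <- pool_random(beta, se)
  expect_lt(abs(r$beta_pooled - true), 2 * r$se_pooled)
  expect_gte(r$se_pooled, pool_fixed(beta, se)$se_pooled)
})

test_that("model choice follows the I^2/Q-p OR rule", {
  mk <- function(i2, qp) {
    structure(list(beta_pooled = 1, se_pooled = 1, model = "fixed",
                   q_stat = 1, q_pvalue = qp, i_squared = i2,
                   tau_squared = 0, k = 5), class = "meta_result")
  }
  mkr <- function() {
    structure(list(beta_pooled = 2, se_pooled = 2, model = "random",
                   q_stat = 1, q_pvalue = 1, i_squared = 0,
                   tau_squared = 1, k = 5), class = "meta_result")
  }
  expect_equal(choose_model(mk(85, 0.20), mkr())$model, "random")
  expect_equal(choose_model(mk(10, 0.50), mkr())$model, "fixed")
  expect_equal(choose_model(mk(50, 0.01), mkr())$model, "random")
})

test_that("pooling is invariant to order and to splitting a study in half", {
  set.seed(14)
  beta <- rnorm(6, 0.01, 0.004)
  se <- runif(6, 0.002, 0.01)
  r <- pool_fixed(beta, se)
  o <- sample(6)
  expect_equal(pool_fixed(beta[o], se[o])$beta_pooled, r$beta_pooled,
               tolerance = 1e-14)
  # one study split into two copies at double variance (half weight each)
  beta2 <- c(beta, beta[1])
  se2 <- c(se, se[1])
  se2[c(1, 7)] <- se[1] * sqrt(2)
  expect_equal(pool_fixed(beta2, se2)$beta_pooled, r$beta_pooled,
               tolerance = 1e-12)
})

test_that("I^2 is consistent with Q and k, and large tau^2 gives the mean", {
  set.seed(15)
  beta <- rnorm(7, 0.01, 0.01)
  se <- runif(7, 0.001, 0.01)
  for (r in list(pool_fixed(beta, se), pool_random(beta, se))) {
    expect_equal(r$i_squared,
                 if (r$q_stat > 0) max(0, (r$q_stat - (r$k - 1)) / r$q_stat) * 100 else 0)
  }
  # with dominant between-study variance the weights equalize
  ws <- 1 / (se^2 + 1e6)
  expect_equal(sum(ws * beta) / sum(ws), mean(beta), tolerance = 1e-9)
  r_big <- pool_random(beta * 1e4, se) # Q >> k so tau^2 dominates se range
  expect_equal(r_big$beta_pooled, mean(beta * 1e4),
               tolerance = abs(mean(beta * 1e4)) * 0.05)
})

test_that("Begg's test matches metafor's rank test and detects concordance", {
  # perfectly concordant deviates vs variances: tau = 1
  se <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  beta <- 2 * se^2 # effects growing faster than precision shrinks
  b <- begg_test(beta, se)
  expect_equal(b$begg_tau, 1)

  expect_warning(b2 <- begg_test(c(0.1, 0.2), c(0.1, 0.1)), ">=3")
  expect_true(is.na(b2$begg_tau))
  expect_warning(b3 <- begg_test(c(0.1, 0.2, 0.3), c(0.1, 0.1, 0.1)), "tied")
  expect_equal(b3$begg_tau, 0)

  set.seed(16)
  for (i in 1:5) {
    k <- 10
    se_i <- runif(k, 0.001, 0.01)
    beta_i <- rnorm(k, 0, se_i)
    ours <- begg_test(beta_i, se_i)
    m <- metafor::ranktest(x = beta_i, sei = se_i, exact = FALSE)
    expect_equal(ours$begg_tau, unname(m$tau), tolerance = 1e-10)
    expect_equal(ours$begg_pvalue, unname(m$pval), tolerance = 0.02)
  }
})

test_that("funnel guide curves bracket the fixed-effect center", {
  set.seed(17)
  beta <- rnorm(6, 0.01, 0.002)
  se <- runif(6, 0.001, 0.01)
  f <- funnel_data(beta, se)
  expect_equal(f$center, pool_fixed(beta, se)$beta_pooled)
  expect_equal(f$guides$upper, f$center + qnorm(0.975) * f$guides$se)
  expect_equal(f$guides$lower, f$center - qnorm(0.975) * f$guides$se)
  # symmetric triple centered on the middle estimate
  f3 <- funnel_data(c(0.01, 0.02, 0.03), c(0.005, 0.005, 0.005))
  expect_equal(f3$center, 0.02)
})

test_that("pool_slopes pools per stratum and applies the mortality fallback", {
  slopes <- data.frame(
    study_id = c("a", "b", "c", "d"),
    sex = c("male", "male", "male", "female"),
    site = c("liver", "liver", "liver", "breast"),
    outcome = "incidence",
    beta = c(0.002, 0.003, 0.0025, 0.001),
    se_beta = c(0.0005, 0.0008, 0.0007, 0.0002)
  )
  out <- pool_slopes(slopes, mortality_fallback = TRUE)
  liver_inc <- out[out$site == "liver" & out$outcome == "incidence", ]
  liver_mort <- out[out$site == "liver" & out$outcome == "mortality", ]
  expect_equal(liver_inc$k, 3)
  expect_equal(liver_mort$beta, liver_inc$beta)
  expect_equal(liver_mort$fallback, "incidence_beta")
  # single-study stratum passes through as fixed
  breast <- out[out$site == "breast" & out$outcome == "incidence", ]
  expect_equal(breast$model, "fixed")
  expect_equal(breast$beta, 0.001)
})
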