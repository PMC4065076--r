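# small in-code fixtures shared across test files

# a risk table with exactly log-linear RRs at a given slope
make_linear_table <- function(beta, mids = c(10, 20, 40), width = 5,
                              ci = TRUE, study_id = "s1") {
  tab <- data.frame(
    study_id = study_id, sex = "male", site = "oral_cavity",
    outcome = "incidence", design = "cohort",
    lower_gday = c(0, mids - width), upper_gday = c(0, mids + width),
    rr = c(1, exp(beta * mids)),
    ci_low = NA_real_, ci_high = NA_real_,
    n_cases = 100L,
    is_reference = c(TRUE, rep(FALSE, length(mids))),
    stringsAsFactors = FALSE
  )
  if (ci) {
    se <- rep(0.2, length(mids))
    tab$ci_low[-1] <- exp(beta * mids - qnorm(0.975) * se)
    tab$ci_high[-1] <- exp(beta * mids + qnorm(0.975) * se)
  }
  tab
}

# a random valid risk table for property-style loops
random_table <- function(n_cat = sample(2:5, 1), study_id = "r1") {
  mids <- sort(runif(n_cat, 5, 80))
  width <- min(diff(c(0, mids))) / 2.1
  se <- runif(n_cat, 0.05, 0.5)
  logrr <- rnorm(n_cat, 0.01 * mids, 0.1)
  data.frame(
    study_id = study_id, sex = "male", site = "oral_cavity",
    outcome = "incidence", design = "cohort",
    lower_gday = c(0, mids - width), upper_gday = c(0, mids + width),
    rr = c(1, exp(logrr)),
    ci_low = c(NA, exp(logrr - qnorm(0.975) * se)),
    ci_high = c(NA, exp(logrr + qnorm(0.975) * se)),
    n_cases = 100L,
    is_reference = c(TRUE, rep(FALSE, n_cat)),
    stringsAsFactors = FALSE
  )
}

# brute-force forced-origin WLS by 1-d numerical minimization of the
# weighted SSE (independent of the closed-form implementation)
grid_slope <- function(tab) {
  dose <- afrac::assign_midpoints(tab)
  y <- ifelse(tab$is_reference, 0, log(tab$rr))
  nonref <- !tab$is_reference
  se <- (log(tab$ci_high[nonref]) - log(tab$ci_low[nonref])) /
    (2 * qnorm(0.975))
  w <- numeric(nrow(tab))
  w[nonref] <- 1 / se^2
  w[tab$is_reference] <- max(w[nonref])
  sse <- function(b) sum(w * (y - b * dose)^2)
  optimize(sse, interval = c(-1, 1), tol = 1e-12)$minimum
}
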