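#' Specification for simulating categorical dose-response study tables
#'
#' Defines the generating process for a set of published-style study tables:
#' each study draws its own slope from
#' `Normal(true_beta, between_study_sd^2)`, partitions the dose range into
#' exposure categories, and observes category log RRs with independent
#' normal noise whose variance follows a two-cell Poisson approximation,
#' `se^2 = 1/cases_exposed + 1/cases_reference`. The defaults emulate the
#' evidence base the pipeline was built for: ten studies of three to five
#' exposure categories over 0-80 g/day, 50-200 cases per category, a true
#' slope of 0.015 log RR per g/day and a between-study standard deviation
#' of 0.002.
#'
#' @param true_beta True average slope, log RR per g/day.
#' @param k_studies Number of studies.
#' @param categories_per_study Integer range `c(min, max)` of non-reference
#'   categories per study.
#' @param dose_range_gday Dose interval partitioned into categories.
#' @param cases_per_category Integer range of case counts per category.
#' @param between_study_sd Between-study SD of the true slopes (log RR
#'   scale, >= 0).
#' @param open_top Emit the top category of each study as open-ended.
#' @param seed Integer seed; identical seeds reproduce identical tables.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(true_beta = 0.015, k_studies = 10L,
                            categories_per_study = c(3L, 5L),
                            dose_range_gday = c(0, 80),
                            cases_per_category = c(50L, 200L),
                            between_study_sd = 0.002,
                            open_top = FALSE, seed = 1L) {
  stop_if(k_studies < 1L, "k_studies must be positive")
  stop_if(any(categories_per_study < 2L),
          "need at least 2 categories per study")
  stop_if(any(cases_per_category < 1), "case counts must be positive")
  stop_if(between_study_sd < 0, "between_study_sd must be >= 0")
  stop_if(diff(dose_range_gday) <= 0, "dose_range_gday must have width")
  structure(
    list(
      true_beta = true_beta, k_studies = as.integer(k_studies),
      categories_per_study = as.integer(categories_per_study),
      dose_range_gday = dose_range_gday,
      cases_per_category = round(cases_per_category),
      between_study_sd = between_study_sd,
      open_top = isTRUE(open_top), seed = as.integer(seed)
    ),
    class = "simulation_spec"
  )
}

# uniform integer draw on [lo, hi] without materializing the range
r_int <- function(n, lo, hi) {
  pmin(hi, lo + floor(stats::runif(n) * (hi - lo + 1)))
}

#' Simulate categorical risk tables from a known dose-response slope
#'
#' Draws `k_studies` study tables under the generating process described in
#' [simulation_spec()]. Reported 95% CIs are exactly
#' `exp(log_rr +/- 1.959964 * se)`, so [se_from_ci()] recovers the
#' generating standard error.
#'
#' @param spec A [simulation_spec()].
#' @return Data frame in the long `studies.csv` shape (one row per exposure
#'   category) with an extra attribute `true_betas`, the per-study slopes
#'   actually drawn.
#' @export
simulate_study_tables <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  rows <- list()
  true_betas <- numeric(spec$k_studies)
  for (i in seq_len(spec$k_studies)) {
    beta_i <- rnorm(1, spec$true_beta, spec$between_study_sd)
    true_betas[i] <- beta_i
    n_cat <- r_int(1L, spec$categories_per_study[1L],
                   spec$categories_per_study[2L])
    breaks <- seq(spec$dose_range_gday[1L], spec$dose_range_gday[2L],
                  length.out = n_cat + 1L)
    lo <- breaks[-length(breaks)]
    hi <- breaks[-1L]
    mid <- (lo + hi) / 2
    cases <- r_int(n_cat + 1L, spec$cases_per_category[1L],
                   spec$cases_per_category[2L])
    cases_ref <- cases[1L]
    cases_exp <- cases[-1L]
    # two-cell Poisson approximation, floored to keep weights finite in
    # the cases -> infinity limit
    se <- pmax(sqrt(1 / cases_exp + 1 / cases_ref), 1e-6)
    logrr <- rnorm(n_cat, beta_i * mid, se)
    if (spec$open_top) hi[n_cat] <- NA_real_
    study <- data.frame(
      study_id = sprintf("sim%02d", i),
      sex = "both", site = "oral_cavity", outcome = "incidence",
      design = "cohort",
      lower_gday = c(0, lo), upper_gday = c(0, hi),
      rr = c(1, exp(logrr)),
      ci_low = c(NA_real_, exp(logrr - Z95 * se)),
      ci_high = c(NA_real_, exp(logrr + Z95 * se)),
      n_cases = c(cases_ref, cases_exp),
      is_reference = c(TRUE, rep(FALSE, n_cat)),
      stringsAsFactors = FALSE
    )
    # the reference row carries rr = 1 with no CI; fitting treats its
    # log RR as known exactly
    rows[[i]] <- study
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "true_betas") <- true_betas
  out
}

#' Specification for simulating a consumption survey
#'
#' Drinker status is Bernoulli with probability `p_drinkers`; doses among
#' drinkers follow a log-normal distribution (the canonical right-skewed
#' consumption model) with parameters `log_mean` and `log_sd` on the log
#' scale.
#'
#' @param p_drinkers Proportion of current drinkers in `[0, 1]`.
#' @param log_mean,log_sd Log-scale parameters of the drinker-dose
#'   log-normal (mean dose is `exp(log_mean + log_sd^2/2)`).
#' @param n_respondents Number of survey respondents (>= 20).
#' @param seed Integer seed.
#' @return Object of class `consumption_survey_spec`.
#' @export
consumption_survey_spec <- function(p_drinkers = 0.775, log_mean = log(15),
                                    log_sd = 1.0, n_respondents = 10000L,
                                    seed = 1L) {
  check_proportion(p_drinkers, "p_drinkers")
  stop_if(log_sd < 0, "log_sd must be >= 0")
  stop_if(n_respondents < 20L, "need at least 20 respondents")
  structure(
    list(p_drinkers = p_drinkers, log_mean = log_mean, log_sd = log_sd,
         n_respondents = as.integer(n_respondents), seed = as.integer(seed)),
    class = "consumption_survey_spec"
  )
}

#' Simulate a consumption survey and summarize it as exposure prevalence
#'
#' Returns the empirical drinker proportion, the mean dose among drinkers,
#' and the medians of the first and fourth empirical quartiles of drinker
#' dose — the summary statistics the PAF engine consumes.
#'
#' @param spec A [consumption_survey_spec()].
#' @return Data frame with one row: `p_drinkers`, `mean_dose_gday`,
#'   `q1_median_gday`, `q4_median_gday`, `n_drinkers`.
#' @export
simulate_consumption_survey <- function(spec) {
  stopifnot(inherits(spec, "consumption_survey_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  drinker <- rbinom(spec$n_respondents, 1L, spec$p_drinkers) == 1L
  doses <- rlnorm(sum(drinker), spec$log_mean, spec$log_sd)
  if (length(doses) == 0L) {
    return(data.frame(p_drinkers = 0, mean_dose_gday = 0,
                      q1_median_gday = 0, q4_median_gday = 0, n_drinkers = 0L))
  }
  qs <- quantile(doses, c(0.25, 0.75), names = FALSE, type = 7)
  data.frame(
    p_drinkers = mean(drinker),
    mean_dose_gday = mean(doses),
    q1_median_gday = median(doses[doses <= qs[1L]]),
    q4_median_gday = median(doses[doses >= qs[2L]]),
    n_drinkers = sum(drinker)
  )
}

#' End-to-end parameter-recovery study
#'
#' Runs the full chain — per-study slope fitting, meta-analytic pooling, and
#' Levin's continuous-exposure PAF — on simulated inputs over independent
#' replicates, and reports bias and RMSE of the pooled slope and of the PAF
#' against their generating values.
#'
#' @param spec A [simulation_spec()]; each replicate reseeds it with
#'   `spec$seed + replicate - 1`.
#' @param survey A [consumption_survey_spec()] supplying the prevalence and
#'   doses (held fixed across replicates at its own seed).
#' @param n_replicates Number of independent replicates.
#' @return List with `true_beta`, `true_paf`, and a data frame `replicates`
#'   (`beta_hat`, `se_hat`, `paf_hat`, `covered` — whether the 95% CI of
#'   the pooled slope covered the truth), plus summary `bias_beta`,
#'   `rmse_beta`, `bias_paf`, `rmse_paf`, `coverage`.
#' @export
end_to_end_recovery <- function(spec, survey, n_replicates = 50L) {
  stopifnot(inherits(spec, "simulation_spec"),
            inherits(survey, "consumption_survey_spec"))
  prev <- simulate_consumption_survey(survey)
  true_paf <- paf_levin_continuous(prev$p_drinkers, spec$true_beta,
                                   prev$mean_dose_gday)
  reps <- lapply(seq_len(n_replicates), function(r) {
    sp <- spec
    sp$seed <- spec$seed + r - 1L
    tabs <- simulate_study_tables(sp)
    sl <- fit_slopes(tabs)
    res <- if (nrow(sl) >= 2L) {
      choose_model(pool_fixed(sl$beta, sl$se_beta),
                   pool_random(sl$beta, sl$se_beta))
    } else {
      pool_fixed(sl$beta, sl$se_beta)
    }
    paf_hat <- paf_levin_continuous(prev$p_drinkers, res$beta_pooled,
                                    prev$mean_dose_gday)
    data.frame(
      beta_hat = res$beta_pooled, se_hat = res$se_pooled, paf_hat = paf_hat,
      covered = abs(res$beta_pooled - spec$true_beta) <=
        Z95 * res$se_pooled
    )
  })
  reps <- do.call(rbind, reps)
  list(
    true_beta = spec$true_beta, true_paf = true_paf, replicates = reps,
    bias_beta = mean(reps$beta_hat) - spec$true_beta,
    rmse_beta = sqrt(mean((reps$beta_hat - spec$true_beta)^2)),
    bias_paf = mean(reps$paf_hat) - true_paf,
    rmse_paf = sqrt(mean((reps$paf_hat - true_paf)^2)),
    coverage = mean(reps$covered)
  )
}
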