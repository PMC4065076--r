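#' Relative risk at a continuous dose
#'
#' Evaluates the log-linear dose-response model `RR(dose) = exp(beta * dose)`
#' at a given consumption level, e.g. the mean g/day among drinkers.
#'
#' @param beta Slope, log RR per g/day.
#' @param dose Dose in g/day (>= 0).
#' @return Relative risk (numeric, vectorized).
#' @export
#' @examples
#' rr_at_dose(0.015, 28.53) # ~1.53
rr_at_dose <- function(beta, dose) {
  check_nonneg(dose, "dose")
  exp(beta * dose)
}

#' Population attributable fraction for a continuous exposure (Levin)
#'
#' Levin's formula `PAF = P(RR - 1) / (P(RR - 1) + 1)` with the relative
#' risk evaluated at a continuous dose, `RR = exp(beta * dose)`: `p` is the
#' proportion of current drinkers in the population and `dose` the average
#' consumption (g/day) among drinkers. Returns a proportion at full floating
#' precision; conversion to percent belongs to report formatting only.
#'
#' @param p Proportion of exposed (drinkers) in `[0, 1]`.
#' @param beta Slope, log RR per g/day.
#' @param dose Mean dose among the exposed, g/day (>= 0).
#' @return PAF as a proportion in `[0, 1)` (vectorized).
#' @export
#' @examples
#' paf_levin_continuous(1, log(2) / 10, 10) # RR = 2 -> PAF = 0.5
paf_levin_continuous <- function(p, beta, dose) {
  check_proportion(p, "p")
  check_nonneg(dose, "dose")
  x <- p * (exp(beta * dose) - 1)
  x / (x + 1)
}

#' Back-calculate exposure prevalence from a known PAF
#'
#' Inverts Levin's continuous-exposure formula:
#' `p = PAF / ((1 - PAF) * (exp(beta * dose) - 1))`. Used to recover a
#' drinker proportion from a published PAF when the underlying survey
#' prevalence is not directly available; round-trips through
#' [paf_levin_continuous()] to near machine precision.
#'
#' @param paf_known Known PAF as a proportion in (0, 1).
#' @param beta Slope, log RR per g/day.
#' @param dose Dose in g/day; `beta * dose` must be positive.
#' @return Exposure prevalence `p`.
#' @export
#' @examples
#' p <- calibrate_prevalence(0.433, 0.024, 28.53)
#' paf_levin_continuous(p, 0.024, 28.53) # 0.433
calibrate_prevalence <- function(paf_known, beta, dose) {
  stop_if(any(paf_known <= 0 | paf_known >= 1),
          "paf_known must lie strictly in (0, 1)")
  stop_if(any(beta * dose <= 0), "beta * dose must be positive")
  paf_known / ((1 - paf_known) * (exp(beta * dose) - 1))
}

#' Delta-method 95% confidence interval for a PAF
#'
#' Propagates only the sampling variance of the slope through Levin's
#' formula on the identity scale: with `g(beta) = p(e^{bd}-1)/(p(e^{bd}-1)+1)`
#' and `g'(beta) = p d e^{bd} / (p(e^{bd}-1)+1)^2`, the interval is
#' `g(beta) +/- 1.959964 * |g'(beta)| * se_beta`, clipped to `[0, 1)`.
#' The drinker proportion and the dose are treated as fixed constants.
#'
#' @inheritParams paf_levin_continuous
#' @param se_beta Standard error of `beta` (>= 0).
#' @return Named numeric vector `c(low, high)`.
#' @export
paf_ci_delta <- function(p, beta, se_beta, dose) {
  check_proportion(p, "p")
  check_nonneg(se_beta, "se_beta")
  check_nonneg(dose, "dose")
  denom <- p * (exp(beta * dose) - 1) + 1
  g <- p * (exp(beta * dose) - 1) / denom
  gprime <- p * dose * exp(beta * dose) / denom^2
  half <- Z95 * abs(gprime) * se_beta
  c(low = pmax(0, g - half), high = pmin(1 - .Machine$double.eps, g + half))
}

#' Sensitivity bounds for a PAF from the RR confidence interval
#'
#' Recomputes the PAF with the slope replaced by the bounds implied by the
#' 95% CI of the pooled RR at the average dose: `beta_bound =
#' log(rr_bound) / dose`, then Levin's formula at the same dose. A lower RR
#' bound below 1 (protective) clips the lower PAF bound at 0.
#'
#' @inheritParams paf_levin_continuous
#' @param rr_ci_low,rr_ci_high 95% CI bounds of the RR at the average dose.
#' @return Named numeric vector `c(low, high)` of PAF bounds.
#' @export
#' @examples
#' sensitivity_bounds(0.233, 0.88, 1.60, 6.38) # women colorectal: hi ~ 0.12
sensitivity_bounds <- function(p, rr_ci_low, rr_ci_high, dose) {
  check_proportion(p, "p")
  stop_if(any(rr_ci_low <= 0 | rr_ci_high < rr_ci_low),
          "need 0 < rr_ci_low <= rr_ci_high")
  stop_if(any(dose <= 0), "dose must be positive")
  bound_paf <- function(rr) {
    ifelse(rr <= 1, 0, paf_levin_continuous(p, log(rr) / dose, dose))
  }
  c(low = bound_paf(rr_ci_low), high = bound_paf(rr_ci_high))
}

#' Counterfactual-scenario PAF
#'
#' Recomputes the PAF with the drinkers' dose replaced by a scenario dose,
#' e.g. the median of the lowest (Q1) or highest (Q4) consumption quartile;
#' the drinker proportion is unchanged.
#'
#' @inheritParams paf_levin_continuous
#' @param scenario_dose Replacement dose in g/day (>= 0).
#' @param label Scenario label (e.g. `"q1"`, `"q4"`, `"baseline"`).
#' @return List with `paf`, `rr_at_dose`, `dose`, and `scenario_label`.
#' @export
scenario_paf <- function(p, beta, scenario_dose, label = "custom") {
  check_nonneg(scenario_dose, "scenario_dose")
  list(
    paf = paf_levin_continuous(p, beta, scenario_dose),
    rr_at_dose = rr_at_dose(beta, scenario_dose),
    dose = scenario_dose,
    scenario_label = label
  )
}

#' Impact of an across-the-board dose reduction
#'
#' Recomputes the PAF after every drinker reduces consumption by
#' `delta_gday` g/day (floored at zero), e.g. one glass of beer or soju
#' (about 12 g of ethanol); reports the absolute and relative change, and
#' the implied change in attributable cases when a case count is supplied.
#'
#' @inheritParams paf_levin_continuous
#' @param delta_gday Reduction in g/day (>= 0).
#' @param count Optional registry count to translate the PAF change into
#'   attributable cases.
#' @return List with `paf_before`, `paf_after`, `absolute_change`,
#'   `relative_change`, and (when `count` is given) `cases_before`,
#'   `cases_after`, `cases_averted`.
#' @export
dose_reduction_impact <- function(p, beta, dose, delta_gday, count = NULL) {
  check_nonneg(delta_gday, "delta_gday")
  before <- paf_levin_continuous(p, beta, dose)
  after <- paf_levin_continuous(p, beta, pmax(0, dose - delta_gday))
  out <- list(
    paf_before = before,
    paf_after = after,
    absolute_change = before - after,
    relative_change = ifelse(before > 0, (before - after) / before, 0)
  )
  if (!is.null(count)) {
    out$cases_before <- attributable_count(before, count)
    out$cases_after <- attributable_count(after, count)
    out$cases_averted <- out$cases_before - out$cases_after
  }
  out
}

#' Build the PAF table for pooled slopes and exposure prevalences
#'
#' Joins a pooled-slope table with sex-specific exposure prevalences and
#' evaluates, per stratum, the baseline PAF (at the mean dose among
#' drinkers) with its delta-method CI and RR-bound sensitivity interval,
#' plus the Q1 and Q4 counterfactual scenarios.
#'
#' @param pooled Data frame with columns `sex`, `site`, `outcome`, `beta`,
#'   `se`, and optionally `rr_ci_low`/`rr_ci_high` (CI of the RR at the
#'   average dose, used for the sensitivity bounds).
#' @param prevalence Data frame with columns `sex`, `p_drinkers`,
#'   `mean_dose_gday`, `q1_median_gday`, `q4_median_gday`.
#' @return Long data frame (`paf.csv` shape): one row per stratum and
#'   scenario (`baseline`, `q1`, `q4`) with `beta`, `dose`, `p`,
#'   `rr_at_dose`, `paf`, `paf_ci_low`, `paf_ci_high`, `paf_sens_low`,
#'   `paf_sens_high`.
#' @export
paf_table <- function(pooled, prevalence) {
  stop_if(!all(pooled$sex %in% prevalence$sex),
          "prevalence missing for sex: %s",
          paste(setdiff(pooled$sex, prevalence$sex), collapse = ", "))
  rows <- vector("list", nrow(pooled) * 3L)
  idx <- 0L
  for (i in seq_len(nrow(pooled))) {
    pr <- prevalence[match(pooled$sex[i], prevalence$sex), , drop = FALSE]
    beta <- pooled$beta[i]
    se <- if ("se" %in% names(pooled)) pooled$se[i] else NA_real_
    doses <- c(baseline = pr$mean_dose_gday, q1 = pr$q1_median_gday,
               q4 = pr$q4_median_gday)
    for (sc in names(doses)) {
      d <- doses[[sc]]
      paf <- paf_levin_continuous(pr$p_drinkers, beta, d)
      ci <- if (!is.na(se)) {
        paf_ci_delta(pr$p_drinkers, beta, se, d)
      } else {
        c(low = NA_real_, high = NA_real_)
      }
      sens <- if (sc == "baseline" &&
                    all(c("rr_ci_low", "rr_ci_high") %in% names(pooled)) &&
                    !is.na(pooled$rr_ci_low[i])) {
        sensitivity_bounds(pr$p_drinkers, pooled$rr_ci_low[i],
                           pooled$rr_ci_high[i], pr$mean_dose_gday)
      } else {
        c(low = NA_real_, high = NA_real_)
      }
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        sex = pooled$sex[i], site = pooled$site[i],
        outcome = pooled$outcome[i], scenario_label = sc,
        beta = beta, dose = d, p = pr$p_drinkers,
        rr_at_dose = rr_at_dose(beta, d), paf = paf,
        paf_ci_low = unname(ci["low"]), paf_ci_high = unname(ci["high"]),
        paf_sens_low = unname(sens["low"]),
        paf_sens_high = unname(sens["high"]),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows[seq_len(idx)])
  rownames(out) <- NULL
  out
}
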