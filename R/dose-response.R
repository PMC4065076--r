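#' Assign midpoint doses to the exposure categories of a study risk table
#'
#' Converts the categorical alcohol-consumption intervals of one study into
#' the single doses (g ethanol/day) used as the x-values of the log-linear
#' trend regression. Closed intervals get their arithmetic midpoint, the
#' non-drinking reference category gets dose 0, and an open-ended top
#' category gets its lower bound plus half the width of the adjacent closed
#' category below it (the usual imputation in summarized dose-response
#' analysis).
#'
#' @param table Data frame with one row per exposure category and columns
#'   `lower_gday`, `upper_gday` (`NA` = open-ended) and `is_reference`
#'   (logical). Rows must be ordered by `lower_gday`.
#' @return Numeric vector of doses in g/day, one per row of `table`.
#' @export
#' @examples
#' tab <- data.frame(
#'   lower_gday = c(0, 10, 30, 60), upper_gday = c(0, 30, 60, NA),
#'   is_reference = c(TRUE, FALSE, FALSE, FALSE)
#' )
#' assign_midpoints(tab) # 0, 20, 45, 75
assign_midpoints <- function(table) {
  stopifnot(is.data.frame(table))
  need <- c("lower_gday", "upper_gday", "is_reference")
  stop_if(!all(need %in% names(table)),
          "table must have columns %s", paste(need, collapse = ", "))
  lo <- table$lower_gday
  hi <- table$upper_gday
  stop_if(anyNA(lo) || any(lo < 0), "lower_gday must be non-negative and non-missing")
  closed <- !is.na(hi)
  stop_if(any(closed & hi < lo), "upper_gday must be >= lower_gday")
  dose <- numeric(nrow(table))
  dose[closed] <- (lo[closed] + hi[closed]) / 2
  for (i in which(!closed)) {
    # open-ended: impute lower + half the width of the nearest closed
    # category below (non-reference widths only; the reference is a point)
    below <- which(closed & !table$is_reference & lo < lo[i])
    stop_if(length(below) == 0L, "cannot impute open interval")
    j <- below[which.max(lo[below])]
    dose[i] <- lo[i] + (hi[j] - lo[j]) / 2
  }
  dose[table$is_reference] <- 0
  dose
}

#' Standard error of a log relative risk from its 95% confidence interval
#'
#' Recovers the standard error of `log(rr)` as
#' `(log(ci_high) - log(ci_low)) / (2 * 1.959964)`, the usual inversion of a
#' symmetric normal interval on the log scale.
#'
#' @param rr Relative risk (or odds ratio), > 0.
#' @param ci_low,ci_high 95% confidence bounds, > 0, with
#'   `ci_low <= rr <= ci_high`.
#' @return Standard error of `log(rr)` (0, with a warning, when the interval
#'   is degenerate).
#' @export
#' @examples
#' se_from_ci(1.53, 0.77, 2.96)
se_from_ci <- function(rr, ci_low, ci_high) {
  stop_if(!is.numeric(rr) || !is.numeric(ci_low) || !is.numeric(ci_high),
          "rr and CI bounds must be numeric")
  stop_if(any(rr <= 0 | ci_low <= 0 | ci_high <= 0),
          "rr and CI bounds must be positive")
  stop_if(any(ci_low > rr | rr > ci_high),
          "CI bounds must bracket rr (ci_low <= rr <= ci_high)")
  se <- (log(ci_high) - log(ci_low)) / (2 * Z95)
  if (any(se == 0)) warning("degenerate confidence interval (zero width)")
  se
}

validate_risk_table <- function(table) {
  need <- c("lower_gday", "upper_gday", "rr", "is_reference")
  stop_if(!all(need %in% names(table)),
          "risk table must have columns %s", paste(need, collapse = ", "))
  stop_if(sum(table$is_reference) != 1L,
          "exactly one category must be the reference")
  stop_if(abs(table$rr[table$is_reference] - 1) > .Machine$double.eps^0.5,
          "reference RR must be 1")
  stop_if(any(table$rr <= 0), "rr must be positive")
  nonref <- table[!table$is_reference, , drop = FALSE]
  stop_if(nrow(nonref) < 2L,
          "at least 2 non-reference categories are required to fit a slope")
  o <- order(table$lower_gday)
  tab <- table[o, , drop = FALSE]
  closed <- !is.na(tab$upper_gday)
  if (nrow(tab) > 1L) {
    up <- tab$upper_gday[-nrow(tab)]
    lo <- tab$lower_gday[-1L]
    stop_if(any(!is.na(up) & lo < up - .Machine$double.eps^0.5 &
                  !tab$is_reference[-nrow(tab)]),
            "exposure categories overlap")
  }
  tab
}

#' Fit a per-study log-linear dose-response slope
#'
#' Regresses `log(rr)` on midpoint dose through the origin, yielding the
#' study's log relative risk per 1 g ethanol/day. The line is forced through
#' the origin because RR is 1 by definition at the reference dose 0; the
#' reference category contributes the exact point (0, 0). When every
#' non-reference category reports a 95% CI the fit is weighted by the
#' inverse variance of `log(rr)` (the reference point receives the largest
#' finite weight in the table); if any CI is missing the whole table is fit
#' unweighted, since mixing weighting schemes within one study would bias
#' the slope. Odds ratios from case-control studies enter unchanged under
#' the rare-disease assumption.
#'
#' With inverse-variance weights the slope standard error treats the
#' category variances as known, `se = 1/sqrt(sum(w * x^2))`; the unweighted
#' fallback uses the classical residual-based OLS standard error.
#'
#' @param table Data frame with columns `lower_gday`, `upper_gday`, `rr`,
#'   `ci_low`, `ci_high` (optional pair), `is_reference`, and optionally
#'   `study_id`.
#' @return Object of class `slope_estimate`: a list with `beta`, `se_beta`,
#'   `n_points`, `weighted` and `study_id`.
#' @export
#' @examples
#' tab <- data.frame(
#'   lower_gday = c(0, 5, 15), upper_gday = c(0, 15, 25),
#'   rr = c(1, exp(0.1), exp(0.2)),
#'   is_reference = c(TRUE, FALSE, FALSE)
#' )
#' fit_loglinear_slope(tab)$beta # exactly 0.01
fit_loglinear_slope <- function(table) {
  tab <- validate_risk_table(table)
  dose <- assign_midpoints(tab)
  nonref <- !tab$is_reference
  stop_if(length(unique(dose[nonref])) < 2L, "no dose spread")

  have_ci <- all(c("ci_low", "ci_high") %in% names(tab)) &&
    all(!is.na(tab$ci_low[nonref]) & !is.na(tab$ci_high[nonref]))
  y <- log(tab$rr)
  y[tab$is_reference] <- 0
  if (have_ci) {
    se <- rep(NA_real_, nrow(tab))
    se[nonref] <- suppressWarnings(
      se_from_ci(tab$rr[nonref], tab$ci_low[nonref], tab$ci_high[nonref])
    )
    stop_if(any(se[nonref] == 0), "zero-width CI gives an infinite weight")
    w <- 1 / se^2
    w[tab$is_reference] <- max(w[nonref])
  } else {
    w <- rep(1, nrow(tab))
  }

  sxx <- sum(w * dose^2)
  beta <- sum(w * dose * y) / sxx
  if (have_ci) {
    se_beta <- sqrt(1 / sxx)
  } else {
    res <- y - beta * dose
    s2 <- sum(res^2) / (length(y) - 1L)
    se_beta <- sqrt(s2 / sum(dose^2))
  }

  structure(
    list(
      beta = beta,
      se_beta = se_beta,
      n_points = length(y),
      weighted = have_ci,
      study_id = if ("study_id" %in% names(tab)) tab$study_id[1L] else NA_character_
    ),
    class = "slope_estimate"
  )
}

#' @export
print.slope_estimate <- function(x, ...) {
  cat(sprintf(
    "log-linear dose-response slope (%s)\n  beta  = %.6g per g/day\n  se    = %.6g\n  points: %d (%s)\n",
    if (is.na(x$study_id)) "unlabelled study" else x$study_id,
    x$beta, x$se_beta, x$n_points,
    if (x$weighted) "inverse-variance weighted" else "unweighted"
  ))
  invisible(x)
}

#' Fit dose-response slopes for every study in a long table
#'
#' Splits a long category-level table (one row per exposure category, as read
#' by [read_studies()]) by study and stratum and fits [fit_loglinear_slope()]
#' to each.
#'
#' @param studies Data frame with the `studies.csv` columns: `study_id`,
#'   `sex`, `site`, `outcome`, `design`, `lower_gday`, `upper_gday`, `rr`,
#'   `ci_low`, `ci_high`, `n_cases`, `is_reference`.
#' @return Data frame with one row per study x stratum: `study_id`, `sex`,
#'   `site`, `outcome`, `beta`, `se_beta`, `n_points`.
#' @export
fit_slopes <- function(studies) {
  key <- interaction(studies$study_id, studies$sex, studies$site,
                     studies$outcome, drop = TRUE)
  parts <- split(studies, key)
  rows <- lapply(parts, function(tab) {
    est <- fit_loglinear_slope(tab)
    data.frame(
      study_id = tab$study_id[1L], sex = tab$sex[1L], site = tab$site[1L],
      outcome = tab$outcome[1L], beta = est$beta, se_beta = est$se_beta,
      n_points = est$n_points, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$sex, out$site, out$outcome, out$study_id), , drop = FALSE]
}
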