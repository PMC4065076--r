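new_meta_result <- function(beta, se, model, q, k, tau2 = 0,
                            begg_tau = NA_real_, begg_p = NA_real_) {
  qp <- if (k <= 1L) 1 else 1 - pchisq(q, df = k - 1L)
  i2 <- if (q > 0) max(0, (q - (k - 1L)) / q) * 100 else 0
  structure(
    list(
      beta_pooled = beta, se_pooled = se, model = model,
      q_stat = q, q_pvalue = qp, i_squared = i2, tau_squared = tau2,
      k = k, begg_tau = begg_tau, begg_pvalue = begg_p
    ),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "%s-effect%s pooled slope over %d stud%s\n  beta = %.6g (se %.6g)\n  Q = %.4g (p = %.3g), I^2 = %.1f%%, tau^2 = %.3g\n",
    if (x$model == "fixed") "fixed" else "random",
    if (x$model == "fixed") "" else "s", x$k, if (x$k == 1L) "y" else "ies",
    x$beta_pooled, x$se_pooled, x$q_stat, x$q_pvalue, x$i_squared,
    x$tau_squared
  ))
  invisible(x)
}

check_estimates <- function(beta, se) {
  stop_if(length(beta) == 0L, "no slope estimates to pool")
  stop_if(length(beta) != length(se), "beta and se must have equal length")
  stop_if(anyNA(beta) || anyNA(se) || any(se <= 0),
          "all standard errors must be positive and non-missing")
}

#' Fixed-effect (inverse-variance) pooling of dose-response slopes
#'
#' Pools per-study slopes by inverse-variance weighting and reports Cochran's
#' Q heterogeneity statistic (chi-square with k - 1 df) and Higgins'
#' `I^2 = max(0, (Q - df)/Q) * 100`.
#'
#' @param beta Numeric vector of per-study slopes (log RR per g/day).
#' @param se Numeric vector of their standard errors (> 0).
#' @return A `meta_result` list: `beta_pooled`, `se_pooled`, `model`,
#'   `q_stat`, `q_pvalue`, `i_squared`, `tau_squared`, `k`.
#' @export
#' @examples
#' pool_fixed(c(0.01, 0.01), c(0.005, 0.005))
pool_fixed <- function(beta, se) {
  check_estimates(beta, se)
  w <- 1 / se^2
  bp <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - bp)^2)
  new_meta_result(bp, sqrt(1 / sum(w)), "fixed", q, length(beta))
}

#' DerSimonian-Laird random-effects pooling of dose-response slopes
#'
#' Method-of-moments between-study variance
#' `tau^2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))` with
#' fixed-effect weights, then inverse-variance pooling with
#' `w* = 1/(se^2 + tau^2)`. Homogeneous inputs (Q <= k - 1) truncate to
#' `tau^2 = 0` and reproduce the fixed-effect result.
#'
#' @inheritParams pool_fixed
#' @return A `meta_result` list (see [pool_fixed()]); `model = "random"`.
#' @export
pool_random <- function(beta, se) {
  check_estimates(beta, se)
  k <- length(beta)
  stop_if(k < 2L, "random-effects needs >=2 studies")
  w <- 1 / se^2
  bf <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - bf)^2)
  tau2 <- max(0, (q - (k - 1L)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  new_meta_result(sum(ws * beta) / sum(ws), sqrt(1 / sum(ws)), "random",
                  q, k, tau2 = tau2)
}

#' Select fixed- or random-effects estimate by the heterogeneity rule
#'
#' Returns the random-effects result when heterogeneity is flagged by either
#' trigger — `I^2 >= 80` or Cochran's Q p-value < 0.05 — and the fixed-effect
#' result otherwise. Reading the two triggers as OR is the conservative
#' interpretation of "in cases of heterogeneity".
#'
#' @param fixed,random `meta_result` objects computed from the same
#'   estimates by [pool_fixed()] and [pool_random()].
#' @param i2_threshold,p_threshold The two triggers (defaults 80 and 0.05).
#' @return The selected `meta_result`.
#' @export
choose_model <- function(fixed, random, i2_threshold = 80, p_threshold = 0.05) {
  stopifnot(inherits(fixed, "meta_result"), inherits(random, "meta_result"))
  stop_if(fixed$k != random$k, "fixed and random must pool the same studies")
  if (fixed$i_squared >= i2_threshold || fixed$q_pvalue < p_threshold) {
    random
  } else {
    fixed
  }
}

#' Begg's rank-correlation test for publication bias
#'
#' Kendall's rank correlation between the standardized deviates
#' `t_i = (beta_i - beta_fixed) / sqrt(se_i^2 - 1/sum(w))` and the sampling
#' variances `se_i^2`. The two-sided p-value uses the continuity-free normal
#' approximation `z = 3 * tau * sqrt(k(k-1)) / sqrt(2(2k+5))`; for small
#' meta-analyses (`k <= 8`) an exact permutation p-value from the Kendall
#' null distribution can be requested instead.
#'
#' @inheritParams pool_fixed
#' @param exact Use the exact Kendall null distribution (only honoured for
#'   `k <= 8` without ties).
#' @return List with `begg_tau` and `begg_pvalue` (`NA` with a warning when
#'   `k < 3`).
#' @export
begg_test <- function(beta, se, exact = FALSE) {
  check_estimates(beta, se)
  k <- length(beta)
  if (k < 3L) {
    warning("Begg's test needs >=3 studies; returning NA")
    return(list(begg_tau = NA_real_, begg_pvalue = NA_real_))
  }
  v <- se^2
  if (length(unique(v)) == 1L) {
    warning("all variances tied; Begg's tau set to 0")
    return(list(begg_tau = 0, begg_pvalue = 1))
  }
  w <- 1 / v
  bf <- sum(w * beta) / sum(w)
  vstar <- v - 1 / sum(w)
  # vstar > 0 whenever k >= 2 and weights are finite
  t_i <- (beta - bf) / sqrt(vstar)
  if (exact && k <= 8L) {
    ct <- suppressWarnings(cor.test(t_i, v, method = "kendall", exact = TRUE))
    return(list(begg_tau = unname(ct$estimate), begg_pvalue = ct$p.value))
  }
  tau <- unname(cor(rank(t_i), rank(v), method = "kendall"))
  z <- 3 * tau * sqrt(k * (k - 1)) / sqrt(2 * (2 * k + 5))
  list(begg_tau = tau, begg_pvalue = 2 * (1 - stats::pnorm(abs(z))))
}

#' Funnel-plot coordinates for a set of slope estimates
#'
#' Returns the (beta, se) scatter plus pseudo-confidence guide curves
#' `beta_fixed +/- 1.959964 * se` over a grid of standard errors, the usual
#' funnel-plot overlay. Purely numeric; no plotting.
#'
#' @inheritParams pool_fixed
#' @param n_grid Number of points in the guide-curve se grid.
#' @return List with data frames `points` (`beta`, `se`) and `guides`
#'   (`se`, `lower`, `upper`) and the scalar `center`.
#' @export
funnel_data <- function(beta, se, n_grid = 50L) {
  check_estimates(beta, se)
  w <- 1 / se^2
  center <- sum(w * beta) / sum(w)
  grid <- seq(0, max(se), length.out = n_grid)
  list(
    points = data.frame(beta = beta, se = se),
    guides = data.frame(se = grid,
                        lower = center - Z95 * grid,
                        upper = center + Z95 * grid),
    center = center
  )
}

#' Pool per-study slopes within each sex x site x outcome stratum
#'
#' Applies the fixed/random model-choice rule of [choose_model()] per
#' stratum (single-study strata pass through as fixed) and attaches Begg's
#' test where at least three studies are available. Strata with no
#' mortality-specific slope can optionally inherit the incidence slope
#' ("incidence RR used for mortality"), flagged in `fallback`.
#'
#' @param slopes Data frame from [fit_slopes()] (columns `study_id`, `sex`,
#'   `site`, `outcome`, `beta`, `se_beta`).
#' @param mortality_fallback Reuse each site/sex incidence pool for mortality
#'   when no mortality studies exist.
#' @return Data frame with one row per stratum: `sex`, `site`, `outcome`,
#'   `beta`, `se`, `model`, `k`, `q_stat`, `q_pvalue`, `i_squared`,
#'   `tau_squared`, `begg_tau`, `begg_pvalue`, `fallback`.
#' @export
pool_slopes <- function(slopes, mortality_fallback = TRUE) {
  key <- interaction(slopes$sex, slopes$site, slopes$outcome, drop = TRUE)
  rows <- lapply(split(slopes, key), function(d) {
    k <- nrow(d)
    fx <- pool_fixed(d$beta, d$se_beta)
    res <- if (k >= 2L) choose_model(fx, pool_random(d$beta, d$se_beta)) else fx
    bg <- if (k >= 3L) begg_test(d$beta, d$se_beta) else
      list(begg_tau = NA_real_, begg_pvalue = NA_real_)
    data.frame(
      sex = d$sex[1L], site = d$site[1L], outcome = d$outcome[1L],
      beta = res$beta_pooled, se = res$se_pooled, model = res$model, k = k,
      q_stat = res$q_stat, q_pvalue = res$q_pvalue,
      i_squared = res$i_squared, tau_squared = res$tau_squared,
      begg_tau = bg$begg_tau, begg_pvalue = bg$begg_pvalue,
      fallback = "none", stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (mortality_fallback) {
    inc <- out[out$outcome == "incidence", , drop = FALSE]
    for (i in seq_len(nrow(inc))) {
      has_mort <- any(out$outcome == "mortality" &
                        out$sex == inc$sex[i] & out$site == inc$site[i])
      if (!has_mort) {
        row <- inc[i, , drop = FALSE]
        row$outcome <- "mortality"
        row$fallback <- "incidence_beta"
        out <- rbind(out, row)
      }
    }
  }
  out <- out[order(out$sex, out$site, out$outcome), , drop = FALSE]
  rownames(out) <- NULL
  out
}
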