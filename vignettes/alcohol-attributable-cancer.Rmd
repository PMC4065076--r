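---
title: "Estimating the alcohol-attributable cancer burden from summarized dose-response data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the alcohol-attributable cancer burden from summarized dose-response data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afrac)
```

## The estimation problem

Alcoholic beverages are an established human carcinogen for cancers of the
oral cavity, pharynx, esophagus, colon, rectum, liver, larynx and the female
breast. Given (i) published categorical relative-risk tables relating
consumption (g of pure ethanol per day) to site-specific cancer risk,
(ii) the proportion of current drinkers in a population and their average
consumption, and (iii) registry counts of incident cases and deaths, `afrac`
estimates how much of the observed cancer burden is attributable to
drinking. The chain has four stages, each usable on its own:

1. **Dose-response slopes.** Each study's exposure categories are collapsed
   to midpoint doses and `log(RR)` is regressed on dose through the origin,
   yielding a slope $\beta$ in log relative risk per g/day.
2. **Meta-analytic pooling.** Per-study slopes are pooled by inverse
   variance, with a DerSimonian-Laird random-effects model when
   heterogeneity is flagged, plus Begg's rank-correlation diagnostic for
   small-study effects.
3. **Attributable fractions.** Levin's formula, extended to a continuous
   exposure, converts a pooled slope, a drinker proportion $P$ and a mean
   dose $d$ into
   $$\mathrm{PAF} = \frac{P(e^{\beta d} - 1)}{P(e^{\beta d} - 1) + 1},$$
   with delta-method confidence intervals, sensitivity bounds from the RR
   confidence limits, and counterfactual quartile scenarios.
4. **Burden.** PAFs times registry counts give attributable cases and
   deaths, totals, and the share of all cancers.

## Dose-response stage: assumptions and choices

The log-linear model $\log RR(d) = \beta d$ assumes risk grows
exponentially in dose, which summarizes the published categorical tables
well over the observed range (roughly 0-100 g/day); no spline or other
nonlinear shape is attempted.

Several decisions here were genuinely open and are worth recording:

* **No intercept.** RR is 1 by definition at dose 0, so the regression is
  forced through the origin and the non-drinking reference category enters
  as the exact point (0, 0). A free intercept would contradict
  $RR(0) = 1$.
* **Midpoints.** Closed categories use the arithmetic midpoint; the
  reference is dose 0; an open-ended top category ("$\geq 60$ g/day") is
  imputed as its lower bound plus half the width of the adjacent closed
  category, the common convention in summarized dose-response analysis.
* **Weights.** When every non-reference category reports a 95% CI, the fit
  is weighted by the inverse variance of `log(RR)`, with the variance
  recovered as $\left(\frac{\log \mathrm{ci_{high}} - \log
  \mathrm{ci_{low}}}{2 \times 1.959964}\right)^2$. If any CI is missing the
  whole table is fit unweighted — mixing weighted and unweighted points
  within one study would bias the slope. The reference point's log RR is
  known exactly; since a zero-variance weight is numerically degenerate it
  receives the largest finite weight in the table (it cannot influence the
  slope anyway, sitting at $x = 0$).
* **Standard errors.** With inverse-variance weights the category variances
  are treated as known, so $\mathrm{se}(\hat\beta) = (\sum_i w_i
  x_i^2)^{-1/2}$; the unweighted fallback uses the classical residual-based
  OLS standard error. We deliberately do not use `lm`'s residual-based se
  in the weighted case: on a table whose log RRs happen to be exactly
  log-linear it would report zero uncertainty.
* **Odds ratios** from case-control studies are treated as relative risks
  (rare-disease assumption), matching how the source literature pools them.
* Correlation between category estimates induced by the shared reference
  group (the Greenland-Longnecker problem) is ignored, as in the simple
  midpoint method; see "Limitations".

## Pooling stage

Fixed-effect pooling is the inverse-variance mean; heterogeneity is
summarized by Cochran's $Q$ (chi-square, $k-1$ df) and
$I^2 = \max(0, (Q - (k-1))/Q) \times 100$. The random-effects model is
DerSimonian-Laird: $\tau^2 = \max\!\left(0, \frac{Q - (k-1)}{\sum w_i -
\sum w_i^2 / \sum w_i}\right)$, then re-pooling with weights
$1/(se_i^2 + \tau^2)$.

The model-choice rule — random effects when $I^2 \geq 80$ **or** the $Q$
test has $p < 0.05$ — reads the two published triggers as a disjunction,
the conservative interpretation: either signal of heterogeneity switches to
the wider-variance model. Single-study strata pass through unchanged, and
strata with no mortality-specific studies can inherit the incidence slope
(flagged explicitly in the output), reflecting the assumption that drinking
affects cancer occurrence rather than survival.

Begg's test correlates the standardized deviates
$t_i = (\beta_i - \hat\beta_{fixed}) / \sqrt{se_i^2 - 1/\sum w_j}$ with the
variances $se_i^2$ by Kendall's $\tau$; the default p-value is the
continuity-free normal approximation
$z = 3\tau\sqrt{k(k-1)} / \sqrt{2(2k+5)}$, with an exact Kendall
permutation p-value available for $k \leq 8$, where the approximation is
crudest. With fewer than three studies the test is refused (a warning, not
an error). Funnel-plot coordinates are emitted as numbers; plotting is left
to the caller.

## PAF stage

All internal arithmetic is in proportions; percent appears only in reports
(one decimal for PAFs, two for RRs). Attributable counts multiply the
*unrounded* PAF by the registry count and round half away from zero —
rounding the PAF first visibly distorts large-count strata (e.g. a
four-decimal PAF difference moves hundreds of liver cases).

**Confidence intervals.** Only the slope's sampling variance is propagated,
on the identity scale:
$g'(\beta) = P d e^{\beta d} / (P(e^{\beta d}-1)+1)^2$ and
$\mathrm{CI} = g(\beta) \pm 1.959964\, |g'(\beta)|\, se_\beta$, clipped to
$[0, 1)$. The drinker proportion and dose are treated as fixed survey
constants. The delta method is first-order: against an exact
parametric-bootstrap oracle ($\beta^* \sim N(\beta, se^2)$, quantiles of
the monotone transform) it agrees to a few thousandths when
$se_\beta \cdot d \lesssim 0.06$, the regime of precisely pooled slopes,
and departs by the curvature term for wide-RR strata. For those strata the
appropriate published-practice summary is the **sensitivity interval**:
recompute the PAF with $\beta$ replaced by $\log(\mathrm{rr_{bound}})/d$
for each bound of the RR's 95% CI, clipping protective lower bounds at
zero.

**Calibrated prevalence.** The packaged Korea 2009 example needs the 1989
drinker proportions, which were published only in a supplementary table.
They are back-derived by inverting Levin's formula,
$P = \mathrm{PAF} / \left((1-\mathrm{PAF})(e^{\beta d}-1)\right)$, from two
published PAFs (male pharyngeal incidence 43.3%, female colorectal
incidence 4.2%), giving $P_{men} = 0.7767$ and $P_{women} = 0.2332$. The
inversion round-trips through the forward formula to $10^{-12}$. Because
43.3% is itself a rounded print, the calibrated proportion carries up to
about half a display unit of error into downstream values: most reproduce
the published PAFs to the printed decimal, while male larynx (computed
25.86%) and the male oral-cavity Q4 scenario (50.55%) sit one display unit
from the printed 25.8 and 50.5, consistent with the source analysis having
used an unrounded survey proportion near 0.775-0.776. Users with the actual
survey table can simply override `korea2009_prevalence()`.

**Scenarios.** Counterfactual PAFs replace the mean dose with the median of
the lowest (Q1) or highest (Q4) consumption quartile (56.0/2.80 g/day in
men, 28.0/0.80 in women for the packaged example), keeping $P$ fixed; the
Q4-Q1 difference summarizes the burden movable by shifting heavy drinkers
to light drinking. `dose_reduction_impact()` likewise recomputes the PAF
after an across-the-board reduction (one glass of beer or soju is about
12 g of ethanol) and joins it with counts.

## What the synthetic-data generator emulates

`simulate_study_tables()` reproduces the statistical structure the chain
assumes, so every stage is testable without downloads: study-level slopes
$\beta_i \sim N(\beta, \sigma_b^2)$, equal-width categories over a dose
range, and observed category log RRs with independent normal noise whose
variance follows a two-cell Poisson approximation
($se^2 = 1/\mathrm{cases}_{exposed} + 1/\mathrm{cases}_{ref}$, floored at
$10^{-6}$ so the infinite-case limit stays finite). Emitted CIs are exactly
$\exp(\log rr \pm 1.959964\, se)$, so the fitting stage recovers the
generating weights. The defaults — ten studies, three to five categories
over 0-80 g/day, 50-200 cases per category, true slope 0.015,
between-study SD 0.002 — mirror a small national evidence base of modest
cohort and case-control studies with moderate heterogeneity
(the implied true $I^2$ is near 60%).

What it does **not** emulate: correlated category errors from the shared
reference group, exposure measurement error and under-reporting (real
consumption surveys under-report heavy drinking, biasing PAFs downward),
non-log-linear dose-response shapes, and selective publication. Recovery
and coverage results under the generator are therefore best-case statements
about the estimator, not about field data.

`simulate_consumption_survey()` draws drinker status as Bernoulli and doses
as log-normal — the canonical right-skewed consumption law — and returns
the empirical drinker proportion, mean dose, and medians of the first and
fourth empirical quartiles, i.e. exactly the summary shape the PAF engine
consumes. Parameters are exposed, not hard-coded; matching a target mean
dose uses $E[X] = e^{\mu + \sigma^2/2}$.

## Numerical conventions

* The normal quantile is `qnorm(0.975)` = 1.959964 everywhere a 95%
  interval is built or inverted, so CI round-trips are exact.
* Degenerate inputs fail loudly: fewer than two non-reference categories,
  overlapping categories, an open interval with nothing below it to set its
  width, a reference RR different from 1, non-positive standard errors.
  A zero-width CI is flagged as degenerate rather than silently producing
  an infinite weight.
* $I^2$ is truncated at 0, $\tau^2$ at 0, PAF CIs at $[0, 1)$; Levin's
  formula returns exactly 0 when any of $P$, $\beta$, dose is 0.
* Generators save and restore the caller's RNG state, so fixed-seed
  fixtures are byte-identical regardless of surrounding code.
* Problem sizes used by the validation suite: 500 generator seeds for
  CI coverage of the pooled slope, 1000 null replicates for the size of
  Begg's test, $10^5$ bootstrap draws for the delta-method comparison, and
  a $10^6$-person two-stratum expected-case computation for the Levin
  equivalence — sizes at which Monte-Carlo error is well below the
  tolerances being checked.

## Known limitations

* **DerSimonian-Laird undercoverage.** With around ten studies and
  moderate heterogeneity, 95% CIs built as $\hat\beta \pm 1.96\,
  \mathrm{se}$ around the DL estimate are known to cover the true slope in
  only roughly 90% of replicates, because $\hat\tau^2$ is noisy and the
  normal quantile ignores that noise. The validation suite measures ~89%
  coverage under the generator defaults. Remedies such as the
  Hartung-Knapp adjustment are deliberately out of scope (the pipeline
  mirrors the plain DL practice of the underlying literature), so pooled
  CIs should be read as slightly optimistic when heterogeneity is
  substantial.
* **Delta-method domain.** As discussed above, identity-scale delta CIs
  are only claimed for precisely pooled slopes; elsewhere use the
  sensitivity bounds.
* **Published-table inconsistencies.** In the packaged Korea 2009 example
  a few published cells cannot be reproduced from the published inputs and
  are reported as computed instead: the female breast PAF computes to
  0.149% (printed as 0.2); the female colon/rectum attributable counts
  compute to 195/145 from the printed 4.2% PAF (the printed 236/178 imply
  about 5.1%); the female laryngeal mortality count 1,878 is internally
  inconsistent with its printed attributable count of 1 and is carried as
  printed; and the "one glass less per day" headline is exposed as an
  operation (`dose_reduction_impact()`) whose result is reported, not
  pinned, because its published derivation is ambiguous.
* PAFs here are fractions of current burden under instant, complete
  exposure removal with a fixed ~20-year latency alignment of survey and
  registry years; no lag structure, age stratification, or projection over
  time is modelled.

## A worked example

```{r}
res <- korea2009_paf_analysis()
subset(res$scenarios, sex == "male" & outcome == "incidence",
       select = -outcome)
res$burden$totals
```
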