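#' Round half away from zero
#'
#' Commercial rounding used for attributable counts; `round_half_out(0.5)`
#' is 1 (base `round()` would give 0 under round-half-even).
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @export
round_half_out <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Attributable cases or deaths for one stratum
#'
#' Multiplies the unrounded PAF by the registry count and rounds half away
#' from zero. Multiplying the full-precision PAF (rather than a PAF already
#' rounded for display) is what keeps large-count strata consistent with
#' their published attributable counts.
#'
#' @param paf PAF as a proportion in `[0, 1)`.
#' @param count Non-negative registry count.
#' @return Integer-valued numeric vector of attributable counts.
#' @export
#' @examples
#' attributable_count(0.43292, 703) # 304
attributable_count <- function(paf, count) {
  stop_if(any(paf < 0 | paf >= 1), "paf must lie in [0, 1)")
  stop_if(any(count < 0), "count must be non-negative")
  round_half_out(paf * count)
}

#' Join PAFs with registry counts into an attributable-burden table
#'
#' Produces the site-by-sex burden report: per-stratum attributable counts,
#' totals per sex and outcome, and the attributable percentage of all
#' cancers. Colon and rectum stay separate rows; a derived colorectal
#' aggregate can be appended for comparisons published at the combined
#' granularity.
#'
#' @param pafs Data frame with columns `sex`, `site`, `outcome`, `paf`
#'   (proportions); typically the `scenario_label == "baseline"` rows of
#'   [paf_table()].
#' @param counts Data frame with columns `sex`, `site`, `outcome`, `count`,
#'   `all_cancers_count`.
#' @param colorectal_aggregate Append a combined colon + rectum row per
#'   sex x outcome.
#' @return List of class `burden_table` with elements `rows` (per-site
#'   burden, `paf_percent` at full precision), `totals` (per sex x outcome:
#'   `attributable`, `all_cancers_count`, `percent_of_all_cancers`), and
#'   optionally `colorectal`.
#' @export
build_burden_table <- function(pafs, counts, colorectal_aggregate = TRUE) {
  stop_if(nrow(pafs) > 0 && any(duplicated(pafs[c("sex", "site", "outcome")])),
          "duplicate sex/site/outcome rows in pafs")
  key_p <- paste(pafs$sex, pafs$site, pafs$outcome, sep = "|")
  key_c <- paste(counts$sex, counts$site, counts$outcome, sep = "|")
  missing <- setdiff(key_p, key_c)
  stop_if(length(missing) > 0L,
          "no registry counts for: %s", paste(missing, collapse = "; "))
  m <- match(key_p, key_c)
  rows <- data.frame(
    sex = pafs$sex, site = pafs$site, outcome = pafs$outcome,
    paf = pafs$paf, paf_percent = 100 * pafs$paf,
    count = counts$count[m],
    attributable = attributable_count(pafs$paf, counts$count[m]),
    all_cancers_count = counts$all_cancers_count[m],
    stringsAsFactors = FALSE
  )
  rows <- rows[order(rows$sex, rows$outcome, rows$site), , drop = FALSE]
  rownames(rows) <- NULL

  totals <- if (nrow(rows) > 0) {
    agg <- aggregate(cbind(attributable = attributable) ~ sex + outcome,
                     data = rows, FUN = sum)
    denom <- rows[!duplicated(rows[c("sex", "outcome")]),
                  c("sex", "outcome", "all_cancers_count")]
    agg <- merge(agg, denom, by = c("sex", "outcome"))
    agg$percent_of_all_cancers <- 100 * agg$attributable / agg$all_cancers_count
    agg[order(agg$sex, agg$outcome), , drop = FALSE]
  } else {
    data.frame(sex = character(), outcome = character(),
               attributable = numeric(), all_cancers_count = numeric(),
               percent_of_all_cancers = numeric())
  }
  rownames(totals) <- NULL

  out <- list(rows = rows, totals = totals)
  if (colorectal_aggregate && nrow(rows) > 0) {
    cr <- rows[rows$site %in% c("colon", "rectum"), , drop = FALSE]
    if (nrow(cr) > 0) {
      agg <- aggregate(cbind(count = count, attributable = attributable) ~
                         sex + outcome, data = cr, FUN = sum)
      agg$site <- "colorectal"
      out$colorectal <- agg[, c("sex", "site", "outcome", "count",
                                "attributable")]
      rownames(out$colorectal) <- NULL
    }
  }
  class(out) <- "burden_table"
  out
}

#' @export
print.burden_table <- function(x, ...) {
  cat("Attributable burden\n")
  if (nrow(x$rows) == 0) {
    cat("  (empty)\n")
    return(invisible(x))
  }
  df <- x$rows
  df$paf_percent <- sprintf("%.1f", df$paf_percent)
  print(df[, c("sex", "site", "outcome", "paf_percent", "count",
               "attributable")], row.names = FALSE)
  cat("\nTotals\n")
  tt <- x$totals
  tt$percent_of_all_cancers <- sprintf("%.1f", tt$percent_of_all_cancers)
  print(tt, row.names = FALSE)
  invisible(x)
}

#' Counterfactual-scenario PAF report
#'
#' Reshapes a long scenario PAF table into the wide per-site report with
#' baseline, Q4 and Q1 PAFs and the Q4 - Q1 difference, in percent.
#'
#' @param pafs Long data frame from [paf_table()] with `scenario_label` in
#'   `baseline`, `q1`, `q4`.
#' @return Data frame with columns `sex`, `site`, `outcome`,
#'   `paf_percent`, `paf_q4_percent`, `paf_q1_percent`,
#'   `paf_q4_minus_q1_percent` (full precision; round for display).
#' @export
scenario_table <- function(pafs) {
  need <- c("baseline", "q1", "q4")
  strata <- unique(pafs[c("sex", "site", "outcome")])
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    sel <- pafs$sex == strata$sex[i] & pafs$site == strata$site[i] &
      pafs$outcome == strata$outcome[i]
    d <- pafs[sel, , drop = FALSE]
    have <- need %in% d$scenario_label
    stop_if(!all(have), "missing scenario(s) %s for %s/%s/%s",
            paste(need[!have], collapse = ", "),
            strata$sex[i], strata$site[i], strata$outcome[i])
    g <- function(sc) 100 * d$paf[d$scenario_label == sc][1L]
    data.frame(
      sex = strata$sex[i], site = strata$site[i], outcome = strata$outcome[i],
      paf_percent = g("baseline"), paf_q4_percent = g("q4"),
      paf_q1_percent = g("q1"),
      paf_q4_minus_q1_percent = g("q4") - g("q1"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a burden + scenario report as Markdown lines
#'
#' Human-readable mirror of the burden and scenario tables, with PAFs at one
#' decimal of percent and RRs at two decimals.
#'
#' @param burden A `burden_table` from [build_burden_table()].
#' @param scenarios Optional data frame from [scenario_table()].
#' @return Character vector of Markdown lines (invisibly printable via
#'   `writeLines`).
#' @export
render_burden_report <- function(burden, scenarios = NULL) {
  lines <- c("# Alcohol-attributable cancer burden", "",
             "| sex | site | outcome | PAF (%) | count | attributable |",
             "|---|---|---|---|---|---|")
  r <- burden$rows
  lines <- c(lines, sprintf("| %s | %s | %s | %.1f | %d | %d |",
                            r$sex, r$site, r$outcome, r$paf_percent,
                            as.integer(r$count), as.integer(r$attributable)))
  t <- burden$totals
  lines <- c(lines, "", "| sex | outcome | attributable | all cancers | % of all |",
             "|---|---|---|---|---|",
             sprintf("| %s | %s | %d | %d | %.1f |", t$sex, t$outcome,
                     as.integer(t$attributable),
                     as.integer(t$all_cancers_count),
                     t$percent_of_all_cancers))
  if (!is.null(scenarios)) {
    lines <- c(lines, "", "## Consumption scenarios", "",
               "| sex | site | outcome | PAF | PAF(Q4) | PAF(Q1) | PAF(Q4-Q1) |",
               "|---|---|---|---|---|---|---|",
               sprintf("| %s | %s | %s | %.1f | %.1f | %.1f | %.1f |",
                       scenarios$sex, scenarios$site, scenarios$outcome,
                       scenarios$paf_percent, scenarios$paf_q4_percent,
                       scenarios$paf_q1_percent,
                       scenarios$paf_q4_minus_q1_percent))
  }
  lines
}
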