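#' Read a long category-level studies table
#'
#' Reads `studies.csv` (UTF-8, header; one row per exposure category) with
#' columns `study_id`, `sex`, `site`, `outcome`, `design`, `lower_gday`,
#' `upper_gday` (empty = open-ended), `rr`, `ci_low`, `ci_high`, `n_cases`,
#' `is_reference`.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_studies <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$is_reference <- as.logical(df$is_reference)
  df
}

valid_sexes <- c("male", "female", "both")
valid_outcomes <- c("incidence", "mortality")
valid_designs <- c("cohort", "case_control")

#' Validate the pipeline input tables
#'
#' Schema and invariant checks for the three input tables. Violations are
#' itemized with row numbers; hard errors (which would make a downstream
#' stage fail or give a wrong answer) are separated from warnings. Site
#' labels outside the eight alcohol-associated sites are warned about
#' unless listed in `extra_sites`.
#'
#' @param studies Category-level study table ([read_studies()] shape), or
#'   `NULL` if the run starts from pooled slopes.
#' @param prevalence Exposure prevalence table (`sex`, `p_drinkers`,
#'   `mean_dose_gday`, `q1_median_gday`, `q4_median_gday`).
#' @param counts Registry count table (`sex`, `site`, `outcome`, `count`,
#'   `all_cancers_count`).
#' @param extra_sites Additional site labels to accept silently.
#' @return List of class `validation_report` with character vectors
#'   `errors` and `warnings`; empty `errors` means the inputs are usable.
#' @export
validate_inputs <- function(studies = NULL, prevalence = NULL, counts = NULL,
                            extra_sites = character()) {
  errors <- character()
  warns <- character()
  sites_ok <- c(names(alcohol_cancer_sites()), extra_sites)
  add_err <- function(...) errors <<- c(errors, sprintf(...))
  add_warn <- function(...) warns <<- c(warns, sprintf(...))

  if (!is.null(studies)) {
    need <- c("study_id", "sex", "site", "outcome", "lower_gday",
              "upper_gday", "rr", "is_reference")
    miss <- setdiff(need, names(studies))
    if (length(miss)) {
      add_err("studies: missing column(s) %s", paste(miss, collapse = ", "))
    } else {
      bad <- which(!is.na(studies$rr) & studies$rr <= 0)
      for (i in bad) add_err("studies row %d: rr must be positive", i)
      bad <- which(is.na(studies$rr))
      for (i in bad) add_err("studies row %d: rr is missing", i)
      bad <- which(studies$is_reference &
                     abs(studies$rr - 1) > .Machine$double.eps^0.5)
      for (i in bad) add_err("studies row %d: reference RR must be 1", i)
      bad <- which(is.na(studies$lower_gday) | studies$lower_gday < 0)
      for (i in bad) add_err("studies row %d: lower_gday must be >= 0", i)
      bad <- which(!is.na(studies$upper_gday) &
                     studies$upper_gday < studies$lower_gday)
      for (i in bad) add_err("studies row %d: upper_gday < lower_gday", i)
      has_ci <- !is.na(studies$ci_low) & !is.na(studies$ci_high)
      bad <- which(has_ci & (studies$ci_low > studies$rr |
                               studies$rr > studies$ci_high))
      for (i in bad) add_err("studies row %d: CI must bracket rr", i)
      bad <- which(!studies$sex %in% valid_sexes)
      for (i in bad) add_err("studies row %d: sex must be one of %s", i,
                             paste(valid_sexes, collapse = "/"))
      bad <- which(!studies$outcome %in% valid_outcomes)
      for (i in bad) add_err("studies row %d: unknown outcome", i)
      bad <- which(!studies$site %in% sites_ok)
      for (i in bad) add_warn("studies row %d: site '%s' is not one of the eight alcohol-associated sites", i, studies$site[i])
      key <- interaction(studies$study_id, studies$sex, studies$site,
                         studies$outcome, drop = TRUE)
      for (g in split(seq_len(nrow(studies)), key)) {
        nref <- sum(studies$is_reference[g])
        if (nref != 1L) {
          add_err("studies %s: %d reference categories (need exactly 1)",
                  as.character(key[g[1L]]), nref)
        }
        if (sum(!studies$is_reference[g]) < 2L) {
          add_err("studies %s: fewer than 2 non-reference categories",
                  as.character(key[g[1L]]))
        }
      }
    }
  }

  if (!is.null(prevalence)) {
    need <- c("sex", "p_drinkers", "mean_dose_gday", "q1_median_gday",
              "q4_median_gday")
    miss <- setdiff(need, names(prevalence))
    if (length(miss)) {
      add_err("prevalence: missing column(s) %s", paste(miss, collapse = ", "))
    } else {
      bad <- which(prevalence$p_drinkers < 0 | prevalence$p_drinkers > 1)
      for (i in bad) add_err("prevalence row %d: p_drinkers outside [0, 1]", i)
      bad <- which(prevalence$q1_median_gday > prevalence$q4_median_gday)
      for (i in bad) add_err("prevalence row %d: q1 median exceeds q4 median", i)
      bad <- which(prevalence$mean_dose_gday < 0 |
                     prevalence$q1_median_gday < 0)
      for (i in bad) add_err("prevalence row %d: doses must be >= 0", i)
    }
  }

  if (!is.null(counts)) {
    need <- c("sex", "site", "outcome", "count", "all_cancers_count")
    miss <- setdiff(need, names(counts))
    if (length(miss)) {
      add_err("counts: missing column(s) %s", paste(miss, collapse = ", "))
    } else {
      bad <- which(counts$count < 0)
      for (i in bad) add_err("counts row %d: negative count", i)
      bad <- which(counts$count > counts$all_cancers_count)
      for (i in bad) add_err("counts row %d: count exceeds all-cancers total", i)
      bad <- which(!counts$site %in% sites_ok)
      for (i in bad) add_warn("counts row %d: site '%s' is not one of the eight alcohol-associated sites", i, counts$site[i])
    }
  }

  structure(list(errors = errors, warnings = warns),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (length(x$errors) == 0 && length(x$warnings) == 0) {
    cat("inputs valid: no issues found\n")
  }
  if (length(x$errors)) {
    cat("errors:\n")
    cat(paste0("  - ", x$errors, "\n"), sep = "")
  }
  if (length(x$warnings)) {
    cat("warnings:\n")
    cat(paste0("  - ", x$warnings, "\n"), sep = "")
  }
  invisible(x)
}

#' Run the attributable-fraction pipeline end to end
#'
#' Executes slope fitting (when a category-level studies table is given),
#' meta-analytic pooling, the PAF engine and the burden builder, writing
#' `slopes.csv`, `pooled.csv`, `paf.csv`, `burden.csv`, `scenarios.csv`,
#' `report.md` and `run_log.txt` to `out_dir`. A run may instead start from
#' an already-pooled slope table (as the packaged Korea 2009 example does)
#' by passing `pooled`.
#'
#' @param studies Category-level studies data frame, or `NULL`.
#' @param pooled Pooled-slope data frame (`sex`, `site`, `outcome`, `beta`,
#'   `se`, optional `rr_ci_low`/`rr_ci_high`), required when `studies` is
#'   `NULL`.
#' @param prevalence Exposure prevalence data frame.
#' @param counts Registry counts data frame.
#' @param out_dir Output directory (created if absent); `NULL` skips
#'   writing.
#' @param seed Integer seed recorded in the run log (the deterministic
#'   stages do not consume randomness, but downstream simulation helpers
#'   honour it).
#' @return Invisible list with `slopes`, `pooled`, `paf`, `burden`,
#'   `scenarios`.
#' @export
run_pipeline <- function(studies = NULL, pooled = NULL, prevalence, counts,
                         out_dir = NULL, seed = 1L) {
  rep <- validate_inputs(studies = studies, prevalence = prevalence,
                         counts = counts)
  stop_if(length(rep$errors) > 0L, "input validation failed:\n%s",
          paste(rep$errors, collapse = "\n"))
  stop_if(is.null(studies) && is.null(pooled),
          "need either a studies table or a pooled slope table")

  slopes <- NULL
  if (!is.null(studies)) {
    slopes <- tryCatch(fit_slopes(studies), error = function(e)
      stop("dose_response stage failed: ", conditionMessage(e), call. = FALSE))
    pooled_fit <- tryCatch(pool_slopes(slopes), error = function(e)
      stop("meta_analysis stage failed: ", conditionMessage(e), call. = FALSE))
    if (is.null(pooled)) pooled <- pooled_fit
  }
  paf <- tryCatch(paf_table(pooled, prevalence), error = function(e)
    stop("paf_engine stage failed: ", conditionMessage(e), call. = FALSE))
  baseline <- paf[paf$scenario_label == "baseline", , drop = FALSE]
  keep <- paste(baseline$sex, baseline$site, baseline$outcome) %in%
    paste(counts$sex, counts$site, counts$outcome)
  burden <- tryCatch(build_burden_table(baseline[keep, , drop = FALSE], counts),
                     error = function(e)
    stop("burden stage failed: ", conditionMessage(e), call. = FALSE))
  scenarios <- scenario_table(paf)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      write.csv(df, file.path(out_dir, name), row.names = FALSE)
    }
    if (!is.null(slopes)) wr(slopes, "slopes.csv")
    wr(pooled, "pooled.csv")
    wr(paf, "paf.csv")
    wr(burden$rows, "burden.csv")
    wr(scenarios, "scenarios.csv")
    writeLines(render_burden_report(burden, scenarios),
               file.path(out_dir, "report.md"))
    writeLines(c(
      sprintf("seed: %d", seed),
      sprintf("run time (UTC): %s", format(Sys.time(), tz = "UTC")),
      sprintf("strata: %d pooled, %d paf rows, %d burden rows",
              nrow(pooled), nrow(paf), nrow(burden$rows))
    ), file.path(out_dir, "run_log.txt"))
  }
  invisible(list(slopes = slopes, pooled = pooled, paf = paf,
                 burden = burden, scenarios = scenarios))
}
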