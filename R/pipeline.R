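# Full-analysis orchestration --------------------------------------------

#' Analysis configuration
#'
#' @param endpoints Endpoints to analyse (`"os"`, `"pfs"` or both).
#' @param horizons Strictly increasing predictive-value horizons in months.
#' @param bootstrap_B Bootstrap replicates for marker comparisons (>= 100).
#' @param seed Integer seed for the bootstrap.
#' @param chemo_exempt_nlr2 Passed to [apply_exclusions()].
#' @return A validated list of class `analysis_config`.
#' @export
analysis_config <- function(endpoints = c("os", "pfs"),
                            horizons = c(6, 12, 18, 24),
                            bootstrap_B = 2000,
                            seed = 1L,
                            chemo_exempt_nlr2 = FALSE) {
  stopifnot(all(endpoints %in% c("os", "pfs")),
            all(horizons > 0), !is.unsorted(horizons, strictly = TRUE),
            bootstrap_B >= 100)
  structure(list(endpoints = endpoints, horizons = horizons,
                 bootstrap_B = bootstrap_B, seed = as.integer(seed),
                 chemo_exempt_nlr2 = chemo_exempt_nlr2),
            class = "analysis_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("analysis stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full iSEND analysis
#'
#' Executes, in order: exclusion cascade, haematology derivation, scoring
#' and group sizes, per-endpoint Kaplan-Meier curves with medians and
#' log-rank across iSEND groups (pooled and per cohort label), reverse-KM
#' median follow-up, multivariate Cox (male sex, ECOG >= 2, composite
#' biomarker) per cohort, time-dependent PPV/NPV marker comparisons
#' restricted to PD-L1-available patients, the demographics comparison
#' table, and the four-group sex-by-smoking subgroup analysis. Any stage
#' failure aborts with the stage name.
#'
#' @param cohort Raw cohort data frame (canonical schema).
#' @param config An [analysis_config()].
#' @return A list of class `isend_analysis` with sections `exclusions`,
#'   `groups`, `survival` (per endpoint: `medians`, `log_rank` per cohort
#'   label and pooled), `followup`, `cox` (per cohort label and pooled),
#'   `predictive` (PPV poor vs PD-L1 0\% and NPV good vs PD-L1 >= 50\%, or
#'   a `NOT_ESTIMABLE` marker when no PD-L1 data), `table1`, `subgroups`,
#'   and `meta` (config, seeds, package version).
#' @export
run_full_analysis <- function(cohort, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  excl <- stage("exclusions",
                apply_exclusions(cohort, config$chemo_exempt_nlr2))
  dat <- stage("haematology", derive_haematology(excl$records))
  scored <- stage("scoring", assign_groups(dat))
  dat <- scored$records
  labels <- unique(dat$cohort[!is.na(dat$cohort)])
  surv_section <- list()
  for (ep in config$endpoints) {
    per_label <- list()
    per_label$pooled <- stage(paste0("km_", ep), {
      e <- endpoint_cols(dat, ep)
      km_by_group(e$time, e$event, dat$isend_group)
    })
    for (lb in labels) {
      sub <- dat[dat$cohort == lb, , drop = FALSE]
      per_label[[lb]] <- stage(paste0("km_", ep, "_", lb), {
        e <- endpoint_cols(sub, ep)
        if (length(unique(sub$isend_group)) >= 2 && nrow(sub) > 0)
          km_by_group(e$time, e$event, sub$isend_group) else NULL
      })
    }
    surv_section[[ep]] <- per_label
  }
  followup <- stage("followup",
                    reverse_km_followup(dat$os_time, dat$os_event))
  cox_for <- function(sub) {
    cox_ph(data.frame(male = as.integer(sub$sex == "male"),
                      ecog2plus = as.integer(sub$ecog >= 2),
                      composite = sub$composite_flag),
           sub$os_time, sub$os_event)
  }
  cox_section <- list(pooled = stage("cox_pooled", cox_for(dat)))
  for (lb in labels)
    cox_section[[lb]] <- stage(paste0("cox_", lb), {
      sub <- dat[dat$cohort == lb, , drop = FALSE]
      if (sum(sub$os_event) >= 10) cox_for(sub) else NULL
    })
  pdl1_avail <- dat[!is.na(dat$pdl1) & dat$pdl1 != "unknown", , drop = FALSE]
  predictive <- if (nrow(pdl1_avail) == 0 ||
                    !any(pdl1_avail$pdl1 == "p0") ||
                    !any(pdl1_avail$isend_group == "poor")) {
    list(status = "NOT_ESTIMABLE",
         reason = "no PD-L1-available patients with the compared markers")
  } else stage("predictive_values", {
    list(status = "ok",
         n_pdl1 = nrow(pdl1_avail),
         ppv_poor_vs_pdl1_0 = compare_markers_table(
           pdl1_avail, marker_isend_poor(), marker_pdl1_0(),
           horizons = config$horizons, endpoint = "os", kind = "ppv",
           B = config$bootstrap_B, seed = config$seed),
         npv_good_vs_pdl1_high = if (any(pdl1_avail$pdl1 == "p50plus") &&
                                       any(pdl1_avail$isend_group == "good"))
           compare_markers_table(
             pdl1_avail, marker_isend_good(), marker_pdl1_high(),
             horizons = config$horizons, endpoint = "os", kind = "npv",
             B = config$bootstrap_B, seed = config$seed + 1000L)
         else NULL)
  })
  tab1 <- stage("table1", build_table1(dat))
  subgroups <- stage("subgroups", subgroup_analysis(dat, endpoint = "pfs"))
  structure(list(exclusions = excl$tally,
                 n_analysis = nrow(dat),
                 groups = scored$summary,
                 survival = surv_section,
                 followup = followup,
                 cox = cox_section,
                 predictive = predictive,
                 table1 = tab1,
                 subgroups = subgroups,
                 meta = list(config = unclass(config),
                             package_version =
                               as.character(utils::packageVersion("isend")))),
            class = "isend_analysis")
}

#' Sex-by-smoking subgroup survival analysis
#'
#' Regroups patients into the four sex-by-smoking-history subgroups, in the
#' order: female with smoking history, male with smoking history, female
#' without smoking history, male without smoking history. Unknown smoking
#' history is excluded. Returns per-subgroup KM medians with CIs and the
#' overall log-rank test across the non-empty subgroups (a warning is
#' issued for each empty subgroup, which is excluded; df adjusts
#' accordingly).
#'
#' @param cohort Cohort data frame with `sex` and `smoking`.
#' @param endpoint `"os"` or `"pfs"`.
#' @return A list: `medians` (data frame in the fixed subgroup order, empty
#'   subgroups marked `n = 0`), `log_rank`, `n_excluded_unknown`.
#' @export
subgroup_analysis <- function(cohort, endpoint = c("pfs", "os")) {
  endpoint <- match.arg(endpoint)
  known <- !is.na(cohort$smoking) & cohort$smoking != "unknown"
  sub <- cohort[known, , drop = FALSE]
  lv <- c("female_smoker", "male_smoker", "female_never", "male_never")
  g <- factor(paste0(sub$sex, ifelse(sub$smoking == "any",
                                     "_smoker", "_never")), levels = lv)
  e <- endpoint_cols(sub, endpoint)
  med_rows <- lapply(lv, function(l) {
    i <- g == l
    if (!any(i)) {
      warning("empty subgroup excluded: ", l)
      return(data.frame(group = l, n = 0L, n_events = 0L,
                        median = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, stringsAsFactors = FALSE))
    }
    m <- median_survival(km_curve(e$time[i], e$event[i]))
    data.frame(group = l, n = m$n, n_events = m$n_events,
               median = m$median, ci_lower = m$ci_lower,
               ci_upper = m$ci_upper, stringsAsFactors = FALSE)
  })
  nonempty <- levels(droplevels(g))
  lr <- if (length(nonempty) >= 2) {
    i <- g %in% nonempty
    log_rank(e$time[i], e$event[i], droplevels(g[i]))
  } else NULL
  list(medians = do.call(rbind, med_rows), log_rank = lr,
       n_excluded_unknown = sum(!known))
}

#' Write an analysis bundle to disk
#'
#' Emits the report files: `exclusions.json`, `groups.csv`, `medians_<ep>.csv`,
#' `cox_<label>.csv`, `ppv_comparison.csv` (+ `ppv_meta.json`),
#' `table1_categorical.csv`, `table1_continuous.csv`, `subgroups.csv` and a
#' plain-text `run_log.txt` recording exclusion counts, seeds and the
#' scoring-module version. Re-running with identical inputs and config
#' yields byte-identical files.
#'
#' @param bundle An `isend_analysis` from [run_full_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "isend_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                        row.names = FALSE, na = "NR")
  write_exclusion_tally(bundle$exclusions, file.path(dir, "exclusions.json"))
  w(bundle$groups, "groups.csv")
  for (ep in names(bundle$survival)) {
    med <- bundle$survival[[ep]]$pooled$medians
    w(med, sprintf("medians_%s.csv", ep))
  }
  for (lb in names(bundle$cox))
    if (!is.null(bundle$cox[[lb]]))
      w(as.data.frame(bundle$cox[[lb]]), sprintf("cox_%s.csv", lb))
  if (identical(bundle$predictive$status, "ok")) {
    w(bundle$predictive$ppv_poor_vs_pdl1_0, "ppv_comparison.csv")
    jsonlite::write_json(
      list(B = bundle$meta$config$bootstrap_B,
           seed = bundle$meta$config$seed,
           method = "paired bootstrap + Wald"),
      file.path(dir, "ppv_meta.json"), auto_unbox = TRUE)
  }
  w(bundle$table1$categorical, "table1_categorical.csv")
  w(bundle$table1$continuous, "table1_continuous.csv")
  w(bundle$subgroups$medians, "subgroups.csv")
  log_lines <- c(
    "isend run log",
    sprintf("package_version: %s", bundle$meta$package_version),
    sprintf("n_analysis: %d", bundle$n_analysis),
    sprintf("exclusions: %s",
            paste(names(bundle$exclusions), bundle$exclusions,
                  sep = "=", collapse = ", ")),
    sprintf("bootstrap_seed: %d", bundle$meta$config$seed),
    sprintf("bootstrap_B: %d", bundle$meta$config$bootstrap_B),
    sprintf("endpoints: %s",
            paste(bundle$meta$config$endpoints, collapse = ",")),
    sprintf("horizons: %s",
            paste(bundle$meta$config$horizons, collapse = ",")))
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}
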