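# Time-dependent predictive values of binary prognostic markers ----------
#
# Estimand: for a marker oriented towards predicting the event,
# PPV(t) = P(event <= t | marker positive), estimated as 1 - S_KM(t) where
# S_KM is the Kaplan-Meier curve restricted to the marker-positive patients.
# For a marker oriented towards predicting survival,
# NPV(t) = P(event-free at t | marker positive) = S_KM(t).
# This within-group product-limit definition handles right censoring and
# reduces to the naive binomial proportion when no one is censored before t.

#' Define a binary prognostic marker
#'
#' @param name Marker name used in reports.
#' @param positive A predicate: function taking the cohort data frame and
#'   returning a logical vector (must be total, i.e. no `NA`).
#' @param orientation `"predicts_event"` (PPV-type, e.g. iSEND Poor,
#'   PD-L1 = 0\%) or `"predicts_survival"` (NPV-type, e.g. iSEND Good,
#'   PD-L1 >= 50\%).
#' @return An object of class `binary_marker`.
#' @export
binary_marker <- function(name, positive,
                          orientation = c("predicts_event",
                                          "predicts_survival")) {
  stopifnot(is.function(positive))
  structure(list(name = name, positive = positive,
                 orientation = match.arg(orientation)),
            class = "binary_marker")
}

#' Built-in markers for the iSEND / PD-L1 comparison
#'
#' `isend_poor` and `pdl1_0` predict mortality; `isend_good` and
#' `pdl1_high` predict survival. The iSEND markers require an
#' `isend_group` column (see [assign_groups()]).
#'
#' @name standard_markers
#' @return A `binary_marker`.
NULL

#' @rdname standard_markers
#' @export
marker_isend_poor <- function()
  binary_marker("iSEND Poor", function(d) d$isend_group == "poor",
                "predicts_event")

#' @rdname standard_markers
#' @export
marker_isend_good <- function()
  binary_marker("iSEND Good", function(d) d$isend_group == "good",
                "predicts_survival")

#' @rdname standard_markers
#' @export
marker_pdl1_0 <- function()
  binary_marker("PD-L1 0%", function(d) !is.na(d$pdl1) & d$pdl1 == "p0",
                "predicts_event")

#' @rdname standard_markers
#' @export
marker_pdl1_high <- function()
  binary_marker("PD-L1 >= 50%",
                function(d) !is.na(d$pdl1) & d$pdl1 == "p50plus",
                "predicts_survival")

endpoint_cols <- function(cohort, endpoint = c("os", "pfs")) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "os") list(time = cohort$os_time, event = cohort$os_event)
  else list(time = cohort$pfs_time, event = cohort$pfs_event)
}

# Fast scalar product-limit evaluation used in the bootstrap inner loop;
# cross-checked against survfit in the test suite. Events before censorings
# at tied times. Returns S(t0), or NA when no subject is at risk at t0 and
# the curve has not already dropped to zero.
.km_surv_at <- function(time, event, t0) {
  dt <- unique(time[event == 1 & time <= t0])
  s <- 1
  for (d in dt) {
    nr <- sum(time >= d)
    s <- s * (1 - sum(time == d & event == 1) / nr)
  }
  if (s > 0 && !any(time >= t0)) return(NA_real_)
  s
}

pv_not_estimable <- function(marker, horizon, kind, reason, n_group = 0L) {
  structure(list(marker = marker$name, horizon = horizon, kind = kind,
                 value = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                 n_group = n_group, estimable = FALSE, reason = reason),
            class = "predictive_value")
}

pv_estimate <- function(cohort, marker, horizon, endpoint, kind) {
  if (horizon <= 0) stop("horizon must be positive")
  pos <- marker$positive(cohort)
  if (any(is.na(pos))) stop("marker predicate must be total (no NA)")
  n_group <- sum(pos)
  if (n_group == 0)
    return(pv_not_estimable(marker, horizon, kind, "empty marker group"))
  ep <- endpoint_cols(cohort, endpoint)
  tt <- ep$time[pos]; ev <- ep$event[pos]
  fit <- survival::survfit(survival::Surv(tt, ev) ~ 1, conf.type = "log-log")
  sm <- summary(fit, times = horizon, extend = TRUE)
  if (sm$n.risk < 1 && min(fit$surv) > 0)
    return(pv_not_estimable(marker, horizon, kind,
                            "no subject at risk at horizon", n_group))
  s <- sm$surv; lo <- sm$lower; up <- sm$upper
  if (kind == "ppv") {
    value <- 1 - s
    ci <- c(1 - up, 1 - lo)       # complemented log-log Greenwood band
  } else {
    value <- s
    ci <- c(lo, up)
  }
  if (anyNA(ci)) ci <- c(NA_real_, NA_real_)
  structure(list(marker = marker$name, horizon = horizon, kind = kind,
                 value = value, ci_lower = ci[1], ci_upper = ci[2],
                 n_group = n_group, estimable = TRUE, reason = NA_character_),
            class = "predictive_value")
}

#' Time-dependent positive predictive value
#'
#' PPV(t) of a binary marker for the event (mortality for `endpoint = "os"`,
#' progression-or-death for `"pfs"`): the probability of the event by the
#' horizon given a positive marker, estimated as one minus the Kaplan-Meier
#' survival of the marker-positive subgroup, with the complemented log-log
#' Greenwood band as CI. With no censoring before the horizon this is
#' exactly the binomial proportion of events.
#'
#' @param cohort Cohort data frame.
#' @param marker A [binary_marker()] (oriented `predicts_event`).
#' @param horizon Horizon in months (> 0).
#' @param endpoint `"os"` or `"pfs"`.
#' @return A `predictive_value` object: `value`, `ci_lower`, `ci_upper`,
#'   `n_group`, `estimable`, `reason`. An empty marker group or zero at-risk
#'   count at the horizon yields an inestimable result with a reason, not an
#'   error.
#' @export
time_dependent_ppv <- function(cohort, marker, horizon, endpoint = "os")
  pv_estimate(cohort, marker, horizon, endpoint, "ppv")

#' Time-dependent negative predictive value
#'
#' NPV(t) of a favourable marker: the probability of remaining event-free at
#' the horizon given the marker indicates good outcome, i.e. the
#' Kaplan-Meier survival of the marker-positive subgroup itself.
#'
#' @inheritParams time_dependent_ppv
#' @param marker A [binary_marker()] (oriented `predicts_survival`).
#' @return A `predictive_value` object (see [time_dependent_ppv()]).
#' @export
time_dependent_npv <- function(cohort, marker, horizon, endpoint = "os")
  pv_estimate(cohort, marker, horizon, endpoint, "npv")

#' @export
print.predictive_value <- function(x, digits = 3, ...) {
  if (!x$estimable) {
    cat(sprintf("%s %s(%g mo): not estimable (%s)\n",
                x$marker, toupper(x$kind), x$horizon, x$reason))
  } else {
    cat(sprintf("%s %s(%g mo) = %.*f (95%% CI %.*f-%.*f), n = %d\n",
                x$marker, toupper(x$kind), x$horizon, digits, x$value,
                digits, x$ci_lower, digits, x$ci_upper, x$n_group))
  }
  invisible(x)
}

#' Compare two markers' predictive values by paired bootstrap
#'
#' Tests the difference of two markers' PPVs (or NPVs) at a fixed horizon on
#' the same cohort, allowing overlapping marker groups. Patients are
#' resampled with replacement `B` times from the union cohort; both
#' predictive values are recomputed on each replicate; the p-value is a
#' two-sided Wald test of the observed difference against the bootstrap
#' standard error. Replicates in which either marker group is empty or has
#' no subject at risk at the horizon are redrawn, up to `10 * B` total
#' attempts.
#'
#' @param cohort Cohort data frame (both marker groups estimable at the
#'   horizon).
#' @param marker_a,marker_b Two [binary_marker()] objects.
#' @param horizon Horizon in months.
#' @param endpoint `"os"` or `"pfs"`.
#' @param kind `"ppv"` or `"npv"`.
#' @param B Bootstrap replicates (default 2000).
#' @param seed Integer seed; recorded in the result for reproducibility.
#' @return An object of class `marker_comparison`: `estimate_a`,
#'   `estimate_b` (`predictive_value`s), `difference` (a minus b),
#'   `se_boot`, `p_value`, `B`, `seed`, `method`.
#' @export
compare_markers <- function(cohort, marker_a, marker_b, horizon,
                            endpoint = "os", kind = c("ppv", "npv"),
                            B = 2000, seed) {
  kind <- match.arg(kind)
  if (missing(seed)) stop("seed is required for reproducibility")
  est_a <- pv_estimate(cohort, marker_a, horizon, endpoint, kind)
  est_b <- pv_estimate(cohort, marker_b, horizon, endpoint, kind)
  if (!est_a$estimable || !est_b$estimable)
    stop("both marker groups must be estimable at the horizon")
  ep <- endpoint_cols(cohort, endpoint)
  pos_a <- marker_a$positive(cohort)
  pos_b <- marker_b$positive(cohort)
  n <- nrow(cohort)
  boot_value <- function(idx, pos) {
    p <- pos[idx]
    if (!any(p)) return(NA_real_)
    s <- .km_surv_at(ep$time[idx][p], ep$event[idx][p], horizon)
    if (is.na(s)) return(NA_real_)
    if (kind == "ppv") 1 - s else s
  }
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  diffs <- numeric(B)
  got <- 0L; attempts <- 0L
  while (got < B && attempts < 10L * B) {
    attempts <- attempts + 1L
    idx <- sample.int(n, n, replace = TRUE)
    da <- boot_value(idx, pos_a)
    db <- boot_value(idx, pos_b)
    if (is.na(da) || is.na(db)) next
    got <- got + 1L
    diffs[got] <- da - db
  }
  if (got < B)
    return(structure(list(estimate_a = est_a, estimate_b = est_b,
                          difference = est_a$value - est_b$value,
                          se_boot = NA_real_, p_value = NA_real_,
                          B = B, seed = seed, estimable = FALSE,
                          method = "paired bootstrap + Wald",
                          reason = "too many degenerate replicates"),
                     class = "marker_comparison"))
  d_obs <- est_a$value - est_b$value
  se <- stats::sd(diffs)
  p <- if (se == 0) {
    if (d_obs == 0) 1 else 0   # degenerate bootstrap: all replicates equal
  } else 2 * stats::pnorm(-abs(d_obs) / se)
  structure(list(estimate_a = est_a, estimate_b = est_b,
                 difference = d_obs, se_boot = se, p_value = p,
                 B = B, seed = seed, estimable = TRUE,
                 method = "paired bootstrap + Wald",
                 reason = NA_character_),
            class = "marker_comparison")
}

#' @export
print.marker_comparison <- function(x, digits = 3, ...) {
  print(x$estimate_a, digits); print(x$estimate_b, digits)
  cat(sprintf("difference = %.*f, p = %s (%s, B = %d, seed = %d)\n",
              digits, x$difference, format_p(x$p_value), x$method,
              x$B, x$seed))
  invisible(x)
}

#' Predictive-value comparison table over several horizons
#'
#' Builds the report table pairing two markers at each horizon: predictive
#' values with CIs and the bootstrap p-value.
#'
#' @inheritParams compare_markers
#' @param horizons Increasing vector of horizons in months (default
#'   `c(6, 12, 18, 24)`).
#' @return A data frame with one row per horizon (`horizon`, `value_a`,
#'   `ci_lower_a`, `ci_upper_a`, `value_b`, ..., `difference`, `p_value`,
#'   `estimable`).
#' @export
compare_markers_table <- function(cohort, marker_a, marker_b,
                                  horizons = c(6, 12, 18, 24),
                                  endpoint = "os", kind = "ppv",
                                  B = 2000, seed) {
  stopifnot(all(horizons > 0), !is.unsorted(horizons, strictly = TRUE))
  rows <- lapply(seq_along(horizons), function(i) {
    cm <- tryCatch(
      compare_markers(cohort, marker_a, marker_b, horizons[i], endpoint,
                      kind, B, seed + i - 1L),
      error = function(e) NULL)
    if (is.null(cm))
      return(data.frame(horizon = horizons[i], value_a = NA_real_,
                        ci_lower_a = NA_real_, ci_upper_a = NA_real_,
                        value_b = NA_real_, ci_lower_b = NA_real_,
                        ci_upper_b = NA_real_, difference = NA_real_,
                        p_value = NA_real_, estimable = FALSE))
    data.frame(horizon = horizons[i],
               value_a = cm$estimate_a$value,
               ci_lower_a = cm$estimate_a$ci_lower,
               ci_upper_a = cm$estimate_a$ci_upper,
               value_b = cm$estimate_b$value,
               ci_lower_b = cm$estimate_b$ci_lower,
               ci_upper_b = cm$estimate_b$ci_upper,
               difference = cm$difference, p_value = cm$p_value,
               estimable = cm$estimable)
  })
  do.call(rbind, rows)
}
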