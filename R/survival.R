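# Right-censored survival estimation and testing ------------------------
# Thin, contract-enforcing layer over the survival package: product-limit
# curves with Greenwood variance and log-log bands, median with
# Brookmeyer-Crowley CI, reverse-KM follow-up, log-rank, Cox PH (Efron ties).

#' Kaplan-Meier curve with Greenwood variance
#'
#' Product-limit estimate of the survival function under right censoring.
#' At tied times, events are processed before censorings. Confidence bands
#' use the complementary log-log transform of the Greenwood variance (the
#' clinical-reporting default); `conf_type = "plain"` gives the linear
#' Greenwood band.
#'
#' @param time Follow-up times in months (>= 0).
#' @param event Event indicator, 1 = event observed, 0 = right-censored.
#' @param conf_type `"log-log"` (default) or `"plain"`.
#' @return An object of class `km_curve`: a data frame with one row per
#'   distinct observed event time (`time`, `n_risk`, `n_event`, `surv`,
#'   `greenwood_var`, `lower`, `upper`) and attributes `n`, `n_events`,
#'   `fit` (the underlying [survival::survfit] object) and `conf_type`.
#'   All-censored input is legal and yields a zero-row curve with S = 1
#'   throughout.
#' @export
km_curve <- function(time, event, conf_type = c("log-log", "plain")) {
  conf_type <- match.arg(conf_type)
  if (length(time) == 0) stop("empty input")
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (any(is.na(time)) || any(is.na(event))) stop("missing time/event values")
  if (any(time < 0)) stop("times must be non-negative")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  fit <- survival::survfit(
    survival::Surv(time, event) ~ 1,
    conf.type = if (conf_type == "log-log") "log-log" else "plain")
  keep <- fit$n.event > 0
  curve <- data.frame(time = fit$time[keep],
                      n_risk = fit$n.risk[keep],
                      n_event = fit$n.event[keep],
                      surv = fit$surv[keep],
                      # survfit std.err is the SE of the cumulative hazard;
                      # Greenwood variance of S is (S * se_H)^2
                      greenwood_var = (fit$surv[keep] * fit$std.err[keep])^2,
                      lower = fit$lower[keep],
                      upper = fit$upper[keep])
  rownames(curve) <- NULL
  structure(curve, class = c("km_curve", "data.frame"),
            n = sum(fit$n), n_events = sum(fit$n.event),
            fit = fit, conf_type = conf_type)
}

#' Median survival with Brookmeyer-Crowley confidence interval
#'
#' The median is the smallest observed event time at which the survival
#' estimate drops to 0.5 or below; the CI is read off the times where the
#' (log-log transformed Greenwood) confidence band crosses 0.5. A bound the
#' band never crosses is reported as `NA`, printed `NR` (not reached).
#'
#' @param x A `km_curve`, or a numeric vector of times (with `event` then
#'   required).
#' @param event Event indicator, only when `x` is a time vector.
#' @return An object of class `median_estimate`: list with `median`,
#'   `ci_lower`, `ci_upper` (months, `NA` = not reached) and `n`, `n_events`.
#' @export
median_survival <- function(x, event = NULL) {
  if (!inherits(x, "km_curve")) x <- km_curve(x, event)
  fit <- attr(x, "fit")
  tab <- summary(fit)$table
  out <- list(median = unname(tab["median"]),
              ci_lower = unname(tab["0.95LCL"]),
              ci_upper = unname(tab["0.95UCL"]),
              n = attr(x, "n"), n_events = attr(x, "n_events"))
  class(out) <- "median_estimate"
  out
}

#' @export
print.median_estimate <- function(x, digits = 3, ...) {
  fmt <- function(v) if (is.na(v)) "NR" else format(round(v, digits))
  cat(sprintf("median %s months (95%% CI: %s-%s), n = %d, events = %d\n",
              fmt(x$median), fmt(x$ci_lower), fmt(x$ci_upper),
              x$n, x$n_events))
  invisible(x)
}

#' Median follow-up by reverse Kaplan-Meier
#'
#' Estimates the median follow-up duration by running the Kaplan-Meier
#' estimator with the event indicator complemented, so that censoring
#' becomes the "event" and deaths are censored.
#'
#' @inheritParams km_curve
#' @return A `median_estimate` for the follow-up distribution
#'   (`NA`/"NR" when no subject was censored).
#' @export
reverse_km_followup <- function(time, event) {
  median_survival(km_curve(time, 1 - event))
}

#' Log-rank test across groups
#'
#' Standard (unweighted) log-rank test over pooled event times.
#'
#' @param time,event Follow-up times and 0/1 event indicators.
#' @param group Group label per subject (>= 2 non-empty groups).
#' @return A list with `statistic` (chi-square), `df` (number of groups
#'   minus one), `p_value`, and `n` per group.
#' @export
log_rank <- function(time, event, group) {
  group <- as.factor(as.character(group))
  if (nlevels(group) < 2) stop("log-rank needs >= 2 non-empty groups")
  if (any(table(group) == 0)) stop("a group has zero observations")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       n = as.vector(sd$n))
}

#' Format a p-value for reports
#'
#' Values below the floor are printed as `"< floor"` (clinical convention);
#' the raw value is retained by the caller.
#'
#' @param p Numeric p-value(s).
#' @param floor Reporting floor (default 1e-4).
#' @return Character vector.
#' @export
format_p <- function(p, floor = 1e-4) {
  ifelse(p < floor, paste0("< ", format(floor)), format(round(p, 4)))
}

#' Multivariate Cox proportional hazards fit
#'
#' Maximises the Cox partial likelihood with the Efron tie correction.
#' Covariates with zero variance are reported with coefficient 0 (hazard
#' ratio 1) rather than dropped silently; apparent monotone-likelihood
#' divergence (a coefficient beyond `sep_bound`) is flagged.
#'
#' @param covariates Data frame or matrix of numeric/binary covariates, no
#'   missing values.
#' @param time,event Follow-up times and 0/1 event indicators (>= 1 event).
#' @return An object of class `cox_fit`: data frame with one row per
#'   covariate (`term`, `coef`, `se`, `hr`, `ci_lower`, `ci_upper`,
#'   `p_value`) and attributes `loglik` (at the solution), `loglik0` (at the
#'   null), `n`, `n_events`, `converged`, `flags`.
#' @param sep_bound Absolute coefficient bound beyond which complete
#'   separation is flagged (default 15, i.e. hazard ratios beyond e^15).
#' @export
cox_ph <- function(covariates, time, event, sep_bound = 15) {
  covariates <- as.data.frame(covariates)
  if (any(is.na(covariates))) stop("covariates must have no missing values")
  if (sum(event) < 1) stop("at least one event is required")
  const <- vapply(covariates, function(v) length(unique(as.numeric(v))) == 1,
                  logical(1))
  dat <- cbind(covariates, .time = time, .event = event)
  active <- names(covariates)[!const]
  flags <- character(0)
  if (length(active) == 0) stop("no non-constant covariates")
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(active, collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron",
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 100))
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(0.975)
  res <- data.frame(term = names(covariates),
                    coef = 0, se = NA_real_, hr = 1,
                    ci_lower = NA_real_, ci_upper = NA_real_,
                    p_value = NA_real_, stringsAsFactors = FALSE)
  idx <- match(active, res$term)
  res$coef[idx] <- unname(co)
  res$se[idx] <- unname(se)
  res$hr[idx] <- exp(unname(co))
  res$ci_lower[idx] <- exp(unname(co) - z * unname(se))
  res$ci_upper[idx] <- exp(unname(co) + z * unname(se))
  res$p_value[idx] <- 2 * stats::pnorm(-abs(unname(co) / unname(se)))
  if (any(const)) flags <- c(flags, paste0("constant covariate: ",
                                           paste(names(covariates)[const],
                                                 collapse = ", ")))
  if (any(abs(co) > sep_bound))
    flags <- c(flags, paste0("possible complete separation: ",
                             paste(active[abs(co) > sep_bound],
                                   collapse = ", ")))
  converged <- fit$iter < 100 && all(is.finite(co)) && all(is.finite(se))
  if (!converged) flags <- c(flags, "Newton iteration did not converge")
  structure(res, class = c("cox_fit", "data.frame"),
            loglik = fit$loglik[2], loglik0 = fit$loglik[1],
            n = fit$n, n_events = fit$nevent,
            converged = converged, flags = flags)
}

#' Per-group Kaplan-Meier summary table
#'
#' Convenience wrapper computing a `km_curve` and `median_estimate` per
#' level of a grouping variable.
#'
#' @inheritParams log_rank
#' @return A list with `curves` (named list of `km_curve`), `medians` (data
#'   frame `group`, `n`, `n_events`, `median`, `ci_lower`, `ci_upper`) and
#'   `log_rank` (`NULL` when fewer than 2 non-empty groups).
#' @export
km_by_group <- function(time, event, group) {
  group <- as.factor(as.character(group))
  lv <- levels(group)[tabulate(group, nlevels(group)) > 0]
  curves <- lapply(lv, function(g) km_curve(time[group == g],
                                            event[group == g]))
  names(curves) <- lv
  med <- do.call(rbind, lapply(lv, function(g) {
    m <- median_survival(curves[[g]])
    data.frame(group = g, n = m$n, n_events = m$n_events,
               median = m$median, ci_lower = m$ci_lower,
               ci_upper = m$ci_upper, stringsAsFactors = FALSE)
  }))
  lr <- if (length(lv) >= 2)
    log_rank(time[group %in% lv], event[group %in% lv],
             droplevels(group[group %in% lv])) else NULL
  list(curves = curves, medians = med, log_rank = lr)
}
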