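# Cohort-comparison statistics (demographics table) ----------------------

#' Pearson chi-square test on a contingency table
#'
#' Uncorrected Pearson chi-square: statistic
#' \eqn{\sum (O - E)^2 / E} with expected counts from the product of margins
#' over the grand total, df = (rows - 1)(cols - 1), p from the chi-square
#' upper tail. No Yates continuity correction (the convention under which
#' the published cohort-comparison p-values reproduce). Categories named in
#' `exclude` (e.g. "unknown") are dropped before testing.
#'
#' @param counts Non-negative integer matrix (rows = variable levels,
#'   columns = cohorts), with dimnames if `exclude` is used.
#' @param exclude Row or column names to drop before testing.
#' @return A list: `statistic`, `df`, `p_value`, `method`, `expected`.
#' @export
pearson_chi_square <- function(counts, exclude = NULL) {
  m <- as.matrix(counts)
  if (!is.null(exclude)) {
    if (!is.null(rownames(m))) m <- m[!(rownames(m) %in% exclude), , drop = FALSE]
    if (!is.null(colnames(m))) m <- m[, !(colnames(m) %in% exclude), drop = FALSE]
  }
  if (any(m < 0)) stop("counts must be non-negative")
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("need at least 2 rows and 2 columns after exclusions")
  rs <- rowSums(m); cs <- colSums(m)
  rn <- if (is.null(rownames(m))) as.character(seq_len(nrow(m))) else rownames(m)
  cn <- if (is.null(colnames(m))) as.character(seq_len(ncol(m))) else colnames(m)
  if (any(rs == 0))
    stop("zero margin for row category: ",
         paste(rn[rs == 0], collapse = ", "))
  if (any(cs == 0))
    stop("zero margin for column category: ",
         paste(cn[cs == 0], collapse = ", "))
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), method = "pearson_chi_square",
       expected = ct$expected)
}

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum test with mid-ranks for ties. Exact two-sided p-value
#' when both samples have fewer than 50 observations and there are no ties;
#' otherwise the normal approximation with tie-corrected variance and
#' continuity correction (the `stats::wilcox.test` convention).
#'
#' @param values_a,values_b Non-empty numeric samples (`NA` dropped).
#' @return A list: `statistic` (Mann-Whitney U for sample a), `p_value`,
#'   `method`, `exact`.
#' @export
wilcoxon_rank_sum <- function(values_a, values_b) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) == 0 || length(values_b) == 0)
    stop("both samples must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            correct = TRUE))
  exact_used <- length(values_a) < 50 && length(values_b) < 50 &&
    !any(duplicated(c(values_a, values_b)))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = "wilcoxon_rank_sum", exact = exact_used)
}

table1_variables <- function() {
  list(
    categorical = list(
      sex = list(levels = c("male", "female"), exclude = NULL),
      smoking = list(levels = c("unknown", "any", "never"),
                     exclude = "unknown"),
      ecog_class = list(levels = c("ecog_0_1", "ecog_2_3"), exclude = NULL),
      histology = list(levels = c("squamous", "non_squamous"),
                       exclude = NULL),
      egfr_alk = list(levels = c("unknown", "no", "yes"),
                      exclude = "unknown"),
      composite = list(levels = c("others", "composite"), exclude = NULL)),
    continuous = c("age", "prior_lines", "nlr1", "dnlr"))
}

#' Build the cohort-comparison (demographics) table
#'
#' For each categorical variable: counts and percentages per cohort and
#' pooled, plus the uncorrected Pearson chi-square p-value comparing the
#' training and validation cohorts ("Unknown" levels are shown but excluded
#' from the tests). For each continuous variable (age, prior lines, NLR1,
#' DNLR): median (range) per cohort and the Wilcoxon rank-sum p-value.
#'
#' @param cohort Cohort data frame with `cohort` labels; rows labelled
#'   `training`/`validation` enter the tests. ECOG is dichotomised 0-1 vs
#'   2-3+ and the haematologic composite is derived via
#'   [derive_haematology()] if absent.
#' @param digits Decimal places for percentages (default 1).
#' @return A list: `categorical` (data frame `variable`, `level`, pooled and
#'   per-cohort `n`/`pct`, `p_value` on the first row of each variable),
#'   `continuous` (data frame `variable`, medians and ranges, `p_value`),
#'   `n` (named sizes). With a single cohort label only the pooled column is
#'   filled and no tests are run.
#' @export
build_table1 <- function(cohort, digits = 1) {
  if (!"dnlr" %in% names(cohort) &&
      !any(is.na(cohort$nlr1)) && !any(is.na(cohort$nlr2)))
    cohort <- derive_haematology(cohort)
  df <- cohort
  df$ecog_class <- ifelse(df$ecog >= 2, "ecog_2_3", "ecog_0_1")
  if ("composite_flag" %in% names(df))
    df$composite <- ifelse(df$composite_flag == 1, "composite", "others")
  in_test <- !is.na(df$cohort) & df$cohort %in% c("training", "validation")
  two_cohorts <- length(unique(df$cohort[in_test])) == 2
  vars <- table1_variables()
  cat_rows <- list()
  for (v in names(vars$categorical)) {
    if (!v %in% names(df)) { warning("variable absent, skipped: ", v); next }
    spec <- vars$categorical[[v]]
    x <- factor(ifelse(is.na(df[[v]]), "unknown", as.character(df[[v]])),
                levels = spec$levels)
    pooled_n <- as.integer(table(x))
    row <- data.frame(variable = v, level = spec$levels,
                      pooled_n = pooled_n,
                      pooled_pct = round(100 * pooled_n / length(x), digits),
                      stringsAsFactors = FALSE)
    if (two_cohorts) {
      for (cl in c("training", "validation")) {
        xn <- as.integer(table(x[in_test & df$cohort == cl]))
        row[[paste0(cl, "_n")]] <- xn
        row[[paste0(cl, "_pct")]] <- round(100 * xn / sum(xn), digits)
      }
      tab <- table(x[in_test], df$cohort[in_test])
      p <- tryCatch(
        pearson_chi_square(tab, exclude = spec$exclude)$p_value,
        error = function(e) NA_real_)
      row$p_value <- c(p, rep(NA_real_, nrow(row) - 1))
    } else row$p_value <- NA_real_
    cat_rows[[v]] <- row
  }
  cont_rows <- list()
  for (v in vars$continuous) {
    if (!v %in% names(df)) { warning("variable absent, skipped: ", v); next }
    x <- df[[v]]
    med_rng <- function(z) {
      z <- z[!is.na(z)]
      if (!length(z)) return(c(NA_real_, NA_real_, NA_real_))
      c(stats::median(z), min(z), max(z))
    }
    pm <- med_rng(x)
    row <- data.frame(variable = v, pooled_median = pm[1],
                      pooled_min = pm[2], pooled_max = pm[3],
                      stringsAsFactors = FALSE)
    if (two_cohorts) {
      for (cl in c("training", "validation")) {
        cm <- med_rng(x[in_test & df$cohort == cl])
        row[[paste0(cl, "_median")]] <- cm[1]
        row[[paste0(cl, "_min")]] <- cm[2]
        row[[paste0(cl, "_max")]] <- cm[3]
      }
      row$p_value <- tryCatch(
        wilcoxon_rank_sum(x[in_test & df$cohort == "training"],
                          x[in_test & df$cohort == "validation"])$p_value,
        error = function(e) NA_real_)
    } else row$p_value <- NA_real_
    cont_rows[[v]] <- row
  }
  list(categorical = do.call(rbind, c(cat_rows, make.row.names = FALSE)),
       continuous = do.call(rbind, c(cont_rows, make.row.names = FALSE)),
       n = c(pooled = nrow(df),
             training = sum(in_test & df$cohort == "training"),
             validation = sum(in_test & df$cohort == "validation")))
}
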