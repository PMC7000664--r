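# Canonical cohort schema ------------------------------------------------

#' Canonical cohort column schema
#'
#' Returns the canonical column names of a patient-level cohort data frame,
#' their types and their allowed factor levels. One row per patient; times in
#' months; event indicators coded 1 = event observed, 0 = right-censored.
#'
#' @return A named list with elements `columns` (character vector of canonical
#'   names), `mandatory` (names that must be mappable on read) and `levels`
#'   (allowed levels for each categorical column).
#' @export
cohort_schema <- function() {
  list(
    columns = c("patient_id", "sex", "age", "smoking", "ecog", "histology",
                "egfr_alk", "nlr1", "nlr2", "pdl1", "prior_lines",
                "treatment", "line_setting", "cohort",
                "os_time", "os_event", "pfs_time", "pfs_event"),
    mandatory = c("sex", "ecog", "nlr1", "nlr2", "os_time", "os_event"),
    levels = list(
      sex          = c("male", "female"),
      smoking      = c("any", "never", "unknown"),
      histology    = c("squamous", "non_squamous"),
      egfr_alk     = c("yes", "no", "unknown"),
      pdl1         = c("p0", "p1_49", "p50plus", "unknown"),
      treatment    = c("pd1_mono", "chemo_only"),
      line_setting = c("post_platinum", "first_line", "combination"),
      cohort       = c("training", "validation", "chemo")
    )
  )
}

# Per-row validation. Returns a data.frame of diagnostics (possibly 0 rows)
# with columns row, field, message.
validate_cohort_rows <- function(df) {
  sch <- cohort_schema()
  diag <- list()
  bad <- function(idx, field, message) {
    if (any(idx)) {
      diag[[length(diag) + 1L]] <<- data.frame(
        row = which(idx), field = field, message = message,
        stringsAsFactors = FALSE)
    }
  }
  for (f in names(sch$levels)) {
    if (f %in% names(df)) {
      v <- df[[f]]
      bad(!is.na(v) & !(v %in% sch$levels[[f]]), f,
          sprintf("%s must be one of {%s}", f,
                  paste(sch$levels[[f]], collapse = ", ")))
    }
  }
  bad(is.na(df$sex), "sex", "sex is mandatory")
  bad(is.na(df$ecog), "ecog", "ecog is mandatory")
  bad(!is.na(df$ecog) & (df$ecog < 0 | df$ecog > 4 | df$ecog != round(df$ecog)),
      "ecog", "ecog must be an integer in 0..4")
  if ("age" %in% names(df))
    bad(!is.na(df$age) & df$age < 18, "age", "age must be >= 18")
  bad(!is.na(df$nlr1) & df$nlr1 <= 0, "nlr1", "nlr1 must be positive")
  bad(!is.na(df$nlr2) & df$nlr2 <= 0, "nlr2", "nlr2 must be positive")
  if ("prior_lines" %in% names(df))
    bad(!is.na(df$prior_lines) & df$prior_lines < 0, "prior_lines",
        "prior_lines must be >= 0")
  for (tm in c("os_time", "pfs_time")) {
    if (tm %in% names(df))
      bad(!is.na(df[[tm]]) & df[[tm]] < 0, tm,
          sprintf("%s must be non-negative", tm))
  }
  for (ev in c("os_event", "pfs_event")) {
    if (ev %in% names(df))
      bad(!is.na(df[[ev]]) & !(df[[ev]] %in% c(0, 1)), ev,
          sprintf("%s must be 0 or 1", ev))
  }
  if (all(c("pfs_time", "os_time") %in% names(df)))
    bad(!is.na(df$pfs_time) & !is.na(df$os_time) & df$pfs_time > df$os_time,
        "pfs_time", "pfs_time cannot exceed os_time")
  if (length(diag)) do.call(rbind, diag)
  else data.frame(row = integer(), field = character(), message = character(),
                  stringsAsFactors = FALSE)
}

#' Read a patient-level cohort from CSV
#'
#' Reads a cohort CSV (UTF-8, comma-separated, header row, missing values as
#' empty string or `NA`), optionally remapping file column names to the
#' canonical schema, validates every row, and returns the accepted records
#' together with row-indexed diagnostics for the rejected ones. Missing
#' optional fields become explicit `NA`/`"unknown"` values; nothing is
#' silently imputed.
#'
#' @param path Path to the CSV file.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(nlr1 = "baseline_nlr")`. Unmapped canonical names are looked up
#'   verbatim.
#' @return A list with `records` (data frame of valid rows, canonical
#'   columns), `diagnostics` (data frame with `row`, `field`, `message` for
#'   every rejected row, indexed by file row) and `n_rejected`.
#' @export
read_cohort <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), check.names = FALSE)
  sch <- cohort_schema()
  # resolve file column for each canonical name
  resolved <- vapply(sch$columns, function(cn) {
    fn <- if (!is.null(col_map) && cn %in% names(col_map)) col_map[[cn]] else cn
    if (fn %in% names(raw)) fn else NA_character_
  }, character(1))
  missing_mand <- sch$mandatory[is.na(resolved[sch$mandatory])]
  if (length(missing_mand))
    stop("mandatory column(s) not mappable: ",
         paste(missing_mand, collapse = ", "))
  df <- as.data.frame(
    lapply(resolved, function(fn) if (is.na(fn)) NA else raw[[fn]]),
    stringsAsFactors = FALSE)
  names(df) <- sch$columns
  if (all(is.na(df$patient_id)))
    df$patient_id <- sprintf("row%04d", seq_len(nrow(df)))
  # numeric coercion with per-cell diagnostics
  num_cols <- c("age", "ecog", "nlr1", "nlr2", "prior_lines",
                "os_time", "os_event", "pfs_time", "pfs_event")
  coerce_diag <- list()
  for (cn in num_cols) {
    v <- df[[cn]]
    if (is.character(v)) {
      suppressWarnings(vn <- as.numeric(v))
      badc <- !is.na(v) & is.na(vn)
      if (any(badc))
        coerce_diag[[cn]] <- data.frame(row = which(badc), field = cn,
                                        message = sprintf("unparseable value for %s", cn),
                                        stringsAsFactors = FALSE)
      df[[cn]] <- vn
    } else df[[cn]] <- as.numeric(v)
  }
  diag <- rbind(
    if (length(coerce_diag)) do.call(rbind, coerce_diag)
    else data.frame(row = integer(), field = character(),
                    message = character(), stringsAsFactors = FALSE),
    validate_cohort_rows(df))
  keep <- !(seq_len(nrow(df)) %in% diag$row)
  rownames(diag) <- NULL
  list(records = df[keep, , drop = FALSE],
       diagnostics = diag,
       n_rejected = sum(!keep))
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: writes canonical columns, encoding missing
#' values as `NA`, at full numeric precision so that a write/read round trip
#' reproduces every field exactly.
#'
#' @param cohort Cohort data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  for (cn in names(out)) {
    if (is.double(out[[cn]])) {
      v <- sprintf("%.17g", out[[cn]])  # round-trip exact for doubles
      v[is.na(out[[cn]])] <- NA
      out[[cn]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "NA", quote = FALSE)
  invisible(path)
}

# Exclusion cascade ------------------------------------------------------

#' Apply the study exclusion cascade
#'
#' Removes, in order: (1) first-line checkpoint-inhibitor monotherapy without
#' previous platinum, (2) concomitant combination treatment, (3) duplicate
#' patient ids (keeping the first occurrence in file order), (4) records
#' missing either the baseline NLR or the on-treatment NLR. The tally reports
#' one count per reason, attributing each excluded record to the first rule
#' that caught it.
#'
#' @param cohort Cohort data frame (validated).
#' @param chemo_exempt_nlr2 If `TRUE`, chemotherapy-control records
#'   (`cohort == "chemo"`) are exempt from the missing-`nlr2` rule. Default
#'   `FALSE`: the same rule is applied to every record.
#' @return A list with `records` (the analysis set) and `tally` (named
#'   integer vector: `first_line`, `combination`, `duplicate`, `missing_nlr`).
#' @export
apply_exclusions <- function(cohort, chemo_exempt_nlr2 = FALSE) {
  df <- cohort
  tally <- c(first_line = 0L, combination = 0L, duplicate = 0L,
             missing_nlr = 0L)
  drop_fl <- !is.na(df$line_setting) & df$line_setting == "first_line"
  tally["first_line"] <- sum(drop_fl)
  df <- df[!drop_fl, , drop = FALSE]
  drop_cb <- !is.na(df$line_setting) & df$line_setting == "combination"
  tally["combination"] <- sum(drop_cb)
  df <- df[!drop_cb, , drop = FALSE]
  drop_dup <- duplicated(df$patient_id)
  tally["duplicate"] <- sum(drop_dup)
  df <- df[!drop_dup, , drop = FALSE]
  drop_nlr <- is.na(df$nlr1) | is.na(df$nlr2)
  if (chemo_exempt_nlr2)
    drop_nlr <- drop_nlr & !(is.na(df$nlr2) & !is.na(df$nlr1) &
                               !is.na(df$cohort) & df$cohort == "chemo")
  tally["missing_nlr"] <- sum(drop_nlr)
  df <- df[!drop_nlr, , drop = FALSE]
  rownames(df) <- NULL
  list(records = df, tally = tally)
}

# Derived haematology ----------------------------------------------------

#' Derive the haematologic composite from NLR1 and NLR2
#'
#' Computes the on-treatment NLR change `dnlr = nlr2 - nlr1` and the composite
#' biomarker flag, 1 iff `nlr1 >= 5` AND `dnlr >= 0` (a conjunction; both
#' boundaries inclusive).
#'
#' @param cohort Cohort data frame with `nlr1` and `nlr2` present for every
#'   row (exclusions already applied).
#' @return `cohort` with columns `dnlr` and `composite_flag` appended.
#' @export
derive_haematology <- function(cohort) {
  if (any(is.na(cohort$nlr1)) || any(is.na(cohort$nlr2)))
    stop("haematology undefined: nlr1/nlr2 missing for ",
         sum(is.na(cohort$nlr1) | is.na(cohort$nlr2)),
         " record(s); apply exclusions first")
  cohort$dnlr <- cohort$nlr2 - cohort$nlr1
  cohort$composite_flag <- as.integer(cohort$nlr1 >= 5 & cohort$dnlr >= 0)
  cohort
}

#' Write an exclusion tally as JSON
#'
#' @param tally Named integer vector from [apply_exclusions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exclusion_tally <- function(tally, path) {
  jsonlite::write_json(as.list(tally), path, auto_unbox = TRUE)
  invisible(path)
}
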