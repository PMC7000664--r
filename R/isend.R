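# iSEND score: sex + ECOG + NLR/DNLR composite ---------------------------

#' Compute the iSEND score and risk group
#'
#' The iSEND score (immunotherapy Sex, ECOG, NLR, Delta-NLR) is
#' \deqn{score = [male = 1] + [ECOG \ge 2 = 1] + [NLR1 \ge 5 \& \Delta NLR \ge 0 = 2]}
#' with risk groups Good (score 0), Intermediate (score 1) and Poor
#' (score >= 2). Both composite boundaries are inclusive and the composite is
#' a conjunction: `nlr1 = 5` with `dnlr = 0` scores the 2 points, while a
#' high NLR1 with falling NLR (`dnlr < 0`) does not.
#'
#' The published grouping line reads "Poor: <= 2", which contradicts
#' Good = 0 / Intermediate = 1; the only internally consistent reading,
#' used here, is Poor iff score >= 2.
#'
#' All arguments are vectorised and recycled to a common length.
#'
#' @param sex `"male"` or `"female"`.
#' @param ecog Integer ECOG performance status 0--4 (only the >= 2 dichotomy
#'   enters the score; ECOG 4 is accepted and treated as >= 2).
#' @param nlr1 Baseline neutrophil-to-lymphocyte ratio (> 0).
#' @param dnlr On-treatment NLR change (NLR before second dose minus NLR1).
#' @return A data frame with one row per patient: `sex_pts` (0/1),
#'   `ecog_pts` (0/1), `composite_pts` (0/2), `score` (0--4) and `group`
#'   (factor `good` < `intermediate` < `poor`).
#' @examples
#' isend_score("male", 2, 6.0, 0.5)   # score 4, poor
#' isend_score("female", 0, 3.0, -1)  # score 0, good
#' @export
isend_score <- function(sex, ecog, nlr1, dnlr) {
  n <- max(length(sex), length(ecog), length(nlr1), length(dnlr))
  sex <- rep_len(sex, n); ecog <- rep_len(ecog, n)
  nlr1 <- rep_len(nlr1, n); dnlr <- rep_len(dnlr, n)
  if (any(is.na(sex) | is.na(ecog) | is.na(nlr1) | is.na(dnlr)))
    stop("score undefined: missing input at position ",
         which(is.na(sex) | is.na(ecog) | is.na(nlr1) | is.na(dnlr))[1])
  if (!all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  if (any(ecog < 0 | ecog > 4)) stop("ecog must be in 0..4")
  if (any(nlr1 <= 0)) stop("nlr1 must be positive")
  sex_pts <- as.integer(sex == "male")
  ecog_pts <- as.integer(ecog >= 2)
  composite_pts <- 2L * as.integer(nlr1 >= 5 & dnlr >= 0)
  score <- sex_pts + ecog_pts + composite_pts
  group <- factor(ifelse(score == 0L, "good",
                         ifelse(score == 1L, "intermediate", "poor")),
                  levels = c("good", "intermediate", "poor"), ordered = TRUE)
  data.frame(sex_pts = sex_pts, ecog_pts = ecog_pts,
             composite_pts = composite_pts, score = score, group = group)
}

#' Score a cohort and summarise the risk groups
#'
#' Applies [isend_score()] to every patient (deriving `dnlr` via
#' [derive_haematology()] if absent) and returns the scored cohort together
#' with group counts and percentages.
#'
#' @param cohort Cohort data frame with exclusions applied (`nlr1`, `nlr2`
#'   present for all rows).
#' @param digits Decimal places for the group percentages (default 1).
#' @return A list with `records` (the cohort plus `isend_score` and
#'   `isend_group` columns) and `summary` (data frame `group`, `n`,
#'   `percent`). An empty cohort yields zero counts.
#' @export
assign_groups <- function(cohort, digits = 1) {
  if (!"dnlr" %in% names(cohort)) cohort <- derive_haematology(cohort)
  if (nrow(cohort) == 0) {
    smry <- data.frame(group = c("good", "intermediate", "poor"),
                       n = c(0L, 0L, 0L), percent = c(NA_real_, NA_real_, NA_real_))
    cohort$isend_score <- integer(0)
    cohort$isend_group <- factor(character(0),
                                 levels = c("good", "intermediate", "poor"))
    return(list(records = cohort, summary = smry))
  }
  res <- tryCatch(
    isend_score(cohort$sex, cohort$ecog, cohort$nlr1, cohort$dnlr),
    error = function(e) {
      bad <- which(is.na(cohort$sex) | is.na(cohort$ecog) |
                     is.na(cohort$nlr1) | is.na(cohort$dnlr))
      id <- if (length(bad) && "patient_id" %in% names(cohort))
        cohort$patient_id[bad[1]] else "<unknown>"
      stop("scoring failed (patient ", id, "): ", conditionMessage(e))
    })
  cohort$isend_score <- res$score
  cohort$isend_group <- res$group
  tab <- table(res$group)
  smry <- data.frame(group = names(tab), n = as.integer(tab),
                     percent = round(100 * as.integer(tab) / nrow(cohort),
                                     digits))
  list(records = cohort, summary = smry)
}
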