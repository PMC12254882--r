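# Adapted vigiGrade completeness scorer: ten elements, multiplicative
# penalties of 10/30/50 percent, well-documented threshold 0.8.

#' The ten completeness elements
#'
#' Element identifiers used throughout the scorer, in canonical order:
#' time-to-onset, reaction duration, dose, occupation of administrator,
#' breed, age, sex, neuter status, comments (the reaction description) and
#' additional comments (attached clinical notes or a stated reason for
#' their absence).
#'
#' @format Character vector of length 10.
#' @export
AE_ELEMENTS <- c("TIME_TO_ONSET", "REACTION_DURATION", "DOSE", "OCCUPATION",
                 "BREED", "AGE", "SEX", "NEUTER", "COMMENTS", "ADDITIONAL")

JUDGMENT_VERDICTS <- c("RESOLVES", "AMBIGUOUS", "ABSENT")
JUDGMENT_SOURCES <- c("REPORT_FIELDS", "CLINICAL_NOTES", "REVIEWER")
ASSESSMENT_MODES <- c("FIELDS_ONLY", "WITH_NOTES")

#' Well-documented classification threshold
#'
#' A report is well-documented when its final multiplicative completeness
#' score is 0.8 or higher.
#' @format Numeric scalar.
#' @export
WELL_DOCUMENTED_THRESHOLD <- 0.8

# elements whose penalty can be lifted by information found in the free-text
# clinical notes; the remaining elements have no free-text clause and their
# penalties stand in both assessment modes
NOTES_RESOLVABLE_ELEMENTS <- c("TIME_TO_ONSET", "REACTION_DURATION", "DOSE")

#' Reachable score levels per element
#'
#' The only values each element score can take under the adapted scoring
#' rules: time-to-onset is 1 or 0.5 (50 percent penalty for any ambiguity);
#' reaction duration, dose, comments and additional comments are 1 or 0.9;
#' occupation, breed, sex and neuter status are 1 or 0.7; age is 1, 0.9
#' (recorded as a bare zero) or 0.7 (unknown).
#'
#' @return Named list mapping each element to its numeric score levels.
#' @export
element_score_levels <- function() {
  list(
    TIME_TO_ONSET = c(1, 0.5),
    REACTION_DURATION = c(1, 0.9),
    DOSE = c(1, 0.9),
    OCCUPATION = c(1, 0.7),
    BREED = c(1, 0.7),
    AGE = c(1, 0.9, 0.7),
    SEX = c(1, 0.7),
    NEUTER = c(1, 0.7),
    COMMENTS = c(1, 0.9),
    ADDITIONAL = c(1, 0.9)
  )
}

#' Record a judgment about a free-text-dependent scoring rule
#'
#' Several scoring rules depend on whether information can be elucidated
#' from free text (the reaction description, dosage details, or attached
#' clinical notes). These judgments are supplied explicitly — by a human
#' reviewer or a heuristic — rather than inferred, keeping the scorer
#' deterministic. The conservative default when no judgment exists is
#' `ABSENT` (the penalty applies).
#'
#' @param element One of [AE_ELEMENTS].
#' @param verdict `RESOLVES` (the free text settles the element),
#'   `AMBIGUOUS`, or `ABSENT`.
#' @param source `REPORT_FIELDS` (description/dosage text on the report
#'   itself), `CLINICAL_NOTES` (attached notes; ignored in `FIELDS_ONLY`
#'   mode) or `REVIEWER`.
#' @param report_id Optional report identifier the judgment refers to.
#' @return An object of class `element_judgment`.
#' @export
element_judgment <- function(element, verdict, source = "REVIEWER",
                             report_id = NULL) {
  structure(list(
    report_id = if (is.null(report_id)) NULL else as.character(report_id),
    element = assert_enum(element, AE_ELEMENTS, "element"),
    verdict = assert_enum(verdict, JUDGMENT_VERDICTS, "verdict"),
    source = assert_enum(source, JUDGMENT_SOURCES, "source")
  ), class = "element_judgment")
}

# judgments applicable to one element in one mode (FIELDS_ONLY drops
# CLINICAL_NOTES-sourced judgments); enforces one-judgment-per-source
applicable_judgments <- function(judgments, element, mode) {
  if (length(judgments) == 0) return(list())
  sel <- judgments[vapply(judgments, function(j) {
    inherits(j, "element_judgment") && j$element == element &&
      (mode == "WITH_NOTES" || j$source != "CLINICAL_NOTES")
  }, logical(1))]
  srcs <- vapply(sel, function(j) j$source, character(1))
  if (anyDuplicated(srcs)) {
    stop(sprintf("more than one judgment for element %s from source %s",
                 element, srcs[duplicated(srcs)][1]), call. = FALSE)
  }
  sel
}

has_verdict <- function(judgments, verdict) {
  any(vapply(judgments, function(j) j$verdict == verdict, logical(1)))
}

# effective transmitted age: explicit age fields take precedence over a
# derivable date of birth (the system may transmit a coarser record, e.g. a
# bare 0 for animals under one year)
effective_age <- function(report) {
  if (!is.null(report$age_years)) {
    return(list(years = report$age_years, months = report$age_months))
  }
  ref <- report$reaction_date %||%
    (if (is.null(report$submission_timestamp)) NULL
     else as.Date(report$submission_timestamp))
  if (is.null(report$date_of_birth) || is.null(ref)) {
    return(list(years = "UNKNOWN", months = NULL))
  }
  derive_age(report$date_of_birth, ref)
}

#' Score one completeness element of a report
#'
#' Applies the adapted scoring rules. Time-to-onset scores 1 when the drug
#' start date strictly precedes the reaction date; same-day administration
#' scores 1 only if free text states the drug preceded the reaction (a
#' `RESOLVES` judgment), and any other ambiguity — a missing date, a start
#' after the reaction, an `AMBIGUOUS` judgment — carries the 50 percent
#' penalty. With several suspect drugs the most pessimistic drug decides.
#' Reaction duration and dose carry 10 percent penalties when
#' undeterminable (vaccine/pipette doses are exempt); occupation, breed,
#' sex and neuter status carry 30 percent penalties when unknown; age
#' carries 30 percent when unknown and 10 percent when recorded as a bare
#' zero; the comments and additional-comments elements carry 10 percent
#' penalties for a placeholder description and for unattached clinical
#' notes without a stated reason, respectively.
#'
#' In `FIELDS_ONLY` mode judgments sourced from `CLINICAL_NOTES` are
#' ignored; in `WITH_NOTES` mode they are honored.
#'
#' @param element One of [AE_ELEMENTS].
#' @param report An [ae_report()].
#' @param judgments List of [element_judgment()] records for this report.
#' @param mode `FIELDS_ONLY` or `WITH_NOTES`.
#' @return A score in `{1, 0.9, 0.7, 0.5}`.
#' @export
score_element <- function(element, report, judgments = list(),
                          mode = "FIELDS_ONLY") {
  element <- assert_enum(element, AE_ELEMENTS, "element")
  mode <- assert_enum(mode, ASSESSMENT_MODES, "mode")
  stopifnot(inherits(report, "ae_report"))
  j <- applicable_judgments(judgments, element, mode)
  resolves <- has_verdict(j, "RESOLVES")
  ambiguous <- has_verdict(j, "AMBIGUOUS")

  unknown_penalty <- function(value, unknown_token = "UNKNOWN") {
    if (is.null(value) || !nzchar(trimws(as.character(value))) ||
        toupper(value) == unknown_token) 0.7 else 1.0
  }

  switch(element,
    TIME_TO_ONSET = {
      if (ambiguous || length(report$suspect_drugs) == 0) return(0.5)
      per_drug <- vapply(report$suspect_drugs, function(d) {
        if (is.null(d$start_date) || is.null(report$reaction_date)) return(0.5)
        if (d$start_date < report$reaction_date) return(1.0)
        if (d$start_date == report$reaction_date && resolves) return(1.0)
        0.5
      }, numeric(1))
      min(per_drug)
    },
    REACTION_DURATION = {
      if (!is.null(report$reaction_duration) || resolves) 1.0 else 0.9
    },
    DOSE = {
      drugs <- report$suspect_drugs
      all_exempt <- length(drugs) > 0 &&
        all(vapply(drugs, function(d) d$is_vaccine_or_pipette, logical(1)))
      if (all_exempt || resolves) 1.0 else 0.9
    },
    OCCUPATION = {
      if (length(report$suspect_drugs) == 0) return(0.7)
      admins <- vapply(report$suspect_drugs, function(d) d$administrator,
                       character(1))
      if (all(admins %in% c("VET", "VET_NURSE", "OWNER", "OTHER"))) 1.0
      else 0.7
    },
    BREED = unknown_penalty(report$breed),
    AGE = {
      age <- effective_age(report)
      if (identical(age$years, "UNKNOWN")) 0.7
      else if (age$years > 0L) 1.0
      else if (!is.null(age$months)) 1.0
      else 0.9
    },
    SEX = unknown_penalty(report$sex),
    NEUTER = unknown_penalty(report$neuter_status),
    COMMENTS = {
      if (is_placeholder_description(report$reaction_description)) 0.9
      else 1.0
    },
    ADDITIONAL = {
      if (length(report$clinical_notes) > 0 || resolves) 1.0 else 0.9
    }
  )
}

#' Combine element scores into a final completeness score
#'
#' The final report score is the product of the ten element scores, carried
#' at full floating precision; classification against the well-documented
#' threshold uses the unrounded product.
#'
#' @param scores Named numeric vector covering all of [AE_ELEMENTS], each
#'   value a reachable level for its element.
#' @return The multiplicative final score.
#' @export
combine_element_scores <- function(scores) {
  if (!all(AE_ELEMENTS %in% names(scores))) {
    stop("scores must be named over all ten elements", call. = FALSE)
  }
  scores <- scores[AE_ELEMENTS]
  levels <- element_score_levels()
  for (e in AE_ELEMENTS) {
    if (!any(abs(scores[[e]] - levels[[e]]) < 1e-9)) {
      stop(sprintf("score %.3f is not reachable for element %s",
                   scores[[e]], e), call. = FALSE)
    }
  }
  prod(scores)
}

new_assessment <- function(report_id, mode, element_scores,
                           reviewer_id = NULL) {
  final <- combine_element_scores(element_scores)
  structure(list(
    report_id = report_id,
    mode = mode,
    element_scores = element_scores[AE_ELEMENTS],
    final_score = final,
    well_documented = final >= WELL_DOCUMENTED_THRESHOLD,
    reviewer_id = reviewer_id
  ), class = "completeness_assessment")
}

#' Assess the completeness of one report
#'
#' Scores all ten elements with [score_element()] and multiplies them into
#' the final completeness score; the report is well-documented when that
#' product is 0.8 or higher. A report failing the minimum reporting
#' criteria is still assessed, with a warning.
#'
#' @inheritParams score_element
#' @param reviewer_id Optional identifier of the scoring reviewer.
#' @return An object of class `completeness_assessment` with fields
#'   `report_id`, `mode`, `element_scores` (named over [AE_ELEMENTS]),
#'   `final_score`, `well_documented` and `reviewer_id`.
#' @export
assess_report <- function(report, judgments = list(), mode = "FIELDS_ONLY",
                          reviewer_id = NULL) {
  mode <- assert_enum(mode, ASSESSMENT_MODES, "mode")
  v <- validate_minimum_criteria(report)
  if (!v$is_valid) {
    warning(sprintf("report %s fails the minimum reporting criteria (%s)",
                    report$report_id, paste(v$messages, collapse = "; ")),
            call. = FALSE)
  }
  scores <- vapply(AE_ELEMENTS, score_element, numeric(1), report = report,
                   judgments = judgments, mode = mode)
  new_assessment(report$report_id, mode, scores, reviewer_id)
}

#' @export
print.completeness_assessment <- function(x, ...) {
  cat(sprintf("<completeness_assessment %s> mode %s, final %.2f%s\n",
              x$report_id, x$mode, x$final_score,
              if (x$well_documented) " (well-documented)" else ""))
  invisible(x)
}

#' Assess a report in both modes
#'
#' Runs [assess_report()] twice on identical inputs: once considering only
#' the information in the report fields (`FIELDS_ONLY`) and once also
#' honoring judgments drawn from the attached free-text clinical notes
#' (`WITH_NOTES`). Because notes can only lift penalties, the with-notes
#' score is never lower.
#'
#' @inheritParams assess_report
#' @return List with components `fields_only` and `with_notes`, each a
#'   `completeness_assessment`.
#' @export
dual_assess <- function(report, judgments = list(), reviewer_id = NULL) {
  list(
    fields_only = assess_report(report, judgments, "FIELDS_ONLY",
                                reviewer_id),
    with_notes = assess_report(report, judgments, "WITH_NOTES", reviewer_id)
  )
}

#' Compare the scores of two independent reviewers
#'
#' A report counts as complete agreement only when all ten element scores
#' match exactly; per-element disagreement counts identify which rules
#' reviewers interpret differently.
#'
#' @param a,b Lists of `completeness_assessment` objects covering the same
#'   report identifiers in the same mode.
#' @return An object of class `agreement_result`: `n_reports`,
#'   `n_complete_agreement`, `proportion`, `per_element_disagreements`
#'   (named integer over [AE_ELEMENTS]).
#' @export
compare_reviewers <- function(a, b) {
  ids_a <- vapply(a, function(x) x$report_id, character(1))
  ids_b <- vapply(b, function(x) x$report_id, character(1))
  if (!setequal(ids_a, ids_b) || anyDuplicated(ids_a) || anyDuplicated(ids_b)) {
    stop("reviewer assessments must cover the same report_ids exactly once",
         call. = FALSE)
  }
  modes <- unique(c(vapply(a, function(x) x$mode, character(1)),
                    vapply(b, function(x) x$mode, character(1))))
  if (length(modes) > 1) {
    stop("assessments mix modes; compare within one mode", call. = FALSE)
  }
  b <- b[match(ids_a, ids_b)]
  dis <- setNames(integer(length(AE_ELEMENTS)), AE_ELEMENTS)
  agree <- logical(length(a))
  for (i in seq_along(a)) {
    diff_e <- AE_ELEMENTS[abs(a[[i]]$element_scores[AE_ELEMENTS] -
                              b[[i]]$element_scores[AE_ELEMENTS]) > 1e-9]
    dis[diff_e] <- dis[diff_e] + 1L
    agree[i] <- length(diff_e) == 0
  }
  structure(list(
    n_reports = length(a),
    n_complete_agreement = sum(agree),
    proportion = sum(agree) / length(a),
    per_element_disagreements = dis
  ), class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> %d/%d reports in complete agreement (%.1f%%)\n",
              x$n_complete_agreement, x$n_reports, 100 * x$proportion))
  invisible(x)
}

#' Reconcile two reviewers' assessments into a consensus
#'
#' Discrepancies between reviewers are resolved by discussion; the
#' consensus takes agreed scores where the reviewers match and the supplied
#' resolution elsewhere, then recomputes the final score and the
#' well-documented flag.
#'
#' @param a,b `completeness_assessment` objects for the same report and
#'   mode.
#' @param resolutions Named numeric vector whose names are exactly the
#'   disagreeing elements; each value must be a reachable score level.
#' @return The consensus `completeness_assessment` (reviewer_id
#'   `"consensus"`).
#' @export
reconcile <- function(a, b, resolutions = numeric()) {
  stopifnot(inherits(a, "completeness_assessment"),
            inherits(b, "completeness_assessment"))
  if (a$report_id != b$report_id || a$mode != b$mode) {
    stop("assessments must refer to the same report and mode", call. = FALSE)
  }
  sa <- a$element_scores[AE_ELEMENTS]
  sb <- b$element_scores[AE_ELEMENTS]
  disagree <- AE_ELEMENTS[abs(sa - sb) > 1e-9]
  if (!setequal(names(resolutions), disagree)) {
    stop(sprintf(
      "resolutions must cover exactly the disagreeing elements (%s)",
      if (length(disagree)) paste(disagree, collapse = ", ") else "none"),
      call. = FALSE)
  }
  consensus <- sa
  consensus[disagree] <- as.numeric(resolutions[disagree])
  new_assessment(a$report_id, a$mode, consensus, reviewer_id = "consensus")
}
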