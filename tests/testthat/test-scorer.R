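test_that("time-to-onset scoring handles ordering, same-day and ambiguity", {
  base <- complete_report()
  expect_equal(score_element("TIME_TO_ONSET", base), 1.0)

  same_day <- complete_report(
    suspect_drugs = list(drug_entry("V", start_date = "2020-10-03",
                                    administrator = "VET",
                                    is_vaccine_or_pipette = TRUE)))
  expect_equal(score_element("TIME_TO_ONSET", same_day), 0.5)
  j <- list(element_judgment("TIME_TO_ONSET", "RESOLVES", "CLINICAL_NOTES"))
  expect_equal(score_element("TIME_TO_ONSET", same_day, j, "WITH_NOTES"), 1.0)
  # the same judgment is invisible in fields-only mode
  expect_equal(score_element("TIME_TO_ONSET", same_day, j, "FIELDS_ONLY"),
               0.5)
  # a report-fields judgment (description states the order) counts in both
  jf <- list(element_judgment("TIME_TO_ONSET", "RESOLVES", "REPORT_FIELDS"))
  expect_equal(score_element("TIME_TO_ONSET", same_day, jf, "FIELDS_ONLY"),
               1.0)

  missing_date <- complete_report(
    suspect_drugs = list(drug_entry("V", administrator = "VET")))
  expect_equal(score_element("TIME_TO_ONSET", missing_date), 0.5)
  # start after reaction is ambiguous too
  reversed <- complete_report(
    suspect_drugs = list(drug_entry("V", start_date = "2020-10-05",
                                    administrator = "VET")))
  expect_equal(score_element("TIME_TO_ONSET", reversed), 0.5)
  # an explicit AMBIGUOUS judgment overrides clean dates
  ja <- list(element_judgment("TIME_TO_ONSET", "AMBIGUOUS", "REVIEWER"))
  expect_equal(score_element("TIME_TO_ONSET", base, ja), 0.5)
})

test_that("multiple suspect drugs take the most pessimistic time-to-onset", {
  two <- complete_report(suspect_drugs = list(
    drug_entry("A", start_date = "2020-10-01", administrator = "VET"),
    drug_entry("B", start_date = "2020-10-03", administrator = "VET")))
  expect_equal(score_element("TIME_TO_ONSET", two), 0.5)
  both_clean <- complete_report(suspect_drugs = list(
    drug_entry("A", start_date = "2020-10-01", administrator = "VET"),
    drug_entry("B", start_date = "2020-10-02", administrator = "VET")))
  expect_equal(score_element("TIME_TO_ONSET", both_clean), 1.0)
})

test_that("10/30 percent penalties apply per element rule", {
  r <- complete_report()
  # reaction duration: field or judgment, else 10%
  expect_equal(score_element("REACTION_DURATION", r), 1.0)
  nd <- complete_report(reaction_duration = NULL,
                        reaction_duration_unit = NULL)
  expect_equal(score_element("REACTION_DURATION", nd), 0.9)
  expect_equal(score_element(
    "REACTION_DURATION", nd,
    list(element_judgment("REACTION_DURATION", "RESOLVES",
                          "CLINICAL_NOTES")), "WITH_NOTES"), 1.0)

  # dose: vaccine/pipette exempt; judgment resolves; else 10%
  expect_equal(score_element("DOSE", r), 1.0)  # vaccine entry
  tablet <- complete_report(
    suspect_drugs = list(drug_entry("T", start_date = "2020-10-01",
                                    dosage_text = "1 tab",
                                    administrator = "VET")))
  expect_equal(score_element("DOSE", tablet), 0.9)
  expect_equal(score_element(
    "DOSE", tablet,
    list(element_judgment("DOSE", "RESOLVES", "REPORT_FIELDS"))), 1.0)

  # occupation: OTHER unpenalized, UNKNOWN 30%
  expect_equal(score_element("OCCUPATION", r), 1.0)
  other <- complete_report(
    suspect_drugs = list(drug_entry("V", start_date = "2020-10-01",
                                    administrator = "OTHER")))
  expect_equal(score_element("OCCUPATION", other), 1.0)
  unk <- complete_report(
    suspect_drugs = list(drug_entry("V", start_date = "2020-10-01")))
  expect_equal(score_element("OCCUPATION", unk), 0.7)

  # breed / sex / neuter: UNKNOWN or absent = 30%
  expect_equal(score_element("BREED", complete_report(breed = "UNKNOWN")),
               0.7)
  expect_equal(score_element("SEX", complete_report(sex = "UNKNOWN")), 0.7)
  expect_equal(score_element("NEUTER",
                             complete_report(neuter_status = "UNKNOWN")),
               0.7)

  # comments: placeholder = 10%
  expect_equal(score_element("COMMENTS", r), 1.0)
  expect_equal(score_element("COMMENTS",
                             complete_report(reaction_description = "...")),
               0.9)

  # additional: notes attached or a stated reason = 1, else 10%
  expect_equal(score_element("ADDITIONAL", r), 1.0)
  nonotes <- complete_report(clinical_notes = list())
  expect_equal(score_element("ADDITIONAL", nonotes), 0.9)
  expect_equal(score_element(
    "ADDITIONAL", nonotes,
    list(element_judgment("ADDITIONAL", "RESOLVES", "REVIEWER"))), 1.0)
})

test_that("age scoring distinguishes unknown, bare zero, and months", {
  expect_equal(score_element("AGE", complete_report()), 1.0)
  expect_equal(score_element("AGE", complete_report(age_years = NULL,
                                                    age_months = NULL)),
               0.7)
  bare0 <- complete_report(age_years = 0L, age_months = NULL)
  expect_equal(score_element("AGE", bare0), 0.9)
  with_months <- complete_report(age_years = 0L, age_months = 4L)
  expect_equal(score_element("AGE", with_months), 1.0)
  # age derivable from date of birth when no transmitted age record
  dob <- complete_report(age_years = NULL, age_months = NULL,
                         date_of_birth = "2020-06-01")
  expect_equal(score_element("AGE", dob), 1.0)
})

test_that("final score is the product and classifies at 0.8", {
  a <- assess_report(complete_report())
  expect_equal(a$final_score, 1.0)
  expect_true(a$well_documented)

  two_unknown <- complete_report(breed = "UNKNOWN", sex = "UNKNOWN")
  a2 <- assess_report(two_unknown)
  expect_equal(a2$final_score, 0.49, tolerance = 1e-12)
  expect_false(a2$well_documented)

  worst <- ae_report(
    report_id = "W", practice_id = "P001", species = "DOG",
    breed = "UNKNOWN", sex = "UNKNOWN", neuter_status = "UNKNOWN",
    suspect_drugs = list(drug_entry("T")),
    reaction_description = "n/a")
  expect_warning(aw <- assess_report(worst), "minimum reporting criteria")
  expect_equal(aw$final_score, 0.5 * 0.9^4 * 0.7^5, tolerance = 1e-12)
})

test_that("the full reachable score lattice matches an independent product", {
  levels <- element_score_levels()
  grid <- expand.grid(levels, KEEP.OUT.ATTRS = FALSE)
  expect_lte(nrow(grid), 1536)
  for (i in seq_len(nrow(grid))) {
    s <- setNames(as.numeric(grid[i, ]), names(levels))
    final <- combine_element_scores(s)
    oracle <- 1
    for (e in names(levels)) oracle <- oracle * s[[e]]
    expect_equal(final, oracle, tolerance = 1e-12)
    expect_identical(final >= 0.8, oracle >= 0.8)
  }
  expect_error(combine_element_scores(
    setNames(c(0.8, rep(1, 9)), AE_ELEMENTS)), "not reachable")
})

test_that("dual assessment honors notes only in the second pass", {
  same_day <- complete_report(
    suspect_drugs = list(drug_entry("V", start_date = "2020-10-03",
                                    administrator = "VET",
                                    is_vaccine_or_pipette = TRUE)))
  j <- list(element_judgment("TIME_TO_ONSET", "RESOLVES", "CLINICAL_NOTES"))
  d <- dual_assess(same_day, j)
  expect_equal(d$fields_only$final_score, 0.5)
  expect_equal(d$with_notes$final_score, 1.0)

  # unresolvable age penalty persists in both passes
  age_unknown <- complete_report(age_years = NULL, age_months = NULL)
  d2 <- dual_assess(age_unknown, list())
  expect_equal(d2$fields_only$final_score, 0.7)
  expect_equal(d2$with_notes$final_score, 0.7)

  d3 <- dual_assess(complete_report(), list())
  expect_identical(d3$fields_only$element_scores,
                   d3$with_notes$element_scores)
})

test_that("judgments only ever raise scores; notes mode never scores lower", {
  set.seed(99)
  cfg <- generator_config(n_reports = 120, seed = 303,
                          p_notes_attached = 0.7, p_extra_drug = 0.2)
  corpus <- generate_corpus(cfg)
  ids <- vapply(corpus$judgments, `[[`, character(1), "report_id")
  for (k in seq_along(corpus$reports)) {
    r <- corpus$reports[[k]]
    j <- corpus$judgments[ids == r$report_id]
    d <- dual_assess(r, j)
    expect_gte(d$with_notes$final_score, d$fields_only$final_score)
    expect_true(all(d$with_notes$element_scores >=
                    d$fields_only$element_scores))
    # removing all judgments never raises any element score
    bare <- assess_report(r, list(), "WITH_NOTES")
    expect_true(all(bare$element_scores <= d$with_notes$element_scores))
  }
})

test_that("reviewer agreement counts exact element-score matches", {
  cfg <- generator_config(n_reports = 45, seed = 12)
  corpus <- generate_corpus(cfg)
  ids <- vapply(corpus$judgments, `[[`, character(1), "report_id")
  assess_all <- function(reports, judgments) {
    lapply(reports, function(r)
      assess_report(r, judgments[ids == r$report_id], "FIELDS_ONLY"))
  }
  a <- assess_all(corpus$reports, corpus$judgments)
  expect_equal(compare_reviewers(a, a)$proportion, 1.0)

  # reviewer B penalizes reaction duration on 13 reports (12 would differ in
  # the study's pattern; here we alter 13 and check the bookkeeping)
  b <- a
  flip <- which(vapply(a, function(x)
    x$element_scores[["REACTION_DURATION"]] == 1, logical(1)))[1:13]
  for (i in flip) {
    s <- b[[i]]$element_scores
    s[["REACTION_DURATION"]] <- 0.9
    b[[i]] <- vetgrade:::new_assessment(b[[i]]$report_id, b[[i]]$mode, s)
  }
  res <- compare_reviewers(a, b)
  expect_equal(res$n_complete_agreement, 32)
  expect_equal(res$proportion, 32 / 45, tolerance = 1e-12)
  expect_equal(res$per_element_disagreements[["REACTION_DURATION"]], 13L)
  expect_equal(sum(res$per_element_disagreements), 13L)

  expect_error(compare_reviewers(a, a[-1]), "same report_ids")
})

test_that("reconciliation applies resolutions exactly where needed", {
  a <- assess_report(complete_report())
  expect_identical(reconcile(a, a)$element_scores, a$element_scores)

  s <- a$element_scores
  s[["REACTION_DURATION"]] <- 0.9
  b <- vetgrade:::new_assessment(a$report_id, a$mode, s)
  cons <- reconcile(a, b, c(REACTION_DURATION = 1.0))
  expect_equal(cons$element_scores[["REACTION_DURATION"]], 1.0)
  expect_equal(cons$final_score, 1.0)
  cons2 <- reconcile(a, b, c(REACTION_DURATION = 0.9))
  expect_equal(cons2$final_score, 0.9)

  expect_error(reconcile(a, b), "resolutions")
  expect_error(reconcile(a, b, c(BREED = 1.0)), "resolutions")
  expect_error(reconcile(a, a, c(BREED = 1.0)), "resolutions")
})
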