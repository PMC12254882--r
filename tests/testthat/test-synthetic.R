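corpus_fingerprint <- function(corpus) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_reports_json(corpus$reports, tmp)
  paste(readLines(tmp), collapse = "\n")
}

test_that("generation is deterministic and prefix-stable in n", {
  cfg <- generator_config(n_reports = 15, seed = 77)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(corpus_fingerprint(c1), corpus_fingerprint(c2))
  expect_identical(c1$truth, c2$truth)

  longer <- generate_corpus(generator_config(n_reports = 30, seed = 77))
  expect_identical(lapply(longer$reports[1:15], `[[`, "report_id"),
                   lapply(c1$reports, `[[`, "report_id"))
  expect_identical(longer$truth[1:15, ], c1$truth)
})

test_that("every generated report passes the minimum reporting criteria", {
  corpus <- generate_corpus(generator_config(n_reports = 80, seed = 5,
                                             p_extra_drug = 0.3))
  ok <- vapply(corpus$reports,
               function(r) validate_minimum_criteria(r)$is_valid,
               logical(1))
  expect_true(all(ok))
})

test_that("degenerate configurations pin element scores", {
  perfect <- generator_config(
    n_reports = 25, seed = 9,
    theta = setNames(rep(1, 10), AE_ELEMENTS),
    p_notes_attached = 1, p_age_zero = 0)
  corpus <- generate_corpus(perfect)
  af <- assess_corpus(corpus$reports, corpus$judgments, "FIELDS_ONLY")
  an <- assess_corpus(corpus$reports, corpus$judgments, "WITH_NOTES")
  expect_true(all(af$final_score == 1))
  expect_true(all(an$final_score == 1))

  no_breed <- generator_config(n_reports = 25, seed = 9,
                               theta = c(BREED = 0))
  ab <- assess_corpus(generate_corpus(no_breed)$reports, list(),
                      "FIELDS_ONLY")
  expect_true(all(ab$BREED == 0.7))
})

test_that("truth records reproduce the scorer's output exactly", {
  cfg <- generator_config(n_reports = 250, seed = 41,
                          p_notes_attached = 0.8, p_extra_drug = 0.15)
  corpus <- generate_corpus(cfg)
  af <- assess_corpus(corpus$reports, corpus$judgments, "FIELDS_ONLY")
  an <- assess_corpus(corpus$reports, corpus$judgments, "WITH_NOTES")
  expect_equal(af$final_score, corpus$truth$score_fields_only,
               tolerance = 1e-12)
  expect_equal(an$final_score, corpus$truth$score_with_notes,
               tolerance = 1e-12)
  # strict improvement exactly when a notes judgment resolves a penalty
  expect_identical(an$final_score > af$final_score,
                   corpus$truth$notes_improve)
})

test_that("analytic expected score matches hand-derived cases", {
  all_complete <- generator_config(theta = setNames(rep(1, 10), AE_ELEMENTS),
                                   p_age_zero = 0)
  expect_equal(expected_score(all_complete, "FIELDS_ONLY"), 1.0)
  expect_equal(expected_score(all_complete, "WITH_NOTES"), 1.0)

  half_breed <- generator_config(
    theta = modifyList(as.list(setNames(rep(1, 10), AE_ELEMENTS)),
                       list(BREED = 0.5)) |> unlist(),
    p_age_zero = 0)
  expect_equal(expected_score(half_breed, "FIELDS_ONLY"), 0.85,
               tolerance = 1e-12)

  # age: known-but-zero and unknown contributions
  age_cfg <- generator_config(
    theta = modifyList(as.list(setNames(rep(1, 10), AE_ELEMENTS)),
                       list(AGE = 0.8)) |> unlist(),
    p_age_zero = 0.25)
  expect_equal(expected_score(age_cfg, "FIELDS_ONLY"),
               0.8 * (0.75 + 0.25 * 0.9) + 0.2 * 0.7, tolerance = 1e-12)

  # with-notes folds attachment and resolution into time-to-onset
  tto_cfg <- generator_config(
    theta = modifyList(as.list(setNames(rep(1, 10), AE_ELEMENTS)),
                       list(TIME_TO_ONSET = 0.4)) |> unlist(),
    p_age_zero = 0, p_same_day = 1, p_notes_attached = 0.5,
    rho_notes_resolve = c(TIME_TO_ONSET = 1))
  expect_equal(expected_score(tto_cfg, "FIELDS_ONLY"), 0.4 + 0.6 * 0.5,
               tolerance = 1e-12)
  expect_equal(expected_score(tto_cfg, "WITH_NOTES"),
               0.5 * (0.4 + 0.6 * 1) + 0.5 * (0.4 + 0.6 * 0.5),
               tolerance = 1e-12)
})

test_that("Monte-Carlo means track the analytic expectation", {
  cfg <- generator_config(n_reports = 2500, seed = 61,
                          p_notes_attached = 0.6)
  corpus <- generate_corpus(cfg)
  for (mode in c("FIELDS_ONLY", "WITH_NOTES")) {
    col <- if (mode == "FIELDS_ONLY") "score_fields_only"
           else "score_with_notes"
    x <- corpus$truth[[col]]
    se <- stats::sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - expected_score(cfg, mode)), 3 * se)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(theta = c(BREED = 1.4)), "probability")
  expect_error(generator_config(p_same_day = -0.1), "probability")
  expect_error(generator_config(rho_notes_resolve = c(AGE = 0.5)),
               "notes-resolvable")
  expect_error(generator_config(n_reports = 2.5), "integer")
  expect_error(generator_config(
    species_pool = list(values = character(), weights = numeric())),
    "pools")
  expect_warning(generator_config(theta = c(COMMENTS = 0.5)),
                 "minimum reporting criteria")
})

test_that("generator configs round-trip through YAML and JSON", {
  cfg <- generator_config(n_reports = 10, seed = 3,
                          theta = c(BREED = 0.5),
                          rho_notes_resolve = c(DOSE = 0.2))
  y <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_reports = 10, seed = 3,
                        theta = list(BREED = 0.5),
                        rho_notes_resolve = list(DOSE = 0.2)), y)
  cfg_y <- read_generator_config(y)
  expect_equal(cfg_y$theta, cfg$theta)
  expect_equal(cfg_y$rho_notes_resolve, cfg$rho_notes_resolve)
  expect_identical(corpus_fingerprint(generate_corpus(cfg_y)),
                   corpus_fingerprint(generate_corpus(cfg)))

  j <- tempfile(fileext = ".json")
  jsonlite::write_json(list(n_reports = 10, seed = 3,
                            theta = list(BREED = 0.5),
                            rho_notes_resolve = list(DOSE = 0.2)),
                       j, auto_unbox = TRUE)
  expect_equal(read_generator_config(j)$theta, cfg$theta)
})
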