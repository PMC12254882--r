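# Seeded synthetic report corpora with known per-element completeness
# structure: the statistical stand-in for real (unpublishable) spontaneous
# report data, plus the analytic expected final score for any configuration.

default_species_pool <- function() {
  # mix follows the observed species distribution in a small-animal
  # first-opinion corpus: ~51% dogs, ~41% cats, ~7% rabbits
  list(values = c("DOG", "CAT", "RABBIT", "OTHER"), weights = c(30, 24, 4, 1))
}

default_breed_pool <- function() {
  list(values = c("Labrador Retriever", "Domestic Shorthair", "Cocker Spaniel",
                  "French Bulldog", "Crossbreed", "Dwarf Lop", "Siamese"),
       weights = rep(1, 7))
}

default_product_pool <- function() {
  # weights echo an ATCvet first-level mix dominated by immunologicals;
  # names match the synthetic terminology fixtures shipped with the package
  list(values = c("Vaccamune DHP", "Felivac Trio", "Parashield Spot-On",
                  "Wormexol Tablets", "Thyronorm Drops", "Flexicam Oral",
                  "Cardiopril 5mg", "Clavubactin 250", "Calmexin Gel",
                  "Herbal Soothe Balm"),
       weights = c(33, 16, 10, 4, 5, 4, 1, 1, 1, 1))
}

default_sign_pool <- function() {
  list(values = c("vomiting", "lethargy", "injection site swelling",
                  "pruritus", "diarrhoea", "anorexia", "seizure", "ataxia",
                  "urticaria", "pyrexia"),
       weights = c(11, 11, 8, 6, 6, 4, 2, 2, 2, 2))
}

default_theta <- function() {
  # anchored to the observed per-element penalty rates where the study
  # reports them (time-to-onset 17/45 penalized, occupation 1/45 missing);
  # remaining rates are plausible field-completeness levels for an
  # EHR-pre-populated form
  c(TIME_TO_ONSET = 28 / 45, REACTION_DURATION = 0.7, DOSE = 0.75,
    OCCUPATION = 44 / 45, BREED = 0.95, AGE = 1.0, SEX = 0.95,
    NEUTER = 0.9, COMMENTS = 1.0, ADDITIONAL = 0.7)
}

#' Configure the synthetic report generator
#'
#' Defines the joint distribution the generator draws corpora from: one
#' Bernoulli completeness state per element (probability `theta[e]` of
#' being complete), the time-to-onset ambiguity split, clinical-note
#' attachment, and per-element probabilities that attached notes resolve a
#' penalized element. Defaults emulate a small-animal practice corpus in
#' which every incomplete time-to-onset is a same-day case fully resolvable
#' from the notes, while age penalties (auto-populated bare "0" for animals
#' under one year, probability `p_age_zero`) are never resolvable.
#'
#' @param n_reports Number of reports to generate.
#' @param seed Integer seed; the random stream is split per report, so
#'   corpora for the same seed share a common prefix as `n_reports` grows.
#' @param theta Named probability vector over [AE_ELEMENTS]: probability
#'   each element is complete on the report fields. `COMMENTS` below 1
#'   produces placeholder descriptions, i.e. reports that fail the minimum
#'   reporting criteria (a warning is raised).
#' @param p_same_day Probability that an incomplete time-to-onset is a
#'   same-day drug-start/reaction pair (notes-resolvable ambiguity) rather
#'   than a missing drug start date (never resolvable).
#' @param p_notes_attached Probability clinical notes are appended.
#' @param rho_notes_resolve Named probabilities that attached notes resolve
#'   an incomplete element; names must be among `TIME_TO_ONSET`,
#'   `REACTION_DURATION`, `DOSE` (the only elements with free-text
#'   clauses).
#' @param p_age_zero Probability an animal with known age is under one
#'   year, in which case the system transmits a bare age of 0 (10 percent
#'   penalty).
#' @param p_extra_drug Probability a report lists a second suspect product
#'   (exercises the worst-case time-to-onset rule).
#' @param species_pool,breed_pool,product_pool,sign_pool Lists with
#'   `values` and `weights` for categorical sampling.
#' @return An object of class `generator_config`.
#' @seealso [generate_corpus()], [expected_score()]
#' @export
generator_config <- function(n_reports = 45,
                             seed = 20200918,
                             theta = default_theta(),
                             p_same_day = 1.0,
                             p_notes_attached = 0.9,
                             rho_notes_resolve = c(TIME_TO_ONSET = 1.0,
                                                   REACTION_DURATION = 0.7,
                                                   DOSE = 0.7),
                             p_age_zero = 14 / 45,
                             p_extra_drug = 0,
                             species_pool = default_species_pool(),
                             breed_pool = default_breed_pool(),
                             product_pool = default_product_pool(),
                             sign_pool = default_sign_pool()) {
  theta <- modifyList(as.list(default_theta()), as.list(theta))
  theta <- unlist(theta)[AE_ELEMENTS]
  if (anyNA(theta)) stop("'theta' must cover only known elements",
                         call. = FALSE)
  assert_probability(theta, "theta")
  assert_probability(p_same_day, "p_same_day")
  assert_probability(p_notes_attached, "p_notes_attached")
  assert_probability(p_age_zero, "p_age_zero")
  assert_probability(p_extra_drug, "p_extra_drug")
  rho <- setNames(numeric(length(NOTES_RESOLVABLE_ELEMENTS)),
                  NOTES_RESOLVABLE_ELEMENTS)
  if (length(rho_notes_resolve) > 0) {
    bad <- setdiff(names(rho_notes_resolve), NOTES_RESOLVABLE_ELEMENTS)
    if (length(bad) > 0) {
      stop(sprintf(
        "rho_notes_resolve keys must be notes-resolvable elements (%s); got: %s",
        paste(NOTES_RESOLVABLE_ELEMENTS, collapse = ", "),
        paste(bad, collapse = ", ")), call. = FALSE)
    }
    assert_probability(rho_notes_resolve, "rho_notes_resolve")
    rho[names(rho_notes_resolve)] <- rho_notes_resolve
  }
  if (theta[["COMMENTS"]] < 1) {
    warning(paste("theta['COMMENTS'] < 1 generates placeholder descriptions:",
                  "such reports fail the minimum reporting criteria"),
            call. = FALSE)
  }
  for (pool in list(species_pool, breed_pool, product_pool, sign_pool)) {
    if (length(pool$values) == 0 || length(pool$values) !=
        length(pool$weights) || any(pool$weights < 0)) {
      stop("pools must be non-empty with matching non-negative weights",
           call. = FALSE)
    }
  }
  if (n_reports < 0 || n_reports != round(n_reports)) {
    stop("'n_reports' must be a non-negative integer", call. = FALSE)
  }
  structure(list(
    n_reports = as.integer(n_reports), seed = seed, theta = theta,
    p_same_day = p_same_day, p_notes_attached = p_notes_attached,
    rho_notes_resolve = rho, p_age_zero = p_age_zero,
    p_extra_drug = p_extra_drug, species_pool = species_pool,
    breed_pool = breed_pool, product_pool = product_pool,
    sign_pool = sign_pool
  ), class = "generator_config")
}

#' Read a generator configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose keys are
#'   arguments of [generator_config()].
#' @return A `generator_config` object.
#' @export
read_generator_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  for (nm in c("theta", "rho_notes_resolve")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(generator_config, raw)
}

sample_pool <- function(pool, n = 1) {
  pool$values[sample.int(length(pool$values), n, replace = TRUE,
                         prob = pool$weights)]
}

implied_element_scores <- function(state, mode) {
  with_notes <- mode == "WITH_NOTES"
  c(
    TIME_TO_ONSET = if (state$tto_state == "COMPLETE" ||
                        (with_notes && state$tto_state == "SAME_DAY" &&
                         state$tto_resolved)) 1.0 else 0.5,
    REACTION_DURATION = if (state$rd_complete ||
                            (with_notes && state$rd_resolved)) 1.0 else 0.9,
    DOSE = if (state$dose_complete ||
               (with_notes && state$dose_resolved)) 1.0 else 0.9,
    OCCUPATION = if (state$occ_known) 1.0 else 0.7,
    BREED = if (state$breed_known) 1.0 else 0.7,
    AGE = switch(state$age_state, KNOWN = 1.0, ZERO = 0.9, UNKNOWN = 0.7),
    SEX = if (state$sex_known) 1.0 else 0.7,
    NEUTER = if (state$neuter_known) 1.0 else 0.7,
    COMMENTS = if (state$comments_ok) 1.0 else 0.9,
    ADDITIONAL = if (state$notes_attached || state$additional_reason) 1.0
                 else 0.9
  )
}

generate_one <- function(config, i) {
  set.seed(derive_seed(config$seed, i))
  th <- config$theta
  # element completeness states
  tto_state <- if (runif(1) < th[["TIME_TO_ONSET"]]) "COMPLETE"
               else if (runif(1) < config$p_same_day) "SAME_DAY"
               else "MISSING_DATE"
  notes_attached <- runif(1) < config$p_notes_attached
  rho <- config$rho_notes_resolve
  rd_complete <- runif(1) < th[["REACTION_DURATION"]]
  dose_complete <- runif(1) < th[["DOSE"]]
  occ_known <- runif(1) < th[["OCCUPATION"]]
  breed_known <- runif(1) < th[["BREED"]]
  age_known <- runif(1) < th[["AGE"]]
  age_zero <- age_known && runif(1) < config$p_age_zero
  sex_known <- runif(1) < th[["SEX"]]
  neuter_known <- runif(1) < th[["NEUTER"]]
  comments_ok <- runif(1) < th[["COMMENTS"]]
  additional_reason <- runif(1) < th[["ADDITIONAL"]]
  tto_resolved <- tto_state == "SAME_DAY" && notes_attached &&
    runif(1) < rho[["TIME_TO_ONSET"]]
  rd_resolved <- !rd_complete && notes_attached &&
    runif(1) < rho[["REACTION_DURATION"]]
  dose_resolved <- !dose_complete && notes_attached &&
    runif(1) < rho[["DOSE"]]

  report_id <- sprintf("SYN-%05d", i)
  reaction_date <- as.Date("2020-09-18") + sample.int(541, 1) - 1
  species <- sample_pool(config$species_pool)
  sex <- if (sex_known) sample(c("MALE", "FEMALE"), 1) else "UNKNOWN"
  administrator <- if (occ_known) {
    sample(c("VET", "OWNER", "VET_NURSE"), 1, prob = c(33, 22, 3))
  } else "UNKNOWN"
  start_date <- switch(tto_state,
    COMPLETE = reaction_date - sample.int(30, 1),
    SAME_DAY = reaction_date,
    MISSING_DATE = NULL)
  dosage_text <- if (dose_complete) {
    sprintf("%d mg once daily", sample(c(5L, 10L, 25L, 50L), 1))
  } else NULL
  age <- if (!age_known) {
    list(dob = NULL, years = NULL, months = NULL)
  } else if (age_zero) {
    # the system auto-populates a bare 0 for animals under one year
    list(dob = reaction_date - sample(30:330, 1), years = 0L, months = NULL)
  } else {
    dob <- reaction_date - sample(400:4000, 1)
    a <- derive_age(dob, reaction_date)
    list(dob = dob, years = a$years, months = a$months)
  }
  signs <- unique(sample_pool(config$sign_pool, sample.int(3, 1)))
  description <- if (comments_ok) paste(signs, collapse = "; ") else "n/a"
  notes <- if (notes_attached) {
    list(clinical_note(reaction_date, text = paste(
      "O reports", paste(signs, collapse = " and "),
      "after product given earlier the same day; advised monitoring."),
      window_tag = "CURRENT_CONSULT"))
  } else list()

  drugs <- list(drug_entry(
    product_name = sample_pool(config$product_pool),
    start_date = start_date,
    dosage_text = dosage_text,
    administrator = administrator))
  if (runif(1) < config$p_extra_drug) {
    drugs <- c(drugs, list(drug_entry(
      product_name = sample_pool(config$product_pool),
      start_date = if (is.null(start_date)) NULL else start_date,
      administrator = administrator)))
  }

  report <- ae_report(
    report_id = report_id,
    practice_id = sprintf("P%03d", sample.int(42, 1)),
    species = species,
    breed = if (breed_known) sample_pool(config$breed_pool) else "UNKNOWN",
    date_of_birth = age$dob,
    age_years = age$years,
    age_months = age$months,
    sex = sex,
    neuter_status = if (neuter_known) sample(c("NEUTERED", "ENTIRE"), 1)
                    else "UNKNOWN",
    weight = round(runif(1, 1, 40), 1),
    suspect_drugs = drugs,
    reaction_date = reaction_date,
    reaction_duration = if (rd_complete) sample.int(14, 1) else NULL,
    reaction_duration_unit = if (rd_complete) "DAYS" else NULL,
    fatal = "NO",
    reaction_description = description,
    clinical_notes = notes,
    submitted_to_manufacturer = sample(c("YES", "NO"), 1, prob = c(1, 3)),
    wants_copy = "NO",
    submission_timestamp = as.POSIXct(reaction_date, tz = "UTC") + 3600 * 20
  )

  judgments <- list()
  if (dose_complete) {
    judgments <- c(judgments, list(element_judgment(
      "DOSE", "RESOLVES", "REPORT_FIELDS", report_id)))
  }
  if (additional_reason && !notes_attached) {
    judgments <- c(judgments, list(element_judgment(
      "ADDITIONAL", "RESOLVES", "REVIEWER", report_id)))
  }
  for (spec in list(list(tto_resolved, "TIME_TO_ONSET"),
                    list(rd_resolved, "REACTION_DURATION"),
                    list(dose_resolved, "DOSE"))) {
    if (spec[[1]]) {
      judgments <- c(judgments, list(element_judgment(
        spec[[2]], "RESOLVES", "CLINICAL_NOTES", report_id)))
    }
  }

  state <- list(tto_state = tto_state, tto_resolved = tto_resolved,
                rd_complete = rd_complete, rd_resolved = rd_resolved,
                dose_complete = dose_complete, dose_resolved = dose_resolved,
                occ_known = occ_known, breed_known = breed_known,
                age_state = if (!age_known) "UNKNOWN"
                            else if (age_zero) "ZERO" else "KNOWN",
                sex_known = sex_known, neuter_known = neuter_known,
                comments_ok = comments_ok, notes_attached = notes_attached,
                additional_reason = additional_reason)
  sf <- implied_element_scores(state, "FIELDS_ONLY")
  sn <- implied_element_scores(state, "WITH_NOTES")
  truth <- c(list(report_id = report_id), state,
             list(score_fields_only = prod(sf), score_with_notes = prod(sn),
                  notes_improve = tto_resolved || rd_resolved ||
                    dose_resolved))
  list(report = report, judgments = judgments, truth = truth)
}

#' Generate a synthetic report corpus
#'
#' Draws `n_reports` reports with independent per-element completeness
#' states, matching clinical-note judgments, and a truth record per report
#' carrying the drawn states and the implied final scores in both
#' assessment modes. Deterministic given the seed; the stream is split per
#' report so a longer corpus extends a shorter one generated from the same
#' seed.
#'
#' @param config A [generator_config()].
#' @return List with `reports` (list of [ae_report()]), `judgments` (flat
#'   list of [element_judgment()] with `report_id` set) and `truth` (data
#'   frame, one row per report).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  out <- lapply(seq_len(config$n_reports), function(i)
    generate_one(config, i))
  truth <- if (length(out) == 0) data.frame() else {
    fields <- names(out[[1]]$truth)
    as.data.frame(setNames(lapply(fields, function(f)
      unlist(lapply(out, function(x) x$truth[[f]]))), fields),
      stringsAsFactors = FALSE)
  }
  list(
    reports = lapply(out, `[[`, "report"),
    judgments = unlist(lapply(out, `[[`, "judgments"), recursive = FALSE),
    truth = truth
  )
}

#' Analytic expected final score under a generator configuration
#'
#' Closed-form expectation of the multiplicative final score. Element
#' states are independent given whether clinical notes are attached, but
#' note attachment couples the additional-comments element with the
#' notes-resolution events, so the expectation is computed by conditioning
#' on attachment: a mixture over attached/not of the product of
#' per-element conditional expectations.
#'
#' @param config A [generator_config()].
#' @param mode `FIELDS_ONLY` or `WITH_NOTES`.
#' @return The expected final score in (0, 1].
#' @export
expected_score <- function(config, mode = "FIELDS_ONLY") {
  stopifnot(inherits(config, "generator_config"))
  mode <- assert_enum(mode, ASSESSMENT_MODES, "mode")
  th <- config$theta
  rho <- config$rho_notes_resolve
  p0 <- config$p_age_zero
  per_attachment <- function(attached) {
    r <- function(e) if (mode == "WITH_NOTES" && attached) rho[[e]] else 0
    e_tto <- th[["TIME_TO_ONSET"]] + (1 - th[["TIME_TO_ONSET"]]) *
      (config$p_same_day * (r("TIME_TO_ONSET") +
                            (1 - r("TIME_TO_ONSET")) * 0.5) +
       (1 - config$p_same_day) * 0.5)
    e_pen10 <- function(theta, rr) theta + (1 - theta) * (rr + (1 - rr) * 0.9)
    e_pen30 <- function(theta) theta + (1 - theta) * 0.7
    e_age <- th[["AGE"]] * ((1 - p0) + p0 * 0.9) + (1 - th[["AGE"]]) * 0.7
    e_add <- if (attached) 1 else
      th[["ADDITIONAL"]] + (1 - th[["ADDITIONAL"]]) * 0.9
    e_tto *
      e_pen10(th[["REACTION_DURATION"]], r("REACTION_DURATION")) *
      e_pen10(th[["DOSE"]], r("DOSE")) *
      e_pen30(th[["OCCUPATION"]]) * e_pen30(th[["BREED"]]) * e_age *
      e_pen30(th[["SEX"]]) * e_pen30(th[["NEUTER"]]) *
      e_pen10(th[["COMMENTS"]], 0) * e_add
  }
  config$p_notes_attached * per_attachment(TRUE) +
    (1 - config$p_notes_attached) * per_attachment(FALSE)
}

#' Assess every report in a corpus
#'
#' Convenience bulk scorer: splits a flat judgment list by report and runs
#' [assess_report()] over the corpus in one mode.
#'
#' @param reports List of [ae_report()] objects.
#' @param judgments Flat list of [element_judgment()] records with
#'   `report_id` set (judgments without a `report_id` are ignored).
#' @param mode `FIELDS_ONLY` or `WITH_NOTES`.
#' @param reviewer_id Optional reviewer identifier stamped on every
#'   assessment.
#' @return Data frame with one row per report: `report_id`, `mode`, one
#'   column per element score, `final_score`, `well_documented`,
#'   `reviewer_id`.
#' @export
assess_corpus <- function(reports, judgments = list(), mode = "FIELDS_ONLY",
                          reviewer_id = NA_character_) {
  mode <- assert_enum(mode, ASSESSMENT_MODES, "mode")
  ids <- vapply(judgments, function(j) j$report_id %||% NA_character_,
                character(1))
  by_report <- split(judgments[!is.na(ids)], ids[!is.na(ids)])
  scores <- vapply(reports, function(r) {
    a <- assess_report(r, by_report[[r$report_id]] %||% list(), mode)
    a$element_scores
  }, numeric(length(AE_ELEMENTS)))
  finals <- apply(scores, 2, prod)
  df <- data.frame(
    report_id = vapply(reports, `[[`, character(1), "report_id"),
    mode = mode, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(t(scores)))
  df$final_score <- finals
  df$well_documented <- finals >= WELL_DOCUMENTED_THRESHOLD
  df$reviewer_id <- reviewer_id
  rownames(df) <- NULL
  df
}
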