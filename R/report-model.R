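# Structured AE report model mirroring the four-screen reporting form
# (animal / drug / reaction / contact) plus minimum-criteria validation.

SPECIES_LEVELS <- c("DOG", "CAT", "RABBIT", "OTHER", "HUMAN_FLAGGED", "UNKNOWN")
SEX_LEVELS <- c("MALE", "FEMALE", "UNKNOWN")
NEUTER_LEVELS <- c("NEUTERED", "ENTIRE", "UNKNOWN")
DURATION_UNITS <- c("HOURS", "DAYS", "WEEKS", "MONTHS")
ADMINISTRATOR_LEVELS <- c("VET", "VET_NURSE", "OWNER", "OTHER", "UNKNOWN")
ROUTE_LEVELS <- c("ORAL", "TOPICAL", "SUBCUTANEOUS", "INTRAMUSCULAR",
                  "INTRAVENOUS", "OCULAR", "AURICULAR", "INHALATION", "OTHER")
YES_NO <- c("YES", "NO")
NOTE_WINDOWS <- c("CURRENT_CONSULT", "PRIOR_TWO_MONTHS")

#' Create a suspect-drug entry
#'
#' One suspect veterinary medicinal product within an adverse-event report:
#' the product name (the only mandatory field), administration dates and
#' details, and who administered it. `is_vaccine_or_pipette` is an explicit
#' flag (never inferred from the product name) because vaccine and pipette
#' doses are exempt from the dose-completeness penalty.
#'
#' @param product_name Product name; must be non-empty.
#' @param start_date Drug start date (coerced with [as.Date()]), or `NULL`.
#' @param marketing_auth_number,batch_number Optional free-text identifiers.
#' @param route Route of administration from a standardized list, or `NULL`.
#' @param admin_duration,admin_duration_unit Duration of administration and
#'   its unit (`HOURS`, `DAYS`, `WEEKS`, `MONTHS`); both present or both
#'   absent.
#' @param dosage_text Free-text dosage details, or `NULL`.
#' @param administrator Occupation of the person who administered the
#'   product: `VET`, `VET_NURSE`, `OWNER`, `OTHER` or `UNKNOWN`.
#' @param is_vaccine_or_pipette Logical; `TRUE` exempts the entry from the
#'   dose penalty.
#' @return An object of class `drug_entry`.
#' @export
#' @examples
#' drug_entry("Vaccine X", start_date = "2020-10-01",
#'            administrator = "VET", is_vaccine_or_pipette = TRUE)
drug_entry <- function(product_name,
                       start_date = NULL,
                       marketing_auth_number = NULL,
                       batch_number = NULL,
                       route = NULL,
                       admin_duration = NULL,
                       admin_duration_unit = NULL,
                       dosage_text = NULL,
                       administrator = "UNKNOWN",
                       is_vaccine_or_pipette = FALSE) {
  if (is.null(product_name) || !nzchar(trimws(product_name))) {
    stop("field 'product_name' must be non-empty", call. = FALSE)
  }
  admin_duration <- assert_nonneg_scalar(admin_duration, "admin_duration")
  admin_duration_unit <- assert_enum(admin_duration_unit, DURATION_UNITS,
                                     "admin_duration_unit", allow_null = TRUE)
  if (is.null(admin_duration) != is.null(admin_duration_unit)) {
    stop("'admin_duration' and 'admin_duration_unit' must be given together",
         call. = FALSE)
  }
  structure(list(
    product_name = as.character(product_name),
    marketing_auth_number = marketing_auth_number,
    batch_number = batch_number,
    route = assert_enum(route, ROUTE_LEVELS, "route", allow_null = TRUE),
    start_date = as_date_scalar(start_date, "start_date"),
    admin_duration = admin_duration,
    admin_duration_unit = admin_duration_unit,
    dosage_text = dosage_text,
    administrator = assert_enum(administrator, ADMINISTRATOR_LEVELS,
                                "administrator"),
    is_vaccine_or_pipette = isTRUE(is_vaccine_or_pipette)
  ), class = "drug_entry")
}

#' Create a clinical note attached to a report
#'
#' Anonymized free-text clinical notes from the electronic health record,
#' either from the consultation at which the report was made
#' (`CURRENT_CONSULT`) or from the preceding two months
#' (`PRIOR_TWO_MONTHS`).
#'
#' @param note_date Date of the note.
#' @param text Anonymized note text; may be empty only for
#'   `CURRENT_CONSULT` placeholder notes.
#' @param window_tag `CURRENT_CONSULT` or `PRIOR_TWO_MONTHS`.
#' @return An object of class `clinical_note`.
#' @export
clinical_note <- function(note_date, text = "",
                          window_tag = "CURRENT_CONSULT") {
  window_tag <- assert_enum(window_tag, NOTE_WINDOWS, "window_tag")
  text <- as.character(text %||% "")
  if (!nzchar(text) && window_tag != "CURRENT_CONSULT") {
    stop("note text may be empty only for CURRENT_CONSULT placeholder notes",
         call. = FALSE)
  }
  structure(list(
    note_date = as_date_scalar(note_date, "note_date"),
    text = text,
    window_tag = window_tag
  ), class = "clinical_note")
}

#' Create a structured adverse-event report
#'
#' One spontaneous adverse-event report, mirroring a four-screen practice
#' reporting form (animal, drug, reaction and contact information).
#' Animal demographics default to `UNKNOWN` rather than absent, matching
#' auto-populated form behaviour; `UNKNOWN` and structurally absent are
#' treated identically by the completeness scorer.
#'
#' `age_years`/`age_months` carry the age record as transmitted by the
#' reporting system, which may be coarser than `date_of_birth` implies (a
#' bare `age_years = 0` with no months is the under-one-year case the
#' scorer penalizes by 10 percent). When they are absent the scorer derives
#' age from `date_of_birth` via [derive_age()].
#'
#' A `HUMAN_FLAGGED` species marks a report that concerns a human; it
#' forces all animal fields (breed, dates of birth, age, sex, neuter
#' status, weight) to be absent.
#'
#' @param report_id,practice_id Opaque identifiers; `practice_id` stands
#'   for the unique practice identifier that satisfies the reporter
#'   criterion.
#' @param species One of `DOG`, `CAT`, `RABBIT`, `OTHER`, `HUMAN_FLAGGED`,
#'   `UNKNOWN`.
#' @param breed Free string or `"UNKNOWN"`.
#' @param date_of_birth Date or `NULL`.
#' @param age_years,age_months Transmitted age record (integers), or
#'   `NULL`; `age_months` requires `age_years`.
#' @param sex `MALE`, `FEMALE` or `UNKNOWN`.
#' @param neuter_status `NEUTERED`, `ENTIRE` or `UNKNOWN`.
#' @param weight Weight in kg, or `NULL`.
#' @param suspect_drugs List of [drug_entry()] objects (at least one for a
#'   submittable report).
#' @param concurrent_products Character vector of concurrent product names.
#' @param reaction_date Date of the reaction, or `NULL`.
#' @param reaction_duration,reaction_duration_unit Duration of the reaction
#'   and its unit; both present or both absent.
#' @param fatal `"YES"`, `"NO"` or `NULL`.
#' @param other_animals_text,reaction_description Free text; the reaction
#'   description is the mandatory narrative of the event.
#' @param clinical_notes List of [clinical_note()] objects.
#' @param submitted_to_manufacturer,wants_copy `"YES"` or `"NO"`.
#' @param practice_postcode_area Free string or `NULL`.
#' @param reporter_name,reporter_email,reporter_phone Optional contact
#'   strings.
#' @param submission_timestamp `POSIXct` or parseable string, or `NULL`.
#' @return An object of class `ae_report`.
#' @seealso [validate_minimum_criteria()], [assess_report()]
#' @export
#' @examples
#' rpt <- ae_report(
#'   report_id = "R1", practice_id = "P001", species = "DOG",
#'   breed = "Labrador", sex = "MALE", neuter_status = "NEUTERED",
#'   suspect_drugs = list(drug_entry("Drug A", start_date = "2020-10-01")),
#'   reaction_date = "2020-10-03",
#'   reaction_description = "vomited twice")
#' validate_minimum_criteria(rpt)$is_valid
ae_report <- function(report_id,
                      practice_id = "",
                      species = "UNKNOWN",
                      breed = "UNKNOWN",
                      date_of_birth = NULL,
                      age_years = NULL,
                      age_months = NULL,
                      sex = "UNKNOWN",
                      neuter_status = "UNKNOWN",
                      weight = NULL,
                      suspect_drugs = list(),
                      concurrent_products = character(),
                      reaction_date = NULL,
                      reaction_duration = NULL,
                      reaction_duration_unit = NULL,
                      fatal = NULL,
                      other_animals_text = "",
                      reaction_description = "",
                      clinical_notes = list(),
                      submitted_to_manufacturer = "NO",
                      practice_postcode_area = NULL,
                      reporter_name = NULL,
                      reporter_email = NULL,
                      reporter_phone = NULL,
                      wants_copy = "NO",
                      submission_timestamp = NULL) {
  if (is.null(report_id) || !nzchar(as.character(report_id))) {
    stop("field 'report_id' must be non-empty", call. = FALSE)
  }
  species <- assert_enum(species, SPECIES_LEVELS, "species")
  reaction_duration <- assert_nonneg_scalar(reaction_duration,
                                            "reaction_duration")
  reaction_duration_unit <- assert_enum(reaction_duration_unit,
                                        DURATION_UNITS,
                                        "reaction_duration_unit",
                                        allow_null = TRUE)
  if (is.null(reaction_duration) != is.null(reaction_duration_unit)) {
    stop(paste("'reaction_duration' and 'reaction_duration_unit' must be",
               "given together"), call. = FALSE)
  }
  if (!is.list(suspect_drugs) ||
      !all(vapply(suspect_drugs, inherits, logical(1), "drug_entry"))) {
    stop("'suspect_drugs' must be a list of drug_entry objects",
         call. = FALSE)
  }
  if (!is.list(clinical_notes) ||
      !all(vapply(clinical_notes, inherits, logical(1), "clinical_note"))) {
    stop("'clinical_notes' must be a list of clinical_note objects",
         call. = FALSE)
  }
  if (!is.null(age_months) && is.null(age_years)) {
    stop("'age_months' requires 'age_years'", call. = FALSE)
  }
  if (!is.null(age_years)) {
    age_years <- as.integer(assert_nonneg_scalar(age_years, "age_years"))
  }
  if (!is.null(age_months)) {
    age_months <- as.integer(assert_nonneg_scalar(age_months, "age_months"))
    if (age_months > 11) stop("'age_months' must be in 0-11", call. = FALSE)
  }
  if (species == "HUMAN_FLAGGED") {
    animal_given <- !(identical(toupper(breed %||% "UNKNOWN"), "UNKNOWN")) ||
      !is.null(date_of_birth) || !is.null(age_years) || !is.null(weight) ||
      !identical(toupper(sex), "UNKNOWN") ||
      !identical(toupper(neuter_status), "UNKNOWN")
    if (animal_given) {
      stop("a HUMAN_FLAGGED report must not carry animal fields",
           call. = FALSE)
    }
    breed <- NULL; sex <- "UNKNOWN"; neuter_status <- "UNKNOWN"
  }
  ts <- NULL
  if (!is.null(submission_timestamp)) {
    ts <- if (is.character(submission_timestamp)) {
      tryCatch(as.POSIXct(submission_timestamp, tz = "UTC",
                          tryFormats = c("%Y-%m-%dT%H:%M:%OSZ",
                                         "%Y-%m-%dT%H:%M:%OS",
                                         "%Y-%m-%d %H:%M:%OS",
                                         "%Y-%m-%d")),
               error = function(e) NA)
    } else {
      tryCatch(as.POSIXct(submission_timestamp, tz = "UTC"),
               error = function(e) NA)
    }
    if (length(ts) != 1 || is.na(ts)) {
      stop("field 'submission_timestamp' does not parse as a datetime",
           call. = FALSE)
    }
  }
  structure(list(
    report_id = as.character(report_id),
    practice_id = as.character(practice_id %||% ""),
    species = species,
    breed = if (is.null(breed)) NULL else as.character(breed),
    date_of_birth = as_date_scalar(date_of_birth, "date_of_birth"),
    age_years = age_years,
    age_months = age_months,
    sex = assert_enum(sex, SEX_LEVELS, "sex"),
    neuter_status = assert_enum(neuter_status, NEUTER_LEVELS,
                                "neuter_status"),
    weight = assert_nonneg_scalar(weight, "weight"),
    suspect_drugs = suspect_drugs,
    concurrent_products = as.character(concurrent_products),
    reaction_date = as_date_scalar(reaction_date, "reaction_date"),
    reaction_duration = reaction_duration,
    reaction_duration_unit = reaction_duration_unit,
    fatal = assert_enum(fatal, YES_NO, "fatal", allow_null = TRUE),
    other_animals_text = as.character(other_animals_text %||% ""),
    reaction_description = as.character(reaction_description %||% ""),
    clinical_notes = clinical_notes,
    submitted_to_manufacturer = assert_enum(submitted_to_manufacturer,
                                            YES_NO,
                                            "submitted_to_manufacturer"),
    practice_postcode_area = practice_postcode_area,
    reporter_name = reporter_name,
    reporter_email = reporter_email,
    reporter_phone = reporter_phone,
    wants_copy = assert_enum(wants_copy, YES_NO, "wants_copy"),
    submission_timestamp = ts
  ), class = "ae_report")
}

#' @export
print.ae_report <- function(x, ...) {
  cat(sprintf("<ae_report %s> %s, %d suspect drug(s), reaction %s\n",
              x$report_id, x$species, length(x$suspect_drugs),
              iso_date(x$reaction_date)))
  invisible(x)
}

#' Check a report against the four minimum reporting criteria
#'
#' A spontaneous adverse-event report is valid only if it carries an
#' identifiable reporter, an identifiable patient, at least one suspect
#' product, and a description of the reaction. The reporter criterion is
#' met by the unique practice identifier or by any reporter contact field;
#' the patient criterion by a known species; the suspect-product criterion
#' by at least one drug entry with a non-empty product name; and the
#' reaction-description criterion by a free-text description that is not a
#' placeholder (`"n/a"`, `"na"`, `"..."`, `"-"` or blank, case-insensitive
#' after trimming).
#'
#' @param report An [ae_report()].
#' @return An object of class `validation_result` with fields `is_valid`
#'   (logical), `criteria_present` (named logical over `REPORTER`,
#'   `PATIENT`, `SUSPECT_PRODUCT`, `REACTION_DESCRIPTION`) and `messages`
#'   (character, one message per failed criterion).
#' @export
validate_minimum_criteria <- function(report) {
  stopifnot(inherits(report, "ae_report"))
  contact <- c(report$reporter_name, report$reporter_email,
               report$reporter_phone)
  contact_present <- any(vapply(contact,
                                function(x) !is.null(x) && nzchar(trimws(x)),
                                logical(1))) %||% FALSE
  criteria <- c(
    REPORTER = nzchar(trimws(report$practice_id)) || isTRUE(contact_present),
    PATIENT = report$species != "UNKNOWN",
    SUSPECT_PRODUCT = length(report$suspect_drugs) >= 1 &&
      all(vapply(report$suspect_drugs,
                 function(d) nzchar(trimws(d$product_name)), logical(1))),
    REACTION_DESCRIPTION = !is_placeholder_description(
      report$reaction_description)
  )
  msgs <- c(
    if (!criteria[["REPORTER"]])
      "no identifiable reporter: practice_id and all contact fields empty",
    if (!criteria[["PATIENT"]]) "no identifiable patient: species UNKNOWN",
    if (!criteria[["SUSPECT_PRODUCT"]]) "no suspect product listed",
    if (!criteria[["REACTION_DESCRIPTION"]])
      "reaction description empty or placeholder"
  )
  structure(list(
    is_valid = all(criteria),
    criteria_present = criteria,
    messages = as.character(msgs %||% character())
  ), class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("<validation_result> valid: %s\n", x$is_valid))
  for (m in x$messages) cat(" -", m, "\n")
  invisible(x)
}

#' Normalize a pre-populated product list
#'
#' Drug fields pre-populated from recently dispensed products can contain
#' non-pharmaceutical invoice items (e.g. "puppy check"); reporters remove
#' those and may add products dispensed elsewhere. Matching for removal is
#' exact after case/whitespace normalization; order is preserved
#' (pre-populated entries first, then additions) and duplicates are
#' collapsed on the normalized name, keeping the first spelling seen.
#'
#' @param prepopulated Character vector of pre-populated product names.
#' @param removals Character vector of names to remove; a removal that
#'   matches nothing raises a warning, not an error.
#' @param additions Character vector of names to append.
#' @return Character vector of product names.
#' @export
#' @examples
#' normalize_product_list(c("Drug A", "puppy check"), removals = "puppy check")
normalize_product_list <- function(prepopulated, removals = character(),
                                   additions = character()) {
  prepopulated <- as.character(prepopulated %||% character())
  removals <- as.character(removals %||% character())
  additions <- as.character(additions %||% character())
  pool <- c(prepopulated, additions)
  keys <- norm_term(pool)
  rem_keys <- norm_term(removals)
  missing_rem <- removals[!(rem_keys %in% keys)]
  if (length(missing_rem) > 0) {
    warning(sprintf("removal(s) not present in product list: %s",
                    paste(missing_rem, collapse = ", ")), call. = FALSE)
  }
  keep <- !(keys %in% rem_keys) & !duplicated(keys) & nzchar(keys)
  pool[keep]
}

#' Derive an age record from a date of birth
#'
#' Whole-year age plus the residual whole months; months matter because a
#' bare age of zero years (no months) attracts a completeness penalty for
#' animals under one year old.
#'
#' @param date_of_birth Date or `NULL`; `NULL` yields an `UNKNOWN` age.
#' @param reference_date Date the age is computed at (e.g. reaction date).
#' @return A list with `years` (integer, or the string `"UNKNOWN"`) and
#'   `months` (integer 0-11, present whenever the date of birth is known).
#' @export
#' @examples
#' derive_age(as.Date("2020-06-01"), as.Date("2020-10-01"))  # 0 y, 4 m
derive_age <- function(date_of_birth, reference_date) {
  reference_date <- as_date_scalar(reference_date, "reference_date")
  if (is.null(reference_date)) {
    stop("'reference_date' is required", call. = FALSE)
  }
  date_of_birth <- as_date_scalar(date_of_birth, "date_of_birth")
  if (is.null(date_of_birth)) {
    return(list(years = "UNKNOWN", months = NULL))
  }
  if (date_of_birth > reference_date) {
    stop("date_of_birth is after the reference date: impossible age",
         call. = FALSE)
  }
  b <- as.POSIXlt(date_of_birth)
  r <- as.POSIXlt(reference_date)
  months_total <- 12L * (r$year - b$year) + (r$mon - b$mon) -
    as.integer(r$mday < b$mday)
  list(years = months_total %/% 12L, months = as.integer(months_total %% 12L))
}
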