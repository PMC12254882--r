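# Round-trip readers/writers for the report dialects: JSON (one object per
# report, clinical notes nested) and flat CSV (one row per report x suspect
# drug, notes in a separate file keyed by report_id). Column layout is
# documented in inst/extdata/data-dictionary.tsv.

report_to_list <- function(r) {
  list(
    report_id = r$report_id,
    practice_id = r$practice_id,
    species = r$species,
    breed = r$breed,
    date_of_birth = iso_date(r$date_of_birth),
    age_years = r$age_years,
    age_months = r$age_months,
    sex = r$sex,
    neuter_status = r$neuter_status,
    weight = r$weight,
    suspect_drugs = lapply(r$suspect_drugs, function(d) list(
      product_name = d$product_name,
      marketing_auth_number = d$marketing_auth_number,
      batch_number = d$batch_number,
      route = d$route,
      start_date = iso_date(d$start_date),
      admin_duration = d$admin_duration,
      admin_duration_unit = d$admin_duration_unit,
      dosage_text = d$dosage_text,
      administrator = d$administrator,
      is_vaccine_or_pipette = d$is_vaccine_or_pipette
    )),
    concurrent_products = as.list(r$concurrent_products),
    reaction_date = iso_date(r$reaction_date),
    reaction_duration = r$reaction_duration,
    reaction_duration_unit = r$reaction_duration_unit,
    fatal = r$fatal,
    other_animals_text = r$other_animals_text,
    reaction_description = r$reaction_description,
    clinical_notes = lapply(r$clinical_notes, function(n) list(
      note_date = iso_date(n$note_date),
      text = n$text,
      window_tag = n$window_tag
    )),
    submitted_to_manufacturer = r$submitted_to_manufacturer,
    practice_postcode_area = r$practice_postcode_area,
    reporter_name = r$reporter_name,
    reporter_email = r$reporter_email,
    reporter_phone = r$reporter_phone,
    wants_copy = r$wants_copy,
    submission_timestamp = if (is.null(r$submission_timestamp)) NULL
      else format(r$submission_timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  )
}

maybe <- function(x) {
  if (is.null(x) || (length(x) == 1 && (is.na(x) || identical(x, "NA"))))
    NULL
  else x
}

list_to_report <- function(x) {
  ae_report(
    report_id = x$report_id,
    practice_id = x$practice_id %||% "",
    species = x$species %||% "UNKNOWN",
    breed = maybe(x$breed),
    date_of_birth = maybe(x$date_of_birth),
    age_years = maybe(x$age_years),
    age_months = maybe(x$age_months),
    sex = x$sex %||% "UNKNOWN",
    neuter_status = x$neuter_status %||% "UNKNOWN",
    weight = maybe(x$weight),
    suspect_drugs = lapply(x$suspect_drugs %||% list(), function(d)
      drug_entry(
        product_name = d$product_name,
        marketing_auth_number = maybe(d$marketing_auth_number),
        batch_number = maybe(d$batch_number),
        route = maybe(d$route),
        start_date = maybe(d$start_date),
        admin_duration = maybe(d$admin_duration),
        admin_duration_unit = maybe(d$admin_duration_unit),
        dosage_text = maybe(d$dosage_text),
        administrator = d$administrator %||% "UNKNOWN",
        is_vaccine_or_pipette = isTRUE(as.logical(
          d$is_vaccine_or_pipette %||% FALSE)))),
    concurrent_products = unlist(x$concurrent_products %||% character()) %||%
      character(),
    reaction_date = maybe(x$reaction_date),
    reaction_duration = maybe(x$reaction_duration),
    reaction_duration_unit = maybe(x$reaction_duration_unit),
    fatal = maybe(x$fatal),
    other_animals_text = x$other_animals_text %||% "",
    reaction_description = x$reaction_description %||% "",
    clinical_notes = lapply(x$clinical_notes %||% list(), function(n)
      clinical_note(n$note_date, n$text %||% "",
                    n$window_tag %||% "CURRENT_CONSULT")),
    submitted_to_manufacturer = x$submitted_to_manufacturer %||% "NO",
    practice_postcode_area = maybe(x$practice_postcode_area),
    reporter_name = maybe(x$reporter_name),
    reporter_email = maybe(x$reporter_email),
    reporter_phone = maybe(x$reporter_phone),
    wants_copy = x$wants_copy %||% "NO",
    submission_timestamp = maybe(x$submission_timestamp)
  )
}

#' Write and read reports as JSON
#'
#' One JSON object per report, clinical notes and suspect drugs nested;
#' dates ISO 8601, enums as uppercase tokens, absent fields omitted.
#'
#' @param reports List of [ae_report()] objects.
#' @param path File path.
#' @return `write_reports_json` returns `path` invisibly;
#'   `read_reports_json` returns a list of [ae_report()] objects.
#' @export
write_reports_json <- function(reports, path) {
  payload <- lapply(reports, report_to_list)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_reports_json
#' @export
read_reports_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, list_to_report)
}

REPORT_CSV_COLUMNS <- c(
  "report_id", "practice_id", "species", "breed", "date_of_birth",
  "age_years", "age_months", "sex", "neuter_status", "weight",
  "concurrent_products", "reaction_date", "reaction_duration",
  "reaction_duration_unit", "fatal", "other_animals_text",
  "reaction_description", "submitted_to_manufacturer",
  "practice_postcode_area", "reporter_name", "reporter_email",
  "reporter_phone", "wants_copy", "submission_timestamp", "drug_index",
  "product_name", "marketing_auth_number", "batch_number", "route",
  "start_date", "admin_duration", "admin_duration_unit", "dosage_text",
  "administrator", "is_vaccine_or_pipette")

#' Write and read reports as flat CSV
#'
#' One row per report x suspect drug (report-level fields repeated);
#' clinical notes go to a separate CSV keyed by `report_id`. Column names
#' are fixed by the data dictionary shipped at
#' `system.file("extdata", "data-dictionary.tsv", package = "vetgrade")`.
#'
#' @param reports List of [ae_report()] objects.
#' @param path Reports CSV path.
#' @param notes_path Optional clinical-notes CSV path.
#' @return `write_reports_csv` returns `path` invisibly;
#'   `read_reports_csv` returns a list of [ae_report()] objects.
#' @export
write_reports_csv <- function(reports, path, notes_path = NULL) {
  chr <- function(x) if (is.null(x)) NA else as.character(x)
  rows <- list(); notes <- list()
  for (r in reports) {
    l <- report_to_list(r)
    base <- data.frame(
      report_id = l$report_id, practice_id = l$practice_id,
      species = l$species, breed = chr(l$breed),
      date_of_birth = chr(l$date_of_birth), age_years = chr(l$age_years),
      age_months = chr(l$age_months), sex = l$sex,
      neuter_status = l$neuter_status, weight = chr(l$weight),
      concurrent_products = paste(r$concurrent_products, collapse = ";"),
      reaction_date = chr(l$reaction_date),
      reaction_duration = chr(l$reaction_duration),
      reaction_duration_unit = chr(l$reaction_duration_unit),
      fatal = chr(l$fatal), other_animals_text = l$other_animals_text,
      reaction_description = l$reaction_description,
      submitted_to_manufacturer = l$submitted_to_manufacturer,
      practice_postcode_area = chr(l$practice_postcode_area),
      reporter_name = chr(l$reporter_name),
      reporter_email = chr(l$reporter_email),
      reporter_phone = chr(l$reporter_phone), wants_copy = l$wants_copy,
      submission_timestamp = chr(l$submission_timestamp),
      stringsAsFactors = FALSE)
    for (i in seq_along(l$suspect_drugs)) {
      d <- l$suspect_drugs[[i]]
      rows[[length(rows) + 1]] <- cbind(base, data.frame(
        drug_index = i, product_name = d$product_name,
        marketing_auth_number = chr(d$marketing_auth_number),
        batch_number = chr(d$batch_number), route = chr(d$route),
        start_date = chr(d$start_date),
        admin_duration = chr(d$admin_duration),
        admin_duration_unit = chr(d$admin_duration_unit),
        dosage_text = chr(d$dosage_text), administrator = d$administrator,
        is_vaccine_or_pipette = d$is_vaccine_or_pipette,
        stringsAsFactors = FALSE))
    }
    for (n in l$clinical_notes) {
      notes[[length(notes) + 1]] <- data.frame(
        report_id = l$report_id, note_date = n$note_date,
        window_tag = n$window_tag, text = n$text, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)[, REPORT_CSV_COLUMNS]
  write.csv(df, path, row.names = FALSE, na = "")
  if (!is.null(notes_path)) {
    ndf <- if (length(notes)) do.call(rbind, notes) else
      data.frame(report_id = character(), note_date = character(),
                 window_tag = character(), text = character())
    write.csv(ndf, notes_path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' @rdname write_reports_csv
#' @export
read_reports_csv <- function(path, notes_path = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 na.strings = "")
  ndf <- if (!is.null(notes_path)) {
    read.csv(notes_path, stringsAsFactors = FALSE,
             colClasses = "character", na.strings = "")
  } else NULL
  opt <- function(x) if (is.null(x) || is.na(x)) NULL else x
  num <- function(x) if (is.null(x) || is.na(x)) NULL else as.numeric(x)
  txt <- function(x) if (is.null(x) || is.na(x)) "" else x
  lapply(split(df, factor(df$report_id, levels = unique(df$report_id))),
         function(g) {
    g <- g[order(as.integer(g$drug_index)), , drop = FALSE]
    h <- g[1, ]
    drugs <- lapply(seq_len(nrow(g)), function(i) drug_entry(
      product_name = g$product_name[i],
      marketing_auth_number = opt(g$marketing_auth_number[i]),
      batch_number = opt(g$batch_number[i]),
      route = opt(g$route[i]),
      start_date = opt(g$start_date[i]),
      admin_duration = num(g$admin_duration[i]),
      admin_duration_unit = opt(g$admin_duration_unit[i]),
      dosage_text = opt(g$dosage_text[i]),
      administrator = g$administrator[i],
      is_vaccine_or_pipette = as.logical(g$is_vaccine_or_pipette[i])))
    notes <- list()
    if (!is.null(ndf)) {
      sel <- ndf[ndf$report_id == h$report_id, , drop = FALSE]
      notes <- lapply(seq_len(nrow(sel)), function(i) clinical_note(
        sel$note_date[i], sel$text[i], sel$window_tag[i]))
    }
    ae_report(
      report_id = h$report_id, practice_id = txt(h$practice_id),
      species = h$species, breed = opt(h$breed),
      date_of_birth = opt(h$date_of_birth),
      age_years = num(h$age_years), age_months = num(h$age_months),
      sex = h$sex, neuter_status = h$neuter_status,
      weight = num(h$weight),
      suspect_drugs = drugs,
      concurrent_products = if (is.na(h$concurrent_products) ||
                                !nzchar(h$concurrent_products)) character()
                            else strsplit(h$concurrent_products, ";")[[1]],
      reaction_date = opt(h$reaction_date),
      reaction_duration = num(h$reaction_duration),
      reaction_duration_unit = opt(h$reaction_duration_unit),
      fatal = opt(h$fatal),
      other_animals_text = txt(h$other_animals_text),
      reaction_description = txt(h$reaction_description),
      clinical_notes = notes,
      submitted_to_manufacturer = h$submitted_to_manufacturer,
      practice_postcode_area = opt(h$practice_postcode_area),
      reporter_name = opt(h$reporter_name),
      reporter_email = opt(h$reporter_email),
      reporter_phone = opt(h$reporter_phone),
      wants_copy = h$wants_copy,
      submission_timestamp = opt(h$submission_timestamp))
  }) |> unname()
}

#' Write and read element judgments as CSV
#'
#' Columns: `report_id`, `element`, `verdict`, `source`.
#'
#' @param judgments Flat list of [element_judgment()] records.
#' @param path File path.
#' @return `write_judgments_csv` returns `path` invisibly;
#'   `read_judgments_csv` returns a list of [element_judgment()] records.
#' @export
write_judgments_csv <- function(judgments, path) {
  df <- data.frame(
    report_id = vapply(judgments, function(j) j$report_id %||% NA_character_,
                       character(1)),
    element = vapply(judgments, `[[`, character(1), "element"),
    verdict = vapply(judgments, `[[`, character(1), "verdict"),
    source = vapply(judgments, `[[`, character(1), "source"),
    stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_judgments_csv
#' @export
read_judgments_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 na.strings = "")
  lapply(seq_len(nrow(df)), function(i) element_judgment(
    df$element[i], df$verdict[i], df$source[i],
    report_id = if (is.na(df$report_id[i])) NULL else df$report_id[i]))
}

#' Write assessments as CSV
#'
#' One row per assessment: `report_id`, `mode`, the ten element-score
#' columns, `final_score`, `well_documented`, `reviewer_id`.
#'
#' @param assessments A data frame from [assess_corpus()] or a list of
#'   `completeness_assessment` objects.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_assessments_csv <- function(assessments, path) {
  if (!is.data.frame(assessments)) {
    assessments <- do.call(rbind, lapply(assessments, function(a)
      as.data.frame(c(list(report_id = a$report_id, mode = a$mode),
                      as.list(a$element_scores),
                      list(final_score = a$final_score,
                           well_documented = a$well_documented,
                           reviewer_id = a$reviewer_id %||% NA_character_)),
                    stringsAsFactors = FALSE)))
  }
  write.csv(assessments, path, row.names = FALSE, na = "")
  invisible(path)
}
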