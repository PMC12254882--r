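# XML batch export for gateway-style submission. The element list and
# order are defined by the schema shipped at inst/extdata/ae-batch.xsd;
# round-tripping a batch reproduces every report field exactly.

#' Deterministic reference number for a submitted report
#'
#' Reference numbers are the MD5 digest of the report's canonical JSON
#' serialization concatenated with the batch identifier, so resubmitting
#' identical content yields the same reference.
#'
#' @param report An [ae_report()].
#' @param batch_id Batch identifier string.
#' @return Uppercase 32-character hex string.
#' @export
reference_number <- function(report, batch_id) {
  payload <- jsonlite::toJSON(report_to_list(report), auto_unbox = TRUE,
                              null = "null", digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste0(batch_id, "|", payload), tmp)
  toupper(unname(tools::md5sum(tmp)))
}

xsd_path <- function() {
  system.file("extdata", "ae-batch.xsd", package = "vetgrade")
}

add_scalar <- function(parent, name, value) {
  if (is.null(value) || (length(value) == 1 && is.na(value))) {
    return(invisible())
  }
  node <- xml2::xml_add_child(parent, name)
  xml2::xml_text(node) <- if (is.logical(value)) {
    tolower(as.character(value))
  } else if (is.numeric(value)) {
    format(value, digits = 15, scientific = FALSE, trim = TRUE)
  } else as.character(value)
  invisible(node)
}

#' Export a report batch as XML
#'
#' Serializes validated reports into one batch document (fixed element
#' order, ISO 8601 dates, uppercase enum tokens, clinical notes embedded as
#' text with `window_tag` attributes) conforming to the schema shipped with
#' the package. Every report must pass the minimum reporting criteria; an
#' empty batch is an error.
#'
#' @param reports Non-empty list of valid [ae_report()] objects.
#' @param batch_id Batch identifier.
#' @param path Optional output file; when `NULL` the `xml_document` is
#'   returned without writing.
#' @param created_at Batch creation time (`POSIXct`).
#' @return The `xml_document`, invisibly when `path` is given.
#' @seealso [read_xml_batch()], [validate_xml_batch()]
#' @export
export_xml <- function(reports, batch_id, path = NULL,
                       created_at = as.POSIXct("2020-09-18 02:00:00",
                                               tz = "UTC")) {
  if (length(reports) == 0) stop("cannot export an empty batch",
                                 call. = FALSE)
  for (r in reports) {
    v <- validate_minimum_criteria(r)
    if (!v$is_valid) {
      stop(sprintf("report %s is not a valid AE report: %s", r$report_id,
                   paste(v$messages, collapse = "; ")), call. = FALSE)
    }
  }
  doc <- xml2::xml_new_root("ae_batch",
                            batch_id = as.character(batch_id),
                            created_at = format(created_at,
                                                "%Y-%m-%dT%H:%M:%SZ",
                                                tz = "UTC"))
  for (r in reports) {
    l <- report_to_list(r)
    rep_node <- xml2::xml_add_child(doc, "report",
                                    reference = reference_number(r, batch_id))
    for (f in c("report_id", "practice_id", "species", "breed",
                "date_of_birth", "age_years", "age_months", "sex",
                "neuter_status", "weight")) {
      add_scalar(rep_node, f, l[[f]])
    }
    drugs_node <- xml2::xml_add_child(rep_node, "suspect_drugs")
    for (d in l$suspect_drugs) {
      d_node <- xml2::xml_add_child(drugs_node, "drug")
      for (f in c("product_name", "marketing_auth_number", "batch_number",
                  "route", "start_date", "admin_duration",
                  "admin_duration_unit", "dosage_text", "administrator",
                  "is_vaccine_or_pipette")) {
        add_scalar(d_node, f, d[[f]])
      }
    }
    cp_node <- xml2::xml_add_child(rep_node, "concurrent_products")
    for (p in l$concurrent_products) add_scalar(cp_node, "product", p)
    for (f in c("reaction_date", "reaction_duration",
                "reaction_duration_unit", "fatal", "other_animals_text",
                "reaction_description")) {
      add_scalar(rep_node, f, l[[f]])
    }
    notes_node <- xml2::xml_add_child(rep_node, "clinical_notes")
    for (n in l$clinical_notes) {
      n_node <- xml2::xml_add_child(notes_node, "note",
                                    note_date = n$note_date,
                                    window_tag = n$window_tag)
      xml2::xml_text(n_node) <- n$text
    }
    for (f in c("submitted_to_manufacturer", "practice_postcode_area",
                "reporter_name", "reporter_email", "reporter_phone",
                "wants_copy", "submission_timestamp")) {
      add_scalar(rep_node, f, l[[f]])
    }
  }
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Validate a batch document against the shipped schema
#'
#' @param doc An `xml_document` or a path to an XML file.
#' @return Logical; attributes carry libxml2 messages on failure.
#' @export
validate_xml_batch <- function(doc) {
  if (is.character(doc)) doc <- xml2::read_xml(doc)
  xml2::xml_validate(doc, xml2::read_xml(xsd_path()))
}

xml_scalar <- function(node, name) {
  child <- xml2::xml_find_first(node, name)
  if (inherits(child, "xml_missing")) NULL else xml2::xml_text(child)
}

#' Read a report batch from XML
#'
#' Inverse of [export_xml()]: reconstructs the reports field-for-field.
#'
#' @param path Path to a batch XML file (or an `xml_document`).
#' @return List with `batch_id`, `created_at` (string) and `reports` (list
#'   of [ae_report()]).
#' @export
read_xml_batch <- function(path) {
  doc <- if (is.character(path)) xml2::read_xml(path) else path
  root <- xml2::xml_root(doc)
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  reports <- lapply(xml2::xml_find_all(root, "report"), function(rn) {
    drugs <- lapply(xml2::xml_find_all(rn, "suspect_drugs/drug"),
                    function(dn) drug_entry(
      product_name = xml_scalar(dn, "product_name"),
      marketing_auth_number = xml_scalar(dn, "marketing_auth_number"),
      batch_number = xml_scalar(dn, "batch_number"),
      route = xml_scalar(dn, "route"),
      start_date = xml_scalar(dn, "start_date"),
      admin_duration = num(xml_scalar(dn, "admin_duration")),
      admin_duration_unit = xml_scalar(dn, "admin_duration_unit"),
      dosage_text = xml_scalar(dn, "dosage_text"),
      administrator = xml_scalar(dn, "administrator"),
      is_vaccine_or_pipette = identical(
        xml_scalar(dn, "is_vaccine_or_pipette"), "true")))
    notes <- lapply(xml2::xml_find_all(rn, "clinical_notes/note"),
                    function(nn) clinical_note(
      xml2::xml_attr(nn, "note_date"), xml2::xml_text(nn),
      xml2::xml_attr(nn, "window_tag")))
    ae_report(
      report_id = xml_scalar(rn, "report_id"),
      practice_id = xml_scalar(rn, "practice_id") %||% "",
      species = xml_scalar(rn, "species"),
      breed = xml_scalar(rn, "breed"),
      date_of_birth = xml_scalar(rn, "date_of_birth"),
      age_years = num(xml_scalar(rn, "age_years")),
      age_months = num(xml_scalar(rn, "age_months")),
      sex = xml_scalar(rn, "sex"),
      neuter_status = xml_scalar(rn, "neuter_status"),
      weight = num(xml_scalar(rn, "weight")),
      suspect_drugs = drugs,
      concurrent_products = xml2::xml_text(
        xml2::xml_find_all(rn, "concurrent_products/product")),
      reaction_date = xml_scalar(rn, "reaction_date"),
      reaction_duration = num(xml_scalar(rn, "reaction_duration")),
      reaction_duration_unit = xml_scalar(rn, "reaction_duration_unit"),
      fatal = xml_scalar(rn, "fatal"),
      other_animals_text = xml_scalar(rn, "other_animals_text") %||% "",
      reaction_description = xml_scalar(rn, "reaction_description") %||% "",
      clinical_notes = notes,
      submitted_to_manufacturer = xml_scalar(rn, "submitted_to_manufacturer"),
      practice_postcode_area = xml_scalar(rn, "practice_postcode_area"),
      reporter_name = xml_scalar(rn, "reporter_name"),
      reporter_email = xml_scalar(rn, "reporter_email"),
      reporter_phone = xml_scalar(rn, "reporter_phone"),
      wants_copy = xml_scalar(rn, "wants_copy"),
      submission_timestamp = xml_scalar(rn, "submission_timestamp"))
  })
  list(batch_id = xml2::xml_attr(root, "batch_id"),
       created_at = xml2::xml_attr(root, "created_at"),
       reports = reports)
}
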