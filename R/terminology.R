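# Terminology coding: VeDDRA low-level terms, ATCvet first-level product
# groups, and expectedness against SPC listed events. Matching is exact
# after normalization (lowercase, trimmed, whitespace collapsed) -- no
# fuzzy matching, no synonym expansion.

#' Build terminology lookup tables
#'
#' Holds the three lookups used for coding: clinical-sign term to VeDDRA
#' low-level term (LLT) and system organ class (SOC); product or active
#' substance to ATCvet first-level group; and product to the set of event
#' terms listed in its Summary of Product Characteristics (SPC). Keys are
#' normalized (lowercase, trimmed, internal whitespace collapsed) and must
#' be unique after normalization. Any table may be empty.
#'
#' The package ships only small synthetic fixture tables
#' (`inst/extdata/*-synthetic.tsv`); real VeDDRA/ATCvet content is licensed
#' and must be supplied by the user as TSV via
#' [read_terminology_tables()].
#'
#' @param veddra Data frame with columns `term`, `llt_code`, `llt_name`,
#'   `soc`, or `NULL`.
#' @param atcvet Data frame with columns `product_or_substance`, `group`,
#'   or `NULL`.
#' @param spc Data frame with columns `product`, `listed_term` (one row per
#'   listed term), or `NULL`.
#' @return An object of class `terminology_tables`.
#' @export
terminology_tables <- function(veddra = NULL, atcvet = NULL, spc = NULL) {
  empty <- function(cols) {
    as.data.frame(setNames(rep(list(character()), length(cols)), cols))
  }
  veddra <- veddra %||% empty(c("term", "llt_code", "llt_name", "soc"))
  atcvet <- atcvet %||% empty(c("product_or_substance", "group"))
  spc <- spc %||% empty(c("product", "listed_term"))
  need <- function(df, cols, what) {
    if (!all(cols %in% names(df))) {
      stop(sprintf("%s table needs columns: %s", what,
                   paste(cols, collapse = ", ")), call. = FALSE)
    }
    df
  }
  veddra <- need(veddra, c("term", "llt_code", "llt_name", "soc"), "veddra")
  atcvet <- need(atcvet, c("product_or_substance", "group"), "atcvet")
  spc <- need(spc, c("product", "listed_term"), "spc")
  veddra$key <- norm_term(veddra$term)
  atcvet$key <- norm_term(atcvet$product_or_substance)
  spc$key <- norm_term(spc$product)
  spc$term_key <- norm_term(spc$listed_term)
  if (anyDuplicated(veddra$key)) {
    stop("veddra keys not unique after normalization", call. = FALSE)
  }
  if (anyDuplicated(atcvet$key)) {
    stop("atcvet keys not unique after normalization", call. = FALSE)
  }
  structure(list(veddra = veddra, atcvet = atcvet, spc = spc),
            class = "terminology_tables")
}

#' Read terminology lookup tables from TSV files
#'
#' @param veddra_path,atcvet_path,spc_path Paths to tab-separated files
#'   with the column layouts documented in [terminology_tables()]; any may
#'   be `NULL`.
#' @return A `terminology_tables` object.
#' @export
read_terminology_tables <- function(veddra_path = NULL, atcvet_path = NULL,
                                    spc_path = NULL) {
  rd <- function(p) {
    if (is.null(p)) return(NULL)
    read.delim(p, stringsAsFactors = FALSE, colClasses = "character")
  }
  terminology_tables(veddra = rd(veddra_path), atcvet = rd(atcvet_path),
                     spc = rd(spc_path))
}

#' Code clinical-sign terms to VeDDRA LLT and SOC
#'
#' Exact match after normalization; terms without a dictionary entry are
#' preserved with `UNMAPPED` markers (being unmapped is a value, not an
#' error).
#'
#' @param terms Character vector of clinical-sign terms.
#' @param tables A [terminology_tables()] object.
#' @return Data frame with columns `term`, `llt_code`, `llt_name`, `soc`.
#' @export
code_events <- function(terms, tables) {
  stopifnot(inherits(tables, "terminology_tables"))
  terms <- as.character(terms)
  idx <- match(norm_term(terms), tables$veddra$key)
  data.frame(
    term = terms,
    llt_code = ifelse(is.na(idx), "UNMAPPED", tables$veddra$llt_code[idx]),
    llt_name = ifelse(is.na(idx), "UNMAPPED", tables$veddra$llt_name[idx]),
    soc = ifelse(is.na(idx), "UNMAPPED", tables$veddra$soc[idx]),
    stringsAsFactors = FALSE
  )
}

#' Split a reaction description into clinical-sign terms
#'
#' Descriptions composed as sign lists ("vomiting; lethargy") are split on
#' semicolons and commas; terms are trimmed and empties dropped. This is a
#' deterministic tokenizer, not clinical NLP.
#'
#' @param text Character vector of descriptions.
#' @return List of character vectors, one per description.
#' @export
split_signs <- function(text) {
  lapply(as.character(text), function(x) {
    parts <- trimws(strsplit(x, "[;,]")[[1]])
    parts[nzchar(parts)]
  })
}

#' Enumerate drug-event pairs from a report corpus
#'
#' One pair per (report, suspect product): a report listing several suspect
#' products contributes several pairs, so the pair count equals the total
#' number of suspect products across the corpus. Each pair carries the
#' report's event terms (by default, [split_signs()] applied to the
#' reaction description; supply `events` to override, keyed by report_id).
#'
#' @param reports List of [ae_report()] objects.
#' @param events Optional named list mapping report_id to a character
#'   vector of event terms.
#' @return Data frame with columns `report_id`, `product_name` and a list
#'   column `event_terms`.
#' @export
enumerate_pairs <- function(reports, events = NULL) {
  rows <- lapply(reports, function(r) {
    terms <- if (!is.null(events)) events[[r$report_id]] %||% character()
             else split_signs(r$reaction_description)[[1]]
    lapply(r$suspect_drugs, function(d) {
      list(report_id = r$report_id, product_name = d$product_name,
           event_terms = terms)
    })
  })
  rows <- unlist(rows, recursive = FALSE)
  if (length(rows) == 0) {
    return(data.frame(report_id = character(), product_name = character(),
                      event_terms = I(list())))
  }
  data.frame(
    report_id = vapply(rows, `[[`, character(1), "report_id"),
    product_name = vapply(rows, `[[`, character(1), "product_name"),
    event_terms = I(lapply(rows, `[[`, "event_terms")),
    stringsAsFactors = FALSE
  )
}

#' Classify drug-event pairs as expected, unexpected or unassessable
#'
#' A pair is `EXPECTED` only if every one of its event terms is listed in
#' the product's SPC; `UNEXPECTED` if the product has an SPC entry but at
#' least one term is not listed; `UNASSESSABLE` if the product has no SPC
#' entry at all (or the pair carries no event terms).
#'
#' @param pairs Data frame from [enumerate_pairs()].
#' @param tables A [terminology_tables()] object.
#' @return `pairs` with an added character column `expectedness`.
#' @export
classify_expectedness <- function(pairs, tables) {
  stopifnot(inherits(tables, "terminology_tables"))
  spc_products <- unique(tables$spc$key)
  pairs$expectedness <- vapply(seq_len(nrow(pairs)), function(i) {
    pk <- norm_term(pairs$product_name[i])
    terms <- norm_term(pairs$event_terms[[i]])
    if (!(pk %in% spc_products) || length(terms) == 0) return("UNASSESSABLE")
    listed <- tables$spc$term_key[tables$spc$key == pk]
    if (all(terms %in% listed)) "EXPECTED" else "UNEXPECTED"
  }, character(1))
  pairs
}

#' Group drug-event pairs by ATCvet first-level group
#'
#' Counts pairs (overall frequency, not unique products) per first-level
#' group; products without an ATCvet mapping are counted under `Unknown`.
#' Percentages are of the total pair count.
#'
#' @param pairs Data frame from [enumerate_pairs()].
#' @param tables A [terminology_tables()] object.
#' @return Data frame with columns `group`, `count`, `percent`, sorted by
#'   descending count.
#' @export
group_products <- function(pairs, tables) {
  stopifnot(inherits(tables, "terminology_tables"))
  if (nrow(pairs) == 0) {
    return(data.frame(group = character(), count = integer(),
                      percent = numeric()))
  }
  idx <- match(norm_term(pairs$product_name), tables$atcvet$key)
  grp <- ifelse(is.na(idx), "Unknown", tables$atcvet$group[idx])
  tab <- sort(table(grp), decreasing = TRUE)
  data.frame(
    group = names(tab),
    count = as.integer(tab),
    percent = 100 * as.integer(tab) / nrow(pairs),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
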