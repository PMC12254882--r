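# In-code fixtures: a fully complete report scores 1.0 on every element
# (vaccine drug => dose exempt, attached note => additional complete).

complete_report <- function(id = "R1", ...) {
  defaults <- list(
    report_id = id,
    practice_id = "P001",
    species = "DOG",
    breed = "Labrador Retriever",
    age_years = 3L,
    age_months = 2L,
    sex = "MALE",
    neuter_status = "NEUTERED",
    weight = 24.5,
    suspect_drugs = list(drug_entry("Vaccamune DHP",
                                    start_date = "2020-10-01",
                                    administrator = "VET",
                                    is_vaccine_or_pipette = TRUE)),
    reaction_date = "2020-10-03",
    reaction_duration = 2,
    reaction_duration_unit = "DAYS",
    reaction_description = "vomiting; lethargy",
    clinical_notes = list(clinical_note("2020-10-03",
                                        "lethargic after vaccination")),
    submitted_to_manufacturer = "NO",
    wants_copy = "NO")
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(ae_report, defaults)
}

# minimal valid report leaving most optional elements penalized
minimal_report <- function(id = "M1", ...) {
  defaults <- list(
    report_id = id,
    practice_id = "P002",
    species = "CAT",
    suspect_drugs = list(drug_entry("Flexicam Oral")),
    reaction_description = "vomiting")
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(ae_report, defaults)
}

# independent exhaustive oracle for the two-sided exact signed-rank p-value:
# enumerate all 2^n sign assignments of the nonzero differences
signflip_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.numeric(signs %*% r)
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# whole-month difference oracle by linear search: the largest m such that
# date_of_birth shifted by m calendar months is not after the reference
# (birth days restricted to 1..28 keep month shifts unambiguous)
months_between_oracle <- function(dob, ref) {
  add_months <- function(d, m) {
    p <- as.POSIXlt(d)
    total <- p$year * 12 + p$mon + m
    as.Date(sprintf("%04d-%02d-%02d", total %/% 12 + 1900, total %% 12 + 1,
                    p$mday))
  }
  m <- 0
  while (add_months(dob, m + 1) <= ref) m <- m + 1
  m
}
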