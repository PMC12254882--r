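column	level	type	description
report_id	report	string	Opaque report identifier
practice_id	report	string	Unique practice identifier (reporter criterion)
species	report	enum	DOG, CAT, RABBIT, OTHER, HUMAN_FLAGGED, UNKNOWN
breed	report	string	Breed, free text or UNKNOWN; empty for human-flagged reports
date_of_birth	report	date	ISO 8601 date of birth, empty if unknown
age_years	report	integer	Transmitted whole-year age, empty if not transmitted
age_months	report	integer	Residual months (0-11); empty when not transmitted (a bare age of 0 with empty months is the penalized under-one-year case)
sex	report	enum	MALE, FEMALE, UNKNOWN
neuter_status	report	enum	NEUTERED, ENTIRE, UNKNOWN
weight	report	number	Weight in kg, empty if unknown
concurrent_products	report	string	Semicolon-joined concurrent product names
reaction_date	report	date	ISO 8601 date of the reaction
reaction_duration	report	number	Duration of the reaction; requires reaction_duration_unit
reaction_duration_unit	report	enum	HOURS, DAYS, WEEKS, MONTHS
fatal	report	enum	YES, NO, empty
other_animals_text	report	string	Details on other animals treated
reaction_description	report	string	Mandatory free-text description of the adverse event
submitted_to_manufacturer	report	enum	YES, NO
practice_postcode_area	report	string	Practice postcode area, empty if removed
reporter_name	report	string	Optional reporter contact name
reporter_email	report	string	Optional reporter email
reporter_phone	report	string	Optional reporter telephone
wants_copy	report	enum	YES, NO
submission_timestamp	report	datetime	ISO 8601 UTC submission time
drug_index	drug	integer	1-based position of the suspect drug within the report
product_name	drug	string	Suspect product name (mandatory)
marketing_auth_number	drug	string	Marketing authorization number, optional
batch_number	drug	string	Batch number, optional
route	drug	enum	Standardized route of administration, optional
start_date	drug	date	Drug start date, ISO 8601
admin_duration	drug	number	Duration of administration; requires admin_duration_unit
admin_duration_unit	drug	enum	HOURS, DAYS, WEEKS, MONTHS
dosage_text	drug	string	Free-text dosage details
administrator	drug	enum	VET, VET_NURSE, OWNER, OTHER, UNKNOWN
is_vaccine_or_pipette	drug	boolean	TRUE exempts the entry from the dose penalty
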