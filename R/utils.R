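`%||%` <- function(x, y) if (is.null(x)) y else x

# lowercase, trim, collapse internal whitespace -- the normalization used for
# terminology keys, product-list matching and placeholder detection
norm_term <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# descriptions that do not count as information (Table-2 style "blank, n/a, ...")
PLACEHOLDER_DESCRIPTIONS <- c("", "n/a", "na", "...", "-", "…")

is_placeholder_description <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x)) return(TRUE)
  norm_term(x) %in% PLACEHOLDER_DESCRIPTIONS
}

as_date_scalar <- function(x, field) {
  if (is.null(x) || (length(x) == 1 && is.na(x))) return(NULL)
  d <- tryCatch(as.Date(x), error = function(e) NA)
  if (length(d) != 1 || is.na(d)) {
    stop(sprintf("field '%s' is not a valid calendar date: %s", field,
                 paste(format(x), collapse = ", ")), call. = FALSE)
  }
  d
}

assert_enum <- function(x, levels, field, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(NULL)
    stop(sprintf("field '%s' is required", field), call. = FALSE)
  }
  x <- toupper(as.character(x))
  if (length(x) != 1 || !(x %in% levels)) {
    stop(sprintf("field '%s' must be one of %s", field,
                 paste(levels, collapse = ", ")), call. = FALSE)
  }
  x
}

assert_nonneg_scalar <- function(x, field, allow_null = TRUE) {
  if (is.null(x)) {
    if (allow_null) return(NULL)
    stop(sprintf("field '%s' is required", field), call. = FALSE)
  }
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0) {
    stop(sprintf("field '%s' must be a non-negative number", field),
         call. = FALSE)
  }
  as.numeric(x)
}

assert_probability <- function(x, field) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must be a probability in [0, 1]", field), call. = FALSE)
  }
  x
}

iso_date <- function(d) if (is.null(d)) NA_character_ else format(d, "%Y-%m-%d")

# seed stream split: an independent, reproducible sub-seed per unit so corpus
# prefixes are stable as n grows; kept below 2^31 - 1
derive_seed <- function(seed, index) {
  (as.double(seed) %% 2147483647 + index * 48271) %% 2147483629 + 1
}
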