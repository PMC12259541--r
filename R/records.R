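# Record table schema ---------------------------------------------------------

#' Host-record schema vocabularies
#'
#' Column names, controlled vocabularies and evidence flags of the host-record
#' table. One row of the table is one independent report of a parasite on a
#' host ("record"); repeated reports under new references are new records,
#' while suspected reiterations of an earlier report are excluded upstream by
#' the curator.
#'
#' @return `host_record_columns()` returns the full ordered character vector of
#'   column names; `evidence_flags()` the names of the logical evidence
#'   columns; `habit_levels()` and `record_type_levels()` the controlled
#'   vocabularies; `confidence_levels()` the three rating levels.
#' @export
host_record_columns <- function() {
  c(
    "record_id", "parasite_species", "parasite_genus", "parasite_family",
    "host_species", "host_genus", "host_family", "host_order",
    "host_habit", "region", "record_type", "reference_id", "confidence",
    evidence_flags()
  )
}

#' @rdname host_record_columns
#' @export
evidence_flags <- function() {
  c(
    "excavated_confirmed", "expert_report", "host_material_on_sheet",
    "photo_connection_visible", "photo_host_visible", "pre_1950",
    "excavation_explicit", "herbarium_host_named_no_material",
    "database_observation", "has_photo", "author_flags_dubious"
  )
}

#' @rdname host_record_columns
#' @export
habit_levels <- function() {
  c("annual_herb", "biennial_herb", "perennial_herb", "liana", "shrub",
    "tree", "unknown")
}

#' @rdname host_record_columns
#' @export
record_type_levels <- function() {
  c("protologue", "flora", "monograph", "article", "herbarium",
    "database_obs", "other")
}

#' @rdname host_record_columns
#' @export
confidence_levels <- function() c("low", "medium", "high")

# columns that must be present in an input file
required_record_columns <- function() {
  c("record_id", "parasite_species", "parasite_genus", "parasite_family",
    "host_family", "reference_id")
}

blank_to_na <- function(x) {
  x <- stringr::str_trim(as.character(x))
  ifelse(is.na(x) | x == "", NA_character_, x)
}

# Reading and writing ----------------------------------------------------------

#' Read a host-record table
#'
#' Reads a CSV or TSV of host records (delimiter auto-detected from the header
#' line), checks the schema, parses the controlled vocabularies and returns a
#' record tibble. Empty strings are treated as missing. Evidence flags may be
#' given as `TRUE`/`FALSE`/`1`/`0`/`yes`/`no`; a record whose evidence columns
#' are all missing carries no evidence and must supply `confidence` directly.
#'
#' @param path path to a CSV/TSV file with a header. Column order is free but
#'   names are fixed (see [host_record_columns()]); columns beyond the required
#'   set may be omitted and are filled as missing.
#' @param strict if `TRUE`, unknown habit / record-type / confidence strings
#'   are an error naming the offending row; if `FALSE` (default) unknown
#'   habits fall back to `"unknown"` and unknown record types to `"other"`,
#'   with a warning.
#' @return a record tibble with one row per record.
#' @export
read_host_records <- function(path, strict = FALSE) {
  if (!file.exists(path)) abort(paste0("record file not found: ", path))
  header <- readLines(path, n = 1L)
  delim <- if (stringr::str_count(header, "\t") >
               stringr::str_count(header, ",")) "\t" else ","
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, show_col_types = FALSE
  )
  names(raw) <- stringr::str_trim(names(raw))

  missing_cols <- setdiff(required_record_columns(), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("schema error: missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  unknown_cols <- setdiff(names(raw), host_record_columns())
  if (length(unknown_cols) > 0) {
    warn(paste0("ignoring unknown column(s): ",
                paste(unknown_cols, collapse = ", ")))
    raw <- raw[, intersect(names(raw), host_record_columns()), drop = FALSE]
  }
  for (col in setdiff(host_record_columns(), names(raw))) raw[[col]] <- NA_character_
  raw <- raw[, host_record_columns()]

  chr_cols <- setdiff(host_record_columns(), evidence_flags())
  rec <- raw |> mutate(across(all_of(chr_cols), blank_to_na))

  if (anyDuplicated(rec$record_id)) {
    dup <- unique(rec$record_id[duplicated(rec$record_id)])
    abort(paste0("integrity error: duplicate record_id: ",
                 paste(head(dup, 5), collapse = ", ")))
  }

  rec$host_habit <- parse_vocab(rec$host_habit, habit_levels(), "unknown",
                                "host_habit", strict)
  rec$record_type <- parse_vocab(rec$record_type, record_type_levels(), "other",
                                 "record_type", strict)
  bad_conf <- !is.na(rec$confidence) & !(rec$confidence %in% confidence_levels())
  if (any(bad_conf)) {
    abort(paste0("parse error: unknown confidence in row(s) ",
                 paste(which(bad_conf), collapse = ", ")))
  }
  for (fl in evidence_flags()) rec[[fl]] <- parse_flag(rec[[fl]], fl)
  as_tibble(rec)
}

parse_vocab <- function(x, levels, fallback, what, strict) {
  x0 <- ifelse(is.na(x), fallback, x)
  bad <- !(x0 %in% levels)
  if (any(bad)) {
    if (strict) {
      abort(paste0("parse error: unknown ", what, " ",
                   paste0("'", unique(x0[bad]), "'", collapse = ", "),
                   " in row(s) ", paste(which(bad), collapse = ", ")))
    }
    warn(paste0(sum(bad), " unknown ", what, " value(s) mapped to '",
                fallback, "': ", paste(unique(x0[bad]), collapse = ", ")))
    x0[bad] <- fallback
  }
  x0
}

parse_flag <- function(x, what) {
  if (is.logical(x)) return(x)
  x <- tolower(stringr::str_trim(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[x %in% c("false", "f", "0", "no", "n")] <- FALSE
  bad <- !is.na(x) & x != "" & is.na(out)
  if (any(bad)) {
    abort(paste0("parse error: non-boolean value for ", what, " in row(s) ",
                 paste(which(bad), collapse = ", ")))
  }
  out
}

#' Write a host-record table
#'
#' Inverse of [read_host_records()]: writes records as CSV with empty strings
#' for missing values, so that a read/write/read cycle round-trips
#' field-for-field.
#'
#' @param records a record tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_host_records <- function(records, path) {
  out <- records[, host_record_columns()]
  for (col in setdiff(names(out), evidence_flags())) {
    out[[col]] <- ifelse(is.na(out[[col]]), "", out[[col]])
  }
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

# Validation -------------------------------------------------------------------

#' Validate host records against the schema invariants
#'
#' Report-only check of every record-level invariant: required parasite fields
#' and host family non-empty, host species implies host genus, confidence
#' levels, record-id uniqueness, and internal consistency of the evidence
#' flags (a visible photo implies a photo exists; explicit excavation implies
#' confirmed excavation).
#'
#' @param records a record tibble.
#' @return a tibble with columns `record_id`, `rule`, `detail`; zero rows if
#'   and only if every invariant holds.
#' @export
validate_records <- function(records) {
  v <- list()
  bad_id <- is.na(records$record_id)
  v$missing_id <- tibble(record_id = records$record_id[bad_id],
                         rule = "record-id", detail = "record_id missing")
  dup <- records$record_id[duplicated(records$record_id) & !bad_id]
  v$dup <- tibble(record_id = unique(dup), rule = "unique-id",
                  detail = "record_id appears more than once")
  for (col in c("parasite_species", "parasite_genus", "parasite_family")) {
    bad <- is.na(records[[col]])
    v[[col]] <- tibble(record_id = records$record_id[bad],
                       rule = "parasite-fields",
                       detail = paste0(col, " missing"))
  }
  bad <- is.na(records$host_family)
  v$hf <- tibble(record_id = records$record_id[bad],
                 rule = "required-host-family", detail = "host_family missing")
  bad <- !is.na(records$host_species) & is.na(records$host_genus)
  v$sig <- tibble(record_id = records$record_id[bad],
                  rule = "species-implies-genus",
                  detail = "host_species set but host_genus missing")
  bad <- !is.na(records$confidence) &
    !(records$confidence %in% confidence_levels())
  v$conf <- tibble(record_id = records$record_id[bad],
                   rule = "confidence-level",
                   detail = "confidence not one of low/medium/high")
  imp <- list(
    c("photo_connection_visible", "has_photo"),
    c("photo_host_visible", "has_photo"),
    c("excavation_explicit", "excavated_confirmed")
  )
  for (pair in imp) {
    bad <- isTRUE_vec(records[[pair[1]]]) & !isTRUE_vec(records[[pair[2]]])
    v[[paste(pair, collapse = "-")]] <- tibble(
      record_id = records$record_id[bad], rule = "evidence-implication",
      detail = paste0(pair[1], " implies ", pair[2])
    )
  }
  bind_rows(v)
}

isTRUE_vec <- function(x) !is.na(x) & x

# Deduplication ----------------------------------------------------------------

#' Collapse exact duplicate records
#'
#' Removes exact duplicates on the key (parasite species, host species — or
#' host family when the host is not identified to species — and reference),
#' keeping the first occurrence. Records of the same parasite–host pair under
#' *different* references are independent reports and are never removed;
#' cross-reference repeats are only flagged as possible reiterations for
#' curator review.
#'
#' @param records a validated record tibble.
#' @return a list of class `host_dedup` with elements `records` (the collapsed
#'   tibble), `removed_record_ids`, and `flagged_reiterations` (a tibble of
#'   parasite/host pairs reported under more than one reference).
#' @export
deduplicate_records <- function(records) {
  host_key <- ifelse(is.na(records$host_species),
                     paste0("family:", records$host_family),
                     paste0("species:", records$host_species))
  key <- paste(records$parasite_species, host_key, records$reference_id,
               sep = "\r")
  keep <- !duplicated(key)
  pair <- paste(records$parasite_species, host_key, sep = "\r")
  flagged <- tibble(parasite_species = records$parasite_species[keep],
                    host = host_key[keep],
                    reference_id = records$reference_id[keep]) |>
    group_by(.data$parasite_species, .data$host) |>
    filter(n_distinct(.data$reference_id) > 1) |>
    summarise(n_references = n_distinct(.data$reference_id), .groups = "drop")
  structure(
    list(records = records[keep, , drop = FALSE],
         removed_record_ids = records$record_id[!keep],
         flagged_reiterations = flagged),
    class = "host_dedup"
  )
}

#' @export
print.host_dedup <- function(x, ...) {
  cat("<host_dedup> ", nrow(x$records), " records kept, ",
      length(x$removed_record_ids), " exact duplicates removed, ",
      nrow(x$flagged_reiterations),
      " parasite-host pairs flagged as possible reiterations\n", sep = "")
  invisible(x)
}

#' @export
glance.host_dedup <- function(x, ...) {
  tibble(n_kept = nrow(x$records),
         n_removed = length(x$removed_record_ids),
         n_flagged_pairs = nrow(x$flagged_reiterations))
}
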