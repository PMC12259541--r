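# Analysis-set construction: drop low-confidence records, then exclude
# parasite species supported by a single medium-confidence report unless a
# congeneric parasite has a high-confidence report from the same host family.

#' Drop low-confidence records
#'
#' @param records a fully rated record tibble.
#' @return the medium and high records, input order preserved.
#' @export
drop_low <- function(records) {
  if (nrow(records) > 0 && any(is.na(records$confidence))) {
    abort("unrated record(s) present; run apply_confidence() first")
  }
  records |> filter(.data$confidence != "low")
}

#' Exclude parasites known from a single medium-confidence report
#'
#' A parasite species whose entire record set is one medium-confidence report
#' is excluded — unless that report's host family also features in a
#' high-confidence report of at least one *other* parasite species in the
#' same parasite genus, in which case the species is kept and the rescue
#' logged. Input must already be free of low-confidence records.
#'
#' @param records a rated record tibble containing no low records.
#' @return a `host_filter` object: list with `kept` (record tibble),
#'   `removed_record_ids`, `removed_parasite_species`, and `rescue_log`
#'   (tibble of parasite species, host family, rescuing parasite species).
#' @export
single_medium_filter <- function(records) {
  if (nrow(records) > 0 && any(records$confidence == "low")) {
    abort("low-confidence record(s) present; run drop_low() first")
  }
  counts <- records |> count(.data$parasite_species, name = "n_records")
  singleton_sp <- counts$parasite_species[counts$n_records == 1L]
  cand <- records |>
    filter(.data$parasite_species %in% singleton_sp,
           .data$confidence == "medium")

  high <- records |>
    filter(.data$confidence == "high") |>
    distinct(.data$parasite_species, .data$parasite_genus, .data$host_family)

  rescue <- cand |>
    select("parasite_species", "parasite_genus", "host_family") |>
    dplyr::inner_join(high, by = c("parasite_genus", "host_family"),
                      suffix = c("", "_rescuer"),
                      relationship = "many-to-many") |>
    filter(.data$parasite_species != .data$parasite_species_rescuer) |>
    group_by(.data$parasite_species, .data$host_family) |>
    summarise(rescuing_parasite_species = first(.data$parasite_species_rescuer),
              .groups = "drop")

  removed <- cand |> filter(!(.data$parasite_species %in%
                                rescue$parasite_species))
  kept <- records |> filter(!(.data$record_id %in% removed$record_id))
  structure(
    list(kept = kept,
         removed_record_ids = removed$record_id,
         removed_parasite_species = unique(removed$parasite_species),
         rescue_log = rescue,
         n_low_dropped = 0L,
         n_input = nrow(records)),
    class = "host_filter"
  )
}

#' Build the analysis set
#'
#' Composition of [drop_low()] and [single_medium_filter()]: the `kept`
#' element is the analysis set consumed by all downstream statistics. The
#' operation is idempotent.
#'
#' @param records a fully rated record tibble.
#' @return a `host_filter` object (see [single_medium_filter()]); element
#'   `n_low_dropped` counts records removed as low-confidence and
#'   `n_input` the size of the input set.
#' @export
build_analysis_set <- function(records) {
  no_low <- drop_low(records)
  res <- single_medium_filter(no_low)
  res$n_low_dropped <- nrow(records) - nrow(no_low)
  res$n_input <- nrow(records)
  res
}

#' @export
print.host_filter <- function(x, ...) {
  cat("<host_filter> ", nrow(x$kept), " records kept of ", x$n_input,
      " rated inputs\n  low-confidence dropped: ", x$n_low_dropped,
      "\n  single-medium removals: ", length(x$removed_record_ids), " record(s), ",
      length(x$removed_parasite_species), " parasite species\n  rescues: ",
      nrow(x$rescue_log), "\n", sep = "")
  invisible(x)
}

#' @rdname single_medium_filter
#' @param x a `host_filter` object.
#' @param ... unused.
#' @export
tidy.host_filter <- function(x, ...) {
  bind_rows(
    tibble(parasite_species = x$removed_parasite_species,
           action = "removed", partner = NA_character_),
    tibble(parasite_species = x$rescue_log$parasite_species,
           action = "rescued",
           partner = x$rescue_log$rescuing_parasite_species)
  )
}

#' @rdname single_medium_filter
#' @export
glance.host_filter <- function(x, ...) {
  tibble(n_input = x$n_input,
         n_low_dropped = x$n_low_dropped,
         n_after_low = x$n_input - x$n_low_dropped,
         n_singleton_removed = length(x$removed_record_ids),
         n_parasites_removed = length(x$removed_parasite_species),
         n_rescued = nrow(x$rescue_log),
         n_kept = nrow(x$kept))
}
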