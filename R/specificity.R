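# Per-parasite host-specificity profiles at species, genus and family rank,
# lineage-level medians, and extreme specialist/generalist flags.

#' Host-specificity profiles for every parasite in an analysis set
#'
#' Counts unique host names at three taxonomic ranks per parasite species.
#' Hosts identified only to genus contribute to the genus and family counts
#' but not the species count; hosts identified only to family contribute to
#' the family count alone. Unidentified hosts never create phantom names.
#'
#' @param analysis_set a filtered record tibble (see [build_analysis_set()]).
#' @return a tibble with one row per parasite species: `parasite_species`,
#'   `parasite_genus`, `parasite_family`, `n_records`, `n_host_species`,
#'   `n_host_genera`, `n_host_families`.
#' @export
specificity_profiles <- function(analysis_set) {
  analysis_set |>
    group_by(.data$parasite_species, .data$parasite_genus,
             .data$parasite_family) |>
    summarise(
      n_records = n(),
      n_host_species = n_distinct(.data$host_species, na.rm = TRUE),
      n_host_genera = n_distinct(.data$host_genus, na.rm = TRUE),
      n_host_families = n_distinct(.data$host_family, na.rm = TRUE),
      .groups = "drop"
    ) |>
    arrange(.data$parasite_family, .data$parasite_species)
}

#' @rdname specificity_profiles
#' @param parasite_species a single parasite species present in the set.
#' @export
host_counts <- function(analysis_set, parasite_species) {
  sp <- parasite_species
  sub <- analysis_set |> filter(.data$parasite_species == sp)
  if (nrow(sub) == 0) {
    abort(paste0("parasite not found in analysis set: ", parasite_species))
  }
  specificity_profiles(sub)
}

#' Subset profiles to well-supported parasites
#'
#' Keeps a parasite if some host species has at least two records for it, or
#' if it has at least one high-confidence record. This is the subset used for
#' the specificity distributions and medians. The `"overall"` variant counts
#' two records of any host (not necessarily the same species) as sufficient;
#' the default `"same_species"` reading is the literal one.
#'
#' @param profiles output of [specificity_profiles()].
#' @param analysis_set the record tibble the profiles were computed from.
#' @param rule `"same_species"` (default) or `"overall"`.
#' @return the filtered profile tibble.
#' @export
subset_well_supported <- function(profiles, analysis_set,
                                  rule = c("same_species", "overall")) {
  rule <- match.arg(rule)
  high_sp <- analysis_set |>
    filter(.data$confidence == "high") |>
    dplyr::pull(.data$parasite_species) |> unique()
  if (rule == "same_species") {
    rep_sp <- analysis_set |>
      filter(!is.na(.data$host_species)) |>
      count(.data$parasite_species, .data$host_species) |>
      filter(.data$n >= 2) |>
      dplyr::pull(.data$parasite_species) |> unique()
  } else {
    rep_sp <- analysis_set |>
      count(.data$parasite_species) |>
      filter(.data$n >= 2) |>
      dplyr::pull(.data$parasite_species)
  }
  profiles |>
    filter(.data$parasite_species %in% c(rep_sp, high_sp))
}

#' Median host specificity per parasite lineage
#'
#' Standard medians (mean of the two central order statistics for even n) of
#' the three specificity counts, per parasite family and overall (row
#' `parasite_family == "all"`). Intended for profiles already passed through
#' [subset_well_supported()].
#'
#' @param profiles a profile tibble.
#' @return a tibble: `parasite_family`, `n_parasite_species_with_data`,
#'   `median_host_species`, `median_host_genera`, `median_host_families`.
#' @export
lineage_medians <- function(profiles) {
  if (nrow(profiles) == 0) {
    warn("no profiles; returning empty summary")
    return(tibble(parasite_family = character(),
                  n_parasite_species_with_data = integer(),
                  median_host_species = double(),
                  median_host_genera = double(),
                  median_host_families = double()))
  }
  per <- profiles |>
    group_by(.data$parasite_family) |>
    summarise(n_parasite_species_with_data = n(),
              median_host_species = median(.data$n_host_species),
              median_host_genera = median(.data$n_host_genera),
              median_host_families = median(.data$n_host_families),
              .groups = "drop")
  overall <- profiles |>
    summarise(parasite_family = "all",
              n_parasite_species_with_data = n(),
              median_host_species = median(.data$n_host_species),
              median_host_genera = median(.data$n_host_genera),
              median_host_families = median(.data$n_host_families))
  bind_rows(per, overall)
}

#' Flag extreme specialists and generalists
#'
#' An extreme specialist has a single exclusive host species, with every host
#' record identified to species, and that host either recorded at least twice
#' or backed by one high-confidence record (species with fewer than two
#' records of their sole host and no high-confidence backing are not
#' flagged). An extreme generalist has hosts from six or more families. The
#' two flags are mutually exclusive by construction.
#'
#' @param profiles a profile tibble.
#' @param analysis_set the record tibble the profiles were computed from.
#' @param generalist_min_families threshold on host families (default 6).
#' @return `profiles` with logical columns `is_extreme_specialist` and
#'   `is_extreme_generalist`.
#' @export
flag_extremes <- function(profiles, analysis_set, generalist_min_families = 6) {
  per_parasite <- analysis_set |>
    group_by(.data$parasite_species) |>
    summarise(
      all_identified = all(!is.na(.data$host_species)),
      any_high = any(.data$confidence == "high"),
      max_same_host = if (all(is.na(.data$host_species))) 0L else
        max(table(.data$host_species[!is.na(.data$host_species)])),
      .groups = "drop"
    )
  profiles |>
    left_join(per_parasite, by = "parasite_species") |>
    mutate(
      is_extreme_specialist = .data$n_host_species == 1L &
        .data$all_identified &
        (.data$max_same_host >= 2L | .data$any_high),
      is_extreme_generalist = .data$n_host_families >= generalist_min_families
    ) |>
    select(-"all_identified", -"any_high", -"max_same_host")
}
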