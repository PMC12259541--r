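# Host-side statistics: per-host-family parasite counts and convergence
# across independent parasite lineages, disproportionality relative to
# angiosperm diversity shares, major-clade partition, Asteraceae tribe
# breakdown, and host-habit summary.

#' Per-host-family parasite counts
#'
#' One row per host family appearing in at least one record, with the number
#' of distinct parasite species, parasite genera and parasite lineages
#' (parasite families) recorded on it. Multiple independent lineages on one
#' host family is the convergence signal.
#'
#' @param analysis_set a filtered record tibble.
#' @return a tibble sorted by decreasing parasite species count.
#' @export
host_family_summary <- function(analysis_set) {
  analysis_set |>
    filter(!is.na(.data$host_family)) |>
    group_by(host_family = .data$host_family) |>
    summarise(n_parasite_species = n_distinct(.data$parasite_species),
              n_parasite_genera = n_distinct(.data$parasite_genus),
              n_parasite_lineages = n_distinct(.data$parasite_family),
              .groups = "drop") |>
    arrange(dplyr::desc(.data$n_parasite_species), .data$host_family)
}

#' Host-family breadth of each parasite lineage
#'
#' @param analysis_set a filtered record tibble.
#' @return a tibble: `parasite_family`, `n_parasite_species` (species with
#'   data), `n_host_families` (distinct host families recorded).
#' @export
parasite_family_breadth <- function(analysis_set) {
  analysis_set |>
    group_by(parasite_family = .data$parasite_family) |>
    summarise(n_parasite_species = n_distinct(.data$parasite_species),
              n_host_families = n_distinct(.data$host_family, na.rm = TRUE),
              .groups = "drop") |>
    arrange(dplyr::desc(.data$n_host_families))
}

#' Disproportionality of parasitism relative to diversity share
#'
#' Ratio of the share of parasite species recorded on a group to the group's
#' share of angiosperm species diversity; values above 1 mark
#' over-parasitized groups. Groups without a diversity share get `NA`.
#'
#' @param summary a tibble with a grouping column (first column) and an
#'   `n_parasite_species` column, e.g. [host_family_summary()] output.
#' @param shares a tibble with columns `group` and `share` (fractions of
#'   angiosperm species diversity, each in (0, 1]).
#' @param total_parasite_species the denominator for the parasite share.
#' @return `summary` with added `parasite_share` and `disproportionality`.
#' @export
disproportionality <- function(summary, shares, total_parasite_species) {
  stopifnot(total_parasite_species > 0)
  if (any(shares$share <= 0 | shares$share > 1)) {
    abort("diversity shares must lie in (0, 1]")
  }
  key <- names(summary)[1]
  joined <- summary |>
    left_join(shares |> rename(!!key := "group"), by = key)
  joined |>
    mutate(parasite_share = .data$n_parasite_species / total_parasite_species,
           disproportionality = .data$parasite_share / .data$share) |>
    select(-"share")
}

#' Partition hosts by major clade
#'
#' Groups recorded host families by major clade (monocot, eudicot, other
#' angiosperm, gymnosperm, fern/lycopod) using a host-family to clade map.
#' Unmapped families are reported under clade `"unmapped"` and in the
#' `unmapped` attribute, never silently dropped.
#'
#' @param analysis_set a filtered record tibble.
#' @param clade_map a tibble with columns `host_family`, `clade`.
#' @return a tibble per clade: `n_host_families`, `n_parasite_species`;
#'   attribute `unmapped` lists unmapped host families.
#' @export
clade_partition <- function(analysis_set, clade_map) {
  joined <- analysis_set |>
    filter(!is.na(.data$host_family)) |>
    left_join(clade_map, by = "host_family")
  unmapped <- joined |> filter(is.na(.data$clade)) |>
    dplyr::pull(.data$host_family) |> unique()
  if (length(unmapped) > 0) {
    warn(paste0("host families missing from clade map: ",
                paste(unmapped, collapse = ", ")))
  }
  out <- joined |>
    mutate(clade = ifelse(is.na(.data$clade), "unmapped", .data$clade)) |>
    group_by(.data$clade) |>
    summarise(n_host_families = n_distinct(.data$host_family),
              n_parasite_species = n_distinct(.data$parasite_species),
              .groups = "drop")
  attr(out, "unmapped") <- unmapped
  out
}

#' Asteraceae tribe breakdown
#'
#' Groups Asteraceae-host records by the tribe of the host genus and counts
#' distinct parasite species and parasite families per tribe. Genera absent
#' from the tribe map are reported under `"unmapped"`.
#'
#' @param analysis_set a filtered record tibble.
#' @param tribe_map a tibble with columns `host_genus`, `tribe`.
#' @param family host family to break down (default `"Asteraceae"`).
#' @return a tibble: `tribe`, `n_parasite_species`, `n_parasite_families`.
#' @export
tribe_breakdown <- function(analysis_set, tribe_map, family = "Asteraceae") {
  sub <- analysis_set |> filter(.data$host_family == family)
  if (nrow(sub) == 0) {
    return(tibble(tribe = character(), n_parasite_species = integer(),
                  n_parasite_families = integer()))
  }
  joined <- sub |> left_join(tribe_map, by = "host_genus")
  unmapped <- joined |> filter(is.na(.data$tribe), !is.na(.data$host_genus)) |>
    dplyr::pull(.data$host_genus) |> unique()
  if (length(unmapped) > 0) {
    inform(paste0("host genera missing from tribe map: ",
                  paste(unmapped, collapse = ", ")))
  }
  joined |>
    mutate(tribe = ifelse(is.na(.data$tribe), "unmapped", .data$tribe)) |>
    group_by(.data$tribe) |>
    summarise(n_parasite_species = n_distinct(.data$parasite_species),
              n_parasite_families = n_distinct(.data$parasite_family),
              .groups = "drop") |>
    arrange(dplyr::desc(.data$n_parasite_species))
}

#' Host-habit summary
#'
#' Proportions of hosts per habit class. A host is a distinct host species
#' when identified; records whose host is not identified to species fall
#' back to a family-level host entry with habit `"unknown"`. Where a host
#' species is recorded under conflicting habits, the most frequent one wins
#' (ties broken alphabetically). Record-level counts are exported alongside.
#'
#' @param analysis_set a filtered record tibble.
#' @return a tibble per habit: `n_hosts`, `prop_hosts`, `n_records`,
#'   `prop_records`; both proportion columns sum to 1.
#' @export
habit_summary <- function(analysis_set) {
  if (nrow(analysis_set) == 0) {
    return(tibble(host_habit = character(), n_hosts = integer(),
                  prop_hosts = double(), n_records = integer(),
                  prop_records = double()))
  }
  units <- analysis_set |>
    mutate(
      host_unit = ifelse(is.na(.data$host_species),
                         paste0(.data$host_family, " (indet.)"),
                         .data$host_species),
      unit_habit = ifelse(is.na(.data$host_species), "unknown",
                          .data$host_habit)
    )
  per_host <- units |>
    count(.data$host_unit, .data$unit_habit) |>
    group_by(.data$host_unit) |>
    arrange(dplyr::desc(.data$n), .data$unit_habit, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    count(host_habit = .data$unit_habit, name = "n_hosts")
  per_record <- units |>
    count(host_habit = .data$unit_habit, name = "n_records")
  per_host |>
    full_join(per_record, by = "host_habit") |>
    mutate(n_hosts = tidyr::replace_na(.data$n_hosts, 0L),
           n_records = tidyr::replace_na(.data$n_records, 0L),
           prop_hosts = .data$n_hosts / sum(.data$n_hosts),
           prop_records = .data$n_records / sum(.data$n_records)) |>
    select("host_habit", "n_hosts", "prop_hosts", "n_records",
           "prop_records") |>
    arrange(dplyr::desc(.data$n_hosts))
}
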