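# Synthetic host-record databases with known ground truth. The generator
# emulates the structure of a curated holoparasite host-preference database:
# several independent parasite lineages, right-skewed per-species host ranges
# with rare multi-family generalists, hosts nested in a species < genus <
# family < clade taxonomy with strong within-genus clustering, a
# low/medium/high confidence mixture realised through evidence flags that
# each trigger exactly one classification rule, and per-parasite occurrence
# point clouds drawn uniformly in a geographic disc.

#' Configuration for the synthetic record generator
#'
#' Defaults emulate the scale and shape of the curated holoparasite
#' database: nine independent lineages, a zero-truncated negative-binomial
#' host range (mean 5, right-skewed) with ~3.5 % multi-family generalists,
#' a confidence mixture matching the curated low/medium/high proportions,
#' and hosts drawn overwhelmingly from eudicot families.
#'
#' @param seed integer seed; all randomness flows from it.
#' @param n_lineages number of parasite lineages (families), at most 9.
#' @param genera_per_lineage,species_per_genus parasite taxonomy shape.
#' @param host_clades named integer vector: families per host clade.
#' @param host_genera_per_family,host_species_per_genus host taxonomy shape.
#' @param clade_weights relative sampling weight of each host clade.
#' @param host_range_mean,host_range_dispersion zero-truncated negative
#'   binomial parameters for the number of host species per parasite.
#' @param p_generalist probability of the generalist branch (hosts drawn
#'   from at least `generalist_min_families` families).
#' @param generalist_min_families family threshold for generalists.
#' @param p_second_family probability a clustered (non-generalist) host set
#'   spills one species into a second family.
#' @param records_per_interaction_mean mean records per parasite-host pair
#'   (1 + Poisson).
#' @param confidence_mixture probabilities of low/medium/high labels; must
#'   sum to 1.
#' @param p_host_identified_to_species,p_host_identified_to_genus
#'   probability a record identifies its host to species rank; failing
#'   that, to genus rank (the remainder is family-rank only).
#' @param habit_distribution named probabilities over habit classes.
#' @param region_pool TDWG Level-2 codes records are assigned to.
#' @param n_occurrence_points occurrence points per parasite.
#' @param range_radius_km length-2 range (min, max) of the true range-disc
#'   radius.
#' @return a validated config list of class `host_synth_config`.
#' @export
synthetic_config <- function(
    seed = 1L,
    n_lineages = 9L,
    genera_per_lineage = 5L,
    species_per_genus = 8L,
    host_clades = c(eudicot = 60L, monocot = 15L, gymnosperm = 3L),
    host_genera_per_family = 4L,
    host_species_per_genus = 5L,
    clade_weights = c(eudicot = 1, monocot = 0.02, gymnosperm = 0.01),
    host_range_mean = 5,
    host_range_dispersion = 1.2,
    p_generalist = 0.035,
    generalist_min_families = 6L,
    p_second_family = 0.15,
    records_per_interaction_mean = 1.8,
    confidence_mixture = c(low = 0.033, medium = 0.7274, high = 0.2396),
    p_host_identified_to_species = 0.9,
    p_host_identified_to_genus = 0.08,
    habit_distribution = c(shrub = 0.36, perennial_herb = 0.31, tree = 0.16,
                           annual_herb = 0.08, liana = 0.03,
                           biennial_herb = 0.02, unknown = 0.04),
    region_pool = c("12", "13", "14", "20", "27", "33", "34", "36", "42",
                    "50", "76", "79", "85"),
    n_occurrence_points = 40L,
    range_radius_km = c(50, 1000)) {
  cfg <- list(
    seed = as.integer(seed), n_lineages = n_lineages,
    genera_per_lineage = genera_per_lineage,
    species_per_genus = species_per_genus, host_clades = host_clades,
    host_genera_per_family = host_genera_per_family,
    host_species_per_genus = host_species_per_genus,
    clade_weights = clade_weights, host_range_mean = host_range_mean,
    host_range_dispersion = host_range_dispersion,
    p_generalist = p_generalist,
    generalist_min_families = generalist_min_families,
    p_second_family = p_second_family,
    records_per_interaction_mean = records_per_interaction_mean,
    confidence_mixture = confidence_mixture,
    p_host_identified_to_species = p_host_identified_to_species,
    p_host_identified_to_genus = p_host_identified_to_genus,
    habit_distribution = habit_distribution, region_pool = region_pool,
    n_occurrence_points = n_occurrence_points,
    range_radius_km = range_radius_km
  )
  validate_synth_config(cfg)
  structure(cfg, class = "host_synth_config")
}

holoparasite_lineages <- function() {
  c("Orobanchaceae", "Balanophoraceae", "Hydnoraceae", "Cytinaceae",
    "Apodanthaceae", "Mitrastemonaceae", "Rafflesiaceae", "Cynomoriaceae",
    "Lennooideae")
}

validate_synth_config <- function(cfg) {
  probs <- c(cfg$p_generalist, cfg$p_second_family,
             cfg$p_host_identified_to_species, cfg$p_host_identified_to_genus,
             cfg$confidence_mixture, cfg$habit_distribution)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (abs(sum(cfg$confidence_mixture) - 1) > 1e-8) {
    abort("confidence_mixture must sum to 1")
  }
  if (abs(sum(cfg$habit_distribution) - 1) > 1e-8) {
    abort("habit_distribution must sum to 1")
  }
  counts <- c(cfg$n_lineages, cfg$genera_per_lineage, cfg$species_per_genus,
              cfg$host_clades, cfg$host_genera_per_family,
              cfg$host_species_per_genus, cfg$n_occurrence_points)
  if (any(counts < 1)) abort("all counts must be >= 1")
  if (cfg$n_lineages > 9) abort("at most nine holoparasite lineages exist")
  if (!all(names(cfg$host_clades) %in% names(cfg$clade_weights))) {
    abort("clade_weights must cover every clade in host_clades")
  }
  if (cfg$p_generalist > 0 &&
      sum(cfg$host_clades) < cfg$generalist_min_families) {
    abort("infeasible config: fewer host families than generalist threshold")
  }
  n_hosts <- sum(cfg$host_clades) * cfg$host_genera_per_family *
    cfg$host_species_per_genus
  if (cfg$host_range_mean > n_hosts) {
    abort("infeasible config: host range larger than host pool")
  }
  invisible(cfg)
}

# nested host taxonomy; families grouped into orders of three within a clade
synth_host_taxonomy <- function(cfg) {
  purrr::imap(cfg$host_clades, function(nfam, clade) {
    pre <- toupper(substr(clade, 1, 1))
    fam <- sprintf("%sfam%02d", pre, seq_len(nfam))
    ord <- sprintf("%sord%02d", pre, (seq_len(nfam) - 1) %/% 3 + 1)
    tidyr::expand_grid(
      host_family = fam,
      genus_i = seq_len(cfg$host_genera_per_family),
      sp_i = seq_len(cfg$host_species_per_genus)
    ) |>
      mutate(clade = clade,
             host_order = ord[match(.data$host_family, fam)],
             host_genus = paste0(.data$host_family, "gen", .data$genus_i),
             host_species = paste(.data$host_genus,
                                  paste0("sp", .data$sp_i))) |>
      select("clade", "host_order", "host_family", "host_genus",
             "host_species")
  }) |> bind_rows()
}

rztnbinom <- function(n, mu, size) {
  p0 <- pnbinom(0, mu = mu, size = size)
  qnbinom(runif(n, min = p0, max = 1), mu = mu, size = size)
}

# draw one parasite's true host set from the taxonomy
draw_host_set <- function(cfg, taxonomy, fam_weights) {
  fams <- unique(taxonomy$host_family)
  if (runif(1) < cfg$p_generalist) {
    fam_range <- seq(cfg$generalist_min_families,
                     min(cfg$generalist_min_families + 4, length(fams)))
    n_fam <- fam_range[sample.int(length(fam_range), 1)]
    chosen_f <- sample(fams, n_fam, prob = fam_weights[fams])
    purrr::map(chosen_f, function(f) {
      pool <- taxonomy |> filter(.data$host_family == f)
      pool[sample(nrow(pool), sample(1:2, 1)), ]
    }) |> bind_rows()
  } else {
    k <- rztnbinom(1, cfg$host_range_mean, cfg$host_range_dispersion)
    if (k > nrow(taxonomy)) {
      abort("infeasible config: host range larger than host pool")
    }
    f1 <- sample(fams, 1, prob = fam_weights[fams])
    pool <- taxonomy |> filter(.data$host_family == f1)
    # cluster within few genera of the focal family
    genera <- unique(pool$host_genus)
    n_gen <- min(1 + rpois(1, 0.6), length(genera))
    pool <- pool |> filter(.data$host_genus %in% sample(genera, n_gen))
    take <- min(k, nrow(pool))
    hosts <- pool[sample(nrow(pool), take), ]
    if (take < k) {   # focal genera exhausted: widen to the family
      rest <- taxonomy |> filter(.data$host_family == f1) |>
        anti_join(hosts, by = "host_species")
      extra <- min(k - take, nrow(rest))
      hosts <- bind_rows(hosts, rest[sample(nrow(rest), extra), ])
    }
    if (nrow(hosts) >= 3 && runif(1) < cfg$p_second_family) {
      f2 <- sample(setdiff(fams, f1), 1)
      pool2 <- taxonomy |> filter(.data$host_family == f2)
      hosts <- bind_rows(hosts[-1, ], pool2[sample(nrow(pool2), 1), ])
    }
    hosts
  }
}

# evidence flags such that exactly one classification rule fires
evidence_for_label <- function(label) {
  ev <- setNames(as.list(rep(FALSE, length(evidence_flags()))),
                 evidence_flags())
  if (label == "high") {
    ev$excavated_confirmed <- TRUE          # H1
  } else if (label == "medium") {
    ev$herbarium_host_named_no_material <- TRUE   # M3
  } else {
    ev$author_flags_dubious <- TRUE         # L1 via dubious-flag dominance
  }
  ev
}

#' Generate a synthetic host-record database with ground truth
#'
#' Deterministic for a fixed config (the seed covers every random draw).
#' Per parasite species, a true host set is drawn (zero-truncated negative
#' binomial size with within-genus clustering, or the generalist branch),
#' records are emitted per parasite-host interaction with evidence flags
#' consistent with the drawn confidence label, and occurrence points are
#' sampled uniformly in the species' true range disc.
#'
#' @param cfg a [synthetic_config()].
#' @return a list of class `host_synth`: `records` (schema tibble, passes
#'   [validate_records()] by construction), `occurrences`, and `truth`
#'   (list with `parasites`, `record_labels`, `host_taxonomy`).
#' @export
generate_host_data <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "host_synth_config"))
  withr::local_seed(cfg$seed)
  taxonomy <- synth_host_taxonomy(cfg)
  fam_clade <- taxonomy |> distinct(.data$host_family, .data$clade)
  fam_weights <- setNames(cfg$clade_weights[fam_clade$clade],
                          fam_clade$host_family)
  habit_pool <- names(cfg$habit_distribution)
  host_habits <- setNames(
    sample(habit_pool, n_distinct(taxonomy$host_species), replace = TRUE,
           prob = cfg$habit_distribution),
    unique(taxonomy$host_species)
  )

  lineages <- holoparasite_lineages()[seq_len(cfg$n_lineages)]
  parasites <- tidyr::expand_grid(
    parasite_family = lineages,
    gen_i = seq_len(cfg$genera_per_lineage),
    sp_i = seq_len(cfg$species_per_genus)
  ) |>
    mutate(
      parasite_genus = paste0(substr(.data$parasite_family, 1, 4), "genus",
                              .data$gen_i),
      parasite_species = paste0(.data$parasite_genus, " species", .data$sp_i)
    ) |>
    select("parasite_family", "parasite_genus", "parasite_species")

  rec_rows <- list()
  truth_rows <- list()
  occ_rows <- list()
  rec_i <- 0L
  for (i in seq_len(nrow(parasites))) {
    p <- parasites[i, ]
    hosts <- draw_host_set(cfg, taxonomy, fam_weights)
    n_rec_per <- 1L + rpois(nrow(hosts),
                            max(cfg$records_per_interaction_mean - 1, 0))
    labels <- sample(names(cfg$confidence_mixture), sum(n_rec_per),
                     replace = TRUE, prob = cfg$confidence_mixture)
    hrep <- hosts[rep(seq_len(nrow(hosts)), n_rec_per), ]
    id_rank <- sample(c("species", "genus", "family"), nrow(hrep),
                      replace = TRUE,
                      prob = c(cfg$p_host_identified_to_species,
                               cfg$p_host_identified_to_genus,
                               1 - cfg$p_host_identified_to_species -
                                 cfg$p_host_identified_to_genus))
    ev <- bind_rows(lapply(labels, evidence_for_label))
    ids <- sprintf("r%06d", rec_i + seq_len(nrow(hrep)))
    rec_i <- rec_i + nrow(hrep)
    rec_rows[[i]] <- bind_cols(
      tibble(
        record_id = ids,
        parasite_species = p$parasite_species,
        parasite_genus = p$parasite_genus,
        parasite_family = p$parasite_family,
        host_species = ifelse(id_rank == "species", hrep$host_species,
                              NA_character_),
        host_genus = ifelse(id_rank %in% c("species", "genus"),
                            hrep$host_genus, NA_character_),
        host_family = hrep$host_family,
        host_order = hrep$host_order,
        host_habit = ifelse(id_rank == "species",
                            unname(host_habits[hrep$host_species]),
                            "unknown"),
        region = sample(cfg$region_pool, nrow(hrep), replace = TRUE),
        record_type = dplyr::case_match(labels, "high" ~ "article",
                                        "medium" ~ "herbarium",
                                        "low" ~ "flora"),
        reference_id = paste0("ref", ids),
        confidence = NA_character_
      ),
      ev
    )
    truth_rows[[i]] <- p |> mutate(
      n_true_host_species = n_distinct(hosts$host_species),
      n_true_host_genera = n_distinct(hosts$host_genus),
      n_true_host_families = n_distinct(hosts$host_family),
      true_specialist = .data$n_true_host_species == 1L,
      true_generalist = .data$n_true_host_families >=
        cfg$generalist_min_families,
      centre_lon = runif(1, -180, 180),
      centre_lat = runif(1, -60, 60),
      radius_km = runif(1, cfg$range_radius_km[1], cfg$range_radius_km[2]),
      true_area_km2 = 2 * pi * .earth_radius_km^2 *
        (1 - cos(.data$radius_km / .earth_radius_km))
    )
    occ_rows[[i]] <- disc_points(truth_rows[[i]], cfg$n_occurrence_points)
  }
  records <- bind_rows(rec_rows)
  truth <- bind_rows(truth_rows)
  structure(
    list(
      records = records,
      occurrences = bind_rows(occ_rows),
      truth = list(
        parasites = truth,
        record_labels = tibble(
          record_id = records$record_id,
          true_confidence = dplyr::case_match(records$record_type,
                                              "article" ~ "high",
                                              "herbarium" ~ "medium",
                                              "flora" ~ "low")
        ),
        host_taxonomy = taxonomy
      ),
      config = cfg
    ),
    class = "host_synth"
  )
}

# uniform points in a spherical disc around the parasite's range centre
disc_points <- function(truth_row, n) {
  delta <- truth_row$radius_km * sqrt(runif(n)) / .earth_radius_km
  theta <- runif(n, 0, 2 * pi)
  phi1 <- truth_row$centre_lat * pi / 180
  lam1 <- truth_row$centre_lon * pi / 180
  phi2 <- asin(sin(phi1) * cos(delta) + cos(phi1) * sin(delta) * cos(theta))
  lam2 <- lam1 + atan2(sin(theta) * sin(delta) * cos(phi1),
                       cos(delta) - sin(phi1) * sin(phi2))
  lon <- ((lam2 * 180 / pi + 180) %% 360) - 180
  tibble(parasite_species = truth_row$parasite_species,
         longitude = lon, latitude = phi2 * 180 / pi)
}

#' @export
print.host_synth <- function(x, ...) {
  cat("<host_synth> ", nrow(x$records), " records for ",
      nrow(x$truth$parasites), " parasite species (seed ",
      x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Parameter-recovery report for a synthetic dataset
#'
#' Compares pipeline outputs computed from a generated dataset against its
#' ground truth: overall median host-range recovery error,
#' specialist/generalist precision and recall, the fraction of records whose
#' engine rating equals the generating confidence label, and the relative
#' error of the convex-hull extent of occurrence against the true disc area.
#'
#' @param synth a `host_synth` from [generate_host_data()].
#' @param profiles flagged profiles ([flag_extremes()] output) computed from
#'   the synthetic records; optional.
#' @param rated_records [apply_confidence()] output on the synthetic records;
#'   optional.
#' @param eoo [eoo_table()] output on the synthetic occurrences; optional.
#' @return a one-row tibble of recovery metrics (`NA` for omitted inputs).
#' @export
recovery_report <- function(synth, profiles = NULL, rated_records = NULL,
                            eoo = NULL) {
  stopifnot(inherits(synth, "host_synth"))
  truth <- synth$truth$parasites
  out <- tibble(
    n_parasites = nrow(truth),
    true_median_host_species = median(truth$n_true_host_species),
    recovered_median_host_species = NA_real_,
    median_recovery_error = NA_real_,
    specialist_precision = NA_real_, specialist_recall = NA_real_,
    generalist_precision = NA_real_, generalist_recall = NA_real_,
    confidence_agreement = NA_real_,
    eoo_median_relative_error = NA_real_,
    eoo_all_within_true_disc = NA
  )
  if (!is.null(profiles)) {
    if (!all(profiles$parasite_species %in% truth$parasite_species)) {
      abort("mismatched parasite ids between profiles and truth")
    }
    j <- left_join(truth, profiles, by = "parasite_species")
    out$recovered_median_host_species <-
      median(j$n_host_species, na.rm = TRUE)
    out$median_recovery_error <- out$recovered_median_host_species -
      out$true_median_host_species
    if (all(c("is_extreme_specialist", "is_extreme_generalist") %in%
            names(j))) {
      sp <- pr(j$is_extreme_specialist, j$true_specialist)
      ge <- pr(j$is_extreme_generalist, j$true_generalist)
      out$specialist_precision <- unname(sp["precision"])
      out$specialist_recall <- unname(sp["recall"])
      out$generalist_precision <- unname(ge["precision"])
      out$generalist_recall <- unname(ge["recall"])
    }
  }
  if (!is.null(rated_records)) {
    j <- left_join(synth$truth$record_labels,
                   rated_records[, c("record_id", "confidence")],
                   by = "record_id")
    if (any(is.na(j$confidence))) {
      abort("mismatched record ids between rated records and truth")
    }
    out$confidence_agreement <- mean(j$confidence == j$true_confidence)
  }
  if (!is.null(eoo)) {
    j <- dplyr::inner_join(eoo, truth, by = "parasite_species")
    if (nrow(j) == 0) abort("mismatched parasite ids between EOO and truth")
    out$eoo_median_relative_error <-
      median((j$area_km2 - j$true_area_km2) / j$true_area_km2)
    out$eoo_all_within_true_disc <- all(j$area_km2 <= j$true_area_km2 + 1e-6)
  }
  out
}

pr <- function(pred, truth) {
  pred <- isTRUE_vec(pred); truth <- isTRUE_vec(truth)
  c(precision = if (sum(pred) == 0) NA_real_ else
      sum(pred & truth) / sum(pred),
    recall = if (sum(truth) == 0) NA_real_ else
      sum(pred & truth) / sum(truth))
}
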