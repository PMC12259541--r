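# Fixtures are built in code: a single-record constructor with sensible
# defaults, small toy sets, and an independent spherical-excess area oracle.

false_evidence <- function() {
  stats::setNames(as.list(rep(FALSE, length(evidence_flags()))),
                  evidence_flags())
}

# one host record as a one-row tibble; evidence flags default to FALSE and
# are overridden via ...
make_record <- function(record_id = "r1",
                        parasite_species = "Para alpha",
                        parasite_genus = "Para",
                        parasite_family = "Orobanchaceae",
                        host_species = "Hosta una",
                        host_genus = "Hosta",
                        host_family = "Fam1",
                        host_order = "Ord1",
                        host_habit = "shrub",
                        region = "12",
                        record_type = "article",
                        reference_id = "ref1",
                        confidence = NA_character_,
                        ...) {
  ev <- utils::modifyList(false_evidence(), list(...))
  dplyr::bind_cols(
    tibble::tibble(
      record_id = record_id, parasite_species = parasite_species,
      parasite_genus = parasite_genus, parasite_family = parasite_family,
      host_species = host_species, host_genus = host_genus,
      host_family = host_family, host_order = host_order,
      host_habit = host_habit, region = region, record_type = record_type,
      reference_id = reference_id, confidence = confidence
    ),
    tibble::as_tibble(ev)
  )
}

# n records in one call; vectorised over the named arguments
make_records <- function(...) {
  args <- list(...)
  n <- max(vapply(args, length, integer(1)))
  rows <- lapply(seq_len(n), function(i) {
    one <- lapply(args, function(a) a[[((i - 1) %% length(a)) + 1]])
    if (!("record_id" %in% names(one))) one$record_id <- paste0("r", i)
    do.call(make_record, one)
  })
  dplyr::bind_rows(rows)
}

# Independent extent-of-occurrence oracle: convex hull on raw lon/lat, fan
# triangulation, spherical excess per triangle by l'Huilier on the authalic
# sphere. Valid for convex polygons of modest extent (<= ~10 degrees), which
# is what the property tests use.
oracle_spherical_area <- function(lon, lat) {
  R <- 6371.0071809
  hull <- grDevices::chull(lon, lat)
  lon <- lon[hull]; lat <- lat[hull]
  if (length(lon) < 3) return(0)
  to_xyz <- function(lon, lat) {
    rad <- pi / 180
    cbind(cos(lat * rad) * cos(lon * rad),
          cos(lat * rad) * sin(lon * rad),
          sin(lat * rad))
  }
  v <- to_xyz(lon, lat)
  ang <- function(a, b) acos(pmin(1, pmax(-1, sum(a * b))))
  tri_excess <- function(a, b, c) {
    s1 <- ang(a, b); s2 <- ang(b, c); s3 <- ang(c, a)
    s <- (s1 + s2 + s3) / 2
    t <- tan(s / 2) * tan((s - s1) / 2) * tan((s - s2) / 2) *
      tan((s - s3) / 2)
    4 * atan(sqrt(max(t, 0)))
  }
  ex <- 0
  for (i in 2:(length(lon) - 1)) {
    ex <- ex + tri_excess(v[1, ], v[i, ], v[i + 1, ])
  }
  R^2 * ex
}

# small synthetic config for fast property tests
small_synth_config <- function(seed, ...) {
  defaults <- list(
    seed = seed, n_lineages = 4L, genera_per_lineage = 3L,
    species_per_genus = 4L, host_clades = c(eudicot = 20L, monocot = 5L),
    clade_weights = c(eudicot = 1, monocot = 0.05),
    n_occurrence_points = 15L
  )
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

rate_and_filter <- function(records) {
  rated <- suppressWarnings(apply_confidence(records))
  build_analysis_set(rated)
}

conf_rank <- function(x) match(x, c("low", "medium", "high"))
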