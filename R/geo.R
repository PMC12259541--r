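# Extent of occurrence (EOO): minimum convex polygon area of a species'
# occurrence points. Points are projected with a Lambert azimuthal equal-area
# projection on the authalic sphere, centred on the point centroid, and the
# planar hull area is returned in km^2. Antimeridian-spanning clouds are
# handled by the longitude rotation implicit in centring the projection.

# WGS84 authalic sphere radius, km
.earth_radius_km <- 6371.0071809

#' Extent of occurrence of one point set
#'
#' Projects occurrence points with a Lambert azimuthal equal-area projection
#' centred on their centroid, takes the planar convex hull and returns its
#' area in square kilometres. Fewer than three distinct non-collinear points
#' give area 0 with the `degenerate` flag set. The area is invariant to point
#' order and duplication.
#'
#' @param points a data frame with numeric columns `longitude` and `latitude`
#'   in decimal degrees (Darwin-Core `decimalLongitude`/`decimalLatitude`
#'   also accepted), or a two-column matrix (lon, lat).
#' @return a one-row tibble: `n_points`, `area_km2`, `degenerate`.
#' @export
eoo_area <- function(points) {
  pts <- normalise_points(points)
  if (nrow(pts) == 0) abort("empty point list")
  bad <- which(abs(pts$longitude) > 180 | abs(pts$latitude) > 90 |
                 is.na(pts$longitude) | is.na(pts$latitude))
  if (length(bad) > 0) {
    abort(paste0("coordinate out of bounds at point(s) ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  n_points <- nrow(pts)
  pts <- distinct(pts)
  if (nrow(pts) < 3) {
    return(tibble(n_points = n_points, area_km2 = 0, degenerate = TRUE))
  }
  xy <- laea_project(pts$longitude, pts$latitude)
  hull <- grDevices::chull(xy)
  area <- polygon_area(xy[hull, 1], xy[hull, 2])
  tibble(n_points = n_points, area_km2 = area,
         degenerate = area == 0)
}

normalise_points <- function(points) {
  if (is.matrix(points)) {
    points <- tibble(longitude = points[, 1], latitude = points[, 2])
  }
  nm <- names(points)
  lon <- nm[nm %in% c("longitude", "decimalLongitude", "lon")][1]
  lat <- nm[nm %in% c("latitude", "decimalLatitude", "lat")][1]
  if (is.na(lon) || is.na(lat)) {
    abort("points need longitude/latitude (or decimalLongitude/decimalLatitude) columns")
  }
  tibble(longitude = as.numeric(points[[lon]]),
         latitude = as.numeric(points[[lat]]))
}

# Lambert azimuthal equal-area about the circular-mean longitude and mean
# latitude of the (distinct) points; returns km coordinates
laea_project <- function(lon, lat) {
  rad <- pi / 180
  lam <- lon * rad
  phi <- lat * rad
  lam0 <- atan2(mean(sin(lam)), mean(cos(lam)))   # antimeridian-safe centre
  phi0 <- mean(phi)
  dl <- lam - lam0
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(dl)
  k <- sqrt(2 / denom)
  x <- .earth_radius_km * k * cos(phi) * sin(dl)
  y <- .earth_radius_km * k *
    (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(dl))
  cbind(x, y)
}

# shoelace, absolute value
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Extent of occurrence per species
#'
#' @param occurrences a tibble with columns `parasite_species` (or `species`)
#'   and coordinate columns as in [eoo_area()].
#' @return a tibble with one row per species: `parasite_species`, `n_points`,
#'   `area_km2`, `degenerate`.
#' @export
eoo_table <- function(occurrences) {
  nm <- names(occurrences)
  spcol <- nm[nm %in% c("parasite_species", "species")][1]
  if (is.na(spcol)) abort("occurrences need a parasite_species/species column")
  occurrences |>
    dplyr::group_split(species_key = .data[[spcol]]) |>
    purrr::map(function(g) {
      bind_cols(tibble(parasite_species = g$species_key[1]),
                eoo_area(g[, setdiff(names(g), "species_key")]))
    }) |>
    bind_rows() |>
    arrange(.data$parasite_species)
}

#' Read an occurrence CSV
#'
#' Accepts Darwin-Core-compatible column names (`species`,
#' `decimalLongitude`, `decimalLatitude`) or plain
#' `parasite_species`/`longitude`/`latitude`.
#'
#' @param path CSV path.
#' @return a tibble `parasite_species`, `longitude`, `latitude`.
#' @export
read_occurrences <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  nm <- names(raw)
  spcol <- nm[nm %in% c("parasite_species", "species")][1]
  if (is.na(spcol)) abort("schema error: no species column in occurrence file")
  pts <- normalise_points(raw)
  tibble(parasite_species = as.character(raw[[spcol]]),
         longitude = pts$longitude, latitude = pts$latitude)
}

#' Join extent of occurrence with host specificity
#'
#' One row per parasite species with the EOO, its log10(area + 1) transform
#' (so species with degenerate ranges remain plottable at 0), and the three
#' specificity counts. Species present on only one side are retained with
#' `NA` on the other and listed in the `missing_eoo` / `missing_profile`
#' attributes rather than dropped silently.
#'
#' @param eoo output of [eoo_table()].
#' @param profiles output of [specificity_profiles()].
#' @return a joined tibble with column `log10_area_km2`.
#' @export
eoo_specificity_table <- function(eoo, profiles) {
  out <- full_join(eoo, profiles, by = "parasite_species") |>
    mutate(log10_area_km2 = log10(.data$area_km2 + 1))
  attr(out, "missing_eoo") <-
    setdiff(profiles$parasite_species, eoo$parasite_species)
  attr(out, "missing_profile") <-
    setdiff(eoo$parasite_species, profiles$parasite_species)
  out
}

#' Per-region record counts by confidence
#'
#' Counts low/medium/high records per botanical recording region (TDWG
#' World Geographical Scheme Level 2). Records without a region are
#' aggregated under `"unassigned"`; codes outside the supplied vocabulary
#' are kept but reported with a warning.
#'
#' @param records a rated record tibble.
#' @param region_codes optional character vector of valid region codes
#'   (default: the Level-2 codes shipped with the package, see
#'   [tdwg_level2_regions()]).
#' @return a tibble per region: `low`, `medium`, `high`, `total`.
#' @export
regional_counts <- function(records, region_codes = NULL) {
  if (nrow(records) == 0) {
    return(tibble(region = character(), low = integer(), medium = integer(),
                  high = integer(), total = integer()))
  }
  if (is.null(region_codes)) region_codes <- tdwg_level2_regions()$code
  region <- ifelse(is.na(records$region), "unassigned", records$region)
  unknown <- setdiff(unique(region), c(region_codes, "unassigned"))
  if (length(unknown) > 0) {
    warn(paste0("region code(s) outside the vocabulary: ",
                paste(unknown, collapse = ", ")))
  }
  tibble(region = region, confidence = records$confidence) |>
    count(.data$region, .data$confidence) |>
    tidyr::pivot_wider(names_from = "confidence", values_from = "n",
                       values_fill = 0L) |>
    (\(d) {
      for (lv in confidence_levels()) if (!lv %in% names(d)) d[[lv]] <- 0L
      d
    })() |>
    mutate(total = .data$low + .data$medium + .data$high) |>
    select("region", "low", "medium", "high", "total") |>
    arrange(.data$region)
}

#' TDWG Level-2 region vocabulary
#'
#' The 52 Level-2 region codes of the World Geographical Scheme for
#' Recording Plant Distributions, shipped as plain CSV in `extdata`.
#'
#' @return a tibble with columns `code`, `name`.
#' @export
tdwg_level2_regions <- function() {
  readr::read_csv(system.file("extdata", "tdwg_level2.csv",
                              package = "hostrange"),
                  col_types = "cc", progress = FALSE)
}
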