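# Three-tier confidence rating of host records.
#
# The engine is deterministic and two-pass. Pass one applies only the
# context-free rules to find provisionally high-rated records; pass two may
# additionally consult two dataset-level facts: (i) which host genera carry a
# high-rated record for each parasite, and (ii) which host families/orders
# are recorded at all for each parasite. Precedence:
#   P0  author flags the report as dubious                       -> low  (L1)
#   P1  any high criterion H1-H4, unless published before 1950
#       without explicit excavation (cap)                        -> high
#   P2  any medium criterion M1-M4                               -> medium
#   P3  low fallbacks L2-L3                                      -> low
#   P4  default, logged as unmatched-evidence                    -> medium (M0)
#
# H1 parasite excavated and host contact confirmed
# H2 report made by an expert in the group
# H3 herbarium sheet carries identified host material
# H4 database observation with the host connection visible in a photo
# M2 published before 1950 without explicit excavation (also caps H1-H4)
# M3 herbarium sheet names a host but carries no host material
# M4 database observation with the host visible in a photo, or whose host
#    genus already carries a high-rated record for this parasite
# M1 direct report where excavation is unclear (may be the nearest plant),
#    host family related (shares an order) with the parasite's other hosts
# L2 unconfirmed report from a family unrelated (no shared order) to every
#    other host family recorded for the parasite
# L3 database observation without a photo whose host genus carries no
#    high-rated record for the parasite

#' Build the dataset-level context for confidence classification
#'
#' First pass of the two-pass confidence engine: applies the context-free
#' rules only (no reference to other records) and collects, per parasite
#' species, the set of host genera with a provisionally high rating together
#' with all recorded host families and their orders. The result is
#' deterministic for a fixed record set and independent of record order.
#'
#' @param records a record tibble (see [read_host_records()]).
#' @return a list of class `host_confidence_ctx` with elements `high_genera`
#'   (named list: parasite species -> character vector of host genera) and
#'   `family_orders` (tibble of parasite species, host family, host order).
#' @export
build_confidence_context <- function(records) {
  fam <- records |>
    filter(!is.na(.data$host_family)) |>
    distinct(.data$parasite_species, .data$host_family, .data$host_order)
  if (nrow(records) == 0) {
    return(structure(list(high_genera = list(), family_orders = fam),
                     class = "host_confidence_ctx"))
  }
  ev <- evidence_matrix(records)
  prov_high <- (context_free_high(ev) & !ev[, "author_flags_dubious"] &
                  has_evidence(records)) |
    (!is.na(records$confidence) & records$confidence == "high")
  hg <- tibble(parasite_species = records$parasite_species,
               host_genus = records$host_genus)[prov_high &
                                                  !is.na(records$host_genus), ]
  high_genera <- split(hg$host_genus, hg$parasite_species)
  high_genera <- lapply(high_genera, unique)
  structure(list(high_genera = high_genera, family_orders = fam),
            class = "host_confidence_ctx")
}

#' @export
print.host_confidence_ctx <- function(x, ...) {
  cat("<host_confidence_ctx> high-genus map for ", length(x$high_genera),
      " parasite species; ", nrow(x$family_orders),
      " recorded parasite-family pairs\n", sep = "")
  invisible(x)
}

# evidence columns as a logical matrix with NA -> FALSE
evidence_matrix <- function(records) {
  m <- as.matrix(as.data.frame(records[, evidence_flags()]))
  mode(m) <- "logical"
  m[is.na(m)] <- FALSE
  m
}

has_evidence <- function(records) {
  rowSums(!is.na(as.data.frame(records[, evidence_flags()]))) > 0
}

context_free_high <- function(ev) {
  high_raw <- ev[, "excavated_confirmed"] | ev[, "expert_report"] |
    ev[, "host_material_on_sheet"] |
    (ev[, "database_observation"] & ev[, "photo_connection_visible"])
  capped <- ev[, "pre_1950"] & !ev[, "excavation_explicit"]
  high_raw & !capped
}

#' Classify record confidence
#'
#' Applies the three-tier rule engine to every record that carries evidence
#' flags, returning exactly one rating per record plus the identifier of the
#' rule that fired. Records without evidence are an error: their confidence
#' must be supplied directly.
#'
#' @param records a record tibble; every row must carry evidence.
#' @param ctx a context from [build_confidence_context()]; defaults to the
#'   context built from `records` itself.
#' @return a tibble with columns `record_id`, `confidence`, `rule_id`.
#' @export
classify_confidence <- function(records, ctx = build_confidence_context(records)) {
  if (nrow(records) == 0) {
    return(tibble(record_id = character(), confidence = character(),
                  rule_id = character()))
  }
  no_ev <- !has_evidence(records)
  if (any(no_ev)) {
    abort(paste0("classification error: no evidence; supply confidence ",
                 "directly for record(s): ",
                 paste(head(records$record_id[no_ev], 5), collapse = ", ")))
  }
  ev <- evidence_matrix(records)

  in_high_genus <- purrr::map2_lgl(
    records$parasite_species, records$host_genus,
    function(p, g) !is.na(g) && g %in% (ctx$high_genera[[p]] %||% character())
  )
  unrelated <- unrelated_family(records, ctx)

  high_raw <- ev[, "excavated_confirmed"] | ev[, "expert_report"] |
    ev[, "host_material_on_sheet"] |
    (ev[, "database_observation"] & ev[, "photo_connection_visible"])
  cap <- ev[, "pre_1950"] & !ev[, "excavation_explicit"]
  high_rule <- dplyr::case_when(
    ev[, "excavated_confirmed"] ~ "H1",
    ev[, "expert_report"] ~ "H2",
    ev[, "host_material_on_sheet"] ~ "H3",
    ev[, "database_observation"] & ev[, "photo_connection_visible"] ~ "H4",
    .default = NA_character_
  )

  m2 <- cap                      # pre-1950 without explicit excavation
  m3 <- ev[, "herbarium_host_named_no_material"]
  m4 <- ev[, "database_observation"] &
    (ev[, "photo_host_visible"] | in_high_genus)
  m1 <- !ev[, "database_observation"] & !ev[, "excavated_confirmed"] &
    !ev[, "herbarium_host_named_no_material"] & !unrelated

  l2 <- !ev[, "database_observation"] & unrelated
  l3 <- ev[, "database_observation"] & !ev[, "has_photo"] & !in_high_genus

  rule_id <- rep(NA_character_, nrow(records))
  confidence <- rep(NA_character_, nrow(records))

  p0 <- ev[, "author_flags_dubious"]
  confidence[p0] <- "low"; rule_id[p0] <- "L1"

  p1 <- is.na(confidence) & high_raw & !cap
  confidence[p1] <- "high"; rule_id[p1] <- high_rule[p1]
  p1cap <- is.na(confidence) & high_raw & cap
  confidence[p1cap] <- "medium"; rule_id[p1cap] <- "M2"

  for (r in list(list("M2", m2), list("M3", m3), list("M4", m4),
                 list("M1", m1))) {
    sel <- is.na(confidence) & r[[2]]
    confidence[sel] <- "medium"; rule_id[sel] <- r[[1]]
  }
  for (r in list(list("L2", l2), list("L3", l3))) {
    sel <- is.na(confidence) & r[[2]]
    confidence[sel] <- "low"; rule_id[sel] <- r[[1]]
  }
  rest <- is.na(confidence)
  confidence[rest] <- "medium"; rule_id[rest] <- "M0"
  if (any(rest)) {
    inform(paste0(sum(rest), " record(s) matched no rule; rated medium ",
                  "(unmatched-evidence)"))
  }
  tibble(record_id = records$record_id, confidence = confidence,
         rule_id = rule_id)
}

# TRUE where the record's host family shares no order with any *other* host
# family recorded for the same parasite (order is the finest rank always
# present; unknown orders or a sole recorded family never count as unrelated)
unrelated_family <- function(records, ctx) {
  fo <- ctx$family_orders |> filter(!is.na(.data$host_order))
  orders_by_parasite <- split(fo[, c("host_family", "host_order")],
                              fo$parasite_species)
  purrr::pmap_lgl(
    list(records$parasite_species, records$host_family, records$host_order),
    function(p, f, o) {
      if (is.na(o) || is.na(f)) return(FALSE)
      others <- orders_by_parasite[[p]]
      if (is.null(others)) return(FALSE)
      other_orders <- unique(others$host_order[others$host_family != f])
      length(other_orders) > 0 && !(o %in% other_orders)
    }
  )
}

#' Rate every record in a set
#'
#' Runs the two-pass confidence engine over the whole record set. Records with
#' a pre-set confidence keep it unless `overwrite = TRUE`; records with
#' neither evidence nor a pre-set confidence are left unrated and reported in
#' the `unrated` attribute with a warning. The operation is idempotent.
#'
#' @param records a record tibble.
#' @param overwrite re-rate records that already carry a confidence.
#' @return the record tibble with `confidence` filled and a `confidence_rule`
#'   column; attribute `unrated` lists record ids that could not be rated.
#' @export
apply_confidence <- function(records, overwrite = FALSE) {
  if (!("confidence_rule" %in% names(records))) {
    records$confidence_rule <- NA_character_
  }
  if (nrow(records) == 0) return(records)
  ctx <- build_confidence_context(records)
  target <- has_evidence(records) & (overwrite | is.na(records$confidence))
  if (any(target)) {
    cls <- classify_confidence(records[target, , drop = FALSE], ctx)
    records$confidence[target] <- cls$confidence
    records$confidence_rule[target] <- cls$rule_id
  }
  unrated <- records$record_id[is.na(records$confidence)]
  if (length(unrated) > 0) {
    warn(paste0(length(unrated), " record(s) with neither evidence nor ",
                "pre-set confidence left unrated: ",
                paste(head(unrated, 5), collapse = ", ")))
  }
  attr(records, "unrated") <- unrated
  records
}

#' Tally records by confidence rating
#'
#' @param records a fully rated record tibble.
#' @return a one-row tibble with columns `low`, `medium`, `high`, `total`.
#' @export
confidence_tally <- function(records) {
  if (nrow(records) > 0 && any(is.na(records$confidence))) {
    abort("unrated record(s) present; run apply_confidence() first")
  }
  tibble(
    low = sum(records$confidence == "low"),
    medium = sum(records$confidence == "medium"),
    high = sum(records$confidence == "high"),
    total = nrow(records)
  )
}
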