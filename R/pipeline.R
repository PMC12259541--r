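# End-to-end wiring: rate -> filter -> statistics -> geometry -> matrix,
# with every table written to disk under a manifest.

#' Run the full host-preference analysis
#'
#' Rates the records, builds the analysis set, computes the specificity,
#' convergence, habit, geometry and interaction-matrix outputs, and writes
#' each as CSV to `out_dir` together with a `manifest.json`. Stages whose
#' inputs were not supplied (tree, occurrences, maps) are skipped and marked
#' in the manifest. Outputs are deterministic for identical inputs.
#'
#' @param records a record tibble (already read/validated).
#' @param out_dir output directory, created if needed.
#' @param tree optional host-family phylogeny ([read_family_tree()]).
#' @param occurrences optional occurrence tibble ([read_occurrences()]).
#' @param clade_map,tribe_map,shares optional config tibbles (see
#'   [clade_partition()], [tribe_breakdown()], [disproportionality()]).
#' @param overwrite_ratings re-rate records with pre-set confidence.
#' @param well_supported_rule passed to [subset_well_supported()].
#' @return the manifest (named list of written files), invisibly.
#' @export
run_host_analysis <- function(records, out_dir, tree = NULL,
                              occurrences = NULL, clade_map = NULL,
                              tribe_map = NULL, shares = NULL,
                              overwrite_ratings = FALSE,
                              well_supported_rule = "same_species") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  emit <- function(name, tbl) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(tbl, path, na = "", progress = FALSE)
    manifest[[name]] <<- basename(path)
  }

  bad <- validate_records(records)
  if (nrow(bad) > 0) {
    abort(paste0("invalid records: ", nrow(bad), " violation(s); ",
                 "see validate_records()"))
  }
  rated <- apply_confidence(records, overwrite = overwrite_ratings)
  emit("rated_records", rated)
  emit("confidence_tally", confidence_tally(rated))

  flt <- build_analysis_set(rated)
  analysis <- flt$kept
  emit("filter_log", tidy(flt))
  emit("filter_summary", glance(flt))

  profiles <- specificity_profiles(analysis)
  supported <- subset_well_supported(profiles, analysis,
                                     rule = well_supported_rule)
  flagged <- flag_extremes(supported, analysis)
  emit("specificity_profiles", flagged)
  emit("lineage_medians", lineage_medians(supported))

  emit("host_family_summary", host_family_summary(analysis))
  emit("parasite_family_breadth", parasite_family_breadth(analysis))
  if (!is.null(shares)) {
    emit("disproportionality",
         disproportionality(host_family_summary(analysis), shares,
                            n_distinct(analysis$parasite_species)))
  }
  if (!is.null(clade_map)) {
    emit("clade_partition", clade_partition(analysis, clade_map))
  }
  if (!is.null(tribe_map)) {
    emit("tribe_breakdown", tribe_breakdown(analysis, tribe_map))
  }
  emit("habit_summary", habit_summary(analysis))
  emit("regional_counts", regional_counts(rated))

  if (!is.null(occurrences)) {
    eoo <- eoo_table(occurrences)
    emit("eoo", eoo)
    emit("eoo_specificity", eoo_specificity_table(eoo, profiles))
  }
  if (!is.null(tree)) {
    m <- interaction_matrix(analysis, tree)
    write_interaction_matrix(m, file.path(out_dir, "interaction_matrix.csv"))
    manifest[["interaction_matrix"]] <- "interaction_matrix.csv"
    emit("top_hosts", top_hosts(m, k = min(10, ncol(m))))
  }
  manifest[["skipped"]] <- setdiff(
    c("tree", "occurrences", "clade_map", "tribe_map", "shares"),
    names(which(!vapply(list(tree = tree, occurrences = occurrences,
                             clade_map = clade_map, tribe_map = tribe_map,
                             shares = shares), is.null, logical(1))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Write a synthetic dataset to disk
#'
#' Generates a dataset from a config and writes the record CSV (readable by
#' [read_host_records()]), the occurrence CSV and the ground truth as JSON.
#' Rerunning with the same config writes identical files.
#'
#' @param cfg a [synthetic_config()].
#' @param out_dir output directory, created if needed.
#' @return the `host_synth` object, invisibly.
#' @export
simulate_host_data <- function(cfg = synthetic_config(), out_dir) {
  synth <- generate_host_data(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_host_records(synth$records, file.path(out_dir, "records.csv"))
  readr::write_csv(synth$occurrences, file.path(out_dir, "occurrences.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(parasites = synth$truth$parasites,
         record_labels = synth$truth$record_labels),
    file.path(out_dir, "ground_truth.json"), digits = NA
  )
  invisible(synth)
}
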