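# Parasite-genus x host-family presence matrix, columns ordered by the tips
# of a family-level seed-plant phylogeny.

#' Read a family-level host phylogeny
#'
#' Parses a newick tree whose tips are host family names. Branch lengths, if
#' present, are preserved but unused. Duplicate tip labels are an error.
#'
#' @param path newick file path.
#' @return an `ape::phylo` tree.
#' @export
read_family_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) abort(paste0("newick parse error: ",
                                                    conditionMessage(e))))
  if (is.null(tree)) abort("newick parse error: no tree in file")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    abort(paste0("duplicate tip label(s): ", paste(dup, collapse = ", ")))
  }
  inform(paste0("read tree with ", length(tree$tip.label), " tips"))
  tree
}

# left-to-right tip order as written in the newick (ape keeps input order in
# tip.label for read.tree; made explicit via cladewise edge traversal)
tip_order <- function(tree) {
  ord <- ape::reorder.phylo(tree, "cladewise")
  tips <- ord$edge[, 2][ord$edge[, 2] <= length(tree$tip.label)]
  tree$tip.label[tips]
}

normalise_name <- function(x) tolower(stringr::str_squish(x))

#' Phylogeny-ordered interaction matrix
#'
#' Presence matrix with one row per parasite genus (rows grouped by parasite
#' family) and one column per host family in the tree's left-to-right tip
#' order; a cell is `TRUE` when at least one analysis-set record links the
#' genus to the family. Host families absent from the tree are appended
#' after the ordered columns and listed in the `missing_from_tree`
#' attribute. Name matching is exact after whitespace/case normalization.
#'
#' @param analysis_set a filtered record tibble.
#' @param tree a host-family phylogeny from [read_family_tree()].
#' @param drop_empty_tips drop tree families with no record (default `TRUE`).
#' @return a `host_interaction_matrix`: logical matrix with attributes
#'   `parasite_family` (named by row), `missing_from_tree`, `tip_order`.
#' @export
interaction_matrix <- function(analysis_set, tree, drop_empty_tips = TRUE) {
  edges <- analysis_set |>
    filter(!is.na(.data$host_family)) |>
    distinct(.data$parasite_family, .data$parasite_genus, .data$host_family)
  tips <- tip_order(tree)
  fam_in_tree <- tips[normalise_name(tips) %in%
                        normalise_name(unique(edges$host_family))]
  missing <- sort(setdiff(unique(normalise_name(edges$host_family)),
                          normalise_name(tips)))
  missing <- unique(edges$host_family[normalise_name(edges$host_family) %in%
                                        missing])
  cols <- c(if (drop_empty_tips) fam_in_tree else tips, sort(missing))
  rows <- edges |>
    distinct(.data$parasite_family, .data$parasite_genus) |>
    arrange(.data$parasite_family, .data$parasite_genus)
  m <- matrix(FALSE, nrow = nrow(rows), ncol = length(cols),
              dimnames = list(rows$parasite_genus, cols))
  if (nrow(edges) > 0 && length(cols) > 0) {
    col_idx <- match(normalise_name(edges$host_family), normalise_name(cols))
    row_idx <- match(edges$parasite_genus, rows$parasite_genus)
    m[cbind(row_idx, col_idx)] <- TRUE
  }
  structure(m,
            class = c("host_interaction_matrix", "matrix", "array"),
            parasite_family = setNames(rows$parasite_family,
                                       rows$parasite_genus),
            missing_from_tree = missing,
            tip_order = tips)
}

#' @export
print.host_interaction_matrix <- function(x, ...) {
  cat("<host_interaction_matrix> ", nrow(x), " parasite genera x ", ncol(x),
      " host families (", sum(x), " interactions; ",
      length(attr(x, "missing_from_tree")), " families not in tree)\n",
      sep = "")
  invisible(x)
}

#' @rdname interaction_matrix
#' @param x a `host_interaction_matrix`.
#' @param ... unused.
#' @export
tidy.host_interaction_matrix <- function(x, ...) {
  idx <- which(unclass(x), arr.ind = TRUE)
  fam <- attr(x, "parasite_family")
  tibble(parasite_family = unname(fam[rownames(x)[idx[, 1]]]),
         parasite_genus = rownames(x)[idx[, 1]],
         host_family = colnames(x)[idx[, 2]]) |>
    arrange(.data$parasite_family, .data$parasite_genus, .data$host_family)
}

#' Export an interaction matrix as CSV
#'
#' Writes the presence matrix with row and column headers (`wide`) or the
#' long-format edge list (`long`).
#'
#' @param m a `host_interaction_matrix`.
#' @param path output path.
#' @param format `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_interaction_matrix <- function(m, path, format = c("wide", "long")) {
  format <- match.arg(format)
  if (format == "long") {
    readr::write_csv(tidy(m), path, progress = FALSE)
  } else {
    wide <- as_tibble(unclass(m) * 1L)
    wide <- bind_cols(
      tibble(parasite_family = unname(attr(m, "parasite_family")[rownames(m)]),
             parasite_genus = rownames(m)), wide)
    readr::write_csv(wide, path, progress = FALSE)
  }
  invisible(path)
}

#' Rank host families by number of parasite genera
#'
#' Columns are ranked by the number of parasite genera recorded on them, with
#' ties broken by the number of parasite lineages (families), then by name.
#'
#' @param m a `host_interaction_matrix`.
#' @param k how many families to return; if `k` exceeds the number of
#'   columns the full ranking is returned with a warning.
#' @return a tibble: `host_family`, `n_parasite_genera`,
#'   `n_parasite_lineages`.
#' @export
top_hosts <- function(m, k = 10) {
  stopifnot(k >= 1)
  fam <- attr(m, "parasite_family")
  n_genera <- colSums(m)
  n_lineages <- apply(unclass(m), 2,
                      function(col) n_distinct(fam[rownames(m)[col]]))
  out <- tibble(host_family = colnames(m),
                n_parasite_genera = as.integer(n_genera),
                n_parasite_lineages = as.integer(n_lineages)) |>
    arrange(dplyr::desc(.data$n_parasite_genera),
            dplyr::desc(.data$n_parasite_lineages), .data$host_family)
  if (k > nrow(out)) {
    warn(paste0("k = ", k, " exceeds the ", nrow(out),
                " host families; returning all"))
    k <- nrow(out)
  }
  head(out, k)
}
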