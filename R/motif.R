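# Primary tissue motifs: the non-redundant set of cell types an FTU
# contains, plus its anatomical location, and the set-theoretic relations
# between motifs (equivalence, subsumption, overlap).

#' Construct a primary tissue motif
#'
#' A primary tissue motif (PTM) is the non-redundant set of cell-type
#' ontology terms observed in one functional tissue unit, together with the
#' anatomical region the tissue came from. Motifs are pure sets: duplicates
#' collapse, order is irrelevant for equality, and cell multiplicities
#' belong to the spatial model, not the motif.
#'
#' @param id Motif identifier, unique within a collection.
#' @param term_ids Non-empty character vector of cell-type term accessions.
#' @param location Optional anatomy term (e.g. an FMA accession or name).
#' @return An object of class `tissue_motif` with components `motif_id`,
#'   `cell_types` (sorted, distinct) and `anatomical_location`.
#' @examples
#' make_motif("demo", c("CL_0000057", "CL_0000115", "CL_0000057"))
#' @export
make_motif <- function(id, term_ids, location = NULL) {
  if (length(term_ids) == 0 || all(!nzchar(term_ids))) {
    ftu_validation_error("a motif needs at least one cell-type term")
  }
  structure(
    list(motif_id = as.character(id),
         cell_types = sort(unique(as.character(term_ids))),
         anatomical_location = if (is.null(location) || is.na(location)) NA_character_
                               else as.character(location)),
    class = "tissue_motif"
  )
}

#' @export
print.tissue_motif <- function(x, ...) {
  cat(sprintf("tissue_motif %s (%d cell types%s)\n  %s\n",
              x$motif_id, length(x$cell_types),
              if (is.na(x$anatomical_location)) "" else
                paste0(", ", x$anatomical_location),
              paste(x$cell_types, collapse = ", ")))
  invisible(x)
}

#' Set-theoretic relation between two motifs
#'
#' Compares the cell-type sets of two motifs: `equivalent` (equal sets),
#' `x_subsumed_by_y` / `y_subsumed_by_x` (proper subset), `overlap`
#' (non-empty intersection, neither contained), or `disjoint`.
#'
#' @param x,y `tissue_motif` objects.
#' @return An object of class `motif_relation`: list with `kind` and
#'   `shared` (the intersection of the two cell-type sets).
#' @export
relate_motifs <- function(x, y) {
  stopifnot(inherits(x, "tissue_motif"), inherits(y, "tissue_motif"))
  a <- x$cell_types; b <- y$cell_types
  shared <- intersect(a, b)
  kind <-
    if (setequal(a, b)) "equivalent"
    else if (all(a %in% b)) "x_subsumed_by_y"
    else if (all(b %in% a)) "y_subsumed_by_x"
    else if (length(shared) > 0) "overlap"
    else "disjoint"
  structure(list(kind = kind, shared = sort(shared)), class = "motif_relation")
}

#' @export
print.motif_relation <- function(x, ...) {
  cat(sprintf("motif_relation: %s (%d shared)\n", x$kind, length(x$shared)))
  invisible(x)
}

#' Union of primary tissue motifs
#'
#' The motif of a compound tissue region: the union of the member motifs'
#' cell-type sets. The location is kept only when all members agree on it.
#'
#' @param motifs Non-empty list of `tissue_motif` objects.
#' @param id Identifier for the union motif; defaults to the member ids
#'   joined with `"+"`.
#' @return A `tissue_motif`.
#' @export
motif_union <- function(motifs, id = NULL) {
  if (inherits(motifs, "tissue_motif")) motifs <- list(motifs)
  if (length(motifs) == 0) ftu_validation_error("motif_union needs at least one motif")
  stopifnot(all(vapply(motifs, inherits, logical(1), "tissue_motif")))
  locs <- unique(vapply(motifs, function(m) m$anatomical_location, character(1)))
  make_motif(
    id %||% paste(vapply(motifs, function(m) m$motif_id, character(1)), collapse = "+"),
    unlist(lapply(motifs, function(m) m$cell_types), use.names = FALSE),
    location = if (length(locs) == 1 && !is.na(locs)) locs else NULL
  )
}

#' Read / write motif collections
#'
#' JSON form: an array of `{id, cell_types: [...], location}` objects.
#' TSV form: columns `motif_id`, `cell_types` (comma-separated accessions),
#' `location` (empty when unset).
#'
#' @param path File path.
#' @return Readers return a named list of [make_motif()] objects (names are
#'   motif ids); writers return `path` invisibly.
#' @export
read_motifs_json <- function(path) {
  if (!file.exists(path)) ftu_io_error(sprintf("cannot read motif JSON: %s", path))
  recs <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
                   error = function(e) ftu_parse_error(
                     sprintf("invalid motif JSON %s: %s", path, conditionMessage(e))))
  motifs <- lapply(recs, function(r) {
    if (is.null(r$id) || is.null(r$cell_types)) {
      ftu_parse_error("each motif record needs 'id' and 'cell_types'")
    }
    make_motif(r$id, unlist(r$cell_types), location = r$location)
  })
  check_unique_ids(motifs)
  stats::setNames(motifs, vapply(motifs, function(m) m$motif_id, character(1)))
}

#' @rdname read_motifs_json
#' @param motifs List of `tissue_motif` objects.
#' @export
write_motifs_json <- function(motifs, path) {
  recs <- lapply(motifs, function(m) {
    r <- list(id = m$motif_id, cell_types = m$cell_types)
    if (!is.na(m$anatomical_location)) r$location <- m$anatomical_location
    r
  })
  jsonlite::write_json(unname(recs), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname read_motifs_json
#' @export
read_motifs_tsv <- function(path) {
  if (!file.exists(path)) ftu_io_error(sprintf("cannot read motif TSV: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("motif_id", "cell_types") %in% names(df))) {
    ftu_parse_error("motif TSV needs columns 'motif_id' and 'cell_types'")
  }
  motifs <- lapply(seq_len(nrow(df)), function(i) {
    loc <- if ("location" %in% names(df) && nzchar(df$location[i])) df$location[i] else NULL
    make_motif(df$motif_id[i], trimws(strsplit(df$cell_types[i], ",")[[1]]), location = loc)
  })
  check_unique_ids(motifs)
  stats::setNames(motifs, vapply(motifs, function(m) m$motif_id, character(1)))
}

#' @rdname read_motifs_json
#' @export
write_motifs_tsv <- function(motifs, path) {
  df <- data.frame(
    motif_id = vapply(motifs, function(m) m$motif_id, character(1)),
    cell_types = vapply(motifs, function(m) paste(m$cell_types, collapse = ","), character(1)),
    location = vapply(motifs, function(m)
      if (is.na(m$anatomical_location)) "" else m$anatomical_location, character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

check_unique_ids <- function(motifs) {
  ids <- unname(vapply(motifs, function(m) m$motif_id, character(1)))
  if (anyDuplicated(ids)) {
    ftu_validation_error(sprintf("duplicate motif id: %s", ids[duplicated(ids)][1]))
  }
  invisible(ids)
}
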