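# Cell-type ontology support: a light DAG container, OBO 1.2 flat-file
# reading/writing, ancestor traversal and pairwise term semantic similarity.

#' Construct an ontology graph
#'
#' A directed acyclic graph of ontology terms. Edges point from child to
#' parent and carry a relation label (typically `is_a`, optionally `part_of`
#' or others). Used as the substrate for term semantic similarity.
#'
#' @param terms Character vector of term accessions (e.g. `"CL_0000057"`).
#' @param edges Data frame with character columns `child`, `parent`,
#'   `relation`; both endpoints must appear in `terms`.
#' @param labels Optional named character vector of human-readable names,
#'   named by term accession.
#' @return An object of class `ontology_graph` with components `terms`,
#'   `edges`, `labels` and a derived `roots` vector (terms with no parent).
#' @seealso [load_obo()], [ancestors()], [term_similarity()]
#' @export
ontology_graph <- function(terms, edges = NULL, labels = NULL) {
  terms <- as.character(terms)
  if (length(terms) == 0) ftu_validation_error("an ontology graph needs at least one term")
  if (anyDuplicated(terms)) {
    ftu_validation_error(sprintf("duplicate term id: %s", terms[duplicated(terms)][1]))
  }
  if (is.null(edges)) {
    edges <- data.frame(child = character(), parent = character(),
                        relation = character(), stringsAsFactors = FALSE)
  }
  edges <- data.frame(child = as.character(edges$child),
                      parent = as.character(edges$parent),
                      relation = as.character(edges$relation),
                      stringsAsFactors = FALSE)
  missing <- setdiff(unique(c(edges$child, edges$parent)), terms)
  if (length(missing) > 0) {
    ftu_validation_error(sprintf("edge endpoint not in term set: %s", missing[1]))
  }
  g <- structure(
    list(terms = terms, edges = edges, labels = labels,
         parent_map = split(edges$parent, factor(edges$child, levels = terms))),
    class = "ontology_graph"
  )
  cyc <- find_cycle_member(g)
  if (!is.na(cyc)) {
    ftu_structural_error(sprintf("ontology graph is cyclic (cycle involves %s)", cyc))
  }
  g$roots <- setdiff(terms, unique(edges$child))
  g
}

# Kahn's algorithm; returns NA when acyclic, otherwise one term on a cycle.
find_cycle_member <- function(g) {
  n_parents <- lengths(g$parent_map)
  children_of <- split(g$edges$child, factor(g$edges$parent, levels = g$terms))
  queue <- g$terms[n_parents == 0]
  seen <- 0L
  while (length(queue) > 0) {
    t <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (ch in children_of[[t]]) {
      n_parents[[ch]] <- n_parents[[ch]] - 1L
      if (n_parents[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen == length(g$terms)) NA_character_ else g$terms[n_parents > 0][1]
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("ontology_graph: %d terms, %d edges, %d root(s)\n",
              length(x$terms), nrow(x$edges), length(x$roots)))
  invisible(x)
}

#' Load an ontology from an OBO 1.2 flat file
#'
#' Reads `[Term]` stanzas, keeping `id`, `name`, `is_a` and `relationship`
#' lines. Obsolete terms are dropped (a count is reported on standard
#' error), and only edges whose relation label is in `relations` are kept.
#' Edges pointing at terms absent from the file (e.g. targets of dropped
#' stanzas) are discarded.
#'
#' @param path Path to an OBO flat file.
#' @param relations Character vector of relation labels to traverse;
#'   default `"is_a"` (cell-type subsumption). Add `"part_of"` or others to
#'   widen the graph.
#' @return An [ontology_graph()].
#' @export
load_obo <- function(path, relations = "is_a") {
  if (length(relations) == 0) ftu_validation_error("`relations` must be non-empty")
  if (!file.exists(path)) ftu_io_error(sprintf("cannot read OBO file: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")

  terms <- character()
  labels <- character()
  obsolete <- character()
  ch <- pa <- rel <- character()

  in_term <- FALSE
  cur_id <- NA_character_
  cur_obsolete <- FALSE
  cur_name <- NA_character_
  cur_edges <- list()

  flush_term <- function() {
    if (is.na(cur_id)) return()
    if (cur_obsolete) {
      obsolete[[length(obsolete) + 1L]] <<- cur_id
    } else {
      terms[[length(terms) + 1L]] <<- cur_id
      if (!is.na(cur_name)) labels[[cur_id]] <<- cur_name
      for (e in cur_edges) {
        ch[[length(ch) + 1L]] <<- cur_id
        pa[[length(pa) + 1L]] <<- e[[2]]
        rel[[length(rel) + 1L]] <<- e[[1]]
      }
    }
  }

  for (line in lines) {
    line <- sub("!.*$", "", line)        # trailing comments
    line <- trimws(line)
    if (line == "") next
    if (grepl("^\\[", line)) {
      flush_term()
      in_term <- line == "[Term]"
      cur_id <- NA_character_; cur_obsolete <- FALSE
      cur_name <- NA_character_; cur_edges <- list()
      next
    }
    if (!in_term) next
    key <- sub(":.*$", "", line)
    val <- trimws(sub("^[^:]+:", "", line))
    if (key == "id") cur_id <- val
    else if (key == "name") cur_name <- val
    else if (key == "is_a") cur_edges <- c(cur_edges, list(c("is_a", val)))
    else if (key == "is_obsolete") cur_obsolete <- tolower(val) %in% c("true", "1")
    else if (key == "relationship") {
      parts <- strsplit(val, "\\s+")[[1]]
      if (length(parts) >= 2) cur_edges <- c(cur_edges, list(c(parts[1], parts[2])))
    }
  }
  flush_term()

  if (length(obsolete) > 0) {
    message(sprintf("load_obo: dropped %d obsolete term(s)", length(obsolete)))
  }
  if (length(terms) == 0) ftu_parse_error(sprintf("no [Term] stanzas found in %s", path))

  keep <- rel %in% relations & pa %in% terms & ch %in% terms
  ontology_graph(
    terms,
    data.frame(child = ch[keep], parent = pa[keep], relation = rel[keep],
               stringsAsFactors = FALSE),
    labels = if (length(labels)) labels else NULL
  )
}

#' Write an ontology graph as an OBO 1.2 flat file
#'
#' Inverse of [load_obo()]: `is_a` edges become `is_a:` lines, any other
#' relation becomes a `relationship:` line.
#'
#' @param graph An [ontology_graph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  stopifnot(inherits(graph, "ontology_graph"))
  out <- c("format-version: 1.2", "")
  for (t in graph$terms) {
    out <- c(out, "[Term]", sprintf("id: %s", t))
    if (!is.null(graph$labels) && !is.na(graph$labels[t]) && t %in% names(graph$labels)) {
      out <- c(out, sprintf("name: %s", graph$labels[[t]]))
    }
    e <- graph$edges[graph$edges$child == t, , drop = FALSE]
    for (i in seq_len(nrow(e))) {
      out <- c(out, if (e$relation[i] == "is_a") {
        sprintf("is_a: %s", e$parent[i])
      } else {
        sprintf("relationship: %s %s", e$relation[i], e$parent[i])
      })
    }
    out <- c(out, "")
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Ancestors of a term
#'
#' Transitive closure over the stored (child -> parent) edges.
#'
#' @param graph An [ontology_graph()].
#' @param term A term accession present in the graph.
#' @param reflexive Include `term` itself? Default `FALSE`.
#' @return Character vector of ancestor accessions (unordered).
#' @export
ancestors <- function(graph, term, reflexive = FALSE) {
  stopifnot(inherits(graph, "ontology_graph"))
  if (!term %in% graph$terms) {
    ftu_lookup_error(sprintf("term not in ontology graph: %s", term))
  }
  seen <- character()
  frontier <- term
  while (length(frontier) > 0) {
    parents <- unique(unlist(graph$parent_map[frontier], use.names = FALSE))
    frontier <- setdiff(parents, seen)
    seen <- union(seen, frontier)
  }
  if (reflexive) union(seen, term) else setdiff(seen, term)
}

# Strict descendant counts for every term, by inverting per-term ancestor
# sets. IC(t) = -log((descendants(t) + 1) / (N + 1)); topology-based with
# +1 smoothing because no annotation corpus is attached to the graph.
descendant_counts <- function(graph) {
  counts <- stats::setNames(integer(length(graph$terms)), graph$terms)
  for (t in graph$terms) {
    anc <- ancestors(graph, t, reflexive = FALSE)
    counts[anc] <- counts[anc] + 1L
  }
  counts
}

information_content <- function(graph) {
  n <- length(graph$terms)
  -log((descendant_counts(graph) + 1) / (n + 1))
}

#' Semantic similarity between two ontology terms
#'
#' Pairwise similarity in `[0, 1]` over the ontology DAG. Three measures:
#'
#' * `simUI` (default): Jaccard index of the two terms' reflexive ancestor
#'   sets (induced-subgraph overlap).
#' * `resnik_norm`: information content (IC) of the most informative common
#'   ancestor, scaled by the maximum IC in the graph.
#' * `lin`: `2 IC(MICA) / (IC(a) + IC(b))`.
#'
#' IC is topology-based, `-log((descendants + 1) / (N + 1))`, since no
#' annotation corpus is assumed. Identity is exact-match by definition:
#' every measure returns 1 when `a == b`. Terms sharing no ancestor (under
#' disjoint roots) score 0.
#'
#' @param graph An [ontology_graph()].
#' @param a,b Term accessions present in the graph.
#' @param measure One of `"simUI"`, `"resnik_norm"`, `"lin"`.
#' @return A similarity score in `[0, 1]`.
#' @examples
#' g <- gen_dag_ontology(10, seed = 1)
#' term_similarity(g, g$terms[5], g$terms[7])
#' @export
term_similarity <- function(graph, a, b, measure = c("simUI", "resnik_norm", "lin")) {
  measure <- match.arg(measure)
  stopifnot(inherits(graph, "ontology_graph"))
  if (a == b) {
    if (!a %in% graph$terms) ftu_lookup_error(sprintf("term not in ontology graph: %s", a))
    return(1.0)
  }
  anc_a <- ancestors(graph, a, reflexive = TRUE)
  anc_b <- ancestors(graph, b, reflexive = TRUE)
  common <- intersect(anc_a, anc_b)
  if (measure == "simUI") {
    return(length(common) / length(union(anc_a, anc_b)))
  }
  if (length(common) == 0) return(0)
  ic <- information_content(graph)
  ic_mica <- max(ic[common])
  if (measure == "resnik_norm") {
    ic_max <- max(ic)
    if (ic_max == 0) return(0)
    return(ic_mica / ic_max)
  }
  denom <- ic[[a]] + ic[[b]]
  if (denom == 0) return(0)
  2 * ic_mica / denom
}

#' All-vs-all similarity matrix over a term list
#'
#' @param graph An [ontology_graph()].
#' @param terms Character vector of distinct term accessions (all in the
#'   graph); matrix rows/columns follow this order.
#' @param measure Passed to [term_similarity()].
#' @return A [sim_matrix()] over `terms`.
#' @export
build_matrix <- function(graph, terms, measure = c("simUI", "resnik_norm", "lin")) {
  measure <- match.arg(measure)
  if (length(terms) == 0) ftu_validation_error("`terms` must be non-empty")
  if (anyDuplicated(terms)) {
    ftu_validation_error(sprintf("duplicate term in list: %s", terms[duplicated(terms)][1]))
  }
  n <- length(terms)
  m <- diag(1, n)
  dimnames(m) <- list(terms, terms)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        m[i, j] <- m[j, i] <- term_similarity(graph, terms[i], terms[j], measure)
      }
    }
  }
  sim_matrix(m)
}
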