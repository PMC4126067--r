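# Classification of a motif collection: agglomerative clustering on the
# distance 1 - s() into a binary tree, with Newick and JSON serialisation.

#' Cluster motifs into a binary tree
#'
#' Agglomerative hierarchical clustering of a motif collection on the
#' distance `d = 1 - s`, where `s` is the pairwise motif similarity table
#' from [all_vs_all()]. Default linkage is UPGMA (average); single and
#' complete linkage are available. Labels are sorted lexicographically
#' before clustering so the topology does not depend on input order, and
#' ties resolve the same way on every run.
#'
#' @param score_table A [sim_matrix()] of pairwise motif similarities
#'   (symmetric, diagonal 1, at least 2 motifs).
#' @param linkage `"average"` (UPGMA, default), `"single"` or
#'   `"complete"`.
#' @return An object of class `motif_dendrogram`: list with `hclust` (the
#'   [stats::hclust()] fit), `linkage` and `labels`.
#' @examples
#' fx <- table1_fixture()
#' s <- all_vs_all(fx$motifs, fx$matrix)
#' cluster_motifs(s)
#' @export
cluster_motifs <- function(score_table, linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  m <- sim_matrix(unclass(score_table))   # revalidate: symmetry, diag, range
  if (nrow(m) < 2) ftu_validation_error("clustering needs at least two motifs")
  ord <- order(rownames(m))
  m <- m[ord, ord]
  h <- stats::hclust(stats::as.dist(1 - m), method = linkage)
  structure(list(hclust = h, linkage = linkage, labels = h$labels),
            class = "motif_dendrogram")
}

#' @export
print.motif_dendrogram <- function(x, ...) {
  cat(sprintf("motif_dendrogram (%s linkage, %d leaves)\n%s\n",
              x$linkage, length(x$labels), to_newick(x)))
  invisible(x)
}

#' Leaf labels under each merge
#'
#' @param tree A [cluster_motifs()] result.
#' @return List (one element per merge, in merge order) of character
#'   vectors: the leaf labels of the cluster formed by that merge.
#' @export
merge_members <- function(tree) {
  h <- tree$hclust
  out <- vector("list", nrow(h$merge))
  members <- function(k) {
    if (k < 0) h$labels[-k] else out[[k]]
  }
  for (i in seq_len(nrow(h$merge))) {
    out[[i]] <- sort(c(members(h$merge[i, 1]), members(h$merge[i, 2])))
  }
  out
}

#' Serialize a motif dendrogram as Newick
#'
#' Branch lengths, when requested, are height differences along the tree
#' (a leaf under a merge at height 0.3 gets branch length 0.3). Labels
#' containing Newick-special characters are single-quoted.
#'
#' @param tree A [cluster_motifs()] result.
#' @param with_heights Emit branch lengths? Default `TRUE`.
#' @return A single Newick string, semicolon-terminated.
#' @examples
#' fx <- table1_fixture()
#' to_newick(cluster_motifs(all_vs_all(fx$motifs, fx$matrix)))
#' @export
to_newick <- function(tree, with_heights = TRUE) {
  h <- tree$hclust
  lab <- function(x) {
    if (grepl("[][():;,'\" \t]", x)) paste0("'", gsub("'", "''", x), "'") else x
  }
  node <- function(k, parent_height) {
    if (k < 0) {
      s <- lab(h$labels[-k])
      child_height <- 0
    } else {
      s <- paste0("(", node(h$merge[k, 1], h$height[k]), ",",
                  node(h$merge[k, 2], h$height[k]), ")")
      child_height <- h$height[k]
    }
    if (with_heights && !is.na(parent_height)) {
      s <- paste0(s, ":", fmt_num(parent_height - child_height))
    }
    s
  }
  paste0(node(nrow(h$merge), NA_real_), ";")
}

#' Dendrogram as a nested list / JSON
#'
#' @param tree A [cluster_motifs()] result.
#' @return Nested list, each node `{label}` (leaf) or
#'   `{height, children}` (internal); pass to [jsonlite::toJSON()] for the
#'   JSON dump.
#' @export
tree_as_list <- function(tree) {
  h <- tree$hclust
  node <- function(k) {
    if (k < 0) list(label = h$labels[-k])
    else list(height = h$height[k],
              children = list(node(h$merge[k, 1]), node(h$merge[k, 2])))
  }
  node(nrow(h$merge))
}
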