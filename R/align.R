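# Motif alignment and scoring: the exclusive best-match pair list p{}
# between the cell types of two motifs, and the similarity index s()
# obtained by summing pair scores and normalising. This mirrors pairwise
# sequence alignment with the term-similarity matrix c() in the role of a
# substitution matrix, except that motifs are sets, so the "alignment" is a
# one-to-one matching rather than an ordered path.

#' Exclusive best-match alignment of two motifs
#'
#' Builds the pair list p\{\}: `min(|X|, |Y|)` one-to-one pairs of cell-type
#' terms (one per motif), each term in at most one pair.
#'
#' Strategies:
#' * `greedy` (default): repeatedly take the highest-scoring unused cross
#'   pair; ties broken lexicographically on `(term_x, term_y)` so results
#'   are deterministic.
#' * `optimal`: maximum-weight bipartite matching of the same size (via
#'   the Hungarian-type matcher in \pkg{igraph}); guards against
#'   rare cases where greedy choices block a better global pairing.
#'
#' @param x,y [make_motif()] objects.
#' @param sim A [sim_matrix()] covering every cell type of both motifs.
#' @param strategy `"greedy"` or `"optimal"`.
#' @return An object of class `pair_alignment`: list with `x_id`, `y_id`,
#'   `pairs` (data frame `term_x`, `term_y`, `c_score`, sorted by
#'   descending score then lexicographically), `unpaired_x`, `unpaired_y`,
#'   `strategy`.
#' @examples
#' fx <- table1_fixture()
#' align_motifs(fx$motifs$ptm_1, fx$motifs$ptm_2, fx$matrix)
#' @export
align_motifs <- function(x, y, sim, strategy = c("greedy", "optimal")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(x, "tissue_motif"), inherits(y, "tissue_motif"))
  tx <- x$cell_types
  ty <- y$cell_types
  w <- sim_lookup(sim, tx, ty)
  w <- matrix(w, nrow = length(tx), ncol = length(ty), dimnames = list(tx, ty))

  idx <- if (strategy == "greedy") greedy_matching(w) else optimal_matching(w)

  pairs <- data.frame(
    term_x = tx[idx[, 1]], term_y = ty[idx[, 2]],
    c_score = w[idx],
    stringsAsFactors = FALSE
  )
  pairs <- pairs[order(-pairs$c_score, pairs$term_x, pairs$term_y), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(
    list(x_id = x$motif_id, y_id = y$motif_id, pairs = pairs,
         unpaired_x = sort(setdiff(tx, pairs$term_x)),
         unpaired_y = sort(setdiff(ty, pairs$term_y)),
         strategy = strategy),
    class = "pair_alignment"
  )
}

# Static sorted scan is equivalent to iterated pick-the-global-max under
# the (-score, term_x, term_y) order.
greedy_matching <- function(w) {
  tx <- rownames(w); ty <- colnames(w)
  cand <- expand.grid(i = seq_along(tx), j = seq_along(ty))
  cand$score <- w[cbind(cand$i, cand$j)]
  cand <- cand[order(-cand$score, tx[cand$i], ty[cand$j]), , drop = FALSE]
  used_i <- logical(length(tx)); used_j <- logical(length(ty))
  n_target <- min(length(tx), length(ty))
  out <- matrix(0L, n_target, 2)
  k <- 0L
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (used_i[i] || used_j[j]) next
    used_i[i] <- used_j[j] <- TRUE
    k <- k + 1L
    out[k, ] <- c(i, j)
    if (k == n_target) break
  }
  out
}

# Maximum-weight bipartite matching. Shifting every weight by +2 (> any
# possible per-pair gain, weights being in [0,1]) makes maximum weight
# imply maximum cardinality, so the matching always has min(|X|,|Y|) pairs.
optimal_matching <- function(w) {
  nx <- nrow(w); ny <- ncol(w)
  g <- igraph::make_empty_graph(n = nx + ny, directed = FALSE)
  igraph::V(g)$type <- c(rep(FALSE, nx), rep(TRUE, ny))
  cand <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  g <- igraph::add_edges(g, rbind(cand$i, cand$j + nx))
  igraph::E(g)$weight <- w[cbind(cand$i, cand$j)] + 2
  m <- igraph::max_bipartite_match(g, types = igraph::V(g)$type,
                                   weights = igraph::E(g)$weight)$matching
  i <- seq_len(nx)
  j <- m[i] - nx
  keep <- !is.na(j)
  cbind(i[keep], j[keep])
}

#' @export
print.pair_alignment <- function(x, ...) {
  cat(sprintf("pair_alignment %s vs %s (%s): %d pair(s)\n",
              x$x_id, x$y_id, x$strategy, nrow(x$pairs)))
  for (i in seq_len(nrow(x$pairs))) {
    cat(sprintf("  %s - %s : %s\n", x$pairs$term_x[i], x$pairs$term_y[i],
                fmt_num(x$pairs$c_score[i])))
  }
  if (length(x$unpaired_x)) cat("  unpaired in x:", paste(x$unpaired_x, collapse = ", "), "\n")
  if (length(x$unpaired_y)) cat("  unpaired in y:", paste(x$unpaired_y, collapse = ", "), "\n")
  invisible(x)
}

#' Similarity index s() between two motifs
#'
#' Sums the pair scores of the exclusive best-match alignment and divides
#' by a normalising count. `divisor_mode = "pair_count"` (default) divides
#' by the number of pairs, `min(|X|, |Y|)`; `"average_size"` divides by the
#' mean motif size, `(|X| + |Y|) / 2`. With similarities in `[0, 1]`,
#' pair-count mode keeps `s` in `[0, 1]` and gives `s(x, x) = 1`.
#'
#' @inheritParams align_motifs
#' @param divisor_mode `"pair_count"` or `"average_size"`.
#' @return An object of class `motif_score`: list with `raw_sum`,
#'   `n_pairs`, `divisor_mode`, `divisor`, `value`, and the underlying
#'   `alignment`.
#' @examples
#' fx <- table1_fixture()
#' score_motifs(fx$motifs$ptm_1, fx$motifs$ptm_2, fx$matrix)$value
#' @export
score_motifs <- function(x, y, sim, strategy = c("greedy", "optimal"),
                         divisor_mode = c("pair_count", "average_size")) {
  divisor_mode <- match.arg(divisor_mode)
  aln <- align_motifs(x, y, sim, strategy)
  raw_sum <- sum(aln$pairs$c_score)
  n_pairs <- nrow(aln$pairs)
  divisor <- switch(divisor_mode,
    pair_count = n_pairs,
    average_size = (length(x$cell_types) + length(y$cell_types)) / 2
  )
  structure(
    list(raw_sum = raw_sum, n_pairs = n_pairs, divisor_mode = divisor_mode,
         divisor = divisor, value = raw_sum / divisor, alignment = aln),
    class = "motif_score"
  )
}

#' @export
print.motif_score <- function(x, ...) {
  cat(sprintf("motif_score %s vs %s: s = %s (%s/%s, %s)\n",
              x$alignment$x_id, x$alignment$y_id, fmt_num(x$value),
              fmt_num(x$raw_sum), fmt_num(x$divisor), x$divisor_mode))
  invisible(x)
}

#' All-vs-all motif similarity table
#'
#' Pairwise s() over a motif collection; the input to motif
#' classification.
#'
#' @param motifs List of at least two [make_motif()] objects with distinct
#'   ids.
#' @inheritParams score_motifs
#' @return A [sim_matrix()] whose rows/columns are motif ids (in input
#'   order), diagonal 1.
#' @export
all_vs_all <- function(motifs, sim, strategy = c("greedy", "optimal"),
                       divisor_mode = c("pair_count", "average_size")) {
  strategy <- match.arg(strategy)
  divisor_mode <- match.arg(divisor_mode)
  if (length(motifs) < 2) ftu_validation_error("all_vs_all needs at least two motifs")
  ids <- check_unique_ids(motifs)
  n <- length(motifs)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      m[i, j] <- m[j, i] <-
        score_motifs(motifs[[i]], motifs[[j]], sim, strategy, divisor_mode)$value
    }
  }
  sim_matrix(m)
}

#' Export an alignment report as JSON
#'
#' Machine-readable record of one comparison: motif ids, strategy, pair
#' list with scores, unpaired leftovers, and the resulting s() with its
#' decomposition.
#'
#' @param x,y,sim,strategy,divisor_mode As in [score_motifs()].
#' @param digits Decimal places for the reported (not internal) `s`;
#'   rounding is half-up.
#' @return A list ready for [jsonlite::toJSON()]; used by the command-line
#'   interface.
#' @export
alignment_report <- function(x, y, sim, strategy = c("greedy", "optimal"),
                             divisor_mode = c("pair_count", "average_size"),
                             digits = 2) {
  sc <- score_motifs(x, y, sim, strategy, divisor_mode)
  aln <- sc$alignment
  list(
    x = aln$x_id, y = aln$y_id,
    strategy = aln$strategy, divisor_mode = sc$divisor_mode,
    pairs = lapply(seq_len(nrow(aln$pairs)), function(i) {
      list(x = aln$pairs$term_x[i], y = aln$pairs$term_y[i],
           c = aln$pairs$c_score[i])
    }),
    unpaired_x = as.list(aln$unpaired_x),
    unpaired_y = as.list(aln$unpaired_y),
    raw_sum = sc$raw_sum, divisor = sc$divisor,
    s = round_half_up(sc$value, digits)
  )
}
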