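# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, fixed-point closure,
# dense resampling.

# all permutations of a vector (tiny n only)
perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

# maximum pair-score sum over all complete matchings of a weight matrix
brute_best_matching <- function(w) {
  if (nrow(w) > ncol(w)) w <- t(w)
  n <- nrow(w)
  best <- -Inf
  for (p in perms(seq_len(ncol(w)))) {
    best <- max(best, sum(w[cbind(seq_len(n), p[seq_len(n)])]))
  }
  best
}

# independent re-implementation of greedy exclusive pairing with the
# lexicographic (term_x, term_y) tie-break
greedy_reference <- function(w) {
  tx <- rownames(w); ty <- colnames(w)
  pairs <- NULL
  repeat {
    if (nrow(w) == 0 || ncol(w) == 0) break
    mx <- max(w)
    hits <- which(w == mx, arr.ind = TRUE)
    hits <- hits[order(rownames(w)[hits[, 1]], colnames(w)[hits[, 2]]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    pairs <- rbind(pairs, data.frame(term_x = rownames(w)[i],
                                     term_y = colnames(w)[j],
                                     c_score = w[i, j],
                                     stringsAsFactors = FALSE))
    w <- w[-i, -j, drop = FALSE]
  }
  pairs
}

# ancestor set by fixed-point expansion over the raw edge list
brute_ancestors <- function(graph, term, reflexive = FALSE) {
  cur <- term
  repeat {
    nxt <- union(cur, graph$edges$parent[graph$edges$child %in% cur])
    if (setequal(nxt, cur)) break
    cur <- nxt
  }
  if (reflexive) cur else setdiff(cur, term)
}

# min distance from points to a densely resampled polyline
resampled_min_dist <- function(capillary, points, step = 0.01) {
  pl <- capillary$polyline
  samp <- do.call(rbind, lapply(seq_len(nrow(pl) - 1), function(k) {
    a <- pl[k, ]; b <- pl[k + 1, ]
    n <- max(2, ceiling(sqrt(sum((b - a)^2)) / step))
    t <- seq(0, 1, length.out = n)
    outer(t, b - a) + matrix(a, n, 3, byrow = TRUE)
  }))
  pts <- as.matrix(points)
  vapply(seq_len(nrow(pts)), function(i) {
    sqrt(min(rowSums(sweep(samp, 2, pts[i, ])^2)))
  }, numeric(1))
}

# a proper rotation matrix from a seeded random QR decomposition
random_rotation <- function(seed) {
  withr::with_seed(seed, {
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}

# write a minimal 3-term chain OBO file: leaf is_a mid is_a root
write_chain_obo <- function(path) {
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: X_0000001", "name: root", "",
    "[Term]", "id: X_0000002", "name: mid", "is_a: X_0000001 ! root", "",
    "[Term]", "id: X_0000003", "name: leaf", "is_a: X_0000002 ! mid", ""
  ), path)
  path
}
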