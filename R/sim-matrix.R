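# The term-similarity matrix c(): symmetric, unit diagonal, values in [0,1].
# Plays the role an amino-acid substitution matrix plays in sequence
# alignment, but over cell-type ontology terms.

#' Construct a term-similarity matrix
#'
#' Validates and classes a square numeric matrix of pairwise term
#' similarities: symmetric, diagonal exactly 1, all entries in `[0, 1]`,
#' with term accessions as dimnames.
#'
#' @param values Square numeric matrix with identical row and column names.
#' @param tol Numerical tolerance for the symmetry and diagonal checks.
#' @return The matrix, classed `sim_matrix`, diagonal snapped to exactly 1.
#' @seealso [build_matrix()], [read_matrix_tsv()]
#' @export
sim_matrix <- function(values, tol = 1e-8) {
  if (!is.matrix(values) || !is.numeric(values)) {
    ftu_validation_error("similarity matrix must be a numeric matrix")
  }
  if (nrow(values) != ncol(values)) {
    ftu_validation_error("similarity matrix must be square")
  }
  terms <- rownames(values)
  if (is.null(terms) || is.null(colnames(values))) {
    ftu_validation_error("similarity matrix needs term ids as row and column names")
  }
  if (!identical(terms, colnames(values))) {
    ftu_validation_error("row and column term order must be identical")
  }
  if (anyDuplicated(terms)) {
    ftu_validation_error(sprintf("duplicate term id: %s", terms[duplicated(terms)][1]))
  }
  asym <- abs(values - t(values))
  if (any(asym > tol)) {
    w <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    ftu_validation_error(sprintf(
      "similarity matrix is asymmetric: worst cell (%s, %s), |%.6g - %.6g| = %.3g",
      terms[w[1]], terms[w[2]], values[w[1], w[2]], values[w[2], w[1]], max(asym)))
  }
  if (any(abs(diag(values) - 1) > tol)) {
    w <- which.max(abs(diag(values) - 1))
    ftu_validation_error(sprintf("diagonal must be 1.0; term %s has %.6g",
                                 terms[w], diag(values)[w]))
  }
  if (any(values < -tol) || any(values > 1 + tol)) {
    w <- which(values < -tol | values > 1 + tol, arr.ind = TRUE)[1, ]
    ftu_validation_error(sprintf("similarity out of [0,1]: cell (%s, %s) = %.6g",
                                 terms[w[1]], terms[w[2]], values[w[1], w[2]]))
  }
  diag(values) <- 1
  values[values < 0] <- 0
  values[values > 1] <- 1
  class(values) <- c("sim_matrix", class(matrix()))
  values
}

#' @export
print.sim_matrix <- function(x, ...) {
  cat(sprintf("sim_matrix: %d terms\n", nrow(x)))
  print(unclass(x), ...)
  invisible(x)
}

sim_lookup <- function(m, a, b) {
  for (t in unique(c(a, b))) {
    if (!t %in% rownames(m)) {
      ftu_lookup_error(sprintf("term not in similarity matrix: %s", t))
    }
  }
  m[a, b]
}

#' Read / write a similarity matrix as TSV
#'
#' Dialect: UTF-8, tab-separated, `.` decimal separator, no quoting; header
#' row of term accessions preceded by a `term_id` corner cell, one id-led
#' row per term, values written at 6 decimal places. Reading validates that
#' row and column term sets match and that the matrix passes [sim_matrix()]
#' checks; parse errors report the offending cell.
#'
#' @param path File path.
#' @return `read_matrix_tsv()`: a [sim_matrix()]. `write_matrix_tsv()`:
#'   `path`, invisibly.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) ftu_io_error(sprintf("cannot read matrix TSV: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) ftu_parse_error(sprintf("matrix TSV too short: %s", path))
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  row_ids <- vapply(rows, `[[`, character(1), 1)
  miss_r <- setdiff(header, row_ids)
  miss_c <- setdiff(row_ids, header)
  if (length(miss_r) > 0) ftu_parse_error(sprintf("term %s has a column but no row", miss_r[1]))
  if (length(miss_c) > 0) ftu_parse_error(sprintf("term %s has a row but no column", miss_c[1]))
  n <- length(header)
  m <- matrix(NA_real_, n, n, dimnames = list(row_ids, header))
  for (i in seq_len(n)) {
    cells <- rows[[i]][-1]
    if (length(cells) != n) {
      ftu_parse_error(sprintf("row %s has %d cells, expected %d", row_ids[i], length(cells), n))
    }
    vals <- suppressWarnings(as.numeric(cells))
    if (anyNA(vals)) {
      j <- which(is.na(vals))[1]
      ftu_parse_error(sprintf("non-numeric cell at row %s, column %s: '%s'",
                              row_ids[i], header[j], cells[j]))
    }
    m[i, ] <- vals
  }
  m <- m[, row_ids, drop = FALSE]   # align column order to row order
  sim_matrix(m)
}

#' @rdname read_matrix_tsv
#' @param matrix A [sim_matrix()] (or any validatable square matrix).
#' @export
write_matrix_tsv <- function(matrix, path) {
  m <- sim_matrix(unclass(matrix))
  ids <- rownames(m)
  body <- vapply(seq_along(ids), function(i) {
    paste(c(ids[i], sprintf("%.6f", m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(paste(c("term_id", ids), collapse = "\t"), body), path, useBytes = TRUE)
  invisible(path)
}
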