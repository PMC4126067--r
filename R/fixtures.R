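# Worked five-tissue example and seeded synthetic-data generators. The
# fixture bundles the published comparison of five motifs (hepatic,
# cardiac, pulmonary, colonic, gastric) over 15 Cell Ontology terms; the
# generators produce random ontology DAGs and FTU point clouds so every
# component is testable without any download.

# Printed best-pair term-similarity values from the five-tissue example;
# all unprinted cross pairs take the filler value below.
TABLE1_FILLER <- 0.05

table1_motif_terms <- function() {
  list(
    ptm_1 = c("CL_0000182", "CL_0000632", "CL_0000057", "CL_0000091", "CL_0000115"),
    ptm_2 = c("CL_0002068", "CL_0000057", "CL_0000746", "CL_0000115"),
    ptm_3 = c("CL_0000158", "CL_0000082", "CL_0000057", "CL_0002598", "CL_0000115"),
    ptm_4 = c("CL_1000320", "CL_0002071", "CL_0000057", "CL_0000115"),
    ptm_5 = c("CL_0002182", "CL_0000508", "CL_0000057", "CL_1000323", "CL_0000115")
  )
}

table1_printed_cross_pairs <- function() {
  # term_a, term_b, printed c() -- order within a pair is not meaningful
  rows <- list(
    c("CL_0000182", "CL_0000746", 0.29), c("CL_0000632", "CL_0002068", 0.25),
    c("CL_0000182", "CL_0000082", 0.46), c("CL_0000632", "CL_0000158", 0.30),
    c("CL_0000091", "CL_0002598", 0.23),
    c("CL_0000182", "CL_0002071", 0.30), c("CL_0000632", "CL_1000320", 0.24),
    c("CL_0000182", "CL_0000508", 0.32), c("CL_0000632", "CL_0002182", 0.29),
    c("CL_0000091", "CL_1000323", 0.17),
    c("CL_0002598", "CL_0000746", 0.64), c("CL_0000082", "CL_0002068", 0.25),
    c("CL_0000746", "CL_0002071", 0.22), c("CL_0002068", "CL_1000320", 0.17),
    c("CL_0000508", "CL_0000746", 0.23), c("CL_0002182", "CL_0002068", 0.20),
    c("CL_0000158", "CL_1000320", 0.30), c("CL_0000082", "CL_0002071", 0.29),
    c("CL_0000158", "CL_0002182", 0.35), c("CL_0000082", "CL_0000508", 0.31),
    c("CL_0002598", "CL_1000323", 0.21),
    c("CL_1000323", "CL_1000320", 0.52), c("CL_0002182", "CL_0002071", 0.33)
  )
  data.frame(
    term_a = vapply(rows, `[[`, character(1), 1),
    term_b = vapply(rows, `[[`, character(1), 2),
    c_score = as.numeric(vapply(rows, `[[`, character(1), 3)),
    stringsAsFactors = FALSE
  )
}

#' The packaged five-tissue worked example
#'
#' Deterministically reconstructs the published comparison of five primary
#' tissue motifs (hepatic `ptm_1`, cardiac `ptm_2`, pulmonary `ptm_3`,
#' colonic `ptm_4`, gastric `ptm_5`) over 15 Cell Ontology terms:
#'
#' * `motifs`: the five motifs, with tissue-of-origin locations;
#' * `matrix`: a 15 x 15 term-similarity matrix holding every published
#'   best-pair c() value, diagonal 1, and a filler of 0.05 (strictly below
#'   the smallest published pair score, 0.17) for every unpublished cross
#'   pair. The matrix is therefore a *reconstruction* sufficient to
#'   reproduce the published pairings and scores, not a computed
#'   similarity matrix: the original values came from an external
#'   annotated-ontology calculation whose full table was never released.
#' * `expected`: data frame of all 15 comparisons with the published
#'   rounded score (`s_printed`);
#' * `pairs`: for each off-diagonal comparison (named `"x|y"`), the
#'   published exclusive best-match pair list with c() scores.
#'
#' @return A list as described, class `table1_fixture`.
#' @examples
#' fx <- table1_fixture()
#' length(motif_union(fx$motifs)$cell_types) # 15
#' @export
table1_fixture <- function() {
  mt <- table1_motif_terms()
  locations <- c(ptm_1 = "liver", ptm_2 = "heart", ptm_3 = "lung",
                 ptm_4 = "colon", ptm_5 = "stomach")
  motifs <- lapply(names(mt), function(id) make_motif(id, mt[[id]], locations[[id]]))
  names(motifs) <- names(mt)

  terms <- unique(unlist(mt, use.names = FALSE))
  n <- length(terms)
  m <- matrix(TABLE1_FILLER, n, n, dimnames = list(terms, terms))
  diag(m) <- 1
  cp <- table1_printed_cross_pairs()
  for (i in seq_len(nrow(cp))) {
    m[cp$term_a[i], cp$term_b[i]] <- m[cp$term_b[i], cp$term_a[i]] <- cp$c_score[i]
  }

  combos <- expand.grid(xi = 1:5, yi = 1:5)
  combos <- combos[combos$xi <= combos$yi, ]
  combos <- combos[order(combos$xi, combos$yi), ]
  s_printed <- c(1.0, 0.64, 0.6, 0.64, 0.55,
                 1.0, 0.72, 0.6, 0.6,
                 1.0, 0.64, 0.57,
                 1.0, 0.71,
                 1.0)
  expected <- data.frame(
    x = names(mt)[combos$xi], y = names(mt)[combos$yi],
    s_printed = s_printed, stringsAsFactors = FALSE
  )

  pair_rows <- list(
    "ptm_1|ptm_2" = rbind(id_pairs(c("CL_0000057", "CL_0000115")),
                          cp[c(1, 2), ]),
    "ptm_1|ptm_3" = rbind(id_pairs(c("CL_0000057", "CL_0000115")),
                          cp[c(3, 4, 5), ]),
    "ptm_1|ptm_4" = rbind(id_pairs(c("CL_0000057", "CL_0000115")),
                          cp[c(6, 7), ]),
    "ptm_1|ptm_5" = rbind(id_pairs(c("CL_0000057", "CL_0000115")),
                          cp[c(8, 9, 10), ]),
    "ptm_2|ptm_3" = rbind(id_pairs(c("CL_0000057", "CL_0000115")),
                          cp[c(11, 12), ]),
    "ptm_2|ptm_4" = rbind(id_pairs(c("CL_0000057", "CL_0000115")),
                          cp[c(13, 14), ]),
    "ptm_2|ptm_5" = rbind(id_pairs(c("CL_0000057", "CL_0000115")),
                          cp[c(15, 16), ]),
    "ptm_3|ptm_4" = rbind(id_pairs(c("CL_0000057", "CL_0000115")),
                          cp[c(17, 18), ]),
    "ptm_3|ptm_5" = rbind(id_pairs(c("CL_0000057", "CL_0000115")),
                          cp[c(19, 20, 21), ]),
    "ptm_4|ptm_5" = rbind(id_pairs(c("CL_0000057", "CL_0000115")),
                          cp[c(22, 23), ])
  )
  pair_rows <- lapply(pair_rows, function(df) { rownames(df) <- NULL; df })

  structure(list(motifs = motifs, matrix = sim_matrix(m),
                 expected = expected, pairs = pair_rows),
            class = "table1_fixture")
}

id_pairs <- function(terms) {
  data.frame(term_a = terms, term_b = terms, c_score = 1.0,
             stringsAsFactors = FALSE)
}

#' Generate a random ontology DAG
#'
#' Terms `TS_0001 ... TS_n`; each term after the first draws 1 to
#' `max_parents` `is_a` parents uniformly from the earlier terms, so the
#' graph is acyclic by construction and rooted at `TS_0001`.
#'
#' @param n_terms Number of terms (>= 1).
#' @param max_parents Maximum parents per term (default 2).
#' @param seed Integer seed; same seed, same graph.
#' @return An [ontology_graph()].
#' @export
gen_dag_ontology <- function(n_terms, max_parents = 2, seed = 1) {
  stopifnot(n_terms >= 1, max_parents >= 1)
  terms <- sprintf("TS_%04d", seq_len(n_terms))
  edges <- withr::with_seed(seed, {
    ch <- pa <- character()
    for (i in seq_len(n_terms)[-1]) {
      k <- sample.int(min(max_parents, i - 1), 1)
      parents <- if (i == 2) 1L else sample.int(i - 1, k)
      ch <- c(ch, rep(terms[i], length(parents)))
      pa <- c(pa, terms[parents])
    }
    data.frame(child = ch, parent = pa, relation = rep("is_a", length(ch)),
               stringsAsFactors = FALSE)
  })
  ontology_graph(terms, edges)
}

#' Generate a synthetic FTU point cloud with known membership
#'
#' Emulates an annotated capillary neighbourhood: a straight capillary
#' along the x axis, member cells placed uniformly inside the FTU cylinder
#' (each motif cell type appearing at least once), and a `noise_frac`
#' share of cells placed radially outside the cylinder wall and
#' ground-truth labelled as non-members.
#'
#' @param motif A [make_motif()]: the generating cell-type set.
#' @param n_cells Total cells (>= the number of motif cell types).
#' @param cylinder List with `diameter`, `length` (um); default the
#'   optimal cylinder for a 100-um diffusion span.
#' @param noise_frac Fraction of cells generated outside the cylinder
#'   (default 0).
#' @param seed Integer seed; same seed, byte-identical output.
#' @return List with `cells` (data frame `cell_id,x,y,z,cell_type`),
#'   `capillary` (a [capillary_segment()] spanning the cylinder axis),
#'   `membership` (logical ground truth per cell row), `motif`,
#'   `cylinder`.
#' @export
gen_ftu_pointcloud <- function(motif, n_cells,
                               cylinder = optimal_cylinder(100),
                               noise_frac = 0, seed = 1) {
  stopifnot(inherits(motif, "tissue_motif"),
            noise_frac >= 0, noise_frac < 1)
  types <- motif$cell_types
  n_noise <- floor(n_cells * noise_frac)
  n_member <- n_cells - n_noise
  if (n_member < length(types)) {
    ftu_validation_error("n_cells too small to show every motif cell type")
  }
  r_max <- cylinder$diameter / 2
  l <- cylinder$length
  cells <- withr::with_seed(seed, {
    # members: uniform in the cylinder (area-uniform radius)
    xm <- stats::runif(n_member, 0, l)
    # 0.01-um inset keeps rounded coordinates strictly inside the wall
    rm_ <- (r_max - 0.01) * sqrt(stats::runif(n_member))
    am <- stats::runif(n_member, 0, 2 * pi)
    tm <- c(types, sample(types, n_member - length(types), replace = TRUE))
    # noise: same axial window, strictly outside the cylinder wall
    xn <- stats::runif(n_noise, 0, l)
    rn <- stats::runif(n_noise, r_max + 1, r_max + 30)
    an <- stats::runif(n_noise, 0, 2 * pi)
    tn <- if (n_noise > 0) sample(types, n_noise, replace = TRUE) else character()
    df <- data.frame(
      cell_id = sprintf("cell_%04d", seq_len(n_cells)),
      x = round(c(xm, xn), 3),
      y = round(c(rm_ * cos(am), rn * cos(an)), 3),
      z = round(c(rm_ * sin(am), rn * sin(an)), 3),
      cell_type = c(tm, tn),
      stringsAsFactors = FALSE
    )
    df[sample.int(n_cells), , drop = FALSE]   # shuffle member/noise order
  })
  member_ids <- sprintf("cell_%04d", seq_len(n_member))
  membership <- cells$cell_id %in% member_ids
  rownames(cells) <- NULL
  list(
    cells = cells,
    capillary = capillary_segment(rbind(c(0, 0, 0), c(l, 0, 0))),
    membership = membership,
    motif = motif,
    cylinder = cylinder
  )
}

#' Paths to the shipped fixture files
#'
#' The five-tissue example is also shipped as plain-text files
#' (`table1_motifs.json`, `table1_matrix.tsv`) so the file readers can be
#' exercised and external tools can consume the example directly. Their
#' content equals [table1_fixture()].
#'
#' @param file File name within the package's `extdata`, or `NULL` to list.
#' @return Full path(s).
#' @export
ftu_example_file <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "ftumotifs"), full.names = TRUE)
  } else {
    p <- system.file("extdata", file, package = "ftumotifs")
    if (p == "") ftu_io_error(sprintf("no packaged file '%s'", file))
    p
  }
}
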