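# FTU biophysical geometry. An FTU is a cylindrical block of tissue whose
# long axis is the feeding capillary, constrained so no two cells are more
# than d_max (~100 um) apart -- the span over which diffusion remains an
# effective transport mechanism. Among cylinders satisfying the constraint
# the canonical choice maximises volume (greatest mass of metabolic
# machinery), which fixes diameter and length in closed form.

#' Geometry parameters for FTU extraction
#'
#' @param d_max Maximum cell-to-cell diffusion span in micrometres
#'   (default 100): the distance beyond which diffusive exchange is no
#'   longer effective.
#' @param capillary_proximity Maximum distance from a cell to its feeding
#'   capillary, micrometres (default 50, i.e. `d_max / 2`).
#' @param dilation_radius Radius of the approximate diffusive field drawn
#'   around a vessel lumen when annotating images, micrometres
#'   (default 40).
#' @return An object of class `geometry_params`.
#' @export
geometry_params <- function(d_max = 100, capillary_proximity = 50,
                            dilation_radius = 40) {
  if (d_max <= 0 || capillary_proximity <= 0 || dilation_radius <= 0) {
    ftu_validation_error("all geometry parameters must be strictly positive")
  }
  if (capillary_proximity > d_max / 2) {
    ftu_validation_error("capillary_proximity must not exceed d_max / 2")
  }
  structure(list(d_max = d_max, capillary_proximity = capillary_proximity,
                 dilation_radius = dilation_radius),
            class = "geometry_params")
}

#' Maximal-volume FTU cylinder
#'
#' Maximises the cylinder volume `pi (d/2)^2 L` subject to the diffusion
#' constraint that the cylinder's space diagonal not exceed `d_max`:
#' `sqrt(d^2 + L^2) <= d_max` (the two most distant points of a cylinder
#' are diametrically opposite corners). The optimum is on the constraint
#' boundary, at `d = d_max sqrt(2/3)`, `L = d_max / sqrt(3)`: for the
#' canonical 100-um diffusion span, a diameter of ~81.6 um and length of
#' ~57.7 um (about 80 by 60 um).
#'
#' @param d_max Diffusion span in micrometres.
#' @return List with `diameter`, `length` (um) and `volume` (um^3).
#' @examples
#' optimal_cylinder(100)
#' @export
optimal_cylinder <- function(d_max = 100) {
  if (!is.numeric(d_max) || length(d_max) != 1 || !is.finite(d_max) || d_max <= 0) {
    ftu_validation_error("d_max must be a single positive number")
  }
  d <- d_max * sqrt(2 / 3)
  l <- d_max / sqrt(3)
  list(diameter = d, length = l, volume = pi * (d / 2)^2 * l)
}

#' Construct a capillary segment
#'
#' The capillary axis as an ordered 3D polyline (micrometres); real vessels
#' are rarely straight or orthogonal to the section plane, so a polyline is
#' the general form and a straight axis is the 2-point special case.
#'
#' @param polyline Numeric matrix with >= 2 rows and 3 columns (x, y, z in
#'   um); consecutive points must be distinct.
#' @param lumen_radius Lumen radius in um (metadata; default 4).
#' @return An object of class `capillary_segment` with the polyline,
#'   per-vertex cumulative arc length, and `lumen_radius`.
#' @export
capillary_segment <- function(polyline, lumen_radius = 4) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2 || ncol(polyline) != 3 || !all(is.finite(polyline))) {
    ftu_validation_error("capillary polyline needs >= 2 finite 3D points")
  }
  seg <- diff(polyline)
  seg_len <- sqrt(rowSums(seg^2))
  if (any(seg_len == 0)) {
    ftu_validation_error("consecutive capillary polyline points must be distinct")
  }
  dimnames(polyline) <- list(NULL, c("x", "y", "z"))
  structure(list(polyline = polyline, arc = c(0, cumsum(seg_len)),
                 lumen_radius = lumen_radius),
            class = "capillary_segment")
}

# Closest point on the polyline for each query point. Returns, per point:
# dist (to the closest point on the polyline) and arc (arc length of that
# closest point along the axis). For points radially alongside a segment,
# dist is the perpendicular distance to the axis.
project_polyline <- function(capillary, points) {
  pts <- as.matrix(points)
  pl <- capillary$polyline
  n_seg <- nrow(pl) - 1
  best_d2 <- rep(Inf, nrow(pts))
  best_arc <- rep(NA_real_, nrow(pts))
  for (k in seq_len(n_seg)) {
    a <- pl[k, ]; b <- pl[k + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    ap <- sweep(pts, 2, a)
    t <- pmin(1, pmax(0, as.vector(ap %*% ab) / len2))
    closest <- outer(t, ab) + matrix(a, nrow(pts), 3, byrow = TRUE)
    d2 <- rowSums((pts - closest)^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_arc[upd] <- capillary$arc[k] + t[upd] * sqrt(len2)
  }
  data.frame(dist = sqrt(best_d2), arc = best_arc)
}

#' Select the cells of an FTU cylinder around a capillary
#'
#' A cell belongs to the FTU when its radial distance to the capillary axis
#' is at most `d/2` and its arc-length projection falls within the
#' cylinder's axial window `[axial_origin, axial_origin + L]`. All distance
#' thresholds are closed (boundary cells included).
#'
#' @param cells Data frame with columns `cell_id`, `x`, `y`, `z` (um) and
#'   `cell_type` (term accessions). See [read_cells_csv()].
#' @param capillary A [capillary_segment()].
#' @param params A [geometry_params()]; the cylinder must satisfy
#'   `sqrt(d^2 + L^2) <= d_max`.
#' @param cylinder List with `diameter` and `length` (um); default the
#'   [optimal_cylinder()] for `params$d_max`.
#' @param axial_origin Arc-length start of the cylinder along the
#'   capillary, um (default 0).
#' @param ftu_id Identifier for the resulting model.
#' @param location Optional anatomical location to record.
#' @return An object of class `ftu_model`: list with `ftu_id`, `capillary`,
#'   `cells` (the included rows, plus their `radial` and `arc`
#'   coordinates), `cylinder`, `axial_origin`, `anatomical_location`,
#'   `params`. An empty selection warns rather than errs.
#' @export
cells_in_ftu <- function(cells, capillary, params = geometry_params(),
                         cylinder = optimal_cylinder(params$d_max),
                         axial_origin = 0, ftu_id = "ftu", location = NULL) {
  check_cells_df(cells)
  stopifnot(inherits(capillary, "capillary_segment"),
            inherits(params, "geometry_params"))
  d <- cylinder$diameter; l <- cylinder$length
  if (sqrt(d^2 + l^2) > params$d_max * (1 + 1e-9)) {
    ftu_validation_error(sprintf(
      "cylinder diagonal %.3f um exceeds the diffusion span d_max = %g um",
      sqrt(d^2 + l^2), params$d_max))
  }
  proj <- project_polyline(capillary, cells[, c("x", "y", "z")])
  inside <- proj$dist <= d / 2 &
    proj$arc >= axial_origin & proj$arc <= axial_origin + l
  sel <- cells[inside, , drop = FALSE]
  sel$radial <- proj$dist[inside]
  sel$arc <- proj$arc[inside]
  rownames(sel) <- NULL
  if (nrow(sel) == 0) {
    warning("cells_in_ftu: no cell falls inside the FTU cylinder")
  }
  structure(
    list(ftu_id = ftu_id, capillary = capillary, cells = sel,
         cylinder = list(diameter = d, length = l),
         axial_origin = axial_origin,
         anatomical_location = location %||% NA_character_,
         params = params),
    class = "ftu_model"
  )
}

#' @export
print.ftu_model <- function(x, ...) {
  cat(sprintf("ftu_model %s: %d cells, cylinder %.1f x %.1f um\n",
              x$ftu_id, nrow(x$cells), x$cylinder$diameter, x$cylinder$length))
  invisible(x)
}

#' Check the pairwise diffusion constraint of an FTU model
#'
#' Lists every pair of cells farther apart than `d_max`. For cells selected
#' by the optimal cylinder this list is empty by construction, since the
#' cylinder's space diagonal equals `d_max`.
#'
#' @param model An [cells_in_ftu()] result with at least one cell.
#' @param params A [geometry_params()]; defaults to the model's own.
#' @return An object of class `diffusion_report`: list with `n_cells`,
#'   `d_max` and `violations`, a data frame (`cell_a`, `cell_b`,
#'   `distance`) of offending pairs.
#' @export
validate_diffusion <- function(model, params = model$params) {
  stopifnot(inherits(model, "ftu_model"))
  cells <- model$cells
  if (nrow(cells) == 0) ftu_validation_error("model has no cells to validate")
  dm <- as.matrix(stats::dist(cells[, c("x", "y", "z")]))
  bad <- which(upper.tri(dm) & dm > params$d_max, arr.ind = TRUE)
  violations <- data.frame(
    cell_a = cells$cell_id[bad[, 1]],
    cell_b = cells$cell_id[bad[, 2]],
    distance = dm[bad],
    stringsAsFactors = FALSE
  )
  structure(list(n_cells = nrow(cells), d_max = params$d_max,
                 violations = violations),
            class = "diffusion_report")
}

#' @export
print.diffusion_report <- function(x, ...) {
  cat(sprintf("diffusion_report: %d cells, d_max = %g um, %d violation(s)\n",
              x$n_cells, x$d_max, nrow(x$violations)))
  invisible(x)
}

#' Membership in the diffusive field of a vessel
#'
#' Emulates the dilation step of image annotation: a point belongs to the
#' approximate diffusive field when its distance to the vessel axis
#' polyline is at most `radius` (closed boundary).
#'
#' @param capillary A [capillary_segment()].
#' @param radius Field radius in um (e.g. 40 for the annotation dilation,
#'   50 for the canonical capillary proximity).
#' @param points Numeric matrix/data frame of 3D positions (um).
#' @return Logical vector, one flag per point.
#' @export
diffusive_field <- function(capillary, radius, points) {
  stopifnot(inherits(capillary, "capillary_segment"))
  if (!is.numeric(radius) || radius <= 0) {
    ftu_validation_error("radius must be strictly positive")
  }
  project_polyline(capillary, points)$dist <= radius
}

#' Extract the primary tissue motif of an FTU model
#'
#' The motif is the set of distinct cell types among the model's cells; the
#' anatomical location is carried over.
#'
#' @param model An [cells_in_ftu()] result with at least one cell.
#' @param motif_id Identifier for the motif; defaults to the model's
#'   `ftu_id`.
#' @return A [make_motif()] object.
#' @export
extract_ptm <- function(model, motif_id = model$ftu_id) {
  stopifnot(inherits(model, "ftu_model"))
  if (nrow(model$cells) == 0) {
    ftu_validation_error("cannot extract a motif from an empty FTU model")
  }
  make_motif(motif_id, unique(model$cells$cell_type),
             location = if (is.na(model$anatomical_location)) NULL
                        else model$anatomical_location)
}

check_cells_df <- function(cells) {
  need <- c("cell_id", "x", "y", "z", "cell_type")
  if (!is.data.frame(cells) || !all(need %in% names(cells))) {
    ftu_validation_error(sprintf("cell table needs columns: %s",
                                 paste(need, collapse = ", ")))
  }
  if (!all(is.finite(as.matrix(cells[, c("x", "y", "z")])))) {
    ftu_validation_error("cell coordinates must be finite")
  }
  invisible(cells)
}

#' Read / write cell point clouds and capillary polylines as CSV
#'
#' Cell CSV columns: `cell_id,x,y,z,cell_type` (header required,
#' coordinates in micrometres). Capillary CSV columns: `x,y,z`, rows in
#' axis order.
#'
#' @param path File path.
#' @return `read_cells_csv()`: a data frame of cells;
#'   `read_capillary_csv()`: a [capillary_segment()]; writers return
#'   `path` invisibly.
#' @export
read_cells_csv <- function(path) {
  if (!file.exists(path)) ftu_io_error(sprintf("cannot read cell CSV: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "x", "y", "z", "cell_type")
  if (!all(need %in% names(df))) {
    ftu_parse_error(sprintf("cell CSV %s needs header columns: %s",
                            path, paste(need, collapse = ",")))
  }
  check_cells_df(df[, need])
}

#' @rdname read_cells_csv
#' @param cells Data frame of cells.
#' @export
write_cells_csv <- function(cells, path) {
  check_cells_df(cells)
  utils::write.csv(cells[, c("cell_id", "x", "y", "z", "cell_type")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_cells_csv
#' @param lumen_radius Lumen radius metadata for the capillary, um.
#' @export
read_capillary_csv <- function(path, lumen_radius = 4) {
  if (!file.exists(path)) ftu_io_error(sprintf("cannot read capillary CSV: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y", "z") %in% names(df))) {
    ftu_parse_error(sprintf("capillary CSV %s needs header columns: x,y,z", path))
  }
  capillary_segment(as.matrix(df[, c("x", "y", "z")]), lumen_radius = lumen_radius)
}

#' @rdname read_cells_csv
#' @param capillary A [capillary_segment()].
#' @export
write_capillary_csv <- function(capillary, path) {
  stopifnot(inherits(capillary, "capillary_segment"))
  utils::write.csv(as.data.frame(capillary$polyline), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
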