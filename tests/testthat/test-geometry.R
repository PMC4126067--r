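test_that("the maximal-volume cylinder has the closed-form dimensions", {
  cyl <- optimal_cylinder(100)
  expect_equal(cyl$diameter, 100 * sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(cyl$length, 100 / sqrt(3), tolerance = 1e-12)
  # constraint active: the space diagonal equals the diffusion span
  expect_equal(sqrt(cyl$diameter^2 + cyl$length^2), 100, tolerance = 1e-9)
  # rounded to the nearest 10 um: the canonical 80 x 60 um block
  expect_equal(round(cyl$diameter / 10) * 10, 80)
  expect_equal(round(cyl$length / 10) * 10, 60)

  big <- optimal_cylinder(200)
  expect_equal(big$diameter, 2 * cyl$diameter)
  expect_equal(big$length, 2 * cyl$length)

  expect_error(optimal_cylinder(0), class = "ftu_validation_error")
  expect_error(optimal_cylinder(-5), class = "ftu_validation_error")
})

test_that("closed form beats a 200x200 grid search over feasible cylinders", {
  cyl <- optimal_cylinder(100)
  d <- seq(1, 100, length.out = 200)
  l <- seq(1, 100, length.out = 200)
  grid <- expand.grid(d = d, l = l)
  grid <- grid[sqrt(grid$d^2 + grid$l^2) <= 100, ]
  expect_gte(cyl$volume, max(pi * (grid$d / 2)^2 * grid$l))
})

test_that("perturbing the optimum along the constraint surface lowers volume", {
  cyl <- optimal_cylinder(100)
  for (eps in c(-0.01, 0.01)) {
    d <- cyl$diameter * (1 + eps)
    l <- sqrt(100^2 - d^2)   # stay on the constraint boundary
    expect_lte(pi * (d / 2)^2 * l, cyl$volume)
  }
})

test_that("geometry parameters are validated", {
  expect_error(geometry_params(d_max = -1), class = "ftu_validation_error")
  expect_error(geometry_params(capillary_proximity = 60), class = "ftu_validation_error")
  expect_silent(geometry_params())
  expect_error(capillary_segment(matrix(0, 1, 3)), class = "ftu_validation_error")
  expect_error(capillary_segment(rbind(c(0, 0, 0), c(0, 0, 0))),
               class = "ftu_validation_error")
})

test_that("cylinder membership has closed boundaries and exact edges", {
  cap <- capillary_segment(rbind(c(0, 0, 0), c(100, 0, 0)))
  cyl <- optimal_cylinder(100)
  r <- cyl$diameter / 2
  cells <- data.frame(
    cell_id = c("on_axis", "on_wall", "just_out", "past_end"),
    x = c(cyl$length / 2, cyl$length / 2, cyl$length / 2, cyl$length + 5),
    y = c(0, r, r + 1e-6, 0),
    z = 0,
    cell_type = "CL_0000057"
  )
  model <- cells_in_ftu(cells, cap)
  expect_setequal(model$cells$cell_id, c("on_axis", "on_wall"))
  expect_warning(
    cells_in_ftu(cells[3, ], cap),
    "no cell"
  )
  # a cylinder violating the diffusion span is rejected
  expect_error(
    cells_in_ftu(cells, cap, cylinder = list(diameter = 90, length = 60)),
    class = "ftu_validation_error"
  )
  # the axial window follows axial_origin
  shifted <- cells_in_ftu(cells, cap, axial_origin = cyl$length + 1)
  expect_setequal(shifted$cells$cell_id, "past_end")
})

test_that("synthetic FTU membership is recovered exactly", {
  fx <- table1_fixture()
  pc <- gen_ftu_pointcloud(fx$motifs$ptm_4, n_cells = 120, noise_frac = 0.25, seed = 31)
  model <- cells_in_ftu(pc$cells, pc$capillary)
  expect_setequal(model$cells$cell_id, pc$cells$cell_id[pc$membership])
})

test_that("membership is invariant under rigid-body motion of cells and capillary", {
  fx <- table1_fixture()
  pc <- gen_ftu_pointcloud(fx$motifs$ptm_2, n_cells = 60, noise_frac = 0.3, seed = 12)
  rot <- random_rotation(5)
  shift <- c(42, -13, 7)
  cells2 <- pc$cells
  xyz <- as.matrix(pc$cells[, c("x", "y", "z")]) %*% t(rot)
  cells2$x <- xyz[, 1] + shift[1]
  cells2$y <- xyz[, 2] + shift[2]
  cells2$z <- xyz[, 3] + shift[3]
  cap2 <- capillary_segment(sweep(pc$capillary$polyline %*% t(rot), 2, -shift))
  m1 <- cells_in_ftu(pc$cells, pc$capillary)
  m2 <- cells_in_ftu(cells2, cap2)
  expect_setequal(m2$cells$cell_id, m1$cells$cell_id)
})

test_that("diffusion validation agrees with the brute-force all-pairs oracle", {
  # cells selected by the optimal cylinder can never violate the span
  fx <- table1_fixture()
  pc <- gen_ftu_pointcloud(fx$motifs$ptm_1, n_cells = 150, seed = 8)
  model <- cells_in_ftu(pc$cells, pc$capillary)
  expect_equal(nrow(validate_diffusion(model)$violations), 0)

  # two cells 101 um apart: one violation
  far <- structure(list(
    cells = data.frame(cell_id = c("a", "b"), x = c(0, 101), y = 0, z = 0,
                       cell_type = "CL_0000057"),
    params = geometry_params()
  ), class = "ftu_model")
  rep <- validate_diffusion(far)
  expect_equal(nrow(rep$violations), 1)
  expect_equal(rep$violations$distance, 101)

  # random point clouds: violation list equals the O(n^2) oracle
  for (seed in c(2, 6)) {
    pts <- withr::with_seed(seed, data.frame(
      cell_id = sprintf("p%03d", 1:40),
      x = runif(40, 0, 180), y = runif(40, 0, 180), z = runif(40, 0, 60),
      cell_type = "CL_0000115"
    ))
    mod <- structure(list(cells = pts, params = geometry_params()),
                     class = "ftu_model")
    got <- validate_diffusion(mod)$violations
    want <- 0L
    for (i in 1:39) for (j in (i + 1):40) {
      dd <- sqrt(sum((pts[i, c("x", "y", "z")] - pts[j, c("x", "y", "z")])^2))
      if (dd > 100) {
        want <- want + 1L
        expect_true(any(got$cell_a == pts$cell_id[i] & got$cell_b == pts$cell_id[j]))
      }
    }
    expect_equal(nrow(got), want)
  }
})

test_that("diffusive field membership uses a closed boundary and matches resampling", {
  cap <- capillary_segment(rbind(c(0, 0, 0), c(30, 5, 0), c(60, 5, 20)))
  expect_true(diffusive_field(cap, 1e-9, matrix(c(30, 5, 0), 1)))   # on the polyline
  straight <- capillary_segment(rbind(c(0, 0, 0), c(50, 0, 0)))
  expect_true(diffusive_field(straight, 40, matrix(c(25, 40, 0), 1)))      # at exactly 40
  expect_false(diffusive_field(straight, 40, matrix(c(25, 40.001, 0), 1)))

  pts <- withr::with_seed(14, matrix(runif(90, -20, 80), ncol = 3))
  d_true <- resampled_min_dist(cap, pts, step = 0.005)
  for (radius in c(20, 40)) {
    flags <- diffusive_field(cap, radius, pts)
    clear <- abs(d_true - radius) > 0.01   # away from the resolution limit
    expect_identical(flags[clear], (d_true <= radius)[clear])
  }
  expect_error(diffusive_field(cap, 0, pts), class = "ftu_validation_error")
})

test_that("extract_ptm derives the motif of a model", {
  # three broad categories, as in a colon demonstration annotation
  cap <- capillary_segment(rbind(c(0, 0, 0), c(57, 0, 0)))
  cells <- data.frame(
    cell_id = sprintf("n%02d", 1:9),
    x = seq(5, 53, length.out = 9), y = rep(c(0, 10, -15), 3), z = 0,
    cell_type = rep(c("endothelial", "epithelial", "connective tissue"), each = 3)
  )
  model <- cells_in_ftu(cells, cap, location = "colon")
  motif <- extract_ptm(model)
  expect_length(motif$cell_types, 3)
  expect_equal(motif$anatomical_location, "colon")

  mono <- cells
  mono$cell_type <- "epithelial"
  expect_length(extract_ptm(cells_in_ftu(mono, cap))$cell_types, 1)

  empty <- structure(list(cells = cells[0, ], ftu_id = "e",
                          anatomical_location = NA_character_),
                     class = "ftu_model")
  expect_error(extract_ptm(empty), class = "ftu_validation_error")
})

test_that("motif recovery from generated FTUs is exact at high density, subsumed at low", {
  fx <- table1_fixture()
  gen <- fx$motifs$ptm_5
  dense <- gen_ftu_pointcloud(gen, n_cells = 10 * length(gen$cell_types), seed = 44)
  got <- extract_ptm(cells_in_ftu(dense$cells, dense$capillary))
  expect_equal(relate_motifs(got, gen)$kind, "equivalent")

  sparse <- gen_ftu_pointcloud(gen, n_cells = length(gen$cell_types), seed = 45)
  got2 <- extract_ptm(cells_in_ftu(sparse$cells, sparse$capillary))
  expect_true(relate_motifs(got2, gen)$kind %in% c("equivalent", "x_subsumed_by_y"))
})

test_that("cell and capillary CSVs round-trip", {
  fx <- table1_fixture()
  pc <- gen_ftu_pointcloud(fx$motifs$ptm_1, n_cells = 20, seed = 2)
  cp <- withr::local_tempfile(fileext = ".csv")
  kp <- withr::local_tempfile(fileext = ".csv")
  write_cells_csv(pc$cells, cp)
  write_capillary_csv(pc$capillary, kp)
  cells <- read_cells_csv(cp)
  expect_equal(cells, pc$cells)
  cap <- read_capillary_csv(kp)
  expect_equal(cap$polyline, pc$capillary$polyline)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,x,y", "a,1,2"), bad)
  expect_error(read_cells_csv(bad), class = "ftu_parse_error")
})
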