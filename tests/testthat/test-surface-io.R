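test_that("ascii PLY meshes parse, round-trip, and reject bad input", {
  tmp <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0",
               "element vertex 3",
               "property float x", "property float y", "property float z",
               "element face 1",
               "property list uchar int vertex_indices", "end_header",
               "0 0 0", "1 0 0", "0 1 0", "3 0 1 2"), tmp)
  mesh <- read_ply(tmp)
  expect_equal(nrow(mesh$vertices), 3)
  expect_equal(nrow(mesh$faces), 1)
  expect_equal(mesh$faces[1, ], c(1L, 2L, 3L))

  # out-of-range face index
  writeLines(c("ply", "format ascii 1.0",
               "element vertex 4",
               "property float x", "property float y", "property float z",
               "element face 1",
               "property list uchar int vertex_indices", "end_header",
               "0 0 0", "1 0 0", "0 1 0", "1 1 0", "3 0 1 7"), tmp)
  expect_error(read_ply(tmp), "out of range")

  # malformed header names the offending line
  writeLines(c("ply", "format ascii 1.0", "element vertex x",
               "end_header"), tmp)
  expect_error(read_ply(tmp), "malformed PLY header")

  # quad faces triangulated as a fan with a warning
  writeLines(c("ply", "format ascii 1.0",
               "element vertex 4",
               "property float x", "property float y", "property float z",
               "element face 1",
               "property list uchar int vertex_indices", "end_header",
               "0 0 0", "1 0 0", "1 1 0", "0 1 0", "4 0 1 2 3"), tmp)
  expect_warning(mesh <- read_ply(tmp), "triangulated")
  expect_equal(nrow(mesh$faces), 2)
})

test_that("generator surfaces survive a PLY round-trip in both encodings", {
  hm <- make_surface(surface_spec("pyramid", n_rows = 9, n_cols = 9))
  yy <- hm$origin[1] + (seq_len(nrow(hm$values)) - 1) * hm$spacing_row
  xx <- hm$origin[2] + (seq_len(ncol(hm$values)) - 1) * hm$spacing_col
  verts <- cbind(rep(xx, each = 9), rep(yy, 9), as.vector(hm$values))
  mesh <- list(vertices = verts, faces = matrix(c(1L, 2L, 3L), 1))
  for (fmt in c("ascii", "binary_little_endian")) {
    tmp <- withr::local_tempfile(fileext = ".ply")
    write_ply(mesh, tmp, format = fmt)
    back <- read_ply(tmp)
    expect_equal(back$vertices, verts, tolerance = 1e-6)
    expect_equal(back$faces, mesh$faces)
    expect_equal(back$provenance$format, fmt)
  }
})

test_that("XYZ point clouds read, round-trip, and report parse errors", {
  tmp <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("0 0 0", "1 0 0"), tmp)
  expect_equal(nrow(read_xyz(tmp)$points), 2)

  writeLines(c("# comment", "0, 1, 2", "", "3 4 5"), tmp)
  expect_equal(read_xyz(tmp)$points, rbind(c(0, 1, 2), c(3, 4, 5)))

  set.seed(42)
  pts <- matrix(rnorm(300), 100, 3)
  write_xyz(pts, tmp)
  expect_equal(read_xyz(tmp)$points, pts)

  writeLines("1 2", tmp)
  expect_error(read_xyz(tmp), "line 1")
})

test_that("Surfer DSAA grids obey the dialect and round-trip bit-identically", {
  tmp <- withr::local_tempfile(fileext = ".grd")
  writeLines(c("DSAA", "2 2", "0 1", "0 1", "1 1",
               "1.0 1.0", "1.0 1.0"), tmp)
  hm <- read_surfer_grid(tmp)
  expect_equal(hm$values, matrix(1, 2, 2))
  expect_true(all(hm$mask))

  # blank sentinel masks the cell
  writeLines(c("DSAA", "2 2", "0 1", "0 1", "1 1",
               "1.0 1.70141e38", "1.0 1.0"), tmp)
  hm <- read_surfer_grid(tmp)
  expect_equal(sum(hm$mask), 3)
  expect_true(is.na(hm$values[1, 2]))

  set.seed(7)
  v <- matrix(rnorm(600), 20, 30)
  v[sample(600, 40)] <- NA
  hm0 <- height_map(v, spacing_row = 0.2, spacing_col = 0.4, origin = c(3, 5))
  write_surfer_grid(hm0, tmp)
  hm1 <- read_surfer_grid(tmp)
  expect_identical(hm1$values, hm0$values)
  expect_identical(hm1$mask, hm0$mask)
  expect_equal(hm1$spacing_row, hm0$spacing_row)
  expect_equal(hm1$origin, hm0$origin)

  writeLines(c("XYZZY", "2 2"), tmp)
  expect_error(read_surfer_grid(tmp), "DSAA")
  writeLines(c("DSAA", "2 2", "0 1", "0 1", "1 1", "1 2 3"), tmp)
  expect_error(read_surfer_grid(tmp), "mismatch")
})

test_that("point-cloud rasterization keeps the occlusal (max-z) envelope", {
  pts <- rbind(c(0.25, 0.25, 1), c(0.75, 0.25, 2),
               c(0.25, 0.75, 3), c(0.75, 0.75, 4))
  hm <- grid_point_cloud(pts, target_rows = 2)
  expect_equal(dim(hm$values), c(2, 2))
  expect_equal(sort(as.vector(hm$values)), 1:4)

  # two points in one cell: the upper surface wins
  pts2 <- rbind(pts, c(0.26, 0.26, 9))
  hm2 <- grid_point_cloud(pts2, target_rows = 2)
  expect_equal(max(hm2$values), 9)

  # invariant to the order of input points
  set.seed(11)
  cloud <- cbind(runif(500), runif(500), rnorm(500))
  a <- grid_point_cloud(cloud, target_rows = 10)
  b <- grid_point_cloud(cloud[sample(500), ], target_rows = 10)
  expect_identical(a$values, b$values)
  expect_identical(a$mask, b$mask)

  expect_error(grid_point_cloud(cbind(0, 0:4, 1), target_rows = 3),
               "degenerate")
})

test_that("a dense generator cloud re-gridded at 50 rows is nearly unmasked", {
  hm <- make_surface(surface_spec("cusp_field", n_rows = 101, n_cols = 101,
                                  spacing = 0.01, n_cusps = 3,
                                  cusp_width = 0.06, seed = 3))
  yy <- hm$origin[1] + (seq_len(101) - 1) * hm$spacing_row
  xx <- hm$origin[2] + (seq_len(101) - 1) * hm$spacing_col
  pts <- cbind(rep(xx, each = 101), rep(yy, 101), as.vector(hm$values))
  grid <- grid_point_cloud(pts, target_rows = 50)
  expect_lt(mean(!grid$mask), 0.05)
})

test_that("tooth rows standardize to 50 data rows per tooth", {
  z <- outer(seq_len(400), seq_len(120), function(r, c) sin(r / 20) + c / 60)
  hm <- height_map(z, spacing_row = 0.05, spacing_col = 0.05)
  trg <- standardize_tooth_row(hm, n_teeth = 4)
  expect_equal(nrow(trg$heightmap$values), 200)   # 4 teeth -> 200 rows
  expect_equal(trg$n_teeth, 4L)
  # columns rescaled by the same factor
  expect_equal(ncol(trg$heightmap$values), 60)

  hm1 <- height_map(matrix(rnorm(50 * 20), 50, 20))
  trg1 <- standardize_tooth_row(hm1, n_teeth = 1)
  expect_equal(nrow(trg1$heightmap$values), 50)   # 1 tooth -> unchanged

  # interpolation preserves constants
  hmc <- height_map(matrix(2.5, 37, 11))
  trgc <- standardize_tooth_row(hmc, n_teeth = 2)
  expect_lt(max(abs(trgc$heightmap$values - 2.5)), 1e-9)

  expect_error(standardize_tooth_row(hm, n_teeth = 0), "positive integer")
})

test_that("standardization is idempotent and masks conservatively", {
  set.seed(5)
  z <- matrix(rnorm(80 * 30), 80, 30)
  z[10, 5] <- NA
  hm <- height_map(z)
  t1 <- standardize_tooth_row(hm, n_teeth = 2)
  t2 <- standardize_tooth_row(t1$heightmap, n_teeth = 2)
  v1 <- t1$heightmap$values; v2 <- t2$heightmap$values
  common <- t1$heightmap$mask & t2$heightmap$mask
  expect_lt(max(abs((v1[common] - v2[common]) /
                      pmax(abs(v1[common]), 1))), 1e-6)
  # the masked input cell masks every output cell it contributes to
  expect_gt(sum(!t1$heightmap$mask), 0)
})
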