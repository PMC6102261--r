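test_that("point-in-polygon matches the crossing-number oracle and closes boundaries", {
  set.seed(61)
  poly <- cbind(c(100, 900, 950, 500, 80), c(100, 60, 800, 980, 700))
  x <- runif(1000, 0, 1000); y <- runif(1000, 0, 1000)
  ours <- point_in_polygon(x, y, poly)
  ref <- vapply(seq_along(x), function(i)
    oracle_point_in_polygon(x[i], y[i], poly), logical(1))
  expect_identical(ours, ref)
  # vertices and edge midpoints count as inside
  expect_true(all(point_in_polygon(poly[, 1], poly[, 2], poly)))
  mids <- (poly + poly[c(2:5, 1), ]) / 2
  expect_true(all(point_in_polygon(mids[, 1], mids[, 2], poly)))
})

test_that("roi sets validate their polygons", {
  expect_error(roi_set(list(cbind(c(0, 1), c(0, 1))), "cell"), ">= 3")
  bowtie <- cbind(c(0, 100, 100, 0), c(0, 100, 0, 100))
  expect_error(roi_set(list(bowtie), "adhesion"), "self-intersecting")
  ok <- roi_set(list(cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))), "cell")
  expect_s3_class(ok, "roi_set")
  expect_equal(polygon_area_nm2(ok$polygons[[1]]), 1e4)
})

test_that("roi labels partition every point set", {
  w <- obs_window(0, 0, 10000, 10000)
  cell <- cbind(c(1000, 9000, 9000, 1000), c(1000, 1000, 9000, 9000))
  adh <- cbind(c(2000, 4000, 4000, 2000), c(2000, 2000, 4000, 4000))
  rois <- roi_set(list(cell, adh), c("cell", "adhesion"))
  expect_equal(as.character(assign_points_to_rois(
    point_pattern(3000, 3000, w), rois)), "in_adhesion")
  p <- simulate_csr(30, w, seed = 62)
  lab <- assign_points_to_rois(p, rois)
  expect_equal(sum(table(lab)), n_points(p))
  expect_true(all(lab[point_in_polygon(p$x, p$y, adh)] == "in_adhesion"))
})

test_that("in/out densities use exclusive areas and exact counts", {
  w <- obs_window(0, 0, 10000, 10000)
  cell <- cbind(c(0, 10000, 10000, 0), c(0, 0, 10000, 10000))
  adh <- cbind(c(0, 5000, 5000, 0), c(0, 0, 10000, 10000)) # half the cell
  rois <- roi_set(list(cell, adh), c("cell", "adhesion"))
  # area bookkeeping: adhesion + out = cell
  cmp0 <- density_in_out(point_pattern(c(2000, 7000), c(500, 500), w), rois)
  expect_equal(cmp0$area_in_um2 + cmp0$area_out_um2, 100)
  expect_equal(cmp0$n_in, 1); expect_equal(cmp0$n_out, 1)

  # hand-placed scene: 7 points in the adhesion half, 3 outside
  xs <- c(1000, 2000, 3000, 4000, 1500, 2500, 3500, 6000, 7000, 8000)
  ys <- rep(5000, 10)
  cmp <- density_in_out(point_pattern(xs, ys, w), rois)
  expect_equal(cmp$n_in, 7)
  expect_equal(cmp$n_out, 3)
  expect_equal(cmp$density_in, 7 / 50)
  expect_equal(cmp$density_out, 3 / 50)

  # CSR over the cell: halves agree within sampling error
  p <- simulate_csr(100, w, seed = 63)
  cmpc <- density_in_out(p, rois)
  expect_lt(abs(cmpc$ratio - 1), 0.1)
  expect_error(density_in_out(p, roi_set(list(cell), "cell")), "adhesion")
})

test_that("surface versus under-cell densities compare correctly", {
  w <- obs_window(0, 0, 10000, 10000)
  cell <- cbind(c(2000, 8000, 8000, 2000), c(2000, 2000, 8000, 8000))
  rois <- roi_set(list(cell), "cell")
  p <- simulate_csr(50, w, seed = 64)
  sv <- surface_vs_undercell_density(p, rois, w)
  expect_equal(sv$surface_density, n_points(p) / 100)
  expect_lt(abs(sv$undercell_density / sv$surface_density - 1), 0.1)

  empty <- point_pattern(numeric(0), numeric(0), w)
  sv0 <- surface_vs_undercell_density(empty, rois, w)
  expect_equal(sv0$surface_density, 0)
  expect_equal(sv0$undercell_density, 0)

  # ligands only under the cell: surface average is diluted by the window
  q <- point_pattern(runif(100, 2000, 8000), runif(100, 2000, 8000), w)
  svq <- surface_vs_undercell_density(q, rois, w)
  expect_equal(svq$n_surface, 100)
  expect_equal(svq$n_undercell, 100)
  expect_lt(svq$surface_density, svq$undercell_density)
})

test_that("adhesion-support classification applies the reported thresholds", {
  expect_equal(as.character(classify_adhesion_support(0.5)), "none")
  expect_equal(as.character(classify_adhesion_support(0.8)), "none") # strict >
  expect_equal(as.character(classify_adhesion_support(2)), "tether")
  expect_equal(as.character(classify_adhesion_support(5)), "spread")
  expect_error(classify_adhesion_support(-1), ">= 0")
})
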