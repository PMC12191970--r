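## Tilted-cylinder fill geometry and voxelization.

test_that("fill plane height: upright closed forms", {
  r <- 0.0145; L <- 0.115
  v <- vesselGeometry(r, L, 90, 16e-6)
  expect_equal(fillPlaneHeight(v), 16e-6 / (pi * r^2), tolerance = 1e-9)
  vhalf <- vesselGeometry(r, L, 90, pi * r^2 * L / 2)
  expect_equal(fillPlaneHeight(vhalf), L / 2, tolerance = 1e-9)
})

test_that("tilted fill plane matches a Monte-Carlo volume oracle", {
  v <- vesselGeometry(0.0145, 0.115, 22, 16e-6)
  h <- fillPlaneHeight(v)
  ## sample uniformly inside the cylinder, count below the plane
  set.seed(42)
  N <- 1e6
  th <- 22 * pi / 180
  t <- runif(N, 0, v$inner_length)
  u <- sqrt(runif(N)) * v$inner_radius
  ph <- runif(N, 0, 2 * pi)
  ## z = zA + t sin(th) + (radial component along the tilted normal)
  z <- v$inner_radius * cos(th) + t * sin(th) + u * cos(ph) * cos(th)
  V_mc <- mean(z <= h) * pi * v$inner_radius^2 * v$inner_length
  expect_equal(V_mc, 16e-6, tolerance = 2e-3)
  ## and the analytic slice volume agrees with the requested fill exactly
  expect_equal(volumeBelowPlane(v, h), 16e-6, tolerance = 1e-6)
})

test_that("fill volume outside the vessel capacity is rejected", {
  expect_error(vesselGeometry(0.01, 0.1, 45, 1), "fill_volume")
  expect_error(vesselGeometry(0.01, 0.1, 45, 0), "fill_volume")
  expect_error(vesselGeometry(0.01, 0.1, 95, 1e-6), "tilt_angle")
})

test_that("exposed surface area: circle, unclipped ellipse, tilt ordering", {
  r <- 0.0145
  v90 <- vesselGeometry(r, 0.115, 90, 16e-6)
  expect_equal(exposedSurfaceArea(v90), pi * r^2, tolerance = 1e-9)
  ## a mid-fill 45-degree vessel has its surface ellipse fully inside
  v45 <- vesselGeometry(r, 0.115, 45, 30e-6)
  expect_true(fillPlaneInside(v45))
  expect_equal(exposedSurfaceArea(v45), pi * r^2 / sin(45 * pi / 180),
               tolerance = 1e-9)
  ## tilting increases the exposed area at fixed fill
  for (fill in c(16e-6, 17.6e-6)) {
    a22 <- exposedSurfaceArea(vesselGeometry(r, 0.115, 22, fill))
    a90 <- exposedSurfaceArea(vesselGeometry(r, 0.115, 90, fill))
    expect_gt(a22, a90)
  }
})

test_that("clipped ellipse area matches a 2-D Monte-Carlo oracle", {
  v <- vesselGeometry(0.0145, 0.115, 22, 16e-6)
  h <- fillPlaneHeight(v)
  ## sample the plane z = h over the cylinder's bounding box in (x, y)
  set.seed(7)
  N <- 1e6
  th <- 22 * pi / 180
  r <- v$inner_radius; L <- v$inner_length
  xmin <- -r * sin(th); xmax <- L * cos(th) + r * sin(th)
  x <- runif(N, xmin, xmax); y <- runif(N, -r, r)
  zA <- r * cos(th)
  tau <- x * cos(th) + (h - zA) * sin(th)
  rad2 <- x^2 + y^2 + (h - zA)^2 - tau^2
  inside <- tau >= 0 & tau <= L & rad2 <= r^2
  A_mc <- mean(inside) * (xmax - xmin) * 2 * r
  expect_equal(exposedSurfaceArea(v), A_mc, tolerance = 5e-3)
})

test_that("voxel mesh reproduces fill volume and exposed area, converging under refinement", {
  for (tilt in c(22, 90)) {
    v <- vesselGeometry(0.0145, 0.115, tilt, 16e-6)
    m1 <- voxelize(v, 2e-3)
    expect_lt(abs(meshFrozenVolume(m1) - 16e-6) / 16e-6, 0.01)
    expect_lt(abs(meshExposedArea(m1) - exposedSurfaceArea(v)) /
                exposedSurfaceArea(v), 0.05)
    m2 <- voxelize(v, 1e-3)
    expect_lt(abs(meshFrozenVolume(m2) - 16e-6) / 16e-6, 0.0025)
  }
})

test_that("upright voxelization is a stack of disks with one exposed layer", {
  v <- vesselGeometry(0.0145, 0.115, 90, 16e-6)
  m <- voxelize(v, 2.5e-3)
  ## all exposed faces lie on a single horizontal layer
  expect_equal(length(unique(round(m$exposed_faces$center[, 3], 9))), 1L)
  ## every exposed face belongs to a cell that holds ice
  expect_true(all(m$solid_frac[m$exposed_faces$cell] > 0))
})

test_that("degenerate resolution is rejected", {
  v <- vesselGeometry(0.0145, 0.115, 90, 16e-6)
  expect_error(voxelize(v, 0.005), "8 cells")
})

test_that("shelf contact: full base disk upright, point patch tilted", {
  v90 <- vesselGeometry(0.0145, 0.115, 90, 16e-6)
  v22 <- vesselGeometry(0.0145, 0.115, 22, 16e-6)
  A90 <- shelfContactArea(v90)
  A22 <- shelfContactArea(v22)
  expect_gte(A90, pi * 0.0145^2)            # at least the base disk
  expect_lt(A90, 1.2 * pi * 0.0145^2)
  expect_lt(A22, 0.05 * A90)                # tilted: point-like contact
  ## normalized conductance: tagged faces scale to the analytic area
  m22 <- voxelize(v22, 2e-3)
  n <- length(m22$shelf_contact_faces$cell)
  expect_equal(n * m22$cell_size^2 * m22$shelf_contact_faces$scale, A22,
               tolerance = 1e-9)
})

test_that("mesh export writes parseable VTK image data", {
  skip_if_not_installed("xml2")
  v <- vesselGeometry(0.0145, 0.115, 22, 16e-6)
  m <- voxelize(v, 3e-3)
  f <- tempfile(fileext = ".vti")
  exportMeshVTK(m, f)
  doc <- xml2::read_xml(f)
  expect_equal(xml2::xml_name(doc), "VTKFile")
  vals <- strsplit(trimws(xml2::xml_text(
    xml2::xml_find_first(doc, "//DataArray[@Name='label']"))), "\\s+")[[1]]
  expect_equal(length(vals), prod(m$dims))
})
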