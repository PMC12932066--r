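# Mesh structure, divergence-theorem integrals and STL round trips.

test_that("unit cube parses from both STL dialects with merged vertices", {
  cube <- mesh_box(center = c(0.5, 0.5, 0.5), size = c(1, 1, 1))
  for (dialect in c("ascii", "binary")) {
    tf <- tempfile(fileext = ".stl")
    write_stl(cube, tf, dialect = dialect)
    m <- read_stl(tf)
    # 36 facet-duplicated vertices merge back to the cube's 8
    expect_equal(nrow(m$vertices), 8L)
    expect_equal(nrow(m$faces), 12L)
    expect_equal(mesh_volume(m), 1, tolerance = 1e-12)
    expect_true(is_watertight(m))
    unlink(tf)
  }
})

test_that("save/load is the identity on vertex set and volume", {
  ph <- quick_phantom(seed = 1)
  for (mesh in list(ph$boundary, mesh_icosphere(10, c(3, -2, 7), 3))) {
    # ASCII: full double precision, exact round trip
    tf <- tempfile(fileext = ".stl")
    write_stl(mesh, tf, dialect = "ascii")
    m2 <- read_stl(tf)
    expect_equal(nrow(m2$vertices), nrow(mesh$vertices))
    d <- prostamould:::cpp_point_mesh_distance(mesh$vertices, mesh$faces - 1L,
                                               m2$vertices)
    expect_lt(max(d), 1e-6)
    expect_equal(mesh_volume(m2), mesh_volume(mesh), tolerance = 1e-12)
    unlink(tf)
    # binary: float32 storage, exact to format quantisation
    tf <- tempfile(fileext = ".stl")
    write_stl(mesh, tf, dialect = "binary")
    m3 <- read_stl(tf)
    expect_equal(nrow(m3$vertices), nrow(mesh$vertices))
    tol32 <- max(abs(mesh$vertices)) * 2^-22
    d <- prostamould:::cpp_point_mesh_distance(mesh$vertices, mesh$faces - 1L,
                                               m3$vertices)
    expect_lt(max(d), tol32)
    expect_equal(mesh_volume(m3), mesh_volume(mesh), tolerance = 1e-6)
    unlink(tf)
  }
})

test_that("defective meshes are reported, not silently repaired", {
  cube <- mesh_box(size = c(2, 2, 2))
  # one face deleted -> open edges, refused on load
  open_cube <- surface_mesh(cube$vertices, cube$faces[-1, ], validate = FALSE)
  rep_ <- mesh_report(open_cube)
  expect_false(rep_$is_watertight)
  expect_true("open_edge" %in% rep_$defects)
  tf <- tempfile(fileext = ".stl")
  # write the defective soup by hand (write_stl would refuse it)
  v <- open_cube$vertices[t(open_cube$faces), ]
  lines <- c("solid broken",
             sprintf(" facet normal 0 0 0\n  outer loop\n   vertex %g %g %g\n   vertex %g %g %g\n   vertex %g %g %g\n  endloop\n endfacet",
                     v[seq(1, nrow(v), 3), 1], v[seq(1, nrow(v), 3), 2], v[seq(1, nrow(v), 3), 3],
                     v[seq(2, nrow(v), 3), 1], v[seq(2, nrow(v), 3), 2], v[seq(2, nrow(v), 3), 3],
                     v[seq(3, nrow(v), 3), 1], v[seq(3, nrow(v), 3), 2], v[seq(3, nrow(v), 3), 3]),
             "endsolid broken")
  writeLines(lines, tf)
  err <- tryCatch(read_stl(tf), error = function(e) e)
  expect_s3_class(err, "prostamould_validation_error")
  expect_true("open_edge" %in% err$report$defects)
  unlink(tf)
  # NaN vertex -> refused on save
  bad <- cube
  bad$vertices[1, 1] <- NaN
  expect_error(write_stl(bad, tempfile(fileext = ".stl")),
               class = "prostamould_validation_error")
  # write_stl refuses open meshes (moulds must be printable)
  expect_error(write_stl(open_cube, tempfile(fileext = ".stl")),
               class = "prostamould_validation_error")
})

test_that("mesh_report: volume, components, inversion", {
  s <- mesh_icosphere(10, subdivisions = 4)
  rep_ <- mesh_report(s)
  expect_true(rep_$is_watertight)
  expect_equal(rep_$signed_volume_ml * 1000, 4 / 3 * pi * 1000, tolerance = 0.01)
  expect_equal(rep_$n_components, 1L)
  # two disjoint spheres
  s2 <- mesh_icosphere(3, c(30, 0, 0), 2)
  both <- surface_mesh(rbind(s$vertices, s2$vertices),
                       rbind(s$faces, s2$faces + nrow(s$vertices)))
  expect_equal(mesh_report(both)$n_components, 2L)
  # inverted winding
  inv <- surface_mesh(s$vertices, s$faces[, c(1, 3, 2)])
  rep_inv <- mesh_report(inv)
  expect_lt(rep_inv$signed_volume_ml, 0)
  expect_true("inverted" %in% rep_inv$defects)
})

test_that("icosphere volume converges to the closed form with subdivision", {
  true_vol <- 4 / 3 * pi * 10^3
  errs <- vapply(2:4, function(k)
    abs(mesh_volume(mesh_icosphere(10, subdivisions = k)) - true_vol) / true_vol,
    0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.01)   # < 1% at 4 subdivisions
})

test_that("centroid and bbox are frame-consistent", {
  e <- mesh_ellipsoid(c(4, 5, 6), c(-1, 2, 3), 3)
  expect_equal(mesh_centroid(e), c(-1, 2, 3), tolerance = 1e-9)
  rep_ <- mesh_report(e)
  expect_equal(rep_$bbox_mm["min", ], c(-5, -3, -3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(rep_$bbox_mm["max", ], c(3, 7, 9), tolerance = 1e-9,
               ignore_attr = TRUE)
})
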