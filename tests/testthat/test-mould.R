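# Mould construction: offsetting, block arithmetic, cavity subtraction,
# insertion opening, offset variants.

test_that("outward offset reproduces the sphere closed form", {
  s <- mesh_icosphere(10, subdivisions = 4)
  off <- offset_surface(s, 1)
  expect_true(is_watertight(off))
  expect_equal(mesh_volume(off), 4 / 3 * pi * 11^3, tolerance = 0.02)
  # delta = 0 is the identity
  off0 <- offset_surface(s, 0)
  expect_lt(abs(mesh_volume(off0) - mesh_volume(s)) / mesh_volume(s), 0.005)
})

test_that("offset surface strictly contains the input", {
  ph <- quick_phantom(seed = 3)
  off <- offset_surface(ph$boundary, 2)
  inside <- prostamould:::cpp_points_inside(off$vertices, off$faces - 1L,
                                            ph$boundary$vertices)
  expect_true(all(inside))
  # clearance between input vertices and the offset surface is ~delta
  d <- prostamould:::cpp_point_mesh_distance(off$vertices, off$faces - 1L,
                                             ph$boundary$vertices)
  expect_gte(min(d), 0)
  expect_lte(max(d), 2 + 2 * 0.7)   # delta + mesh tolerance
  expect_gte(min(d), 2 - 2 * 0.7)
})

test_that("block is the margin-expanded bounding box", {
  s <- mesh_icosphere(10, subdivisions = 3)
  blk <- build_block(s, 10)
  b <- prostamould:::block_bounds(blk)
  expect_equal(b["min", ], c(-20, -20, -20), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(b["max", ], c(20, 20, 20), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(mesh_volume(blk), 40^3, tolerance = 1e-9)
  e <- mesh_ellipsoid(c(20, 18, 22), subdivisions = 3)
  be <- prostamould:::block_bounds(build_block(e, 10))
  expect_equal(be["max", ] - be["min", ], c(60, 56, 64), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(build_block(s, 2, min_wall_mm = 3), "min_wall")
})

test_that("cavity subtraction is exact for the nested case", {
  blk <- build_block(mesh_icosphere(10, subdivisions = 4), 10)
  cav <- mesh_icosphere(10, subdivisions = 4)
  mould <- subtract_cavity(blk, cav)
  expect_true(is_watertight(mould))
  expect_equal(mesh_volume(mould), 40^3 - mesh_volume(cav), tolerance = 1e-9)
  expect_equal(mesh_volume(mould), 64000 - 4188.79, tolerance = 0.01)
  # volume conservation identity
  expect_lt(abs(mesh_volume(mould) - (mesh_volume(blk) - mesh_volume(cav))) /
              mesh_volume(blk), 0.01)
  # independent voxel-count route agrees on the curved cavity (node counting
  # is unbiased on curved surfaces; the box part of the difference is exact)
  expect_equal(voxel_mesh_volume(cav, 0.5), mesh_volume(cav), tolerance = 0.02)
  # touching cavity is rejected
  big <- mesh_icosphere(20, subdivisions = 3)
  expect_error(subtract_cavity(blk, big), "strictly inside")
  touch <- mesh_icosphere(10, c(10, 0, 0), 3)
  expect_error(subtract_cavity(build_block(cav, 10), touch), "strictly inside")
})

test_that("insertion opening matches the silhouette cross-section", {
  cav <- mesh_icosphere(10, subdivisions = 4)
  blk <- build_block(cav, 10)
  mould <- subtract_cavity(blk, cav)
  spec <- mould_spec()
  opened <- cut_insertion_opening(mould, cav, "anterior", spec)
  expect_true(is_watertight(opened))
  expect_lt(mesh_volume(opened), mesh_volume(mould))
  # at a plane through the prism, the removed cross-section is the circle
  # pi r^2 (anterior of the sphere centre, i.e. y < 0 in LPS)
  a_solid <- cross_section_area(opened, axis = 2, coord = -5, s = 0.1)
  a_block <- 40 * 40
  expect_equal(a_block - a_solid, pi * 10^2, tolerance = 0.02)
  # opening an approach face is refused
  expect_error(cut_insertion_opening(mould, cav, "superior", spec),
               "approach")
})

test_that("variants share one guide plan and grow strictly with offset", {
  ph <- quick_phantom(seed = 5)
  models <- study_models_for(ph)
  expect_length(models, 3L)
  expect_equal(vapply(models, `[[`, 0, "variant_offset_mm"), c(0, 1, 2))
  cav_vols <- vapply(models, function(m) m$checks$cavity_volume_ml, 0)
  expect_true(all(diff(cav_vols) > 0))
  # identical guide plans across variants
  g0 <- prostamould:::guide_table(models[[1]]$guides)
  for (m in models[-1])
    expect_identical(prostamould:::guide_table(m$guides), g0)
  # containment of the boundary in every variant cavity
  for (m in models) {
    expect_true(m$checks$solid_watertight)
    expect_true(m$checks$boundary_contained)
  }
})

test_that("the variant build is deterministic (identical STL bytes)", {
  ph <- quick_phantom(seed = 5)
  spec <- coarse_spec()
  m1 <- build_mould_variants(ph, spec)[[1]]
  m2 <- build_mould_variants(ph, spec)[[1]]
  f1 <- tempfile(fileext = ".stl"); f2 <- tempfile(fileext = ".stl")
  write_stl(m1$solid, f1); write_stl(m2$solid, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})
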