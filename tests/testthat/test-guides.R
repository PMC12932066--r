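# Guide planning: centres of mass, approach choice, length calibration,
# channel carving.

test_that("centre of mass matches symmetric and voxel oracles", {
  s <- mesh_icosphere(7, c(10, 20, 30), 4)
  expect_lt(sqrt(sum((center_of_mass(s) - c(10, 20, 30))^2)), 1e-3)
  cube <- mesh_box(center = c(0.5, 0.5, 0.5), size = c(1, 1, 1))
  expect_equal(center_of_mass(cube), c(0.5, 0.5, 0.5), tolerance = 1e-12)
  # asymmetric union of two tangent spheres (r=5 at origin, r=3 at (8,0,0)),
  # merged through an SDF union, vs a 0.2 mm voxel-sampling centroid of the
  # analytic union
  grid <- prostamould:::sdf_grid(c(-6, -6, -6), c(12, 6, 6), 0.35)
  f1 <- prostamould:::sdf_mesh(grid, mesh_icosphere(5, subdivisions = 4), 1.5)
  f2 <- prostamould:::sdf_mesh(grid, mesh_icosphere(3, c(8, 0, 0), 4), 1.5)
  merged <- prostamould:::mesh_from_field(grid, pmin(f1, f2))
  com <- center_of_mass(merged)
  s_ <- 0.2
  xs <- seq(-5.5, 11.5, by = s_); ys <- seq(-5.5, 5.5, by = s_)
  zs <- seq(-5.5, 5.5, by = s_)
  pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  inside <- sqrt(rowSums(pts^2)) < 5 |
    sqrt((pts[, 1] - 8)^2 + pts[, 2]^2 + pts[, 3]^2) < 3
  vox_com <- colMeans(pts[inside, ])
  expect_lt(sqrt(sum((com - vox_com)^2)), 0.1)
  # open meshes are refused
  open_s <- surface_mesh(s$vertices, s$faces[-1, ], validate = FALSE)
  expect_error(center_of_mass(open_s), class = "prostamould_validation_error")
})

test_that("approach faces are ranked by distance with fixed tie-breaks", {
  spec <- mould_spec()
  b <- rbind(min = c(-20, -20, -20), max = c(20, 20, 20))
  # dead centre of a cubic block: all four faces equidistant -> tie-break
  expect_equal(choose_approaches(c(0, 0, 0), b, spec),
               c("superior", "posterior"))
  # displaced toward the left (+x in LPS) face
  expect_equal(choose_approaches(c(8, 0, 0), b, spec)[1], "left-lateral")
  # more guides than allowed faces
  expect_error(mould_spec(guides_per_roi = 5),
               "exceeds the number of approach faces")
  spec3 <- mould_spec(guides_per_roi = 3,
                      approaches = c("superior", "posterior", "left-lateral"))
  expect_length(choose_approaches(c(0, 0, 0), b, spec3), 3L)
})

test_that("guide calibration satisfies the insertion-depth identity", {
  spec <- mould_spec()   # depth 50, tip-targeted needle (notch centre at tip)
  b <- rbind(min = c(-30, -30, -50), max = c(30, 30, 10))
  # face -> centroid distance exactly the reach: zero tower
  g <- calibrate_guide(c(0, 0, -40), "superior", b, spec)
  expect_equal(g$tower_height_mm, 0)
  # distance 30: 20 mm tower, and the advanced tip lands on the centroid
  g2 <- calibrate_guide(c(0, 0, -20), "superior", b, spec)
  expect_equal(g2$tower_height_mm, 20)
  tip <- g2$entry_point_mm + spec$insertion_depth_mm * g2$direction
  expect_lt(sqrt(sum((tip - c(0, 0, -20))^2)), 1e-6)
  expect_equal(sqrt(sum((g2$entry_point_mm - g2$target_point_mm)^2)),
               spec$insertion_depth_mm - spec$needle$tip_to_notch_center_mm,
               tolerance = 1e-12)
  # axis passes through the centroid
  rel <- g2$target_point_mm - g2$entry_point_mm
  perp <- rel - sum(rel * g2$direction) * g2$direction
  expect_lt(sqrt(sum(perp^2)), 1e-6)
  # unreachable target names the deficit
  err <- tryCatch(calibrate_guide(c(0, 0, -50), "superior", b, spec),
                  error = function(e) e)
  expect_s3_class(err, "prostamould_calibration_error")
  expect_match(conditionMessage(err), "deficit 10")
  # notch-offset needle shortens the reach
  spec18 <- mould_spec(needle = needle_bard_18g())
  g3 <- calibrate_guide(c(0, 0, -20), "superior", b, spec18)
  expect_equal(sqrt(sum((g3$entry_point_mm - g3$target_point_mm)^2)), 37)
})

test_that("carving changes volume by the closed-form cylinder amounts", {
  cav <- mesh_icosphere(10, subdivisions = 4)
  blk <- build_block(cav, 10)
  mould <- subtract_cavity(blk, cav)
  spec <- mould_spec()
  g <- calibrate_guide(c(0, 0, 0), "superior", blk, spec,
                       cavity = cav, roi_label = "A")
  carved <- carve_guides(mould, list(g), spec)
  expect_true(is_watertight(carved))
  r <- g$channel_diameter_mm / 2
  R <- r + spec$tower_wall_mm
  tower_h <- g$tower_height_mm           # 50 - 20 = 30
  expect_equal(tower_h, 30)
  wall_len <- 10                          # block face at z=20 to sphere at z=10
  expected_net <- pi * R^2 * tower_h - pi * r^2 * (tower_h + wall_len)
  expect_equal(mesh_volume(carved) - mesh_volume(mould), expected_net,
               tolerance = 0.02)
})

test_that("colliding channels are rejected with the pair named", {
  spec <- mould_spec()
  b <- rbind(min = c(-20, -20, -20), max = c(20, 20, 20))
  g1 <- calibrate_guide(c(0, 0, 0), "superior", b, spec, roi_label = "A")
  g2 <- calibrate_guide(c(1, 0, 0), "superior", b, spec, roi_label = "B")
  err <- tryCatch(prostamould:::check_channel_collisions(list(g1, g2)),
                  error = function(e) e)
  expect_s3_class(err, "prostamould_layout_error")
  expect_match(conditionMessage(err), "A:superior")
  expect_match(conditionMessage(err), "B:superior")
  # same-ROI guides from different faces meet only in the cavity: no error
  g3 <- calibrate_guide(c(0, 0, 0), "posterior", b, spec, roi_label = "A")
  expect_silent(prostamould:::check_channel_collisions(list(g1, g3)))
})

test_that("multi-ROI carving yields one channel pair per ROI, voxel-checked", {
  spec3 <- phantom_spec(
    prostate_semi_axes_mm = c(22, 20, 24),
    roi_specs = list(
      list(label = "A", center_mm = c(8, 2, 6), radius_mm = 4),
      list(label = "B", center_mm = c(-8, 3, -6), radius_mm = 4),
      list(label = "C", center_mm = c(0, -6, -9), radius_mm = 3.5)),
    seed = 9)
  ph <- generate_phantom(spec3)
  models <- build_mould_variants(ph, mould_spec())
  m <- models[[1]]
  expect_length(m$guides, 6L)
  expect_equal(sort(table(vapply(m$guides, `[[`, "", "roi_label"))),
               sort(c(A = 2L, B = 2L, C = 2L)), ignore_attr = TRUE)
  expect_true(is_watertight(m$solid))
  vx <- voxel_mould_volume(m, 0.5)
  expect_equal(mesh_volume(m$solid), vx, tolerance = 0.02)
})
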