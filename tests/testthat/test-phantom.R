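# Synthetic case generator: closed-form volumes, ground-truth centroids,
# determinism, cohort emulation ranges.

test_that("phantom volumes match ellipsoid closed forms within 1%", {
  ph <- generate_phantom(phantom_spec(prostate_semi_axes_mm = c(20, 18, 22)))
  true_vol <- 4 / 3 * pi * 20 * 18 * 22
  expect_equal(mesh_volume(ph$boundary), true_vol, tolerance = 0.01)
  for (nm in names(ph$rois)) {
    rs <- Filter(function(r) r$label == nm, ph$spec$roi_specs)[[1]]
    expect_equal(mesh_volume(ph$rois[[nm]]), 4 / 3 * pi * rs$radius_mm^3,
                 tolerance = 0.01)
  }
})

test_that("true centroids equal analytic centres and mesh centroids", {
  spec <- phantom_spec(roi_specs = list(
    list(label = "A", center_mm = c(5, -3, 4), radius_mm = 5)))
  ph <- generate_phantom(spec)
  expect_equal(ph$true_centroids_mm$A, c(5, -3, 4))
  expect_lt(sqrt(sum((mesh_centroid(ph$rois$A) - c(5, -3, 4))^2)), 0.05)
  expect_lt(sqrt(sum((mesh_centroid(ph$boundary) - c(0, 0, 0))^2)), 0.05)
})

test_that("generation is bit-identical under a fixed seed", {
  spec <- phantom_spec(boundary_noise_mm = 1, seed = 42)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$boundary$vertices, b$boundary$vertices)
  expect_identical(a$rois$A$vertices, b$rois$A$vertices)
  cohort1 <- default_cohort_phantoms(3, seed = 11)
  cohort2 <- default_cohort_phantoms(3, seed = 11)
  expect_identical(lapply(cohort1, function(p) p$boundary$vertices),
                   lapply(cohort2, function(p) p$boundary$vertices))
})

test_that("smooth boundary noise keeps the surface watertight", {
  ph <- generate_phantom(phantom_spec(boundary_noise_mm = 1.5, seed = 3))
  rep_ <- mesh_report(ph$boundary)
  expect_true(rep_$is_watertight)
  # amplitude-bounded: volume stays near the ellipsoid's
  expect_equal(mesh_volume(ph$boundary), 4 / 3 * pi * 20 * 18 * 22,
               tolerance = 0.1)
  # ROIs stay strictly inside
  for (nm in names(ph$rois))
    expect_true(all(prostamould:::cpp_points_inside(
      ph$boundary$vertices, ph$boundary$faces - 1L, ph$rois[[nm]]$vertices)))
})

test_that("default cohort draws stay inside the emulated clinical ranges", {
  cases <- default_cohort_phantoms(12, seed = 7)
  expect_length(cases, 12L)
  for (ph in cases) {
    ax <- ph$spec$prostate_semi_axes_mm
    vol_ml <- 4 / 3 * pi * prod(ax) / 1000
    expect_gte(vol_ml, 25.5); expect_lte(vol_ml, 55.4)
    expect_equal(mesh_volume(ph$boundary) / 1000, vol_ml, tolerance = 0.01)
    expect_true(length(ph$rois) %in% 1:2)
    for (rs in ph$spec$roi_specs) {
      roi_ml <- 4 / 3 * pi * rs$radius_mm^3 / 1000
      expect_gte(roi_ml, 0.13); expect_lte(roi_ml, 2.41)
    }
  }
  # exhaustive check over a larger generated set
  big <- default_cohort_phantoms(200, seed = 7)
  pvol <- vapply(big, function(p)
    4 / 3 * pi * prod(p$spec$prostate_semi_axes_mm) / 1000, 0)
  rvol <- unlist(lapply(big, function(p)
    vapply(p$spec$roi_specs, function(r) 4 / 3 * pi * r$radius_mm^3 / 1000, 0)))
  expect_gte(min(pvol), 25.5); expect_lte(max(pvol), 55.4)
  expect_gte(min(rvol), 0.13); expect_lte(max(rvol), 2.41)
})

test_that("a ROI breaching the containment margin is rejected", {
  expect_error(
    phantom_spec(roi_specs = list(
      list(label = "A", center_mm = c(16, 0, 0), radius_mm = 5))),
    "containment")
  expect_error(
    phantom_spec(roi_specs = list(
      list(label = "A", center_mm = c(0, 0, 0), radius_mm = 19))),
    "too large")
})
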