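# Needle-insertion simulation: chord geometry, determinism, degradation
# under placement error.

fake_mould <- function(spec = mould_spec()) {
  structure(list(spec = spec), class = "mould_model")
}

axis_guide <- function(target, spec = mould_spec(), label = "A") {
  b <- rbind(min = target - 30, max = target + 30)
  calibrate_guide(target, "superior", b, spec, roi_label = label)
}

test_that("notch-ROI intersection follows the sphere chord formula", {
  spec <- mould_spec()   # notch 18 mm centred on the target at full depth
  target <- c(0, 0, 0)
  g <- axis_guide(target, spec)
  m <- fake_mould(spec)
  # axis through the centre: chord = diameter
  roi <- mesh_icosphere(5, target, 4)
  rep1 <- simulate_insertion(m, g, roi)
  expect_equal(rep1$notch_roi_intersection_mm, 10, tolerance = 0.01)
  expect_true(rep1$hit)
  expect_lt(rep1$axis_to_centroid_mm, 1e-6)
  # axis displaced 6 mm from an r=5 sphere: clean miss
  rep2 <- simulate_insertion(m, g, mesh_icosphere(5, target + c(6, 0, 0), 4))
  expect_equal(rep2$notch_roi_intersection_mm, 0)
  expect_false(rep2$hit)
  # displaced 3 mm: chord 2*sqrt(25 - 9) = 8
  rep3 <- simulate_insertion(m, g, mesh_icosphere(5, target + c(3, 0, 0), 4))
  expect_equal(rep3$notch_roi_intersection_mm, sphere_chord(5, 3),
               tolerance = 0.01)
  # property: chord formula holds across displacements, and intersection
  # never exceeds the notch length
  for (d in seq(0.5, 5.5, by = 1)) {
    repd <- simulate_insertion(m, g, mesh_icosphere(5, target + c(d, 0, 0), 4))
    expect_equal(repd$notch_roi_intersection_mm, sphere_chord(5, d),
                 tolerance = 0.015)
    expect_lte(repd$notch_roi_intersection_mm, spec$needle$notch_length_mm)
  }
})

test_that("a needle wider than the channel is refused", {
  spec <- mould_spec()
  g <- axis_guide(c(0, 0, 0), spec)
  fat <- needle_model(outer_diameter_mm = 5)
  expect_error(simulate_insertion(fake_mould(spec), g,
                                  mesh_icosphere(5, c(0, 0, 0), 3), fat),
               "exceeds channel diameter")
})

test_that("notch clipping is exact when the notch ends inside the ROI", {
  # short-notch needle: interval shorter than the chord
  spec <- mould_spec(needle = needle_model(notch_length_mm = 4))
  g <- axis_guide(c(0, 0, 0), spec)
  rep1 <- simulate_insertion(fake_mould(spec), g, mesh_icosphere(5, c(0, 0, 0), 4))
  expect_equal(rep1$notch_roi_intersection_mm, 4, tolerance = 1e-6)
})

test_that("zero-error simulation hits every guide with rate 1", {
  ph <- quick_phantom(seed = 2)
  m <- study_models_for(ph)[[1]]
  rep0 <- perturbed_hit_rate(m, ph, error_model(seed = 9), n_trials = 25)
  expect_true(all(rep0$hit_rate == 1))
  expect_true(all(rep0$axis_to_centroid_mm < 1e-6))
})

test_that("Monte-Carlo trials are reproducible under the seed", {
  ph <- quick_phantom(seed = 2)
  m <- study_models_for(ph)[[1]]
  err <- error_model(translation_sigma_mm = 4, rotation_sigma_deg = 3, seed = 17)
  r1 <- perturbed_hit_rate(m, ph, err, n_trials = 40)
  r2 <- perturbed_hit_rate(m, ph, err, n_trials = 40)
  expect_identical(r1, r2)
  expect_true(all(r1$hit_rate < 1))   # 4 mm sigma on a 5 mm ROI degrades hits
})

test_that("hit rate degrades with translation error", {
  ph <- quick_phantom(seed = 2)
  m <- study_models_for(ph)[[1]]
  lo <- perturbed_hit_rate(m, ph, error_model(translation_sigma_mm = 2,
                                              seed = 3), n_trials = 150)
  hi <- perturbed_hit_rate(m, ph, error_model(translation_sigma_mm = 10,
                                              seed = 3), n_trials = 150)
  expect_gt(mean(lo$hit_rate), mean(hi$hit_rate))
})
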