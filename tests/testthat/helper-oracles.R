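# Independent oracles and shared fixtures for the test suite.

# chord length of a line through a sphere of radius r at perpendicular
# distance d from its centre
sphere_chord <- function(r, d) ifelse(d >= r, 0, 2 * sqrt(r^2 - d^2))

# Probability that a sphere of radius r, centred on the notch centre and
# displaced by an isotropic 3D Gaussian (sd sigma per axis), still
# intersects the fixed notch segment of length notch_len on the needle
# axis. Reduce by symmetry: radial displacement rho has rho^2/sigma^2 ~
# chi^2_2, axial displacement z ~ N(0, sigma); the sphere hits the segment
# iff sqrt(max(|z| - L/2, 0)^2 + rho^2) < r. One numeric integral over z.
notch_hit_probability <- function(sigma, r, notch_len) {
  gz <- function(z) {
    d <- pmax(abs(z) - notch_len / 2, 0)
    a <- pmax(r^2 - d^2, 0)
    ifelse(a > 0, 1 - exp(-a / (2 * sigma^2)), 0)
  }
  stats::integrate(function(z) stats::dnorm(z, 0, sigma) * gz(z),
                   -notch_len / 2 - r, notch_len / 2 + r,
                   subdivisions = 1000L, rel.tol = 1e-8)$value
}

# voxel-count volume of a watertight mesh: parity inside test at the nodes
# of an s-mm grid (an implementation-independent route from the
# divergence-theorem surface integral)
voxel_mesh_volume <- function(mesh, s = 0.5) {
  b <- rbind(apply(mesh$vertices, 2, min) - 2 * s,
             apply(mesh$vertices, 2, max) + 2 * s)
  dims <- as.integer(ceiling((b[2, ] - b[1, ]) / s) + 1L)
  origin <- b[1, ] + s * c(0.0137, 0.0213, 0.0167)
  inside <- prostamould:::cpp_grid_inside(mesh$vertices, mesh$faces - 1L,
                                          origin, s, dims)
  sum(inside) * s^3
}

# cross-section area of the solid at a plane normal to `axis`, by dense
# point sampling with the parity inside test
cross_section_area <- function(mesh, axis, coord, s = 0.1) {
  b <- rbind(apply(mesh$vertices, 2, min), apply(mesh$vertices, 2, max))
  others <- setdiff(1:3, axis)
  u <- seq(b[1, others[1]] - s, b[2, others[1]] + s, by = s)
  w <- seq(b[1, others[2]] - s, b[2, others[2]] + s, by = s)
  pts <- matrix(0, length(u) * length(w), 3)
  pts[, others[1]] <- rep(u, times = length(w))
  pts[, others[2]] <- rep(w, each = length(u))
  pts[, axis] <- coord
  inside <- prostamould:::cpp_points_inside(mesh$vertices, mesh$faces - 1L, pts)
  sum(inside) * s^2
}

# memoised 12-case study cohort (seed 7) and its mould variants, shared by
# the acceptance checks so the pipeline runs once
.cohort_cache <- new.env(parent = emptyenv())

study_cohort <- function() {
  if (is.null(.cohort_cache$cases)) {
    .cohort_cache$cases <- default_cohort_phantoms(12, seed = 7)
    .cohort_cache$spec <- mould_spec()
    .cohort_cache$models <- lapply(.cohort_cache$cases, build_mould_variants,
                                   spec = .cohort_cache$spec)
  }
  .cohort_cache
}

# a small quick phantom for unit tests
quick_phantom <- function(seed = 5) generate_phantom(phantom_spec(seed = seed))

# build (and cache) default-spec variants for one phantom
.model_cache <- new.env(parent = emptyenv())
study_models_for <- function(ph) {
  key <- ph$case_id
  if (is.null(.model_cache[[key]]))
    .model_cache[[key]] <- build_mould_variants(ph, mould_spec())
  .model_cache[[key]]
}

# coarse spec for tests where geometry accuracy is not the point
coarse_spec <- function(...) mould_spec(mesh_resolution_mm = 1.2, ...)
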