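# Seeded synthetic prostate cases emulating MR-US fusion platform exports:
# an ellipsoidal prostate boundary (optionally perturbed by a smooth radial
# noise field) plus spherical/ellipsoidal ROIs strictly inside it, with the
# analytic shape centres recorded as ground truth.

#' Specify a synthetic prostate phantom
#'
#' The defaults give a 33 ml ellipsoidal prostate (semi-axes 20 x 18 x 22
#' mm) with one 0.5 ml spherical ROI, inside the size ranges seen in
#' MRI-targeted biopsy cohorts (prostates 25.5-55.4 ml, lesions 0.13-2.41
#' ml). Closed-form shapes keep every downstream quantity checkable against
#' an analytic oracle.
#'
#' @param prostate_semi_axes_mm ellipsoid semi-axes (mm).
#' @param prostate_center_mm prostate centre (mm).
#' @param roi_specs list of ROIs; each a list with `label`, `center_mm` and
#'   either `radius_mm` (sphere) or `semi_axes_mm` (ellipsoid).
#' @param boundary_noise_mm amplitude of the smooth radial boundary
#'   perturbation (0 = exact ellipsoid).
#' @param mesh_resolution icosphere subdivision level of generated meshes.
#' @param seed integer seed (noise field only; shapes are deterministic).
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(prostate_semi_axes_mm = c(20, 18, 22),
                         prostate_center_mm = c(0, 0, 0),
                         roi_specs = list(list(label = "A",
                                               center_mm = c(5, -3, 4),
                                               radius_mm = 5)),
                         boundary_noise_mm = 0,
                         mesh_resolution = 4L,
                         seed = 1L) {
  stopifnot(length(prostate_semi_axes_mm) == 3, all(prostate_semi_axes_mm > 0),
            boundary_noise_mm >= 0, mesh_resolution >= 1, length(roi_specs) >= 1)
  for (rs in roi_specs) {
    if (is.null(rs$label) || is.null(rs$center_mm))
      stop("each roi_spec needs a label and center_mm", call. = FALSE)
    r <- roi_extent(rs)
    # conservative containment: centre inside the ellipsoid shrunk by the
    # ROI extent + 1 mm margin + noise amplitude on every axis
    shrink <- prostate_semi_axes_mm - r - 1 - boundary_noise_mm
    if (any(shrink <= 0))
      stop(sprintf("ROI '%s' too large for the prostate", rs$label),
           call. = FALSE)
    rel <- (rs$center_mm - prostate_center_mm) / shrink
    if (sum(rel^2) > 1)
      stop(sprintf(
        "ROI '%s' violates the >= 1 mm containment margin inside the prostate",
        rs$label), call. = FALSE)
  }
  structure(list(prostate_semi_axes_mm = prostate_semi_axes_mm,
                 prostate_center_mm = prostate_center_mm,
                 roi_specs = roi_specs,
                 boundary_noise_mm = boundary_noise_mm,
                 mesh_resolution = as.integer(mesh_resolution),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

roi_extent <- function(rs) {
  if (!is.null(rs$radius_mm)) rs$radius_mm else max(rs$semi_axes_mm)
}

roi_mesh <- function(rs, subdivisions, frame_label = "LPS") {
  if (!is.null(rs$radius_mm))
    mesh_icosphere(rs$radius_mm, rs$center_mm, subdivisions, frame_label)
  else
    mesh_ellipsoid(rs$semi_axes_mm, rs$center_mm, subdivisions, frame_label)
}

# smooth low-frequency radial noise: a fixed small sum of plane-wave
# sinusoids of the unit direction, normalised to the requested amplitude.
# Smoothness (not i.i.d. per vertex) keeps the perturbed surface watertight.
radial_noise_field <- function(unit_dirs, amplitude) {
  K <- 4L
  d <- matrix(stats::rnorm(3 * K), K, 3)
  d <- d / sqrt(rowSums(d^2))
  freq <- stats::runif(K, 2, 5)
  phase <- stats::runif(K, 0, 2 * pi)
  amp <- stats::rnorm(K)
  g <- rep(0, nrow(unit_dirs))
  for (k in seq_len(K))
    g <- g + amp[k] * sin(freq[k] * (unit_dirs %*% d[k, ]) + phase[k])
  g <- as.numeric(g)
  if (max(abs(g)) > 0) g <- g / max(abs(g)) * amplitude
  g
}

#' Generate a synthetic prostate case
#'
#' Deterministic for a fixed spec (including its seed). Boundary noise is a
#' seeded smooth radial perturbation of the ellipsoid, re-validated
#' watertight (with up to two re-draws before failing); ROI meshes are
#' never perturbed and their recorded true centroids are the analytic shape
#' centres.
#'
#' @param spec a [phantom_spec()].
#' @param frame_label anatomical frame tag for all meshes.
#' @return list of class `phantom_case` with `boundary`, `rois` (named list
#'   of meshes), `true_centroids_mm` (named list), `case_id`, `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec(), frame_label = "LPS") {
  boundary <- mesh_ellipsoid(spec$prostate_semi_axes_mm,
                             spec$prostate_center_mm,
                             spec$mesh_resolution, frame_label)
  boundary$source_name <- "phantom prostate boundary"
  if (spec$boundary_noise_mm > 0) {
    ok <- FALSE
    for (attempt in 1:3) {
      pert <- with_seed(spec$seed + (attempt - 1L) * 7919L, {
        v <- sweep(boundary$vertices, 2, spec$prostate_center_mm, "-")
        rad <- sqrt(rowSums(v^2))
        u <- v / rad
        disp <- radial_noise_field(u, spec$boundary_noise_mm)
        b2 <- boundary
        b2$vertices <- sweep(u * (rad + disp), 2, spec$prostate_center_mm, "+")
        b2
      })
      rep_ <- mesh_report(pert)
      if (rep_$is_watertight && rep_$signed_volume_ml > 0) {
        boundary <- pert; ok <- TRUE; break
      }
    }
    if (!ok)
      stop_validation("boundary noise broke watertightness after 3 attempts")
  }
  rois <- list()
  cents <- list()
  for (rs in spec$roi_specs) {
    m <- roi_mesh(rs, spec$mesh_resolution, frame_label)
    m$source_name <- paste0("phantom ROI ", rs$label)
    rois[[rs$label]] <- m
    cents[[rs$label]] <- rs$center_mm
    inside <- cpp_points_inside(boundary$vertices, f0(boundary), m$vertices)
    if (!all(inside))
      stop(sprintf("ROI '%s' is not strictly inside the phantom boundary",
                   rs$label), call. = FALSE)
  }
  structure(list(boundary = boundary, rois = rois,
                 true_centroids_mm = cents,
                 case_id = sprintf("phantom-%d", spec$seed),
                 spec = spec),
            class = "phantom_case")
}

#' Seeded cohort of synthetic cases
#'
#' Draws `n` phantoms emulating the reference cohort's ranges: prostate
#' volumes uniform in 25.5-55.4 ml mapped to ellipsoid axes with fixed
#' anisotropy 1 : 0.9 : 1.1, and one or two spherical ROIs per case
#' (probability 1/3 of a second lesion, as in the reference cohort) with
#' volumes uniform in 0.13-2.41 ml, placed uniformly inside the gland with
#' at least a 2 mm containment margin. When two maximal lesions cannot
#' coexist in a small gland the second lesion is re-drawn smaller, matching
#' the cohort's small secondary lesions.
#'
#' @param n number of cases, >= 1.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @param boundary_noise_mm smooth boundary perturbation amplitude.
#' @return list of `phantom_case` objects.
#' @export
default_cohort_phantoms <- function(n, seed = 1L, boundary_noise_mm = 0) {
  stopifnot(n >= 1)
  with_seed(seed, {
    specs <- lapply(seq_len(n), function(i) {
      vol_ml <- stats::runif(1, 25.5, 55.4)
      s <- (vol_ml * 1000 * 3 / (4 * pi * 1 * 0.9 * 1.1))^(1 / 3)
      axes <- s * c(1, 0.9, 1.1)
      n_roi <- 1L + stats::rbinom(1, 1, 1 / 3)
      margin <- 2
      # rejection-sample a jointly feasible lesion layout: lesions must sit
      # >= `margin` inside the gland and must not overlap (>= 2 mm apart);
      # an infeasible joint draw (e.g. two large lesions in a small gland)
      # redraws the whole layout, keeping volumes uniform given feasibility
      rois <- NULL
      for (attempt in 1:400) {
        cand <- list()
        ok <- TRUE
        for (j in seq_len(n_roi)) {
          vol_roi <- stats::runif(1, 0.13, 2.41)
          r <- (3 * vol_roi * 1000 / (4 * pi))^(1 / 3)
          shrink <- axes - r - margin
          u <- stats::rnorm(3)
          u <- u / sqrt(sum(u^2))
          # a second lesion prefers the hemisphere away from the first
          if (j > 1 && sum(u * cand[[1]]$center_mm) > 0) u <- -u
          if (any(shrink <= 0)) { ok <- FALSE; break }
          dmax <- 1 / sqrt(sum(u^2 / shrink^2))
          cen <- u * stats::runif(1, 0, 0.85) * dmax
          for (k in seq_len(j - 1)) {
            if (sqrt(sum((cen - cand[[k]]$center_mm)^2)) <
                r + cand[[k]]$radius_mm + 2) ok <- FALSE
          }
          if (!ok) break
          cand[[j]] <- list(label = LETTERS[j], center_mm = cen,
                            radius_mm = r, volume_ml = vol_roi)
        }
        if (ok) { rois <- cand; break }
      }
      if (is.null(rois))
        stop("could not draw a feasible lesion layout", call. = FALSE)
      phantom_spec(prostate_semi_axes_mm = axes,
                   prostate_center_mm = c(0, 0, 0),
                   roi_specs = rois,
                   boundary_noise_mm = boundary_noise_mm,
                   seed = sample.int(99999999L, 1))
    })
    lapply(seq_along(specs), function(i) {
      ph <- generate_phantom(specs[[i]])
      ph$case_id <- sprintf("cohort-%d-case-%02d", seed, i)
      ph
    })
  })
}

#' Wrap clinical meshes as a case
#'
#' The clinical-input analogue of a `phantom_case`: a boundary segmentation
#' plus labelled ROI segmentations, e.g. as loaded from fusion-platform STL
#' exports with [read_stl()].
#'
#' @param boundary watertight prostate boundary mesh.
#' @param rois named list of watertight ROI meshes.
#' @param case_id identifier recorded in manifests.
#' @param metadata free-form list (PI-RADS, volumes, grades, ...).
#' @return list of class `prostate_case`.
#' @export
prostate_case <- function(boundary, rois, case_id = "case", metadata = list()) {
  assert_printable(boundary, "boundary")
  if (is.null(names(rois)) || any(!nzchar(names(rois))))
    stop("rois must be a named list", call. = FALSE)
  for (nm in names(rois)) assert_printable(rois[[nm]], paste("ROI", nm))
  structure(list(boundary = boundary, rois = rois, case_id = case_id,
                 metadata = metadata),
            class = "prostate_case")
}
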