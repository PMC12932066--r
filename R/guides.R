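# Needle-guide planning: approach choice, guide-length calibration against
# the fixed insertion depth, and carving of guide channels and towers.

as_bounds <- function(block) {
  if (is.matrix(block) && all(dim(block) == c(2, 3))) return(block)
  block_bounds(block)
}

#' Rank and choose biopsy approach faces for an ROI
#'
#' Chooses the `guides_per_roi` approach faces with the shortest
#' perpendicular distance from the ROI centroid to the block face, among
#' the spec's allowed approaches (the insertion face is never allowed).
#' Ties are broken deterministically in the fixed order superior,
#' posterior, left-lateral, right-lateral, anterior, inferior.
#'
#' @param centroid ROI centre of mass (mm), inside the block.
#' @param block mould block mesh (or its 2 x 3 bounds matrix).
#' @param spec a [mould_spec()].
#' @return character vector of face tags, length `guides_per_roi`.
#' @export
choose_approaches <- function(centroid, block, spec = mould_spec()) {
  ranked <- ranked_approaches(centroid, block, spec)
  if (spec$guides_per_roi > length(ranked))
    stop(sprintf("guides_per_roi (%d) exceeds the %d allowed approach faces",
                 spec$guides_per_roi, length(ranked)), call. = FALSE)
  ranked[seq_len(spec$guides_per_roi)]
}

# all allowed faces ordered by (distance, fixed tie-break)
ranked_approaches <- function(centroid, block, spec) {
  b <- as_bounds(block)
  if (any(centroid < b[1, ]) || any(centroid > b[2, ]))
    stop("ROI centroid lies outside the block", call. = FALSE)
  faces <- setdiff(spec$approaches, spec$insertion_face)
  dist <- vapply(faces, function(f) {
    fa <- face_axis(f, spec$frame_label)
    fc <- if (fa$sign > 0) b[2, fa$axis] else b[1, fa$axis]
    fa$sign * (fc - centroid[fa$axis])
  }, 0)
  ord <- order(dist, match(faces, FACE_TIEBREAK))
  faces[ord]
}

#' Calibrate a needle guide against the fixed insertion depth
#'
#' Builds the guide for one ROI and one approach face. The guide axis is
#' the inward face normal through the ROI centroid. With a fixed needle
#' insertion depth D and a needle whose notch centres `t` mm behind the
#' tip, the notch centre lands on the centroid exactly when the guide-top
#' entry point sits `D - t` mm from the centroid; the tower height is
#' therefore `(D - t)` minus the block-face-to-centroid distance. A target
#' deeper than `D - t` from every face is unreachable and raises a
#' calibration error naming the deficit.
#'
#' @param centroid ROI centre of mass (mm).
#' @param approach anatomical face tag.
#' @param block mould block mesh or 2 x 3 bounds matrix.
#' @param spec a [mould_spec()].
#' @param cavity optional cavity surface used to measure the channel length
#'   (guide top to cavity surface along the axis).
#' @param roi_label label recorded on the guide.
#' @return list of class `needle_guide`.
#' @export
calibrate_guide <- function(centroid, approach, block, spec = mould_spec(),
                            cavity = NULL, roi_label = "roi") {
  approach <- match.arg(approach, ANATOMICAL_FACES)
  b <- as_bounds(block)
  if (any(centroid < b[1, ]) || any(centroid > b[2, ]))
    stop("ROI centroid lies outside the block", call. = FALSE)
  fa <- face_axis(approach, spec$frame_label)
  face_coord <- if (fa$sign > 0) b[2, fa$axis] else b[1, fa$axis]
  dist_face <- fa$sign * (face_coord - centroid[fa$axis])
  reach <- spec$insertion_depth_mm - spec$needle$tip_to_notch_center_mm
  tower <- reach - dist_face
  if (tower < -1e-9)
    stop_calibration(sprintf(
      paste0("guide '%s' via %s cannot reach the target: centroid is %.2f mm ",
             "from the block face but the %g mm insertion depth (notch centre ",
             "%g mm behind tip) reaches only %.2f mm; deficit %.2f mm"),
      roi_label, approach, dist_face, spec$insertion_depth_mm,
      spec$needle$tip_to_notch_center_mm, reach, dist_face - reach))
  tower <- max(tower, 0)
  direction <- numeric(3)
  direction[fa$axis] <- -fa$sign          # inward face normal
  entry <- centroid
  entry[fa$axis] <- centroid[fa$axis] + fa$sign * reach
  channel_length <- NA_real_
  if (!is.null(cavity)) {
    ts <- cpp_ray_mesh_t(cavity$vertices, f0(cavity), entry, direction)
    ts <- ts[ts > 1e-9]
    if (length(ts)) channel_length <- ts[1]
  }
  structure(list(
    roi_label = roi_label,
    approach = approach,
    entry_point_mm = entry,
    direction = direction,
    channel_length_mm = channel_length,
    tower_height_mm = tower,
    target_point_mm = centroid,
    channel_diameter_mm = 2 * channel_radius(spec),
    guide_id = paste(roi_label, approach, sep = ":")),
    class = "needle_guide")
}

#' @export
print.needle_guide <- function(x, ...) {
  cat(sprintf(
    "needle_guide %s: entry (%.1f, %.1f, %.1f), tower %.1f mm, channel d=%.2f mm\n",
    x$guide_id, x$entry_point_mm[1], x$entry_point_mm[2], x$entry_point_mm[3],
    x$tower_height_mm, x$channel_diameter_mm))
  invisible(x)
}

# material segment of a guide channel: entry -> cavity surface (or target
# if the cavity crossing is unknown); the only part that can collide
guide_material_segment <- function(g) {
  len <- if (is.finite(g$channel_length_mm)) g$channel_length_mm
         else sqrt(sum((g$target_point_mm - g$entry_point_mm)^2))
  list(p = g$entry_point_mm, q = g$entry_point_mm + len * g$direction)
}

# minimum distance between two 3D segments
seg_seg_distance <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  if (a <= 1e-12 && e <= 1e-12) return(sqrt(sum(r * r)))
  if (a <= 1e-12) { s <- 0; t <- min(max(f / e, 0), 1) }
  else {
    c_ <- sum(d1 * r)
    if (e <= 1e-12) { t <- 0; s <- min(max(-c_ / a, 0), 1) }
    else {
      b <- sum(d1 * d2); den <- a * e - b * b
      s <- if (den > 1e-12) min(max((b * f - c_ * e) / den, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(max(-c_ / a, 0), 1) }
      else if (t > 1) { t <- 1; s <- min(max((b - c_) / a, 0), 1) }
    }
  }
  v <- (p1 + s * d1) - (p2 + t * d2)
  sqrt(sum(v * v))
}

# pairwise channel collisions between guides of *different* ROIs (guides of
# the same ROI meet only inside the cavity void, which carries no material)
check_channel_collisions <- function(guides) {
  n <- length(guides)
  if (n < 2) return(invisible(TRUE))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      gi <- guides[[i]]; gj <- guides[[j]]
      if (identical(gi$roi_label, gj$roi_label)) next
      si <- guide_material_segment(gi); sj <- guide_material_segment(gj)
      d <- seg_seg_distance(si$p, si$q, sj$p, sj$q)
      if (d < (gi$channel_diameter_mm + gj$channel_diameter_mm) / 2)
        stop_layout(sprintf(
          "guide channels collide: %s and %s (axis distance %.2f mm < %.2f mm)",
          gi$guide_id, gj$guide_id, d,
          (gi$channel_diameter_mm + gj$channel_diameter_mm) / 2))
    }
  }
  invisible(TRUE)
}

# Collision-aware guide planning: per ROI take approach faces in ranked
# order, skipping faces whose channel would collide with an already planned
# guide or whose tower would be negative; error if a ROI cannot place all
# its guides.
plan_guides <- function(centroids, block, spec, cavity = NULL) {
  guides <- list()
  for (label in names(centroids)) {
    ranked <- ranked_approaches(centroids[[label]], block, spec)
    placed <- 0L
    for (f in ranked) {
      if (placed >= spec$guides_per_roi) break
      g <- tryCatch(
        calibrate_guide(centroids[[label]], f, block, spec,
                        cavity = cavity, roi_label = label),
        prostamould_calibration_error = function(e) NULL)
      if (is.null(g)) next
      ok <- tryCatch({ check_channel_collisions(c(guides, list(g))); TRUE },
                     prostamould_layout_error = function(e) FALSE)
      if (ok) { guides <- c(guides, list(g)); placed <- placed + 1L }
    }
    if (placed < spec$guides_per_roi) {
      # no silent shortfall: refit strictly and surface the real error
      for (f in ranked[seq_len(spec$guides_per_roi)])
        calibrate_guide(centroids[[label]], f, block, spec,
                        roi_label = label)
      stop_layout(sprintf(
        "could only place %d of %d guides for ROI '%s' without channel collisions",
        placed, spec$guides_per_roi, label))
    }
  }
  guides
}

# union towers then subtract channels on an SDF field
apply_guides_field <- function(grid, field, guides, spec) {
  b_ <- NULL
  for (g in guides) {
    fa <- face_axis(g$approach, spec$frame_label)
    others <- setdiff(1:3, fa$axis)
    c2 <- g$entry_point_mm[others]
    entry_coord <- g$entry_point_mm[fa$axis]
    face_coord <- entry_coord - fa$sign * g$tower_height_mm
    if (g$tower_height_mm > 1e-9) {
      span <- sort(c(face_coord - fa$sign * 1.0, entry_coord))
      tw <- sdf_cylinder(grid, fa$axis, c2,
                         g$channel_diameter_mm / 2 + spec$tower_wall_mm, span)
      field <- pmin(field, tw)
    }
  }
  for (g in guides) {
    fa <- face_axis(g$approach, spec$frame_label)
    others <- setdiff(1:3, fa$axis)
    c2 <- g$entry_point_mm[others]
    entry_coord <- g$entry_point_mm[fa$axis]
    span <- sort(c(entry_coord + fa$sign * 1.0, g$target_point_mm[fa$axis]))
    ch <- sdf_cylinder(grid, fa$axis, c2, g$channel_diameter_mm / 2, span)
    field <- pmax(field, -ch)
  }
  field
}

# grid bounds needed to contain block plus all guide towers
guide_grid_bounds <- function(bounds, guides, spec) {
  lower <- bounds[1, ]; upper <- bounds[2, ]
  for (g in guides) {
    fa <- face_axis(g$approach, spec$frame_label)
    reach <- g$entry_point_mm[fa$axis] + fa$sign * 2
    if (fa$sign > 0) upper[fa$axis] <- max(upper[fa$axis], reach)
    else lower[fa$axis] <- min(lower[fa$axis], reach)
  }
  rbind(min = lower, max = upper)
}

# conservative manufacturability check: sample a ring just outside each
# channel bore over its proximal guidance section (first few mm of wall
# below the block face) and require mould material there; an insertion
# opening cutting into the bore at the face trips this. Distally a channel
# may terminate at the opening instead of the cavity, so no clearance is
# demanded there.
check_opening_clearance <- function(mould, guides, spec) {
  b <- block_bounds(mould)
  h <- spec$mesh_resolution_mm
  for (g in guides) {
    fa <- face_axis(g$approach, spec$frame_label)
    others <- setdiff(1:3, fa$axis)
    face_coord <- if (fa$sign > 0) b[2, fa$axis] else b[1, fa$axis]
    seg <- guide_material_segment(g)
    t_face <- abs(face_coord - g$entry_point_mm[fa$axis])
    t_end <- sqrt(sum((seg$q - seg$p)^2))
    rr <- g$channel_diameter_mm / 2 + max(h, 0.5)
    guard <- max(5, 2 * g$channel_diameter_mm)
    t_stop <- min(t_face + guard,
                  t_end - (g$channel_diameter_mm / 2 + spec$min_wall_mm) - h)
    if (t_stop <= t_face) next
    tt <- seq(t_face + h, t_stop, length.out = 8)
    ring <- lapply(seq(0, 2 * pi, length.out = 9)[-9], function(a) {
      off <- numeric(3)
      off[others] <- rr * c(cos(a), sin(a))
      off
    })
    pts <- do.call(rbind, lapply(tt, function(t_) {
      do.call(rbind, lapply(ring, function(off)
        g$entry_point_mm + t_ * g$direction + off))
    }))
    inside <- cpp_points_inside(mould$vertices, f0(mould), pts)
    if (!all(inside))
      stop_layout(sprintf(
        "channel %s breaches the insertion opening or block boundary along its shaft (min_wall %g mm)",
        g$guide_id, spec$min_wall_mm))
  }
  invisible(TRUE)
}

#' Carve guide channels and towers into a mould
#'
#' Subtracts each guide's channel cylinder (from above the guide top down
#' to where the cavity begins - the channel never continues into the far
#' cavity wall because it ends at the target centroid inside the void) and
#' unions an annular guide tower onto the block face wherever the
#' calibrated tower height is positive. Channels of different ROIs must not
#' intersect, and no channel may run within `min_wall_mm` of the specimen
#' insertion opening.
#'
#' @param mould the mould solid (cavity already subtracted, opening cut).
#' @param guides list of [calibrate_guide()] results for this block.
#' @param spec a [mould_spec()].
#' @return the carved mould, watertight.
#' @export
carve_guides <- function(mould, guides, spec = mould_spec()) {
  assert_printable(mould, "mould")
  check_channel_collisions(guides)
  check_opening_clearance(mould, guides, spec)
  h <- spec$mesh_resolution_mm
  gb <- guide_grid_bounds(block_bounds(mould), guides, spec)
  grid <- sdf_grid(gb[1, ], gb[2, ], h)
  field <- sdf_mesh(grid, mould, band = 3 * h)
  field <- apply_guides_field(grid, field, guides, spec)
  out <- mesh_from_field(grid, field, source_name = "mould (carved)",
                         frame_label = mould$frame_label,
                         what = "carve_guides")
  attr(out, "bounds") <- block_bounds(mould)
  out
}
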