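# End-to-end per-case pipeline: one mould per boundary offset, sharing a
# single guide plan computed from the unoffset boundary so the three
# printed variants target identically.

#' Build the mould variants for a case
#'
#' Runs the whole construction for one case: block from the boundary
#' bounding box plus wall margin, guide plan (ROI centres of mass, nearest
#' approach faces with deterministic tie-breaks and collision-aware
#' fallback, tower calibration against the fixed insertion depth), then per
#' offset in `spec$offsets_mm` a mould solid composed on one
#' signed-distance grid: block minus offset cavity minus insertion-opening
#' prism, plus guide towers, minus guide channels, remeshed by marching
#' tetrahedra. The block and the guide plan are shared across variants, so
#' entry points and tower heights are identical on all moulds.
#'
#' @param case a `phantom_case` or [prostate_case()].
#' @param spec a [mould_spec()].
#' @return list of `mould_model` objects, one per offset, each with fields
#'   `solid` (the printable mould), `block`, `cavity_surface`, `guides`,
#'   `variant_offset_mm`, `spec`, `case_id` and a `checks` list.
#' @export
build_mould_variants <- function(case, spec = mould_spec()) {
  boundary <- case$boundary
  assert_printable(boundary, "boundary")
  for (nm in names(case$rois)) assert_printable(case$rois[[nm]], paste("ROI", nm))
  block <- build_block(boundary, spec$wall_margin_mm, spec$min_wall_mm)
  b <- block_bounds(block)
  centroids <- lapply(case$rois, center_of_mass)
  guides <- plan_guides(centroids, block, spec, cavity = boundary)
  h <- spec$mesh_resolution_mm
  gb <- guide_grid_bounds(b, guides, spec)
  grid <- sdf_grid(gb[1, ], gb[2, ], h)
  max_off <- max(spec$offsets_mm)
  bfield <- sdf_mesh(grid, boundary, band = max_off + 4 * h)
  box_f <- sdf_box(grid, b)
  ifa <- face_axis(spec$insertion_face, spec$frame_label)
  cut_coord <- mesh_centroid(boundary)[ifa$axis]
  lapply(spec$offsets_mm, function(delta) {
    cav_f <- bfield - delta
    prism <- sdf_silhouette_prism(grid, cav_f, ifa$axis, ifa$sign, cut_coord)
    check_prism_clearance(grid, prism, guides, spec)
    field <- pmax(box_f, -cav_f, -prism)
    field <- apply_guides_field(grid, field, guides, spec)
    solid <- mesh_from_field(
      grid, field,
      source_name = sprintf("%s mould offset %gmm", case$case_id, delta),
      frame_label = spec$frame_label,
      what = sprintf("mould variant %g mm", delta))
    attr(solid, "bounds") <- b
    cavity_surface <- if (delta == 0) boundary else
      mesh_from_field(grid, cav_f,
                      source_name = sprintf("cavity offset %gmm", delta),
                      frame_label = spec$frame_label,
                      what = sprintf("offset cavity %g mm", delta))
    checks <- list(
      solid_watertight = TRUE,   # mesh_from_field would have raised otherwise
      cavity_watertight = is_watertight(cavity_surface),
      boundary_contained = delta == 0 ||
        all(cpp_points_inside(cavity_surface$vertices, f0(cavity_surface),
                              boundary$vertices)),
      solid_volume_ml = mesh_volume(solid) / 1000,
      cavity_volume_ml = mesh_volume(cavity_surface) / 1000,
      block_volume_ml = mesh_volume(block) / 1000)
    structure(list(variant_offset_mm = delta,
                   solid = solid,
                   block = block,
                   cavity_surface = cavity_surface,
                   boundary = boundary,
                   guides = guides,
                   opening = list(face = spec$insertion_face,
                                  axis = ifa$axis, sign = ifa$sign,
                                  cut_coord = cut_coord),
                   spec = spec,
                   case_id = case$case_id,
                   checks = checks),
              class = "mould_model")
  })
}

# prism-field analogue of check_opening_clearance, used before remeshing:
# the opening must not cut into any channel bore over its proximal guidance
# section (tower plus the first few mm of wall). Distally a channel may
# legitimately terminate at the opening instead of the cavity - the needle
# then crosses a short open gap straight into the specimen surface - so no
# clearance is demanded there.
check_prism_clearance <- function(grid, prism, guides, spec) {
  h <- spec$mesh_resolution_mm
  for (g in guides) {
    seg <- guide_material_segment(g)
    len <- sqrt(sum((seg$q - seg$p)^2))
    r <- g$channel_diameter_mm / 2
    guard <- max(5, 2 * g$channel_diameter_mm)
    t_stop <- min(g$tower_height_mm + guard, len - (r + spec$min_wall_mm))
    if (t_stop <= 0) next
    tt <- seq(0, t_stop, length.out = 16)
    pts <- t(vapply(tt, function(t_) seg$p + t_ * g$direction, numeric(3)))
    vals <- field_at(grid, prism, pts)
    if (any(vals < r + h, na.rm = TRUE))
      stop_layout(sprintf(
        "insertion opening cuts into the guidance section of channel %s",
        g$guide_id))
  }
  invisible(TRUE)
}

# trilinear interpolation of a grid field at arbitrary points
field_at <- function(grid, field, pts) {
  d <- grid$dims
  arr <- array(field, d)
  vapply(seq_len(nrow(pts)), function(i) {
    u <- (pts[i, ] - grid$origin) / grid$h
    i0 <- pmin(pmax(floor(u), 0), d - 2)
    fr <- u - i0
    i0 <- as.integer(i0) + 1L
    v <- 0
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      w <- prod(ifelse(c(cx, cy, cz) == 1, fr, 1 - fr))
      v <- v + w * arr[i0[1] + cx, i0[2] + cy, i0[3] + cz]
    }
    v
  }, 0)
}

#' @export
print.mould_model <- function(x, ...) {
  cat(sprintf(
    "mould_model '%s' offset %g mm: solid %.1f ml, cavity %.1f ml, %d guides\n",
    x$case_id, x$variant_offset_mm, x$checks$solid_volume_ml,
    x$checks$cavity_volume_ml, length(x$guides)))
  invisible(x)
}

guide_table <- function(guides) {
  do.call(rbind, lapply(guides, function(g) data.frame(
    guide_id = g$guide_id, roi_label = g$roi_label, approach = g$approach,
    entry_x = g$entry_point_mm[1], entry_y = g$entry_point_mm[2],
    entry_z = g$entry_point_mm[3],
    dir_x = g$direction[1], dir_y = g$direction[2], dir_z = g$direction[3],
    target_x = g$target_point_mm[1], target_y = g$target_point_mm[2],
    target_z = g$target_point_mm[3],
    tower_height_mm = g$tower_height_mm,
    channel_length_mm = g$channel_length_mm,
    channel_diameter_mm = g$channel_diameter_mm,
    stringsAsFactors = FALSE)))
}

#' Voxel-boolean volume oracle for a mould variant
#'
#' Recomputes the mould volume independently of the marching-tetrahedra
#' surface: the axis-aligned block is taken at its exact volume, and the
#' curved parts - offset cavity (boundary signed distance below the offset),
#' opening prism, guide towers and channels - are measured by classifying
#' and counting the nodes of a dense `voxel_mm` grid. Keeping the block
#' analytic avoids the coherent half-voxel bias that node counting incurs
#' on large grid-aligned planar faces; the remaining boundaries are curved,
#' where node counting is unbiased. Used to cross-check the meshed solid's
#' divergence-theorem volume.
#'
#' @param model a `mould_model`.
#' @param voxel_mm voxel pitch (mm), default 0.5.
#' @return volume in mm^3.
#' @export
voxel_mould_volume <- function(model, voxel_mm = 0.5) {
  spec <- model$spec
  b <- block_bounds(model$block)
  gb <- guide_grid_bounds(b, model$guides, spec)
  grid <- sdf_grid(gb[1, ], gb[2, ], voxel_mm)
  delta <- model$variant_offset_mm
  bsd <- sdf_mesh(grid, model$boundary, band = delta + 3 * voxel_mm)
  in_box <- sdf_box(grid, b) < 0
  in_cav <- bsd < delta
  # opening prism: silhouette of the offset cavity, on the opening side
  silh <- broadcast_axis(
    reduce_min_axis(bsd - delta, grid$dims, model$opening$axis),
    grid$dims, model$opening$axis)
  tc <- grid_coord(grid, model$opening$axis)
  ax <- if (model$opening$sign > 0) model$opening$cut_coord - tc
        else tc - model$opening$cut_coord
  in_prism <- silh < 0 & ax < 0
  in_tower <- rep(FALSE, grid_n(grid))
  in_chan <- rep(FALSE, grid_n(grid))
  for (g in model$guides) {
    fa <- face_axis(g$approach, spec$frame_label)
    others <- setdiff(1:3, fa$axis)
    c2 <- g$entry_point_mm[others]
    entry_coord <- g$entry_point_mm[fa$axis]
    face_coord <- entry_coord - fa$sign * g$tower_height_mm
    if (g$tower_height_mm > 1e-9) {
      span <- sort(c(face_coord, entry_coord))
      tw <- sdf_cylinder(grid, fa$axis, c2,
                         g$channel_diameter_mm / 2 + spec$tower_wall_mm, span)
      in_tower <- in_tower | (tw < 0)
    }
    span <- sort(c(entry_coord + fa$sign * 1.0, g$target_point_mm[fa$axis]))
    ch <- sdf_cylinder(grid, fa$axis, c2, g$channel_diameter_mm / 2, span)
    in_chan <- in_chan | (ch < 0)
  }
  v_box <- prod(b[2, ] - b[1, ])
  removed_in_box <- sum(in_box & (in_cav | in_prism | in_chan))
  added_towers <- sum(!in_box & in_tower & !in_chan)
  v_box + (added_towers - removed_in_box) * voxel_mm^3
}
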