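# Mould construction: boundary offsetting, block creation, cavity
# subtraction, specimen-insertion opening, and the per-offset variant
# pipeline.

# ----------------------------------------------------------- anatomy

ANATOMICAL_FACES <- c("superior", "inferior", "anterior", "posterior",
                      "left-lateral", "right-lateral")
# deterministic tie-break order for equidistant approach faces
FACE_TIEBREAK <- c("superior", "posterior", "left-lateral", "right-lateral",
                   "anterior", "inferior")

#' Anatomical face to axis mapping
#'
#' Resolves an anatomical face tag to a coordinate axis and outward sign
#' under the mesh's frame convention. `"LPS"` (default, the DICOM
#' convention): +x left, +y posterior, +z superior. `"RAS"`: +x right,
#' +y anterior, +z superior.
#'
#' @param face one of `r paste(ANATOMICAL_FACES, collapse=", ")`.
#' @param frame_label `"LPS"` or `"RAS"`.
#' @return list with `axis` (1, 2 or 3) and `sign` (+1/-1, outward).
#' @export
face_axis <- function(face, frame_label = "LPS") {
  face <- match.arg(face, ANATOMICAL_FACES)
  tab <- switch(toupper(frame_label),
    LPS = list("left-lateral" = c(1, 1), "right-lateral" = c(1, -1),
               "posterior" = c(2, 1), "anterior" = c(2, -1),
               "superior" = c(3, 1), "inferior" = c(3, -1)),
    RAS = list("right-lateral" = c(1, 1), "left-lateral" = c(1, -1),
               "anterior" = c(2, 1), "posterior" = c(2, -1),
               "superior" = c(3, 1), "inferior" = c(3, -1)),
    stop("unknown frame_label: ", frame_label, call. = FALSE))
  v <- tab[[face]]
  list(axis = as.integer(v[1]), sign = v[2])
}

# ----------------------------------------------------------- needle model

#' Core-biopsy needle models
#'
#' Geometry of the sampling needle. `tip_to_notch_center_mm` is the
#' distance from the (fired or fully inserted) tip back to the centre of
#' the specimen notch; the guide-length calibration places the ROI centre
#' of mass exactly there at the fixed insertion depth. Defaults model the
#' 14-gauge manual Tru-Cut (tip-targeted, outer diameter 2.11 mm);
#' [needle_bard_18g()] models an 18-gauge spring-loaded device whose fired
#' notch centres 13 mm behind the tip. The devices' hole sizes are not part
#' of the published workflow, so every field is configurable.
#'
#' @param gauge_label free-text device label.
#' @param outer_diameter_mm needle outer diameter (mm).
#' @param throw_mm forward travel of the cutting sequence (mm).
#' @param notch_length_mm specimen notch length (mm).
#' @param tip_to_notch_center_mm tip to notch-centre distance (mm).
#' @return list of class `needle_model`.
#' @export
needle_model <- function(gauge_label = "14G Tru-Cut",
                         outer_diameter_mm = 2.11,
                         throw_mm = 20,
                         notch_length_mm = 18,
                         tip_to_notch_center_mm = 0) {
  stopifnot(outer_diameter_mm > 0, throw_mm > 0, notch_length_mm > 0,
            tip_to_notch_center_mm >= 0)
  if (tip_to_notch_center_mm > throw_mm + notch_length_mm)
    stop("tip_to_notch_center_mm exceeds throw + notch length", call. = FALSE)
  structure(list(gauge_label = gauge_label,
                 outer_diameter_mm = outer_diameter_mm,
                 throw_mm = throw_mm,
                 notch_length_mm = notch_length_mm,
                 tip_to_notch_center_mm = tip_to_notch_center_mm),
            class = "needle_model")
}

#' @rdname needle_model
#' @export
needle_bard_18g <- function() {
  needle_model(gauge_label = "18G spring-loaded", outer_diameter_mm = 1.27,
               throw_mm = 22, notch_length_mm = 18,
               tip_to_notch_center_mm = 13)
}

# ----------------------------------------------------------- mould spec

#' Mould generation parameters
#'
#' All knobs of the mould generator. Three moulds per case are built by
#' default: the original boundary plus 1 and 2 mm outward offsets, to
#' tolerate slight MRI segmentation error. The needle enters perpendicular
#' to a block face; guide-tower heights are calibrated so a fixed
#' `insertion_depth_mm` (50 mm) places the notch centre on the ROI centre
#' of mass. The specimen is inserted through an opening cut into
#' `insertion_face` (anterior by default, since sampling uses the
#' superior/posterior/lateral faces).
#'
#' @param wall_margin_mm block wall margin beyond the boundary bounding box.
#' @param offsets_mm non-negative, strictly increasing cavity offsets.
#' @param insertion_face face opened for specimen insertion; must not be an
#'   approach face.
#' @param needle a [needle_model()].
#' @param insertion_depth_mm fixed needle insertion depth (mm).
#' @param approaches candidate biopsy approach faces.
#' @param guides_per_roi number of guides aimed at each ROI.
#' @param channel_clearance_mm radial clearance between needle and channel.
#' @param min_wall_mm minimum printable wall thickness.
#' @param tower_wall_mm guide-tower wall thickness around the channel.
#' @param mesh_resolution_mm grid spacing of the SDF/remeshing engine.
#' @param frame_label anatomical frame of all inputs.
#' @return list of class `mould_spec`.
#' @export
mould_spec <- function(wall_margin_mm = 10,
                       offsets_mm = c(0, 1, 2),
                       insertion_face = "anterior",
                       needle = needle_model(),
                       insertion_depth_mm = 50,
                       approaches = c("superior", "posterior",
                                      "left-lateral", "right-lateral"),
                       guides_per_roi = 2L,
                       channel_clearance_mm = 0.25,
                       min_wall_mm = 3,
                       tower_wall_mm = 1.5,
                       mesh_resolution_mm = 0.7,
                       frame_label = "LPS") {
  insertion_face <- match.arg(insertion_face, ANATOMICAL_FACES)
  approaches <- vapply(approaches, function(f) match.arg(f, ANATOMICAL_FACES), "")
  names(approaches) <- NULL
  if (any(offsets_mm < 0)) stop("offsets_mm must be >= 0", call. = FALSE)
  if (is.unsorted(offsets_mm, strictly = TRUE))
    stop("offsets_mm must be strictly increasing", call. = FALSE)
  if (insertion_face %in% approaches)
    stop("insertion_face must not be an approach face", call. = FALSE)
  if (guides_per_roi > length(approaches))
    stop("guides_per_roi exceeds the number of approach faces", call. = FALSE)
  stopifnot(wall_margin_mm > 0, insertion_depth_mm > 0,
            channel_clearance_mm >= 0, min_wall_mm > 0, tower_wall_mm > 0,
            mesh_resolution_mm > 0)
  structure(list(wall_margin_mm = wall_margin_mm, offsets_mm = offsets_mm,
                 insertion_face = insertion_face, needle = needle,
                 insertion_depth_mm = insertion_depth_mm,
                 approaches = approaches,
                 guides_per_roi = as.integer(guides_per_roi),
                 channel_clearance_mm = channel_clearance_mm,
                 min_wall_mm = min_wall_mm, tower_wall_mm = tower_wall_mm,
                 mesh_resolution_mm = mesh_resolution_mm,
                 frame_label = frame_label),
            class = "mould_spec")
}

channel_radius <- function(spec) {
  (spec$needle$outer_diameter_mm + 2 * spec$channel_clearance_mm) / 2
}

# ----------------------------------------------------------- operations

#' Outward surface offset
#'
#' Dilates a closed surface by `delta_mm`: the result is the set of points
#' at signed distance `delta_mm` from the input, extracted from a
#' narrow-band signed-distance grid by marching tetrahedra. Offsetting by 1
#' and 2 mm produces the looser mould variants that tolerate segmentation
#' error. `delta_mm = 0` returns the input unchanged.
#'
#' @param mesh a watertight [surface_mesh()].
#' @param delta_mm offset distance, >= 0 (mm).
#' @param resolution_mm grid spacing of the distance field (mm).
#' @return offset [surface_mesh()], strictly containing the input.
#' @export
offset_surface <- function(mesh, delta_mm, resolution_mm = 0.7) {
  stopifnot(delta_mm >= 0)
  assert_printable(mesh, "offset_surface input")
  if (delta_mm == 0) return(mesh)
  h <- resolution_mm
  b <- mesh_bounds(mesh)
  grid <- sdf_grid(b[1, ] - delta_mm - 2 * h, b[2, ] + delta_mm + 2 * h, h)
  field <- sdf_mesh(grid, mesh, band = delta_mm + 3 * h)
  out <- tryCatch(
    mesh_from_field(grid, field - delta_mm,
                    source_name = sprintf("%s+%gmm", mesh$source_name, delta_mm),
                    frame_label = mesh$frame_label,
                    what = "offset_surface (signed-distance offset)"),
    error = function(e) stop_validation(sprintf(
      "offset_surface: SDF offset by %g mm failed (%s); try a finer resolution_mm",
      delta_mm, conditionMessage(e))))
  out
}

#' Material-optimised mould block
#'
#' The block the cavity is carved out of: the cavity's axis-aligned
#' bounding box expanded by `wall_margin_mm` on every face. This is the
#' published workflow's "large cube" after material optimisation - a tight
#' rectangular block rather than a literal cube.
#'
#' @param cavity the cavity surface (the, possibly offset, prostate boundary).
#' @param wall_margin_mm wall margin (mm); must be at least `min_wall_mm`.
#' @param min_wall_mm minimum printable wall (mm).
#' @return a box [surface_mesh()] with a `bounds` attribute (2 x 3 matrix).
#' @export
build_block <- function(cavity, wall_margin_mm = 10, min_wall_mm = 3) {
  if (wall_margin_mm < min_wall_mm)
    stop(sprintf("wall_margin_mm (%g) below min_wall_mm (%g)",
                 wall_margin_mm, min_wall_mm), call. = FALSE)
  b <- mesh_bounds(cavity)
  lower <- b[1, ] - wall_margin_mm
  upper <- b[2, ] + wall_margin_mm
  blk <- mesh_box(center = (lower + upper) / 2, size = upper - lower,
                  frame_label = cavity$frame_label)
  blk$source_name <- "mould block"
  attr(blk, "bounds") <- rbind(min = lower, max = upper)
  blk
}

block_bounds <- function(block) {
  b <- attr(block, "bounds")
  if (is.null(b)) b <- mesh_bounds(block)
  b
}

#' Subtract the cavity from the block
#'
#' Boolean difference for the nested case: because the cavity lies strictly
#' inside the block, the difference's boundary is exactly the block surface
#' plus the orientation-flipped cavity surface. The result is watertight by
#' construction and its volume is exactly block minus cavity.
#'
#' @param block outer solid (watertight [surface_mesh()]).
#' @param cavity inner solid, strictly inside `block`.
#' @return the mould shell as a [surface_mesh()] (two shells, one solid).
#' @export
subtract_cavity <- function(block, cavity) {
  assert_printable(block, "block")
  assert_printable(cavity, "cavity")
  inside <- cpp_points_inside(block$vertices, f0(block), cavity$vertices)
  dmin <- min(cpp_point_mesh_distance(block$vertices, f0(block), cavity$vertices))
  if (!all(inside) || dmin <= 1e-7)
    stop(sprintf(
      "cavity must lie strictly inside the block (min clearance %.3g mm)", dmin),
      call. = FALSE)
  cav <- flip_faces(cavity)
  mesh <- surface_mesh(rbind(block$vertices, cav$vertices),
                       rbind(block$faces, cav$faces + nrow(block$vertices)),
                       frame_label = block$frame_label,
                       source_name = "mould (block minus cavity)")
  attr(mesh, "bounds") <- block_bounds(block)
  mesh
}

#' Cut the specimen-insertion opening
#'
#' Opens one block face so the explanted specimen can be placed into the
#' cavity: subtracts the prism swept from the cavity's silhouette on that
#' face, from the cavity's mid-plane out through the block. The face must
#' not be a biopsy approach face.
#'
#' @param mould the mould solid (e.g. from [subtract_cavity()]).
#' @param cavity the cavity surface that shaped the mould.
#' @param face anatomical face tag to open.
#' @param spec a [mould_spec()] (approach faces, frame, grid resolution).
#' @return the opened mould as a watertight [surface_mesh()].
#' @export
cut_insertion_opening <- function(mould, cavity, face = "anterior",
                                  spec = mould_spec()) {
  face <- match.arg(face, ANATOMICAL_FACES)
  if (face %in% spec$approaches)
    stop("cannot open an approach face: ", face, call. = FALSE)
  assert_printable(mould, "mould")
  assert_printable(cavity, "cavity")
  fa <- face_axis(face, spec$frame_label)
  h <- spec$mesh_resolution_mm
  b <- block_bounds(mould)
  grid <- sdf_grid(b[1, ], b[2, ], h)
  mould_field <- sdf_mesh(grid, mould, band = 3 * h)
  cavity_field <- sdf_mesh(grid, cavity, band = 3 * h)
  cut_coord <- mesh_centroid(cavity)[fa$axis]
  prism <- sdf_silhouette_prism(grid, cavity_field, fa$axis, fa$sign, cut_coord)
  out <- mesh_from_field(grid, pmax(mould_field, -prism),
                         source_name = "mould (opened)",
                         frame_label = mould$frame_label,
                         what = "cut_insertion_opening")
  attr(out, "bounds") <- b
  out
}
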