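#' Closed triangulated surface mesh
#'
#' The currency of the whole pipeline: an indexed triangle mesh in
#' millimetres, carried together with an anatomical-frame tag. All solids
#' the package emits (mould blocks, cavities, guide channels) are
#' `surface_mesh` objects, and printability everywhere means *watertight*:
#' every edge shared by exactly two consistently wound faces, signed
#' volume positive.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle,
#'   counter-clockwise seen from outside (outward normals).
#' @param frame_label anatomical frame tag; `"LPS"` (+x left, +y posterior,
#'   +z superior, the DICOM convention) or `"RAS"`.
#' @param source_name free-text provenance tag.
#' @param validate if `TRUE`, reject structurally broken input (non-finite
#'   coordinates, out-of-range indices, fewer than 4 vertices/faces).
#'   Watertightness is *not* enforced here; use [mesh_report()] or the
#'   printability gates in the mould operations.
#' @return an object of class `surface_mesh`.
#' @seealso [read_stl()], [mesh_report()], [mesh_volume()]
#' @export
surface_mesh <- function(vertices, faces, frame_label = "LPS",
                         source_name = "", validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (validate) {
    if (ncol(vertices) != 3L || ncol(faces) != 3L)
      stop("vertices and faces must both have 3 columns", call. = FALSE)
    if (nrow(vertices) < 4L || nrow(faces) < 4L)
      stop("a closed surface needs at least 4 vertices and 4 faces",
           call. = FALSE)
    if (!all(is.finite(vertices)))
      stop("vertex coordinates must be finite", call. = FALSE)
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range", call. = FALSE)
  }
  structure(
    list(vertices = vertices, faces = faces,
         frame_label = frame_label, source_name = source_name),
    class = "surface_mesh")
}

# zero-based faces for the compiled kernels
f0 <- function(mesh) mesh$faces - 1L

#' @export
print.surface_mesh <- function(x, ...) {
  vol <- tryCatch(cpp_signed_volume(x$vertices, f0(x)), error = function(e) NA)
  cat(sprintf(
    "surface_mesh: %d vertices, %d faces [%s]%s\n  signed volume %.3f ml, bbox %s mm\n",
    nrow(x$vertices), nrow(x$faces), x$frame_label,
    if (nzchar(x$source_name)) paste0(" <", x$source_name, ">") else "",
    vol / 1000,
    paste(sprintf("%.1f", apply(x$vertices, 2, max) - apply(x$vertices, 2, min)),
          collapse = " x ")))
  invisible(x)
}

#' Enclosed volume and volumetric centroid
#'
#' Signed volume and uniform-density centroid of a closed, consistently
#' oriented surface, by the divergence theorem (summing signed tetrahedra
#' against the origin). A positively oriented watertight mesh has positive
#' volume; an inner void shell contributes negatively.
#'
#' @param mesh a [surface_mesh()].
#' @return `mesh_volume()`: signed volume in mm^3. `mesh_centroid()`:
#'   length-3 point in mm.
#' @export
mesh_volume <- function(mesh) cpp_signed_volume(mesh$vertices, f0(mesh))

#' @rdname mesh_volume
#' @export
mesh_centroid <- function(mesh) {
  vc <- cpp_volume_centroid(mesh$vertices, f0(mesh))
  as.numeric(vc$centroid)
}

#' Centre of mass of a region-of-interest surface
#'
#' The volumetric (uniform-density) centre of mass of a watertight,
#' positively oriented mesh: the point every needle guide is aimed at.
#'
#' @param mesh a watertight [surface_mesh()].
#' @return length-3 point (mm).
#' @export
center_of_mass <- function(mesh) {
  rep_ <- mesh_report(mesh)
  if (!rep_$is_watertight)
    stop_validation("center_of_mass requires a watertight mesh", rep_)
  if (rep_$signed_volume_ml <= 0)
    stop_validation("center_of_mass requires positive enclosed volume", rep_)
  mesh_centroid(mesh)
}

#' Structural audit of a triangle mesh
#'
#' Reports, without raising, everything the printability gates check:
#' watertightness (every edge in exactly two faces), signed volume (ml, by
#' the divergence theorem), connected components, bounding box, and a
#' vector of defect tags (`"open_edge"`, `"nonmanifold_edge"`,
#' `"misoriented"`, `"inverted"`, `"nan_coordinates"`, `"too_few_faces"`).
#'
#' @param mesh a [surface_mesh()] (may be defective).
#' @return list of class `mesh_report`.
#' @export
mesh_report <- function(mesh) {
  defects <- character(0)
  finite <- all(is.finite(mesh$vertices))
  if (!finite) defects <- c(defects, "nan_coordinates")
  if (nrow(mesh$vertices) < 4L || nrow(mesh$faces) < 4L)
    defects <- c(defects, "too_few_faces")
  audit <- cpp_edge_audit(f0(mesh), nrow(mesh$vertices))
  if (audit$n_boundary_edges > 0) defects <- c(defects, "open_edge")
  if (audit$n_nonmanifold_edges > 0) defects <- c(defects, "nonmanifold_edge")
  if (audit$n_misoriented_edges > 0) defects <- c(defects, "misoriented")
  vol <- if (finite) cpp_signed_volume(mesh$vertices, f0(mesh)) else NA_real_
  if (isTRUE(vol < 0)) defects <- c(defects, "inverted")
  bbox <- if (finite)
    rbind(min = apply(mesh$vertices, 2, min), max = apply(mesh$vertices, 2, max))
  else matrix(NA_real_, 2, 3, dimnames = list(c("min", "max"), NULL))
  structure(
    list(is_watertight = isTRUE(audit$watertight) && finite &&
           !("too_few_faces" %in% defects),
         signed_volume_ml = vol / 1000,
         n_components = audit$n_components,
         bbox_mm = bbox,
         defects = defects),
    class = "mesh_report")
}

#' @export
print.mesh_report <- function(x, ...) {
  cat(sprintf("mesh_report: watertight=%s volume=%.4f ml components=%d\n",
              x$is_watertight, x$signed_volume_ml, x$n_components))
  if (length(x$defects)) cat("  defects:", paste(x$defects, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname mesh_report
#' @export
is_watertight <- function(mesh) mesh_report(mesh)$is_watertight

stop_validation <- function(msg, report = NULL) {
  cond <- structure(
    class = c("prostamould_validation_error", "error", "condition"),
    list(message = paste0(
      msg,
      if (!is.null(report) && length(report$defects))
        paste0(" [defects: ", paste(report$defects, collapse = ", "), "]")
      else ""),
      call = NULL, report = report))
  stop(cond)
}

stop_format <- function(msg) {
  stop(structure(class = c("prostamould_format_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

stop_calibration <- function(msg) {
  stop(structure(class = c("prostamould_calibration_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

stop_layout <- function(msg) {
  stop(structure(class = c("prostamould_layout_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# gate used before anything is written or boolean-combined
assert_printable <- function(mesh, what = "mesh") {
  rep_ <- mesh_report(mesh)
  if (!all(is.finite(mesh$vertices)))
    stop_validation(sprintf("%s has non-finite vertex coordinates", what), rep_)
  if (!rep_$is_watertight)
    stop_validation(sprintf("%s is not watertight", what), rep_)
  invisible(rep_)
}

# ------------------------------------------------------------ primitives

#' Mesh primitives
#'
#' Exact triangulations used as test oracles and building blocks: an
#' axis-aligned box (12 faces), an icosphere (icosahedron subdivided
#' `subdivisions` times, vertices on the sphere), and an ellipsoid
#' (anisotropically scaled icosphere).
#'
#' @param center centre point (mm).
#' @param size,radius,semi_axes dimensions in mm.
#' @param subdivisions icosphere refinement level; level 4 (5120 faces)
#'   encloses a sphere volume accurate to well under 1%.
#' @param frame_label anatomical frame tag.
#' @return a [surface_mesh()].
#' @export
mesh_box <- function(center = c(0, 0, 0), size = c(1, 1, 1), frame_label = "LPS") {
  hx <- size[1] / 2; hy <- size[2] / 2; hz <- size[3] / 2
  v <- cbind(
    x = c(-hx, hx, hx, -hx, -hx, hx, hx, -hx),
    y = c(-hy, -hy, hy, hy, -hy, -hy, hy, hy),
    z = c(-hz, -hz, -hz, -hz, hz, hz, hz, hz))
  v <- sweep(v, 2, center, "+")
  f <- rbind(
    c(1, 3, 2), c(1, 4, 3),   # bottom (-z)
    c(5, 6, 7), c(5, 7, 8),   # top (+z)
    c(1, 2, 6), c(1, 6, 5),   # -y
    c(3, 4, 8), c(3, 8, 7),   # +y
    c(2, 3, 7), c(2, 7, 6),   # +x
    c(4, 1, 5), c(4, 5, 8))   # -x
  surface_mesh(v, f, frame_label = frame_label, source_name = "box")
}

# memoised unit icospheres per subdivision level
.icosphere_cache <- new.env(parent = emptyenv())

unit_icosphere <- function(subdivisions) {
  key <- as.character(subdivisions)
  if (!is.null(.icosphere_cache[[key]])) return(.icosphere_cache[[key]])
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lvl in seq_len(subdivisions)) {
    nv <- nrow(v)
    # grow vertex table with midpoints (vectorised over unique edges)
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    ekey <- e[, 1] * (nv + 1) + e[, 2]
    ue <- !duplicated(ekey)
    uedges <- e[ue, , drop = FALSE]
    mid <- (v[uedges[, 1], , drop = FALSE] + v[uedges[, 2], , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    midid <- nv + seq_len(nrow(uedges))
    names(midid) <- as.character(uedges[, 1] * (nv + 1) + uedges[, 2])
    eid <- matrix(midid[as.character(ekey)], ncol = 3)  # per face: m12, m23, m31
    nf <- nrow(f)
    m12 <- eid[seq_len(nf)]
    m23 <- eid[nf + seq_len(nf)]
    m31 <- eid[2 * nf + seq_len(nf)]
    f <- rbind(
      cbind(f[, 1], m12, m31),
      cbind(f[, 2], m23, m12),
      cbind(f[, 3], m31, m23),
      cbind(m12, m23, m31))
    v <- rbind(v, mid)
  }
  out <- list(vertices = v, faces = f)
  .icosphere_cache[[key]] <- out
  out
}

#' @rdname mesh_box
#' @export
mesh_icosphere <- function(radius = 1, center = c(0, 0, 0), subdivisions = 4,
                           frame_label = "LPS") {
  u <- unit_icosphere(subdivisions)
  surface_mesh(sweep(u$vertices * radius, 2, center, "+"), u$faces,
               frame_label = frame_label, source_name = "icosphere")
}

#' @rdname mesh_box
#' @export
mesh_ellipsoid <- function(semi_axes = c(1, 1, 1), center = c(0, 0, 0),
                           subdivisions = 4, frame_label = "LPS") {
  u <- unit_icosphere(subdivisions)
  v <- sweep(u$vertices, 2, semi_axes, "*")
  surface_mesh(sweep(v, 2, center, "+"), u$faces,
               frame_label = frame_label, source_name = "ellipsoid")
}

# ------------------------------------------------------- transforms, misc

translate_mesh <- function(mesh, offset) {
  mesh$vertices <- sweep(mesh$vertices, 2, offset, "+")
  mesh
}

flip_faces <- function(mesh) {
  mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  mesh
}

# rigid transform: rotate by 3x3 matrix R about `pivot`, then translate
rigid_transform_mesh <- function(mesh, R = diag(3), pivot = c(0, 0, 0),
                                 translation = c(0, 0, 0)) {
  v <- sweep(mesh$vertices, 2, pivot, "-") %*% t(R)
  mesh$vertices <- sweep(sweep(v, 2, pivot, "+"), 2, translation, "+")
  mesh
}

rotation_about_axis <- function(axis, angle_rad) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle_rad); s <- sin(angle_rad)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + s * K + (1 - c_) * (K %*% K)
}

mesh_bounds <- function(mesh) {
  rbind(min = apply(mesh$vertices, 2, min),
        max = apply(mesh$vertices, 2, max))
}
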