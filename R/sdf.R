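# Signed-distance-field engine. Solids are represented as signed distances
# (negative inside) sampled at the nodes of an axis-aligned grid; boolean
# union/intersection/difference are pmin/pmax compositions; surfaces are
# recovered by marching tetrahedra (Kuhn 6-tet subdivision, watertight by
# construction when the field is positive on the grid boundary).
#
# Mesh-sampled fields are exact unsigned distances within a narrow band of
# the surface (clamped outside it) with the sign taken from watertight ray
# parity, which is all the zero crossing and any offset up to the band need.
#
# The grid origin carries a fixed sub-voxel jitter so mesh vertices and
# edges generically avoid landing exactly on grid nodes or ray rows.

GRID_JITTER <- c(0.0137521, 0.0213117, 0.0167303)

sdf_grid <- function(lower, upper, h) {
  lower <- lower - 2 * h
  upper <- upper + 2 * h
  dims <- pmax(ceiling((upper - lower) / h) + 1L, 2L)
  origin <- lower + GRID_JITTER * h
  list(origin = origin, h = h, dims = as.integer(dims),
       xs = origin[1] + h * (seq_len(dims[1]) - 1L),
       ys = origin[2] + h * (seq_len(dims[2]) - 1L),
       zs = origin[3] + h * (seq_len(dims[3]) - 1L))
}

grid_n <- function(grid) prod(grid$dims)

# node coordinate vectors in array order (x fastest)
grid_coord <- function(grid, axis) {
  d <- grid$dims
  switch(axis,
         rep(grid$xs, times = d[2] * d[3]),
         rep(rep(grid$ys, each = d[1]), times = d[3]),
         rep(grid$zs, each = d[1] * d[2]))
}

sdf_mesh <- function(grid, mesh, band) {
  cpp_grid_sdf(mesh$vertices, f0(mesh), grid$origin, grid$h, grid$dims, band)
}

# exact SDF of an axis-aligned box given corner bounds (2 x 3 matrix)
sdf_box <- function(grid, bounds) {
  center <- colMeans(bounds)
  half <- (bounds[2, ] - bounds[1, ]) / 2
  qx <- abs(grid_coord(grid, 1) - center[1]) - half[1]
  qy <- abs(grid_coord(grid, 2) - center[2]) - half[2]
  qz <- abs(grid_coord(grid, 3) - center[3]) - half[3]
  inside <- pmin(pmax(qx, qy, qz), 0)
  qx[qx < 0] <- 0; qy[qy < 0] <- 0; qz[qz < 0] <- 0
  inside + sqrt(qx^2 + qy^2 + qz^2)
}

# exact SDF of a finite solid cylinder along coordinate `axis`, cross-section
# centred at `center2` (the two other coordinates in axis order), spanning
# [span[1], span[2]] along the axis
sdf_cylinder <- function(grid, axis, center2, radius, span) {
  others <- setdiff(1:3, axis)
  u <- grid_coord(grid, others[1]) - center2[1]
  w <- grid_coord(grid, others[2]) - center2[2]
  radial <- sqrt(u^2 + w^2) - radius
  t_ <- grid_coord(grid, axis)
  axial <- pmax(span[1] - t_, t_ - span[2])
  inside <- pmin(pmax(radial, axial), 0)
  radial[radial < 0] <- 0
  axial[axial < 0] <- 0
  inside + sqrt(radial^2 + axial^2)
}

# min-reduce a field over one axis -> matrix over the remaining two axes
reduce_min_axis <- function(field, dims, axis) {
  arr <- array(field, dims)
  if (axis == 1L) {
    out <- arr[1, , ]
    for (i in seq_len(dims[1])[-1]) out <- pmin(out, arr[i, , ])
  } else if (axis == 2L) {
    out <- arr[, 1, ]
    for (j in seq_len(dims[2])[-1]) out <- pmin(out, arr[, j, ])
  } else {
    out <- arr[, , 1]
    for (k in seq_len(dims[3])[-1]) out <- pmin(out, arr[, , k])
  }
  out
}

# broadcast a 2-axis matrix (the two non-`axis` dims, in order) back to 3D
broadcast_axis <- function(mat, dims, axis) {
  if (axis == 1L) {
    as.vector(aperm(array(rep(as.vector(mat), dims[1]),
                          c(dims[2], dims[3], dims[1])), c(3, 1, 2)))
  } else if (axis == 2L) {
    as.vector(aperm(array(rep(as.vector(mat), dims[2]),
                          c(dims[1], dims[3], dims[2])), c(1, 3, 2)))
  } else {
    rep(as.vector(mat), dims[3])
  }
}

# Prism swept from the cavity silhouette: silhouette distance is the
# min of the cavity field along the sweep axis (exact outside the
# silhouette, correct sign inside), restricted to the half-space on the
# `sign_axis` side of `cut_coord`.
sdf_silhouette_prism <- function(grid, cavity_field, axis, sign_axis, cut_coord) {
  silh <- broadcast_axis(reduce_min_axis(cavity_field, grid$dims, axis),
                         grid$dims, axis)
  t_ <- grid_coord(grid, axis)
  axial <- if (sign_axis > 0) cut_coord - t_ else t_ - cut_coord
  pmax(silh, axial)
}

# extract the zero level set as a surface mesh; errors if the result is not
# a closed printable surface
mesh_from_field <- function(grid, field, source_name = "iso-surface",
                            frame_label = "LPS", what = "iso-surface") {
  mt <- cpp_marching_tets(field, grid$dims, grid$origin, grid$h)
  if (nrow(mt$vertices) < 4L)
    stop_validation(sprintf(
      "%s: marching tetrahedra produced no surface (empty or out-of-grid solid)",
      what))
  mesh <- surface_mesh(mt$vertices, mt$faces + 1L, frame_label = frame_label,
                       source_name = source_name, validate = FALSE)
  rep_ <- mesh_report(mesh)
  if (!rep_$is_watertight)
    stop_validation(sprintf(
      "%s: extracted surface is not watertight; increase the grid margin or refine mesh_resolution_mm",
      what), rep_)
  mesh
}
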