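# STL reading/writing. Binary STL stores one float32 normal + three float32
# vertices per facet (vertices duplicated across facets); ASCII STL is the
# "solid ... facet normal ... vertex ..." text form. The package writes
# ASCII coordinates with 17 significant digits so an ASCII round trip is
# exact in double precision; binary round trips are exact to float32
# quantisation (about |x| * 2^-23 per coordinate), a property of the format
# itself.

#' Read an STL surface mesh
#'
#' Reads binary or ASCII STL (auto-detected), merges facet-duplicated
#' vertices within `merge_tolerance`, re-winds faces to a consistent
#' orientation (flipping globally if the total signed volume is negative),
#' and validates the result. No repair beyond merging and re-winding is
#' attempted: holes in a boundary segmentation are a data error, not noise,
#' and raise a validation error carrying the [mesh_report()].
#'
#' Units are taken to be millimetres throughout the package (the convention
#' of DICOM-derived exports); STL itself is unitless.
#'
#' @param path file path.
#' @param frame_label anatomical frame tag to attach (default `"LPS"`).
#' @param merge_tolerance vertex merge tolerance in mm.
#' @return a validated [surface_mesh()].
#' @export
read_stl <- function(path, frame_label = "LPS", merge_tolerance = 1e-6) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  tri <- tryCatch({
    if (is_binary_stl(path)) read_stl_binary(path) else read_stl_ascii(path)
  }, error = function(e) {
    if (inherits(e, "prostamould_format_error")) stop(e)
    stop_format(sprintf("cannot parse '%s' as STL: %s", path,
                        conditionMessage(e)))
  })
  if (nrow(tri) < 12L)
    stop_format(sprintf("'%s' holds fewer than 4 facets", path))
  nf <- nrow(tri) / 3L
  faces0 <- matrix(seq_len(nrow(tri)) - 1L, ncol = 3, byrow = TRUE)
  merged <- cpp_merge_vertices(tri, faces0, merge_tolerance)
  ori <- cpp_orient_consistent(merged$faces)
  faces <- ori$faces + 1L
  mesh <- surface_mesh(merged$vertices, faces, frame_label = frame_label,
                       source_name = basename(path), validate = FALSE)
  if (mesh_volume(mesh) < 0) mesh <- flip_faces(mesh)
  rep_ <- mesh_report(mesh)
  if (!isTRUE(ori$orientable))
    stop_validation(sprintf("'%s' is non-orientable after vertex merge", path), rep_)
  if (!rep_$is_watertight)
    stop_validation(sprintf("'%s' is not a closed surface after vertex merge", path),
                    rep_)
  mesh
}

#' Write an STL surface mesh
#'
#' Refuses non-watertight or non-finite meshes: everything written is meant
#' to be printable. Binary is the default dialect (compact, what slicers
#' and segmentation platforms exchange); ASCII preserves full double
#' precision.
#'
#' @param mesh a watertight [surface_mesh()].
#' @param path output file path.
#' @param dialect `"binary"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  assert_printable(mesh, sprintf("mesh for '%s'", basename(path)))
  V <- mesh$vertices
  F1 <- mesh$faces
  a <- V[F1[, 1], , drop = FALSE]
  b <- V[F1[, 2], , drop = FALSE]
  c_ <- V[F1[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  if (dialect == "binary") {
    nf <- nrow(F1)
    rec <- t(cbind(n, a, b, c_))            # 12 floats per facet, column = facet
    fraw <- writeBin(as.numeric(rec), raw(), size = 4L, endian = "little")
    body <- matrix(as.raw(0), nrow = 50L, ncol = nf)
    body[1:48, ] <- matrix(fraw, nrow = 48L)
    header <- charToRaw(sprintf("%-80s", "prostamould binary STL (mm)"))[1:80]
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(header, con)
    writeBin(as.integer(nf), con, size = 4L, endian = "little")
    writeBin(as.vector(body), con)
  } else {
    name <- gsub("[^A-Za-z0-9_.-]", "_", mesh$source_name)
    if (!nzchar(name)) name <- "mesh"
    fmt <- paste0(
      " facet normal %.17g %.17g %.17g\n  outer loop\n",
      "   vertex %.17g %.17g %.17g\n   vertex %.17g %.17g %.17g\n",
      "   vertex %.17g %.17g %.17g\n  endloop\n endfacet")
    lines <- sprintf(fmt,
                     n[, 1], n[, 2], n[, 3],
                     a[, 1], a[, 2], a[, 3],
                     b[, 1], b[, 2], b[, 3],
                     c_[, 1], c_[, 2], c_[, 3])
    writeLines(c(paste("solid", name), lines, paste("endsolid", name)), path)
  }
  invisible(path)
}

# A file is binary STL iff its size matches 84 + 50 * facet count; ASCII
# files that merely start with "solid" are caught by this size test.
is_binary_stl <- function(path) {
  sz <- file.size(path)
  if (is.na(sz) || sz < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80L))
  nf <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  !is.na(nf) && nf >= 0 && sz == 84 + 50 * as.numeric(nf)
}

read_stl_binary <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80L))
  nf <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  body <- readBin(con, "raw", sz - 84)
  if (length(body) != 50 * nf) stop_format("binary STL truncated")
  dim(body) <- c(50L, nf)
  fl <- readBin(as.vector(body[1:48, , drop = FALSE]), "numeric",
                n = 12L * nf, size = 4L, endian = "little")
  rec <- matrix(fl, nrow = 12L)           # rows 4..12 are the three vertices
  tri <- matrix(0, nrow = 3L * nf, ncol = 3L)
  tri[seq(1, 3 * nf, by = 3), ] <- t(rec[4:6, , drop = FALSE])
  tri[seq(2, 3 * nf, by = 3), ] <- t(rec[7:9, , drop = FALSE])
  tri[seq(3, 3 * nf, by = 3), ] <- t(rec[10:12, , drop = FALSE])
  tri
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop_format("ASCII STL has no complete facets")
  nums <- regmatches(vl, gregexpr("[-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?", vl))
  bad <- lengths(nums) != 3L
  if (any(bad)) stop_format("malformed vertex line in ASCII STL")
  matrix(as.numeric(unlist(nums)), ncol = 3L, byrow = TRUE)
}
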