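# Needle-insertion simulator: advances the needle to the fixed insertion
# depth along a guide axis, models the specimen notch as a 1D interval on
# that axis, and measures its intersection with the ROI volume by exact
# segment-mesh clipping. Rigid placement error is Monte-Carlo jitter of the
# specimen meshes relative to the mould.

#' Rigid specimen placement-error model
#'
#' Per-trial jitter applied to the specimen (boundary and ROI meshes)
#' relative to the mould: translation ~ N(0, `translation_sigma_mm`) per
#' axis, rotation ~ N(0, `rotation_sigma_deg`) about a random axis through
#' the cavity centroid, plus free play of up to
#' `boundary_offset_error_mm` (uniform in a ball) modelling a specimen
#' sitting loosely in an offset cavity.
#'
#' @param translation_sigma_mm per-axis translation SD (mm), >= 0.
#' @param rotation_sigma_deg rotation-angle SD (degrees), >= 0.
#' @param boundary_offset_error_mm free-play radius (mm), >= 0.
#' @param seed integer seed making trials reproducible.
#' @return list of class `error_model`.
#' @export
error_model <- function(translation_sigma_mm = 0, rotation_sigma_deg = 0,
                        boundary_offset_error_mm = 0, seed = 1L) {
  stopifnot(translation_sigma_mm >= 0, rotation_sigma_deg >= 0,
            boundary_offset_error_mm >= 0)
  structure(list(translation_sigma_mm = translation_sigma_mm,
                 rotation_sigma_deg = rotation_sigma_deg,
                 boundary_offset_error_mm = boundary_offset_error_mm,
                 seed = as.integer(seed)),
            class = "error_model")
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# total length of the intersection between the axis interval [t0, t1] and
# the inside of a watertight mesh, along origin + t * dir. A ray through a
# shared vertex or edge is reported once per incident triangle; collapsing
# near-identical parameters restores the crossing parity.
segment_mesh_overlap <- function(mesh, origin, dir, t0, t1) {
  ts <- cpp_ray_mesh_t(mesh$vertices, f0(mesh), origin, dir)
  if (length(ts) >= 2) ts <- ts[c(TRUE, diff(ts) > 1e-9)]
  if (length(ts) < 2) return(0)
  ts <- ts[seq_len(2 * (length(ts) %/% 2))]
  ivl <- matrix(ts, ncol = 2, byrow = TRUE)   # inside intervals
  lo <- pmax(ivl[, 1], t0)
  hi <- pmin(ivl[, 2], t1)
  sum(pmax(hi - lo, 0))
}

#' Simulate one needle insertion through a guide
#'
#' Advances the needle tip to the spec's fixed insertion depth along the
#' guide axis; the specimen notch is the interval of length
#' `notch_length_mm` centred `tip_to_notch_center_mm` behind the tip. The
#' notch-ROI intersection length comes from exact segment-mesh clipping; a
#' hit is any positive intersection.
#'
#' @param mould a `mould_model` from [build_mould_variants()] (provides the
#'   spec the guide was calibrated against).
#' @param guide a [calibrate_guide()] result belonging to that mould.
#' @param roi the target ROI surface (possibly perturbed).
#' @param needle the [needle_model()] inserted; its diameter must fit the
#'   channel.
#' @return one-row data.frame of class `targeting_report`: `guide_id`,
#'   `axis_to_centroid_mm`, `notch_roi_intersection_mm`, `hit`, `n_trials`,
#'   `hit_rate`.
#' @export
simulate_insertion <- function(mould, guide, roi, needle = NULL) {
  spec <- mould$spec
  if (is.null(needle)) needle <- spec$needle
  if (needle$outer_diameter_mm > guide$channel_diameter_mm)
    stop(sprintf("needle diameter %.2f mm exceeds channel diameter %.2f mm",
                 needle$outer_diameter_mm, guide$channel_diameter_mm),
         call. = FALSE)
  depth <- spec$insertion_depth_mm
  notch_mid <- depth - needle$tip_to_notch_center_mm
  t0 <- notch_mid - needle$notch_length_mm / 2
  t1 <- notch_mid + needle$notch_length_mm / 2
  len <- segment_mesh_overlap(roi, guide$entry_point_mm, guide$direction, t0, t1)
  cen <- mesh_centroid(roi)
  rel <- cen - guide$entry_point_mm
  perp <- rel - sum(rel * guide$direction) * guide$direction
  structure(data.frame(
    guide_id = guide$guide_id,
    axis_to_centroid_mm = sqrt(sum(perp^2)),
    notch_roi_intersection_mm = len,
    hit = len > 0,
    n_trials = 1L,
    hit_rate = NA_real_,
    stringsAsFactors = FALSE),
    class = c("targeting_report", "data.frame"))
}

#' Monte-Carlo hit rate under rigid placement error
#'
#' Applies the error model's seeded rigid jitter to the specimen's ROI
#' meshes relative to the mould, re-simulates every guide each trial, and
#' aggregates hit rates. With a zero error model every guide hits with rate
#' 1 by the calibration identity (the notch centre sits on the ROI
#' centroid).
#'
#' @param mould a `mould_model`.
#' @param case the `phantom_case` (or `prostate_case`) the mould was built
#'   for; provides the boundary (rotation pivot) and ROI meshes.
#' @param err an [error_model()].
#' @param n_trials number of Monte-Carlo trials, >= 1.
#' @return data.frame of class `targeting_report`, one row per guide, with
#'   `hit_rate` over trials and mean intersection/axis-distance.
#' @export
perturbed_hit_rate <- function(mould, case, err = error_model(),
                               n_trials = 100L) {
  stopifnot(n_trials >= 1)
  guides <- mould$guides
  pivot <- mesh_centroid(case$boundary)
  nt <- as.integer(n_trials)
  with_seed(err$seed, {
    trans <- matrix(stats::rnorm(3 * nt, 0, err$translation_sigma_mm), nt, 3)
    angs <- stats::rnorm(nt, 0, err$rotation_sigma_deg) * pi / 180
    axes <- matrix(stats::rnorm(3 * nt), nt, 3)
    if (err$boundary_offset_error_mm > 0) {
      u <- matrix(stats::rnorm(3 * nt), nt, 3)
      u <- u / sqrt(rowSums(u^2))
      play <- u * (err$boundary_offset_error_mm * stats::runif(nt)^(1 / 3))
      trans <- trans + play
    }
    hits <- matrix(0L, nt, length(guides))
    ilen <- matrix(0, nt, length(guides))
    adist <- matrix(0, nt, length(guides))
    for (i in seq_len(nt)) {
      R <- if (err$rotation_sigma_deg > 0)
        rotation_about_axis(axes[i, ], angs[i]) else diag(3)
      for (k in seq_along(guides)) {
        g <- guides[[k]]
        roi <- case$rois[[g$roi_label]]
        roi_t <- rigid_transform_mesh(roi, R, pivot, trans[i, ])
        rep1 <- simulate_insertion(mould, g, roi_t)
        hits[i, k] <- as.integer(rep1$hit)
        ilen[i, k] <- rep1$notch_roi_intersection_mm
        adist[i, k] <- rep1$axis_to_centroid_mm
      }
    }
    structure(data.frame(
      guide_id = vapply(guides, `[[`, "", "guide_id"),
      roi_label = vapply(guides, `[[`, "", "roi_label"),
      approach = vapply(guides, `[[`, "", "approach"),
      axis_to_centroid_mm = colMeans(adist),
      notch_roi_intersection_mm = colMeans(ilen),
      hit = colMeans(hits) == 1,
      n_trials = nt,
      hit_rate = colMeans(hits),
      stringsAsFactors = FALSE),
      class = c("targeting_report", "data.frame"))
  })
}
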