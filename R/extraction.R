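# Extraction: turn masked mandible pixels into a weighted, oriented point
# cloud.  The grey value becomes a third coordinate ("intensity lift") after
# two normalizations: a first-frame scale bringing greys into the spatial
# units, and a per-frame decile match keeping every frame in the first
# frame's grey range.

interdecile <- function(v) {
  q <- quantile(v, c(0.1, 0.9), names = FALSE, type = 7)
  q[2L] - q[1L]
}

#' First-frame intensity normalization parameters
#'
#' Computes the scale bringing grey values into the spatial (mm) range:
#' `scale_first = interdecile(proj) / (8 * interdecile(greys))`, where `proj`
#' is the projection of the pixel coordinates onto the least-variance
#' principal axis of the 2D coordinates, and `interdecile` is the 90th minus
#' the 10th percentile (linear interpolation between order statistics).
#' Also records the first decile and interdecile spread of the first-frame
#' greys for the per-frame distribution match.
#'
#' @param coords n x 2 matrix of masked-pixel coordinates (mm), n >= 10.
#' @param greys grey values of those pixels; must not be constant.
#' @return List of class `normalization_params`: `scale_first`, `d1_first`,
#'   `interdecile_first`.
#' @export
compute_intensity_scale <- function(coords, greys) {
  coords <- as_points(coords)
  if (nrow(coords) < 10L)
    stop_tmj("tmj_insufficient_data", "need at least 10 pixels")
  if (length(greys) != nrow(coords))
    stop_tmj("tmj_invalid_input", "one grey value per pixel required")
  idg <- interdecile(greys)
  if (idg <= 0)
    stop_tmj("tmj_zero_spread", "grey values have zero interdecile spread")
  ev <- eigen(cov(coords), symmetric = TRUE)
  minor_axis <- ev$vectors[, 2L]   # least-variance principal axis
  proj <- coords %*% minor_axis
  scale_first <- interdecile(proj) / (8 * idg)
  if (scale_first <= 0)
    stop_tmj("tmj_zero_spread", "coordinates have zero spread on the minor axis")
  structure(list(scale_first = scale_first,
                 d1_first = quantile(greys, 0.1, names = FALSE, type = 7),
                 interdecile_first = idg),
            class = "normalization_params")
}

#' Match a frame's grey distribution to the first frame's
#'
#' Affine map sending the current frame's first decile and interdecile spread
#' onto the first frame's:
#' `(g - d1_curr) * interdecile_first / interdecile_curr + d1_first`.
#' Mapping the first frame onto itself is the identity.
#'
#' @param greys_curr grey values of the current frame's masked pixels.
#' @param params a [compute_intensity_scale()] result for the first frame.
#' @param d1_curr,interdecile_curr optionally precomputed current-frame
#'   deciles (computed from `greys_curr` when omitted).
#' @return Matched grey values.
#' @export
match_grey_distribution <- function(greys_curr, params, d1_curr = NULL,
                                    interdecile_curr = NULL) {
  if (is.null(d1_curr))
    d1_curr <- quantile(greys_curr, 0.1, names = FALSE, type = 7)
  if (is.null(interdecile_curr)) interdecile_curr <- interdecile(greys_curr)
  if (interdecile_curr <= 0)
    stop_tmj("tmj_zero_spread", "current frame has zero grey spread")
  (greys_curr - d1_curr) * params$interdecile_first / interdecile_curr +
    params$d1_first
}

#' Lift masked pixels to a 3D point cloud
#'
#' One point per masked pixel: `x, y` from the pixel position times the
#' spacing, `z = scale_first * matched grey` so that intensity and space
#' share units.
#'
#' @param mask logical matrix (rows x cols).
#' @param image numeric matrix of the same shape (grey values).
#' @param slice_id slice number carried by every point.
#' @param params first-frame [compute_intensity_scale()] result for this
#'   slice.
#' @param spacing `c(sx, sy)` mm.
#' @param match if `FALSE`, greys are used as-is (the first frame matched
#'   against itself); otherwise they pass through
#'   [match_grey_distribution()].
#' @return A `point_cloud` data.frame: `x, y, z, nx, ny, nz, weight,
#'   slice_id, is_condyle` plus pixel bookkeeping `px_row, px_col`.
#' @export
lift_to_cloud <- function(mask, image, slice_id, params, spacing,
                          match = TRUE) {
  if (!any(mask)) stop_tmj("tmj_empty_mask", "mask is empty")
  spacing <- rep_len(as.numeric(spacing), 2L)
  idx <- which(mask, arr.ind = TRUE)
  greys <- image[idx]
  z <- params$scale_first *
    (if (match) match_grey_distribution(greys, params) else greys)
  cloud <- data.frame(
    x = (idx[, 2L] - 1) * spacing[1L],
    y = (idx[, 1L] - 1) * spacing[2L],
    z = z,
    nx = NA_real_, ny = NA_real_, nz = NA_real_,
    weight = 1,
    slice_id = as.integer(slice_id),
    is_condyle = FALSE,
    px_row = idx[, 1L],
    px_col = idx[, 2L]
  )
  class(cloud) <- c("point_cloud", "data.frame")
  cloud
}

#' Estimate per-point surface normals by neighborhood PCA
#'
#' For each point, the unit normal is the least-variance principal axis of
#' the lifted 3D positions of the point and its 8-connected lattice
#' neighbours (within the same slice).  The sign is fixed so the z-component
#' is >= 0.  Points with fewer than 3 neighbours are excluded from the
#' returned cloud.
#'
#' @param cloud a [lift_to_cloud()] result (possibly several slices bound
#'   together).
#' @return The cloud with `nx, ny, nz` set; isolated points dropped.
#' @export
estimate_normals <- function(cloud) {
  out <- lapply(split(cloud, cloud$slice_id), estimate_normals_slice)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("point_cloud", "data.frame")
  res
}

estimate_normals_slice <- function(cloud) {
  n <- nrow(cloud)
  nr <- max(cloud$px_row); nc <- max(cloud$px_col)
  idx <- matrix(0L, nr + 2L, nc + 2L)   # 1-px border so offsets never go OOB
  idx[cbind(cloud$px_row + 1L, cloud$px_col + 1L)] <- seq_len(n)
  pos <- cbind(cloud$x, cloud$y, cloud$z)
  # accumulate neighbourhood first and second moments via shifted lookups
  cnt <- numeric(n)
  S1 <- matrix(0, n, 3L)
  S2 <- matrix(0, n, 6L)  # xx, xy, xz, yy, yz, zz
  for (dr in -1:1) for (dc in -1:1) {
    nb <- idx[cbind(cloud$px_row + 1L + dr, cloud$px_col + 1L + dc)]
    has <- nb > 0L
    nbi <- nb[has]
    cnt[has] <- cnt[has] + 1
    p <- pos[nbi, , drop = FALSE]
    S1[has, ] <- S1[has, ] + p
    S2[has, ] <- S2[has, ] + cbind(p[, 1L]^2, p[, 1L] * p[, 2L],
                                   p[, 1L] * p[, 3L], p[, 2L]^2,
                                   p[, 2L] * p[, 3L], p[, 3L]^2)
  }
  keep <- cnt >= 4   # the point plus at least 3 neighbours
  normals <- matrix(NA_real_, n, 3L)
  for (i in which(keep)) {
    m <- S1[i, ] / cnt[i]
    C <- matrix(c(S2[i, 1L], S2[i, 2L], S2[i, 3L],
                  S2[i, 2L], S2[i, 4L], S2[i, 5L],
                  S2[i, 3L], S2[i, 5L], S2[i, 6L]), 3L, 3L) / cnt[i] -
      tcrossprod(m)
    v <- eigen(C, symmetric = TRUE)$vectors[, 3L]
    if (v[3L] < 0 || (v[3L] == 0 && v[1L] < 0)) v <- -v
    normals[i, ] <- v
  }
  cloud$nx <- normals[, 1L]; cloud$ny <- normals[, 2L]; cloud$nz <- normals[, 3L]
  cloud[keep, , drop = FALSE]
}

#' Remove points with near-vertical normals
#'
#' Pixels in flat-intensity surroundings have normals close to the vertical
#' (z) axis and carry little registration information; points whose normal is
#' strictly closer than `threshold_deg` to vertical are removed (a point at
#' exactly the threshold is retained).
#'
#' @param cloud cloud with normals set.
#' @param threshold_deg removal threshold in degrees (default 8).
#' @return The filtered cloud.
#' @export
filter_near_vertical <- function(cloud, threshold_deg = 8) {
  ang <- acos(pmin(1, pmax(-1, abs(cloud$nz)))) * 180 / pi
  # small slack so a point at exactly the threshold survives rounding
  out <- cloud[ang >= threshold_deg - 1e-9, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("point_cloud", "data.frame")
  out
}

#' Assign registration weights
#'
#' Base weight 1; points inside the condyle region have their weight doubled;
#' points on the middle slice (centred on the TMJ) receive a supplementary
#' increase of 150% (i.e. a further factor 2.5).  The factors combine
#' multiplicatively, giving weights in {1, 2, 2.5, 5}.
#'
#' @param cloud point cloud spanning one or more slices.
#' @param condyle_regions named list (by slice id) of condyle-region polygons
#'   (the condyle contour, closed), or a single polygon used for all slices.
#' @param middle_slice_id id of the middle slice.
#' @return The cloud with `weight` and `is_condyle` set.
#' @export
assign_weights <- function(cloud, condyle_regions, middle_slice_id) {
  if (!is.list(condyle_regions))
    condyle_regions <- stats::setNames(
      rep(list(condyle_regions), length(unique(cloud$slice_id))),
      as.character(unique(cloud$slice_id)))
  is_condyle <- logical(nrow(cloud))
  for (s in unique(cloud$slice_id)) {
    poly <- condyle_regions[[as.character(s)]]
    if (is.null(poly)) next
    sel <- cloud$slice_id == s
    is_condyle[sel] <- point_in_polygon(cloud$x[sel], cloud$y[sel], poly)
  }
  cloud$is_condyle <- is_condyle
  cloud$weight <- ifelse(is_condyle, 2, 1) *
    ifelse(cloud$slice_id == middle_slice_id, 2.5, 1)
  cloud
}

#' Full model-cloud extraction for one slice
#'
#' Convenience chain: rasterize mask, lift, estimate normals, filter
#' near-vertical points.  Weights are assigned afterwards across slices with
#' [assign_weights()].
#'
#' @param image grey matrix of the frame.
#' @param area [area_annotation()] for the slice.
#' @param params first-frame [compute_intensity_scale()] result.
#' @param spacing pixel spacing, mm.
#' @param vertical_filter_deg threshold for [filter_near_vertical()].
#' @param match passed to [lift_to_cloud()].
#' @return A `point_cloud`.
#' @export
extract_slice_cloud <- function(image, area, params, spacing,
                                vertical_filter_deg = 8, match = TRUE) {
  mask <- rasterize_area(area, dim(image), spacing)
  cloud <- lift_to_cloud(mask, image, area$slice_id, params, spacing,
                         match = match)
  cloud <- estimate_normals(cloud)
  filter_near_vertical(cloud, vertical_filter_deg)
}

#' Write a point cloud to CSV (debug dump)
#' @param cloud a `point_cloud`.
#' @param path output file.
#' @export
write_cloud_csv <- function(cloud, path) {
  utils::write.csv(cloud[, c("x", "y", "z", "nx", "ny", "nz", "weight",
                             "slice_id", "is_condyle")],
                   path, row.names = FALSE)
}
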