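# Synthetic phantom: a rigidly moving mandible-like shape (bright condyle
# disc with a smooth radial profile, attached ramus bar) over a static
# temporal-bone background, rendered at the acquisition geometry of the
# emulated protocol (128 x 128 px, 0.75 mm in-plane, 10 frames/s, 100
# frames, 3 slices).  Ground-truth transforms and landmark tracks make every
# other module testable without patient data.

logistic <- function(x) 1 / (1 + exp(-x))

#' Phantom specification
#'
#' Defaults state the emulated acquisition and a realistic opening-closing
#' movement: 10 mm condylar translation along a circular "eminence path" arc
#' and 30 degrees of jaw rotation, both modulated by a sin^2 open-close
#' profile that is zero outside the movement cycle and peaks at the maximum
#' mouth opening (MMO) frame; mild through-plane shape change (fractional
#' erosion of the section, peaking at MMO); additive Gaussian grey noise.
#'
#' @param image_shape `c(rows, cols)` in px.
#' @param pixel_spacing `c(sx, sy)` mm.
#' @param n_frames,n_slices sequence size.
#' @param frame_rate frames per second.
#' @param slice_gap inter-slice distance, mm.
#' @param max_translation_mm peak condylar translation (chord of the arc).
#' @param max_rotation_deg peak jaw rotation.
#' @param cycle `c(first, last)` frames of the movement cycle.
#' @param mmo_frame frame of maximum mouth opening (default mid-cycle).
#' @param deformation_amplitude fractional shape erosion at MMO, in
#'   `[0, 0.2]`.
#' @param noise_sigma additive Gaussian noise, grey units.
#' @param seed RNG seed for the noise.
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(image_shape = c(128, 128),
                         pixel_spacing = c(0.75, 0.75),
                         n_frames = 100, n_slices = 3,
                         frame_rate = 10, slice_gap = 6,
                         max_translation_mm = 10, max_rotation_deg = 30,
                         cycle = NULL, mmo_frame = NULL,
                         deformation_amplitude = 0.1, noise_sigma = 5,
                         seed = 1) {
  if (n_frames < 2) stop_tmj("tmj_invalid_input", "n_frames must be >= 2")
  if (any(pixel_spacing <= 0))
    stop_tmj("tmj_invalid_input", "pixel spacing must be positive")
  if (deformation_amplitude < 0 || deformation_amplitude > 0.2)
    stop_tmj("tmj_invalid_input", "deformation_amplitude must be in [0, 0.2]")
  if (is.null(cycle))
    cycle <- c(max(2L, round(0.05 * n_frames)),
               min(n_frames - 1L, round(0.95 * n_frames)))
  if (cycle[2L] - cycle[1L] < 2)
    stop_tmj("tmj_invalid_input", "cycle needs at least one interior frame")
  if (is.null(mmo_frame))
    mmo_frame <- min(cycle[2L] - 1L, max(cycle[1L] + 1L, round(mean(cycle))))
  if (!(cycle[1L] < mmo_frame && mmo_frame < cycle[2L]))
    stop_tmj("tmj_invalid_input", "mmo_frame must lie inside the cycle")
  structure(list(image_shape = as.integer(image_shape),
                 pixel_spacing = as.numeric(pixel_spacing),
                 n_frames = as.integer(n_frames),
                 n_slices = as.integer(n_slices),
                 frame_rate = frame_rate, slice_gap = slice_gap,
                 max_translation_mm = max_translation_mm,
                 max_rotation_deg = max_rotation_deg,
                 cycle = as.integer(cycle),
                 mmo_frame = as.integer(mmo_frame),
                 deformation_amplitude = deformation_amplitude,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Open-close profile: 0 outside the cycle, sin^2 ramp to 1 at the MMO frame.
open_close_profile <- function(spec) {
  t <- seq_len(spec$n_frames)
  cf <- spec$cycle[1L]; cl <- spec$cycle[2L]; mmo <- spec$mmo_frame
  s <- numeric(spec$n_frames)
  up <- t > cf & t <= mmo
  dn <- t > mmo & t < cl
  s[up] <- sin(pi / 2 * (t[up] - cf) / (mmo - cf))^2
  s[dn] <- sin(pi / 2 * (cl - t[dn]) / (cl - mmo))^2
  s
}

# Frame-1 anatomy of the phantom, mm.  The condyle disc sits under a static
# temporal-bone band; the ramus bar runs down to the gonion.
phantom_geometry <- function(spec) {
  mid <- (spec$n_slices + 1L) %/% 2L
  radii <- 6 - 0.4 * abs(seq_len(spec$n_slices) - mid)
  list(
    condyle_center = c(62, 26),
    condyle_radii = radii,
    bar_start = c(60, 30),
    gonion = c(46, 64),
    bar_halfwidth = 5,
    eminence_center = c(57, 12),
    landmarks = landmark_set(rbind(
      eminence_crest_inferior = c(52, 13),
      fossa_superior = c(64, 11),
      condyle_superior = c(62, 26 - radii[mid]),
      incisura_inferior = c(55, 35),
      gonion = c(46, 64)
    )),
    middle_slice = mid
  )
}

# True rigid transform at movement progress s in [0, 1]: the condyle centre
# slides along the eminence arc while the jaw rotates about it.
phantom_transform <- function(spec, geom, s) {
  c0 <- geom$condyle_center
  e <- geom$eminence_center
  re <- sqrt(sum((c0 - e)^2))
  phi0 <- atan2(c0[2L] - e[2L], c0[1L] - e[1L])
  dphi <- 2 * asin(min(1, spec$max_translation_mm / (2 * re)))
  phi <- phi0 + dphi * s
  ct <- e + re * c(cos(phi), sin(phi))
  theta <- -spec$max_rotation_deg * pi / 180 * s
  R <- rotmat2(theta)
  tt <- ct - R %*% c0
  rigid_transform2d(theta, tt[1L], tt[2L])
}

# Render one slice of one frame (noise-free), greys as a rows x cols matrix.
render_slice <- function(spec, geom, slice, transform, shrink) {
  nr <- spec$image_shape[1L]; nc <- spec$image_shape[2L]
  sp <- spec$pixel_spacing
  px <- rep((seq_len(nc) - 1) * sp[1L], each = nr)
  py <- rep((seq_len(nr) - 1) * sp[2L], times = nc)
  # pull back pixel centres to frame-1 shape coordinates
  Ri <- rotmat2(-transform$theta)
  dx <- px - transform$tx; dy <- py - transform$ty
  x0 <- Ri[1L, 1L] * dx + Ri[1L, 2L] * dy
  y0 <- Ri[2L, 1L] * dx + Ri[2L, 2L] * dy
  r <- geom$condyle_radii[slice] * shrink
  c0 <- geom$condyle_center
  d <- sqrt((x0 - c0[1L])^2 + (y0 - c0[2L])^2)
  disc <- 170 * logistic((r - d) / 1.5) *
    (1 - 0.25 * pmin(d / r, 1)^2)
  a <- geom$bar_start; g <- geom$gonion
  v <- g - a; L2 <- sum(v^2)
  u <- pmin(1, pmax(0, ((x0 - a[1L]) * v[1L] + (y0 - a[2L]) * v[2L]) / L2))
  ds <- sqrt((x0 - (a[1L] + u * v[1L]))^2 + (y0 - (a[2L] + u * v[2L]))^2)
  bar <- 140 * logistic((geom$bar_halfwidth * shrink - ds) / 1.5) *
    (1 - 0.15 * u)
  mandible <- pmax(disc, bar)
  background <- 15 + 95 * logistic((13 - py) / 1.2)
  matrix(pmax(mandible, background), nr, nc)
}

# Extreme points of the mandible shape in frame-1 coordinates (with edge
# margin), used for the out-of-bounds check.
phantom_extremes <- function(geom, slice) {
  r <- geom$condyle_radii[slice] + 2.5
  c0 <- geom$condyle_center
  hw <- geom$bar_halfwidth + 2.5
  a <- geom$bar_start; g <- geom$gonion
  v <- (g - a) / sqrt(sum((g - a)^2))
  n <- c(-v[2L], v[1L])
  rbind(c0 + c(r, 0), c0 - c(r, 0), c0 + c(0, r), c0 - c(0, r),
        a + hw * n, a - hw * n, g + hw * n, g - hw * n, g + hw * v)
}

#' Generate a phantom sequence with ground truth
#'
#' Renders the phantom per [phantom_spec()], returning the frame sequence and
#' a `phantom_ground_truth` holding the true per-frame rigid transforms,
#' landmark tracks (condyle superior, gonion, condyle centre), and a complete
#' [study_annotation()] (keyframes by the keyframe rule, with exact landmark
#' positions; mandible area polygon, condyle and fossa contours per slice).
#' Identical spec and seed give bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return List: `frames` (a [frame_sequence()]) and `truth`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  geom <- phantom_geometry(spec)
  s <- open_close_profile(spec)
  transforms <- lapply(s, function(si) phantom_transform(spec, geom, si))
  fov <- (spec$image_shape - 1) * rev(spec$pixel_spacing)  # c(y, x) extent
  for (t in seq_len(spec$n_frames)) {
    ext <- apply_transform(transforms[[t]], phantom_extremes(geom, 1L))
    if (any(ext[, 1L] < 0 | ext[, 1L] > fov[2L] |
            ext[, 2L] < 0 | ext[, 2L] > fov[1L]))
      stop_tmj("tmj_out_of_bounds", "phantom shape leaves the field of view")
  }
  data <- array(0, c(spec$image_shape[1L], spec$image_shape[2L],
                     spec$n_slices, spec$n_frames))
  set.seed(spec$seed)
  for (t in seq_len(spec$n_frames)) {
    shrink <- 1 - spec$deformation_amplitude * s[t]
    for (sl in seq_len(spec$n_slices)) {
      img <- render_slice(spec, geom, sl, transforms[[t]], shrink)
      if (spec$noise_sigma > 0)
        img <- img + matrix(rnorm(length(img), 0, spec$noise_sigma), nrow(img))
      data[, , sl, t] <- img
    }
  }
  frames <- frame_sequence(data, spec$pixel_spacing, spec$frame_rate,
                           spec$slice_gap)
  lm1 <- unclass(geom$landmarks)
  tracks <- list(
    condyle_superior = t(vapply(transforms, function(tr)
      drop(apply_transform(tr, lm1["condyle_superior", ])), numeric(2))),
    gonion = t(vapply(transforms, function(tr)
      drop(apply_transform(tr, lm1["gonion", ])), numeric(2))),
    condyle_center = t(vapply(transforms, function(tr)
      drop(apply_transform(tr, geom$condyle_center)), numeric(2)))
  )
  annotation <- phantom_annotation(spec, geom, transforms)
  truth <- structure(list(transforms = transforms, tracks = tracks,
                          annotation = annotation, spec = spec, geom = geom,
                          profile = s),
                     class = "phantom_ground_truth")
  list(frames = frames, truth = truth)
}

# Annotation as a rater would draw it on frame 1, with exact keyframe
# landmarks taken from the ground-truth transforms.
phantom_annotation <- function(spec, geom, transforms) {
  slices <- lapply(seq_len(spec$n_slices), function(sl) {
    r <- geom$condyle_radii[sl]
    c0 <- geom$condyle_center
    ang <- seq(0, 2 * pi, length.out = 25L)[-25L]
    contour <- cbind(c0[1L] + r * cos(ang), c0[2L] + r * sin(ang))
    hull_pts <- rbind(cbind(c0[1L] + (r + 2) * cos(ang),
                            c0[2L] + (r + 2) * sin(ang)),
                      capsule_outline(geom$bar_start, geom$gonion,
                                      geom$bar_halfwidth + 2))
    poly <- hull_pts[grDevices::chull(hull_pts), , drop = FALSE]
    e <- geom$eminence_center
    fa <- seq(0.6, 2.5, length.out = 12L)
    fossa <- cbind(e[1L] + 13 * cos(fa), e[2L] + 13 * sin(fa))
    area_annotation(sl, poly, contour, fossa)
  })
  kf <- select_keyframes(spec$n_frames, spec$cycle[1L], spec$cycle[2L])
  lm1 <- unclass(geom$landmarks)
  static <- c("eminence_crest_inferior", "fossa_superior")
  sets <- lapply(kf, function(k) {
    m <- lm1
    m[MANDIBULAR_LANDMARKS, ] <-
      apply_transform(transforms[[k]], lm1[MANDIBULAR_LANDMARKS, ])
    m[static, ] <- lm1[static, ]
    landmark_set(m)
  })
  study_annotation(spec$pixel_spacing, spec$n_frames, slices,
                   keyframe_track(kf, sets), spec$cycle,
                   middle_slice = geom$middle_slice)
}

# Point samples covering a capsule (segment with rounded ends); only used to
# feed the convex hull of the rater-style area polygon, so full circles at
# the two ends plus the side corners are sufficient.
capsule_outline <- function(a, g, hw) {
  v <- g - a; v <- v / sqrt(sum(v^2))
  n <- c(-v[2L], v[1L])
  ang <- seq(0, 2 * pi, length.out = 13L)[-13L]
  rbind(a + hw * n, g + hw * n, a - hw * n, g - hw * n,
        cbind(a[1L] + hw * cos(ang), a[2L] + hw * sin(ang)),
        cbind(g[1L] + hw * cos(ang), g[2L] + hw * sin(ang)))
}

#' Perturb ground-truth manual landmarks
#'
#' Adds isotropic Gaussian noise of `sigma_px` pixels (converted to mm) to
#' the true condyle-superior and gonion tracks, emulating unreliable manual
#' placement.  `sigma_px = 0` returns the truth.
#'
#' @param truth a `phantom_ground_truth`.
#' @param sigma_px noise standard deviation per coordinate, px.
#' @param seed RNG seed.
#' @return Data.frame `frame, cs_x, cs_y, go_x, go_y` (mm).
#' @export
perturb_landmarks <- function(truth, sigma_px, seed = 1) {
  if (sigma_px < 0) stop_tmj("tmj_invalid_input", "sigma must be >= 0")
  sp <- truth$spec$pixel_spacing
  n <- truth$spec$n_frames
  cs <- truth$tracks$condyle_superior
  go <- truth$tracks$gonion
  set.seed(seed)
  if (sigma_px > 0) {
    cs <- cs + cbind(rnorm(n, 0, sigma_px * sp[1L]),
                     rnorm(n, 0, sigma_px * sp[2L]))
    go <- go + cbind(rnorm(n, 0, sigma_px * sp[1L]),
                     rnorm(n, 0, sigma_px * sp[2L]))
  }
  data.frame(frame = seq_len(n), cs_x = cs[, 1L], cs_y = cs[, 2L],
             go_x = go[, 1L], go_y = go[, 2L])
}

#' Perturb the annotation's keyframe landmarks
#'
#' Same noise model as [perturb_landmarks()] applied to the sparse keyframe
#' landmark sets of the phantom annotation (all five landmarks), emulating
#' imprecise placement on the keyframes that feed the rough transform.
#'
#' @param truth a `phantom_ground_truth`.
#' @param sigma_px noise standard deviation per coordinate, px.
#' @param seed RNG seed.
#' @return A [study_annotation()] with perturbed keyframe landmarks.
#' @export
perturb_annotation_landmarks <- function(truth, sigma_px, seed = 1) {
  ann <- truth$annotation
  if (sigma_px == 0) return(ann)
  sp <- truth$spec$pixel_spacing
  set.seed(seed)
  sets <- lapply(ann$keyframe_track$landmark_sets, function(ls) {
    m <- unclass(ls)
    m[, 1L] <- m[, 1L] + rnorm(nrow(m), 0, sigma_px * sp[1L])
    m[, 2L] <- m[, 2L] + rnorm(nrow(m), 0, sigma_px * sp[2L])
    landmark_set(m)
  })
  ann$keyframe_track <- keyframe_track(ann$keyframe_track$keyframes, sets)
  ann
}
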