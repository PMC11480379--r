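# The LMS registration core: nearest-point pairing, superimposition error,
# weighted point-to-plane rigid fit, diagonal-scaling refinement, per-frame
# convergence loop, whole-sequence tracking.
#
# The transform acts on (x, y) only; the lifted grey coordinate z is compared
# during pairing and in the error but never transformed.  Normals are
# transported by the rotation (in-plane components rotated, z untouched).

cloud_xyz <- function(cloud) cbind(cloud$x, cloud$y, cloud$z)

cloud_normals <- function(cloud) cbind(cloud$nx, cloud$ny, cloud$nz)

#' Transform a point cloud
#'
#' Applies a planar transform to a cloud's (x, y) positions and rotates the
#' in-plane normal components by the transform's rotation; z is untouched.
#'
#' @param t a `transform2d`.
#' @param cloud a `point_cloud`.
#' @return The transformed cloud.
#' @export
transform_cloud <- function(t, cloud) {
  xy <- apply_transform(t, cbind(cloud$x, cloud$y))
  cloud$x <- xy[, 1L]; cloud$y <- xy[, 2L]
  R <- rotmat2(t$theta)
  nxy <- cbind(cloud$nx, cloud$ny) %*% t(R)
  cloud$nx <- nxy[, 1L]; cloud$ny <- nxy[, 2L]
  cloud
}

#' Nearest-point pairing
#'
#' Pairs every model point with the closest observed point in 3D (Euclidean
#' distance; ties broken by lowest observed index).  The model cloud should
#' already be transformed by the current estimate.
#'
#' @param model,observed `point_cloud`s (or n x 3 matrices).
#' @return List of class `pairing`: `indices` (into the observed cloud),
#'   `offsets` (model minus observed, n x 3) and `distances`.
#' @export
pair_points <- function(model, observed) {
  pm <- if (is.matrix(model)) model else cloud_xyz(model)
  po <- if (is.matrix(observed)) observed else cloud_xyz(observed)
  if (nrow(pm) == 0L || nrow(po) == 0L)
    stop_tmj("tmj_empty_mask", "cannot pair with an empty cloud")
  idx <- nn_pair_cpp(pm, po)
  off <- pm - po[idx, , drop = FALSE]
  structure(list(indices = idx, offsets = off,
                 distances = sqrt(rowSums(off^2))),
            class = "pairing")
}

#' Superimposition error
#'
#' The mean, over model points, of the absolute distance between a
#' transformed model point and its paired observed point projected onto the
#' model point's surface normal: `mean(|n_i . (p_i - q_i)|)`.  The mean is
#' unweighted; weights enter only the optimization.  The value mixes spatial
#' and lifted-grey distances and is therefore dimensionless by convention.
#'
#' @param model transformed model `point_cloud` (normals transported).
#' @param observed observed `point_cloud`.
#' @param pairing a [pair_points()] result (recomputed when omitted).
#' @return Non-negative scalar.
#' @export
superimposition_error <- function(model, observed, pairing = NULL) {
  if (is.null(pairing)) pairing <- pair_points(model, observed)
  mean(abs(rowSums(cloud_normals(model) * pairing$offsets)))
}

# Weighted linear least squares with explicit rank check.
solve_wls <- function(A, b, w) {
  Aw <- A * w
  M <- crossprod(Aw, A)
  if (rcond(M) < 1e-12)
    stop_tmj("tmj_degenerate_geometry",
             "normal-equation system is rank deficient (degenerate normals)")
  solve(M, crossprod(Aw, b))
}

#' Weighted point-to-plane rigid fit
#'
#' Given a fixed pairing, finds `(theta, T)` minimizing the weighted squared
#' projected residual `sum w_i [n_i . (R x_i + T - q_i)]^2`, where the
#' transform acts on (x, y) only and the normal is transported by the current
#' rotation.  Solved by iterated small-angle linearization; the inner loop
#' stops when the objective decreases by less than `1e-10`.
#'
#' @param model model `point_cloud` in its own (frame-1) coordinates, with
#'   normals and weights set; an optional diagonal pre-scaling `h` (length 2)
#'   is applied to the model coordinates first, so a cycle's rigid step can
#'   keep the previous scaling fixed.
#' @param targets n x 3 matrix of paired observed points (one per model
#'   point).
#' @param theta_init starting rotation (radians).
#' @param h fixed diagonal scaling applied before the rotation
#'   (default `c(1, 1)`).
#' @return A `rigid_transform2d`.
#' @export
fit_rigid_point_to_plane <- function(model, targets, theta_init = 0,
                                     h = c(1, 1)) {
  if (nrow(model) < 3L)
    stop_tmj("tmj_degenerate_geometry", "need at least 3 pairs")
  x <- cbind(model$x * h[1L], model$y * h[2L])
  z <- model$z
  nrm <- cloud_normals(model)
  w <- model$weight
  qxy <- targets[, 1:2, drop = FALSE]
  dz <- z - targets[, 3L]
  theta <- theta_init
  prev_obj <- Inf
  tt <- c(0, 0)
  for (iter in 1:50) {
    R <- rotmat2(theta)
    a <- x %*% t(R)
    nxy <- cbind(model$nx, model$ny) %*% t(R)
    # residual r = nxy.(a + d J a + T - q) + nz dz, J = 90 deg ccw rotation
    Ja <- cbind(-a[, 2L], a[, 1L])
    A <- cbind(rowSums(nxy * Ja), nxy[, 1L], nxy[, 2L])
    b <- -(rowSums(nxy * (a - qxy)) + nrm[, 3L] * dz)
    sol <- solve_wls(A, b, w)
    theta_new <- theta + sol[1L]
    tt <- sol[2:3]
    Rn <- rotmat2(theta_new)
    an <- x %*% t(Rn)
    nn <- cbind(model$nx, model$ny) %*% t(Rn)
    r <- rowSums(nn * (sweep(an, 2L, tt, `+`) - qxy)) + nrm[, 3L] * dz
    obj <- sum(w * r^2)
    theta <- theta_new
    if (prev_obj - obj < 1e-10) break
    prev_obj <- obj
  }
  rigid_transform2d(wrap_angle(theta), tt[1L], tt[2L])
}

#' Weighted scaling (homothety) fit with fixed rotation
#'
#' With the rotation fixed, finds the translation and diagonal scaling
#' `(h11, h22, Tx, Ty)` minimizing the weighted squared projected residual
#' `sum w_i [n_i . (R H x_i + T - q_i)]^2` — a linear least-squares problem
#' in the four unknowns.  The scalings are clamped to `clamp` (default
#' `[0.8, 1.25]`) to stop the step collapsing the cloud on degenerate
#' geometry; when a clamp engages, the translation is re-solved with the
#' scaling fixed.
#'
#' @param model model `point_cloud` (frame-1 coordinates, normals, weights).
#' @param targets n x 3 matrix of paired observed points.
#' @param theta fixed rotation (radians).
#' @param clamp allowed scaling interval.
#' @return A `scaled_transform2d`.
#' @export
fit_scaling <- function(model, targets, theta, clamp = c(0.8, 1.25)) {
  if (nrow(model) < 4L)
    stop_tmj("tmj_degenerate_geometry", "need at least 4 pairs")
  R <- rotmat2(theta)
  nxy <- cbind(model$nx, model$ny) %*% t(R)
  w <- model$weight
  qxy <- targets[, 1:2, drop = FALSE]
  dz <- model$z - targets[, 3L]
  # R H x = h11 x1 R[,1] + h22 x2 R[,2]
  c1 <- cbind(model$x * R[1L, 1L], model$x * R[2L, 1L])
  c2 <- cbind(model$y * R[1L, 2L], model$y * R[2L, 2L])
  A <- cbind(rowSums(nxy * c1), rowSums(nxy * c2), nxy[, 1L], nxy[, 2L])
  b <- rowSums(nxy * qxy) - cbind(model$nz)[, 1L] * dz
  sol <- solve_wls(A, b, w)
  h <- pmin(clamp[2L], pmax(clamp[1L], sol[1:2]))
  if (any(h != sol[1:2])) {
    # re-solve translation with the clamped scaling fixed
    b2 <- b - A[, 1L] * h[1L] - A[, 2L] * h[2L]
    sol2 <- solve_wls(A[, 3:4, drop = FALSE], b2, w)
    tt <- sol2
  } else tt <- sol[3:4]
  scaled_transform2d(wrap_angle(theta), tt[1L], tt[2L], h[1L], h[2L])
}

#' Registration configuration
#'
#' @param tol relative superimposition-error change below which the cycle
#'   loop stops (default 1e-4).
#' @param max_iterations maximum pairing/rigid/scaling cycles (default 50).
#' @param vertical_filter_deg near-vertical normal removal threshold
#'   (default 8 degrees).
#' @param weight_condyle condyle weight factor (default 2).
#' @param weight_middle_slice middle-slice weight factor (default 2.5, i.e. a
#'   supplementary increase of 150%).
#' @param scaling_bounds clamp interval for the homothety
#'   (default `c(0.8, 1.25)`).
#' @param icr_min_rotation_deg minimum incremental rotation for a defined ICR
#'   (default 0.1 degrees).
#' @return List of class `registration_config`.
#' @export
registration_config <- function(tol = 1e-4, max_iterations = 50,
                                vertical_filter_deg = 8,
                                weight_condyle = 2,
                                weight_middle_slice = 2.5,
                                scaling_bounds = c(0.8, 1.25),
                                icr_min_rotation_deg = 0.1) {
  structure(list(tol = tol, max_iterations = max_iterations,
                 vertical_filter_deg = vertical_filter_deg,
                 weight_condyle = weight_condyle,
                 weight_middle_slice = weight_middle_slice,
                 scaling_bounds = scaling_bounds,
                 icr_min_rotation_deg = icr_min_rotation_deg),
            class = "registration_config")
}

#' Register one frame
#'
#' The iterative cycle: (1) pair each transformed model point with the
#' closest observed point, (2) refit the rigid transform (scaling held
#' fixed), (3) refit translation and scaling with the rotation fixed.  After
#' each cycle the superimposition error is recomputed under a fresh pairing;
#' the loop stops when the relative error change drops below `config$tol`,
#' after `config$max_iterations` cycles, or when a cycle increases the error
#' (the previous state is returned, so the accepted-error series is
#' non-increasing).
#'
#' @param model prepared model `point_cloud` (normals, weights, filtering
#'   done), in frame-1 coordinates.
#' @param observed observed `point_cloud` of the current frame.
#' @param init initial transform (typically the rough landmark transform).
#' @param config a [registration_config()].
#' @return List of class `frame_registration`: `transform`,
#'   `superimposition_error`, `n_iterations`, `converged`.
#' @export
register_frame <- function(model, observed, init = rigid_transform2d(),
                           config = registration_config()) {
  state <- scaled_transform2d(init$theta, init$tx, init$ty, init$h11, init$h22)
  tm <- transform_cloud(state, model)
  pairing <- pair_points(tm, observed)
  err <- superimposition_error(tm, observed, pairing)
  converged <- FALSE
  n_iter <- 0L
  obs_xyz <- cloud_xyz(observed)
  for (cycle in seq_len(config$max_iterations)) {
    targets <- obs_xyz[pairing$indices, , drop = FALSE]
    rigid <- fit_rigid_point_to_plane(model, targets, theta_init = state$theta,
                                      h = c(state$h11, state$h22))
    scaled <- fit_scaling(model, targets, rigid$theta,
                          clamp = config$scaling_bounds)
    cand <- scaled
    tm_c <- transform_cloud(cand, model)
    pairing_c <- pair_points(tm_c, observed)
    err_c <- superimposition_error(tm_c, observed, pairing_c)
    if (err_c > err) { converged <- TRUE; break }  # local optimum: keep previous
    n_iter <- cycle
    rel <- if (err > 0) (err - err_c) / err else 0
    state <- cand
    pairing <- pairing_c
    err <- err_c
    if (rel < config$tol) { converged <- TRUE; break }
  }
  structure(list(transform = state, superimposition_error = err,
                 n_iterations = n_iter, converged = converged),
            class = "frame_registration")
}

# -- whole-sequence tracking -------------------------------------------------

# Rough transform at a frame: rigid SVD fit of the three mandibular
# landmarks from frame 1 to the (interpolated) current frame.
rough_transform_at <- function(track, frame, lm1 = NULL) {
  if (is.null(lm1)) lm1 <- interpolate_landmarks(track, 1L)
  lmt <- interpolate_landmarks(track, frame)
  fit_rigid_svd(unclass(lm1)[MANDIBULAR_LANDMARKS, ],
                unclass(lmt)[MANDIBULAR_LANDMARKS, ])
}

# Build the per-slice first-frame normalization params and the model cloud.
build_model <- function(frames, annotation, config) {
  sp <- annotation$pixel_spacing
  params <- list()
  clouds <- list()
  for (s in seq_along(annotation$slices)) {
    area <- annotation$slices[[s]]
    img1 <- frames$data[, , s, 1L]
    mask <- rasterize_area(area, dim(img1), sp)
    idx <- which(mask, arr.ind = TRUE)
    coords <- cbind((idx[, 2L] - 1) * sp[1L], (idx[, 1L] - 1) * sp[2L])
    params[[s]] <- compute_intensity_scale(coords, img1[idx])
    clouds[[s]] <- extract_slice_cloud(img1, area, params[[s]], sp,
                                       config$vertical_filter_deg,
                                       match = FALSE)
  }
  model <- do.call(rbind, clouds)
  class(model) <- c("point_cloud", "data.frame")
  regions <- stats::setNames(
    lapply(annotation$slices, `[[`, "condyle_contour"),
    vapply(annotation$slices, function(a) as.character(a$slice_id), ""))
  model <- assign_weights(model, regions, annotation$middle_slice)
  list(model = model, params = params)
}

# Observed cloud at frame t under a transform-mapped first-frame polygon.
build_observed <- function(frames, annotation, params, frame, mapping) {
  sp <- annotation$pixel_spacing
  clouds <- list()
  for (s in seq_along(annotation$slices)) {
    area <- annotation$slices[[s]]
    poly_t <- apply_transform(mapping, area$mandible_polygon)
    img <- frames$data[, , s, frame]
    mask <- tryCatch(rasterize_area(poly_t, dim(img), sp),
                     tmj_empty_mask = function(e) NULL)
    if (is.null(mask)) next
    clouds[[length(clouds) + 1L]] <-
      lift_to_cloud(mask, img, area$slice_id, params[[s]], sp, match = TRUE)
  }
  if (length(clouds) == 0L) return(NULL)
  obs <- do.call(rbind, clouds)
  class(obs) <- c("point_cloud", "data.frame")
  obs
}

#' Track a whole sequence automatically
#'
#' For each frame: interpolate the keyframe landmarks, fit the rough rigid
#' transform from the three mandibular landmarks (frame 1 to frame t), map
#' the first-frame mandible polygon through it to mask the frame, lift the
#' masked pixels to an observed cloud, and register the first-frame model
#' cloud against it starting from the rough transform.
#'
#' @param frames a [frame_sequence()].
#' @param annotation a [study_annotation()].
#' @param config a [registration_config()].
#' @param verbose print one progress line per frame.
#' @return List of class `tracking_result`: `registrations` (per frame),
#'   `transforms`, `errors`, `rough_transforms`, `rough_errors`, `failed`
#'   (logical per frame), `model` (the first-frame cloud), `config`.
#' @export
track_sequence <- function(frames, annotation, config = registration_config(),
                           verbose = FALSE) {
  check_geometry(frames, annotation)
  mp <- build_model(frames, annotation, config)
  model <- mp$model
  track <- annotation$keyframe_track
  lm1 <- interpolate_landmarks(track, 1L)
  n <- frames$n_frames
  regs <- vector("list", n)
  roughs <- vector("list", n)
  rough_errors <- rep(NA_real_, n)
  failed <- logical(n)
  for (t in seq_len(n)) {
    rough <- rough_transform_at(track, t, lm1)
    roughs[[t]] <- rough
    obs <- build_observed(frames, annotation, mp$params, t, rough)
    if (is.null(obs)) {
      failed[t] <- TRUE
      regs[[t]] <- structure(list(transform = scaled_transform2d(
        rough$theta, rough$tx, rough$ty),
        superimposition_error = NA_real_, n_iterations = 0L,
        converged = FALSE), class = "frame_registration")
      next
    }
    tm_rough <- transform_cloud(rough, model)
    rough_errors[t] <- superimposition_error(tm_rough, obs)
    regs[[t]] <- register_frame(model, obs, init = rough, config = config)
    if (verbose)
      message(sprintf("frame %3d: %2d cycles, error %.5f", t,
                      regs[[t]]$n_iterations, regs[[t]]$superimposition_error))
  }
  structure(list(
    registrations = regs,
    transforms = lapply(regs, `[[`, "transform"),
    errors = vapply(regs, `[[`, 0, "superimposition_error"),
    rough_transforms = roughs,
    rough_errors = rough_errors,
    failed = failed,
    model = model,
    config = config
  ), class = "tracking_result")
}

#' @export
as.data.frame.tracking_result <- function(x, ...) {
  df <- transforms_to_df(x$transforms)
  df$superimposition_error <- x$errors
  df$n_iterations <- vapply(x$registrations, `[[`, 0L, "n_iterations")
  df$converged <- vapply(x$registrations, `[[`, NA, "converged") & !x$failed
  df
}

#' @export
print.tracking_result <- function(x, ...) {
  cat(sprintf(
    "<tracking_result> %d frames, %d failed, mean error %.4f, model %d points\n",
    length(x$errors), sum(x$failed), mean(x$errors, na.rm = TRUE),
    nrow(x$model)))
  invisible(x)
}
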