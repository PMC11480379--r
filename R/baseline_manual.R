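# Manual-tracking baseline: two landmarks per frame (condyle superior and
# gonion).  Translation follows condyle superior; rotation is adjusted with
# gonion.  The rotation centre is the current condyle superior so both
# landmark constraints are met exactly.

#' Rigid transform from two manually placed landmarks
#'
#' Translation is the displacement of condyle superior; rotation is the
#' signed angle from the first frame's condyle-superior-to-gonion direction
#' to the current frame's, applied about the current condyle superior.  The
#' returned transform maps first-frame points to current-frame points and is
#' exact on both defining landmarks.
#'
#' @param first,current lists with `condyle_superior` and `gonion` (length-2
#'   mm coordinates).
#' @return A `rigid_transform2d`.
#' @export
manual_track_frame <- function(first, current) {
  v1 <- first$gonion - first$condyle_superior
  v2 <- current$gonion - current$condyle_superior
  if (sqrt(sum(v1^2)) < 1e-9 || sqrt(sum(v2^2)) < 1e-9)
    stop_tmj("tmj_degenerate", "condyle superior and gonion are coincident")
  theta <- atan2(v1[1L] * v2[2L] - v1[2L] * v2[1L], sum(v1 * v2))
  R <- rotmat2(theta)
  tt <- current$condyle_superior - R %*% first$condyle_superior
  rigid_transform2d(theta, tt[1L], tt[2L])
}

#' Manual transforms for a whole sequence
#'
#' @param landmarks a data.frame with columns `frame, cs_x, cs_y, go_x, go_y`
#'   (mm), one row per frame, frame 1 first.
#' @return List of `rigid_transform2d`, one per frame.
#' @export
manual_track_all <- function(landmarks) {
  landmarks <- landmarks[order(landmarks$frame), , drop = FALSE]
  first <- list(condyle_superior = c(landmarks$cs_x[1L], landmarks$cs_y[1L]),
                gonion = c(landmarks$go_x[1L], landmarks$go_y[1L]))
  lapply(seq_len(nrow(landmarks)), function(i) {
    manual_track_frame(first, list(
      condyle_superior = c(landmarks$cs_x[i], landmarks$cs_y[i]),
      gonion = c(landmarks$go_x[i], landmarks$go_y[i])))
  })
}

#' Superimposition-error series of the manual method
#'
#' Applies each manual transform to the first-frame model cloud and evaluates
#' the same superimposition error used by the automatic method (pairing
#' recomputed per frame against the same observed clouds).
#'
#' @param transforms per-frame rigid transforms (e.g. [manual_track_all()]).
#' @param model prepared model `point_cloud`.
#' @param observed_list list of observed `point_cloud`s, one per frame
#'   (`NULL` entries yield `NA`).
#' @return Numeric vector of per-frame errors.
#' @export
manual_error_series <- function(transforms, model, observed_list) {
  vapply(seq_along(transforms), function(t) {
    obs <- observed_list[[t]]
    if (is.null(obs)) return(NA_real_)
    tm <- transform_cloud(transforms[[t]], model)
    superimposition_error(tm, obs)
  }, 0)
}

#' Track a sequence with the manual baseline
#'
#' Computes the per-frame manual transforms from the landmark table, builds
#' the observed clouds with the same masking and extraction machinery as the
#' automatic method (the first-frame polygon mapped through the manual
#' transform), and evaluates the superimposition error per frame.
#'
#' @param frames a [frame_sequence()].
#' @param annotation a [study_annotation()].
#' @param landmarks manual landmark table (see [manual_track_all()]).
#' @param config a [registration_config()].
#' @return List of class `manual_tracking_result`: `transforms`, `errors`,
#'   `failed`, `model`.
#' @export
manual_track_sequence <- function(frames, annotation, landmarks,
                                  config = registration_config()) {
  check_geometry(frames, annotation)
  if (nrow(landmarks) != frames$n_frames)
    stop_tmj("tmj_invalid_input", "need one landmark row per frame")
  transforms <- manual_track_all(landmarks)
  mp <- build_model(frames, annotation, config)
  n <- frames$n_frames
  errors <- rep(NA_real_, n)
  failed <- logical(n)
  for (t in seq_len(n)) {
    obs <- build_observed(frames, annotation, mp$params, t, transforms[[t]])
    if (is.null(obs)) { failed[t] <- TRUE; next }
    tm <- transform_cloud(transforms[[t]], mp$model)
    errors[t] <- superimposition_error(tm, obs)
  }
  structure(list(transforms = transforms, errors = errors, failed = failed,
                 model = mp$model),
            class = "manual_tracking_result")
}
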