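# Annotation data model: per-slice mandible areas and contours, named
# landmarks on sparse keyframes, keyframe selection and interpolation,
# polygon rasterization.

#' Landmark names
#'
#' The five named landmarks: two on the temporal bone (most inferior point of
#' the eminence crest; most superior point of the articular fossa) and three
#' on the mandible (most superior point of the condyle; most inferior point
#' of the mandibular incisura; gonion).  The mandibular three drive the rough
#' landmark-based transform; the temporal two are static reference anatomy.
#' @export
LANDMARK_NAMES <- c("eminence_crest_inferior", "fossa_superior",
                    "condyle_superior", "incisura_inferior", "gonion")

#' @rdname LANDMARK_NAMES
#' @export
MANDIBULAR_LANDMARKS <- c("condyle_superior", "incisura_inferior", "gonion")

#' Construct a landmark set
#'
#' @param coords a 5 x 2 matrix of mm coordinates with rownames covering
#'   [LANDMARK_NAMES], or a named list of length-2 vectors.
#' @return A 5 x 2 matrix (rows ordered as [LANDMARK_NAMES]) of class
#'   `landmark_set`.
#' @export
landmark_set <- function(coords) {
  if (is.list(coords) && !is.data.frame(coords))
    coords <- do.call(rbind, coords)
  coords <- as.matrix(coords)
  if (is.null(rownames(coords)) || !all(LANDMARK_NAMES %in% rownames(coords)))
    stop_tmj("tmj_invalid_input",
             paste("landmark set must name all of:",
                   paste(LANDMARK_NAMES, collapse = ", ")))
  m <- coords[LANDMARK_NAMES, , drop = FALSE]
  storage.mode(m) <- "double"
  if (!all(is.finite(m)))
    stop_tmj("tmj_invalid_input", "landmark coordinates must be finite")
  structure(m, class = c("landmark_set", "matrix"))
}

#' Keyframe selection rule
#'
#' Returns the sorted, de-duplicated union of: the first and last frame of
#' the scan; the first and last frame of the movement cycle; every multiple
#' of 25 strictly between the first and last frame.  For a 100-frame scan
#' with interior cycle bounds this yields seven keyframes.
#'
#' @param n_frames number of frames in the scan.
#' @param cycle_first,cycle_last first and last frame of the movement cycle
#'   (1-based, `cycle_first < cycle_last`).
#' @return Sorted integer vector of keyframe indices.
#' @examples
#' select_keyframes(100, 5, 95)  # 1 5 25 50 75 95 100
#' @export
select_keyframes <- function(n_frames, cycle_first, cycle_last) {
  if (length(n_frames) != 1L || n_frames < 2 ||
      n_frames != as.integer(n_frames))
    stop_tmj("tmj_invalid_input", "n_frames must be an integer >= 2")
  if (!(1 <= cycle_first && cycle_first < cycle_last && cycle_last <= n_frames))
    stop_tmj("tmj_invalid_input",
             "need 1 <= cycle_first < cycle_last <= n_frames")
  every25 <- seq(25L, by = 25L, length.out = max(0L, (n_frames - 1L) %/% 25L))
  every25 <- every25[every25 > 1L & every25 < n_frames]
  sort(unique(as.integer(c(1L, n_frames, cycle_first, cycle_last, every25))))
}

#' Keyframe track of landmark sets
#'
#' @param keyframes sorted distinct 1-based frame indices; the first must be
#'   1 and the last must equal the number of frames.
#' @param landmark_sets list of [landmark_set()]s, one per keyframe.
#' @export
keyframe_track <- function(keyframes, landmark_sets) {
  keyframes <- as.integer(keyframes)
  if (is.unsorted(keyframes, strictly = TRUE))
    stop_tmj("tmj_invalid_input", "keyframe indices must be strictly increasing")
  if (keyframes[1L] != 1L)
    stop_tmj("tmj_invalid_input", "first keyframe must be frame 1")
  if (length(landmark_sets) != length(keyframes))
    stop_tmj("tmj_invalid_input", "one landmark set per keyframe required")
  landmark_sets <- lapply(landmark_sets, landmark_set)
  structure(list(keyframes = keyframes, landmark_sets = landmark_sets),
            class = "keyframe_track")
}

#' Interpolate landmarks at an arbitrary frame
#'
#' Linear interpolation, per coordinate, between the two keyframes bracketing
#' `frame`; exact at keyframes.
#'
#' @param track a [keyframe_track()].
#' @param frame integer frame index, `1 <= frame <= last keyframe`.
#' @return A [landmark_set()].
#' @export
interpolate_landmarks <- function(track, frame) {
  kf <- track$keyframes
  if (frame < 1 || frame > kf[length(kf)])
    stop_tmj("tmj_invalid_input", sprintf("frame %s out of keyframe range", frame))
  hit <- match(frame, kf)
  if (!is.na(hit)) return(track$landmark_sets[[hit]])
  hi <- which(kf > frame)[1L]
  lo <- hi - 1L
  a <- (frame - kf[lo]) / (kf[hi] - kf[lo])
  landmark_set((1 - a) * unclass(track$landmark_sets[[lo]]) +
               a * unclass(track$landmark_sets[[hi]]))
}

polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(FALSE)
  seg <- cbind(poly, poly[c(2:n, 1L), , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      p1 <- seg[i, 1:2]; p2 <- seg[i, 3:4]; q1 <- seg[j, 1:2]; q2 <- seg[j, 3:4]
      d1 <- cross(p1[1], p1[2], p2[1], p2[2], q1[1], q1[2])
      d2 <- cross(p1[1], p1[2], p2[1], p2[2], q2[1], q2[2])
      d3 <- cross(q1[1], q1[2], q2[1], q2[2], p1[1], p1[2])
      d4 <- cross(q1[1], q1[2], q2[1], q2[2], p2[1], p2[2])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(FALSE)
    }
  }
  TRUE
}

#' Per-slice area annotation
#'
#' Holds the rater-drawn mandible area polygon (the pixels used for
#' registration), the condyle-head contour (used only to define the condyle
#' centre by circle fitting) and the articular-fossa contour.
#'
#' @param slice_id slice number (1-based).
#' @param mandible_polygon closed simple polygon, n x 2 mm coordinates
#'   (last vertex implicitly joins the first).
#' @param condyle_contour polyline along the condyle head, >= 3 points.
#' @param fossa_contour polyline along the fossa (may be NULL).
#' @export
area_annotation <- function(slice_id, mandible_polygon, condyle_contour,
                            fossa_contour = NULL) {
  mandible_polygon <- as_points(mandible_polygon)
  if (nrow(mandible_polygon) < 3L)
    stop_tmj("tmj_invalid_input", "mandible polygon needs >= 3 vertices")
  if (!polygon_is_simple(mandible_polygon))
    stop_tmj("tmj_invalid_input", "mandible polygon is self-intersecting")
  condyle_contour <- as_points(condyle_contour)
  if (!is.null(fossa_contour)) fossa_contour <- as_points(fossa_contour)
  structure(list(slice_id = as.integer(slice_id),
                 mandible_polygon = mandible_polygon,
                 condyle_contour = condyle_contour,
                 fossa_contour = fossa_contour),
            class = "area_annotation")
}

#' Vectorized even-odd point-in-polygon test
#'
#' Crossing-number (even-odd) rule; points exactly on an edge follow the
#' half-open convention of the crossing test.  Used for rasterization and for
#' flagging condyle points.
#'
#' @param px,py point coordinates (mm).
#' @param poly n x 2 polygon vertex matrix (closed implicitly).
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  poly <- as_points(poly)
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize an area polygon to a pixel mask
#'
#' A pixel is included iff its centre lies inside the polygon under the
#' even-odd rule.  Pixel centres sit at `x = (col-1)*sx`, `y = (row-1)*sy`.
#'
#' @param poly an [area_annotation()] or a plain n x 2 polygon matrix.
#' @param shape image shape `c(n_rows, n_cols)`.
#' @param spacing pixel spacing `c(sx, sy)` in mm (scalar recycled).
#' @return Logical matrix of dim `shape`; errors if empty.
#' @export
rasterize_area <- function(poly, shape, spacing) {
  if (inherits(poly, "area_annotation")) poly <- poly$mandible_polygon
  poly <- as_points(poly)
  spacing <- rep_len(as.numeric(spacing), 2L)
  nr <- shape[1L]; nc <- shape[2L]
  px <- rep((seq_len(nc) - 1) * spacing[1L], each = nr)
  py <- rep((seq_len(nr) - 1) * spacing[2L], times = nc)
  mask <- matrix(point_in_polygon(px, py, poly), nr, nc)
  if (!any(mask))
    stop_tmj("tmj_empty_mask", "polygon covers no pixel centre")
  mask
}

#' Automatic condyle centre
#'
#' The condyle centre is never placed by the rater: it is the centre of the
#' Pratt circle fitted to the condyle-head contour.
#'
#' @param area an [area_annotation()].
#' @return Length-2 numeric, mm.
#' @export
condyle_center <- function(area) {
  fit <- fit_circle_pratt(area$condyle_contour)
  c(fit$cx, fit$cy)
}

#' Study annotation container
#'
#' @param pixel_spacing `c(sx, sy)` mm.
#' @param n_frames number of frames.
#' @param slices list of [area_annotation()], one per slice.
#' @param keyframe_track a [keyframe_track()] (landmarks are annotated on the
#'   middle slice and shared across slices).
#' @param cycle `c(first, last)` frames of the movement cycle.
#' @param middle_slice id of the slice centred on the TMJ (default: middle of
#'   the slice list).
#' @export
study_annotation <- function(pixel_spacing, n_frames, slices, keyframe_track,
                             cycle, middle_slice = NULL) {
  if (length(slices) < 1L)
    stop_tmj("tmj_invalid_input", "need at least one slice annotation")
  kf <- keyframe_track$keyframes
  if (kf[length(kf)] != n_frames)
    stop_tmj("tmj_invalid_input", "last keyframe must equal n_frames")
  if (is.null(middle_slice)) middle_slice <- (length(slices) + 1L) %/% 2L
  structure(list(pixel_spacing = rep_len(as.numeric(pixel_spacing), 2L),
                 n_frames = as.integer(n_frames),
                 slices = slices,
                 keyframe_track = keyframe_track,
                 cycle = as.integer(cycle),
                 middle_slice = as.integer(middle_slice)),
            class = "study_annotation")
}
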