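# Readers and writers: frame sequences (lossless plain-text stack),
# annotation JSON, landmark and result CSVs, configuration JSON.
#
# rt-MRI exports vary; this package stores image sequences in a simple
# self-describing text format (one header line, then one whitespace-
# separated block per slice of each frame, full double precision) so that
# studies round-trip losslessly on any system without binary-format
# dependencies.

#' Frame sequence container
#'
#' @param data numeric array `[row, col, slice, frame]` of grey values.
#' @param pixel_spacing `c(sx, sy)` mm.
#' @param frame_rate frames per second.
#' @param slice_gap inter-slice distance, mm.
#' @return List of class `frame_sequence` with `data`, `pixel_spacing`,
#'   `frame_rate`, `slice_gap`, `n_frames`, `n_slices`, `shape`.
#' @export
frame_sequence <- function(data, pixel_spacing, frame_rate = 10,
                           slice_gap = 6) {
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L, 1L)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L)
    stop_tmj("tmj_invalid_input", "data must be a [row, col, slice, frame] array")
  pixel_spacing <- rep_len(as.numeric(pixel_spacing), 2L)
  if (any(pixel_spacing <= 0))
    stop_tmj("tmj_invalid_input", "pixel spacing must be positive")
  d <- dim(data)
  structure(list(data = data, pixel_spacing = pixel_spacing,
                 frame_rate = frame_rate, slice_gap = slice_gap,
                 n_frames = d[4L], n_slices = d[3L], shape = d[1:2]),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf(
    "<frame_sequence> %d x %d px, %d slice(s), %d frame(s), %.2f x %.2f mm/px\n",
    x$shape[1L], x$shape[2L], x$n_slices, x$n_frames,
    x$pixel_spacing[1L], x$pixel_spacing[2L]))
  invisible(x)
}

#' Write / read a frame sequence as plain text
#'
#' Lossless (`%.17g`) self-describing stack: a header line
#' `tmjtrack-frames <rows> <cols> <slices> <frames> <sx> <sy> <rate> <gap>`
#' followed by the grey values in column-major order.
#'
#' @param frames a [frame_sequence()].
#' @param path file path.
#' @export
write_frames <- function(frames, path) {
  con <- tryCatch(file(path, "w"), error = function(e)
    stop_tmj("tmj_io_error", paste("cannot open for writing:", path)))
  on.exit(close(con))
  d <- dim(frames$data)
  writeLines(paste("tmjtrack-frames", d[1L], d[2L], d[3L], d[4L],
                   frames$pixel_spacing[1L], frames$pixel_spacing[2L],
                   frames$frame_rate, frames$slice_gap), con)
  writeLines(sprintf("%.17g", as.vector(frames$data)), con)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  if (!file.exists(path))
    stop_tmj("tmj_io_error", paste("file not found:", path))
  header <- strsplit(readLines(path, n = 1L), "\\s+")[[1L]]
  if (length(header) != 9L || header[1L] != "tmjtrack-frames")
    stop_tmj("tmj_io_error", "not a tmjtrack frame stack")
  h <- as.numeric(header[-1L])
  vals <- scan(path, skip = 1L, quiet = TRUE)
  if (length(vals) != prod(h[1:4]))
    stop_tmj("tmj_io_error", "truncated frame stack")
  frame_sequence(array(vals, h[1:4]), h[5:6], h[7L], h[8L])
}

#' Write / read annotation JSON
#'
#' Schema: `pixel_spacing_mm`, `n_frames`, `slices` (each with `slice_id`,
#' `mandible_polygon`, `condyle_contour`, `fossa_contour`), `keyframes`
#' (each with `frame` and named `landmarks`), `cycle`, `middle_slice`; all
#' coordinates in mm.
#'
#' @param annotation a [study_annotation()].
#' @param path JSON file path.
#' @export
write_annotation <- function(annotation, path) {
  obj <- list(
    pixel_spacing_mm = annotation$pixel_spacing,
    n_frames = annotation$n_frames,
    slices = lapply(annotation$slices, function(a) list(
      slice_id = a$slice_id,
      mandible_polygon = unname(a$mandible_polygon),
      condyle_contour = unname(a$condyle_contour),
      fossa_contour = if (is.null(a$fossa_contour)) NULL else
        unname(a$fossa_contour))),
    keyframes = mapply(function(k, ls) {
      list(frame = k,
           landmarks = stats::setNames(
             lapply(seq_len(nrow(ls)), function(i) unname(unclass(ls)[i, ])),
             rownames(ls)))
    }, annotation$keyframe_track$keyframes,
       annotation$keyframe_track$landmark_sets, SIMPLIFY = FALSE),
    cycle = annotation$cycle,
    middle_slice = annotation$middle_slice
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  if (!file.exists(path))
    stop_tmj("tmj_io_error", paste("file not found:", path))
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    stop_tmj("tmj_malformed_annotation",
                             paste("malformed annotation JSON:",
                                   conditionMessage(e))))
  need <- c("pixel_spacing_mm", "n_frames", "slices", "keyframes", "cycle")
  if (!is.list(obj) || !all(need %in% names(obj)))
    stop_tmj("tmj_malformed_annotation",
             paste("annotation missing fields:",
                   paste(setdiff(need, names(obj)), collapse = ", ")))
  pts <- function(x) do.call(rbind, lapply(x, function(p) unlist(p)))
  slices <- lapply(obj$slices, function(s)
    area_annotation(s$slice_id, pts(s$mandible_polygon),
                    pts(s$condyle_contour),
                    if (is.null(s$fossa_contour)) NULL else
                      pts(s$fossa_contour)))
  frames_idx <- vapply(obj$keyframes, function(k) as.integer(k$frame), 0L)
  sets <- lapply(obj$keyframes, function(k)
    landmark_set(do.call(rbind, lapply(k$landmarks, unlist))))
  study_annotation(unlist(obj$pixel_spacing_mm), obj$n_frames, slices,
                   keyframe_track(frames_idx, sets), unlist(obj$cycle),
                   middle_slice = obj$middle_slice)
}

check_geometry <- function(frames, annotation) {
  if (annotation$n_frames != frames$n_frames)
    stop_tmj("tmj_geometry_mismatch",
             sprintf("annotation has %d frames, images have %d",
                     annotation$n_frames, frames$n_frames))
  if (length(annotation$slices) != frames$n_slices)
    stop_tmj("tmj_geometry_mismatch",
             sprintf("annotation has %d slices, images have %d",
                     length(annotation$slices), frames$n_slices))
  if (max(abs(annotation$pixel_spacing - frames$pixel_spacing)) > 1e-9)
    stop_tmj("tmj_geometry_mismatch", "pixel spacing mismatch")
  invisible(TRUE)
}

#' Load a study (images + annotation) with validation
#'
#' @param frames_path path of a [write_frames()] stack.
#' @param annotation_path path of a [write_annotation()] JSON.
#' @return List: `frames`, `annotation`.
#' @export
load_study <- function(frames_path, annotation_path) {
  frames <- read_frames(frames_path)
  annotation <- read_annotation(annotation_path)
  check_geometry(frames, annotation)
  list(frames = frames, annotation = annotation)
}

#' Save tracking results
#'
#' Writes `transforms.csv` (frame, transform parameters, error, iterations,
#' convergence), `pathways.csv` when pathways are supplied, and
#' `comparison.json` when a comparison report is supplied.  Values
#' round-trip at full double precision.
#'
#' @param result a `tracking_result`.
#' @param out_dir output directory (created if needed).
#' @param report optional `comparison_report`.
#' @param pathways optional named list of `pathway` data.frames.
#' @return Character vector of files written.
#' @export
save_results <- function(result, out_dir, report = NULL, pathways = NULL) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_tmj("tmj_io_error", paste("cannot create directory:", out_dir))
  files <- character()
  tf <- file.path(out_dir, "transforms.csv")
  df <- as.data.frame(result)
  num <- vapply(df, is.numeric, NA)
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  write.csv(df, tf, row.names = FALSE, quote = FALSE)
  files <- c(files, tf)
  if (!is.null(pathways)) {
    pw <- do.call(rbind, lapply(names(pathways), function(nm) {
      p <- pathways[[nm]]
      data.frame(landmark = nm, frame = p$frame,
                 x = sprintf("%.17g", p$x), y = sprintf("%.17g", p$y))
    }))
    pf <- file.path(out_dir, "pathways.csv")
    write.csv(pw, pf, row.names = FALSE, quote = FALSE)
    files <- c(files, pf)
  }
  if (!is.null(report)) {
    cf <- file.path(out_dir, "comparison.json")
    jsonlite::write_json(unclass(report), cf, auto_unbox = TRUE, digits = NA,
                         na = "null")
    files <- c(files, cf)
  }
  files
}

#' Read a configuration JSON into a [registration_config()]
#'
#' Unknown keys are rejected; missing keys take their defaults.
#' @param path JSON file path.
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(registration_config))
  bad <- setdiff(names(obj), known)
  if (length(bad))
    stop_tmj("tmj_invalid_input",
             paste("unknown config keys:", paste(bad, collapse = ", ")))
  do.call(registration_config, obj)
}
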