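# Derived kinematics and method comparison: pathway propagation, inclination
# series, ICR path, path-distance metrics, upper-third medians, one-sided
# signed-rank threshold tests.

#' Propagate a frame-1 point through per-frame transforms
#'
#' @param transforms list of per-frame transforms (frame 1 first).
#' @param point length-2 mm coordinates at frame 1.
#' @param name landmark name attached to the pathway.
#' @return Data.frame of class `pathway`: `frame, x, y`.
#' @export
propagate_point <- function(transforms, point, name = "landmark") {
  pts <- t(vapply(transforms, function(tr) drop(apply_transform(tr, point)),
                  numeric(2)))
  structure(data.frame(frame = seq_along(transforms),
                       x = pts[, 1L], y = pts[, 2L]),
            landmark = name, class = c("pathway", "data.frame"))
}

#' Inclination series
#'
#' The mandible's rotation angle relative to frame 1, in degrees, per frame.
#'
#' @param transforms list of per-frame transforms.
#' @return Numeric vector (frame 1 is 0 when its transform is the identity).
#' @export
inclination_series <- function(transforms) {
  vapply(transforms, function(tr) tr$theta * 180 / pi, 0)
}

#' Instantaneous-centre-of-rotation pathway
#'
#' Entry t is [compute_icr()] of the transforms at frames t-1 and t; the
#' first entry is undefined, as are frames whose incremental rotation falls
#' below the threshold.
#'
#' @param transforms list of per-frame transforms (>= 2).
#' @param min_rotation_deg threshold passed to [compute_icr()].
#' @return A `pathway` data.frame with `NA` rows where undefined.
#' @export
icr_pathway <- function(transforms, min_rotation_deg = 0.1) {
  n <- length(transforms)
  if (n < 2L) stop_tmj("tmj_invalid_input", "need at least 2 frames")
  pts <- matrix(NA_real_, n, 2L)
  for (t in 2:n)
    pts[t, ] <- compute_icr(transforms[[t - 1L]], transforms[[t]],
                            min_rotation_deg)
  structure(data.frame(frame = seq_len(n), x = pts[, 1L], y = pts[, 2L]),
            landmark = "ICR", class = c("pathway", "data.frame"))
}

#' Distance between two pathways, per frame
#'
#' Euclidean distance per frame; frames where either entry is undefined give
#' `NA` and are skipped by downstream statistics.
#'
#' @param a,b `pathway` data.frames over the same frames.
#' @return Numeric vector (NA where undefined).
#' @export
path_distance_series <- function(a, b) {
  if (nrow(a) != nrow(b))
    stop_tmj("tmj_invalid_input", "pathways must cover the same frames")
  d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
  if (all(is.na(d)))
    stop_tmj("tmj_invalid_input", "no common defined frames")
  d
}

#' Median of the most distant third
#'
#' Sorts the values in decreasing order, keeps the first `ceiling(n/3)`, and
#' returns their median.  `NA`s (undefined frames) are dropped first.
#'
#' @param values numeric vector, >= 3 finite values.
#' @return Scalar.
#' @export
upper_third_median <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3L)
    stop_tmj("tmj_insufficient_data", "need at least 3 values")
  top <- sort(values, decreasing = TRUE)[seq_len(ceiling(length(values) / 3))]
  median(top)
}

#' One-sided signed-rank threshold test
#'
#' Wilcoxon signed-rank test of whether the values exceed a threshold
#' (alternative `greater`: right tail).  Zero differences are dropped
#' (Wilcoxon convention); the null distribution is exact for n <= 25 without
#' ties in the absolute differences, and a normal approximation with
#' continuity and tie correction otherwise.  A Shapiro-Wilk normality check
#' is reported alongside but does not change the test used.
#'
#' @param values numeric vector (>= 5 observations).
#' @param threshold the threshold under test.
#' @param alternative `"greater"` (default) or `"less"`.
#' @return List: `p.value`, `statistic` (V), `n` (non-zero differences),
#'   `shapiro_p`, `degenerate`, `method`.
#' @export
threshold_test <- function(values, threshold, alternative = "greater") {
  alternative <- match.arg(alternative, c("greater", "less"))
  values <- values[!is.na(values)]
  if (length(values) < 5L)
    stop_tmj("tmj_insufficient_data", "need at least 5 observations")
  d <- values - threshold
  shapiro_p <- tryCatch(shapiro.test(d)$p.value, error = function(e) NA_real_)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(p.value = 1, statistic = NA_real_, n = 0L,
                shapiro_p = shapiro_p, degenerate = TRUE,
                method = "degenerate (all differences zero)"))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25L && !ties) {
    p_greater <- 1 - psignrank(V - 1, n)     # P(V >= v)
    p_less <- psignrank(V, n)
    method <- "exact signed rank"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    p_greater <- pnorm((V - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
    p_less <- pnorm((V - mu + 0.5) / sqrt(sigma2))
    method <- "normal approximation signed rank"
  }
  p <- if (alternative == "greater") p_greater else p_less
  list(p.value = min(1, max(0, p)), statistic = V, n = n,
       shapiro_p = shapiro_p, degenerate = FALSE, method = method)
}

#' Compare automatic and manual tracking
#'
#' Builds, for both methods, the pathways of the condyle superior, the
#' circle-fit condyle centre, the gonion and the ICR; the per-frame pathway
#' distances and the inclination difference; the upper-third medians; and
#' the one-sided signed-rank tests against the distance (mm) and angle (deg)
#' thresholds.
#'
#' @param auto_transforms,manual_transforms per-frame transform lists.
#' @param annotation a [study_annotation()] (for the frame-1 landmark
#'   positions and condyle contour of the middle slice).
#' @param distance_threshold_mm,angle_threshold_deg thresholds (defaults
#'   1 mm and 1 degree).
#' @param icr_min_rotation_deg ICR definition threshold.
#' @return List of class `comparison_report`: per-landmark `distances`,
#'   `upper_third` medians, `tests`; `inclination_diff`,
#'   `inclination_upper_third`, `inclination_test`.
#' @export
compare_methods <- function(auto_transforms, manual_transforms, annotation,
                            distance_threshold_mm = 1,
                            angle_threshold_deg = 1,
                            icr_min_rotation_deg = 0.1) {
  lm1 <- interpolate_landmarks(annotation$keyframe_track, 1L)
  mid <- annotation$middle_slice
  ccen <- condyle_center(annotation$slices[[mid]])
  pts <- list(condyle_superior = unclass(lm1)["condyle_superior", ],
              condyle_center = ccen,
              gonion = unclass(lm1)["gonion", ])
  distances <- list(); upper <- list(); tests <- list()
  for (nm in names(pts)) {
    pa <- propagate_point(auto_transforms, pts[[nm]], nm)
    pm <- propagate_point(manual_transforms, pts[[nm]], nm)
    d <- path_distance_series(pa, pm)
    distances[[nm]] <- d
    upper[[nm]] <- upper_third_median(d)
    tests[[nm]] <- threshold_test(d, distance_threshold_mm)
  }
  icr_a <- icr_pathway(auto_transforms, icr_min_rotation_deg)
  icr_m <- icr_pathway(manual_transforms, icr_min_rotation_deg)
  d_icr <- sqrt((icr_a$x - icr_m$x)^2 + (icr_a$y - icr_m$y)^2)
  distances$ICR <- d_icr
  if (sum(!is.na(d_icr)) >= 3L) {
    upper$ICR <- upper_third_median(d_icr)
    if (sum(!is.na(d_icr)) >= 5L)
      tests$ICR <- threshold_test(d_icr, distance_threshold_mm)
  }
  inc_diff <- abs(inclination_series(auto_transforms) -
                  inclination_series(manual_transforms))
  structure(list(
    distances = distances,
    upper_third = upper,
    tests = tests,
    inclination_diff = inc_diff,
    inclination_upper_third = upper_third_median(inc_diff),
    inclination_test = threshold_test(inc_diff, angle_threshold_deg)
  ), class = "comparison_report")
}

#' Plot per-frame error envelopes
#'
#' Draws per-frame mean curves with a 20th-80th percentile envelope for one
#' or more series groups (rows = runs, columns = frames).
#'
#' @param series_list named list of numeric matrices.
#' @param col line colours.
#' @param ... passed to [graphics::matplot()].
#' @export
plot_error_envelopes <- function(series_list,
                                 col = seq_along(series_list), ...) {
  nfr <- ncol(series_list[[1L]])
  rng <- range(unlist(series_list), na.rm = TRUE)
  graphics::plot(NULL, xlim = c(1, nfr), ylim = rng, xlab = "frame",
                 ylab = "superimposition error", ...)
  for (i in seq_along(series_list)) {
    m <- series_list[[i]]
    q <- apply(m, 2L, quantile, c(0.2, 0.8), na.rm = TRUE)
    graphics::polygon(c(1:nfr, nfr:1), c(q[1L, ], rev(q[2L, ])),
                      col = grDevices::adjustcolor(col[i], 0.25), border = NA)
    graphics::lines(1:nfr, colMeans(m, na.rm = TRUE), col = col[i], lwd = 2)
  }
  graphics::legend("topright", legend = names(series_list), col = col, lwd = 2)
}
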