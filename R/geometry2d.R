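#' @useDynLib tmjtrack, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats quantile median optim rnorm runif pnorm psignrank
#'   shapiro.test cov
#' @importFrom utils read.csv write.csv head tail
#' @keywords internal
"_PACKAGE"

# Coordinate and angle conventions used everywhere in this package:
#   x = (column - 1) * spacing_x, y = (row - 1) * spacing_y, in mm,
#   origin at the centre of the top-left pixel, y pointing down the image.
#   Rotation angles are counterclockwise-positive in this (x right, y down)
#   frame; the rotation matrix is [cos -sin; sin cos].

stop_tmj <- function(class, msg, call. = FALSE) {
  cond <- structure(
    class = c(class, "tmj_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1))
  )
  stop(cond)
}

as_points <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) != 2L)
      stop_tmj("tmj_invalid_input", "points must be an n x 2 matrix")
    points <- matrix(points, ncol = 2L)
  }
  points <- as.matrix(points)
  if (ncol(points) != 2L)
    stop_tmj("tmj_invalid_input", "points must be an n x 2 matrix")
  storage.mode(points) <- "double"
  points
}

rotmat2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

wrap_angle <- function(theta) {
  # wrap to (-pi, pi]
  w <- (theta + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Planar rigid and scaled transforms
#'
#' A `transform2d` maps model (frame-1) coordinates `x` to current-frame
#' coordinates via `y = T + R(theta) %*% H %*% x` with `H = diag(h11, h22)`
#' applied before the rotation.  `rigid_transform2d()` fixes `h11 = h22 = 1`.
#' Angles are counterclockwise-positive in image coordinates (x right,
#' y down); translations are in mm.
#'
#' @param theta rotation angle in radians.
#' @param tx,ty translation in mm.
#' @param h11,h22 diagonal scaling factors (dimensionless, > 0).
#' @return An object of class `transform2d` (and `rigid_transform2d` when the
#'   scaling is the identity).
#' @examples
#' t <- rigid_transform2d(pi / 2, 1, 2)
#' apply_transform(t, c(1, 0))  # (1, 3)
#' @export
scaled_transform2d <- function(theta = 0, tx = 0, ty = 0, h11 = 1, h22 = 1) {
  vals <- c(theta, tx, ty, h11, h22)
  if (!all(is.finite(vals)))
    stop_tmj("tmj_invalid_input", "transform parameters must be finite")
  if (h11 <= 0 || h22 <= 0)
    stop_tmj("tmj_invalid_input", "scaling factors must be positive")
  structure(
    list(theta = theta, tx = tx, ty = ty, h11 = h11, h22 = h22),
    class = c(if (h11 == 1 && h22 == 1) "rigid_transform2d", "transform2d")
  )
}

#' @rdname scaled_transform2d
#' @export
rigid_transform2d <- function(theta = 0, tx = 0, ty = 0) {
  scaled_transform2d(theta, tx, ty, 1, 1)
}

is_rigid <- function(t) t$h11 == 1 && t$h22 == 1

rigid_part <- function(t) rigid_transform2d(t$theta, t$tx, t$ty)

#' @export
print.transform2d <- function(x, ...) {
  cat(sprintf(
    "<%s> theta = %.4f deg, t = (%.4f, %.4f) mm, H = diag(%.4f, %.4f)\n",
    class(x)[1L], x$theta * 180 / pi, x$tx, x$ty, x$h11, x$h22))
  invisible(x)
}

#' Apply a planar transform to points
#'
#' Computes `y_i = T + R %*% H %*% x_i` for each row of `points`.
#'
#' @param t a [scaled_transform2d()] or [rigid_transform2d()].
#' @param points an n x 2 matrix (or length-2 vector) of mm coordinates.
#' @return An n x 2 matrix of transformed coordinates.
#' @export
apply_transform <- function(t, points) {
  points <- as_points(points)
  if (!all(is.finite(points)))
    stop_tmj("tmj_invalid_input", "points must be finite")
  R <- rotmat2(t$theta)
  scaled <- cbind(points[, 1L] * t$h11, points[, 2L] * t$h22)
  out <- scaled %*% t(R)
  out[, 1L] <- out[, 1L] + t$tx
  out[, 2L] <- out[, 2L] + t$ty
  out
}

#' Compose and invert rigid transforms
#'
#' `compose_transform(a, b)` returns the rigid transform equivalent to
#' applying `b` first and then `a`; `invert_transform(a)` returns the rigid
#' inverse.  Both are defined for the rigid parts only: a composition of two
#' scaled transforms is not in general of the form `T + R H x`, so scaling is
#' rejected here (the registration composes rigid motions only, e.g. for the
#' instantaneous centre of rotation).
#'
#' @param a,b rigid transforms.
#' @return A `rigid_transform2d`.
#' @export
compose_transform <- function(a, b) {
  if (!is_rigid(a) || !is_rigid(b))
    stop_tmj("tmj_invalid_input", "composition is defined for rigid transforms")
  Ra <- rotmat2(a$theta)
  tt <- Ra %*% c(b$tx, b$ty) + c(a$tx, a$ty)
  rigid_transform2d(wrap_angle(a$theta + b$theta), tt[1L], tt[2L])
}

#' @rdname compose_transform
#' @export
invert_transform <- function(a) {
  if (!is_rigid(a))
    stop_tmj("tmj_invalid_input", "inversion is defined for rigid transforms")
  Ri <- rotmat2(-a$theta)
  tt <- -(Ri %*% c(a$tx, a$ty))
  rigid_transform2d(-a$theta, tt[1L], tt[2L])
}

#' Least-squares rigid transform between two landmark sets
#'
#' Finds the rigid transform minimizing `sum ||T + R src_i - dst_i||^2` by the
#' SVD (Kabsch/Procrustes) construction: the cross-covariance of the centred
#' point sets is decomposed and the rotation is the closest proper rotation.
#' Exact whenever `dst` is a rigid image of `src`.
#'
#' @param src,dst n x 2 matrices of corresponding points (n >= 2).
#' @return A `rigid_transform2d`.
#' @export
fit_rigid_svd <- function(src, dst) {
  src <- as_points(src); dst <- as_points(dst)
  if (nrow(src) != nrow(dst))
    stop_tmj("tmj_invalid_input", "src and dst must have equal length")
  if (nrow(src) < 2L)
    stop_tmj("tmj_degenerate", "need at least 2 landmark pairs")
  if (!all(is.finite(src)) || !all(is.finite(dst)))
    stop_tmj("tmj_invalid_input", "landmarks must be finite")
  cs <- colMeans(src); cd <- colMeans(dst)
  sc <- sweep(src, 2L, cs); dc <- sweep(dst, 2L, cd)
  if (max(abs(sc)) < 1e-12 || max(abs(dc)) < 1e-12)
    stop_tmj("tmj_degenerate", "landmarks are coincident")
  H <- t(sc) %*% dc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
  theta <- atan2(R[2L, 1L], R[1L, 1L])
  tt <- cd - R %*% cs
  rigid_transform2d(theta, tt[1L], tt[2L])
}

#' Pratt algebraic circle fit
#'
#' Fits `A (x^2 + y^2) + B x + C y + D = 0` subject to Pratt's normalization
#' `B^2 + C^2 - 4 A D = 1`, solved as the generalized eigenproblem
#' `M v = eta B_c v` on the moment matrix of `[x^2 + y^2, x, y, 1]`.  Exact on
#' points lying on a circle.
#'
#' @param points n x 2 matrix, n >= 3, not all collinear.
#' @return A list of class `circle_fit` with `cx`, `cy`, `r` (mm) and `rms`,
#'   the root-mean-square radial residual.
#' @references Pratt, V. (1987). Direct least-squares fitting of algebraic
#'   surfaces. Computer Graphics 21(4), 145-152.
#' @export
fit_circle_pratt <- function(points) {
  points <- as_points(points)
  n <- nrow(points)
  if (n < 3L)
    stop_tmj("tmj_degenerate", "need at least 3 points to fit a circle")
  x <- points[, 1L]; y <- points[, 2L]
  # collinearity check on the centred points
  cc <- cbind(x - mean(x), y - mean(y))
  if (min(svd(cc)$d) < 1e-9 * max(1, max(svd(cc)$d)))
    stop_tmj("tmj_degenerate", "points are collinear")
  z <- x^2 + y^2
  Z <- cbind(z, x, y, 1)
  M <- crossprod(Z) / n
  Bc <- matrix(c(0, 0, 0, -2,
                 0, 1, 0, 0,
                 0, 0, 1, 0,
                 -2, 0, 0, 0), 4L, 4L, byrow = TRUE)
  ev <- eigen(solve(Bc, M))
  eta <- Re(ev$values)
  vecs <- Re(ev$vectors)
  ok <- which(eta > -1e-9 * max(abs(eta)))
  pick <- ok[which.min(eta[ok])]
  v <- vecs[, pick]
  A <- v[1L]; B <- v[2L]; C <- v[3L]; D <- v[4L]
  if (abs(A) < 1e-14)
    stop_tmj("tmj_degenerate", "circle fit degenerated to a line")
  cx <- -B / (2 * A); cy <- -C / (2 * A)
  r2 <- (B^2 + C^2 - 4 * A * D) / (4 * A^2)
  if (r2 <= 0)
    stop_tmj("tmj_degenerate", "circle fit produced non-positive radius")
  r <- sqrt(r2)
  rms <- sqrt(mean((sqrt((x - cx)^2 + (y - cy)^2) - r)^2))
  structure(list(cx = cx, cy = cy, r = r, rms = rms), class = "circle_fit")
}

#' Instantaneous centre of rotation of a frame-to-frame motion
#'
#' Forms the incremental rigid motion `delta = t_curr o t_prev^-1` (rigid
#' parts only; scaling is ignored) and, when its rotation magnitude reaches
#' `min_rotation_deg`, returns the fixed point `c = R c + T`, i.e.
#' `c = (I - R)^-1 T`.  Below the threshold the inversion of `I - R` is
#' near-singular and the ICR is reported undefined (`c(NA, NA)`).
#'
#' @param t_prev,t_curr transforms of two consecutive frames (each mapping
#'   frame-1 coordinates to that frame).
#' @param min_rotation_deg minimum incremental rotation, degrees
#'   (default 0.1).
#' @return Length-2 numeric: the ICR in mm, or `c(NA, NA)` if undefined.
#' @export
compute_icr <- function(t_prev, t_curr, min_rotation_deg = 0.1) {
  delta <- compose_transform(rigid_part(t_curr), invert_transform(rigid_part(t_prev)))
  if (abs(wrap_angle(delta$theta)) < min_rotation_deg * pi / 180)
    return(c(NA_real_, NA_real_))
  R <- rotmat2(delta$theta)
  c(solve(diag(2) - R, c(delta$tx, delta$ty)))
}

#' Serialize transforms to a data frame
#'
#' One row per frame with columns `frame`, `tx_mm`, `ty_mm`, `theta_deg`,
#' `h11`, `h22` — the CSV schema used throughout the package.
#'
#' @param transforms list of `transform2d`, one per frame.
#' @return A data.frame.
#' @export
transforms_to_df <- function(transforms) {
  data.frame(
    frame = seq_along(transforms),
    tx_mm = vapply(transforms, `[[`, 0, "tx"),
    ty_mm = vapply(transforms, `[[`, 0, "ty"),
    theta_deg = vapply(transforms, function(t) t$theta * 180 / pi, 0),
    h11 = vapply(transforms, `[[`, 0, "h11"),
    h22 = vapply(transforms, `[[`, 0, "h22")
  )
}

#' @rdname transforms_to_df
#' @param df a data.frame in the `transforms_to_df()` schema.
#' @export
df_to_transforms <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    scaled_transform2d(df$theta_deg[i] * pi / 180, df$tx_mm[i], df$ty_mm[i],
                       df$h11[i], df$h22[i])
  })
}
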