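# Shared fixtures and independent oracles used across the suite.

# Small phantom used by several module tests (cached per session).
small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      # 52 frames so the every-25th keyframe rule covers the cycle the way it
      # does at protocol scale (keyframes 1, 2, 25, 50, 51, 52)
      cache <<- generate_phantom(phantom_spec(
        image_shape = c(128, 128), n_frames = 52, n_slices = 2,
        max_translation_mm = 8, max_rotation_deg = 20,
        cycle = c(2, 51), mmo_frame = 26,
        deformation_amplitude = 0, noise_sigma = 0, seed = 42))
    cache
  }
})

# Random simple (star-shaped) polygon around a centre.
random_star_polygon <- function(center, n = 9, rmin = 2, rmax = 8) {
  ang <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, rmin, rmax)
  cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
}

# --- oracles (independent of the implementation paths they check) ---------

# Scalar crossing-count point-in-polygon, one point at a time.
oracle_point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- FALSE
  for (i in seq_len(n)) {
    j <- if (i == 1) n else i - 1
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > y) != (yj > y) && x < (xj - xi) * (y - yi) / (yj - yi) + xi)
      inside <- !inside
  }
  inside
}

# O(n^2) exhaustive nearest-neighbour pairing in plain R.
oracle_pairing <- function(model, observed) {
  apply(model, 1, function(p) {
    d <- colSums((t(observed) - p)^2)
    which.min(d)  # which.min takes the first (lowest-index) minimum
  })
}

# Geometric (iterative) least-squares circle fit: minimizes sum (d_i - r)^2.
oracle_circle_geometric <- function(points, start) {
  obj <- function(par) {
    d <- sqrt((points[, 1] - par[1])^2 + (points[, 2] - par[2])^2)
    sum((d - par[3])^2)
  }
  optim(start, obj, method = "BFGS", control = list(maxit = 500))$par
}

# Grid-search rigid-transform oracle over (theta, tx, ty); returns the best
# grid node of the weighted point-to-plane objective.
oracle_p2p_objective <- function(model, targets, theta, tt) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  a <- cbind(model$x, model$y) %*% t(R)
  nxy <- cbind(model$nx, model$ny) %*% t(R)
  r <- rowSums(nxy * (sweep(a, 2, tt, `+`) - targets[, 1:2])) +
    model$nz * (model$z - targets[, 3])
  sum(model$weight * r^2)
}

# Build a flat lattice cloud z = f(x, y) for normal-estimation tests.
lattice_cloud <- function(nr, nc, spacing = 1, zfun = function(x, y) 0) {
  g <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  x <- (g$col - 1) * spacing
  y <- (g$row - 1) * spacing
  cloud <- data.frame(x = x, y = y, z = zfun(x, y),
                      nx = NA_real_, ny = NA_real_, nz = NA_real_,
                      weight = 1, slice_id = 1L, is_condyle = FALSE,
                      px_row = g$row, px_col = g$col)
  class(cloud) <- c("point_cloud", "data.frame")
  cloud
}

# Deciles by explicit sorting-based linear interpolation between order
# statistics (type-7 convention re-derived from scratch).
oracle_decile <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}
oracle_interdecile <- function(v) oracle_decile(v, 0.9) - oracle_decile(v, 0.1)
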