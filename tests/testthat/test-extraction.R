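test_that("intensity scale follows the printed definition", {
  # coords whose minor-axis projections have interdecile 8, greys interdecile 100
  set.seed(3)
  n <- 200
  x <- runif(n, -50, 50)                       # dominant axis
  y <- runif(n, -10, 10)
  coords <- cbind(x, y)
  yq <- quantile(y, c(0.1, 0.9), names = FALSE)
  y <- y * 8 / (yq[2] - yq[1])                 # force minor interdecile = 8
  coords <- cbind(x, y)
  g <- runif(n, 0, 1)
  gq <- quantile(g, c(0.1, 0.9), names = FALSE)
  greys <- g * 100 / (gq[2] - gq[1])           # force grey interdecile = 100
  p <- compute_intensity_scale(coords, greys)
  # the sample minor axis deviates slightly from the y axis, hence 1% slack
  expect_equal(p$scale_first, 8 / (8 * 100), tolerance = 1e-2)

  expect_error(compute_intensity_scale(coords, rep(7, n)),
               class = "tmj_zero_spread")
  expect_error(compute_intensity_scale(coords[1:5, ], greys[1:5]),
               class = "tmj_insufficient_data")
})

test_that("intensity scale matches an independent percentile/eigen oracle", {
  set.seed(17)
  n <- 500
  A <- matrix(c(3, 1.2, 1.2, 0.8), 2)          # anisotropic covariance factor
  coords <- matrix(rnorm(2 * n), ncol = 2) %*% chol(A)
  greys <- runif(n, 0, 200)
  p <- compute_intensity_scale(coords, greys)
  # oracle: full eigendecomposition + sorting-based deciles, written separately
  C <- crossprod(sweep(coords, 2, colMeans(coords))) / (n - 1)
  ev <- eigen(C, symmetric = TRUE)
  proj <- coords %*% ev$vectors[, which.min(ev$values)]
  expected <- oracle_interdecile(proj) / (8 * oracle_interdecile(greys))
  expect_equal(p$scale_first, expected, tolerance = 0.02 * expected)
})

test_that("grey-distribution matching cancels affine intensity changes", {
  set.seed(19)
  g1 <- runif(300, 40, 180)
  p <- compute_intensity_scale(cbind(runif(300, 0, 40), runif(300, 0, 40)), g1)
  expect_equal(match_grey_distribution(g1, p), g1, tolerance = 1e-12)
  expect_equal(match_grey_distribution(g1 + 50, p), g1, tolerance = 1e-9)
  expect_equal(match_grey_distribution(2 * g1, p), g1, tolerance = 1e-9)
  expect_error(match_grey_distribution(rep(1, 300), p),
               class = "tmj_zero_spread")
})

test_that("lift_to_cloud maps pixels and greys as documented", {
  img <- matrix(runif(100, 0, 100), 10, 10)
  mask <- matrix(FALSE, 10, 10); mask[4:7, 4:7] <- TRUE
  p <- list(scale_first = 0.01, d1_first = 0, interdecile_first = 1)
  class(p) <- "normalization_params"
  # uniform grey: all z equal
  img2 <- matrix(7, 10, 10)
  cl <- lift_to_cloud(mask, img2, 1, p, c(0.5, 0.5), match = FALSE)
  expect_equal(nrow(cl), 16)
  expect_true(all(cl$z == 0.07))
  expect_equal(sort(unique(cl$x)), c(1.5, 2.0, 2.5, 3.0))
  # ramp along x (columns): z strictly increasing in x
  img3 <- matrix(rep(1:10, each = 10), 10, 10)
  cl3 <- lift_to_cloud(mask, img3, 1, p, c(0.5, 0.5), match = FALSE)
  agg <- tapply(cl3$z, cl3$x, unique)
  expect_true(all(diff(unlist(agg)) > 0))
  # matched greys equal an independent recomputation
  g1 <- img[mask]
  pp <- compute_intensity_scale(cbind(cl$x, cl$y), g1)
  cl4 <- lift_to_cloud(mask, img, 1, pp, c(0.5, 0.5), match = TRUE)
  expect_equal(cl4$z, pp$scale_first * match_grey_distribution(g1, pp))
  expect_error(lift_to_cloud(matrix(FALSE, 10, 10), img, 1, p, 0.5),
               class = "tmj_empty_mask")
})

test_that("normal estimation recovers plane orientations", {
  flat <- estimate_normals(lattice_cloud(8, 8))
  expect_true(all(abs(flat$nz - 1) < 1e-9))
  expect_true(all(abs(flat$nx) < 1e-9))

  incline <- estimate_normals(lattice_cloud(8, 8, zfun = function(x, y) x))
  expected <- c(-1, 0, 1) / sqrt(2)
  for (i in seq_len(nrow(incline)))
    expect_equal(c(incline$nx[i], incline$ny[i], incline$nz[i]), expected,
                 tolerance = 1e-9)

  # unit length
  expect_equal(incline$nx^2 + incline$ny^2 + incline$nz^2,
               rep(1, nrow(incline)), tolerance = 1e-9)
})

test_that("noisy-plane normals match a per-neighbourhood eigen oracle", {
  set.seed(23)
  noise <- matrix(rnorm(144, 0, 0.01), 12, 12)
  zf <- function(x, y) 0.3 * x + 0.1 * y + noise[cbind(y + 1, x + 1)]
  cl <- estimate_normals(lattice_cloud(12, 12, zfun = zf))
  truth <- c(-0.3, -0.1, 1) / sqrt(1 + 0.09 + 0.01)
  interior <- cl$px_row > 1 & cl$px_row < 12 & cl$px_col > 1 & cl$px_col < 12
  angles <- acos(pmin(1, abs(cl$nx * truth[1] + cl$ny * truth[2] +
                             cl$nz * truth[3])))
  expect_true(all(angles[interior] < 2 * pi / 180))
  # oracle: explicit covariance eigendecomposition for a few interior points
  pos <- cbind(cl$x, cl$y, cl$z)
  for (i in sample(which(interior), 5)) {
    nb <- which(abs(cl$px_row - cl$px_row[i]) <= 1 &
                abs(cl$px_col - cl$px_col[i]) <= 1)
    C <- cov(pos[nb, ]) * (length(nb) - 1) / length(nb)
    v <- eigen(C, symmetric = TRUE)$vectors[, 3]
    if (v[3] < 0) v <- -v
    expect_equal(c(cl$nx[i], cl$ny[i], cl$nz[i]), v, tolerance = 1e-9)
  }
})

test_that("normal estimation is 90-degree rotation equivariant", {
  set.seed(29)
  z <- matrix(runif(64, 0, 1), 8, 8)
  cl1 <- estimate_normals(lattice_cloud(8, 8, zfun = function(x, y)
    z[cbind(y + 1, x + 1)]))
  # rotate the lattice 90 deg ccw: (x, y) -> (-y, x); implement via transpose
  zr <- t(z)[, rev(seq_len(8))]   # z rotated on the grid
  clr <- estimate_normals(lattice_cloud(8, 8, zfun = function(x, y)
    zr[cbind(y + 1, x + 1)]))
  # match points: (x, y) in original -> (7 - y, x) in rotated grid coords
  key1 <- paste(7 - cl1$y, cl1$x)
  keyr <- paste(clr$x, clr$y)
  m <- match(key1, keyr)
  expect_false(anyNA(m))
  # in-plane normal components rotate by 90 deg: (nx, ny) -> (-ny, nx)
  expect_equal(clr$nx[m], -cl1$ny, tolerance = 1e-9)
  expect_equal(clr$ny[m], cl1$nx, tolerance = 1e-9)
  expect_equal(clr$nz[m], cl1$nz, tolerance = 1e-9)
})

test_that("near-vertical filter honours the boundary convention", {
  mk <- function(nx, ny, nz) {
    cl <- lattice_cloud(2, 2)
    cl$nx <- nx; cl$ny <- ny; cl$nz <- nz
    cl
  }
  expect_equal(nrow(filter_near_vertical(mk(0, 0, 1))), 0)         # 0 deg
  ex8 <- mk(sin(8 * pi / 180), 0, cos(8 * pi / 180))               # exactly 8
  expect_equal(nrow(filter_near_vertical(ex8)), 4)
  just_under <- mk(sin(7.9 * pi / 180), 0, cos(7.9 * pi / 180))
  expect_equal(nrow(filter_near_vertical(just_under)), 0)
  # 45-degree plane: nothing removed; flat patch: everything removed
  incline <- estimate_normals(lattice_cloud(6, 6, zfun = function(x, y) x))
  expect_equal(nrow(filter_near_vertical(incline)), nrow(incline))
  flat <- estimate_normals(lattice_cloud(6, 6))
  expect_equal(nrow(filter_near_vertical(flat)), 0)
})

test_that("weights multiply condyle and middle-slice factors", {
  cl <- rbind(lattice_cloud(4, 4), transform(lattice_cloud(4, 4),
                                             slice_id = 2L))
  class(cl) <- c("point_cloud", "data.frame")
  condyle <- rbind(c(-0.5, -0.5), c(1.5, -0.5), c(1.5, 1.5), c(-0.5, 1.5))
  out <- assign_weights(cl, condyle, middle_slice_id = 2L)
  w <- function(slice, inside) unique(out$weight[out$slice_id == slice &
                                                 out$is_condyle == inside])
  expect_equal(w(1, FALSE), 1)
  expect_equal(w(1, TRUE), 2)
  expect_equal(w(2, FALSE), 2.5)
  expect_equal(w(2, TRUE), 5)
  expect_setequal(unique(out$weight), c(1, 2, 2.5, 5))
})

test_that("first-frame self-extraction lifts z = scale * greys exactly", {
  ph <- small_phantom()
  ann <- ph$truth$annotation
  img <- ph$frames$data[, , 1, 1]
  mask <- rasterize_area(ann$slices[[1]], dim(img), ann$pixel_spacing)
  idx <- which(mask, arr.ind = TRUE)
  coords <- cbind((idx[, 2] - 1) * ann$pixel_spacing[1],
                  (idx[, 1] - 1) * ann$pixel_spacing[2])
  p <- compute_intensity_scale(coords, img[idx])
  cl <- lift_to_cloud(mask, img, 1, p, ann$pixel_spacing, match = FALSE)
  expect_equal(cl$z, p$scale_first * img[idx])
  # matching the first frame against itself is also exact
  cl2 <- lift_to_cloud(mask, img, 1, p, ann$pixel_spacing, match = TRUE)
  expect_equal(cl2$z, cl$z, tolerance = 1e-12)
})
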