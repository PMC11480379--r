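# A small synthetic cloud with informative geometry for fitting tests:
# a noisy paraboloid patch gives normals spanning all in-plane directions.
make_test_cloud <- function(n_side = 15, seed = 1) {
  set.seed(seed)
  cl <- lattice_cloud(n_side, n_side, spacing = 1,
                      zfun = function(x, y)
                        0.05 * ((x - n_side / 2)^2 + (y - n_side / 2)^2) +
                        rnorm(length(x), 0, 0.05))
  estimate_normals(cl)
}

test_that("pairing matches the exhaustive O(n^2) oracle", {
  set.seed(2)
  model <- matrix(runif(600, 0, 20), ncol = 3)
  observed <- matrix(runif(900, 0, 20), ncol = 3)
  p <- pair_points(model, observed)
  expect_equal(p$indices, oracle_pairing(model, observed))
  expect_equal(p$distances,
               sqrt(rowSums((model - observed[p$indices, ])^2)))
  # tie-breaking by lowest observed index
  m1 <- matrix(c(0, 0, 0), 1)
  o2 <- rbind(c(1, 0, 0), c(-1, 0, 0))
  expect_equal(pair_points(m1, o2)$indices, 1L)
  expect_equal(pair_points(m1, o2)$distances, 1)
  expect_error(pair_points(m1, matrix(numeric(0), ncol = 3)),
               class = "tmj_empty_mask")
})

test_that("superimposition error is the mean absolute projected distance", {
  cl <- make_test_cloud()
  expect_equal(superimposition_error(cl, cl), 0)
  # one pair, normal (1,0,0), offset (2,5,0) -> 2
  m <- lattice_cloud(1, 1)
  m$nx <- 1; m$ny <- 0; m$nz <- 0
  obs <- m; obs$x <- -2; obs$y <- -5
  expect_equal(superimposition_error(m, obs), 2)
  # two pairs with projected distances 1 and 3 -> mean 2
  m2 <- lattice_cloud(1, 2, spacing = 100)
  m2$nx <- 1; m2$ny <- 0; m2$nz <- 0
  obs2 <- m2; obs2$x <- m2$x - c(1, 3)
  expect_equal(superimposition_error(m2, obs2), 2)
})

test_that("point-to-plane rigid fit recovers translations and rotations", {
  cl <- make_test_cloud()
  xyz <- cbind(cl$x, cl$y, cl$z)
  # observed = model -> zero transform
  fit0 <- fit_rigid_point_to_plane(cl, xyz)
  expect_lt(abs(fit0$theta), 1e-9)
  expect_lt(max(abs(c(fit0$tx, fit0$ty))), 1e-9)

  # pure translation
  t1 <- cbind(cl$x + 1, cl$y, cl$z)
  fit1 <- fit_rigid_point_to_plane(cl, t1)
  expect_lt(abs(fit1$tx - 1), 1e-6)
  expect_lt(abs(fit1$ty), 1e-6)
  expect_lt(abs(fit1$theta), 1e-6)

  # rotation of 2 degrees about the centroid
  th <- 2 * pi / 180
  cx <- mean(cl$x); cy <- mean(cl$y)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- t(R %*% rbind(cl$x - cx, cl$y - cy)) + cbind(rep(cx, nrow(cl)), cy)
  fit2 <- fit_rigid_point_to_plane(cl, cbind(rot, cl$z))
  expect_lt(abs(fit2$theta - th) * 180 / pi, 0.05)

  # the optimum beats a grid search around the truth
  obj_fit <- oracle_p2p_objective(cl, cbind(rot, cl$z), fit2$theta,
                                  c(fit2$tx, fit2$ty))
  grid <- expand.grid(dth = seq(-0.01, 0.01, length.out = 7),
                      dx = seq(-0.05, 0.05, length.out = 7),
                      dy = seq(-0.05, 0.05, length.out = 7))
  obj_grid <- min(apply(grid, 1, function(g)
    oracle_p2p_objective(cl, cbind(rot, cl$z), fit2$theta + g[1],
                         c(fit2$tx + g[2], fit2$ty + g[3]))))
  expect_lte(obj_fit, obj_grid + 1e-9)
})

test_that("scaling fit recovers diagonal stretches and clamps", {
  cl <- make_test_cloud()
  xyz <- cbind(cl$x, cl$y, cl$z)
  fit0 <- fit_scaling(cl, xyz, theta = 0)
  expect_equal(c(fit0$h11, fit0$h22), c(1, 1), tolerance = 1e-9)
  expect_lt(max(abs(c(fit0$tx, fit0$ty))), 1e-9)

  stretch <- cbind(1.1 * cl$x, cl$y, cl$z)
  fit1 <- fit_scaling(cl, stretch, theta = 0)
  expect_equal(fit1$h11, 1.1, tolerance = 1e-3)
  expect_equal(fit1$h22, 1.0, tolerance = 1e-3)
  # closed-form solution matches a numeric minimizer oracle
  oracle <- optim(c(1, 1, 0, 0), function(par) {
    rx <- par[1] * cl$x + par[3] - stretch[, 1]
    ry <- par[2] * cl$y + par[4] - stretch[, 2]
    sum(cl$weight * (cl$nx * rx + cl$ny * ry)^2)
  }, method = "BFGS")$par
  expect_equal(fit1$h11, oracle[1], tolerance = 1e-4)
  expect_equal(fit1$h22, oracle[2], tolerance = 1e-4)

  big <- cbind(1.5 * cl$x, cl$y, cl$z)
  fit2 <- fit_scaling(cl, big, theta = 0)
  expect_equal(fit2$h11, 1.25)   # clamped at the upper bound
})

test_that("register_frame recovers rigid motions from offset inits", {
  cl <- make_test_cloud(n_side = 20, seed = 4)
  # identical clouds, identity init -> identity, error ~ 0
  r0 <- register_frame(cl, cl)
  expect_lt(abs(r0$transform$theta), 1e-9)
  expect_lt(r0$superimposition_error, 1e-12)
  expect_true(r0$converged)

  # translation (2.0, -1.5), init off by 0.5
  tr <- rigid_transform2d(0, 2, -1.5)
  obs <- transform_cloud(tr, cl)
  r1 <- register_frame(cl, obs, init = rigid_transform2d(0, 1.5, -1.5))
  expect_lt(sqrt((r1$transform$tx - 2)^2 + (r1$transform$ty + 1.5)^2), 0.1)

  # rotation 15 deg + translation, init from 3 exact landmarks
  tr2 <- rigid_transform2d(15 * pi / 180, 1, 2)
  obs2 <- transform_cloud(tr2, cl)
  lms <- rbind(c(0, 0), c(10, 0), c(0, 10))
  init <- fit_rigid_svd(lms, apply_transform(tr2, lms))
  r2 <- register_frame(cl, obs2, init = init)
  expect_lt(abs(r2$transform$theta - tr2$theta) * 180 / pi, 0.5)
  expect_lt(sqrt((r2$transform$tx - tr2$tx)^2 + (r2$transform$ty - tr2$ty)^2),
            0.25)
})

test_that("registration is robust to small init perturbations and inverts", {
  cl <- make_test_cloud(n_side = 18, seed = 6)
  for (i in 1:3) {
    set.seed(100 + i)
    init <- rigid_transform2d(runif(1, -1, 1) * pi / 180,
                              runif(1, -1, 1), runif(1, -1, 1))
    r <- register_frame(cl, cl, init = init)
    expect_lt(abs(r$transform$theta) * 180 / pi, 0.05)
    expect_lt(max(abs(c(r$transform$tx, r$transform$ty))), 0.05)
  }
  # random rigid motions compose with their inverse to the identity
  set.seed(31)
  for (i in 1:8) {
    tr <- rigid_transform2d(runif(1, -20, 20) * pi / 180,
                            runif(1, -5, 5), runif(1, -5, 5))
    obs <- transform_cloud(tr, cl)
    r <- register_frame(cl, obs, init = tr)  # exact init: checks stability
    comp <- compose_transform(invert_transform(tr),
                              rigid_part(r$transform))
    expect_lt(abs(comp$theta) * 180 / pi, 0.1)
    expect_lt(max(abs(c(comp$tx, comp$ty))), 0.1)
  }
})

test_that("doubling all weights leaves the fits unchanged", {
  cl <- make_test_cloud()
  obs <- transform_cloud(rigid_transform2d(0.05, 0.7, -0.3), cl)
  targets <- cbind(obs$x, obs$y, obs$z)
  f1 <- fit_rigid_point_to_plane(cl, targets)
  cl2 <- cl; cl2$weight <- cl$weight * 2
  f2 <- fit_rigid_point_to_plane(cl2, targets)
  expect_equal(f1$theta, f2$theta, tolerance = 1e-12)
  expect_equal(c(f1$tx, f1$ty), c(f2$tx, f2$ty), tolerance = 1e-12)
  s1 <- fit_scaling(cl, targets, f1$theta)
  s2 <- fit_scaling(cl2, targets, f2$theta)
  expect_equal(c(s1$h11, s1$h22), c(s2$h11, s2$h22), tolerance = 1e-12)
})

test_that("degenerate geometry raises the documented error", {
  # all normals parallel: rotation/translation along the normal unidentified
  cl <- lattice_cloud(5, 5)
  cl$nx <- 1; cl$ny <- 0; cl$nz <- 0
  expect_error(fit_rigid_point_to_plane(cl, cbind(cl$x, cl$y, cl$z)),
               class = "tmj_degenerate_geometry")
})

test_that("track_sequence on a static sequence returns identities", {
  ph <- small_phantom()
  static <- ph$frames
  for (t in 2:static$n_frames) static$data[, , , t] <- static$data[, , , 1]
  ann <- ph$truth$annotation
  # static landmarks too
  kt <- ann$keyframe_track
  kt$landmark_sets <- rep(kt$landmark_sets[1], length(kt$keyframes))
  ann$keyframe_track <- kt
  res <- track_sequence(static, ann)
  for (t in seq_len(static$n_frames)) {
    expect_lt(abs(res$transforms[[t]]$theta) * 180 / pi, 0.05)
    expect_lt(max(abs(c(res$transforms[[t]]$tx, res$transforms[[t]]$ty))), 0.05)
    expect_lt(res$errors[t], 1e-9)
  }
})

test_that("tracking a rigid phantom recovers the ground truth", {
  ph <- small_phantom()   # zero noise, zero deformation
  res <- track_sequence(ph$frames, ph$truth$annotation)
  expect_false(any(res$failed))
  cc <- ph$truth$tracks$condyle_center
  sp <- ph$truth$spec$pixel_spacing[1]
  for (t in seq_len(ph$frames$n_frames)) {
    pos <- drop(apply_transform(res$transforms[[t]], cc[1, ]))
    expect_lt(sqrt(sum((pos - cc[t, ])^2)), 0.5 * sp)
    expect_lt(abs(res$transforms[[t]]$theta - ph$truth$transforms[[t]]$theta) *
                180 / pi, 0.5)
  }
  # accepted-error series per frame is consistent with convergence flags
  expect_true(all(vapply(res$registrations, `[[`, 0L, "n_iterations") <=
                  res$config$max_iterations))
})
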