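rand_points <- function(n, seed) {
  set.seed(seed)
  matrix(stats::runif(3 * n, -1, 1), n, 3)
}

test_that("identical landmark sets give the identity transform", {
  P <- rand_points(15, 1)
  f <- fit_rigid(landmark_set(P), landmark_set(P))
  expect_lt(max(abs(f$transform$R - diag(3))), 1e-12)
  expect_lt(max(abs(f$transform$t)), 1e-12)
  expect_equal(f$rms_residual, 0, tolerance = 1e-14)
})

test_that("a known rigid motion is recovered to machine precision", {
  P <- rand_points(15, 2)
  R <- rotation_about(c(0, 0, 1), 30)
  T0 <- rigid_transform(R, c(0.3, -0.2, 0.5))
  f <- fit_rigid(landmark_set(P), landmark_set(apply_rigid(T0, P)))
  expect_lt(max(abs(f$transform$R - R)), 1e-10)
  expect_lt(max(abs(f$transform$t - T0$t)), 1e-10)
  expect_lt(f$rms_residual, 1e-10)
})

test_that("rms residual under landmark noise scales with the noise level", {
  # Monte-Carlo: with isotropic destination noise sigma, the per-coordinate
  # rms residual has expectation sigma * sqrt(1 - 2/n)
  P <- rand_points(15, 3)
  T0 <- rigid_transform(rotation_about(c(1, 2, 0.5), 17), c(0.1, 0.4, -0.3))
  Q0 <- apply_rigid(T0, P)
  sigma <- 0.02
  set.seed(42)
  rms <- replicate(100, {
    Q <- Q0 + matrix(rnorm(45, 0, sigma), 15, 3)
    fit_rigid(landmark_set(P), landmark_set(Q))$rms_residual
  })
  pooled <- sqrt(mean(rms^2))
  expect_gt(pooled, 0.5 * sigma)
  expect_lt(pooled, 1.5 * sigma)
})

test_that("fit is invariant to a common rigid motion of both point sets", {
  P <- rand_points(12, 4)
  Q <- apply_rigid(rigid_transform(rotation_about(c(0, 1, 0), 25), c(0.2, 0, 0)), P) +
    matrix(rnorm(36, 0, 0.01), 12, 3)
  f0 <- fit_rigid(landmark_set(P), landmark_set(Q))
  M <- rigid_transform(rotation_about(c(1, 1, 1), 40), c(-1, 2, 0.5))
  f1 <- fit_rigid(landmark_set(apply_rigid(M, P)), landmark_set(apply_rigid(M, Q)))
  expect_equal(f1$rms_residual, f0$rms_residual, tolerance = 1e-10)
})

test_that("recovered transforms never reflect, even for flat configurations", {
  set.seed(5)
  P <- cbind(runif(10), runif(10), rnorm(10, 0, 1e-7))   # nearly planar
  Q <- apply_rigid(rigid_transform(rotation_about(c(0, 0, 1), 80), c(1, 0, 0)), P) +
    matrix(rnorm(30, 0, 1e-4), 10, 3)
  f <- fit_rigid(landmark_set(P), landmark_set(Q))
  expect_gt(det(f$transform$R), 0.999)
  # truly collinear points leave the rotation undetermined
  L <- cbind(seq_len(5), 2 * seq_len(5), -seq_len(5))
  expect_error(fit_rigid(landmark_set(L), landmark_set(L + 1)), "collinear")
})

test_that("two-step registration equals the single fine fit for exact input", {
  P3 <- rand_points(3, 6)
  P15 <- rand_points(15, 7)
  T0 <- rigid_transform(rotation_about(c(0.2, 1, 0), -35), c(0.5, 0.1, -0.2))
  Tc <- two_step_register(landmark_set(P3), landmark_set(apply_rigid(T0, P3)),
                          landmark_set(P15), landmark_set(apply_rigid(T0, P15)))
  single <- fit_rigid(landmark_set(P15),
                      landmark_set(apply_rigid(T0, P15)))$transform
  expect_lt(max(abs(Tc$R - single$R)), 1e-10)
  expect_lt(max(abs(Tc$t - single$t)), 1e-10)
  # the 3-marker coarse step alone recovers an exact motion
  co <- fit_rigid(landmark_set(P3), landmark_set(apply_rigid(T0, P3)))
  expect_lt(max(abs(co$transform$R - T0$R)), 1e-10)
})

test_that("the phantom separation transforms are recovered from landmarks", {
  ph <- tiny_phantom()
  for (bone in c("femur", "tibia")) {
    lm <- ph$truth$landmarks[[bone]]
    T <- two_step_register(lm$coarse_stained, lm$coarse_rest,
                           lm$fine_stained, lm$fine_rest)
    T0 <- ph$truth$transforms[[bone]]
    expect_lt(max(abs(T$R - T0$R)), 1e-8)
    expect_lt(max(abs(T$t - T0$t)), 1e-8)
  }
})

test_that("resampling through the identity reproduces the image", {
  set.seed(8)
  img <- voxel_image(array(rnorm(16^3, 50, 5), c(16, 16, 16)), 0.03)
  out <- resample(img, rigid_transform())
  i <- 3:14
  expect_lt(max(abs(out$values[i, i, i] - img$values[i, i, i])), 1e-10)
})

test_that("integer-voxel translation resampling matches the mask shift oracle", {
  set.seed(9)
  d <- c(20, 20, 20)
  # binary-exact spacing so pulled-back samples land exactly on centres
  img <- voxel_image(array(ifelse(runif(prod(d)) < 0.3, 200, 20), d), 0.0625)
  T <- rigid_transform(diag(3), c(0, 0, 3 * 0.0625))   # +3 voxels in z
  res <- resample(img, T, fill = 20)
  m0 <- threshold_segment(img, 100)
  m1 <- translate_mask(m0, c(0, 0, 3))
  mres <- threshold_segment(res, 100)
  # compare on the overlap of the two grids
  expect_identical(mres$values[, , 4:20], m1$values[, , 4:20])
})

test_that("constant images stay constant in the interior under any transform", {
  img <- voxel_image(array(7, c(14, 14, 14)), 0.1)
  T <- rigid_transform(rotation_about(c(0, 0, 1), 20), c(0.05, -0.02, 0.01))
  out <- resample(img, T, fill = 7)
  expect_lt(max(abs(out$values - 7)), 1e-12)
})

test_that("double resampling through T and its inverse keeps a high PSNR", {
  d <- c(30, 30, 30)
  idx <- arrayInd(seq_len(prod(d)), d)
  blob <- 100 * exp(-rowSums(sweep(idx, 2, c(15.3, 14.7, 15.9))^2) / 60)
  img <- voxel_image(array(blob, d), 0.02)
  T <- rigid_transform(rotation_about(c(0.3, 1, 0.2), 12), c(0.013, -0.021, 0.008))
  fwd <- resample(img, T, fill = 0)
  back <- resample(fwd, invert_rigid(T), fill = 0)
  i <- 6:25
  err <- back$values[i, i, i] - img$values[i, i, i]
  psnr <- 10 * log10(max(img$values)^2 / mean(err^2))
  expect_gt(psnr, 40)
})

test_that("landmark and transform files round-trip", {
  lm <- landmark_set(rand_points(5, 10), ids = paste0("P", 1:5))
  f1 <- tempfile(fileext = ".csv")
  write_landmarks(lm, f1)
  lm2 <- read_landmarks(f1)
  expect_equal(lm2$points, lm$points, tolerance = 1e-12,
               ignore_attr = TRUE)
  T0 <- rigid_transform(rotation_about(c(1, 0, 0), 12), c(1, 2, 3))
  f2 <- tempfile(fileext = ".json")
  write_transform(T0, f2)
  T1 <- read_transform(f2)
  expect_lt(max(abs(T1$R - T0$R)), 1e-12)
  expect_lt(max(abs(T1$t - T0$t)), 1e-12)
  unlink(c(f1, f2))
})
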