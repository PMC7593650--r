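test_that("gaussian smoothing is mean-preserving and matches the kernel oracle", {
  set.seed(1)
  img <- voxel_image(array(rnorm(18^3, 100, 12), c(18, 18, 18)), 0.02)
  sm <- gaussian_smooth(img, 1)
  expect_lt(abs(mean(sm$values) - mean(img$values)) / mean(img$values), 1e-6)

  cst <- voxel_image(array(5, c(7, 7, 7)), 0.01)
  expect_equal(gaussian_smooth(cst, 2)$values, cst$values, tolerance = 1e-12)

  # unit impulse reproduces the separable discrete kernel exactly
  imp <- array(0, c(15, 15, 15)); imp[8, 8, 8] <- 1
  out <- gaussian_smooth(voxel_image(imp, 0.01), 1)$values
  k <- kneefem:::gaussian_kernel_1d(1)
  r <- (length(k) - 1) / 2
  K3 <- outer(outer(k, k), k)
  expect_equal(out[(8 - r):(8 + r), (8 - r):(8 + r), (8 - r):(8 + r)], K3,
               tolerance = 1e-14)

  bad <- img; bad$values[1] <- NA
  expect_error(gaussian_smooth(bad, 1), "finite")
})

test_that("threshold segmentation counts voxels at and above the level", {
  v <- array(c(rep(10, 100), rep(200, 50)), c(150, 1, 1))
  img <- voxel_image(v, 1)
  expect_equal(sum(threshold_segment(img, 100)$values), 50)
  expect_equal(sum(threshold_segment(img, 10)$values), 150)   # level = min
  expect_error(threshold_segment(img, 300), "range")
})

test_that("suggested threshold separates the dominant modes", {
  img <- voxel_image(array(c(rep(10, 100), rep(200, 50)), c(150, 1, 1)), 1)
  lv <- suggest_threshold(img)
  expect_gt(lv, 10); expect_lt(lv, 200)
  expect_error(suggest_threshold(voxel_image(array(3, c(5, 5, 5)), 1)),
               "unimodal")
})

test_that("segmenting the phantom rest scan at the suggested level recovers bone", {
  ph <- generate_phantom(phantom_spec(voxel_spacing_um = 40, noise_sd = 5, seed = 2L))
  sm <- gaussian_smooth(ph$rest_scan, 1)
  lv <- suggest_threshold(sm)
  seg <- threshold_segment(sm, lv)
  truth <- ph$truth$masks
  mineral <- label_mask(truth$femur_bone$values | truth$tibia_bone$values |
                          truth$calcified_meniscus$values,
                        seg$spacing, seg$origin)
  expect_gte(mask_dice(seg, mineral), 0.95)
})

test_that("mask Boolean algebra matches the voxelwise brute-force oracle", {
  for (seed in 1:4) {
    a <- random_mask(20, 0.4, seed = seed)
    b <- random_mask(20, 0.4, seed = seed + 100)
    ia <- which(a$values); ib <- which(b$values)
    expect_identical(which(mask_boolean(a, b, "subtract")$values),
                     setdiff(ia, ib))
    expect_identical(which(mask_boolean(a, b, "union")$values),
                     sort(union(ia, ib)))
    expect_identical(which(mask_boolean(a, b, "intersect")$values),
                     intersect(ia, ib))
    # set-theoretic identities
    expect_false(any(mask_boolean(a, a, "subtract")$values))
    expect_identical(mask_boolean(a, b, "union")$values,
                     mask_boolean(b, a, "union")$values)
    expect_false(any(mask_boolean(a, b, "subtract")$values & b$values))
  }
  g1 <- random_mask(20, 0.3, seed = 1)
  g2 <- random_mask(19, 0.3, seed = 2)
  expect_error(mask_boolean(g1, g2, "union"), "grids")
})

test_that("mask smoothing regularises boundaries without losing volume", {
  cube <- label_mask(array(TRUE, c(20, 20, 20)), 1)
  pad <- array(FALSE, c(30, 30, 30)); pad[6:25, 6:25, 6:25] <- TRUE
  cube <- label_mask(pad, 1)
  sm <- mask_smooth(cube, 2)
  expect_lt(abs(sum(sm$values) - sum(cube$values)) / sum(cube$values), 0.10)

  d <- c(40, 40, 40)
  idx <- arrayInd(seq_len(prod(d)), d)
  ball <- label_mask(array(rowSums((idx - 20.3)^2) <= 12^2, d), 1)
  sm2 <- mask_smooth(ball, 2)
  expect_gte(mask_dice(ball, sm2), 0.98)

  lone <- label_mask(array(c(TRUE, rep(FALSE, 7^3 - 1)), c(7, 7, 7)), 1)
  expect_error(mask_smooth(lone, 2), "emptied")
})

test_that("integer translation preserves volume and inverts exactly", {
  m <- random_mask(15, 0.3, spacing = 0.00435, seed = 9)
  sh <- translate_mask(m, c(0, 0, 20))        # 20 voxels = 87 um at 4.35 um
  expect_equal(sum(sh$values), sum(m$values))
  expect_equal(sh$origin, m$origin)           # positive shift pads above
  # physical voxel-centre sets: shift then inverse shift recovers the set
  coords <- function(mm) {
    w <- which(mm$values, arr.ind = TRUE)
    node_key(sweep((w - 1) * mm$spacing, 2, mm$origin, "+"))
  }
  back <- translate_mask(sh, c(0, 0, -20))
  expect_setequal(coords(back), coords(m))
  expect_identical(translate_mask(m, c(0, 0, 0))$values, m$values)
})

test_that("meniscus wrap fills gaps and stays disjoint from its inputs", {
  d <- c(16, 16, 24)
  slab <- function(z0, z1) {
    a <- array(FALSE, d); a[4:13, 4:13, z0:z1] <- TRUE
    label_mask(a, 1)
  }
  lower <- slab(3, 6); upper <- slab(12, 15)          # 5-voxel gap
  calc <- slab(7, 7); calc$values[, 1:7, ] <- FALSE   # a bar inside the gap
  out <- wrap_meniscus(calc, upper, lower, max_gap = 10)
  expect_gt(sum(out$values), 0)
  expect_false(any(out$values & (calc$values | upper$values | lower$values)))
  # gap voxels between the slabs near the calcified bar are filled
  filled <- which(out$values, arr.ind = TRUE)
  expect_true(any(filled[, 3] >= 8 & filled[, 3] <= 11))
  # brute-force closing oracle on the same union
  u <- calc$values | upper$values | lower$values
  w_u <- which(u, arr.ind = TRUE)
  alln <- arrayInd(seq_len(prod(d)), d)
  mind2 <- function(pts, set) {
    out <- numeric(nrow(pts))
    for (i in seq_len(nrow(pts)))
      out[i] <- min(colSums((t(set) - pts[i, ])^2))
    out
  }
  dil <- mind2(alln, w_u) <= 5^2 + 1e-9
  w_bg <- alln[!dil, , drop = FALSE]
  closed <- dil & (mind2(alln, w_bg) > 5^2 + 1e-9)
  fill_oracle <- array(closed, d) & !u
  near_calc <- array(mind2(alln, which(calc$values, arr.ind = TRUE)) <= 100 + 1e-9, d)
  expect_identical(out$values, fill_oracle & near_calc)

  expect_warning(w0 <- wrap_meniscus(calc, upper, lower, max_gap = 0), "empty")
  expect_false(any(w0$values))
  empty <- label_mask(array(FALSE, d), 1)
  expect_error(wrap_meniscus(empty, upper, lower, 5), "empty")
})

test_that("generic cartilage thickness halves the minimal bone gap", {
  # parallel slabs with an 8-voxel gap: layers of g/2 on each bone just touch
  d <- c(20, 20, 30)
  mk <- function(z0, z1, tissue) {
    a <- array(FALSE, d); a[3:18, 3:18, z0:z1] <- TRUE
    label_mask(a, 0.05, tissue = tissue)
  }
  tib <- mk(3, 8, "tibia_bone"); fem <- mk(17, 24, "femur_bone")
  gen <- build_generic_cartilage(fem, tib, "one_thickness", corridor = 10)
  g <- 8 * 0.05
  expect_lt(abs(gen$thickness[["lateral"]] - g / 2), 0.05)  # within 1 voxel
  # output layers sit between the bones and are disjoint from them
  expect_false(any(gen$femur_cart$values & (fem$values | tib$values)))
  expect_false(any(gen$femur_cart$values & gen$tibia_cart$values))
  # the layer's distance-transform thickness agrees with the returned t
  # within a voxel; depths evaluated over the full layer, medianed over the
  # central columns so the slab-edge skirts do not bias the estimate
  fcart <- gen$femur_cart
  inv <- label_mask(!fcart$values, fcart$spacing, fcart$origin)
  depth <- sqrt(distance_sq(inv))
  core <- array(FALSE, d); core[6:15, 6:15, ] <- TRUE
  dmed <- median(depth[fcart$values & core])
  t_est <- 4 * (dmed - fcart$spacing / 2)
  expect_lt(abs(t_est - gen$thickness[["lateral"]]), 0.05 * 1.5)
})

test_that("two-thickness mode is thicker on the wider compartment", {
  ph <- tiny_phantom()
  ms <- ph$truth$masks
  gen <- build_generic_cartilage(ms$femur_bone, ms$tibia_bone, "two_thickness")
  expect_gt(gen$thickness[["medial"]], gen$thickness[["lateral"]])
  g1 <- build_generic_cartilage(ms$femur_bone, ms$tibia_bone, "one_thickness")
  expect_equal(g1$thickness[["lateral"]], g1$thickness[["medial"]])
  expect_equal(g1$thickness[["lateral"]], gen$thickness[["lateral"]],
               tolerance = 1e-12)
})

test_that("distance-transform offset shell matches the analytic shell volume", {
  d <- c(128, 128, 128)
  h <- 0.0125
  idx <- arrayInd(seq_len(prod(d)), d)
  ctr <- c(64.4, 64.2, 64.3)
  R <- 0.55
  ball <- label_mask(array(rowSums(sweep(idx, 2, ctr)^2) * h^2 <= R^2, d), h)
  t <- 0.15
  dF <- sqrt(distance_sq(ball))
  shell <- !ball$values & dF <= t
  vol_num <- sum(shell) * h^3
  vol_ana <- 4 / 3 * pi * ((R + t)^3 - R^3)
  expect_lt(abs(vol_num - vol_ana) / vol_ana, 0.03)
})
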