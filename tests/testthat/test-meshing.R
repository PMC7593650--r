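test_that("a single voxel splits into 6 positive tets filling it exactly", {
  m <- label_mask(array(TRUE, c(1, 1, 1)), 0.3, tissue = "t")
  mesh <- voxels_to_tets(list(t = m), mesh_params(coarsen = 1),
                         body_map = c(t = "b"))
  v <- tet_volumes(mesh)
  expect_length(v, 6)
  expect_true(all(v > 0))
  expect_equal(sum(v), 0.3^3, tolerance = 1e-15)
})

test_that("voxel meshes conserve volume exactly at 1-voxel coarsening", {
  cube <- label_mask(array(TRUE, c(10, 10, 10)), 0.1, tissue = "t")
  mesh <- voxels_to_tets(list(t = cube), mesh_params(coarsen = 1),
                         body_map = c(t = "b"))
  expect_lt(abs(sum(tet_volumes(mesh)) - 1) / 1, 1e-12)

  # multi-tissue: per-region volume equals the mask volume
  ph <- tiny_phantom()
  ms <- ph$truth$masks[c("tibia_bone", "tibia_cartilage")]
  mesh2 <- voxels_to_tets(ms, mesh_params(coarsen = 1))
  V <- tapply(tet_volumes(mesh2), mesh2$region, sum)
  for (r in names(ms))
    expect_equal(V[[r]], mask_volume(ms[[r]]), tolerance = 1e-12)
})

test_that("meshes are conforming: interior faces shared by exactly two tets", {
  ph <- tiny_phantom()
  ms <- ph$truth$masks[c("tibia_bone", "tibia_cartilage")]
  mesh <- voxels_to_tets(ms, mesh_params(coarsen = 1))
  dt <- as.data.frame(kneefem:::mesh_faces(mesh))
  expect_true(all(dt$cnt %in% c(1L, 2L)))
  # region-interface faces are shared by tets of different regions
  dt2 <- dt[dt$cnt == 2L, ]
  dt2 <- dt2[order(dt2$a, dt2$b, dt2$c), ]
  o1 <- dt2$owner[seq(1, nrow(dt2), by = 2)]
  o2 <- dt2$owner[seq(2, nrow(dt2), by = 2)]
  n_iface <- sum(mesh$region[o1] != mesh$region[o2])
  expect_gt(n_iface, 0)          # the bone-cartilage interface exists
})

test_that("no element inversion at any integer coarsening level", {
  ph <- tiny_phantom()
  ms <- ph$truth$masks[c("femur_bone", "femur_cartilage")]
  for (f in 1:3) {
    mesh <- voxels_to_tets(ms, mesh_params(coarsen = f))
    expect_true(all(tet_volumes(mesh) > 0))
  }
})

test_that("overlapping masks are rejected", {
  a <- label_mask(array(TRUE, c(3, 3, 3)), 1, tissue = "a")
  expect_error(voxels_to_tets(list(a = a, b = a), mesh_params(coarsen = 1)),
               "overlap")
})

test_that("named boundary sets select the geometric extremes", {
  arr1 <- array(FALSE, c(6, 6, 8)); arr1[, , 1:4] <- TRUE
  arr2 <- array(FALSE, c(6, 6, 8)); arr2[, , 5:8] <- TRUE
  mesh <- voxels_to_tets(list(tibia_bone = label_mask(arr1, 0.1, tissue = "tibia_bone"),
                              tibia_cartilage = label_mask(arr2, 0.1, tissue = "tibia_cartilage")),
                         mesh_params(coarsen = 1))
  mesh <- extract_named_sets(mesh, layers = 2)
  z <- mesh$nodes[, 3]
  fixed <- mesh$node_sets$tibia_distal_fixed
  expect_true(all(z[fixed] <= min(z) + 2 * 0.1 + 1e-9))
  # every bottom-face node is selected
  bottom <- which(abs(z - min(z)) < 1e-9)
  expect_true(all(bottom %in% fixed))
  # cartilage surface facets exclude the interior bone-cartilage interface
  fs <- mesh$facet_sets$tibial_cartilage_surface
  expect_gt(nrow(fs), 0)
  zc <- matrix(z[fs[, 1:3]], ncol = 3)
  expect_true(all(zc > 0.35))    # all facet nodes above the interface plane
})

test_that("femoral articular facet set covers the articular boundary", {
  ph <- tiny_phantom()
  ms <- ph$truth$masks[c("femur_bone", "femur_cartilage")]
  mesh <- extract_named_sets(voxels_to_tets(ms, mesh_params(coarsen = 1)))
  fs <- mesh$facet_sets$femoral_cartilage_surface
  # brute-force boundary scan: every exterior face owned by a cartilage
  # element must be in the set
  dt <- kneefem:::mesh_faces(mesh)
  bound <- dt[dt$cnt == 1L, ]
  cart_owned <- bound[mesh$region[bound$owner] == "femur_cartilage", ]
  expect_equal(nrow(fs), nrow(cart_owned))
  # projected articular area approximates the analytic inferior cap area:
  # sum |nz| A over downward facets ~ pi * r_cap^2 per condyle
  nrm <- facet_normals(mesh, fs)
  ar <- attr(nrm, "area")
  proj <- sum(ar[nrm[, 3] < 0] * abs(nrm[nrm[, 3] < 0, 3]))
  g <- ph$truth$geometry
  ana <- 0
  for (s in 1:2) {
    Ro <- g$R[s] + g$t_fem[s]
    zcut <- g$zc[s] - 0.6 * g$R[s]
    ana <- ana + pi * (Ro^2 - (g$zc[s] - zcut)^2)
  }
  expect_lt(abs(proj - ana) / ana, 0.05)
})

test_that("mesh quality metrics behave on reference shapes", {
  # regular tetrahedron: aspect ratio and scaled Jacobian both 1
  p <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, -1, 1), c(-1, 1, -1))
  tm <- structure(list(nodes = p, elems = matrix(1:4, 1), region = "t",
                       body = "b", node_sets = list(), facet_sets = list(),
                       edge_length = 2 * sqrt(2), tissues = "t",
                       body_map = NULL), class = "tet_mesh")
  q <- mesh_quality(tm)
  expect_equal(q$max_aspect, 1, tolerance = 1e-12)
  expect_equal(q$median_scaled_jacobian, 1, tolerance = 1e-12)

  mesh <- block_mesh(3, 0.2)
  q2 <- mesh_quality(mesh)
  expect_gt(q2$min_scaled_jacobian, 0)
  expect_equal(q2$n_flagged, 0)
  expect_equal(as.numeric(q2$volume_by_region), (3 * 0.2)^3, tolerance = 1e-12)
})

test_that("coarsening majority-votes block labels and respects emptiness", {
  lab <- label_mask(array(FALSE, c(4, 4, 4)), 0.1, tissue = "a")
  lab$values[1:4, 1:4, 1:2] <- TRUE         # bottom half solid
  mesh <- voxels_to_tets(list(a = lab), mesh_params(coarsen = 2),
                         body_map = c(a = "b"))
  # 2x2x2 blocks: bottom layer of blocks is half-full (4/8 voxels) -> kept,
  # top layer empty
  expect_equal(nrow(mesh$elems), 4 * 6)
  expect_equal(sum(tet_volumes(mesh)), 4 * 0.2^3, tolerance = 1e-12)
})

test_that("VTU and INP exports round-trip the mesh", {
  mesh <- block_mesh(2, 0.5, tissue = "tibia_bone")
  mesh <- extract_named_sets(mesh)
  f1 <- tempfile(fileext = ".vtu")
  write_vtu(mesh, f1, point_data = list(u = matrix(0, nrow(mesh$nodes), 3)),
            cell_data = list(vm = rep(1, nrow(mesh$elems))))
  txt <- readLines(f1)
  expect_true(any(grepl("UnstructuredGrid", txt)))
  expect_true(any(grepl(sprintf('NumberOfCells="%d"', nrow(mesh$elems)), txt)))

  f2 <- tempfile(fileext = ".inp")
  write_inp(mesh, f2)
  back <- read_inp(f2)
  expect_equal(back$nodes, mesh$nodes, tolerance = 1e-9)
  expect_identical(back$elems, mesh$elems)
  expect_identical(sort(unique(back$region)), sort(unique(mesh$region)))
  unlink(c(f1, f2))
})
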