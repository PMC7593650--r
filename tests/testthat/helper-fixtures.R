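# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# small, quiet phantom for module tests (coarser than the study default)
tiny_phantom_spec <- function(...) {
  phantom_spec(voxel_spacing_um = 40, noise_sd = 0, seed = 7L, ...)
}

tiny_phantom <- function() memo("tiny_phantom", generate_phantom(tiny_phantom_spec()))

default_phantom <- function() memo("default_phantom",
                                   generate_phantom(phantom_spec(noise_sd = 0)))

# uniform single-region block mesh (n^3 voxels of edge h, one body)
block_mesh <- function(n = 4, h = 0.25, tissue = "block") {
  masks <- list(label_mask(array(TRUE, c(n, n, n)), h, tissue = tissue))
  names(masks) <- tissue
  bm <- "blk"; names(bm) <- tissue
  voxels_to_tets(masks, mesh_params(coarsen = 1), body_map = bm)
}

# two stacked block bodies (lower fixed, upper driven), plus the matching
# monolithic mesh; used by the tie / penalty-contact equivalence checks
stacked_blocks <- function(n = 4, nz = 8, h = 0.25) {
  memo(sprintf("stacked_%d_%d", n, nz), {
    arrA <- array(FALSE, c(n, n, nz)); arrA[, , seq_len(nz / 2)] <- TRUE
    arrB <- array(FALSE, c(n, n, nz)); arrB[, , nz / 2 + seq_len(nz / 2)] <- TRUE
    meshS <- voxels_to_tets(list(lower = label_mask(arrA, h, tissue = "lower"),
                                 upper = label_mask(arrB, h, tissue = "upper")),
                            mesh_params(coarsen = 1),
                            body_map = c(lower = "A", upper = "B"))
    meshM <- voxels_to_tets(list(block = label_mask(array(TRUE, c(n, n, nz)), h,
                                                    tissue = "block")),
                            mesh_params(coarsen = 1), body_map = c(block = "M"))
    dtf <- kneefem:::mesh_faces(meshS)
    bd <- dtf[dtf$cnt == 1L, ]
    facets_of <- function(regsel, up) {
      f <- as.matrix(bd[bd$owner %in% which(meshS$region == regsel),
                        c("n1", "n2", "n3", "owner")])
      nr <- facet_normals(meshS, f)
      if (up) f[nr[, 3] > 0.5, , drop = FALSE] else f[nr[, 3] < -0.5, , drop = FALSE]
    }
    list(split = meshS, mono = meshM,
         lower_top = facets_of("lower", TRUE),
         upper_bottom = facets_of("upper", FALSE))
  })
}

node_key <- function(p) paste(round(p[, 1], 9), round(p[, 2], 9), round(p[, 3], 9))

# random small masks for the Boolean brute-force property tests
random_mask <- function(n = 20, p = 0.4, spacing = 1, seed) {
  set.seed(seed)
  label_mask(array(stats::runif(n^3) < p, c(n, n, n)), spacing)
}
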