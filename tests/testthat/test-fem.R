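# independent oracle: element stiffness by explicit B^T D B quadrature
element_K_oracle <- function(p, E, nu) {
  Jm <- rbind(p[2, ] - p[1, ], p[3, ] - p[1, ], p[4, ] - p[1, ])
  V <- det(Jm) / 6
  G <- t(solve(Jm))
  g <- rbind(-colSums(G), G)
  B <- matrix(0, 6, 12)
  for (i in 1:4) {
    c0 <- 3 * (i - 1)
    B[1, c0 + 1] <- g[i, 1]; B[2, c0 + 2] <- g[i, 2]; B[3, c0 + 3] <- g[i, 3]
    B[4, c0 + 1] <- g[i, 2]; B[4, c0 + 2] <- g[i, 1]
    B[5, c0 + 2] <- g[i, 3]; B[5, c0 + 3] <- g[i, 2]
    B[6, c0 + 1] <- g[i, 3]; B[6, c0 + 3] <- g[i, 1]
  }
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam + 2 * mu * diag(3)
  D[4:6, 4:6] <- mu * diag(3)
  V * t(B) %*% D %*% B
}

one_tet_mesh <- function(p) {
  structure(list(nodes = p, elems = matrix(1:4, 1), region = "t", body = "b",
                 node_sets = list(), facet_sets = list(), edge_length = 1,
                 tissues = "t", body_map = NULL), class = "tet_mesh")
}

test_that("element stiffness equals the quadrature oracle", {
  set.seed(12)
  for (trial in 1:3) {
    p <- matrix(rnorm(12), 4, 3)
    if (det(rbind(p[2, ] - p[1, ], p[3, ] - p[1, ], p[4, ] - p[1, ])) < 0)
      p <- p[c(1, 3, 2, 4), ]
    for (nu in c(0, 0.3, 0.49)) {
      fs <- assemble_stiffness(one_tet_mesh(p), list(t = material(1, nu)))
      Ko <- element_K_oracle(p, 1, nu)
      expect_lt(max(abs(as.matrix(fs$K) - Ko)), 1e-11 * max(abs(Ko)))
    }
  }
})

test_that("stiffness scales linearly in the Young modulus", {
  mesh <- block_mesh(2, 0.5)
  K1 <- assemble_stiffness(mesh, list(block = material(3, 0.3)))$K
  K2 <- assemble_stiffness(mesh, list(block = material(6, 0.3)))$K
  expect_lt(max(abs(K2 - 2 * K1)), 1e-12 * max(abs(K1)))
})

test_that("patch test: an affine field is reproduced exactly", {
  mesh <- block_mesh(4, 0.25)
  fem <- assemble_stiffness(mesh, list(block = material(10, 0.3)))
  A <- matrix(c(0.01, 0.002, 0, 0.003, -0.005, 0.001, 0, 0.002, 0.004), 3, 3)
  b <- c(0.001, -0.002, 0.0005)
  uaff <- mesh$nodes %*% t(A) + matrix(b, nrow(mesh$nodes), 3, byrow = TRUE)
  bb <- apply(mesh$nodes, 2, range)
  onb <- apply(mesh$nodes, 1, function(q)
    any(abs(q - bb[1, ]) < 1e-9 | abs(q - bb[2, ]) < 1e-9))
  cons <- add_dirichlet(fe_constraints(mesh), which(onb), uaff[which(onb), ])
  sol <- solve_linear(fem, cons)
  expect_lt(max(abs(sol$u - uaff)) / max(abs(uaff)), 1e-10)
})

test_that("a free mesh has exactly six rigid-body modes", {
  mesh <- block_mesh(2, 0.5)
  fem <- assemble_stiffness(mesh, list(block = material(1, 0.25)))
  ev <- sort(abs(eigen(as.matrix(fem$K), symmetric = TRUE,
                       only.values = TRUE)$values))
  expect_lt(ev[6] / ev[7], 1e-8)
  expect_gt(ev[7], 0)
})

test_that("kinematic coupling equals direct prescription of the node set", {
  mesh <- block_mesh(3, 0.3)
  fem <- assemble_stiffness(mesh, list(block = material(5, 0.3)))
  z <- mesh$nodes[, 3]
  bot <- which(abs(z - min(z)) < 1e-9)
  top <- which(abs(z - max(z)) < 1e-9)
  c1 <- apply_coupling(add_dirichlet(fe_constraints(mesh), bot, c(0, 0, 0)),
                       top, c(0.45, 0.45, max(z)))
  s1 <- solve_linear(fem, c1, ref_disp = matrix(c(0, 0, -0.01), 1))
  c2 <- add_dirichlet(add_dirichlet(fe_constraints(mesh), bot, c(0, 0, 0)),
                      top, c(0, 0, -0.01))
  s2 <- solve_linear(fem, c2)
  expect_lt(max(abs(s1$u - s2$u)), 1e-12)
  # reference reaction balances the fixed-base reactions
  bd <- as.integer(t(outer(3 * (bot - 1), 1:3, "+")))
  Rb <- colSums(matrix(s1$reactions[bd], ncol = 3, byrow = TRUE))
  expect_lt(abs(s1$ref_reaction[3] + Rb[3]), 1e-10)
  # zero prescribed displacement gives zero reaction
  s0 <- solve_linear(fem, c1, ref_disp = matrix(0, 1, 3))
  expect_lt(max(abs(s0$ref_reaction)), 1e-12)
})

test_that("conflicting constraints on one node are rejected", {
  mesh <- block_mesh(2, 0.5)
  z <- mesh$nodes[, 3]
  top <- which(abs(z - max(z)) < 1e-9)
  cons <- apply_coupling(fe_constraints(mesh), top, c(0, 0, 1))
  cons <- apply_coupling(cons, top[1], c(0, 0, 1), name = "ref2")
  expect_error(solve_linear(assemble_stiffness(mesh, list(block = material(1, 0.3))),
                            cons, ref_disp = matrix(0, 2, 3)),
               "conflicting")
})

test_that("tied stacked blocks match the monolithic solution", {
  fx <- stacked_blocks()
  meshS <- fx$split; meshM <- fx$mono
  mats <- function(mesh) {
    out <- lapply(unique(mesh$region), function(r) material(10, 0.3))
    names(out) <- unique(mesh$region)
    out
  }
  femS <- assemble_stiffness(meshS, mats(meshS))
  femM <- assemble_stiffness(meshM, mats(meshM))
  zS <- meshS$nodes[, 3]; zM <- meshM$nodes[, 3]
  solM <- solve_linear(femM, add_dirichlet(
    add_dirichlet(fe_constraints(meshM), which(abs(zM - min(zM)) < 1e-9), c(0, 0, 0)),
    which(abs(zM - max(zM)) < 1e-9), c(0, 0, -0.02)))
  upN <- unique(as.integer(meshS$elems[meshS$region == "upper", ]))
  slv <- upN[abs(zS[upN] - min(zS[upN])) < 1e-9]
  consT <- apply_tie(add_dirichlet(
    add_dirichlet(fe_constraints(meshS), which(abs(zS - min(zS)) < 1e-9), c(0, 0, 0)),
    which(abs(zS - max(zS)) < 1e-9), c(0, 0, -0.02)),
    meshS, slv, fx$lower_top, tol = 1e-6)
  solT <- solve_linear(femS, consT)
  mp <- match(node_key(meshM$nodes), node_key(meshS$nodes))
  rel <- sqrt(sum((solT$u[mp, ] - solM$u)^2) / sum(solM$u^2))
  expect_lt(rel, 0.01)
  # Newton's third law: all reactions (including tie forces) sum to zero
  expect_lt(max(abs(colSums(matrix(solT$reactions, ncol = 3, byrow = TRUE)))),
            1e-9)
})

test_that("a tie slave coincident with a master vertex reduces to node equality", {
  fx <- stacked_blocks()
  meshS <- fx$split
  zS <- meshS$nodes[, 3]
  upN <- unique(as.integer(meshS$elems[meshS$region == "upper", ]))
  slv <- upN[abs(zS[upN] - min(zS[upN])) < 1e-9][1]
  cons <- apply_tie(fe_constraints(meshS), meshS, slv, fx$lower_top, tol = 1e-6)
  m <- cons$mpc[[1]]
  expect_length(m$masters, 1)
  expect_equal(m$coefs, 1, tolerance = 1e-9)
  # slaves beyond tolerance raise a structured error naming nodes
  far <- which.max(zS)
  expect_error(apply_tie(fe_constraints(meshS), meshS, far, fx$lower_top,
                         tol = 1e-6), "beyond tolerance")
})

test_that("external work equals strain energy without contact", {
  mesh <- block_mesh(3, 0.3)
  fem <- assemble_stiffness(mesh, list(block = material(7, 0.35)))
  z <- mesh$nodes[, 3]
  bot <- which(abs(z - min(z)) < 1e-9)
  top <- which(abs(z - max(z)) < 1e-9)
  cons <- add_dirichlet(add_dirichlet(fe_constraints(mesh), bot, c(0, 0, 0)),
                        top, c(0, 0, -0.03))
  sol <- solve_linear(fem, cons)
  td <- as.integer(t(outer(3 * (top - 1), 1:3, "+")))
  W <- 0.5 * sum(sol$reactions[td] * as.numeric(t(sol$u[top, , drop = FALSE])))
  U <- strain_energy(fem, sol$u)
  expect_lt(abs(W - U) / U, 1e-8)
})

test_that("von Mises stress has its closed-form values", {
  expect_equal(von_mises(c(-3, -3, -3, 0, 0, 0)), 0)
  expect_equal(von_mises(c(0, 0, 5, 0, 0, 0)), 5)
  expect_equal(von_mises(c(0, 0, 0, 2, 0, 0)), 2 * sqrt(3))
  m <- rbind(c(1, 1, 1, 0, 0, 0), c(2, 0, 0, 0, 0, 0))
  expect_equal(as.numeric(von_mises(m)), c(0, 2))
})

test_that("solutions are frame-invariant under 90-degree rotation", {
  mesh <- block_mesh(3, 0.3)
  fem <- assemble_stiffness(mesh, list(block = material(5, 0.3)))
  z <- mesh$nodes[, 3]
  bot <- which(abs(z - min(z)) < 1e-9)
  top <- which(abs(z - max(z)) < 1e-9)
  cons <- add_dirichlet(add_dirichlet(fe_constraints(mesh), bot, c(0, 0, 0)),
                        top, c(0.002, 0, -0.01))
  sol <- solve_linear(fem, cons)
  # rotate the whole problem by 90 degrees about x: z -> y, y -> -z
  R <- rotation_about(c(1, 0, 0), 90)
  meshR <- mesh
  meshR$nodes <- mesh$nodes %*% t(R)
  femR <- assemble_stiffness(meshR, list(block = material(5, 0.3)))
  consR <- add_dirichlet(add_dirichlet(fe_constraints(meshR), bot, c(0, 0, 0)),
                         top, as.numeric(R %*% c(0.002, 0, -0.01)))
  solR <- solve_linear(femR, consR)
  expect_lt(max(abs(solR$u - sol$u %*% t(R))), 1e-9)
})
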