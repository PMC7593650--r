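#' Structured sphere-on-plane benchmark mesh (solver validation geometry)
#'
#' A sphere-capped cylinder: the bottom surface is the exact spherical cap
#' `z = R - sqrt(R^2 - r^2)` (tangent to the plane `z = 0` at the origin),
#' the top is flat. The planform disc is meshed by an elliptical
#' square-to-disc map with power-law grading towards the contact axis, and
#' layers are graded towards the cap, so the contact zone is well resolved;
#' hexahedral cells are subdivided into 6 tetrahedra (Kuhn), conforming.
#'
#' @param radius sphere radius `R`, mm.
#' @param layer optional soft-layer thickness (mm) measured from the cap
#'   surface; elements within it get region `"layer"`, the rest
#'   `"indenter"` (with `layer = NULL` everything is `"indenter"`).
#' @param edge_length target in-plane edge near the contact axis, mm
#'   (must be `< radius/4`).
#' @param r_max,height planform radius and total height, mm.
#' @param grading_r,grading_z radial / vertical grading exponents.
#' @return A `tet_mesh` with node set `top_driven` and facet set
#'   `contact_bottom`.
#' @export
generate_hertz_benchmark <- function(radius, layer = NULL, edge_length,
                                     r_max = 0.55 * radius,
                                     height = 0.7 * radius,
                                     grading_r = 1.45, grading_z = 1.8) {
  if (edge_length >= radius / 4)
    stop("edge_length must be smaller than radius/4")
  if (r_max >= radius) stop("planform radius must be smaller than the sphere radius")
  # n chosen so the mid-radius cell is ~ edge_length (grading refines centre)
  n <- 2L * max(4L, as.integer(ceiling(r_max / edge_length / 2)))
  nz <- max(6L, as.integer(ceiling(n * 0.35)))

  tg <- seq(-1, 1, length.out = n + 1L)
  s <- sign(tg) * abs(tg)^grading_r
  # elliptical square-to-disc map
  U <- outer(s, rep(1, n + 1L))
  V <- outer(rep(1, n + 1L), s)
  X <- r_max * U * sqrt(1 - V^2 / 2)
  Y <- r_max * V * sqrt(1 - U^2 / 2)
  R2 <- X^2 + Y^2
  ZB <- radius - sqrt(radius^2 - R2)

  nl <- (seq_len(nz + 1L) - 1L) / nz
  zfrac <- nl^grading_z
  npl <- (n + 1L)^2
  nnode <- npl * (nz + 1L)
  nodes <- matrix(0, nnode, 3)
  for (k in seq_len(nz + 1L)) {
    idx <- (k - 1L) * npl + seq_len(npl)
    nodes[idx, 1] <- as.numeric(X)
    nodes[idx, 2] <- as.numeric(Y)
    nodes[idx, 3] <- as.numeric(ZB) + (height - as.numeric(ZB)) * zfrac[k]
  }

  nid <- function(i, j, k) (k - 1L) * npl + (j - 1L) * (n + 1L) + i
  tpl <- kuhn_template()
  ci <- rep(seq_len(n), times = n * nz)
  cj <- rep(rep(seq_len(n), each = n), times = nz)
  ck <- rep(seq_len(nz), each = n * n)
  corners <- cbind(nid(ci, cj, ck),         nid(ci + 1L, cj, ck),
                   nid(ci, cj + 1L, ck),    nid(ci + 1L, cj + 1L, ck),
                   nid(ci, cj, ck + 1L),    nid(ci + 1L, cj, ck + 1L),
                   nid(ci, cj + 1L, ck + 1L), nid(ci + 1L, cj + 1L, ck + 1L))
  nc <- nrow(corners)
  elems <- matrix(0L, 6L * nc, 4L)
  for (p in 1:6)
    elems[seq.int(p, by = 6L, length.out = nc), ] <- corners[, tpl[p, ]]

  region <- rep("indenter", 6L * nc)
  if (!is.null(layer) && layer > 0) {
    # element centroid height above the local cap surface
    cz <- (nodes[elems[, 1], 3] + nodes[elems[, 2], 3] +
             nodes[elems[, 3], 3] + nodes[elems[, 4], 3]) / 4
    cxy <- cbind((nodes[elems[, 1], 1] + nodes[elems[, 2], 1] +
                    nodes[elems[, 3], 1] + nodes[elems[, 4], 1]) / 4,
                 (nodes[elems[, 1], 2] + nodes[elems[, 2], 2] +
                    nodes[elems[, 3], 2] + nodes[elems[, 4], 2]) / 4)
    zb_c <- radius - sqrt(pmax(0, radius^2 - rowSums(cxy^2)))
    region[cz - zb_c < layer] <- "layer"
  }

  mesh <- structure(list(
    nodes = nodes, elems = elems, region = region,
    body = rep("indenter_body", nrow(elems)),
    node_sets = list(), facet_sets = list(),
    edge_length = 2 * r_max / n, tissues = unique(region),
    body_map = NULL), class = "tet_mesh")
  vol <- tet_volumes(mesh)
  if (any(vol <= 0)) stop("hertz benchmark meshing failed: inverted elements")

  bottom_nodes <- nid(rep(seq_len(n + 1L), n + 1L),
                      rep(seq_len(n + 1L), each = n + 1L), 1L)
  top_nodes <- bottom_nodes + npl * nz
  dt <- mesh_faces(mesh)
  bound <- dt[dt$cnt == 1L, ]
  isbot <- matrix(as.matrix(bound[, c("n1", "n2", "n3")]) %in% bottom_nodes,
                  nrow(bound), 3)
  mesh$facet_sets$contact_bottom <-
    as.matrix(bound[rowSums(isbot) == 3L, c("n1", "n2", "n3", "owner")])
  mesh$node_sets$top_driven <- top_nodes
  mesh
}

#' Closed-form Hertz sphere-on-rigid-plane solution
#'
#' For total normal force `F` on a sphere of radius `R` against a rigid
#' frictionless plane: `E* = E / (1 - nu^2)`, contact radius
#' `a = (3 F R / (4 E*))^{1/3}` and peak pressure `p0 = 3F / (2 pi a^2)`.
#'
#' @param F normal force, N.
#' @param radius sphere radius, mm.
#' @param E,nu elastic constants of the sphere (MPa, -).
#' @export
hertz_analytic <- function(F, radius, E, nu) {
  Estar <- E / (1 - nu^2)
  a <- (3 * F * radius / (4 * Estar))^(1 / 3)
  list(a = a, p0 = 3 * F / (2 * pi * a^2), F = F, Estar = Estar)
}

#' Run the sphere-on-rigid-plane validation benchmark
#'
#' Displacement-controlled indentation of the elastic cap against the rigid
#' plane `z = 0` via the penalty contact solver; the finite-element peak
#' pressure and contact radius are compared with the Hertz closed form
#' evaluated at the *measured* reaction force (so the comparison does not
#' depend on the far-field compliance of the finite mesh).
#'
#' @param radius,E,nu sphere radius (mm) and elasticity (MPa, -).
#' @param indentation prescribed downward displacement of the top face, mm.
#' @param edge_length central in-plane mesh edge, mm.
#' @param n_steps increments for the indentation.
#' @param control solver control list.
#' @return list with the measured `F`, `p0_fem`, `a_fem`, the matched
#'   `hertz` solution and relative errors.
#' @export
run_hertz_benchmark <- function(radius = 1, E = 10, nu = 0.3,
                                indentation = 0.0625, edge_length = 0.028,
                                n_steps = 3L, control = list()) {
  mesh <- generate_hertz_benchmark(radius, layer = NULL, edge_length = edge_length)
  mats <- list(indenter = material(E, nu), layer = material(E, nu))
  fem <- assemble_stiffness(mesh, mats)
  cons <- fe_constraints(mesh)
  pair <- contact_pair(mesh, slave_facets = mesh$facet_sets$contact_bottom,
                       E_slave = E,
                       rigid_plane = list(point = c(0, 0, 0), normal = c(0, 0, 1)),
                       name = "sphere_plane")
  protocol <- load_protocol(gap_translation = 0,
                            initialization_displacement = 0,
                            loading_displacement = indentation,
                            n_steps = n_steps)
  sol <- solve_contact_steps(fem, cons, protocol, list(pair),
                             driven_nodes = mesh$node_sets$top_driven,
                             control = control)
  last <- sol$steps[[length(sol$steps)]]
  cc <- last$contact$sphere_plane
  F <- last$reaction
  act <- cc$in_contact
  r <- sqrt(rowSums(mesh$nodes[cc$nodes, 1:2, drop = FALSE]^2))
  a_fem <- max(r[act])
  p0_fem <- max(cc$pressure)
  hz <- hertz_analytic(F, radius, E, nu)
  list(F = F, p0_fem = p0_fem, a_fem = a_fem, hertz = hz,
       p0_rel_err = abs(p0_fem - hz$p0) / hz$p0,
       a_rel_err = abs(a_fem - hz$a) / hz$a,
       solution = sol, mesh = mesh)
}

#' Analytic volume of the benchmark solid (for mesh verification)
#' @param radius,r_max,height as in [generate_hertz_benchmark()].
#' @export
hertz_benchmark_volume <- function(radius, r_max = 0.55 * radius,
                                   height = 0.7 * radius) {
  cap_int <- pi * r_max^2 * radius -
    (2 * pi / 3) * (radius^3 - (radius^2 - r_max^2)^1.5)
  pi * r_max^2 * height - cap_int
}
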