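#' Linear elastic material
#'
#' Homogeneous isotropic small-strain material. The tissue properties used
#' throughout are cartilage E = 6 MPa, nu = 0.49; meniscus E = 59 MPa,
#' nu = 0.49; bone E = 18000 MPa, nu = 0.3.
#'
#' @param E Young's modulus, MPa.
#' @param nu Poisson ratio, in (0, 0.5).
#' @export
material <- function(E, nu) {
  if (!is.finite(E) || E <= 0) stop("E must be positive")
  if (!is.finite(nu) || nu < 0 || nu >= 0.5) stop("nu must be in [0, 0.5)")
  structure(list(E = E, nu = nu), class = "material")
}

#' Default tissue material map
#' @export
default_materials <- function() {
  list(
    femur_bone = material(18000, 0.3),
    tibia_bone = material(18000, 0.3),
    calcified_meniscus = material(18000, 0.3),
    femur_cartilage = material(6, 0.49),
    tibia_cartilage = material(6, 0.49),
    soft_meniscus = material(59, 0.49)
  )
}

#' Assemble the global stiffness of a tetrahedral mesh
#'
#' Constant-strain tetrahedra. For an isotropic material the 12x12 element
#' matrix has the closed form
#' `K[(i,r),(j,s)] = V (lambda gi_r gj_s + mu gi_s gj_r + mu delta_rs gi.gj)`
#' with `gi` the shape-function gradients; assembly is fully vectorised over
#' elements. Units: mm, N, MPa.
#'
#' @param mesh a `tet_mesh`.
#' @param materials named list region -> [material()].
#' @return An `fe_system`: sparse symmetric `K`, per-element gradients,
#'   volumes and Lame constants (used later for stress recovery).
#' @export
assemble_stiffness <- function(mesh, materials) {
  regs <- unique(mesh$region)
  missing_mat <- setdiff(regs, names(materials))
  if (length(missing_mat))
    stop("no material for region(s): ", paste(missing_mat, collapse = ", "))
  p <- mesh$nodes
  e <- mesh$elems
  m <- nrow(e)
  V <- tet_volumes(mesh)
  if (any(V <= 0))
    stop("inverted element(s): ", paste(utils::head(which(V <= 0)), collapse = ", "))

  # Jacobian rows: edges from node 1
  a1 <- p[e[, 2], , drop = FALSE] - p[e[, 1], , drop = FALSE]
  a2 <- p[e[, 3], , drop = FALSE] - p[e[, 1], , drop = FALSE]
  a3 <- p[e[, 4], , drop = FALSE] - p[e[, 1], , drop = FALSE]
  detJ <- 6 * V
  cross <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                u[, 1] * v[, 2] - u[, 2] * v[, 1])
  # gradients of shape functions 2..4 are rows of inv(J)^T = cofactors / detJ
  g2 <- cross(a2, a3) / detJ
  g3 <- cross(a3, a1) / detJ
  g4 <- cross(a1, a2) / detJ
  g1 <- -(g2 + g3 + g4)
  G <- array(0, c(m, 4, 3))
  G[, 1, ] <- g1; G[, 2, ] <- g2; G[, 3, ] <- g3; G[, 4, ] <- g4

  Evec <- numeric(m); nuvec <- numeric(m)
  for (r in regs) {
    sel <- mesh$region == r
    Evec[sel] <- materials[[r]]$E
    nuvec[sel] <- materials[[r]]$nu
  }
  lam <- Evec * nuvec / ((1 + nuvec) * (1 - 2 * nuvec))
  mu <- Evec / (2 * (1 + nuvec))

  nn <- nrow(p)
  ntrip <- 144L * m
  ii <- integer(ntrip); jj <- integer(ntrip); xx <- numeric(ntrip)
  pos <- 1L
  gdot <- array(0, c(m, 4, 4))
  for (i in 1:4) for (j in 1:4)
    gdot[, i, j] <- G[, i, 1] * G[, j, 1] + G[, i, 2] * G[, j, 2] +
      G[, i, 3] * G[, j, 3]
  for (i in 1:4) for (j in 1:4) {
    di <- 3L * (e[, i] - 1L)
    dj <- 3L * (e[, j] - 1L)
    for (r in 1:3) for (s in 1:3) {
      val <- V * (lam * G[, i, r] * G[, j, s] + mu * G[, i, s] * G[, j, r])
      if (r == s) val <- val + V * mu * gdot[, i, j]
      idx <- pos:(pos + m - 1L)
      ii[idx] <- di + r
      jj[idx] <- dj + s
      xx[idx] <- val
      pos <- pos + m
    }
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(3L * nn, 3L * nn))
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2, uplo = "U")
  structure(list(K = K, grads = G, V = V, lambda = lam, mu = mu,
                 mesh = mesh, n_nodes = nn),
            class = "fe_system")
}

#' Recover element stresses and strain energy from a displacement field
#'
#' @param fem an `fe_system`.
#' @param u n x 3 nodal displacement matrix (mm).
#' @return m x 6 Cauchy stress matrix (MPa), columns
#'   `xx, yy, zz, xy, yz, xz`.
#' @export
element_stress <- function(fem, u) {
  e <- fem$mesh$elems
  G <- fem$grads
  m <- nrow(e)
  H <- array(0, c(m, 3, 3))            # displacement gradient
  for (i in 1:4)
    for (r in 1:3) for (s in 1:3)
      H[, r, s] <- H[, r, s] + u[e[, i], r] * G[, i, s]
  eps <- array(0, c(m, 3, 3))
  for (r in 1:3) for (s in 1:3) eps[, r, s] <- (H[, r, s] + H[, s, r]) / 2
  tr <- eps[, 1, 1] + eps[, 2, 2] + eps[, 3, 3]
  sig <- cbind(
    xx = fem$lambda * tr + 2 * fem$mu * eps[, 1, 1],
    yy = fem$lambda * tr + 2 * fem$mu * eps[, 2, 2],
    zz = fem$lambda * tr + 2 * fem$mu * eps[, 3, 3],
    xy = 2 * fem$mu * eps[, 1, 2],
    yz = 2 * fem$mu * eps[, 2, 3],
    xz = 2 * fem$mu * eps[, 1, 3]
  )
  sig
}

#' Von Mises equivalent stress
#'
#' `sigma_vm = sqrt(3/2 dev(sigma):dev(sigma))`: zero for hydrostatic
#' states, `|s|` for uniaxial stress `s`, `sqrt(3) tau` for pure shear.
#'
#' @param stress m x 6 matrix (`xx, yy, zz, xy, yz, xz`) or length-6 vector.
#' @export
von_mises <- function(stress) {
  s <- rbind(stress)
  unname(sqrt(0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 +
                       (s[, 3] - s[, 1])^2) +
                3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2)))
}

#' Strain energy of a displacement field
#' @param fem an `fe_system`; `u` n x 3 displacements.
#' @export
strain_energy <- function(fem, u) {
  uv <- as.numeric(t(u))
  as.numeric(0.5 * (uv %*% (fem$K %*% uv)))
}

#' Constraint sets: Dirichlet, kinematic coupling and tied interfaces
#'
#' `fe_constraints` starts an empty set for a mesh; constraints are added
#' with [add_dirichlet()], [apply_coupling()] and [apply_tie()]. Reference
#' points introduced by couplings append 3 extra degrees of freedom each.
#'
#' @param mesh a `tet_mesh`.
#' @export
fe_constraints <- function(mesh) {
  structure(list(n_nodes = nrow(mesh$nodes), ref_points = NULL,
                 dirichlet_nodes = integer(), dirichlet_values = NULL,
                 mpc = list(), ref_names = character()),
            class = "fe_constraints")
}

#' @rdname fe_constraints
#' @param cons an `fe_constraints`.
#' @param nodes node indices.
#' @param value length-3 displacement (mm) applied to all `nodes`, or an
#'   n x 3 matrix.
#' @export
add_dirichlet <- function(cons, nodes, value = c(0, 0, 0)) {
  nodes <- as.integer(nodes)
  vals <- if (is.matrix(value)) value else
    matrix(value, length(nodes), 3, byrow = TRUE)
  stopifnot(nrow(vals) == length(nodes))
  cons$dirichlet_nodes <- c(cons$dirichlet_nodes, nodes)
  cons$dirichlet_values <- rbind(cons$dirichlet_values, vals)
  cons
}

#' Kinematic translation coupling of a node set to a reference point
#'
#' Every translational degree of freedom of each coupled node is set equal
#' to the reference point's (rotations are not modelled); the reference
#' point's reaction is the sum of the constraint forces, i.e. the force
#' transmitted through the coupled surface.
#'
#' @param cons an `fe_constraints`.
#' @param node_set node indices (e.g. the superior femoral surface).
#' @param reference_point length-3 coordinates (mm), bookkeeping only.
#' @param name reference-point name.
#' @export
apply_coupling <- function(cons, node_set, reference_point, name = "ref") {
  if (length(node_set) == 0) stop("empty coupling node set")
  ref_id <- nrow(cons$ref_points %||% matrix(0, 0, 3)) + 1L
  cons$ref_points <- rbind(cons$ref_points, matrix(reference_point, 1, 3))
  cons$ref_names <- c(cons$ref_names, name)
  for (nd in as.integer(node_set)) {
    for (r in 1:3) {
      cons$mpc[[length(cons$mpc) + 1L]] <- list(
        slave = 3L * (nd - 1L) + r,
        masters = 3L * (cons$n_nodes + ref_id - 1L) + r,
        coefs = 1
      )
    }
  }
  cons
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tied (bonded) interface between a slave node set and master facets
#'
#' Each slave node is projected onto the closest master facet in the
#' reference configuration; its displacement is constrained to the
#' barycentric interpolation of the facet's nodal displacements (a
#' multipoint constraint). A slave node coincident with a master vertex
#' degenerates to node equality. Slave nodes farther than `tol` from the
#' master surface raise an error listing the offending nodes.
#'
#' @param cons an `fe_constraints`.
#' @param mesh the `tet_mesh`.
#' @param slave_nodes node indices (e.g. the inferior meniscal surface).
#' @param master_facets facet matrix (`n1, n2, n3, owner`), e.g. the tibial
#'   cartilage surface.
#' @param tol gap tolerance, mm.
#' @export
apply_tie <- function(cons, mesh, slave_nodes, master_facets, tol) {
  slave_nodes <- as.integer(unique(slave_nodes))
  tv <- facet_vertex_matrix(mesh$nodes, master_facets)
  pr <- .project_points_tris(mesh$nodes[slave_nodes, , drop = FALSE], tv,
                             max_dist = max(tol * 2, 1e-9))
  bad <- which(pr$tri == 0L | pr$dist > tol)
  if (length(bad))
    stop("tie slave nodes beyond tolerance: ",
         paste(utils::head(slave_nodes[bad], 10), collapse = ", "))
  for (i in seq_along(slave_nodes)) {
    tri <- master_facets[pr$tri[i], 1:3]
    w <- pr$bary[i, ]
    keep <- w > 1e-12
    for (r in 1:3) {
      cons$mpc[[length(cons$mpc) + 1L]] <- list(
        slave = 3L * (slave_nodes[i] - 1L) + r,
        masters = 3L * (as.integer(tri[keep]) - 1L) + r,
        coefs = w[keep]
      )
    }
  }
  cons
}

facet_vertex_matrix <- function(nodes, facets) {
  cbind(nodes[facets[, 1], , drop = FALSE],
        nodes[facets[, 2], , drop = FALSE],
        nodes[facets[, 3], , drop = FALSE])
}

# Build the reduction u = S[, free] q + S[, presc] g.
# Returns S (ndof x ndof sparse), free/prescribed column indices and the
# prescribed values vector aligned with `presc`.
build_reduction <- function(cons, ref_disp = NULL) {
  nref <- nrow(cons$ref_points %||% matrix(0, 0, 3))
  ndof <- 3L * (cons$n_nodes + nref)
  slave <- vapply(cons$mpc, function(m) m$slave, 1L)
  if (anyDuplicated(slave))
    stop("node in two conflicting constraints (duplicate MPC slave dof)")
  dir_dofs <- as.integer(t(outer(3L * (cons$dirichlet_nodes - 1L), 1:3, "+")))
  dir_vals <- as.numeric(t(cons$dirichlet_values %||% matrix(0, 0, 3)))
  if (anyDuplicated(dir_dofs)) {
    keep <- !duplicated(dir_dofs)
    # conflicting duplicate prescriptions are an error; repeats of the same
    # value are collapsed
    agg <- tapply(dir_vals, dir_dofs, function(v) diff(range(v)))
    if (any(agg > 1e-12)) stop("conflicting Dirichlet values on a dof")
    dir_dofs <- dir_dofs[keep]; dir_vals <- dir_vals[keep]
  }
  if (length(intersect(slave, dir_dofs)))
    stop("node in two conflicting constraints (MPC slave also prescribed)")

  ii <- setdiff(seq_len(ndof), slave)
  trip_i <- ii; trip_j <- ii; trip_x <- rep(1, length(ii))
  for (m in cons$mpc) {
    trip_i <- c(trip_i, rep(m$slave, length(m$masters)))
    trip_j <- c(trip_j, m$masters)
    trip_x <- c(trip_x, m$coefs)
  }
  S <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(ndof, ndof))
  ref_dofs <- if (nref > 0) 3L * cons$n_nodes + seq_len(3L * nref) else integer()
  presc <- c(dir_dofs, ref_dofs)
  pvals <- c(dir_vals, as.numeric(t(ref_disp %||% matrix(0, nref, 3))))
  free <- setdiff(seq_len(ndof), union(slave, presc))
  list(S = S, free = free, presc = presc, pvals = pvals, ndof = ndof,
       ref_dofs = ref_dofs)
}

# Cache the constraint-reduced pieces of the linear system for one
# increment: u = SF q + u0 with A0 = SF' K SF and b0 = -SF' K u0 fixed,
# while the penalty contribution changes every contact iteration.
reduced_operator <- function(fem, red) {
  ndof <- red$ndof
  Kt <- pad_sparse(fem$K, ndof)
  SF <- red$S[, red$free, drop = FALSE]
  u0 <- as.numeric(red$S[, red$presc, drop = FALSE] %*% red$pvals)
  list(ndof = ndof, nm = 3L * fem$n_nodes, Kt = Kt, SF = SF, u0 = u0,
       A0 = Matrix::forceSymmetric(Matrix::t(SF) %*% Kt %*% SF),
       b0 = as.numeric(Matrix::t(SF) %*% (-(Kt %*% u0))),
       S = red$S, ref_dofs = red$ref_dofs)
}

# Solve one contact iteration on the cached operator.
solve_operator <- function(op, Kpen = NULL, fpen = NULL, f_ext = NULL) {
  A <- op$A0
  b <- op$b0
  if (!is.null(f_ext)) {
    f <- numeric(op$ndof); f[seq_along(f_ext)] <- f_ext
    b <- b + as.numeric(Matrix::t(op$SF) %*% f)
  }
  if (!is.null(Kpen)) {
    A <- A + Matrix::forceSymmetric(Matrix::t(op$SF) %*% Kpen %*% op$SF)
    b <- b + as.numeric(Matrix::t(op$SF) %*% (fpen - Kpen %*% op$u0))
  } else if (!is.null(fpen)) {
    b <- b + as.numeric(Matrix::t(op$SF) %*% fpen)
  }
  ch <- Matrix::Cholesky(A, LDL = FALSE, perm = TRUE, super = TRUE)
  q <- as.numeric(Matrix::solve(ch, b))
  ufull <- as.numeric(op$SF %*% q) + op$u0
  matrix(ufull[seq_len(op$nm)], ncol = 3, byrow = TRUE)
}

# Reactions at prescribed/reference dofs for a given full state.
operator_reactions <- function(op, u, Kpen = NULL, fpen = NULL, f_ext = NULL) {
  ufull <- c(as.numeric(t(u)), rep(0, op$ndof - op$nm))
  # reference dofs carry the prescribed values, not zeros
  if (length(op$ref_dofs)) ufull[op$ref_dofs] <- op$u0[op$ref_dofs]
  f <- numeric(op$ndof)
  if (!is.null(f_ext)) f[seq_along(f_ext)] <- f_ext
  if (!is.null(fpen)) f <- f + fpen
  Kt <- op$Kt
  if (!is.null(Kpen)) Kt <- Kt + Kpen
  resid <- as.numeric(Kt %*% ufull - f)
  as.numeric(Matrix::t(op$S) %*% resid)
}

solve_reduced <- function(fem, red, Kpen = NULL, fpen = NULL, f_ext = NULL) {
  op <- reduced_operator(fem, red)
  u <- solve_operator(op, Kpen, fpen, f_ext)
  list(u = u, reactions = operator_reactions(op, u, Kpen, fpen, f_ext))
}

pad_sparse <- function(K, ndof) {
  n0 <- nrow(K)
  if (ndof == n0) return(K)
  Matrix::bdiag(K, Matrix::Diagonal(ndof - n0, x = 0))
}

#' Solve a constrained linear elastic problem (no contact)
#'
#' @param fem an `fe_system`.
#' @param cons an `fe_constraints` (Dirichlet / coupling / tie).
#' @param ref_disp nref x 3 prescribed reference-point displacements.
#' @param f_ext optional external nodal force vector (length 3n, N).
#' @return list with `u` (n x 3 mm), `reactions` (per dof, N) and
#'   `ref_reaction` (nref x 3 matrix, N) when reference points exist.
#' @export
solve_linear <- function(fem, cons, ref_disp = NULL, f_ext = NULL) {
  red <- build_reduction(cons, ref_disp)
  sol <- solve_reduced(fem, red, f_ext = f_ext)
  refR <- if (length(red$ref_dofs))
    matrix(sol$reactions[red$ref_dofs], ncol = 3, byrow = TRUE) else NULL
  list(u = sol$u, reactions = sol$reactions, ref_reaction = refR)
}
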