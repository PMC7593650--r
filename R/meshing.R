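#' Meshing parameters
#'
#' Target minimum edge lengths of 100 um for bone and 5 um for soft tissue
#' reproduce the acquisition-scale meshes, which run to millions of
#' elements; the desk-scale default instead coarsens the label grid by an
#' integer factor before subdividing voxels into tetrahedra. A single global
#' factor is used for all tissues so that every inter-tissue interface stays
#' conforming; it is the smallest per-tissue factor implied by the targets
#' unless `coarsen` overrides it.
#'
#' @param target_edge_bone_um,target_edge_soft_um target edges, um.
#' @param coarsen optional explicit integer coarsening factor (voxels per
#'   element edge); overrides the targets.
#' @export
mesh_params <- function(target_edge_bone_um = 100, target_edge_soft_um = 5,
                        coarsen = NULL) {
  if (target_edge_bone_um <= 0 || target_edge_soft_um <= 0)
    stop("target edges must be positive")
  if (target_edge_soft_um > target_edge_bone_um)
    stop("soft-tissue target edge must not exceed the bone target edge")
  structure(list(target_edge_bone_um = target_edge_bone_um,
                 target_edge_soft_um = target_edge_soft_um,
                 coarsen = if (!is.null(coarsen)) as.integer(coarsen)),
            class = "mesh_params")
}

default_body_map <- c(
  femur_bone = "femur", femur_cartilage = "femur",
  tibia_bone = "tibia", tibia_cartilage = "tibia",
  soft_meniscus = "meniscus", calcified_meniscus = "meniscus"
)

# Kuhn 6-tetrahedron decomposition of the unit cube. Corners are numbered
# 1..8 by 1 + dx + 2*dy + 4*dz; every tet contains the main diagonal 1-8, so
# shared cube faces are triangulated identically in neighbouring cubes.
kuhn_template <- function() {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  corner <- function(b) 1L + b[1] + 2L * b[2] + 4L * b[3]
  tpl <- matrix(0L, 6, 4)
  for (p in seq_len(6)) {
    b <- c(0L, 0L, 0L)
    verts <- corner(b)
    for (ax in perms[p, ]) {
      b[ax] <- 1L
      verts <- c(verts, corner(b))
    }
    tpl[p, ] <- verts
  }
  # orient for positive volume on the unit cube
  cpos <- cbind(c(0, 1, 0, 1, 0, 1, 0, 1), c(0, 0, 1, 1, 0, 0, 1, 1),
                c(0, 0, 0, 0, 1, 1, 1, 1))
  for (p in seq_len(6)) {
    v <- cpos[tpl[p, ], ]
    vol <- det(rbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ]))
    if (vol < 0) tpl[p, c(3, 4)] <- tpl[p, c(4, 3)]
  }
  tpl
}

#' Convert disjoint label masks into a multi-body tetrahedral mesh
#'
#' Each labelled voxel (after optional integer coarsening of the label grid)
#' is split into 6 tetrahedra by the Kuhn subdivision, which conforms across
#' neighbouring voxels without parity bookkeeping. Tissues belonging to one
#' *body* (see `body_map`) share nodes, so bone-cartilage interfaces are
#' welded; distinct bodies (femur, tibia, meniscus) get duplicated nodes so
#' they can separate, contact or be tied explicitly.
#'
#' At `coarsen = 1` the mesh volume per tissue equals the mask volume
#' exactly (each voxel cube is partitioned). Coarsened blocks take the
#' majority label of their sub-voxels (empty wins only with an absolute
#' majority; label ties go to the softer tissue to protect thin layers).
#'
#' @param masks named list of `label_mask`s on one grid, pairwise disjoint.
#' @param params a [mesh_params()].
#' @param body_map named character vector tissue -> body.
#' @return A `tet_mesh`: nodes (mm), elements, region and body per element,
#'   empty named sets, and grid provenance.
#' @export
voxels_to_tets <- function(masks, params = mesh_params(coarsen = 1),
                           body_map = default_body_map) {
  stopifnot(length(masks) >= 1)
  tissues <- names(masks)
  if (is.null(tissues) || any(tissues == ""))
    stop("masks must be a named list")
  g0 <- masks[[1]]
  lab <- array(0L, dim(g0$values))
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    if (!same_grid(g0, m)) stop("masks are on different grids")
    if (any(lab[m$values] != 0L))
      stop(sprintf("masks overlap ('%s'); they must be pairwise disjoint",
                   tissues[i]))
    lab[m$values] <- i
  }
  h <- g0$spacing
  f <- params$coarsen
  if (is.null(f)) {
    f <- max(1L, as.integer(floor(params$target_edge_soft_um / (h * 1000))))
  }
  if (f > 1L) {
    lab <- coarsen_labels(lab, f, priority = order_soft_first(tissues))
  }
  H <- h * f
  origin_blk <- g0$origin + (f - 1) / 2 * h   # centre of block (1,1,1)

  occ <- which(lab != 0L)
  if (length(occ) == 0) stop("no labelled voxels to mesh")
  d <- dim(lab)
  ai <- arrayInd(occ, d)
  region_id <- lab[occ]
  body_of_tissue <- body_map[tissues]
  body_of_tissue[is.na(body_of_tissue)] <- tissues[is.na(body_of_tissue)]
  vox_body <- body_of_tissue[region_id]

  tpl <- kuhn_template()
  nxc <- d[1] + 1L
  nyc <- d[2] + 1L
  corner_lin <- function(ci, cj, ck) ci + nxc * (cj + (d[2] + 1L) * ck) # 0-based
  # 8 corner linear ids per voxel (0-based corner indices = voxel index - 1 + d)
  dx <- c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L)
  dy <- c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L)
  dz <- c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L)
  nvox <- length(occ)
  corn <- matrix(0L, nvox, 8)
  for (c8 in 1:8)
    corn[, c8] <- corner_lin(ai[, 1] - 1L + dx[c8], ai[, 2] - 1L + dy[c8],
                             ai[, 3] - 1L + dz[c8])

  nodes_list <- list()
  elem_list <- list()
  reg_list <- list()
  node_offset <- 0L
  for (b in unique(vox_body)) {
    vb <- vox_body == b
    cb <- corn[vb, , drop = FALSE]
    un <- sort(unique(as.integer(cb)))
    loc <- matrix(findInterval(as.integer(cb), un), nrow(cb), 8)
    # corner 0-based (ci, cj, ck) back from linear id
    ci <- un %% nxc
    rest <- un %/% nxc
    cj <- rest %% (d[2] + 1L)
    ck <- rest %/% (d[2] + 1L)
    xyz <- cbind(origin_blk[1] - H / 2 + H * ci,
                 origin_blk[2] - H / 2 + H * cj,
                 origin_blk[3] - H / 2 + H * ck)
    nb <- nrow(cb)
    els <- matrix(0L, nb * 6L, 4L)
    for (p in 1:6)
      els[seq.int(p, by = 6L, length.out = nb), ] <- loc[, tpl[p, ]]
    nodes_list[[b]] <- xyz
    elem_list[[b]] <- els + node_offset
    reg_list[[b]] <- rep(region_id[vb], each = 6L)
    node_offset <- node_offset + length(un)
  }
  nodes <- do.call(rbind, nodes_list)
  elems <- do.call(rbind, elem_list)
  region <- tissues[unlist(reg_list, use.names = FALSE)]
  body <- rep(names(elem_list), vapply(elem_list, nrow, 1L))

  mesh <- structure(list(
    nodes = nodes, elems = elems, region = region, body = body,
    node_sets = list(), facet_sets = list(),
    edge_length = H, tissues = tissues, body_map = body_of_tissue
  ), class = "tet_mesh")
  vol <- tet_volumes(mesh)
  if (any(vol <= 0)) stop("meshing produced non-positive tetrahedra")
  mesh
}

order_soft_first <- function(tissues) {
  pref <- c(soft_meniscus = 1, femur_cartilage = 2, tibia_cartilage = 2,
            calcified_meniscus = 3, femur_bone = 4, tibia_bone = 4)
  r <- pref[tissues]
  r[is.na(r)] <- 5
  order(r)  # tissue indices, softest first (tie-break order)
}

coarsen_labels <- function(lab, f, priority) {
  d <- dim(lab)
  nd <- d %/% f
  if (any(nd == 0)) stop("coarsening factor larger than the volume")
  lab <- lab[seq_len(nd[1] * f), seq_len(nd[2] * f), seq_len(nd[3] * f)]
  K <- max(lab)
  votes <- vector("list", K)
  occd <- array(0L, nd)
  sub <- function(a, i, j, k)
    a[seq.int(i, by = f, length.out = nd[1]),
      seq.int(j, by = f, length.out = nd[2]),
      seq.int(k, by = f, length.out = nd[3])]
  for (t in seq_len(K)) votes[[t]] <- array(0L, nd)
  for (i in seq_len(f)) for (j in seq_len(f)) for (k in seq_len(f)) {
    s <- sub(lab, i, j, k)
    occd <- occd + (s != 0L)
    for (t in seq_len(K)) votes[[t]] <- votes[[t]] + (s == t)
  }
  out <- array(0L, nd)
  best <- array(0L, nd)
  for (t in priority[priority <= K]) {
    better <- votes[[t]] > best
    out[better] <- t
    best[better] <- votes[[t]][better]
  }
  out[2L * occd < f^3] <- 0L   # mostly-empty blocks stay empty
  out
}

#' Signed tetrahedron volumes (mm^3)
#' @param mesh a `tet_mesh`.
#' @export
tet_volumes <- function(mesh) {
  p <- mesh$nodes
  e <- mesh$elems
  a <- p[e[, 2], , drop = FALSE] - p[e[, 1], , drop = FALSE]
  b <- p[e[, 3], , drop = FALSE] - p[e[, 1], , drop = FALSE]
  c3 <- p[e[, 4], , drop = FALSE] - p[e[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
   a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
   a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d nodes, %d tets, edge %.3g mm\n",
              nrow(x$nodes), nrow(x$elems), x$edge_length))
  tab <- table(x$region)
  for (r in names(tab)) cat(sprintf("  %-20s %d elements\n", r, tab[[r]]))
  if (length(x$node_sets))
    cat("  node sets:", paste(names(x$node_sets), collapse = ", "), "\n")
  if (length(x$facet_sets))
    cat("  facet sets:", paste(names(x$facet_sets), collapse = ", "), "\n")
  invisible(x)
}

# Face table of a mesh: all 4 oriented faces per tet with owner info.
# Faces are outward-oriented for the owner element.
mesh_faces <- function(mesh) {
  e <- mesh$elems
  m <- nrow(e)
  fidx <- rbind(c(2, 3, 4), c(1, 4, 3), c(1, 2, 4), c(1, 3, 2))
  faces <- matrix(0L, 4L * m, 3L)
  for (ff in 1:4)
    faces[seq.int(ff, by = 4L, length.out = m), ] <- e[, fidx[ff, ]]
  owner <- integer(4L * m)
  for (ff in 1:4) owner[seq.int(ff, by = 4L, length.out = m)] <- seq_len(m)
  key <- t(apply(faces, 1, sort))
  dt <- data.table::data.table(a = key[, 1], b = key[, 2], c = key[, 3],
                               owner = owner,
                               n1 = faces[, 1], n2 = faces[, 2], n3 = faces[, 3])
  dt[, grp := .GRP, by = .(a, b, c)]
  dt[, cnt := .N, by = grp]
  dt
}

#' Populate the named node and facet sets used as boundary conditions
#'
#' * `tibia_distal_fixed`: tibia-bone nodes within `layers` element layers
#'   of the minimal tibial z extent (fixed in every direction).
#' * `femur_top_coupled`: femur-bone nodes within `layers` element layers of
#'   the maximal femoral z extent (kinematically coupled to the reference
#'   point).
#' * `femoral_cartilage_surface`, `tibial_cartilage_surface`: exterior
#'   cartilage facets of the femur/tibia body (the bone-cartilage interface
#'   is interior to the body and therefore excluded automatically).
#' * `meniscus_superior` / `meniscus_inferior`: exterior meniscus-body
#'   facets with outward normal z-component above / below `normal_cut`.
#'
#' @param mesh a `tet_mesh`.
#' @param layers boundary-layer depth in elements (default 2).
#' @param normal_cut |nz| cut-off separating superior/inferior meniscus
#'   facets.
#' @return The mesh with `node_sets` and `facet_sets` filled; facet sets are
#'   integer matrices with columns `n1, n2, n3, owner` (outward-oriented).
#' @export
extract_named_sets <- function(mesh, layers = 2, normal_cut = 0.3) {
  dt <- mesh_faces(mesh)
  bound <- dt[dt$cnt == 1L, ]
  reg <- mesh$region
  body <- mesh$body
  fs <- list()
  take <- function(sel) {
    as.matrix(bound[sel, c("n1", "n2", "n3", "owner")])
  }
  if (any(reg == "femur_cartilage"))
    fs$femoral_cartilage_surface <- take(reg[bound$owner] == "femur_cartilage")
  if (any(reg == "tibia_cartilage"))
    fs$tibial_cartilage_surface <- take(reg[bound$owner] == "tibia_cartilage")
  if (any(body == "meniscus")) {
    men <- take(body[bound$owner] == "meniscus")
    nrm <- facet_normals(mesh, men)
    fs$meniscus_superior <- men[nrm[, 3] > normal_cut, , drop = FALSE]
    fs$meniscus_inferior <- men[nrm[, 3] < -normal_cut, , drop = FALSE]
  }
  ns <- list()
  H <- mesh$edge_length
  if (any(reg == "tibia_bone")) {
    tn <- unique(as.integer(mesh$elems[reg == "tibia_bone", ]))
    zmin <- min(mesh$nodes[tn, 3])
    ns$tibia_distal_fixed <- tn[mesh$nodes[tn, 3] <= zmin + layers * H + 1e-9]
  }
  if (any(reg == "femur_bone")) {
    fn <- unique(as.integer(mesh$elems[reg == "femur_bone", ]))
    zmax <- max(mesh$nodes[fn, 3])
    ns$femur_top_coupled <- fn[mesh$nodes[fn, 3] >= zmax - layers * H - 1e-9]
  }
  empty <- c(names(fs)[vapply(fs, nrow, 1L) == 0],
             names(ns)[vapply(ns, length, 1L) == 0])
  if (length(empty))
    stop("empty named set(s): ", paste(empty, collapse = ", "))
  mesh$facet_sets <- fs
  mesh$node_sets <- ns
  mesh
}

#' Outward facet normals and areas
#' @param mesh a `tet_mesh`; `facets` a facet matrix (`n1,n2,n3,owner`).
#' @return matrix with unit normal columns and an `area` attribute (mm^2).
#' @export
facet_normals <- function(mesh, facets) {
  p <- mesh$nodes
  a <- p[facets[, 2], , drop = FALSE] - p[facets[, 1], , drop = FALSE]
  b <- p[facets[, 3], , drop = FALSE] - p[facets[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(n^2))
  out <- n / len
  attr(out, "area") <- len / 2
  out
}

#' Mesh quality report
#'
#' Scaled Jacobian `6 sqrt(2) V / l_rms^3` (1 for the regular tetrahedron),
#' aspect ratio `l_max / (2 sqrt(6) r_in)` (1 for the regular tetrahedron),
#' and volume per region; elements with scaled Jacobian below 0.05 are
#' flagged.
#' @param mesh a `tet_mesh`.
#' @export
mesh_quality <- function(mesh) {
  p <- mesh$nodes
  e <- mesh$elems
  V <- tet_volumes(mesh)
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  l2 <- matrix(0, nrow(e), 6)
  for (k in 1:6)
    l2[, k] <- rowSums((p[e[, pairs[k, 1]], , drop = FALSE] -
                        p[e[, pairs[k, 2]], , drop = FALSE])^2)
  lrms <- sqrt(rowMeans(l2))
  lmax <- sqrt(apply(l2, 1, max))
  sj <- 6 * sqrt(2) * V / lrms^3
  # total face area for the inradius
  fidx <- rbind(c(2, 3, 4), c(1, 4, 3), c(1, 2, 4), c(1, 3, 2))
  A <- 0
  for (ff in 1:4) {
    a <- p[e[, fidx[ff, 2]], , drop = FALSE] - p[e[, fidx[ff, 1]], , drop = FALSE]
    b <- p[e[, fidx[ff, 3]], , drop = FALSE] - p[e[, fidx[ff, 1]], , drop = FALSE]
    A <- A + sqrt(rowSums(cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])^2)) / 2
  }
  rin <- 3 * V / A
  aspect <- lmax / (2 * sqrt(6) * rin)
  vols <- tapply(V, mesh$region, sum)
  list(min_scaled_jacobian = min(sj), median_scaled_jacobian = stats::median(sj),
       max_aspect = max(aspect), median_aspect = stats::median(aspect),
       volume_by_region = vols, n_flagged = sum(sj < 0.05),
       flagged = which(sj < 0.05))
}

#' Export a mesh as ASCII VTU (XML unstructured grid)
#'
#' Optional `point_data` / `cell_data` are named lists of numeric vectors or
#' matrices (one row per node / element).
#' @param mesh a `tet_mesh`.
#' @param path output path.
#' @param point_data,cell_data optional fields.
#' @export
write_vtu <- function(mesh, path, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  num <- function(x) paste(format(x, digits = 9, trim = TRUE, scientific = TRUE),
                           collapse = " ")
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid><Piece NumberOfPoints="', n, '" NumberOfCells="', m, '">')
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w(num(as.numeric(t(mesh$nodes))))
  w('</DataArray></Points>')
  w('<Cells><DataArray type="Int64" Name="connectivity" format="ascii">')
  w(paste(as.integer(t(mesh$elems)) - 1L, collapse = " "))
  w('</DataArray><DataArray type="Int64" Name="offsets" format="ascii">')
  w(paste(seq_len(m) * 4L, collapse = " "))
  w('</DataArray><DataArray type="UInt8" Name="types" format="ascii">')
  w(paste(rep(10L, m), collapse = " "))
  w('</DataArray></Cells>')
  dump_fields <- function(fields, where, extra = NULL) {
    w('<', where, '>')
    if (!is.null(extra)) {
      w('<DataArray type="Int32" Name="region" format="ascii">')
      w(paste(as.integer(factor(mesh$region)), collapse = " "))
      w('</DataArray>')
    }
    for (nm in names(fields)) {
      x <- fields[[nm]]
      nc <- if (is.matrix(x)) ncol(x) else 1L
      w('<DataArray type="Float64" Name="', nm, '" NumberOfComponents="', nc,
        '" format="ascii">')
      w(num(if (is.matrix(x)) as.numeric(t(x)) else as.numeric(x)))
      w('</DataArray>')
    }
    w('</', where, '>')
  }
  dump_fields(point_data, "PointData")
  dump_fields(cell_data, "CellData", extra = TRUE)
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(path)
}

#' Export a mesh as an Abaqus INP subset
#'
#' Nodes, C3D4 elements with one ELSET per region, and NSETs for the named
#' node sets; sufficient for cross-checking the assembled model in a
#' commercial solver.
#' @param mesh a `tet_mesh`; `path` output path.
#' @export
write_inp <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat("*HEADING\nkneefem mesh export\n*NODE\n", file = con)
  utils::write.table(cbind(seq_len(nrow(mesh$nodes)), mesh$nodes), con,
                     sep = ", ", col.names = FALSE, row.names = FALSE)
  off <- 0L
  for (r in unique(mesh$region)) {
    sel <- mesh$region == r
    cat(sprintf("*ELEMENT, TYPE=C3D4, ELSET=%s\n", toupper(r)), file = con)
    ids <- which(sel)
    utils::write.table(cbind(ids, mesh$elems[sel, , drop = FALSE]), con,
                       sep = ", ", col.names = FALSE, row.names = FALSE)
    off <- off + sum(sel)
  }
  for (nm in names(mesh$node_sets)) {
    cat(sprintf("*NSET, NSET=%s\n", toupper(nm)), file = con)
    v <- mesh$node_sets[[nm]]
    for (i in seq(1, length(v), by = 12))
      cat(paste(v[i:min(i + 11, length(v))], collapse = ", "), "\n",
          sep = "", file = con)
  }
  invisible(path)
}

#' Read back the INP subset written by [write_inp()]
#' @param path INP file path.
#' @export
read_inp <- function(path) {
  lines <- readLines(path)
  nodes <- NULL
  elems <- NULL
  region <- character()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^\\*NODE", ln, ignore.case = TRUE)) {
      j <- i + 1L
      while (j <= length(lines) && !grepl("^\\*", lines[j])) j <- j + 1L
      tab <- utils::read.csv(text = lines[(i + 1):(j - 1)], header = FALSE)
      nodes <- as.matrix(tab[order(tab[[1]]), 2:4])
      i <- j
    } else if (grepl("^\\*ELEMENT", ln, ignore.case = TRUE)) {
      elset <- sub(".*ELSET=([^,]+).*", "\\1", ln)
      j <- i + 1L
      while (j <= length(lines) && !grepl("^\\*", lines[j])) j <- j + 1L
      tab <- utils::read.csv(text = lines[(i + 1):(j - 1)], header = FALSE)
      elems <- rbind(elems, as.matrix(tab[, 2:5]))
      region <- c(region, rep(tolower(elset), nrow(tab)))
      i <- j
    } else i <- i + 1L
  }
  dimnames(nodes) <- NULL
  dimnames(elems) <- NULL
  structure(list(nodes = nodes, elems = matrix(as.integer(elems), ncol = 4),
                 region = region, body = rep("imported", nrow(elems)),
                 node_sets = list(), facet_sets = list(),
                 edge_length = NA_real_, tissues = unique(region),
                 body_map = NULL),
            class = "tet_mesh")
}
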