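#' Landmark sets and rigid transforms
#'
#' A `landmark_set` is an ordered table of 3D points (mm) with character ids
#' and a frame tag (`rest`, `stained_femur`, `stained_tibia`, ...). Paired
#' sets must have matching ids. A `rigid_transform` is a rotation matrix plus
#' translation mapping stained-scan coordinates into rest-position
#' coordinates: `y = R x + t`.
#'
#' @param points n x 3 numeric matrix (mm).
#' @param ids character vector of landmark ids (default `L1..Ln`).
#' @param frame frame tag.
#' @export
landmark_set <- function(points, ids = NULL, frame = "rest") {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  if (nrow(points) < 3) stop("a landmark set needs at least 3 points")
  if (is.null(ids)) ids <- paste0("L", seq_len(nrow(points)))
  if (anyDuplicated(ids)) stop("duplicate landmark ids")
  structure(list(points = points, ids = as.character(ids), frame = frame),
            class = "landmark_set")
}

#' @rdname landmark_set
#' @param rotation 3x3 rotation matrix (orthogonal, det +1).
#' @param translation length-3 numeric (mm).
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation matrix is not orthogonal")
  if (det(rotation) < 0) stop("rotation has negative determinant (reflection)")
  structure(list(R = rotation, t = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$R)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%.4g, %.4g, %.4g) mm\n",
              ang, x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

#' Apply, compose and invert rigid transforms
#' @param T,A,B `rigid_transform`s.
#' @param x n x 3 matrix of points (mm).
#' @export
apply_rigid <- function(T, x) {
  x <- rbind(x)  # accept a single point
  sweep(x %*% t(T$R), 2, T$t, "+")
}

#' @rdname apply_rigid
#' @export
compose_rigid <- function(A, B) {
  # (A o B)(x) = A(B(x))
  rigid_transform(A$R %*% B$R, as.numeric(A$R %*% B$t) + A$t)
}

#' @rdname apply_rigid
#' @export
invert_rigid <- function(T) {
  rigid_transform(t(T$R), as.numeric(-t(T$R) %*% T$t))
}

#' Closed-form rigid landmark registration (orthogonal Procrustes / Kabsch)
#'
#' Finds the rigid transform minimising `sum ||T(src_i) - dst_i||^2` over
#' rotations and translations, via the SVD of the cross-covariance with a
#' sign-corrected last singular vector so the result is always a proper
#' rotation (no reflection), even for near-degenerate configurations.
#'
#' The reported `rms_residual` is the root-mean-square over all 3n coordinate
#' residuals, `sqrt(SS / (3n))`; with isotropic landmark noise of standard
#' deviation sigma on the destination points its expectation is
#' `sigma * sqrt(1 - 2/n)`.
#'
#' @param src,dst `landmark_set`s with matching ids (any order).
#' @return list with `transform` (a `rigid_transform`) and `rms_residual` (mm).
#' @export
fit_rigid <- function(src, dst) {
  stopifnot(inherits(src, "landmark_set"), inherits(dst, "landmark_set"))
  if (nrow(src$points) != nrow(dst$points))
    stop("paired landmark sets must have equal length")
  ord <- match(src$ids, dst$ids)
  if (anyNA(ord)) stop("landmark ids do not match between sets")
  P <- src$points
  Q <- dst$points[ord, , drop = FALSE]
  n <- nrow(P)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  # collinear/degenerate: rank < 2 leaves the rotation undetermined
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300))
    stop("degenerate (collinear) landmark configuration: rotation undetermined")
  S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% S %*% t(sv$u)
  tvec <- cq - as.numeric(R %*% cp)
  T <- rigid_transform(R, tvec)
  res <- apply_rigid(T, P) - Q
  list(transform = T, rms_residual = sqrt(sum(res^2) / (3 * n)))
}

#' Two-step landmark registration: coarse 3-marker fit, then fine fit
#'
#' Mirrors the acquisition workflow: a rough registration with three markers
#' selects the region of interest, then a fine registration with >= 15
#' landmarks refines it. If `fine_in_coarse_frame = TRUE` the fine source
#' landmarks are taken as already mapped by the coarse transform (the fine
#' step then composes on top of it); otherwise they are raw stained-frame
#' coordinates and the coarse fit only serves as the initial bracket, the
#' composition being algebraically identical to a single-step fine fit.
#'
#' @param coarse_src,coarse_dst 3-point `landmark_set`s.
#' @param fine_src,fine_dst `landmark_set`s with >= 15 points.
#' @param fine_in_coarse_frame flag, see above.
#' @return a `rigid_transform` mapping the raw source frame to `dst`.
#' @export
two_step_register <- function(coarse_src, coarse_dst, fine_src, fine_dst,
                              fine_in_coarse_frame = FALSE) {
  if (nrow(fine_src$points) < 15)
    warning("fewer than 15 fine landmarks; fine registration may be weak")
  coarse <- fit_rigid(coarse_src, coarse_dst)$transform
  if (fine_in_coarse_frame) {
    fine <- fit_rigid(fine_src, fine_dst)$transform
    compose_rigid(fine, coarse)
  } else {
    mapped <- landmark_set(apply_rigid(coarse, fine_src$points),
                           fine_src$ids, frame = "coarse_registered")
    fine <- fit_rigid(mapped, fine_dst)$transform
    compose_rigid(fine, coarse)
  }
}

#' Resample a voxel image through a rigid transform (linear interpolation)
#'
#' Pull-back trilinear resampling onto a target grid: the output voxel at
#' physical position `y` takes the source intensity at `T^{-1}(y)`, so an
#' image of a bone in stained-scan space lands in rest-position space when
#' `T` maps stained coordinates to rest coordinates. Out-of-field voxels get
#' `fill` (default: the source intensity mode, a robust background value).
#'
#' @param img source `voxel_image`.
#' @param T a `rigid_transform` (source frame -> target frame).
#' @param target a `voxel_image` or `label_mask` defining the output grid
#'   (default: the source grid).
#' @param fill background fill; `NULL` picks the source histogram mode.
#' @export
resample <- function(img, T, target = img, fill = NULL) {
  stopifnot(inherits(img, "voxel_image"), inherits(T, "rigid_transform"))
  if (is.null(fill)) {
    v <- as.numeric(img$values)
    brk <- 64L
    rng <- range(v)
    if (diff(rng) == 0) fill <- rng[1] else {
      b <- seq(rng[1], rng[2], length.out = brk + 1L)
      h <- tabulate(findInterval(v, b, rightmost.closed = TRUE), brk)
      fill <- (b[which.max(h)] + b[which.max(h) + 1L]) / 2
    }
  }
  Ti <- invert_rigid(T)
  out <- .resample_trilinear(
    as.numeric(img$values), dim(img$values),
    rep(img$spacing, 3), img$origin,
    dim(target$values), rep(target$spacing, 3), target$origin,
    Ti$R, Ti$t, fill
  )
  voxel_image(array(out, dim(target$values)), target$spacing, target$origin)
}

#' Landmark CSV and transform JSON serialisation
#'
#' Landmarks: CSV with columns `id, x, y, z` (mm). Transforms: 4x4
#' homogeneous matrix as JSON.
#' @param lm a `landmark_set`; `path` a file path.
#' @export
write_landmarks <- function(lm, path) {
  utils::write.csv(data.frame(id = lm$ids, x = lm$points[, 1],
                              y = lm$points[, 2], z = lm$points[, 3]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @param frame frame tag for the loaded set.
#' @export
read_landmarks <- function(path, frame = "rest") {
  d <- utils::read.csv(path)
  landmark_set(as.matrix(d[, c("x", "y", "z")]), ids = d$id, frame = frame)
}

#' @rdname write_landmarks
#' @param T a `rigid_transform`.
#' @export
write_transform <- function(T, path) {
  H <- rbind(cbind(T$R, T$t), c(0, 0, 0, 1))
  jsonlite::write_json(list(matrix = H), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_transform <- function(path) {
  H <- jsonlite::fromJSON(path)$matrix
  rigid_transform(H[1:3, 1:3], H[1:3, 4])
}

#' Axis-angle rotation matrix helper
#' @param axis length-3 vector; @param angle_deg rotation angle in degrees.
#' @export
rotation_about <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
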