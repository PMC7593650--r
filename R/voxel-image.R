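#' Voxel image: a 3D scalar grid with physical spacing and origin
#'
#' The carrier of every imaging step of the pipeline. `values` is a numeric
#' 3D array in column-major (x, y, z) order; `spacing` is the isotropic voxel
#' size in millimetres; `origin` is the physical coordinate (mm) of the centre
#' of voxel `[1, 1, 1]`. The physical coordinate of voxel `(i, j, k)` (1-based
#' array index) is `origin + spacing * (index - 1)`; the superior direction is
#' `+z`.
#'
#' @param values numeric 3D array.
#' @param spacing voxel edge length in mm (scalar, isotropic).
#' @param origin length-3 numeric, mm.
#' @return An object of class `voxel_image`.
#' @export
voxel_image <- function(values, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("spacing must be a single positive length (mm)")
  if (!all(is.finite(values))) stop("voxel values must be finite")
  structure(
    list(values = values, spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = "voxel_image"
  )
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_image> %d x %d x %d voxels, spacing %.4g mm (%.4g um)\n",
              d[1], d[2], d[3], x$spacing, x$spacing * 1000))
  cat(sprintf("  origin (mm): %.4g %.4g %.4g; intensity range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.voxel_image <- function(x) dim(x$values)

#' Label mask: a boolean volume sharing a voxel_image grid
#'
#' @param values logical 3D array.
#' @param spacing,origin grid geometry, as in [voxel_image()].
#' @param tissue tissue name, one of the recognised tissue labels (or any
#'   string for scratch masks).
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(values, spacing, origin = c(0, 0, 0), tissue = "unspecified") {
  stopifnot(is.array(values), length(dim(values)) == 3)
  storage.mode(values) <- "logical"
  structure(
    list(values = values, spacing = as.numeric(spacing),
         origin = as.numeric(origin), tissue = tissue),
    class = "label_mask"
  )
}

#' Recognised tissue labels
#' @export
TISSUES <- c("femur_bone", "tibia_bone", "femur_cartilage", "tibia_cartilage",
             "calcified_meniscus", "soft_meniscus")

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<label_mask> '%s' %d x %d x %d voxels, %d set (%.3g mm^3)\n",
              x$tissue, d[1], d[2], d[3], sum(x$values),
              sum(x$values) * x$spacing^3))
  invisible(x)
}

#' @export
dim.label_mask <- function(x) dim(x$values)

#' Physical volume of a mask in mm^3
#' @param m a `label_mask`.
#' @export
mask_volume <- function(m) sum(m$values) * m$spacing^3

same_grid <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$spacing - b$spacing) < tol &&
    all(abs(a$origin - b$origin) < tol)
}

grid_coords <- function(img) {
  d <- dim(img$values)
  list(x = img$origin[1] + img$spacing * (seq_len(d[1]) - 1),
       y = img$origin[2] + img$spacing * (seq_len(d[2]) - 1),
       z = img$origin[3] + img$spacing * (seq_len(d[3]) - 1))
}

#' Gaussian smoothing of a voxel image
#'
#' Separable discrete Gaussian filtering with half-sample reflective
#' boundaries (which conserves the image sum, hence the mean, exactly for the
#' symmetric normalised kernel). The default `sigma_voxels = 1` is the value
#' used to condition micro-CT volumes before single-level thresholding.
#'
#' @param img a `voxel_image`.
#' @param sigma_voxels Gaussian standard deviation in voxels (> 0).
#' @return Smoothed `voxel_image` on the same grid.
#' @export
gaussian_smooth <- function(img, sigma_voxels = 1) {
  stopifnot(inherits(img, "voxel_image"))
  if (!is.finite(sigma_voxels) || sigma_voxels <= 0)
    stop("sigma_voxels must be a positive number")
  if (!all(is.finite(img$values))) stop("image contains non-finite values")
  k <- gaussian_kernel_1d(sigma_voxels)
  d <- dim(img$values)
  v <- as.numeric(img$values)
  for (axis in 1:3) v <- .conv_axis(v, d, k, axis)
  voxel_image(array(v, d), img$spacing, img$origin)
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Single-level threshold segmentation
#'
#' `mask = values >= level`, the standard single-level threshold used after
#' Gaussian smoothing to extract mineralised tissue from a micro-CT volume.
#' An empty result raises a warning, not an error.
#'
#' @param img a `voxel_image`.
#' @param level threshold intensity; must lie within the image intensity range.
#' @param tissue tissue label for the result.
#' @export
threshold_segment <- function(img, level, tissue = "unspecified") {
  stopifnot(inherits(img, "voxel_image"))
  rng <- range(img$values)
  if (level < rng[1] || level > rng[2])
    stop(sprintf("threshold %g outside image intensity range [%g, %g]",
                 level, rng[1], rng[2]))
  m <- img$values >= level
  if (!any(m)) warning("threshold produced an empty mask")
  label_mask(m, img$spacing, img$origin, tissue)
}

#' Suggest a threshold between the two dominant intensity modes
#'
#' Otsu's criterion on a 256-bin histogram: the returned level maximises the
#' between-class variance of the two-class split, i.e. it falls in the valley
#' between the two dominant modes. For an effectively unimodal histogram
#' (degenerate split) a structured error suggests choosing a level manually.
#'
#' @param img a `voxel_image`.
#' @param nbins number of histogram bins.
#' @return A single intensity level.
#' @export
suggest_threshold <- function(img, nbins = 256L) {
  stopifnot(inherits(img, "voxel_image"))
  v <- as.numeric(img$values)
  rng <- range(v)
  if (diff(rng) <= 0)
    stop("histogram is unimodal (constant image); choose a threshold manually")
  brk <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(v, brk, rightmost.closed = TRUE), nbins)
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  w <- h / sum(h)
  mu <- cumsum(w * mids)
  omega <- cumsum(w)
  mt <- mu[nbins]
  # between-class variance for every candidate split
  denom <- omega * (1 - omega)
  bcv <- ifelse(denom > 0, (mt * omega - mu)^2 / denom, 0)
  # the maximiser is a plateau for well-separated modes: take its midpoint
  plateau <- which(bcv >= max(bcv) * (1 - 1e-9))
  kbest <- plateau[ceiling(length(plateau) / 2)]
  # degenerate split: one class nearly empty means no real second mode
  if (min(omega[kbest], 1 - omega[kbest]) < 1e-4 || max(bcv) <= 0)
    stop("histogram looks unimodal; choose a threshold manually")
  (brk[kbest] + brk[kbest + 1L]) / 2
}

#' Voxelwise Boolean mask algebra
#'
#' Set semantics on masks sharing one grid: `subtract`, `union`, `intersect`.
#' Used to cut registered bone masks out of stained-scan cartilage masks and
#' to delete wrap intersections.
#'
#' @param a,b `label_mask`s on the same grid.
#' @param op one of `"subtract"`, `"union"`, `"intersect"`.
#' @param tissue tissue label of the result (default: `a$tissue`).
#' @export
mask_boolean <- function(a, b, op = c("subtract", "union", "intersect"),
                         tissue = a$tissue) {
  op <- match.arg(op)
  stopifnot(inherits(a, "label_mask"), inherits(b, "label_mask"))
  if (!same_grid(a, b)) stop("masks are on different grids")
  v <- switch(op,
    subtract = a$values & !b$values,
    union = a$values | b$values,
    intersect = a$values & b$values
  )
  label_mask(v, a$spacing, a$origin, tissue)
}

#' Boundary-regularising mask smoothing
#'
#' Implemented as Gaussian blur of the 0/1 indicator with `sigma =
#' radius_voxels / 2`, re-thresholded at 0.5. This keeps the mask volume
#' within a few percent while rounding staircase boundaries; the 2-voxel
#' default radius matches the smoothing applied to the manually contoured
#' cartilage masks before Boolean subtraction of the bone.
#'
#' @param m a `label_mask`.
#' @param radius_voxels smoothing radius in voxels (>= 1).
#' @export
mask_smooth <- function(m, radius_voxels = 2) {
  stopifnot(inherits(m, "label_mask"))
  if (radius_voxels < 1) stop("radius_voxels must be >= 1")
  img <- voxel_image(array(as.numeric(m$values), dim(m$values)),
                     m$spacing, m$origin)
  sm <- gaussian_smooth(img, sigma_voxels = radius_voxels / 2)
  out <- sm$values >= 0.5
  if (!any(out)) stop("mask_smooth emptied the mask; reduce the radius")
  label_mask(out, m$spacing, m$origin, m$tissue)
}

#' Integer-voxel translation of a mask
#'
#' Pure shift in voxel units; the mask is padded as needed so the shifted
#' volume is preserved exactly. Used to move the femur superiorly (for
#' example 20 voxels = 87 um at 4.35 um spacing) before contact
#' initialisation.
#'
#' @param m a `label_mask`.
#' @param offset_voxels integer 3-vector, voxels.
#' @export
translate_mask <- function(m, offset_voxels) {
  stopifnot(inherits(m, "label_mask"), length(offset_voxels) == 3)
  off <- as.integer(round(offset_voxels))
  d <- dim(m$values)
  # pad so nothing falls off either side
  padlo <- pmax(0L, -off)
  padhi <- pmax(0L, off)
  nd <- d + padlo + padhi
  out <- array(FALSE, nd)
  idx <- which(m$values, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    shifted <- sweep(idx, 2, padlo + off, "+")
    out[shifted] <- TRUE
  }
  # origin moves so that unpadded voxels keep their physical position
  label_mask(out, m$spacing, m$origin - padlo * m$spacing, m$tissue)
}

#' Squared Euclidean distance transform (mm^2)
#'
#' Distance from every voxel centre to the nearest voxel centre inside the
#' mask. Exact (Felzenszwalb-Huttenlocher separable algorithm).
#'
#' @param m a `label_mask`.
#' @return numeric 3D array of squared distances in mm^2.
#' @export
distance_sq <- function(m) {
  d <- dim(m$values)
  sp <- rep(m$spacing, 3)
  array(.edt_sq(as.logical(m$values), d, sp), d)
}

dilate_mask <- function(m, radius_mm) {
  if (radius_mm <= 0) return(m)
  d2 <- distance_sq(m)
  label_mask(d2 <= radius_mm^2 + 1e-12, m$spacing, m$origin, m$tissue)
}

erode_mask <- function(m, radius_mm) {
  if (radius_mm <= 0) return(m)
  inv <- label_mask(!m$values, m$spacing, m$origin, m$tissue)
  d2 <- distance_sq(inv)
  label_mask(m$values & (d2 > radius_mm^2 + 1e-12), m$spacing, m$origin, m$tissue)
}

close_mask <- function(m, radius_mm) erode_mask(dilate_mask(m, radius_mm), radius_mm)

open_mask <- function(m, radius_mm) dilate_mask(erode_mask(m, radius_mm), radius_mm)

#' Fill the soft meniscus between calcified menisci and cartilage surfaces
#'
#' Morphological gap wrap: the union of the calcified meniscus and the two
#' cartilage masks is closed with a ball of radius `max_gap / 2`; the filled
#' voxels (closing minus the union) are then restricted to the neighbourhood
#' of the calcified meniscus (within `max_gap`) and all intersections with
#' the input masks are deleted, so the result is disjoint from every input.
#' If the gap is wider than `max_gap` everywhere the result is empty, with a
#' warning.
#'
#' @param calcified,femur_cart,tibia_cart `label_mask`s on one grid.
#' @param max_gap largest bridged gap, mm.
#' @export
wrap_meniscus <- function(calcified, femur_cart, tibia_cart, max_gap) {
  stopifnot(inherits(calcified, "label_mask"))
  if (!any(calcified$values)) stop("calcified meniscus mask is empty")
  if (!same_grid(calcified, femur_cart) || !same_grid(calcified, tibia_cart))
    stop("wrap_meniscus inputs must share one grid")
  if (max_gap <= 0) {
    warning("max_gap <= 0: soft meniscus is empty")
    return(label_mask(array(FALSE, dim(calcified$values)), calcified$spacing,
                      calcified$origin, "soft_meniscus"))
  }
  u <- mask_boolean(mask_boolean(calcified, femur_cart, "union"),
                    tibia_cart, "union")
  closed <- close_mask(u, max_gap / 2)
  fill <- closed$values & !u$values
  # keep only gap fill near the calcified meniscus
  near <- distance_sq(calcified) <= max_gap^2 + 1e-12
  out <- fill & near
  if (!any(out))
    warning("gap wider than max_gap everywhere: soft meniscus is empty")
  label_mask(out, calcified$spacing, calcified$origin, "soft_meniscus")
}

#' Generic homogeneous cartilage layers by constant-distance offset
#'
#' Builds cartilage as an offset shell of each bone's articular surface using
#' the Euclidean distance transform, with the layer thickness chosen from the
#' minimal bone-to-bone gap so that the opposing layers just touch:
#' one layer of thickness `t = g/2` on each bone fills a gap `g`.
#'
#' * `one_thickness`: a single thickness for both condyles, `t = g_min/2`
#'   where `g_min` is the minimal gap over the whole joint (in practice the
#'   lateral compartment); the compartment with the wider gap may then be
#'   left without contact.
#' * `two_thickness`: a thickness per condyle, `t_side = g_side/2`, so both
#'   compartments' layers just touch.
#'
#' The shells are restricted to the articular corridor: voxels whose summed
#' distance to the two bones is within `corridor` of the local minimal gap,
#' which confines the layers to the opposing condylar surfaces.
#'
#' @param bone_femur,bone_tibia bone `label_mask`s on one grid (not touching).
#' @param mode `"one_thickness"` or `"two_thickness"`.
#' @param split_x x-coordinate (mm) of the sagittal plane separating the
#'   lateral (smaller x) and medial compartments; default: midpoint of the
#'   femoral mask x-extent.
#' @param corridor articular corridor width, mm (default 0.25).
#' @return list with `femur_cart`, `tibia_cart` (`label_mask`s) and
#'   `thickness` (named per side, mm).
#' @export
build_generic_cartilage <- function(bone_femur, bone_tibia,
                                    mode = c("one_thickness", "two_thickness"),
                                    split_x = NULL, corridor = 0.25) {
  mode <- match.arg(mode)
  stopifnot(inherits(bone_femur, "label_mask"), inherits(bone_tibia, "label_mask"))
  if (!same_grid(bone_femur, bone_tibia)) stop("bone masks on different grids")
  if (any(bone_femur$values & bone_tibia$values)) stop("bone masks touch/overlap")

  dF <- sqrt(distance_sq(bone_femur))
  dT <- sqrt(distance_sq(bone_tibia))
  gap <- dF + dT                       # ~ bone-to-bone clearance through a voxel
  d <- dim(bone_femur$values)
  xs <- grid_coords(bone_femur)$x
  if (is.null(split_x)) {
    fx <- which(apply(bone_femur$values, 1, any))
    if (length(fx) == 0) stop("femur mask empty")
    split_x <- (xs[min(fx)] + xs[max(fx)]) / 2
  }
  lat <- array(rep(xs < split_x, times = d[2] * d[3]), d)
  free <- !(bone_femur$values | bone_tibia$values)

  gap_side <- function(side) {
    g <- gap[free & side]
    if (length(g) == 0) stop("condyle gap not measurable: no opposing surfaces")
    # distances are centre-to-centre, so across a surface-to-surface gap of
    # n empty voxels min(dF+dT) = (n+1)*spacing: remove the one-voxel bias
    max(min(g) - bone_femur$spacing, bone_femur$spacing)
  }
  g_lat <- gap_side(lat)
  g_med <- gap_side(!lat)

  if (mode == "one_thickness") {
    t_lat <- t_med <- min(g_lat, g_med) / 2
  } else {
    t_lat <- g_lat / 2
    t_med <- g_med / 2
  }
  tmap <- array(ifelse(lat, t_lat, t_med), d)
  gmin <- array(ifelse(lat, g_lat, g_med), d)
  corridor_ok <- gap <= gmin + corridor

  fc <- free & corridor_ok & (dF <= tmap + 1e-12) & (dF < dT)
  tc <- free & corridor_ok & (dT <= tmap + 1e-12) & (dT <= dF)
  list(
    femur_cart = label_mask(fc, bone_femur$spacing, bone_femur$origin, "femur_cartilage"),
    tibia_cart = label_mask(tc, bone_femur$spacing, bone_femur$origin, "tibia_cartilage"),
    thickness = c(lateral = t_lat, medial = t_med)
  )
}

#' Dice overlap of two masks
#' @param a,b `label_mask`s on one grid.
#' @export
mask_dice <- function(a, b) {
  stopifnot(same_grid(a, b))
  2 * sum(a$values & b$values) / (sum(a$values) + sum(b$values))
}

#' Median thickness of a layer mask (mm), via the distance transform
#'
#' For voxels uniformly distributed through a layer of thickness `t`, the
#' depth `D` (distance to the complement, corrected by the half-voxel
#' centre offset) is uniform on `[0, t/2]`, so `t = 4 * median(D - h/2)`.
#' Exact for flat slabs; mildly underestimates strongly curved shells.
#' @param m a `label_mask` holding a thin layer.
#' @export
mask_median_thickness <- function(m) {
  inv <- label_mask(!m$values, m$spacing, m$origin)
  d2 <- distance_sq(inv)
  depth <- sqrt(d2[m$values])
  4 * (stats::median(depth) - m$spacing / 2)
}

#' Read / write volumes and masks as NIfTI
#'
#' Volumes are exchanged as NIfTI-1 with isotropic pixdim equal to the voxel
#' spacing (mm). Masks are stored as uint8 label volumes.
#' @param img a `voxel_image` or `label_mask`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(img, path) {
  v <- img$values
  if (is.logical(v)) storage.mode(v) <- "integer"
  nii <- RNifti::asNifti(v)
  RNifti::pixdim(nii) <- rep(img$spacing, 3)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname write_volume
#' @param spacing,origin grid geometry override when the header is silent.
#' @export
read_volume <- function(path, spacing = NULL, origin = c(0, 0, 0)) {
  nii <- RNifti::readNifti(path)
  sp <- if (is.null(spacing)) RNifti::pixdim(nii)[1] else spacing
  voxel_image(array(as.numeric(nii), dim(nii)[1:3]), sp, origin)
}
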