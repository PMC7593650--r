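#' Parametric mouse-knee phantom specification
#'
#' Defines a knee-like synthetic specimen: a femur made of two spherical
#' condyles bridged by a bar and a short shaft, above a tibial plateau with
#' shallow convex crowns under the condyles, with cartilage layers on both
#' articular surfaces and calcified meniscal arcs around each condyle.
#' Superior is `+z`; the lateral condyle sits at smaller `x`.
#'
#' Two acquisitions are emulated: a *rest-position* scan in which bone and
#' the calcified menisci are bright and cartilage is invisible, and two
#' *stained* scans of the separated femur and tibia, rigidly displaced by
#' known transforms, in which the cartilage shells appear at intermediate
#' intensity.
#'
#' The default geometry is a desk-scale murine stylisation: condyle radii
#' around half a millimetre, cartilage roughly 0.1 mm thick (thicker
#' medially, `cartilage_thickness_ratio_medial`), and the lateral cartilage
#' layers touching at rest while the medial compartment keeps a small
#' clearance (`medial_clearance`). The voxel spacing defaults to 25 um;
#' 4.35 um reproduces the micro-CT acquisition resolution but is only
#' practical for small crops.
#'
#' @param condyle_radius_lateral,condyle_radius_medial condyle bone radii, mm.
#' @param condyle_separation centre-to-centre condyle distance, mm.
#' @param cartilage_thickness_femur,cartilage_thickness_tibia lateral-side
#'   cartilage thicknesses, mm.
#' @param cartilage_thickness_ratio_medial medial/lateral thickness ratio.
#' @param medial_clearance rest-position cartilage-to-cartilage clearance of
#'   the medial compartment, mm (lateral clearance is 0: layers touch).
#' @param plateau_extent tibial plateau length along x, mm.
#' @param meniscus_arc_deg,meniscus_tube_radius calcified meniscal arc span
#'   (degrees) and cross-section radius (mm).
#' @param voxel_spacing_um isotropic voxel size, um.
#' @param intensity_bone,intensity_cartilage_stained,intensity_background
#'   mean intensities (arbitrary units).
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param transform_femur,transform_tibia `rigid_transform`s mapping each
#'   stained-scan frame into the rest-position frame.
#' @param seed integer seed controlling the noise.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(condyle_radius_lateral = 0.50,
                         condyle_radius_medial = 0.42,
                         condyle_separation = 1.05,
                         cartilage_thickness_femur = 0.10,
                         cartilage_thickness_tibia = 0.10,
                         cartilage_thickness_ratio_medial = 1.5,
                         medial_clearance = 0.004,
                         plateau_extent = 1.90,
                         meniscus_arc_deg = 240,
                         meniscus_tube_radius = 0.055,
                         voxel_spacing_um = 25,
                         intensity_bone = 200,
                         intensity_cartilage_stained = 90,
                         intensity_background = 20,
                         noise_sd = 5,
                         transform_femur = rigid_transform(
                           rotation_about(c(0, 1, 0.3), 20), c(0.40, -0.30, 0.90)),
                         transform_tibia = rigid_transform(
                           rotation_about(c(1, 0.2, 0), -15), c(-0.30, 0.25, -0.60)),
                         seed = 1L) {
  spec <- list(
    condyle_radius_lateral = condyle_radius_lateral,
    condyle_radius_medial = condyle_radius_medial,
    condyle_separation = condyle_separation,
    cartilage_thickness_femur = cartilage_thickness_femur,
    cartilage_thickness_tibia = cartilage_thickness_tibia,
    cartilage_thickness_ratio_medial = cartilage_thickness_ratio_medial,
    medial_clearance = medial_clearance,
    plateau_extent = plateau_extent,
    meniscus_arc_deg = meniscus_arc_deg,
    meniscus_tube_radius = meniscus_tube_radius,
    voxel_spacing_um = voxel_spacing_um,
    intensity_bone = intensity_bone,
    intensity_cartilage_stained = intensity_cartilage_stained,
    intensity_background = intensity_background,
    noise_sd = noise_sd,
    transform_femur = transform_femur,
    transform_tibia = transform_tibia,
    seed = as.integer(seed)
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  lens <- c(spec$condyle_radius_lateral, spec$condyle_radius_medial,
            spec$condyle_separation, spec$plateau_extent,
            spec$meniscus_tube_radius, spec$voxel_spacing_um)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all phantom lengths must be positive")
  if (spec$cartilage_thickness_femur < 0 || spec$cartilage_thickness_tibia < 0)
    stop("cartilage thicknesses must be >= 0")
  tmax <- max(spec$cartilage_thickness_femur, spec$cartilage_thickness_tibia) *
    max(1, spec$cartilage_thickness_ratio_medial)
  if (tmax >= min(spec$condyle_radius_lateral, spec$condyle_radius_medial))
    stop("cartilage thickness must be smaller than the condyle radii")
  with(spec, {
    if (!(intensity_bone > intensity_cartilage_stained &&
          intensity_cartilage_stained > intensity_background))
      stop("intensities must satisfy bone > stained cartilage > background")
  })
  invisible(spec)
}

#' Derived phantom geometry (placement of every solid)
#'
#' All heights, centres and extents derived from a [phantom_spec()]; exposed
#' so tests can reason about the geometry analytically.
#' @param spec a `phantom_spec`.
#' @export
phantom_geometry <- function(spec) {
  R_l <- spec$condyle_radius_lateral
  R_m <- spec$condyle_radius_medial
  rmed <- spec$cartilage_thickness_ratio_medial
  tf_l <- spec$cartilage_thickness_femur
  tf_m <- tf_l * rmed
  tt_l <- spec$cartilage_thickness_tibia
  tt_m <- tt_l * rmed

  x_lat <- 0.65
  x_med <- x_lat + spec$condyle_separation
  y0 <- 0.55
  z_slab_bot <- 0.10
  z_slab_top <- 0.30
  h_crown <- 0.05
  crown_R <- c(lateral = 1.1, medial = 1.0)
  z_apex <- z_slab_top + h_crown
  # flat cartilage tables on top of the crowns
  z_cart_top <- c(lateral = z_apex + tt_l, medial = z_apex + tt_m)
  # femoral outer (cartilage) surface bottoms: lateral touches, medial clears
  z_fem_out_bot <- c(lateral = z_cart_top[["lateral"]],
                     medial = z_cart_top[["medial"]] + spec$medial_clearance)
  zc <- c(lateral = z_fem_out_bot[["lateral"]] + R_l + tf_l,
          medial = z_fem_out_bot[["medial"]] + R_m + tf_m)
  sphere_cut <- 0.15                     # keep sphere below zc - cut? (cap)
  cap_top <- zc - sphere_cut
  bridge <- list(x = c(x_lat + 0.05, x_med - 0.05),
                 y = c(y0 - 0.20, y0 + 0.20),
                 z = c(min(cap_top), max(cap_top) + 0.20))
  shaft <- list(center = c((x_lat + x_med) / 2, y0),
                radius = 0.22,
                z = c(bridge$z[2], bridge$z[2] + 0.20))
  plat_x <- (x_lat + x_med) / 2 + c(-0.5, 0.5) * spec$plateau_extent
  plat_y <- c(y0 - 0.36, y0 + 0.36)
  cap_r_tib <- c(lateral = 0.42, medial = 0.38)
  men_ring <- c(lateral = 0.48, medial = 0.44)
  men_z <- 0.42
  dom <- list(x = c(0, x_med + R_m + 0.23), y = c(0, 2 * y0),
              z = c(0, shaft$z[2] + 0.10))
  list(R = c(lateral = R_l, medial = R_m),
       t_fem = c(lateral = tf_l, medial = tf_m),
       t_tib = c(lateral = tt_l, medial = tt_m),
       xc = c(lateral = x_lat, medial = x_med), y0 = y0,
       x_mid = (x_lat + x_med) / 2,
       z_slab = c(z_slab_bot, z_slab_top), h_crown = h_crown,
       crown_R = crown_R, z_apex = z_apex,
       z_cart_top = z_cart_top, z_fem_out_bot = z_fem_out_bot,
       zc = zc, cap_top = cap_top, bridge = bridge, shaft = shaft,
       plat_x = plat_x, plat_y = plat_y, cap_r_tib = cap_r_tib,
       men_ring = men_ring, men_z = men_z,
       men_tube = spec$meniscus_tube_radius,
       men_arc = spec$meniscus_arc_deg,
       domain = dom)
}

# Evaluate tissue membership at physical points (vectorised over x, y, z).
# Returns integer codes: 0 none, 1 femur_bone, 2 tibia_bone, 3 femur_cart,
# 4 tibia_cart, 5 calcified_meniscus. Solids are constructed disjoint.
phantom_membership <- function(geom, x, y, z) {
  out <- integer(length(x))
  insph <- function(cx, cy, cz, R) (x - cx)^2 + (y - cy)^2 + (z - cz)^2 <= R^2

  # femur bone: two sphere caps + bridge + shaft
  fb <- (insph(geom$xc[1], geom$y0, geom$zc[1], geom$R[1]) & z <= geom$cap_top[1]) |
        (insph(geom$xc[2], geom$y0, geom$zc[2], geom$R[2]) & z <= geom$cap_top[2]) |
        (x >= geom$bridge$x[1] & x <= geom$bridge$x[2] &
         y >= geom$bridge$y[1] & y <= geom$bridge$y[2] &
         z >= geom$bridge$z[1] & z <= geom$bridge$z[2]) |
        ((x - geom$shaft$center[1])^2 + (y - geom$shaft$center[2])^2 <=
           geom$shaft$radius^2 & z > geom$shaft$z[1] & z <= geom$shaft$z[2])

  # tibia bone: slab + convex crowns
  crown <- rep(FALSE, length(x))
  for (s in 1:2) {
    rho <- geom$crown_R[s]
    crown <- crown | (insph(geom$xc[s], geom$y0, geom$z_apex - rho, rho) &
                        z > geom$z_slab[2])
  }
  tb <- (x >= geom$plat_x[1] & x <= geom$plat_x[2] &
         y >= geom$plat_y[1] & y <= geom$plat_y[2] &
         z >= geom$z_slab[1] & z <= geom$z_slab[2]) | crown

  # femoral cartilage: spherical shells on the inferior caps
  fc <- rep(FALSE, length(x))
  for (s in 1:2) {
    d2 <- (x - geom$xc[s])^2 + (y - geom$y0)^2 + (z - geom$zc[s])^2
    Ro <- geom$R[s] + geom$t_fem[s]
    fc <- fc | (d2 > geom$R[s]^2 & d2 <= Ro^2 & z <= geom$zc[s] - 0.6 * geom$R[s])
  }

  # tibial cartilage: from the bone surface up to a flat table, per condyle
  tc <- rep(FALSE, length(x))
  for (s in 1:2) {
    r2 <- (x - geom$xc[s])^2 + (y - geom$y0)^2
    tc <- tc | (r2 <= geom$cap_r_tib[s]^2 & z > geom$z_slab[2] &
                  z < geom$z_cart_top[s])
  }
  tc <- tc & !crown & !fc

  # calcified meniscal arcs, opening towards the intercondylar notch
  cm <- rep(FALSE, length(x))
  half_open <- (360 - geom$men_arc) / 2 * pi / 180
  for (s in 1:2) {
    r <- sqrt((x - geom$xc[s])^2 + (y - geom$y0)^2)
    th <- atan2(y - geom$y0, x - geom$xc[s])
    notch_dir <- if (s == 1) 0 else pi     # towards the other condyle
    dth <- abs(atan2(sin(th - notch_dir), cos(th - notch_dir)))
    cm <- cm | ((r - geom$men_ring[s])^2 + (z - geom$men_z)^2 <=
                  geom$men_tube^2 & dth >= half_open)
  }

  out[cm] <- 5L
  out[tc] <- 4L
  out[fc] <- 3L
  out[tb] <- 2L
  out[fb] <- 1L
  overlap <- (fb & tb) | (fb & fc) | (fb & tc) | (tb & tc) | (tb & fc) |
    (fc & tc) | (cm & (fb | tb | fc | tc))
  attr(out, "n_overlap") <- sum(overlap)
  out
}

#' Generate the phantom scans and ground truth
#'
#' Produces the rest-position scan (bone and calcified menisci bright,
#' cartilage invisible), the two stained separated scans (each bone plus its
#' cartilage shell, rigidly displaced by the spec's transforms), and the
#' ground truth: per-tissue masks on the rest grid, medial/lateral condyle
#' labels for every cartilage voxel, exact landmark pairs (3 coarse + 15
#' fine per bone) and the generating transforms. Same spec and seed give
#' bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return list with `rest_scan`, `stained_femur_scan`, `stained_tibia_scan`
#'   (`voxel_image`s) and `truth`.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  geom <- phantom_geometry(spec)
  h <- spec$voxel_spacing_um / 1000

  # grid origin deliberately offset by a sub-voxel fraction so that the
  # analytic solids never align degenerately with the voxel lattice (a real
  # scanner lattice never aligns with the anatomy)
  grid_for <- function(lo, hi) {
    n <- pmax(2L, as.integer(ceiling((hi - lo) / h)) + 2L)
    list(n = n, origin = lo - 0.37 * h)
  }
  dom <- geom$domain
  g <- grid_for(c(dom$x[1], dom$y[1], dom$z[1]), c(dom$x[2], dom$y[2], dom$z[2]))
  d <- g$n
  xs <- g$origin[1] + h * (seq_len(d[1]) - 1)
  ys <- g$origin[2] + h * (seq_len(d[2]) - 1)
  zs <- g$origin[3] + h * (seq_len(d[3]) - 1)
  X <- rep(xs, times = d[2] * d[3])
  Y <- rep(rep(ys, each = d[1]), times = d[3])
  Z <- rep(zs, each = d[1] * d[2])

  lab <- phantom_membership(geom, X, Y, Z)
  if (attr(lab, "n_overlap") > 0)
    stop(sprintf("phantom solids overlap at this resolution (%d voxels); adjust the spec",
                 attr(lab, "n_overlap")))
  lab_arr <- array(lab, d)

  mk <- function(code, tissue) label_mask(lab_arr == code, h, g$origin, tissue)
  masks <- list(
    femur_bone = mk(1L, "femur_bone"),
    tibia_bone = mk(2L, "tibia_bone"),
    femur_cartilage = mk(3L, "femur_cartilage"),
    tibia_cartilage = mk(4L, "tibia_cartilage"),
    calcified_meniscus = mk(5L, "calcified_meniscus")
  )
  condyle <- array(0L, d)
  cart <- lab_arr == 3L | lab_arr == 4L
  condyle[cart] <- ifelse(X[cart] < geom$x_mid, 1L, 2L)  # 1 lateral, 2 medial

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  intensity_from <- function(code_vec) {
    v <- rep(spec$intensity_background, length(code_vec))
    v[code_vec %in% c(1L, 2L, 5L)] <- spec$intensity_bone
    v
  }
  rest_vals <- intensity_from(lab)
  if (spec$noise_sd > 0)
    rest_vals <- rest_vals + stats::rnorm(length(rest_vals), 0, spec$noise_sd)
  rest_scan <- voxel_image(array(rest_vals, d), h, g$origin)

  stained_scan <- function(T, bone_code, cart_code) {
    # stained grid: bounding box of the transformed bone + margin
    bone_idx <- which(lab == bone_code | lab == cart_code)
    pts <- cbind(X[bone_idx], Y[bone_idx], Z[bone_idx])
    Ti <- invert_rigid(T)                # rest -> stained
    sp <- apply_rigid(Ti, pts)
    lo <- apply(sp, 2, min) - 0.15
    hi <- apply(sp, 2, max) + 0.15
    gg <- grid_for(lo, hi)
    dd <- gg$n
    sx <- gg$origin[1] + h * (seq_len(dd[1]) - 1)
    sy <- gg$origin[2] + h * (seq_len(dd[2]) - 1)
    sz <- gg$origin[3] + h * (seq_len(dd[3]) - 1)
    SX <- rep(sx, times = dd[2] * dd[3])
    SY <- rep(rep(sy, each = dd[1]), times = dd[3])
    SZ <- rep(sz, each = dd[1] * dd[2])
    rp <- apply_rigid(T, cbind(SX, SY, SZ))  # stained voxel -> rest coords
    sl <- phantom_membership(geom, rp[, 1], rp[, 2], rp[, 3])
    v <- rep(spec$intensity_background, length(sl))
    v[sl == bone_code] <- spec$intensity_bone
    v[sl == cart_code] <- spec$intensity_cartilage_stained
    if (spec$noise_sd > 0) v <- v + stats::rnorm(length(v), 0, spec$noise_sd)
    voxel_image(array(v, dd), h, gg$origin)
  }
  stained_femur <- stained_scan(spec$transform_femur, 1L, 3L)
  stained_tibia <- stained_scan(spec$transform_tibia, 2L, 4L)

  lm <- list(
    femur = phantom_landmarks(masks$femur_bone, spec$transform_femur, "femur"),
    tibia = phantom_landmarks(masks$tibia_bone, spec$transform_tibia, "tibia")
  )

  truth <- list(masks = masks, condyle = condyle, landmarks = lm,
                transforms = list(femur = spec$transform_femur,
                                  tibia = spec$transform_tibia),
                geometry = geom, spec = spec)
  list(rest_scan = rest_scan, stained_femur_scan = stained_femur,
       stained_tibia_scan = stained_tibia, truth = truth)
}

# Deterministic landmark pairs: farthest-point sampling of bone surface
# voxel centres in the rest frame; stained coordinates are the exact
# pre-images under the separation transform (noiseless correspondence).
phantom_landmarks <- function(bone_mask, T, bone, n_fine = 15L, n_coarse = 3L) {
  d2bg <- distance_sq(label_mask(!bone_mask$values, bone_mask$spacing,
                                 bone_mask$origin))
  surf <- bone_mask$values & (d2bg <= bone_mask$spacing^2 * 1.01)
  idx <- which(surf, arr.ind = TRUE)
  pts <- sweep((idx - 1) * bone_mask$spacing, 2, bone_mask$origin, "+")
  # thin out deterministically before farthest-point sampling
  if (nrow(pts) > 4000) pts <- pts[seq(1, nrow(pts), length.out = 4000), ]
  n <- n_fine + n_coarse
  sel <- integer(n)
  sel[1] <- which.max(pts[, 1] + pts[, 2] + pts[, 3])
  dmin <- rowSums(sweep(pts, 2, pts[sel[1], ])^2)
  for (i in 2:n) {
    sel[i] <- which.max(dmin)
    dmin <- pmin(dmin, rowSums(sweep(pts, 2, pts[sel[i], ])^2))
  }
  rest_pts <- pts[sel, , drop = FALSE]
  stained_pts <- apply_rigid(invert_rigid(T), rest_pts)
  ids <- paste0(substr(bone, 1, 1), seq_len(n))
  list(
    coarse_rest = landmark_set(rest_pts[1:n_coarse, ], ids[1:n_coarse], "rest"),
    coarse_stained = landmark_set(stained_pts[1:n_coarse, ], ids[1:n_coarse],
                                  paste0("stained_", bone)),
    fine_rest = landmark_set(rest_pts[(n_coarse + 1):n, ], ids[(n_coarse + 1):n],
                             "rest"),
    fine_stained = landmark_set(stained_pts[(n_coarse + 1):n, ],
                                ids[(n_coarse + 1):n], paste0("stained_", bone))
  )
}
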