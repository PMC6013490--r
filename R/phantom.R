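#' Phantom specification
#'
#' Parameters of the 3D digital head phantom used to emulate paired
#' contrast-enhanced gradient-echo (GRE) and black-blood (BB) acquisitions
#' with known ground truth. The phantom is an ellipsoidal "brain" with a
#' grey-matter shell and white-matter core, three caliber classes of tubular
#' vessels (large midline trunks, medium lateral branches, small cortical
#' branches), spherical blob metastases, additive Gaussian noise, a mild
#' blur on the BB channel and, optionally, residual unsuppressed vessel
#' voxels on BB (imperfect flow suppression) and a bright skull rim.
#'
#' Intensity roles per modality are given as named levels in `[0, 1]`:
#' on GRE both vessels and lesions are bright relative to white matter; on
#' BB vessels sit at the background level, lesions stay bright, and the
#' white/grey-matter contrast is reduced.
#'
#' @param grid_shape Integer length-3 voxel counts per axis.
#' @param voxel_size_mm Isotropic voxel spacing in mm.
#' @param n_lesions Number of spherical metastasis-like lesions.
#' @param lesion_radius_range_mm Min/max lesion radius in mm.
#' @param vessel_counts Integer length-3: number of vessels for caliber
#'   classes 1 (large midline), 2 (medium lateral), 3 (small cortical).
#' @param vessel_radius_mm Numeric length-3 tube radius per class, mm.
#' @param tissue_levels_gre,tissue_levels_bb Named numeric vectors with
#'   entries `background`, `gm`, `wm`, `vessel`, `lesion`, `skull`, all in
#'   `[0, 1]`.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param bb_blur_sigma_vox Gaussian blur (voxels) applied to BB only.
#' @param residual_vessel_fraction Fraction of vessel voxels left at
#'   GRE-level intensity on BB (imperfect suppression); in `[0, 1]`.
#' @param skull_rim Add a bright rim shell outside the brain.
#' @param seed Integer RNG seed; fixed seed gives bit-identical phantoms.
#' @return An object of class `bb_phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 96L),
                         voxel_size_mm = 1,
                         n_lesions = 8L,
                         lesion_radius_range_mm = c(0.8, 6),
                         vessel_counts = c(3L, 4L, 8L),
                         vessel_radius_mm = c(3, 2, 1),
                         tissue_levels_gre = c(background = 0.05, gm = 0.35,
                                               wm = 0.55, vessel = 0.95,
                                               lesion = 0.85, skull = 0.70),
                         tissue_levels_bb = c(background = 0.05, gm = 0.40,
                                              wm = 0.48, vessel = 0.05,
                                              lesion = 0.82, skull = 0.30),
                         noise_sd = 0.02,
                         bb_blur_sigma_vox = 0.4,
                         residual_vessel_fraction = 0.02,
                         skull_rim = FALSE,
                         seed = 1L) {
  roles <- c("background", "gm", "wm", "vessel", "lesion", "skull")
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 16L),
            voxel_size_mm > 0,
            n_lesions >= 0L,
            length(lesion_radius_range_mm) == 2L,
            all(lesion_radius_range_mm > 0),
            diff(lesion_radius_range_mm) >= 0,
            length(vessel_counts) == 3L, all(vessel_counts >= 0L),
            length(vessel_radius_mm) == 3L, all(vessel_radius_mm > 0),
            all(roles %in% names(tissue_levels_gre)),
            all(roles %in% names(tissue_levels_bb)),
            all(tissue_levels_gre >= 0 & tissue_levels_gre <= 1),
            all(tissue_levels_bb >= 0 & tissue_levels_bb <= 1),
            noise_sd >= 0, bb_blur_sigma_vox >= 0,
            residual_vessel_fraction >= 0, residual_vessel_fraction <= 1)
  if (max(lesion_radius_range_mm) / voxel_size_mm >= min(grid_shape) / 2)
    stop("lesion radius exceeds grid extent", call. = FALSE)
  structure(
    list(grid_shape = as.integer(grid_shape), voxel_size_mm = voxel_size_mm,
         n_lesions = as.integer(n_lesions),
         lesion_radius_range_mm = lesion_radius_range_mm,
         vessel_counts = as.integer(vessel_counts),
         vessel_radius_mm = vessel_radius_mm,
         tissue_levels_gre = tissue_levels_gre[roles],
         tissue_levels_bb = tissue_levels_bb[roles],
         noise_sd = noise_sd, bb_blur_sigma_vox = bb_blur_sigma_vox,
         residual_vessel_fraction = residual_vessel_fraction,
         skull_rim = isTRUE(skull_rim), seed = as.integer(seed)),
    class = "bb_phantom_spec")
}

# label codes used in the ground-truth label map
PHANTOM_LABELS <- c(background = 0L, gm = 1L, wm = 2L, vessel1 = 3L,
                    vessel2 = 4L, vessel3 = 5L, lesion = 6L, skull = 7L)

# squared normalized ellipsoid coordinate for every voxel
ellipsoid_field <- function(dims, center, semi) {
  x <- ((seq_len(dims[1]) - center[1]) / semi[1])^2
  y <- ((seq_len(dims[2]) - center[2]) / semi[2])^2
  z <- ((seq_len(dims[3]) - center[3]) / semi[3])^2
  outer(outer(x, y, `+`), z, `+`)
}

# stamp a tube of radius r (voxels) along a polyline into linear indices
tube_voxels <- function(points, radius, dims) {
  idx <- integer(0)
  for (i in seq_len(nrow(points) - 1L)) {
    p0 <- points[i, ]; p1 <- points[i + 1L, ]
    len <- sqrt(sum((p1 - p0)^2))
    nstep <- max(2L, ceiling(len / 0.3))
    ts <- seq(0, 1, length.out = nstep)
    for (t in ts) {
      idx <- c(idx, ball_voxels(p0 + t * (p1 - p0), radius, dims))
    }
  }
  unique(idx)
}

# vessel centerline geometry; all coordinates in voxels
make_vessel_polylines <- function(spec, center, semi_wm, semi_brain) {
  segs <- list()
  vox <- spec$voxel_size_mm
  r_vox <- spec$vessel_radius_mm / vox
  cx <- center[1]; cy <- center[2]; cz <- center[3]

  add <- function(points, type) {
    segs[[length(segs) + 1L]] <<- list(points = points,
                                       radius_mm = spec$vessel_radius_mm[type],
                                       type = type)
  }

  # --- type 1: large midline structures ---
  n1 <- spec$vessel_counts[1]
  if (n1 >= 1L) {  # deep midline trunk (pericallosal-like), slight wobble
    ys <- seq(cy - 0.75 * semi_wm[2], cy + 0.75 * semi_wm[2], length.out = 40)
    pts <- cbind(cx + 1.5 * sin((ys - cy) / 9), ys,
                 cz + 2 * cos((ys - cy) / 14))
    add(pts, 1L)
  }
  if (n1 >= 2L) {  # superior midline arc (sagittal-sinus-like)
    ys <- seq(cy - 0.7 * semi_wm[2], cy + 0.7 * semi_wm[2], length.out = 40)
    zs <- cz + 0.82 * semi_wm[3] * sqrt(pmax(0, 1 - ((ys - cy) /
                                                     semi_wm[2])^2))
    add(cbind(rep(cx, length(ys)), ys, zs), 1L)
  }
  if (n1 >= 3L) {  # deep posterior vein (Galen-like)
    ys <- seq(cy, cy + 0.65 * semi_wm[2], length.out = 20)
    pts <- cbind(rep(cx, length(ys)), ys,
                 cz - 8 - 0.12 * (ys - cy))
    add(pts, 1L)
  }
  if (n1 > 3L) {  # extra parallel deep tubes
    for (i in seq_len(n1 - 3L)) {
      zoff <- -14 - 4 * i
      ys <- seq(cy - 0.6 * semi_wm[2], cy + 0.6 * semi_wm[2], length.out = 30)
      add(cbind(rep(cx, length(ys)), ys, rep(cz + zoff, length(ys))), 1L)
    }
  }

  # --- type 2: medium lateral branches off the deep trunk ---
  n2 <- spec$vessel_counts[2]
  if (n2 > 0L) {
    yset <- seq(cy - 0.55 * semi_wm[2], cy + 0.55 * semi_wm[2],
                length.out = n2)
    for (i in seq_len(n2)) {
      side <- if (i %% 2L == 0L) 1 else -1
      y0 <- yset[i]
      start <- c(cx + 1.5 * sin((y0 - cy) / 9), y0,
                 cz + 2 * cos((y0 - cy) / 14))
      dir <- c(side, runif(1, -0.25, 0.25), runif(1, -0.35, 0.35))
      dir <- dir / sqrt(sum(dir^2))
      len <- 0.62 * semi_wm[1]
      pts <- t(sapply(seq(0, 1, length.out = 18),
                      function(t) start + t * len * dir))
      # keep inside the white matter by trimming the far end
      inside <- rowSums(((t(t(pts) - center)) / semi_wm)^2) <= 0.92
      if (sum(inside) >= 4L) pts <- pts[seq_len(max(which(inside))), ]
      add(pts, 2L)
    }
  }

  # --- type 3: short thin cortical branches near the brain surface ---
  n3 <- spec$vessel_counts[3]
  if (n3 > 0L) {
    placed <- 0L
    tries <- 0L
    while (placed < n3 && tries < 400L) {
      tries <- tries + 1L
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      tang <- rnorm(3); tang <- tang - sum(tang * u) * u
      tang <- tang / sqrt(sum(tang^2))
      len <- min(runif(1, 8, 12), 0.55 * min(semi_brain))
      # a point just beneath the cortical surface, pulled in far enough
      # that the whole branch fits inside the brain on small grids
      allowed <- min(semi_brain) - r_vox[3] - 1
      f <- min(0.88, sqrt(max(allowed^2 - (len / 2)^2, 0)) / max(semi_brain))
      p0 <- center + u * semi_brain * f
      pts <- t(sapply(seq(0, 1, length.out = 10),
                      function(t) p0 + (t - 0.5) * len * tang))
      ell <- rowSums(((t(t(pts) - center)) / (semi_brain - r_vox[3] - 1))^2)
      if (all(ell <= 1)) {
        add(pts, 3L)
        placed <- placed + 1L
      }
    }
    if (placed < n3)
      stop("could not place requested type-3 vessels", call. = FALSE)
  }
  segs
}

#' Generate phantom ground truth
#'
#' Builds the label map, vessel centerlines, lesion table and residual
#' (unsuppressed-on-BB) vessel voxel set for one phantom. Deterministic for
#' a fixed `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `bb_phantom_truth` with fields `label_map`
#'   (integer array; codes background 0, gm 1, wm 2, vessel types 3/4/5,
#'   lesion 6, skull 7), `lesions` (data frame: voxel center, radius and
#'   maximum axial diameter in mm), `vessel_segments` (list of centerline
#'   polylines with radius and type), `residual_vessel_voxels` (linear
#'   indices) and `spec`.
#' @export
generate_truth <- function(spec) {
  stopifnot(inherits(spec, "bb_phantom_spec"))
  dims <- spec$grid_shape
  vox <- spec$voxel_size_mm
  center <- (dims + 1) / 2
  semi_brain <- 0.40 * dims
  gm_thick <- max(3, round(4 / vox))
  semi_wm <- semi_brain - gm_thick

  with_seed(spec$seed, {
    ell_brain <- ellipsoid_field(dims, center, semi_brain)
    ell_wm <- ellipsoid_field(dims, center, semi_wm)
    label <- array(PHANTOM_LABELS[["background"]], dims)
    label[ell_brain <= 1] <- PHANTOM_LABELS[["gm"]]
    label[ell_wm <= 1] <- PHANTOM_LABELS[["wm"]]

    if (spec$skull_rim) {
      # the CSF/scalp gap must stay wider than twice the closing radius
      # used in brain extraction, or closing would weld rim to brain
      ell_in <- ellipsoid_field(dims, center, semi_brain + 6 / vox)
      ell_out <- ellipsoid_field(dims, center, semi_brain + 8 / vox)
      label[ell_out <= 1 & ell_in > 1] <- PHANTOM_LABELS[["skull"]]
    }

    segs <- make_vessel_polylines(spec, center, semi_wm, semi_brain)
    brain <- ell_brain <= 1
    for (s in segs) {
      idx <- tube_voxels(s$points, s$radius_mm / vox, dims)
      idx <- idx[brain[idx]]
      code <- PHANTOM_LABELS[["vessel1"]] + s$type - 1L
      # vessels may touch but do not overwrite one another
      idx <- idx[label[idx] %in% c(PHANTOM_LABELS[["gm"]],
                                   PHANTOM_LABELS[["wm"]])]
      label[idx] <- code
    }

    lesions <- data.frame(x = integer(0), y = integer(0), z = integer(0),
                          radius_mm = numeric(0), diameter_mm = numeric(0))
    if (spec$n_lesions > 0L) {
      vessel_mask <- label >= PHANTOM_LABELS[["vessel1"]] &
        label <= PHANTOM_LABELS[["vessel3"]]
      margin <- max(2, round(2 / vox))
      for (i in seq_len(spec$n_lesions)) {
        ok <- FALSE
        for (try in seq_len(200L)) {
          r_mm <- runif(1, spec$lesion_radius_range_mm[1],
                        spec$lesion_radius_range_mm[2])
          r_vox <- r_mm / vox
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
          rad <- runif(1)^(1 / 3)
          cen <- round(center + u * rad * pmax(semi_brain - r_vox - 2, 1))
          if (any(cen < 1) || any(cen > dims)) next
          ell <- sum(((cen - center) / (semi_brain - r_vox - 1))^2)
          if (ell > 1) next
          probe <- ball_voxels(cen, r_vox + margin, dims)
          if (any(label[probe] %in% c(PHANTOM_LABELS[["vessel1"]],
                                      PHANTOM_LABELS[["vessel2"]],
                                      PHANTOM_LABELS[["vessel3"]],
                                      PHANTOM_LABELS[["lesion"]],
                                      PHANTOM_LABELS[["background"]],
                                      PHANTOM_LABELS[["skull"]]))) next
          idx <- ball_voxels(cen, r_vox, dims)
          label[idx] <- PHANTOM_LABELS[["lesion"]]
          lesions <- rbind(lesions,
                           data.frame(x = cen[1], y = cen[2], z = cen[3],
                                      radius_mm = r_mm,
                                      diameter_mm = 2 * r_mm))
          ok <- TRUE
          break
        }
        if (!ok)
          stop(sprintf(paste0("placement error: could not fit lesion %d of %d",
                              " without overlap"), i, spec$n_lesions),
               call. = FALSE)
      }
    }

    vessel_idx <- which(label >= PHANTOM_LABELS[["vessel1"]] &
                          label <= PHANTOM_LABELS[["vessel3"]])
    residual <- integer(0)
    if (spec$residual_vessel_fraction > 0 && length(vessel_idx) > 0) {
      keep <- runif(length(vessel_idx)) < spec$residual_vessel_fraction
      residual <- vessel_idx[keep]
    }

    structure(
      list(label_map = label, lesions = lesions, vessel_segments = segs,
           residual_vessel_voxels = residual, spec = spec),
      class = "bb_phantom_truth")
  })
}

#' Render a registered GRE/BB phantom pair
#'
#' Maps the truth label map through the per-modality tissue intensity
#' levels, applies the BB-only degradations (residual unsuppressed vessel
#' voxels at GRE level, Gaussian blur) and adds clipped Gaussian noise.
#' The two volumes are voxelwise registered by construction. Deterministic
#' for a fixed `spec$seed` (noise uses `seed + 1` so it is independent of
#' the geometry stream).
#'
#' @param truth A [generate_truth()] result.
#' @param spec The matching [phantom_spec()].
#' @return List with elements `gre` and `bb`, both [volume3d()].
#' @export
render_pair <- function(truth, spec = truth$spec) {
  stopifnot(inherits(truth, "bb_phantom_truth"),
            inherits(spec, "bb_phantom_spec"))
  if (!identical(dim(truth$label_map), as.integer(spec$grid_shape)))
    stop("truth/spec grid shape mismatch", call. = FALSE)
  dims <- spec$grid_shape
  lv_g <- spec$tissue_levels_gre
  lv_b <- spec$tissue_levels_bb
  # label code -> level lookup (codes 0..7)
  lut_g <- c(lv_g[["background"]], lv_g[["gm"]], lv_g[["wm"]],
             rep(lv_g[["vessel"]], 3), lv_g[["lesion"]], lv_g[["skull"]])
  lut_b <- c(lv_b[["background"]], lv_b[["gm"]], lv_b[["wm"]],
             rep(lv_b[["vessel"]], 3), lv_b[["lesion"]], lv_b[["skull"]])
  gre <- array(lut_g[truth$label_map + 1L], dims)
  bb <- array(lut_b[truth$label_map + 1L], dims)
  if (length(truth$residual_vessel_voxels))
    bb[truth$residual_vessel_voxels] <- lv_g[["vessel"]]
  if (spec$bb_blur_sigma_vox > 0)
    bb <- cpp_gaussian_blur(bb, spec$bb_blur_sigma_vox)
  if (spec$noise_sd > 0) {
    with_seed(spec$seed + 1L, {
      gre <- gre + rnorm(length(gre), 0, spec$noise_sd)
      bb <- bb + rnorm(length(bb), 0, spec$noise_sd)
    })
    gre <- pmin(pmax(gre, 0), 1)
    bb <- pmin(pmax(bb, 0), 1)
    dim(gre) <- dims
    dim(bb) <- dims
  }
  list(gre = volume3d(gre, spacing_mm = rep(spec$voxel_size_mm, 3),
                      modality = "GRE"),
       bb = volume3d(bb, spacing_mm = rep(spec$voxel_size_mm, 3),
                     modality = "BB"))
}

#' Write a phantom to disk
#'
#' Writes the paired volumes as NIfTI, the label map as integer NIfTI and
#' the lesion/vessel truth tables as JSON.
#'
#' @param truth A [generate_truth()] result.
#' @param pair A [render_pair()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(truth, pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(pair$gre, file.path(dir, "gre.nii.gz"))
  write_volume(pair$bb, file.path(dir, "bb.nii.gz"))
  lab <- volume3d(truth$label_map + 0,
                  spacing_mm = rep(truth$spec$voxel_size_mm, 3))
  write_volume(lab, file.path(dir, "labels.nii.gz"))
  meta <- list(
    lesions = truth$lesions,
    vessel_segments = lapply(truth$vessel_segments, function(s)
      list(points = unname(s$points), radius_mm = s$radius_mm,
           type = s$type)),
    residual_vessel_voxels = truth$residual_vessel_voxels,
    spec = truth$spec[setdiff(names(truth$spec), character(0))])
  jsonlite::write_json(meta, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
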