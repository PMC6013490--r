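#' Registered study pair
#'
#' Bundles a GRE volume, a BB volume and a brain mask on a common grid.
#'
#' @param gre,bb [volume3d()] objects sharing grid shape and spacing.
#' @param brain_mask Logical 3D array (or `NULL`).
#' @param registered Flag: the two volumes are voxelwise aligned.
#' @return An object of class `bb_study_pair`.
#' @export
study_pair <- function(gre, bb, brain_mask = NULL, registered = FALSE) {
  gre <- as_volume3d(gre, "GRE")
  bb <- as_volume3d(bb, "BB")
  if (!identical(dim(gre$data), dim(bb$data)))
    stop("GRE and BB grids differ", call. = FALSE)
  if (!isTRUE(all.equal(gre$spacing_mm, bb$spacing_mm)))
    stop("GRE and BB spacings differ", call. = FALSE)
  if (!is.null(brain_mask)) {
    if (!identical(dim(brain_mask), dim(gre$data)))
      stop("brain mask grid differs from volumes", call. = FALSE)
    if (!any(brain_mask)) stop("brain mask is empty", call. = FALSE)
  }
  structure(list(gre = gre, bb = bb, brain_mask = brain_mask,
                 registered = isTRUE(registered)),
            class = "bb_study_pair")
}

#' Extract a brain mask
#'
#' Otsu intensity thresholding followed by morphological closing and
#' retention of the largest 26-connected component. A detached bright rim
#' (skull/scalp analogue) is discarded because it does not join the largest
#' component.
#'
#' @param vol A normalized [volume3d()].
#' @param closing_radius Structuring radius (voxels) for the closing step.
#' @return Logical 3D mask.
#' @export
extract_brain <- function(vol, closing_radius = 2L) {
  vol <- as_volume3d(vol)
  thr <- otsu_threshold(as.numeric(vol$data))
  mask <- vol$data > thr
  dim(mask) <- dim(vol$data)
  if (!any(mask)) stop("brain extraction produced an empty mask",
                       call. = FALSE)
  if (closing_radius > 0)
    mask <- cpp_erode_ball(cpp_dilate_ball(mask, closing_radius),
                           closing_radius)
  mask <- largest_component(mask)
  if (!any(mask)) stop("brain extraction produced an empty mask",
                       call. = FALSE)
  mask
}

rigid_matrix <- function(par, center) {
  tr <- par[1:3]
  ang <- par[4:6] * pi / 180
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  R <- Rz %*% Ry %*% Rx
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- center - R %*% center + tr
  m
}

ncc_metric <- function(a, b) {
  sa <- sd(a); sb <- sd(b)
  if (sa == 0 || sb == 0) return(0)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

downsample2 <- function(a) {
  d <- dim(a) %/% 2L
  a <- a[seq_len(2L * d[1]), seq_len(2L * d[2]), seq_len(2L * d[3])]
  b <- array(0, d)
  for (i in 0:1) for (j in 0:1) for (k in 0:1)
    b <- b + a[seq(1L + i, by = 2L, length.out = d[1]),
               seq(1L + j, by = 2L, length.out = d[2]),
               seq(1L + k, by = 2L, length.out = d[3])]
  b / 8
}

#' Rigid registration of two volumes
#'
#' Six-parameter (3 translations, 3 rotations) rigid alignment of `moving`
#' to `fixed`, maximizing normalized cross-correlation with a
#' multi-resolution Nelder-Mead search. The translation is initialized from
#' the centre-of-mass offset. The returned transform maps fixed-grid voxel
#' coordinates (0-based) to moving-grid coordinates; the resampled moving
#' volume lives on the fixed grid.
#'
#' @param moving,fixed [volume3d()] objects with identical grids.
#' @param maxit Nelder-Mead iteration cap per resolution level.
#' @param min_ncc Final normalized cross-correlation below which the result
#'   is flagged as non-converged (best-effort transform still returned).
#' @return List with `volume` (resampled moving volume), `par`
#'   (tx, ty, tz in voxels; rx, ry, rz in degrees), `matrix` (4x4 affine),
#'   `metric_before`, `metric_after`, `converged`.
#' @export
register_rigid <- function(moving, fixed, maxit = 300L, min_ncc = 0.2) {
  moving <- as_volume3d(moving)
  fixed <- as_volume3d(fixed)
  if (!identical(dim(moving$data), dim(fixed$data)))
    stop("register_rigid expects volumes on identical grids", call. = FALSE)
  dims <- dim(fixed$data)
  center <- (dims - 1) / 2

  objective <- function(par, mv, fx, ctr) {
    m <- rigid_matrix(par, ctr)
    res <- cpp_resample_affine(mv, m[1:3, , drop = FALSE], 0)
    -ncc_metric(as.numeric(res), as.numeric(fx))
  }

  # centre-of-mass translation initialization
  com <- function(a) {
    w <- pmax(a - min(a), 0)
    s <- sum(w)
    if (s == 0) return((dim(a) - 1) / 2)
    idx <- index_to_coord(seq_along(a), dim(a)) - 1L
    colSums(idx * as.numeric(w)) / s
  }
  t0 <- com(moving$data) - com(fixed$data)
  cand <- list(rep(0, 6), c(t0, 0, 0, 0))

  par <- cand[[which.min(vapply(cand, objective, numeric(1),
                                mv = moving$data, fx = fixed$data,
                                ctr = center))]]

  if (min(dims) >= 32L) {  # coarse level
    mv2 <- downsample2(moving$data)
    fx2 <- downsample2(fixed$data)
    ctr2 <- (dim(mv2) - 1) / 2
    p2 <- c(par[1:3] / 2, par[4:6])
    fit2 <- optim(p2, objective, mv = mv2, fx = fx2, ctr = ctr2,
                  method = "Nelder-Mead",
                  control = list(maxit = maxit, reltol = 1e-9))
    par <- c(fit2$par[1:3] * 2, fit2$par[4:6])
  }
  fit <- optim(par, objective, mv = moving$data, fx = fixed$data,
               ctr = center, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-10))

  metric_before <- ncc_metric(as.numeric(moving$data),
                              as.numeric(fixed$data))
  # keep the best of {identity, initialization, refined}
  choices <- list(rep(0, 6), par, fit$par)
  scores <- vapply(choices, objective, numeric(1), mv = moving$data,
                   fx = fixed$data, ctr = center)
  best <- choices[[which.min(scores)]]
  metric_after <- -min(scores)

  m <- rigid_matrix(best, center)
  res <- cpp_resample_affine(moving$data, m[1:3, , drop = FALSE], 0)
  list(volume = volume3d(res, spacing_mm = fixed$spacing_mm,
                         modality = moving$modality),
       par = best, matrix = m,
       metric_before = metric_before, metric_after = metric_after,
       converged = metric_after >= min_ncc)
}

#' Write a rigid transform as JSON
#'
#' @param transform Result of [register_rigid()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(list(par = transform$par,
                            matrix = transform$matrix,
                            converged = transform$converged),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
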