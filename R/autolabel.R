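#' Auto-labelling parameters
#'
#' Tunable parameters of the two-pass vessel extraction and replacement
#' procedure that turns a registered GRE/BB pair into a synthetic
#' black-blood label volume.
#'
#' @param n_clusters Fuzzy c-means cluster count over brain voxels
#'   (default 3: dark tissue / grey-ish / bright, where the brightest
#'   cluster is the WM+vessel candidate class).
#' @param fuzziness_m FCM fuzziness exponent (> 1).
#' @param fcm_tol Convergence threshold on the maximum centroid shift.
#' @param fcm_max_iter Iteration cap.
#' @param seed_percentile Intensity percentile (within the candidate class)
#'   above which voxels seed region growing; default 0.995 (top 0.5%).
#' @param seed_floor Absolute minimum normalized intensity for a seed.
#'   After max-normalization, enhancing vessels sit near the top of the
#'   `[0, 1]` range; the floor prevents spurious seeding when no bright
#'   structure is present (in which case an empty mask is returned).
#' @param grow_tol Intensity tolerance during growth: voxels join the
#'   region while their intensity is within `grow_tol` of the seed-region
#'   mean (normalized units).
#' @param dilation_radius_vox Width of the dilated blending ring around
#'   each vessel mask (voxels).
#' @param blend_weight_bb Weight of the BB image in the ring blend, in
#'   `[0, 1]`.
#' @param residual_threshold Threshold applied to the difference image
#'   (intermediate synthetic BB minus BB) in the second pass; must be > 0.
#' @param rng_seed Integer seed (reserved for stochastic options; the
#'   default pipeline is fully deterministic).
#' @return An object of class `bb_autolabel_params`.
#' @export
autolabel_params <- function(n_clusters = 3L, fuzziness_m = 2,
                             fcm_tol = 1e-5, fcm_max_iter = 200L,
                             seed_percentile = 0.995, seed_floor = 0.8,
                             grow_tol = 0.1, dilation_radius_vox = 1L,
                             blend_weight_bb = 0.5,
                             residual_threshold = 0.2, rng_seed = 1L) {
  stopifnot(n_clusters >= 2L, fuzziness_m > 1, fcm_tol > 0,
            fcm_max_iter >= 1L,
            seed_percentile > 0, seed_percentile <= 1,
            seed_floor >= 0, seed_floor <= 1,
            grow_tol > 0, dilation_radius_vox >= 1L,
            blend_weight_bb >= 0, blend_weight_bb <= 1,
            residual_threshold > 0)
  structure(list(n_clusters = as.integer(n_clusters),
                 fuzziness_m = fuzziness_m, fcm_tol = fcm_tol,
                 fcm_max_iter = as.integer(fcm_max_iter),
                 seed_percentile = seed_percentile, seed_floor = seed_floor,
                 grow_tol = grow_tol,
                 dilation_radius_vox = as.integer(dilation_radius_vox),
                 blend_weight_bb = blend_weight_bb,
                 residual_threshold = residual_threshold,
                 rng_seed = as.integer(rng_seed)),
            class = "bb_autolabel_params")
}

#' Fuzzy c-means clustering of voxel intensities
#'
#' One-dimensional fuzzy c-means over the voxels of `vol` inside `mask`.
#' Centroids are initialized at fixed intensity quantiles (deterministic,
#' no random restarts), memberships and centroids are updated alternately,
#' and the objective is tracked per iteration. Centroids are kept sorted
#' ascending so the last cluster is always the brightest (the WM+vessel
#' candidate class).
#'
#' @param vol A [volume3d()] with intensities in `[0, 1]`.
#' @param mask Logical 3D array selecting the voxels to cluster.
#' @param params A [autolabel_params()].
#' @return An object of class `bb_fcm` with `memberships` (n x k matrix for
#'   masked voxels, rows sum to 1), `centroids` (ascending), `objective`
#'   (per-iteration), `n_iter`, `converged` and `mask`.
#' @export
fcm_cluster <- function(vol, mask, params = autolabel_params()) {
  vol <- as_volume3d(vol)
  stopifnot(identical(dim(mask), dim(vol$data)))
  x <- as.numeric(vol$data[mask])
  if (length(x) == 0L) stop("mask is empty", call. = FALSE)
  if (diff(range(x)) < 1e-12)
    stop("degenerate clustering: constant-intensity region", call. = FALSE)
  k <- params$n_clusters
  m <- params$fuzziness_m
  cen <- as.numeric(quantile(x, probs = (seq_len(k) - 0.5) / k,
                             names = FALSE))
  # ensure strictly increasing starting centroids
  eps_c <- 1e-6 * max(diff(range(x)), 1e-12)
  for (j in seq_len(k - 1L))
    if (cen[j + 1L] <= cen[j]) cen[j + 1L] <- cen[j] + eps_c
  obj <- numeric(0)
  converged <- FALSE
  n_iter <- 0L
  u <- NULL
  for (it in seq_len(params$fcm_max_iter)) {
    n_iter <- it
    d2 <- outer(x, cen, function(a, b) (a - b)^2)
    zero <- d2 < 1e-20
    w <- d2^(-1 / (m - 1))
    anyzero <- rowSums(zero) > 0
    if (any(anyzero)) {
      w[anyzero, ] <- 0
      w[cbind(which(anyzero), max.col(zero[anyzero, , drop = FALSE],
                                      ties.method = "first"))] <- 1
    }
    u <- w / rowSums(w)
    um <- u^m
    obj <- c(obj, sum(um * d2))
    den <- colSums(um)
    cen_new <- colSums(um * x) / den
    # a cluster starved of membership (possible when the data take fewer
    # distinct values than clusters) keeps its previous centroid
    starved <- !is.finite(cen_new) | den < 1e-12
    cen_new[starved] <- cen[starved]
    ord <- order(cen_new)
    cen_new <- cen_new[ord]
    u <- u[, ord, drop = FALSE]
    shift <- max(abs(cen_new - cen[order(cen)]))
    cen <- cen_new
    if (shift < params$fcm_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("fuzzy c-means did not converge within fcm_max_iter iterations")
  structure(list(memberships = u, centroids = cen, objective = obj,
                 n_iter = n_iter, converged = converged, mask = mask),
            class = "bb_fcm")
}

#' Hard cluster assignment from fuzzy memberships
#'
#' Assigns every masked voxel to its cluster of maximal membership (ties go
#' to the lower centroid index).
#'
#' @param fcm A [fcm_cluster()] result.
#' @return Integer 3D array: 0 outside the mask, cluster index 1..k inside
#'   (clusters ordered by ascending centroid).
#' @export
defuzzify <- function(fcm) {
  stopifnot(inherits(fcm, "bb_fcm"))
  out <- array(0L, dim(fcm$mask))
  out[fcm$mask] <- max.col(fcm$memberships, ties.method = "first")
  out
}

#' Binary vessel mask with blending ring
#'
#' @param core Logical 3D array of vessel voxels.
#' @param ring Logical 3D array, disjoint from `core` (the dilated shell
#'   used for weighted blending).
#' @param pass_id 1 (clustering + region growing) or 2 (difference-image
#'   thresholding).
#' @return An object of class `bb_vessel_mask`.
#' @export
vessel_mask <- function(core, ring, pass_id) {
  stopifnot(identical(dim(core), dim(ring)), pass_id %in% c(1L, 2L))
  if (any(core & ring))
    stop("vessel mask core and ring must be disjoint", call. = FALSE)
  structure(list(core = core, ring = ring, pass_id = as.integer(pass_id)),
            class = "bb_vessel_mask")
}

make_vessel_mask <- function(core, params, brain_mask = NULL, pass_id = 1L) {
  ring <- cpp_dilate(core, params$dilation_radius_vox) & !core
  if (!is.null(brain_mask)) {
    core <- core & brain_mask
    ring <- ring & brain_mask
  }
  dim(core) <- dim(ring)
  vessel_mask(core, ring, pass_id)
}

#' First-pass vessel mask by seeded region growing
#'
#' Seeds are candidate-class voxels whose intensity reaches both the
#' `seed_percentile` quantile of candidate intensities and the absolute
#' `seed_floor`. The region grows from the seeds through the candidate
#' class by 26-connectivity while voxel intensity stays within `grow_tol`
#' of the seed-region mean. If no voxel reaches the seed threshold an empty
#' mask is returned with a warning (not an error).
#'
#' @param vol The GRE [volume3d()] (normalized).
#' @param candidate_mask Logical 3D array: the defuzzified brightest
#'   (WM+vessel) class from [fcm_cluster()].
#' @param params A [autolabel_params()].
#' @param brain_mask Optional logical array restricting core and ring.
#' @return A [vessel_mask()] with `pass_id = 1`.
#' @export
grow_vessel_mask <- function(vol, candidate_mask,
                             params = autolabel_params(),
                             brain_mask = NULL) {
  vol <- as_volume3d(vol)
  stopifnot(identical(dim(candidate_mask), dim(vol$data)))
  empty <- array(FALSE, dim(vol$data))
  if (!any(candidate_mask)) {
    warning("candidate mask is empty; returning empty vessel mask")
    return(make_vessel_mask(empty, params, brain_mask, 1L))
  }
  xc <- vol$data[candidate_mask]
  thr <- max(quantile(xc, params$seed_percentile, names = FALSE),
             params$seed_floor)
  seeds <- candidate_mask & vol$data >= thr
  dim(seeds) <- dim(vol$data)
  if (!any(seeds)) {
    warning("no voxels reach the region-growing seed threshold; ",
            "returning empty vessel mask")
    return(make_vessel_mask(empty, params, brain_mask, 1L))
  }
  seed_mean <- mean(vol$data[seeds])
  core <- cpp_region_grow(vol$data, candidate_mask, seeds,
                          seed_mean - params$grow_tol,
                          seed_mean + params$grow_tol)
  make_vessel_mask(core, params, brain_mask, 1L)
}

#' Replace vessel voxels and blend the surrounding ring
#'
#' On the mask core the output takes the BB value exactly; on the dilated
#' ring it takes the weighted sum
#' `blend_weight_bb * bb + (1 - blend_weight_bb) * base`; everywhere else
#' it equals `base` exactly.
#'
#' @param base The volume being edited (GRE in pass 1, the intermediate
#'   synthetic BB in pass 2).
#' @param bb The paired BB [volume3d()].
#' @param mask A [vessel_mask()].
#' @param params A [autolabel_params()].
#' @return A [volume3d()] (modality `SYNTH_BB`).
#' @export
fill_and_blend <- function(base, bb, mask, params = autolabel_params()) {
  base <- as_volume3d(base)
  bb <- as_volume3d(bb)
  stopifnot(inherits(mask, "bb_vessel_mask"))
  if (!identical(dim(base$data), dim(bb$data)) ||
      !identical(dim(base$data), dim(mask$core)))
    stop("base, bb and mask grids differ", call. = FALSE)
  out <- base$data
  out[mask$core] <- bb$data[mask$core]
  w <- params$blend_weight_bb
  out[mask$ring] <- w * bb$data[mask$ring] + (1 - w) * base$data[mask$ring]
  volume3d(out, spacing_mm = base$spacing_mm, modality = "SYNTH_BB")
}

#' Second-pass vessel mask from the difference image
#'
#' Subtracting the paired BB image from the intermediate synthetic BB image
#' suppresses non-vessel tissue (both images agree there), leaving the
#' still-unreplaced vessels as the dominant positive residue; thresholding
#' the difference at `residual_threshold` yields the second-pass mask.
#'
#' @param intermediate Intermediate synthetic BB [volume3d()] from the
#'   first [fill_and_blend()].
#' @param bb The paired BB [volume3d()].
#' @param params A [autolabel_params()].
#' @param brain_mask Optional logical array restricting the mask.
#' @return A [vessel_mask()] with `pass_id = 2`.
#' @export
residual_vessel_mask <- function(intermediate, bb,
                                 params = autolabel_params(),
                                 brain_mask = NULL) {
  intermediate <- as_volume3d(intermediate)
  bb <- as_volume3d(bb)
  if (!identical(dim(intermediate$data), dim(bb$data)))
    stop("intermediate and bb grids differ", call. = FALSE)
  if (params$residual_threshold <= 0)
    stop("residual_threshold must be positive", call. = FALSE)
  diff_img <- intermediate$data - bb$data
  core <- diff_img > params$residual_threshold
  dim(core) <- dim(bb$data)
  if (!is.null(brain_mask)) core <- core & brain_mask
  dim(core) <- dim(bb$data)
  make_vessel_mask(core, params, brain_mask, 2L)
}

#' Synthesize a black-blood label volume from a registered pair
#'
#' Runs the full two-pass auto-labelling chain: fuzzy c-means clustering of
#' the GRE brain voxels, seeded region growing of the brightest class
#' (pass-1 vessel mask), replacement of the mask with BB values plus ring
#' blending, difference-image thresholding (pass-2 mask), and a second
#' replacement in which the ring blends the intermediate image with BB.
#' Voxels outside both masks and rings keep their GRE value exactly, so
#' metastases and parenchyma are untouched.
#'
#' @param pair A [study_pair()] with `registered = TRUE` and a brain mask.
#' @param params A [autolabel_params()].
#' @return List with `synth` (the synthetic BB [volume3d()]), `mask1`,
#'   `mask2` (both [vessel_mask()]) and `fcm` (the clustering result).
#' @export
synthesize_bb <- function(pair, params = autolabel_params()) {
  stopifnot(inherits(pair, "bb_study_pair"))
  if (!pair$registered)
    stop("pair must be registered before auto-labelling", call. = FALSE)
  if (is.null(pair$brain_mask))
    stop("pair must carry a brain mask", call. = FALSE)
  gre <- pair$gre
  bb <- pair$bb
  brain <- pair$brain_mask

  fcm <- fcm_cluster(gre, brain, params)
  assign_map <- defuzzify(fcm)
  candidate <- assign_map == params$n_clusters
  dim(candidate) <- dim(gre$data)

  mask1 <- grow_vessel_mask(gre, candidate, params, brain)
  intermediate <- fill_and_blend(gre, bb, mask1, params)
  mask2 <- residual_vessel_mask(intermediate, bb, params, brain)
  synth <- fill_and_blend(intermediate, bb, mask2, params)
  list(synth = synth, mask1 = mask1, mask2 = mask2, fcm = fcm)
}
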