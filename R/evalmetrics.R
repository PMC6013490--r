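#' Place evaluation ROIs on a phantom
#'
#' The phantom analogue of the nine-ROI scheme used for vessel-suppression
#' scoring: three spherical ROIs per vessel caliber class, centered on
#' vessel centerlines, plus one ROI in a homogeneous white-matter region
#' free of vessels and lesions.
#'
#' @param truth A [generate_truth()] result with at least three vessel
#'   segments of every type.
#' @param spec The matching [phantom_spec()].
#' @param rng_seed Seed for the (deterministic) ROI draws.
#' @param wm_radius_vox Radius of the white-matter ROI.
#' @return An object of class `bb_roi_set`: `wm_roi` (linear voxel
#'   indices), `vessel_rois` (list of nine, each with `type` and `voxels`).
#' @export
place_phantom_rois <- function(truth, spec = truth$spec, rng_seed = 1L,
                               wm_radius_vox = 3L) {
  stopifnot(inherits(truth, "bb_phantom_truth"))
  dims <- dim(truth$label_map)
  vox <- spec$voxel_size_mm
  types <- vapply(truth$vessel_segments, `[[`, integer(1), "type")
  for (t in 1:3)
    if (sum(types == t) < 3L)
      stop(sprintf("need at least 3 vessels of type %d, found %d", t,
                   sum(types == t)), call. = FALSE)
  with_seed(rng_seed, {
    vessel_rois <- list()
    for (t in 1:3) {
      segs <- which(types == t)
      pick <- if (length(segs) == 3L) segs else sort(sample(segs, 3L))
      for (s in pick) {
        seg <- truth$vessel_segments[[s]]
        mid <- round(seg$points[ceiling(nrow(seg$points) / 2), ])
        r <- max(1, round(seg$radius_mm / vox))
        voxels <- ball_voxels(mid, r, dims)
        vessel_rois[[length(vessel_rois) + 1L]] <-
          list(type = t, voxels = voxels)
      }
    }
    # homogeneous WM ROI: a ball fully inside white matter, away from
    # vessels and lesions
    wm_code <- PHANTOM_LABELS[["wm"]]
    wm_idx <- which(truth$label_map == wm_code)
    wm_roi <- NULL
    for (try in seq_len(1000L)) {
      cen <- index_to_coord(sample(wm_idx, 1L), dims)[1, ]
      probe <- ball_voxels(cen, wm_radius_vox + 2, dims)
      if (all(truth$label_map[probe] == wm_code)) {
        wm_roi <- ball_voxels(cen, wm_radius_vox, dims)
        break
      }
    }
    if (is.null(wm_roi))
      stop("could not find a homogeneous white-matter ROI", call. = FALSE)
    all_rois <- c(list(wm_roi), lapply(vessel_rois, `[[`, "voxels"))
    for (i in seq_along(all_rois))
      for (j in seq_len(i - 1L))
        if (length(intersect(all_rois[[i]], all_rois[[j]])))
          stop("ROIs are not pairwise disjoint", call. = FALSE)
    structure(list(wm_roi = wm_roi, vessel_rois = vessel_rois),
              class = "bb_roi_set")
  })
}

#' Mean signal over an ROI
#'
#' @param vol A [volume3d()].
#' @param roi Integer linear voxel indices.
#' @return The arithmetic mean of the ROI voxel values.
#' @export
roi_mean <- function(vol, roi) {
  vol <- as_volume3d(vol)
  if (length(roi) == 0L) stop("ROI is empty", call. = FALSE)
  if (any(roi < 1L) || any(roi > length(vol$data)))
    stop("ROI indices out of bounds", call. = FALSE)
  mean(vol$data[roi])
}

#' Vessel suppression ratio
#'
#' `R_s = SI_WM / (0.5 * (SI_WM + SI_vessel))`, where `SI_WM` is the mean
#' white-matter ROI signal and `SI_vessel` the mean signal of the three
#' vessel ROIs of one caliber class. Ranges over (0, 2]: 2 means the
#' vessel signal is completely suppressed to background, 1 means vessels
#' are as bright as white matter, and values below 1 mean vessels are
#' brighter than white matter.
#'
#' @param si_wm Mean WM signal (> 0).
#' @param si_vessel Mean vessel signal (>= 0).
#' @return The suppression ratio.
#' @export
vessel_suppression_ratio <- function(si_wm, si_vessel) {
  if (any(si_wm <= 0)) stop("si_wm must be positive", call. = FALSE)
  if (any(si_vessel < 0)) stop("si_vessel must be non-negative",
                               call. = FALSE)
  si_wm / (0.5 * (si_wm + si_vessel))
}

#' Vessel-suppression report across modalities
#'
#' For each volume and vessel type computes `SI_vessel` as the mean of the
#' three per-ROI means of that type (not the pooled voxel mean), `SI_WM`
#' from the WM ROI, and the suppression ratio.
#'
#' @param vols Named list of [volume3d()] objects sharing the ROI grid.
#' @param rois A [place_phantom_rois()] result.
#' @return A data frame (class `bb_suppression_report`) with columns
#'   `modality`, `vessel_type`, `si_wm`, `si_vessel`, `r_s`, ordered as the
#'   input volumes.
#' @export
suppression_report <- function(vols, rois) {
  stopifnot(inherits(rois, "bb_roi_set"), length(vols) >= 1L)
  if (is.null(names(vols)) || any(!nzchar(names(vols))))
    names(vols) <- paste0("vol", seq_along(vols))
  out <- NULL
  for (nm in names(vols)) {
    v <- as_volume3d(vols[[nm]])
    si_wm <- roi_mean(v, rois$wm_roi)
    for (t in 1:3) {
      means <- vapply(Filter(function(r) r$type == t, rois$vessel_rois),
                      function(r) roi_mean(v, r$voxels), numeric(1))
      si_vessel <- mean(means)
      out <- rbind(out, data.frame(modality = nm, vessel_type = t,
                                   si_wm = si_wm, si_vessel = si_vessel,
                                   r_s = vessel_suppression_ratio(si_wm,
                                                                  si_vessel)))
    }
  }
  class(out) <- c("bb_suppression_report", class(out))
  out
}

#' Per-lesion sensitivity from matched counts
#'
#' @param matched Number of detected (matched) lesions.
#' @param total Number of reference lesions.
#' @return Sensitivity in percent, `100 * matched / total`.
#' @export
detection_summary <- function(matched, total) {
  stopifnot(all(matched >= 0), all(total > 0), all(matched <= total))
  100 * matched / total
}

#' Lesion detection scoring against phantom truth
#'
#' Candidate calls are 26-connected components of `vol > call_threshold`
#' inside brain tissue, outside the known vessel truth, of size at least
#' `min_size_vox`. A call matches a true lesion when its centroid lies
#' within that lesion's radius; each lesion can be matched at most once.
#' Sensitivity is `100 * TP / (TP + FN)`, reported overall and for the
#' subgroup of lesions with maximum axial diameter >= 2 mm.
#'
#' Two conventions keep the false-positive count aligned with its clinical
#' meaning (a non-lesion location called a metastasis): the vessel-truth
#' exclusion is dilated by `vessel_exclusion_dilation_vox` so that
#' vessel-boundary voxels (ring-blended or blurred vessel edges) are not
#' scored, and additional calls landing on an already-matched lesion are
#' ignored rather than counted as false positives (one lesion, one
#' detection).
#'
#' @param vol The volume being scored (e.g. deep-learned BB output).
#' @param truth The phantom [generate_truth()] result.
#' @param call_threshold Intensity above which voxels are candidate calls.
#' @param min_size_vox Minimum component size in voxels.
#' @param vessel_exclusion_dilation_vox Guard band (voxels) around the
#'   known vessel truth excluded from candidate calls.
#' @return An object of class `bb_detection_report`: counts (`tp`, `fn`,
#'   `fp`, `n_lesions`), `sensitivity`, `sensitivity_ge2mm`, subgroup
#'   counts, the per-lesion `matched` flags, `volume_detected` (any true
#'   lesion found; `NA` when the phantom has none) and `volume_fp` (any
#'   spurious call).
#' @export
detect_lesions <- function(vol, truth, call_threshold = 0.7,
                           min_size_vox = 3L,
                           vessel_exclusion_dilation_vox = 1L) {
  vol <- as_volume3d(vol)
  stopifnot(inherits(truth, "bb_phantom_truth"))
  if (!identical(dim(vol$data), dim(truth$label_map)))
    stop("volume and truth grids differ", call. = FALSE)
  dims <- dim(vol$data)
  vox <- truth$spec$voxel_size_mm
  tissue <- truth$label_map %in% c(PHANTOM_LABELS[["gm"]],
                                   PHANTOM_LABELS[["wm"]],
                                   PHANTOM_LABELS[["lesion"]])
  dim(tissue) <- dims
  vess <- truth$label_map >= PHANTOM_LABELS[["vessel1"]] &
    truth$label_map <= PHANTOM_LABELS[["vessel3"]]
  dim(vess) <- dims
  if (vessel_exclusion_dilation_vox > 0L && any(vess))
    vess <- cpp_dilate(vess, as.integer(vessel_exclusion_dilation_vox))
  bin <- vol$data > call_threshold & tissue & !vess
  dim(bin) <- dims
  lab <- cpp_label_components(bin)
  ncomp <- attr(lab, "n_components")
  lesions <- truth$lesions
  n_lesions <- nrow(lesions)
  matched <- rep(FALSE, n_lesions)
  fp <- 0L
  if (ncomp > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
    keep <- which(sizes >= min_size_vox)
    # largest calls claim lesions first
    keep <- keep[order(sizes[keep], decreasing = TRUE)]
    for (cl in keep) {
      idx <- which(lab == cl)
      cen <- colMeans(index_to_coord(idx, dims))
      hit <- FALSE
      if (n_lesions > 0L) {
        d_mm <- sqrt((cen[1] - lesions$x)^2 + (cen[2] - lesions$y)^2 +
                       (cen[3] - lesions$z)^2) * vox
        inside <- d_mm <= lesions$radius_mm + 1e-9
        ok <- which(!matched & inside)
        if (length(ok)) {
          matched[ok[which.min(d_mm[ok])]] <- TRUE
          hit <- TRUE
        } else if (any(inside)) {
          hit <- TRUE  # duplicate mark on a matched lesion: not an FP
        }
      }
      if (!hit) fp <- fp + 1L
    }
  }
  tp <- sum(matched)
  fn <- n_lesions - tp
  ge2 <- if (n_lesions) lesions$diameter_mm >= 2 else logical(0)
  sens <- if (n_lesions > 0L) detection_summary(tp, n_lesions) else NA_real_
  sens2 <- if (any(ge2)) detection_summary(sum(matched[ge2]), sum(ge2))
           else NA_real_
  structure(list(tp = tp, fn = fn, fp = fp, n_lesions = n_lesions,
                 sensitivity = sens, sensitivity_ge2mm = sens2,
                 tp_ge2mm = sum(matched[ge2]), n_ge2mm = sum(ge2),
                 matched = matched,
                 volume_detected = if (n_lesions > 0L) tp > 0L else NA,
                 volume_fp = fp > 0L),
            class = "bb_detection_report")
}

#' @export
print.bb_detection_report <- function(x, ...) {
  cat(sprintf("<detection> TP %d / FN %d / FP %d  sensitivity %s  (>=2 mm: %s)\n",
              x$tp, x$fn, x$fp,
              ifelse(is.na(x$sensitivity), "NA",
                     sprintf("%.1f%%", x$sensitivity)),
              ifelse(is.na(x$sensitivity_ge2mm), "NA",
                     sprintf("%.1f%%", x$sensitivity_ge2mm))))
  invisible(x)
}

kappa_weights <- function(k, scheme = c("linear", "quadratic")) {
  scheme <- match.arg(scheme)
  d <- abs(outer(seq_len(k), seq_len(k), `-`)) / (k - 1)
  if (scheme == "linear") 1 - d else 1 - d^2
}

#' Weighted kappa from a rater contingency table
#'
#' @param tab k x k contingency table of two raters' ordinal scores
#'   (counts; rows rater 1, columns rater 2, categories in order).
#' @param weights `"linear"` (default) or `"quadratic"` agreement weights.
#' @return The weighted kappa in `[-1, 1]`, or `NA` (with a warning) when
#'   chance agreement is 1 (a single category used throughout).
#' @export
weighted_kappa_from_table <- function(tab,
                                      weights = c("linear", "quadratic")) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == ncol(tab), all(tab >= 0), sum(tab) > 0)
  k <- nrow(tab)
  if (k == 1L) {
    warning("single rating category: weighted kappa undefined")
    return(NA_real_)
  }
  w <- kappa_weights(k, weights)
  p <- tab / sum(tab)
  po <- sum(w * p)
  pe <- sum(w * outer(rowSums(p), colSums(p)))
  if (abs(1 - pe) < 1e-15) {
    warning("chance agreement is 1: weighted kappa undefined")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Weighted kappa for two raters' ordinal scores
#'
#' Interobserver agreement on an ordinal scale (e.g. three-point vessel
#' suppression or lesion conspicuity scores). Conventional interpretation
#' bands: 0.81-1.0 excellent, 0.61-0.80 good, 0.41-0.60 moderate,
#' 0.21-0.40 fair, 0-0.20 slight.
#'
#' @param scores n x 2 matrix or data frame of the two raters' scores per
#'   item.
#' @param categories The ordered score levels (default: the sorted union
#'   of observed scores).
#' @param weights `"linear"` (default) or `"quadratic"`.
#' @return The weighted kappa.
#' @export
weighted_kappa <- function(scores, categories = NULL,
                           weights = c("linear", "quadratic")) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == 2L, nrow(scores) >= 2L,
            all(!is.na(scores)))
  if (is.null(categories)) categories <- sort(unique(as.vector(scores)))
  f1 <- factor(scores[, 1], levels = categories)
  f2 <- factor(scores[, 2], levels = categories)
  weighted_kappa_from_table(table(f1, f2), weights = weights)
}
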