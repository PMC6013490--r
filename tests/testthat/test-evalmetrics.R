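# independent direct-formula weighted kappa used as a brute-force oracle
kappa_oracle <- function(tab, quadratic = FALSE) {
  k <- nrow(tab)
  n <- sum(tab)
  po <- 0; pe <- 0
  r <- rowSums(tab) / n
  cc <- colSums(tab) / n
  for (i in seq_len(k)) for (j in seq_len(k)) {
    w <- if (quadratic) 1 - ((i - j) / (k - 1))^2 else
      1 - abs(i - j) / (k - 1)
    po <- po + w * tab[i, j] / n
    pe <- pe + w * r[i] * cc[j]
  }
  (po - pe) / (1 - pe)
}

test_that("ROI placement produces nine disjoint vessel ROIs plus WM", {
  ph <- phantom48()
  rois <- place_phantom_rois(ph$truth)
  expect_length(rois$vessel_rois, 9L)
  types <- vapply(rois$vessel_rois, `[[`, numeric(1), "type")
  expect_equal(as.integer(table(types)), c(3L, 3L, 3L))
  all_rois <- c(list(rois$wm_roi), lapply(rois$vessel_rois, `[[`, "voxels"))
  for (i in seq_along(all_rois)) {
    expect_gt(length(all_rois[[i]]), 0L)
    for (j in seq_len(i - 1L))
      expect_length(intersect(all_rois[[i]], all_rois[[j]]), 0L)
  }
  # WM ROI really sits in clean white matter
  expect_true(all(ph$truth$label_map[rois$wm_roi] == 2L))
})

test_that("ROI placement fails when a vessel class is missing", {
  spec <- phantom_spec(grid_shape = c(48L, 48L, 48L),
                       vessel_counts = c(3L, 3L, 0L), n_lesions = 0L,
                       seed = 2L)
  truth <- generate_truth(spec)
  expect_error(place_phantom_rois(truth), "type 3")
})

test_that("roi_mean is the arithmetic mean and validates input", {
  v <- volume3d(array(0.7, c(8, 8, 8)))
  expect_equal(roi_mean(v, 1:10), 0.7)
  v$data[1] <- 0.2; v$data[2] <- 0.4
  expect_equal(roi_mean(v, 1:2), 0.3)
  expect_error(roi_mean(v, integer(0)), "empty")
  expect_error(roi_mean(v, c(1, 10000)), "out of bounds")
})

test_that("the suppression ratio follows its closed form", {
  expect_identical(vessel_suppression_ratio(0.5, 0), 2)
  expect_identical(vessel_suppression_ratio(0.37, 0.37), 1)
  expect_equal(vessel_suppression_ratio(0.4, 0.6), 0.8)
  expect_error(vessel_suppression_ratio(0, 0.5), "positive")
  expect_error(vessel_suppression_ratio(0.5, -0.1), "non-negative")
})

test_that("suppression report orders modalities and separates vessel types", {
  ph <- phantom48(seed = 13, residual_vessel_fraction = 0)
  rois <- place_phantom_rois(ph$truth)
  rep <- suppression_report(list(GRE = ph$pair$gre, BB = ph$pair$bb), rois)
  expect_equal(unique(rep$modality), c("GRE", "BB"))
  expect_equal(rep$vessel_type, rep(1:3, 2))
  # with full suppression the BB ratio beats GRE for every type
  for (t in 1:3)
    expect_gt(rep$r_s[rep$modality == "BB" & rep$vessel_type == t],
              rep$r_s[rep$modality == "GRE" & rep$vessel_type == t])
  expect_true(all(rep$r_s > 0 & rep$r_s <= 2))
})

test_that("detection on a lesion-bright volume scores perfectly", {
  ph <- phantom48()
  det <- detect_lesions(ph$pair$gre, ph$truth)
  expect_equal(det$tp + det$fn, nrow(ph$truth$lesions))
  ge2 <- ph$truth$lesions$diameter_mm >= 2
  expect_equal(det$tp_ge2mm, sum(ge2))
  expect_equal(det$sensitivity_ge2mm, 100)
  expect_equal(det$fp, 0L)
  expect_true(det$volume_detected)
})

test_that("an empty-truth phantom yields a flagged report", {
  spec <- phantom_spec(grid_shape = c(48L, 48L, 48L), n_lesions = 0L,
                       vessel_counts = c(3L, 3L, 4L), seed = 3L)
  truth <- generate_truth(spec)
  pair <- render_pair(truth, spec)
  det <- detect_lesions(pair$gre, truth)
  expect_true(is.na(det$sensitivity))
  expect_true(is.na(det$volume_detected))
  expect_equal(det$fp, 0L)
})

test_that("detection_summary reproduces simple tallies", {
  expect_equal(detection_summary(5, 10), 50)
  expect_error(detection_summary(11, 10))
})

test_that("weighted kappa matches the direct-formula oracle", {
  expect_equal(weighted_kappa(cbind(rep(1:3, 7)[1:20], rep(1:3, 7)[1:20])),
               1)
  set.seed(4)
  for (i in 1:50) {
    tab <- matrix(rpois(9, 4) + 1, 3, 3)
    expect_equal(weighted_kappa_from_table(tab), kappa_oracle(tab),
                 tolerance = 1e-12)
    expect_equal(weighted_kappa_from_table(tab, weights = "quadratic"),
                 kappa_oracle(tab, quadratic = TRUE), tolerance = 1e-12)
  }
})

test_that("independent raters give near-zero kappa", {
  set.seed(9)
  scores <- cbind(sample(1:3, 1e5, TRUE), sample(1:3, 1e5, TRUE))
  expect_lt(abs(weighted_kappa(scores)), 0.02)
})

test_that("quadratic weights on two categories equal unweighted kappa", {
  set.seed(5)
  tab <- matrix(c(30, 5, 8, 40), 2, 2)
  p <- tab / sum(tab)
  po <- sum(diag(p))
  pe <- sum(rowSums(p) * colSums(p))
  unweighted <- (po - pe) / (1 - pe)
  expect_equal(weighted_kappa_from_table(tab, weights = "quadratic"),
               unweighted, tolerance = 1e-12)
})

test_that("degenerate rating tables are flagged", {
  expect_warning(k <- weighted_kappa_from_table(matrix(10, 1, 1)),
                 "undefined")
  expect_true(is.na(k))
})
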