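test_that("brain extraction excludes a detached skull rim and covers the brain", {
  # 64^3 so the rim shell and its gap to the brain fit inside the grid
  spec <- phantom_spec(grid_shape = c(64L, 64L, 64L), n_lesions = 4L,
                       vessel_counts = c(3L, 3L, 4L),
                       lesion_radius_range_mm = c(0.8, 4),
                       skull_rim = TRUE, seed = 6L)
  truth <- generate_truth(spec)
  ph <- list(truth = truth, pair = render_pair(truth, spec))
  mask <- extract_brain(ph$pair$gre)
  rim <- ph$truth$label_map == 7L
  truebrain <- ph$truth$label_map %in% 1:6
  expect_equal(sum(mask & rim), 0L)
  expect_gte(sum(mask & truebrain) / sum(truebrain), 0.99)
  # one 26-connected component by construction
  lab <- bbsynth:::cpp_label_components(mask)
  expect_equal(attr(lab, "n_components"), 1L)
})

test_that("brain extraction fails on an all-background volume", {
  expect_error(extract_brain(volume3d(array(0.05, c(16, 16, 16)))))
})

test_that("registering a volume to itself recovers the identity", {
  ph <- phantom48()
  fit <- register_rigid(ph$pair$gre, ph$pair$gre)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$par[1:3])), 0.1)  # voxels
  expect_lt(max(abs(fit$par[4:6])), 0.1)  # degrees
  expect_gte(fit$metric_after, fit$metric_before)
})

test_that("a known translation is recovered within half a voxel", {
  ph <- phantom48()
  a <- ph$pair$gre$data
  shifted <- array(0, dim(a))
  shifted[6:48, , ] <- a[1:43, , ]  # content moved +5 voxels along x
  fit <- register_rigid(volume3d(shifted), ph$pair$gre)
  expect_lt(abs(fit$par[1] - 5), 0.5)
  expect_lt(max(abs(fit$par[2:3])), 0.5)
  expect_gte(fit$metric_after, fit$metric_before)
})

test_that("registered phantom pairs need no further alignment", {
  ph <- phantom48()
  fit <- register_rigid(ph$pair$bb, ph$pair$gre)
  expect_lt(max(abs(fit$par[1:3])), 0.5)
  expect_lt(max(abs(fit$par[4:6])), 1)
})

test_that("disjoint-content volumes are flagged as non-converged", {
  set.seed(1)
  a <- array(0, c(24, 24, 24)); a[4:8, 4:8, 4:8] <- 1
  b <- array(runif(24^3) > 0.5, c(24, 24, 24)) * 1.0
  fit <- register_rigid(volume3d(a), volume3d(b))
  expect_false(fit$converged)
})

test_that("study_pair validates grids and masks", {
  ph <- phantom48()
  expect_error(study_pair(ph$pair$gre,
                          volume3d(array(0.1, c(24, 24, 24)))),
               "grids differ")
  expect_error(study_pair(ph$pair$gre, ph$pair$bb,
                          brain_mask = array(FALSE, c(48, 48, 48))),
               "empty")
})
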