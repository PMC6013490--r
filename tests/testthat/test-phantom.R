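test_that("truth generation conserves counts and is deterministic", {
  spec <- phantom_spec(grid_shape = c(48L, 48L, 48L), n_lesions = 4L,
                       vessel_counts = c(3L, 3L, 4L),
                       lesion_radius_range_mm = c(0.8, 4), seed = 7L)
  t1 <- generate_truth(spec)
  t2 <- generate_truth(spec)
  expect_equal(nrow(t1$lesions), 4L)
  types <- vapply(t1$vessel_segments, `[[`, integer(1), "type")
  expect_equal(as.integer(table(factor(types, levels = 1:3))),
               c(3L, 3L, 4L))
  expect_identical(t1$label_map, t2$label_map)
  expect_identical(t1$lesions, t2$lesions)
  expect_identical(t1$residual_vessel_voxels, t2$residual_vessel_voxels)
  p1 <- render_pair(t1, spec)
  p2 <- render_pair(t2, spec)
  expect_identical(p1$gre$data, p2$gre$data)
  expect_identical(p1$bb$data, p2$bb$data)
})

test_that("infeasible packing raises a placement error", {
  spec <- phantom_spec(grid_shape = c(32L, 32L, 32L), n_lesions = 500L,
                       lesion_radius_range_mm = c(2, 4),
                       vessel_counts = c(1L, 1L, 1L), seed = 1L)
  expect_error(generate_truth(spec), "placement error")
})

test_that("label map partitions the grid into exclusive classes", {
  ph <- phantom48()
  expect_true(all(ph$truth$label_map %in% 0:7))
  # every lesion center lies inside brain tissue
  idx <- lesion_center_index(ph$truth)
  expect_true(all(ph$truth$label_map[idx] == 6L))
})

test_that("rendered contrast matches the modality roles", {
  ph <- phantom48()
  lab <- ph$truth$label_map
  gre <- ph$pair$gre$data
  bb <- ph$pair$bb$data
  wm <- lab == 2L
  gm <- lab == 1L
  vess <- vessel_voxels(ph$truth)
  les <- lesion_voxels(ph$truth)
  nonres <- vess
  nonres[ph$truth$residual_vessel_voxels] <- FALSE
  # GRE: vessels and lesions brighter than WM
  expect_gt(mean(gre[vess]), mean(gre[wm]))
  expect_gt(mean(gre[les]), mean(gre[wm]))
  # BB: suppressed vessels near background, lesions still bright
  bg <- lab == 0L
  expect_lt(abs(mean(bb[nonres]) - mean(bb[bg])), 0.05)
  expect_gt(mean(bb[les]), mean(bb[wm]))
  # BB has lower WM/GM contrast than GRE
  expect_lt(abs(mean(bb[wm]) - mean(bb[gm])),
            abs(mean(gre[wm]) - mean(gre[gm])))
})

test_that("noiseless rendering reproduces tissue levels exactly", {
  spec <- phantom_spec(grid_shape = c(48L, 48L, 48L), n_lesions = 2L,
                       vessel_counts = c(3L, 3L, 3L),
                       lesion_radius_range_mm = c(1.5, 3),
                       noise_sd = 0, bb_blur_sigma_vox = 0,
                       residual_vessel_fraction = 0, seed = 3L)
  truth <- generate_truth(spec)
  pair <- render_pair(truth, spec)
  # BB at a type-2 vessel centerline voxel equals background exactly
  seg <- truth$vessel_segments[[which(vapply(truth$vessel_segments, `[[`,
                                             integer(1), "type") == 2L)[1]]]
  mid <- round(seg$points[ceiling(nrow(seg$points) / 2), ])
  expect_identical(pair$bb$data[mid[1], mid[2], mid[3]],
                   spec$tissue_levels_bb[["background"]])
  # GRE lesion-center intensity equals the lesion level exactly
  idx <- lesion_center_index(truth)
  expect_true(all(pair$gre$data[idx] == spec$tissue_levels_gre[["lesion"]]))
})

test_that("residual vessel fraction is matched on large vessel sets", {
  spec <- phantom_spec(grid_shape = c(80L, 80L, 80L),
                       vessel_counts = c(7L, 10L, 10L),
                       vessel_radius_mm = c(3.5, 2.5, 1),
                       n_lesions = 0L, noise_sd = 0, bb_blur_sigma_vox = 0,
                       residual_vessel_fraction = 0.1, seed = 9L)
  truth <- generate_truth(spec)
  vess <- vessel_voxels(truth)
  expect_gte(sum(vess), 1e4)
  pair <- render_pair(truth, spec)
  bright <- pair$bb$data > 0.5 * (spec$tissue_levels_gre[["vessel"]] +
                                    spec$tissue_levels_bb[["background"]])
  frac <- sum(bright & vess) / sum(vess)
  expect_lt(abs(frac - 0.1), 0.02)
})
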