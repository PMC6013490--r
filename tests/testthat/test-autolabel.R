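two_component_volume <- function(n = 24, seed = 2) {
  with_seed <- getFromNamespace("with_seed", "bbsynth")
  with_seed(seed, {
    a <- array(rnorm(n^3, 0.2, 0.02), c(n, n, n))
    hot <- array(runif(n^3) < 0.5, c(n, n, n))
    a[hot] <- rnorm(sum(hot), 0.8, 0.02)
    a <- pmin(pmax(a, 0), 1)
    dim(a) <- c(n, n, n)
    list(vol = volume3d(a), hot = hot)
  })
}

test_that("FCM separates a two-component volume almost perfectly", {
  tc <- two_component_volume()
  params <- autolabel_params(n_clusters = 2L)
  fcm <- fcm_cluster(tc$vol, array(TRUE, dim(tc$vol$data)), params)
  expect_true(fcm$converged)
  hard <- defuzzify(fcm)
  acc <- mean((hard == 2L) == tc$hot)
  expect_gte(acc, 0.99)
  # memberships sum to one, objective never increases
  expect_lt(max(abs(rowSums(fcm$memberships) - 1)), 1e-6)
  expect_true(all(diff(fcm$objective) <= 1e-9))
  expect_equal(fcm$centroids, sort(fcm$centroids))
})

test_that("FCM agrees with an independent implementation", {
  tc <- two_component_volume(n = 12, seed = 8)
  params <- autolabel_params(n_clusters = 2L, fcm_tol = 1e-8)
  fcm <- fcm_cluster(tc$vol, array(TRUE, dim(tc$vol$data)), params)
  x <- as.numeric(tc$vol$data)
  ref <- e1071::cmeans(matrix(x), centers = matrix(fcm$centroids), m = 2,
                       iter.max = 300)
  expect_equal(sort(fcm$centroids), sort(as.numeric(ref$centers)),
               tolerance = 1e-3)
})

test_that("FCM rejects constant regions", {
  expect_error(fcm_cluster(volume3d(array(0.5, c(8, 8, 8))),
                           array(TRUE, c(8, 8, 8))),
               "degenerate")
})

test_that("region growing recovers a bright tube and spares white matter", {
  ph <- phantom48()
  brain <- ph$truth$label_map %in% 1:6
  dim(brain) <- dim(ph$truth$label_map)
  params <- autolabel_params()
  fcm <- fcm_cluster(ph$pair$gre, brain, params)
  cand <- defuzzify(fcm) == params$n_clusters
  dim(cand) <- dim(brain)
  m <- grow_vessel_mask(ph$pair$gre, cand, params, brain)
  vess <- vessel_voxels(ph$truth)
  wm <- ph$truth$label_map == 2L
  expect_gte(sum(m$core & vess) / sum(vess), 0.95)
  expect_lte(sum(m$core & wm) / sum(wm), 0.01)
  expect_true(all(!m$core | cand))  # core is a subset of the candidate class
})

test_that("a candidate region below the seed threshold yields an empty mask", {
  a <- array(0.5, c(12, 12, 12))
  a[1] <- 0.51  # not constant, still far below the seed floor
  cand <- array(TRUE, c(12, 12, 12))
  expect_warning(m <- grow_vessel_mask(volume3d(a), cand,
                                       autolabel_params()),
                 "seed threshold")
  expect_equal(sum(m$core), 0L)
})

test_that("fill_and_blend follows its pointwise definition", {
  d <- c(8, 8, 8)
  base <- array(0.8, d)
  bb <- array(0.2, d)
  core <- array(FALSE, d); core[4, 4, 4] <- TRUE
  ring <- array(FALSE, d); ring[5, 4, 4] <- TRUE
  mask <- vessel_mask(core, ring, 1L)
  params <- autolabel_params(blend_weight_bb = 0.5)
  out <- fill_and_blend(volume3d(base), volume3d(bb), mask, params)
  expect_identical(out$data[4, 4, 4], 0.2)             # core: bb exactly
  expect_identical(out$data[5, 4, 4], 0.5 * 0.2 + 0.5 * 0.8)  # ring blend
  untouched <- !(core | ring)
  expect_identical(out$data[untouched], base[untouched])
})

test_that("the difference-image pass flags exactly the remaining segment", {
  d <- c(16, 16, 16)
  bb <- array(0.1, d)
  interm <- array(0.1, d)
  interm[] <- interm + runif(prod(d), 0, 0.05)  # everywhere within 0.05
  seg <- array(FALSE, d); seg[5:9, 8, 8] <- TRUE
  interm[seg] <- 0.9
  params <- autolabel_params(residual_threshold = 0.3)
  m <- residual_vessel_mask(volume3d(interm), volume3d(bb), params)
  expect_identical(m$core, seg)
  # identical images give an empty mask
  m0 <- residual_vessel_mask(volume3d(bb), volume3d(bb), params)
  expect_equal(sum(m0$core), 0L)
  # a threshold above the maximum difference gives an empty mask
  m1 <- residual_vessel_mask(volume3d(interm), volume3d(bb),
                             autolabel_params(residual_threshold = 0.95))
  expect_equal(sum(m1$core), 0L)
})

test_that("vessel mask core and ring must be disjoint", {
  core <- array(TRUE, c(4, 4, 4))
  expect_error(vessel_mask(core, core, 1L), "disjoint")
})

test_that("auto-labelling suppresses vessels and preserves lesions", {
  fx <- autolabelled48()
  vess <- vessel_voxels(fx$truth)
  les <- lesion_voxels(fx$truth)
  gre <- fx$pair$gre$data
  synth <- fx$res$synth$data
  # vessels darker in synthetic BB than in GRE
  expect_lt(mean(synth[vess]), mean(gre[vess]))
  # masks cover vessels, spare lesions
  cov <- mask_union(fx$res)
  expect_gte(sum(cov & vess) / sum(vess), 0.95)
  expect_lt(sum(cov & les) / sum(les), 0.01)
  # lesion centers untouched within 5%
  idx <- lesion_center_index(fx$truth)
  expect_lt(max(abs(synth[idx] - gre[idx]) / gre[idx]), 0.05)
  # deterministic
  res2 <- synthesize_bb(study_pair(fx$pair$gre, fx$pair$bb, fx$brain,
                                   registered = TRUE))
  expect_identical(res2$synth$data, synth)
})
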