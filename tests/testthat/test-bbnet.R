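dyadic_volume <- function(dims, seed = 1) {
  # voxel values on a 1/256 grid are exactly representable in single
  # precision, so engine round trips are bitwise exact
  with_seed <- getFromNamespace("with_seed", "bbsynth")
  with_seed(seed, array(sample(0:255, prod(dims), TRUE) / 256, dims))
}

test_that("the full-scale architecture has the stated parameter structure", {
  cfg <- network_config(n_conv_layers = 25L, n_feature_maps = 64L)
  net <- build_network(cfg, rng_seed = 1)
  expect_length(net$layers, 25L)
  widths <- vapply(net$layers, function(l) ncol(l$W), integer(1))
  expect_equal(widths, c(rep(64L, 24), 1L))
  fanins <- vapply(net$layers, function(l) nrow(l$W), integer(1))
  expect_equal(fanins, c(27L, rep(27L * 64L, 24)))
  # hidden layers carry batch-norm parameters, the final layer does not
  expect_true(all(vapply(net$layers[1:24], function(l)
    !is.null(l$gamma), logical(1))))
  expect_null(net$layers[[25]]$gamma)
  expect_error(network_config(n_conv_layers = 1L))
})

test_that("zeroing the final layer makes the network an exact identity", {
  net <- build_network(desk_network_config(), rng_seed = 2)
  net$layers[[5]]$W[] <- 0
  net$layers[[5]]$b[] <- 0
  x <- dyadic_volume(c(20, 22, 24))
  out <- infer_bbnet(net, volume3d(x))
  expect_identical(out$data, x)
  expect_equal(out$modality, "DL_BB")
})

test_that("output shape equals input shape on arbitrary grids", {
  net <- build_network(desk_network_config(), rng_seed = 3)
  for (d in list(c(12, 18, 25), c(31, 31, 31), c(40, 16, 22))) {
    out <- infer_bbnet(net, volume3d(array(runif(prod(d)), d)))
    expect_identical(dim(out$data), as.integer(d))
    expect_true(all(is.finite(out$data)))
  }
})

test_that("tiled inference equals a whole-volume pass", {
  # batch-normalized configuration, so tiling is checked through the
  # running-statistics inference path too
  net <- build_network(network_config(n_conv_layers = 5L,
                                      n_feature_maps = 16L,
                                      use_batchnorm = TRUE), rng_seed = 4)
  v <- volume3d(array(runif(40^3), c(40, 40, 40)))
  direct <- infer_bbnet(net, v, tile = 40)
  tiled <- infer_bbnet(net, v, tile = 16)
  expect_lt(max(abs(direct$data - tiled$data)), 1e-5)
})

test_that("the learning-rate schedule steps by a factor of 10 every 10 epochs", {
  cfg <- train_config()  # full-scale defaults: 1e-5, /10 every 10
  expect_equal(lr_schedule(1, cfg), 1e-5)
  expect_equal(lr_schedule(9, cfg), 1e-5)
  expect_equal(lr_schedule(10, cfg), 1e-6)
  expect_equal(lr_schedule(19, cfg), 1e-6)
  expect_equal(lr_schedule(20, cfg), 1e-7)
})

test_that("gradients are clipped to the global-norm bound", {
  g <- list(matrix(5, 10, 10), rep(-5, 100))  # norm 50 * sqrt(2)... scaled
  g[[1]][] <- 5 / sqrt(2); g[[2]][] <- -5 / sqrt(2)  # joint norm 50
  clipped <- clip_gradients(g, 1)
  expect_equal(attr(clipped, "norm_before"), 50, tolerance = 1e-12)
  expect_equal(attr(clipped, "norm_after"), 1, tolerance = 1e-12)
  norm <- sqrt(sum(unlist(clipped)^2))
  expect_lte(norm, 1 + 1e-12)
  # below the bound gradients pass through unchanged
  small <- clip_gradients(list(c(0.1, 0.2)), 1)
  expect_equal(small[[1]], c(0.1, 0.2))
})

test_that("patch sampling honors its contract", {
  ph <- phantom48()
  cfg <- train_config(patch_size = 31L, rng_seed = 11L)
  o <- sample_patches(ph$pair$gre, ph$pair$bb, cfg, n = 100L)
  expect_equal(nrow(o), 100L)
  expect_true(all(o >= 1L) && all(o <= 48L - 31L + 1L))
  p_in <- extract_patch(ph$pair$gre, o[1, ], 31L)
  p_lab <- extract_patch(ph$pair$bb, o[1, ], 31L)
  expect_identical(dim(p_in), rep(31L, 3))
  expect_identical(dim(p_lab), rep(31L, 3))
  # fixed seed reproduces the origin list
  o2 <- sample_patches(ph$pair$gre, ph$pair$bb, cfg, n = 100L)
  expect_identical(o, o2)
  # foreground floor holds when truth is supplied
  cfg2 <- train_config(fg_fraction = 0.6, rng_seed = 12L)
  of <- sample_patches(ph$pair$gre, ph$pair$bb, cfg2, truth = ph$truth,
                       n = 50L)
  fg <- ph$truth$label_map >= 3L & ph$truth$label_map <= 6L
  contains_fg <- apply(of, 1, function(org) {
    any(fg[org[1]:(org[1] + 30), org[2]:(org[2] + 30),
           org[3]:(org[3] + 30)])
  })
  expect_gte(mean(contains_fg), 0.6)
})

test_that("volumes smaller than the patch are rejected", {
  v <- volume3d(array(runif(16^3), c(16, 16, 16)))
  expect_error(sample_patches(v, v, train_config(patch_size = 31L)),
               "smaller than")
})

test_that("training drives the loss down on a one-patch overfit problem", {
  fx <- autolabelled48()
  # constant rate: each epoch is one optimizer step here, so the usual
  # every-10-epochs decay would freeze the rate long before 200 steps
  cfg <- desk_train_config(rng_seed = 21L, patches_per_volume = 1L,
                           fg_fraction = 1, batch_size = 1L,
                           n_epochs = 200L, patience = 1000L,
                           lr_decay_every_epochs = 1000L)
  net <- build_network(desk_network_config(), rng_seed = 21L)
  fit <- train_bbnet(net, list(list(input = fx$pair$gre,
                                    label = fx$res$synth)), cfg = cfg,
                     truths = list(fx$truth))
  expect_lt(tail(fit$log$train_loss, 1), 0.1 * fit$log$train_loss[1])
  expect_equal(fit$stop_reason, "max_epochs")
  expect_equal(fit$log$lr[1], 1e-3)
})

test_that("the training loop's epoch log follows the step decay", {
  fx <- autolabelled48()
  cfg <- desk_train_config(rng_seed = 24L, patches_per_volume = 2L,
                           batch_size = 2L, n_epochs = 11L,
                           patience = 1000L)
  net <- build_network(desk_network_config(), rng_seed = 24L)
  fit <- train_bbnet(net, list(list(input = fx$pair$gre,
                                    label = fx$res$synth)), cfg = cfg)
  expect_equal(fit$log$lr[9], 1e-3)
  expect_equal(fit$log$lr[10], 1e-4)
  expect_equal(fit$log$lr[11], 1e-4)
})

test_that("fine-tuning starts at a tenth of the training rate", {
  fx <- autolabelled48()
  cfg <- desk_train_config(rng_seed = 22L, patches_per_volume = 2L,
                           batch_size = 2L)
  net <- build_network(desk_network_config(), rng_seed = 22L)
  ft <- fine_tune_bbnet(net, list(list(input = fx$pair$gre,
                                       label = fx$res$synth)),
                        cfg = cfg, n_epochs = 1L)
  expect_equal(ft$log$lr[1], 1e-3 / 10)
  # zero epochs leaves the network unchanged
  ft0 <- fine_tune_bbnet(net, list(list(input = fx$pair$gre,
                                        label = fx$res$synth)),
                         cfg = cfg, n_epochs = 0L)
  expect_identical(ft0$network$layers, net$layers)
  expect_equal(ft0$stop_epoch, 0L)
  expect_true(ft0$stop_reason %in% c("max_epochs", "validation_saturation"))
})

test_that("training is reproducible under a fixed seed", {
  fx <- autolabelled48()
  cfg <- desk_train_config(rng_seed = 23L, patches_per_volume = 4L,
                           batch_size = 2L, n_epochs = 2L)
  # batch-normalized net: covers the BN training path and its statistics
  run <- function() {
    net <- build_network(network_config(n_conv_layers = 3L,
                                        n_feature_maps = 8L,
                                        use_batchnorm = TRUE),
                         rng_seed = 23L)
    train_bbnet(net, list(list(input = fx$pair$gre, label = fx$res$synth)),
                cfg = cfg)
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$log, f2$log)
  expect_identical(f1$network$layers, f2$network$layers)
})
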