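#' Network architecture configuration
#'
#' The image-to-image 3D CNN: a stack of 3x3x3 convolution layers with
#' batch normalization and ReLU after every layer except the last, one
#' feature map in the final layer, zero padding of one voxel on every face
#' (so the output grid equals the input grid), and an elementwise residual
#' addition of the network input to the final convolution output. The
#' full-scale configuration is 25 layers of width 64; a desk-scale
#' configuration (5 layers, width 16) is provided for CPU-sized
#' experiments.
#'
#' @param n_conv_layers Number of convolution layers (>= 2; full scale 25).
#' @param kernel_size Per-axis kernel size; the engine implements 3x3x3.
#' @param n_feature_maps Hidden width (full scale 64).
#' @param use_batchnorm Batch normalization after each hidden convolution.
#' @param residual_add Elementwise addition of the input to the final
#'   convolution output.
#' @return An object of class `bb_network_config`.
#' @export
network_config <- function(n_conv_layers = 25L, kernel_size = c(3L, 3L, 3L),
                           n_feature_maps = 64L, use_batchnorm = TRUE,
                           residual_add = TRUE) {
  stopifnot(n_conv_layers >= 2L, n_feature_maps >= 1L)
  if (!all(kernel_size == 3L))
    stop("the convolution engine implements 3x3x3 kernels", call. = FALSE)
  structure(list(n_conv_layers = as.integer(n_conv_layers),
                 kernel_size = c(3L, 3L, 3L),
                 n_feature_maps = as.integer(n_feature_maps),
                 final_maps = 1L, use_batchnorm = isTRUE(use_batchnorm),
                 residual_add = isTRUE(residual_add), padding_vox = 1L),
            class = "bb_network_config")
}

#' @rdname network_config
#' @export
desk_network_config <- function() {
  # the desk-scale net forgoes batch normalization: at a few hundred
  # optimizer steps, per-batch whitening discards the absolute intensity
  # scale that separates enhancing lesions from the brighter blood pool,
  # and training see-saws between suppression and lesion preservation;
  # without it convergence is monotone (the full-scale configuration
  # keeps batch normalization)
  network_config(n_conv_layers = 5L, n_feature_maps = 16L,
                 use_batchnorm = FALSE)
}

#' Training configuration
#'
#' Optimization hyperparameters. The full-scale defaults follow the
#' reference schedule: Adam at 1e-5 decayed by a factor of 10 every 10
#' epochs, gradient clipped at global norm 1, batch size 10, MSE loss,
#' 31x31x31 co-located patches, 30-epoch cap with validation-saturation
#' stopping. `desk_train_config()` is the CPU-sized counterpart used with
#' [desk_network_config()]: a conventional Adam rate (1e-3) and small
#' patch/epoch budget so a phantom study trains in minutes.
#'
#' @param learning_rate Initial Adam learning rate.
#' @param lr_decay_factor Learning-rate division factor.
#' @param lr_decay_every_epochs Epoch period of the decay.
#' @param grad_clip Global-norm gradient clipping bound.
#' @param batch_size Patches per optimization step.
#' @param n_epochs Epoch cap.
#' @param patch_size Cubic patch edge (voxels).
#' @param patches_per_volume Patches sampled from each training volume.
#' @param val_patches_per_volume Patches sampled from each validation
#'   volume.
#' @param fg_fraction Minimum fraction of sampled patches that must
#'   contain vessel or lesion voxels when ground truth is available.
#' @param patience Epochs without validation improvement before stopping.
#' @param min_delta Minimum relative validation improvement that counts.
#' @param bn_momentum Running-statistics momentum for batch normalization.
#' @param rng_seed Integer seed controlling sampling, shuffling and
#'   initialization.
#' @param verbose Print per-epoch losses.
#' @return An object of class `bb_train_config`.
#' @export
train_config <- function(learning_rate = 1e-5, lr_decay_factor = 10,
                         lr_decay_every_epochs = 10L, grad_clip = 1,
                         batch_size = 10L, n_epochs = 30L, patch_size = 31L,
                         patches_per_volume = 500L,
                         val_patches_per_volume = 100L,
                         fg_fraction = 0.5, patience = 5L, min_delta = 0,
                         bn_momentum = 0.1, rng_seed = 1L, verbose = FALSE) {
  stopifnot(learning_rate > 0, lr_decay_factor > 0,
            lr_decay_every_epochs >= 1L, grad_clip > 0, batch_size >= 1L,
            n_epochs >= 0L, patch_size >= 3L, patches_per_volume >= 1L,
            val_patches_per_volume >= 1L,
            fg_fraction >= 0, fg_fraction <= 1, patience >= 1L,
            min_delta >= 0, bn_momentum > 0, bn_momentum <= 1)
  structure(list(learning_rate = learning_rate,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every_epochs = as.integer(lr_decay_every_epochs),
                 grad_clip = grad_clip, batch_size = as.integer(batch_size),
                 loss = "mse", n_epochs = as.integer(n_epochs),
                 patch_size = as.integer(patch_size),
                 patches_per_volume = as.integer(patches_per_volume),
                 val_patches_per_volume = as.integer(val_patches_per_volume),
                 fg_fraction = fg_fraction, patience = as.integer(patience),
                 min_delta = min_delta, bn_momentum = bn_momentum,
                 rng_seed = as.integer(rng_seed),
                 verbose = isTRUE(verbose)),
            class = "bb_train_config")
}

#' @rdname train_config
#' @param ... Overrides passed through to [train_config()].
#' @export
desk_train_config <- function(rng_seed = 1L, ...) {
  args <- list(learning_rate = 1e-3, batch_size = 5L, n_epochs = 8L,
               patches_per_volume = 90L, val_patches_per_volume = 60L,
               fg_fraction = 0.6, patience = 8L, min_delta = 0.005,
               rng_seed = rng_seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(train_config, args)
}

#' Learning-rate schedule
#'
#' The step schedule: the rate is divided by `lr_decay_factor` every
#' `lr_decay_every_epochs` epochs (so with the full-scale defaults, epochs
#' 1-9 run at 1e-5 and epoch 10 drops to 1e-6).
#'
#' @param epoch Epoch number (1-based).
#' @param cfg A [train_config()].
#' @return The learning rate in effect at `epoch`.
#' @export
lr_schedule <- function(epoch, cfg) {
  stopifnot(epoch >= 1)
  cfg$learning_rate *
    (1 / cfg$lr_decay_factor)^(epoch %/% cfg$lr_decay_every_epochs)
}

#' Clip gradients by global norm
#'
#' Scales a collection of gradient arrays so that their joint L2 norm does
#' not exceed `max_norm` — the rule applied to every optimization step
#' during training.
#'
#' @param grads List of numeric arrays/vectors.
#' @param max_norm Positive bound on the global norm.
#' @return The scaled list, with attributes `norm_before` / `norm_after`.
#' @export
clip_gradients <- function(grads, max_norm = 1) {
  stopifnot(is.list(grads), max_norm > 0)
  cpp_clip_global_norm(grads, max_norm)
}

#' Build a randomly initialized network
#'
#' Convolution weights use variance-scaled rectifier (MSRA) initialization,
#' `sd = sqrt(2 / fan_in)` with `fan_in = 27 * n_input_channels`; biases
#' start at zero, batch-norm scale/shift at 1/0.
#'
#' @param cfg A [network_config()].
#' @param rng_seed Integer seed for the weight draw.
#' @return An object of class `bb_network`: a list with `layers` (each
#'   carrying `W` of shape `(27 * C_in) x C_out`, `b`, and batch-norm
#'   parameters on hidden layers) and `config`.
#' @export
build_network <- function(cfg = network_config(), rng_seed = 1L) {
  stopifnot(inherits(cfg, "bb_network_config"))
  L <- cfg$n_conv_layers
  width <- cfg$n_feature_maps
  with_seed(rng_seed, {
    layers <- vector("list", L)
    for (l in seq_len(L)) {
      c_in <- if (l == 1L) 1L else width
      c_out <- if (l == L) 1L else width
      fan_in <- 27L * c_in
      W <- matrix(rnorm(fan_in * c_out, sd = sqrt(2 / fan_in)),
                  nrow = fan_in, ncol = c_out)
      ly <- list(W = W, b = numeric(c_out))
      if (cfg$use_batchnorm && l < L) {
        ly$gamma <- rep(1, c_out)
        ly$beta <- numeric(c_out)
        ly$run_mean <- numeric(c_out)
        ly$run_var <- rep(1, c_out)
      }
      layers[[l]] <- ly
    }
    structure(list(layers = layers, config = cfg), class = "bb_network")
  })
}

#' @export
print.bb_network <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$layers, function(l)
    length(l$W) + length(l$b) + length(l$gamma) + length(l$beta),
    numeric(1)))
  cat(sprintf("<bb_network> %d conv layers (3x3x3), width %d, %s%s%d parameters\n",
              cfg$n_conv_layers, cfg$n_feature_maps,
              if (cfg$use_batchnorm) "batchnorm+ReLU, " else "ReLU, ",
              if (cfg$residual_add) "residual, " else "", round(n_par)))
  invisible(x)
}

#' Sample co-located patch origins from a volume pair
#'
#' Draws seeded-random patch origins valid for both volumes (the pair is
#' registered, so one origin serves input and label). When phantom truth is
#' supplied, at least `cfg$fg_fraction` of the patches are guaranteed to
#' contain vessel or lesion voxels.
#'
#' @param input,label [volume3d()] objects (or arrays) of equal shape.
#' @param cfg A [train_config()].
#' @param truth Optional [generate_truth()] result for the volume.
#' @param n Number of patches (defaults to `cfg$patches_per_volume`).
#' @param rng_seed Seed (defaults to `cfg$rng_seed`).
#' @return Integer matrix with columns `x`, `y`, `z` of 1-based origins.
#' @export
sample_patches <- function(input, label, cfg = train_config(), truth = NULL,
                           n = NULL, rng_seed = NULL) {
  input <- as_volume3d(input)
  label <- as_volume3d(label)
  if (!identical(dim(input$data), dim(label$data)))
    stop("input and label grids differ", call. = FALSE)
  P <- cfg$patch_size
  dims <- dim(input$data)
  if (any(dims < P))
    stop(sprintf("volume (%s) smaller than patch size %d",
                 paste(dims, collapse = "x"), P), call. = FALSE)
  if (is.null(n)) n <- cfg$patches_per_volume
  if (is.null(rng_seed)) rng_seed <- cfg$rng_seed
  hi <- dims - P + 1L
  fg <- les <- NULL
  if (!is.null(truth)) {
    stopifnot(inherits(truth, "bb_phantom_truth"))
    fg_idx <- which(truth$label_map >= PHANTOM_LABELS[["vessel1"]] &
                      truth$label_map <= PHANTOM_LABELS[["lesion"]])
    if (length(fg_idx)) fg <- index_to_coord(fg_idx, dims)
    les_idx <- which(truth$label_map == PHANTOM_LABELS[["lesion"]])
    if (length(les_idx)) les <- index_to_coord(les_idx, dims)
  }
  with_seed(rng_seed, {
    draw <- function(k) cbind(x = sample.int(hi[1], k, replace = TRUE),
                              y = sample.int(hi[2], k, replace = TRUE),
                              z = sample.int(hi[3], k, replace = TRUE))
    contains <- function(coords, o) {
      any(coords[, 1] >= o[1] & coords[, 1] < o[1] + P &
            coords[, 2] >= o[2] & coords[, 2] < o[2] + P &
            coords[, 3] >= o[3] & coords[, 3] < o[3] + P)
    }
    # resample rows of `origins` flagged FALSE in `ok` until `need` rows
    # satisfy the predicate (bounded retries keep this deterministic-cost)
    topup <- function(origins, ok, need, pred) {
      tries <- 0L
      while (sum(ok) < need && tries < 80L) {
        tries <- tries + 1L
        rows <- which(!ok)[seq_len(min(sum(!ok), need - sum(ok)))]
        cand <- draw(length(rows))
        keep <- apply(cand, 1, pred)
        if (any(keep)) {
          origins[rows[keep], ] <- cand[keep, , drop = FALSE]
          ok[rows[keep]] <- TRUE
        }
      }
      list(origins = origins, ok = ok)
    }
    origins <- draw(n)
    if (!is.null(fg) && cfg$fg_fraction > 0) {
      need_fg <- ceiling(cfg$fg_fraction * n)
      is_fg <- apply(origins, 1, function(o) contains(fg, o))
      up <- topup(origins, is_fg, need_fg, function(o) contains(fg, o))
      origins <- up$origins
      # lesions are a small minority of foreground voxels; dedicate half of
      # the foreground quota to patches centered on (jittered) lesion
      # centers so the preservation target is strongly represented
      if (!is.null(truth) && nrow(truth$lesions) > 0L) {
        need_les <- ceiling(need_fg / 2)
        centers <- as.matrix(truth$lesions[, c("x", "y", "z")])
        pick <- centers[sample.int(nrow(centers), need_les, replace = TRUE),
                        , drop = FALSE]
        jit <- matrix(sample(-5:5, 3L * need_les, replace = TRUE),
                      ncol = 3L)
        org <- pick + jit - (P %/% 2L)
        for (d3 in 1:3) org[, d3] <- pmin(pmax(org[, d3], 1L), hi[d3])
        rows <- sample.int(n, need_les)
        origins[rows, ] <- org
      }
    }
    origins
  })
}

#' Extract a cubic patch
#'
#' @param vol A [volume3d()] or 3D array.
#' @param origin Integer length-3, 1-based patch origin.
#' @param size Patch edge length.
#' @return A 3D array of dimension `size^3`.
#' @export
extract_patch <- function(vol, origin, size) {
  a <- if (inherits(vol, "volume3d")) vol$data else vol
  stopifnot(all(origin >= 1L), all(origin + size - 1L <= dim(a)))
  a[origin[1]:(origin[1] + size - 1L),
    origin[2]:(origin[2] + size - 1L),
    origin[3]:(origin[3] + size - 1L)]
}

# assemble the volume lists + origin tables consumed by the C++ trainer
prepare_training_set <- function(pairs, cfg, truths, n_per_volume,
                                 seed_offset) {
  vols_in <- list()
  vols_lab <- list()
  origins <- NULL
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    input <- as_volume3d(p$input)
    label <- as_volume3d(p$label)
    o <- sample_patches(input, label, cfg,
                        truth = if (is.null(truths)) NULL else truths[[i]],
                        n = n_per_volume,
                        rng_seed = cfg$rng_seed + seed_offset + i)
    vols_in[[i]] <- input$data
    vols_lab[[i]] <- label$data
    origins <- rbind(origins, cbind(vol = i, o))
  }
  list(vols_in = vols_in, vols_lab = vols_lab, origins = origins)
}

#' Train the network on co-located patch pairs
#'
#' Adam with global-norm gradient clipping and the step learning-rate
#' schedule, MSE loss between network output and label patches, optional
#' validation-saturation early stopping (training stops once the
#' validation loss has not improved by `min_delta` for `patience` epochs).
#'
#' @param network A [build_network()] result.
#' @param train_pairs List of `list(input = , label = )` volume pairs.
#' @param val_pairs Like `train_pairs`; may be empty (then training stops
#'   only at `n_epochs`).
#' @param cfg A [train_config()].
#' @param truths,val_truths Optional lists of [generate_truth()] results
#'   aligned with the pairs (enables foreground-aware patch sampling).
#' @return List with `network` (trained), `log` (data frame: epoch,
#'   train_loss, val_loss, lr), `stop_epoch` and `stop_reason`
#'   (`"max_epochs"` or `"validation_saturation"`).
#' @export
train_bbnet <- function(network, train_pairs, val_pairs = list(),
                        cfg = train_config(), truths = NULL,
                        val_truths = NULL) {
  stopifnot(inherits(network, "bb_network"), length(train_pairs) >= 1L)
  if (cfg$n_epochs == 0L) {
    return(list(network = network,
                log = data.frame(epoch = integer(0),
                                 train_loss = numeric(0),
                                 val_loss = numeric(0), lr = numeric(0)),
                stop_epoch = 0L, stop_reason = "max_epochs"))
  }
  tr <- prepare_training_set(train_pairs, cfg, truths,
                             cfg$patches_per_volume, seed_offset = 0L)
  n_train_vols <- length(tr$vols_in)
  vols_in <- tr$vols_in
  vols_lab <- tr$vols_lab
  origins <- tr$origins
  val_origins <- matrix(integer(0), nrow = 0, ncol = 4)
  if (length(val_pairs)) {
    va <- prepare_training_set(val_pairs, cfg, val_truths,
                               cfg$val_patches_per_volume,
                               seed_offset = 10000L)
    vols_in <- c(vols_in, va$vols_in)
    vols_lab <- c(vols_lab, va$vols_lab)
    va$origins[, 1] <- va$origins[, 1] + n_train_vols
    val_origins <- va$origins
  }
  ccfg <- c(cfg, list(residual_add = network$config$residual_add))
  res <- cnn_train_cpp(vols_in, vols_lab, origins, val_origins,
                       network$layers, ccfg)
  network$layers <- res$weights
  log <- data.frame(epoch = seq_along(res$train_loss),
                    train_loss = res$train_loss, val_loss = res$val_loss,
                    lr = res$lr)
  list(network = network, log = log, stop_epoch = res$stop_epoch,
       stop_reason = res$stop_reason)
}

#' Fine-tune a trained network
#'
#' Identical to [train_bbnet()] except that the initial learning rate is
#' one tenth of `cfg$learning_rate` and the epoch cap defaults to 60.
#'
#' @inheritParams train_bbnet
#' @param n_epochs Epoch cap for fine-tuning.
#' @return As [train_bbnet()].
#' @export
fine_tune_bbnet <- function(network, train_pairs, val_pairs = list(),
                            cfg = train_config(), truths = NULL,
                            val_truths = NULL, n_epochs = 60L) {
  cfg$learning_rate <- cfg$learning_rate / 10
  cfg$n_epochs <- as.integer(n_epochs)
  train_bbnet(network, train_pairs, val_pairs, cfg, truths, val_truths)
}

#' Whole-volume inference
#'
#' Feeds a full volume through the trained network (batch normalization
#' uses accumulated statistics). Large volumes are processed in overlapping
#' tiles whose margins equal the network's receptive-field radius, so tiled
#' and direct inference agree voxel for voxel.
#'
#' @param network A trained [build_network()] result.
#' @param vol Input [volume3d()] (normalized GRE).
#' @param tile Tile core edge in voxels, or `NULL` to pick automatically.
#' @return A [volume3d()] with modality `DL_BB`.
#' @export
infer_bbnet <- function(network, vol, tile = NULL) {
  stopifnot(inherits(network, "bb_network"))
  vol <- as_volume3d(vol)
  dims <- dim(vol$data)
  margin <- network$config$n_conv_layers  # receptive-field radius
  if (is.null(tile)) tile <- if (max(dims) <= 64L) max(dims) else 48L
  residual <- network$config$residual_add
  if (all(dims <= tile)) {
    out <- cnn_forward_cpp(network$layers, vol$data, residual)
  } else {
    out <- array(0, dims)
    starts <- lapply(dims, function(d) seq(1L, d, by = tile))
    for (sx in starts[[1]]) for (sy in starts[[2]]) for (sz in starts[[3]]) {
      core_lo <- c(sx, sy, sz)
      core_hi <- pmin(core_lo + tile - 1L, dims)
      # clip the margin at the volume bounds: where the block face meets the
      # volume face, the engine's per-layer zero padding applies exactly as
      # it would in a whole-volume pass
      ext_lo <- pmax(core_lo - margin, 1L)
      ext_hi <- pmin(core_hi + margin, dims)
      block <- vol$data[ext_lo[1]:ext_hi[1], ext_lo[2]:ext_hi[2],
                        ext_lo[3]:ext_hi[3]]
      bout <- cnn_forward_cpp(network$layers, block, residual)
      keep_lo <- core_lo - ext_lo + 1L
      keep_hi <- keep_lo + (core_hi - core_lo)
      out[core_lo[1]:core_hi[1], core_lo[2]:core_hi[2],
          core_lo[3]:core_hi[3]] <-
        bout[keep_lo[1]:keep_hi[1], keep_lo[2]:keep_hi[2],
             keep_lo[3]:keep_hi[3]]
    }
  }
  if (!all(is.finite(out)))
    stop("inference produced non-finite voxels", call. = FALSE)
  # clamp to the normalized intensity codomain of the training labels
  out <- pmin(pmax(out, 0), 1)
  dim(out) <- dims
  volume3d(out, spacing_mm = vol$spacing_mm, modality = "DL_BB")
}
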