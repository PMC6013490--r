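# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (!exists(name, envir = .fixtures)) assign(name, maker(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# A compact 48^3 phantom: full structure (3 vessel classes, lesions) at a
# size where every pipeline stage runs in seconds.
phantom48 <- function(seed = 5, ...) {
  args <- list(...)
  key <- paste0("ph48_", seed, "_", paste(names(args), unlist(args),
                                          collapse = "_"))
  fixture(key, function() {
    spec <- do.call(phantom_spec, c(list(
      grid_shape = c(48L, 48L, 48L), n_lesions = 4L,
      vessel_counts = c(3L, 3L, 4L),
      lesion_radius_range_mm = c(0.8, 4), seed = seed), args))
    truth <- generate_truth(spec)
    pair <- render_pair(truth, spec)
    list(spec = spec, truth = truth, pair = pair)
  })
}

# The same phantom taken through brain extraction and auto-labelling.
autolabelled48 <- function(seed = 5) {
  fixture(paste0("auto48_", seed), function() {
    ph <- phantom48(seed)
    brain <- extract_brain(ph$pair$gre)
    res <- synthesize_bb(study_pair(ph$pair$gre, ph$pair$bb, brain,
                                    registered = TRUE))
    c(ph, list(brain = brain, res = res))
  })
}

vessel_voxels <- function(truth) {
  m <- truth$label_map >= 3L & truth$label_map <= 5L
  dim(m) <- dim(truth$label_map)
  m
}

lesion_voxels <- function(truth) {
  m <- truth$label_map == 6L
  dim(m) <- dim(truth$label_map)
  m
}

mask_union <- function(res) {
  res$mask1$core | res$mask1$ring | res$mask2$core | res$mask2$ring
}

lesion_center_index <- function(truth) {
  d <- dim(truth$label_map)
  with(truth$lesions, x + d[1] * (y - 1L) + d[1] * d[2] * (z - 1L))
}
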