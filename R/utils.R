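# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Linear indices of voxels within `radius` (voxels) of `center` (1-based),
# clipped to the grid.
ball_voxels <- function(center, radius, dims) {
  lo <- pmax(1L, floor(center - radius))
  hi <- pmin(dims, ceiling(center + radius))
  if (any(lo > hi)) return(integer(0))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  g <- expand.grid(x = xs, y = ys, z = zs)
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  keep <- d2 <= radius^2
  (g$x[keep] - 1L) + dims[1] * (g$y[keep] - 1L) +
    dims[1] * dims[2] * (g$z[keep] - 1L) + 1L
}

# voxel (x, y, z) coordinates (1-based) for linear indices
index_to_coord <- function(idx, dims) {
  idx0 <- idx - 1L
  z <- idx0 %/% (dims[1] * dims[2])
  rem <- idx0 %% (dims[1] * dims[2])
  cbind(x = rem %% dims[1] + 1L, y = rem %/% dims[1] + 1L, z = z + 1L)
}

# Otsu's threshold on a numeric vector (maximizes between-class variance
# over a fixed-bin histogram).
otsu_threshold <- function(x, n_bins = 256L) {
  r <- range(x)
  if (diff(r) <= 0) stop("cannot threshold a constant volume", call. = FALSE)
  breaks <- seq(r[1], r[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  mids[which.max(sigma_b)]
}

# Largest 26-connected component of a logical 3D mask.
largest_component <- function(mask) {
  lab <- cpp_label_components(mask)
  n <- attr(lab, "n_components")
  if (n == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  out <- lab == which.max(sizes)
  dim(out) <- dim(mask)
  out
}

stop_if_not_3d <- function(a, what = "volume") {
  if (is.null(dim(a)) || length(dim(a)) != 3L)
    stop(sprintf("%s must be a 3D array (got %s dimensions)", what,
                 if (is.null(dim(a))) "no" else length(dim(a))), call. = FALSE)
}
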