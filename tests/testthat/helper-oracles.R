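# Independent oracles and small fixture builders used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force flood-fill connected-component labelling (BFS), independent of
# the package's graph-based implementation. Accepts 2D or 3D logical arrays.
flood_fill_components <- function(mask, connectivity = "full") {
  d <- dim(mask)
  if (length(d) == 2L) {
    mask <- array(mask, c(1L, d))
    d <- dim(mask)
  }
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == "face") offs <- offs[rowSums(abs(offs)) == 1, ]
  labels <- array(0L, d)
  nxt <- 0L
  fg <- which(mask)
  for (start in fg) {
    if (labels[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    labels[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      co <- arrayInd(cur, d)
      for (r in seq_len(nrow(offs))) {
        z <- co[1] + offs$dz[r]; y <- co[2] + offs$dy[r]; x <- co[3] + offs$dx[r]
        if (z < 1 || z > d[1] || y < 1 || y > d[2] || x < 1 || x > d[3]) next
        lin <- z + (y - 1) * d[1] + (x - 1) * d[1] * d[2]
        if (mask[lin] && labels[lin] == 0L) {
          labels[lin] <- nxt
          queue <- c(queue, lin)
        }
      }
    }
  }
  list(n = nxt, labels = labels)
}

# Exhaustive 1D k-means for tiny inputs: tries every threshold split into k
# contiguous groups of the sorted values and returns the minimum
# within-cluster sum of squares assignment (1D optimal clustering is
# contiguous in sorted order).
brute_kmeans1d <- function(x, k) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  cuts <- utils::combn(n - 1, k - 1)
  best <- NULL; best_ss <- Inf
  for (j in seq_len(ncol(cuts))) {
    bounds <- c(0, cuts[, j], n)
    ss <- 0
    asg <- integer(n)
    for (g in seq_len(k)) {
      idx <- (bounds[g] + 1):bounds[g + 1]
      ss <- ss + sum((xs[idx] - mean(xs[idx]))^2)
      asg[idx] <- g
    }
    if (ss < best_ss) { best_ss <- ss; best <- asg }
  }
  out <- integer(n)
  out[ord] <- best
  out
}

# Line profile object from bare vectors (bypasses image sampling).
profile_from_values <- function(positions, intensity, axis = "x") {
  structure(list(positions_nm = positions, intensity = intensity, axis = axis,
                 spacing_nm = diff(positions[1:2])),
            class = "line_profile")
}

# One centred point reflector, optionally noiseless, for impulse-response and
# persistence checks.
point_scene <- function(shape = c(24, 64, 64), amplitude = 1000, seed = 1) {
  truth <- generate_ground_truth(shape = shape, voxel_size_nm = c(200, 60, 60),
                                 n_clusters = 1,
                                 amplitude_range = c(amplitude, amplitude),
                                 radius_range = c(0, 0),
                                 background_level = 0, seed = seed)
  ctr_nm <- (shape / 2) * c(200, 60, 60)
  truth$np_clusters$z_nm <- ctr_nm[1]
  truth$np_clusters$y_nm <- ctr_nm[2]
  truth$np_clusters$x_nm <- ctr_nm[3]
  truth
}

render_quiet <- function(...) withCallingHandlers(
  render_scene(...),
  warning = function(w) {
    if (grepl("Nyquist", conditionMessage(w))) invokeRestart("muffleWarning")
  })
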