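#' Segmentation parameters
#'
#' @param smooth_sigma Gaussian smoothing sigma in voxels applied before
#'   clustering (0 disables smoothing).
#' @param n_clusters number of k-means intensity clusters (k >= 2). Cell and
#'   nucleus segmentation use k = 2 (background vs stain); nanoparticle
#'   segmentation defaults to k = 3 (background / cellular reflectance /
#'   nanoparticle signal).
#' @param threshold_multiplier `m` in the control-derived threshold
#'   `median + m * MAD` applied after clustering in [segment_np()].
#' @param connectivity neighbourhood for component labelling: `"full"`
#'   (26-neighbour in 3D, 8 in 2D) or `"face"` (6- / 4-neighbour).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(smooth_sigma = 1, n_clusters = 2,
                                threshold_multiplier = 3,
                                connectivity = c("full", "face")) {
  connectivity <- match.arg(connectivity)
  if (n_clusters < 2) stop("n_clusters must be >= 2")
  if (smooth_sigma < 0) stop("smooth_sigma must be >= 0")
  if (threshold_multiplier < 0) stop("threshold_multiplier must be >= 0")
  structure(list(smooth_sigma = smooth_sigma,
                 n_clusters = as.integer(n_clusters),
                 threshold_multiplier = threshold_multiplier,
                 connectivity = connectivity),
            class = "segmentation_params")
}

# Deterministic 1D k-means: centers seeded at evenly spaced quantiles, no
# random restarts, clusters relabelled in increasing order of center.
# Constant (non-separable) input raises an explicit degenerate-input error.
kmeans_intensity <- function(x, k, fit_max = 200000L) {
  n <- length(x)
  # very large inputs: fit centers on a deterministic stride subsample, then
  # assign every voxel to its nearest center (1D: midpoint thresholds)
  rng <- range(x)
  if (diff(rng) <= 1e-9 * max(abs(rng), 1))
    stop("degenerate input: intensities do not separate into ", k, " clusters")
  xf <- if (n > 2L * fit_max) x[seq(1L, n, by = ceiling(n / fit_max))] else x
  qs <- stats::quantile(xf, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  if (length(unique(qs)) < k) {
    # mass concentrated in one mode (e.g. sparse foreground): seed from the
    # unique intensity values instead, still deterministic
    ux <- unique(xf)
    qs <- if (length(ux) >= k)
      stats::quantile(ux, probs = (seq_len(k) - 0.5) / k, names = FALSE)
    else ux
  }
  if (length(unique(qs)) < k)
    stop("degenerate input: intensities do not separate into ", k, " clusters")
  km <- suppressWarnings(
    stats::kmeans(xf, centers = matrix(qs, ncol = 1), iter.max = 100))
  ord <- order(km$centers)
  centers <- sort(as.vector(km$centers))
  cluster <- if (length(xf) == n) match(km$cluster, ord)
             else findInterval(x, (centers[-k] + centers[-1]) / 2) + 1L
  list(cluster = cluster, centers = centers)
}

#' Segment the cell body from a cytoplasmic stain channel
#'
#' Gaussian smoothing followed by two-cluster k-means on voxel intensities;
#' the cluster with the higher mean intensity is the cell.
#'
#' @param cytoplasm a [volume_image] (or 3D array) of the cytoplasmic stain.
#' @param params a [segmentation_params()] (k must be 2).
#' @return Logical array of the input shape: `TRUE` inside the cell.
#' @export
segment_cell <- function(cytoplasm, params = segmentation_params()) {
  a <- as_vol_array(cytoplasm)
  if (params$n_clusters != 2L)
    stop("cell segmentation uses k = 2 (stain vs background)")
  sm <- gaussian_blur(a, params$smooth_sigma)
  km <- kmeans_intensity(as.vector(sm), 2L)
  mask <- array(km$cluster == 2L, dim(a))
  mask
}

#' Segment nuclei and report centroids
#'
#' Foreground by the same smooth-then-cluster rule as [segment_cell()], then
#' connected-component labelling; centroids are returned in physical nm,
#' sorted by label. An empty foreground yields an empty centroid list.
#'
#' @param nucleus a [volume_image] (or 3D array) of the nuclear stain.
#' @param params a [segmentation_params()].
#' @param voxel_size_nm required if `nucleus` is a bare array.
#' @return List with `labels` (integer array), `centroids_nm` (matrix with
#'   columns `z_nm, y_nm, x_nm`, one row per label) and `table` (the region
#'   table from [connected_components()]).
#' @export
segment_nuclei <- function(nucleus, params = segmentation_params(),
                           voxel_size_nm = NULL) {
  a <- as_vol_array(nucleus)
  vox <- vol_voxel_size(nucleus, default = voxel_size_nm)
  sm <- gaussian_blur(a, params$smooth_sigma)
  km <- kmeans_intensity(as.vector(sm), 2L)
  mask <- array(km$cluster == 2L, dim(a))
  cc <- connected_components(mask, connectivity = params$connectivity,
                             voxel_size_nm = vox)
  cen <- as.matrix(cc$table[, c("centroid_z_nm", "centroid_y_nm", "centroid_x_nm")])
  colnames(cen) <- c("z_nm", "y_nm", "x_nm")
  list(labels = cc$labels, centroids_nm = cen, table = cc$table)
}

#' Segment nanoparticle reflectance signal against control baselines
#'
#' Implements control-normalised nanoparticle detection: (1) treated and
#' control reflectance volumes are pooled and jointly min-max normalised to
#' `[0, 1]`, preserving the treated-vs-control intensity ordering; (2) each
#' volume is Gaussian-smoothed; (3) k-means clusters the pooled intensities
#' and the highest-mean cluster is the candidate foreground; (4) only voxels
#' exceeding `median + m * MAD` of the control images' cellular-reflectance
#' voxels (control voxels in the non-background clusters) are retained, so
#' the inherent reflectance of untreated cells sets the detection floor.
#'
#' @param treated a [volume_image] or list of them (reflectance channel of
#'   treated acquisitions).
#' @param control a [volume_image] or list of them from untreated control
#'   cells (mandatory: the control baseline defines what is background).
#' @param params a [segmentation_params()]; defaults to
#'   `segmentation_params(smooth_sigma = 0.7, n_clusters = 3)`.
#' @return A list of logical masks (one per treated volume), attribute
#'   `threshold` giving the control-derived cutoff on the normalised scale.
#' @export
segment_np <- function(treated, control,
                       params = segmentation_params(smooth_sigma = 0.7,
                                                    n_clusters = 3)) {
  treated <- if (inherits(treated, "volume_image") || (is.array(treated) &&
    length(dim(treated)) == 3L)) list(treated) else treated
  control <- if (inherits(control, "volume_image") || (is.array(control) &&
    length(dim(control)) == 3L)) list(control) else control
  if (!length(control))
    stop("at least one untreated control image is required as the baseline")
  if (!length(treated)) stop("at least one treated image is required")

  tr <- lapply(treated, as_vol_array)
  ct <- lapply(control, as_vol_array)
  all_imgs <- c(tr, ct)

  rng <- range(vapply(all_imgs, min, 0), vapply(all_imgs, max, 0))
  if (diff(rng) <= 0)
    stop("degenerate input: pooled images are constant")
  norm_smooth <- lapply(all_imgs, function(a)
    gaussian_blur((a - rng[1]) / diff(rng), params$smooth_sigma))

  k <- params$n_clusters
  pooled <- unlist(lapply(norm_smooth, as.vector), use.names = FALSE)
  km <- kmeans_intensity(pooled, k)

  sizes <- vapply(norm_smooth, length, 0L)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  n_tr <- length(tr)

  ctrl_cluster <- unlist(lapply(seq_along(ct), function(i) {
    j <- n_tr + i
    km$cluster[starts[j]:ends[j]]
  }), use.names = FALSE)
  ctrl_vals <- unlist(lapply(seq_along(ct), function(i)
    as.vector(norm_smooth[[n_tr + i]])), use.names = FALSE)
  fg <- ctrl_vals[ctrl_cluster >= 2L]
  if (!length(fg)) fg <- ctrl_vals
  thr <- stats::median(fg) + params$threshold_multiplier * stats::mad(fg)

  masks <- lapply(seq_len(n_tr), function(i) {
    cl <- km$cluster[starts[i]:ends[i]]
    v <- as.vector(norm_smooth[[i]])
    array(cl == k & v > thr, dim(tr[[i]]))
  })
  attr(masks, "threshold") <- thr
  masks
}

#' Remove large-scale background from an image
#'
#' Subtracts the image's own large-sigma Gaussian blur (an estimate of the
#' diffuse background reflectance) and clips at zero. Used before
#' intensity-based registration and before line-profile width measurement so
#' background reflectance does not inflate either.
#'
#' @param image a [volume_image], [planar_image], 3D array or matrix.
#' @param sigma_bg background blur sigma in voxels; must exceed the smoothing
#'   sigma used for detection.
#' @return Same type as the input, with `data` replaced by
#'   `pmax(data - blur(data, sigma_bg), 0)`.
#' @export
subtract_background <- function(image, sigma_bg = 6) {
  if (sigma_bg <= 0) stop("sigma_bg must be positive")
  sub <- function(a) pmax(a - gaussian_blur(a, sigma_bg), 0)
  if (inherits(image, "volume_image")) {
    image$data <- sub(image$data)
    image
  } else if (inherits(image, "planar_image")) {
    image$data <- sub(image$data)
    image
  } else if (is.array(image)) {
    sub(image)
  } else stop("unsupported image type")
}
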