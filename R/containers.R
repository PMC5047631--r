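#' Single-channel 3D intensity volume
#'
#' Wraps a numeric 3D array together with its physical voxel size and the
#' imaging modality it came from. Arrays are indexed `(z, y, x)`; the
#' physical coordinate of voxel `i` along an axis is `(i - 1) * voxel_size_nm`
#' for that axis (voxel centres at integer physical multiples).
#'
#' @param data numeric 3D array, dimensions `(nz, ny, nx)`.
#' @param voxel_size_nm numeric length-3 voxel size in nm, order `(z, y, x)`.
#'   A scalar is recycled.
#' @param modality character tag, e.g. `"RCM"`, `"RSIM"`, `"generic"`.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, voxel_size_nm, modality = "generic") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (z, y, x)")
  voxel_size_nm <- rep_len(as.numeric(voxel_size_nm), 3L)
  if (any(!is.finite(voxel_size_nm)) || any(voxel_size_nm <= 0))
    stop("voxel sizes must be positive and finite")
  structure(
    list(data = data, voxel_size_nm = voxel_size_nm,
         modality = as.character(modality)[1L]),
    class = "volume_image"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<volume_image> %s, %d x %d x %d voxels (z,y,x), voxel %s nm, range [%.3g, %.3g]\n",
    x$modality, d[1], d[2], d[3],
    paste(signif(x$voxel_size_nm, 4), collapse = " x "),
    min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$data)

#' Single-channel 2D image with physical pixel size
#'
#' @param data numeric matrix, dimensions `(ny, nx)`.
#' @param pixel_size_nm numeric length-2 pixel size in nm, order `(y, x)`.
#'   A scalar is recycled.
#' @param modality character tag.
#' @return An object of class `planar_image`.
#' @export
planar_image <- function(data, pixel_size_nm, modality = "generic") {
  if (!is.matrix(data)) stop("`data` must be a matrix (y, x)")
  pixel_size_nm <- rep_len(as.numeric(pixel_size_nm), 2L)
  if (any(!is.finite(pixel_size_nm)) || any(pixel_size_nm <= 0))
    stop("pixel sizes must be positive and finite")
  structure(
    list(data = data, pixel_size_nm = pixel_size_nm,
         modality = as.character(modality)[1L]),
    class = "planar_image"
  )
}

#' @export
print.planar_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<planar_image> %s, %d x %d pixels (y,x), pixel %s nm, range [%.3g, %.3g]\n",
    x$modality, d[1], d[2],
    paste(signif(x$pixel_size_nm, 4), collapse = " x "),
    min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.planar_image <- function(x) dim(x$data)

#' Named set of co-registered volumes from one acquisition
#'
#' @param channels named list of [volume_image] objects sharing grid shape and
#'   voxel size (typically `reflectance`, `cytoplasm`, `nucleus`, optionally
#'   `lysosome`).
#' @param meta list of acquisition metadata (modality, seed, ...).
#' @return An object of class `multichannel_stack`.
#' @export
multichannel_stack <- function(channels, meta = list()) {
  if (!length(channels) || is.null(names(channels)) || any(names(channels) == ""))
    stop("`channels` must be a non-empty named list")
  if (!all(vapply(channels, inherits, logical(1), "volume_image")))
    stop("all channels must be volume_image objects")
  d0 <- dim(channels[[1]]$data)
  v0 <- channels[[1]]$voxel_size_nm
  for (ch in channels) {
    if (!identical(dim(ch$data), d0)) stop("channel grids must share shape")
    if (max(abs(ch$voxel_size_nm - v0)) > 1e-9) stop("channel voxel sizes must agree")
  }
  structure(list(channels = channels, meta = meta), class = "multichannel_stack")
}

#' @export
print.multichannel_stack <- function(x, ...) {
  d <- dim(x$channels[[1]]$data)
  cat(sprintf("<multichannel_stack> %s: %s | %d x %d x %d voxels\n",
              x$channels[[1]]$modality,
              paste(names(x$channels), collapse = ", "), d[1], d[2], d[3]))
  invisible(x)
}

# Coerce to bare array/matrix and fetch geometry, accepting wrapped or raw input.
as_vol_array <- function(x) {
  if (inherits(x, "volume_image")) x$data
  else if (is.array(x) && length(dim(x)) == 3L) x
  else stop("expected a volume_image or 3D array")
}

vol_voxel_size <- function(x, default = NULL) {
  if (inherits(x, "volume_image")) x$voxel_size_nm
  else if (!is.null(default)) rep_len(as.numeric(default), 3L)
  else stop("voxel size unknown: pass a volume_image or supply voxel_size_nm")
}

as_plane_matrix <- function(x) {
  if (inherits(x, "planar_image")) x$data
  else if (is.matrix(x)) x
  else stop("expected a planar_image or matrix")
}

plane_pixel_size <- function(x, default = NULL) {
  if (inherits(x, "planar_image")) x$pixel_size_nm
  else if (!is.null(default)) rep_len(as.numeric(default), 2L)
  else stop("pixel size unknown: pass a planar_image or supply pixel_size_nm")
}

#' Instrument point-spread-function presets
#'
#' Anisotropic Gaussian PSF widths for the supported modalities, stated as
#' full width at half maximum (FWHM): RCM 345 nm lateral / 1077 nm axial,
#' R-SIM 115 nm lateral / 685 nm axial (the ~2x super-resolution gain of
#' structured illumination), and a TEM-like preset with a 2 nm lateral width
#' and no axial component (sections are physically thin). The Gaussian sigma
#' is `FWHM / (2 * sqrt(2 * log(2)))`.
#'
#' @param modality one of `"RCM"`, `"RSIM"`, `"TEM"`.
#' @param fwhm_lateral,fwhm_axial optional overrides in nm.
#' @return An object of class `psf_preset` with fields `modality`,
#'   `fwhm_lateral`, `fwhm_axial` (NA for TEM).
#' @export
#' @examples
#' psf_preset("RSIM")
psf_preset <- function(modality = c("RCM", "RSIM", "TEM"),
                       fwhm_lateral = NULL, fwhm_axial = NULL) {
  modality <- match.arg(modality)
  defaults <- switch(modality,
    RCM  = c(lateral = 345, axial = 1077),
    RSIM = c(lateral = 115, axial = 685),
    TEM  = c(lateral = 2, axial = NA_real_))
  lat <- if (is.null(fwhm_lateral)) defaults[["lateral"]] else as.numeric(fwhm_lateral)
  ax <- if (is.null(fwhm_axial)) defaults[["axial"]] else as.numeric(fwhm_axial)
  if (!is.finite(lat) || lat <= 0) stop("fwhm_lateral must be positive")
  if (modality != "TEM") {
    if (!is.finite(ax) || ax <= 0) stop("fwhm_axial must be positive")
    if (ax <= lat) stop("fwhm_axial must exceed fwhm_lateral for optical modalities")
  }
  structure(list(modality = modality, fwhm_lateral = lat, fwhm_axial = ax),
            class = "psf_preset")
}

#' @export
print.psf_preset <- function(x, ...) {
  cat(sprintf("<psf_preset> %s: lateral FWHM %.4g nm, axial FWHM %s nm\n",
              x$modality, x$fwhm_lateral,
              if (is.na(x$fwhm_axial)) "-" else format(x$fwhm_axial)))
  invisible(x)
}

# FWHM of a Gaussian = 2*sqrt(2*log(2)) * sigma
FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

#' Poisson-Gaussian acquisition noise parameters
#'
#' Signal-dependent shot noise (Poisson on the intensity scaled by
#' `photon_scale`, then rescaled) followed by additive Gaussian read noise.
#' `photon_scale = 0` disables shot noise; `read_sigma = 0` disables read
#' noise.
#'
#' @param photon_scale non-negative photons per intensity unit.
#' @param read_sigma non-negative Gaussian read-noise SD (intensity units).
#' @param seed integer RNG seed used when the noise is applied.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(photon_scale = 1, read_sigma = 0, seed = 1L) {
  if (photon_scale < 0) stop("photon_scale must be >= 0")
  if (read_sigma < 0) stop("read_sigma must be >= 0")
  structure(list(photon_scale = as.numeric(photon_scale),
                 read_sigma = as.numeric(read_sigma),
                 seed = as.integer(seed)),
            class = "noise_params")
}

# --- low-level numerics shared across modules ------------------------------

# 1D Gaussian kernel, truncated and renormalised
gauss_kernel <- function(sigma, truncate = 4) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(truncate * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Convolve array `a` along `axis` with kernel `k`, renormalising at the edges
# (replicate-free: weights outside the support are dropped and the remaining
# weights rescaled, so constants are preserved exactly).
conv_axis <- function(a, k, axis) {
  d <- dim(a)
  n <- d[axis]
  if (length(k) == 1L) return(a)
  half <- (length(k) - 1L) %/% 2L
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - half):(i + half)
    ok <- j >= 1L & j <= n
    M[i, j[ok]] <- k[ok] / sum(k[ok])
  }
  nd <- length(d)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  ap <- aperm(a, perm)
  dim(ap) <- c(n, prod(d[-axis]))
  out <- M %*% ap
  dim(out) <- d[perm]
  aperm(out, order(perm))
}

# Separable Gaussian blur of a 2D or 3D array; sigma per axis in voxels.
gaussian_blur <- function(a, sigma, truncate = 4) {
  d <- dim(a)
  sigma <- rep_len(sigma, length(d))
  for (ax in seq_along(d)) {
    if (sigma[ax] > 0 && d[ax] > 1L)
      a <- conv_axis(a, gauss_kernel(sigma[ax], truncate), ax)
  }
  a
}

# Trilinear interpolation of a 3D array at continuous 1-based voxel
# coordinates (matrix pts: columns z, y, x). Out-of-bounds -> NA.
interp3 <- function(a, pts) {
  d <- dim(a)
  out <- rep(NA_real_, nrow(pts))
  inb <- pts[, 1] >= 1 & pts[, 1] <= d[1] &
         pts[, 2] >= 1 & pts[, 2] <= d[2] &
         pts[, 3] >= 1 & pts[, 3] <= d[3]
  if (!any(inb)) return(out)
  p <- pts[inb, , drop = FALSE]
  lo <- pmin(pmax(floor(p), 1), matrix(rep(pmax(d - 1L, 1L), each = nrow(p)), ncol = 3))
  fr <- p - lo
  fr[, d == 1L] <- 0
  hi <- pmin(lo + 1, matrix(rep(d, each = nrow(p)), ncol = 3))
  idx <- function(z, y, x) z + (y - 1) * d[1] + (x - 1) * d[1] * d[2]
  v <- 0
  for (bz in 0:1) for (by in 0:1) for (bx in 0:1) {
    w <- (if (bz) fr[, 1] else 1 - fr[, 1]) *
         (if (by) fr[, 2] else 1 - fr[, 2]) *
         (if (bx) fr[, 3] else 1 - fr[, 3])
    z <- if (bz) hi[, 1] else lo[, 1]
    y <- if (by) hi[, 2] else lo[, 2]
    x <- if (bx) hi[, 3] else lo[, 3]
    v <- v + w * a[idx(z, y, x)]
  }
  out[inb] <- v
  out
}

# Bilinear interpolation of a matrix at continuous 1-based (row, col)
# coordinates. Out-of-bounds -> NA.
interp2 <- function(m, y, x) {
  a <- array(m, dim = c(dim(m), 1L))
  interp3(a, cbind(y, x, 1))
}
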