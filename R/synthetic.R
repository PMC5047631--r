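#' Generate a ground-truth nanoparticle scene
#'
#' Builds the geometry a forward model renders: an ellipsoidal cell mask
#' centred in the grid (semi-axes 45% of each grid extent), one or more
#' nuclei strictly inside it, and nanoparticle (NP) cluster centres sampled
#' uniformly from the cytoplasm (cell minus nuclei). Control scenes carry no
#' clusters and emulate untreated cells, whose inherent cellular reflectance
#' is the negative-control baseline for segmentation.
#'
#' Cluster centres are continuous physical positions (uniform jitter within
#' the selected voxel). When `min_separation_nm` is given, centres are
#' accepted by dart throwing under an ellipsoidal exclusion zone (length-3
#' `(z, y, x)` semi-axes, or a scalar for a sphere), which keeps clusters
#' mutually resolvable for point-source experiments.
#'
#' @param shape integer length-3 grid shape `(nz, ny, nx)`, at least
#'   `(8, 64, 64)`.
#' @param voxel_size_nm length-3 voxel size in nm `(z, y, x)` (scalar
#'   recycled).
#' @param n_clusters number of NP clusters (0 for control scenes).
#' @param amplitude_range length-2 range of peak reflectance amplitudes
#'   (arbitrary intensity units) sampled uniformly per cluster.
#' @param radius_range length-2 range of cluster radii in nm (Gaussian radius
#'   of the agglomerate; 0 = ideal point source).
#' @param background_level cellular background reflectance level, in the same
#'   intensity units as the amplitudes. Defaults to 10% of the smallest
#'   cluster amplitude, giving the 5-15% textured baseline at render time.
#' @param control logical; `TRUE` forces an empty cluster list.
#' @param n_nuclei number of nuclei (1 or 2).
#' @param min_separation_nm scalar or length-3 minimum centre separation
#'   (0 disables).
#' @param misalignment optional [planar_transform] recording the known
#'   inter-modality misalignment applied when rendering non-reference
#'   modalities.
#' @param seed integer seed; the same `(parameters, seed)` pair always
#'   reproduces the identical scene.
#' @return An object of class `scene_truth` with fields `cell_mask`,
#'   `nucleus_mask` (logical arrays), `np_clusters` (data frame with
#'   `z_nm, y_nm, x_nm, amplitude, radius_nm`), `background_level`,
#'   `control`, `misalignment`, `shape`, `voxel_size_nm`, `seed`.
#' @export
#' @examples
#' truth <- generate_ground_truth(shape = c(8, 64, 64), n_clusters = 5, seed = 2)
#' nrow(truth$np_clusters)
generate_ground_truth <- function(shape = c(16, 128, 128),
                                  voxel_size_nm = c(200, 60, 60),
                                  n_clusters = 20,
                                  amplitude_range = c(800, 1200),
                                  radius_range = c(0, 0),
                                  background_level = NULL,
                                  control = FALSE,
                                  n_nuclei = 1,
                                  min_separation_nm = 0,
                                  misalignment = NULL,
                                  seed = 1L) {
  shape <- as.integer(rep_len(shape, 3L))
  if (any(shape < c(8L, 64L, 64L)))
    stop("grid shape must be at least (8, 64, 64)")
  voxel_size_nm <- rep_len(as.numeric(voxel_size_nm), 3L)
  if (any(voxel_size_nm <= 0)) stop("voxel sizes must be positive")
  if (control) n_clusters <- 0L
  n_clusters <- as.integer(n_clusters)
  if (n_clusters < 0) stop("n_clusters must be non-negative")
  if (!n_nuclei %in% 1:2) stop("n_nuclei must be 1 or 2")

  ctr <- (shape + 1) / 2
  semi <- 0.45 * shape
  cell_mask <- ellipsoid_mask(shape, ctr, semi)

  nuc_semi <- 0.4 * semi
  if (n_nuclei == 1L) {
    nucleus_mask <- ellipsoid_mask(shape, ctr, nuc_semi)
  } else {
    off <- c(0, 0, 0.4 * semi[3])
    nucleus_mask <- ellipsoid_mask(shape, ctr - off, 0.75 * nuc_semi) |
      ellipsoid_mask(shape, ctr + off, 0.75 * nuc_semi)
  }
  nucleus_mask <- nucleus_mask & cell_mask

  cyto <- which(cell_mask & !nucleus_mask)
  if (n_clusters > length(cyto))
    stop("n_clusters exceeds the number of available cytoplasm voxels")

  clusters <- with_seed(seed, {
    if (n_clusters == 0L) {
      data.frame(z_nm = numeric(0), y_nm = numeric(0), x_nm = numeric(0),
                 amplitude = numeric(0), radius_nm = numeric(0))
    } else {
      sep <- rep_len(as.numeric(min_separation_nm), 3L)
      ord <- cyto[sample.int(length(cyto))]
      coords <- arrayInd(ord, shape)
      pos_nm <- sweep(coords - 1, 2, voxel_size_nm, "*") +
        sweep(matrix(stats::runif(3 * length(ord), -0.5, 0.5), ncol = 3),
              2, voxel_size_nm, "*")
      if (all(sep <= 0)) {
        keep <- seq_len(n_clusters)
      } else {
        sep[sep <= 0] <- 1e-9
        keep <- integer(0)
        for (i in seq_len(nrow(pos_nm))) {
          if (length(keep)) {
            dn <- sweep(pos_nm[keep, , drop = FALSE], 2, pos_nm[i, ])
            dn <- sweep(dn, 2, sep, "/")
            if (min(rowSums(dn^2)) < 1) next
          }
          keep <- c(keep, i)
          if (length(keep) == n_clusters) break
        }
        if (length(keep) < n_clusters)
          stop("could not place ", n_clusters,
               " clusters at the requested minimum separation")
      }
      pos <- pos_nm[keep, , drop = FALSE]
      data.frame(
        z_nm = pos[, 1], y_nm = pos[, 2], x_nm = pos[, 3],
        amplitude = stats::runif(n_clusters, amplitude_range[1], amplitude_range[2]),
        radius_nm = stats::runif(n_clusters, radius_range[1], radius_range[2]))
    }
  })

  if (is.null(background_level)) {
    amp_floor <- if (n_clusters > 0) min(clusters$amplitude) else min(amplitude_range)
    background_level <- 0.1 * amp_floor
  }

  structure(list(
    shape = shape, voxel_size_nm = voxel_size_nm,
    cell_mask = cell_mask, nucleus_mask = nucleus_mask,
    np_clusters = clusters, background_level = background_level,
    control = control, misalignment = misalignment,
    n_nuclei = as.integer(n_nuclei), seed = as.integer(seed)),
    class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf(
    "<scene_truth> %d x %d x %d grid, %d NP clusters%s, %d nucle%s, seed %d\n",
    x$shape[1], x$shape[2], x$shape[3], nrow(x$np_clusters),
    if (x$control) " (control)" else "", x$n_nuclei,
    if (x$n_nuclei == 1) "us" else "i", x$seed))
  invisible(x)
}

ellipsoid_mask <- function(shape, centre, semi) {
  z2 <- ((seq_len(shape[1]) - centre[1]) / semi[1])^2
  y2 <- ((seq_len(shape[2]) - centre[2]) / semi[2])^2
  x2 <- ((seq_len(shape[3]) - centre[3]) / semi[3])^2
  outer(outer(z2, y2, "+"), x2, "+") <= 1
}

#' Render a ground-truth scene through an optical forward model
#'
#' Produces a [multichannel_stack] for one modality. The reflectance channel
#' is the sum of each cluster's anisotropic Gaussian response (peak amplitude
#' preserved; per-axis sigma combines the PSF sigma with the cluster radius
#' in quadrature) plus a low-amplitude textured cellular background restricted
#' to the cell mask, with Poisson-Gaussian noise applied last. The cytoplasm
#' and nucleus channels are smoothed, scaled masks. For R-SIM, cluster
#' contributions are cut once the axial distance from the focal plane exceeds
#' the axial FWHM, emulating the reconstruction retaining only high-contrast
#' in-focus signal.
#'
#' The textured background is present in control renderings too: untreated
#' cells show inherent reflectance, which is exactly what the control-baseline
#' segmentation must reject. Texture = uniform noise smoothed with a 3-voxel
#' sigma, rescaled inside the cell to 0.5-1.5x `background_level` (5-15% of
#' the smallest cluster amplitude at the default level).
#'
#' @param truth a [generate_ground_truth()] scene.
#' @param psf a [psf_preset()] (optical modality; use
#'   [render_tem_sections()] for TEM).
#' @param noise a [noise_params()] object, or `NULL` for a noiseless render.
#' @param channels subset of `c("reflectance", "cytoplasm", "nucleus")`.
#' @param channel_amplitude intensity scale of the stain channels.
#' @param apply_misalignment logical; if `TRUE` and the truth carries a
#'   `misalignment` transform, cluster positions are moved through it in the
#'   lateral plane before rendering (emulating a modality acquired on a
#'   shifted stage).
#' @return A [multichannel_stack]; `meta` records modality, preset, seed and
#'   any sampling-adequacy warning.
#' @export
render_scene <- function(truth, psf, noise = noise_params(seed = truth$seed),
                         channels = c("reflectance", "cytoplasm", "nucleus"),
                         channel_amplitude = 1000,
                         apply_misalignment = FALSE) {
  stopifnot(inherits(truth, "scene_truth"), inherits(psf, "psf_preset"))
  if (psf$modality == "TEM")
    stop("use render_tem_sections() for the TEM forward model")
  channels <- match.arg(channels, several.ok = TRUE)
  d <- truth$shape
  vox <- truth$voxel_size_nm
  sigma_nm <- c(psf$fwhm_axial, psf$fwhm_lateral, psf$fwhm_lateral) * FWHM_TO_SIGMA

  sampling_ok <- c(psf$fwhm_axial, psf$fwhm_lateral, psf$fwhm_lateral) >= 2 * vox
  warn <- NULL
  if (!all(sampling_ok)) {
    warn <- paste0("PSF FWHM below twice the voxel size on axis ",
                   paste(c("z", "y", "x")[!sampling_ok], collapse = ","),
                   "; sampling is below Nyquist")
    warning(warn)
  }

  clusters <- truth$np_clusters
  if (apply_misalignment && !is.null(truth$misalignment) && nrow(clusters)) {
    p <- transform_points(truth$misalignment,
                          cbind(clusters$x_nm, clusters$y_nm))
    clusters$x_nm <- p[, 1]
    clusters$y_nm <- p[, 2]
  }

  out <- list()
  seed0 <- if (is.null(noise)) truth$seed else noise$seed

  if ("reflectance" %in% channels) {
    refl <- array(0, d)
    if (nrow(clusters)) {
      axial_cut <- if (psf$modality == "RSIM") psf$fwhm_axial else Inf
      for (i in seq_len(nrow(clusters))) {
        refl <- add_gaussian_spot(
          refl, vox,
          centre_nm = c(clusters$z_nm[i], clusters$y_nm[i], clusters$x_nm[i]),
          sigma_nm = sqrt(sigma_nm^2 + clusters$radius_nm[i]^2),
          amplitude = clusters$amplitude[i],
          axial_cut_nm = axial_cut)
      }
    }
    if (truth$background_level > 0) {
      tex <- with_seed(seed0 + 101L, array(stats::runif(prod(d)), d))
      tex <- gaussian_blur(tex, 3)
      inside <- truth$cell_mask
      tv <- tex[inside]
      rng <- range(tv)
      scale01 <- if (diff(rng) > 0) (tv - rng[1]) / diff(rng) else rep(0.5, length(tv))
      bg <- array(0, d)
      bg[inside] <- truth$background_level * (0.5 + scale01)
      refl <- refl + bg
    }
    out$reflectance <- apply_noise(refl, noise, seed_offset = 1L)
  }
  if ("cytoplasm" %in% channels) {
    cy <- gaussian_blur(truth$cell_mask * channel_amplitude, 1)
    out$cytoplasm <- apply_noise(cy, noise, seed_offset = 2L)
  }
  if ("nucleus" %in% channels) {
    nu <- gaussian_blur(truth$nucleus_mask * channel_amplitude, 1)
    out$nucleus <- apply_noise(nu, noise, seed_offset = 3L)
  }

  chans <- lapply(out, volume_image, voxel_size_nm = vox, modality = psf$modality)
  multichannel_stack(chans, meta = list(
    modality = psf$modality, psf = psf, seed = seed0,
    noise = noise, sampling_warning = warn,
    misaligned = isTRUE(apply_misalignment) && !is.null(truth$misalignment)))
}

# Add one anisotropic Gaussian peak (evaluated analytically on voxel centres
# over a +/-4 sigma window) to a (z,y,x) array. axial_cut_nm zeroes
# contributions beyond that axial distance from the spot centre.
add_gaussian_spot <- function(a, vox, centre_nm, sigma_nm, amplitude,
                              axial_cut_nm = Inf) {
  d <- dim(a)
  sigma_nm <- pmax(sigma_nm, 1e-6)
  ctr_idx <- centre_nm / vox + 1
  half <- pmin(ceiling(4 * sigma_nm / vox),
               if (is.finite(axial_cut_nm)) c(ceiling(axial_cut_nm / vox[1]), Inf, Inf)
               else Inf)
  lo <- pmax(1, floor(ctr_idx - half))
  hi <- pmin(d, ceiling(ctr_idx + half))
  if (any(lo > hi)) return(a)
  iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
  gz <- exp(-(((iz - 1) * vox[1] - centre_nm[1])^2) / (2 * sigma_nm[1]^2))
  if (is.finite(axial_cut_nm))
    gz[abs((iz - 1) * vox[1] - centre_nm[1]) > axial_cut_nm] <- 0
  gy <- exp(-(((iy - 1) * vox[2] - centre_nm[2])^2) / (2 * sigma_nm[2]^2))
  gx <- exp(-(((ix - 1) * vox[3] - centre_nm[3])^2) / (2 * sigma_nm[3]^2))
  spot <- amplitude * outer(outer(gz, gy), gx)
  a[iz, iy, ix] <- a[iz, iy, ix] + spot
  a
}

# Poisson shot noise then additive Gaussian read noise, seeded.
apply_noise <- function(img, noise, seed_offset = 0L) {
  if (is.null(noise) || (noise$photon_scale == 0 && noise$read_sigma == 0))
    return(img)
  d <- dim(img)
  with_seed(noise$seed + seed_offset, {
    out <- img
    if (noise$photon_scale > 0) {
      lam <- pmax(img, 0) * noise$photon_scale
      out <- array(stats::rpois(length(lam), lam) / noise$photon_scale, d)
    }
    if (noise$read_sigma > 0)
      out <- out + array(stats::rnorm(length(out), 0, noise$read_sigma), d)
    out
  })
}

#' Render TEM-like serial sections of a scene
#'
#' Integrates nanoparticle density over consecutive physical slabs and images
#' each slab at fine pixel pitch with TEM contrast (electron-dense particles
#' dark on a bright background). Sections tile the axial range starting at
#' `z_start_nm`. Lateral spot width combines the TEM preset width with the
#' cluster radius; the in-slab fraction of a cluster is the mass of a Gaussian
#' of sigma `max(radius, 1 nm)` falling inside the slab.
#'
#' @param truth a [generate_ground_truth()] scene.
#' @param section_thickness_nm physical slab thickness (> 0), e.g. 150 nm.
#' @param n_sections number of consecutive sections.
#' @param pixel_size_nm lateral pixel pitch, at most 10 nm.
#' @param background bright-field background intensity.
#' @param contrast maximum darkness of a fully contained spot, as a fraction
#'   of `background`.
#' @param z_start_nm axial start of the first slab.
#' @param psf TEM [psf_preset()].
#' @return List of [planar_image] sections; attribute `z_ranges_nm` holds the
#'   per-section `(z0, z1)` slabs.
#' @export
render_tem_sections <- function(truth, section_thickness_nm = 150,
                                n_sections = 2, pixel_size_nm = 10,
                                background = 1, contrast = 0.8,
                                z_start_nm = 0, psf = psf_preset("TEM")) {
  stopifnot(inherits(truth, "scene_truth"))
  if (section_thickness_nm <= 0) stop("section_thickness_nm must be positive")
  if (pixel_size_nm > 10) stop("TEM pixel size must be <= 10 nm")
  depth_nm <- truth$shape[1] * truth$voxel_size_nm[1]
  if (z_start_nm + n_sections * section_thickness_nm > depth_nm)
    stop("sections exceed the axial extent of the scene (",
         depth_nm, " nm)")
  ext_y <- (truth$shape[2] - 1) * truth$voxel_size_nm[2]
  ext_x <- (truth$shape[3] - 1) * truth$voxel_size_nm[3]
  ny <- floor(ext_y / pixel_size_nm) + 1L
  nx <- floor(ext_x / pixel_size_nm) + 1L
  sig_tem <- psf$fwhm_lateral * FWHM_TO_SIGMA
  cl <- truth$np_clusters

  sections <- vector("list", n_sections)
  z_ranges <- matrix(0, n_sections, 2)
  for (s in seq_len(n_sections)) {
    z0 <- z_start_nm + (s - 1) * section_thickness_nm
    z1 <- z0 + section_thickness_nm
    z_ranges[s, ] <- c(z0, z1)
    img <- matrix(background, ny, nx)
    if (nrow(cl)) {
      for (i in seq_len(nrow(cl))) {
        sz <- max(cl$radius_nm[i], 1)
        frac <- stats::pnorm((z1 - cl$z_nm[i]) / sz) -
          stats::pnorm((z0 - cl$z_nm[i]) / sz)
        if (frac < 1e-6) next
        sl <- sqrt(sig_tem^2 + cl$radius_nm[i]^2)
        half_px <- ceiling(4 * max(sl, pixel_size_nm) / pixel_size_nm)
        cy <- cl$y_nm[i] / pixel_size_nm + 1
        cx <- cl$x_nm[i] / pixel_size_nm + 1
        iy <- max(1, floor(cy - half_px)):min(ny, ceiling(cy + half_px))
        ix <- max(1, floor(cx - half_px)):min(nx, ceiling(cx + half_px))
        gy <- exp(-(((iy - 1) * pixel_size_nm - cl$y_nm[i])^2) / (2 * sl^2))
        gx <- exp(-(((ix - 1) * pixel_size_nm - cl$x_nm[i])^2) / (2 * sl^2))
        img[iy, ix] <- img[iy, ix] - contrast * background * frac * outer(gy, gx)
      }
    }
    img[img < 0] <- 0
    sections[[s]] <- planar_image(img, pixel_size_nm, modality = "TEM")
  }
  attr(sections, "z_ranges_nm") <- z_ranges
  sections
}
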