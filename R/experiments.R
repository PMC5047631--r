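#' Parameter-recovery experiment for instrument resolution
#'
#' End-to-end validation of the resolution read-out: render many isolated
#' point reflectors inside synthetic cells through a modality's PSF at
#' Nyquist sampling with moderate noise, detect them against a control
#' rendering with [segment_np()], and measure their widths with line-scan
#' FWHM estimation on the background-subtracted reflectance. The mean
#' recovered FWHM should match the preset width of the modality, which is
#' how instrument resolution is reported from real data.
#'
#' Point reflectors are amplitude-matched ideal points (radius 0) placed with
#' an anisotropic minimum-separation rule (2.2 x FWHM per axis) so neighbours
#' never merge or contaminate each other's profiles. Lateral runs use
#' shallow, wide grids; axial runs use deeper grids so z-profiles stay in
#' bounds. Regions whose profile leaves the grid are skipped by
#' [measure_regions()], so slightly more points than `n_points` are rendered.
#'
#' @param modality `"RCM"` or `"RSIM"`.
#' @param axes `"lateral"` (x/y line scans, averaged per region) or
#'   `"axial"` (z line scans).
#' @param n_points target number of measured regions.
#' @param seed integer seed controlling placement and noise.
#' @param snr peak amplitude over read-noise SD.
#' @param points_per_scene reflectors per rendered scene.
#' @param voxel_size_nm acquisition grid pitch `(z, y, x)`; the default is
#'   Nyquist for both modalities laterally (60 nm) with 200 nm z-steps.
#' @param psf optional [psf_preset()] override.
#' @return Object of class `fwhm_recovery`: `summary` (a
#'   [summarize_fwhm()] result), `estimates` (per-region data frame),
#'   `preset_fwhm_nm`, `modality`, `axes`, `n_scenes`.
#' @export
fwhm_recovery_experiment <- function(modality = c("RCM", "RSIM"),
                                     axes = c("lateral", "axial"),
                                     n_points = 100, seed = 1L, snr = 20,
                                     points_per_scene = 20L,
                                     voxel_size_nm = c(200, 60, 60),
                                     psf = NULL) {
  modality <- match.arg(modality)
  axes <- match.arg(axes)
  if (is.null(psf)) psf <- psf_preset(modality)
  fw <- c(z = psf$fwhm_axial, y = psf$fwhm_lateral, x = psf$fwhm_lateral)
  preset <- if (axes == "lateral") psf$fwhm_lateral else psf$fwhm_axial
  prof_axes <- if (axes == "lateral") c("x", "y") else "z"
  half_len <- 1.5 * preset

  shape <- if (axes == "lateral") c(14L, 320L, 320L) else c(36L, 192L, 192L)
  sep <- 2.2 * fw  # (z, y, x) exclusion semi-axes

  amp <- 1000
  read_sigma <- amp / snr
  est_list <- list()
  n_scenes <- 0L
  max_scenes <- ceiling(n_points / points_per_scene) + 3L
  quiet_render <- function(...) withCallingHandlers(
    render_scene(...),
    warning = function(w) {
      if (grepl("Nyquist", conditionMessage(w))) invokeRestart("muffleWarning")
    })

  while (sum(vapply(est_list, nrow, 0L)) < n_points && n_scenes < max_scenes) {
    n_scenes <- n_scenes + 1L
    sseed <- (as.integer(seed) + 104729L * n_scenes) %% 2147480000L
    truth <- generate_ground_truth(
      shape = shape, voxel_size_nm = voxel_size_nm,
      n_clusters = points_per_scene, amplitude_range = c(amp, amp),
      radius_range = c(0, 0), min_separation_nm = sep, seed = sseed)
    ctrl <- generate_ground_truth(
      shape = shape, voxel_size_nm = voxel_size_nm, n_clusters = 0,
      amplitude_range = c(amp, amp), control = TRUE, seed = sseed + 1L)
    st_t <- quiet_render(truth, psf, noise_params(1, read_sigma, sseed + 2L),
                         channels = "reflectance")
    st_c <- quiet_render(ctrl, psf, noise_params(1, read_sigma, sseed + 3L),
                         channels = "reflectance")
    mask <- segment_np(st_t$channels$reflectance,
                       st_c$channels$reflectance)[[1]]
    cc <- connected_components(mask, "full", voxel_size_nm = voxel_size_nm)
    keep <- cc$table$label[cc$table$n_voxels >= 5]
    cc$table <- cc$table[cc$table$label %in% keep, , drop = FALSE]
    if (!nrow(cc$table)) next
    sub <- subtract_background(st_t$channels$reflectance, 6)
    meas <- measure_regions(sub, cc, axes = prof_axes,
                            half_length_nm = half_len, baseline = "zero")
    vals <- if (axes == "lateral") lateral_fwhm(meas)
            else meas[, c("label", "fwhm_nm"), drop = FALSE]
    if (nrow(vals)) {
      vals$scene <- n_scenes
      est_list[[length(est_list) + 1L]] <- vals
    }
  }
  est <- do.call(rbind, est_list)
  structure(list(summary = summarize_fwhm(est$fwhm_nm),
                 estimates = est, preset_fwhm_nm = preset,
                 modality = modality, axes = axes, n_scenes = n_scenes,
                 seed = as.integer(seed)),
            class = "fwhm_recovery")
}

#' @export
print.fwhm_recovery <- function(x, ...) {
  cat(sprintf(
    "<fwhm_recovery> %s %s: mean %.1f nm (preset %.0f nm, %+.1f%%), sd %.1f, n = %d over %d scenes\n",
    x$modality, x$axes, x$summary$mean, x$preset_fwhm_nm,
    100 * (x$summary$mean - x$preset_fwhm_nm) / x$preset_fwhm_nm,
    x$summary$sd, x$summary$n, x$n_scenes))
  invisible(x)
}

#' Paired-modality co-occurrence experiment
#'
#' Renders the same nanoparticle ground truth through the RCM and R-SIM
#' forward models, segments each against its own control, and computes the
#' object-based co-occurrence of the two masks over a common central
#' z-window. The compared window emulates the imperfectly matched
#' acquisition volumes of paired real acquisitions: particles just outside
#' it still bleed into the RCM mask (its broader axial response extends
#' further than the detection threshold) but are cut from the R-SIM mask by
#' the reconstruction's hard axial window, while RCM additionally merges
#' close cluster pairs that R-SIM separates. Both effects push the
#' percentages in the same direction: more R-SIM objects are confirmed in
#' RCM than vice versa.
#'
#' @param n_scenes number of independently seeded paired scenes.
#' @param seed base seed.
#' @param n_clusters clusters per scene.
#' @param shape,voxel_size_nm scene grid.
#' @param z_window number of central z-slices compared.
#' @return Data frame (class `cooccurrence_experiment`) with one row per
#'   scene: `pct_rsim_in_rcm`, `pct_rcm_in_rsim`, `n_rcm`, `n_rsim`.
#' @export
cooccurrence_experiment <- function(n_scenes = 10, seed = 1L,
                                    n_clusters = 15,
                                    shape = c(22, 160, 160),
                                    voxel_size_nm = c(200, 60, 60),
                                    z_window = 10L) {
  res <- vector("list", n_scenes)
  psfs <- list(RCM = psf_preset("RCM"), RSIM = psf_preset("RSIM"))
  quiet_render <- function(...) withCallingHandlers(
    render_scene(...),
    warning = function(w) {
      if (grepl("Nyquist", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  z0 <- floor((shape[1] - z_window) / 2) + 1L
  zidx <- z0:(z0 + z_window - 1L)
  for (i in seq_len(n_scenes)) {
    sseed <- (as.integer(seed) + 7919L * i) %% 2147480000L
    truth <- generate_ground_truth(
      shape = shape, voxel_size_nm = voxel_size_nm, n_clusters = n_clusters,
      amplitude_range = c(800, 1200), radius_range = c(40, 120),
      min_separation_nm = 800, seed = sseed)
    ctrl <- generate_ground_truth(
      shape = shape, voxel_size_nm = voxel_size_nm, n_clusters = 0,
      amplitude_range = c(800, 1200), control = TRUE, seed = sseed + 1L)
    masks <- lapply(names(psfs), function(mod) {
      off <- if (mod == "RCM") 0L else 10L
      st_t <- quiet_render(truth, psfs[[mod]],
                           noise_params(1, 50, sseed + 2L + off),
                           channels = "reflectance")
      st_c <- quiet_render(ctrl, psfs[[mod]],
                           noise_params(1, 50, sseed + 3L + off),
                           channels = "reflectance")
      segment_np(st_t$channels$reflectance, st_c$channels$reflectance)[[1]]
    })
    names(masks) <- names(psfs)
    co <- cooccurrence(masks$RSIM[zidx, , , drop = FALSE],
                       masks$RCM[zidx, , , drop = FALSE])
    res[[i]] <- data.frame(scene = i,
                           pct_rsim_in_rcm = co$pct_A_in_B,
                           pct_rcm_in_rsim = co$pct_B_in_A,
                           n_rsim = co$n_A, n_rcm = co$n_B)
  }
  out <- do.call(rbind, res)
  class(out) <- c("cooccurrence_experiment", class(out))
  out
}
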