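#' Default pipeline configuration
#'
#' A nested list describing an end-to-end run: scene generation, the
#' per-modality PSF presets, noise, segmentation, co-occurrence, resolution
#' and registration settings. Every stochastic stage derives its stream from
#' the single `seed`, so a run is reproducible byte-for-byte.
#'
#' @param seed integer master seed.
#' @param n_scenes number of independent scenes.
#' @return Config list (editable before passing to [run_pipeline()]).
#' @export
default_pipeline_config <- function(seed = 1L, n_scenes = 2L) {
  list(
    seed = as.integer(seed),
    n_scenes = as.integer(n_scenes),
    scene = list(shape = c(12L, 96L, 96L), voxel_size_nm = c(200, 60, 60),
                 n_clusters = 8L, amplitude_range = c(800, 1200),
                 radius_range = c(40, 120), min_separation_nm = 600,
                 control = FALSE),
    modalities = c("RCM", "RSIM"),
    noise = list(photon_scale = 1, read_sigma = 50),
    segmentation = list(smooth_sigma = 0.7, n_clusters = 3L,
                        threshold_multiplier = 3, connectivity = "full"),
    cooccurrence = list(enabled = TRUE, connectivity = "full"),
    resolution = list(axes = c("x", "y"), half_length_factor = 1.5,
                      baseline = "zero", sigma_bg = 6),
    registration = list(enabled = TRUE, model = "rigid", metric = "auto")
  )
}

pipeline_config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full simulate-segment-quantify-resolve-register pipeline
#'
#' For each scene: generates a ground truth and a matched untreated control,
#' renders both through every configured modality, segments the cell and the
#' nanoparticle signal against the control baseline, tabulates connected
#' components and per-cell uptake, measures FWHM distributions on the
#' background-subtracted reflectance, computes cross-modality object
#' co-occurrence, and registers the modality pair's maximum projections.
#' Results are collected into a machine-readable report (JSON when `outdir`
#' is given) stamped with the config hash and seed; region tables are written
#' as CSV and masks optionally as TIFF. A failing stage aborts with the
#' stage name; artefacts written before the failure are retained.
#'
#' @param config a [default_pipeline_config()]-shaped list.
#' @param outdir output directory, or `NULL` to skip writing.
#' @param write_images also write rendered stacks and masks as TIFF.
#' @param verbose log per-stage progress messages.
#' @return The report, invisibly when `outdir` is given.
#' @export
run_pipeline <- function(config = default_pipeline_config(), outdir = NULL,
                         write_images = FALSE, verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  say <- function(...) if (verbose)
    message(sprintf("[%6.1fs] ", proc.time()[["elapsed"]] - t0), ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- pipeline_config_hash(config)
  sc <- config$scene
  sp <- segmentation_params(config$segmentation$smooth_sigma,
                            config$segmentation$n_clusters,
                            config$segmentation$threshold_multiplier,
                            config$segmentation$connectivity)
  psfs <- lapply(config$modalities, psf_preset)
  names(psfs) <- config$modalities
  quiet_render <- function(...) withCallingHandlers(
    render_scene(...),
    warning = function(w) {
      if (grepl("Nyquist", conditionMessage(w))) invokeRestart("muffleWarning")
    })

  scenes <- vector("list", config$n_scenes)
  for (i in seq_len(config$n_scenes)) {
    sseed <- (config$seed + 7919L * i) %% 2147480000L
    say("scene ", i, ": generating truth (seed ", sseed, ")")
    truth <- stage("generate_truth", generate_ground_truth(
      shape = sc$shape, voxel_size_nm = sc$voxel_size_nm,
      n_clusters = sc$n_clusters, amplitude_range = sc$amplitude_range,
      radius_range = sc$radius_range,
      min_separation_nm = sc$min_separation_nm,
      control = isTRUE(sc$control), seed = sseed))
    ctrl <- stage("generate_control", generate_ground_truth(
      shape = sc$shape, voxel_size_nm = sc$voxel_size_nm, n_clusters = 0,
      amplitude_range = sc$amplitude_range, control = TRUE,
      seed = sseed + 1L))

    mod_out <- list(); np_masks <- list(); projections <- list()
    for (mod in config$modalities) {
      off <- 10L * match(mod, config$modalities)
      nz <- noise_params(config$noise$photon_scale, config$noise$read_sigma,
                         sseed + off)
      st_t <- stage("render", quiet_render(truth, psfs[[mod]], nz))
      st_c <- stage("render_control", quiet_render(
        ctrl, psfs[[mod]],
        noise_params(config$noise$photon_scale, config$noise$read_sigma,
                     sseed + off + 1L)))
      say("scene ", i, " ", mod, ": segmenting")
      cell <- stage("segment_cell", segment_cell(
        st_t$channels$cytoplasm, segmentation_params(1, 2)))
      mask <- stage("segment_np", segment_np(
        st_t$channels$reflectance, st_c$channels$reflectance, sp))[[1]]
      np_masks[[mod]] <- mask
      cc <- stage("connected_components", connected_components(
        mask, config$cooccurrence$connectivity,
        intensity = st_t$channels$reflectance,
        voxel_size_nm = sc$voxel_size_nm))
      cell_sum <- stage("per_cell_summary", per_cell_summary(
        cell, mask, intensity = st_t$channels$reflectance,
        connectivity = config$cooccurrence$connectivity,
        voxel_size_nm = sc$voxel_size_nm))
      say("scene ", i, " ", mod, ": ", cc$n, " NP component(s)")
      fw <- NULL
      if (cc$n >= 2) {
        sub <- subtract_background(st_t$channels$reflectance,
                                   config$resolution$sigma_bg)
        hl <- config$resolution$half_length_factor * psfs[[mod]]$fwhm_lateral
        meas <- stage("measure_regions", measure_regions(
          sub, cc, axes = config$resolution$axes, half_length_nm = hl,
          baseline = config$resolution$baseline))
        lat <- lateral_fwhm(meas)
        if (nrow(lat) >= 2) {
          s <- summarize_fwhm(lat$fwhm_nm)
          fw <- list(mean_nm = s$mean, sd_nm = s$sd, n = s$n)
        }
      }
      projections[[mod]] <- max_projection(st_t$channels$reflectance)
      if (!is.null(outdir)) {
        utils::write.csv(cc$table,
                         file.path(outdir, sprintf("scene%02d_%s_regions.csv", i, mod)),
                         row.names = FALSE)
        if (write_images) {
          write_stack_tiff(st_t, outdir, sprintf("scene%02d_%s", i, mod))
          write_mask_tiff(mask,
                          file.path(outdir, sprintf("scene%02d_%s_npmask.tif", i, mod)))
        }
      }
      mod_out[[mod]] <- list(
        n_np_components = cc$n,
        n_np_components_in_cell = cell_sum$n_components,
        total_np_volume_nm3 = sum(cc$table$volume_nm3),
        mean_spot_intensity = cell_sum$mean_intensity,
        cell_voxels = sum(cell),
        fwhm = fw)
    }

    co <- NULL
    if (isTRUE(config$cooccurrence$enabled) && length(np_masks) >= 2) {
      co_raw <- stage("cooccurrence", cooccurrence(
        np_masks[[1]], np_masks[[2]], config$cooccurrence$connectivity))
      co <- list(A = names(np_masks)[1], B = names(np_masks)[2],
                 n_A = co_raw$n_A, n_B = co_raw$n_B,
                 pct_A_in_B = co_raw$pct_A_in_B,
                 pct_B_in_A = co_raw$pct_B_in_A)
    }
    reg <- NULL
    if (isTRUE(config$registration$enabled) && length(projections) >= 2 &&
        !isTRUE(sc$control)) {
      tf <- stage("register", tryCatch(
        register_intensity(projections[[1]], projections[[2]],
                           model = config$registration$model,
                           metric = config$registration$metric),
        npreflect_registration_error = function(e) e$transform))
      reg <- list(fixed = names(projections)[1],
                  moving = names(projections)[2],
                  model = tf$model, angle_deg = rotation_angle(tf),
                  translation_nm = tf$translation,
                  metric = as.numeric(attr(tf, "metric")))
    }
    scenes[[i]] <- list(scene = i, seed = sseed, modalities = mod_out,
                        cooccurrence = co, registration = reg)
  }

  report <- list(package = "npreflect",
                 version = as.character(utils::packageVersion("npreflect")),
                 seed = config$seed, config_hash = hash,
                 n_scenes = config$n_scenes, scenes = scenes)
  if (!is.null(outdir)) {
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    say("report written to ", file.path(outdir, "report.json"))
    return(invisible(report))
  }
  report
}
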