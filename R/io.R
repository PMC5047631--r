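#' Write a multi-channel stack as TIFF files with a JSON sidecar
#'
#' Each channel becomes one multi-page 16-bit TIFF (one page per z-slice);
#' intensities are scaled into `[0, 1]` per channel and the scale factors,
#' voxel size, modality and seed go into `<prefix>_meta.json` so
#' [read_stack_tiff()] restores the original values.
#'
#' @param stack a [multichannel_stack].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the sidecar path.
#' @export
write_stack_tiff <- function(stack, dir, prefix = "stack") {
  stopifnot(inherits(stack, "multichannel_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(voxel_size_nm = stack$channels[[1]]$voxel_size_nm,
               modality = stack$channels[[1]]$modality,
               seed = stack$meta$seed, channels = list())
  for (nm in names(stack$channels)) {
    a <- stack$channels[[nm]]$data
    lo <- min(a); hi <- max(a)
    sc <- if (hi > lo) (a - lo) / (hi - lo) else a * 0
    pages <- lapply(seq_len(dim(a)[1]), function(z) sc[z, , ])
    path <- file.path(dir, sprintf("%s_%s.tif", prefix, nm))
    tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
    meta$channels[[nm]] <- list(file = basename(path), min = lo, max = hi,
                                nz = dim(a)[1])
  }
  side <- file.path(dir, sprintf("%s_meta.json", prefix))
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(dir, prefix = "stack") {
  meta <- jsonlite::read_json(file.path(dir, sprintf("%s_meta.json", prefix)),
                              simplifyVector = TRUE)
  chans <- list()
  for (nm in names(meta$channels)) {
    info <- meta$channels[[nm]]
    pages <- tiff::readTIFF(file.path(dir, info$file), all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d <- c(length(pages), dim(pages[[1]]))
    a <- array(0, d)
    for (z in seq_len(d[1])) a[z, , ] <- pages[[z]]
    a <- a * (info$max - info$min) + info$min
    chans[[nm]] <- volume_image(a, meta$voxel_size_nm, meta$modality)
  }
  multichannel_stack(chans, meta = list(modality = meta$modality,
                                        seed = meta$seed))
}

#' Write / read a binary mask as an 8-bit TIFF
#'
#' @param mask logical 3D array (or [volume_image]).
#' @param path output path.
#' @return `write_mask_tiff` returns the path invisibly; `read_mask_tiff`
#'   a logical array.
#' @export
write_mask_tiff <- function(mask, path) {
  a <- if (inherits(mask, "volume_image")) mask$data else mask
  pages <- lapply(seq_len(dim(a)[1]), function(z) (a[z, , ]) * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8, compression = "none")
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(length(pages), dim(pages[[1]]))
  a <- array(FALSE, d)
  for (z in seq_len(d[1])) a[z, , ] <- pages[[z]] > 0.5
  a
}

#' Write ground truth tables for a scene
#'
#' Cluster table as CSV plus a JSON record of grid, seed and control flag,
#' for test harnesses and provenance.
#'
#' @param truth a [generate_ground_truth()] scene.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return Invisibly, the CSV path.
#' @export
write_truth <- function(truth, dir, prefix = "truth") {
  stopifnot(inherits(truth, "scene_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, sprintf("%s_clusters.csv", prefix))
  utils::write.csv(truth$np_clusters, csv, row.names = FALSE)
  jsonlite::write_json(list(shape = truth$shape,
                            voxel_size_nm = truth$voxel_size_nm,
                            background_level = truth$background_level,
                            control = truth$control, seed = truth$seed),
                       file.path(dir, sprintf("%s_meta.json", prefix)),
                       auto_unbox = TRUE, digits = NA)
  invisible(csv)
}
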