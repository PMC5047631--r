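#' Label connected components and tabulate region properties
#'
#' Labels every maximal connected foreground set of a 2D or 3D binary mask
#' under the requested connectivity and returns a region table: voxel count,
#' physical area (2D) or volume (3D), centroid in voxel and physical
#' coordinates, and mean/max intensity when an intensity image is supplied.
#' Labels are contiguous from 1, ordered by first (column-major) foreground
#' voxel. Adjacency edges between foreground voxels are resolved to
#' components with `igraph`.
#'
#' @param mask logical array/matrix (or [volume_image] with logical data).
#' @param connectivity `"full"` (includes diagonals: 8-neighbour in 2D,
#'   26-neighbour in 3D) or `"face"` (4- / 6-neighbour).
#' @param intensity optional intensity image matching `mask`.
#' @param voxel_size_nm physical voxel size (length matching the mask
#'   dimensionality, or scalar); needed for physical areas/volumes.
#' @return Object of class `cc_result`: list with `table` (data frame),
#'   `labels` (integer array, 0 = background), `n`, `connectivity`,
#'   `voxel_size_nm`.
#' @export
#' @examples
#' m <- matrix(FALSE, 4, 4); m[1, 1] <- m[2, 2] <- TRUE
#' connected_components(m, "full")$n  # diagonal touch: one component
#' connected_components(m, "face")$n  # two
connected_components <- function(mask, connectivity = c("full", "face"),
                                 intensity = NULL, voxel_size_nm = 1) {
  connectivity <- match.arg(connectivity)
  if (inherits(mask, "volume_image")) {
    voxel_size_nm <- mask$voxel_size_nm
    mask <- mask$data
  }
  if (inherits(intensity, "volume_image")) intensity <- intensity$data
  nd_in <- length(dim(mask))
  if (is.null(dim(mask)) || !nd_in %in% 2:3)
    stop("mask must be a 2D or 3D array")
  d_in <- dim(mask)
  vox <- rep_len(as.numeric(voxel_size_nm), nd_in)
  mode(mask) <- "logical"

  # promote 2D to a single-slice 3D problem
  d <- if (nd_in == 2L) c(1L, d_in) else d_in
  dim(mask) <- d
  if (!is.null(intensity)) dim(intensity) <- d

  fg <- which(mask)
  nfg <- length(fg)
  labels <- array(0L, d)
  empty <- data.frame(label = integer(0), n_voxels = integer(0),
                      size_nm = numeric(0),
                      centroid_z = numeric(0), centroid_y = numeric(0),
                      centroid_x = numeric(0),
                      centroid_z_nm = numeric(0), centroid_y_nm = numeric(0),
                      centroid_x_nm = numeric(0),
                      mean_intensity = numeric(0), max_intensity = numeric(0))
  if (nfg == 0L) {
    dim(labels) <- d_in
    names(empty)[names(empty) == "size_nm"] <-
      if (nd_in == 2L) "area_nm2" else "volume_nm3"
    return(structure(list(table = empty, labels = labels, n = 0L,
                          connectivity = connectivity, voxel_size_nm = vox),
                     class = "cc_result"))
  }

  co <- arrayInd(fg, d)
  id_of <- integer(prod(d))
  id_of[fg] <- seq_len(nfg)

  offs <- neighbour_offsets(connectivity, forward_only = TRUE)
  efrom <- integer(0); eto <- integer(0)
  for (r in seq_len(nrow(offs))) {
    oz <- offs[r, 1]; oy <- offs[r, 2]; ox <- offs[r, 3]
    z <- co[, 1] + oz; y <- co[, 2] + oy; x <- co[, 3] + ox
    ok <- z >= 1L & z <= d[1] & y >= 1L & y <= d[2] & x >= 1L & x <= d[3]
    if (!any(ok)) next
    nb <- id_of[z[ok] + (y[ok] - 1L) * d[1] + (x[ok] - 1L) * d[1] * d[2]]
    hit <- nb > 0L
    efrom <- c(efrom, which(ok)[hit])
    eto <- c(eto, nb[hit])
  }
  if (length(efrom)) {
    g <- igraph::make_graph(as.vector(rbind(efrom, eto)), n = nfg,
                            directed = FALSE)
    mem <- igraph::components(g)$membership
  } else {
    mem <- seq_len(nfg)
  }
  # contiguous labels ordered by first foreground voxel
  first <- !duplicated(mem)
  relab <- integer(max(mem))
  relab[mem[first]] <- seq_len(sum(first))
  mem <- relab[mem]
  ncomp <- max(mem)

  labels[fg] <- mem
  nvox <- tabulate(mem, ncomp)
  cen <- rowsum(co, mem) / nvox
  # physical coords: slice the voxel sizes back to input dimensionality
  vox3 <- if (nd_in == 2L) c(1, vox) else vox
  cen_nm <- sweep(cen - 1, 2, vox3, "*")
  unit <- prod(vox)
  tab <- data.frame(
    label = seq_len(ncomp), n_voxels = nvox, size_nm = nvox * unit,
    centroid_z = cen[, 1], centroid_y = cen[, 2], centroid_x = cen[, 3],
    centroid_z_nm = cen_nm[, 1], centroid_y_nm = cen_nm[, 2],
    centroid_x_nm = cen_nm[, 3],
    mean_intensity = NA_real_, max_intensity = NA_real_)
  if (!is.null(intensity)) {
    vals <- intensity[fg]
    tab$mean_intensity <- as.vector(rowsum(vals, mem) / nvox)
    tab$max_intensity <- as.vector(tapply(vals, mem, max))
  }
  names(tab)[names(tab) == "size_nm"] <-
    if (nd_in == 2L) "area_nm2" else "volume_nm3"
  dim(labels) <- d_in
  structure(list(table = tab, labels = labels, n = ncomp,
                 connectivity = connectivity, voxel_size_nm = vox),
            class = "cc_result")
}

#' @export
print.cc_result <- function(x, ...) {
  cat(sprintf("<cc_result> %d component%s (%s connectivity)\n",
              x$n, if (x$n == 1) "" else "s", x$connectivity))
  if (x$n) print(utils::head(x$table, 10))
  invisible(x)
}

neighbour_offsets <- function(connectivity, forward_only = FALSE) {
  if (connectivity == "face") {
    offs <- rbind(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
    if (!forward_only) offs <- rbind(offs, -offs)
    return(offs)
  }
  g <- as.matrix(expand.grid(z = -1:1, y = -1:1, x = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (forward_only) {
    # keep one of each +/- pair: first nonzero coordinate positive
    keep <- apply(g, 1, function(o) o[which(o != 0)[1]] > 0)
    g <- g[keep, , drop = FALSE]
  }
  storage.mode(g) <- "integer"
  g
}

#' Object-based co-occurrence of two segmentation masks
#'
#' Counts, for each mask, how many of its connected components overlap the
#' other mask's foreground in at least one voxel (the voxel-wise product of
#' the binary images), and expresses them as percentages of that mask's
#' component count. Components, not voxels, are the unit of comparison:
#' voxel-based measures are not meaningful across modalities with different
#' resolutions. Each source component counts at most once however many
#' product fragments touch it.
#'
#' @param mask_A,mask_B logical arrays of identical shape (equalise pixel
#'   sizes and register first).
#' @param connectivity passed to [connected_components()].
#' @return Object of class `cooccurrence_result`: `n_A`, `n_B`, `n_A_in_B`,
#'   `n_B_in_A`, `pct_A_in_B`, `pct_B_in_A`.
#' @export
cooccurrence <- function(mask_A, mask_B, connectivity = c("full", "face")) {
  connectivity <- match.arg(connectivity)
  a <- if (inherits(mask_A, "volume_image")) mask_A$data else mask_A
  b <- if (inherits(mask_B, "volume_image")) mask_B$data else mask_B
  if (!identical(dim(a), dim(b)))
    stop("mask shapes differ; equalise pixel size and register first")
  ca <- connected_components(a, connectivity)
  cb <- connected_components(b, connectivity)
  both <- which(a & b)
  n_A_in_B <- length(unique(ca$labels[both]))
  n_B_in_A <- length(unique(cb$labels[both]))
  structure(list(
    n_A = ca$n, n_B = cb$n, n_A_in_B = n_A_in_B, n_B_in_A = n_B_in_A,
    pct_A_in_B = if (ca$n) 100 * n_A_in_B / ca$n else NA_real_,
    pct_B_in_A = if (cb$n) 100 * n_B_in_A / cb$n else NA_real_),
    class = "cooccurrence_result")
}

#' @export
print.cooccurrence_result <- function(x, ...) {
  cat(sprintf("<cooccurrence> A: %d components, %.1f%% in B | B: %d components, %.1f%% in A\n",
              x$n_A, x$pct_A_in_B, x$n_B, x$pct_B_in_A))
  invisible(x)
}

#' Axial persistence of 3D components
#'
#' For each 3D connected component, the length of its maximal run of
#' consecutive z-slices containing at least one voxel — the number of optical
#' sections a particle appears in. A component whose occupied slices have
#' gaps (possible only through in-plane connections skipping slices under
#' face connectivity, or disjoint labelling artefacts) is flagged with a
#' warning.
#'
#' @param mask 3D logical array or [volume_image] (labelled internally), a
#'   [connected_components()] result, or an integer label array from another
#'   labelling (where gaps can genuinely occur, e.g. per-slice 2D labels
#'   merged by object id).
#' @param connectivity passed to [connected_components()] when `mask` is
#'   binary.
#' @return Data frame with `label`, `persistence` (max consecutive-slice
#'   run) and `has_gap`.
#' @export
axial_persistence <- function(mask, connectivity = c("full", "face")) {
  connectivity <- match.arg(connectivity)
  labels <- if (inherits(mask, "cc_result")) {
    mask$labels
  } else {
    a <- if (inherits(mask, "volume_image")) mask$data else mask
    if (is.integer(a) && any(a > 1L)) a
    else connected_components(a, connectivity)$labels
  }
  if (length(dim(labels)) != 3L) stop("axial persistence needs a 3D mask")
  if (!any(labels > 0))
    return(data.frame(label = integer(0), persistence = integer(0),
                      has_gap = logical(0)))
  fg <- which(labels > 0)
  z <- arrayInd(fg, dim(labels))[, 1]
  lab <- labels[fg]
  res <- lapply(split(z, lab), function(zs) {
    zs <- sort(unique(zs))
    runs <- split(zs, cumsum(c(1L, diff(zs) != 1L)))
    c(persistence = max(lengths(runs)), has_gap = length(runs) > 1L)
  })
  out <- data.frame(label = as.integer(names(res)),
                    persistence = vapply(res, `[[`, 0, "persistence"),
                    has_gap = vapply(res, `[[`, 0, "has_gap") > 0,
                    row.names = NULL)
  out <- out[order(out$label), , drop = FALSE]
  rownames(out) <- NULL
  if (any(out$has_gap))
    warning("component(s) ", paste(out$label[out$has_gap], collapse = ", "),
            " span non-consecutive z-slices")
  out
}

#' Per-cell nanoparticle uptake summary
#'
#' Restricts the nanoparticle mask to the cell and reports the connected
#' component count, total physical volume and mean spot intensity — the
#' uptake read-out used to compare treated against control cells.
#'
#' @param cell_mask,np_mask logical arrays of equal shape.
#' @param intensity optional intensity image for the mean spot intensity.
#' @param connectivity passed to [connected_components()].
#' @param voxel_size_nm physical voxel size.
#' @return List with `n_components`, `total_volume_nm3` (or `total_area_nm2`
#'   in 2D), `mean_intensity`.
#' @export
per_cell_summary <- function(cell_mask, np_mask, intensity = NULL,
                             connectivity = c("full", "face"),
                             voxel_size_nm = 1) {
  connectivity <- match.arg(connectivity)
  cm <- if (inherits(cell_mask, "volume_image")) cell_mask$data else cell_mask
  nm <- if (inherits(np_mask, "volume_image")) np_mask$data else np_mask
  if (!identical(dim(cm), dim(nm))) stop("mask shapes differ")
  if (!any(cm)) stop("empty cell mask")
  inside <- nm & cm
  cc <- connected_components(inside, connectivity, intensity = intensity,
                             voxel_size_nm = voxel_size_nm)
  sz_col <- intersect(c("volume_nm3", "area_nm2"), names(cc$table))
  vals <- if (!is.null(intensity)) {
    ii <- if (inherits(intensity, "volume_image")) intensity$data else intensity
    if (any(inside)) mean(ii[inside]) else NA_real_
  } else NA_real_
  out <- list(n_components = cc$n,
              total = sum(cc$table[[sz_col]]),
              mean_intensity = vals)
  names(out)[2] <- paste0("total_", sub("_nm", "_nm", sz_col))
  out
}

#' Two-sample Student's t-test
#'
#' Two-sided comparison of group means, pooled-variance Student form by
#' default (Welch optional), as used for treated-vs-control uptake and
#' modality FWHM comparisons. Delegates to [stats::t.test()].
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param welch logical; `TRUE` for the Welch (unequal-variance) form.
#' @return List with `t`, `p`, `df`.
#' @export
two_sample_ttest <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 observations")
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0)
    stop("zero variance in both groups: t statistic undefined")
  ht <- stats::t.test(group_a, group_b, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}
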