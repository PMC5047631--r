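#' Least-squares transform from corresponding point pairs
#'
#' Estimates the planar transform minimising the sum of squared residuals
#' `sum ||T(moving_i) - fixed_i||^2` over known correspondences: rigid
#' (rotation + translation) by orthogonal Procrustes, affine by the normal
#' equations. This is the point-pair alignment workflow (a handful of
#' manually picked landmark pairs), with the affine model accommodating the
#' anisotropic shrinkage TEM processing introduces.
#'
#' @param fixed,moving n x 2 matrices of corresponding `(x, y)` nm points,
#'   equal row counts (n >= 2 rigid, n >= 3 non-collinear affine).
#' @param model `"rigid"` or `"affine"`.
#' @return A [planar_transform] mapping moving to fixed; attribute `rmse`
#'   holds the root-mean-square residual.
#' @export
estimate_from_points <- function(fixed, moving, model = c("rigid", "affine")) {
  model <- match.arg(model)
  fixed <- as.matrix(fixed); moving <- as.matrix(moving)
  if (!identical(dim(fixed), dim(moving)) || ncol(fixed) != 2L)
    stop("fixed and moving must be n x 2 matrices with equal n")
  n <- nrow(fixed)
  if (model == "rigid" && n < 2L) stop("rigid estimation needs >= 2 pairs")
  if (model == "affine" && n < 3L) stop("affine estimation needs >= 3 pairs")

  if (model == "rigid") {
    cf <- colMeans(fixed); cm <- colMeans(moving)
    H <- crossprod(sweep(moving, 2, cm), sweep(fixed, 2, cf))
    sv <- svd(H)
    dsign <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, dsign)) %*% t(sv$u)
    tf <- planar_transform("rigid", R, cf - as.vector(R %*% cm))
  } else {
    X <- cbind(moving, 1)
    B <- tryCatch(solve(crossprod(X), crossprod(X, fixed)),
                  error = function(e)
                    stop("degenerate (collinear) point configuration for affine estimation"))
    M <- t(B[1:2, , drop = FALSE])
    if (abs(det(M)) < 1e-12)
      stop("degenerate (collinear) point configuration for affine estimation")
    tf <- planar_transform("affine", M, B[3, ])
  }
  res <- transform_points(tf, moving) - fixed
  attr(tf, "rmse") <- sqrt(mean(rowSums(res^2)))
  tf
}

#' Resample a 2D image through a planar transform
#'
#' Pulls each fixed-grid pixel from the moving image through the inverse
#' map with bilinear interpolation (physical nm coordinates; pixel `(1,1)`
#' sits at 0 nm).
#'
#' @param moving a [planar_image] or matrix.
#' @param transform [planar_transform] mapping moving to fixed coordinates.
#' @param fixed_dim output dimensions `(ny, nx)`; defaults to the moving
#'   image's.
#' @param fixed_pixel_size_nm output pixel size; defaults to the moving
#'   image's.
#' @param fill value for pixels mapping outside the moving image.
#' @return Matrix of dimensions `fixed_dim`.
#' @export
warp_image <- function(moving, transform, fixed_dim = NULL,
                       fixed_pixel_size_nm = NULL, fill = NA_real_) {
  m <- as_plane_matrix(moving)
  mpx <- plane_pixel_size(moving, default = fixed_pixel_size_nm)
  if (is.null(fixed_dim)) fixed_dim <- dim(m)
  fpx <- if (is.null(fixed_pixel_size_nm)) mpx
         else rep_len(as.numeric(fixed_pixel_size_nm), 2L)
  inv <- invert_transform(transform)
  gx <- (seq_len(fixed_dim[2]) - 1) * fpx[2]
  gy <- (seq_len(fixed_dim[1]) - 1) * fpx[1]
  pts <- cbind(rep(gx, each = fixed_dim[1]), rep(gy, times = fixed_dim[2]))
  src <- transform_points(inv, pts)
  vals <- interp2(m, src[, 2] / mpx[1] + 1, src[, 1] / mpx[2] + 1)
  vals[is.na(vals)] <- fill
  matrix(vals, fixed_dim[1], fixed_dim[2])
}

ncc_metric <- function(f, w) {
  ok <- is.finite(f) & is.finite(w)
  if (sum(ok) < 32 || stats::sd(f[ok]) == 0 || stats::sd(w[ok]) == 0)
    return(-Inf)
  stats::cor(f[ok], w[ok])
}

mi_metric <- function(f, w, bins = 32) {
  ok <- is.finite(f) & is.finite(w)
  if (sum(ok) < 64) return(-Inf)
  fb <- cut(f[ok], bins, labels = FALSE)
  wb <- cut(w[ok], bins, labels = FALSE)
  jt <- table(fb, wb) / sum(ok)
  px <- rowSums(jt); py <- colSums(jt)
  nz <- jt > 0
  sum(jt[nz] * log(jt[nz] / outer(px, py)[nz]))
}

#' Intensity-based 2D registration
#'
#' Automates alignment of two single-plane images by maximising an intensity
#' similarity metric over rigid (or affine-refined) transforms: normalized
#' cross-correlation within a modality, mutual information across
#' modalities. To succeed on reflectance data the images are first smoothed
#' and background subtracted (otherwise the diffuse cellular background
#' dominates the metric); set `preprocess = FALSE` to see why that matters.
#' The optimum is found by an FFT cross-correlation translation sweep at each
#' candidate rotation, followed by Nelder-Mead refinement on the full metric.
#'
#' @param fixed,moving [planar_image] objects (pixel sizes are equalised
#'   first) or matrices sharing a pixel size.
#' @param model `"rigid"` (rotation + translation) or `"affine"` (adds a
#'   6-parameter refinement).
#' @param preprocess smooth (sigma 1.5 px) and background-subtract
#'   (sigma 12 px) both images first.
#' @param metric `"auto"` (NCC when modality tags match, MI otherwise),
#'   `"ncc"` or `"mi"`.
#' @param rotation_range_deg half-range of candidate rotations.
#' @param rotation_step_deg coarse rotation step.
#' @param max_iter Nelder-Mead iteration cap; exceeding it raises an error of
#'   class `npreflect_registration_error` carrying the best-so-far transform
#'   in its `transform` field.
#' @return A [planar_transform] (moving to fixed, nm) with attributes
#'   `metric` (final value) and `metric_name`.
#' @export
register_intensity <- function(fixed, moving, model = c("rigid", "affine"),
                               preprocess = TRUE,
                               metric = c("auto", "ncc", "mi"),
                               rotation_range_deg = 10,
                               rotation_step_deg = 2.5,
                               max_iter = 500) {
  model <- match.arg(model)
  metric <- match.arg(metric)
  if (metric == "auto") {
    mf <- if (inherits(fixed, "planar_image")) fixed$modality else "generic"
    mm <- if (inherits(moving, "planar_image")) moving$modality else "generic"
    metric <- if (identical(mf, mm)) "ncc" else "mi"
  }
  eq <- equalize_pixel_size(fixed, moving)
  px <- plane_pixel_size(eq[[1]], default = 1)
  f <- as_plane_matrix(eq[[1]])
  m <- as_plane_matrix(eq[[2]])
  if (preprocess) {
    f <- pmax(gaussian_blur(f, 1.5) - gaussian_blur(f, 12), 0)
    m <- pmax(gaussian_blur(m, 1.5) - gaussian_blur(m, 12), 0)
  }
  score_fun <- if (metric == "ncc") ncc_metric else mi_metric

  eval_par <- function(par) {
    tf <- rigid_transform(par[3], par[1:2])
    w <- warp_image(planar_image(m, px), tf, fixed_dim = dim(f),
                    fixed_pixel_size_nm = px)
    score_fun(f, w)
  }

  # coarse: FFT cross-correlation translation sweep per candidate rotation
  angles <- seq(-rotation_range_deg, rotation_range_deg, by = rotation_step_deg)
  best <- list(score = -Inf, par = c(0, 0, 0))
  f0 <- f - mean(f)
  nyx <- dim(f)
  for (th in angles) {
    mr <- if (th != 0) {
      w <- warp_image(planar_image(m, px), rigid_transform(th),
                      fixed_dim = dim(m), fixed_pixel_size_nm = px, fill = 0)
      w
    } else m
    mr0 <- matrix(0, nyx[1], nyx[2])
    cp <- pmin(dim(mr), nyx)
    mr0[seq_len(cp[1]), seq_len(cp[2])] <- mr[seq_len(cp[1]), seq_len(cp[2])]
    mr0 <- mr0 - mean(mr0)
    cc <- Re(stats::fft(stats::fft(f0) * Conj(stats::fft(mr0)), inverse = TRUE))
    pk <- which.max(cc)
    iy <- (pk - 1) %% nyx[1]
    ix <- (pk - 1) %/% nyx[1]
    if (iy > nyx[1] / 2) iy <- iy - nyx[1]
    if (ix > nyx[2] / 2) ix <- ix - nyx[2]
    par <- c(ix * px[2], iy * px[1], th)
    # rotation in warp is about the origin; the FFT shift already includes it
    sc <- eval_par(par)
    if (sc > best$score) best <- list(score = sc, par = par)
  }

  opt <- stats::optim(best$par, function(p) -eval_par(p),
                      method = "Nelder-Mead",
                      control = list(maxit = max_iter,
                                     parscale = c(px[2], px[1], 0.5)))
  par <- opt$par
  tf <- rigid_transform(par[3], par[1:2])
  value <- -opt$value

  if (model == "affine") {
    p0 <- c(as.vector(tf$matrix), tf$translation)
    eval_aff <- function(p) {
      M <- matrix(p[1:4], 2, 2)
      if (abs(det(M)) < 1e-6) return(-Inf)
      taf <- planar_transform("affine", M, p[5:6])
      w <- warp_image(planar_image(m, px), taf, fixed_dim = dim(f),
                      fixed_pixel_size_nm = px)
      score_fun(f, w)
    }
    opta <- stats::optim(p0, function(p) -eval_aff(p), method = "Nelder-Mead",
                         control = list(maxit = max_iter,
                                        parscale = c(rep(0.05, 4), px[2], px[1])))
    if (-opta$value >= value) {
      tf <- planar_transform("affine", matrix(opta$par[1:4], 2, 2),
                             opta$par[5:6])
      value <- -opta$value
      opt <- opta
    }
  }
  if (opt$convergence == 1L) {
    cond <- structure(class = c("npreflect_registration_error", "error",
                                "condition"),
                      list(message = paste0("registration did not converge within ",
                                            max_iter, " iterations"),
                           call = sys.call(), transform = tf, metric = value))
    stop(cond)
  }
  attr(tf, "metric") <- value
  attr(tf, "metric_name") <- metric
  tf
}

#' Coherent Point Drift registration of two point sets
#'
#' Fits the moving set to the fixed set without known correspondences: the
#' moving points are the centroids of an isotropic Gaussian mixture, a
#' uniform outlier component takes weight `w`, and EM alternates soft
#' assignment (E-step) with a closed-form rigid (rotation via orthogonal
#' decomposition, optional scale, translation) or affine update and variance
#' re-estimation (M-step). Deterministic: the transform starts at identity
#' and the variance at the mean pairwise squared distance.
#'
#' @param fixed n x 2 matrix of `(x, y)` nm points (the reference set).
#' @param moving m x 2 matrix of points to register onto `fixed`.
#' @param model `"rigid"` or `"affine"`.
#' @param w outlier weight in `[0, 1)`.
#' @param scale logical; estimate an isotropic scale in the rigid model.
#' @param tol convergence threshold on the change in mixture variance.
#' @param max_iter maximum EM iterations (a warning is issued with the last
#'   iterate if reached).
#' @return List of class `cpd_result`: `transform` (a [planar_transform];
#'   rigid with scale estimation is reported as model `"rigid"` with a scaled
#'   rotation), `P` (m x n soft correspondence matrix, rows summing to at
#'   most 1 with the remainder being outlier probability), `sigma2`,
#'   `iterations`, `converged`.
#' @export
cpd_register <- function(fixed, moving, model = c("rigid", "affine"),
                         w = 0.1, scale = FALSE, tol = 1e-8, max_iter = 200) {
  model <- match.arg(model)
  X <- as.matrix(fixed); Y <- as.matrix(moving)
  if (!nrow(X) || !nrow(Y)) stop("point sets must be non-empty")
  if (ncol(X) != 2L || ncol(Y) != 2L) stop("point sets must be n x 2")
  if (w < 0 || w >= 1) stop("w must be in [0, 1)")
  N <- nrow(X); M <- nrow(Y); D <- 2

  TY <- Y
  d2 <- function(A, B) {
    outer(rowSums(A^2), rep(1, nrow(B))) +
      outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  }
  sigma2 <- sum(d2(Y, X)) / (D * M * N)
  B <- diag(2); tvec <- c(0, 0); s <- 1
  conv <- FALSE; it <- 0; P <- NULL

  while (it < max_iter) {
    it <- it + 1
    D2 <- d2(TY, X)                              # M x N
    num <- exp(-D2 / (2 * sigma2))
    cden <- (2 * pi * sigma2)^(D / 2) * w / (1 - w) * M / N
    den <- colSums(num) + cden                   # length N
    P <- sweep(num, 2, den, "/")
    Np <- sum(P)
    if (Np < 1e-12) break
    P1 <- rowSums(P)                             # length M
    Pt1 <- colSums(P)                            # length N
    mu_x <- as.vector(t(X) %*% Pt1) / Np
    mu_y <- as.vector(t(Y) %*% P1) / Np
    Xh <- sweep(X, 2, mu_x)
    Yh <- sweep(Y, 2, mu_y)
    A <- t(Xh) %*% t(P) %*% Yh                   # D x D
    if (model == "rigid") {
      sv <- svd(A)
      C <- diag(c(1, sign(det(sv$u %*% t(sv$v)))))
      R <- sv$u %*% C %*% t(sv$v)
      denom <- sum(P1 * rowSums(Yh^2))
      s <- if (scale) sum(diag(t(A) %*% R)) / denom else 1
      B <- s * R
    } else {
      B <- A %*% solve(t(Yh) %*% (P1 * Yh))
    }
    tvec <- mu_x - as.vector(B %*% mu_y)
    TY <- sweep(Y %*% t(B), 2, tvec, "+")
    sigma2_new <- (sum(Pt1 * rowSums(Xh^2)) -
                     sum(diag(A %*% t(B)))) / (Np * D)
    if (!is.finite(sigma2_new) || sigma2_new < 1e-12) {
      sigma2 <- max(sigma2_new, 1e-12)
      conv <- TRUE
      break
    }
    if (abs(sigma2 - sigma2_new) < tol) {
      sigma2 <- sigma2_new
      conv <- TRUE
      break
    }
    sigma2 <- sigma2_new
  }
  if (!conv)
    warning("CPD reached max_iter = ", max_iter,
            " before the variance change fell below tol; returning last iterate")
  model_out <- if (model == "rigid") "rigid" else "affine"
  structure(list(
    transform = planar_transform(model_out, B, tvec),
    P = P, sigma2 = sigma2, iterations = it, converged = conv),
    class = "cpd_result")
}

#' @export
print.cpd_result <- function(x, ...) {
  cat(sprintf("<cpd_result> %s, %d iterations (%sconverged), sigma2 %.4g\n",
              x$transform$model, x$iterations,
              if (x$converged) "" else "NOT ", x$sigma2))
  print(x$transform)
  invisible(x)
}

#' Resample two images onto the finer of their pixel grids
#'
#' The coarser image is linearly interpolated onto the finer pitch per axis;
#' physical extents are preserved (pixel centres at `(i - 1) * pitch`).
#' Images already on equal pitches are returned unchanged.
#'
#' @param a,b [planar_image] objects.
#' @return List of two [planar_image] objects on the common (finer) pitch.
#' @export
equalize_pixel_size <- function(a, b) {
  if (!inherits(a, "planar_image") || !inherits(b, "planar_image")) {
    # bare matrices carry no pixel size: treat as already equal if same shape
    if (is.matrix(a) && is.matrix(b)) return(list(planar_image(a, 1), planar_image(b, 1)))
    stop("pixel size unknown: supply planar_image inputs")
  }
  target <- pmin(a$pixel_size_nm, b$pixel_size_nm)
  resample <- function(img) {
    if (max(abs(img$pixel_size_nm - target)) < 1e-9) return(img)
    d <- dim(img$data)
    ext <- (d - 1) * img$pixel_size_nm
    nd <- pmax(floor(round(ext / target, 9)) + 1L, 2L)
    yy <- (seq_len(nd[1]) - 1) * target[1] / img$pixel_size_nm[1] + 1
    xx <- (seq_len(nd[2]) - 1) * target[2] / img$pixel_size_nm[2] + 1
    vals <- interp2(img$data, rep(yy, times = nd[2]), rep(xx, each = nd[1]))
    planar_image(matrix(vals, nd[1], nd[2]), target, img$modality)
  }
  list(resample(a), resample(b))
}

#' Minimum projection of aligned serial sections
#'
#' Voxel-wise minimum across pre-aligned 2D sections: electron-dense (dark)
#' particles survive, merging thin serial TEM sections into one composite
#' comparable to a thicker optical slice.
#'
#' @param sections non-empty list of [planar_image] objects or matrices of
#'   equal shape.
#' @return Same type as the first section.
#' @export
min_projection <- function(sections) {
  if (!length(sections)) stop("empty section list")
  mats <- lapply(sections, as_plane_matrix)
  d0 <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), d0), TRUE)))
    stop("sections must share shape (register them first)")
  out <- Reduce(pmin, mats)
  if (inherits(sections[[1]], "planar_image"))
    planar_image(out, sections[[1]]$pixel_size_nm, sections[[1]]$modality)
  else out
}

#' Maximum intensity z-projection of a volume
#'
#' Voxel-wise maximum along z: bright reflectance spots survive, producing
#' the standard overview image of a z-stack.
#'
#' @param stack a [volume_image] or 3D array.
#' @return A [planar_image] (pixel size from the lateral voxel size) or
#'   matrix.
#' @export
max_projection <- function(stack) {
  a <- as_vol_array(stack)
  out <- apply(a, c(2, 3), max)
  if (inherits(stack, "volume_image"))
    planar_image(out, stack$voxel_size_nm[2:3], stack$modality)
  else out
}
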