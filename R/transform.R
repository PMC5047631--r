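#' 2D planar transform in physical coordinates
#'
#' An affine map `p -> M p + t` on `(x, y)` points in nm, tagged with its
#' model. Rigid transforms are a rotation times a positive scale plus a
#' translation (reflections are disallowed); affine transforms need only be
#' invertible. All transforms map moving coordinates to fixed coordinates.
#'
#' @param model `"rigid"` or `"affine"`.
#' @param matrix 2 x 2 linear part.
#' @param translation length-2 translation in nm `(x, y)`.
#' @return Object of class `planar_transform`.
#' @export
planar_transform <- function(model = c("rigid", "affine"),
                             matrix = diag(2), translation = c(0, 0)) {
  model <- match.arg(model)
  M <- base::matrix(as.numeric(matrix), 2, 2)
  t <- as.numeric(translation)
  if (length(t) != 2L) stop("translation must have length 2")
  dt <- det(M)
  if (model == "rigid") {
    if (dt <= 0) stop("rigid transforms cannot reflect (determinant must be positive)")
    s <- sqrt(dt)
    if (max(abs(crossprod(M / s) - diag(2))) > 1e-6)
      stop("rigid linear part must be a rotation times a positive scale")
  } else {
    if (abs(dt) < 1e-12) stop("affine linear part must be invertible")
  }
  structure(list(model = model, matrix = M, translation = t),
            class = "planar_transform")
}

#' Convenience rigid transform from angle, translation and scale
#'
#' @param angle_deg rotation angle in degrees (counter-clockwise).
#' @param translation length-2 `(x, y)` translation in nm.
#' @param scale positive isotropic scale.
#' @return A rigid [planar_transform].
#' @export
rigid_transform <- function(angle_deg = 0, translation = c(0, 0), scale = 1) {
  th <- angle_deg * pi / 180
  planar_transform("rigid",
                   scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2),
                   translation)
}

#' @export
print.planar_transform <- function(x, ...) {
  cat(sprintf("<planar_transform> %s: angle %.3f deg, scale %.4g, translation (%.4g, %.4g) nm\n",
              x$model, rotation_angle(x), sqrt(abs(det(x$matrix))),
              x$translation[1], x$translation[2]))
  invisible(x)
}

#' Apply a planar transform to points
#'
#' @param transform a [planar_transform].
#' @param points n x 2 matrix of `(x, y)` nm coordinates (a length-2 vector
#'   is treated as one point).
#' @return n x 2 matrix of transformed coordinates.
#' @export
transform_points <- function(transform, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  sweep(points %*% t(transform$matrix), 2, transform$translation, "+")
}

#' Invert a planar transform
#' @param transform a [planar_transform].
#' @return The inverse [planar_transform].
#' @export
invert_transform <- function(transform) {
  Mi <- solve(transform$matrix)
  planar_transform(transform$model, Mi, -as.vector(Mi %*% transform$translation))
}

#' Compose two planar transforms
#'
#' `compose_transforms(a, b)` applies `b` first, then `a`.
#' @param a,b [planar_transform] objects.
#' @return The composite [planar_transform] (affine unless both are rigid).
#' @export
compose_transforms <- function(a, b) {
  model <- if (a$model == "rigid" && b$model == "rigid") "rigid" else "affine"
  planar_transform(model, a$matrix %*% b$matrix,
                   as.vector(a$matrix %*% b$translation) + a$translation)
}

#' Rotation angle of a transform's linear part
#' @param transform a [planar_transform].
#' @return Angle in degrees.
#' @export
rotation_angle <- function(transform) {
  atan2(transform$matrix[2, 1], transform$matrix[1, 1]) * 180 / pi
}

#' Serialise / restore a planar transform as JSON
#'
#' @param transform a [planar_transform].
#' @param path file path; the matrix is stored row-major with nm units.
#' @return `transform_to_json` returns the path invisibly;
#'   `transform_from_json` returns the [planar_transform].
#' @export
transform_to_json <- function(transform, path) {
  jsonlite::write_json(list(
    model = transform$model,
    matrix_row_major = as.vector(t(transform$matrix)),
    translation = transform$translation,
    units = "nm"), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname transform_to_json
#' @export
transform_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  planar_transform(j$model, matrix(j$matrix_row_major, 2, 2, byrow = TRUE),
                   j$translation)
}
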