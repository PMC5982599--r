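#' Similarity transform between the two camera grids
#'
#' The two systems image the same scene through a shared positioning ring,
#' so their pixel grids are related by a similarity transform: a rotation
#' about the grid centre, an isotropic scale, and a small translation.
#' Pixel coordinates are 0-based `(x, y)` with `x` the column index, `y`
#' the row index, origin at the top-left pixel centre. The transform maps
#' source-grid coordinates to destination-grid coordinates as
#'
#'   p_dst = s * Rot(theta) (p_src - c_src) + c_dst + t
#'
#' with `c` the grid centres `((w-1)/2, (h-1)/2)`.
#'
#' @param rotation_deg rotation angle in degrees (positive rotates +x
#'   towards +y, i.e. clockwise on screen with y pointing down).
#' @param scale isotropic scale factor (> 0).
#' @param translation numeric `c(tx, ty)` in destination pixels.
#' @param src_dim,dst_dim `c(width, height)` of the source and destination
#'   grids.
#' @return A `registration_transform` object.
#' @export
registration_transform <- function(rotation_deg = 0, scale = 1,
                                   translation = c(0, 0),
                                   src_dim, dst_dim) {
  stopifnot(is.numeric(scale), length(scale) == 1, is.finite(scale), scale > 0,
            length(translation) == 2,
            length(src_dim) == 2, length(dst_dim) == 2)
  structure(list(rotation_deg = as.numeric(rotation_deg),
                 scale = as.numeric(scale),
                 translation = as.numeric(translation),
                 src_dim = as.integer(src_dim),
                 dst_dim = as.integer(dst_dim)),
            class = "registration_transform")
}

#' @export
print.registration_transform <- function(x, ...) {
  cat(sprintf(
    "<registration_transform: rot %.3g deg, scale %.4g, t (%.3g, %.3g), %dx%d -> %dx%d>\n",
    x$rotation_deg, x$scale, x$translation[1], x$translation[2],
    x$src_dim[1], x$src_dim[2], x$dst_dim[1], x$dst_dim[2]))
  invisible(x)
}

rot_matrix <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

grid_centre <- function(dim) (dim - 1) / 2

#' Apply a registration transform to points
#'
#' @param t a [registration_transform()].
#' @param xy n x 2 matrix (or length-2 vector) of source-grid `(x, y)`
#'   pixel coordinates.
#' @return n x 2 matrix of destination-grid coordinates.
#' @export
apply_transform <- function(t, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  R <- rot_matrix(t$rotation_deg)
  cs <- grid_centre(t$src_dim)
  cd <- grid_centre(t$dst_dim)
  out <- t$scale * t(R %*% (t(xy) - cs))
  sweep(out, 2, cd + t$translation, "+")
}

#' Invert a registration transform
#'
#' @param t a [registration_transform()].
#' @return the inverse `registration_transform` (destination -> source).
#' @export
invert_transform <- function(t) {
  s <- 1 / t$scale
  R <- rot_matrix(-t$rotation_deg)
  tr <- -s * as.vector(R %*% t$translation)
  registration_transform(rotation_deg = -t$rotation_deg, scale = s,
                         translation = tr,
                         src_dim = t$dst_dim, dst_dim = t$src_dim)
}
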