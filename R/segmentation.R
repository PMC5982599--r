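## Lesion segmentation: quadrant-wise Otsu thresholding on the 414 nm
## reflectance image (melanin gives lesions their strongest contrast
## there), plus transfer of the resulting mask to the exNIR grid through
## the inter-camera similarity transform.

#' Otsu threshold of a grayscale image
#'
#' Builds an `n_gray_levels`-bin equal-width histogram over the image's
#' value range and returns the threshold (a bin edge) maximizing the
#' between-class variance of the two populations it separates. Ties are
#' broken towards the lower threshold.
#'
#' @param image numeric matrix (NAs ignored).
#' @param n_gray_levels number of histogram bins (default 256).
#' @return threshold value on the intensity scale of `image`.
#' @export
otsu_threshold <- function(image, n_gray_levels = 256) {
  v <- as.numeric(image)
  v <- v[is.finite(v)]
  if (length(v) == 0 || diff(range(v)) == 0)
    stop("degenerate: image has fewer than 2 distinct values")
  n <- as.integer(n_gray_levels)
  lo <- min(v); hi <- max(v)
  wdt <- (hi - lo) / n
  idx <- pmin(floor((v - lo) / wdt), n - 1) + 1
  p <- tabulate(idx, n) / length(v)
  i <- seq_len(n) - 1
  omega <- cumsum(p)                       # class-0 weight up to bin t
  mu <- cumsum(p * i)
  mu_t <- mu[n]
  ## candidate thresholds after bins 1 .. n-1
  w0 <- omega[-n]; m0 <- mu[-n]
  sigma_b <- (mu_t * w0 - m0)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  t_bin <- which.max(sigma_b)              # first maximum = lower threshold
  lo + t_bin * wdt
}

## 8-connected components via igraph; returns integer label matrix
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, h, w)
  if (length(idx) == 0) return(lab)
  pos <- matrix(0L, h, w)
  pos[idx] <- seq_along(idx)
  r <- ((idx - 1) %% h) + 1
  cl <- ((idx - 1) %/% h) + 1
  edges <- integer(0)
  for (d in list(c(1, 0), c(0, 1), c(1, 1), c(-1, 1))) {
    r2 <- r + d[1]; c2 <- cl + d[2]
    ok <- r2 >= 1 & r2 <= h & c2 >= 1 & c2 <= w
    nb <- pos[cbind(r2[ok], c2[ok])]
    keep <- nb > 0
    edges <- c(edges, rbind(pos[idx[ok]][keep], nb[keep]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[idx] <- comp
  lab
}

#' Keep the largest 8-connected foreground component
#'
#' @param mask logical matrix.
#' @return logical matrix retaining only the largest component (all-FALSE
#'   input is returned unchanged).
#' @export
largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

#' Fill holes in a binary mask
#'
#' @param mask logical matrix.
#' @return logical matrix with enclosed background regions filled.
#' @export
fill_holes <- function(mask) {
  EBImage::fillHull(mask * 1L) > 0
}

#' Dilate a binary mask with a disc structuring element
#'
#' @param mask logical matrix.
#' @param radius disc radius in pixels.
#' @return dilated logical matrix.
#' @export
dilate_mask <- function(mask, radius = 5) {
  if (radius < 1) return(mask)
  brush <- EBImage::makeBrush(2 * floor(radius) + 1, shape = "disc")
  EBImage::dilate(mask * 1L, brush) > 0
}

#' Healthy-skin region for minus-skin variants
#'
#' The skin region is the complement of the lesion mask dilated by
#' `margin_px` pixels, which keeps a guard band around the lesion boundary
#' out of the skin average.
#'
#' @param lesion_mask logical lesion mask.
#' @param margin_px dilation radius (default 5 px).
#' @return logical skin mask, disjoint from the lesion mask.
#' @export
skin_region <- function(lesion_mask, margin_px = 5) {
  !dilate_mask(lesion_mask, margin_px)
}

#' Quadrant-wise Otsu segmentation of the 414 nm image
#'
#' Splits the image into four equal quadrants (odd dimensions give the
#' extra row/column to the bottom/right quadrants), applies
#' [otsu_threshold()] independently per quadrant, and marks pixels
#' strictly below their quadrant's threshold as lesion (lesions are darker
#' than skin at 414 nm). Quadrants with constant values contribute
#' all-background. The reassembled mask is post-processed by keeping the
#' largest 8-connected component and filling holes (both can be turned
#' off).
#'
#' @param image numeric matrix, usually the 414 nm reflectance image.
#' @param n_gray_levels histogram bins per quadrant Otsu.
#' @param keep_largest,fill logical post-processing toggles.
#' @return A `lesion_mask` object: logical matrix with attributes
#'   `source = "otsu_quadrant"` and `thresholds` (per-quadrant, NA where
#'   degenerate).
#' @export
segment_quadrants <- function(image, n_gray_levels = 256,
                              keep_largest = TRUE, fill = TRUE) {
  h <- nrow(image); w <- ncol(image)
  if (h < 2 || w < 2) stop("image must be at least 2x2")
  rsplit <- list(1:floor(h / 2), (floor(h / 2) + 1):h)
  csplit <- list(1:floor(w / 2), (floor(w / 2) + 1):w)
  mask <- matrix(FALSE, h, w)
  thresholds <- matrix(NA_real_, 2, 2,
                       dimnames = list(c("top", "bottom"), c("left", "right")))
  for (qi in 1:2) for (qj in 1:2) {
    sub <- image[rsplit[[qi]], csplit[[qj]], drop = FALSE]
    vals <- sub[is.finite(sub)]
    if (length(vals) == 0 || diff(range(vals)) == 0) next  # all-background
    thr <- otsu_threshold(sub, n_gray_levels)
    thresholds[qi, qj] <- thr
    mask[rsplit[[qi]], csplit[[qj]]] <- is.finite(sub) & sub < thr
  }
  if (keep_largest) mask <- largest_component(mask)
  if (fill) mask <- fill_holes(mask)
  structure(mask, source = "otsu_quadrant", thresholds = thresholds,
            class = c("lesion_mask", class(mask)))
}

#' Transfer a lesion mask to the other camera grid
#'
#' Resamples a binary mask through a [registration_transform()] by
#' nearest-neighbour lookup: each destination pixel centre is mapped back
#' through the inverse transform and takes the value of the nearest
#' source pixel (out-of-field pixels are background).
#'
#' @param mask logical mask on the transform's source grid.
#' @param t a [registration_transform()] whose `src_dim` matches `mask`.
#' @return logical mask on the destination grid with attribute
#'   `source = "transferred"`.
#' @export
transfer_mask <- function(mask, t) {
  stopifnot(nrow(mask) == t$src_dim[2], ncol(mask) == t$src_dim[1])
  w2 <- t$dst_dim[1]; h2 <- t$dst_dim[2]
  inv <- invert_transform(t)
  xy <- cbind(rep(0:(w2 - 1), each = h2), rep(0:(h2 - 1), times = w2))
  src <- apply_transform(inv, xy)
  xs <- round(src[, 1]); ys <- round(src[, 2])
  ok <- xs >= 0 & xs < t$src_dim[1] & ys >= 0 & ys < t$src_dim[2]
  out <- rep(FALSE, w2 * h2)
  out[ok] <- mask[cbind(ys[ok] + 1, xs[ok] + 1)]
  out <- matrix(out, h2, w2)
  if (!any(out)) stop("out of field: transformed mask is empty on the target grid")
  structure(out, source = "transferred",
            class = c("lesion_mask", class(out)))
}

#' Dice overlap coefficient of two binary masks
#'
#' @param a,b logical matrices of equal dimension.
#' @return `2|a&b| / (|a| + |b|)`.
#' @export
dice <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}
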