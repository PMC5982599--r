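## Reflectance calibration: raw digital levels -> reflectance via the
## gray-reference / dark-frame ratio, plus the three derived image
## variants (minus-skin and the two absorbance forms).

#' Select the exposure step closest to half the dynamic range
#'
#' The acquisition targets a mean digital level of about half of full
#' scale; given a per-exposure image stack this returns the index whose
#' mean DL is closest to `(2^bit_depth - 1) / 2`. Ties are broken towards
#' the smaller exposure time (stacks are ordered by increasing exposure).
#'
#' @param reference_stack list of images (matrices) ordered by increasing
#'   exposure time.
#' @param bit_depth sensor bit depth.
#' @return integer index into `reference_stack`.
#' @export
select_exposure <- function(reference_stack, bit_depth) {
  stopifnot(length(reference_stack) >= 1)
  full <- 2^bit_depth - 1
  means <- vapply(reference_stack, function(m) mean(as.numeric(m)), numeric(1))
  if (all(means >= 0.98 * full))
    stop("saturation: every exposure has mean DL >= 98% of full scale")
  which.min(abs(means - full / 2))
}

#' Reflectance stack container
#'
#' @param system_id `"VISNIR"` or `"EXNIR"`.
#' @param images named list (by wavelength) of numeric matrices.
#' @param variant one of `"R"`, `"R_minus_skin"`, `"A"`, `"A_minus_skin"`.
#' @param valid logical validity mask shared by all bands (`NULL` = all).
#' @param k gray-reference reflectance used in the calibration.
#' @param mask optional lesion mask attached to the stack.
#' @return A `reflectance_stack` object.
#' @export
reflectance_stack <- function(system_id, images, variant = "R",
                              valid = NULL, k = NA_real_, mask = NULL) {
  variant <- match.arg(variant, VARIANTS)
  structure(list(system_id = system_id, images = images, variant = variant,
                 valid = valid, k = k, mask = mask),
            class = "reflectance_stack")
}

#' @export
print.reflectance_stack <- function(x, ...) {
  cat(sprintf("<reflectance_stack %s [%s]: %d bands, %dx%d px>\n",
              x$system_id, x$variant, length(x$images),
              ncol(x$images[[1]]), nrow(x$images[[1]])))
  invisible(x)
}

#' Compute per-band reflectance from a raw capture
#'
#' For every band the reflectance at pixel (i, j) is
#'
#'   R(i,j) = k * (I(i,j) - I_D(i,j)) / (I_N(i,j) - I_D(i,j)),
#'
#' where I is the raw digital-level image, I_N and I_D the gray-reference
#' and dark-current images acquired at the same exposure time, and k the
#' calibrated reflectance of the gray reference. Pixels whose reference
#' signal `I_N - I_D` does not exceed `eps` are flagged invalid (NA).
#'
#' @param raw a `raw_capture` (one image per band plus exposure metadata).
#' @param cal a `calibration_set` (ten-exposure reference and dark stacks).
#' @param eps minimum usable reference signal in DL.
#' @return A [reflectance_stack()] of variant `"R"` with a validity mask.
#' @export
compute_reflectance <- function(raw, cal, eps = 1) {
  stopifnot(inherits(raw, "raw_capture"), inherits(cal, "calibration_set"))
  out <- list(); valid <- NULL
  for (key in names(raw$images)) {
    texp <- raw$exposure_time[[key]]
    j <- match(TRUE, abs(cal$exposure_times - texp) <
                 1e-9 * max(cal$exposure_times))
    if (is.na(j))
      stop("no calibration images at exposure time ", texp, " for band ", key)
    i_n <- cal$reference[[key]][[j]]
    i_d <- cal$dark[[key]][[j]]
    denom <- as.numeric(i_n) - as.numeric(i_d)
    ## reference pixels at full scale are saturated and unusable
    ok <- matrix(denom > eps & as.numeric(i_n) < 2^raw$bit_depth - 1,
                 nrow = nrow(i_n))
    r <- matrix(cal$k * (as.numeric(raw$images[[key]]) - as.numeric(i_d)) / denom,
                nrow = nrow(i_n))
    r[!ok] <- NA_real_
    out[[key]] <- r
    valid <- if (is.null(valid)) ok else valid & ok
  }
  reflectance_stack(raw$system_id, out, variant = "R", valid = valid, k = cal$k)
}

#' Subtract the mean healthy-skin value from a lesion image
#'
#' Per band, subtracts the mean of the image over the healthy-skin region
#' and restricts the result to the lesion (pixels outside become NA).
#' Applied to a reflectance stack this yields the `R_minus_skin` variant;
#' applied to an absorbance stack, `A_minus_skin`.
#'
#' @param stack a [reflectance_stack()] of variant `"R"` or `"A"`.
#' @param lesion_mask,skin_mask disjoint non-empty logical masks on the
#'   stack's pixel grid.
#' @return A [reflectance_stack()] of the corresponding minus-skin variant.
#' @export
subtract_skin <- function(stack, lesion_mask, skin_mask) {
  stopifnot(inherits(stack, "reflectance_stack"))
  if (!stack$variant %in% c("R", "A"))
    stop("minus-skin variants are derived from variant R or A stacks")
  if (!any(skin_mask)) stop("empty skin mask")
  if (!any(lesion_mask)) stop("empty lesion mask")
  if (any(skin_mask & lesion_mask)) stop("skin and lesion masks overlap")
  out <- lapply(stack$images, function(img) {
    m <- img - mean(img[skin_mask], na.rm = TRUE)
    m[!lesion_mask] <- NA_real_
    m
  })
  reflectance_stack(stack$system_id, out,
                    variant = paste0(stack$variant, "_minus_skin"),
                    valid = stack$valid, k = stack$k, mask = lesion_mask)
}

#' Convert reflectance to absorbance
#'
#' Absorbance is `A = -log10(max(R, eps))`; the floor `eps` keeps the
#' logarithm defined for non-positive inputs (which can occur in the
#' minus-skin variant). The number of clamped pixels is recorded in the
#' `"n_clamped"` attribute.
#'
#' @param stack a [reflectance_stack()] of variant `"R"` or
#'   `"R_minus_skin"`.
#' @param eps clamp floor (default 1e-4).
#' @return A [reflectance_stack()] of variant `"A"` or `"A_minus_skin"`.
#' @export
to_absorbance <- function(stack, eps = 1e-4) {
  stopifnot(inherits(stack, "reflectance_stack"))
  if (!stack$variant %in% c("R", "R_minus_skin"))
    stop("absorbance is derived from variant R or R_minus_skin stacks")
  n_clamped <- 0L
  out <- lapply(stack$images, function(img) {
    n_clamped <<- n_clamped + sum(img < eps, na.rm = TRUE)
    -log10(pmax(img, eps))
  })
  res <- reflectance_stack(stack$system_id, out,
                           variant = sub("^R", "A", stack$variant),
                           valid = stack$valid, k = stack$k, mask = stack$mask)
  attr(res, "n_clamped") <- n_clamped
  res
}

#' Build all four analysis variants of a reflectance stack
#'
#' Produces `R`, `R_minus_skin`, `A` and `A_minus_skin`. By default
#' (`absorbance_order = "log_first"`) the minus-skin absorbance is
#' computed as `A - mean(A over skin)`, i.e. the skin subtraction is
#' applied after the logarithm, which keeps the operation defined when the
#' reflectance difference is negative. `"subtract_first"` instead takes
#' the (clamped) logarithm of the reflectance difference.
#'
#' @param stack a variant-`R` [reflectance_stack()].
#' @param lesion_mask,skin_mask see [subtract_skin()].
#' @param absorbance_order `"log_first"` (default) or `"subtract_first"`.
#' @param eps clamp floor for [to_absorbance()].
#' @return named list of four [reflectance_stack()]s.
#' @export
make_variants <- function(stack, lesion_mask, skin_mask,
                          absorbance_order = c("log_first", "subtract_first"),
                          eps = 1e-4) {
  absorbance_order <- match.arg(absorbance_order)
  stopifnot(identical(stack$variant, "R"))
  r_ms <- subtract_skin(stack, lesion_mask, skin_mask)
  a <- to_absorbance(stack, eps)
  a_ms <- if (absorbance_order == "log_first")
    subtract_skin(a, lesion_mask, skin_mask)
  else
    to_absorbance(r_ms, eps)
  list(R = stack, R_minus_skin = r_ms, A = a, A_minus_skin = a_ms)
}
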