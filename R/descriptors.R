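## First-order histogram descriptors of the in-lesion intensity
## distribution: mean / max / min / std on the raw pixel values, and
## energy / entropy / third central moment on the N-bin histogram.
##
## The energy, entropy and third-moment forms follow the source
## formulation in which the histogram frequencies enter squared:
##
##   En = sum_i P(i)^2
##   Ep = -sum_i P(i)^2 log2[P(i)^2]          ("as_printed")
##   mu3 = sum_i (i - mu)^3 P(i)^2            ("as_printed")
##
## The squared frequencies in Ep and mu3 are non-standard; the textbook
## forms (-sum P log2 P and the sigma^3-normalized index skewness) are
## available as mode "standard" / "normalized". Only the standard entropy
## attains log2(N) on a uniform histogram, and only the normalized third
## moment is confined near [-1, 1].

#' Equal-width histogram of in-mask pixel values
#'
#' Bins span the value range `[min, max]` of the input; the maximum falls
#' in the last bin. A constant input occupies a single bin.
#'
#' @param values numeric vector (NAs dropped).
#' @param N number of bins (default 256).
#' @return A `fo_histogram` object: list with `N`, `edges` (length N+1)
#'   and `P` (relative frequencies summing to 1).
#' @export
build_histogram <- function(values, N = 256) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  if (length(v) == 0) stop("empty mask: no values to histogram")
  N <- as.integer(N)
  if (N < 2) stop("N must be >= 2")
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    p <- c(1, rep(0, N - 1))
    edges <- seq(lo - 0.5, lo + 0.5, length.out = N + 1)
  } else {
    wdt <- (hi - lo) / N
    idx <- pmin(floor((v - lo) / wdt), N - 1) + 1
    p <- tabulate(idx, N) / length(v)
    edges <- seq(lo, hi, length.out = N + 1)
  }
  structure(list(N = N, edges = edges, P = p), class = "fo_histogram")
}

#' Histogram energy (uniformity)
#'
#' `sum(P^2)`: 1 for a constant image, `1/N` for a uniform N-bin
#' histogram; higher for more uniform images.
#'
#' @param h a [build_histogram()] result.
#' @return energy in (0, 1].
#' @export
energy <- function(h) {
  stopifnot(inherits(h, "fo_histogram"))
  sum(h$P^2)
}

#' Histogram entropy (randomness)
#'
#' In the default `"as_printed"` mode, `-sum(P^2 * log2(P^2))` over
#' occupied bins; in `"standard"` mode the Shannon entropy
#' `-sum(P * log2(P))`, which is 0 for a constant image and `log2(N)` for
#' a uniform histogram.
#'
#' @param h a [build_histogram()] result.
#' @param mode `"as_printed"` (default) or `"standard"`.
#' @return entropy in bits.
#' @export
entropy <- function(h, mode = c("as_printed", "standard")) {
  stopifnot(inherits(h, "fo_histogram"))
  mode <- match.arg(mode)
  p <- h$P[h$P > 0]
  ## `+ 0` normalizes the signed zero of -sum(0)
  if (mode == "as_printed") -sum(p^2 * log2(p^2)) + 0 else -sum(p * log2(p)) + 0
}

#' Third central moment of the histogram (skewness)
#'
#' Computed on bin indices `i = 0 .. N-1` about the index-weighted mean
#' `mu = sum(i * P(i))`. The default `"as_printed"` mode weights by
#' `P(i)^2`; `"normalized"` divides the as-printed value by `sigma^3`
#' where `sigma^2 = sum((i - mu)^2 * P(i))` (0 when `sigma = 0`).
#'
#' @param h a [build_histogram()] result.
#' @param mode `"as_printed"` (default) or `"normalized"`.
#' @return third central moment; 0 for symmetric histograms.
#' @export
third_central_moment <- function(h, mode = c("as_printed", "normalized")) {
  stopifnot(inherits(h, "fo_histogram"))
  mode <- match.arg(mode)
  i <- seq_len(h$N) - 1
  mu <- sum(i * h$P)
  m3 <- sum((i - mu)^3 * h$P^2)
  if (mode == "as_printed") return(m3)
  sigma <- sqrt(sum((i - mu)^2 * h$P))
  if (sigma == 0) 0 else m3 / sigma^3
}

#' Mean, maximum, minimum and population standard deviation
#'
#' Computed on the raw in-mask pixel values (not on bin centres); the
#' standard deviation uses the population convention (divide by n).
#'
#' @param values numeric vector (NAs dropped).
#' @return named numeric vector `(mean, max, min, std)`.
#' @export
basic_stats <- function(values) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  if (length(v) == 0) stop("empty mask: no values")
  m <- mean(v)
  c(mean = m, max = max(v), min = min(v),
    std = sqrt(mean((v - m)^2)))
}

#' All seven first-order statistics of one image under one mask
#'
#' @param img numeric matrix.
#' @param mask logical matrix (same dimension); NAs in `img` are dropped.
#' @param N histogram bins.
#' @param entropy_mode,mu3_mode see [entropy()] and
#'   [third_central_moment()].
#' @return named numeric vector over `mean, max, min, std, energy,
#'   entropy, mu3`.
#' @export
first_order_stats <- function(img, mask, N = 256,
                              entropy_mode = "as_printed",
                              mu3_mode = "as_printed") {
  v <- img[mask]
  v <- v[is.finite(v)]
  if (length(v) == 0) stop("empty mask: no in-mask values")
  h <- build_histogram(v, N)
  c(basic_stats(v),
    energy = energy(h),
    entropy = entropy(h, entropy_mode),
    mu3 = third_central_moment(h, mu3_mode))
}

#' Descriptor vector of one lesion
#'
#' @param variants_by_system named list (by system) of the four-variant
#'   stack lists produced by [make_variants()].
#' @param masks_by_system named list (by system) of logical lesion masks.
#' @param N,entropy_mode,mu3_mode see [first_order_stats()].
#' @return named numeric vector keyed by descriptor id (see
#'   [descriptor_ids()]), ordered system, band, variant, statistic.
#' @export
lesion_descriptors <- function(variants_by_system, masks_by_system,
                               N = 256, entropy_mode = "as_printed",
                               mu3_mode = "as_printed") {
  out <- numeric(0)
  for (sid in names(variants_by_system)) {
    variants <- variants_by_system[[sid]]
    if (!all(VARIANTS %in% names(variants)))
      stop("lesion lacks a variant stack for system ", sid)
    mask <- masks_by_system[[sid]]
    bands <- names(variants$R$images)
    for (band in bands) {
      for (vn in VARIANTS) {
        st <- first_order_stats(variants[[vn]]$images[[band]], mask, N,
                                entropy_mode, mu3_mode)
        names(st) <- paste(sid, band, vn, STATISTICS, sep = ".")
        out <- c(out, st)
      }
    }
  }
  out
}

#' Assemble the per-lesion descriptor table
#'
#' One row per lesion, one column per descriptor id (392 for the default
#' two-system setup: 8 bands x 4 variants x 7 statistics VIS-NIR plus
#' 6 x 4 x 7 exNIR), preceded by `id` and `class` columns. Lesions whose
#' descriptor computation fails are excluded with a message.
#'
#' @param lesions named list; each element is a list with `class`
#'   (`"nevus"`/`"melanoma"`), `variants` and `masks` as accepted by
#'   [lesion_descriptors()].
#' @param N,entropy_mode,mu3_mode see [first_order_stats()].
#' @return data.frame with columns `id`, `class`, then the descriptors.
#' @export
compute_descriptor_table <- function(lesions, N = 256,
                                     entropy_mode = "as_printed",
                                     mu3_mode = "as_printed") {
  rows <- list()
  for (id in names(lesions)) {
    les <- lesions[[id]]
    row <- tryCatch(
      lesion_descriptors(les$variants, les$masks, N, entropy_mode, mu3_mode),
      error = function(e) {
        message("excluding lesion ", id, ": ", conditionMessage(e))
        NULL
      })
    if (!is.null(row)) rows[[id]] <- row
  }
  if (length(rows) == 0) stop("no lesions could be processed")
  cols <- names(rows[[1]])
  mat <- do.call(rbind, lapply(rows, function(r) r[cols]))
  df <- data.frame(id = names(rows),
                   class = vapply(lesions[names(rows)], `[[`, "", "class"),
                   mat, check.names = FALSE, row.names = NULL)
  df
}
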