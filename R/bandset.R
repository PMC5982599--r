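#' Spectral band set of one imaging system
#'
#' Describes one multispectral camera system: its LED peak wavelengths,
#' nominal bandwidths, sensor bit depth and pixel grid. Two systems are
#' supported: a 12-bit silicon CCD covering the visible/near-infrared
#' (`"VISNIR"`) and a 16-bit InGaAs camera covering the extended
#' near-infrared (`"EXNIR"`).
#'
#' @param system_id `"VISNIR"` or `"EXNIR"`.
#' @param wavelengths_nm strictly increasing numeric vector of band peak
#'   wavelengths (nm).
#' @param fwhm_nm per-band full width at half maximum (nm); recycled.
#' @param bit_depth sensor bit depth, 12 or 16. Digital levels run from 0
#'   to `2^bit_depth - 1`.
#' @param resolution integer `c(width, height)` in pixels.
#' @return A `band_set` object (list).
#' @seealso [visnir_band_set()], [exnir_band_set()], [default_band_sets()]
#' @export
band_set <- function(system_id, wavelengths_nm, fwhm_nm, bit_depth, resolution) {
  system_id <- match.arg(system_id, c("VISNIR", "EXNIR"))
  stopifnot(length(wavelengths_nm) >= 1, all(diff(wavelengths_nm) > 0))
  if (!bit_depth %in% c(12L, 16L))
    stop("bit_depth must be 12 or 16")
  stopifnot(length(resolution) == 2, all(resolution >= 2))
  structure(list(
    system_id = system_id,
    wavelengths_nm = as.numeric(wavelengths_nm),
    fwhm_nm = rep_len(as.numeric(fwhm_nm), length(wavelengths_nm)),
    bit_depth = as.integer(bit_depth),
    resolution = as.integer(round(resolution))
  ), class = "band_set")
}

#' @rdname band_set
#' @param resolution_scale scalar in (0, 1]; scales the native pixel grid
#'   (1280x960 VIS-NIR, 320x256 exNIR) for reduced-size simulation runs.
#' @export
visnir_band_set <- function(resolution_scale = 1) {
  band_set("VISNIR",
           wavelengths_nm = c(414, 447, 477, 524, 671, 735, 890, 995),
           fwhm_nm = 25,
           bit_depth = 12L,
           resolution = pmax(8, round(c(1280, 960) * resolution_scale)))
}

#' @rdname band_set
#' @export
exnir_band_set <- function(resolution_scale = 1) {
  band_set("EXNIR",
           wavelengths_nm = c(995, 1081, 1214, 1340, 1486, 1613),
           fwhm_nm = 80,
           bit_depth = 16L,
           resolution = pmax(8, round(c(320, 256) * resolution_scale)))
}

#' @rdname band_set
#' @export
default_band_sets <- function(resolution_scale = 1) {
  list(VISNIR = visnir_band_set(resolution_scale),
       EXNIR = exnir_band_set(resolution_scale))
}

#' @export
print.band_set <- function(x, ...) {
  cat(sprintf("<band_set %s: %d bands (%g-%g nm), %d-bit, %dx%d px>\n",
              x$system_id, length(x$wavelengths_nm),
              min(x$wavelengths_nm), max(x$wavelengths_nm),
              x$bit_depth, x$resolution[1], x$resolution[2]))
  invisible(x)
}

## canonical orderings used for the descriptor-table columns
VARIANTS <- c("R", "R_minus_skin", "A", "A_minus_skin")
STATISTICS <- c("mean", "max", "min", "std", "energy", "entropy", "mu3")

#' Enumerate descriptor identifiers
#'
#' One descriptor is a (system, band, image variant, statistic) tuple,
#' written `"SYSTEM.band.variant.statistic"`, e.g.
#' `"VISNIR.414.R_minus_skin.min"`. With both default systems the
#' enumeration has 8*4*7 + 6*4*7 = 392 entries, ordered by system, band,
#' variant, statistic.
#'
#' @param band_sets named list of [band_set()] objects.
#' @return character vector of descriptor ids.
#' @examples
#' length(descriptor_ids())  # 392
#' @export
descriptor_ids <- function(band_sets = default_band_sets()) {
  unlist(lapply(band_sets, function(bs) {
    as.vector(vapply(bs$wavelengths_nm, function(w) {
      as.vector(vapply(VARIANTS, function(v)
        paste(bs$system_id, w, v, STATISTICS, sep = "."),
        character(length(STATISTICS))))
    }, character(length(VARIANTS) * length(STATISTICS))))
  }), use.names = FALSE)
}

#' Parse a descriptor identifier
#'
#' @param id descriptor id string, e.g. `"EXNIR.1214.A_minus_skin.std"`.
#' @return list with `system_id`, `band_nm`, `variant`, `statistic`.
#' @export
parse_descriptor_id <- function(id) {
  parts <- strsplit(id, ".", fixed = TRUE)[[1]]
  if (length(parts) != 4)
    stop("malformed descriptor id: ", id)
  if (!parts[3] %in% VARIANTS || !parts[4] %in% STATISTICS)
    stop("malformed descriptor id: ", id)
  list(system_id = parts[1], band_nm = as.numeric(parts[2]),
       variant = parts[3], statistic = parts[4])
}
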