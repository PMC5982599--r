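## File formats: 16-bit grayscale TIFF for digital-level images (one file
## per band and exposure), 32-bit float TIFF for reflectance variants,
## 8-bit PNG (0/255) for masks, JSON for metadata, CSV for tables.

write_dl_tiff <- function(img, path, bit_depth) {
  ## DLs are stored as 16-bit integers regardless of sensor bit depth
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

read_dl_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow = nrow(m))
}

#' Write / read a lesion mask as 8-bit PNG
#'
#' @param mask logical matrix.
#' @param path PNG path.
#' @return `read_mask_png()` returns a logical matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > 0.5
}

#' Write a reflectance stack as 32-bit float TIFFs
#'
#' One file `reflectance_<variant>_<band>.tif` per band; NAs are stored
#' as a sentinel (-999) and restored on read.
#'
#' @param stack a [reflectance_stack()].
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_reflectance_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (band in names(stack$images)) {
    img <- stack$images[[band]]
    img[is.na(img)] <- -999
    p <- file.path(dir, sprintf("reflectance_%s_%s.tif", stack$variant, band))
    tiff::writeTIFF(img, p, bits.per.sample = 32L)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a phantom to disk
#'
#' Layout: `<dir>/<system>/raw_<band>.tif` (selected-exposure capture),
#' `<dir>/<system>/ref_<band>_<j>.tif` and `dark_<band>_<j>.tif` for the
#' ten-exposure calibration stacks, `<dir>/<system>/truth_mask.png`, and
#' `<dir>/truth.json` (class, transform, exposure metadata, k).
#'
#' @param phantom a [generate_phantom()] result.
#' @param dir output directory (created).
#' @return invisibly, `dir`.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(truth_class = phantom$truth_class,
               k = phantom$config$k_reference,
               systems = list())
  for (sid in names(phantom$captures)) {
    sdir <- file.path(dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    cap <- phantom$captures[[sid]]
    cal <- phantom$calibrations[[sid]]
    for (band in names(cap$images)) {
      write_dl_tiff(cap$images[[band]],
                    file.path(sdir, sprintf("raw_%s.tif", band)))
      for (j in seq_along(cal$exposure_times)) {
        write_dl_tiff(cal$reference[[band]][[j]],
                      file.path(sdir, sprintf("ref_%s_%02d.tif", band, j)))
        write_dl_tiff(cal$dark[[band]][[j]],
                      file.path(sdir, sprintf("dark_%s_%02d.tif", band, j)))
      }
    }
    write_mask_png(phantom$truth_mask[[sid]],
                   file.path(sdir, "truth_mask.png"))
    meta$systems[[sid]] <- list(
      wavelengths_nm = cap$band_set$wavelengths_nm,
      bit_depth = cap$band_set$bit_depth,
      resolution = cap$band_set$resolution,
      exposure_times = cal$exposure_times,
      exposure_index = as.list(cap$exposure_index))
  }
  if (!is.null(phantom$truth_transform)) {
    t <- phantom$truth_transform
    meta$truth_transform <- list(rotation_deg = t$rotation_deg,
                                 scale = t$scale,
                                 translation = t$translation,
                                 src_dim = t$src_dim, dst_dim = t$dst_dim)
  }
  jsonlite::write_json(meta, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a phantom written by [write_phantom()]
#'
#' @param dir phantom directory.
#' @return a `phantom`-like list with `captures`, `calibrations`,
#'   `truth_mask`, `truth_class` and `truth_transform` (no
#'   `truth_reflectance`; that is not persisted).
#' @export
read_phantom <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
  captures <- list(); calibrations <- list(); truth_mask <- list()
  for (sid in names(meta$systems)) {
    ms <- meta$systems[[sid]]
    sdir <- file.path(dir, sid)
    bands <- as.character(ms$wavelengths_nm)
    raw <- list(); ref <- list(); dark <- list()
    for (band in bands) {
      raw[[band]] <- read_dl_tiff(file.path(sdir, sprintf("raw_%s.tif", band)))
      ref[[band]] <- lapply(seq_along(ms$exposure_times), function(j)
        read_dl_tiff(file.path(sdir, sprintf("ref_%s_%02d.tif", band, j))))
      dark[[band]] <- lapply(seq_along(ms$exposure_times), function(j)
        read_dl_tiff(file.path(sdir, sprintf("dark_%s_%02d.tif", band, j))))
    }
    bs <- band_set(sid, ms$wavelengths_nm, fwhm_nm = NA,
                   bit_depth = ms$bit_depth, resolution = ms$resolution)
    eidx <- unlist(ms$exposure_index[bands])
    captures[[sid]] <- structure(list(
      system_id = sid, band_set = bs, images = raw,
      exposure_index = eidx,
      exposure_time = stats::setNames(ms$exposure_times[eidx], bands),
      bit_depth = ms$bit_depth), class = "raw_capture")
    calibrations[[sid]] <- structure(list(
      system_id = sid, band_set = bs, reference = ref, dark = dark,
      exposure_times = ms$exposure_times, k = meta$k),
      class = "calibration_set")
    truth_mask[[sid]] <- read_mask_png(file.path(sdir, "truth_mask.png"))
  }
  truth_transform <- NULL
  if (!is.null(meta$truth_transform)) {
    tt <- meta$truth_transform
    truth_transform <- registration_transform(tt$rotation_deg, tt$scale,
                                              tt$translation,
                                              tt$src_dim, tt$dst_dim)
  }
  structure(list(captures = captures, calibrations = calibrations,
                 truth_mask = truth_mask, truth_class = meta$truth_class,
                 truth_transform = truth_transform),
            class = "phantom")
}

#' Write / read a descriptor table as CSV
#'
#' @param table a [compute_descriptor_table()] result.
#' @param path CSV path.
#' @return `read_descriptor_table()` returns the data.frame.
#' @export
write_descriptor_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_descriptor_table
#' @export
read_descriptor_table <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
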