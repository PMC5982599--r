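## Synthetic dual-modality lesion phantoms.
##
## The forward model is the exact inverse of the reflectance equation used
## by the calibration module: a pixel with true reflectance R is recorded
## at digital level  DL = clip(round(I_D + (R/k) * (I_N - I_D) + noise)),
## with the gray-reference signal I_N - I_D proportional to exposure time.

#' Wavelengths covered by the two default systems
#' @return numeric vector of the 13 distinct LED peak wavelengths (nm).
#' @export
default_wavelengths <- function() {
  c(414, 447, 477, 524, 671, 735, 890, 995, 1081, 1214, 1340, 1486, 1613)
}

#' Default mean reflectance spectra of healthy skin and lesions
#'
#' Spectra are indexed by wavelength (names, nm) and chosen to reproduce
#' the qualitative class contrast seen in clinical cohorts: nevi reflect
#' more than melanomas at every band, with the largest gap in the
#' 995-1350 nm water-transparency window; both lesion classes are darker
#' than the surrounding skin in the visible (melanin absorption at short
#' wavelengths), and all tissues darken sharply beyond 1400 nm (water).
#'
#' @return named numeric vector of reflectances in (0, 1].
#' @export
default_skin_profile <- function() {
  stats::setNames(
    c(0.18, 0.20, 0.23, 0.27, 0.38, 0.44, 0.52, 0.50, 0.48, 0.45, 0.38, 0.18, 0.22),
    default_wavelengths())
}

#' @rdname default_skin_profile
#' @param lesion_class `"nevus"` or `"melanoma"`.
#' @export
default_lesion_profile <- function(lesion_class = c("nevus", "melanoma")) {
  lesion_class <- match.arg(lesion_class)
  v <- switch(lesion_class,
    nevus    = c(0.070, 0.080, 0.090, 0.110, 0.200, 0.280, 0.380, 0.440,
                 0.430, 0.400, 0.330, 0.150, 0.180),
    melanoma = c(0.050, 0.055, 0.060, 0.075, 0.140, 0.200, 0.280, 0.300,
                 0.290, 0.260, 0.220, 0.110, 0.140))
  stats::setNames(v, default_wavelengths())
}

#' Default within-lesion texture parameters
#'
#' Lesion interiors carry a smoothed random field on top of the class mean
#' spectrum. Nevi get a Gaussian-marginal field with small amplitude
#' (near-homogeneous lesions); melanomas get the same spatially correlated
#' field rank-mapped to a uniform marginal with larger amplitude, which
#' broadens the in-lesion intensity histogram (lower energy, higher
#' entropy) as observed for malignant lesions.
#'
#' @param lesion_class `"nevus"` or `"melanoma"`.
#' @return list with `sigma` (relative reflectance SD of the field),
#'   `blob_scale` (correlation length as a fraction of VIS-NIR image
#'   height) and `marginal` (`"gaussian"` or `"uniform"`).
#' @export
default_texture <- function(lesion_class = c("nevus", "melanoma")) {
  lesion_class <- match.arg(lesion_class)
  switch(lesion_class,
    nevus    = list(sigma = 0.04, blob_scale = 0.03, marginal = "gaussian"),
    melanoma = list(sigma = 0.10, blob_scale = 0.03, marginal = "uniform"))
}

#' Phantom configuration
#'
#' Bundles everything [generate_phantom()] needs: lesion class and shape,
#' reflectance spectra, texture model, inter-camera misregistration,
#' sensor noise, the gray-reference reflectance `k`, and the ten-step
#' exposure ladder per system.
#'
#' @param lesion_class `"nevus"` or `"melanoma"`.
#' @param lesion_shape list with `center` (fractions of VIS-NIR width and
#'   height), `axes` (ellipse semi-axes as fractions of VIS-NIR image
#'   height) and `rotation_deg`.
#' @param skin_profile,lesion_profile named reflectance spectra in (0, 1]
#'   covering every configured wavelength (names = nm).
#' @param texture see [default_texture()].
#' @param misregistration list with `rotation_deg`, `scale` (`NULL` means
#'   the resolution ratio of the two grids) and `translation_px` on the
#'   exNIR grid, defining the VIS-NIR -> exNIR similarity transform.
#' @param noise per-system list of `read_sd` (Gaussian read noise SD, DL)
#'   and `dark_level` (mean dark-current DL), plus logical `poisson`
#'   turning Poisson shot noise on (off by default).
#' @param k_reference calibrated reflectance of the gray reference tile.
#' @param exposure_times named list of 10 strictly increasing exposure
#'   times (ms) per system; `NULL` for the default geometric ladder.
#' @param seed integer RNG seed; phantoms are bit-reproducible given it.
#' @param resolution_scale scales both native camera grids, see
#'   [default_band_sets()].
#' @param band_sets named list of [band_set()]s; overrides
#'   `resolution_scale` when given.
#' @param systems which systems to simulate (default both).
#' @return A validated `phantom_config` object.
#' @export
phantom_config <- function(lesion_class = c("nevus", "melanoma"),
                           lesion_shape = list(center = c(0.5, 0.5),
                                               axes = c(0.26, 0.19),
                                               rotation_deg = 20),
                           skin_profile = default_skin_profile(),
                           lesion_profile = NULL,
                           texture = NULL,
                           misregistration = list(rotation_deg = 3,
                                                  scale = NULL,
                                                  translation_px = c(1.2, -0.8)),
                           noise = list(
                             VISNIR = list(read_sd = 2, dark_level = 40),
                             EXNIR = list(read_sd = 40, dark_level = 600),
                             poisson = FALSE),
                           k_reference = 0.20,
                           exposure_times = NULL,
                           seed = 1L,
                           resolution_scale = 1,
                           band_sets = NULL,
                           systems = c("VISNIR", "EXNIR")) {
  lesion_class <- match.arg(lesion_class)
  if (is.null(lesion_profile)) lesion_profile <- default_lesion_profile(lesion_class)
  if (is.null(texture)) texture <- default_texture(lesion_class)
  if (is.null(band_sets)) band_sets <- default_band_sets(resolution_scale)
  systems <- match.arg(systems, c("VISNIR", "EXNIR"), several.ok = TRUE)
  band_sets <- band_sets[systems]
  if (is.null(exposure_times))
    exposure_times <- list(VISNIR = 2 * 1.35^(0:9), EXNIR = 1 * 1.35^(0:9))
  cfg <- structure(list(
    lesion_class = lesion_class, lesion_shape = lesion_shape,
    skin_profile = skin_profile, lesion_profile = lesion_profile,
    texture = texture, misregistration = misregistration, noise = noise,
    k_reference = k_reference, exposure_times = exposure_times,
    seed = as.integer(seed), band_sets = band_sets, systems = systems),
    class = "phantom_config")
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  for (p in list(cfg$skin_profile, cfg$lesion_profile)) {
    if (any(p <= 0) || any(p > 1))
      stop("reflectance profiles must lie in (0, 1]")
  }
  for (bs in cfg$band_sets) {
    wl <- as.character(bs$wavelengths_nm)
    if (!all(wl %in% names(cfg$skin_profile)) ||
        !all(wl %in% names(cfg$lesion_profile)))
      stop("profiles must cover every configured wavelength")
  }
  if (cfg$k_reference <= 0 || cfg$k_reference > 1)
    stop("k_reference must lie in (0, 1]")
  for (s in cfg$systems) {
    et <- cfg$exposure_times[[s]]
    if (length(et) != 10 || any(diff(et) <= 0))
      stop("exactly 10 strictly increasing exposure times required per system")
  }
  if (!is.null(cfg$texture$sigma) && cfg$texture$sigma < 0)
    stop("texture sigma must be >= 0")
  invisible(cfg)
}

#' Rasterize an ellipse as a logical mask
#'
#' A pixel is foreground when its centre lies inside the ellipse.
#'
#' @param dim `c(width, height)` of the grid.
#' @param center `c(x, y)` in 0-based pixel coordinates.
#' @param axes semi-axes `c(a, b)` in pixels.
#' @param rotation_deg rotation of the `a` axis from +x.
#' @return logical matrix (rows = y, columns = x).
#' @export
ellipse_mask <- function(dim, center, axes, rotation_deg = 0) {
  w <- dim[1]; h <- dim[2]
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  y <- matrix(rep(0:(h - 1), times = w), h, w)
  R <- rot_matrix(-rotation_deg)
  dx <- x - center[1]; dy <- y - center[2]
  u <- R[1, 1] * dx + R[1, 2] * dy
  v <- R[2, 1] * dx + R[2, 2] * dy
  (u / axes[1])^2 + (v / axes[2])^2 <= 1
}

## smoothed, standardized Gaussian random field (unit marginal SD)
random_field <- function(dim, blob_px) {
  h <- dim[2]; w <- dim[1]
  z <- matrix(stats::rnorm(h * w), h, w)
  if (blob_px >= 0.5) {
    z <- as.matrix(EBImage::gblur(z, sigma = blob_px))
  }
  (z - mean(z)) / stats::sd(z)
}

clip_dl <- function(x, max_dl) {
  m <- matrix(as.integer(pmin(pmax(round(x), 0), max_dl)), nrow = nrow(x))
  m
}

#' Generate one dual-modality lesion phantom
#'
#' Simulates the full acquisition of one lesion by both camera systems:
#' the true per-band reflectance scene (skin plus a textured elliptical
#' lesion), the ten-exposure gray-reference and dark calibration stacks,
#' and the raw lesion capture at the exposure whose predicted mean digital
#' level is closest to half the dynamic range. Reference signal grows
#' linearly with exposure time; all images carry Gaussian read noise (and
#' optionally Poisson shot noise) before rounding and clipping to the
#' sensor's digital-level range.
#'
#' @param config a [phantom_config()].
#' @return A `phantom` object with elements `captures`, `calibrations`,
#'   `truth_mask`, `truth_reflectance` (per system, per band),
#'   `truth_class`, `truth_transform` (VIS-NIR -> exNIR, `NULL` when only
#'   one system is simulated) and `config`.
#' @export
generate_phantom <- function(config) {
  validate_phantom_config(config)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)

  vis <- config$band_sets[["VISNIR"]]
  exn <- config$band_sets[["EXNIR"]]

  ## geometry: lesion ellipse on the VIS-NIR grid (or, when only the
  ## exNIR system is simulated, directly on the exNIR grid)
  ref_bs <- if (!is.null(vis)) vis else exn
  dimr <- ref_bs$resolution
  centre_px <- config$lesion_shape$center * (dimr - 1)
  axes_px <- config$lesion_shape$axes * dimr[2]
  rot <- config$lesion_shape$rotation_deg

  truth_transform <- NULL
  truth_mask <- list()
  ellipses <- list()
  ellipses[[ref_bs$system_id]] <-
    list(center = centre_px, axes = axes_px, rotation = rot)
  if (!is.null(vis) && !is.null(exn)) {
    mr <- config$misregistration
    s <- if (is.null(mr$scale)) exn$resolution[1] / vis$resolution[1] else mr$scale
    truth_transform <- registration_transform(
      rotation_deg = mr$rotation_deg, scale = s,
      translation = mr$translation_px,
      src_dim = vis$resolution, dst_dim = exn$resolution)
    ellipses[["EXNIR"]] <- list(
      center = as.vector(apply_transform(truth_transform, centre_px)),
      axes = axes_px * s,
      rotation = rot + mr$rotation_deg)
  }
  for (sid in names(config$band_sets)) {
    e <- ellipses[[sid]]
    truth_mask[[sid]] <- ellipse_mask(config$band_sets[[sid]]$resolution,
                                      e$center, e$axes, e$rotation)
    if (!any(truth_mask[[sid]]))
      stop("lesion mask is empty on the ", sid, " grid")
  }

  captures <- list(); calibrations <- list(); truth_reflectance <- list()
  k <- config$k_reference
  tex <- config$texture

  for (sid in names(config$band_sets)) {
    bs <- config$band_sets[[sid]]
    w <- bs$resolution[1]; h <- bs$resolution[2]
    max_dl <- 2^bs$bit_depth - 1
    half <- max_dl / 2
    nz <- config$noise[[sid]]
    et <- config$exposure_times[[sid]]
    mask <- truth_mask[[sid]]

    ## one spatial texture field shared by all bands of a system
    blob_px <- max(tex$blob_scale * h, 0)
    field <- random_field(bs$resolution, blob_px)
    if (identical(tex$marginal, "uniform"))
      field <- sqrt(3) * (2 * stats::pnorm(field) - 1)
    field <- tex$sigma * field

    ## reference signal rate: exact half scale at the 6th exposure step
    s_ref <- (half - nz$dark_level) / et[6]

    ref_imgs <- list(); dark_imgs <- list(); raw_imgs <- list()
    rtruth <- list(); expo_idx <- integer(0); expo_time <- numeric(0)

    for (wl in bs$wavelengths_nm) {
      key <- as.character(wl)
      r_true <- matrix(config$skin_profile[[key]], h, w)
      lesion_val <- config$lesion_profile[[key]] * (1 + field[mask])
      r_true[mask] <- pmin(pmax(lesion_val, 1e-4), 1)
      rtruth[[key]] <- r_true

      ## ten-exposure reference + dark stacks
      refs <- vector("list", length(et)); darks <- vector("list", length(et))
      for (j in seq_along(et)) {
        sig <- nz$dark_level + s_ref * et[j]
        refs[[j]] <- clip_dl(noisy(matrix(sig, h, w), nz, config$noise$poisson,
                                   signal = sig - nz$dark_level), max_dl)
        darks[[j]] <- clip_dl(noisy(matrix(nz$dark_level, h, w), nz, FALSE), max_dl)
      }
      ref_imgs[[key]] <- refs; dark_imgs[[key]] <- darks

      ## raw capture at the exposure predicted to land nearest half scale,
      ## restricted to exposures whose reference is not saturated
      usable <- which(nz$dark_level + s_ref * et <= 0.98 * max_dl)
      pred <- nz$dark_level + mean(r_true) / k * s_ref * et[usable]
      if (length(usable) == 0 || all(pred >= 0.98 * max_dl))
        stop("unusable calibration: lesion capture saturates at every exposure time")
      j_raw <- usable[which.min(abs(pred - half))]
      sig <- (r_true / k) * (s_ref * et[j_raw])
      raw_imgs[[key]] <- clip_dl(noisy(nz$dark_level + sig, nz,
                                       config$noise$poisson, signal = sig), max_dl)
      expo_idx <- c(expo_idx, j_raw); expo_time <- c(expo_time, et[j_raw])
    }

    captures[[sid]] <- structure(list(
      system_id = sid, band_set = bs, images = raw_imgs,
      exposure_index = stats::setNames(expo_idx, names(raw_imgs)),
      exposure_time = stats::setNames(expo_time, names(raw_imgs)),
      bit_depth = bs$bit_depth), class = "raw_capture")
    calibrations[[sid]] <- structure(list(
      system_id = sid, band_set = bs, reference = ref_imgs, dark = dark_imgs,
      exposure_times = et, k = k), class = "calibration_set")
    truth_reflectance[[sid]] <- rtruth
  }

  structure(list(captures = captures, calibrations = calibrations,
                 truth_mask = truth_mask,
                 truth_reflectance = truth_reflectance,
                 truth_class = config$lesion_class,
                 truth_transform = truth_transform,
                 config = config),
            class = "phantom")
}

## add sensor noise to an ideal (pre-quantization) image
noisy <- function(ideal, nz, poisson = FALSE, signal = NULL) {
  out <- ideal
  if (isTRUE(poisson) && !is.null(signal)) {
    sig <- pmax(signal, 0)
    out <- out - sig + stats::rpois(length(out), sig)
  }
  if (nz$read_sd > 0)
    out <- out + stats::rnorm(length(out), sd = nz$read_sd)
  matrix(out, nrow = nrow(ideal))
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom: %s, systems %s, seed %d>\n", x$truth_class,
              paste(names(x$captures), collapse = "+"), x$config$seed))
  invisible(x)
}

#' Default per-lesion jitter for cohort generation
#'
#' Uniform jitter ranges applied independently per lesion: a global scale
#' on the lesion spectrum (`profile_scale`, the dominant source of
#' within-class variance), a scale on the skin spectrum, shape centre and
#' axis perturbations, free ellipse orientation, texture amplitude scale
#' and small misregistration perturbations.
#'
#' @return named list of jitter half-ranges.
#' @export
cohort_jitter <- function() {
  list(profile_scale = 0.18, skin_scale = 0.06, center = 0.05,
       axes_scale = 0.25, rotation = c(0, 180), texture_scale = 0.2,
       misreg_rotation = 1, translation_px = 2)
}

#' Per-lesion configurations for a synthetic cohort
#'
#' Draws per-lesion jitter around a base configuration and returns one
#' [phantom_config()] per lesion (nevi first, then melanomas), each with
#' its own derived seed. [generate_cohort()] materializes them;
#' `cohort_configs()` is exposed separately so large cohorts can be
#' generated and processed one lesion at a time.
#'
#' @param n_nevi,n_melanomas cohort composition (default 39 + 14).
#' @param base_config the shared [phantom_config()] template.
#' @param seed cohort-level seed.
#' @param jitter see [cohort_jitter()].
#' @param class_profiles named list (`nevus`, `melanoma`) of lesion
#'   spectra; defaults to [default_lesion_profile()] per class.
#' @param class_texture named list of texture parameter lists per class;
#'   defaults to [default_texture()] per class.
#' @return list of `phantom_config` objects with names `lesion_001`, ...
#' @export
cohort_configs <- function(n_nevi = 39, n_melanomas = 14,
                           base_config = phantom_config(),
                           seed = 1L, jitter = cohort_jitter(),
                           class_profiles = NULL, class_texture = NULL) {
  stopifnot(n_nevi >= 0, n_melanomas >= 0)
  n <- n_nevi + n_melanomas
  if (n == 0) return(list())
  if (is.null(class_profiles))
    class_profiles <- list(nevus = default_lesion_profile("nevus"),
                           melanoma = default_lesion_profile("melanoma"))
  if (is.null(class_texture))
    class_texture <- list(nevus = default_texture("nevus"),
                          melanoma = default_texture("melanoma"))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  classes <- c(rep("nevus", n_nevi), rep("melanoma", n_melanomas))
  runif2 <- function(a) stats::runif(1, -a, a)
  configs <- vector("list", n)
  for (i in seq_len(n)) {
    cl <- classes[i]
    cfg <- base_config
    cfg$lesion_class <- cl
    cfg$lesion_profile <- pmin(class_profiles[[cl]] *
                                 (1 + runif2(jitter$profile_scale)), 1)
    cfg$skin_profile <- pmin(base_config$skin_profile *
                               (1 + runif2(jitter$skin_scale)), 1)
    cfg$lesion_shape$center <- base_config$lesion_shape$center +
      c(runif2(jitter$center), runif2(jitter$center))
    cfg$lesion_shape$axes <- base_config$lesion_shape$axes *
      (1 + c(runif2(jitter$axes_scale), runif2(jitter$axes_scale)))
    cfg$lesion_shape$rotation_deg <- stats::runif(1, jitter$rotation[1],
                                                  jitter$rotation[2])
    cfg$texture <- class_texture[[cl]]
    cfg$texture$sigma <- cfg$texture$sigma * (1 + runif2(jitter$texture_scale))
    cfg$misregistration$rotation_deg <-
      base_config$misregistration$rotation_deg + runif2(jitter$misreg_rotation)
    cfg$misregistration$translation_px <-
      c(runif2(jitter$translation_px), runif2(jitter$translation_px))
    cfg$seed <- seeds[i]
    configs[[i]] <- validate_phantom_config(cfg)
  }
  names(configs) <- sprintf("lesion_%03d", seq_len(n))
  configs
}

#' Generate a synthetic lesion cohort
#'
#' @inheritParams cohort_configs
#' @param ... passed on to [cohort_configs()].
#' @return list of [generate_phantom()] results, nevi first.
#' @export
generate_cohort <- function(n_nevi = 39, n_melanomas = 14,
                            base_config = phantom_config(), seed = 1L, ...) {
  lapply(cohort_configs(n_nevi, n_melanomas, base_config, seed, ...),
         generate_phantom)
}
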