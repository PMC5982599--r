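test_that("histograms are equal-width, normalized, and handle constants", {
  h <- build_histogram(c(0, 0, 1, 1), N = 2)
  expect_equal(h$P, c(0.5, 0.5))
  hc <- build_histogram(rep(0.3, 10), N = 256)
  expect_equal(hc$P[1], 1)
  expect_equal(sum(hc$P), 1)
  set.seed(1)
  hr <- build_histogram(runif(500), N = 64)
  expect_equal(sum(hr$P), 1, tolerance = 1e-12)
  expect_true(all(hr$P >= 0))
  expect_error(build_histogram(numeric(0)), "empty")
  expect_error(build_histogram(1:5, N = 1), "N must be")
})

test_that("energy attains its analytic values", {
  expect_equal(energy(build_histogram(rep(0.7, 32 * 32), 256)), 1)
  expect_equal(energy(build_histogram(c(0, 0, 1, 1), 2)), 0.5)
  N <- 64
  expect_equal(energy(build_histogram(seq_len(N) - 0.5, N)), 1 / N)
})

test_that("entropy attains its analytic values in both modes", {
  hc <- build_histogram(rep(0.7, 32 * 32), 256)
  expect_equal(entropy(hc, "as_printed"), 0)
  expect_equal(entropy(hc, "standard"), 0)
  h2 <- build_histogram(c(0, 0, 1, 1), 2)
  expect_equal(entropy(h2, "as_printed"), 1.0)   # -2 * 0.25 * log2(0.25)
  N <- 128
  hu <- build_histogram(seq_len(N) - 0.5, N)
  expect_equal(entropy(hu, "standard"), log2(N))
})

test_that("the third central moment vanishes for symmetric histograms and matches the hand value", {
  sym <- build_histogram(rep(c(1, 2, 3), c(2, 5, 2)), 3)
  expect_equal(third_central_moment(sym, "as_printed"), 0)
  expect_equal(third_central_moment(sym, "normalized"), 0)
  expect_equal(third_central_moment(build_histogram(rep(1, 5), 8)), 0)
  ## P = (0.5, 0.25, 0.25) over i = 0,1,2 with squared-frequency weights
  h <- build_histogram(rep(c(0, 1, 2), c(2, 1, 1)), 3)
  expect_equal(h$P, c(0.5, 0.25, 0.25))
  expect_equal(third_central_moment(h, "as_printed"), 0.017578125)
})

test_that("basic statistics use raw values and the population deviation", {
  expect_equal(basic_stats(c(0.2, 0.2)),
               c(mean = 0.2, max = 0.2, min = 0.2, std = 0))
  expect_equal(basic_stats(c(0, 1)),
               c(mean = 0.5, max = 1, min = 0, std = 0.5))
  expect_equal(basic_stats(3.7), c(mean = 3.7, max = 3.7, min = 3.7, std = 0))
  expect_error(basic_stats(NA_real_), "empty")
})

test_that("descriptors match naive loop oracles on random masked images", {
  set.seed(30)
  for (i in 1:10) {
    img <- matrix(rnorm(32 * 32, 0.4, 0.1), 32, 32)
    mask <- matrix(runif(32 * 32) < 0.4, 32, 32)
    v <- img[mask]
    h <- build_histogram(v, 256)
    P <- oracle_histogram(v, 256)
    expect_equal(h$P, P, tolerance = 1e-12)
    expect_equal(energy(h), oracle_energy(P), tolerance = 1e-10)
    expect_equal(entropy(h, "as_printed"), oracle_entropy(P, TRUE),
                 tolerance = 1e-10)
    expect_equal(entropy(h, "standard"), oracle_entropy(P, FALSE),
                 tolerance = 1e-10)
    expect_equal(third_central_moment(h, "as_printed"), oracle_mu3(P),
                 tolerance = 1e-10)
    expect_equal(third_central_moment(h, "normalized"), oracle_mu3(P, TRUE),
                 tolerance = 1e-10)
    expect_equal(basic_stats(v), oracle_basic(v), tolerance = 1e-10)
  }
})

test_that("descriptors are invariant to pixel order and equivariant under affine maps", {
  set.seed(31)
  v <- rnorm(400, 0.5, 0.1)
  s <- first_order_stats(matrix(v, 20, 20), matrix(TRUE, 20, 20))
  sp <- first_order_stats(matrix(sample(v), 20, 20), matrix(TRUE, 20, 20))
  expect_equal(s, sp, tolerance = 1e-12)

  a <- 2.5; b <- -0.3
  sa <- first_order_stats(matrix(a * v + b, 20, 20), matrix(TRUE, 20, 20))
  expect_equal(sa[["energy"]], s[["energy"]], tolerance = 1e-9)
  expect_equal(sa[["entropy"]], s[["entropy"]], tolerance = 1e-9)
  expect_equal(sa[["mu3"]], s[["mu3"]], tolerance = 1e-9)
  expect_equal(sa[["mean"]], a * s[["mean"]] + b, tolerance = 1e-9)
  expect_equal(sa[["max"]], a * s[["max"]] + b, tolerance = 1e-9)
  expect_equal(sa[["min"]], a * s[["min"]] + b, tolerance = 1e-9)
  expect_equal(sa[["std"]], a * s[["std"]], tolerance = 1e-9)
})

test_that("planted texture classes separate in entropy and energy at 1214 nm", {
  base <- phantom_config(resolution_scale = 1 / 4, systems = "EXNIR")
  stat_1214 <- function(class, seeds) t(vapply(seeds, function(s) {
    cfgs <- cohort_configs(as.integer(class == "nevus"),
                           as.integer(class == "melanoma"),
                           base_config = base, seed = s)
    ph <- generate_phantom(cfgs[[1]])
    st <- compute_reflectance(ph$captures$EXNIR, ph$calibrations$EXNIR)
    h <- build_histogram(st$images[["1214"]][ph$truth_mask$EXNIR], 256)
    c(entropy = entropy(h, "standard"), energy = energy(h))
  }, c(entropy = 0, energy = 0)))
  nev <- stat_1214("nevus", 1:6)
  mel <- stat_1214("melanoma", 101:106)
  ## melanomas: broader histograms -> higher disorder, lower uniformity
  expect_gt(mean(mel[, "entropy"]), mean(nev[, "entropy"]))
  expect_gt(mean(nev[, "energy"]), mean(mel[, "energy"]))
})

test_that("the descriptor table enumerates 392 (or 224 VIS-only) columns in canonical order", {
  ids <- descriptor_ids()
  expect_length(ids, 392)
  expect_length(descriptor_ids(list(VISNIR = visnir_band_set())), 224)
  expect_length(descriptor_ids(list(EXNIR = exnir_band_set())), 168)

  set.seed(32)
  mkstack <- function(bs, variant, const = NULL) {
    imgs <- lapply(stats::setNames(bs$wavelengths_nm,
                                   bs$wavelengths_nm), function(wl) {
      if (is.null(const)) matrix(runif(64, 0.1, 0.9), 8, 8)
      else matrix(const, 8, 8)
    })
    reflectance_stack(bs$system_id, imgs, variant)
  }
  bss <- default_band_sets(1 / 160)  # 8x6 / 8x8 grids, irrelevant here
  mask <- matrix(FALSE, 8, 8); mask[3:6, 3:6] <- TRUE
  lesions <- list(
    L1 = list(class = "nevus",
              variants = lapply(bss, function(bs)
                stats::setNames(lapply(c("R", "R_minus_skin", "A", "A_minus_skin"),
                                       function(v) mkstack(bs, v)),
                                c("R", "R_minus_skin", "A", "A_minus_skin"))),
              masks = list(VISNIR = mask, EXNIR = mask)))
  tab <- compute_descriptor_table(lesions)
  expect_equal(ncol(tab) - 2, 392)
  expect_identical(names(tab)[-(1:2)], ids)

  ## constant images: energy 1, entropy 0, mu3 0 in every band and variant
  lesions$L1$variants <- lapply(bss, function(bs)
    stats::setNames(lapply(c("R", "R_minus_skin", "A", "A_minus_skin"),
                           function(v) mkstack(bs, v, const = 0.42)),
                    c("R", "R_minus_skin", "A", "A_minus_skin")))
  tabc <- compute_descriptor_table(lesions)
  expect_true(all(tabc[, grepl("\\.energy$", names(tabc))] == 1))
  expect_true(all(tabc[, grepl("\\.entropy$", names(tabc))] == 0))
  expect_true(all(tabc[, grepl("\\.mu3$", names(tabc))] == 0))
})

test_that("lesions with missing variants are excluded with a message", {
  bs <- list(VISNIR = visnir_band_set(1 / 160))
  mask <- matrix(TRUE, 4, 4)
  good <- list(class = "nevus",
               variants = list(VISNIR = stats::setNames(
                 lapply(c("R", "R_minus_skin", "A", "A_minus_skin"), function(v)
                   reflectance_stack("VISNIR", lapply(
                     stats::setNames(bs$VISNIR$wavelengths_nm,
                                     bs$VISNIR$wavelengths_nm),
                     function(wl) matrix(runif(16), 4, 4)), v)),
                 c("R", "R_minus_skin", "A", "A_minus_skin"))),
               masks = list(VISNIR = mask))
  bad <- good
  bad$variants$VISNIR$A <- NULL
  expect_message(tab <- compute_descriptor_table(list(L1 = good, L2 = bad)),
                 "excluding lesion L2")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$id, "L1")
})
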