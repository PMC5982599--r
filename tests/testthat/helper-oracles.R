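## Independent brute-force oracles used across the suite. Everything here
## is deliberately written as plain loops, separate from the package's
## vectorized implementations.

## histogram by explicit loop (equal-width bins, max value in last bin)
oracle_histogram <- function(values, N) {
  v <- values[is.finite(values)]
  lo <- min(v); hi <- max(v)
  counts <- rep(0, N)
  if (hi == lo) {
    counts[1] <- length(v)
  } else {
    w <- (hi - lo) / N
    for (x in v) {
      b <- floor((x - lo) / w) + 1
      if (b > N) b <- N
      counts[b] <- counts[b] + 1
    }
  }
  counts / length(v)
}

oracle_energy <- function(P) {
  s <- 0
  for (p in P) s <- s + p * p
  s
}

oracle_entropy <- function(P, as_printed = TRUE) {
  s <- 0
  for (p in P) {
    if (p > 0) {
      s <- s + if (as_printed) -p^2 * log2(p^2) else -p * log2(p)
    }
  }
  s
}

oracle_mu3 <- function(P, normalized = FALSE) {
  N <- length(P)
  mu <- 0
  for (i in 0:(N - 1)) mu <- mu + i * P[i + 1]
  m3 <- 0; v2 <- 0
  for (i in 0:(N - 1)) {
    m3 <- m3 + (i - mu)^3 * P[i + 1]^2
    v2 <- v2 + (i - mu)^2 * P[i + 1]
  }
  if (!normalized) return(m3)
  if (v2 == 0) 0 else m3 / v2^1.5
}

oracle_basic <- function(v) {
  v <- v[is.finite(v)]
  n <- length(v)
  m <- 0
  for (x in v) m <- m + x
  m <- m / n
  ss <- 0
  for (x in v) ss <- ss + (x - m)^2
  c(mean = m, max = max(v), min = min(v), std = sqrt(ss / n))
}

## exhaustive Otsu: maximize between-class variance over every candidate
## bin-edge threshold of an N-bin histogram
oracle_otsu <- function(image, N = 256) {
  v <- as.numeric(image)
  v <- v[is.finite(v)]
  lo <- min(v); hi <- max(v)
  w <- (hi - lo) / N
  P <- oracle_histogram(v, N)
  best <- -Inf; best_t <- NA
  for (t in 1:(N - 1)) {
    w0 <- sum(P[1:t]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    i <- 0:(N - 1)
    mu0 <- sum(i[1:t] * P[1:t]) / w0
    mu1 <- sum(i[(t + 1):N] * P[(t + 1):N]) / w1
    sb <- w0 * w1 * (mu0 - mu1)^2
    if (sb > best) { best <- sb; best_t <- t }
  }
  lo + best_t * w
}

## loop-based mean-skin subtraction
oracle_subtract_skin <- function(img, lesion, skin) {
  s <- 0; n <- 0
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    if (skin[i, j]) { s <- s + img[i, j]; n <- n + 1 }
  }
  mu <- s / n
  out <- matrix(NA_real_, nrow(img), ncol(img))
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    if (lesion[i, j]) out[i, j] <- img[i, j] - mu
  }
  out
}

## forward greedy rule accumulation re-implemented with explicit sets
oracle_greedy <- function(table, rules) {
  mel <- which(table$class == "melanoma")
  caught <- c()
  picked <- character(0)
  for (r in rules) {
    v <- table[[r$descriptor]]
    fl <- which((v > r$upper | v < r$lower) & seq_along(v) %in% mel)
    if (length(setdiff(fl, caught)) >= 1) {
      caught <- union(caught, fl)
      picked <- c(picked, r$descriptor)
    }
  }
  picked
}

## small fast phantom configuration for unit tests
tiny_config <- function(seed = 1, ...) {
  phantom_config(resolution_scale = 1 / 16, seed = seed, ...)
}

## noise-free, texture-free configuration (exact forward model)
noiseless_config <- function(seed = 1, lesion_profile = NULL, k = 0.2, ...) {
  cfg <- phantom_config(
    resolution_scale = 1 / 16, seed = seed,
    texture = list(sigma = 0, blob_scale = 0.03, marginal = "gaussian"),
    noise = list(VISNIR = list(read_sd = 0, dark_level = 40),
                 EXNIR = list(read_sd = 0, dark_level = 600),
                 poisson = FALSE),
    k_reference = k, ...)
  if (!is.null(lesion_profile)) cfg$lesion_profile <- lesion_profile
  cfg
}

## build a minimal raw_capture / calibration_set pair from plain matrices
fake_capture <- function(I, I_N, I_D, k = 0.2, bit_depth = 12L,
                         exposure_time = 5) {
  bs <- band_set("VISNIR", 414, 25, bit_depth,
                 c(ncol(I), nrow(I)))
  raw <- structure(list(system_id = "VISNIR", band_set = bs,
                        images = list(`414` = I),
                        exposure_index = c(`414` = 1L),
                        exposure_time = c(`414` = exposure_time),
                        bit_depth = bit_depth), class = "raw_capture")
  cal <- structure(list(system_id = "VISNIR", band_set = bs,
                        reference = list(`414` = list(I_N)),
                        dark = list(`414` = list(I_D)),
                        exposure_times = exposure_time, k = k),
                   class = "calibration_set")
  list(raw = raw, cal = cal)
}

## descriptor table fixture: planted descriptor columns + classes
fixture_table <- function(values, classes) {
  df <- data.frame(id = sprintf("L%02d", seq_along(classes)),
                   class = classes, check.names = FALSE)
  for (nm in names(values)) df[[nm]] <- values[[nm]]
  df
}
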