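test_that("the frequency grid is geometric with exact endpoints", {
  expect_equal(as.numeric(make_grid(2, 120, 2)), c(2, 120))
  expect_equal(as.numeric(make_grid(2, 8, 3)), c(2, 4, 8))
  g <- make_grid(2, 120, 100)
  ratios <- g[-1] / g[-100]
  expect_equal(ratios, rep(60^(1 / 99), 99), tolerance = 1e-12)
  expect_equal(g[1], 2)
  expect_equal(g[100], 120)
  expect_error(make_grid(0, 120, 10), class = "cfcdetect_grid")
  expect_error(make_grid(5, 2, 10), class = "cfcdetect_grid")
  expect_error(make_grid(2, 120, 1), class = "cfcdetect_grid")
})

test_that("the spectrogram localises a pure tone at the nearest grid point", {
  fs <- 256
  t <- (0:(20 * fs - 1)) / fs
  x <- sin(2 * pi * 10 * t)
  grid <- make_grid(2, 120, 100)
  sp <- compute_spectrogram(x, fs, grid)
  target <- which.min(abs(as.numeric(grid) - 10))
  argmaxes <- apply(sp$power, 1, which.max)
  expect_true(all(argmaxes == target))
})

test_that("white-noise spectra are flat and silence stays finite", {
  set.seed(5)
  fs <- 256
  x <- rnorm(120 * fs)
  sp <- compute_spectrogram(x, fs, make_grid(2, 120, 50))
  avg <- colMeans(sp$power)
  expect_lt(max(avg) - min(avg), 6)    # within +/- 3 dB of each other
  z <- compute_spectrogram(numeric(10 * fs), fs, make_grid(2, 120, 20))
  expect_true(all(is.finite(z$power)))
})

test_that("spectrogram preconditions are enforced", {
  fs <- 256
  expect_error(compute_spectrogram(rnorm(100), fs, make_grid(2, 120, 10)),
               class = "cfcdetect_too_short")
  expect_error(compute_spectrogram(rnorm(fs * 10), fs,
                                   make_grid(2, 140, 10)),
               class = "cfcdetect_grid")
  expect_error(compute_spectrogram(rnorm(fs * 10), fs,
                                   make_grid(2, 120, 10), window_s = 0.5),
               class = "cfcdetect_grid")
})

fake_spec <- function(power, fs = 256, n = ncol(power)) {
  structure(list(power = power, grid = make_grid(2, 120, n),
                 window_s = 2, overlap = 0.5, fs = fs),
            class = "spectrogram")
}

test_that("comodulograms are symmetric, unit-diagonal and bounded", {
  set.seed(6)
  C <- compute_comodulogram(fake_spec(matrix(rnorm(40 * 30), 40)))
  expect_true(isSymmetric(unclass(C)))
  expect_equal(unname(diag(C)), rep(1, 30))
  expect_true(all(C >= -1 & C <= 1))
})

test_that("a shared power envelope couples its two frequencies", {
  set.seed(7)
  env <- rnorm(60)
  P <- matrix(rnorm(60 * 20, sd = 1), 60)
  P[, 4] <- 5 * env + rnorm(60, sd = 0.5)
  P[, 11] <- 5 * env + rnorm(60, sd = 0.5)
  C <- compute_comodulogram(fake_spec(P))
  expect_gt(C[4, 11], 0.9)
  # oracle: the injected envelopes themselves correlate at least as strongly
  expect_gt(cor(P[, 4], P[, 11]), 0.9)
})

test_that("independent powers stay inside the correlation null band", {
  set.seed(8)
  C <- compute_comodulogram(fake_spec(matrix(rnorm(200 * 25), 200)))
  off <- abs(C[upper.tri(C)])
  expect_gt(mean(off < 0.25), 0.99)
})

test_that("zero-variance power traces yield 0 coupling and 1 diagonal", {
  set.seed(9)
  P <- matrix(rnorm(30 * 10), 30)
  P[, 3] <- 7
  expect_message(C <- compute_comodulogram(fake_spec(P)), "zero-variance")
  expect_equal(unname(C[3, -3]), rep(0, 9))
  expect_equal(unname(C[3, 3]), 1)
})

test_that("too few windows is an explicit error", {
  expect_error(compute_comodulogram(fake_spec(matrix(rnorm(7 * 10), 7))),
               class = "cfcdetect_insufficient_data")
})

test_that("shuffling one power trace destroys its couplings", {
  set.seed(10)
  env <- rnorm(120)
  P <- matrix(rnorm(120 * 12, sd = 0.3), 120) + env
  C <- compute_comodulogram(fake_spec(P))
  expect_gt(min(C[upper.tri(C)]), 0.8)
  P2 <- P
  P2[, 5] <- P[sample(120), 5]
  C2 <- compute_comodulogram(fake_spec(P2))
  expect_lt(max(abs(C2[5, -5])), 0.35)
})

test_that("per-segment comodulograms average over components", {
  set.seed(11)
  fs <- 256
  mk_acts <- function(m) {
    structure(list(acts = m, fs = fs, segment_id = "s", label = "seizure"),
              class = "ic_activations")
  }
  x1 <- rnorm(fs * 12)
  x2 <- rnorm(fs * 12)
  g <- make_grid(2, 120, 20)
  C1 <- segment_cfc(mk_acts(matrix(x1, 1, byrow = TRUE)), grid = g)
  C2 <- segment_cfc(mk_acts(matrix(x2, 1, byrow = TRUE)), grid = g)
  # one component: equals that component's matrix; duplicated: unchanged
  Cd <- segment_cfc(mk_acts(rbind(x1, x1)), grid = g)
  expect_equal(unclass(Cd), unclass(C1), tolerance = 1e-12)
  # two different components: the element-wise mean
  Cm <- segment_cfc(mk_acts(rbind(x1, x2)), grid = g)
  expect_equal(unclass(Cm), (unclass(C1) + unclass(C2)) / 2,
               tolerance = 1e-12)
})

test_that("a 15 Hz non-sinusoid shows harmonic maxima at (15,30) and (15,45)", {
  set.seed(12)
  fs <- 256
  n <- 60 * fs
  jit <- stats::filter(rnorm(n, sd = 1), rep(1 / 256, 256), circular = TRUE)
  theta <- 2 * pi * cumsum(15 * (1 + 0.02 * as.numeric(jit))) / fs
  env <- stats::filter(rnorm(n), rep(1 / 512, 512), circular = TRUE)
  env <- pmax(1 + 8 * as.numeric(env), 0.05)
  x <- env * (cos(theta) + 0.7 * cos(2 * theta) + 0.5 * cos(3 * theta)) +
    rnorm(n, sd = 0.05)
  grid <- make_grid(2, 120, 100)
  sp <- compute_spectrogram(x, fs, grid)
  C <- compute_comodulogram(sp)
  near <- function(f) which.min(abs(as.numeric(grid) - f))
  i15 <- near(15); i30 <- near(30); i45 <- near(45)
  # harmonic pairs couple strongly...
  expect_gt(C[i15, i30], 0.8)
  expect_gt(C[i15, i45], 0.8)
  # ...and stand out as local maxima along the 15 Hz row relative to
  # off-harmonic control frequencies
  ctrl <- c(near(22), near(37), near(70))
  expect_gt(C[i15, i30], max(C[i15, ctrl]))
  expect_gt(C[i15, i45], max(C[i15, ctrl]))
})

test_that("seizure-minus-background coupling is positive in the 15-80 Hz block", {
  cfg <- tiny_cfg()
  grid <- make_grid(2, 120, 40)
  avg_cfc <- function(gen) {
    acc <- 0
    for (seed in 1:4) {
      seg <- gen(cfg, seed = seed)
      acts <- apply_unmixing(common_average_reference(seg),
                             identity_unmixing(cfg$n_channels))
      acc <- acc + unclass(segment_cfc(acts, grid = grid))
    }
    acc / 4
  }
  Cs <- avg_cfc(generate_seizure)
  Cb <- avg_cfc(generate_background)
  block <- as.numeric(grid) >= 15 & as.numeric(grid) <= 80
  D <- (Cs - Cb)[block, block]
  expect_gt(mean(D[upper.tri(D)]), 0)
})

test_that("comodulograms flatten and export consistently", {
  set.seed(13)
  C <- compute_comodulogram(fake_spec(matrix(rnorm(20 * 10), 20)))
  v <- flatten_cfc(C)
  expect_length(v, 10 * 11 / 2)
  expect_true(all(v >= -1 & v <= 1))
  expect_length(flatten_cfc(C, full = TRUE), 100)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cfc_csv(C, path)
  back <- as.matrix(utils::read.csv(path))
  expect_lt(max(abs(back - unclass(C))), 1e-6)
})
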