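# Normalization, mean spectra, noise estimation, peak picking, data cubes.

test_that("rms_normalize yields unit-RMS spectra and is idempotent", {
  # hand-computed: RMS of [3, 4] is sqrt((9+16)/2) = 3.53553
  ds <- msi_dataset(data.frame(x = 0L, y = 0L), mz = c(100, 200),
                    intensity = matrix(c(3, 4), 1), mode = "continuous")
  out <- rms_normalize(ds)
  expect_equal(as.numeric(out$intensity), c(0.84853, 1.13137),
               tolerance = 1e-5)
  expect_equal(sqrt(mean(out$intensity^2)), 1, tolerance = 1e-12)
  # idempotence
  twice <- rms_normalize(out)
  expect_equal(twice$intensity, out$intensity, tolerance = 1e-12)
  # degenerate all-zero spectrum left unchanged with a warning
  dz <- msi_dataset(data.frame(x = 0:1, y = c(0L, 0L)), mz = c(100, 200),
                    intensity = rbind(c(0, 0), c(1, 1)),
                    mode = "continuous")
  expect_warning(outz <- rms_normalize(dz), "all-zero")
  expect_equal(as.numeric(outz$intensity[1, ]), c(0, 0))
  # every spectrum of a phantom section has RMS 1 after normalization
  ds2 <- rms_normalize(read_imzml(small_manifest()$imzml[1]))
  expect_equal(sqrt(rowMeans(ds2$intensity^2)),
               rep(1, n_pixels(ds2)), tolerance = 1e-9)
})

test_that("mean_spectrum is the arithmetic mean over selected pixels", {
  ds <- msi_dataset(data.frame(x = 0:1, y = c(0L, 0L)), mz = c(100, 200),
                    intensity = rbind(c(1, 2), c(3, 6)),
                    mode = "continuous")
  ms <- mean_spectrum(ds)
  expect_equal(ms$intensity, c(2, 4))     # linearity: (a + 3a)/2 = 2a
  # one selected pixel returns its own spectrum
  one <- msi_dataset(data.frame(x = 0L, y = 0L), mz = c(100, 200),
                     intensity = matrix(c(1, 2), 1), mode = "continuous")
  expect_equal(mean_spectrum(one)$intensity, c(1, 2))
  # empty ROI errors
  grid <- matrix(1L, 1, 2)
  m <- roi_mask(grid)
  expect_error(mean_spectrum(ds, m), "empty ROI")
  # processed-mode resampling agrees with direct interpolation
  dp <- tiny_processed()
  ms2 <- mean_spectrum(dp, bin_width = 10)
  manual <- rowMeans(vapply(seq_len(4), function(i) {
    approx(dp$mz[[i]], dp$intensity[[i]], xout = ms2$mz,
           yleft = 0, yright = 0)$y
  }, numeric(length(ms2$mz))))
  expect_equal(ms2$intensity, manual)
})

test_that("a masked mean spectrum is dominated by the compartment profile", {
  truth <- small_truth()
  man <- small_manifest()
  ds <- read_imzml(man$imzml[1])
  mask <- truth$masks[[1]]
  ms <- mean_spectrum(ds, mask, labels = "osteoid")
  # intensity at the planted apexes should track the osteoid base profile
  apex <- vapply(truth$peaks$mz, function(m) {
    ms$intensity[which.min(abs(ms$mz - m))]
  }, numeric(1))
  expect_gt(cor(apex, truth$base["osteoid", ]), 0.95)
})

test_that("estimate_noise recovers a known sigma and resists spikes", {
  set.seed(31)
  mz <- seq(100, 110, by = 0.0025)
  y <- rnorm(length(mz), 0, 1)
  noise <- estimate_noise(mz, y, window = 1)
  expect_gt(mean(abs(noise - 1) <= 0.15), 0.95)
  # constant spectrum has zero noise
  expect_equal(estimate_noise(mz, rep(5, length(mz)), 1),
               rep(0, length(mz)))
  # a single huge spike barely moves the robust estimate
  y2 <- y; y2[2000] <- 1e5
  noise2 <- estimate_noise(mz, y2, window = 1)
  expect_lt(max(abs(noise2[-2000] - noise[-2000])), 0.2)
  expect_error(estimate_noise(mz, y, window = 0), "window")
  expect_error(estimate_noise(mz, y, window = 1e-4), "bin spacing")
})

test_that("pick_peaks keeps exactly the peaks above the S/N threshold", {
  # flat spectrum: no peaks
  flat <- list(mz = seq(100, 101, by = 0.01), intensity = rep(2, 101))
  expect_equal(nrow(pick_peaks(flat)), 0L)
  # one Gaussian at 200.0 with the apex at exactly 10x the noise level.
  # Zero-median bounded (uniform) noise off the peak support: baseline
  # local maxima stay ~1.3x the MAD noise and the apex height is exact.
  set.seed(5)
  mz <- seq(199, 201, by = 0.002)
  u <- runif(length(mz)) - 0.5
  noise_level <- mad(u)      # mad() already carries the 1.4826 scaling
  gauss <- function(center) exp(-(mz - center)^2 / (2 * 0.01^2))
  with_peaks <- function(amps, centers) {
    shape <- Reduce(`+`, Map(function(a, c) a * noise_level * gauss(c),
                             amps, centers))
    ifelse(shape > 0.001 * noise_level, shape, u)
  }
  y <- with_peaks(10, 200)
  pk <- pick_peaks(list(mz = mz, intensity = y), snr_threshold = 3)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$mz, mz[which.max(y)])   # center is the apex bin
  # two peaks at 10x and 2x noise: threshold 3 keeps only the first
  y2 <- with_peaks(c(10, 2), c(199.5, 200.5))
  pk2 <- pick_peaks(list(mz = mz, intensity = y2), snr_threshold = 3)
  expect_equal(nrow(pk2), 1L)
  expect_lt(abs(pk2$mz - 199.5), 0.01)
})

test_that("pick_peaks is monotone in the threshold", {
  man <- small_manifest()
  ds <- rms_normalize(read_imzml(man$imzml[1]))
  ms <- mean_spectrum(ds)
  p3 <- pick_peaks(ms, 3)
  p4 <- pick_peaks(ms, 4)
  expect_true(all(p4$mz %in% p3$mz))
  expect_true(all(p3$snr >= 3))
})

test_that("build_datacube equals a brute-force windowed sum", {
  ds <- tiny_continuous()
  centers <- sort(ds$mz[c(3, 8, 15)])
  peaks <- data.frame(mz = centers)
  cube <- build_datacube(ds, peaks, tol_ppm = 4)
  # naive double loop oracle with the same half-open window
  oracle <- matrix(0, n_pixels(ds), length(centers))
  for (i in seq_len(n_pixels(ds))) {
    for (k in seq_along(centers)) {
      lo <- centers[k] * (1 - 4e-6); hi <- centers[k] * (1 + 4e-6)
      inside <- ds$mz >= lo & ds$mz < hi
      oracle[i, k] <- sum(ds$intensity[i, inside])
    }
  }
  expect_equal(unname(cube$intensity), oracle)
  # a point at center * (1 + 5e-6) is outside a 4 ppm window
  ds2 <- msi_dataset(data.frame(x = 0L, y = 0L),
                     mz = c(200, 200 * (1 + 5e-6)),
                     intensity = matrix(c(7, 9), 1), mode = "continuous")
  cube2 <- build_datacube(ds2, data.frame(mz = 200), tol_ppm = 4)
  expect_equal(as.numeric(cube2$intensity), 7)
  # column sums are invariant under pixel reordering
  ord <- sample(n_pixels(ds))
  dsr <- ds; dsr$coords <- ds$coords[ord, ]; dsr$intensity <- ds$intensity[ord, ]
  cuber <- build_datacube(dsr, peaks, tol_ppm = 4)
  expect_equal(colSums(cuber$intensity), colSums(cube$intensity))
})

test_that("median baseline subtraction preserves intensity ratios", {
  # two 'pixels' whose peak differs 8x on a constant baseline
  mz <- seq(99.5, 100.5, by = 0.01)
  shape <- exp(-(mz - 100)^2 / (2 * 0.004^2))
  baseline <- 0.7
  ds <- msi_dataset(data.frame(x = 0:1, y = c(0L, 0L)), mz = mz,
                    intensity = rbind(2 * shape + baseline,
                                      16 * shape + baseline),
                    mode = "continuous")
  raw <- build_datacube(ds, data.frame(mz = 100), tol_ppm = 4)
  sub <- build_datacube(ds, data.frame(mz = 100), tol_ppm = 4,
                        baseline = "median", baseline_window = 0.6)
  # raw ratio is compressed by the shared baseline; subtraction restores it
  expect_lt(raw$intensity[2, 1] / raw$intensity[1, 1], 8)
  expect_equal(sub$intensity[2, 1] / sub$intensity[1, 1], 8,
               tolerance = 0.01)
})
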