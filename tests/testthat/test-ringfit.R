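ringSpectrum <- function(L, rFun, width = 4, floorVal = 1) {
  ctr <- floor(L / 2) + 1
  dx <- seq_len(L) - ctr
  r <- sqrt(outer(dx^2, dx^2, `+`))
  th <- atan2(rep(dx, each = L), rep(dx, times = L))
  rt <- matrix(rFun(th), L, L)
  v <- floorVal + 50 * exp(-(r - rt)^2 / (2 * width))
  new("PowerSpectrum2D", values = v, L = as.integer(L), nAccumulated = 1L,
      whitened = TRUE)
}

test_that("azimuthal peaks recover circular and elliptical rings to 0.3 px", {
  L <- 512; R <- 170
  circ <- ringSpectrum(L, function(th) rep(R, length(th)))
  pks <- azimuthalPeaks(circ, R, nWedges = 36)
  expect_equal(nrow(pks), 36)
  expect_true(all(abs(pks$radius - R) < 0.3))
  ell <- ringSpectrum(L, function(th)
    1 / sqrt(cos(th)^2 / (R * 1.01)^2 + sin(th)^2 / (R * 0.99)^2))
  pks2 <- azimuthalPeaks(ell, R, nWedges = 36)
  rExp <- 1 / sqrt(cos(pks2$angle)^2 / (R * 1.01)^2 +
                     sin(pks2$angle)^2 / (R * 0.99)^2)
  expect_true(all(abs(pks2$radius - rExp) < 0.3))
})

test_that("a ring present over only 90 degrees raises an incomplete-ring error", {
  L <- 512; R <- 170
  ctr <- floor(L / 2) + 1
  dx <- seq_len(L) - ctr
  r <- sqrt(outer(dx^2, dx^2, `+`))
  th <- matrix(atan2(rep(dx, each = L), rep(dx, times = L)), L, L)
  v <- 1 + 50 * exp(-(r - R)^2 / 8) * (abs(th) < pi / 4)
  ps <- new("PowerSpectrum2D", values = v, L = as.integer(L),
            nAccumulated = 1L, whitened = TRUE)
  expect_error(azimuthalPeaks(ps, R), "incomplete ring")
})

test_that("ellipse fits are exact on noiseless points and unbiased enough on noise", {
  ang <- seq(-pi, pi, length.out = 37)[-37]
  circ <- data.frame(angle = ang, radius = rep(200, 36))
  f0 <- fitEllipse(circ)
  expect_equal(f0@semiMajor, 200, tolerance = 1e-9)
  expect_lt(anisotropyPercent(f0), 1e-6)
  # axis ratio 1.017 at a 30-degree axis
  a <- 200 * sqrt(1.017); b <- 200 / sqrt(1.017); phi <- pi / 6
  rEll <- 1 / sqrt(cos(ang - phi)^2 / a^2 + sin(ang - phi)^2 / b^2)
  f1 <- fitEllipse(data.frame(angle = ang, radius = rEll))
  expect_equal(anisotropyPercent(f1), 1.7, tolerance = 0.01)
  expect_equal(f1@angle, phi, tolerance = 1e-6)
  expect_lt(f1@residualRMS, 1e-9)
  # true mild ellipses are recovered within 10% of the injected ratio
  ratio <- 1.005
  rE <- 1 / sqrt(cos(ang)^2 / (200 * ratio)^2 + sin(ang)^2 / 200^2)
  set.seed(41)
  rec <- replicate(50, {
    f <- fitEllipse(data.frame(angle = ang, radius = rE + rnorm(36, sd = 0.1)))
    f@semiMajor / f@semiMinor
  })
  expect_equal(mean(rec), ratio, tolerance = 0.1 * (ratio - 1) / ratio)
})

test_that("noise induces only a small positive anisotropy bias on circles", {
  # radial noise sd 0.3 px on 36 points of a circle of radius 200: the
  # spurious cos(2 theta) amplitude is Rayleigh with scale
  # 0.3*sqrt(2/36), so the 95th percentile of the anisotropy is
  # 100 * 2 * 2.448 * 0.3 * sqrt(2/36) / 200 = 0.173%
  ang <- seq(-pi, pi, length.out = 37)[-37]
  set.seed(42)
  an <- replicate(200, {
    f <- fitEllipse(data.frame(angle = ang, radius = 200 + rnorm(36, sd = 0.3)))
    anisotropyPercent(f)
  })
  expect_gt(mean(an), 0)                      # positivity bias exists
  rayleigh95 <- 100 * 2 * sqrt(-2 * log(0.05)) * 0.3 * sqrt(2 / 36) / 200
  expect_lt(quantile(an, 0.95), rayleigh95 * 1.25)
  expect_equal(mean(an), 100 * 2 * sqrt(pi / 2) * 0.3 * sqrt(2 / 36) / 200,
               tolerance = 0.25)
})

test_that("fitEllipse validates its input", {
  ang <- seq(0, pi / 3, length.out = 12)      # only 60 degrees of azimuth
  expect_error(fitEllipse(data.frame(angle = ang, radius = 200)),
               "azimuth")
  expect_error(fitEllipse(data.frame(angle = c(0, 1), radius = c(1, 1))),
               "at least 8")
})

test_that("pixel size conversion follows P = r d / L and exposes the mis-assignment hazard", {
  expect_equal(pixelSizeFromRadius(512, 1024, 2.35), 1.175)
  expect_equal(pixelSizeFromRadius(2 * 512, 2 * 1024, 2.35),
               pixelSizeFromRadius(512, 1024, 2.35))
  # a 2.48 A ring read as 2.35 A biases P by 2.35/2.48: > 5% error
  L <- 1024; P <- 0.6484
  rTrue <- L * P / 2.48
  wrong <- pixelSizeFromRadius(rTrue, L, 2.35)
  err <- 100 * abs(wrong - P) / P
  expect_gt(err, 5)
  expect_equal(err, 100 * (1 - 2.35 / 2.48), tolerance = 1e-9)
})

test_that("calibrate recovers truth and sigma/sem accounting on a small dataset", {
  mics <- lapply(1:4, function(s) generateMicrograph(smallScene(s)))
  est <- calibrate(mics)
  expect_s4_class(est, "PixelSizeEstimate")
  expect_equal(est@n, 4L)
  expect_lt(abs(est@value - 0.6484) / 0.6484, 0.005)
  expect_equal(est@sem, est@sigma / sqrt(4))
  per <- perMicrograph(est)
  expect_equal(nrow(per), 4)
  expect_equal(mean(per$pixel_size), est@value)
  # subsampling the same population: sem follows sigma/sqrt(n)
  est2 <- calibrate(mics[1:2])
  expect_equal(est2@sem, est2@sigma / sqrt(2))
})

test_that("calibration aggregates in accumulated-spectrum mode too", {
  mics <- lapply(7:9, function(s) generateMicrograph(smallScene(s)))
  est <- calibrate(mics, mode = "accumulated")
  expect_equal(est@n, 1L)
  expect_lt(abs(est@value - 0.6484) / 0.6484, 0.005)
})

test_that("geometric-mean pixel size is invariant under a 90-degree rotation", {
  m <- generateMicrograph(smallScene(17, noise = "none"))
  rot <- new("Micrograph", pixels = t(m@pixels)[nrow(m@pixels):1, ],
             pixelSize = m@pixelSize, source = "rotated")
  e1 <- calibrate(m)
  e2 <- calibrate(rot)
  expect_equal(e2@value, e1@value, tolerance = 2e-4)
})

test_that("an anisotropic stretch is recovered in the axis values", {
  m <- generateMicrograph(smallScene(23, L = 1024, crystallites = 200,
                                     noise = "none", stretch = 1.017))
  est <- calibrate(m)
  expect_equal(est@anisotropyPercent, 1.7, tolerance = 0.1)
  expect_equal(perMicrograph(est)$pixel_size_major /
                 perMicrograph(est)$pixel_size_minor, 1.017,
               tolerance = 1e-3)
  # geometric-mean truth is preserved under the area-preserving stretch
  expect_lt(abs(est@value - 0.6484) / 0.6484, 0.002)
})

test_that("blank micrographs fail calibration with per-file reasons", {
  blank <- new("Micrograph", pixels = matrix(rnorm(256^2), 256, 256),
               pixelSize = 0.6484, source = "blank")
  expect_error(calibrate(blank), "calibration failed")
  expect_error(calibrate(blank), "blank")
})

test_that("end-to-end recovery stays within 0.5% (noisy) and 0.1% (noiseless)", {
  errFor <- function(seed, noise) {
    m <- generateMicrograph(smallScene(seed, noise = noise))
    abs(calibrate(m)@value - 0.6484) / 0.6484
  }
  noisy <- vapply(101:120, errFor, numeric(1), noise = "poisson")
  expect_lt(median(noisy), 0.005)
  quiet <- vapply(121:126, errFor, numeric(1), noise = "none")
  expect_lt(median(quiet), 0.001)
})
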