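test_that("power spectrum obeys the basic Fourier pairs and Parseval", {
  L <- 128
  # constant image: all power in the DC bin
  ps <- powerSpectrum(matrix(5, L, L) + 0)
  expect_equal(sum(spectrumValues(ps)), 0)  # mean-subtracted constant
  # cosine grating of period p: two symmetric maxima at radius L/p
  p <- 8
  img <- outer(rep(1, L), cos(2 * pi * (seq_len(L) - 1) / p))
  ps <- powerSpectrum(img)
  v <- spectrumValues(ps)
  ctr <- dcIndex(ps)
  top2 <- order(v, decreasing = TRUE)[1:2]
  rc <- cbind((top2 - 1) %% L + 1, (top2 - 1) %/% L + 1)
  radii <- sqrt((rc[, 1] - ctr[1])^2 + (rc[, 2] - ctr[2])^2)
  expect_equal(radii, rep(L / p, 2))
  # Parseval: sum of spectrum = L^2 * sum((x - mean)^2)
  set.seed(21)
  x <- matrix(rnorm(L * L), L, L)
  ps <- powerSpectrum(x)
  expect_equal(sum(spectrumValues(ps)), L^2 * sum((x - mean(x))^2),
               tolerance = 1e-10)
})

test_that("spectra are centro-symmetric about DC", {
  set.seed(22)
  ps <- powerSpectrum(matrix(rnorm(64 * 64), 64, 64))
  v <- spectrumValues(ps)
  # for even L the conjugate-symmetric partner of bin (i,j) is (2c-i, 2c-j)
  idx <- 2:64
  expect_equal(v[idx, idx], v[rev(idx), rev(idx)], tolerance = 1e-8)
})

test_that("accumulation averages spectra and tightens annulus scatter ~ 1/sqrt(k)", {
  set.seed(23)
  mk <- function() powerSpectrum(matrix(rnorm(96 * 96), 96, 96))
  s1 <- mk()
  expect_equal(spectrumValues(accumulateSpectra(list(s1, s1))),
               spectrumValues(s1))
  expect_equal(accumulateSpectra(list(s1, s1))@nAccumulated, 2L)
  ss <- replicate(4, mk(), simplify = FALSE)
  acc <- accumulateSpectra(ss)
  expect_equal(spectrumValues(acc),
               Reduce(`+`, lapply(ss, spectrumValues)) / 4,
               tolerance = 1e-12)
  relScatter <- function(k) {
    a <- accumulateSpectra(replicate(k, mk(), simplify = FALSE))
    pr <- radialProfile(a)
    sel <- pr@radii > 10 & pr@radii < 40
    sd(pr@intensity[sel]) / mean(pr@intensity[sel])
  }
  r1 <- relScatter(1); r4 <- relScatter(4); r16 <- relScatter(16)
  expect_lt(r4, r1)
  expect_lt(r16, r4)
  expect_equal(r1 / r16, 4, tolerance = 0.5)
  expect_error(accumulateSpectra(list(s1, powerSpectrum(matrix(0, 64, 64) +
    rnorm(64 * 64)))), "same width")
})

test_that("radial profile locates an isotropic ring and is linear", {
  L <- 256
  ring <- analyticSpectrum(L, function(r) exp(-(r - 70)^2 / 8))
  pr <- radialProfile(ring)
  expect_equal(pr@radii[which.max(pr@intensity)], 70, tolerance = 1)
  # linearity: profile of accumulate([s, s]) equals profile of s
  pr2 <- radialProfile(accumulateSpectra(list(ring, ring)))
  expect_equal(pr2@intensity, pr@intensity)
  # white noise is flat after whitening
  set.seed(24)
  wn <- powerSpectrum(matrix(rnorm(L * L), L, L))
  pw <- radialProfile(whiten(wn))
  sel <- pw@radii > 0.1 * L / 2 & pw@radii < 0.9 * L / 2
  expect_lt(sd(pw@intensity[sel]), 0.1)
})

test_that("whitening flattens a decaying background to ~1", {
  L <- 256
  bgOnly <- analyticSpectrum(L, function(r) 1e6 * exp(-r / 30))
  w <- whiten(bgOnly)
  pr <- radialProfile(w)
  sel <- pr@radii > 0.1 * L / 2 & pr@radii < 0.9 * L / 2
  expect_true(all(abs(pr@intensity[sel] - 1) < 0.05))
  # flat spectrum: whitening is the identity up to a constant factor
  flat <- analyticSpectrum(L, function(r) 7 + 0 * r)
  wf <- radialProfile(whiten(flat))
  expect_lt(diff(range(wf@intensity)), 1e-6)
})

test_that("whitening removes the inward bias of a weak peak on a decaying background", {
  L <- 512
  r0 <- 170
  raw <- analyticSpectrum(L, function(r)
    1e5 * exp(-r / 35) * (1 + 0.6 * exp(-(r - r0)^2 / 30)))
  prRaw <- radialProfile(raw)
  w <- whiten(raw, exclusionWindows = list(r0 * c(0.93, 1.07)))
  prW <- radialProfile(w)
  sel <- prRaw@radii > r0 - 20 & prRaw@radii < r0 + 20
  argRaw <- prRaw@radii[sel][which.max(prRaw@intensity[sel])]
  argW <- prW@radii[sel][which.max(prW@intensity[sel])]
  expect_lt(argRaw, argW)            # raw peak pulled toward the centre
  expect_equal(argW, r0, tolerance = 1.5)
})

test_that("whitening is invariant to intensity scaling and preserves strong peaks", {
  L <- 256
  sp <- analyticSpectrum(L, function(r)
    1e4 * exp(-r / 40) * (1 + 12 * exp(-(r - 80)^2 / 10)))
  w1 <- radialProfile(whiten(sp, list(c(72, 88))))
  sp2 <- sp; sp2@values <- sp2@values * 37.5
  w2 <- radialProfile(whiten(sp2, list(c(72, 88))))
  expect_equal(w1@intensity, w2@intensity, tolerance = 1e-9)
  pk1 <- findRingPeak(w1, expectedD = 2.35, pixelSize = 2.35 * 80 / L, L = L)
  rawPk <- ringProminence(radialProfile(sp), 2.35, 2.35 * 80 / L, L)
  expect_lt(abs(pk1@radius - rawPk$radius), 0.5)
})

test_that("whiten refuses exclusion windows covering most usable radii", {
  L <- 256
  sp <- analyticSpectrum(L, function(r) exp(-r / 50))
  expect_error(whiten(sp, exclusionWindows = list(c(0, 0.95 * L / 2))),
               "80%")
})

test_that("sub-pixel ring peak is found to 0.2 px and weak/flat profiles are rejected", {
  L <- 512
  radii <- seq(0.5, L / 2 - 0.5, by = 1)
  target <- 237.4
  prof <- analyticProfile(radii, 1 + 6 * exp(-(radii - target)^2 / 18))
  d <- 2.35
  P <- target * d / L                      # place expectation on the peak
  pk <- findRingPeak(prof, d, P, L)
  expect_equal(pk@radius, target, tolerance = 0.2)
  expect_gt(pk@height, 0)
  # flat profile: no-peak error
  expect_error(findRingPeak(analyticProfile(radii, rep(1, length(radii))),
                            d, P, L), "no ring peak")
  # peak outside the tolerance annulus: rejected, not silently used
  off <- analyticProfile(radii, 1 + 6 * exp(-(radii - 200)^2 / 18))
  expect_error(findRingPeak(off, d, P, L), "no ring peak")
})

test_that("with two gold rings the search annulus selects the outer fcc peak", {
  L <- 1024; P <- 0.6484
  radii <- seq(0.5, L / 2 - 0.5, by = 1)
  rFcc <- L * P / 2.35
  rHcp <- L * P / 2.48
  prof <- analyticProfile(radii,
    1 + 8 * exp(-(radii - rHcp)^2 / 12) + 5 * exp(-(radii - rFcc)^2 / 12))
  pk <- findRingPeak(prof, expectedD = 2.35, pixelSize = P, L = L,
                     toleranceFraction = 0.03)
  expect_equal(pk@radius, rFcc, tolerance = 0.3)
  # the hcp peak is the stronger one overall, as ringProminence reports
  pHcp <- ringProminence(prof, 2.48, P, L)
  pFcc <- ringProminence(prof, 2.35, P, L)
  expect_gt(pHcp$height, pFcc$height)
})

test_that("noiseless synthetic fringes give the theoretical ring radius within 0.3 px", {
  cfg <- smallScene(31, L = 512, noise = "none", backgroundAmplitude = 0)
  ps <- powerSpectrum(generateMicrograph(cfg))
  d <- dSpacingCubic(goldLatticeConstant(81), c(1, 1, 1))
  w <- whiten(ps, list(512 * 0.6484 / d * c(0.93, 1.07)))
  pk <- findRingPeak(radialProfile(w), d, 0.6484, 512)
  expect_equal(pk@radius, 512 * 0.6484 / d, tolerance = 0.3)
})
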