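test_that("electron wavelength matches the relativistic formula", {
  expect_equal(signif(electronWavelength(300), 3), 0.0197)
  expect_equal(signif(electronWavelength(100), 3), 0.0370)
  expect_lt(electronWavelength(300), electronWavelength(200))
})

test_that("chi and CTF agree with an independent oracle on a dense grid", {
  opt <- opticsParams(300, csMM = 2.7, defocusUM = -1.5, ampContrast = 0.04)
  q <- seq(0, 0.5, length.out = 1000)
  expect_equal(ctf(q, opt), oracleCTF(q, 300, 2.7, -1.5, 0.04),
               tolerance = 1e-12)
  expect_equal(chiPhase(0, opt), 0)
  expect_true(all(abs(ctf(q, opt)) <= 1 + 1e-12))
  expect_equal(ctf(0, opt), -0.04)
  # no aberrations: chi identically zero
  opt0 <- opticsParams(300, csMM = 0, defocusUM = 0)
  expect_equal(chiPhase(q, opt0), rep(0, 1000))
})

test_that("the first zero of sin(chi) matches a brute-force root find", {
  opt <- opticsParams(300, csMM = 2.7, defocusUM = -1.5)
  # oracle: dense scan of the independently coded phase for a sign change
  lam <- electronWavelength(300)
  chiOracle <- function(q)
    pi * lam * (-1.5e4) * q^2 + 0.5 * pi * lam^3 * 2.7e7 * q^4
  qs <- seq(1e-4, 0.2, by = 1e-6)
  s <- sin(chiOracle(qs))
  i <- which(diff(sign(s)) != 0)[1]
  qOracle <- uniroot(function(q) sin(chiOracle(q)), qs[c(i, i + 1)],
                     tol = 1e-12)$root
  qImpl <- uniroot(function(q) sin(chiPhase(q, opt)),
                   c(qs[i] - 1e-4, qs[i] + 1e-4), tol = 1e-12)$root
  expect_equal(qImpl, qOracle, tolerance = 1e-8)
})

test_that("defocus refit compensates a pixel-size error only at low frequency", {
  opt <- opticsParams(300, csMM = 2.7, defocusUM = -1.5)
  zero <- ctfErrorCurve(0, opt)
  expect_true(all(zero$error == 0))
  for (eps in c(0.01, 0.02, 0.05)) {
    raw <- ctfErrorCurve(eps, opt, refitDefocus = FALSE)
    ref <- ctfErrorCurve(eps, opt, refitDefocus = TRUE)
    expect_lte(attr(ref, "rms_error"), attr(raw, "rms_error"))
    # residual error grows with q: the upper quartile carries most of it
    n <- nrow(ref)
    lowQ <- sqrt(mean(ref$error[seq_len(n %/% 4)]^2))
    highQ <- sqrt(mean(ref$error[(3 * n %/% 4):n]^2))
    expect_gt(highQ, lowQ)
    # the refitted defocus moved away from the true value
    expect_false(isTRUE(all.equal(attr(ref, "refit_defocus_um"), -1.5)))
  }
})

test_that("Z40 <-> apparent Cs conversion round-trips and has the right sign", {
  lam <- electronWavelength(300)
  qMax <- 1 / (2 * 0.669)
  expect_equal(csApparentFromZ40(0, 2.7, lam, qMax = qMax), 2.7)
  for (dCs in c(0.01, 0.1, 0.5, -0.2)) {
    z40 <- z40FromDeltaCs(dCs, lam, qMax)
    expect_equal(csApparentFromZ40(z40, 2.7, lam, qMax = qMax) - 2.7, dCs,
                 tolerance = 1e-12)
  }
  expect_gt(csApparentFromZ40(0.5, 2.7, lam, qMax = qMax), 2.7)
})

test_that("apparent Cs corrects the pixel size by the quartic root", {
  expect_equal(pixelSizeFromCs(0.669, 2.7, 2.7), 0.669)
  ratio <- (0.669 / 0.6476)^4
  expect_equal(signif(ratio, 4), 1.139)
  expect_equal(pixelSizeFromCs(0.669, 2.7, 2.7 * ratio), 0.6476,
               tolerance = 1e-9)
  expect_lt(pixelSizeFromCs(0.669, 2.7, 3.2),
            pixelSizeFromCs(0.669, 2.7, 3.0))
  expect_error(pixelSizeFromCs(0.669, -1, 2.7), "positive")
})

test_that("an injected pixel-size error is recovered through the Z40 route to 1e-10", {
  lam <- electronWavelength(300)
  Pnom <- 0.669
  qMax <- 1 / (2 * Pnom)
  csTrue <- 2.7
  for (errFrac in c(0.01, 0.033, -0.02)) {
    Ptrue <- Pnom * (1 - errFrac)
    # the apparent Cs that aberration refinement would report
    csApp <- csTrue * (Pnom / Ptrue)^4
    z40 <- z40FromDeltaCs(csApp - csTrue, lam, qMax)
    zs <- new("ZernikeSet", coefficients = c(rep(0, 6), z40), z40 = z40,
              qMax = qMax)
    rec <- pixelSizeFromCs(Pnom, csTrue, csApparentFromZ40(zs, csTrue, lam))
    expect_equal(rec, Ptrue, tolerance = 1e-10)
  }
})

test_that("rlnEvenZernike STAR parsing extracts Z40 per optics group", {
  f <- starFixture(tempfile(fileext = ".star"), z40 = 0.5, pixel = 0.669)
  zs <- readZernikeStar(f)
  expect_length(zs, 1)
  expect_equal(zs[[1]]@z40, 0.5)
  expect_equal(zs[[1]]@qMax, 1 / (2 * 0.669))
  # multiple optics groups -> one ZernikeSet each
  f2 <- starFixture(tempfile(fileext = ".star"), z40 = 0.25, groups = 3)
  zs2 <- readZernikeStar(f2)
  expect_length(zs2, 3)
  expect_equal(vapply(zs2, function(z) z@z40, numeric(1)),
               0.25 * (1:3))
  expect_equal(vapply(zs2, function(z) z@group, character(1)),
               as.character(1:3))
  # explicit qMax override
  expect_equal(readZernikeStar(f, qMax = 0.5)[[1]]@qMax, 0.5)
})

test_that("STAR files without the Zernike field fail with the tables named", {
  f <- tempfile(fileext = ".star")
  writeLines(c("data_optics", "loop_", "_rlnOpticsGroup #1", "1"), f)
  expect_error(readZernikeStar(f), "rlnEvenZernike")
  expect_error(readZernikeStar(f), "optics")
})
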