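# Independent oracles and fixture builders used across the suite.

# d-spacing from explicitly constructed reciprocal basis vectors:
# B = 2*pi*t(solve(A)), d = 2*pi / |h b1 + k b2 + l b3|.
oracleDSpacing <- function(system, a, c = NA, hkl) {
  A <- switch(system,
    cubic = diag(c(a, a, a)),
    hexagonal = rbind(c(a, 0, 0),
                      c(-a / 2, a * sqrt(3) / 2, 0),
                      c(0, 0, c)))
  B <- 2 * pi * t(solve(A))
  g <- hkl[1] * B[1, ] + hkl[2] * B[2, ] + hkl[3] * B[3, ]
  2 * pi / sqrt(sum(g^2))
}

# direct evaluation of the standard CTF expression, written separately from
# the package implementation (all conversions inline)
oracleCTF <- function(q, kv, csMM, dzUM, W) {
  V <- kv * 1000
  lam <- (6.62607015e-34 /
    sqrt(2 * 9.1093837015e-31 * 1.602176634e-19 * V *
           (1 + 1.602176634e-19 * V /
              (2 * 9.1093837015e-31 * 299792458^2)))) * 1e10
  chi <- pi * lam * (dzUM * 1e4) * q^2 + 0.5 * pi * lam^3 * (csMM * 1e7) * q^4
  sqrt(1 - W^2) * sin(chi) - W * cos(chi)
}

# a DC-centred spectrum with a radially symmetric analytic form
analyticSpectrum <- function(L, fun) {
  ctr <- floor(L / 2) + 1
  r <- sqrt(outer((seq_len(L) - ctr)^2, (seq_len(L) - ctr)^2, `+`))
  new("PowerSpectrum2D", values = fun(r), L = as.integer(L),
      nAccumulated = 1L, whitened = FALSE)
}

# a radial profile object built from an analytic 1D curve
analyticProfile <- function(radii, intensity) {
  new("RadialProfile", radii = radii, intensity = intensity,
      counts = rep(100L, length(radii)))
}

# quick small-scene config for pipeline tests
smallScene <- function(seed, L = 512, noise = "poisson", stretch = 1,
                       crystallites = 80, P = 0.6484, ...) {
  syntheticSceneConfig(imageSize = L, truePixelSize = P,
                       nCrystallites = crystallites, noiseModel = noise,
                       stretch = stretch, seed = seed, ...)
}

starFixture <- function(path, z40 = 0.5, pixel = 0.669, groups = 1) {
  lines <- c(
    "data_optics", "", "loop_",
    "_rlnOpticsGroup #1",
    "_rlnImagePixelSize #2",
    "_rlnEvenZernike #3",
    vapply(seq_len(groups), function(g)
      sprintf("%d %.4f [0,0,0,0,0,0,%.8g,0,0]", g, pixel,
              z40 * g), character(1)),
    "")
  writeLines(lines, path)
  path
}
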