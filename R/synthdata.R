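#' Configuration for a synthetic polycrystalline-foil micrograph
#'
#' The generator emulates a motion-corrected image of a thin polycrystalline
#' metal foil: the frame is tessellated into crystallites (nearest-seed
#' regions from a seeded random point set), each crystallite carries a
#' cosine lattice fringe at one of the configured d-spacings with a random
#' in-plane orientation and phase, a smoothly varying background field with
#' a radially decaying power spectrum stands in for detector MTF and
#' low-angle scattering, and counting noise is added last. An optional
#' anisotropic stretch emulates anisotropic magnification; it is applied as
#' an exact, area-preserving affine of the scene coordinates (factors
#' sqrt(s) and 1/sqrt(s) along the stretch axes) so `truePixelSize` remains
#' the geometric-mean ground truth.
#'
#' @param imageSize image width L (pixels), square.
#' @param truePixelSize ground-truth magnified pixel size (Angstrom).
#' @param spacings data.frame with columns `d` (Angstrom) and `amplitude`
#'   (relative fringe amplitude); default the fcc gold (111) spacing at the
#'   81 K lattice constant.
#' @param nCrystallites number of crystallites tessellating the frame.
#' @param crystalliteScale optional typical crystallite diameter (pixels);
#'   when given it overrides `nCrystallites` via (L / scale)^2.
#' @param fringeContrast fringe amplitude relative to the mean intensity.
#' @param backgroundDecay decay length (Fourier pixels) of the background
#'   power envelope exp(-r / decay).
#' @param backgroundAmplitude background field standard deviation relative
#'   to the mean intensity.
#' @param noiseModel `"none"`, `"gaussian"` or `"poisson"` (default).
#' @param noiseParam Gaussian sigma (relative to mean) or Poisson mean
#'   counts per pixel (default 50, a typical integrated cryoEM exposure).
#' @param stretch anisotropic magnification stretch ratio (>= 1; 1 = none).
#' @param stretchAngle stretch axis angle (radians).
#' @param seed integer seed; fully determines the image.
#' @return a list of class `"SyntheticSceneConfig"`.
#' @export
syntheticSceneConfig <- function(imageSize = 1024,
                                 truePixelSize = 0.6484,
                                 spacings = data.frame(
                                   d = dSpacingCubic(goldLatticeConstant(81),
                                                     c(1, 1, 1)),
                                   amplitude = 1),
                                 nCrystallites = 200,
                                 crystalliteScale = NULL,
                                 fringeContrast = 0.1,
                                 backgroundDecay = 100,
                                 backgroundAmplitude = 0.15,
                                 noiseModel = c("poisson", "gaussian", "none"),
                                 noiseParam = 50,
                                 stretch = 1,
                                 stretchAngle = 0,
                                 seed = 1L) {
  noiseModel <- match.arg(noiseModel)
  stopifnot(imageSize >= 64, truePixelSize > 0, all(spacings$d > 0),
            stretch >= 1, nCrystallites >= 1)
  if (!is.null(crystalliteScale))
    nCrystallites <- max(1L, round((imageSize / crystalliteScale)^2))
  minPeriod <- min(spacings$d) / truePixelSize / sqrt(stretch)
  if (minPeriod < 2)
    stop("fringe period ", signif(minPeriod, 3), " px is below Nyquist; ",
         "aliasing simulation is a separate flag, not the default",
         call. = FALSE)
  structure(list(
    imageSize = as.integer(imageSize),
    truePixelSize = truePixelSize,
    spacings = spacings,
    nCrystallites = as.integer(nCrystallites),
    fringeContrast = fringeContrast,
    backgroundDecay = backgroundDecay,
    backgroundAmplitude = backgroundAmplitude,
    noiseModel = noiseModel,
    noiseParam = noiseParam,
    stretch = stretch,
    stretchAngle = stretchAngle,
    seed = as.integer(seed)
  ), class = "SyntheticSceneConfig")
}

#' Generate one synthetic polycrystalline micrograph
#'
#' See [syntheticSceneConfig()] for the scene model. The image is built on a
#' unit mean level: fringes are additive cosines (sufficient because the
#' calibration estimators consume only Bragg-peak positions), the
#' background field is coloured Gaussian noise with the configured spectral
#' envelope, and counting noise is applied per pixel.
#'
#' @param cfg a `SyntheticSceneConfig`.
#' @return a [Micrograph-class] whose `pixelSize` slot holds the TRUE pixel
#'   size (use [generateDataset()] to write files carrying a decoy nominal
#'   value).
#' @export
generateMicrograph <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticSceneConfig"))
  set.seed(cfg$seed)
  L <- cfg$imageSize
  ctr <- (L + 1) / 2

  # scene coordinates: inverse area-preserving stretch about the centre,
  # so the output image is the stretched view of an isotropic scene
  xg <- rep(seq_len(L) - ctr, times = L)
  yg <- rep(seq_len(L) - ctr, each = L)
  if (cfg$stretch > 1) {
    ca <- cos(cfg$stretchAngle); sa <- sin(cfg$stretchAngle)
    rs <- sqrt(cfg$stretch)
    u <- ca * xg + sa * yg
    v <- -sa * xg + ca * yg
    u <- u / rs          # stretched by rs on output -> divide to invert
    v <- v * rs
    xs <- ca * u - sa * v
    ys <- sa * u + ca * v
  } else {
    xs <- xg; ys <- yg
  }

  # nearest-seed tessellation into crystallites
  nc <- cfg$nCrystallites
  sx <- stats::runif(nc, -ctr, ctr)
  sy <- stats::runif(nc, -ctr, ctr)
  best <- rep(Inf, L * L)
  lab <- integer(L * L)
  for (i in seq_len(nc)) {
    d2 <- (xs - sx[i])^2 + (ys - sy[i])^2
    upd <- d2 < best
    best[upd] <- d2[upd]
    lab[upd] <- i
  }

  # per-crystallite fringe parameters
  sp <- cfg$spacings
  which_d <- sample.int(nrow(sp), nc, replace = TRUE,
                        prob = sp$amplitude / sum(sp$amplitude))
  freq <- cfg$truePixelSize / sp$d[which_d]        # cycles per scene pixel
  ori <- stats::runif(nc, 0, 2 * pi)
  phase <- stats::runif(nc, 0, 2 * pi)
  contrast <- rep(cfg$fringeContrast, nc)

  kx <- 2 * pi * freq * cos(ori)
  ky <- 2 * pi * freq * sin(ori)
  img <- 1 + contrast[lab] * cos(kx[lab] * xs + ky[lab] * ys + phase[lab])

  if (cfg$backgroundAmplitude > 0) {
    wn <- matrix(stats::rnorm(L * L), L, L)
    r <- radiusMap(L)
    env <- exp(-r / cfg$backgroundDecay)
    f <- stats::fft(wn) * fftshift2(sqrt(env))
    bgf <- Re(stats::fft(f, inverse = TRUE)) / (L * L)
    bgf <- bgf / stats::sd(bgf) * cfg$backgroundAmplitude
    img <- img + as.vector(bgf)
  }

  img <- matrix(img, L, L)
  img <- switch(cfg$noiseModel,
    none = img,
    gaussian = img + matrix(stats::rnorm(L * L, sd = cfg$noiseParam), L, L),
    poisson = {
      lam <- pmax(img, 0) * cfg$noiseParam
      matrix(stats::rpois(L * L, as.vector(lam)), L, L)
    })
  new("Micrograph", pixels = img, pixelSize = cfg$truePixelSize,
      source = sprintf("synthetic(seed=%d)", cfg$seed))
}

#' Generate a synthetic calibration dataset on disk
#'
#' Writes `n` seeded variants of the configured scene as MRC2014 files plus
#' a JSON ground-truth sidecar (`ground_truth.json`). The MRC headers carry
#' `nominalPixelSize` — by default a decoy value different from the truth —
#' so that calibration code is exercised exactly as on real data, where the
#' header value is only nominal; the truth lives solely in the sidecar.
#'
#' Sidecar schema: `{true_pixel_size, nominal_pixel_size, stretch,
#' stretch_angle, spacings: [{d, amplitude}], n_micrographs, master_seed,
#' files: [name, seed]}`.
#'
#' @param cfg a [syntheticSceneConfig()]; its `seed` acts as the master seed
#'   (file k uses seed `seed + k - 1`).
#' @param n number of micrographs.
#' @param outDir output directory (created if missing).
#' @param nominalPixelSize header pixel size (Angstrom); defaults to the
#'   truth (set a decoy, e.g. 0.669 vs truth 0.6484, to emulate a
#'   deliberately mis-set microscope nominal).
#' @return character vector of MRC paths, with the sidecar path as
#'   attribute `"sidecar"`.
#' @export
generateDataset <- function(cfg, n = 10, outDir,
                            nominalPixelSize = cfg$truePixelSize) {
  stopifnot(inherits(cfg, "SyntheticSceneConfig"), n >= 1)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(n)
  for (k in seq_len(n)) {
    ck <- cfg
    ck$seed <- cfg$seed + k - 1L
    m <- generateMicrograph(ck)
    paths[k] <- file.path(outDir, sprintf("synthetic_%03d.mrc", k))
    writeMRC(m@pixels, paths[k], pixelSize = nominalPixelSize, mode = 2L)
  }
  sidecar <- file.path(outDir, "ground_truth.json")
  jsonlite::write_json(list(
    true_pixel_size = cfg$truePixelSize,
    nominal_pixel_size = nominalPixelSize,
    stretch = cfg$stretch,
    stretch_angle = cfg$stretchAngle,
    spacings = cfg$spacings,
    n_micrographs = n,
    master_seed = cfg$seed,
    files = data.frame(name = basename(paths),
                       seed = cfg$seed + seq_len(n) - 1L)
  ), sidecar, auto_unbox = TRUE, digits = NA)
  attr(paths, "sidecar") <- sidecar
  paths
}
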