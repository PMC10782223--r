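#' Power spectrum of a micrograph
#'
#' Squared modulus of the 2D discrete Fourier transform of the
#' mean-subtracted image, shifted so DC sits at the centre bin
#' (index L/2 + 1 for even L). Apodization (a Hann edge taper) is off by
#' default because windowing broadens Bragg peaks; it is available for
#' diagnostics on images with strong edge discontinuities.
#'
#' @param m a [Micrograph-class] or numeric matrix.
#' @param padTo optional width to zero-pad to (>= image width); padding
#'   refines the ring-radius sampling without changing peak positions in
#'   fractional-Nyquist terms.
#' @param apodize logical; apply a Hann edge taper before transforming.
#' @return a [PowerSpectrum2D-class].
#' @export
powerSpectrum <- function(m, padTo = NULL, apodize = FALSE) {
  px <- if (is(m, "Micrograph")) m@pixels else m
  stopifnot(is.matrix(px), nrow(px) == ncol(px))
  L0 <- nrow(px)
  x <- px - mean(px)
  if (apodize) {
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L0) - 1) / (L0 - 1))
    x <- x * outer(w, w)
  }
  L <- if (is.null(padTo)) L0 else as.integer(padTo)
  if (L < L0) stop("padTo must be >= image width", call. = FALSE)
  if (L > L0) {
    xp <- matrix(0, L, L)
    xp[seq_len(L0), seq_len(L0)] <- x
    x <- xp
  }
  f <- stats::fft(x)
  ps <- fftshift2(Mod(f)^2)
  new("PowerSpectrum2D", values = ps, L = L, nAccumulated = 1L,
      whitened = FALSE)
}

# swap quadrants so DC moves from [1,1] to [L/2+1, L/2+1]
fftshift2 <- function(m) {
  L1 <- nrow(m); L2 <- ncol(m)
  s1 <- c(seq(floor(L1 / 2) + 1, L1), seq_len(floor(L1 / 2)))
  s2 <- c(seq(floor(L2 / 2) + 1, L2), seq_len(floor(L2 / 2)))
  m[s1, s2, drop = FALSE]
}

#' Centre (DC) index of a spectrum
#' @param ps a [PowerSpectrum2D-class].
#' @return numeric length-2 (row, col) 1-based index of the DC bin.
#' @export
dcIndex <- function(ps) {
  rep(floor(ps@L / 2) + 1, 2)
}

#' Average several power spectra
#'
#' Element-wise mean of spectra of equal width; `nAccumulated` adds up.
#' Accumulating n independent-noise spectra reduces the annulus-wise
#' relative scatter by about 1/sqrt(n).
#'
#' @param spectra list of [PowerSpectrum2D-class] objects of equal L.
#' @return a [PowerSpectrum2D-class].
#' @export
accumulateSpectra <- function(spectra) {
  stopifnot(length(spectra) >= 1L)
  Ls <- vapply(spectra, function(s) s@L, integer(1))
  if (length(unique(Ls)) != 1L)
    stop("all spectra must have the same width L", call. = FALSE)
  vals <- Reduce(`+`, lapply(spectra, function(s) s@values)) / length(spectra)
  n <- sum(vapply(spectra, function(s) s@nAccumulated, integer(1)))
  new("PowerSpectrum2D", values = vals, L = Ls[1], nAccumulated = n,
      whitened = spectra[[1]]@whitened)
}

# radius of every Fourier pixel from the DC bin centre (matrix)
radiusMap <- function(L, center = NULL) {
  if (is.null(center)) center <- rep(floor(L / 2) + 1, 2)
  dx <- seq_len(L) - center[1]
  dy <- seq_len(L) - center[2]
  sqrt(outer(dx^2, dy^2, `+`))
}

#' Radial profile of a power spectrum
#'
#' Mean intensity in unit-width annuli about a centre (the DC bin by
#' default). Bin i covers radii [i-1, i); the reported bin centre is i-0.5.
#'
#' @param ps a [PowerSpectrum2D-class].
#' @param center optional sub-pixel (row, col) centre; defaults to DC.
#' @return a [RadialProfile-class].
#' @export
radialProfile <- function(ps, center = NULL) {
  stopifnot(is(ps, "PowerSpectrum2D"))
  r <- radiusMap(ps@L, center)
  idx <- floor(r) + 1L
  rmax <- floor(ps@L / 2)
  keep <- idx <= rmax
  sums <- tapply(ps@values[keep], idx[keep], sum)
  cnts <- tabulate(idx[keep], nbins = rmax)
  bins <- as.integer(names(sums))
  nonzero <- cnts[bins] > 0L
  bins <- bins[nonzero]
  new("RadialProfile",
      radii = bins - 0.5,
      intensity = as.numeric(sums[nonzero]) / cnts[bins],
      counts = cnts[bins])
}

#' Whiten a power spectrum against a smooth radial background
#'
#' Divides the spectrum by a smooth, radially symmetric background model so
#' the noise floor fluctuates about 1. Without whitening, a weak Bragg peak
#' sitting on a decaying background has its apparent maximum pulled toward
#' the centre; whitening removes that bias. The background is a low-order
#' polynomial fitted to log intensity versus radius, with annuli inside
#' `exclusionWindows` (known Bragg rings) excluded from the fit, then
#' exponentiated.
#'
#' @param ps a [PowerSpectrum2D-class].
#' @param exclusionWindows list of numeric (r_lo, r_hi) pairs, in pixels,
#'   excluded from the background fit.
#' @param degree polynomial degree of the log-background fit (default 5).
#' @param rRange usable radius range as a fraction of Nyquist; annuli outside
#'   are left out of the fit (defaults to 2 px to 97.5% of L/2).
#' @return a whitened [PowerSpectrum2D-class].
#' @export
whiten <- function(ps, exclusionWindows = list(), degree = 5,
                   rRange = NULL) {
  stopifnot(is(ps, "PowerSpectrum2D"))
  prof <- radialProfile(ps)
  rmax <- floor(ps@L / 2)
  if (is.null(rRange)) rRange <- c(2, 0.975 * rmax)
  use <- prof@radii >= rRange[1] & prof@radii <= rRange[2] &
    prof@intensity > 0
  usable <- sum(use)
  for (w in exclusionWindows)
    use <- use & !(prof@radii >= w[1] & prof@radii <= w[2])
  if (usable > 0 && sum(use) < 0.2 * usable)
    stop("exclusion windows cover more than 80% of usable radii",
         call. = FALSE)
  if (sum(use) <= degree + 1)
    stop("too few annuli to fit the background model", call. = FALSE)
  df <- data.frame(r = prof@radii[use], ly = log(prof@intensity[use]))
  fit <- stats::lm(ly ~ stats::poly(r, degree), data = df)
  bg1d <- exp(stats::predict(fit, newdata = data.frame(r = prof@radii)))
  r <- radiusMap(ps@L)
  bg <- stats::approx(prof@radii, bg1d, xout = pmin(pmax(r, min(prof@radii)),
                                                    max(prof@radii)),
                      rule = 2)$y
  bg <- matrix(bg, ps@L, ps@L)
  new("PowerSpectrum2D", values = ps@values / bg, L = ps@L,
      nAccumulated = ps@nAccumulated, whitened = TRUE,
      background = list(radii = prof@radii, value = bg1d))
}

# Peak measurement against flanking-band statistics: the candidate peak is
# the interpolated maximum inside `win`; baseline and scatter come from the
# bands just outside the window (half a window-width on each side), where
# the whitened background is flat. Returns NULL when the window has too few
# bins or the maximum sits on the window edge.
peakWithFlanks <- function(radii, intensity, win) {
  inWin <- radii >= win[1] & radii <= win[2]
  if (sum(inWin) < 3) return(NULL)
  half <- (win[2] - win[1]) / 2
  flank <- (radii >= win[1] - half & radii < win[1]) |
    (radii > win[2] & radii <= win[2] + half)
  pk <- interiorMaxPeak(radii[inWin], intensity[inWin])
  if (is.null(pk)) return(NULL)
  ref <- if (sum(flank) >= 3) intensity[flank] else intensity[inWin]
  base <- stats::median(ref)
  scat <- stats::mad(ref)
  if (!is.finite(scat) || scat <= 0) scat <- stats::sd(ref)
  height <- pk$height - base
  snr <- if (is.finite(scat) && scat > 0) height / scat else 0
  list(radius = pk$radius, height = height, snr = snr)
}

# Most prominent interior local maximum, parabolic-interpolated. Using a
# local maximum rather than the window argmax keeps the shoulder of a
# neighbouring ring leaking over the window edge from masquerading as the
# peak. Ties resolve to the larger radius (outer ring).
interiorMaxPeak <- function(radii, intensity) {
  n <- length(intensity)
  i <- 2:(n - 1)
  isMax <- intensity[i] >= intensity[i - 1] & intensity[i] >= intensity[i + 1] &
    (intensity[i] > intensity[i - 1] | intensity[i] > intensity[i + 1])
  cand <- i[isMax]
  if (length(cand) == 0L) return(NULL)
  best <- cand[intensity[cand] == max(intensity[cand])]
  b <- max(best)                               # tie-break: outer ring
  y0 <- intensity[b - 1]; y1 <- intensity[b]; y2 <- intensity[b + 1]
  denom <- y0 - 2 * y1 + y2
  delta <- if (abs(denom) < .Machine$double.eps) 0 else
    0.5 * (y0 - y2) / denom
  delta <- max(-0.5, min(0.5, delta))
  step <- radii[min(b + 1, n)] - radii[b]
  list(radius = radii[b] + delta * step,
       height = y1 - 0.25 * (y0 - y2) * delta,
       index = b)
}

# 3-point parabolic sub-pixel interpolation around a discrete argmax.
# Ties on equal maxima resolve to the larger radius (outer ring).
parabolicPeak <- function(radii, intensity) {
  i <- length(intensity) + 1L - which.max(rev(intensity))
  if (i == 1L || i == length(intensity))
    return(list(radius = radii[i], height = intensity[i], index = i))
  y0 <- intensity[i - 1]; y1 <- intensity[i]; y2 <- intensity[i + 1]
  denom <- y0 - 2 * y1 + y2
  delta <- if (abs(denom) < .Machine$double.eps) 0 else
    0.5 * (y0 - y2) / denom
  delta <- max(-0.5, min(0.5, delta))
  step <- radii[i + 1] - radii[i]
  list(radius = radii[i] + delta * step,
       height = y1 - 0.25 * (y0 - y2) * delta,
       index = i)
}

#' Find a diffraction-ring peak in a whitened radial profile
#'
#' Searches the annulus r_expected (1 +/- toleranceFraction), where
#' r_expected = L * pixelSize / d, for the strongest profile maximum, and
#' refines it to sub-pixel precision by 3-point parabolic interpolation.
#' The peak must stand out from the local whitened background by at least
#' `minProminence` robust standard deviations, otherwise a no-peak error is
#' raised so the micrograph is rejected rather than silently mis-measured.
#'
#' @param profile a [RadialProfile-class] (of a whitened spectrum).
#' @param expectedD expected interplanar spacing d (Angstrom).
#' @param pixelSize nominal magnified pixel size (Angstrom).
#' @param L full width of the Fourier transform (pixels).
#' @param toleranceFraction half-width of the search annulus as a fraction of
#'   the expected radius (default 0.05: wide enough for a 2% magnification
#'   error, narrow enough to exclude the hcp gold ring when targeting the
#'   fcc ring 5.5% away).
#' @param minProminence minimum peak height over the annulus baseline in
#'   units of the flanking-annulus robust scatter (default 5).
#' @return a [RingPeak-class].
#' @export
findRingPeak <- function(profile, expectedD, pixelSize, L,
                         toleranceFraction = 0.05, minProminence = 5) {
  stopifnot(is(profile, "RadialProfile"))
  rExp <- L * pixelSize / expectedD
  win <- rExp * c(1 - toleranceFraction, 1 + toleranceFraction)
  if (win[1] <= 0 || win[2] >= L / 2)
    stop("search annulus for d = ", signif(expectedD, 4),
         " A falls outside the spectrum", call. = FALSE)
  pk <- peakWithFlanks(profile@radii, profile@intensity, win)
  if (is.null(pk))
    stop("no ring peak: search annulus near r = ", round(rExp, 1),
         " px has no interior maximum", call. = FALSE)
  if (pk$snr < minProminence || pk$height <= 0)
    stop("no ring peak above prominence threshold near r = ",
         round(rExp, 1), " px", call. = FALSE)
  new("RingPeak", radius = pk$radius, height = pk$height, window = win)
}

#' Peak prominence near an expected ring, without rejection
#'
#' Helper used for reflection assignment: measures (peak - baseline) /
#' scatter inside the search annulus, returning 0 when no interior maximum
#' exists. Unlike [findRingPeak()] this never throws.
#'
#' @inheritParams findRingPeak
#' @return list with `radius`, `height` (peak over flanking baseline) and
#'   `snr` (height over flanking scatter).
#' @export
ringProminence <- function(profile, expectedD, pixelSize, L,
                           toleranceFraction = 0.05) {
  rExp <- L * pixelSize / expectedD
  win <- rExp * c(1 - toleranceFraction, 1 + toleranceFraction)
  if (win[2] >= L / 2) return(list(radius = NA_real_, height = 0, snr = 0))
  pk <- peakWithFlanks(profile@radii, profile@intensity, win)
  if (is.null(pk)) return(list(radius = NA_real_, height = 0, snr = 0))
  list(radius = pk$radius, height = pk$height, snr = pk$snr)
}
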