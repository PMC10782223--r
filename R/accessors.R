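# Accessors and show methods for the S4 containers.

#' @describeIn Micrograph-class pixel matrix accessor
#' @param x object.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @export
setMethod("pixels", "Micrograph", function(x) x@pixels)

#' @describeIn Micrograph-class nominal pixel size accessor (Angstrom)
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @export
setMethod("pixelSize", "Micrograph", function(x) x@pixelSize)
#' @export
setMethod("pixelSize", "PixelSizeEstimate", function(x) x@value)

#' @describeIn PowerSpectrum2D-class spectrum value matrix
#' @param x object.
#' @export
setGeneric("spectrumValues", function(x) standardGeneric("spectrumValues"))
#' @export
setMethod("spectrumValues", "PowerSpectrum2D", function(x) x@values)

#' @describeIn Reflection-class interplanar spacing accessor (Angstrom)
#' @param x object.
#' @export
setGeneric("dSpacing", function(x) standardGeneric("dSpacing"))
#' @export
setMethod("dSpacing", "Reflection", function(x) x@d)

#' @describeIn EllipseFit-class semi-axes accessor, c(major, minor)
#' @param x object.
#' @export
setGeneric("semiAxes", function(x) standardGeneric("semiAxes"))
#' @export
setMethod("semiAxes", "EllipseFit", function(x)
  c(major = x@semiMajor, minor = x@semiMinor))

#' @describeIn PixelSizeEstimate-class per-micrograph result table
#' @param x object.
#' @export
setGeneric("perMicrograph", function(x) standardGeneric("perMicrograph"))
#' @export
setMethod("perMicrograph", "PixelSizeEstimate", function(x) x@perMicrograph)

setMethod("show", "Micrograph", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("Micrograph %dx%d px, nominal pixel size %.4f A\n  source: %s\n",
              d[1], d[2], object@pixelSize, object@source))
})

setMethod("show", "PowerSpectrum2D", function(object) {
  cat(sprintf("PowerSpectrum2D %dx%d (DC-centred)%s, %d micrograph(s)\n",
              object@L, object@L,
              if (object@whitened) ", whitened" else "",
              object@nAccumulated))
})

setMethod("show", "LatticeSpec", function(object) {
  cat(sprintf("LatticeSpec '%s' (%s): a = %.4f A", object@material,
              object@system, object@a))
  if (is.finite(object@c)) cat(sprintf(", c = %.4f A", object@c))
  cat(if (is.null(object@thermal)) "\n" else " (thermal model attached)\n")
})

setMethod("show", "Reflection", function(object) {
  cat(sprintf("Reflection (%d %d %d) of %s: d = %.4f A\n",
              object@hkl[1], object@hkl[2], object@hkl[3],
              object@material, object@d))
})

setMethod("show", "RingPeak", function(object) {
  cat(sprintf("RingPeak at r = %.2f px (height %.3g) in [%.1f, %.1f]\n",
              object@radius, object@height,
              object@window[1], object@window[2]))
})

setMethod("show", "EllipseFit", function(object) {
  cat(sprintf(
    "EllipseFit: semi-axes %.3f / %.3f px (anisotropy %.3f%%), angle %.1f deg\n  %d wedges, residual RMS %.3f px\n",
    object@semiMajor, object@semiMinor, anisotropyPercent(object),
    object@angle * 180 / pi, object@nWedgesUsed, object@residualRMS))
})

setMethod("show", "PixelSizeEstimate", function(object) {
  cat(sprintf("PixelSizeEstimate: %.4f A (n = %d)\n", object@value, object@n))
  if (is.finite(object@sigma))
    cat(sprintf("  sigma = %.4f A, sem = %.4f A\n", object@sigma, object@sem))
  cat(sprintf("  axes: %.4f / %.4f A, anisotropy %.2f%%\n",
              object@valueMajor, object@valueMinor, object@anisotropyPercent))
  if (any(object@perMicrograph$mixed_lattice_flag))
    cat("  WARNING: mixed-lattice flag raised on ",
        sum(object@perMicrograph$mixed_lattice_flag), " micrograph(s)\n")
})

setMethod("show", "OpticsParams", function(object) {
  cat(sprintf(
    "OpticsParams: %g kV (lambda %.5f A), Cs %.2f mm, defocus %.2f um, W %.3f\n",
    object@voltageKV, object@wavelength, object@csMM, object@defocusUM,
    object@ampContrast))
})

setMethod("show", "ZernikeSet", function(object) {
  cat(sprintf("ZernikeSet group %s: %d even coefficients, Z40 = %.4g, qMax = %.4f 1/A\n",
              object@group, length(object@coefficients), object@z40,
              object@qMax))
})

#' Plot a radial profile
#'
#' @param x a [RadialProfile-class].
#' @param y ignored.
#' @param log plot log intensity (default TRUE).
#' @param ... passed to [graphics::plot()].
#' @export
setMethod("plot", signature(x = "RadialProfile", y = "missing"),
  function(x, y, log = TRUE, ...) {
    graphics::plot(x@radii, if (log) log10(x@intensity) else x@intensity,
                   type = "l", xlab = "radius (px)",
                   ylab = if (log) "log10 mean power" else "mean power", ...)
  })
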