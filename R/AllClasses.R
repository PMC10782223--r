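#' @import methods
NULL

#' Thermal expansion model for a lattice constant
#'
#' Linear model \eqn{a(T) = a_0 + s\,T} with a hard low-temperature clamp:
#' below `clampTemperature` the lattice constant is held at `clampValue`
#' (thermal contraction levels off near absolute zero, so the linear law
#' over-contracts there).
#'
#' @slot a0 intercept of the linear law (Angstrom).
#' @slot slope expansion slope (Angstrom per Kelvin).
#' @slot clampTemperature temperature (K) below which the constant is clamped.
#' @slot clampValue lattice constant (Angstrom) used below the clamp.
#' @exportClass ThermalModel
setClass("ThermalModel",
  representation(
    a0 = "numeric",
    slope = "numeric",
    clampTemperature = "numeric",
    clampValue = "numeric"
  )
)

setValidity("ThermalModel", function(object) {
  if (length(object@a0) != 1L || object@a0 <= 0) return("a0 must be a positive scalar")
  if (length(object@slope) != 1L) return("slope must be a scalar")
  if (length(object@clampTemperature) != 1L || object@clampTemperature < 0)
    return("clampTemperature must be a non-negative scalar")
  if (length(object@clampValue) != 1L || object@clampValue <= 0)
    return("clampValue must be a positive scalar")
  TRUE
})

#' Crystalline calibration material
#'
#' Describes a calibration lattice: crystal system, lattice constants and an
#' optional thermal model. Hexagonal materials carry both `a` and `c`; cubic
#' ones only `a` (slot `c` is `NA`).
#'
#' @slot material character id, e.g. `"gold_fcc"`.
#' @slot system `"cubic"` or `"hexagonal"`.
#' @slot a lattice constant a (Angstrom).
#' @slot c lattice constant c (Angstrom, hexagonal only; `NA` for cubic).
#' @slot thermal a [ThermalModel-class] or `NULL`.
#' @exportClass LatticeSpec
setClass("LatticeSpec",
  representation(
    material = "character",
    system = "character",
    a = "numeric",
    c = "numeric",
    thermal = "ANY"
  ),
  prototype(c = NA_real_, thermal = NULL)
)

setValidity("LatticeSpec", function(object) {
  if (!object@system %in% c("cubic", "hexagonal"))
    return("system must be 'cubic' or 'hexagonal'")
  if (length(object@a) != 1L || !is.finite(object@a) || object@a <= 0)
    return("lattice constant a must be a positive scalar")
  if (object@system == "hexagonal" &&
      (length(object@c) != 1L || !is.finite(object@c) || object@c <= 0))
    return("hexagonal system requires a positive lattice constant c")
  if (!is.null(object@thermal) && !is(object@thermal, "ThermalModel"))
    return("thermal must be NULL or a ThermalModel")
  TRUE
})

#' A single Bragg reflection
#'
#' @slot hkl integer Miller indices, length 3.
#' @slot d interplanar spacing (Angstrom).
#' @slot material character id of the parent lattice.
#' @exportClass Reflection
setClass("Reflection",
  representation(hkl = "integer", d = "numeric", material = "character")
)

setValidity("Reflection", function(object) {
  if (length(object@hkl) != 3L) return("hkl must have length 3")
  if (all(object@hkl == 0L)) return("hkl must not be (0,0,0)")
  if (length(object@d) != 1L || !is.finite(object@d) || object@d <= 0)
    return("d must be a positive scalar")
  TRUE
})

#' A single real-valued micrograph
#'
#' @slot pixels numeric matrix of pixel values.
#' @slot pixelSize nominal magnified pixel size (Angstrom).
#' @slot source path or label identifying the image origin.
#' @exportClass Micrograph
setClass("Micrograph",
  representation(pixels = "matrix", pixelSize = "numeric", source = "character")
)

setValidity("Micrograph", function(object) {
  d <- dim(object@pixels)
  if (any(d < 64L)) return("micrograph must be at least 64x64 pixels")
  if (!all(is.finite(object@pixels))) return("pixel values must be finite")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("pixelSize must be a positive scalar (Angstrom)")
  TRUE
})

#' Accumulated 2D power spectrum
#'
#' DC-centred squared-modulus Fourier transform of one or more micrographs.
#' For even width L the DC component sits at index (L/2 + 1, L/2 + 1)
#' (1-based); radii are measured from that bin centre.
#'
#' @slot values non-negative L x L matrix, DC-centred.
#' @slot L full width of the transform in pixels.
#' @slot nAccumulated number of micrographs averaged into this spectrum.
#' @slot whitened logical; has the spectrum been divided by a background model.
#' @slot background for a whitened spectrum, the fitted radial background
#'   model (list with `radii`, `value`) that was divided out; `NULL` otherwise.
#' @exportClass PowerSpectrum2D
setClass("PowerSpectrum2D",
  representation(
    values = "matrix",
    L = "integer",
    nAccumulated = "integer",
    whitened = "logical",
    background = "ANY"
  ),
  prototype(nAccumulated = 1L, whitened = FALSE, background = NULL)
)

setValidity("PowerSpectrum2D", function(object) {
  d <- dim(object@values)
  if (d[1] != d[2]) return("power spectrum must be square")
  if (d[1] != object@L) return("L must equal the matrix width")
  if (any(object@values < 0)) return("power values must be non-negative")
  if (object@nAccumulated < 1L) return("nAccumulated must be >= 1")
  TRUE
})

#' Radial (azimuthally averaged) profile of a power spectrum
#'
#' @slot radii annulus bin centres (pixels), strictly increasing.
#' @slot intensity mean power per annulus.
#' @slot counts number of Fourier pixels per annulus.
#' @exportClass RadialProfile
setClass("RadialProfile",
  representation(radii = "numeric", intensity = "numeric", counts = "integer")
)

setValidity("RadialProfile", function(object) {
  n <- length(object@radii)
  if (length(object@intensity) != n || length(object@counts) != n)
    return("radii, intensity and counts must have equal length")
  if (n > 1 && any(diff(object@radii) <= 0))
    return("radii must be strictly increasing")
  if (any(object@counts <= 0L)) return("counts must be positive")
  TRUE
})

#' A detected diffraction-ring peak
#'
#' @slot radius sub-pixel peak radius (pixels).
#' @slot height peak prominence over the whitened background.
#' @slot window numeric length-2 search annulus (r_lo, r_hi) in pixels.
#' @exportClass RingPeak
setClass("RingPeak",
  representation(radius = "numeric", height = "numeric", window = "numeric")
)

setValidity("RingPeak", function(object) {
  if (length(object@window) != 2L || object@window[1] >= object@window[2])
    return("window must be (r_lo, r_hi) with r_lo < r_hi")
  if (object@radius <= object@window[1] || object@radius >= object@window[2])
    return("radius must lie strictly inside the search window")
  if (object@height <= 0) return("accepted peak must have positive height")
  TRUE
})

#' Centred ellipse fitted to azimuthal ring-peak positions
#'
#' @slot center sub-pixel (x, y) centre in spectrum coordinates.
#' @slot semiMajor semi-major axis (pixels).
#' @slot semiMinor semi-minor axis (pixels).
#' @slot angle major-axis orientation, radians in (-pi/2, pi/2].
#' @slot nWedgesUsed number of azimuthal wedges contributing peaks.
#' @slot residualRMS root-mean-square radial residual (pixels).
#' @exportClass EllipseFit
setClass("EllipseFit",
  representation(
    center = "numeric",
    semiMajor = "numeric",
    semiMinor = "numeric",
    angle = "numeric",
    nWedgesUsed = "integer",
    residualRMS = "numeric"
  )
)

setValidity("EllipseFit", function(object) {
  if (object@semiMinor <= 0) return("semiMinor must be positive")
  if (object@semiMajor < object@semiMinor)
    return("semiMajor must be >= semiMinor")
  if (object@angle <= -pi / 2 || object@angle > pi / 2)
    return("angle must lie in (-pi/2, pi/2]")
  TRUE
})

#' Calibrated magnified pixel size with uncertainty
#'
#' The scalar `value` is the geometric mean of the two elliptical axis values,
#' so it preserves area scaling under anisotropic magnification. A larger ring
#' radius along an axis corresponds to a larger pixel size along that axis
#' (P = r d / L at fixed d).
#'
#' @slot value geometric-mean magnified pixel size (Angstrom).
#' @slot valueMajor pixel size along the ellipse major (radius) axis.
#' @slot valueMinor pixel size along the ellipse minor (radius) axis.
#' @slot anisotropyPercent 100 (major - minor) / mean of the axis radii.
#' @slot perMicrograph data.frame of per-image results.
#' @slot sigma standard deviation of the per-micrograph values (Angstrom).
#' @slot sem standard error of the mean, sigma / sqrt(n).
#' @slot n number of micrographs used.
#' @exportClass PixelSizeEstimate
setClass("PixelSizeEstimate",
  representation(
    value = "numeric",
    valueMajor = "numeric",
    valueMinor = "numeric",
    anisotropyPercent = "numeric",
    perMicrograph = "data.frame",
    sigma = "numeric",
    sem = "numeric",
    n = "integer"
  )
)

setValidity("PixelSizeEstimate", function(object) {
  if (object@value <= 0) return("value must be positive")
  if (object@n >= 1L && is.finite(object@sigma) && is.finite(object@sem)) {
    if (abs(object@sem - object@sigma / sqrt(object@n)) >
        1e-9 * max(1, object@sigma))
      return("sem must equal sigma / sqrt(n)")
  }
  TRUE
})

#' Microscope optical parameters for CTF evaluation
#'
#' User-facing units follow microscopy convention: accelerating voltage in kV,
#' spherical aberration Cs in mm, defocus in micrometres (underfocus
#' negative), wavelength in Angstrom. All internal computation converts to
#' Angstrom.
#'
#' @slot voltageKV accelerating voltage (kV).
#' @slot wavelength relativistic electron wavelength (Angstrom), derived.
#' @slot csMM spherical aberration coefficient (mm).
#' @slot defocusUM defocus (micrometres, underfocus negative).
#' @slot ampContrast amplitude contrast fraction W, in (0, 1).
#' @exportClass OpticsParams
setClass("OpticsParams",
  representation(
    voltageKV = "numeric",
    wavelength = "numeric",
    csMM = "numeric",
    defocusUM = "numeric",
    ampContrast = "numeric"
  )
)

setValidity("OpticsParams", function(object) {
  if (object@voltageKV <= 0) return("voltage must be positive")
  if (object@ampContrast <= 0 || object@ampContrast >= 1)
    return("amplitude contrast must lie in (0, 1)")
  lam <- electronWavelength(object@voltageKV)
  if (abs(object@wavelength - lam) > 1e-9 * lam)
    return("wavelength inconsistent with voltage")
  TRUE
})

#' Even Zernike coefficients from aberration refinement
#'
#' The 7th entry of the even-coefficient list is the Z40 (primary spherical)
#' term used to back out an apparent-Cs shift; `qMax` is the spatial-frequency
#' normalisation radius of the polynomial basis (1/Angstrom).
#'
#' @slot coefficients ordered even-Zernike coefficient list.
#' @slot z40 the 7th coefficient.
#' @slot qMax normalisation spatial frequency (1/Angstrom).
#' @slot group optics-group label.
#' @exportClass ZernikeSet
setClass("ZernikeSet",
  representation(
    coefficients = "numeric",
    z40 = "numeric",
    qMax = "numeric",
    group = "character"
  ),
  prototype(group = NA_character_)
)

setValidity("ZernikeSet", function(object) {
  if (length(object@coefficients) < 7L)
    return("need at least 7 even Zernike coefficients to read Z40")
  if (!isTRUE(all.equal(object@z40, object@coefficients[7L])))
    return("z40 must be the 7th coefficient")
  if (object@qMax <= 0) return("qMax must be positive")
  TRUE
})
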