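# Unit policy: user-facing kV / mm / um / Angstrom; everything internal in
# Angstrom and radians. 1 mm = 1e7 A, 1 um = 1e4 A.
MM_TO_A <- 1e7
UM_TO_A <- 1e4

#' Relativistic electron wavelength
#'
#' lambda = h / sqrt(2 m0 e V (1 + e V / (2 m0 c^2))), in Angstrom.
#'
#' @param voltageKV accelerating voltage (kV), positive. Vectorised.
#' @return wavelength (Angstrom); about 0.0197 A at 300 kV.
#' @export
electronWavelength <- function(voltageKV) {
  if (any(voltageKV <= 0)) stop("voltage must be positive", call. = FALSE)
  V <- voltageKV * 1e3
  h <- 6.62607015e-34
  m0 <- 9.1093837015e-31
  e <- 1.602176634e-19
  c <- 299792458
  lambda_m <- h / sqrt(2 * m0 * e * V * (1 + e * V / (2 * m0 * c^2)))
  lambda_m * 1e10
}

#' Construct microscope optics parameters
#'
#' @param voltageKV accelerating voltage (kV).
#' @param csMM spherical aberration coefficient (mm).
#' @param defocusUM defocus (micrometres); underfocus is negative.
#' @param ampContrast amplitude contrast fraction W (default 0.04, typical
#'   for 300 kV without energy filtering).
#' @return an [OpticsParams-class].
#' @examples
#' opticsParams(300, csMM = 2.7, defocusUM = -1.5)
#' @export
opticsParams <- function(voltageKV, csMM = 2.7, defocusUM = -1,
                         ampContrast = 0.04) {
  new("OpticsParams",
      voltageKV = voltageKV,
      wavelength = electronWavelength(voltageKV),
      csMM = csMM,
      defocusUM = defocusUM,
      ampContrast = ampContrast)
}

#' Aberration phase shift chi(q)
#'
#' chi(q) = pi lambda dz q^2 + (pi/2) lambda^3 Cs q^4, with all lengths in
#' Angstrom (dz negative for underfocus) and q in 1/Angstrom.
#'
#' @param q spatial frequency (1/Angstrom), vectorised.
#' @param optics an [OpticsParams-class].
#' @return phase shift (radians); chi(0) = 0.
#' @export
chiPhase <- function(q, optics) {
  stopifnot(is(optics, "OpticsParams"))
  lam <- optics@wavelength
  dz <- optics@defocusUM * UM_TO_A
  cs <- optics@csMM * MM_TO_A
  pi * lam * dz * q^2 + (pi / 2) * lam^3 * cs * q^4
}

#' Contrast transfer function
#'
#' CTF(q) = sqrt(1 - W^2) sin chi(q) - W cos chi(q); bounded by 1 in
#' absolute value, and CTF(0) = -W.
#'
#' @inheritParams chiPhase
#' @return CTF values in [-1, 1].
#' @export
ctf <- function(q, optics) {
  W <- optics@ampContrast
  x <- chiPhase(q, optics)
  sqrt(1 - W^2) * sin(x) - W * cos(x)
}

#' CTF error induced by a pixel-size error
#'
#' The CTF assumed under a fractional pixel-size error epsilon samples
#' spatial frequencies scaled by (1 + epsilon):
#' error(q) = CTF_true(q) - CTF_assumed(q (1 + epsilon)). With
#' `refitDefocus` the assumed defocus is re-optimised first (bounded 1-D
#' minimisation of the RMS CTF difference over the grid), mimicking how
#' defocus estimation partially absorbs a magnification error. Because the
#' defocus and Cs terms carry different powers of q, the compensation is
#' only good at low spatial frequency; the residual error grows with q.
#'
#' @param pixelErrorFraction fractional pixel-size error, |eps| < 0.1.
#' @param optics an [OpticsParams-class] (the true optics).
#' @param refitDefocus logical; re-optimise the assumed defocus.
#' @param qGrid spatial-frequency grid (1/Angstrom); default 512 points up
#'   to 0.9 x Nyquist of a 1 Angstrom pixel.
#' @param nominalPixelSize pixel size (Angstrom) used for the default grid.
#' @return data.frame with `q`, `ctf_true`, `ctf_assumed`, `error`, and
#'   attributes `refit_defocus_um`, `rms_error`.
#' @export
ctfErrorCurve <- function(pixelErrorFraction, optics, refitDefocus = FALSE,
                          qGrid = NULL, nominalPixelSize = 1) {
  stopifnot(abs(pixelErrorFraction) < 0.1)
  if (is.null(qGrid))
    qGrid <- seq(1e-4, 0.9 / (2 * nominalPixelSize), length.out = 512)
  qAssumed <- qGrid * (1 + pixelErrorFraction)
  ctfTrue <- ctf(qGrid, optics)
  assumed <- optics
  if (refitDefocus) {
    obj <- function(dzUM) {
      a <- assumed
      a@defocusUM <- dzUM
      sqrt(mean((ctfTrue - ctf(qAssumed, a))^2))
    }
    # the RMS objective oscillates with defocus, so a dense grid scan
    # brackets the global minimum before the local refinement
    lo <- optics@defocusUM - abs(optics@defocusUM) - 1
    hi <- optics@defocusUM + abs(optics@defocusUM) + 1
    grid <- seq(lo, hi, length.out = 801)
    vals <- vapply(grid, obj, numeric(1))
    if (!all(is.finite(vals)))
      stop("defocus refit failed to converge (objective not finite); ",
           "interval [", lo, ", ", hi, "] um", call. = FALSE)
    i <- which.min(vals)
    bracket <- grid[c(max(1, i - 1), min(length(grid), i + 1))]
    opt <- stats::optimize(obj, interval = bracket, tol = 1e-10)
    assumed@defocusUM <- if (opt$objective <= vals[i]) opt$minimum else grid[i]
  }
  ctfAssumed <- ctf(qAssumed, assumed)
  out <- data.frame(q = qGrid, ctf_true = ctfTrue, ctf_assumed = ctfAssumed,
                    error = ctfTrue - ctfAssumed)
  attr(out, "refit_defocus_um") <- assumed@defocusUM
  attr(out, "rms_error") <- sqrt(mean(out$error^2))
  out
}

#' Apparent Cs from the Z40 Zernike coefficient
#'
#' Aberration refinement absorbs a magnification error into the primary
#' spherical term Z40 of the normalised even-Zernike polynomial
#' 6 rho^4 - 6 rho^2 + 1 (rho = q / qMax; the lower-order parts are
#' cancelled by the lower even coefficients). Matching the q^4 phase
#' coefficient against the Cs term (pi/2) lambda^3 Cs q^4 gives
#' deltaCs = 12 Z40 / (pi lambda^3 qMax^4), so
#' Cs_apparent = Cs_true + deltaCs.
#'
#' @param z a [ZernikeSet-class], or a bare numeric Z40 value together with
#'   `qMax`.
#' @param csTrueMM true (calibrated) spherical aberration (mm).
#' @param wavelength electron wavelength (Angstrom).
#' @param qMax normalisation spatial frequency (1/Angstrom); taken from the
#'   ZernikeSet when one is supplied.
#' @return apparent Cs (mm).
#' @export
csApparentFromZ40 <- function(z, csTrueMM, wavelength, qMax = NULL) {
  if (is(z, "ZernikeSet")) {
    z40 <- z@z40
    qMax <- z@qMax
  } else {
    z40 <- z
    if (is.null(qMax)) stop("qMax required with a bare Z40", call. = FALSE)
  }
  dCsA <- 12 * z40 / (pi * wavelength^3 * qMax^4)  # Angstrom
  csTrueMM + dCsA / MM_TO_A
}

#' Z40 coefficient corresponding to a Cs shift
#'
#' Algebraic inverse of [csApparentFromZ40()]; used to simulate
#' aberration-refinement output with a known injected error.
#'
#' @param deltaCsMM Cs shift (mm).
#' @param wavelength electron wavelength (Angstrom).
#' @param qMax normalisation spatial frequency (1/Angstrom).
#' @return the Z40 coefficient.
#' @export
z40FromDeltaCs <- function(deltaCsMM, wavelength, qMax) {
  deltaCsMM * MM_TO_A * pi * wavelength^3 * qMax^4 / 12
}

#' Corrected pixel size from apparent Cs
#'
#' P_true = P_nom (Cs_true / Cs_apparent)^(1/4): the apparent Cs scales with
#' the fourth power of the spatial-frequency (hence inverse pixel-size)
#' error, so its quartic root corrects the nominal pixel size.
#'
#' @param nominalPixelSize nominal pixel size (Angstrom).
#' @param csTrueMM true Cs (mm), positive.
#' @param csApparentMM apparent Cs from aberration refinement (mm), positive.
#' @return corrected magnified pixel size (Angstrom).
#' @export
pixelSizeFromCs <- function(nominalPixelSize, csTrueMM, csApparentMM) {
  if (csTrueMM <= 0 || csApparentMM <= 0)
    stop("Cs values must be positive", call. = FALSE)
  nominalPixelSize * (csTrueMM / csApparentMM)^(1 / 4)
}

#' Read even-Zernike coefficients from a RELION-style STAR file
#'
#' Parses the optics (or particles) table and extracts the
#' `rlnEvenZernike` field, one [ZernikeSet-class] per optics group. The Z40
#' term is the 7th coefficient. The normalisation radius `qMax` defaults to
#' the Nyquist frequency 1/(2 Pnom) of the group's nominal pixel size
#' (taken from `rlnImagePixelSize` or `rlnMicrographOriginalPixelSize` when
#' present, else `nominalPixelSize`).
#'
#' @param path STAR file path.
#' @param nominalPixelSize fallback pixel size (Angstrom) for the Nyquist
#'   normalisation when the file carries none.
#' @param qMax explicit normalisation spatial frequency (1/Angstrom),
#'   overriding the Nyquist default.
#' @return list of [ZernikeSet-class], one per optics group.
#' @export
readZernikeStar <- function(path, nominalPixelSize = NULL, qMax = NULL) {
  blocks <- parseStar(path)
  hit <- NULL
  for (nm in names(blocks)) {
    if ("rlnEvenZernike" %in% names(blocks[[nm]])) { hit <- nm; break }
  }
  if (is.null(hit))
    stop("no rlnEvenZernike field found; tables present: ",
         paste(names(blocks), collapse = ", "), call. = FALSE)
  tab <- blocks[[hit]]
  pxCol <- intersect(c("rlnImagePixelSize", "rlnMicrographOriginalPixelSize",
                       "rlnMicrographPixelSize"), names(tab))
  lapply(seq_len(nrow(tab)), function(i) {
    coefs <- parseZernikeVector(tab$rlnEvenZernike[i])
    if (length(coefs) < 7L)
      stop("rlnEvenZernike has fewer than 7 coefficients", call. = FALSE)
    qm <- qMax
    if (is.null(qm)) {
      px <- if (length(pxCol)) as.numeric(tab[[pxCol[1]]][i]) else
        nominalPixelSize
      if (is.null(px) || !is.finite(px))
        stop("no pixel size available to set the Zernike normalisation; ",
             "supply nominalPixelSize or qMax", call. = FALSE)
      qm <- 1 / (2 * px)
    }
    grp <- if ("rlnOpticsGroup" %in% names(tab))
      as.character(tab$rlnOpticsGroup[i]) else as.character(i)
    new("ZernikeSet", coefficients = coefs, z40 = coefs[7L], qMax = qm,
        group = grp)
  })
}

parseZernikeVector <- function(s) {
  s <- gsub("\\[|\\]", "", s)
  as.numeric(strsplit(trimws(s), "[,[:space:]]+")[[1]])
}

# Minimal STAR reader: named data_ blocks with loop_ tables or key-value
# pairs; returns a named list of data.frames (one row for key-value blocks).
parseStar <- function(path) {
  if (!file.exists(path)) stop("STAR file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  blocks <- list()
  i <- 1L; n <- length(lines)
  while (i <= n) {
    if (!startsWith(lines[i], "data_")) { i <- i + 1L; next }
    bname <- sub("^data_", "", lines[i])
    if (bname == "") bname <- "unnamed"
    i <- i + 1L
    kv <- list(); tab <- NULL
    while (i <= n && !startsWith(lines[i], "data_")) {
      ln <- lines[i]
      if (ln == "") { i <- i + 1L; next }
      if (ln == "loop_") {
        i <- i + 1L
        cols <- character(0)
        while (i <= n && startsWith(lines[i], "_")) {
          cols <- c(cols, sub("^_", "", strsplit(lines[i], "[[:space:]]+")[[1]][1]))
          i <- i + 1L
        }
        rows <- list()
        while (i <= n && lines[i] != "" && !startsWith(lines[i], "data_") &&
               !startsWith(lines[i], "loop_") && !startsWith(lines[i], "_")) {
          rows[[length(rows) + 1L]] <- starTokens(lines[i])
          i <- i + 1L
        }
        if (length(rows)) {
          mat <- do.call(rbind, rows)
          tab <- as.data.frame(mat, stringsAsFactors = FALSE)
          names(tab) <- cols[seq_len(ncol(tab))]
        }
      } else if (startsWith(ln, "_")) {
        parts <- starTokens(ln)
        kv[[sub("^_", "", parts[1])]] <- parts[2]
        i <- i + 1L
      } else {
        i <- i + 1L
      }
    }
    if (is.null(tab) && length(kv))
      tab <- as.data.frame(kv, stringsAsFactors = FALSE)
    if (!is.null(tab)) blocks[[bname]] <- tab
  }
  blocks
}

# split a STAR data line into tokens, keeping bracketed vectors intact
starTokens <- function(ln) {
  toks <- character(0)
  rest <- ln
  while (nchar(rest) > 0) {
    rest <- sub("^[[:space:]]+", "", rest)
    if (rest == "") break
    if (startsWith(rest, "[")) {
      end <- regexpr("\\]", rest)
      if (end < 0) end <- nchar(rest)
      toks <- c(toks, substr(rest, 1, end))
      rest <- substr(rest, end + 1, nchar(rest))
    } else {
      sp <- regexpr("[[:space:]]", rest)
      if (sp < 0) { toks <- c(toks, rest); rest <- "" }
      else {
        toks <- c(toks, substr(rest, 1, sp - 1))
        rest <- substr(rest, sp, nchar(rest))
      }
    }
  }
  toks
}
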