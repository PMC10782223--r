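#' Interplanar spacing for a cubic lattice
#'
#' d = a / sqrt(h^2 + k^2 + l^2). Invariant under any permutation or sign
#' flip of the Miller indices and linear in `a`.
#'
#' @param a lattice constant (Angstrom), positive.
#' @param hkl integer Miller indices, length 3, not all zero.
#' @return interplanar spacing d (Angstrom).
#' @examples
#' dSpacingCubic(4.07, c(1, 1, 1))  # the fcc gold (111) ring near 2.35 A
#' @export
dSpacingCubic <- function(a, hkl) {
  stopifnot(is.numeric(a), length(a) == 1L, a > 0)
  hkl <- checkHKL(hkl)
  a / sqrt(sum(hkl^2))
}

#' Interplanar spacing for a hexagonal lattice
#'
#' Three-index convention: 1/d^2 = (4/3)(h^2 + hk + k^2)/a^2 + l^2/c^2.
#' Negative Miller indices are accepted; the quadratic form makes d identical
#' for the index pairs that differ only in the sign pattern of an equivalent
#' reflection.
#'
#' @param a basal lattice constant (Angstrom), positive.
#' @param c axial lattice constant (Angstrom), positive.
#' @param hkl integer Miller indices (three-index, not Miller-Bravais).
#' @return interplanar spacing d (Angstrom).
#' @examples
#' dSpacingHexagonal(2.88, 4.96, c(0, 0, 2))  # hcp gold (002) at 2.48 A
#' @export
dSpacingHexagonal <- function(a, c, hkl) {
  stopifnot(is.numeric(a), length(a) == 1L, a > 0,
            is.numeric(c), length(c) == 1L, c > 0)
  hkl <- checkHKL(hkl)
  h <- hkl[1]; k <- hkl[2]; l <- hkl[3]
  inv_d2 <- (4 / 3) * (h^2 + h * k + k^2) / a^2 + l^2 / c^2
  1 / sqrt(inv_d2)
}

checkHKL <- function(hkl) {
  if (length(hkl) != 3L || any(hkl != round(hkl)))
    stop("hkl must be three integers", call. = FALSE)
  hkl <- as.integer(hkl)
  if (all(hkl == 0L))
    stop("invalid reflection: hkl = (0,0,0)", call. = FALSE)
  hkl
}

#' Temperature-dependent fcc gold lattice constant
#'
#' Linear thermal-expansion law a(T) = 4.0611 + 5.67075e-5 * T Angstrom,
#' clamped to 4.0636 Angstrom below 43 K: thermal contraction levels off
#' approaching absolute zero, and the measured constant at 13 K corresponds
#' to the 43 K value of the linear law. The clamp is a hard switch, so a
#' discontinuity of order 1e-4 Angstrom exists at the boundary.
#'
#' @param temperature specimen temperature (K), non-negative. Vectorised.
#' @return lattice constant a (Angstrom).
#' @examples
#' goldLatticeConstant(81)   # liquid-nitrogen stage
#' goldLatticeConstant(13)   # clamped value 4.0636
#' @export
goldLatticeConstant <- function(temperature) {
  if (any(!is.finite(temperature)) || any(temperature < 0))
    stop("temperature must be non-negative (Kelvin)", call. = FALSE)
  tm <- goldThermalModel()
  ifelse(temperature < tm@clampTemperature,
         tm@clampValue,
         tm@a0 + tm@slope * temperature)
}

goldThermalModel <- function() {
  new("ThermalModel", a0 = 4.0611, slope = 5.67075e-5,
      clampTemperature = 43, clampValue = 4.0636)
}

#' Evaluate a thermal model at a temperature
#'
#' @param model a [ThermalModel-class].
#' @param temperature temperature (K).
#' @return lattice constant (Angstrom).
#' @export
evalThermalModel <- function(model, temperature) {
  stopifnot(is(model, "ThermalModel"))
  if (any(!is.finite(temperature)) || any(temperature < 0))
    stop("temperature must be non-negative (Kelvin)", call. = FALSE)
  ifelse(temperature < model@clampTemperature,
         model@clampValue,
         model@a0 + model@slope * temperature)
}

#' Built-in calibration material catalogue
#'
#' Reads the human-editable material table shipped with the package
#' (`inst/extdata/materials.csv`) or a user-supplied file of the same layout.
#' Columns: material_id, system, a, c, thermal_a0, thermal_slope,
#' clamp_temperature, clamp_value (empty fields mean "not applicable").
#'
#' Defaults: fcc gold (cubic, thermal model with low-T clamp), hcp gold
#' (hexagonal a = 2.88, c = 4.96 Angstrom, no thermal model), graphitized
#' carbon (treated as cubic with a = 5.92 Angstrom as measured at 81 K, so
#' its (111) spacing reproduces the 3.42 Angstrom calibration peak; no
#' thermal model).
#'
#' @param path optional path to an alternative catalogue CSV.
#' @return named list of [LatticeSpec-class] objects.
#' @export
materialCatalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "materials.csv", package = "magcal")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("material_id", "system", "a")
  if (!all(needed %in% names(tab)))
    stop("material catalogue must have columns material_id, system, a",
         call. = FALSE)
  specs <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    thermal <- NULL
    if (!is.null(row$thermal_a0) && is.finite(row$thermal_a0)) {
      thermal <- new("ThermalModel",
        a0 = row$thermal_a0, slope = row$thermal_slope,
        clampTemperature = row$clamp_temperature,
        clampValue = row$clamp_value)
    }
    new("LatticeSpec",
        material = row$material_id,
        system = row$system,
        a = row$a,
        c = if (is.finite(row$c)) row$c else NA_real_,
        thermal = thermal)
  })
  names(specs) <- tab$material_id
  specs
}

#' Look up a calibration material
#'
#' @param material one of `"gold_fcc"`, `"gold_hcp"`, `"graphitized_carbon"`
#'   (hyphenated spellings are accepted), or any id present in `catalog`.
#' @param catalog a catalogue list from [materialCatalog()].
#' @return a [LatticeSpec-class].
#' @export
latticeSpec <- function(material, catalog = materialCatalog()) {
  key <- gsub("-", "_", material)
  if (!key %in% names(catalog))
    stop("unsupported material '", material, "'; known: ",
         paste(names(catalog), collapse = ", "), call. = FALSE)
  catalog[[key]]
}

#' Temperature-corrected Bragg reflection for a material
#'
#' Computes the d-spacing of the requested reflection from the material's
#' lattice constants, applying the thermal model where one exists. Materials
#' without a thermal model (hcp gold; graphitized carbon, whose constant was
#' only measured at 81 K) ignore `temperature`.
#'
#' @param material material id, see [latticeSpec()].
#' @param hkl integer Miller indices.
#' @param temperature specimen temperature (K); default 81 (cryo stage).
#' @param catalog material catalogue.
#' @return a [Reflection-class] with the computed d-spacing.
#' @examples
#' reflectionFor("gold_fcc", c(1, 1, 1), temperature = 81)
#' @export
reflectionFor <- function(material, hkl, temperature = 81,
                          catalog = materialCatalog()) {
  spec <- latticeSpec(material, catalog)
  hkl <- checkHKL(hkl)
  a <- spec@a
  if (!is.null(spec@thermal)) a <- evalThermalModel(spec@thermal, temperature)
  d <- switch(spec@system,
    cubic = dSpacingCubic(a, hkl),
    hexagonal = dSpacingHexagonal(a, spec@c, hkl)
  )
  new("Reflection", hkl = hkl, d = d, material = spec@material)
}

#' Effective lattice constant of a material at a temperature
#'
#' @inheritParams reflectionFor
#' @return lattice constant a (Angstrom).
#' @export
latticeConstantAt <- function(material, temperature = 81,
                              catalog = materialCatalog()) {
  spec <- latticeSpec(material, catalog)
  if (is.null(spec@thermal)) spec@a
  else evalThermalModel(spec@thermal, temperature)
}
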