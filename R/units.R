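# Unit canonicalization and M_xFe_(3-x)O_4 composition arithmetic.
#
# Literature reports of magnetic nanoparticle properties use heterogeneous
# units (emu/g vs emu/cm3 vs kA/m for magnetization; Oe vs mT for coercivity;
# SAR per gram of nanoparticle vs per gram of Fe or metal). Every converter
# here maps to one canonical unit so that downstream features are comparable
# across sources.

#' Atomic weights used in composition arithmetic
#'
#' Metal weights follow the convention used for doped-magnetite harmonization
#' (Zn 65.4, Co 58.9, Mn 54.9, Mg 24.3, Fe 55.84 g/mol); oxygen is the
#' standard IUPAC 15.999 g/mol.
#'
#' @return Named numeric vector of atomic weights in g/mol.
#' @export
atomic_weights <- function() {
  c(Zn = 65.4, Co = 58.9, Mn = 54.9, Mg = 24.3, Fe = 55.84, O = 15.999)
}

#' Doped-magnetite composition M_xFe_(3-x)O_4
#'
#' @param dopant_element One of `"none"`, `"Zn"`, `"Mn"`, `"Co"`, `"Mg"`.
#' @param x Doping fraction in `[0, 3)`; must be 0 when `dopant_element`
#'   is `"none"`.
#' @return An object of class `composition`.
#' @examples
#' composition("Zn", 0.5)
#' molar_mass(composition())
#' @export
composition <- function(dopant_element = "none", x = 0) {
  dopant_element <- match.arg(dopant_element, c("none", "Zn", "Mn", "Co", "Mg"))
  if (!is_number(x) || x < 0 || x >= 3) {
    stopf("doping fraction x must be a number in [0, 3), got %s", format(x))
  }
  if (dopant_element == "none" && x != 0) {
    stopf("x must be 0 for an undoped composition")
  }
  structure(list(dopant_element = dopant_element, x = x), class = "composition")
}

#' @exportS3Method base::print
print.composition <- function(x, ...) {
  if (x$dopant_element == "none") {
    cat("Fe3O4 (undoped magnetite)\n")
  } else {
    cat(sprintf("%s_%gFe_%gO4\n", x$dopant_element, x$x, 3 - x$x))
  }
  invisible(x)
}

as_composition <- function(comp) {
  if (inherits(comp, "composition")) return(comp)
  stopf("expected a composition object")
}

#' Molar mass of M_xFe_(3-x)O_4
#'
#' `x * W_M + (3 - x) * W_Fe + 4 * W_O` in g/mol.
#'
#' @param comp A [composition()].
#' @return Molar mass in g/mol.
#' @export
molar_mass <- function(comp) {
  comp <- as_composition(comp)
  w <- atomic_weights()
  wm <- if (comp$dopant_element == "none") 0 else w[[comp$dopant_element]]
  comp$x * wm + (3 - comp$x) * w[["Fe"]] + 4 * w[["O"]]
}

#' Iron mass fraction of a composition
#'
#' @param comp A [composition()].
#' @return Fraction of the formula mass contributed by Fe_(3-x).
#' @export
fe_mass_fraction <- function(comp) {
  comp <- as_composition(comp)
  (3 - comp$x) * atomic_weights()[["Fe"]] / molar_mass(comp)
}

#' Total metal (Fe + dopant) mass fraction of a composition
#'
#' @param comp A [composition()].
#' @return Fraction of the formula mass contributed by Fe_(3-x) plus M_x.
#' @export
metal_mass_fraction <- function(comp) {
  comp <- as_composition(comp)
  w <- atomic_weights()
  wm <- if (comp$dopant_element == "none") 0 else w[[comp$dopant_element]]
  ((3 - comp$x) * w[["Fe"]] + comp$x * wm) / molar_mass(comp)
}

#' Convert magnetization to emu/g nanoparticle
#'
#' Conversions: 1 Am2/kg is identically 1 emu/g; emu/cm3 and kA/m (1 kA/m is
#' 1 emu/cm3) are divided by the average nanoparticle density of 5 g/cm3;
#' emu per gram of Fe is scaled by the Fe mass fraction of the composition.
#'
#' @param value Numeric magnetization value(s).
#' @param unit One of `"emu/g"`, `"emu/gFe"`, `"emu/cm3"`, `"Am2/kg"`,
#'   `"kA/m"`.
#' @param comp A [composition()]; required only for `"emu/gFe"`.
#' @return Magnetization in emu/g nanoparticle.
#' @export
magnetization_to_emu_per_g <- function(value, unit, comp = NULL) {
  stopifnot(is.numeric(value), all(is.finite(value)))
  unit <- match.arg(unit, c("emu/g", "emu/gFe", "emu/cm3", "Am2/kg", "kA/m"))
  density <- 5 # average SPION density, g/cm3
  switch(unit,
    "emu/g" = value,
    "Am2/kg" = value,
    "emu/cm3" = value / density,
    "kA/m" = value / density,
    "emu/gFe" = {
      if (is.null(comp)) stopf("a composition is required to convert emu/gFe")
      value * fe_mass_fraction(comp)
    }
  )
}

#' Convert coercivity to Oe
#'
#' 1 mT corresponds to 10 Oe and to 0.7958 kA/m, so kA/m values are first
#' mapped to mT via 1/0.7958 and then scaled by 10.
#'
#' @param value Numeric coercivity value(s).
#' @param unit One of `"Oe"`, `"mT"`, `"kA/m"`.
#' @return Coercivity in Oe.
#' @export
coercivity_to_oe <- function(value, unit) {
  stopifnot(is.numeric(value), all(is.finite(value)))
  unit <- match.arg(unit, c("Oe", "mT", "kA/m"))
  switch(unit,
    "Oe" = value,
    "mT" = value * 10,
    "kA/m" = value / 0.7958 * 10
  )
}

#' Inverse of [coercivity_to_oe()] for round-trip checks
#'
#' @param value Coercivity in Oe.
#' @param unit Target unit, `"Oe"`, `"mT"` or `"kA/m"`.
#' @return Coercivity in the requested unit.
#' @export
oe_to_coercivity_unit <- function(value, unit) {
  unit <- match.arg(unit, c("Oe", "mT", "kA/m"))
  switch(unit,
    "Oe" = value,
    "mT" = value / 10,
    "kA/m" = value / 10 * 0.7958
  )
}

#' Parse a measurement temperature to Kelvin
#'
#' Numeric inputs pass through; the literal marker "room temperature" (case
#' insensitive) maps to 300 K; numeric strings are parsed.
#'
#' @param value_or_text Numeric temperature in K or a text marker.
#' @return Temperature in K.
#' @export
temperature_to_kelvin <- function(value_or_text) {
  if (is.numeric(value_or_text)) {
    if (!all(is.finite(value_or_text))) stopf("non-finite temperature")
    return(as.numeric(value_or_text))
  }
  txt <- tolower(trimws(as.character(value_or_text)))
  out <- suppressWarnings(as.numeric(txt))
  out[txt %in% c("room temperature", "rt")] <- 300
  if (anyNA(out)) {
    stopf("cannot parse temperature: %s", paste(txt[is.na(out)], collapse = ", "))
  }
  out
}

#' Parse a remanence report, treating "negligible" as 0 emu/g
#'
#' @param value_or_text Numeric remanence or the literal "negligible".
#' @return Remanence in emu/g.
#' @export
remanence_value <- function(value_or_text) {
  if (is.numeric(value_or_text)) return(as.numeric(value_or_text))
  txt <- tolower(trimws(as.character(value_or_text)))
  out <- suppressWarnings(as.numeric(txt))
  out[txt == "negligible"] <- 0
  if (anyNA(out)) stopf("cannot parse remanence: %s", paste(txt[is.na(out)], collapse = ", "))
  out
}

#' Renormalize SAR to W per gram of nanoparticle
#'
#' Values reported per gram of Fe are scaled by the Fe mass fraction of the
#' composition; values per gram of total metal by the (Fe + dopant) mass
#' fraction; values already per gram of nanoparticle pass through.
#'
#' @param value Nonnegative SAR value(s).
#' @param basis One of `"per_g_np"`, `"per_g_Fe"`, `"per_g_metal"`.
#' @param comp A [composition()]; required for the non-nanoparticle bases.
#' @return SAR in W/g nanoparticle.
#' @export
sar_to_w_per_g_np <- function(value, basis, comp = NULL) {
  stopifnot(is.numeric(value), all(value >= 0))
  basis <- match.arg(basis, c("per_g_np", "per_g_Fe", "per_g_metal"))
  if (basis == "per_g_np") return(value)
  if (is.null(comp)) stopf("a composition is required for basis '%s'", basis)
  switch(basis,
    per_g_Fe = value * fe_mass_fraction(comp),
    per_g_metal = value * metal_mass_fraction(comp)
  )
}

#' Dopant-iron ratio feature vector
#'
#' Encodes the composition as the four features (Zn-Fe, Mn-Fe, Co-Fe, Mg-Fe).
#' The component for the record's dopant equals the doping fraction `x`
#' (default) or the molar ratio `x / (3 - x)`; the other three are 0.
#'
#' @param comp A [composition()].
#' @param mode `"x"` (doping fraction, default) or `"molar"` (`x / (3 - x)`).
#' @return Named numeric vector `c(Zn_Fe, Mn_Fe, Co_Fe, Mg_Fe)`.
#' @export
dopant_ratio_features <- function(comp, mode = c("x", "molar")) {
  comp <- as_composition(comp)
  mode <- match.arg(mode)
  out <- c(Zn_Fe = 0, Mn_Fe = 0, Co_Fe = 0, Mg_Fe = 0)
  if (comp$dopant_element != "none") {
    v <- if (mode == "x") comp$x else comp$x / (3 - comp$x)
    out[paste0(comp$dopant_element, "_Fe")] <- v
  }
  out
}
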