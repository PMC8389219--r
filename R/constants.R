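# Physical constants (CODATA 2018 exact values where defined) and the unit
# conversions used throughout. The canonical internal energy unit is kcal/mol;
# Hartree, kJ/mol and the cm^-1 energy equivalent are input/output dialects.

.codata <- list(
  kB_J_per_K    = 1.380649e-23,      # Boltzmann constant, J/K
  h_J_s         = 6.62607015e-34,    # Planck constant, J s
  c_cm_per_s    = 2.99792458e10,     # speed of light, cm/s
  N_A           = 6.02214076e23,     # Avogadro constant, 1/mol
  R_kcal        = 1.98720425e-3,     # gas constant, kcal/(mol K)
  hartree_kcal  = 627.5095,          # 1 Hartree in kcal/mol
  kcal_kJ       = 4.184              # thermochemical calorie
)
# 1 cm^-1 as a molar energy: h c N_A / 4184 (kcal/mol)
.codata$cm1_kcal <- with(.codata, h_J_s * c_cm_per_s * N_A / 4184)
# second radiation constant h c / kB (cm K): converts wavenumber to temperature
.codata$c2_cm_K <- with(.codata, h_J_s * c_cm_per_s / kB_J_per_K)

#' Physical constants used by the package
#'
#' Returns the pinned constant set (CODATA 2018 exact values for `kB`, `h`,
#' `c`, `N_A`; `R` in kcal/(mol K); the Hartree-to-kcal/mol factor 627.5095).
#' All rate and thermodynamic arithmetic in the package draws from this list,
#' so results are reproducible to the last digit.
#'
#' @return A named list of constants:
#'   `kB_J_per_K`, `h_J_s`, `c_cm_per_s`, `N_A`, `R_kcal` (kcal/(mol K)),
#'   `hartree_kcal`, `kcal_kJ`, `cm1_kcal` (1 cm^-1 in kcal/mol),
#'   `c2_cm_K` (h c / kB in cm K).
#' @examples
#' physical_constants()$R_kcal
#' @export
physical_constants <- function() .codata

# internal: supported energy unit labels, canonical spelling
.energy_units <- c("hartree", "kcal/mol", "kJ/mol", "cm-1")

.normalize_unit <- function(unit) {
  u <- tolower(trimws(unit))
  u <- sub("^cm\\^?-1$|^1/cm$|^wavenumber$", "cm-1", u)
  u <- sub("^kcal$", "kcal/mol", u)
  u <- sub("^kj$|^kj/mol$", "kJ/mol", u)
  u <- sub("^au$|^a\\.u\\.$", "hartree", u)
  if (u == "kj/mol") u <- "kJ/mol"
  if (!u %in% .energy_units) {
    stop(sprintf("unknown energy unit '%s'; supported units are: %s",
                 unit, paste(.energy_units, collapse = ", ")), call. = FALSE)
  }
  u
}

# factors to kcal/mol
.to_kcal_factor <- function(unit) {
  switch(unit,
    "hartree"  = .codata$hartree_kcal,
    "kcal/mol" = 1,
    "kJ/mol"   = 1 / .codata$kcal_kJ,
    "cm-1"     = .codata$cm1_kcal
  )
}

#' Convert a molar energy between supported units
#'
#' Supported units: `"hartree"`, `"kcal/mol"`, `"kJ/mol"` and the spectroscopic
#' energy equivalent `"cm-1"`. Conversion goes through kcal/mol with pinned
#' factors, so any round trip A -> B -> A is an identity to better than 1e-12
#' relative.
#'
#' @param value Numeric energy value(s).
#' @param from,to Unit labels.
#' @return The converted value(s).
#' @examples
#' convert_energy(1, "hartree", "kcal/mol")   # 627.5095
#' convert_energy(72.9, "kcal/mol", "kJ/mol") # 305.0136
#' @export
convert_energy <- function(value, from, to) {
  stopifnot(is.numeric(value))
  from <- .normalize_unit(from)
  to <- .normalize_unit(to)
  if (from == to) return(value)
  value * .to_kcal_factor(from) / .to_kcal_factor(to)
}

#' Thermal energy RT in kcal/mol
#'
#' @param temperature Temperature in kelvin (> 0).
#' @return `R * T` with R = 1.98720425e-3 kcal/(mol K).
#' @examples
#' thermal_rt(298.15) # 0.59248...
#' @export
thermal_rt <- function(temperature) {
  if (!is.numeric(temperature) || any(!is.finite(temperature)) ||
      any(temperature <= 0)) {
    stop("temperature must be a finite positive number (kelvin)", call. = FALSE)
  }
  .codata$R_kcal * temperature
}
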