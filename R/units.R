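# Energy units recognised throughout the package. Canonical internal unit
# is eV: the SHE reference and vertical gaps are conventionally quoted in
# V/eV, and for one exchanged electron 1 eV maps onto 1 V.
.ev_per_unit <- c(
  hartree      = 27.211386,
  eV           = 1,
  kcal_per_mol = 0.0433641
)

.normalise_unit <- function(unit) {
  u <- gsub("[ /]", "_", trimws(unit))
  u[tolower(u) %in% c("ev", "electronvolt")] <- "eV"
  u[tolower(u) %in% c("hartree", "ha", "au")] <- "hartree"
  u[tolower(u) %in% c("kcal_mol", "kcal_per_mol", "kcal_mol-1")] <- "kcal_per_mol"
  u
}

#' Convert energies between hartree, eV and kcal/mol
#'
#' Linear unit conversion through the eV scale using the conversion
#' factors 27.211386 eV/hartree and 0.0433641 eV/(kcal/mol). Conversions
#' compose consistently: converting through any chain of units returns
#' the original magnitude to better than 1e-10 relative error.
#'
#' @param value numeric vector of energy magnitudes.
#' @param from,to unit names; one of `"hartree"`, `"eV"`,
#'   `"kcal_per_mol"` (the spelling `"kcal/mol"` is accepted).
#' @return numeric vector of magnitudes expressed in `to`.
#' @examples
#' convert_energy(1, "hartree", "eV")          # 27.211386
#' convert_energy(-0.867, "kcal/mol", "eV")    # -0.0376
#' @export
convert_energy <- function(value, from, to) {
  from <- .normalise_unit(from)
  to <- .normalise_unit(to)
  for (u in unique(c(from, to))) {
    if (!u %in% names(.ev_per_unit)) {
      stop("unknown energy unit: '", u, "' (recognised: ",
           paste(names(.ev_per_unit), collapse = ", "), ")", call. = FALSE)
    }
  }
  value * unname(.ev_per_unit[from]) / unname(.ev_per_unit[to])
}

#' Physical constants and reference conventions
#'
#' Bundles the constants shared by every protocol: the absolute
#' reduction potential of the standard hydrogen electrode (SHE), the
#' gas-phase free energy of the electron obtained from Fermi-Dirac
#' statistics (which the SHE value of 4.281 V presupposes, so it must be
#' subtracted explicitly in every half-reaction free energy), and the
#' thermal energy k_B T. For n = 1 exchanged electron an energy of 1 eV
#' corresponds to 1 V, so no explicit Faraday constant appears in the
#' numerics.
#'
#' The electron free-energy sign convention used everywhere in the
#' package: G_c(e-) is subtracted in the reduction free energy, i.e.
#' Delta G_red = G(N) - G(N+) - G_c(e-) for N+ + e- -> N.
#'
#' @param she_potential_V absolute SHE reduction potential in volts.
#'   Default 4.281 V. A different reference electrode can be emulated by
#'   overriding this value.
#' @param electron_free_energy_kcal_mol gas-phase free energy of the
#'   electron in kcal/mol. Default -0.867.
#' @param temperature_K temperature in kelvin; enters only through
#'   k_B T (Boltzmann weights, reorganization energies). Default 298.15.
#' @return an object of class `energy_constants`: a list with the
#'   arguments plus `electron_free_energy_eV` and `kT_eV`
#'   (0.025693 eV at the default temperature).
#' @seealso [read_constants()] to load overrides from a YAML/JSON file.
#' @export
energy_constants <- function(she_potential_V = 4.281,
                             electron_free_energy_kcal_mol = -0.867,
                             temperature_K = 298.15) {
  stopifnot(is.numeric(she_potential_V), length(she_potential_V) == 1,
            she_potential_V > 0,
            is.numeric(temperature_K), length(temperature_K) == 1,
            temperature_K > 0,
            is.numeric(electron_free_energy_kcal_mol),
            length(electron_free_energy_kcal_mol) == 1)
  kB_eV_per_K <- 8.617333262e-5   # CODATA
  out <- list(
    she_potential_V = she_potential_V,
    electron_free_energy_kcal_mol = electron_free_energy_kcal_mol,
    electron_free_energy_eV = convert_energy(electron_free_energy_kcal_mol,
                                             "kcal_per_mol", "eV"),
    temperature_K = temperature_K,
    kT_eV = kB_eV_per_K * temperature_K
  )
  class(out) <- "energy_constants"
  out
}

#' @export
print.energy_constants <- function(x, ...) {
  cat("Physical constants for potential calculations\n")
  cat(sprintf("  SHE reference:        %.3f V\n", x$she_potential_V))
  cat(sprintf("  G(e-), gas phase:     %.3f kcal/mol (%.5f eV)\n",
              x$electron_free_energy_kcal_mol, x$electron_free_energy_eV))
  cat(sprintf("  Temperature:          %.2f K (kT = %.6f eV)\n",
              x$temperature_K, x$kT_eV))
  invisible(x)
}

#' Load constant overrides from a configuration file
#'
#' Reads a YAML or JSON file with any of the keys `she_potential_V`,
#' `electron_free_energy_kcal_mol` and `temperature_K`; missing keys
#' keep their defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return an [energy_constants()] object.
#' @export
read_constants <- function(path) {
  if (!file.exists(path)) stop("constants file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  allowed <- c("she_potential_V", "electron_free_energy_kcal_mol", "temperature_K")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    stop("unknown constants key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(energy_constants, cfg[intersect(allowed, names(cfg))])
}

#' Reduction potential relative to the SHE
#'
#' Maps a reduction free energy onto a potential versus the standard
#' hydrogen electrode: E = -Delta G_red / (n F) - E_SHE, evaluated
#' numerically as (-Delta G_red\[eV\] / n) - E_SHE\[V\]. The input free
#' energy must already include the electron free-energy term (the
#' protocol functions take care of that).
#'
#' @param delta_g_red_eV reduction free energy in eV.
#' @param n_electrons number of exchanged electrons (a positive
#'   integer; 1 for the one-electron couples treated here).
#' @param constants an [energy_constants()] object.
#' @return potential in volts vs SHE.
#' @examples
#' potential_vs_she(-4.281)    # 0: reference cancellation
#' potential_vs_she(-5.0624)   # 0.781
#' @export
potential_vs_she <- function(delta_g_red_eV, n_electrons = 1L,
                             constants = energy_constants()) {
  stopifnot(inherits(constants, "energy_constants"),
            is.numeric(delta_g_red_eV))
  if (!is.numeric(n_electrons) || length(n_electrons) != 1 ||
      n_electrons < 1 || n_electrons != round(n_electrons)) {
    stop("n_electrons must be a positive integer", call. = FALSE)
  }
  (-delta_g_red_eV / as.numeric(n_electrons)) - constants$she_potential_V
}
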