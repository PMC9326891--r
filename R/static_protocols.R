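# Static protocols: the direct route from adiabatic free energies in a
# continuum solvent, and two thermodynamic cycles that move the thermal
# correction to the gas phase. All free energies in eV, potentials in V.

# Internal record lookup with informative failure.
.get_energy <- function(records, species, charge_state, phase, geometry,
                        quantity, method_tag = NULL, context = NULL) {
  stopifnot(inherits(records, "species_energy_records"))
  sel <- records$species == species &
    records$charge_state == charge_state &
    records$phase == phase &
    records$geometry == geometry &
    records$quantity == quantity
  if (!is.null(method_tag)) sel <- sel & records$method_tag == method_tag
  hit <- which(sel)
  key <- paste0("(species=", species, ", charge_state=", charge_state,
                ", phase=", phase, ", geometry=", geometry,
                ", quantity=", quantity,
                if (!is.null(method_tag)) paste0(", method_tag=", method_tag),
                ")")
  if (length(hit) == 0) {
    stop("missing record ", key,
         if (!is.null(context)) paste0(" -- required by ", context),
         call. = FALSE)
  }
  if (length(hit) > 1) {
    stop("ambiguous record ", key, ": ", length(hit),
         " method_tags match; pass method_tag explicitly", call. = FALSE)
  }
  records$value_eV[hit]
}

.static_result <- function(species, protocol, delta_g_red_eV, components,
                           constants) {
  out <- list(
    species = species,
    protocol = protocol,
    delta_g_red_eV = delta_g_red_eV,
    potential_V = potential_vs_she(delta_g_red_eV, 1L, constants),
    components = components
  )
  class(out) <- "static_result"
  out
}

#' @export
print.static_result <- function(x, ...) {
  cat(sprintf("%s potential for %s: %.3f V vs SHE (Delta G_red = %.4f eV)\n",
              x$protocol, x$species, x$potential_V, x$delta_g_red_eV))
  for (nm in names(x$components)) {
    cat(sprintf("  %-22s %.4f eV\n", nm, x$components[[nm]]))
  }
  invisible(x)
}

#' Static direct oxidation potential
#'
#' Computes the one-electron oxidation potential (quoted, by convention,
#' in the reduction direction of the N+/N couple) from adiabatic free
#' energies in a continuum solvent: Delta G_red =
#' \[E_e(N) + G_T(N)\] - \[E_e(N+) + G_T(N+)\] - G_c(e-), with all four
#' terms taken from solvent-phase records at their solvent-optimized
#' geometries. The potential follows from [potential_vs_she()].
#'
#' @param records a [species_energy_records()] set containing, for both
#'   charge states, solvent-phase E_e and G_T at `solvent_optimized`
#'   geometry.
#' @param species species identifier to compute.
#' @param constants an [energy_constants()] object.
#' @param method_tag optional method label to disambiguate records.
#' @return a `static_result`: species, protocol, `delta_g_red_eV`,
#'   `potential_V`, and a component breakdown.
#' @export
static_direct <- function(records, species, constants = energy_constants(),
                          method_tag = NULL) {
  ctx <- "static_direct"
  g <- function(charge, quantity) {
    .get_energy(records, species, charge, "solvent", "solvent_optimized",
                quantity, method_tag, ctx)
  }
  g_neutral <- g("neutral", "E_e") + g("neutral", "G_T")
  g_cation <- g("cation", "E_e") + g("cation", "G_T")
  dg <- g_neutral - g_cation - constants$electron_free_energy_eV
  .static_result(species, "static_direct", dg, list(
    g_neutral_eV = g_neutral,
    g_cation_eV = g_cation,
    electron_free_energy_eV = constants$electron_free_energy_eV
  ), constants)
}

#' Solvation free energy of one charge state
#'
#' Difference between the electronic energy of the solute in solvent and
#' in the gas phase. The two cycle variants differ in the geometries
#' used: `cycle1` evaluates the solvent-phase energy at the
#' solvent-optimized geometry (solute relaxation upon solvation is
#' included), `cycle2` evaluates both phases at the gas-optimized
#' geometry.
#'
#' @param records a [species_energy_records()] set.
#' @param species species identifier.
#' @param charge_state `"neutral"` or `"cation"`.
#' @param variant `"cycle1"` or `"cycle2"`.
#' @param method_tag optional method label.
#' @return solvation free energy Delta G_s in eV.
#' @export
solvation_free_energy <- function(records, species, charge_state,
                                  variant = c("cycle1", "cycle2"),
                                  method_tag = NULL) {
  variant <- match.arg(variant)
  charge_state <- match.arg(charge_state, .charge_states)
  solv_geom <- if (variant == "cycle1") "solvent_optimized" else "gas_optimized"
  ctx <- paste0("solvation_free_energy variant ", variant,
                " (needs solvent-phase E_e at ", solv_geom,
                " geometry and gas-phase E_e at gas_optimized geometry)")
  e_solv <- .get_energy(records, species, charge_state, "solvent", solv_geom,
                        "E_e", method_tag, ctx)
  e_gas <- .get_energy(records, species, charge_state, "gas", "gas_optimized",
                       "E_e", method_tag, ctx)
  e_solv - e_gas
}

#' Thermodynamic-cycle oxidation potential
#'
#' Decomposes the solution-phase reduction free energy into a gas-phase
#' reaction term plus solvation free energies:
#' Delta G_red = Delta G_red,gas + Delta G_s(N) - Delta G_s(N+), with
#' Delta G_red,gas =
#' \[E_e(N_gas) + G_T(N_gas)\] - \[E_e(N+_gas) + G_T(N+_gas)\] - G_c(e-).
#' Thermal corrections are always taken from gas-phase records (the
#' ideal-gas/rigid-rotor/harmonic-oscillator partition functions behind
#' G_T are not meaningful in solvent), even when solvent-phase G_T
#' records are present. The electron's solvation free energy is zero by
#' default (the electron is treated in the gas phase as a formalism that
#' cancels between half reactions); `electron_solvation_eV` overrides it
#' for solvated-electron conventions.
#'
#' @inheritParams static_direct
#' @param variant `"cycle1"` or `"cycle2"`, see
#'   [solvation_free_energy()].
#' @param electron_solvation_eV solvation free energy assigned to the
#'   electron (default 0).
#' @return a `static_result` with the component breakdown
#'   (`delta_g_red_gas_eV`, `dgs_neutral_eV`, `dgs_cation_eV`); the
#'   components sum exactly to `delta_g_red_eV`.
#' @export
cycle_potential <- function(records, species,
                            variant = c("cycle1", "cycle2"),
                            constants = energy_constants(),
                            method_tag = NULL,
                            electron_solvation_eV = 0) {
  variant <- match.arg(variant)
  ctx <- paste0("cycle_potential variant ", variant)
  g <- function(charge, quantity) {
    .get_energy(records, species, charge, "gas", "gas_optimized",
                quantity, method_tag, ctx)
  }
  dg_gas <- (g("neutral", "E_e") + g("neutral", "G_T")) -
    (g("cation", "E_e") + g("cation", "G_T")) -
    constants$electron_free_energy_eV
  dgs_n <- solvation_free_energy(records, species, "neutral", variant,
                                 method_tag)
  dgs_c <- solvation_free_energy(records, species, "cation", variant,
                                 method_tag)
  dg <- dg_gas + dgs_n - dgs_c + electron_solvation_eV
  .static_result(species, variant, dg, list(
    delta_g_red_gas_eV = dg_gas,
    dgs_neutral_eV = dgs_n,
    dgs_cation_eV = dgs_c,
    electron_solvation_eV = electron_solvation_eV
  ), constants)
}
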