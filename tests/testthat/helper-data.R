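# Fixture builders: everything is generated in code, no stored data.

# Long-format species table for one species (both charge states,
# solvent phase at solvent-optimized geometry), values in `unit`.
toy_species_df <- function(species = "G", ee = c(-100, -95),
                           gt = c(0.05, 0.06), unit = "eV",
                           phase = "solvent", geometry = "solvent_optimized",
                           method_tag = "toy") {
  data.frame(
    species = species,
    charge_state = rep(c("neutral", "cation"), 2),
    phase = phase, geometry = geometry,
    quantity = rep(c("E_e", "G_T"), each = 2),
    value = c(ee, gt), unit = unit, method_tag = method_tag,
    stringsAsFactors = FALSE
  )
}

write_gap_csv <- function(values, path, species = "G", gap_kind = "VIE",
                          sampled_state = NULL, unit = "eV",
                          solvent_model = "implicit", method_tag = "toy",
                          snapshot_id = seq_along(values)) {
  if (is.null(sampled_state)) {
    sampled_state <- if (gap_kind == "VAE") "cation" else "neutral"
  }
  df <- data.frame(species = species, gap_kind = gap_kind,
                   sampled_state = sampled_state, snapshot_id = snapshot_id,
                   value = values, unit = unit,
                   solvent_model = solvent_model, method_tag = method_tag)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Constants with the electron free-energy term switched off, for tests
# whose arithmetic is cleaner without it.
constants_no_electron <- function() {
  energy_constants(electron_free_energy_kcal_mol = 0)
}
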