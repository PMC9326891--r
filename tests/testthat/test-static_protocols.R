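test_that("static direct recovers the defining arithmetic", {
  # equal free energies, no electron term -> Delta G = 0 -> -E_SHE
  cc0 <- constants_no_electron()
  rec <- species_energy_records(toy_species_df(ee = c(-100, -100),
                                               gt = c(0.05, 0.05)))
  res <- static_direct(rec, "G", cc0)
  expect_equal(res$delta_g_red_eV, 0)
  expect_equal(res$potential_V, -4.281)

  # free-energy difference of -5.10 eV -> 0.781 V with default constants
  cc <- energy_constants()
  rec2 <- species_energy_records(toy_species_df(ee = c(-100.10, -95),
                                                gt = c(0.05, 0.05)))
  res2 <- static_direct(rec2, "G", cc)
  expect_equal(res2$delta_g_red_eV, -5.10 - cc$electron_free_energy_eV)
  expect_equal(round(res2$potential_V, 3), 0.781)

  # missing thermal correction fails naming the key
  no_gt <- species_energy_records(toy_species_df()[c(1, 2, 3), ])
  expect_error(static_direct(no_gt, "G"), "cation.*G_T")
})

test_that("adding a constant to both charge states cancels; to one does not", {
  cc <- energy_constants()
  base <- toy_species_df(ee = c(-100.10, -95), gt = c(0.05, 0.06))
  p0 <- static_direct(species_energy_records(base), "G", cc)$potential_V
  shifted <- base
  shifted$value[shifted$quantity == "E_e"] <-
    shifted$value[shifted$quantity == "E_e"] + 3.21
  expect_equal(static_direct(species_energy_records(shifted), "G",
                             cc)$potential_V, p0)
  one_sided <- base
  one_sided$value[1] <- one_sided$value[1] + 3.21
  expect_equal(static_direct(species_energy_records(one_sided), "G",
                             cc)$potential_V, p0 - 3.21)
})

test_that("solvation free energies follow the variant's geometry rules", {
  mk <- function(ee_solv_sgeom, ee_solv_ggeom, ee_gas) {
    species_energy_records(data.frame(
      species = "G", charge_state = "neutral",
      phase = c("solvent", "solvent", "gas"),
      geometry = c("solvent_optimized", "gas_optimized", "gas_optimized"),
      quantity = "E_e", value = c(ee_solv_sgeom, ee_solv_ggeom, ee_gas),
      unit = "eV", method_tag = "toy", stringsAsFactors = FALSE))
  }
  expect_equal(solvation_free_energy(mk(-100, -100, -100), "G", "neutral",
                                     "cycle1"), 0)
  expect_equal(solvation_free_energy(mk(-100.10, -100.05, -100), "G",
                                     "neutral", "cycle1"), -0.10)
  expect_equal(solvation_free_energy(mk(-100.10, -100.05, -100), "G",
                                     "neutral", "cycle2"), -0.05)
  # cycle1 - cycle2 == E_e(solv@solv_geom) - E_e(solv@gas_geom)
  r <- mk(-100.37, -100.11, -100)
  expect_equal(
    solvation_free_energy(r, "G", "neutral", "cycle1") -
      solvation_free_energy(r, "G", "neutral", "cycle2"),
    -100.37 - (-100.11))
  # variant-specific failure names what is missing
  incomplete <- mk(-100.37, -100.11, -100)
  incomplete <- incomplete[incomplete$geometry != "solvent_optimized" |
                             incomplete$phase != "solvent", ]
  class(incomplete) <- c("species_energy_records", "data.frame")
  expect_error(solvation_free_energy(incomplete, "G", "neutral", "cycle1"),
               "cycle1")
})

test_that("cycle potentials decompose exactly into their components", {
  cc <- energy_constants()
  # target chosen so Delta G_red = -5.10 eV; prescribed shifts make
  # Delta G_red,gas = -5.00 eV
  rec <- mock_static_records(5.10 - cc$she_potential_V,
                             solvation_shifts_eV = c(-0.30, -0.20),
                             constants = cc)
  res <- cycle_potential(rec, "MOCK", "cycle1", cc)
  expect_equal(res$delta_g_red_eV, -5.10)
  expect_equal(res$components$delta_g_red_gas_eV, -5.00)
  expect_equal(res$components$dgs_neutral_eV, -0.30)
  expect_equal(res$components$dgs_cation_eV, -0.20)
  # exact telescoping of the component sum
  expect_identical(res$delta_g_red_eV,
                   res$components$delta_g_red_gas_eV +
                     res$components$dgs_neutral_eV -
                     res$components$dgs_cation_eV +
                     res$components$electron_solvation_eV)
})

test_that("cycle1 equals static direct when gas and solvent G_T agree", {
  cc <- energy_constants()
  rec <- mock_static_records(0.85, constants = cc)  # equal G_T by default
  sd_ <- static_direct(rec, "MOCK", cc)
  c1 <- cycle_potential(rec, "MOCK", "cycle1", cc)
  c2 <- cycle_potential(rec, "MOCK", "cycle2", cc)
  expect_equal(c1$potential_V, sd_$potential_V)
  expect_equal(c2$potential_V, sd_$potential_V)
  expect_equal(sd_$potential_V, 0.85)

  # zero solvation shifts: cycle potential reduces to the gas-phase one
  rec0 <- mock_static_records(0.85, solvation_shifts_eV = c(0, 0),
                              constants = cc)
  c10 <- cycle_potential(rec0, "MOCK", "cycle1", cc)
  expect_equal(c10$delta_g_red_eV, c10$components$delta_g_red_gas_eV)
})

test_that("the electron solvation term is zero by default but overridable", {
  cc <- energy_constants()
  rec <- mock_static_records(0.85, constants = cc)
  base <- cycle_potential(rec, "MOCK", "cycle1", cc)
  shifted <- cycle_potential(rec, "MOCK", "cycle1", cc,
                             electron_solvation_eV = -0.1)
  expect_equal(base$components$electron_solvation_eV, 0)
  expect_equal(shifted$potential_V - base$potential_V, 0.1)
})
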