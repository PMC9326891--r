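# Synthetic energy-ensemble generator. Produces gap ensembles with the
# exact statistical structure the dynamic estimators assume (or with
# controlled violations of it) and self-consistent static energy
# records with a known ground-truth potential, so that every stage of
# the analysis is testable without electronic-structure or MD input.

# Evaluate `code` under a fixed seed of R's default Mersenne-Twister
# generator, restoring the caller's RNG state afterwards.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Standardised skewed deviates: a shifted lognormal scaled to zero mean
# and unit variance, with the lognormal shape chosen to hit the
# requested skewness exactly (in distribution); negative skew mirrors.
.rskewed <- function(n, skew) {
  g <- abs(skew)
  shape <- stats::uniroot(
    function(s) (exp(s^2) + 2) * sqrt(exp(s^2) - 1) - g,
    c(1e-8, 5), tol = 1e-12
  )$root
  L <- stats::rlnorm(n, meanlog = 0, sdlog = shape)
  z <- (L - exp(shape^2 / 2)) / sqrt((exp(shape^2) - 1) * exp(shape^2))
  sign(skew) * z
}

#' Sample a VIE/VAE pair obeying exact linear response
#'
#' Draws the two vertical-gap ensembles from the Gaussian linear-response
#' construction: VIE ~ N(delta_a + lam, sigma), VAE ~ N(delta_a - lam,
#' sigma) with the fluctuation-dissipation width sigma =
#' sqrt(2 lam kT). On this output the Marcus half-sum estimates
#' `delta_a`, and all three reorganization-energy estimators agree in
#' expectation.
#'
#' @param delta_a ground-truth oxidation free-energy gap in eV.
#' @param lam reorganization energy lambda in eV (>= 0).
#' @param kT_eV thermal energy in eV.
#' @param n ensemble size (>= 2).
#' @param seed integer seed (R's Mersenne-Twister); the VIE ensemble is
#'   drawn first, then the VAE ensemble. Identical seeds give
#'   bit-identical output.
#' @param species,solvent_model,method_tag ensemble metadata.
#' @return list with elements `vie` and `vae` ([gap_ensemble()]s) plus
#'   `sigma`, the common population standard deviation.
#' @export
sample_linear_response <- function(delta_a, lam,
                                   kT_eV = energy_constants()$kT_eV,
                                   n = 200L, seed = 1L,
                                   species = "synthetic",
                                   solvent_model = "implicit",
                                   method_tag = "synthetic-linear") {
  stopifnot(lam >= 0, n >= 2, kT_eV > 0)
  sigma <- sqrt(2 * lam * kT_eV)
  vals <- .with_seed(seed, list(
    vie = stats::rnorm(n, delta_a + lam, sigma),
    vae = stats::rnorm(n, delta_a - lam, sigma)
  ))
  list(
    vie = gap_ensemble(vals$vie, species, "VIE",
                       solvent_model = solvent_model,
                       method_tag = method_tag),
    vae = gap_ensemble(vals$vae, species, "VAE",
                       solvent_model = solvent_model,
                       method_tag = method_tag),
    sigma = sigma
  )
}

#' Sample a VIE/VAE pair violating linear response
#'
#' Controlled violations of the Marcus conditions: per-state
#' reorganization energies set the two widths independently
#' (sigma_state = sqrt(2 lam_state kT), so unequal lams give unequal
#' variances) and a nonzero `skew` replaces the Gaussian deviates with
#' standardised shifted-lognormal ones of that skewness. Means stay at
#' delta_a + lam_neutral (VIE) and delta_a - lam_cation (VAE).
#'
#' @param delta_a nominal free-energy gap in eV.
#' @param lam_neutral,lam_cation per-state reorganization energies in
#'   eV; must differ, or `skew` must be nonzero (otherwise use
#'   [sample_linear_response()]).
#' @param skew skewness of the gap distributions (0 = Gaussian).
#' @inheritParams sample_linear_response
#' @return list with `vie`, `vae`, `sigma_vie`, `sigma_vae`.
#' @export
sample_nonlinear <- function(delta_a, lam_neutral, lam_cation, skew = 0,
                             kT_eV = energy_constants()$kT_eV,
                             n = 200L, seed = 1L,
                             species = "synthetic",
                             solvent_model = "explicit",
                             method_tag = "synthetic-nonlinear") {
  stopifnot(lam_neutral >= 0, lam_cation >= 0, n >= 2, kT_eV > 0)
  if (lam_neutral == lam_cation && skew == 0) {
    stop("equal per-state lambdas with zero skew is the linear-response ",
         "regime; use sample_linear_response()", call. = FALSE)
  }
  s_vie <- sqrt(2 * lam_neutral * kT_eV)
  s_vae <- sqrt(2 * lam_cation * kT_eV)
  draw <- function(n) if (skew == 0) stats::rnorm(n) else .rskewed(n, skew)
  vals <- .with_seed(seed, list(
    vie = delta_a + lam_neutral + s_vie * draw(n),
    vae = delta_a - lam_cation + s_vae * draw(n)
  ))
  list(
    vie = gap_ensemble(vals$vie, species, "VIE",
                       solvent_model = solvent_model,
                       method_tag = method_tag),
    vae = gap_ensemble(vals$vae, species, "VAE",
                       solvent_model = solvent_model,
                       method_tag = method_tag),
    sigma_vie = s_vie, sigma_vae = s_vae
  )
}

#' Mock static energy records with a known ground-truth potential
#'
#' Solves the inverse problem of the static protocols: builds a
#' self-consistent record set (gas and solvent phases, both charge
#' states, E_e and G_T) such that [static_direct()] returns
#' `target_potential_V` exactly and the thermodynamic-cycle components
#' equal the prescribed solvation shifts. Solvent-phase electronic
#' energies at the gas-optimized geometry are set equal to those at the
#' solvent-optimized geometry, so cycle 1 and cycle 2 coincide on mock
#' records.
#'
#' @param target_potential_V ground-truth potential in volts.
#' @param solvation_shifts_eV length-2 numeric, solvation free energies
#'   of the neutral and cation species in eV.
#' @param thermal_terms_eV length-4 numeric: G_T for (neutral gas,
#'   cation gas, neutral solvent, cation solvent) in eV.
#' @param constants an [energy_constants()] object.
#' @param species,method_tag record metadata.
#' @param base_energy_eV arbitrary absolute scale of the electronic
#'   energies (cancels in every protocol).
#' @return a [species_energy_records()] set.
#' @export
mock_static_records <- function(target_potential_V,
                                solvation_shifts_eV = c(neutral = -0.3,
                                                        cation = -1.5),
                                thermal_terms_eV = c(neutral_gas = 0.05,
                                                     cation_gas = 0.05,
                                                     neutral_solvent = 0.05,
                                                     cation_solvent = 0.05),
                                constants = energy_constants(),
                                species = "MOCK", method_tag = "mock",
                                base_energy_eV = -7000) {
  stopifnot(length(solvation_shifts_eV) == 2, length(thermal_terms_eV) == 4,
            all(is.finite(c(target_potential_V, solvation_shifts_eV,
                            thermal_terms_eV, base_energy_eV))))
  dgs_n <- solvation_shifts_eV[[1]]
  dgs_c <- solvation_shifts_eV[[2]]
  gt_ngas <- thermal_terms_eV[[1]]; gt_cgas <- thermal_terms_eV[[2]]
  gt_nsol <- thermal_terms_eV[[3]]; gt_csol <- thermal_terms_eV[[4]]

  # Invert E_red = -dG_red - E_SHE with
  # dG_red = [E_e(N)+G_T(N)] - [E_e(N+)+G_T(N+)] - G_c(e-).
  dg_red <- -(target_potential_V + constants$she_potential_V)
  ee_csol <- base_energy_eV
  ee_nsol <- dg_red + constants$electron_free_energy_eV +
    ee_csol + gt_csol - gt_nsol
  ee_ngas <- ee_nsol - dgs_n
  ee_cgas <- ee_csol - dgs_c

  row <- function(charge, phase, geometry, quantity, value) {
    data.frame(species = species, charge_state = charge, phase = phase,
               geometry = geometry, quantity = quantity, value = value,
               unit = "eV", method_tag = method_tag,
               stringsAsFactors = FALSE)
  }
  df <- rbind(
    row("neutral", "solvent", "solvent_optimized", "E_e", ee_nsol),
    row("cation",  "solvent", "solvent_optimized", "E_e", ee_csol),
    row("neutral", "solvent", "solvent_optimized", "G_T", gt_nsol),
    row("cation",  "solvent", "solvent_optimized", "G_T", gt_csol),
    row("neutral", "gas", "gas_optimized", "E_e", ee_ngas),
    row("cation",  "gas", "gas_optimized", "E_e", ee_cgas),
    row("neutral", "gas", "gas_optimized", "G_T", gt_ngas),
    row("cation",  "gas", "gas_optimized", "G_T", gt_cgas),
    row("neutral", "solvent", "gas_optimized", "E_e", ee_nsol),
    row("cation",  "solvent", "gas_optimized", "E_e", ee_csol)
  )
  species_energy_records(df)
}
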