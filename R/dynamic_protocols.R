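# Dynamic protocols: ensemble averages over sampled geometries replace
# the explicit thermal correction of the static routes. Two estimators:
# the direct difference of total-energy averages, and the Marcus
# linear-response half-sum of the mean vertical gaps.

.dynamic_result <- function(species, protocol, solvent_model, delta_g_eV,
                            spread_V, n_used, constants, extra = list()) {
  out <- c(list(
    species = species,
    protocol = protocol,
    solvent_model = solvent_model,
    delta_g_eV = delta_g_eV,
    potential_V = potential_vs_she(delta_g_eV, 1L, constants),
    spread_V = spread_V,
    n_snapshots_used = n_used
  ), extra)
  class(out) <- "dynamic_result"
  out
}

#' @export
print.dynamic_result <- function(x, ...) {
  cat(sprintf("%s potential for %s (%s solvent): %.3f +/- %.3f V vs SHE\n",
              x$protocol, x$species, x$solvent_model, x$potential_V,
              x$spread_V))
  cat(sprintf("  Delta G_red = %.4f eV over %s snapshots\n", x$delta_g_eV,
              paste(x$n_snapshots_used, collapse = " + ")))
  invisible(x)
}

#' Dynamic direct oxidation potential
#'
#' Direct estimator from two total-energy ensembles sampled in their own
#' phase spaces: Delta G_red = <E(N)>_N - <E(N+)>_N+ - G_c(e-). The
#' spread is the quadrature sum of the two ensemble standard deviations,
#' expressed in volts.
#'
#' @param neutral_energies,cation_energies [gap_ensemble()] objects of
#'   kind `total_potential_energy`, sampled on the neutral and cation
#'   states respectively, with matching solvent models.
#' @param constants an [energy_constants()] object.
#' @return a `dynamic_result` with protocol `dynamic_direct`.
#' @export
dynamic_direct <- function(neutral_energies, cation_energies,
                           constants = energy_constants()) {
  .check_pair(neutral_energies, cation_energies,
              c("total_potential_energy", "total_potential_energy"))
  if (neutral_energies$sampled_state != "neutral" ||
      cation_energies$sampled_state != "cation") {
    stop("dynamic_direct expects ensembles sampled on (neutral, cation) ",
         "states, got (", neutral_energies$sampled_state, ", ",
         cation_energies$sampled_state, ")", call. = FALSE)
  }
  sn <- ensemble_mean_sd(neutral_energies)
  sc <- ensemble_mean_sd(cation_energies)
  dg <- sn$mean - sc$mean - constants$electron_free_energy_eV
  .dynamic_result(neutral_energies$species, "dynamic_direct",
                  neutral_energies$solvent_model, dg,
                  sqrt(sn$sd^2 + sc$sd^2),
                  c(length(neutral_energies$values),
                    length(cation_energies$values)),
                  constants)
}

#' Dynamic Marcus oxidation potential
#'
#' Linear-response estimator: assuming the solvent responds linearly to
#' the change in solute charge, both vertical-gap distributions are
#' Gaussian with equal variance and the oxidation free energy is the
#' half-sum of their means, Delta A_ox = (<VIE> + <VAE>)/2. The
#' reduction free energy entering [potential_vs_she()] is then
#' -Delta A_ox - G_c(e-). The spread is the half-quadrature of the two
#' gap standard deviations, in volts.
#'
#' Whether the linear-response assumption actually holds for a given
#' pair should be checked with [linear_response_report()]; when it does
#' not, [matyushov_voth_corrected()] provides a nonlinear-response
#' estimate.
#'
#' @param vie VIE [gap_ensemble()] (sampled on the neutral state).
#' @param vae VAE [gap_ensemble()] (sampled on the cation state), same
#'   species and solvent model.
#' @param constants an [energy_constants()] object.
#' @return a `dynamic_result` with protocol `dynamic_marcus` and extra
#'   elements `mean_vie_eV`, `mean_vae_eV`, `gap_eV`, `lambda_eV`.
#' @examples
#' # printed guanine example: <VIE> = 5.30 eV, <VAE> = 4.90 eV -> 0.78 V
#' vie <- gap_ensemble(c(5.25, 5.35), "G", "VIE")
#' vae <- gap_ensemble(c(4.85, 4.95), "G", "VAE")
#' marcus_free_energy(vie, vae)$potential_V
#' @export
marcus_free_energy <- function(vie, vae, constants = energy_constants()) {
  .check_pair(vie, vae, c("VIE", "VAE"))
  sv <- ensemble_mean_sd(vie)
  sa <- ensemble_mean_sd(vae)
  gap <- (sv$mean + sa$mean) / 2
  dg <- -gap - constants$electron_free_energy_eV
  .dynamic_result(vie$species, "dynamic_marcus", vie$solvent_model, dg,
                  sqrt(sv$sd^2 + sa$sd^2) / 2,
                  c(length(vie$values), length(vae$values)),
                  constants,
                  extra = list(mean_vie_eV = sv$mean, mean_vae_eV = sa$mean,
                               gap_eV = gap,
                               lambda_eV = (sv$mean - sa$mean) / 2))
}

# Run one estimator on a subsampled ensemble pair.
.subsample_estimate <- function(a, b, estimator, idx_a, idx_b, constants) {
  sub <- function(e, idx) {
    gap_ensemble(e$values[idx], e$species, e$gap_kind, e$sampled_state,
                 e$solvent_model, e$method_tag)
  }
  r <- if (estimator == "marcus") {
    marcus_free_energy(sub(a, idx_a), sub(b, idx_b), constants)
  } else {
    dynamic_direct(sub(a, idx_a), sub(b, idx_b), constants)
  }
  r$potential_V
}

#' Convergence of a dynamic potential with the number of snapshots
#'
#' Recomputes a dynamic estimator on seeded random subsamples (without
#' replacement, mirroring snapshots fetched randomly from a trajectory)
#' of increasing size n = step, 2 step, ..., up to the full ensembles.
#' The final point always uses every snapshot, so the curve ends at the
#' full-ensemble potential. Deterministic for a given seed
#' (Mersenne-Twister, R's default generator).
#'
#' @param ens_a,ens_b the ensemble pair: (VIE, VAE) for
#'   `estimator = "marcus"`, (neutral, cation) total energies for
#'   `estimator = "direct"`.
#' @param estimator `"marcus"` or `"direct"`.
#' @param step subsample-size increment (>= 1, at most the shorter
#'   ensemble length).
#' @param seed integer seed for the subsampling.
#' @param constants an [energy_constants()] object.
#' @return a `convergence_curve`: `n_values` (increasing integers) and
#'   `running_potentials` (volts), plus metadata.
#' @export
convergence_curve <- function(ens_a, ens_b,
                              estimator = c("marcus", "direct"),
                              step = 10L, seed = 1L,
                              constants = energy_constants()) {
  estimator <- match.arg(estimator)
  kinds <- if (estimator == "marcus") c("VIE", "VAE") else
    c("total_potential_energy", "total_potential_energy")
  .check_pair(ens_a, ens_b, kinds)
  na <- length(ens_a$values); nb <- length(ens_b$values)
  n_max <- min(na, nb)
  if (!is.numeric(step) || step < 1 || step != round(step)) {
    stop("step must be a positive integer", call. = FALSE)
  }
  if (step > n_max) {
    stop("step (", step, ") exceeds the ensemble length (", n_max, ")",
         call. = FALSE)
  }
  grid <- seq.int(step, n_max, by = step)
  if (grid[length(grid)] != n_max) grid <- c(grid, n_max)
  pots <- .with_seed(seed, {
    vapply(grid, function(n) {
      idx_a <- if (n == n_max && n == na) seq_len(na) else sample.int(na, n)
      idx_b <- if (n == n_max && n == nb) seq_len(nb) else sample.int(nb, n)
      .subsample_estimate(ens_a, ens_b, estimator, idx_a, idx_b, constants)
    }, numeric(1))
  })
  out <- list(species = ens_a$species, estimator = estimator,
              n_values = as.integer(grid), running_potentials = pots,
              seed = as.integer(seed))
  class(out) <- "convergence_curve"
  out
}

#' @export
print.convergence_curve <- function(x, ...) {
  cat(sprintf("Convergence curve (%s, %s): %d points, n = %d..%d\n",
              x$species, x$estimator, length(x$n_values),
              min(x$n_values), max(x$n_values)))
  cat(sprintf("  final potential %.3f V (seed %d)\n",
              x$running_potentials[length(x$running_potentials)], x$seed))
  invisible(x)
}

#' Snapshot count at which a convergence curve stabilises
#'
#' Returns the smallest n such that every running potential over the
#' trailing `window` curve points lies within `tol` volts of their mean,
#' or `NA` if the curve never settles.
#'
#' @param curve a [convergence_curve()].
#' @param window number of trailing points that must agree (>= 2).
#' @param tol half-width of the agreement band in volts. The defaults
#'   (window 5, 0.02 V) resolve the contrast between continuum-like
#'   ensembles (sd ~ 0.1 eV, settling within a few tens of snapshots)
#'   and explicit-solvent-like ensembles (sd ~ 1 eV, needing on the
#'   order of a hundred).
#' @return integer snapshot count, or `NA_integer_` if not converged.
#' @export
converged_at <- function(curve, window = 5L, tol = 0.02) {
  stopifnot(inherits(curve, "convergence_curve"))
  if (!is.numeric(window) || window < 2 || window != round(window)) {
    stop("window must be an integer >= 2", call. = FALSE)
  }
  stopifnot(is.numeric(tol), tol > 0)
  v <- curve$running_potentials
  if (length(v) < window) return(NA_integer_)
  for (k in seq.int(window, length(v))) {
    w <- v[(k - window + 1):k]
    if (all(abs(w - mean(w)) <= tol)) return(curve$n_values[k])
  }
  NA_integer_
}
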