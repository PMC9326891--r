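# Tautomer populations and the population-weighted ensemble potential.
# In protic solvents several tautomers of one parent species coexist;
# their populations are assumed Boltzmann-distributed and the observable
# potential is a weighted combination of per-tautomer reduction
# equilibrium constants.

#' Boltzmann populations from relative free energies
#'
#' chi_k = exp(-dG_k / kT) / sum_j exp(-dG_j / kT). Invariant to
#' shifting all energies by a common constant; `Inf` is accepted as a
#' sentinel for an inaccessible tautomer (population 0).
#'
#' @param relative_free_energies_eV free energies relative to any common
#'   reference, in eV (at least one, not all infinite).
#' @param kT_eV thermal energy in eV (> 0).
#' @return population fractions summing to 1.
#' @examples
#' boltzmann_populations(c(0, 0.1037))   # c(0.983, 0.017)
#' @export
boltzmann_populations <- function(relative_free_energies_eV,
                                  kT_eV = energy_constants()$kT_eV) {
  dg <- relative_free_energies_eV
  if (length(dg) < 1 || anyNA(dg)) {
    stop("need at least one finite relative free energy", call. = FALSE)
  }
  if (!is.numeric(kT_eV) || kT_eV <= 0) stop("kT must be positive", call. = FALSE)
  if (all(!is.finite(dg))) stop("all free energies infinite", call. = FALSE)
  w <- exp(-(dg - min(dg[is.finite(dg)])) / kT_eV)
  w[!is.finite(dg)] <- 0
  w / sum(w)
}

#' Relative free energies from populations
#'
#' Inverse of [boltzmann_populations()] up to the reference shift:
#' dG_k = -kT ln(chi_k / chi_1), so the first tautomer is the zero
#' reference. Used to rescale low-level tautomer energies so that they
#' reproduce populations from a higher level of theory.
#'
#' @param populations strictly positive fractions (renormalised
#'   internally).
#' @param kT_eV thermal energy in eV (> 0).
#' @return relative free energies in eV, first element 0.
#' @export
populations_to_relative_energies <- function(populations,
                                             kT_eV = energy_constants()$kT_eV) {
  if (!is.numeric(kT_eV) || kT_eV <= 0) stop("kT must be positive", call. = FALSE)
  if (any(populations <= 0)) {
    stop("populations must be strictly positive (log undefined at zero)",
         call. = FALSE)
  }
  p <- populations / sum(populations)
  -kT_eV * log(p / p[1])
}

#' Assemble a tautomer set
#'
#' Collects per-tautomer potentials and neutral/cation populations for
#' one parent species. Population vectors must lie in \[0, 1\] and are
#' renormalised to sum to 1 (with a warning when the printed inputs sum
#' elsewhere, e.g. when minor tautomers were dropped upstream).
#'
#' @param parent_species parent identifier (e.g. `"A"`, `"G"`).
#' @param labels tautomer labels.
#' @param potential_V per-tautomer one-electron oxidation potentials in
#'   volts.
#' @param population_neutral,population_cation population fractions of
#'   each tautomer in the reduced (neutral) and oxidized (cation) forms.
#' @param min_population drop tautomers whose neutral and cation
#'   populations are both below this fraction (populations are then
#'   renormalised); default 0 keeps all members.
#' @return a `tautomer_set`.
#' @export
tautomer_set <- function(parent_species, labels, potential_V,
                         population_neutral, population_cation,
                         min_population = 0) {
  n <- length(labels)
  stopifnot(n >= 1, length(potential_V) == n,
            length(population_neutral) == n,
            length(population_cation) == n)
  for (nm in c("population_neutral", "population_cation")) {
    p <- get(nm)
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
      stop(nm, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (anyNA(potential_V)) {
    stop("missing potential for tautomer '", labels[which(is.na(potential_V))[1]],
         "'", call. = FALSE)
  }
  if (min_population > 0) {
    keep <- population_neutral >= min_population |
      population_cation >= min_population
    if (!any(keep)) stop("min_population filter removed every tautomer",
                         call. = FALSE)
    labels <- labels[keep]; potential_V <- potential_V[keep]
    population_neutral <- population_neutral[keep]
    population_cation <- population_cation[keep]
  }
  renorm <- function(p, nm) {
    s <- sum(p)
    if (s <= 0) stop(nm, " sums to zero", call. = FALSE)
    if (abs(s - 1) > 1e-6) {
      warning(nm, " sums to ", format(s), "; renormalising to 1",
              call. = FALSE)
    }
    p / s
  }
  out <- list(
    parent_species = as.character(parent_species),
    members = data.frame(
      label = as.character(labels),
      potential_V = as.numeric(potential_V),
      population_neutral = renorm(population_neutral, "population_neutral"),
      population_cation = renorm(population_cation, "population_cation"),
      stringsAsFactors = FALSE
    )
  )
  class(out) <- "tautomer_set"
  out
}

#' Read a tautomer set from JSON
#'
#' Schema: an object with `parent_species` and `members`, an array of
#' objects with `label`, `potential_V`, `population_neutral`,
#' `population_cation`.
#'
#' @param path JSON file.
#' @param min_population passed to [tautomer_set()].
#' @return a `tautomer_set`.
#' @export
read_tautomer_set <- function(path, min_population = 0) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- jsonlite::fromJSON(path)
  need <- c("label", "potential_V", "population_neutral", "population_cation")
  missing_cols <- setdiff(need, names(x$members))
  if (is.null(x$parent_species) || length(missing_cols) > 0) {
    stop("tautomer-set JSON needs parent_species and members with fields ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  tautomer_set(x$parent_species, x$members$label, x$members$potential_V,
               x$members$population_neutral, x$members$population_cation,
               min_population = min_population)
}

#' @export
print.tautomer_set <- function(x, ...) {
  cat(sprintf("Tautomer set for %s (%d member%s)\n", x$parent_species,
              nrow(x$members), if (nrow(x$members) == 1) "" else "s"))
  print(x$members, row.names = FALSE)
  invisible(x)
}

# log(sum(w * exp(x))) with overflow protection.
.log_sum_wexp <- function(x, w) {
  m <- max(x)
  m + log(sum(w * exp(x - m)))
}

#' Tautomer-population-weighted oxidation potential
#'
#' Combines per-tautomer potentials into the observable potential of the
#' tautomeric mixture by averaging reduction equilibrium constants
#' K_j = exp(F E_j / RT): the constants are averaged under the oxidized
#' (cation) populations and their reciprocals under the reduced
#' (neutral) populations, and the ensemble potential is the half-sum of
#' the two resulting log-mean estimates,
#' E = (kT/2) \[ln sum_i chi_i e^{E_i/kT} - ln sum_j chi'_j e^{-E_j/kT}\].
#' For populations Boltzmann-consistent with the potentials the two
#' estimates coincide and the expression is thermodynamically exact;
#' when every member has the same potential it returns that potential
#' regardless of the populations.
#'
#' @param ts a [tautomer_set()].
#' @param constants an [energy_constants()] object.
#' @return ensemble potential in volts; always within the range of the
#'   member potentials.
#' @export
ensemble_potential <- function(ts, constants = energy_constants()) {
  stopifnot(inherits(ts, "tautomer_set"))
  m <- ts$members
  kT <- constants$kT_eV
  e_ox <- kT * .log_sum_wexp(m$potential_V / kT, m$population_cation)
  e_red <- -kT * .log_sum_wexp(-m$potential_V / kT, m$population_neutral)
  (e_ox + e_red) / 2
}
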