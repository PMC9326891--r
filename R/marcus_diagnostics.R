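# Validity diagnostics for the Marcus linear-response regime, the
# energy-gap distribution / free-energy surface construction, and the
# quadratic-coupling correction for nonlinear solvation response.

#' Reorganization energy from the two mean gaps
#'
#' lambda = (<VIE> - <VAE>)/2: half the Stokes shift between the forward
#' and backward vertical gaps.
#'
#' @param mean_vie_eV,mean_vae_eV ensemble-average gaps in eV.
#' @return reorganization energy in eV.
#' @examples
#' reorganization_from_gaps(5.30, 4.90)   # 0.20
#' @export
reorganization_from_gaps <- function(mean_vie_eV, mean_vae_eV) {
  (mean_vie_eV - mean_vae_eV) / 2
}

#' Reorganization energy from gap fluctuations
#'
#' Under linear response, the gap variance in either state carries the
#' same reorganization energy: lambda = sigma^2 / (2 kT).
#'
#' @param sigma_eV gap standard deviation in eV (>= 0).
#' @param kT_eV thermal energy in eV (> 0).
#' @return reorganization energy in eV.
#' @export
reorganization_from_variance <- function(sigma_eV,
                                         kT_eV = energy_constants()$kT_eV) {
  stopifnot(is.numeric(sigma_eV), all(sigma_eV >= 0))
  if (!is.numeric(kT_eV) || any(kT_eV <= 0)) {
    stop("kT must be positive", call. = FALSE)
  }
  sigma_eV^2 / (2 * kT_eV)
}

# Normality test p-value; Shapiro-Wilk up to its implementation limit,
# Anderson-Darling beyond.
.normality_p <- function(x) {
  if (length(x) <= 5000) {
    stats::shapiro.test(x)$p.value
  } else {
    nortest::ad.test(x)$p.value
  }
}

.gaussian_verdict <- function(x, tol) {
  sk <- e1071::skewness(x)
  ku <- e1071::kurtosis(x)   # excess kurtosis
  p <- .normality_p(x)
  moments_ok <- abs(sk) <= tol$skew && abs(ku) <= tol$kurtosis
  test_ok <- p >= tol$alpha
  # Flag non-Gaussian only when the moment screen and the significance
  # test agree: either alone has a non-negligible false-alarm rate at
  # typical ensemble sizes (n ~ 200).
  list(pass = moments_ok || test_ok, skewness = sk, excess_kurtosis = ku,
       p_value = p)
}

#' Test the Marcus linear-response conditions on a VIE/VAE pair
#'
#' Three conditions must hold for the Marcus half-sum to be valid:
#' (i) both gap distributions are Gaussian, (ii) their standard
#' deviations are equal, and (iii) the reorganization energy from the
#' mean gaps ([reorganization_from_gaps()]) agrees with the
#' fluctuation-based estimates of both states
#' ([reorganization_from_variance()]). Each condition is reported as a
#' pass/fail verdict with its statistic; the overall `regime` is
#' `"marcus"` only when all verdicts pass.
#'
#' A distribution is flagged non-Gaussian when it both violates a
#' moment bound (|skewness| > `skew`, |excess kurtosis| > `kurtosis`)
#' and fails the normality test at level `alpha`; requiring agreement
#' keeps the false-alarm rate on genuinely Gaussian ensembles near 1%.
#'
#' @param vie,vae matched [gap_ensemble()] pair (each with >= 8 values;
#'   the tests are undefined below that).
#' @param constants an [energy_constants()] object.
#' @param tolerances named list overriding any of: `skew` (0.5),
#'   `kurtosis` (1.0), `alpha` (0.05), `sigma_ratio` (1.25, maximum
#'   allowed max(sigma)/min(sigma)), `lambda_rel` (0.25, maximum
#'   relative disagreement between each fluctuation-based lambda and the
#'   gap-based lambda).
#' @return a `marcus_diagnostics` object: sigmas, the three lambda
#'   estimates, the four verdicts with statistics, and `regime`
#'   (`"marcus"` / `"non_marcus"`).
#' @export
linear_response_report <- function(vie, vae, constants = energy_constants(),
                                   tolerances = list()) {
  .check_pair(vie, vae, c("VIE", "VAE"))
  if (length(vie$values) < 8 || length(vae$values) < 8) {
    stop("linear-response diagnostics need at least 8 snapshots per ",
         "ensemble", call. = FALSE)
  }
  tol <- utils::modifyList(
    list(skew = 0.5, kurtosis = 1.0, alpha = 0.05,
         sigma_ratio = 1.25, lambda_rel = 0.25),
    tolerances
  )
  sv <- ensemble_mean_sd(vie)
  sa <- ensemble_mean_sd(vae)
  g_vie <- .gaussian_verdict(vie$values, tol)
  g_vae <- .gaussian_verdict(vae$values, tol)
  sigma_equal <- max(sv$sd, sa$sd) <= tol$sigma_ratio * min(sv$sd, sa$sd)

  lam_gap <- reorganization_from_gaps(sv$mean, sa$mean)
  lam_n <- reorganization_from_variance(sv$sd, constants$kT_eV)
  lam_c <- reorganization_from_variance(sa$sd, constants$kT_eV)
  lam_ok <- function(lam_state) {
    denom <- max(abs(lam_gap), abs(lam_state), .Machine$double.eps)
    abs(lam_state - lam_gap) <= tol$lambda_rel * denom
  }
  lambda_consistent <- lam_ok(lam_n) && lam_ok(lam_c)

  verdict <- function(ok) if (ok) "pass" else "fail"
  out <- list(
    species = vie$species,
    solvent_model = vie$solvent_model,
    sigma_vie_eV = sv$sd, sigma_vae_eV = sa$sd,
    lambda_gap_eV = lam_gap, lambda_neutral_eV = lam_n,
    lambda_cation_eV = lam_c,
    gaussian_vie = verdict(g_vie$pass), gaussian_vie_stats = g_vie,
    gaussian_vae = verdict(g_vae$pass), gaussian_vae_stats = g_vae,
    sigma_equal = verdict(sigma_equal),
    lambda_consistent = verdict(lambda_consistent),
    tolerances = tol
  )
  all_pass <- g_vie$pass && g_vae$pass && sigma_equal && lambda_consistent
  out$regime <- if (all_pass) "marcus" else "non_marcus"
  class(out) <- "marcus_diagnostics"
  out
}

#' @export
print.marcus_diagnostics <- function(x, ...) {
  cat(sprintf("Marcus linear-response diagnostics: %s (%s solvent)\n",
              x$species, x$solvent_model))
  cat(sprintf("  sigma_VIE = %.3f eV, sigma_VAE = %.3f eV  [sigma_equal: %s]\n",
              x$sigma_vie_eV, x$sigma_vae_eV, x$sigma_equal))
  cat(sprintf("  lambda: gap %.3f, neutral %.3f, cation %.3f eV  [consistent: %s]\n",
              x$lambda_gap_eV, x$lambda_neutral_eV, x$lambda_cation_eV,
              x$lambda_consistent))
  cat(sprintf("  Gaussian shape: VIE %s (skew %.2f, p %.3f), VAE %s (skew %.2f, p %.3f)\n",
              x$gaussian_vie, x$gaussian_vie_stats$skewness,
              x$gaussian_vie_stats$p_value,
              x$gaussian_vae, x$gaussian_vae_stats$skewness,
              x$gaussian_vae_stats$p_value))
  cat("  regime:", x$regime, "\n")
  invisible(x)
}

#' Energy-gap distribution and free-energy surface
#'
#' Histograms the mean-centered gaps Delta E_mu of one ensemble and
#' converts the relative populations p(Delta E_mu) into free energies
#' A(Delta E_mu) = -kT ln p(Delta E_mu). Empty bins carry an undefined
#' free energy, flagged by `occupied = FALSE`. For a Gaussian ensemble A
#' is a parabola with curvature kT/(2 sigma^2).
#'
#' @param ens a [gap_ensemble()] (>= 2 values).
#' @param n_bins number of equal-width bins (>= 3); by default chosen by
#'   the Freedman-Diaconis rule.
#' @param constants an [energy_constants()] object (supplies kT).
#' @return a `gap_distribution` data frame with columns `center` (eV,
#'   mean-centered), `p` (populations summing to 1), `A_eV`, `occupied`.
#' @export
gap_distribution <- function(ens, n_bins = NULL,
                             constants = energy_constants()) {
  stopifnot(inherits(ens, "gap_ensemble"))
  x <- ens$values - mean(ens$values)
  n <- length(x)
  if (n < 2) stop("gap_distribution needs at least 2 values", call. = FALSE)
  if (is.null(n_bins)) {
    iqr <- stats::IQR(x)
    h <- 2 * iqr / n^(1 / 3)     # Freedman-Diaconis
    span <- diff(range(x))
    n_bins <- if (h <= 0 || span <= 0) 3L else max(3L, ceiling(span / h))
  }
  if (!is.numeric(n_bins) || n_bins < 3) {
    stop("n_bins must be >= 3", call. = FALSE)
  }
  span <- diff(range(x))
  eps <- if (span > 0) span * 1e-9 else 1e-9
  breaks <- seq(min(x) - eps, max(x) + eps, length.out = n_bins + 1)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  p <- counts / n
  out <- data.frame(
    center = (breaks[-1] + breaks[-length(breaks)]) / 2,
    p = p,
    A_eV = ifelse(p > 0, -constants$kT_eV * log(p), NA_real_),
    occupied = p > 0
  )
  attr(out, "species") <- ens$species
  attr(out, "gap_kind") <- ens$gap_kind
  class(out) <- c("gap_distribution", "data.frame")
  out
}

# ---------------------------------------------------------------------
# Quadratic-coupling (Matyushov-Voth) correction for nonlinear response.
#
# Model: a single Gaussian solvent mode q with state-dependent force
# constants k1 (initial state, sampled by the VIE ensemble) and k2
# (final state, VAE ensemble), minima separated by q0, energy offset
# dI. The vertical gap X = E2 - E1 is quadratic in q, which makes the
# free-energy surfaces along X non-parabolic and the two gap variances
# unequal. Gauge freedom in scaling q leaves three invariant
# parameters: r = k2/k1 (curvature ratio), z = k1 q0^2 (displacement
# energy), and dI. They are fitted to the variance ratio and the Stokes
# shift; the free-energy gap then follows exactly from the two
# harmonic partition functions:
#   dA = (m1 + m2)/2 - kT (r^2 - 1)/(4 r) - z (r - 1)/4 + (kT/2) ln r.
# At r = 1 every correction term vanishes and the Marcus half-sum is
# recovered; swapping which ensemble carries the larger variance maps
# r -> 1/r, z -> z r and flips the sign of the correction exactly.

# Model moments for gauge-fixed parameters (r, z) at thermal energy kT.
.qc_moments <- function(r, z, kT) {
  list(
    stokes = -kT * (r - 1)^2 / (2 * r) + (1 + r) * z / 2,
    var1 = kT^2 * (r - 1)^2 / 2 + r^2 * z * kT,
    var2 = kT^2 * (r - 1)^2 / (2 * r^2) + z * kT / r
  )
}

# Solve for (r, z) given the observed Stokes shift and variance ratio.
.qc_fit <- function(stokes, s1, s2, kT) {
  if (stokes <= 0) {
    stop("quadratic-coupling model undefined: mean VIE must exceed mean ",
         "VAE (observed Stokes shift ", format(stokes), " eV <= 0)",
         call. = FALSE)
  }
  z_of_r <- function(r) 2 * (stokes + kT * (r - 1)^2 / (2 * r)) / (1 + r)
  if (abs(s1 - s2) <= 1e-12 * max(s1, s2)) {
    return(list(r = 1, z = z_of_r(1)))
  }
  target <- (s1 / s2)^2
  f <- function(lr) {
    r <- exp(lr)
    m <- .qc_moments(r, z_of_r(r), kT)
    log(m$var1 / m$var2) - log(target)
  }
  # var1/var2 ~ r^3 for displacements large against kT, so bracket
  # around the cube-root guess.
  lr0 <- (2 / 3) * log(s1 / s2)
  lo <- lr0 - 5; hi <- lr0 + 5
  flo <- f(lo); fhi <- f(hi)
  tries <- 0
  while (flo * fhi > 0 && tries < 20) {
    lo <- lo - 2; hi <- hi + 2
    flo <- f(lo); fhi <- f(hi)
    tries <- tries + 1
  }
  if (flo * fhi > 0) {
    stop("no quadratic-coupling parameterisation reproduces this ",
         "variance ratio; inputs outside the model's validity domain",
         call. = FALSE)
  }
  r <- exp(stats::uniroot(f, c(lo, hi), tol = 1e-14)$root)
  z <- z_of_r(r)
  if (!is.finite(r) || r <= 0 || !is.finite(z) || z <= 0) {
    stop("quadratic-coupling fit left the model's validity domain ",
         "(requires positive curvature ratio and displacement energy)",
         call. = FALSE)
  }
  list(r = r, z = z)
}

#' Nonlinear-response corrected dynamic potential
#'
#' Replaces the Marcus half-sum when the linear-response conditions
#' fail, using a three-parameter quadratic-coupling model of the
#' solvent mode (state-dependent force constants, after Matyushov and
#' Voth) that accommodates unequal VIE/VAE variances. The model's
#' gauge-invariant parameters are fitted to the observed Stokes shift
#' and variance ratio; the free-energy gap follows in closed form from
#' the model's partition functions. When the two sample standard
#' deviations are equal the correction vanishes identically and the
#' result equals [marcus_free_energy()].
#'
#' Fails explicitly (never falls back silently) when the ensembles
#' cannot be represented by the model: non-positive Stokes shift, or no
#' positive curvature-ratio/displacement solution.
#'
#' @inheritParams marcus_free_energy
#' @return a `dynamic_result` with protocol `dynamic_marcus_corrected`
#'   and extra elements `correction_eV` (the shift applied to the Marcus
#'   gap) and `model_parameters` (curvature ratio `r`, displacement
#'   energy `z_eV`, and the residual mismatch of the absolute variance
#'   scale, which the three-parameter fit does not constrain).
#' @export
matyushov_voth_corrected <- function(vie, vae,
                                     constants = energy_constants()) {
  .check_pair(vie, vae, c("VIE", "VAE"))
  sv <- ensemble_mean_sd(vie)
  sa <- ensemble_mean_sd(vae)
  kT <- constants$kT_eV
  fit <- .qc_fit(sv$mean - sa$mean, sv$sd, sa$sd, kT)
  r <- fit$r; z <- fit$z
  correction <- -kT * (r^2 - 1) / (4 * r) - z * (r - 1) / 4 +
    (kT / 2) * log(r)
  gap <- (sv$mean + sa$mean) / 2 + correction
  dg <- -gap - constants$electron_free_energy_eV
  mom <- .qc_moments(r, z, kT)
  .dynamic_result(vie$species, "dynamic_marcus_corrected",
                  vie$solvent_model, dg,
                  sqrt(sv$sd^2 + sa$sd^2) / 2,
                  c(length(vie$values), length(vae$values)),
                  constants,
                  extra = list(
                    mean_vie_eV = sv$mean, mean_vae_eV = sa$mean,
                    gap_eV = gap, correction_eV = correction,
                    model_parameters = list(
                      r = r, z_eV = z,
                      variance_scale_residual = sv$sd^2 / mom$var1
                    )))
}

#' Jackknife agreement between gap- and fluctuation-based lambda
#'
#' Paired delete-one jackknife for the differences D_state =
#' lambda(gaps) - lambda_state(variance): deleting snapshot i from both
#' ensembles simultaneously gives a jackknife standard error for each
#' difference, so "the three reorganization energies agree" can be
#' stated as |D| within a few SEs. Requires equally long ensembles.
#'
#' @inheritParams marcus_free_energy
#' @return list with `d_neutral`, `d_cation` (eV), `se_neutral`,
#'   `se_cation` (jackknife SEs, eV) and `n`.
#' @export
reorganization_consistency <- function(vie, vae,
                                       constants = energy_constants()) {
  .check_pair(vie, vae, c("VIE", "VAE"))
  x <- vie$values; y <- vae$values
  n <- length(x)
  if (length(y) != n) {
    stop("paired jackknife needs equally long ensembles", call. = FALSE)
  }
  if (n < 8) stop("need at least 8 snapshots", call. = FALSE)
  kT <- constants$kT_eV
  stat <- function(xs, ys) {
    lam_gap <- (mean(xs) - mean(ys)) / 2
    c(lam_gap - stats::var(xs) / (2 * kT),
      lam_gap - stats::var(ys) / (2 * kT))
  }
  full <- stat(x, y)
  loo <- vapply(seq_len(n), function(i) stat(x[-i], y[-i]), numeric(2))
  se <- sqrt((n - 1) / n * rowSums((loo - rowMeans(loo))^2))
  list(d_neutral = full[1], d_cation = full[2],
       se_neutral = se[1], se_cation = se[2], n = n)
}
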