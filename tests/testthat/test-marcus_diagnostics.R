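test_that("reorganization energies follow their defining formulas", {
  expect_equal(reorganization_from_gaps(5.30, 4.90), 0.20)
  expect_equal(reorganization_from_gaps(8.09, 4.08), 2.005)
  expect_equal(reorganization_from_gaps(5, 5), 0)
  expect_equal(reorganization_from_variance(0), 0)
  expect_equal(reorganization_from_variance(0.10, 0.025693), 0.1946,
               tolerance = 1e-4)
  expect_error(reorganization_from_variance(0.1, kT_eV = 0), "positive")
  # generator identity sigma^2 = 2 lambda kT
  s <- sample_linear_response(5.10, 0.20, n = 5000, seed = 2)
  lam_hat <- reorganization_from_variance(sd(s$vie$values))
  expect_lt(abs(lam_hat - 0.20), 0.20 * 3 * sqrt(2 / 5000))
})

test_that("linear-response diagnostics separate the two regimes", {
  kT <- energy_constants()$kT_eV
  # linear-response data: all verdicts pass
  s <- sample_linear_response(5.10, 0.20, n = 200, seed = 1)
  d <- linear_response_report(s$vie, s$vae)
  expect_equal(d$regime, "marcus")
  expect_equal(d$sigma_equal, "pass")
  expect_equal(d$lambda_consistent, "pass")

  # sigma pair emulating explicit-solvent behaviour (0.81 vs 1.20 eV)
  nl <- sample_nonlinear(6.0, 0.81^2 / (2 * kT), 1.20^2 / (2 * kT),
                         n = 200, seed = 1)
  dn <- linear_response_report(nl$vie, nl$vae)
  expect_equal(dn$sigma_equal, "fail")
  expect_equal(dn$regime, "non_marcus")

  # heavily skewed ensembles fail the Gaussian-shape check
  sk <- sample_nonlinear(5.0, 0.20, 0.20, skew = 2.5, n = 200, seed = 3)
  ds <- linear_response_report(sk$vie, sk$vae)
  expect_equal(ds$gaussian_vie, "fail")
  expect_equal(ds$gaussian_vae, "fail")
  expect_equal(ds$regime, "non_marcus")

  short <- gap_ensemble(stats::rnorm(5), "X", "VIE")
  short2 <- gap_ensemble(stats::rnorm(5), "X", "VAE")
  expect_error(linear_response_report(short, short2), "at least 8")
})

test_that("the three lambda estimates agree within jackknife error on linear data", {
  s <- sample_linear_response(5.10, 0.20, n = 5000, seed = 17)
  j <- reorganization_consistency(s$vie, s$vae)
  expect_lt(abs(j$d_neutral), 3 * j$se_neutral)
  expect_lt(abs(j$d_cation), 3 * j$se_cation)
})

test_that("gap distributions normalise and flag empty bins", {
  # constant ensemble: one occupied bin with p = 1 and A = 0
  g0 <- gap_distribution(gap_ensemble(rep(5.3, 20), "X", "VIE"))
  expect_equal(sum(g0$p), 1, tolerance = 1e-9)
  occ <- g0[g0$occupied, ]
  expect_equal(nrow(occ), 1)
  expect_equal(occ$p, 1)
  expect_equal(occ$A_eV, 0)
  expect_true(all(is.na(g0$A_eV[!g0$occupied])))

  set.seed(5)
  v <- stats::rnorm(2000, 5.3, 0.1)
  g <- gap_distribution(gap_ensemble(v, "X", "VIE"))
  expect_equal(sum(g$p), 1, tolerance = 1e-9)
  # invariance under a constant shift of all gaps (mean-centering)
  g_shift <- gap_distribution(gap_ensemble(v + 2.34, "X", "VIE"))
  expect_equal(g$center, g_shift$center)
  expect_equal(g$A_eV, g_shift$A_eV)
  expect_error(gap_distribution(gap_ensemble(v, "X", "VIE"), n_bins = 2),
               "n_bins")
})

test_that("a Gaussian ensemble yields a parabolic free-energy surface", {
  kT <- energy_constants()$kT_eV
  set.seed(42)
  v <- stats::rnorm(1e4, 5.3, 0.1)
  g <- gap_distribution(gap_ensemble(v, "X", "VIE"))
  occ <- g[g$occupied, ]
  fit <- stats::lm(A_eV ~ poly(center, 2, raw = TRUE), data = occ,
                   weights = occ$p)
  curvature <- unname(stats::coef(fit)[3])
  expect_equal(curvature, kT / (2 * stats::sd(v)^2), tolerance = 0.15)
})

test_that("paired Gaussian ensembles obey the linear free-energy relation", {
  # A_red(E) - A_ox(E) = E - DeltaA + const for exact linear response
  s <- sample_linear_response(5.0, 0.2, n = 2e4, seed = 9)
  gi <- gap_distribution(s$vie)
  ga <- gap_distribution(s$vae)
  Ei <- gi$center + mean(s$vie$values)
  Ea <- ga$center + mean(s$vae$values)
  oi <- gi$occupied & gi$p > 5 / 2e4   # drop sparsely populated tails
  oa <- ga$occupied & ga$p > 5 / 2e4
  a_red <- stats::approx(Ea[oa], ga$A_eV[oa], xout = Ei[oi])$y
  keep <- !is.na(a_red)
  slope <- unname(stats::coef(
    stats::lm(I(a_red[keep] - gi$A_eV[oi][keep]) ~ Ei[oi][keep]))[2])
  expect_equal(slope, 1, tolerance = 0.15)
})

test_that("the nonlinear correction reduces to Marcus at equal variances", {
  set.seed(1)
  x <- stats::rnorm(200, 5.3, 0.1)
  vie <- gap_ensemble(x, "G", "VIE")
  vae <- gap_ensemble(x - 0.4, "G", "VAE")   # identical sample sd
  m <- marcus_free_energy(vie, vae)
  cor <- matyushov_voth_corrected(vie, vae)
  expect_lt(abs(cor$potential_V - m$potential_V), 1e-10)
  expect_equal(cor$protocol, "dynamic_marcus_corrected")
})

test_that("unequal variances shift the corrected result, antisymmetrically", {
  kT <- energy_constants()$kT_eV
  s <- sample_nonlinear(5.0, 0.81^2 / (2 * kT), 1.20^2 / (2 * kT),
                        n = 200, seed = 7)
  m <- marcus_free_energy(s$vie, s$vae)
  cor <- matyushov_voth_corrected(s$vie, s$vae)
  expect_gt(abs(cor$potential_V - m$potential_V), 1e-6)

  # swapping which ensemble carries the larger sigma (means fixed)
  # flips the sign of the correction exactly
  v1 <- s$vie$values; v2 <- s$vae$values
  sw1 <- mean(v1) + (v1 - mean(v1)) * stats::sd(v2) / stats::sd(v1)
  sw2 <- mean(v2) + (v2 - mean(v2)) * stats::sd(v1) / stats::sd(v2)
  cor_sw <- matyushov_voth_corrected(
    gap_ensemble(sw1, "synthetic", "VIE", solvent_model = "explicit"),
    gap_ensemble(sw2, "synthetic", "VAE", solvent_model = "explicit"))
  expect_equal(cor_sw$correction_eV, -cor$correction_eV, tolerance = 1e-9)

  # inverted mean ordering is outside the model's domain
  expect_error(
    matyushov_voth_corrected(
      gap_ensemble(v2, "synthetic", "VIE", solvent_model = "explicit"),
      gap_ensemble(v1, "synthetic", "VAE", solvent_model = "explicit")),
    "Stokes")
})
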