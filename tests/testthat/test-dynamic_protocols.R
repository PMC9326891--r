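test_that("dynamic direct reduces to static arithmetic on constant ensembles", {
  cc0 <- constants_no_electron()
  en <- gap_ensemble(rep(-100, 5), "G", "total_potential_energy", "neutral")
  ec <- gap_ensemble(rep(-100, 5), "G", "total_potential_energy", "cation")
  res <- dynamic_direct(en, ec, cc0)
  expect_equal(res$potential_V, -4.281)
  expect_equal(res$spread_V, 0)
  expect_equal(res$n_snapshots_used, c(5, 5))

  # cation ensemble exactly 5.10 eV above the neutral one -> 0.781 V
  cc <- energy_constants()
  set.seed(4)
  v <- stats::rnorm(100, -100, 0.05)
  en2 <- gap_ensemble(v, "G", "total_potential_energy", "neutral")
  ec2 <- gap_ensemble(v + 5.10, "G", "total_potential_energy", "cation")
  expect_equal(round(dynamic_direct(en2, ec2, cc)$potential_V, 3), 0.781)

  # guards
  ec_im <- gap_ensemble(v, "G", "total_potential_energy", "cation",
                        solvent_model = "explicit")
  expect_error(dynamic_direct(en2, ec_im, cc), "solvent model")
  expect_error(dynamic_direct(ec2, en2, cc), "sampled")
})

test_that("dynamic direct recovers a generated mean difference within CLT bounds", {
  cc0 <- constants_no_electron()
  set.seed(21)
  n <- 400
  en <- gap_ensemble(stats::rnorm(n, -100, 0.3), "S",
                     "total_potential_energy", "neutral")
  ec <- gap_ensemble(stats::rnorm(n, -94.9, 0.3), "S",
                     "total_potential_energy", "cation")
  res <- dynamic_direct(en, ec, cc0)
  se <- sqrt(2) * 0.3 / sqrt(n)
  expect_lt(abs(res$delta_g_eV - (-5.1)), 3 * se)
})

test_that("the Marcus half-sum reproduces the printed guanine example", {
  cc <- energy_constants()
  vie <- gap_ensemble(c(5.25, 5.30, 5.35), "G", "VIE")
  vae <- gap_ensemble(c(4.85, 4.90, 4.95), "G", "VAE")
  res <- marcus_free_energy(vie, vae, cc)
  expect_equal(res$gap_eV, 5.10)
  expect_equal(res$lambda_eV, 0.20)
  expect_equal(round(res$potential_V, 2), 0.78)

  # zero-reorganization limit: equals a static result with Delta G = -g
  g <- 5.0
  vie0 <- gap_ensemble(c(g, g), "X", "VIE")
  vae0 <- gap_ensemble(c(g, g), "X", "VAE")
  expect_equal(marcus_free_energy(vie0, vae0, cc)$potential_V,
               potential_vs_she(-g - cc$electron_free_energy_eV, 1, cc))

  expect_error(marcus_free_energy(vae, vae, cc), "VIE")
})

test_that("Marcus estimator recovers the generator ground truth", {
  s <- sample_linear_response(5.00, 0.20, n = 2000, seed = 8)
  res <- marcus_free_energy(s$vie, s$vae)
  se <- sqrt(2) * s$sigma / (2 * sqrt(2000))
  expect_lt(abs(res$gap_eV - 5.00), 3 * se)
})

test_that("convergence curves are deterministic and end at the full value", {
  s <- sample_linear_response(5.10, 0.20, n = 200, seed = 3)
  cv1 <- convergence_curve(s$vie, s$vae, "marcus", step = 10, seed = 5)
  cv2 <- convergence_curve(s$vie, s$vae, "marcus", step = 10, seed = 5)
  expect_identical(cv1$running_potentials, cv2$running_potentials)
  expect_equal(cv1$n_values, seq(10, 200, by = 10))
  full <- marcus_free_energy(s$vie, s$vae)$potential_V
  expect_equal(cv1$running_potentials[length(cv1$running_potentials)], full)

  # a different seed subsamples differently (except the final full point)
  cv3 <- convergence_curve(s$vie, s$vae, "marcus", step = 10, seed = 6)
  expect_false(identical(cv1$running_potentials[1:19],
                         cv3$running_potentials[1:19]))

  # constant ensembles give a flat curve
  vc <- gap_ensemble(rep(5.3, 50), "X", "VIE")
  ac <- gap_ensemble(rep(4.9, 50), "X", "VAE")
  flat <- convergence_curve(vc, ac, "marcus", step = 5, seed = 1)
  expect_equal(diff(range(flat$running_potentials)), 0)

  expect_error(convergence_curve(vc, ac, "marcus", step = 51, seed = 1),
               "exceeds")
})

test_that("converged_at matches a brute-force scan of its definition", {
  brute <- function(n_values, v, window, tol) {
    for (k in seq(window, length(v))) {
      w <- v[(k - window + 1):k]
      if (all(abs(w - mean(w)) <= tol)) return(n_values[k])
    }
    NA_integer_
  }
  # flat curve: first window end
  vc <- gap_ensemble(rep(5.3, 60), "X", "VIE")
  ac <- gap_ensemble(rep(4.9, 60), "X", "VAE")
  flat <- convergence_curve(vc, ac, "marcus", step = 5, seed = 1)
  expect_equal(converged_at(flat, window = 5, tol = 0.01), flat$n_values[5])

  # alternating curve beyond tolerance never converges
  alt <- flat
  alt$running_potentials <- 0.8 + rep(c(-0.04, 0.04), 6)
  expect_identical(converged_at(alt, window = 5, tol = 0.02), NA_integer_)

  # seeded synthetic curves agree with the oracle
  for (seed in 1:5) {
    s <- sample_linear_response(5.10, 0.5, n = 200, seed = seed)
    cv <- convergence_curve(s$vie, s$vae, "marcus", step = 10, seed = seed)
    expect_identical(converged_at(cv, 5, 0.02),
                     brute(cv$n_values, cv$running_potentials, 5, 0.02))
  }
})

test_that("narrow ensembles converge with fewer snapshots than wide ones", {
  kT <- energy_constants()$kT_eV
  lam_implicit <- 0.1^2 / (2 * kT)   # sigma = 0.1 eV, continuum-like
  lam_explicit <- 1.0^2 / (2 * kT)   # sigma = 1.0 eV, explicit-like
  ni <- ne <- integer(5)
  for (s in 1:5) {
    li <- sample_linear_response(5.10, lam_implicit, n = 200, seed = s)
    le <- sample_linear_response(5.10, lam_explicit, n = 200, seed = 100 + s)
    ni[s] <- converged_at(convergence_curve(li$vie, li$vae, "marcus",
                                            step = 10, seed = s))
    ne[s] <- converged_at(convergence_curve(le$vie, le$vae, "marcus",
                                            step = 10, seed = s))
  }
  expect_true(all(ni <= 60))
  expect_true(all(is.na(ne) | ne >= 100))
})
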