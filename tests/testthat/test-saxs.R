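test_that("Debye limits hold for point scatterers", {
  # coincident atoms: I(q) = (f1+f2)^2 everywhere
  coords <- array(0, c(1, 2, 3))
  ens <- conformer_ensemble(coords, atom_names = c("H", "H"),
                            residue_ids = 1:2)
  prof <- debye_profile(ens, q = seq(0, 0.5, length.out = 20))
  expect_equal(prof$I, rep(4, 20), tolerance = 1e-12)

  # I(0) = (sum f)^2 for any geometry
  chain <- sample_gaussian_chain(30, n_conformers = 2, seed = 5)
  prof <- debye_profile(chain)
  expect_equal(prof$I[1], (30 * 6)^2, tolerance = 1e-9)

  # positivity and boundedness by the forward intensity
  expect_true(all(prof$I > 0))
  expect_true(all(prof$I <= prof$I[1] + 1e-9))

  expect_error(debye_profile(chain, q = c(-0.1, 0.2)), "non-negative")
})

test_that("sphere fixture reproduces the analytic form factor", {
  N <- 2000
  ens <- sample_sphere_beads(15, N, n_conformers = 32, seed = 8)
  prof <- debye_profile(ens)
  # comparing discrete beads against the continuous-density form factor
  # requires excluding the incoherent self terms (an N f^2 floor of
  # (1-P)/N ~ 6.6% of P at qR = 4); the cross-term normalization is the
  # unbiased estimator of P(q)
  f2 <- 36
  P_hat <- (prof$I - N * f2) / (N * (N - 1) * f2)
  P <- sphere_form_factor(prof$q, 15)
  sel <- prof$q > 0 & prof$q * 15 < 4
  expect_lt(max(abs(P_hat[sel] - P[sel]) / P[sel]), 0.05)
})

test_that("replicate averaging yields SEM errors", {
  q <- seq(0, 0.5, length.out = 10)
  base <- scattering_profile(q, exp(-q^2 * 100))
  same <- average_profiles(list(base, base, base))
  expect_equal(same$I, base$I)
  expect_equal(same$eps, rep(0, 10))

  eps <- 0.03
  shifted <- scattering_profile(q, base$I + 2 * eps)
  two <- average_profiles(list(base, shifted))
  expect_equal(two$eps, rep(eps, 10), tolerance = 1e-12)

  expect_warning(one <- average_profiles(list(base)), "single replicate")
  expect_equal(one$eps, rep(0, 10))

  other <- scattering_profile(q + 0.01, base$I)
  expect_error(average_profiles(list(base, other)), "mismatched")
})

test_that("profile fitting recovers linear transformations exactly", {
  q <- default_q_grid()
  comp <- scattering_profile(q, 1e5 * sphere_form_factor(q, 12),
                             eps = rep(10, length(q)))
  # self-fit
  fit <- fit_profile(comp, scattering_profile(q, comp$I,
                                              eps = rep(5, length(q))))
  expect_equal(fit$m, 1, tolerance = 1e-9)
  expect_equal(fit$n, 0, tolerance = 1e-6)
  expect_lt(fit$chi2, 1e-18)
  expect_true(all(abs(fit$residuals) < 1e-9))

  # exact recovery of (m, n)
  exp_prof <- scattering_profile(q, 2.5 * comp$I + 0.1,
                                 eps = rep(7, length(q)))
  fit <- fit_profile(comp, exp_prof)
  expect_equal(fit$m, 2.5, tolerance = 1e-9)
  expect_equal(fit$n, 0.1, tolerance = 1e-6)
  expect_equal(fit$eps_fit, 2.5 * comp$eps)

  # chi2 of a calibrated-noise fit lands in the chi2-distribution band
  set.seed(99)
  sig <- 0.02 * comp$I + 50
  noisy <- scattering_profile(q, 1.7 * comp$I + 200 + rnorm(length(q)) * sig,
                              eps = sig)
  comp0 <- scattering_profile(q, comp$I, eps = rep(0, length(q)))
  fit <- fit_profile(comp0, noisy)
  n_pts <- length(q)
  expect_gt(fit$chi2, n_pts - 4 * sqrt(2 * n_pts))
  expect_lt(fit$chi2, n_pts + 4 * sqrt(2 * n_pts))
  expect_equal(fit$chi2_reduced, fit$chi2 / (n_pts - 2))
})

test_that("chi-square is invariant under rescaling and amplitude changes", {
  q <- default_q_grid()
  set.seed(12)
  comp <- scattering_profile(q, 1e4 * sphere_form_factor(q, 10) + 50,
                             eps = rep(0, length(q)))
  exp_prof <- scattering_profile(q, 3 * comp$I + 40 + rnorm(length(q), 0, 30),
                                 eps = rep(30, length(q)))
  fit <- fit_profile(comp, exp_prof)

  # fitting a*comp returns m/a with identical chi2
  a <- 7.3
  comp_a <- scattering_profile(q, a * comp$I, eps = a * comp$eps)
  fit_a <- fit_profile(comp_a, exp_prof)
  expect_equal(fit_a$m, fit$m / a, tolerance = 1e-9)
  expect_equal(fit_a$chi2, fit$chi2, tolerance = 1e-9)

  # common rescaling of both profiles and both error arrays
  s <- 0.013
  fit_s <- fit_profile(
    scattering_profile(q, s * comp$I, eps = s * comp$eps),
    scattering_profile(q, s * exp_prof$I, eps = s * exp_prof$eps))
  expect_equal(fit_s$chi2, fit$chi2, tolerance = 1e-9)

  # constant computed profile cannot be fitted
  flat <- scattering_profile(q, rep(3, length(q)), eps = rep(1, length(q)))
  expect_error(fit_profile(flat, exp_prof), "singular")
})

test_that("closed-form fit equals a Levenberg-Marquardt solve", {
  skip_if_not_installed("minpack.lm")
  q <- default_q_grid()
  set.seed(4)
  comp <- scattering_profile(q, 1e4 * sphere_form_factor(q, 14) + 30,
                             eps = 5 + 5 * runif(length(q)))
  exp_prof <- scattering_profile(q, 2.1 * comp$I + 15 + rnorm(length(q), 0, 40),
                                 eps = rep(40, length(q)))
  fit <- fit_profile(comp, exp_prof)
  w <- 1 / sqrt(comp$eps^2 + exp_prof$eps^2)
  lm_fit <- minpack.lm::nls.lm(
    par = list(m = 1, n = 0),
    fn = function(par) w * (par$m * comp$I + par$n - exp_prof$I),
    control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                         maxiter = 500))
  expect_equal(fit$m, lm_fit$par$m, tolerance = 1e-9)
  # the offset lives on the intensity scale; compare relative to it
  expect_lt(abs(fit$n - lm_fit$par$n) / stats::sd(exp_prof$I), 1e-9)
})

test_that("Kratky transform reveals the Gaussian-chain plateau", {
  q <- seq(0, 0.5, length.out = 200)
  expect_equal(kratky(scattering_profile(q, rep(1, 200)))$I, q^2)
  expect_equal(kratky(scattering_profile(q, rep(1, 200)))$I[1], 0)

  # Debye function of a Gaussian chain: q^2 I -> 2/Rg^2
  rg <- 30
  x <- (q * rg)^2
  I_debye <- ifelse(x == 0, 1, 2 * (exp(-x) + x - 1) / x^2)
  kr <- kratky(scattering_profile(q, I_debye))
  # the Debye function deviates from the plateau by 1/(q rg)^2, so the
  # 10% band is reached from q rg = sqrt(10) on
  plateau_idx <- q * rg >= sqrt(10) + 0.05
  expect_gt(sum(plateau_idx), 50)
  expect_true(all(abs(kr$I[plateau_idx] / (2 / rg^2) - 1) < 0.10))
})

test_that("Guinier analysis recovers R_G from low-q behavior", {
  q <- seq(0, 0.2, length.out = 120)
  rg <- 30
  exact <- scattering_profile(q, exp(-q^2 * rg^2 / 3))
  g <- guinier_fit(exact)
  expect_lt(abs(g$rg / rg - 1), 1e-3)
  expect_equal(g$I0, 1, tolerance = 1e-3)
  expect_lte(g$q_max * g$rg, 1.1)

  # flat profile: slope 0 -> R_G = 0
  flat <- scattering_profile(q, rep(2, length(q)))
  expect_equal(guinier_fit(flat)$rg, 0)

  # sphere profile through the full Debye calculator
  ens <- sample_sphere_beads(15, 1500, n_conformers = 2, seed = 13)
  g <- guinier_fit(debye_profile(ens))
  expect_lt(abs(g$rg / (sqrt(3 / 5) * 15) - 1), 0.03)

  tiny <- scattering_profile(c(0, 0.01, 0.02), c(1, 0.9, 0.8))
  expect_error(guinier_fit(tiny, rg_seed = 200), "fewer than 3")
  neg <- scattering_profile(q, exp(-q^2 * 900) - 0.5)
  expect_error(guinier_fit(neg, rg_seed = 30), "non-positive")
})

test_that("Guinier R_G agrees with the coordinate-space R_G for chains", {
  chain <- sample_gaussian_chain(91, b = 3.8, n_conformers = 250, seed = 17)
  prof <- debye_profile(chain, q = seq(0, 0.12, length.out = 40))
  g <- guinier_fit(prof)
  rg_coord <- sqrt(mean(radius_of_gyration(chain)$rg^2))
  expect_lt(abs(g$rg / rg_coord - 1), 0.05)
})

test_that("experimental profile I/O skips headers and interpolates on fit", {
  path <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("Sample description: test",
               "  q I sigma",
               " 0.00 100.0 1.0",
               " 0.10  50.0 0.8",
               " 0.20  10.0 0.5"), path)
  prof <- read_saxs_profile(path)
  expect_equal(prof$q, c(0, 0.1, 0.2))
  expect_equal(prof$eps, c(1, 0.8, 0.5))

  q2 <- seq(0, 0.2, length.out = 5)
  comp <- scattering_profile(q2, 100 * exp(-q2 * 10), eps = rep(1, 5))
  expect_error(fit_profile(comp, prof, interpolate = FALSE), "disabled")
  fit <- fit_profile(comp, prof)
  expect_true(is.finite(fit$chi2))

  out <- withr::local_tempfile(fileext = ".dat")
  write_saxs_profile(prof, out)
  back <- read_saxs_profile(out)
  expect_equal(back$I, prof$I, tolerance = 1e-7)
})
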