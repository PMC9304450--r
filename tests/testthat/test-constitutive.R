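# HGO strain energy, biaxial Cauchy stresses, fitting, elastic modulus.

test_that("energy and stresses vanish at the unloaded reference state", {
  set.seed(11)
  for (i in 1:20) {
    p <- hgo_params(runif(1, 0.1, 5), runif(1, 0, 5), runif(1, 0.1, 10),
                    runif(1, 0, 1 / 3), runif(1, 0, pi / 2))
    expect_equal(hgo_strain_energy(p, 1, 1), 0)
    s <- hgo_cauchy_stress(p, 1, 1)
    expect_equal(s$sigma_theta, 0)
    expect_equal(s$sigma_z, 0)
  }
})

test_that("energy matches frozen closed-form oracle values", {
  # isotropic term only (k1 = 0): c/2 (1.44 + 1 + 1/1.44 - 3)
  p_iso <- hgo_params(1, 0, 1, 0, 0)
  expect_equal(hgo_strain_energy(p_iso, 1.2, 1.0), 0.067222222222222222,
               tolerance = 1e-12)
  # cohort-mean parameters at lambda_theta = 1.3, lambda_z = 1.4
  # (frozen from a 30-digit arbitrary-precision evaluation of the energy)
  expect_equal(hgo_strain_energy(ref_params(), 1.3, 1.4),
               1.0357640733425633, tolerance = 1e-12)
})

test_that("energy is non-negative over the physiologic stretch window", {
  set.seed(12)
  grid <- expand.grid(lt = seq(0.8, 1.8, length.out = 11),
                      lz = seq(0.8, 1.8, length.out = 11))
  for (i in 1:10) {
    p <- hgo_params(runif(1, 0.1, 5), runif(1, 0, 5), runif(1, 0.1, 10),
                    runif(1, 0, 1 / 3), runif(1, 0, pi / 2))
    expect_true(all(hgo_strain_energy(p, grid$lt, grid$lz) >= 0))
  }
})

test_that("analytic stresses agree with finite differences of the energy", {
  set.seed(13)
  h <- 1e-6
  n_checked <- 0
  while (n_checked < 25) {
    p <- hgo_params(runif(1, 0.2, 4), runif(1, 0.05, 3), runif(1, 0.2, 8),
                    runif(1, 0, 1 / 3), runif(1, 0.1, pi / 2 - 0.1))
    lt <- runif(1, 1.05, 1.6); lz <- runif(1, 1.05, 1.6)
    # stay away from the tension-switch boundary where Psi is only C1
    e4 <- p$kappa * (lt^2 + lz^2 + (lt * lz)^-2) +
      (1 - 3 * p$kappa) * (lt^2 * cos(p$gamma)^2 + lz^2 * sin(p$gamma)^2) - 1
    if (abs(e4) < 1e-2) next
    s <- hgo_cauchy_stress(p, lt, lz)
    fd_t <- lt * (hgo_strain_energy(p, lt + h, lz) -
                  hgo_strain_energy(p, lt - h, lz)) / (2 * h)
    fd_z <- lz * (hgo_strain_energy(p, lt, lz + h) -
                  hgo_strain_energy(p, lt, lz - h)) / (2 * h)
    expect_equal(s$sigma_theta, fd_t, tolerance = 1e-6)
    expect_equal(s$sigma_z, fd_z, tolerance = 1e-6)
    n_checked <- n_checked + 1
  }
  # frozen oracle stresses at the cohort-mean parameter point
  s <- hgo_cauchy_stress(ref_params(), 1.3, 1.4)
  expect_equal(s$sigma_theta, 3.6629031697219937, tolerance = 1e-10)
  expect_equal(s$sigma_z, 4.3455598560234425, tolerance = 1e-10)
})

test_that("k1 = 0 reduces to the incompressible neo-Hookean closed form", {
  p <- hgo_params(1.3, 0, 1, 0, 0)
  lt <- c(1.1, 1.25, 1.4); lz <- c(1.3, 1.3, 1.5)
  s <- hgo_cauchy_stress(p, lt, lz)
  expect_equal(s$sigma_theta, 1.3 * (lt^2 - (lt * lz)^-2), tolerance = 1e-12)
  expect_equal(s$sigma_z, 1.3 * (lz^2 - (lt * lz)^-2), tolerance = 1e-12)
})

test_that("invalid stretches and parameters are rejected", {
  p <- ref_params()
  expect_error(hgo_strain_energy(p, -1, 1), "stretches")
  expect_error(hgo_cauchy_stress(p, 1, 0), "stretches")
  expect_error(hgo_params(-1, 1, 1, 0.1, 0.3), "c must")
  expect_error(hgo_params(1, 1, 1, 0.5, 0.3), "kappa")
  expect_error(hgo_params(1, 1, 1, 0.1, 2), "gamma")
})

test_that("elastic modulus is E = c(1+nu), linear and monotone in c", {
  expect_equal(elastic_modulus(0), 0)
  expect_equal(elastic_modulus(1, 0.5), 1.5)
  cs <- seq(0.2, 3, by = 0.2)
  expect_equal(elastic_modulus(cs, 0.3), cs * 1.3)
  expect_true(all(diff(elastic_modulus(cs)) > 0))
  expect_error(elastic_modulus(1, 0.7), "nu")
})

test_that("thin-wall Laplace helper matches direct arithmetic", {
  # P = 100 mmHg = 13332.2 Pa = 0.0133322 MPa; r = 0.6 mm, h = 0.1 mm
  out <- laplace_stresses(100, 0.6, 0.1, 2)
  expect_equal(out$sigma_theta, 0.0133322 * 0.6 / 0.1, tolerance = 1e-6)
  expect_equal(out$sigma_z,
               (2e-3 + 0.0133322 * pi * 0.36) / (pi * 0.1 * 1.3),
               tolerance = 1e-6)
})

test_that("fit recovers the stress curves and respects the noise floor", {
  bx <- gen_biaxial(noise_sd_kpa = 0)
  fit <- fit_hgo(bx, n_starts = 20, seed = 2)
  expect_true(fit$converged)
  expect_lt(fit$mse, 1e-10)
  s <- hgo_cauchy_stress(fit$params, bx$records$lambda_theta,
                         bx$records$lambda_z)
  expect_equal(s$sigma_theta, bx$records$sigma_theta_mpa, tolerance = 1e-5)

  # with kappa and gamma held at truth, c and k1 are identified to < 2%
  tr <- ref_params()
  fitf <- fit_hgo(bx, n_starts = 10, seed = 2,
                  fixed = c(kappa = tr$kappa, gamma = tr$gamma))
  expect_lt(abs(fitf$params$c / tr$c - 1), 0.02)
  expect_lt(abs(fitf$params$k1 / tr$k1 - 1), 0.02)

  # gaussian noise at 5 kPa: fitted residual RMSE lands near the noise floor
  bxn <- gen_biaxial(noise_sd_kpa = 5, seed = 7)
  fitn <- fit_hgo(bxn, n_starts = 20, seed = 2)
  rmse_kpa <- sqrt(fitn$mse / 2) * 1e3
  expect_gt(rmse_kpa, 0.5 * 5)
  expect_lt(rmse_kpa, 2 * 5)
})

test_that("degenerate fitting inputs are handled", {
  bx <- gen_biaxial(noise_sd_kpa = 0)
  few <- biaxial_sample(bx$records[1:5, ])
  expect_error(fit_hgo(few), ">= 10 records")
  one <- biaxial_sample(
    bx$records[bx$records$protocol_id == "inflation_1.4", ])
  expect_warning(fit <- fit_hgo(one, n_starts = 10, seed = 3),
                 "single-protocol")
  expect_true(is.finite(fit$mse))
  expect_true(is.finite(fit$start_spread))
})

test_that("biaxial CSV round-trips", {
  bx <- gen_biaxial(noise_sd_kpa = 2, n_per_protocol = 4, seed = 5)
  path <- tempfile(fileext = ".csv")
  write_biaxial_csv(bx, path)
  bx2 <- read_biaxial_csv(path)
  expect_equal(bx2$records$sigma_theta_mpa, bx$records$sigma_theta_mpa,
               tolerance = 1e-12)
  expect_equal(bx2$records$protocol_id, bx$records$protocol_id)
})
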