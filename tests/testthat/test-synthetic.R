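# Generators: determinism, self-consistency, sidecar ground truth,
# published-range calibration.

test_that("every generator is reproducible under a fixed seed", {
  expect_identical(gen_biaxial(noise_sd_kpa = 3, seed = 5),
                   gen_biaxial(noise_sd_kpa = 3, seed = 5))
  expect_identical(gen_wss_field(seed = 5), gen_wss_field(seed = 5))
  expect_identical(gen_vessel(noise_mm = 0.02, seed = 5),
                   gen_vessel(noise_mm = 0.02, seed = 5))
  expect_identical(gen_cohort(generator_config(seed = 5)),
                   gen_cohort(generator_config(seed = 5)))
  # and distinct seeds genuinely differ
  expect_false(identical(gen_wss_field(seed = 5), gen_wss_field(seed = 6)))
})

test_that("noiseless biaxial output reproduces the truth stresses exactly", {
  tr <- ref_params()
  bx <- gen_biaxial(truth = tr, noise_sd_kpa = 0)
  s <- hgo_cauchy_stress(tr, bx$records$lambda_theta, bx$records$lambda_z)
  expect_equal(bx$records$sigma_theta_mpa, s$sigma_theta, tolerance = 1e-12)
  expect_equal(bx$records$sigma_z_mpa, s$sigma_z, tolerance = 1e-12)
  expect_setequal(unique(bx$records$protocol_id), biaxial_protocols())
  # equilibrium: sigma_theta increases along each inflation pressure sweep
  for (pr in c("inflation_1.3", "inflation_1.4", "inflation_1.5")) {
    sub <- bx$records[bx$records$protocol_id == pr, ]
    sub <- sub[order(sub$pressure_mmhg), ]
    expect_true(all(diff(sub$sigma_theta_mpa) > 0))
  }
})

test_that("WSS field sidecar truth matches the measured biomarkers", {
  ws <- gen_wss_field(n_times = 64, seed = 8)
  truth <- attr(ws, "truth")
  expect_equal(tawss(ws), truth$tawss, tolerance = 1e-3)
  expect_equal(osi(ws), truth$osi, tolerance = 1e-3)
  # closed-form special cases
  ws0 <- gen_wss_field(n_circ = 4, n_axial = 3, amplitude = 2,
                       osc_frac = 0, sway = 0, seed = 1)
  expect_equal(tawss(ws0), rep(2, 12), tolerance = 1e-12)
  expect_equal(osi(ws0), rep(0, 12), tolerance = 1e-12)
  ws1 <- gen_wss_field(n_circ = 4, n_axial = 3, n_times = 128, amplitude = 2,
                       osc_frac = 1, sway = 0, seed = 1)
  expect_equal(osi(ws1), rep(0.5, 12), tolerance = 1e-10)
  expect_equal(tawss(ws1), rep(2 * 2 / pi, 12), tolerance = 1e-3)
  expect_error(gen_wss_field(osc_frac = 1.2), "\\[0, 1\\]")
})

test_that("default WSS fields land inside the published cohort ranges", {
  for (seed in 1:5) {
    ws <- gen_wss_field(seed = seed)
    ta <- tawss(ws); os <- osi(ws)
    expect_gte(mean(os), 0.17); expect_lte(mean(os), 0.38)
    expect_gte(max(ta), 6.1);   expect_lte(max(ta), 11)
    expect_gte(mean(ta), 0.9);  expect_lte(mean(ta), 3.42)
    expect_gte(min(ta), 0.005); expect_lte(min(ta), 0.33)
    expect_true(all(os >= 0 & os <= 0.5))
  }
})

test_that("vessel generator: analytic sidecar, straight limit, bulge", {
  straight <- gen_vessel(tortuosity_amplitude_mm = 0)
  expect_equal(tortuosity_index(straight), 0, tolerance = 1e-9)
  cl <- gen_vessel(seed = 3)
  truth <- attr(cl, "truth")
  expect_equal(actual_length(cl), truth$al, tolerance = 1e-3)
  expect_equal(geometric_length(cl), truth$gl, tolerance = 1e-9)
  expect_equal(tortuosity_index(cl), truth$ati, tolerance = 1e-2)
  # aneurysm at the top of the published diameter range
  big <- gen_vessel(bulge_peak_mm = 3.3)
  expect_equal(max_diameter(big), 3.3, tolerance = 1e-6)
  expect_equal(attr(big, "truth")$d_max, 3.3, tolerance = 1e-9)
  expect_error(gen_vessel(tortuosity_amplitude_mm = 50), "self-intersecting")
})

test_that("inflow waveform: periodicity, stroke volume, C1 smoothness", {
  wf <- gen_inflow(period = 0.1, peak_flow = 1500, systole_fraction = 0.35)
  expect_equal(wf$q[1], wf$q[length(wf$q)])
  truth <- attr(wf, "truth")
  expect_equal(trapz(wf$times, wf$q), truth$stroke_volume, tolerance = 1e-3)
  # sin^2 systole: the slope at ejection onset vanishes as the grid refines
  wf_fine <- gen_inflow(n_times = 1025)
  dq <- diff(wf_fine$q) / diff(wf_fine$times)
  expect_lt(abs(dq[1]), 0.05 * max(abs(dq)))
  expect_error(gen_inflow(systole_fraction = 1.2), "systole")
})

test_that("cohort generator respects published ranges and the censor rule", {
  rng <- biomarker_ranges()
  co <- gen_cohort(generator_config(seed = 2))
  for (v in c("P_max", "Re_max", "OSI_mean", "TAWSS_max", "ATI", "D_max",
              "Wo")) {
    r <- rng[rng$abbrev == v, ]
    expect_true(all(co$t6[[v]] >= r$lo & co$t6[[v]] <= r$hi))
  }
  expect_true(all(co$t6$lifespan_months <= 25))
  expect_identical(as.logical(co$t6$censored),
                   co$t6$lifespan_months == 25)
  # two-month values precede the six-month ones; deltas within range
  dd <- delta_biomarkers(co$t2, co$t6)
  r <- rng[rng$abbrev == "delta_D_max", ]
  expect_true(all(dd$delta_D_max >= r$lo - 1e-12 &
                  dd$delta_D_max <= r$hi + 1e-12))
  expect_true(all(co$t2$D_max <= co$t6$D_max))
})

test_that("lifespan signal strength drives the fitted pseudo-r2", {
  null_co <- gen_cohort(generator_config(seed = 10, n_subjects = 500,
                                         lifespan_beta1 = 0,
                                         lifespan_beta0 = 20))$t6
  fit0 <- tobit_fit(null_co$OSI_mean, null_co$lifespan_months,
                    null_co$censored, 25)
  expect_lt(pseudo_r2(fit0), 0.05)

  strong <- gen_cohort(generator_config(seed = 11, n_subjects = 200,
                                        lifespan_sigma = 0.1))$t6
  fit1 <- tobit_fit(strong$OSI_mean, strong$lifespan_months,
                    strong$censored, 25)
  expect_gt(pseudo_r2(fit1), 0.95)

  # the emulated study shape: n = 10 with some censored subjects
  small <- gen_cohort(generator_config(seed = 12))$t6
  expect_equal(nrow(small), 10)
  expect_gt(sum(small$censored), 0)
})

test_that("truth sidecars serialize next to the primary output", {
  cl <- gen_vessel(seed = 2)
  out <- file.path(tempdir(), "vessel.csv")
  write_centerline_csv(cl, out)
  sc <- write_truth_sidecar(cl, out)
  expect_true(file.exists(paste0(out, ".truth.json")))
  truth <- jsonlite::read_json(paste0(out, ".truth.json"))
  expect_equal(truth$ati, attr(cl, "truth")$ati, tolerance = 1e-9)
})
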