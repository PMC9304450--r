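# Tobit regression, pseudo-r2, correlation maps, delta biomarkers.

test_that("with zero censoring the Tobit fit reduces to OLS", {
  set.seed(41)
  x <- runif(40, 0, 10)
  y <- 3 + 1.5 * x + rnorm(40, 0, 2)
  y <- pmin(y, 24)  # keep everything below the cut-off
  fit <- tobit_fit(x, y, censored = rep(FALSE, 40), y_max = 25)
  o <- lm(y ~ x)
  expect_equal(unname(fit$beta), unname(coef(o)), tolerance = 1e-6)
  expect_equal(fit$sigma, sqrt(mean(residuals(o)^2)), tolerance = 1e-6)
  expect_equal(pseudo_r2(fit), summary(o)$r.squared, tolerance = 1e-6)
  expect_equal(pseudo_r2(fit, "latent"), summary(o)$r.squared,
               tolerance = 1e-6)
})

test_that("the censored MLE matches the survreg oracle on the mouse cohort", {
  skip_if_not_installed("survival")
  co <- mouse_cohort()
  fit <- tobit_fit(co$ati, co$lifespan_months, co$censored, 25)
  expect_equal(fit$n_censored, 4L)
  sv <- survival::survreg(
    survival::Surv(co$lifespan_months, 1 - co$censored, type = "right") ~
      co$ati, dist = "gaussian")
  expect_equal(unname(fit$beta), unname(coef(sv)), tolerance = 1e-4)
  expect_equal(fit$sigma, sv$scale, tolerance = 1e-4)
})

test_that("the returned MLE beats the OLS starting point in likelihood", {
  set.seed(42)
  for (i in 1:5) {
    cc <- gen_cohort(generator_config(seed = 100 + i, n_subjects = 50,
                                      lifespan_beta0 = 13,
                                      lifespan_beta1 = 40,
                                      lifespan_sigma = 3))$t6
    fit <- tobit_fit(cc$OSI_mean, cc$lifespan_months, cc$censored, 25)
    o <- lm(cc$lifespan_months ~ cc$OSI_mean)
    nll_fit <- tobit_nll_oracle(fit$beta[1], fit$beta[2], fit$sigma,
                                cc$OSI_mean, cc$lifespan_months,
                                as.logical(cc$censored), 25)
    nll_ols <- tobit_nll_oracle(coef(o)[1], coef(o)[2],
                                sqrt(mean(residuals(o)^2)),
                                cc$OSI_mean, cc$lifespan_months,
                                as.logical(cc$censored), 25)
    expect_lte(nll_fit, nll_ols + 1e-8)
    expect_equal(-nll_fit, fit$loglik, tolerance = 1e-8)
  }
})

test_that("pseudo-r2 is bounded and affine-invariant in the predictor", {
  co <- mouse_cohort()
  fit <- tobit_fit(co$ati, co$lifespan_months, co$censored, 25)
  for (m in c("correlation", "latent")) {
    r0 <- pseudo_r2(fit, m)
    expect_gte(r0, 0); expect_lte(r0, 1)
    fit2 <- tobit_fit(3.7 * co$ati - 12, co$lifespan_months, co$censored, 25)
    expect_equal(pseudo_r2(fit2, m), r0, tolerance = 1e-4)
  }
})

test_that("Tobit estimates approach OLS as the censoring fraction shrinks", {
  set.seed(43)
  n <- 300
  x <- runif(n, 0, 1)
  # intercepts chosen to give ~0%, ~10% and ~40% censoring at the cut-off
  res <- sapply(c(5, 20, 22.7), function(b0) {
    y_lat <- b0 + 5 * x + rnorm(n, 0, 2)
    cens <- y_lat >= 25
    y <- pmin(y_lat, 25)
    fit <- tobit_fit(x, y, cens, 25)
    o <- lm(y ~ x)
    c(gap = abs(unname(fit$beta[2] - coef(o)[2])), frac = mean(cens))
  })
  expect_equal(unname(res["frac", ]), c(0, 0.1, 0.4), tolerance = 0.5)
  expect_lt(res["gap", 1], 1e-6)   # no censoring: identical to OLS
  expect_lt(res["gap", 2], 1)      # mild censoring: close
  expect_true(all(is.finite(res["gap", ])))
})

test_that("degenerate Tobit inputs error clearly", {
  expect_error(tobit_fit(rep(1, 10), 1:10, rep(FALSE, 10)), "constant")
  expect_error(tobit_fit(1:10, rep(25, 10), rep(TRUE, 10)), "censored")
  expect_error(tobit_fit(1:2, 1:2, c(FALSE, FALSE)), ">= 3")
})

test_that("correlation maps: self-cells, OLS symmetry, null cohort", {
  cc <- gen_cohort(generator_config(seed = 9, n_subjects = 200,
                                    lifespan_beta1 = 0))$t6
  map <- correlation_map(cc, variables = c("ATI", "D_max", "OSI_mean"))
  expect_equal(unname(diag(map$r2)), rep(1, 4))
  expect_equal(map$r2["ATI", "D_max"], map$r2["D_max", "ATI"],
               tolerance = 1e-12)
  # independent columns: everything off-diagonal is near zero at n = 200
  off <- map$r2[upper.tri(map$r2)]
  expect_true(all(off < 0.05))
  # deterministic: identical input, identical output
  map2 <- correlation_map(cc, variables = c("ATI", "D_max", "OSI_mean"))
  expect_identical(map, map2)
  expect_error(correlation_map(cc, variables = c("ATI", "nope")), "nope")
})

test_that("delta biomarkers take absolute two-timepoint differences", {
  t1 <- data.frame(subject_id = c("a", "b"), D_max = c(1.2, 3.3))
  t2 <- data.frame(subject_id = c("b", "a"), D_max = c(1.2, 3.3))
  dd <- delta_biomarkers(t1, t2)
  expect_equal(dd$delta_D_max, c(2.1, 2.1))
  dd0 <- delta_biomarkers(t1, t1)
  expect_equal(dd0$delta_D_max, c(0, 0))
  t3 <- data.frame(subject_id = c("a", "c"), D_max = 1:2)
  expect_error(delta_biomarkers(t1, t3), "c")
})

test_that("cohort validation enforces the censoring convention", {
  bad <- data.frame(subject_id = 1:5, lifespan_months = c(10, 20, 26, 25, 25),
                    censored = c(0, 0, 0, 1, 1))
  expect_error(cohort_table(bad), "exceed")
  bad2 <- data.frame(subject_id = 1:5, lifespan_months = c(10, 20, 24, 25, 25),
                     censored = c(0, 0, 1, 1, 1))
  expect_error(cohort_table(bad2), "inconsistent")
  expect_silent(cohort_table(bad2, strict = FALSE))
})
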