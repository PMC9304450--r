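# HGO constitutive model for the arterial wall: strain energy, biaxial Cauchy
# stresses under incompressibility, multistart least-squares fitting, and the
# derived elastic modulus E = c (1 + nu).

#' Construct and validate HGO material parameters
#'
#' The Holzapfel--Gasser--Ogden strain-energy function combines a neo-Hookean
#' matrix (modulus \code{c}) with two symmetric dispersed fiber families
#' (modulus \code{k1}, nonlinearity \code{k2}, dispersion \code{kappa}, angle
#' \code{gamma} measured from the circumferential axis). The fiber families
#' lie at +gamma and -gamma, so under biaxial kinematics they contribute
#' identically.
#'
#' @param c neo-Hookean modulus (MPa), > 0.
#' @param k1 fiber modulus (MPa), >= 0.
#' @param k2 dimensionless fiber nonlinearity, > 0.
#' @param kappa fiber dispersion in \code{[0, kappa_max]}; 0 = perfectly
#'   aligned, 1/3 = isotropic dispersion.
#' @param gamma fiber angle; radians unless \code{degrees = TRUE}.
#' @param degrees interpret \code{gamma} in degrees.
#' @param kappa_max upper admissibility bound for \code{kappa}; the classical
#'   bound 1/3 by default.
#' @return an object of class \code{hgo_params}.
#' @export
#' @examples
#' hgo_params(1.77, 0.43, 2.01, 0.17, 44.95, degrees = TRUE)
hgo_params <- function(c, k1, k2, kappa, gamma, degrees = FALSE,
                       kappa_max = 1 / 3) {
  if (degrees) gamma <- gamma * pi / 180
  stopifnot(is.numeric(c), is.numeric(k1), is.numeric(k2),
            is.numeric(kappa), is.numeric(gamma))
  if (!(c > 0)) stop("c must be > 0")
  if (k1 < 0) stop("k1 must be >= 0")
  if (!(k2 > 0)) stop("k2 must be > 0")
  if (kappa < 0 || kappa > kappa_max + 1e-12)
    stop(sprintf("kappa must lie in [0, %.4f]", kappa_max))
  if (gamma < 0 || gamma > pi / 2 + 1e-12)
    stop("gamma must lie in [0, pi/2]")
  structure(list(c = c, k1 = k1, k2 = k2, kappa = kappa, gamma = gamma),
            class = "hgo_params")
}

#' @export
print.hgo_params <- function(x, ...) {
  cat(sprintf(
    "HGO parameters: c = %.4g MPa, k1 = %.4g MPa, k2 = %.4g, kappa = %.4g, gamma = %.2f deg\n",
    x$c, x$k1, x$k2, x$kappa, x$gamma * 180 / pi))
  invisible(x)
}

check_stretches <- function(lambda_theta, lambda_z) {
  if (any(!is.finite(lambda_theta)) || any(!is.finite(lambda_z)) ||
      any(lambda_theta <= 0) || any(lambda_z <= 0))
    stop("stretches must be finite and > 0")
}

# Fiber pseudo-invariant E = kappa*I1 + (1-3kappa)*I4 - 1, identical for the
# +gamma and -gamma families under (lambda_theta, lambda_z) kinematics.
hgo_fiber_strain <- function(params, lambda_theta, lambda_z) {
  I1 <- lambda_theta^2 + lambda_z^2 + (lambda_theta * lambda_z)^-2
  I4 <- lambda_theta^2 * cos(params$gamma)^2 + lambda_z^2 * sin(params$gamma)^2
  params$kappa * I1 + (1 - 3 * params$kappa) * I4 - 1
}

#' HGO strain-energy density under incompressible biaxial kinematics
#'
#' Evaluates \deqn{\Psi = \frac{c}{2}(I_1 - 3) + \sum_{i=1,2}
#' \frac{k_1}{2 k_2}\left[e^{k_2 (\kappa I_1 + (1-3\kappa) I_{4i} - 1)^2} -
#' 1\right]} with the radial stretch eliminated by incompressibility,
#' \eqn{\lambda_r = 1/(\lambda_\theta \lambda_z)}, so that
#' \eqn{I_1 = \lambda_\theta^2 + \lambda_z^2 +
#' (\lambda_\theta\lambda_z)^{-2}} and
#' \eqn{I_{4i} = \lambda_\theta^2\cos^2\gamma + \lambda_z^2\sin^2\gamma}.
#' The fiber term is active only in tension
#' (\eqn{\kappa I_1 + (1-3\kappa) I_4 - 1 > 0}) unless
#' \code{tension_only = FALSE}.
#'
#' @param params an \code{\link{hgo_params}} object.
#' @param lambda_theta circumferential stretch(es), > 0.
#' @param lambda_z axial stretch(es), > 0.
#' @param tension_only apply the tension-only fiber switch (default TRUE).
#' @return strain-energy density in MPa (vectorized over stretches).
#' @export
#' @examples
#' p <- hgo_params(1.77, 0.43, 2.01, 0.17, 44.95, degrees = TRUE)
#' hgo_strain_energy(p, 1.3, 1.4)
hgo_strain_energy <- function(params, lambda_theta, lambda_z,
                              tension_only = TRUE) {
  stopifnot(inherits(params, "hgo_params"))
  check_stretches(lambda_theta, lambda_z)
  I1 <- lambda_theta^2 + lambda_z^2 + (lambda_theta * lambda_z)^-2
  E4 <- hgo_fiber_strain(params, lambda_theta, lambda_z)
  active <- if (tension_only) as.numeric(E4 > 0) else 1
  iso <- params$c / 2 * (I1 - 3)
  aniso <- if (params$k1 > 0) {
    # two identical fiber families, k1/(2 k2) each; exponent capped to keep
    # the optimizer finite in extreme corners of the search box
    active * (params$k1 / params$k2) *
      (exp(pmin(params$k2 * E4^2, 700)) - 1)
  } else 0
  iso + aniso
}

#' Biaxial Cauchy stresses from the HGO model
#'
#' Analytic \eqn{\sigma_\theta = \lambda_\theta \partial\Psi/\partial
#' \lambda_\theta} and \eqn{\sigma_z = \lambda_z \partial\Psi/\partial
#' \lambda_z} of the incompressibility-reduced energy (equivalent to the
#' plane-stress condition \eqn{\sigma_r = 0}).
#'
#' @inheritParams hgo_strain_energy
#' @return a list with numeric components \code{sigma_theta} and
#'   \code{sigma_z} (MPa), vectorized over stretches.
#' @export
hgo_cauchy_stress <- function(params, lambda_theta, lambda_z,
                              tension_only = TRUE) {
  stopifnot(inherits(params, "hgo_params"))
  check_stretches(lambda_theta, lambda_z)
  lt <- lambda_theta; lz <- lambda_z
  E4 <- hgo_fiber_strain(params, lt, lz)
  active <- if (tension_only) as.numeric(E4 > 0) else 1
  # per-family dPsi/dE = k1 E exp(k2 E^2); capped exponent as in the energy
  fib <- if (params$k1 == 0) 0 else
    active * params$k1 * E4 * exp(pmin(params$k2 * E4^2, 700))
  # each family contributes k1/(2k2) d/dE[exp(k2 E^2)-1] = k1 E exp(k2 E^2);
  # two identical families double it:
  dPsi_dI1 <- params$c / 2 + 2 * fib * params$kappa
  dPsi_dI4 <- 2 * fib * (1 - 3 * params$kappa)
  dI1_dlt <- 2 * lt - 2 * lt^-3 * lz^-2
  dI1_dlz <- 2 * lz - 2 * lz^-3 * lt^-2
  dI4_dlt <- 2 * lt * cos(params$gamma)^2
  dI4_dlz <- 2 * lz * sin(params$gamma)^2
  list(sigma_theta = lt * (dPsi_dI1 * dI1_dlt + dPsi_dI4 * dI4_dlt),
       sigma_z     = lz * (dPsi_dI1 * dI1_dlz + dPsi_dI4 * dI4_dlz))
}

#' Elastic modulus from the isotropic HGO contribution
#'
#' A rough overall stiffness measure, \eqn{E = c (1 + \nu)}, with Poisson's
#' ratio \code{nu} defaulting to the incompressible value 0.5.
#'
#' @param c neo-Hookean modulus (MPa), >= 0.
#' @param nu Poisson's ratio in \code{[0, 0.5]}.
#' @return elastic modulus E (MPa).
#' @export
elastic_modulus <- function(c, nu = 0.5) {
  if (any(c < 0)) stop("c must be >= 0")
  if (any(nu < 0 | nu > 0.5)) stop("nu must lie in [0, 0.5]")
  c * (1 + nu)
}

#' Thin-wall Laplace stresses from pressure-diameter-force records
#'
#' Optional pre-processing for raw pressure myograph output: circumferential
#' stress \eqn{\sigma_\theta = P r / h} and axial stress
#' \eqn{\sigma_z = (f + P \pi r^2) / (\pi h (2 r + h))} for deformed inner
#' radius \code{r} and wall thickness \code{h}.
#'
#' @param pressure_mmhg luminal pressure (mmHg).
#' @param inner_radius_mm deformed inner radius (mm).
#' @param thickness_mm deformed wall thickness (mm).
#' @param axial_force_mN transducer axial force (mN).
#' @return list with \code{sigma_theta} and \code{sigma_z} in MPa.
#' @export
laplace_stresses <- function(pressure_mmhg, inner_radius_mm, thickness_mm,
                             axial_force_mN) {
  if (any(inner_radius_mm <= 0) || any(thickness_mm <= 0))
    stop("radius and thickness must be > 0")
  p_mpa <- mmhg_to_pa(pressure_mmhg) * 1e-6    # MPa
  f_n <- axial_force_mN * 1e-3                 # N; 1 N/mm^2 = 1 MPa
  r <- inner_radius_mm; h <- thickness_mm
  list(sigma_theta = p_mpa * r / h,
       sigma_z = (f_n + p_mpa * pi * r^2) / (pi * h * (2 * r + h)))
}

#' Assemble a biaxial mechanical-test sample
#'
#' Records of (circumferential stretch, axial stretch, circumferential and
#' axial Cauchy stress) labelled by loading protocol. The canonical protocol
#' vocabulary covers three inflation sweeps at fixed axial stretch
#' (\code{inflation_1.3/1.4/1.5}) and three axial-extension sweeps at fixed
#' pressure (\code{extension_50/100/150}); other labels are accepted as
#' \code{"custom"}-style protocols.
#'
#' @param records data.frame with columns \code{protocol_id},
#'   \code{lambda_theta}, \code{lambda_z}, \code{sigma_theta_mpa},
#'   \code{sigma_z_mpa}.
#' @param unloaded optional list with \code{outer_diameter_mm} and
#'   \code{thickness_mm} of the unloaded ring.
#' @return object of class \code{biaxial_sample}.
#' @export
biaxial_sample <- function(records, unloaded = NULL) {
  need <- c("protocol_id", "lambda_theta", "lambda_z",
            "sigma_theta_mpa", "sigma_z_mpa")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(records$lambda_theta <= 0) || any(records$lambda_z <= 0))
    stop("stretches must be > 0")
  structure(list(records = as.data.frame(records), unloaded = unloaded),
            class = "biaxial_sample")
}

#' Canonical six-protocol labels
#' @return character vector of the six protocol ids.
#' @export
biaxial_protocols <- function() {
  c("inflation_1.3", "inflation_1.4", "inflation_1.5",
    "extension_50", "extension_100", "extension_150")
}

#' Read / write biaxial CSV
#'
#' CSV columns: \code{protocol_id, lambda_theta, lambda_z, sigma_theta_mpa,
#' sigma_z_mpa}.
#'
#' @param path CSV file path.
#' @return \code{read_biaxial_csv}: a \code{\link{biaxial_sample}}.
#' @export
read_biaxial_csv <- function(path) {
  biaxial_sample(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_biaxial_csv
#' @param sample a \code{\link{biaxial_sample}}.
#' @export
write_biaxial_csv <- function(sample, path) {
  write.csv(sample$records, path, row.names = FALSE)
  invisible(path)
}

# Latin-hypercube-style stratified draws in [0,1]^d
lhs_unit <- function(n, d) {
  sapply(seq_len(d), function(j) (sample(n) - runif(n)) / n)
}

#' Fit the HGO model to biaxial stress data
#'
#' Minimizes the mean squared error between model and experimental
#' circumferential plus axial Cauchy stresses,
#' \eqn{\mathrm{mean}[(\sigma_\theta - \sigma_\theta^{exp})^2 +
#' (\sigma_z - \sigma_z^{exp})^2]}, over bounded parameters
#' using \code{n_starts} L-BFGS-B runs from Latin-hypercube initial points.
#' The best (lowest-MSE) run wins; ties go to the lower \code{k2}.
#'
#' @param data a \code{\link{biaxial_sample}} with >= 10 records spanning
#'   >= 2 protocols.
#' @param n_starts number of multistart local minimizations (default 20).
#' @param seed RNG seed making the multistart deterministic.
#' @param lower,upper named bounds for \code{c, k1, k2, kappa, gamma}
#'   (gamma in radians). Defaults: c in (0, 50], k1 in [0, 50], k2 in
#'   (0, 100], kappa in [0, 1/3], gamma in [0, pi/2]. A fit landing on the
#'   kappa bound is flagged with a warning.
#' @param nu Poisson's ratio for the derived elastic modulus (default 0.5).
#' @param tension_only tension-only fiber switch passed to the model.
#' @param fixed optional named numeric vector of parameters held at the
#'   given values (e.g. \code{c(kappa = 0.17, gamma = 0.78)}) while the
#'   rest are fitted.
#' @return object of class \code{hgo_fit}: \code{params}, \code{mse} (MPa^2),
#'   \code{per_protocol_rmse}, \code{n_starts}, \code{converged},
#'   \code{elastic_modulus}, \code{start_spread} (sd of per-start parameter
#'   vectors among near-optimal starts; large spread signals
#'   non-identifiability).
#' @export
fit_hgo <- function(data, n_starts = 20, seed = 1,
                    lower = c(c = 1e-4, k1 = 0, k2 = 1e-4, kappa = 0, gamma = 0),
                    upper = c(c = 50, k1 = 50, k2 = 100, kappa = 1 / 3,
                              gamma = pi / 2),
                    nu = 0.5, tension_only = TRUE, fixed = NULL) {
  stopifnot(inherits(data, "biaxial_sample"))
  rec <- data$records
  if (nrow(rec) < 10) stop("need >= 10 records for identifiability")
  if (length(unique(rec$protocol_id)) < 2)
    warning("single-protocol data: HGO parameters are weakly identifiable")
  nm <- c("c", "k1", "k2", "kappa", "gamma")
  lower <- lower[nm]; upper <- upper[nm]
  free <- setdiff(nm, names(fixed))

  full_theta <- function(theta_free) {
    th <- setNames(numeric(5), nm)
    th[free] <- theta_free
    if (length(fixed)) th[names(fixed)] <- fixed
    th
  }
  obj <- function(theta_free) {
    th <- full_theta(theta_free)
    p <- structure(as.list(th), class = "hgo_params")
    s <- hgo_cauchy_stress(p, rec$lambda_theta, rec$lambda_z,
                           tension_only = tension_only)
    mean((s$sigma_theta - rec$sigma_theta_mpa)^2 +
         (s$sigma_z - rec$sigma_z_mpa)^2)
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  u <- lhs_unit(n_starts, length(free))
  starts <- sweep(sweep(u, 2, (upper - lower)[free], "*"), 2, lower[free], "+")
  colnames(starts) <- free

  run_one <- function(par0) {
    tryCatch(
      optim(par0, obj, method = "L-BFGS-B",
            lower = lower[free], upper = upper[free],
            control = list(maxit = 2000, factr = 1, pgtol = 0)),
      error = function(e) NULL)
  }
  runs <- lapply(seq_len(n_starts), function(i) run_one(starts[i, ]))
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) {
    return(structure(list(params = NULL, mse = NA_real_,
                          per_protocol_rmse = NULL, n_starts = n_starts,
                          converged = FALSE, elastic_modulus = NA_real_,
                          start_spread = NA_real_,
                          diagnostics = "all starts failed"),
                     class = "hgo_fit"))
  }
  runs <- runs[ok]
  mses <- vapply(runs, function(r) r$value, numeric(1))
  k2s <- vapply(runs, function(r) full_theta(r$par)[["k2"]], numeric(1))
  best_i <- order(mses, k2s)[1]
  best <- runs[[best_i]]
  # polish the leading starts with tighter PORT local runs
  for (i in utils::head(order(mses, k2s), 3)) {
    pol <- tryCatch(
      stats::nlminb(runs[[i]]$par, obj, lower = lower[free],
                    upper = upper[free],
                    control = list(eval.max = 5000, iter.max = 2000,
                                   rel.tol = 1e-15, x.tol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(pol) && is.finite(pol$objective) &&
        pol$objective < best$value)
      best <- list(par = pol$par, value = pol$objective,
                   convergence = best$convergence)
  }
  theta <- full_theta(best$par)

  if (theta["kappa"] > upper["kappa"] - 1e-6)
    warning("fitted kappa is at its upper bound (", signif(upper["kappa"], 4),
            "); consider relaxing `upper['kappa']`")

  params <- hgo_params(theta["c"], theta["k1"], theta["k2"], theta["kappa"],
                       min(theta["gamma"], pi / 2),
                       kappa_max = upper["kappa"])
  s <- hgo_cauchy_stress(params, rec$lambda_theta, rec$lambda_z,
                         tension_only = tension_only)
  sq <- (s$sigma_theta - rec$sigma_theta_mpa)^2 +
        (s$sigma_z - rec$sigma_z_mpa)^2
  per_proto <- tapply(sq, rec$protocol_id, function(v) sqrt(mean(v) / 2))

  near <- mses <= min(mses) * 1.01 + 1e-12
  spread <- if (sum(near) > 1) {
    mat <- do.call(rbind, lapply(runs[near], function(r) r$par))
    mean(apply(mat, 2, sd) / pmax(abs(colMeans(mat)), 1e-8))
  } else {
    mat <- do.call(rbind, lapply(runs, function(r) r$par))
    mean(apply(mat, 2, sd) / pmax(abs(colMeans(mat)), 1e-8))
  }

  structure(list(params = params, mse = best$value,
                 per_protocol_rmse = as.list(per_proto),
                 n_starts = n_starts,
                 converged = best$convergence == 0,
                 elastic_modulus = elastic_modulus(theta[["c"]], nu),
                 nu = nu, seed = seed, start_spread = spread,
                 diagnostics = NULL),
            class = "hgo_fit")
}

#' @export
print.hgo_fit <- function(x, ...) {
  cat("HGO fit (", x$n_starts, " starts): mse = ", signif(x$mse, 4),
      " MPa^2, converged = ", x$converged, "\n", sep = "")
  if (!is.null(x$params)) print(x$params)
  cat("elastic modulus E = c(1+nu) =", signif(x$elastic_modulus, 4), "MPa\n")
  invisible(x)
}

#' Serialize a fit result to JSON
#' @param fit an \code{hgo_fit}.
#' @param path output path.
#' @export
write_fit_json <- function(fit, path) {
  p <- fit$params
  out <- list(
    params = list(c = p$c, k1 = p$k1, k2 = p$k2, kappa = p$kappa,
                  gamma_rad = p$gamma, gamma_deg = p$gamma * 180 / pi),
    mse = fit$mse, per_protocol_rmse = fit$per_protocol_rmse,
    n_starts = fit$n_starts, seed = fit$seed, converged = fit$converged,
    elastic_modulus = fit$elastic_modulus, nu = fit$nu)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# save/restore global RNG state so seeded helpers don't clobber the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
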