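# Seeded generators emulating every input of the mouse ATAA study: biaxial
# test protocols, WSS fields with controllable oscillatory content, tortuous
# aneurysmal vessels, the systolic inflow waveform, and censored lifespan
# cohorts. Each generator records a ground-truth sidecar (attribute "truth")
# sufficient to score downstream recovery.

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  expr
}

#' Generator configuration for the synthetic cohort
#'
#' Bundles the "stated world" of the emulated study: cohort size 10 with
#' lifespans right-censored at 25 months, murine cardiac period 0.1 s
#' (about 600 bpm), cohort-mean HGO truth for the wall, and a linear-Gaussian
#' lifespan model driven by one biomarker.
#'
#' @param seed RNG seed.
#' @param n_subjects cohort size (default 10).
#' @param hgo_truth \code{\link{hgo_params}} generator truth.
#' @param stress_noise_kpa biaxial stress noise sd (kPa).
#' @param geometry_noise_mm centerline jitter sd (mm).
#' @param period cardiac period T (s).
#' @param censor_level censoring age (months, default 25).
#' @param lifespan_beta0,lifespan_beta1 intercept/slope of the latent
#'   lifespan model (months; slope per unit of the predictor biomarker).
#' @param lifespan_sigma residual sd of the latent lifespan (months).
#' @param lifespan_predictor biomarker column driving lifespan
#'   (default \code{"OSI_mean"}).
#' @return validated list of class \code{generator_config}.
#' @export
generator_config <- function(seed = 1, n_subjects = 10,
                             hgo_truth = hgo_reference_params(),
                             stress_noise_kpa = 5,
                             geometry_noise_mm = 0.02,
                             period = 0.1,
                             censor_level = 25,
                             lifespan_beta0 = 2,
                             lifespan_beta1 = 60,
                             lifespan_sigma = 2.5,
                             lifespan_predictor = "OSI_mean") {
  stopifnot(inherits(hgo_truth, "hgo_params"))
  if (stress_noise_kpa < 0 || geometry_noise_mm < 0 || lifespan_sigma < 0)
    stop("noise levels must be >= 0")
  if (period <= 0 || censor_level <= 0 || n_subjects < 3)
    stop("invalid config")
  structure(list(seed = seed, n_subjects = n_subjects, hgo_truth = hgo_truth,
                 stress_noise_kpa = stress_noise_kpa,
                 geometry_noise_mm = geometry_noise_mm, period = period,
                 censor_level = censor_level,
                 lifespan_beta0 = lifespan_beta0,
                 lifespan_beta1 = lifespan_beta1,
                 lifespan_sigma = lifespan_sigma,
                 lifespan_predictor = lifespan_predictor),
            class = "generator_config")
}

#' Generate six-protocol biaxial test data from known HGO truth
#'
#' Emulates the pressure-myograph design: three inflation sweeps
#' (0--175 mmHg at axial stretches 1.3, 1.4, 1.5) and three axial-extension
#' sweeps (lambda_z 1.3--1.5 at 50, 100, 150 mmHg). For each load state the
#' circumferential stretch solves the thin-wall (Laplace) equilibrium
#' \eqn{\sigma_\theta(\lambda_\theta, \lambda_z) = P \lambda_\theta^2
#' \lambda_z R / H} (unloaded mid-wall radius R, thickness H) by bracketed
#' root finding; Gaussian noise is then added to both stress components.
#'
#' @param truth an \code{\link{hgo_params}} ground truth.
#' @param geometry list with \code{outer_diameter_mm} and
#'   \code{thickness_mm} of the unloaded ring (defaults 1.2 / 0.142 mm).
#' @param noise_sd_kpa i.i.d. stress noise sd (kPa; 0 = noiseless).
#' @param n_per_protocol load states per protocol (default 15).
#' @param seed RNG seed.
#' @return a \code{\link{biaxial_sample}} with attribute \code{"truth"}
#'   (truth parameters, geometry, noise level, seed).
#' @export
gen_biaxial <- function(truth = hgo_reference_params(),
                        geometry = list(outer_diameter_mm = 1.2,
                                        thickness_mm = 0.142),
                        noise_sd_kpa = 0, n_per_protocol = 15, seed = 1) {
  stopifnot(inherits(truth, "hgo_params"))
  R <- (geometry$outer_diameter_mm - geometry$thickness_mm) / 2  # mid-wall
  H <- geometry$thickness_mm
  solve_lt <- function(p_mpa, lz, protocol) {
    g <- function(lt)
      hgo_cauchy_stress(truth, lt, lz)$sigma_theta - p_mpa * lt^2 * lz * R / H
    out <- tryCatch(uniroot(g, c(0.25, 4), tol = 1e-12), error = function(e) e)
    if (inherits(out, "error"))
      stop("thin-wall equilibrium root finding failed in protocol ", protocol)
    out$root
  }
  rows <- list()
  for (lz in c(1.3, 1.4, 1.5)) {
    proto <- sprintf("inflation_%.1f", lz)
    for (p in seq(0, 175, length.out = n_per_protocol)) {
      lt <- solve_lt(mmhg_to_pa(p) * 1e-6, lz, proto)
      rows[[length(rows) + 1]] <- data.frame(
        protocol_id = proto, pressure_mmhg = p,
        lambda_theta = lt, lambda_z = lz)
    }
  }
  for (p in c(50, 100, 150)) {
    proto <- sprintf("extension_%d", p)
    for (lz in seq(1.3, 1.5, length.out = n_per_protocol)) {
      lt <- solve_lt(mmhg_to_pa(p) * 1e-6, lz, proto)
      rows[[length(rows) + 1]] <- data.frame(
        protocol_id = proto, pressure_mmhg = p,
        lambda_theta = lt, lambda_z = lz)
    }
  }
  rec <- do.call(rbind, rows)
  s <- hgo_cauchy_stress(truth, rec$lambda_theta, rec$lambda_z)
  noise <- noise_sd_kpa * 1e-3  # MPa
  with_seed(seed, {
    rec$sigma_theta_mpa <- s$sigma_theta + rnorm(nrow(rec), 0, noise)
    rec$sigma_z_mpa <- s$sigma_z + rnorm(nrow(rec), 0, noise)
  })
  out <- biaxial_sample(rec, unloaded = geometry)
  attr(out, "truth") <- list(params = unclass(truth), geometry = geometry,
                             noise_sd_kpa = noise_sd_kpa, seed = seed)
  out
}

# continuous-time per-node TAWSS and OSI of the surrogate WSS field
# tau(t) = A [ ((1-f) + f cos(wt)) e1 + g sin(wt) e2 ], by dense quadrature
wss_truth_quadrature <- function(A, f, g, n_quad = 4096) {
  th <- seq(0, 2 * pi, length.out = n_quad + 1)
  co <- cos(th); si <- sin(th)
  w <- trapz_weights(th) / (2 * pi)
  tawss <- numeric(length(A)); osi <- numeric(length(A))
  for (i in seq_along(A)) {
    c1 <- (1 - f[i]) + f[i] * co
    c2 <- g[i] * si
    mag <- sqrt(c1^2 + c2^2)
    imean <- sum(mag * w)
    n1 <- sum(c1 * w); n2 <- sum(c2 * w)
    tawss[i] <- A[i] * imean
    osi[i] <- if (imean > 0) 0.5 * (1 - sqrt(n1^2 + n2^2) / imean) else 0
  }
  list(tawss = tawss, osi = osi)
}

#' Generate a surrogate WSS time series on a tubular mesh
#'
#' Stand-in for a 3D fluid--structure solution: a cylindrical surface with
#' region labels (ascending / arch / descending thirds) carrying per-node
#' WSS vectors \deqn{\tau(t) = A\left[((1-f) + f\cos(2\pi t/T))\,\hat e_1 +
#' g\sin(2\pi t/T)\,\hat e_2\right],} where \code{A} is the magnitude scale
#' (Pa), \code{f} in [0,1] the oscillatory fraction (f = 1, g = 0 gives
#' symmetric full reversal, OSI = 0.5) and \code{g} a transverse sway.
#' Default spatial profiles emulate the study's qualitative pattern -- low
#' TAWSS in the aneurysmal ascending region, high oscillation in the
#' tortuous descending aorta -- with summary statistics inside the published
#' cohort ranges. The continuous-time per-node TAWSS/OSI ground truth
#' (dense-quadrature, independent of \code{n_times}) is attached as
#' attribute \code{"truth"}.
#'
#' @param n_circ,n_axial mesh resolution (default 12 x 24).
#' @param n_times time samples over one cycle (>= 8, default 32).
#' @param period cardiac period T (s).
#' @param amplitude per-node magnitude A (Pa): scalar, length-n vector, or
#'   NULL for the default axial profile.
#' @param osc_frac per-node oscillatory fraction f in [0, 1] (scalar, vector
#'   or NULL for the default regional profile).
#' @param sway per-node transverse fraction g (scalar, vector or NULL for
#'   the default regional profile: near zero in the ascending region, 0.2
#'   elsewhere).
#' @param radius_mm,length_mm tube geometry.
#' @param seed RNG seed for the small node-level variability.
#' @return a \code{\link{wss_series}} with attribute \code{"truth"} (lists
#'   \code{tawss}, \code{osi}, plus the A/f/g fields and seed).
#' @export
gen_wss_field <- function(n_circ = 12, n_axial = 24, n_times = 32,
                          period = 0.1, amplitude = NULL, osc_frac = NULL,
                          sway = NULL, radius_mm = 0.75, length_mm = 20,
                          seed = 1) {
  if (n_times < 8) stop("need n_times >= 8")
  n <- n_circ * n_axial
  ax <- rep(seq(0, 1, length.out = n_axial), each = n_circ)  # axial fraction
  ang <- rep(seq(0, 2 * pi, length.out = n_circ + 1)[-1], n_axial)
  region <- cut(ax, c(-0.01, 1 / 3, 2 / 3, 1.01),
                labels = c("ascending", "arch", "descending"))
  region <- as.character(region)

  with_seed(seed, {
    if (is.null(amplitude)) {
      # low TAWSS in the ascending (aneurysmal) region, high distally
      base <- ifelse(region == "ascending", 0.25,
              ifelse(region == "arch", 2.5, 5.5))
      amplitude <- base * exp(rnorm(n, 0, 0.25)) + 2.5 * ax^2
    } else if (length(amplitude) == 1) amplitude <- rep(amplitude, n)
    if (is.null(osc_frac)) {
      osc_frac <- ifelse(region == "descending",
                         runif(n, 0.8, 1),
                         ifelse(region == "arch", runif(n, 0.55, 0.8),
                                runif(n, 0.0005, 0.1)))
    } else if (length(osc_frac) == 1) osc_frac <- rep(osc_frac, n)
    if (is.null(sway)) {
      # near-unidirectional shear in the ascending region
      sway <- ifelse(region == "ascending", runif(n, 0.002, 0.02), 0.2)
    } else if (length(sway) == 1) sway <- rep(sway, n)
  })
  if (any(osc_frac < 0 | osc_frac > 1))
    stop("oscillatory fraction must lie in [0, 1]")

  nodes <- cbind(radius_mm * cos(ang), radius_mm * sin(ang), ax * length_mm)
  # local surface basis: e1 axial, e2 circumferential
  e1 <- cbind(0, 0, 1)[rep(1, n), ]
  e2 <- cbind(-sin(ang), cos(ang), 0)
  times <- seq(0, period, length.out = n_times)
  tau <- array(0, c(n, n_times, 3))
  for (j in seq_len(n_times)) {
    ph <- 2 * pi * times[j] / period
    c1 <- amplitude * ((1 - osc_frac) + osc_frac * cos(ph))
    c2 <- amplitude * sway * sin(ph)
    tau[, j, ] <- c1 * e1 + c2 * e2
  }
  out <- wss_series(nodes, times, tau, region = region)
  tq <- wss_truth_quadrature(amplitude, osc_frac, sway)
  attr(out, "truth") <- list(tawss = tq$tawss, osi = tq$osi,
                             amplitude = amplitude, osc_frac = osc_frac,
                             sway = sway, seed = seed)
  out
}

#' Generate a tortuous, optionally aneurysmal vessel
#'
#' A sinusoidally perturbed centerline along z with a Gaussian diameter
#' bulge in the ascending segment, with analytic (dense-sample) AL, GL, ATI
#' and D_max recorded in the sidecar; optionally voxelized to a binary axial
#' mask stack at MR-like resolution (defaults 187.5 um in-plane, 500 um
#' slices).
#'
#' @param tortuosity_amplitude_mm lateral sine amplitude a (mm); 0 gives a
#'   straight vessel (ATI = 0). Default 1.9 (ATI about 40).
#' @param n_waves number of lateral periods over the length (default 2).
#' @param bulge_peak_mm peak (aneurysmal) diameter (mm, default 3.0).
#' @param base_diameter_mm baseline diameter (mm, default 1.2).
#' @param length_mm vessel length (default 20).
#' @param n_points emitted centerline samples (default 201).
#' @param noise_mm centroid jitter sd (mm, default 0).
#' @param voxelize also build a \code{\link{mask_stack}}.
#' @param pixel_mm,slice_mm voxelization resolution.
#' @param seed RNG seed (jitter only).
#' @return a \code{\link{centerline}} with attribute \code{"truth"} (AL, GL,
#'   ATI, D_max) and, if \code{voxelize}, attribute \code{"mask_stack"}.
#' @export
gen_vessel <- function(tortuosity_amplitude_mm = 1.9, n_waves = 2,
                       bulge_peak_mm = 3.0, base_diameter_mm = 1.2,
                       length_mm = 20, n_points = 201, noise_mm = 0,
                       voxelize = FALSE, pixel_mm = 0.1875, slice_mm = 0.5,
                       seed = 1) {
  if (base_diameter_mm <= 0 || length_mm <= 0) stop("dimensions must be > 0")
  if (tortuosity_amplitude_mm > length_mm / 2)
    stop("requested tortuosity amplitude yields a self-intersecting vessel")
  a <- tortuosity_amplitude_mm
  curve <- function(t) cbind(a * sin(2 * pi * n_waves * t),
                             0.5 * a * (1 - cos(2 * pi * n_waves * t)),
                             length_mm * t)
  diam <- function(t) base_diameter_mm +
    (bulge_peak_mm - base_diameter_mm) * exp(-(t - 0.2)^2 / (2 * 0.05^2))

  td <- seq(0, 1, length.out = 20001)      # dense reference sampling
  pd <- curve(td)
  al <- sum(sqrt(rowSums(diff(pd)^2)))
  gl <- sqrt(sum((pd[nrow(pd), ] - pd[1, ])^2))
  truth <- list(al = al, gl = gl, ati = (al / gl - 1) * 100,
                d_max = max(diam(td)), seed = seed)

  t <- seq(0, 1, length.out = n_points)
  pts <- curve(t)
  if (noise_mm > 0)
    pts <- with_seed(seed, pts + matrix(rnorm(length(pts), 0, noise_mm),
                                        ncol = 3))
  cl <- centerline(pts, diam(t),
                   region = ifelse(t < 1 / 3, "ascending",
                                   ifelse(t < 2 / 3, "arch", "descending")))
  attr(cl, "truth") <- truth
  if (voxelize) {
    margin <- bulge_peak_mm / 2 + pixel_mm
    xr <- range(pts[, 1]); yr <- range(pts[, 2])
    x0 <- xr[1] - margin; y0 <- yr[1] - margin
    nx <- ceiling((diff(xr) + 2 * margin) / pixel_mm) + 1
    ny <- ceiling((diff(yr) + 2 * margin) / pixel_mm) + 1
    nz <- floor(length_mm / slice_mm) + 1
    px <- (seq_len(nx) - 1) * pixel_mm + x0
    py <- (seq_len(ny) - 1) * pixel_mm + y0
    slices <- vector("list", nz)
    for (k in seq_len(nz)) {
      z <- (k - 1) * slice_mm
      tk <- z / length_mm
      ck <- curve(tk); r <- diam(tk) / 2
      m <- outer((px - ck[1])^2, (py - ck[2])^2, "+") <= r^2
      slices[[k]] <- m * 1L
    }
    st <- mask_stack(slices, pixel_mm, slice_mm)
    # mask coordinates are relative to the grid origin; record the offset
    attr(st, "origin_mm") <- c(x0, y0, 0)
    attr(cl, "mask_stack") <- st
  }
  cl
}

#' Generate a systolic inflow waveform
#'
#' Smooth C1-continuous half-cycle: \eqn{Q(t) = Q_{peak}\sin^2(\pi
#' t/(sT))} during systole (fraction \code{s} of the period), zero in
#' diastole. Emulates the shape of a murine aortic-root flow waveform; the
#' stroke volume \eqn{Q_{peak} s T / 2} is recorded in the sidecar.
#'
#' @param period cardiac period T (s, default 0.1).
#' @param peak_flow peak flow rate (mm^3/s, default 1500; stroke volume
#'   about 26 uL at the defaults).
#' @param systole_fraction systolic fraction of the cycle in (0, 1).
#' @param n_times samples over one period (default 64).
#' @return a \code{\link{flow_waveform}} with attribute \code{"truth"}
#'   (stroke volume, mean flow).
#' @export
gen_inflow <- function(period = 0.1, peak_flow = 1500,
                       systole_fraction = 0.35, n_times = 64) {
  if (systole_fraction <= 0 || systole_fraction >= 1)
    stop("systole fraction must lie in (0, 1)")
  tt <- seq(0, period, length.out = n_times)
  ts <- systole_fraction * period
  q <- ifelse(tt <= ts, peak_flow * sin(pi * tt / ts)^2, 0)
  wf <- flow_waveform(tt, q, period)
  attr(wf, "truth") <- list(stroke_volume = peak_flow * ts / 2,
                            mean_flow = peak_flow * ts / 2 / period)
  wf
}

#' Generate a two-timepoint censored lifespan cohort
#'
#' Draws per-subject six-month biomarkers uniformly within the published
#' cohort ranges, derives two-month values by subtracting a change drawn
#' within the published delta ranges, and generates lifespan from the
#' linear-Gaussian latent model \eqn{LS^* = \beta_0 + \beta_1 x + \epsilon}
#' on the configured predictor, right-censored at the censor level.
#'
#' @param config a \code{\link{generator_config}}.
#' @return list with \code{t6} and \code{t2} cohort data.frames (class
#'   \code{cohort_table} for \code{t6}) and a \code{truth} sidecar
#'   (beta0, beta1, sigma, predictor, latent lifespans).
#' @export
gen_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  rng <- biomarker_ranges()
  base_vars <- rng$abbrev[!grepl("^delta_", rng$abbrev) & rng$abbrev != "LS"]
  n <- config$n_subjects
  with_seed(config$seed, {
    t6 <- data.frame(subject_id = sprintf("S%03d", seq_len(n)))
    for (v in base_vars) {
      r <- rng[rng$abbrev == v, ]
      t6[[v]] <- runif(n, r$lo, r$hi)
    }
    t2 <- t6
    for (v in base_vars) {
      dv <- paste0("delta_", v)
      if (dv %in% rng$abbrev) {
        r <- rng[rng$abbrev == dv, ]
        rb <- rng[rng$abbrev == v, ]
        # growth from 2 to 6 months: earlier values are lower; the change is
        # drawn inside its published range, truncated so the two-month value
        # stays above the published biomarker minimum
        hi_eff <- pmin(r$hi, t6[[v]] - rb$lo)
        delta <- numeric(n)
        ok <- hi_eff > r$lo
        delta[ok] <- runif(sum(ok), r$lo, hi_eff[ok])
        delta[!ok] <- pmax(t6[[v]][!ok] - rb$lo, 0)
        t2[[v]] <- t6[[v]] - delta
      }
    }
    x <- t6[[config$lifespan_predictor]]
    latent <- config$lifespan_beta0 + config$lifespan_beta1 * x +
      rnorm(n, 0, config$lifespan_sigma)
  })
  cens <- latent >= config$censor_level
  ls <- pmin(latent, config$censor_level)
  t6$lifespan_months <- ls; t6$censored <- as.integer(cens)
  t2$lifespan_months <- ls; t2$censored <- as.integer(cens)
  t6 <- cohort_table(t6, y_max = config$censor_level)
  truth <- list(beta0 = config$lifespan_beta0, beta1 = config$lifespan_beta1,
                sigma = config$lifespan_sigma,
                predictor = config$lifespan_predictor,
                latent_lifespan = latent, seed = config$seed)
  list(t6 = t6, t2 = t2, truth = truth)
}

#' Write a generator ground-truth sidecar
#'
#' Serializes the \code{"truth"} attribute of a generated object to
#' \code{<output>.truth.json}.
#'
#' @param x a generated object carrying a \code{"truth"} attribute.
#' @param output_path the path of the primary output file.
#' @return the sidecar path, invisibly.
#' @export
write_truth_sidecar <- function(x, output_path) {
  truth <- attr(x, "truth")
  if (is.null(truth)) stop("object has no ground-truth sidecar")
  path <- paste0(output_path, ".truth.json")
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
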