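# Orchestration: per-subject biomarker assembly, two-timepoint delta
# analysis, correlation maps with scatter reports, and the material /
# rheology sensitivity harness.

#' Assemble the biomarker row for one subject
#'
#' Combines a WSS series, a centerline, and an inflow waveform with a
#' Windkessel outlet into the standard biomarker vector: P_max (mmHg, from
#' the Windkessel pressure trace), Re_max, OSI_min, OSI_mean, TAWSS_mean,
#' TAWSS_max, TAWSS_min (Pa), Wo, ATI, D_max (mm) and the pass-through
#' vMs_max (kPa) if supplied. The peak velocity for Re_max defaults to the
#' peak inflow divided by the mean-diameter lumen area; override with
#' \code{v_max_m_s} when a measured value exists.
#'
#' @param wss a \code{\link{wss_series}}.
#' @param cl a \code{\link{centerline}}.
#' @param waveform a \code{\link{flow_waveform}}.
#' @param wk a \code{\link{windkessel_params}} (default distal outlet).
#' @param flow_fraction fraction of the inflow routed to the Windkessel
#'   outlet (default 0.12; calibrated so mean pressure is physiological).
#' @param rheology \code{"carreau_yasuda"} (viscosity evaluated at the
#'   near-wall shear rate \code{shear_rate}) or \code{"newtonian"}
#'   (\code{mu_avg}).
#' @param mu_avg Newtonian / average viscosity (Pa.s, default 3.35 cP).
#' @param shear_rate near-wall shear rate for the Carreau--Yasuda branch
#'   (1/s, default 350).
#' @param rho blood density (kg/m^3).
#' @param v_max_m_s optional measured peak velocity (m/s).
#' @param vms_max_kpa optional externally supplied max von Mises stress.
#' @return one-row data.frame of biomarkers.
#' @export
subject_biomarkers <- function(wss, cl, waveform, wk = windkessel_outlets()$outlet,
                               flow_fraction = 0.12,
                               rheology = c("carreau_yasuda", "newtonian"),
                               mu_avg = cp_to_pas(3.35), shear_rate = 350,
                               rho = 1027, v_max_m_s = NULL,
                               vms_max_kpa = NA_real_) {
  rheology <- match.arg(rheology)
  mu_eff <- if (rheology == "carreau_yasuda")
    carreau_yasuda_viscosity(shear_rate) else mu_avg

  ta <- tawss(wss)
  os <- osi(wss)
  d_max_mm <- max_diameter(cl)
  d_mean_mm <- mean(cl$diameters)
  ati <- tortuosity_index(cl)

  wf_out <- flow_waveform(waveform$times, waveform$q * flow_fraction,
                          waveform$period)
  pres <- windkessel_pressure(wf_out, wk)
  p_max_mmhg <- pa_to_mmhg(max(pres$p))

  if (is.null(v_max_m_s)) {
    area_mm2 <- pi * (d_mean_mm / 2)^2
    v_max_m_s <- max(waveform$q) / area_mm2 * 1e-3  # mm/s -> m/s
  }
  re <- reynolds_max(v_max_m_s, d_max_mm * 1e-3, rho = rho, mu_avg = mu_eff)
  wo <- womersley(d_mean_mm * 1e-3, waveform$period, rho = rho, mu = mu_eff)

  data.frame(
    P_max = p_max_mmhg,
    vMs_max = vms_max_kpa,
    Re_max = re,
    OSI_min = field_summary(os, "min")$value,
    OSI_mean = field_summary(os, "mean")$value,
    TAWSS_mean = field_summary(ta, "mean")$value,
    TAWSS_max = field_summary(ta, "max")$value,
    TAWSS_min = field_summary(ta, "min")$value,
    Wo = wo,
    ATI = ati,
    D_max = d_max_mm)
}

#' Run the biomarker assembly over a cohort of subjects
#'
#' Each subject is a list with components \code{id}, \code{wss}, \code{cl},
#' \code{waveform} and optional overrides passed to
#' \code{\link{subject_biomarkers}}. Per-subject failures are caught: the
#' run continues and failures are reported in the \code{"failures"}
#' attribute.
#'
#' @param subjects list of subject input lists.
#' @param ... defaults forwarded to \code{\link{subject_biomarkers}}.
#' @return data.frame with one row per successful subject (possibly empty),
#'   attribute \code{"failures"} naming the failed ids.
#' @export
run_biomarkers <- function(subjects, ...) {
  if (length(subjects) == 0) {
    warning("empty cohort: returning empty biomarker table")
    return(structure(data.frame(), failures = character(0)))
  }
  rows <- list(); failures <- character(0)
  defaults <- list(...)
  for (s in subjects) {
    row <- tryCatch({
      args <- c(list(wss = s$wss, cl = s$cl, waveform = s$waveform),
                s[setdiff(names(s), c("id", "wss", "cl", "waveform"))],
                defaults)
      cbind(data.frame(subject_id = s$id), do.call(subject_biomarkers, args))
    }, error = function(e) {
      failures <<- c(failures, paste0(s$id, ": ", conditionMessage(e)))
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  attr(out, "failures") <- failures
  out
}

#' Correlation maps and Tobit scatter reports for a cohort
#'
#' Builds the six-month biomarker--lifespan correlation map and, when a
#' two-month table is given, the delta (two-to-six-month absolute change)
#' map; also emits per-biomarker scatter data with the fitted Tobit line
#' and the censoring cut-off, mirroring the study's correlation figures.
#'
#' @param t6 six-month \code{\link{cohort_table}}.
#' @param t2 optional two-month table (same subjects).
#' @param variables biomarker columns (default: auto-detected).
#' @param r2_method pseudo-r2 convention (see \code{\link{pseudo_r2}}).
#' @return list: \code{map_t6}, \code{map_delta} (or NULL), \code{scatter}
#'   (per-biomarker list with x, y, censored, tobit beta, cutoff).
#' @export
run_correlations <- function(t6, t2 = NULL, variables = NULL,
                             r2_method = "correlation") {
  y_max <- attr(t6, "y_max"); if (is.null(y_max)) y_max <- 25
  map6 <- correlation_map(t6, variables, r2_method = r2_method)
  vars <- setdiff(rownames(map6$r2), "LS")
  scatter <- lapply(vars, function(v) {
    fit <- tobit_fit(t6[[v]], t6$lifespan_months, t6$censored, y_max)
    list(biomarker = v, x = t6[[v]], y = t6$lifespan_months,
         censored = as.logical(t6$censored), beta = fit$beta,
         pseudo_r2 = pseudo_r2(fit, r2_method), cutoff = y_max)
  })
  names(scatter) <- vars
  map_delta <- NULL
  if (!is.null(t2)) {
    dd <- delta_biomarkers(t2, t6, variables)
    dd$lifespan_months <- t6$lifespan_months[match(dd$subject_id,
                                                   t6$subject_id)]
    dd$censored <- t6$censored[match(dd$subject_id, t6$subject_id)]
    dd <- cohort_table(dd, y_max = y_max, strict = FALSE)
    map_delta <- correlation_map(dd, r2_method = r2_method)
  }
  list(map_t6 = map6, map_delta = map_delta, scatter = scatter)
}

#' Material-parameter and rheology sensitivity harness
#'
#' Re-evaluates the biomarker vector of one synthetic subject under scaled
#' wall moduli (factors on \code{c} and \code{k1}) and under the two
#' rheology models, reporting each biomarker normalized by its baseline
#' (factor 1) value. Because the 3D solver is out of scope, wall stiffness
#' enters through a thin-wall distensibility surrogate: the effective
#' modulus \eqn{E_{eff} = c(1+\nu) + k_1} sets a diameter scale factor
#' \eqn{d_f = 1 + \phi(E_{eff}^{base}/E_{eff} - 1)} (softer wall, larger
#' lumen), and WSS magnitudes scale as \eqn{d_f^{-3}} (Poiseuille), peak
#' velocity as \eqn{d_f^{-2}}, diameters as \eqn{d_f}. OSI (a shape
#' measure) and pressures (flow-driven) are unchanged by this surrogate.
#'
#' @param subject list with \code{wss}, \code{cl}, \code{waveform} (e.g. a
#'   generated synthetic subject).
#' @param hgo baseline \code{\link{hgo_params}}.
#' @param factors multiplicative perturbations (default 0.5, 0.75, 1.25,
#'   1.5) applied to each parameter in \code{params}.
#' @param params which HGO moduli to perturb (default c and k1).
#' @param rheologies rheology models to compare.
#' @param phi diameter-sensitivity of the surrogate (default 0.1).
#' @param ... forwarded to \code{\link{subject_biomarkers}}.
#' @return long data.frame: \code{parameter}, \code{factor},
#'   \code{biomarker}, \code{value}, \code{normalized}.
#' @export
run_sensitivity <- function(subject, hgo = hgo_reference_params(),
                            factors = c(0.5, 0.75, 1.25, 1.5),
                            params = c("c", "k1"),
                            rheologies = c("carreau_yasuda", "newtonian"),
                            phi = 0.1, ...) {
  if (any(factors <= 0)) stop("factors must be > 0")
  e_base <- elastic_modulus(hgo$c) + hgo$k1

  eval_case <- function(d_f, rheology) {
    wss2 <- subject$wss
    wss2$tau <- wss2$tau / d_f^3
    cl2 <- centerline(subject$cl$points, subject$cl$diameters * d_f,
                      subject$cl$region)
    area_mm2 <- pi * (mean(subject$cl$diameters) / 2)^2
    v_base <- max(subject$waveform$q) / area_mm2 * 1e-3
    subject_biomarkers(wss2, cl2, subject$waveform, rheology = rheology,
                       v_max_m_s = v_base / d_f^2, ...)
  }

  base_row <- eval_case(1, rheologies[1])
  bio <- names(base_row)
  out <- list()
  add <- function(parameter, factor, row) {
    out[[length(out) + 1]] <<- data.frame(
      parameter = parameter, factor = factor, biomarker = bio,
      value = as.numeric(row[1, ]),
      normalized = as.numeric(row[1, ]) / as.numeric(base_row[1, ]))
  }
  add("baseline", 1, base_row)
  for (pm in params) {
    for (f in factors) {
      h2 <- unclass(hgo); h2[[pm]] <- h2[[pm]] * f
      ok <- tryCatch({
        hgo_params(h2$c, h2$k1, h2$k2, h2$kappa, h2$gamma); TRUE
      }, error = function(e) FALSE)
      if (!ok) { message("skipping invalid perturbation ", pm, " x ", f); next }
      e_pert <- elastic_modulus(h2$c) + h2$k1
      d_f <- 1 + phi * (e_base / e_pert - 1)
      add(pm, f, eval_case(d_f, rheologies[1]))
    }
  }
  for (rh in rheologies) add(paste0("rheology_", rh), 1, eval_case(1, rh))
  do.call(rbind, out)
}
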