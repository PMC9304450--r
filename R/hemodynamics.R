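# Lumped hemodynamics: Carreau-Yasuda rheology, three-element (RCR)
# Windkessel outlet pressures, Robin wall traction, and the dimensionless
# Reynolds / Womersley numbers. Internal units: Pa, mm, s, mm^3/s.

#' Carreau--Yasuda parameters
#'
#' Five-parameter shear-thinning viscosity law interpolating between the
#' zero-shear plateau \code{eta_0} and the infinite-shear plateau
#' \code{eta_inf}. Defaults are the healthy-blood values used for murine
#' aortic flow: eta_inf = 2 cP, eta_0 = 11 cP, lambda = 1.5 s, a = 0.2,
#' n = 0.71.
#'
#' @param eta_inf infinite-shear viscosity (Pa.s).
#' @param eta_0 zero-shear viscosity (Pa.s).
#' @param lambda_cy time constant (s).
#' @param a transition exponent.
#' @param n power-law index in (0, 1].
#' @return object of class \code{carreau_yasuda}.
#' @export
carreau_yasuda_params <- function(eta_inf = cp_to_pas(2),
                                  eta_0 = cp_to_pas(11),
                                  lambda_cy = 1.5, a = 0.2, n = 0.71) {
  if (!(eta_0 > eta_inf && eta_inf > 0)) stop("need eta_0 > eta_inf > 0")
  if (lambda_cy <= 0 || a <= 0) stop("lambda_cy and a must be > 0")
  if (n <= 0 || n > 1) stop("n must lie in (0, 1]")
  structure(list(eta_inf = eta_inf, eta_0 = eta_0, lambda_cy = lambda_cy,
                 a = a, n = n), class = "carreau_yasuda")
}

#' Carreau--Yasuda apparent viscosity
#'
#' \deqn{\eta(\dot\gamma) = \eta_\infty + (\eta_0 - \eta_\infty)
#' \left[1 + (\lambda\dot\gamma)^a\right]^{(n-1)/a}}
#' (the standard plus-sign form; monotone non-increasing in the shear rate
#' and bounded in \code{[eta_inf, eta_0]}).
#'
#' @param shear_rate shear rate (1/s), >= 0; vectorized.
#' @param params a \code{\link{carreau_yasuda_params}} object.
#' @return apparent viscosity (Pa.s).
#' @export
#' @examples
#' carreau_yasuda_viscosity(350)  # near-wall murine aortic shear rate
carreau_yasuda_viscosity <- function(shear_rate,
                                     params = carreau_yasuda_params()) {
  if (any(shear_rate < 0)) stop("shear rate must be >= 0")
  with(params,
       eta_inf + (eta_0 - eta_inf) * (1 + (lambda_cy * shear_rate)^a)^((n - 1) / a))
}

#' Three-element Windkessel outlet parameters
#'
#' @param r_p proximal resistance (Pa.s/mm^3).
#' @param c_wk compliance (mm^3/Pa).
#' @param r_d distal resistance (Pa.s/mm^3).
#' @param outlet_name label.
#' @return object of class \code{windkessel_params}.
#' @export
windkessel_params <- function(r_p, c_wk, r_d, outlet_name = "outlet") {
  if (any(c(r_p, c_wk, r_d) <= 0)) stop("all Windkessel parameters must be > 0")
  structure(list(r_p = r_p, c_wk = c_wk, r_d = r_d,
                 outlet_name = outlet_name), class = "windkessel_params")
}

#' Periodic inflow waveform
#'
#' @param times sample times (s), strictly increasing from 0 to the period.
#' @param q flow rate (mm^3/s) at \code{times}; must close periodically
#'   (\code{q[1] == q[length(q)]} within tolerance).
#' @param period cycle length T (s); defaults to \code{max(times)}.
#' @return object of class \code{flow_waveform}.
#' @export
flow_waveform <- function(times, q, period = max(times)) {
  if (length(times) != length(q) || length(times) < 3)
    stop("times and q must have equal length >= 3")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (abs(times[1]) > 1e-12 || abs(times[length(times)] - period) > 1e-9)
    stop("times must span [0, period]")
  qscale <- max(abs(q), 1e-12)
  if (abs(q[1] - q[length(q)]) > 1e-6 * qscale)
    stop("waveform is not periodic: q(0) != q(T)")
  structure(list(times = times, q = q, period = period),
            class = "flow_waveform")
}

#' Integrate the three-element Windkessel pressure ODE
#'
#' Solves \deqn{\frac{dp}{dt} + \frac{p}{R_d C} = \frac{Q}{C}\left(1 +
#' \frac{R_p}{R_d}\right) + R_p \frac{dQ}{dt}} by the A-stable implicit
#' trapezoidal rule on the waveform grid, with \eqn{dQ/dt} from a periodic
#' spline. The waveform is repeated until the cycle-to-cycle pressure change
#' falls below \code{tol_pa} or \code{n_cycles} is reached; the final cycle
#' is returned.
#'
#' @param waveform a \code{\link{flow_waveform}}.
#' @param params a \code{\link{windkessel_params}}.
#' @param n_cycles maximum number of cycles (default 10).
#' @param p_init initial pressure (Pa, default 0).
#' @param tol_pa cycle-to-cycle convergence tolerance (Pa, default 0.1).
#' @return list: \code{times} (s, within one cycle), \code{p} (Pa),
#'   \code{periodicity_residual} = |p(0) - p(T)| on the final cycle,
#'   \code{cycles_run}, \code{converged}.
#' @export
windkessel_pressure <- function(waveform, params, n_cycles = 10, p_init = 0,
                                tol_pa = 0.1) {
  stopifnot(inherits(waveform, "flow_waveform"),
            inherits(params, "windkessel_params"))
  tt <- waveform$times; qq <- waveform$q; T <- waveform$period
  qq[length(qq)] <- qq[1]  # periodicity already validated to tolerance
  dq_fun <- splinefun(tt, qq, method = "periodic")
  dq <- dq_fun(tt, deriv = 1)
  rhs <- qq / params$c_wk * (1 + params$r_p / params$r_d) + params$r_p * dq
  k <- 1 / (params$r_d * params$c_wk)
  n <- length(tt)
  p <- numeric(n)
  p_prev_cycle <- NULL
  p0 <- p_init
  cycles <- 0L
  converged <- FALSE
  for (cyc in seq_len(n_cycles)) {
    p[1] <- p0
    for (i in seq_len(n - 1)) {
      dt <- tt[i + 1] - tt[i]
      p[i + 1] <- (p[i] * (1 - dt * k / 2) + dt / 2 * (rhs[i] + rhs[i + 1])) /
                  (1 + dt * k / 2)
    }
    cycles <- cyc
    if (!is.null(p_prev_cycle) && max(abs(p - p_prev_cycle)) < tol_pa) {
      converged <- TRUE
      break
    }
    p_prev_cycle <- p
    p0 <- p[n]
  }
  list(times = tt, p = p, periodicity_residual = abs(p[1] - p[n]),
       cycles_run = cycles, converged = converged)
}

#' Robin (elastic support) wall traction
#'
#' Perivascular tissue support modelled as a spring--dashpot--pressure
#' boundary: \deqn{\sigma_s n = -k_s u - c_s \frac{\partial u}{\partial t} -
#' p_0 n.} Defaults: k_s = 1e7 N/m^3-type printed magnitude, c_s = 1e4,
#' p_0 = 0 Pa.
#'
#' @param u displacement vector (m).
#' @param dudt velocity vector (m/s).
#' @param normal outward unit normal.
#' @param k_s spring coefficient (default 1e7).
#' @param c_s damping coefficient (default 1e4).
#' @param p_0 external cavity pressure (Pa, default 0).
#' @return traction vector (Pa).
#' @export
robin_traction <- function(u, dudt, normal, k_s = 1e7, c_s = 1e4, p_0 = 0) {
  if (abs(sqrt(sum(normal^2)) - 1) > 1e-8) stop("normal must have unit length")
  -k_s * u - c_s * dudt - p_0 * normal
}

#' Maximum Reynolds number
#'
#' \eqn{Re = \rho V_{max} D_{max} / \mu_{avg}} with blood density
#' rho = 1027 kg/m^3 and cycle-average viscosity mu = 3.35 cP by default.
#'
#' @param v_max peak velocity (m/s).
#' @param d_max maximum diameter (m).
#' @param rho blood density (kg/m^3).
#' @param mu_avg average dynamic viscosity (Pa.s).
#' @return Reynolds number.
#' @export
reynolds_max <- function(v_max, d_max, rho = 1027, mu_avg = cp_to_pas(3.35)) {
  if (any(c(v_max, d_max, rho, mu_avg) <= 0)) stop("inputs must be > 0")
  rho * v_max * d_max / mu_avg
}

#' Womersley number
#'
#' Radius-based convention with angular frequency \eqn{\omega = 2\pi/T}:
#' \eqn{Wo = (d/2)\sqrt{2\pi\rho/(T\mu)}}.
#'
#' @param d vessel diameter (m).
#' @param period cardiac period (s).
#' @param rho blood density (kg/m^3).
#' @param mu dynamic viscosity (Pa.s).
#' @return Womersley number.
#' @export
womersley <- function(d, period, rho = 1027, mu = cp_to_pas(3.35)) {
  if (any(c(d, period, rho, mu) <= 0)) stop("inputs must be > 0")
  (d / 2) * sqrt(2 * pi * rho / (period * mu))
}
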