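# Shared independent oracles and small fixture builders.

# plain composite trapezoid, written independently of the package internals
trapz <- function(t, y) sum((y[-1] + y[-length(y)]) / 2 * diff(t))

# random 3D rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# build a single-node wss_series from a vector-valued function of time
wss_from_function <- function(f, times) {
  tau <- array(0, c(1, length(times), 3))
  for (j in seq_along(times)) tau[1, j, ] <- f(times[j])
  wss_series(matrix(0, 1, 3), times, tau)
}

# reference HGO parameter set (cohort means) used across tests
ref_params <- function() hgo_params(1.77, 0.43, 2.01, 0.17, 44.95,
                                    degrees = TRUE)

# tobit negative log-likelihood, transcribed independently in the tests
tobit_nll_oracle <- function(beta0, beta1, sigma, x, y, cens, y_max) {
  eta <- beta0 + beta1 * x
  -sum(ifelse(cens,
              pnorm((y_max - eta) / sigma, lower.tail = FALSE, log.p = TRUE),
              dnorm(y, eta, sigma, log = TRUE)))
}
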