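# Wall-shear-stress time series on a surface mesh and the derived per-node
# biomarkers TAWSS (cycle-averaged magnitude) and OSI (directional reversal).

#' Wall-shear-stress time series
#'
#' Per-node WSS vectors over one cardiac cycle on a (optionally triangulated,
#' optionally region-labelled) surface mesh.
#'
#' @param nodes n x 3 matrix of node coordinates (mm).
#' @param times sample times (s), strictly increasing, spanning \code{[0, T]}.
#' @param tau array \code{[n_nodes, n_times, 3]} of WSS vectors (Pa).
#' @param region optional per-node labels (\code{ascending}, \code{arch},
#'   \code{descending}).
#' @param triangles optional m x 3 connectivity (1-based node indices).
#' @return object of class \code{wss_series}.
#' @export
wss_series <- function(nodes, times, tau, region = NULL, triangles = NULL) {
  nodes <- as.matrix(nodes)
  if (ncol(nodes) != 3) stop("nodes must be n x 3")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!is.array(tau) || length(dim(tau)) != 3 ||
      dim(tau)[1] != nrow(nodes) || dim(tau)[2] != length(times) ||
      dim(tau)[3] != 3)
    stop("tau must be an [n_nodes, n_times, 3] array")
  if (any(!is.finite(tau))) stop("tau must be finite")
  if (!is.null(region) && length(region) != nrow(nodes))
    stop("region must have one label per node")
  structure(list(nodes = nodes, times = times, tau = tau,
                 region = region, triangles = triangles),
            class = "wss_series")
}

# trapezoid weights for a (possibly nonuniform) grid
trapz_weights <- function(t) {
  n <- length(t)
  w <- numeric(n)
  dt <- diff(t)
  w[1] <- dt[1] / 2
  w[n] <- dt[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dt[-1] + dt[-(n - 1)]) / 2
  w
}

check_series_times <- function(series) {
  if (length(series$times) < 3) stop("need >= 3 time samples")
  if (any(diff(series$times) <= 0)) stop("times must be strictly increasing")
}

#' Time-averaged wall shear stress (TAWSS)
#'
#' Per-node trapezoidal time average of the WSS magnitude,
#' \deqn{TAWSS = \frac{1}{T}\int_0^T |\tau|\,dt.}
#'
#' @param series a \code{\link{wss_series}}.
#' @return numeric vector, one non-negative value per node (Pa).
#' @export
tawss <- function(series) {
  stopifnot(inherits(series, "wss_series"))
  check_series_times(series)
  t <- series$times
  w <- trapz_weights(t)
  mag <- sqrt(series$tau[, , 1]^2 + series$tau[, , 2]^2 + series$tau[, , 3]^2)
  drop(mag %*% w) / (t[length(t)] - t[1])
}

#' Oscillatory shear index (OSI)
#'
#' \deqn{OSI = \frac{1}{2}\left(1 - \frac{|\int_0^T \tau\,dt|}
#' {\int_0^T |\tau|\,dt}\right)} per node, in \code{[0, 0.5]}: 0 when the
#' WSS vector never changes direction, 0.5 for symmetric 180-degree
#' reversal. Nodes with identically zero WSS return 0 by convention.
#'
#' @param series a \code{\link{wss_series}}.
#' @return numeric vector of per-node OSI values in \code{[0, 0.5]}.
#' @export
osi <- function(series) {
  stopifnot(inherits(series, "wss_series"))
  check_series_times(series)
  w <- trapz_weights(series$times)
  ix <- drop(series$tau[, , 1] %*% w)
  iy <- drop(series$tau[, , 2] %*% w)
  iz <- drop(series$tau[, , 3] %*% w)
  mag <- sqrt(series$tau[, , 1]^2 + series$tau[, , 2]^2 + series$tau[, , 3]^2)
  imag <- drop(mag %*% w)
  num <- sqrt(ix^2 + iy^2 + iz^2)
  out <- ifelse(imag > 0, 0.5 * (1 - num / imag), 0)
  pmin(pmax(out, 0), 0.5)
}

#' Summary statistic of a per-node scalar field
#'
#' Min / mean / max over all nodes or a region subset, as used to reduce
#' TAWSS and OSI fields to scalar biomarkers. The mean is unweighted by node
#' unless per-node \code{weights} (e.g. nodal areas) are supplied.
#'
#' @param values per-node scalar field.
#' @param statistic one of \code{"min"}, \code{"mean"}, \code{"max"}.
#' @param mask optional logical per-node selector (e.g. a region).
#' @param weights optional per-node weights for the mean.
#' @return list with \code{statistic}, \code{value}, \code{n}.
#' @export
field_summary <- function(values, statistic = c("min", "mean", "max"),
                          mask = NULL, weights = NULL) {
  statistic <- match.arg(statistic)
  if (!is.null(mask)) {
    values <- values[mask]
    if (!is.null(weights)) weights <- weights[mask]
  }
  if (length(values) == 0) stop("empty node selection")
  value <- switch(statistic,
    min = min(values),
    max = max(values),
    mean = if (is.null(weights)) mean(values)
           else sum(values * weights) / sum(weights))
  list(statistic = statistic, value = value, n = length(values))
}

#' Read / write a WSS series as a CSV bundle
#'
#' \code{mesh.csv}: \code{node_id, x, y, z, region};
#' \code{wss.csv} (long format): \code{node_id, time_s, tx, ty, tz}.
#'
#' @param mesh_path path to the mesh CSV.
#' @param wss_path path to the long-format WSS CSV.
#' @return \code{read_wss_csv}: a \code{\link{wss_series}}.
#' @export
read_wss_csv <- function(mesh_path, wss_path) {
  mesh <- read.csv(mesh_path, stringsAsFactors = FALSE)
  wss <- read.csv(wss_path, stringsAsFactors = FALSE)
  mesh <- mesh[order(mesh$node_id), ]
  times <- sort(unique(wss$time_s))
  n <- nrow(mesh); nt <- length(times)
  tau <- array(NA_real_, c(n, nt, 3))
  wss <- wss[order(wss$time_s, wss$node_id), ]
  if (nrow(wss) != n * nt) stop("wss.csv is not a complete node x time grid")
  tau[, , 1] <- matrix(wss$tx, n, nt)
  tau[, , 2] <- matrix(wss$ty, n, nt)
  tau[, , 3] <- matrix(wss$tz, n, nt)
  wss_series(as.matrix(mesh[, c("x", "y", "z")]), times, tau,
             region = if ("region" %in% names(mesh)) mesh$region else NULL)
}

#' @rdname read_wss_csv
#' @param series a \code{\link{wss_series}}.
#' @export
write_wss_csv <- function(series, mesh_path, wss_path) {
  n <- nrow(series$nodes); nt <- length(series$times)
  mesh <- data.frame(node_id = seq_len(n),
                     x = series$nodes[, 1], y = series$nodes[, 2],
                     z = series$nodes[, 3],
                     region = if (is.null(series$region)) NA else series$region)
  write.csv(mesh, mesh_path, row.names = FALSE)
  long <- data.frame(
    node_id = rep(seq_len(n), nt),
    time_s = rep(series$times, each = n),
    tx = as.vector(series$tau[, , 1]),
    ty = as.vector(series$tau[, , 2]),
    tz = as.vector(series$tau[, , 3]))
  write.csv(long, wss_path, row.names = FALSE)
  invisible(c(mesh_path, wss_path))
}
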