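# Centerline-based geometric biomarkers: actual (contour) length, geometric
# (chord) length, aortic tortuosity index ATI = (AL/GL - 1) * 100, and
# maximum fitted diameter; plus a mask-stack -> centerline extractor.

#' Vessel centerline
#'
#' Ordered 3D centroid points with per-point diameters, as fitted along the
#' aorta from the root to the bifurcation.
#'
#' @param points n x 3 matrix of centroids (mm), n >= 2, consecutive points
#'   distinct.
#' @param diameters per-point diameters (mm), > 0.
#' @param region optional per-point labels.
#' @return object of class \code{centerline}.
#' @export
centerline <- function(points, diameters, region = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must be n x 3")
  if (nrow(points) < 2) stop("need >= 2 centerline points")
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  if (any(seg == 0)) stop("consecutive centerline points must be distinct")
  if (length(diameters) != nrow(points)) stop("one diameter per point")
  if (any(diameters <= 0)) stop("diameters must be > 0")
  structure(list(points = points, diameters = diameters, region = region),
            class = "centerline")
}

#' Optional moving-average smoothing of a centerline
#' @param cl a \code{\link{centerline}}.
#' @param k odd window size (default 1 = off).
#' @return smoothed \code{centerline}.
#' @export
smooth_centerline <- function(cl, k = 1) {
  stopifnot(inherits(cl, "centerline"))
  if (k <= 1) return(cl)
  if (k %% 2 == 0) stop("k must be odd")
  n <- nrow(cl$points)
  half <- (k - 1) / 2
  sm <- cl$points
  # endpoints (and any index without a full window) are left untouched so
  # smoothing never shortens the vessel ends
  if (n > k) {
    for (i in (half + 1):(n - half)) {
      idx <- (i - half):(i + half)
      sm[i, ] <- colMeans(cl$points[idx, , drop = FALSE])
    }
  }
  centerline(sm, cl$diameters, cl$region)
}

#' Actual (contour) length of a centerline
#'
#' Sum of consecutive point-to-point Euclidean distances along the fitted
#' centroids.
#'
#' @param cl a \code{\link{centerline}}.
#' @return AL in mm.
#' @export
actual_length <- function(cl) {
  stopifnot(inherits(cl, "centerline"))
  p <- cl$points
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Geometric (chord) length of a centerline
#'
#' Straight-line distance between the first and last centroid.
#'
#' @param cl a \code{\link{centerline}}.
#' @param warn_tol warn if GL falls below this fraction of AL (near-closed
#'   curve; default 0.01).
#' @return GL in mm.
#' @export
geometric_length <- function(cl, warn_tol = 0.01) {
  stopifnot(inherits(cl, "centerline"))
  p <- cl$points
  gl <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
  if (gl < warn_tol * actual_length(cl))
    warning("endpoints nearly coincide: geometric length is degenerate")
  gl
}

#' Aortic tortuosity index
#'
#' \deqn{ATI = (AL/GL - 1) \times 100,} non-negative, zero for a straight
#' centerline, about 57.08 for a semicircular arch.
#'
#' @param cl a \code{\link{centerline}}.
#' @param gl_tol error below this GL (mm); degenerate geometry.
#' @return ATI (dimensionless, percent scale).
#' @export
tortuosity_index <- function(cl, gl_tol = 1e-9) {
  al <- actual_length(cl)
  gl <- suppressWarnings(geometric_length(cl))
  if (gl < gl_tol) stop("geometric length ~ 0: degenerate (closed) centerline")
  (al / gl - 1) * 100
}

#' Maximum fitted diameter along a centerline
#' @param cl a \code{\link{centerline}}.
#' @return D_max in mm.
#' @export
max_diameter <- function(cl) {
  stopifnot(inherits(cl, "centerline"))
  max(cl$diameters)
}

#' Binary axial mask stack
#'
#' @param slices list of binary (0/1 or logical) matrices, ordered along z.
#' @param pixel_mm in-plane pixel size (mm).
#' @param slice_mm slice thickness (mm).
#' @return object of class \code{mask_stack}.
#' @export
mask_stack <- function(slices, pixel_mm, slice_mm) {
  if (pixel_mm <= 0 || slice_mm <= 0) stop("spacings must be > 0")
  if (!length(slices)) stop("empty stack")
  structure(list(slices = slices, pixel_mm = pixel_mm, slice_mm = slice_mm),
            class = "mask_stack")
}

#' Extract a centerline from a binary axial mask stack
#'
#' Per-slice foreground centroid (voxel-center convention, 0-based indices
#' scaled to mm) and equivalent-area diameter \eqn{2\sqrt{area/\pi}}. Empty
#' slices are skipped with a message.
#'
#' @param stack a \code{\link{mask_stack}}.
#' @return a \code{\link{centerline}}.
#' @export
centerline_from_masks <- function(stack) {
  stopifnot(inherits(stack, "mask_stack"))
  pts <- list(); dia <- numeric(0)
  n_empty <- 0L
  for (k in seq_along(stack$slices)) {
    m <- stack$slices[[k]]
    idx <- which(m != 0, arr.ind = TRUE)
    if (nrow(idx) == 0) { n_empty <- n_empty + 1L; next }
    # voxel centers: 0-based index * pixel size
    x <- mean(idx[, 1] - 1) * stack$pixel_mm
    y <- mean(idx[, 2] - 1) * stack$pixel_mm
    z <- (k - 1) * stack$slice_mm
    area <- nrow(idx) * stack$pixel_mm^2
    pts[[length(pts) + 1]] <- c(x, y, z)
    dia <- c(dia, 2 * sqrt(area / pi))
  }
  if (n_empty > 0)
    message(n_empty, " empty slice(s) skipped")
  if (length(pts) < 2) stop("need >= 2 non-empty slices")
  centerline(do.call(rbind, pts), dia)
}

#' Read / write a centerline CSV
#'
#' Columns: \code{point_index, x_mm, y_mm, z_mm, diameter_mm, region}.
#'
#' @param path CSV path.
#' @return \code{read_centerline_csv}: a \code{\link{centerline}}.
#' @export
read_centerline_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  d <- d[order(d$point_index), ]
  centerline(as.matrix(d[, c("x_mm", "y_mm", "z_mm")]), d$diameter_mm,
             region = if ("region" %in% names(d)) d$region else NULL)
}

#' @rdname read_centerline_csv
#' @param cl a \code{\link{centerline}}.
#' @export
write_centerline_csv <- function(cl, path) {
  d <- data.frame(point_index = seq_len(nrow(cl$points)),
                  x_mm = cl$points[, 1], y_mm = cl$points[, 2],
                  z_mm = cl$points[, 3], diameter_mm = cl$diameters,
                  region = if (is.null(cl$region)) NA else cl$region)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
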