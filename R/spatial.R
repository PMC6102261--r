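#' Ripley K and L functions of a point pattern
#'
#' Second-order summary of clustering: for each radius r the estimator is
#' `K(r) = (area / n^2) * sum_i sum_{j != i} w_ij * 1[d_ij <= r]`, the
#' average number of neighbours within r of a typical point divided by
#' the overall intensity. Under complete spatial randomness
#' `K(r) = pi r^2`, so the derived `L(r) - r = sqrt(K/pi) - r` is zero in
#' expectation, positive for clustered patterns, and peaks near the
#' characteristic cluster scale.
#'
#' Edge corrections: `"none"` (w = 1, biased downwards near the
#' boundary), `"toroidal"` (periodic distances; unbiased for synthetic
#' periodic scenes), `"isotropic"` (Ripley's weight, the reciprocal
#' fraction of the circle of radius d_ij centred on point i that lies
#' inside the rectangular window; appropriate for real ROIs).
#'
#' @param pattern A [point_pattern()] with at least 2 points.
#' @param radii Increasing radii in nm; default 10-500 nm in 10 nm steps.
#'   A warning is issued if the maximum exceeds a quarter of the shorter
#'   window side, where edge corrections degrade.
#' @param correction `"toroidal"` (default), `"isotropic"` or `"none"`.
#' @return A data.frame of class `ripley_curve` with columns `r_nm`, `K`,
#'   `L`, `L_minus_r` and attribute `correction`.
#' @export
ripley_k <- function(pattern, radii = seq(10, 500, by = 10),
                     correction = c("toroidal", "isotropic", "none")) {
  stopifnot(inherits(pattern, "point_pattern"))
  correction <- match.arg(correction)
  n <- n_points(pattern)
  if (n < 2) stop("ripley_k: need at least 2 points")
  if (any(diff(radii) <= 0) || any(radii <= 0)) {
    stop("ripley_k: radii must be positive and strictly increasing")
  }
  sides <- window_sides_nm(pattern$window)
  if (max(radii) > min(sides) / 4) {
    warning("ripley_k: max radius exceeds a quarter of the shorter window side; edge correction unreliable")
  }
  code <- c(none = 0L, toroidal = 1L, isotropic = 2L)[[correction]]
  sums <- cpp_ripley_pair_sums(pattern$x - pattern$window$x_min,
                               pattern$y - pattern$window$y_min,
                               sides[1], sides[2], as.numeric(radii), code)
  area_nm2 <- prod(sides)
  K <- area_nm2 * sums / (n * n)
  L <- sqrt(K / pi)
  out <- data.frame(r_nm = radii, K = K, L = L, L_minus_r = L - radii)
  class(out) <- c("ripley_curve", "data.frame")
  attr(out, "correction") <- correction
  out
}

#' Point density in a region
#'
#' Number of points inside the region divided by the region area, in
#' molecules per um^2. Regions are closed: boundary points count as
#' inside (even-odd rule for polygons).
#'
#' @param pattern A [point_pattern()].
#' @param region An [obs_window()] or a 2-column polygon vertex matrix
#'   (nm). Defaults to the pattern's own window.
#' @return Density in um^-2.
#' @export
point_density <- function(pattern, region = pattern$window) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (inherits(region, "smlm_window")) {
    area <- window_area_um2(region)
    if (area <= 0) stop("point_density: zero-area region")
    return(sum(in_window(pattern$x, pattern$y, region)) / area)
  }
  region <- as.matrix(region)
  area <- polygon_area_nm2(region) / 1e6
  if (area <= 0) stop("point_density: zero-area region")
  sum(point_in_polygon(pattern$x, pattern$y, region)) / area
}

#' Mean nearest-neighbour spacing of a CSR field at a given density
#'
#' For a homogeneous Poisson process of intensity lambda (um^-2) the mean
#' nearest-neighbour distance is `1 / (2 sqrt(lambda))` — the conversion
#' used to express a measured ligand surface density as an average
#' ligand-to-ligand spacing (0.01 um^-2 corresponds to 5 um). The exact
#' inverse is `lambda = 1 / (4 spacing^2)`.
#'
#' @param density Intensity in molecules per um^2 (> 0).
#' @param unit Output unit, `"nm"` (default) or `"um"`.
#' @return Mean CSR nearest-neighbour spacing.
#' @examples
#' mean_nn_spacing_from_density(0.01, "um")  # 5 um
#' mean_nn_spacing_from_density(1)           # 500 nm
#' @export
mean_nn_spacing_from_density <- function(density, unit = c("nm", "um")) {
  unit <- match.arg(unit)
  if (any(density <= 0)) {
    stop("mean_nn_spacing_from_density: density must be > 0")
  }
  um <- 1 / (2 * sqrt(density))
  if (unit == "um") um else um * 1000
}

#' Nearest-neighbour distances within or between patterns
#'
#' For each point of `pattern_a`, the Euclidean distance to the nearest
#' point of `pattern_b` (the cross-channel distances entering the DoC
#' correction) or, when `pattern_b` is omitted, to its own nearest
#' neighbour (self excluded).
#'
#' @param pattern_a Query [point_pattern()].
#' @param pattern_b Target [point_pattern()]; `NULL` for self-distances.
#' @return Numeric vector of distances in nm, length `n_points(pattern_a)`.
#' @export
nn_distances <- function(pattern_a, pattern_b = NULL) {
  stopifnot(inherits(pattern_a, "point_pattern"))
  self <- is.null(pattern_b)
  tgt <- if (self) pattern_a else pattern_b
  stopifnot(inherits(tgt, "point_pattern"))
  if (n_points(tgt) < 1 + self) {
    stop("nn_distances: target pattern has no (other) points")
  }
  cpp_nn_dist(pattern_a$x, pattern_a$y, tgt$x, tgt$y, self)
}
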