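#' Rectangular observation window
#'
#' Defines the region over which point patterns live and over which
#' intensities (molecules per square micrometre) are computed. All
#' coordinates in the package are in nanometres.
#'
#' @param x_min,y_min,x_max,y_max Window bounds in nm; `x_max > x_min`
#'   and `y_max > y_min`.
#' @return An object of class `smlm_window`.
#' @examples
#' w <- obs_window(0, 0, 10000, 10000)  # 10 x 10 um
#' window_area_um2(w)
#' @export
obs_window <- function(x_min, y_min, x_max, y_max) {
  stopifnot(is.numeric(x_min), is.numeric(y_min),
            is.numeric(x_max), is.numeric(y_max))
  if (!(x_max > x_min) || !(y_max > y_min)) {
    stop("obs_window: require x_max > x_min and y_max > y_min")
  }
  structure(list(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                 x_max = as.numeric(x_max), y_max = as.numeric(y_max)),
            class = "smlm_window")
}

#' @rdname obs_window
#' @param window An `smlm_window`.
#' @export
window_area_um2 <- function(window) {
  stopifnot(inherits(window, "smlm_window"))
  (window$x_max - window$x_min) * (window$y_max - window$y_min) / 1e6
}

window_sides_nm <- function(window) {
  c(window$x_max - window$x_min, window$y_max - window$y_min)
}

in_window <- function(x, y, window) {
  x >= window$x_min & x <= window$x_max &
    y >= window$y_min & y <= window$y_max
}

#' @export
print.smlm_window <- function(x, ...) {
  cat(sprintf("window: [%g, %g] x [%g, %g] nm (%.4g um^2)\n",
              x$x_min, x$x_max, x$y_min, x$y_max, window_area_um2(x)))
  invisible(x)
}

#' Planar point pattern
#'
#' The basic container for molecular coordinates: positions in nm inside a
#' rectangular observation window, with a channel label. All spatial
#' statistics ([ripley_k()], [nn_distances()], [dbscan_clusters()],
#' [doc_scores()]) consume this class.
#'
#' @param x,y Numeric coordinate vectors (nm), equal length.
#' @param window An [obs_window()]; every point must lie inside it
#'   (boundary included).
#' @param channel Channel label, e.g. `"ligand"` or `"paxillin"`.
#' @return An object of class `point_pattern` with elements `x`, `y`,
#'   `window`, `channel`.
#' @export
point_pattern <- function(x, y, window, channel = "ch1") {
  stopifnot(inherits(window, "smlm_window"),
            is.numeric(x), is.numeric(y), length(x) == length(y))
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) && any(!in_window(x, y, window))) {
    stop("point_pattern: all points must lie inside the window")
  }
  structure(list(x = x, y = y, window = window,
                 channel = as.character(channel)),
            class = "point_pattern")
}

#' @rdname point_pattern
#' @param pattern A `point_pattern`.
#' @export
n_points <- function(pattern) {
  stopifnot(inherits(pattern, "point_pattern"))
  length(pattern$x)
}

#' @rdname point_pattern
#' @export
intensity_um2 <- function(pattern) {
  n_points(pattern) / window_area_um2(pattern$window)
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point pattern: %d points, channel '%s', %.3g um^-2\n",
              n_points(x), x$channel, intensity_um2(x)))
  print(x$window)
  invisible(x)
}

#' @export
as.data.frame.point_pattern <- function(x, ...) {
  data.frame(x_nm = x$x, y_nm = x$y, channel = rep(x$channel, length(x$x)),
             stringsAsFactors = FALSE)
}
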