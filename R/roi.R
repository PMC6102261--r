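#' Labelled polygon region sets
#'
#' An `roi_set` holds manually segmented regions of interest — cell
#' footprints and adhesive structures — as simple polygons in nm
#' coordinates, mirroring the workflow in which adhesions are traced on
#' TIRF images and localisations are compared inside versus outside them.
#'
#' @param polygons A list of polygons; each polygon is a 2-column numeric
#'   matrix (or data.frame) of vertices in nm, at least 3 vertices, not
#'   self-intersecting. An open last edge is implied (do not repeat the
#'   first vertex).
#' @param labels Character vector, one per polygon; typically `"cell"` or
#'   `"adhesion"`.
#' @return An object of class `roi_set`.
#' @seealso [read_roi_json()], [assign_points_to_rois()], [density_in_out()]
#' @export
roi_set <- function(polygons, labels) {
  stopifnot(is.list(polygons), length(polygons) == length(labels))
  polygons <- lapply(seq_along(polygons), function(i) {
    p <- as.matrix(polygons[[i]])
    storage.mode(p) <- "double"
    if (ncol(p) != 2 || nrow(p) < 3) {
      stop(sprintf("roi_set: polygon %d must have >= 3 two-column vertices", i))
    }
    # drop a repeated closing vertex
    if (nrow(p) > 3 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    if (polygon_self_intersects(p)) {
      stop(sprintf("roi_set: polygon %d ('%s') is self-intersecting", i, labels[i]))
    }
    dimnames(p) <- list(NULL, c("x", "y"))
    p
  })
  structure(list(polygons = polygons, labels = as.character(labels)),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("roi_set: %d polygons (%s)\n", length(x$polygons),
              paste(sprintf("%s: %d", names(table(x$labels)),
                            as.integer(table(x$labels))), collapse = ", ")))
  invisible(x)
}

# segment intersection test for simple-polygon validation; shared endpoints
# between adjacent edges are ignored
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

polygon_self_intersects <- function(p) {
  n <- nrow(p)
  if (n < 4) return(FALSE)
  edges <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next # adjacent through the closing edge
      if (segments_cross(p[edges[i, 1], ], p[edges[i, 2], ],
                         p[edges[j, 1], ], p[edges[j, 2], ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Point-in-polygon test (even-odd rule, boundary inclusive)
#'
#' Crossing-number test with the even-odd rule; points lying exactly on a
#' polygon edge or vertex count as inside, so regions are closed. This
#' convention matters for densities near ROI boundaries and is applied
#' consistently across the package.
#'
#' @param x,y Query coordinates (nm).
#' @param polygon 2-column vertex matrix (nm), open (first vertex not
#'   repeated).
#' @return Logical vector, one per query point.
#' @export
point_in_polygon <- function(x, y, polygon) {
  p <- as.matrix(polygon)
  n <- nrow(p)
  px <- p[, 1]; py <- p[, 2]
  qx <- p[c(2:n, 1), 1]; qy <- p[c(2:n, 1), 2]
  nq <- length(x)
  inside <- logical(nq)
  on_edge <- logical(nq)
  for (e in seq_len(n)) {
    x1 <- px[e]; y1 <- py[e]; x2 <- qx[e]; y2 <- qy[e]
    # boundary: collinear and within the segment's bounding box
    cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    on_this <- abs(cross) <= 1e-9 * max(1, abs(x2 - x1) + abs(y2 - y1)) &
      x >= pmin(x1, x2) - 1e-12 & x <= pmax(x1, x2) + 1e-12 &
      y >= pmin(y1, y2) - 1e-12 & y <= pmax(y1, y2) + 1e-12
    on_edge <- on_edge | on_this
    # even-odd ray crossing (ray towards +x)
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

#' Polygon area by the shoelace formula
#'
#' @param polygon 2-column vertex matrix (nm).
#' @return Absolute area in nm^2.
#' @export
polygon_area_nm2 <- function(polygon) {
  p <- as.matrix(polygon)
  n <- nrow(p)
  if (n < 3) return(0)
  xs <- p[, 1]; ys <- p[, 2]
  xn <- xs[c(2:n, 1)]; yn <- ys[c(2:n, 1)]
  abs(sum(xs * yn - xn * ys)) / 2
}

# area of the union of polygons, nm^2. Exact (shoelace sum) when bounding
# boxes are pairwise disjoint; otherwise estimated on a fine grid with the
# even-odd test (resolution: `grid_n` cells along the longer side).
union_area_nm2 <- function(polygons, grid_n = 1024) {
  if (length(polygons) == 0) return(0)
  if (length(polygons) == 1) return(polygon_area_nm2(polygons[[1]]))
  bb <- t(vapply(polygons, function(p)
    c(min(p[, 1]), max(p[, 1]), min(p[, 2]), max(p[, 2])), numeric(4)))
  disjoint <- TRUE
  for (i in seq_len(nrow(bb) - 1)) {
    for (j in (i + 1):nrow(bb)) {
      if (!(bb[i, 2] < bb[j, 1] || bb[j, 2] < bb[i, 1] ||
            bb[i, 4] < bb[j, 3] || bb[j, 4] < bb[i, 3])) disjoint <- FALSE
    }
  }
  if (disjoint) return(sum(vapply(polygons, polygon_area_nm2, numeric(1))))
  x0 <- min(bb[, 1]); x1 <- max(bb[, 2]); y0 <- min(bb[, 3]); y1 <- max(bb[, 4])
  long <- max(x1 - x0, y1 - y0)
  h <- long / grid_n
  gx <- seq(x0 + h / 2, x1 - h / 2, by = h)
  gy <- seq(y0 + h / 2, y1 - h / 2, by = h)
  gr <- expand.grid(x = gx, y = gy)
  covered <- rep(FALSE, nrow(gr))
  for (p in polygons) {
    covered <- covered | point_in_polygon(gr$x, gr$y, p)
  }
  sum(covered) * h * h
}

#' Assign localisations to ROI compartments
#'
#' Labels every point of a pattern as `in_adhesion`, `in_cell` (inside a
#' cell footprint but outside all adhesion polygons) or `outside`
#' (outside every cell polygon). Boundaries count as inside, and adhesion
#' membership takes precedence over plain cell membership, so the three
#' labels partition the pattern.
#'
#' @param pattern A [point_pattern()].
#' @param rois An [roi_set()] with at least one `cell` and/or `adhesion`
#'   polygon.
#' @return Factor of length `n_points(pattern)` with levels
#'   `c("in_adhesion", "in_cell", "outside")`.
#' @export
assign_points_to_rois <- function(pattern, rois) {
  stopifnot(inherits(pattern, "point_pattern"), inherits(rois, "roi_set"))
  n <- n_points(pattern)
  in_adh <- rep(FALSE, n)
  in_cell <- rep(FALSE, n)
  for (i in seq_along(rois$polygons)) {
    hit <- point_in_polygon(pattern$x, pattern$y, rois$polygons[[i]])
    if (rois$labels[i] == "adhesion") in_adh <- in_adh | hit
    if (rois$labels[i] == "cell") in_cell <- in_cell | hit
  }
  lab <- ifelse(in_adh, "in_adhesion", ifelse(in_cell, "in_cell", "outside"))
  factor(lab, levels = c("in_adhesion", "in_cell", "outside"))
}

#' Density inside versus outside adhesive structures
#'
#' Computes the molecular density inside adhesion polygons and in the rest
#' of the cell footprint (cell area minus adhesion area), the comparison
#' used to quantify how strongly an adhesion protein such as paxillin is
#' enriched in adhesive structures, and to test whether ligand positions
#' are independent of adhesion placement.
#'
#' @param pattern A [point_pattern()].
#' @param rois An [roi_set()] containing at least one `cell` and one
#'   `adhesion` polygon.
#' @return A list of class `density_comparison`: counts, areas (um^2),
#'   `density_in`, `density_out` (um^-2) and their `ratio`.
#' @export
density_in_out <- function(pattern, rois) {
  stopifnot(inherits(rois, "roi_set"))
  if (!any(rois$labels == "cell") || !any(rois$labels == "adhesion")) {
    stop("density_in_out: need at least one 'cell' and one 'adhesion' polygon")
  }
  lab <- assign_points_to_rois(pattern, rois)
  adh_polys <- rois$polygons[rois$labels == "adhesion"]
  cell_polys <- rois$polygons[rois$labels == "cell"]
  area_adh <- union_area_nm2(adh_polys) / 1e6
  area_cell <- union_area_nm2(cell_polys) / 1e6
  area_out <- area_cell - area_adh
  if (area_adh <= 0 || area_out <= 0) {
    stop("density_in_out: zero-area compartment")
  }
  n_in <- sum(lab == "in_adhesion")
  n_out <- sum(lab == "in_cell")
  structure(list(
    n_in = n_in, n_out = n_out,
    area_in_um2 = area_adh, area_out_um2 = area_out,
    density_in = n_in / area_adh, density_out = n_out / area_out,
    ratio = (n_in / area_adh) / (n_out / area_out)
  ), class = "density_comparison")
}

#' @export
print.density_comparison <- function(x, ...) {
  cat(sprintf("in:  %d pts / %.4g um^2 = %.4g um^-2\n",
              x$n_in, x$area_in_um2, x$density_in))
  cat(sprintf("out: %d pts / %.4g um^2 = %.4g um^-2  (ratio %.3g)\n",
              x$n_out, x$area_out_um2, x$density_out, x$ratio))
  invisible(x)
}

#' Ligand density over the surface versus under cells
#'
#' Compares the average density over the full imaged window with the
#' average over the union of cell footprints — the comparison used to show
#' that cells occupy regions of above-threshold ligand density.
#'
#' @param pattern A [point_pattern()] (typically the ligand channel).
#' @param cell_rois An [roi_set()]; polygons labelled `cell` are used.
#' @param window The full-surface [obs_window()]; defaults to the
#'   pattern's window.
#' @return List with `surface_density` and `undercell_density` (um^-2)
#'   plus counts and areas.
#' @export
surface_vs_undercell_density <- function(pattern, cell_rois,
                                         window = pattern$window) {
  stopifnot(inherits(pattern, "point_pattern"), inherits(cell_rois, "roi_set"))
  cells <- cell_rois$polygons[cell_rois$labels == "cell"]
  if (length(cells) == 0) stop("surface_vs_undercell_density: no 'cell' polygon")
  area_surf <- window_area_um2(window)
  n_surf <- sum(in_window(pattern$x, pattern$y, window))
  under <- rep(FALSE, n_points(pattern))
  for (p in cells) under <- under | point_in_polygon(pattern$x, pattern$y, p)
  area_cell <- union_area_nm2(cells) / 1e6
  if (area_cell <= 0) stop("surface_vs_undercell_density: zero cell area")
  list(surface_density = n_surf / area_surf,
       undercell_density = sum(under) / area_cell,
       n_surface = n_surf, n_undercell = sum(under),
       area_surface_um2 = area_surf, area_undercell_um2 = area_cell)
}

#' Classify local ligand density against adhesion-support thresholds
#'
#' Applies the reported density thresholds for cell behaviour on
#' RGD-functionalised surfaces: densities at or below the tethering
#' threshold support no adhesion (`none`), densities strictly above it but
#' below the spreading range only tether cells (`tether`), and densities
#' at or above the lower spreading bound support spreading and focal
#' adhesion formation (`spread`). The thresholds are reported empirical
#' constants, exposed as arguments, not re-derived quantities.
#'
#' @param local_density Ligand density in um^-2 (vectorised).
#' @param tether_threshold Minimum density for tethering; default 0.8
#'   um^-2 (strict inequality).
#' @param spread_range Density range needed for spreading; default
#'   `c(4, 7)` um^-2 (classification uses the lower bound).
#' @return Factor with levels `c("none", "tether", "spread")`.
#' @export
classify_adhesion_support <- function(local_density, tether_threshold = 0.8,
                                      spread_range = c(4, 7)) {
  if (any(local_density < 0)) {
    stop("classify_adhesion_support: density must be >= 0")
  }
  out <- ifelse(local_density >= spread_range[1], "spread",
                ifelse(local_density > tether_threshold, "tether", "none"))
  factor(out, levels = c("none", "tether", "spread"))
}
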