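#' DBSCAN segmentation of a localisation pattern
#'
#' Density-based spatial clustering (DBSCAN): a point is a core point if
#' at least `min_neighbors` other points lie within `eps` of it; clusters
#' are the maximal sets connected through core points; remaining points
#' are noise. The defaults (`eps` = 20 nm, `min_neighbors` = 3) are the
#' segmentation parameters used for adhesion-protein clusters. Neighbour
#' counting excludes the point itself (the original DBSCAN convention;
#' set via `count_self` if a self-inclusive count is wanted). Border
#' points reachable from two clusters join the first-discovered cluster
#' in input order — the documented tie-break; core/noise status and the
#' partition itself do not depend on order.
#'
#' @param pattern A [point_pattern()] (may be empty).
#' @param eps Search radius r in nm (> 0); default 20.
#' @param min_neighbors Minimum neighbour count epsilon (>= 1); default 3.
#' @param count_self If `TRUE`, the point itself counts towards
#'   `min_neighbors`.
#' @return Integer vector of labels, one per point: 0 for noise, clusters
#'   numbered from 1.
#' @seealso [cluster_stats()]
#' @export
dbscan_clusters <- function(pattern, eps = 20, min_neighbors = 3,
                            count_self = FALSE) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (eps <= 0 || min_neighbors < 1) {
    stop("dbscan_clusters: require eps > 0 and min_neighbors >= 1")
  }
  mn <- if (count_self) min_neighbors - 1L else min_neighbors
  cpp_dbscan(pattern$x, pattern$y, eps, as.integer(mn))
}

# convex-hull area via chull + shoelace; degenerate hulls give 0
hull_area_nm2 <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(h) < 3) return(0)
  polygon_area_nm2(pts[h, , drop = FALSE])
}

#' Per-cluster morphology statistics
#'
#' Summarises each DBSCAN cluster the way adhesion-protein clusters are
#' reported: number of molecules, cluster area (convex hull of the
#' members, nm^2) and molecular density (points per um^2 of hull area).
#' Degenerate hulls (fewer than 3 distinct points, or collinear members)
#' have zero area and an undefined (`NA`) density.
#'
#' @param pattern A [point_pattern()].
#' @param labels Labels from [dbscan_clusters()] on the same pattern.
#' @return data.frame with one row per cluster: `cluster_id`, `n`,
#'   `area_nm2`, `density_per_um2`, `cx_nm`, `cy_nm`.
#' @export
cluster_stats <- function(pattern, labels) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (length(labels) != n_points(pattern)) {
    stop("cluster_stats: labels length must match the pattern")
  }
  ids <- sort(unique(labels[labels > 0]))
  out <- lapply(ids, function(id) {
    sel <- labels == id
    area <- hull_area_nm2(pattern$x[sel], pattern$y[sel])
    data.frame(cluster_id = id, n = sum(sel), area_nm2 = area,
               density_per_um2 = if (area > 0) sum(sel) / (area / 1e6) else NA_real_,
               cx_nm = mean(pattern$x[sel]), cy_nm = mean(pattern$y[sel]))
  })
  if (length(out) == 0) {
    return(data.frame(cluster_id = integer(0), n = integer(0),
                      area_nm2 = numeric(0), density_per_um2 = numeric(0),
                      cx_nm = numeric(0), cy_nm = numeric(0)))
  }
  do.call(rbind, out)
}
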