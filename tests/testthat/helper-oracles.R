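# Independent reference implementations used as oracles. All are written
# for clarity, not speed, and stay independent of the package's code paths.

# DBSCAN by explicit neighbour graph + connected components over core
# points; border points attach to the smallest cluster id among their core
# neighbours (equivalent to first-discovered under sequential expansion).
oracle_dbscan <- function(x, y, eps, min_neighbors) {
  n <- length(x)
  labels <- integer(n)
  if (n == 0) return(labels)
  d <- as.matrix(stats::dist(cbind(x, y)))
  nbr <- d <= eps & row(d) != col(d)
  core <- rowSums(nbr) >= min_neighbors
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    members <- i
    repeat {
      reach <- which(core & labels == 0L & !(seq_len(n) %in% members) &
                       colSums(nbr[members, , drop = FALSE]) > 0)
      if (length(reach) == 0) break
      members <- c(members, reach)
    }
    labels[members] <- cl
  }
  for (i in which(!core)) {
    adj <- which(nbr[i, ] & core)
    if (length(adj)) labels[i] <- min(labels[adj])
  }
  labels
}

# classic pnpoly crossing-number test, one point at a time
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# shoelace on an ordered vertex ring
oracle_shoelace <- function(poly) {
  n <- nrow(poly)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + poly[i, 1] * poly[j, 2] - poly[j, 1] * poly[i, 2]
  }
  abs(s) / 2
}

# uncorrected Ripley K by a double loop over all pairs
oracle_ripley_none <- function(x, y, area_nm2, radii) {
  n <- length(x)
  sums <- numeric(length(radii))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      sums <- sums + (d <= radii)
    }
  }
  area_nm2 * sums / n^2
}

# Mortensen precision by direct arithmetic (kept separate from the
# package's vectorised implementation)
oracle_mortensen <- function(N, sigma, b, a) {
  sa2 <- sigma^2 + a^2 / 12
  sqrt((sa2 / N) * (16 / 9 + 8 * pi * sa2 * b^2 / (N * a^2)))
}

# closed-form Thomas-process K function (kappa in nm^-2)
thomas_K <- function(r, kappa_nm2, sigma) {
  pi * r^2 + (1 - exp(-r^2 / (4 * sigma^2))) / kappa_nm2
}

make_window <- function(side_um = 10) obs_window(0, 0, side_um * 1000, side_um * 1000)

# greedy hard-core thinning: keep a point only if no earlier kept point
# lies within min_sep
hard_core_thin <- function(x, y, min_sep, window) {
  keep <- logical(length(x))
  for (i in seq_along(x)) {
    keep[i] <- !any(keep & (x - x[i])^2 + (y - y[i])^2 < min_sep^2)
  }
  point_pattern(x[keep], y[keep], window)
}
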