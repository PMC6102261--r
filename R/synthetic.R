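#' Simulate complete spatial randomness (CSR)
#'
#' Homogeneous Poisson point process: the point count is
#' Poisson(density x area) and positions are i.i.d. uniform in the
#' window. CSR is the null model behind the density-to-spacing conversion
#' ([mean_nn_spacing_from_density()]) and the Ripley K calibration.
#'
#' @param density Intensity in molecules per um^2 (>= 0).
#' @param window An [obs_window()].
#' @param seed Integer RNG seed; fixed seed gives a bit-reproducible
#'   pattern. `NULL` uses the current RNG state.
#' @param channel Channel label for the returned pattern.
#' @return A [point_pattern()].
#' @export
simulate_csr <- function(density, window, seed = NULL, channel = "ch1") {
  if (!is.numeric(density) || length(density) != 1 || density < 0) {
    stop("simulate_csr: density must be a single non-negative number")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1, density * window_area_um2(window))
  point_pattern(stats::runif(n, window$x_min, window$x_max),
                stats::runif(n, window$y_min, window$y_max),
                window, channel)
}

#' Simulate a Thomas cluster process
#'
#' Poisson-distributed parents with Poisson(offspring_mean) children per
#' parent, displaced by isotropic Gaussian offsets of standard deviation
#' `cluster_sigma`. Parents are drawn in a window buffered by
#' `4 * cluster_sigma` on every side so clusters straddling the boundary
#' are not under-represented; children falling outside the window are
#' discarded. The process has the closed-form pair correlation
#' g(r) = 1 + exp(-r^2 / (4 sigma^2)) / (4 pi sigma^2 kappa), which makes
#' it the natural ground truth for locally clustered ligand fields whose
#' Ripley L(r) - r curve peaks at the cluster length scale.
#'
#' @param parent_density Parent intensity kappa in um^-2 (> 0).
#' @param offspring_mean Mean children per parent (> 0; 0 allowed and
#'   yields an empty pattern).
#' @param cluster_sigma Gaussian cluster radius in nm (> 0).
#' @param window An [obs_window()].
#' @param seed Integer RNG seed or `NULL`.
#' @param channel Channel label.
#' @return A [point_pattern()].
#' @export
simulate_thomas <- function(parent_density, offspring_mean, cluster_sigma,
                            window, seed = NULL, channel = "ch1") {
  if (parent_density <= 0 || offspring_mean < 0 || cluster_sigma <= 0) {
    stop("simulate_thomas: parent_density and cluster_sigma must be > 0, offspring_mean >= 0")
  }
  if (!is.null(seed)) set.seed(seed)
  buf <- 4 * cluster_sigma
  big <- obs_window(window$x_min - buf, window$y_min - buf,
                    window$x_max + buf, window$y_max + buf)
  n_par <- stats::rpois(1, parent_density * window_area_um2(big))
  if (n_par == 0 || offspring_mean == 0) {
    return(point_pattern(numeric(0), numeric(0), window, channel))
  }
  px <- stats::runif(n_par, big$x_min, big$x_max)
  py <- stats::runif(n_par, big$y_min, big$y_max)
  kids <- stats::rpois(n_par, offspring_mean)
  cx <- rep(px, kids) + stats::rnorm(sum(kids), 0, cluster_sigma)
  cy <- rep(py, kids) + stats::rnorm(sum(kids), 0, cluster_sigma)
  keep <- in_window(cx, cy, window)
  point_pattern(cx[keep], cy[keep], window, channel)
}

#' Simulate a two-colour scene with known colocalisation structure
#'
#' Ground truth for the degree-of-colocalisation statistic:
#' \describe{
#'   \item{`colocalized`}{channel 2 is channel 1 displaced by isotropic
#'     Gaussian jitter of sd `jitter_sigma` (labelling noise /
#'     localisation error); jittered points leaving the window are
#'     dropped from channel 2.}
#'   \item{`independent`}{two independent CSR draws at the same density —
#'     the null of no spatial relationship.}
#'   \item{`segregated`}{the two channels are CSR at the given density
#'     but confined to the left (channel 1) and right (channel 2) halves
#'     of the window — anticolocalisation.}
#' }
#'
#' @param mode One of `"colocalized"`, `"independent"`, `"segregated"`.
#' @param density Per-channel intensity in um^-2 (> 0; for `segregated`
#'   this is the density within each half).
#' @param jitter_sigma Jitter sd in nm (>= 0; only used by `colocalized`).
#' @param window An [obs_window()].
#' @param seed Integer RNG seed or `NULL`.
#' @param base `"csr"` (default) draws each underlying field as CSR;
#'   `"clustered"` draws it as a Thomas cluster field of the same overall
#'   intensity (parameters in `cluster_params`). Clustered fields are the
#'   regime in which the DoC statistic has signal: on a structureless CSR
#'   field the per-molecule density gradients carry only counting noise
#'   and colocalisation scores are strongly attenuated.
#' @param cluster_params For `base = "clustered"`: list with
#'   `offspring_mean` and `cluster_sigma` (nm); the parent density is
#'   `density / offspring_mean`.
#' @return List with elements `ch1` and `ch2`, both [point_pattern()]s on
#'   the full window.
#' @export
simulate_two_color <- function(mode = c("colocalized", "independent", "segregated"),
                               density, jitter_sigma = 0, window, seed = NULL,
                               base = c("csr", "clustered"),
                               cluster_params = list(offspring_mean = 20,
                                                     cluster_sigma = 40)) {
  mode <- match.arg(mode)
  base <- match.arg(base)
  if (density <= 0) stop("simulate_two_color: density must be > 0")
  if (jitter_sigma < 0) stop("simulate_two_color: jitter_sigma must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  draw_field <- function(w, channel) {
    if (base == "csr") {
      simulate_csr(density, w, seed = NULL, channel = channel)
    } else {
      simulate_thomas(density / cluster_params$offspring_mean,
                      cluster_params$offspring_mean,
                      cluster_params$cluster_sigma, w,
                      seed = NULL, channel = channel)
    }
  }
  if (mode == "colocalized") {
    a <- draw_field(window, "ch1")
    x2 <- a$x + stats::rnorm(n_points(a), 0, jitter_sigma)
    y2 <- a$y + stats::rnorm(n_points(a), 0, jitter_sigma)
    keep <- in_window(x2, y2, window)
    b <- point_pattern(x2[keep], y2[keep], window, "ch2")
  } else if (mode == "independent") {
    a <- draw_field(window, "ch1")
    b <- draw_field(window, "ch2")
    b$channel <- "ch2"
  } else {
    mid <- (window$x_min + window$x_max) / 2
    left <- obs_window(window$x_min, window$y_min, mid, window$y_max)
    right <- obs_window(mid, window$y_min, window$x_max, window$y_max)
    al <- draw_field(left, "ch1")
    br <- draw_field(right, "ch2")
    # exclude boundary coincidences so the halves stay disjoint
    keep <- al$x < mid
    a <- point_pattern(al$x[keep], al$y[keep], window, "ch1")
    b <- point_pattern(br$x, br$y, window, "ch2")
  }
  list(ch1 = a, ch2 = b)
}

# uniform points inside a polygon at a given intensity (um^-2), by
# rejection from the bounding box; optionally excluding sub-polygons
sample_in_polygon <- function(density, polygon, seed_rng_ready,
                              exclude = list()) {
  area <- polygon_area_nm2(polygon) / 1e6
  bb <- c(min(polygon[, 1]), max(polygon[, 1]),
          min(polygon[, 2]), max(polygon[, 2]))
  n_target <- stats::rpois(1, density * area)
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n_target) {
    m <- max(100, 2 * (n_target - length(xs)))
    cx <- stats::runif(m, bb[1], bb[2])
    cy <- stats::runif(m, bb[3], bb[4])
    ok <- point_in_polygon(cx, cy, polygon)
    xs <- c(xs, cx[ok]); ys <- c(ys, cy[ok])
  }
  xs <- xs[seq_len(n_target)]; ys <- ys[seq_len(n_target)]
  if (length(exclude) && length(xs)) {
    drop <- rep(FALSE, length(xs))
    for (p in exclude) drop <- drop | point_in_polygon(xs, ys, p)
    xs <- xs[!drop]; ys <- ys[!drop]
  }
  cbind(xs, ys)
}

#' Simulate a cell-on-surface adhesion scene with ground truth
#'
#' Builds a two-channel scene emulating a cell with focal adhesions on a
#' ligand-functionalised surface: the adhesion-protein ("paxillin")
#' channel is drawn at `paxillin_density_in` inside adhesion polygons and
#' `paxillin_density_out` in the rest of the cell footprint, while the
#' ligand channel is CSR over the whole window, independent of the ROIs —
#' the configuration in which adhesion placement carries no information
#' about ligand positions.
#'
#' @param cell_polygon 2-column vertex matrix (nm) of the cell footprint.
#' @param adhesion_polygons List of 2-column vertex matrices, each fully
#'   inside the cell polygon.
#' @param paxillin_density_in,paxillin_density_out Paxillin intensities
#'   (um^-2) inside adhesions and elsewhere in the cell.
#' @param ligand_density Ligand intensity (um^-2) over the whole window.
#' @param window An [obs_window()] containing the cell.
#' @param seed Integer RNG seed or `NULL`.
#' @return A list of class `ground_truth_scene`: `paxillin` and `ligand`
#'   [point_pattern()]s, the [roi_set()], and per-molecule ground-truth
#'   labels `paxillin_in_adhesion` (logical).
#' @export
simulate_adhesion_scene <- function(cell_polygon, adhesion_polygons,
                                    paxillin_density_in, paxillin_density_out,
                                    ligand_density, window, seed = NULL) {
  if (paxillin_density_in < 0 || paxillin_density_out < 0 || ligand_density < 0) {
    stop("simulate_adhesion_scene: densities must be >= 0")
  }
  cell_polygon <- as.matrix(cell_polygon)
  adhesion_polygons <- lapply(adhesion_polygons, as.matrix)
  for (i in seq_along(adhesion_polygons)) {
    if (!all(point_in_polygon(adhesion_polygons[[i]][, 1],
                              adhesion_polygons[[i]][, 2], cell_polygon))) {
      stop(sprintf("simulate_adhesion_scene: adhesion polygon %d escapes the cell polygon", i))
    }
  }
  if (!is.null(seed)) set.seed(seed)
  pax_in <- do.call(rbind, lapply(adhesion_polygons, function(p)
    sample_in_polygon(paxillin_density_in, p)))
  if (is.null(pax_in)) pax_in <- matrix(numeric(0), ncol = 2)
  pax_out <- sample_in_polygon(paxillin_density_out, cell_polygon,
                               exclude = adhesion_polygons)
  pax <- point_pattern(c(pax_in[, 1], pax_out[, 1]),
                       c(pax_in[, 2], pax_out[, 2]), window, "paxillin")
  lig <- simulate_csr(ligand_density, window, seed = NULL, channel = "ligand")
  rois <- roi_set(c(list(cell_polygon), adhesion_polygons),
                  c("cell", rep("adhesion", length(adhesion_polygons))))
  structure(list(
    paxillin = pax, ligand = lig, rois = rois,
    paxillin_in_adhesion = rep(c(TRUE, FALSE),
                               c(nrow(pax_in), nrow(pax_out)))
  ), class = "ground_truth_scene")
}

#' Photophysics parameters for blinking simulation
#'
#' Blink-count, on-time and off-gap distributions are geometric (support
#' >= 1, p = 1/mean): the memoryless minimal model consistent with
#' grouping rules expressed as maximum on-time and maximum off-gap. The
#' defaults are typical dSTORM-scale values and are stated here rather
#' than inferred from any particular dye.
#'
#' @param mean_photons_per_frame Mean detected photons per frame while on.
#' @param on_time_mean Mean frames per blink (>= 1 effective support).
#' @param off_gap_mean Mean dark frames between blinks of one molecule.
#' @param n_blinks_mean Mean number of blinks per molecule.
#' @param background_rate Background photons per pixel per frame.
#' @return List of class `photophysics_params`.
#' @export
photophysics_params <- function(mean_photons_per_frame = 1000,
                                on_time_mean = 2,
                                off_gap_mean = 10,
                                n_blinks_mean = 2,
                                background_rate = 10) {
  vals <- c(mean_photons_per_frame, on_time_mean, off_gap_mean,
            n_blinks_mean, background_rate)
  if (any(vals <= 0)) stop("photophysics_params: all parameters must be > 0")
  structure(list(mean_photons_per_frame = mean_photons_per_frame,
                 on_time_mean = on_time_mean, off_gap_mean = off_gap_mean,
                 n_blinks_mean = n_blinks_mean,
                 background_rate = background_rate),
            class = "photophysics_params")
}

# shifted geometric on {1, 2, ...} with the requested mean
rgeom1 <- function(n, mean) {
  if (mean <= 1) return(rep(1L, n))
  1L + stats::rgeom(n, prob = 1 / mean)
}

#' Piecewise-linear drift trajectory
#'
#' Stage drift as displacement knots at given frames, linearly
#' interpolated between them. The displacement at frame 0 must be (0, 0).
#'
#' @param knot_frames Strictly increasing integer frame indices (0-based),
#'   starting at 0.
#' @param dx_nm,dy_nm Displacements at the knots, in nm.
#' @return Object of class `drift_trajectory`.
#' @seealso [drift_at()], [estimate_drift()], [apply_drift_correction()]
#' @export
drift_trajectory <- function(knot_frames, dx_nm, dy_nm) {
  stopifnot(length(knot_frames) == length(dx_nm),
            length(knot_frames) == length(dy_nm))
  if (any(diff(knot_frames) <= 0)) {
    stop("drift_trajectory: knot frames must be strictly increasing")
  }
  if (knot_frames[1] == 0 && (dx_nm[1] != 0 || dy_nm[1] != 0)) {
    stop("drift_trajectory: displacement at frame 0 must be (0, 0)")
  }
  structure(list(frames = as.numeric(knot_frames),
                 dx = as.numeric(dx_nm), dy = as.numeric(dy_nm)),
            class = "drift_trajectory")
}

#' @rdname drift_trajectory
#' @param drift A `drift_trajectory` (or `NULL`, meaning no drift).
#' @param frames Frame indices at which to evaluate the displacement.
#' @return `drift_at`: a 2-column matrix (dx, dy) in nm.
#' @export
drift_at <- function(drift, frames) {
  if (is.null(drift)) return(cbind(dx = numeric(length(frames)),
                                   dy = numeric(length(frames))))
  stopifnot(inherits(drift, "drift_trajectory"))
  if (any(frames < min(drift$frames)) || any(frames > max(drift$frames))) {
    stop("drift_at: frame outside the trajectory's domain")
  }
  cbind(dx = stats::approx(drift$frames, drift$dx, xout = frames)$y,
        dy = stats::approx(drift$frames, drift$dy, xout = frames)$y)
}

# expected fraction of a Gaussian PSF integrated over one pixel row/column
integrated_gauss_1d <- function(edges_lo, edges_hi, mu, sigma) {
  stats::pnorm(edges_hi, mu, sigma) - stats::pnorm(edges_lo, mu, sigma)
}

#' Render a blinking SMLM movie with ground truth
#'
#' Turns a molecular point pattern into a camera image stack: each
#' molecule produces a geometric number of blinks, each blink lasts a
#' geometric number of consecutive frames starting at a uniform random
#' frame, the per-frame photon count is Poisson, and each emission is
#' rendered as an integrated 2-D Gaussian PSF on the pixel grid. Constant
#' Poisson background is added everywhere; fiducials emit in every frame;
#' a drift trajectory displaces all emitters. Pixel (i, j) (0-based
#' column i, row j) covers x in [i a, (i+1) a) with its centre at
#' ((i + 0.5) a, (j + 0.5) a) nm.
#'
#' @param molecules A [point_pattern()]; the frame geometry is derived
#'   from its window and `pixel_size`.
#' @param photophysics A [photophysics_params()].
#' @param psf_sigma PSF standard deviation in nm.
#' @param pixel_size Camera pixel size a in nm (> 0).
#' @param n_frames Number of frames (>= 1).
#' @param drift Optional [drift_trajectory()] applied to all emitters.
#' @param fiducials Optional [point_pattern()] of constant emitters.
#' @param fiducial_photons Photons per frame per fiducial.
#' @param seed Integer RNG seed or `NULL`.
#' @param noise If `FALSE`, expected pixel values are returned without
#'   Poisson sampling of pixels or photon counts (for exactness tests).
#' @return List of class `frame_stack`: `frames` (array ny x nx x
#'   n_frames, photons), `pixel_size`, `window`, and `truth` — a
#'   data.frame (molecule, frame, x_nm, y_nm, photons) listing every
#'   emission, fiducials with negative molecule ids.
#' @export
render_blinking_stack <- function(molecules, photophysics, psf_sigma,
                                  pixel_size, n_frames, drift = NULL,
                                  fiducials = NULL, fiducial_photons = 2e4,
                                  seed = NULL, noise = TRUE) {
  stopifnot(inherits(molecules, "point_pattern"),
            inherits(photophysics, "photophysics_params"))
  if (pixel_size <= 0) stop("render_blinking_stack: pixel_size must be > 0")
  if (n_frames < 1) stop("render_blinking_stack: n_frames must be >= 1")
  if (psf_sigma < pixel_size / 4) {
    warning("render_blinking_stack: PSF sigma < pixel_size/4 (undersampled)")
  }
  if (!is.null(seed)) set.seed(seed)
  w <- molecules$window
  nx <- ceiling((w$x_max - w$x_min) / pixel_size)
  ny <- ceiling((w$y_max - w$y_min) / pixel_size)

  # schedule emissions: (molecule, frame, x, y, photons)
  mol_id <- integer(0); frame <- integer(0)
  ex <- numeric(0); ey <- numeric(0); nph <- numeric(0)
  n_mol <- n_points(molecules)
  if (n_mol > 0) {
    for (m in seq_len(n_mol)) {
      nb <- rgeom1(1, photophysics$n_blinks_mean)
      f <- sample.int(n_frames, 1) - 1L # 0-based start of first blink
      for (b in seq_len(nb)) {
        on <- rgeom1(1, photophysics$on_time_mean)
        fr <- f + seq_len(on) - 1L
        fr <- fr[fr < n_frames]
        if (length(fr)) {
          mol_id <- c(mol_id, rep(m, length(fr)))
          frame <- c(frame, fr)
          ex <- c(ex, rep(molecules$x[m], length(fr)))
          ey <- c(ey, rep(molecules$y[m], length(fr)))
        }
        f <- f + on + rgeom1(1, photophysics$off_gap_mean)
        if (f >= n_frames) break
      }
    }
  }
  if (!is.null(fiducials) && n_points(fiducials) > 0) {
    for (m in seq_len(n_points(fiducials))) {
      mol_id <- c(mol_id, rep(-m, n_frames))
      frame <- c(frame, 0:(n_frames - 1))
      ex <- c(ex, rep(fiducials$x[m], n_frames))
      ey <- c(ey, rep(fiducials$y[m], n_frames))
    }
  }
  n_ev <- length(mol_id)
  if (n_ev) {
    mean_ph <- ifelse(mol_id > 0, photophysics$mean_photons_per_frame,
                      fiducial_photons)
    nph <- if (noise) stats::rpois(n_ev, mean_ph) else mean_ph
    disp <- drift_at(drift, frame)
    ex <- ex + disp[, "dx"]
    ey <- ey + disp[, "dy"]
  }

  frames <- array(photophysics$background_rate, dim = c(ny, nx, n_frames))
  if (n_ev) {
    x_edges <- w$x_min + pixel_size * 0:nx
    y_edges <- w$y_min + pixel_size * 0:ny
    for (e in seq_len(n_ev)) {
      if (nph[e] <= 0) next
      gx <- integrated_gauss_1d(x_edges[-(nx + 1)], x_edges[-1], ex[e], psf_sigma)
      gy <- integrated_gauss_1d(y_edges[-(ny + 1)], y_edges[-1], ey[e], psf_sigma)
      frames[, , frame[e] + 1L] <- frames[, , frame[e] + 1L] +
        nph[e] * (gy %o% gx)
    }
  }
  if (noise) {
    frames[] <- stats::rpois(length(frames), frames)
  }
  truth <- data.frame(molecule = mol_id, frame = frame,
                      x_nm = ex, y_nm = ey,
                      photons = if (n_ev) nph else numeric(0))
  truth <- truth[order(truth$frame, truth$molecule), , drop = FALSE]
  rownames(truth) <- NULL
  frame_stack(frames, pixel_size, window = w, truth = truth)
}

#' Camera frame stack
#'
#' @param frames Numeric array ny x nx x n_frames (photons or counts).
#' @param pixel_size Pixel size in nm.
#' @param window The [obs_window()] the stack images; defaults to the
#'   pixel grid anchored at (0, 0).
#' @param truth Optional ground-truth emission table.
#' @return Object of class `frame_stack`.
#' @export
frame_stack <- function(frames, pixel_size, window = NULL, truth = NULL) {
  if (length(dim(frames)) == 2) dim(frames) <- c(dim(frames), 1)
  stopifnot(length(dim(frames)) == 3, pixel_size > 0)
  if (is.null(window)) {
    window <- obs_window(0, 0, dim(frames)[2] * pixel_size,
                         dim(frames)[1] * pixel_size)
  }
  structure(list(frames = frames, pixel_size = pixel_size,
                 window = window, truth = truth),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("frame stack: %d x %d px, %d frames, pixel %g nm\n",
              d[2], d[1], d[3], x$pixel_size))
  invisible(x)
}
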