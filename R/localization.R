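#' Detection and camera configuration
#'
#' `detection_config` holds the event-detection parameters: the Gaussian
#' filter width applied before thresholding, the threshold multiplier k
#' of the rule `I - M > k S` (filtered event intensity I exceeding the
#' frame mean M by more than k frame standard deviations S; k = 6 by
#' default), and the half-width of the square PSF fit window (4 pixels by
#' default, i.e. a 9 x 9 window as used for the far-red dye channel; 3 is
#' typical for the photoconvertible-protein channel).
#' `camera_model` holds the pixel size a (nm) and gain (counts/photon);
#' pixel values are divided by the gain before fitting so all fits are in
#' photon units.
#'
#' @param filter_sigma Gaussian filter sd in pixels.
#' @param k Threshold multiplier (> 0).
#' @param fit_halfwidth Fit-window half-width in pixels (>= 1).
#' @return A list of class `detection_config` / `camera_model`.
#' @export
detection_config <- function(filter_sigma = 1.2, k = 6, fit_halfwidth = 4) {
  if (k <= 0 || fit_halfwidth < 1 || filter_sigma <= 0) {
    stop("detection_config: require filter_sigma > 0, k > 0, fit_halfwidth >= 1")
  }
  structure(list(filter_sigma = filter_sigma, k = k,
                 fit_halfwidth = as.integer(fit_halfwidth)),
            class = "detection_config")
}

#' @rdname detection_config
#' @param pixel_size Pixel size in nm (> 0).
#' @param gain Camera gain in counts per photon (> 0).
#' @export
camera_model <- function(pixel_size = 100, gain = 1) {
  if (pixel_size <= 0 || gain <= 0) {
    stop("camera_model: pixel_size and gain must be > 0")
  }
  structure(list(pixel_size = pixel_size, gain = gain),
            class = "camera_model")
}

# strict local maxima of a matrix over the 8-neighbourhood
local_maxima <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  is_max <- matrix(TRUE, nr, nc)
  for (di in -1:1) {
    for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      nb <- pad[(2:(nr + 1)) + di, (2:(nc + 1)) + dj]
      is_max <- is_max & (m > nb)
    }
  }
  which(is_max, arr.ind = TRUE)
}

#' Detect blinking events in a camera stack
#'
#' Per frame: the image is Gaussian-filtered, the frame mean M and
#' standard deviation S are computed over all (filtered) pixels, and
#' strict local maxima whose filtered intensity I satisfies `I - M > k S`
#' are returned as candidates. Maxima within one fit-window half-width of
#' a brighter candidate are merged into it (duplicate suppression). A
#' perfectly uniform frame yields no events, and an empty stack an empty
#' table.
#'
#' @param stack A [frame_stack()].
#' @param cfg A [detection_config()].
#' @return data.frame with columns `frame` (0-based), `px`, `py` (0-based
#'   pixel indices: column, row) and `intensity` (filtered value).
#' @export
detect_events <- function(stack, cfg = detection_config()) {
  stopifnot(inherits(stack, "frame_stack"), inherits(cfg, "detection_config"))
  n_frames <- dim(stack$frames)[3]
  out <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    img <- stack$frames[, , f]
    flt <- ebimage_gblur(img, cfg$filter_sigma)
    m <- mean(flt); s <- stats::sd(flt)
    mx <- local_maxima(flt)
    if (nrow(mx) == 0) next
    keep <- (flt[mx] - m) > cfg$k * s
    mx <- mx[keep, , drop = FALSE]
    if (nrow(mx) == 0) next
    vals <- flt[mx]
    ord <- order(vals, decreasing = TRUE)
    mx <- mx[ord, , drop = FALSE]; vals <- vals[ord]
    # suppress duplicate maxima of one emitter (noise-split peaks sit within
    # ~2 px); farther maxima are distinct emitters left for the joint fit
    merge_px <- max(1, floor(cfg$fit_halfwidth / 2))
    sel <- rep(TRUE, nrow(mx))
    for (i in seq_len(nrow(mx))) {
      if (!sel[i]) next
      if (i < nrow(mx)) {
        later <- (i + 1):nrow(mx)
        close <- pmax(abs(mx[later, 1] - mx[i, 1]),
                      abs(mx[later, 2] - mx[i, 2])) <= merge_px
        sel[later][close] <- FALSE
      }
    }
    mx <- mx[sel, , drop = FALSE]; vals <- vals[sel]
    out[[f]] <- data.frame(frame = f - 1L, px = mx[, 2] - 1L,
                           py = mx[, 1] - 1L, intensity = vals)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(frame = integer(0), px = integer(0), py = integer(0),
                      intensity = numeric(0))
  }
  rownames(out) <- NULL
  out
}

ebimage_gblur <- function(img, sigma) {
  EBImage::gblur(img, sigma = sigma, boundary = "replicate")
}

# pixel-centre convention: 0-based pixel (i, j) spans
# [x_min + i a, x_min + (i+1) a) with centre at x_min + (i + 0.5) a
psf_model_window <- function(par, n_em, cols, rows, x_min, y_min, a) {
  b <- par[length(par)]
  sigma <- abs(par[length(par) - 1]) # width enters through |sigma|
  if (sigma < 1e-6) sigma <- 1e-6
  mu <- matrix(b, length(rows), length(cols))
  for (k in seq_len(n_em)) {
    xk <- par[3 * (k - 1) + 1]; yk <- par[3 * (k - 1) + 2]
    nk <- par[3 * (k - 1) + 3]
    gx <- integrated_gauss_1d(x_min + a * cols, x_min + a * (cols + 1), xk, sigma)
    gy <- integrated_gauss_1d(y_min + a * rows, y_min + a * (rows + 1), yk, sigma)
    mu <- mu + nk * (gy %o% gx)
  }
  mu
}

#' Fit an integrated 2-D Gaussian PSF to detected candidates
#'
#' Least-squares fit of `N * IntGauss(x0, y0, sigma) + b` (integrated
#' over pixels) on the fit window around a candidate, in photon units.
#' Candidates whose windows overlap are fitted jointly as a multi-emitter
#' model (up to 3 emitters sharing one sigma); larger pile-ups are
#' discarded by the caller. Non-converged fits are flagged.
#'
#' @param frame 2-D numeric matrix (counts; divided by `camera$gain`).
#' @param candidates data.frame with `px`, `py` (0-based pixel indices)
#'   of 1-3 candidates fitted jointly.
#' @param camera A [camera_model()].
#' @param cfg A [detection_config()] (fit window half-width).
#' @param window Optional [obs_window()] giving the nm origin of pixel
#'   (0, 0); defaults to origin (0, 0).
#' @param sigma_start Starting PSF sd in nm.
#' @return data.frame with one row per emitter: `x_nm`, `y_nm`,
#'   `photons`, `bkg` (photons/pixel), `bkg_sd`, `sigma_nm`, `rmse`,
#'   `converged`.
#' @export
fit_psf <- function(frame, candidates, camera, cfg = detection_config(),
                    window = NULL, sigma_start = 1.3 * camera$pixel_size) {
  stopifnot(inherits(camera, "camera_model"))
  n_em <- nrow(candidates)
  if (n_em < 1 || n_em > 3) stop("fit_psf: 1 to 3 candidates per joint fit")
  a <- camera$pixel_size
  x0 <- if (is.null(window)) 0 else window$x_min
  y0 <- if (is.null(window)) 0 else window$y_min
  h <- cfg$fit_halfwidth
  cols <- max(0, min(candidates$px) - h):min(ncol(frame) - 1, max(candidates$px) + h)
  rows <- max(0, min(candidates$py) - h):min(nrow(frame) - 1, max(candidates$py) + h)
  z <- frame[rows + 1, cols + 1, drop = FALSE] / camera$gain
  b0 <- stats::median(z)
  par0 <- numeric(0)
  for (k in seq_len(n_em)) {
    par0 <- c(par0,
              x0 + (candidates$px[k] + 0.5) * a,
              y0 + (candidates$py[k] + 0.5) * a,
              max(1, sum(z - b0)) / n_em)
  }
  par0 <- c(par0, sigma_start, b0)
  resid_fn <- function(p) {
    as.vector(psf_model_window(p, n_em, cols, rows, x0, y0, a) - z)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par0, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    p <- par0; conv <- FALSE; rmse <- NA_real_
  } else {
    p <- fit$par
    conv <- fit$info %in% 1:4 && p[length(p) - 1] > 0
    rmse <- sqrt(mean(fit$fvec^2))
  }
  bkg <- p[length(p)]
  data.frame(
    x_nm = p[3 * (seq_len(n_em) - 1) + 1],
    y_nm = p[3 * (seq_len(n_em) - 1) + 2],
    photons = p[3 * (seq_len(n_em) - 1) + 3],
    bkg = bkg, bkg_sd = sqrt(max(bkg, 0)),
    sigma_nm = abs(p[length(p) - 1]),
    rmse = rmse, converged = conv)
}

#' Theoretical localisation precision (Mortensen formula)
#'
#' Predicted standard deviation of a fitted emitter position for an
#' integrated Gaussian PSF on a pixelated detector:
#' `sigma_loc = sqrt( (sa2 / N) * (16/9 + 8 pi sa2 b^2 / (N a^2)) )` with
#' `sa2 = sigma^2 + a^2 / 12`, where N is the photon count, sigma the PSF
#' sd (nm), a the pixel size (nm) and b the background noise standard
#' deviation per pixel (for a Poisson camera, the square root of the
#' expected background photons per pixel). At b = 0 this reduces to
#' `(4/3) * sigma_a / sqrt(N)`.
#'
#' @param photons Photon count N (> 0); vectorised.
#' @param sigma_nm Fitted PSF sd in nm.
#' @param bkg_sd Background noise sd b in photons/pixel.
#' @param pixel_size Pixel size a in nm.
#' @return Precision in nm.
#' @examples
#' # sigma_a = 120 nm, N = 400, b = 0 -> (4/3) * 120 / 20 = 8 nm
#' localization_precision(400, sqrt(120^2 - 100^2 / 12), 0, 100)
#' @export
localization_precision <- function(photons, sigma_nm, bkg_sd = 0,
                                   pixel_size = 100) {
  if (any(photons <= 0)) stop("localization_precision: photons must be > 0")
  sa2 <- sigma_nm^2 + pixel_size^2 / 12
  sqrt((sa2 / photons) *
         (16 / 9 + 8 * pi * sa2 * bkg_sd^2 / (photons * pixel_size^2)))
}

#' Localise all events in a camera stack
#'
#' Runs [detect_events()] and [fit_psf()] over every frame, grouping
#' detections whose fit windows overlap into joint multi-emitter fits
#' (pile-ups of more than `max_joint` candidates are discarded), and
#' assembles the localisation table with Mortensen precision per record.
#' Non-converged or non-positive-photon fits are dropped and counted in
#' the attribute `n_discarded`.
#'
#' @param stack A [frame_stack()].
#' @param camera A [camera_model()]; its pixel size must match the stack.
#' @param cfg A [detection_config()].
#' @param channel Channel label for the output table.
#' @param max_joint Maximum emitters per joint fit (default 3).
#' @return A localisation data.frame: `frame`, `x_nm`, `y_nm`, `photons`,
#'   `bkg`, `sigma_nm`, `precision_nm`, `channel`, `group_id` (NA until
#'   [group_localizations()]).
#' @export
localize_stack <- function(stack, camera = camera_model(stack$pixel_size),
                           cfg = detection_config(), channel = "ch1",
                           max_joint = 3) {
  stopifnot(inherits(stack, "frame_stack"))
  if (abs(camera$pixel_size - stack$pixel_size) > 1e-9) {
    stop("localize_stack: camera pixel size does not match the stack")
  }
  cand <- detect_events(stack, cfg)
  rows_out <- list()
  n_disc <- 0L
  for (f in unique(cand$frame)) {
    cf <- cand[cand$frame == f, , drop = FALSE]
    img <- stack$frames[, , f + 1L]
    # cluster candidates whose windows overlap (Chebyshev <= 2 halfwidths)
    grp <- seq_len(nrow(cf))
    if (nrow(cf) > 1) {
      for (i in 2:nrow(cf)) {
        for (j in 1:(i - 1)) {
          if (max(abs(cf$px[i] - cf$px[j]), abs(cf$py[i] - cf$py[j])) <=
              2 * cfg$fit_halfwidth) {
            grp[grp == grp[i]] <- grp[j]
            break
          }
        }
      }
    }
    for (g in unique(grp)) {
      cg <- cf[grp == g, , drop = FALSE]
      if (nrow(cg) > max_joint) {
        n_disc <- n_disc + nrow(cg)
        next
      }
      fit <- fit_psf(img, cg, camera, cfg, window = stack$window)
      ok <- fit$converged & fit$photons > 0
      n_disc <- n_disc + sum(!ok)
      fit <- fit[ok, , drop = FALSE]
      if (nrow(fit) == 0) next
      rows_out[[length(rows_out) + 1L]] <- data.frame(
        frame = f, x_nm = fit$x_nm, y_nm = fit$y_nm,
        photons = fit$photons, bkg = fit$bkg, sigma_nm = fit$sigma_nm,
        precision_nm = localization_precision(fit$photons, fit$sigma_nm,
                                              fit$bkg_sd, camera$pixel_size),
        channel = channel, group_id = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows_out)) do.call(rbind, rows_out) else
    empty_localization_table(channel)
  rownames(out) <- NULL
  attr(out, "n_discarded") <- n_disc
  out
}

empty_localization_table <- function(channel = "ch1") {
  data.frame(frame = integer(0), x_nm = numeric(0), y_nm = numeric(0),
             photons = numeric(0), bkg = numeric(0), sigma_nm = numeric(0),
             precision_nm = numeric(0), channel = character(0),
             group_id = integer(0), stringsAsFactors = FALSE)
}

#' Group localisations into molecules
#'
#' Merges repeated detections of the same fluorophore into one record per
#' molecule: localisations chain into a group when they fall within
#' `radius` of the group's (photon-weighted) position and are temporally
#' linked — consecutive-frame runs of at most `max_on` frames, separated
#' by dark gaps of at most `max_gap` frames. A contiguous run exceeding
#' `max_on` starts a new group (conservative split), and a gap exceeding
#' `max_gap` closes the group. The defaults (100 nm, 5 on-frames, 50
#' gap-frames) are the grouping rules of the published pipeline. Merged
#' position is the photon-weighted mean of the members, merged photons
#' their exact sum, merged precision the inverse-variance combination.
#'
#' @param table Localisation data.frame (needs `frame`, `x_nm`, `y_nm`;
#'   `photons` and `precision_nm` used when present).
#' @param radius Grouping radius in nm.
#' @param max_on Maximum consecutive on-frames per run.
#' @param max_gap Maximum dark gap in frames between runs.
#' @return List: `labels` (group id per input row, in input order) and
#'   `merged` (one row per group: frame = first frame, photon-weighted
#'   x/y, summed photons, combined precision, `n_events`).
#' @export
group_localizations <- function(table, radius = 100, max_on = 5,
                                max_gap = 50) {
  n <- nrow(table)
  labels <- integer(n)
  if (n == 0) {
    return(list(labels = labels,
                merged = cbind(empty_localization_table(), n_events = integer(0))))
  }
  photons <- if ("photons" %in% names(table)) table$photons else rep(1, n)
  ord <- order(table$frame)
  # open groups: id, x, y (weighted), w, last_frame, run_len
  gid <- integer(0); gx <- numeric(0); gy <- numeric(0); gw <- numeric(0)
  glast <- integer(0); grun <- integer(0)
  next_id <- 0L
  for (i in ord) {
    f <- table$frame[i]; x <- table$x_nm[i]; y <- table$y_nm[i]
    w <- max(photons[i], .Machine$double.eps)
    # retire groups whose gap can no longer close
    live <- (f - glast) <= (max_gap + 1L)
    gid <- gid[live]; gx <- gx[live]; gy <- gy[live]; gw <- gw[live]
    glast <- glast[live]; grun <- grun[live]
    best <- NA_integer_; best_d <- Inf
    if (length(gid)) {
      d <- sqrt((gx / gw - x)^2 + (gy / gw - y)^2)
      gap <- f - glast
      elig <- d <= radius & gap >= 1 &
        !(gap == 1 & grun + 1L > max_on)
      if (any(elig)) {
        best <- which(elig)[which.min(d[elig])]
        best_d <- d[best]
      }
    }
    if (is.na(best)) {
      next_id <- next_id + 1L
      labels[i] <- next_id
      gid <- c(gid, next_id); gx <- c(gx, x * w); gy <- c(gy, y * w)
      gw <- c(gw, w); glast <- c(glast, f); grun <- c(grun, 1L)
    } else {
      labels[i] <- gid[best]
      gx[best] <- gx[best] + x * w
      gy[best] <- gy[best] + y * w
      gw[best] <- gw[best] + w
      grun[best] <- if (f - glast[best] == 1L) grun[best] + 1L else 1L
      glast[best] <- f
    }
  }
  merged <- do.call(rbind, lapply(split(seq_len(n), labels), function(idx) {
    w <- pmax(photons[idx], .Machine$double.eps)
    prec <- if ("precision_nm" %in% names(table)) {
      sqrt(1 / sum(1 / table$precision_nm[idx]^2))
    } else NA_real_
    data.frame(
      frame = min(table$frame[idx]),
      x_nm = sum(table$x_nm[idx] * w) / sum(w),
      y_nm = sum(table$y_nm[idx] * w) / sum(w),
      photons = sum(photons[idx]),
      bkg = if ("bkg" %in% names(table)) mean(table$bkg[idx]) else NA_real_,
      sigma_nm = if ("sigma_nm" %in% names(table))
        sum(table$sigma_nm[idx] * w) / sum(w) else NA_real_,
      precision_nm = prec,
      channel = if ("channel" %in% names(table)) table$channel[idx][1] else "ch1",
      group_id = labels[idx][1], n_events = length(idx),
      stringsAsFactors = FALSE)
  }))
  merged <- merged[order(merged$group_id), , drop = FALSE]
  rownames(merged) <- NULL
  list(labels = labels, merged = merged)
}

#' Estimate stage drift from fiducial markers
#'
#' Tracks each fiducial through the movie by nearest-neighbour linking
#' (starting from the supplied seed positions, within `search_radius`),
#' converts each track to displacements relative to its start, averages
#' displacements within knot bins of `knot_spacing` frames and across
#' fiducials, and returns a piecewise-linear [drift_trajectory()]
#' covering the full frame range, anchored so the displacement at frame 0
#' is exactly zero.
#'
#' @param table Localisation data.frame including the fiducial
#'   localisations (bright emitters present in most frames).
#' @param fiducial_seeds 2-column matrix of approximate fiducial
#'   positions (nm).
#' @param n_frames Total frame count of the movie.
#' @param knot_spacing Knot bin width in frames.
#' @param search_radius Maximum linking distance in nm.
#' @return A [drift_trajectory()].
#' @export
estimate_drift <- function(table, fiducial_seeds, n_frames,
                           knot_spacing = 100, search_radius = 500) {
  seeds <- matrix(as.numeric(as.matrix(fiducial_seeds)), ncol = 2)
  frames_list <- split(seq_len(nrow(table)), table$frame)
  disp <- matrix(NA_real_, n_frames, 2)
  counts <- numeric(n_frames)
  sum_disp <- matrix(0, n_frames, 2)
  any_track <- FALSE
  for (s in seq_len(nrow(seeds))) {
    p <- seeds[s, ]
    ref <- NULL
    found <- 0L
    track <- matrix(NA_real_, n_frames, 2)
    for (f in 0:(n_frames - 1)) {
      idx <- frames_list[[as.character(f)]]
      if (is.null(idx)) next
      d <- sqrt((table$x_nm[idx] - p[1])^2 + (table$y_nm[idx] - p[2])^2)
      j <- which.min(d)
      if (d[j] > search_radius) next
      pos <- c(table$x_nm[idx[j]], table$y_nm[idx[j]])
      if (is.null(ref)) ref <- pos
      track[f + 1, ] <- pos - ref
      p <- pos
      found <- found + 1L
    }
    if (found < max(2, n_frames / 10)) {
      stop(sprintf(paste0("estimate_drift: fiducial %d near (%.0f, %.0f) nm ",
                          "found in only %d/%d frames within %g nm"),
                   s, seeds[s, 1], seeds[s, 2], found, n_frames, search_radius))
    }
    any_track <- TRUE
    ok <- !is.na(track[, 1])
    sum_disp[ok, ] <- sum_disp[ok, ] + track[ok, ]
    counts[ok] <- counts[ok] + 1
  }
  if (!any_track) stop("estimate_drift: no fiducial track recovered")
  ok <- counts > 0
  frames <- (0:(n_frames - 1))[ok]
  mdisp <- sum_disp[ok, , drop = FALSE] / counts[ok]
  bins <- floor(frames / knot_spacing)
  knot_f <- tapply(frames, bins, mean)
  knot_dx <- tapply(mdisp[, 1], bins, mean)
  knot_dy <- tapply(mdisp[, 2], bins, mean)
  # extend to the full frame range by linear extrapolation, then anchor 0
  ext <- function(kf, kv, at) {
    if (length(kf) == 1) return(kv[1])
    fit <- if (at <= kf[1]) 1:2 else (length(kf) - 1):length(kf)
    slope <- (kv[fit[2]] - kv[fit[1]]) / (kf[fit[2]] - kf[fit[1]])
    kv[fit[1]] + slope * (at - kf[fit[1]])
  }
  kf <- as.numeric(knot_f); kx <- as.numeric(knot_dx); ky <- as.numeric(knot_dy)
  if (kf[1] > 0) {
    kx <- c(ext(kf, kx, 0), kx); ky <- c(ext(kf, ky, 0), ky); kf <- c(0, kf)
  }
  last <- n_frames - 1
  if (kf[length(kf)] < last) {
    kx <- c(kx, ext(kf, kx, last)); ky <- c(ky, ext(kf, ky, last))
    kf <- c(kf, last)
  }
  kx <- kx - kx[1]; ky <- ky - ky[1]
  drift_trajectory(kf, kx, ky)
}

#' Apply (or undo) a drift correction
#'
#' Subtracts the interpolated drift displacement at each record's frame
#' from its coordinates — the exact inverse of injecting the same
#' trajectory at render time. Frames outside the trajectory's domain are
#' an error.
#'
#' @param table Localisation data.frame with `frame`, `x_nm`, `y_nm`.
#' @param drift A [drift_trajectory()].
#' @return The table with corrected coordinates.
#' @export
apply_drift_correction <- function(table, drift) {
  d <- drift_at(drift, table$frame)
  table$x_nm <- table$x_nm - d[, "dx"]
  table$y_nm <- table$y_nm - d[, "dy"]
  table
}
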