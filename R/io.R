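#' Read and write localisation tables (CSV)
#'
#' The on-disk format is a plain CSV with header columns
#' `frame, x_nm, y_nm, photons, bkg, sigma_nm, precision_nm, channel,
#' group_id` — a ThunderSTORM-style dialect with units fixed to nm in
#' the column names. Only `frame`, `x_nm` and `y_nm` are mandatory;
#' unknown extra columns are preserved on a round-trip.
#'
#' @param path File path.
#' @param channel Optional channel label; when reading, restricts the
#'   returned rows to that channel.
#' @return `read_localizations`: a localisation data.frame.
#' @export
read_localizations <- function(path, channel = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("frame", "x_nm", "y_nm")) {
    if (!col %in% names(tab)) {
      stop(sprintf("read_localizations: missing mandatory column '%s'", col))
    }
  }
  if (!is.null(channel) && "channel" %in% names(tab)) {
    tab <- tab[tab$channel %in% channel, , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' @rdname read_localizations
#' @param table Localisation data.frame to write.
#' @export
write_localizations <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Localisation table to point pattern
#'
#' @param table Localisation data.frame.
#' @param window An [obs_window()]; defaults to the bounding box of the
#'   coordinates.
#' @param channel Optional channel filter.
#' @return A [point_pattern()].
#' @export
table_to_pattern <- function(table, window = NULL, channel = NULL) {
  if (!is.null(channel) && "channel" %in% names(table)) {
    table <- table[table$channel %in% channel, , drop = FALSE]
  }
  if (is.null(window)) {
    window <- obs_window(min(table$x_nm), min(table$y_nm),
                         max(table$x_nm) + 1e-9, max(table$y_nm) + 1e-9)
  }
  ch <- if (!is.null(channel)) channel else
    if ("channel" %in% names(table) && nrow(table)) table$channel[1] else "ch1"
  point_pattern(table$x_nm, table$y_nm, window, ch)
}

#' Read and write ROI polygon sets (JSON)
#'
#' Schema: `{"rois": [{"label": "cell"|"adhesion", "vertices_nm":
#' [[x, y], ...]}, ...]}` with coordinates in nm.
#'
#' @param path File path.
#' @return `read_roi_json`: an [roi_set()].
#' @export
read_roi_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$rois)) stop("read_roi_json: no 'rois' element")
  rois <- obj$rois
  if (is.data.frame(rois)) {
    polys <- lapply(rois$vertices_nm, function(v) matrix(unlist(v), ncol = 2, byrow = is.list(v)))
    labels <- rois$label
  } else {
    polys <- lapply(rois, function(r) do.call(rbind, lapply(r$vertices_nm, unlist)))
    labels <- vapply(rois, function(r) r$label, character(1))
  }
  roi_set(polys, labels)
}

#' @rdname read_roi_json
#' @param rois An [roi_set()] to write.
#' @export
write_roi_json <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  obj <- list(rois = lapply(seq_along(rois$polygons), function(i) {
    list(label = rois$labels[i],
         vertices_nm = unname(lapply(seq_len(nrow(rois$polygons[[i]])),
                                     function(j) rois$polygons[[i]][j, ])))
  }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write camera stacks as multi-page 16-bit TIFF
#'
#' Pixel values are stored as 16-bit unsigned integers (counts are
#' rounded and clamped to 0-65535) and recovered value-exactly.
#'
#' @param path File path.
#' @param pixel_size Pixel size in nm to attach on read.
#' @return `read_frame_stack`: a [frame_stack()].
#' @export
read_frame_stack <- function(path, pixel_size = 100) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- pages[[i]]
  frame_stack(frames, pixel_size)
}

#' @rdname read_frame_stack
#' @param stack A [frame_stack()] to write.
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  vals <- pmin(pmax(round(stack$frames), 0), 65535)
  pages <- lapply(seq_len(dim(vals)[3]), function(i) vals[, , i] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' One nested list collecting every tunable stage parameter, preloaded
#' with the published defaults of the analysis chain: detection threshold
#' k = 6, grouping radius 100 nm with 5 on-frames and 50 gap-frames,
#' DBSCAN r = 20 nm with 3 minimum neighbours, DoC radii 10-500 nm with
#' threshold 0.4, and the adhesion-support density thresholds 0.8 and
#' 4-7 um^-2. The configuration round-trips losslessly through YAML.
#'
#' @param ... Named overrides of the form `section$field`, e.g.
#'   `smlm_config(cluster = list(eps_nm = 30))` (partial lists are merged
#'   over the defaults).
#' @return Nested list of class `smlm_config`.
#' @export
smlm_config <- function(...) {
  cfg <- list(
    detection = list(filter_sigma_px = 1.2, k = 6, fit_halfwidth_px = 4),
    camera = list(pixel_size_nm = 100, gain = 1),
    grouping = list(radius_nm = 100, max_on_frames = 5, max_gap_frames = 50),
    cluster = list(eps_nm = 20, min_neighbors = 3),
    doc = list(r_min_nm = 10, r_max_nm = 500, r_step_nm = 10, threshold = 0.4),
    roi = list(tether_threshold_um2 = 0.8, spread_range_um2 = c(4, 7)),
    photophysics = unclass(photophysics_params()),
    seed = 1L
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  structure(cfg, class = "smlm_config")
}

#' @rdname smlm_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(smlm_config, cfg)
}

#' @rdname smlm_config
#' @param config An `smlm_config` to write.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname smlm_config
#' @export
doc_radii <- function(config) {
  seq(config$doc$r_min_nm, config$doc$r_max_nm, by = config$doc$r_step_nm)
}
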