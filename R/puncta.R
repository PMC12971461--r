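#' Segment fluorescent particles in a calibrated image
#'
#' Thresholds the intensity image (Otsu by default, via EBImage), labels
#' connected components, and measures each particle's area (um^2),
#' perimeter (um) and circularity `4*pi*A/P^2` (values above 1 from
#' discrete perimeter underestimation are clamped to 1).
#'
#' @param image numeric matrix in `[0, 1]` (rows = depth/y) or an EBImage
#'   `Image`.
#' @param pixel_size um per pixel; required.
#' @param threshold_method `"otsu"` (default) or a numeric threshold in
#'   `(0, 1)`.
#' @return list with `labels` (integer matrix, 0 = background) and
#'   `particles`, a data.frame with `id`, `area_um2`, `area_px`,
#'   `perimeter_um`, `circularity`, `cx_um`, `cy_um`.
#' @export
segment_particles <- function(image, pixel_size,
                              threshold_method = "otsu") {
  if (missing(pixel_size) || is.null(pixel_size) || !is.finite(pixel_size) ||
      pixel_size <= 0)
    stop("missing pixel calibration: pixel_size (um/px) is required")
  m <- if (inherits(image, "Image")) EBImage::imageData(image) else image
  if (!is.matrix(m)) stop("image must be a matrix")
  # EBImage images are x-by-y; our matrices are row = y, column = x
  ebi <- EBImage::Image(t(m))
  thr <- if (identical(threshold_method, "otsu"))
    EBImage::otsu(ebi, range = c(0, 1)) else as.numeric(threshold_method)
  mask <- ebi > thr
  # featureless fields: when the threshold fails to isolate a sparse
  # foreground (no contrast, or >30% of pixels "above threshold" as happens
  # when Otsu splits pure background noise), report no particles
  if (mean(mask) > 0.3 || diff(range(m)) < 1e-6)
    mask[] <- FALSE
  lab <- EBImage::bwlabel(mask)
  n_obj <- max(lab)
  empty <- data.frame(id = integer(), area_um2 = numeric(),
                      area_px = integer(), perimeter_um = numeric(),
                      circularity = numeric(), cx_um = numeric(),
                      cy_um = numeric(), stringsAsFactors = FALSE)
  if (n_obj == 0)
    return(list(labels = matrix(0L, nrow(m), ncol(m)), particles = empty))
  shp <- EBImage::computeFeatures.shape(lab)
  mom <- EBImage::computeFeatures.moment(lab)
  area_px <- shp[, "s.area"]
  per_px <- shp[, "s.perimeter"]
  circ <- pmin(1, 4 * pi * area_px / pmax(per_px, 1e-9)^2)
  particles <- data.frame(
    id = seq_len(n_obj),
    area_um2 = area_px * pixel_size^2,
    area_px = as.integer(area_px),
    perimeter_um = per_px * pixel_size,
    circularity = circ,
    cx_um = mom[, "m.cx"] * pixel_size,
    cy_um = mom[, "m.cy"] * pixel_size,
    stringsAsFactors = FALSE)
  list(labels = t(EBImage::imageData(lab)), particles = particles)
}

#' Particle retention filter
#'
#' The published quantification windows: GLAST/synaptophysin particles of
#' 0.05-3 um^2 with circularity ("contour") 0.3-1; GFAP particles of at
#' least 1 um^2 with circularity 0.3-1 (no upper area bound). All bounds
#' inclusive.
#'
#' @param min_area minimum area, um^2.
#' @param max_area maximum area, um^2, or `Inf` for no upper bound.
#' @param circularity numeric length-2 circularity bounds inside `[0, 1]`.
#' @return list of class `particle_filter`.
#' @export
particle_filter <- function(min_area = 0.05, max_area = 3,
                            circularity = c(0.3, 1)) {
  if (is.null(max_area) || is.na(max_area)) max_area <- Inf
  if (min_area >= max_area) stop("min_area must be below max_area")
  if (any(circularity < 0 | circularity > 1) ||
      circularity[1] > circularity[2])
    stop("circularity bounds must be ordered within [0, 1]")
  structure(list(min_area = min_area, max_area = max_area,
                 circularity = circularity), class = "particle_filter")
}

#' @rdname particle_filter
#' @export
glast_filter <- function() particle_filter(0.05, 3, c(0.3, 1))

#' @rdname particle_filter
#' @export
gfap_filter <- function() particle_filter(1, Inf, c(0.3, 1))

#' Apply a particle filter to a particle table
#'
#' Retains rows with `min_area <= area <= max_area` and circularity within
#' the filter's bounds (all inclusive). Idempotent and row-order
#' independent.
#'
#' @param particles data.frame with `area_um2` and `circularity` columns.
#' @param filter a [particle_filter()].
#' @return the filtered data.frame.
#' @export
apply_filter <- function(particles, filter = glast_filter()) {
  stopifnot(inherits(filter, "particle_filter"))
  if (!all(c("area_um2", "circularity") %in% names(particles)))
    stop("particle table needs area_um2 and circularity columns")
  keep <- particles$area_um2 >= filter$min_area &
    particles$area_um2 <= filter$max_area &
    particles$circularity >= filter$circularity[1] &
    particles$circularity <= filter$circularity[2]
  particles[keep, , drop = FALSE]
}

#' Rectangular layer region of interest
#'
#' A laminar ROI: full image width over a depth interval. Depth is the
#' image's y/row coordinate in um.
#'
#' @param width_um ROI width in um.
#' @param depth_range numeric length-2 `(top, bottom)` depth in um.
#' @param label layer label (e.g. "I", "II", "III", "I-1").
#' @return list of class `layer_roi` with `width_um`, `depth_range`,
#'   `label`, `area_um2`.
#' @export
layer_roi <- function(width_um, depth_range, label = "") {
  if (diff(depth_range) <= 0 || width_um <= 0)
    stop("degenerate ROI geometry")
  structure(list(width_um = width_um,
                 depth_range = as.numeric(depth_range), label = label,
                 area_um2 = width_um * diff(depth_range)),
            class = "layer_roi")
}

#' Subdivide a layer-I ROI into three equal-depth sublayers
#'
#' Returns the superficial, middle and deep bands (labels `I-1`, `I-2`,
#' `I-3`) partitioning the ROI's depth extent into equal thirds; band areas
#' sum exactly to the ROI area.
#'
#' @param roi a [layer_roi()].
#' @return list of three `layer_roi` objects ordered superficial to deep.
#' @export
subdivide_layer1 <- function(roi) {
  stopifnot(inherits(roi, "layer_roi"))
  d0 <- roi$depth_range[1]; d1 <- roi$depth_range[2]
  cuts <- seq(d0, d1, length.out = 4)
  lapply(1:3, function(k)
    layer_roi(roi$width_um, c(cuts[k], cuts[k + 1]),
              label = paste0(roi$label, "-", k)))
}

#' Laminar puncta metrics within an ROI
#'
#' Particles whose centroid depth (`cy_um`) falls inside the ROI's
#' half-open depth band contribute to: mean particle area (um^2; `NA` when
#' no particles), fractional coverage (100 * total particle area / ROI
#' area, %), and density (particles per 1000 um^2).
#'
#' @param particles data.frame with `area_um2` and `cy_um` columns
#'   (typically already filtered with [apply_filter()]).
#' @param roi a [layer_roi()].
#' @return data.frame row: `layer`, `n`, `mean_area_um2`, `coverage_pct`,
#'   `density_per_1000um2`, `roi_area_um2`.
#' @export
layer_metrics <- function(particles, roi) {
  stopifnot(inherits(roi, "layer_roi"))
  if (roi$area_um2 <= 0) stop("ROI area must be positive")
  inside <- particles$cy_um >= roi$depth_range[1] &
    particles$cy_um < roi$depth_range[2]
  sub <- particles[inside, , drop = FALSE]
  n <- nrow(sub)
  data.frame(
    layer = roi$label,
    n = n,
    mean_area_um2 = if (n > 0) mean(sub$area_um2) else NA_real_,
    coverage_pct = 100 * sum(sub$area_um2) / roi$area_um2,
    density_per_1000um2 = 1000 * n / roi$area_um2,
    roi_area_um2 = roi$area_um2,
    stringsAsFactors = FALSE)
}
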