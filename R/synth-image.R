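#' Specification for a synthetic laminar puncta image
#'
#' Describes a calibrated grayscale field containing non-overlapping
#' disk/elliptical puncta distributed across horizontal depth bands
#' (cortical layers). Ground truth for every punctum is returned alongside
#' the image, making segmentation and laminar metrics fully checkable.
#'
#' @param field_size numeric length-2 `(width, depth)` in um.
#' @param pixel_size um per pixel (> 0).
#' @param layer_bands named list of `(depth_min, depth_max)` um intervals,
#'   one per layer, non-overlapping.
#' @param puncta_per_layer named integer vector, counts per layer (names
#'   matching `layer_bands`).
#' @param area_mean,area_sd lognormal-ish area distribution parameters
#'   (um^2); areas are drawn normal and truncated at `area_range`.
#' @param area_range hard truncation `(min, max)` of drawn areas (um^2).
#' @param circularity_range `(min, max)` of drawn circularities; disks are
#'   deformed into ellipses to hit the target.
#' @param seed integer seed.
#' @return list of class `image_spec`.
#' @export
image_spec <- function(field_size = c(100, 90), pixel_size = 0.1,
                       layer_bands = list("I" = c(0, 30), "II" = c(30, 60),
                                          "III" = c(60, 90)),
                       puncta_per_layer = c("I" = 30, "II" = 30,
                                            "III" = 30),
                       area_mean = 1, area_sd = 0.5,
                       area_range = c(0.05, 3),
                       circularity_range = c(0.6, 1), seed = 1L) {
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (!all(names(puncta_per_layer) %in% names(layer_bands)))
    stop("puncta_per_layer names must match layer_bands")
  if (any(field_size <= 0)) stop("field_size must be positive")
  structure(list(field_size = field_size, pixel_size = pixel_size,
                 layer_bands = layer_bands,
                 puncta_per_layer = puncta_per_layer,
                 area_mean = area_mean, area_sd = area_sd,
                 area_range = area_range,
                 circularity_range = circularity_range,
                 seed = as.integer(seed)),
            class = "image_spec")
}

# rasterize an axis-aligned ellipse; returns TRUE-mask over the image grid
.ellipse_mask <- function(nx, ny, cx, cy, a, b, theta) {
  xr <- max(1L, floor(cx - a - 2)):min(nx, ceiling(cx + a + 2))
  yr <- max(1L, floor(cy - a - 2)):min(ny, ceiling(cy + a + 2))
  gx <- outer(xr - cx, rep(1, length(yr)))
  gy <- outer(rep(1, length(xr)), yr - cy)
  u <- gx * cos(theta) + gy * sin(theta)
  v <- -gx * sin(theta) + gy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  halo <- (u / (a + 2))^2 + (v / (b + 2))^2 <= 1
  list(x = xr, y = yr, inside = inside, halo = halo)
}

#' Generate a synthetic puncta image with ground truth
#'
#' Places non-overlapping elliptical puncta (pixel value near 1 on a dim
#' noisy background) at the requested per-layer counts with areas and
#' circularities drawn from the requested distributions. The generator retries
#' placement up to 200 times per punctum and errors if the field is too
#' crowded. The returned ground truth records, per punctum: centroid (um),
#' analytic area (pi*a*b, um^2), rasterized pixel count, analytic
#' circularity and layer.
#'
#' @param spec an [image_spec()].
#' @return list with `image` (numeric matrix in \[0,1\], rows = depth/y,
#'   columns = width/x), `ground_truth` (data.frame), `pixel_size`.
#' @export
gen_puncta_image <- function(spec) {
  stopifnot(inherits(spec, "image_spec"))
  px <- spec$pixel_size
  nx <- round(spec$field_size[1] / px)   # width, columns
  ny <- round(spec$field_size[2] / px)   # depth, rows
  withr::with_seed(spec$seed, {
    img <- matrix(0.1 + 0.02 * stats::runif(nx * ny), nrow = ny, ncol = nx)
    occupied <- matrix(FALSE, ny, nx)
    rows <- list()
    for (layer in names(spec$puncta_per_layer)) {
      k <- spec$puncta_per_layer[[layer]]
      if (k == 0) next
      band <- spec$layer_bands[[layer]]
      for (j in seq_len(k)) {
        placed <- FALSE
        for (try in seq_len(200L)) {
          area <- stats::rnorm(1, spec$area_mean, spec$area_sd)
          area <- min(max(area, spec$area_range[1]), spec$area_range[2])
          circ <- stats::runif(1, spec$circularity_range[1],
                               spec$circularity_range[2])
          # ellipse semi-axes from area and target circularity: for an
          # ellipse C = 4*pi*A/P^2 with P ~ Ramanujan; solve axis ratio
          # numerically
          ratio <- .axis_ratio_for_circ(circ)
          a_um <- sqrt(area * ratio / pi)   # semi-major
          b_um <- a_um / ratio              # semi-minor
          a <- a_um / px; b <- b_um / px
          theta <- stats::runif(1, 0, pi)
          cx <- stats::runif(1, a + 2, nx - a - 2)
          # centroid depth constrained to the layer band, punctum fully
          # inside the field
          y_lo <- max(band[1] / px, a + 2)
          y_hi <- min(band[2] / px, ny - a - 2)
          if (y_hi <= y_lo) stop("layer band too thin for punctum")
          cy <- stats::runif(1, y_lo, y_hi)
          m <- .ellipse_mask(nx, ny, cx, cy, a, b, theta)
          # keep a 2-px moat between puncta so components never touch
          sub <- occupied[m$y, m$x, drop = FALSE]
          dil <- m$inside
          if (any(sub & t(m$halo))) next
          occupied[m$y, m$x] <- sub | t(m$halo)
          img_sub <- img[m$y, m$x, drop = FALSE]
          img_sub[t(dil)] <- 0.9 + 0.05 * stats::runif(sum(dil))
          img[m$y, m$x] <- img_sub
          rows[[length(rows) + 1L]] <- data.frame(
            layer = layer, cx_um = cx * px, cy_um = cy * px,
            area_um2 = pi * a_um * b_um,
            area_px = sum(dil),
            circularity = circ, stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (!placed)
          stop("could not place punctum without overlap after 200 retries")
      }
    }
    gt <- if (length(rows)) do.call(rbind, rows) else
      data.frame(layer = character(), cx_um = numeric(), cy_um = numeric(),
                 area_um2 = numeric(), area_px = integer(),
                 circularity = numeric(), stringsAsFactors = FALSE)
    list(image = img, ground_truth = gt, pixel_size = px)
  })
}

# ellipse axis ratio r >= 1 whose analytic circularity (4 pi A / P^2, with
# the exact perimeter) equals `circ`
.axis_ratio_for_circ <- function(circ) {
  if (circ >= 0.999) return(1)
  f <- function(r) {
    a <- r; b <- 1
    h <- ((a - b) / (a + b))^2
    p <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
    4 * pi * (pi * a * b) / p^2 - circ
  }
  stats::uniroot(f, c(1, 50))$root
}

#' Write a puncta image as TIFF with a JSON calibration sidecar
#'
#' @param x result of [gen_puncta_image()].
#' @param path output TIFF path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_puncta_tiff <- function(x, path) {
  tiff::writeTIFF(x$image, path, bits.per.sample = 16)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(list(pixel_size_um = x$pixel_size),
                         paste0(path, ".json"), auto_unbox = TRUE)
  } else {
    writeLines(sprintf('{"pixel_size_um": %g}', x$pixel_size),
               paste0(path, ".json"))
  }
  invisible(path)
}
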