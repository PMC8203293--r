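#' Stiffness map objects
#'
#' A `stiffness_map` holds a 2D grid of tissue elastic moduli (kPa) as produced
#' by shear-wave elastography, together with the isotropic pixel size (mm) and
#' a logical region-of-interest mask outlining the tumor. Pixels are indexed
#' 0-based conceptually as (row, col) = (y, x); in R the grid is an ordinary
#' row-major-interpreted matrix.
#'
#' Elastography dropouts (unmeasurable pixels) may be encoded as `NA`/`NaN` or
#' negative sentinels inside the ROI; they are excluded from all statistics and
#' reported as a dropout fraction.
#'
#' @param values Numeric matrix of elasticity values in kPa.
#' @param pixel_size_mm Isotropic pixel edge length in millimetres.
#' @param roi Logical matrix of the same shape as `values`; `TRUE` marks tumor
#'   pixels. Defaults to the full frame.
#' @param subject_id Optional subject identifier.
#' @param timepoint Optional acquisition timepoint (days since implantation).
#' @return A `stiffness_map` object.
#' @examples
#' m <- stiffness_map(matrix(c(50, 10, 10, 10), 2, 2), pixel_size_mm = 0.1)
#' compute_roi_summary(m, threshold_kPa = 40)
#' @export
stiffness_map <- function(values, pixel_size_mm, roi = NULL,
                          subject_id = NA_character_, timepoint = NA_real_) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix of stiffness in kPa.")
  }
  if (!is.numeric(pixel_size_mm) || length(pixel_size_mm) != 1L ||
      !is.finite(pixel_size_mm) || pixel_size_mm <= 0) {
    abort("`pixel_size_mm` must be a single positive number.")
  }
  if (is.null(roi)) roi <- matrix(TRUE, nrow(values), ncol(values))
  if (!is.logical(roi) || !identical(dim(roi), dim(values))) {
    abort("`roi` must be a logical matrix with the same shape as `values`.")
  }
  roi[is.na(roi)] <- FALSE
  if (!any(roi)) abort("ROI is empty: no tumor region to quantify.")
  structure(
    list(values = values, pixel_size_mm = pixel_size_mm, roi = roi,
         subject_id = as.character(subject_id), timepoint = as.numeric(timepoint)),
    class = "stiffness_map"
  )
}

#' @export
print.stiffness_map <- function(x, ...) {
  cat(sprintf("<stiffness_map> %d x %d px @ %.3g mm/px, %d ROI px",
              nrow(x$values), ncol(x$values), x$pixel_size_mm, sum(x$roi)))
  if (!is.na(x$subject_id)) cat(", subject", x$subject_id)
  cat("\n")
  invisible(x)
}

#' Summarise a stiffness map inside its tumor ROI
#'
#' Computes, over in-ROI pixels only, the mean, minimum, maximum and sample
#' standard deviation of stiffness, the ROI area, and the stiff-area fraction:
#' the proportion of in-ROI pixels with stiffness strictly greater than
#' `threshold_kPa` (default 40 kPa, the conventional cut-off for "very stiff"
#' tumor regions).
#'
#' Dropout pixels (`NA`/`NaN` or negative values inside the ROI) are excluded
#' from every statistic, including the stiff-fraction denominator, and are
#' reported in `dropout_fraction`. `area_mm2` counts all ROI pixels.
#'
#' @param map A [stiffness_map()].
#' @param threshold_kPa Positive stiffness threshold in kPa.
#' @return A one-row tibble with columns `subject_id`, `timepoint`, `mean_kPa`,
#'   `min_kPa`, `max_kPa`, `sd_kPa`, `area_mm2`, `stiff_fraction`,
#'   `threshold_kPa`, `dropout_fraction`, `n_pixels`.
#' @export
compute_roi_summary <- function(map, threshold_kPa = 40) {
  stopifnot(inherits(map, "stiffness_map"))
  if (!is.numeric(threshold_kPa) || length(threshold_kPa) != 1L || threshold_kPa <= 0) {
    abort("`threshold_kPa` must be a single positive number (kPa).")
  }
  v <- map$values[map$roi]
  dropout <- !is.finite(v) | v < 0
  if (all(dropout)) {
    abort(sprintf("All %d in-ROI pixels are dropouts (non-finite or negative).",
                  length(v)))
  }
  ok <- v[!dropout]
  tibble(
    subject_id = map$subject_id,
    timepoint = map$timepoint,
    mean_kPa = mean(ok),
    min_kPa = min(ok),
    max_kPa = max(ok),
    sd_kPa = if (length(ok) > 1L) sd(ok) else 0,
    area_mm2 = length(v) * map$pixel_size_mm^2,
    stiff_fraction = sum(ok > threshold_kPa) / length(ok),
    threshold_kPa = threshold_kPa,
    dropout_fraction = sum(dropout) / length(v),
    n_pixels = length(ok)
  )
}

#' Fraction of ROI pixels above a stiffness threshold
#'
#' Convenience projection of [compute_roi_summary()]: the fraction (in `[0,1]`)
#' of in-ROI pixels with stiffness strictly above `threshold_kPa`. Pixels at
#' exactly the threshold are not counted as stiff.
#'
#' @inheritParams compute_roi_summary
#' @return A single number in `[0, 1]`.
#' @export
stiff_area_fraction <- function(map, threshold_kPa = 40) {
  compute_roi_summary(map, threshold_kPa)$stiff_fraction
}

#' Normalise a stiffness time series to its first timepoint
#'
#' Divides each timepoint's mean stiffness by the first timepoint's value
#' (stiffness at t_n over stiffness at t_0), so the first ratio is 1.
#'
#' @param series Data frame with numeric columns `timepoint` (strictly
#'   increasing) and `mean_kPa`.
#' @return A tibble with columns `timepoint`, `mean_kPa`, `ratio`.
#' @examples
#' normalized_stiffness(data.frame(timepoint = c(0, 3, 6), mean_kPa = c(10, 20, 15)))
#' @export
normalized_stiffness <- function(series) {
  series <- as_tibble(series)
  if (!all(c("timepoint", "mean_kPa") %in% names(series)) || nrow(series) < 1L) {
    abort("`series` needs columns `timepoint` and `mean_kPa` and at least one row.")
  }
  if (is.unsorted(series$timepoint, strictly = TRUE)) {
    abort("`timepoint` must be strictly increasing.")
  }
  if (!is.finite(series$mean_kPa[1]) || series$mean_kPa[1] <= 0) {
    abort("Baseline mean stiffness must be positive to normalise the series.")
  }
  mutate(series, ratio = .data$mean_kPa / .data$mean_kPa[1])
}

#' Caliper tumor volume
#'
#' Ellipsoid-approximation xenograft volume from two perpendicular caliper
#' diameters: `x * y^2 / 2`, with `x` the longest and `y` the shortest
#' diameter (both mm).
#'
#' @param x_mm Longest diameter, mm.
#' @param y_mm Shortest diameter, mm. Vectorised with `x_mm`.
#' @return Volume in mm^3.
#' @examples
#' caliper_volume(10, 5) # 125
#' @export
caliper_volume <- function(x_mm, y_mm) {
  if (any(!is.finite(x_mm)) || any(!is.finite(y_mm)) ||
      any(x_mm <= 0) || any(y_mm <= 0)) {
    abort("Diameters must be positive and finite (mm).")
  }
  if (any(y_mm > x_mm)) {
    abort("`y_mm` exceeds `x_mm`: pass the longest diameter as `x_mm` (swap the arguments).")
  }
  x_mm * y_mm^2 / 2
}

#' Rasterise a polygon ROI onto a pixel grid
#'
#' Even-odd (ray-casting) fill; a pixel belongs to the ROI when its centre is
#' inside the polygon. Polygon vertices are in pixel units with x along
#' columns and y along rows; the centre of pixel (row r, col c) is at
#' (x, y) = (c - 0.5, r - 0.5).
#'
#' @param polygon Two-column matrix or data frame of (x, y) vertices.
#' @param dim Integer vector `c(nrow, ncol)` of the target grid.
#' @return Logical matrix of shape `dim`.
#' @export
roi_from_polygon <- function(polygon, dim) {
  poly <- as.matrix(polygon)
  if (ncol(poly) != 2L || nrow(poly) < 3L) {
    abort("`polygon` must have >= 3 (x, y) vertices.")
  }
  nr <- dim[1]; nc <- dim[2]
  cx <- rep(seq_len(nc) - 0.5, each = nr)
  cy <- rep(seq_len(nr) - 0.5, times = nc)
  inside <- rep(FALSE, nr * nc)
  px <- poly[, 1]; py <- poly[, 2]
  j <- nrow(poly)
  for (i in seq_len(nrow(poly))) {
    crosses <- ((py[i] > cy) != (py[j] > cy)) &
      (cx < (px[j] - px[i]) * (cy - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, nr, nc)
}

#' Read a stiffness map from TIFF or CSV
#'
#' Reads a single-channel float TIFF (values in kPa) or a headerless CSV grid,
#' with the ROI given either as a binary TIFF mask or as a JSON sidecar of the
#' form `{"polygon": [[x, y], ...]}` in pixel coordinates.
#'
#' @param path Path to the map (`.tif`/`.tiff` or `.csv`).
#' @param pixel_size_mm Pixel edge length, mm.
#' @param roi Optional path to a mask TIFF or polygon JSON; `NULL` uses the
#'   full frame.
#' @param tiff_max_kPa For 16-bit TIFFs written by [write_stiffness_map()]:
#'   the quantisation full scale. `NULL` (default) reads TIFF samples as-is
#'   (float32 kPa).
#' @inheritParams stiffness_map
#' @return A [stiffness_map()].
#' @export
read_stiffness_map <- function(path, pixel_size_mm, roi = NULL,
                               subject_id = NA_character_, timepoint = NA_real_,
                               tiff_max_kPa = NULL) {
  values <- read_grid(path, tiff_max_kPa)
  mask <- NULL
  if (!is.null(roi)) {
    if (grepl("\\.json$", roi, ignore.case = TRUE)) {
      side <- jsonlite::fromJSON(roi)
      if (is.null(side$polygon)) abort("ROI JSON must contain a `polygon` field.")
      mask <- roi_from_polygon(side$polygon, dim(values))
    } else {
      mask <- read_grid(roi) > 0
    }
  }
  stiffness_map(values, pixel_size_mm, roi = mask,
                subject_id = subject_id, timepoint = timepoint)
}

read_grid <- function(path, tiff_max_kPa = NULL) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    img <- tiff::readTIFF(path, as.is = is.null(tiff_max_kPa))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    if (!is.null(tiff_max_kPa)) img <- img * tiff_max_kPa
    img
  } else {
    as.matrix(utils::read.csv(path, header = FALSE))
  }
}

#' Write a stiffness map to TIFF
#'
#' Writes the kPa grid as a 16-bit TIFF quantised against a fixed full scale
#' (`max_kPa`, default 200 kPa, i.e. about 0.003 kPa resolution). Read such a
#' file back with `read_stiffness_map(..., tiff_max_kPa = 200)`.
#'
#' @param map A [stiffness_map()].
#' @param path Output path.
#' @param max_kPa Full-scale stiffness of the quantisation.
#' @return `path`, invisibly.
#' @export
write_stiffness_map <- function(map, path, max_kPa = 200) {
  stopifnot(inherits(map, "stiffness_map"))
  v <- pmin(pmax(map$values, 0), max_kPa) / max_kPa
  tiff::writeTIFF(v, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' @describeIn stiffness_map Heatmap of the stiffness grid with the ROI outline.
#' @param object,x A `stiffness_map`.
#' @param ... Unused.
#' @export
autoplot.stiffness_map <- function(object, ...) {
  df <- tibble(
    x = rep(seq_len(ncol(object$values)), each = nrow(object$values)),
    y = rep(seq_len(nrow(object$values)), times = ncol(object$values)),
    kPa = as.vector(object$values),
    roi = as.vector(object$roi)
  )
  ggplot(df, aes(.data$x, .data$y, fill = .data$kPa)) +
    geom_raster() +
    geom_point(data = dplyr::filter(df, !.data$roi),
               aes(.data$x, .data$y), colour = "white", size = 0.1,
               inherit.aes = FALSE, alpha = 0.3) +
    scale_fill_viridis_c(name = "kPa") +
    coord_equal() +
    labs(x = "x (px)", y = "y (px)") +
    theme_minimal()
}
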