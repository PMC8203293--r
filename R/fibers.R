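#' SHG image objects
#'
#' Wraps a non-negative 2D intensity grid from second-harmonic generation
#' (or two-photon fluorescence) microscopy with its isotropic pixel size in
#' micrometres.
#'
#' @param intensity Numeric matrix, arbitrary units, all values >= 0.
#' @param pixel_size_um Micrometres per pixel.
#' @return An `shg_image` object.
#' @export
shg_image <- function(intensity, pixel_size_um) {
  if (!is.matrix(intensity) || !is.numeric(intensity)) {
    abort("`intensity` must be a numeric matrix.")
  }
  if (any(intensity < 0, na.rm = TRUE)) abort("SHG intensities must be >= 0.")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    abort("`pixel_size_um` must be a single positive number; pixel size is required.")
  }
  structure(list(intensity = intensity, pixel_size_um = pixel_size_um),
            class = "shg_image")
}

#' @export
print.shg_image <- function(x, ...) {
  cat(sprintf("<shg_image> %d x %d px @ %.3g um/px\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_size_um))
  invisible(x)
}

path_arc_length <- function(path) {
  d <- diff(path)
  sum(sqrt(rowSums(d^2)))
}

#' Curvature ratio of a fiber path
#'
#' The curvature ratio CR is the fiber arc length A divided by the straight
#' chord B between its endpoints, CR = A/B. A perfectly linear fiber has
#' CR = 1; wavier fibers have larger CR. By the triangle inequality CR >= 1
#' for any polyline.
#'
#' @param path Two-column numeric matrix of ordered (x, y) points (any length
#'   unit) with at least 2 rows, or a list of such matrices.
#' @return Numeric scalar (or vector for a list input), always >= 1.
#' @examples
#' th <- seq(0, pi, length.out = 200)
#' curvature_ratio(cbind(cos(th), sin(th))) # semicircle: pi/2
#' @export
curvature_ratio <- function(path) {
  if (is.list(path) && !is.data.frame(path)) {
    return(map_dbl(path, curvature_ratio))
  }
  path <- as.matrix(path)
  if (nrow(path) < 2L || ncol(path) != 2L) {
    abort("`path` must be a two-column matrix with >= 2 points.")
  }
  chord <- sqrt(sum((path[nrow(path), ] - path[1, ])^2))
  if (chord == 0) {
    abort("Fiber endpoints coincide (closed path): curvature ratio is undefined.")
  }
  path_arc_length(path) / chord
}

#' Dominant orientation of a fiber path
#'
#' Angle of the principal axis of the path's point cloud, measured in degrees
#' from the image x-axis and folded into `[0, 180)`.
#'
#' @inheritParams curvature_ratio
#' @return Angle in degrees in `[0, 180)`.
#' @export
path_orientation <- function(path) {
  if (is.list(path) && !is.data.frame(path)) {
    return(map_dbl(path, path_orientation))
  }
  path <- as.matrix(path)
  if (nrow(path) < 2L) abort("`path` must have >= 2 points.")
  centred <- sweep(path, 2, colMeans(path))
  cv <- crossprod(centred) / nrow(path)
  e <- eigen(cv, symmetric = TRUE)
  ang <- atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi
  ang %% 180
}

#' Build a fiber set from traced paths
#'
#' Assembles per-fiber paths (ordered (x, y) points in micrometres) and width
#' estimates into a tidy fiber table: one row per fiber with its path as a
#' list-column and the derived metrics (arc length, dominant orientation,
#' curvature ratio).
#'
#' @param paths List of two-column matrices, micrometre coordinates.
#' @param width_um Numeric vector of mean full widths (um), recycled.
#' @param source_id Identifier of the source image.
#' @return A `fiber_set` tibble with columns `fiber_id`, `path`, `width_um`,
#'   `length_um`, `orientation_deg`, `curvature_ratio`.
#' @export
fiber_set <- function(paths = list(), width_um = NA_real_, source_id = NA_character_) {
  if (length(paths) == 0L) {
    out <- tibble(fiber_id = integer(), path = list(), width_um = double(),
                  length_um = double(), orientation_deg = double(),
                  curvature_ratio = double())
  } else {
    out <- tibble(
      fiber_id = seq_along(paths),
      path = lapply(paths, as.matrix),
      width_um = rep_len(width_um, length(paths)),
      length_um = map_dbl(paths, path_arc_length),
      orientation_deg = map_dbl(paths, path_orientation),
      curvature_ratio = map_dbl(paths, curvature_ratio)
    )
  }
  attr(out, "source_id") <- source_id
  class(out) <- c("fiber_set", class(out))
  out
}

#' Orientation coefficient of variation
#'
#' Fiber alignment statistic: the sample standard deviation (n - 1
#' denominator) of per-fiber orientation angles divided by their mean, with
#' angles in degrees in `[0, 180)`. Smaller CV means better-aligned fibers.
#' The statistic is frame-dependent (it uses raw angles, not circular
#' statistics); keep a fixed angular reference across images being compared.
#'
#' @param x Numeric vector of angles in degrees, or a [fiber_set()] (its
#'   `orientation_deg` column is used).
#' @return Dimensionless CV >= 0.
#' @examples
#' orientation_cv(c(30, 90)) # 0.7071
#' @export
orientation_cv <- function(x) {
  if (inherits(x, "fiber_set")) x <- x$orientation_deg
  x <- as.numeric(x)
  if (length(x) < 2L) abort("Orientation CV needs >= 2 fibers.")
  if (any(x < 0 | x >= 180)) abort("Angles must lie in [0, 180) degrees.")
  m <- mean(x)
  if (m == 0) {
    abort(paste("Mean angle is 0 (all fibers at exactly 0 degrees): CV is",
                "undefined; rotate the angular reference frame."))
  }
  sd(x) / m
}

#' Architecture summary of a fiber set
#'
#' Per-image summary of traced collagen fibers: fiber count, mean width and
#' length with their per-fiber distributions, mean curvature ratio, and the
#' orientation CV.
#'
#' @param fibers A [fiber_set()] with >= 1 fiber.
#' @return A one-row tibble with columns `n_fibers`, `mean_width_um`,
#'   `mean_length_um`, `mean_curvature_ratio`, `orientation_cv`,
#'   `width_distribution`, `length_distribution` (list-columns).
#' @export
architecture_summary <- function(fibers) {
  stopifnot(inherits(fibers, "fiber_set"))
  if (nrow(fibers) == 0L) abort("No fibers to summarise.")
  tibble(
    n_fibers = nrow(fibers),
    mean_width_um = mean(fibers$width_um),
    mean_length_um = mean(fibers$length_um),
    mean_curvature_ratio = mean(fibers$curvature_ratio),
    orientation_cv = if (nrow(fibers) >= 2L) orientation_cv(fibers) else NA_real_,
    width_distribution = list(fibers$width_um),
    length_distribution = list(fibers$length_um)
  )
}

#' Packed-fiber fraction from a Sirius-red RGB image
#'
#' Under polarised light, thick and densely packed collagen fibers give a
#' red-orange birefringence. This returns the percentage of tissue pixels
#' classified red-orange. Two modes: `"hue"` classifies by HSV hue in
#' `[0, 40]` or `[320, 360]` degrees with value above a darkness floor
#' (robust to white balance); `"red-dominance"` uses R > G and R > B.
#' Tissue pixels are those with value above the floor.
#'
#' @param image Numeric array `height x width x 3` (RGB). Values may be on
#'   any common positive scale (0-1 or 0-255).
#' @param mode `"hue"` or `"red-dominance"`.
#' @param value_floor HSV value below which a pixel is treated as empty glass
#'   (after scaling to `[0, 1]`).
#' @return Percentage in `[0, 100]`.
#' @export
packed_fiber_fraction <- function(image, mode = c("hue", "red-dominance"),
                                  value_floor = 0.1) {
  mode <- match.arg(mode)
  if (length(dim(image)) != 3L || dim(image)[3] < 3L) {
    abort("`image` must be an RGB array (height x width x 3); grayscale input is not supported.")
  }
  r <- as.vector(image[, , 1]); g <- as.vector(image[, , 2]); b <- as.vector(image[, , 3])
  top <- max(r, g, b, 1e-12)
  hsv <- grDevices::rgb2hsv(rbind(r, g, b) / top, maxColorValue = 1)
  value <- hsv[3, ]
  tissue <- value > value_floor
  if (!any(tissue)) return(0)
  if (mode == "hue") {
    hue_deg <- hsv[1, ] * 360
    red <- tissue & (hue_deg <= 40 | hue_deg >= 320)
  } else {
    red <- tissue & r > g & r > b
  }
  100 * sum(red) / sum(tissue)
}

#' SHG-positive mask
#'
#' Thresholds an SHG image into collagen-positive regions. The default rule
#' computes an Otsu threshold over the nonzero pixels (zero pixels are
#' typically empty background outside the tissue); a fixed numeric threshold
#' can be supplied instead.
#'
#' @param image An [shg_image()].
#' @param method `"otsu"` or a single numeric cut: mask is `intensity > cut`.
#' @return Logical matrix, `TRUE` where SHG-positive.
#' @export
shg_positive_mask <- function(image, method = "otsu") {
  stopifnot(inherits(image, "shg_image"))
  x <- image$intensity
  if (is.numeric(method)) return(x > method[1])
  nz <- x[x > 0]
  rng <- range(x)
  if (length(nz) == 0L || rng[1] == rng[2]) {
    abort("Image is constant: threshold is degenerate, no SHG-positive region separable.")
  }
  if (min(nz) == max(nz)) {
    # binary image: the only separating cut lies between 0 and the nonzero level
    return(x > max(nz) / 2)
  }
  scaled <- (x - rng[1]) / (rng[2] - rng[1])
  cut <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  x > (cut * (rng[2] - rng[1]) + rng[1])
}

#' Background-subtracted mean fluorescence in a mask
#'
#' Mean fluorescence signal over mask-true pixels minus a background estimate,
#' as used for quantifying collagen-crosslink (PYD/DPD) autofluorescence
#' inside SHG-positive regions. A negative result is reported as-is.
#'
#' @param fluor Numeric matrix of fluorescence intensities.
#' @param mask Logical matrix, same shape, with >= 1 `TRUE` pixel.
#' @param background Scalar background level subtracted from the masked mean.
#' @return Background-subtracted mean signal.
#' @export
crosslink_fluorescence <- function(fluor, mask, background = 0) {
  if (!identical(dim(fluor), dim(mask))) abort("`fluor` and `mask` shapes differ.")
  if (!any(mask)) abort("Mask is empty: no SHG-positive region to measure.")
  mean(fluor[mask]) - background
}

#' @describeIn fiber_set Plot fiber paths coloured by curvature ratio.
#' @param object A `fiber_set`.
#' @param ... Unused.
#' @export
autoplot.fiber_set <- function(object, ...) {
  if (nrow(object) == 0L) abort("Empty fiber set: nothing to plot.")
  df <- list_rbind(imap(object$path, function(p, i) {
    tibble(fiber_id = object$fiber_id[i], x = p[, 1], y = p[, 2],
           curvature_ratio = object$curvature_ratio[i])
  }))
  ggplot(df, aes(.data$x, .data$y, group = .data$fiber_id,
                 colour = .data$curvature_ratio)) +
    geom_path(linewidth = 0.8) +
    coord_equal() +
    labs(x = "x (µm)", y = "y (µm)", colour = "CR") +
    theme_minimal()
}
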