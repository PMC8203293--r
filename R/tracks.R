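#' Validate a cell-track table
#'
#' Track tables are tidy data frames with one row per detection and columns
#' `track_id`, `t_s` (seconds), `x_um`, `y_um`, `z_um` (micrometres; `z_um`
#' is depth below the slice surface). Within each track timestamps must be
#' strictly increasing; gaps (missed frames) are allowed.
#'
#' @param tracks Data frame of detections.
#' @return The validated table as a tibble, invisibly usable in pipes.
#' @export
validate_tracks <- function(tracks) {
  tracks <- as_tibble(tracks)
  need <- c("track_id", "t_s", "x_um", "y_um", "z_um")
  miss <- setdiff(need, names(tracks))
  if (length(miss)) abort(paste("Track table lacks columns:", toString(miss)))
  bad <- tracks |>
    group_by(.data$track_id) |>
    summarise(ok = !is.unsorted(.data$t_s, strictly = TRUE), .groups = "drop")
  if (any(!bad$ok)) {
    abort(paste("Non-increasing or duplicated timestamps in track(s):",
                toString(bad$track_id[!bad$ok])))
  }
  tracks
}

#' Remove superficial track samples
#'
#' Drops detections at or above the cut depth (default 15 um below the slice
#' surface), excluding cells near the cut surface whose motility is
#' artefactual. Tracks left with fewer than 2 samples are removed entirely.
#' The boundary is exclusive: a sample at exactly the cut depth is removed.
#'
#' @param tracks Track table (see [validate_tracks()]).
#' @param cut_depth_um Cut depth in um.
#' @return Filtered track table (possibly empty).
#' @export
depth_filter <- function(tracks, cut_depth_um = 15) {
  tracks <- validate_tracks(tracks)
  tracks |>
    filter(.data$z_um > cut_depth_um) |>
    group_by(.data$track_id) |>
    filter(n() >= 2L) |>
    ungroup()
}

#' Keep tracks covering more than a fraction of the recording
#'
#' Retains tracks whose duration (`t_last - t_first`, robust to gaps) is
#' strictly greater than `min_fraction` of the total recording time. A track
#' of exactly the threshold duration is excluded.
#'
#' @param tracks Track table.
#' @param recording_s Total recording time, seconds.
#' @param min_fraction Minimum duration fraction (default 0.1).
#' @return Filtered track table.
#' @export
duration_filter <- function(tracks, recording_s, min_fraction = 0.1) {
  if (recording_s <= 0) abort("`recording_s` must be positive.")
  tracks <- validate_tracks(tracks)
  tracks |>
    group_by(.data$track_id) |>
    filter(max(.data$t_s) - min(.data$t_s) > min_fraction * recording_s) |>
    ungroup()
}

#' Per-track motility statistics
#'
#' For each track: total path length (sum of consecutive Euclidean steps),
#' duration (`t_last - t_first`), mean migration speed in um/min
#' (path length / duration), net displacement (Euclidean distance from first
#' to last position) and straightness (displacement / path length, defined as
#' 0 for a zero-length path). Statistics are 3D by default; `dims = c("x", "y")`
#' gives the 2D projection used by planar trackers.
#'
#' @param tracks Track table with >= 2 samples per track.
#' @param dims Coordinate axes to use: subset of `c("x", "y", "z")`.
#' @return A tibble with one row per track: `track_id`, `n_samples`,
#'   `duration_s`, `path_length_um`, `speed_um_per_min`, `displacement_um`,
#'   `straightness`.
#' @examples
#' tr <- data.frame(track_id = "a", t_s = c(0, 30, 60),
#'                  x_um = c(0, 1, 2), y_um = 0, z_um = 20)
#' motility_summary(tr)
#' @export
motility_summary <- function(tracks, dims = c("x", "y", "z")) {
  tracks <- validate_tracks(tracks)
  dims <- match.arg(dims, c("x", "y", "z"), several.ok = TRUE)
  cols <- paste0(dims, "_um")
  one <- function(df) {
    if (nrow(df) < 2L) abort("Tracks must have >= 2 samples; filter first.")
    xyz <- as.matrix(df[, cols])
    steps <- sqrt(rowSums(diff(xyz)^2))
    path <- sum(steps)
    disp <- sqrt(sum((xyz[nrow(xyz), ] - xyz[1, ])^2))
    dur <- df$t_s[nrow(df)] - df$t_s[1]
    tibble(
      n_samples = nrow(df),
      duration_s = dur,
      path_length_um = path,
      speed_um_per_min = path / dur * 60,
      displacement_um = disp,
      straightness = if (path > 0) disp / path else 0
    )
  }
  tracks |>
    arrange(.data$track_id, .data$t_s) |>
    group_by(.data$track_id) |>
    dplyr::group_modify(~ one(.x)) |>
    ungroup()
}

#' Cell density per labelled tissue region
#'
#' Counts cell positions falling on each label of a region mask (e.g. stroma
#' vs tumor islet) and divides by the region area in mm^2.
#'
#' @param cell_positions Data frame with pixel-coordinate columns `x`, `y`
#'   (x along columns, y along rows, 0-based continuous coordinates: a
#'   position in `[0, ncol) x [0, nrow)`).
#' @param region_mask Integer or character matrix of region labels;
#'   `0`/`NA`/`"background"` is background.
#' @param pixel_size_mm Pixel edge, mm.
#' @param labels Optional named character vector mapping mask values to
#'   region names.
#' @return Tibble with `region_label`, `n_cells`, `region_area_mm2`,
#'   `cells_per_mm2`.
#' @export
region_density <- function(cell_positions, region_mask, pixel_size_mm,
                           labels = NULL) {
  lab <- region_mask
  if (!is.null(labels)) {
    lab <- matrix(labels[as.character(region_mask)], nrow(region_mask))
  }
  lab[is.na(lab) | lab == 0 | lab == "0" | lab == "background"] <- NA
  regions <- sort(unique(stats::na.omit(as.vector(lab))))
  if (length(regions) == 0L) abort("Mask contains no non-background region.")
  areas <- vapply(regions, function(r) sum(lab == r, na.rm = TRUE), numeric(1)) *
    pixel_size_mm^2
  if (any(areas == 0)) abort("Region with zero area in mask.")
  counts <- stats::setNames(numeric(length(regions)), regions)
  if (nrow(cell_positions) > 0L) {
    r <- floor(cell_positions$y) + 1L
    c <- floor(cell_positions$x) + 1L
    ok <- r >= 1 & r <= nrow(lab) & c >= 1 & c <= ncol(lab)
    hit <- lab[cbind(r[ok], c[ok])]
    tb <- table(hit)
    counts[names(tb)] <- as.numeric(tb)
  }
  tibble(region_label = regions,
         n_cells = as.numeric(counts),
         region_area_mm2 = as.numeric(areas),
         cells_per_mm2 = as.numeric(counts) / as.numeric(areas))
}

#' Read a track CSV
#'
#' Expects header `track_id,frame,t_s,x_um,y_um,z_um` (the `frame` column is
#' optional) with one row per detection.
#'
#' @param path CSV path.
#' @return Validated track tibble.
#' @export
read_tracks <- function(path) {
  validate_tracks(utils::read.csv(path))
}

#' Plot track trajectories in the xy plane
#'
#' @param tracks Track table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_tracks <- function(tracks, ...) {
  tracks <- validate_tracks(tracks)
  ggplot(tracks, aes(.data$x_um, .data$y_um, group = .data$track_id,
                     colour = .data$track_id)) +
    geom_path(show.legend = FALSE) +
    coord_equal() +
    labs(x = "x (µm)", y = "y (µm)") +
    theme_minimal()
}
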