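# Seeded generators with known ground truth for every pipeline stage.
# A single study seed fans out to per-object substreams (see substream_seed),
# so generating one more object never perturbs the streams of earlier ones.

#' Simulate a stiffness map with stiff patches
#'
#' Gaussian background field (clipped at 0 kPa) with circular stiff patches
#' set to `patch_kPa`, emulating the heterogeneous stiff regions seen in
#' elastography maps of desmoplastic tumors. The exact fraction of pixels
#' above 40 kPa is returned as ground truth.
#'
#' @param grid_size_px Edge of the square grid, px.
#' @param background_mean_kPa,background_sd_kPa Background field moments, kPa.
#' @param n_patches Number of stiff discs.
#' @param patch_kPa Stiffness assigned inside patches, kPa.
#' @param patch_radius_px Disc radius, px; discs must fit inside the grid.
#' @param pixel_size_mm Pixel edge, mm.
#' @param seed Integer seed.
#' @return List with `map` (a [stiffness_map()]) and `stiff_fraction_truth`
#'   (exact fraction of pixels > 40 kPa).
#' @export
gen_stiffness_map <- function(grid_size_px = 64, background_mean_kPa = 10,
                              background_sd_kPa = 3, n_patches = 3,
                              patch_kPa = 60, patch_radius_px = 6,
                              pixel_size_mm = 0.2, seed = 1) {
  if (2 * patch_radius_px + 2 > grid_size_px && n_patches > 0) {
    abort("Patch radius too large for the grid: patches would fall off-grid.")
  }
  values <- with_substream(seed, 11L, {
    v <- matrix(pmax(rnorm(grid_size_px^2, background_mean_kPa,
                           background_sd_kPa), 0),
                grid_size_px, grid_size_px)
    if (n_patches > 0) {
      lim <- c(patch_radius_px + 1, grid_size_px - patch_radius_px)
      for (i in seq_len(n_patches)) {
        cy <- runif(1, lim[1], lim[2]); cx <- runif(1, lim[1], lim[2])
        rr <- row(v) - cy; cc <- col(v) - cx
        v[rr^2 + cc^2 <= patch_radius_px^2] <- patch_kPa
      }
    }
    v
  })
  list(map = stiffness_map(values, pixel_size_mm),
       stiff_fraction_truth = mean(values > 40))
}

# distance from each pixel centre in a bounding box to a polyline, used to
# rasterise fibers of finite width
rasterize_polyline <- function(path_px, half_width_px, dim) {
  pad <- ceiling(half_width_px) + 2
  r0 <- max(1, floor(min(path_px[, 2])) - pad)
  r1 <- min(dim[1], ceiling(max(path_px[, 2])) + pad)
  c0 <- max(1, floor(min(path_px[, 1])) - pad)
  c1 <- min(dim[2], ceiling(max(path_px[, 1])) + pad)
  rows <- r0:r1; cols <- c0:c1
  gx <- rep(cols, each = length(rows))
  gy <- rep(rows, times = length(cols))
  dmin <- rep(Inf, length(gx))
  for (i in seq_len(nrow(path_px) - 1L)) {
    a <- path_px[i, ]; b <- path_px[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) rep(0, length(gx)) else {
      pmin(pmax(((gx - a[1]) * ab[1] + (gy - a[2]) * ab[2]) / len2, 0), 1)
    }
    d2 <- (gx - (a[1] + t * ab[1]))^2 + (gy - (a[2] + t * ab[2]))^2
    dmin <- pmin(dmin, d2)
  }
  hit <- dmin <= half_width_px^2
  out <- matrix(FALSE, dim[1], dim[2])
  out[cbind(gy[hit], gx[hit])] <- TRUE
  out
}

fiber_centerline <- function(length_um, angle_deg, center_um, amplitude_um,
                             wavelength_um, phase, step_um) {
  s <- seq(-length_um / 2, length_um / 2, by = step_um)
  if (s[length(s)] < length_um / 2) s <- c(s, length_um / 2)
  th <- angle_deg * pi / 180
  u <- c(cos(th), sin(th)); v <- c(-sin(th), cos(th))
  off <- if (amplitude_um > 0) {
    amplitude_um * sin(2 * pi * (s + length_um / 2) / wavelength_um + phase)
  } else {
    rep(0, length(s))
  }
  cbind(center_um[1] + s * u[1] + off * v[1],
        center_um[2] + s * u[2] + off * v[2])
}

#' Simulate an SHG-like fiber image with ground truth
#'
#' Renders `n_fibers` sinusoidal fibers of finite width as bright curvilinear
#' structures on a dark background, applies a Gaussian optical blur and
#' Poisson shot noise, and returns the exact per-fiber geometry (width,
#' centerline arc length, chord orientation, curvature ratio) as ground
#' truth. Fibers are placed by rejection sampling with a pixel-overlap cap so
#' they remain separable; an error is raised if a fiber cannot be placed
#' within `max_attempts` tries.
#'
#' Orientations are sampled around `mean_orientation_deg` with axial
#' dispersion controlled by `alignment_kappa` (concentration: larger is more
#' aligned; 0 gives uniform orientations on `[0, 180)`).
#'
#' @param n_fibers Number of fibers.
#' @param width_um_range,length_um_range Uniform sampling ranges, um.
#' @param waviness_amplitude_um,waviness_wavelength_um Sinusoidal path
#'   perturbation amplitude and wavelength, um (amplitude 0 = straight).
#' @param alignment_kappa Orientation concentration (1/sqrt(kappa) rad axial
#'   SD; 0 = uniform).
#' @param mean_orientation_deg Mean fiber axis, degrees.
#' @param image_size_px Square image edge, px.
#' @param pixel_size_um Pixel edge, um.
#' @param fiber_intensity,background_intensity Mean photon counts on fiber
#'   and background.
#' @param blur_um Gaussian optical blur sigma, um.
#' @param poisson_noise Apply Poisson shot noise.
#' @param max_overlap_frac Maximum allowed fraction of a new fiber's pixels
#'   overlapping already-placed fibers.
#' @param max_attempts Placement attempts per fiber before erroring.
#' @param seed Integer seed.
#' @return List with `image` (an [shg_image()]) and `truth` (a [fiber_set()]
#'   of the generating geometry).
#' @export
gen_fiber_image <- function(n_fibers = 5,
                            width_um_range = c(3, 8),
                            length_um_range = c(40, 120),
                            waviness_amplitude_um = 0,
                            waviness_wavelength_um = 40,
                            alignment_kappa = 0,
                            mean_orientation_deg = 90,
                            image_size_px = 384,
                            pixel_size_um = 0.5,
                            fiber_intensity = 100,
                            background_intensity = 5,
                            blur_um = 0.5,
                            poisson_noise = TRUE,
                            max_overlap_frac = 0.1,
                            max_attempts = 1000,
                            seed = 1) {
  ext_um <- image_size_px * pixel_size_um
  need <- max(length_um_range) + max(width_um_range) + 4 * pixel_size_um
  if (n_fibers > 0 && need > ext_um) {
    abort("Image too small to hold the longest fiber; enlarge `image_size_px`.")
  }
  px <- pixel_size_um
  dims <- c(image_size_px, image_size_px)
  clean <- matrix(0, dims[1], dims[2])
  occ <- matrix(FALSE, dims[1], dims[2])
  paths <- list(); widths <- c()
  for (i in seq_len(n_fibers)) {
    placed <- with_substream(seed, 100L + i, {
      ok <- NULL
      for (att in seq_len(max_attempts)) {
        w <- runif(1, width_um_range[1], width_um_range[2])
        L <- runif(1, length_um_range[1], length_um_range[2])
        ang <- if (alignment_kappa > 0) {
          (mean_orientation_deg + rnorm(1, 0, 180 / pi / sqrt(alignment_kappa))) %% 180
        } else {
          runif(1, 0, 180)
        }
        phase <- runif(1, 0, 2 * pi)
        margin <- L / 2 + w / 2 + waviness_amplitude_um + 3 * px
        if (2 * margin >= ext_um) margin <- ext_um / 2 - px
        ctr <- runif(2, margin, ext_um - margin)
        path_um <- fiber_centerline(L, ang, ctr, waviness_amplitude_um,
                                    waviness_wavelength_um, phase,
                                    step_um = 1.5 * px)
        if (any(path_um < w / 2 + px) || any(path_um > ext_um - w / 2 - px)) next
        m <- rasterize_polyline(path_um / px, (w / 2) / px, dims)
        if (max_overlap_frac <= 0) {
          # non-overlapping mode also enforces a small clearance so fiber
          # masks never touch (no junctions after skeletonization)
          m_dil <- EBImage::imageData(EBImage::dilate(
            EBImage::Image(m * 1), EBImage::makeBrush(5, "disc"))) > 0
          if (any(m_dil & occ)) next
        } else if (sum(m & occ) > max_overlap_frac * sum(m)) {
          next
        }
        ok <- list(mask = m, path = path_um, width = w)
        break
      }
      ok
    })
    if (is.null(placed)) {
      abort(sprintf("Could not place fiber %d without excessive overlap in %d attempts.",
                    i, max_attempts))
    }
    occ <- occ | placed$mask
    clean[placed$mask] <- fiber_intensity
    paths[[i]] <- placed$path
    widths <- c(widths, placed$width)
  }
  signal <- clean + background_intensity
  if (blur_um / px >= 0.5) {
    signal <- EBImage::imageData(EBImage::gblur(EBImage::Image(signal),
                                                sigma = blur_um / px))
  }
  if (poisson_noise) {
    signal <- with_substream(seed, 99L, {
      matrix(rpois(length(signal), pmax(signal, 0)), dims[1], dims[2])
    })
  }
  img <- shg_image(matrix(as.numeric(signal), dims[1], dims[2]), px)
  list(image = img, truth = fiber_set(paths, width_um = widths,
                                      source_id = sprintf("sim-seed%s", seed)))
}

#' Simulate a Hertzian force-indentation curve
#'
#' Forward-models force over an even indentation grid with the spherical
#' Hertz model and adds seeded Gaussian force noise.
#'
#' @param E_Pa True Young's modulus, Pa.
#' @param n_points Number of samples.
#' @param delta_max_m Maximum indentation, m.
#' @param noise_sd_N Additive Gaussian force noise SD, N (0 = noiseless).
#' @param noise_relative If not `NULL`, multiplicative noise: each force is
#'   scaled by `1 + rnorm(0, noise_relative)` (overrides `noise_sd_N`).
#' @param spring_constant_N_per_m,bead_radius_m,poisson_ratio Probe metadata.
#' @param seed Integer seed.
#' @return A [force_curve()] with attribute `true_E_Pa`.
#' @export
gen_force_curve <- function(E_Pa, n_points = 200, delta_max_m = 1e-6,
                            noise_sd_N = 0, noise_relative = NULL,
                            spring_constant_N_per_m = 0.6,
                            bead_radius_m = 2.25e-6, poisson_ratio = 0.5,
                            seed = 1) {
  if (E_Pa < 0) abort("`E_Pa` must be >= 0.")
  delta <- seq(0, delta_max_m, length.out = n_points)
  f <- hertz_force(E_Pa, poisson_ratio, bead_radius_m, delta)
  f <- with_substream(seed, 7L, {
    if (!is.null(noise_relative)) {
      f * (1 + rnorm(n_points, 0, noise_relative))
    } else if (noise_sd_N > 0) {
      f + rnorm(n_points, 0, noise_sd_N)
    } else {
      f
    }
  })
  out <- force_curve(delta, f,
                     spring_constant_N_per_m = spring_constant_N_per_m,
                     bead_radius_m = bead_radius_m,
                     poisson_ratio = poisson_ratio)
  attr(out, "true_E_Pa") <- E_Pa
  out
}

rotate_heading <- function(h, angle) {
  # rotate unit vector h by `angle` about a random axis perpendicular to h
  rnd <- rnorm(3)
  perp <- c(h[2] * rnd[3] - h[3] * rnd[2],
            h[3] * rnd[1] - h[1] * rnd[3],
            h[1] * rnd[2] - h[2] * rnd[1])
  nrm <- sqrt(sum(perp^2))
  if (nrm < 1e-12) return(h)
  perp <- perp / nrm
  v <- h * cos(angle) + perp * sin(angle)
  v / sqrt(sum(v^2))
}

#' Simulate persistent-random-walk T-cell tracks
#'
#' 3D persistent random walk at constant step length (speed times frame
#' interval): at every frame the heading is rotated by a Gaussian turning
#' angle (SD `turning_sd_deg`) about a random perpendicular axis. Walls of
#' the arena and the imaging depth window reflect both position and heading.
#' `turning_sd_deg = 0` gives ballistic (perfectly straight) tracks.
#'
#' @param n_tracks Number of tracks.
#' @param speed_um_per_min Constant cell speed, um/min.
#' @param turning_sd_deg Per-frame turning-angle SD, degrees.
#' @param frame_interval_s Frame interval, s.
#' @param duration_min Recording duration, min.
#' @param arena_um `c(x, y)` extent of the lateral arena, um.
#' @param z_range_um Imaging depth window `c(min, max)`, um below surface.
#' @param seed Integer seed.
#' @return Track tibble (see [validate_tracks()]) with attributes
#'   `speed_um_per_min` and `turning_sd_deg` recording the generator truth.
#' @export
gen_tracks <- function(n_tracks = 50, speed_um_per_min = 3,
                       turning_sd_deg = 30, frame_interval_s = 30,
                       duration_min = 20, arena_um = c(400, 400),
                       z_range_um = c(15, 80), seed = 1) {
  n_steps <- round(duration_min * 60 / frame_interval_s)
  if (n_steps < 1L) abort("Duration must cover >= 2 frames.")
  step_len <- speed_um_per_min * frame_interval_s / 60
  lo <- c(0, 0, z_range_um[1]); hi <- c(arena_um[1], arena_um[2], z_range_um[2])
  tracks <- lapply(seq_len(n_tracks), function(i) {
    with_substream(seed, 1000L + i, {
      pos <- runif(3, lo, hi)
      h <- rnorm(3); h <- h / sqrt(sum(h^2))
      out <- matrix(NA_real_, n_steps + 1L, 3)
      out[1, ] <- pos
      for (s in seq_len(n_steps)) {
        if (turning_sd_deg > 0) {
          h <- rotate_heading(h, rnorm(1, 0, turning_sd_deg * pi / 180))
        }
        pos <- pos + step_len * h
        for (d in 1:3) { # reflective boundaries
          if (pos[d] < lo[d]) { pos[d] <- 2 * lo[d] - pos[d]; h[d] <- -h[d] }
          if (pos[d] > hi[d]) { pos[d] <- 2 * hi[d] - pos[d]; h[d] <- -h[d] }
          pos[d] <- min(max(pos[d], lo[d]), hi[d])
        }
        out[s + 1L, ] <- pos
      }
      tibble(track_id = sprintf("t%04d", i),
             t_s = (0:n_steps) * frame_interval_s,
             x_um = out[, 1], y_um = out[, 2], z_um = out[, 3])
    })
  })
  out <- list_rbind(tracks)
  attr(out, "speed_um_per_min") <- speed_um_per_min
  attr(out, "turning_sd_deg") <- turning_sd_deg
  attr(out, "frame_interval_s") <- frame_interval_s
  out
}
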