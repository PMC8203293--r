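test_that("every generator is bit-reproducible under a fixed seed", {
  a <- gen_stiffness_map(seed = 5); b <- gen_stiffness_map(seed = 5)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  fa <- gen_fiber_image(n_fibers = 2, image_size_px = 160,
                        length_um_range = c(25, 40), seed = 5)
  fb <- gen_fiber_image(n_fibers = 2, image_size_px = 160,
                        length_um_range = c(25, 40), seed = 5)
  expect_identical(serialize(fa, NULL), serialize(fb, NULL))
  ca <- gen_force_curve(2000, noise_sd_N = 1e-10, seed = 5)
  cb <- gen_force_curve(2000, noise_sd_N = 1e-10, seed = 5)
  expect_identical(ca$force_N, cb$force_N)
  ta <- gen_tracks(n_tracks = 4, seed = 5); tb <- gen_tracks(n_tracks = 4, seed = 5)
  expect_identical(ta, tb)
  # different seeds differ
  expect_false(identical(gen_stiffness_map(seed = 6)$map$values, a$map$values))
})

test_that("stiffness generator reports an exact ground-truth stiff fraction", {
  soft <- gen_stiffness_map(n_patches = 0, background_mean_kPa = 10,
                            background_sd_kPa = 0, seed = 1)
  expect_equal(soft$stiff_fraction_truth, 0)
  one <- gen_stiffness_map(n_patches = 1, background_mean_kPa = 10,
                           background_sd_kPa = 0, patch_kPa = 60,
                           patch_radius_px = 10, grid_size_px = 64, seed = 2)
  # the disc is the only stiff structure: truth matches the rasterised disc
  expect_equal(one$stiff_fraction_truth, mean(one$map$values == 60))
  expect_equal(one$stiff_fraction_truth, pi * 10^2 / 64^2, tolerance = 0.05)
  # and the quantification layer recovers it exactly
  expect_equal(stiff_area_fraction(one$map, 40), one$stiff_fraction_truth)
  expect_error(gen_stiffness_map(grid_size_px = 16, patch_radius_px = 10),
               "off-grid")
})

test_that("fiber renders carry exact geometric ground truth", {
  empty <- gen_fiber_image(n_fibers = 0, image_size_px = 128, seed = 3)
  expect_equal(nrow(empty$truth), 0)
  expect_true(all(empty$image$intensity >= 0))

  straight <- gen_fiber_image(n_fibers = 3, waviness_amplitude_um = 0,
                              image_size_px = 288, length_um_range = c(40, 80),
                              seed = 4)
  expect_true(all(abs(straight$truth$curvature_ratio - 1) < 1e-9))

  wavy <- gen_fiber_image(n_fibers = 3, waviness_amplitude_um = 4,
                          waviness_wavelength_um = 40, image_size_px = 288,
                          length_um_range = c(40, 80), seed = 4)
  expect_true(all(wavy$truth$curvature_ratio > 1.01))
})

test_that("ground-truth curvature matches numerical quadrature of the sinusoid", {
  a <- 3; lam <- 40
  g <- gen_fiber_image(n_fibers = 1, waviness_amplitude_um = a,
                       waviness_wavelength_um = lam, image_size_px = 288,
                       length_um_range = c(60, 60), width_um_range = c(4, 4),
                       seed = 7)
  p <- g$truth$path[[1]]
  # independent quadrature for the arc length of the generating sinusoid
  L <- 60
  # recover the phase from the rendered path offsets is unnecessary: the arc
  # length is phase-independent only over whole periods, so integrate the
  # actual offset series instead via fine re-sampling of the stated model
  arc_poly <- oracle_arc_chord(p)["arc"]
  f <- function(s, phase) sqrt(1 + (a * 2 * pi / lam * cos(2 * pi * s / lam + phase))^2)
  # find the phase that reproduces the polyline arc length
  phases <- seq(0, 2 * pi, length.out = 721)
  arcs <- vapply(phases, function(ph) stats::integrate(f, 0, L, phase = ph,
                                                       rel.tol = 1e-10)$value,
                 numeric(1))
  expect_lt(min(abs(arcs - arc_poly)) / arc_poly, 2e-3)
  expect_gte(g$truth$curvature_ratio[1], 1)
})

test_that("ground-truth curvature increases with waviness amplitude", {
  crs <- vapply(c(0, 1.5, 3, 4.5), function(a) {
    g <- gen_fiber_image(n_fibers = 3, waviness_amplitude_um = a,
                         waviness_wavelength_um = 40, image_size_px = 288,
                         length_um_range = c(50, 70), seed = 8)
    mean(g$truth$curvature_ratio)
  }, numeric(1))
  expect_true(all(diff(crs) > 0))
})

test_that("force-curve generator follows the forward model", {
  cv <- gen_force_curve(2500, noise_sd_N = 0, seed = 1)
  expect_equal(cv$force_N,
               hertz_force(2500, 0.5, 2.25e-6, cv$indentation_m))
  z <- gen_force_curve(0, noise_sd_N = 0, seed = 1)
  expect_true(all(z$force_N == 0))
  # noisy curve: residual SD within 15% of nominal at n = 200
  sdn <- 2e-10
  noisy <- gen_force_curve(2500, noise_sd_N = sdn, n_points = 200, seed = 2)
  resid <- noisy$force_N - cv$force_N
  expect_lt(abs(sd(resid) - sdn) / sdn, 0.15)
})

test_that("track generator spans the ballistic-to-diffusive range", {
  # ballistic limit, arena wide enough that no wall is met
  straight <- gen_tracks(n_tracks = 10, turning_sd_deg = 0,
                         arena_um = c(5000, 5000), z_range_um = c(15, 5000),
                         seed = 9)
  ms <- motility_summary(straight)
  expect_equal(ms$straightness, rep(1, 10), tolerance = 1e-9)
  expect_equal(ms$speed_um_per_min, rep(3, 10), tolerance = 1e-9)

  # near-uniform turning: strongly tortuous tracks
  diffuse <- gen_tracks(n_tracks = 500, turning_sd_deg = 180, seed = 10)
  md <- motility_summary(diffuse)
  expect_lt(mean(md$straightness), 0.35)

  # constant step length means the estimated speed matches the setting exactly
  prw <- gen_tracks(n_tracks = 200, speed_um_per_min = 3.2,
                    turning_sd_deg = 40, seed = 11)
  expect_lt(abs(mean(motility_summary(prw)$speed_um_per_min) - 3.2) / 3.2, 0.05)
})

test_that("generated objects satisfy their consumers' contracts", {
  sm <- gen_stiffness_map(seed = 12)
  expect_s3_class(compute_roi_summary(sm$map), "tbl_df")
  tr <- gen_tracks(n_tracks = 5, seed = 12)
  expect_s3_class(motility_summary(depth_filter(tr)), "tbl_df")
  cv <- gen_force_curve(1000, seed = 12)
  expect_gte(as.numeric(fit_young_modulus(cv)), 0)
  fi <- gen_fiber_image(n_fibers = 2, image_size_px = 192,
                        length_um_range = c(30, 50), seed = 12)
  expect_s3_class(trace_fibers(fi$image), "fiber_set")
})

test_that("infeasible fiber packing raises a placement error", {
  expect_error(
    gen_fiber_image(n_fibers = 60, image_size_px = 150,
                    length_um_range = c(40, 50), width_um_range = c(6, 8),
                    max_overlap_frac = 0, max_attempts = 30, seed = 13),
    "place"
  )
})
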