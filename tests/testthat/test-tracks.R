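straight_track <- function(id = "a") {
  data.frame(track_id = id, t_s = c(0, 30, 60),
             x_um = c(0, 1, 2), y_um = 0, z_um = 20)
}

test_that("depth filtering removes superficial samples and stub tracks", {
  shallow <- data.frame(track_id = "s", t_s = c(0, 30), x_um = 0, y_um = 0,
                        z_um = 10)
  deep <- straight_track("d")
  out <- depth_filter(rbind(shallow, deep), 15)
  expect_equal(unique(out$track_id), "d")
  expect_equal(nrow(out), 3)
  # boundary: a sample at exactly the cut depth is removed
  edge <- data.frame(track_id = "e", t_s = c(0, 30, 60), x_um = 0, y_um = 0,
                     z_um = c(15, 20, 20))
  expect_equal(nrow(depth_filter(edge, 15)), 2)

  set.seed(51)
  mixed <- do.call(rbind, lapply(1:20, function(i) {
    n <- sample(3:10, 1)
    data.frame(track_id = sprintf("t%02d", i), t_s = (0:(n - 1)) * 30,
               x_um = rnorm(n), y_um = rnorm(n), z_um = runif(n, 5, 40))
  }))
  out2 <- depth_filter(mixed, 15)
  # brute-force expectation
  kept <- 0L
  for (id in unique(mixed$track_id)) {
    df <- mixed[mixed$track_id == id, ]
    nk <- sum(df$z_um > 15)
    if (nk >= 2) kept <- kept + nk
  }
  expect_equal(nrow(out2), kept)
})

test_that("duration filter keeps tracks strictly above the fraction", {
  rec <- 20 * 60
  mk <- function(id, dur_s) data.frame(track_id = id, t_s = seq(0, dur_s, by = 30),
                                       x_um = 0, y_um = 0, z_um = 20)
  short <- mk("one_min", 60)
  ok <- mk("three_min", 180)
  boundary <- mk("two_min", 120)          # exactly 10% of 20 min
  plus_one <- mk("two_min_plus", 150)     # one frame beyond 10%
  out <- duration_filter(rbind(short, ok, boundary, plus_one), rec, 0.1)
  expect_setequal(unique(out$track_id), c("three_min", "two_min_plus"))
})

test_that("motility statistics match their definitions", {
  m <- motility_summary(straight_track())
  expect_equal(m$speed_um_per_min, 2)
  expect_equal(m$displacement_um, 2)
  expect_equal(m$straightness, 1)
  expect_equal(m$duration_s, 60)

  loop <- data.frame(track_id = "l", t_s = c(0, 30, 60, 90),
                     x_um = c(0, 1, 1, 0), y_um = c(0, 0, 1, 0), z_um = 20)
  ml <- motility_summary(loop)
  expect_equal(ml$displacement_um, 0)
  expect_equal(ml$straightness, 0)

  set.seed(52)
  xyz <- apply(matrix(rnorm(41 * 3), 41, 3), 2, cumsum)
  walk <- data.frame(track_id = "w", t_s = (0:40) * 30, x_um = xyz[, 1],
                     y_um = xyz[, 2], z_um = xyz[, 3] + 50)
  mw <- motility_summary(walk)
  o <- oracle_motility(walk$t_s, xyz)
  expect_equal(mw$speed_um_per_min, o$speed, tolerance = 1e-12)
  expect_equal(mw$displacement_um, o$displacement, tolerance = 1e-12)
  expect_equal(mw$straightness, o$straightness, tolerance = 1e-12)
  expect_error(motility_summary(data.frame(track_id = "x", t_s = c(0, 0),
                                           x_um = 1:2, y_um = 0, z_um = 0)))
})

test_that("motility statistics are rigid-motion invariant and bounded", {
  set.seed(53)
  for (i in 1:10) {
    xyz <- apply(matrix(rnorm(20 * 3), 20, 3), 2, cumsum)
    tr <- data.frame(track_id = "a", t_s = (0:19) * 30, x_um = xyz[, 1],
                     y_um = xyz[, 2], z_um = xyz[, 3])
    m <- motility_summary(tr)
    expect_gte(m$straightness, 0)
    expect_lte(m$straightness, 1)
    expect_lte(m$displacement_um, m$path_length_um + 1e-12)
    th <- runif(1, 0, 2 * pi)
    Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    rot <- xyz %*% Rz
    tr2 <- data.frame(track_id = "a", t_s = tr$t_s, x_um = rot[, 1] + 5,
                      y_um = rot[, 2] - 3, z_um = rot[, 3] + 11)
    m2 <- motility_summary(tr2)
    expect_equal(m2$speed_um_per_min, m$speed_um_per_min, tolerance = 1e-9)
    expect_equal(m2$displacement_um, m$displacement_um, tolerance = 1e-9)
  }
})

test_that("2D projection mode drops the z contribution", {
  tr <- data.frame(track_id = "a", t_s = c(0, 30), x_um = c(0, 3),
                   y_um = c(0, 4), z_um = c(0, 12))
  expect_equal(motility_summary(tr)$displacement_um, 13)
  expect_equal(motility_summary(tr, dims = c("x", "y"))$displacement_um, 5)
})

test_that("region densities divide label counts by label areas", {
  mask <- matrix("background", 10, 10)
  mask[1:5, 1:10] <- "stroma"        # 50 px
  mask[6:10, 1:5] <- "tumor_islet"   # 25 px
  px_mm <- sqrt(0.001)               # 0.001 mm2 per px -> stroma 0.05 mm2
  cells <- data.frame(x = c(0.5, 2.5, 4.5, 6.5, 8.5), y = rep(2.5, 5)) # stroma
  out <- region_density(cells, mask, px_mm)
  expect_equal(out$cells_per_mm2[out$region_label == "stroma"], 100)
  expect_equal(out$n_cells[out$region_label == "tumor_islet"], 0)
  expect_equal(out$region_area_mm2, c(0.05, 0.025))

  set.seed(54)
  pts <- data.frame(x = runif(200, 0, 10), y = runif(200, 0, 10))
  out2 <- region_density(pts, mask, px_mm)
  counts <- c(stroma = 0, tumor_islet = 0)
  for (i in 1:200) {
    lab <- mask[floor(pts$y[i]) + 1, floor(pts$x[i]) + 1]
    if (lab != "background") counts[lab] <- counts[lab] + 1
  }
  expect_equal(out2$n_cells, as.numeric(counts))
  expect_error(region_density(cells, matrix("background", 4, 4), 0.01),
               "no non-background")
})

test_that("track CSV ingestion validates ordering", {
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(straight_track(), csv, row.names = FALSE)
  tr <- read_tracks(csv)
  expect_equal(nrow(tr), 3)
  bad <- straight_track(); bad$t_s <- c(0, 30, 30)
  utils::write.csv(bad, csv, row.names = FALSE)
  expect_error(read_tracks(csv), "timestamps")
})
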