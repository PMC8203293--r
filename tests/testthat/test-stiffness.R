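test_that("ROI summary matches direct counts on small maps", {
  m <- stiffness_map(matrix(c(50, 10, 10, 10), 2, 2), pixel_size_mm = 0.1)
  s <- compute_roi_summary(m, threshold_kPa = 40)
  expect_equal(s$stiff_fraction, 0.25)
  expect_equal(s$mean_kPa, 20)
  expect_equal(s$min_kPa, 10)
  expect_equal(s$max_kPa, 50)
  expect_equal(s$sd_kPa, sd(c(50, 10, 10, 10)))
  expect_equal(s$area_mm2, 4 * 0.1^2)
  expect_equal(s$dropout_fraction, 0)
})

test_that("pixels at exactly the threshold are not stiff (strict inequality)", {
  m <- stiffness_map(matrix(40, 8, 8), pixel_size_mm = 0.1)
  expect_equal(stiff_area_fraction(m, 40), 0)
  expect_equal(stiff_area_fraction(stiffness_map(matrix(0, 4, 4), 0.1)), 0)
  expect_equal(stiff_area_fraction(stiffness_map(matrix(41, 4, 4), 0.1)), 1)
})

test_that("stiff fraction equals a brute-force per-pixel count on random maps", {
  set.seed(41)
  for (i in 1:5) {
    v <- matrix(runif(64 * 64, 0, 80), 64, 64)
    roi <- matrix(runif(64 * 64) < 0.7, 64, 64)
    if (!any(roi)) roi[1, 1] <- TRUE
    m <- stiffness_map(v, 0.15, roi = roi)
    expect_equal(stiff_area_fraction(m, 40),
                 oracle_stiff_fraction(v, roi, 40), tolerance = 1e-12)
  }
})

test_that("stiff fraction is monotone non-increasing in the threshold", {
  set.seed(7)
  m <- stiffness_map(matrix(runif(900, 0, 80), 30, 30), 0.1)
  fr <- vapply(seq(5, 75, by = 5), function(th) stiff_area_fraction(m, th),
               numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("summary ignores pixels outside the ROI", {
  set.seed(8)
  v <- matrix(runif(400, 0, 50), 20, 20)
  roi <- matrix(FALSE, 20, 20); roi[5:15, 5:15] <- TRUE
  base <- compute_roi_summary(stiffness_map(v, 0.1, roi), 40)
  for (i in 1:10) {
    v2 <- v
    v2[!roi] <- runif(sum(!roi), -100, 1000)
    fuzz <- compute_roi_summary(stiffness_map(v2, 0.1, roi), 40)
    expect_equal(fuzz, base)
  }
})

test_that("in-ROI dropouts (NaN or negative) are excluded and reported", {
  v <- matrix(10, 4, 4)
  v[1, 1] <- NaN; v[2, 2] <- -1; v[3, 3] <- 50
  s <- compute_roi_summary(stiffness_map(v, 0.1), 40)
  expect_equal(s$dropout_fraction, 2 / 16)
  expect_equal(s$n_pixels, 14)
  expect_equal(s$stiff_fraction, 1 / 14)
  expect_equal(s$mean_kPa, mean(c(rep(10, 13), 50)))
  # all-dropout ROI is an error naming the pixel count
  roi <- matrix(FALSE, 4, 4); roi[1, 1] <- TRUE; roi[2, 2] <- TRUE
  expect_error(compute_roi_summary(stiffness_map(v, 0.1, roi)), "2 in-ROI")
})

test_that("degenerate stiffness inputs are rejected", {
  expect_error(stiffness_map(matrix(1, 2, 2), 0.1, roi = matrix(FALSE, 2, 2)),
               "empty")
  expect_error(compute_roi_summary(stiffness_map(matrix(1, 2, 2), 0.1), -5),
               "positive")
  expect_error(stiffness_map(matrix(1, 2, 2), 0))
})

test_that("normalized stiffness divides by the baseline timepoint", {
  out <- normalized_stiffness(
    data.frame(timepoint = c(0, 3, 6), mean_kPa = c(10, 20, 15)))
  expect_equal(out$ratio, c(1, 2, 1.5))
  expect_equal(normalized_stiffness(data.frame(timepoint = 0, mean_kPa = 5))$ratio, 1)
  set.seed(9)
  ser <- data.frame(timepoint = 1:10, mean_kPa = runif(10, 5, 40))
  expect_equal(normalized_stiffness(ser)$ratio, ser$mean_kPa / ser$mean_kPa[1])
  expect_error(normalized_stiffness(
    data.frame(timepoint = c(3, 0), mean_kPa = c(1, 2))), "increasing")
  expect_error(normalized_stiffness(
    data.frame(timepoint = c(0, 3), mean_kPa = c(0, 2))), "positive")
})

test_that("caliper volume follows x*y^2/2 and its ordering rules", {
  expect_equal(caliper_volume(10, 5), 125)
  expect_equal(caliper_volume(2, 2), 4)
  expect_equal(caliper_volume(7.3, 4.1), 7.3 * 4.1^2 / 2)
  expect_error(caliper_volume(4, 7), "swap")
  expect_error(caliper_volume(-1, -2), "positive")
  # strictly increasing in each argument
  set.seed(10)
  x <- runif(50, 5, 10); y <- runif(50, 1, 5)
  expect_true(all(caliper_volume(x + 0.5, y) > caliper_volume(x, y)))
  expect_true(all(caliper_volume(x, y + 0.5) > caliper_volume(x, y)))
})

test_that("polygon ROIs rasterise by pixel-centre membership", {
  # rectangle covering pixel centres (cols 3..6) x (rows 2..4)
  poly <- cbind(c(2, 6, 6, 2), c(1, 1, 4, 4))
  roi <- roi_from_polygon(poly, c(6, 8))
  expect_equal(sum(roi), 4 * 3)
  expect_true(all(roi[2:4, 3:6]))
  # triangle area approximately recovered on a fine grid
  tri <- cbind(c(0, 40, 0), c(0, 0, 40))
  roi2 <- roi_from_polygon(tri, c(40, 40))
  expect_equal(sum(roi2), 0.5 * 40 * 40, tolerance = 0.03)
})

test_that("stiffness maps round-trip through TIFF and CSV with ROI sidecars", {
  set.seed(11)
  v <- matrix(round(runif(256, 0, 60), 3), 16, 16)
  tmp <- withr::local_tempfile(fileext = ".tif")
  write_stiffness_map(stiffness_map(v, 0.1), tmp)
  m2 <- read_stiffness_map(tmp, 0.1, tiff_max_kPa = 200)
  expect_equal(m2$values, v, tolerance = 2e-4) # 16-bit quantisation
  expect_equal(stiff_area_fraction(m2, 40), stiff_area_fraction(stiffness_map(v, 0.1), 40))

  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(v, csv, sep = ",", row.names = FALSE, col.names = FALSE)
  m3 <- read_stiffness_map(csv, 0.1)
  expect_equal(unname(as.matrix(m3$values)), v, ignore_attr = TRUE)

  roi_json <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(polygon = cbind(c(2, 10, 10, 2), c(2, 2, 10, 10)))),
             roi_json)
  m4 <- read_stiffness_map(csv, 0.1, roi = roi_json)
  expect_equal(sum(m4$roi), 8 * 8)
})
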