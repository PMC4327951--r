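test_that("back_scan enforces its grid invariants", {
  p <- plate_scan()
  expect_s3_class(p, "back_scan")
  expect_identical(dim(p), c(6L, 7L))

  # grids smaller than 3 x 3
  expect_error(plate_scan(nr = 2), "at least 3 x 3")

  # profiles must be ordered along the translation direction
  bad_x <- matrix(c(0, 2, 1), 3, 3)
  expect_error(
    back_scan(bad_x, matrix(1:3, 3, 3, byrow = TRUE), matrix(0, 3, 3)),
    "monotonic"
  )

  # brightness outside [0, 1] on valid cells
  expect_error(
    back_scan(matrix(1:3, 3, 3), matrix(1:3, 3, 3, byrow = TRUE),
      matrix(0, 3, 3),
      brightness = matrix(2, 3, 3)
    ),
    "brightness"
  )

  # long-tibble round trip preserves everything
  tb <- as_tibble(p)
  expect_named(tb, c("v", "u", "x", "y", "z", "brightness", "valid"))
  expect_scan_equal(as_back_scan(tb, profile_spacing_mm = p$profile_spacing_mm), p)
})

test_that("scans round-trip through every on-disk format", {
  sim <- generate_scan(small_spec(seed = 11, n_rows = 12, n_cols = 10))
  scan <- sim$scan
  scan$valid[3, 4:6] <- FALSE # dropouts must survive the trip

  for (fmt in list(
    list(format = "ply", ply_encoding = "ascii"),
    list(format = "ply", ply_encoding = "binary"),
    list(format = "grid-text")
  )) {
    path <- tempfile(fileext = if (fmt$format == "ply") ".ply" else ".txt")
    do.call(write_scan, c(list(scan, path), fmt))
    back <- read_scan(path)
    expect_scan_equal(back, scan, tol = 1e-6)
    expect_equal(back$profile_spacing_mm, scan$profile_spacing_mm, tolerance = 1e-9)
    unlink(path)
  }
})

test_that("loader failures are distinct and descriptive", {
  expect_error(read_scan(file.path(tempdir(), "nope.ply")), "not found")
  expect_error(write_scan(plate_scan(), tempfile(), format = "xyz"), "unsupported")

  # header declaring more points than the file carries
  p <- tempfile(fileext = ".txt")
  write_scan(plate_scan(5, 5), p, format = "grid-text")
  lines <- readLines(p)
  writeLines(c("spinescan-grid 10 10", lines[-1]), p)
  expect_error(read_scan(p), "100 points.*25 data lines")

  # non-monotonic profile ordering is rejected at load
  write_scan(plate_scan(5, 5), p, format = "grid-text")
  lines <- readLines(p)
  body <- lines[-(1:2)]
  swapped <- c(body[6:10], body[1:5], body[11:25]) # swap profiles 1 and 2
  writeLines(c(lines[1:2], swapped), p)
  expect_error(read_scan(p), "monotonic")
  unlink(p)
})

test_that("integer-scale brightness is min-max normalised at load", {
  p <- tempfile(fileext = ".txt")
  scan <- plate_scan(4, 4)
  write_scan(scan, p, format = "grid-text")
  lines <- readLines(p)
  body <- do.call(rbind, lapply(strsplit(lines[-(1:2)], " "), as.numeric))
  body[, 4] <- seq(0, 255, length.out = nrow(body)) # 8-bit style brightness
  writeLines(
    c(lines[1:2], apply(body, 1, function(r) {
      paste(paste(sprintf("%.9f", r[1:4]), collapse = " "), r[5])
    })),
    p
  )
  back <- read_scan(p)
  b <- back$brightness[back$valid]
  expect_gte(min(b), 0)
  expect_equal(max(b), 1.0)
  expect_equal(min(b), 0)
  unlink(p)
})

test_that("crop_roi crops indices but never coordinates", {
  sim <- generate_scan(small_spec(seed = 3, n_rows = 100, n_cols = 40))
  scan <- sim$scan

  expect_scan_equal(crop_roi(scan, full_roi(scan)), scan, tol = 0)

  roi <- scan_roi(10, 20, 1, 40)
  cropped <- crop_roi(scan, roi)
  expect_identical(dim(cropped), c(11L, 40L))
  expect_identical(cropped$x, scan$x[10:20, ])

  # nested crops equal the single intersection crop
  c1 <- crop_roi(crop_roi(scan, scan_roi(5, 60, 3, 35)), scan_roi(6, 40, 2, 30))
  c2 <- crop_roi(scan, scan_roi(10, 44, 4, 32))
  expect_scan_equal(c1, c2, tol = 0)

  expect_error(scan_roi(20, 10, 1, 5), "v_min")
  expect_error(crop_roi(scan, scan_roi(1, 200, 1, 10)), "exceeds")
  expect_error(crop_roi(scan, scan_roi(1, 2, 1, 40)), "smaller than 3 x 3")
})

test_that("rotation about X is rigid, invertible and preserves radii", {
  sim <- generate_scan(small_spec(seed = 5, noise_sd_mm = 0))
  scan <- sim$scan

  expect_scan_equal(rotate_about_x(scan, 0), scan, tol = 0)

  # pure rotation of a point: (Y, Z) = (10, 0) by 90 degrees -> (0, 10)
  r <- spinescan:::rotate_yz(10, 0, 90)
  expect_equal(r$y, 0, tolerance = 1e-12)
  expect_equal(r$z, 10, tolerance = 1e-12)

  # distance to the X axis is invariant before regridding
  set.seed(42)
  y <- runif(50, -100, 100)
  z <- runif(50, 0, 60)
  rr <- spinescan:::rotate_yz(y, z, 37.3)
  expect_lt(max(abs(sqrt(rr$y^2 + rr$z^2) - sqrt(y^2 + z^2))), 1e-9)

  # rotate forth and back: Z(Y) recovered up to resampling error
  back <- rotate_about_x(rotate_about_x(scan, 5), -5)
  both <- scan$valid & back$valid
  expect_gt(mean(both), 0.9)
  expect_lt(sqrt(mean((back$z[both] - scan$z[both])^2)), 0.05)
})
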