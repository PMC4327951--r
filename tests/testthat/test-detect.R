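test_that("sub-pixel refinement returns the quadratic's vertex", {
  # symmetric peak refines to the middle sample
  expect_equal(subpixel_extremum(c(1, 3, 1), 0:2)$position, 1.0, tolerance = 1e-12)

  # closed form: the parabola through (0,1), (1,3), (2,2) peaks at 7/6
  r <- subpixel_extremum(c(1, 3, 2), 0:2)
  expect_equal(r$position, 7 / 6, tolerance = 1e-9)
  expect_equal(r$value, 73 / 24, tolerance = 1e-9)
  expect_true(r$refined)

  # minima work symmetrically
  expect_equal(
    subpixel_extremum(c(3, 1, 2), 0:2, mode = "min")$position,
    subpixel_extremum(c(-3, -1, -2), 0:2, mode = "max")$position
  )

  expect_error(subpixel_extremum(c(2, 2, 2), 0:2), "no extremum")
  expect_error(subpixel_extremum(c(1, 3, 1), c(0, 0, 1)), "strictly increasing")
  expect_error(subpixel_extremum(c(1, 3, 1), 0:2, window = 4), "odd")
})

test_that("sub-pixel positions match a brute-force optimiser on random windows", {
  set.seed(123)
  for (i in 1:200) {
    pos <- sort(runif(5, 0, 10))
    a <- -runif(1, 0.2, 2)
    vtx <- runif(1, pos[2], pos[4])
    vals <- a * (pos - vtx)^2 + rnorm(5, sd = 0.01 * abs(a))
    if (which.max(vals) != 3) next # both routes must fit the same 5 points
    r <- subpixel_extremum(vals, pos, window = 5)
    if (!r$refined) next
    # independent route: explicit quadratic LS fit + 1-D optimiser
    fit <- stats::lm(vals ~ pos + I(pos^2))
    oracle <- stats::optimize(
      function(p) sum(coef(fit) * c(1, p, p^2)),
      range(pos),
      maximum = TRUE, tol = 1e-10
    )$maximum
    expect_equal(r$position, oracle, tolerance = 1e-6)
  }
})

test_that("row detection finds every extremum of the requested polarity", {
  spec <- small_spec(seed = 8, noise_sd_mm = 0)
  sim <- generate_scan(spec)
  km <- curvature_map(sim$scan)
  dets <- detect_rows(km, mode = "curvature-max", threshold = 0)
  per_row <- table(dets$v)
  interior <- as.integer(names(per_row))
  expect_true(all(per_row == 1)) # a single furrow: one ridge per row
  expect_gt(length(interior), spec$n_rows - 10)

  # two synthetic ridges 30 columns apart -> two detections per row
  two <- matrix(0, 10, 80)
  u <- seq_len(80)
  for (v in 1:10) two[v, ] <- exp(-(u - 25)^2 / 8) + exp(-(u - 55)^2 / 8)
  d2 <- detect_rows(two, mode = "curvature-max", threshold = 0)
  expect_true(all(table(d2$v) == 2))

  # intensity minima above the cut are rejected
  bright <- matrix(0.5 + 0.1 * sin(seq_len(40)), 5, 40, byrow = TRUE)
  expect_identical(
    nrow(detect_rows(bright, mode = "intensity-min", threshold = 0.10)), 0L
  )
  # ... and accepted once below it
  bright[, 20] <- 0.05
  d3 <- detect_rows(bright, mode = "intensity-min", threshold = 0.10)
  expect_identical(nrow(d3), 5L)
  expect_true(all(abs(d3$u - 20) <= 1))
})

test_that("greedy linking chains, bridges gaps and splits distant tracks", {
  # one drifting detection per row joins into a single candidate
  drift <- tibble::tibble(
    v = 1:50, u = 10 + 0.5 * (1:50), strength = 1, refined = TRUE
  )
  cands <- link_candidates(drift, min_length = 20)
  expect_identical(nrow(cands), 1L)
  expect_identical(cands$n_rows[1], 50L)

  # two parallel tracks 30 columns apart can never associate
  two <- dplyr::bind_rows(drift, dplyr::mutate(drift, u = u + 30))
  cands <- link_candidates(dplyr::arrange(two, v, u), min_length = 20)
  expect_identical(nrow(cands), 2L)
  expect_true(all(cands$n_rows == 50L))

  # a 4-row dropout inside a 100-row track is bridged and flagged
  gappy <- tibble::tibble(
    v = setdiff(1:100, 41:44), u = 15, strength = 1, refined = TRUE
  )
  cands <- link_candidates(gappy, max_gap = 5, min_length = 20)
  expect_identical(nrow(cands), 1L)
  curve <- cands$curve[[1]]
  expect_identical(curve$v, 1:100) # continuous
  expect_identical(which(curve$interpolated), 41:44)
  expect_equal(curve$u, rep(15, 100))

  # ... but a gap beyond max_gap splits the track
  cands <- link_candidates(gappy, max_gap = 3, min_length = 20)
  expect_identical(nrow(cands), 2L)

  expect_identical(nrow(link_candidates(drift[0, ])), 0L)
})

test_that("seed-point selection picks the nearest candidate, ties by length", {
  mk <- function(u, v) {
    tibble::tibble(v = v, u = u, strength = 1, refined = TRUE)
  }
  cands <- link_candidates(
    dplyr::arrange(dplyr::bind_rows(mk(10, 1:100), mk(50, 1:40)), v, u),
    min_length = 20
  )
  expect_identical(nrow(cands), 2L)
  expect_equal(mean(select_curve(cands, c(15, 50))$u), 10)
  expect_equal(mean(select_curve(cands, c(49, 20))$u), 50)
  # equidistant seed: the 100-row candidate wins
  expect_equal(mean(select_curve(cands, c(30, 20))$u), 10)
  expect_error(select_curve(cands[0, ], c(1, 1)), "empty")
})

test_that("the marker line is recovered to sub-sample accuracy", {
  for (contrast in c(0.9, 0.95)) {
    spec <- small_spec(seed = 13, marker_contrast = contrast)
    sim <- generate_scan(spec)
    curve <- detect_manual(sim$scan, intensity_threshold = 0.10)
    lifted <- lift_curve(sim$scan, curve)
    expect_identical(attr(lifted, "provenance"), "manual")
    cmp <- compare_curves(sim$truth$marker, lifted)
    expect_lt(cmp$rmsd_frontal_mm, 0.3)
  }

  # a faint marker leaves nothing below the cut
  faint <- generate_scan(small_spec(seed = 13, marker_contrast = 0.05))
  expect_error(
    detect_manual(faint$scan, intensity_threshold = 0.10),
    "no marker line"
  )
})

test_that("manual detection interpolates across a contrast gap", {
  spec <- small_spec(seed = 14, noise_sd_mm = 0)
  sim <- generate_scan(spec)
  gap <- 70:79
  sim$scan$brightness[gap, ] <- 1 # marker wiped over 10 rows
  curve <- detect_manual(sim$scan)
  expect_identical(curve$v, min(curve$v):max(curve$v))
  covered <- curve$v %in% gap
  expect_true(any(covered))
  expect_true(all(curve$interpolated[curve$v %in% 72:77]))
  # interpolated positions still track the marker (smooth centerline)
  lifted <- lift_curve(sim$scan, curve)
  cmp <- compare_curves(sim$truth$marker, lifted)
  expect_lt(cmp$rmsd_frontal_mm, 0.3)
})

test_that("manual recovery degrades monotonically with depth noise", {
  for (seed in 1:3) {
    err <- vapply(c(0, 0.1, 0.3), function(ns) {
      sim <- generate_scan(small_spec(seed = seed, noise_sd_mm = ns))
      lifted <- lift_curve(sim$scan, detect_manual(sim$scan))
      d <- tidy(compare_curves(sim$truth$marker, lifted))
      sqrt(mean(d$dy^2 + d$dz^2))
    }, numeric(1))
    expect_true(all(diff(err) > 0))
  }
})

test_that("automatic detection is deterministic and tracks the furrow", {
  spec <- small_spec(seed = 15, noise_sd_mm = 0)
  sim <- generate_scan(spec)
  cands <- detect_auto(sim$scan)
  expect_identical(cands, detect_auto(sim$scan))
  mid <- round(spec$n_rows / 2)
  uc <- (spec$n_cols + 1) / 2
  sel <- select_curve(cands, c(uc + sim$truth$spine$y[mid], mid))
  lifted <- lift_curve(sim$scan, sel)
  cmp <- compare_curves(sim$truth$spine, lifted)
  expect_lt(cmp$rmsd_frontal_mm, 0.5)

  # a flat plate has no concave ridge at all
  plate <- generate_scan(small_spec(
    seed = 1, torso_depth_mm = 0, furrow_depth_mm = 0,
    noise_sd_mm = 0, sagittal_profile = c(0)
  ))$scan
  expect_identical(nrow(detect_auto(plate)), 0L)
})

test_that("shoulder-blade relief spawns extra candidates without stealing the furrow", {
  spec <- small_spec(
    seed = 16, noise_sd_mm = 0,
    n_cols = 240, blade_height_mm = 10, blade_halfwidth_mm = 18,
    blade_offset_mm = 60
  )
  sim <- generate_scan(spec)
  cands <- detect_auto(sim$scan)
  expect_gte(nrow(cands), 3L)
  mid <- round(spec$n_rows / 2)
  uc <- (spec$n_cols + 1) / 2
  sel <- select_curve(cands, c(uc + sim$truth$spine$y[mid], mid))
  lifted <- lift_curve(sim$scan, sel)
  expect_lt(compare_curves(sim$truth$spine, lifted)$rmsd_frontal_mm, 0.5)
})
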