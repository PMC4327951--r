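mk_curve <- function(x, y, z = 0 * x) spinescan:::new_curve3d(x, y, z)

test_that("common spans intersect X ranges and reject disjoint curves", {
  a <- mk_curve(seq(0, 100, 10), 0)
  b <- mk_curve(seq(20, 120, 10), 0)
  expect_equal(common_span(a, b), c(20, 100))
  expect_equal(common_span(a, a), c(0, 100))
  expect_error(
    common_span(mk_curve(0:10, 0), mk_curve(20:30, 0)),
    "disjoint"
  )
})

test_that("RMSD matches hand-computed values", {
  x <- seq(0, 90, by = 0.9)
  m <- mk_curve(x, sin(x / 20), cos(x / 30))

  ident <- compare_curves(m, m)
  expect_equal(ident$rmsd_frontal_mm, 0)
  expect_equal(ident$rmsd_sagittal_mm, 0)
  expect_identical(ident$n_rows, length(x))

  shifted <- mk_curve(x, sin(x / 20) + 2, cos(x / 30))
  cmp <- compare_curves(m, shifted)
  expect_equal(cmp$rmsd_frontal_mm, 2.0, tolerance = 1e-12)
  expect_equal(cmp$rmsd_sagittal_mm, 0)

  # the (1, 2, 2) toy: sqrt((1 + 4 + 4) / 3) = sqrt(3)
  a <- mk_curve(0:2, c(0, 0, 0))
  b <- mk_curve(0:2, c(1, 2, 2))
  expect_equal(compare_curves(a, b)$rmsd_frontal_mm, sqrt(3), tolerance = 1e-12)

  expect_error(compare_curves(a, mk_curve(10:12, 0:2)), "disjoint")
})

test_that("RMSD is symmetric, translation-invariant and bounds the mean", {
  set.seed(31)
  x <- seq(0, 50, 1)
  a <- mk_curve(x, rnorm(51), rnorm(51))
  b <- mk_curve(x, rnorm(51), rnorm(51))
  ab <- compare_curves(a, b)
  ba <- compare_curves(b, a)
  expect_equal(ab$rmsd_frontal_mm, ba$rmsd_frontal_mm, tolerance = 1e-12)

  shift <- function(cv) mk_curve(cv$x, cv$y + 7, cv$z - 3)
  cmp2 <- compare_curves(shift(a), shift(b))
  expect_equal(ab$rmsd_frontal_mm, cmp2$rmsd_frontal_mm, tolerance = 1e-12)
  expect_equal(ab$rmsd_sagittal_mm, cmp2$rmsd_sagittal_mm, tolerance = 1e-12)

  d <- tidy(ab)
  expect_gte(ab$rmsd_frontal_mm, abs(mean(d$dy)))
  # equality holds iff the difference is constant
  expect_equal(
    compare_curves(a, shift(a))$rmsd_frontal_mm,
    abs(mean(tidy(compare_curves(a, shift(a)))$dy)),
    tolerance = 1e-12
  )
})

test_that("cohort summaries use the population SD convention", {
  expect_equal(
    as.data.frame(cohort_summary(5.0)),
    data.frame(n = 1L, mean = 5, sd = 0, median = 5, min = 5, max = 5)
  )

  set.seed(5)
  v <- rnorm(24)
  s <- cohort_summary(v)
  expect_equal(s$sd, sqrt(mean((v - mean(v))^2)))
  expect_equal(cohort_summary(sample(v))$mean, s$mean)

  expect_error(cohort_summary(numeric(0)), "empty")
})

test_that("the packaged cohort table reproduces its printed summary row", {
  tab <- utils::read.csv(system.file("extdata", "cohort_rmsd.csv", package = "spinescan"))
  expect_identical(nrow(tab), 24L)
  s <- cohort_summary(tab)
  frontal <- s[s$variable == "rmsd_frontal_mm", ]
  sagittal <- s[s$variable == "rmsd_sagittal_mm", ]
  expect_equal(round(frontal$mean, 2), 4.63)
  expect_equal(round(frontal$sd, 2), 1.48)
  expect_equal(frontal$max, 7.75)
  expect_equal(round(sagittal$mean, 2), 0.88)
  expect_equal(round(sagittal$sd, 2), 0.43)

  ops <- utils::read.csv(system.file("extdata", "interoperator_rmsd.csv", package = "spinescan"))
  so <- cohort_summary(ops)
  expect_equal(round(so$mean[so$variable == "rmsd_frontal_mm"], 2), 4.65)
  expect_equal(round(so$mean[so$variable == "rmsd_sagittal_mm"], 2), 0.75)
})

test_that("repeatability separates posture variation from method variation", {
  x <- seq(0, 100, 1)
  truth <- mk_curve(x, sin(x / 15), cos(x / 25))

  # identical repeats: no variation of any kind
  same <- tibble::tibble(manual = list(truth, truth, truth), auto = list(truth, truth, truth))
  g <- glance(repeatability(same))
  expect_equal(g$avg_sd_manual_frontal_mm, 0)
  expect_equal(g$avg_sd_diff_frontal_mm, 0)

  # manuals offset by -1, 0, +1 mm with autos tracking exactly:
  # posture SD = sqrt(2/3), method SD = 0
  offs <- lapply(c(-1, 0, 1), function(d) mk_curve(x, sin(x / 15) + d, cos(x / 25)))
  pairs <- tibble::tibble(manual = offs, auto = offs)
  g <- glance(repeatability(pairs))
  expect_equal(g$avg_sd_manual_frontal_mm, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(g$avg_sd_diff_frontal_mm, 0)

  # averages are the means of the per-X curves
  r <- repeatability(pairs)
  expect_equal(g$avg_sd_manual_frontal_mm, mean(tidy(r)$sd_manual_frontal))

  expect_error(repeatability(same[1, ]), "at least 2")
  far <- tibble::tibble(
    manual = list(truth, mk_curve(x + 500, 0)),
    auto = list(truth, mk_curve(x + 500, 0))
  )
  expect_error(repeatability(far), "common X span")
})

test_that("simulated repeat experiments recover their generating SDs", {
  x <- seq(0, 300, 0.9)
  truth <- mk_curve(x, 10 * sin(x / 60), 5 * cos(x / 80))
  for (seed in 1:3) {
    reps <- simulate_repeats(truth,
      n_repeats = 20, posture_sd_mm = 2,
      detection_sd_mm = 0.4, seed = seed
    )
    g <- glance(repeatability(reps))
    expect_lt(abs(g$avg_sd_manual_frontal_mm / 2 - 1), 0.25)
    expect_lt(abs(g$avg_sd_diff_frontal_mm / (0.4 * sqrt(2)) - 1), 0.25)
    # posture dominates method noise, as in intra-operator practice
    expect_lt(g$avg_sd_diff_frontal_mm, g$avg_sd_manual_frontal_mm)
  }
  # deterministic given the seed
  a <- simulate_repeats(truth, n_repeats = 3, seed = 7)
  b <- simulate_repeats(truth, n_repeats = 3, seed = 7)
  expect_identical(a$manual[[1]], b$manual[[1]])
})
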