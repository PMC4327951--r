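#' Common longitudinal span of two spatial curves
#'
#' The automatic curve is typically shorter than the manual one (the furrow
#' fades in the neck region), so curves must be compared over the
#' intersection of their X ranges only.
#'
#' @param a,b `curve3d` tibbles.
#' @return Numeric `c(x_lo, x_hi)` in mm.
#' @export
common_span <- function(a, b) {
  if (!nrow(a) || !nrow(b)) abort("cannot intersect spans of empty curves.")
  lo <- max(min(a$x), min(b$x))
  hi <- min(max(a$x), max(b$x))
  if (lo > hi) {
    abort(sprintf(
      "curves cover disjoint X spans ([%.1f, %.1f] vs [%.1f, %.1f] mm).",
      min(a$x), max(a$x), min(b$x), max(b$x)
    ))
  }
  c(lo, hi)
}

rmsd <- function(d) sqrt(mean(d^2))
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Compare manual and automatic spine curves by per-plane RMSD
#'
#' Resamples both curves at the profile-row X positions of the first curve
#' inside their common span and computes, separately per anatomical plane,
#' the root mean square deviation between point pairs lying in the same X
#' row:
#' \deqn{RMSD_{X\mbox{-}Y} = \sqrt{\tfrac{1}{n}\sum_i (Y_{M,i}-Y_{A,i})^2},
#' \qquad
#' RMSD_{X\mbox{-}Z} = \sqrt{\tfrac{1}{n}\sum_i (Z_{M,i}-Z_{A,i})^2}.}
#'
#' @param manual,auto `curve3d` tibbles (the manual reference curve and the
#'   automatically detected curve; any two comparable curves work).
#' @return A one-row `curve_comparison` tibble: `rmsd_frontal_mm`,
#'   `rmsd_sagittal_mm`, `n_rows`, `x_span_mm`. `tidy()` recovers the
#'   per-row differences.
#' @export
compare_curves <- function(manual, auto) {
  validate_curve3d(manual)
  validate_curve3d(auto)
  span <- common_span(manual, auto)
  grid <- manual$x[manual$x >= span[1] & manual$x <= span[2]]
  if (length(grid) < 2) abort("fewer than 2 common rows: cannot compute RMSD.")
  my <- approx(manual$x, manual$y, xout = grid, ties = "ordered")$y
  mz <- approx(manual$x, manual$z, xout = grid, ties = "ordered")$y
  ay <- approx(auto$x, auto$y, xout = grid, ties = "ordered")$y
  az <- approx(auto$x, auto$z, xout = grid, ties = "ordered")$y
  diffs <- tibble::tibble(x = grid, dy = my - ay, dz = mz - az)
  out <- tibble::tibble(
    rmsd_frontal_mm = rmsd(diffs$dy),
    rmsd_sagittal_mm = rmsd(diffs$dz),
    n_rows = length(grid),
    x_span_mm = span[2] - span[1]
  )
  class(out) <- c("curve_comparison", class(out))
  attr(out, "differences") <- diffs
  out
}

#' @exportS3Method generics::tidy
tidy.curve_comparison <- function(x, ...) attr(x, "differences")

#' @exportS3Method generics::glance
glance.curve_comparison <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
print.curve_comparison <- function(x, ...) {
  cat(sprintf(
    "<curve_comparison> RMSD frontal %.2f mm, sagittal %.2f mm (n = %d rows over %.1f mm)\n",
    x$rmsd_frontal_mm, x$rmsd_sagittal_mm, x$n_rows, x$x_span_mm
  ))
  invisible(x)
}

#' Cohort summary statistics
#'
#' Descriptive statistics of per-patient quantities (typically RMSD values):
#' arithmetic mean, population standard deviation (divisor `n`, the
#' convention under which the package's summary rows reproduce printed
#' cohort tables), median, minimum and maximum. Rounding is left to
#' presentation; all values are returned in full precision.
#'
#' @param x A numeric vector, or a data frame (each numeric column is
#'   summarised in its own row).
#' @param ... Unused.
#' @return A tibble with columns `variable` (for data frames), `n`, `mean`,
#'   `sd`, `median`, `min`, `max`.
#' @export
#' @examples
#' cohort_summary(c(5, 7, 9))
cohort_summary <- function(x, ...) UseMethod("cohort_summary")

#' @export
cohort_summary.numeric <- function(x, ...) {
  if (!length(x)) abort("cannot summarise an empty cohort.")
  if (anyNA(x)) abort("cohort values must not contain NA.")
  tibble::tibble(
    n = length(x), mean = mean(x), sd = sd_pop(x),
    median = median(x), min = min(x), max = max(x)
  )
}

#' @export
cohort_summary.data.frame <- function(x, ...) {
  num <- names(x)[vapply(x, is.numeric, logical(1))]
  if (!length(num)) abort("no numeric columns to summarise.")
  dplyr::bind_rows(lapply(num, function(nm) {
    dplyr::bind_cols(tibble::tibble(variable = nm), cohort_summary(x[[nm]]))
  }))
}

#' Intra-/inter-operator repeatability statistics
#'
#' Given repeated (manual, automatic) curve pairs of the same subject,
#' computes, at every X row of the shared span, the standard deviation
#' across repeats of (i) the manual curve position -- the posture-variation
#' curve -- and (ii) the per-repeat manual-minus-automatic difference -- the
#' method-variation curve -- separately for the frontal (Y) and sagittal
#' (Z) planes. The four headline scalars are the means of these SD-vs-X
#' curves. SDs use the population divisor, matching [cohort_summary()].
#'
#' @param pairs A data frame with list-columns `manual` and `auto`
#'   (each element a `curve3d`), one row per repeat, e.g. from
#'   [simulate_repeats()]; alternatively a plain list of
#'   `list(manual = , auto = )` pairs.
#' @return A `repeatability_result`: `glance()` gives the one-row summary
#'   (`avg_sd_manual_frontal_mm`, `avg_sd_diff_frontal_mm`,
#'   `avg_sd_manual_sagittal_mm`, `avg_sd_diff_sagittal_mm`, `n_repeats`,
#'   `n_rows`), `tidy()` the per-X SD curves.
#' @export
repeatability <- function(pairs) {
  if (is.data.frame(pairs)) {
    manuals <- pairs$manual
    autos <- pairs$auto
  } else {
    manuals <- purrr::map(pairs, "manual")
    autos <- purrr::map(pairs, "auto")
  }
  n_rep <- length(manuals)
  if (n_rep < 2) abort("repeatability needs at least 2 repeats.")
  if (length(autos) != n_rep) abort("each repeat needs both a manual and an automatic curve.")
  all_curves <- c(manuals, autos)
  lo <- max(purrr::map_dbl(all_curves, function(cv) min(cv$x)))
  hi <- min(purrr::map_dbl(all_curves, function(cv) max(cv$x)))
  if (lo > hi) abort("repeats share no common X span.")
  grid <- manuals[[1]]$x[manuals[[1]]$x >= lo & manuals[[1]]$x <= hi]
  if (length(grid) < 2) abort("fewer than 2 rows in the common span.")
  res <- function(curves, what) {
    vapply(
      curves,
      function(cv) approx(cv$x, cv[[what]], xout = grid, ties = "ordered")$y,
      numeric(length(grid))
    )
  }
  my <- res(manuals, "y")
  mz <- res(manuals, "z")
  ay <- res(autos, "y")
  az <- res(autos, "z")
  row_sd <- function(m) apply(m, 1, sd_pop)
  per_x <- tibble::tibble(
    x = grid,
    sd_manual_frontal = row_sd(my),
    sd_diff_frontal = row_sd(my - ay),
    sd_manual_sagittal = row_sd(mz),
    sd_diff_sagittal = row_sd(mz - az)
  )
  summary <- tibble::tibble(
    avg_sd_manual_frontal_mm = mean(per_x$sd_manual_frontal),
    avg_sd_diff_frontal_mm = mean(per_x$sd_diff_frontal),
    avg_sd_manual_sagittal_mm = mean(per_x$sd_manual_sagittal),
    avg_sd_diff_sagittal_mm = mean(per_x$sd_diff_sagittal),
    n_repeats = n_rep,
    n_rows = length(grid)
  )
  structure(list(per_x = per_x, summary = summary), class = "repeatability_result")
}

#' @exportS3Method generics::tidy
tidy.repeatability_result <- function(x, ...) x$per_x

#' @exportS3Method generics::glance
glance.repeatability_result <- function(x, ...) x$summary

#' @export
print.repeatability_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0(
      "<repeatability_result> %d repeats over %d rows\n",
      "  frontal : posture SD %.2f mm, method SD %.2f mm\n",
      "  sagittal: posture SD %.2f mm, method SD %.2f mm\n"
    ),
    s$n_repeats, s$n_rows,
    s$avg_sd_manual_frontal_mm, s$avg_sd_diff_frontal_mm,
    s$avg_sd_manual_sagittal_mm, s$avg_sd_diff_sagittal_mm
  ))
  invisible(x)
}

#' Simulate repeated curve determinations
#'
#' Curve-level generative model of a repeatability experiment: each repeat
#' carries a posture deviation field (lateral and sagittal values drawn
#' independently at every profile row) that is shared by the manual and the
#' automatic curve of that repeat, since both are extracted from the same
#' measurement; each detected curve additionally carries its own independent
#' per-row detection noise. Posture variation therefore inflates the
#' across-repeat spread of either curve but cancels from their difference,
#' which isolates the method's own variability -- the separation the
#' repeatability statistics are designed to expose.
#'
#' @param truth A `curve3d` ground-truth centerline (e.g. from
#'   [ground_truth_curve()]).
#' @param n_repeats Number of repeated measurements (the reference
#'   experiment uses 20).
#' @param posture_sd_mm SD of the per-row posture deviation.
#' @param detection_sd_mm SD of the independent per-row detection noise
#'   applied to each curve.
#' @param seed RNG seed (mandatory).
#' @return A tibble with one row per repeat and list-columns `manual`,
#'   `auto`, ready for [repeatability()].
#' @export
simulate_repeats <- function(truth, n_repeats = 20, posture_sd_mm = 2,
                             detection_sd_mm = 0.4, seed) {
  if (missing(seed)) abort("`seed` is mandatory.")
  validate_curve3d(truth)
  n <- nrow(truth)
  with_seed(seed, {
    reps <- purrr::map(seq_len(n_repeats), function(r) {
      dy <- rnorm(n, sd = posture_sd_mm)
      dz <- rnorm(n, sd = posture_sd_mm)
      mk <- function(prov) {
        new_curve3d(
          truth$x,
          truth$y + dy + rnorm(n, sd = detection_sd_mm),
          truth$z + dz + rnorm(n, sd = detection_sd_mm),
          smoothed = FALSE, provenance = prov
        )
      }
      tibble::tibble(rep = r, manual = list(mk("manual")), auto = list(mk("automatic")))
    })
    dplyr::bind_rows(reps)
  })
}
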