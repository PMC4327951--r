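new_curve3d <- function(x, y, z, smoothed = FALSE, provenance = "unknown") {
  out <- tibble::tibble(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  class(out) <- c("curve3d", class(out))
  attr(out, "smoothed") <- smoothed
  attr(out, "provenance") <- provenance
  out
}

validate_curve3d <- function(curve) {
  if (!nrow(curve)) abort("empty spatial curve.")
  if (anyNA(curve$x) || anyNA(curve$y) || anyNA(curve$z)) {
    abort("spatial curve coordinates must be finite.")
  }
  d <- diff(curve$x)
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    abort("spatial curve X must be strictly monotonic.")
  }
  invisible(curve)
}

#' @export
print.curve3d <- function(x, ...) {
  cat(sprintf(
    "<curve3d> %s%s, %d samples, X %.1f..%.1f mm\n",
    attr(x, "provenance") %||% "?",
    if (isTRUE(attr(x, "smoothed"))) " (smoothed)" else "",
    nrow(x), min(x$x), max(x$x)
  ))
  NextMethod()
}

#' Lift a detected image-space curve to 3D
#'
#' Converts a continuous 2D curve in image coordinates `(u, v)` into the
#' spatial spine curve by reading the scan's `X`, `Y`, `Z` grids at the
#' curve's sub-pixel positions: within each covered profile row, coordinates
#' are linearly interpolated between the two grid columns bracketing
#' `u`. Rows where either bracketing cell is invalid are dropped (and
#' reported via a message and the `dropped_rows` attribute).
#'
#' @param scan A [back_scan()].
#' @param curve A `curve2d` from [detect_manual()] or [select_curve()].
#' @return A `curve3d` tibble (columns `x`, `y`, `z` in mm, one row per
#'   lifted profile row) with provenance `"manual"` or `"automatic"`
#'   according to the detection mode.
#' @export
lift_curve <- function(scan, curve) {
  dm <- dim(scan)
  xs <- ys <- zs <- numeric(nrow(curve))
  keep <- logical(nrow(curve))
  for (i in seq_len(nrow(curve))) {
    v <- curve$v[i]
    u <- curve$u[i]
    if (v < 1 || v > dm[1] || u < 1 || u > dm[2]) next
    i0 <- floor(u)
    i1 <- min(i0 + 1L, dm[2])
    if (u == i0) i1 <- i0
    if (!scan$valid[v, i0] || !scan$valid[v, i1]) next
    f <- u - i0
    xs[i] <- (1 - f) * scan$x[v, i0] + f * scan$x[v, i1]
    ys[i] <- (1 - f) * scan$y[v, i0] + f * scan$y[v, i1]
    zs[i] <- (1 - f) * scan$z[v, i0] + f * scan$z[v, i1]
    keep[i] <- TRUE
  }
  if (!any(keep)) abort("curve lies entirely outside the valid scan data.")
  if (any(!keep)) {
    message(sprintf("lift_curve: dropped %d row(s) with invalid neighbours.", sum(!keep)))
  }
  prov <- switch(attr(curve, "mode") %||% "",
    "intensity-min" = "manual",
    "curvature-max" = "automatic",
    "unknown"
  )
  out <- new_curve3d(xs[keep], ys[keep], zs[keep], smoothed = FALSE, provenance = prov)
  attr(out, "dropped_rows") <- curve$v[!keep]
  validate_curve3d(out)
  out
}

# least-squares cubic spline fit with uniform interior knots, evaluated at x
ls_spline_fit <- function(x, y, knot_spacing_mm) {
  rng <- range(x)
  interior <- seq(rng[1], rng[2], by = knot_spacing_mm)
  interior <- interior[interior > rng[1] & interior < rng[2]]
  basis <- splines::bs(x,
    knots = interior, degree = 3, intercept = TRUE,
    Boundary.knots = rng
  )
  if (length(x) < ncol(basis)) {
    abort(sprintf(
      "too few samples (%d) for a cubic spline with %d knots at %.3g mm spacing.",
      length(x), length(interior), knot_spacing_mm
    ))
  }
  fit <- stats::lm.fit(basis, y)
  y - fit$residuals
}

#' Smooth a spatial curve with a least-squares cubic spline
#'
#' Fits cubic smoothing splines with uniform interior knots independently to
#' `Y(X)` and `Z(X)` and evaluates them at the original X positions. Splines
#' are used instead of high-degree polynomials to preserve the back's
#' morphological features (up to the four anatomical curvature lobes of the
#' sagittal profile) while avoiding the end-interval oscillation of
#' high-degree polynomial fits (Runge's phenomenon).
#'
#' @param curve A `curve3d`.
#' @param knot_spacing_mm Interior knot spacing in mm (default 30, which
#'   resolves the anatomical lobes over a ~500 mm thoraco-lumbar span while
#'   suppressing point noise); must exceed twice the sample spacing.
#' @return The smoothed `curve3d` (marked `smoothed`). Smoothing an
#'   already-smoothed curve with the same knots is a no-op (least-squares
#'   projection).
#' @export
smooth_curve <- function(curve, knot_spacing_mm = 30) {
  validate_curve3d(curve)
  if (nrow(curve) < 8) abort("need at least 8 samples to smooth a spatial curve.")
  dx <- mean(abs(diff(curve$x)))
  if (knot_spacing_mm <= 2 * dx) {
    abort(sprintf(
      "knot spacing (%.3g mm) must exceed twice the sample spacing (%.3g mm).",
      knot_spacing_mm, dx
    ))
  }
  out <- new_curve3d(
    curve$x,
    ls_spline_fit(curve$x, curve$y, knot_spacing_mm),
    ls_spline_fit(curve$x, curve$z, knot_spacing_mm),
    smoothed = TRUE,
    provenance = attr(curve, "provenance") %||% "unknown"
  )
  out
}

#' Project a spatial curve to an anatomical plane
#'
#' @param curve A `curve3d`.
#' @param plane `"frontal"` (X--Y view, lateral spine deviation) or
#'   `"sagittal"` (X--Z view, kyphotic/lordotic deviation).
#' @return A tibble of `(x, value)` pairs in the original order, with a
#'   `plane` attribute.
#' @export
project_curve <- function(curve, plane = c("frontal", "sagittal")) {
  plane <- match.arg(plane)
  out <- tibble::tibble(
    x = curve$x,
    value = if (plane == "frontal") curve$y else curve$z
  )
  attr(out, "plane") <- plane
  out
}
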