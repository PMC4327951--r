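#' Specification of a synthetic scoliotic back surface
#'
#' Defines the parametric torso used to validate every detection and
#' comparison stage against a known ground truth. The model is an elliptic
#' torso cross-section plus a smooth sagittal offset `s(X)` (the
#' kyphosis/lordosis double-S), carved by a Gaussian posterior-median-furrow
#' depression that follows a prescribed lateral centerline `c(X)`, with
#' independent Gaussian sensor noise on the depth channel only. The
#' brightness channel carries a dark marker line drawn at a configurable
#' lateral offset from the true centerline, emulating palpation error.
#'
#' The default sampling emulates the scanner this package targets:
#' profiles every 0.9 mm over a 700-row (~630 mm) longitudinal span, 300
#' samples per profile at 1 mm over a 300 mm field, and 0.1 mm single-point
#' depth accuracy.
#'
#' `sagittal_profile` and `spine_curve` are polynomial coefficients
#' (ascending powers) evaluated in the normalised coordinate
#' `t = X / max(X)` in `[0, 1]`, or arbitrary functions of `t`. The furrow
#' depth tapers linearly to 30 % of its nominal value over the top (cranial)
#' quarter of rows, reproducing the fading of the furrow above the shoulder
#' blades that forces a row-direction ROI reduction on real scans.
#'
#' @param n_rows,n_cols Grid size (profiles x samples per profile).
#' @param profile_spacing_mm,col_spacing_mm Grid pitch along X and Y.
#' @param torso_half_width_mm,torso_depth_mm Semi-axes of the elliptic torso
#'   section (lateral, depth). `torso_depth_mm = 0` gives a flat plate.
#' @param sagittal_profile Coefficients (or function of `t`) for the
#'   sagittal Z offset `s(X)` in mm.
#' @param spine_curve Coefficients (or function of `t`) for the lateral
#'   centerline `c(X)` in mm.
#' @param furrow_depth_mm,furrow_halfwidth_mm Gaussian furrow depth and
#'   half-width (mm); the half-width must stay below the torso half-width.
#' @param marker_offset_mm Lateral offset of the drawn marker line from
#'   `c(X)` (simulated palpation error; palpation itself is only accurate to
#'   about the spinous-process width, 9.8 mm).
#' @param marker_halfwidth_mm,marker_contrast Width (mm) and brightness-dip
#'   depth (in `[0, 1]`) of the marker line.
#' @param blade_height_mm,blade_halfwidth_mm,blade_offset_mm Optional
#'   shoulder-blade bumps (two lateral Gaussian ridges in the upper torso);
#'   height 0 disables them.
#' @param noise_sd_mm SD of the Gaussian depth noise (mm).
#' @param seed Mandatory integer RNG seed; identical seeds give bit-identical
#'   scans.
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_scan()], [ground_truth_curve()]
#' @export
#' @examples
#' spec <- synthetic_spec(n_rows = 120, n_cols = 80, seed = 1)
#' sim <- generate_scan(spec)
#' sim$scan
synthetic_spec <- function(n_rows = 700, n_cols = 300,
                           profile_spacing_mm = 0.9, col_spacing_mm = 1.0,
                           torso_half_width_mm = 170, torso_depth_mm = 50,
                           sagittal_profile = c(0, 120, -360, 240),
                           spine_curve = c(0, 40, -40),
                           furrow_depth_mm = 4, furrow_halfwidth_mm = 10,
                           marker_offset_mm = 0, marker_halfwidth_mm = 2.5,
                           marker_contrast = 0.8,
                           blade_height_mm = 0, blade_halfwidth_mm = 30,
                           blade_offset_mm = 60,
                           noise_sd_mm = 0.1, seed) {
  if (missing(seed)) abort("`seed` is mandatory: synthetic scans must be reproducible.")
  spec <- structure(as.list(environment()), class = "synthetic_spec")
  with(spec, {
    if (n_rows < 3 || n_cols < 3) abort("grid must be at least 3 x 3.")
    if (profile_spacing_mm <= 0 || col_spacing_mm <= 0) abort("grid spacings must be > 0.")
    if (torso_half_width_mm <= 0) abort("torso_half_width_mm must be > 0.")
    if (torso_depth_mm < 0 || furrow_depth_mm < 0 || blade_height_mm < 0) {
      abort("depths/heights must be >= 0.")
    }
    if (furrow_halfwidth_mm <= 0 || marker_halfwidth_mm <= 0 || blade_halfwidth_mm <= 0) {
      abort("half-widths must be > 0.")
    }
    if (furrow_halfwidth_mm >= torso_half_width_mm) {
      abort("furrow_halfwidth_mm must be smaller than torso_half_width_mm.")
    }
    if (marker_contrast < 0 || marker_contrast > 1) abort("marker_contrast must be in [0, 1].")
    if (noise_sd_mm < 0) abort("noise_sd_mm must be >= 0.")
  })
  spec
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec> %d x %d grid (%.2f x %.2f mm pitch), furrow %.1f/%.1f mm, noise %.2f mm, seed %d\n",
    x$n_rows, x$n_cols, x$profile_spacing_mm, x$col_spacing_mm,
    x$furrow_depth_mm, x$furrow_halfwidth_mm, x$noise_sd_mm, x$seed
  ))
  invisible(x)
}

poly_eval <- function(coef_or_fn, t) {
  if (is.function(coef_or_fn)) {
    return(coef_or_fn(t))
  }
  out <- numeric(length(t))
  for (k in seq_along(coef_or_fn)) out <- out + coef_or_fn[k] * t^(k - 1)
  out
}

# geometry shared by the generator and the analytic ground truth
synth_axes <- function(spec) {
  x <- (seq_len(spec$n_rows) - 1) * spec$profile_spacing_mm
  y <- (seq_len(spec$n_cols) - (spec$n_cols + 1) / 2) * spec$col_spacing_mm
  t <- if (max(x) > 0) x / max(x) else x * 0
  list(x = x, y = y, t = t)
}

# furrow depth taper: full depth up to t = 0.75, then linear to 30 % at t = 1
furrow_taper <- function(t) ifelse(t <= 0.75, 1, 1 - 0.7 * (t - 0.75) / 0.25)

torso_section <- function(y, spec) {
  if (spec$torso_depth_mm == 0) {
    return(rep(0, length(y)))
  }
  r2 <- 1 - (y / spec$torso_half_width_mm)^2
  ifelse(r2 > 0, spec$torso_depth_mm * sqrt(pmax(r2, 0)), NA_real_)
}

# noise-free surface height at lateral positions y (vector) for one row
synth_surface_row <- function(y, t_row, spec) {
  cx <- poly_eval(spec$spine_curve, t_row)
  z <- torso_section(y, spec) + poly_eval(spec$sagittal_profile, t_row)
  z <- z - spec$furrow_depth_mm * furrow_taper(t_row) *
    exp(-(y - cx)^2 / (2 * spec$furrow_halfwidth_mm^2))
  if (spec$blade_height_mm > 0) {
    env <- exp(-(t_row - 0.75)^2 / (2 * 0.12^2))
    z <- z + spec$blade_height_mm * env *
      (exp(-(y - spec$blade_offset_mm)^2 / (2 * spec$blade_halfwidth_mm^2)) +
        exp(-(y + spec$blade_offset_mm)^2 / (2 * spec$blade_halfwidth_mm^2)))
  }
  z
}

#' Generate a synthetic back-surface scan with known ground truth
#'
#' Evaluates the parametric surface of [synthetic_spec()] on the scan grid,
#' adds Gaussian depth noise, renders the marker line into the brightness
#' channel and returns the scan together with the analytic ground-truth
#' curves.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `scan` (a [back_scan()]) and `truth`
#'   (the [ground_truth_curve()] result: `$spine` and `$marker` curves).
#' @export
generate_scan <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ax <- synth_axes(spec)
  nr <- spec$n_rows
  nc <- spec$n_cols
  z <- matrix(NA_real_, nr, nc)
  bright <- matrix(1, nr, nc)
  for (v in seq_len(nr)) {
    z[v, ] <- synth_surface_row(ax$y, ax$t[v], spec)
    cx <- poly_eval(spec$spine_curve, ax$t[v])
    bright[v, ] <- 1 - spec$marker_contrast *
      exp(-(ax$y - cx - spec$marker_offset_mm)^2 / (2 * spec$marker_halfwidth_mm^2))
  }
  valid <- is.finite(z)
  if (spec$noise_sd_mm > 0) {
    z <- z + with_seed(spec$seed, matrix(rnorm(nr * nc, sd = spec$noise_sd_mm), nr, nc))
  }
  z[!valid] <- NA_real_
  scan <- back_scan(
    x = matrix(ax$x, nr, nc),
    y = matrix(ax$y, nr, nc, byrow = TRUE),
    z = z, brightness = bright, valid = valid,
    profile_spacing_mm = spec$profile_spacing_mm,
    metadata = list(source = "synthetic", seed = as.character(spec$seed))
  )
  list(scan = scan, truth = ground_truth_curve(spec))
}

#' Analytic ground-truth curves of a synthetic back
#'
#' Noise-free evaluation of the spine centerline and the marker centerline
#' on the row grid: for each profile row, the lateral position and the
#' surface depth at that position.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of two `curve3d` tibbles, `spine` (at the furrow bottom)
#'   and `marker` (on the surface under the marker line), each with one
#'   sample per generated row.
#' @export
ground_truth_curve <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ax <- synth_axes(spec)
  cx <- poly_eval(spec$spine_curve, ax$t)
  spine_z <- vapply(
    seq_along(ax$x),
    function(v) synth_surface_row(cx[v], ax$t[v], spec),
    numeric(1)
  )
  my <- cx + spec$marker_offset_mm
  marker_z <- vapply(
    seq_along(ax$x),
    function(v) synth_surface_row(my[v], ax$t[v], spec),
    numeric(1)
  )
  list(
    spine = new_curve3d(ax$x, cx, spine_z, smoothed = FALSE, provenance = "ground-truth"),
    marker = new_curve3d(ax$x, my, marker_z, smoothed = FALSE, provenance = "ground-truth")
  )
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
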