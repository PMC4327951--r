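#' Ordered back-surface scan
#'
#' Constructs a `back_scan`, the central container of the package: a regular
#' grid of measured surface points indexed by `(v, u)`, where `v` indexes
#' laser profiles (constant-X rows) and `u` indexes samples along a profile.
#' Each cell holds spatial coordinates `X`, `Y`, `Z` in mm and a brightness
#' value normalised to `[0, 1]`. Cells where the scanner recorded no valid
#' return (laser occlusion dropouts) are flagged invalid rather than carrying
#' sentinel coordinates.
#'
#' @param x,y,z Numeric matrices of identical dimension (rows = profiles `v`,
#'   columns = samples `u`), at least 3 x 3, coordinates in mm.
#' @param brightness Numeric matrix on `[0, 1]`, same dimension; defaults to
#'   all ones (no brightness channel recorded).
#' @param valid Logical matrix, same dimension; defaults to cells with finite
#'   coordinates.
#' @param profile_spacing_mm Nominal spacing between adjacent profiles;
#'   defaults to the mean spacing of per-profile mean X.
#' @param metadata Named list of free-form provenance strings.
#'
#' @return An object of class `back_scan`.
#'
#' @details The per-profile mean X must be strictly monotonic in `v`:
#' profiles are ordered along the translation direction of the scanner.
#' Brightness must lie in `[0, 1]` wherever valid; invalid cells carry no
#' constraints.
#'
#' @seealso [read_scan()], [generate_scan()], [crop_roi()],
#'   [rotate_about_x()], [as_tibble.back_scan()]
#' @export
#' @examples
#' z <- matrix(0, 5, 5)
#' xy <- expand.grid(u = 1:5, v = 1:5)
#' scan <- back_scan(
#'   x = matrix(xy$v * 0.9, 5, 5),
#'   y = matrix(xy$u * 1.0, 5, 5),
#'   z = z
#' )
#' scan
back_scan <- function(x, y, z, brightness = NULL, valid = NULL,
                      profile_spacing_mm = NULL, metadata = list()) {
  if (!is.matrix(x) || !is.matrix(y) || !is.matrix(z)) {
    abort("`x`, `y` and `z` must be matrices (profiles in rows, samples in columns).")
  }
  dm <- dim(z)
  if (!identical(dim(x), dm) || !identical(dim(y), dm)) {
    abort("`x`, `y` and `z` must have identical dimensions.")
  }
  if (is.null(brightness)) brightness <- matrix(1, dm[1], dm[2])
  if (is.null(valid)) valid <- is.finite(x) & is.finite(y) & is.finite(z)
  if (!identical(dim(brightness), dm) || !identical(dim(valid), dm)) {
    abort("`brightness` and `valid` must match the coordinate grids in dimension.")
  }
  storage.mode(valid) <- "logical"
  scan <- structure(
    list(
      x = x, y = y, z = z,
      brightness = brightness,
      valid = valid,
      profile_spacing_mm = profile_spacing_mm,
      metadata = metadata
    ),
    class = "back_scan"
  )
  if (is.null(profile_spacing_mm)) {
    mx <- profile_mean_x(scan)
    scan$profile_spacing_mm <- if (length(mx) > 1) mean(abs(diff(mx))) else NA_real_
  }
  validate_back_scan(scan)
  scan
}

profile_mean_x <- function(scan) {
  vapply(seq_len(nrow(scan$x)), function(v) {
    ok <- scan$valid[v, ]
    if (!any(ok)) NA_real_ else mean(scan$x[v, ok])
  }, numeric(1))
}

validate_back_scan <- function(scan) {
  dm <- dim(scan$z)
  if (dm[1] < 3 || dm[2] < 3) {
    abort(sprintf("scan grid must be at least 3 x 3, got %d x %d.", dm[1], dm[2]))
  }
  b <- scan$brightness[scan$valid]
  if (length(b) && (anyNA(b) || min(b) < 0 || max(b) > 1)) {
    abort("brightness must lie in [0, 1] wherever valid.")
  }
  mx <- profile_mean_x(scan)
  mx <- mx[!is.na(mx)]
  if (length(mx) > 1) {
    d <- diff(mx)
    if (!(all(d > 0) || all(d < 0))) {
      abort(paste0(
        "profiles are not ordered along the translation direction: ",
        "per-profile mean X must be strictly monotonic in v."
      ))
    }
  }
  invisible(scan)
}

#' @export
print.back_scan <- function(x, ...) {
  dm <- dim(x$z)
  cat(sprintf(
    "<back_scan> %d profiles x %d samples (%.1f%% valid)\n",
    dm[1], dm[2], 100 * mean(x$valid)
  ))
  ok <- x$valid
  if (any(ok)) {
    cat(sprintf(
      "  X: [%.1f, %.1f] mm   Y: [%.1f, %.1f] mm   Z: [%.2f, %.2f] mm\n",
      min(x$x[ok]), max(x$x[ok]), min(x$y[ok]), max(x$y[ok]),
      min(x$z[ok]), max(x$z[ok])
    ))
  }
  cat(sprintf("  profile spacing: %.3g mm\n", x$profile_spacing_mm))
  if (length(x$metadata)) {
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
      sep = "=", collapse = ", "
    ), "\n")
  }
  invisible(x)
}

#' @export
dim.back_scan <- function(x) dim(x$z)

#' Convert a scan to or from a long tibble
#'
#' `as_tibble()` flattens the grid to one row per cell with columns
#' `v`, `u`, `x`, `y`, `z`, `brightness`, `valid`; `as_back_scan()` rebuilds
#' the grid container from such a tibble.
#'
#' @param x A `back_scan` (for `as_tibble`) or a data frame with columns
#'   `v`, `u`, `x`, `y`, `z` and optionally `brightness`, `valid`.
#' @param profile_spacing_mm,metadata Passed on to [back_scan()].
#' @param ... Unused.
#' @return A tibble, or a `back_scan`.
#' @exportS3Method tibble::as_tibble
as_tibble.back_scan <- function(x, ...) {
  dm <- dim(x$z)
  scan <- x # tibble() lets later columns see earlier ones; keep the object
  tibble::tibble(
    v = rep(seq_len(dm[1]), times = dm[2]),
    u = rep(seq_len(dm[2]), each = dm[1]),
    x = as.vector(scan$x),
    y = as.vector(scan$y),
    z = as.vector(scan$z),
    brightness = as.vector(scan$brightness),
    valid = as.vector(scan$valid)
  )
}

#' @rdname as_tibble.back_scan
#' @export
as_back_scan <- function(x, profile_spacing_mm = NULL, metadata = list()) {
  need <- c("v", "u", "x", "y", "z")
  if (!all(need %in% names(x))) {
    abort("need columns v, u, x, y, z (and optionally brightness, valid).")
  }
  nv <- max(x$v)
  nu <- max(x$u)
  if (nrow(x) != nv * nu) abort("tibble does not cover a complete v x u grid.")
  ord <- order(x$u, x$v)
  grid <- function(col, default) {
    if (is.null(x[[col]])) {
      matrix(default, nv, nu)
    } else {
      matrix(x[[col]][ord], nv, nu)
    }
  }
  back_scan(
    x = grid("x", NA_real_), y = grid("y", NA_real_), z = grid("z", NA_real_),
    brightness = grid("brightness", 1),
    valid = grid("valid", TRUE),
    profile_spacing_mm = profile_spacing_mm, metadata = metadata
  )
}

#' Rectangular region of interest on the scan grid
#'
#' Inclusive grid-index bounds selecting the portion of the scan analysed
#' downstream. On real scans the cranial rows are typically excluded because
#' the posterior median furrow fades above the shoulder blades, so the region
#' must be reduced in the X (row) direction before curves are compared.
#'
#' @param v_min,v_max,u_min,u_max Inclusive bounds, `v` = profile row,
#'   `u` = sample column.
#' @return An object of class `scan_roi`.
#' @seealso [full_roi()], [crop_roi()]
#' @export
scan_roi <- function(v_min, v_max, u_min, u_max) {
  b <- vapply(list(v_min, v_max, u_min, u_max), as.integer, integer(1))
  if (anyNA(b)) abort("ROI bounds must be integers.")
  if (b[1] > b[2] || b[3] > b[4]) {
    abort("invalid ROI: need v_min <= v_max and u_min <= u_max.")
  }
  if (any(b < 1)) abort("ROI bounds must be >= 1.")
  structure(
    list(v_min = b[1], v_max = b[2], u_min = b[3], u_max = b[4]),
    class = "scan_roi"
  )
}

#' @export
print.scan_roi <- function(x, ...) {
  cat(sprintf(
    "<scan_roi> v %d..%d, u %d..%d\n",
    x$v_min, x$v_max, x$u_min, x$u_max
  ))
  invisible(x)
}

#' @rdname scan_roi
#' @param scan A `back_scan`.
#' @export
full_roi <- function(scan) {
  dm <- dim(scan)
  scan_roi(1L, dm[1], 1L, dm[2])
}

check_roi <- function(scan, roi) {
  if (is.null(roi)) {
    return(full_roi(scan))
  }
  if (!inherits(roi, "scan_roi")) abort("`roi` must be created by scan_roi().")
  dm <- dim(scan)
  if (roi$v_max > dm[1] || roi$u_max > dm[2]) {
    abort(sprintf(
      "ROI (v <= %d, u <= %d) exceeds the %d x %d scan grid.",
      roi$v_max, roi$u_max, dm[1], dm[2]
    ))
  }
  roi
}

#' Crop a scan to a region of interest
#'
#' @param scan A `back_scan`.
#' @param roi A [scan_roi()] lying inside the grid.
#' @return A `back_scan` covering only the ROI; coordinates are unchanged.
#' @export
crop_roi <- function(scan, roi) {
  roi <- check_roi(scan, roi)
  vs <- roi$v_min:roi$v_max
  us <- roi$u_min:roi$u_max
  if (length(vs) < 3 || length(us) < 3) {
    abort("cropped grid would be smaller than 3 x 3.")
  }
  back_scan(
    x = scan$x[vs, us, drop = FALSE],
    y = scan$y[vs, us, drop = FALSE],
    z = scan$z[vs, us, drop = FALSE],
    brightness = scan$brightness[vs, us, drop = FALSE],
    valid = scan$valid[vs, us, drop = FALSE],
    profile_spacing_mm = scan$profile_spacing_mm,
    metadata = scan$metadata
  )
}

#' Row view of a scan
#'
#' Extracts one laser profile as a tibble aligned by `u`, the plumbing unit
#' consumed by [profile_curvature()].
#'
#' @param scan A `back_scan`.
#' @param v Profile row index.
#' @return A tibble with columns `u`, `x`, `y`, `z`, `brightness`, `valid`.
#' @export
profile_samples <- function(scan, v) {
  dm <- dim(scan)
  if (v < 1 || v > dm[1]) abort(sprintf("row %d outside the %d-profile grid.", v, dm[1]))
  tibble::tibble(
    u = seq_len(dm[2]),
    x = scan$x[v, ],
    y = scan$y[v, ],
    z = scan$z[v, ],
    brightness = scan$brightness[v, ],
    valid = scan$valid[v, ]
  )
}

rotate_yz <- function(y, z, angle_deg) {
  a <- angle_deg * pi / 180
  list(y = y * cos(a) - z * sin(a), z = y * sin(a) + z * cos(a))
}

#' Rigidly rotate a scan about the scanner axis
#'
#' Rotates every point's `(Y, Z)` by `angle_deg` about the X axis and
#' resamples each profile back onto its original uniform Y grid by linear
#' interpolation, so the result remains a depth graph `Z(Y)`. `X` is
#' unchanged. Cells whose target Y falls outside the rotated profile's span
#' (leaving the field of view) become invalid. Used to emulate a patient
#' standing rotated relative to the scanner, against which the curvature
#' method should be invariant.
#'
#' @param scan A `back_scan`.
#' @param angle_deg Rotation angle in degrees (right-handed about +X).
#' @return A `back_scan` on the same grid.
#' @export
rotate_about_x <- function(scan, angle_deg) {
  if (angle_deg == 0) {
    return(scan)
  }
  out <- scan
  dm <- dim(scan)
  for (v in seq_len(dm[1])) {
    ok <- scan$valid[v, ]
    target_y <- scan$y[v, ]
    out$valid[v, ] <- FALSE
    if (sum(ok) < 2) next
    r <- rotate_yz(scan$y[v, ok], scan$z[v, ok], angle_deg)
    ord <- order(r$y)
    ry <- r$y[ord]
    rz <- r$z[ord]
    rb <- scan$brightness[v, ok][ord]
    inside <- target_y >= ry[1] & target_y <= ry[length(ry)]
    if (!any(inside)) next
    out$z[v, inside] <- approx(ry, rz, xout = target_y[inside], ties = "ordered")$y
    out$brightness[v, inside] <-
      approx(ry, rb, xout = target_y[inside], ties = "ordered")$y
    out$valid[v, inside] <- TRUE
  }
  # cropping can empty rows; grid geometry (x, y) is untouched
  out$metadata$rotated_deg <- as.character(angle_deg)
  validate_back_scan(out)
  out
}
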