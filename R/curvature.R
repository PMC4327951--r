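# 1-D Gaussian smoothing with renormalisation over the available support.
# Kernel truncated at 3 sigma; endpoints are smoothed against a shortened,
# renormalised kernel rather than padded data.
gauss_smooth1d <- function(z, sigma) {
  n <- length(z)
  if (sigma <= 0 || n < 2) {
    return(z)
  }
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  zp <- c(rep(0, r), z, rep(0, r))
  wp <- c(rep(0, r), rep(1, n), rep(0, r))
  num <- stats::filter(zp, k, sides = 2)
  den <- stats::filter(wp, k, sides = 2)
  as.numeric((num / den)[(r + 1):(r + n)])
}

# contiguous runs of TRUE as a list of index vectors
valid_runs <- function(ok) {
  if (!any(ok)) {
    return(list())
  }
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  Map(`:`, starts[r$values], ends[r$values])
}

# transverse curvature on one strictly-increasing (y, z) run, length >= 5;
# non-uniform 3-point central differences. Samples whose presmoothing kernel
# extends past the run (the first/last kernel-radius samples, at least the
# run endpoints) are flagged NA: their smoothed value depends on data that
# does not exist, which otherwise fabricates strong curvature at run edges.
curvature_run <- function(y, z, presmooth_sigma) {
  zs <- gauss_smooth1d(z, presmooth_sigma)
  n <- length(y)
  i <- 2:(n - 1)
  h1 <- y[i] - y[i - 1]
  h2 <- y[i + 1] - y[i]
  d1 <- (-h2 / (h1 * (h1 + h2))) * zs[i - 1] +
    ((h2 - h1) / (h1 * h2)) * zs[i] +
    (h1 / (h2 * (h1 + h2))) * zs[i + 1]
  d2 <- 2 * (zs[i - 1] / (h1 * (h1 + h2)) - zs[i] / (h1 * h2) +
    zs[i + 1] / (h2 * (h1 + h2)))
  k <- rep(NA_real_, n)
  k[i] <- d2 / (1 + d1^2)^1.5
  edge <- max(1L, if (presmooth_sigma > 0) as.integer(ceiling(3 * presmooth_sigma)) else 1L)
  edge <- min(edge, (n - 1L) %/% 2L)
  k[seq_len(edge)] <- NA_real_
  k[seq.int(n - edge + 1L, n)] <- NA_real_
  k
}

#' Transverse curvature of a single profile
#'
#' Computes the surface curvature along the profile (Y) direction,
#' \deqn{K = \frac{d^2Z/dY^2}{\left[1 + (dZ/dY)^2\right]^{3/2}},}
#' from the measured depth graph `Z(Y)`. Derivatives use 3-point central
#' finite differences with non-uniform-spacing weights on the (optionally
#' Gaussian-presmoothed) depth sequence. With the package's axis convention
#' (Z toward the camera) a concave depression -- the posterior median
#' furrow -- yields `K > 0`.
#'
#' @param profile A data frame with columns `y`, `z` and optionally `valid`
#'   (e.g. from [profile_samples()]), `y` strictly increasing within each
#'   valid run.
#' @param presmooth_sigma SD (in samples) of the 1-D Gaussian applied to `Z`
#'   before differentiation; 0 disables. Second derivatives amplify the
#'   ~0.1 mm sensor noise, so the smoothing scale should sit well above the
#'   one-sample noise correlation length but below the ~10 mm furrow
#'   half-width; the default is 4 samples.
#' @return Numeric vector of curvature values (1/mm) aligned with the
#'   profile; `NA` at invalid samples and at the first/last sample of each
#'   valid run.
#' @export
#' @examples
#' p <- tibble::tibble(y = -30:30, z = 0.005 * (-30:30)^2)
#' k <- profile_curvature(p, presmooth_sigma = 0)
#' k[31] # ~ 0.01 = 2a at the apex of the parabola
profile_curvature <- function(profile, presmooth_sigma = 4) {
  y <- profile$y
  z <- profile$z
  ok <- if ("valid" %in% names(profile)) profile$valid else rep(TRUE, length(y))
  ok <- ok & is.finite(y) & is.finite(z)
  if (sum(ok) < 5) abort("profile curvature needs at least 5 valid samples.")
  k <- rep(NA_real_, length(y))
  for (run in valid_runs(ok)) {
    if (length(run) < 5) next
    if (any(diff(y[run]) <= 0)) abort("Y must be strictly increasing along the profile.")
    k[run] <- curvature_run(y[run], z[run], presmooth_sigma)
  }
  k
}

#' Transverse surface-curvature map of a scan
#'
#' Applies [profile_curvature()] independently to every profile row inside
#' the region of interest, yielding the curvature image in which the
#' posterior median furrow appears as a band of positive curvature (bright
#' in the conventional rendering) and convex relief as negative.
#'
#' @param scan A [back_scan()].
#' @param roi A [scan_roi()]; default the full grid.
#' @param presmooth_sigma Depth presmoothing SD in samples (see
#'   [profile_curvature()]).
#' @return An object of class `curvature_map`: the curvature grid `k`
#'   (1/mm, `NA` where not computable), the validity mask, and the source
#'   scan dimensions. Grid shape equals the scan shape; cells outside the
#'   ROI, invalid cells, their run endpoints and rows with fewer than 5
#'   valid samples are invalid.
#' @seealso [detect_auto()], [autoplot.curvature_map()]
#' @export
curvature_map <- function(scan, roi = NULL, presmooth_sigma = 4) {
  roi <- check_roi(scan, roi)
  dm <- dim(scan)
  k <- matrix(NA_real_, dm[1], dm[2])
  us <- roi$u_min:roi$u_max
  computed <- FALSE
  for (v in roi$v_min:roi$v_max) {
    ok <- scan$valid[v, us]
    if (sum(ok) < 5) next
    kv <- rep(NA_real_, length(us))
    for (run in valid_runs(ok)) {
      if (length(run) < 5) next
      y <- scan$y[v, us[run]]
      if (any(diff(y) <= 0)) abort("Y must be strictly increasing along each profile.")
      kv[run] <- curvature_run(y, scan$z[v, us[run]], presmooth_sigma)
      computed <- TRUE
    }
    k[v, us] <- kv
  }
  if (!computed) abort("no row inside the ROI has enough valid samples for curvature.")
  structure(
    list(k = k, valid = is.finite(k), roi = roi, presmooth_sigma = presmooth_sigma),
    class = "curvature_map"
  )
}

#' @export
print.curvature_map <- function(x, ...) {
  cat(sprintf(
    "<curvature_map> %d x %d grid, %d valid cells, K in [%.4g, %.4g] /mm\n",
    nrow(x$k), ncol(x$k), sum(x$valid),
    min(x$k, na.rm = TRUE), max(x$k, na.rm = TRUE)
  ))
  invisible(x)
}

#' @export
dim.curvature_map <- function(x) dim(x$k)

#' @rdname as_tibble.back_scan
#' @exportS3Method tibble::as_tibble
as_tibble.curvature_map <- function(x, ...) {
  dm <- dim(x$k)
  tibble::tibble(
    v = rep(seq_len(dm[1]), times = dm[2]),
    u = rep(seq_len(dm[2]), each = dm[1]),
    k = as.vector(x$k),
    valid = as.vector(x$valid)
  )
}
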