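new_curve2d <- function(v, u, strength, interpolated = rep(FALSE, length(v)),
                        mode = "curvature-max", roi = NULL) {
  out <- tibble::tibble(
    v = as.integer(v), u = as.numeric(u),
    strength = as.numeric(strength), interpolated = interpolated
  )
  class(out) <- c("curve2d", class(out))
  attr(out, "mode") <- mode
  attr(out, "roi") <- roi
  out
}

#' @export
print.curve2d <- function(x, ...) {
  cat(sprintf(
    "<curve2d> %s, rows %d..%d (%d samples, %d interpolated)\n",
    attr(x, "mode") %||% "?", min(x$v), max(x$v), nrow(x), sum(x$interpolated)
  ))
  NextMethod()
}

#' Sub-pixel extremum localisation by quadratic fit
#'
#' Refines a discrete extremum of a sampled sequence to sub-sample accuracy
#' by least-squares fitting a quadratic polynomial to a window of points
#' centred on the discrete extremum and returning the parabola's vertex,
#' `-b / (2a)`. If the fitted vertex falls outside the window, or the
#' quadratic opens the wrong way, the discrete extremum is returned and the
#' result is flagged unrefined.
#'
#' @param values Sampled values.
#' @param positions Strictly increasing sample positions (same length).
#' @param window Odd window size, >= 3 (clipped at the sequence ends but
#'   never below 3 points).
#' @param mode `"max"` or `"min"`: polarity of the extremum sought.
#' @return A list with `position`, `value` (of the fitted parabola at the
#'   vertex, or the discrete sample when unrefined) and `refined` (logical).
#' @export
#' @examples
#' subpixel_extremum(c(1, 3, 2), 0:2)$position # 7/6
subpixel_extremum <- function(values, positions = seq_along(values),
                              window = 5, mode = c("max", "min")) {
  mode <- match.arg(mode)
  n <- length(values)
  if (n < 3) abort("need at least 3 samples for sub-pixel refinement.")
  if (length(positions) != n) abort("`values` and `positions` must have equal length.")
  if (any(diff(positions) <= 0)) abort("`positions` must be strictly increasing.")
  if (window < 3 || window %% 2 == 0) abort("`window` must be an odd integer >= 3.")
  if (diff(range(values)) == 0) abort("no extremum: all values are equal.")
  i0 <- if (mode == "max") which.max(values) else which.min(values)
  refine_window(values, positions, i0, window, mode)
}

# quadratic LS refinement around index i0; shared with detect_rows
refine_window <- function(values, positions, i0, window, mode) {
  n <- length(values)
  half <- (window - 1) %/% 2
  idx <- max(1L, i0 - half):min(n, i0 + half)
  if (length(idx) < 3) idx <- max(1L, min(i0 - 1L, n - 2L)) + 0:2
  p <- positions[idx]
  f <- values[idx]
  pc <- p - p[ceiling(length(p) / 2)] # centre for conditioning
  X <- cbind(1, pc, pc^2)
  cf <- tryCatch(qr.solve(crossprod(X), crossprod(X, f)), error = function(e) NULL)
  fallback <- list(position = positions[i0], value = values[i0], refined = FALSE)
  if (is.null(cf)) {
    return(fallback)
  }
  a <- cf[3]
  b <- cf[2]
  wrong_sign <- (mode == "max" && a >= 0) || (mode == "min" && a <= 0)
  if (wrong_sign || a == 0) {
    return(fallback)
  }
  vtx <- -b / (2 * a)
  if (vtx < min(pc) || vtx > max(pc)) {
    return(fallback)
  }
  list(
    position = vtx + p[ceiling(length(p) / 2)],
    value = as.numeric(cf[1] + b * vtx + a * vtx^2),
    refined = TRUE
  )
}

#' Per-row extremum detection
#'
#' Scans every grid row inside the ROI for local extrema of the requested
#' polarity and reports each accepted extremum with sub-pixel position.
#' In `"curvature-max"` mode an extremum is accepted when its curvature
#' strictly exceeds `threshold` (the working threshold is zero, so every
#' concave ridge becomes a candidate); `strength` is the curvature value.
#' In `"intensity-min"` mode a brightness minimum is accepted when the
#' brightness lies strictly below `threshold`; `strength` is
#' `1 - brightness` at the minimum.
#'
#' @param map_values A [curvature_map()], or a numeric matrix (brightness or
#'   curvature grid) with `NA` marking invalid cells.
#' @param roi A [scan_roi()]; default the full grid.
#' @param mode `"curvature-max"` or `"intensity-min"`.
#' @param threshold Acceptance threshold (see above).
#' @param window Odd sub-pixel refinement window (see
#'   [subpixel_extremum()]).
#' @return A tibble with one row per detection: `v`, `u` (sub-pixel),
#'   `strength`, `refined`.
#' @export
detect_rows <- function(map_values, roi = NULL,
                        mode = c("curvature-max", "intensity-min"),
                        threshold = 0, window = 5) {
  mode <- match.arg(mode)
  m <- if (inherits(map_values, "curvature_map")) map_values$k else map_values
  if (!is.matrix(m)) abort("`map_values` must be a matrix or a curvature_map.")
  dmf <- dim(m)
  roi <- if (is.null(roi)) scan_roi(1, dmf[1], 1, dmf[2]) else roi
  if (roi$v_max > dmf[1] || roi$u_max > dmf[2]) abort("ROI exceeds the grid.")
  us <- roi$u_min:roi$u_max
  out <- vector("list", roi$v_max - roi$v_min + 1L)
  for (v in roi$v_min:roi$v_max) {
    row <- m[v, us]
    dets <- detect_in_row(row, mode, threshold, window)
    if (nrow(dets)) {
      dets$v <- v
      dets$u <- dets$u + roi$u_min - 1
      out[[v - roi$v_min + 1L]] <- dets
    }
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) {
    res <- tibble::tibble(
      v = integer(), u = numeric(), strength = numeric(), refined = logical()
    )
  }
  dplyr::select(res, "v", "u", "strength", "refined")
}

detect_in_row <- function(row, mode, threshold, window) {
  empty <- tibble::tibble(u = numeric(), strength = numeric(), refined = logical())
  ok <- is.finite(row)
  hits <- list()
  for (run in valid_runs(ok)) {
    if (length(run) < 3) next
    f <- row[run]
    sgn <- if (mode == "curvature-max") 1 else -1
    g <- sgn * f
    n <- length(g)
    loc <- which(g[2:(n - 1)] > g[1:(n - 2)] & g[2:(n - 1)] > g[3:n]) + 1L
    for (i in loc) {
      val <- f[i]
      accept <- if (mode == "curvature-max") val > threshold else val < threshold
      if (!accept) next
      ref <- refine_window(g, seq_len(n), i, window, "max")
      strength <- if (mode == "curvature-max") sgn * ref$value else 1 - (-ref$value)
      hits[[length(hits) + 1L]] <- tibble::tibble(
        u = ref$position + run[1] - 1, strength = strength, refined = ref$refined
      )
    }
  }
  if (!length(hits)) {
    return(empty)
  }
  out <- dplyr::bind_rows(hits)
  # two extrema inside one refinement window are a single unresolvable
  # feature (noise can split a peak): keep the stronger of any pair closer
  # than the refinement half-window
  min_sep <- (window - 1) / 2
  out <- out[order(-out$strength), ]
  keep <- rep(TRUE, nrow(out))
  for (j in seq_len(nrow(out))[-1]) {
    if (any(abs(out$u[j] - out$u[keep & seq_len(nrow(out)) < j]) < min_sep)) keep[j] <- FALSE
  }
  out <- out[keep, ]
  out[order(out$u), ]
}

#' Link per-row detections into candidate curves
#'
#' Greedy row-by-row association: proceeding down the rows, each detection
#' joins the open candidate whose last position is laterally nearest and
#' within `max_jump` columns (and not more than `max_gap` rows stale);
#' otherwise it opens a new candidate. Row gaps up to `max_gap` are bridged
#' by linear interpolation (bridged rows are flagged and carry `NA`
#' strength). Candidates covering fewer than `min_length` rows are
#' discarded. The result is the family of possible spine-curve candidates
#' from which one is picked by a seed point ([select_curve()]).
#'
#' @param detections Detection tibble from [detect_rows()].
#' @param max_jump Maximum lateral step between linked detections (columns).
#' @param max_gap Maximum number of missing rows bridged inside a candidate.
#' @param min_length Minimum covered rows for a candidate to be kept.
#' @param mode Detection mode label propagated to the curves.
#' @return A `candidate_set` tibble, sorted by decreasing length: columns
#'   `candidate`, `n_rows`, `mean_strength` and a `curve` list-column of
#'   `curve2d` tibbles.
#' @export
link_candidates <- function(detections, max_jump = 3, max_gap = 5,
                            min_length = 20, mode = "curvature-max") {
  cands <- list() # each: list(v = int vec, u = num vec, s = num vec)
  if (nrow(detections)) {
    detections <- dplyr::arrange(detections, .data$v, .data$u)
    for (vv in unique(detections$v)) {
      dets <- detections[detections$v == vv, ]
      last_v <- vapply(cands, function(cc) cc$v[length(cc$v)], numeric(1))
      last_u <- vapply(cands, function(cc) cc$u[length(cc$u)], numeric(1))
      open <- which(last_v < vv & (vv - last_v - 1) <= max_gap)
      taken <- integer()
      # nearest-first assignment so close pairs win conflicts deterministically
      if (length(open) && nrow(dets)) {
        dist <- abs(outer(dets$u, last_u[open], "-"))
        ord <- order(dist)
        assigned_det <- rep(FALSE, nrow(dets))
        for (k in ord) {
          if (dist[k] > max_jump) break
          di <- (k - 1) %% nrow(dets) + 1
          ci <- open[(k - 1) %/% nrow(dets) + 1]
          if (assigned_det[di] || ci %in% taken) next
          cands[[ci]]$v <- c(cands[[ci]]$v, vv)
          cands[[ci]]$u <- c(cands[[ci]]$u, dets$u[di])
          cands[[ci]]$s <- c(cands[[ci]]$s, dets$strength[di])
          assigned_det[di] <- TRUE
          taken <- c(taken, ci)
        }
        dets <- dets[!assigned_det, ]
      }
      for (di in seq_len(nrow(dets))) {
        cands[[length(cands) + 1L]] <- list(
          v = vv, u = dets$u[di], s = dets$strength[di]
        )
      }
    }
  }
  curves <- lapply(cands, function(cc) {
    vs <- cc$v[1]:cc$v[length(cc$v)]
    u <- if (length(cc$v) == 1) cc$u else approx(cc$v, cc$u, xout = vs, ties = "ordered")$y
    s <- rep(NA_real_, length(vs))
    s[match(cc$v, vs)] <- cc$s
    new_curve2d(vs, u, s, interpolated = !(vs %in% cc$v), mode = mode)
  })
  keep <- vapply(curves, nrow, integer(1)) >= min_length
  curves <- curves[keep]
  out <- tibble::tibble(
    candidate = seq_along(curves),
    n_rows = vapply(curves, nrow, integer(1)),
    mean_strength = vapply(
      curves,
      function(cv) mean(cv$strength, na.rm = TRUE), numeric(1)
    ),
    curve = curves
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$n_rows))
  out$candidate <- seq_len(nrow(out))
  class(out) <- c("candidate_set", class(out))
  out
}

#' Select a candidate curve by a seed point
#'
#' Replaces the operator's single mouse click of the interactive workflow
#' with an explicit image-coordinate seed: the candidate whose polyline lies
#' nearest (perpendicular distance) to the seed point wins; ties are broken
#' by greater length, then greater mean strength.
#'
#' @param candidates A `candidate_set` from [link_candidates()] /
#'   [detect_auto()].
#' @param seed_uv Numeric `c(u, v)` seed point in image coordinates.
#' @return The selected `curve2d`.
#' @export
select_curve <- function(candidates, seed_uv) {
  if (!nrow(candidates)) abort("empty candidate set: nothing to select from.")
  if (length(seed_uv) != 2) abort("`seed_uv` must be c(u, v).")
  d <- vapply(
    candidates$curve,
    function(cv) point_polyline_dist(seed_uv[1], seed_uv[2], cv$u, cv$v),
    numeric(1)
  )
  ord <- order(
    round(d, 9), -candidates$n_rows, -candidates$mean_strength
  )
  candidates$curve[[ord[1]]]
}

point_polyline_dist <- function(pu, pv, us, vs) {
  if (length(us) == 1) {
    return(sqrt((pu - us)^2 + (pv - vs)^2))
  }
  au <- us[-length(us)]
  av <- vs[-length(vs)]
  bu <- us[-1]
  bv <- vs[-1]
  du <- bu - au
  dv <- bv - av
  len2 <- du^2 + dv^2
  t <- pmin(1, pmax(0, ((pu - au) * du + (pv - av) * dv) / pmax(len2, 1e-12)))
  min(sqrt((pu - (au + t * du))^2 + (pv - (av + t * dv))^2))
}

# separable Gaussian smoothing of a matrix with validity renormalisation,
# fixed odd kernel size (7 x 7 for the marker image)
gauss_smooth2d <- function(m, valid, size = 7, sigma = 1.5) {
  r <- (size - 1) %/% 2
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  w <- matrix(0, nrow(m), ncol(m))
  w[valid] <- 1
  mv <- m
  mv[!valid] <- 0
  conv1 <- function(vec) {
    as.numeric(stats::filter(c(rep(0, r), vec, rep(0, r)), k, sides = 2))[(r + 1):(r + length(vec))]
  }
  pass <- function(mat) {
    tmp <- t(apply(mat, 1, conv1)) # along u
    apply(tmp, 2, conv1) # along v
  }
  num <- pass(mv)
  den <- pass(w)
  out <- num / den
  out[den <= 0] <- NA_real_
  out
}

#' Manual (marker-line) curve detection
#'
#' Extracts the reference spine curve from the brightness channel carrying
#' the dark marker line drawn over the palpated spinous processes. The
#' brightness image is smoothed with a 7 x 7 Gaussian kernel to suppress the
#' wide high-contrast marking, then the global intensity minimum of each row
#' is accepted when it lies below `intensity_threshold` and refined to
#' sub-pixel position by quadratic fit. Rows without an accepted minimum
#' (between the first and last accepted rows) are filled by 1-D linear
#' interpolation, yielding a continuous 2D curve in image coordinates.
#'
#' @param scan A [back_scan()] with a brightness channel.
#' @param roi A [scan_roi()]; default the full grid.
#' @param intensity_threshold Acceptance cut on the normalised `[0, 1]`
#'   scale: the row's smoothed minimum must dip more than this far below the
#'   row's background level (its median smoothed brightness). Useful
#'   settings range over 0.08--0.15; default 0.10. The cut is
#'   background-relative because smoothing necessarily raises the dip
#'   bottom of a marker of finite contrast, so an absolute cut would reject
#'   legitimate markers of moderate contrast while the relative cut keeps
#'   the same working range on images whose background is near 1.
#' @param window Odd sub-pixel refinement window.
#' @param kernel_sigma SD (samples) of the 7 x 7 Gaussian; default 1.5 so
#'   the kernel is effectively supported in 7 x 7.
#' @return A `curve2d` in `intensity-min` mode (`strength` is
#'   `1 - brightness`).
#' @export
detect_manual <- function(scan, roi = NULL, intensity_threshold = 0.10,
                          window = 5, kernel_sigma = 1.5) {
  roi <- check_roi(scan, roi)
  sm <- gauss_smooth2d(scan$brightness, scan$valid, size = 7, sigma = kernel_sigma)
  us <- roi$u_min:roi$u_max
  acc_v <- integer()
  acc_u <- numeric()
  acc_s <- numeric()
  for (v in roi$v_min:roi$v_max) {
    row <- sm[v, us]
    ok <- is.finite(row) & scan$valid[v, us]
    if (sum(ok) < 3) next
    row[!ok] <- NA_real_
    i0 <- which.min(row)
    background <- median(row, na.rm = TRUE)
    if (is.na(row[i0]) || (background - row[i0]) <= intensity_threshold) next
    run <- valid_runs(is.finite(row))
    run <- run[[which(vapply(run, function(r) i0 %in% r, logical(1)))]]
    if (length(run) < 3) next
    ref <- refine_window(row[run], seq_along(run), match(i0, run), window, "min")
    acc_v <- c(acc_v, v)
    acc_u <- c(acc_u, ref$position + run[1] - 1 + roi$u_min - 1)
    acc_s <- c(acc_s, 1 - ref$value)
  }
  if (!length(acc_v)) {
    abort(sprintf(
      "no row has a smoothed brightness minimum below %.3g: no marker line detected.",
      intensity_threshold
    ))
  }
  vs <- acc_v[1]:acc_v[length(acc_v)]
  u <- approx(acc_v, acc_u, xout = vs, ties = "ordered")$y
  s <- rep(NA_real_, length(vs))
  s[match(acc_v, vs)] <- acc_s
  new_curve2d(vs, u, s,
    interpolated = !(vs %in% acc_v),
    mode = "intensity-min", roi = roi
  )
}

#' Automatic (surface-curvature) curve detection
#'
#' The fully automatic detection chain: transverse curvature map
#' ([curvature_map()]), per-row curvature maxima above a zero threshold
#' ([detect_rows()]), and greedy linking into candidate curves
#' ([link_candidates()]). The zero threshold deliberately keeps every
#' concave ridge, so the result is the whole candidate family; pick the
#' spine curve with [select_curve()] and a midline seed point.
#' Deterministic for fixed input and parameters.
#'
#' @inheritParams curvature_map
#' @inheritParams link_candidates
#' @param threshold Curvature acceptance threshold (1/mm); the working
#'   value is 0.
#' @param window Odd sub-pixel refinement window.
#' @return A `candidate_set` (see [link_candidates()]).
#' @export
#' @examples
#' sim <- generate_scan(synthetic_spec(n_rows = 80, n_cols = 60, seed = 7))
#' cands <- detect_auto(sim$scan)
#' spine <- select_curve(cands, seed_uv = c(ncol(sim$scan$z) / 2, nrow(sim$scan$z) / 2))
detect_auto <- function(scan, roi = NULL, presmooth_sigma = 4, threshold = 0,
                        window = 5, max_jump = 3, max_gap = 5, min_length = 20) {
  roi <- check_roi(scan, roi)
  km <- curvature_map(scan, roi, presmooth_sigma)
  dets <- detect_rows(km, roi,
    mode = "curvature-max",
    threshold = threshold, window = window
  )
  link_candidates(dets,
    max_jump = max_jump, max_gap = max_gap,
    min_length = min_length, mode = "curvature-max"
  )
}
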