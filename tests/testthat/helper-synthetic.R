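# small but fully featured synthetic back for fast unit tests
small_spec <- function(seed = 1, n_rows = 150, n_cols = 100, ...) {
  synthetic_spec(n_rows = n_rows, n_cols = n_cols, ..., seed = seed)
}

# operator emulation: seed point on the visibly strongest curvature band at
# mid-height, then the usual select -> lift -> smooth chain
auto_spine_curve <- function(scan, presmooth_sigma = 4, smooth = TRUE) {
  km <- curvature_map(scan, presmooth_sigma = presmooth_sigma)
  mid <- round(nrow(scan$z) / 2)
  seed_u <- which.max(km$k[mid, ])
  cands <- link_candidates(detect_rows(km, mode = "curvature-max"))
  sel <- select_curve(cands, c(seed_u, mid))
  out <- lift_curve(scan, sel)
  if (smooth) out <- smooth_curve(out)
  out
}

# tiny hand-built scan: flat tilted plate on a regular grid
plate_scan <- function(nr = 6, nc = 7, spacing = 0.9) {
  back_scan(
    x = matrix((seq_len(nr) - 1) * spacing, nr, nc),
    y = matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE),
    z = matrix(5, nr, nc),
    brightness = matrix(0.5, nr, nc)
  )
}

expect_scan_equal <- function(a, b, tol = 1e-6) {
  expect_identical(dim(a), dim(b))
  expect_identical(a$valid, b$valid)
  ok <- a$valid
  expect_lte(max(abs(a$x[ok] - b$x[ok])), tol)
  expect_lte(max(abs(a$y[ok] - b$y[ok])), tol)
  expect_lte(max(abs(a$z[ok] - b$z[ok])), tol)
  expect_lte(max(abs(a$brightness[ok] - b$brightness[ok])), tol)
}
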