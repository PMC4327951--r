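#' Read an ordered back-surface scan from disk
#'
#' Supports two on-disk layouts:
#' \describe{
#'   \item{`ply`}{Standard PLY, ASCII or binary little-endian, with vertex
#'     properties `x`, `y`, `z`, `intensity` (doubles) and `valid` (uchar).
#'     The grid shape is declared in header comments
#'     `grid_rows R`, `grid_cols C` and `profile_spacing_mm S`; vertices are
#'     stored row-major (all samples of profile 1, then profile 2, ...).}
#'   \item{`grid-text`}{A human-diffable whitespace-delimited format with a
#'     two-line header (`spinescan-grid R C` and `profile_spacing_mm S`)
#'     followed by `R * C` data lines `x y z brightness valid` in the same
#'     row-major order.}
#' }
#'
#' Brightness stored on another scale (e.g. 8-bit 0--255) is min--max
#' normalised to `[0, 1]` over the valid cells at load time; values already
#' in `[0, 1]` are left untouched. Cells flagged invalid in the file stay
#' invalid.
#'
#' @param path File to read.
#' @param format `"auto"` (sniff the first line), `"ply"` or `"grid-text"`.
#' @return A [back_scan()].
#' @seealso [write_scan()]
#' @export
read_scan <- function(path, format = c("auto", "ply", "grid-text")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("scan file not found: '%s'", path))
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (identical(first, "ply")) "ply" else "grid-text"
  }
  switch(format,
    "ply" = read_scan_ply(path),
    "grid-text" = read_scan_gridtext(path)
  )
}

#' Write an ordered back-surface scan to disk
#'
#' @param scan A [back_scan()].
#' @param path Output file.
#' @param format `"ply"` or `"grid-text"` (see [read_scan()] for the layouts).
#' @param ply_encoding For PLY output, `"ascii"` or `"binary"`
#'   (binary little-endian).
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path, format = c("ply", "grid-text"),
                       ply_encoding = c("ascii", "binary")) {
  if (!is.character(format) || !format[1] %in% c("ply", "grid-text")) {
    abort(sprintf("unsupported scan format '%s' (use \"ply\" or \"grid-text\").", format[1]))
  }
  format <- match.arg(format)
  ply_encoding <- match.arg(ply_encoding)
  validate_back_scan(scan)
  switch(format,
    "ply" = write_scan_ply(scan, path, ply_encoding),
    "grid-text" = write_scan_gridtext(scan, path)
  )
  invisible(path)
}

# row-major flattening: profile v = 1 first, u running fastest
flatten_scan <- function(scan) {
  fin <- function(m) {
    m[!is.finite(m)] <- 0
    m
  }
  cbind(
    as.vector(t(fin(scan$x))), as.vector(t(fin(scan$y))),
    as.vector(t(fin(scan$z))), as.vector(t(fin(scan$brightness)))
  )
}

unflatten_scan <- function(vals, valid, nr, nc, spacing, meta) {
  shape <- function(i) matrix(vals[, i], nr, nc, byrow = TRUE)
  b <- shape(4)
  vm <- matrix(as.logical(valid), nr, nc, byrow = TRUE)
  bv <- b[vm]
  if (length(bv) && (min(bv) < 0 || max(bv) > 1)) {
    rng <- range(bv)
    b <- if (rng[2] > rng[1]) (b - rng[1]) / (rng[2] - rng[1]) else b * 0 + 1
  }
  back_scan(
    x = shape(1), y = shape(2), z = shape(3), brightness = b, valid = vm,
    profile_spacing_mm = spacing, metadata = meta
  )
}

write_scan_ply <- function(scan, path, encoding) {
  dm <- dim(scan)
  n <- dm[1] * dm[2]
  header <- c(
    "ply",
    sprintf("format %s 1.0", if (encoding == "ascii") "ascii" else "binary_little_endian"),
    "comment spinescan ordered back-surface scan",
    sprintf("comment grid_rows %d grid_cols %d", dm[1], dm[2]),
    sprintf("comment profile_spacing_mm %.9g", scan$profile_spacing_mm),
    sprintf("element vertex %d", n),
    "property double x",
    "property double y",
    "property double z",
    "property double intensity",
    "property uchar valid",
    "end_header"
  )
  vals <- flatten_scan(scan)
  vmask <- as.integer(as.vector(t(scan$valid)))
  if (encoding == "ascii") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(
      sprintf(
        "%.9f %.9f %.9f %.9f %d",
        vals[, 1], vals[, 2], vals[, 3], vals[, 4], vmask
      ),
      con
    )
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con)
    body <- rbind(
      matrix(writeBin(as.vector(t(vals)), raw(), size = 8, endian = "little"), nrow = 32),
      as.raw(vmask)
    )
    writeBin(as.vector(body), con)
  }
  invisible(path)
}

read_scan_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) abort(sprintf("'%s': PLY header has no end_header line.", path))
    header <- c(header, line)
    if (identical(line, "end_header")) break
  }
  if (!identical(header[1], "ply")) abort(sprintf("'%s' is not a PLY file.", path))
  fmt <- sub("^format (\\S+).*", "\\1", grep("^format ", header, value = TRUE)[1])
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    abort(sprintf("unsupported PLY format '%s'.", fmt))
  }
  n <- as.integer(sub("^element vertex (\\d+).*", "\\1", grep("^element vertex ", header, value = TRUE)[1]))
  gl <- grep("^comment grid_rows ", header, value = TRUE)
  if (!length(gl)) abort(sprintf("'%s': missing 'comment grid_rows R grid_cols C' header.", path))
  gv <- as.integer(strsplit(gl[1], "\\s+")[[1]][c(3, 5)])
  nr <- gv[1]
  nc <- gv[2]
  if (nr * nc != n) {
    abort(sprintf(
      "'%s': header declares a %d x %d grid but %d vertices.", path, nr, nc, n
    ))
  }
  sl <- grep("^comment profile_spacing_mm ", header, value = TRUE)
  spacing <- if (length(sl)) as.numeric(strsplit(sl[1], "\\s+")[[1]][3]) else NULL
  props <- sub("^property \\S+ ", "", grep("^property ", header, value = TRUE))
  has_valid <- "valid" %in% props
  ncol_num <- sum(props != "valid")
  if (fmt == "ascii") {
    dat <- matrix(scan(con, quiet = TRUE, n = n * length(props)),
      nrow = n, byrow = TRUE
    )
    vals <- dat[, seq_len(ncol_num), drop = FALSE]
    valid <- if (has_valid) dat[, ncol_num + 1] else rep(1, n)
  } else {
    stride <- 8L * ncol_num + if (has_valid) 1L else 0L
    raw <- readBin(con, "raw", n = n * stride)
    if (length(raw) < n * stride) abort(sprintf("'%s': truncated PLY body.", path))
    m <- matrix(raw, nrow = stride)
    vals <- matrix(
      readBin(as.vector(m[seq_len(8L * ncol_num), , drop = FALSE]),
        "double",
        n = n * ncol_num, size = 8, endian = "little"
      ),
      nrow = n, byrow = TRUE
    )
    valid <- if (has_valid) as.integer(m[stride, ]) else rep(1, n)
  }
  if (ncol_num < 4) vals <- cbind(vals, matrix(1, n, 4 - ncol_num))
  unflatten_scan(vals, valid, nr, nc, spacing,
    meta = list(source = basename(path), format = "ply")
  )
}

write_scan_gridtext <- function(scan, path) {
  dm <- dim(scan)
  vals <- flatten_scan(scan)
  vmask <- as.integer(as.vector(t(scan$valid)))
  lines <- c(
    sprintf("spinescan-grid %d %d", dm[1], dm[2]),
    sprintf("profile_spacing_mm %.9g", scan$profile_spacing_mm),
    sprintf(
      "%.9f %.9f %.9f %.9f %d",
      vals[, 1], vals[, 2], vals[, 3], vals[, 4], vmask
    )
  )
  writeLines(lines, path)
  invisible(path)
}

read_scan_gridtext <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || !startsWith(lines[1], "spinescan-grid")) {
    abort(sprintf("'%s' is not a spinescan grid-text file.", path))
  }
  hd <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]][2:3])
  nr <- hd[1]
  nc <- hd[2]
  spacing <- as.numeric(strsplit(trimws(lines[2]), "\\s+")[[1]][2])
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nr * nc) {
    abort(sprintf(
      "'%s': header declares a %d x %d grid (%d points) but file has %d data lines.",
      path, nr, nc, nr * nc, length(body)
    ))
  }
  dat <- matrix(scan(text = body, quiet = TRUE), nrow = nr * nc, byrow = TRUE)
  if (ncol(dat) != 5) abort(sprintf("'%s': expected 5 columns (x y z brightness valid).", path))
  unflatten_scan(dat[, 1:4, drop = FALSE], dat[, 5], nr, nc, spacing,
    meta = list(source = basename(path), format = "grid-text")
  )
}

#' Read and write detected curves
#'
#' Image-space curves ([detect_auto()] / [detect_manual()] output) are stored
#' as 3-column whitespace text `v u strength` (strength is `NaN` on rows
#' bridged by interpolation); spatial curves as 4-column text
#' `x y z smoothed` after a one-line `#` header recording mode/provenance.
#'
#' @param curve A `curve2d` or `curve3d` tibble.
#' @param path File path.
#' @return Readers return the curve tibble; writers return `path` invisibly.
#' @name curve_io
NULL

#' @rdname curve_io
#' @export
write_curve2d <- function(curve, path) {
  hdr <- sprintf("# spinescan curve2d mode=%s", attr(curve, "mode") %||% "unknown")
  writeLines(
    c(hdr, sprintf("%d %.9f %.9g", curve$v, curve$u, curve$strength)),
    path
  )
  invisible(path)
}

#' @rdname curve_io
#' @export
read_curve2d <- function(path) {
  if (!file.exists(path)) abort(sprintf("curve file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  mode <- "unknown"
  if (length(lines) && startsWith(lines[1], "#")) {
    m <- regmatches(lines[1], regexpr("mode=\\S+", lines[1]))
    if (length(m)) mode <- sub("mode=", "", m)
    lines <- lines[-1]
  }
  dat <- matrix(scan(text = lines, quiet = TRUE), ncol = 3, byrow = TRUE)
  new_curve2d(
    v = as.integer(dat[, 1]), u = dat[, 2], strength = dat[, 3],
    interpolated = !is.finite(dat[, 3]), mode = mode
  )
}

#' @rdname curve_io
#' @export
write_curve3d <- function(curve, path) {
  hdr <- sprintf(
    "# spinescan curve3d provenance=%s",
    attr(curve, "provenance") %||% "unknown"
  )
  sm <- as.integer(isTRUE(attr(curve, "smoothed")))
  writeLines(
    c(hdr, sprintf("%.9f %.9f %.9f %d", curve$x, curve$y, curve$z, sm)),
    path
  )
  invisible(path)
}

#' @rdname curve_io
#' @export
read_curve3d <- function(path) {
  if (!file.exists(path)) abort(sprintf("curve file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  prov <- "unknown"
  if (length(lines) && startsWith(lines[1], "#")) {
    m <- regmatches(lines[1], regexpr("provenance=\\S+", lines[1]))
    if (length(m)) prov <- sub("provenance=", "", m)
    lines <- lines[-1]
  }
  dat <- matrix(scan(text = lines, quiet = TRUE), ncol = 4, byrow = TRUE)
  new_curve3d(
    x = dat[, 1], y = dat[, 2], z = dat[, 3],
    smoothed = any(dat[, 4] > 0), provenance = prov
  )
}
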