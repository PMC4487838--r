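# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# 1-based cyclic frame index
cyc <- function(i, n) ((i - 1L) %% n) + 1L

# frames walking forward (cyclically) from `from` to `to`, both inclusive
cyc_seq <- function(from, to, n) {
  if (from <= to) seq.int(from, to) else c(seq.int(from, n), seq.int(1L, to))
}

# frames strictly between `from` and `to`, walking forward cyclically
cyc_between <- function(from, to, n) {
  s <- cyc_seq(from, to, n)
  if (length(s) <= 2L) integer(0) else s[-c(1L, length(s))]
}

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)

# Bilinear interpolation of a matrix at (possibly fractional) row/col
# positions. Coordinates are clamped to the image; `clamped` attribute
# reports whether any sample fell outside.
bilinear_sample <- function(img, rows, cols) {
  nr <- nrow(img); nc <- ncol(img)
  clamped <- any(rows < 1 | rows > nr | cols < 1 | cols > nc)
  r <- pmin(pmax(rows, 1), nr)
  c <- pmin(pmax(cols, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  v00 <- img[cbind(r0, c0)]
  v10 <- img[cbind(r0 + 1, c0)]
  v01 <- img[cbind(r0, c0 + 1)]
  v11 <- img[cbind(r0 + 1, c0 + 1)]
  out <- v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
    v01 * (1 - fr) * fc + v11 * fr * fc
  attr(out, "clamped") <- clamped
  out
}

# mm <-> pixel index (pixel i has its centre at (i - 0.5) * spacing)
mm_to_px <- function(x_mm, spacing_mm) x_mm / spacing_mm + 0.5
px_to_mm <- function(i_px, spacing_mm) (i_px - 0.5) * spacing_mm

# FNV-1a 32-bit hash of a character scalar, as 8 hex digits. Used to stamp
# output artifacts with a configuration fingerprint.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x1f"))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte (b < 256); keeps h a plain double
    low <- h %% 256
    h <- (h - low) + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit modular multiply by the FNV prime 16777619 = 2^24 + 403,
    # split so every intermediate stays exactly representable in a double
    h <- ((h %% 256) * 16777216 + h * 403) %% 4294967296
  }
  h <- h %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# polyline arc length (open)
polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

# Resample an open polyline to (approximately) equal arc-length spacing,
# preserving the endpoints (mitral-annulus anchors). Point count is chosen
# from the total length and requested spacing.
resample_polyline <- function(pts, spacing_mm = 2, n_points = NULL) {
  stopifnot(is.matrix(pts), ncol(pts) == 2, nrow(pts) >= 2)
  seg <- sqrt(rowSums(diff(pts)^2))
  keep <- c(TRUE, seg > 0)
  pts <- pts[keep, , drop = FALSE]
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  n <- n_points %||% max(3L, round(L / spacing_mm) + 1L)
  si <- seq(0, L, length.out = n)
  x <- stats::approx(s, pts[, 1], xout = si)$y
  y <- stats::approx(s, pts[, 2], xout = si)$y
  cbind(x = x, y = y)
}
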