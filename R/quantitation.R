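# LA volumetry, phase detection, ejection fractions, strain and
# strain-rate peaks.
#
# Conventions: the open endocardial polyline is closed by the straight
# mitral-annulus chord for area computation; the chamber length is the
# perpendicular distance from the chord midpoint to the farthest contour
# point (the atrial roof); strain is referenced to the minimum-volume
# frame, so the reservoir peak is positive; mm^3 are converted to ml
# (divide by 1000) inside the volume operations only.

# segment-intersection test for polygon simplicity (non-adjacent pairs)
polygon_is_simple <- function(pts) {
  n <- nrow(pts)
  if (n < 4) return(TRUE)
  p1 <- pts
  p2 <- pts[c(2:n, 1), , drop = FALSE]
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    j <- seq.int(i + 2, n)
    j <- j[!(i == 1 & j == n)]  # skip adjacent (wrapping) pair
    if (!length(j)) next
    d1 <- cross(p1[i, 1], p1[i, 2], p2[i, 1], p2[i, 2], p1[j, 1], p1[j, 2])
    d2 <- cross(p1[i, 1], p1[i, 2], p2[i, 1], p2[i, 2], p2[j, 1], p2[j, 2])
    d3 <- cross(p1[j, 1], p1[j, 2], p2[j, 1], p2[j, 2], rep(p1[i, 1], length(j)),
                rep(p1[i, 2], length(j)))
    d4 <- cross(p1[j, 1], p1[j, 2], p2[j, 1], p2[j, 2], rep(p2[i, 1], length(j)),
                rep(p2[i, 2], length(j)))
    hit <- (d1 * d2 < 0) & (d3 * d4 < 0)
    if (any(hit)) return(FALSE)
  }
  TRUE
}

#' Contour area (annulus-chord closure)
#'
#' Shoelace area of the polygon formed by the open endocardial polyline
#' closed with the straight chord between its two mitral-annulus anchors.
#' The result is orientation-normalized (always positive).
#'
#' @param points n x 2 matrix of `(x, y)` in mm (or a list with `$points`).
#' @param check_simple Verify the closed polygon is non-self-intersecting.
#' @return Area in mm^2.
#' @examples
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' contour_area(sq)  # 1
#' @export
contour_area <- function(points, check_simple = TRUE) {
  if (is.list(points) && !is.null(points$points)) points <- points$points
  stop_if(!is.matrix(points) || ncol(points) != 2 || nrow(points) < 3,
          "need an n x 2 point matrix with n >= 3")
  if (check_simple && !polygon_is_simple(points))
    stop("contour polygon is self-intersecting", call. = FALSE)
  x <- points[, 1]; y <- points[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Chamber length
#'
#' Perpendicular distance from the midpoint of the mitral-annulus chord
#' (the segment joining the first and last contour points) to the farthest
#' contour point, i.e. the annulus-to-roof length used by the area-length
#' method. Invariant under rigid motion of the contour.
#'
#' @param points n x 2 matrix of `(x, y)` in mm (or a list with `$points`).
#' @return Length in mm.
#' @export
chamber_length <- function(points) {
  if (is.list(points) && !is.null(points$points)) points <- points$points
  stop_if(!is.matrix(points) || ncol(points) != 2 || nrow(points) < 3,
          "need an n x 2 point matrix with n >= 3")
  a <- points[1, ]; b <- points[nrow(points), ]
  v <- b - a
  nv <- sqrt(sum(v^2))
  stop_if(nv < 1e-9, "degenerate annulus chord: anchors coincide")
  nrm <- c(-v[2], v[1]) / nv
  mid <- (a + b) / 2
  max(abs((points[, 1] - mid[1]) * nrm[1] + (points[, 2] - mid[2]) * nrm[2]))
}

#' Biplane area-length LA volume
#'
#' `V = 0.848 * A_4ch * A_2ch / ((L_2ch + L_4ch) / 2)`, with areas in mm^2
#' and lengths in mm, converted to ml. The constant 0.848 is the printed
#' rounding of `8 / (3 * pi) = 0.84883`, so the formula matches the exact
#' ellipsoid volume to within 0.15%.
#'
#' @param area_2ch,area_4ch Cross-sectional areas, mm^2.
#' @param len_2ch,len_4ch Annulus-to-roof lengths, mm.
#' @return Volume in ml. Vectorized over frames.
#' @examples
#' biplane_volume(pi * 40 * 20, pi * 40 * 25, 80, 80)  # ~83.7 ml
#' @export
biplane_volume <- function(area_2ch, area_4ch, len_2ch, len_4ch) {
  stop_if(any(c(area_2ch, area_4ch, len_2ch, len_4ch) <= 0),
          "areas and lengths must be positive")
  0.848 * area_4ch * area_2ch / ((len_2ch + len_4ch) / 2) / 1000
}

#' Simpson's (rule of disks) LA volume
#'
#' Sum of short-axis cross-sectional areas times the slice spacing
#' (thickness plus inter-slice gap), converted to ml.
#'
#' @param slice_areas Areas per slice, mm^2.
#' @param thickness_mm Slice thickness (default 8 mm).
#' @param gap_mm Inter-slice gap (default 2 mm).
#' @return Volume in ml.
#' @examples
#' simpson_volume(c(1000, 1000, 1000))  # 30 ml
#' @export
simpson_volume <- function(slice_areas, thickness_mm = 8, gap_mm = 2) {
  stop_if(length(slice_areas) < 1, "need at least one slice")
  stop_if(any(slice_areas < 0), "slice areas must be non-negative")
  stop_if(thickness_mm < 0 || gap_mm < 0, "thickness and gap must be >= 0")
  sum(slice_areas) * (thickness_mm + gap_mm) / 1000
}

#' Per-frame biplane volume curve
#'
#' @param cs_2ch,cs_4ch Tracked `la_contour_sequence`s of the two long-axis
#'   views (equal frame counts).
#' @param time_ms Optional per-frame times; defaults to the contour
#'   sequences' frame interval.
#' @return An object of class `la_volume_curve` with `volume_ml`,
#'   `time_ms`, `method = "biplane"`.
#' @export
volume_curve <- function(cs_2ch, cs_4ch, time_ms = NULL) {
  n <- length(cs_2ch$contours)
  stop_if(n != length(cs_4ch$contours),
          "frame-count mismatch between views")
  if (is.null(time_ms)) {
    dt <- cs_2ch$frame_interval_ms %||% cs_4ch$frame_interval_ms %||% 1
    time_ms <- (seq_len(n) - 1) * dt
  }
  stop_if(length(time_ms) != n, "time_ms length must match frame count")
  v <- vapply(seq_len(n), function(t) {
    a2 <- contour_area(cs_2ch$contours[[t]], check_simple = FALSE)
    a4 <- contour_area(cs_4ch$contours[[t]], check_simple = FALSE)
    l2 <- chamber_length(cs_2ch$contours[[t]])
    l4 <- chamber_length(cs_4ch$contours[[t]])
    biplane_volume(a2, a4, l2, l4)
  }, numeric(1))
  structure(list(volume_ml = v, time_ms = time_ms, method = "biplane"),
            class = "la_volume_curve")
}

as_volume_curve <- function(volume_ml, time_ms, method = "biplane") {
  stop_if(length(volume_ml) != length(time_ms),
          "volume and time lengths differ")
  stop_if(any(volume_ml <= 0), "volumes must be positive")
  structure(list(volume_ml = volume_ml, time_ms = time_ms, method = method),
            class = "la_volume_curve")
}

#' @rdname volume_curve
#' @param x Numeric volume vector (ml).
#' @export
volume_curve_from_volumes <- function(x, time_ms,
                                      method = c("biplane", "simpson")) {
  as_volume_curve(x, time_ms, match.arg(method))
}

cyclic_central_rate <- function(y, dt) {
  n <- length(y)
  (y[cyc(seq_len(n) + 1L, n)] - y[cyc(seq_len(n) - 1L, n)]) / (2 * dt)
}

smooth3 <- function(y) {
  n <- length(y)
  (y[cyc(seq_len(n) - 1L, n)] + y + y[cyc(seq_len(n) + 1L, n)]) / 3
}

#' Volume-rate curve
#'
#' Central finite difference of the volume curve on the cyclically extended
#' cycle (the protocol's frame interval is uniform). Optional 3-point
#' moving-average smoothing, off by default.
#'
#' @param vc An `la_volume_curve` with >= 3 frames.
#' @param smooth Logical; apply the 3-frame moving average first.
#' @return Numeric vector of rates, ml/ms.
#' @export
volume_rate <- function(vc, smooth = FALSE) {
  stopifnot(inherits(vc, "la_volume_curve"))
  n <- length(vc$volume_ml)
  stop_if(n < 3, "need at least 3 frames")
  dts <- diff(vc$time_ms)
  stop_if(any(abs(dts - dts[1]) > 1e-9 * max(abs(dts))),
          "non-uniform frame times: volume_rate assumes a constant interval")
  v <- if (smooth) smooth3(vc$volume_ml) else vc$volume_ml
  cyclic_central_rate(v, dts[1])
}

#' Detect LA phase indices (Vmax, Vmin, VpreA)
#'
#' `i_max` and `i_min` are the frames of the volume maximum and minimum.
#' The pre-atrial-contraction frame `i_preA` is found where the volume
#' change is closest to zero inside the diastolic search window: the
#' cyclic interval from the early-emptying rate minimum after `i_max` up to
#' `i_min` (exclusive), or up to `p_wave_frame` (inclusive) when an ECG
#' P-wave frame is supplied. Volume change is measured as the backward
#' difference (change since the previous frame), so that the selected frame
#' is the last one before active emptying begins; near-ties within
#' `tie_tol` of the observed range resolve to the latest qualifying frame,
#' which maps an exact diastasis plateau to its final frame.
#'
#' @param vc An `la_volume_curve` spanning one full cycle.
#' @param rate Optional precomputed central-difference rate ([volume_rate()]).
#' @param p_wave_frame Optional 1-based P-wave onset frame; overrides the
#'   window's end.
#' @param tie_tol Relative tolerance (fraction of the in-window range of
#'   `|dV|`) for near-zero ties.
#' @return An object of class `la_phase_indices`: list with `i_max`,
#'   `i_min`, `i_pre_a` (1-based).
#' @examples
#' vc <- volume_curve_from_volumes(c(50, 70, 90, 100, 85, 80, 80, 80, 65, 55),
#'                                 time_ms = seq(0, by = 35, length.out = 10))
#' detect_phases(vc)  # i_max 4, i_min 10, i_preA 8 (1-based)
#' @export
detect_phases <- function(vc, rate = NULL, p_wave_frame = NULL,
                          tie_tol = 0.1) {
  stopifnot(inherits(vc, "la_volume_curve"))
  v <- vc$volume_ml
  n <- length(v)
  stop_if(n < 4, "need at least 4 frames")
  dv <- diff(v)
  stop_if(all(dv >= 0) || all(dv <= 0),
          "volume curve is monotone: no full cycle to analyse")
  i_max <- which.max(v)
  # the minimum is reached after the maximum within the displayed cycle
  # (end of active emptying); the first frames may sit at the previous
  # cycle's minimum level, so the argmin is taken after i_max
  i_min <- if (i_max < n) i_max + which.min(v[seq.int(i_max + 1L, n)])
           else which.min(v[seq_len(n - 1L)])
  if (is.null(rate)) rate <- volume_rate(vc)

  # window start: first local minimum of the rate after i_max (the
  # early/conduit emptying peak)
  cand <- cyc_between(i_max, i_min, n)
  stop_if(length(cand) < 1, "no frames between i_max and i_min")
  w0 <- cand[1]
  for (f in cand) {
    prv <- rate[cyc(f - 1L, n)]; nxt <- rate[cyc(f + 1L, n)]
    if (rate[f] <= prv && rate[f] <= nxt) { w0 <- f; break }
  }
  win <- if (!is.null(p_wave_frame)) {
    stop_if(!is_count(p_wave_frame) || p_wave_frame > n,
            "p_wave_frame out of range")
    s <- cyc_seq(w0, as.integer(p_wave_frame), n)
    s[-1]                        # exclude w0, include the P-wave frame
  } else {
    cyc_between(w0, i_min, n)    # exclusive both ends
  }
  stop_if(length(win) < 1, "empty diastolic search window")
  back <- abs(v[win] - v[cyc(win - 1L, n)])
  thr <- min(back) + tie_tol * (max(back) - min(back))
  i_pre <- win[max(which(back <= thr))]
  structure(list(i_max = as.integer(i_max), i_min = as.integer(i_min),
                 i_pre_a = as.integer(i_pre)),
            class = "la_phase_indices")
}

#' @export
print.la_phase_indices <- function(x, ...) {
  cat(sprintf("LA phases (1-based frames): i_max %d, i_preA %d, i_min %d\n",
              x$i_max, x$i_pre_a, x$i_min))
  invisible(x)
}

#' Phasic ejection fractions
#'
#' Total `LAEF = (Vmax - Vmin)/Vmax * 100`, passive
#' `LAPEF = (Vmax - VpreA)/Vmax * 100`, active
#' `LAAEF = (VpreA - Vmin)/VpreA * 100`. These satisfy the identity
#' `LAEF = LAPEF + LAAEF * VpreA / Vmax`.
#'
#' @param v_max,v_min,v_pre_a Phasic volumes in ml, with
#'   `v_max >= v_pre_a >= v_min > 0`.
#' @return An object of class `la_function_result` with the three volumes
#'   and `laef_pct`, `lapef_pct`, `laaef_pct`.
#' @examples
#' ejection_fractions(100, 50, 80)  # LAEF 50, LAPEF 20, LAAEF 37.5
#' @export
ejection_fractions <- function(v_max, v_min, v_pre_a) {
  stop_if(v_min <= 0, "volume ordering violated: need v_min > 0")
  stop_if(v_pre_a < v_min, "volume ordering violated: need v_pre_a >= v_min")
  stop_if(v_max < v_pre_a, "volume ordering violated: need v_max >= v_pre_a")
  structure(list(v_max_ml = v_max, v_min_ml = v_min, v_pre_a_ml = v_pre_a,
                 laef_pct = (v_max - v_min) / v_max * 100,
                 lapef_pct = (v_max - v_pre_a) / v_max * 100,
                 laaef_pct = (v_pre_a - v_min) / v_pre_a * 100),
            class = "la_function_result")
}

#' @export
print.la_function_result <- function(x, ...) {
  cat(sprintf("LA volumes: Vmax %.2f, VpreA %.2f, Vmin %.2f ml\n",
              x$v_max_ml, x$v_pre_a_ml, x$v_min_ml))
  cat(sprintf("LA function: LAEF %.1f%%, LAPEF %.1f%%, LAAEF %.1f%%\n",
              x$laef_pct, x$lapef_pct, x$laaef_pct))
  invisible(x)
}

#' Global longitudinal strain curve
#'
#' Per view, strain is the fractional change of the endocardial polyline
#' arc length relative to the reference frame (the minimum-volume frame, so
#' the reservoir peak is positive):
#' `eps(t) = (L(t) - L(ref)) / L(ref) * 100`. The global curve is the
#' unweighted mean of the 2- and 4-chamber curves.
#'
#' @param cs_2ch,cs_4ch Tracked `la_contour_sequence`s with a fixed point
#'   count across frames.
#' @param ref_frame 1-based strain-reference frame (minimum-volume frame).
#' @return List with `strain_pct` (global), `strain_2ch`, `strain_4ch`,
#'   `ref_frame`.
#' @export
strain_curve <- function(cs_2ch, cs_4ch, ref_frame) {
  n <- length(cs_2ch$contours)
  stop_if(n != length(cs_4ch$contours), "frame-count mismatch between views")
  stop_if(!is_count(ref_frame) || ref_frame > n, "ref_frame out of range")
  view_strain <- function(cs) {
    npts <- vapply(cs$contours, nrow, integer(1))
    stop_if(length(unique(npts)) != 1,
            "contour point count changes across frames")
    L <- vapply(cs$contours, polyline_length, numeric(1))
    (L - L[ref_frame]) / L[ref_frame] * 100
  }
  e2 <- view_strain(cs_2ch)
  e4 <- view_strain(cs_4ch)
  list(strain_pct = (e2 + e4) / 2, strain_2ch = e2, strain_4ch = e4,
       ref_frame = as.integer(ref_frame))
}

#' Strain-rate curve
#'
#' Central finite difference of the strain curve on the cyclic cycle, in
#' %/ms; optional 3-frame smoothing as for [volume_rate()].
#'
#' @param strain_pct Per-frame strain (%), full cycle.
#' @param dt_ms Frame interval, ms.
#' @param smooth Logical.
#' @return Numeric vector, %/ms.
#' @export
strain_rate <- function(strain_pct, dt_ms, smooth = FALSE) {
  stop_if(length(strain_pct) < 3, "need at least 3 frames")
  stop_if(dt_ms <= 0, "dt_ms must be positive")
  s <- if (smooth) smooth3(strain_pct) else strain_pct
  cyclic_central_rate(s, dt_ms)
}

#' Strain and strain-rate peak parameters
#'
#' `s_max` is the peak global longitudinal strain (reservoir peak).
#' `sr_max` is the maximum strain rate on the filling interval (the cyclic
#' interval ending at `i_max`); `sr_e` is the most negative strain rate in
#' the conduit interval `(i_max, i_preA]` (early-diastolic peak); `sr_a`
#' the most negative in the booster interval `(i_preA, i_min]` (atrial
#' contraction peak). Under the minimum-volume strain reference, `sr_e` and
#' `sr_a` are negative.
#'
#' @param strain_pct Global strain curve (%), full cycle.
#' @param sr Strain-rate curve (%/ms) from [strain_rate()].
#' @param phases An `la_phase_indices`.
#' @return An object of class `la_strain_peaks` with `s_max_pct`,
#'   `sr_max_pct_per_ms`, `sr_e_pct_per_ms`, `sr_a_pct_per_ms`.
#' @export
extract_strain_peaks <- function(strain_pct, sr, phases) {
  stopifnot(inherits(phases, "la_phase_indices"))
  n <- length(strain_pct)
  stop_if(length(sr) != n, "strain and strain-rate lengths differ")
  filling <- cyc_seq(phases$i_min, phases$i_max, n)[-1]   # (i_min, i_max]
  conduit <- cyc_seq(phases$i_max, phases$i_pre_a, n)[-1] # (i_max, i_preA]
  booster <- cyc_seq(phases$i_pre_a, phases$i_min, n)[-1] # (i_preA, i_min]
  stop_if(length(filling) < 1 || length(conduit) < 1 || length(booster) < 1,
          "empty phase interval")
  structure(list(s_max_pct = max(strain_pct),
                 sr_max_pct_per_ms = max(sr[filling]),
                 sr_e_pct_per_ms = min(sr[conduit]),
                 sr_a_pct_per_ms = min(sr[booster])),
            class = "la_strain_peaks")
}

#' @export
print.la_strain_peaks <- function(x, ...) {
  cat(sprintf("Strain peaks: Smax %.2f%%; SRmax %.4f, SRe %.4f, SRa %.4f %%/ms\n",
              x$s_max_pct, x$sr_max_pct_per_ms, x$sr_e_pct_per_ms,
              x$sr_a_pct_per_ms))
  invisible(x)
}
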