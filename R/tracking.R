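# Frame-to-frame template-matching contour propagation.
#
# Each contour point carries a square intensity patch (default 10 x 10 mm).
# The patch is resampled (bilinear) at the point's current position in
# frame t and matched against candidate positions in frame t+1 within a
# search window, by zero-normalized cross-correlation. The template is
# refreshed at every step, so matching is strictly frame-to-frame; drift is
# controlled by the wrap-around closure diagnostic.

#' Tracker parameters
#'
#' @param patch_size_mm Side of the square template, mm.
#' @param search_radius_mm Maximum per-frame displacement searched, mm.
#' @param subpixel Logical; refine the integer-pixel correlation maximum by
#'   a 1-D parabolic fit per axis (half-pixel quantization otherwise
#'   dominates the strain error).
#' @param symmetric Logical; after the forward match, match the displaced
#'   point back from the target frame and average the two displacements.
#'   When the tissue pattern deforms (not just translates) between frames,
#'   the correlation peak is shifted by a small bias whose sign follows the
#'   matching direction; forward-backward averaging cancels it to first
#'   order and greatly reduces cumulative drift.
#' @param smooth_window Odd integer >= 1; width of the binomial smoothing
#'   applied to the per-step displacement field along the contour during
#'   propagation (1 disables it). Neighbouring wall points move almost
#'   identically between frames, so smoothing suppresses independent match
#'   jitter that would otherwise make the polyline jagged and inflate its
#'   arc length; it does not affect single-point tracking.
#' @param drift_correction Logical; distribute the per-point wrap-around
#'   closure residual linearly over the cycle (the standard cyclic drift
#'   compensation of speckle/feature tracking), so that the frames tracked
#'   last do not carry the whole accumulated error. The reported
#'   `closure_drift_mm` is always the raw, uncorrected residual.
#' @param quality_floor Minimum acceptable per-frame mean match score;
#'   frames below it are flagged in the quality report, not rejected.
#' @return An object of class `la_tracker_params`.
#' @export
tracker_params <- function(patch_size_mm = 10, search_radius_mm = 5,
                           subpixel = TRUE, symmetric = TRUE,
                           smooth_window = 5L, drift_correction = TRUE,
                           quality_floor = 0.7) {
  stop_if(patch_size_mm <= 0, "patch_size_mm must be positive")
  stop_if(search_radius_mm <= 0, "search_radius_mm must be positive")
  stop_if(!is_count(smooth_window) || smooth_window %% 2 != 1,
          "smooth_window must be an odd positive integer")
  structure(list(patch_size_mm = patch_size_mm,
                 search_radius_mm = search_radius_mm,
                 subpixel = isTRUE(subpixel),
                 symmetric = isTRUE(symmetric),
                 smooth_window = as.integer(smooth_window),
                 drift_correction = isTRUE(drift_correction),
                 quality_floor = quality_floor),
            class = "la_tracker_params")
}

# binomial smoothing of a vector along the (open) contour; endpoints are
# averaged one-sidedly with renormalized weights
smooth_open <- function(v, window) {
  if (window <= 1L || length(v) < 3L) return(v)
  w <- 1
  for (i in seq_len(window - 1L)) w <- c(0, w) + c(w, 0)  # binomial row
  w <- w / sum(w)
  h <- (window - 1L) %/% 2L
  n <- length(v)
  out <- v
  for (i in seq_len(n)) {
    j <- (i - h):(i + h)
    ok <- j >= 1 & j <= n
    out[i] <- sum(v[j[ok]] * w[ok]) / sum(w[ok])
  }
  out
}

#' Zero-normalized cross-correlation of two patches
#'
#' Both patches are mean-subtracted and unit-scaled, so the score lies in
#' `[-1, 1]`, is symmetric in its arguments and invariant to affine
#' intensity rescaling (positive gain) of either patch. A constant
#' (zero-variance) patch yields the sentinel score 0 with attribute
#' `degenerate = TRUE`.
#'
#' @param a,b Numeric matrices (or vectors) of identical shape, >= 2 pixels.
#' @return Correlation score in `[-1, 1]`.
#' @examples
#' a <- matrix(rnorm(25), 5)
#' ncc(a, a)            # 1
#' ncc(a, -a)           # -1
#' @export
ncc <- function(a, b) {
  stop_if(!identical(dim(a), dim(b)) || length(a) != length(b),
          "patches must have identical shapes")
  stop_if(length(a) < 2, "patches need at least 2 pixels")
  za <- a - mean(a); zb <- b - mean(b)
  den2 <- sum(za^2) * sum(zb^2)
  if (den2 <= 0) {
    return(structure(0, degenerate = TRUE))
  }
  structure(min(1, max(-1, sum(za * zb) / sqrt(den2))), degenerate = FALSE)
}

# Core matcher in pixel units. center = c(row, col), continuous pixel
# coordinates in frame_t. Returns integer+subpixel displacement (rows,
# cols), the peak score, and degeneracy/crop flags.
#
# The correlation is spatially weighted by an isotropic Gaussian centred
# on the tracked point (sigma = half the patch half-size). Tissue near the
# point then dominates the match, which keeps the estimate anchored at the
# contour point when the motion field varies across the patch (the wall
# farther from the point moves with a different amplitude under the
# chamber's contraction); the patch still spans the full template so the
# match is driven by speckle texture, not the edge alone.
match_patch <- function(frame_t, frame_t1, center, half_px, radius_px,
                        subpixel = TRUE) {
  nr <- nrow(frame_t); nc <- ncol(frame_t)
  stop_if(center[1] < 1 || center[1] > nr || center[2] < 1 || center[2] > nc,
          "point lies outside the image")
  # symmetric cropping when the template would extend past the borders
  h_r <- min(half_px, floor(center[1] - 1), floor(nr - center[1]))
  h_c <- min(half_px, floor(center[2] - 1), floor(nc - center[2]))
  cropped <- (h_r < half_px) || (h_c < half_px)
  stop_if(h_r < 1 || h_c < 1, "patch has no interior pixels at this point")
  off_r <- seq.int(-h_r, h_r); off_c <- seq.int(-h_c, h_c)
  pr <- length(off_r); pc <- length(off_c)
  tmpl <- bilinear_sample(frame_t,
                          rep(center[1] + off_r, times = pc),
                          rep(center[2] + off_c, each = pr))
  # extended window of frame_t1 sharing the template's fractional offset;
  # every candidate patch is a sub-block of it
  R <- radius_px
  wr <- seq.int(-h_r - R, h_r + R); wc <- seq.int(-h_c - R, h_c + R)
  wsamp <- bilinear_sample(frame_t1,
                           rep(center[1] + wr, times = length(wc)),
                           rep(center[2] + wc, each = length(wr)))
  if (isTRUE(attr(wsamp, "clamped"))) cropped <- TRUE
  W <- matrix(wsamp, length(wr), length(wc))

  sig <- max(half_px / 2, 1)
  wgt <- exp(-(rep(off_r, times = pc)^2 + rep(off_c, each = pr)^2) /
               (2 * sig^2))
  wgt <- wgt / sum(wgt)
  tz <- tmpl - sum(wgt * tmpl)
  t_ss <- sum(wgt * tz^2)
  if (t_ss <= 0 || sd(tmpl) == 0) {
    return(list(d = c(0, 0), score = 0, degenerate = TRUE, cropped = cropped))
  }
  S <- matrix(-Inf, 2 * R + 1, 2 * R + 1)
  for (iv in seq_len(2 * R + 1)) {      # row displacement index
    for (iu in seq_len(2 * R + 1)) {    # col displacement index
      blk <- as.vector(W[(iv - 1) + seq_len(pr), (iu - 1) + seq_len(pc)])
      bz <- blk - sum(wgt * blk)
      b_ss <- sum(wgt * bz^2)
      S[iv, iu] <- if (b_ss <= 0) 0 else sum(wgt * tz * bz) / sqrt(t_ss * b_ss)
    }
  }
  # argmax with deterministic tie-break: smallest displacement magnitude,
  # then row-major order
  dv <- rep(seq.int(-R, R), times = 2 * R + 1)
  du <- rep(seq.int(-R, R), each = 2 * R + 1)
  ord <- order(dv^2 + du^2, dv, du)
  svec <- as.vector(S)
  best <- ord[which.max(svec[ord])]
  iv <- dv[best] + R + 1; iu <- du[best] + R + 1
  dr <- dv[best]; dc <- du[best]
  score <- S[iv, iu]
  if (subpixel) {
    paraf <- function(m1, m0, p1) {
      den <- m1 - 2 * m0 + p1
      if (is.finite(den) && den < 0) min(0.5, max(-0.5, 0.5 * (m1 - p1) / den)) else 0
    }
    if (iv > 1 && iv < 2 * R + 1)
      dr <- dr + paraf(S[iv - 1, iu], S[iv, iu], S[iv + 1, iu])
    if (iu > 1 && iu < 2 * R + 1)
      dc <- dc + paraf(S[iv, iu - 1], S[iv, iu], S[iv, iu + 1])
  }
  list(d = c(dr, dc), score = score, degenerate = FALSE, cropped = cropped)
}

# forward match with optional symmetric (forward-backward) refinement
match_point_px <- function(img_a, img_b, center, half_px, radius_px,
                           subpixel, symmetric) {
  m1 <- match_patch(img_a, img_b, center, half_px, radius_px, subpixel)
  if (symmetric && !m1$degenerate) {
    m2 <- tryCatch(
      match_patch(img_b, img_a, center + m1$d, half_px, radius_px, subpixel),
      error = function(e) NULL)
    if (!is.null(m2) && !m2$degenerate) {
      # ideally d2 = -d1; average the two directions
      m1$d <- (m1$d - m2$d) / 2
    }
  }
  m1
}

#' Track a single point between two frames
#'
#' Finds the displacement (within the search window) of the template
#' centred on `point` that maximizes the normalized cross-correlation in
#' `frame_t1`, with optional parabolic subpixel refinement. A template that
#' partially leaves the image is cropped symmetrically and flagged; a point
#' outside the image is an error.
#'
#' @param frame_t,frame_t1 Numeric image matrices (same size).
#' @param point `(x, y)` position in mm.
#' @param params [tracker_params()].
#' @param spacing_mm Pixel spacing, mm/px.
#' @return List with `point` (tracked `(x, y)` mm), `score`, `degenerate`,
#'   `cropped`.
#' @export
track_point <- function(frame_t, frame_t1, point, params = tracker_params(),
                        spacing_mm) {
  stopifnot(inherits(params, "la_tracker_params"))
  stop_if(!identical(dim(frame_t), dim(frame_t1)),
          "frames must have identical dimensions")
  half_px <- max(1L, floor(params$patch_size_mm / spacing_mm / 2))
  radius_px <- max(1L, ceiling(params$search_radius_mm / spacing_mm))
  center <- c(mm_to_px(point[2], spacing_mm), mm_to_px(point[1], spacing_mm))
  m <- match_point_px(frame_t, frame_t1, center, half_px, radius_px,
                      subpixel = params$subpixel,
                      symmetric = params$symmetric)
  list(point = c(x = point[1] + m$d[2] * spacing_mm,
                 y = point[2] + m$d[1] * spacing_mm),
       score = m$score, degenerate = m$degenerate, cropped = m$cropped)
}

#' Propagate a reference contour across a cine sequence
#'
#' The reference contour (drawn at the ventricular end-systolic frame, when
#' the LA is largest) is resampled to equal arc-length spacing and then
#' tracked sequentially frame-to-frame, forward from the reference frame
#' and wrapping cyclically through the last frame back toward it. The
#' template is resampled at each frame's tracked position. Points whose
#' template is constant (zero variance) score 0 and inherit the mean
#' displacement of the remaining points. After the full cycle the last
#' contour is tracked once more into the reference frame; its mean distance
#' from the input contour is recorded as the wrap-around closure drift.
#'
#' @param seq An [cine_sequence()] with >= 2 frames.
#' @param ref_contour Matrix of `(x, y)` points in mm (open polyline from
#'   one mitral-annulus anchor to the other), or an object with a `points`
#'   matrix and `frame` index.
#' @param params [tracker_params()].
#' @param ref_frame 1-based index of the frame the contour belongs to.
#' @param resample_mm Arc-length spacing for contour resampling (mm);
#'   `NA` keeps the input points.
#' @return An object of class `la_contour_sequence`: per-frame contours
#'   (the reference frame keeps the input contour exactly), a frames x
#'   points matrix of match scores, `ref_frame`, `closure_drift_mm` and the
#'   frames flagged below `quality_floor`.
#' @export
propagate_contour <- function(seq, ref_contour, params = tracker_params(),
                              ref_frame = NULL, resample_mm = 2) {
  stopifnot(inherits(seq, "la_cine"))
  nfr <- length(seq$frames)
  stop_if(nfr < 2, "need at least 2 frames")
  if (is.list(ref_contour) && !is.null(ref_contour$points)) {
    ref_frame <- ref_frame %||% ref_contour$frame
    ref_contour <- ref_contour$points
  }
  stop_if(is.null(ref_frame), "ref_frame must be given")
  stop_if(!is_count(ref_frame) || ref_frame > nfr, "ref_frame out of range")
  stop_if(!is.matrix(ref_contour) || ncol(ref_contour) != 2 ||
            nrow(ref_contour) < 3, "ref_contour must be an n x 2 matrix, n >= 3")
  pts <- if (is.na(resample_mm)) ref_contour else
    resample_polyline(ref_contour, spacing_mm = resample_mm)
  npts <- nrow(pts)
  sp <- seq$pixel_spacing_mm
  half_px <- max(1L, floor(params$patch_size_mm / sp / 2))
  radius_px <- max(1L, ceiling(params$search_radius_mm / sp))

  contours <- vector("list", nfr)
  quality <- matrix(NA_real_, nfr, npts)
  contours[[ref_frame]] <- pts
  quality[ref_frame, ] <- 1

  step <- function(img_a, img_b, cur) {
    nxt <- cur
    sc <- numeric(npts)
    degen <- logical(npts)
    disp <- matrix(0, npts, 2)  # (dr, dc) in px
    for (i in seq_len(npts)) {
      center <- c(mm_to_px(cur[i, 2], sp), mm_to_px(cur[i, 1], sp))
      m <- match_point_px(img_a, img_b, center, half_px, radius_px,
                          subpixel = params$subpixel,
                          symmetric = params$symmetric)
      disp[i, ] <- m$d
      sc[i] <- m$score
      degen[i] <- m$degenerate
    }
    if (any(degen)) {
      fill <- if (all(degen)) c(0, 0) else colMeans(disp[!degen, , drop = FALSE])
      disp[degen, ] <- matrix(fill, sum(degen), 2, byrow = TRUE)
    }
    if (params$smooth_window > 1L) {
      disp[, 1] <- smooth_open(disp[, 1], params$smooth_window)
      disp[, 2] <- smooth_open(disp[, 2], params$smooth_window)
    }
    nxt[, 1] <- cur[, 1] + disp[, 2] * sp
    nxt[, 2] <- cur[, 2] + disp[, 1] * sp
    list(points = nxt, score = sc)
  }

  order_idx <- c(seq.int(ref_frame, nfr), seq_len(ref_frame - 1L))
  cur <- pts
  for (k in seq_len(nfr - 1L)) {
    a <- order_idx[k]; b <- order_idx[k + 1L]
    res <- step(seq$frames[[a]], seq$frames[[b]], cur)
    contours[[b]] <- res$points
    quality[b, ] <- res$score
    cur <- res$points
  }
  # close the loop: last frame back into the reference frame
  last <- order_idx[nfr]
  res <- step(seq$frames[[last]], seq$frames[[ref_frame]], cur)
  resid <- res$points - pts
  closure <- mean(sqrt(rowSums(resid^2)))
  if (params$drift_correction && nfr > 2) {
    # remove the accumulated drift, assuming it grew linearly with the
    # number of tracking steps away from the reference frame
    for (k in seq.int(2L, nfr)) {
      f <- order_idx[k]
      contours[[f]] <- contours[[f]] - ((k - 1) / nfr) * resid
    }
  }

  per_frame <- rowMeans(quality)
  flagged <- which(per_frame < params$quality_floor)
  if (length(flagged))
    warning(sprintf("tracking quality below %.2f in frame(s): %s",
                    params$quality_floor, paste(flagged, collapse = ", ")),
            call. = FALSE)
  structure(list(contours = contours,
                 quality = quality,
                 ref_frame = as.integer(ref_frame),
                 view = seq$view,
                 pixel_spacing_mm = sp,
                 frame_interval_ms = seq$frame_interval_ms,
                 closure_drift_mm = closure,
                 flagged_frames = flagged),
            class = "la_contour_sequence")
}

#' @export
print.la_contour_sequence <- function(x, ...) {
  cat(sprintf("Tracked contour sequence [%s]: %d frames x %d points, ref frame %d\n",
              x$view, length(x$contours), ncol(x$quality), x$ref_frame))
  cat(sprintf("  mean score %.3f, closure drift %.3f mm\n",
              mean(x$quality), x$closure_drift_mm))
  invisible(x)
}

#' Tracking quality report
#'
#' Per-frame mean match scores, the global mean, and the frames whose mean
#' score falls below the floor (mirroring the operator's visual check of
#' the tracking).
#'
#' @param cs An `la_contour_sequence`.
#' @param floor Score threshold in `[-1, 1]`.
#' @return An object of class `la_quality_report`.
#' @export
tracking_quality <- function(cs, floor = 0.7) {
  stopifnot(inherits(cs, "la_contour_sequence"))
  stop_if(length(cs$contours) == 0, "empty contour sequence")
  per_frame <- rowMeans(cs$quality)
  structure(list(per_frame_mean = per_frame,
                 global_mean = mean(cs$quality),
                 floor = floor,
                 flagged_frames = which(per_frame < floor),
                 closure_drift_mm = cs$closure_drift_mm),
            class = "la_quality_report")
}

#' @export
print.la_quality_report <- function(x, ...) {
  cat(sprintf("Tracking quality: global mean score %.3f (floor %.2f)\n",
              x$global_mean, x$floor))
  if (length(x$flagged_frames)) {
    cat("  frames below floor:", paste(x$flagged_frames, collapse = ", "), "\n")
  } else cat("  no frames below floor\n")
  if (!is.null(x$closure_drift_mm))
    cat(sprintf("  wrap-around closure drift %.3f mm\n", x$closure_drift_mm))
  invisible(x)
}

#' Resample an open contour to equal arc-length spacing
#'
#' @param points n x 2 matrix of `(x, y)` mm.
#' @param spacing_mm Target spacing between consecutive points.
#' @param n_points Optional explicit point count (overrides `spacing_mm`).
#' @return Resampled matrix; endpoints (annulus anchors) are preserved.
#' @export
resample_contour <- function(points, spacing_mm = 2, n_points = NULL) {
  resample_polyline(points, spacing_mm, n_points)
}
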