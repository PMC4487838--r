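# High-level analysis: contour sequences -> full LA function result, and
# the end-to-end tracking entry point.

#' Quantify LA function from tracked contour sequences
#'
#' Composes the quantitation chain: biplane volume curve, volume rate,
#' phase detection, phasic ejection fractions, biplane global longitudinal
#' strain (referenced to the minimum-volume frame), strain rate and the
#' four strain/strain-rate peaks.
#'
#' @param cs_2ch,cs_4ch Tracked `la_contour_sequence`s (2- and 4-chamber).
#' @param p_wave_frame Optional 1-based ECG P-wave onset frame; overrides
#'   the volume-rate rule's window end for `i_preA`.
#' @param smooth_rate Logical; smooth volume and strain rates with a
#'   3-frame moving average.
#' @return An object of class `la_analysis`.
#' @export
la_quantify <- function(cs_2ch, cs_4ch, p_wave_frame = NULL,
                        smooth_rate = FALSE) {
  vc <- volume_curve(cs_2ch, cs_4ch)
  rate <- volume_rate(vc, smooth = smooth_rate)
  phases <- detect_phases(vc, rate, p_wave_frame = p_wave_frame)
  fn <- ejection_fractions(vc$volume_ml[phases$i_max],
                           vc$volume_ml[phases$i_min],
                           vc$volume_ml[phases$i_pre_a])
  sc <- strain_curve(cs_2ch, cs_4ch, ref_frame = phases$i_min)
  dt <- diff(vc$time_ms)[1]
  sr <- strain_rate(sc$strain_pct, dt, smooth = smooth_rate)
  peaks <- extract_strain_peaks(sc$strain_pct, sr, phases)
  structure(list(volume = vc, rate = rate, phases = phases,
                 func = fn, strain = sc, strain_rate = sr, peaks = peaks,
                 quality = list(`2ch` = tracking_quality(cs_2ch),
                                `4ch` = tracking_quality(cs_4ch)),
                 contours = list(`2ch` = cs_2ch, `4ch` = cs_4ch),
                 call = match.call()),
            class = "la_analysis")
}

#' End-to-end LA feature-tracking analysis
#'
#' Propagates the reference contours of both long-axis views across the
#' cycle by template matching, then quantifies volumes, phases, ejection
#' fractions and strain. This is the package's main entry point; the
#' result is a classed object with `print`, `summary`, `coef` and `plot`
#' methods.
#'
#' @param cine_2ch,cine_4ch [cine_sequence()]s of the two views.
#' @param ref_contour_2ch,ref_contour_4ch Reference-frame endocardial
#'   contours (n x 2 mm matrices, open polylines anchored at the mitral
#'   annulus), drawn at ventricular end-systole.
#' @param ref_frame 1-based reference frame (default: the views' largest-LA
#'   frame must be supplied by the caller; for the phantom this is the
#'   configured `i_max`).
#' @param params [tracker_params()].
#' @param p_wave_frame Optional P-wave onset frame; defaults to the cine's
#'   metadata if present.
#' @param resample_mm Contour resampling pitch before tracking, mm.
#' @param smooth_rate Logical; see [la_quantify()].
#' @return An `la_analysis` object.
#' @examples
#' \donttest{
#' ph <- make_phantom(phantom_config())
#' gt <- ph$ground_truth
#' fit <- la_analyze(ph$cine_2ch, ph$cine_4ch,
#'                   gt$contours_2ch[[gt$phase_indices$i_max]],
#'                   gt$contours_4ch[[gt$phase_indices$i_max]],
#'                   ref_frame = gt$phase_indices$i_max)
#' coef(fit)
#' }
#' @export
la_analyze <- function(cine_2ch, cine_4ch, ref_contour_2ch, ref_contour_4ch,
                       ref_frame, params = tracker_params(),
                       p_wave_frame = NULL, resample_mm = 2,
                       smooth_rate = FALSE) {
  p_wave_frame <- p_wave_frame %||% cine_2ch$p_wave_frame %||%
    cine_4ch$p_wave_frame
  cs2 <- propagate_contour(cine_2ch, ref_contour_2ch, params,
                           ref_frame = ref_frame, resample_mm = resample_mm)
  cs4 <- propagate_contour(cine_4ch, ref_contour_4ch, params,
                           ref_frame = ref_frame, resample_mm = resample_mm)
  out <- la_quantify(cs2, cs4, p_wave_frame = p_wave_frame,
                     smooth_rate = smooth_rate)
  out$call <- match.call()
  out
}

#' @export
print.la_analysis <- function(x, ...) {
  cat("Left atrial feature-tracking analysis\n")
  print(x$phases)
  print(x$func)
  print(x$peaks)
  invisible(x)
}

#' @export
summary.la_analysis <- function(object, ...) {
  x <- object
  cat("Left atrial feature-tracking analysis\n\n")
  cat(sprintf("Frames: %d (dt %.0f ms), biplane method\n",
              length(x$volume$volume_ml), diff(x$volume$time_ms)[1]))
  print(x$phases)
  print(x$func)
  print(x$peaks)
  q2 <- x$quality$`2ch`; q4 <- x$quality$`4ch`
  cat(sprintf("Tracking quality: 2ch mean %.3f (closure %.2f mm), 4ch mean %.3f (closure %.2f mm)\n",
              q2$global_mean, q2$closure_drift_mm,
              q4$global_mean, q4$closure_drift_mm))
  fl <- union(q2$flagged_frames, q4$flagged_frames)
  if (length(fl)) cat("  frames flagged for review:",
                      paste(sort(fl), collapse = ", "), "\n")
  invisible(x)
}

#' Extract the ten reported LA parameters
#'
#' @param object An `la_analysis`.
#' @param ... Unused.
#' @return Named numeric vector: `v_max_ml`, `v_min_ml`, `v_pre_a_ml`,
#'   `laef_pct`, `lapef_pct`, `laaef_pct`, `s_max_pct`,
#'   `sr_max_pct_per_ms`, `sr_e_pct_per_ms`, `sr_a_pct_per_ms`.
#' @export
coef.la_analysis <- function(object, ...) {
  f <- object$func; p <- object$peaks
  c(v_max_ml = f$v_max_ml, v_min_ml = f$v_min_ml, v_pre_a_ml = f$v_pre_a_ml,
    laef_pct = f$laef_pct, lapef_pct = f$lapef_pct, laaef_pct = f$laaef_pct,
    s_max_pct = p$s_max_pct, sr_max_pct_per_ms = p$sr_max_pct_per_ms,
    sr_e_pct_per_ms = p$sr_e_pct_per_ms, sr_a_pct_per_ms = p$sr_a_pct_per_ms)
}

#' Plot an LA analysis
#'
#' Four panels in the conventional layout: volume, volume rate, strain and
#' strain rate against time, with the detected Vmax (dashed), VpreA
#' (dotted) and Vmin (dash-dot) frames marked.
#'
#' @param x An `la_analysis`.
#' @param ... Passed to the panel `plot` calls.
#' @export
plot.la_analysis <- function(x, ...) {
  op <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  t <- x$volume$time_ms
  mark <- function() {
    abline(v = t[x$phases$i_max], lty = 2, col = "gray40")
    abline(v = t[x$phases$i_pre_a], lty = 3, col = "gray40")
    abline(v = t[x$phases$i_min], lty = 4, col = "gray40")
  }
  plot(t, x$volume$volume_ml, type = "l", xlab = "time (ms)",
       ylab = "LA volume (ml)", main = "Volume", ...)
  mark()
  plot(t, x$rate, type = "l", xlab = "time (ms)",
       ylab = "volume rate (ml/ms)", main = "Volume rate", ...)
  abline(h = 0, col = "gray70"); mark()
  plot(t, x$strain$strain_pct, type = "l", xlab = "time (ms)",
       ylab = "strain (%)", main = "Strain", ...)
  mark()
  plot(t, x$strain_rate, type = "l", xlab = "time (ms)",
       ylab = "strain rate (%/ms)", main = "Strain rate", ...)
  abline(h = 0, col = "gray70"); mark()
  invisible(x)
}

#' One results row for reports
#'
#' @param x An `la_analysis`.
#' @param id Subject/case identifier.
#' @param method Volumetric method label.
#' @return A one-row `data.frame` with the ten parameters.
#' @export
results_row <- function(x, id = "case", method = "biplane") {
  stopifnot(inherits(x, "la_analysis"))
  data.frame(id = id, method = method, t(coef(x)), check.names = FALSE)
}
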