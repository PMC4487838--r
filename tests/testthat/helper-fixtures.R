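# Shared fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

# Default 30-frame phantom (the study conditions) and its end-to-end
# tracked analysis; computed once, reused by tracking/quantitation/
# acceptance tests.
default_phantom <- function() {
  if (is.null(.fixtures$phantom)) .fixtures$phantom <- make_phantom(phantom_config())
  .fixtures$phantom
}

default_analysis <- function() {
  if (is.null(.fixtures$analysis)) {
    ph <- default_phantom()
    gt <- ph$ground_truth
    ref <- gt$phase_indices$i_max
    .fixtures$analysis <- la_analyze(ph$cine_2ch, ph$cine_4ch,
                                     gt$contours_2ch[[ref]],
                                     gt$contours_4ch[[ref]],
                                     ref_frame = ref)
  }
  .fixtures$analysis
}

# small, quick phantom for IO / structural tests
small_phantom <- function(noise_sd = 0, seed = 1, sax = FALSE) {
  make_phantom(phantom_config(n_frames = 8, image_size_px = c(64, 64),
                              semi_axes_mm = c(20, 13, 10),
                              phase_frames = c(3, 5, 6),
                              noise_sd = noise_sd, sax = sax, seed = seed))
}

# smooth textured image for tracker unit tests (sum of random cosines, so
# circular shifts are exact)
textured_image <- function(n = 64, seed = 7) {
  set.seed(seed)
  img <- matrix(0, n, n)
  rc <- row(img); cc <- col(img)
  for (j in 1:25) {
    k <- runif(2, 0.2, 1.2)
    img <- img + runif(1, 0.5, 1) * cos(k[1] * rc + k[2] * cc + runif(1, 0, 2 * pi))
  }
  img
}

# ground-truth ejection fractions of a phantom
phantom_truth_ef <- function(gt) {
  ejection_fractions(max(gt$volume_ml), min(gt$volume_ml),
                     gt$volume_ml[gt$phase_indices$i_pre_a])
}

# ground-truth strain peaks of a phantom, via the analytic strain curve
phantom_truth_peaks <- function(gt) {
  sr <- strain_rate(gt$strain_pct, gt$config$frame_interval_ms)
  phases <- structure(gt$phase_indices, class = "la_phase_indices")
  extract_strain_peaks(gt$strain_pct, sr, phases)
}

polyline_length_for_test <- function(p) sum(sqrt(rowSums(diff(p)^2)))

# RMS distance between a tracked contour and the ground-truth contour
# resampled to the same point count
contour_rms <- function(tracked, gt_contour) {
  g <- resample_contour(gt_contour, n_points = nrow(tracked))
  sqrt(mean(rowSums((tracked - g)^2)))
}
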