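half_ellipse <- function(a = 40, b = 25, n = 721) {
  th <- seq(0, pi, length.out = n)
  cbind(x = a * cos(th), y = b * sin(th))  # chord = major axis
}

test_that("contour_area: shoelace with chord closure, orientation-free", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(contour_area(sq), 1)
  expect_equal(contour_area(sq[4:1, ]), 1)

  he <- half_ellipse()
  expect_equal(contour_area(he), pi * 40 * 25 / 2, tolerance = 1e-3)
  expect_equal(contour_area(he[nrow(he):1, ]), contour_area(he))

  bowtie <- cbind(c(0, 2, 2, 0), c(0, 2, 0, 2))
  expect_error(contour_area(bowtie), "self-intersecting")
})

test_that("chamber_length is the chord-normal extent, rigid-motion invariant", {
  he <- half_ellipse(40, 25)
  expect_equal(chamber_length(he), 25, tolerance = 1e-6)
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- sweep(he %*% R, 2, c(12.3, -4.5), "+")
  expect_equal(chamber_length(moved), chamber_length(he), tolerance = 1e-9)
  degen <- cbind(c(0, 1, 0), c(0, 1, 0))
  expect_error(chamber_length(degen), "anchors coincide")

  # phantom ground-truth contour: annulus-to-roof length a (1 + cos(gap))
  gt <- default_phantom()$ground_truth
  cfg <- gt$config
  i <- gt$phase_indices$i_max
  expect_equal(chamber_length(gt$contours_4ch[[i]]),
               cfg$semi_axes_mm[1] * (1 + cos(cfg$annulus_gap_rad)),
               tolerance = cfg$pixel_spacing_mm)
})

test_that("biplane_volume reproduces worked values and scales correctly", {
  expect_equal(biplane_volume(pi * 40 * 20, pi * 40 * 25, 80, 80), 83.69,
               tolerance = 1e-4)
  expect_equal(biplane_volume(1000, 1000, 50, 50), 16.96)
  v1 <- biplane_volume(1500, 2000, 60, 70)
  expect_equal(biplane_volume(1500, 2000, 120, 140), v1 / 2)
  expect_error(biplane_volume(-1, 10, 10, 10), "positive")
})

test_that("simpson_volume sums areas times slice spacing", {
  expect_equal(simpson_volume(c(1000, 1000, 1000), 8, 2), 30)
  expect_equal(simpson_volume(0), 0)
  expect_error(simpson_volume(c(100, -5)), "non-negative")
})

test_that("volume_rate: zero for flat curves, exact slope on ramps, uniform dt required", {
  flat <- volume_curve_from_volumes(rep(70, 10), seq(0, by = 35, length.out = 10))
  expect_true(all(volume_rate(flat) == 0))

  ramp <- volume_curve_from_volumes(10 * (1:12), seq(0, by = 35, length.out = 12))
  r <- volume_rate(ramp)
  expect_equal(r[2:11], rep(10 / 35, 10))  # interior central differences

  bad <- volume_curve_from_volumes(c(10, 20, 30), c(0, 35, 90))
  expect_error(volume_rate(bad), "non-uniform")
})

test_that("detect_phases follows the plateau construction and tie-break", {
  vc <- volume_curve_from_volumes(c(50, 70, 90, 100, 85, 80, 80, 80, 65, 55),
                                  seq(0, by = 35, length.out = 10))
  ph <- detect_phases(vc)
  expect_identical(ph$i_max, 4L)   # 0-based frame 3
  expect_identical(ph$i_min, 10L)  # 0-based frame 9
  expect_identical(ph$i_pre_a, 8L) # 0-based frame 7: latest near-zero dV

  # invariant to adding a constant and to uniform time rescaling
  ph2 <- detect_phases(volume_curve_from_volumes(vc$volume_ml + 500, vc$time_ms))
  ph3 <- detect_phases(volume_curve_from_volumes(vc$volume_ml, vc$time_ms * 7))
  expect_identical(unclass(ph2)[1:3], unclass(ph)[1:3])
  expect_identical(unclass(ph3)[1:3], unclass(ph)[1:3])

  mono <- volume_curve_from_volumes(1:8, seq(0, by = 35, length.out = 8))
  expect_error(detect_phases(mono), "monotone")
})

test_that("detect_phases recovers the phantom's designed phases, with and without the P wave", {
  gt <- default_phantom()$ground_truth
  vc <- volume_curve_from_volumes(gt$volume_ml, gt$time_ms)
  ph <- detect_phases(vc)
  expect_identical(ph$i_max, gt$phase_indices$i_max)
  expect_identical(ph$i_min, gt$phase_indices$i_min)
  expect_identical(ph$i_pre_a, gt$phase_indices$i_pre_a)
  # supplying the ECG P-wave frame gives the same answer as the rate rule
  ph_pw <- detect_phases(vc, p_wave_frame = gt$p_wave_frame)
  expect_identical(ph_pw$i_pre_a, ph$i_pre_a)
})

test_that("ejection fractions: worked example, boundaries, identity, ordering errors", {
  f <- ejection_fractions(100, 50, 80)
  expect_equal(f$laef_pct, 50)
  expect_equal(f$lapef_pct, 20)
  expect_equal(f$laaef_pct, 37.5)

  b <- ejection_fractions(100, 60, 100)  # v_preA = v_max
  expect_equal(b$lapef_pct, 0)
  expect_equal(b$laef_pct, b$laaef_pct)

  set.seed(9)
  for (i in 1:25) {
    v <- sort(runif(3, 10, 150))
    r <- ejection_fractions(v[3], v[1], v[2])
    expect_equal(r$laef_pct, r$lapef_pct + r$laaef_pct * v[2] / v[3],
                 tolerance = 1e-12)
  }
  expect_error(ejection_fractions(100, 80, 50), "v_pre_a >= v_min")
  expect_error(ejection_fractions(50, 10, 80), "v_max >= v_pre_a")
  expect_error(ejection_fractions(100, -1, 50), "v_min > 0")
})

test_that("strain_curve: zero for constant length, exact arithmetic, count guard", {
  mkcs <- function(contours) {
    structure(list(contours = contours,
                   quality = matrix(1, length(contours), nrow(contours[[1]])),
                   ref_frame = 1L, view = "4ch", frame_interval_ms = 35,
                   closure_drift_mm = 0),
              class = "la_contour_sequence")
  }
  seg <- function(L) cbind(x = c(0, L / 2, L), y = c(0, 0, 0))
  cs_const <- mkcs(list(seg(100), seg(100), seg(100)))
  s <- strain_curve(cs_const, cs_const, ref_frame = 1)
  expect_true(all(s$strain_pct == 0))

  cs_var <- mkcs(list(seg(100), seg(120), seg(90)))
  s2 <- strain_curve(cs_var, cs_var, ref_frame = 1)
  expect_equal(s2$strain_pct, c(0, 20, -10))

  cs_bad <- mkcs(list(seg(100), cbind(x = c(0, 100), y = c(0, 0)), seg(90)))
  expect_error(strain_curve(cs_bad, cs_bad, ref_frame = 1), "point count")
})

test_that("strain_rate: flat, linear ramp and triangular symmetry", {
  expect_true(all(strain_rate(rep(3, 8), 35) == 0))
  r <- strain_rate(2.5 * (1:10), 35)
  expect_equal(r[2:9], rep(2.5 / 35, 8))

  tri <- c(0:5, 4:1)  # symmetric triangle over the cycle
  sr <- strain_rate(tri, 35)
  phases <- structure(list(i_max = 6L, i_min = 1L, i_pre_a = 8L),
                      class = "la_phase_indices")
  pk <- extract_strain_peaks(tri, sr, phases)
  expect_equal(pk$sr_max_pct_per_ms, -pk$sr_e_pct_per_ms)
})

test_that("phantom strain and strain-rate peaks match analytic ground truth", {
  gt <- default_phantom()$ground_truth
  fit <- default_analysis()
  truth <- phantom_truth_peaks(gt)
  # reservoir peak within one strain point
  expect_lt(abs(fit$peaks$s_max_pct - truth$s_max_pct), 1)
  # all four peaks within 10% relative
  for (f in c("s_max_pct", "sr_max_pct_per_ms", "sr_e_pct_per_ms",
              "sr_a_pct_per_ms")) {
    expect_lt(abs(fit$peaks[[f]] - truth[[f]]) / abs(truth[[f]]), 0.10)
  }
  # signs: systolic filling positive, conduit and booster negative
  expect_gt(fit$peaks$sr_max_pct_per_ms, 0)
  expect_lt(fit$peaks$sr_e_pct_per_ms, 0)
  expect_lt(fit$peaks$sr_a_pct_per_ms, 0)
  # strain rate within the designed diastasis plateau is near zero
  gt_sr <- strain_rate(gt$strain_pct, gt$config$frame_interval_ms)
  plateau <- seq(gt$config$phase_frames[2] + 1, gt$config$phase_frames[3] - 1)
  expect_true(all(abs(gt_sr[plateau]) < 1e-9))
})

test_that("volume_curve composes per-frame biplane volumes and guards inputs", {
  gt <- default_phantom()$ground_truth
  mk <- function(contours) {
    structure(list(contours = contours,
                   quality = matrix(1, length(contours), nrow(contours[[1]])),
                   ref_frame = 1L, view = "4ch", frame_interval_ms = 35,
                   closure_drift_mm = 0),
              class = "la_contour_sequence")
  }
  vc <- volume_curve(mk(gt$contours_2ch), mk(gt$contours_4ch))
  expect_equal(vc$volume_ml, gt$volume_ml, tolerance = 0.02)
  expect_error(volume_curve(mk(gt$contours_2ch[1:5]), mk(gt$contours_4ch)),
               "mismatch")
})
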