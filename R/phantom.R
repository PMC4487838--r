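# Synthetic deforming-atrium phantom with analytic ground truth.
#
# The chamber is an ellipsoid with semi-axes (a, b, c): a along the long
# axis, b in the 4-chamber imaging plane, c in the 2-chamber plane. Each
# long-axis view therefore sees an ellipse (a, b) or (a, c). Deformation is
# an isotropic in-plane scaling s(t) about the mitral-annulus midpoint,
# solved from the prescribed tri-phasic volume curve as
# s(t) = (V(t)/Vmax)^(1/3), so areas scale as s^2, lengths as s, and the
# biplane volume exactly tracks V(t). Ground-truth longitudinal strain
# relative to the minimum-volume frame is (s(t)/s_min - 1) * 100, available
# in closed form.

#' Phantom configuration
#'
#' Defines the geometry, deformation, timing and texture of the synthetic
#' cine phantom. Defaults emulate a standard SSFP cine acquisition (30
#' frames at 35 ms temporal resolution, 1 mm in-plane pixels) around an
#' adult-sized left atrium.
#'
#' @param n_frames Number of cine frames per cycle.
#' @param frame_interval_ms Temporal resolution in milliseconds.
#' @param pixel_spacing_mm In-plane pixel size in millimetres.
#' @param image_size_px Image size as `c(rows, cols)`.
#' @param semi_axes_mm Ellipsoid semi-axes `c(a_long, b, c)` in mm at
#'   maximum volume. `b` is seen in the 4-chamber view, `c` in 2-chamber.
#' @param volume_fractions `c(v_min_frac, v_preA_frac)`: minimum and
#'   pre-atrial-contraction volumes as fractions of the maximum. Defaults
#'   (0.54, 0.82) give a total ejection fraction of 46% and a passive
#'   ejection fraction of 18%, typical biplane feature-tracking values.
#' @param phase_frames `c(i_max, plateau_start, plateau_end)`, 1-based frame
#'   indices of the volume maximum, the start and the end of the diastasis
#'   plateau. The minimum-volume frame is the last frame. The P-wave onset
#'   is defined as `plateau_end` (onset of active emptying).
#' @param noise_sd Standard deviation of additive Gaussian image noise, in
#'   intensity units (wall texture has amplitude ~45 on a 0-255-ish scale).
#' @param texture_grain_px Correlation length of the wall speckle, pixels.
#' @param wall_frac Wall thickness as a fraction of the local semi-axis.
#' @param annulus_gap_rad Half-angle of the small annulus gap where the
#'   open endocardial contour meets the mitral plane.
#' @param sax Logical; also render a short-axis image stack (analytic
#'   short-axis slice areas are always part of the ground truth).
#' @param sax_thickness_mm,sax_gap_mm Short-axis slice thickness and
#'   inter-slice gap in mm (slice spacing is their sum).
#' @param seed Integer seed; identical seeds give bit-identical phantoms.
#'
#' @return An object of class `la_phantom_config`.
#' @seealso [make_phantom()]
#' @export
phantom_config <- function(n_frames = 30L,
                           frame_interval_ms = 35,
                           pixel_spacing_mm = 1,
                           image_size_px = c(128L, 128L),
                           semi_axes_mm = c(40, 25, 20),
                           volume_fractions = c(0.54, 0.82),
                           phase_frames = c(11L, 18L, 24L),
                           noise_sd = 5,
                           texture_grain_px = 2,
                           wall_frac = 0.25,
                           annulus_gap_rad = 0.08,
                           sax = FALSE,
                           sax_thickness_mm = 8,
                           sax_gap_mm = 2,
                           seed = 1L) {
  stop_if(!is_count(n_frames) || n_frames < 4, "n_frames must be >= 4")
  stop_if(frame_interval_ms <= 0, "frame_interval_ms must be positive")
  stop_if(pixel_spacing_mm <= 0, "pixel_spacing_mm must be positive")
  stop_if(length(image_size_px) != 2 || any(image_size_px < 16),
          "image_size_px must be c(rows, cols), each >= 16")
  stop_if(length(semi_axes_mm) != 3 || any(semi_axes_mm <= 0),
          "semi_axes_mm must be three positive lengths")
  vf <- volume_fractions
  stop_if(length(vf) != 2 || vf[1] <= 0 || vf[1] > vf[2] || vf[2] > 1,
          "volume_fractions must satisfy 0 < v_min_frac <= v_preA_frac <= 1")
  pf <- as.integer(phase_frames)
  stop_if(length(pf) != 3 || !(pf[1] < pf[2] && pf[2] < pf[3] &&
                                 pf[3] < n_frames),
          "phase_frames must satisfy i_max < plateau_start < plateau_end < n_frames")
  stop_if(noise_sd < 0, "noise_sd must be >= 0")
  stop_if(texture_grain_px <= 0, "texture_grain_px must be positive")
  cfg <- list(
    n_frames = as.integer(n_frames),
    frame_interval_ms = frame_interval_ms,
    pixel_spacing_mm = pixel_spacing_mm,
    image_size_px = as.integer(image_size_px),
    semi_axes_mm = semi_axes_mm,
    volume_fractions = vf,
    phase_frames = pf,
    noise_sd = noise_sd,
    texture_grain_px = texture_grain_px,
    wall_frac = wall_frac,
    annulus_gap_rad = annulus_gap_rad,
    sax = isTRUE(sax),
    sax_thickness_mm = sax_thickness_mm,
    sax_gap_mm = sax_gap_mm,
    seed = as.integer(seed)
  )
  class(cfg) <- "la_phantom_config"
  cfg
}

#' @export
print.la_phantom_config <- function(x, ...) {
  cat("LA phantom configuration\n")
  cat(sprintf("  %d frames @ %g ms, %g mm/px, image %d x %d px\n",
              x$n_frames, x$frame_interval_ms, x$pixel_spacing_mm,
              x$image_size_px[1], x$image_size_px[2]))
  cat(sprintf("  semi-axes (a,b,c) = (%g, %g, %g) mm; Vmax = %.2f ml\n",
              x$semi_axes_mm[1], x$semi_axes_mm[2], x$semi_axes_mm[3],
              ellipsoid_volume_ml(x$semi_axes_mm)))
  cat(sprintf("  volume fractions: Vmin %.2f, VpreA %.2f of Vmax\n",
              x$volume_fractions[1], x$volume_fractions[2]))
  cat(sprintf("  phases: i_max %d, plateau %d..%d, i_min %d; seed %d\n",
              x$phase_frames[1], x$phase_frames[2], x$phase_frames[3],
              x$n_frames, x$seed))
  invisible(x)
}

#' Ellipsoid volume in millilitres
#'
#' @param semi_axes_mm Semi-axes `c(a, b, c)` in mm.
#' @return Volume `(4/3) * pi * a * b * c / 1000` in ml.
#' @export
ellipsoid_volume_ml <- function(semi_axes_mm) {
  (4 / 3) * pi * prod(semi_axes_mm) / 1000
}

# Prescribed tri-phasic volume curve (ml), 1-based frames.
# Reservoir filling (cosine ramp from the virtual previous minimum at
# "frame 0") to i_max, passive emptying to the diastasis plateau, then
# active emptying to the minimum at the last frame.
phantom_volume_curve <- function(cfg) {
  n <- cfg$n_frames
  v_max <- ellipsoid_volume_ml(cfg$semi_axes_mm)
  v_min <- cfg$volume_fractions[1] * v_max
  v_pre <- cfg$volume_fractions[2] * v_max
  i_max <- cfg$phase_frames[1]
  p0 <- cfg$phase_frames[2]
  p1 <- cfg$phase_frames[3]
  v <- numeric(n)
  ramp <- function(t, t0, t1, v0, v1)
    v0 + (v1 - v0) * (1 - cos(pi * (t - t0) / (t1 - t0))) / 2
  t <- seq_len(i_max)
  v[t] <- ramp(t, 0, i_max, v_min, v_max)        # filling from virtual frame 0
  t <- seq.int(i_max, p0)
  v[t] <- ramp(t, i_max, p0, v_max, v_pre)       # passive (conduit) emptying
  v[seq.int(p0, p1)] <- v_pre                    # diastasis plateau
  t <- seq.int(p1, n)
  v[t] <- ramp(t, p1, n, v_pre, v_min)           # active (booster) emptying
  list(volume_ml = v, v_max = v_max, v_min = v_min, v_pre_a = v_pre)
}

# Band-limited speckle texture: a sum of K random plane-wave cosines with
# wavelengths between ~2 and ~6 texture grains. Being analytic in the
# coordinates, it can be evaluated exactly at warped positions, so the wall
# pattern is advected with the deformation without interpolation error.
make_texture <- function(grain_mm, k = 40L) {
  lambda <- runif(k, 2 * grain_mm, 6 * grain_mm)
  theta <- runif(k, 0, 2 * pi)
  list(
    kx = 2 * pi * cos(theta) / lambda,
    ky = 2 * pi * sin(theta) / lambda,
    phase = runif(k, 0, 2 * pi),
    amp = rep(sqrt(2 / k), k)
  )
}

eval_texture <- function(tex, x, y) {
  out <- numeric(length(x))
  for (j in seq_along(tex$kx)) {
    out <- out + tex$amp[j] * cos(tex$kx[j] * x + tex$ky[j] * y + tex$phase[j])
  }
  out
}

# Render one view: ellipse semi-axes (ay along image y, ax along x) at
# reference scale, deformed per frame by s about `center_scale`.
render_view <- function(cfg, ax, ay, s, tex_wall, tex_bg, scale_about_annulus) {
  nr <- cfg$image_size_px[1]; nc <- cfg$image_size_px[2]
  sp <- cfg$pixel_spacing_mm
  cx <- nc * sp / 2; cy <- nr * sp / 2
  m <- if (scale_about_annulus) {
    c(cx, cy + ay * cos(cfg$annulus_gap_rad))
  } else c(cx, cy)
  X <- matrix(px_to_mm(rep(seq_len(nc), each = nr), sp), nr, nc)
  Y <- matrix(px_to_mm(rep(seq_len(nr), times = nc), sp), nr, nc)
  outer_sq <- (1 + cfg$wall_frac)^2
  bg <- 70 + 15 * eval_texture(tex_bg, as.vector(X), as.vector(Y))
  frames <- vector("list", length(s))
  outer_r <- sqrt(outer_sq)
  edge_mm <- 0.4  # partial-volume blur at tissue interfaces, image space
  for (t in seq_along(s)) {
    xr <- m[1] + (as.vector(X) - m[1]) / s[t]
    yr <- m[2] + (as.vector(Y) - m[2]) / s[t]
    rho <- sqrt(((xr - cx) / ax)^2 + ((yr - cy) / ay)^2)
    # approximate signed distance (mm, image space) from the endocardial
    # and epicardial interfaces, measured along the radial direction
    r_loc <- sqrt((xr - cx)^2 + (yr - cy)^2) / pmax(rho, 1e-9)
    d_endo <- (rho - 1) * r_loc * s[t]
    d_epi <- (rho - outer_r) * r_loc * s[t]
    w_in <- 1 / (1 + exp(-d_endo / edge_mm))   # 0 in cavity, 1 in wall
    w_out <- 1 / (1 + exp(-d_epi / edge_mm))   # 0 in wall, 1 outside
    wall_val <- 130 + 45 * eval_texture(tex_wall, xr, yr)
    img <- (1 - w_in) * 30 + w_in * ((1 - w_out) * wall_val + w_out * bg)
    if (cfg$noise_sd > 0) img <- img + rnorm(length(img), 0, cfg$noise_sd)
    frames[[t]] <- matrix(img, nr, nc)
  }
  frames
}

# Reference endocardial contour of one view (open polyline, annulus gap at
# the bottom of the image), densely sampled.
reference_contour <- function(cfg, ax, ay, n_pts = 361L) {
  nr <- cfg$image_size_px[1]; nc <- cfg$image_size_px[2]
  sp <- cfg$pixel_spacing_mm
  cx <- nc * sp / 2; cy <- nr * sp / 2
  th <- seq(cfg$annulus_gap_rad, 2 * pi - cfg$annulus_gap_rad,
            length.out = n_pts)
  # theta = 0 points at the annulus (bottom of image, +y)
  cbind(x = cx + ax * sin(th), y = cy + ay * cos(th))
}

#' Generate the synthetic deforming-atrium phantom
#'
#' Builds textured cine sequences of the 2-chamber and 4-chamber views of a
#' tri-phasically deforming ellipsoidal left atrium, together with exact
#' ground truth: per-frame endocardial contours, volumes, longitudinal
#' strain, phase indices and the P-wave frame. The chamber interior is dark,
#' the wall bright with frozen speckle that is advected with the deformation
#' so that patch tracking is driven by texture, not only by the edge.
#'
#' @param config A [phantom_config()].
#' @return An object of class `la_phantom`: a list with elements
#'   `cine_2ch`, `cine_4ch` ([cine_sequence()] objects), `sax` (a list of
#'   short-axis [cine_sequence()] stacks, or `NULL`), and `ground_truth`
#'   with fields `contours_2ch`, `contours_4ch` (per-frame point matrices,
#'   mm), `volume_ml`, `strain_pct`, `phase_indices`, `p_wave_frame`,
#'   `time_ms`, `sax_areas_mm2` (frames x slices), `sax_positions_mm`.
#' @examples
#' ph <- make_phantom(phantom_config(n_frames = 8, image_size_px = c(64, 64),
#'                                   semi_axes_mm = c(20, 13, 10),
#'                                   phase_frames = c(3, 5, 6)))
#' ph$ground_truth$volume_ml
#' @export
make_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "la_phantom_config"))
  cfg <- config
  a <- cfg$semi_axes_mm[1]; b <- cfg$semi_axes_mm[2]; c3 <- cfg$semi_axes_mm[3]
  sp <- cfg$pixel_spacing_mm
  nr <- cfg$image_size_px[1]; nc <- cfg$image_size_px[2]
  outer <- 1 + cfg$wall_frac
  stop_if(2 * a * outer >= nr * sp || 2 * max(b, c3) * outer >= nc * sp,
          "chamber (with wall) exceeds image bounds at Vmax; ",
          "enlarge image_size_px or shrink semi_axes_mm")

  set.seed(cfg$seed)
  tex_w4 <- make_texture(cfg$texture_grain_px * sp)
  tex_b4 <- make_texture(3 * cfg$texture_grain_px * sp)
  tex_w2 <- make_texture(cfg$texture_grain_px * sp)
  tex_b2 <- make_texture(3 * cfg$texture_grain_px * sp)

  vc <- phantom_volume_curve(cfg)
  s <- (vc$volume_ml / vc$v_max)^(1 / 3)
  i_max <- cfg$phase_frames[1]
  i_min <- which.min(vc$volume_ml)
  i_pre <- cfg$phase_frames[3]

  frames_4 <- render_view(cfg, ax = b, ay = a, s, tex_w4, tex_b4, TRUE)
  frames_2 <- render_view(cfg, ax = c3, ay = a, s, tex_w2, tex_b2, TRUE)

  contours <- function(ax) {
    ref <- reference_contour(cfg, ax, a)
    cx <- nc * sp / 2; cy <- nr * sp / 2
    m <- c(cx, cy + a * cos(cfg$annulus_gap_rad))
    lapply(seq_len(cfg$n_frames), function(t) {
      cbind(x = m[1] + s[t] * (ref[, 1] - m[1]),
            y = m[2] + s[t] * (ref[, 2] - m[2]))
    })
  }
  gt_4 <- contours(b)
  gt_2 <- contours(c3)

  strain <- (s / s[i_min] - 1) * 100

  # analytic short-axis slice areas on a grid fixed at Vmax; the chamber
  # shrinks within it, so end slices can fall outside the scaled ellipsoid
  dz <- cfg$sax_thickness_mm + cfg$sax_gap_mm
  zpos <- seq(-a + dz / 2, a - dz / 2, by = dz)
  sax_areas <- t(vapply(seq_len(cfg$n_frames), function(t) {
    rel <- 1 - (zpos / (s[t] * a))^2
    ifelse(rel > 0, pi * (s[t] * b) * (s[t] * c3) * rel, 0)
  }, numeric(length(zpos))))

  time_ms <- (seq_len(cfg$n_frames) - 1) * cfg$frame_interval_ms

  sax_stack <- NULL
  if (cfg$sax) {
    tex_ws <- make_texture(cfg$texture_grain_px * sp)
    tex_bs <- make_texture(3 * cfg$texture_grain_px * sp)
    sax_stack <- lapply(seq_along(zpos), function(k) {
      rel <- pmax(1 - (zpos[k] / (s * a))^2, 0)
      bx <- b * s * sqrt(rel); cxx <- c3 * s * sqrt(rel)
      fr <- vector("list", cfg$n_frames)
      for (t in seq_len(cfg$n_frames)) {
        if (bx[t] <= sp) {  # slice outside chamber: background only
          img <- matrix(70, nr, nc)
          if (cfg$noise_sd > 0)
            img <- img + matrix(rnorm(nr * nc, 0, cfg$noise_sd), nr, nc)
          fr[[t]] <- img
        } else {
          st <- render_view(cfg, ax = cxx[t], ay = bx[t], s = 1,
                            tex_ws, tex_bs, FALSE)
          fr[[t]] <- st[[1]]
        }
      }
      cine_sequence(fr, sp, cfg$frame_interval_ms, view = "sax")
    })
  }

  gt <- list(
    contours_2ch = gt_2,
    contours_4ch = gt_4,
    volume_ml = vc$volume_ml,
    strain_pct = strain,
    phase_indices = list(i_max = i_max, i_min = i_min, i_pre_a = i_pre),
    p_wave_frame = i_pre,
    time_ms = time_ms,
    scale = s,
    sax_areas_mm2 = sax_areas,
    sax_positions_mm = zpos,
    config = cfg
  )
  class(gt) <- "la_ground_truth"

  out <- list(
    cine_2ch = cine_sequence(frames_2, sp, cfg$frame_interval_ms,
                             view = "2ch", p_wave_frame = i_pre),
    cine_4ch = cine_sequence(frames_4, sp, cfg$frame_interval_ms,
                             view = "4ch", p_wave_frame = i_pre),
    sax = sax_stack,
    ground_truth = gt
  )
  class(out) <- "la_phantom"
  out
}

#' @export
print.la_phantom <- function(x, ...) {
  cfg <- x$ground_truth$config
  cat("LA cine phantom:", cfg$n_frames, "frames,",
      sprintf("Vmax %.2f ml, Vmin %.2f ml,",
              max(x$ground_truth$volume_ml), min(x$ground_truth$volume_ml)),
      sprintf("Smax %.1f%%", max(x$ground_truth$strain_pct)), "\n")
  invisible(x)
}

#' Write a phantom to disk
#'
#' Writes the cine views as NIfTI (default) or multi-page TIFF with spacing
#' metadata, and the ground truth as JSON. Frame and phase indices are
#' 0-based in the files (the R API is 1-based).
#'
#' @param phantom An `la_phantom` from [make_phantom()].
#' @param dir Output directory (created if needed).
#' @param format `"nifti"` or `"tiff"`.
#' @return Invisibly, the vector of files written.
#' @export
write_phantom <- function(phantom, dir, format = c("nifti", "tiff")) {
  stopifnot(inherits(phantom, "la_phantom"))
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stop_if(!dir.exists(dir), "cannot create directory: ", dir)
  ext <- if (format == "nifti") ".nii.gz" else ".tif"
  f2 <- file.path(dir, paste0("la_2ch", ext))
  f4 <- file.path(dir, paste0("la_4ch", ext))
  write_cine(phantom$cine_2ch, f2)
  write_cine(phantom$cine_4ch, f4)
  files <- c(f2, f4)
  if (!is.null(phantom$sax)) {
    for (k in seq_along(phantom$sax)) {
      fk <- file.path(dir, sprintf("la_sax_%02d%s", k, ext))
      write_cine(phantom$sax[[k]], fk)
      files <- c(files, fk)
    }
  }
  gt <- phantom$ground_truth
  cfg <- gt$config
  gt_json <- list(
    schema = "latrack-ground-truth-1",
    seed = cfg$seed,
    config_hash = config_hash(paste(deparse(unclass(cfg)), collapse = "")),
    pixel_spacing_mm = cfg$pixel_spacing_mm,
    frame_interval_ms = cfg$frame_interval_ms,
    n_frames = cfg$n_frames,
    volume_ml = gt$volume_ml,
    strain_pct = gt$strain_pct,
    time_ms = gt$time_ms,
    phase_indices = list(i_max = gt$phase_indices$i_max - 1L,
                         i_min = gt$phase_indices$i_min - 1L,
                         i_pre_a = gt$phase_indices$i_pre_a - 1L),
    p_wave_frame = gt$p_wave_frame - 1L,
    sax_positions_mm = gt$sax_positions_mm,
    sax_areas_mm2 = gt$sax_areas_mm2,
    contours_2ch = lapply(gt$contours_2ch, unname),
    contours_4ch = lapply(gt$contours_4ch, unname)
  )
  fj <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(gt_json, fj, auto_unbox = TRUE, digits = NA)
  invisible(c(files, fj))
}

#' Read phantom ground truth written by [write_phantom()]
#'
#' @param path Path to `ground_truth.json`.
#' @return A list mirroring the in-memory ground truth (1-based indices).
#' @export
read_ground_truth <- function(path) {
  stop_if(!file.exists(path), "no such file: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  stop_if(!identical(j$schema, "latrack-ground-truth-1"),
          "not a latrack ground-truth file: ", path)
  tomat <- function(m) {
    m <- as.matrix(m); colnames(m) <- c("x", "y"); m
  }
  # equal-sized per-frame matrices may come back simplified to a 3-D array
  contour_list <- function(cc) {
    if (is.array(cc) && length(dim(cc)) == 3) {
      lapply(seq_len(dim(cc)[1]), function(i) tomat(cc[i, , ]))
    } else lapply(cc, tomat)
  }
  list(
    seed = j$seed,
    pixel_spacing_mm = j$pixel_spacing_mm,
    frame_interval_ms = j$frame_interval_ms,
    n_frames = j$n_frames,
    volume_ml = j$volume_ml,
    strain_pct = j$strain_pct,
    time_ms = j$time_ms,
    phase_indices = list(i_max = j$phase_indices$i_max + 1L,
                         i_min = j$phase_indices$i_min + 1L,
                         i_pre_a = j$phase_indices$i_pre_a + 1L),
    p_wave_frame = j$p_wave_frame + 1L,
    sax_positions_mm = j$sax_positions_mm,
    sax_areas_mm2 = if (!is.null(j$sax_areas_mm2)) as.matrix(j$sax_areas_mm2),
    contours_2ch = contour_list(j$contours_2ch),
    contours_4ch = contour_list(j$contours_4ch)
  )
}
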