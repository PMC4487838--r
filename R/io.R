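# Readers/writers: cine stacks (NIfTI / multi-page TIFF + JSON sidecar),
# contour files (JSON/CSV) and paired-measurement tables.

#' Cine image sequence
#'
#' Container for one view's stack of 2-D frames with physical metadata.
#'
#' @param frames List of numeric matrices (rows x cols), one per frame,
#'   ordered by time.
#' @param pixel_spacing_mm In-plane pixel size, mm (isotropic).
#' @param frame_interval_ms Time between frames, ms.
#' @param view One of `"2ch"`, `"4ch"`, `"sax"`.
#' @param p_wave_frame Optional 1-based frame index of P-wave onset.
#' @return An object of class `la_cine`.
#' @export
cine_sequence <- function(frames, pixel_spacing_mm, frame_interval_ms,
                          view = c("4ch", "2ch", "sax"),
                          p_wave_frame = NULL) {
  view <- match.arg(view)
  stop_if(!is.list(frames) || length(frames) < 1, "frames must be a non-empty list")
  stop_if(!all(vapply(frames, is.matrix, logical(1))),
          "every frame must be a numeric matrix")
  d <- dim(frames[[1]])
  stop_if(!all(vapply(frames, function(f) identical(dim(f), d), logical(1))),
          "all frames must share the same dimensions")
  stop_if(!is.numeric(pixel_spacing_mm) || pixel_spacing_mm <= 0,
          "pixel_spacing_mm must be a positive number")
  stop_if(!is.numeric(frame_interval_ms) || frame_interval_ms <= 0,
          "frame_interval_ms must be a positive number")
  if (!is.null(p_wave_frame)) {
    stop_if(!is_count(p_wave_frame) || p_wave_frame > length(frames),
            "p_wave_frame out of range")
    p_wave_frame <- as.integer(p_wave_frame)
  }
  structure(list(frames = frames,
                 pixel_spacing_mm = pixel_spacing_mm,
                 frame_interval_ms = frame_interval_ms,
                 view = view,
                 p_wave_frame = p_wave_frame),
            class = "la_cine")
}

#' @export
print.la_cine <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Cine sequence [%s]: %d frames of %d x %d px, %g mm/px, %g ms/frame\n",
              x$view, length(x$frames), d[1], d[2],
              x$pixel_spacing_mm, x$frame_interval_ms))
  invisible(x)
}

#' Number of frames in a cine sequence
#' @param x An `la_cine`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) length(x$frames)

sidecar_path <- function(path) {
  sub("\\.(nii\\.gz|nii|tif|tiff)$", ".json", path, ignore.case = TRUE)
}

#' Write a cine sequence
#'
#' NIfTI files (`.nii`, `.nii.gz`) store frames along the third dimension
#' with `pixdim = (spacing, spacing, frame_interval_ms)` and are lossless
#' (float64). TIFF files (`.tif`, `.tiff`) are written as 32-bit float
#' multi-page stacks scaled to `[0, 1]`, with the intensity scale and the
#' physical metadata in a JSON sidecar next to the image.
#'
#' @param cs An [cine_sequence()].
#' @param path Output path; format chosen by extension.
#' @return Invisibly, `path`.
#' @export
write_cine <- function(cs, path) {
  stopifnot(inherits(cs, "la_cine"))
  nfr <- length(cs$frames)
  d <- dim(cs$frames[[1]])
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    arr <- array(0, dim = c(d[1], d[2], nfr))
    for (t in seq_len(nfr)) arr[, , t] <- cs$frames[[t]]
    img <- RNifti::asNifti(arr)
    img <- RNifti::`pixdim<-`(img, c(cs$pixel_spacing_mm, cs$pixel_spacing_mm,
                                     cs$frame_interval_ms))
    RNifti::writeNifti(img, path, datatype = "double")
    side <- list(pixel_spacing_mm = cs$pixel_spacing_mm,
                 frame_interval_ms = cs$frame_interval_ms,
                 view = cs$view, p_wave_frame_0based = if (!is.null(cs$p_wave_frame))
                   cs$p_wave_frame - 1L)
    jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    lo <- min(vapply(cs$frames, min, numeric(1)))
    hi <- max(vapply(cs$frames, max, numeric(1)))
    scale <- max(hi - lo, 1e-12)
    pages <- lapply(cs$frames, function(f) (f - lo) / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    side <- list(pixel_spacing_mm = cs$pixel_spacing_mm,
                 frame_interval_ms = cs$frame_interval_ms,
                 view = cs$view,
                 intensity_offset = lo, intensity_scale = scale,
                 p_wave_frame_0based = if (!is.null(cs$p_wave_frame))
                   cs$p_wave_frame - 1L)
    jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  } else {
    stop("unknown image format (use .nii, .nii.gz, .tif or .tiff): ", path,
         call. = FALSE)
  }
  invisible(path)
}

#' Read a cine sequence
#'
#' For NIfTI the third dimension is interpreted as time; pixel spacing and
#' the frame interval are taken from `pixdim` (a JSON sidecar, if present,
#' overrides). For TIFF the JSON sidecar is mandatory: a stack without
#' spacing and timing metadata is rejected rather than silently defaulted.
#'
#' @param path Image path (`.nii`, `.nii.gz`, `.tif`, `.tiff`).
#' @param view View label; defaults to the sidecar's, else `"4ch"`.
#' @return An [cine_sequence()].
#' @export
read_cine <- function(path, view = NULL) {
  stop_if(!file.exists(path), "no such file: ", path)
  sc <- NULL
  sp_file <- sidecar_path(path)
  if (file.exists(sp_file)) sc <- jsonlite::read_json(sp_file, simplifyVector = TRUE)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    stop_if(length(dim(arr)) != 3, "expected a 3-D NIfTI (rows, cols, time): ", path)
    pd <- RNifti::pixdim(img)
    spacing <- sc$pixel_spacing_mm %||% pd[1]
    dt <- sc$frame_interval_ms %||% if (length(pd) >= 3) pd[3] else NA_real_
    stop_if(!isTRUE(spacing > 0) || !isTRUE(abs(pd[1] - pd[2]) < 1e-9),
            "missing or anisotropic pixel spacing in ", path,
            " (no silent default; provide pixdim or a JSON sidecar)")
    stop_if(!isTRUE(dt > 0),
            "missing frame interval in ", path,
            " (no silent default; provide pixdim[3] or a JSON sidecar)")
    frames <- lapply(seq_len(dim(arr)[3]), function(t) arr[, , t])
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    stop_if(is.null(sc), "TIFF cine requires a JSON sidecar with ",
            "pixel_spacing_mm and frame_interval_ms: ", sp_file, " not found")
    stop_if(is.null(sc$pixel_spacing_mm) || is.null(sc$frame_interval_ms),
            "sidecar ", sp_file, " lacks pixel_spacing_mm/frame_interval_ms")
    spacing <- sc$pixel_spacing_mm
    dt <- sc$frame_interval_ms
    pages <- tiff::readTIFF(path, all = TRUE)
    off <- sc$intensity_offset %||% 0
    scl <- sc$intensity_scale %||% 1
    frames <- lapply(pages, function(p) p * scl + off)
  } else {
    stop("unknown image format: ", path, call. = FALSE)
  }
  pw <- if (!is.null(sc$p_wave_frame_0based)) sc$p_wave_frame_0based + 1L
  cine_sequence(frames, spacing, dt,
                view = view %||% sc$view %||% "4ch",
                p_wave_frame = pw)
}

#' Write tracked contours to JSON or CSV
#'
#' JSON: one record per frame with `view`, 0-based `frame_index`, the point
#' list in mm and per-point match scores. CSV: long format with columns
#' `view, frame_index, point_index, x_mm, y_mm, score` (0-based indices).
#'
#' @param cs An `la_contour_sequence` from [propagate_contour()].
#' @param path Output path ending in `.json` or `.csv`.
#' @return Invisibly, `path`.
#' @export
write_contours <- function(cs, path) {
  stopifnot(inherits(cs, "la_contour_sequence"))
  nfr <- length(cs$contours)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- lapply(seq_len(nfr), function(t) {
      list(view = cs$view, frame_index = t - 1L,
           points = unname(cs$contours[[t]]),
           score = unname(cs$quality[t, ]))
    })
    jsonlite::write_json(list(schema = "latrack-contours-1",
                              ref_frame = cs$ref_frame - 1L,
                              pixel_spacing_mm = cs$pixel_spacing_mm,
                              frame_interval_ms = cs$frame_interval_ms,
                              closure_drift_mm = cs$closure_drift_mm,
                              frames = recs),
                         path, auto_unbox = TRUE, digits = NA)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    rows <- do.call(rbind, lapply(seq_len(nfr), function(t) {
      p <- cs$contours[[t]]
      data.frame(view = cs$view, frame_index = t - 1L,
                 point_index = seq_len(nrow(p)) - 1L,
                 x_mm = p[, 1], y_mm = p[, 2], score = cs$quality[t, ])
    }))
    write.csv(rows, path, row.names = FALSE)
  } else stop("use a .json or .csv path", call. = FALSE)
  invisible(path)
}

#' Read contours written by [write_contours()]
#'
#' @param path `.json` contour file.
#' @return An `la_contour_sequence`.
#' @export
read_contours <- function(path) {
  stop_if(!file.exists(path), "no such file: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  stop_if(!identical(j$schema, "latrack-contours-1"),
          "not a latrack contour file: ", path)
  tomat <- function(m) {
    m <- as.matrix(m); colnames(m) <- c("x", "y"); m
  }
  pts <- j$frames$points
  contours <- if (is.array(pts) && length(dim(pts)) == 3) {
    lapply(seq_len(dim(pts)[1]), function(i) tomat(pts[i, , ]))
  } else lapply(pts, tomat)
  quality <- if (is.matrix(j$frames$score)) j$frames$score else
    do.call(rbind, j$frames$score)
  structure(list(contours = contours,
                 quality = quality,
                 ref_frame = j$ref_frame + 1L,
                 view = j$frames$view[1],
                 pixel_spacing_mm = j$pixel_spacing_mm,
                 frame_interval_ms = j$frame_interval_ms,
                 closure_drift_mm = j$closure_drift_mm,
                 flagged_frames = integer(0)),
            class = "la_contour_sequence")
}

#' Read a paired-measurement table
#'
#' Expects a CSV with columns `subject_id, parameter, value_a, value_b`.
#' Rows with missing values are dropped pairwise.
#'
#' @param path CSV path.
#' @param labels Length-2 character: names of the two methods/readers/visits.
#' @return A named list of [paired_measurements()], one per parameter.
#' @export
read_paired_csv <- function(path, labels = c("A", "B")) {
  stop_if(!file.exists(path), "no such file: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "parameter", "value_a", "value_b")
  stop_if(!all(need %in% names(d)),
          "paired CSV must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(d, d$parameter), function(g) {
    paired_measurements(g$value_a, g$value_b, labels = labels,
                        parameter = g$parameter[1])
  })
  out
}
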