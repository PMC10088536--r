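#' EBUS video container
#'
#' An `ebus_video` holds an ordered stack of grayscale frames together with
#' the acquisition frame rate and the fan-shaped cone mask delimiting the
#' insonified region. Frame intensities are normalized to `[0, 1]`; pixels
#' outside the cone are zero. Pixel coordinates are 0-based `(row, col)` with
#' the origin at the top-left corner.
#'
#' @param frames Numeric array `rows x cols x n_frames` with values in
#'   `[0, 1]`, or a list of equally sized matrices.
#' @param frame_rate Acquisition rate in frames per second.
#' @param cone_mask Logical matrix marking the ultrasound cone; must match
#'   the frame shape. Defaults to all-`TRUE`.
#'
#' @return An object of class `ebus_video` with elements `frames`,
#'   `frame_rate`, `cone_mask`.
#' @export
ebus_video <- function(frames, frame_rate, cone_mask = NULL) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) {
      abort("All frames must share the same shape.")
    }
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1]], length(frames)))
  }
  if (length(dim(frames)) != 3L) {
    abort("`frames` must be a rows x cols x n_frames array.")
  }
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0) {
    abort("`frame_rate` must be a single positive number (frames/s).")
  }
  if (is.null(cone_mask)) {
    cone_mask <- matrix(TRUE, nrow = dim(frames)[1], ncol = dim(frames)[2])
  }
  cone_mask <- cone_mask > 0
  if (!identical(dim(cone_mask), dim(frames)[1:2])) {
    abort("`cone_mask` shape must match the frames.")
  }
  structure(
    list(frames = frames, frame_rate = frame_rate, cone_mask = cone_mask),
    class = "ebus_video"
  )
}

#' @export
print.ebus_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<ebus_video> %d frames of %d x %d px @ %.6g fps (%.2f s), cone %d px\n",
    d[3], d[1], d[2], x$frame_rate, d[3] / x$frame_rate, sum(x$cone_mask)
  ))
  invisible(x)
}

#' @export
length.ebus_video <- function(x) dim(x$frames)[3]

#' Frame timestamps of a video
#'
#' @param video An [ebus_video()].
#' @return Numeric vector of frame times in seconds, starting at 0.
#' @export
video_times <- function(video) {
  stopifnot(inherits(video, "ebus_video"))
  (seq_len(dim(video$frames)[3]) - 1) / video$frame_rate
}

#' Extract a single frame
#'
#' @param video An [ebus_video()].
#' @param i Frame index (1-based).
#' @return Numeric matrix.
#' @export
video_frame <- function(video, i) {
  stopifnot(inherits(video, "ebus_video"))
  video$frames[, , i]
}

#' Injection annotation
#'
#' Per-injection metadata the analysis needs: the manually identified needle
#' tip, the direction of needle insertion, the injection onset time, the
#' injected volume and the pixel calibration. The needle tip is a 0-based
#' `(row, col)` pixel coordinate; `needle_angle` is measured in degrees from
#' the image column axis toward increasing rows (i.e. clockwise on screen),
#' pointing along the insertion direction away from the transducer.
#'
#' @param needle_tip Numeric length-2, 0-based `(row, col)` pixel position of
#'   the needle tip, or `NULL` when the tip was not visible (see
#'   [inherit_needle_tip()]).
#' @param needle_angle Degrees from the image X (column) axis.
#' @param t0 Injection onset time in seconds from the start of the video.
#' @param injected_volume Total injected volume in mL.
#' @param px_per_cm Pixel calibration, pixels per centimetre.
#' @param injection_id Label such as `"A21"`.
#' @param provenance `"annotated"` or `"inherited"` (set by
#'   [inherit_needle_tip()]).
#'
#' @return An object of class `injection_annotation`.
#' @export
injection_annotation <- function(needle_tip, needle_angle, t0,
                                 injected_volume, px_per_cm,
                                 injection_id = "unlabelled",
                                 provenance = "annotated") {
  if (!is.null(needle_tip)) {
    stopifnot(is.numeric(needle_tip), length(needle_tip) == 2L)
  }
  if (injected_volume <= 0) abort("`injected_volume` must be > 0 mL.")
  if (px_per_cm <= 0) abort("`px_per_cm` must be > 0.")
  structure(
    list(
      needle_tip = needle_tip, needle_angle = needle_angle, t0 = t0,
      injected_volume = injected_volume, px_per_cm = px_per_cm,
      injection_id = injection_id, provenance = provenance
    ),
    class = "injection_annotation"
  )
}

#' Inherit the needle-tip position from the previous injection
#'
#' When the needle tip is not visible in a video, its position (and the
#' needle axis) is assumed identical to the previous injection of the same
#' intervention. The returned annotation is flagged `provenance =
#' "inherited"`.
#'
#' @param current An [injection_annotation()] whose `needle_tip` may be
#'   `NULL`.
#' @param previous The preceding [injection_annotation()] of the same
#'   intervention.
#' @return `current`, unchanged if it already has a tip, otherwise with the
#'   tip and angle copied from `previous`.
#' @export
inherit_needle_tip <- function(current, previous = NULL) {
  stopifnot(inherits(current, "injection_annotation"))
  if (!is.null(current$needle_tip)) {
    return(current)
  }
  if (is.null(previous) || is.null(previous$needle_tip)) {
    abort(paste0(
      "No needle tip for '", current$injection_id,
      "' and no previous annotation to inherit from; annotate the tip manually."
    ))
  }
  current$needle_tip <- previous$needle_tip
  current$needle_angle <- previous$needle_angle
  current$provenance <- "inherited"
  current
}

#' Square region of interest centered on the needle tip
#'
#' Computes the bounds of the square ROI (default 1 cm x 1 cm) centered on
#' the needle tip, clipped to the image. For even side lengths the tip sits
#' at index `floor(side / 2)` of the square (ties broken toward the
#' top-left).
#'
#' @param annotation An [injection_annotation()] with a needle tip.
#' @param image_dim Integer length-2 `(rows, cols)`.
#' @param side_cm Side of the square in cm (default 1).
#' @return A list with 1-based inclusive pixel bounds `row0`, `row1`,
#'   `col0`, `col1`, the realized side length and `clipped` flag.
#' @export
roi_bounds <- function(annotation, image_dim, side_cm = 1) {
  stopifnot(inherits(annotation, "injection_annotation"))
  tip <- annotation$needle_tip
  if (is.null(tip)) abort("Annotation has no needle tip.")
  if (tip[1] < 0 || tip[2] < 0 ||
      tip[1] > image_dim[1] - 1 || tip[2] > image_dim[2] - 1) {
    abort("Needle tip lies outside the image.")
  }
  side <- max(1L, as.integer(round(side_cm * annotation$px_per_cm)))
  # 0-based start so that the tip lands at index floor(side/2) of the square
  r0 <- as.integer(round(tip[1])) - side %/% 2L
  c0 <- as.integer(round(tip[2])) - side %/% 2L
  r1 <- r0 + side - 1L
  c1 <- c0 + side - 1L
  clipped <- r0 < 0L || c0 < 0L || r1 > image_dim[1] - 1L || c1 > image_dim[2] - 1L
  list(
    row0 = max(r0, 0L) + 1L, row1 = min(r1, image_dim[1] - 1L) + 1L,
    col0 = max(c0, 0L) + 1L, col1 = min(c1, image_dim[2] - 1L) + 1L,
    side_px = side, clipped = clipped
  )
}

#' Extract the needle-tip region of interest from a frame
#'
#' @param frame Numeric matrix.
#' @param annotation An [injection_annotation()].
#' @param side_cm ROI side in cm (default 1).
#' @return The square sub-image, with the realized bounds attached as
#'   attribute `"bounds"`.
#' @export
extract_roi <- function(frame, annotation, side_cm = 1) {
  b <- roi_bounds(annotation, dim(frame), side_cm)
  out <- frame[b$row0:b$row1, b$col0:b$col1, drop = FALSE]
  attr(out, "bounds") <- b
  out
}

#' Read a grayscale video from a multi-page TIFF
#'
#' Frames are converted to luminance if RGB and normalized to `[0, 1]`.
#' Lossless multi-page TIFF is the supported container. The frame rate is
#' not stored by TIFF, so it must be supplied (or present in a JSON sidecar
#' written by [write_video()]).
#'
#' @param path Path to a multi-page TIFF.
#' @param frame_rate Frames per second; overrides any sidecar value.
#' @param cone_mask Optional logical matrix; if `NULL` and a sidecar mask
#'   exists it is used, otherwise the mask is estimated with
#'   [estimate_cone_mask()].
#' @return An [ebus_video()].
#' @export
read_video <- function(path, frame_rate = NULL, cone_mask = NULL) {
  if (!file.exists(path)) abort(paste0("Video file not found: ", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L) {
    abort("A video needs at least 2 frames; got a single-page file.")
  }
  to_gray <- function(p) {
    if (length(dim(p)) == 3L) {
      # ITU-R BT.601 luminance
      0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3]
    } else {
      p
    }
  }
  frames <- lapply(pages, to_gray)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  if (is.null(frame_rate)) frame_rate <- meta$frame_rate_fps
  if (is.null(frame_rate)) {
    abort("Frame rate unknown: supply `frame_rate` (no sidecar value found).")
  }
  if (is.null(cone_mask)) {
    mask_path <- paste0(path, ".cone.tif")
    if (file.exists(mask_path)) {
      cone_mask <- tiff::readTIFF(mask_path) > 0.5
    }
  }
  v <- ebus_video(frames, as.numeric(frame_rate), cone_mask)
  if (is.null(cone_mask)) v$cone_mask <- estimate_cone_mask(v)
  v
}

#' Write a video as 8-bit multi-page TIFF
#'
#' Intensities are clamped to `[0, 1]` and quantized to 8 bits. The frame
#' rate is recorded in a JSON sidecar `<path>.json` and the cone mask in
#' `<path>.cone.tif`, so [read_video()] round-trips without extra arguments.
#'
#' @param video An [ebus_video()].
#' @param path Output TIFF path.
#' @param bits Bits per sample, 8 (default) or 16.
#' @return `path`, invisibly.
#' @export
write_video <- function(video, path, bits = 8L) {
  stopifnot(inherits(video, "ebus_video"))
  frames <- lapply(seq_len(length(video)), function(i) {
    pmin(pmax(video$frames[, , i], 0), 1)
  })
  tiff::writeTIFF(frames, path, bits.per.sample = as.integer(bits),
                  compression = "none")
  jsonlite::write_json(
    list(frame_rate_fps = video$frame_rate),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  tiff::writeTIFF(matrix(as.numeric(video$cone_mask),
                         nrow = nrow(video$cone_mask)),
                  paste0(path, ".cone.tif"), bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}

#' Write a binary mask series as multi-page TIFF
#'
#' Masks are stored with values {0, 255} (8-bit).
#'
#' @param masks Logical array `rows x cols x n`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_masks <- function(masks, path) {
  pages <- lapply(seq_len(dim(masks)[3]), function(i) {
    matrix(as.numeric(masks[, , i] > 0), nrow = dim(masks)[1])
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' Estimate the ultrasound cone mask from a clinical-style video
#'
#' Thresholds the temporal maximum image at a small floor (default 2/255)
#' and keeps the largest connected component. Synthetic videos carry their
#' cone mask in a sidecar, so this is only needed for externally produced
#' recordings.
#'
#' @param video An [ebus_video()].
#' @param floor Intensity floor in normalized units.
#' @return Logical matrix.
#' @export
estimate_cone_mask <- function(video, floor = 2 / 255) {
  mx <- apply(video$frames, c(1, 2), max)
  bin <- mx > floor
  lab <- EBImage::bwlabel(bin)
  if (max(lab) == 0) {
    return(bin)
  }
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

#' Read / write an injection annotation JSON sidecar
#'
#' @param path JSON file path.
#' @return [read_annotation()] returns an [injection_annotation()].
#' @export
read_annotation <- function(path) {
  j <- jsonlite::read_json(path)
  injection_annotation(
    needle_tip = if (is.null(j$needle_tip)) NULL else unlist(j$needle_tip),
    needle_angle = j$needle_angle,
    t0 = j$t0,
    injected_volume = j$injected_volume,
    px_per_cm = j$px_per_cm,
    injection_id = j$injection_id %||% "unlabelled",
    provenance = j$provenance %||% "annotated"
  )
}

#' @rdname read_annotation
#' @param annotation An [injection_annotation()].
#' @export
write_annotation <- function(annotation, path) {
  jsonlite::write_json(
    unclass(annotation), path,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
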