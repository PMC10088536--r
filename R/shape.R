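#' Needle-centered coordinate frame
#'
#' A 2-D Cartesian frame with its origin at the needle tip, its x-axis
#' along the needle insertion direction and its y-axis perpendicular
#' (rotated 90 degrees counterclockwise from x in the right-handed
#' image frame whose row axis points downward). All shape metrics are
#' reported in centimetres in this frame.
#'
#' @param annotation An [injection_annotation()] (tip, angle, calibration),
#'   or `NULL` if `tip`, `angle` and `px_per_cm` are given directly.
#' @param tip,angle,px_per_cm Direct specification (0-based `(row, col)`
#'   tip, degrees from the column axis, pixels/cm).
#' @return An object of class `needle_frame`.
#' @export
needle_frame <- function(annotation = NULL, tip = NULL, angle = NULL,
                         px_per_cm = NULL) {
  if (!is.null(annotation)) {
    stopifnot(inherits(annotation, "injection_annotation"))
    tip <- annotation$needle_tip
    angle <- annotation$needle_angle
    px_per_cm <- annotation$px_per_cm
  }
  if (is.null(tip)) abort("A needle tip is required.")
  ax <- needle_axes(angle)
  structure(
    list(origin = tip, u = ax$u, v = ax$v, angle = angle,
         px_per_cm = px_per_cm),
    class = "needle_frame"
  )
}

#' Map mask pixels to needle-frame coordinates
#'
#' Pixel centers of the `TRUE` pixels are mapped to `(x, y)` in cm: origin
#' at the needle tip, x along the insertion direction, y perpendicular.
#'
#' @param mask Logical matrix.
#' @param frame A [needle_frame()].
#' @return A tibble with columns `x`, `y` (cm), one row per mask pixel.
#' @export
to_needle_frame <- function(mask, frame) {
  stopifnot(inherits(frame, "needle_frame"))
  idx <- which(mask > 0, arr.ind = TRUE)
  dr <- (idx[, 1] - 1) - frame$origin[1]
  dc <- (idx[, 2] - 1) - frame$origin[2]
  # (col, row) displacement in cm projected on the needle axes
  x <- (dc * frame$u[1] + dr * frame$u[2]) / frame$px_per_cm
  y <- (dc * frame$v[1] + dr * frame$v[2]) / frame$px_per_cm
  tibble::tibble(x = as.numeric(x), y = as.numeric(y))
}

#' Min/max Feret diameters of a mask
#'
#' The maximum Feret diameter is the convex-hull diameter (largest
#' pairwise distance between hull vertices); the minimum is the smallest
#' width over all directions, found by rotating calipers over hull edges.
#' Computed on pixel centers, in cm.
#'
#' @param mask Logical matrix.
#' @param frame A [needle_frame()] (supplies the calibration).
#' @return Named numeric `c(feret_min, feret_max)` in cm; `NA` for an
#'   empty mask.
#' @export
feret_diameters <- function(mask, frame) {
  pts <- to_needle_frame(mask, frame)
  if (nrow(pts) == 0) {
    return(c(feret_min = NA_real_, feret_max = NA_real_))
  }
  p <- unique(as.matrix(pts))
  if (nrow(p) == 1) {
    return(c(feret_min = 0, feret_max = 0))
  }
  h <- grDevices::chull(p[, 1], p[, 2])
  hp <- p[h, , drop = FALSE]
  d <- as.matrix(stats::dist(hp))
  fmax <- max(d)
  if (nrow(hp) == 2) {
    return(c(feret_min = 0, feret_max = fmax))
  }
  # minimal width: for each hull edge, the farthest vertex distance to the
  # supporting line; the minimum over edges is the caliper width
  nh <- nrow(hp)
  widths <- vapply(seq_len(nh), function(i) {
    a <- hp[i, ]
    b <- hp[if (i == nh) 1L else i + 1L, ]
    e <- b - a
    len <- sqrt(sum(e^2))
    if (len == 0) return(Inf)
    n_hat <- c(-e[2], e[1]) / len
    max(abs((hp[, 1] - a[1]) * n_hat[1] + (hp[, 2] - a[2]) * n_hat[2]))
  }, numeric(1))
  c(feret_min = min(widths), feret_max = fmax)
}

#' Solid-of-revolution volume of a mask about the needle axis
#'
#' The mask is split into its `y > 0` and `y < 0` parts; each contributes
#' via Pappus's theorem (`V = 2 * pi * |y_centroid| * area`, summed over
#' pixels), and the contributions are added. Pixels are assigned by the
#' sign of their center's y coordinate; pixel centers exactly on the axis
#' contribute zero. This two-sided construction is well defined for depots
#' deflected off the needle axis and reduces to the classic solid of
#' revolution for one-sided shapes.
#'
#' @param mask Logical matrix.
#' @param frame A [needle_frame()].
#' @return Volume in cm^3 (= mL).
#' @export
rotation_volume <- function(mask, frame) {
  pts <- to_needle_frame(mask, frame)
  if (nrow(pts) == 0) abort("Cannot compute a rotation volume of an empty mask.")
  px_area <- (1 / frame$px_per_cm)^2
  2 * pi * sum(abs(pts$y)) * px_area
}

#' Per-frame shape metrics of a depot mask series
#'
#' Computes, for every mask, the area, the needle-frame centroid and the
#' min/max Feret diameters. Frames with empty masks yield `NA` (a missing
#' depot is not a depot at the origin).
#'
#' @param series A [depot_mask_series()].
#' @param frame A [needle_frame()].
#' @return A tibble of class `shape_trace`: `time`, `area_cm2`,
#'   `centroid_x`, `centroid_y`, `feret_min`, `feret_max` (cm).
#' @export
shape_trace <- function(series, frame) {
  stopifnot(inherits(series, "depot_mask_series"))
  px_area <- (1 / frame$px_per_cm)^2
  rows <- purrr::map(seq_along(series$times), function(i) {
    m <- series$masks[, , i]
    if (!any(m)) {
      return(tibble::tibble(
        time = series$times[i], area_cm2 = NA_real_,
        centroid_x = NA_real_, centroid_y = NA_real_,
        feret_min = NA_real_, feret_max = NA_real_
      ))
    }
    pts <- to_needle_frame(m, frame)
    fer <- feret_diameters(m, frame)
    tibble::tibble(
      time = series$times[i],
      area_cm2 = nrow(pts) * px_area,
      centroid_x = mean(pts$x), centroid_y = mean(pts$y),
      feret_min = fer[["feret_min"]], feret_max = fer[["feret_max"]]
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("shape_trace", class(out))
  out
}

#' Centroid path of the depot
#'
#' Convenience wrapper around [shape_trace()] returning only the centroid
#' columns.
#'
#' @inheritParams shape_trace
#' @return Tibble `time`, `centroid_x`, `centroid_y` (cm).
#' @export
centroid_path <- function(series, frame) {
  shape_trace(series, frame)[, c("time", "centroid_x", "centroid_y")]
}

#' Retention estimate from the final depot mask
#'
#' The retained drug volume is estimated as the solid of revolution of the
#' segmented area at the end of the injection about the needle axis; the
#' retention percentage is that volume over the injected volume, and the
#' difference estimates the volume escaping the imaged region. A per-frame
#' retention trace (smoothed with a 1-s moving average) is attached for
#' plotting the time course.
#'
#' @param series A [depot_mask_series()].
#' @param frame A [needle_frame()].
#' @param injected_volume mL.
#' @return An object of class `retention_estimate` with
#'   `rotation_volume_ml`, `injected_volume_ml`, `retention_pct`,
#'   `escaped_volume_ml` and a `trace` tibble (`time`,
#'   `retention_pct`).
#' @export
retention <- function(series, frame, injected_volume) {
  stopifnot(inherits(series, "depot_mask_series"))
  if (injected_volume <= 0) abort("`injected_volume` must be > 0 mL.")
  n <- length(series$times)
  final <- series$masks[, , n]
  if (!any(final)) {
    abort("Final mask is empty: no depot detected at the end of the injection.")
  }
  vol <- rotation_volume(final, frame)
  vols <- vapply(seq_len(n), function(i) {
    m <- series$masks[, , i]
    if (!any(m)) 0 else rotation_volume(m, frame)
  }, numeric(1))
  fr <- if (n > 1) 1 / stats::median(diff(series$times)) else 1
  tr <- new_intensity_trace(
    series$times - series$times[1], 100 * vols / injected_volume,
    region = "cone", frame_rate = fr
  )
  tr_sm <- if (n > 1 && fr >= 1) moving_average(tr, 1) else tr
  structure(
    list(
      rotation_volume_ml = vol,
      injected_volume_ml = injected_volume,
      retention_pct = 100 * vol / injected_volume,
      escaped_volume_ml = injected_volume - vol,
      trace = tibble::tibble(time = tr_sm$time,
                             retention_pct = tr_sm$value)
    ),
    class = "retention_estimate"
  )
}

#' @export
print.retention_estimate <- function(x, ...) {
  cat(sprintf(
    "<retention_estimate> %.2f mL of %.2f mL retained (%.1f%%), %.2f mL escaped\n",
    x$rotation_volume_ml, x$injected_volume_ml, x$retention_pct,
    x$escaped_volume_ml
  ))
  invisible(x)
}

#' @rdname retention
#' @param x A `retention_estimate`.
#' @param ... Unused.
#' @export
glance.retention_estimate <- function(x, ...) {
  tibble::tibble(
    rotation_volume_ml = x$rotation_volume_ml,
    injected_volume_ml = x$injected_volume_ml,
    retention_pct = x$retention_pct,
    escaped_volume_ml = x$escaped_volume_ml
  )
}

#' Plot depot shape metrics over time
#'
#' @param object A `shape_trace`.
#' @param ... Unused.
#' @return A ggplot (centroid and Feret panels).
#' @export
autoplot.shape_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as.data.frame(object),
    c("centroid_x", "centroid_y", "feret_min", "feret_max"),
    names_to = "metric", values_to = "cm"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$cm,
                                     colour = .data$metric)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "time (s)", y = "cm") +
    ggplot2::theme_minimal()
}
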