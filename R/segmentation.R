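#' Pre-injection background model
#'
#' The background is the pixel-wise mean of the frames in the window
#' immediately preceding the injection onset, `[t0 - window, t0)`. It
#' captures the static scene (tissue echo, needle artifact) and is removed
#' before depot segmentation and before the mean-cone uptake trace.
#'
#' @param video An [ebus_video()].
#' @param t0 Injection onset, seconds.
#' @param window Averaging window, seconds (default 1).
#' @return An object of class `background_model` (`image`, `window`, `t0`,
#'   `n_frames`).
#' @export
compute_background <- function(video, t0, window = 1) {
  stopifnot(inherits(video, "ebus_video"))
  if (t0 < window) {
    abort(sprintf(
      "Cannot average a %.3g-s background window before t0 = %.3g s (%.3g s short).",
      window, t0, window - t0
    ))
  }
  times <- video_times(video)
  keep <- which(times >= t0 - window & times < t0)
  if (length(keep) == 0) abort("No frames fall in the background window.")
  img <- apply(video$frames[, , keep, drop = FALSE], c(1, 2), mean)
  structure(
    list(image = img, window = window, t0 = t0, n_frames = length(keep)),
    class = "background_model"
  )
}

#' Edge-preserving despeckling by anisotropic diffusion
#'
#' Perona-Malik diffusion with exponential conductance
#' `g(|grad|) = exp(-(|grad| / K)^2)`: smoothing is strong inside
#' homogeneous speckle regions and shuts down across high-gradient
#' boundaries, so depot edges survive while speckle is averaged out. The
#' edge scale `K` defaults to the 90th percentile of the initial gradient
#' magnitudes.
#'
#' @param image Numeric matrix.
#' @param iterations Diffusion iterations (default 10); 0 returns the input.
#' @param conductance Edge scale `K`; `NULL` (default) uses the 90th
#'   percentile of `|grad|` of the input.
#' @param lambda Step size, must be `<= 0.25` for stability (default 0.25).
#' @return The filtered matrix.
#' @export
despeckle <- function(image, iterations = 10, conductance = NULL,
                      lambda = 0.25) {
  if (!all(is.finite(image))) abort("`image` must be finite.")
  if (iterations == 0) return(image)
  if (lambda > 0.25 || lambda <= 0) abort("`lambda` must lie in (0, 0.25].")
  u <- image
  if (is.null(conductance)) {
    gn <- u[-1, ] - u[-nrow(u), ]
    ge <- u[, -1] - u[, -ncol(u)]
    conductance <- as.numeric(quantile(abs(c(gn, ge)), 0.9))
    if (conductance <= 0) return(image) # flat image: nothing to diffuse
  }
  k2 <- conductance^2
  nr <- nrow(u)
  nc <- ncol(u)
  for (i in seq_len(iterations)) {
    # 4-neighbour differences with replicated borders
    dn <- rbind(u[1, , drop = FALSE], u[-nr, , drop = FALSE]) - u
    ds <- rbind(u[-1, , drop = FALSE], u[nr, , drop = FALSE]) - u
    dw <- cbind(u[, 1, drop = FALSE], u[, -nc, drop = FALSE]) - u
    de <- cbind(u[, -1, drop = FALSE], u[, nc, drop = FALSE]) - u
    u <- u + lambda * (
      exp(-(dn / conductance)^2) * dn + exp(-(ds / conductance)^2) * ds +
      exp(-(dw / conductance)^2) * dw + exp(-(de / conductance)^2) * de
    )
  }
  u
}

#' Two-cluster intensity threshold over the cone (Otsu's criterion)
#'
#' Splits the within-cone intensity histogram (256 bins) into foreground
#' and background at the cut maximizing the between-class variance. If the
#' best split's between-class variance falls below `floor_var` the frame is
#' declared depot-free and an empty mask is returned, preventing pure noise
#' from being thresholded into foreground.
#'
#' @param image Numeric matrix (typically background-subtracted and
#'   despeckled).
#' @param cone Logical cone mask.
#' @param floor_var Between-class variance floor, normalized intensity
#'   squared (default 1e-4).
#' @param n_bins Histogram bins (default 256).
#' @return Logical mask (`TRUE` above the threshold, inside the cone), with
#'   the threshold attached as attribute `"threshold"`.
#' @export
threshold_clusters <- function(image, cone, floor_var = 1e-4, n_bins = 256L) {
  if (!any(cone)) abort("Cone mask is empty.")
  v <- image[cone]
  lo <- min(v)
  hi <- max(v)
  empty <- matrix(FALSE, nrow(image), ncol(image))
  if (hi <= lo) {
    attr(empty, "threshold") <- NA_real_
    return(empty)
  }
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- tabulate(
    pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), n_bins),
    nbins = n_bins
  )
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu_cum <- cumsum(p * mids)
  mu_tot <- mu_cum[n_bins]
  # between-class variance for a cut after bin k
  with_mass <- omega > 0 & omega < 1
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[with_mass] <- (mu_tot * omega[with_mass] - mu_cum[with_mass])^2 /
    (omega[with_mass] * (1 - omega[with_mass]))
  k <- which.max(sigma_b)
  if (!is.finite(sigma_b[k]) || sigma_b[k] < floor_var) {
    attr(empty, "threshold") <- NA_real_
    return(empty)
  }
  thr <- edges[k + 1L]
  out <- image > thr & cone
  attr(out, "threshold") <- thr
  out
}

#' Morphological refinement of a depot mask
#'
#' Closes the mask with a disk structuring element of radius
#' `round(radius_cm * px_per_cm)` pixels to bridge nearby segmented areas,
#' then flood-fills interior holes. The result is a superset of the input;
#' the outer boundary is unchanged except where gaps narrower than twice
#' the radius are bridged.
#'
#' @param mask Logical matrix.
#' @param radius_cm Closing radius in cm (default 0.05, about one speckle
#'   cell).
#' @param px_per_cm Pixel calibration.
#' @return Refined logical mask.
#' @export
morph_refine <- function(mask, radius_cm = 0.05, px_per_cm) {
  if (radius_cm < 0) abort("`radius_cm` must be >= 0.")
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  r_px <- as.integer(round(radius_cm * px_per_cm))
  if (r_px >= 1L && any(m > 0)) {
    brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
    m <- EBImage::closing(m, brush)
  }
  if (any(m > 0)) m <- EBImage::fillHull(m)
  out <- m > 0
  out | (mask > 0)
}

#' Depot mask series
#'
#' @param masks Logical array `rows x cols x n` of post-onset masks.
#' @param times Seconds (aligned with the source frames, original clock).
#' @param params List of the segmentation settings used.
#' @return An object of class `depot_mask_series`.
#' @export
depot_mask_series <- function(masks, times, params = list()) {
  stopifnot(length(dim(masks)) == 3L, dim(masks)[3] == length(times))
  structure(list(masks = masks, times = times, params = params),
            class = "depot_mask_series")
}

#' @export
print.depot_mask_series <- function(x, ...) {
  areas <- apply(x$masks, 3, sum)
  cat(sprintf(
    "<depot_mask_series> %d masks over %.2f-%.2f s, area %d-%d px\n",
    length(x$times), min(x$times), max(x$times), min(areas), max(areas)
  ))
  invisible(x)
}

#' Segment the drug depot in every post-onset frame
#'
#' Per frame: subtract the pre-injection background (clamping negative
#' values to zero, since the depot is hyperechoic), despeckle by
#' anisotropic diffusion, threshold by the two-cluster (Otsu) rule over the
#' cone, refine morphologically, and keep only connected components that
#' intersect the 1 cm x 1 cm needle-tip window (distant bright artifacts
#' are discarded). All settings are recorded in `params`.
#'
#' @param video An [ebus_video()].
#' @param background A `background_model` (or matrix).
#' @param annotation An [injection_annotation()]; supplies `t0`, the needle
#'   tip and the calibration.
#' @param iterations,conductance,lambda Passed to [despeckle()].
#' @param floor_var Passed to [threshold_clusters()].
#' @param closing_radius_cm Passed to [morph_refine()].
#' @param roi_side_cm Needle-tip window used for component selection.
#' @param frame_stride Segment every `frame_stride`-th post-onset frame
#'   (default 1 = all).
#' @return A [depot_mask_series()].
#' @export
segment_depot <- function(video, background, annotation,
                          iterations = 10, conductance = NULL, lambda = 0.25,
                          floor_var = 1e-4, closing_radius_cm = 0.05,
                          roi_side_cm = 1, frame_stride = 1L) {
  stopifnot(inherits(video, "ebus_video"))
  bg <- if (inherits(background, "background_model")) background$image else background
  cone <- video$cone_mask
  times <- video_times(video)
  post <- which(times >= annotation$t0)
  if (length(post) == 0) abort("No frames at or after the injection onset.")
  post <- post[seq(1L, length(post), by = as.integer(frame_stride))]
  rb <- roi_bounds(annotation, dim(video$frames)[1:2], roi_side_cm)
  masks <- array(FALSE, dim = c(dim(video$frames)[1:2], length(post)))
  for (j in seq_along(post)) {
    sub <- pmax(video$frames[, , post[j]] - bg, 0)
    filt <- despeckle(sub, iterations = iterations,
                      conductance = conductance, lambda = lambda)
    m <- threshold_clusters(filt, cone, floor_var = floor_var)
    m <- morph_refine(m, closing_radius_cm, annotation$px_per_cm) & cone
    masks[, , j] <- select_components_near_tip(m, rb)
  }
  depot_mask_series(
    masks, times[post],
    params = list(
      iterations = iterations, conductance = conductance, lambda = lambda,
      floor_var = floor_var, closing_radius_cm = closing_radius_cm,
      roi_side_cm = roi_side_cm, frame_stride = frame_stride,
      t0 = annotation$t0
    )
  )
}

# keep connected components that touch the needle-tip window
select_components_near_tip <- function(mask, rb) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask)))
  window_labels <- unique(as.vector(lab[rb$row0:rb$row1, rb$col0:rb$col1]))
  window_labels <- window_labels[window_labels > 0]
  if (length(window_labels) == 0) {
    return(matrix(FALSE, nrow(mask), ncol(mask)))
  }
  matrix(lab %in% window_labels, nrow(mask))
}

#' Dice overlap between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; 1 when both masks are empty.
#'
#' @param a,b Logical matrices.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  a <- a > 0
  b <- b > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
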