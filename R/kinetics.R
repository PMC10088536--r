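#' Intensity trace constructor
#'
#' An intensity trace is a tibble with columns `time` (seconds, uniformly
#' spaced) and `value`, carrying the sampled region (`"roi"` or `"cone"`),
#' the frame rate and any smoothing window as attributes.
#'
#' @param time Seconds, strictly increasing, uniform spacing.
#' @param value Trace values (percent for the variation signal, normalized
#'   intensity for the background-subtracted cone mean).
#' @param region `"roi"` or `"cone"`.
#' @param frame_rate Frames per second.
#' @param smoothing_window Smoothing window in seconds, or `NULL` for a raw
#'   trace.
#' @return A tibble of class `intensity_trace`.
#' @export
new_intensity_trace <- function(time, value, region, frame_rate,
                                smoothing_window = NULL) {
  stopifnot(length(time) == length(value))
  out <- tibble::tibble(time = as.numeric(time), value = as.numeric(value))
  attr(out, "region") <- region
  attr(out, "frame_rate") <- frame_rate
  attr(out, "smoothing_window") <- smoothing_window
  class(out) <- c("intensity_trace", class(out))
  out
}

trace_frame_rate <- function(trace) {
  fr <- attr(trace, "frame_rate")
  if (is.null(fr)) fr <- 1 / stats::median(diff(trace$time))
  fr
}

#' Normalized percent intensity variation in the needle-tip ROI
#'
#' For every frame, the mean pixel intensity inside the square region of
#' interest centered on the needle tip is compared with the first frame:
#' `100 * (mean_t - mean_0) / mean_0`. The first value is 0 by construction,
#' and the signal is invariant to rescaling all frames by a positive
#' constant.
#'
#' @param video An [ebus_video()].
#' @param annotation An [injection_annotation()] (provides tip and
#'   calibration).
#' @param side_cm ROI side, cm (default 1).
#' @return An `intensity_trace` (percent units, region `"roi"`).
#' @export
intensity_variation <- function(video, annotation, side_cm = 1) {
  stopifnot(inherits(video, "ebus_video"))
  n <- length(video)
  if (n < 2) abort("Need at least 2 frames.")
  b <- roi_bounds(annotation, dim(video$frames)[1:2], side_cm)
  roi_means <- vapply(seq_len(n), function(i) {
    mean(video$frames[b$row0:b$row1, b$col0:b$col1, i])
  }, numeric(1))
  if (roi_means[1] == 0) {
    abort("Reference (first) frame has zero mean in the ROI; cannot normalize.")
  }
  vals <- 100 * (roi_means - roi_means[1]) / roi_means[1]
  new_intensity_trace(video_times(video), vals,
                      region = "roi", frame_rate = video$frame_rate)
}

#' Centered moving average of a trace
#'
#' Smooths with a centered moving mean over `round(window * frame_rate)`
#' samples; windows shrink near the edges so the output has the same length
#' and no padding bias. For even window lengths the extra sample is taken
#' from the later side.
#'
#' @param trace An `intensity_trace`.
#' @param window Window length in seconds (default 1, the heartbeat
#'   suppression window); must be at least one sample period.
#' @return The smoothed `intensity_trace` (`smoothing_window` recorded).
#' @export
moving_average <- function(trace, window = 1) {
  fr <- trace_frame_rate(trace)
  if (window < 1 / fr) {
    abort("`window` must be at least one sample period (1/frame_rate).")
  }
  k <- max(1L, as.integer(round(window * fr)))
  x <- trace$value
  n <- length(x)
  half_lo <- (k - 1L) %/% 2L
  half_hi <- k - 1L - half_lo
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  out <- new_intensity_trace(trace$time, sm,
                             region = attr(trace, "region"),
                             frame_rate = fr,
                             smoothing_window = window)
  out
}

#' Screening rule: does the smoothed variation signal rise above threshold?
#'
#' An injection video is retained for analysis only when the smoothed ROI
#' intensity-variation signal rises strictly above the threshold (default
#' 20 %), i.e. when the appearance of drug is clearly visible over the
#' speckle and heartbeat noise floor.
#'
#' @param trace A smoothed `intensity_trace` (percent units). Passing an
#'   unsmoothed trace logs a warning but the criterion is still applied.
#' @param threshold_pct Threshold, percent (default 20).
#' @return A list with `included` (logical) and `max_pct` (achieved
#'   maximum).
#' @export
passes_inclusion <- function(trace, threshold_pct = 20) {
  if (is.null(attr(trace, "smoothing_window"))) {
    warn("Trace is unsmoothed; applying the inclusion criterion anyway.")
  }
  mx <- max(trace$value)
  list(included = mx > threshold_pct, max_pct = mx)
}

#' Background-subtracted mean cone intensity after injection onset
#'
#' For each frame at `t >= t0`, the mean intensity over the cone mask minus
#' the mean of the background model over the same mask. Times are re-zeroed
#' so that the injection onset maps to `t = 0`, which is the time origin of
#' the uptake model.
#'
#' @param video An [ebus_video()].
#' @param background A `background_model` from [compute_background()] (or a
#'   plain matrix).
#' @param t0 Injection onset, seconds.
#' @return An `intensity_trace` (normalized intensity, region `"cone"`).
#' @export
mean_cone_trace <- function(video, background, t0) {
  stopifnot(inherits(video, "ebus_video"))
  if (inherits(background, "background_model")) background <- background$image
  cone <- video$cone_mask
  if (!any(cone)) abort("Cone mask is empty.")
  times <- video_times(video)
  keep <- which(times >= t0)
  if (length(keep) < 2) {
    abort("No post-onset samples: `t0` is at or beyond the last frame.")
  }
  bg_mean <- mean(background[cone])
  vals <- vapply(keep, function(i) {
    mean(video$frames[, , i][cone]) - bg_mean
  }, numeric(1))
  new_intensity_trace(times[keep] - times[keep[1]], vals,
                      region = "cone", frame_rate = video$frame_rate)
}

uptake_model <- function(t, a, b, c) c + a * (1 - exp(-b * t))

#' Fit the exponential-plateau uptake model to a trace
#'
#' Fits `value = c + a * (1 - exp(-b * time))` by constrained nonlinear
#' least squares (`a >= 0`, `b > 0`), starting from `c0` = first sample,
#' `a0` = last minus first and `b0 = ln(20) / (duration / 2)`, with a
#' multi-start over `b0 * {0.2, 1, 5}` if the first attempt fails. The
#' injection duration is derived as `delta_t = ln(20) / b`, the time at
#' which the background-subtracted trace reaches 95 % of its plateau
#' (`1 - exp(-b * delta_t) = 0.95`). `R^2` is computed on the raw
#' (unsmoothed) residuals.
#'
#' @param trace An `intensity_trace` starting at injection onset (`time`
#'   zeroed at onset), at least 5 samples.
#' @return An object of class `uptake_fit` with elements `a`, `b`, `c`,
#'   `r_squared`, `delta_t`, `residuals`, `data`, `boundary` (flag set when
#'   `b` stopped at its constraint).
#' @export
fit_uptake <- function(trace) {
  if (nrow(trace) < 5) abort("Need at least 5 samples to fit the uptake model.")
  tt <- trace$time
  y <- trace$value
  dur <- max(tt) - min(tt)
  c0 <- y[1]
  a0 <- max(y[length(y)] - y[1], 1e-6)
  b0 <- log(20) / (dur / 2)
  lower <- c(a = 0, b = 1e-8, c = -Inf)
  dat <- data.frame(t = tt, y = y)
  fit <- NULL
  tried <- character(0)
  for (mult in c(1, 0.2, 5)) {
    res <- try(
      minpack.lm::nlsLM(
        y ~ c + a * (1 - exp(-b * t)),
        data = dat,
        start = list(a = a0, b = b0 * mult, c = c0),
        lower = lower,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      silent = TRUE
    )
    if (!inherits(res, "try-error")) {
      fit <- res
      break
    }
    tried <- c(tried, attr(res, "condition")$message)
  }
  if (is.null(fit)) {
    abort(paste0(
      "Uptake fit did not converge after multi-start; messages: ",
      paste(unique(tried), collapse = " | ")
    ))
  }
  cf <- coef(fit)
  rsd <- y - uptake_model(tt, cf[["a"]], cf[["b"]], cf[["c"]])
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(rsd^2) / ss_tot else NA_real_
  boundary <- cf[["b"]] <= 2e-8
  if (boundary) {
    warn("Rate constant b stopped at its lower constraint; fit flagged.")
  }
  structure(
    list(
      a = unname(cf[["a"]]), b = unname(cf[["b"]]), c = unname(cf[["c"]]),
      r_squared = r2, delta_t = log(20) / cf[["b"]],
      residuals = rsd, data = tibble::tibble(time = tt, value = y),
      boundary = boundary
    ),
    class = "uptake_fit"
  )
}

#' @export
print.uptake_fit <- function(x, ...) {
  cat(sprintf(
    "<uptake_fit> mu(t) = %.4g + %.4g (1 - exp(-%.4g t));  R^2 = %.3f, delta_t = %.2f s%s\n",
    x$c, x$a, x$b, x$r_squared, x$delta_t,
    if (x$boundary) "  [b at constraint]" else ""
  ))
  invisible(x)
}

#' @rdname fit_uptake
#' @param x An `uptake_fit`.
#' @param ... Unused.
#' @export
tidy.uptake_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b", "c"),
    estimate = c(x$a, x$b, x$c),
    unit = c("intensity", "1/s", "intensity")
  )
}

#' @rdname fit_uptake
#' @export
glance.uptake_fit <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared,
    delta_t_s = x$delta_t,
    n = nrow(x$data),
    b_at_boundary = x$boundary
  )
}

#' Constant injection flow rate from the fitted duration
#'
#' Under the constant-rate assumption the flow is the total injected volume
#' divided by the injection duration `delta_t`.
#'
#' @param injected_volume mL.
#' @param fit An `uptake_fit`, or a number interpreted directly as
#'   `delta_t` in seconds.
#' @return A one-row tibble with `q_ml_per_s`, `injected_volume_ml`,
#'   `delta_t_s`.
#' @export
flow_rate <- function(injected_volume, fit) {
  if (injected_volume <= 0) abort("`injected_volume` must be > 0 mL.")
  delta_t <- if (inherits(fit, "uptake_fit")) fit$delta_t else as.numeric(fit)
  if (delta_t <= 0) abort("`delta_t` must be > 0 s.")
  tibble::tibble(
    q_ml_per_s = injected_volume / delta_t,
    injected_volume_ml = injected_volume,
    delta_t_s = delta_t
  )
}

#' Detect the injection onset from the smoothed variation signal
#'
#' When no annotated onset is available: the onset is the first time the
#' smoothed percent-variation signal exceeds 5 % and stays above it for a
#' full second, backtracked to the preceding local minimum.
#'
#' @param trace A smoothed `intensity_trace` in percent units.
#' @param rise_pct Sustained-rise threshold, percent (default 5).
#' @param hold_s Required hold time above threshold, seconds (default 1).
#' @return Onset time in seconds.
#' @export
detect_onset <- function(trace, rise_pct = 5, hold_s = 1) {
  fr <- trace_frame_rate(trace)
  hold_n <- max(1L, as.integer(round(hold_s * fr)))
  above <- trace$value > rise_pct
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values & runs$lengths >= hold_n)
  if (length(cand) == 0) {
    abort("No sustained rise found; cannot detect the injection onset.")
  }
  i0 <- starts[cand[1]]
  # backtrack to the preceding local minimum
  while (i0 > 1 && trace$value[i0 - 1] <= trace$value[i0]) i0 <- i0 - 1L
  trace$time[i0]
}

#' Plot an intensity trace
#'
#' @param object An `intensity_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.intensity_trace <- function(object, ...) {
  unit <- if (identical(attr(object, "region"), "roi")) {
    "intensity variation (%)"
  } else {
    "mean cone intensity above background"
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time (s)", y = unit) +
    ggplot2::theme_minimal()
}

#' Plot an uptake fit over its data
#'
#' @param object An `uptake_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.uptake_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- uptake_model(d$time, object$a, object$b, object$c)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$value), colour = "grey50") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(
      x = "time since onset (s)",
      y = "mean cone intensity above background",
      subtitle = sprintf("delta_t = %.2f s, R^2 = %.2f",
                         object$delta_t, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Export a trace as CSV
#'
#' Columns: `time_s`, `value`, `smoothed` (logical).
#'
#' @param trace An `intensity_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  smoothed <- !is.null(attr(trace, "smoothing_window"))
  utils::write.csv(
    data.frame(time_s = trace$time, value = trace$value, smoothed = smoothed),
    path, row.names = FALSE
  )
  invisible(path)
}
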