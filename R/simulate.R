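#' Configuration for the synthetic EBUS injection simulator
#'
#' Defines a phantom B-mode recording of an intratumoral injection: a
#' fan-shaped imaging cone with multiplicative speckle, a static bright
#' needle-line artifact, sinusoidal heartbeat intensity modulation, and a
#' hyperechoic depot that grows from the needle tip after injection onset so
#' that the noiseless mean cone intensity above background follows the
#' exponential-plateau law `a * (1 - exp(-b * (t - t0)))`.
#'
#' The depot is an ellipse anchored at the needle tip and elongating along
#' the needle axis (aspect ratio `depot_aspect` = lateral/axial semi-axis),
#' optionally deflected laterally by `depot_deflection_cm` to emulate
#' off-axis spreading. Its final size is chosen so that the solid of
#' revolution of the final mask about the needle axis equals
#' `true_retention * injected_volume` (within rasterization error, about
#' 5 % at the default calibration).
#'
#' @param frame_rate Frames per second (default 30, a typical clinical video
#'   rate).
#' @param duration Recording length in seconds.
#' @param image_size Integer `(rows, cols)` of each frame.
#' @param px_per_cm Pixel calibration.
#' @param cone_apex 0-based `(row, col)` of the fan apex (may be fractional).
#' @param cone_half_angle_deg Fan half-opening angle in degrees.
#' @param cone_radius_cm Fan depth in cm.
#' @param needle_angle Needle insertion direction, degrees from the image
#'   column axis toward increasing rows.
#' @param needle_depth_cm Distance from the apex to the needle tip along the
#'   needle axis; ignored when `needle_tip` is given.
#' @param needle_tip Optional explicit 0-based `(row, col)` tip position.
#' @param t0 Injection onset time, seconds.
#' @param a Plateau amplitude of the uptake law, normalized intensity units.
#' @param b Uptake rate constant, 1/s.
#' @param c Baseline cone intensity, normalized units.
#' @param speckle_scale Coefficient of variation of the multiplicative
#'   (unit-mean gamma) speckle; 0 disables speckle.
#' @param heartbeat_freq Heartbeat modulation frequency, Hz.
#' @param heartbeat_amp Fractional amplitude of the heartbeat modulation.
#' @param true_retention Fraction of the injected volume retained as depot.
#' @param injected_volume Injected volume, mL.
#' @param depot_aspect Lateral/axial semi-axis ratio of the depot ellipse.
#' @param depot_deflection_cm Lateral offset of the final depot center, cm
#'   (positive toward the needle-frame +y direction).
#' @param rng_seed Integer seed; identical configurations produce
#'   bit-identical videos.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(frame_rate = 30,
                              duration = 30,
                              image_size = c(200L, 200L),
                              px_per_cm = 40,
                              cone_apex = c(2, (image_size[2] - 1) / 2),
                              cone_half_angle_deg = 30,
                              cone_radius_cm = 4.5,
                              needle_angle = 75,
                              needle_depth_cm = 1.6,
                              needle_tip = NULL,
                              t0 = 5,
                              a = 0.05,
                              b = 0.15,
                              c = 0.25,
                              speckle_scale = 0.3,
                              heartbeat_freq = 1.2,
                              heartbeat_amp = 0.05,
                              true_retention = 0.15,
                              injected_volume = 8,
                              depot_aspect = 0.5,
                              depot_deflection_cm = 0,
                              rng_seed = 1L) {
  cfg <- list(
    frame_rate = frame_rate, duration = duration,
    image_size = as.integer(image_size), px_per_cm = px_per_cm,
    cone_apex = cone_apex, cone_half_angle_deg = cone_half_angle_deg,
    cone_radius_cm = cone_radius_cm,
    needle_angle = needle_angle, needle_depth_cm = needle_depth_cm,
    needle_tip = needle_tip,
    t0 = t0, a = a, b = b, c = c,
    speckle_scale = speckle_scale,
    heartbeat_freq = heartbeat_freq, heartbeat_amp = heartbeat_amp,
    true_retention = true_retention, injected_volume = injected_volume,
    depot_aspect = depot_aspect, depot_deflection_cm = depot_deflection_cm,
    rng_seed = as.integer(rng_seed)
  )
  if (frame_rate <= 0) abort("`frame_rate` must be > 0.")
  if (b <= 0) abort("`b` must be > 0 (1/s).")
  if (a < 0) abort("`a` must be >= 0.")
  if (true_retention < 0 || true_retention > 1) {
    abort("`true_retention` must lie in [0, 1].")
  }
  if (t0 >= duration) abort("`t0` must precede the end of the video.")
  if (px_per_cm <= 0) abort("`px_per_cm` must be > 0.")
  if (injected_volume <= 0) abort("`injected_volume` must be > 0 mL.")
  if (is.null(cfg$needle_tip)) {
    th <- needle_angle * pi / 180
    cfg$needle_tip <- c(
      cone_apex[1] + sin(th) * needle_depth_cm * px_per_cm,
      cone_apex[2] + cos(th) * needle_depth_cm * px_per_cm
    )
  }
  structure(cfg, class = "simulation_config")
}

# needle-frame unit vectors in (col, row) image coordinates;
# +y is 90 deg counterclockwise from the needle axis in the right-handed
# (col, row-down) frame
needle_axes <- function(angle_deg) {
  th <- angle_deg * pi / 180
  list(u = c(cos(th), sin(th)), v = c(-sin(th), cos(th)))
}

# fan mask: pixels within radius of the apex whose bearing deviates less
# than the half angle from straight down
make_cone_mask <- function(cfg) {
  nr <- cfg$image_size[1]
  nc <- cfg$image_size[2]
  r <- matrix(seq_len(nr) - 1, nr, nc)
  cc <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  dr <- r - cfg$cone_apex[1]
  dc <- cc - cfg$cone_apex[2]
  dist_px <- sqrt(dr^2 + dc^2)
  ang <- atan2(dc, dr) # 0 = straight down
  dist_px <= cfg$cone_radius_cm * cfg$px_per_cm &
    abs(ang) <= cfg$cone_half_angle_deg * pi / 180 &
    dr >= 0
}

# two-sided Pappus volume (mL) of the continuous depot ellipse with axial
# semi-axis A, lateral semi-axis B = aspect*A, lateral center offset d,
# rotated about the needle axis
ellipse_rotation_volume <- function(A, aspect, d, n = 2000L) {
  B <- aspect * A
  x <- seq(-A, A, length.out = n)
  beta <- B * sqrt(pmax(0, 1 - (x / A)^2))
  lo <- d - beta
  hi <- d + beta
  seg <- ifelse(lo >= 0, (hi^2 - lo^2) / 2,
                ifelse(hi <= 0, (lo^2 - hi^2) / 2, (hi^2 + lo^2) / 2))
  2 * pi * sum(seg) * (x[2] - x[1])
}

# rasterize the depot ellipse (cm geometry) onto the pixel grid
rasterize_depot <- function(cfg, axes, A_cm, B_cm, defl_cm) {
  if (A_cm <= 0 || B_cm <= 0) {
    return(matrix(FALSE, cfg$image_size[1], cfg$image_size[2]))
  }
  ppc <- cfg$px_per_cm
  tip <- cfg$needle_tip # (row, col)
  center_col <- tip[2] + (A_cm * axes$u[1] + defl_cm * axes$v[1]) * ppc
  center_row <- tip[1] + (A_cm * axes$u[2] + defl_cm * axes$v[2]) * ppc
  nr <- cfg$image_size[1]
  nc <- cfg$image_size[2]
  r <- matrix(seq_len(nr) - 1, nr, nc)
  cc <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  dx <- ((cc - center_col) * axes$u[1] + (r - center_row) * axes$u[2]) / ppc
  dy <- ((cc - center_col) * axes$v[1] + (r - center_row) * axes$v[2]) / ppc
  (dx / A_cm)^2 + (dy / B_cm)^2 <= 1
}

#' Simulate a synthetic EBUS injection video with known ground truth
#'
#' Produces a phantom grayscale video (see [simulation_config()]) plus the
#' ground truth needed to score every downstream stage: per-frame depot
#' masks, the noiseless mean-intensity trace, the true injection duration
#' `ln(20)/b`, and the true retention fraction.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `video` (an [ebus_video()]), `truth` (class
#'   `ebus_ground_truth`: `depot_masks`, `mu_true`, `area_px`,
#'   `delta_t_true`, `retention_true`, `config`) and `annotation` (an
#'   [injection_annotation()] matching the simulated needle).
#' @export
simulate_video <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  axes <- needle_axes(cfg$needle_angle)
  cone <- make_cone_mask(cfg)
  n_cone <- sum(cone)
  if (n_cone == 0) abort("Cone mask is empty; check cone parameters.")
  nframes <- as.integer(floor(cfg$duration * cfg$frame_rate))
  times <- (seq_len(nframes) - 1) / cfg$frame_rate

  tip_px <- round(cfg$needle_tip) + 1
  if (!cone[tip_px[1], tip_px[2]]) {
    abort("Needle tip lies outside the imaging cone.")
  }

  # final depot size from the retention target
  v_target <- cfg$true_retention * cfg$injected_volume
  depot_on <- cfg$a > 0 && v_target > 0
  A_final <- 0
  if (depot_on) {
    f <- function(A) {
      ellipse_rotation_volume(A, cfg$depot_aspect, cfg$depot_deflection_cm) -
        v_target
    }
    A_final <- uniroot(f, c(1e-4, 25), tol = 1e-10)$root
    final_mask <- rasterize_depot(cfg, axes, A_final,
                                  cfg$depot_aspect * A_final,
                                  cfg$depot_deflection_cm)
    if (any(final_mask & !cone)) {
      abort(sprintf(paste0(
        "Depot does not fit in the cone: true_retention = %.3g and ",
        "injected_volume = %.3g mL demand an ellipse of %.2f x %.2f cm, ",
        "exceeding the %.2f cm fan at the configured needle position."),
        cfg$true_retention, cfg$injected_volume,
        2 * A_final, 2 * cfg$depot_aspect * A_final, cfg$cone_radius_cm))
    }
  }

  # static scene: uniform tissue echo + bright needle line
  base <- matrix(0, cfg$image_size[1], cfg$image_size[2])
  base[cone] <- cfg$c
  needle <- needle_line_mask(cfg, axes) & cone
  base[needle] <- min(1, cfg$c + 0.45)

  growth_end <- 1 - exp(-cfg$b * (times[nframes] - cfg$t0))
  post <- times >= cfg$t0

  # preserve the caller's RNG state; the simulation is seeded by config
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(cfg$rng_seed)

  frames <- array(0, dim = c(cfg$image_size[1], cfg$image_size[2], nframes))
  masks <- array(FALSE, dim = dim(frames))
  mu_true <- rep(cfg$c, nframes)
  area_px <- numeric(nframes)
  shape_k <- if (cfg$speckle_scale > 0) 1 / cfg$speckle_scale^2 else Inf

  for (i in seq_len(nframes)) {
    img <- base
    if (depot_on && post[i]) {
      growth <- 1 - exp(-cfg$b * (times[i] - cfg$t0))
      s <- sqrt(growth / growth_end)
      m <- rasterize_depot(cfg, axes, A_final * s,
                           cfg$depot_aspect * A_final * s,
                           cfg$depot_deflection_cm * s)
      m <- m & cone
      if (!any(m)) m[tip_px[1], tip_px[2]] <- TRUE
      # uniform depot contrast chosen so the cone-mean increase is exactly
      # a * (1 - exp(-b (t - t0))) despite rasterization; pixels on the
      # needle artifact saturate at 1, so the contrast is solved over the
      # two base-intensity classes
      target <- cfg$a * growth * n_cone
      n_hi <- sum(m & needle)
      n_lo <- sum(m) - n_hi
      headroom_hi <- 1 - min(1, cfg$c + 0.45)
      kappa <- target / sum(m)
      if (kappa > headroom_hi && n_lo > 0) {
        kappa <- (target - n_hi * headroom_hi) / n_lo
      }
      if (kappa + cfg$c > 1 + 1e-9) {
        abort(sprintf(paste0(
          "Depot contrast %.3f + baseline %.3f exceeds the intensity range; ",
          "reduce `a` (%.3g) or increase the depot size ",
          "(true_retention %.3g, injected_volume %.3g mL)."),
          kappa, cfg$c, cfg$a, cfg$true_retention, cfg$injected_volume))
      }
      img[m] <- pmin(img[m] + kappa, 1)
      masks[, , i] <- m
      area_px[i] <- sum(m)
      mu_true[i] <- cfg$c + cfg$a * growth
    }
    if (cfg$speckle_scale > 0) {
      noise <- rgamma(n_cone, shape = shape_k, rate = shape_k)
      img[cone] <- img[cone] * noise
    }
    if (cfg$heartbeat_amp > 0) {
      hb <- 1 + cfg$heartbeat_amp * sin(2 * pi * cfg$heartbeat_freq * times[i])
      img[cone] <- img[cone] * hb
    }
    frames[, , i] <- pmin(pmax(img, 0), 1)
  }

  video <- ebus_video(frames, cfg$frame_rate, cone)
  truth <- structure(
    list(
      depot_masks = masks, mu_true = mu_true, area_px = area_px,
      times = times, delta_t_true = log(20) / cfg$b,
      retention_true = cfg$true_retention, config = cfg
    ),
    class = "ebus_ground_truth"
  )
  annotation <- injection_annotation(
    needle_tip = cfg$needle_tip, needle_angle = cfg$needle_angle,
    t0 = cfg$t0, injected_volume = cfg$injected_volume,
    px_per_cm = cfg$px_per_cm, injection_id = "synthetic"
  )
  list(video = video, truth = truth, annotation = annotation)
}

# pixels within ~0.75 px of the apex-to-tip segment
needle_line_mask <- function(cfg, axes) {
  nr <- cfg$image_size[1]
  nc <- cfg$image_size[2]
  a0 <- c(cfg$cone_apex[2], cfg$cone_apex[1]) # (col, row)
  a1 <- c(cfg$needle_tip[2], cfg$needle_tip[1])
  r <- matrix(seq_len(nr) - 1, nr, nc)
  cc <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  dx <- a1[1] - a0[1]
  dy <- a1[2] - a0[2]
  len2 <- dx^2 + dy^2
  t_par <- ((cc - a0[1]) * dx + (r - a0[2]) * dy) / len2
  t_par <- pmin(pmax(t_par, 0), 1)
  px <- a0[1] + t_par * dx
  py <- a0[2] + t_par * dy
  sqrt((cc - px)^2 + (r - py)^2) <= 0.75
}

#' Extract a ground-truth trace from a simulation
#'
#' @param truth An `ebus_ground_truth` from [simulate_video()].
#' @param stat `"mu"` for the noiseless mean-cone-intensity trace or
#'   `"area"` for the per-frame depot mask area (pixels).
#' @return An intensity-trace tibble (`time`, `value`) as produced by the
#'   kinetics functions.
#' @export
ground_truth_trace <- function(truth, stat = c("mu", "area")) {
  stopifnot(inherits(truth, "ebus_ground_truth"))
  stat <- match.arg(stat)
  vals <- switch(stat, mu = truth$mu_true, area = truth$area_px)
  new_intensity_trace(truth$times, vals,
                      region = "cone",
                      frame_rate = truth$config$frame_rate)
}

#' Write a simulated recording to disk
#'
#' Writes the video and ground-truth masks as multi-page TIFF, and the
#' annotation plus ground-truth scalars as JSON sidecars.
#'
#' @param sim Result of [simulate_video()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_video(sim$video, file.path(dir, "video.tif"))
  write_masks(sim$truth$depot_masks, file.path(dir, "truth_masks.tif"))
  write_annotation(sim$annotation, file.path(dir, "annotation.json"))
  cfg <- sim$truth$config
  jsonlite::write_json(
    list(
      delta_t_true_s = sim$truth$delta_t_true,
      retention_true = sim$truth$retention_true,
      mu_true = sim$truth$mu_true,
      config = unclass(cfg)
    ),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(dir)
}
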