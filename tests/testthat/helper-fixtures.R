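# Small, fast simulator configurations shared across tests.

small_config <- function(...) {
  defaults <- list(
    duration = 12, t0 = 2, frame_rate = 10,
    image_size = c(160L, 160L), px_per_cm = 32,
    b = 0.3, rng_seed = 42L
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

noiseless_config <- function(...) {
  small_config(speckle_scale = 0, heartbeat_amp = 0, ...)
}

# disk mask helper: center (row, col) 0-based, radius in px
disk_mask <- function(nr, nc, center, radius) {
  r <- matrix(seq_len(nr) - 1, nr, nc)
  cc <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  (r - center[1])^2 + (cc - center[2])^2 <= radius^2
}

# analytic uptake trace with optional gaussian noise
make_uptake_trace <- function(a, b, c = 0, duration = 60, frame_rate = 30,
                              noise_sd = 0) {
  t <- seq(0, duration - 1 / frame_rate, by = 1 / frame_rate)
  y <- c + a * (1 - exp(-b * t))
  if (noise_sd > 0) y <- y + rnorm(length(y), sd = noise_sd)
  new_intensity_trace(t, y, region = "cone", frame_rate = frame_rate)
}

# brute-force Feret oracle: caliper widths over n directions from the
# projections of all mask points
feret_bruteforce <- function(mask, frame, n_dir = 720L) {
  pts <- to_needle_frame(mask, frame)
  phis <- seq(0, pi, length.out = n_dir + 1L)[-(n_dir + 1L)]
  widths <- vapply(phis, function(phi) {
    proj <- pts$x * cos(phi) + pts$y * sin(phi)
    max(proj) - min(proj)
  }, numeric(1))
  c(feret_min = min(widths), feret_max = max(widths))
}
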