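test_that("background model averages exactly the pre-onset window", {
  const <- ebus_video(array(0.4, dim = c(20, 20, 30)), frame_rate = 10)
  bg <- compute_background(const, t0 = 2)
  expect_equal(bg$image, matrix(0.4, 20, 20))
  expect_equal(bg$n_frames, 10) # 1 s at 10 fps
  expect_error(compute_background(const, t0 = 0.5), "short")
})

test_that("background converges to the noiseless base at the speckle rate", {
  cfg <- small_config(a = 0, true_retention = 0, heartbeat_amp = 0,
                      duration = 3, t0 = 3 - 1e-9)
  sim <- simulate_video(cfg)
  bg <- compute_background(sim$video, t0 = 2.9, window = 2.9)
  cone <- sim$video$cone_mask
  base <- cfg$c
  n <- bg$n_frames
  sigma <- cfg$speckle_scale * base
  dev <- abs(bg$image[cone] - base)
  expect_lt(mean(dev > 3 * sigma / sqrt(n)), 0.01)
})

test_that("anisotropic diffusion smooths speckle but preserves edges", {
  expect_equal(despeckle(matrix(2, 10, 10)), matrix(2, 10, 10))
  img <- matrix(runif(100), 10, 10)
  expect_identical(despeckle(img, iterations = 0), img)

  set.seed(3)
  step <- matrix(0.2, 60, 120)
  step[, 61:120] <- 0.8
  noisy <- step * rgamma(60 * 120, shape = 25, rate = 25)
  out <- despeckle(noisy, iterations = 10)
  flat_before <- stats::var(as.numeric(noisy[, 1:50]))
  flat_after <- stats::var(as.numeric(out[, 1:50]))
  expect_lt(flat_after, 0.25 * flat_before)
  height_before <- mean(step[, 71:110]) - mean(step[, 11:50])
  height_after <- mean(out[, 71:110]) - mean(out[, 11:50])
  expect_gt(height_after, 0.8 * height_before)
})

test_that("cluster thresholding splits separable modes and rejects flat frames", {
  cone <- matrix(TRUE, 30, 30)
  img <- matrix(0.1, 30, 30)
  img[10:20, 10:20] <- 0.9
  m <- threshold_clusters(img, cone)
  thr <- attr(m, "threshold")
  expect_gt(thr, 0.1)
  expect_lt(thr, 0.9)
  expect_equal(as.vector(m), as.vector(img > 0.5))

  flat <- matrix(0.3, 30, 30)
  expect_equal(sum(threshold_clusters(flat, cone)), 0)
})

test_that("the threshold maximizes between-class variance (brute-force oracle)", {
  set.seed(5)
  cone <- matrix(TRUE, 40, 40)
  for (rep in 1:5) {
    img <- matrix(sample(0:255, 1600, replace = TRUE,
                         prob = c(stats::dnorm(0:120, 60, 25),
                                  stats::dnorm(121:255, 190, 20))) / 255,
                  40, 40)
    m <- threshold_clusters(img, cone, floor_var = 0)
    thr <- attr(m, "threshold")
    # exhaustive oracle over all candidate cuts of the same histogram
    v <- img[cone]
    edges <- seq(min(v), max(v), length.out = 257)
    mids <- (edges[-1] + edges[-257]) / 2
    counts <- tabulate(pmin(pmax(findInterval(v, edges,
                                              rightmost.closed = TRUE),
                                 1L), 256L), nbins = 256)
    best <- -Inf
    best_k <- NA
    for (k in 1:255) {
      w0 <- sum(counts[1:k])
      w1 <- sum(counts) - w0
      if (w0 == 0 || w1 == 0) next
      m0 <- sum(counts[1:k] * mids[1:k]) / w0
      m1 <- sum(counts[(k + 1):256] * mids[(k + 1):256]) / w1
      sb <- (w0 / sum(counts)) * (w1 / sum(counts)) * (m0 - m1)^2
      if (sb > best) {
        best <- sb
        best_k <- k
      }
    }
    expect_equal(thr, edges[best_k + 1], tolerance = 1e-12)
  }
})

test_that("morphological refinement closes gaps and fills holes, never shrinking", {
  solid <- disk_mask(60, 60, c(30, 30), 12)
  out <- morph_refine(solid, radius_cm = 0.05, px_per_cm = 40)
  expect_equal(unname(out), unname(solid))

  holey <- solid & !disk_mask(60, 60, c(30, 30), 4)
  filled <- morph_refine(holey, radius_cm = 0.05, px_per_cm = 40)
  expect_true(all(filled[solid]))

  two <- disk_mask(60, 60, c(30, 20), 6) | disk_mask(60, 60, c(30, 37), 6)
  # gap of ~5 px, radius 3 px -> bridged
  joined <- morph_refine(two, radius_cm = 0.075, px_per_cm = 40)
  lab <- EBImage::bwlabel(matrix(as.numeric(joined), 60))
  expect_equal(max(lab), 1)
  expect_true(all(joined[two])) # superset of the input
})

test_that("noiseless depots are segmented nearly perfectly", {
  cfg <- noiseless_config(duration = 8)
  sim <- simulate_video(cfg)
  bg <- compute_background(sim$video, cfg$t0)
  seg <- segment_depot(sim$video, bg, sim$annotation, frame_stride = 10L)
  times <- video_times(sim$video)
  post <- which(times >= cfg$t0)
  post <- post[seq(1, length(post), by = 10)]
  dices <- vapply(seq_along(post), function(j) {
    dice(seg$masks[, , j], sim$truth$depot_masks[, , post[j]])
  }, numeric(1))
  areas <- sim$truth$area_px[post] / cfg$px_per_cm^2
  expect_gte(min(dices[areas >= 0.05]), 0.95)
})

test_that("segmentation at default noise overlaps truth and is reproducible", {
  cfg <- small_config(duration = 8)
  sim <- simulate_video(cfg)
  bg <- compute_background(sim$video, cfg$t0)
  seg1 <- segment_depot(sim$video, bg, sim$annotation, frame_stride = 6L)
  seg2 <- segment_depot(sim$video, bg, sim$annotation, frame_stride = 6L)
  expect_identical(seg1$masks, seg2$masks)
  times <- video_times(sim$video)
  post <- which(times >= cfg$t0)
  post <- post[seq(1, length(post), by = 6)]
  dices <- vapply(seq_along(post), function(j) {
    dice(seg1$masks[, , j], sim$truth$depot_masks[, , post[j]])
  }, numeric(1))
  areas <- sim$truth$area_px[post] / cfg$px_per_cm^2
  expect_gte(median(dices[areas >= 0.05]), 0.8)
  outside <- apply(seg1$masks, 3, function(m) any(m & !sim$video$cone_mask))
  expect_false(any(outside))
})

test_that("depot-free videos yield essentially empty masks", {
  cfg <- small_config(a = 0, true_retention = 0, duration = 8)
  sim <- simulate_video(cfg)
  bg <- compute_background(sim$video, cfg$t0)
  seg <- segment_depot(sim$video, bg, sim$annotation, frame_stride = 6L)
  mean_frac <- mean(apply(seg$masks, 3, sum)) / sum(sim$video$cone_mask)
  expect_lt(mean_frac, 0.01)
})

test_that("higher depot contrast never hurts segmentation overlap", {
  meds <- vapply(c(0.03, 0.05), function(a) {
    cfg <- small_config(a = a, duration = 8)
    sim <- simulate_video(cfg)
    bg <- compute_background(sim$video, cfg$t0)
    seg <- segment_depot(sim$video, bg, sim$annotation, frame_stride = 10L)
    times <- video_times(sim$video)
    post <- which(times >= cfg$t0)
    post <- post[seq(1, length(post), by = 10)]
    median(vapply(seq_along(post), function(j) {
      dice(seg$masks[, , j], sim$truth$depot_masks[, , post[j]])
    }, numeric(1)))
  }, numeric(1))
  expect_gte(meds[2], meds[1] - 0.02)
})
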