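frame_for <- function(tip = c(60, 60), angle = 90, ppc = 40) {
  needle_frame(tip = tip, angle = angle, px_per_cm = ppc)
}

test_that("needle-frame mapping sends the tip to the origin and scales to cm", {
  nf <- frame_for(angle = 90, ppc = 100)
  m <- matrix(FALSE, 200, 200)
  m[61, 61] <- TRUE # the tip pixel itself
  expect_equal(unlist(to_needle_frame(m, nf)), c(x = 0, y = 0))

  m2 <- matrix(FALSE, 200, 200)
  m2[161, 61] <- TRUE # 100 px along the (downward) needle axis
  pt <- to_needle_frame(m2, nf)
  expect_equal(pt$x, 1)
  expect_equal(pt$y, 0, tolerance = 1e-12)
})

test_that("needle-frame coordinates are equivariant under 90-degree rotation", {
  set.seed(21)
  m <- disk_mask(80, 80, c(50, 44), 7) | disk_mask(80, 80, c(40, 52), 5)
  nf <- frame_for(tip = c(30, 36), angle = 60, ppc = 40)
  pts <- to_needle_frame(m, nf)
  # rotate the image 90 degrees clockwise: (r, c) -> (c, N-1-r)
  n <- 80
  m_rot <- t(m)[, n:1]
  tip_rot <- c(36, n - 1 - 30)
  nf_rot <- frame_for(tip = tip_rot, angle = 60 + 90, ppc = 40)
  pts_rot <- to_needle_frame(m_rot, nf_rot)
  o <- order(pts$x, pts$y)
  o2 <- order(pts_rot$x, pts_rot$y)
  expect_equal(pts$x[o], pts_rot$x[o2], tolerance = 1e-9)
  expect_equal(pts$y[o], pts_rot$y[o2], tolerance = 1e-9)
})

test_that("Feret diameters match closed forms for squares and disks", {
  nf <- frame_for(ppc = 40)
  sq <- matrix(FALSE, 120, 120)
  sq[41:80, 41:80] <- TRUE # 40 px = 1 cm side
  fer <- feret_diameters(sq, nf)
  expect_equal(unname(fer["feret_min"]), 1, tolerance = 2 / 40)
  expect_equal(unname(fer["feret_max"]), sqrt(2), tolerance = 2 * sqrt(2) / 40)

  dk <- disk_mask(120, 120, c(60, 60), 20) # diameter 40 px = 1 cm
  fer_d <- feret_diameters(dk, nf)
  expect_equal(unname(fer_d["feret_min"]), 1, tolerance = 2 / 40)
  expect_equal(unname(fer_d["feret_max"]), 1, tolerance = 2 / 40)
  expect_lte(fer_d["feret_min"], fer_d["feret_max"])

  empty <- matrix(FALSE, 10, 10)
  expect_true(all(is.na(feret_diameters(empty, nf))))
})

test_that("Feret diameters agree with a 720-direction brute-force sweep", {
  set.seed(31)
  nf <- frame_for(ppc = 40)
  for (i in 1:25) {
    m <- matrix(FALSE, 90, 90)
    nblob <- sample(1:3, 1)
    for (b in seq_len(nblob)) {
      m <- m | disk_mask(90, 90, c(sample(20:70, 1), sample(20:70, 1)),
                         sample(4:14, 1))
    }
    fer <- feret_diameters(m, nf)
    ref <- feret_bruteforce(m, nf)
    expect_equal(unname(fer["feret_max"]), unname(ref["feret_max"]),
                 tolerance = 0.01)
    expect_equal(unname(fer["feret_min"]), unname(ref["feret_min"]),
                 tolerance = 0.01)
  }
})

test_that("rotation volume reproduces Pappus closed forms", {
  # half-disk with its flat edge on the axis sweeps a full sphere
  ppc <- 100
  nf <- frame_for(tip = c(200, 200), angle = 0, ppc = ppc)
  r_px <- 50 # 0.5 cm
  m <- disk_mask(400, 400, c(200, 200), r_px)
  pts <- to_needle_frame(m, nf)
  half <- m
  half[which(m)[pts$y <= 0]] <- FALSE
  v <- rotation_volume(half, nf)
  expect_equal(v, 4 / 3 * pi * 0.5^3, tolerance = 0.02)

  # 1 cm x 0.2 cm rectangle, long edge on the axis, fully on one side;
  # tip row at 200.5 so pixel centers sample |y| = 0.005 .. 0.195 cm
  nf_half <- frame_for(tip = c(200.5, 200), angle = 0, ppc = ppc)
  rect <- matrix(FALSE, 400, 400)
  rect[202:221, 201:300] <- TRUE
  v_rect <- rotation_volume(rect, nf_half)
  expect_equal(v_rect, 2 * pi * 0.1 * 0.2, tolerance = 0.02)
})

test_that("rotation volume matches a continuous washer oracle on ellipses", {
  # oracle: continuous two-sided washer integration of the same ellipse
  washer <- function(A, B, d, n = 4000L) {
    x <- seq(-A, A, length.out = n)
    beta <- B * sqrt(pmax(0, 1 - (x / A)^2))
    lo <- d - beta
    hi <- d + beta
    seg <- ifelse(lo >= 0, hi^2 - lo^2,
                  ifelse(hi <= 0, lo^2 - hi^2, hi^2 + lo^2))
    pi * sum(seg) * (x[2] - x[1])
  }
  set.seed(41)
  ppc <- 100
  nr <- 360
  for (i in 1:6) {
    A <- runif(1, 0.4, 0.9)
    B <- runif(1, 0.2, 0.5)
    d <- runif(1, -0.3, 0.4)
    nf <- frame_for(tip = c(180, 30), angle = 0, ppc = ppc)
    r <- matrix(seq_len(nr) - 1, nr, nr)
    cc <- matrix(seq_len(nr) - 1, nr, nr, byrow = TRUE)
    x <- (cc - 30) / ppc - (A + 0.2)
    y <- -(r - 180) / ppc - d # +y is up for angle 0
    m <- (x / A)^2 + (y / B)^2 <= 1
    v <- rotation_volume(m, nf)
    expect_equal(v, washer(A, B, d), tolerance = 0.02)
  }
})

test_that("rotation volume is reflection-invariant and scales cubically", {
  ppc <- 100
  nf <- frame_for(tip = c(150, 150), angle = 0, ppc = ppc)
  m <- matrix(FALSE, 300, 300)
  m[100:130, 160:240] <- TRUE # blob in y > 0
  m_ref <- matrix(FALSE, 300, 300)
  m_ref[300 - (100:130) + 2, 160:240] <- TRUE # mirrored about the tip row
  expect_equal(rotation_volume(m, nf), rotation_volume(m_ref, nf),
               tolerance = 1e-9)

  # isotropic scaling by 2 about the tip scales volume by 8
  m_small <- matrix(FALSE, 300, 300)
  m_small[135:142, 160:200] <- TRUE
  m_big <- matrix(FALSE, 300, 300)
  idx <- which(m_small, arr.ind = TRUE)
  big_idx <- cbind(round((idx[, 1] - 151) * 2 + 151),
                   round((idx[, 2] - 151) * 2 + 151))
  # rasterize the scaled region densely instead of mapping sparse pixels
  rr <- range(big_idx[, 1])
  cr <- range(big_idx[, 2])
  m_big[rr[1]:rr[2], cr[1]:cr[2]] <- TRUE
  expect_equal(rotation_volume(m_big, nf) / rotation_volume(m_small, nf), 8,
               tolerance = 0.1)

  # nested one-sided masks have monotone volume
  inner <- matrix(FALSE, 300, 300)
  inner[110:125, 170:230] <- TRUE
  outer <- inner
  outer[100:130, 160:240] <- TRUE
  expect_lte(rotation_volume(inner, nf), rotation_volume(outer, nf))
})

test_that("centroid paths sit where the depot is", {
  nf <- frame_for(tip = c(60, 60), angle = 90, ppc = 40)
  at_tip <- disk_mask(120, 120, c(60, 60), 10)
  series <- depot_mask_series(array(at_tip, dim = c(120, 120, 1)), times = 0)
  st <- shape_trace(series, nf)
  expect_equal(st$centroid_x, 0, tolerance = 0.02)
  expect_equal(st$centroid_y, 0, tolerance = 0.02)

  ahead <- disk_mask(120, 120, c(80, 60), 10) # 20 px = 0.5 cm down the axis
  series2 <- depot_mask_series(array(ahead, dim = c(120, 120, 1)), times = 0)
  st2 <- shape_trace(series2, nf)
  expect_equal(st2$centroid_x, 0.5, tolerance = 0.02)
  expect_equal(st2$centroid_y, 0, tolerance = 0.02)

  empty <- depot_mask_series(array(FALSE, dim = c(120, 120, 1)), times = 0)
  expect_true(all(is.na(shape_trace(empty, nf)[, -1])))
})

test_that("axis-symmetric simulated growth keeps the centroid on the axis", {
  sim <- simulate_video(noiseless_config(duration = 8))
  nf <- needle_frame(sim$annotation)
  times <- video_times(sim$video)
  keep <- which(times >= 2.5)
  keep <- keep[seq(1, length(keep), by = 10)]
  series <- depot_mask_series(sim$truth$depot_masks[, , keep],
                              times = times[keep])
  st <- shape_trace(series, nf)
  expect_true(all(abs(st$centroid_y) <= 0.05))
})

test_that("retention arithmetic and failure modes are as defined", {
  ppc <- 40
  nf <- frame_for(tip = c(60, 60), angle = 0, ppc = ppc)
  # construct a mask whose rotation volume is known, then check percentages
  m <- matrix(FALSE, 120, 120)
  m[30:50, 70:110] <- TRUE
  v <- rotation_volume(m, nf)
  series <- depot_mask_series(array(m, dim = c(120, 120, 1)), times = 10)
  ret <- retention(series, nf, injected_volume = v * 5)
  expect_equal(ret$retention_pct, 20, tolerance = 1e-9)
  expect_equal(ret$escaped_volume_ml, v * 4, tolerance = 1e-9)
  expect_equal(glance(ret)$rotation_volume_ml, v)

  empty <- depot_mask_series(array(FALSE, dim = c(120, 120, 1)), times = 0)
  expect_error(retention(empty, nf, 8), "empty")
})
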