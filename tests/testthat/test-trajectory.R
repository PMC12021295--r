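test_that("the 3-4-5 track yields unit distances and speeds", {
  tr <- new_track(1, 0:2, c(0, 3, 6), c(0, 4, 8))
  m <- track_measures(tr, frame_interval_s = 0.5, pixel_size_nm = 100)
  expect_equal(m$d_total_um, 1.0)
  expect_equal(m$d_net_um, 1.0)
  expect_equal(m$t_traj_s, 1.0)
  expect_equal(m$v_curvilinear_um_s, 1.0)
  expect_equal(m$v_line_um_s, 1.0)
})

test_that("an out-and-back track has zero net but full path distance", {
  tr <- new_track(1, 0:2, c(0, 3, 0), c(0, 4, 0))
  m <- track_measures(tr, frame_interval_s = 0.5, pixel_size_nm = 100)
  expect_equal(m$d_net_um, 0)
  expect_equal(m$v_line_um_s, 0)
  expect_equal(m$d_total_um, 1.0)
  expect_equal(m$d_max_um, 0.5)
})

test_that("net orientation equals the step heading of a straight track", {
  tr <- fx_line_track(5, dx = 1, dy = -1)       # up-right on screen
  m <- track_measures(tr, frame_interval_s = 0.25, pixel_size_nm = 100)
  expect_equal(m$theta_net_deg, 45)
  down <- fx_line_track(5, dx = 0, dy = 1)
  m2 <- track_measures(down, frame_interval_s = 0.25, pixel_size_nm = 100)
  expect_equal(m2$theta_net_deg, 270)
})

test_that("gap frames count toward trajectory time", {
  tr <- new_track(1, c(0, 1, 4), c(0, 1, 4), c(0, 0, 0))
  m <- track_measures(tr, frame_interval_s = 1, pixel_size_nm = 1000)
  expect_equal(m$t_traj_s, 4)
  expect_equal(m$v_curvilinear_um_s, 1)
})

test_that("missing metadata fails loudly", {
  tr <- fx_line_track(5)
  expect_error(track_measures(tr, NULL, 100), "require")
  expect_error(axis_displacement(tr, 90, NULL), "pixel_size_nm")
})

test_that("distance and speed orderings hold on random tracks", {
  set.seed(31)
  for (i in 1:1000) {
    tr <- fx_random_track(sample(3:12, 1))
    m <- track_measures(tr, frame_interval_s = 0.25, pixel_size_nm = 100)
    expect_lte(m$d_net_um, m$d_max_um + 1e-12)
    expect_lte(m$d_max_um, m$d_total_um + 1e-12)
    expect_lte(m$v_line_um_s, m$v_curvilinear_um_s + 1e-12)
  }
})

test_that("MSD segmentation separates ballistic, stationary and mixed tracks", {
  lin <- fx_line_track(20, dx = 2)
  s <- segment_motion(lin)
  expect_equal(s$k, 1)
  expect_equal(s$segments$start, 1)
  expect_equal(s$segments$end, 20)

  set.seed(7)
  jit <- new_track(1, 0:19, 50 + rnorm(20, 0, 0.1), 50 + rnorm(20, 0, 0.1))
  expect_equal(segment_motion(jit)$k, 0)

  # move - pause - move
  x <- c(seq(0, 22, by = 2), rep(22, 10), seq(24, 46, by = 2))
  tr <- new_track(1, seq_along(x) - 1, x, rep(0, length(x)))
  s3 <- segment_motion(tr)
  expect_equal(s3$k, 2)
  # t_avg equals the mean duration of the two segments derived from labels
  m <- track_measures(tr, frame_interval_s = 0.25, pixel_size_nm = 100)
  expect_equal(m$t_avg_s, mean(s3$segments$n_steps) * 0.25)

  short <- fx_line_track(4)
  ss <- segment_motion(short)
  expect_true(all(ss$labels == "unsegmentable"))
  expect_true(is.na(ss$k))
})

test_that("the sliding-window maximum speed finds the fastest stretch", {
  # constant speed: the windowed maximum is that speed
  tr <- fx_line_track(20, dx = 1)                  # 1 px / frame
  v <- max_segment_speed(tr, window_s = 1, frame_interval_s = 0.25,
                         pixel_size_nm = 100)
  expect_equal(v, 0.4)                             # 4 px/s * 0.1 um

  # 1 um/s for 10 frames then 2 um/s for 10 frames at 4 fps
  x1 <- seq(0, by = 2.5, length.out = 10)          # 2.5 px/frame = 1 um/s
  x2 <- seq(x1[10] + 5, by = 5, length.out = 10)   # 5 px/frame = 2 um/s
  tr2 <- new_track(1, 0:19, c(x1, x2), rep(0, 20))
  v2 <- max_segment_speed(tr2, window_s = 1, frame_interval_s = 0.25,
                          pixel_size_nm = 100)
  expect_equal(v2, 2)

  # window longer than any moving segment: undefined
  v3 <- max_segment_speed(fx_line_track(6), window_s = 10,
                          frame_interval_s = 0.25, pixel_size_nm = 100)
  expect_true(is.na(v3))
})

test_that("direction classes follow the 45-degree quadrant rule", {
  expect_equal(classify_direction(100, 90), "apical")
  expect_equal(classify_direction(140, 90), "lateral")
  expect_equal(classify_direction(270, 90), "basal")
  expect_equal(classify_direction(45, 90), "apical")    # tie goes axial
  expect_equal(classify_direction(0, 0, c("leading", "perpendicular",
                                          "trailing")), "leading")
})

test_that("isotropic headings split 25/50/25 across the quadrants", {
  set.seed(41)
  theta <- runif(10000, 0, 360)
  cls <- classify_direction(theta, 90)
  p <- table(cls) / 10000
  tol <- 4 * sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(p[["apical"]] - 0.25), tol)
  expect_lt(abs(p[["basal"]] - 0.25), tol)
  expect_lt(abs(p[["lateral"]] - 0.50), 4 * sqrt(0.5 * 0.5 / 10000))
})

test_that("polar histograms bin, normalize and filter by net distance", {
  mk <- function(theta, dnet) list(theta_net_deg = theta, d_net_um = dnet)
  ms <- list(mk(5, 2), mk(12, 1.5), mk(355, 1), mk(100, 0.8), mk(360, 1.2))
  h <- polar_histogram(ms, duration_min = 2)
  expect_equal(sum(h$count), 4)                 # the 0.8 um track is out
  expect_equal(h$count[h$bin_start == 0], 2)    # 5 deg and the wrapped 360
  expect_equal(h$count[h$bin_start == 10], 1)
  expect_equal(h$count[h$bin_start == 350], 1)
  expect_equal(h$count_per_min, h$count / 2)
  expect_equal(sum(h$net_distance_sum_um), 2 + 1.5 + 1 + 1.2)
})

test_that("axis displacement projects signed distances and is additive", {
  up3 <- new_track(1, 0:1, c(0, 0), c(0, -30))       # 3 um toward apical
  expect_equal(axis_displacement(up3, 90, 100), 3)
  down2 <- new_track(1, 0:1, c(0, 0), c(0, 20))
  expect_equal(axis_displacement(down2, 90, 100), -2)
  perp <- new_track(1, 0:1, c(0, 30), c(0, 0))
  expect_equal(axis_displacement(perp, 90, 100), 0)

  set.seed(13)
  a <- fx_random_track(6)
  bdet <- a$det[nrow(a$det), ]
  b <- new_track(2, 6:10, bdet$x + c(0, cumsum(rnorm(4))),
                 bdet$y + c(0, cumsum(rnorm(4))))
  whole <- new_track(3, 0:10, c(a$det$x, b$det$x), c(a$det$y, b$det$y))
  expect_equal(axis_displacement(whole, 37, 100),
               axis_displacement(a, 37, 100) + axis_displacement(b, 37, 100))
})

test_that("framewise correlation matches its analytic limits", {
  set.seed(51)
  frames <- array(runif(32 * 32 * 4, 10, 100), c(32, 32, 4))
  a <- image_sequence(frames)
  same <- framewise_pearson(a, a)
  expect_equal(same$r, rep(1, 4))

  neg <- image_sequence(array(apply(frames, 3, function(f)
    2 * mean(f) - f), c(32, 32, 4)))
  expect_equal(framewise_pearson(a, neg)$r, rep(-1, 4))

  # independent channels decorrelate
  b <- image_sequence(array(runif(64 * 64 * 40, 10, 100), c(64, 64, 40)))
  c2 <- image_sequence(array(runif(64 * 64 * 40, 10, 100), c(64, 64, 40)))
  r <- framewise_pearson(b, c2)$r
  expect_gte(mean(abs(r) < 0.1), 0.95)

  # constant frame is flagged undefined
  cf <- frames; cf[, , 2] <- 7
  fp <- framewise_pearson(image_sequence(cf), a)
  expect_true(fp$undefined[2])
  expect_true(is.na(fp$r[2]))

  # normalization anchors the reference at zero and peaks at one: build a
  # channel whose correlation with `a` rises over time
  sds <- c(40, 25, 10, 0)
  rising <- frames
  for (t in 1:4) rising[, , t] <- pmax(frames[, , t] +
    rnorm(32 * 32, 0, sds[t]), 0)
  fp2 <- framewise_pearson(a, image_sequence(rising))
  expect_equal(fp2$delta[1], 0)
  expect_equal(which.max(fp2$normalized), 4)
  expect_equal(max(fp2$normalized, na.rm = TRUE), 1, tolerance = 1e-12)
})
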