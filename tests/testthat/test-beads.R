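# Spot detection, track linking with the step gate, displacement filtering.

render_beads <- function(positions, nr, nc, pix, sigma_px = 2.12) {
  img <- matrix(0, nr, nc)
  for (b in seq_len(nrow(positions))) {
    cx <- positions[b, 1] / pix + 0.5
    cy <- positions[b, 2] / pix + 0.5
    ii <- max(1, floor(cx - 9)):min(nr, ceiling(cx + 9))
    jj <- max(1, floor(cy - 9)):min(nc, ceiling(cy + 9))
    img[ii, jj] <- img[ii, jj] +
      outer(exp(-(ii - cx)^2 / (2 * sigma_px^2)),
            exp(-(jj - cy)^2 / (2 * sigma_px^2)))
  }
  img
}

test_that("isolated beads are detected with sub-pixel centers", {
  pix <- 2
  for (x in c(30, 50, 70.3)) {
    fr <- render_beads(cbind(x, 50), 100, 50, pix)
    sp <- detect_spots(list(fr), pixel_size = pix, diameter = 10)
    d <- sp$spots[[1]]
    expect_equal(nrow(d), 1L)
    expect_lt(sqrt((d$x - x)^2 + (d$y - 50)^2), 0.4)   # < 0.2 voxel
  }
  # two beads three diameters apart stay separate
  fr2 <- render_beads(rbind(c(40, 30), c(40, 60)), 100, 50, pix)
  sp2 <- detect_spots(list(fr2), pixel_size = pix, diameter = 10)
  expect_equal(nrow(sp2$spots[[1]]), 2L)
  # empty frames yield an empty spot set
  sp0 <- detect_spots(list(matrix(0, 60, 60)), pixel_size = 2, diameter = 10)
  expect_equal(nrow(sp0$spots[[1]]), 0L)
  expect_error(detect_spots(list(matrix(0, 4, 4)), 2, diameter = 100),
               "larger")
})

test_that("constant-velocity beads link into full tracks with exact speeds", {
  pix <- 2
  y0 <- seq(15, 105, length.out = 6)
  frames <- lapply(1:30, function(f)
    render_beads(cbind(20 + 5 * (f - 1), y0), 150, 60, pix))
  sp <- detect_spots(frames, pixel_size = pix, diameter = 10)
  tr <- link_tracks(sp, frame_interval = 0.05, max_step = 15, min_frames = 3)
  res <- filter_and_summarize(tr, min_displacement = 125)
  expect_equal(nrow(res$summary), 6L)
  expect_equal(res$summary$n_frames, rep(30L, 6))
  # 5 um / 0.05 s = 100 um/s exactly (up to detection noise)
  expect_true(all(abs(res$summary$mean_speed - 100) < 1))
  # frame-interval invariance: halving dt with identical physical motion
  res2 <- filter_and_summarize(link_tracks(sp, 0.025, 15, 3), 125)
  expect_equal(res2$summary$mean_speed, 2 * res$summary$mean_speed,
               tolerance = 1e-9)
})

test_that("the step gate breaks tracks and short fragments are dropped", {
  # a 200-um jump between frames must not link under the 150-um gate
  sp <- list(data.frame(x = 10, y = 50, intensity = 1, quality = 9),
             data.frame(x = 210, y = 50, intensity = 1, quality = 9),
             data.frame(x = 260, y = 50, intensity = 1, quality = 9),
             data.frame(x = 310, y = 50, intensity = 1, quality = 9))
  tr <- link_tracks(sp, frame_interval = 1, max_step = 150, min_frames = 3)
  # the fragment after the jump spans 3 frames and survives; the 1-frame
  # fragment before it is dropped
  expect_equal(length(tr$tracks), 1L)
  expect_equal(tr$tracks[[1]]$frame, 2:4)
  # a 140-um step does link
  sp2 <- list(data.frame(x = 10, y = 50, intensity = 1, quality = 9),
              data.frame(x = 150, y = 50, intensity = 1, quality = 9),
              data.frame(x = 290, y = 50, intensity = 1, quality = 9))
  tr2 <- link_tracks(sp2, 1, max_step = 150, min_frames = 3)
  expect_equal(length(tr2$tracks), 1L)
  expect_equal(nrow(tr2$tracks[[1]]), 3L)
})

test_that("the displacement filter keeps 125 um and drops 120 um", {
  mk_track <- function(step) lapply(0:4, function(f)
    data.frame(x = 10 + f * step, y = 50, intensity = 1, quality = 9))
  # displacement 120: removed
  t120 <- filter_and_summarize(link_tracks(mk_track(30), 1, 150, 3), 125)
  expect_equal(nrow(t120$summary), 0L)
  # displacement 130: kept
  t130 <- filter_and_summarize(link_tracks(mk_track(32.5), 1, 150, 3), 125)
  expect_equal(nrow(t130$summary), 1L)
  expect_equal(t130$summary$displacement, 130)
  # exactly at the threshold: kept
  t125 <- filter_and_summarize(link_tracks(mk_track(31.25), 1, 150, 3), 125)
  expect_equal(nrow(t125$summary), 1L)
  # constant-velocity speed is exact
  expect_equal(t130$summary$mean_speed, 32.5)
})

test_that("a stationary bead masked out upstream produces no track", {
  # the mask removes the stuck bead before detection, per the pipeline
  # contract: supply frames with the stuck bead erased
  pix <- 2
  moving <- lapply(1:6, function(f)
    render_beads(cbind(20 + 30 * (f - 1), 40), 120, 60, pix))
  sp <- detect_spots(moving, pixel_size = pix, diameter = 10)
  tr <- link_tracks(sp, 1, max_step = 150, min_frames = 3)
  res <- filter_and_summarize(tr, min_displacement = 125)
  expect_equal(nrow(res$summary), 1L)
  # no spurious stationary track exists anywhere
  expect_true(all(res$summary$displacement >= 125))
})
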