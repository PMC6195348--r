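test_that("background model is the filtered mean of the stack", {
  h <- 40; w <- 60
  const <- array(0.3, c(h, w, 5))
  expect_equal(build_background(const, sigma = 0), matrix(0.3, h, w))
  two <- array(c(matrix(0, h, w), matrix(1, h, w)), c(h, w, 2))
  expect_equal(build_background(two, sigma = 0), matrix(0.5, h, w))
  expect_error(build_background(array(0, c(h, w, 0))), "at least one")
})

test_that("background estimate converges to truth over 185 noisy frames", {
  cfg <- synth_config(13)
  tr <- synth_trajectory(cfg, 1)
  vid <- synth_arena_video(cfg, tr, n_background = 185)
  bg <- build_background(vid$frames[, , 1:185])
  # true background is the flat dark level; averaging + smoothing beats the
  # per-pixel noise SD everywhere
  expect_lt(max(abs(bg - 0.08)), cfg$video_noise_sd)
})

test_that("track_frame finds a blob, applies the jump rule, infers when blank", {
  bg <- matrix(0, 80, 260)
  params <- tracker_params(threshold = 0.2, sigma = 1)
  blob_frame <- function(cx, cy) {
    f <- bg
    f[(cy - 3):(cy + 3), (cx - 3):(cx + 3)] <- 1
    f
  }
  r <- track_frame(blob_frame(200, 50), bg, params, previous = c(198, 50))
  expect_identical(r$valid, "detected")
  expect_lt(sqrt((r$x - 200)^2 + (r$y - 50)^2), 2)
  # only candidate 150 px away from the previous position: excluded
  r2 <- track_frame(blob_frame(200, 50), bg, params, previous = c(50, 50))
  expect_identical(r2$valid, "inferred")
  expect_identical(c(r2$x, r2$y), c(50, 50))
  # frame identical to background: nothing above threshold
  r3 <- track_frame(bg, bg, params, previous = c(30, 30))
  expect_identical(r3$valid, "inferred")
  # no previous position and no blob: undefined start
  r4 <- track_frame(bg, bg, params, previous = NULL)
  expect_identical(r4$valid, "undefined")
  expect_true(is.na(r4$x))
  expect_error(track_frame(matrix(0, 2, 2), bg, params), "same shape")
})

test_that("exclusion areas and bounds suppress candidate blobs", {
  bg <- matrix(0, 100, 100)
  params <- tracker_params(threshold = 0.2, sigma = 1)
  f <- bg; f[10:16, 10:16] <- 1
  arena <- arena_geometry(list(z = cbind(c(30, 90, 90, 30),
                                         c(30, 30, 90, 90))),
                          bounds = cbind(c(30, 90, 90, 30), c(30, 30, 90, 90)),
                          px_per_cm = 4)
  r <- track_frame(f, bg, params, previous = c(50, 50), arena = arena)
  expect_identical(r$valid, "inferred")   # blob outside the bounds
  arena2 <- arena_geometry(list(z = cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))),
                           bounds = cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)),
                           px_per_cm = 4,
                           exclusions = list(cbind(c(5, 20, 20, 5),
                                                   c(5, 5, 20, 20))))
  r2 <- track_frame(f, bg, params, previous = c(50, 50), arena = arena2)
  expect_identical(r2$valid, "inferred")  # blob inside an exclusion area
})

test_that("trajectory invariants hold on a tracked synthetic video", {
  cfg <- synth_config(17)
  tr <- synth_trajectory(cfg, 250)
  vid <- synth_arena_video(cfg, tr, n_background = 20)
  got <- track_video(vid, params = tracker_params(threshold = 0.2))
  expect_identical(nrow(got), 250L)            # one output row per frame
  det <- got$valid == "detected"
  expect_true(all(point_in_polygon(cbind(got$x[det], got$y[det]),
                                   vid$arena$bounds)))
  # inferred rows repeat the most recent detected position
  for (i in which(got$valid == "inferred")) {
    prev <- max(which(det[seq_len(i - 1L)]))
    expect_identical(c(got$x[i], got$y[i]), c(got$x[prev], got$y[prev]))
  }
  err <- sqrt((got$x - tr$x)^2 + (got$y - tr$y)^2)
  expect_lt(mean(err), 2)
  expect_lt(mean(got$valid == "inferred"), 0.01)
})

test_that("occupancy, entrances, distance and velocity follow the formulas", {
  arena <- two_zone_arena(px_per_cm = 4)
  still <- path_trajectory(rep(100, 500))
  occ <- occupancy_and_entrances(still, arena)
  expect_equal(unname(occ$time[["left"]]), 10.0)
  expect_equal(unname(occ$entrances[["right"]]), 0L)
  straight <- path_trajectory(seq(0, 400, length.out = 101))
  occ2 <- occupancy_and_entrances(straight, arena)
  expect_equal(occ2$distance_cm, 100)      # 400 px at 4 px/cm
  expect_equal(occ2$mean_velocity_cms, 100 / (101 / 50))
  # zone times plus out-of-zone time account for the whole session
  expect_equal(sum(occ2$time), nrow(straight) / 50)
  expect_error(occupancy_and_entrances(straight[0, ], arena), "empty")
})

test_that("planted zone visits are counted as entrances exactly", {
  arena <- two_zone_arena()
  # 7 excursions into the right half
  xs <- rep(c(rep(100, 10), rep(300, 10)), 7)
  occ <- occupancy_and_entrances(path_trajectory(xs), arena)
  expect_identical(unname(occ$entrances[["right"]]), 7L)
  expect_identical(unname(occ$entrances[["left"]]), 6L)
})

test_that("cup approaches are scored within the interaction annulus", {
  arena <- arena_three_chamber()
  cup <- arena$cups$mouse
  xs <- c(rep(cup$center[1], 20), rep(cup$center[1] + 200, 20))
  traj <- trajectory(seq_along(xs) / 50, xs, rep(cup$center[2], 40),
                     frame_rate = 50)
  ca <- cup_approaches(traj, arena)
  expect_equal(ca$time_s[ca$cup == "mouse"], 0.4)
  expect_equal(ca$approaches[ca$cup == "mouse"], 1L)
  expect_equal(ca$time_s[ca$cup == "object"], 0)
})

test_that("EPM entries split into full and jittery by penetration depth", {
  arena <- arena_epm(px_per_cm = 3)   # arm entrance at x = 161.25 for right
  ctr <- 150
  full_depth <- 4 * 3                 # 4 cm in px
  deep <- c(seq(ctr, ctr + 11.25 + 90, length.out = 30),
            seq(ctr + 11.25 + 90, ctr, length.out = 30))
  shallow <- c(seq(ctr, ctr + 11.25 + 3, length.out = 10),  # 1 cm deep
               seq(ctr + 11.25 + 3, ctr, length.out = 10))
  mk <- function(xs) trajectory(seq_along(xs) / 50, xs,
                                rep(ctr, length(xs)), frame_rate = 50)
  e1 <- classify_epm_entries(mk(deep), arena, full_depth_cm = 4)
  r1 <- e1[e1$arm == "open_right", ]
  expect_identical(c(r1$full, r1$jittery), c(1L, 0L))
  e2 <- classify_epm_entries(mk(shallow), arena, full_depth_cm = 4)
  r2 <- e2[e2$arm == "open_right", ]
  expect_identical(c(r2$full, r2$jittery), c(0L, 1L))
})
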