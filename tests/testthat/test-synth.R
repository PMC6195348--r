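test_that("eyeblink session composition is exact and typed correctly", {
  sb <- synth_eyeblink_session(synth_config(11))
  tab <- table(sb$session$trials$type)
  expect_identical(unname(tab[["paired"]]), 200L)
  expect_identical(unname(tab[["cs_only"]]), 20L)
  expect_identical(unname(tab[["us_only"]]), 10L)
  counted <- sb$session$trials$type != "us_only"
  expect_false(anyNA(sb$session$trials$cs_onset[counted]))
  expect_true(all(is.na(sb$session$trials$cs_onset[!counted])))
  # order is randomized, not blocked by type
  expect_gt(length(rle(sb$session$trials$type)$lengths), 20)
})

test_that("US co-terminates with the CS: reflex peaks 500 ms after CS onset", {
  sb <- synth_eyeblink_session(synth_config(12))
  s <- sb$session
  us <- which(s$trials$type == "us_only")
  tt <- (seq_len(ncol(s$traces)) - 1L) / s$sample_rate
  peak_t <- mean(vapply(us, function(i) tt[which.max(s$traces[i, ])],
                        numeric(1L)))
  # CS onset 0.2 s, CS 500 ms, US 30 ms co-terminating: US onset at
  # 0.2 + 0.47 s, UR transient peaking ~30 ms later
  expect_lt(abs(peak_t - (0.2 + 0.47 + 0.03)), 0.015)
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- synth_config(99)
  tr1 <- synth_trajectory(cfg, 50)
  tr2 <- synth_trajectory(cfg, 50)
  expect_identical(tr1, tr2)
  v1 <- synth_arena_video(cfg, tr1, n_background = 10)
  v2 <- synth_arena_video(cfg, tr2, n_background = 10)
  expect_identical(v1$frames, v2$frames)
  m1 <- synth_metric_groups(cfg, n_control = 8,
                            groups = list(g = list(n = 5)))
  m2 <- synth_metric_groups(cfg, n_control = 8,
                            groups = list(g = list(n = 5)))
  expect_identical(m1, m2)
  e1 <- synth_eyeblink_session(cfg, n_paired = 5, n_cs_only = 2,
                               n_us_only = 2)
  e2 <- synth_eyeblink_session(cfg, n_paired = 5, n_cs_only = 2,
                               n_us_only = 2)
  expect_identical(e1$session$traces, e2$session$traces)
  # and the caller's RNG stream is left untouched
  set.seed(5); a <- rnorm(1)
  set.seed(5); invisible(synth_trajectory(cfg, 10)); b <- rnorm(1)
  expect_identical(a, b)
})

test_that("arena video has the requested background segment and rejects
           out-of-bounds trajectories", {
  cfg <- synth_config(7)
  tr <- synth_trajectory(cfg, 30)
  vid <- synth_arena_video(cfg, tr, n_background = 185)
  expect_identical(vid$n_background, 185L)
  expect_identical(dim(vid$frames)[3], 185L + 30L)
  bad <- trajectory(1:3 / 50, c(10, 500, 10), c(10, 10, 10), frame_rate = 50)
  expect_error(synth_arena_video(cfg, bad), "bounds")
})

test_that("noise-free video tracks to the intensity-weighted centroid", {
  cfg <- synth_config(3, video_noise_sd = 0)
  tr <- synth_trajectory(cfg, 60)
  vid <- synth_arena_video(cfg, tr, n_background = 5)
  params <- tracker_params(threshold = 0.2)
  bg <- build_background(vid$frames[, , 1:5], sigma = params$sigma)
  got <- track_video(vid, params = params)
  for (i in seq_len(60)) {
    fr <- vid$frames[, , 5 + i]
    d <- abs(fr - bg)
    mask <- d > params$threshold
    w <- d * mask
    # oracle: intensity-weighted centroid of the suprathreshold difference
    cx <- sum(col(fr) * w) / sum(w)
    cy <- sum(row(fr) * w) / sum(w)
    expect_lt(sqrt((got$x[i] - cx)^2 + (got$y[i] - cy)^2), 1)
  }
})

test_that("null metric groups are KS-indistinguishable in most seeds", {
  ok <- vapply(1:100, function(s) {
    m <- synth_metric_groups(synth_config(s), metrics = c("a", "b"),
                             n_control = 12,
                             groups = list(g = list(n = 12)))
    ks_compare(m$a[m$group == "control"], m$a[m$group == "g"])$p > 0.05
  }, logical(1L))
  expect_gte(mean(ok), 0.90)
})

test_that("a planted 3-SD shift yields Cohen's d near 3", {
  m <- synth_metric_groups(synth_config(21), metrics = c("a", "b"),
                           n_control = 400,
                           groups = list(g = list(n = 400,
                                                  shift = c(a = 3))))
  d <- cohens_d(m$a[m$group == "g"], m$a[m$group == "control"])
  expect_lt(abs(d - 3), 0.35)
  d0 <- cohens_d(m$b[m$group == "g"], m$b[m$group == "control"])
  expect_lt(abs(d0), 0.35)
})

test_that("variance inflation and degenerate covariances behave", {
  m <- synth_metric_groups(synth_config(4), metrics = c("a", "b"),
                           n_control = 300,
                           groups = list(g = list(n = 300,
                                                  var_inflation = c(a = 4))))
  r <- var(m$a[m$group == "g"]) / var(m$a[m$group == "control"])
  expect_gt(r, 2.5); expect_lt(r, 6)
  badR <- matrix(1, 2, 2)  # perfectly collinear: not positive definite
  expect_error(synth_metric_groups(synth_config(1), metrics = c("a", "b"),
                                   corr = badR), "positive definite")
  expect_error(synth_metric_groups(synth_config(1),
                                   groups = list(g = list(n = 2))), "n >= 3")
})

test_that("expression cohort plants realistic dominant fractions", {
  ch <- synth_expression_cohort(synth_config(31), n_mice = 50)
  dom <- vapply(seq_len(50), function(i)
    ch$fractions[i, ch$truth$target[i]], numeric(1L))
  expect_gt(mean(dom), 0.15)
  expect_lt(mean(dom), 0.27)
  expect_true(all(ch$fractions >= 0 & ch$fractions <= 1))
})

test_that("generated datasets round-trip through writers and readers", {
  cfg <- synth_config(5)
  dir <- withr::local_tempdir()
  tr <- synth_trajectory(cfg, 20)
  write_trajectory(tr, file.path(dir, "t.csv"))
  expect_equal(read_trajectory(file.path(dir, "t.csv")), tr)

  vid <- synth_arena_video(cfg, synth_trajectory(cfg, 4), n_background = 3)
  write_frames(vid, file.path(dir, "frames"))
  rt <- read_frames(file.path(dir, "frames"))
  expect_identical(rt$frames, vid$frames)   # 8-bit quantized: lossless
  expect_identical(rt$n_background, 3L)

  sb <- synth_eyeblink_session(cfg, n_paired = 4, n_cs_only = 2,
                               n_us_only = 2)
  write_eyeblink_session(sb$session, file.path(dir, "s.csv"))
  rs <- read_eyeblink_session(file.path(dir, "s.csv"))
  expect_equal(rs$traces, sb$session$traces, ignore_attr = TRUE)
  expect_equal(rs$trials$type, sb$session$trials$type)

  m <- synth_metric_groups(cfg, metrics = c("a", "b"), n_control = 5)
  m$a[2] <- NA
  write_metric_matrix(m, file.path(dir, "m.csv"))
  rm_ <- read_metric_matrix(file.path(dir, "m.csv"))
  expect_equal(rm_$a, m$a)
  expect_equal(attr(rm_, "metrics"), attr(m, "metrics"))

  ch <- synth_expression_cohort(cfg, n_mice = 2, dims = c(8, 4, 4))
  write_expression_volume(ch$volumes[[1]], file.path(dir, "vol"))
  rv <- read_expression_volume(file.path(dir, "vol"))
  expect_identical(rv$label, ch$volumes[[1]]$label)
  expect_identical(rv$masks, ch$volumes[[1]]$masks)

  pp <- synth_paw_placements(cfg, n_steps = 4)
  write_paw_placements(pp, file.path(dir, "p.csv"))
  rp <- read_paw_placements(file.path(dir, "p.csv"))
  expect_equal(rp$x, pp$x)
  expect_identical(attr(rp, "px_per_cm"), attr(pp, "px_per_cm"))

  gl <- synth_grooming_log(cfg)
  write_grooming_log(gl, file.path(dir, "g.csv"))
  expect_equal(read_grooming_log(file.path(dir, "g.csv"))$end, gl$end)

  st <- synth_spike_train(cfg, duration = 2)
  write_spike_train(st, file.path(dir, "sp.csv"))
  expect_equal(read_spike_train(file.path(dir, "sp.csv")), st)

  ar <- arena_epm()
  write_arena(ar, file.path(dir, "a.json"))
  ra <- read_arena(file.path(dir, "a.json"))
  expect_equal(ra$zones, ar$zones)
  expect_equal(ra$px_per_cm, ar$px_per_cm)
})
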