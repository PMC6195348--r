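# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures on disk.

# A tiny manually-built eyeblink session: constant-baseline traces with
# rectangular deflections at known times. Sample rate 1000 Hz, 1 s trials,
# CS at 0.2 s for counted trials.
manual_session <- function(deflections, sample_rate = 1000, ur_amp = 1,
                           baseline = 0.3) {
  # deflections: list of per-trial list(type, at, amp, width)
  n <- length(deflections)
  tt <- seq(0, 1 - 1 / sample_rate, by = 1 / sample_rate)
  traces <- matrix(baseline, n, length(tt))
  type <- character(n)
  for (i in seq_len(n)) {
    d <- deflections[[i]]
    type[i] <- d$type
    if (!is.null(d$at))
      traces[i, tt >= d$at & tt < d$at + (d$width %||% 0.05)] <-
        baseline + d$amp
    if (d$type == "us_only")
      traces[i, tt >= 0.7 & tt < 0.75] <- baseline + ur_amp
  }
  trials <- data.frame(trial = seq_len(n), type = type,
                       cs_onset = ifelse(type == "us_only", NA_real_, 0.2))
  eyeblink_session(trials, traces, sample_rate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A rectangular two-zone arena: left/right halves of a 200 x 400 px box.
two_zone_arena <- function(px_per_cm = 4) {
  arena_geometry(
    zones = list(left = cbind(c(0, 200, 200, 0), c(0, 0, 200, 200)),
                 right = cbind(c(200, 400, 400, 200), c(0, 0, 200, 200))),
    bounds = cbind(c(0, 400, 400, 0), c(0, 0, 200, 200)),
    px_per_cm = px_per_cm)
}

# Trajectory visiting given x positions at fixed y (50 Hz).
path_trajectory <- function(xs, y = 100, frame_rate = 50) {
  trajectory(seq_along(xs) / frame_rate, xs, rep(y, length(xs)),
             frame_rate = frame_rate)
}

# Independent brute-force Spearman permutation p: enumerate permutations via
# expand.grid filtering, compute the correlation with cor() per permutation.
brute_spearman_p <- function(x, y) {
  n <- length(x)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- grid[apply(grid, 1L, function(r) length(unique(r)) == n), ,
                drop = FALSE]
  obs <- abs(cor(x, y, method = "spearman"))
  stat <- apply(perms, 1L, function(pp)
    abs(cor(x, y[pp], method = "spearman")))
  mean(stat >= obs - 1e-9)
}
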