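#' Configuration for the synthetic-data generators
#'
#' Collects the shared knobs of the synthetic-data module. Every generator is
#' fully deterministic given `seed` (the global RNG state is saved and
#' restored around each call), so the same configuration always reproduces the
#' same dataset bit for bit.
#'
#' @param seed integer seed driving all generated randomness.
#' @param frame_rate video acquisition rate in Hz (cameras in this kind of
#'   arena setup typically run at 50 frames/s, the default).
#' @param frame_size video frame size as `c(rows, cols)` pixels.
#' @param video_noise_sd additive pixel noise SD on 0..1 grayscale frames.
#' @param eyelid_noise_sd eyelid-trace noise SD, in fraction-of-full-UR units.
#' @param px_per_cm default pixel scale for generated arenas.
#' @param n_control,n_per_group default cohort sizes for metric-table
#'   generation (36 pooled controls, as in a combined untreated + vehicle
#'   control group; experimental groups of 10).
#' @param dosage_weights named numeric vector `c(intercept, lobule_vi,
#'   lobule_vii, crus_i, crus_ii)`: the planted forward model of the
#'   expression-dosage cohort.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, frame_rate = 50, frame_size = c(120, 160),
                         video_noise_sd = 0.02, eyelid_noise_sd = 0.02,
                         px_per_cm = 4, n_control = 36, n_per_group = 10,
                         dosage_weights = c(intercept = 0.5, lobule_vi = -3,
                                            lobule_vii = 0, crus_i = -2,
                                            crus_ii = 0)) {
  if (frame_rate <= 0) stop2("frame_rate must be positive")
  structure(list(seed = as.integer(seed), frame_rate = frame_rate,
                 frame_size = as.integer(frame_size),
                 video_noise_sd = video_noise_sd,
                 eyelid_noise_sd = eyelid_noise_sd, px_per_cm = px_per_cm,
                 n_control = n_control, n_per_group = n_per_group,
                 dosage_weights = dosage_weights),
            class = "synth_config")
}

# Evaluate code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Default arena for synthetic videos
#'
#' A rectangular open arena filling the configured frame with a small margin.
#'
#' @param config a [synth_config()].
#' @param margin_px margin between frame edge and arena wall.
#' @return an [arena_geometry()] with a single `arena` zone.
#' @export
synth_arena <- function(config, margin_px = 4) {
  h <- config$frame_size[1L]; w <- config$frame_size[2L]
  b <- rect_poly(margin_px, margin_px, w - margin_px, h - margin_px)
  arena_geometry(list(arena = b), b, config$px_per_cm)
}

#' Generate a smooth trajectory inside an arena
#'
#' Either a smoothed random wander (an autoregressive velocity process,
#' reflected at the walls) or a constant-speed path through given waypoints.
#'
#' @param config a [synth_config()].
#' @param n_frames number of frames.
#' @param arena an [arena_geometry()]; default [synth_arena()].
#' @param kind `"wander"` or `"waypoints"`.
#' @param speed_px mean speed, pixels per frame, for `"wander"`.
#' @param margin_px wall standoff of the wander region.
#' @param region optional `c(xmin, xmax, ymin, ymax)` sub-rectangle to confine
#'   the wander.
#' @param waypoints two-column matrix of pixel waypoints for `"waypoints"`.
#' @return a [trajectory()], every position strictly inside the arena bounds.
#' @export
synth_trajectory <- function(config, n_frames, arena = synth_arena(config),
                             kind = c("wander", "waypoints"), speed_px = 2,
                             margin_px = 10, region = NULL, waypoints = NULL) {
  kind <- match.arg(kind)
  bb <- apply(arena$bounds, 2L, range)
  lim <- c(bb[1L, 1L] + margin_px, bb[2L, 1L] - margin_px,
           bb[1L, 2L] + margin_px, bb[2L, 2L] - margin_px)
  if (!is.null(region)) lim <- region
  pos <- with_seed(config$seed, {
    if (kind == "wander") {
      p <- matrix(NA_real_, n_frames, 2L)
      xy <- c(mean(lim[1:2]), mean(lim[3:4]))
      v <- rnorm(2L, 0, speed_px / 2)
      for (i in seq_len(n_frames)) {
        v <- 0.9 * v + rnorm(2L, 0, speed_px / 3)
        xy <- xy + v
        # reflect at the walls
        if (xy[1L] < lim[1L]) { xy[1L] <- 2 * lim[1L] - xy[1L]; v[1L] <- -v[1L] }
        if (xy[1L] > lim[2L]) { xy[1L] <- 2 * lim[2L] - xy[1L]; v[1L] <- -v[1L] }
        if (xy[2L] < lim[3L]) { xy[2L] <- 2 * lim[3L] - xy[2L]; v[2L] <- -v[2L] }
        if (xy[2L] > lim[4L]) { xy[2L] <- 2 * lim[4L] - xy[2L]; v[2L] <- -v[2L] }
        p[i, ] <- xy
      }
      p
    } else {
      wp <- as.matrix(waypoints)
      if (is.null(wp) || nrow(wp) < 2L)
        stop2("waypoints kind needs a matrix of >= 2 waypoints")
      seg <- sqrt(rowSums(diff(wp)^2))
      s <- c(0, cumsum(seg))
      at <- seq(0, s[length(s)], length.out = n_frames)
      cbind(approx(s, wp[, 1L], xout = at)$y, approx(s, wp[, 2L], xout = at)$y)
    }
  })
  trajectory(seq_len(n_frames) / config$frame_rate, pos[, 1L], pos[, 2L],
             frame_rate = config$frame_rate)
}

render_blob <- function(frame, cx, cy, sx, sy, amp) {
  h <- nrow(frame); w <- ncol(frame)
  gy <- exp(-((seq_len(h) - cy)^2) / (2 * sy^2))
  gx <- exp(-((seq_len(w) - cx)^2) / (2 * sx^2))
  frame + amp * outer(gy, gx)
}

#' Render a synthetic arena video around a true trajectory
#'
#' Produces a mouse-free background segment followed by frames containing a
#' bright anisotropic-Gaussian blob centred on the true position, over a dark
#' background with additive pixel noise, quantized to 8-bit grayscale.
#' Optionally adds a distractor blob that jumps to a new random location every
#' frame (always far from the animal), and drops the animal blob on a
#' configured fraction of frames.
#'
#' @param config a [synth_config()].
#' @param traj a [trajectory()] of true positions; must lie inside the arena
#'   bounds or the call is rejected.
#' @param arena an [arena_geometry()].
#' @param n_background number of leading mouse-free frames (a 5 s background
#'   segment at 50 frames/s minus overhead is conventionally 185 frames).
#' @param blob_sigma blob axes `c(sx, sy)` in pixels.
#' @param blob_amp blob peak intensity above background.
#' @param distractor_rate fraction of mouse frames carrying a distractor blob.
#' @param distractor_min_dist minimum distance (px) between distractor and the
#'   true position; above the tracker's jump limit this exercises the
#'   jump-exclusion rule.
#' @param dropout_rate fraction of mouse frames in which the animal blob is
#'   omitted (occlusion model).
#' @return a list of class `synth_video`: `frames` (rows x cols x n array in
#'   0..1, 8-bit quantized), `n_background`, `truth` (the input trajectory),
#'   `frame_rate`, `arena`, and `distractor` (per-frame logical).
#' @export
synth_arena_video <- function(config, traj, arena = synth_arena(config),
                              n_background = 185, blob_sigma = c(5, 3.5),
                              blob_amp = 0.8, distractor_rate = 0,
                              distractor_min_dist = 110, dropout_rate = 0) {
  inside <- point_in_polygon(cbind(traj$x, traj$y), arena$bounds)
  if (!all(inside)) stop2("trajectory leaves the arena bounds; rejected")
  h <- config$frame_size[1L]; w <- config$frame_size[2L]
  n <- nrow(traj)
  n_background <- as.integer(n_background)
  bg_level <- 0.08
  with_seed(config$seed + 1L, {
    frames <- array(0, c(h, w, n_background + n))
    has_distractor <- rep(FALSE, n_background + n)
    for (i in seq_len(n_background)) {
      f <- matrix(bg_level, h, w)
      if (config$video_noise_sd > 0)
        f <- f + matrix(rnorm(h * w, 0, config$video_noise_sd), h, w)
      frames[, , i] <- f
    }
    dropped <- runif(n) < dropout_rate
    distract <- runif(n) < distractor_rate
    for (i in seq_len(n)) {
      f <- matrix(bg_level, h, w)
      if (!dropped[i])
        f <- render_blob(f, traj$x[i], traj$y[i], blob_sigma[1L],
                         blob_sigma[2L], blob_amp)
      if (distract[i]) {
        repeat {
          dx <- runif(1L, 5, w - 5); dy <- runif(1L, 5, h - 5)
          if (sqrt((dx - traj$x[i])^2 + (dy - traj$y[i])^2) >=
              distractor_min_dist) break
        }
        f <- render_blob(f, dx, dy, 3, 3, blob_amp)
        has_distractor[n_background + i] <- TRUE
      }
      if (config$video_noise_sd > 0)
        f <- f + matrix(rnorm(h * w, 0, config$video_noise_sd), h, w)
      frames[, , n_background + i] <- f
    }
    frames <- round(pmin(pmax(frames, 0), 1) * 255) / 255
    structure(list(frames = frames, n_background = n_background, truth = traj,
                   frame_rate = config$frame_rate, arena = arena,
                   distractor = has_distractor),
              class = "synth_video")
  })
}

#' Generate an eyeblink-conditioning session with planted responses
#'
#' One day of training: by default exactly 200 paired (CS+US), 20 CS-only
#' probe and 10 US-only trials in randomized order. The CS is a 500 ms light;
#' on paired trials a 30 ms airpuff US co-terminates with the CS (US onset
#' 470 ms after CS onset). Each trial's raw eyelid trace is a per-trial
#' baseline offset plus alpha-function transients: an unconditioned-response
#' blink after every US (amplitude defining full eye closure), and, on trials
#' planted as conditioned responders, an anticipatory CR bump of configured
#' amplitude (in fraction-of-full-UR units) peaking inside the CS-US interval.
#'
#' @param config a [synth_config()].
#' @param n_paired,n_cs_only,n_us_only exact trial counts.
#' @param cr_rate fraction of counted (paired + CS-only) trials planted with
#'   a CR.
#' @param cr_amp CR amplitude range (fraction-of-UR); drawn uniformly.
#' @param noncr_amp residual bump amplitude range on non-CR trials.
#' @param cr_peak CR peak latency range, s after CS onset.
#' @param sample_rate trace sampling rate, Hz.
#' @param trial_dur,cs_onset,cs_dur,us_dur timing parameters, s.
#' @param gain volts per unit eyelid closure of the simulated sensor.
#' @return a list of class `synth_eyeblink`: `session` (an
#'   [eyeblink_session()]) and `truth` (data frame with planted `cr`
#'   labels, amplitudes and peak latencies per trial).
#' @export
synth_eyeblink_session <- function(config, n_paired = 200, n_cs_only = 20,
                                   n_us_only = 10, cr_rate = 0.5,
                                   cr_amp = c(0.3, 0.8), noncr_amp = c(0, 0),
                                   cr_peak = c(0.15, 0.23), sample_rate = 1000,
                                   trial_dur = 1, cs_onset = 0.2, cs_dur = 0.5,
                                   us_dur = 0.03, gain = 2) {
  with_seed(config$seed + 2L, {
    type <- sample(c(rep("paired", n_paired), rep("cs_only", n_cs_only),
                     rep("us_only", n_us_only)))
    n <- length(type)
    us_onset <- cs_onset + cs_dur - us_dur
    tt <- seq(0, trial_dur - 1 / sample_rate, by = 1 / sample_rate)
    counted <- type != "us_only"
    cr <- rep(NA, n)
    cr[counted] <- runif(sum(counted)) < cr_rate
    amp <- ifelse(!is.na(cr) & cr, runif(n, cr_amp[1L], cr_amp[2L]),
                  runif(n, noncr_amp[1L], noncr_amp[2L]))
    amp[!counted] <- 0
    peak <- runif(n, cr_peak[1L], cr_peak[2L])
    alpha_bump <- function(t0, tau) {
      x <- (tt - t0) / tau
      ifelse(x > 0, x * exp(1 - x), 0)
    }
    traces <- matrix(0, n, length(tt))
    for (i in seq_len(n)) {
      base <- 0.1 + rnorm(1L, 0, 0.02)
      y <- rep(base, length(tt))
      if (counted[i] && amp[i] > 0) {
        # CR onset 50 ms after CS, peak at the planted latency
        tau <- peak[i] - 0.05
        y <- y + gain * amp[i] * alpha_bump(cs_onset + 0.05, tau)
      }
      if (type[i] != "cs_only")
        y <- y + gain * 1 * alpha_bump(us_onset, us_dur)
      y <- y + rnorm(length(tt), 0, config$eyelid_noise_sd * gain)
      traces[i, ] <- y
    }
    session <- eyeblink_session(
      trials = data.frame(trial = seq_len(n), type = type,
                          cs_onset = ifelse(counted, cs_onset, NA_real_),
                          stringsAsFactors = FALSE),
      traces = traces, sample_rate = sample_rate)
    truth <- data.frame(trial = seq_len(n), type = type, cr = cr, amp = amp,
                        peak_latency = ifelse(amp > 0, peak, NA_real_))
    structure(list(session = session, truth = truth), class = "synth_eyeblink")
  })
}

#' Table of the behavioral metric names
#'
#' The 19 assay metrics (elevated plus-maze, grooming, social chamber,
#' Y-maze), in their canonical order.
#'
#' @return character vector of 19 metric names.
#' @export
table2_metrics <- function() {
  c("EPM_Commitment", "EPM_Distance", "EPM_Exploration Entrances",
    "EPM_Exploration Time", "EPM_Open-Arm Preference", "GR_Grooming Ratio",
    "SC_Baseline Distance", "SC_Novelty-Seeking", "SC_Social Preference",
    "SC_Test Distance", "YM_Final Learning", "YM_Initial Learning",
    "YM_Multisession Learning", "YM_Distance", "YM_Final Reversal 1",
    "YM_Initial Reversal 1", "YM_Multisession Reversal 1",
    "YM_Final Reversal 2", "YM_Initial Reversal 2")
}

default_metric_scales <- function(metrics) {
  mu <- c("EPM_Commitment" = 0.75, "EPM_Distance" = 1500,
          "EPM_Exploration Entrances" = 25, "EPM_Exploration Time" = 60,
          "EPM_Open-Arm Preference" = 0.30, "GR_Grooming Ratio" = 0.10,
          "SC_Baseline Distance" = 25, "SC_Novelty-Seeking" = 0.20,
          "SC_Social Preference" = 0.70, "SC_Test Distance" = 22,
          "YM_Final Learning" = 90, "YM_Initial Learning" = 65,
          "YM_Multisession Learning" = 15, "YM_Distance" = 15,
          "YM_Final Reversal 1" = 85, "YM_Initial Reversal 1" = 35,
          "YM_Multisession Reversal 1" = 20, "YM_Final Reversal 2" = 90,
          "YM_Initial Reversal 2" = 70)
  sdv <- c("EPM_Commitment" = 0.10, "EPM_Distance" = 300,
           "EPM_Exploration Entrances" = 6, "EPM_Exploration Time" = 15,
           "EPM_Open-Arm Preference" = 0.10, "GR_Grooming Ratio" = 0.25,
           "SC_Baseline Distance" = 5, "SC_Novelty-Seeking" = 0.15,
           "SC_Social Preference" = 0.08, "SC_Test Distance" = 5,
           "YM_Final Learning" = 8, "YM_Initial Learning" = 12,
           "YM_Multisession Learning" = 5, "YM_Distance" = 3,
           "YM_Final Reversal 1" = 10, "YM_Initial Reversal 1" = 12,
           "YM_Multisession Reversal 1" = 6, "YM_Final Reversal 2" = 8,
           "YM_Initial Reversal 2" = 12)
  if (all(metrics %in% names(mu)))
    list(mu = mu[metrics], sd = sdv[metrics])
  else
    list(mu = setNames(rep(0, length(metrics)), metrics),
         sd = setNames(rep(1, length(metrics)), metrics))
}

default_metric_corr <- function(metrics) {
  p <- length(metrics)
  R <- diag(p); dimnames(R) <- list(metrics, metrics)
  block <- function(members, r) {
    members <- intersect(members, metrics)
    for (a in members) for (b in members) if (a != b) R[a, b] <<- r
  }
  # movement metrics covary strongly; PC1 of controls is a distance component
  block(c("EPM_Distance", "SC_Baseline Distance", "SC_Test Distance",
          "YM_Distance"), 0.8)
  block(c("YM_Multisession Learning", "YM_Multisession Reversal 1",
          "YM_Final Reversal 1"), 0.5)
  R
}

#' Generate control and experimental behavioral metric tables
#'
#' Draws a control group from a multivariate normal with a configured
#' covariance (default: realistic per-metric scales with a strongly
#' correlated movement/distance block), and each experimental group from the
#' same distribution displaced by a planted mean shift and/or a planted
#' variance inflation on selected metrics.
#'
#' @param config a [synth_config()].
#' @param metrics metric names; default the full 19-metric panel.
#' @param n_control control group size.
#' @param groups named list of experimental groups, each a list with
#'   elements `n` (size, >= 3), and optionally `shift` (named, in population
#'   SD units), `shift_raw` (named, raw metric units), `var_inflation`
#'   (named variance multipliers).
#' @param mu,sd optional named population mean / SD vectors.
#' @param corr optional correlation matrix (must be positive definite).
#' @return a [metric_matrix()] with a `truth` attribute recording the planted
#'   population parameters.
#' @export
synth_metric_groups <- function(config, metrics = table2_metrics(),
                                n_control = config$n_control, groups = list(),
                                mu = NULL, sd = NULL, corr = NULL) {
  p <- length(metrics)
  scales <- default_metric_scales(metrics)
  if (is.null(mu)) mu <- scales$mu
  if (is.null(sd)) sd <- scales$sd
  if (is.null(corr)) corr <- default_metric_corr(metrics)
  Sigma <- diag(sd) %*% corr %*% diag(sd)
  dimnames(Sigma) <- list(metrics, metrics)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) stop2("metric covariance is not positive definite")
  for (g in groups)
    if (is.null(g$n) || g$n < 3L) stop2("each group needs size n >= 3")
  with_seed(config$seed + 3L, {
    draw <- function(n, label, shift_raw = NULL, inflation = NULL) {
      X <- MASS::mvrnorm(n, mu, Sigma)
      X <- matrix(X, n, p, dimnames = list(NULL, metrics))
      if (!is.null(inflation))
        for (m in names(inflation))
          X[, m] <- mu[m] + (X[, m] - mu[m]) * sqrt(inflation[[m]])
      if (!is.null(shift_raw))
        for (m in names(shift_raw)) X[, m] <- X[, m] + shift_raw[[m]]
      data.frame(mouse = paste0(label, "_", seq_len(n)), group = label,
                 X, check.names = FALSE, stringsAsFactors = FALSE)
    }
    out <- draw(n_control, "control")
    truth_groups <- list()
    for (nm in names(groups)) {
      g <- groups[[nm]]
      shift_raw <- numeric(0)
      if (!is.null(g$shift))
        shift_raw <- setNames(as.numeric(g$shift) * sd[names(g$shift)],
                              names(g$shift))
      if (!is.null(g$shift_raw))
        shift_raw <- c(shift_raw, unlist(g$shift_raw))
      out <- rbind(out, draw(g$n, nm, shift_raw = as.list(shift_raw),
                             inflation = g$var_inflation))
      truth_groups[[nm]] <- list(shift_raw = shift_raw,
                                 var_inflation = g$var_inflation)
    }
    mm <- metric_matrix(out, metrics)
    attr(mm, "truth") <- list(mu = mu, sd = sd, corr = corr,
                              groups = truth_groups)
    mm
  })
}

#' Generate an expression cohort: labeled volumes plus dosage-driven metrics
#'
#' Per mouse, builds a binary labeled-voxel volume over four disjoint lobule
#' masks, mimicking a targeted injection with spillover: the targeted lobule's
#' labeled fraction is drawn from a truncated normal with mean 0.21 and SD
#' 0.12, the next (spillover) lobule from mean 0.11, SD 0.11, and the
#' remaining lobules carry traces near zero. Behavioral metric values follow
#' the planted linear forward model `intercept + weights . fractions` plus
#' Gaussian noise.
#'
#' @param config a [synth_config()]; `config$dosage_weights` is the planted
#'   model unless `weights` is given.
#' @param n_mice cohort size.
#' @param weights named list of planted weight vectors, one per metric; each
#'   is `c(intercept, lobule_vi, lobule_vii, crus_i, crus_ii)`.
#' @param noise_sd Gaussian noise SD on the metric values.
#' @param dims volume dimensions `c(ap, dv, ml)` (anterior-posterior,
#'   dorsoventral, mediolateral); lobules are consecutive AP slabs.
#' @param dominant,spill `c(mean, sd)` of the targeted- and spillover-lobule
#'   fraction distributions.
#' @return a list of class `synth_cohort`: `volumes` (list of
#'   [expression_volume()]), `fractions` (n x 4 realized fraction matrix),
#'   `metrics` (a [metric_matrix()]), `truth` (planted weights, targeted
#'   lobule per mouse, noise SD).
#' @export
synth_expression_cohort <- function(config, n_mice = 20,
                                    weights = list(score = config$dosage_weights),
                                    noise_sd = 1, dims = c(40, 12, 12),
                                    dominant = c(0.21, 0.12),
                                    spill = c(0.11, 0.11)) {
  lobules <- c("lobule_vi", "lobule_vii", "crus_i", "crus_ii")
  ap_cut <- round(seq(0, dims[1L], length.out = 5L))
  masks <- lapply(seq_len(4L), function(k) {
    m <- array(FALSE, dims)
    m[(ap_cut[k] + 1L):ap_cut[k + 1L], , ] <- TRUE
    m
  })
  names(masks) <- lobules
  rtnorm <- function(n, mean, sd, lo, hi) {
    x <- rnorm(n, mean, sd)
    while (any(bad <- x < lo | x > hi)) x[bad] <- rnorm(sum(bad), mean, sd)
    x
  }
  with_seed(config$seed + 4L, {
    target <- rep_len(lobules, n_mice)
    fractions <- matrix(0, n_mice, 4L, dimnames = list(NULL, lobules))
    volumes <- vector("list", n_mice)
    for (i in seq_len(n_mice)) {
      f <- setNames(pmax(rnorm(4L, 0.01, 0.01), 0), lobules)
      f[target[i]] <- rtnorm(1L, dominant[1L], dominant[2L], 0.005, 0.95)
      neighbor <- sample(setdiff(lobules, target[i]), 1L)
      f[neighbor] <- rtnorm(1L, spill[1L], spill[2L], 0, 0.9)
      label <- array(FALSE, dims)
      for (k in seq_len(4L)) {
        vox <- which(masks[[k]])
        n_on <- round(f[k] * length(vox))
        if (n_on > 0L) label[sample(vox, n_on)] <- TRUE
        fractions[i, k] <- n_on / length(vox)
      }
      volumes[[i]] <- expression_volume(label, masks)
    }
    vals <- lapply(weights, function(w) {
      w <- as.numeric(w)
      w[1L] + fractions %*% w[2:5] + rnorm(n_mice, 0, noise_sd)
    })
    df <- data.frame(mouse = paste0("inj_", seq_len(n_mice)),
                     group = target, stringsAsFactors = FALSE)
    for (nm in names(vals)) df[[nm]] <- as.numeric(vals[[nm]])
    mm <- metric_matrix(df, names(weights))
    structure(list(volumes = volumes, fractions = fractions, metrics = mm,
                   truth = list(weights = weights, target = target,
                                noise_sd = noise_sd)),
              class = "synth_cohort")
  })
}

#' Generate paw placements of a straight walker
#'
#' Lays out left/right fore and hind paw placements along a travel direction
#' with a planted stride length and fore/hind stance widths, plus isotropic
#' placement jitter.
#'
#' @param config a [synth_config()].
#' @param n_steps placements per paw.
#' @param stride_cm distance between successive placements of the same paw.
#' @param stance_fore_cm,stance_hind_cm left-right separation of the fore and
#'   hind girdle.
#' @param jitter_cm placement jitter SD.
#' @param direction_deg travel direction (degrees, 0 = +x).
#' @param px_per_cm pixel scale (in-view ruler calibration).
#' @param origin start position, px.
#' @return a data frame of class `paw_placements` with columns
#'   `paw` (LF/RF/LH/RH), `step`, `x`, `y`; attributes `px_per_cm` and
#'   `truth` (the planted parameters).
#' @export
synth_paw_placements <- function(config, n_steps = 8, stride_cm = 6.5,
                                 stance_fore_cm = 1.8, stance_hind_cm = 2.6,
                                 jitter_cm = 0.1, direction_deg = 0,
                                 px_per_cm = 20, origin = c(100, 300)) {
  th <- direction_deg * pi / 180
  u <- c(cos(th), sin(th)); v <- c(-sin(th), cos(th))
  with_seed(config$seed + 5L, {
    rows <- list()
    layout <- list(LF = c(0, +stance_fore_cm / 2, 0),
                 RF = c(0.5, -stance_fore_cm / 2, 0),
                 LH = c(0.25, +stance_hind_cm / 2, -3),
                 RH = c(0.75, -stance_hind_cm / 2, -3))
    for (paw in names(layout)) {
      ph <- layout[[paw]][1L]; lat <- layout[[paw]][2L]; ap <- layout[[paw]][3L]
      along <- (seq_len(n_steps) - 1 + ph) * stride_cm + ap
      pts <- t(vapply(seq_len(n_steps), function(i)
        origin + (along[i] * u + lat * v) * px_per_cm +
          rnorm(2L, 0, jitter_cm * px_per_cm), numeric(2L)))
      rows[[paw]] <- data.frame(paw = paw, step = seq_len(n_steps),
                                x = pts[, 1L], y = pts[, 2L],
                                stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "px_per_cm") <- px_per_cm
    attr(out, "truth") <- list(stride_cm = stride_cm,
                               stance_fore_cm = stance_fore_cm,
                               stance_hind_cm = stance_hind_cm,
                               jitter_cm = jitter_cm,
                               direction_deg = direction_deg)
    class(out) <- c("paw_placements", "data.frame")
    out
  })
}

#' Generate a grooming event log
#'
#' Sequential non-overlapping grooming bouts over a 10-min observation
#' window, for a saline and a CNO condition, with a configurable fraction of
#' sub-second micro-events (which the analysis filter removes).
#'
#' @param config a [synth_config()].
#' @param mean_bout named `c(saline, cno)` mean bout lengths (s).
#' @param n_events target number of events per condition.
#' @param short_frac fraction of events drawn under 1 s.
#' @param session_dur observation window (s).
#' @return a data frame of class `grooming_log` with columns
#'   `condition, start, end` (s).
#' @export
synth_grooming_log <- function(config, mean_bout = c(saline = 4, cno = 3),
                               n_events = 15, short_frac = 0.2,
                               session_dur = 600) {
  with_seed(config$seed + 6L, {
    rows <- list()
    for (cond in names(mean_bout)) {
      t0 <- 0; ev <- list()
      for (i in seq_len(n_events)) {
        gap <- rexp(1L, rate = n_events / (session_dur * 0.6))
        dur <- if (runif(1L) < short_frac) runif(1L, 0.2, 0.95) else
          rgamma(1L, shape = 4, scale = mean_bout[[cond]] / 4)
        if (t0 + gap + dur > session_dur) break
        ev[[i]] <- c(t0 + gap, t0 + gap + dur)
        t0 <- t0 + gap + dur
      }
      if (length(ev)) {
        m <- do.call(rbind, ev)
        rows[[cond]] <- data.frame(condition = cond, start = m[, 1L],
                                   end = m[, 2L], stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("grooming_log", "data.frame")
    out
  })
}

#' Generate a spike train
#'
#' @param config a [synth_config()].
#' @param duration recording length (s).
#' @param rate mean firing rate (Hz).
#' @param pattern `"poisson"` (CV2 near 1), `"regular"` (CV2 = 0) or
#'   `"gamma"` (intermediate regularity; `shape` > 1 lowers CV2).
#' @param shape gamma shape for `pattern = "gamma"`.
#' @return numeric vector of strictly increasing spike times (s).
#' @export
synth_spike_train <- function(config, duration = 60, rate = 80,
                              pattern = c("poisson", "regular", "gamma"),
                              shape = 4) {
  pattern <- match.arg(pattern)
  with_seed(config$seed + 7L, {
    n_expect <- ceiling(duration * rate * 1.5) + 10L
    isi <- switch(pattern,
      poisson = rexp(n_expect, rate),
      regular = rep(1 / rate, n_expect),
      gamma   = rgamma(n_expect, shape = shape, rate = shape * rate))
    tm <- cumsum(isi)
    tm[tm <= duration]
  })
}
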