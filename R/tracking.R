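#' Tracker parameters
#'
#' @param threshold difference-image threshold (0..1 grayscale units); the
#'   user-defined value separating animal from background after background
#'   subtraction.
#' @param sigma Gaussian smoothing sigma in pixels applied to frames and to
#'   the background mean projection.
#' @param jump_limit maximum plausible per-frame displacement in pixels;
#'   candidate blobs whose center is farther than this from the previous
#'   position are excluded.
#' @param min_area minimum blob area in pixels (suppresses single-pixel
#'   noise components).
#' @return an object of class `tracker_params`.
#' @export
tracker_params <- function(threshold = 0.3, sigma = 2, jump_limit = 100,
                           min_area = 5) {
  if (jump_limit <= 0) stop2("jump_limit must be positive")
  if (threshold <= 0) stop2("threshold must be positive")
  structure(list(threshold = threshold, sigma = sigma,
                 jump_limit = jump_limit, min_area = min_area),
            class = "tracker_params")
}

#' Build the background image from mouse-free frames
#'
#' Pixel-wise mean projection of a mouse-free segment (conventionally the
#' 5 to 30 s acquired before the animal is inserted), Gaussian-filtered.
#'
#' @param frames a rows x cols x n array (or a single matrix) of grayscale
#'   frames in 0..1.
#' @param sigma Gaussian filter sigma (px); 0 skips filtering.
#' @return the background image (matrix).
#' @export
build_background <- function(frames, sigma = 2) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (length(dim(frames)) != 3L || dim(frames)[3L] < 1L)
    stop2("need at least one background frame")
  m <- apply(frames, c(1L, 2L), mean)
  if (sigma > 0) m <- as.matrix(EBImage::gblur(m, sigma = sigma))
  m
}

# Candidate blobs of one frame: difference, threshold, connected components.
frame_components <- function(frame, background, params) {
  sm <- if (params$sigma > 0)
    as.matrix(EBImage::gblur(frame, sigma = params$sigma)) else frame
  d <- abs(sm - background)
  mask <- d > params$threshold
  if (!any(mask)) return(NULL)
  lab <- EBImage::bwlabel(mask)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= params$min_area)
  if (!length(keep)) return(NULL)
  cent <- t(vapply(keep, function(k) {
    ij <- which(lab == k, arr.ind = TRUE)
    c(mean(ij[, 2L]), mean(ij[, 1L]))    # (x = col, y = row)
  }, numeric(2L)))
  data.frame(x = cent[, 1L], y = cent[, 2L], area = areas[keep])
}

#' Locate the animal in one frame
#'
#' Computes the absolute difference between the Gaussian-filtered frame and
#' the background, thresholds it, extracts the connected regions of the
#' binary image and takes the largest-area region's centroid as the animal
#' position. A candidate region is excluded if its center is farther than
#' the jump limit from the previous position, outside the arena bounds, or
#' inside an exclusion area. If no acceptable region remains the previous
#' position is returned flagged `"inferred"`; before the first detection the
#' position is undefined.
#'
#' @param frame grayscale frame, same shape as `background`.
#' @param background background image from [build_background()].
#' @param params a [tracker_params()].
#' @param previous previous position `c(x, y)`, or `NULL` at session start
#'   (the jump rule is suspended until the first accepted detection).
#' @param arena optional [arena_geometry()] supplying bounds and exclusion
#'   areas.
#' @return list with `x`, `y` (NA if still undefined) and `valid` of
#'   `"detected"`, `"inferred"` or `"undefined"`.
#' @export
track_frame <- function(frame, background, params = tracker_params(),
                        previous = NULL, arena = NULL) {
  if (!all(dim(frame) == dim(background)))
    stop2("frame and background must have the same shape")
  comp <- frame_components(frame, background, params)
  if (!is.null(comp)) {
    ok <- rep(TRUE, nrow(comp))
    if (!is.null(previous) && !any(is.na(previous))) {
      dist <- sqrt((comp$x - previous[1L])^2 + (comp$y - previous[2L])^2)
      ok <- ok & dist <= params$jump_limit
    }
    if (!is.null(arena)) {
      ok <- ok & point_in_polygon(cbind(comp$x, comp$y), arena$bounds)
      for (ex in arena$exclusions)
        ok <- ok & !point_in_polygon(cbind(comp$x, comp$y), ex)
    }
    comp <- comp[ok, , drop = FALSE]
  }
  if (!is.null(comp) && nrow(comp)) {
    # tie between equal-area largest regions: nearest to the previous position
    best <- which(comp$area == max(comp$area))
    if (length(best) > 1L && !is.null(previous) && !any(is.na(previous))) {
      d2 <- (comp$x[best] - previous[1L])^2 + (comp$y[best] - previous[2L])^2
      best <- best[which.min(d2)]
    } else best <- best[1L]
    return(list(x = comp$x[best], y = comp$y[best], valid = "detected"))
  }
  if (is.null(previous) || any(is.na(previous)))
    return(list(x = NA_real_, y = NA_real_, valid = "undefined"))
  list(x = previous[1L], y = previous[2L], valid = "inferred")
}

#' Track an animal through a frame stack
#'
#' Applies [track_frame()] to every frame in order, threading the previous
#' position through the jump-exclusion rule.
#'
#' @param frames rows x cols x n array of grayscale frames, or a
#'   `synth_video` object (whose background segment is then used to build the
#'   background automatically).
#' @param background background image; computed from the video's background
#'   segment when `frames` is a `synth_video`.
#' @param params a [tracker_params()].
#' @param arena optional [arena_geometry()].
#' @param frame_rate frames per second of the stack.
#' @return a [trajectory()] with one row per (non-background) frame.
#' @export
track_video <- function(frames, background = NULL,
                        params = tracker_params(), arena = NULL,
                        frame_rate = 50) {
  if (inherits(frames, "synth_video")) {
    vid <- frames
    if (is.null(background))
      background <- build_background(
        vid$frames[, , seq_len(vid$n_background), drop = FALSE],
        sigma = params$sigma)
    if (is.null(arena)) arena <- vid$arena
    frame_rate <- vid$frame_rate
    frames <- vid$frames[, , -seq_len(vid$n_background), drop = FALSE]
  }
  if (is.null(background)) stop2("background image required")
  n <- dim(frames)[3L]
  if (is.null(n) || n < 1L) stop2("no frames to track")
  x <- y <- rep(NA_real_, n)
  valid <- character(n)
  prev <- NULL
  for (i in seq_len(n)) {
    r <- track_frame(frames[, , i], background, params, prev, arena)
    x[i] <- r$x; y[i] <- r$y; valid[i] <- r$valid
    if (r$valid != "undefined") prev <- c(r$x, r$y)
  }
  trajectory(seq_len(n) / frame_rate, x, y, valid, frame_rate = frame_rate)
}

#' Zone occupancy, entrances, distance and velocity of a trajectory
#'
#' Time in a zone is the number of frames whose position falls in the zone
#' divided by the frame rate; an entrance is a transition of the zone label
#' into the zone; distance traveled is the sum of consecutive-position
#' Euclidean steps divided by the pixel scale.
#'
#' @param traj a [trajectory()].
#' @param arena an [arena_geometry()] with non-overlapping zones.
#' @return list with `time` (named seconds per zone, plus `.none` for
#'   out-of-zone frames), `entrances` (named counts), `transitions` (data
#'   frame `time, from, to`), `distance_cm` and `mean_velocity_cms`.
#' @export
occupancy_and_entrances <- function(traj, arena) {
  if (!nrow(traj)) stop2("empty trajectory")
  fr <- attr(traj, "frame_rate")
  lab <- zone_label(traj, arena)
  lab[is.na(lab)] <- ".none"
  zones <- c(names(arena$zones), ".none")
  time <- setNames(vapply(zones, function(z) sum(lab == z), 0) / fr, zones)
  chg <- which(lab[-1L] != lab[-length(lab)])
  transitions <- data.frame(time = traj$time[chg + 1L],
                            from = lab[chg], to = lab[chg + 1L],
                            stringsAsFactors = FALSE)
  entrances <- setNames(vapply(zones, function(z)
    sum(transitions$to == z), 0L), zones)
  ok <- !is.na(traj$x)
  steps <- sqrt(diff(traj$x[ok])^2 + diff(traj$y[ok])^2)
  distance_cm <- sum(steps) / arena$px_per_cm
  list(time = time, entrances = entrances, transitions = transitions,
       distance_cm = distance_cm,
       mean_velocity_cms = distance_cm / (nrow(traj) / fr))
}

#' Near-cup interaction time and approaches
#'
#' Interaction is scored while the centroid lies within an annulus of the cup
#' center (cup radius plus a proximity margin).
#'
#' @param traj a [trajectory()].
#' @param arena an [arena_geometry()] with `cups`.
#' @param margin_cm proximity margin beyond the cup radius.
#' @return data frame, one row per cup: `cup`, `time_s`, `approaches`.
#' @export
cup_approaches <- function(traj, arena, margin_cm = 2) {
  if (is.null(arena$cups)) stop2("arena has no cups")
  fr <- attr(traj, "frame_rate")
  out <- lapply(names(arena$cups), function(nm) {
    cup <- arena$cups[[nm]]
    r <- cup$radius_px + margin_cm * arena$px_per_cm
    near <- !is.na(traj$x) &
      sqrt((traj$x - cup$center[1L])^2 + (traj$y - cup$center[2L])^2) <= r
    data.frame(cup = nm, time_s = sum(near) / fr,
               approaches = sum(diff(c(FALSE, near)) == 1L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify arm entries as full or jittery
#'
#' An arm-border crossing that penetrates at least `full_depth_cm` into the
#' arm before returning counts as a full entry; a crossing that enters the
#' arm but never reaches that depth counts as a jittery entry (a
#' stretch-and-retreat operationalized on the tracked centroid).
#'
#' @param traj a [trajectory()].
#' @param arena an [arena_geometry()] whose `arms` describe entrance border
#'   and inward axis per arm (see [arena_epm()]).
#' @param full_depth_cm penetration depth separating full from jittery
#'   entries.
#' @return data frame, one row per arm: `arm`, `class`, `full`, `jittery`.
#' @export
classify_epm_entries <- function(traj, arena, full_depth_cm = 4) {
  if (is.null(arena$arms)) stop2("arena has no arm descriptors")
  lab <- zone_label(traj, arena)
  depth_px <- full_depth_cm * arena$px_per_cm
  out <- lapply(arena$arms, function(arm) {
    inarm <- !is.na(lab) & lab == arm$name
    starts <- which(diff(c(FALSE, inarm)) == 1L)
    ends <- which(diff(c(inarm, FALSE)) == -1L)
    full <- 0L; jittery <- 0L
    for (k in seq_along(starts)) {
      ix <- starts[k]:ends[k]
      depth <- (traj$x[ix] - arm$entrance[1L]) * arm$axis[1L] +
               (traj$y[ix] - arm$entrance[2L]) * arm$axis[2L]
      if (max(depth) >= depth_px) full <- full + 1L else jittery <- jittery + 1L
    }
    data.frame(arm = arm$name, class = arm$class, full = full,
               jittery = jittery, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
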