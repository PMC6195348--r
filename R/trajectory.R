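#' Animal trajectory
#'
#' A per-frame record of tracked positions. Timestamps increase strictly at
#' `1/frame_rate`; frames in which no acceptable blob was found carry the most
#' recent detected position and are flagged `"inferred"`. Frames before the
#' first detection have `NA` positions and the flag `"undefined"`.
#'
#' @param time numeric vector of frame times (s).
#' @param x,y positions in pixels (origin top-left, x rightward, y downward).
#' @param valid character vector, one of `"detected"`, `"inferred"`,
#'   `"undefined"` per frame.
#' @param frame_rate acquisition rate (Hz).
#' @return a data frame of class `trajectory` with attribute `frame_rate`.
#' @export
trajectory <- function(time, x, y, valid = rep("detected", length(time)),
                       frame_rate) {
  n <- length(time)
  if (length(x) != n || length(y) != n || length(valid) != n)
    stop2("time, x, y and valid must have equal length")
  if (n > 1L && any(diff(time) <= 0))
    stop2("trajectory timestamps must be strictly increasing")
  if (!all(valid %in% c("detected", "inferred", "undefined")))
    stop2("valid flags must be 'detected', 'inferred' or 'undefined'")
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    stop2("frame_rate must be positive")
  out <- data.frame(time = as.numeric(time), x = as.numeric(x),
                    y = as.numeric(y), valid = as.character(valid),
                    stringsAsFactors = FALSE)
  attr(out, "frame_rate") <- as.numeric(frame_rate)
  class(out) <- c("trajectory", "data.frame")
  out
}

#' @export
print.trajectory <- function(x, ...) {
  n <- nrow(x)
  cat("Trajectory:", n, "frames at", attr(x, "frame_rate"), "Hz (",
      sum(x$valid == "detected"), "detected,",
      sum(x$valid == "inferred"), "inferred )\n")
  print(utils::head(as.data.frame(x), 4L))
  if (n > 4L) cat("...", n - 4L, "more frames\n")
  invisible(x)
}

#' @export
plot.trajectory <- function(x, arena = NULL, ...) {
  ok <- !is.na(x$x)
  plot(x$x[ok], x$y[ok], type = "l", xlab = "x (px)", ylab = "y (px)",
       ylim = rev(range(x$y[ok])), asp = 1, ...)
  if (!is.null(arena))
    for (p in arena$zones) lines(rbind(p, p[1L, ]), col = "grey60")
  invisible(x)
}

#' Write / read a trajectory as CSV
#'
#' Columns `time, x, y, valid`; the frame rate is stored in a `# frame_rate:`
#' comment header so the file round-trips losslessly.
#'
#' @param traj a [trajectory()].
#' @param path CSV file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns the [trajectory()].
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# frame_rate: ",
                    format(attr(traj, "frame_rate"), digits = 17)), con)
  write.csv(as.data.frame(traj), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  hdr <- readLines(path, n = 1L)
  fr <- as.numeric(sub("# frame_rate: *", "", hdr))
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  trajectory(df$time, df$x, df$y, df$valid, frame_rate = fr)
}
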