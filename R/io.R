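#' Write / read a frame stack as a directory of PNGs
#'
#' Frames are written as numbered 8-bit grayscale PNGs
#' (`frame_000001.png`, ...) with a JSON sidecar (`stack.json`) recording the
#' frame rate and the number of leading background frames. Because the
#' generators quantize frames to 8 bits, the round trip is lossless.
#'
#' @param frames rows x cols x n array in 0..1, or a `synth_video` object.
#' @param dir output directory (created if needed).
#' @param frame_rate,n_background stack metadata; taken from the
#'   `synth_video` when one is given.
#' @return `write_frames` returns `dir` invisibly; `read_frames` returns a
#'   list with `frames`, `frame_rate`, `n_background`.
#' @export
write_frames <- function(frames, dir, frame_rate = 50, n_background = 0L) {
  if (inherits(frames, "synth_video")) {
    frame_rate <- frames$frame_rate
    n_background <- frames$n_background
    frames <- frames$frames
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(frames)[3L]
  for (i in seq_len(n))
    png::writePNG(frames[, , i],
                  file.path(dir, sprintf("frame_%06d.png", i)))
  jsonlite::write_json(list(frame_rate = frame_rate,
                            n_background = as.integer(n_background),
                            n_frames = n),
                       file.path(dir, "stack.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"),
                              simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^frame_[0-9]+\\.png$",
                           full.names = TRUE))
  first <- png::readPNG(files[1L])
  frames <- array(0, c(dim(first)[1L], dim(first)[2L], length(files)))
  frames[, , 1L] <- first
  for (i in seq_along(files)[-1L]) frames[, , i] <- png::readPNG(files[i])
  list(frames = frames, frame_rate = meta$frame_rate,
       n_background = meta$n_background)
}

#' Write / read a grooming log as CSV
#'
#' @param log a grooming-log data frame (`condition, start, end`).
#' @param path CSV file path.
#' @return `write_grooming_log` returns `path` invisibly;
#'   `read_grooming_log` returns the data frame.
#' @export
write_grooming_log <- function(log, path) {
  write.csv(as.data.frame(log)[c("condition", "start", "end")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_grooming_log
#' @export
read_grooming_log <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("grooming_log", "data.frame")
  df
}
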