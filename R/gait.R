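#' Per-paw stride lengths
#'
#' Stride length is the average Euclidean distance between successive
#' placements of the same paw, converted to centimetres with the in-view
#' ruler calibration.
#'
#' @param placements data frame with columns `paw` (LF/RF/LH/RH), `step`,
#'   `x`, `y` (px), e.g. from [synth_paw_placements()] or
#'   [read_paw_placements()].
#' @param px_per_cm pixel scale; default taken from the `px_per_cm`
#'   attribute of `placements`.
#' @return named numeric vector of mean stride (cm) per paw; paws with fewer
#'   than two placements are `NA`.
#' @export
stride_lengths <- function(placements, px_per_cm = attr(placements, "px_per_cm")) {
  if (is.null(px_per_cm) || px_per_cm <= 0) stop2("px_per_cm must be positive")
  paws <- c("LF", "RF", "LH", "RH")
  out <- setNames(rep(NA_real_, 4L), paws)
  for (p in paws) {
    sub <- placements[placements$paw == p, ]
    sub <- sub[order(sub$step), ]
    if (nrow(sub) >= 2L)
      out[p] <- mean(sqrt(diff(sub$x)^2 + diff(sub$y)^2)) / px_per_cm
  }
  out
}

#' Fore and hind stance widths
#'
#' The locomotion direction is taken as the principal axis of all
#' placements; stance is the mean distance between step-paired left and
#' right placements of the same girdle, projected perpendicular to that
#' axis, in centimetres. When the left and right paws have unequal placement
#' counts they are paired by step index after trimming to the common length
#' and the result is flagged.
#'
#' @inheritParams stride_lengths
#' @return named numeric vector `c(fore, hind)` (cm) with attribute
#'   `trimmed` naming girdles whose placements needed trimming.
#' @export
stances <- function(placements, px_per_cm = attr(placements, "px_per_cm")) {
  if (is.null(px_per_cm) || px_per_cm <= 0) stop2("px_per_cm must be positive")
  xy <- cbind(placements$x, placements$y)
  # principal axis of travel; its perpendicular carries the stance width
  ev <- eigen(cov(xy), symmetric = TRUE)
  perp <- ev$vectors[, 2L]
  girdle <- function(left, right) {
    l <- placements[placements$paw == left, ]; l <- l[order(l$step), ]
    r <- placements[placements$paw == right, ]; r <- r[order(r$step), ]
    if (!nrow(l) || !nrow(r)) return(list(value = NA_real_, trimmed = FALSE))
    n <- min(nrow(l), nrow(r))
    d <- cbind(l$x[seq_len(n)] - r$x[seq_len(n)],
               l$y[seq_len(n)] - r$y[seq_len(n)])
    list(value = mean(abs(d %*% perp)) / px_per_cm,
         trimmed = nrow(l) != nrow(r))
  }
  fore <- girdle("LF", "RF"); hind <- girdle("LH", "RH")
  out <- c(fore = fore$value, hind = hind$value)
  attr(out, "trimmed") <- c("fore", "hind")[c(fore$trimmed, hind$trimmed)]
  out
}

#' Write / read paw placements as CSV
#'
#' Columns `paw, step, x, y`; the pixel scale is stored in a `# px_per_cm:`
#' comment header.
#'
#' @param placements a paw-placement data frame.
#' @param path CSV file path.
#' @return `write_paw_placements` returns `path` invisibly;
#'   `read_paw_placements` returns the data frame with its `px_per_cm`
#'   attribute.
#' @export
write_paw_placements <- function(placements, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# px_per_cm: ",
                    format(attr(placements, "px_per_cm"), digits = 17)), con)
  write.csv(placements[c("paw", "step", "x", "y")], con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_paw_placements
#' @export
read_paw_placements <- function(path) {
  hdr <- readLines(path, n = 1L)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  attr(df, "px_per_cm") <- as.numeric(sub("# px_per_cm: *", "", hdr))
  class(df) <- c("paw_placements", "data.frame")
  df
}
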