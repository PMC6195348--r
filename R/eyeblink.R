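#' Eyeblink conditioning session
#'
#' Eyelid-position traces segmented into trials. Trial types are `"paired"`
#' (CS followed by a co-terminating US), `"cs_only"` (probe trials) and
#' `"us_only"` (reflex-only trials used to calibrate full eye closure).
#' Paired and CS-only trials must carry a CS onset; US-only trials must not.
#'
#' @param trials data frame with columns `trial`, `type`, `cs_onset` (s from
#'   trial start; `NA` for US-only trials).
#' @param traces numeric matrix, one row per trial, of eyelid positions
#'   (sensor units, voltage-proportional).
#' @param sample_rate sampling rate, Hz.
#' @return an object of class `eyeblink_session`.
#' @export
eyeblink_session <- function(trials, traces, sample_rate) {
  if (!all(c("trial", "type", "cs_onset") %in% names(trials)))
    stop2("trials needs columns trial, type, cs_onset")
  if (!all(trials$type %in% c("paired", "cs_only", "us_only")))
    stop2("trial types must be paired, cs_only or us_only")
  if (nrow(trials) != nrow(traces))
    stop2("one trace row per trial required")
  counted <- trials$type != "us_only"
  if (any(is.na(trials$cs_onset[counted])))
    stop2("paired and CS-only trials must have a CS onset")
  if (any(!is.na(trials$cs_onset[!counted])))
    stop2("US-only trials must not have a CS onset")
  structure(list(trials = trials, traces = as.matrix(traces),
                 sample_rate = sample_rate, normalized = FALSE),
            class = "eyeblink_session")
}

#' @export
print.eyeblink_session <- function(x, ...) {
  cat("Eyeblink session:", nrow(x$trials), "trials (",
      sum(x$trials$type == "paired"), "paired,",
      sum(x$trials$type == "cs_only"), "CS-only,",
      sum(x$trials$type == "us_only"), "US-only ) at", x$sample_rate, "Hz",
      if (x$normalized) "[normalized]" else "[raw]", "\n")
  invisible(x)
}

trial_baseline <- function(session, i, window = 0.2) {
  tr <- session$traces[i, ]
  cs <- session$trials$cs_onset[i]
  sr <- session$sample_rate
  tt <- (seq_along(tr) - 1L) / sr
  ix <- if (is.na(cs)) tt < window else tt >= cs - window & tt < cs
  if (!any(ix)) ix <- seq_len(max(1L, round(window * sr)))
  mean(tr[ix])
}

#' Normalize eyelid traces to fraction-of-full-UR units
#'
#' The full range of eyelid closure is calibrated from the US-only trials:
#' the mean, over US-only trials, of the peak deflection above the pre-trial
#' baseline. Every trace is then rescaled so its own baseline maps to 0 and
#' full closure to 1. Baseline is the mean of the 200 ms preceding the CS
#' (or the first 200 ms of the trial for US-only trials).
#'
#' @param session an [eyeblink_session()] with raw traces.
#' @param baseline_window baseline window length (s).
#' @return the session with normalized traces and a `full_range` element.
#' @export
normalize_session <- function(session, baseline_window = 0.2) {
  us <- which(session$trials$type == "us_only")
  if (!length(us)) stop2("no US-only trials: cannot calibrate full closure")
  base <- vapply(seq_len(nrow(session$trials)), trial_baseline,
                 numeric(1L), session = session, window = baseline_window)
  peaks <- vapply(us, function(i) max(session$traces[i, ]) - base[i],
                  numeric(1L))
  full <- mean(peaks)
  if (full <= 0) stop2("calibrated full range is not positive")
  session$traces <- (session$traces - base) / full
  session$full_range <- full
  session$normalized <- TRUE
  session
}

#' Detect a conditioned response in one normalized trial
#'
#' A trial is scored as a CR when the normalized eyelid trace exceeds the
#' threshold (default 0.15, i.e. 15% of the full range of the UR) anywhere in
#' the detection window, by default 100 to 280 ms after CS onset. The window
#' is half-open: samples at exactly CS+100 ms are outside, at CS+280 ms
#' inside.
#'
#' @param trace normalized eyelid trace (fraction-of-full-UR units).
#' @param cs_onset CS onset time (s from trial start).
#' @param sample_rate sampling rate, Hz.
#' @param threshold CR amplitude criterion.
#' @param window detection window `c(lo, hi)` in s after CS onset.
#' @return logical: CR detected.
#' @export
detect_cr <- function(trace, cs_onset, sample_rate, threshold = 0.15,
                      window = c(0.1, 0.28)) {
  tt <- (seq_along(trace) - 1L) / sample_rate
  if (cs_onset + window[2L] > tt[length(tt)] + 1e-9)
    stop2("detection window extends beyond the recorded trace")
  ix <- tt > cs_onset + window[1L] & tt <= cs_onset + window[2L] + 1e-12
  max(trace[ix]) > threshold
}

#' Score every counted trial of a session
#'
#' Normalizes the session if needed, then applies [detect_cr()] to every
#' paired and CS-only trial.
#'
#' @param session an [eyeblink_session()].
#' @param threshold,window CR criterion, see [detect_cr()].
#' @return data frame `trial, type, cr` over counted trials.
#' @export
score_session <- function(session, threshold = 0.15, window = c(0.1, 0.28)) {
  if (!session$normalized) session <- normalize_session(session)
  counted <- which(session$trials$type != "us_only")
  cr <- vapply(counted, function(i)
    detect_cr(session$traces[i, ], session$trials$cs_onset[i],
              session$sample_rate, threshold, window), logical(1L))
  data.frame(trial = session$trials$trial[counted],
             type = session$trials$type[counted], cr = cr,
             stringsAsFactors = FALSE)
}

#' CR response probability of a session
#'
#' The fraction of counted CRs over the total number of counted trials
#' (paired plus CS-only; US-only trials are calibration, not counted).
#'
#' @param x an [eyeblink_session()] or the data frame from [score_session()].
#' @param ... passed to [score_session()] when `x` is a session.
#' @return fraction in 0..1.
#' @export
response_probability <- function(x, ...) {
  scores <- if (inherits(x, "eyeblink_session")) score_session(x, ...) else x
  if (!nrow(scores)) stop2("no counted trials")
  mean(scores$cr)
}

#' Firing frequency and CV2 of a spike train
#'
#' Firing frequency is `(N - 1) / (t_N - t_1)`. CV2 is the local coefficient
#' of variation over adjacent interspike intervals,
#' `mean( 2 |ISI[i+1] - ISI[i]| / (ISI[i+1] + ISI[i]) )`: 0 for perfectly
#' regular firing, near 1 for Poisson firing, always below 2.
#'
#' @param times strictly increasing spike times (s).
#' @return list with `ff` (Hz; `NA` with fewer than 2 spikes) and `cv2`
#'   (`NA` with fewer than 3 spikes).
#' @export
spike_summaries <- function(times) {
  if (length(times) > 1L && any(diff(times) <= 0))
    stop2("spike times must be strictly increasing")
  ff <- if (length(times) < 2L) NA_real_ else
    (length(times) - 1L) / (times[length(times)] - times[1L])
  cv2 <- NA_real_
  if (length(times) >= 3L) {
    isi <- diff(times)
    cv2 <- mean(2 * abs(diff(isi)) / (isi[-length(isi)] + isi[-1L]))
  }
  list(ff = ff, cv2 = cv2)
}

#' Write / read an eyeblink session as CSV
#'
#' Wide format: columns `trial, type, cs_onset, sample_rate` followed by one
#' column per trace sample (`s1 ... sN`).
#'
#' @param session an [eyeblink_session()].
#' @param path CSV file path.
#' @return `write_eyeblink_session` returns `path` invisibly;
#'   `read_eyeblink_session` returns the [eyeblink_session()].
#' @export
write_eyeblink_session <- function(session, path) {
  df <- cbind(session$trials,
              sample_rate = session$sample_rate,
              as.data.frame(session$traces,
                            col.names = paste0("s", seq_len(ncol(session$traces)))))
  names(df)[-(1:4)] <- paste0("s", seq_len(ncol(session$traces)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eyeblink_session
#' @export
read_eyeblink_session <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  scol <- grep("^s[0-9]+$", names(df))
  eyeblink_session(df[c("trial", "type", "cs_onset")],
                   as.matrix(df[scol]), sample_rate = df$sample_rate[1L])
}

#' Write / read a spike train as one-column CSV
#'
#' @param times spike times (s).
#' @param path CSV file path.
#' @return `write_spike_train` returns `path` invisibly; `read_spike_train`
#'   returns the numeric vector.
#' @export
write_spike_train <- function(times, path) {
  write.csv(data.frame(time = times), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_train
#' @export
read_spike_train <- function(path) read.csv(path)$time
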