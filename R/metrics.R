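#' Mice-by-metrics table
#'
#' A data frame with one row per mouse, a `mouse` identifier column, a
#' `group` label column, and one numeric column per behavioral metric.
#' Missing observations (e.g. mice without eyeblink data) are `NA` and
#' propagate through downstream statistics as pairwise-complete.
#'
#' @param df data frame with columns `mouse`, `group` and the metric columns.
#' @param metrics character vector of metric column names; default: all
#'   columns except `mouse` and `group`. Names must be unique.
#' @return `df` with class `metric_matrix` and attribute `metrics`.
#' @export
metric_matrix <- function(df, metrics = setdiff(names(df),
                                                c("mouse", "group"))) {
  if (!all(c("mouse", "group") %in% names(df)))
    stop2("metric matrix needs 'mouse' and 'group' columns")
  if (anyDuplicated(metrics)) stop2("metric names must be unique")
  missing_cols <- setdiff(metrics, names(df))
  if (length(missing_cols))
    stop2("missing metric columns: ", paste(missing_cols, collapse = ", "))
  for (m in metrics) df[[m]] <- as.numeric(df[[m]])
  attr(df, "metrics") <- metrics
  class(df) <- c("metric_matrix", "data.frame")
  df
}

#' @export
print.metric_matrix <- function(x, ...) {
  cat("Metric matrix:", nrow(x), "mice x", length(attr(x, "metrics")),
      "metrics;", sum(is.na(as.matrix(x[attr(x, "metrics")]))),
      "missing cells\n")
  cat("  groups:", paste(unique(x$group), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a metric matrix as tidy CSV
#'
#' Long format with columns `mouse, group, metric, value` (missing cells
#' written as empty values).
#'
#' @param m a [metric_matrix()].
#' @param path CSV file path.
#' @return `write_metric_matrix` returns `path` invisibly;
#'   `read_metric_matrix` returns the [metric_matrix()].
#' @export
write_metric_matrix <- function(m, path) {
  metrics <- attr(m, "metrics")
  long <- do.call(rbind, lapply(metrics, function(mm)
    data.frame(mouse = m$mouse, group = m$group, metric = mm,
               value = m[[mm]], stringsAsFactors = FALSE)))
  write.csv(long, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_metric_matrix
#' @export
read_metric_matrix <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  metrics <- unique(long$metric)
  mice <- unique(long[c("mouse", "group")])
  wide <- mice
  for (mm in metrics) {
    sub <- long[long$metric == mm, ]
    wide[[mm]] <- sub$value[match(wide$mouse, sub$mouse)]
  }
  metric_matrix(wide, metrics)
}

#' Filter grooming events and summarize bouts
#'
#' Events shorter than `min_dur` are excluded (strictly shorter: a bout of
#' exactly one second survives the default filter). Summaries are computed on
#' the surviving events, per condition: cumulative grooming time, event
#' count, mean bout length, and mean gap between consecutive events.
#'
#' @param log data frame with columns `start`, `end` (s) and optionally
#'   `condition`; events must be non-overlapping within a condition and have
#'   `end > start`.
#' @param min_dur minimum bout duration retained (s).
#' @return list with `log` (the surviving events) and `summary` (data frame
#'   `condition, cumulative_s, n_events, mean_bout_s, mean_gap_s`; empty
#'   conditions yield zero counts and `NA` means).
#' @export
filter_grooming <- function(log, min_dur = 1.0) {
  if (!all(c("start", "end") %in% names(log)))
    stop2("grooming log needs 'start' and 'end' columns")
  if (is.null(log$condition))
    log$condition <- rep("all", nrow(log))
  if (nrow(log)) {
    if (any(log$end <= log$start)) stop2("grooming events must have end > start")
    for (cond in unique(log$condition)) {
      sub <- log[log$condition == cond, ]
      sub <- sub[order(sub$start), ]
      if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)]))
        stop2("grooming events overlap within condition '", cond, "'")
    }
  }
  keep <- log[(log$end - log$start) >= min_dur, , drop = FALSE]
  conds <- if (nrow(log)) unique(log$condition) else "all"
  summ <- do.call(rbind, lapply(conds, function(cond) {
    sub <- keep[keep$condition == cond, , drop = FALSE]
    sub <- sub[order(sub$start), ]
    dur <- sub$end - sub$start
    gaps <- if (nrow(sub) > 1L) sub$start[-1L] - sub$end[-nrow(sub)] else
      numeric(0)
    data.frame(condition = cond, cumulative_s = sum(dur),
               n_events = nrow(sub),
               mean_bout_s = if (nrow(sub)) mean(dur) else NA_real_,
               mean_gap_s = if (length(gaps)) mean(gaps) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(log = keep, summary = summ)
}

#' Grooming ratio
#'
#' Difference between the average grooming bout length under CNO and under
#' saline, relative to the saline condition:
#' `(AVGsaline - AVGcno) / AVGsaline`.
#'
#' @param avg_saline,avg_cno mean bout lengths (s) in the two conditions.
#' @return the ratio, or `NA` (flagged missing) when `avg_saline` is zero or
#'   missing.
#' @export
grooming_ratio <- function(avg_saline, avg_cno) {
  if (is.na(avg_saline) || is.na(avg_cno) || avg_saline <= 0)
    return(NA_real_)
  (avg_saline - avg_cno) / avg_saline
}

# least-squares slope of y over sessions 1..length(y)
session_slope <- function(y) {
  x <- seq_along(y)
  unname(coef(lm(y ~ x))[2L])
}

#' Y-maze learning metrics from per-session percent-correct scores
#'
#' Computes the nine Y-maze metrics from the acquisition day, reversal day 1
#' and reversal day 2 session scores plus the habituation swim distances:
#' initial learning (= session 1), final learning (mean of sessions 3 and 4),
#' multisession learning (least-squares slope over sessions 1-3), the three
#' analogues for reversal day 1, final reversal 2 (mean of all four
#' sessions), initial reversal 2 (= session 1), and total habituation
#' distance. Missing sessions flag the affected metrics as `NA`.
#'
#' @param acq,rd1,rd2 numeric length-4 vectors of percent-correct scores
#'   (0..100) for the four sessions of each scored day.
#' @param hab_dist numeric length-3 vector of habituation swim distances (m).
#' @return named numeric vector of the nine `YM_` metrics.
#' @export
ymaze_metrics <- function(acq, rd1, rd2, hab_dist = rep(NA_real_, 3)) {
  chk <- function(v, n, what) {
    if (length(v) != n) stop2(what, " needs ", n, " values")
    if (any(!is.na(v) & (v < 0 | v > 100)) && what != "hab_dist")
      stop2(what, " percent-correct scores must lie in [0, 100]")
    v
  }
  acq <- chk(acq, 4L, "acq"); rd1 <- chk(rd1, 4L, "rd1")
  rd2 <- chk(rd2, 4L, "rd2")
  if (length(hab_dist) != 3L) stop2("hab_dist needs 3 values")
  mean_or_na <- function(v) if (any(is.na(v))) NA_real_ else mean(v)
  slope_or_na <- function(v) if (any(is.na(v))) NA_real_ else session_slope(v)
  first_or_na <- function(v) v[1L]
  c("YM_Final Learning" = mean_or_na(acq[3:4]),
    "YM_Initial Learning" = first_or_na(acq),
    "YM_Multisession Learning" = slope_or_na(acq[1:3]),
    "YM_Distance" = if (any(is.na(hab_dist))) NA_real_ else sum(hab_dist),
    "YM_Final Reversal 1" = mean_or_na(rd1[3:4]),
    "YM_Initial Reversal 1" = first_or_na(rd1),
    "YM_Multisession Reversal 1" = slope_or_na(rd1[1:3]),
    "YM_Final Reversal 2" = mean_or_na(rd2),
    "YM_Initial Reversal 2" = first_or_na(rd2))
}

#' Social chamber metrics
#'
#' Social preference is the time interacting with the novel mouse relative
#' to total interaction time with mouse or object,
#' `TimeNearM / (TimeNearM + TimeNearO)`. Novelty-seeking is the drop in
#' summed chamber entrances from baseline to test, relative to baseline:
#' `((EntrMbs + EntrObs) - (EntrMtest + EntrOtest)) / (EntrMbs + EntrObs)`.
#' The printed sign convention is kept (larger values mean a bigger drop in
#' entrances during the test phase); `negate_novelty` flips it.
#'
#' @param time_near_m,time_near_o interaction times (s) near the mouse and
#'   object cups during the test phase.
#' @param entr_m_bs,entr_o_bs entrances into the (future) mouse and object
#'   chambers during the baseline phase.
#' @param entr_m_test,entr_o_test the same during the test phase.
#' @param bs_distance_m,test_distance_m distance traveled (m) in each phase.
#' @param negate_novelty flip the sign of novelty-seeking.
#' @return named numeric vector of the four `SC_` metrics; ratios with zero
#'   denominators are `NA`.
#' @export
social_metrics <- function(time_near_m, time_near_o, entr_m_bs, entr_o_bs,
                           entr_m_test, entr_o_test, bs_distance_m,
                           test_distance_m, negate_novelty = FALSE) {
  tot_near <- time_near_m + time_near_o
  pref <- if (is.na(tot_near) || tot_near == 0) NA_real_ else
    time_near_m / tot_near
  bs <- entr_m_bs + entr_o_bs
  novel <- if (is.na(bs) || bs == 0) NA_real_ else
    (bs - (entr_m_test + entr_o_test)) / bs
  if (negate_novelty && !is.na(novel)) novel <- -novel
  c("SC_Baseline Distance" = as.numeric(bs_distance_m),
    "SC_Novelty-Seeking" = novel,
    "SC_Social Preference" = pref,
    "SC_Test Distance" = as.numeric(test_distance_m))
}

#' Elevated plus-maze metrics
#'
#' Commitment is the fraction of open-arm entries that are full entries,
#' `EntrOfull / (EntrOfull + EntrOjitter)`; open-arm preference is
#' `Timeopen / (Timeclosed + Timeopen)`; exploration time and entrances are
#' the time spent in, and entrances into, the central crossroads area.
#'
#' @param time_open,time_closed,time_central zone occupancy times (s).
#' @param entr_central entrances into the central area.
#' @param entr_o_full,entr_o_jitter full and jittery open-arm entries
#'   (see [classify_epm_entries()]).
#' @param distance_cm distance traveled in the 10-min session (cm).
#' @return named numeric vector of the five `EPM_` metrics; ratios with zero
#'   denominators are `NA`.
#' @export
epm_metrics <- function(time_open, time_closed, time_central, entr_central,
                        entr_o_full, entr_o_jitter, distance_cm) {
  entr <- entr_o_full + entr_o_jitter
  commitment <- if (is.na(entr) || entr == 0) NA_real_ else
    entr_o_full / entr
  tot <- time_open + time_closed
  open_pref <- if (is.na(tot) || tot == 0) NA_real_ else time_open / tot
  c("EPM_Commitment" = commitment,
    "EPM_Distance" = as.numeric(distance_cm),
    "EPM_Exploration Entrances" = as.numeric(entr_central),
    "EPM_Exploration Time" = as.numeric(time_central),
    "EPM_Open-Arm Preference" = open_pref)
}

#' First-choice arm from a Y-maze trajectory
#'
#' Auxiliary scorer: the first non-start arm whose zone the centroid enters.
#'
#' @param traj a [trajectory()].
#' @param arena a Y-maze [arena_geometry()] (see [arena_ymaze()]).
#' @param start_arm name of the arm the trial starts from.
#' @return the arm name, or `NA` if no other arm is entered.
#' @export
ymaze_first_choice <- function(traj, arena, start_arm = "arm_start") {
  lab <- zone_label(traj, arena)
  arms <- setdiff(vapply(arena$arms, `[[`, "", "name"), start_arm)
  hit <- lab[!is.na(lab) & lab %in% arms]
  if (!length(hit)) NA_character_ else hit[1L]
}
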