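#' Linearly interpolate short artifact gaps
#'
#' Blink and artifact samples arrive pre-marked as missing (`NA`). Runs of
#' missing samples no longer than `max_gap` milliseconds that have a valid
#' sample on both sides are filled by linear interpolation between those
#' anchors. Longer gaps, and gaps touching a trial edge, are left missing, so
#' that the trial-matrix stage later drops the whole trial (the strict
#' omission rule). Non-missing samples are never altered.
#'
#' @param rec a [pupil_recording].
#' @param max_gap maximum gap duration to fill, in ms (number of missing
#'   samples times the sampling interval). Default 500 ms.
#' @return the recording with short gaps filled; a per-trial interpolation
#'   report (`subject`, `trial`, `n_missing`, `n_filled`, `frac_filled`) is
#'   attached as attribute `"interp_report"`.
#' @export
interpolate_gaps <- function(rec, max_gap = 500) {
  stopifnot(inherits(rec, "pupil_recording"))
  if (!is.numeric(max_gap) || max_gap <= 0) stop("max_gap must be > 0",
                                                 call. = FALSE)
  tid <- trial_id(rec)
  sel_list <- split(seq_len(nrow(rec)), factor(tid, levels = unique(tid)))
  ids <- names(sel_list)
  pupil <- rec$pupil
  rep_rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sel <- sel_list[[i]]
    y <- pupil[sel]
    tt <- rec$time[sel]
    n_missing <- sum(is.na(y))
    n_filled <- 0L
    if (n_missing > 0L && length(y) > 1L) {
      dt <- tt[2L] - tt[1L]
      r <- rle(is.na(y))
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in which(r$values)) {
        a <- starts[j] - 1L
        b <- ends[j] + 1L
        if (a < 1L || b > length(y)) next            # edge gap: leave missing
        if (r$lengths[j] * dt > max_gap) next        # too long: leave missing
        idx <- starts[j]:ends[j]
        y[idx] <- y[a] + (y[b] - y[a]) * (tt[idx] - tt[a]) / (tt[b] - tt[a])
        n_filled <- n_filled + length(idx)
      }
      pupil[sel] <- y
    }
    rep_rows[[i]] <- data.frame(subject = rec$subject[sel[1L]],
                                trial = rec$trial[sel[1L]],
                                n_missing = n_missing, n_filled = n_filled,
                                frac_filled = n_filled / length(y),
                                stringsAsFactors = FALSE)
  }
  out <- rec
  out$pupil <- pupil
  out <- restore_recording(out, rec)
  attr(out, "interp_report") <- do.call(rbind, rep_rows)
  out
}

#' Z-score pupil size within groups
#'
#' Standardizes pupil size so traces are comparable across subjects: within
#' each group (by default one group per subject, over the subject's whole
#' session) the pupil values are centered on the group mean and divided by the
#' group sample standard deviation (denominator n - 1). Missing samples stay
#' missing and do not contribute to the moments.
#'
#' @param rec a [pupil_recording].
#' @param grouping grouping variable for the standardization; only
#'   `"subject"` (the default) or `"trial"` are supported.
#' @return the recording with `pupil` replaced by its within-group z-score.
#' @export
zscore_pupil <- function(rec, grouping = c("subject", "trial")) {
  stopifnot(inherits(rec, "pupil_recording"))
  grouping <- match.arg(grouping)
  g <- if (grouping == "subject") rec$subject else trial_id(rec)
  pupil <- rec$pupil
  for (gi in unique(g)) {
    sel <- which(g == gi)
    y <- pupil[sel]
    ok <- !is.na(y)
    if (sum(ok) < 2L)
      stop("group '", sub("\r", "/", gi),
           "' has fewer than 2 non-missing samples", call. = FALSE)
    s <- stats::sd(y[ok])
    if (!is.finite(s) || s == 0)
      stop("group '", sub("\r", "/", gi), "' has zero spread; cannot z-score",
           call. = FALSE)
    pupil[sel] <- (y - mean(y[ok])) / s
  }
  out <- rec
  out$pupil <- pupil
  restore_recording(out, rec)
}

#' Baseline-correct each trial
#'
#' Subtracts from every sample of a trial the trial's average pupil size in a
#' window around target onset, so phasic changes are measured relative to the
#' trial's starting state. The default is a 500-ms window centered on target
#' onset, i.e. \eqn{[-250, +250)} ms. Trials without any non-missing sample in
#' the window cannot be corrected; they are dropped with a warning and listed
#' in the attached report.
#'
#' @param rec a [pupil_recording].
#' @param window numeric length-2, `(start, end)` in ms; samples with
#'   `start <= time < end` form the baseline. Default `c(-250, 250)`.
#' @param stat `"mean"` (default) or `"median"` baseline statistic.
#' @return the corrected recording, with attribute `"baseline_dropped"`
#'   listing any dropped trials.
#' @export
baseline_correct <- function(rec, window = c(-250, 250),
                             stat = c("mean", "median")) {
  stopifnot(inherits(rec, "pupil_recording"))
  stat <- match.arg(stat)
  if (length(window) != 2L || !(window[1L] < window[2L]))
    stop("window must be (start, end) with start < end", call. = FALSE)
  f <- if (stat == "mean") mean else stats::median
  tid <- trial_id(rec)
  sel_list <- split(seq_len(nrow(rec)), factor(tid, levels = unique(tid)))
  pupil <- rec$pupil
  drop_ids <- character()
  for (id in names(sel_list)) {
    sel <- sel_list[[id]]
    inwin <- rec$time[sel] >= window[1L] & rec$time[sel] < window[2L]
    base <- pupil[sel][inwin]
    base <- base[!is.na(base)]
    if (!length(base)) {
      drop_ids <- c(drop_ids, id)
      next
    }
    pupil[sel] <- pupil[sel] - f(base)
  }
  out <- rec
  out$pupil <- pupil
  if (length(drop_ids)) {
    warning(length(drop_ids),
            " trial(s) had no baseline samples and were dropped",
            call. = FALSE)
    out <- out[!(tid %in% drop_ids), , drop = FALSE]
  }
  out <- restore_recording(out, rec)
  attr(out, "baseline_dropped") <- sub("\r", "/", drop_ids)
  out
}

#' Restrict a recording to the post-onset epoch
#'
#' Keeps samples in the half-open interval `t_start <= time < t_end`. The
#' half-open convention makes sample counts unambiguous: an epoch of
#' \eqn{[0, 4500)} ms at 100 Hz holds exactly 450 samples per trial. Only
#' post-onset epochs should feed the reduction stage, since pre-onset,
#' baseline-corrected samples can have (near-)zero variance.
#'
#' @param rec a [pupil_recording].
#' @param t_start,t_end epoch bounds in ms; `t_start < t_end`.
#' @return the epoched recording; trials left empty are dropped with a
#'   warning.
#' @export
epoch_trials <- function(rec, t_start = 0, t_end = 4500) {
  stopifnot(inherits(rec, "pupil_recording"))
  if (!(t_start < t_end)) stop("t_start must be < t_end", call. = FALSE)
  keep <- rec$time >= t_start & rec$time < t_end
  if (!any(keep)) stop("epoch leaves no samples in any trial", call. = FALSE)
  before <- unique(trial_id(rec))
  out <- rec[keep, , drop = FALSE]
  out <- restore_recording(out, rec)
  after <- unique(trial_id(out))
  lost <- setdiff(before, after)
  if (length(lost))
    warning(length(lost), " trial(s) had no samples inside the epoch and were dropped",
            call. = FALSE)
  out
}
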