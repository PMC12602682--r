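#' Build the trials-by-timepoints matrix
#'
#' Reshapes an epoched, preprocessed recording into the wide matrix that the
#' reduction stage consumes: one row per trial, one column per timepoint of
#' the common grid, so that each timepoint acts as a standalone variable.
#' Trials containing any missing sample are omitted entirely (the strict
#' omission rule); short gaps should have been interpolated beforehand if the
#' trials are to be kept.
#'
#' @param rec an epoched [pupil_recording]; all trials must share an
#'   identical time grid.
#' @return a `trial_matrix`: list with `values` (trials x timepoints numeric
#'   matrix, no missing cells), `row_meta` (data frame with `subject`,
#'   `trial` and the condition columns, one row per kept trial), `col_times`
#'   (ms per column) and `dropped` (count of omitted incomplete trials).
#' @export
to_trial_matrix <- function(rec) {
  stopifnot(inherits(rec, "pupil_recording"))
  tid <- trial_id(rec)
  sel_list <- split(seq_len(nrow(rec)), factor(tid, levels = unique(tid)))
  ids <- names(sel_list)
  grid <- rec$time[sel_list[[1L]]]
  cond <- conditions(rec)

  rows <- vector("list", length(ids))
  meta <- vector("list", length(ids))
  complete <- logical(length(ids))
  for (i in seq_along(ids)) {
    sel <- sel_list[[i]]
    tt <- rec$time[sel]
    if (length(tt) != length(grid) || any(abs(tt - grid) > 1e-6))
      stop("inconsistent time grid across trials (trial ",
           sub("\r", "/", ids[i]), ")", call. = FALSE)
    y <- rec$pupil[sel]
    complete[i] <- !anyNA(y)
    rows[[i]] <- y
    m <- data.frame(subject = rec$subject[sel[1L]], trial = rec$trial[sel[1L]],
                    stringsAsFactors = FALSE)
    for (cn in cond) m[[cn]] <- rec[[cn]][sel[1L]]
    meta[[i]] <- m
  }
  n_dropped <- sum(!complete)
  if (sum(complete) < 2L)
    stop("fewer than 2 complete trials after applying the omission rule",
         call. = FALSE)
  values <- do.call(rbind, rows[complete])
  colnames(values) <- paste0("t", grid)
  row_meta <- do.call(rbind, meta[complete])
  rownames(row_meta) <- NULL

  structure(list(values = values, row_meta = row_meta, col_times = grid,
                 dropped = n_dropped),
            class = "trial_matrix")
}

#' @export
print.trial_matrix <- function(x, ...) {
  cat("<trial_matrix> ", nrow(x$values), " trials x ", ncol(x$values),
      " timepoints (", x$col_times[1L], "..",
      x$col_times[length(x$col_times)], " ms); ",
      x$dropped, " incomplete trial(s) omitted\n", sep = "")
  invisible(x)
}

# structural checks shared by tests and downstream stages
check_trial_matrix <- function(tm) {
  stopifnot(inherits(tm, "trial_matrix"))
  v <- tm$values
  if (anyNA(v)) stop("trial matrix contains missing cells", call. = FALSE)
  if (nrow(v) < 2L || ncol(v) < 2L)
    stop("trial matrix needs at least 2 rows and 2 columns", call. = FALSE)
  if (any(diff(tm$col_times) <= 0))
    stop("col_times must be strictly increasing", call. = FALSE)
  if (nrow(tm$row_meta) != nrow(v))
    stop("row metadata does not align with the matrix", call. = FALSE)
  invisible(TRUE)
}
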