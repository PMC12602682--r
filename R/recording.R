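#' Pupillometry recordings in long format
#'
#' A `pupil_recording` is a plain data frame in long format -- one row per
#' sample -- with the canonical columns `subject`, `trial`, `time` and
#' `pupil`, plus zero or more per-trial condition columns (for instance a
#' luminance level). `time` is expressed in milliseconds relative to target
#' onset: 0 marks the onset, negative values the baseline period. Missing
#' pupil samples (blinks, artifacts marked upstream) are encoded as `NA`,
#' never as sentinel numbers.
#'
#' The constructor validates the structural invariants that the rest of the
#' pipeline relies on:
#' \itemize{
#'   \item `(subject, trial, time)` triples are unique;
#'   \item within every trial, `time` is strictly increasing and evenly
#'     spaced (constant sampling interval, tolerance `1e-6` ms);
#'   \item condition values are constant within a trial.
#' }
#'
#' @param data data frame holding the long-format samples.
#' @param conditions character vector naming per-trial condition columns
#'   present in `data` (may be empty).
#' @return A `pupil_recording`: the validated data frame, ordered by subject,
#'   trial and time, carrying the condition names as an attribute.
#' @export
pupil_recording <- function(data, conditions = character()) {
  stopifnot(is.data.frame(data))
  needed <- c("subject", "trial", "time", "pupil")
  missing_cols <- setdiff(c(needed, conditions), names(data))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(data) == 0L)
    stop("recording has no samples", call. = FALSE)

  data <- as.data.frame(data)[, c(needed, conditions), drop = FALSE]
  data$subject <- as.character(data$subject)
  data$trial <- as.character(data$trial)
  data$time <- as.numeric(data$time)
  data$pupil <- as.numeric(data$pupil)
  data <- data[order(data$subject, data$trial, data$time), , drop = FALSE]
  rownames(data) <- NULL

  tid <- trial_id(data)
  n <- nrow(data)
  if (n > 1L) {
    same <- tid[-1L] == tid[-n]                 # adjacent rows, same trial
    dts <- diff(data$time)[same]
    if (any(dts <= 0)) {
      bad <- tid[-1L][same][which(dts <= 0)[1L]]
      stop(if (any(dts[tid[-1L][same] == bad] == 0))
        "duplicate (subject, trial, time) sample(s) in trial " else
          "time not strictly increasing within trial ",
        sub("\r", "/", bad), call. = FALSE)
    }
    gid <- factor(tid[-1L][same])
    if (length(dts)) {
      spread <- tapply(dts, gid, function(d) diff(range(d)))
      if (any(spread > 1e-6))
        stop("uneven sampling interval within trial ",
             sub("\r", "/", names(spread)[which(spread > 1e-6)[1L]]),
             call. = FALSE)
    }
    for (cn in conditions) {
      pairs <- !duplicated(paste(tid, data[[cn]], sep = "\r"))
      if (sum(pairs) != length(unique(tid)))
        stop("condition '", cn, "' varies within a trial", call. = FALSE)
    }
  }

  structure(data,
            conditions = conditions,
            class = c("pupil_recording", "data.frame"))
}

#' @export
print.pupil_recording <- function(x, ...) {
  tid <- trial_id(x)
  cat("<pupil_recording> ", nrow(x), " samples, ",
      length(unique(x$subject)), " subject(s), ",
      length(unique(tid)), " trial(s)\n", sep = "")
  cond <- attr(x, "conditions")
  if (length(cond)) cat("  conditions: ", paste(cond, collapse = ", "), "\n", sep = "")
  cat("  time range: [", min(x$time), ", ", max(x$time), "] ms; ",
      sum(is.na(x$pupil)), " missing sample(s)\n", sep = "")
  invisible(x)
}

# unique trial key (trial ids are only unique within subject)
trial_id <- function(data) paste(data$subject, data$trial, sep = "\r")

#' Condition column names of a recording
#' @param rec a `pupil_recording`.
#' @return character vector of condition column names.
#' @export
conditions <- function(rec) attr(rec, "conditions")

# rebuild the class/attributes after a transformation that preserved validity;
# assumes `data` came from a valid pupil_recording and row order was kept.
restore_recording <- function(data, template) {
  structure(as.data.frame(data),
            conditions = attr(template, "conditions"),
            class = c("pupil_recording", "data.frame"))
}

#' Read a long-format pupil trace table
#'
#' Reads a delimited text file (comma- or tab-separated, header row, UTF-8)
#' with one row per sample and maps its columns onto the canonical recording
#' schema. Column mapping follows the naming convention of published
#' pupillometry datasets (`Subject`, `Trial`, `Time`, `Pupil` plus condition
#' columns such as `Luminance`).
#'
#' @param path path to the delimited file.
#' @param column_map named character vector mapping canonical names
#'   (`subject`, `trial`, `time`, `pupil`) to the file's column names.
#' @param conditions character vector of condition column names in the file,
#'   preserved per trial (values kept as character/categorical).
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return a validated [pupil_recording].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(Subject = "s1", Trial = 1, Time = c(0, 10),
#'                      Luminance = 3, Pupil = c(0.1, 0.2)),
#'           f, row.names = FALSE)
#' rec <- read_pupil_data(f, conditions = "Luminance")
#' @export
read_pupil_data <- function(path,
                            column_map = c(subject = "Subject", trial = "Trial",
                                           time = "Time", pupil = "Pupil"),
                            conditions = character(),
                            sep = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("input file is empty: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L, warn = FALSE)
    if (!length(header) || !nzchar(header))
      stop("input file is empty: ", path, call. = FALSE)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           fileEncoding = "UTF-8")
  if (nrow(raw) == 0L) stop("input file has a header but no rows: ", path,
                            call. = FALSE)
  needed <- c("subject", "trial", "time", "pupil")
  if (!all(needed %in% names(column_map)))
    stop("column_map must map all of: ", paste(needed, collapse = ", "),
         call. = FALSE)
  absent <- setdiff(c(unname(column_map[needed]), conditions), names(raw))
  if (length(absent))
    stop("column(s) not present in file: ", paste(absent, collapse = ", "),
         call. = FALSE)

  out <- data.frame(subject = raw[[column_map[["subject"]]]],
                    trial = raw[[column_map[["trial"]]]],
                    time = raw[[column_map[["time"]]]],
                    pupil = raw[[column_map[["pupil"]]]],
                    stringsAsFactors = FALSE)
  for (cn in conditions) out[[cn]] <- as.character(raw[[cn]])
  pupil_recording(out, conditions = conditions)
}

#' Write a recording back to delimited text
#'
#' @param rec a [pupil_recording].
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_pupil_data <- function(rec, path, sep = "\t") {
  utils::write.table(as.data.frame(rec), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
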