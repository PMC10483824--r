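#' Event timing tables
#'
#' An event table holds the stimulus timing of one functional run: onset and
#' duration in seconds from the start of the run, plus a condition label
#' (`trial_type`). Tables are kept sorted by onset. Any extra columns found in
#' a BIDS `events.tsv` are preserved untouched.
#'
#' @param onset numeric vector of event onsets in seconds (all `>= 0`).
#' @param duration numeric vector of event durations in seconds (all `>= 0`).
#' @param trial_type character vector of non-empty condition labels.
#' @param run_id integer run identifier.
#' @param subject,task,session optional BIDS entity labels.
#' @param extra optional data frame of additional per-event columns.
#' @return An object of class `event_table`: a data frame with columns
#'   `onset`, `duration`, `trial_type` (plus any extras), sorted by onset,
#'   carrying `run_id`, `subject`, `task` and `session` attributes.
#' @examples
#' ev <- event_table(onset = c(10, 0), duration = c(2, 2),
#'                   trial_type = c("house", "face"))
#' ev$onset  # sorted: 0, 10
#' @export
event_table <- function(onset, duration, trial_type, run_id = NA_integer_,
                        subject = NA_character_, task = NA_character_,
                        session = NULL, extra = NULL) {
  onset <- as.numeric(onset)
  duration <- as.numeric(duration)
  trial_type <- as.character(trial_type)
  n <- length(onset)
  if (length(duration) != n || length(trial_type) != n)
    stop("onset, duration and trial_type must have equal length")
  if (anyNA(onset) || anyNA(duration))
    stop("onset and duration must be numeric and non-missing")
  if (any(onset < 0)) stop("event onsets must be >= 0")
  if (any(duration < 0)) stop("event durations must be >= 0")
  if (any(!nzchar(trial_type)) || anyNA(trial_type))
    stop("trial_type labels must be non-empty strings")
  df <- data.frame(onset = onset, duration = duration,
                   trial_type = trial_type, stringsAsFactors = FALSE)
  if (!is.null(extra) && ncol(extra) > 0L) {
    stopifnot(nrow(extra) == n)
    df <- cbind(df, extra)
  }
  ord <- order(df$onset)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, run_id = as.integer(run_id), subject = subject,
            task = task, session = session,
            class = c("event_table", "data.frame"))
}

#' Read a BIDS events.tsv file
#'
#' Parses a tab-separated events file with a header row. The columns `onset`,
#' `duration` and `trial_type` are required; all other columns are kept as
#' opaque per-event metadata. Rows are returned sorted by onset.
#'
#' @param path path to a tab-separated events file.
#' @param run_id,subject,task,session optional entity labels attached to the
#'   returned table.
#' @return An [event_table].
#' @export
load_events <- function(path, run_id = NA_integer_, subject = NA_character_,
                        task = NA_character_, session = NULL) {
  if (!file.exists(path)) stop("events file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  for (col in c("onset", "duration", "trial_type")) {
    if (!col %in% names(raw))
      stop("events file ", path, " is missing required column '", col, "'")
  }
  parse_num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric '", col, "' in ", path, " at data row ", bad[1L],
           " (value '", raw[[col]][bad[1L]], "')")
    v
  }
  onset <- parse_num("onset")
  duration <- parse_num("duration")
  extra_cols <- setdiff(names(raw), c("onset", "duration", "trial_type"))
  extra <- if (length(extra_cols)) raw[, extra_cols, drop = FALSE] else NULL
  event_table(onset, duration, raw$trial_type, run_id = run_id,
              subject = subject, task = task, session = session,
              extra = extra)
}

#' Write an event table as a BIDS-style events.tsv
#'
#' Inverse of [load_events()] on the (onset, duration, trial_type) triple.
#'
#' @param events an [event_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  df <- as.data.frame(events)
  df$onset <- fmt_num(df$onset)
  df$duration <- fmt_num(df$duration)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("Event table: %d events, %d condition(s)\n",
              nrow(x), length(unique(x$trial_type))))
  if (!is.na(attr(x, "run_id"))) cat("  run:", attr(x, "run_id"), "\n")
  print(as.data.frame(x), ...)
  invisible(x)
}
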