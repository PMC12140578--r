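#' Scout-level recording container
#'
#' A `scout_recording` holds a scouts-by-samples signal matrix together with
#' its sampling rate, scout labels, study labels (subject, condition,
#' timepoint) and an eye-state annotation track.  Scouts are atlas-defined
#' cortical regions of interest; all connectivity in this package is computed
#' between scouts rather than sensors.
#'
#' @param data numeric matrix, scouts in rows, samples in columns.
#' @param fs sampling rate in Hz.
#' @param scout_names character vector of unique scout labels, one per row.
#' @param subject,condition,timepoint study labels (free-form strings).
#' @param eye_states data.frame with columns `start`, `end` (seconds) and
#'   `state` (`"open"` or `"closed"`); intervals must not overlap and must lie
#'   within the recording.  May be `NULL` when no annotation exists.
#' @return an object of class `scout_recording`.
#' @export
scout_recording <- function(data, fs, scout_names = NULL, subject = NA_character_,
                            condition = NA_character_, timepoint = NA_character_,
                            eye_states = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop_input("`data` must be a numeric matrix (scouts x samples)")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop_input("`fs` must be a positive sampling rate in Hz")
  }
  fs <- as.numeric(fs)
  if (is.null(scout_names)) {
    scout_names <- rownames(data) %||% sprintf("scout%02d", seq_len(nrow(data)))
  }
  if (length(scout_names) != nrow(data) || anyDuplicated(scout_names)) {
    stop_input("`scout_names` must be unique and match the number of rows")
  }
  dur <- ncol(data) / fs
  if (!is.null(eye_states)) {
    eye_states <- validate_eye_states(eye_states, dur)
  }
  rownames(data) <- scout_names
  structure(
    list(data = data, fs = fs, scout_names = scout_names,
         subject = subject, condition = condition, timepoint = timepoint,
         eye_states = eye_states),
    class = "scout_recording"
  )
}

validate_eye_states <- function(eye_states, duration) {
  need <- c("start", "end", "state")
  if (!is.data.frame(eye_states) || !all(need %in% names(eye_states))) {
    stop_input("`eye_states` needs columns start, end, state")
  }
  eye_states <- eye_states[order(eye_states$start), need, drop = FALSE]
  if (any(eye_states$end <= eye_states$start)) {
    stop_input("eye-state intervals must have end > start")
  }
  if (any(eye_states$start < 0) || any(eye_states$end > duration + 1e-9)) {
    stop_input("eye-state intervals must lie within the recording")
  }
  if (nrow(eye_states) > 1L &&
      any(eye_states$start[-1L] < eye_states$end[-nrow(eye_states)] - 1e-9)) {
    stop_input("eye-state intervals must not overlap")
  }
  if (!all(eye_states$state %in% c("open", "closed"))) {
    stop_input("eye states must be 'open' or 'closed'")
  }
  eye_states
}

#' @export
print.scout_recording <- function(x, ...) {
  cat(sprintf("<scout_recording> %d scouts x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat(sprintf("  subject=%s condition=%s timepoint=%s\n",
              x$subject, x$condition, x$timepoint))
  if (!is.null(x$eye_states)) {
    cat(sprintf("  eye-state intervals: %d (%.1f s closed)\n",
                nrow(x$eye_states),
                sum(with(x$eye_states, (end - start)[state == "closed"]))))
  }
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a `scout_recording`.
#' @return duration in seconds.
#' @export
rec_duration <- function(rec) ncol(rec$data) / rec$fs

#' Write / read a scout recording
#'
#' The on-disk format is a plain CSV (samples in rows, one column per scout)
#' next to a JSON sidecar carrying the sampling rate, labels and eye-state
#' intervals.
#'
#' @param rec a `scout_recording`.
#' @param prefix file path without extension; writes `<prefix>.csv` and
#'   `<prefix>.json`.
#' @return `write_recording` returns `prefix` invisibly; `read_recording`
#'   returns a `scout_recording`.
#' @export
write_recording <- function(rec, prefix) {
  stopifnot(inherits(rec, "scout_recording"))
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$scout_names
  utils::write.csv(df, paste0(prefix, ".csv"), row.names = FALSE)
  sidecar <- list(fs = rec$fs, scout_names = rec$scout_names,
                  subject = rec$subject, condition = rec$condition,
                  timepoint = rec$timepoint)
  if (!is.null(rec$eye_states)) sidecar$eye_states <- rec$eye_states
  jsonlite::write_json(sidecar, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_recording
#' @export
read_recording <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(paste0(prefix, ".csv"), check.names = FALSE)
  eye <- meta$eye_states
  if (!is.null(eye)) eye <- as.data.frame(eye)
  scout_recording(t(as.matrix(df)), fs = meta$fs,
                  scout_names = meta$scout_names,
                  subject = meta$subject %||% NA_character_,
                  condition = meta$condition %||% NA_character_,
                  timepoint = meta$timepoint %||% NA_character_,
                  eye_states = eye)
}
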