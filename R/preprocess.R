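#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward and backward (`signal::filtfilt`),
#' so the filter has exactly zero phase: cross-spectral phase, and hence
#' imaginary coherence, is unaffected by the filtering step.
#'
#' @param rec a [scout_recording()].
#' @param low,high band edges in Hz; `0 < low < high < fs/2`.
#' @param order Butterworth order of the single-pass prototype (doubled
#'   effectively by the forward-backward application).
#' @return the filtered [scout_recording()].
#' @export
bandpass <- function(rec, low = 0.5, high = 40, order = 4) {
  stopifnot(inherits(rec, "scout_recording"))
  if (low <= 0 || low >= high) stop_input("need 0 < low < high")
  if (high >= rec$fs / 2) stop_input("`high` must be below the Nyquist frequency")
  bf <- signal::butter(order, c(low, high) / (rec$fs / 2), type = "pass")
  out <- rec
  out$data <- t(apply(rec$data, 1L, function(x) signal::filtfilt(bf, x)))
  rownames(out$data) <- rec$scout_names
  out
}

#' Average reference
#'
#' Subtracts, at every sample, the mean over all scouts, so the referenced
#' data have zero spatial mean.  Pairwise differences between scouts are
#' preserved exactly; the operation is idempotent.
#'
#' @param rec a [scout_recording()] with at least two scouts.
#' @return the re-referenced [scout_recording()].
#' @export
average_reference <- function(rec) {
  stopifnot(inherits(rec, "scout_recording"))
  if (nrow(rec$data) < 2L) stop_input("average reference needs >= 2 scouts")
  out <- rec
  out$data <- sweep(rec$data, 2L, colMeans(rec$data))
  out
}

#' Extract segments of one eye state
#'
#' Returns the contiguous stretches of the requested eye state as separate
#' recordings, in temporal order.  A symmetric guard trim (default 1 s) is
#' removed from each segment boundary to suppress eye-transition artifacts;
#' segments shorter than `min_s` after trimming are dropped with a warning.
#'
#' @param rec a [scout_recording()] with an eye-state track.
#' @param state `"closed"` (default) or `"open"`.
#' @param guard_s guard trim in seconds removed from each end of every
#'   matching interval.
#' @param min_s minimum retained segment length in seconds (one spectral
#'   window by default).
#' @return list of [scout_recording()] segments (possibly empty).
#' @export
segment_eye_state <- function(rec, state = c("closed", "open"),
                              guard_s = 1, min_s = 1) {
  stopifnot(inherits(rec, "scout_recording"))
  state <- match.arg(state)
  if (is.null(rec$eye_states)) stop_input("recording has no eye-state track")
  iv <- rec$eye_states[rec$eye_states$state == state, , drop = FALSE]
  if (!nrow(iv)) return(list())
  segs <- list(); dropped <- 0L
  for (r in seq_len(nrow(iv))) {
    a <- iv$start[r] + guard_s
    b <- iv$end[r] - guard_s
    if (b - a < min_s) { dropped <- dropped + 1L; next }
    i0 <- floor(a * rec$fs) + 1L
    i1 <- floor(b * rec$fs)
    seg <- rec
    seg$data <- rec$data[, i0:i1, drop = FALSE]
    seg$eye_states <- data.frame(start = 0, end = (i1 - i0 + 1L) / rec$fs,
                                 state = state)
    segs[[length(segs) + 1L]] <- seg
  }
  if (dropped > 0L) {
    warning(sprintf("dropped %d %s segment(s) shorter than %g s after trimming",
                    dropped, state, min_s))
  }
  segs
}
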