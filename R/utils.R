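# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("icnet_config_error", "error")))
}

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("icnet_input_error", "error")))
}

stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...), class = c("icnet_degenerate_error", "error")))
}

# Analytic signal via the frequency-domain Hilbert construction: zero out
# negative frequencies, double positive ones.  Used to phase-shift narrowband
# carriers; only valid for (approximately) band-limited input.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Draw independent sub-seeds from one master seed so that nested generators
# stay reproducible without sharing a stream.  Kept below .Machine$integer.max.
derive_seeds <- function(seed, n) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x) && x >= 0
}
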