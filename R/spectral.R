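#' Welch auto- and cross-spectral estimation
#'
#' Estimates the full scout-by-scout cross-spectral matrix by averaging
#' windowed periodograms: Hann-tapered windows of `window_s` seconds at 50%
#' overlap, mean-removed per window, pooled across all supplied segments.
#' With the default 1 s window the frequency resolution is 1 Hz.  Scaling is
#' one-sided density scaling, so the auto-spectrum integrates to the signal
#' variance (Parseval).
#'
#' @param segments a [scout_recording()] or a list of them (e.g. the
#'   eyes-closed segments of one recording); all must share sampling rate and
#'   scout set.
#' @param window_s window length in seconds.
#' @param overlap fractional overlap between consecutive windows in \[0, 1).
#' @return an object of class `cross_spectrum`: list with `freqs` (Hz grid,
#'   0..Nyquist), `S` (complex array scouts x scouts x freq; `S[x, x, f]`
#'   real auto-spectra, `S[y, x, f] = Conj(S[x, y, f])`), `n_windows`, `fs`,
#'   `scout_names`, `window_s`.
#' @export
welch_cross_spectra <- function(segments, window_s = 1, overlap = 0.5) {
  if (inherits(segments, "scout_recording")) segments <- list(segments)
  if (!length(segments)) stop_input("no segments supplied")
  if (overlap < 0 || overlap >= 1) stop_input("`overlap` must be in [0, 1)")
  fs <- segments[[1L]]$fs
  scouts <- segments[[1L]]$scout_names
  for (s in segments) {
    if (!inherits(s, "scout_recording")) stop_input("segments must be scout_recordings")
    if (s$fs != fs) stop_input("segments have mismatched sampling rates")
    if (!identical(s$scout_names, scouts)) {
      stop_input("segments have mismatched scout sets")
    }
  }
  nwin <- round(fs * window_s)
  hop <- max(1L, round(nwin * (1 - overlap)))
  w <- as.numeric(signal::hanning(nwin))
  U <- sum(w^2)
  n_scouts <- length(scouts)
  n_freq <- nwin %/% 2L + 1L

  ffts <- list()
  for (s in segments) {
    n <- ncol(s$data)
    if (n < nwin) next
    starts <- seq(1L, n - nwin + 1L, by = hop)
    for (i0 in starts) {
      seg <- s$data[, i0:(i0 + nwin - 1L), drop = FALSE]
      seg <- seg - rowMeans(seg)          # constant detrend per window
      seg <- t(t(seg) * w)
      F <- stats::mvfft(t(seg))[seq_len(n_freq), , drop = FALSE]
      ffts[[length(ffts) + 1L]] <- F      # freq x scout
    }
  }
  n_windows <- length(ffts)
  if (n_windows < 1L) stop_input("no usable windows: all segments shorter than the window")

  # stack as scout x window per frequency, then average outer products
  S <- array(complex(real = 0), c(n_scouts, n_scouts, n_freq))
  A <- array(unlist(ffts), c(n_freq, n_scouts, n_windows))
  scale <- 1 / (fs * U * n_windows)
  for (f in seq_len(n_freq)) {
    Fm <- matrix(A[f, , ], n_scouts, n_windows)
    Sf <- (Fm %*% Conj(t(Fm))) * scale
    # one-sided density: double all bins except DC (and Nyquist when present)
    if (f > 1L && !(nwin %% 2L == 0L && f == n_freq)) Sf <- 2 * Sf
    S[, , f] <- Sf
  }
  structure(list(freqs = (seq_len(n_freq) - 1L) / window_s,
                 S = S, n_windows = n_windows, fs = fs,
                 scout_names = scouts, window_s = window_s),
            class = "cross_spectrum")
}

#' @export
print.cross_spectrum <- function(x, ...) {
  cat(sprintf("<cross_spectrum> %d scouts, %d freq bins (0-%g Hz), %d windows\n",
              length(x$scout_names), length(x$freqs), max(x$freqs), x$n_windows))
  invisible(x)
}
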