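#' Coupling specification for synthetic scout signals
#'
#' Describes the generative model for one scout-level recording: lagged
#' narrowband couplings between scout pairs, an instantaneous leakage mixing
#' matrix emulating source leakage / volume conduction, and the per-scout
#' background noise amplitude.
#'
#' @param edges data.frame with columns `i`, `j` (scout indices), `f0`
#'   (carrier center frequency, Hz), `strength` (coupling amplitude in
#'   \[0, 1\] relative to unit background noise) and `lag` (phase lag in
#'   radians at the carrier frequency).  May be `NULL` / empty for no
#'   coupling.
#' @param leakage_mix square mixing matrix with unit diagonal applied
#'   instantaneously after coupling, or `NULL` for the identity (no leakage).
#' @param noise_sd per-scout additive background noise standard deviation
#'   (scalar or one value per scout).
#' @return an object of class `coupling_spec`.
#' @export
coupling_spec <- function(edges = NULL, leakage_mix = NULL, noise_sd = 1) {
  if (is.null(edges)) {
    edges <- data.frame(i = integer(), j = integer(), f0 = numeric(),
                        strength = numeric(), lag = numeric())
  }
  need <- c("i", "j", "f0", "strength", "lag")
  if (!is.data.frame(edges) || !all(need %in% names(edges))) {
    stop_config("`edges` needs columns i, j, f0, strength, lag")
  }
  if (nrow(edges) && (any(edges$strength < 0) || any(edges$strength > 1))) {
    stop_config("coupling strengths must lie in [0, 1]")
  }
  if (!is.null(leakage_mix)) {
    if (!is.matrix(leakage_mix) || nrow(leakage_mix) != ncol(leakage_mix)) {
      stop_config("`leakage_mix` must be a square matrix")
    }
    if (max(abs(diag(leakage_mix) - 1)) > 1e-10) {
      stop_config("`leakage_mix` must have a unit diagonal")
    }
  }
  if (any(noise_sd < 0)) stop_config("`noise_sd` must be non-negative")
  structure(list(edges = edges[need], leakage_mix = leakage_mix,
                 noise_sd = noise_sd),
            class = "coupling_spec")
}

#' Dense instantaneous leakage matrix
#'
#' Random mixing matrix emulating source leakage / volume conduction: unit
#' diagonal, every off-diagonal entry drawn uniformly from `strength_range`,
#' so each scout instantaneously receives a share of every other source.
#' Zero-lag mixing of this kind inflates real coherence but not imaginary
#' coherence, which is the confound the pipeline's connectivity measure is
#' designed to reject.
#'
#' @param n_scouts matrix dimension.
#' @param strength_range range of the off-diagonal mixing weights.
#' @param seed integer seed.
#' @return an `n_scouts` x `n_scouts` mixing matrix with unit diagonal.
#' @export
leakage_matrix <- function(n_scouts, strength_range = c(0.05, 0.30),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(stats::runif(n_scouts^2, strength_range[1L], strength_range[2L]),
              n_scouts, n_scouts)
  diag(W) <- 1
  W
}

# Unit-variance narrowband carrier: white noise band-pass filtered around f0.
narrowband_carrier <- function(n, fs, f0, bw = 2) {
  lo <- max(f0 - bw / 2, 0.1)
  hi <- min(f0 + bw / 2, fs / 2 * 0.98)
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  x / stats::sd(x)
}

#' Generate one synthetic scout-level recording
#'
#' Each scout starts as independent white background noise.  For every coupled
#' pair a shared narrowband carrier is added to both scouts, with the second
#' scout receiving a phase-shifted copy (via the analytic signal), giving
#' direct control over the lag that imaginary coherence detects.  The leakage
#' mixing matrix is applied last, so zero-lag mixing acts on the fully formed
#' sources, exactly the confound imaginary coherence is designed to reject.
#'
#' @param spec a [coupling_spec()].
#' @param n_scouts number of scouts.
#' @param fs sampling rate (Hz); must exceed twice the highest carrier
#'   frequency.
#' @param duration recording length in seconds (at least 2).
#' @param seed integer seed; identical seeds give bit-identical recordings.
#' @param eye_block_s length in seconds of the alternating eyes-open /
#'   eyes-closed blocks written into the annotation track (first block open).
#' @param subject,condition,timepoint labels stored on the recording.
#' @return a [scout_recording()].
#' @export
gen_scout_signals <- function(spec, n_scouts, fs, duration, seed = NULL,
                              eye_block_s = 35,
                              subject = NA_character_,
                              condition = NA_character_,
                              timepoint = NA_character_) {
  stopifnot(inherits(spec, "coupling_spec"))
  if (!is.numeric(duration) || duration <= 0) {
    stop_input("`duration` must be positive")
  }
  if (duration < 2) stop_input("`duration` must be at least 2 s")
  ed <- spec$edges
  if (nrow(ed)) {
    if (any(ed$i < 1) || any(ed$j < 1) || any(ed$i > n_scouts) ||
        any(ed$j > n_scouts) || any(ed$i == ed$j)) {
      stop_config("edge scout indices must be distinct and within 1..n_scouts")
    }
    if (fs <= 2 * max(ed$f0)) {
      stop_input("`fs` must exceed twice the highest carrier frequency")
    }
  }
  if (!is.null(spec$leakage_mix) && nrow(spec$leakage_mix) != n_scouts) {
    stop_config("`leakage_mix` dimension must equal `n_scouts`")
  }
  if (!is.null(seed)) set.seed(seed)

  n <- round(fs * duration)
  noise_sd <- rep_len(spec$noise_sd, n_scouts)
  data <- matrix(stats::rnorm(n_scouts * n), n_scouts, n) * noise_sd

  if (nrow(ed)) {
    for (k in seq_len(nrow(ed))) {
      u <- narrowband_carrier(n, fs, ed$f0[k])
      a <- analytic_signal(u)
      data[ed$i[k], ] <- data[ed$i[k], ] + ed$strength[k] * u
      data[ed$j[k], ] <- data[ed$j[k], ] +
        ed$strength[k] * Re(a * exp(-1i * ed$lag[k]))
    }
  }
  if (!is.null(spec$leakage_mix)) data <- spec$leakage_mix %*% data

  scout_recording(data, fs,
                  scout_names = sprintf("scout%02d", seq_len(n_scouts)),
                  subject = subject, condition = condition,
                  timepoint = timepoint,
                  eye_states = eye_state_track(duration, eye_block_s))
}

# Alternating open/closed blocks, starting open, truncated at the recording
# end (a trailing partial block keeps its state).
eye_state_track <- function(duration, block_s) {
  if (block_s >= duration) {
    return(data.frame(start = 0, end = duration, state = "closed"))
  }
  starts <- seq(0, duration, by = block_s)
  starts <- starts[starts < duration]
  data.frame(start = starts,
             end = pmin(starts + block_s, duration),
             state = rep_len(c("open", "closed"), length(starts)))
}
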