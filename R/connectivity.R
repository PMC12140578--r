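#' Imaginary coherence per frequency
#'
#' Computes, for every scout pair and frequency bin, the absolute imaginary
#' part of coherency: `IC_xy(f) = |Im( S_xy(f) / sqrt(S_xx(f) S_yy(f)) )|`,
#' ranging from 0 to 1.  Because an instantaneous (zero-lag) mixture of
#' sources produces a purely real coherency, nonzero IC cannot be explained
#' by volume conduction / source leakage alone.  The diagonal is exactly 0
#' (auto-coherency is real).  Frequency bins where an auto-spectrum is zero
#' are flagged undefined (`NA`) and excluded from later band aggregation,
#' with a warning.
#'
#' @param cs a `cross_spectrum` from [welch_cross_spectra()].
#' @return an object of class `per_freq_ic`: list with `ic` (array scouts x
#'   scouts x freq in \[0, 1\]), `freqs`, `scout_names`, `n_windows`.
#' @export
imaginary_coherence <- function(cs) {
  stopifnot(inherits(cs, "cross_spectrum"))
  n <- length(cs$scout_names)
  nf <- length(cs$freqs)
  ic <- array(NA_real_, c(n, n, nf))
  n_bad <- 0L
  for (f in seq_len(nf)) {
    Sxx <- Re(diag(cs$S[, , f]))
    bad <- Sxx <= 0
    denom <- sqrt(outer(Sxx, Sxx))
    C <- cs$S[, , f] / denom
    v <- abs(Im(C))
    diag(v) <- 0
    if (any(bad)) {
      v[bad, ] <- NA_real_
      v[, bad] <- NA_real_
      n_bad <- n_bad + 1L
    }
    ic[, , f] <- v
  }
  if (n_bad > 0L) {
    warning(sprintf("zero auto-spectrum in %d bin(s); flagged undefined", n_bad))
  }
  structure(list(ic = ic, freqs = cs$freqs, scout_names = cs$scout_names,
                 n_windows = cs$n_windows),
            class = "per_freq_ic")
}

#' Band-aggregated imaginary coherence
#'
#' Averages per-frequency IC over the bins inside the band (endpoints
#' inclusive): the alpha default 8-12 Hz at 1 Hz resolution spans 5 bins.
#' Undefined bins are excluded from the mean.
#'
#' @param pf a `per_freq_ic` from [imaginary_coherence()].
#' @param band numeric length-2, `(f_lo, f_hi)` in Hz.
#' @return an object of class `ic_matrix`: list with `ic` (symmetric matrix,
#'   zero diagonal, entries in \[0, 1\]), `band`, `scout_names`,
#'   `n_windows`.
#' @export
band_ic <- function(pf, band = c(8, 12)) {
  stopifnot(inherits(pf, "per_freq_ic"))
  sel <- which(pf$freqs >= band[1L] & pf$freqs <= band[2L])
  if (!length(sel)) stop_input("band contains no frequency bins")
  m <- apply(pf$ic[, , sel, drop = FALSE], c(1L, 2L), mean, na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  diag(m) <- 0
  dimnames(m) <- list(pf$scout_names, pf$scout_names)
  structure(list(ic = m, band = band, scout_names = pf$scout_names,
                 n_windows = pf$n_windows),
            class = "ic_matrix")
}

#' @export
print.ic_matrix <- function(x, ...) {
  cat(sprintf("<ic_matrix> %d scouts, band %g-%g Hz, %d windows; mean IC %.4f\n",
              length(x$scout_names), x$band[1L], x$band[2L], x$n_windows,
              mean(x$ic[upper.tri(x$ic)], na.rm = TRUE)))
  invisible(x)
}

#' Aggregate vertex-level values to scout level
#'
#' Each scout's value is the unweighted mean over its member vertices.
#' Singleton memberships make the operation the identity (the pass-through
#' case when data already arrive at scout level).
#'
#' @param values numeric vector (per vertex) or matrix with vertices in rows.
#' @param membership named list of integer vectors partitioning the vertices
#'   into scouts.
#' @return named vector (or matrix with scouts in rows) of scout means.
#' @export
scout_aggregate <- function(values, membership) {
  if (any(lengths(membership) == 0L)) stop_config("empty scout in membership")
  if (is.matrix(values)) {
    out <- t(vapply(membership, function(ix) {
      colMeans(values[ix, , drop = FALSE])
    }, numeric(ncol(values))))
    rownames(out) <- names(membership)
    out
  } else {
    vapply(membership, function(ix) mean(values[ix]), numeric(1))
  }
}

#' Surrogate noise ceiling for band IC
#'
#' Empirical null for the band-averaged IC of two *independent* signals at a
#' matched data length: simulates white-noise pairs, runs them through the
#' package's own Welch / IC / band-aggregation path, and returns a quantile
#' of the resulting null distribution.  Band IC above this ceiling is
#' unlikely (at level `1 - prob`) to arise from finite-sample bias alone.
#'
#' @param n_samples number of samples per simulated signal (match the data
#'   analyzed).
#' @param fs sampling rate (Hz).
#' @param window_s,overlap Welch parameters (match the analysis).
#' @param band frequency band, as in [band_ic()].
#' @param n_sim number of simulated independent pairs.
#' @param prob quantile of the null distribution returned.
#' @param seed integer seed.
#' @return the ceiling (scalar); the simulated null values are attached as
#'   attribute `"null"`.
#' @export
ic_noise_ceiling <- function(n_samples, fs, window_s = 1, overlap = 0.5,
                             band = c(8, 12), n_sim = 500, prob = 0.95,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vals <- vapply(seq_len(n_sim), function(k) {
    rec <- scout_recording(matrix(stats::rnorm(2L * n_samples), 2L, n_samples),
                           fs = fs)
    icm <- band_ic(imaginary_coherence(
      welch_cross_spectra(rec, window_s = window_s, overlap = overlap)),
      band = band)
    icm$ic[1L, 2L]
  }, numeric(1))
  structure(stats::quantile(vals, prob, names = FALSE), null = vals)
}
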