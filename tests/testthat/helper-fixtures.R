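# Shared fixtures: everything is generated in code at test time.

# a small atlas with n scouts split into left/right halves, the first
# `n_frontal` scouts of each half forming the frontal region sets
tiny_atlas <- function(n = 16, n_frontal = 4) {
  stopifnot(n %% 2 == 0)
  half <- n / 2
  names_ <- sprintf("s%02d", seq_len(n))
  hemi <- rep(c("L", "R"), each = half)
  lobe <- rep(c(rep("frontal", n_frontal), rep("parietal", half - n_frontal)), 2)
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    scouts = data.frame(name = names_, hemisphere = hemi, lobe = lobe),
    region_sets = list(frontal_left = names_[hemi == "L" & lobe == "frontal"],
                       frontal_right = names_[hemi == "R" & lobe == "frontal"])),
    path, auto_unbox = TRUE)
  load_atlas(path)
}

# reduced-size analysis configuration used across tests
quick_config <- function(seed = 1L, n_perm = 500) {
  run_config(bp_high = 30, n_perm = n_perm, seed = seed)
}

# a reduced synthetic study: short recordings, fully eyes-closed blocks
quick_study <- function(n_subjects = 6, n_scouts = 10, effect_edges = NULL,
                        behavior_link = 0, seed = 1L, duration = 12,
                        fs = 64, leakage = FALSE) {
  design <- study_design(n_subjects = n_subjects, effect_edges = effect_edges,
                         behavior_link = behavior_link, seed = seed)
  mix <- if (leakage) leakage_matrix(n_scouts, seed = seed) else NULL
  gen_study(design, coupling_spec(leakage_mix = mix), n_scouts = n_scouts,
            fs = fs, duration = duration, eye_block_s = duration)
}

# direct-DFT cross-spectrum oracle for a single window (no averaging),
# mirroring Hann taper, per-window demeaning and one-sided density scaling
dft_cross_oracle <- function(data, fs) {
  nwin <- ncol(data)
  w <- as.numeric(signal::hanning(nwin))
  U <- sum(w^2)
  data <- data - rowMeans(data)
  data <- t(t(data) * w)
  n_freq <- nwin %/% 2 + 1
  Fm <- t(stats::mvfft(t(data)))[, seq_len(n_freq), drop = FALSE]
  S <- array(complex(real = 0), c(nrow(data), nrow(data), n_freq))
  for (f in seq_len(n_freq)) {
    Sf <- Fm[, f] %*% Conj(t(Fm[, f])) / (fs * U)
    if (f > 1 && !(nwin %% 2 == 0 && f == n_freq)) Sf <- 2 * Sf
    S[, , f] <- Sf
  }
  S
}
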