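#' Study design for the synthetic two-condition crossover
#'
#' Describes a within-subject crossover study: every subject is recorded at
#' two timepoints (pre, post) under two conditions (tRNS, sham).  Condition
#' effects are injected as additional lagged couplings present only in the
#' tRNS-post recording, with a per-subject random magnitude so that
#' brain-behavior coupling is identifiable.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param effect_edges data.frame with columns `i`, `j`, `delta` giving scout
#'   pairs and the nominal extra coupling applied only in tRNS-post; may be
#'   `NULL` for a global-null study.
#' @param behavior_link coefficient in \[0, 1\] tying each subject's injected
#'   connectivity change to their behavioral-score change (see
#'   [gen_behavior()]); 0 means no association.
#' @param subject_scale_sd standard deviation of the per-subject multiplier
#'   on `delta` (mean 1, truncated at 0.1); gives the between-subject spread
#'   the brain-behavior regression relies on.
#' @param effect_f0,effect_lag carrier frequency (Hz) and phase lag (radians)
#'   of injected effect couplings.
#' @param seed integer master seed for the whole study.
#' @return an object of class `study_design`.
#' @export
study_design <- function(n_subjects = 40, effect_edges = NULL,
                         behavior_link = 0, subject_scale_sd = 0.35,
                         effect_f0 = 10, effect_lag = pi / 2, seed = 1L) {
  if (!is_count(n_subjects) || n_subjects < 2) {
    stop_config("`n_subjects` must be an integer >= 2")
  }
  if (is.null(effect_edges)) {
    effect_edges <- data.frame(i = integer(), j = integer(), delta = numeric())
  }
  need <- c("i", "j", "delta")
  if (!is.data.frame(effect_edges) || !all(need %in% names(effect_edges))) {
    stop_config("`effect_edges` needs columns i, j, delta")
  }
  key <- paste(pmin(effect_edges$i, effect_edges$j),
               pmax(effect_edges$i, effect_edges$j))
  if (anyDuplicated(key)) stop_config("duplicated effect edge")
  if (behavior_link < -1 || behavior_link > 1) {
    stop_config("`behavior_link` must lie in [-1, 1]")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 conditions = c("tRNS", "sham"),
                 timepoints = c("pre", "post"),
                 effect_edges = effect_edges[need],
                 behavior_link = behavior_link,
                 subject_scale_sd = subject_scale_sd,
                 effect_f0 = effect_f0, effect_lag = effect_lag,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Generate a full synthetic study
#'
#' Produces 4 recordings per subject (2 conditions x 2 timepoints) from a
#' shared baseline [coupling_spec()], perturbing only the tRNS-post recording
#' by the design's effect edges, and a ground-truth table of the per-subject
#' injected effect magnitudes.
#'
#' @param design a [study_design()].
#' @param base_spec baseline [coupling_spec()] common to all recordings.
#' @param n_scouts,fs,duration recording geometry passed to
#'   [gen_scout_signals()].
#' @param eye_block_s eyes-open/closed block length in seconds.
#' @return list with `recordings` (list of [scout_recording()]s),
#'   `ground_truth` (data.frame: subject, i, j, delta_nominal, delta_applied,
#'   subject_scale) and `design`.
#' @export
gen_study <- function(design, base_spec = coupling_spec(),
                      n_scouts = 62, fs = 250, duration = 300,
                      eye_block_s = 35) {
  stopifnot(inherits(design, "study_design"))
  ee <- design$effect_edges
  if (nrow(ee) && (any(ee$i < 1) || any(ee$j < 1) || any(ee$i > n_scouts) ||
                   any(ee$j > n_scouts) || any(ee$i == ee$j))) {
    stop_config("effect edges reference invalid scouts for n_scouts = ", n_scouts)
  }
  ns <- design$n_subjects
  set.seed(design$seed)
  subject_scale <- pmax(stats::rnorm(ns, 1, design$subject_scale_sd), 0.1)
  rec_seeds <- matrix(derive_seeds(NULL, ns * 4L), ns, 4L)

  cells <- expand.grid(condition = design$conditions,
                       timepoint = design$timepoints,
                       stringsAsFactors = FALSE)
  recordings <- vector("list", ns * 4L)
  idx <- 0L
  for (s in seq_len(ns)) {
    for (k in seq_len(nrow(cells))) {
      cond <- cells$condition[k]
      tp <- cells$timepoint[k]
      spec <- base_spec
      if (cond == "tRNS" && tp == "post" && nrow(ee)) {
        extra <- data.frame(i = ee$i, j = ee$j, f0 = design$effect_f0,
                            strength = pmin(ee$delta * subject_scale[s], 1),
                            lag = design$effect_lag)
        spec <- coupling_spec(rbind(base_spec$edges, extra),
                              leakage_mix = base_spec$leakage_mix,
                              noise_sd = base_spec$noise_sd)
      }
      idx <- idx + 1L
      recordings[[idx]] <- gen_scout_signals(
        spec, n_scouts = n_scouts, fs = fs, duration = duration,
        seed = rec_seeds[s, k], eye_block_s = eye_block_s,
        subject = sprintf("sub%02d", s), condition = cond, timepoint = tp)
    }
  }

  if (nrow(ee)) {
    gt <- do.call(rbind, lapply(seq_len(ns), function(s) {
      data.frame(subject = sprintf("sub%02d", s), i = ee$i, j = ee$j,
                 delta_nominal = ee$delta,
                 delta_applied = pmin(ee$delta * subject_scale[s], 1),
                 subject_scale = subject_scale[s])
    }))
  } else {
    gt <- data.frame(subject = sprintf("sub%02d", seq_len(ns)),
                     i = NA_integer_, j = NA_integer_,
                     delta_nominal = 0, delta_applied = 0,
                     subject_scale = subject_scale)
  }
  list(recordings = recordings, ground_truth = gt, design = design)
}
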