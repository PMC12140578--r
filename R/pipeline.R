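#' Analysis configuration
#'
#' Collects every tunable of the pipeline with its default: band-pass edges,
#' analysis band, Welch window and overlap, guard trim, permutation count and
#' alpha levels, FDR variant, backward-elimination threshold, flexibility
#' variant and the master seed.  Every output written by the pipeline echoes
#' this configuration.
#'
#' @param band analysis band in Hz (alpha by default).
#' @param bp_low,bp_high zero-phase band-pass filter edges in Hz.
#' @param window_s,overlap Welch spectral-estimation parameters.
#' @param guard_s guard trim at eye-state segment boundaries (s).
#' @param n_perm Monte-Carlo permutation draws.
#' @param alpha_levels significance levels reported for edge statistics.
#' @param fdr_method `"BH"` or `"BY"`.
#' @param removal_p backward-elimination removal threshold.
#' @param flexibility_method `"pairwise"` or `"consecutive"`.
#' @param seed master seed for every stochastic step of a run.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(band = c(8, 12), bp_low = 0.5, bp_high = 40,
                       window_s = 1, overlap = 0.5, guard_s = 1,
                       n_perm = 5000, alpha_levels = c(0.05, 0.01),
                       fdr_method = "BH", removal_p = 0.10,
                       flexibility_method = "pairwise", seed = 1L) {
  structure(list(band = band, bp_low = bp_low, bp_high = bp_high,
                 window_s = window_s, overlap = overlap, guard_s = guard_s,
                 n_perm = n_perm, alpha_levels = alpha_levels,
                 fdr_method = fdr_method, removal_p = removal_p,
                 flexibility_method = flexibility_method,
                 seed = as.integer(seed)),
            class = "run_config")
}

match_atlas <- function(rec, atlas) {
  if (is.null(atlas)) return(rec)
  if (identical(rec$scout_names, atlas$scout_names)) return(rec)
  if (length(rec$scout_names) == length(atlas$scout_names) &&
      all(grepl("^scout[0-9]+$", rec$scout_names))) {
    # synthetic recordings carry positional names; adopt the atlas labels
    rec$scout_names <- atlas$scout_names
    rownames(rec$data) <- atlas$scout_names
    return(rec)
  }
  missing <- setdiff(atlas$scout_names, rec$scout_names)
  stop_config("recording does not match atlas; missing scouts: ",
              paste(utils::head(missing, 8L), collapse = ", "),
              if (length(missing) > 8L) ", ..." else "")
}

# preprocess -> cross-spectra -> band IC for one recording; fixed order
# filter, average reference, segmentation.
recording_band_ic <- function(rec, config) {
  rec <- bandpass(rec, config$bp_low, config$bp_high)
  rec <- average_reference(rec)
  segs <- segment_eye_state(rec, "closed", guard_s = config$guard_s,
                            min_s = config$window_s)
  if (!length(segs)) stop_input("no eyes-closed data in recording")
  cs <- welch_cross_spectra(segs, window_s = config$window_s,
                            overlap = config$overlap)
  band_ic(imaginary_coherence(cs), band = config$band)
}

#' Analyze a set of recordings in memory
#'
#' Runs the full EEG side of the pipeline: per-recording band IC matrices,
#' network metrics (wND, z, frontal region means), baseline paired t-tests
#' (tRNS-pre vs sham-pre per frontal region), per-subject raw IC change
#' (post - pre) per condition, and the edge-wise sign-flip permutation test
#' on the condition difference of those changes with FDR correction.
#'
#' @param recordings list of [scout_recording()]s covering 2 conditions x 2
#'   timepoints per subject.
#' @param atlas a `scout_atlas` (or `NULL` to skip region metrics and
#'   baseline tests).
#' @param config a [run_config()].
#' @return list with `ic_matrices` (named by subject_condition_timepoint),
#'   `metrics` (long data.frame of region means), `baseline_tests`,
#'   `edge_stats`, `network_changes` (a `change_table` network component).
#' @export
analyze_recordings <- function(recordings, atlas = NULL,
                               config = run_config()) {
  ics <- list()
  met_rows <- list()
  for (rec in recordings) {
    rec <- match_atlas(rec, atlas)
    key <- paste(rec$subject, rec$condition, rec$timepoint, sep = "_")
    icm <- recording_band_ic(rec, config)
    ics[[key]] <- icm
    if (!is.null(atlas)) {
      nm <- network_metrics(icm, atlas)
      for (r in names(nm$region_means)) {
        met_rows[[length(met_rows) + 1L]] <- data.frame(
          subject = rec$subject, condition = rec$condition,
          timepoint = rec$timepoint, region = r,
          value = nm$region_means[[r]], stringsAsFactors = FALSE)
      }
    }
  }
  metrics <- if (length(met_rows)) do.call(rbind, met_rows) else NULL

  baseline <- NULL
  changes <- NULL
  if (!is.null(metrics)) {
    baseline <- lapply(stats::setNames(nm = unique(metrics$region)), function(r) {
      pre <- metrics[metrics$timepoint == "pre" & metrics$region == r, ]
      wide <- merge(pre[pre$condition == "tRNS", c("subject", "value")],
                    pre[pre$condition == "sham", c("subject", "value")],
                    by = "subject", suffixes = c("_tRNS", "_sham"))
      paired_t(wide$value_tRNS, wide$value_sham)
    })
    changes <- change_scores(metrics)$network
  }

  # per-subject raw IC change (post - pre) per condition, on edges
  info <- do.call(rbind, lapply(names(ics), function(k) {
    p <- strsplit(k, "_")[[1L]]
    data.frame(key = k, subject = p[1L], condition = p[2L],
               timepoint = p[3L], stringsAsFactors = FALSE)
  }))
  subjects <- sort(unique(info$subject))
  delta_for <- function(cond) {
    mats <- lapply(subjects, function(s) {
      post <- info$key[info$subject == s & info$condition == cond &
                         info$timepoint == "post"]
      pre <- info$key[info$subject == s & info$condition == cond &
                        info$timepoint == "pre"]
      if (length(post) != 1L || length(pre) != 1L) {
        stop_input("subject ", s, " is missing a ", cond, " recording cell")
      }
      ics[[post]]$ic - ics[[pre]]$ic
    })
    flatten_edges(mats)
  }
  delta_trns <- delta_for("tRNS")
  delta_sham <- delta_for("sham")
  edge_stats <- perm_paired_edges(delta_trns, delta_sham,
                                  n_perm = config$n_perm,
                                  seed = config$seed)
  if (config$fdr_method != "BH") {
    edge_stats$p_fdr <- fdr_bh(edge_stats$p, method = config$fdr_method)
  }
  list(ic_matrices = ics, metrics = metrics, baseline_tests = baseline,
       edge_stats = edge_stats, network_changes = changes,
       delta_trns = delta_trns, delta_sham = delta_sham)
}

#' Brain-behavior regressions
#'
#' Scores the verbal responses, forms tRNS-sham behavioral change scores,
#' and runs one backward-elimination regression per task and frontal region
#' (response: the region's wND change; predictors: the task's fluency,
#' originality and flexibility changes), plus follow-up simple regressions
#' for every model that retains more than one predictor.
#'
#' @param network_changes data.frame from [analyze_recordings()]
#'   (`network_changes`).
#' @param responses,embeddings,synonyms,common_uses behavioral inputs, see
#'   [score_responses()].
#' @param config a [run_config()].
#' @return list with `scores`, `behavior_changes` and `models` (named list,
#'   `<task>_<region>`, of `regression_result` plus `simple` follow-ups).
#' @export
brain_behavior_regressions <- function(network_changes, responses, embeddings,
                                       synonyms = NULL, common_uses = NULL,
                                       config = run_config()) {
  scores <- score_responses(responses, embeddings, synonyms, common_uses,
                            flexibility_method = config$flexibility_method)
  long <- stats::reshape(scores, direction = "long",
                         varying = c("fluency", "flexibility", "originality"),
                         v.names = "value", timevar = "measure",
                         times = c("fluency", "flexibility", "originality"),
                         idvar = c("participant", "condition", "task"))
  rownames(long) <- NULL
  bch <- change_scores(
    network = data.frame(subject = character(), condition = character(),
                         timepoint = character(), region = character(),
                         value = numeric()),
    behavior = long)$behavior

  models <- list()
  for (task in unique(bch$task)) {
    wide <- stats::reshape(bch[bch$task == task, ], direction = "wide",
                           idvar = "participant", timevar = "measure",
                           drop = "task")
    names(wide) <- sub("^change\\.", "", names(wide))
    for (region in unique(network_changes$region)) {
      resp <- network_changes[network_changes$region == region,
                              c("subject", "wnd_change")]
      df <- merge(wide, resp, by.x = "participant", by.y = "subject")
      preds <- intersect(c("fluency", "originality", "flexibility"), names(df))
      fit <- backward_regression(df, "wnd_change", preds,
                                 removal_p = config$removal_p)
      if (length(fit$retained) > 1L) {
        fit$simple <- lapply(stats::setNames(nm = fit$retained), function(pr) {
          simple_regression(df, "wnd_change", pr)
        })
      }
      models[[paste(task, region, sep = "_")]] <- fit
    }
  }
  list(scores = scores, behavior_changes = bch, models = models)
}

#' Simulate a study to disk
#'
#' Generates the synthetic study (recordings, verbal responses, embeddings,
#' ground truth) and writes everything under `out_dir` together with a
#' manifest echoing the design, parameters and seed.
#'
#' @param design a [study_design()].
#' @param base_spec baseline [coupling_spec()].
#' @param pool an [answer_pool()] (built with the design seed when `NULL`).
#' @param out_dir output directory (created).
#' @param n_scouts,fs,duration,eye_block_s recording geometry, see
#'   [gen_study()].
#' @return the manifest, invisibly.
#' @export
simulate_study <- function(design, base_spec = coupling_spec(), pool = NULL,
                           out_dir, n_scouts = 62, fs = 250, duration = 300,
                           eye_block_s = 35) {
  stopifnot(inherits(design, "study_design"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "recordings"), showWarnings = FALSE)
  study <- gen_study(design, base_spec, n_scouts = n_scouts, fs = fs,
                     duration = duration, eye_block_s = eye_block_s)
  pool <- pool %||% answer_pool(seed = design$seed + 13L)
  beh <- gen_behavior(pool, design, study$ground_truth)

  files <- character()
  for (rec in study$recordings) {
    prefix <- file.path(out_dir, "recordings",
                        paste(rec$subject, rec$condition, rec$timepoint,
                              sep = "_"))
    write_recording(rec, prefix)
    files <- c(files, paste0(basename(prefix), ".csv"))
  }
  utils::write.csv(study$ground_truth, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(beh$responses, file.path(out_dir, "responses.csv"),
                   row.names = FALSE)
  utils::write.csv(beh$embeddings, file.path(out_dir, "embeddings.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(synonyms = as.list(beh$synonyms),
         common_uses = as.list(beh$common_uses)),
    file.path(out_dir, "lexicon.json"), auto_unbox = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("icnet")),
    seed = design$seed, n_subjects = design$n_subjects,
    n_recordings = length(study$recordings),
    n_scouts = n_scouts, fs = fs, duration = duration,
    eye_block_s = eye_block_s,
    behavior_link = design$behavior_link,
    effect_edges = study$design$effect_edges,
    recording_files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Analyze a simulated (or compatible) study directory
#'
#' Reads the recordings and behavioral tables written by [simulate_study()],
#' runs [analyze_recordings()] and [brain_behavior_regressions()], and
#' writes: per-recording dense IC matrices, the region metrics and change
#' tables, the edge statistics (long CSV: edge, t, p, p_fdr, sign), the
#' regression tables, and a machine-readable `summary.json` (significant
#' edge counts at each alpha level, retained predictors and R-squared per
#' model, baseline tests, configuration echo).
#'
#' @param data_dir directory written by [simulate_study()].
#' @param out_dir results directory (created).
#' @param atlas a `scout_atlas`; the packaged default when `NULL`.
#' @param config a [run_config()].
#' @return the summary list, invisibly.
#' @export
analyze_study <- function(data_dir, out_dir, atlas = NULL,
                          config = run_config()) {
  atlas <- atlas %||% load_atlas()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rec_files <- list.files(file.path(data_dir, "recordings"),
                          pattern = "\\.csv$", full.names = TRUE)
  if (!length(rec_files)) stop_input("no recordings found in ", data_dir)
  recordings <- lapply(sub("\\.csv$", "", rec_files), read_recording)

  eeg <- analyze_recordings(recordings, atlas, config)

  dir.create(file.path(out_dir, "ic"), showWarnings = FALSE)
  for (key in names(eeg$ic_matrices)) {
    utils::write.csv(eeg$ic_matrices[[key]]$ic,
                     file.path(out_dir, "ic", paste0(key, ".csv")))
  }
  utils::write.csv(eeg$metrics, file.path(out_dir, "region_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(eeg$network_changes,
                   file.path(out_dir, "network_changes.csv"),
                   row.names = FALSE)
  utils::write.csv(eeg$edge_stats, file.path(out_dir, "edge_stats.csv"),
                   row.names = FALSE)

  responses <- utils::read.csv(file.path(data_dir, "responses.csv"))
  embeddings <- utils::read.csv(file.path(data_dir, "embeddings.csv"))
  lex <- jsonlite::read_json(file.path(data_dir, "lexicon.json"),
                             simplifyVector = TRUE)
  bb <- brain_behavior_regressions(eeg$network_changes, responses, embeddings,
                                   synonyms = unlist(lex$synonyms),
                                   common_uses = unlist(lex$common_uses),
                                   config = config)
  utils::write.csv(bb$scores, file.path(out_dir, "behavior_scores.csv"),
                   row.names = FALSE)
  utils::write.csv(bb$behavior_changes,
                   file.path(out_dir, "behavior_changes.csv"),
                   row.names = FALSE)
  reg_rows <- do.call(rbind, lapply(names(bb$models), function(nm) {
    co <- bb$models[[nm]]$coefficients
    co$model <- nm
    co$retained <- co$term %in% bb$models[[nm]]$retained
    co
  }))
  utils::write.csv(reg_rows, file.path(out_dir, "regressions.csv"),
                   row.names = FALSE)

  summary <- list(
    package_version = as.character(utils::packageVersion("icnet")),
    config = unclass(config),
    n_subjects = length(unique(eeg$metrics$subject)),
    n_edges = nrow(eeg$edge_stats),
    significant_edges = lapply(
      stats::setNames(config$alpha_levels,
                      paste0("alpha_", config$alpha_levels)),
      function(a) list(raw = sum(eeg$edge_stats$p < a),
                       fdr = sum(eeg$edge_stats$p_fdr < a))),
    baseline_tests = lapply(eeg$baseline_tests, function(b) {
      list(t = b$statistic, df = b$df, p = b$p)
    }),
    models = lapply(bb$models, function(m) {
      list(retained = as.list(m$retained), r_squared = m$r_squared,
           model_p = m$model_p)
    }))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Render a human-readable run report
#'
#' Tabulates significant edges split by the sign of t (post-stimulation
#' increases vs decreases), group-mean wND change per region, and the
#' regression tables, from a results directory written by [analyze_study()].
#'
#' @param results_dir directory with `edge_stats.csv`, `network_changes.csv`
#'   and `regressions.csv`.
#' @param alpha_levels significance levels to report.
#' @return character vector of report lines (also written to `report.txt`),
#'   invisibly.
#' @export
report_results <- function(results_dir, alpha_levels = c(0.05, 0.01)) {
  lines <- c("icnet run report", strrep("=", 16))
  es_path <- file.path(results_dir, "edge_stats.csv")
  if (file.exists(es_path)) {
    es <- utils::read.csv(es_path)
    for (a in alpha_levels) {
      sig <- es[es$p_fdr < a, ]
      lines <- c(lines, "",
                 sprintf("FDR-significant edges at alpha = %g: %d", a, nrow(sig)))
      if (!nrow(sig)) {
        lines <- c(lines, "  (none)")
      } else {
        pos <- sig[sig$sign > 0, ]; neg <- sig[sig$sign < 0, ]
        lines <- c(lines,
                   sprintf("  increases (t > 0): %d", nrow(pos)),
                   sprintf("    %s", paste(pos$edge, collapse = ", ")),
                   sprintf("  decreases (t < 0): %d", nrow(neg)),
                   sprintf("    %s", paste(neg$edge, collapse = ", ")))
      }
    }
  } else {
    lines <- c(lines, "", "edge statistics: MISSING")
  }
  nc_path <- file.path(results_dir, "network_changes.csv")
  if (file.exists(nc_path)) {
    nc <- utils::read.csv(nc_path)
    lines <- c(lines, "", "group-mean wND change by region:")
    for (r in unique(nc$region)) {
      lines <- c(lines, sprintf("  %-16s %+.4f", r,
                                mean(nc$wnd_change[nc$region == r])))
    }
  } else {
    lines <- c(lines, "", "network changes: MISSING")
  }
  rg_path <- file.path(results_dir, "regressions.csv")
  if (file.exists(rg_path)) {
    rg <- utils::read.csv(rg_path)
    lines <- c(lines, "", "regression models (final step):")
    for (m in unique(rg$model)) {
      sel <- rg[rg$model == m, ]
      lines <- c(lines, sprintf("  %s", m))
      for (i in seq_len(nrow(sel))) {
        lines <- c(lines, sprintf(
          "    %-12s B = %8.3f  SE B = %7.3f  beta = %7.3f  p = %.4f%s",
          sel$term[i], sel$B[i], sel$SE_B[i],
          ifelse(is.na(sel$beta[i]), NA, sel$beta[i]), sel$p[i],
          ifelse(sel$retained[i], " *", "")))
      }
    }
  } else {
    lines <- c(lines, "", "regressions: MISSING")
  }
  writeLines(lines, file.path(results_dir, "report.txt"))
  invisible(lines)
}
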