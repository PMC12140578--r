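test_that("gen_scout_signals is deterministic and validates its inputs", {
  spec <- coupling_spec(data.frame(i = 1L, j = 2L, f0 = 10, strength = 0.5,
                                   lag = pi / 2))
  a <- gen_scout_signals(spec, 4, 128, 4, seed = 11)
  b <- gen_scout_signals(spec, 4, 128, 4, seed = 11)
  expect_identical(a$data, b$data)
  c <- gen_scout_signals(spec, 4, 128, 4, seed = 12)
  expect_false(identical(a$data, c$data))

  expect_error(gen_scout_signals(spec, 1, 128, 4, seed = 1),
               class = "icnet_config_error")   # edge j=2 out of range
  expect_error(gen_scout_signals(spec, 4, 128, -1), class = "icnet_input_error")
  expect_error(gen_scout_signals(spec, 4, 15, 4), class = "icnet_input_error")
  expect_error(coupling_spec(data.frame(i = 1, j = 2, f0 = 10, strength = 1.2,
                                        lag = 0)),
               class = "icnet_config_error")
  expect_error(coupling_spec(leakage_mix = matrix(c(2, 0, 0, 1), 2)),
               class = "icnet_config_error")
})

test_that("a strongly coupled lagged pair dominates the band IC matrix", {
  spec <- coupling_spec(data.frame(i = 1L, j = 2L, f0 = 10, strength = 0.9,
                                   lag = pi / 2))
  rec <- gen_scout_signals(spec, 62, 250, 60, seed = 21, eye_block_s = 60)
  icm <- band_ic(imaginary_coherence(welch_cross_spectra(rec)))
  v <- icm$ic[upper.tri(icm$ic)]
  expect_equal(max(v), icm$ic[1, 2])          # maximal of all 1891 pairs
  expect_gt(icm$ic[1, 2], 0.5)
})

test_that("with no coupling all pairs stay below the surrogate noise ceiling", {
  rec <- gen_scout_signals(coupling_spec(), 12, 128, 30, seed = 31,
                           eye_block_s = 30)
  icm <- band_ic(imaginary_coherence(welch_cross_spectra(rec)))
  ceiling <- ic_noise_ceiling(ncol(rec$data), fs = 128, n_sim = 400,
                              prob = 0.999, seed = 32)
  v <- icm$ic[upper.tri(icm$ic)]
  expect_lt(mean(v > ceiling), 0.05)
})

test_that("measured band IC increases monotonically with coupling strength", {
  strengths <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  ic <- vapply(seq_along(strengths), function(k) {
    spec <- coupling_spec(data.frame(i = 1L, j = 2L, f0 = 10,
                                     strength = strengths[k], lag = pi / 2))
    rec <- gen_scout_signals(spec, 2, 128, 40, seed = 40 + k,
                             eye_block_s = 40)
    band_ic(imaginary_coherence(welch_cross_spectra(rec)))$ic[1, 2]
  }, numeric(1))
  expect_gt(cor(strengths, ic, method = "spearman"), 0)
  expect_true(all(diff(ic) > -0.05))  # monotone up to estimation noise
})

test_that("gen_study honours the design contract", {
  st <- quick_study(n_subjects = 2, n_scouts = 4, duration = 4)
  expect_length(st$recordings, 8)   # 2 subjects x 2 conditions x 2 timepoints
  cells <- table(vapply(st$recordings, function(r)
    paste(r$condition, r$timepoint), character(1)))
  expect_true(all(cells == 2))

  # effect edges perturb only tRNS-post: all other cells identical to the
  # same-seed null study
  ee <- data.frame(i = 1L, j = 3L, delta = 0.5)
  st0 <- quick_study(n_subjects = 2, n_scouts = 4, duration = 4, seed = 5)
  st1 <- quick_study(n_subjects = 2, n_scouts = 4, duration = 4, seed = 5,
                     effect_edges = ee)
  for (k in seq_along(st0$recordings)) {
    r0 <- st0$recordings[[k]]; r1 <- st1$recordings[[k]]
    if (r0$condition == "tRNS" && r0$timepoint == "post") {
      expect_false(identical(r0$data, r1$data))
    } else {
      expect_identical(r0$data, r1$data)
    }
  }
  expect_equal(nrow(st1$ground_truth), 2)
  expect_true(all(st1$ground_truth$delta_applied ==
                    pmin(0.5 * st1$ground_truth$subject_scale, 1)))

  expect_error(study_design(n_subjects = 1), class = "icnet_config_error")
  expect_error(study_design(effect_edges = data.frame(i = c(1, 2), j = c(2, 1),
                                                      delta = 0.1)),
               class = "icnet_config_error")
})

test_that("gen_behavior produces 3 items per session per task and is null-safe", {
  st <- quick_study(n_subjects = 2, n_scouts = 4, duration = 4, seed = 9)
  pool <- answer_pool(seed = 9)
  beh <- gen_behavior(pool, st$design, st$ground_truth)
  r1 <- beh$responses[beh$responses$participant == "sub01", ]
  per_cell <- aggregate(item ~ condition + task, r1,
                        function(x) length(unique(x)))
  expect_true(all(per_cell$item == 3))
  # every answer token has an embedding row
  expect_true(all(normalize_answer(r1$answer) %in%
                    normalize_answer(beh$embeddings$token)))
  expect_error(gen_behavior(structure(list(vocabulary = data.frame()),
                                      class = "answer_pool"),
                            st$design, st$ground_truth),
               class = "icnet_config_error")
})
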