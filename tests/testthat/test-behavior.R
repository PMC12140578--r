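test_that("fluency counts valid distinct answers", {
  expect_equal(score_fluency(c("wool", "wool", "meadow"), "AFT"), 2)
  expect_equal(score_fluency(character(0), "AUT"), 0)
  expect_equal(score_fluency(c("", "  "), "AUT"), 0)
  # the prompt's common use is excluded for AUT but not for AFT
  ans <- c("sitting", "ladder", "firewood", "Sitting!", "art object")
  expect_equal(score_fluency(ans, "AUT", common_use = "sitting"), 3)
  expect_equal(score_fluency(ans, "AFT"), 4)
  # case and punctuation do not create distinct answers
  expect_equal(score_fluency(c("Door-stop", "door stop", "doorstop"), "AUT"), 2)
})

test_that("originality is the inverted pooled relative frequency", {
  pool <- c(rep("candle holder", 1), rep("paperweight", 9))
  sc <- originality_scorer(pool)
  expect_equal(unname(sc("candle holder")), 0.9)
  expect_equal(unname(sc("paperweight")), 0.1)
  # an answer that is the entire pool scores 0
  sc2 <- originality_scorer(rep("paperweight", 12))
  expect_equal(unname(sc2("paperweight")), 0)
  # equal counts give equal scores
  sc3 <- originality_scorer(c(rep("a", 3), rep("b", 3), rep("c", 6)))
  expect_equal(unname(sc3("a")), unname(sc3("b")))
  # scores stay in [0, 1] and duplicating an answer never raises its score
  sc4 <- originality_scorer(c(pool, "paperweight"))
  expect_lte(unname(sc4("paperweight")), unname(sc("paperweight")))
  expect_true(all(sc(unique(pool)) >= 0 & sc(unique(pool)) <= 1))
  # synonyms pool into one frequency
  sc5 <- originality_scorer(c("sofa", "couch", "table"),
                            synonyms = c(couch = "sofa"))
  expect_equal(unname(sc5("couch")), 1 - 2 / 3)
  expect_error(originality_scorer(character(0)), class = "icnet_input_error")
})

test_that("flexibility is the mean pairwise cosine distance", {
  emb <- rbind(a = c(1, 0, 0), b = c(0, 1, 0), c = c(0, 0, 1),
               d = c(1, 0, 0))
  # identical / synonymous answers share one vector -> 0
  expect_equal(score_flexibility(c("a", "a"), emb), 0)
  expect_equal(score_flexibility(c("a", "syn"), emb,
                                 synonyms = c(syn = "a")), 0)
  # two orthogonal unit vectors -> 1
  expect_equal(score_flexibility(c("a", "b"), emb), 1)
  # fewer than two answers -> 0
  expect_equal(score_flexibility("a", emb), 0)
  # 4 answers against the explicit 6-pair hand computation
  set.seed(16)
  V <- matrix(rnorm(12), 4, dimnames = list(c("w", "x", "y", "z")))
  cosd <- function(u, v) 1 - sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  pairs <- combn(4, 2)
  oracle <- mean(apply(pairs, 2, function(p) cosd(V[p[1], ], V[p[2], ])))
  expect_equal(score_flexibility(c("w", "x", "y", "z"), V), oracle)
  # invariant to answer order and duplication of synonymous answers
  expect_equal(score_flexibility(c("z", "w", "y", "x", "z"), V), oracle)
  # OOV handling: multi-word averages in-vocab tokens; all-OOV is NA
  expect_equal(score_flexibility(c("a b", "c"), emb),
               score_flexibility(c("ab", "c"),
                                 rbind(ab = c(0.5, 0.5, 0), c = c(0, 0, 1))))
  expect_warning(out <- score_flexibility(c("qq", "zz"), emb), "vocabulary")
  expect_true(is.na(out))
  # consecutive-pair variant
  cons <- mean(c(cosd(V[1, ], V[2, ]), cosd(V[2, ], V[3, ]),
                 cosd(V[3, ], V[4, ])))
  expect_equal(score_flexibility(c("w", "x", "y", "z"), V,
                                 method = "consecutive"), cons)
})

test_that("session aggregation averages the three items", {
  sc <- data.frame(item = c("i1", "i2", "i3"), fluency = c(4, 6, 8),
                   flexibility = c(0.2, 0.4, 0.6),
                   originality = c(0.5, 0.7, 0.9))
  out <- aggregate_session(sc)
  expect_equal(out$fluency, 6)
  expect_equal(out$flexibility, 0.4)
  expect_equal(out$originality, 0.7)
  expect_equal(aggregate_session(sc[1, ])$fluency, 4)   # one item: identity
  sc$originality[2] <- NA
  expect_warning(out2 <- aggregate_session(sc), "missing")
  expect_equal(out2$originality, 0.7)   # mean of remaining two
})

test_that("score_responses scores a full synthetic response table", {
  st <- quick_study(n_subjects = 4, n_scouts = 4, duration = 4, seed = 17)
  beh <- gen_behavior(answer_pool(seed = 17), st$design, st$ground_truth)
  scores <- score_responses(beh$responses, beh$embeddings, beh$synonyms,
                            beh$common_uses)
  expect_equal(nrow(scores), 4 * 2 * 2)   # participant x condition x task
  expect_true(all(scores$fluency > 0))
  expect_true(all(scores$originality >= 0 & scores$originality <= 1))
  expect_true(all(scores$flexibility >= 0))
  # single participant, 3 items per session -> 6 item scores per condition
  one <- beh$responses[beh$responses$participant == "sub01", ]
  per_cond <- table(unique(one[c("condition", "task", "item")])$condition)
  expect_true(all(per_cond == 6))
})
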