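#' Synthetic answer pool for the verbal divergent-thinking tasks
#'
#' Builds, per prompt item, a long-tailed (Zipf-weighted) vocabulary of
#' candidate answers, a synonym map (groups of tokens sharing one embedding
#' vector), and an embedding space in which frequent answers cluster near an
#' item-specific semantic center while rare answers are dispersed.  The
#' dispersion gradient is what lets tail-heavy sampling raise both
#' originality (statistical infrequency) and flexibility (embedding spread).
#'
#' @param aut_items,aft_items prompt words for the alternative-uses and
#'   associative-fluency tasks (6 each, split into two parallel session sets
#'   of 3).
#' @param vocab_size candidate answers per item.
#' @param zipf_s Zipf exponent of the answer-frequency distribution.
#' @param synonym_rate fraction of tokens folded into synonym pairs.
#' @param embedding_dim embedding dimensionality.
#' @param seed integer seed.
#' @return an object of class `answer_pool` with elements `items`
#'   (data.frame: task, item, set, common_use), `vocabulary` (data.frame:
#'   task, item, token, weight, canonical), `embeddings` (data.frame: token,
#'   v1..vD), `synonyms` (named character: token -> canonical) and
#'   `common_uses` (named character, AUT items only).
#' @export
answer_pool <- function(aut_items = c("safety pin", "chair", "watch",
                                      "automobile tire", "eyeglasses",
                                      "wooden pencil"),
                        aft_items = c("carpet", "sheep", "table",
                                      "eagle", "house", "scissors"),
                        vocab_size = 60, zipf_s = 1.15,
                        synonym_rate = 0.08, embedding_dim = 50,
                        seed = NULL) {
  if (vocab_size < 5) stop_config("`vocab_size` must be at least 5")
  if (!is.null(seed)) set.seed(seed)
  items <- rbind(
    data.frame(task = "AUT", item = aut_items,
               set = rep(c("A", "B"), each = 3), stringsAsFactors = FALSE),
    data.frame(task = "AFT", item = aft_items,
               set = rep(c("A", "B"), each = 3), stringsAsFactors = FALSE)
  )
  items$common_use <- ifelse(items$task == "AUT",
                             paste0("commonuse ", gsub(" ", "", items$item)),
                             NA_character_)

  vocab_list <- list(); emb_list <- list(); syn <- character()
  for (r in seq_len(nrow(items))) {
    it <- gsub(" ", "", items$item[r])
    tokens <- sprintf("%s_ans%03d", it, seq_len(vocab_size))
    w <- (1 / seq_len(vocab_size)^zipf_s)
    w <- w / sum(w)
    # fold some mid-rank tokens into synonym pairs
    n_syn <- floor(vocab_size * synonym_rate)
    canonical <- tokens
    if (n_syn > 0) {
      pick <- sample(2:vocab_size, 2 * n_syn)
      for (k in seq_len(n_syn)) {
        a <- pick[2 * k - 1]; b <- pick[2 * k]
        canonical[b] <- tokens[a]
        syn[tokens[b]] <- tokens[a]
      }
    }
    # embeddings: frequent answers hug the item center, rare ones scatter
    center <- stats::rnorm(embedding_dim)
    center <- center / sqrt(sum(center^2))
    kappa <- 0.4 + 1.2 * (seq_len(vocab_size) - 1) / vocab_size
    vecs <- t(vapply(seq_len(vocab_size), function(k) {
      v <- center + kappa[k] * stats::rnorm(embedding_dim)
      v / sqrt(sum(v^2))
    }, numeric(embedding_dim)))
    rownames(vecs) <- tokens
    # synonyms share the canonical token's vector
    vecs <- vecs[match(canonical, tokens), , drop = FALSE]
    rownames(vecs) <- tokens
    # the stated common use is a (very frequent) valid token for AUT items
    if (!is.na(items$common_use[r])) {
      cu <- items$common_use[r]
      tokens <- c(cu, tokens)
      canonical <- c(cu, canonical)
      w <- c(max(w), w); w <- w / sum(w)
      cu_vec <- center + 0.2 * stats::rnorm(embedding_dim)
      vecs <- rbind(matrix(cu_vec / sqrt(sum(cu_vec^2)), 1,
                           dimnames = list(cu)), vecs)
    }
    vocab_list[[r]] <- data.frame(task = items$task[r], item = items$item[r],
                                  token = tokens, weight = w,
                                  canonical = canonical,
                                  stringsAsFactors = FALSE)
    emb_list[[r]] <- vecs
  }
  emb <- do.call(rbind, emb_list)
  emb_df <- data.frame(token = rownames(emb), emb, row.names = NULL,
                       stringsAsFactors = FALSE)
  names(emb_df) <- c("token", paste0("v", seq_len(embedding_dim)))
  cu <- items$common_use[items$task == "AUT"]
  names(cu) <- items$item[items$task == "AUT"]
  structure(list(items = items, vocabulary = do.call(rbind, vocab_list),
                 embeddings = emb_df, synonyms = syn, common_uses = cu,
                 embedding_dim = embedding_dim),
            class = "answer_pool")
}

#' Generate verbal responses tied to the injected connectivity ground truth
#'
#' Samples ordered answer lists per participant, session, task and item from
#' the pool's long-tailed vocabulary.  In the tRNS session the sampling
#' distribution of a subject is tempered (weights raised to an exponent
#' below 1) in proportion to `behavior_link` times that subject's
#' standardized injected connectivity magnitude, pushing their answers into
#' the long tail; this raises scored originality and flexibility changes in
#' step with the injected connectivity change.  With `behavior_link = 0` the
#' tempering is pure noise and the population association is nil.  Fluency is
#' left null by design (same answer-count distribution in both conditions).
#'
#' @param pool an [answer_pool()].
#' @param design a [study_design()] (supplies `behavior_link` and the seed).
#' @param ground_truth ground-truth table from [gen_study()].
#' @param lambda_fluency Poisson mean of the per-item answer count (plus 2).
#' @param temper_gain scale mapping the standardized subject effect onto the
#'   tempering exponent (exponent = 1 - gain * g, clamped to \[0.1, 1.9\]).
#' @param dup_rate probability of appending a duplicate answer (exercises
#'   double-listing exclusion); AUT lists also include the item's common use
#'   with this probability (exercises the validity predicate).
#' @return list with `responses` (data.frame: participant, session,
#'   condition, task, item, answer_index, answer), `embeddings`, `synonyms`,
#'   `common_uses` and `subject_effects` (participant, g: the latent
#'   behavioral-effect score used for tempering).
#' @export
gen_behavior <- function(pool, design, ground_truth, lambda_fluency = 10,
                         temper_gain = 0.8, dup_rate = 0.05) {
  stopifnot(inherits(pool, "answer_pool"), inherits(design, "study_design"))
  if (!nrow(pool$vocabulary)) stop_config("empty vocabulary")
  subs <- unique(ground_truth[c("subject", "subject_scale")])
  ns <- nrow(subs)
  set.seed(design$seed + 77L)
  u <- subs$subject_scale
  u <- if (stats::sd(u) > 0) (u - mean(u)) / stats::sd(u) else rep(0, ns)
  # latent behavioral effect: mixing weight between the subject's injected
  # connectivity magnitude and independent noise; link = 0 is pure noise,
  # link = 1 a deterministic tie
  link <- design$behavior_link
  g <- link * u + (1 - abs(link)) * stats::rnorm(ns)
  if (stats::sd(g) > 0) g <- g / stats::sd(g)
  exponent <- pmin(pmax(1 - temper_gain * g, 0.1), 1.9)

  rows <- list(); ri <- 0L
  for (s in seq_len(ns)) {
    # counterbalance parallel item sets across conditions by subject parity
    sets <- if (s %% 2 == 1) c(tRNS = "A", sham = "B") else c(tRNS = "B", sham = "A")
    for (cond in design$conditions) {
      e <- if (cond == "tRNS") exponent[s] else 1
      sess <- if (cond == "tRNS") 1L else 2L
      items <- pool$items[pool$items$set == sets[[cond]], ]
      for (r in seq_len(nrow(items))) {
        voc <- pool$vocabulary[pool$vocabulary$item == items$item[r], ]
        n_ans <- stats::rpois(1, lambda_fluency) + 2L
        n_ans <- min(n_ans, nrow(voc) - 1L)
        p <- voc$weight^e
        ans <- sample(voc$token, n_ans, prob = p / sum(p))
        if (items$task[r] == "AUT" && stats::runif(1) < dup_rate) {
          ans <- c(ans, items$common_use[r])
        }
        if (stats::runif(1) < dup_rate) ans <- c(ans, ans[1L])
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          participant = subs$subject[s], session = sess, condition = cond,
          task = items$task[r], item = items$item[r],
          answer_index = seq_along(ans), answer = ans,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(responses = do.call(rbind, rows),
       embeddings = pool$embeddings,
       synonyms = pool$synonyms,
       common_uses = pool$common_uses,
       subject_effects = data.frame(participant = subs$subject, g = g))
}
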