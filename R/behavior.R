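#' Normalize a free-text answer
#'
#' Casefolds, strips punctuation and collapses whitespace.  No stemming is
#' applied (German-safe).
#'
#' @param x character vector of raw answers.
#' @return normalized character vector.
#' @export
normalize_answer <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[[:punct:]]", "", x)
  gsub("[[:space:]]+", " ", x)
}

canonicalize <- function(x, synonyms = NULL) {
  if (is.null(synonyms) || !length(synonyms)) return(x)
  hit <- match(x, names(synonyms))
  x[!is.na(hit)] <- unname(synonyms[hit[!is.na(hit)]])
  x
}

# Validity filter applied before fluency/originality scoring.  AUT: answers
# must be non-empty, distinct after normalization, and must not repeat the
# prompt's stated common use.  AFT: non-empty and distinct (double listings
# excluded).
valid_answers <- function(answers, task, common_use = NA_character_) {
  a <- normalize_answer(answers)
  a <- a[nzchar(a)]
  a <- a[!duplicated(a)]
  if (task == "AUT" && !is.na(common_use)) {
    a <- a[a != normalize_answer(common_use)]
  }
  a
}

#' Fluency score of one response set
#'
#' Number of valid answers: for the associative-fluency task the count of
#' distinct normalized answers; for the alternative-uses task additionally
#' excluding the prompt's stated common use.
#'
#' @param answers character vector of raw answers (one response set).
#' @param task `"AUT"` or `"AFT"`.
#' @param common_use the prompt's common use (AUT only), or `NA`.
#' @return non-negative integer count.
#' @export
score_fluency <- function(answers, task = c("AUT", "AFT"),
                          common_use = NA_character_) {
  task <- match.arg(task)
  length(valid_answers(answers, task, common_use))
}

#' Originality by statistical infrequency
#'
#' Builds the answer-frequency table of one item from the pooled valid
#' answers of all participants (both sessions), after synonym
#' canonicalization.  An answer's originality is one minus its relative
#' frequency in that pool; a participant's item score is the mean over their
#' valid answers.
#'
#' @param pooled_answers character vector: every valid answer given for the
#'   item by any participant in any session (already validity-filtered per
#'   response set).
#' @param synonyms named character vector token -> canonical, or `NULL`.
#' @return a function of class `originality_scorer`: takes a character vector
#'   of answers and returns their originality scores in \[0, 1\].  The
#'   frequency table is exposed as attribute `"freq"`.
#' @export
originality_scorer <- function(pooled_answers, synonyms = NULL) {
  pool <- canonicalize(normalize_answer(pooled_answers), synonyms)
  pool <- pool[nzchar(pool)]
  if (!length(pool)) stop_input("empty answer pool: originality undefined")
  tab <- table(pool) / length(pool)
  f <- function(answers) {
    a <- canonicalize(normalize_answer(answers), synonyms)
    rf <- as.numeric(tab[a])
    rf[is.na(rf)] <- 0   # unseen answer: maximally infrequent
    1 - rf
  }
  attr(f, "freq") <- tab
  class(f) <- c("originality_scorer", class(f))
  f
}

# Resolve one answer to an embedding vector.  Exact (normalized) token match
# first; multi-word answers fall back to the mean of in-vocabulary word
# vectors.  Returns NULL when fully out of vocabulary.
answer_vector <- function(answer, emb) {
  a <- normalize_answer(answer)
  i <- match(a, rownames(emb))
  if (!is.na(i)) return(emb[i, ])
  parts <- strsplit(a, " ", fixed = TRUE)[[1L]]
  hit <- match(parts, rownames(emb))
  hit <- hit[!is.na(hit)]
  if (!length(hit)) return(NULL)
  colMeans(emb[hit, , drop = FALSE])
}

cosine_distance <- function(u, v) {
  1 - sum(u * v) / sqrt(sum(u^2) * sum(v^2))
}

#' Flexibility from embedding distances
#'
#' Mean pairwise cosine distance (1 - cosine similarity) among the distinct
#' canonical answer vectors of one response set; synonymous answers share a
#' vector and therefore contribute once.  Fewer than two usable vectors give
#' a score of 0.  The consecutive-pair variant averages distances between
#' successive answers in listing order instead.
#'
#' @param answers character vector of raw answers, in listing order.
#' @param embeddings embedding matrix with (normalized) tokens as rownames,
#'   or a data.frame with a `token` column followed by vector components.
#' @param synonyms named character vector token -> canonical, or `NULL`.
#' @param method `"pairwise"` (all unordered pairs, default) or
#'   `"consecutive"`.
#' @return numeric score >= 0, or `NA` when every answer is out of
#'   vocabulary (with a warning).
#' @export
score_flexibility <- function(answers, embeddings, synonyms = NULL,
                              method = c("pairwise", "consecutive")) {
  method <- match.arg(method)
  emb <- as_embedding_matrix(embeddings)
  a <- canonicalize(normalize_answer(answers), synonyms)
  a <- a[nzchar(a)]
  a <- a[!duplicated(a)]
  vecs <- lapply(a, answer_vector, emb = emb)
  keep <- !vapply(vecs, is.null, logical(1))
  if (length(a) && !any(keep)) {
    warning("all answers out of vocabulary; flexibility undefined")
    return(NA_real_)
  }
  vecs <- vecs[keep]
  m <- length(vecs)
  if (m < 2L) return(0)
  if (method == "pairwise") {
    d <- 0; np <- 0L
    for (i in 1:(m - 1L)) for (j in (i + 1L):m) {
      d <- d + cosine_distance(vecs[[i]], vecs[[j]]); np <- np + 1L
    }
    d / np
  } else {
    mean(vapply(seq_len(m - 1L), function(i) {
      cosine_distance(vecs[[i]], vecs[[i + 1L]])
    }, numeric(1)))
  }
}

as_embedding_matrix <- function(embeddings) {
  if (is.matrix(embeddings)) {
    emb <- embeddings
  } else if (is.data.frame(embeddings) && "token" %in% names(embeddings)) {
    emb <- as.matrix(embeddings[setdiff(names(embeddings), "token")])
    rownames(emb) <- embeddings$token
  } else {
    stop_input("`embeddings` must be a matrix with token rownames or a ",
               "data.frame with a token column")
  }
  rownames(emb) <- normalize_answer(rownames(emb))
  emb
}

#' Session-level aggregation of item scores
#'
#' Unweighted mean over the session's items, per measure.  Missing item
#' scores are dropped with a warning.
#'
#' @param item_scores data.frame with columns `item`, `fluency`,
#'   `flexibility`, `originality` (one row per item of the session).
#' @return one-row data.frame with the session means.
#' @export
aggregate_session <- function(item_scores) {
  meas <- c("fluency", "flexibility", "originality")
  if (anyNA(item_scores[meas])) {
    warning("missing item score(s); averaging over available items")
  }
  out <- lapply(item_scores[meas], mean, na.rm = TRUE)
  as.data.frame(out)
}

#' Score a full response table
#'
#' Runs fluency, originality (statistical infrequency, pooled per item over
#' all participants and both sessions) and flexibility scoring over a tidy
#' response table, then averages each measure over the session's items.
#'
#' @param responses data.frame with columns `participant`, `condition`,
#'   `task`, `item`, `answer_index`, `answer` (as written by
#'   [gen_behavior()]).
#' @param embeddings embedding table or matrix (see [score_flexibility()]).
#' @param synonyms named character vector token -> canonical, or `NULL`.
#' @param common_uses named character vector item -> stated common use (AUT
#'   validity predicate), or `NULL`.
#' @param flexibility_method passed to [score_flexibility()].
#' @return data.frame: participant, condition, task, fluency, flexibility,
#'   originality.
#' @export
score_responses <- function(responses, embeddings, synonyms = NULL,
                            common_uses = NULL,
                            flexibility_method = "pairwise") {
  need <- c("participant", "condition", "task", "item", "answer")
  if (!all(need %in% names(responses))) {
    stop_input("`responses` needs columns ", paste(need, collapse = ", "))
  }
  if ("answer_index" %in% names(responses)) {
    responses <- responses[order(responses$participant, responses$condition,
                                 responses$task, responses$item,
                                 responses$answer_index), ]
  }
  emb <- as_embedding_matrix(embeddings)

  # per-item originality scorers from the pooled valid answers
  scorers <- list()
  for (it in unique(responses$item)) {
    sel <- responses$item == it
    task <- responses$task[sel][1L]
    cu <- if (!is.null(common_uses)) common_uses[it] else NA_character_
    pieces <- split(responses$answer[sel],
                    interaction(responses$participant[sel],
                                responses$condition[sel], drop = TRUE))
    pooled <- unlist(lapply(pieces, valid_answers, task = task,
                            common_use = cu), use.names = FALSE)
    scorers[[it]] <- originality_scorer(pooled, synonyms)
  }

  keys <- unique(responses[c("participant", "condition", "task", "item")])
  item_rows <- lapply(seq_len(nrow(keys)), function(r) {
    k <- keys[r, ]
    sel <- responses$participant == k$participant &
      responses$condition == k$condition & responses$item == k$item
    ans <- responses$answer[sel]
    cu <- if (!is.null(common_uses)) common_uses[k$item] else NA_character_
    va <- valid_answers(ans, k$task, cu)
    data.frame(
      k,
      fluency = length(va),
      flexibility = score_flexibility(ans, emb, synonyms,
                                      method = flexibility_method),
      originality = if (length(va)) mean(scorers[[k$item]](va)) else NA_real_,
      stringsAsFactors = FALSE)
  })
  items <- do.call(rbind, item_rows)

  grp <- unique(items[c("participant", "condition", "task")])
  out <- lapply(seq_len(nrow(grp)), function(r) {
    g <- grp[r, ]
    sel <- items$participant == g$participant &
      items$condition == g$condition & items$task == g$task
    cbind(g, aggregate_session(items[sel, ]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
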