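#' Paired t-test
#'
#' Classical paired t statistic on two equal-length samples with
#' `df = n - 1` and a two-sided analytic p-value.  All-zero differences give
#' `t = 0, p = 1`; a nonzero constant difference (zero variance) is
#' degenerate and flagged.
#'
#' @param x,y paired numeric samples.
#' @return object of class `stat_result`: list with `statistic`, `df`, `p`,
#'   `n`, `degenerate`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop_input("paired samples must have equal length")
  n <- length(x)
  if (n < 2L) stop_input("need n >= 2 pairs")
  d <- x - y
  s <- stats::sd(d)
  if (s == 0) {
    if (all(d == 0)) {
      return(structure(list(statistic = 0, df = n - 1L, p = 1, n = n,
                            degenerate = FALSE), class = "stat_result"))
    }
    return(structure(list(statistic = sign(mean(d)) * Inf, df = n - 1L,
                          p = 0, n = n, degenerate = TRUE),
                     class = "stat_result"))
  }
  t <- mean(d) / (s / sqrt(n))
  structure(list(statistic = t, df = n - 1L,
                 p = 2 * stats::pt(-abs(t), n - 1L), n = n,
                 degenerate = FALSE),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4g%s\n", x$df, x$statistic, x$p,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values with enforced monotonicity, capped at 1.  The
#' Benjamini-Yekutieli variant (valid under arbitrary dependence) is
#' available by flag.
#'
#' @param p numeric vector of raw p-values in (0, 1\].
#' @param method `"BH"` (default) or `"BY"`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
fdr_bh <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (!length(p)) return(numeric(0))
  if (any(p <= 0 | p > 1, na.rm = TRUE)) stop_input("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = method)
}

#' Edge-wise permutation paired t-tests
#'
#' For every edge, the observed statistic is the paired t on the per-subject
#' difference of condition deltas (e.g. post-pre IC change under tRNS minus
#' under sham).  The permutation null flips the sign of each subject's whole
#' difference vector at random -- flips are shared across edges within a
#' permutation, preserving the edge correlation structure -- which is the
#' exact exchangeability scheme for a paired design under the null of no
#' condition effect.  The Monte-Carlo two-sided p-value uses the +1
#' correction, `p = (1 + #\{|t*| >= |t|\}) / (1 + n_perm)`, so p is always
#' positive.
#'
#' @param delta_a,delta_b numeric matrices, subjects x edges: the per-subject
#'   per-edge deltas under each condition (same dimensions and edge order).
#' @param n_perm number of Monte-Carlo draws from the permutation
#'   distribution (5000 in the reference analysis).
#' @param seed integer seed for the sign flips.
#' @param edge_names optional character vector of edge labels.
#' @return data.frame with one row per edge: `edge`, `t`, `df`, `p`,
#'   `p_fdr` (Benjamini-Hochberg over all edges), `sign`; attributes
#'   `n_perm`, `seed`, `n_subjects`.
#' @export
perm_paired_edges <- function(delta_a, delta_b, n_perm = 5000, seed = NULL,
                              edge_names = NULL) {
  if (!is.matrix(delta_a)) delta_a <- matrix(delta_a, ncol = 1L)
  if (!is.matrix(delta_b)) delta_b <- matrix(delta_b, ncol = 1L)
  if (!all(dim(delta_a) == dim(delta_b))) {
    stop_input("condition delta matrices must have identical dimensions")
  }
  n <- nrow(delta_a)
  if (n < 2L) stop_input("need >= 2 subjects")
  if (n_perm < 1L) stop_input("`n_perm` must be >= 1")
  d <- delta_a - delta_b                   # subjects x edges
  m <- ncol(d)
  edge_names <- edge_names %||% colnames(d) %||% sprintf("edge%04d", seq_len(m))

  ss <- colSums(d^2)                       # invariant under sign flips
  t_of <- function(means) {
    var_d <- pmax(ss - n * means^2, 0) / (n - 1L)
    out <- means / sqrt(var_d / n)
    out[var_d == 0 & means == 0] <- 0
    out
  }
  t_obs <- t_of(colMeans(d))

  if (!is.null(seed)) set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  M <- (signs %*% d) / n                   # n_perm x edges permuted means
  exceed <- integer(m)
  for (k in seq_len(n_perm)) {             # row-wise keeps memory flat
    exceed <- exceed + (abs(t_of(M[k, ])) >= abs(t_obs))
  }
  p <- (1 + exceed) / (1 + n_perm)

  res <- data.frame(edge = edge_names, t = t_obs, df = n - 1L, p = p,
                    p_fdr = fdr_bh(p), sign = sign(t_obs),
                    stringsAsFactors = FALSE)
  attr(res, "n_perm") <- n_perm
  attr(res, "seed") <- seed
  attr(res, "n_subjects") <- n
  res
}

#' Flatten per-subject IC (or IC-change) matrices to an edge table
#'
#' Stacks the upper triangle of each subject's symmetric scout matrix into a
#' subjects x edges matrix whose columns are the unordered scout pairs
#' (1891 edges for 62 scouts).
#'
#' @param mats list of symmetric matrices, one per subject (identical
#'   dimensions).
#' @return numeric matrix subjects x edges with `"a|b"` column names;
#'   attribute `"pairs"` holds the two-column index matrix.
#' @export
flatten_edges <- function(mats) {
  if (!length(mats)) stop_input("no matrices supplied")
  n <- nrow(mats[[1L]])
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ut <- ut[order(ut[, 1L], ut[, 2L]), , drop = FALSE]
  nms <- rownames(mats[[1L]]) %||% as.character(seq_len(n))
  # upper.tri linearizes column-wise; rebuild in (row, col) sorted order
  lin <- matrix(seq_len(n * n), n, n)
  idx <- lin[upper.tri(lin)]
  ord <- order(((idx - 1L) %% n) + 1L, ((idx - 1L) %/% n) + 1L)
  out <- t(vapply(mats, function(m) m[upper.tri(m)][ord], numeric(length(idx))))
  colnames(out) <- paste(nms[ut[, 1L]], nms[ut[, 2L]], sep = "|")
  attr(out, "pairs") <- ut
  out
}

ols_fit <- function(data, response, predictors) {
  fml <- stats::reformulate(if (length(predictors)) predictors else "1",
                            response = response)
  fit <- stats::lm(fml, data = data)
  sm <- summary(fit)
  co <- stats::coef(sm)
  terms <- setdiff(rownames(co), "(Intercept)")
  sy <- stats::sd(data[[response]])
  beta <- vapply(terms, function(tm) {
    co[tm, "Estimate"] * stats::sd(data[[tm]]) / sy
  }, numeric(1))
  model_p <- if (length(terms)) {
    fstat <- sm$fstatistic
    stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
  } else NA_real_
  list(fit = fit, summary = sm,
       coefficients = data.frame(
         term = rownames(co), B = co[, "Estimate"], SE_B = co[, "Std. Error"],
         beta = c(NA_real_, beta)[match(rownames(co), c("(Intercept)", terms))],
         p = co[, "Pr(>|t|)"], row.names = NULL, stringsAsFactors = FALSE),
       r_squared = sm$r.squared, model_p = unname(model_p))
}

#' Backward-elimination multiple regression
#'
#' Starts from the full ordinary-least-squares model and iteratively removes
#' the predictor with the largest p-value above `removal_p` until every
#' retained predictor satisfies `p <= removal_p` (possibly leaving the
#' intercept-only model).  Reports unstandardized coefficients (B), their
#' standard errors, standardized coefficients (beta = B * sd(x) / sd(y)),
#' the model R-squared and F-test p-value, and the full elimination trace.
#'
#' @param data data.frame holding response and predictors.
#' @param response name of the response column.
#' @param predictors character vector of predictor column names.
#' @param removal_p removal threshold: a predictor is eliminated while its
#'   p-value exceeds this (0.10 by default; 1 keeps the full model, 0
#'   reduces to intercept-only).
#' @return object of class `regression_result`: list with `retained`,
#'   `coefficients` (term, B, SE_B, beta, p), `r_squared`, `model_p`,
#'   `trace` (step, removed, p_at_removal), `n`, `removal_p`.
#' @export
backward_regression <- function(data, response, predictors, removal_p = 0.10) {
  if (!response %in% names(data)) stop_input("response not found in data")
  if (!all(predictors %in% names(data))) stop_input("predictor(s) not found in data")
  n <- nrow(data)
  if (n < length(predictors) + 2L) {
    stop_input("need n >= number of predictors + 2")
  }
  X <- as.matrix(data[predictors])
  if (length(predictors) && qr(cbind(1, X))$rank < length(predictors) + 1L) {
    stop_input("singular design among predictors: ",
               paste(predictors, collapse = ", "))
  }
  current <- predictors
  trace <- data.frame(step = integer(), removed = character(),
                      p_at_removal = numeric(), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    m <- ols_fit(data, response, current)
    pv <- m$coefficients$p[m$coefficients$term != "(Intercept)"]
    names(pv) <- m$coefficients$term[m$coefficients$term != "(Intercept)"]
    if (!length(pv) || max(pv) <= removal_p) break
    worst <- names(pv)[which.max(pv)]
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, removed = worst,
                                     p_at_removal = unname(max(pv)),
                                     stringsAsFactors = FALSE))
    current <- setdiff(current, worst)
  }
  structure(list(retained = current, coefficients = m$coefficients,
                 r_squared = m$r_squared, model_p = m$model_p,
                 trace = trace, n = n, removal_p = removal_p),
            class = "regression_result")
}

#' Simple linear regression
#'
#' One-predictor OLS; the standardized coefficient equals the Pearson
#' correlation and R-squared equals its square.
#'
#' @param data data.frame.
#' @param response,predictor column names.
#' @return a `regression_result` (see [backward_regression()]).
#' @export
simple_regression <- function(data, response, predictor) {
  if (nrow(data) < 3L) stop_input("need n >= 3")
  if (stats::sd(data[[predictor]]) == 0) {
    stop_input("zero-variance predictor '", predictor, "'")
  }
  m <- ols_fit(data, response, predictor)
  structure(list(retained = predictor, coefficients = m$coefficients,
                 r_squared = m$r_squared, model_p = m$model_p,
                 trace = data.frame(step = integer(), removed = character(),
                                    p_at_removal = numeric()),
                 n = nrow(data), removal_p = NA_real_),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> n = %d, R^2 = %.3f, model p = %.4g\n",
              x$n, x$r_squared, x$model_p))
  cat("  retained:", if (length(x$retained)) paste(x$retained, collapse = ", ")
      else "(intercept only)", "\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}
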