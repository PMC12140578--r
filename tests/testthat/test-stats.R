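test_that("paired t matches the textbook formula and handles degeneracy", {
  x <- c(2, 4, 6, 8); y <- c(1, 2, 3, 4)   # differences 1,2,3,4
  r <- paired_t(x, y)
  expect_equal(r$statistic, 2.5 / (sqrt(5 / 3) / 2), tolerance = 1e-12)
  expect_equal(r$statistic, 3.873, tolerance = 1e-3)
  expect_equal(r$df, 3)
  expect_equal(r$p, unname(t.test(x, y, paired = TRUE)$p.value))

  r0 <- paired_t(1:5, 1:5)
  expect_equal(r0$statistic, 0); expect_equal(r0$p, 1)
  rc <- paired_t(1:5 + 2, 1:5)           # constant nonzero difference
  expect_true(rc$degenerate)
  expect_error(paired_t(1:3, 1:2), class = "icnet_input_error")
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_bh(0.2), 0.2)
  expect_identical(fdr_bh(numeric(0)), numeric(0))
  # hand oracle on an unsorted vector: p * m / rank, running minimum from the top
  set.seed(18)
  p <- runif(20)
  o <- order(p); m <- length(p)
  stepup <- pmin(rev(cummin(rev(p[o] * m / seq_len(m)))), 1)
  oracle <- numeric(m); oracle[o] <- stepup
  expect_equal(fdr_bh(p), oracle)
  # monotone in raw-p rank, capped at 1
  adj <- fdr_bh(p)
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_true(all(adj <= 1))
  expect_error(fdr_bh(c(0, 0.5)), class = "icnet_input_error")
})

test_that("Monte-Carlo permutation p agrees with exhaustive sign-flip enumeration", {
  set.seed(19)
  d <- c(0.8, 0.3, -0.2, 0.6, 0.4)       # n = 5 paired differences
  tstat <- function(v) mean(v) / (sd(v) / sqrt(length(v)))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 5)))
  t_null <- apply(signs, 1, function(s) tstat(s * d))
  p_exact <- mean(abs(t_null) >= abs(tstat(d)))

  res <- perm_paired_edges(matrix(d, ncol = 1), matrix(0, 5, 1),
                           n_perm = 5000, seed = 20)
  expect_equal(res$p, p_exact, tolerance = 0.02)  # within MC binomial error
  expect_equal(res$t, tstat(d), tolerance = 1e-12)

  # all-zero differences on an edge -> p = 1
  res0 <- perm_paired_edges(matrix(0, 5, 2), matrix(0, 5, 2), n_perm = 200,
                            seed = 21)
  expect_equal(res0$p, c(1, 1))
  # reproducible under seed
  resa <- perm_paired_edges(matrix(d, ncol = 1), matrix(0, 5, 1),
                            n_perm = 500, seed = 7)
  resb <- perm_paired_edges(matrix(d, ncol = 1), matrix(0, 5, 1),
                            n_perm = 500, seed = 7)
  expect_identical(resa$p, resb$p)
  expect_error(perm_paired_edges(matrix(1, 1, 2), matrix(0, 1, 2)),
               class = "icnet_input_error")
})

test_that("flatten_edges stacks upper triangles in scout-pair order", {
  m1 <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  m1[upper.tri(m1)] <- c(12, 13, 23); m1 <- m1 + t(m1)
  m2 <- m1 * 2
  fl <- flatten_edges(list(m1, m2))
  expect_equal(colnames(fl), c("a|b", "a|c", "b|c"))
  expect_equal(unname(fl[1, ]), c(12, 13, 23))
  expect_equal(unname(fl[2, ]), c(24, 26, 46))
})

test_that("backward elimination honours the removal threshold", {
  set.seed(22)
  n <- 40
  df <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  df$y <- 0.5 * df$x1 + rnorm(n)
  full <- backward_regression(df, "y", c("x1", "x2", "x3"), removal_p = 1)
  expect_setequal(full$retained, c("x1", "x2", "x3"))
  none <- backward_regression(df, "y", c("x1", "x2", "x3"), removal_p = 0)
  expect_length(none$retained, 0)
  expect_equal(nrow(none$trace), 3)

  # single significant predictor reduces to simple OLS closed forms
  one <- backward_regression(df, "y", "x1", removal_p = 0.1)
  b_hat <- cov(df$x1, df$y) / var(df$x1)
  resid <- df$y - mean(df$y) - b_hat * (df$x1 - mean(df$x1))
  se_hat <- sqrt(sum(resid^2) / (n - 2)) / (sd(df$x1) * sqrt(n - 1))
  co <- one$coefficients[one$coefficients$term == "x1", ]
  expect_equal(co$B, b_hat, tolerance = 1e-10)
  expect_equal(co$SE_B, se_hat, tolerance = 1e-10)
  expect_equal(one$r_squared, cor(df$x1, df$y)^2, tolerance = 1e-10)

  # standardized beta equals the slope on z-scored variables
  zdf <- as.data.frame(scale(df))
  zfit <- lm(y ~ x1 + x2 + x3, zdf)
  multi <- backward_regression(df, "y", c("x1", "x2", "x3"), removal_p = 1)
  expect_equal(multi$coefficients$beta[match(c("x1", "x2", "x3"),
                                             multi$coefficients$term)],
               unname(coef(zfit)[c("x1", "x2", "x3")]), tolerance = 1e-10)

  expect_error(backward_regression(df, "y", c("x1", "x1b")),
               class = "icnet_input_error")
  df$x1b <- df$x1
  expect_error(backward_regression(df, "y", c("x1", "x1b")),
               class = "icnet_input_error")   # singular design
})

test_that("backward elimination recovers a true slope and rejects pure noise", {
  set.seed(23)
  hits <- 0L; null_keep <- 0L
  for (k in 1:50) {
    n <- 40
    df <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
    df$y <- 0.5 * df$x1 + rnorm(n)
    fit <- backward_regression(df, "y", c("x1", "x2", "x3"))
    hits <- hits + ("x1" %in% fit$retained)
    dfn <- df; dfn$y <- rnorm(n)
    fitn <- backward_regression(dfn, "y", c("x1", "x2", "x3"))
    null_keep <- null_keep + (length(fitn$retained) == 0)
  }
  expect_gte(hits, 40)        # >= 80% of 50 replicates
  expect_gt(null_keep, 25)    # intercept-only in the majority under the null
})

test_that("simple regression reports beta = r and R^2 = r^2", {
  df <- data.frame(x = 1:10)
  df$y <- 2 * df$x
  # exact fit: summary.lm warns about a perfect fit, which is the point here
  r <- suppressWarnings(simple_regression(df, "y", "x"))
  expect_equal(r$coefficients$beta[r$coefficients$term == "x"], 1)
  expect_equal(r$r_squared, 1)
  # constructed orthogonal predictor
  df2 <- data.frame(x = c(-1, 0, 1, -1, 0, 1), y = c(1, -2, 1, 1, -2, 1))
  r2 <- simple_regression(df2, "y", "x")
  expect_equal(r2$coefficients$beta[r2$coefficients$term == "x"], 0)
  expect_equal(r2$r_squared, 0)
  # 10-point toy set against closed-form least squares
  set.seed(24)
  df3 <- data.frame(x = rnorm(10), y = rnorm(10))
  r3 <- simple_regression(df3, "y", "x")
  expect_equal(r3$coefficients$B[2], cov(df3$x, df3$y) / var(df3$x),
               tolerance = 1e-12)
  expect_equal(r3$coefficients$beta[2], cor(df3$x, df3$y), tolerance = 1e-12)
  expect_error(simple_regression(data.frame(x = rep(1, 5), y = 1:5), "y", "x"),
               class = "icnet_input_error")
})
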