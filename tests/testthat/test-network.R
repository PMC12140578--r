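test_that("weighted node degree equals row sums of the zero-diagonal matrix", {
  m <- matrix(c(0, .1, .2, .1, 0, .3, .2, .3, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(weighted_node_degree(m), c(a = 0.3, b = 0.4, c = 0.5))
  expect_equal(unname(weighted_node_degree(matrix(0, 4, 4))), rep(0, 4))

  set.seed(14)
  n <- 62
  ic <- matrix(runif(n * n), n, n); ic <- (ic + t(ic)) / 2; diag(ic) <- 0
  oracle <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    oracle[i] <- oracle[i] + ic[i, j]
  }
  expect_equal(unname(weighted_node_degree(ic)), oracle)
  # complete graph with constant IC c: wnd = 61 c everywhere
  const <- matrix(0.2, n, n); diag(const) <- 0
  expect_equal(unname(weighted_node_degree(const)), rep(61 * 0.2, n))
})

test_that("z-normalization uses the sample sd and is affine-invariant", {
  expect_equal(z_normalize(c(0.3, 0.4, 0.5)), c(-1, 0, 1))
  set.seed(15)
  w <- runif(62)
  expect_equal(z_normalize(3 * w + 7), z_normalize(w))
  expect_equal(z_normalize(w), (w - mean(w)) / sd(w))
  expect_equal(mean(z_normalize(w)), 0, tolerance = 1e-12)
  expect_equal(sd(z_normalize(w)), 1, tolerance = 1e-12)
  expect_error(z_normalize(rep(0.5, 10)), class = "icnet_degenerate_error")
})

test_that("region means average z-scores over atlas scouts", {
  atlas <- tiny_atlas(8, 2)   # frontal_left = s01 s02, frontal_right = s05 s06
  z <- c(s01 = 1.0, s02 = -0.5, s03 = 2, s04 = 0, s05 = 0.3, s06 = 0.7,
         s07 = -1, s08 = -2.5)
  expect_equal(region_mean(z, atlas, "frontal_left"), 0.25)
  expect_equal(region_mean(z, atlas, "frontal_right"), 0.5)
  expect_error(region_mean(z, atlas, "occipital"),
               class = "icnet_config_error")
  # full-brain region of any z-normalized vector averages to ~0
  zz <- z_normalize(runif(8))
  names(zz) <- names(z)
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(scouts = data.frame(name = names(z),
                                                hemisphere = rep(c("L", "R"), each = 4),
                                                lobe = "x"),
                            region_sets = list(all = names(z))),
                       path, auto_unbox = TRUE)
  expect_equal(region_mean(zz, load_atlas(path), "all"), 0, tolerance = 1e-12)
})

test_that("degenerate wND yields missing region metrics with a warning", {
  atlas <- tiny_atlas(8, 2)
  const <- matrix(0.2, 8, 8); diag(const) <- 0
  dimnames(const) <- list(atlas$scout_names, atlas$scout_names)
  icm <- structure(list(ic = const, band = c(8, 12),
                        scout_names = atlas$scout_names, n_windows = 5),
                   class = "ic_matrix")
  expect_warning(nm <- network_metrics(icm, atlas), "zero wND")
  expect_true(all(is.na(nm$z)))
  expect_true(all(is.na(nm$region_means)))
  expect_equal(unname(nm$wnd), rep(7 * 0.2, 8))
})

test_that("change scores implement the difference-of-differences algebra", {
  grid <- expand.grid(subject = "s1", condition = c("tRNS", "sham"),
                      timepoint = c("pre", "post"), region = "frontal_left",
                      stringsAsFactors = FALSE)
  grid$value <- c(0.2, 0.4, 1.0, 0.5)  # tRNS pre, sham pre, tRNS post, sham post
  ct <- change_scores(grid)
  expect_equal(ct$network$delta_tRNS, 0.8)
  expect_equal(ct$network$delta_sham, 0.1)
  expect_equal(ct$network$wnd_change, 0.7)

  # identical conditions -> zero change
  grid2 <- grid; grid2$value <- c(0.3, 0.3, 0.9, 0.9)
  expect_equal(change_scores(grid2)$network$wnd_change, 0)

  # antisymmetric under swapping condition labels
  grid3 <- grid
  grid3$condition <- ifelse(grid$condition == "tRNS", "sham", "tRNS")
  expect_equal(change_scores(grid3)$network$wnd_change,
               -ct$network$wnd_change)

  # missing cell excludes the subject with a warning
  expect_warning(ct4 <- change_scores(grid[-1, ]), "incomplete")
  expect_null(ct4$network)

  # behavioral change = tRNS - sham
  beh <- data.frame(participant = "p1", condition = c("tRNS", "sham"),
                    task = "AUT", measure = "originality",
                    value = c(0.8, 0.6))
  ct5 <- change_scores(grid, beh)
  expect_equal(ct5$behavior$change, 0.2)
})

test_that("the packaged atlas defines 62 scouts with frontal region sets", {
  atlas <- load_atlas()
  expect_length(atlas$scout_names, 62)
  expect_false(anyDuplicated(atlas$scout_names) > 0)
  expect_setequal(names(atlas$region_sets), c("frontal_left", "frontal_right"))
  expect_equal(length(atlas$region_sets$frontal_left),
               length(atlas$region_sets$frontal_right))
  expect_true(all(grepl("_L$", atlas$region_sets$frontal_left)))
  expect_true(all(grepl("_R$", atlas$region_sets$frontal_right)))
})
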