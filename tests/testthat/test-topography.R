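test_that("anosim matches hand-worked and brute-force rank oracles", {
  # A = {0, 1}, B = {10, 11} on a line: within ranks {1.5, 1.5},
  # between {3, 4.5, 4.5, 6} -> R = (4.5 - 1.5) / 3 = 1
  d <- as.matrix(dist(c(0, 1, 10, 11)))
  res <- anosim(d, c("A", "A", "B", "B"), n_perm = 99, seed = 1)
  expect_equal(res$R, 1)
  # all points identical -> all ranks tied -> R = 0
  expect_equal(anosim(matrix(0, 6, 6), rep(c("a", "b"), 3), n_perm = 9,
                      seed = 1)$R, 0)
  # random data vs exhaustive double-loop oracle, several cases
  set.seed(3)
  for (i in 1:4) {
    pts <- matrix(rnorm(16), 8, 2)
    labs <- rep(c("a", "b"), each = 4)
    dd <- as.matrix(dist(pts))
    expect_equal(anosim(dd, labs, n_perm = 9, seed = i)$R,
                 anosim_oracle(dd, labs))
  }
  # perfectly separated 1-D groups of unequal sizes
  x <- c(0, 0.5, 1, 10, 11)
  labs <- c("a", "a", "a", "b", "b")
  dd <- as.matrix(dist(x))
  expect_equal(anosim(dd, labs, n_perm = 9, seed = 1)$R,
               anosim_oracle(dd, labs))
  # monotone-transform invariance of R
  expect_equal(anosim(dd^3, labs, n_perm = 9, seed = 1)$R,
               anosim(dd, labs, n_perm = 9, seed = 1)$R)
  # p-value add-one convention: never exactly 0
  set.seed(9)
  big <- anosim(as.matrix(dist(c(rnorm(5), rnorm(5) + 50))),
                rep(c("a", "b"), each = 5), n_perm = 999, seed = 2)
  expect_gte(big$p, 1 / 1000)
  expect_error(anosim(dd, c("a", "a", "a", "a", "b"), n_perm = 9, seed = 1),
               ">= 2 members")
})

test_that("anosim agrees with the vegan reference implementation", {
  skip_if_not_installed("vegan")
  set.seed(8)
  pts <- matrix(rnorm(40), 20, 2)
  labs <- rep(c("a", "b", "c", "d"), each = 5)
  mine <- anosim(as.matrix(dist(pts)), labs, n_perm = 49, seed = 1)$R
  ref <- suppressWarnings(vegan::anosim(dist(pts), labs,
                                        permutations = 9))$statistic
  expect_equal(mine, unname(ref), tolerance = 1e-12)
})

test_that("anosim null p-values are approximately uniform", {
  # labels assigned at random; add-one permutation p should be uniform
  set.seed(12)
  ps <- vapply(1:300, function(i) {
    pts <- matrix(rnorm(24), 12, 2)
    labs <- sample(rep(c("a", "b"), each = 6))
    anosim(as.matrix(dist(pts)), labs, n_perm = 199, seed = 1000 + i)$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("peak location tests find planted single-axis shifts", {
  set.seed(5)
  n <- 300
  a <- cbind(R = rnorm(n), A = rnorm(n), S = rnorm(n))
  b <- cbind(R = rnorm(n), A = rnorm(n) + 10, S = rnorm(n))
  pk <- tibble::tibble(label = rep(c("g1", "g2"), each = n),
                       R = c(a[, 1], b[, 1]), A = c(a[, 2], b[, 2]),
                       S = c(a[, 3], b[, 3]))
  res <- peak_location_tests(pk)
  kw <- dplyr::filter(res, test == "kruskal_wallis")
  expect_true(kw$significant[kw$axis == "A"])
  expect_false(any(kw$significant[kw$axis != "A"]))
  expect_true(attr(res, "joint_significant"))
  # Bonferroni multiplies by the family size, capped at 1
  expect_equal(kw$p_bonferroni,
               pmin(1, kw$p_value * 3))
  mw <- dplyr::filter(res, test == "mann_whitney")
  expect_equal(mw$p_bonferroni, pmin(1, mw$p_value * nrow(mw)))
})

test_that("identical-distribution groups rarely reach significance", {
  rejections <- vapply(1:60, function(i) {
    set.seed(2000 + i)
    pk <- tibble::tibble(label = rep(c("g1", "g2"), each = 40),
                         R = rnorm(80), A = rnorm(80), S = rnorm(80))
    attr(peak_location_tests(pk), "joint_significant")
  }, logical(1))
  expect_lte(mean(rejections), 0.25)   # nominal ~5% with 3 Bonferroni axes
})

test_that("explicit-parameter mixture AIC prefers the generative model", {
  set.seed(31)
  one <- matrix(rnorm(300), 100, 3)
  labs3 <- rep(c("a", "b", "c"), length.out = 100)
  cm1 <- compare_mixtures(one, labs3, ks = c(1, 3))
  expect_lt(cm1$aic[cm1$k == 1], cm1$aic[cm1$k == 3])
  three <- rbind(matrix(rnorm(150), 50, 3),
                 sweep(matrix(rnorm(150), 50, 3), 2, c(15, 0, 0), "+"),
                 sweep(matrix(rnorm(150), 50, 3), 2, c(0, 15, 15), "+"))
  labs <- rep(c("a", "b", "c"), each = 50)
  cm3 <- compare_mixtures(three, labs, ks = c(1, 3))
  expect_lt(cm3$aic[cm3$k == 3], cm3$aic[cm3$k == 1])
  expect_lt(cm3$relative_likelihood[cm3$k == 1], 0.05)
  # AIC formula: 2 * df - 2 * logLik
  fit <- mixture_aic(three, labs, 3)
  expect_equal(fit$aic, 2 * fit$df - 2 * fit$log_likelihood)
  expect_equal(fit$df, 3 * 10 - 1)
  expect_error(mixture_aic(three, labs, 2), "number of groups")
  expect_error(mixture_aic(three[1:6, ], rep(c("a", "b"), 3), 2),
               ">= 4 points")
})

test_that("dice overlap satisfies its defining identities", {
  a <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1))
  b <- array(c(TRUE, FALSE, TRUE, FALSE), c(2, 2, 1))
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, !a), 0)
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(array(FALSE, c(2, 2, 1)), array(FALSE, c(2, 2, 1))), 0)
  expect_equal(dice(a, b), dice(b, a))
  expect_error(dice(a, array(TRUE, c(3, 2, 1))), "grids")
})

test_that("harvest_peaks returns the requested number of labelled peaks", {
  spec <- signal_spec(grid_shape = c(10, 10, 10), seed = 41, regions =
    tibble::tibble(level = c("familiarity", "subcategory"),
                   R = c(1.75, 1.75), A = c(-5.25, 5.25), S = c(1.75, 1.75),
                   radius = 7, amplitude = 1))
  d <- generate_design(8, seed = 41)
  mask <- analysis_box_mask(spec, margin = 7)
  nb <- build_neighborhoods(mask, k = 30, grid_shape = spec$grid_shape,
                            affine = spec$affine)
  pats <- lapply(1:2, function(s) {
    generate_patterns(d, spec, noise_sd = 3, seed = 500 + s,
                      conditions = "categories", voxels = mask)
  })
  pk_u <- harvest_peaks(pats, nb, "univariate_contrast", n_perm = 7,
                        seed = 3)
  expect_equal(nrow(pk_u), 7)
  expect_true(all(pk_u$label == "familiarity"))
  pk_s <- harvest_peaks(pats, nb, "subcategory_searchlight", n_perm = 6,
                        seed = 3)
  expect_equal(nrow(pk_s), 6)
  # peaks lie inside the analysis mask
  xyz <- voxel_to_mm(mask, spec$grid_shape, spec$affine)
  expect_true(all(pk_s$R %in% xyz[, 1] & pk_s$A %in% xyz[, 2] &
                    pk_s$S %in% xyz[, 3]))
  # noiseless limit (univariate path, single planted region): contrast t is
  # +Inf exactly on positive-template region voxels and 0/0 elsewhere, so
  # every permutation peaks at the same voxel, inside the region
  spec1 <- signal_spec(grid_shape = c(10, 10, 10), seed = 41, regions =
    tibble::tibble(level = "familiarity", R = 1.75, A = -5.25, S = 1.75,
                   radius = 7, amplitude = 1))
  pats0 <- list(generate_patterns(d, spec1, noise_sd = 0, seed = 1,
                                  conditions = "categories", voxels = mask))
  pk0 <- harvest_peaks(pats0, nb, "univariate_contrast", n_perm = 6,
                       seed = 3)
  expect_equal(nrow(dplyr::distinct(pk0[, c("R", "A", "S")])), 1L)
  expect_lte(sqrt((pk0$R[1] - 1.75)^2 + (pk0$A[1] + 5.25)^2 +
                    (pk0$S[1] - 1.75)^2), 7 + 1e-6)
})
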