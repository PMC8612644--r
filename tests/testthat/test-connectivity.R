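test_that("nuisance residualization annihilates its own column space", {
  gs <- c(4, 4, 2)
  aff <- default_affine(gs)
  n_t <- 60
  set.seed(1)
  stim <- sin(seq_len(n_t) / 3)
  mot <- matrix(rnorm(n_t * 2), n_t, 2)
  # data built purely from nuisance columns
  W <- cbind(1, stim, mot)
  Y <- W %*% matrix(rnorm(4 * 10), 4, 10)
  ts <- voxel_timeseries(Y, tr = 2, run = 1, voxels = 1:10, grid_shape = gs,
                         affine = aff)
  expect_warning(
    res <- nuisance_residualize(list(ts), stimulus_regressor = list(stim),
                                motion = list(mot)),
    NA)
  # residuals ~ 0 before z-scoring would make z-scores NA; accept NA or tiny
  raw <- Y - W %*% qr.coef(qr(W), Y)
  expect_lt(max(abs(raw)), 1e-8)
  # with noise added, residuals orthogonal to all regressors
  Y2 <- Y + matrix(rnorm(n_t * 10), n_t, 10)
  ts2 <- voxel_timeseries(Y2, tr = 2, run = 1, voxels = 1:10,
                          grid_shape = gs, affine = aff)
  r2 <- nuisance_residualize(list(ts2), stimulus_regressor = list(stim),
                             motion = list(mot))
  raw2 <- Y2 - W %*% qr.coef(qr(W), Y2)
  Wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  expect_lt(max(abs(crossprod(Wn, raw2))), 1e-6)
  # z-scored per voxel
  expect_equal(unname(colMeans(r2$data)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(r2$data, 2, sd)), rep(1, 10), tolerance = 1e-12)
})

test_that("tissue PCs match a brute-force eigendecomposition oracle", {
  set.seed(2)
  n_t <- 50
  wm <- matrix(rnorm(n_t * 12), n_t, 12) %*% diag(c(5, 4, 3, 2, 1,
                                                    rep(0.1, 7)))
  pcs <- prcomp(wm, center = TRUE, scale. = FALSE)$x[, 1:5]
  # oracle: eigenvectors of the covariance matrix
  cc <- cov(wm)
  ev <- eigen(cc, symmetric = TRUE)$vectors[, 1:5]
  scores <- scale(wm, scale = FALSE) %*% ev
  # same subspace: projection distance ~ 0
  q1 <- qr.Q(qr(pcs)); q2 <- qr.Q(qr(scores))
  expect_lt(max(abs(tcrossprod(q1) - tcrossprod(q2))), 1e-6)
})

test_that("fisher transform is odd and matches its closed form", {
  r <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(fisher_z(-r), -fisher_z(r), tolerance = 1e-12)
  expect_equal(fisher_z(0.12), 0.5 * log(1.12 / 0.88), tolerance = 1e-15)
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(1), Inf)
})

test_that("seed maps correlate, threshold, and flag degenerate voxels", {
  gs <- c(4, 4, 2)
  aff <- default_affine(gs)
  set.seed(3)
  Y <- matrix(rnorm(80 * 8), 80, 8)
  Y[, 2] <- Y[, 1]                 # identical to seed voxel
  Y[, 3] <- 5                      # zero variance
  ts <- voxel_timeseries(Y, tr = 2, run = 1, voxels = 1:8, grid_shape = gs,
                         affine = aff)
  res <- structure(list(data = Y, run_boundaries = 1L, voxels = 1:8,
                        grid_shape = gs, affine = aff),
                   class = "residual_series")
  cm <- seed_map(res, seed_mask = c(TRUE, rep(FALSE, 7)))
  expect_equal(cm$r[1], 1)
  expect_equal(cm$r[2], 1)
  expect_true(is.infinite(cm$z[1]))
  expect_true(is.na(cm$r[3]))
  expect_equal(cm$mask, !is.na(cm$r) & cm$r >= 0.12)
  expect_error(seed_map(res, rep(FALSE, 8)), "empty")
})

test_that("winner-take-all recovers a planted four-zone partition", {
  gs <- c(5, 5, 4)
  aff <- default_affine(gs)
  dat <- generate_connectivity_dataset(n_time = 120, n_runs = 4,
                                       voxels = 1:100, grid_shape = gs,
                                       affine = aff, snr = 1, seed = 7)
  res <- nuisance_residualize(dat$ts_list)
  amask <- Reduce(`|`, lapply(dat$seed_masks,
                              function(m) seed_map(res, m)$mask))
  wta <- winner_take_all(res, dat$seed_masks, amask)
  truth <- paste0("seed", dat$zone[match(wta$voxel, 1:100)])
  expect_gte(mean(wta$winner == truth), 0.95)
})

test_that("winner-take-all tie-breaking and collinearity guards work", {
  gs <- c(4, 2, 1)
  aff <- default_affine(gs)
  set.seed(4)
  s1 <- rnorm(40); s2 <- rnorm(40)
  Y <- cbind(s1, s2, s1 + s2, s1 + s2)  # equal-mix voxels
  res <- structure(list(data = Y, run_boundaries = 1L, voxels = 1:4,
                        grid_shape = gs, affine = aff),
                   class = "residual_series")
  masks <- list(a = c(TRUE, FALSE, FALSE, FALSE),
                b = c(FALSE, TRUE, FALSE, FALSE))
  wta <- winner_take_all(res, masks, rep(TRUE, 4))
  # exact tie at the equal-mix voxels goes to the lowest seed index
  expect_equal(wta$winner[3], "a")
  expect_equal(wta$winner[4], "a")
  # collinear seeds rejected with names
  masks2 <- list(a = c(TRUE, FALSE, FALSE, FALSE),
                 dup = c(FALSE, FALSE, TRUE, FALSE),
                 b = c(FALSE, TRUE, FALSE, FALSE))
  res2 <- res
  res2$data[, 3] <- s1
  expect_error(winner_take_all(res2, masks2, rep(TRUE, 4)),
               "collinear.*a.*dup")
})

test_that("seed balls and planted coupling behave as expected", {
  gs <- c(6, 6, 6)
  aff <- default_affine(gs)
  masks <- seed_ball_masks(rbind(p1 = c(0, 0, 0)), voxels = 1:216,
                           grid_shape = gs, affine = aff, radius = 5)
  xyz <- voxel_to_mm(1:216, gs, aff)
  expect_equal(masks$p1,
               sqrt(rowSums(xyz^2)) <= 5)
  # ROI-coupling analogue: a zone correlates most with its own seed
  dat <- generate_connectivity_dataset(n_time = 100, n_runs = 3,
                                       voxels = 1:80, grid_shape = c(5, 4, 4),
                                       affine = default_affine(c(5, 4, 4)),
                                       snr = 1, seed = 9)
  res <- nuisance_residualize(dat$ts_list)
  zone1 <- which(dat$zone == 1 & !dat$seed_masks$seed1)
  roi_series <- rowMeans(res$data[, zone1])
  rr <- vapply(dat$seed_masks, function(m) {
    cor(roi_series, rowMeans(res$data[, which(m)]))
  }, numeric(1))
  expect_equal(which.max(rr), 1L, ignore_attr = TRUE)
})

test_that("the repeated-measures F matches aov on a balanced table", {
  set.seed(6)
  tbl <- tidyr::expand_grid(subject = paste0("s", 1:6),
                            condition = paste0("c", 1:4))
  tbl$value <- rnorm(24) + rep(c(0, 0.5, 1, 0), each = 1)
  mine <- coupling_rm_anova(tbl)
  ref <- summary(stats::aov(value ~ condition + Error(subject / condition),
                            data = tbl))
  refrow <- ref[["Error: subject:condition"]][[1]]
  expect_equal(mine$f_statistic, refrow$`F value`[1], tolerance = 1e-10)
  expect_equal(mine$p_value, refrow$`Pr(>F)`[1], tolerance = 1e-10)
})
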