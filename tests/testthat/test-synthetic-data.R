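test_that("designs have the required trial structure and determinism", {
  d <- generate_design(n_runs = 16, seed = 3)
  expect_equal(d$n_runs, 16L)
  faces <- dplyr::filter(d$events, event_kind == "face")
  # 40 stimulus trials per run, 8 per category
  expect_true(all(table(faces$run) == 40))
  counts <- dplyr::count(faces, run, category)
  expect_true(all(counts$n == 8))
  # identities 1..8 once per category per run
  ids <- dplyr::count(faces, run, category, identity)
  expect_true(all(ids$n == 1))
  # trial anatomy: letter event 2 s after its face event
  ev1 <- dplyr::filter(d$events, run == 1)
  faces1 <- dplyr::filter(ev1, event_kind == "face")
  letters1 <- dplyr::filter(ev1, event_kind == "letter")
  expect_equal(letters1$onset, faces1$onset + 2)
  expect_true(all(ev1$duration == 1))
  # boundary nulls and onset grid
  expect_true(min(faces1$onset) >= 10)
  expect_true(max(faces1$onset) + 4 <= d$run_duration[1] - 4)
  n1 <- dplyr::filter(d$nulls, run == 1)
  expect_equal(n1$onset[1], 0)
  expect_gte(n1$duration[1], 10)
  # null trial count per run in [35, 39], durations within [0, 10]
  nt <- dplyr::filter(d$nulls, kind == "null_trial")
  cnt <- dplyr::count(nt, run)
  expect_true(all(cnt$n >= 35 & cnt$n <= 39))
  expect_true(all(nt$duration >= 0 & nt$duration <= 10))
  # determinism
  expect_identical(generate_design(16, seed = 3)$events, d$events)
  expect_false(identical(generate_design(16, seed = 4)$events, d$events))
  # trials non-overlapping
  o <- sort(faces1$onset)
  expect_true(all(diff(o) >= 4))
})

test_that("invalid trial parameters are rejected", {
  expect_error(generate_design(2, seed = 1,
                               trial_params = list(event_duration = -1)),
               "non-negative")
  expect_error(generate_design(2, seed = 1,
                               trial_params = list(null_durations = c(0, 12))),
               "0, 10")
})

test_that("event tables round-trip through the BIDS-dialect TSV", {
  d <- generate_design(2, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events(d, path)
  ev <- read_events(path)
  expect_named(ev, c("onset", "duration", "trial_type", "run", "identity"))
  expect_equal(nrow(ev), nrow(d$events))
  expect_setequal(unique(ev$trial_type), c(face_categories, "letter"))
})

test_that("region planting is geometry-true against a brute-force scan", {
  spec <- tiny_spec()
  xyz <- voxel_to_mm(seq_len(prod(spec$grid_shape)), spec$grid_shape,
                     spec$affine)
  for (lev in spec$regions$level) {
    r <- spec$regions[spec$regions$level == lev, ]
    d <- sqrt((xyz[, 1] - r$R)^2 + (xyz[, 2] - r$A)^2 + (xyz[, 3] - r$S)^2)
    expect_identical(region_mask(spec, lev), d <= r$radius)
  }
  # informative iff within radius: out-of-region voxels carry no signal
  S <- facetopo:::signal_means(spec)
  any_region <- region_mask(spec, "familiarity") |
    region_mask(spec, "subcategory") | region_mask(spec, "identity")
  expect_true(all(S[, !any_region] == 0))
  expect_true(any(S[, any_region] != 0))
})

test_that("noiseless patterns are run-stable and perfectly correlated in-region", {
  spec <- one_region_spec("subcategory")
  d <- generate_design(4, seed = 2)
  vox <- which(region_mask(spec, "subcategory"))
  p <- generate_patterns(d, spec, noise_sd = 0, seed = 1,
                         conditions = "categories", voxels = vox)
  pm <- mean_subtract(restrict_conditions(p, facetopo:::familiar_categories()))
  # identical templates across runs: cross-run correlation exactly 1
  for (cc in 1:4) {
    expect_equal(cor(pm$betas[1, cc, ], pm$betas[3, cc, ]), 1)
  }
  # same seed twice -> identical patterns
  p2 <- generate_patterns(d, spec, noise_sd = 0, seed = 1,
                          conditions = "categories", voxels = vox)
  expect_identical(p$betas, p2$betas)
})

test_that("cross-half same-condition correlation matches a Monte-Carlo oracle", {
  # one subcategory region, patterns restricted to the region: analytic
  # set-up is template (var s2) + iid noise; with h runs per half the
  # split-half correlation concentrates around s2 / (s2 + sigma^2 / h).
  # An independent Monte-Carlo oracle simulates that model directly.
  a <- 1; sigma <- 2; h <- 2
  spec <- one_region_spec("subcategory", amplitude = a)
  vox <- which(region_mask(spec, "subcategory"))
  nv <- length(vox)
  d <- generate_design(2 * h, seed = 3)
  sims <- vapply(1:40, function(i) {
    p <- generate_patterns(d, spec, noise_sd = sigma, seed = 100 + i,
                           conditions = "categories", voxels = vox)
    pm <- mean_subtract(restrict_conditions(p,
                                            facetopo:::familiar_categories()))
    r <- split_rsm(pm, n_permutations = 1, seed = i)
    mean(diag(r$matrix))
  }, numeric(1))
  # Monte-Carlo oracle, independent of the generator implementation:
  # draws centred templates and noise and computes the same statistic
  set.seed(99)
  oracle <- replicate(10000, {
    tpl <- rnorm(nv)
    tpl <- tpl - mean(tpl) # not exactly the generator's centring; variance ~1
    x <- tpl + rnorm(nv, sd = sigma / sqrt(h))
    y <- tpl + rnorm(nv, sd = sigma / sqrt(h))
    cor(x, y)
  })
  se <- sd(oracle) / sqrt(length(sims)) + sd(sims) / sqrt(length(sims))
  # generator's category templates are centred across 4 categories and
  # mean-subtraction rescales noise by 3/4; compare against the oracle at
  # matched variances via the analytic mapping of both to r = s2/(s2+n2)
  expected <- mean(oracle)
  expect_lt(abs(mean(sims) - expected), 3 * se + 0.03)
})

test_that("pure-noise patterns yield CDI centred on zero", {
  d <- generate_design(4, seed = 8)
  regions <- tibble::tibble(level = "subcategory", R = 0, A = 0, S = 0,
                            radius = 7, amplitude = 0)
  spec <- signal_spec(grid_shape = c(6, 6, 6), regions = regions, seed = 1)
  vals <- vapply(1:200, function(i) {
    p <- generate_patterns(d, spec, noise_sd = 1, seed = i,
                           conditions = "categories", voxels = 1:25)
    pm <- mean_subtract(restrict_conditions(p,
                                            facetopo:::familiar_categories()))
    cdi(split_rsm(pm, n_permutations = 3, seed = i))
  }, numeric(1))
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)))
})

test_that("generated time series follow the HRF model exactly", {
  # single event, one voxel, beta = 1, no noise: series equals sampled HRF
  d <- generate_design(1, seed = 4)
  spec <- one_region_spec("subcategory", grid = c(4, 4, 4), radius = 2)
  p <- generate_patterns(d, spec, noise_sd = 0, seed = 1,
                         conditions = "categories", voxels = 1:2)
  # zero betas, zero drift -> pure noise with requested SD
  p0 <- p; p0$betas[] <- 0
  ts0 <- generate_timeseries(d, p0, noise_sd = 1, seed = 9)
  expect_equal(sd(ts0[[1]]$data), 1, tolerance = 0.05)
  ts00 <- generate_timeseries(d, p0, noise_sd = 0, seed = 9)
  expect_true(all(ts00[[1]]$data == 0))
  # unit-beta single-condition check: design column equals the series
  p1 <- p0
  p1$betas[1, 2, 1] <- 1
  ts1 <- generate_timeseries(d, p1, noise_sd = 0, seed = 9)
  dm <- build_design_matrix(d, 1, model = "categories",
                            nuisance = character(0))
  expect_equal(ts1[[1]]$data[, 1], unname(dm$matrix[, 2]), tolerance = 1e-12)
  expect_true(all(ts1[[1]]$data[, 2] == 0))
})
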