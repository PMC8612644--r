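# Shared fixtures, built in code at test time.

# Small grid spec with the three default-level regions scaled down.
tiny_spec <- function(grid = c(8, 8, 8), seed = 7, ...) {
  signal_spec(grid_shape = grid, seed = seed, ...)
}

# A spec with a single informative region of one level.
one_region_spec <- function(level, grid = c(8, 8, 8), amplitude = 1,
                            radius = 7, seed = 7) {
  regions <- tibble::tibble(level = level, R = 1.75, A = 1.75, S = 1.75,
                            radius = radius, amplitude = amplitude)
  signal_spec(grid_shape = grid, regions = regions, seed = seed)
}

# Beta patterns of pure noise (amplitudes zero).
null_patterns <- function(n_runs = 4, n_cond = 4, n_vox = 30, seed = 1,
                          sd = 1) {
  b <- array(stats::rnorm(n_runs * n_cond * n_vox, sd = sd),
             dim = c(n_runs, n_cond, n_vox))
  beta_patterns(b, paste0("c", seq_len(n_cond)), seq_len(n_vox),
                c(n_vox, 1, 1), default_affine(c(n_vox, 1, 1)))
}

# Brute-force double-loop split-RSM oracle for one explicit half split.
rsm_oracle <- function(betas, half) {
  other <- setdiff(seq_len(dim(betas)[1]), half)
  nc <- dim(betas)[2]
  out <- matrix(NA_real_, nc, nc)
  for (i in seq_len(nc)) {
    for (j in seq_len(nc)) {
      a <- colMeans(matrix(betas[half, i, ], nrow = length(half)))
      b <- colMeans(matrix(betas[other, j, ], nrow = length(other)))
      out[i, j] <- stats::cor(a, b)
    }
  }
  out
}

# Brute-force Kendall tau-a by exhaustive pair enumeration.
tau_oracle <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- s + sign(x[i] - x[j]) * sign(y[i] - y[j])
    }
  }
  s / (n * (n - 1) / 2)
}

# Brute-force BH step-up oracle: largest k with p_(k) <= k * alpha / m.
bh_oracle <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * alpha / m) k <- i
  flags <- rep(FALSE, m)
  if (k > 0) flags[ord[seq_len(k)]] <- TRUE
  flags
}

# Exhaustive-rank ANOSIM oracle (double loop, mid-ranks).
anosim_oracle <- function(d, labels) {
  n <- nrow(d)
  vals <- c()
  between <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      vals <- c(vals, d[i, j])
      between <- c(between, labels[i] != labels[j])
    }
  }
  rk <- rank(vals)
  (mean(rk[between]) - mean(rk[!between])) / (length(rk) / 2)
}
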