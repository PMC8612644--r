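#' Fisher r-to-z transform
#'
#' `z = 0.5 ln((1 + r) / (1 - r))`; `|r| = 1` maps to +/-Inf (flagged
#' unbounded, excluded from averages downstream).
#'
#' @param r Correlation values in `[-1, 1]`.
#' @return z values.
#' @export
fisher_z <- function(r) {
  0.5 * log((1 + r) / (1 - r))
}

#' Regress out nuisance signals and return z-scored residuals
#'
#' Per run, OLS-residualizes every voxel's time series against an intercept,
#' the stimulus-related regressor, optional motion columns, and the top five
#' principal components of the white-matter and ventricular-CSF voxel sets;
#' residuals are z-scored per voxel within the run and runs are then
#' concatenated.
#'
#' @param ts_list List of `voxel_timeseries`, one per run.
#' @param stimulus_regressor List (per run) of stimulus regressors, or NULL.
#' @param motion List (per run) of time x k motion matrices, or NULL.
#' @param wm_series,vcsf_series Lists (per run) of time x voxel matrices of
#'   white-matter / ventricular-CSF voxel time series, or NULL.
#' @param n_pcs Number of principal components per tissue set (default 5).
#' @return A `residual_series`: list with `data` (concatenated time x
#'   voxel), `run_boundaries` (first row of each run), `voxels`,
#'   `grid_shape`, `affine`.
#' @export
nuisance_residualize <- function(ts_list, stimulus_regressor = NULL,
                                 motion = NULL, wm_series = NULL,
                                 vcsf_series = NULL, n_pcs = 5L) {
  per_run <- lapply(seq_along(ts_list), function(r) {
    Y <- ts_list[[r]]$data
    X <- cbind(intercept = rep(1, nrow(Y)))
    if (!is.null(stimulus_regressor)) X <- cbind(X, stim = stimulus_regressor[[r]])
    if (!is.null(motion)) X <- cbind(X, motion[[r]])
    for (tissue in list(wm_series, vcsf_series)) {
      if (!is.null(tissue)) {
        pcs <- prcomp(tissue[[r]], center = TRUE, scale. = FALSE)$x
        X <- cbind(X, pcs[, seq_len(min(n_pcs, ncol(pcs))), drop = FALSE])
      }
    }
    if (ncol(X) >= nrow(Y)) {
      stop("more nuisance regressors than time points", call. = FALSE)
    }
    res <- Y - X %*% qr.coef(qr(X), Y)
    s <- apply(res, 2, sd)
    s[s == 0] <- NA_real_
    scale(res, center = colMeans(res), scale = s)
  })
  n_per <- vapply(per_run, nrow, integer(1))
  structure(list(
    data = do.call(rbind, per_run),
    run_boundaries = cumsum(c(1L, head(n_per, -1L))),
    voxels = ts_list[[1]]$voxels,
    grid_shape = ts_list[[1]]$grid_shape,
    affine = ts_list[[1]]$affine
  ), class = "residual_series")
}

#' Seed-based connectivity map
#'
#' Correlates the mean time series of a seed region with every voxel's time
#' series (Pearson), Fisher-transforms the correlations, and thresholds at
#' `r >= r_threshold`.
#'
#' @param res A `residual_series`.
#' @param seed_mask Logical vector over the series' voxels, or integer
#'   positions.
#' @param r_threshold Correlation threshold (default 0.12).
#' @return A `connectivity_map`: list with `r`, `z`, `mask` (r >=
#'   threshold), `threshold`, `voxels`, `grid_shape`, `affine`. Zero-variance
#'   voxels get `NA` correlations.
#' @export
seed_map <- function(res, seed_mask, r_threshold = 0.12) {
  idx <- if (is.logical(seed_mask)) which(seed_mask) else as.integer(seed_mask)
  if (length(idx) == 0L) stop("seed mask is empty", call. = FALSE)
  s <- rowMeans(res$data[, idx, drop = FALSE])
  r <- suppressWarnings(as.vector(cor(s, res$data)))
  structure(list(
    r = r,
    z = fisher_z(r),
    mask = !is.na(r) & r >= r_threshold,
    threshold = r_threshold,
    voxels = res$voxels,
    grid_shape = res$grid_shape,
    affine = res$affine
  ), class = "connectivity_map")
}

#' @export
print.connectivity_map <- function(x, ...) {
  cat(sprintf("<connectivity_map> %d voxel(s), %d above r >= %g\n",
              length(x$r), sum(x$mask, na.rm = TRUE), x$threshold))
  invisible(x)
}

#' Winner-take-all seed assignment by multiple regression
#'
#' Regresses every in-mask voxel's time series jointly on all seed mean
#' series (plus an intercept) and assigns the label of the seed with the
#' largest coefficient; exact ties go to the lowest seed index. With a list
#' of subjects' residual series, coefficients are averaged across subjects
#' before assignment.
#'
#' @param res A `residual_series` or a list of them (one per subject).
#' @param seed_masks Named list of non-overlapping seed masks (logical or
#'   integer positions into the series' voxels).
#' @param analysis_mask Logical vector of voxels to label; conventionally the
#'   union of the seeds' thresholded connectivity masks.
#' @return Tibble: `voxel` (grid index), `winner` (seed name), one beta
#'   column per seed.
#' @export
winner_take_all <- function(res, seed_masks, analysis_mask) {
  res_list <- if (inherits(res, "residual_series")) list(res) else res
  idx_list <- lapply(seed_masks, function(m) {
    if (is.logical(m)) which(m) else as.integer(m)
  })
  ov <- Reduce(intersect, idx_list)
  if (length(idx_list) > 1L && length(ov) > 0L) {
    stop("seed masks overlap", call. = FALSE)
  }
  mask_idx <- if (is.logical(analysis_mask)) which(analysis_mask) else
    as.integer(analysis_mask)
  nseed <- length(idx_list)
  beta_sum <- NULL
  for (rs in res_list) {
    S <- vapply(idx_list, function(ix) rowMeans(rs$data[, ix, drop = FALSE]),
                numeric(nrow(rs$data)))
    cs <- cor(S)
    hi <- which(abs(cs) > 0.999 & row(cs) < col(cs), arr.ind = TRUE)
    if (nrow(hi) > 0L) {
      nms <- names(seed_masks) %||% as.character(seq_len(nseed))
      stop(sprintf("collinear seed series: %s and %s (|r| > 0.999)",
                   nms[hi[1, 1]], nms[hi[1, 2]]), call. = FALSE)
    }
    X <- cbind(1, S)
    B <- qr.coef(qr(X), rs$data[, mask_idx, drop = FALSE])[-1, , drop = FALSE]
    beta_sum <- if (is.null(beta_sum)) B else beta_sum + B
  }
  B <- t(beta_sum / length(res_list))            # voxel x seed
  nms <- names(seed_masks) %||% paste0("seed", seq_len(nseed))
  colnames(B) <- nms
  winner <- nms[max.col(B, ties.method = "first")]
  out <- tibble::tibble(voxel = res_list[[1]]$voxels[mask_idx],
                        winner = winner)
  dplyr::bind_cols(out, tibble::as_tibble(B))
}

#' Spherical seed masks around peak coordinates
#'
#' Defines each seed as the set of voxels within `radius` mm of a supplied
#' metric coordinate.
#'
#' @param centers Matrix/data frame of seed centre coordinates (R, A, S mm),
#'   one row per seed; row names become seed names.
#' @param voxels Grid voxel indices of the analysis space.
#' @param grid_shape,affine Grid geometry.
#' @param radius Seed radius in mm (default 5).
#' @return Named list of logical vectors over `voxels`.
#' @export
seed_ball_masks <- function(centers, voxels, grid_shape, affine, radius = 5) {
  xyz <- voxel_to_mm(voxels, grid_shape, affine)
  centers <- as.matrix(centers)
  out <- lapply(seq_len(nrow(centers)), function(i) {
    d2 <- (xyz[, 1] - centers[i, 1])^2 + (xyz[, 2] - centers[i, 2])^2 +
      (xyz[, 3] - centers[i, 3])^2
    d2 <= radius^2
  })
  names(out) <- rownames(centers) %||% paste0("seed", seq_len(nrow(centers)))
  out
}

#' One-way repeated-measures ANOVA on a coupling table
#'
#' Reporting utility for seed-by-ROI coupling comparisons: a standard
#' one-way repeated-measures F with subjects as the blocking factor.
#'
#' @param tbl Tibble with columns `subject`, `condition`, `value`.
#' @return Tibble: `f_statistic`, `df1`, `df2`, `p_value`.
#' @export
coupling_rm_anova <- function(tbl) {
  y <- tbl$value
  subj <- as.factor(tbl$subject)
  cond <- as.factor(tbl$condition)
  n <- nlevels(subj)
  k <- nlevels(cond)
  grand <- mean(y)
  cond_means <- tapply(y, cond, mean)
  subj_means <- tapply(y, subj, mean)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  f <- (ss_cond / df1) / (ss_err / df2)
  tibble::tibble(f_statistic = f, df1 = df1, df2 = df2,
                 p_value = pf(f, df1, df2, lower.tail = FALSE))
}

#' Generate a synthetic seed-driven connectivity dataset
#'
#' Builds a four-zone network: each of four seed regions has a latent time
#' series, and every voxel of a zone is that zone's latent series scaled to
#' unit variance plus independent Gaussian noise
#' (`snr` = signal SD / noise SD). Zones and seeds live on the supplied
#' voxel set, split into four contiguous blocks; the first `seed_size`
#' voxels of each block form the seed.
#'
#' @param n_time Time points per run.
#' @param n_runs Number of runs.
#' @param voxels Grid voxel indices (divisible into 4 zones).
#' @param grid_shape,affine Grid geometry.
#' @param snr Signal-to-noise ratio (default 1).
#' @param seed_size Voxels per seed region (default 5).
#' @param seed RNG seed.
#' @return List: `ts_list` (per-run `voxel_timeseries`), `zone` (per-voxel
#'   zone id 1..4), `seed_masks` (named list of logical vectors).
#' @export
generate_connectivity_dataset <- function(n_time = 120L, n_runs = 4L,
                                          voxels, grid_shape, affine,
                                          snr = 1, seed_size = 5L, seed = 1L) {
  nv <- length(voxels)
  zone <- sort(rep(1:4, length.out = nv))
  ts_list <- lapply(seq_len(n_runs), function(r) {
    with_seed(sub_seed(seed, 500L + r), {
      latent <- matrix(rnorm(n_time * 4L), n_time, 4L)
      latent <- scale(latent)
      Y <- latent[, zone] * snr + matrix(rnorm(n_time * nv), n_time, nv)
      voxel_timeseries(Y, tr = 2, run = r, voxels = voxels,
                       grid_shape = grid_shape, affine = affine)
    })
  })
  seed_masks <- lapply(1:4, function(z) {
    idx <- which(zone == z)[seq_len(seed_size)]
    m <- rep(FALSE, nv)
    m[idx] <- TRUE
    m
  })
  names(seed_masks) <- paste0("seed", 1:4)
  list(ts_list = ts_list, zone = zone, seed_masks = seed_masks)
}
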