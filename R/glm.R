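#' Canonical double-gamma hemodynamic response function
#'
#' `h(t) = g(t; shape1, scale) - ratio * g(t; shape2, scale)` with gamma
#' densities `g`, normalised to peak 1. Defaults give the familiar canonical
#' shape (positive lobe peaking near 5-6 s, undershoot near 15 s).
#'
#' @param t Time points (s).
#' @param shape1,shape2,scale,ratio Gamma parameters of the positive lobe and
#'   undershoot and their amplitude ratio.
#' @return HRF values at `t`.
#' @export
hrf_double_gamma <- function(t, shape1 = 6, shape2 = 16, scale = 1,
                             ratio = 1 / 6) {
  h <- dgamma(t, shape = shape1, scale = scale) -
    ratio * dgamma(t, shape = shape2, scale = scale)
  h / max(dgamma(seq(0, 32, by = 0.01), shape = shape1, scale = scale) -
            ratio * dgamma(seq(0, 32, by = 0.01), shape = shape2, scale = scale))
}

# Convolve boxcar events with the HRF on an oversampled grid and sample at
# frame times (frame i covers [i*tr, (i+1)*tr), value taken at its onset).
convolve_events <- function(onsets, durations, n_frames, tr, hrf_params,
                            dt = 0.1) {
  total <- n_frames * tr
  grid <- seq(0, total - dt, by = dt)
  box <- numeric(length(grid))
  for (i in seq_along(onsets)) {
    on <- pmin(pmax(onsets[i], 0), total)
    off <- pmin(onsets[i] + durations[i], total)
    box[grid >= on & grid < off] <- box[grid >= on & grid < off] + 1
  }
  hp <- utils::modifyList(list(shape1 = 6, shape2 = 16, scale = 1,
                               ratio = 1 / 6), hrf_params %||% list())
  h <- hrf_double_gamma(seq(0, 32, by = dt), hp$shape1, hp$shape2, hp$scale,
                        hp$ratio)
  y <- convolve(c(box, numeric(length(h))), rev(h), type = "open") * dt
  y <- y[seq_along(box)]
  y[round(seq(0, n_frames - 1) * tr / dt) + 1]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a GLM design matrix for one run
#'
#' Task regressors are HRF-convolved boxcars: the `"categories"` model has 6
#' task regressors (five face categories + one letter regressor), the
#' `"identities"` model 41 (40 individual face events + letter). Nuisance
#' regressors (linear trend, quadratic trend, mean confound, optional motion
#' columns) are appended after the task block.
#'
#' @param design An `experiment_design`.
#' @param run Run number.
#' @param model `"categories"` or `"identities"`.
#' @param hrf_params Optional list passed to [hrf_double_gamma()].
#' @param nuisance Character subset of `c("linear", "quadratic", "mean")`
#'   (default all three); use `character(0)` for task columns only.
#' @param motion Optional time x k matrix of motion regressors.
#' @return A `design_matrix` object: list with `matrix` (time x regressor),
#'   `task_cols` (indices of task regressors), `frame_times`, `tr`.
#' @export
build_design_matrix <- function(design, run, model = c("categories", "identities"),
                                hrf_params = list(),
                                nuisance = c("linear", "quadratic", "mean"),
                                motion = NULL) {
  model <- match.arg(model)
  tr <- design$tr
  if (tr <= 0) stop("tr must be positive", call. = FALSE)
  dur <- design$run_duration[run]
  n_frames <- as.integer(round(dur / tr))
  ev <- design$events[design$events$run == run, ]
  faces <- ev[ev$event_kind == "face", ]
  letters <- ev[ev$event_kind == "letter", ]

  if (model == "categories") {
    task_names <- face_categories
    cols <- lapply(face_categories, function(cat) {
      e <- faces[faces$category == cat, ]
      convolve_events(e$onset, e$duration, n_frames, tr, hrf_params)
    })
  } else {
    task_names <- identity_conditions()
    cols <- lapply(task_names, function(cond) {
      parts <- strsplit(cond, ":", fixed = TRUE)[[1]]
      e <- faces[faces$category == parts[1] & faces$identity == as.integer(parts[2]), ]
      convolve_events(e$onset, e$duration, n_frames, tr, hrf_params)
    })
  }
  cols <- c(cols, list(convolve_events(letters$onset, letters$duration,
                                       n_frames, tr, hrf_params)))
  task_names <- c(task_names, "letter")
  X <- do.call(cbind, cols)

  nuis <- NULL
  nuis_names <- character(0)
  tt <- seq_len(n_frames)
  lin <- 2 * (tt - 1) / (n_frames - 1) - 1
  if ("linear" %in% nuisance) {
    nuis <- cbind(nuis, lin); nuis_names <- c(nuis_names, "trend_linear")
  }
  if ("quadratic" %in% nuisance) {
    nuis <- cbind(nuis, lin^2 - mean(lin^2))
    nuis_names <- c(nuis_names, "trend_quadratic")
  }
  if ("mean" %in% nuisance) {
    nuis <- cbind(nuis, rep(1, n_frames)); nuis_names <- c(nuis_names, "mean")
  }
  if (!is.null(motion)) {
    stopifnot(nrow(motion) == n_frames)
    nuis <- cbind(nuis, motion)
    nuis_names <- c(nuis_names,
                    colnames(motion) %||% paste0("motion", seq_len(ncol(motion))))
  }
  mat <- cbind(X, nuis)
  colnames(mat) <- c(task_names, nuis_names)
  if (any(colSums(abs(mat[, seq_along(task_names), drop = FALSE])) == 0)) {
    stop("design has an all-zero task regressor", call. = FALSE)
  }
  structure(list(
    matrix = mat,
    task_cols = seq_along(task_names),
    frame_times = (tt - 1) * tr,
    tr = tr,
    run = run,
    model = model
  ), class = "design_matrix")
}

#' Intensity-normalize a voxel time series
#'
#' Rescales every value by the grand mean over in-mask voxels and time points
#' so the in-mask global mean becomes exactly 100.
#'
#' @param ts A `voxel_timeseries`.
#' @param brain_mask Optional logical vector over the series' voxels
#'   (default: all voxels).
#' @return The normalized `voxel_timeseries`.
#' @export
normalize_intensity <- function(ts, brain_mask = NULL) {
  if (is.null(brain_mask)) brain_mask <- rep(TRUE, ncol(ts$data))
  if (!any(brain_mask)) stop("brain_mask is empty", call. = FALSE)
  g <- mean(ts$data[, brain_mask])
  if (!is.finite(g) || abs(g) < .Machine$double.eps * 100) {
    stop("grand mean is zero; cannot intensity-normalize", call. = FALSE)
  }
  ts$data <- ts$data / g * 100
  ts
}

#' Fit an ordinary-least-squares GLM to one run
#'
#' Discards the first `discard_initial` frames of both data and design, then
#' estimates per-voxel OLS coefficients. Returns the task betas as a
#' single-run [beta_patterns] object; the full coefficient matrix and the
#' residuals are attached as attributes `"coefficients"` and `"residuals"`.
#'
#' @param ts A `voxel_timeseries`.
#' @param dm A `design_matrix` for the same run.
#' @param discard_initial Frames dropped from the run start (default 4).
#' @return A single-run `beta_patterns` (task conditions only; the letter
#'   regressor's beta is excluded from the pattern set).
#' @export
fit_glm <- function(ts, dm, discard_initial = 4L) {
  X <- dm$matrix
  if (nrow(X) != nrow(ts$data)) {
    stop("design matrix rows do not match time series length", call. = FALSE)
  }
  keep <- seq_len(nrow(X)) > discard_initial
  X <- X[keep, , drop = FALSE]
  Y <- ts$data[keep, , drop = FALSE]
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  coefs <- qr.coef(qx, Y)
  resid <- Y - X %*% coefs
  task <- dm$task_cols
  task <- task[colnames(X)[task] != "letter"]
  betas <- aperm(array(coefs[task, , drop = FALSE],
                       dim = c(length(task), ncol(Y), 1L)), c(3L, 1L, 2L))
  out <- beta_patterns(betas, colnames(X)[task], ts$voxels, ts$grid_shape,
                       ts$affine)
  attr(out, "coefficients") <- coefs
  attr(out, "residuals") <- resid
  out
}

#' Fit per-run GLMs across all runs of a dataset
#'
#' @param ts_list List of `voxel_timeseries`, one per run.
#' @param design The `experiment_design` used to build per-run design
#'   matrices.
#' @param model `"categories"` or `"identities"`.
#' @param ... Passed to [build_design_matrix()].
#' @param discard_initial Frames dropped per run (default 4).
#' @return A multi-run `beta_patterns`.
#' @export
fit_glm_runs <- function(ts_list, design, model = "categories", ...,
                         discard_initial = 4L) {
  fits <- lapply(seq_along(ts_list), function(r) {
    dm <- build_design_matrix(design, r, model = model, ...)
    fit_glm(ts_list[[r]], dm, discard_initial = discard_initial)
  })
  b1 <- fits[[1]]
  betas <- array(NA_real_, dim = c(length(fits), dim(b1$betas)[2:3]))
  for (r in seq_along(fits)) betas[r, , ] <- fits[[r]]$betas[1, , ]
  beta_patterns(betas, b1$conditions, b1$voxels, b1$grid_shape, b1$affine)
}

#' Gaussian-smooth a 3-D volume
#'
#' Separable Gaussian filtering on the voxel grid; used on the univariate and
#' connectivity paths only (pattern analyses are never smoothed).
#'
#' @param vol 3-D numeric array.
#' @param fwhm Full width at half maximum, mm.
#' @param voxel_size Voxel edge, mm.
#' @return Smoothed array of the same shape.
#' @export
smooth_volume <- function(vol, fwhm = 6, voxel_size = 3.5) {
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxel_size
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth_axis <- function(a, axis) {
    apply(a, setdiff(1:3, axis), function(v) {
      n <- length(v)
      vp <- c(rep(v[1], half), v, rep(v[n], half))
      as.numeric(stats::filter(vp, k, sides = 2))[(half + 1):(half + n)]
    })
  }
  for (ax in 1:3) {
    s <- smooth_axis(vol, ax)
    # apply() returns axis-first; restore original order
    vol <- aperm(array(s, dim = c(dim(vol)[ax], dim(vol)[-ax])),
                 order(c(ax, setdiff(1:3, ax))))
  }
  vol
}
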