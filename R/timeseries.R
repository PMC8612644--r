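#' Construct a voxel time series
#'
#' @param data time x voxel matrix (arbitrary signal units).
#' @param tr Repetition time, s.
#' @param run Run id.
#' @param voxels Grid voxel indices (length = ncol(data)).
#' @param grid_shape,affine Grid geometry.
#' @return A `voxel_timeseries` object.
#' @export
voxel_timeseries <- function(data, tr, run, voxels, grid_shape, affine) {
  if (tr <= 0) stop("tr must be positive", call. = FALSE)
  stopifnot(ncol(data) == length(voxels))
  structure(list(
    data = data, tr = tr, run = run, voxels = as.integer(voxels),
    grid_shape = as.integer(grid_shape), affine = affine
  ), class = "voxel_timeseries")
}

#' @export
print.voxel_timeseries <- function(x, ...) {
  cat(sprintf("<voxel_timeseries> run %s: %d frames x %d voxels, TR = %g s\n",
              format(x$run), nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

#' Generate voxel time series from a design and planted betas
#'
#' Simulates event-related BOLD data per run:
#' `data = X_task %*% beta + drift + noise`, where `X_task` is the
#' HRF-convolved task design (face condition regressors plus the letter
#' regressor as a separate source) built by [build_design_matrix()].
#'
#' @param design An `experiment_design`.
#' @param patterns A `beta_patterns` covering all conditions in the design
#'   (5 category-level or 40 identity-level conditions).
#' @param hrf_params Optional HRF parameter list.
#' @param noise_sd Gaussian noise SD (default 1).
#' @param seed Noise seed.
#' @param drift_amplitude Peak-to-peak/2 amplitude of an added linear drift
#'   (default 0).
#' @param letter_beta Per-voxel response amplitude of the letter events
#'   (default 0).
#' @return A list of `voxel_timeseries`, one per run.
#' @export
generate_timeseries <- function(design, patterns, hrf_params = list(),
                                noise_sd = 1, seed = 1L, drift_amplitude = 0,
                                letter_beta = 0) {
  stopifnot_scalar_number(noise_sd, "noise_sd", min = 0)
  model <- if (length(patterns$conditions) == length(face_categories)) {
    "categories"
  } else if (length(patterns$conditions) == length(identity_conditions())) {
    "identities"
  } else {
    stop("patterns must cover all conditions in the design", call. = FALSE)
  }
  nv <- length(patterns$voxels)
  lb <- rep_len(letter_beta, nv)
  lapply(seq_len(design$n_runs), function(r) {
    dm <- build_design_matrix(design, r, model = model,
                              hrf_params = hrf_params,
                              nuisance = character(0))
    X <- dm$matrix # task columns (+ letter) only
    ord <- match(colnames(X)[-ncol(X)], patterns$conditions)
    if (anyNA(ord)) stop("patterns must cover all conditions in the design",
                         call. = FALSE)
    B <- rbind(matrix(patterns$betas[r, ord, ], nrow = length(ord)),
               letter = lb)
    stopifnot(ncol(X) == nrow(B))
    Y <- X %*% B
    if (drift_amplitude != 0) {
      lin <- seq(-1, 1, length.out = nrow(Y))
      Y <- Y + drift_amplitude * lin
    }
    if (noise_sd > 0) {
      Y <- Y + with_seed(sub_seed(seed, 9000L + r), {
        matrix(rnorm(length(Y), sd = noise_sd), nrow = nrow(Y))
      })
    }
    voxel_timeseries(Y, design$tr, r, patterns$voxels, patterns$grid_shape,
                     patterns$affine)
  })
}
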