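#' Fixed-cardinality searchlight neighborhoods
#'
#' For every in-mask voxel, finds its `k` nearest in-mask voxels by metric
#' (mm) distance, the center itself included (distance 0). Distance ties at
#' the k-th neighbor are broken by voxel index order, so neighborhoods are
#' deterministic.
#'
#' @param mask Logical vector/array over the grid, or integer grid voxel
#'   indices.
#' @param k Neighborhood size (default 100 voxels).
#' @param grid_shape 3-vector of voxel counts.
#' @param affine 4x4 voxel-to-mm matrix.
#' @return A `neighborhoods` object: list with `voxels` (in-mask grid
#'   indices), `members` (k x n matrix of positions into `voxels`),
#'   `centers` (= seq_along(voxels)), `k`, `grid_shape`, `affine`.
#' @export
build_neighborhoods <- function(mask, k = 100L, grid_shape, affine) {
  voxels <- if (is.logical(mask)) which(as.vector(mask)) else as.integer(mask)
  n <- length(voxels)
  if (n < k) {
    stop(sprintf("mask has %d voxels, fewer than k = %d", n, k),
         call. = FALSE)
  }
  xyz <- voxel_to_mm(voxels, grid_shape, affine)
  members <- matrix(0L, nrow = k, ncol = n)
  # chunked distance computation to bound memory
  chunk <- max(1L, floor(2e7 / n))
  sq <- rowSums(xyz^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d2 <- outer(sq[s:e], sq, "+") - 2 * xyz[s:e, , drop = FALSE] %*% t(xyz)
    for (ii in seq_len(e - s + 1L)) {
      # ties at the k-th neighbor break by grid voxel index, so the chosen
      # set is independent of the storage order of `voxels`
      members[, s + ii - 1L] <- order(d2[ii, ], voxels)[seq_len(k)]
    }
  }
  structure(list(
    voxels = voxels, members = members, centers = seq_len(n), k = as.integer(k),
    grid_shape = as.integer(grid_shape), affine = affine
  ), class = "neighborhoods")
}

#' @export
print.neighborhoods <- function(x, ...) {
  cat(sprintf("<neighborhoods> %d center(s), k = %d voxels each\n",
              length(x$centers), x$k))
  invisible(x)
}

# tau-a of pooled entry rows (centers x entries) against a binary 0/1 model
# vector, via the Mann-Whitney identity C - D = 2 U - n1 n0 (mid-ranks).
tau_a_binary_rows <- function(E, w) {
  n1 <- sum(w == 1)
  n0 <- sum(w == 0)
  n <- n1 + n0
  ones <- which(w == 1)
  apply(E, 1, function(v) {
    rk <- rank(v)
    U <- sum(rk[ones]) - n1 * (n1 + 1) / 2
    (2 * U - n1 * n0) / (n * (n - 1) / 2)
  })
}

# Per-center averaged sdRSM entries via sparse neighborhood sums.
# Returns m x (nc*nc) matrix; entry column (j-1)*nc + i holds r(A_i, B_j).
searchlight_rsm_entries <- function(patterns, nbhd, n_permutations, seed) {
  splits <- sample_half_splits(dim(patterns$betas)[1], n_permutations, seed)
  searchlight_rsm_entries_splits(patterns, nbhd, splits)
}

searchlight_rsm_entries_splits <- function(patterns, nbhd, splits) {
  b <- patterns$betas
  n_runs <- dim(b)[1]
  nc <- dim(b)[2]
  nv <- dim(b)[3]
  k <- nbhd$k
  m <- length(nbhd$centers)
  N <- Matrix::sparseMatrix(
    i = rep(seq_len(m), each = k),
    j = as.vector(nbhd$members),
    x = 1, dims = c(m, nv)
  )
  acc <- matrix(0, m, nc * nc)
  for (half in splits) {
    other <- setdiff(seq_len(n_runs), half)
    A <- apply(b[half, , , drop = FALSE], c(2, 3), mean)   # nc x nv
    B <- apply(b[other, , , drop = FALSE], c(2, 3), mean)
    AA <- t(A); BB <- t(B)
    cross <- AA[, rep(seq_len(nc), times = nc), drop = FALSE] *
      BB[, rep(seq_len(nc), each = nc), drop = FALSE]
    S <- as.matrix(N %*% cbind(AA, BB, AA^2, BB^2, cross))
    sA <- S[, seq_len(nc), drop = FALSE]
    sB <- S[, nc + seq_len(nc), drop = FALSE]
    sA2 <- S[, 2 * nc + seq_len(nc), drop = FALSE]
    sB2 <- S[, 3 * nc + seq_len(nc), drop = FALSE]
    sAB <- S[, 4 * nc + seq_len(nc * nc), drop = FALSE]
    vi <- rep(seq_len(nc), times = nc)
    vj <- rep(seq_len(nc), each = nc)
    num <- sAB - sA[, vi, drop = FALSE] * sB[, vj, drop = FALSE] / k
    den <- sqrt((sA2[, vi, drop = FALSE] - sA[, vi, drop = FALSE]^2 / k) *
                  (sB2[, vj, drop = FALSE] - sB[, vj, drop = FALSE]^2 / k))
    acc <- acc + num / den
  }
  acc / length(splits)
}

#' Map a pattern statistic over the volume
#'
#' Computes, for every neighborhood center, the statistic of the pattern set
#' restricted to that neighborhood's voxels: the averaged split-data RSM of
#' the member voxels followed by either the Kendall tau-a correlation with a
#' categorical model (`stat = "model_correlation"`) or the category
#' discriminability index (`stat = "cdi"`). The value is assigned to the
#' central voxel. A custom `stat` function of a `beta_patterns` may be
#' supplied instead. Pattern normalization (mean subtraction) is expected to
#' have been applied to the full pattern set beforehand — subtraction happens
#' before neighborhood restriction, never after.
#'
#' For the built-in statistics a vectorized path (sparse neighborhood sums)
#' is used; it is numerically identical to looping [split_rsm()] over
#' restricted pattern sets with the same seed.
#'
#' @param patterns A `beta_patterns` whose voxel axis matches `nbhd$voxels`.
#' @param nbhd A `neighborhoods` object.
#' @param stat `"model_correlation"`, `"cdi"`, or a function
#'   `beta_patterns -> numeric(1)`.
#' @param model A `model_matrix` (required for `"model_correlation"`); its
#'   size must equal the number of conditions in `patterns`.
#' @param n_permutations Run splits averaged per neighborhood (default 20).
#' @param seed Split seed.
#' @return A `stat_map`: list with `values` (per center), `voxels`,
#'   `grid_shape`, `affine`, `stat_name`. Failures at individual centers
#'   yield `NA` values and an entry in attribute `"log"`.
#' @export
run_searchlight <- function(patterns, nbhd, stat = "model_correlation",
                            model = NULL, n_permutations = 20L, seed = 1L) {
  if (!identical(patterns$voxels, nbhd$voxels)) {
    stop("patterns and neighborhoods cover different voxel sets",
         call. = FALSE)
  }
  nc <- dim(patterns$betas)[2]
  stat_name <- if (is.function(stat)) "custom" else match.arg(
    stat, c("model_correlation", "cdi"))

  if (!is.function(stat)) {
    if (stat_name == "model_correlation") {
      if (is.null(model)) stop("model required", call. = FALSE)
      if (!all(dim(model$matrix) == nc)) {
        stop("model size does not match pattern conditions", call. = FALSE)
      }
    }
    E <- searchlight_rsm_entries(patterns, nbhd, n_permutations, seed)
    if (stat_name == "cdi") {
      diag_cols <- (seq_len(nc) - 1L) * nc + seq_len(nc)
      values <- rowMeans(E[, diag_cols, drop = FALSE]) -
        rowMeans(E[, -diag_cols, drop = FALSE])
    } else {
      # symmetrized diagonal + upper-triangle entries, matching
      # model_correlation()
      iu <- which(upper.tri(matrix(0, nc, nc), diag = TRUE))
      ii <- ((iu - 1L) %% nc) + 1L
      jj <- ((iu - 1L) %/% nc) + 1L
      Esym <- (E[, (jj - 1L) * nc + ii, drop = FALSE] +
                 E[, (ii - 1L) * nc + jj, drop = FALSE]) / 2
      w <- model$matrix[cbind(ii, jj)]
      values <- tau_a_binary_rows(Esym, w)
    }
    log <- character(0)
    values[!is.finite(values)] <- NA_real_
  } else {
    values <- rep(NA_real_, length(nbhd$centers))
    log <- character(0)
    for (ci in seq_along(nbhd$centers)) {
      sub <- restrict_voxels(patterns, nbhd$members[, ci])
      values[ci] <- tryCatch(stat(sub), error = function(e) {
        log <<- c(log, sprintf("center %d: %s", ci, conditionMessage(e)))
        NA_real_
      })
    }
  }
  out <- structure(list(
    values = values, voxels = nbhd$voxels,
    grid_shape = nbhd$grid_shape, affine = nbhd$affine,
    stat_name = stat_name
  ), class = "stat_map")
  attr(out, "log") <- log
  out
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s over %d center(s); range [%.3g, %.3g]\n",
              x$stat_name, length(x$values),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Convert a stat map to a full 3-D array
#'
#' @param map A `stat_map`.
#' @return 3-D array with `NA` outside the mapped voxels.
#' @export
as_volume <- function(map) {
  vol <- array(NA_real_, dim = map$grid_shape)
  vol[map$voxels] <- map$values
  vol
}

#' Peak (argmax) coordinate of a stat map
#'
#' @param map A `stat_map` (or values + voxels).
#' @return Named numeric (R, A, S) mm coordinates of the in-mask maximum.
#' @export
peak_coordinate <- function(map) {
  if (all(is.na(map$values))) stop("all map values missing", call. = FALSE)
  i <- which.max(map$values)
  drop(voxel_to_mm(map$voxels[i], map$grid_shape, map$affine))
}
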