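# Internal helpers shared across modules.

# Derive a deterministic 32-bit sub-seed from a master seed and a stream id.
# Keeps every source of randomness traceable to one user-supplied seed.
sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 1299709) %%
               2147483399)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    stop(sprintf("`%s` must be a single finite number >= %s", name, min),
         call. = FALSE)
  }
  invisible(x)
}

#' Default voxel-to-mm affine for an isotropic RAS grid
#'
#' Maps 0-based voxel indices (i, j, k) to right-anterior-superior (RAS)
#' millimetre coordinates, with the grid centre at the metric origin.
#'
#' @param grid_shape Integer vector of 3 voxel counts.
#' @param voxel_size Isotropic voxel edge in mm (default 3.5).
#' @return A 4x4 affine matrix.
#' @export
default_affine <- function(grid_shape, voxel_size = 3.5) {
  stopifnot(length(grid_shape) == 3L)
  origin <- -(grid_shape - 1) / 2 * voxel_size
  aff <- diag(c(rep(voxel_size, 3), 1))
  aff[1:3, 4] <- origin
  aff
}

# 1-based grid index -> 0-based (i,j,k) matrix
voxel_ijk <- function(idx, grid_shape) {
  idx0 <- idx - 1L
  i <- idx0 %% grid_shape[1]
  j <- (idx0 %/% grid_shape[1]) %% grid_shape[2]
  k <- idx0 %/% (grid_shape[1] * grid_shape[2])
  cbind(i = i, j = j, k = k)
}

#' Convert voxel grid indices to metric RAS coordinates
#'
#' @param idx 1-based linear voxel indices into the grid.
#' @param grid_shape Integer vector of 3 voxel counts.
#' @param affine 4x4 voxel(0-based)-to-mm matrix.
#' @return An n x 3 matrix of (R, A, S) mm coordinates.
#' @export
voxel_to_mm <- function(idx, grid_shape, affine) {
  ijk <- voxel_ijk(idx, grid_shape)
  xyz <- cbind(ijk, 1) %*% t(affine)
  colnames(xyz) <- c("R", "A", "S", "w")
  xyz[, 1:3, drop = FALSE]
}

# mm -> nearest 1-based linear voxel index
mm_to_voxel <- function(xyz, grid_shape, affine) {
  xyz <- matrix(xyz, ncol = 3)
  ijk <- round(cbind(xyz, 1) %*% t(solve(affine)))[, 1:3, drop = FALSE]
  as.integer(ijk[, 1] + grid_shape[1] * (ijk[, 2] + grid_shape[2] * ijk[, 3]) + 1)
}
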