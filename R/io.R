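#' Read and write NIfTI volumes
#'
#' Thin wrappers around RNifti keeping the package's affine convention
#' (voxel 0-based indices to RAS mm).
#'
#' @param vol 3-D or 4-D numeric array.
#' @param path File path (`.nii` or `.nii.gz`).
#' @param affine 4x4 voxel-to-mm matrix.
#' @return `write_volume()` returns `path` invisibly; `read_volume()`
#'   returns a list with `data` (array) and `affine`.
#' @export
write_volume <- function(vol, path, affine) {
  img <- RNifti::asNifti(vol)
  RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = as.array(img), affine = unclass(RNifti::xform(img)))
}

#' Write a beta pattern set as NIfTI plus a JSON sidecar
#'
#' One 4-D volume per run (condition as the 4th axis), stored alongside a
#' JSON sidecar recording condition order and grid voxel indices.
#'
#' @param patterns A `beta_patterns`.
#' @param prefix Output path prefix; writes `<prefix>_run<i>.nii.gz` and
#'   `<prefix>.json`.
#' @return Invisibly, the sidecar path.
#' @export
write_betas <- function(patterns, prefix) {
  d <- dim(patterns$betas)
  for (r in seq_len(d[1])) {
    vol <- array(NA_real_, dim = c(patterns$grid_shape, d[2]))
    for (cc in seq_len(d[2])) {
      v3 <- array(NA_real_, dim = patterns$grid_shape)
      v3[patterns$voxels] <- patterns$betas[r, cc, ]
      vol[, , , cc] <- v3
    }
    write_volume(vol, sprintf("%s_run%02d.nii.gz", prefix, r),
                 patterns$affine)
  }
  sidecar <- sprintf("%s.json", prefix)
  jsonlite::write_json(list(conditions = patterns$conditions,
                            voxels = patterns$voxels,
                            grid_shape = patterns$grid_shape),
                       sidecar, auto_unbox = FALSE)
  invisible(sidecar)
}

#' Write a split-data RSM as CSV with a JSON metadata sidecar
#'
#' @param rsm A `split_rsm`.
#' @param path CSV path (the sidecar replaces the extension with `.json`).
#' @return `path`, invisibly.
#' @export
write_rsm <- function(rsm, path) {
  readr::write_csv(tibble::as_tibble(rsm$matrix, .name_repair = "minimal"),
                   path)
  jsonlite::write_json(
    list(conditions = rsm$conditions,
         n_permutations_averaged = rsm$n_permutations_averaged,
         symmetrized = rsm$symmetrized, seed = rsm$seed),
    sub("\\.[^.]+$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}

#' Read a declarative key-value configuration file
#'
#' YAML file controlling grid, regions, amplitudes, noise and seeds.
#'
#' @param path YAML path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read config files", call. = FALSE)
  }
  yaml::read_yaml(path)
}
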