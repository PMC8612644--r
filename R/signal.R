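#' Specify planted spatial signal structure
#'
#' Describes a voxel grid and a set of spherical informative regions, one per
#' representational level: a familiarity region (a pattern common to all
#' familiar categories, with positive mean so the familiar-vs-unfamiliar
#' contrast is detectable), a subcategory region (one pattern per category),
#' and an identity region (per-identity patterns nested inside the category
#' pattern). Deterministic voxel templates are drawn once per spec from
#' `seed`; the signal is run-stable, only noise varies across runs.
#'
#' The default geometry mirrors a posterior-midline arrangement in which the
#' subcategory region sits anterior to the familiarity region and the
#' identity region superior to both, with centres offset by 2-4 voxels.
#'
#' @param grid_shape 3-vector of voxel counts (default 20 x 20 x 20).
#' @param voxel_size Isotropic voxel size in mm (default 3.5).
#' @param regions Tibble with columns `level`
#'   (familiarity/subcategory/identity), `R`, `A`, `S` (centre, mm),
#'   `radius` (mm), `amplitude` (signal units, >= 0).
#' @param nesting_weight Fraction of the category template carried inside
#'   the identity region (default 0.5).
#' @param seed Template seed.
#' @return An object of class `signal_spec`.
#' @export
signal_spec <- function(grid_shape = c(20L, 20L, 20L),
                        voxel_size = 3.5,
                        regions = default_regions(voxel_size),
                        nesting_weight = 0.5,
                        seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0))
  affine <- default_affine(grid_shape, voxel_size)
  stopifnot(all(c("level", "R", "A", "S", "radius", "amplitude") %in%
                  names(regions)))
  if (any(regions$amplitude < 0)) {
    stop("region amplitudes must be >= 0", call. = FALSE)
  }
  half <- (grid_shape - 1) / 2 * voxel_size
  centers <- as.matrix(regions[, c("R", "A", "S")])
  if (any(abs(centers) > rep(half, each = nrow(centers)))) {
    stop("region centers must lie inside the grid", call. = FALSE)
  }
  structure(list(
    grid_shape = grid_shape,
    voxel_size = voxel_size,
    affine = affine,
    regions = tibble::as_tibble(regions),
    nesting_weight = nesting_weight,
    seed = as.integer(seed)
  ), class = "signal_spec")
}

#' @rdname signal_spec
#' @export
default_regions <- function(voxel_size = 3.5) {
  # centers lie on voxel centers of the default even-sized grid (odd
  # multiples of voxel_size/2); the subcategory region sits 3 voxels
  #  anterior to the familiarity region, the identity region 4 voxels
  # anterior / 3 voxels superior to it
  v <- voxel_size
  tibble::tribble(
    ~level,         ~R,      ~A,       ~S,       ~radius, ~amplitude,
    "familiarity",  0.5 * v, -1.5 * v, -1.5 * v, 2 * v,   1,
    "subcategory",  0.5 * v, 1.5 * v,  -1.5 * v, 2 * v,   1,
    "identity",     0.5 * v, 2.5 * v,  1.5 * v,  2 * v,   1
  )
}

#' Compact box-shaped analysis mask around the planted regions
#'
#' Returns the grid voxel indices of the axis-aligned bounding box of all
#' region centers, expanded by `margin` mm — the volumetric analogue of a
#' compact anatomical ROI containing the regions of interest. (Thin or
#' ragged masks are poor searchlight domains: fixed-cardinality
#' neighborhoods at a thin mask's fringe stretch far along it.)
#'
#' @param spec A `signal_spec`.
#' @param margin Margin in mm beyond the outermost region centers
#'   (default 12).
#' @return Integer vector of grid voxel indices.
#' @export
analysis_box_mask <- function(spec, margin = 12) {
  xyz <- voxel_to_mm(seq_len(prod(spec$grid_shape)), spec$grid_shape,
                     spec$affine)
  lo <- apply(spec$regions[, c("R", "A", "S")], 2, min) - margin
  hi <- apply(spec$regions[, c("R", "A", "S")], 2, max) + margin
  which(xyz[, 1] >= lo[1] & xyz[, 1] <= hi[1] &
          xyz[, 2] >= lo[2] & xyz[, 2] <= hi[2] &
          xyz[, 3] >= lo[3] & xyz[, 3] <= hi[3])
}

#' @export
print.signal_spec <- function(x, ...) {
  cat(sprintf("<signal_spec> grid %s at %g mm, %d region(s)\n",
              paste(x$grid_shape, collapse = "x"), x$voxel_size,
              nrow(x$regions)))
  print(x$regions)
  invisible(x)
}

#' In-region voxel indicator for a signal spec
#'
#' A voxel is informative for a level iff its metric centre lies within
#' `radius` mm of that level's region centre.
#'
#' @param spec A `signal_spec`.
#' @param level One of "familiarity", "subcategory", "identity".
#' @return Logical vector over the grid's voxels (linear order).
#' @export
region_mask <- function(spec, level) {
  r <- spec$regions[spec$regions$level == level, , drop = FALSE]
  if (nrow(r) == 0L) {
    return(rep(FALSE, prod(spec$grid_shape)))
  }
  xyz <- voxel_to_mm(seq_len(prod(spec$grid_shape)), spec$grid_shape,
                     spec$affine)
  ok <- rep(FALSE, nrow(xyz))
  for (i in seq_len(nrow(r))) {
    d2 <- (xyz[, 1] - r$R[i])^2 + (xyz[, 2] - r$A[i])^2 + (xyz[, 3] - r$S[i])^2
    ok <- ok | d2 <= r$radius[i]^2
  }
  ok
}

# All 40 identity-level condition labels, category-major.
identity_conditions <- function() {
  as.vector(t(outer(face_categories, 1:8, paste, sep = ":")))
}

# Deterministic per-level voxel templates over the full grid. Each level
# carries only its own kind of information: the familiarity template (mean 1,
# so the familiar-vs-unfamiliar contrast is positive) is common to familiar
# categories; category templates are per-voxel centered across the four
# familiar categories (zero for unfamiliar), so they encode only
# between-category differences; identity perturbations are centered across
# the eight identities within each category, so they encode only
# between-identity differences and average out of category-level patterns.
build_templates <- function(spec) {
  nv <- prod(spec$grid_shape)
  with_seed(sub_seed(spec$seed, 104729L), {
    t_fam <- rnorm(nv, mean = 1, sd = 1)
    t_cat <- matrix(0, nrow = 5L, ncol = nv,
                    dimnames = list(face_categories, NULL))
    fam_rows <- which(face_categories != "unfamiliar")
    raw <- matrix(rnorm(length(fam_rows) * nv), nrow = length(fam_rows))
    t_cat[fam_rows, ] <- sweep(raw, 2, colMeans(raw))
    perturb <- array(0, dim = c(5L, 8L, nv),
                     dimnames = list(face_categories, NULL, NULL))
    for (ci in fam_rows) {
      pr <- matrix(rnorm(8L * nv), nrow = 8L)
      perturb[ci, , ] <- sweep(pr, 2, colMeans(pr))
    }
    list(fam = t_fam, cat = t_cat, perturb = perturb)
  })
}

# Noise-free identity-level mean signal matrix (40 conditions x voxels).
signal_means <- function(spec) {
  tpl <- build_templates(spec)
  nv <- prod(spec$grid_shape)
  amp <- function(level) {
    a <- spec$regions$amplitude[spec$regions$level == level]
    if (length(a)) a[1] else 0
  }
  m_fam <- region_mask(spec, "familiarity")
  m_sub <- region_mask(spec, "subcategory")
  m_id <- region_mask(spec, "identity")
  w <- spec$nesting_weight
  conds <- identity_conditions()
  S <- matrix(0, nrow = length(conds), ncol = nv,
              dimnames = list(conds, NULL))
  for (ci in seq_along(face_categories)) {
    cat <- face_categories[ci]
    fam_term <- if (cat != "unfamiliar") amp("familiarity") * tpl$fam * m_fam else 0
    sub_term <- amp("subcategory") * tpl$cat[ci, ] * m_sub
    for (id in 1:8) {
      id_term <- amp("identity") *
        (w * tpl$cat[ci, ] + tpl$perturb[ci, id, ]) * m_id
      S[paste(cat, id, sep = ":"), ] <- fam_term + sub_term + id_term
    }
  }
  S
}

#' Generate per-run beta patterns with planted structure
#'
#' Draws, for every run and condition, the deterministic planted signal plus
#' i.i.d. Gaussian noise: `beta[r, c, v] = signal(c)[v] + eps`,
#' `eps ~ N(0, noise_sd^2)`. Category-level condition signals are the mean of
#' the corresponding eight identity-level signals (a category response pools
#' its identities' responses).
#'
#' The default `noise_sd` of 5 (against unit region amplitudes) puts the
#' same-condition split-half pattern correlation of a 100-voxel neighborhood
#' covering a region near 0.1, the weak-effect regime typical of
#' event-related pattern analyses; much lower noise drives rank-based map
#' statistics into degenerate exact-tie plateaus no real dataset shows.
#'
#' @param design An `experiment_design` (supplies the run count).
#' @param spec A `signal_spec`.
#' @param noise_sd Noise standard deviation (>= 0, default 5).
#' @param seed Noise seed.
#' @param conditions `"categories"` (5 conditions) or `"identities"`
#'   (40 conditions, `category:identity` labels).
#' @param voxels Optional integer vector of grid voxel indices restricting
#'   the pattern set to an ROI (default: whole grid).
#' @return A `beta_patterns` object: list with `betas`
#'   (run x condition x voxel array), `conditions`, `voxels`, `grid_shape`,
#'   `affine`.
#' @export
generate_patterns <- function(design, spec, noise_sd = 5, seed = 1L,
                              conditions = c("categories", "identities"),
                              voxels = NULL) {
  conditions <- match.arg(conditions)
  stopifnot_scalar_number(noise_sd, "noise_sd", min = 0)
  nv_grid <- prod(spec$grid_shape)
  if (is.null(voxels)) voxels <- seq_len(nv_grid)
  if (any(voxels < 1 | voxels > nv_grid)) {
    stop("`voxels` out of range for the spec's grid", call. = FALSE)
  }
  S <- signal_means(spec)[, voxels, drop = FALSE]
  if (conditions == "categories") {
    grp <- rep(face_categories, each = 8L)
    S <- rowsum(S, grp, reorder = FALSE) / 8
    S <- S[face_categories, , drop = FALSE]
  }
  labels <- rownames(S)
  n_runs <- design$n_runs
  betas <- array(NA_real_, dim = c(n_runs, nrow(S), ncol(S)),
                 dimnames = list(NULL, labels, NULL))
  for (r in seq_len(n_runs)) {
    eps <- with_seed(sub_seed(seed, 7000L + r), {
      matrix(rnorm(length(S), sd = noise_sd), nrow = nrow(S))
    })
    betas[r, , ] <- S + eps
  }
  beta_patterns(betas, labels, voxels, spec$grid_shape, spec$affine)
}

#' Construct a beta pattern set
#'
#' @param betas run x condition x voxel array.
#' @param conditions Condition labels (length = dim 2).
#' @param voxels Grid voxel indices (length = dim 3).
#' @param grid_shape,affine Grid geometry.
#' @return A `beta_patterns` object.
#' @export
beta_patterns <- function(betas, conditions, voxels, grid_shape, affine) {
  stopifnot(length(dim(betas)) == 3L,
            dim(betas)[2] == length(conditions),
            dim(betas)[3] == length(voxels))
  structure(list(
    betas = betas,
    conditions = conditions,
    voxels = as.integer(voxels),
    grid_shape = as.integer(grid_shape),
    affine = affine
  ), class = "beta_patterns")
}

#' @export
print.beta_patterns <- function(x, ...) {
  d <- dim(x$betas)
  cat(sprintf("<beta_patterns> %d run(s) x %d condition(s) x %d voxel(s)\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Restrict a beta pattern set to a subset of its voxels
#'
#' @param patterns A `beta_patterns` object.
#' @param idx Positions into the pattern set's voxel axis (not grid indices).
#' @return A `beta_patterns` object over the selected voxels.
#' @export
restrict_voxels <- function(patterns, idx) {
  beta_patterns(patterns$betas[, , idx, drop = FALSE], patterns$conditions,
                patterns$voxels[idx], patterns$grid_shape, patterns$affine)
}

#' Restrict a beta pattern set to a subset of conditions
#'
#' @param patterns A `beta_patterns` object.
#' @param keep Condition labels to keep.
#' @return A `beta_patterns` object.
#' @export
restrict_conditions <- function(patterns, keep) {
  j <- match(keep, patterns$conditions)
  if (anyNA(j)) {
    stop("unknown condition(s): ", paste(keep[is.na(j)], collapse = ", "),
         call. = FALSE)
  }
  beta_patterns(patterns$betas[, j, , drop = FALSE], patterns$conditions[j],
                patterns$voxels, patterns$grid_shape, patterns$affine)
}
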