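#' Subtract the mean pattern across conditions
#'
#' Removes the common response pattern: for every run and voxel, the mean
#' over conditions becomes exactly zero.
#'
#' @param patterns A `beta_patterns` with at least two conditions.
#' @return The normalized `beta_patterns`.
#' @export
mean_subtract <- function(patterns) {
  d <- dim(patterns$betas)
  if (d[2] < 2L) {
    stop("mean subtraction needs at least two conditions", call. = FALSE)
  }
  m <- apply(patterns$betas, c(1, 3), mean)       # run x voxel
  patterns$betas <- patterns$betas -
    aperm(array(m, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
  patterns
}

# All distinct unordered half-partitions of runs, canonically keyed by the
# half containing run 1. Samples `n` without replacement (or enumerates all
# when fewer exist).
sample_half_splits <- function(n_runs, n, seed) {
  h <- n_runs / 2
  total <- choose(n_runs - 1L, h - 1L)   # partitions with run 1 fixed in half A
  if (n >= total) {
    others <- combn(2:n_runs, h - 1L)
    return(lapply(seq_len(ncol(others)), function(i) c(1L, others[, i])))
  }
  with_seed(seed, {
    seen <- character(0)
    out <- list()
    while (length(out) < n) {
      half <- sort(c(1L, sample(2:n_runs, h - 1L)))
      key <- paste(half, collapse = ",")
      if (!key %in% seen) {
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- half
      }
    }
    out
  })
}

#' Split-data representational similarity matrix
#'
#' For each of `n_permutations` random splits of the runs into two equal
#' halves, condition patterns are averaged within each half and every
#' condition pair is correlated across halves (Pearson), giving an N x N
#' matrix with rows indexed by half-A conditions; matrices are then averaged
#' over the sampled splits. Splits are distinct unordered half-partitions
#' sampled without replacement (all of them when fewer exist than requested).
#'
#' @param patterns A `beta_patterns` with an even number (>= 2) of runs and
#'   >= 2 voxels. Normally mean-subtracted first (see [mean_subtract()]).
#' @param n_permutations Number of run splits to average (default 100).
#' @param seed Split-sampling seed.
#' @param symmetrize If `TRUE`, average the matrix with its transpose.
#' @return A `split_rsm` object: list with `matrix`, `conditions`,
#'   `n_permutations_averaged`, `symmetrized`, `seed`.
#' @export
split_rsm <- function(patterns, n_permutations = 100L, seed = 1L,
                      symmetrize = FALSE) {
  b <- patterns$betas
  n_runs <- dim(b)[1]
  if (n_runs < 2L || n_runs %% 2L != 0L) {
    stop("split_rsm needs an even number (>= 2) of runs", call. = FALSE)
  }
  if (dim(b)[3] < 2L) stop("split_rsm needs >= 2 voxels", call. = FALSE)
  splits <- sample_half_splits(n_runs, n_permutations, seed)
  nc <- dim(b)[2]
  acc <- matrix(0, nc, nc)
  n_missing <- 0L
  for (half in splits) {
    other <- setdiff(seq_len(n_runs), half)
    A <- apply(b[half, , , drop = FALSE], c(2, 3), mean)
    B <- apply(b[other, , , drop = FALSE], c(2, 3), mean)
    R <- suppressWarnings(cor(t(A), t(B)))
    if (anyNA(R)) n_missing <- n_missing + 1L
    acc <- acc + R
  }
  if (n_missing > 0L) {
    warning(sprintf(
      "zero-variance pattern(s): undefined correlations in %d split(s) propagate as NA",
      n_missing))
  }
  m <- acc / length(splits)
  if (symmetrize) m <- (m + t(m)) / 2
  dimnames(m) <- list(patterns$conditions, patterns$conditions)
  structure(list(
    matrix = m,
    conditions = patterns$conditions,
    n_permutations_averaged = length(splits),
    symmetrized = symmetrize,
    seed = seed
  ), class = "split_rsm")
}

#' @export
print.split_rsm <- function(x, ...) {
  cat(sprintf("<split_rsm> %d conditions, %d split(s) averaged%s\n",
              length(x$conditions), x$n_permutations_averaged,
              if (x$symmetrized) ", symmetrized" else ""))
  invisible(x)
}

#' Category discriminability index
#'
#' Mean of the diagonal (within-condition cross-half correlations) minus the
#' mean of all off-diagonal entries of a split-data RSM. Missing entries are
#' excluded from either mean with a warning.
#'
#' @param rsm A `split_rsm` or a square numeric matrix.
#' @return The CDI value.
#' @export
cdi <- function(rsm) {
  m <- if (inherits(rsm, "split_rsm")) rsm$matrix else as.matrix(rsm)
  if (nrow(m) < 2L || nrow(m) != ncol(m)) {
    stop("cdi needs a square matrix with N >= 2", call. = FALSE)
  }
  if (anyNA(m)) warning("missing entries excluded from CDI means")
  on <- diag(m)
  off <- m[row(m) != col(m)]
  mean(on, na.rm = TRUE) - mean(off, na.rm = TRUE)
}

#' Ideal categorical model matrix
#'
#' The identity matrix: 1 on the diagonal (same condition), 0 elsewhere.
#'
#' @param label `"subcategories"` (N = 4) or `"identities"` (N = 32), or any
#'   vector of condition labels.
#' @return A `model_matrix` object (binary symmetric matrix with trace N).
#' @export
model_matrix <- function(label = c("subcategories", "identities")) {
  if (length(label) == 1L && label %in% c("subcategories", "identities")) {
    conds <- if (label == "subcategories") {
      familiar_categories()
    } else {
      as.vector(t(outer(familiar_categories(), 1:8, paste, sep = ":")))
    }
  } else {
    conds <- label
    label <- "custom"
  }
  m <- diag(length(conds))
  dimnames(m) <- list(conds, conds)
  structure(list(matrix = m, label = label, conditions = conds),
            class = "model_matrix")
}

#' Kendall rank correlation, tau-a variant
#'
#' `tau_a = (C - D) / (n (n - 1) / 2)` over all pairs; tied pairs (in either
#' vector) count as neither concordant nor discordant.
#'
#' @param x,y Numeric vectors of equal length.
#' @return tau-a in `[-1, 1]`.
#' @export
kendall_tau_a <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  up <- upper.tri(sx)
  sum(sx[up] * sy[up]) / (n * (n - 1) / 2)
}

#' Correlate a split-data RSM with a categorical model
#'
#' Kendall tau-a between the vectorized symmetrized RSM (diagonal plus
#' upper-triangle entries) and the same entries of the model matrix. The
#' diagonal is included: for an identity-matrix model the off-diagonal is
#' constant, so excluding it would leave the model vector constant and tau
#' undefined.
#'
#' @param rsm A `split_rsm` (or square matrix) matching the model's size.
#' @param model A `model_matrix`.
#' @return Kendall tau-a.
#' @export
model_correlation <- function(rsm, model) {
  m <- if (inherits(rsm, "split_rsm")) rsm$matrix else as.matrix(rsm)
  mm <- model$matrix
  if (!all(dim(m) == dim(mm))) {
    stop("rsm and model dimensions differ", call. = FALSE)
  }
  sym <- (m + t(m)) / 2
  keep <- upper.tri(sym, diag = TRUE)
  v <- sym[keep]
  w <- mm[keep]
  if (anyNA(v)) stop("rsm contains missing entries", call. = FALSE)
  if (max(v) - min(v) < .Machine$double.eps * 100) {
    stop("constant rsm vector: Kendall tau undefined", call. = FALSE)
  }
  kendall_tau_a(v, w)
}

#' Group-level inference with BH-FDR control
#'
#' One-sample t tests of per-subject values against a null value, one test
#' per column, with Benjamini-Hochberg step-up correction across tests.
#'
#' @param per_subject_values Numeric matrix (subjects x tests) or vector
#'   (one test).
#' @param null_value Null hypothesis value (e.g. 0 for CDI/tau, 0.5 for
#'   decoding accuracy).
#' @param alpha FDR level (default 0.05).
#' @param alternative Passed to [stats::t.test()] (default `"two.sided"`).
#' @return A tibble: test, estimate, statistic, p_value, p_adjusted,
#'   fdr_significant, degenerate.
#' @export
group_inference <- function(per_subject_values, null_value = 0, alpha = 0.05,
                            alternative = "two.sided") {
  x <- as.matrix(per_subject_values)
  if (nrow(x) < 2L) stop("group inference needs >= 2 subjects", call. = FALSE)
  tests <- colnames(x) %||% paste0("test", seq_len(ncol(x)))
  res <- lapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    if (sd(v) == 0) {
      return(tibble::tibble(test = tests[j], estimate = mean(v),
                            statistic = NA_real_,
                            p_value = if (mean(v) == null_value) 1 else NA_real_,
                            degenerate = TRUE))
    }
    tt <- t.test(v, mu = null_value, alternative = alternative)
    tibble::tibble(test = tests[j], estimate = unname(tt$estimate),
                   statistic = unname(tt$statistic), p_value = tt$p.value,
                   degenerate = FALSE)
  })
  out <- dplyr::bind_rows(res)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out$fdr_significant <- !is.na(out$p_adjusted) & out$p_adjusted <= alpha
  out[, c("test", "estimate", "statistic", "p_value", "p_adjusted",
          "fdr_significant", "degenerate")]
}
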