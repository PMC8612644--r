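# Refactored entry computation shared with run_searchlight: optional
# explicit list of run-halves instead of sampled splits.
searchlight_tau_map <- function(patterns, nbhd, model, splits) {
  E <- searchlight_rsm_entries_splits(patterns, nbhd, splits)
  nc <- dim(patterns$betas)[2]
  iu <- which(upper.tri(matrix(0, nc, nc), diag = TRUE))
  ii <- ((iu - 1L) %% nc) + 1L
  jj <- ((iu - 1L) %/% nc) + 1L
  Esym <- (E[, (jj - 1L) * nc + ii, drop = FALSE] +
             E[, (ii - 1L) * nc + jj, drop = FALSE]) / 2
  w <- model$matrix[cbind(ii, jj)]
  tau_a_binary_rows(Esym, w)
}

# Per-run familiarity contrast t-map over a half-set of runs, one subject.
univariate_half_t <- function(patterns, half) {
  fam <- match(familiar_categories(), patterns$conditions)
  unf <- match("unfamiliar", patterns$conditions)
  if (anyNA(c(fam, unf))) {
    stop("univariate contrast needs category-level patterns", call. = FALSE)
  }
  b <- patterns$betas[half, , , drop = FALSE]
  contr <- apply(b[, fam, , drop = FALSE], c(1, 3), mean) -
    b[, unf, ]                                   # run x voxel
  mu <- colMeans(contr)
  se <- apply(contr, 2, sd) / sqrt(length(half))
  mu / se
}

#' Harvest peak-activation coordinates over run-split permutations
#'
#' Repeats an analysis over random splits of the runs and records, for each
#' permutation, the metric coordinate of the in-mask maximum of the
#' subject-averaged map:
#' * `univariate_contrast` — familiar-vs-unfamiliar contrast t-map per
#'   half-set of runs (each split contributes its two complementary halves,
#'   so `ceiling(n_perm / 2)` splits give `n_perm` peaks);
#' * `subcategory_searchlight` — single-split searchlight map of Kendall
#'   tau-a with the 4 x 4 categorical model (familiar categories);
#' * `identity_searchlight` — same with the 32 x 32 identity model.
#'
#' Searchlight maps are computed per subject on mean-subtracted patterns of
#' the familiar conditions and averaged across subjects before the argmax.
#'
#' @param patterns_by_subject List of `beta_patterns`, one per subject:
#'   category-level (5 conditions) for the univariate and subcategory
#'   analyses, identity-level (40 conditions) for the identity analysis.
#' @param nbhd A `neighborhoods` over the analysis mask (its voxel set also
#'   defines the univariate peak-search mask).
#' @param analysis Which analysis to permute.
#' @param n_perm Number of peaks to harvest (default 500).
#' @param seed Split-sampling seed.
#' @return A `peak_set` tibble: `label`, `perm`, `R`, `A`, `S` (mm).
#' @export
harvest_peaks <- function(patterns_by_subject,
                          nbhd,
                          analysis = c("univariate_contrast",
                                       "subcategory_searchlight",
                                       "identity_searchlight"),
                          n_perm = 500L, seed = 1L) {
  analysis <- match.arg(analysis)
  stopifnot(length(patterns_by_subject) >= 1L)
  n_runs <- dim(patterns_by_subject[[1]]$betas)[1]
  if (n_runs %% 2L != 0L) stop("even run count required", call. = FALSE)
  label <- c(univariate_contrast = "familiarity",
             subcategory_searchlight = "subcategory",
             identity_searchlight = "identity")[[analysis]]

  if (analysis == "univariate_contrast") {
    n_splits <- ceiling(n_perm / 2)
    splits <- sample_half_splits(n_runs, n_splits, sub_seed(seed, 11L))
    halves <- list()
    for (s in splits) {
      halves <- c(halves, list(s), list(setdiff(seq_len(n_runs), s)))
    }
    halves <- halves[seq_len(n_perm)]
    peaks <- vapply(halves, function(half) {
      maps <- vapply(patterns_by_subject, univariate_half_t, half = half,
                     numeric(length(nbhd$voxels)))
      v <- rowMeans(maps)
      if (all(is.na(v))) stop("all-missing map; cannot harvest peak",
                              call. = FALSE)
      drop(voxel_to_mm(nbhd$voxels[which.max(v)], nbhd$grid_shape,
                       nbhd$affine))
    }, numeric(3))
  } else {
    model <- if (analysis == "subcategory_searchlight") {
      model_matrix("subcategories")
    } else {
      model_matrix("identities")
    }
    prepped <- lapply(patterns_by_subject, function(p) {
      mean_subtract(restrict_conditions(p, model$conditions))
    })
    splits <- sample_half_splits(n_runs, n_perm, sub_seed(seed, 13L))
    if (length(splits) < n_perm) {
      # fewer distinct partitions than requested permutations: reuse
      splits <- rep(splits, length.out = n_perm)
    }
    peaks <- vapply(splits, function(half) {
      maps <- vapply(prepped, function(p) {
        searchlight_tau_map(p, nbhd, model, list(half))
      }, numeric(length(nbhd$centers)))
      v <- rowMeans(maps)
      if (all(is.na(v))) stop("all-missing map; cannot harvest peak",
                              call. = FALSE)
      drop(voxel_to_mm(nbhd$voxels[which.max(v)], nbhd$grid_shape,
                       nbhd$affine))
    }, numeric(3))
  }

  out <- tibble::tibble(
    label = label,
    perm = seq_len(ncol(peaks)),
    R = peaks[1, ], A = peaks[2, ], S = peaks[3, ]
  )
  class(out) <- c("peak_set", class(out))
  out
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of group separation on a dissimilarity
#' matrix: `R = (mean rank between-group - mean rank within-group) / (M/2)`
#' with `M = n(n-1)/2` pairwise dissimilarities and mid-ranks for ties. The
#' permutation p-value uses the add-one convention
#' `p = (1 + #\{permuted R >= observed\}) / (1 + n_perm)`.
#'
#' @param dissimilarity Square symmetric nonnegative matrix (or `dist`).
#' @param labels Group labels, length n; every group must have >= 2 members.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Permutation seed.
#' @return An `anosim_result`: list with `R`, `p`, `n_permutations`,
#'   `perm_R`.
#' @export
anosim <- function(dissimilarity, labels, n_perm = 1000L, seed = 1L) {
  d <- as.matrix(dissimilarity)
  n <- nrow(d)
  stopifnot(ncol(d) == n, length(labels) == n)
  if (any(d < 0) || max(abs(d - t(d))) > 1e-8) {
    stop("dissimilarity must be square, symmetric and nonnegative",
         call. = FALSE)
  }
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(table(labels) < 2L)) {
    stop("every group needs >= 2 members (within-group mean undefined)",
         call. = FALSE)
  }
  pairs <- which(upper.tri(d))
  ii <- ((pairs - 1L) %% n) + 1L
  jj <- ((pairs - 1L) %/% n) + 1L
  rk <- rank(d[pairs])            # mid-ranks for ties
  M <- length(rk)
  r_stat <- function(lab) {
    between <- lab[ii] != lab[jj]
    (mean(rk[between]) - mean(rk[!between])) / (M / 2)
  }
  R_obs <- r_stat(labels)
  perm_R <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) r_stat(sample(labels)), numeric(1))
  })
  structure(list(
    R = R_obs,
    p = (1 + sum(perm_R >= R_obs)) / (1 + n_perm),
    n_permutations = as.integer(n_perm),
    perm_R = perm_R
  ), class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM R = %.4f, p = %.4g (%d permutations)\n",
              x$R, x$p, x$n_permutations))
  invisible(x)
}

#' Rank tests on peak coordinate distributions
#'
#' Kruskal-Wallis test on each coordinate axis (R, A, S) across all labels,
#' plus pairwise two-tailed Mann-Whitney U tests per axis (normal
#' approximation with tie correction). Bonferroni correction is applied
#' within each family: the 3 axis-wise Kruskal-Wallis tests, and the
#' `3 x n_pairs` pairwise tests. The joint decision is "any axis significant
#' after correction".
#'
#' @param peaks A `peak_set` (or tibble with `label`, `R`, `A`, `S`); >= 2
#'   groups with >= 2 points each.
#' @param alpha Significance level (default 0.05).
#' @return A tibble: `test` (kruskal_wallis / mann_whitney), `axis`,
#'   `group1`, `group2` (NA for the omnibus test), `statistic`, `p_value`,
#'   `p_bonferroni`, `significant`; attribute `"joint_significant"`.
#' @export
peak_location_tests <- function(peaks, alpha = 0.05) {
  labs <- as.factor(peaks$label)
  stopifnot(nlevels(labs) >= 2L, all(table(labs) >= 2L))
  axes <- c("R", "A", "S")
  rows <- list()
  for (ax in axes) {
    v <- peaks[[ax]]
    if (all(vapply(split(v, labs), function(g) length(unique(g)) == 1L,
                   logical(1))) && length(unique(v)) == 1L) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        test = "kruskal_wallis", axis = ax, group1 = NA_character_,
        group2 = NA_character_, statistic = NA_real_, p_value = NA_real_,
        note = "constant axis; test skipped")
      next
    }
    kw <- kruskal.test(v, labs)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      test = "kruskal_wallis", axis = ax, group1 = NA_character_,
      group2 = NA_character_, statistic = unname(kw$statistic),
      p_value = kw$p.value, note = NA_character_)
  }
  prs <- combn(levels(labs), 2L)
  for (i in seq_len(ncol(prs))) {
    for (ax in axes) {
      a <- peaks[[ax]][labs == prs[1, i]]
      b <- peaks[[ax]][labs == prs[2, i]]
      if (length(unique(c(a, b))) == 1L) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          test = "mann_whitney", axis = ax, group1 = prs[1, i],
          group2 = prs[2, i], statistic = NA_real_, p_value = NA_real_,
          note = "constant axis; test skipped")
        next
      }
      mw <- suppressWarnings(
        wilcox.test(a, b, alternative = "two.sided", exact = FALSE,
                    correct = TRUE))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        test = "mann_whitney", axis = ax, group1 = prs[1, i],
        group2 = prs[2, i], statistic = unname(mw$statistic),
        p_value = mw$p.value, note = NA_character_)
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::group_by(out, .data$test)
  out <- dplyr::mutate(out,
                       p_bonferroni = pmin(1, .data$p_value * sum(!is.na(.data$p_value))))
  out <- dplyr::ungroup(out)
  out$significant <- !is.na(out$p_bonferroni) & out$p_bonferroni <= alpha
  attr(out, "joint_significant") <-
    any(out$significant[out$test == "kruskal_wallis"])
  out
}

# log multivariate normal density via Cholesky, with trace regularization
# for singular covariances
log_dmvnorm <- function(x, mu, sigma, reg = 1e-6) {
  p <- ncol(x)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    warning("singular covariance regularized")
    sigma <- sigma + diag(reg * sum(diag(sigma)) / p + reg, p)
    ch <- chol(sigma)
  }
  z <- forwardsolve(t(ch), t(x) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * p * log(2 * pi)
}

#' Explicit-parameter Gaussian mixture fit with AIC
#'
#' Fits a k-component 3-D Gaussian mixture whose parameters are plugged in
#' directly from group sample statistics (no iterative fitting): component
#' means are the group means, covariances the group sample covariances,
#' mixing proportions the group sizes over the total. `k = 1` uses pooled
#' statistics; otherwise `k` must equal the number of groups. The free
#' parameter count is `k (3 + 6 + 1) - 1` (means, symmetric covariances,
#' proportions, minus the sum-to-one constraint) and
#' `AIC = 2 df - 2 logLik`.
#'
#' @param points n x 3 matrix of coordinates.
#' @param group_labels Length-n group labels (each group needs >= 4 points).
#' @param k Component count (1, or the number of groups).
#' @return A `mixture_fit`: list with `k`, `log_likelihood`, `df`, `aic`.
#' @export
mixture_aic <- function(points, group_labels, k) {
  x <- as.matrix(points)
  stopifnot(ncol(x) == 3L)
  labs <- as.factor(group_labels)
  if (any(table(labs) < 4L)) {
    stop("each group needs >= 4 points to estimate its covariance",
         call. = FALSE)
  }
  if (k == 1L) {
    comps <- list(list(mu = colMeans(x), sigma = stats::cov(x), pi = 1))
  } else if (k == nlevels(labs)) {
    comps <- lapply(levels(labs), function(l) {
      xi <- x[labs == l, , drop = FALSE]
      list(mu = colMeans(xi), sigma = stats::cov(xi),
           pi = nrow(xi) / nrow(x))
    })
  } else {
    stop("k must be 1 or the number of groups", call. = FALSE)
  }
  dens <- vapply(comps, function(cp) {
    cp$pi * exp(log_dmvnorm(x, cp$mu, cp$sigma))
  }, numeric(nrow(x)))
  ll <- sum(log(rowSums(matrix(dens, nrow = nrow(x)))))
  df <- k * (3 + 6 + 1) - 1
  structure(list(k = as.integer(k), log_likelihood = ll, df = df,
                 aic = 2 * df - 2 * ll),
            class = "mixture_fit")
}

#' Compare explicit-parameter mixture models by AIC
#'
#' @param points n x 3 coordinates.
#' @param group_labels Group labels.
#' @param ks Component counts to compare (default 1 and the group count).
#' @return Tibble: `k`, `log_likelihood`, `df`, `aic`,
#'   `relative_likelihood` (`exp((min AIC - AIC)/2)`, 1 for the best model).
#' @export
compare_mixtures <- function(points, group_labels,
                             ks = c(1L, nlevels(as.factor(group_labels)))) {
  fits <- lapply(ks, function(k) mixture_aic(points, group_labels, k))
  out <- tibble::tibble(
    k = vapply(fits, `[[`, integer(1), "k"),
    log_likelihood = vapply(fits, `[[`, numeric(1), "log_likelihood"),
    df = vapply(fits, `[[`, numeric(1), "df"),
    aic = vapply(fits, `[[`, numeric(1), "aic")
  )
  out$relative_likelihood <- exp((min(out$aic) - out$aic) / 2)
  out
}

#' Dice overlap coefficient of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 0 when both masks are
#' empty.
#'
#' @param maskA,maskB Logical arrays/vectors on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(maskA, maskB) {
  if (!all(dim(maskA) %||% length(maskA) == dim(maskB) %||% length(maskB))) {
    stop("masks are on different grids", call. = FALSE)
  }
  a <- as.logical(maskA)
  b <- as.logical(maskB)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(0)
  2 * sum(a & b) / denom
}
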