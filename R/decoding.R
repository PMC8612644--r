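#' Pairwise linear-SVM decoding with leave-one-run-out cross-validation
#'
#' For one category pair, trains a linear soft-margin support-vector
#' classifier on all runs but one (one pattern per condition per run) and
#' tests on the left-out run, cycling through every run. A test pattern whose
#' decision value is exactly 0 (a tie on the boundary) counts as an error.
#'
#' @param patterns A `beta_patterns`; both categories must be present.
#' @param pair Character vector of two condition labels.
#' @param cost Soft-margin cost (default 1).
#' @param standardize If `TRUE`, per-fold feature standardization fit on the
#'   training folds only (default `FALSE`: patterns are assumed
#'   mean-subtracted already).
#' @return A `decoding_result` tibble with one row per fold: `pair`, `fold`
#'   (left-out run), `accuracy`; attributes `mean_accuracy` and `pair`.
#' @export
pairwise_svm_cv <- function(patterns, pair, cost = 1, standardize = FALSE) {
  stopifnot(length(pair) == 2L)
  j <- match(pair, patterns$conditions)
  if (anyNA(j)) {
    stop("pair contains unknown condition(s): ",
         paste(pair[is.na(j)], collapse = ", "), call. = FALSE)
  }
  b <- patterns$betas
  n_runs <- dim(b)[1]
  if (n_runs < 2L) stop("need >= 2 runs for cross-validation", call. = FALSE)
  if (any(!is.finite(b[, j, ]))) {
    bad <- which(apply(!is.finite(b[, j, , drop = FALSE]), 1, any))
    stop("category missing/non-finite in run(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  X <- rbind(matrix(b[, j[1], ], nrow = n_runs),
             matrix(b[, j[2], ], nrow = n_runs))
  y <- factor(rep(pair, each = n_runs), levels = pair)
  run_of <- rep(seq_len(n_runs), times = 2L)

  fold_acc <- vapply(seq_len(n_runs), function(r) {
    tr <- run_of != r
    Xtr <- X[tr, , drop = FALSE]
    Xte <- X[!tr, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(Xtr)
      s <- apply(Xtr, 2, sd)
      s[s == 0] <- 1
      Xtr <- scale(Xtr, mu, s)
      Xte <- scale(Xte, mu, s)
    }
    fit <- e1071::svm(Xtr, y[tr], kernel = "linear", cost = cost,
                      scale = FALSE)
    pred <- stats::predict(fit, Xte, decision.values = TRUE)
    dec <- attr(pred, "decision.values")
    mean(pred == y[!tr] & as.numeric(dec) != 0)
  }, numeric(1))

  out <- tibble::tibble(
    pair = paste(pair, collapse = " vs "),
    fold = seq_len(n_runs),
    accuracy = fold_acc
  )
  class(out) <- c("decoding_result", class(out))
  attr(out, "mean_accuracy") <- mean(fold_acc)
  attr(out, "pair") <- pair
  out
}

#' Decode all six familiar-category pairs
#'
#' Runs [pairwise_svm_cv()] for every unordered pair of the four familiar
#' categories (or of any supplied condition set).
#'
#' @param patterns A `beta_patterns`.
#' @param categories Conditions to pair (default the four familiar
#'   categories).
#' @param ... Passed to [pairwise_svm_cv()].
#' @return Tibble: pair, mean_accuracy.
#' @export
decode_all_pairs <- function(patterns, categories = familiar_categories(),
                             ...) {
  pairs <- combn(categories, 2L)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    res <- pairwise_svm_cv(patterns, pairs[, i], ...)
    tibble::tibble(pair = res$pair[1],
                   mean_accuracy = attr(res, "mean_accuracy"))
  })
}

#' Group significance of decoding accuracies against chance
#'
#' One-sample t test per category pair versus chance level, BH-FDR corrected
#' across pairs (delegates to [group_inference()]).
#'
#' @param results_by_subject Matrix (subjects x pairs) of mean accuracies,
#'   or a tibble with columns `subject`, `pair`, `mean_accuracy`.
#' @param chance Chance accuracy (default 0.5).
#' @param alpha FDR level (default 0.05).
#' @return The [group_inference()] tibble.
#' @export
decoding_significance <- function(results_by_subject, chance = 0.5,
                                  alpha = 0.05) {
  x <- results_by_subject
  if (is.data.frame(x)) {
    w <- tidyr::pivot_wider(x[, c("subject", "pair", "mean_accuracy")],
                            names_from = "pair",
                            values_from = "mean_accuracy")
    x <- as.matrix(w[, -1, drop = FALSE])
  }
  group_inference(x, null_value = chance, alpha = alpha)
}
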