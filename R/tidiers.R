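#' Tidy a split-data RSM into long form
#'
#' @param x A `split_rsm`.
#' @param ... Unused.
#' @return Tibble: `condition_a`, `condition_b`, `r`.
#' @export
tidy.split_rsm <- function(x, ...) {
  m <- x$matrix
  tibble::tibble(
    condition_a = rep(rownames(m), times = ncol(m)),
    condition_b = rep(colnames(m), each = nrow(m)),
    r = as.vector(m)
  )
}

#' One-row summary of a split-data RSM
#'
#' @param x A `split_rsm`.
#' @param ... Unused.
#' @return Tibble with `n_conditions`, `n_permutations_averaged`, `cdi`.
#' @export
glance.split_rsm <- function(x, ...) {
  tibble::tibble(
    n_conditions = length(x$conditions),
    n_permutations_averaged = x$n_permutations_averaged,
    symmetrized = x$symmetrized,
    cdi = cdi(x)
  )
}

#' Tidy an ANOSIM result
#'
#' @param x An `anosim_result`.
#' @param ... Unused.
#' @return One-row tibble: `R`, `p_value`, `n_permutations`.
#' @export
tidy.anosim_result <- function(x, ...) {
  tibble::tibble(R = x$R, p_value = x$p, n_permutations = x$n_permutations)
}

#' Tidy a mixture fit
#'
#' @param x A `mixture_fit`.
#' @param ... Unused.
#' @return One-row tibble: `k`, `log_likelihood`, `df`, `aic`.
#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble::tibble(k = x$k, log_likelihood = x$log_likelihood, df = x$df,
                 aic = x$aic)
}

#' Tidy a multiclass LOOCV result
#'
#' @param x A `loocv_result`.
#' @param ... Unused.
#' @return Long confusion-matrix tibble: `expected`, `predicted`, `count`.
#' @export
tidy.loocv_result <- function(x, ...) {
  conf <- x$confusion
  tibble::tibble(
    expected = rep(rownames(conf), times = ncol(conf)),
    predicted = rep(colnames(conf), each = nrow(conf)),
    count = as.vector(conf)
  )
}

#' @rdname tidy.loocv_result
#' @export
glance.loocv_result <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy,
                 perm_p = x$perm_p %||% NA_real_)
}
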