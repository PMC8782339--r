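#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Kruskal-Wallis result
#'
#' @param x a `speechlr_kw` object.
#' @param ... unused.
#' @return A one-row tibble: `statistic`, `df`, `p.value`, `k`, `n`.
#' @export
tidy.speechlr_kw <- function(x, ...) {
  tibble::tibble(statistic = x$H, df = x$df, p.value = x$p, k = x$k, n = x$n)
}

#' @rdname tidy.speechlr_kw
#' @export
glance.speechlr_kw <- function(x, ...) {
  dplyr::bind_cols(tidy(x), eta_squared_kw(x))
}

#' Tidy a score set
#'
#' @param x a `speechlr_scores` object.
#' @param ... unused.
#' @return The underlying trial tibble plus a `parameter` column.
#' @export
tidy.speechlr_scores <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$parameter <- attr(x, "parameter")
  out$calibrated <- attr(x, "calibrated")
  out
}

#' @rdname tidy.speechlr_scores
#' @return `glance()`: one row of system metrics (`cllr_raw`, `cllr_cal`,
#'   `eer`, trial counts).
#' @export
glance.speechlr_scores <- function(x, ...) {
  if (isTRUE(attr(x, "calibrated"))) {
    abort("glance() expects raw scores; calibration is applied internally")
  }
  system_metrics(x)
}

#' Tidy an LR model
#'
#' @param x an `lr_model`.
#' @param ... unused.
#' @return Tibble of background speaker means.
#' @export
tidy.lr_model <- function(x, ...) {
  tibble::tibble(speaker_mean = x$speaker_means)
}

#' @rdname tidy.lr_model
#' @export
glance.lr_model <- function(x, ...) {
  tibble::tibble(k = x$k, within_sd = sqrt(x$within_var),
                 bandwidth = x$bandwidth)
}
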