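resolve_groups <- function(data, value, group) {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  v <- rlang::eval_tidy(value, data)
  g <- as.character(rlang::eval_tidy(group, data))
  keep <- is.finite(v) & !is.na(g)
  list(values = v[keep], groups = g[keep])
}

#' Kruskal-Wallis rank-sum test across speakers
#'
#' Thin, tidy wrapper around [stats::kruskal.test()] (tie-corrected H,
#' chi-square reference with `k - 1` degrees of freedom), the omnibus test
#' used to ask whether a timing parameter differs across speakers at all.
#'
#' @param data a data frame of observations.
#' @param value,group tidy-selected columns holding the observation values
#'   and the group (speaker) labels. Defaults `value`, `speaker`.
#' @return An object of class `speechlr_kw` with fields `H`, `df`, `p`, `k`,
#'   `n`; see [tidy()] / [glance()].
#' @examples
#' d <- data.frame(speaker = rep(c("A1", "A2"), each = 3),
#'                 value = c(1, 2, 3, 4, 5, 6))
#' kruskal_wallis(d)
#' @export
kruskal_wallis <- function(data, value = value, group = speaker) {
  gd <- resolve_groups(data, {{ value }}, {{ group }})
  k <- length(unique(gd$groups))
  if (k < 2) abort("need at least 2 groups")
  if (any(table(gd$groups) == 0)) abort("every group must be nonempty")
  if (length(unique(gd$values)) == 1) {
    abort("all values identical: Kruskal-Wallis statistic undefined (tie correction degenerates)")
  }
  kt <- stats::kruskal.test(gd$values, factor(gd$groups))
  structure(list(
    H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value,
    k = k, n = length(gd$values)
  ), class = "speechlr_kw")
}

#' @export
print.speechlr_kw <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g (k = %d, n = %d)\n",
              x$H, x$df, x$p, x$k, x$n))
  invisible(x)
}

#' Dunn's multiple-comparison test with Bonferroni adjustment
#'
#' Two-tailed pairwise rank comparisons after a Kruskal-Wallis test, with the
#' usual tie correction in the pooled-rank variance. Adjusted p-values are
#' `min(1, m * p_raw)`; with 20 speakers the default `m` is the 190
#' comparisons among all individuals.
#'
#' @inheritParams kruskal_wallis
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @param m number of comparisons for the Bonferroni factor; default
#'   `k * (k - 1) / 2`.
#' @return A tibble with one row per unordered pair: `speaker_a`,
#'   `speaker_b`, `z`, `p_raw`, `p_adj`, `significant`.
#' @export
dunn_posthoc <- function(data, value = value, group = speaker,
                         alpha = 0.05, m = NULL) {
  gd <- resolve_groups(data, {{ value }}, {{ group }})
  labs <- sort(unique(gd$groups))
  k <- length(labs)
  if (k < 2) abort("need at least 2 groups")
  ni <- table(factor(gd$groups, levels = labs))
  if (any(ni == 0)) abort("every group must be nonempty")
  m <- m %||% (k * (k - 1) / 2)
  N <- length(gd$values)
  r <- rank(gd$values)
  rbar <- tapply(r, factor(gd$groups, levels = labs), mean)
  ties <- table(gd$values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_corr
  pairs <- utils::combn(labs, 2)
  z <- p_raw <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(v0 * (1 / ni[[a]] + 1 / ni[[b]]))
    z[j] <- if (se == 0) 0 else (rbar[[a]] - rbar[[b]]) / se
    p_raw[j] <- 2 * pnorm(-abs(z[j]))
  }
  p_adj <- pmin(1, m * p_raw)
  tibble::tibble(
    speaker_a = pairs[1, ], speaker_b = pairs[2, ],
    z = z, p_raw = p_raw, p_adj = p_adj,
    significant = p_adj < alpha
  )
}

#' Kruskal-Wallis effect size (eta squared)
#'
#' The rank-based eta squared, `(H - k + 1) / (n - k)`: the share of variance
#' in the parameter explained by speaker identity. Reported as a percentage
#' it is rounded half-up to one decimal.
#'
#' @param H Kruskal-Wallis statistic (or a `speechlr_kw` object, in which
#'   case `k` and `n` are taken from it).
#' @param k number of groups (speakers).
#' @param n total number of observations.
#' @return A one-row tibble: `eta2`, `percent` (half-up, 1 decimal),
#'   `magnitude`.
#' @examples
#' eta_squared_kw(148.7, k = 20, n = 851) # 15.6%, large
#' @export
eta_squared_kw <- function(H, k = NULL, n = NULL) {
  if (inherits(H, "speechlr_kw")) {
    k <- H$k; n <- H$n; H <- H$H
  }
  if (is.null(k) || is.null(n)) abort("`k` and `n` are required")
  if (k < 2) abort("need k >= 2 groups")
  if (n <= k) abort("need n > k observations")
  eta2 <- (H - k + 1) / (n - k)
  tibble::tibble(
    eta2 = eta2,
    percent = round_half_up(100 * eta2, 1),
    magnitude = magnitude_band(eta2)
  )
}

#' Effect-size magnitude band
#'
#' Conventional eta-squared bands: below 0.01 negligible, `[0.01, 0.06)`
#' small, `[0.06, 0.14)` moderate, `>= 0.14` large.
#'
#' @param eta2 numeric vector of eta-squared values.
#' @return Character vector of band labels.
#' @export
magnitude_band <- function(eta2) {
  if (any(!is.finite(eta2))) abort("`eta2` must be finite")
  dplyr::case_when(
    eta2 >= 0.14 ~ "large",
    eta2 >= 0.06 ~ "moderate",
    eta2 >= 0.01 ~ "small",
    TRUE ~ "negligible"
  )
}

#' Balance observation counts by down-sampling
#'
#' Randomly down-samples every speaker's observations of one parameter,
#' without replacement, to the minority speaker's count, removing the n-size
#' imbalance that unscripted speech produces. Deterministic given `seed`.
#'
#' @param data a long parameter table (`speaker`, `parameter`, `value`, ...).
#' @param parameter parameter to balance; `NULL` uses all rows as-is (the
#'   table must then hold a single parameter).
#' @param seed integer seed.
#' @return The balanced table (same columns), every speaker at the minority
#'   count, in deterministic row order.
#' @export
downsample_balance <- function(data, parameter = NULL, seed = 1L) {
  if (!is.null(parameter)) data <- data[data$parameter == parameter, , drop = FALSE]
  counts <- table(data$speaker)
  if (nrow(data) == 0 || any(counts == 0)) {
    missing <- names(counts)[counts == 0]
    abort(paste0("every speaker needs at least one observation of the ",
                 "parameter; none found for: ",
                 paste(missing, collapse = ", ")))
  }
  n_min <- min(counts)
  data <- dplyr::arrange(data, .data$speaker)
  withr::with_seed(seed, {
    dplyr::slice_sample(dplyr::group_by(data, .data$speaker), n = n_min) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$speaker)
  })
}

#' Replicated balanced post-hoc testing
#'
#' Because down-sampling is random, a single balanced Dunn run can be a fluke:
#' the protocol repeats balance-then-test `n_reps` times with independent
#' derived seeds and counts, per speaker pair, how many replications flag the
#' pair significant.
#'
#' @inheritParams downsample_balance
#' @param n_reps number of replications (the study protocol uses 3, 10, 20).
#' @param alpha,m passed to [dunn_posthoc()].
#' @return A tibble: `speaker_a`, `speaker_b`, `n_significant`, `n_reps`,
#'   `balanced_n` (the minority count used), with attribute `parameter`.
#' @export
replication_consistency <- function(data, parameter = NULL, n_reps = 10,
                                    alpha = 0.05, m = NULL, seed = 1L) {
  if (n_reps < 1) abort("`n_reps` must be >= 1")
  if (!is.null(parameter)) data <- data[data$parameter == parameter, , drop = FALSE]
  balanced_n <- min(table(data$speaker))
  tallies <- NULL
  for (r in seq_len(n_reps)) {
    bal <- downsample_balance(data, seed = derive_seed(seed, r))
    d <- dunn_posthoc(bal, alpha = alpha, m = m)
    if (is.null(tallies)) {
      tallies <- d[, c("speaker_a", "speaker_b")]
      tallies$n_significant <- 0L
    }
    tallies$n_significant <- tallies$n_significant + as.integer(d$significant)
  }
  tallies$n_reps <- as.integer(n_reps)
  tallies$balanced_n <- as.integer(balanced_n)
  attr(tallies, "parameter") <- parameter
  tallies
}
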