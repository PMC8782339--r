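#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_line geom_point
#'   geom_vline geom_hline geom_tile geom_col labs theme_minimal
#'   scale_fill_gradient2 facet_wrap coord_flip
NULL

#' @export
ggplot2::autoplot

#' Tippett plot of a score set
#'
#' Cumulative proportions of same-speaker log LRs at or below, and
#' different-speaker log LRs at or above, each threshold — the standard view
#' of an LR system's strength and calibration. Curves crossing far from
#' log10 LR = 0 signal miscalibration.
#'
#' @param object a `speechlr_scores` object.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.speechlr_scores <- function(object, ...) {
  ss <- sort(ss_of(object)); ds <- sort(ds_of(object))
  d <- dplyr::bind_rows(
    tibble::tibble(llr = ss, prop = seq_along(ss) / length(ss),
                   hypothesis = "same speaker (cumulative <=)"),
    tibble::tibble(llr = ds, prop = 1 - (seq_along(ds) - 1) / length(ds),
                   hypothesis = "different speaker (cumulative >=)")
  )
  ggplot(d, aes(x = .data$llr, y = .data$prop, colour = .data$hypothesis)) +
    geom_step() +
    geom_vline(xintercept = 0, linetype = 3) +
    labs(x = expression(log[10] ~ LR), y = "cumulative proportion of trials",
         title = paste0("Tippett plot",
                        if (!is.na(attr(object, "parameter")))
                          paste0(" - ", attr(object, "parameter")) else ""),
         colour = NULL) +
    theme_minimal()
}

#' Plot a pairwise AUC matrix
#'
#' Heatmap of speaker-by-speaker separability (fixed orientation: the row
#' speaker is the positive class). Twin pairs sit next to each other on both
#' axes, so twin similarity shows up as near-0.5 cells hugging the diagonal.
#'
#' @param m matrix from [pairwise_auc_matrix()].
#' @param title optional plot title.
#' @return A ggplot.
#' @export
plot_auc_matrix <- function(m, title = "Pairwise AUC") {
  d <- as.data.frame(as.table(m), stringsAsFactors = FALSE)
  names(d) <- c("a", "b", "auc")
  d$a <- factor(d$a, levels = rev(rownames(m)))
  d$b <- factor(d$b, levels = colnames(m))
  ggplot(d, aes(x = .data$b, y = .data$a, fill = .data$auc)) +
    geom_tile() +
    scale_fill_gradient2(midpoint = 0.5, limits = c(0, 1)) +
    labs(x = NULL, y = NULL, title = title, fill = "AUC") +
    theme_minimal()
}

#' Overview plot of a study report
#'
#' Dot chart of per-parameter system metrics (calibrated Cllr, EER, multiclass
#' AUC), the at-a-glance comparison of which timing parameters discriminate
#' speakers best.
#'
#' @param object a `study_report`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.study_report <- function(object, ...) {
  sm <- object$system_metrics
  if (nrow(sm) == 0) abort("report has no system metrics to plot")
  d <- tidyr::pivot_longer(
    sm[, c("parameter", "cllr_cal", "eer", "auc_multiclass")],
    -"parameter", names_to = "metric", values_to = "value")
  d$parameter <- factor(d$parameter,
                        levels = rev(intersect(timing_parameter_info()$parameter,
                                               sm$parameter)))
  ggplot(d, aes(x = .data$value, y = .data$parameter)) +
    geom_point() +
    facet_wrap(~metric, scales = "free_x") +
    labs(x = NULL, y = NULL, title = "Speaker-discriminatory performance") +
    theme_minimal()
}
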