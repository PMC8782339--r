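#' Study configuration
#'
#' Bundles everything [run_study()] needs: where observations come from
#' (simulate a population, read a directory of TextGrids, or load a long CSV
#' table), the statistical settings, and the seeds.
#'
#' @param mode `"simulate"`, `"textgrid_dir"` or `"parameter_csv"`.
#' @param input directory of `.TextGrid` files or a CSV path (ignored when
#'   simulating).
#' @param population a [population_config()] (simulate mode).
#' @param salience a [salience_params()] for extraction.
#' @param alpha significance level for post-hoc tests (default 0.05).
#' @param m Bonferroni comparison count; `NULL` = `k(k-1)/2`.
#' @param n_reps replication counts for the down-sampling protocol.
#' @param lr_min_obs minimum per-speaker observations for the LR experiment;
#'   parameters below it are flagged skipped.
#' @param seed master seed.
#' @param output_dir optional directory to persist every table.
#' @return A list of class `study_config`.
#' @export
study_config <- function(mode = c("simulate", "textgrid_dir", "parameter_csv"),
                         input = NULL, population = population_config(),
                         salience = salience_params(), alpha = 0.05, m = NULL,
                         n_reps = c(3, 10, 20), lr_min_obs = 4, seed = 1L,
                         output_dir = NULL) {
  mode <- match.arg(mode)
  if (mode != "simulate" && is.null(input)) {
    abort(paste0("mode '", mode, "' requires `input`"))
  }
  structure(list(mode = mode, input = input, population = population,
                 salience = salience, alpha = alpha, m = m, n_reps = n_reps,
                 lr_min_obs = lr_min_obs, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "study_config")
}

load_observations <- function(config) {
  switch(config$mode,
    simulate = {
      pop <- config$population
      pop$master_seed <- config$seed
      simulate_population(pop)
    },
    textgrid_dir = {
      files <- sort(list.files(config$input, pattern = "\\.[Tt]ext[Gg]rid$",
                               full.names = TRUE))
      if (length(files) == 0) abort(paste0("no TextGrid files in ", config$input))
      dplyr::bind_rows(purrr::map(files, function(f) {
        extract_all(read_textgrid(f), salience = config$salience)
      }))
    },
    parameter_csv = {
      tab <- utils::read.csv(config$input, stringsAsFactors = FALSE)
      need <- c("speaker", "parameter", "value")
      if (!all(need %in% names(tab))) {
        abort("parameter CSV needs columns speaker, parameter, value")
      }
      tibble::as_tibble(tab)
    }
  )
}

#' Run the full speaker-comparison study
#'
#' End-to-end orchestration: obtain observations, describe them (per-parameter
#' medians, means, SDs and the range of speaker means), run the inferential
#' battery (Kruskal-Wallis, eta squared with magnitude, Dunn post hoc with
#' cross-pair and intra-twin counts), the balanced-replication protocol, and
#' the per-parameter LR system evaluation (raw/calibrated Cllr, EER,
#' multiclass AUC) with pairwise AUC matrices. Deterministic given the
#' config's seeds; intra-twin comparisons are tabulated separately from
#' cross-pair counts throughout.
#'
#' @param config a [study_config()].
#' @return A list of class `study_report`: `observations`, `descriptives`,
#'   `group_stats`, `dunn`, `replication`, `system_metrics`, `auc_matrices`,
#'   `scores`, `meta`.
#' @export
run_study <- function(config) {
  if (!inherits(config, "study_config")) abort("`config` must be a study_config")
  obs <- load_observations(config)
  params <- intersect(timing_parameter_info()$parameter, unique(obs$parameter))
  speakers <- sort(unique(obs$speaker))
  k <- length(speakers)

  descriptives <- obs |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = median(.data$value), mean = mean(.data$value),
      sd = sd(.data$value),
      mean_min = min(tapply(.data$value, .data$speaker, mean)),
      mean_max = max(tapply(.data$value, .data$speaker, mean)),
      unit = .data$unit[1], .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$parameter, params))

  m_comp <- config$m %||% (k * (k - 1) / 2)
  dunn_all <- list()
  gs <- purrr::map(params, function(p) {
    sub <- obs[obs$parameter == p, , drop = FALSE]
    kw <- kruskal_wallis(sub)
    es <- eta_squared_kw(kw)
    d <- dunn_posthoc(sub, alpha = config$alpha, m = m_comp)
    d$intra_twin <- twin_prefix(d$speaker_a) == twin_prefix(d$speaker_b)
    dunn_all[[p]] <<- dplyr::mutate(d, parameter = p, .before = 1)
    sig_twin <- d[d$significant & d$intra_twin, , drop = FALSE]
    tibble::tibble(
      parameter = p, n = kw$n, H = kw$H, df = kw$df, p_value = kw$p,
      cross_pair_sig = sum(d$significant),
      cross_pair_pct = round_half_up(100 * sum(d$significant) / m_comp, 1),
      intra_twin_sig = paste(paste0(sig_twin$speaker_a, "-", sig_twin$speaker_b),
                             collapse = "/"),
      eta2 = es$eta2, eta2_percent = es$percent, magnitude = es$magnitude
    )
  })
  group_stats <- dplyr::bind_rows(gs)

  rep_grid <- tidyr::expand_grid(parameter = params, n_reps = config$n_reps)
  replication <- dplyr::bind_rows(purrr::map(seq_len(nrow(rep_grid)), function(i) {
    p <- rep_grid$parameter[i]; nr <- rep_grid$n_reps[i]
    rr <- replication_consistency(obs, parameter = p, n_reps = nr,
                                  alpha = config$alpha, m = m_comp,
                                  seed = derive_seed(config$seed, 101 * i))
    rr$intra_twin <- twin_prefix(rr$speaker_a) == twin_prefix(rr$speaker_b)
    dplyr::mutate(rr, parameter = p, .before = 1)
  }))

  scores <- list(); auc_matrices <- list(); sm <- list(); skipped <- character(0)
  for (p in params) {
    sub <- obs[obs$parameter == p, , drop = FALSE]
    if (min(table(sub$speaker)) < config$lr_min_obs ||
        length(unique(sub$speaker)) < 3) {
      skipped <- c(skipped, p)
      next
    }
    sc <- cross_validated_scores(sub, parameter = p, min_obs = config$lr_min_obs)
    scores[[p]] <- sc
    auc_matrices[[p]] <- pairwise_auc_matrix(sub)
    sm[[p]] <- system_metrics(sc, data = sub)
  }
  system_metrics_tbl <- dplyr::bind_rows(sm)
  if (length(skipped) > 0) {
    inform(paste0("LR system skipped (too few observations per speaker): ",
                  paste(skipped, collapse = ", ")))
  }

  report <- structure(list(
    observations = obs,
    descriptives = descriptives,
    group_stats = group_stats,
    dunn = dplyr::bind_rows(dunn_all),
    replication = replication,
    system_metrics = system_metrics_tbl,
    auc_matrices = auc_matrices,
    scores = scores,
    meta = list(seed = config$seed, mode = config$mode, k = k,
                m = m_comp, alpha = config$alpha,
                lr_skipped = skipped,
                package_version = as.character(utils::packageVersion("speechlr")))
  ), class = "study_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>", x$meta$k, "speakers,",
      nrow(x$descriptives), "parameters, seed", x$meta$seed, "\n\n")
  cat("Group statistics:\n")
  print(as.data.frame(x$group_stats[, c("parameter", "n", "H", "eta2_percent",
                                        "magnitude", "cross_pair_sig")]))
  if (nrow(x$system_metrics) > 0) {
    cat("\nSystem metrics:\n")
    print(as.data.frame(dplyr::mutate(
      x$system_metrics,
      dplyr::across(dplyr::where(is.numeric), function(v) round(v, 2)))))
  }
  invisible(x)
}

#' Persist a study report
#'
#' Writes every table as CSV plus a single `report.json`; output is a pure
#' function of (inputs, config, seeds), so identical runs produce identical
#' bytes.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(tbl, name) {
    utils::write.csv(tbl, file.path(dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  wr(report$observations, "observations")
  wr(report$descriptives, "descriptives")
  wr(report$group_stats, "group_stats")
  wr(report$dunn, "dunn_posthoc")
  wr(report$replication, "replication")
  wr(report$system_metrics, "system_metrics")
  for (p in names(report$auc_matrices)) {
    utils::write.csv(report$auc_matrices[[p]],
                     file.path(dir, paste0("auc_matrix_", p, ".csv")))
  }
  json <- list(
    meta = report$meta,
    descriptives = report$descriptives,
    group_stats = report$group_stats,
    system_metrics = report$system_metrics
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "rows")
  invisible(dir)
}
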