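#' The eleven speech-timing parameters
#'
#' @description
#' The extraction layer turns a tiered annotation into a long observation
#' table covering eleven timing parameters, grouped by the duration of the
#' unit they are measured on:
#'
#' * **Macro** (units longer than a syllable): `SRATE` — V-V units per second
#'   of chunk time including pauses; `ARTRATE_I` — excluding silent-pause
#'   time; `ARTRATE_II` — excluding silent- and filled-pause time; `SGDUR` —
#'   stress-group duration in seconds (between two consecutive salient V-V
#'   units).
#' * **Micro** (syllable-sized and below): `VVDUR_I` — all V-V unit durations
#'   (ms); `VVDUR_II` — non-salient V-V units only (ms); `VOWEL_DUR` — oral
#'   monophthong durations (ms).
#' * **Pause-related**: `SILPAUSES`, `FILPAUSES`, `ALLPAUSES` — pause
#'   durations (ms) at or above the 100 ms threshold; `IPI` — inter-pausal
#'   interval, the speech stretch between two consecutive silent pauses (s).
#'
#' @name timing_parameters
#' @keywords internal
NULL

#' Canonical parameter names and units
#' @return A tibble with columns `parameter`, `unit`, `category`.
#' @export
timing_parameter_info <- function() {
  tibble::tribble(
    ~parameter,   ~unit,  ~category,
    "SRATE",      "vv/s", "macro",
    "ARTRATE_I",  "vv/s", "macro",
    "ARTRATE_II", "vv/s", "macro",
    "SGDUR",      "s",    "macro",
    "VVDUR_I",    "ms",   "micro",
    "VVDUR_II",   "ms",   "micro",
    "VOWEL_DUR",  "ms",   "micro",
    "SILPAUSES",  "ms",   "pause",
    "FILPAUSES",  "ms",   "pause",
    "ALLPAUSES",  "ms",   "pause",
    "IPI",        "s",    "pause"
  )
}

#' Split a recording into speech chunks
#'
#' One row per speech-chunk interval, carrying the V-V units and the
#' qualifying silent/filled pauses contained in it (containment within `tol`).
#' Chunks holding fewer than `min_vv` V-V units are flagged `excluded`: they
#' are kept for pause statistics but never used for rate computation, a rule
#' that guards the rates against phrase-final lengthening in very short
#' chunks.
#'
#' @param recording an [annotated_recording()].
#' @param min_vv minimum V-V units for a chunk to enter rate computation.
#' @param tol containment tolerance in seconds (default 10 ms).
#' @param warn_unattached warn when a pause interval lies outside every chunk?
#'   Chunk-delimiting pauses between chunks are normal in corpus data, so
#'   bulk extraction silences this.
#' @return A tibble with columns `speaker`, `chunk_id`, `start`, `end`,
#'   `duration`, `n_vv`, `excluded`, and list-columns `vv`, `silent_pauses`,
#'   `filled_pauses` holding the member intervals.
#' @export
derive_chunks <- function(recording, min_vv = 3, tol = 0.01,
                          warn_unattached = TRUE) {
  chunks <- recording$tiers$speech_chunks
  if (is.null(chunks) || nrow(chunks) == 0) {
    warn("speech_chunks tier empty: no chunks derived")
    return(tibble::tibble(
      speaker = character(), chunk_id = character(), start = numeric(),
      end = numeric(), duration = numeric(), n_vv = integer(),
      excluded = logical(), vv = list(), silent_pauses = list(),
      filled_pauses = list()))
  }
  vv <- recording$tiers$vv_units %||% tibble::tibble(start = numeric(), end = numeric(), label = character())
  sil <- recording$tiers$silent_pauses %||% tibble::tibble(start = numeric(), end = numeric(), label = character())
  fil <- recording$tiers$filled_pauses %||% tibble::tibble(start = numeric(), end = numeric(), label = character())
  inside <- function(tab, s, e) tab[tab$start >= s - tol & tab$end <= e + tol, , drop = FALSE]
  out <- purrr::map(seq_len(nrow(chunks)), function(i) {
    s <- chunks$start[i]; e <- chunks$end[i]
    vv_i <- inside(vv, s, e)
    tibble::tibble(
      speaker = recording$speaker_id,
      chunk_id = if (chunks$label[i] != "") chunks$label[i] else paste0("chunk", i),
      start = s, end = e, duration = e - s,
      n_vv = nrow(vv_i), excluded = nrow(vv_i) < min_vv,
      vv = list(vv_i),
      silent_pauses = list(inside(sil, s, e)),
      filled_pauses = list(inside(fil, s, e))
    )
  })
  res <- dplyr::bind_rows(out)
  if (warn_unattached) {
    covered <- function(tab) {
      if (nrow(tab) == 0) return(logical(0))
      purrr::map_lgl(seq_len(nrow(tab)), function(j) {
        any(tab$start[j] >= chunks$start - tol & tab$end[j] <= chunks$end + tol)
      })
    }
    n_out <- sum(!covered(sil)) + sum(!covered(fil))
    if (n_out > 0) {
      warn(paste0(n_out, " pause interval(s) lie outside every speech chunk ",
                  "and were not attached"))
    }
  }
  res
}

stop_if_excluded <- function(chunks, what) {
  if (any(chunks$excluded)) {
    abort(paste0(what, " is undefined for chunks excluded by the minimum ",
                 "V-V unit rule (>= 3 V-V units per chunk); drop excluded ",
                 "chunks first"))
  }
}

qualifying_time <- function(tabs, threshold_s) {
  purrr::map_dbl(tabs, function(p) {
    d <- p$end - p$start
    sum(d[d >= threshold_s - 1e-9])
  })
}

#' Speech rate of each chunk
#'
#' V-V units per second of total chunk time, pauses included.
#'
#' @param chunks output of [derive_chunks()], excluded chunks removed.
#' @return Numeric vector, one rate (vv/s) per chunk.
#' @export
speech_rate <- function(chunks) {
  stop_if_excluded(chunks, "speech rate")
  chunks$n_vv / chunks$duration
}

#' Articulation rate I of each chunk
#'
#' V-V units per second after removing silent-pause time (pauses at or above
#' the threshold only) from the chunk duration.
#'
#' @inheritParams speech_rate
#' @param pause_threshold minimum pause duration counted, in seconds
#'   (default 0.1 = 100 ms).
#' @return Numeric vector of rates (vv/s).
#' @export
articulation_rate_I <- function(chunks, pause_threshold = 0.1) {
  stop_if_excluded(chunks, "articulation rate I")
  den <- chunks$duration - qualifying_time(chunks$silent_pauses, pause_threshold)
  if (any(den <= 0)) {
    abort("degenerate chunk: silent-pause time >= chunk duration")
  }
  chunks$n_vv / den
}

#' Articulation rate II of each chunk
#'
#' V-V units per second after removing both silent-pause and filled-pause
#' (lengthened-vowel) time from the chunk duration. The V-V count in the
#' numerator is kept unchanged; the exclusion is read as acting on the time
#' base only.
#'
#' @inheritParams articulation_rate_I
#' @return Numeric vector of rates (vv/s).
#' @export
articulation_rate_II <- function(chunks, pause_threshold = 0.1) {
  stop_if_excluded(chunks, "articulation rate II")
  den <- chunks$duration -
    qualifying_time(chunks$silent_pauses, pause_threshold) -
    qualifying_time(chunks$filled_pauses, pause_threshold)
  if (any(den <= 0)) {
    abort("degenerate chunk: pause time >= chunk duration")
  }
  chunks$n_vv / den
}

#' Salience-detection parameters
#'
#' Salient V-V units are those at a local peak of the smoothed z-scored
#' duration contour — the automatic correlate of a perceived duration
#' increase. The reference literature leaves the detector's internals open,
#' so every choice is a parameter here: z-scores are taken against the
#' recording's (or speaker's) own mean/SD, smoothed with a centred moving
#' average, and peaks are local maxima, by default required to sit above the
#' mean (smoothed z > 0).
#'
#' @param smoothing_window odd window length in points (default 5).
#' @param z_reference `"per_recording"` (default) or `"per_speaker"`.
#' @param peak_rule `"local_max_above_zero"` (default) or `"local_max"`.
#' @param min_prominence minimum smoothed z at the peak (default 0).
#' @return A list of class `salience_params`.
#' @export
salience_params <- function(smoothing_window = 5,
                            z_reference = c("per_recording", "per_speaker"),
                            peak_rule = c("local_max_above_zero", "local_max"),
                            min_prominence = 0) {
  if (smoothing_window < 1 || smoothing_window %% 2 != 1) {
    abort("`smoothing_window` must be an odd integer >= 1")
  }
  structure(list(
    smoothing_window = as.integer(smoothing_window),
    z_reference = match.arg(z_reference),
    peak_rule = match.arg(peak_rule),
    min_prominence = min_prominence
  ), class = "salience_params")
}

# centred moving average with shrinking windows at the edges
smooth_ma <- function(x, window) {
  if (window <= 1 || length(x) < 2) return(x)
  h <- (window - 1) %/% 2
  n <- length(x)
  purrr::map_dbl(seq_len(n), function(i) {
    mean(x[max(1, i - h):min(n, i + h)])
  })
}

#' Detect salient V-V units on a duration contour
#'
#' z-scores the durations, smooths the contour, and marks local maxima under
#' the configured peak rule. Ties on a plateau break to the earlier unit, so
#' detection is deterministic. With zero duration variance no salience is
#' definable and the mask is all-`FALSE`.
#'
#' @param durations V-V unit durations in temporal order (seconds).
#' @param params a [salience_params()].
#' @param reference optional numeric vector supplying the mean/SD reference
#'   (e.g. a speaker's pooled durations when `z_reference = "per_speaker"`);
#'   defaults to `durations` itself.
#' @return Logical mask, `TRUE` at salient units.
#' @export
detect_salient_vv <- function(durations, params = salience_params(),
                              reference = NULL) {
  n <- length(durations)
  if (n < params$smoothing_window) {
    abort("need at least `smoothing_window` durations to detect salience")
  }
  ref <- reference %||% durations
  s <- sd(ref)
  if (!is.finite(s) || s == 0) return(rep(FALSE, n))
  z <- (durations - mean(ref)) / s
  zs <- smooth_ma(z, params$smoothing_window)
  prev <- c(-Inf, zs[-n])
  nxt <- c(zs[-1], -Inf)
  peak <- zs > prev & zs >= nxt
  if (params$peak_rule == "local_max_above_zero") peak <- peak & zs > 0
  peak & zs >= params$min_prominence
}

#' Stress-group durations
#'
#' A stress group spans from one salient V-V unit to the next: for each
#' consecutive salient pair (i, j) the group duration is `end(j) - end(i)`
#' seconds (each group ends with a salient unit). Fewer than two salient
#' units yield no group.
#'
#' @param vv_intervals tibble of V-V intervals (`start`, `end`) in temporal
#'   order.
#' @param salience logical mask aligned with `vv_intervals`.
#' @return Numeric vector of stress-group durations in seconds.
#' @export
stress_group_durations <- function(vv_intervals, salience) {
  if (nrow(vv_intervals) != length(salience)) {
    abort("`salience` must align with `vv_intervals`")
  }
  idx <- which(salience)
  if (length(idx) < 2) return(numeric(0))
  ends <- vv_intervals$end[idx]
  diff(ends)
}

#' Pause durations
#'
#' Durations, in milliseconds, of the silent and/or filled pauses at or above
#' the threshold ("equal or superior to 100 ms"; shorter events are excluded
#' as likely plosive occlusions or sub-threshold lengthenings).
#'
#' @param recording an [annotated_recording()].
#' @param kind `"silent"`, `"filled"` or `"all"` (union of both tiers).
#' @param threshold_ms minimum duration in ms (default 100).
#' @return Numeric vector of durations in ms.
#' @export
pause_durations <- function(recording, kind = c("silent", "filled", "all"),
                            threshold_ms = 100) {
  kind <- match.arg(kind)
  grab <- function(role) {
    tier <- recording$tiers[[role]]
    if (is.null(tier) || nrow(tier) == 0) return(numeric(0))
    d <- (tier$end - tier$start) * 1000
    d[d >= threshold_ms - 1e-6]
  }
  switch(kind,
    silent = grab("silent_pauses"),
    filled = grab("filled_pauses"),
    all = c(grab("silent_pauses"), grab("filled_pauses"))
  )
}

#' Inter-pausal intervals
#'
#' The speech stretch between two consecutive qualifying silent pauses: for
#' pauses `[a1, b1]` and `[a2, b2]` with `b1 < a2`, the interval is
#' `a2 - b1` seconds — emitted only when at least one V-V unit lies in
#' between (two abutting pauses bound no speech).
#'
#' @param recording an [annotated_recording()].
#' @param threshold_ms minimum silent-pause duration in ms (default 100).
#' @param tol boundary tolerance in seconds.
#' @return Numeric vector of IPI values in seconds.
#' @export
inter_pausal_intervals <- function(recording, threshold_ms = 100, tol = 0.01) {
  sil <- recording$tiers$silent_pauses
  if (is.null(sil) || nrow(sil) == 0) return(numeric(0))
  sil <- sil[(sil$end - sil$start) * 1000 >= threshold_ms - 1e-6, , drop = FALSE]
  if (nrow(sil) < 2) return(numeric(0))
  sil <- dplyr::arrange(sil, .data$start)
  vv <- recording$tiers$vv_units
  out <- numeric(0)
  for (i in seq_len(nrow(sil) - 1)) {
    b1 <- sil$end[i]; a2 <- sil$start[i + 1]
    if (a2 <= b1 + tol) next
    has_speech <- !is.null(vv) && nrow(vv) > 0 &&
      any(vv$start >= b1 - tol & vv$end <= a2 + tol)
    if (has_speech) out <- c(out, a2 - b1)
  }
  out
}

#' Extract the full parameter table from a recording
#'
#' Runs the whole extraction battery and returns one long observation table:
#' chunk-level rates, stress-group durations (salience detected on the
#' recording's V-V duration contour; groups never cross chunk boundaries),
#' V-V and vowel durations, pause durations and inter-pausal intervals.
#' Parameters whose source tier is absent are simply missing from the table
#' (a message notes which).
#'
#' @param recording an [annotated_recording()].
#' @param salience a [salience_params()].
#' @param min_vv minimum V-V units per chunk for rate computation.
#' @param pause_threshold_ms pause-duration threshold in ms.
#' @param tol containment tolerance in seconds.
#' @return A tibble with columns `speaker`, `parameter`, `value`, `unit`,
#'   `chunk_id`, ordered deterministically (parameter, then chunk/token).
#' @export
extract_all <- function(recording, salience = salience_params(),
                        min_vv = 3, pause_threshold_ms = 100, tol = 0.01) {
  info <- timing_parameter_info()
  unit_of <- function(p) info$unit[info$parameter == p]
  obs <- function(parameter, value, chunk_id) {
    u <- unit_of(parameter)
    tibble::tibble(speaker = recording$speaker_id, parameter = parameter,
                   value = value, unit = u,
                   chunk_id = as.character(chunk_id))
  }
  rows <- list()
  skipped <- character(0)

  chunks <- derive_chunks(recording, min_vv = min_vv, tol = tol,
                          warn_unattached = FALSE)
  rate_chunks <- chunks[!chunks$excluded, , drop = FALSE]
  if (nrow(rate_chunks) > 0) {
    rows$SRATE <- obs("SRATE", speech_rate(rate_chunks), rate_chunks$chunk_id)
    rows$ARTRATE_I <- obs("ARTRATE_I",
      articulation_rate_I(rate_chunks, pause_threshold_ms / 1000),
      rate_chunks$chunk_id)
    rows$ARTRATE_II <- obs("ARTRATE_II",
      articulation_rate_II(rate_chunks, pause_threshold_ms / 1000),
      rate_chunks$chunk_id)
  }

  vv <- recording$tiers$vv_units
  if (!is.null(vv) && nrow(vv) > 0) {
    vv <- dplyr::arrange(vv, .data$start)
    dur <- vv$end - vv$start
    sal <- if (length(dur) >= salience$smoothing_window) {
      detect_salient_vv(dur, salience)
    } else rep(FALSE, length(dur))
    rows$VVDUR_I <- obs("VVDUR_I", dur * 1000, seq_along(dur))
    rows$VVDUR_II <- obs("VVDUR_II", dur[!sal] * 1000, which(!sal))
    # stress groups: within each chunk only
    sg <- numeric(0)
    for (i in seq_len(nrow(chunks))) {
      in_chunk <- vv$start >= chunks$start[i] - tol & vv$end <= chunks$end[i] + tol
      sg <- c(sg, stress_group_durations(vv[in_chunk, , drop = FALSE],
                                         sal[in_chunk]))
    }
    if (length(sg) > 0) rows$SGDUR <- obs("SGDUR", sg, seq_along(sg))
  } else {
    skipped <- c(skipped, "VVDUR_I", "VVDUR_II", "SGDUR")
  }

  mono <- recording$tiers$oral_monophthongs
  if (!is.null(mono) && nrow(mono) > 0) {
    rows$VOWEL_DUR <- obs("VOWEL_DUR", (mono$end - mono$start) * 1000,
                          seq_len(nrow(mono)))
  } else {
    skipped <- c(skipped, "VOWEL_DUR")
  }

  for (spec in list(c("SILPAUSES", "silent"), c("FILPAUSES", "filled"),
                    c("ALLPAUSES", "all"))) {
    d <- pause_durations(recording, spec[2], threshold_ms = pause_threshold_ms)
    if (length(d) > 0) {
      rows[[spec[1]]] <- obs(spec[1], d, seq_along(d))
    } else {
      skipped <- c(skipped, spec[1])
    }
  }

  ipi <- inter_pausal_intervals(recording, threshold_ms = pause_threshold_ms,
                                tol = tol)
  if (length(ipi) > 0) {
    rows$IPI <- obs("IPI", ipi, seq_along(ipi))
  } else {
    skipped <- c(skipped, "IPI")
  }

  if (length(skipped) > 0) {
    inform(paste0("speaker ", recording$speaker_id, ": no observations for ",
                  paste(skipped, collapse = ", ")))
  }
  out <- dplyr::bind_rows(rows[intersect(info$parameter, names(rows))])
  if (nrow(out) == 0) {
    out <- tibble::tibble(speaker = character(), parameter = character(),
                          value = numeric(), unit = character(),
                          chunk_id = character())
  }
  out
}

#' Observation counts per parameter
#'
#' @param table a long parameter table (`speaker`, `parameter`, `value`).
#' @return A tibble with columns `parameter`, `n`.
#' @export
parameter_counts <- function(table) {
  dplyr::count(table, .data$parameter, name = "n")
}
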