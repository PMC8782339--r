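#' The 11-layer annotation schema
#'
#' Tiered interval annotations of spontaneous speech are organised in eleven
#' layers: dialogue parts, speech chunks, all vocalic segments, oral
#' monophthongs, oral diphthongs, filled pauses, silent pauses, all pauses
#' (the combination of silent and filled), vowel-to-vowel (V-V) units,
#' smoothed z-score peak values (a point layer marking salient V-V units) and
#' stress groups. `tg_schema()` declares the canonical roles, the tier names
#' they match in a TextGrid (case-insensitively, after collapsing
#' spaces/hyphens/underscores), which roles are required, and which role is a
#' point tier.
#'
#' @param required character vector of roles that must be present when a file
#'   is read. Defaults to the two tiers every timing parameter ultimately
#'   depends on; optional tiers that are absent simply make the corresponding
#'   parameters unavailable.
#' @param extra_names optional named list mapping role -> extra tier names to
#'   accept, for corpora with local naming conventions.
#' @return A tibble with columns `role`, `layer`, `point_tier`, `required`
#'   and a list-column `names` of accepted tier names.
#' @examples
#' tg_schema()
#' @export
tg_schema <- function(required = c("speech_chunks", "vv_units"),
                      extra_names = NULL) {
  roles <- c(
    "dialogue_part", "speech_chunks", "all_vowels", "oral_monophthongs",
    "oral_diphthongs", "filled_pauses", "silent_pauses", "all_pauses",
    "vv_units", "z_peaks", "stress_groups"
  )
  bad <- setdiff(required, roles)
  if (length(bad) > 0) {
    abort(paste0("unknown schema role(s): ", paste(bad, collapse = ", ")))
  }
  names_default <- list(
    dialogue_part     = c("dialogue part", "dialogue parts"),
    speech_chunks     = c("speech chunks", "chunks"),
    all_vowels        = c("all vowels", "vowels", "all vocalic segments"),
    oral_monophthongs = c("oral monophthongs", "monophthongs"),
    oral_diphthongs   = c("oral diphthongs", "diphthongs"),
    filled_pauses     = c("filled pauses"),
    silent_pauses     = c("silent pauses"),
    all_pauses        = c("all pauses"),
    vv_units          = c("vv units", "v v units", "vowel to vowel units"),
    z_peaks           = c("z peaks", "smoothed z scores peak values",
                          "z scores peaks", "z score peaks"),
    stress_groups     = c("stress groups")
  )
  nm <- purrr::imap(names_default, function(v, role) {
    unique(c(role, gsub("_", " ", role), v, extra_names[[role]]))
  })
  tibble::tibble(
    role = roles,
    layer = seq_along(roles),
    point_tier = roles == "z_peaks",
    required = roles %in% required,
    names = unname(nm[roles])
  )
}

normalise_tier_name <- function(x) {
  x <- tolower(trimws(x))
  gsub("[-_[:space:]]+", " ", x)
}

match_tier_role <- function(name, schema) {
  n <- normalise_tier_name(name)
  hit <- purrr::map_lgl(schema$names, function(v) n %in% normalise_tier_name(v))
  if (!any(hit)) NA_character_ else schema$role[which(hit)[1]]
}

#' Construct a tiered annotated recording
#'
#' An `annotated_recording` holds one speaker's interval annotation: a named
#' list of tiers (each a tibble with columns `start`, `end`, `label`, in
#' seconds; the `z_peaks` tier is a point tier with columns `time`, `label`),
#' a total duration, and identifiers. Hard structural invariants (finite
#' boundaries, `start < end`, within-tier ordering and non-overlap, intervals
#' inside `[0, duration]`) are enforced here; the cross-tier containment and
#' coincidence conventions are checked by [validate_schema()], which reports
#' violations as data.
#'
#' @param speaker_id speaker identifier; the corpus convention is a letter
#'   followed by a digit (e.g. `"A1"`, `"A2"` for the two members of twin
#'   pair A).
#' @param tiers named list of tier tibbles, names being schema roles.
#' @param duration total recording duration in seconds.
#' @param recording_id optional recording identifier.
#' @return An object of class `annotated_recording`.
#' @export
annotated_recording <- function(speaker_id, tiers, duration,
                                recording_id = speaker_id) {
  stopifnot(is.character(speaker_id), length(speaker_id) == 1)
  if (!is.numeric(duration) || length(duration) != 1 || !is.finite(duration) ||
      duration <= 0) {
    abort("`duration` must be a single positive finite number of seconds")
  }
  if (is.null(names(tiers)) || any(names(tiers) == "")) {
    abort("`tiers` must be a named list keyed by schema role")
  }
  tiers <- purrr::imap(tiers, function(tier, role) {
    tier <- tibble::as_tibble(tier)
    if (role == "z_peaks" && all(c("time", "label") %in% names(tier))) {
      if (nrow(tier) > 0) {
        if (any(!is.finite(tier$time))) {
          abort("tier 'z_peaks': non-finite point time")
        }
        tier <- dplyr::arrange(tier, .data$time)
        if (any(tier$time < 0 | tier$time > duration)) {
          abort("tier 'z_peaks': point outside [0, duration]")
        }
      }
      return(tier[, c("time", "label")])
    }
    if (!all(c("start", "end") %in% names(tier))) {
      abort(paste0("tier '", role, "': needs columns start, end"))
    }
    if (!("label" %in% names(tier))) tier$label <- rep("", nrow(tier))
    tier$label <- as.character(tier$label)
    if (nrow(tier) > 0) {
      if (any(!is.finite(tier$start)) || any(!is.finite(tier$end))) {
        abort(paste0("tier '", role, "': non-finite interval boundary"))
      }
      if (any(tier$end <= tier$start)) {
        i <- which(tier$end <= tier$start)[1]
        abort(paste0("tier '", role, "': interval ", i, " has end <= start"))
      }
      tier <- dplyr::arrange(tier, .data$start)
      if (nrow(tier) > 1 &&
          any(tier$end[-nrow(tier)] > tier$start[-1] + 1e-9)) {
        i <- which(tier$end[-nrow(tier)] > tier$start[-1] + 1e-9)[1]
        abort(paste0("tier '", role, "': intervals ", i, " and ", i + 1,
                     " overlap"))
      }
      if (any(tier$start < -1e-9) || any(tier$end > duration + 1e-9)) {
        abort(paste0("tier '", role, "': interval outside [0, duration]"))
      }
    }
    tier[, c("start", "end", "label")]
  })
  structure(
    list(speaker_id = speaker_id, recording_id = recording_id,
         duration = duration, tiers = tiers),
    class = "annotated_recording"
  )
}

#' @export
print.annotated_recording <- function(x, ...) {
  cat("<annotated_recording> speaker", x$speaker_id,
      sprintf("(%.2f s)\n", x$duration))
  for (nm in names(x$tiers)) {
    n <- nrow(x$tiers[[nm]])
    lab <- if (nm == "z_peaks") "points" else "intervals"
    cat(sprintf("  %-18s %4d %s\n", nm, n, lab))
  }
  invisible(x)
}

# ---- TextGrid parsing ------------------------------------------------------

# Read text as lines, handling UTF-8 (with/without BOM) and UTF-16 via BOM.
read_textgrid_lines <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) >= 2 && raw[1] == as.raw(0xFF) && raw[2] == as.raw(0xFE)) {
    txt <- iconv(list(raw[-(1:2)]), from = "UTF-16LE", to = "UTF-8")
  } else if (length(raw) >= 2 && raw[1] == as.raw(0xFE) && raw[2] == as.raw(0xFF)) {
    txt <- iconv(list(raw[-(1:2)]), from = "UTF-16BE", to = "UTF-8")
  } else if (length(raw) >= 3 && raw[1] == as.raw(0xEF) &&
             raw[2] == as.raw(0xBB) && raw[3] == as.raw(0xBF)) {
    txt <- rawToChar(raw[-(1:3)])
  } else {
    txt <- rawToChar(raw)
  }
  Encoding(txt) <- "UTF-8"
  strsplit(txt, "\r\n|\r|\n")[[1]]
}

# Tokenise a TextGrid into an ordered stream of typed tokens. Long and short
# dialects carry the same values in the same order; the long dialect merely
# prefixes them with 'key =' decoration and bracketed indices, which are
# stripped here. Quoted strings use Praat's doubled-quote escape.
tokenise_textgrid <- function(lines) {
  toks <- list()
  push <- function(type, value) toks[[length(toks) + 1L]] <<- list(type = type, value = value)
  for (line in lines) {
    line <- gsub("\\[[0-9]*\\]", "", line)
    if (grepl("<exists>", line, fixed = TRUE)) {
      push("exists", TRUE)
      next
    }
    if (grepl("<absent>", line, fixed = TRUE)) {
      push("exists", FALSE)
      next
    }
    # pull quoted strings in order, then numbers from the unquoted remainder
    rest <- line
    repeat {
      m <- regexpr("\"((?:[^\"]|\"\")*)\"", rest, perl = TRUE)
      if (m == -1) break
      pre <- substr(rest, 1, m - 1)
      for (num in regmatches(pre, gregexpr("-?[0-9]+\\.?[0-9]*(e-?[0-9]+)?", pre))[[1]]) {
        push("num", as.numeric(num))
      }
      s <- regmatches(rest, m)
      s <- substr(s, 2, nchar(s) - 1)
      push("str", gsub("\"\"", "\"", s, fixed = TRUE))
      rest <- substr(rest, m + attr(m, "match.length"), nchar(rest))
    }
    for (num in regmatches(rest, gregexpr("-?[0-9]+\\.?[0-9]*(e-?[0-9]+)?", rest))[[1]]) {
      push("num", as.numeric(num))
    }
  }
  toks
}

#' Read a Praat TextGrid
#'
#' Parses a TextGrid in either the long or the short text dialect (UTF-8 or
#' UTF-16 input) and maps its tiers onto the 11-layer schema by
#' case-insensitive name matching. The z-peaks layer may be stored in the
#' file as a point tier or as an interval tier with degenerate (peak-labelled)
#' intervals; it is normalised to time-stamped points.
#'
#' @param path path to a `.TextGrid` file.
#' @param schema an [tg_schema()] declaring required tiers and name aliases.
#' @param speaker_id speaker identifier; defaults to the file name without
#'   extension.
#' @param keep_unmatched keep tiers whose names match no schema role (stored
#'   under their own names)? Default drops them.
#' @return An [annotated_recording()].
#' @export
read_textgrid <- function(path, schema = tg_schema(), speaker_id = NULL,
                          keep_unmatched = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  toks <- tokenise_textgrid(read_textgrid_lines(path))
  i <- 0L
  take <- function(type) {
    i <<- i + 1L
    if (i > length(toks)) abort(paste0("malformed TextGrid (", path,
                                       "): unexpected end of file"))
    tk <- toks[[i]]
    if (!is.null(type) && tk$type != type) {
      abort(paste0("malformed TextGrid (", path, "): expected ", type,
                   " token, got ", tk$type))
    }
    tk$value
  }
  ftype <- take("str")
  oclass <- take("str")
  if (!identical(ftype, "ooTextFile") || !identical(oclass, "TextGrid")) {
    abort(paste0("not a TextGrid file: ", path))
  }
  xmin <- take("num")
  xmax <- take("num")
  has_tiers <- TRUE
  if (i < length(toks) && toks[[i + 1L]]$type == "exists") has_tiers <- take("exists")
  ntier <- if (has_tiers) take("num") else 0
  tiers <- list()
  tier_names <- character(0)
  for (t in seq_len(ntier)) {
    cls <- take("str")
    nm <- take("str")
    take("num") # tier xmin
    take("num") # tier xmax
    n <- take("num")
    if (cls == "IntervalTier") {
      start <- end <- numeric(n)
      label <- character(n)
      for (j in seq_len(n)) {
        start[j] <- take("num")
        end[j] <- take("num")
        label[j] <- take("str")
      }
      tiers[[t]] <- tibble::tibble(start = start, end = end, label = label)
    } else if (cls == "TextTier") {
      time <- numeric(n)
      label <- character(n)
      for (j in seq_len(n)) {
        time[j] <- take("num")
        label[j] <- take("str")
      }
      tiers[[t]] <- tibble::tibble(time = time, label = label)
    } else {
      abort(paste0("unsupported tier class '", cls, "' in ", path))
    }
    tier_names[t] <- nm
  }

  roles <- purrr::map_chr(tier_names, match_tier_role, schema = schema)
  out <- list()
  for (t in seq_along(tiers)) {
    key <- if (is.na(roles[t])) {
      if (!keep_unmatched) next
      tier_names[t]
    } else roles[t]
    tier <- tiers[[t]]
    if (!is.na(roles[t]) && roles[t] == "z_peaks" && "start" %in% names(tier)) {
      # interval-tier representation of the peak layer: labelled (degenerate)
      # intervals stand for points at their midpoint
      lab <- tier[tier$label != "", , drop = FALSE]
      tier <- tibble::tibble(time = (lab$start + lab$end) / 2, label = lab$label)
    }
    if (key %in% names(out)) {
      abort(paste0("duplicate tier for role '", key, "' in ", path))
    }
    # drop empty-label intervals: they are unannotated spans
    if ("start" %in% names(tier)) tier <- tier[tier$label != "", , drop = FALSE]
    out[[key]] <- tier
  }
  missing <- setdiff(schema$role[schema$required], names(out))
  if (length(missing) > 0) {
    abort(paste0("schema error: required tier role(s) missing from ", path,
                 ": ", paste(missing, collapse = ", ")))
  }
  if (is.null(speaker_id)) {
    speaker_id <- sub("\\.[Tt]ext[Gg]rid$", "", basename(path))
  }
  annotated_recording(speaker_id, out, duration = xmax - xmin,
                      recording_id = speaker_id)
}

fmt_tg_num <- function(x) {
  # fixed 6-decimal rendering keeps round-trips within 1e-6 s and output
  # byte-stable across runs
  sprintf("%.6f", x)
}

fmt_tg_str <- function(x) {
  paste0("\"", gsub("\"", "\"\"", x, fixed = TRUE), "\"")
}

#' Write a Praat TextGrid (long dialect)
#'
#' Serialises an [annotated_recording()] to the long TextGrid text format,
#' emitting one tier per schema role present on the recording, in schema
#' layer order followed by any non-schema tiers. Unannotated spans between
#' labelled intervals are filled with empty-label intervals so the tier tiles
#' `[0, duration]`, as Praat requires. The recording is validated before any
#' byte is written.
#'
#' @param recording an [annotated_recording()].
#' @param path output file path.
#' @param schema schema used to order tiers.
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(recording, path, schema = tg_schema()) {
  if (!inherits(recording, "annotated_recording")) {
    abort("`recording` must be an annotated_recording")
  }
  # re-run construction: catches invalid objects mutated after creation
  recording <- annotated_recording(recording$speaker_id, recording$tiers,
                                   recording$duration, recording$recording_id)
  dur <- recording$duration
  order_roles <- c(intersect(schema$role, names(recording$tiers)),
                   setdiff(names(recording$tiers), schema$role))
  lines <- c(
    "File type = \"ooTextFile\"",
    "Object class = \"TextGrid\"",
    "",
    "xmin = 0.000000",
    paste0("xmax = ", fmt_tg_num(dur)),
    "tiers? <exists>",
    paste0("size = ", length(order_roles)),
    "item []:"
  )
  for (t in seq_along(order_roles)) {
    role <- order_roles[t]
    tier <- recording$tiers[[role]]
    lines <- c(lines, paste0("    item [", t, "]:"))
    if (role == "z_peaks" && "time" %in% names(tier)) {
      lines <- c(lines,
        "        class = \"TextTier\"",
        paste0("        name = ", fmt_tg_str(role)),
        "        xmin = 0.000000",
        paste0("        xmax = ", fmt_tg_num(dur)),
        paste0("        points: size = ", nrow(tier)))
      for (j in seq_len(nrow(tier))) {
        lines <- c(lines,
          paste0("        points [", j, "]:"),
          paste0("            number = ", fmt_tg_num(tier$time[j])),
          paste0("            mark = ", fmt_tg_str(tier$label[j])))
      }
    } else {
      filled <- fill_tier_gaps(tier, dur)
      lines <- c(lines,
        "        class = \"IntervalTier\"",
        paste0("        name = ", fmt_tg_str(role)),
        "        xmin = 0.000000",
        paste0("        xmax = ", fmt_tg_num(dur)),
        paste0("        intervals: size = ", nrow(filled)))
      for (j in seq_len(nrow(filled))) {
        lines <- c(lines,
          paste0("        intervals [", j, "]:"),
          paste0("            xmin = ", fmt_tg_num(filled$start[j])),
          paste0("            xmax = ", fmt_tg_num(filled$end[j])),
          paste0("            text = ", fmt_tg_str(filled$label[j])))
      }
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

# tile [0, dur] by inserting empty-label intervals in gaps (> 1e-6 s)
fill_tier_gaps <- function(tier, dur) {
  if (nrow(tier) == 0) {
    return(tibble::tibble(start = 0, end = dur, label = ""))
  }
  tier <- dplyr::arrange(tier, .data$start)
  out <- vector("list", 2 * nrow(tier) + 1)
  cur <- 0
  k <- 0
  for (j in seq_len(nrow(tier))) {
    if (tier$start[j] > cur + 1e-6) {
      k <- k + 1
      out[[k]] <- tibble::tibble(start = cur, end = tier$start[j], label = "")
    }
    k <- k + 1
    out[[k]] <- tier[j, ]
    cur <- max(cur, tier$end[j])
  }
  if (dur > cur + 1e-6) {
    k <- k + 1
    out[[k]] <- tibble::tibble(start = cur, end = dur, label = "")
  }
  dplyr::bind_rows(out[seq_len(k)])
}

#' Check cross-tier schema conventions
#'
#' Verifies the containment and coincidence conventions the extraction step
#' relies on: every V-V unit lies inside exactly one speech chunk, and every
#' all-pauses interval coincides with a silent- or filled-pause interval
#' (boundary agreement within `tol` — manual segmentation jitter is expected).
#' Violations are returned as data, one row each, never raised as errors.
#'
#' @param recording an [annotated_recording()].
#' @param schema an [tg_schema()]; required-tier absence is also reported.
#' @param tol boundary tolerance in seconds (default 10 ms).
#' @return A tibble with columns `tier`, `index`, `type`, `message`
#'   (zero rows when the recording conforms).
#' @export
validate_schema <- function(recording, schema = tg_schema(), tol = 0.01) {
  viol <- list()
  add <- function(tier, index, type, message) {
    viol[[length(viol) + 1L]] <<- tibble::tibble(
      tier = tier, index = as.integer(index), type = type, message = message)
  }
  for (role in schema$role[schema$required]) {
    if (!role %in% names(recording$tiers)) {
      add(role, NA, "missing_tier", paste0("required tier '", role, "' absent"))
    }
  }
  chunks <- recording$tiers$speech_chunks
  vv <- recording$tiers$vv_units
  if (!is.null(chunks) && !is.null(vv) && nrow(vv) > 0) {
    for (j in seq_len(nrow(vv))) {
      inside <- !is.null(chunks) && nrow(chunks) > 0 &&
        any(vv$start[j] >= chunks$start - tol & vv$end[j] <= chunks$end + tol)
      if (!inside) {
        add("vv_units", j, "containment",
            sprintf("V-V unit [%.3f, %.3f] not contained in any speech chunk",
                    vv$start[j], vv$end[j]))
      }
    }
  }
  ap <- recording$tiers$all_pauses
  if (!is.null(ap) && nrow(ap) > 0) {
    sil <- recording$tiers$silent_pauses
    fil <- recording$tiers$filled_pauses
    src <- dplyr::bind_rows(
      if (!is.null(sil)) sil[, c("start", "end")] else NULL,
      if (!is.null(fil)) fil[, c("start", "end")] else NULL
    )
    for (j in seq_len(nrow(ap))) {
      hit <- nrow(src) > 0 &&
        any(abs(src$start - ap$start[j]) <= tol & abs(src$end - ap$end[j]) <= tol)
      if (!hit) {
        add("all_pauses", j, "coincidence",
            sprintf("all-pauses interval [%.3f, %.3f] matches no silent or filled pause",
                    ap$start[j], ap$end[j]))
      }
    }
  }
  if (length(viol) == 0) {
    tibble::tibble(tier = character(), index = integer(),
                   type = character(), message = character())
  } else {
    dplyr::bind_rows(viol)
  }
}
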