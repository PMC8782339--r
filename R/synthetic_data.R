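#' Generative specification for one timing parameter
#'
#' A parameter is generated hierarchically: each speaker has a latent level
#' drawn from a between-speaker law, and tokens scatter around that level
#' with within-speaker dispersion. Rates use a (zero-truncated) normal family;
#' duration-type parameters use a lognormal family, matching their positive
#' support and right skew (their corpus means exceed their medians). For the
#' lognormal family the between/within split is applied on the log scale,
#' partitioning the moment-matched total log-variance by the natural-scale
#' variance fractions.
#'
#' @param parameter canonical parameter name.
#' @param family `"normal"` or `"lognormal"`.
#' @param population_mean population mean in the canonical unit.
#' @param between_speaker_sd,within_speaker_sd dispersion of speaker levels /
#'   of tokens around their speaker level (natural scale).
#' @param tokens_per_speaker tokens generated per speaker.
#' @param unit canonical unit label.
#' @return A one-row tibble.
#' @export
parameter_spec <- function(parameter, family = c("normal", "lognormal"),
                           population_mean, between_speaker_sd,
                           within_speaker_sd, tokens_per_speaker, unit = "") {
  family <- match.arg(family)
  if (between_speaker_sd < 0 || within_speaker_sd < 0) abort("SDs must be >= 0")
  if (tokens_per_speaker < 1) abort("tokens_per_speaker must be >= 1")
  if (family == "lognormal" && population_mean <= 0) {
    abort("lognormal family needs a positive mean")
  }
  tibble::tibble(parameter = parameter, family = family,
                 population_mean = population_mean,
                 between_speaker_sd = between_speaker_sd,
                 within_speaker_sd = within_speaker_sd,
                 tokens_per_speaker = as.integer(tokens_per_speaker),
                 unit = unit)
}

#' Default parameter specifications for the emulated corpus
#'
#' Targets chosen to emulate a 20-speaker spontaneous-dialogue corpus:
#' population means and total dispersions follow the descriptive profile of
#' such data (speech rate around 4.6 vv/s with SD 1.3, vowel durations around
#' 84 ms, silent pauses around 550 ms, ...), token counts per speaker are of
#' the order of the corpus observation counts divided by 20 speakers, and the
#' total SD is decomposed into a between-speaker part (set from the spread of
#' individual speaker means, roughly range/4) and a within-speaker remainder.
#'
#' @return A tibble of 11 [parameter_spec()] rows.
#' @export
default_parameter_specs <- function() {
  spl <- function(total_sd, between_sd) sqrt(max(total_sd^2 - between_sd^2, 1e-12))
  dplyr::bind_rows(
    parameter_spec("SRATE", "normal", 4.6, 0.55, spl(1.3, 0.55), 43, "vv/s"),
    parameter_spec("ARTRATE_I", "normal", 5.4, 0.38, spl(1.1, 0.38), 43, "vv/s"),
    parameter_spec("ARTRATE_II", "normal", 5.9, 0.35, spl(1.0, 0.35), 43, "vv/s"),
    parameter_spec("SGDUR", "lognormal", 1.2, 0.21, spl(0.702, 0.21), 105, "s"),
    parameter_spec("VVDUR_I", "lognormal", 207, 24, spl(199, 24), 630, "ms"),
    parameter_spec("VVDUR_II", "lognormal", 163, 17, spl(98, 17), 525, "ms"),
    parameter_spec("VOWEL_DUR", "lognormal", 84, 8.8, spl(67, 8.8), 472, "ms"),
    parameter_spec("SILPAUSES", "lognormal", 547, 94, spl(333, 94), 43, "ms"),
    parameter_spec("FILPAUSES", "lognormal", 298, 42, spl(146, 42), 28, "ms"),
    parameter_spec("ALLPAUSES", "lognormal", 449, 76, spl(301, 76), 71, "ms"),
    parameter_spec("IPI", "lognormal", 2.3, 0.53, spl(1.3, 0.53), 34, "s")
  )
}

#' Configuration of a synthetic twin-structured population
#'
#' Speakers come in identical-twin pairs whose latent levels are correlated:
#' with twin similarity `rho`, the two members of a pair share a fraction
#' `rho` of the between-speaker variance (at `rho = 1` their levels are
#' identical; at 0 they are ordinary distinct speakers). The default emulates
#' the study population: 20 male speakers in 10 twin pairs with very high
#' timing similarity.
#'
#' @param n_speakers even speaker count (default 20).
#' @param n_twin_pairs number of twin pairs (default 10); `2 * n_twin_pairs`
#'   may not exceed `n_speakers`.
#' @param twin_similarity correlation `rho` of twin latent levels, in
#'   `[0, 1]` (default 0.95).
#' @param specs tibble of [parameter_spec()] rows.
#' @param master_seed integer seed governing every draw.
#' @return A list of class `population_config`.
#' @export
population_config <- function(n_speakers = 20, n_twin_pairs = 10,
                              twin_similarity = 0.95,
                              specs = default_parameter_specs(),
                              master_seed = 1L) {
  if (n_speakers %% 2 != 0) abort("`n_speakers` must be even")
  if (2 * n_twin_pairs > n_speakers) {
    abort("2 * n_twin_pairs must not exceed n_speakers")
  }
  if (twin_similarity < 0 || twin_similarity > 1) {
    abort("`twin_similarity` must lie in [0, 1]")
  }
  structure(list(n_speakers = n_speakers, n_twin_pairs = n_twin_pairs,
                 twin_similarity = twin_similarity, specs = specs,
                 master_seed = as.integer(master_seed)),
            class = "population_config")
}

#' Speaker roster with twin structure
#'
#' Identifiers follow the letter+digit corpus convention: the two members of
#' twin pair A are `A1` and `A2`; non-twin speakers get their own letter with
#' suffix 1.
#'
#' @param n_speakers,n_twin_pairs as in [population_config()].
#' @return A tibble: `speaker`, `pair` (letter), `twin` (logical).
#' @export
speaker_roster <- function(n_speakers, n_twin_pairs) {
  letters_pool <- c(LETTERS, paste0(rep(LETTERS, each = 26), rep(LETTERS, 26)))
  ids <- character(0); pair <- character(0); twin <- logical(0)
  for (p in seq_len(n_twin_pairs)) {
    ids <- c(ids, paste0(letters_pool[p], 1:2))
    pair <- c(pair, rep(letters_pool[p], 2))
    twin <- c(twin, TRUE, TRUE)
  }
  n_single <- n_speakers - 2 * n_twin_pairs
  for (q in seq_len(n_single)) {
    ids <- c(ids, paste0(letters_pool[n_twin_pairs + q], 1))
    pair <- c(pair, letters_pool[n_twin_pairs + q])
    twin <- c(twin, FALSE)
  }
  tibble::tibble(speaker = ids, pair = pair, twin = twin)
}

# latent standard-normal speaker effects with twin correlation rho
draw_twin_effects <- function(roster, rho) {
  z_pair <- rnorm(length(unique(roster$pair)))
  names(z_pair) <- unique(roster$pair)
  z_own <- rnorm(nrow(roster))
  sqrt(rho) * z_pair[roster$pair] + sqrt(1 - rho) * z_own
}

#' Simulate a population's parameter table
#'
#' Draws, for every parameter spec, each speaker's latent level from the
#' between-speaker law (twin pairs correlated at `twin_similarity`), then the
#' per-speaker tokens from the within-speaker law. Deterministic given
#' `master_seed`.
#'
#' @param config a [population_config()].
#' @return A long tibble (`speaker`, `parameter`, `value`, `unit`,
#'   `chunk_id` = token index) with attributes `roster` and `config`.
#' @export
simulate_population <- function(config) {
  if (!inherits(config, "population_config")) {
    abort("`config` must be a population_config")
  }
  roster <- speaker_roster(config$n_speakers, config$n_twin_pairs)
  specs <- config$specs
  out <- withr::with_seed(config$master_seed, {
    purrr::map(seq_len(nrow(specs)), function(si) {
      sp <- specs[si, ]
      eff <- draw_twin_effects(roster, config$twin_similarity)
      if (sp$family == "normal") {
        level <- sp$population_mean + sp$between_speaker_sd * eff
        vals <- purrr::map(level, function(mu) {
          v <- rnorm(sp$tokens_per_speaker, mu, sp$within_speaker_sd)
          # rates live on (0, Inf); redraw the rare non-positive token
          while (any(v <= 0)) {
            v[v <= 0] <- rnorm(sum(v <= 0), mu, sp$within_speaker_sd)
          }
          v
        })
      } else {
        m <- sp$population_mean
        tot_var <- sp$between_speaker_sd^2 + sp$within_speaker_sd^2
        sdlog_tot <- sqrt(log(1 + tot_var / m^2))
        fb <- if (tot_var > 0) sp$between_speaker_sd^2 / tot_var else 0
        sdlog_b <- sqrt(fb) * sdlog_tot
        sdlog_w <- sqrt(1 - fb) * sdlog_tot
        meanlog <- log(m) - sdlog_tot^2 / 2
        level <- meanlog + sdlog_b * eff
        vals <- purrr::map(level, function(mu) rlnorm(sp$tokens_per_speaker, mu, sdlog_w))
      }
      tibble::tibble(
        speaker = rep(roster$speaker, each = sp$tokens_per_speaker),
        parameter = sp$parameter,
        value = unlist(vals),
        unit = sp$unit,
        chunk_id = as.character(rep(seq_len(sp$tokens_per_speaker),
                                    times = nrow(roster)))
      )
    })
  })
  res <- dplyr::bind_rows(out)
  attr(res, "roster") <- roster
  attr(res, "config") <- config
  res
}

#' Latent profile of one synthetic speaker
#'
#' Everything [render_recording()] needs to emit a full tiered annotation:
#' the speaker's articulation-rate level, chunk-level rate variability, V-V
#' duration dispersion, and the pause processes (silent pauses per second of
#' articulated speech, probability that a V-V unit is a lengthened vowel /
#' filled pause, and their mean durations).
#'
#' @param speaker_id letter+digit identifier.
#' @param artrate speaker articulation-rate level, V-V units/s.
#' @param artrate_chunk_sd SD of the chunk-level articulation rate.
#' @param vv_cv coefficient of variation of V-V durations within a chunk.
#' @param silent_pause_rate silent pauses per second of articulated speech.
#' @param filled_pause_prob probability a V-V unit is produced lengthened.
#' @param silent_pause_mean,filled_pause_min mean silent-pause duration /
#'   minimum filled-vowel duration, seconds.
#' @param chunk_vv_mean mean V-V units per chunk (minimum 3 enforced).
#' @return A list of class `speaker_profile`.
#' @export
speaker_profile <- function(speaker_id, artrate = 5.4, artrate_chunk_sd = 0.5,
                            vv_cv = 0.3, silent_pause_rate = 0.25,
                            filled_pause_prob = 0.06,
                            silent_pause_mean = 0.55,
                            filled_pause_min = 0.15,
                            chunk_vv_mean = 9.9) {
  if (artrate <= 0 || silent_pause_rate < 0 || filled_pause_prob < 0 ||
      filled_pause_prob > 1 || silent_pause_mean < 0.1) {
    abort("invalid speaker profile rates")
  }
  structure(list(speaker_id = speaker_id, artrate = artrate,
                 artrate_chunk_sd = artrate_chunk_sd, vv_cv = vv_cv,
                 silent_pause_rate = silent_pause_rate,
                 filled_pause_prob = filled_pause_prob,
                 silent_pause_mean = silent_pause_mean,
                 filled_pause_min = filled_pause_min,
                 chunk_vv_mean = chunk_vv_mean),
            class = "speaker_profile")
}

#' Render a speaker profile into a full tiered recording
#'
#' Builds chunk by chunk: a chunk draws its V-V count (minimum 3, mean from
#' the profile) and its articulation rate, lays out V-V units whose durations
#' are scaled to realise that rate exactly, lengthens a random subset of V-V
#' units into filled pauses (>= 100 ms), inserts within-chunk silent pauses
#' (>= 100 ms) per the pause process, and separates chunks by longer silent
#' pauses. The z-peaks and stress-group layers are generated from the same
#' salience detector the extraction uses, so annotations are self-consistent
#' and the rendered file passes [validate_schema()] cleanly.
#'
#' @param profile a [speaker_profile()].
#' @param target_duration approximate recording length in seconds.
#' @param seed integer seed; output is byte-stable given the seed.
#' @param salience a [salience_params()] used for layers 10-11.
#' @return An [annotated_recording()] with all 11 layers.
#' @export
render_recording <- function(profile, target_duration = 120, seed = 1L,
                             salience = salience_params()) {
  if (target_duration * profile$artrate < 3) {
    abort("infeasible profile: rate x duration leaves fewer than 3 V-V units")
  }
  withr::with_seed(seed, {
    t <- 0.25 # lead-in silence
    vv <- list(); mono <- list(); sil <- list(); fil <- list(); chk <- list()
    ci <- 0
    while (t < target_duration) {
      ci <- ci + 1
      n_vv <- 3 + rpois(1, max(profile$chunk_vv_mean - 3, 0))
      rate <- max(profile$artrate + rnorm(1, 0, profile$artrate_chunk_sd), 1)
      artic_time <- n_vv / rate
      raw <- rlnorm(n_vv, 0, sqrt(log(1 + profile$vv_cv^2)))
      d_vv <- raw / sum(raw) * artic_time
      # lengthened vowels (filled pauses): only units long enough to qualify
      is_fil <- runif(n_vv) < profile$filled_pause_prob & d_vv >= profile$filled_pause_min
      # within-chunk silent pauses at interior V-V boundaries
      n_sil <- if (n_vv > 1) rpois(1, profile$silent_pause_rate * artic_time) else 0
      n_sil <- min(n_sil, n_vv - 1)
      sil_pos <- if (n_sil > 0) sort(sample(seq_len(n_vv - 1), n_sil)) else integer(0)
      sil_dur <- 0.1 + rexp(n_sil, 1 / max(profile$silent_pause_mean - 0.1, 0.05))
      c_start <- t
      for (u in seq_len(n_vv)) {
        vv[[length(vv) + 1]] <- c(t, t + d_vv[u])
        vlen <- if (is_fil[u]) d_vv[u] else 0.45 * d_vv[u]
        mono[[length(mono) + 1]] <- c(t, t + vlen)
        if (is_fil[u]) fil[[length(fil) + 1]] <- c(t, t + d_vv[u])
        t <- t + d_vv[u]
        hit <- which(sil_pos == u)
        if (length(hit) == 1) {
          sil[[length(sil) + 1]] <- c(t, t + sil_dur[hit])
          t <- t + sil_dur[hit]
        }
      }
      chk[[ci]] <- c(c_start, t)
      # chunk-delimiting silent pause
      gap <- 0.3 + rexp(1, 1 / 0.3)
      sil[[length(sil) + 1]] <- c(t, t + gap)
      t <- t + gap
    }
    dur <- t + 0.25
    as_tier <- function(lst, labels = NULL) {
      if (length(lst) == 0) {
        return(tibble::tibble(start = numeric(), end = numeric(),
                              label = character()))
      }
      m <- do.call(rbind, lst)
      tibble::tibble(start = m[, 1], end = m[, 2],
                     label = labels %||% paste0("x", seq_len(nrow(m))))
    }
    vv_tier <- as_tier(vv, paste0("vv", seq_along(vv)))
    sil_tier <- as_tier(sil, paste0("sil", seq_along(sil)))
    fil_tier <- as_tier(fil, paste0("fil", seq_along(fil)))
    chk_tier <- as_tier(chk, paste0("c", seq_along(chk)))
    mono_tier <- as_tier(mono, rep("a", length(mono)))
    all_pauses <- dplyr::arrange(dplyr::bind_rows(sil_tier, fil_tier), .data$start)

    d <- vv_tier$end - vv_tier$start
    sal <- if (length(d) >= salience$smoothing_window) {
      detect_salient_vv(d, salience)
    } else rep(FALSE, length(d))
    z <- if (sd(d) > 0) (d - mean(d)) / sd(d) else rep(0, length(d))
    zs <- smooth_ma(z, salience$smoothing_window)
    zp_tier <- tibble::tibble(time = vv_tier$end[sal],
                              label = sprintf("%.3f", zs[sal]))
    sg <- list()
    for (i in seq_len(nrow(chk_tier))) {
      in_chunk <- which(vv_tier$start >= chk_tier$start[i] - 1e-9 &
                        vv_tier$end <= chk_tier$end[i] + 1e-9)
      sal_i <- in_chunk[sal[in_chunk]]
      if (length(sal_i) >= 2) {
        for (j in seq_len(length(sal_i) - 1)) {
          sg[[length(sg) + 1]] <- c(vv_tier$end[sal_i[j]], vv_tier$end[sal_i[j + 1]])
        }
      }
    }
    sg_tier <- as_tier(sg, if (length(sg)) paste0("sg", seq_along(sg)) else NULL)

    annotated_recording(
      speaker_id = profile$speaker_id,
      tiers = list(
        dialogue_part = tibble::tibble(start = 0, end = dur, label = "dialogue"),
        speech_chunks = chk_tier,
        all_vowels = mono_tier,
        oral_monophthongs = mono_tier,
        oral_diphthongs = tibble::tibble(start = numeric(), end = numeric(),
                                         label = character()),
        filled_pauses = fil_tier,
        silent_pauses = sil_tier,
        all_pauses = all_pauses,
        vv_units = vv_tier,
        z_peaks = zp_tier,
        stress_groups = sg_tier
      ),
      duration = dur
    )
  })
}

#' Write a small bundled synthetic corpus
#'
#' Renders a compact twin-structured corpus (default 6 speakers in 3 twin
#' pairs, about 5 chunks each) as TextGrid files plus a JSON manifest of
#' every latent generating parameter, for regression tests and examples.
#'
#' @param out_dir writable output directory (created if needed).
#' @param master_seed integer seed.
#' @param n_speakers,n_twin_pairs roster shape.
#' @param target_duration per-recording length in seconds (~5 chunks).
#' @param twin_similarity twin correlation of articulation-rate levels.
#' @return Invisibly, a tibble of the files written (`speaker`, `path`).
#' @export
make_fixture_suite <- function(out_dir, master_seed = 20L, n_speakers = 6,
                               n_twin_pairs = 3, target_duration = 18,
                               twin_similarity = 0.95) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  roster <- speaker_roster(n_speakers, n_twin_pairs)
  profiles <- withr::with_seed(master_seed, {
    eff <- draw_twin_effects(roster, twin_similarity)
    purrr::map(seq_len(nrow(roster)), function(i) {
      speaker_profile(roster$speaker[i], artrate = 5.4 + 0.4 * eff[i])
    })
  })
  files <- purrr::map_chr(seq_along(profiles), function(i) {
    rec <- render_recording(profiles[[i]], target_duration = target_duration,
                            seed = derive_seed(master_seed, i))
    path <- file.path(out_dir, paste0(roster$speaker[i], ".TextGrid"))
    write_textgrid(rec, path)
    path
  })
  manifest <- list(
    master_seed = master_seed,
    n_speakers = n_speakers,
    n_twin_pairs = n_twin_pairs,
    twin_similarity = twin_similarity,
    target_duration = target_duration,
    speakers = purrr::map(profiles, function(p) unclass(p))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(tibble::tibble(speaker = roster$speaker, path = files))
}
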