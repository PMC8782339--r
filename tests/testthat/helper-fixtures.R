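# Handmade recordings with known member counts, built in code.

# One speaker, two chunks, hand-placed units:
#   chunk c1 [0.5, 2.5]: 4 V-V units, one 0.30 s silent pause, one 0.20 s
#     filled pause (coinciding with vv3)
#   chunk c2 [3.0, 4.0]: 2 V-V units (excluded from rates by the >=3 rule)
# silent pauses: within-c1 [1.2, 1.5], between-chunk [2.5, 3.0], trailing
#   [4.0, 4.4]; plus one 80 ms sub-threshold silence inside c2
toy_recording <- function() {
  vv <- tibble::tibble(
    start = c(0.5, 0.8, 1.5, 1.7, 3.0, 3.55),
    end   = c(0.8, 1.2, 1.7, 2.5, 3.47, 4.0),
    label = paste0("vv", 1:6)
  )
  sil <- tibble::tibble(
    start = c(1.2, 2.5, 3.47, 4.0),
    end   = c(1.5, 3.0, 3.55, 4.4),
    label = c("sil1", "sil2", "sil80ms", "sil3")
  )
  fil <- tibble::tibble(start = 1.5, end = 1.7, label = "fil1")
  annotated_recording(
    speaker_id = "A1",
    duration = 5,
    tiers = list(
      dialogue_part = tibble::tibble(start = 0, end = 5, label = "dialogue"),
      speech_chunks = tibble::tibble(start = c(0.5, 3.0), end = c(2.5, 4.0),
                                     label = c("c1", "c2")),
      all_vowels = tibble::tibble(start = vv$start, end = vv$start + 0.1,
                                  label = rep("a", 6)),
      oral_monophthongs = tibble::tibble(start = vv$start,
                                         end = vv$start + 0.1,
                                         label = rep("a", 6)),
      oral_diphthongs = tibble::tibble(start = numeric(), end = numeric(),
                                       label = character()),
      filled_pauses = fil,
      silent_pauses = sil,
      all_pauses = dplyr::arrange(dplyr::bind_rows(sil, fil), start),
      vv_units = vv,
      z_peaks = tibble::tibble(time = numeric(), label = character()),
      stress_groups = tibble::tibble(start = numeric(), end = numeric(),
                                     label = character())
    )
  )
}

# minimal short-dialect TextGrid text with a single tier/interval
short_textgrid_text <- function() {
  c('"ooTextFile"', '"TextGrid"', "0", "1", "<exists>", "1",
    '"IntervalTier"', '"vv units"', "0", "1", "1", "0", "1", '"a"')
}

# random score sets for property tests
random_scores <- function(n_ss = 30, n_ds = 60, shift = 0, scale = 1) {
  score_set(rnorm(n_ss, shift + 1, scale), rnorm(n_ds, shift - 1, scale))
}

zero_effect_population <- function(seed, tokens = 50, n_speakers = 20) {
  spec <- parameter_spec("SRATE", "normal", 4.6,
                         between_speaker_sd = 0, within_speaker_sd = 1.3,
                         tokens_per_speaker = tokens, unit = "vv/s")
  simulate_population(population_config(
    n_speakers = n_speakers, n_twin_pairs = n_speakers / 2,
    twin_similarity = 0.95, specs = spec, master_seed = seed))
}
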