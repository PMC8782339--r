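test_that("chunks collect their members and the <3 V-V rule flags exclusion", {
  chunks <- derive_chunks(toy_recording(), warn_unattached = FALSE)
  expect_equal(nrow(chunks), 2)
  expect_equal(chunks$n_vv, c(4, 2))
  expect_equal(chunks$excluded, c(FALSE, TRUE))
  expect_equal(nrow(chunks$silent_pauses[[1]]), 1)
  expect_equal(nrow(chunks$filled_pauses[[1]]), 1)
  expect_warning(derive_chunks(toy_recording()), "outside every speech chunk")
})

test_that("rates follow their defining ratios and pause exclusions", {
  chunks <- derive_chunks(toy_recording(), warn_unattached = FALSE)
  c1 <- chunks[!chunks$excluded, ]
  # 4 V-V units in a 2.0 s chunk, 0.3 s silent + 0.2 s filled pause
  expect_equal(speech_rate(c1), 2.0)
  expect_equal(articulation_rate_I(c1), 4 / 1.7)
  expect_equal(articulation_rate_II(c1), 4 / 1.5)
  expect_error(speech_rate(chunks), "V-V unit rule")

  # textbook ratios
  mk <- function(n_vv, dur, sil = numeric(), fil = numeric()) {
    tibble::tibble(
      speaker = "X1", chunk_id = "c", start = 0, end = dur, duration = dur,
      n_vv = n_vv, excluded = FALSE,
      vv = list(tibble::tibble(start = seq(0, dur - 0.01, length.out = n_vv),
                               end = seq(0.01, dur, length.out = n_vv))),
      silent_pauses = list(tibble::tibble(start = cumsum(sil) - sil,
                                          end = cumsum(sil), label = "s")),
      filled_pauses = list(tibble::tibble(start = cumsum(fil) - fil,
                                          end = cumsum(fil), label = "f"))
    )
  }
  expect_equal(speech_rate(mk(10, 2.0)), 5.0)
  expect_equal(speech_rate(mk(3, 1.5)), 2.0)
  # internal pause does not change SRATE
  expect_equal(speech_rate(mk(10, 2.0, sil = 0.5)), 5.0)
  expect_equal(articulation_rate_I(mk(10, 2.0, sil = 0.5)), 10 / 1.5)
  # sub-threshold events are not subtracted
  expect_equal(articulation_rate_I(mk(10, 2.0, sil = 0.09)), 5.0)
  expect_equal(articulation_rate_II(mk(10, 2.0, sil = 0.5, fil = 0.3)), 10 / 1.2)
  expect_equal(articulation_rate_II(mk(10, 2.0, sil = 0.5, fil = 0.099)), 10 / 1.5)
  # no pauses: all three coincide
  expect_equal(articulation_rate_I(mk(7, 2.1)), speech_rate(mk(7, 2.1)))
  expect_equal(articulation_rate_II(mk(7, 2.1)), speech_rate(mk(7, 2.1)))
  expect_error(articulation_rate_I(mk(4, 1.0, sil = 1.2)), "degenerate")
})

test_that("salience detection matches a brute-force z-score oracle", {
  # constant contour: zero variance, nothing salient
  expect_equal(detect_salient_vv(rep(0.2, 12)), rep(FALSE, 12))

  # single spike on a flat contour (no smoothing): salient exactly there
  d <- rep(0.2, 15); d[8] <- 0.8
  mask <- detect_salient_vv(d, salience_params(smoothing_window = 1))
  expect_equal(which(mask), 8)

  # adjacent equal maxima: tie breaks to the earlier unit
  d2 <- c(0.2, 0.2, 0.6, 0.6, 0.2, 0.2)
  mask2 <- detect_salient_vv(d2, salience_params(smoothing_window = 1))
  expect_equal(which(mask2), 3)

  # oracle equivalence on random contours, unsmoothed local-max-above-zero
  set.seed(42)
  for (rep_i in 1:25) {
    d <- rlnorm(20, log(0.2), 0.4)
    z <- (d - mean(d)) / sd(d)
    oracle <- vapply(seq_along(z), function(i) {
      left <- if (i == 1) -Inf else z[i - 1]
      right <- if (i == length(z)) -Inf else z[i + 1]
      z[i] > left && z[i] >= right && z[i] > 0
    }, logical(1))
    expect_equal(detect_salient_vv(d, salience_params(smoothing_window = 1)),
                 oracle)
  }
})

test_that("stress groups span consecutive salient units and sum V-V durations", {
  vv <- tibble::tibble(start = seq(0, 1.6, by = 0.2),
                       end = seq(0.2, 1.8, by = 0.2))
  sal <- rep(FALSE, 9)
  sal[c(3, 6)] <- TRUE
  # end(3) = 0.6, end(6) = 1.2
  expect_equal(stress_group_durations(vv, sal), 0.6)
  # a stress group is the sum of the consecutive V-V durations it spans
  expect_equal(stress_group_durations(vv, sal),
               sum((vv$end - vv$start)[4:6]))
  sal[9] <- TRUE
  expect_length(stress_group_durations(vv, sal), 2)
  expect_length(stress_group_durations(vv, rep(FALSE, 9)), 0)
  expect_length(stress_group_durations(vv, sal & (seq_len(9) == 3)), 0)
})

test_that("pause durations respect the 100 ms threshold inclusively", {
  rec <- toy_recording()
  expect_equal(sort(pause_durations(rec, "silent")), c(300, 400, 500))
  expect_equal(pause_durations(rec, "filled"), 200)
  expect_equal(sort(pause_durations(rec, "all")), c(200, 300, 400, 500))
  # exactly 100 ms is included ("equal or superior")
  rec2 <- toy_recording()
  rec2$tiers$silent_pauses$end[3] <- rec2$tiers$silent_pauses$start[3] + 0.1
  expect_equal(sort(pause_durations(rec2, "silent")), c(100, 300, 400, 500))
  # 80, 120, 300 -> {120, 300}
  rec3 <- annotated_recording("B1", duration = 3, tiers = list(
    silent_pauses = tibble::tibble(start = c(0.1, 0.5, 1.0),
                                   end = c(0.18, 0.62, 1.3),
                                   label = c("s", "s", "s"))))
  expect_equal(pause_durations(rec3, "silent"), c(120, 300))
  expect_equal(pause_durations(rec3, "filled"), numeric(0))
})

test_that("inter-pausal intervals require intervening speech", {
  expect_equal(inter_pausal_intervals(toy_recording()), c(1.0, 1.0))
  # pause ending at 2.0 and pause starting at 4.3 with speech between -> 2.3
  rec <- annotated_recording("C1", duration = 6, tiers = list(
    silent_pauses = tibble::tibble(start = c(1.5, 4.3), end = c(2.0, 4.8),
                                   label = c("s", "s")),
    vv_units = tibble::tibble(start = 2.5, end = 3.0, label = "v")))
  expect_equal(inter_pausal_intervals(rec), 2.3)
  # abutting pauses bound no speech
  rec2 <- annotated_recording("C1", duration = 6, tiers = list(
    silent_pauses = tibble::tibble(start = c(1.5, 2.0), end = c(2.0, 2.4),
                                   label = c("s", "s")),
    vv_units = tibble::tibble(start = 3, end = 3.5, label = "v")))
  expect_length(inter_pausal_intervals(rec2), 0)
  # a single pause yields nothing
  rec3 <- annotated_recording("C1", duration = 6, tiers = list(
    silent_pauses = tibble::tibble(start = 1.5, end = 2.0, label = "s")))
  expect_length(inter_pausal_intervals(rec3), 0)
})

test_that("extract_all reproduces hand-counted observation numbers", {
  tab <- suppressMessages(extract_all(toy_recording()))
  counts <- parameter_counts(tab)
  expected <- c(ALLPAUSES = 4, ARTRATE_I = 1, ARTRATE_II = 1, FILPAUSES = 1,
                IPI = 2, SILPAUSES = 3, SRATE = 1, VOWEL_DUR = 6,
                VVDUR_I = 6, VVDUR_II = 5)
  expect_equal(setNames(counts$n, counts$parameter), expected)
  expect_equal(tab$value[tab$parameter == "SRATE"], 2.0)
  expect_equal(tab$value[tab$parameter == "ARTRATE_II"], 4 / 1.5)
  # ALLPAUSES multiset is the union of silent and filled
  expect_setequal(tab$value[tab$parameter == "ALLPAUSES"],
                  c(tab$value[tab$parameter == "SILPAUSES"],
                    tab$value[tab$parameter == "FILPAUSES"]))
  # VVDUR_II count + salient units = VVDUR_I count
  expect_equal(sum(tab$parameter == "VVDUR_I") - sum(tab$parameter == "VVDUR_II"), 1)
  # canonical units
  expect_equal(unique(tab$unit[tab$parameter == "SRATE"]), "vv/s")
  expect_equal(unique(tab$unit[tab$parameter == "VVDUR_I"]), "ms")
})

test_that("rate ordering holds on every chunk of rendered recordings", {
  rec <- render_recording(speaker_profile("D1", silent_pause_rate = 0.4,
                                          filled_pause_prob = 0.12),
                          60, seed = 5)
  chunks <- derive_chunks(rec, warn_unattached = FALSE)
  chunks <- chunks[!chunks$excluded, ]
  sr <- speech_rate(chunks)
  a1 <- articulation_rate_I(chunks)
  a2 <- articulation_rate_II(chunks)
  expect_true(all(a2 >= a1 - 1e-9))
  expect_true(all(a1 >= sr - 1e-9))
  has_sil <- purrr::map_int(chunks$silent_pauses, nrow) > 0
  expect_true(all((a1 > sr + 1e-12) == has_sil))
})
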