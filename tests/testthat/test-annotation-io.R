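test_that("a minimal one-tier TextGrid parses to the single interval", {
  f <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(c(
    'File type = "ooTextFile"',
    'Object class = "TextGrid"',
    "",
    "xmin = 0",
    "xmax = 1",
    "tiers? <exists>",
    "size = 1",
    "item []:",
    "    item [1]:",
    '        class = "IntervalTier"',
    '        name = "vv units"',
    "        xmin = 0",
    "        xmax = 1",
    "        intervals: size = 1",
    "        intervals [1]:",
    "            xmin = 0",
    "            xmax = 1",
    '            text = "a"'
  ), f)
  rec <- read_textgrid(f, schema = tg_schema(required = "vv_units"))
  expect_s3_class(rec, "annotated_recording")
  expect_equal(rec$duration, 1)
  expect_equal(rec$tiers$vv_units,
               tibble::tibble(start = 0, end = 1, label = "a"))
})

test_that("the short dialect parses to the same recording", {
  f <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(short_textgrid_text(), f)
  rec <- read_textgrid(f, schema = tg_schema(required = "vv_units"))
  expect_equal(rec$tiers$vv_units$label, "a")
  expect_equal(rec$tiers$vv_units$end, 1)
})

test_that("UTF-16 input with BOM is read transparently", {
  f <- withr::local_tempfile(fileext = ".TextGrid")
  txt <- paste(short_textgrid_text(), collapse = "\n")
  raw16 <- iconv(txt, from = "UTF-8", to = "UTF-16LE", toRaw = TRUE)[[1]]
  writeBin(c(as.raw(c(0xFF, 0xFE)), raw16), f)
  rec <- read_textgrid(f, schema = tg_schema(required = "vv_units"))
  expect_equal(rec$tiers$vv_units$label, "a")
})

test_that("write -> read is the identity on valid recordings", {
  rec <- toy_recording()
  f <- withr::local_tempfile(fileext = ".TextGrid")
  write_textgrid(rec, f)
  rec2 <- read_textgrid(f, speaker_id = rec$speaker_id)
  expect_equal(rec2$speaker_id, rec$speaker_id)
  for (role in names(rec$tiers)) {
    a <- rec$tiers[[role]]; b <- rec2$tiers[[role]]
    expect_equal(nrow(b), nrow(a), info = role)
    if (nrow(a) == 0) next
    if (role == "z_peaks") {
      expect_equal(b$time, a$time, tolerance = 1e-6)
    } else {
      expect_equal(b$start, a$start, tolerance = 1e-6, info = role)
      expect_equal(b$end, a$end, tolerance = 1e-6, info = role)
      expect_equal(b$label, a$label, info = role)
    }
  }

  # and on a rendered synthetic recording, including the point tier
  rec3 <- render_recording(speaker_profile("B1"), 30, seed = 11)
  f3 <- withr::local_tempfile(fileext = ".TextGrid")
  write_textgrid(rec3, f3)
  rec4 <- read_textgrid(f3)
  expect_equal(rec4$tiers$vv_units$start, rec3$tiers$vv_units$start,
               tolerance = 1e-6)
  expect_equal(rec4$tiers$z_peaks$time, rec3$tiers$z_peaks$time,
               tolerance = 1e-6)
})

test_that("structural violations are rejected with tier and index", {
  expect_error(
    annotated_recording("A1", duration = 1, tiers = list(
      vv_units = tibble::tibble(start = c(0, 0.4), end = c(0.5, 0.9),
                                label = c("v1", "v2")))),
    "vv_units.*overlap"
  )
  expect_error(
    annotated_recording("A1", duration = 1, tiers = list(
      vv_units = tibble::tibble(start = 0, end = NaN, label = "v"))),
    "non-finite"
  )
  rec <- toy_recording()
  rec$tiers$vv_units$end[1] <- Inf
  f <- withr::local_tempfile(fileext = ".TextGrid")
  expect_error(write_textgrid(rec, f), "non-finite")
  expect_false(file.exists(f))
})

test_that("a file with overlapping intervals fails to read", {
  f <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(c('"ooTextFile"', '"TextGrid"', "0", "1", "<exists>", "1",
               '"IntervalTier"', '"vv units"', "0", "1", "2",
               "0", "0.5", '"a"', "0.4", "0.9", '"b"'), f)
  expect_error(read_textgrid(f, schema = tg_schema(required = "vv_units")),
               "vv_units.*overlap")
})

test_that("a required tier missing from the file is a schema error", {
  f <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(short_textgrid_text(), f)
  expect_error(read_textgrid(f, schema = tg_schema()),
               "schema error.*speech_chunks")
})

test_that("an empty recording still writes all 11 tiers", {
  empty <- function() tibble::tibble(start = numeric(), end = numeric(),
                                     label = character())
  tiers <- purrr::map(setNames(tg_schema()$role, tg_schema()$role),
                      function(r) {
                        if (r == "z_peaks") {
                          tibble::tibble(time = numeric(), label = character())
                        } else empty()
                      })
  rec <- annotated_recording("Z1", tiers, duration = 2)
  f <- withr::local_tempfile(fileext = ".TextGrid")
  write_textgrid(rec, f)
  txt <- readLines(f)
  expect_equal(sum(grepl("^        class =", txt)), 11)
  expect_equal(sum(grepl('text = ""', txt)), 10) # one gap-filler per interval tier
})

test_that("validate_schema reports containment and coincidence violations as data", {
  rec <- toy_recording()
  expect_equal(nrow(validate_schema(rec)), 0)

  # V-V unit straddling two chunks -> one containment violation
  straddle <- annotated_recording("A1", duration = 3, tiers = list(
    speech_chunks = tibble::tibble(start = c(0, 1.5), end = c(1, 2.5),
                                   label = c("c1", "c2")),
    vv_units = tibble::tibble(start = c(0.2, 0.9), end = c(0.8, 1.6),
                              label = c("v1", "vX"))))
  rep1 <- validate_schema(straddle)
  expect_equal(nrow(rep1), 1)
  expect_equal(rep1$type, "containment")
  expect_equal(rep1$tier, "vv_units")

  # all_pauses interval matching no silent/filled pause -> coincidence violation
  bad2 <- rec
  bad2$tiers$all_pauses <- dplyr::bind_rows(
    bad2$tiers$all_pauses, tibble::tibble(start = 4.5, end = 4.8, label = "ghost"))
  rep2 <- validate_schema(annotated_recording("A1", bad2$tiers, 5))
  expect_equal(nrow(rep2), 1)
  expect_equal(rep2$type, "coincidence")

  # monotone: adding a violating interval never shrinks the report
  tiers3 <- straddle$tiers
  tiers3$all_pauses <- tibble::tibble(start = 2.6, end = 2.9, label = "ghost")
  rep3 <- validate_schema(annotated_recording("A1", tiers3, 3))
  expect_equal(nrow(rep3), 2)
  expect_setequal(rep3$type, c("containment", "coincidence"))
})

test_that("tier names map to roles case-insensitively and by alias", {
  expect_equal(match_tier_role("Vowel-to-vowel units", tg_schema()), "vv_units")
  expect_equal(match_tier_role("SPEECH CHUNKS", tg_schema()), "speech_chunks")
  expect_equal(match_tier_role("Smoothed z-scores peak values", tg_schema()),
               "z_peaks")
  expect_true(is.na(match_tier_role("mystery tier", tg_schema())))
  s <- tg_schema(extra_names = list(vv_units = "sillabes"))
  expect_equal(match_tier_role("Sillabes", s), "vv_units")
})
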