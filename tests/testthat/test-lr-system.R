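toy_background <- function(k = 3, n = 6, means = NULL, seed = 2) {
  set.seed(seed)
  means <- means %||% seq(0, 4, length.out = k)
  tibble::tibble(
    speaker = rep(sprintf("S%02d", seq_len(k)), each = n),
    value = rnorm(k * n, rep(means, each = n), 1)
  )
}

test_that("model fitting pools within variance and refuses degeneracy", {
  bg <- toy_background(k = 4)
  m <- fit_lr_model(bg)
  expect_equal(m$k, 4)
  expect_length(m$speaker_means, 4)
  expect_gt(m$within_var, 0)
  # pooled within variance equals the classical estimator
  by_sp <- split(bg$value, bg$speaker)
  pooled <- sum(vapply(by_sp, function(v) sum((v - mean(v))^2), numeric(1))) /
    sum(lengths(by_sp) - 1)
  expect_equal(m$within_var, pooled)
  # Silverman-type bandwidth on the background means
  expect_equal(m$bandwidth, sd(m$speaker_means) * (4 / (3 * 4))^(1 / 5))

  expect_error(fit_lr_model(bg[bg$speaker == "S01", ]), "2 background speakers")
  const <- tibble::tibble(speaker = rep(c("a", "b"), each = 3), value = rep(1, 6))
  expect_error(fit_lr_model(const), "within-source variance|speaker means")
})

test_that("log LR matches the quadrature oracle on toy backgrounds", {
  set.seed(31)
  for (i in 1:30) {
    k <- sample(3:6, 1)
    bg <- toy_background(k = k, n = sample(3:8, 1),
                         means = rnorm(k, 0, 2), seed = 100 + i)
    m <- fit_lr_model(bg)
    x <- rnorm(sample(2:6, 1), rnorm(1, 0, 2), 1)
    y <- rnorm(sample(2:6, 1), rnorm(1, 0, 2), 1)
    expect_equal(
      score_lr(m, x, y),
      lr_quadrature_oracle(x, y, m$speaker_means, m$within_var, m$bandwidth),
      tolerance = 1e-6
    )
  }
})

test_that("log LR signs follow sample agreement", {
  bg <- toy_background(k = 6, means = seq(-5, 5, length.out = 6))
  m <- fit_lr_model(bg)
  # questioned mean equal to suspect mean, diffuse background: support
  expect_gt(score_lr(m, rnorm(20, 0, 0.3), rnorm(20, 0, 0.3)), 0)
  # questioned far in the tail of the suspect distribution: counter-support
  expect_lt(score_lr(m, rnorm(20, -4, 0.3), rnorm(20, 4, 0.3)), 0)
})

test_that("cross-validated scoring builds 190 ds and 20 ss trials", {
  tbl <- zero_effect_population(seed = 8, tokens = 12)
  sc <- cross_validated_scores(tbl, "SRATE")
  expect_equal(sum(sc$type == "ds"), 190)
  expect_equal(sum(sc$type == "ss"), 20)
  expect_equal(sum(sc$intra_twin), 10)
  expect_true(all(!sc$intra_twin[sc$type == "ss"]))
  expect_true(all(is.finite(sc$llr)))
  # insufficient data for the split names the speaker
  short <- tbl[!(tbl$speaker == "A1" & tbl$chunk_id %in% as.character(1:10)), ]
  expect_error(cross_validated_scores(short, "SRATE"), "A1")
})

test_that("Cllr evaluates the penalty sum exactly", {
  # trivial LR = 1 system costs exactly 1 bit
  expect_equal(cllr(score_set(0, 0)), 1.0)
  expect_equal(cllr(score_set(rep(0, 5), rep(0, 9))), 1.0)
  # hand-evaluable two-score set
  expect_equal(cllr(score_set(log10(4), log10(1 / 4))), log2(1.25),
               tolerance = 1e-12)
  # random sets match direct evaluation of the penalty formula
  set.seed(12)
  for (i in 1:20) {
    s <- random_scores()
    expect_equal(cllr(s), cllr_direct(10^ss_of(s), 10^ds_of(s)),
                 tolerance = 1e-12)
  }
  # perfect-system limit
  expect_lt(cllr(score_set(c(40, 50), c(-40, -50))), 1e-9)
})

test_that("calibration never loses to the best affine map, and fixes shifts", {
  set.seed(23)
  for (i in 1:100) {
    s <- random_scores(n_ss = sample(10:40, 1), n_ds = sample(10:80, 1),
                       shift = rnorm(1), scale = runif(1, 0.5, 2))
    expect_lte(cllr(suppressWarnings(calibrate(s))), cllr(s) + 1e-6)
  }
  # a known shift is removed
  set.seed(5)
  base <- score_set(rnorm(200, 1, 1), rnorm(200, -1, 1))
  shifted <- score_set(ss_of(base) + 2, ds_of(base) + 2)
  expect_lt(cllr(calibrate(shifted)), cllr(shifted))
  expect_equal(cllr(calibrate(shifted)), cllr(calibrate(base)), tolerance = 1e-8)
  # uninformative scores: calibrated cost ~ 1 bit
  set.seed(6)
  z <- rnorm(400)
  uninf <- score_set(z, sample(z))
  expect_equal(cllr(calibrate(uninf)), 1.0, tolerance = 0.02)
  # perfect separation falls back to a penalised fit with a warning
  expect_warning(calibrate(score_set(c(2, 3, 4), c(-2, -1, 0))), "separation")
})

test_that("EER matches the exhaustive sweep oracle", {
  expect_equal(eer(score_set(c(2, 3), c(0, 1))), 0)
  s <- score_set(c(0, 1, 2), c(0, 1, 2))
  expect_equal(eer(s), 0.5)
  set.seed(14)
  for (i in 1:200) {
    ss <- round(rnorm(sample(3:15, 1), 0.5), 1)
    ds <- round(rnorm(sample(3:15, 1), -0.5), 1)
    expect_equal(eer(score_set(ss, ds)), eer_oracle(ss, ds), tolerance = 1e-12)
  }
})

test_that("pairwise AUC equals exhaustive enumeration and the U statistic", {
  expect_equal(pairwise_auc(c(1, 2, 3), c(4, 5, 6)), 0)
  expect_equal(pairwise_auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(pairwise_auc(c(1, 2, 3), c(2, 3, 4)), 2 / 9)
  set.seed(15)
  for (i in 1:200) {
    a <- round(rnorm(sample(1:12, 1)), 1)
    b <- round(rnorm(sample(1:12, 1)), 1)
    expect_equal(pairwise_auc(a, b), auc_oracle(a, b))
    # Mann-Whitney U equivalence
    if (length(a) > 0 && length(b) > 0) {
      u <- suppressWarnings(stats::wilcox.test(a, b)$statistic)
      expect_equal(pairwise_auc(a, b), unname(u) / (length(a) * length(b)))
    }
  }
})

test_that("EER and AUC are invariant under strictly increasing transforms", {
  set.seed(16)
  ss <- rnorm(25, 1)
  ds <- rnorm(40, -1)
  f <- function(x) exp(x / 3) + x
  expect_equal(eer(score_set(f(ss), f(ds))), eer(score_set(ss, ds)))
  expect_equal(pairwise_auc(f(ss), f(ds)), pairwise_auc(ss, ds))
  d <- tibble::tibble(speaker = rep(c("a", "b", "c"), each = 10),
                      value = rnorm(30))
  d2 <- dplyr::mutate(d, value = f(value))
  expect_equal(multiclass_auc(d2), multiclass_auc(d))
})

test_that("multiclass AUC averages pair separabilities", {
  # exchangeable speakers: near chance
  set.seed(17)
  d0 <- tibble::tibble(speaker = rep(sprintf("S%02d", 1:10), each = 40),
                       value = rnorm(400))
  expect_lt(multiclass_auc(d0), 0.62)
  # widely separated speakers: near 1
  d1 <- tibble::tibble(speaker = rep(c("a", "b", "c"), each = 20),
                       value = rnorm(60, rep(c(0, 10, 20), each = 20), 1))
  expect_gt(multiclass_auc(d1), 0.99)
  # two speakers: the max-oriented pairwise AUC
  d2 <- d1[d1$speaker != "c", ]
  a <- pairwise_auc(d2$value[d2$speaker == "a"], d2$value[d2$speaker == "b"])
  expect_equal(multiclass_auc(d2), max(a, 1 - a))
  # cross-check against pROC's pairwise average on a small instance
  skip_if_not_installed("pROC")
  d3 <- tibble::tibble(speaker = rep(c("a", "b", "c"), each = 15),
                       value = rnorm(45, rep(c(0, 1, 2), each = 15), 1))
  ref <- suppressMessages(as.numeric(pROC::multiclass.roc(d3$speaker, d3$value)$auc))
  expect_equal(multiclass_auc(d3), ref, tolerance = 1e-10)
})

test_that("discrimination metrics respond to the between/within ratio", {
  metrics_at <- function(ratio, seed) {
    spec <- parameter_spec("P", "normal", 10, between_speaker_sd = ratio,
                           within_speaker_sd = 1, tokens_per_speaker = 20)
    tbl <- simulate_population(population_config(
      n_speakers = 10, n_twin_pairs = 0, twin_similarity = 0,
      specs = spec, master_seed = seed))
    sc <- cross_validated_scores(tbl, "P")
    c(cllr = cllr(sc), auc = multiclass_auc(tbl))
  }
  m0 <- rowMeans(vapply(1:5, function(s) metrics_at(0, s), numeric(2)))
  m2 <- rowMeans(vapply(1:5, function(s) metrics_at(2, s), numeric(2)))
  expect_lt(m2["cllr"], m0["cllr"])
  expect_gt(m2["auc"], m0["auc"])
})
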