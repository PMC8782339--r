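#' Fit a univariate two-level kernel-density LR model
#'
#' The forensic score for a timing parameter is a likelihood ratio
#' `LR = p(E | same speaker) / p(E | different speakers)` computed under a
#' two-level model estimated on a *background* population: within a speaker,
#' observations are normal around the speaker's level with a pooled
#' within-source variance; across speakers, the speaker levels follow a
#' normal-kernel density over the background speakers' means (bandwidth from
#' Silverman's rule on those means). This is the univariate specialisation of
#' the multivariate kernel-density (MVKD) approach; each timing parameter is
#' scored separately.
#'
#' @param background long table (`speaker`, `value`) of background
#'   observations — all speakers except the two being compared.
#' @param value,group tidy-selected value / speaker columns.
#' @return An object of class `lr_model`: `speaker_means`, `within_var`
#'   (pooled), `bandwidth`, `k`.
#' @export
fit_lr_model <- function(background, value = value, group = speaker) {
  gd <- resolve_groups(background, {{ value }}, {{ group }})
  labs <- unique(gd$groups)
  k <- length(labs)
  if (k < 2) abort("need at least 2 background speakers")
  split_v <- split(gd$values, factor(gd$groups, levels = labs))
  ni <- lengths(split_v)
  if (any(ni < 2)) {
    abort("every background speaker needs >= 2 observations to pool within-source variance")
  }
  mu <- purrr::map_dbl(split_v, mean)
  ss <- sum(purrr::map_dbl(split_v, function(v) sum((v - mean(v))^2)))
  within_var <- ss / sum(ni - 1)
  if (within_var <= 0) abort("zero within-source variance in background")
  sb <- sd(mu)
  if (sb == 0) abort("degenerate background: all speaker means equal")
  bandwidth <- sb * (4 / (3 * k))^(1 / 5)
  structure(list(speaker_means = unname(mu), within_var = within_var,
                 bandwidth = bandwidth, k = k),
            class = "lr_model")
}

#' @export
print.lr_model <- function(x, ...) {
  cat(sprintf("<lr_model> %d background speakers, within SD %.4g, bandwidth %.4g\n",
              x$k, sqrt(x$within_var), x$bandwidth))
  invisible(x)
}

#' Score a comparison: log10 likelihood ratio
#'
#' Evaluates the evidence that the suspect and questioned samples share a
#' source. Under the two-level model the sample means are sufficient:
#' `xbar ~ N(theta, sigma_w^2 / n)` given the speaker level `theta`, and
#' `theta` follows the background kernel density. All integrals are Gaussian
#' and evaluated in closed form:
#' numerator `= N(xbar - ybar; 0, A + B) * mean_i N(w; mu_i, V + h^2)` with
#' `A = s2/nx`, `B = s2/ny`, `V = (1/A + 1/B)^-1`, `w = V (xbar/A + ybar/B)`;
#' denominator `= mean_i N(xbar; mu_i, A + h^2) * mean_i N(ybar; mu_i, B + h^2)`.
#'
#' @param model an [fit_lr_model()].
#' @param suspect_data,questioned_data numeric observation vectors.
#' @return log10 LR (positive values support the same-speaker hypothesis).
#' @export
score_lr <- function(model, suspect_data, questioned_data) {
  x <- suspect_data[is.finite(suspect_data)]
  y <- questioned_data[is.finite(questioned_data)]
  if (length(x) == 0 || length(y) == 0) abort("both samples must be nonempty")
  s2 <- model$within_var
  h2 <- model$bandwidth^2
  mu <- model$speaker_means
  A <- s2 / length(x); B <- s2 / length(y)
  xb <- mean(x); yb <- mean(y)
  V <- 1 / (1 / A + 1 / B)
  w <- V * (xb / A + yb / B)
  log_num <- dnorm(xb - yb, 0, sqrt(A + B), log = TRUE) +
    (lse(dnorm(w, mu, sqrt(V + h2), log = TRUE)) - log(length(mu)))
  log_den <- (lse(dnorm(xb, mu, sqrt(A + h2), log = TRUE)) - log(length(mu))) +
    (lse(dnorm(yb, mu, sqrt(B + h2), log = TRUE)) - log(length(mu)))
  llr <- (log_num - log_den) / log(10)
  if (!is.finite(llr)) abort("non-finite likelihood ratio")
  llr
}

twin_prefix <- function(id) sub("[0-9]+$", "", id)

#' Cross-validated same- and different-speaker scores
#'
#' Builds one parameter's full comparison experiment. Every speaker's
#' observations are first split into two pseudo-sessions by interleaving in
#' temporal order (odd/even tokens, a deterministic convention), so that all
#' trials — same-speaker and different-speaker alike — compare session-sized
#' samples and the two trial types are exchangeable when no speaker
#' information exists. Same-speaker trials score a speaker's first session
#' against their second (one trial per speaker); different-speaker trials
#' score, for every unordered pair, each speaker's first session against the
#' other's second and collapse the two directed log LRs by averaging (20
#' speakers give 190 trials), flagged `intra_twin` when both members share a
#' twin-pair prefix (e.g. A1 vs A2). The background always excludes the
#' compared speaker(s) (cross-validation).
#'
#' @param data long parameter table (`speaker`, `value`, optionally
#'   `parameter`).
#' @param parameter restrict to this parameter first (required when the table
#'   holds several).
#' @param min_obs minimum observations a speaker needs (each session must
#'   hold >= 2 tokens).
#' @return A `speechlr_scores` tibble: `type` ("ss"/"ds"), `speaker_a`,
#'   `speaker_b`, `intra_twin`, `llr` (log10), with attributes `parameter`
#'   and `calibrated = FALSE`.
#' @export
cross_validated_scores <- function(data, parameter = NULL, min_obs = 4) {
  if (!is.null(parameter)) data <- data[data$parameter == parameter, , drop = FALSE]
  if ("parameter" %in% names(data) && length(unique(data$parameter)) > 1) {
    abort("table holds several parameters; pass `parameter`")
  }
  speakers <- sort(unique(data$speaker))
  if (length(speakers) < 3) abort("need at least 3 speakers (2 compared + background)")
  split_v <- split(data$value, factor(data$speaker, levels = speakers))
  short <- names(split_v)[lengths(split_v) < min_obs]
  if (length(short) > 0) {
    abort(paste0("insufficient data for split: speaker(s) ",
                 paste(short, collapse = ", "), " have fewer than ",
                 min_obs, " observations"))
  }
  sess <- purrr::map(split_v, function(v) {
    idx <- seq_along(v)
    list(v[idx %% 2 == 1], v[idx %% 2 == 0])
  })
  bg_table <- function(exclude) {
    keep <- setdiff(speakers, exclude)
    tibble::tibble(
      speaker = rep(keep, lengths(split_v[keep])),
      value = unlist(split_v[keep], use.names = FALSE)
    )
  }
  pairs <- utils::combn(speakers, 2)
  ds <- purrr::map(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    model <- fit_lr_model(bg_table(c(a, b)))
    llr <- (score_lr(model, sess[[a]][[1]], sess[[b]][[2]]) +
            score_lr(model, sess[[b]][[1]], sess[[a]][[2]])) / 2
    tibble::tibble(type = "ds", speaker_a = a, speaker_b = b,
                   intra_twin = twin_prefix(a) == twin_prefix(b),
                   llr = llr)
  })
  ss <- purrr::map(speakers, function(s) {
    model <- fit_lr_model(bg_table(s))
    tibble::tibble(type = "ss", speaker_a = s, speaker_b = s,
                   intra_twin = FALSE,
                   llr = score_lr(model, sess[[s]][[1]], sess[[s]][[2]]))
  })
  out <- dplyr::bind_rows(c(ss, ds))
  new_scores(out, parameter = parameter %||% unique(data$parameter) %||% NA_character_,
             calibrated = FALSE)
}

new_scores <- function(tbl, parameter, calibrated) {
  structure(tbl,
            parameter = parameter, calibrated = calibrated,
            class = c("speechlr_scores", class(tibble::as_tibble(tbl))))
}

#' Construct a score set directly
#'
#' @param ss_llr,ds_llr log10 LRs of same- and different-speaker trials.
#' @param parameter optional parameter name.
#' @param calibrated whether the scores are already calibrated.
#' @return A `speechlr_scores` tibble.
#' @export
score_set <- function(ss_llr, ds_llr, parameter = NA_character_,
                      calibrated = FALSE) {
  if (length(ss_llr) < 1 || length(ds_llr) < 1) {
    abort("need at least one score of each type")
  }
  if (any(!is.finite(c(ss_llr, ds_llr)))) abort("scores must be finite")
  new_scores(tibble::tibble(
    type = rep(c("ss", "ds"), c(length(ss_llr), length(ds_llr))),
    speaker_a = NA_character_, speaker_b = NA_character_,
    intra_twin = FALSE, llr = c(ss_llr, ds_llr)
  ), parameter = parameter, calibrated = calibrated)
}

ss_of <- function(scores) scores$llr[scores$type == "ss"]
ds_of <- function(scores) scores$llr[scores$type == "ds"]

# log2(1 + 10^u), overflow-safe
log2_1p_pow10 <- function(u) {
  ifelse(u > 30, u / log10(2), log1p(10^u) / log(2))
}

#' Log-likelihood-ratio cost (Cllr)
#'
#' The proper scoring rule for LR-based systems, in bits:
#' `Cllr = 1/2 ( mean log2(1 + 1/LR_ss) + mean log2(1 + LR_ds) )`.
#' Misleading and miscalibrated LRs are both penalised; the trivial system
#' that always answers LR = 1 costs exactly 1 bit, and a perfectly
#' discriminating, well-calibrated system approaches 0.
#'
#' @param scores a `speechlr_scores` object (log10 LRs).
#' @return Cllr in bits.
#' @export
cllr <- function(scores) {
  ss <- ss_of(scores); ds <- ds_of(scores)
  0.5 * (mean(log2_1p_pow10(-ss)) + mean(log2_1p_pow10(ds)))
}

#' Logistic self-calibration of LR scores
#'
#' Fits an affine map of the log-LR scores by equal-class-weighted logistic
#' regression on the scores themselves (self-calibration) and returns the
#' remapped scores. Equal class weighting matches the symmetric weighting of
#' the Cllr objective, so calibration can never do worse than the best affine
#' transform — in particular never worse than the identity. Under perfect
#' separation the unpenalised fit diverges; a lightly ridge-penalised fit is
#' used instead, with a warning.
#'
#' @param scores a `speechlr_scores` object with raw log10 LRs.
#' @return A `speechlr_scores` object with calibrated log10 LRs
#'   (`calibrated` attribute set).
#' @export
calibrate <- function(scores) {
  ss <- ss_of(scores); ds <- ds_of(scores)
  if (length(ss) < 2 || length(ds) < 2) {
    abort("need >= 2 scores per class to calibrate")
  }
  s <- c(ss, ds)
  y <- rep(c(1, 0), c(length(ss), length(ds)))
  w <- ifelse(y == 1, 0.5 / length(ss), 0.5 / length(ds))
  w <- w * length(y) # scale-free for glm; keeps IRLS well-conditioned
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ s, family = stats::binomial(), weights = w),
    warning = function(wc) {
      msg <- conditionMessage(wc)
      if (grepl("fitted probabilities numerically 0 or 1", msg) ||
          grepl("algorithm did not converge", msg)) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
      if (grepl("non-integer #successes", msg)) {
        # expected: equal-class weights are fractional by design
        invokeRestart("muffleWarning")
      }
    }
  )
  coefs <- stats::coef(fit)
  if (sep_warn || any(!is.finite(coefs))) {
    warn("perfect or quasi-perfect separation: using ridge-penalised calibration")
    coefs <- ridge_logistic(s, y, w, lambda = 1e-2)
  }
  llr_cal <- (coefs[1] + coefs[2] * scores$llr) / log(10)
  out <- scores
  out$llr <- as.numeric(llr_cal)
  new_scores(tibble::as_tibble(out), parameter = attr(scores, "parameter"),
             calibrated = TRUE)
}

# weighted logistic regression with a light L2 penalty, fitted by BFGS on the
# penalised log-likelihood (numerically stable under complete separation)
ridge_logistic <- function(s, y, w, lambda = 1e-2) {
  nll <- function(b) {
    eta <- b[1] + b[2] * s
    -sum(w * (y * stats::plogis(eta, log.p = TRUE) +
              (1 - y) * stats::plogis(-eta, log.p = TRUE))) +
      0.5 * lambda * b[2]^2 + 0.5 * 1e-6 * b[1]^2
  }
  fit <- stats::optim(c(0, 1), nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  fit$par
}

#' Equal error rate
#'
#' Sweeps an accept threshold over the pooled scores; the false-reject rate
#' (same-speaker trials below threshold) rises while the false-accept rate
#' (different-speaker trials at or above it) falls, and the EER is their
#' crossing point, linearly interpolated between adjacent operating points.
#'
#' @param scores a `speechlr_scores` object.
#' @return EER as a fraction in `[0, 1]`.
#' @export
eer <- function(scores) {
  ss <- ss_of(scores); ds <- ds_of(scores)
  thr <- c(sort(unique(c(ss, ds))), Inf)
  frr <- purrr::map_dbl(thr, function(t) mean(ss < t))
  far <- purrr::map_dbl(thr, function(t) mean(ds >= t))
  d <- frr - far
  i <- which(d >= 0)[1]
  if (d[i] == 0) return(frr[i])
  if (i == 1) return(frr[1])
  r0 <- frr[i - 1]; f0 <- far[i - 1]
  r1 <- frr[i]; f1 <- far[i]
  alpha <- (f0 - r0) / ((r1 - r0) - (f1 - f0))
  r0 + alpha * (r1 - r0)
}

#' Pairwise AUC with fixed orientation
#'
#' `P(X_a > X_b) + 0.5 P(X_a = X_b)` — the Mann-Whitney probability that a
#' value from speaker a exceeds one from speaker b. The orientation is fixed
#' (a-positive), so values below 0.5 are meaningful: they say speaker a tends
#' to sit *below* speaker b.
#'
#' @param x_a,x_b numeric observation vectors.
#' @return A fraction in `[0, 1]`.
#' @export
pairwise_auc <- function(x_a, x_b) {
  na <- length(x_a); nb <- length(x_b)
  if (na == 0 || nb == 0) abort("both samples must be nonempty")
  r <- rank(c(x_a, x_b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  u / (na * nb)
}

#' Pairwise AUC matrix across speakers
#'
#' @param data long parameter table (`speaker`, `value`).
#' @param parameter optional restriction.
#' @return A square matrix, entry `[i, j]` = `pairwise_auc(values_i, values_j)`
#'   (rows oriented positive); diagonal 0.5.
#' @export
pairwise_auc_matrix <- function(data, parameter = NULL) {
  if (!is.null(parameter)) data <- data[data$parameter == parameter, , drop = FALSE]
  speakers <- sort(unique(data$speaker))
  split_v <- split(data$value, factor(data$speaker, levels = speakers))
  k <- length(speakers)
  m <- matrix(0.5, k, k, dimnames = list(speakers, speakers))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      a <- pairwise_auc(split_v[[i]], split_v[[j]])
      m[i, j] <- a
      m[j, i] <- 1 - a
    }
  }
  m
}

#' Multiclass AUC (averaged pairwise separability)
#'
#' The multiclass generalisation of the AUC: for each unordered speaker pair
#' the separability is the orientation-free pairwise AUC `max(A, 1 - A)`, and
#' the multiclass AUC is the average over all pairs. With all speakers drawn
#' from one distribution it sits near 0.5; with well-separated speakers it
#' approaches 1. No single ROC curve corresponds to it.
#'
#' @inheritParams pairwise_auc_matrix
#' @return A fraction in `[0.5, 1]`.
#' @export
multiclass_auc <- function(data, parameter = NULL) {
  m <- pairwise_auc_matrix(data, parameter)
  k <- nrow(m)
  if (k < 2) abort("need at least 2 speakers")
  vals <- m[upper.tri(m)]
  mean(pmax(vals, 1 - vals))
}

#' System metrics for one parameter
#'
#' Bundles the evaluation of a parameter's LR system: raw and self-calibrated
#' Cllr (bits), EER, and the multiclass AUC of the raw parameter values.
#'
#' @param scores a `speechlr_scores` object (raw).
#' @param data the parameter table the scores were computed from (for the
#'   multiclass AUC); `NULL` skips it.
#' @param parameter optional restriction for `data`.
#' @return A one-row tibble: `parameter`, `cllr_raw`, `cllr_cal`, `eer`,
#'   `auc_multiclass`, `n_ss`, `n_ds`.
#' @export
system_metrics <- function(scores, data = NULL, parameter = NULL) {
  cal <- calibrate(scores)
  tibble::tibble(
    parameter = attr(scores, "parameter"),
    cllr_raw = cllr(scores),
    cllr_cal = cllr(cal),
    eer = eer(scores),
    auc_multiclass = if (is.null(data)) NA_real_ else multiclass_auc(data, parameter),
    n_ss = length(ss_of(scores)),
    n_ds = length(ds_of(scores))
  )
}
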