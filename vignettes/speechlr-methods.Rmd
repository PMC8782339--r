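---
title: "Speech timing as forensic evidence: models and design choices in speechlr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speech timing as forensic evidence: models and design choices in speechlr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechlr)
```

## The problem

Forensic speaker comparison asks how strongly a piece of recorded speech
supports the hypothesis that two recordings share a speaker. Spectral
features (formants, cepstra) dominate practice; `speechlr` implements the
complementary *temporal* route: how fast a person speaks, how long their
syllable-sized units and vowels last, how they pause. The package covers the
full chain for eleven timing parameters extracted from tiered interval
annotations of spontaneous dialogue:

1. **Annotation I/O** — Praat TextGrid reading/writing against an 11-layer
   schema (dialogue parts, speech chunks, vowels, oral monophthongs and
   diphthongs, filled/silent/all pauses, vowel-to-vowel units, smoothed
   z-score peaks, stress groups).
2. **Extraction** — speech rate (`SRATE`), articulation rates (`ARTRATE_I`,
   `ARTRATE_II`), stress-group duration (`SGDUR`), V-V unit durations
   (`VVDUR_I`, `VVDUR_II`), vowel duration (`VOWEL_DUR`), pause durations
   (`SILPAUSES`, `FILPAUSES`, `ALLPAUSES`) and inter-pausal intervals
   (`IPI`).
3. **Group statistics** — Kruskal–Wallis across speakers, Dunn's post hoc
   with Bonferroni adjustment, rank eta-squared effect sizes, and a balanced
   down-sampling replication protocol.
4. **LR system evaluation** — per-parameter likelihood-ratio systems with
   cross-validated backgrounds, logistic self-calibration, and the Cllr /
   EER / multiclass-AUC metric battery.
5. **Synthetic populations** — a hierarchical generator of twin-structured
   speaker populations and fully tiered synthetic recordings, so the entire
   pipeline is testable without any audio corpus.

The reference population the defaults emulate is 20 male speakers forming 10
identical twin pairs, recorded in spontaneous telephone dialogues: roughly
42 speech chunks of about 3 s per speaker, each chunk holding at least three
V-V units, and pauses annotated only at or above 100 ms.

## Extraction definitions and conventions

A *speech chunk* is an annotated stretch of speech, mostly an inter-pause
interval. Rates are chunk-level quantities in V-V units per second:

* `SRATE = n_vv / chunk duration` (pauses included);
* `ARTRATE_I = n_vv / (duration − silent-pause time)`;
* `ARTRATE_II = n_vv / (duration − silent-pause time − filled-pause time)`.

So `ARTRATE_II ≥ ARTRATE_I ≥ SRATE` on every chunk, with equality exactly
when the corresponding pause set is empty. Three conventions deserve
explanation:

* **The ≥ 3 V-V rule.** Chunks with fewer than three V-V units are excluded
  from rate computation (they are dominated by phrase-final lengthening) but
  still contribute pause observations; the rule targets rates, not pauses.
* **The 100 ms threshold** applies inclusively ("equal or superior") to both
  silent and filled pauses; shorter silences are treated as plosive
  occlusions, shorter lengthenings as ordinary phonetic variation.
* **`ARTRATE_II`'s numerator** keeps the full V-V count; the exclusion of
  lengthened vowels is read as acting on the time base only. The alternative
  reading (also dropping the lengthened units from the count) is coherent
  but makes `ARTRATE_II` non-monotone against `ARTRATE_I`; the time-base
  reading preserves the observed ordering of the three rates.

**Salience and stress groups.** A V-V unit is *salient* when it sits at a
local peak of the smoothed z-scored duration contour — the automatic
correlate of a perceived duration increase. The upstream detection script is
not public, so every knob is exposed in `salience_params()`: z-reference
(default: the recording's own mean/SD), smoothing window (default: 5-point
centred moving average, shrinking at the edges), peak rule (default: local
maximum with smoothed z > 0), and a minimum prominence (default 0). Ties on
a plateau break to the earlier unit, making extraction deterministic. These
defaults are documented choices, not a claim of bit-for-bit equivalence with
the original tool. A *stress group* spans from one salient unit's end to the
next salient unit's end and never crosses a chunk boundary.

**Boundary tolerance.** Containment and coincidence checks
(`validate_schema()`, `derive_chunks()`) use a 10 ms tolerance: manual
segmentation jitters, and the schema does not promise exact boundary
agreement across tiers.

**Units.** Seconds everywhere internally; milliseconds only where the
reporting convention uses them (V-V, vowel and pause durations). Rates are
V-V units per second; `SGDUR` and `IPI` are in seconds.

## Group statistics

Speakers rarely produce equal numbers of tokens, so inference is
non-parametric throughout: Kruskal–Wallis (tie-corrected, via
`stats::kruskal.test`) as the omnibus test, Dunn's two-tailed pairwise z
tests afterwards, with Bonferroni adjustment `p_adj = min(1, m · p_raw)`.
With 20 speakers the default `m` is the 190 comparisons among all
individuals. The published protocol's significance threshold is ambiguous
between α = 0.05 and α = 0.025 after adjustment; `speechlr` adjusts by `m`
and flags at a configurable `alpha` (default 0.05), with 0.025 available as
an argument.

The effect size is the rank eta-squared

> η² = (H − k + 1) / (n − k),

banded as negligible (< 0.01), small ([0.01, 0.06)), moderate
([0.06, 0.14)) or large (≥ 0.14). Percentages are rounded **half-up** to one
decimal — `round()`'s banker's rounding would turn 0.1555 into 15.5 vs 15.6
depending on binary representation; half-up reproduces the published worked
examples exactly:

```{r}
eta_squared_kw(148.7, k = 20, n = 851)  # speech rate: 15.6%, large
eta_squared_kw(121.3, k = 20, n = 851)  # articulation rate II: 12.3%, moderate
```

**Down-sampling.** Because a single random balance can be a fluke, the
protocol repeats *balance to the minority class, then test* 3–20 times and
counts, per speaker pair, how many replications flag it significant.
Replication seeds derive from a master seed by a fixed counter scheme
(`seed + 1000003 · r mod (2³¹ − 1)`), so reports are reproducible and
replications distinct.

## The likelihood-ratio model

Each timing parameter is scored separately with a univariate two-level
model, the scalar specialisation of the multivariate kernel-density (MVKD)
approach standard in forensic voice comparison:

* within a speaker, observations are normal around the speaker's level θ
  with pooled within-source variance σ²_w;
* across speakers, θ follows a normal-kernel density over the background
  speakers' means, bandwidth `h = sd(means) · (4/(3k))^{1/5}` (Silverman's
  rule on the k background means).

For suspect data x and questioned data y the sample means are sufficient,
and every integral is Gaussian, so the log₁₀ LR has a closed form: with
`A = σ²_w/n_x`, `B = σ²_w/n_y`, `V = (1/A + 1/B)⁻¹`,
`w = V(x̄/A + ȳ/B)`,

> numerator = N(x̄ − ȳ; 0, A + B) · meanᵢ N(w; μᵢ, V + h²),
> denominator = meanᵢ N(x̄; μᵢ, A + h²) · meanᵢ N(ȳ; μᵢ, B + h²).

The test suite verifies this closed form against direct numerical
quadrature of the two-level integrals to 10⁻⁶. Degenerate backgrounds (all
speaker means equal, or zero within variance) are refused rather than
allowed to emit infinite LRs.

**Trial design.** Every speaker's observations are split into two
pseudo-sessions by odd/even interleaving in temporal order. Same-speaker
trials score session 1 against session 2 (one per speaker, N_ss = 20);
different-speaker trials score each speaker's session 1 against the other's
session 2 and average the two directed log-LRs into one score per unordered
pair (N_ds = 190 for 20 speakers). The background always excludes the
compared speaker(s). Scoring session-sized samples on *both* trial types
makes them exchangeable when no speaker information exists — an asymmetric
design (half-samples against full samples) pushes the null EER away from
0.5 purely because the log-LR distribution depends on sample size.

**Calibration and metrics.** Self-calibration fits an affine map of the
log-LR scores by equal-class-weighted logistic regression on the scores
themselves. Equal class weights make the logistic deviance proportional to
Cllr, so the calibrated cost can never exceed that of any affine transform —
in particular the identity, hence `Cllr_cal ≤ Cllr_raw` up to numerical
noise. Under (quasi-)separation the unpenalised fit diverges; a lightly
ridge-penalised fit (λ = 0.01 on the slope) takes over, with a warning.

* `cllr()` evaluates the log-LR cost exactly, in bits; the trivial LR = 1
  system costs exactly 1 bit.
* `eer()` sweeps an accept threshold over all distinct operating points and
  interpolates linearly where the false-reject and false-accept curves
  cross.
* `pairwise_auc()` is the Mann–Whitney probability with **fixed**
  orientation, so values below 0.5 are meaningful (speaker a sits below
  speaker b).
* `multiclass_auc()` averages the orientation-free separability
  `max(A, 1 − A)` over all speaker pairs.

**A bias worth knowing about.** Because the orientation of each pair is
chosen on the same data that estimates its AUC, the multiclass AUC is
≥ 0.5 by construction and its *null* expectation sits above 0.5 at finite
sample sizes: with n tokens per speaker the per-pair null AUC has standard
deviation ≈ √((2n+1)/(12n²)), and the expected separability is
0.5 + √(2/π) times that (≈ 0.546 at n = 50). Any orientation-selecting
estimator — including the standard multiclass-ROC implementations — shares
this property. Interpret small multiclass-AUC elevations above 0.5
accordingly; the package's null-system tests assert the *measured* behaviour
of this estimator rather than the idealised 0.5.

## The synthetic population generator

The study's recordings are not distributable, so the generator reproduces
their *statistical structure*, which is what the downstream methods consume:

* **Hierarchy.** Each parameter has a population mean, a between-speaker SD
  (spread of speaker levels) and a within-speaker SD (token scatter).
  Rates are zero-truncated normal; duration-type parameters are lognormal
  (positive support, right skew — their corpus means exceed their medians),
  with the between/within split applied on the log scale by partitioning the
  moment-matched total log-variance.
* **Defaults** (`default_parameter_specs()`) take population means and total
  SDs from the corpus descriptives (speech rate 4.6 ± 1.3 vv/s, vowel
  duration 84 ± 67 ms, silent pauses 547 ± 333 ms, ...), token counts per
  speaker of the order of the corpus counts divided by 20 (e.g. 43 rate
  observations, 472 vowels), and decompose total SD using the published
  range of speaker means as the between-speaker spread (≈ range/4). The
  corpus does not publish a variance decomposition; this one is a
  documented, fixed choice, not a claim about the study's truth.
* **Twins.** The two members of a pair share a fraction ρ of the
  between-speaker variance: speaker level = m + σ_b(√ρ · z_pair +
  √(1−ρ) · z_own). ρ = 1 makes twin levels identical; the default ρ = 0.95
  encodes the near-complete overlap of twin timing distributions the study
  reports. Entrainment *dynamics* (time-locked convergence within the
  dialogue) are deliberately not modelled — twin similarity is static.
* **Rendered recordings.** `render_recording()` emits all 11 tiers: chunks
  draw a V-V count (min 3) and an articulation rate, V-V durations are
  scaled to realise that rate exactly, a random subset of V-V units become
  lengthened vowels (filled pauses ≥ 100 ms), within-chunk silent pauses
  follow a Poisson process, and chunks are separated by longer silent
  pauses. The z-peak and stress-group tiers are produced by the *same*
  salience detector the extraction uses, so rendered files pass
  `validate_schema()` with an empty report and round-trip through the
  TextGrid writer/reader bit-stably for a fixed seed.

What passing tests on synthetic data do **not** show: robustness to manual
segmentation errors, to dialect or style mismatch, to channel effects, or to
real prosodic structure (the generator has no linguistics — no lexical
items, no intonational phrasing beyond chunking, no turn-taking).

## Numerical choices

* Log-sum-exp for all kernel mixtures; `log1p`-based Cllr with a linear
  regime for |log₁₀ LR| > 30, so extreme scores cannot overflow.
* TextGrid numbers are written with six decimals (1 µs); round-trips agree
  to 10⁻⁶ s, the documented boundary tolerance.
* Kruskal–Wallis on constant data is an error (the tie correction
  degenerates), as is a balanced down-sample for a speaker with zero
  observations; both name the offending condition.
* Salience on a zero-variance contour is defined as "nothing salient".
* All randomness flows through explicit seeds; derived sub-seeds stay below
  2³¹.

## Problem sizes used by the test suite

The statistical acceptance checks run at the emulated study's scale:
20 speakers × 50 tokens × 20 Monte-Carlo repeats for the null-system
recovery; 4 between/within ratios × 20 repeats for effect-recovery
monotonicity; 20 simulated studies for the twin contrast; 300 s rendered
recordings (≈ 100 chunks) for extraction round-trips, where the 2 %
recovery check has ≈ 2 standard errors of headroom. Oracle-equivalence
suites use 100–200 random instances each. The full suite completes in under
two minutes on one CPU.

## Known limitations

* Univariate scoring only: no joint-parameter fusion, no GMM/i-vector
  systems, and no speaker-sampling uncertainty intervals on Cllr.
* The salience detector is a parameterised reconstruction, not the original
  semi-automatic tool.
* Diphthong durations (schema layer 5) are carried through I/O but not
  analysed.
* The TextGrid parser expects single-line interval labels (Praat's doubled
  quote escape is supported; embedded newlines are not).
* `IPI` is computed across chunk boundaries within a recording; if the
  original protocol restricted it to within-chunk pause pairs, absolute IPI
  values will differ while speaker contrasts remain comparable.
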