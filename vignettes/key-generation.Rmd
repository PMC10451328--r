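---
title: "Margin-based key generation from neural band-power features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Margin-based key generation from neural band-power features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurokey)
library(dplyr)
```

## The problem

Biometric authentication from brain signals is attractive because neural
activity is hard to steal or imitate, and — unlike a fingerprint — a
brain-derived credential can be *revoked*: re-enrolling the same person under
a different behavioural paradigm yields a statistically independent key.
neurokey implements a complete pipeline that turns multichannel
electrophysiological recordings (intracortical local field potentials being
the motivating modality) into per-subject binary key templates, and
authenticates freshly recorded signals against them by Hamming distance.

The pipeline is:

1. **Preprocessing** — zero-phase Butterworth bandpass filtering (default
   0.5–300 Hz, second-order design), behaviour segmentation, and framing into
   non-overlapping 2-s trials.
2. **Features** — per trial and channel, log power in the five classical
   bands (delta, theta, alpha, beta, gamma) plus the log total, estimated by
   Hanning-windowed FFTs (512-point windows, 100-ms hop) averaged within the
   trial. Sixteen channels thus give 96 features; all unordered feature pairs
   (4560 for 96 features) form the two-dimensional spaces the quantizer
   operates on.
3. **Quantization** — the margin model described below selects, per subject,
   the feature pairs that are reliably far from the population centre and
   encodes each as 2 bits.
4. **Authentication** — a key regenerated from fresh trials is accepted when
   its normalized Hamming distance to the stored template is at most the
   subject's calibrated threshold $\gamma$.

## The quantization model

Both the population and each subject are modelled per feature pair $f$ as
axis-aligned bivariate Gaussians (correlation fixed to zero):
$\mathrm{pop} \sim N(\mu_{pop}^f, \Sigma_{pop}^f)$ and subject $S_i \sim
N(\mu_{S_i}^f, \Sigma_{S_i}^f)$, all fitted by maximum likelihood. The
population fit pools the raw training trials of every enrolled subject —
the gallery *is* the population.

A subject's bit on an axis is the side of the population centre its mean
falls on. The bit is unreliable when the subject's distribution overlaps the
centre: the **overlap parameter** $\alpha \in (0, 0.5)$ caps the tolerated
wrong-side probability mass. Working with the worst-case subject — the one
maximising $\sigma_X^2 + \sigma_Y^2$ on that pair — the margin $m$ solves

$$\int_0^{m} N(0, \sigma_{S_j})\,dx = \tfrac12 - \alpha
  \quad\Longleftrightarrow\quad m = \sigma_{S_j}\,\Phi^{-1}(1-\alpha),$$

applied per axis. A pair is **reliable** for subject $i$ when
$|\mu_{S_i} - \mu_{pop}| \ge m$ on both axes *and* strictly more than a
fraction $\beta$ of the subject's raw training trials fall strictly beyond
the margins on the subject's side (boundary samples count as invalid). The
selected pair indices are stored as non-secret helper data; the 2-bit
quadrant codes (a Gray code: `00`, `01`, `10`, `11` with adjacent quadrants
differing in one bit) concatenated over the selected pairs form the key
template. A 1-bit mode codes single features by the same margin logic.

At authentication the margins are dropped and codes are assigned by quadrant
sign alone. The margin equations budget error mass *up to the centre*, which
makes the centre — not the margin boundary — the natural decision boundary
once the reliable pairs are fixed; leaving the margin band undefined at test
time would discard exactly the presentations the selection step was designed
to make safe.

### The margin convention

Read as a joint quadrant integral, the two-dimensional margin equation has
one equation and two unknowns, and the quadrant of a centred Gaussian holds
at most a quarter of the mass, so a joint solution exists only for
$\alpha \ge 0.25$ (with an infinite margin at the boundary). The package
therefore defaults to per-axis margins $m_{axis} = \sigma_{axis}
\Phi^{-1}(1-\alpha)$, which are well defined on the whole useful range
$\alpha \in (0, 0.5)$ and match the convention implied by sweeping $\alpha$
down to 0.20. The joint reading (shared standardized margin $u$ solving
$(\Phi(u)-\tfrac12)^2 = \tfrac12-\alpha$) is available via
`margin_convention = "joint"` and errors when infeasible.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.3 | max wrong-side mass per axis; larger → smaller margins, longer keys, less reliable bits |
| `beta` | 0.8 | min fraction of training trials strictly inside the code region; larger → fewer, more stable pairs |
| `gamma` | calibrated | per-subject normalized Hamming threshold |
| `bits_per_feature` | 2 | 2-bit quadrant codes on pairs; 1-bit codes on single features |
| `n_auth_trials` | 5 | trials (2 s each) averaged into one authentication presentation |
| `window_points`, `hop_seconds` | 512, 0.1 | spectral estimation grain |

**Why `n_auth_trials = 5`.** The authentication step fits the subject's
statistics to the presented samples before encoding; a single 2-s trial
admits no fit and makes each key a function of one noisy draw. With
per-trial keys and a threshold calibrated as the largest genuine validation
distance, the expected accuracy is capped near $n_{val}/(n_{val}+1)$ for
purely rank-statistical reasons, regardless of how separable the subjects
are. Batching a 10-s presentation (5 trials) shrinks the mean's noise by
$\sqrt 5$ and restores the regime the method is designed for. The batch size
is a free protocol choice exposed in every entry point.

**Calibrating $\gamma$.** The enrollment protocol reserves a validation
split; for each subject the package scans the achievable distance grid
$\{0, 1/L, \dots, 1\}$ and picks the $\gamma$ maximising accuracy minus
false acceptance rate, breaking ties first toward higher accuracy and then
toward the smallest (strictest) threshold. With separable cohorts this ends
at the largest genuine validation distance, typically 0.

## The synthetic cohort

No public recording of the motivating kind exists, so the package ships a
two-level generator. `simulate_feature_cohort()` draws the nested Gaussian
structure the model assumes directly: subject means
$\sim N(0, \sigma_b^2)$ per feature, trials $\sim N(\text{mean},
\sigma_w^2)$, independent features, and independently redrawn means per
context. Its defaults are the package's reference study conditions: 10
subjects, 96 features, 200 trials per context, $\sigma_b/\sigma_w = 10$ —
a spread ratio consistent with strongly subject-specific spectral profiles.
`simulate_signals()` additionally exercises the raw-signal path: 1/f-shaped
broadband noise with subject/channel/band log-gain offsets, through
filtering, framing and spectral estimation.

What the generator deliberately lacks: cross-feature correlation (band
powers from one channel are correlated in real recordings), non-Gaussian
tails, session-to-session drift, artefacts, and oscillatory structure.
Passing tests therefore demonstrate the *method* is implemented correctly
and behaves as designed under its own assumptions — not that real LFP
cohorts will reach any particular accuracy.

## Numerical choices and degenerate inputs

* Gaussian fits use maximum-likelihood (1/n) standard deviations.
* Band powers are floored at a tiny positive value before the log;
  all-zero channels trigger a warning rather than `-Inf` features.
* Population axes with pooled spread below `1e-9` times the mean spread are
  flagged unusable and excluded from selection; worst-case-subject ties are
  broken by subject order.
* Margins at $\alpha = 0.5$ are exactly 0; strict encoding then treats a
  mean exactly at the centre as undecidable (a measure-zero event).
* The $\beta$ rule uses strict inequalities: a sample exactly on a margin
  boundary is invalid, and selection requires strictly more than $\beta$.
* Distance/threshold comparisons add a `1e-12` tolerance so grid thresholds
  behave inclusively under floating-point round-off.
* Everything downstream of the simulators is deterministic; the simulators
  take explicit integer seeds and are bit-reproducible.

## Problem sizes used in the test-suite experiments

The reference experiments enrol the default cohort (10 subjects, 96
features → 4560 pairs, 200 trials split 80/10/10), run parameter sweeps on
reduced cohorts (24 features for the $\alpha$ sweep), verify the margin
closed form against numeric integration on a $(\sigma, \alpha)$ grid at
$10^{-6}$, and check the boundary flip probability with $10^5$ Monte-Carlo
draws. These sizes were chosen to exercise the full pair enumeration at the
study scale while keeping each experiment a few seconds long.

## Known limitations

* Keys are raw bit strings; no fuzzy-extractor strengthening, hashing or
  error-correcting codes are applied.
* Codes beyond 2 bits per pair are out of scope (the margin machinery
  extends naturally, but selection/encoding are implemented for 1 and 2).
* Min-entropy is computed over subjects' sign codes per pair and averaged
  across pairs; it measures code-book balance, not a formal security proof.
* The population model must be refitted when the gallery changes; helper
  data reference a model version and authentication refuses mismatched
  lengths.

## A worked example

```{r example}
cohort <- simulate_feature_cohort(n_subjects = 6, n_features = 24,
                                  n_trials = 120, seed = 9)
parts <- split_trials(cohort, seed = 9)
enr <- enroll_cohort(filter(parts, split == "train"),
                     filter(parts, split == "validation"),
                     alpha = 0.3, beta = 0.8)
tidy(enr)
report <- evaluate_enrollment(enr, filter(parts, split == "test"))
glance(report)
```

```{r plot, fig.width = 6, fig.height = 5}
autoplot(report)
```
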