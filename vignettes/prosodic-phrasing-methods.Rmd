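---
title: "Measuring prosodic marking of contrastive discourse status: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring prosodic marking of contrastive discourse status: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prosocontrast)
```

## The scientific problem

In French, speakers do not mark contrastive information with a special
pitch-accent type, as English speakers do; they mark it with *prosodic
phrasing* — how words are grouped into Accentual Phrases (APs), the
smallest prosodic unit of the language. In a cooperative map-task
dialogue, a director naming pairs of coloured landmarks ("the purple
candles and the purple candies") can phrase a target noun together with
its adjective in one AP when the noun repeats what was just said (given
status), or break it out into its own AP when it contrasts with the
previous noun (contrastive status). Whether a speaker makes this
distinction is interesting clinically: marking contrast presupposes
tracking what the listener already knows, a theory-of-mind (ToM)
ability that is often impaired in schizophrenia.

`prosocontrast` implements the full analysis pipeline for such a study:
rule-based AP-boundary classification from acoustic annotations, a
per-participant phrasing score on a 0–20 scale, crossed random-effects
models for the group × condition design, and the correlation of
phrasing ability with a hinting-task (ToM) score. Because no recordings
or raw data are distributed, the package includes a first-class
synthetic-data generator that emulates the study's hierarchical design,
so every stage is exercised end to end.

## Boundary classification

A target noun counts as phrased in its own AP (label `TWO_AP`) when a
pitch accent is realised on its last full syllable. Two acoustic
criteria operationalise this:

* **Pitch accent**: the f0 maximum H associated with the last syllable
  (S2) is at least 10% higher than the preceding "early L" minimum,
  i.e. `f0_h >= 1.10 * f0_l`.
* **Pre-boundary lengthening**: S2 is at least 10% longer than the
  noun's first full syllable S1, i.e. `dur_s2 >= 1.10 * dur_s1`.

Both criteria must hold for a `TWO_AP` label; failing either yields
`ONE_AP`. We read the two criteria as jointly necessary — the pitch
rise identifies the accent and the lengthening verifies it — rather
than as alternatives; a disjunctive rule would label a merely
lengthened syllable as accented. Tokens with a disfluency or an object
naming error are excluded before classification, and the filter report
accounts for every input token.

Three numerical choices matter here:

* Ratios are computed on raw Hz and raw seconds, not semitones or
  log-durations; the criteria are defined on hertz and duration values
  directly.
* "At least 10%" is inclusive: a ratio of exactly 1.10 meets the
  criterion. Because 1.10 is not representable in binary floating
  point, the comparison carries a relative tolerance of 1e-12, so that
  decimal-entered annotations sitting exactly at the threshold
  (198 Hz vs 180 Hz) are classified as criterion-met. The tolerance is
  twelve orders of magnitude below annotation precision and cannot
  affect real measurements.
* The thresholds default to 0.10 but are arguments
  (`pitch_threshold`, `length_threshold`) to support sensitivity
  analyses.

## The phrasing score

The expected phrasing is `ONE_AP` for given nouns and `TWO_AP` for
contrastive nouns. A participant's score is the proportion of
analyzable tokens whose produced phrasing matches the expected one,
pooled across both conditions and scaled to 0–20 for comparability
with the hinting task (also a 0–20 scale). A participant with 3/9
matches under given and 6/9 under contrastive scores
20 × 9/18 = 10.

Two decisions are worth making explicit. First, the score pools tokens
across conditions rather than averaging two per-condition proportions;
with balanced conditions the two definitions coincide, and pooling is
the behaviour consistent with the 9/18 arithmetic above for unbalanced
ones. Second, although the quantity is sometimes described as a
"deviation", it is an agreement score (higher is better); we keep the
agreement direction and full fractional precision. A participant whose
tokens were all filtered out has no defined score and is omitted with
a message — an undefined score is never silently reported as 0.

## Statistical models

The phrasing outcome (coded `TWO_AP = 1`) is modelled with a binomial
logit GLMM with fixed effects for discourse condition, group, and
their interaction, and crossed random intercepts for participant and
item:

```
outcome ~ condition * group + (1 | participant) + (1 | item)
```

fitted by Laplace approximation with `lme4::glmer`. Treatment coding
uses *given* and *HC* (healthy control) as reference levels, so the
condition coefficient is the contrastive effect in the HC group and
the interaction measures how much smaller that effect is in the SZ
group. We fit with the bobyqa optimizer for both stages: on binary
crossed-random-effects data the default optimizer mix occasionally
stops on a flat ridge with an unusable Hessian, which bobyqa avoids.
Convergence is surfaced in the `converged` flag and retained optimizer
messages, never masked. A constant outcome raises a separation error
rather than returning a degenerate fit. Coding note: the convention
`TWO_AP = 1` makes a positive condition coefficient mean "more two-AP
phrasing when contrastive", which is the direction of the hypothesis;
the opposite coding simply flips all signs.

Random slopes are available (`random = "maximal"`: by-participant
condition slopes, by-item condition × group slopes) so that the
retained intercept-only structure can be justified by AIC comparison
(`compare_aic`), mirroring standard model-simplification practice.
Intercept-only is the primary structure because it is the structure
the downstream analyses interpret.

The two acoustic correlates are checked with linear mixed models on
the natural log of S2 duration and of the H f0 maximum, with the same
fixed and random structure. The log transform normalises within- and
across-speaker variability and makes unit changes a pure intercept
shift. Denominator degrees of freedom and p-values use the
Satterthwaite approximation (`lmerTest`) by default, with a Wald
normal approximation as an option; a parametric-bootstrap
likelihood-ratio p-value for a single term is available via
`lmm_pb_pvalue` (simulate from the null fit, refit both models). We do
not attempt to reproduce MCMC-sampled p-values: the Satterthwaite and
bootstrap routes are the currently standard approximations, and for
balanced designs of this size they agree closely.

Group comparisons on participant-level measures (hinting score, total
task time, speaking turns) use the pooled-variance unpaired t-test,
`df = n1 + n2 - 2`; with 10 participants per group this gives the
df = 18 tests reported for such designs. `t_test_from_summary`
computes the same test directly from printed means/SDs/ns, which is
how published group summaries can be checked without raw data; a
Welch option exists but is not the default. Spearman's rho is the
Pearson correlation of average ranks (ties get mean ranks), with the
t approximation (`df = n - 2`) for p; for n ≤ 10 without ties an
exact-null p-value is available, which matters at clinical group
sizes.

## The synthetic-data generator

The generator embodies the same model class the analysis fits — a
logistic model with crossed Gaussian random intercepts — run in the
generative direction. Defaults are the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_participants_per_group` | 10 | directors per group (HC, SZ) |
| `n_items` | 20 | critical noun-adjective pairs, condition alternating by item (10/10) |
| `true_coefficients` | −1.2384, 2.5982, 0.5948, −2.0395 | intercept, contrastive, SZ, interaction, log-odds of TWO_AP |
| `var_participant`, `var_item` | 0.7949, 0.35673 | random-intercept variances |
| `dropout_prob` | 0.1925 | disfluency/error flag rate (80.75% retention) |
| `criterion_noise` | 0 | probability of acoustics inconsistent with the latent label |

The fixed effects and variance components are the published estimates
for this design, so parameter-recovery tests have a documented truth.
Acoustic realization works backwards from the classifier: S1 duration
and L f0 are drawn from lognormals around 0.15 s and 120 Hz (plausible
medians for French full syllables and adult speakers of mixed sex; the
classifier is scale-invariant, so these bases are cosmetic), and S2/H
are obtained by multiplying by a ratio drawn uniformly from the
label's configured interval — `U[1.12, 1.40]` (duration) and
`U[1.12, 1.45]` (f0) for TWO_AP, `U[0.90, 1.08]` for ONE_AP. The
intervals deliberately straddle the 1.10 thresholds with a small
margin, so that with `criterion_noise = 0` the classifier reconstructs
every latent label exactly and the end-to-end pipeline is testable
against the latent simulation; narrowing them toward `[1.08, 1.12]`
stresses boundary behaviour. Hinting scores are drawn from a normal
centred at the group mean (17.9 HC, 14.9 SZ) shifted by
`propensity_weight` times the participant's centred phrasing-match
propensity, then rounded and clamped to [0, 20] — the weakest
mechanism that yields the monotone phrasing–ToM association the
analysis probes, with no stronger structural claim encoded.

One subtlety: with nonzero random-intercept variances the *marginal*
probability of TWO_AP in a design cell is not `plogis(eta)` but its
logit-normal average, which at the default variances (total ≈ 1.15)
attenuates, e.g., the HC-contrastive cell from ≈ 0.80 to ≈ 0.76. Our
convergence tests therefore check `plogis(eta)` only under zero
variances, and check the correct logit-normal integral under the
defaults. Conditional (subject-specific) coefficients, which are what
the GLMM estimates, are unaffected by this distinction.

What the generator does *not* emulate: waveforms or f0 contours (only
the four scalar measurements per token), dialogue dynamics and filler
items, within-participant correlation between disfluency and
condition, item-specific segmental content, and any relationship
between clinical covariates and phrasing beyond the hinting link.
Passing tests on synthetic data therefore demonstrate the pipeline's
correctness and the estimators' behaviour under the assumed model, not
the empirical claims themselves.

## Reproducibility and the pipeline

`run_pipeline` executes ingest/simulate → filter → detect → score →
fit → t-tests → correlations, writing intermediate CSVs and a
versioned JSON report. All randomness flows from a single seed in the
generator configuration, and the report's provenance embeds the fully
resolved configuration; a timestamp is included only on request so
that identical configuration + seed yields byte-identical reports.
Praat TextGrid/PitchTier ingestion parses both the long and short text
formats in UTF-8 or UTF-16, takes S1/S2 durations from interval
bounds, and evaluates f0 at L/H point times by linear interpolation
between PitchTier samples (the PitchTier's own semantics); H points up
to 50 ms beyond the S2 offset are accepted but flagged, never silently.
The command-line entry points (`simulate`, `detect`, `score`, `fit`,
`run`) are a thin wrapper over these functions in
`inst/scripts/prosocontrast.R`.

Simulation-based checks in the test suite run at design sizes chosen
to balance statistical resolution against runtime: parameter-recovery
suites use 20 replicates at 40 participants/group × 20 items,
null-calibration suites use 50 replicates at the study's own
10/group, and convergence-of-proportions checks use 400
participants/group. At these sizes the whole suite completes in well
under a minute of compute per heavy file.

## Known limitations

* The classifier consumes already-placed S1/S2/L/H annotations; it
  performs no forced alignment, f0 tracking, or octave-error
  correction, and no detection of AP left-edge cues (initial rise) or
  Intonational-Phrase boundaries.
* Laplace-approximate standard errors for binary crossed-random-effect
  GLMMs run slightly small at these sample sizes; Wald z tests are
  therefore mildly anti-conservative, which is the standard trade-off
  of this estimator.
* The phrasing score treats both conditions as equally diagnostic;
  participants with tokens in only one condition are scored on that
  condition alone, with per-condition counts reported so the pooling
  is auditable.
* The hinting link in the generator is linear-in-propensity with
  Gaussian noise; it is meant to produce a monotone association, not
  to model the cognitive mechanism.
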