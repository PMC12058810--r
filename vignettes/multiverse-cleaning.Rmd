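---
title: "Cleaning-pipeline multiverses for reading eye-movement data: models, conventions, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cleaning-pipeline multiverses for reading eye-movement data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fixverse)
```

This vignette is the package's own account of its science: what is being
modeled, which knobs matter, what the synthetic generator does and does not
establish, and where genuinely open design questions were settled. It
states no empirical result that the test suite or the acceptance script
does not itself compute.

## 1. The analysis being multiversed

The unit of analysis is the **single fixation duration** (SFD) on a target
word: the duration of the sole first-pass fixation on that word. We define
first pass operationally as the maximal run of consecutive fixations inside
the target interest area starting at the first entry into it; an SFD exists
iff that run has length exactly one. Two consequences of this definition
are deliberate: a first-pass refixation voids the SFD for that trial, and
rereading *after* the eyes have left the region does not retroactively
void it. The field uses the term without a fully operational definition;
this is the reading we fixed, and the extraction tests pin it down case by
case.

Every universe applies the same fixed stage order — fixation-level
cleaning, then trial-level filtering, then SFD extraction, then
observation-level outlier trimming, then a model — because cleaning from
the lowest level of the data upward is the only defensible order (trimming
by subject means before removing fixation artifacts would let artifacts
define the means). The multiverse varies what happens *within* each stage,
never the order.

## 2. The cleaning function

Stages 1–2 share one merge engine. A fixation shorter than `max_dur_ms` is
absorbed into a *temporally adjacent* neighbor that is *strictly longer*
and lies within `max_dist_deg` (Euclidean distance, converted through
`pixels_per_degree`). Repeatedly, the earliest such mergeable fixation is
absorbed and the scan restarts, until a fixed point is reached. Choices
the literature leaves open, fixed here and enforced by tests:

* **Adjacency.** Only the immediate temporal neighbors are merge hosts.
  Rationale: the merge exists to undo double-step corrective saccades,
  which are adjacent by nature, and adjacency makes the algorithm
  order-deterministic.
* **Tie-breaks.** If both neighbors qualify: nearer wins, then longer,
  then the preceding one. Stated so results are reproducible bit for bit.
* **Host survival.** The host keeps its position and interest area and
  gains the absorbed duration (mass conservation: stages 1–3 never change
  a trial's total fixation duration — a tested invariant).
* **Unmergeable shorts are left in place.** Their removal is the job of
  stage 4's minimum cutoff, not of the merge stages.

Stage 3 collapses every *maximal run of three or more* consecutive
fixations, each shorter than its threshold and all inside one interest
area, into a single fixation with summed duration and duration-weighted
centroid. "At least three", not "exactly three", is an interpretation; it
is documented as such rather than asserted as faithful to any vendor
implementation. Stage 4 removes fixations *strictly* below `min_dur_ms` or
*strictly* above `max_dur_ms`; 140 ms and 800 ms survive their own cutoffs.

The 14-entry `cleaning_catalog()` spans: the standard settings
(80 ms/0.5°, 40 ms/1.25°, 140 ms, 140–800 ms, outside-IA deletion off),
no cleaning, each stage off in turn, threshold variants per stage, and
outside-IA deletion on. The published table it replicates survives in the
source text only as a figure placeholder plus a handful of named variants,
so this catalog is a reconstruction of the same *kind* of variation, not a
cell-for-cell copy.

All per-trial cleaning operations are verified against independent
brute-force re-statements of the rules (naive rescanning reference
implementations in the test helpers) on a thousand randomized trials, plus
idempotence and mass-conservation checks; the find-earliest-and-restart
fixed point makes each merge stage idempotent by construction.

## 3. Preprocessing decisions

* **Trial filter.** Trials are kept when they have strictly more than
  `min_fixations` fixations; 0/3/5 are the standard levels.
* **Outlier rule.** One-shot trimming on the SFD observation table: drop
  observations with `|sfd − m| > k·s`, where `(m, s)` are the mean and
  sample SD (n−1) of the reference cell — all observations (grand), the
  subject's, or the subject-by-condition cell — computed once on untrimmed
  data. No iteration: re-estimating after removal would make the rule's
  meaning depend on convergence behavior. Cells with fewer than two
  observations or zero SD pass through. Note an arithmetic consequence the
  tests exploit: one-shot trimming can remove nothing from a cell of size
  n unless `(n−1)/√n > k`, so small cells are effectively untrimmable at
  k = 2.5.
* Trimming operates on SFD observations rather than raw fixations because
  the observation is the analysis unit; offering both would multiply the
  universe grammar without changing what the multiverse measures.

## 4. The three models

All families share the fixed-effect structure `~ condition` with treatment
coding (high-frequency reference, so β estimates low − high; positive is
the canonical frequency effect) and crossed random intercepts for subjects
and items, no slopes. Significance is the two-sided Wald test against the
normal reference at α = 0.05; degrees-of-freedom corrections
(Satterthwaite, Kenward–Roger) are out of scope and the Wald convention is
declared rather than argued. The Gamma family uses the identity link —
skewed durations modeled without transformation — and is fitted with
`lme4::glmer(nAGQ = 0)`; the contract is the estimate, SE and convergence
flag, not the optimizer. Log-scale effects are made comparable in ms at
the fixed-effect scale, `exp(α + β) − exp(α)`, ignoring the variance
correction; that simplification is stated, not hidden.

Convergence failures and singular (non-positive-definite) variance
estimates are *recorded* (`converged = FALSE`, effect undefined), never
raised, inside multiverse runs; a universe with a failed fit stays in the
curve as non-converged.

## 5. The synthetic world

`synthetic_config()` states a world; its defaults are the stated
conditions of the motivating design and are not tuned afterwards:

| parameter | default | meaning |
|---|---|---|
| `n_subjects × n_items` | 100 × 78 | design size; conditions counterbalanced 39/39 |
| `exgauss_mu_ms, sigma, tau` | 180, 35, 60 | baseline ex-Gaussian (mean 240 ms, realistic for SFDs) |
| `effect_mu_ms + effect_tau_ms` | 10 + 5 | frequency effect on the Gaussian mean and the tail; population mean effect 15 ms |
| `sd_subject_ms, sd_item_ms` | 30, 15 | crossed random-intercept SDs |
| `zipf_mean/sd`, `len_mean/sd/range` | 5.28/0.36, 3.22/0.43; 5.4/0.87, 4–9 | stimulus calibration, matched exactly (Zipf, by affine recentering) or to printed rounding (integer lengths, by lattice repair) |
| `p_skip_base` | 0.25 | skip probability of a 4-letter word, decaying with length |
| `artifact_short_rate` | 0.05 | per-trial 20–79 ms insertion beside a host (within 0.5° half the time, 0.6–3° otherwise) |
| `artifact_long_rate` | 0.02 | per-trial inflation to 801–2000 ms |
| `sparse_trial_rate` | 0.003 | per-trial truncation to 1–3 fixations; matches the ~0.1–0.3% prevalence of few-fixation trials the motivating study reports |
| `min_duration_floor_ms` | 21 | physical floor; artifact shorts are injected explicitly rather than arising from the tail, so the cleaning stages have a controllable target |
| `pixels_per_degree`, `char_width_px` | 40, 12 | display geometry; all distance thresholds are configured in degrees |

The reading model (length-dependent skipping, occasional refixations and
one-word regressions, Gaussian landing sites clamped to the word box, a
single text line) is *invented plumbing*: no generative model is published
for the source data, and this one's only obligations are (a) realistic SFD
availability (≥ 50% of trials yield an SFD under defaults, tested) and
(b) positions that interest-area assignment can resolve. Randomness is
split hierarchically from one master seed (stimuli / subject intercepts /
item intercepts / one stream per subject), so enlarging the subject pool
never reshuffles the stimuli — a tested property.

**What a green test does and does not establish.** The generator shares
the analysis model's skeleton (ex-Gaussian durations, additive crossed
intercepts, label-independent artifacts). Green parameter-recovery and
type-I tests therefore establish internal consistency of the pipeline, not
realism: real reading data have non-additive subject-item structure,
position and predictability confounds, drift and calibration error, and
artifact processes far richer than three rates. Conclusions about the
*real* study's numbers (its 1,890-universe count, its 10.54–16.57 ms
range) are inputs we check arithmetic against, not outputs we claim to
reproduce.

## 6. Multiverse mechanics and numerical conventions

* Universe enumeration is the Cartesian product of the four decision
  points in fixed nested order, with the no-trimming rule collapsed to a
  single placeholder (a "none" scope combined with a k-cutoff is
  redundant); the standard catalog yields 14 × 3 × 7 × 3 = 882 universes.
  The motivating study prints 1,890, which is not derivable from its
  stated factor levels; the engine reports what its catalog implies and
  does not force the printed count.
* Label permutation is at the **item** level, because frequency is an item
  property; trial-level shuffling would break the crossed design. The full
  pipeline is re-run per shuffled dataset. The add-one estimator
  `(1 + b)/(1 + B)` is reported alongside the quotable bound `p < 1/B`
  (flagged only when no null count reaches the empirical count).
* Pipeline stages that cannot depend on condition labels (cleaning,
  filtering, extraction) are cached across universes that share them; the
  result is provably identical to running each universe stand-alone, and a
  test cross-checks one universe against its stand-alone run.
* Observation tables are fingerprinted (md5 of a canonical serialization)
  so dataset-identity questions — which cleaning configurations produce
  literally identical analysis tables — are answerable on any input.
* Determinism: every random stage draws from a sub-seed derived by an
  integer hash of (master seed, stream key); parallel model fitting
  partitions work deterministically and reassembles in spec order, so the
  degree of parallelism cannot change a single byte of output.
* Boundary conventions: interest areas are half-open `[min, max)` (a
  fixation on a shared edge belongs to the right-hand word); all indices
  are 1-based; missing interest area is an empty field, never 0.

## 7. Known limitations

* **The permutation bar is reachable in small multiverses.** With few
  items and a handful of near-perfectly correlated universes, a single
  item-label permutation occasionally produces a significance sweep across
  *all* universes, in which case the empirical count cannot strictly exceed
  every null count. This is a property of the statistic, not a bug; the
  package reports the add-one p either way. The scaled acceptance world
  (36 universes, 40 items, B = 50) hits exactly this at its fixed seeds —
  one sweep in 50 shuffles — and the corresponding acceptance assertion is
  deliberately left failing with the analysis recorded in the project
  notes, rather than reseeded away.
* **Gamma-vs-identity coefficient ordering is not reproduced.** The
  motivating study observed log < gamma < identity coefficient magnitudes.
  In this generator the log model's raw coefficient is reliably the
  smallest, but with an identity link the Gamma GLMM and the identity LMM
  estimate the same conditional-mean contrast, and their ordering here is
  sampling noise (measured fraction gamma < identity ≈ 0.45–0.58 across
  seed blocks). The published ordering is evidently a feature of that
  study's real error structure; the test suite asserts only the robust
  part.
* Wald/normal inference with ~40–78 items is mildly anti-conservative
  (t-reference with ~n_items df would be exact-er); the type-I acceptance
  band absorbs this at the tested sizes.
* No saccade parsing, binocular data, multi-line layouts, alternative
  dependent variables (first fixation, gaze duration, total time), random
  slopes, or Bayesian fits — all deliberately out of scope.
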