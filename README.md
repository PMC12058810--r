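# fixverse

Multiverse analysis of fixation-cleaning and modeling pipelines for
sentence-reading eye-movement data.

## The problem

Before a reading researcher can estimate an effect such as the **word
frequency effect** (shorter fixations on high- than low-frequency words),
the raw fixation report passes through a chain of discretionary cleaning
decisions: merging very short fixations into nearby longer ones, temporal
cutoffs, dropping sparse trials, SD-based outlier trimming, and a choice of
mixed-model family. Each choice is individually defensible; jointly they
define a *garden of forking paths*. `fixverse` makes that garden an object
of study: it enumerates every combination (each one a **universe**), runs
the full pipeline per universe, assembles the **specification curve** and
decision dashboard, and judges the multiverse with a label-permutation
test.

It is aimed at reading/eye-movement researchers who want to audit the
robustness of an effect across cleaning pipelines, and at methodologists
who need a tested, deterministic implementation of the pieces.

## What is implemented

**Four-stage cleaning function** (every threshold a parameter, 14-entry
catalog):

1. merge fixations `< 80 ms` into a strictly longer adjacent fixation
   within `0.5°`;
2. same, `< 40 ms` within `1.25°`;
3. collapse runs of `≥ 3` consecutive fixations `< 140 ms` in one interest
   area;
4. remove fixations `< 140 ms` or `> 800 ms`; plus an optional deletion of
   fixations outside all interest areas.

**Preprocessing:** trial filters (`> 0 / > 3 / > 5` fixations), **single
fixation duration** (SFD) extraction (the sole first-pass fixation on the
target word), and one-shot outlier trimming at `k ∈ {2.5, 3}` SDs from the
grand, per-subject, or per-subject-by-condition mean.

**Models:** crossed random-intercept mixed models
`sfd ~ condition + (1|subject) + (1|item)` on the raw scale, the natural-log
scale, and as a Gamma GLMM with identity link (all via `lme4`); the
frequency coefficient `β` estimates low − high, and log-scale effects are
back-transformed as `exp(α + β) − exp(α)` ms.

**Multiverse inference:** the empirical count of significant universes is
compared with the counts from `B` item-label permutations; reported as the
add-one p-value `(1 + #{null ≥ empirical}) / (1 + B)` and the paper-style
bound `p < 1/B` when no null count reaches the empirical one.

**Synthetic data:** a generator emulating the motivating study's design —
100 subjects × 78 single-line sentences, one high- or low-frequency target
word per sentence (Zipf M 5.28/3.22, SD 0.36/0.43; lengths 4–9, M 5.4,
SD 0.87), ex-Gaussian durations (`mean = μ + τ`) with subject/item random
intercepts, a frequency effect loading on both `μ` and the tail `τ`, and
injectable artifacts (20–79 ms spurious fixations near/far from a host,
801–2000 ms inflations, 1–3-fixation sparse trials).

## Worked example

```r
library(fixverse)

ts <- generate_dataset(synthetic_config(n_subjects = 100, n_items = 78, seed = 7))
ts
#> <trialset> 75085 fixations, 7800 trials, 100 subjects, 78 items

r <- apply_cleaning(ts, cleaning_catalog()$standard)
r$stats
#> <cleaning_stats> standard: 75085 -> 69418 fixations (s1 305, s2 34, s3 0 merged; s4 5328, outside 0 removed)

obs <- extract_sfd(filter_trials(r$trialset, 3))
fit_model(obs, model_spec("lmm_identity"))
#> <model_result> lmm_identity: beta = 10.515 (SE 3.026), z = 3.48, p = 0.0005103, effect = 10.51 ms, converged = TRUE
```

The generator's true effect is 10 ms on `μ` plus 5 ms on `τ` (15 ms in
population mean); the standard pipeline reports 10.5 ms because stage-4
cutoffs and trimming eat into the tail, where a third of the effect lives —
precisely the pipeline-dependence the package exists to expose. A small
multiverse over 2 cleaning configurations × 2 trial filters × 2 outlier
rules × 2 model families:

```r
specs <- enumerate_universes(list(
  cleaning = cleaning_catalog()[c("no_cleaning", "standard")],
  min_fixations = c(0L, 3L),
  outliers = list(outlier_rule("none"), outlier_rule("subject", 2.5)),
  models = c("lmm_identity", "lmm_log")))
mv <- run_multiverse(ts, specs)
mv
#> <multiverse_result> 16 universes: 16 significant, 0 non-converged

specification_curve_table(mv)[c(1, 16), .(rank, universe_id, effect_ms, class)]
#>     rank                      universe_id effect_ms       class
#> 1:     1 standard|f0|subject_k2.5|lmm_log  8.793794 significant
#> 2:    16  no_cleaning|f0|none|lmm_identity 12.802265 significant

permutation_test(ts, specs, n_perm = 20, seed = 11)
#> <permutation_result> empirical = 16 significant; add-one p = 0.04762 (paper-style bound: p < 0.05)
```

Reading the numbers: the frequency effect survives every pipeline (16/16
significant) but its size spans 8.8–12.8 ms — the heaviest-trimming
universes report the smallest effects. No label permutation matched the
empirical count, so the multiverse-level add-one p is 1/21 and the
paper-style bound `p < 1/B` applies.

## File formats

Fixation report (TSV, tab-separated, `.` decimals, missing `ia_index` is an
empty field; EyeLink Data Viewer column aliases such as
`CURRENT_FIX_DURATION` are accepted on read):

```
subject_id  trial_id  item_id  condition  fix_index  x_px    y_px    duration_ms  ia_index
1           100001    1        low        1          116.08  307.47  121.457      1
1           100001    1        low        2          254.52  291.66  167.737      3
1           100001    1        low        3          352.08  294.72  221.485      5
1           100001    1        low        4          425.85  302.98  224.383      6
1           100001    1        low        5          417.93  300.60  264.908      6
```

Interest-area table (TSV, half-open pixel bounds `[min, max)`, origin
top-left): `item_id  ia_index  x_min_px  x_max_px  y_min_px  y_max_px`.
Item table: `item_id  condition  target_ia_index  [target_len  zipf_target  n_words]`.

## Command line

```sh
inst/cli/fixverse simulate   --config cfg.json --seed 7 --out run/
inst/cli/fixverse clean      --in run/fixations.tsv --ia run/ias.tsv \
                             --cleaning-id standard --out cleaned.tsv --stats stats.json
inst/cli/fixverse multiverse --config cfg.json --in run/fixations.tsv \
                             --ia run/ias.tsv --targets run/items.tsv --out results/
inst/cli/fixverse permute    --config cfg.json --in run/fixations.tsv \
                             --ia run/ias.tsv --targets run/items.tsv \
                             --seed 11 --out permutation.json
```

The run configuration is a single JSON file with sections `synthetic`,
`cleaning`, `min_fixations`, `outliers`, `models`, `permutation`.

## Further reading

The methods vignette (`vignettes/multiverse-cleaning.Rmd`) documents the
model and its assumptions, every tunable parameter with units and defaults,
what the synthetic generator does and does not emulate, numerical
conventions (tie-breaks, boundary handling, degenerate cells), and known
limitations.
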