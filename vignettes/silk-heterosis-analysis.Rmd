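---
title: "Methods: heterotic pattern analysis of 2-DE spot intensities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heterotic pattern analysis of 2-DE spot intensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silkhet)
```

## The problem

In maize breeding, the length of time a silk (the stigma/style of the
pistil) stays receptive to pollen determines the seed setting rate after
delayed pollination, and hybrids routinely keep viable silks for longer
than their inbred parents — a textbook case of heterosis. Proteomic
studies of this phenomenon quantify proteins as spots on two-dimensional
electrophoresis (2-DE) gels, with three biological replicates per
genotype and developmental stage, and then ask two questions:

1. Which protein spots change during silk development within a line
   (time-course screen)?
2. How does each spot's abundance in an F1 hybrid relate to its two
   parents (heterosis screen), and in particular does it sit at the
   mid-parent value (additive) or not (non-additive)?

`silkhet` implements the complete numerical pipeline for these questions:
normalization, differential screening, heterotic pattern classification,
the mid-parent heterosis statistic, and Fisher LSD letter groupings for
the seed-setting phenotype — together with a synthetic-data generator so
every stage can be validated against known truth.

## Data model

All tables are long (tidy): one row per (spot, genotype, stage,
replicate) observation. Wide replicate-by-stage matrices are derived
views, never the canonical store, because the long form makes replicate
handling unambiguous. Stage order is always declared (in a
`triad_design()` or as a `stages` argument) and never inferred from the
labels — "D10" sorts before "D6" lexically, which would silently reorder
a time course. A replicate missing from a (genotype, stage) cell makes
the spot ineligible for any test at that cell; nothing is imputed,
because densitometry gives no principled fill-in value. One intensity per
biological replicate is expected; if technical replicates exist upstream,
averaging them is the caller's responsibility.

## Normalization

`normalize_total_ppm()` implements total-quantity normalization: each
spot's intensity is expressed as parts per million of the summed
intensity of all valid spots on its gel (one gel per genotype ×
stage × replicate). This removes gel-to-gel loading and staining
differences exactly — multiplying one gel's raw intensities by any
constant leaves its normalized values unchanged — and each gel sums to
`ppm_scale` (default $10^6$) to within $10^{-9}$ relative tolerance.

The method's assumption is worth stating: it treats the *total* spot
volume as comparable across gels, which holds when differentially
accumulated spots are a small, roughly balanced fraction of all valid
spots (the usual 2-DE regime, hundreds of spots of which a few dozen
change). A dataset in which most spots are planted high in one genotype
violates this assumption and the normalization would then shift that
genotype's values down globally. This matters for how the synthetic
recovery tests are constructed (see below). Normalization happens before
the same-trend screen; the screen compares signs of changes, which
normalization does not flip when its assumption holds.

## Differential screening

The inbred time-course screen (`select_inbred_differential()`) retains a
spot only if all three conditions hold:

* **Same-trend rule**: the sign (up / down / flat) of the change between
  every pair of consecutive stages is identical in all biological
  replicates. "Flat" means $|\Delta| \le \varepsilon \cdot
  \overline{xy}$ with $\varepsilon$ = `trend_epsilon` (default 0.02).
  The flatness tolerance is ours: without it, replicate noise of any
  size would flip signs on truly flat spots and the rule would reject
  almost everything; 2% is small relative to the 5%-CV replicate noise
  scale and is exposed in `analysis_config()`.
* **One-way ANOVA** of replicate intensities across stages at
  $p < \alpha$ (default 0.05). All replicate values enter (so
  $\mathrm{df}_\text{within} = N - k$); collapsing to stage means first
  would discard the only variance estimate available at $n = 3$.
* **Maximum fold change** of the stage means strictly greater than
  `fc_inbred` (default 1.5). Fold change is
  $\max(\bar x_j)/\min(\bar x_j)$ over group means, and the inequality
  is strict ("more than 1.5-fold").

The triad screen (`select_triad_differential()`) compares the F1 and its
two parents at one stage with the same ANOVA and a strict 2-fold
(`fc_triad`) criterion; the same-trend rule belongs to the time-course
design only. No multiple-testing correction is applied across spots —
the screen reproduces the source procedure's raw $p < 0.05$ rule, which
is a known statistical limitation of that procedure, not an oversight
(with 2000 null spots, about 100 will pass the ANOVA by chance; the fold
filter removes most of these at low CV).

## Heterotic pattern classification

For each spot, `classify_pattern()` compares the F1 replicates against
three references derived from the parents: the mid-parent (MP), the high
parent (HP, larger parental mean) and the low parent (LP). The MP
comparison needs a replicate-level sample, so the parents' replicates
are paired by index and averaged into *mid-parent pseudovalues*
$(p_{1i}+p_{2i})/2$ — a two-sample t-test of F1 against these preserves
a variance estimate on both sides, rather than testing against a single
fixed number. Welch's unequal-variance t is the default (robust at
$n = 3$; switchable to pooled t via `analysis_config(welch = FALSE)`).

The decision tree, evaluated in order:

| step | condition | pattern |
|------|-----------|---------|
| 1 | $p_{MP} \ge \alpha$ | `A` (additive) |
| 2 | $p_{HP} < \alpha$ and $\bar F_1 > HP$ | `++` (over-dominant) |
| 3 | $p_{LP} < \alpha$ and $\bar F_1 < LP$ | `--` (under-dominant) |
| 4 | $p_{HP} \ge \alpha$ | `+` (high-parent-like) |
| 5 | $p_{LP} \ge \alpha$ | `-` (low-parent-like) |
| 6 | otherwise | `+-` (partially dominant, between the parents) |

Checking `++`/`--` before `+`/`-` makes beyond-parent calls unambiguous
when F1 differs from both MP and HP in the same direction. If the two
parental means coincide exactly, "between the parents" is empty, and any
significant deviation is called `++` above or `--` below the common
value. Ties are impossible by construction — the first matching step
wins — so classification is deterministic, exhaustive and exclusive:
every non-degenerate triad receives exactly one of the six labels.
Degenerate inputs (zero variance on both sides of a comparison) are an
error rather than a silent call.

`mph_percent()` computes the mid-parent heterosis degree
$100(\bar F_1 - MP)/MP$; full precision is kept and reports round to one
decimal. `tally_patterns()` does the bookkeeping (counts, additive vs
non-additive split, shares of total and of the non-additive subset) with
raw fractions retained next to the integer-rounded percentages used in
published tallies.

## Phenotype statistics

Seed setting rate is `filled_seeds / total_spikelets` per replicate,
analyzed on the raw proportion scale (no arcsine transform — a
documented simplification; rates here sit mostly far from 0/1 where the
transform matters least). `stage_course_anova()` tests stage differences
per genotype; `lsd_letters()` computes Fisher's least significant
difference
$\mathrm{LSD}_{ij} = t_{1-\alpha/2,\,\mathrm{df}} \sqrt{\mathrm{MSE}
(1/n_i + 1/n_j)}$
and assigns compact letters by a descending-mean sweep: start a new
letter at the largest unlettered mean, extend it to every mean within
LSD of that anchor, repeat. With per-pair $n_i, n_j$ this generalizes to
unbalanced designs. The sweep is verified in the tests against an
exhaustive pairwise-t oracle (the two are algebraically equivalent
decisions at the same $\alpha$).

## Synthetic data

`generate_triads()` plants each heterotic class at a canonical effect
placement (parents at 100 and 300 ppm-scale units, a 3-fold separation):
`A` at MP, `+` at HP, `-` at LP, `++` at $1.6 \times$ HP, `--` at
$0.6 \times$ LP, `+-` midway between MP and HP, and `null` spots with
all three genotypes equal. The beyond-parent offsets (±60%) and the 3×
parental separation are our choices — no canonical effect sizes exist
for 2-DE — picked to be comfortably detectable at $n = 3$ and 5% CV and
exposed in `synthetic_spec()`. Replicate noise is multiplicative
log-normal, because densitometry is positive and right-skewed: we use
the exact log-normal relation $\sigma_{\log} = \sqrt{\ln(1 + cv^2)}$
with the mean-correcting $\mu_{\log} = \ln m - \sigma_{\log}^2/2$, so
the arithmetic mean and CV of the draws equal the planted values (this
makes the 1%-tolerance moment checks in the tests exact rather than
approximate). The default 5% CV is a stand-in — real 2-DE replicate CVs
for this design were not reported — and is config-exposed.
`generate_stage_course()` plants monotone geometric time courses
(default 3-fold end-to-end over four stages) among flat spots, and
`generate_seedset()` draws filled seeds per ear from a binomial
(10 ears × 150 mid-base spikelets per replicate by default) and
aggregates per replicate. Every generator is deterministic given the
spec's seed.

What the generator does *not* emulate: spot overlap and mis-matching,
missing-spot dropout, gel warping, and — deliberately — the mostly-null
composition of real gels when asked for pure class mixes. That last
point drives a testing decision: a table in which *every* spot is
differential breaks the total-quantity normalization assumption (F1 gel
totals then differ systematically from parent gel totals, shifting all
F1 values by ~15%), so the per-class recovery checks (200 spots/class,
5% CV, $n = 3$; observed recovery ≥ 94% for `A`, `+`, `-`, `++`, `--`)
apply the classifier to the generator's intensities, which are already
on a common per-gel scale. The full
generate → normalize → classify pipeline is validated separately in the
regime the normalization is designed for: gels dominated by null spots,
with random per-gel loading factors planted and removed by
normalization. Passing these tests therefore shows the statistics are
correct under the stated noise model; it does not certify performance on
real gels with matching artifacts. `+-` recovery is intrinsically lower
(~70–80%) because it requires three simultaneous rejections at $n = 3$;
no acceptance bound is placed on it.

## Problem sizes and determinism

The shipped tests run the classifier on 1200 triads (200 per class), the
type-I check on 2000 null triads (observed false-positive rate within
three binomial standard errors of 0.05), and oracle comparisons on dozens
of small random instances; the whole suite takes well under a minute. All
stochastic tests fix seeds via `synthetic_spec(seed = )` or `set.seed()`;
identical config + seed gives byte-identical outputs end to end, which
the CLI tests assert literally on files.

## Known limitations

* Raw per-replicate intensities behind the published tables of the
  motivating study design are not public, so numeric end-to-end checks
  use printed group means and the transcribed pattern table; everything
  replicate-level is validated on synthetic truth.
* No multiple-testing correction (by design, see above).
* Proportions analyzed untransformed; LSD letters inherit the usual
  caveats of unprotected pairwise comparisons.
* The `Y/N` presence flag in triad reports is derived from the
  three-group ANOVA at $\alpha$; the numeric fold is always reported
  alongside it, since no published rule separates printed folds from
  flags.
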