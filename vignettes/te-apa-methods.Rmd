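---
title: "Methods: from TE insertion to polyadenylation choice and phenotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from TE insertion to polyadenylation choice and phenotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apaTE)
```

`apaTE` chains five analysis stages around one biological scenario: a short
transposable element (TE) inserted between a gene's distal polyadenylation
signal (PAS) and the corresponding cleavage site (CS). This vignette is the
package's account of the models behind each stage, the parameters that
matter, what the synthetic-data generators do and do not emulate, and the
design decisions taken where more than one convention was defensible.

## The locus model

Coordinates are 1-based and inclusive throughout, the GFF3 convention, and
overlap is the size of the inclusive intersection. A cleavage site is stored
as the *last transcribed base*; cleavage occurs immediately 3′ of it. A
3′UTR is counted from the first base after the stop codon through the CS,
inclusive, in the sense strand of the gene.

A TE insertion is parameterised as (`after_base`, `length`, `tsd_length`):
the element lands between `after_base` and `after_base + 1`, and
`tsd_length` bases immediately 5′ of that point are duplicated on the 3′
side (target-site duplication, TSD). Coordinates beyond the insertion point
therefore shift by `length + tsd_length`; `apply_insertion` performs the
lift and `delete_insertion` inverts it exactly. For the packaged locus a
186-bp element with a 2-bp TSD explains the observed 188-bp difference in
antisense-transcript length.

The PAS–TE–CS distances reported by `insertion_context` are
`after_base − pas_end` (bases strictly between the PAS 3′ end and the
element) and `cs − after_base`, the latter measured so that on the with-TE
frame it equals the gap between the element's 3′ end (including the
duplicated target site) and the shifted CS. On the packaged locus these are
7 and 12 bp.

**The packaged fixture.** The published structural quantities for this
locus are mutually inconsistent by 1 bp under any single coordinate
convention: the 110/221-bp 3′UTRs imply an inter-CS distance of 111 bp
while the 28/140-bp antisense overlaps imply 112 bp, and a 186-bp element
produces a 188-bp length difference only with a duplication the original
description does not state. The fixture therefore declares coordinates per
genotype (the with-TE annotation is written out, not derived by the lift),
so that each printed value is reproduced exactly; the package deliberately
does not "correct" any of them. The simulator, by contrast, derives its
with-TE genotype via `apply_insertion`, which is self-consistent (and gives
a 29-bp overlap).

## PAS/DSE scanning

Scoring follows the classical position-specific scoring matrix: per
position, `score = log2((f + c) / (0.25 + c))` against an equiprobable
background, with pseudocount `c = 0.01` by default. The log base and
pseudocount only rescale scores; every rank-based decision (best hit,
weak/strong ordering) is invariant to them, which is why neither needed to
be fixed by the data. A window's score is the sum over positions; `N`
contributes zero.

Hexamer windows slide over the 50 bp upstream of the CS and 7-mer windows
over the 50 bp downstream. The annotated PAS is the highest-scoring hexamer
whose *entire window* lies within offsets −26..−12 (so window starts in
−26..−17); the DSE likewise within +1..+25. Whole-motif containment is the
strictest reading of "located between"; `containment = "start"` relaxes it
to start-in-region. Ties go to the window whose centre is closest to the
region centre, then to the most upstream — a deterministic rule, needed
because composition-insensitive matrices (like the default DSE model)
score permutations identically. Minus-strand genes are reverse-complemented
before scanning and offsets are always reported in transcript sense.

The package ships documented default matrices — an AATAAA-dominant hexamer
model admitting the ATTAAA variant, and a uniform GU/U-rich 7-mer — because
the empirical *D. melanogaster* matrices used in the original analysis are
not reprinted anywhere we can ship from. Any user matrix can be supplied as
TSV (`read_frequency_matrix`). All package tests use either the defaults or
spec-level toy matrices; none depends on the exact default frequencies,
only on consensus dominance.

`predict_insertion_effect` reports two loss rules separately, and never
collapses them, because the biology genuinely distinguishes them: a PAS
physically separated from its CS (`insertion_separates_pas_cs`, triggered
when the element sits between the PAS 3′ end and the CS and stretches their
distance beyond `max_pas_cs_span`), and an insertion landing inside the DSE
region itself (`insertion_disrupts_dse`, +1..+25 of the CS). The original
description invokes a disrupted DSE for an element inserted *upstream* of
the CS — where DSEs do not live — so the package keeps both calls visible
rather than guessing which mechanism was meant. `max_pas_cs_span` defaults
to 40 bp: functional PAS-CS spacing is ~10–30 bp, the intact fixture
geometry is 19 bp, and the with-TE geometry is ~207 bp, so any threshold
between those reproduces the usage call; 40 bp sits near published upper
bounds for functional spacing.

## qPCR quantification

Standard-curve (absolute) quantification, not ΔΔCq: each amplicon's
dilution series is fit by OLS, `Cq = intercept + slope · log10(copies)`,
efficiency `10^(−1/slope) − 1`, and unknowns are inverted through their own
curve, so differing primer efficiencies are handled per amplicon.
Normalisation divides by the reference-gene copy number of the same sample.
The long-isoform amplicon counts only long transcripts; the total amplicon
counts both; `copies_short = total − long`, clipped at zero with a warning
when noise puts `long > total` (which genuinely happens when the long
isoform is barely detectable).

Fold change is the ratio of genotype means of normalised totals
(`ratio_of_means`); whether published "~2.6-fold" style values are ratios
of means or means of ratios is rarely stated, so the alternative is a
config switch, not a silent default. Significance is a two-sided Welch t
test on replicate values. Zero-variance input (exactly what noise-free
synthetic data produces) returns `p = NA` with a `degenerate` flag instead
of erroring, so the deterministic recovery runs can flow through the same
code path as real data.

## Enzymology

Initial rates are OLS slopes of A340 against time, in mOD·min⁻¹, divided
by protein mass (mg). A trace must have at least 4 points and pass an
R² > 0.98 linearity gate (configurable) to enter the kinetics fit — the
gate value mirrors standard initial-rate practice. The Michaelis–Menten fit
minimises squared error with a Levenberg–Marquardt optimiser seeded by a
Lineweaver–Burk regression and falls back to a small multistart grid; the
reciprocal seed alone is notoriously noise-sensitive, which is why it is
only ever a starting point. Confidence intervals are asymptotic
(linearisation) intervals, `estimate ± t(df) · SE` — the convention of
mainstream curve-fitting tools — with profile intervals deliberately out of
scope. Km is fixed at 0.1 mM in all simulation defaults: the source
analysis reports only Vmax, and 0.1 mM sits mid-range of the assayed
substrate series (0.01, 0.05, 0.1, 0.5, 1 mM), so the design brackets it
from both sides.

The replicates lack-of-fit test partitions residual error into pure error
(within replicated concentrations) and lack of fit:
`F = (SS_lof/df_lof) / (SS_pe/df_pe)` with `df_lof = m − 2` for `m`
concentrations. Replicates are pooled into the fit (not averaged first);
fitting replicate means instead is possible upstream but pooling is the
default since the test needs the within-concentration scatter. A fit whose
curve passes through every replicate mean returns `F = 0, p = 1`; with no
replication the test is reported as unavailable rather than fabricating a
denominator.

## Survival statistics

Acute assays: replicate counts are pooled into a single 2×2 table per
sex × condition (a published per-sex odds ratio with one CI implies
pooling); a Mantel–Haenszel stratified variant is provided for
heterogeneous replicates. The odds ratio uses the Haldane–Anscombe 0.5
correction only when a zero cell occurs (flagged), and the Woolf log-scale
interval — standard practice, since the original analyses do not name
their CI method. Proportion tests on per-replicate survival fractions are
Welch t or exact Mann–Whitney; raw proportions are the default and an
arcsine transform is left to the caller.

Chronic assays: interval death counts are expanded to individual event
times; survivors are administratively censored at the final observation.
Curves are product-limit estimates and the two-group comparison is the
one-degree-of-freedom log-rank test (`survival::survfit`/`survdiff` under
the package surface; hand-computed O−E/V tables serve as test oracles).
Published odds ratios attached to chronic curves rarely state their census
time, so `compare_survival` defaults to the last common observation time
and records that choice in its output. No mortality correction (e.g.
Abbott) is applied: raw survival is analysed in both arms.

## Synthetic data

Each generator draws from its own stream derived from the master seed
(`stage_seed`), so stages can be regenerated independently and identical
config + seed gives byte-identical files. Defaults are the study
conditions: 3 biological qPCR replicates with a 70% long-isoform fraction
(without TE), barely detectable (0.5%) with TE, folds 2.6 (male)/2.3
(female), 95% efficiencies; kinetics at the five assay concentrations × 3
replicates with Vmax 44.73/24.06 mOD·min⁻¹·mg⁻¹; acute designs of 9 × 50
flies per group; chronic designs of 20 × 20 with twice-daily observations
for a week, exponential times with a 60-h median and hazard ratio 0.7.
Noise models are the minimal standard choices — Gaussian on Cq and on
velocities, binomial deaths, exponential (optionally Weibull) death times —
because the original data carry no stated noise model. The hazard-ratio
parameter scales the exponential rate; under a Weibull shape ≠ 1 it scales
the rate, not the proportional hazard.

What the simulations do *not* emulate: PCR inhibition or melt-curve
artefacts, non-linear early/late phases of absorbance traces, overdispersed
or correlated deaths within vials, background sequence composition bias,
and chromatin or expression context of the TE. Passing the recovery tests
therefore shows the estimators are correct and calibrated under their
stated models, not that real assays meet those models.

## Test design and problem sizes

The suite verifies closed-form examples (frozen from independent hand
computations), property-style invariants under fixed seeds (brute-force
best-hit and per-base overlap oracles, permutation and rank-enumeration
oracles for the tests, algebraic inverses), and statistical calibration:
log-rank type-I error and lack-of-fit p-value uniformity over 500 null
simulations each, Vmax CI coverage over 200 noisy designs, Hill-model
power over 100 designs, and noise-free end-to-end recovery of every
generating parameter to ≤1e−6 relative error. These sizes give the
calibration checks enough resolution (binomial SE ~1% at 500 draws) while
keeping the whole suite around a minute on one CPU.

## Known limitations

- The locus model handles a single, non-nested insertion per application;
  splice-graph effects are out of scope (the modelled effect is purely
  3′-terminal).
- The PAS model is a PSSM, not a machine-learned polyA-site predictor, and
  cleavage sites come from annotation (as from 3′RACE), never de novo.
- Only one reference gene is supported for normalisation.
- Asymptotic Vmax/Km intervals can undercover for strongly curved designs;
  the coverage test pins the default design, not arbitrary ones.
- Wet-lab-derived statistics (published odds ratios, p-values, expression
  means) are not recomputable without the underlying counts, which were
  never deposited; the package reproduces the computable structural and
  parameter-recovery quantities instead.
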