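---
title: "Models and methods in raredex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in raredex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

raredex re-implements, as a tested and reusable pipeline, the analysis of a
dye-swapped two-colour cDNA microarray experiment, its qRT-PCR validation
arm, and an in-silico search for retinoic acid response elements (RAREs) in
aligned promoter regions.  This vignette explains the models and the design
choices, in particular where the underlying procedure was under-specified
and the package had to fix a convention.

## 1. Two-colour preprocessing

### Quality control

A spot is excluded for exactly one reason, assigned in priority order:

1. **flag** — its flag code is in `bad_flag_codes` (default: the negative
   GenePix-style codes);
2. **saturation** — either channel's foreground median sits at the scanner
   ceiling `saturation_level` (default 65535, the 16-bit maximum);
3. **signal-to-background** — either channel's foreground/background ratio
   is *strictly* below `sb_min` (default 1.5); a ratio of exactly 1.5 is
   kept, and a zero background with positive foreground counts as infinite
   S/B.

Applying the S/B rule per channel with "either fails ⇒ exclude" is the
conservative, dye-symmetric reading of a one-number filter.  Filtering is
monotone in `sb_min`: loosening the threshold can only retain more spots
(property-tested).

### The background-subtraction decision

Whether local spot background should be subtracted from the foreground is a
long-standing judgement call: subtraction removes additive offsets but can
inflate variance when background is mere scanner noise.  The package
follows the correlation heuristic: per channel, it computes the Pearson
correlation of log2 foreground vs log2 background over retained spots and
subtracts only when r ≥ `bg_correlation_threshold` (default 0.5).  The
statistic, direction and threshold are all configurable because the source
procedure names the idea but none of the three numbers; every decision is
logged in the provenance record.  An undefined correlation (constant
background) means no subtraction.  The decision is taken per slide and per
channel — the least-aggregated defensible unit.

A consequence worth knowing: when an additive background is present but
*not* subtracted (the independent-background branch), log-ratios are
compressed toward zero at low intensity, because
`log2((t1+b)/(t2+b)) < log2(t1/t2)` for `b > 0`.  The tests document this
attenuation explicitly rather than hiding it; with background around 10% of
median signal the recovered effect of a planted 2× change is roughly 0.87
of its true log2 value, while the subtract branch recovers it without bias.

### M, A, lowess

Per retained spot, with background-handled signals floored at 1 count
(floored spots are annotated, not dropped — this keeps logs finite without
discarding data):

* `M = log2(signal_treated / signal_control)` — the treated condition is
  always the numerator, resolved from the slide's dye orientation in the
  design table, never from the dye itself;
* `A = ½·log2(signal_635 · signal_532)`.

The intensity-dependent dye bias is removed per slide by robust lowess
(`stats::lowess`, 3 robustifying iterations) with smoother span 2/3, the
span used by the original pipeline: `M ← M − fit(A)`.  Lowess is fitted
globally per slide; print-tip groups are out of scope.  Note that a span
this wide under-fits strong curvature: the residual median scales with the
bias curve's second derivative, and stays within ±0.02 for realistic
amplitudes (≲ 0.4 log2 units across the intensity range).  Steeper bias
needs a smaller `lowess_span`, which is exposed.

### Dye-swap combination and the replicate unit

Within a replicate pair, duplicate spots of a gene are collapsed by median
per slide (robust to a single bad spot), and `dye_swap_combine()` averages
the two sign-resolved slide values.  Because an additive log-scale dye bias
enters the forward slide's M as `+d` and the swapped slide's sign-resolved
M as `−d`, the average is exactly bias-free — even for gene-specific bias —
which is verified to machine precision on noiseless simulations.

For *inference*, however, `normalize_experiment()` defaults to
`replicate_unit = "slide"`: each lowess-corrected, sign-resolved slide is
one observation, so k dye-swap pairs give n = 2k replicates.  The
alternative, one pair-averaged value per pair (`replicate_unit = "pair"`),
is also implemented.  The default was chosen after a power analysis: with
the study-scale design of 3 pairs, a one-sample t-test on pair means has
only 2 degrees of freedom, and after Benjamini–Hochberg control at
q < 0.05 over 1000 genes its sensitivity for a 2-fold change at realistic
spot noise collapses to a few percent — the heavy t tails at df = 2 put a
floor on attainable p-values.  Slide-level replication (df = 5) restores
sensitivity above 90% at the same familywise guarantees.  The
intensity-dependent dye bias is already removed per slide by lowess, and
dye-swap balance keeps the *mean* across slides free of any residual
additive bias, so slide-level observations are unbiased; what the pair unit
additionally cancels — exactly — is gene-specific dye bias, which is why
the pair route remains available and the combination algebra is tested in
its own right.

## 2. Per-gene inference and selection

Per gene, a two-sided one-sample t-test of the replicate M values against
0 (df = n−1).  Genes with fewer than `min_replicates` (default 2)
observations, or zero sample variance, get `NA` statistics and can never be
selected — a constant M across replicates is evidence of nothing but
degeneracy.  Benjamini–Hochberg adjustment is implemented directly from the
step-up definition (`q_(i) = min_{j≥i} p_(j)·m/j`, capped at 1, NA
pass-through) and is exhaustively checked against a literal-definition
oracle and `stats::p.adjust`.

Fold changes are reported on the signed scale: `FC = 2^mean(M)` and
`FC* = −1/FC` when `FC < 1`, so a halving is −2.0 and `|FC| ≥ 1` always.
`FC` is computed from the mean of per-replicate M (consistent with
log-scale normalization), not the mean of raw ratios.  Selection takes
`|FC| ≥ fc_min` (default 1.5, boundary inclusive) and *optionally*
`q ≤ q_max`: the original selection's use of a significance cut alongside
the fold-change cut is ambiguous, so significance is opt-in, with q
reported for every gene either way.

Cross-comparison intersection classifies common selected genes as
concordant or discordant by the sign agreement of their two signed fold
changes.  Category summaries report percentages against the full input
list, with unannotated genes pooled as "unknown", so percentages total 100.

## 3. ΔΔCt quantification

Per (group, gene): `ΔCt = mean(Ct_target) − mean(Ct_reference)`,
`ΔΔCt = ΔCt − ΔCt_calibrator`, `rq = 2^−ΔΔCt`.  The calibrator group has
`rq = 1` exactly.  Dispersion is taken over per-replicate ΔCt values —
the level at which replication actually happened — and the SEM is mapped
through the exponential at the point estimate
(`sem = rq · ln2 · sd(ΔCt)/√n`).  Group tests (one-way ANOVA, pairwise
t-tests; pooled variance by default so the two-group ANOVA and t-test
agree) run on per-replicate ΔCt.  `rq` is also reported in the microarray
signed-FC convention for side-by-side comparison.  Invariances verified by
tests: a constant shift of every Ct leaves all `rq` unchanged;
`rq(ΔΔCt)·rq(−ΔΔCt) = 1`; noiseless generator round-trips are exact.
Amplification-efficiency correction (Pfaffl) is out of scope.

## 4. RARE scanning

The half-site consensus is `PuG(G/T)TCA` = IUPAC `RGKTCA`; `N` in a
sequence never matches and counts as a mismatch.  Direct repeats are pairs
of same-strand half-site matches separated by a spacer in `{1, 2, 5}`
(DR1/DR2/DR5, the classical RAR/RXR geometries); both the spacer set and a
per-half-site mismatch budget are parameters, so e.g. DR3-like elements are
reachable by configuration rather than special-casing.  Minus-strand
geometry is evaluated on the reverse complement and mapped back.
Overlapping qualifying pairs each count (a chained triple repeat is two
hits); there is no greedy de-duplication.  The scanner is validated by
exact set equality against brute-force enumeration on random sequences.

**Coordinates.**  Promoter sequences run 5′→3′ and end at the anchor
(`TSS` by default, `ATG` supported — the source used both phrasings, so
neither is guessed).  A hit's offset is the negative 1-based distance of
its 5′-most base (plus strand) from the anchor: the last base of the
sequence is −1, and a repeat whose plus-strand footprint starts 2177 bases
upstream is at −2177.

**Conservation.**  Alignment is delegated to
`Biostrings::pairwiseAlignment` (global, affine gaps; the package's
gap convention — a length-L gap costs `gap_open + (L−1)·gap_extend` — is
mapped onto Biostrings' opening/extension parameters, and tie-breaking is
Biostrings' deterministic traceback).  Conserved blocks are maximal unions
of 100-column windows with ≥ 70% identity (gaps and N count as
mismatches), with block identity recomputed over the merged span; a
window's whole span enters the block, so block edges carry up to
window−1 columns of slack, which the tests assert rather than assume away.
A hit is conserved iff its entire footprint lies inside one block.  The
original report of a "highly conserved region" states neither window nor
threshold; both are explicit configuration here, and no attempt is made to
reproduce its exact 476-nt extent.

## 5. The synthetic-data generators

`simulate_two_color_experiment()` states this world: per-gene latent log2
expression ~ N(10, 1.5²) (counts 2⁶–2¹⁴ on a 16-bit scanner); a fraction
`de_fraction` (default 0.1) of genes planted at ±`true_log2fc_magnitude`
(default 1 log2 unit, random sign); per-channel spot noise sd 0.3;
an additive intensity-dependent dye-bias curve (quadratic by default),
identical across the slides of a pair, entering the two channels as ±d/2 —
this makes dye-swap cancellation exact by construction, matching the
normalization algebra under test; optional gene-specific dye bias;
log-normal local background (mean 100, sd 30 counts — about 10% of median
signal) added to the foreground and reported in the background columns,
with an optional log-scale correlation knob to drive the
background-subtraction decision down either branch; clipping at 65535;
2% of spots flagged bad.  Counts are emitted as continuous values:
quantizing to integers would make the machine-precision dye-swap identity
impossible, and nothing downstream requires integrality.

What the generator does *not* emulate: print-tip/spatial block effects,
between-array batch effects, pixel-level segmentation artifacts,
correlated noise between the channels of one spot, or non-additive
(multiplicative) dye bias beyond what the curve expresses.  A green
recovery test therefore establishes the pipeline's algebra and statistics,
not robustness to spatial artefacts.

`simulate_promoter_pair()` writes planted repeats exactly (half-sites drawn
uniformly from the consensus expansion), mutates the second species at a
uniform substitution rate outside the planted footprints (plants stay
perfectly conserved by design, so conservation filtering is testable), and
emits the gap-free identity alignment.  Indels are deliberately absent:
substitution-only divergence lets alignment tests make exact statements.

`simulate_qpcr_experiment()`: target Ct = baseline − log2(true FC) +
noise; reference Ct independent of group; Gaussian per-well noise.

Replication realism: the source study pooled embryos per litter and does
not state an effective replicate count; the generators expose
`n_replicate_pairs` (default 3) and `n_replicates` (default 3, matching
run-in-triplicate practice) rather than guessing.

## 6. Numerical and degenerate-input conventions

* Background-corrected signals are floored at 1 count and annotated.
* An undefined background correlation (zero variance) decides "do not
  subtract"; fewer than 3 retained spots is an error, as is lowess on
  fewer than 10 spots.
* `fdr_adjust` propagates `NA` without counting it in m.
* Zero-variance or under-replicated genes: `NA` statistics, never selected.
* qPCR groups with a single replicate: `rq` computed, SEM absent, warning.
* All-equal ΔCt across groups: `NA` p-values with a warning rather than 0/0.
* Window identity uses a 1e-12 slack against float rounding at exact
  thresholds; BH's `q ≥ p` holds up to the same float slack.
* Generators are seed-deterministic; `run_pipeline()` writes an MD5
  manifest and identical config+seed reproduce identical digests.

## 7. Known limitations

* No moderated (empirical-Bayes) variance model — small-n gene variance
  estimates are noisy, which is precisely why the slide-level replicate
  default matters.
* No between-array normalization (quantile/VSN) and no spatial model.
* The scanner is consensus-based, not a position-weight matrix; affinity
  differences between matches are invisible.
* GO-style summaries count an input list against a provided map; no
  enrichment statistics are computed.
* Reproducing the original study's exact gene lists or its 476-nt
  conserved block requires its raw data and unpublished thresholds, and is
  explicitly not attempted.
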