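---
title: "Calling translocon clients from knockdown proteomics: models and choices"
author: "trapclient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling translocon clients from knockdown proteomics: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapclient)
```

## The scientific problem

Most secretory and membrane proteins reach the endoplasmic reticulum through
the Sec61 channel; the translocon-associated protein (TRAP) complex assists
a subset of precursors. Which precursors depend on TRAP can be read out of a
knockdown experiment: after siRNA depletion of a transport component,
precursors that rely on it fail to translocate, are degraded in the cytosol,
and their steady-state abundance falls. `trapclient` implements the
computational tail of that strategy: from label-free quantification (LFQ)
intensity matrices to lists of negatively affected proteins (candidate
clients) and positively affected proteins (candidate compensatory factors),
followed by an analysis of what distinguishes client signal peptides —
glycine-plus-proline (GP) content and Kyte-Doolittle hydrophobicity.

The experimental design the pipeline assumes is one control group
(non-targeting siRNA) and at least one targeting group, each with replicate
LFQ measurements; the canonical shape is three groups (control plus two
independent siRNAs against the same gene) with three replicates.

## The pipeline, stage by stage

### Missing values: a two-case imputation

LFQ data are missing not at random: low-abundance proteins drop below the
detection limit preferentially. The pipeline therefore distinguishes two
regimes, applied on the log2 scale:

* **Proteins with no valid data point** are drawn from the *bottom tail* of
  each sample's observed distribution: `Normal(mean_j - downshift * sd_j,
  (width * sd_j)^2)` for sample `j`. The defaults `downshift = 1.8` and
  `width = 0.3` (in units of the per-sample standard deviation) are the
  canonical values of the Perseus-style strategy this emulates. Per-sample
  distributions are the default; a pooled mode is available
  (`pooled_tail = TRUE`) because "the whole distribution" is ambiguous in
  common usage.
* **Proteins with at least one valid data point** are completed by local
  least squares (LLS): candidate neighbors are fully observed proteins,
  ranked by absolute Pearson correlation with the target over the target's
  observed samples (ties broken by protein id for determinism); the top `k`
  (default 10) enter an ordinary least squares fit *with intercept* — log2
  abundances have arbitrary per-protein offsets, so a no-intercept fit would
  be mis-specified. Targets observed in fewer than `min_overlap` samples
  (default 3), or without any usable neighbor, fall back to their observed
  row mean.

One numerical guard matters in small designs: the regression never uses more
than `n_observed - 4` neighbors. With nine samples and `k = 10` an
unconstrained fit would saturate (interpolate) the observed points and
extrapolate wildly into the missing columns; in simulation this guard is the
difference between a median absolute imputation error of ~0.24 log2 units
(below the replicate noise) and occasional errors of hundreds of log2
units. Bottom-tail-imputed rows are excluded from the LLS neighbor pool to
avoid circularity, and imputation runs bottom-tail first, then LLS.

### Normalization

After imputation the matrix is quantile normalized. Classical
(`mode = "sample"`) quantile normalization replaces the i-th smallest value
in each sample by the across-sample mean of i-th smallest values, making
every sample's distribution identical — the cross-sample comparability the
downstream contrasts need, and the default. Because the phrase "gene-based"
normalization is genuinely ambiguous, a `mode = "gene"` variant (the same
procedure along rows) is provided, but it is not the default: equalizing
each protein's distribution across samples erases abundance differences
except through ranks. Ties share the mean of the reference values at their
tied ranks, which keeps the procedure deterministic and idempotent. Note
that only each column's *ranks* matter: a strictly increasing transform of
one column leaves every quantile assignment unchanged (the shared reference
vector, computed from all columns, does shift — so the output values are
only rank-invariant, not value-invariant).

### Differential testing with permutation FDR

Each targeting group is contrasted against the control with an unpaired
two-sample statistic on log2 values; the log2 mean difference equals the
log2-transformed abundance ratio. Two statistics are available:

* `student_t`: the pooled-variance Student t. This is the API default.
* `moderated_d`: the significance-analysis-of-microarrays statistic
  `d = (mean_t - mean_c) / (s + s0)`, where `s` is the pooled standard
  error and `s0` a fudge factor selected (by default) as the candidate
  percentile of the standard errors minimizing the coefficient of variation
  of the statistic's spread across standard-error bins.

In a 3-versus-3 design the practical difference is stark. The permutation
null of the plain t pools t-like statistics with 4 degrees of freedom, whose
tails are heavy (about 1.6% of null proteins exceed |t| = 4), so at 2000
proteins every q-value estimate is swamped by null exceedances and nothing
reaches q < 0.05 regardless of effect size. The `s0` moderation bounds the
statistic for small-variance proteins and restores power; analyses that need
calls in small designs should use `moderated_d`, and the package's own
operating-characteristic checks do.

Multiple testing is controlled by a permutation false discovery rate. The
contrast's samples are relabeled — all `choose(6, 3) = 20` splits
exhaustively by default; sampling without replacement of distinct splits is
available for larger designs — and null statistics are pooled across
proteins to overcome the 20-split granularity. Tails are treated
*directionally* (asymmetric cutoffs, the convention of the
significance-analysis procedure): for a protein with a negative statistic
the threshold counts only null and observed statistics in the negative
tail. For threshold `t` the estimate is

  `q = pi0 * median_b( #{null_b beyond t} ) / #{observed beyond t}`

with `pi0` (the null fraction) estimated from the share of observed
statistics inside the central 50% of the pooled null, and q monotonized so
a stronger statistic never has a larger q. Proteins with `q < alpha`
(default 0.05) and a consistent sign in **every** targeting contrast form
the negatively / positively affected sets — the intersection is what
filters single-siRNA off-target artifacts.

### Sequence features and enrichment

Signal peptide (SP) and transmembrane helix (TMH) sequences are scored two
ways: GP content, `100 * (#G + #P) / length`, and hydrophobicity, the
arithmetic mean of Kyte-Doolittle hydropathy values over the full sequence.
Values are kept at full precision internally and rounded half-up for table
display. Sequences above a strict 15% GP threshold are classified `high_gp`
— the regime associated with TRAP dependence. Client and background cohorts
are compared with a two-sided Wilcoxon rank-sum test (exact by enumeration
for small tie-free samples, normal approximation with tie and continuity
correction otherwise) plus the client/background mean ratio.

A caveat the package asserts rather than hides: the full-length
Kyte-Doolittle mean does **not** reproduce the hydrophobicity column printed
in the published client tables (for the calreticulin SP the full-length mean
is 41.1/17 = 2.418 against a printed 2.307; for NAGLU 1.774 against 1.461).
The exact windowing or scale variant behind the printed column is not
documented anywhere we could follow, so hydrophobicity is excluded from
exact value anchoring; GP content, which does reproduce, is anchored
exactly. Printed TMH tables report GP over a predicted helix rather than
the printed sequence window, so they are likewise not used as exact anchors.

Annotation enrichment of an affected set against the quantified background
(the proteins present in the matrix — the "quantified in all samples"
universe, not the whole proteome) is the ratio of annotated fractions
`(k/n) / (K/N)`, with an upper-tail hypergeometric probability and
Benjamini-Hochberg correction across the report. The published analysis
reports only fold factors; the significance test is an addition of this
implementation and is labelled as such in the output.

## The synthetic data generator

`generate_lfq_dataset()` emulates the study conditions so the pipeline is
testable end to end without the original deposition:

* per-protein log2 baselines `Normal(25, 2)`; replicate noise sd 0.25
  (additive in log2, i.e. multiplicative in intensity);
* 60 clients at −1 log2 fold change in both targeting groups (the scale of
  a proteasome-degraded client cohort), 15 compensatory proteins at +0.5,
  and 20 off-target decoys per targeting group at −1 in that group only;
* missing-not-at-random cells: `P(missing | x) = plogis((midpoint - x) /
  slope)` with midpoint two baseline standard deviations below the baseline
  mean and slope 1 log2 unit — the regime bottom-tail imputation assumes.

What it does **not** emulate: peptide-level roll-up, shared-peptide
ambiguity, batch structure, or correlated biological variation between
proteins. Passing the recovery tests therefore demonstrates the statistical
machinery under the stated noise model, not performance on any real
deposition.

The generator's defaults are the package's fixed study conditions; problem
sizes used by the test-suite checks are 2000 proteins × 9 samples, with 20
seeded repetitions for operating characteristics (about half a minute per
batch on one core).

## Operating characteristics, honestly stated

Under the null scenario (no planted effects, MNAR missingness active) the
fraction of proteins reaching q < 0.05 in any contrast is about 0.1% —
comfortably below the nominal 5%. On the default knockdown scenario the
intersected negative set recovers about 75–80% of planted clients at an
empirical FDR near 1%.

Two limitations are worth stating plainly. First, the missingness model
interacts with the effect: knockdown lowers client intensities, which makes
exactly those cells likelier to be missing; LLS then reconstructs them from
mostly unaffected neighbors, shrinking the planted dip. Roughly a quarter of
clients with low baselines lose enough signal this way that no calibrated
q < 0.05 caller recovers them — without missingness the same machinery
reaches ~91% intersected sensitivity. Second, for the same reason a decoy
that is heavily missing can occasionally acquire an imputation-driven false
dip in its null contrast and slip through the intersection (we observe ~1
leak per ~400 decoys across seeded runs). Both effects are properties of
imputation-then-test pipelines on MNAR data generally, and both argue for
treating borderline calls near the detection limit with caution.

## Reproducibility choices

Every stochastic step takes an explicit seed; the pipeline derives
per-stage seeds from one global seed by stage-name hashing, so stages can be
re-run in isolation. Exhaustive permutations make the testing stage fully
deterministic. Result tables are written with fixed column order, and the
run manifest records row counts and md5 hashes — identical configuration
and seed give an identical manifest hash.

## A worked example

```{r example, eval = FALSE}
fix <- tempfile(); out <- tempfile()
end_to_end_fixture("default_knockdown", fix, seed = 1)
cfg <- yaml::read_yaml(file.path(fix, "run.yaml"))
cfg$diff$statistic <- "moderated_d"   # power in a 3v3 design
cfg$.base <- fix
run <- run_pipeline(cfg, out)
run$affected
run$tables$feature_comparison
```

The negatively affected set contains the recovered clients; the feature
comparison shows the planted GP excess of client signal peptides (mean
ratio ~1.4 against the background cohort) with a small Wilcoxon p-value.
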