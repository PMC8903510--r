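---
title: "Bridge-channel normalization and power analysis for multi-plex TMT proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bridge-channel normalization and power analysis for multi-plex TMT proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plexbridge)
```

## The problem

An isobaric (TMT) 10-plex quantifies up to ten samples in one LC-MS run
through reporter-ion intensities.  Studies that need more samples than
one kit holds spread them over several plexes and include, in every
plex, an aliquot of the *same* pooled sample — the bridge, used here as
the reference channel.  Ratios to that channel put all plexes on one
scale, at the price of two new artifacts this package deals with
explicitly: per-plex batch shifts, and protein dropout whenever
data-dependent acquisition fails to sample a protein in some plex.

The reference design emulated throughout is a vitreous-proteomics
comparison of proliferative diabetic retinopathy (PDR) against
non-diabetic controls: four 10-plexes, each with eight individual
patient channels, one aliquot of a control-only pool (a cross-plex
technical replicate), and one aliquot of a mixed control+PDR pool used
as the reference channel.  That yields a 36-column unified matrix, of
which 32 columns (10 control, 22 PDR) enter differential analysis.

## PSM filtering

The quantification unit is the peptide-spectrum match (PSM).  Four
quality rules are applied per plex: (a) PSMs without a TMT label carry
no reporter signal; (b) PSMs lacking reference-channel quantification
have no ratio denominator; (c) precursor-ion purity below 50% (strict
inequality: 0.50 is kept) signals co-isolation that distorts reporter
ratios; (d) PSMs whose summed reporter intensity falls in the bottom 5th
percentile are too weak to quantify reliably.  PSMs mapping to external
contaminant proteins are removed; both unique and razor peptide
assignments are kept.  Redundant PSMs — the same (peptide sequence,
charge) in the same run — collapse to the single PSM with the highest
summed reporter intensity, ties broken by spectrum id so the result is
order-independent.

Two numerical conventions deserve note.  The percentile in rule (d) is a
linear-interpolation sample quantile computed over the PSMs surviving
(a)–(c), with an *inclusive* boundary ("5th percentile or lower"), and it
is a *relative* rule: re-filtering an already-filtered table removes a
fresh bottom slice.  The absolute rules (a)–(c) are idempotent;
`intensity_percentile = 0` disables (d) when a loss-free pass is needed.
Whether the percentile should be computed per plex or per MS run is not
settled by any reference we know of; per plex is the default and the
scope is a parameter.

## Normalization model

For each kept PSM, each channel intensity is log2-transformed and the
reference channel subtracted.  Zero intensities are treated as
non-detection and become missing, never `-Inf`; zero *reference*
intensities invalidate the whole PSM.  Per entry (gene, protein or
peptide, set by `level`) and sample, ratios are IQR-trimmed
(`Q1 - 1.5*IQR`, `Q3 + 1.5*IQR`, linear-interpolation quartiles — the
same centralized quantile convention as rule (d)) and summarized by the
median.

Columns are then scaled by median absolute deviation, jointly across
all samples of all plexes:

$$ R^N_{ij} = \frac{R_{ij} - M_i}{\mathrm{MAD}_i}\,\mathrm{MAD}_0 + M_0 $$

with $M_i$ the sample median, $\mathrm{MAD}_i$ the unscaled median
absolute deviation (no 1.4826 consistency constant — the scaling is a
ratio of MADs, so a constant would cancel), and $M_0, \mathrm{MAD}_0$
medians of those across samples.  Afterward every sample has median
$M_0$ and MAD $\mathrm{MAD}_0$ *exactly*, a post-condition the test
suite asserts.  A sample with zero MAD (degenerate, e.g. a nearly
constant column) keeps unit scale and is flagged.

Because the map is per-sample strictly increasing affine, within-sample
rank orders — and hence Spearman correlations — are untouched.  One
consequence worth stating plainly: when a large fraction of the proteome
genuinely shifts between groups, the group-specific columns acquire
larger MADs and the scaling *compresses* between-group contrasts by a
few percent.  This is a property of MAD normalization itself, not an
implementation artifact; recovery tests for fold changes and effect
sizes therefore run either in ratio space (where recovery is exact with
zero technical noise) or in a small-effect regime where the compression
is negligible.

Ratios return to an absolute scale through per-entry reference
intensities: in each plex, the top (up to) 3 PSMs by MS1 precursor
intensity contribute `ms1 × (reference reporter share)`; plexes without
any PSM for the entry are imputed with the global minimum observed
reference value *before* averaging over all plexes (so an entry seen in
one plex of four is pulled toward the floor), and
`A_ij = RN_ij + log2(REF_i)`.  Per-plex additive log2 batch shifts hit
every channel of a plex including the reference, so they cancel in ratio
space; the test suite verifies that multiplying all reporters of a plex
by a constant leaves ratio and normalized matrices unchanged to 1e-12.

## Differential expression

Pool columns are trimmed away and only entries measured in every
remaining sample are tested (no imputation).  Per entry, a two-group
comparison (PDR minus control) uses an empirical-Bayes moderated t: the
pooled variance on $df_g$ degrees of freedom is shrunk toward a prior,

$$ s^2_{post} = \frac{d_0 s_0^2 + df_g\, s^2}{d_0 + df_g}, \qquad
   t = \frac{\Delta}{\sqrt{s^2_{post}(1/n_1 + 1/n_2)}}, $$

on $d_0 + df_g$ degrees of freedom.  The hyperparameters are fitted by
matching moments of the log sample variances against a scaled F
distribution (Newton inversion of the trigamma function; $d_0 = \infty$
when the observed dispersion falls below the theoretical minimum).  The
limits $d_0 = 0$ (ordinary pooled t) and $d_0 = \infty$ (fully shared
variance) are exposed as testing hooks, and the fitted results are
cross-checked against an independent implementation (limma) in the test
suite.  Multiplicity is handled by Storey q-values with the fixed
$\lambda = 0.5$ estimator $\hat\pi_0 = \#\{p > \lambda\}/((1-\lambda)m)$
capped at 1; with $\hat\pi_0 = 1$ the q-values equal Benjamini-Hochberg
exactly.  The volcano classification uses strict cuts, q < 0.05 and
linear fold change > 1.5.

## Effect sizes and FDR-controlled power

Hedges' g is the bias-corrected standardized mean difference,
$g = J\,\Delta/s_p$ with $J = 1 - 3/(4\,df - 1)$; its 95% CI inverts
the noncentral-t pivot of the two-sample statistic (normal approximation
beyond 200 df).  Zero pooled spread yields a flagged, undefined effect
rather than silent omission — such distributional violations are exactly
the cases where a standardized effect should be distrusted.

Prospective power under FDR control solves, for a planned per-group size
$n$, anticipated effect $g$ and null fraction $\pi_0$, the
per-comparison level $\alpha$ at which

$$ \mathrm{FDR} = \frac{\pi_0\,\alpha}{\pi_0\,\alpha +
   (1-\pi_0)(1-\beta(\alpha))} $$

with $1-\beta$ the two-sided two-sample t power at noncentrality
$g\sqrt{n/2}$ on $2n-2$ df (equal group sizes for the planning curve; an
unequal-size noncentrality $g\sqrt{n_1 n_2/(n_1+n_2)}$ variant serves
retrospective checks).  The root is bracketed and polished to an FDR
residual below 1e-10, and the analytic power is validated against a
200 000-draw Monte-Carlo rejection rate to within 0.01.  For small
effects at very small $n$ the target FDR can be unattainable — the
heavy t tails bound $\pi_0\alpha / (\pi_0\alpha + (1-\pi_0)\,power)$
away from zero — in which case power 0 is returned with a flag.
Defaults FDR = 0.05 and $\pi_0 = 0.7$ are planning conventions, and the
0.8 power target is common but arbitrary.

## QC, dropout and subphenotypes

Spearman matrices use pairwise-complete entries with average-rank ties
(pairs sharing under 3 entries are flagged missing); whether a
complete-case policy would be preferable is a judgment call, and the
pairwise choice is stated rather than hidden.  PCA uses only complete
entries and centers each protein without unit-variance scaling, since
all abundances already share the post-normalization log2 scale.
Hierarchical clustering is Ward's method on Euclidean distances
(`ward.D2`), with variants that exclude, or restrict to, the annotated
blood proteins.

Dropout accounting partitions every quantified entry into exactly one of
three classes: *complete* (measured in all samples), *inter-plex*
(each plex either fully measured or wholly absent, at least one absent —
the signature of data-dependent acquisition undersampling), and
*intra-plex* (a strict subset of a plex's samples missing; this class
takes precedence when both patterns occur).

PDR samples are banded by vitreous hemoglobin: PDR-L at or below
1.0e-4 g/dL, PDR-M within [2.0e-4, 1.7e-3], PDR-H within
[4.9e-3, 8.4e-3], endpoints inclusive.  Concentrations falling in the
gaps between bands are labeled `unclassified` rather than snapped to the
nearest band — the bands describe observed sample ranges, not a
partition of the line.  For scale, even the highest band sits three
orders of magnitude below whole blood (~15 g/dL).  The packaged
annotation sets — 23 high-abundance plasma proteins and 7
erythroid-enriched proteins — are reconstructions from standard
plasma/erythrocyte references, overridable by user lists; overlaps
resolve erythroid-first.

## The synthetic generator

`simulate_experiment()` emits PSM tables with a known truth so that
every stage is testable without real data.  The model: log2-normal
protein baselines (mean 16, SD 2.2); per-sample biological noise
(SD 0.35 log2); non-null proteins carry a standardized effect drawn
N(0, 3.0) with null fraction `pi0 = 0.25`; per-plex per-protein additive
shifts (SD 0.3) applied to every channel including the reference; pooled
channels are exact linear mixtures of the individual samples' true
abundances (all samples for the bridge, controls only for the validation
pool); reporter noise of 0.2 log2 per channel on top of shared peptide
and PSM offsets; Beta(5, 1.5) precursor purity; 1% unlabeled PSMs and 1%
contaminant PSMs; inter-/intra-plex dropout injected per protein at
rates 390/1157 and 40/1157.  Erythroid-annotated proteins receive a
PDR-specific +2 log2 upshift; plasma-annotated proteins get no phenotype
effect.  Hemoglobin is drawn by first assigning a subphenotype
(proportions 10:6:6) and then sampling uniformly within its band, which
guarantees all bands are populated.  A master seed feeds one substream
for the protein-level truth, one for clinical/sample effects, and one
per plex, so adding a plex never perturbs earlier plexes.

The defaults were fixed once to land the reference study's observed
behavior — roughly 60% of complete proteins significant at q < 0.05
with a third clearing a 1.5 fold change, technical-replicate Spearman
around 0.99 within a plex and biological correlations near 0.95, and
dropout classes near 727/390/40 out of ~1150 — and are documented as
tunables, not estimates.  What the generator deliberately does *not*
model: isotopic impurity interference, chromatographic structure,
missing-not-at-random mechanisms beyond the two dropout classes, or
non-normal heavy-tailed biological variation.  Passing tests therefore
demonstrate correctness of the pipeline's arithmetic and its behavior
under a plausible generative model, not robustness to every pathology of
real spectra.

## Problem sizes and numerical choices

The test suite exercises the full pipeline at 1157 proteins x 4 plexes
(the reference scale) and property checks at 500-2000 proteins;
normalization is verified against an independently transcribed
straight-line oracle on 1000 random matrices up to 5x5 at 1e-12, and
Monte-Carlo power checks use 200 000 draws per grid point.  Binomial
acceptance bands are +/-3 sigma at the stated problem size.  All quantile
computations share one convention (type-7 linear interpolation) defined
in a single internal helper, so changing the convention is a one-line
edit.  Degenerate inputs — empty PSM tables, zero-MAD samples, zero
reference intensities, all-null variance — return flagged results or
typed errors rather than silent numbers.

## Known limitations

* Completeness-based trimming discards inter-plex-dropout proteins from
  differential analysis; abundance imputation is out of scope.
* MAD scaling compresses contrasts when most of the proteome shifts
  (documented above); fold changes on such data are mildly conservative.
* The moderated-t extension for abundance-dependent variance trends is
  not fitted by default; `fit_moderated_t()` operates on the standard
  shared-prior model.
* Protein inference, search-engine output parsing and pathway analysis
  are upstream/downstream of this package and intentionally absent.
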