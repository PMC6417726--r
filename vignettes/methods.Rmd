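---
title: "Detecting heterochronic cuticle maturation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting heterochronic cuticle maturation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beecuticle)
```

Eusocial bees emerge from the brood cell with a pale, incompletely
sclerotized cuticle that keeps maturing through early adult life, while
solitary bees leave the nest with an essentially finished exoskeleton.
`beecuticle` implements the comparative analysis that makes this
heterochrony measurable from three kinds of evidence: integument
transcriptomes across developmental phases (pharate adult `Pbm`, newly
emerged `Ne`, forager `Fg`), cuticular hydrocarbon (CHC) profiles from
GC-MS peak tables, and cuticle-thickness measurements. Every stage can be
exercised end to end on seeded synthetic data with known ground truth, so
the statistical machinery is testable without any sequencing or
chromatography archive.

This vignette records the models, the parameters that matter, and the
design decisions taken where more than one defensible choice existed.

## The synthetic study design

`generate_expression()` emulates a 3-species x 3-phase x 3-replicate
RNA-seq design: two eusocial species and one solitary outgroup, each
replicate a pooled-integument library. Counts are negative binomial in the
mean-dispersion parameterization, `Var = mu + alpha * mu^2`; `alpha = 0.1`
is the package default, a conventional bulk-RNA-seq value — the protocol
the design emulates reports only sequencing depth, not dispersion
estimates, so this default is a convention, not a fitted quantity. With
`dispersion = 0` the generator degenerates to counts equal to the planted
means, which is what makes exact recovery tests possible.

Each gene carries one planted profile class: `eusocial_heterochronic`
(the signature of interest — the eusocial pair shares a profile the
solitary species inverts), `all_shared`, `solitary_shifted` (the solitary
species tracks eusocial species 1 while species 2 peaks mid-development),
`species_specific`, and `flat`. The default class fractions
(0.20/0.25/0.20/0.10/0.25) mirror the composition of a curated
developmental-gene panel in which roughly a fifth of orthologs carry the
eusocial-shared signature and a quarter show no phase structure.

Two generator details deserve explanation:

* **Balanced regulation directions.** Planted profiles alternate between
  declining (high in `Pbm`) and rising (high in `Fg`) gene by gene, using
  additive-complement shapes so the per-phase expected library size is
  constant. This mirrors real integument data — cuticle-construction genes
  peak before emergence, chemoreception and detoxification genes peak in
  foragers — and it is also a statistical necessity: if all planted
  regulation pointed one way, per-million scaling would imprint a shared
  phase profile on every unregulated gene and manufacture spurious
  cross-species correlations.
* **Ortholog dropout.** A configurable fraction of solitary-species map
  entries is removed (rows dropped, not zeroed), reproducing the
  "transcript not identified in the solitary species" situation that gets
  its own pattern label downstream.

`generate_chc()` builds per-individual GC-MS peak tables by inverting a
known calibration: true per-bee amounts are converted to analyte /
internal-standard area ratios through the curve assigned to each
compound's chain length, then multiplied by lognormal noise. Defaults
follow the study design the package serves: 15 individuals per phase for
eusocial species (4/7/7 for the solitary one), a 6-level standard series
at 1.25-20 µg/ml, pooling of three bees for the small-bodied species
(areas three-fold, amounts divided back by the pool size), and forager
amounts a few-fold higher for n-alkanes and about seven-fold for
unsaturated CHCs while branched alkanes stay level — magnitudes chosen to
match the reported per-bee quantities for eusocial workers. Because the
branched share shrinks as the n-alkane and unsaturated load grows, the
*percent* composition also separates foragers, which is what the Euclidean
clustering stage consumes.

`generate_thickness()` draws per-phase cuticle-thickness samples from a
normal or moment-matched lognormal family.

## Differential expression

`test_de()` is deliberately minimal: a per-gene NB Wald test with pooled
method-of-moments dispersion (floored at zero) on library-size-normalized
counts, plus an exact replicate-label permutation test. `method = "both"`
requires a gene to be significant under each test at its own BH q — the
intersection semantics of requiring two independent tools to agree. Note
the arithmetic of the 3v3 design: the exact permutation test has 20 label
splits, so its smallest two-sided p is 0.1 and the intersection cannot
reach q < 0.05 at that replication; `nb_wald` is therefore the default,
and `both` is most useful at higher replication.

The DEG filter applies the study thresholds with their printed bounds:
q < 0.05 (strict), |log2FC| >= 1 (inclusive), and an abundance floor of 5
on the *larger* of the two phase means — a gene expressed in only one
phase should remain testable. log2 fold changes use a pseudo-count of 1 to
avoid infinities. Upregulation percentages are computed over the species'
DEG universe (all genes significant in at least one pairwise comparison),
and species are contrasted with the pooled two-proportion z-test.

## Bootstrap clustering and AU support

Samples (or CHC individuals) are clustered by complete linkage on
correlation distance `1 - r` (Euclidean for CHC profiles). Support values
come from multiscale bootstrap: features are resampled with replacement to
`round(n * rho)` for ten scales `rho = 0.5 ... 1.4`, each with `nboot`
replicates; per cluster, the probit-transformed containment frequencies
are fitted as `z(rho) = v * sqrt(rho) + c / sqrt(rho)` by weighted least
squares, and `AU = 100 * (1 - pnorm(v - c))`. `BP` is the raw frequency at
`rho = 1`. Items are never resampled, so every bootstrap tree has the same
leaf set; cluster identity is the leaf set itself.

Numerical choices: frequencies of exactly 0 or 1 are clipped to `1/(2B)`
and `1 - 1/(2B)` before the probit transform; scales with `0 < BP < 1`
carry the fit. A cluster saturated across the *entire* grid is off-model
(the fitted curve cannot be constant) and corresponds to a diverging
signed distance, so its AU is pinned to the saturation limit — 100 when
always present, 0 when never — rather than left to a degenerate fit that
would report ~50 for the strongest clusters in the data. The default
`nboot` in `run_study()` is 10,000 per scale, the full-protocol depth;
unit tests use a few hundred.

## Ortholog profile correlation

For each ortholog, the replicate-level profiles (phases in order,
replicates sorted within phase — nine points in the default design) are
compared between species pairs with Pearson correlation. A pair "passes
positively" iff `r >= 0.6` and `p <= 0.1`, both bounds inclusive;
"negatively or non-correlated" is simply the complement. Replicate-level
pairing is a deliberate choice: with only three phase means, `p <= 0.1`
would demand `|r| >= 0.988` and the `r >= 0.6` bound would be vacuous,
whereas at n = 9 the critical `|r|` at p = 0.1 is about 0.58, making the
two thresholds nearly coincident and both meaningful. A phase-mean mode is
provided for sensitivity analysis.

The pattern label is a pure function of the three pair outcomes
(pass / fail / absent): all pass = `ALL_SHARED`; eusocial pair passes and
both solitary pairs fail = `EUSOCIAL_SHARED`; eusocial pair passes with
the solitary member absent = `EUSOCIAL_SHARED_SOLITARY_ABSENT` (a failed
solitary comparison outweighs an absent one); exactly one
solitary-containing pair passes = `AM_CA_SHARED` / `FV_CA_SHARED`;
everything else `NONE`. The function is verified exhaustively over all 27
outcome triples. One calibration fact worth knowing: under the null, a
pair passes positively with probability ~0.044 at n = 9, so even a purely
flat gene is labelled something other than `NONE` about 13% of the time —
an irreducible property of the thresholds, not an implementation artifact.
Rows with no computable pair at all (e.g. constant profiles in a
zero-noise simulation) are labelled `NA` and reported as unclassified.

## Co-expression networks

Within a species, all gene pairs are correlated across the nine samples
(phases pooled, one network per species); an edge requires
`|r| >= 0.95` and `p <= 0.05`, inclusive, with no multiplicity correction
— at n = 9 the r bound corresponds to p ~ 9e-5 and dominates. Cross-species
"common interactions" map both endpoints through the ortholog table and
require the same edge with the same correlation sign in the partner
network (a flag relaxes the sign match). Intersection is symmetric in
argument order up to id relabeling, and edge counts are monotone
non-increasing in the r threshold.

## CHC quantification

Relative profiles are percent-of-total peak area per individual, either
over all compounds or repeated within each class (n-alkanes, unsaturated,
branched). Absolute quantification uses internal-standard calibration.
The calibration sentence in the source protocol is internally inconsistent
(it calls `y` the known amount but `a` a peak area); the package implements
the only reading compatible with an analytical curve built "to establish
the correlation between the quantities of the used standards and the
CHCs": ordinary least squares of known amount on the analyte /
internal-standard area ratio, `amount = a * ratio + b`, inverted for
unknowns. Curve assignment follows chain length: up to C24 the C23 curve,
C25-C29 the C25 curve, above C29 up to C35 the C32 curve — anything outside
20-35 carbons is rejected rather than extrapolated. Amounts are scaled by
the extract volume (160 µl default, 100 µl for the pooled species),
divided by the pool size, and negative inverse predictions (area below the
calibration background) are clamped to zero and flagged
`below_quantification` — the package never silently omits a
below-quantification compound. Per-peak and per-class phase contrasts use
one-way ANOVA with Tukey HSD and compact letters; composition structure is
summarized by column-centered PCA.

## Thickness decision tree

With exactly two phases the comparison is Student's t. With more, a
Shapiro-Wilk gate on pooled per-phase-demeaned residuals (a single gate,
matching a whole-dataset normality statement; the per-group alternative
was rejected as it multiplies gate tests without a stated rule for
combining them) routes to ANOVA + Tukey HSD or to Kruskal-Wallis with the
Conover-Iman post hoc, Bonferroni-corrected — the correction is attached
to the post hoc only, where the source protocol places it. Conover-Iman
and the insert-and-absorb compact-letter display are implemented in the
package; ties use midranks with the tie-corrected rank variance.

## Letters

All pairwise outcomes are encoded by `cld_letters()`: start with one
letter covering all groups, split any letter containing a significantly
different pair, absorb subsets, assign letters deterministically in group
order. The display satisfies the contract in both directions — two groups
share a letter exactly when their comparison is non-significant — and the
tests verify this against the underlying p-value matrix rather than
trusting the construction.

## Problem sizes and what the tests show

The test suite runs the generators at a few hundred to two thousand genes,
bootstrap depths of a few hundred per scale (10,000 for the two end-to-end
protocol runs), and a 100,000-draw Monte-Carlo studentized-range oracle —
sizes chosen so the whole suite completes comfortably on a laptop-class
single core while keeping Monte-Carlo error well below the asserted
margins. Stochastic recovery checks fix their seeds and, where a rate is
compared to a bound close to its expectation, pool two seeded replicates
to keep the Monte-Carlo error small.

Passing tests demonstrate that the estimators recover what the generators
plant under the stated noise models. Real integument RNA-seq adds
mapping/assembly artifacts, gene-length and GC biases, batch structure and
biological covariance between genes that the simulator does not model;
real chromatograms add co-elution, baseline drift and detector
saturation. Conclusions about real data therefore rest on the correctness
of the statistical machinery verified here, not on the generators being a
complete model of the measurement process.

## Limitations

* Orthology inference, read processing, assembly and quantification are
  out of scope; the package consumes their outputs.
* The NB Wald test uses a per-gene moment dispersion without shrinkage;
  at n = 3 it is noticeably noisier than shrinkage estimators, which is
  acceptable here because the planted effects are large and the test is
  cross-checked against an established NB implementation in the suite.
* AU support is the two-parameter multiscale approximation; higher-order
  corrections are not implemented.
* The pattern classifier is threshold-based; it inherits the ~4.4%
  per-pair null pass rate discussed above.
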