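---
title: "Identifying Z and W chromosomes from female:male sequencing depth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying Z and W chromosomes from female:male sequencing depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zdosage)
```

## The dosage model

In female-heterogametic taxa such as Lepidoptera, females carry one Z
(ZW or Z0) while males carry two. Genomic sequencing depth is
proportional to copy number, so on autosomal scaffolds the summed female
and male depths are equal, on Z-linked scaffolds the female depth is
halved, and on W-derived scaffolds the male depth is zero and the female
depth is half the autosomal level. On the log2 female:male scale
(`log2_fm()`), autosomes sit at a mode we call `A_mode` and Z-linked
scaffolds at roughly `A_mode - 1`; W scaffolds have no finite ratio at
all. Everything this package does — classifying scaffolds, confirming
chromosome-level Z homology, detecting neo-Z fusions, scanning for W
candidates, sexing unlabelled samples — is a different projection of this
one dosage signal.

Depths are summed across libraries *grouped by sex* before the ratio is
taken. No pseudocount is added: a pseudocount would drag the Z mode
toward zero and bias the offsets below; scaffolds with a zero numerator
or denominator are instead flagged non-finite and excluded from
histograms and classification (they re-enter through the W scan, where
zero male depth is the signal rather than a nuisance).

## Scaffold pre-filter

`prefilter_scaffolds()` retains scaffolds longer than 1500 bp whose
grouped-male depth exceeds 5 and falls below the 99.5th percentile of
grouped-male depth. The length and depth floors drop scaffolds whose
ratio is dominated by sampling noise; the percentile cap removes
collapsed repeats, which show inflated depth in both sexes. Both
inequalities are strict, and all three are configurable. The percentile
is computed once, on the population the filter first sees, and recorded
on the result, so re-application is a no-op rather than a slow erosion of
the right tail. The filter is not meant for the degenerate zero-noise
limit, where every male sum ties the cap; the simulator's noise-free mode
is therefore classified unfiltered in our tests.

## Lenient classification

`find_autosomal_mode()` locates `A_mode` as the centre of the most
populated class of an equal-width histogram over the finite ratios
(`n_bins` = 200 or 120 depending on how well-populated the distribution
is; both are exposed). A tie between modal bins is broken toward the bin
nearer 0, because the autosomal peak is by assumption the dominant one.
`classify_lenient()` then labels ratios below `A_mode - 0.6` Z-linked and
ratios above `A_mode - 0.4` autosomal. The offsets bracket the expected
one-unit separation between the modes while leaving a buffer gap;
scaffolds in the gap are `unclassified`. Because both rules are strict
inequalities, a ratio exactly at either cutoff falls in the gap — the
conservative reading of "less than"/"more than".

## Stringent classification

The stringent method borrows information from a reference genome.
`calibrate_stringent_cutoff()` sweeps the Z cutoff from the lenient value
toward stricter values and tracks the fraction of Z-classified,
chromosome-assigned scaffolds that land on the reference Z: the fraction
rises while contaminating autosomal scaffolds are being excluded and
plateaus once (almost) only true Z scaffolds remain. The plateau is
detected programmatically as the most lenient cutoff at which the gain
over a sliding span of 0.1 log2 units drops below one percentage point
(`span` and `tol` arguments); published anchor cutoffs can be supplied
verbatim through `stringent_config()` instead. Whether such plateaus are
best picked algorithmically or by eye is genuinely open — the sweep curve
is returned as an attribute and written out by the analysis drivers so it
can be inspected. If the curve never flattens, the strictest swept value
is returned with a warning.

`classify_stringent()` then calls a scaffold Z only if its ratio is below
the cutoff *and* its grouped female depth is below the female median
(a single-copy region in a female cannot exceed the genome-wide typical
depth); it calls a scaffold autosomal if its ratio is at or above the
10th percentile of ratios among scaffolds assigned to reference
autosomes. That percentile comparison is inclusive at the boundary: with
continuous ratios the choice is immaterial, but in the degenerate case
where all autosome-assigned ratios coincide (the noise-free limit) the
inclusive rule still classifies autosomes instead of abstaining on all of
them.

## Homology assignment and neo-Z detection

Ortholog hits are reduced to one location per gene (`best_hit_per_gene()`,
minimum mapping score 50, ties broken lexicographically then leftmost),
then overlapping genes on a scaffold are resolved (`resolve_overlaps()`):
among genes overlapping by more than 20 bp only the highest-scoring
survives; exactly 20 bp is tolerated. Resolution is a greedy
score-descending sweep — the published rule is pairwise only, and the
greedy sweep is its natural transitive extension; the test suite checks
it against exhaustive subset resolution on small cases.
`assign_chromosome()` is a majority vote of gene counts per scaffold,
falling back to the larger summed mapping score on count ties and to
`unassigned` on double ties.

`test_chromosome_coverage()` compares each chromosome's assigned-scaffold
ratios with the reference Z by one-tailed Wilcoxon rank-sum tests. The
neo-Z rule is a reconstruction of an informal compound judgement: a
chromosome is flagged when it is *not* significantly different from the
reference Z (two-sided) and *is* significantly lower than every unflagged
autosome. P values are reported raw — multiple chromosomes are tested, so
a Bonferroni column is emitted alongside for transparency — and
chromosomes with fewer than 10 assigned scaffolds are skipped as
uninformative. `sliding_profile()` orders a chromosome's scaffolds by
their best hit's reference position and reports a 10-scaffold moving
average, the plot-ready view of within-chromosome dosage.

## Gene movement on the four-species tree

The rooted topology `(((bmori, cohridella), ndegeerella), tsylvina)` is
fixed; it is a property of the analysis, not a user input. Genes
classified Z or A in all four species (`build_linkage_matrix()`) are
assigned to categories by `infer_movement()`:

* **ancestral Z**: Z in *tsylvina* and at least one other species;
* **ancestral to the Ditrysia + ndegeerella node**: the ancestral set
  plus genes Z in *ndegeerella* and both Ditrysia (a gain on that stem);
* **Ditrysia-root gain**: Z in both Ditrysia only;
* **terminal gains**: Z in exactly one of the three ingroup species;
* **losses**: the mirror rules applied to ancestral-Z genes, with a
  double loss in both Ditrysia counted as one event at their root;
* **unpolarizable**: Z in *tsylvina* only — without an outgroup the
  deepest branch cannot be polarized, so these genes are reported but
  assigned to no branch.

Two of the sixteen Z/A patterns (Z in *bmori* + *ndegeerella* only, or
*cohridella* + *ndegeerella* only) admit two equally parsimonious
histories; they are attributed as two independent terminal gains, and the
full per-pattern attribution ships as `movement_rules()` so the choice is
inspectable rather than implicit. For the same reason an off-Z event
cannot be planted on the Ditrysia+ndegeerella stem in the simulator: its
footprint is identical to a *tsylvina*-only gain.

`rescale_total()` converts a branch count into a chromosome-wide estimate
by dividing by the sampling fraction of reference Z genes present in the
classified set, rounding to the nearest integer for reporting;
`compare_branch_rates()` tests per-branch rate homogeneity with an
uncorrected chi-square on the moved/stayed table, warning when an
expected cell drops below 1.

## W scan and sex inference

`detect_w_candidates()` implements the female-specificity filter:
length above 1000 bp, depth below 1.1 in *every* male library, and depth
strictly between one quarter of and one times the female median in
*every* female library. The female medians are per-library (the natural
reading of a per-sample rule; a grouped-median option exists) and are
computed over all scaffolds passing only a 200 bp floor — deliberately
*not* the classification pre-filter, whose male-coverage floor would
discard exactly the scaffolds sought here. The stringent preset
(`w_stringent_preset()`) raises the floor to 2000 bp and requires
exactly zero male depth.

`infer_sex()` compares an unlabelled library's depths on Z-classified
versus autosome-classified scaffolds with a one-tailed rank-sum test:
significantly lower Z depth means one Z copy, hence female; otherwise
male. Classes under 30 scaffolds give `indeterminate`. Depths are
compared raw, as medians of the same library, so no cross-library
normalization is needed (an optional scaling hook exists for cross-library
use). A dosage call cannot distinguish ZW from Z0 females — both carry
one Z — and does not attempt to.

## The simulator and what it does (not) emulate

`sim_config()` encodes the study conditions: 31 chromosomes (the
ancestral ditrysian karyotype) with chr1 the Z carrying 3.7% of the
genome, an optional W (2% of scaffolds) and optional neo-Z, log-normal
scaffold lengths (median 3 kb, floor 200 bp, matching a fragmented
short-read assembly), two male and two female libraries at 30× each so
the grouped per-sex depth is ≈60×, and 1% depth-outlier scaffolds
inflated 5–20× in both sexes to exercise the percentile cap.

Depth noise is a multiplicative gamma factor with mean 1 and variance
`depth_dispersion` — the continuous analogue of gamma-mixed
(negative-binomial-like) counts. No per-scaffold variance is published
for data of this kind, so the default 0.02 (≈14% CV per library, ≈0.2 sd
on the grouped log2 ratio) was fixed once as a plausible mappability-
dominated spread; at dispersion 0 the model degenerates to exact expected
depths, which is what makes the noise-free identities (ratio exactly 0 on
autosomes, −1 on the Z) testable.

The simulator does *not* model read-level error, GC or mappability bias
along chromosomes, assembly chimerism, or pseudoautosomal/partial-dosage
regions, and W scaffolds carry no ortholog genes. Passing tests on this
generator therefore demonstrate correctness of the decision rules under
the dosage model, not robustness to every artefact of real libraries —
the published anchor cutoffs exist precisely because real distributions
are messier than a two-component mixture.

## Problem sizes and determinism

The test suite runs genomes of 500–10,000 scaffolds, the movement
property tests enumerate all 16 Z/A patterns and 1,000 random matrices,
and the sex-call check runs 100 seeded simulations at 20×; everything is
seeded through `sim_config(rng_seed=)` and reruns byte-identically. The
worked movement example (5 observed root gains among 86 sampled of 654
annotated reference-Z genes, rescaling to 38) is recomputed from scratch
by `scripts/acceptance.R`.
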