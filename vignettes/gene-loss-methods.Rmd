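---
title: "Methods: gene-loss calling, the F-index, expression specificity and the k-mer survey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-loss calling, the F-index, expression specificity and the k-mer survey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genelossr)
```

This vignette documents the statistical and algorithmic choices behind
`genelossr`: what each procedure assumes, which knobs matter, what the
synthetic-data generators do and do not emulate, and where the design was
genuinely open.

## Conserved orthogroups and loss calling

The unit of analysis is the **orthogroup**: a set of genes across species
descended from one ancestral gene. Orthogroup membership is an *input*
(an OrthoFinder-style count table); this package does not build orthogroups
from sequences or trees.

An orthogroup is **conserved** when it is present (count ≥ 1) in a
designated reference species and in at least `min_present` of a panel of
autotrophic species. The rule is pure presence/absence: no abundance
threshold is applied, because conservation here means "an autotroph is
expected to have this gene", not "to have many copies". The default
`min_present = 5` against a six-species panel tolerates one annotation
dropout per family, which matters in practice since single-species absences
in draft annotations are common. Counts in the target (heterotrophic)
species are deliberately ignored by the rule, so that loss calling is not
circular.

A conserved orthogroup is **lost** in a target when the target's count is
zero. Loss calling is deterministic, so on synthetic data with planted
zero rows recovery must be exact — this is a correctness check, not a
benchmark. Losses of two targets called against the same conserved set are
partitioned into joint and species-specific sets by plain set algebra;
`|specific| = |lost| − |joint|` holds by construction and is asserted on
every pipeline run.

## The F-index

For family *g* and species *s* with count *n* and all-species mean
*x̄ > 0*,

$$F_{g,s} = \frac{n}{n + \bar x_g}.$$

This is the simplest smooth statistic with the properties the analysis
needs: range [0, 1); *F* = 0.5 exactly when *n = x̄*; strictly increasing in
*n* with the other counts fixed; *F* = 0 for an absent species in a
non-empty family. Two choices deserve a note:

* **The mean includes the focal species.** "The average size of this gene
  family in all species" is read literally. Excluding the focal species
  would shift the 0.5 anchor; the chosen form keeps "equal to the average"
  and "F = 0.5" synonymous. The kernel is isolated in `f_ratio()` and
  `f_index_table(f_fun = )` accepts a replacement, so the alternative
  convention is one line away.
* **Ties count as "not below".** `fraction_below_half` uses the strict
  inequality *n < x̄*: a family whose count equals its average is not
  "smaller than the average".

All-zero families are rejected with an error rather than silently scored —
an all-zero row is a data problem, not an observation.

Distribution summaries follow Tukey boxplot conventions: quartiles by
linear interpolation of order statistics (the `type = 7` rule, R's
default — stated explicitly because quartile conventions differ), whiskers
at the most extreme data within 1.5 × IQR of the nearer quartile, outliers
beyond the whiskers, and the mean reported alongside.

## PET and PEG classification

A tissue *t* is a **principally expressed tissue** (PET) of gene *g* when

$$x_{g,t} \ \ge\ \texttt{fold\_threshold} \times \mathrm{mean}_{t' \ne t}\, x_{g,t'} .$$

The phrase "at least one-fold greater than the average" admits two
readings: ≥ 1 × the average (at least as high) or greater *by* one fold
(≥ 2 ×). The "-fold greater" idiom favours the second, so the default is
`fold_threshold = 2`; the first reading is available by passing 1, and both
are exercised in the tests. A **principally expressed gene** (PEG) of a
focal tissue set applies the same inequality to the focal-vs-remaining
means; with a single focal tissue the two rules coincide, and the suite
asserts that consistency.

Further conventions: the comparison mean always excludes the focal
tissue(s) ("its expression levels in *other* tissues"); no pseudocount is
added, and all-zero genes get an empty PET set rather than a vacuous
"every tissue qualifies" (the inequality 0 ≥ 0 is guarded by requiring
non-zero total expression); a gene may have several PETs — the rule as
stated permits it.

**Tabulating lost orthogroups by PET class.** Lost orthogroups are linked
to genes of proxy autotrophic species by a user-supplied (possibly
one-to-many) ortholog map; an orthogroup's PET classes are the union over
its mapped genes, so one orthogroup can contribute to several of the
classes leaves/roots/flowers/other. Orthogroups with no map entry and
mapped orthogroups with no PET are reported as separate tallies instead of
being dropped. The percentage normalisation is ambiguous in the analyses
this package reimplements, so both candidates are emitted, clearly
labelled: `pct_of_class` (per class: lost members of the class over *all*
mapped orthogroups with a PET in that class) and `pct_of_lost` (per
cohort: over the number of lost orthogroups tabulated).

**Enrichment.** Over-representation of annotation terms in a gene set uses
the upper-tail hypergeometric probability (`stats::phyper`) with
Benjamini–Hochberg adjustment across the tested terms; terms with zero
query hits are excluded before adjustment, since an untestable term should
not dilute the correction. Ontology structure (term parentage,
propagation) is out of scope: the statistic takes a flat term → gene map.

## Pseudogene lesion detection

A candidate locus is compared to an intact reference CDS (ATG … stop,
length divisible by 3, no internal in-frame stop — validated on input) by
global Needleman–Wunsch alignment with affine gap penalties, delegated to
`Biostrings::pairwiseAlignment` (a gap of length *L* costs
|open| + *L* × |extend|; defaults +2 / −3 / −5 / −2, recorded in the
report object). Two lesion kinds are called on the alignment:

* **frameshift** — each maximal run of gap columns whose length is not
  divisible by 3, at the reference coordinate of the first affected base
  (for insertions, of the next reference base);
* **premature stop** — the candidate's codons are read consecutively from
  its start, so the reading frame tracks the cumulative indel offset, and
  any TAA/TAG/TGA whose reference position precedes the reference's final
  codon is reported.

A candidate is a **pseudogene** iff it has at least one lesion. Choices
made where the criteria leave room: any in-frame stop strictly before the
terminal codon counts — no "last 5%" grace window, because the criterion as
stated has none; frame-preserving indels are not lesions; coordinates are
1-based on the reference; candidates are assumed sense-strand. Inside a
homopolymer or short repeat the optimal alignment can place an indel gap a
few bases away from where it was "really" introduced; planted-truth tests
therefore accept frameshift coordinates within ±3 nt, while premature-stop
coordinates must match exactly. Genome-wide pseudogene *discovery*
(finding candidate loci in an assembly) is out of scope; this module scores
given reference/candidate pairs.

## k-mer genome survey

The estimator is the classical quotient: with *K* the total number of
k-mer observations (Σ depth × count) above an error threshold and *D* the
coverage-peak depth, genome size *G = K / D*. No mixture model is fitted —
only the printed formula is implemented, with a transparent heuristic for
its two inputs:

* **error threshold** — sequencing errors produce a spike of distinct
  low-depth k-mers, so the depth-count curve falls, bottoms out, and rises
  into the coverage peak; the threshold is the first local minimum. A
  histogram that does not descend-then-rise has no detectable valley and
  the function refuses, telling the user to supply `error_threshold`
  manually (as one must for error-free simulations).
* **peak** — the most frequent depth above the threshold, ties broken
  toward the smaller depth (deterministic, and biased in the conservative
  direction for genome size). Note that a Poisson(λ) depth distribution
  with integer λ has equal mass at λ−1 and λ, so a detected peak one below
  the planted coverage is expected behaviour, not a failure — tests accept
  ±1.

The **naive** estimate (no error filtering) is reported alongside the
filtered one, because published k-mer totals are sometimes pre-filtered and
sometimes not, and the two can disagree by several percent.

**Repeat fraction** is the share of *K* at depths ≥
`repeat_multiplier × D`. The default multiplier is 2 ("well above
single-copy coverage"). Be aware of a bump-overlap effect: repeats of copy
number *c* put their k-mer mass near *c × D*, so a cutoff at exactly
*c × D* splits that bump and underestimates the repeat share (for *c* = 2,
roughly half the repeat mass falls below a 2× cutoff). When the copy
number is known, a multiplier midway between 1 and *c* (e.g. 1.5 for
two-copy repeats) separates the bumps cleanly; the planted-truth test uses
1.5 for exactly this reason, and the parameter is exposed rather than
hidden.

## The synthetic-data generators

Each generator is a pure function of its parameters and a seed
(`withr::with_seed`), emits data satisfying the consuming module's
invariants by construction, and returns the planted truth alongside.
Defaults encode the study conditions of a nine-species parasitic-plant
comparison: a reference-plus-six-autotroph panel with `min_present = 5`,
marginal loss rates 0.117 and 0.130 with a joint-loss rate of 0.047 (an
excess over independence, as observed for convergently reduced species),
17-mers at 42× coverage. Distributional choices, and what they do *not*
capture:

* **Count matrix** — family sizes are shifted Poisson (minimum 1 where
  presence is planted; mean 3 by default, a typical conserved-family size);
  conserved/non-conserved status, per-target loss categories and
  contraction/expansion labels are planted independently per row. Real
  count matrices have phylogenetically correlated sizes and heavy-tailed
  large families; nothing here models that, which is acceptable because
  the consumers under test are deterministic rules, not estimators.
* **Expression** — planted-PET genes are flat at a base level with one
  elevated tissue; noise is multiplicative lognormal with a given CV
  (mean 1, so planted signal is unbiased). Real atlases have correlated
  tissues, library-size effects and zero inflation; consequently the
  recovery tests certify the classifier's logic and noise robustness, not
  its behaviour on real TPM matrices.
* **CDS pairs** — references are random intact ORFs; background
  substitutions are rejection-sampled so they never create an in-frame
  stop, ensuring the planted lesion is the only pseudogenising signal;
  planted lesions are single 1–2 bp indels or one stop codon in the
  interior (codons 10 to L−10). Real pseudogenes accumulate multiple,
  overlapping lesions and large truncations — detection still works there,
  but planted-truth exactness is only claimed for this clean regime.
* **k-mer histogram** — unique mass at Poisson(coverage), repeat mass at
  Poisson(copy × coverage), error k-mers at depths 1–2 with count
  proportional to error_rate × k × coverage × genome size. Heterozygosity
  (a half-coverage bump) is deliberately not simulated, matching the
  estimator's scope.

## Problem sizes and reproducibility

The test suite and the acceptance script size their simulations to what the
checks need, as a deliberate choice: 10,000 random families for F-index
range/semantics, 1,000 conserved families for planted-loss recovery, 200
CDS pairs of 200 codons for the pseudogene confusion matrix, twenty seeds
of a 1 Mb genome at 42× for the survey, 10,000 permutations for the
enrichment oracle. The pipeline defaults (2,000 orthogroups, 500 genes,
100 pairs) run in seconds; every output is reproduced byte-for-byte by
rerunning with the same seed, and the pipeline's run directory includes a
manifest of version, seed and parameters. The single global seed is
expanded into fixed per-generator substreams (seed + 1 … + 4), so a stage
can be regenerated without rerunning the others.

## Known limitations

* Orthogroup construction, birth–death significance tests for family
  expansion/contraction, and selection scans are out of scope; this
  package consumes their outputs.
* The F-index kernel reproduces the documented properties of the statistic
  it reimplements, but the original's exact formula was not published in
  full; the kernel is therefore pluggable.
* The lost-PET percentage normalisation is reported both ways because the
  original description is ambiguous; downstream code should pick one
  explicitly.
* The genome-size estimator inherits the biases of the plain quotient:
  error filtering is threshold-based, and heterozygous genomes (not
  modelled) would inflate the k-mer count relative to the peak.
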