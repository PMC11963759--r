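---
title: "Modeling germline-encoded microhomology in V(D)J junction formation"
author: "junctionMH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling germline-encoded microhomology in V(D)J junction formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(junctionMH)
```

## The scientific problem

During V(D)J recombination, a V gene end and a J gene end are trimmed by a
nuclease and then ligated to form the junction of a T- or B-cell receptor
gene. Short stretches of identical sequence shared between the two gene ends
— *microhomology* (MH) — can guide this process: the shared nucleotides pair
across the break and appear only once in the joined product. When the shared
stretch is encoded in the germline (rather than created by N-insertions), an
observed junction that lacks N-insertions can be explained by several
different *annotations*: triples (delV, delJ, MH) of trimming amounts and
used microhomology that all assemble to exactly the observed sequence.
Conventional annotation tools attribute shared nucleotides to only one gene
and thereby ignore most of these explanations.

`junctionMH` implements a statistical pipeline that

1. enumerates, for an observed zero-N-insertion junction and its gene pair,
   *every* consistent annotation;
2. models the joint choice of trimming and ligation scenario with a two-step
   conditional logit whose features include two microhomology terms;
3. fits the model by expectation-maximization (EM), treating the true
   annotation of each sequence as latent;
4. quantifies uncertainty (bootstrap Wald tests) and model adequacy
   (likelihood-ratio test of the nested no-MH variant); and
5. measures how MH parameterization changes per-sequence annotation
   probabilities and rankings.

A synthetic-repertoire generator with known ground-truth coefficients stands
in for repertoire data, so the entire pipeline is testable offline.

## Conventions for gene ends, trimming and productivity

All sequences are stored on the coding (top) strand, 5'→3'. Hairpin opening
at the +2 position leaves each gene end with two palindromic
**P-nucleotides**: a V end gains the reverse complement of its last two
nucleotides appended 3'; a J end (whose physical overhang lies on the bottom
strand) gains the reverse complement of its first two nucleotides prepended.
Internally, all cut-site computations mirror the J gene (reverse complement
of its extended sequence) so both genes are trimmed "from the right"; this
is equivalent to working on the J bottom strand and keeps the file formats
simple.

Deletions use IGoR-style indexing on the interval \[-2, 14\]: `d = -2`
retains both P-nucleotides, `d = 0` deletes exactly the P-nucleotides
(any germline deletion removes all P-nucleotides), and `d > 0` removes
germline nucleotides.

```{r}
v <- germlineGene("toyV", "V", "CACAG")
j <- germlineGene("toyJ", "J", "AGGTA")
extendedSeq(v)
trimGene(v, -2)
trimGene(j, 2)
```

Productivity is called on the junction alone: productive iff the junction
length plus a configurable `frameOffset` (default 0) is a multiple of 3 and
no stop codon occurs in a complete codon of that frame. Real loci anchor
the reading frame in flanking sequence that upstream annotation software
knows about; the offset is this package's stand-in for that anchor, which
keeps the productive/non-productive partition that the model conditions on
without requiring external references.

## Scenario spaces and annotation sets

A **ligation scenario** for a trimmed pair is any overlap length `m` such
that the last `m` nt of the trimmed V equal the first `m` nt of the trimmed
J (on the coding strand; this is exact Watson–Crick complementarity of the
physical overhangs). `m = 0` is always available — joining does not require
microhomology. Mismatched or partial-complement overlaps are not counted.

```{r}
ligationScenarios("CACAG", "AGGTA")
assembleJunction("CACAG", "AGGTA", 2)
```

The **choice set** for a gene pair and productivity class Q is the full
deletion grid × admissible ligation scenarios, restricted to junctions of
productivity Q; it is the normalization domain of the model. The
**annotation set** of an observed junction `x` is the subset whose junction
equals `x` exactly; it is computed directly by a prefix/suffix scan (every
trimmed V that prefixes `x` crossed with every trimmed J that suffixes `x`,
with the overlap forced by the length identity `a + b - m = |x|`), and is
validated against brute-force grid filtering in the test suite. A junction
that its assigned pair cannot produce is an explicit error, not a silent
drop; a pipeline-level switch can drop such rows with a logged count.

```{r}
ax <- enumerateAnnotations("CACAGGTA", v, j)
annotations(ax)
```

## The two-step conditional logit

Scenario `s` in choice set `C` receives the probability

$$P(s \mid C; \beta) = \frac{10^{\eta(s)}}{\sum_{s' \in C} 10^{\eta(s')}},
\qquad \eta(s) = \beta_{\mathrm{trim}} \cdot f_{\mathrm{trim}}(s) +
\beta_{\mathrm{lig}} \cdot f_{\mathrm{lig}}(s).$$

Base-10 exponentiation means every coefficient is the change in the log10
odds of a scenario per unit of feature — a coefficient `b` multiplies the
odds by `10^b`, reported by `oddsPercent()` as a percent change. The
features are:

* **Trimming motif** (per gene): one-hot nucleotide indicators in a
  three-nucleotide window around the cut — two retained-side positions
  (−2, −1) and one trimmed-side position (+1), read on the P-extended
  sequence. Nucleotide A is the dropped reference level for
  identifiability; positions beyond the extended sequence take an explicit
  padding level `X`. The 2 + 1 split of the window is a configuration knob
  (`motifUpstream` / `motifDownstream`).
* **Base counts** (per gene): raw GC and AT counts 5' (retained side) and
  3' (trimmed side) of the motif window. The 3' totals grow one-for-one
  with the deletion amount, so they encode the absolute position of the
  trimming site; the 5' counts proxy local sequence-breathing capacity.
  The 5' AT count is computed but excluded from the default feature set
  (`includeFivepAT = FALSE`); both configurations are supported because
  published descriptions of such models differ on whether it is included.
  Windows may extend into P-nucleotides; an optional `maxSpan` caps the
  scanned length for long inputs (default: the whole supplied germline
  end, which is short by construction).
* **`mh_trim`**: the *average* number of microhomologous nucleotides over
  the ligation scenarios available to the trimmed pair — a property of the
  trimming scenario alone. Its coefficient is the trimming-step MH effect.
* **`mh_lig`**: the number of microhomologous nucleotides actually used in
  the ligation. Its coefficient is the ligation-step MH effect.

The joint factors exactly as
$$P(\mathrm{delVJ}, \mathrm{MH} \mid \mathrm{VJ}, Q) =
P(\mathrm{delVJ} \mid \mathrm{VJ}, Q)\,
P(\mathrm{MH} \mid \mathrm{delVJ}, \mathrm{VJ}, Q)$$
because productivity conditioning is realized as choice-set restriction
*before* normalization: the trimming marginal sums the joint over each
trimming scenario's surviving ligation options, and the ligation
conditional renormalizes the `mh_lig` term within them. This also makes
the trimming marginal depend on the ligation coefficient, exactly as the
two-step generative story requires when conditioning on productivity. The
factorization identity is verified to 1e-12 in the tests.

```{r}
cs <- buildChoiceSet(v, j, "non-productive")
dist <- jointDistribution(cs, mhParameters(c(mh_lig = log10(2))))
sum(scenarioProbs(dist))
annotationPosteriors(ax, mhParameters(c(mh_lig = log10(2))))$annotations
```

## Fitting with latent annotations

The true annotation of each observed sequence is latent; its likelihood
contribution is the sum of the joint probabilities over its annotation set.
`fitEM()` alternates:

* **E-step** — posterior responsibilities over each sequence's annotation
  set under the current coefficients (uniform at the `beta = 0` start);
* **M-step** — a weighted conditional-logit fit over full choice sets
  (`conditionalLogitFit()`), maximized by BFGS with the analytic gradient
  to a relative function tolerance of 1e-12.

Sequences sharing a choice set and junction are aggregated into units, so
the per-iteration cost scales with the number of distinct junctions, not
sequences. Iteration stops when the relative change of the observed-data
log-likelihood falls below `tol` (default 1e-6) or after `maxIter`
(default 100) iterations; the trace is checked to be non-decreasing (the
EM guarantee — a decrease aborts loudly because it would indicate an M-step
defect). On the default synthetic study scale (one planted-overlap gene
pair, 2000 non-productive sequences, `mh_both` regime) convergence takes
roughly 15–25 iterations.

Numerical choices worth knowing:

* All softmaxes are log-sum-exp stabilized by max-subtraction; likelihoods
  are clipped at 1e-300 before logs and the clip is flagged.
* A coefficient whose magnitude exceeds 50 triggers a separation flag: a
  one-hot level with no posterior support has an unbounded ML estimate.
  This is expected occasionally in small bootstrap resamples;
  `bootstrapSE()` counts these flags (attribute `nFlagged`) rather than
  failing.
* Ties in annotation ranking are broken deterministically (higher
  probability, then higher `mh`, then smaller total trim, then enumeration
  order (delV, delJ, mh ascending)). Flip statistics depend on this rule,
  so it is fixed and documented rather than left to sort stability.

## Inference

* `bootstrapSE()` resamples sequences with replacement (the sampling unit
  is the sequence), refits warm-started from the point estimate, and
  returns per-coefficient standard deviations over replicates. The
  study-scale default is B = 1000; the package's tests use B = 30–40,
  which is adequate for ±2 SE coverage checks.
* `waldTests()` computes `T = estimate / se`, two-sided normal p-values,
  and applies a Bonferroni threshold of `alpha` divided by the number of
  parameters in the configured model (the parameter count, and hence the
  threshold, depends on the feature configuration).
* `lrtTest()` compares nested variants with `LR = 2 (L_MH - L_noMH)`
  against a chi-square with df equal to the number of added parameters
  (2 for the MH pair). Because both fits stop at a finite tolerance, a
  tiny negative LR within optimization slack is clamped to zero; only
  larger violations raise a nesting error.

Model adequacy on held-out data uses the expected per-sequence log loss
(natural-log scale — the base is a reporting convention and is documented
rather than inferable) and a mean absolute error against an empirical
reference. Since true annotations are unobservable, the empirical
reference splits each sequence's count uniformly across its annotation set
— a deterministic, model-independent construction — and strata with fewer
than `minStratumCount` (default 10) sequences are excluded.

## The synthetic-repertoire generator

`generateGenePair()` draws random ACGT gene ends (default 16 nt, matching
the short coding-end segments the deletion grid covers with a little slack
beyond the 14-deletion cap) and plants a shared motif (default `"AGG"`)
two germline nucleotides in from the V 3' end and the J 5' end, so interior
microhomology is exposed at known trim depths and terminal/interior regimes
are both exercised. `sampleRepertoire()` draws scenarios i.i.d. from the
model's joint distribution under a regime's true coefficients and emits
junctions with ground truth attached. The four regimes (`no_mh`,
`mh_trim_only`, `mh_lig_only`, `mh_both`) use effect sizes 0.45 / 0.13 on
the log10-odds scale — the magnitude of fitted real-data effects — and
background motif/base-count coefficients of realistic sign and size
(upstream GC positive, downstream counts negative, ≈0.1–0.15 in
magnitude). Sampling restricted to non-productive junctions mirrors the
training restriction used on real repertoires, where non-productive
rearrangements approximate pre-selection recombination statistics.

What the generator does *not* emulate: N-insertions (out of scope by
design), sequencing error, selection on productive sequences, gene-usage
variation beyond uniform pair sampling, and the allele diversity of a real
germline reference. Passing recovery tests therefore demonstrates
correctness of the estimator under the model's own assumptions — not that
real repertoires satisfy those assumptions.

## Problem sizes used in the checks

The packaged checks run at desk scale, chosen to exercise the full
pipeline with comfortable statistical resolution: recovery uses 20
replicates per regime at n = 2000 with B = 30 bootstrap replicates;
LRT calibration uses 200 null replicates at n = 500 (the LR statistic is
well inside its chi-square reference there) and 20 alternative replicates
for power; the enumeration oracle checks 500 random gene-pair/junction
instances. Real-data quantities that require external repertoires (fitted
coefficient values, the repertoire-wide flip fractions, the
pair-level correlation) are computable with the same functions once such
data are supplied as a repertoire table plus germline FASTA.

## Known limitations

* Productivity calling ignores flanking-anchor context (see above); with
  the default `frameOffset = 0` the partition is internally consistent but
  not locus-faithful.
* The empirical MAE reference (uniform split over annotation sets) is one
  deterministic choice among several defensible ones; comparisons between
  models are meaningful, absolute MAE values depend on the choice.
* Interior hairpin-opening positions other than +2 are not modeled, so
  every gene end carries exactly two P-nucleotides.
* The no-cap policy on `mh` (bounded only by trimmed lengths) follows the
  enumeration exactly; practical values in biological data are 1–4 nt.
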