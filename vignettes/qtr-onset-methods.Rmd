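---
title: "Methods: hexamer QTR genotyping and ascertainment-corrected onset association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hexamer QTR genotyping and ascertainment-corrected onset association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

qtronset joins two pieces of machinery around one scientific question: does
the length of the hexanucleotide quasi-tandem repeat (QTR) in *TCERG1*
modify the age at motor onset of Huntington's disease? The first piece
calls diploid QTR/STR genotypes from 75 bp short reads localized to the
repeat locus; the second estimates the repeat-length effect on residual
age at onset while correcting for the extreme-phenotype ascertainment of
sequenced cohorts. This vignette describes both models, the choices made
where the design was genuinely open, and what the simulation-based tests
do and do not establish.

```{r setup}
library(qtronset)
```

## The locus model

The locus is declared, not discovered: a 228 bp tract of 38 hexamer units
at chr5:145,838,546-145,838,773 (hg19), with a central perfect
(CAGGCC)\_6 short tandem repeat (STR) embedded in imperfect quasi-repeat
units, the whole tract translating to an imperfect glutamine/alanine
repeat with occasional valines. Eight alleles are built in (A1-A8),
varying mostly by central STR length, plus one same-length allele (A6)
that differs by a synonymous SNV and two alleles (A5, A8) with
length changes in the imperfect part of the tract.

```{r}
allele_inventory()
```

Three locus-level details are design choices because they are not
machine-readable from any public table:

* **Flanks.** The caller and simulator need anchoring sequence either
  side of the tract. Defaults are synthetic, non-repetitive 150 bp
  flanks with unique 20-mers; any real flank can be supplied to
  `repeat_locus()`.
* **The imperfect unit arrangement.** The exact variant units of the
  quasi-repeat are not available as machine-readable sequence. The
  synthetic reference tract places QA-coding variant units
  (CAGGCA/CAGGCT/CAGGCG/CAAGCC) and four valine-coding GTGGCC units so
  that (i) no pure run outside the central STR exceeds 2 units, and
  (ii) the arrangement is aperiodic. Aperiodicity matters: with a
  periodic arrangement, a multi-unit deletion adjacent to the central
  run can reconstruct a sequence locally identical to a multi-unit
  insertion, and no 75 bp read can tell the two apart. The real
  imperfect tract does not have that symmetry, so the synthetic default
  should not either.
* **A6's synonymous SNV** defaults to a third-codon-position T-to-G in a
  non-STR unit (tract offset 30); it is configurable via
  `allele_spec()`.

Coordinates are 1-based inclusive throughout, the native R/Bioconductor
convention; the printed hg19 coordinates therefore pass through
unchanged.

## Read alignment by match matrix and mismatch error

A read is aligned to the reference window through the match matrix: the
grid of base equalities whose maximal exact diagonal runs are the
candidate *match pieces*. A path chains pieces left to right; uncovered
read bases on an unchanged diagonal are substitutions, and each diagonal
jump is a *gap* of height $\Delta_i$ (bases jumped) flanked by pieces of
minimum length $l_i$. The path score is the mismatch error

$$M = m + \sum_{i=1}^{N} \Delta_i \, e^{\,5 - l_i},$$

with $m$ the total substitution count. The exponential discount makes a
gap essentially free once both flanking pieces exceed ~30 bp, which is
what lets a single 75 bp read vote decisively for a multi-unit repeat
indel it spans: a read crossing a 3-unit deletion with 36 bp anchored on
each side scores $18 e^{-31} \approx 6\times10^{-13}$ on the gapped path
versus $m \ge 2$ on any gapless one.

The scoring function is exact; the search over paths needs three
conventions the scoring alone does not fix:

* **Seeding.** Candidate pieces are maximal exact runs of at least 8 bp
  (configurable). Substitutions inside a path are charged when chaining
  runs on one diagonal, so mismatched reads need no special seeding.
* **Junction splits.** Inside a tandem repeat, the maximal runs on the
  two sides of an indel overlap heavily. At each junction the overlap
  is resolved by the split maximising $\min(l_\text{left},
  l_\text{right})$ — precisely the quantity the penalty discounts, so
  this is the split minimising $M$. A small Pareto front of (error, gap
  count, remaining-length) states per piece keeps the dynamic program
  exact for this cost model; a brute-force enumeration oracle in the
  test suite verifies the equality on random instances.
* **Ties.** Exact ties (periodic placements) are broken by fewest gaps,
  then leftmost reference placement, and indel signatures are always
  *reported* at the leftmost equivalent position. Error comparisons are
  relative with tolerance $10^{-14}$: penalty terms span many orders of
  magnitude, and all terms are nonnegative, so relative comparison is
  safe, while gaps whose penalty falls below double precision relative
  to $m$ are deliberately treated as ties (a gap that cheap carries no
  evidence against the gapless explanation).

Reads with best error above `m_max` (default 5) are discarded, and reads
shorter than `min_anchor` (default 20 bp) are not aligned at all. These
thresholds are configurable in `call_config()` because no canonical value exists
for a bad-alignment cutoff at a repeat locus.

## Genotype calling

`call_genotype()` composes the pipeline: align every read to the
reference window; drop badly aligned reads; enumerate candidate
haplotypes from the observed indel signatures (each signature, plus
unions of compatible signatures, on top of the reference); realign every
read to every candidate and keep the minimum-error assignment; resolve
ambiguous reads by their mates; build an asterisk-padded multiple
alignment in which insertions expand the reference with `*` columns and
deletions appear as `*` in the read rows, so indels become
substitutions; and split the reads into at most two groups that agree at
every discordant column, each group's column-majority consensus becoming
one allele. QTR units are consensus tract length over six; STR units are
the longest pure-unit run.

Three numerical details were settled empirically during design, and the
reasons are worth recording:

* **Canonical candidate order is parsimony first** (fewest indel
  operations, then fewest indel bases, then signature string). Repeat
  periodicity manufactures observationally equivalent explanations —
  e.g. a 2-unit insertion in the central run versus two 1-unit deletions
  elsewhere — and reads tied between them must fall to a deterministic,
  scientifically sensible choice.
* **Candidate elimination.** A candidate that no *unambiguously placed*
  read prefers is eliminated, weakest first, and assignment is redone
  from the stored alignment matrices (cheap bookkeeping, no realignment).
  A read is "ambiguous" when its tied placements write it into different
  columns of the padded frame; ties between a candidate and its
  supersets write identical columns and are harmless. This is the
  collective reads-correct-reads step, and without it spurious periodic
  signatures fragment the read support of true alleles.
* **Discordant columns require both `min_support` (default 3) reads and
  a 20% minor fraction.** A true heterozygous column carries roughly
  half the covering reads; isolated sequencing-error columns carry one
  or two, and at 0.2% per-base error the chance of three identical
  errors in one column is what the fraction threshold suppresses.

Homozygote versus heterozygote follows the read-splitting outcome: a
heterozygote needs two groups with at least `min_support` reads each;
three or more well-supported incompatible groups raise a multiallelic
error. Calls need `min_depth` (default 10) tract-overlapping reads;
below that the sample is reported uncallable, the honest report when read
support cannot distinguish the two alleles. `cross_sample_correct()`
adds candidates confirmed in other samples and repeats realignment once.

Reads that carry no anchor into unique sequence (short pure-repeat or
flank-only reads) tie across candidates, are counted for depth, and
contribute no length evidence. This is the central engineering
consequence of calling a 228 bp tract from 75 bp reads: length evidence
comes exclusively from flank- or variant-unit-anchored indel signatures,
never from assembling the whole tract.

## Residual age at onset and repeat statistics

Expected onset given CAG length uses the published parametric relation
$E[\text{onset}] = 21.54 + \exp(9.556 - 0.146\,\text{CAG})$ years
(Langbehn et al. 2004), validated for CAG in 36-60 by default and
replaceable via `expected_onset(params=)`. The residual is observed
minus expected, so positive means later onset than CAG predicts. From
the two allelic QTR unit counts, `repeat_statistics()` derives the sum,
absolute difference, minimum, maximum, and the 3-repeat allele dosage
(`n_3rep`, defined by a central STR of 3 units).

## The selection model and regression with selection

Cohorts sequenced for extreme phenotypes are not random samples. The
population residual is modelled $R \sim N(0, \sigma^2)$, and recruitment
is a sigmoid in $|R|$:

$$S(R) = \frac{1}{1 + \exp\!\big((R_\text{thr} - |R|)/\Delta\big)},$$

with threshold $R_\text{thr}$ and width $\Delta$ in years; $\Delta \to
0$ is the hard two-tail truncation of the original recruitment, and a
finite $\Delta$ arises when residuals are re-computed with improved CAG
measurements after selection. The selected-sample density is
$p_N(R)\,S(R)$ renormalized.

`fit_selection_model()` estimates $(\sigma, R_\text{thr}, \Delta)$ by
minimising the Kolmogorov distance $D$ between the model and empirical
CDFs of $|R|$ (multi-start Nelder-Mead over $\log\sigma$,
$R_\text{thr}$, $\log\Delta$; the model CDF by cumulative trapezoid on a
2001-point grid). The one-sample KS p-value derived from $D$ is labelled
approximate: the parameters were fitted to the same data, so the
classical null distribution is conservative or anticonservative in unknown ways.

Under selection, ordinary least squares on residual versus repeat
statistic overestimates the effect. The corrected likelihood for record
$i$ with $\varepsilon_i = R_i - (\beta_0 + \beta_1 x_i)$ is

$$\mathcal{L}_i = \frac{p_N(\varepsilon_i)\, S(R_i)}
{\int p_N\big(R - (\beta_0 + \beta_1 x_i)\big)\, S(R)\, dR},$$

whose denominator depends on each individual's statistic $x_i$. With $S
\equiv 1$ every term reduces exactly to the OLS normal likelihood (a
machine-precision test). `fit_regression_with_selection()` maximises the
summed log likelihood over $(\beta_0, \beta_1, \log\sigma)$ from the OLS
start with a Nelder-Mead/BFGS combination; significance is the
likelihood-ratio test of $\beta_1$ against $\chi^2_1$, and the 95% CI is
profile likelihood (the likelihood is visibly asymmetric near strong
truncation, where Wald intervals mislead).

Numerics of the denominator: a closed normal-CDF form when $\Delta$ is
numerically zero; otherwise either adaptive quadrature (`integrate`,
rel. tol $10^{-8}$, cached per distinct $x_i$ — the reference method) or
a composite Simpson rule split at $R = 0$, the only kink of $S$
(801 points per half, vectorized over all distinct means, relative error
about $10^{-10}$ against the adaptive reference). Fitting uses the
Simpson method; the test suite pins the two against each other and
against Monte Carlo integration.

`compare_statistics()` implements the nested-model comparison: for every
ordered pair of statistics, an F-test of `residual ~ A` against
`residual ~ A + B`; a statistic is best-fitting when no addition
improves it at $\alpha = 0.05$, with rank-deficient additions reported
as collinear rather than failed. `conditional_association()` fits both
conditioning directions for a primary statistic and a covariate (e.g. a
tagging SNV dosage) under either engine.

## The synthetic-data generator

`simulate_reads()` emulates whole-exome sequencing geometry: 75 bp
paired-end reads, fragment length 300 ± 50 bp, 30× coverage, uniform
substitution errors (default 0). Fragments are sampled over a padded
template and only reads falling entirely inside the locus window are
emitted — the padding matters, because constraining 300 bp fragments to
a 528 bp window would depress read-start coverage exactly over the
repeat junctions, a geometry artefact a genome-scale library does not
have. Reads are emitted in reference-forward orientation; strand and
quality modelling are out of scope.

`simulate_cohort()` draws diploid genotypes from the inventory
frequencies under Hardy-Weinberg equilibrium, residuals $R = \beta_0 +
\beta_1(N_\text{sum} - \overline{N}_\text{sum}) + N(0, \sigma^2)$
(centring keeps $\beta_0$ interpretable as the mean residual; the
association functions regress on the raw sum, whose intercept absorbs
the shift), applies selection by accept/reject with probability $S(R)$,
and generates a biallelic marker that tags allele A2: with probability
equal to the fidelity (default 0.99) the marker chromosome copies the
A2 indicator, otherwise it is drawn independently from the A2 frequency,
making the marker-A2 correlation equal the fidelity. Defaults describe the
cohort regime the analysis targets: $\sigma = 7.02$, $R_\text{thr} = 17.6$, $\Delta =
3.30$, $\beta_1 = -1$ year per hexamer, $n = 610$. The cohort's CAG
distribution is not published; the uniform 40-50 default is a stand-in
and configurable.

What passing tests on these simulations show: the caller inverts the
generator exactly on clean data and almost always at 0.2% error; the
selection machinery recovers its own generating parameters; the
corrected regression is unbiased where OLS inflates; the LRT holds its
nominal size. What they cannot show: robustness to real-data features
the generator omits — indel sequencing errors, quality ramps, PCR
duplicates and stutter, alignment reference bias, population structure,
or deviation of real onset residuals from normality.

## Problem sizes used by the test suite

Stochastic checks run at sizes chosen to make their tolerances
meaningful: all 36 ordered genotypes at 30× for clean-data exactness;
200 seeded replicates of frequency-weighted genotypes at 0.2% error;
selection-model self-consistency at n = 5000; effect-size recovery over
200 cohorts of n = 610; LRT calibration over 1000 cohorts of n = 300
(calibration at this size was verified to match n = 610 behaviour);
conditional-analysis patterns summarised over 11 cohorts of n = 468 by
medians, so that single-draw p-value noise cannot flip the qualitative
conclusion.

## Known limitations

* Haplotypes observationally equivalent for 75 bp single reads (they
  exist when tract periodicity survives an indel) are resolved by
  parsimony, not by fragment-length evidence; mate insert sizes are not
  modelled.
* The caller hard-fails on three or more well-supported read groups
  rather than attempting somatic or contamination modelling.
* The KS p-value after parameter fitting is approximate, as flagged.
* `n_3rep` requires STR lengths or falls back to matching QTR length 35
  (the 3-repeat allele's length in the built-in inventory).
* The Langbehn onset expectation is a point model; uncertainty in the
  expected-onset curve is not propagated into residuals.
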