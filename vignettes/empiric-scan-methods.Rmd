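---
title: "Methods: from barcoded reads to comparative fitness landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from barcoded reads to comparative fitness landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(empiricscan)
library(SummarizedExperiment)
```

## The experiment being modelled

An EMPIRIC-type scan builds, for each 10-residue library window, every
single-codon variant of a gene (640 variants per library; 21 amino-acid
outcome classes per position once synonymous codons are pooled), competes
the pool in bulk growth under selection, and samples the population at 6–10
time points spanning roughly four wild-type doublings. Each sampling time is
tagged with a ligated barcode so all time points can be sequenced together
as short (36 nt) single-end reads.

The package covers three IGPS-style orthologues per study (8 libraries of 10
positions each, 80 positions per orthologue), but none of the machinery is
specific to that geometry except the four-fold symmetry index, which assumes
8 libraries.

## Fitness model

For variant $i$, with counts $N_i(t)$ and wild-type reference counts
$N_i^{WT}(t)$, raw fitness is the OLS slope

$$w_i = \mathrm{slope}_t \; \log_2 \frac{N_i(t)}{N_i^{WT}(t)},$$

with $t$ in wild-type doublings, so $w$ is a per-generation log-enrichment
rate: $w=0$ is WT-like, $w=1$ doubles its relative abundance every doubling.
Selection coefficients rescale $w$ by the library's internal null: with
$\bar w_{STOP}$ the mean raw fitness of all stop-codon mutations in the same
10-residue library,

$$s_i = -\,w_i / \bar w_{STOP}.$$

This is the unique linear map with $s(0)=0$ under which the stop codons of a
library average $s=-1$. Normalizing per library absorbs between-experiment
differences in selection strength. A library whose stop-codon mean is not
negative has not undergone effective selection; it is flagged
unnormalizable and yields no selection coefficients rather than sign-flipped
ones.

Numerical choices:

* **Zero counts.** Time points where either count is zero are dropped from
  the regression (and recorded); fewer than two usable points flags the cell
  `low_coverage` with no slope. A `pseudocount` argument offers the
  alternative of retaining all points. We default to dropping because a
  pseudocount biases slopes of strongly depleted variants toward an
  arbitrary floor set by depth.
* **Weighting.** The regression is unweighted OLS; no depth weighting is
  applied.
* **Normalization tolerance.** The per-library stop mean of $s$ equals $-1$
  by construction; tests assert it to $10^{-9}$ (floating point only).

## Read filtering

Reads pass four criteria, evaluated in a fixed order so rejection reports
are reproducible: quality, barcode, reference, MmeI. The order is a design
choice (any order gives the same accepted set; only the attribution of
multiply-failing reads changes).

* **Quality**: Phred $\ge 20$ at every base. The threshold is the stated
  error probability of 0.01 ($Q = 20$); it is configurable.
* **Barcode**: the leading bases must exactly match a known time barcode.
* **Reference**: the insert must equal a library's wild-type window exactly,
  or differ within exactly one codon of the mutagenized window (single-codon
  libraries make multi-codon mismatches unclassifiable). Matching is exact
  anchored comparison — with deterministic cassette libraries and 36 nt
  reads there are no indels to align.
* **MmeI**: the enzyme used to ligate time barcodes recognises TCCRAC; reads
  carrying the site on either strand (TCCAAC, TCCGAC, GTTGGA, GTCGGA) are
  removed. The motif itself is fixed by the enzyme, not a tunable.

Wild-type accounting: reads identical to the reference are counted as the
wild-type denominator for every position of their library. Synonymous
wild-type codon variants form their own outcome class (the WT amino-acid
class) and are *not* pooled into the denominator by default, since the 21
outcome classes include the WT amino acid as a class; `poolSynonymousWT`
provides the alternative, as the original accounting is ambiguous on this
point.

Cell-level exclusions mirror the read filter: a (position, outcome) cell is
excluded as `mmei` when *every* codon realising it creates an MmeI site in
context, and as `low_coverage` when its count at the first time point falls
below `minCountT0` (default 10 reads; the threshold is not dictated by the
assay and is configurable). When both apply, `mmei` is recorded. Exclusions
only remove cells; surviving values are never altered.

## The synthetic-data generator

The generator defines the conditions under which the pipeline is validated:

* **Growth**: within a library, all variants and the wild type start at
  equal abundance and grow exponentially; variant $i$ changes relative
  abundance by $2^{w_i t}$ after $t$ doublings. True raw fitness is
  $w_i = s_i \,|\bar w_{STOP}|$ with a default true stop-codon raw fitness
  of $-1$ per doubling, so the per-doubling log2-ratio slope of a variant
  equals its true selection coefficient.
* **Counts**: multinomial draws of a fixed total per library and time point
  (default depth $10^5$), emulating a fixed sequencing budget; Poisson and
  noise-free alternatives are available. Depth and the count noise model are
  generator choices, not claims about any particular experiment.
* **Truth**: the default distribution of fitness effects is bimodal — 55%
  deleterious near the stop-codon null (uniform on $[-1.1, -0.8]$) and the
  rest WT-like with a slight beneficial bias (uniform on $[-0.4, 0.3]$) —
  matching the qualitative shape reported for TIM-barrel scans (a majority
  of strongly deleterious mutations plus a high-fitness mode with beneficial
  outliers). Stops are $s=-1$; the wild-type-synonymous class is neutral.
* **Reads**: one read per counted molecule — barcode plus the library window
  with the variant codon substituted, constant Phred 30. Corruption is
  injected through three independent channels (one low-quality base, an
  invalid barcode, mismatches outside any codon) purely as filter
  scaffolding; real error processes (PCR jackpots, base-call substitution
  profiles, growth lag) are deliberately not modelled. Passing round-trip
  tests therefore shows the bookkeeping is exact, not that the filters are
  robust to real Illumina error structure.
* **Landscape trios**: per aligned position, each orthologue's 20-value
  profile is $\sqrt{\rho}\, z + \sqrt{1-\rho}\, e$ with standardized shared
  and private components, so the expected between-orthologue profile
  correlation is $\rho$. This is a null/alternative generator for the
  correlation framework; it makes no claim that real landscape correlations
  arise from an additive shared signal.
* **MSAs**: columns drawn i.i.d. from stated amino-acid profiles; no
  phylogenetic correlation between sequences, so conservation estimates are
  binomially distributed and easy to test, but column covariation (as
  exploited by coupling analyses) is absent by construction.

## Comparative statistics

**Profile correlations.** The Pearson $R$ between the selection-coefficient
profiles of two positions. The outcome set is a policy: the default
`exclude_both_wt` drops amino acids that are wild type at either position
(leaving 18–19 substitutions — the "19 substitutions" convention), because
the WT cell measures synonymous variation, not substitution response;
`include_all_20` keeps all 20. Stop outcomes are excluded from profiles by
default: they report expression loss rather than residue preference. Every
result records the policy. Pairs with fewer than 3 shared non-missing
outcomes or zero variance are skipped and counted, never imputed.

**Position sets.** `identical_wt` (equal WT residue, any position),
`aligned` (structural map), `aligned_nonidentical`, `fourfold` (same
quadrant and offset under the barrel's four-fold symmetry: quadrant
$\lceil \mathrm{library}/2 \rceil$, offset = within-library position, +10
for even libraries), and the `null_all_pairs` Cartesian product, of which
every other set is a subset. Distributions over sets are compared with the
two-sample KS test (`stats::ks.test`).

**Permutation test on the beneficial fraction.** Whole per-position profiles
are reassigned to random positions (equivalently: a random position subset
of the same size is drawn) and the subset's fraction of $s>0$ mutations
recomputed; 10,000 permutations by default. The p-value uses the add-one
(Phipson–Smyth) correction so $p \ge 1/(n_{perm}+1)$, and is two-sided by
default (twice the smaller tail, capped at 1) — the original reports do not
state sidedness, so the conservative default is two-sided with one-sided
options.

**Transformative mutations.** For aligned pairs with differing wild types,
the substitutions converting one orthologue's residue into the other's, in
both directions; summarised by the detrimental fraction ($s < -0.5$) and
compared against all mutations by KS and by resampling equally sized
mutation sets.

**PCA.** Scores matrices are decomposed by SVD (`stats::prcomp`) after one
of two normalizations. `per_position_z` standardizes every position to equal
mean and s.d. — but under that normalization PC1 cannot be collinear with
the per-position average, since the averages are all equal afterwards. Since
the first component of these scans is characteristically the position's mean
fitness, the default is `per_column_center` (center each outcome column),
the only scheme under which the PC1–mean-fitness collinearity is
reproducible; both schemes are implemented and every result names its
scheme. Component signs follow a fixed convention (non-negative loading
sums) so feature correlations have reproducible signs. Excluded cells are
imputed by the row (position) mean before PCA — the least structured choice
that preserves the position's average — and the imputation is recorded.
Alignment frequency matrices use a pseudocount of $1/(n_{seq}+20)$ before
the log transform so no entry is $-\infty$.

**Annotation.** RSA is ASA divided by the residue's empirical maximum
(Tien-style Gly-X-Gly table, shipped as data and replaceable), capped at 1
by default. Hydrophobicity defaults to Kyte–Doolittle; the scale is an
argument and is recorded. Conservation is identity to the construct's
wild-type residue among non-gap rows (column-majority identity is available
through `informationContent` and custom columns); all-gap columns are
flagged rather than silently dropped.

## Validation scale

The test suite validates the pipeline at desk scale, chosen to keep the full
run in minutes while leaving statistical checks well powered: recovery at
depths $10^3/10^4/10^5$ on a 210-variant library over 8 time points
(Pearson $R \ge 0.95$ at the deepest setting, with RMSE decreasing in
depth); correlation-framework calibration over 200 seeds at $\rho=0$ and
power over 100 seeds at $\rho=0.6$ on 80 positions; permutation-test
calibration over 500 trials at 2,000 permutations; and exact design
accounting on the full 5,040-cell, three-orthologue layout with its 79
MmeI and 7 poor-coverage exclusions (4,954 analysed cells). The MmeI and
poor-coverage exclusion sets of the original libraries depend on the actual
gene sequences and library QC, so they enter the accounting as explicit
exclusion lists applied through the same `applyExclusions()` path as
computed exclusions.

## Known limitations

* Single-end, fixed-length, indel-free reads only; the classifier is an
  exact anchored matcher, not an aligner.
* No replicate-merging model: replicates are compared by correlation, not
  jointly fitted; fitness estimation is per-cell OLS, not hierarchical.
* The four-fold index presumes the canonical 8-library layout.
* The generator omits PCR amplification bias, base-call error profiles and
  growth-phase lag; conclusions about robustness to those processes cannot
  be drawn from these simulations.
* Statistical coupling analysis and any computation of structural
  superpositions or surface areas from coordinates are out of scope;
  alignments and structural annotations are consumed as tables.
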