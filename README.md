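# empiricscan

Analysis of EMPIRIC-style deep mutational scans: bulk growth competitions of
saturation-mutagenesis libraries (10 residues per library, all 64 codons per
position, 21 amino-acid outcome classes) read out by time-resolved deep
sequencing with time-stamping barcodes. The package takes raw barcoded reads
to selection coefficients, and selection-coefficient landscapes to the
comparative statistics used to study orthologous proteins — e.g. TIM-barrel
enzymes such as indole-3-glycerol phosphate synthase (IGPS), where the fold's
four-fold βαβα symmetry gives a natural structural alignment of positions.

It is aimed at groups running (or reanalysing) codon-level mutational scans
who need a transparent, testable implementation of the whole chain, plus a
synthetic-data generator so every stage can be validated without external
sequencing data.

## The model

For mutant *i* with counts *N<sub>i</sub>(t)* and wild-type reference counts
*N<sub>i</sub><sup>WT</sup>(t)* sampled at times *t* (in WT doublings), raw
fitness is the ordinary-least-squares slope

&nbsp;&nbsp;&nbsp;&nbsp;*w<sub>i</sub>* = slope of log₂ [ *N<sub>i</sub>(t)* / *N<sub>i</sub><sup>WT</sup>(t)* ] versus *t*,

over 6–10 time points spanning ~4 doublings. Selection coefficients are
normalized by the mean raw fitness of all stop-codon mutations within the
same 10-residue library, *w̄*<sub>STOP</sub>:

&nbsp;&nbsp;&nbsp;&nbsp;*s<sub>i</sub>* = −*w<sub>i</sub>* / *w̄*<sub>STOP</sub>,

so *s* = 0 is WT-like growth and the stop codons of a library average
*s* = −1 (null behaviour). Reads are accepted only if they pass, in order:
Phred ≥ 20 at every base, a valid time barcode, a single-codon match to the
reference, and absence of an MmeI recognition site (TCCRAC on either strand).
Cells whose variants all create MmeI sites, and poorly covered cells, are
excluded from analysis.

Downstream, per-position 20-value substitution profiles are compared across
orthologues by Pearson correlation over four position sets (identical WT,
structurally aligned, aligned with non-identical WT, four-fold symmetric),
tested against the all-pairs null by two-sample Kolmogorov–Smirnov tests;
distributions of fitness effects over structural strata are compared by a
permutation test on the beneficial fraction; "transformative" mutations
(substitutions to another orthologue's WT residue) probe epistasis; and PCA
of the 80 × 20 score matrices (experimental *s*, or log amino-acid
frequencies from alignments) separates the major sources of fitness
variance.

## Worked example

```r
library(empiricscan)
library(SummarizedExperiment)

design <- randomScanDesign(nLibraries = 8, seed = 1)  # 8 x 10 positions
config <- simulationConfig(depth = 1e5, seed = 2)     # 8 time points, 4 doublings
counts <- simulateGrowthCounts(design, config)
fl     <- estimateLandscape(counts, design)
fl
#> FitnessLandscape: 80 positions x 21 outcome classes
#>   analysed cells: 1678 of 1680 ( 2 excluded )
#>   per-library stop-mean raw fitness: -1.01, -1.04, -1.01, -0.991, -0.961, -0.989, -0.998, -1.01

st <- landscapeStats(fl)
round(100 * c(deleterious = st$fracDeleterious, beneficial = st$fracBeneficial), 1)
#> deleterious  beneficial
#>        57.1        19.8

s  <- selCoef(fl); tr <- assays(fl)$trueS; ok <- !is.na(s) & !is.na(tr)
cor(s[ok], tr[ok])
#> [1] 0.998
```

The landscape summary says most simulated mutations are strongly deleterious
(*s* < −0.75) with a minority beneficial — the bimodal distribution of
fitness effects the generator emulates — and that the estimator recovers the
generating truth almost perfectly at this depth. Comparing two orthologues
from the correlated-trio generator:

```r
trio <- simulateLandscapeTrio(nPositions = 80, rho = 0.6, seed = 3)
A <- trio$landscapes$orthA; B <- trio$landscapes$orthB
al <- buildPositionSet(A, B, "aligned", map = trio$maps$AB)
nl <- buildPositionSet(A, B, "null_all_pairs")
dA <- correlationDistribution(A, B, al, "aligned")
dA
#> CorrelationDistribution [aligned]: 80 R values (0 skipped), mode 0.58, policy exclude_both_wt
compareDistributionsKS(dA, correlationDistribution(A, B, nl, "null_all_pairs"))$p
#> [1] 0   # D = 0.879: aligned positions are far from the all-pairs null
```

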