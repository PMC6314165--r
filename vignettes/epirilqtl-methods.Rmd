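---
title: "Methods: epigenotype-to-phenotype inference in epiRIL populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epigenotype-to-phenotype inference in epiRIL populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epirilqtl)
```

## The population model

epiRILs are inbred lines derived from a cross between Col-0 and the
hypomethylated *ddm1-2* mutant; after backcrossing and selfing, each line
carries a mosaic of parental methylation states over a near-identical DNA
sequence. Differentially methylated regions act as codominant two-allele
markers (`COL` / `DDM1`), so linkage analysis proceeds exactly as in a
RIL, with two homozygous genotype classes and no heterozygotes.

Along each chromosome the package models the epigenotype as a two-state
Markov chain in map distance. The switch probability over a gap of $d$ cM
follows the Haldane map function $r(d) = (1 - e^{-2d/100})/2$. Because
the backcross design biases the population toward Col-0 epialleles, the
stationary DDM1 frequency $p$ is not 1/2; the chain therefore uses
detailed-balance transitions $P(\mathrm{COL}\to\mathrm{DDM1}) = 2rp$ and
$P(\mathrm{DDM1}\to\mathrm{COL}) = 2r(1-p)$, which reduce to $r$ at
$p = 1/2$ and keep the marginal DDM1 frequency at $p$ everywhere. The
second eigenvalue of the transition matrix over $d$ cM is
$\lambda(d) = e^{-2d/100}$, which composes multiplicatively across gaps;
conditional genotype probabilities at pseudomarkers (given the nearest
observed flanking markers) follow directly, and the adjacent-marker
concordance has the closed form $1 - 4rp(1-p)$ used in the tests. By
default $p$ is estimated from the observed calls; 0.3 is the generator's
default, reflecting the design bias.

## Interval mapping and significance

`hk_scan()` is Haley-Knott regression: ordinary least squares of the
trait on the expected DDM1 probability at each position, optionally with
marker cofactors (a multiple-QTL model). The LOD is
$(n/2)\log_{10}(\mathrm{RSS}_0/\mathrm{RSS}_1)$, with the null model
retaining the cofactors but not the position term. Cofactors within
10 cM of the test position are excluded there (the window is an argument;
10 cM is the conventional choice for composite interval mapping and is
not derivable from first principles). A cofactor collinear with the test
position is dropped from both models rather than zeroing the scan.
Cofactor selection (`select_cofactors()`) starts from evenly cM-spaced
candidates and removes the least significant one until all partial-F
p-values fall at or below `drop_alpha = 0.02`.

Genome-wide significance comes from permuting trait values across lines
while keeping epigenotype rows intact, preserving marker linkage
disequilibrium. The threshold is the empirical $(1-\alpha)$ quantile
(type-7) of the per-permutation maximum LOD; defaults are 1000
permutations and $\alpha = 0.05$. For the no-cofactor case the
permutation scan is computed by correlation-matrix algebra
(LOD $= -(n/2)\log_{10}(1-r^2)$), which is the same estimator as the
general path and makes the calibration experiments cheap. Missing trait
values are dropped pairwise, never imputed.

Peaks are local maxima at or above the threshold, accepted greedily
(highest first) with a 10 cM minimum separation. The support interval is
the contiguous run with LOD within 1.5 of the peak, extended outward to
marker positions — the conventional 1.5-LOD confidence region. The effect
sign is $\mathrm{sign}(\bar y_{COL} - \bar y_{DDM1})$, so a negative
sign means increased trait values in ddm1-derived epigenotypes.

## Methylation scoring and the cis funnel

Probe methylation is scored from the posterior probabilities of the
unmethylated and methylated states as $ml = -post(U) + post(M)$, a score
in $[-1, 1]$. Scores in $[-1, -0.3)$ are hypomethylated and $[-0.3, 1]$
methylated; the boundary $-0.3$ is assigned to the methylated side, and
region scores are probe means over promoter, gene body, or the 1 kb
downstream window. The promoter is 1000 bp upstream of the TSS,
strand-aware and clipped at chromosome ends; the extent is configurable
because no canonical value exists for this analysis.

The cis funnel evaluates, per gene inside a QTL support interval and
with short-circuiting: (optional) pathway membership from a local
two-column table; methylation-trait association — linear regression of
the log10 trait on the continuous region score, two-sided t-test on the
slope, significant if any of the three regions has $p \le 0.05$ (a
binary-state two-group test is available by flag; regression is the
default because the continuous score retains more information); and
cosegregation of the best region's binary state with the peak-marker
call — a 2x2 chi-square without continuity correction, switching to
Fisher's exact test when any expected cell is below 5, with $p = 1$ and a
degenerate flag when a margin is zero. No multiple-testing correction is
applied by default, matching raw per-gene reporting at $P < 0.05$;
Benjamini-Hochberg is available via `knockout_compare(adjust = "BH")`
and the same convention holds there. Survivors are ranked by DMR
position with weights promoter:body:downstream = 3:2:1 plus one point
each for a TE within 1 kb and for supplied expression evidence; the
weights encode an ordinal preference, not a calibrated quantity. Funnel
counts are monotone non-increasing across stages by construction.

Stage comparisons use $p \le \alpha$, so $\alpha = 1$ disables a stage
and $\alpha = 0$ empties the funnel — convenient boundary behaviour for
testing.

## Trans discovery

Candidate trans targets must pass five criteria: promoter probes exist;
the binary methylation calls vary across the epiRILs; the parents are
polymorphic at those probes; at least two consecutive promoter probes
(adjacent in genomic order) correlate with the QTL peak-marker coding,
each at $p < 0.05$ and with the same sign; and the gene lies outside the
QTL interval (cM projected to bp by linear interpolation between the
flanking markers' DMR midpoints).

For passing genes, `find_match_segments()` enumerates every maximal
exact match of at least 21 nt between the promoter and the QTL region,
forward and reverse-complement, via seeded extension; an exhaustive
all-substring oracle verifies it over thousands of random and planted
cases in the tests. The physical QTL region spans the DMR intervals of
all markers inside the support interval, so a sharp peak still
contributes at least its own DMR. Segments are decomposed into all 21-24
nt windows on both strands ($\sum_k 2(L-k+1)$ windows for a segment of
length $L$); 21-24 nt spans the canonical plant sRNA size classes, 24 nt
being the RdDM class. AGO-loading scoring is a pluggable interface; the
default heuristic encodes the canonical sorting signals (24 nt with 5'
adenine scores AGO4 = 0.9; 21-22 nt with 5' uridine scores AGO4 = 0.1
with AGO6 = AGO9 = 0.4; all else 0.2) and stands in for a trained
classifier, which is outside this package's scope. Candidates passing
the 0.5 score cutoff are matched exactly (mismatch tolerance up to 2 by
flag) against WT and *ddm1* sRNA libraries in both orientations, and
annotated with TE proximity (strictly less than 1000 bp from a TE on
genome coordinates). The report ranks genes by eQTL colocalization (peak
inside the closed cM interval), library support, then best AGO score.

## The synthetic-data generator

The generator emulates the study design at desk scale: 126 DMR markers
on five chromosomes (4 cM spacing, 1 kb DMR every 2 kb), stationary DDM1
frequency 0.3, planted fractional QTL effects spanning 4-41% (a
fractional effect $f$ shifts the log10 intensity of the DDM1 group by
$\log_{10}(1+f)$, so the raw-scale group ratio is $1+f$), four
measurement batches with mean-zero log-scale offsets removed exactly by
batch correction, residual log10 noise of 0.1, a 5% per-line-per-DMR
reversion of DDM1 epialleles to WT-like methylation, probe posteriors
with truncated Gaussian noise (SD 0.05), transgressive metabolites
present only under a two-marker DDM1 combination, one flowering-time
marker (25 d baseline, +5 d effect) driving designated pleiotropic
traits, trans targets whose promoters carry exact repeat segments from
QTL intervals within 1 kb of an annotated TE, and sRNA libraries tiling
those repeats with *ddm1* counts Poisson-depleted 10-fold. Values below
1% of a metabolite's median are treated as undetected. Where the study
design does not pin a value (reversion rate, noise scales, batch count,
detection floor), the defaults are one-time choices of plausible
magnitudes for untargeted LC-MS data on inbred lines, and all are
configurable.

What the generator does *not* emulate: pedigree structure (it models
marginal frequencies and linkage, not the backcross-selfing genealogy),
raw MeDIP hybridisation or bisulphite reads (posteriors are the input),
LC-MS peak picking and alignment, correlated metabolite families, or
genome-scale sequence complexity (background sequence is i.i.d. random,
which makes spurious 21-mer matches essentially impossible — real
promoters share repeats far more often). Passing recovery tests
therefore demonstrates correctness of the inference machinery under the
stated model, not performance on real arrays or chromatograms.

## Numerical choices and degenerate inputs

All genomic intervals are 0-based half-open internally; GFF3 import and
export convert explicitly. A constant trait or zero-variance regressor
yields LOD 0 rather than an error; correlations are clipped to
$[-1, 1]$; an RSS of zero is floored at the smallest double. The
quantile estimator for permutation thresholds is R's default type 7.
Single-sample batches correct to exactly 1, and an all-missing
(metabolite, batch) cell stays missing with a warning. Every generator
and the pipeline are pure functions of (configuration, seed); reruns are
byte-identical, and `write_results()` records the seed and a
configuration hash in a manifest.

The test suite runs its heavier experiments at sizes chosen to keep the
whole suite around two minutes on one CPU: 500 null traits with 1000
permutations each for the type-I calibration, 200 simulations for
interval coverage, n = 2000 for effect-ratio recovery, and 1000 random
sequence pairs (up to 200 bp) against the brute-force match oracle.

## Scope and limitations

The package does not call methylation from raw data, does not retrain an
AGO-loading classifier, and performs no multi-QTL model averaging or
epistasis scan. The cofactor seeding used in the original composite
interval mapping workflow is not reconstructable from a published marker
list, so evenly spaced candidates plus backward elimination stand in.
The trait-pair statistic reported for shared pleiotropy regions is a
correlation t-test, labelled as such. The command-line entry points of a
production deployment are deliberately thin: the exported functions,
`run_pipeline()`, and this vignette are the interface.
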