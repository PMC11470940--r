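---
title: "Methods behind baokit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind baokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baokit)
```

baokit implements the downstream characterization stages of a polyploid
plant genome project — ploidy inference, k-mer genome profiling, LTR
retrotransposon dynamics, satellite/telomere topography, Ks-based dating of
whole-genome multiplication (WGM) with syntenic retention, and population
structure — together with simulators that generate every input with
recorded ground truth.  This vignette explains each model, the tunable
parameters and their defaults, the numerical choices, and what the
simulators do and do not emulate.

## Why simulators are first-class

The quantities this pipeline produces on real data (genome sizes in the
hundreds of Mb, solo:intact ratios, weighted Fst between wild populations)
depend on sequencing data far beyond desk scale.  Every analysis stage is
therefore paired with a generator that plants a known truth — ploidy and
per-site dosage, genome size and heterozygosity, solo/intact/decoy labels,
monomer and tract lengths, synonymous distances, the Balding–Nichols F,
per-gene copy numbers — so that correctness is established by recovery of
planted parameters rather than by comparison to irreproducible numbers.
All generators draw from a private RNG stream seeded explicitly and restore
the caller's RNG state, so results are byte-reproducible and never depend
on global state.

What the simulators do **not** emulate: read-level error profiles and
mapping artifacts (allele depths are clean Poisson/Binomial draws), linkage
disequilibrium and demography beyond the island-model covariance of
Balding–Nichols, TE nesting and fragmentation, satellite library turnover,
and codon usage or transition/transversion bias in coding sequence.
A green suite therefore shows the estimators are correct under their
stated sampling models, not that those models capture every pathology of
real libraries.

## Allele-balance ploidy inference

At a heterozygous biallelic site with alternate-allele dosage $d$ in a
ploidy-$P$ individual, the fraction of reads carrying the alternate allele
concentrates around $d/P$.  A diploid therefore shows one allele-balance
peak at $1/2$; an autotetraploid shows folded peaks at $1/4$ and $1/2$.

`sim_allele_depths()` draws total depth from Poisson(`mean_depth`),
dosage from `dosage_weights` over $1..P-1$ (uniform by default: class
proportions at heterozygous sites are not observable a priori, and the
uniform choice is the maximum-entropy default), and alternate reads from
Binomial with success probability $d/P$ perturbed by a symmetric error
rate (default 0.001, a post-filtering short-read error scale).

`histogram_modes()` folds fractions to the minor allele, bins at 0.02,
smooths with a 3-bin moving average, and reports local maxima with height
at least 10% of the tallest bin, merging modes closer than 0.05.  The
folded fraction is computed as `min(ref, alt) / (ref + alt)` directly from
the depths, which makes the histogram exactly invariant under swapping the
two alleles (computing `1 - f` in floating point does not).

`classify_ploidy()` follows the fixed-mean mixture convention of
allele-balance ploidy tools: for each hypothesis $P$ a Gaussian mixture
with means fixed at $i/P$, shared variance and free weights is fitted by
EM (200 iterations maximum, tolerance $10^{-6}$ on the log-likelihood,
variance floored at $10^{-4}$) on the unfolded fractions, and compared
with a free 3-component mixture fitted by the same EM.  The called
hypothesis minimizes $\log L_{free} - \log L_{fixed}$ **plus a BIC-style
penalty** of $(P-2)\log(n)/2$ for the extra free mixture weights.  The
penalty matters: with 20,000 diploid sites at depth 60, the tetraploid
model can park a weight of order $10^{-4}$ on its $1/4$ component and
absorb the ~30 deepest binomial tail sites, beating the diploid model by
about 1.5 log-units essentially every time.  Penalizing its two extra free
weights by $\log(n)/2 \approx 5$ each removes this artifact while leaving
genuinely tetraploid data (where the gap is thousands of log-units)
untouched.  Raw comparison is available via `penalty = "none"`; ties break
toward the smaller ploidy.

The depth window of `extract_allele_balance()` defaults to minimum site
quality 20, minimum depth 20 (below which allele-balance peaks blur
together) and maximum depth three times the median (a guard against
collapsed repeats masquerading as heterozygous sites).

## K-mer genome profiling

`fit_spectrum()` is a deliberately simple peak-based model of the standard
k-mer survey geometry, not a reimplementation of a full mixture-model
fitter.  The error cutoff is the first rise of the 3-bin-smoothed counts;
the homozygous peak is the dominant mode above it; haploid genome size is
above-cutoff mass divided by the homozygous peak depth; k-mers deeper than
1.5x the homozygous peak are repeat-derived and their mass defines
`repeat_bp` (so a genome in which a fraction $r$ of positions belong to
duplicated sequence reports `repeat_fraction` $\approx r$).
Heterozygosity comes from the distinct-k-mer balance between the
half-depth and full-depth peaks: with $f$ the fraction of
haplotype-specific distinct k-mers, $h = 1 - (1-f)^{1/k}$.

One genuine ambiguity deserves note: a heterozygosity-dominated spectrum
(mode at half the homozygous depth, homozygous peak at twice the mode) and
a repeat-heavy spectrum (mode at the homozygous depth, repeat peak at
twice it) have the same two-peak geometry.  `fit_spectrum()` resolves it
by asking whether the "het" interpretation implies a plausible
heterozygosity ($\le 0.055$, just above the simulator's legal range); a
repeat peak's distinct-k-mer balance implies far more.  Genomes where more
than roughly 60% of k-mer mass is two-copy repeat would still be
mis-resolved — at that point a parametric fitter is the right tool.

## Solo/intact LTR dynamics

Solo LTRs — single long terminal repeats left behind by intra-element
recombination — are identified from homology-method LTR annotations by six
filters applied in a fixed order, the first failure being recorded:
length $\ge$ 100 bp; identity to the reference LTR $\ge$ 0.8; alignment
score $\ge$ 300; no shared element ID among the four nearest flanking
LTR-RT annotations (two per side, same chromosome; chromosome ends simply
have fewer neighbors); distance $\ge$ 5000 bp to the nearest adjacent
annotation; and length within the 95th percentile of intact-element LTR
lengths, computed genome-wide (a per-family percentile would need family
assignments the annotation does not reliably carry).  The pass/fail
verdict is order-independent — only the recorded first violation depends
on the order — which the suite verifies against an all-rules evaluation.
Identity absent from the annotation fails the identity rule
(conservative), and the alignment score is read from the annotation, not
recomputed, since the original scoring scheme is not recoverable from the
GFF alone.

Insertion ages use the divergence of an element's two LTRs, which are
identical upon insertion: raw p-distance over ungapped columns,
Jukes–Cantor corrected ($d = -\tfrac34\ln(1 - \tfrac43 p)$, undefined at
$p \ge 0.75$), and age $= d / (2\mu)$ with $\mu = 4.72\times10^{-9}$
substitutions per site per year by default.  JC correction is the default
because p-distances on Myr-old elements are already in the
multiple-hit regime; `correction = "raw"` reproduces uncorrected
clock arithmetic.

## Repeat topography

`detect_tandem_structure()` scores each candidate period $p$ (default
50–1000 bp, covering typical plant centromere monomers and their
higher-order repeats) by the mean per-base identity between the sequence
and itself shifted by $p$.  The monomer is the smallest local maximum
within 2% of the global maximum, refined to sub-bp precision by parabolic
interpolation; periods scoring below 0.6 everywhere mean "no tandem
structure" (a result, not an error).  A higher-order repeat is reported at
a multiple $q \cdot m$ when its score exceeds the monomer score by more
than 0.005: in a plain array the shift-identity at $2m$ equals that at
$m$, while alternating divergent monomer variants depress the monomer
score by their pairwise divergence, leaving the HOR period strictly
higher.  Scoring uses at most 100 kb from the center of the input, which
leaves the estimate unchanged on arrays long enough to matter while
bounding cost.

`identity_heatmap()` tiles the sequence into windows (default 5 kb) and
maps k-mer Jaccard similarity (k = 15) to approximate per-base identity
through the Mash distance transform — the standard sketch shortcut for
satellite dot-plot-style heatmaps.

`measure_telomeres()` extends from each sequence end through consecutive
copies of the telomere motif, accepting any circular permutation of the
motif or of its reverse complement, allowing one mismatch per copy by
default and stopping after two consecutive failing copies.  The default
motif is the 7-mer `AAACCCT`; the 6-mer spelling `AAACCT` that also
circulates for plant telomeres is accepted by passing it explicitly.
Tract length is exact on mismatch-free tracts and within one motif copy
under 1% substitution noise.

## Ks, dating, synteny and retention

`compute_ks()` implements Nei–Gojobori (1986) with the standard genetic
code: per-codon synonymous site counts exclude mutations to stop codons
from the site denominator; differences at multi-hit codons are averaged
over all mutational pathways, excluding pathways through stop codons
unless all are blocked; $S$ is averaged over the two sequences; and
$pS = S_d/S$ is Jukes–Cantor corrected.  $pS \ge 0.75$ yields a
`saturated` flag with infinite Ks rather than a number.  NG86 with equal
pathway weighting was chosen over maximum-likelihood codon models because
the downstream use — locating Ks peaks — needs an unbiased, fast,
assumption-light distance, and the simulator can plant exact NG86 truths.
Codon alignment is an input contract; `align_codons()` provides a
convenience global aligner on translated sequences (match 1, mismatch -1,
gap -2) back-threaded to codons.

`sim_paralog_cds()` builds coding sequence from fourfold-degenerate codon
families chosen so every codon carries exactly one synonymous site (the
Leu/Arg families with synonymous first positions are excluded), then
applies the number of third-position substitutions whose realized Ks is
nearest the target; targets unreachable at the given codon count are
rejected rather than approximated.

`ks_peaks()` runs a Gaussian kernel density over $(0, 3]$ and reports
local maxima with at least 10% of the peak density, merging micro-modes
closer than twice the bandwidth.  `ks_to_time()` is the exact transform
$T = K_s / (2r)$ with $r = 6.56\times10^{-9}$ per site per year by
default.

`chain_anchors()` is a deliberate simplification of MCscan-style
collinearity: per chromosome pair and orientation, a dynamic program finds
the longest chain of anchors monotone in both genomes with rank gaps at
most `max_gap_genes` (default 20) on both sides; blocks are extracted
greedily best-first, each anchor joining at most one block, and chains
shorter than `min_anchors` (default 4) are dropped.  Chain score is anchor
count with no distance penalty; ties are resolved to the lexicographically
smallest chain of (query, target) ranks and then to the forward
orientation, making the output bit-reproducible and directly comparable to
exhaustive enumeration on small instances (which the suite does, 200
random instances of up to 15 anchors).

`depth_and_retention()` counts, per query gene, the number of blocks
containing an anchor for that gene.  Membership rather than block-span
coverage is deliberate: after a WGM, target chromosomes are near-complete
collinear copies, so every gene sits inside the span of all blocks and
span-coverage would read depth 5 everywhere; membership recovers the
planted copy-number profile exactly, including the depth-0 (fully
fractionated) class, and matches per-gene depth semantics of collinearity
toolkits.  The headline ratio is the modal non-zero depth, reported as
"d:1".

## Population structure

`weighted_fst()` computes the Weir–Cockerham (1984) per-locus variance
components $a$ (among populations), $b$ (among individuals within
populations) and $c$ (within individuals), with observed heterozygosity
from the genotype calls, and reports $\sum a / \sum(a+b+c)$.  The
estimator is defined for diploid calls, so tetraploid dosages are
diploidized by default (0..4 mapped half-up to 0/1/2) — mirroring the
standard caveat that Fst is a diploid-model statistic — with a
frequency-based Hudson estimator (`method = "hudson"`) as the
ploidy-agnostic alternative.  Loci with undefined components (e.g.
monomorphic) are excluded and counted.  `sim_genotypes_bn()` draws
population frequencies from the Balding–Nichols Beta law, whose $F$
parameter equals expected Fst — giving the estimator a closed-form
recovery target.

`genotype_pca()` drops loci with more than 20% missing dosages,
mean-imputes the rest per locus, removes zero-variance loci and
decomposes the column-centered matrix by SVD (optional
$\sqrt{p(1-p)}$ standardization).

`local_pca_partition()` summarizes each window (3 kb genomic span by
default, or a fixed SNP count — the windowed-PCA literature uses SNP
windows and genomic spans interchangeably, so both are exposed) by the
rank-2 eigenstructure of its centered sample covariance, eigenvalues
normalized to unit total; window dissimilarity is the Frobenius norm
between rank-k approximations; classical (Torgerson) MDS embeds the
windows, truncating negative eigenvalues at zero.  Outliers are windows
farther than the median plus three median-absolute-deviations from the
medoid window; they are grouped by average-linkage clustering cut at the
outlier threshold (capped at three clusters) and labelled LS1–LS3 by
decreasing size.  Windows with fewer than $k+1$ polymorphic loci are
skipped and counted.

## Problem sizes and numerical conventions

The test suite exercises the pipeline at sizes chosen to make sampling
noise negligible relative to each stated tolerance while keeping a full
run in a few minutes: 50,000 sites for histogram mode structure, 100
replicates per ploidy at 20,000 sites for classifier accuracy, 1 Mb
genomes for k-mer size recovery, 3,000 genes for retention profiles,
50 replicates per $F$ at 2,000 loci for Fst bias, and 200 random
instances for chaining optimality.  Throughout the package, coordinates
in annotations are 1-based inclusive (GFF3 convention) and exported
interval files are 0-based half-open (BED convention); all tie-breaks
(mode merging, EM initialization, chain selection, peak ordering) are
deterministic so that equal inputs give byte-equal outputs.

## Known limitations

* The k-mer model is peak-based; heavily repetitive (> ~60% duplicated
  mass) or high-ploidy spectra need a parametric fitter.
* The ploidy classifier assumes a single sample with one dominant ploidy;
  mosaicism and aneuploidy are out of scope.
* Anchor chaining has no gap or distance penalty, so extremely sparse
  collinear signals chain more readily than under MCscan scoring.
* Fst on tetraploids via diploidization is an approximation; the Hudson
  mode avoids the genotype model but ignores individual-level structure.
* Insertion-age and Ks dating inherit the calibration uncertainty of
  their substitution rates; both are exposed as parameters.
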