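---
title: "Models and methods behind ribovar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ribovar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`ribovar` analyses multi-individual, multi-replicate ribosome profiling and
RNA-seq studies: which genes differ between individuals at the RNA level,
which at the level of ribosome occupancy (RO), how translation efficiency
(TE) links the two to protein levels, and which 5′ UTR variants — upstream
open reading frame (uORF) changes and Kozak-context changes — act
specifically on translation. This vignette explains the models, the
tunable parameters, the synthetic-data generator used for validation, and
the numerical and design choices, in that order.

## Normalization

Counts are filtered on counts-per-million (cpm > 1 in at least 90% of the
libraries of *each* assay; both the threshold and the fraction are
arguments). The 90% figure generalizes absolute library counts used at
study scale to any synthetic design size. TMM scaling factors are computed
by `edgeR::calcNormFactors` over a single pool containing both assays
(trim fractions 0.30 on M, 0.05 on A; factors have geometric mean 1).
Pooling the assays is a deliberate choice: TE estimation contrasts ribo
against RNA libraries, so both must sit on one common scale. A
`per_assay = TRUE` switch normalizes each assay separately for users who
prefer within-assay references.

The voom transform (`limma::voom`) produces
`log2((count + 0.5) / (libsize · factor + 1) · 1e6)` and observation-level
precision weights from a lowess mean–variance trend, with the
individual-by-assay cell means as the design so replicate libraries of the
same individual do not inflate the residual variance. Weights are floored
at `1e-4`. These weights are treated as *fixed known precisions* by every
downstream model.

## Translation efficiency

Per gene, a weighted least-squares model regresses log2-cpm on individual
indicators plus a per-individual ribo-contrast indicator:

$$y_{gl} = a_{g,i(l)} + t_{g,i(l)}\,\mathbf{1}[\text{assay}(l)=\text{ribo}] + e_{gl}.$$

Because each individual's parameters touch only that individual's
libraries, the fit decouples: $\hat t_{g,i}$ is the weighted mean ribo
log2-cpm minus the weighted mean RNA log2-cpm of individual $i$, with a
residual variance pooled over the whole gene. This cell-means + contrast
parameterization was chosen over a common-assay-effect model because it
makes each individual's TE directly readable as a coefficient; the global
TE — the precision-weighted mean of the per-individual TEs — coincides
with the generalized least-squares estimate of a single common contrast,
so the common-assay-effect model is available implicitly (`te_global`) and
is the quantity used in the Kozak per-position tests. The residual
variance cancels from the precision weights of that mean, which keeps the
global TE defined even for degenerate zero-residual fits.

## Inter-individual variance components

For one gene and one assay, the model is a Gaussian one-way random-effects
model with known observation precisions $w_{ij}$:

$$y_{ij} = \mu + b_i + e_{ij},\quad b_i \sim N(0, \sigma^2_{\text{ind}}),
\quad e_{ij} \sim N(0, \sigma^2_{\text{res}}/w_{ij}).$$

Fitting is by maximum likelihood (not REML), with
$\sigma^2_{\text{ind}} \ge 0$ constrained to the boundary. For fixed
variance ratio $\lambda = \sigma^2_{\text{ind}}/\sigma^2_{\text{res}}$ the
profile over $\mu$ and $\sigma^2_{\text{res}}$ is analytic (Woodbury
identity on the per-individual compound-symmetric blocks), so the fit is a
one-dimensional maximization: a coarse log-spaced grid over
$\lambda \in [10^{-4}, 3.4\times10^7]$ followed by golden-section
refinement (tolerance $10^{-9}$ relative). The wide upper end matters for
near-noiseless data, where the optimal ratio is huge. The implementation
is compiled code; the test suite checks it against a dense-matrix
likelihood maximized on a fine grid.

Because the usual $\chi^2_1$ asymptotics fail on the boundary (the null
law is approximately the mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$), the test of
$\sigma^2_{\text{ind}} = 0$ uses a finite-sample simulation: the LRT
statistic is invariant to location and scale, so its exact null law for a
given design and weight vector is obtained by simulating
$y^*_{ij} \sim N(0, 1/w_{ij})$, refitting both models, and using the
add-one estimator $p = (1 + \#\{T^* \ge T\})/(1 + B)$, which can never
return 0 and returns exactly 1 when the observed statistic sits at the
boundary. A parametric-bootstrap null was preferred over a spectral
fast-simulation algorithm because it is exact by construction and easy to
audit. The default $B$ is 10,000; note that the attainable minimum p-value
is $1/(B+1)$, so $B$ must exceed (number of genes)/$\alpha$ for a Holm
correction to be able to reject at all — the pipeline default of 10,000
supports families of up to ~500 genes at $\alpha = 0.05$.

Holm correction is applied separately per assay; genes are classified
`none / rna_only / ribo_only / both`, and `both` genes get a dominance
subset by the ratio of estimated individual variances with a labeled
default threshold of 2 (the dominance rule is a package choice, not an
inferred convention).

## uORF analysis

A uORF initiates at ATG or CTG strictly upstream of the annotated start
and ends at the first in-frame UAA/UAG/UGA. CTG starts are scanned
identically to ATG (a deprioritization switch exists but is off). Stops
may lie inside the CDS; such uORFs carry an `overlaps_cds` flag rather
than being dropped, because both conventions exist in the literature —
`require_stop_in_utr5 = TRUE` selects the stricter one. No minimum length
is imposed beyond start + stop (a `min_length` argument exists).

Per transcript, every observed haplotype allele combination over the UTR
variants is materialized as a sequence, scanned, and reduced to a
canonical configuration signature. Haplotypes sharing a changed signature
are pooled into one *event* — so two different SNVs that each ablate the
same stop codon, merging two uORFs, contribute carriers to a single event.
Event types come from set comparison of (start, stop) pairs: `gain`,
`loss`, `premature_stop`, `merge` (an extension that reaches at/past the
stop of another reference uORF), `stop_loss_extension`, `other`.
`defining_variants` lists only alleles whose removal from a carrier
haplotype changes its configuration, excluding passenger alleles. Events
carried by fewer than 3 individuals are dropped; the default of 3 mirrors
the minimum-carrier convention used for Kozak variants, applied here for
symmetry.

Association uses two routes per event: weighted OLS of per-library RO
log2-cpm on dosage (0/1/2 haplotypes with the configuration), and a
conservative linear mixed model with an individual random intercept
(libraries of one individual as technical replicates; Wald p). BH FDR at
5% over events; the same regression on RNA sets the
translation-specificity flag (RNA nominal p > 0.05 or opposite-signed
coefficient).

## Kozak analysis

The Kozak region is the 6 nt before the start codon plus nt +4 and +5
(+1 = A of AUG). The PWM accumulates counts over all transcripts with a
long-enough UTR, adds a pseudocount of 0.5 per cell, and takes log2 odds
against a uniform background; pseudocount, log base, and background are
all explicit arguments because no single convention dominates, and both
probabilities and log-odds are emitted. The start codon itself is excluded
from the PWM and from variant scoring: a start-ablating variant belongs to
CDS-disruption analysis, not context scoring.

Per-position effects on TE use Kruskal–Wallis across nucleotide groups on
the global TE (one value per gene — the test concerns transcripts, not
individuals), Bonferroni-corrected for the 8 positions; positions with
fewer than two observed groups return NA but still count in the ×8.
Variants are scored by the log-odds difference at their position
(additive across positions by construction), individuals by
$\sum_v \Delta\text{PWM}_v \cdot \text{dosage}_v$; association mirrors the
uORF procedure but at 10% BH FDR with a stricter RNA threshold (nominal
p > 0.01), both stated levels of the procedure being reproduced.

## Integration: ranks, SOM, affinity propagation, protein correlation

RO, RNA, TE and protein level are each converted to percentiles by their
empirical CDF over genes, which equalizes scale and variance before
distance-based learning. The SOM is the classic online algorithm on a
hexagonal 14×10 grid (140 units; both dimensions are arguments, the
aspect ratio being a labeled choice), codebook initialized by sampling
data points, Gaussian neighborhood with linearly decaying radius (from
2/3 of the grid diagonal to 0.1 — effectively best-matching-unit-only fine
tuning at the end) and learning rate 0.05 → 0.01 over 100 epochs. All
randomness (initialization, presentation order) is drawn on the R side
under one seed, making training bit-reproducible. Affinity propagation
runs on negative squared Euclidean distances between codebook vectors with
median-similarity preference and damping 0.9, iterating responsibilities
and availabilities until exemplars are stable for 50 iterations (cap
1,000); the per-cluster summary reports each exemplar unit's mean rank in
the four measures and the gene count — the cluster-level view of how RNA
level and TE combine into protein level.

Per-gene expression–protein Spearman correlations across individuals
(minimum 8 shared individuals, BH FDR 5%) can be stratified by the
variability classes, reproducing the logic of comparing correlation
distributions between variable and non-variable genes.

## cis-QTL and enrichment

cis-QTL mapping regresses replicate-averaged expression on 0/1/2 dosage
per gene × variant, restricted to MAF > 10% in the caller-supplied panel
(unrelated individuals by design). BH FDR is used and labeled as a
package decision, since the upstream convention is not specified at this
level; a permutation switch is not provided in this release. Enrichment
uses one-sided Fisher tests (hypergeometric tail) with Haldane 0.5
correction for zero cells, a min-p permutation family-wise adjustment
(random same-size queries from the background; add-one estimator; clamped
from below by the raw p so the discrete permutation atoms cannot undercut
it), significance = odds ratio > 2 and adjusted p < 0.05, and a term graph
of kappa similarities > 0.1 between significant terms.

## The synthetic-study generator

The generator is first-class, tested code, and its defaults are the study
conditions used everywhere: 30 individuals, 3 RNA-seq + 2 ribosome
profiling replicates each, negative-binomial counts with per-gene
log-normal dispersion around 0.05, per-gene baselines
$\log_2\text{cpm} \sim N(5, 1.5^2)$, library sizes log-uniform over a 3×
range (to exercise TMM), 20% of genes RNA-variable and 10% RO-variable
(independent draws; the overlap forms the `both` class) with individual
effects of SD 0.8 log2 — about twice the replicate-level SD at these
depths — and protein per individual generated as
`2 · rank-percentile(true RO) + N(0, 0.5)`.

Sequences follow a constrained grammar: 5′ UTR pads use only A/C, so
start and stop motifs exist exactly where planted, making the planted
architecture the provable ground truth for the scanner; Kozak regions are
drawn from an A/C/G consensus-like composition (no T, so they cannot
create motifs), and A at −3 adds 0.3 log2 to the gene's TE, planting the
strongest known context effect as recoverable structure. Each uORF event
class is planted at least once (the merge via two distinct stop-ablating
SNVs whose carriers pool into one event); planted effects (default |β| of
0.6–0.8 log2 per copy) act on ribosome-profiling libraries only. Kozak
variant alternates are chosen weakening with probability 0.65. Genotypes
are Hardy–Weinberg at MAFs uniform in [0.10, 0.40], phased, with 8%
emitted unphased to exercise the seeded phase randomization. Protein is
driven by RO (not RNA) so that the ordering "RO predicts protein better
than RNA" is planted, recoverable structure rather than an assumption of
the analysis.

What the generator does **not** emulate: read-level artifacts (alignment,
PCR duplicates, footprint periodicity), GC/length bias, batch structure,
linkage disequilibrium between variants, NMD coupling between uORF
changes and RNA levels, population stratification, and missingness in the
protein matrix. Passing tests therefore demonstrate correctness of the
statistical machinery and recoverability of planted effects under clean
count noise — not robustness to those real-data complications.

## Numerical choices and degenerate inputs

Indels and multi-allelic VCF records are excluded (SNV-only bookkeeping;
how such records were treated upstream is not stated, so exclusion is the
labeled choice), as are records whose REF disagrees with the transcript
sequence. All internal coordinates are 0-based half-open in transcript
orientation; VCF I/O converts at the boundary, and synthetic VCFs use one
contig per transcript so the genomic↔transcript map is the identity (a
plug-in map function is the interface for real annotations). Unphased
heterozygotes are assigned a haplotype uniformly at random under a
mandatory seed. Zero-variance predictors are skipped with a warning;
non-converging LMMs fall back to `p = NA`; genes whose variance-component
fit fails are reported with NA and excluded from the Holm family size.

## Problem sizes in the test suite

The suite validates each stage at sizes chosen to make the statistical
assertions sharp but quick: 1,000 random UTRs for scanner-oracle
equivalence, 1,000 null genes × 2,000 bootstrap draws for LRT calibration,
a 28-individual × 200-gene study for class recovery, 50 replicate studies
for association power and 25 for FDR calibration, 4×10⁴ uniform sequences
(10⁴ expected observations per PWM cell) for the log-odds
law-of-large-numbers check, and 20 seeds for SOM quantization
monotonicity. The full default pipeline runs end-to-end in about two
minutes on one CPU.

## Known limitations

Weights are conditioned on, not re-estimated, inside the bootstrap; the
LMM route reports Wald p-values (no Satterthwaite correction); isoform-
level TE, codon-level occupancy, kinship/stratification covariates, LD
pruning and trans effects are out of scope; and the enrichment stage
consumes flat term→gene maps rather than a full ontology graph.
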