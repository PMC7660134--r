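---
title: "Methods: models, parameters and design choices in subloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in subloc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subloc)
```

# Scope

`subloc` quantifies where mRNAs and proteins sit inside migrating cells,
from four kinds of evidence: paired protrusion/cell-body omics (3' mRNA-seq
counts and proteomic ratio panels), iCLIP crosslink data for a localizing
RNA-binding protein, pulsed-SILAC label dynamics, and RNA-FISH spot
statistics. Every stage consumes and returns plain tables (tibbles), so the
pipeline composes with ordinary dplyr verbs. A synthetic-data module
generates each input type with planted, recorded ground truth; all claims in
the test suite are made against those planted truths, never against external
data.

# Compartment ratios

`log2_ratio_table()` converts paired protrusion (P) and cell-body (B) raw
counts into per-gene log2 ratios. Steps, in order:

1. each library is scaled to counts per million (CPM) — compartment
   libraries differ in depth for technical reasons, and the ratio should not
   absorb that;
2. a pseudocount (default 1 CPM) is added to both compartments before the
   ratio, so dropout genes give large-but-finite ratios; for well-measured
   genes (hundreds of CPM) the perturbation is negligible;
3. genes with summed raw counts below `min_count` (default 10) are dropped
   per sample — 3' tag counting is sparse and ratios of a handful of reads
   are noise; the count of dropped genes is attached as an attribute;
4. optionally (default on), each sample's median log2 ratio is subtracted,
   the standard median-centering normalization for this assay, which removes
   residual global asymmetry between the fractions.

Both the CPM scaling and the median subtraction are recorded in the
function's attributes. Swapping the compartment labels negates every ratio,
and centering preserves all between-gene ratio differences; both properties
are tested.

# The rank-based enrichment kernel

Category localization calls use an adapted Wilcoxon–Mann–Whitney test: for
an annotation set of size $n_1$ inside a universe of $n$ ranked values, the
member rank sum gives $U$, and the enrichment score is the rank-biserial
correlation

$$s = \frac{2U}{n_1 n_2} - 1 \in (-1, 1),$$

which is $+1$ when every member outranks the whole complement. The test
itself names no score, so the rank-biserial was chosen for being bounded,
sign-interpretable and standard for this statistic. Ties get midranks.

**Exact vs approximate p-values.** When $n_1 n_2 \le 200$ the two-sided
p-value is exact: the null distribution of the member rank sum over all
$\binom{n}{n_1}$ assignments is computed by dynamic programming over doubled
midranks (doubling makes midranks integral, so ties are handled without
approximation); the two-sided p is twice the smaller tail, capped at 1.
Larger problems use the normal approximation with a 0.5 continuity
correction and the usual tie correction of the variance. The switch point
trades exactness where it is cheap for a stated approximation elsewhere; the
test suite checks the two branches agree to $|\Delta p| \le 0.01$ at
$n_1 = 10$, $n_2 = 40$.

**Families for FDR control.** `bh_fdr()` is a literal Benjamini–Hochberg
step-up. Correction runs across the categories of one enrichment call
(`annotation_enrichment_1d/2d`), and across the features of one
meta-analysis call (`one_sample_t_meta`) — matching how each reported figure
applies a single correction per analysis. When a single category is tested
in isolation its q equals its p. The default enrichment cut-off is
q < 0.02 and the minimum category size is 5 members inside the universe;
neither is dictated by the underlying test, so both are configurable and the
skipped sets are reported.

**Two-dimensional enrichment.** Each set is scored independently in two
value dimensions (e.g. knockdown response in protrusions vs in cell bodies);
a set is significant when either dimension passes BH at the cut-off. The
sign pattern of the two scores assigns a quadrant: same-sign quadrants are
read as an expression change throughout the cell, opposite-sign quadrants as
a mislocalization candidate (material moved between compartments).

`one_sample_t_meta()` tests each feature's log2 ratios across independent
samples against zero (two-sided Student t). Features with fewer than three
values are reported untested rather than silently dropped; zero-variance
rows are flagged degenerate with p set to 0 (nonzero mean) or 1 (zero mean).
`fisher_over_representation()` is the one-sided hypergeometric upper tail.

# Pulsed-SILAC accounting

Whole-cell pulsed-SILAC experiments use two reciprocally labeled replicates:
in one, the heavy label marks the open-pore (protrusion-forming) condition;
in the other, the medium label does. `translation_rate_ratios()` harmonizes
the orientation through an explicit per-replicate `label_scheme` column and
returns per-protein log2(open/closed); permuting the M/H intensities together
with the scheme is a tested no-op. Zero intensities propagate to missing
values, never to infinities. Proteins quantified in both replicates form the
main table; singletons go to a side attribute, since the replicate-vs-
replicate scatter is only defined for the intersection.

`compartment_fractions()` turns per-compartment iBAQ triplets into
percentages per label — old protein (L) and the two nascent labels (M, H)
are normalized independently, so each label's percentages sum to 100 and are
invariant to rescaling a protein's intensities. `nascent_vs_old_summary()`
compares old vs nascent nuclear percentages for a protein set with a
two-tailed, equal-variance two-sample t-test. The source protocol calls this
a "two-way t test"; it is implemented as the homoscedastic two-sample test
(the reading consistent with the protocol's other tests), and because it is
not stated whether proteins are pooled or paired, both variants are
reported.

`kd_proteome_shift()` derives log2(KD/NT) from spike-in-referenced H/L
ratios as $\log_2((H/L)_{NT} / (H/L)_{KD})$ — with a common heavy reference,
larger H/L means less endogenous protein — and hands the values to the
enrichment kernel.

# iCLIP processing

Read prefixes are 12 nt: three random W (A/T) bases, a 5-nt experimental
barcode, four random bases. The 7-nt UMI is the concatenation of the two
random parts. `demultiplex()` matches barcodes exactly (0 mismatches; the
upstream tool's tolerance is not documented, and with 5-nt barcodes one
mismatch already risks cross-talk). The crosslink site is the nucleotide
immediately 5' of the cDNA insert: `start − 1` on the plus strand, `end` on
the minus strand, in the package-wide 0-based half-open convention (one
convention everywhere eliminates off-by-one drift between crosslinks,
annotation and BED output). PCR duplicates collapse by distinct
(position, strand, UMI); the track count at a position is the number of
distinct molecules.

## Paraclu peak calling

For one chromosome and strand, the deduplicated track is a sparse count
vector. Scanning a density threshold upward yields a nested family of
maximal clusters; each cluster records the threshold at which it was born
from its parent (`min_density`) and the threshold at which it splits
(`max_density`), and the stability fold is their ratio. The implementation
is top-down: at each node, every gap between consecutive positions carries
two candidate boundary densities — the prefix side
$\sum_{i \le g} c_i / (p_{g+1} - p_{beg})$ and the suffix side
$\sum_{i > g} c_i / (p_{end} - p_g)$ — and the node splits at the weakest
gap. Numerical choices:

- **Tied weakest gaps are all cut at once.** Cutting only one (say, the
  leftmost) would make the family depend on chirality; the set of minimal
  gaps is invariant under strand mirroring, so the multi-cut keeps the whole
  pipeline exactly mirror-symmetric, a tested invariant. Ties are exact
  floating-point comparisons of rationals built from integer counts and
  integer spans, so they are reproducible.
- Density denominators are interval lengths in nucleotides under half-open
  coordinates; a single position has length 1 and an infinite split
  threshold.
- The root of each chromosome/strand is born at density 0, so its stability
  fold is infinite: an isolated locus with no competing structure is
  maximally stable.

Reported peaks satisfy the published filter set — in-cluster sum ≥ 10,
length ≤ 200 nt, fold ≥ 2 ("minimal density increase set to 2" is read as
the stability fold `max_density/min_density ≥ 2`, the standard
interpretation). Because surviving clusters can be nested, a flat peak list
is produced by keeping, within any overlapping chain, the cluster with the
**higher stability ceiling** (`max_density`; ties broken by shorter length,
then leftmost). The ceiling, not the fold, decides: the root's fold is
infinite by construction, so a fold rule would always prefer the loosest
enclosing interval over a sharply resolved peak inside it; preferring the
higher ceiling selects the densest stable representation of each locus.
This resolution is the package's own design choice (the published pipeline
reports flat peak counts without stating its rule) and is recorded in
output headers via the run log.

`subtract_control()` implements any-overlap subtraction (`intersect -v`
semantics, strand-aware): a peak overlapping a control peak by one
nucleotide is removed. `call_targets()` calls a gene when a specific peak
overlaps any of its annotated regions on the same strand; a peak spanning
two genes calls both and is flagged ambiguous. `region_distribution()`
assigns each peak by its midpoint — a peak straddling a boundary has no
defined region, and the midpoint is the least surprising deterministic rule
— with the 5'TOP window taking precedence: the first 15 nt downstream of
the TSS (the terminal oligopyrimidine tract spans 6–12 pyrimidines;
15 covers it with the start-position uncertainty), configurable.
`metaprofile()` aggregates counts at 1-nt resolution (no bin width is
stated upstream; 1 nt is the native resolution of truncation events) in
strand-oriented offsets, normalized to crosslinks per million of library
size.

# Imaging statistics

`polarization_index()` is the displacement of the (intensity-weighted)
signal centroid from the nucleus centroid, divided by the radius of gyration
of the signal about the nucleus centroid. The printed source formula
repeats the x-term twice; it is implemented as
$\sqrt{(\bar x_{RNA} - \bar x_{cell})^2 + (\bar y_{RNA} - \bar y_{cell})^2} / R_g$,
the evident intent. By Cauchy–Schwarz the index lies in [0, 1]; it is 0 for
balanced distributions, approaches 1 when all signal sits at one displaced
point, and is invariant under rigid motions and uniform unit changes (all
tested). When every spot coincides with the nucleus centroid, $R_g = 0$ and
the index is reported undefined rather than divided through. Whether pixels
are thresholded before the centroid is an upstream concern; centroids are
intensity-weighted by default with an unweighted variant behind a flag.

`spot_colocalization()` matches A-spots to B-spots greedily by increasing
distance within a radius, each spot used once, with index tie-breaks after
canonical coordinate ordering — deterministic and order-invariant (the
reference plugin's internal rule is unpublished; greedy nearest-neighbour is
the conventional reading). `compartment_signal_ratio()`,
`particle_density()` and `normalized_stain_intensity()` are guarded
arithmetic: density ratios in log2, zero denominators capped (with a flag)
or rejected rather than returned as infinities.

# The synthetic world

Each generator plants a known effect and serializes it as a truth table:

- `gen_compartment_counts()`: negative-binomial counts (mean–dispersion
  parameterization, dispersion 0.2) with lognormal baseline expression
  (mean 200 counts, sdlog 1 — typical of 3' tag data) and a planted log2
  protrusion shift split symmetrically across compartments. The NB is the
  standard overdispersed RNA-seq model; the source states none.
- `gen_ratio_panel()`: per-sample Gaussian ratios, Normal(δ, σ) for the
  planted set, Normal(0, σ) otherwise; defaults σ = 0.3 and six samples
  mirror a six-cell-line panel.
- `gen_pulsed_silac()`: two reciprocally labeled whole-cell replicates with
  a planted log2 rate shift (replicate noise SD 0.25), plus per-compartment
  iBAQ triplets. Nascent labels of the planted set put 80% of signal in the
  nucleus vs 40% for the old pool, membrane ≈ 0, background proteins 30/65/5
  — chosen once to match the qualitative statement that newly made ribosomal
  proteins accumulate in the nucleus and avoid the membrane fraction;
  multiplicative lognormal noise (sdlog 0.1) preserves exact zeros so
  degenerate plantings stay degenerate.
- `gen_iclip_reads()`: one pseudo-chromosome of random sequence; fresh reads
  sample a crosslink from planted clusters (weight ∝ rate × width, uniform
  within) or uniform background; the insert starts one position downstream
  of the crosslink on the read's strand, so the truncation rule recovers the
  site exactly. PCR duplication resamples existing (position, UMI) events at
  a stated rate — the simplest mechanism that exercises deduplication.
- `gen_spot_field()`: isotropic Gaussian spots around the nucleus centroid
  plus a displacement; the expected polarization index increases with
  displacement/spread, which the tests verify by Monte-Carlo.

What the generators do **not** emulate: sequence-content biases, alignment
and mapping error, peptide-to-protein inference, segmentation error, or
correlated noise between compartments. A green test therefore establishes
that the statistics recover what they are defined to recover under their own
model assumptions — not that those assumptions hold on any particular real
dataset.

Every generator is byte-reproducible from its seed and restores the
caller's RNG state.

# Known limitations

- Paraclu density ties are resolved by simultaneous multi-cut; the original
  reference implementation cuts one boundary per recursion, so cluster
  families can differ from it exactly at ties (and only there).
- The per-line compartment design (one replicate per cell line) admits no
  per-line significance statement; only the cross-line meta-analysis is
  computed.
- Real-data iCLIP mode starts from pre-aligned insert coordinates; no
  aligner is bundled.
- Masks in the imaging module are rectangles (or unions of them); arbitrary
  polygon masks would need a point-in-polygon test that nothing in the
  validation currently requires.
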