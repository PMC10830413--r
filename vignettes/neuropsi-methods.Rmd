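---
title: "Quantification methods in neuropsi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods in neuropsi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuropsi)
```

`neuropsi` packages the quantification steps that recur in studies of
latrophilin-3 (*Lphn3*) alternative splicing and its neuronal consequences:
building a named exon catalog for a single gene, estimating percent spliced
in (PSI) for internal cassette exons and for mutually exclusive 3'-terminal
exons, scoring single cells by immediate-early-gene (IEG) expression and
relating activity to splicing, classifying CRISPR amplicon reads by whether
they disrupt the PDZ-binding motif (PBM), quantifying fluorescence scenes
(synapse puncta, traced somata, condensate droplets), extracting
synchronized network events from calcium ΔF/F traces, and fitting FRAP
recovery curves. Every stage has a synthetic-data generator with ground
truth, so the whole pipeline is testable without any external download.

This vignette explains the models and rules, the tunable parameters and
their defaults, what the generators emulate (and do not), and the numerical
choices made where the design was genuinely open.

## Exon catalog construction

Coordinates are 0-based half-open internally, so exon length is simply
`end - start`; GTF/GFF3 input (1-based inclusive) is converted on read by
`read_gene_annotation()`.

Naming follows the field convention for the *Lphn3* exon list:
non-overlapping exons are numbered in ascending transcript (5'→3') order,
and exons that overlap on the genome — usually alternative donor/acceptor
variants — share a number and take letter suffixes (`E30b`). On minus-strand
genes transcript order is descending genomic order, and the letter order
follows the 5'-most start.

Two filters produce the final catalog:

* **Longest-UTR rule.** Among alternative annotated exons of a UTR end only
  the longest is kept (the analysis focuses on the coding region). An exact
  length tie is broken by the smaller start coordinate; the annotation does
  not dictate a rule, so determinism was the only requirement.
* **Translation evidence.** Annotated exons that are never observed in a
  translating-mRNA-enriched read set are dropped. "Observed" means at least
  one read overlapping the exon by at least one base — the minimal positive
  reading of "detected"; the threshold is a `min_reads` argument for
  stricter use.

Classification is operational: an exon is an **internal cassette** if some
evidence read skips it via a junction joining its two flanking exons; a
**terminal pair** is created when two distinct evidence-supported last exons
exist (every transcript of the gene ends in exactly one of them); everything
else is constitutive.

## PSI estimation

Two read-counting rules, matching the two exon geometries:

* **Internal cassette exons** use junction reads only:
  $$\mathrm{PSI} = 100 \cdot \frac{n_\text{inclusion}}{n_\text{inclusion} + n_\text{exclusion}}$$
  where an inclusion read spans a flank→target or target→flank junction and
  an exclusion read spans the flank→flank junction. Junctions must match
  catalog exon boundaries exactly; reads are the unit, so a read spanning
  both inclusion junctions counts once. A zero denominator yields a missing
  estimate flagged as undefined — never 0 or 50, which would bias sparse
  single-cell use.
* **Mutually exclusive terminal exons** use all reads containing either
  exon, normalized to exon length before forming the percentage: with
  densities $d_x = n_x / L_x$,
  $$\mathrm{PSI}_a = 100 \cdot \frac{d_a}{d_a + d_b}, \qquad \mathrm{PSI}_b = 100 - \mathrm{PSI}_a.$$
  The normalization matters because at equal transcript abundance a 2,000-bp
  terminal exon collects about four times the containment reads of a 500-bp
  one; the density ratio, not the count ratio, recovers the abundance split.
  The package's acceptance script demonstrates this: at a 2:1 split the
  normalized estimate is ≈66.7% while the raw count ratio is ≈89%.

The gene-level depth filter for downstream differential expression keeps
genes with strictly more than 350 total reads (`filter_genes_min_count`);
the boundary is exclusive by construction. qPCR relative quantification is
the standard ΔΔCt: ΔCt against the reference gene from the same sample,
ΔΔCt against the control-group mean, fold change $2^{-\Delta\Delta C_t}$.

## Single-cell activity and splicing

The IEG panel is Fos (anchor), Ier2, Egr1, Junb and Dusp1.
`rank_ieg_candidates()` ranks genes by Pearson correlation with the anchor
on log1p depth-normalized expression (counts per 10⁴ per cell). Raw counts
are heavy-tailed, so correlations are computed on the log scale; constancy,
however, is judged on raw counts, since depth variation makes even a flat
gene's normalized values wiggle.

The **IEG score** is the mean across panel genes of the per-gene z-score
(across cells) of log-normalized expression; a zero-variance gene
contributes 0. No formula is canonical for "combining" a marker panel; the
z-score mean is scale-free, treats the five genes symmetrically, and is
invariant to jointly scaling a cell's counts and depth. Cells are binned at
score quantiles (`low_q = 0.40`, `high_q = 0.92`, linear-interpolation
quantiles): the defaults approximate the low/medium/high proportions of the
reference single-cell analysis (roughly a third low, over half medium, and
under a tenth high) and are configurable because the original thresholds
are not published.

Per-cell PSI applies the bulk terminal rule to each cell's own E31/E32
counts; a cell is eligible with at least one count for either exon, and
ineligible cells get missing PSI. Group comparisons use the two-sided
Wilcoxon rank-sum test: exact enumeration of all rank assignments (with
midranks, so ties are handled and identical groups give p = 1) when the
combined n is at most 10, otherwise the tie-corrected normal approximation
with continuity correction.

## Amplicon edit classification

The reference amplicon carries a coding sequence whose last three codons
are the PBM, followed by the stop codon. A read is `PBM_KO` when

1. its indels produce a net frameshift (net inserted-minus-deleted coding
   bases ≢ 0 mod 3) upstream of the PBM — compensating indels that restore
   frame before an untouched PBM are intact, matching the protein-level
   meaning of "frameshift";
2. any indel overlaps the PBM or the stop codon — an insertion strictly
   between the PBM and the stop also counts, because it displaces the motif
   from the C terminus, which is what a PDZ-binding motif requires; or
3. any substitution falls inside the PBM interval. Substitutions are
   classified at the nucleotide level, so a synonymous PBM substitution is
   still called KO; the protein-level oracle disagrees there by design, and
   the two routes are only compared on indel sets.

An independent `protein_ko_oracle()` reconstructs the edited sequence,
translates from the (mapped) coding start to the first stop, and checks the
terminal three residues; the test suite verifies 100% agreement with the
rule over the exhaustive enumeration of indels of length −6..+6 at every
position of the toy amplicon. The toy amplicon's coding sequence contains
no codon starting with T upstream of the stop, so in-frame indels cannot
create premature stop codons and the comparison is clean.

Indel calling from raw reads uses global alignment with affine gaps
(match 2, mismatch −3, gap open 5, gap extend 1) via Biostrings; the
constants are fixed so results are reproducible.

## Image quantification

All rules take the strict reading of the field conventions, at the default
pixel size of 0.20714 µm/px:

* binarization is `intensity > threshold` (thresholds are user-supplied per
  channel per batch; the original values are not published);
* connectivity is 8-neighbour everywhere; "more than two neighbouring
  pixels" is component area ≥ 3; soma rules are ≥ 81 px (red) and
  ≥ 151 px (green);
* the dendrite halo is morphological dilation by a Euclidean disk of
  radius 5 px — the least anisotropic choice where the metric is unstated.
  Synapse puncta are components of vGluT1 ∧ HOMER ∧ halo;
* dendrite length: the mask is thinned (Zhang–Suen) to a 1-px skeleton and
  each component contributes its geodesic diameter — the longest shortest
  path with orthogonal steps of weight 1 and diagonal steps of weight √2 —
  matching the filament-length convention; a total-skeleton-length mode is
  available behind `mode = "total"`;
* droplet analysis: clusters are connected components of the droplet mask
  ("contacting droplets count as one cluster"); droplets within a cluster
  are resolved as distance-transform maxima with a 3-px minimum separation
  (plateau maxima are merged), and areas come from growing the markers over
  the mask. The 12.86-µm line profile samples channels at pixel spacing
  with bilinear interpolation and reports an edge/centre enrichment ratio
  (outer 20% of samples over central 20%), which exceeds 1 only for
  surface-localized signal;
* reporter ratios (`fov_intensity_ratio`) are mean-over-mean after constant
  background subtraction. Rolling-ball background subtraction is out of
  scope (performed upstream in the original workflow).

## Calcium network events

The synchronized-firing trace of a field of view is the pointwise mean of
all somata's ΔF/F traces. Events are detected with the standard peak
semantics at the stated parameters — height ≥ 0.15 ΔF/F, interpolated width
at half prominence within (2, 20) samples, minimum separation 20 samples —
where prominence is computed against the lowest contour enclosing only that
peak, plateaus reduce to their midpoint, and the separation rule keeps
taller peaks first (equal heights keep the earlier; determinism again).
The firing rate is events over recording time; batch summaries take the
median rate and median event amplitude across fields of view. Whether the
original amplitude summary was a mean or median per trace is not stated;
the median was chosen for robustness and applied consistently.

Source extraction from movies is consumed, not performed: the module
ingests ΔF/F CSV tables.

## FRAP and BRET

FRAP recovery is fit by bounded Levenberg–Marquardt least squares to
$y = a e^{-bx} + c$ with $t_{1/2} = \ln 2 / b$, initialized at
$a_0 = y_1 - y_n$, $c_0 = y_n$, $b_0 = 3/\text{span}$, and $b$ bounded below
at 10⁻⁶ so the recovery direction cannot flip sign. Only the kinetics
(b, t½) are primary; the span and plateau are reported but secondary,
because the recovery fraction is sensitive to the photobleach duration.
Net BRET is the GFP2:RLuc8 emission ratio minus the 0 ng (constitutive)
baseline ratio within each transducer pairing.

## Synthetic data: what it emulates, and what it does not

Every generator is a deterministic function of its arguments and seed
(Mersenne–Twister, inversion normals, set explicitly) and emits the ground
truth needed to score the corresponding estimator.

* `gen_junction_reads`: for internal targets, reads are drawn from the
  junction-spanning start windows of the chosen isoform (inclusion with
  probability ψ/100), because the PSI library *is* junction-spanning reads;
  the estimator is then a plain binomial proportion. For terminal pairs the
  isoform is chosen proportionally to abundance × effective length and the
  start is uniform along the isoform — standard fragment sampling — which
  makes containment counts proportional to abundance × exon length, exactly
  the bias the length normalization inverts.
* `gen_sc_counts`: latent activity a ~ U(0,1); panel-gene means scale as
  exp(k·a); background genes are activity-independent; terminal reads are
  Poisson (mean 2 per cell, a realistic sparsity for one gene's terminal
  exons in deep single-cell data) split with inclusion probability
  logistic(α + β·a). Poisson noise is the default; real single-cell data
  are overdispersed and batch-structured, so passing tests here show
  estimator correctness, not robustness to those artefacts.
* `gen_synapse_scene`: the dendrite is a steered random-walk curve with a
  ~3-px Gaussian profile; puncta are ~0.5-µm Gaussian spots planted within
  the halo (paired in both synaptic channels) or, as decoys, 8 px off the
  curve — beyond the halo radius plus dendrite half-width plus spot radius,
  so the halo rule excludes them exactly. Optics are Gaussian; no PSF
  tails, no antibody background structure.
* `gen_soma_scene` plants blobs with *exact* pixel areas (nearest-k pixels
  around a centre) so the strict size rules can be checked exactly;
  `gen_droplet_scene` builds clusters as touching-disc chains placed far
  apart, so the ground-truth contact-graph components are the clusters, and
  renders the reporter channel uniform or rim-localized (shell).
* `gen_ca_traces`: one common event train (exponential gaps with a hard
  minimum separation) convolved with an exponential-decay kernel
  (τ = 0.4 s at 85 ms frames), per-cell gain jitter, Gaussian noise.
* `gen_frap_curve` and `gen_amplicon_reads` close the loop on the fitters
  and the classifier; amplicon ground truth is labelled by the protein
  oracle, keeping the nucleotide rule as the independent route under test.

## Problem sizes and numerical notes

The test and acceptance computations use: PSI recovery at depth 10⁴ over
ψ ∈ {0, 10, 30, 50, 70, 90, 100} × 20 seeds; single-cell simulations at
500 cells × 60 genes (10 coupled seeds; 200 null simulations); exhaustive
amplicon enumeration of 711 single indels on a 60-bp reference; 20-droplet
scenes × 10 seeds; 100-seed event-train and FRAP-noise replicates. These
sizes keep every stage's sampling error far below the tolerances being
checked while remaining desk-scale.

Degenerate inputs are handled explicitly rather than silently: undefined
PSI is missing and flagged; an all-equal score vector bins every cell
IEG-medium with a warning; a constant FRAP curve is an error and a rate at
the lower bound is flagged invalid; empty masks yield zero length and zero
counts.

## Known limitations

Single-gene focus (nothing forbids looping over genes, but no multi-gene
catalog is built); no read alignment, isoform assembly, differential
expression internals, movie source extraction, off-target search, or 3-D
segmentation — those are consumed through their standard outputs. The
synthetic scenes are idealized in the ways listed above, so green tests
certify the rules and estimators, not performance on raw microscope or
sequencing data.
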