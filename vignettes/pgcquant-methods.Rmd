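---
title: "Methods: quantifying germ-cell epigenetic signatures"
author: "pgcquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying germ-cell epigenetic signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgcquant)
```

Primordial germ cells (PGCs) can carry a chromatin state that differs
sharply from the surrounding somatic cells: in birds, gonadal germ cells
show a strong global enrichment of the heterochromatin mark H3K9me3
together with visibly decondensed chromatin. Establishing such a
signature quantitatively requires two kinds of measurement: per-nucleus
immunofluorescence quantification in tissue images, and genome-wide
localization of the mark from ChIP-seq. This vignette describes how
pgcquant implements both, the assumptions behind each step, and what the
synthetic-data generator does and does not emulate.

## Imaging arm

### Per-nucleus quantification and somatic normalization

Inputs are intensity rasters (one per channel) plus an integer label mask
of nuclei; segmentation itself is upstream (the mask is taken as given,
including any manual correction). For each non-excluded nucleus the mark
and DNA-counterstain intensities are summed and the ratio
`mark_total / dna_total` estimates the mark level per amount of
chromatin, cancelling differences in nucleus size and in the amount of
chromatin sampled by the section plane. Dividing by the mean ratio of
the somatic nuclei of the *same image* removes image-to-image staining
and acquisition differences, so normalized records pool across images.
Consequences that the tests pin down:

* the somatic mean of normalized intensity is 1 in every image (to
  1e-9);
* normalized quantities are invariant to rescaling a channel by any
  positive constant;
* nuclei with zero DNA total are flagged invalid and never enter the
  somatic reference; an image without a valid somatic nucleus is an
  error, not a silent NaN.

Chromatin density is `dna_total / area` normalized the same way. For
samples where the DNA counterstain is unusable (e.g. after the harsh
denaturation needed for methylation immunodetection), `quantify_mark()`
accepts a per-class density table measured on matched samples and uses
`density * area` in place of the DNA total.

Nuclei touching the image border are excluded by default: truncation
biases both area and totals, and equatorial-plane selection upstream
implies complete nucleus sections.

### Radial profiles (eroded volume fraction)

The 3-D eroded-volume-fraction idea is applied to 2-D nucleus sections:
pixels are ranked by exact Euclidean distance to the nucleus boundary
(the image border counts as background) and cut into `n_shells = 25`
quantile bins. This guarantees equal shell areas within one pixel on
arbitrarily irregular masks, where iterated morphological erosion would
not. Ties at quantile boundaries are broken deterministically by pixel
linear index. Shell 1 is the outermost (peripheral) shell; profiles are
percentages of total nucleus intensity. With equal areas, the
percentage-of-total formulation is equivalent to reporting mean shell
intensities up to the one-pixel discretization, which is why a uniform
nucleus yields 4.0% ± 0.1 per shell. No background subtraction is
performed; inputs are assumed pre-corrected. The test suite checks the
construction against a brute-force per-pixel oracle that recomputes
distances and quantile bins directly.

### Focus segmentation and enrichment

Bright nuclear foci (e.g. macroH2A1 accumulations at pericentric
heterochromatin) are segmented with a white top-hat filter using a disc
structuring element (`se_radius`, default 5 px — chosen above the
typical focus radius so foci survive the opening), thresholded at
`mean + k_sigma * SD` (default `k_sigma = 2`) of the top-hat response
inside the nucleus, keeping connected components of at least `min_size`
pixels (default 4). The image is padded by edge replication before
filtering so that a flat image yields exactly zero response at the
borders. Enrichment of a co-detected channel is its mean over the focus
divided by its mean over the whole nucleus; a value of 3 means the
protein is three-fold more concentrated at the focus than in the nucleus
at large.

## Genomic arm

### Final-domain rule

Broad repressive domains are poorly served by narrow-peak models. The
pipeline therefore consumes two upstream callers — SICER islands (with
an FDR per island) and MACS2 broad peaks — and combines them: islands
with FDR strictly below `1e-10` are kept outright; islands above the cut
are rescued when at least 1 bp of a broad peak supports them. Peaks only
gate inclusion — island geometry is preserved — and the surviving
islands are then normalized (sorted; overlapping or book-ended islands
merged). Merging before counting is a deliberate choice: base-level set
semantics cannot distinguish adjacency from union, and it makes domain
counts well-defined. Raising the FDR cut can only add domains
(monotonicity, tested).

### Interval algebra

All region and coverage computations reduce to an exact half-open
(BED-convention) interval algebra: normalize, intersect, subtract,
complement, union, total bases, coverage fraction. It is implemented
directly on sorted per-chromosome coordinate vectors, which keeps a set
operation at microseconds and lets the test suite afford 1,000
randomized comparisons against a per-base boolean occupancy oracle. The
"whole genome" is always the user-declared chromosome list — in a real
analysis typically the autosomal main scaffolds — with no hidden
filtering.

### Two-cell-type base classification

For cell types A and B, every in-domain base is classified as:

* **shared core** — covered by domains of both cell types
  (`intersect(A, B)`);
* **cell-type-specific** — in a domain with zero overlap with any domain
  of the other cell type;
* **expansion** — all remaining bases, i.e. non-shared bases of domains
  that do overlap the other cell type somewhere.

"Expansion" deliberately includes bases bridging internal gaps of the
other type's coverage, not only flanking extensions: the gap-robust rule
is deterministic and preserves the partition identity
`core + expansion + specific = total` per cell type, with the shared-core
count equal between cell types (both asserted on every run). Class
distributions are compared with a Pearson chi-squared test on the 2 x 3
base-count table without continuity correction; using bases as counting
units inflates `n`, which is inherent to the published formulation and
reproduced as such.

### Functional regions, gene coverage and expression

Region classes from gene annotation: promoters (1 kb centered on the
TSS, strand-independent, clipped at chromosome ends), gene bodies (TSS
to TTS), intergenic (complement of promoters and bodies), repeats
(elements of at least 50 bp), and the whole genome. Two promoter
definitions coexist on purpose: the symmetric 1-kb window for region
classes, and a strand-oriented 500-bp upstream extension for per-gene
loci; each is applied in its own context and both are arguments.

Per-gene coverage is the covered fraction of the promoter-extended locus
against the final domains, binned into five classes
`{0, (0,25], (25,50], (50,75], (75,100]}` percent. A separate zero class
distinguishes "not overlapped at all" from low coverage. Gene expression
is the transcript-TPM sum per replicate, averaged over replicates
(preserving total TPM mass, tested). Class-wise TPM distributions are
compared with two-sided Wilcoxon–Mann–Whitney tests — between cell
types within a class, or across classes within one cell type — matching
an exact enumeration oracle for small groups. Gene-set selection uses
the first quartile (linear-interpolation sample quantile, type 7) of the
mean TPM over the analysis universe as the repression threshold,
inclusive (`TPM <= Q1`); the low-coverage bound of the cross-cell-type
list (10%) is inclusive by default with a strict-inequality switch,
since published wordings differ between "< 10%" and "<= 10%".

### Repeat enrichment

Two summaries: (1) the fraction of sequenced bases inside the
repeat compartment, computed as a depth-weighted base share from a
run-length depth track; (2) RepEnrich-style family enrichment from
IP/input count tables — counts are library-normalized, the IP/input
ratio is formed per element type, and only then are types grouped into
repeat classes. The class statistic is the unweighted mean of member
ratios (a count-weighted mean is available); the ratio-then-group order
matters and is pinned by a regression test. Multi-mapping ambiguity is
acknowledged, not corrected: repeat coverage values may be
underestimates. Excluded RepeatMasker categories (unspecified, unknown,
artefact; simple repeats except the telomeric repeat) are applied at the
table reader and are configurable.

## The synthetic-data generator

The generator provides ground truth, not realism.

**Images.** Nuclei are non-overlapping uniform-intensity discs; germ
nuclei get exactly `germ_density_fold` times the somatic DNA intensity
per pixel and exactly `germ_mark_fold` times the somatic mark/DNA ratio
before noise, so noiseless recovery must be exact to machine precision.
Foci are additive Gaussian spots on the mark channel with recorded
centers. Noise is additive Gaussian, clipped at zero. Defaults (3-fold
mark enrichment, 0.5-fold density, 5% noise in the fold-recovery
setting, 30 germ vs 100 somatic nuclei) mirror the magnitudes reported
for avian germ cells: H3K9me3 folds of 2–4.5 and roughly two-fold lower
chromatin density. Not emulated: 3-D stacks, optics/PSF, staining
heterogeneity within a nucleus, camera noise models, segmentation
errors.

**Genomes.** Domain features are placed in non-colliding slots with
margins wider than any expansion, then each shared core gains, per cell
type and per side, an expansion with probability `expansion_prob`;
specific domains belong to one cell type only. Each truth domain is
re-emitted as 1–3 book-ended SICER-style islands: pieces get FDR 1e-12
(kept by the FDR branch) or FDR 1e-2 with a broad peak strictly inside
(kept by the rescue branch), and decoy islands (FDR 1e-2, no peak,
placed clear of all domains) must be rejected — so the final-domain rule
reconstructs the truth set *exactly*, byte-for-byte in BED. Gene
expression follows `log TPM = baseline − repression_strength × covered
fraction` with a lognormal gene baseline (default mu 1.5, sigma 0.5 in
natural log; kept modest so the coverage effect is visible at desk
scale — real transcriptomes are far more dispersed) and mild lognormal
replicate noise. Half of the genes are deliberately placed so their
locus straddles a domain edge with a uniform offset; this populates all
five coverage classes, standing in for the thousands of border genes a
real genome provides. Boundary placement is best-effort: when edge
neighbourhoods saturate, genes fall back to uniform placement. All
randomness comes from one seeded stream per call, and the caller's RNG
state is untouched; identical seeds give byte-identical output files.

Passing tests on this generator show that the *quantification machinery*
is correct under the stated models; they do not validate segmentation,
alignment, peak calling, or any upstream step the pipeline consumes.

## Numerical choices and problem sizes

* Coordinates are 0-based half-open throughout; 1-based inputs
  (samtools-depth positions) are converted at the reader boundary.
* Floats are serialized as `%.6g` (integers as integers), making
  write→read→write byte-stable for regression tests.
* FDR comparison is strict (`< 1e-10`), as is conventional.
* Quantile type 7 (linear interpolation) for the repression threshold.
* Test and acceptance workloads use desk-scale sizes chosen to exercise
  every code path densely: images up to 900 x 900 px with 130 nuclei,
  toy genomes of 1–1.4 Mb with 50–60 domains and 200–500 genes, and
  1,000 randomized oracle cases on two-chromosome genomes up to 100 kb.

## Limitations

* The imaging model is 2-D; true eroded *volume* fractions from stacks
  are out of scope.
* Focus segmentation parameters (`se_radius`, `k_sigma`, `min_size`)
  are data-dependent; defaults suit foci a few pixels wide over a
  smooth background.
* Domain counts depend on the merge-after-selection convention; a
  pipeline that counts unmerged surviving islands will report more,
  smaller domains over the same bases.
* Enrichment at repetitive sequences inherits the upstream
  multi-mapping caveat; the per-class figures are relative, not
  absolute, measures.
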