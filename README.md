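# pgcquant

Quantification toolkit for the epigenetic signature of primordial germ
cells (PGCs) relative to somatic cells, covering both arms of a typical
germ-line chromatin study:

* **Imaging arm** — per-nucleus quantification of immunofluorescence in
  single-plane images: epigenetic-mark level per amount of chromatin,
  chromatin density per unit area, radial ("eroded volume fraction")
  signal distributions over equal-area concentric shells, and enrichment
  of co-detected proteins at segmented nuclear foci.
* **Genomic arm** — broad H3K9me3 domain calling by reconciling SICER
  islands with MACS2 broad peaks, per-base comparison of two cell types'
  domain sets (shared core / expansion / cell-type-specific), coverage of
  functional genome regions and of single gene loci, the relation of gene
  coverage to expression (TPM), and repeat-element enrichment summaries.

A synthetic-data generator produces nucleus images and toy genomes with
known ground truth, so every stage is testable end to end without any
external data.

## The quantities at the core

**Normalized mark intensity.** For nucleus $i$ with total mark intensity
$M_i$ and total DNA-counterstain intensity $D_i$, the mark level per
amount of chromatin is $r_i = M_i / D_i$, and the normalized intensity is

$$\tilde r_i = \frac{r_i}{\overline{r}_{\text{somatic}}},$$

the ratio divided by the mean ratio of the somatic nuclei **of the same
image**. Somatic nuclei average to 1 by construction, and records from
different images become poolable. Chromatin density per unit area is
$D_i / A_i$ (area $A_i$ in pixels), normalized the same way.

**Radial (EVF) profiles.** A nucleus section is partitioned into
$n = 25$ concentric shells of equal area, built from quantiles of the
Euclidean distance to the nucleus boundary; each shell's intensity is
expressed as a percentage of the nucleus total (reported outermost shell
first).

**Final H3K9me3 domains.** Given SICER islands with per-island FDR and
MACS2 broad peaks, the final domain set is

$$\{\,i : \mathrm{FDR}_i < 10^{-10}\,\} \cup
  \{\,i : \mathrm{FDR}_i \ge 10^{-10} \text{ and } i
  \text{ overlaps a peak by} \ge 1\ \mathrm{bp}\,\},$$

merged after selection; peaks gate inclusion but never alter island
coordinates.

**Domain base classes.** Comparing two cell types' domain sets, each
in-domain base is *shared core* (in domains of both), *cell-type-specific*
(in a domain with zero overlap in the other cell type), or *expansion*
(the remaining non-shared bases of domains that do overlap the other cell
type). The three classes partition each cell type's domain bases, and the
shared-core count is identical between cell types; a 2 x 3 Pearson
chi-squared test compares the class distributions.

**Coverage vs expression.** Each gene locus (500 bp upstream of the TSS
through the TTS, strand-oriented) gets a covered fraction against the
final domains, binned into five classes (0%, (0,25], (25,50], (50,75],
(75,100] percent); gene TPM is the transcript-TPM sum, averaged over
replicates; class-wise TPM distributions are compared with the two-sided
Wilcoxon–Mann–Whitney test. Repeat enrichment follows the RepEnrich
convention: library-normalized IP/input ratios per element type, grouped
into repeat classes only after the ratios are formed.

## Worked example

```r
library(pgcquant)

# imaging: 5 germ + 20 somatic nuclei, programmed mark fold 3x,
# chromatin density fold 0.5x, 5% additive noise
sim <- simulate_nuclei_image(image_sim_spec(
  n_germ = 5, n_somatic = 20, germ_mark_fold = 3,
  germ_density_fold = 0.5, noise_sd = 5, seed = 7))
img <- as_labeled_image(sim)
q <- quantify_mark(img, "mark", "dna")
aggregate(normalized_intensity ~ class, q, function(x) round(mean(x), 3))
#>     class normalized_intensity
#> 1    germ                2.998
#> 2 somatic                1.000

# genomics: two cell types sharing domain cores, A with expansions
gsim <- simulate_genome(genome_sim_spec(seed = 7))
domA <- combine_islands_peaks(gsim$islands$A, gsim$peaks$A, gsim$genome)
domB <- combine_islands_peaks(gsim$islands$B, gsim$peaks$B, gsim$genome)
classify_domain_bases(domA, domB)
#> Domain base classification (A vs B)
#>   shared_core expansion specific  total
#> A      130390     13406    26437 170233
#> B      130390     15840    33972 180202
#> Genome size: 1,000,000 bp
#> Genome percent covered: A 17.02%, B 18.02%

# gene repression tracks domain coverage
expr <- aggregate_gene_tpm(gsim$transcripts$A)
cov  <- gene_coverage(gsim$genes, domA, gsim$genome)
m <- merge(cov, expr, by = "gene_id")
round(tapply(m$mean_tpm, m$coverage_class, median), 2)
#>       0%   (0,25]  (25,50]  (50,75] (75,100]
#>     4.50     4.06     1.99     1.38     0.76
```

The germ nuclei recover the programmed 3-fold mark enrichment, the
domain classification recovers the constructed shared cores plus
expansions and specific domains, and the median TPM decreases
monotonically with domain coverage, as programmed.

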