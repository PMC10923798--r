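---
title: "Methods: windowed scans, gene flow and the speciation continuum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed scans, gene flow and the speciation continuum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contiscan)
```

`contiscan` quantifies where closely related microbial lineages sit along the
speciation continuum — from freely recombining populations to lineages with
complete barriers to gene flow.  The package grew out of the analysis style
used for dense collections of conspecific bacterial genomes (its vocabulary
is that of biocrust cyanobacteria: lineages `M1, M2, ...`, soil/puddle
habitats, homologous recombination as the microbial analogue of gene flow),
but every component operates on generic inputs: a biallelic SNP matrix
against a reference, lineage labels, gene models, recombination-event
intervals with carrier strains, an ANI matrix, sample metadata and a
phylogeny.

# Windowed population-genetic statistics

All diversity statistics reduce to one per-site summary: among the selected
samples, the alternate-allele count and the number of non-missing genotypes.
Missing genotypes are handled *pairwise-complete per site*: each site
contributes the mean difference over the sample pairs actually observed
there.  This is an approximation — Tajima's and Watterson's constants still
use the full subset size `n` — and it reduces exactly to the textbook
definitions when no genotypes are missing.

* **pi** (`nucleotideDiversity`): mean pairwise difference per site, summed
  over SNPs in a window and divided by the *window length* (monomorphic
  positions contribute zero, so only SNPs are visited).
* **Watterson's theta** (`wattersonTheta`): `S / (a1 * L)`.
* **Tajima's D** (`tajimasD`): the standard normalized difference between
  the mean pairwise difference count and `S/a1`, with the 1989 constants;
  `S = 0` or `n < 3` yield `NaN` rather than a value.
* **Fu's F(S)** (`fusF`): the haplotype-based statistic
  `ln(S'/(1-S'))`, where `S'` is the Ewens-sampling-formula probability of
  observing at least the realized number of distinct haplotypes given
  `theta` estimated by the mean pairwise difference.  The Ewens
  probabilities are computed by the sequential (Chinese-restaurant)
  construction — a Bernoulli convolution that is numerically stable for
  large `n`, and exactly equals the Stirling-number form.  Because "Fu's F"
  is ambiguous in parts of the literature, Fu & Li's F* is also available
  (`type = "Fstar"`); F(S) is the default.
* **D_XY** (`dxy`): mean per-site difference over all cross-lineage sample
  pairs.
* **F_ST** (`fstHudson`): Hudson's estimator `1 - Hw/Hb` with
  `Hw = (pi_A + pi_B)/2` and `Hb = D_XY`.  `Hb = 0` yields `NaN`; negative
  estimates are reported as computed.

`scanGenome` evaluates these on two window grids, by default 50 kb windows
with a 12.5 kb step for diversity and differentiation and 10 kb windows with
a 2.5 kb step for the neutrality statistics — the grid sizes commonly used
for multi-Mb bacterial genomes.  Windows start at position 1 and advance by
the step; the final window is the last *full-size* window and any shorter
tail is dropped, so per-site rates are comparable across windows.  Window
sums are assembled from per-site cumulative sums, making the scan linear in
the number of SNPs.

`neutralityDepartureTest` is the conventional one-sample two-sided t-test of
per-window values against zero.  Its independence assumption is discussed
with the simulator below.

# Divergence-outlier regions

`outlierRegions` aggregates F_ST and D_XY per window across lineage pairs
(mean by default; a per-pair mode exists because pooling strategy is a
genuine free choice), takes the `q` quantile of each metric
(linear-interpolation quantile, ties included at the threshold), keeps the
windows extreme in **both** metrics, merges overlapping or adjacent
selections, and attaches genes overlapping the merged regions by at least
1 bp.  The default is `q = 0.99`, the conventional percentile for genome
scans.

One geometric caveat matters at small scale: the fraction of windows the
quantile selects must be commensurate with the extent of differentiated
sequence one hopes to recover.  On a 100 kb simulated genome where an
implanted island spans 10% of the sequence, a 0.99 quantile can select only
a single window and cannot trace the island's boundaries; the validation
experiments therefore pair a 10 kb island with `q = 0.90` and 2 kb windows.
On multi-Mb genomes where differentiated regions are a fraction of a
percent, `q = 0.99` is the appropriate setting.

# McDonald–Kreitman tests

`classifySiteChanges` compares an ingroup (usually one lineage) against the
reference genome sequence, per gene.  A SNP is a *fixed difference* when
every non-missing ingroup genotype carries the alternate allele, and
*polymorphic* when both alleles segregate in the ingroup.  Synonymous versus
nonsynonymous status is decided by translating the codon with each allele
substituted into the *ingroup-consensus* codon background (one site at a
time; consensus ties resolve toward the reference allele), under the
bacterial genetic code; minus-strand genes are reverse-complemented.  Genes
whose length is not a multiple of 3, or whose reference frame contains an
internal stop, are flagged and skipped.  Sites missing in more than half the
ingroup are excluded and counted (threshold configurable).

`mkTest` computes the neutrality index `NI = (Pn/Ps)/(Dn/Ds)` and a
two-sided Fisher exact p on the 2x2 table.  A zero in `Ps`, `Dn` or `Ds`
leaves NI undefined (class `undefined`); no continuity correction is applied
by default, matching the convention of reporting per-gene Fisher
significance.  Classification: `positive` when `NI < 1` and `p < alpha`,
`negative` when `NI > 1` and `p < alpha`.  `genomewideMk` runs this per gene
and lineage, optionally applies Benjamini–Hochberg within lineages, and
flags genes inside outlier regions as candidates.  Polarizing divergence
against the reference sequence (rather than a reconstructed ancestor) is a
deliberate choice: it mirrors how reference-anchored callsets are produced,
at the cost of absorbing reference-lineage-specific changes into `D`.

# Gene flow from recombination events

Recombination events arrive as intervals with carrier-strain sets (the GFF
dialect produced by recombination-detection tools, attribute
`taxa="s1 s2"`).  `attributeEvents` classes an event as within-lineage when
all carriers share one lineage and as between-lineage for *every* pair of
lineages its carriers span — one block may be counted more than once, which
is the counting rule that makes summed fractions comparable across lineages.
Single-carrier (terminal-branch) events count as within-lineage and are
flagged.

`geneflowFractions` offers two modes. *Summed* mode adds event lengths per
category (overlaps counted repeatedly; a lineage's fraction may exceed 1),
matching how such fractions are reported descriptively.  *Union* mode
collapses each category to its interval union first, giving true genome
proportions.  `upcelStages` requires union mode because it interprets the
genome fraction *resistant* to between-lineage gene flow,
`P_div = 1 - fraction_between`, as a proxy of the divergence probability of
the pair under a probabilistic concept of evolutionary lineages.  The stage
labels (species at `P_div >= 0.89`, grey zone at `>= 0.85`, early below) are
presentation thresholds, configurable and explicitly not inference; `P_div`
is labelled a proxy throughout.

Per-strain parameters (`strainRecombParams`): with a strain's SNPs defined
as its alternate-allele positions, `r/m` is the ratio of SNPs inside the
union of its tracts to SNPs outside, and `rho/theta` the ratio of its event
count to outside SNPs — the standard summaries of recombination relative to
mutation.  Lineage and habitat comparisons use the tie-corrected
Kruskal–Wallis test with Dunn's Bonferroni-adjusted post hoc z tests.

# Isolation by distance and environment

Genetic distance is `(100 - ANI)/100`.  Geographic distance is the
spherical haversine with mean Earth radius 6371.0088 km — a documented
simplification of the ellipsoidal geodesic, differing by under 0.5%.
Environmental distance is Euclidean over z-scored variables (heterogeneous
units make standardization the safer default).  `mantelTest` correlates
lower triangles (Pearson) with label permutations of one matrix,
`p = (#{r_perm >= r_obs} + 1)/(n_perm + 1)`; the one-sided `greater`
alternative is the default because distance decay is a directional
hypothesis.  Phylogenetic signal delegates to `phytools::phylosig`:
Blomberg's K with a tip-permutation p, and Pagel's lambda by maximum
likelihood with a likelihood-ratio test against `lambda = 0` using the
50:50 chi-square(0)/chi-square(1) boundary mixture (lambda sits on the
parameter boundary under the null).  `aniCluster` forms single-linkage
connected components above an ANI threshold (95% is the conventional
species threshold; the linkage choice is ours and is stated).  `hgtPerMb`
normalizes HGT counts per Mb and reports both Spearman and Pearson
correlations of count versus genome size, since either is defensible and
reported usage varies.

# The synthetic-data generator

`simulateContinuum` produces datasets with known truth, so that every layer
of the pipeline can be validated by recovery rather than by eyeballing.
The generative model:

* a uniform-random reference genome (gene frames are made stop-free so they
  translate);
* lineage founders diverge from the reference at `Bernoulli(d/2)` sites at
  globally unique positions (infinite sites), so every pair of founders
  differs at rate `d`; an optional island interval multiplies the rate;
* within-lineage haplotypes follow a Kingman coalescent with infinite-sites
  mutation scaled so `E[pi] = theta` and `E[S] = theta * L * a1`;
  genealogies are drawn *independently per block*
  (`recomb_block_len`, default 10 kb), emulating the pervasive homologous
  recombination of such organisms — and giving window statistics the
  approximate independence the departure t-test assumes;
* purifying selection inside genes: nonsynonymous mutations are retained
  with probability `ns_retention` (default 0.2, in line with the
  predominance of deleterious amino-acid changes); without this the neutral
  `Dn:Ds` ratio is ~3:1 and MK contrasts have no power at realistic counts;
* positive selection: designated genes receive `omega_pos` extra fixed
  nonsynonymous differences per lineage, bypassing the thinning;
* HR tracts: per strain a Poisson number of geometric-length tracts is
  copied from a donor chosen by lineage weights (`between_tract_prob`, or a
  full migration matrix for gradients); the donor haplotype overwrites the
  carrier (last writer wins), and each tract is recorded as an event
  carrying `{recipient, donor}`;
* ANI from pairwise SNP identity; the clonal-frame tree as a star of
  lineage coalescent subtrees in substitutions/site; geography scattered
  around lineage centroids; environmental variables by Brownian motion on
  the tree; HGT counts Poisson around lineage-specific per-Mb rates.

Closed-form expectations recorded in the truth set:
`E[D_XY] = d + theta_A (1 - 1/n_A) + theta_B (1 - 1/n_B)` (founder
divergence plus each sample's expected path to its lineage's most recent
common ancestor) and the corresponding Hudson F_ST.  The defaults
(`theta = 0.005`, `d = 0.015`, 100 kb genome, four lineages of ten) sit
inside the within/between-lineage diversity ranges typical of dense
conspecific bacterial collections.

What the generator does **not** emulate: realistic genome content (operons,
GC skew, repeat families), indels and rearrangements (ANI from SNP identity
only), selection acting through time, linkage within blocks beyond the
shared genealogy, ancestral recombination graphs, and sequencing error.
Passing recovery tests therefore demonstrates the *statistical machinery*
is correct under an idealized model — not that real data meet the model's
assumptions.

# Numerical and design notes

* Coordinates are 1-based inclusive everywhere (VCF/GFF convention);
  conversions are confined to the readers/writers.  Writers emit
  deterministic column order and 6-significant-digit numbers; identical
  configurations give byte-identical outputs.
* ANI asymmetry is resolved by the arithmetic mean of reciprocal values;
  self-identity is forced to 100.
* One global RNG stream per simulation, seeded once from the config.
* Quantiles use R's default linear interpolation (type 7).
* `NaN` windows are excluded from quantiles and t-tests, with counts
  reported.
* Fisher's exact test and the Kruskal–Wallis test delegate to `stats`;
  Dunn's test is implemented here (with ties, a zero-variance group set
  yields `z = 0`, `p = 1`) and verified against the rank formula.
* Degenerate inputs follow explicit contracts rather than erroring late:
  fewer than 2 samples (`pi`), fewer than 3 (`D`, `F(S)`), `S = 0`,
  `Hb = 0`, single haplotype — all yield `NaN` with a warning where
  user action is plausible.

## Known limitations

* Tajima's D has a small negative finite-sample expectation (about -0.08
  at `n = 20` with 10 kb windows at `theta` = 0.001/site).  This is a
  property of the statistic, not of the implementation — the package's
  estimator agrees with an independent brute-force implementation to
  1e-12 — so a strict "mean windowed D equals 0" check fails at high
  replicate counts even on perfectly neutral data.  Departure tests against
  0 inherit a mild anti-conservativeness from the same source.
* Missing-genotype handling is pairwise-complete per site; with heavy,
  non-random missingness the neutrality constants (which use the full
  subset size) become approximate.
* The MK implementation operates on the reference-anchored core alignment;
  genes present in only a subset of genomes are analyzed over the samples
  that carry data at those sites rather than over re-aligned orthologue
  sets.
* `P_div` staging is presentation on top of a proxy; it is only as good as
  the recombination-event input.

## Problem sizes used in the validation suite

The test suite exercises the pipeline at desk scale: genomes of 5–100 kb,
2–4 lineages of 4–20 samples, 200 neutral replicates for calibration, 20
seeds for island recovery, 100 Brownian replicates for lambda recovery.
These sizes keep the whole suite in the minutes range while leaving every
statistical property measurable.
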