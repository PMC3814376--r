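---
title: "Methods: differential transcription and promoter chromatin architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential transcription and promoter chromatin architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromarch)
```

## The problem

Genomic run-on (GRO) measures nascent transcription: permeabilised cells
incorporate labelled nucleotides into RNA being made at the moment of the
assay, so the hybridisation signal per gene reflects RNA polymerase density —
a transcription *rate* — rather than steady-state mRNA abundance. Comparing
GRO between a wild-type yeast strain and a strain whose topoisomerase II is
acutely inactivated (a thermosensitive allele shifted to 37 °C for ten
minutes) asks which genes depend on topo II for their transcription right
now, before secondary effects accumulate.

`chromarch` implements that comparison and the structural follow-up: once
up- and downregulated gene sets are defined, it characterises their promoter
geometry, sequence composition, nucleosome organisation, chromatin dynamics
and histone-mark landscape relative to the genome average. A synthetic-data
module generates a complete miniature "world" with planted effects so every
stage can be validated offline against known truth.

## Differential transcription

Each array's gene signals are divided by that array's genomic-DNA
hybridisation signal (`normalize_signals()`), which corrects for per-filter
probe amounts. The gDNA term may be a per-array scalar (the default
assumption) or probe-wise per gene; both are supported because original
array protocols vary and the table format carries the value per row either
way.

Replicates are then screened for outliers, merged, and the per-gene ratio

$$R_g = \frac{\overline{m}_g}{\overline{c}_g}$$

of mean mutant over mean control signal is classified with strict
thresholds: **up** if $R_g > 1.5$, **down** if $R_g < 0.65$. The ratio of
means (rather than mean of ratios) is used because it degrades gracefully
when individual replicates are discarded. A gene is excluded unless both
strains retain at least two valid replicates.

### Outlier screening: why the default pools deviations

The exported primitive `filter_outliers()` retains a value iff
$|x - \mathrm{median}| \le k \cdot \mathrm{MAD}$ with the unscaled MAD and
$k = 3$. This is the right tool for vectors with enough values (its
five-value examples behave exactly as intuition says). But applied to a
*triplicate*, any per-vector MAD rule degenerates: with three values the MAD
equals the smaller of the two spacings around the median, so the rule
becomes a scale-free spacing-ratio test that flags roughly forty percent of
perfectly consistent triplicates. No choice of $k$ rescues it — the test
statistic does not depend on the noise scale at all.

The pipeline default (`outlier_scope = "sample_set"` in
`transcription_changes()`) therefore pools information across genes:
within each strain's replicate set it computes deviations of log signals
from each gene's mean, takes the MAD of all those deviations, and discards
values beyond $k = 4$ pooled MADs ($\approx 2.7$ standard deviations for
Gaussian noise, an expected discard rate of about 0.7%). This keeps the
discard fraction in the sub-percent range expected of consistent replicates
while still catching genuinely aberrant values. The per-gene variant remains
available (`outlier_scope = "per_gene"`).

Replicate quality is summarised by all pairwise Pearson correlations of
normalised signals per strain (`replicate_concordance()`); on synthetic data
at the default noise level every pair exceeds 0.95.

### Stress-response subtraction

Thermal inactivation itself is a mild stress, so genes of the environmental
stress response (ESR) move for reasons unrelated to topo II.
`subtract_esr()` removes ESR-induced ids from the up set and ESR-repressed
ids from the down set, yielding the *strict* sets used by every downstream
enrichment. ESR membership is consumed as externally provided id lists; the
package does not re-derive them.

## The statistical kernel

* **Enrichment ratio** — observed over expected members of a class in a
  subset, expected $= |S| \cdot |C \cap U| / |U|$. The genome average
  corresponds to a ratio of 1.
* **Fisher's exact test** — two-sided, probability-ordering convention;
  delegated to `stats::fisher.test` and cross-checked in the test-suite
  against a brute-force hypergeometric enumeration on all tables with
  margins up to ten.
* **Bootstrap p-values** — `n_trials` random gene sets of the observed size
  (default 1000), two-sided on $|\mathrm{ratio} - 1|$, with add-one
  smoothing $p = (1 + b)/(1 + N)$ so that $p$ is never exactly zero. The
  two-sided tail is a package choice; one-sided alternatives are available
  via the `alternative` argument.
* **Wilcoxon rank-sum** — midranks for ties; exact by enumeration of all
  rank assignments when $n_a + n_b \le 12$, otherwise a normal approximation
  with tie correction. This is implemented in the package (rather than
  wrapping `stats::wilcox.test`) because the exact-with-ties branch is part
  of the contract; the base implementation is the independent cross-check on
  tie-free cases in the tests.
* **Z-scores** — population convention (divisor $n$); constant input is an
  error left to the caller, because the right fallback differs by context
  (TFBS rows are left raw and flagged, degenerate curvature profiles are
  returned raw with a `degenerate` attribute).
* **Expression variability** — absolute difference between the 2nd and 98th
  percentiles after discarding values strictly below the 1st and strictly
  above the 99th percentile; linear-interpolation percentiles throughout.
* **Moving average by covariate** — genes sorted by a covariate (e.g.
  transcriptional plasticity consumed as an external per-gene table), then a
  centred `window`-gene mean. At the edges the window slides (keeps its full
  size, becoming asymmetric) by default, so that `window = n` reproduces the
  global mean everywhere; a symmetric-shrink policy is available.

## Promoter geometry and TFBS

Yeast intergenic space is short (under 500 bp on average), so each gene's
promoter is taken to be the *complete* intergenic interval upstream of its
TSS, ending at the nearest boundary — 5′ or 3′ — of the closest other gene
on either strand (`promoter_regions()`). Divergent gene pairs whose TSSs lie
within 600 bp of each other, with no gene between them, share a
bidirectional promoter (`find_bidirectional_pairs()`); pair distance is
measured TSS-to-TSS, and each gene joins at most one pair.

Binding sites are accumulated per factor into strand-oriented 20-bp bins
around the TSS (`tfbs_bin_matrix()`). The default window is −500..+300,
i.e. 40 bins; both bounds are configurable. Rows can be Z-scored; rows with
zero variance are left raw and flagged rather than dividing by zero.

## Sequence composition and conservation profiles

GC content and the two Chargaff second-parity-rule (PR2) skews,

$$\mathrm{AT\ skew} = \frac{A - T}{A + T}, \qquad
  \mathrm{GC\ skew} = \frac{G - C}{G + C},$$

are computed in 100-nt windows sliding 1 nt (`sliding_composition()`), the
value assigned to the window centre. Windows with a zero denominator return
0 with a flag, keeping profiles rectangular. Per-gene vectors are extracted
5′→3′ in gene orientation and averaged position-wise over genes
(`tss_meta_profile()`). Two subtleties make minus-strand handling exact:
skew values are negated on the minus strand (complementation negates
$A - T$ and $G - C$), and for even window widths the extraction index is
shifted by one so that window *footprints* — not just centre labels —
correspond across strands. Genes whose window crosses a chromosome end are
dropped and counted. Conservation tracks are averaged the same way, with
missing positions treated as absent (mean over genes with data), and a
warning when more than half the interrogated positions lack data.

## Nucleosome organisation and dynamics

Spacing: nucleosomes are assigned to gene bodies by the midpoint rule
(any-overlap is available), and for $N$ nucleosomes the mean of the $N-1$
edge-to-edge linker lengths is reported (`gene_nucleosome_spacing()`).
Edge-to-edge is the only reading compatible with linkers of ~21–29 bp for
~147-bp nucleosomes — centre-to-centre distances would start at 147.

Occupancy: for each gene, the fraction of each 10-bp strand-oriented bin
covered by any nucleosome, averaged over genes
(`occupancy_meta_profile()`); raw values lie in $[0,1]$ and an optional
Z-score standardises the averaged profile. The same computation restricted
to one dynamic label — *appearing* (present only after heat shock),
*evicted* (lost after heat shock), *fragile* (hypersensitive to MNase) — and
reported in percent is `dynamic_overlap_profile()`.

Remodeler association: for each remodeler target list and each gene set,
the enrichment ratio plus a bootstrap p-value from 1000 randomised gene
sets (`remodeler_enrichment()`). Histone marks: per mark and per
compartment (promoter, ORF), a Wilcoxon rank-sum test of the subset against
the rest of the universe with the direction of the median difference and a
significance flag at $p < 0.001$ (`histone_mark_enrichment()`). Raw
p-values are reported with that fixed flag; no multiplicity correction is
applied across marks or remodelers.

## Nucleosome-forming potential from curvature symmetry

Nucleosomal DNA wraps a two-fold symmetric histone octamer, so sequence
with intrinsically mirror-symmetric curvature around a candidate dyad is a
good nucleosome former. The package scores this in two steps:

1. **Curvature** (`predict_curvature()`): a dinucleotide wedge model. Each
   base step deflects the helical axis by a roll angle whose direction
   rotates with the helical twist (repeat 10.4 bp/turn); the curvature at a
   base is the magnitude of the vector sum of deflections over a 31-bp
   window. The bundled roll table is the package's own consensus-style
   scale — A-tract steps rigid and straight, pyrimidine–purine steps (TA,
   CA/TG, CG) flexible, others intermediate — in an editable TSV. A
   roll-only geometry makes the model reverse-complement consistent by
   construction, which the loader verifies; this is what guarantees that
   recomputing on the opposite strand mirrors the profile to within
   rounding.
2. **Symmetry** (`symcurv_score()`): at each position $i$,
   $D(i) = \frac{1}{w}\sum_{k=1}^{w} |c(i-k) - c(i+k)|$ over flanks of
   $w = 73$ bp (the nucleosome half-length), and
   $S(i) = 1/(1 + D(i)) \in (0, 1]$, equal to 1 exactly on mirror-symmetric
   flanks. Ambiguous bases mask every window that touches them, and masks
   propagate from curvature into the symmetry score.

No claim of numerical equality with any published nucleosome-potential
track is made; the score is a faithful implementation of the
curvature-symmetry concept with documented, configurable defaults.
`symcurv_meta_profile()` averages $S$ around TSSs and Z-scores the result;
a numerically constant profile (relative sd below $10^{-8}$) cannot be
standardised and is returned raw with a `degenerate` flag.

## The synthetic world

`world_config()` + `generate_world()` build, deterministically per seed:

* genes tiled over chromosomes with log-normal body lengths (mean 1200 bp,
  minimum 600) and shifted-geometric intergenic gaps (mean 400 bp,
  matching the short intergenic spacing of yeast); random strands make
  roughly a quarter of adjacent pairs divergent;
* GRO signals: control $= b_g \cdot e^{\varepsilon}$, mutant
  $= b_g \cdot f_{\mathrm{class}} \cdot e^{\varepsilon}$ with
  $\varepsilon \sim N(0, \sigma^2)$, $b_g$ log-normal, and per-array gDNA
  scalars multiplied in so normalisation has real work to do; planted folds
  default to 2.0 (up) and 0.5 (down) on 5% and 3% of genes;
* promoter composition: a GC dip over (−250, 0) (deeper for the down class,
  shallower for up) and a PR2 switch — pyrimidine excess upstream, purine
  excess downstream — of amplitude 0.15;
* nucleosomes: an NFR over (−80, 0), a +1 nucleosome at the TSS, a phased
  downstream array with class-specific linkers (29 bp up, 21 bp down,
  25 bp unchanged), and −1/−2 nucleosomes confined to the upstream
  intergenic space so they never intrude into a neighbour's gene body;
* dynamics: an appearing nucleosome at the +1 position of down genes,
  evicted and fragile nucleosomes upstream of deregulated TSSs;
* a 180-bp mirror-symmetric (reverse-complement palindromic) cassette
  centred on the +1 dyad of up genes, which the curvature-symmetry profile
  should find;
* mark scores with class-specific shifts (up genes hypo-acetylated, down
  genes with promoter H2AZK14ac and ORF H3K4me3 gains), remodeler target
  lists over-sampling down genes three-fold and under-sampling up genes,
  and ESR lists containing one-third of each planted set.

What it does **not** emulate: array image noise, probe cross-hybridisation,
cell-cycle structure, transcript-length effects, overlapping or nested
genes, real yeast sequence composition beyond the planted features, and
correlated replicate noise. Passing tests therefore demonstrate that the
pipeline recovers the stated signal kinds at realistic effect sizes and
noise levels — not that it reproduces any particular laboratory data set.

## Numerical choices and degenerate inputs

* Classification thresholds are strict inequalities; $R = 1.5$ is
  `unchanged`.
* MAD is unscaled (no 1.4826 factor) wherever it appears.
* Percentiles use linear interpolation (type 7).
* Coordinates are 0-based half-open everywhere internally and in BED
  output; the TSS is the first transcribed base; bins are half-open
  $[kb, (k+1)b)$; profile offset 0 is the TSS base with upstream negative.
* Zero-variance inputs: `zscore()` errors; TFBS rows are flagged and left
  raw; degenerate curvature profiles are flagged; MAD = 0 retains all
  values.
* Empty gene sets error in profile functions; empty target lists are
  skipped with a warning.
* All stochastic operations accept a seed and restore the caller's RNG
  state.

## Problem sizes used by the checks

The test-suite validates recovery on worlds of 40–400 genes and a
2000-gene world (four 920-kb chromosomes) for classification recovery;
null calibration uses 500 simulations over a 4000-gene universe with
199-trial bootstraps — a design whose p-value discreteness (largest atom
about 0.06) is fine enough to resolve the Kolmogorov distance being
tested; the exact-test cross-check enumerates every 2×2 table with margins
up to ten. These sizes are the package's own choices for a
laptop-friendly, fully offline validation.

## Known limitations

* The curvature parameter scale is a documented default, not a fitted or
  published set; absolute curvature values are in arbitrary units and only
  contrasts and symmetries are interpreted.
* The promoter definition assigns zero-length promoters to genes abutting
  an upstream neighbour; such genes contribute length 0 to summaries.
* Bootstrap p-values are bounded below by $1/(1+N)$; with the default 1000
  trials no p below $10^{-3}$ can be reported.
* With triplicate data, genuinely aberrant single replicates can only be
  detected against the pooled noise scale; a replicate that is consistently
  aberrant across many genes will inflate that scale.
* GO-term analysis is exercised as generic set enrichment over
  user-provided term-to-gene maps; the ontology graph itself is out of
  scope, as are nucleosome calling from reads, TFBS motif scanning and
  conservation-score computation — all are consumed as tables or tracks.
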