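---
title: "Methods: genomic features, 16S diversity and group comparison"
author: "beGenomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic features, 16S diversity and group comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

beGenomics asks a comparative question: do the bacterial genera that turn up
again and again in surveys of the built environment (indoor, outdoor,
underground and extreme human-constructed habitats — the "Common BE" group)
carry genomic signatures that distinguish them from other sequenced
prokaryotes? The package computes four per-chromosome features and a set of
intra-genus 16S rRNA diversity indices, then runs a nonparametric two-group
statistical battery. This vignette explains each method, its assumptions,
the tunable parameters, and the design decisions taken where the underlying
definitions left room.

## Input model

Analyses start from complete annotated replicons in GenBank flat-file
format. When an organism has several replicons, the largest one not
annotated as a plasmid represents the organism (if every record is a
plasmid, the largest overall — this keeps the rule total). Equal lengths are
broken by the lexicographically smallest accession so the choice is
deterministic and order-independent. Coordinates are 1-based inclusive
(GenBank convention) everywhere. Ambiguous bases are retained in the
sequence but never enter a composition denominator.

Group membership is a property of the genus: a genus observed in at least
`threshold` surveyed publications (default 6, roughly 10% of a 54-study
corpus) is "Common BE", everything else is "Other". The genus defaults to
the first whitespace-delimited token of the organism name, with an optional
per-accession override for names such as "Candidatus ...". Genera missing
from the grouping table fall back to "Other" with a warning rather than an
error, because a missing survey entry is an absence of evidence.

## The four genomic features

**Genome size** is the count of unambiguous A/T/G/C characters, and
**GC content** is 100·(G+C)/(A+T+G+C) over the same set.

**GCSI (GC skew index)** quantifies replication-strand compositional
asymmetry. The chromosome is cut into `nWindows` equal windows (default
4096; the trailing `L mod nWindows` bases are truncated rather than padded,
so all windows are equal-sized and the bias is at most `nWindows - 1` bp).
Each window contributes a GC skew (C−G)/(C+G) counting only C and G; a
window with neither gets skew 0. A chromosome with a single
origin/terminus pair replicates as two arcs of opposite strand bias, so its
skew vector oscillates once per genome. GCSI captures this with two
statistics of the 4096-point skew vector:

* `sr`, the spectral ratio: the power of the fundamental frequency (1 cycle
  per genome) of the discrete Fourier transform, divided by the mean power
  over frequencies 1..nWindows/2. The zero-frequency (DC) term is excluded
  from the mean: it measures overall skew offset, not oscillation, and
  including it would let a constant skew depress the ratio.
* `dist`, the amplitude of the cumulative skew curve: max − min of the
  running sum of window skews, which peaks at the terminus for a
  well-skewed chromosome.

The index is the normalized geometric mean
`gcsi = sqrt((sr/6000) · (dist/600))`. The two normalization constants are
exposed as arguments (`srNorm`, `distNorm`); the defaults place typical
strongly skewed bacterial chromosomes near 1 and skew-free sequence near 0.
On i.i.d. random 2 Mb sequence the index stays below 0.05 (the test suite
checks < 0.05; observed values are ~0.001).

**S value** measures translationally selected codon usage bias. Four amino
acids — Phe (TTC/TTT), Tyr (TAC/TAT), Ile (ATC/ATT) and Asn (AAC/AAT) — are
each encoded by a C-ending and a T-ending codon read by the same tRNA, the
C-ending one more efficiently. Selection for translation speed therefore
inflates C-ending usage specifically in highly expressed genes (HEG),
relative to the genome-wide background set by mutation. The HEG set is
identified by product annotation: ribosomal proteins and translation
elongation factors (Tu, G, Ts, P), case-insensitively, with a negative
pattern list excluding enzymes that merely act on ribosomal proteins
(methyltransferases, kinases, hydroxylases, pseudouridine synthases).

With background C-ending proportion $c_f$ for family $f$ (from all
annotated non-pseudo CDS of the chromosome) the HEG C-ending count $k_f$ of
$n_f$ family codons is modeled as Binomial($n_f$, $p_f$) with

$$p_f = \frac{c_f e^S}{1 - c_f + c_f e^S},$$

a single selection strength $S$ shared across the four families. $\hat S$
maximizes the joint log-likelihood over $[-10, 10]$ (Brent optimization,
tolerance $10^{-6}$; the test suite checks agreement with a grid-search
oracle to $10^{-3}$). Degenerate families ($k_f = 0$ or $n_f$) get a 0.5
pseudocount on both HEG codon counts so the estimate stays finite without
biasing typical genomes; families with zero whole-genome usage, or a
background proportion of exactly 0 or 1, carry no information about $S$ and
are dropped. Per-family log-odds differences are reported as diagnostics.

Two interpretation decisions were genuinely open. First, the "entire
genome" background includes the HEG genes themselves: this matches the
phrase literally, and in real genomes HEG are a negligible fraction of
total codons, so the contamination is immaterial (the synthetic defaults
keep HEG at ~2% of codon mass for the same reason). Second, codon counting
is strand-resolved and frame-aware: `codon_start` shifts the frame, a
trailing partial codon is truncated with a warning, the terminal stop codon
is excluded, codons containing ambiguous bases are ignored, and a CDS with
internal stop codons is presumed misannotated and skipped with a warning.

## 16S diversity

Intra-genus diversity uses an aligned 16S rRNA set with genus labels taken
from the alignment's headers (not re-derived). Pairwise distances follow
the Kimura two-parameter (K80) model with pairwise deletion: only columns
where both sequences hold unambiguous A/C/G/T are compared, matching the
default behavior of the standard distance function in the `ape` package
(which the test suite uses as an independent cross-check). With transition
proportion P and transversion proportion Q,

$$d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q).$$

Saturated pairs (non-positive log argument) yield a missing distance with a
warning rather than an infinity; `dmean()` excludes them from the mean and
reports how many were dropped. Dmean is defined only for genera with more
than 2 taxa. Faith's PD is the total branch length of the minimal
root-inclusive subtree spanning the genus's taxa — root-inclusive so that a
single taxon degenerates to its root-to-leaf path and PD is monotone under
taxon addition. Pearson correlations among (N, Dmean, PD) quantify how much
each index merely tracks taxon availability N.

## Group statistics

Each feature is compared between groups with the two-sided Wilcoxon
rank-sum test. The p-value is exact (null distribution of U) whenever
n1·n2 ≤ 400 and there are no ties — exhaustive enumeration is the test
oracle — and otherwise uses the normal approximation with tie correction
and continuity correction, the large-sample behavior of the standard R
test. The switch point keeps desk-scale comparisons exact while matching
the asymptotic regime used for genome-scale group sizes. When every value
in both groups is identical, p = 1 by convention.

q-values are Benjamini–Hochberg step-up adjusted *within each battery* (the
set of features passed to one `compareGroups()` call, or all category ×
feature tests of one `environmentBattery()` call), mirroring joint
adjustment across one analysis run; the battery membership is whatever the
caller passed, and the output records it row by row.

Cliff's delta is the dominance effect size
(#{x>y} − #{x<y})/(n1·n2); ties contribute zero. Magnitudes follow the
conventional thresholds |d| < 0.147 negligible, < 0.33 small, < 0.474
medium, else large. The identity δ = 2U/(n1·n2) − 1 (with half-credit
ties in U) is checked against brute-force pair counting in the tests.

## The synthetic-data generator

The generator exists so that every stage has inputs with known ground
truth. A `genomeSpec()` draws a circular chromosome with:

* an intergenic backbone whose bases are i.i.d. per position with
  strand-dependent probabilities — on the leading arc (origin at fractional
  position 0.0 to terminus at 0.5 by default) P(G) = gc/2·(1+k) and
  P(C) = gc/2·(1−k), reversed on the lagging arc, A/T splitting the rest
  evenly — so `k` directly tunes the strength of replication skew;
* non-overlapping genes on alternating strands (to exercise strand-aware
  extraction), each an ATG start, `codonsPerFamilyPerGene` codons of each
  two-codon family drawn with C-ending probability from the selection model
  (S = `sTrue` for HEG genes, 0 for the rest, background proportion
  `cBackground` = 0.5), `fillerCodonsPerGene` filler codons, and a TAA stop.

Filler codons exclude stop codons and the eight family codons, so the
family counts the estimator sees are exactly the generator's controlled
draws; their base composition is solved numerically so the expected
genome-wide GC equals the target despite the AT-rich family codons (the
tests check agreement within 0.5 percentage points at 2 Mb).

Default study conditions, chosen once: 2 Mb, GC 0.5, k = 0.2, 20 HEG + 980
background genes, sTrue = 1, 12 family codons per family per gene with 270
filler codons (~1 kb genes, HEG ≈ 2% of codon mass — the same order as
ribosomal-protein operons in real bacteria, and small enough that the
background-includes-HEG convention costs the estimator only ~0.03 at
S = 2). Recovery experiments that need 2000 HEG codons per family raise
`codonsPerFamilyPerGene` to 100 and drop the filler, shrinking the genome
to ~1.25 Mb; the conditions constrain codon counts, not intergenic DNA.

`alignmentSpec()` draws a uniform ancestor and evolves each taxon
independently along a branch of d/2 expected substitutions/site using the
closed-form K80 transition probabilities, so every pair is at expected
divergence d (additivity); kappa sets the transition/transversion rate
ratio, and gaps are only introduced on request.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: codon structure outside the four tracked families,
operon organization, gene-length and expression-level variation,
GC-content heterogeneity along the chromosome, indel evolution, horizontal
transfer, rRNA sequence heterogeneity within a genome. Passing the suite
demonstrates that the estimators recover the quantities they define under
their own model assumptions, not that those assumptions hold for any
particular genome.

## Numerical choices and degenerate inputs

* GCSI: truncation not padding; windows with C+G = 0 get skew 0; the index
  is clamped at 0 against numeric noise; `sr` via FFT, validated against a
  brute-force Fourier sum for short vectors.
* S: bounded Brent optimization, interval [−10, 10], tolerance 1e−6;
  pseudocount only on degenerate HEG families; missing (NA) S when the HEG
  set is empty or carries no family codons.
* K80: error on zero comparable columns (distinguishing "no signal" from
  "distance 0"); NA with warning on saturation.
* Wilcoxon: exact/approximate switch at n1·n2 = 400, config-exposed;
  σ² = 0 (all values tied) gives p = 1.
* Replicon ties: lexicographic accession; group partition is always total.
* Malformed GenBank feature locations (including origin-spanning ones) are
  skipped with a warning and counted per record, rather than failing the
  whole file; a record without sequence is a hard error naming the LOCUS.
* RNG: one seed per generator spec; a pipeline run seeds once from its
  config, and reruns with identical inputs and config are byte-identical
  (output tables carry the package version, a config fingerprint that
  excludes the output path, and the seed).

## Problem sizes used in validation

The shipped validation suite uses: 200 replicate genomes (50 per true S in
{0, 0.5, 1, 2}) at 2000 HEG codons per family for S recovery (observed
recovery rate ≥ 95% at |error| < 0.1); 3 null and 25 skewed 2 Mb genomes
(5 seeds × 5 k levels) for the GCSI null level and monotonicity; 8
alignments of 10 taxa × 1500 columns at d = 0.04 for divergence recovery;
exhaustive Wilcoxon enumeration for all group sizes up to 5×5 and 100
random samples for Cliff's delta. A 16-genome two-group cohort with a
constructed S shift exercises the full pipeline end to end. These sizes
were chosen to give each statistical check comfortable power while staying
desk-scale.

## Known limitations

* The GCSI normalization constants are conventions, not fitted quantities;
  comparisons across studies should pin them explicitly.
* Reproducing published per-genome values requires the corresponding
  public-database chromosomes and 16S alignments as inputs; the package
  deliberately performs no downloading.
* The S model assumes a single shared selection strength across the four
  families; per-family log-odds are reported so users can inspect
  heterogeneity, but the joint estimate does not model it.
* Dmean and PD inherit the 16S gene's known limitations (intra-genomic
  heterogeneity, occasional horizontal transfer) and the alignment's
  taxonomy labels are trusted as given.
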