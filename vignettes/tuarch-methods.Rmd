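---
title: "Transcription-unit architecture analysis: models and methods"
author: "tuarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcription-unit architecture analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tuarch)
```

## Scope

`tuarch` analyses bacterial gene expression through the lens of
*transcription-unit (TU) architecture*: each gene's transcript is modeled
as 5'-UTR + CDS + 3'-UTR, delimited by a transcription start site (TSS,
from dRNA-seq-style annotation) and a transcript 3'-end position (TEP,
called from Term-seq 3'-end counts). On that architecture the package
quantifies where ribosomes sit (metagene extremity/torso analysis, UTR
enrichment degree), how transcript and ribosome-footprint abundance
respond to conditions (median-of-ratios normalization, differential
expression, translation efficiency), and what the terminator sequences
look like (positional composition, hairpin free energy against an
intergenic background).

Read trimming and alignment are upstream of this package: inputs are a
genome FASTA, a GFF3 annotation, a TSS table, per-base strand-specific
coverage tracks (bedGraph) and per-gene count matrices. A seeded
synthetic-data generator produces all of these with the statistical
structure the analysis assumes, so every stage is testable end-to-end
without external data.

## Coordinate conventions

All internal computation uses 1-based inclusive genomic coordinates;
bedGraph's 0-based half-open intervals are converted only at I/O. Around
codon anchors two relative systems coexist, and keeping them straight is
the main source of off-by-one risk in this kind of analysis:

* **Signed window coordinates** (no zero): relative to the start codon,
  +1 is the first base of the start codon and -1 the base immediately
  5' of it; relative to the stop codon, -1 is the last base of the stop
  codon and +1 the first base past it. Extremity windows and the torso
  are expressed this way, matching the field's "-1 position of the start
  codon" phrasing. Under this convention the default windows
  [-30, +60] and [-33, +15] cover 60 and 33 CDS bases respectively, so
  a 300-bp CDS has a 207-bp torso.
* **Metagene profile offsets**: integers $-W..+W$ including 0, with
  offset 0 on the anchor base itself. `determine_boundary()` scans
  profiles in this system and converts the crossings it finds into
  signed window coordinates before returning an `extremity_partition`.

`region_positions()` is the single authority mapping windows to genomic
positions; every consumer (torso counts, region fold changes, the
simulator's stall placement) goes through it, so the two conventions
cannot drift apart silently.

## The UTR enrichment degree

For a TU spanning TSS $t$ to TEP $p$ with start codon first base $s$,
stop codon last base $e$, and per-position depth $d_i$ (RNA-seq or RPF),
the 5'-UED is

$$R_{5utr} = \frac{\sum_{i=t}^{s-1} d_i / l_{5utr}}
                  {\sum_{i=t}^{p} d_i / l_{tu}}$$

and the 3'-UED replaces the numerator with the mean depth over
$e+1..p$. Both are ratios of a regional mean to the whole-TU mean: a
uniform track gives exactly 1, any rescaling of the track cancels, and
values above 1 indicate depth enrichment in the UTR (for RPF, ribosome
occupancy beyond the CDS — the signature of stalled or queued
ribosomes near initiation).

Numerical choices:

* **Leaderless genes** ($l_{5utr} = 0$): the 5'-UED divides by the
  5'-UTR length, so it is undefined; these TUs are flagged and excluded
  from 5'-UED tables rather than pseudocounted, because a pseudocount
  distorts short UTRs the most.
* **Zero-depth TUs**: undefined (NA), excluded, reported.
* **Replicates** are averaged position-wise per assay and condition
  before the UED is computed.
* Sums are over the gene's strand only; minus-strand TUs walk genomic
  coordinates downward.

Cross-condition comparison (`ued_compare()`) uses a paired one-sided
Wilcoxon signed-rank test across genes — robust to the heavy right tail
of UED ratios — and UED-pattern clustering works on
$\log_2(\mathrm{UED}_{cond}/\mathrm{UED}_{ref})$ feature vectors.

## Metagene profiles and the extremity/torso boundary

`metagene_profile()` averages depth at fixed strand-aware offsets from
the start or stop codon over genes. By default each gene is first
normalized by its mean CDS depth so that highly expressed genes do not
dominate the average; the raw mode is retained as a flag, since both
conventions appear in the literature. Genes whose window leaves the
contig contribute only their in-range offsets.

The extremity/torso boundary follows a data-driven rule: the reference
profile is the offset-wise mean of the non-stress conditions, and
scanning from each codon outward, the boundary is the last offset before
the stress profile has decreased to the reference. Equality counts as
crossed — an offset where stress merely matches the reference belongs to
the torso. If the stress profile never comes down to the reference
within $\pm W$ the scan errors out and asks for a manual window (the
pipeline then falls back to the configured defaults). No smoothing is
applied by default; a centered moving average of configurable width is
available because single-base noise can otherwise produce spurious early
crossings.

Fold changes per region (extremity = both windows, torso = the interior
CDS) are computed on size-factor-scaled depth sums with a pseudocount,
and clustered with Ward/Euclidean agglomerative clustering (defaults
k = 7 for extremity fold changes, k = 9 for UED patterns — both exposed,
since no principled cluster count exists for these data). Cluster labels
are relabeled stably by decreasing mean of the first feature so that
runs are comparable.

## TEP calling and classification

Term-seq tracks hold transcript 3'-end counts (the track producer maps
each read's 5' end to the opposite strand; this package consumes the
converted tracks). Detection is deliberately simple and fully exposed:
a candidate is a position with count ≥ `min_count` (default 5) that is
a local maximum within ±3 nt, and a TEP is kept only when every
replicate has a candidate within `match_tolerance` (default 0 —
exact agreement). The replicate-consistency criterion and threshold
replace a manual-curation step; both parameters are configurable.

Classification precedence per candidate: **P/S** (inside a same-strand
window extending 250 nt past a stop codon; highest total count is
primary, ties break toward the stop codon, favoring conservative
3'-UTRs) > **I** (inside a sense CDS) > **A** (antisense to a gene) >
**U** (within 150 nt sense-upstream of a start codon, a configurable
choice) > dropped. When two same-strand downstream windows overlap, the
candidate goes to the nearer stop codon with a warning. Exactly one
P-TEP per gene is guaranteed by construction.

3'-UTR length is the strand-aware distance from the first base past the
stop codon through the P-TEP inclusive, so the minimum length is 1.

Terminator sequence characterization extracts the 40-nt transcript-sense
sequence ending at each P-TEP, tabulates positional base composition
over ±50 nt, and compares hairpin free energies against sequences drawn
uniformly from CDS-free intergenic space (default 10,000 windows in the
full pipeline). Folding is an adapter: `fold_rnafold()` shells out to
ViennaRNA's RNAfold when present; `fold_gc_stub()` is a deterministic
structure-free score for tests. Reimplementing folding thermodynamics
is out of scope.

## Expression statistics

* **Size factors** are the median-of-ratios estimator: per sample, the
  median over genes (with positive geometric mean across samples) of
  count / geometric mean. Note what this does and does not provide:
  it equalizes *relative* library composition, so multiplying every
  library by a common constant leaves the factors unchanged and scales
  normalized values — absolute TE therefore carries sequencing scale,
  while all gene- and condition-relative comparisons are invariant.
* **Expression floor**: a gene is analysed when its mean normalized
  value per condition is ≥ 10 in every condition; replicate means are
  taken before thresholding.
* **DEGs**: log2 fold changes from per-condition means (pseudocount 1);
  a gene is differential iff $|\log_2 FC| > 1$ *and* $p < 0.05$
  (raw p, as the thresholds are conventionally quoted; adjustment is a
  caller choice). The default test is a two-sided Welch t-test on
  $\log_2(\text{normalized} + 1)$, with a pluggable `test` argument
  accepting any per-gene p-value function — the interface, not the
  particular test, is the contract.
* **Translation efficiency** is the translation-to-transcription ratio
  of per-condition mean normalized RPF over RNA (pseudocount 1). A
  torso-restricted variant recomputes the RPF side from depth sums
  strictly inside the torso, which is how extremity-inflated RPF counts
  are unmasked: a gene whose apparent RPF increase lives entirely in
  stalled extremities shows a flat or reduced torso TE.
* **Functional enrichment** is an upper-tail hypergeometric test per
  term with Benjamini–Hochberg adjustment across terms; term-to-gene
  maps are plain inputs.

## The synthetic-data generator

The generator is first-class, tested code that defines the study
conditions for every downstream property check. It emulates:

* **Architecture**: single-gene TUs placed without overlap on both
  strands, separated by ≥ 50 bp intergenic spacers. 5'-UTR lengths are
  log-normal with median 53 nt (sdlog 1.0) and 3'-UTR lengths log-normal
  with median 92 nt (sdlog 0.5, floored at 1 nt) — medians matching the
  reported values for the organism class this emulates, with heavy right
  tails consistent with the reported ranges (up to ~2 kb for 5'-UTRs,
  ~500 nt for 3'-UTRs). CDS lengths are uniform multiples of 3 in
  300–3000 bp.
* **Terminators**: each TEP is preceded by a planted intrinsic
  terminator — a G/C stem of 8–12 bp, a 4–8 nt loop, the reverse
  complement stem, then a 6–9 nt U-tract ending exactly at the TEP —
  written into the coding strand (reverse-complemented for minus-strand
  genes).
* **Counts**: negative binomial, mean = baseline (log-uniform
  200–2000) × $2^{\text{planted } \log_2 FC}$ × library size factor
  (log-uniform 0.5–2). A configurable fraction of genes (default 10%)
  carries a planted $|\log_2 FC| = 2$ per non-reference condition.
* **Tracks**: RNA depth piecewise-constant over each TU proportional to
  the gene's RNA count; RPF depth uniform over CDS ± margins (30 bp
  5', 15 bp 3'), multiplied by `stall_factor` inside the extremity
  windows for the stress condition only; Term-seq end counts
  Poisson(`term_depth_mean`) per terminator and replicate, each read on
  the TEP with probability `term_peak_prob` (default 0.8) or
  1 + Geometric(0.5) nt upstream, mimicking imperfect 3'-end processing.
  Gaussian noise (σ = 5% of local mean, clipped at 0) is added to
  RNA/RPF depth; Term-seq counts stay integral.

What it does **not** emulate — and what passing tests therefore do not
establish about real data: operonic multi-gene TUs, condition-specific
TSS/TEP switching, read-level artifacts (ligation and PCR bias,
sequence-dependent coverage), Rho-dependent termination, codon-resolution
ribosome dynamics, and partial rRNA/tRNA depletion. The generator shows
the estimators recover what they claim under the stated model; it cannot
certify mapping or curation choices made upstream on real libraries.

All three generator stages are deterministic functions of the seed, so
pipeline runs are byte-identical under a fixed configuration.

## Problem sizes and verification

The shipped test-suite and the acceptance script exercise the pipeline
at desk scale, chosen to keep full runs in minutes on one CPU while
leaving the statistical checks well-powered: 100–150 genes (~300 kb
genome) for track-level properties, 1,000 genes for DEG operating
characteristics, 10 seeds for the stall-recovery and boundary-recovery
repetitions, and 2,000 intergenic background sequences for the folding
screen (the full-pipeline default remains 10,000). At these sizes the
properties verified are: UED agreement with a brute-force summation
oracle and the piecewise-constant closed form to 1e-9; detection of
≥ 95% of planted terminators within ±2 nt, classified primary; recovery
of the planted extremity windows within ±3 nt; DEG sensitivity ≥ 0.9 at
false-positive rate ≤ 0.05 under the planted conditions; and
hypergeometric p-values matching exact combinatorics to 1e-10.

## Known limitations

* Single-contig genomes only; plasmids and multi-chromosome assemblies
  are out of scope for this version.
* One architecture per gene across conditions; no condition-specific
  TU switching.
* The default differential test is a replicate-level t-test on log
  counts, not an exact NB Wald test; for small replicate numbers its
  p-values are conservative. The pluggable interface exists precisely
  so an NB test can be swapped in.
* The 5'-UED is undefined for leaderless genes; analyses of organisms
  with many leaderless transcripts should rely on the 3'-UED and the
  extremity fold changes, which remain defined.
* Boundary detection assumes the stress profile is elevated at the
  codon itself and decays to the reference within the profile window;
  diffuse, CDS-wide stalling has no crossing and requires a manual
  window.
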