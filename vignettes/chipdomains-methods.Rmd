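---
title: "Models and methods behind chipdomains"
author: "chipdomains authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chipdomains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipdomains)
```

chipdomains implements a pipeline for mapping transcription-factor binding
from single-base ChIP-seq tag data and relating it to chromatin domain
organisation. This vignette explains the models behind each stage, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the numerical choices that were genuinely open.

## Data model and coordinates

Every stage consumes *tags*: the 0-based genomic position of a read's 5'
end plus a strand, with a positive multiplicity. Read length is discarded
on input because no downstream statistic uses it — peak calling, strand
cross-correlation and segmentation all operate on 5' positions only. All
internal coordinates are 0-based and intervals half-open; 1-based dialects
are converted at the file boundary and nowhere else.

## Peak calling

`call_peaks()` counts tags (strands pooled, multiplicities capped at the
count cut-off) in a sliding window of width $W$ (default 600 bp) after
shifting each tag by $s$ bp (default 75) in its 5'→3' direction. The shift
makes the two strand pile-ups of a footprint of length $\approx 2s$
coincide at the footprint midpoint. Windows with at least $T$ tags are
candidates; candidates are accepted greedily in order of decreasing count
(ties: leftmost first), and any candidate whose center falls within the
vicinity range $V$ (default 600 bp) of an accepted center is suppressed,
so reported binding sites are pairwise at least $V$ apart. The reported
position is the window midpoint; a tag-weighted mean is available as an
option.

Candidate windows are anchored at tag positions rather than at every bp.
This loses no optima — a window can always be slid left until its first tag
sits at the window start without changing its content — and the unit tests
pin the equivalence by comparing the maximal tag-anchored window count with
a per-bp enumeration.

The caller deliberately uses no input-control background subtraction and no
P-value ranking; the tag threshold is the single knob, and nested peak sets
across thresholds (raising $T$ never adds peaks) are asserted as an
invariant.

## Weight-matrix model and EM training

Binding specificity is a 4×L additive score matrix; the score of a window
is the sum of the per-column entries for its bases, and scores live on
whatever scale the supplied matrix carries. `scan_genome()` scores both
strands of every window and keeps, per window, only the higher-scoring
strand — a dyad-symmetric motif would otherwise be counted twice at the
same position. `N` bases contribute the column mean, so assembly gaps
neither create nor destroy sites.

`train_matrix_em()` fits a one-occurrence-per-sequence motif model over
both strands by expectation–maximisation: the E-step computes a posterior
over (start, strand) per sequence from the current base-frequency matrix
against a 0-order background estimated from the input; the M-step
re-estimates frequencies from expected base counts with a pseudocount of
0.5 per base (the smoothing constant is an implementation choice; the
sources the procedure emulates do not state one). Training starts from a
consensus string — the dyad-symmetric `TTGGCNNNNNGCCAA` for NFI-family
factors — and stops when the largest per-entry frequency change drops
below `tol` or `max_iter` is reached. The observed-data log likelihood is
returned per iteration and is non-decreasing, which the test suite asserts.

Two EM caveats are worth knowing. First, for a palindromic motif the two
orientations of an embedded site are equivalent maxima; converged runs may
return either orientation of the consensus. Second, the maximum-likelihood
frequencies carry localisation noise on top of counting noise: on 500
200-bp sequences with one planted instance each (the default generator
motif, consensus-base probability 0.85), an estimator that knows the
planted positions reaches a maximum per-column Euclidean error of about
0.035, while EM lands at 0.05–0.12; at 2000 sequences EM reaches about
0.02. Matrix recovery to within 0.05 per column should therefore not be
expected from 500 sequences at this motif sharpness — a limitation of the
sample size, not of the optimiser — and the corresponding acceptance-suite
assertion documents this by failing at those conditions.

## Strand cross-correlation

Single-end sequencing reads start at the two extremities of each
protected fragment, so `+`-strand and `-`-strand tag positions flanking a
binding event are separated by the fragment length. `correlate()` bins
target-feature multiplicities by signed distance to reference features and
normalises by the genome-wide average target frequency, so a uniform
target gives a profile of 1 everywhere — this fixed point is a unit test.
`strand_cross_correlation()` correlates `-` tags around `+` tags; the mode
of the positive side estimates the protected-fragment length. Multiplicity
capping (default 10 per co-localised position) keeps PCR jackpots from
dominating the profile.

Binning follows one fixed tie convention: distance $d$ falls in the
left-open bin $((k-1)b, kb]$, and $d = 0$ is assigned to the first
positive bin. Mirror symmetry of swapped profiles therefore holds exactly
only off bin edges, which the tests respect by construction.

The global normalisation denominator uses the total genome length from the
genome table, not a mappability-corrected length; with real data the
difference is a constant factor on all bins of a profile, so modes and
fold-comparisons between profiles of the same genome are unaffected.

## Two-state segmentation

`partition()` labels each chromosome into signal-rich and signal-poor
segments by maximising

$$\sum_{\text{tags in rich}} c_i \;-\; d \cdot \text{(rich length in bp)}
  \;-\; P \cdot \text{(number of state switches)},$$

with per-position counts $c_i$ capped at the count cut-off (default 5),
density threshold $d = 0.004$ tags/bp and switch penalty $P = 20$.
Chromosome ends are fixed poor, so every rich segment pays $2P$. An
optimal rich segment begins and ends at tag positions, which licenses an
exact $O(n)$ dynamic program over sorted tag positions; exhaustive
enumeration on toy chromosomes pins the implementation. Ties are broken
toward fewer and shorter rich segments. Two consequences of the objective
are useful intuition: a rich segment is only worth opening once its tags
beat $d \cdot \text{length} + 2P$, and a poor gap shorter than $2P/d$
(10 kb at the defaults) between two rich stretches is absorbed rather than
split.

Boundaries are emitted at the two edges of every rich segment, excluding
chromosome ends, with a polarity naming the side on which the enriched
segment lies (`rich-right` at left edges, `rich-left` at right edges).

## Boundary statistics

`match_sites_to_boundaries()` matches each boundary to its nearest site
within a radius (closed interval; 2.5 kb default, the one radius used
throughout), reporting the distance signed toward the enriched side — a
site exactly at the boundary counts as rich-side. Double boundaries
(`colocalize_boundaries()`) pair boundaries of two marks one-to-one,
greedily by distance, requiring opposite polarities by default, which is
what makes an active/silent mark pair delimit a domain. Boundaries are
classified against gene annotation with TSS taking precedence over TES.

Random controls (`sample_random_sites()`) draw, per chromosome, the same
number of uniform positions as the observed site list, and
`enrichment_test()` compares match counts with a one-sided binomial:
$p = P(\mathrm{Bin}(n, k_{\text{rand}}/n) \ge k_{\text{obs}})$. Two
honest caveats. Percentages in the result are truncated, not rounded, to
two decimals — the convention under which published per-row percentages
reproduce from their counts. And treating the control rate as the true
null rate ignores the control's own sampling variance; with a single
same-size control the p-value distribution under a fully random null is
$\Phi(\sqrt{2}\,\Phi^{-1}(U))$ rather than uniform, i.e. anti-conservative
in the tails. The calibration suite therefore estimates the null rate from
a pooled control (200 draws) before checking uniformity; single-control
p-values should be read as rankings rather than exact tail probabilities.

## Expression integration

Features are assigned to genomic compartments with the precedence
5'UTR > 3'UTR > coding exon > intron > 5 kb upstream > 5 kb downstream >
intergenic, so counts partition the feature set; densities divide by the
disjoint span of each compartment. The precedence order is a package
decision — any overlap rule must pick one — and genes without exon
structure contribute their whole body as intron.

Regulation classes compare wild-type and knock-out expression on the array
log scale, $\Delta = \mathrm{wt} - \mathrm{ko}$: up-regulated
($\Delta > 0.5$), down-regulated ($\Delta < -0.5$) and non-regulated
($|\Delta| < 0.05$), with strict inequalities, so intermediate genes belong
to no class. A gene is "bound" when a peak center lies within 5 kb 5' of
its TSS (strand-aware, TSS included); bound and unbound expression means
are compared with a two-tailed Welch test, which the tests check against
the closed form.

## What the synthetic data emulates

The generators in `sim_params()`/`make_genome()`/`make_chip_tags()`/
`make_histone_track()`/`make_genes_expression()` produce inputs with known
ground truth:

* **Genome and sites.** Uniform-base chromosomes with non-overlapping
  motif instances sampled from the weight matrix's implied base
  distribution, tempered per site so realised scores spread over a target
  range (by default the upper half of the attainable range).
* **ChIP tags.** Per site, fragment counts are Poisson around
  $\lambda_0 e^{\gamma (s - s_{low})}$ — the minimal model consistent with
  an exponential score–occupancy relation ($\lambda_0 = 5$, $\gamma = 0.3$
  per score unit by default). Each fragment spans the site, has
  truncated-normal length (180 ± 40 bp, minimum 100 — mono-nucleosome
  sized; a 260 bp sequencing-insert preset is one parameter away), and
  yields one `+` and one `-` tag at its ends. PCR duplication adds
  geometric extra copies per tag (duplication probability 0.3), and
  uniform background tags are added at 8×10⁻⁴ per bp, about one tag per
  1.2 kb.
* **Histone tracks.** Piecewise-constant Poisson tags at 0.02 per bp in
  rich and 0.001 per bp in poor segments; random layouts draw segment
  lengths as 20 kb + Exponential(30 kb), i.e. mean 50 kb with a 20 kb
  floor. The floor reflects the tens-of-kb scale of histone-modification
  domains; it also keeps planted boundaries detectable in principle, since
  a domain much below $2P/d$ is absorbed by the optimal segmentation and
  no exact solver could report it.
* **Expression.** Wild-type levels Uniform(2, 13); knock-out values are
  shifted by a class-dependent $\Delta$ matching the regulation-class
  definitions exactly, so classification can be checked as a label round
  trip.

All generators are deterministic given their seed. What they do *not*
emulate: mappability and repeat structure, GC and fragmentation bias,
chromatin-state-dependent background, probe-level microarray noise, and
correlated occupancy of nearby sites. Passing the recovery tests therefore
shows the estimators are correct under their stated models, not that real
data meets those models.

## Problem sizes and test design choices

The recovery suites run at sizes chosen to make the statistical targets
meaningful: slope recovery uses 500 sites on a 4 Mb genome, since denser
placement lets the 200 bp attribution rule hand tags to interleaved
neighbours and attenuates the fitted slope; boundary recovery uses ten
2 Mb tracks; the footprint-mode check uses fixed-length fragments, where
the mode is sharp, rather than the dispersed default. Oracle-equivalence
suites run the exact algorithms against brute force on hundreds of small
random instances; the segmentation oracle enumerates rich/poor labelings
of the tags, which is complete only on chromosomes shorter than $2P/d$,
and the test instances respect that bound.

## Known limitations

* Published genome-scale counts (peak numbers per threshold, predicted
  site counts at a score cut-off, enrichment factors on real data) depend
  on specific deposited datasets, an mm9 assembly and a proprietary
  mapping step; the package reproduces the printed worked-example
  arithmetic and the methods' statistical behaviour, not those dataset
  counts.
* Matrix scores are opaque units; the published 0–100 scale of the
  deposited NFI matrix comes from an affine transform defined elsewhere,
  so thresholds like 67 or 90 only mean something for that matrix, which
  is an optional external input. The in-package `nfi_matrix()` is a
  consensus-derived synthetic stand-in.
* The binomial enrichment p-value inherits the single-control caveat
  described above.
* EM matrix recovery at 500 input sequences carries localisation noise of
  the order of 0.05–0.1 per column for a motif of the default sharpness;
  supply more sequences (or a sharper motif) when absolute frequency
  accuracy matters.
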