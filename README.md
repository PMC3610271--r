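# chipdomains

Tools for mapping transcription-factor binding from ChIP-seq tag data and
relating it to chromatin domain organisation. The package re-implements,
as tested R functions with a closed synthetic-data testing loop, the
analysis chain used to show that a nucleosome-interacting transcription
factor (NFI/CTF family) binds preferentially at the boundaries between
histone-modification domains:

* **Peak calling** — tags (read 5' ends) are deduplicated, shifted 5'→3',
  counted in a sliding window, thresholded, and greedily suppressed within
  a vicinity range so reported binding sites are well separated
  (`dedupe_and_shift()`, `call_peaks()`).
* **Weight-matrix site prediction** — additive 4×L position weight matrix
  scanning of both strands with per-window strand resolution
  (`scan_genome()`, `score_window()`), and EM training of a matrix from
  bound sequences starting from a consensus (`train_matrix_em()`).
* **Strand cross-correlation** — the distribution of `-`-strand tags
  around `+`-strand tags; its mode estimates the protected-fragment
  (footprint) length (`strand_cross_correlation()`).
* **Two-state segmentation** — an exact dynamic program labels each
  chromosome into signal-rich and signal-poor segments maximising
  `Σ counts − d·(rich length) − P·(switches)`, and emits polarity-bearing
  domain boundaries (`partition()`, `boundaries_from_segments()`).
* **Boundary statistics** — site-to-boundary matching with rich/poor-side
  distances, opposite-polarity double boundaries, TSS/TES classification,
  per-chromosome random controls, and one-sided binomial enrichment
  (`match_sites_to_boundaries()`, `colocalize_boundaries()`,
  `enrichment_test()`).
* **Expression integration** — genomic-compartment densities, expression
  binning, knock-out regulation classes, and bound-vs-unbound expression
  comparison by Welch t-test (`annotate_compartments()`,
  `classify_regulation()`, `bound_vs_unbound_expression()`).
* **Synthetic data with ground truth** — genomes with planted motif
  instances, tag sets with an exponential score–occupancy law and a
  fragment-length model, histone tracks with planted domains, and
  two-condition expression tables (`sim_params()`, `make_genome()`,
  `make_chip_tags()`, `make_histone_track()`, `make_genes_expression()`).

All coordinates are 0-based half-open; tags are single 5'-end positions
with strand and multiplicity. File formats: BED6, FASTA, UCSC
`chrom.sizes`, tab-separated gene/expression tables (see `?read_genes`,
`?read_expression`), a 3/4-column `chrom pos strand [count]` tag dialect,
and plain-text 4×L matrix files.

## Worked example

Simulate a two-chromosome 1 Mb genome with 120 planted binding sites,
generate ChIP tags, and run the pipeline:

```r
library(chipdomains)

params <- sim_params(genome_length = 1e6, n_chroms = 2, seed = 1,
                     n_planted_sites = 120)
sim  <- make_genome(params)                       # genome + ground truth
tags <- make_chip_tags(sim$sites, params, sim$genome)

pp    <- peak_params(threshold = 5)               # W=600, shift=75, V=600
peaks <- call_peaks(dedupe_and_shift(tags, pp, sim$genome), pp, sim$genome)
nrow(peaks)
#> [1] 112
head(as.data.frame(peaks), 3)
#>   chrom center count start   end
#> 1  chr1   7618    29  7318  7918
#> 2  chr1  11437    96 11137 11737
#> 3  chr1  22396     7 22096 22696

# footprint length from the +/- tag cross-correlation (fragments ~180 bp)
xc <- strand_cross_correlation(tags, correlation_params(bin = 10, range = 400),
                               sim$genome)
xc$modal_distance
#> [1] 175

# validate peaks against weight-matrix predictions (ENCODE-style rule)
sites <- scan_genome(sim$matrix, sim$seqs, threshold = sim$score_range[1])
me <- motif_enrichment_profile(peaks, sites)
c(central = me$central_frequency, factor = me$enrichment_factor)
#>  central   factor
#>    0.607      4.2     # encode_pass: TRUE

# segment a histone track into rich/poor domains and test peak-boundary
# co-localisation against a random control
track <- make_histone_track(params, sim$genome, "random")
seg <- partition(track$tags, segmentation_params(), sim$genome)
bnd <- boundaries_from_segments(seg, mark = "H3K27me3")
m   <- match_sites_to_boundaries(bnd, data.frame(chrom = peaks$chrom,
                                                 pos = peaks$center))
rnd <- sample_random_sites(data.frame(chrom = peaks$chrom), sim$genome,
                           seed = 2)
mr  <- match_sites_to_boundaries(bnd, rnd)
et  <- enrichment_test(attr(m, "summary")$n, attr(m, "summary")$k_matched,
                       attr(mr, "summary")$k_matched)
c(et$k_obs, et$k_rand, et$p_value)
#> [1] 13.000 8.000 0.021
```

Of the 20 domain boundaries, 13 (65%) have a called peak within 2.5 kb
versus 8 (40%) for an equally sized random control — a one-sided binomial
p of 0.021. The 112 peaks recover the planted strong sites, the
cross-correlation mode sits at the planted mono-nucleosomal fragment
length, and the peak set passes the four-fold/10% motif-enrichment
validation rule.

A thin command-line wrapper over the same functions is installed at
`inst/cli/chipdomains.R` with `call-peaks`, `partition` and `correlate`
subcommands; see the header of that file for usage.

The methods vignette (`vignettes/chipdomains-methods.Rmd`) documents the
models, the parameter defaults and their units, the synthetic-data
assumptions, and known limitations.

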