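# Binned, globally normalised frequency of target features as a function of
# signed distance to reference features, plus its specialisations.

#' Correlation parameters
#'
#' @param bin bin width b in bp.
#' @param range distance range R in bp on each side of the reference;
#'   rounded up to a multiple of `bin`.
#' @param cap per-position multiplicity cap applied to both feature sets
#'   (co-localised counts above the cap are reset to it).
#' @param oriented flip the sign of distances around `-`-strand references
#'   (used for TSS-centred profiles)?
#' @return A `correlation_params` list.
#' @export
correlation_params <- function(bin = 50, range = 2500, cap = 10,
                               oriented = FALSE) {
  if (bin <= 0) stop("bin must be > 0")
  if (range < bin) stop("range must be >= bin")
  structure(list(bin = bin, range = range, cap = cap, oriented = oriented),
            class = "correlation_params")
}

feature_positions <- function(x) {
  if (!is.null(x$center)) x$center else x$pos
}

#' Positional correlation profile
#'
#' For every reference feature, target multiplicities (capped) are
#' accumulated into bins of signed distance `target - reference`; with
#' `oriented = TRUE` the sign is flipped around `-`-strand references. Bins
#' are left-open: distance d falls in bin `(k-1)b < d <= kb`, and d = 0 is
#' assigned to the first positive bin `(0, b]`. The normalised value is
#'
#'   (bin count / n_reference / b) / (total target count / genome length),
#'
#' i.e. the fold change of the local target frequency over the genome-wide
#' average; a uniformly distributed target gives values around 1
#' everywhere.
#'
#' @param reference,target data frames with columns `chrom`, `pos` (or
#'   `center`), optional `count` and (for oriented references) `strand`.
#' @param params a [correlation_params()].
#' @param genome a [genome_table()]; supplies the total length for the
#'   global normalisation.
#' @param repeat_mask optional interval data frame (`chrom`, `start`,
#'   `end`); target features inside it are removed before correlation.
#' @return A `correlation_profile` data frame with columns `bin_center`
#'   (signed bp), `raw` (accumulated counts) and `value` (fold over global
#'   average), with `n_reference`, `total_target` and the parameters in
#'   attributes.
#' @export
correlate <- function(reference, target, params = correlation_params(),
                      genome, repeat_mask = NULL) {
  if (nrow(reference) == 0L) stop("reference feature set is empty")
  b <- params$bin
  K <- ceiling(params$range / b)
  if (!is.null(repeat_mask)) {
    tp0 <- feature_positions(target)
    target <- target[!point_in_intervals(target$chrom, tp0, repeat_mask), ,
                     drop = FALSE]
  }
  rw <- if (!is.null(reference$count)) pmin(reference$count, params$cap)
        else rep(1, nrow(reference))
  tw <- if (!is.null(target$count)) pmin(target$count, params$cap)
        else rep(1, nrow(target))
  rpos <- feature_positions(reference)
  tpos <- feature_positions(target)
  rstr <- if (params$oriented) {
    if (is.null(reference$strand)) stop("oriented correlation needs reference strands")
    reference$strand
  } else rep("+", nrow(reference))

  raw <- numeric(2L * K)
  for (ch in unique(reference$chrom)) {
    ri <- which(reference$chrom == ch)
    ti <- which(target$chrom == ch)
    if (!base::length(ti)) next
    o <- order(tpos[ti])
    tp <- tpos[ti][o]; tww <- tw[ti][o]
    Rbp <- K * b
    for (i in ri) {
      lo <- findInterval(rpos[i] - Rbp, tp) + 1L
      hi <- findInterval(rpos[i] + Rbp, tp)
      if (lo > hi) next
      d <- tp[lo:hi] - rpos[i]
      if (rstr[i] == "-") d <- -d
      k <- ceiling(d / b)
      k[d == 0] <- 1L
      idx <- k + K
      ok <- idx >= 1L & idx <= 2L * K
      if (any(ok)) {
        tt <- rowsum(rw[i] * tww[lo:hi][ok], idx[ok])
        ii <- as.integer(rownames(tt))
        raw[ii] <- raw[ii] + tt[, 1]
      }
    }
  }
  n_ref <- sum(rw)
  total_target <- sum(tw)
  G <- genome_size(genome)
  denom <- total_target / G
  value <- if (denom > 0) (raw / n_ref / b) / denom else rep(0, 2L * K)
  prof <- data.frame(bin_center = (seq_len(2L * K) - K - 0.5) * b,
                     raw = raw, value = value)
  structure(prof, n_reference = n_ref, total_target = total_target,
            genome_size = G, params = params,
            class = c("correlation_profile", "data.frame"))
}

#' Strand cross-correlation and footprint length
#'
#' Correlates `-`-strand tag positions around `+`-strand tag positions.
#' Because single-end reads start at the two fragment extremities, the mode
#' of this profile at positive distances estimates the protected-fragment
#' (footprint) length of the precipitated complex.
#'
#' @param tags a stranded [tag_collection()]; both strands must be present.
#' @param params a [correlation_params()]; default 10 bp bins over
#'   +/- 500 bp with the co-localised count cap at 10.
#' @param genome a [genome_table()].
#' @param repeat_mask optional intervals removed from the target strand.
#' @return A list: `profile` (the [correlate()] output) and
#'   `modal_distance` (bin center of the maximum over positive distances).
#' @export
strand_cross_correlation <- function(tags,
                                     params = correlation_params(bin = 10,
                                                                 range = 500),
                                     genome, repeat_mask = NULL) {
  plus <- tags[tags$strand == "+", , drop = FALSE]
  minus <- tags[tags$strand == "-", , drop = FALSE]
  if (!nrow(plus) || !nrow(minus))
    stop("both strands must carry tags for strand cross-correlation")
  params$oriented <- FALSE
  prof <- correlate(plus, minus, params, genome, repeat_mask = repeat_mask)
  pos_side <- prof[prof$bin_center > 0, , drop = FALSE]
  modal <- pos_side$bin_center[which.max(pos_side$value)]
  list(profile = prof, modal_distance = modal)
}

#' Motif enrichment around peak centers
#'
#' For each distance window of `window` bp, the fraction of peaks with at
#' least one predicted site in that window. The central frequency is the
#' fraction of peaks with a site within `window/2` of the center; the
#' enrichment factor divides it by the mean per-window frequency over the
#' flanks (|distance| between 3 kb and 10 kb). `encode_pass` applies the
#' ENCODE-style validation rule: at least four-fold central enrichment and
#' a site in at least 10% of the peak regions.
#'
#' @param peaks a `peak_list` (or data frame with `chrom` and `center`).
#' @param sites predicted sites (data frame with `chrom` and `center` or
#'   `pos`); distances are center-to-center.
#' @param window window width in bp.
#' @param range profile half-width in bp; must be >= `window` (>= 10 kb for
#'   the flank definition to apply).
#' @return A list: `profile` (`bin_center`, `frequency`),
#'   `central_frequency`, `enrichment_factor`, `encode_pass`.
#' @export
motif_enrichment_profile <- function(peaks, sites, window = 300,
                                     range = 10000) {
  if (range < window) stop("range must be >= window")
  if (!nrow(peaks) || !nrow(sites)) stop("peaks and sites must be nonempty")
  b <- window
  K <- ceiling(range / b)
  pc <- feature_positions(peaks)
  sp <- feature_positions(sites)
  hit <- matrix(FALSE, nrow(peaks), 2L * K)
  central <- logical(nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    pi_ <- which(peaks$chrom == ch)
    si <- sort(sp[sites$chrom == ch])
    if (!base::length(si)) next
    for (i in pi_) {
      lo <- findInterval(pc[i] - K * b, si) + 1L
      hi <- findInterval(pc[i] + K * b, si)
      if (lo > hi) next
      d <- si[lo:hi] - pc[i]
      central[i] <- any(abs(d) <= window / 2)
      k <- ceiling(d / b)
      k[d == 0] <- 1L
      idx <- unique(k + K)
      idx <- idx[idx >= 1L & idx <= 2L * K]
      hit[i, idx] <- TRUE
    }
  }
  freq <- colMeans(hit)
  centers <- (seq_len(2L * K) - K - 0.5) * b
  flank <- abs(centers) >= 3000 & abs(centers) <= 10000
  flank_mean <- mean(freq[flank])
  central_frequency <- mean(central)
  enrichment_factor <- if (flank_mean > 0) central_frequency / flank_mean else Inf
  list(profile = data.frame(bin_center = centers, frequency = freq),
       central_frequency = central_frequency,
       enrichment_factor = enrichment_factor,
       encode_pass = is.finite(enrichment_factor) &&
         enrichment_factor >= 4 && central_frequency >= 0.10)
}

#' Attribute tags to predicted sites
#'
#' Each `+`-strand tag is attributed to the closest predicted site at or
#' downstream of it (larger coordinate) if they are separated by less than
#' `max_dist`; `-`-strand tags go to the closest upstream site under the
#' same bound. A tag equidistant between two sites is only ever eligible
#' for the rule-consistent one, so no tag is counted twice; unattributed
#' tags are dropped.
#'
#' @param tags a [tag_collection()].
#' @param sites predicted sites (`chrom` plus `center` or `pos`).
#' @param max_dist maximum tag-to-site separation in bp (exclusive).
#' @return `sites` with an added `tag_count` column (summed tag
#'   multiplicities; 0 for sites that attracted no tag).
#' @export
attribute_tags_to_sites <- function(tags, sites, max_dist = 200) {
  out <- as.data.frame(sites)
  out$tag_count <- 0
  sp_all <- feature_positions(sites)
  for (ch in unique(sites$chrom)) {
    si <- which(sites$chrom == ch)
    o <- order(sp_all[si])
    sp <- sp_all[si][o]
    t <- tags[tags$chrom == ch, , drop = FALSE]
    if (!nrow(t)) next
    acc <- numeric(base::length(sp))
    plus <- t$strand == "+"
    if (any(plus)) {
      idx <- findInterval(t$pos[plus] - 0.5, sp) + 1L   # first site >= pos
      okp <- idx <= base::length(sp)
      okp[okp] <- (sp[idx[okp]] - t$pos[plus][okp]) < max_dist
      if (any(okp)) {
        tt <- rowsum(t$count[plus][okp], idx[okp])
        acc[as.integer(rownames(tt))] <- acc[as.integer(rownames(tt))] + tt[, 1]
      }
    }
    if (any(!plus)) {
      idx <- findInterval(t$pos[!plus], sp)             # last site <= pos
      okm <- idx >= 1L
      okm[okm] <- (t$pos[!plus][okm] - sp[idx[okm]]) < max_dist
      if (any(okm)) {
        tt <- rowsum(t$count[!plus][okm], idx[okm])
        acc[as.integer(rownames(tt))] <- acc[as.integer(rownames(tt))] + tt[, 1]
      }
    }
    out$tag_count[si[o]] <- out$tag_count[si[o]] + acc
  }
  out
}

#' Mean tag coverage by matrix-score class
#'
#' Groups sites into score classes of `bin_width` matrix units and reports
#' the class mean tag count (total attributed tags over number of sites in
#' the class, occupied or not). A weighted least-squares fit of
#' `log(mean)` on the class midpoint estimates the exponential
#' score-occupancy slope; under a log-linear affinity model the fitted
#' slope recovers the generating occupancy slope.
#'
#' @param sites sites with `score` and `tag_count` columns (see
#'   [attribute_tags_to_sites()]).
#' @param bin_width score-class width in matrix units.
#' @return A list: `table` (`score_mid`, `n_sites`, `total_tags`,
#'   `mean_count`), `slope` (per score unit), `r` (signed correlation of the
#'   weighted fit). Classes with no sites are omitted; classes with zero
#'   mean are excluded from the fit.
#' @export
coverage_by_score_class <- function(sites, bin_width = 1) {
  stop_if_missing_cols(sites, c("score", "tag_count"), "site table")
  mid <- (floor(sites$score / bin_width) + 0.5) * bin_width
  agg <- aggregate(cbind(n = rep(1, nrow(sites)), tags = sites$tag_count) ~ mid,
                   data = data.frame(mid = mid), FUN = sum)
  tab <- data.frame(score_mid = agg$mid, n_sites = agg$n,
                    total_tags = agg$tags,
                    mean_count = agg$tags / agg$n)
  fitable <- tab[tab$mean_count > 0, , drop = FALSE]
  if (nrow(fitable) >= 2) {
    fit <- lm(log(mean_count) ~ score_mid, data = fitable,
              weights = fitable$n_sites)
    slope <- unname(coef(fit)[2])
    r <- sign(slope) * sqrt(summary(fit)$r.squared)
  } else {
    slope <- NA_real_; r <- NA_real_
  }
  list(table = tab, slope = slope, r = r)
}

#' Oriented profile around transcription start sites
#'
#' Correlates tags (or predicted sites) around gene TSS with
#' orientation-aware distances, so positive distances always point into the
#' transcribed region. Normalisation is the global fold-change of
#' [correlate()].
#'
#' @param features tags or sites (data frame with `chrom`, `pos`/`center`,
#'   optional `count`).
#' @param genes a gene table ([read_genes()]); must be nonempty.
#' @param params a [correlation_params()]; `oriented` is forced on.
#' @param genome a [genome_table()].
#' @return A `correlation_profile` (see [correlate()]).
#' @export
tss_profile <- function(features, genes,
                        params = correlation_params(bin = 100, range = 10000),
                        genome) {
  if (is.null(genes) || nrow(genes) == 0L) stop("gene set is empty")
  ref <- data.frame(chrom = genes$chrom, pos = genes$tss,
                    strand = genes$strand, stringsAsFactors = FALSE)
  params$oriented <- TRUE
  correlate(ref, features, params, genome)
}
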