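# Sliding-window peak calling on deduplicated, 5'->3'-shifted tags.

#' Peak-calling parameters
#'
#' Defaults follow the published ChIP-Peak settings: a 600 bp counting
#' window, a 75 bp 5'->3' tag shift (so the two strand pile-ups of a
#' ~150 bp footprint coincide), a 600 bp vicinity range keeping any two
#' reported peaks at least that far apart, and a per-position count cut-off
#' of 1 (each unique genomic location contributes at most one tag).
#'
#' @param window counting window W in bp.
#' @param shift tag shift s in bp, applied in the tag's 5'->3' direction.
#' @param threshold minimum tag count T per window (typically 5-10).
#' @param vicinity minimum distance V in bp between reported peak centers.
#' @param count_cutoff cap on the per-(chrom, pos, strand) tag count;
#'   `Inf` disables capping.
#' @return A `peak_params` list.
#' @export
peak_params <- function(window = 600, shift = 75, threshold = 6,
                        vicinity = 600, count_cutoff = 1) {
  if (window < 0 || shift < 0 || vicinity < 0) stop("window, shift and vicinity must be >= 0")
  if (threshold < 1) stop("threshold must be >= 1")
  if (count_cutoff < 1) stop("count_cutoff must be >= 1")
  structure(list(window = window, shift = shift, threshold = threshold,
                 vicinity = vicinity, count_cutoff = count_cutoff),
            class = "peak_params")
}

#' Deduplicate and shift tags
#'
#' Collapses identical (chrom, pos, strand) records, caps each at
#' `count_cutoff`, then moves `+` tags to `pos + shift` and `-` tags to
#' `pos - shift` (clamped to the chromosome), pooling the two strand
#' pile-ups onto the footprint midpoint.
#'
#' @param tags a [tag_collection()].
#' @param params a [peak_params()].
#' @param genome a [genome_table()].
#' @return A [tag_collection()] of shifted tags.
#' @export
dedupe_and_shift <- function(tags, params, genome) {
  if (nrow(tags) == 0L) return(tags)
  tags <- dedupe_tags(tags)
  cnt <- if (is.finite(params$count_cutoff))
    pmin(tags$count, as.integer(params$count_cutoff)) else tags$count
  pos <- ifelse(tags$strand == "+", tags$pos + params$shift,
                tags$pos - params$shift)
  cl <- chrom_length(genome, tags$chrom)
  pos <- pmin(pmax(pos, 0), cl - 1)
  tag_collection(tags$chrom, pos, tags$strand, cnt, genome = genome)
}

#' Call peaks by sliding-window tag counting
#'
#' Counts tags (multiplicities summed over both strands) in every
#' window of `params$window` bp anchored at a tag position; windows
#' reaching `params$threshold` become candidates. Candidates are accepted
#' greedily in order of descending count (ties: leftmost window first), and
#' any later candidate whose center lies within `params$vicinity` of an
#' accepted center is suppressed, so reported centers are pairwise at least
#' the vicinity range apart. Anchoring windows at tag positions loses no
#' optima: any window can be slid left until its first tag sits at the
#' window start without changing its content.
#'
#' @param tags a [tag_collection()], already deduplicated and shifted (see
#'   [dedupe_and_shift()]).
#' @param params a [peak_params()].
#' @param genome a [genome_table()].
#' @param repeat_mask optional data frame of 0-based half-open intervals
#'   (`chrom`, `start`, `end`); called peaks whose center falls inside are
#'   dropped.
#' @param center `"midpoint"` reports the window midpoint (rounded down);
#'   `"weighted"` the tag-count-weighted mean position.
#' @return A `peak_list` data frame with columns `chrom`, `center`,
#'   `count`, `start`, `end` (the counting window), sorted by
#'   (chrom, center).
#' @export
call_peaks <- function(tags, params, genome, repeat_mask = NULL,
                       center = c("midpoint", "weighted")) {
  center <- match.arg(center)
  W <- params$window; Tthr <- params$threshold; V <- params$vicinity
  empty <- structure(
    data.frame(chrom = character(), center = numeric(), count = numeric(),
               start = numeric(), end = numeric(), stringsAsFactors = FALSE),
    params = params, class = c("peak_list", "data.frame"))
  if (nrow(tags) == 0L) return(empty)

  cand <- vector("list", nrow(genome))
  for (ci in seq_len(nrow(genome))) {
    t <- tags[tags$chrom == genome$chrom[ci], , drop = FALSE]
    if (!nrow(t)) next
    agg <- aggregate(count ~ pos, data = t, FUN = sum)    # pool strands
    p <- agg$pos; cnt <- agg$count
    cs <- cumsum(cnt)
    starts <- p
    hi <- findInterval(starts + W - 1, p)
    lo <- seq_along(p)                                    # window starts at tag lo
    wcount <- cs[hi] - c(0, cs)[lo]
    keep <- wcount >= Tthr
    if (!any(keep)) next
    ctr <- if (center == "midpoint") starts + W %/% 2 else {
      vapply(which(keep), function(i) {
        sel <- seq.int(lo[i], hi[i])
        floor(weighted.mean(p[sel], cnt[sel]))
      }, numeric(1))
    }
    cand[[ci]] <- data.frame(
      chrom = genome$chrom[ci],
      start = starts[keep],
      count = wcount[keep],
      center = if (center == "midpoint") ctr[keep] else ctr,
      stringsAsFactors = FALSE)
  }
  cand <- do.call(rbind, cand[!vapply(cand, is.null, logical(1))])
  if (is.null(cand) || !nrow(cand)) return(empty)

  o <- order(-cand$count, match(cand$chrom, genome$chrom), cand$start)
  cand <- cand[o, , drop = FALSE]
  accepted <- vector("list", nrow(cand))
  acc_pos <- split(numeric(0), character(0))
  n_acc <- 0L
  for (i in seq_len(nrow(cand))) {
    ch <- cand$chrom[i]
    prev <- acc_pos[[ch]]
    if (!is.null(prev) && any(abs(prev - cand$center[i]) < V)) next
    acc_pos[[ch]] <- c(prev, cand$center[i])
    n_acc <- n_acc + 1L
    accepted[[n_acc]] <- cand[i, , drop = FALSE]
  }
  peaks <- do.call(rbind, accepted[seq_len(n_acc)])
  if (!is.null(repeat_mask))
    peaks <- peaks[!point_in_intervals(peaks$chrom, peaks$center, repeat_mask), ,
                   drop = FALSE]
  if (!nrow(peaks)) return(empty)
  peaks <- data.frame(chrom = peaks$chrom, center = peaks$center,
                      count = peaks$count,
                      start = peaks$center - W %/% 2,
                      end = peaks$center - W %/% 2 + W,
                      stringsAsFactors = FALSE)
  peaks <- peaks[order_genomic(peaks$chrom, peaks$center, genome$chrom), ,
                 drop = FALSE]
  rownames(peaks) <- NULL
  structure(peaks, params = params, class = c("peak_list", "data.frame"))
}

#' Read-mapping summary
#'
#' Echoes the bookkeeping of a mapping run: the fraction of reads mapped to
#' unique genomic positions, as a percentage rounded to one decimal, plus
#' the number of distinct positions hit.
#'
#' @param total_reads total sequenced reads.
#' @param unique_mapped reads mapped to a unique position; must not exceed
#'   `total_reads`.
#' @param unique_positions distinct genomic positions hit by one or more
#'   reads (optional).
#' @return A list with `total_reads`, `unique_mapped`, `mapped_pct` (one
#'   decimal), `unique_positions`.
#' @examples
#' mapping_summary(14358325, 9771440, 3351008)$mapped_pct  # 68.1
#' @export
mapping_summary <- function(total_reads, unique_mapped,
                            unique_positions = NA) {
  if (unique_mapped > total_reads)
    stop("unique_mapped cannot exceed total_reads")
  list(total_reads = total_reads, unique_mapped = unique_mapped,
       mapped_pct = round(100 * unique_mapped / total_reads, 1),
       unique_positions = unique_positions)
}
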