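# Exact two-state (signal-rich / signal-poor) segmentation of a tag track.
#
# The labeling maximises
#     sum of capped tag counts inside rich segments
#   - density_threshold * (total rich length in bp)
#   - transition_penalty * (number of state switches)
# with chromosome ends fixed in the poor state, so every rich segment pays
# the switch penalty at both edges. An optimal rich segment always begins
# and ends at a tag position (trimming empty flanks only reduces the length
# cost), so the dynamic program below over sorted tag positions is exact.

#' Segmentation parameters
#'
#' Defaults follow the published ChIP-Part settings: a count-density
#' threshold of 0.004 tags per bp separating rich from poor, a transition
#' penalty of 20 score units per state switch controlling segment lengths,
#' and a per-position count cut-off of 5 re-setting higher tag counts to
#' the cut-off value.
#'
#' @param density_threshold rich-state length cost d, in tags per bp.
#' @param transition_penalty cost P per state switch, in score units.
#' @param count_cutoff cap c on the pooled per-position tag count.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(density_threshold = 0.004,
                                transition_penalty = 20, count_cutoff = 5) {
  if (density_threshold <= 0) stop("density_threshold must be > 0")
  if (transition_penalty < 0) stop("transition_penalty must be >= 0")
  if (count_cutoff < 1) stop("count_cutoff must be >= 1")
  structure(list(density_threshold = density_threshold,
                 transition_penalty = transition_penalty,
                 count_cutoff = count_cutoff),
            class = "segmentation_params")
}

#' Partition a chromosome into signal-rich and signal-poor segments
#'
#' Pools strands, caps the per-position tag count at
#' `params$count_cutoff`, and solves the penalised maximal-scoring-segments
#' problem exactly by dynamic programming over sorted tag positions. Ties
#' are broken toward fewer and shorter rich segments. An empty chromosome
#' yields a single poor segment.
#'
#' @param tags a [tag_collection()].
#' @param params a [segmentation_params()].
#' @param genome a [genome_table()].
#' @return A `segment_list` data frame (`chrom`, `start`, `end`, `state`,
#'   `score`) tiling each chromosome with alternating states; `score` is
#'   the objective contribution of each rich segment. The total objective
#'   is in attribute `objective`.
#' @export
partition <- function(tags, params = segmentation_params(), genome) {
  d <- params$density_threshold
  P <- params$transition_penalty
  segs <- vector("list", nrow(genome))
  total_obj <- 0
  for (ci in seq_len(nrow(genome))) {
    len <- genome$length[ci]
    t <- tags[tags$chrom == genome$chrom[ci], , drop = FALSE]
    rich <- NULL
    if (nrow(t)) {
      agg <- aggregate(count ~ pos, data = t, FUN = sum)
      p <- agg$pos
      cnt <- pmin(agg$count, params$count_cutoff)
      rich <- segment_dp(p, cnt, d, P)
      total_obj <- total_obj + attr(rich, "objective")
    }
    segs[[ci]] <- tile_chromosome(genome$chrom[ci], len, rich)
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  structure(out, objective = total_obj, params = params,
            class = c("segment_list", "data.frame"))
}

# DP over sorted tag positions; returns rich segments as a data.frame
# (start, end half-open, score) with the chromosome objective attached.
segment_dp <- function(p, cnt, d, P) {
  n <- base::length(p)
  C <- cumsum(cnt)
  best <- numeric(n)          # best objective using tags 1..i
  seg_end <- logical(n)       # best[i] achieved by a segment ending at i
  seg_start <- integer(n)
  M <- -Inf                   # running max of a_j = best[j-1] - C[j-1] + d*p[j]
  Mj <- 0L
  eps <- 1e-9
  for (i in seq_len(n)) {
    a_i <- (if (i > 1L) best[i - 1L] - C[i - 1L] else 0) + d * p[i]
    if (a_i >= M - eps) { M <- max(M, a_i); Mj <- i }  # ties -> later (shorter) start
    W <- C[i] - d * p[i] - d - 2 * P + M
    prev <- if (i > 1L) best[i - 1L] else 0
    if (W > prev + eps) {
      best[i] <- W; seg_end[i] <- TRUE; seg_start[i] <- Mj
    } else {
      best[i] <- prev                            # ties -> fewer segments
    }
  }
  starts <- integer(0); ends <- integer(0)
  i <- n
  while (i >= 1L) {
    if (seg_end[i]) {
      j <- seg_start[i]
      starts <- c(j, starts); ends <- c(i, ends)
      i <- j - 1L
    } else i <- i - 1L
  }
  score <- vapply(seq_along(starts), function(s) {
    j <- starts[s]; i2 <- ends[s]
    (C[i2] - (if (j > 1L) C[j - 1L] else 0)) - d * (p[i2] - p[j] + 1) - 2 * P
  }, numeric(1))
  structure(data.frame(start = p[starts], end = p[ends] + 1, score = score),
            objective = best[n])
}

tile_chromosome <- function(chrom, len, rich) {
  if (is.null(rich) || nrow(rich) == 0L)
    return(data.frame(chrom = chrom, start = 0, end = len, state = "poor",
                      score = 0, stringsAsFactors = FALSE))
  edges_s <- rich$start; edges_e <- rich$end
  rows <- list()
  cur <- 0
  for (s in seq_along(edges_s)) {
    if (edges_s[s] > cur)
      rows[[base::length(rows) + 1L]] <-
        data.frame(chrom = chrom, start = cur, end = edges_s[s],
                   state = "poor", score = 0, stringsAsFactors = FALSE)
    rows[[base::length(rows) + 1L]] <-
      data.frame(chrom = chrom, start = edges_s[s], end = edges_e[s],
                 state = "rich", score = rich$score[s],
                 stringsAsFactors = FALSE)
    cur <- edges_e[s]
  }
  if (cur < len)
    rows[[base::length(rows) + 1L]] <-
      data.frame(chrom = chrom, start = cur, end = len, state = "poor",
                 score = 0, stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Polarity-bearing boundaries of rich segments
#'
#' Emits two boundaries per rich segment — at its left edge with polarity
#' `rich-right` and at its right edge with polarity `rich-left` — excluding
#' edges that coincide with chromosome ends. The polarity names the side on
#' which the modification-enriched segment lies.
#'
#' @param segments a `segment_list` from [partition()] (or any tiling
#'   data frame with `chrom`, `start`, `end`, `state`).
#' @param mark optional track label (e.g. `"H3K36me3"`) carried into the
#'   output.
#' @return A `boundary_list` data frame (`chrom`, `pos`, `polarity`,
#'   `mark`) sorted by (chrom, pos). In BED-style output the polarity maps
#'   to strand: `+` = rich-right, `-` = rich-left.
#' @export
boundaries_from_segments <- function(segments, mark = NA_character_) {
  rows <- list()
  for (ch in unique(segments$chrom)) {
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    chrom_start <- min(seg$start)
    chrom_end <- max(seg$end)
    rich <- seg[seg$state == "rich", , drop = FALSE]
    if (!nrow(rich)) next
    for (s in seq_len(nrow(rich))) {
      if (rich$start[s] > chrom_start)
        rows[[base::length(rows) + 1L]] <-
          data.frame(chrom = ch, pos = rich$start[s], polarity = "rich-right",
                     mark = mark, stringsAsFactors = FALSE)
      if (rich$end[s] < chrom_end)
        rows[[base::length(rows) + 1L]] <-
          data.frame(chrom = ch, pos = rich$end[s], polarity = "rich-left",
                     mark = mark, stringsAsFactors = FALSE)
    }
  }
  out <- if (base::length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = numeric(), polarity = character(),
               mark = character(), stringsAsFactors = FALSE)
  out <- out[order_genomic(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("boundary_list", "data.frame"))
}
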