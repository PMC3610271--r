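# Boundary co-localisation statistics: site-to-boundary matching, double
# boundaries, TSS/TES classification, random genomic controls, binomial
# enrichment, and nearest-distance distributions.

boundary_signed_distance <- function(raw, polarity) {
  # signed distance with positive values toward the rich side
  ifelse(polarity == "rich-right", raw, -raw)
}

#' Match sites to chromatin boundaries
#'
#' Each boundary is matched to its nearest site within `radius` bp (closed
#' interval). The reported distance is signed toward the
#' modification-enriched side of the boundary, so positive distances mean
#' the site lies on the rich side; a site exactly at the boundary counts as
#' rich-side.
#'
#' @param boundaries a `boundary_list` ([boundaries_from_segments()]).
#' @param sites data frame with `chrom` and `pos` (or `center`).
#' @param radius match radius in bp.
#' @return `boundaries` with added columns `matched`, `site_pos`,
#'   `distance` (signed, positive toward rich) and `side`
#'   (`"rich"`/`"poor"`/`NA`). Summary counts are in attribute `summary`.
#' @export
match_sites_to_boundaries <- function(boundaries, sites, radius = 2500) {
  out <- as.data.frame(boundaries)
  out$matched <- FALSE
  out$site_pos <- NA_real_
  out$distance <- NA_real_
  out$side <- NA_character_
  sp_all <- feature_positions(sites)
  for (ch in unique(out$chrom)) {
    bi <- which(out$chrom == ch)
    sp <- sort(sp_all[sites$chrom == ch])
    if (!base::length(sp)) next
    nn <- nearest_in_sorted(out$pos[bi], sp)
    ok <- abs(nn$distance) <= radius
    out$matched[bi] <- ok
    out$site_pos[bi][ok] <- sp[nn$index[ok]]
    sgn <- boundary_signed_distance(nn$distance, out$polarity[bi])
    out$distance[bi][ok] <- sgn[ok]
    out$side[bi][ok] <- ifelse(sgn[ok] >= 0, "rich", "poor")
  }
  attr(out, "summary") <- list(
    n = nrow(out), k_matched = sum(out$matched),
    k_rich = sum(out$side == "rich", na.rm = TRUE),
    k_poor = sum(out$side == "poor", na.rm = TRUE))
  out
}

#' Co-localise two boundary sets
#'
#' Greedy one-to-one pairing: candidate pairs within `radius` bp (and, when
#' `require_opposite_polarity`, with opposite rich-side orientations) are
#' accepted in order of increasing distance, each boundary used at most
#' once. Opposite-polarity pairs of an active and a silent mark delimit
#' "double boundaries" separating expressed from silent chromatin.
#'
#' @param a,b `boundary_list` data frames.
#' @param radius pairing radius in bp (closed).
#' @param require_opposite_polarity only pair boundaries whose rich sides
#'   point away from each other?
#' @return A list: `pairs` (data frame with indices into `a` and `b`,
#'   positions and signed distance `b - a`) and `unmatched_a` (row indices
#'   of `a` without a partner).
#' @export
colocalize_boundaries <- function(a, b, radius = 2500,
                                  require_opposite_polarity = TRUE) {
  cand <- list()
  for (ch in unique(a$chrom)) {
    ai <- which(a$chrom == ch)
    bi <- which(b$chrom == ch)
    if (!base::length(bi)) next
    o <- order(b$pos[bi]); bi <- bi[o]
    bp <- b$pos[bi]
    for (i in ai) {
      lo <- findInterval(a$pos[i] - radius - 0.5, bp) + 1L
      hi <- findInterval(a$pos[i] + radius, bp)
      if (lo > hi) next
      j <- bi[lo:hi]
      if (require_opposite_polarity)
        j <- j[b$polarity[j] != a$polarity[i]]
      if (!base::length(j)) next
      cand[[base::length(cand) + 1L]] <- data.frame(
        a_idx = i, b_idx = j, dist = b$pos[j] - a$pos[i])
    }
  }
  pairs <- data.frame(a_idx = integer(), b_idx = integer(),
                      a_pos = numeric(), b_pos = numeric(),
                      distance = numeric())
  if (base::length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(abs(cand$dist), cand$a_idx), , drop = FALSE]
    used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
    keep <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      ia <- cand$a_idx[r]; ib <- cand$b_idx[r]
      if (!used_a[ia] && !used_b[ib]) {
        keep[r] <- TRUE; used_a[ia] <- TRUE; used_b[ib] <- TRUE
      }
    }
    cand <- cand[keep, , drop = FALSE]
    pairs <- data.frame(a_idx = cand$a_idx, b_idx = cand$b_idx,
                        a_pos = a$pos[cand$a_idx], b_pos = b$pos[cand$b_idx],
                        distance = cand$dist)
    pairs <- pairs[order(pairs$a_idx), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  list(pairs = pairs,
       unmatched_a = base::setdiff(seq_len(nrow(a)), pairs$a_idx))
}

#' Classify boundaries against gene starts and ends
#'
#' Each boundary is assigned to `"tss"` if a transcription start site lies
#' within `radius` bp, else to `"tes"` if a transcription end site does,
#' else to `"neither"`; the partition is exhaustive and disjoint, with TSS
#' taking precedence.
#'
#' @param boundaries a `boundary_list`.
#' @param genes a gene table.
#' @param radius co-localisation radius in bp (closed).
#' @return `boundaries` with an added `gene_class` column; class counts in
#'   attribute `summary`.
#' @export
classify_vs_genes <- function(boundaries, genes, radius = 2500) {
  out <- as.data.frame(boundaries)
  out$gene_class <- "neither"
  for (ch in unique(out$chrom)) {
    bi <- which(out$chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (!nrow(g)) next
    tss <- sort(g$tss); tes <- sort(g$tes)
    near_tss <- abs(nearest_in_sorted(out$pos[bi], tss)$distance) <= radius
    near_tes <- abs(nearest_in_sorted(out$pos[bi], tes)$distance) <= radius
    out$gene_class[bi][near_tes] <- "tes"
    out$gene_class[bi][near_tss] <- "tss"       # TSS precedence
  }
  attr(out, "summary") <- table(factor(out$gene_class,
                                       levels = c("tss", "tes", "neither")))
  out
}

#' Random genomic control sites
#'
#' Draws, from each chromosome, the same number of uniform random positions
#' as the template has sites on that chromosome. Deterministic given
#' `seed`.
#'
#' @param template_sites data frame with a `chrom` column (and any site
#'   columns; only the per-chromosome counts are used).
#' @param genome a [genome_table()].
#' @param seed RNG seed.
#' @return A data frame (`chrom`, `pos`) with per-chromosome counts equal
#'   to the template's.
#' @export
sample_random_sites <- function(template_sites, genome, seed) {
  set.seed(seed)
  counts <- table(factor(template_sites$chrom, levels = genome$chrom))
  rows <- lapply(seq_len(nrow(genome)), function(ci) {
    n <- as.integer(counts[genome$chrom[ci]])
    if (n == 0L) return(NULL)
    data.frame(chrom = genome$chrom[ci],
               pos = floor(runif(n) * genome$length[ci]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(chrom = character(), pos = numeric(),
                      stringsAsFactors = FALSE)
  out <- out[order_genomic(out$chrom, out$pos, genome$chrom), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-sided binomial enrichment against a random control
#'
#' Tests whether `k_obs` matches among `n` boundaries exceed what the
#' random-control match count `k_rand` implies: the null match probability
#' is `p0 = k_rand / n` and the p-value is `P(Binomial(n, p0) >= k_obs)`.
#' When the control yields no matches, `p0` falls back to the continuity
#' floor `0.5 / n` and the result is flagged. Percentage fields are
#' truncated (not rounded) to two decimals, the convention under which the
#' published per-row percentages reproduce from their counts.
#'
#' @param n number of boundaries tested (same for observed and control).
#' @param k_obs observed match count.
#' @param k_rand control match count.
#' @return An `enrichment_result` list: `n`, `k_obs`, `k_rand`, `p0`,
#'   `prop_obs`, `prop_rand`, `pct_obs`, `pct_rand` (two-decimal,
#'   truncated), `p_value`, `floored`.
#' @examples
#' enrichment_test(4687, 148, 45)$pct_obs  # 3.15
#' @export
enrichment_test <- function(n, k_obs, k_rand) {
  if (k_obs < 0 || k_rand < 0 || k_obs > n || k_rand > n)
    stop("need 0 <= k_obs, k_rand <= n")
  floored <- k_rand == 0
  p0 <- if (floored) 0.5 / n else k_rand / n
  p_value <- pbinom(k_obs - 1, n, p0, lower.tail = FALSE)
  trunc2 <- function(x) trunc(x * 100 + 1e-9) / 100
  structure(list(n = n, k_obs = k_obs, k_rand = k_rand, p0 = p0,
                 prop_obs = k_obs / n, prop_rand = k_rand / n,
                 pct_obs = trunc2(100 * k_obs / n),
                 pct_rand = trunc2(100 * k_rand / n),
                 p_value = p_value, floored = floored),
            class = "enrichment_result")
}

#' Percentage of boundaries with a nearby site
#'
#' `round(100 * k / n, 1)` — the one-decimal rounding convention of the
#' in-text boundary-match fractions.
#'
#' @param k numerator, `n` denominator.
#' @param n denominator.
#' @export
proportion_pct <- function(k, n) round(100 * k / n, 1)

#' Smallest boundary-to-site distances on one side
#'
#' For every boundary, the distance to the nearest site strictly on the
#' requested side (`"rich"` includes a site exactly at the boundary);
#' boundaries with no site on that side are skipped. The `k` smallest
#' distances are returned sorted — the shape of this distribution,
#' compared between sides or against random controls, shows which side of
#' the boundary the sites crowd.
#'
#' @param boundaries a `boundary_list`.
#' @param sites data frame with `chrom` and `pos`/`center`.
#' @param side `"rich"` or `"poor"`.
#' @param k number of smallest distances to return; if fewer are available
#'   all are returned with a warning.
#' @return Sorted numeric vector of at most `k` distances (bp).
#' @export
nearest_distance_distribution <- function(boundaries, sites,
                                          side = c("rich", "poor"),
                                          k = 2000) {
  side <- match.arg(side)
  sp_all <- feature_positions(sites)
  dists <- numeric(0)
  for (ch in unique(boundaries$chrom)) {
    bi <- which(boundaries$chrom == ch)
    sp <- sort(sp_all[sites$chrom == ch])
    if (!base::length(sp)) next
    for (i in bi) {
      pos <- boundaries$pos[i]
      rich_right <- boundaries$polarity[i] == "rich-right"
      if ((side == "rich") == rich_right) {
        # sites at or to the right of the boundary
        idx <- findInterval(pos - 0.5, sp) + 1L
        if (side == "poor") {                     # strictly right, excl. pos
          idx <- findInterval(pos, sp) + 1L
        }
        if (idx <= base::length(sp)) dists <- c(dists, sp[idx] - pos)
      } else {
        idx <- findInterval(pos, sp)              # at or left of pos
        if (side == "poor") idx <- findInterval(pos - 0.5, sp)  # strictly left
        if (idx >= 1L) dists <- c(dists, pos - sp[idx])
      }
    }
  }
  dists <- sort(dists)
  if (k > base::length(dists)) {
    warning(sprintf("only %d distances available (k = %d)",
                    base::length(dists), k))
    k <- base::length(dists)
  }
  dists[seq_len(k)]
}

#' Site profile around nuclear-lamina domain edges
#'
#' Treats the edges of lamina-associated domains (LADs) as oriented
#' boundaries pointing from the lamina toward the nuclear interior and
#' correlates sites around them, so positive distances are lamina-free
#' (interior) and negative distances lamina-attached. The side occupancy
#' summarises the mean normalised site frequency on each side.
#'
#' @param lad_intervals data frame of LAD intervals (`chrom`, `start`,
#'   `end`, 0-based half-open); must be nonempty.
#' @param sites data frame with `chrom` and `pos`/`center`.
#' @param params a [correlation_params()]; default 2 kb bins over
#'   +/- 100 kb.
#' @param genome a [genome_table()].
#' @return A list: `profile` (oriented [correlate()] output) and
#'   `side_occupancy` (named means over the lamina-poor and lamina-rich
#'   sides).
#' @export
lamina_alignment <- function(lad_intervals, sites,
                             params = correlation_params(bin = 2000,
                                                         range = 1e5),
                             genome) {
  if (is.null(lad_intervals) || nrow(lad_intervals) == 0L)
    stop("LAD interval list is empty")
  ref <- rbind(
    data.frame(chrom = lad_intervals$chrom, pos = lad_intervals$start,
               strand = "-", stringsAsFactors = FALSE),   # interior to the left
    data.frame(chrom = lad_intervals$chrom, pos = lad_intervals$end,
               strand = "+", stringsAsFactors = FALSE))   # interior to the right
  params$oriented <- TRUE
  prof <- correlate(ref, sites, params, genome)
  list(profile = prof,
       side_occupancy = c(
         lamina_poor = mean(prof$value[prof$bin_center > 0]),
         lamina_rich = mean(prof$value[prof$bin_center < 0])))
}
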