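# Ground-truth simulators. Every generator is deterministic given its seed;
# seeds for the individual generators are derived from params$seed with
# fixed offsets so the stages can be re-run independently.

#' Simulation parameters
#'
#' Holds every knob of the synthetic-data generators, with defaults chosen
#' to emulate a shallow transcription-factor ChIP-seq experiment on
#' nucleosome-sized fragments plus histone-modification tracks with planted
#' domain structure.
#'
#' @param genome_length total genome length in bp, split evenly over
#'   `n_chroms` chromosomes.
#' @param n_chroms number of chromosomes.
#' @param seed master seed; each generator derives its own seed from it.
#' @param n_planted_sites motif instances planted by [make_genome()].
#' @param score_range target `(low, high)` of planted-site scores in matrix
#'   units; `NULL` defaults to the upper half of the attainable range of the
#'   matrix in use.
#' @param occupancy_slope per-score-unit exponential slope linking matrix
#'   score to expected tag yield.
#' @param base_rate expected fragments per occupied site at the low end of
#'   `score_range`.
#' @param background_rate background tags per bp.
#' @param frag_mean,frag_sd,frag_min fragment-length model in bp: normal,
#'   truncated below at `frag_min`. The default 180/40/100 reflects
#'   mono-nucleosome-sized ChIP fragments; `frag_mean = 260` matches a
#'   typical sequencing-insert preset.
#' @param dup_prob PCR duplication probability: each tag carries
#'   `1 + Geometric(1 - dup_prob)` copies.
#' @param rich_rate,poor_rate histone-track tag rates (tags per bp) in
#'   modification-rich and modification-poor segments; `rich_rate >
#'   poor_rate >= 0`.
#' @param segment_length_mean mean planted segment length in bp.
#' @param segment_length_min minimum planted segment length in bp; random
#'   layouts draw lengths as `min + Exponential(mean - min)`, reflecting
#'   the tens-of-kb minimum scale of histone-modification domains.
#' @return A `sim_params` list.
#' @export
sim_params <- function(genome_length = 1e6, n_chroms = 2, seed = 1L,
                       n_planted_sites = 500, score_range = NULL,
                       occupancy_slope = 0.3, base_rate = 5,
                       background_rate = 8e-4,
                       frag_mean = 180, frag_sd = 40, frag_min = 100,
                       dup_prob = 0.3,
                       rich_rate = 0.02, poor_rate = 0.001,
                       segment_length_mean = 5e4,
                       segment_length_min = 2e4) {
  if (segment_length_min >= segment_length_mean)
    stop("segment_length_min must be below segment_length_mean")
  p <- list(genome_length = genome_length, n_chroms = n_chroms,
            seed = as.integer(seed), n_planted_sites = n_planted_sites,
            score_range = score_range, occupancy_slope = occupancy_slope,
            base_rate = base_rate, background_rate = background_rate,
            frag_mean = frag_mean, frag_sd = frag_sd, frag_min = frag_min,
            dup_prob = dup_prob, rich_rate = rich_rate, poor_rate = poor_rate,
            segment_length_mean = segment_length_mean,
            segment_length_min = segment_length_min)
  if (p$frag_min <= 0) stop("frag_min must be > 0")
  if (p$dup_prob < 0 || p$dup_prob >= 1) stop("dup_prob must be in [0, 1)")
  if (!(p$rich_rate > p$poor_rate) || p$poor_rate < 0) {
    if (p$rich_rate != p$poor_rate || p$poor_rate < 0)
      stop("need rich_rate > poor_rate >= 0 (or equal rates for a flat track)")
  }
  structure(p, class = "sim_params")
}

sim_genome_table <- function(params) {
  len <- floor(params$genome_length / params$n_chroms)
  genome_table(paste0("chr", seq_len(params$n_chroms)),
               rep(len, params$n_chroms))
}

#' Synthetic genome with planted motif sites
#'
#' Generates i.i.d. uniform-base chromosomes and plants `n_planted_sites`
#' non-overlapping motif instances drawn from the weight matrix's implied
#' per-column base distribution. Site strengths are spread over
#' `score_range` by sampling each instance from the tempered distribution
#' `p^beta` (beta chosen so the expected score matches a uniform draw from
#' the range), re-drawing until the realised score is at least the low end.
#' Deterministic given `params$seed`.
#'
#' @param params a [sim_params()].
#' @param matrix probability-carrying [weight_matrix()]; default
#'   [nfi_matrix()].
#' @return A list: `seqs` (`DNAStringSet`), `genome` ([genome_table()]),
#'   `sites` (ground truth: `chrom`, `pos`, `center`, `strand`, `score`),
#'   `matrix`, and the resolved `score_range`.
#' @export
make_genome <- function(params, matrix = nfi_matrix()) {
  set.seed(params$seed)
  probs <- attr(matrix, "probs")
  if (is.null(probs)) {
    probs <- apply(unclass(matrix), 2, function(col) {
      w <- exp(col - max(col)); w / sum(w)
    })
  }
  L <- ncol(matrix)
  genome <- sim_genome_table(params)
  seqs <- lapply(genome$length, function(n)
    sample(BASES, n, replace = TRUE))

  n_sites <- params$n_planted_sites
  rng <- params$score_range
  if (is.null(rng)) {
    b <- score_bounds(matrix)
    rng <- c(0.5 * b[2], b[2])
  }
  sites <- NULL
  if (n_sites > 0) {
    total_len <- sum(genome$length)
    if (n_sites * L * 3 > total_len)
      stop("planted sites do not fit in the genome without overlap")
    site_chrom <- sample(seq_len(nrow(genome)), n_sites, replace = TRUE,
                         prob = genome$length)
    # non-overlapping window starts per chromosome
    pos <- integer(n_sites)
    for (ci in seq_len(nrow(genome))) {
      idx <- which(site_chrom == ci)
      if (!base::length(idx)) next
      taken <- numeric(0)
      for (i in idx) {
        ok <- FALSE
        for (try in 1:1000) {
          cand <- floor(runif(1, 0, genome$length[ci] - L))
          if (!base::length(taken) || all(abs(taken - cand) >= L)) {
            ok <- TRUE; break
          }
        }
        if (!ok) stop("could not place planted sites without overlap")
        taken <- c(taken, cand)
        pos[i] <- cand
      }
    }
    # tempered sampling: map a uniform target score to a temperature beta
    beta_grid <- seq(0.2, 8, by = 0.05)
    mean_score <- vapply(beta_grid, function(b) {
      sum(vapply(seq_len(L), function(j) {
        w <- probs[, j]^b; w <- w / sum(w)
        sum(w * unclass(matrix)[, j])
      }, numeric(1)))
    }, numeric(1))
    target <- runif(n_sites, rng[1], rng[2])
    beta <- beta_grid[vapply(target, function(t)
      which.min(abs(mean_score - t)), integer(1))]
    strand <- sample(c("+", "-"), n_sites, replace = TRUE)
    score <- numeric(n_sites)
    site_seq <- character(n_sites)
    for (i in seq_len(n_sites)) {
      for (try in 1:100) {
        s <- vapply(seq_len(L), function(j) {
          w <- probs[, j]^beta[i]
          sample(BASES, 1, prob = w / sum(w))
        }, character(1))
        sc <- score_window(matrix, paste(s, collapse = ""))
        if (sc >= rng[1]) break
      }
      if (sc < rng[1]) {            # fall back to the consensus
        s <- strsplit(matrix_consensus(matrix), "")[[1]]
        sc <- score_window(matrix, paste(s, collapse = ""))
      }
      site_seq[i] <- paste(s, collapse = "")
      score[i] <- sc
      planted <- if (strand[i] == "+") s else strsplit(revcomp(site_seq[i]), "")[[1]]
      seqs[[site_chrom[i]]][(pos[i] + 1):(pos[i] + L)] <- planted
    }
    sites <- data.frame(chrom = genome$chrom[site_chrom], pos = pos,
                        center = pos + L %/% 2, strand = strand,
                        score = score, stringsAsFactors = FALSE)
    sites <- sites[order_genomic(sites$chrom, sites$pos, genome$chrom), ,
                   drop = FALSE]
    rownames(sites) <- NULL
    attr(sites, "score_range") <- rng
  } else {
    sites <- data.frame(chrom = character(), pos = integer(),
                        center = integer(), strand = character(),
                        score = numeric(), stringsAsFactors = FALSE)
  }
  dss <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1), collapse = ""))
  names(dss) <- genome$chrom
  list(seqs = dss, genome = genome, sites = sites, matrix = matrix,
       score_range = rng)
}

#' Simulate ChIP-seq tags over planted sites
#'
#' For each planted site with score s the expected fragment count is
#' `base_rate * exp(occupancy_slope * (s - score_low))`; the realised count
#' is Poisson. Each fragment spans the site center, has truncated-normal
#' length, and yields a `+` tag at its start and a `-` tag at its last
#' base. PCR duplication adds geometric extra copies per tag; uniform
#' background tags are added at `background_rate` per bp. Deterministic
#' given `seed`.
#'
#' @param truth `sites` ground truth from [make_genome()] (needs `chrom`,
#'   `center`, `score`).
#' @param params a [sim_params()].
#' @param genome a [genome_table()].
#' @param score_low low end of the score range used for the exponential
#'   occupancy model; defaults to the range resolved by [make_genome()]
#'   (carried on `truth`), falling back to `params$score_range[1]`.
#' @param seed RNG seed (default `params$seed + 1`).
#' @return A [tag_collection()].
#' @export
make_chip_tags <- function(truth, params, genome,
                           score_low = NULL,
                           seed = params$seed + 1L) {
  set.seed(seed)
  if (is.null(score_low))
    score_low <- (attr(truth, "score_range") %||% params$score_range)[1]
  if (nrow(truth) > 0 && is.null(score_low))
    stop("score_low must be supplied when params$score_range is NULL")
  chrom <- character(0); pos <- numeric(0); strand <- character(0)
  if (nrow(truth) > 0) {
    mu <- params$base_rate *
      exp(params$occupancy_slope * (truth$score - score_low))
    nfrag <- rpois(nrow(truth), mu)
    site_idx <- rep(seq_len(nrow(truth)), nfrag)
    if (base::length(site_idx)) {
      len <- pmax(params$frag_min,
                  round(rnorm(base::length(site_idx), params$frag_mean,
                              params$frag_sd)))
      centers <- truth$center[site_idx]
      f <- centers - floor(runif(base::length(site_idx)) * len)
      chrom <- rep(truth$chrom[site_idx], each = 1)
      chrom <- c(chrom, chrom)
      pos <- c(f, f + len - 1)
      strand <- c(rep("+", base::length(f)), rep("-", base::length(f)))
    }
  }
  n_bg <- rpois(1, params$background_rate * genome_size(genome))
  if (n_bg > 0) {
    bg_chrom_idx <- sample(seq_len(nrow(genome)), n_bg, replace = TRUE,
                           prob = genome$length)
    chrom <- c(chrom, genome$chrom[bg_chrom_idx])
    pos <- c(pos, floor(runif(n_bg) * genome$length[bg_chrom_idx]))
    strand <- c(strand, sample(c("+", "-"), n_bg, replace = TRUE))
  }
  if (!base::length(pos)) return(tag_collection(genome = genome))
  cl <- chrom_length(genome, chrom)
  pos <- pmin(pmax(pos, 0), cl - 1)
  count <- 1L + rgeom(base::length(pos), 1 - params$dup_prob)
  tag_collection(chrom, pos, strand, count, genome = genome)
}

#' Simulate a histone-modification track with planted domains
#'
#' Tags are drawn as a piecewise-constant Poisson process: `rich_rate` per
#' bp inside modification-rich segments, `poor_rate` in poor segments;
#' strands are assigned uniformly (histone tags carry no footprint
#' orientation). Segment layout is either `"random"` (alternating states,
#' exponential lengths with mean `segment_length_mean`, chromosomes start
#' and end poor) or an explicit list of boundary positions per chromosome.
#'
#' @param params a [sim_params()].
#' @param genome a [genome_table()].
#' @param boundary_spec `"random"`, or a named list (per chromosome) of
#'   increasing boundary positions.
#' @param start_state state of the first segment (`"poor"` or `"rich"`)
#'   when `boundary_spec` is explicit.
#' @param mark track label carried into the truth boundaries (e.g.
#'   `"H3K27me3"`).
#' @param seed RNG seed (default `params$seed + 2`).
#' @return A list: `tags` ([tag_collection()]), `segments` (`chrom`,
#'   `start`, `end`, `state`), `boundaries` (`chrom`, `pos`, `polarity`,
#'   `mark`) — the planted ground truth.
#' @export
make_histone_track <- function(params, genome, boundary_spec = "random",
                               start_state = "poor", mark = NA_character_,
                               seed = params$seed + 2L) {
  set.seed(seed)
  flat <- params$rich_rate == params$poor_rate
  seg_list <- vector("list", nrow(genome))
  for (ci in seq_len(nrow(genome))) {
    len <- genome$length[ci]
    if (flat) {
      bnd <- numeric(0); st <- "rich"
    } else if (identical(boundary_spec, "random")) {
      nmax <- ceiling(4 * len / params$segment_length_mean) + 8
      seg_len <- params$segment_length_min +
        ceiling(rexp(nmax, 1 / (params$segment_length_mean -
                                  params$segment_length_min)))
      cuts <- cumsum(seg_len)
      bnd <- cuts[cuts < len]
      st <- "poor"
    } else {
      bnd <- sort(boundary_spec[[genome$chrom[ci]]] %||% numeric(0))
      st <- start_state
    }
    edges <- c(0, bnd, len)
    states <- rep(c(st, base::setdiff(c("poor", "rich"), st)),
                  length.out = base::length(edges) - 1)
    seg_list[[ci]] <- data.frame(chrom = genome$chrom[ci],
                                 start = edges[-base::length(edges)],
                                 end = edges[-1], state = states,
                                 stringsAsFactors = FALSE)
  }
  segments <- do.call(rbind, seg_list)
  rownames(segments) <- NULL

  rate <- ifelse(segments$state == "rich", params$rich_rate, params$poor_rate)
  n_tags <- rpois(nrow(segments), rate * (segments$end - segments$start))
  seg_idx <- rep(seq_len(nrow(segments)), n_tags)
  tags <- if (base::length(seg_idx)) {
    pos <- floor(segments$start[seg_idx] +
                   runif(base::length(seg_idx)) *
                   (segments$end[seg_idx] - segments$start[seg_idx]))
    tag_collection(segments$chrom[seg_idx], pos,
                   sample(c("+", "-"), base::length(seg_idx), replace = TRUE),
                   genome = genome)
  } else tag_collection(genome = genome)

  boundaries <- boundaries_from_segments(segments, mark = mark)
  list(tags = tags, segments = segments, boundaries = boundaries)
}

#' Synthetic double-boundary locus
#'
#' Builds a single-chromosome locus in which a central domain is rich in an
#' active-transcription mark (H3K36me3-like) and depleted of a silent mark
#' (H3K27me3-like), with the flanks reversed — so the two tracks carry
#' boundaries of opposite polarity at the same two positions — and plants a
#' binding site at each domain edge. This emulates the layout of an
#' imprinted locus bracketed by bound sites.
#'
#' @param params a [sim_params()].
#' @param locus_length chromosome length in bp.
#' @param domain `c(start, end)` of the central active domain.
#' @param seed RNG seed (default `params$seed + 3`).
#' @return A list: `genome`, `k36` and `k27` (each as returned by
#'   [make_histone_track()]), `sites` (planted binding positions), and
#'   `domain`.
#' @export
make_double_boundary_locus <- function(params, locus_length = 3e5,
                                       domain = c(1.2e5, 1.8e5),
                                       seed = params$seed + 3L) {
  genome <- genome_table("chrLocus", locus_length)
  spec <- list(chrLocus = domain)
  k36 <- make_histone_track(params, genome, boundary_spec = spec,
                            start_state = "poor", mark = "H3K36me3",
                            seed = seed)
  k27 <- make_histone_track(params, genome, boundary_spec = spec,
                            start_state = "rich", mark = "H3K27me3",
                            seed = seed + 1L)
  sites <- data.frame(chrom = "chrLocus", pos = domain,
                      stringsAsFactors = FALSE)
  list(genome = genome, k36 = k36, k27 = k27, sites = sites, domain = domain)
}

#' Synthetic gene annotation and two-condition expression
#'
#' Genes are tiled at random TSS positions with exponential lengths.
#' Wild-type expression is Uniform(2, 13) on the array log scale; a
#' regulation class is drawn per gene and the knock-out value is
#' `wt - delta` with `delta` in (0.5, 2) for up-regulated, (-2, -0.5) for
#' down-regulated and (-0.05, 0.05) for non-regulated genes, matching the
#' class definitions of [classify_regulation()].
#'
#' @param params a [sim_params()].
#' @param genome a [genome_table()].
#' @param n_genes number of genes.
#' @param class_probs sampling probabilities of the `up`, `down`, `non`
#'   classes (proportions mirroring a typical knock-out profiling
#'   comparison).
#' @param seed RNG seed (default `params$seed + 4`).
#' @return A list: `genes` (gene table), `wt` and `ko`
#'   ([expression_table()]s), `truth` (`id`, `class`).
#' @export
make_genes_expression <- function(params, genome, n_genes = 2000,
                                  class_probs = c(up = 0.13, down = 0.09,
                                                  non = 0.78),
                                  seed = params$seed + 4L) {
  set.seed(seed)
  ci <- sample(seq_len(nrow(genome)), n_genes, replace = TRUE,
               prob = genome$length)
  len <- pmax(2000, round(rexp(n_genes, 1 / 2e4)))
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  cl <- genome$length[ci]
  tss <- floor(runif(n_genes) * pmax(1, cl - 1))
  tes <- ifelse(strand == "+", pmin(tss + len, cl - 1), pmax(tss - len, 0))
  # degenerate placements (gene pinned at a chromosome edge) are re-drawn
  bad <- which(tss == tes)
  for (i in bad) {
    tss[i] <- floor(cl[i] / 3)
    tes[i] <- if (strand[i] == "+") tss[i] + len[i] else tss[i] - len[i]
    tes[i] <- min(max(tes[i], 0), cl[i] - 1)
  }
  ids <- sprintf("gene%05d", seq_len(n_genes))
  genes <- validate_genes(data.frame(
    id = ids, chrom = genome$chrom[ci], tss = tss, tes = tes,
    strand = strand, stringsAsFactors = FALSE))

  class <- sample(names(class_probs), n_genes, replace = TRUE,
                  prob = class_probs)
  wt <- runif(n_genes, 2, 13)
  delta <- numeric(n_genes)
  delta[class == "up"] <- runif(sum(class == "up"), 0.5, 2)
  delta[class == "down"] <- runif(sum(class == "down"), -2, -0.5)
  delta[class == "non"] <- runif(sum(class == "non"), -0.05, 0.05)
  ko <- wt - delta
  list(genes = genes,
       wt = expression_table(ids, wt),
       ko = expression_table(ids, ko),
       truth = data.frame(id = ids, class = class, stringsAsFactors = FALSE))
}
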