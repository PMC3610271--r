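# Integration of binding with gene annotation and two-condition expression.

# GRanges helpers: internal coordinates are 0-based half-open, GRanges is
# 1-based closed.
gr_from_intervals <- function(chrom, start, end) {
  keep <- end > start
  GenomicRanges::GRanges(chrom[keep],
                         IRanges::IRanges(start = start[keep] + 1,
                                          end = end[keep]))
}

gr_from_points <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos + 1, width = 1))
}

parse_pos_list <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(x)) return(numeric(0))
  as.numeric(strsplit(as.character(x), ",")[[1]])
}

gene_body_bounds <- function(genes) {
  data.frame(chrom = genes$chrom,
             start = pmin(genes$tss, genes$tes),
             end = pmax(genes$tss, genes$tes) + 1)
}

#' Assign features to genomic compartments
#'
#' Partitions feature positions (peak or site centers) over the
#' compartments 5'UTR, 3'UTR, coding exon, intron, 5 kb upstream, 5 kb
#' downstream and intergenic, with that precedence, so every feature is
#' counted exactly once. UTR and exon compartments require the
#' corresponding optional gene-table columns (see [read_genes()]); genes
#' without exon structure contribute their whole body as intron. Densities
#' divide counts by the disjoint compartment span (higher-precedence
#' compartments subtracted).
#'
#' @param features data frame with `chrom` and `pos`/`center`.
#' @param genes a gene table.
#' @param genome a [genome_table()].
#' @param flank upstream/downstream flank size in bp.
#' @return A `compartment_stats` data frame (`compartment`, `count`,
#'   `span_mb`, `density_per_mb`); counts sum to `nrow(features)`.
#' @export
annotate_compartments <- function(features, genes, genome, flank = 5000) {
  fpos <- feature_positions(features)
  pts <- gr_from_points(features$chrom, fpos)

  body <- gene_body_bounds(genes)
  cl <- chrom_length(genome, genes$chrom)
  up_start <- ifelse(genes$strand == "+", genes$tss - flank, genes$tss + 1)
  up_end <- ifelse(genes$strand == "+", genes$tss, genes$tss + 1 + flank)
  dn_start <- ifelse(genes$strand == "+", genes$tes + 1, genes$tes - flank)
  dn_end <- ifelse(genes$strand == "+", genes$tes + 1 + flank, genes$tes)
  clamp <- function(x) pmin(pmax(x, 0), cl)

  utr5 <- utr3 <- exon <- NULL
  has_exons <- all(c("exon_starts", "exon_ends") %in% names(genes))
  if (has_exons) {
    ex <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
      s <- parse_pos_list(genes$exon_starts[i])
      e <- parse_pos_list(genes$exon_ends[i])
      if (!base::length(s)) return(NULL)
      data.frame(chrom = genes$chrom[i], start = s, end = e)
    }))
    if (!is.null(ex)) exon <- gr_from_intervals(ex$chrom, ex$start, ex$end)
  }
  if (all(c("utr5_start", "utr5_end") %in% names(genes))) {
    ok <- !is.na(genes$utr5_start)
    utr5 <- gr_from_intervals(genes$chrom[ok], genes$utr5_start[ok],
                              genes$utr5_end[ok])
  }
  if (all(c("utr3_start", "utr3_end") %in% names(genes))) {
    ok <- !is.na(genes$utr3_start)
    utr3 <- gr_from_intervals(genes$chrom[ok], genes$utr3_start[ok],
                              genes$utr3_end[ok])
  }
  body_gr <- gr_from_intervals(body$chrom, body$start, body$end)
  utr_gr <- NULL
  if (!is.null(utr5) || !is.null(utr3)) {
    utr_gr <- if (is.null(utr5)) utr3 else if (is.null(utr3)) utr5 else
      GenomicRanges::union(utr5, utr3)
  }
  coding <- if (!is.null(exon)) {
    if (is.null(utr_gr)) GenomicRanges::reduce(exon) else
      GenomicRanges::setdiff(GenomicRanges::reduce(exon), utr_gr)
  } else NULL
  intron <- if (!is.null(exon)) {
    GenomicRanges::setdiff(GenomicRanges::reduce(body_gr),
                           GenomicRanges::reduce(exon))
  } else GenomicRanges::reduce(body_gr)
  if (!is.null(utr_gr)) intron <- GenomicRanges::setdiff(intron, utr_gr)

  comps <- list(
    utr5 = utr5, utr3 = utr3, coding_exon = coding, intron = intron,
    upstream5kb = gr_from_intervals(genes$chrom, clamp(up_start), clamp(up_end)),
    downstream5kb = gr_from_intervals(genes$chrom, clamp(dn_start), clamp(dn_end)))

  n <- base::length(pts)
  remaining <- rep(TRUE, n)
  counts <- numeric(0); spans <- numeric(0); labels <- character(0)
  covered <- NULL
  for (nm in names(comps)) {
    gr <- comps[[nm]]
    if (is.null(gr)) next
    gr <- GenomicRanges::reduce(gr)
    eff <- if (is.null(covered)) gr else GenomicRanges::setdiff(gr, covered)
    hit <- remaining & IRanges::overlapsAny(pts, gr)
    remaining <- remaining & !hit
    labels <- c(labels, nm)
    counts <- c(counts, sum(hit))
    spans <- c(spans, sum(as.numeric(GenomicRanges::width(eff))))
    covered <- if (is.null(covered)) gr else GenomicRanges::union(covered, gr)
  }
  labels <- c(labels, "intergenic")
  counts <- c(counts, sum(remaining))
  covered_bp <- if (is.null(covered)) 0 else
    sum(as.numeric(GenomicRanges::width(covered)))
  spans <- c(spans, genome_size(genome) - covered_bp)

  structure(data.frame(compartment = labels, count = counts,
                       span_mb = spans / 1e6,
                       density_per_mb = counts / (spans / 1e6),
                       stringsAsFactors = FALSE),
            class = c("compartment_stats", "data.frame"))
}

#' Classify genes by knock-out response
#'
#' The regulation classes compare expression between the wild-type and
#' knock-out conditions on the array log scale, `delta = wt - ko`:
#' up-regulated (`delta > up`), down-regulated (`delta < down`) and
#' non-regulated (`|delta| < non`), with strict inequalities, so genes with
#' intermediate changes belong to no class. Optional size-matched random
#' control gene sets are drawn per class.
#'
#' @param wt,ko [expression_table()]s; genes present in only one table are
#'   excluded with a message.
#' @param up,down,non class thresholds on `delta`.
#' @param control_seed when non-`NULL`, draw one size-matched random
#'   control set per class with this seed.
#' @return A `regulation_classes` list: `up`, `down`, `non` (gene id
#'   vectors), `delta` (named vector over common genes), `controls`,
#'   `excluded`.
#' @export
classify_regulation <- function(wt, ko, up = 0.5, down = -0.5, non = 0.05,
                                control_seed = NULL) {
  common <- intersect(wt$id, ko$id)
  excluded <- c(base::setdiff(wt$id, ko$id), base::setdiff(ko$id, wt$id))
  if (base::length(excluded))
    message(sprintf("classify_regulation: %d gene(s) present in only one table excluded",
                    base::length(excluded)))
  delta <- setNames(wt$value[match(common, wt$id)] -
                      ko$value[match(common, ko$id)], common)
  classes <- list(up = common[delta > up],
                  down = common[delta < down],
                  non = common[abs(delta) < non])
  controls <- NULL
  if (!is.null(control_seed)) {
    set.seed(control_seed)
    controls <- lapply(classes, function(ids)
      sample(common, base::length(ids)))
  }
  structure(c(classes, list(delta = delta, controls = controls,
                            excluded = excluded)),
            class = "regulation_classes")
}

#' Bin genes by expression level
#'
#' Splits genes into the 11 canonical expression groups `<3`, `3-4`, ...,
#' `11-12`, `>12`; interior bins are half-open `[low, high)`, so a value of
#' exactly 3 falls in `3-4`.
#'
#' @param expr an [expression_table()] (or named numeric vector).
#' @param low,high interior bin limits.
#' @return A data frame (`id`, `value`, `bin`) with `bin` a factor over the
#'   11 ordered group labels.
#' @export
expression_bins <- function(expr, low = 3, high = 12) {
  if (is.data.frame(expr)) {
    id <- expr$id; v <- expr$value
  } else {
    id <- names(expr); v <- as.numeric(expr)
  }
  edges <- seq(low, high - 1)
  labels <- c(sprintf("<%d", low),
              sprintf("%d-%d", edges, edges + 1),
              sprintf(">%d", high))
  idx <- ifelse(v < low, 1L,
                ifelse(v >= high, base::length(labels),
                       floor(v) - low + 2L))
  data.frame(id = id, value = v,
             bin = factor(labels[idx], levels = labels),
             stringsAsFactors = FALSE)
}

# ids of genes with >= 1 peak center within `upstream` bp 5' of the TSS
# (strand-aware; the TSS position itself is included)
bound_gene_ids <- function(genes, peaks, upstream = 5000) {
  bound <- logical(nrow(genes))
  pc <- feature_positions(peaks)
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    pp <- sort(pc[peaks$chrom == ch])
    if (!base::length(pp)) next
    lo <- ifelse(genes$strand[gi] == "+", genes$tss[gi] - upstream,
                 genes$tss[gi])
    hi <- ifelse(genes$strand[gi] == "+", genes$tss[gi],
                 genes$tss[gi] + upstream)
    n_in <- findInterval(hi, pp) - findInterval(lo - 0.5, pp)
    bound[gi] <- n_in > 0
  }
  genes$id[bound]
}

#' Expression of bound versus unbound genes
#'
#' A gene is "bound" when at least one peak center lies within `upstream`
#' bp 5' of its TSS (strand-aware). Group means are compared with a
#' two-tailed Welch (unequal-variance) t-test.
#'
#' @param genes a gene table.
#' @param peaks a `peak_list` (or data frame with `chrom`, `center`).
#' @param expr an [expression_table()]; genes without an expression value
#'   are excluded.
#' @param upstream window size in bp.
#' @return A list: `n_bound`, `n_unbound`, `mean_bound`, `mean_unbound`,
#'   `t`, `df`, `p_value`, and `bound_ids`.
#' @export
bound_vs_unbound_expression <- function(genes, peaks, expr, upstream = 5000) {
  bound_ids <- bound_gene_ids(genes, peaks, upstream)
  v <- setNames(expr$value, expr$id)
  have <- genes$id[genes$id %in% expr$id]
  b <- v[intersect(have, bound_ids)]
  u <- v[base::setdiff(have, bound_ids)]
  if (!base::length(b) || !base::length(u))
    stop("both the bound and unbound gene groups must be nonempty")
  tt <- t.test(b, u, var.equal = FALSE)
  list(n_bound = base::length(b), n_unbound = base::length(u),
       mean_bound = mean(b), mean_unbound = mean(u),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, bound_ids = bound_ids)
}

#' Site density per regulation class
#'
#' For each gene class, the span of the class's gene bodies plus flanks
#' (reduced union) and the density of predicted and occupied sites falling
#' in it, in sites per Mb; an `intergenic` row covers the genome outside
#' all genes +/- flank. Empty classes are omitted with a warning.
#'
#' @param sites predicted sites (`chrom`, `pos`/`center`); may be `NULL`.
#' @param peaks occupied sites (`chrom`, `center`); may be `NULL`.
#' @param classes a `regulation_classes` object or named list of gene id
#'   vectors.
#' @param genes a gene table.
#' @param genome a [genome_table()].
#' @param flank flank size in bp.
#' @return A data frame (`class`, `span_mb`, `n_predicted`,
#'   `predicted_per_mb`, `n_occupied`, `occupied_per_mb`).
#' @export
site_density_by_gene_class <- function(sites, peaks, classes, genes, genome,
                                       flank = 5000) {
  if (inherits(classes, "regulation_classes"))
    classes <- classes[c("up", "down", "non")]
  cl <- chrom_length(genome, genes$chrom)
  body <- gene_body_bounds(genes)
  spans <- function(idx) {
    GenomicRanges::reduce(gr_from_intervals(
      genes$chrom[idx],
      pmax(body$start[idx] - flank, 0),
      pmin(body$end[idx] + flank, cl[idx])))
  }
  count_in <- function(x, gr) {
    if (is.null(x) || nrow(x) == 0L) return(0)
    sum(IRanges::overlapsAny(gr_from_points(x$chrom, feature_positions(x)), gr))
  }
  rows <- list()
  for (nm in names(classes)) {
    idx <- which(genes$id %in% classes[[nm]])
    if (!base::length(idx)) {
      warning(sprintf("gene class '%s' is empty; omitted", nm))
      next
    }
    gr <- spans(idx)
    mb <- sum(as.numeric(GenomicRanges::width(gr))) / 1e6
    rows[[nm]] <- data.frame(
      class = nm, span_mb = mb,
      n_predicted = count_in(sites, gr),
      predicted_per_mb = count_in(sites, gr) / mb,
      n_occupied = count_in(peaks, gr),
      occupied_per_mb = count_in(peaks, gr) / mb,
      stringsAsFactors = FALSE)
  }
  all_gr <- spans(seq_len(nrow(genes)))
  inter_mb <- (genome_size(genome) -
                 sum(as.numeric(GenomicRanges::width(all_gr)))) / 1e6
  n_pred_all <- if (is.null(sites)) 0 else nrow(sites)
  n_occ_all <- if (is.null(peaks)) 0 else nrow(peaks)
  rows[["intergenic"]] <- data.frame(
    class = "intergenic", span_mb = inter_mb,
    n_predicted = n_pred_all - count_in(sites, all_gr),
    predicted_per_mb = (n_pred_all - count_in(sites, all_gr)) / inter_mb,
    n_occupied = n_occ_all - count_in(peaks, all_gr),
    occupied_per_mb = (n_occ_all - count_in(peaks, all_gr)) / inter_mb,
    stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
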