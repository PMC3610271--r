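# Independent brute-force oracles and small fixture builders. Each oracle is
# written as plainly as possible and shares no code with the implementation
# it checks.

# exhaustive peak calling: enumerate candidate windows anchored at tag
# positions, count by direct summation, apply greedy suppression by
# descending count (ties: chromosome order then leftmost start)
oracle_call_peaks <- function(tags, params, genome) {
  W <- params$window; Tthr <- params$threshold; V <- params$vicinity
  cands <- list()
  for (ch in genome$chrom) {
    t <- tags[tags$chrom == ch, , drop = FALSE]
    if (!nrow(t)) next
    pos <- t$pos; cnt <- t$count
    for (s in sort(unique(pos))) {
      n_in <- sum(cnt[pos >= s & pos <= s + W - 1])
      if (n_in >= Tthr)
        cands[[length(cands) + 1L]] <- data.frame(
          chrom = ch, start = s, count = n_in, center = s + W %/% 2)
    }
  }
  if (!length(cands))
    return(data.frame(chrom = character(), center = numeric(),
                      count = numeric()))
  cands <- do.call(rbind, cands)
  cands <- cands[order(-cands$count, match(cands$chrom, genome$chrom),
                       cands$start), , drop = FALSE]
  acc <- list()
  for (i in seq_len(nrow(cands))) {
    ok <- TRUE
    for (a in acc)
      if (a$chrom == cands$chrom[i] && abs(a$center - cands$center[i]) < V) {
        ok <- FALSE; break
      }
    if (ok) acc[[length(acc) + 1L]] <- cands[i, ]
  }
  out <- do.call(rbind, acc)
  out <- out[order(match(out$chrom, genome$chrom), out$center), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("chrom", "center", "count")]
}

# maximum per-bp window count (to check that tag-anchored windows lose no
# optimum)
oracle_max_window_count <- function(pos, cnt, W) {
  best <- 0
  for (s in (min(pos) - W):(max(pos))) {
    best <- max(best, sum(cnt[pos >= s & pos <= s + W - 1]))
  }
  best
}

# exhaustive two-state segmentation over one chromosome: enumerate every
# rich/poor labeling of the tags (each rich run of consecutive tags forms a
# segment spanning first..last tag), score directly, return the best
# objective and all optimal segment sets (within tol). Complete whenever the
# chromosome is shorter than 2*P/d bp, where splitting one run into two
# adjacent segments can never pay for the extra switches.
oracle_partition <- function(pos, cnt, d, P, tol = 1e-9) {
  n <- length(pos)
  stopifnot(max(pos) - min(pos) < 2 * P / d)
  best <- list(score = 0, sets = list(list()))   # all-poor baseline
  for (mask in 0:(2^n - 1)) {
    lab <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    segs <- Map(c, starts[r$values], ends[r$values])
    score <- 0
    for (s in segs)
      score <- score + sum(cnt[s[1]:s[2]]) - d * (pos[s[2]] - pos[s[1]] + 1) -
        2 * P
    if (score > best$score + tol) {
      best$score <- score
      best$sets <- list(segs)
    } else if (abs(score - best$score) <= tol) {
      best$sets <- c(best$sets, list(segs))
    }
  }
  key <- vapply(best$sets, function(s)
    paste(vapply(s, paste, character(1), collapse = "-"), collapse = ";"),
    character(1))
  best$sets <- best$sets[!duplicated(key)]
  best
}

# Welch t statistic and two-sided p from the textbook formulas
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# exact upper-tail binomial sum
oracle_binom_tail <- function(n, k, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i), numeric(1)))
}

# random small tag instance on a short chromosome
random_tag_instance <- function(seed, max_tags = 20, chrom_len = 5000) {
  set.seed(seed)
  n <- sample(0:max_tags, 1)
  g <- genome_table("chrT", chrom_len)
  if (n == 0) return(list(tags = tag_collection(genome = g), genome = g))
  list(tags = tag_collection(rep("chrT", n),
                             sort(sample(0:(chrom_len - 1), n, replace = TRUE)),
                             sample(c("+", "-"), n, replace = TRUE),
                             sample(1:3, n, replace = TRUE), genome = g),
       genome = g)
}

# plant one motif instance per sequence, drawn from the matrix's implied
# base distribution, on a random strand
planted_motif_seqs <- function(n, len, probs, seed) {
  set.seed(seed)
  L <- ncol(probs)
  vapply(seq_len(n), function(i) {
    s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    at <- sample(seq_len(len - L + 1), 1)
    motif <- vapply(seq_len(L), function(j)
      sample(c("A", "C", "G", "T"), 1, prob = probs[, j]), character(1))
    if (stats::runif(1) < 0.5)
      motif <- strsplit(revcomp(paste(motif, collapse = "")), "")[[1]]
    s[at:(at + L - 1)] <- motif
    paste(s, collapse = "")
  }, character(1))
}

toy_genes <- function() {
  validate_genes_public(data.frame(
    id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    tss = c(10000, 60000, 20000),
    tes = c(30000, 40000, 45000),
    strand = c("+", "-", "+"),
    stringsAsFactors = FALSE))
}

bound_gene_ids_public <- function(genes, peaks, upstream = 5000) {
  chipdomains:::bound_gene_ids(genes, peaks, upstream)
}

# read_genes without a file round trip
validate_genes_public <- function(df) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  on.exit(unlink(f))
  read_genes(f)
}
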