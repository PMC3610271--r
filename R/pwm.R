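# Additive 4 x L weight-matrix model of binding specificity. Scores are in
# the native units of whatever matrix is supplied; thresholds only have
# meaning on that scale.

BASES <- c("A", "C", "G", "T")

#' Weight matrix
#'
#' A 4 x L matrix of additive per-position scores (rows A, C, G, T). A
#' matrix may carry the per-column base probabilities it was derived from
#' (attribute `probs`) and the background frequencies (attribute
#' `background`); matrices built by [train_matrix_em()] and
#' [pwm_from_consensus()] do.
#'
#' @param scores 4 x L numeric matrix, finite entries, L >= 5.
#' @param probs optional 4 x L column-stochastic probability matrix.
#' @param background length-4 background base frequencies.
#' @return A `weight_matrix` object.
#' @export
weight_matrix <- function(scores, probs = NULL, background = rep(0.25, 4)) {
  m <- as.matrix(scores)
  if (nrow(m) != 4L) stop("weight matrix must have 4 rows (A, C, G, T)")
  if (ncol(m) < 5L) stop("weight matrix length must be >= 5")
  if (any(!is.finite(m))) stop("weight matrix entries must be finite")
  rownames(m) <- BASES
  if (!is.null(probs)) {
    probs <- as.matrix(probs)
    stopifnot(nrow(probs) == 4L, ncol(probs) == ncol(m))
    rownames(probs) <- BASES
  }
  structure(m, probs = probs, background = background,
            class = c("weight_matrix", "matrix"))
}

#' @rdname weight_matrix
#' @param x object to test.
#' @export
is_weight_matrix <- function(x) inherits(x, "weight_matrix")

#' Build a weight matrix from a consensus string
#'
#' Each consensus base gets probability `match_prob` (the rest split equally
#' over the other three bases); `N` positions are uniform. Scores are
#' `log2(prob / background)`, so a uniform column scores 0 everywhere.
#'
#' @param consensus string over `ACGTN`, length >= 5.
#' @param match_prob probability of the consensus base at its position.
#' @return A [weight_matrix()] carrying its `probs`.
#' @export
pwm_from_consensus <- function(consensus, match_prob = 0.85) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  if (!all(chars %in% c(BASES, "N"))) stop("consensus must be over ACGTN")
  L <- base::length(chars)
  probs <- matrix(0.25, 4, L, dimnames = list(BASES, NULL))
  for (j in seq_len(L)) {
    if (chars[j] != "N") {
      probs[, j] <- (1 - match_prob) / 3
      probs[chars[j], j] <- match_prob
    }
  }
  weight_matrix(log2(probs / 0.25), probs = probs)
}

#' Default NFI-style dyad-symmetric matrix
#'
#' A synthetic consensus-derived matrix for the palindromic NFI recognition
#' motif `TTGGCNNNNNGCCAA` (two 5-bp half sites separated by a 5-bp spacer).
#' It is the default motif model of the synthetic-data generators and a
#' stand-in for experimentally trained NFI matrices, which can be supplied
#' via [read_matrix_file()].
#'
#' @param match_prob probability of the consensus base at informative
#'   positions.
#' @return A [weight_matrix()] of length 15.
#' @export
nfi_matrix <- function(match_prob = 0.85) {
  pwm_from_consensus("TTGGCNNNNNGCCAA", match_prob)
}

#' Reverse complement helpers
#'
#' `revcomp` reverse-complements sequences (over `ACGTN`); `revcomp_matrix`
#' reverse-complements a weight matrix (rows A<->T, C<->G; columns
#' reversed), so that scoring a window on the minus strand equals scoring
#' with the reverse-complemented matrix on the plus strand.
#'
#' @param seq character vector of sequences.
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s) {
    chartr("ACGTNacgtn", "TGCANtgcan",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' @rdname revcomp
#' @param matrix a [weight_matrix()].
#' @export
revcomp_matrix <- function(matrix) {
  m <- unclass(matrix)[4:1, ncol(matrix):1, drop = FALSE]
  rownames(m) <- BASES
  p <- attr(matrix, "probs")
  if (!is.null(p)) p <- p[4:1, ncol(p):1, drop = FALSE]
  weight_matrix(m, probs = p, background = attr(matrix, "background"))
}

# integer codes 1..5 for A,C,G,T,N; any other letter is treated as N
seq_codes <- function(seq) {
  code <- match(strsplit(toupper(seq), "")[[1]], c(BASES, "N"))
  code[is.na(code)] <- 5L
  code
}

# 5-row score matrix: row 5 (N) scores as the column mean
with_n_row <- function(matrix) rbind(unclass(matrix), colMeans(unclass(matrix)))

#' Score one window
#'
#' Sum over positions of the matrix entry for the observed base; `N`
#' contributes the column mean, so assembly gaps are score-neutral.
#'
#' @param matrix a [weight_matrix()] of length L.
#' @param seq a single L-mer over `ACGTN`.
#' @return The additive score, in matrix units.
#' @export
score_window <- function(matrix, seq) {
  L <- ncol(matrix)
  if (nchar(seq) != L)
    stop(sprintf("sequence length %d does not match matrix length %d",
                 nchar(seq), L))
  code <- match(strsplit(toupper(seq), "")[[1]], c(BASES, "N"))
  if (anyNA(code)) stop("sequence contains characters outside ACGTN")
  m5 <- with_n_row(matrix)
  sum(m5[cbind(code, seq_len(L))])
}

#' Scan sequences for predicted binding sites
#'
#' Scores every window of both strands and reports windows at or above the
#' threshold. When the two strands of the same window both pass (as happens
#' at dyad-symmetric motifs), only the higher-scoring strand is kept, so
#' each genomic window yields at most one site.
#'
#' @param matrix a [weight_matrix()].
#' @param seqs named character vector, `Biostrings::DNAStringSet`, or path
#'   to a FASTA file. Chromosomes shorter than the matrix are skipped with a
#'   warning.
#' @param threshold minimum score, in matrix units.
#' @return A `predicted_sites` data frame with columns `chrom`, `pos`
#'   (0-based window start), `center` (dyad position, `pos + L %/% 2`),
#'   `strand`, `score`, sorted by (chrom, pos). The matrix length is kept in
#'   attribute `motif_length`.
#' @export
scan_genome <- function(matrix, seqs, threshold) {
  seqs <- as_named_sequences(seqs)
  L <- ncol(matrix)
  m5f <- with_n_row(matrix)
  m5r <- with_n_row(revcomp_matrix(matrix))
  out <- vector("list", base::length(seqs))
  for (i in seq_along(seqs)) {
    n <- nchar(seqs[[i]])
    if (n < L) {
      warning(sprintf("chromosome %s shorter than matrix; skipped", names(seqs)[i]))
      next
    }
    code <- seq_codes(seqs[[i]])
    P <- n - L + 1L
    fwd <- numeric(P)
    rev_ <- numeric(P)
    for (k in seq_len(L)) {
      idx <- code[k:(k + P - 1L)]
      fwd <- fwd + m5f[idx + (k - 1L) * 5L]
      rev_ <- rev_ + m5r[idx + (k - 1L) * 5L]
    }
    keep <- which(fwd >= threshold | rev_ >= threshold)
    if (!base::length(keep)) next
    out[[i]] <- data.frame(
      chrom = names(seqs)[i],
      pos = keep - 1L,
      strand = ifelse(fwd[keep] >= rev_[keep], "+", "-"),
      score = pmax(fwd[keep], rev_[keep]),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(chrom = character(), pos = numeric(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  res <- res[order_genomic(res$chrom, res$pos, names(seqs)), , drop = FALSE]
  res$center <- res$pos + L %/% 2
  res <- res[, c("chrom", "pos", "center", "strand", "score")]
  rownames(res) <- NULL
  structure(res, motif_length = L,
            class = c("predicted_sites", "data.frame"))
}

as_named_sequences <- function(seqs) {
  if (is.character(seqs) && base::length(seqs) == 1L && file.exists(seqs))
    seqs <- Biostrings::readDNAStringSet(seqs)
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (!is.character(seqs) || is.null(names(seqs)))
    stop("seqs must be a named character vector, DNAStringSet, or FASTA path")
  seqs
}

#' Train a weight matrix by expectation-maximisation
#'
#' Fits a one-motif-occurrence-per-sequence model over both strands: the
#' E-step computes, for each sequence, the posterior over motif start and
#' strand under the current base-frequency matrix against a 0-order
#' background estimated from the input; the M-step re-estimates the matrix
#' from expected base counts with pseudocount smoothing. The observed-data
#' log likelihood is non-decreasing across iterations (returned in attribute
#' `loglik`).
#'
#' @param seqs character vector (or `DNAStringSet`) of sequences, each at
#'   least as long as the consensus.
#' @param init_consensus initialising consensus string over `ACGTN`; its
#'   length fixes the motif length L.
#' @param max_iter,tol iteration cap and convergence tolerance on the
#'   largest per-entry frequency change.
#' @param pseudocount added to each expected base count in the M-step.
#' @return A [weight_matrix()] of `log2(freq / background)` scores carrying
#'   `probs`, `background`, `loglik` and `iterations` attributes.
#' @export
train_matrix_em <- function(seqs, init_consensus, max_iter = 100, tol = 1e-3,
                            pseudocount = 0.5) {
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  seqs <- toupper(as.character(seqs))
  if (!base::length(seqs)) stop("no input sequences")
  L <- nchar(init_consensus)
  if (any(nchar(seqs) < L))
    stop("all sequences must be at least as long as the consensus")
  if (base::length(unique(seqs)) == 1L && base::length(seqs) > 1L)
    warning("all input sequences are identical; trained motif has zero entropy")

  codes <- lapply(seqs, seq_codes)
  base_tab <- tabulate(unlist(codes), nbins = 5L)[1:4]
  if (sum(base_tab) == 0) stop("sequences contain no ACGT bases")
  bg <- (base_tab + 1) / sum(base_tab + 1)

  theta <- attr(pwm_from_consensus(init_consensus, match_prob = 0.7), "probs")
  comp <- c(4L, 3L, 2L, 1L, 5L)    # complement on codes, N fixed
  ll_trace <- numeric(0)

  for (iter in seq_len(max_iter)) {
    lr <- log(theta) - log(bg)
    lr5 <- rbind(lr, 0)            # N base: likelihood ratio 1
    counts <- matrix(0, 4, L)
    ll_total <- 0
    for (v in codes) {
      n <- base::length(v)
      P <- n - L + 1L
      llp <- numeric(P)            # motif on + strand at p
      llm <- numeric(P)            # motif on - strand at p
      for (k in seq_len(L)) {
        idx <- v[k:(k + P - 1L)]
        llp <- llp + lr5[idx + (k - 1L) * 5L]
        # minus-strand motif column k reads the complement of position p+L-k
        idy <- comp[v[(L - k + 1L):(n - k + 1L)]]
        llm <- llm + lr5[idy + (k - 1L) * 5L]
      }
      all_ll <- c(llp, llm)
      mx <- max(all_ll)
      w <- exp(all_ll - mx)
      Z <- sum(w)
      w <- w / Z
      ll_total <- ll_total + mx + log(Z) - log(2 * P)
      wp <- w[seq_len(P)]
      wm <- w[P + seq_len(P)]
      for (k in seq_len(L)) {
        idx <- v[k:(k + P - 1L)]
        idy <- comp[v[(L - k + 1L):(n - k + 1L)]]
        for (b in 1:4) {
          counts[b, k] <- counts[b, k] + sum(wp[idx == b]) + sum(wm[idy == b])
        }
      }
    }
    theta_new <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
    ll_trace <- c(ll_trace, ll_total)
    delta <- max(abs(theta_new - theta))
    theta <- theta_new
    if (delta < tol) break
  }
  wm <- weight_matrix(log2(theta / bg), probs = theta, background = bg)
  attr(wm, "loglik") <- ll_trace
  attr(wm, "iterations") <- base::length(ll_trace)
  wm
}

#' Per-column base frequencies and information content
#'
#' For a probability-carrying weight matrix, or a set of aligned
#' equal-length sequences, returns the column-stochastic frequency matrix
#' and the per-column information in bits, `2 - H(column)`.
#'
#' @param x a [weight_matrix()] with `probs`, a 4 x L probability matrix,
#'   or a character vector of aligned equal-length sequences.
#' @return A list with elements `freq` (4 x L) and `bits` (length L).
#' @export
information_content <- function(x) {
  if (is_weight_matrix(x)) {
    freq <- attr(x, "probs")
    if (is.null(freq)) stop("weight matrix carries no base probabilities")
  } else if (is.matrix(x)) {
    freq <- x
    if (nrow(freq) != 4L) stop("frequency matrix must have 4 rows")
  } else {
    seqs <- toupper(as.character(x))
    if (base::length(unique(nchar(seqs))) != 1L)
      stop("sequences must be aligned (equal length)")
    L <- nchar(seqs[1])
    freq <- matrix(0, 4, L, dimnames = list(BASES, NULL))
    mat <- do.call(rbind, lapply(seqs, seq_codes))
    for (k in seq_len(L)) {
      tab <- tabulate(mat[, k], nbins = 5L)[1:4]
      freq[, k] <- tab / sum(tab)
    }
  }
  freq <- sweep(freq, 2, colSums(freq), "/")
  rownames(freq) <- BASES
  plogp <- ifelse(freq > 0, freq * log2(freq), 0)
  list(freq = freq, bits = 2 + colSums(plogp))
}

#' Consensus string of a weight matrix
#'
#' The highest-scoring base at each column (by `probs` when present, else by
#' score).
#'
#' @param matrix a [weight_matrix()].
#' @return A string of length L.
#' @export
matrix_consensus <- function(matrix) {
  m <- attr(matrix, "probs") %||% unclass(matrix)
  paste(BASES[apply(m, 2, which.max)], collapse = "")
}

#' Range of attainable scores
#'
#' @param matrix a [weight_matrix()].
#' @return `c(min, max)` of the additive score over all L-mers.
#' @export
score_bounds <- function(matrix) {
  m <- unclass(matrix)
  c(sum(apply(m, 2, min)), sum(apply(m, 2, max)))
}
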