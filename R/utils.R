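# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# order rows by chromosome (in `chrom_levels` order if given) then position
order_genomic <- function(chrom, pos, chrom_levels = NULL, extra = NULL) {
  key <- if (is.null(chrom_levels)) match(chrom, unique(chrom)) else match(chrom, chrom_levels)
  if (is.null(extra)) order(key, pos) else order(key, pos, extra)
}

# nearest element of a sorted numeric vector; returns list(index, distance)
# distance is signed: sorted[index] - x
nearest_in_sorted <- function(x, sorted) {
  n <- length(sorted)
  if (n == 0L) return(list(index = rep(NA_integer_, length(x)),
                           distance = rep(NA_real_, length(x))))
  lo <- findInterval(x, sorted)            # last index with sorted[i] <= x
  hi <- pmin(lo + 1L, n)
  lo <- pmax(lo, 1L)
  d_lo <- abs(sorted[lo] - x)
  d_hi <- abs(sorted[hi] - x)
  idx <- ifelse(d_hi < d_lo, hi, lo)       # ties -> smaller coordinate
  list(index = idx, distance = sorted[idx] - x)
}

# TRUE for points falling inside any 0-based half-open interval
point_in_intervals <- function(chrom, pos, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) return(rep(FALSE, length(pos)))
  hit <- rep(FALSE, length(pos))
  for (ch in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    o <- order(iv$start)
    s <- iv$start[o]; e <- iv$end[o]
    sel <- which(chrom == ch)
    if (!length(sel)) next
    i <- findInterval(pos[sel], s)
    hit[sel] <- i >= 1L & pos[sel] < e[pmax(i, 1L)]
  }
  hit
}

stop_if_missing_cols <- function(df, cols, what) {
  miss <- base::setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}
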