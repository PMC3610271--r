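# External representations. One fixed convention throughout: coordinates are
# 0-based and intervals half-open; 1-based dialects are converted here, at the
# boundary, and nowhere else.

#' Chromosome name/length table
#'
#' Constructs the genome table against which all coordinates are validated.
#' The row order of the table defines the canonical chromosome order used
#' when sorting genomic output.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length chromosome lengths in bp; all `> 0`.
#' @return A `genome_table` data frame with columns `chrom` and `length`.
#' @examples
#' genome_table(c("chr1", "chr2"), c(5e5, 3e5))
#' @export
genome_table <- function(chrom, length) {
  chrom <- as.character(chrom)
  len <- as.numeric(length)
  if (base::length(chrom) != base::length(len))
    stop("chrom and length must have the same length")
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(!is.finite(len)) || any(len <= 0))
    stop("chromosome lengths must be finite and > 0")
  structure(data.frame(chrom = chrom, length = len, stringsAsFactors = FALSE),
            class = c("genome_table", "data.frame"))
}

#' @rdname genome_table
#' @param path two-column whitespace-separated file (UCSC `chrom.sizes`).
#' @export
read_genome_table <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("genome table must have two columns: chrom, length")
  genome_table(df[[1]], df[[2]])
}

#' @rdname genome_table
#' @param genome a `genome_table`.
#' @export
genome_size <- function(genome) sum(genome$length)

chrom_length <- function(genome, chrom) genome$length[match(chrom, genome$chrom)]

#' Single-base stranded tag collection
#'
#' A tag is the 0-based genomic position of a read's 5' end, its strand, and
#' a positive multiplicity. Collections are kept sorted by (chromosome,
#' position, strand); the chromosome order follows the genome table when one
#' is supplied.
#'
#' @param chrom,pos,strand,count parallel record vectors; `strand` in
#'   `"+"`/`"-"`, `count` positive integers (recycled).
#' @param genome optional [genome_table()]; when given, positions are
#'   validated against chromosome bounds.
#' @return A `tag_collection` data frame with columns `chrom`, `pos`,
#'   `strand`, `count`.
#' @export
tag_collection <- function(chrom = character(), pos = numeric(),
                           strand = character(), count = 1L, genome = NULL) {
  n <- base::length(pos)
  df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   strand = as.character(strand),
                   count = as.integer(rep_len(count, n)),
                   stringsAsFactors = FALSE)
  if (n > 0L) {
    if (!all(df$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
    if (any(df$count < 1L)) stop("tag counts must be positive")
    if (any(df$pos < 0)) stop("tag positions must be >= 0")
    if (!is.null(genome)) {
      cl <- chrom_length(genome, df$chrom)
      if (anyNA(cl)) stop("tag on chromosome absent from genome table")
      if (any(df$pos >= cl)) stop("tag position beyond chromosome end")
    }
    df <- df[order_genomic(df$chrom, df$pos, genome$chrom, extra = df$strand), ,
             drop = FALSE]
    rownames(df) <- NULL
  }
  structure(df, class = c("tag_collection", "data.frame"))
}

#' Collapse duplicate tag records
#'
#' Sums multiplicities over identical (chrom, pos, strand) keys so that each
#' key appears once.
#'
#' @param tags a [tag_collection()].
#' @return A `tag_collection` with unique (chrom, pos, strand) records.
#' @export
dedupe_tags <- function(tags) {
  if (nrow(tags) == 0L) return(tags)
  dt <- data.table::as.data.table(tags)
  out <- dt[, list(count = as.integer(sum(count))),
            by = c("chrom", "pos", "strand")]
  data.table::setDF(out)
  tag_collection(out$chrom, out$pos, out$strand, out$count)
}

#' Read ChIP-seq tags
#'
#' Auto-detects the dialect by column count: 3/4 columns are read as
#' `chrom pos strand [count]` single-base tag records; 6 or more columns are
#' read as BED, and each interval is reduced to the 5' end of the read it
#' represents (`start` for `+` records, `end - 1` for `-` records). Records
#' on chromosomes absent from `genome` are dropped with a message.
#'
#' @param path tab- or space-separated text file.
#' @param genome a [genome_table()].
#' @param dedupe collapse identical (chrom, pos, strand) records, summing
#'   multiplicities?
#' @return A [tag_collection()].
#' @export
read_tags <- function(path, genome, dedupe = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!base::length(lines)) return(tag_collection(genome = genome))
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  ncol0 <- nf[1]
  bad <- which(nf != ncol0)
  if (base::length(bad))
    stop(sprintf("malformed line %d: expected %d fields, found %d",
                 bad[1], ncol0, nf[bad[1]]))
  m <- matrix(unlist(fields), ncol = ncol0, byrow = TRUE)
  if (ncol0 %in% c(3L, 4L)) {
    chrom <- m[, 1]
    pos <- suppressWarnings(as.numeric(m[, 2]))
    strand <- m[, 3]
    count <- if (ncol0 == 4L) suppressWarnings(as.integer(m[, 4])) else 1L
  } else if (ncol0 >= 6L) {
    chrom <- m[, 1]
    start <- suppressWarnings(as.numeric(m[, 2]))
    end <- suppressWarnings(as.numeric(m[, 3]))
    strand <- m[, 6]
    if (anyNA(start) || anyNA(end))
      stop(sprintf("malformed line %d: non-numeric coordinate",
                   which(is.na(start) | is.na(end))[1]))
    pos <- ifelse(strand == "+", start, end - 1)
    count <- 1L
  } else {
    stop("unrecognised tag dialect: need 3/4 columns (chrom pos strand [count]) or >= 6 (BED)")
  }
  if (anyNA(pos))
    stop(sprintf("malformed line %d: non-numeric position", which(is.na(pos))[1]))
  badstr <- which(!strand %in% c("+", "-"))
  if (base::length(badstr))
    stop(sprintf("unknown strand symbol '%s' at line %d",
                 strand[badstr[1]], badstr[1]))
  keep <- chrom %in% genome$chrom
  if (any(!keep))
    message(sprintf("read_tags: dropped %d record(s) on chromosomes absent from genome",
                    sum(!keep)))
  out <- tag_collection(chrom[keep], pos[keep], strand[keep],
                        if (base::length(count) > 1L) count[keep] else count,
                        genome = genome)
  if (dedupe) dedupe_tags(out) else out
}

#' @rdname read_tags
#' @param tags a [tag_collection()] to write (4-column
#'   `chrom pos strand count` dialect; round-trips through `read_tags`).
#' @export
write_tags <- function(tags, path) {
  df <- as.data.frame(tags)[, c("chrom", "pos", "strand", "count")]
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read and write 6-column BED
#'
#' Intervals are 0-based half-open. `write_bed` fills missing `name`,
#' `score`, `strand` columns with `"."`, `0`, `"."`; writing then reading
#' back is lossless.
#'
#' @param intervals data frame with columns `chrom`, `start`, `end` and
#'   optionally `name`, `score`, `strand`.
#' @param path file path.
#' @return `read_bed` returns a data frame with the six BED columns.
#' @export
write_bed <- function(intervals, path) {
  stop_if_missing_cols(intervals, c("chrom", "start", "end"), "BED input")
  df <- as.data.frame(intervals)
  if (nrow(df) > 0L && any(df$start >= df$end))
    stop("BED intervals must satisfy start < end")
  if (is.null(df$name)) df$name <- "."
  if (is.null(df$score)) df$score <- 0
  if (is.null(df$strand)) df$strand <- "."
  df <- df[, c("chrom", "start", "end", "name", "score", "strand")]
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), score = numeric(),
                      strand = character(), stringsAsFactors = FALSE)
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) return(empty)
  df <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = c(1, 4, 6)))
  if (!nrow(df)) return(empty)
  data.table::setDF(df)
  names(df)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  df[, 1:6]
}

#' Gene annotation table
#'
#' Tab-separated with a header line; required columns `id`, `chrom`, `tss`,
#' `tes`, `strand`. `tss`/`tes` are single 0-based positions; the TSS must
#' lie upstream of the TES in the direction of transcription (`tss < tes`
#' on `+`, `tss > tes` on `-`). Optional structure columns (`exon_starts`,
#' `exon_ends` as comma-separated 0-based lists; `utr5_start`, `utr5_end`,
#' `utr3_start`, `utr3_end` as single half-open intervals) enable the
#' UTR/exon compartments of [annotate_compartments()].
#'
#' @param path file path.
#' @return A `gene_table` data frame.
#' @export
read_genes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_genes(df)
}

validate_genes <- function(df) {
  stop_if_missing_cols(df, c("id", "chrom", "tss", "tes", "strand"), "gene table")
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    stop(sprintf("duplicate gene id: %s", df$id[duplicated(df$id)][1]))
  if (!all(df$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  if (any(df$tss == df$tes)) stop("gene with tss == tes rejected")
  bad <- (df$strand == "+" & df$tss > df$tes) | (df$strand == "-" & df$tss < df$tes)
  if (any(bad))
    stop(sprintf("gene %s: tss must lie upstream of tes in transcription direction",
                 df$id[bad][1]))
  rownames(df) <- NULL
  structure(df, class = c("gene_table", "data.frame"))
}

#' @rdname read_genes
#' @param genes a `gene_table` to write.
#' @export
write_genes <- function(genes, path) {
  utils::write.table(as.data.frame(genes), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Expression table
#'
#' Two tab-separated columns: gene id and expression level (microarray log
#' scale). A header line is detected (non-numeric second field) and skipped.
#' Duplicate gene ids are an error.
#'
#' @param path file path.
#' @return An `expression_table` data frame with columns `id`, `value`.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression table must have two columns: id, value")
  if (nrow(df) > 0L && is.na(suppressWarnings(as.numeric(df[1, 2]))))
    df <- df[-1, , drop = FALSE]
  expression_table(df[[1]], as.numeric(df[[2]]))
}

#' @rdname read_expression
#' @param id,value gene ids (unique) and expression levels.
#' @export
expression_table <- function(id, value) {
  id <- as.character(id)
  value <- as.numeric(value)
  if (anyDuplicated(id))
    stop(sprintf("duplicate gene id in expression table: %s",
                 id[duplicated(id)][1]))
  if (anyNA(value)) stop("non-numeric expression value")
  structure(data.frame(id = id, value = value, stringsAsFactors = FALSE),
            class = c("expression_table", "data.frame"))
}

#' @rdname read_expression
#' @param expr an `expression_table` to write (with header).
#' @export
write_expression <- function(expr, path) {
  utils::write.table(as.data.frame(expr), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Plain-text weight-matrix file
#'
#' Four rows (A, C, G, T order; an optional leading base label per row is
#' accepted) of L real scores each. Comment lines starting with `#` or `>`
#' are ignored. Scores stay in whatever units the file carries.
#'
#' @param path file path.
#' @return A [weight_matrix()].
#' @export
read_matrix_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^[#>]", trimws(lines))]
  if (base::length(lines) != 4L)
    stop(sprintf("matrix file must have 4 rows (A, C, G, T); found %d",
                 base::length(lines)))
  rows <- lapply(strsplit(trimws(lines), "[ \t]+"), function(f) {
    if (f[1] %in% c("A", "C", "G", "T", "a", "c", "g", "t")) f <- f[-1]
    as.numeric(f)
  })
  if (base::length(unique(lengths(rows))) != 1L)
    stop("matrix rows differ in length")
  m <- do.call(rbind, rows)
  weight_matrix(m)
}

#' @rdname read_matrix_file
#' @param matrix a [weight_matrix()] to write.
#' @export
write_matrix_file <- function(matrix, path) {
  m <- unclass(matrix)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in 1:4)
    writeLines(paste(c(rownames(m)[i], format(m[i, ], digits = 15)),
                     collapse = "\t"), con)
  invisible(path)
}
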