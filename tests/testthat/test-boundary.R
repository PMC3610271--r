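mk_boundaries <- function(pos, polarity, chrom = "chr1") {
  structure(data.frame(chrom = chrom, pos = pos, polarity = polarity,
                       mark = NA_character_, stringsAsFactors = FALSE),
            class = c("boundary_list", "data.frame"))
}

test_that("site-to-boundary matching signs distances toward the rich side", {
  b <- mk_boundaries(c(10000, 50000), c("rich-right", "rich-left"))
  # site exactly at a boundary: distance 0, side rich by the tie rule
  m0 <- match_sites_to_boundaries(b, data.frame(chrom = "chr1", pos = 10000))
  expect_true(m0$matched[1])
  expect_equal(m0$distance[1], 0)
  expect_equal(m0$side[1], "rich")
  # 1 kb into the rich side of a rich-right boundary -> +1000, rich
  m1 <- match_sites_to_boundaries(b, data.frame(chrom = "chr1", pos = 11000))
  expect_equal(m1$distance[1], 1000)
  expect_equal(m1$side[1], "rich")
  # same offset on a rich-left boundary is the poor side
  m2 <- match_sites_to_boundaries(b, data.frame(chrom = "chr1", pos = 51000))
  expect_equal(m2$distance[2], -1000)
  expect_equal(m2$side[2], "poor")
  # beyond the radius: unmatched
  m3 <- match_sites_to_boundaries(b, data.frame(chrom = "chr1", pos = 13000),
                                  radius = 2500)
  expect_false(m3$matched[1])
  # at the radius exactly: matched (closed interval)
  m4 <- match_sites_to_boundaries(b, data.frame(chrom = "chr1", pos = 12500),
                                  radius = 2500)
  expect_true(m4$matched[1])
})

test_that("rich-side planting is detected as a one-sided excess", {
  set.seed(50)
  n <- 200
  pos <- sort(sample(seq(10000, 4e6, 20000), n))
  pol <- sample(c("rich-right", "rich-left"), n, TRUE)
  b <- mk_boundaries(pos, pol)
  offs <- sample(100:2000, n, TRUE)
  sites <- data.frame(chrom = "chr1",
                      pos = ifelse(pol == "rich-right", pos + offs, pos - offs))
  m <- match_sites_to_boundaries(b, sites)
  s <- attr(m, "summary")
  expect_equal(s$k_rich + s$k_poor, s$k_matched)
  bt <- stats::binom.test(s$k_rich, s$k_matched, 0.5, "greater")
  expect_lt(bt$p.value, 1e-6)
})

test_that("double-boundary pairing needs opposite polarity and one-to-one use", {
  a <- mk_boundaries(c(1000, 5000), c("rich-right", "rich-left"))
  # identical lists with opposite polarity required: nothing pairs
  expect_equal(nrow(colocalize_boundaries(a, a)$pairs), 0)
  # with the polarity requirement off, each pairs with itself at distance 0
  self <- colocalize_boundaries(a, a, require_opposite_polarity = FALSE)
  expect_equal(nrow(self$pairs), 2)
  expect_equal(self$pairs$distance, c(0, 0))

  # disjoint chromosomes never pair
  b2 <- mk_boundaries(c(1000, 5000), c("rich-left", "rich-right"),
                      chrom = "chr2")
  expect_equal(nrow(colocalize_boundaries(a, b2)$pairs), 0)

  # one-to-one greedy: two a-boundaries, one opposite b in range
  a2 <- mk_boundaries(c(1000, 1400), c("rich-right", "rich-right"))
  b3 <- mk_boundaries(1200, "rich-left")
  cl <- colocalize_boundaries(a2, b3, radius = 2500)
  expect_equal(nrow(cl$pairs), 1)
  expect_equal(cl$unmatched_a, 2L)   # the more distant one misses out
})

test_that("planted double-boundary loci are recovered end to end", {
  p <- sim_params(seed = 51)
  loc <- make_double_boundary_locus(p)
  prm <- segmentation_params()
  s36 <- partition(loc$k36$tags, prm, loc$genome)
  s27 <- partition(loc$k27$tags, prm, loc$genome)
  b36 <- boundaries_from_segments(s36, mark = "H3K36me3")
  b27 <- boundaries_from_segments(s27, mark = "H3K27me3")
  cl <- colocalize_boundaries(b27, b36, radius = 2500,
                              require_opposite_polarity = TRUE)
  # both planted domain edges come back as opposite-polarity pairs
  for (edge in loc$domain) {
    hit <- abs(cl$pairs$a_pos - edge) <= 2500
    expect_true(any(hit))
  }
  # and the planted binding sites sit at the recovered boundaries
  m <- match_sites_to_boundaries(b36, loc$sites, radius = 2500)
  expect_gte(attr(m, "summary")$k_matched, 2)
})

test_that("gene classification is exhaustive with TSS precedence", {
  genes <- toy_genes()
  b <- mk_boundaries(c(11000, 29500, 70000), rep("rich-right", 3))
  cls <- classify_vs_genes(b, genes, radius = 2500)
  expect_equal(cls$gene_class, c("tss", "tes", "neither"))

  # TSS wins when both are within the radius
  gboth <- validate_genes_public(data.frame(
    id = "g", chrom = "chr1", tss = 10000, tes = 12000, strand = "+"))
  bb <- mk_boundaries(11000, "rich-right")
  expect_equal(classify_vs_genes(bb, gboth)$gene_class, "tss")

  # gene-free chromosome: everything "neither"; partition sizes add up
  set.seed(52)
  bmany <- mk_boundaries(sort(sample(1:1e6, 1000)),
                         sample(c("rich-right", "rich-left"), 1000, TRUE),
                         chrom = "chrEmpty")
  cl2 <- classify_vs_genes(bmany, genes)
  expect_true(all(cl2$gene_class == "neither"))
  expect_equal(sum(attr(cl2, "summary")), 1000)

  # order invariance
  cls_rev <- classify_vs_genes(b, genes[rev(seq_len(nrow(genes))), ],
                               radius = 2500)
  expect_equal(cls_rev$gene_class, cls$gene_class)
})

test_that("random controls preserve per-chromosome counts deterministically", {
  g <- genome_table(c("chr1", "chr2", "chr3"), c(1e6, 5e5, 2e5))
  tmpl <- data.frame(chrom = c(rep("chr1", 30), rep("chr3", 10)))
  r1 <- sample_random_sites(tmpl, g, seed = 9)
  r2 <- sample_random_sites(tmpl, g, seed = 9)
  expect_identical(r1, r2)
  expect_equal(as.vector(table(factor(r1$chrom, levels = g$chrom))),
               c(30, 0, 10))
  expect_true(all(r1$pos >= 0 & r1$pos < chipdomains::genome_size(g)))
  expect_equal(nrow(sample_random_sites(tmpl[0, , drop = FALSE], g, 1)), 0)
})

test_that("random-site match rates agree with the closed-form expectation", {
  G <- 1e7
  g <- genome_table("chr1", G)
  set.seed(53)
  nb <- 50
  b <- mk_boundaries(sort(sample(seq(1e5, G - 1e5, 1e5), nb)),
                     sample(c("rich-right", "rich-left"), nb, TRUE))
  m_sites <- 200
  tmpl <- data.frame(chrom = rep("chr1", m_sites))
  radius <- 2500
  # per-site probability of landing within +/- radius of some boundary
  p_hit <- 2 * radius * nb / G
  rates <- vapply(1:100, function(s) {
    r <- sample_random_sites(tmpl, g, seed = 1000 + s)
    mean(vapply(r$pos, function(x) any(abs(b$pos - x) <= radius), logical(1)))
  }, numeric(1))
  se <- sqrt(p_hit * (1 - p_hit) / (m_sites * 100))
  expect_lt(abs(mean(rates) - p_hit), 3 * se)
})

test_that("the binomial enrichment test matches printed rows and a tail oracle", {
  r <- enrichment_test(4687, 148, 45)
  expect_equal(r$pct_obs, 3.15)
  expect_equal(r$pct_rand, 0.96)
  expect_equal(r$p_value,
               pbinom(147, 4687, 45 / 4687, lower.tail = FALSE))

  # equality at the mean sits near 0.5
  r2 <- enrichment_test(1000, 100, 100)
  expect_lt(abs(r2$p_value - 0.5), 0.05)

  # exact tail-sum oracle on small n
  for (case in list(c(20, 7, 3), c(50, 10, 5), c(30, 0, 2))) {
    r3 <- enrichment_test(case[1], case[2], case[3])
    expect_equal(r3$p_value,
                 oracle_binom_tail(case[1], case[2], case[3] / case[1]),
                 tolerance = 1e-12)
  }

  # zero control matches: continuity floor, flagged
  r4 <- enrichment_test(200, 5, 0)
  expect_true(r4$floored)
  expect_equal(r4$p0, 0.5 / 200)
  expect_error(enrichment_test(10, 11, 2), "<=")
})

test_that("nearest distances split by side reflect rich-side planting", {
  b <- mk_boundaries(c(10000, 30000), c("rich-right", "rich-left"))
  sites <- data.frame(chrom = "chr1", pos = c(10000, 30000))
  expect_equal(nearest_distance_distribution(b, sites, "rich", k = 2),
               c(0, 0))
  expect_warning(
    d1 <- nearest_distance_distribution(b, sites, "poor", k = 5),
    "available")
  # k = 1 returns the single global minimum
  sites2 <- data.frame(chrom = "chr1", pos = c(10700, 29100))
  expect_equal(nearest_distance_distribution(b, sites2, "rich", k = 1), 700)

  set.seed(54)
  n <- 150
  pos <- sort(sample(seq(1e4, 3e6, 2e4), n))
  pol <- sample(c("rich-right", "rich-left"), n, TRUE)
  bb <- mk_boundaries(pos, pol)
  rich_sites <- data.frame(
    chrom = "chr1",
    pos = ifelse(pol == "rich-right", pos + sample(50:900, n, TRUE),
                 pos - sample(50:900, n, TRUE)))
  dr <- nearest_distance_distribution(bb, rich_sites, "rich", k = 100)
  dp <- suppressWarnings(
    nearest_distance_distribution(bb, rich_sites, "poor", k = 100))
  wt <- stats::wilcox.test(dr, dp, alternative = "less")
  expect_lt(wt$p.value, 0.01)
})

test_that("lamina alignment orients profiles toward the nuclear interior", {
  g <- genome_table("chr1", 1e7)
  set.seed(55)
  lads <- data.frame(chrom = "chr1",
                     start = seq(5e5, 9e6, 1e6),
                     end = seq(5e5, 9e6, 1e6) + 4e5)
  expect_error(lamina_alignment(lads[0, ], data.frame(), genome = g), "empty")

  unif <- data.frame(chrom = "chr1", pos = sample(0:(1e7 - 1), 20000, TRUE))
  la <- lamina_alignment(lads, unif, genome = g)
  expect_lt(abs(la$side_occupancy[["lamina_poor"]] - 1), 0.25)
  expect_lt(abs(la$side_occupancy[["lamina_rich"]] - 1), 0.25)

  # sites planted only in inter-LAD gaps: broad lamin-poor elevation
  gaps <- unlist(lapply(seq_len(nrow(lads) - 1), function(i)
    sample(seq(lads$end[i] + 1000, lads$start[i + 1] - 1000, 200), 40)))
  la2 <- lamina_alignment(lads, data.frame(chrom = "chr1", pos = gaps),
                          genome = g)
  expect_gt(la2$side_occupancy[["lamina_poor"]],
            2 * la2$side_occupancy[["lamina_rich"]])
})
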