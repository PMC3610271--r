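genome <- genome_table(c("chr1", "chr2"), c(2e5, 1e5))

test_that("compartment assignment partitions features with stated precedence", {
  genes <- validate_genes_public(data.frame(
    id = "gA", chrom = "chr1", tss = 50000, tes = 80000, strand = "+",
    exon_starts = "50000,70000", exon_ends = "52000,80000",
    utr5_start = 50000, utr5_end = 50500,
    utr3_start = 79000, utr3_end = 80000))
  feats <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr1", "chr1",
                                "chr1", "chr2"),
                      pos = c(50200,   # utr5 (inside exon1 too)
                              51000,   # coding exon
                              60000,   # intron
                              47000,   # 3 kb upstream of the + TSS
                              82000,   # downstream
                              10000,   # intergenic on chr1
                              50000))  # gene-free chromosome -> intergenic
  st <- annotate_compartments(feats, genes, genome)
  got <- setNames(st$count, st$compartment)
  expect_equal(got[["utr5"]], 1)
  expect_equal(got[["coding_exon"]], 1)
  expect_equal(got[["intron"]], 1)
  expect_equal(got[["upstream5kb"]], 1)
  expect_equal(got[["downstream5kb"]], 1)
  expect_equal(got[["intergenic"]], 2)
  expect_equal(sum(st$count), nrow(feats))
  expect_equal(sum(st$span_mb), chipdomains::genome_size(genome) / 1e6,
               tolerance = 1e-9)
})

test_that("compartment densities divide counts by disjoint spans", {
  genes <- validate_genes_public(data.frame(
    id = "g", chrom = "chr1", tss = 100000, tes = 120000, strand = "+"))
  feats <- data.frame(chrom = rep("chr1", 4), pos = c(105000, 110000,
                                                      96000, 10))
  st <- annotate_compartments(feats, genes, genome)
  intron <- st[st$compartment == "intron", ]
  expect_equal(intron$count, 2)
  expect_equal(intron$span_mb, 20001 / 1e6)
  expect_equal(intron$density_per_mb, 2 / (20001 / 1e6))
})

test_that("regulation thresholds are strict and exclusions are logged", {
  wt <- expression_table(c("a", "b", "c", "d", "e"), c(5, 5, 5, 5, 5))
  ko <- expression_table(c("a", "b", "c", "d", "x"),
                         c(4.4, 5.6, 5.02, 4.5, 1))
  expect_message(cls <- classify_regulation(wt, ko), "excluded")
  expect_equal(cls$up, "a")          # delta 0.6
  expect_equal(cls$down, "b")        # delta -0.6
  expect_equal(cls$non, "c")         # |delta| 0.02
  expect_equal(length(intersect("d", c(cls$up, cls$down, cls$non))), 0)
  expect_setequal(cls$excluded, c("e", "x"))
})

test_that("a |delta| of exactly 0.5 belongs to no class", {
  wt <- expression_table(c("a", "b"), c(5, 5))
  ko <- expression_table(c("a", "b"), c(4.5, 5.5))
  cls <- classify_regulation(wt, ko)
  expect_equal(length(cls$up), 0)
  expect_equal(length(cls$down), 0)
})

test_that("identical conditions give an all-non classification", {
  wt <- expression_table(letters[1:10], runif(10, 2, 13))
  cls <- classify_regulation(wt, wt)
  expect_setequal(cls$non, letters[1:10])
  expect_equal(length(cls$up) + length(cls$down), 0)
})

test_that("size-matched controls are reproducible under the seed", {
  wt <- expression_table(letters[1:20], seq(2, 12, length.out = 20))
  ko <- expression_table(letters[1:20], seq(2, 12, length.out = 20) - 0.6)
  c1 <- classify_regulation(wt, ko, control_seed = 5)
  c2 <- classify_regulation(wt, ko, control_seed = 5)
  expect_identical(c1$controls, c2$controls)
  expect_equal(length(c1$controls$up), length(c1$up))
})

test_that("expression bins are half-open with closed extremes", {
  e <- expression_table(c("a", "b", "c", "d", "e"),
                        c(3.0, 2.999, 12.0, 11.999, 7.5))
  b <- expression_bins(e)
  expect_equal(as.character(b$bin),
               c("3-4", "<3", ">12", "11-12", "7-8"))
  expect_equal(sum(table(b$bin)), 5)
})

test_that("Welch comparison matches the closed form and degenerate cases", {
  g <- genome_table("chr1", 1e6)
  genes <- validate_genes_public(data.frame(
    id = sprintf("g%02d", 1:10), chrom = "chr1",
    tss = seq(50000, 950000, length.out = 10),
    tes = seq(50000, 950000, length.out = 10) + 20000,
    strand = "+"))
  peaks <- data.frame(chrom = "chr1",
                      center = genes$tss[c(1, 3, 5)] - 2000)
  set.seed(60)
  vals <- c(8.1, 5.2, 9.3, 4.8, 7.7, 5.1, 6.0, 5.5, 4.9, 6.2)
  expr <- expression_table(genes$id, vals)
  res <- bound_vs_unbound_expression(genes, peaks, expr)
  want <- oracle_welch(vals[c(1, 3, 5)], vals[-c(1, 3, 5)])
  expect_equal(res$t, want$t, tolerance = 1e-10)
  expect_equal(res$df, want$df, tolerance = 1e-10)
  expect_equal(res$p_value, want$p, tolerance = 1e-10)
  expect_equal(res$n_bound, 3)

  # identical distributions in both groups: t = 0, p = 1
  expr2 <- expression_table(genes$id, rep(c(5, 7), 5))
  peaks2 <- data.frame(chrom = "chr1", center = genes$tss[c(1, 2)] - 100)
  res2 <- bound_vs_unbound_expression(genes, peaks2, expr2)
  expect_equal(res2$t, 0, tolerance = 1e-12)
  expect_equal(res2$p_value, 1, tolerance = 1e-12)

  expect_error(bound_vs_unbound_expression(genes, peaks[0, ], expr),
               "nonempty")
})

test_that("binding is strand-aware and confined to the upstream window", {
  g <- genome_table("chr1", 1e6)
  genes <- validate_genes_public(data.frame(
    id = c("plus", "minus"), chrom = "chr1",
    tss = c(500000, 500000 + 100000), tes = c(520000, 580000),
    strand = c("+", "-")))
  # peak 3 kb before each TSS in transcription direction
  up_plus <- data.frame(chrom = "chr1", center = 497000)
  up_minus <- data.frame(chrom = "chr1", center = 603000)
  down <- data.frame(chrom = "chr1", center = 503000)
  expect_equal(bound_gene_ids_public(genes, up_plus), "plus")
  expect_equal(bound_gene_ids_public(genes, up_minus), "minus")
  expect_equal(length(bound_gene_ids_public(genes, down)), 0)
})

test_that("a planted expression shift between bound and unbound is recovered", {
  set.seed(61)
  g <- genome_table("chr1", 5e7)
  n <- 2000
  # grid spacing ~12.5 kb keeps each peak inside exactly one upstream window
  tss <- sort(sample(seq(1e5, 5e7 - 1e5, length.out = 4000), n))
  genes <- validate_genes_public(data.frame(
    id = sprintf("g%04d", 1:n), chrom = "chr1", tss = tss, tes = tss + 15000,
    strand = "+"))
  bound <- sort(sample(n, 400))
  peaks <- data.frame(chrom = "chr1", center = tss[bound] - 2500)
  vals <- rnorm(n, 5.8, 1.5)
  vals[bound] <- vals[bound] + 0.8
  expr <- expression_table(genes$id, vals)
  res <- bound_vs_unbound_expression(genes, peaks, expr)
  expect_lt(abs((res$mean_bound - res$mean_unbound) - 0.8), 0.1)
  expect_lt(res$p_value, 1e-10)
})

test_that("site densities per gene class track planted enrichment", {
  set.seed(62)
  G <- 2e7
  g <- genome_table("chr1", G)
  n <- 300
  # regular spacing (~65 kb) so gene-plus-flank spans never overlap
  tss <- round(seq(2e5, G - 2e5, length.out = n))
  genes <- validate_genes_public(data.frame(
    id = sprintf("g%03d", 1:n), chrom = "chr1", tss = tss, tes = tss + 20000,
    strand = "+"))
  up_idx <- sort(sample(n, 150))
  classes <- list(up = genes$id[up_idx], non = genes$id[-up_idx])
  # plant twice the site density in "up" gene spans
  mk_sites <- function(idx, per_gene) {
    do.call(rbind, lapply(idx, function(i) data.frame(
      chrom = "chr1",
      pos = sample(seq(genes$tss[i], genes$tes[i]), per_gene))))
  }
  sites <- rbind(mk_sites(up_idx, 8), mk_sites(setdiff(1:n, up_idx), 4))
  dens <- site_density_by_gene_class(sites, NULL, classes, genes, g)
  ratio <- dens$predicted_per_mb[dens$class == "up"] /
    dens$predicted_per_mb[dens$class == "non"]
  expect_lt(abs(ratio - 2), 0.2)

  # empty classes are omitted with a warning; order does not matter
  expect_warning(
    d2 <- site_density_by_gene_class(sites, NULL,
                                     list(up = classes$up, empty = character()),
                                     genes, g),
    "empty")
  expect_false("empty" %in% d2$class)
  d3 <- site_density_by_gene_class(sites, NULL, classes,
                                   genes[sample(nrow(genes)), ], g)
  expect_equal(d3[d3$class == "up", "predicted_per_mb"],
               dens[dens$class == "up", "predicted_per_mb"])
})
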