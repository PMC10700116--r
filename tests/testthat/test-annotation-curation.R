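test_that("interval overlap uses 1-based inclusive arithmetic", {
  a <- data.frame(start = c(1, 1, 5), end = c(10, 10, 14))
  b1 <- data.frame(start = 10, end = 20)
  expect_equal(intervalOverlap(a[1, ], b1)$overlap_bp, 1L)
  b2 <- data.frame(start = 11, end = 20)
  expect_equal(intervalOverlap(a[2, ], b2)$overlap_bp, 0L)
  b3 <- data.frame(start = 1, end = 100)
  ov <- intervalOverlap(a[3, ], b3)
  expect_equal(ov$overlap_bp, 10L)
  expect_equal(ov$fraction, 1.0)
  expect_error(intervalOverlap(data.frame(start = 5, end = 2), b3),
               "end < start")
})

# a compact two-contig scene for the rescue rules
rescueScene <- function() {
  seqlen <- c(c1 = 10000L, c2 = 10000L)
  masked <- exonGR(list(gene = "M1", contig = "c1",
                        exons = cbind(1000, 1500)),
                   list(gene = "M2", contig = "c2",
                        exons = cbind(2000, 2400)), seqlen = seqlen)
  unmasked <- exonGR(
    list(gene = "U_ok", contig = "c1",    # all four criteria pass
         exons = cbind(c(3000, 3500), c(3200, 3700))),
    list(gene = "U_ovl", contig = "c1",   # 1 bp overlap with M1
         exons = cbind(1500, 1900)),
    list(gene = "U_weak", contig = "c2",  # e-value too large
         exons = cbind(5000, 5400)),
    list(gene = "U_rep", contig = "c2",   # sits on a classified repeat
         exons = cbind(7000, 7400)),
    list(gene = "U_simp", contig = "c1",  # one exon 51% simple repeat
         exons = cbind(c(6000, 7000), c(6099, 7099))),
    seqlen = seqlen)
  blast <- data.frame(
    query_id = c("U_ok", "U_ovl", "U_weak", "U_rep", "U_simp"),
    evalue = c(1e-4, 1e-9, 1e-2, 1e-9, 1e-9))
  repeats <- GenomicRanges::GRanges("c2", IRanges::IRanges(7100, 7300),
                                    repeat_class = "LINE")
  # 51 of U_simp's first 100 bp exon; 40 of U_ok's first exon (201 bp)
  simple <- GenomicRanges::GRanges(
    "c1", IRanges::IRanges(c(6000, 3000), c(6050, 3039)),
    repeat_class = "Simple_repeat")
  list(masked = masked, unmasked = unmasked, blast = blast,
       repeats = repeats, simple = simple)
}

test_that("unmasked-model rescue applies all four criteria", {
  s <- rescueScene()
  merged <- rescueUnmaskedModels(s$masked, s$unmasked, s$blast,
                                 s$repeats, s$simple)
  rescued <- unique(merged$gene_id[merged$source_run == "unmasked"])
  expect_equal(rescued, "U_ok")
  # merged set contains every masked gene
  expect_true(all(c("M1", "M2") %in% merged$gene_id))
})

test_that("rescue is order-independent and the summed-length switch works", {
  s <- rescueScene()
  ref <- rescueUnmaskedModels(s$masked, s$unmasked, s$blast,
                              s$repeats, s$simple)
  perm <- sample(length(s$unmasked))
  alt <- rescueUnmaskedModels(s$masked, s$unmasked[perm], s$blast,
                              s$repeats, s$simple)
  expect_equal(sort(unique(ref$gene_id)), sort(unique(alt$gene_id)))

  # summed over both 100 bp exons, U_simp is only 25.5% simple repeat
  sum_mode <- rescueUnmaskedModels(s$masked, s$unmasked, s$blast,
                                   s$repeats, s$simple, per_exon = FALSE)
  expect_true("U_simp" %in% sum_mode$gene_id)
})

test_that("high-confidence set needs two of three evidence sources", {
  ev <- data.frame(gene_id = c("a", "b", "c", "d"),
                   has_rnaseq = c(TRUE, TRUE, TRUE, FALSE),
                   has_orthology = c(TRUE, FALSE, TRUE, FALSE),
                   has_function = c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(highConfidenceSet(ev), c("a", "c"))
})

test_that("evidence table joins sources over the gene universe", {
  ev <- evidenceTable(c("g1", "g2", "g3"), expressedGenes = "g1",
                      orthologGenes = c("g1", "g2"),
                      annotatedGenes = character(0))
  expect_equal(ev$has_rnaseq, c(TRUE, FALSE, FALSE))
  expect_equal(ev$has_orthology, c(TRUE, TRUE, FALSE))
  expect_false(any(ev$has_function))
  expect_warning(evidenceTable("g1", "g9", "g1", "g1"), "ignored")
})

test_that("annotation summary handles the degenerate single-gene case", {
  gr <- exonGR(list(gene = "g1", contig = "c1", exons = cbind(1, 100)))
  s <- summarizeAnnotation(gr)
  expect_equal(s$n_genes, 1L)
  expect_equal(s$mean_gene_length, 100)
  expect_equal(s$median_gene_length, 100)
  expect_equal(s$mean_exons_per_transcript, 1)
  expect_error(summarizeAnnotation(gr[0]), "empty")
})

test_that("summary medians and percentages follow printed-table conventions", {
  # even-sized list: median = mean of the central pair
  gr <- exonGR(list(gene = "g1", contig = "c1", exons = cbind(1, 100)),
               list(gene = "g2", contig = "c1", exons = cbind(500, 799)),
               list(gene = "g3", contig = "c1", exons = cbind(2000, 2499)),
               list(gene = "g4", contig = "c1", exons = cbind(5000, 5999)))
  s <- summarizeAnnotation(gr)
  expect_equal(s$median_gene_length, (300 + 500) / 2)
  ev <- data.frame(gene_id = paste0("g", 1:4),
                   has_rnaseq = c(TRUE, TRUE, TRUE, FALSE),
                   has_orthology = rep(FALSE, 4),
                   has_function = c(TRUE, FALSE, FALSE, FALSE))
  s2 <- summarizeAnnotation(gr, ev)
  expect_equal(s2$support$percent[s2$support$source == "rnaseq"], 75)
  expect_equal(s2$support$percent[s2$support$source == "functional"], 25)
})
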