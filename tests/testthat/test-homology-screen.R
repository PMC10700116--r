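test_that("normalized bitscore is the self-score ratio, clamped to [0, 1]", {
  expect_equal(normalizedBitscore(100, 200), 0.5)
  expect_equal(normalizedBitscore(200, 200), 1.0)
  expect_equal(normalizedBitscore(210, 200), 1.0)
  expect_equal(normalizedBitscore(c(50, 250), 200), c(0.25, 1))
  expect_error(normalizedBitscore(100, 0), "self")
  expect_error(normalizedBitscore(100, -5), "self")
})

test_that("alienIndex computes AI = nbsO - nbsM with the skip rule", {
  # best non-metazoan 0.9, best metazoan (non-skip) 0.2
  h <- makeHits("g1", c("b1", "m1"), c(180, 40),
                c(LIN["bact"], LIN["met"]))
  r <- alienIndex(h)
  expect_equal(r$nbsO, 0.9)
  expect_equal(r$nbsM, 0.2)
  expect_equal(r$AI, 0.7)
  expect_equal(r$n_hits, 2L)
  expect_equal(r$top_outgroup_subject, "b1")

  # only skip-lineage hits: both sides empty, AI = 0
  h2 <- makeHits("g2", c("p1", "p2"), c(190, 150),
                 rep(LIN["skip"], 2))
  r2 <- alienIndex(h2)
  expect_equal(c(r2$nbsO, r2$nbsM, r2$AI), c(0, 0, 0))

  # no non-metazoan hits, best metazoan 0.6
  h3 <- makeHits("g3", "m1", 120, LIN["met"])
  expect_equal(alienIndex(h3)$AI, -0.6)

  expect_error(alienIndex(h3[0, ]), "empty")
  expect_error(alienIndex(h3[-1, ]), "self-hit")
})

test_that("per-subject HSP collapse keeps the best HSP deterministically", {
  # two HSPs to the same subject; the better one defines the ranking
  h <- makeHits("g1", c("b1", "b1", "m1"), c(100, 160, 40),
                c(LIN["bact"], LIN["bact"], LIN["met"]))
  r <- alienIndex(h)
  expect_equal(r$nbsO, 0.8)
  expect_equal(r$n_hits, 2L)  # subjects, not HSPs
})

test_that("AI stays in [-1, 1], equals nbsO - nbsM, and responds to hit deletion", {
  hits <- randomHitTable(30, seed = 42)
  res <- aiTable(computeAlienIndex(hits))
  expect_true(all(res$AI >= -1 & res$AI <= 1))
  expect_equal(res$AI, res$nbsO - res$nbsM, tolerance = 1e-15)

  labs <- strsplit(hits$lineage, ";", fixed = TRUE)
  inRec <- vapply(labs, function(l) "Metazoa" %in% l, logical(1))
  isSelf <- hits$subject_id == hits$query_id
  # deleting all non-recipient hits forces AI <= 0
  onlyRec <- hits[inRec | isSelf, ]
  resR <- aiTable(computeAlienIndex(onlyRec))
  expect_true(all(resR$AI <= 0))
  # deleting all recipient (non-skip) hits forces AI >= 0
  inSkip <- vapply(labs, function(l) "Placobranchoidea" %in% l, logical(1))
  noRec <- hits[!(inRec & !inSkip) | isSelf, ]
  resO <- aiTable(computeAlienIndex(noRec))
  expect_true(all(resO$AI >= 0))
})

test_that("screen matches a brute-force oracle that skips the HSP collapse", {
  for (seed in 1:5) {
    hits <- randomHitTable(sample(5:20, 1), seed = seed)
    mine <- aiTable(computeAlienIndex(hits))
    oracle <- bruteAI(hits)
    expect_equal(mine$AI, oracle$AI, tolerance = 1e-12)
  }
})

test_that("contamination flagging applies both contig rules", {
  gm <- data.frame(gene_id = paste0("g", 1:8),
                   contig_id = rep(c("c1", "c2", "c3"), c(2, 4, 2)))
  ai <- data.frame(gene_id = paste0("g", 1:8),
                   AI = c(0.2, 0.5,             # c1: min > 0  -> rule 1
                          -0.5, 0.3, 0.4, 0.2,  # c2: 3/4 > 0.1 -> rule 2
                          -0.5, 0.05))          # c3: clean
  v <- flagContaminantContigs(ai, gm)
  expect_equal(v$status[v$contig_id == "c1"], "bacterial_contaminant")
  expect_equal(v$status[v$contig_id == "c2"], "bacterial_contaminant")
  expect_equal(v$status[v$contig_id == "c3"], "nuclear")
  expect_match(v$evidence[v$contig_id == "c1"], "min_ai_gt_0")
  expect_match(v$evidence[v$contig_id == "c2"], "half_genes")
  expect_equal(v$evidence[v$contig_id == "c3"], "")
  expect_error(flagContaminantContigs(ai, gm[-1, ]), "not mapped")
})

test_that("raising any single gene's AI never unflags its contig", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(1:6, 1)
    ai <- data.frame(gene_id = paste0("g", seq_len(n)),
                     AI = round(runif(n, -1, 1), 2))
    gm <- data.frame(gene_id = ai$gene_id, contig_id = "c1")
    before <- flagContaminantContigs(ai, gm)$status
    if (before != "bacterial_contaminant") next
    i <- sample(n, 1)
    ai$AI[i] <- min(1, ai$AI[i] + runif(1, 0, 1 - ai$AI[i]))
    after <- flagContaminantContigs(ai, gm)$status
    expect_equal(after, "bacterial_contaminant")
  }
})

test_that("HGT candidate filter enforces AI, hit count, and contig status", {
  rec <- data.frame(gene_id = c("a", "b", "c", "d"),
                    nbsO = c(0.2, 0.2, 0.15, 0.3),
                    nbsM = c(0.05, 0.05, 0.05, 0.05),
                    AI = c(0.15, 0.15, 0.10, 0.25),
                    n_hits = c(60L, 49L, 100L, 80L))
  gm <- data.frame(gene_id = c("a", "b", "c", "d"),
                   contig_id = c("c1", "c1", "c1", "cBad"))
  kept <- filterHgtCandidates(rec, contaminantContigs = "cBad",
                              geneMap = gm)
  expect_equal(kept$gene_id, "a")   # b: too few hits; c: AI not > 0.1;
                                    # d: on a flagged contig
  expect_equal(filterHgtCandidates(rec)$gene_id, c("a", "d"))
})

test_that("organelle flagging needs >= 2 significant hits per contig", {
  h <- data.frame(
    contig_id = c("k1", "k1", "m1", "n1", "n2", "n2"),
    evalue = c(1e-6, 1e-8, 1e-20, 1e-20, 1e-4, 1e-4),
    organelle = c("kleptoplast", "kleptoplast", "mitochondrial",
                  "mitochondrial", "mitochondrial", "mitochondrial"))
  v <- flagOrganelleContigs(h)
  expect_equal(v$status[v$contig_id == "k1"], "kleptoplast")
  expect_equal(v$status[v$contig_id == "m1"], "nuclear")  # single hit
  expect_equal(v$status[v$contig_id == "n1"], "nuclear")
  expect_equal(v$status[v$contig_id == "n2"], "nuclear")  # e > 1e-5
  expect_error(flagOrganelleContigs(transform(h, organelle = "plastid")),
               "unknown organelle")
})
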