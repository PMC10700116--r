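test_that("length-scaled TPM normalizes uniformly and survives zero columns", {
  cts <- matrix(10, 4, 3, dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  lst <- lengthScaledTPM(cts, efflen = rep(500, 4))
  expect_true(all(abs(lst$tpm - 250000) < 1e-9))

  cts[, 2] <- 0
  lst2 <- lengthScaledTPM(cts, efflen = rep(500, 4))
  expect_true(all(lst2$tpm[, 2] == 0))
  expect_true(all(is.finite(lst2$lengthScaled)))
  expect_error(lengthScaledTPM(cts, efflen = c(0, 1, 1, 1)), "length")
})

test_that("TPM columns sum to 1e6 and length-scaled columns to library size", {
  set.seed(11)
  cts <- matrix(rpois(200, 80), 20, 10)
  el <- matrix(runif(200, 300, 3000), 20, 10)
  lst <- lengthScaledTPM(cts, el)
  expect_equal(unname(colSums(lst$tpm)), rep(1e6, 10), tolerance = 1e-9)
  expect_equal(colSums(lst$lengthScaled), colSums(cts), tolerance = 1e-9)
})

test_that("length-scaled TPM matches a straight-line two-step re-derivation", {
  set.seed(5)
  cts <- matrix(rpois(60, 50), 12, 5)
  el <- matrix(runif(60, 200, 2000), 12, 5)
  lst <- lengthScaledTPM(cts, el)
  # independent re-derivation, written step by step
  ref_tpm <- matrix(0, 12, 5)
  for (j in 1:5) {
    r <- cts[, j] / el[, j]
    ref_tpm[, j] <- r / sum(r) * 1e6
  }
  ref_cfa <- ref_tpm * rowMeans(el)
  for (j in 1:5)
    ref_cfa[, j] <- ref_cfa[, j] * sum(cts[, j]) / sum(ref_cfa[, j])
  expect_equal(lst$tpm, ref_tpm, tolerance = 1e-9)
  expect_equal(lst$lengthScaled, ref_cfa, tolerance = 1e-9)
})

test_that("stage expression averages replicates and honours the comparator", {
  m <- rbind(g1 = c(0.5, 1.5, 0.5, 0, 0, 0),
             g2 = c(0, 0, 0, 0, 0, 0),
             g3 = c(1, 1, 1, 2, 2, 2))
  st <- rep(c("egg", "juvenile"), each = 3)
  se <- stageExpression(m, st)
  expect_equal(unname(se$mean["g1", "egg"]), 0.8333333, tolerance = 1e-6)
  expect_false(se$expressed["g1", "egg"])
  expect_false(any(se$expressed["g2", ]))
  # mean exactly 1.0: expressed under >=, not under >
  expect_true(se$expressed["g3", "egg"])
  se2 <- stageExpression(m, st, comparator = ">")
  expect_false(se2$expressed["g3", "egg"])
  expect_error(stageExpression(m, c(st[-1], NA)), "mapped")
})

test_that("expression intersections partition the gene set", {
  set.seed(21)
  ex <- matrix(runif(400) > 0.5, 100, 4,
               dimnames = list(NULL, c("egg", "veliger", "larva",
                                       "juvenile")))
  inter <- expressionIntersections(ex)
  expect_equal(sum(inter$n), 100L)
  expect_equal(nrow(inter), 16L)
  # brute-force enumeration gene by gene
  for (i in sample(nrow(inter), 6)) {
    mask <- rep(TRUE, 100)
    for (s in colnames(ex))
      mask <- mask & (ex[, s] == inter[[s]][i])
    expect_equal(inter$n[i], sum(mask))
  }
  # a gene expressed only in juveniles lands in the {juvenile} subset
  one <- matrix(c(FALSE, FALSE, FALSE, TRUE), 1,
                dimnames = list(NULL, colnames(ex)))
  i1 <- expressionIntersections(one)
  expect_equal(i1$n[i1$subset == "juvenile"], 1L)
  zero <- matrix(FALSE, 3, 4, dimnames = list(NULL, colnames(ex)))
  i0 <- expressionIntersections(zero)
  expect_equal(i0$n[i0$subset == "none"], 3L)
})

test_that("TMM factors are 1 for identical or purely depth-scaled columns", {
  set.seed(3)
  y <- matrix(rpois(400, 100), 200, 2)
  y[, 2] <- y[, 1]
  expect_equal(tmmFactors(y), c(1, 1))
  y[, 2] <- 2L * y[, 1]
  expect_equal(tmmFactors(y), c(1, 1), tolerance = 1e-12)
  expect_error(tmmFactors(y[, 1, drop = FALSE]), "2 samples")
  y0 <- y; y0[, 2] <- 0L
  expect_error(tmmFactors(y0), "all-zero")
})

test_that("TMM geometric mean is 1 and factors track edgeR closely", {
  skip_if_not_installed("edgeR")
  set.seed(9)
  n <- 2000
  mu <- rexp(n, 1 / 200)
  y <- cbind(rpois(n, mu), rpois(n, mu), rpois(n, mu))
  # sample 3 carries a composition bias: 5% of genes grossly inflated
  hot <- sample(n, n * 0.05)
  y[hot, 3] <- y[hot, 3] * 8L
  f <- tmmFactors(y)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  ref <- edgeR::calcNormFactors(y, method = "TMM")
  expect_equal(f, ref, tolerance = 0.02)
})

test_that("NB exact test is symmetric and centred", {
  y <- c(30, 40, 50)
  expect_equal(nbExactTest(y, y, dispersion = 0.3), 1)
  yA <- c(10, 20, 15); yB <- c(60, 75, 60, 70)
  p1 <- nbExactTest(yA, yB, dispersion = 0.1)
  p2 <- nbExactTest(yB, yA, libsizes = rep(1, 7), dispersion = 0.1)
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_error(nbExactTest(yA, yB, dispersion = -1), ">= 0")
  expect_error(nbExactTest(c(-1, 2), yB), "negative")
})

test_that("at dispersion zero the exact test equals the binomial oracle", {
  set.seed(17)
  for (rep in 1:25) {
    nA <- sample(2:4, 1); nB <- sample(2:5, 1)
    yA <- rpois(nA, sample(5:25, 1))
    yB <- rpois(nB, sample(5:25, 1))
    t <- sum(yA) + sum(yB)
    if (t == 0 || t > 200) next
    mine <- nbExactTest(yA, yB, dispersion = 0)
    oracle <- bruteBinomDoubleTail(sum(yA), t, nA / (nA + nB))
    expect_equal(mine, oracle, tolerance = 1e-9)
  }
})

test_that("null exact-test p-values are super-uniform at phi = 0.2", {
  set.seed(23)
  nGenes <- 10000
  means <- matrix(100, nGenes, 12)
  cts <- simulateNBCounts(means, 0.2, seed = 23)
  disp <- rep(0.2, nGenes)
  p <- vapply(seq_len(nGenes), function(i)
    nbExactTest(cts[i, 1:3], cts[i, 4:12], dispersion = 0.2),
    numeric(1))
  expect_lte(mean(p < 0.05), 0.07)
})

test_that("moment dispersion estimates recover the simulation truth", {
  grp <- rep(c("a", "b"), each = 3)
  means <- matrix(exp(runif(2000, log(20), log(500))), 2000, 6)
  cts0 <- simulateNBCounts(means, 0, seed = 31)
  expect_lt(estimateDispersion(cts0, grp)[1], 0.02)
  cts4 <- simulateNBCounts(means, 0.4, seed = 32)
  phi4 <- estimateDispersion(cts4, grp)[1]
  expect_gt(phi4, 0.3); expect_lt(phi4, 0.5)
  # identical replicate columns: estimate floored at 0
  same <- cbind(cts0[, 1], cts0[, 1], cts0[, 1])
  expect_equal(estimateDispersion(same, rep("a", 3))[1], 0)
  expect_error(estimateDispersion(cts0[, 1, drop = FALSE], "a"),
               "replicates")
})

test_that("trended dispersion varies smoothly with abundance", {
  set.seed(41)
  mu <- exp(runif(3000, log(10), log(1000)))
  phiTrue <- 0.6 - 0.1 * (log(mu) - log(10)) / (log(1000) - log(10)) * 4
  phiTrue <- pmax(phiTrue, 0.05)
  cts <- sapply(1:6, function(j) rnbinom(3000, mu = mu, size = 1 / phiTrue))
  d <- estimateDispersion(cts, rep("a", 6), mode = "trended")
  lowAb <- mu < 30; highAb <- mu > 300
  expect_gt(mean(d[lowAb]), mean(d[highAb]))
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(13)
  for (n in c(1, 7, 100, 1000)) {
    p <- runif(n)
    expect_equal(bhAdjust(p), bruteBH(p), tolerance = 1e-12)
  }
})

test_that("DEG calls respect the fold-change and FDR thresholds jointly", {
  set.seed(19)
  sc <- nullStageCounts(nGenes = 80, mean = 120, phi = 0.05, seed = 19)
  # spike 10 juvenile-upregulated genes at log2FC = 3
  cts <- SummarizedExperiment::assay(sc, "counts")
  juv <- stageOf(sc) == "juvenile"
  cts[1:10, juv] <- cts[1:10, juv] * 8L
  sc2 <- StageCounts(cts, effLengths(sc), stageOf(sc))
  de <- callDEGs(sc2)
  expect_equal(de$is_deg, de$log2fc > 2 & de$fdr < 0.01)
  expect_true(all(rownames(cts)[1:10] %in% de$gene_id[de$is_deg]))
  # genes failing the expression filter are excluded before testing
  cts[11, ] <- 0L
  sc3 <- StageCounts(cts, effLengths(sc), stageOf(sc))
  de3 <- callDEGs(sc3)
  expect_false(rownames(cts)[11] %in% de3$gene_id)
  expect_true(rownames(cts)[11] %in% attr(de3, "filtered_out"))
  # per-stage contrast mode returns one table per unfed stage
  perStage <- callDEGs(sc2, perStage = TRUE)
  expect_setequal(names(perStage), c("egg", "veliger", "larva"))
})
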