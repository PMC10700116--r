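# shared in-code fixtures and independent oracles

# minimal hit rows for one query gene
makeHits <- function(gene, subjects, bitscores, lineages,
                     evalues = rep(1e-20, length(subjects)),
                     self_bitscore = 200) {
  rbind(
    data.frame(query_id = gene, subject_id = gene,
               bitscore = self_bitscore, evalue = 0,
               lineage = "root;Metazoa;Placobranchoidea",
               stringsAsFactors = FALSE),
    data.frame(query_id = gene, subject_id = subjects,
               bitscore = bitscores, evalue = evalues,
               lineage = lineages, stringsAsFactors = FALSE))
}

LIN <- c(met = "root;Metazoa;Gastropoda",
         skip = "root;Metazoa;Placobranchoidea",
         bact = "root;Bacteria;Proteobacteria",
         vir = "root;Viruses;Riboviria")

# random multi-gene hit table with genes spread over contigs
randomHitTable <- function(nGenes, seed) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nGenes), function(i) {
    g <- sprintf("g%03d", i)
    n <- sample(1:8, 1)
    makeHits(g, sprintf("s%03d_%d", i, seq_len(n)),
             bitscores = round(runif(n, 1, 240), 1),
             lineages = sample(unname(LIN), n, replace = TRUE),
             evalues = signif(10^runif(n, -80, -2), 3))
  }))
}

# brute-force Alien Index over ALL hits (no per-subject HSP collapse):
# independent oracle for the screen
bruteAI <- function(hits, recipient = "Metazoa",
                    skip = "Placobranchoidea") {
  out <- lapply(split(hits, hits$query_id), function(h) {
    self <- h$subject_id == h$query_id
    sb <- max(h$bitscore[self])
    h <- h[!self, , drop = FALSE]
    labs <- strsplit(h$lineage, ";", fixed = TRUE)
    inSkip <- vapply(labs, function(l) skip %in% l, logical(1))
    inRec <- vapply(labs, function(l) recipient %in% l, logical(1))
    nbs <- pmin(1, h$bitscore / sb)
    nbsO <- if (any(!inRec & !inSkip)) max(nbs[!inRec & !inSkip]) else 0
    nbsM <- if (any(inRec & !inSkip)) max(nbs[inRec & !inSkip]) else 0
    data.frame(gene_id = h$query_id[1], AI = nbsO - nbsM)
  })
  df <- do.call(rbind, out)
  df[order(df$gene_id), , drop = FALSE]
}

# hand-rolled BH step-up, straight from the definition
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

# exact conditional binomial double-tail p-value by direct enumeration
bruteBinomDoubleTail <- function(a, t, prop) {
  f <- vapply(0:t, function(x)
    choose(t, x) * prop^x * (1 - prop)^(t - x), numeric(1))
  f <- f / sum(f)
  lower <- sum(f[0:a + 1L])
  upper <- sum(f[(a:t) + 1L])
  min(1, 2 * min(lower, upper))
}

# a small StageCounts with flat means; all stages identical in expectation
nullStageCounts <- function(nGenes = 50, mean = 100, phi = 0.1, seed = 1) {
  means <- matrix(mean, nGenes, 12,
                  dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                                  sprintf("s%02d", 1:12)))
  cts <- simulateNBCounts(means, phi, seed = seed)
  StageCounts(cts, efflen = rep(1000, nGenes),
              stage = rep(c("egg", "veliger", "larva", "juvenile"),
                          each = 3))
}

# exon-level GRanges from a compact spec list(gene=, contig=, exons=matrix)
exonGR <- function(..., seqlen = NULL) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(contig = r$contig, start = r$exons[, 1], end = r$exons[, 2],
               gene_id = r$gene, stringsAsFactors = FALSE)
  }))
  gr <- GenomicRanges::GRanges(df$contig,
                               IRanges::IRanges(df$start, df$end),
                               strand = "+", gene_id = df$gene_id,
                               transcript_id = paste0(df$gene_id, ".t1"),
                               type = "exon")
  if (!is.null(seqlen)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlen)
    GenomeInfoDb::seqlengths(gr) <- seqlen
  }
  gr
}
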