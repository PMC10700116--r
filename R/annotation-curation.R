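#' @importFrom IRanges IRanges findOverlaps pintersect width
#' @importFrom GenomicRanges GRanges seqnames strand mcols mcols<- ranges
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Pairwise interval overlap (1-based inclusive)
#'
#' For every interval in \code{a}, the total bases shared with intervals in
#' \code{b} and the covered fraction of \code{a}.  Coordinates are 1-based
#' inclusive, so \code{[1,10]} vs \code{[10,20]} overlap by exactly 1 bp.
#' Book-ended intervals (\code{[1,10]} vs \code{[11,20]}) do not intersect.
#'
#' @param a,b data.frames with columns \code{start}, \code{end} (and
#'   optionally \code{seqnames}; if present in both, only intervals on the
#'   same sequence are compared).
#' @return data.frame, one row per row of \code{a}: \code{overlap_bp},
#'   \code{fraction} (overlap divided by the width of \code{a}).
#' @export
intervalOverlap <- function(a, b) {
    if (any(a$end < a$start) || any(b$end < b$start))
        stop("interval end < start")
    haveSeq <- "seqnames" %in% colnames(a) && "seqnames" %in% colnames(b)
    gra <- GRanges(if (haveSeq) a$seqnames else "seq",
                   IRanges(a$start, a$end))
    grb <- GRanges(if (haveSeq) b$seqnames else "seq",
                   IRanges(b$start, b$end))
    ov <- findOverlaps(gra, grb)
    shared <- width(pintersect(gra[queryHits(ov)], grb[subjectHits(ov)]))
    bp <- rep(0L, nrow(a))
    if (length(ov)) {
        agg <- tapply(shared, queryHits(ov), sum)
        bp[as.integer(names(agg))] <- as.integer(agg)
    }
    data.frame(overlap_bp = bp, fraction = bp / (a$end - a$start + 1L))
}

# gene spans (one range per gene) from an exon-level GRanges with $gene_id
.geneSpans <- function(exons) {
    stopifnot(is(exons, "GRanges"), "gene_id" %in% colnames(mcols(exons)))
    sp <- unlist(range(GenomicRanges::split(exons, exons$gene_id)))
    sp
}

#' Rescue unique gene models from an unmasked annotation run
#'
#' Repeat masking can swallow conserved multicopy gene families, so a second
#' annotation run on the unmasked assembly recovers them.  An unmasked gene
#' model is added to the merged set when it (1) shares zero bp with any
#' masked gene span, (2) has a significant protein homology hit
#' (e-value < \code{rescue_e}), (3) shares zero bp with any classified
#' repeat element, and (4) has no exon more than \code{simple_frac} of whose
#' length is covered by simple sequence repeats.
#'
#' @param masked,unmasked exon-level \code{GRanges} with a \code{gene_id}
#'   metadata column (and \code{transcript_id} if available).
#' @param blastHits data.frame with \code{query_id} (gene id of the unmasked
#'   model's protein) and \code{evalue}; the best (minimum) e-value per gene
#'   is used.
#' @param repeats \code{GRanges} of classified repeat elements (LINE, SINE,
#'   LTR, ...).
#' @param simpleRepeats \code{GRanges} of simple sequence repeats.
#' @param rescue_e e-value threshold, strict (default 1e-3).
#' @param simple_frac per-exon simple-repeat coverage above which the model
#'   is disqualified, strict (default 0.5).
#' @param per_exon if TRUE (default) the simple-repeat rule disqualifies on
#'   any single exon; if FALSE it is applied to the summed exon length.
#' @return exon-level \code{GRanges} of the merged set, with a
#'   \code{source_run} metadata column ("masked" or "unmasked"); rescued
#'   gene ids are those with \code{source_run == "unmasked"}.
#' @export
rescueUnmaskedModels <- function(masked, unmasked, blastHits, repeats,
                                 simpleRepeats, rescue_e = 1e-3,
                                 simple_frac = 0.5, per_exon = TRUE) {
    for (gr in list(masked, unmasked)) {
        sl <- GenomeInfoDb::seqlengths(gr)
        if (!all(is.na(sl))) {
            lim <- sl[as.character(seqnames(gr))]
            if (any(!is.na(lim) & GenomicRanges::end(gr) > lim))
                stop("gene model coordinate beyond contig end")
        }
    }
    maskedSpans <- .geneSpans(masked)
    uSpans <- .geneSpans(unmasked)

    # (1) zero-overlap with masked gene spans (either strand)
    ovM <- findOverlaps(uSpans, maskedSpans, ignore.strand = TRUE)
    unique_u <- setdiff(names(uSpans), names(uSpans)[queryHits(ovM)])

    # (2) significant homology support
    bestE <- tapply(blastHits$evalue, blastHits$query_id, min)
    hasBlast <- names(bestE)[bestE < rescue_e]

    # (3) zero-overlap with classified repeats
    ovR <- findOverlaps(uSpans, repeats, ignore.strand = TRUE)
    noRepeat <- setdiff(names(uSpans), names(uSpans)[queryHits(ovR)])

    # (4) simple-repeat exon coverage
    uexon <- unmasked
    covs <- rep(0, length(uexon))
    ovS <- findOverlaps(uexon, simpleRepeats, ignore.strand = TRUE)
    if (length(ovS)) {
        # per-exon covered bp: reduce per-exon fragments to avoid
        # double-counting overlapping simple repeats
        byExon <- split(subjectHits(ovS), queryHits(ovS))
        for (k in names(byExon)) {
            i <- as.integer(k)
            frag <- GenomicRanges::reduce(GenomicRanges::restrict(
                GenomicRanges::granges(simpleRepeats[byExon[[k]]]),
                start = GenomicRanges::start(uexon[i]),
                end = GenomicRanges::end(uexon[i])))
            covs[i] <- sum(width(frag))
        }
    }
    frac <- covs / width(uexon)
    if (per_exon) {
        badGene <- unique(uexon$gene_id[frac > simple_frac])
    } else {
        tot <- tapply(covs, uexon$gene_id, sum) /
            tapply(width(uexon), uexon$gene_id, sum)
        badGene <- names(tot)[tot > simple_frac]
    }
    simpleOK <- setdiff(unique(unmasked$gene_id), badGene)

    rescued <- Reduce(intersect, list(unique_u, hasBlast, noRepeat, simpleOK))
    rescued <- sort(rescued)

    m <- masked
    mcols(m)$source_run <- "masked"
    u <- unmasked[unmasked$gene_id %in% rescued]
    if (length(u)) mcols(u)$source_run <- "unmasked"
    common <- intersect(colnames(mcols(m)), colnames(mcols(u)))
    out <- c(m[, common], u[, common])
    sort(out)
}

#' High-confidence gene set from an evidence table
#'
#' A gene enters the high-confidence set when at least two of its three
#' evidence sources are present: expression support (average length-scaled
#' TPM at/above threshold in at least one stage), orthology support
#' (orthogroup shared with another species), and a functional annotation.
#'
#' @param evidence data.frame with columns \code{gene_id},
#'   \code{has_rnaseq}, \code{has_orthology}, \code{has_function}.
#' @param min_sources minimum number of supporting sources (default 2).
#' @return character vector of gene ids, sorted.
#' @export
highConfidenceSet <- function(evidence, min_sources = 2L) {
    need <- c("gene_id", "has_rnaseq", "has_orthology", "has_function")
    stopifnot(all(need %in% colnames(evidence)))
    nsupport <- rowSums(evidence[, c("has_rnaseq", "has_orthology",
                                     "has_function")])
    sort(evidence$gene_id[nsupport >= min_sources])
}

#' Assemble the per-gene evidence table
#'
#' Joins the three evidence sources by gene id over a declared gene
#' universe.  Genes missing from a source are recorded as unsupported by it
#' (with a warning for genes absent from every source).
#'
#' @param genes character vector: the gene universe (merged gene set).
#' @param expressedGenes gene ids with expression support.
#' @param orthologGenes gene ids assigned to a multi-species orthogroup.
#' @param annotatedGenes gene ids with at least one functional annotation.
#' @return data.frame \code{gene_id}, \code{has_rnaseq},
#'   \code{has_orthology}, \code{has_function}.
#' @export
evidenceTable <- function(genes, expressedGenes, orthologGenes,
                          annotatedGenes) {
    genes <- sort(unique(genes))
    ev <- data.frame(gene_id = genes,
                     has_rnaseq = genes %in% expressedGenes,
                     has_orthology = genes %in% orthologGenes,
                     has_function = genes %in% annotatedGenes,
                     stringsAsFactors = FALSE)
    stray <- setdiff(c(expressedGenes, orthologGenes, annotatedGenes), genes)
    if (length(stray))
        warning(length(stray),
                " evidence gene(s) not in the gene universe were ignored")
    ev
}

#' Summary statistics for a gene-model set
#'
#' Computes the descriptive statistics a genome-report summary table prints:
#' gene and transcript counts, mean/median genomic gene length (span
#' including introns), mean/median exons per transcript, mean/median exon
#' length, and evidence-support counts with half-up two-decimal
#' percentages.
#'
#' @param models exon-level \code{GRanges} with \code{gene_id} and, if
#'   available, \code{transcript_id} metadata columns.
#' @param evidence optional evidence table (see [evidenceTable()]) restricted
#'   or matched to the same genes; evidence rows for other genes are ignored.
#' @return a list of class \code{"annotationSummary"} with fields
#'   \code{n_genes}, \code{n_transcripts}, \code{mean_gene_length},
#'   \code{median_gene_length}, \code{mean_exons_per_transcript},
#'   \code{median_exons_per_transcript}, \code{mean_exon_length},
#'   \code{median_exon_length}, and (with evidence) \code{support} --
#'   a data.frame of counts and percentages per evidence source.
#' @export
summarizeAnnotation <- function(models, evidence = NULL) {
    if (length(models) == 0L) stop("empty gene-model set")
    spans <- .geneSpans(models)
    ng <- length(spans)
    tx <- if ("transcript_id" %in% colnames(mcols(models)))
        models$transcript_id else models$gene_id
    exPerTx <- as.integer(table(tx))
    out <- list(
        n_genes = ng,
        n_transcripts = length(unique(tx)),
        mean_gene_length = roundHalfUp(mean(width(spans)), 2),
        median_gene_length = stats::median(width(spans)),
        mean_exons_per_transcript = roundHalfUp(mean(exPerTx), 2),
        median_exons_per_transcript = stats::median(exPerTx),
        mean_exon_length = roundHalfUp(mean(width(models)), 2),
        median_exon_length = stats::median(width(models))
    )
    if (!is.null(evidence)) {
        ev <- evidence[evidence$gene_id %in% names(spans), , drop = FALSE]
        cnt <- c(rnaseq = sum(ev$has_rnaseq),
                 functional = sum(ev$has_function),
                 orthogroup = sum(ev$has_orthology))
        out$support <- data.frame(source = names(cnt),
                                  n = as.integer(cnt),
                                  percent = asPercent(as.numeric(cnt), ng),
                                  stringsAsFactors = FALSE)
    }
    class(out) <- "annotationSummary"
    out
}

#' @export
print.annotationSummary <- function(x, ...) {
    cat("Gene model summary\n")
    cat(sprintf("  No. protein-coding genes      %d\n", x$n_genes))
    cat(sprintf("  No. transcripts               %d\n", x$n_transcripts))
    cat(sprintf("  Mean gene length              %.2f bp\n", x$mean_gene_length))
    cat(sprintf("  Median gene length            %d bp\n", x$median_gene_length))
    cat(sprintf("  Mean no. exons per transcript %.2f\n",
                x$mean_exons_per_transcript))
    cat(sprintf("  Median no. exons per transcript %s\n",
                format(x$median_exons_per_transcript)))
    cat(sprintf("  Mean exon length              %.2f bp\n", x$mean_exon_length))
    cat(sprintf("  Median exon length            %d bp\n", x$median_exon_length))
    if (!is.null(x$support)) {
        for (i in seq_len(nrow(x$support)))
            cat(sprintf("  Genes supported by %-10s %d (%.2f%%)\n",
                        x$support$source[i], x$support$n[i],
                        x$support$percent[i]))
    }
    invisible(x)
}
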