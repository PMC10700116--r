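#' Normalized bitscore
#'
#' A hit's bitscore divided by the best bitscore achievable for the query,
#' i.e. the bitscore of the query aligned to itself.  Because a local
#' alignment to another sequence can occasionally edge past the self-score
#' (HSP trimming artifacts), the ratio is clamped to [0, 1].
#'
#' @param bitscore numeric, bitscore(s) of the hit under consideration.
#' @param self_bitscore numeric(1), bitscore of the query vs itself; must be
#'   positive (a missing self-hit is an error, not a zero).
#' @return numeric in [0, 1].
#' @examples
#' normalizedBitscore(100, 200)  # 0.5
#' normalizedBitscore(210, 200)  # clamped to 1
#' @export
normalizedBitscore <- function(bitscore, self_bitscore) {
    if (length(self_bitscore) != 1L || is.na(self_bitscore) ||
        self_bitscore <= 0)
        stop("self_bitscore must be a single positive value (self-hit missing?)")
    pmin(1, pmax(0, bitscore / self_bitscore))
}

# split "cellular;Metazoa;Homo sapiens" -> character vector of labels
.lineageLabels <- function(lineage) {
    strsplit(lineage, ";", fixed = TRUE)
}

# collapse to the single best HSP per subject: highest bitscore, ties broken
# by lower e-value then lexicographic subject id (deterministic)
.collapseBestHSP <- function(hits) {
    o <- order(hits$subject_id, -hits$bitscore, hits$evalue,
               method = "radix")
    h <- hits[o, , drop = FALSE]
    h[!duplicated(h$subject_id), , drop = FALSE]
}

#' Alien Index for one gene's hit list
#'
#' Computes \code{AI = nbsO - nbsM} for a single query gene from its protein
#' homology hits.  \code{nbsO} is the normalized bitscore of the best hit to
#' a lineage outside the recipient clade; \code{nbsM} the best hit within
#' the recipient clade, skipping the sublineage that contains the query
#' species itself (so close relatives cannot vouch for the gene).  Hits to
#' the skip lineage contribute to neither side.  A side with no qualifying
#' hit scores 0, so lineage-restricted genes get \code{AI = nbsO}.
#'
#' @param hits data.frame for one gene with columns \code{query_id},
#'   \code{subject_id}, \code{bitscore}, \code{evalue}, \code{lineage}
#'   (semicolon-joined root-to-species labels) and optionally \code{is_self}.
#'   Must contain the self-hit.  Multiple HSPs per subject are collapsed to
#'   the best-scoring one before ranking.
#' @param recipient character(1), recipient lineage label (default
#'   \code{"Metazoa"}).
#' @param skip character(1), self-containing sublineage to exclude
#'   (default \code{"Placobranchoidea"}).
#' @return one-row data.frame: \code{gene_id}, \code{nbsO}, \code{nbsM},
#'   \code{AI}, \code{n_hits} (subjects after HSP collapse, self excluded),
#'   \code{top_outgroup_subject}.
#' @examples
#' h <- data.frame(query_id = "g1",
#'                 subject_id = c("g1", "bact1", "snail1"),
#'                 bitscore = c(200, 180, 40), evalue = c(0, 1e-50, 1e-5),
#'                 lineage = c("cellular;Metazoa;Placobranchoidea;self",
#'                             "cellular;Bacteria;Proteobacteria",
#'                             "cellular;Metazoa;Gastropoda"))
#' alienIndex(h)  # AI = 0.9 - 0.2 = 0.7
#' @export
alienIndex <- function(hits, recipient = "Metazoa",
                       skip = "Placobranchoidea") {
    if (is.null(hits) || nrow(hits) == 0L)
        stop("empty hit list: cannot compute an Alien Index")
    gene <- unique(hits$query_id)
    if (length(gene) != 1L)
        stop("alienIndex() expects hits for exactly one query gene")
    selfmask <- if ("is_self" %in% colnames(hits)) {
        hits$is_self | hits$subject_id == hits$query_id
    } else hits$subject_id == hits$query_id
    if (!any(selfmask))
        stop(sprintf("no self-hit found for gene '%s'", gene))
    self_bs <- max(hits$bitscore[selfmask])

    h <- .collapseBestHSP(hits[!selfmask, , drop = FALSE])
    labs <- .lineageLabels(h$lineage)
    in_skip <- vapply(labs, function(l) skip %in% l, logical(1))
    in_recip <- vapply(labs, function(l) recipient %in% l, logical(1))

    h <- h[!in_skip, , drop = FALSE]
    in_recip <- in_recip[!in_skip]

    nbs <- normalizedBitscore(h$bitscore, self_bs)
    pick <- function(mask) if (any(mask)) max(nbs[mask]) else 0
    nbsO <- pick(!in_recip)
    nbsM <- pick(in_recip)
    top <- NA_character_
    if (any(!in_recip)) {
        cand <- which(!in_recip)
        top <- h$subject_id[cand[which.max(nbs[cand])]]
    }
    data.frame(gene_id = gene, nbsO = nbsO, nbsM = nbsM, AI = nbsO - nbsM,
               n_hits = nrow(h), top_outgroup_subject = top,
               stringsAsFactors = FALSE)
}

#' Alien Index screen over a full hit table
#'
#' Applies [alienIndex()] to every query gene in a homology hit table
#' (12-column BLAST tabular plus subject taxid/lineage columns).
#'
#' @param hits data.frame of hits for many genes (see [alienIndex()]).
#' @param recipient,skip lineage labels, see [alienIndex()].
#' @return an [AlienIndexResults-class] object, one record per query gene,
#'   ordered by gene id.
#' @export
computeAlienIndex <- function(hits, recipient = "Metazoa",
                              skip = "Placobranchoidea") {
    stopifnot(all(c("query_id", "subject_id", "bitscore", "evalue",
                    "lineage") %in% colnames(hits)))
    parts <- split(hits, hits$query_id)
    recs <- do.call(rbind, lapply(parts, alienIndex,
                                  recipient = recipient, skip = skip))
    recs <- recs[order(recs$gene_id), , drop = FALSE]
    rownames(recs) <- NULL
    new("AlienIndexResults", records = DataFrame(recs),
        recipient = recipient, skip = skip)
}

#' Flag bacterially contaminated contigs from per-gene AI scores
#'
#' A contig is flagged as bacterial contamination if the minimum AI over all
#' its genes exceeds 0, or if at least half of its genes have AI > 0.1.
#' Note the first rule flags single-gene contigs with any positive AI --
#' aggressive, but that is the screening rule as stated.
#'
#' @param ai an [AlienIndexResults-class] object or a data.frame with columns
#'   \code{gene_id} and \code{AI}.
#' @param geneMap data.frame with columns \code{gene_id}, \code{contig_id};
#'   every scored gene must map to exactly one contig.
#' @return data.frame with one row per contig: \code{contig_id},
#'   \code{status} ("bacterial_contaminant" or "nuclear"), \code{evidence}
#'   (rule name plus supporting gene ids; empty for nuclear contigs).
#' @export
flagContaminantContigs <- function(ai, geneMap) {
    rec <- if (is(ai, "AlienIndexResults")) aiTable(ai) else ai
    m <- match(rec$gene_id, geneMap$gene_id)
    if (anyNA(m))
        stop("gene(s) not mapped to any contig: ",
             paste(utils::head(rec$gene_id[is.na(m)], 5), collapse = ", "))
    contig <- geneMap$contig_id[m]
    out <- lapply(split(seq_len(nrow(rec)), contig), function(idx) {
        aiv <- rec$AI[idx]
        gid <- rec$gene_id[idx]
        rule1 <- min(aiv) > 0
        hi <- aiv > 0.1
        rule2 <- mean(hi) >= 0.5
        if (rule1 || rule2) {
            rule <- if (rule1) "min_ai_gt_0" else "half_genes_ai_gt_0.1"
            support <- if (rule1) gid else gid[hi]
            data.frame(status = "bacterial_contaminant",
                       evidence = paste0(rule, ":",
                                         paste(support, collapse = ",")),
                       stringsAsFactors = FALSE)
        } else {
            data.frame(status = "nuclear", evidence = "",
                       stringsAsFactors = FALSE)
        }
    })
    res <- do.call(rbind, out)
    res <- data.frame(contig_id = names(out), res, stringsAsFactors = FALSE)
    rownames(res) <- NULL
    res[order(res$contig_id), , drop = FALSE]
}

#' Filter Alien Index records to phylogenetically testable HGT candidates
#'
#' Keeps genes with \code{AI > min_ai} (strict), at least \code{min_hits}
#' database subjects, and not residing on a contamination-flagged contig.
#'
#' @param ai an [AlienIndexResults-class] object or its table.
#' @param contaminantContigs character vector of flagged contig ids.
#' @param geneMap data.frame \code{gene_id}, \code{contig_id} (only needed
#'   when \code{contaminantContigs} is non-empty).
#' @param min_ai strict lower AI bound (default 0.1).
#' @param min_hits minimum number of database subjects (default 50).
#' @return data.frame of retained AI records.
#' @export
filterHgtCandidates <- function(ai, contaminantContigs = character(),
                                geneMap = NULL, min_ai = 0.1,
                                min_hits = 50L) {
    rec <- if (is(ai, "AlienIndexResults")) aiTable(ai) else ai
    keep <- rec$AI > min_ai & rec$n_hits >= min_hits
    if (length(contaminantContigs) > 0L) {
        if (is.null(geneMap))
            stop("geneMap required to exclude genes on flagged contigs")
        contig <- geneMap$contig_id[match(rec$gene_id, geneMap$gene_id)]
        keep <- keep & !(contig %in% contaminantContigs)
    }
    out <- rec[keep & !is.na(keep), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Flag organelle-derived contigs from organellar-protein search hits
#'
#' Contigs with two or more significant hits (e-value at or below the
#' cutoff) to a mitochondrial or kleptoplast (chloroplast) protein set are
#' flagged as derived from that organelle.  When a contig qualifies for
#' both sets, the one with more qualifying hits wins (ties go to
#' mitochondrial, the rarer class).
#'
#' @param hits data.frame with columns \code{contig_id}, \code{evalue},
#'   \code{organelle} (one of "mitochondrial", "kleptoplast").
#' @param max_evalue significance cutoff (default 1e-5, inclusive).
#' @param min_hits minimum qualifying hits (default 2).
#' @return data.frame \code{contig_id}, \code{status} ("mitochondrial",
#'   "kleptoplast", or "nuclear"), \code{evidence} (qualifying hit counts).
#' @export
flagOrganelleContigs <- function(hits, max_evalue = 1e-5, min_hits = 2L) {
    stopifnot(all(c("contig_id", "evalue", "organelle") %in% colnames(hits)))
    bad <- setdiff(unique(hits$organelle), c("mitochondrial", "kleptoplast"))
    if (length(bad))
        stop("unknown organelle class(es): ", paste(bad, collapse = ", "))
    sig <- hits[hits$evalue <= max_evalue, , drop = FALSE]
    out <- lapply(split(sig, sig$contig_id), function(h) {
        nm <- sum(h$organelle == "mitochondrial")
        nk <- sum(h$organelle == "kleptoplast")
        status <- "nuclear"
        if (nm >= min_hits && nm >= nk) status <- "mitochondrial"
        else if (nk >= min_hits) status <- "kleptoplast"
        data.frame(status = status,
                   evidence = sprintf("mito_hits=%d;klepto_hits=%d", nm, nk),
                   stringsAsFactors = FALSE)
    })
    res <- data.frame(contig_id = names(out), do.call(rbind, out),
                      stringsAsFactors = FALSE)
    rownames(res) <- NULL
    # contigs present in the input but with no significant hits are nuclear
    rest <- setdiff(unique(hits$contig_id), res$contig_id)
    if (length(rest))
        res <- rbind(res, data.frame(contig_id = rest, status = "nuclear",
                                     evidence = "", stringsAsFactors = FALSE))
    res[order(res$contig_id), , drop = FALSE]
}
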