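#' Select the longest protein isoform per gene
#'
#' Orthology clustering uses one representative protein per gene: the
#' longest isoform, with ties broken by the lexicographically smallest
#' isoform id so the choice is deterministic.
#'
#' @param proteins an \code{AAStringSet} (or any named object with a
#'   \code{width}/\code{nchar}-able sequence) named by isoform id, or a
#'   data.frame with columns \code{isoform_id} and \code{length}.
#' @param geneOf named character vector mapping isoform id to gene id;
#'   every isoform must be mapped, every gene must have at least one.
#' @return for sequence input, the subset object with one entry per gene
#'   (named by isoform id); for data.frame input, a data.frame
#'   \code{gene_id}, \code{isoform_id}, \code{length}.
#' @export
selectLongestIsoform <- function(proteins, geneOf) {
    if (is.data.frame(proteins)) {
        ids <- proteins$isoform_id
        len <- proteins$length
    } else {
        ids <- names(proteins)
        len <- if (is(proteins, "XStringSet")) Biostrings::width(proteins)
               else nchar(proteins)
    }
    if (is.null(ids) || anyNA(geneOf[ids]))
        stop("every isoform must be named and mapped to a gene")
    gene <- geneOf[ids]
    o <- order(gene, -len, ids, method = "radix")
    pickIdx <- o[!duplicated(gene[o])]
    if (is.data.frame(proteins)) {
        out <- data.frame(gene_id = gene[pickIdx], isoform_id = ids[pickIdx],
                          length = len[pickIdx], stringsAsFactors = FALSE)
        rownames(out) <- NULL
        out[order(out$gene_id), , drop = FALSE]
    } else {
        proteins[pickIdx[order(gene[pickIdx])]]
    }
}

#' Classify orthogroup presence/absence patterns
#'
#' Given declared species roles (kleptoplastic ingroup vs non-kleptoplastic
#' outgroup), each orthogroup is classified by which species it contains:
#' \code{conserved_all} (present in every species), \code{klepto_specific}
#' (present in all kleptoplastic species and absent from every outgroup
#' species), \code{singleton} (exactly one species), otherwise
#' \code{other}.
#'
#' @param orthogroups data.frame, one row per orthogroup: column
#'   \code{og_id} plus one column per species holding comma-joined member
#'   gene ids ("" or NA when absent) -- the usual orthogroup-table layout.
#' @param kleptoplastic character vector of kleptoplastic species columns.
#' @param outgroup character vector of outgroup species columns.
#' @return data.frame \code{og_id}, \code{present_species} (comma-joined),
#'   \code{n_species}, \code{class}.
#' @export
classifyPatterns <- function(orthogroups, kleptoplastic, outgroup) {
    species <- c(kleptoplastic, outgroup)
    missing <- setdiff(species, colnames(orthogroups))
    if (length(missing))
        stop("species not in orthogroup table: ",
             paste(missing, collapse = ", "))
    extra <- setdiff(colnames(orthogroups), c("og_id", species))
    if (length(extra))
        stop("undeclared species column(s): ", paste(extra, collapse = ", "))
    pres <- sapply(species, function(s) {
        v <- orthogroups[[s]]
        !is.na(v) & nzchar(trimws(v))
    })
    if (is.null(dim(pres)))
        pres <- matrix(pres, nrow = 1, dimnames = list(NULL, species))
    nsp <- rowSums(pres)
    allK <- rowSums(pres[, kleptoplastic, drop = FALSE]) ==
        length(kleptoplastic)
    anyO <- rowSums(pres[, outgroup, drop = FALSE]) > 0
    cls <- ifelse(nsp == length(species), "conserved_all",
           ifelse(allK & !anyO, "klepto_specific",
           ifelse(nsp == 1, "singleton", "other")))
    data.frame(og_id = orthogroups$og_id,
               present_species = apply(pres, 1, function(z)
                   paste(species[z], collapse = ",")),
               n_species = nsp, class = cls, stringsAsFactors = FALSE)
}

#' Candidate genes: pattern-class members intersected with DEGs
#'
#' For each orthogroup pattern class, collects the focal species' genes in
#' orthogroups of that class and intersects them with the differentially
#' expressed gene set -- e.g. the kleptoplast-specific, fed-upregulated
#' candidates.
#'
#' @param patterns output of [classifyPatterns()].
#' @param orthogroups the orthogroup table the patterns came from.
#' @param focal focal species column name.
#' @param degs character vector of DEG gene ids in the focal species.
#' @return named list (by class) of sorted candidate gene id vectors.
#' @export
candidateGenes <- function(patterns, orthogroups, focal, degs) {
    stopifnot(focal %in% colnames(orthogroups))
    m <- match(patterns$og_id, orthogroups$og_id)
    memb <- orthogroups[[focal]][m]
    classes <- sort(unique(patterns$class))
    out <- lapply(classes, function(cl) {
        v <- memb[patterns$class == cl]
        v <- v[!is.na(v) & nzchar(v)]
        genes <- unique(trimws(unlist(strsplit(v, ",", fixed = TRUE))))
        sort(intersect(genes, degs))
    })
    names(out) <- classes
    out
}

#' Hypergeometric enrichment of functional terms
#'
#' Upper-tail hypergeometric test per term: with \code{N} background genes
#' of which \code{K} carry the term, and a study set of \code{n} genes of
#' which \code{k} carry it, \code{p = P(X >= k)}.  Terms absent from the
#' study set (k = 0) are not tested; p-values are BH-adjusted across the
#' tested terms.
#'
#' @param geneSet character vector, the study set (must be contained in
#'   \code{background}).
#' @param termMap data.frame with columns \code{gene_id}, \code{term}.
#' @param background character vector, the gene universe.
#' @return data.frame \code{term}, \code{k}, \code{K}, \code{n}, \code{N},
#'   \code{pvalue}, \code{fdr}, ordered by p-value.
#' @export
hypergeomEnrichment <- function(geneSet, termMap, background) {
    geneSet <- unique(geneSet)
    background <- unique(background)
    if (!all(geneSet %in% background))
        stop("gene set is not a subset of the background")
    tm <- termMap[termMap$gene_id %in% background, , drop = FALSE]
    tm <- unique(tm[, c("gene_id", "term")])
    N <- length(background)
    n <- length(geneSet)
    Kv <- table(tm$term)
    inSet <- tm$gene_id %in% geneSet
    kv <- table(factor(tm$term[inSet], levels = names(Kv)))
    keep <- kv > 0
    if (!any(keep))
        return(data.frame(term = character(), k = integer(), K = integer(),
                          n = integer(), N = integer(), pvalue = numeric(),
                          fdr = numeric(), stringsAsFactors = FALSE))
    k <- as.integer(kv[keep]); K <- as.integer(Kv[keep])
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    out <- data.frame(term = names(Kv)[keep], k = k, K = K, n = n, N = N,
                      pvalue = p, fdr = bhAdjust(p),
                      stringsAsFactors = FALSE)
    out <- out[order(out$pvalue, out$term), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Extract the region spanning a set of required domain profiles
#'
#' For a protein with domain-profile hits, returns the maximal region
#' covering every required profile: from the smallest start to the largest
#' end over their hits (1-based inclusive).  The region is returned only if
#' its length falls within \code{[min_len, max_len]}; proteins missing any
#' required profile, or with an out-of-range span, yield \code{NULL}.
#'
#' @param domainHits data.frame with columns \code{profile}, \code{start},
#'   \code{end} for one protein.
#' @param required character vector of profile ids that must all be hit.
#' @param min_len,max_len inclusive length bounds (defaults 350 and 650 aa,
#'   the usual ketoacyl-synthase domain-region window).
#' @return named integer vector \code{c(start, end)} or \code{NULL}.
#' @export
extractDomainSpan <- function(domainHits, required, min_len = 350L,
                              max_len = 650L) {
    if (nrow(domainHits) > 0 &&
        (any(is.na(domainHits$start)) || any(is.na(domainHits$end)) ||
         any(domainHits$end < domainHits$start) ||
         any(domainHits$start < 1)))
        stop("malformed domain hit coordinates")
    h <- domainHits[domainHits$profile %in% required, , drop = FALSE]
    if (length(setdiff(required, h$profile)) > 0) return(NULL)
    region <- c(start = min(h$start), end = max(h$end))
    len <- region["end"] - region["start"] + 1L
    if (len < min_len || len > max_len) return(NULL)
    region
}
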