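#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
NULL

#' StageCounts: gene-level counts with effective lengths and stage labels
#'
#' A \linkS4class{SummarizedExperiment} subclass holding the two assays a
#' developmental RNA-seq quantification produces: integer gene-level
#' \code{counts} and positive per-sample \code{efflen} (effective transcript
#' length, bp).  \code{colData} carries a \code{stage} factor (egg, veliger,
#' larva, juvenile); every sample must be assigned to a stage.
#'
#' @slot .. inherits all slots from SummarizedExperiment.
#' @seealso [StageCounts()] constructor, [stageOf()], [effLengths()]
#' @export
setClass("StageCounts", contains = "SummarizedExperiment")

setValidity("StageCounts", function(object) {
    msg <- NULL
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("counts", "efflen") %in% an))
        msg <- c(msg, "assays must include 'counts' and 'efflen'")
    if (!"stage" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain a 'stage' column")
    if (is.null(msg)) {
        cts <- assay(object, "counts")
        if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
        el <- assay(object, "efflen")
        if (any(el <= 0)) msg <- c(msg, "effective lengths must be positive")
        if (anyNA(colData(object)$stage))
            msg <- c(msg, "every sample must be mapped to a stage")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a StageCounts object
#'
#' @param counts genes x samples matrix of non-negative integer counts, with
#'   gene ids as rownames and sample ids as colnames.
#' @param efflen genes x samples matrix of positive effective lengths (bp);
#'   recycled from a per-gene vector if given as one.
#' @param stage character or factor of length \code{ncol(counts)} mapping each
#'   sample to a developmental stage.
#' @return A [StageCounts-class] object.
#' @examples
#' cts <- matrix(rpois(8, 50), 4, 2, dimnames = list(paste0("g", 1:4), c("s1", "s2")))
#' sc <- StageCounts(cts, efflen = rep(1000, 4), stage = c("egg", "juvenile"))
#' stageOf(sc)
#' @export
StageCounts <- function(counts, efflen, stage) {
    counts <- as.matrix(counts)
    if (is.null(dim(efflen)))
        efflen <- matrix(efflen, nrow(counts), ncol(counts),
                         dimnames = dimnames(counts))
    efflen <- as.matrix(efflen)
    cd <- DataFrame(stage = factor(stage), row.names = colnames(counts))
    new("StageCounts",
        SummarizedExperiment(assays = list(counts = counts, efflen = efflen),
                             colData = cd))
}

#' @describeIn StageCounts stage label of each sample.
#' @param x a StageCounts object.
#' @export
stageOf <- function(x) {
    stopifnot(is(x, "StageCounts"))
    setNames(as.character(colData(x)$stage), colnames(x))
}

#' @describeIn StageCounts effective-length assay matrix.
#' @export
effLengths <- function(x) {
    stopifnot(is(x, "StageCounts"))
    assay(x, "efflen")
}

#' Per-gene Alien Index results
#'
#' Container for the per-gene Alien Index (AI) screen.  The AI contrasts the
#' best normalized bitscore outside the recipient lineage (\code{nbsO})
#' against the best hit inside it (\code{nbsM}, with the self-containing skip
#' lineage excluded): \code{AI = nbsO - nbsM}, bounded in [-1, 1].  Genes
#' with AI > 0 align better to non-recipient sequences and are candidates
#' for contamination or horizontal transfer.
#'
#' @slot records DataFrame with columns \code{gene_id}, \code{nbsO},
#'   \code{nbsM}, \code{AI}, \code{n_hits}, \code{top_outgroup_subject}.
#' @slot recipient character(1), recipient lineage label (e.g. "Metazoa").
#' @slot skip character(1), self-containing lineage excluded from the
#'   recipient side (e.g. "Placobranchoidea").
#' @seealso [computeAlienIndex()], [aiTable()]
#' @export
setClass("AlienIndexResults",
         representation(records = "DataFrame",
                        recipient = "character",
                        skip = "character"))

setValidity("AlienIndexResults", function(object) {
    rec <- object@records
    need <- c("gene_id", "nbsO", "nbsM", "AI", "n_hits")
    if (!all(need %in% colnames(rec)))
        return(paste("records must have columns:", paste(need, collapse = ", ")))
    if (nrow(rec) > 0L) {
        if (any(rec$AI < -1 - 1e-12) || any(rec$AI > 1 + 1e-12))
            return("AI out of [-1, 1]")
        if (max(abs(rec$AI - (rec$nbsO - rec$nbsM))) > 1e-12)
            return("AI must equal nbsO - nbsM")
        if (anyDuplicated(rec$gene_id))
            return("duplicate gene_id in records")
    }
    TRUE
})

#' @describeIn AlienIndexResults the per-gene AI table as a data.frame.
#' @param x an AlienIndexResults object.
#' @export
aiTable <- function(x) {
    stopifnot(is(x, "AlienIndexResults"))
    as.data.frame(x@records)
}

#' @describeIn AlienIndexResults the recipient/skip lineage labels used.
#' @export
aiLineages <- function(x) {
    stopifnot(is(x, "AlienIndexResults"))
    c(recipient = x@recipient, skip = x@skip)
}

setMethod("show", "AlienIndexResults", function(object) {
    rec <- object@records
    cat("AlienIndexResults with", nrow(rec), "genes\n")
    cat("  recipient:", object@recipient, " skip:", object@skip, "\n")
    if (nrow(rec) > 0L) {
        cat(sprintf("  AI range: [%.3f, %.3f]; %d gene(s) with AI > 0\n",
                    min(rec$AI), max(rec$AI), sum(rec$AI > 0)))
    }
    invisible(NULL)
})

#' A synthetic kleptoplasty genome study with recorded ground truth
#'
#' The value returned by [simulateStudy()].  Bundles every input a slug
#' genome analysis consumes -- assembly, two gene-model sets, repeats,
#' protein homology hits, organelle screening hits, a developmental count
#' matrix, orthogroups, functional annotations, candidate phylogenies --
#' together with the ground truth of what was spiked in, so downstream
#' stages can be validated.
#'
#' @slot genome DNAStringSet of contig sequences.
#' @slot models GRanges of exon features from the masked annotation run.
#' @slot modelsUnmasked GRanges of exon features from the unmasked run.
#' @slot repeats GRanges of repeat annotations (classified + simple).
#' @slot hits data.frame of protein homology hits (BLAST tabular + lineage).
#' @slot organelleHits data.frame of organelle-protein screening hits.
#' @slot counts StageCounts for 4 stages x replicates.
#' @slot orthogroups data.frame, one row per orthogroup, comma-joined members
#'   per species column.
#' @slot annotations data.frame mapping gene_id to functional terms.
#' @slot trees named list of `phylo` candidate-gene phylogenies.
#' @slot treeClasses named list of leaf->taxon-class maps, parallel to trees.
#' @slot truth list of ground-truth id sets (see [truth()]).
#' @slot config the FixtureConfig list used.
#' @export
setClass("SlugFixture",
         representation(genome = "ANY", models = "ANY",
                        modelsUnmasked = "ANY", repeats = "ANY",
                        hits = "data.frame", organelleHits = "data.frame",
                        counts = "ANY", orthogroups = "data.frame",
                        annotations = "data.frame", trees = "list",
                        treeClasses = "list", truth = "list",
                        config = "list"))

#' @describeIn SlugFixture ground-truth list: \code{contaminant_contig_ids},
#'   \code{hgt_gene_ids}, \code{organelle_contig_ids}, \code{deg_gene_ids},
#'   \code{klepto_candidate_gene_ids}, \code{true_means} (genes x stages),
#'   \code{rescued_gene_ids}.
#' @param x a SlugFixture.
#' @export
truth <- function(x) {
    stopifnot(is(x, "SlugFixture"))
    x@truth
}

setMethod("show", "SlugFixture", function(object) {
    cat("SlugFixture (synthetic kleptoplasty genome study)\n")
    cat("  contigs:", length(object@genome),
        " genes:", nrow(aiGeneMap(object)), "\n")
    cat("  spiked: ", length(object@truth$contaminant_contig_ids),
        "contaminant contig(s), ",
        length(object@truth$hgt_gene_ids), "HGT gene(s), ",
        length(object@truth$deg_gene_ids), "DEG(s)\n")
    invisible(NULL)
})

#' @describeIn SlugFixture gene-to-contig map (data.frame gene_id, contig_id)
#'   derived from the masked gene models.
#' @export
aiGeneMap <- function(x) {
    stopifnot(is(x, "SlugFixture"))
    gr <- x@models
    gid <- gr$gene_id
    df <- unique(data.frame(gene_id = gid,
                            contig_id = as.character(GenomicRanges::seqnames(gr)),
                            stringsAsFactors = FALSE))
    rownames(df) <- NULL
    df[order(df$gene_id), , drop = FALSE]
}
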