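#' @importFrom utils read.delim write.table
NULL

.HIT_COLS <- c("query_id", "subject_id", "pident", "length", "mismatch",
               "gapopen", "qstart", "qend", "sstart", "send", "evalue",
               "bitscore", "staxid", "lineage")

#' Read a taxonomy-labelled homology hit table
#'
#' 12-column BLAST/DIAMOND tabular (outfmt 6) with two appended columns:
#' subject taxid and a semicolon-joined root-to-species lineage string.
#'
#' @param path TSV file; a header row matching the column names is
#'   accepted but not required.
#' @return data.frame with the 14 standard columns.
#' @export
readHomologyHits <- function(path) {
    first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
    hasHeader <- identical(first[1], "query_id")
    df <- read.delim(path, header = hasHeader, stringsAsFactors = FALSE)
    if (!hasHeader) {
        if (ncol(df) != length(.HIT_COLS))
            stop("expected ", length(.HIT_COLS), " columns, got ", ncol(df))
        colnames(df) <- .HIT_COLS
    }
    df
}

#' @rdname readHomologyHits
#' @param hits data.frame of hits.
#' @export
writeHomologyHits <- function(hits, path) {
    write.table(hits[, .HIT_COLS], path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Read gene models or repeat annotations from GFF3
#'
#' @param path GFF3 file (1-based inclusive coordinates).
#' @return exon-level (or feature-level) \code{GRanges} with the GFF3
#'   attributes as metadata columns.
#' @export
readGeneModels <- function(path) {
    rtracklayer::import(path, format = "gff3")
}

#' @rdname readGeneModels
#' @param gr a \code{GRanges} to write.
#' @export
writeGeneModels <- function(gr, path) {
    rtracklayer::export(gr, path, format = "gff3")
    invisible(path)
}

#' Read a developmental count matrix into a StageCounts object
#'
#' @param countsPath,efflenPath TSV matrices (gene rows, sample columns,
#'   header of sample ids, first column of gene ids).
#' @param stagesPath two-column TSV \code{sample}, \code{stage}.
#' @return a [StageCounts-class] object.
#' @export
readCountMatrix <- function(countsPath, efflenPath, stagesPath) {
    cts <- as.matrix(read.delim(countsPath, row.names = 1L,
                                check.names = FALSE))
    el <- as.matrix(read.delim(efflenPath, row.names = 1L,
                               check.names = FALSE))
    st <- read.delim(stagesPath, stringsAsFactors = FALSE)
    stage <- st$stage[match(colnames(cts), st$sample)]
    if (anyNA(stage)) stop("sample(s) missing from the stage map")
    StageCounts(cts, el[rownames(cts), colnames(cts)], stage)
}

#' Read an orthogroup membership table
#'
#' Standard orthogroup-table layout: one row per orthogroup, first column
#' the orthogroup id, one column per species with comma-joined member gene
#' ids (empty when absent).
#'
#' @param path TSV file.
#' @return data.frame with first column renamed to \code{og_id}.
#' @export
readOrthogroups <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    colnames(df)[1] <- "og_id"
    df[is.na(df)] <- ""
    df
}

#' Read a gene-to-term functional annotation map
#'
#' @param path two-column TSV \code{gene_id}, \code{term}.
#' @return data.frame.
#' @export
readAnnotations <- function(path) {
    read.delim(path, stringsAsFactors = FALSE)
}

#' Read a leaf taxon-class map for tree checks
#'
#' @param path TSV with columns \code{leaf}, \code{class} (values
#'   "recipient", "skip", "other").
#' @return named character vector, leaf -> class.
#' @export
readTaxonClasses <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    stats::setNames(df$class, df$leaf)
}

.writeTSV <- function(df, path)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

#' Write every component of a synthetic fixture to plain-text files
#'
#' Writes the genome (FASTA), both gene-model sets and repeats (GFF3), the
#' homology and organelle hit tables, counts/lengths/stage map,
#' orthogroups, annotations, candidate trees with their leaf-class maps,
#' and the ground-truth tables.  All files round-trip through this
#' package's readers, and the same fixture always produces byte-identical
#' files.
#'
#' @param fx a [SlugFixture-class] object.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
writeFixture <- function(fx, dir) {
    stopifnot(is(fx, "SlugFixture"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(...) file.path(dir, ...)
    paths <- c(genome = p("genome.fasta"),
               masked = p("models_masked.gff3"),
               unmasked = p("models_unmasked.gff3"),
               repeats = p("repeats.gff3"),
               hits = p("hits.tsv"),
               organelle_hits = p("organelle_hits.tsv"),
               counts = p("counts.tsv"), efflen = p("efflen.tsv"),
               stages = p("stages.tsv"),
               orthogroups = p("orthogroups.tsv"),
               annotations = p("annotations.tsv"),
               rescue_blast = p("rescue_blast.tsv"),
               tree_classes = p("tree_classes.tsv"))
    Biostrings::writeXStringSet(fx@genome, paths["genome"])
    writeGeneModels(fx@models, paths["masked"])
    writeGeneModels(fx@modelsUnmasked, paths["unmasked"])
    writeGeneModels(fx@repeats, paths["repeats"])
    writeHomologyHits(fx@hits, paths["hits"])
    .writeTSV(fx@organelleHits, paths["organelle_hits"])

    cts <- assay(fx@counts, "counts")
    el <- effLengths(fx@counts)
    .writeTSV(data.frame(gene_id = rownames(cts), cts,
                         check.names = FALSE), paths["counts"])
    .writeTSV(data.frame(gene_id = rownames(el), round(el, 2),
                         check.names = FALSE), paths["efflen"])
    .writeTSV(data.frame(sample = colnames(cts),
                         stage = stageOf(fx@counts)), paths["stages"])
    og <- fx@orthogroups
    colnames(og)[1] <- "Orthogroup"
    .writeTSV(og, paths["orthogroups"])
    .writeTSV(fx@annotations, paths["annotations"])
    .writeTSV(rescueBlastHits(fx), paths["rescue_blast"])

    dir.create(p("trees"), showWarnings = FALSE)
    cls <- list()
    for (g in names(fx@trees)) {
        tp <- p("trees", paste0(g, ".nwk"))
        writeSupportTree(fx@trees[[g]], tp)
        paths[paste0("tree_", g)] <- tp
        cm <- fx@treeClasses[[g]]
        cls[[g]] <- data.frame(gene_id = g, leaf = names(cm), class = cm,
                               stringsAsFactors = FALSE)
    }
    .writeTSV(do.call(rbind, c(cls, list(make.row.names = FALSE))),
              paths["tree_classes"])

    dir.create(p("truth"), showWarnings = FALSE)
    tr <- fx@truth
    for (nm in setdiff(names(tr), "true_means")) {
        tp <- p("truth", paste0(nm, ".tsv"))
        .writeTSV(data.frame(id = tr[[nm]]), tp)
        paths[paste0("truth_", nm)] <- tp
    }
    tm <- p("truth", "true_means.tsv")
    .writeTSV(data.frame(gene_id = rownames(tr$true_means),
                         round(tr$true_means, 4), check.names = FALSE), tm)
    paths["truth_true_means"] <- tm
    invisible(paths)
}
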