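#' Run configuration for the end-to-end pipeline
#'
#' Collects every tunable threshold of the analysis with the screening
#' defaults: Alien Index candidate filter (AI > 0.1, >= 50 database hits),
#' organelle flagging (>= 2 hits at e <= 1e-5), gene-model rescue
#' (BLASTp e < 1e-3, no classified-repeat overlap, no exon > 50% simple
#' repeats), the expression filter (average length-scaled TPM vs 1),
#' DEG thresholds (log2FC > 2, BH FDR < 0.01), and the tree support
#' threshold (95).
#'
#' @param min_ai,min_hits HGT candidate filter (strict AI bound; minimum
#'   subject count).
#' @param organelle_e e-value cutoff (inclusive) for organelle flagging.
#' @param rescue_e strict e-value bound for unmasked-model rescue.
#' @param simple_repeat_frac strict per-exon simple-repeat coverage bound.
#' @param tpm_threshold expression threshold on mean length-scaled TPM.
#' @param evidence_comparator comparator for the evidence-table expression
#'   call (default ">=", the summary-table definition).
#' @param de_comparator comparator for the pre-test expression filter
#'   (default ">", the differential-expression filter wording).
#' @param fc,fdr DEG thresholds (strict log2FC bound; strict FDR bound).
#' @param support tree support threshold: branches below it are collapsed.
#' @param recipient,skip Alien Index lineage labels.
#' @param focal focal species column in the orthogroup table.
#' @param kleptoplastic,outgroup species roles for pattern classification.
#' @param seed integer seed for any randomized stage.
#' @return validated list of class \code{"runConfig"}.
#' @export
runConfig <- function(min_ai = 0.1, min_hits = 50L, organelle_e = 1e-5,
                      rescue_e = 1e-3, simple_repeat_frac = 0.5,
                      tpm_threshold = 1, evidence_comparator = ">=",
                      de_comparator = ">", fc = 2, fdr = 0.01,
                      support = 95, recipient = "Metazoa",
                      skip = "Placobranchoidea", focal = "Ecla",
                      kleptoplastic = c("Ecla", "Echl", "Pocc", "Emar"),
                      outgroup = "Acal", seed = 1L) {
    cfg <- as.list(environment())
    if (!is.finite(cfg$min_ai) || cfg$min_ai < -1 || cfg$min_ai > 1)
        .badField("min_ai", "must lie in [-1, 1]")
    if (cfg$min_hits < 0) .badField("min_hits", "must be >= 0")
    for (f in c("organelle_e", "rescue_e"))
        if (cfg[[f]] <= 0) .badField(f, "must be > 0")
    if (cfg$simple_repeat_frac < 0 || cfg$simple_repeat_frac > 1)
        .badField("simple_repeat_frac", "must lie in [0, 1]")
    if (cfg$fdr <= 0 || cfg$fdr > 1) .badField("fdr", "must lie in (0, 1]")
    if (cfg$fc < 0) .badField("fc", "must be >= 0")
    if (cfg$support < 0 || cfg$support > 100)
        .badField("support", "must lie in [0, 100]")
    if (!cfg$evidence_comparator %in% c(">=", ">"))
        .badField("evidence_comparator", "must be '>=' or '>'")
    if (!cfg$de_comparator %in% c(">=", ">"))
        .badField("de_comparator", "must be '>=' or '>'")
    class(cfg) <- "runConfig"
    cfg
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE))
}

#' Run the full screening and expression pipeline on a study
#'
#' Executes the five analysis stages in order on a [SlugFixture-class]
#' (real inputs can be assembled into one via the reader functions):
#' \enumerate{
#'   \item \strong{screen}: organelle-contig flagging, Alien Index on all
#'     non-organelle genes, contamination flagging, HGT candidate filter;
#'   \item \strong{curate}: masked/unmasked gene-model merge and the final
#'     gene set (flagged contigs removed);
#'   \item \strong{express}: length-scaled TPM, stage expression and
#'     intersections, TMM + NB exact-test DEG calling; then the evidence
#'     table, high-confidence set and summary statistics;
#'   \item \strong{compare}: orthogroup pattern classes, candidate genes,
#'     hypergeometric term enrichment of the candidates;
#'   \item \strong{trees}: midpoint rooting, support collapsing, and the
#'     automated donor-clade check for every candidate with a phylogeny.
#' }
#'
#' @param fx a [SlugFixture-class] study bundle.
#' @param config a [runConfig()] list.
#' @param outdir optional directory; when given, per-stage TSV outputs and
#'   a JSON manifest (inputs, thresholds, output hashes) are written.
#' @return list with per-stage results and a \code{manifest}.
#' @export
runAll <- function(fx, config = runConfig(), outdir = NULL) {
    stopifnot(is(fx, "SlugFixture"))
    if (!inherits(config, "runConfig")) config <- do.call(runConfig, config)
    cfg <- config
    gm <- aiGeneMap(fx)

    ## ---- stage 1: screen ---------------------------------------------
    screen <- .stage("screen", {
        org <- flagOrganelleContigs(fx@organelleHits,
                                    max_evalue = cfg$organelle_e)
        orgContigs <- org$contig_id[org$status != "nuclear"]
        keepGenes <- gm$gene_id[!gm$contig_id %in% orgContigs]
        ai <- computeAlienIndex(
            fx@hits[fx@hits$query_id %in% keepGenes, , drop = FALSE],
            recipient = cfg$recipient, skip = cfg$skip)
        contam <- flagContaminantContigs(ai, gm)
        contamContigs <-
            contam$contig_id[contam$status == "bacterial_contaminant"]
        cand <- filterHgtCandidates(ai, contamContigs, gm,
                                    min_ai = cfg$min_ai,
                                    min_hits = cfg$min_hits)
        list(organelle = org, organelle_contigs = sort(orgContigs),
             ai = ai, contamination = contam,
             contaminant_contigs = sort(contamContigs),
             hgt_candidates = cand)
    })

    ## ---- stage 2: curate ----------------------------------------------
    curate <- .stage("curate", {
        isSimple <- !is.null(fx@repeats$repeat_class) &
            fx@repeats$repeat_class == "Simple_repeat"
        merged <- rescueUnmaskedModels(
            fx@models, fx@modelsUnmasked, rescueBlastHits(fx),
            fx@repeats[!isSimple], fx@repeats[isSimple],
            rescue_e = cfg$rescue_e, simple_frac = cfg$simple_repeat_frac)
        dropContigs <- c(screen$organelle_contigs,
                         screen$contaminant_contigs)
        finalModels <- merged[!as.character(
            GenomicRanges::seqnames(merged)) %in% dropContigs]
        list(merged = merged,
             rescued = sort(unique(
                 merged$gene_id[merged$source_run == "unmasked"])),
             final_models = finalModels,
             final_genes = sort(unique(finalModels$gene_id)))
    })

    ## ---- stage 3: express ----------------------------------------------
    express <- .stage("express", {
        sc <- fx@counts
        keep <- intersect(rownames(sc), curate$final_genes)
        sc <- sc[keep, ]
        lst <- lengthScaledTPM(assay(sc, "counts"), effLengths(sc))
        se <- stageExpression(lst$lengthScaled, stageOf(sc),
                              cfg$tpm_threshold, cfg$evidence_comparator)
        inter <- expressionIntersections(se$expressed)
        de <- callDEGs(sc, fed = "juvenile",
                       tpm_threshold = cfg$tpm_threshold,
                       tpm_comparator = cfg$de_comparator,
                       fc = cfg$fc, fdr = cfg$fdr)
        degs <- de$gene_id[de$is_deg]

        expressedGenes <- rownames(se$expressed)[rowSums(se$expressed) > 0]
        og <- fx@orthogroups
        others <- setdiff(colnames(og), c("og_id", cfg$focal))
        multi <- rowSums(sapply(others, function(s)
            !is.na(og[[s]]) & nzchar(og[[s]]))) > 0
        orthologGenes <- unique(trimws(unlist(
            strsplit(og[[cfg$focal]][multi], ",", fixed = TRUE))))
        ev <- evidenceTable(curate$final_genes, expressedGenes,
                            orthologGenes, unique(fx@annotations$gene_id))
        hc <- highConfidenceSet(ev)
        summaryTotal <- summarizeAnnotation(curate$final_models, ev)
        hcModels <- curate$final_models[
            curate$final_models$gene_id %in% hc]
        summaryHC <- if (length(hcModels))
            summarizeAnnotation(hcModels, ev) else NULL
        list(tpm = lst$tpm, length_scaled = lst$lengthScaled,
             stage_mean = se$mean, expressed = se$expressed,
             intersections = inter, de = de, degs = degs,
             evidence = ev, high_confidence = hc,
             summary_total = summaryTotal, summary_hc = summaryHC)
    })

    ## ---- stage 4: compare ----------------------------------------------
    compare <- .stage("compare", {
        patterns <- classifyPatterns(fx@orthogroups,
                                     kleptoplastic = cfg$kleptoplastic,
                                     outgroup = cfg$outgroup)
        cand <- candidateGenes(patterns, fx@orthogroups, cfg$focal,
                               express$degs)
        background <- rownames(express$expressed)[
            rowSums(express$expressed) > 0]
        ks <- cand[["klepto_specific"]]
        enrich <- if (length(ks))
            hypergeomEnrichment(intersect(ks, background),
                                fx@annotations, background)
        else NULL
        list(patterns = patterns, candidates = cand, enrichment = enrich)
    })

    ## ---- stage 5: trees -------------------------------------------------
    trees <- .stage("trees", {
        out <- list()
        for (g in intersect(screen$hgt_candidates$gene_id,
                            names(fx@trees))) {
            tr <- collapseLowSupport(midpointRoot(fx@trees[[g]]),
                                     threshold = cfg$support)
            out[[g]] <- hgtSupportCheck(tr, g, fx@treeClasses[[g]])
        }
        verdicts <- data.frame(
            gene_id = names(out),
            supported = vapply(out, `[[`, logical(1), "supported"),
            reason = vapply(out, `[[`, character(1), "reason"),
            stringsAsFactors = FALSE)
        rownames(verdicts) <- NULL
        list(verdicts = verdicts,
             supported_hgt = verdicts$gene_id[verdicts$supported])
    })

    result <- list(screen = screen, curate = curate, express = express,
                   compare = compare, trees = trees)
    result$manifest <- .writeManifest(result, cfg, outdir)
    result
}

.writeManifest <- function(result, cfg, outdir) {
    manifest <- list(
        stages = data.frame(stage = names(result), status = "completed",
                            stringsAsFactors = FALSE),
        thresholds = unclass(cfg),
        generated = format(Sys.time(), tz = "UTC"))
    if (is.null(outdir)) return(manifest)
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(...) file.path(outdir, ...)
    .writeTSV(aiTable(result$screen$ai), p("ai_table.tsv"))
    .writeTSV(rbind(result$screen$contamination, result$screen$organelle),
              p("contig_verdicts.tsv"))
    .writeTSV(result$screen$hgt_candidates, p("hgt_candidates.tsv"))
    writeGeneModels(result$curate$merged, p("merged_models.gff3"))
    .writeTSV(result$express$evidence, p("evidence.tsv"))
    .writeTSV(result$express$intersections, p("intersections.tsv"))
    .writeTSV(result$express$de, p("de_table.tsv"))
    .writeTSV(result$compare$patterns, p("patterns.tsv"))
    if (!is.null(result$compare$enrichment))
        .writeTSV(result$compare$enrichment, p("enrichment.tsv"))
    .writeTSV(result$trees$verdicts, p("tree_verdicts.tsv"))
    files <- list.files(outdir, pattern = "\\.(tsv|gff3)$",
                        full.names = TRUE)
    manifest$outputs <- data.frame(
        file = basename(files),
        md5 = unname(tools::md5sum(files)), stringsAsFactors = FALSE)
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    manifest
}
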