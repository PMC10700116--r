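#' @importFrom Biostrings DNAStringSet
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

.STAGES <- c("egg", "veliger", "larva", "juvenile")

#' Configuration for the synthetic kleptoplasty study
#'
#' Builds and validates the configuration driving [simulateStudy()].  The
#' defaults define the study conditions the generator emulates: a mostly
#' slug-lineage gene complement across 4 developmental stages with 3
#' biological replicates each, spiked bacterial contaminant contigs,
#' exactly one genuine horizontally transferred gene, organelle-derived
#' contigs, and fed-stage-upregulated genes under negative-binomial noise.
#'
#' @param n_contigs number of nuclear contigs (default 40).
#' @param genes_per_contig integer range (length 2) of genes per nuclear
#'   contig (default 3--8).
#' @param n_contaminant_contigs spiked bacterial contigs (default 5).
#' @param n_hgt_genes spiked horizontally transferred genes (default 1).
#' @param n_organelle_contigs organelle-derived contigs (default 3; the
#'   first is mitochondrial, the rest kleptoplast).
#' @param reps_per_stage biological replicates per stage (default 3).
#' @param n_deg genes upregulated in the fed (juvenile) stage (default 50).
#' @param deg_log2fc spiked log2 fold change (default 3).
#' @param nb_dispersion NB dispersion phi of the count noise (default 0.1).
#' @param library_size_mean mean per-sample library size (default 5e5).
#' @param n_klepto_candidates how many spiked DEGs are placed in
#'   kleptoplast-lineage-specific orthogroups (default 10).
#' @param seed integer seed; fully determines every output.
#' @return validated configuration list (class \code{"fixtureConfig"}).
#' @export
fixtureConfig <- function(n_contigs = 40L, genes_per_contig = c(3L, 8L),
                          n_contaminant_contigs = 5L, n_hgt_genes = 1L,
                          n_organelle_contigs = 3L, reps_per_stage = 3L,
                          n_deg = 50L, deg_log2fc = 3,
                          nb_dispersion = 0.1, library_size_mean = 5e5,
                          n_klepto_candidates = 10L, seed = 1L) {
    cfg <- list(n_contigs = as.integer(n_contigs),
                genes_per_contig = as.integer(genes_per_contig),
                n_contaminant_contigs = as.integer(n_contaminant_contigs),
                n_hgt_genes = as.integer(n_hgt_genes),
                n_organelle_contigs = as.integer(n_organelle_contigs),
                n_stages = 4L, stages = .STAGES,
                reps_per_stage = as.integer(reps_per_stage),
                n_deg = as.integer(n_deg), deg_log2fc = deg_log2fc,
                nb_dispersion = nb_dispersion,
                library_size_mean = library_size_mean,
                n_klepto_candidates = as.integer(n_klepto_candidates),
                seed = as.integer(seed))
    counts <- c("n_contigs", "n_contaminant_contigs", "n_hgt_genes",
                "n_organelle_contigs", "reps_per_stage", "n_deg",
                "n_klepto_candidates")
    for (f in counts)
        if (is.na(cfg[[f]]) || cfg[[f]] < 0) .badField(f, "must be >= 0")
    if (cfg$n_contigs < 1) .badField("n_contigs", "must be >= 1")
    if (cfg$reps_per_stage < 1) .badField("reps_per_stage", "must be >= 1")
    if (length(cfg$genes_per_contig) != 2L ||
        any(cfg$genes_per_contig < 1) ||
        cfg$genes_per_contig[1] > cfg$genes_per_contig[2])
        .badField("genes_per_contig", "must be an increasing range >= 1")
    if (!is.finite(cfg$deg_log2fc) || cfg$deg_log2fc <= 0)
        .badField("deg_log2fc", "must be > 0")
    if (!is.finite(cfg$nb_dispersion) || cfg$nb_dispersion < 0)
        .badField("nb_dispersion", "must be >= 0")
    if (cfg$library_size_mean <= 0)
        .badField("library_size_mean", "must be > 0")
    if (is.na(cfg$seed)) .badField("seed", "must be an integer")
    if (cfg$n_klepto_candidates > cfg$n_deg)
        .badField("n_klepto_candidates", "cannot exceed n_deg")
    class(cfg) <- "fixtureConfig"
    cfg
}

#' Draw negative-binomial counts with a given mean structure
#'
#' Counts are drawn gene-by-sample from NB with mean
#' \code{means[g, s] * libsizes[s]} and dispersion \code{phi}
#' (variance = mu + phi mu^2); dispersion 0 reduces to Poisson.
#'
#' @param means genes x samples matrix of non-negative expected counts at
#'   unit library size.
#' @param dispersion NB dispersion phi >= 0.
#' @param libsizes per-sample scaling of the means (default 1).
#' @param seed integer seed.
#' @return integer matrix of the same shape as \code{means}.
#' @export
simulateNBCounts <- function(means, dispersion, libsizes = NULL,
                             seed = 1L) {
    means <- as.matrix(means)
    if (any(means < 0)) stop("negative mean")
    if (dispersion < 0) stop("dispersion must be >= 0")
    if (is.null(libsizes)) libsizes <- rep(1, ncol(means))
    mu <- sweep(means, 2, libsizes, "*")
    set.seed(seed)
    cts <- if (dispersion == 0) {
        stats::rpois(length(mu), lambda = mu)
    } else {
        stats::rnbinom(length(mu), size = 1 / dispersion, mu = mu)
    }
    matrix(as.integer(cts), nrow(means), ncol(means),
           dimnames = dimnames(means))
}

# one simulated gene structure on a contig, returned as exon data.frame
.simGene <- function(gene_id, contig, offset, strand, nExons) {
    exLen <- sample(100:400, nExons, replace = TRUE)
    intLen <- if (nExons > 1) sample(200:2000, nExons - 1, replace = TRUE)
              else integer(0)
    starts <- offset + cumsum(c(0, exLen[-nExons] + intLen))
    data.frame(contig = contig, start = starts,
               end = starts + exLen - 1L, strand = strand,
               gene_id = gene_id, stringsAsFactors = FALSE)
}

# lineage strings of the fixed toy taxonomy
.LINEAGES <- c(
    self    = "root;Metazoa;Placobranchoidea",
    slug    = "root;Metazoa;Placobranchoidea",
    mollusc = "root;Metazoa;Gastropoda",
    fish    = "root;Metazoa;Vertebrata",
    bacteria = "root;Bacteria;Proteobacteria",
    virus   = "root;Viruses;Riboviria",
    alga    = "root;Viridiplantae;Bryopsidales")

# hits for one gene; kind in c("normal","contaminant","hgt","organelle")
.simHits <- function(gene_id, kind) {
    selfB <- sample(300:800, 1)
    mk <- function(subject, lineage, nbs) {
        lineage <- unname(lineage)
        bs <- round(unname(nbs) * selfB, 1)
        data.frame(query_id = gene_id, subject_id = subject,
                   pident = round(stats::runif(length(subject), 30, 95), 1),
                   length = sample(80:400, length(subject), replace = TRUE),
                   mismatch = sample(5:120, length(subject), replace = TRUE),
                   gapopen = sample(0:5, length(subject), replace = TRUE),
                   qstart = 1L, qend = sample(80:400, length(subject),
                                              replace = TRUE),
                   sstart = 1L, send = sample(80:400, length(subject),
                                              replace = TRUE),
                   evalue = signif(10^(-bs / 10), 3), bitscore = bs,
                   staxid = sample(1000:9999, length(subject),
                                   replace = TRUE),
                   lineage = lineage, stringsAsFactors = FALSE)
    }
    selfHit <- mk(gene_id, .LINEAGES["self"], 1)
    hits <- switch(kind,
        normal = {
            nm <- sample(5:25, 1)
            bestM <- stats::runif(1, 0.5, 0.95)
            metNbs <- c(bestM, stats::runif(nm - 1, 0.2, bestM))
            met <- mk(sprintf("met_%s_%02d", gene_id, seq_len(nm)),
                      sample(.LINEAGES[c("mollusc", "fish")], nm,
                             replace = TRUE), metNbs)
            slug <- mk(sprintf("slug_%s", gene_id), .LINEAGES["slug"],
                       stats::runif(1, 0.9, 0.99))
            no <- sample(0:4, 1)
            out <- if (no > 0)
                mk(sprintf("out_%s_%02d", gene_id, seq_len(no)),
                   .LINEAGES["bacteria"],
                   stats::runif(no, 0.02, max(0.05, bestM - 0.25)))
            else NULL
            rbind(met, slug, out)
        },
        contaminant = {
            nb <- sample(10:40, 1)
            bestB <- stats::runif(1, 0.85, 0.99)
            bact <- mk(sprintf("bac_%s_%02d", gene_id, seq_len(nb)),
                       .LINEAGES["bacteria"],
                       c(bestB, stats::runif(nb - 1, 0.3, bestB)))
            nm <- sample(0:2, 1)
            met <- if (nm > 0)
                mk(sprintf("met_%s_%02d", gene_id, seq_len(nm)),
                   .LINEAGES["mollusc"], stats::runif(nm, 0.01, 0.08))
            else NULL
            rbind(bact, met)
        },
        hgt = {
            nv <- 60L
            bestV <- stats::runif(1, 0.75, 0.85)
            vir <- mk(sprintf("vir_%s_%02d", gene_id, seq_len(nv)),
                      .LINEAGES["virus"],
                      c(bestV, stats::runif(nv - 1, 0.2, bestV - 0.05)))
            met <- mk(sprintf("met_%s_%02d", gene_id, 1:8),
                      .LINEAGES[sample(c("mollusc", "fish"), 8,
                                       replace = TRUE)],
                      stats::runif(8, 0.1, 0.3))
            rbind(vir, met)
        },
        organelle = {
            na_ <- sample(8:15, 1)
            mk(sprintf("alg_%s_%02d", gene_id, seq_len(na_)),
               .LINEAGES["alga"],
               c(stats::runif(1, 0.8, 0.95),
                 stats::runif(na_ - 1, 0.3, 0.8)))
        })
    rbind(selfHit, hits)
}

#' Simulate a complete synthetic kleptoplasty genome study
#'
#' Generates every input of the analysis pipeline -- assembly contigs, two
#' gene-model sets (masked and unmasked annotation runs) plus repeat
#' annotations, a taxonomy-labelled protein homology hit table, organelle
#' screening hits, a 4-stage x replicate count matrix with effective
#' lengths, orthogroup and functional-annotation tables, and candidate-gene
#' phylogenies -- together with the ground truth of everything spiked in.
#' The same seed always produces byte-identical outputs.
#'
#' @param config a [fixtureConfig()] list.
#' @param dir optional directory; when given, all components are also
#'   written as plain-text files (FASTA/GFF3/TSV/Newick) that round-trip
#'   through this package's readers, and the paths are recorded in
#'   \code{metadata}.
#' @return a [SlugFixture-class] object.
#' @export
simulateStudy <- function(config = fixtureConfig(), dir = NULL) {
    if (!inherits(config, "fixtureConfig"))
        config <- do.call(fixtureConfig, config)
    cfg <- config

    ## ---- contig and gene layout -------------------------------------
    set.seed(.subSeed(cfg$seed, 101L))
    nTot <- cfg$n_contigs + cfg$n_contaminant_contigs +
        cfg$n_organelle_contigs
    contigs <- sprintf("contig_%04d", seq_len(nTot))
    role <- c(rep("nuclear", cfg$n_contigs),
              rep("contaminant", cfg$n_contaminant_contigs),
              rep("organelle", cfg$n_organelle_contigs))
    contaminantContigs <- contigs[role == "contaminant"]
    organelleContigs <- contigs[role == "organelle"]

    geneRows <- list(); geneInfo <- list(); gidx <- 0L
    for (i in seq_len(nTot)) {
        ng <- switch(role[i],
                     nuclear = sample(cfg$genes_per_contig[1]:
                                      cfg$genes_per_contig[2], 1),
                     contaminant = sample(2:4, 1),
                     organelle = 2L)
        offset <- 1000L
        for (j in seq_len(ng)) {
            gidx <- gidx + 1L
            gid <- sprintf("Ecla%04dg%05d", i, gidx * 10L)
            g <- .simGene(gid, contigs[i], offset,
                          sample(c("+", "-"), 1), sample(1:8, 1))
            offset <- max(g$end) + sample(1500:4000, 1)
            geneRows[[gidx]] <- g
            geneInfo[[gidx]] <- data.frame(gene_id = gid,
                                           contig_id = contigs[i],
                                           role = role[i],
                                           stringsAsFactors = FALSE)
        }
    }
    exons <- do.call(rbind, geneRows)
    genes <- do.call(rbind, geneInfo)
    nuclearGenes <- genes$gene_id[genes$role == "nuclear"]

    ## spiked roles among nuclear genes; the HGT gene sits on a nuclear
    ## contig that carries at least 2 other genes, so its contig is never
    ## flagged by the contamination rules
    hgtGenes <- character(0)
    if (cfg$n_hgt_genes > 0) {
        tab <- table(genes$contig_id[genes$role == "nuclear"])
        bigContigs <- names(tab)[tab >= 3]
        pick <- sample(bigContigs, min(cfg$n_hgt_genes, length(bigContigs)))
        hgtGenes <- vapply(pick, function(ctg) {
            cand <- genes$gene_id[genes$contig_id == ctg]
            sample(cand, 1)
        }, character(1))
        names(hgtGenes) <- NULL
    }

    ## ---- genome sequence --------------------------------------------
    set.seed(.subSeed(cfg$seed, 102L))
    clens <- tapply(exons$end, exons$contig, max)[contigs] + 500L
    genome <- DNAStringSet(vapply(clens, function(L)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
              collapse = ""), character(1)))
    names(genome) <- contigs

    ## ---- masked gene models (one transcript per gene) ----------------
    models <- GRanges(exons$contig, IRanges(exons$start, exons$end),
                      strand = exons$strand, gene_id = exons$gene_id,
                      transcript_id = paste0(exons$gene_id, ".t1"),
                      type = "exon")
    GenomeInfoDb::seqlevels(models) <- contigs
    GenomeInfoDb::seqlengths(models) <- as.integer(clens)

    ## ---- unmasked run: masked models + unique extras -----------------
    ## four extra models per category: rescuable; overlapping a masked
    ## gene; weak homology; simple-repeat-heavy exon
    set.seed(.subSeed(cfg$seed, 103L))
    mkExtra <- function(tag, contig, offset, nEx = 2L)
        .simGene(sprintf("U%s", tag), contig, offset, "+", nEx)
    tailOf <- function(ctg) as.integer(clens[ctg]) - 200L
    nucContigs <- contigs[role == "nuclear"]
    host <- sample(nucContigs, 4)
    ## place extras beyond existing genes; extend contigs to fit
    ex1 <- mkExtra("resc1", host[1], tailOf(host[1]) + 2000L)
    ex2 <- {  # overlaps the first masked gene on its contig by >= 1 bp
        g0 <- exons[exons$contig == host[2], ][1, ]
        mkExtra("ovl1", host[2], g0$end - 50L, 1L)
    }
    ex3 <- mkExtra("weak1", host[3], tailOf(host[3]) + 2000L)
    ex4 <- mkExtra("simp1", host[4], tailOf(host[4]) + 2000L, 1L)
    extras <- rbind(ex1, ex2, ex3, ex4)
    newLens <- clens
    for (ctg in unique(extras$contig))
        newLens[ctg] <- max(newLens[ctg],
                            max(extras$end[extras$contig == ctg]) + 500L)
    clens <- newLens
    unmasked <- GRanges(c(exons$contig, extras$contig),
                        IRanges(c(exons$start, extras$start),
                                c(exons$end, extras$end)),
                        strand = c(exons$strand, extras$strand),
                        gene_id = c(exons$gene_id, extras$gene_id),
                        transcript_id = paste0(c(exons$gene_id,
                                                 extras$gene_id), ".t1"),
                        type = "exon")
    GenomeInfoDb::seqlevels(unmasked) <- contigs
    GenomeInfoDb::seqlengths(unmasked) <- as.integer(clens)
    GenomeInfoDb::seqlengths(models) <- as.integer(clens)
    ## pad genome to the extended lengths
    for (ctg in names(clens)[clens > Biostrings::width(genome)[match(names(clens), names(genome))]]) {
        add <- as.integer(clens[ctg]) - Biostrings::width(genome[ctg])
        pad <- paste(sample(c("A", "C", "G", "T"), add, replace = TRUE),
                     collapse = "")
        genome[[ctg]] <- Biostrings::DNAString(
            paste0(as.character(genome[[ctg]]), pad))
    }

    ## repeats: a classified element over nothing in particular, and a
    ## simple repeat covering ~60% of Usimp1's single exon
    simpStart <- ex4$start[1]
    simpLen <- as.integer(ceiling((ex4$end[1] - ex4$start[1] + 1L) * 0.6))
    repeats <- GRanges(
        c(sample(nucContigs, 3), host[4]),
        IRanges(c(sample(200:800, 3), simpStart),
                width = c(sample(150:600, 3), simpLen)),
        repeat_class = c("LINE", "LTR", "DNA", "Simple_repeat"))
    GenomeInfoDb::seqlevels(repeats) <- contigs
    GenomeInfoDb::seqlengths(repeats) <- as.integer(clens)

    ## ---- homology hit table ------------------------------------------
    set.seed(.subSeed(cfg$seed, 104L))
    kindOf <- function(g) {
        if (g %in% hgtGenes) "hgt"
        else if (genes$role[match(g, genes$gene_id)] == "contaminant")
            "contaminant"
        else if (genes$role[match(g, genes$gene_id)] == "organelle")
            "organelle"
        else "normal"
    }
    hits <- do.call(rbind, lapply(genes$gene_id, function(g)
        .simHits(g, kindOf(g))))
    rownames(hits) <- NULL

    ## ---- organelle screening hits ------------------------------------
    set.seed(.subSeed(cfg$seed, 105L))
    orgClass <- if (cfg$n_organelle_contigs > 0)
        c("mitochondrial",
          rep("kleptoplast", cfg$n_organelle_contigs - 1L))
    else character(0)
    orgHits <- list()
    for (i in seq_along(organelleContigs)) {
        nh <- sample(3:6, 1)
        orgHits[[length(orgHits) + 1L]] <- data.frame(
            contig_id = organelleContigs[i],
            protein_id = sprintf("%s_prot_%02d",
                                 substr(orgClass[i], 1, 4), seq_len(nh)),
            organelle = orgClass[i],
            evalue = signif(10^stats::runif(nh, -40, -6), 3),
            bitscore = round(stats::runif(nh, 80, 400), 1),
            stringsAsFactors = FALSE)
    }
    ## one stray, non-qualifying hit on a nuclear contig
    orgHits[[length(orgHits) + 1L]] <- data.frame(
        contig_id = nucContigs[1], protein_id = "mito_prot_99",
        organelle = "mitochondrial", evalue = 1e-4, bitscore = 42,
        stringsAsFactors = FALSE)
    organelleHits <- do.call(rbind, orgHits)

    ## ---- expression means and counts ---------------------------------
    set.seed(.subSeed(cfg$seed, 106L))
    allGenes <- genes$gene_id
    nG <- length(allGenes)
    base <- stats::rlnorm(nG, meanlog = log(100), sdlog = 1)
    names(base) <- allGenes
    ## contamination and organelle DNA yields no transcripts
    base[genes$role != "nuclear"] <- 0
    ## a slice of nuclear genes is silent, another is unfed-stage-restricted
    nuc <- nuclearGenes
    silent <- sample(setdiff(nuc, hgtGenes),
                     max(0L, round(0.15 * length(nuc))))
    base[silent] <- 0
    restricted <- sample(setdiff(nuc, c(hgtGenes, silent)),
                         max(0L, round(0.10 * length(nuc))))
    ## DEGs: well-expressed nuclear genes, never silent/restricted
    degPool <- setdiff(nuc, c(silent, restricted, hgtGenes))
    if (cfg$n_deg > length(degPool))
        .badField("n_deg", "exceeds the number of eligible nuclear genes")
    degGenes <- sort(sample(degPool, cfg$n_deg))
    base[degGenes] <- pmax(base[degGenes], 50)
    base[hgtGenes] <- 30

    trueMeans <- matrix(base, nG, 4,
                        dimnames = list(allGenes, .STAGES))
    ## restricted genes express only in a random prefix of unfed stages
    for (g in restricted) {
        onStages <- sample(c("egg", "veliger", "larva"),
                           sample(1:3, 1))
        trueMeans[g, setdiff(.STAGES, onStages)] <- 0
    }
    trueMeans[degGenes, "juvenile"] <-
        trueMeans[degGenes, "juvenile"] * 2^cfg$deg_log2fc

    reps <- cfg$reps_per_stage
    samples <- paste0(rep(.STAGES, each = reps), "_r",
                      rep(seq_len(reps), 4))
    stage <- rep(.STAGES, each = reps)
    set.seed(.subSeed(cfg$seed, 107L))
    libsizes <- round(cfg$library_size_mean *
                      stats::runif(length(samples), 0.8, 1.2))
    rel <- trueMeans[, stage, drop = FALSE]
    colTot <- colSums(rel)
    rel <- sweep(rel, 2, ifelse(colTot > 0, colTot, 1), "/")
    colnames(rel) <- samples
    cts <- simulateNBCounts(rel, cfg$nb_dispersion, libsizes,
                            seed = .subSeed(cfg$seed, 108L))

    set.seed(.subSeed(cfg$seed, 109L))
    txLen <- tapply(exons$end - exons$start + 1L, exons$gene_id,
                    sum)[allGenes]
    efflen <- outer(as.numeric(txLen), rep(1, length(samples))) *
        matrix(stats::runif(nG * length(samples), 0.95, 1.05), nG)
    dimnames(efflen) <- list(allGenes, samples)
    counts <- StageCounts(cts, efflen, stage)

    ## ---- orthogroups --------------------------------------------------
    set.seed(.subSeed(cfg$seed, 110L))
    species <- c("Ecla", "Echl", "Pocc", "Emar", "Acal")
    kleptoCandidates <- sort(sample(degGenes,
                                    min(cfg$n_klepto_candidates,
                                        length(degGenes))))
    ogRows <- list(); ogi <- 0L
    addOG <- function(ecla, present) {
        ogi <<- ogi + 1L
        row <- stats::setNames(as.list(rep("", 5)), species)
        row$Ecla <- paste(ecla, collapse = ", ")
        for (s in setdiff(present, "Ecla"))
            row[[s]] <- sprintf("%s_g%04d", s, ogi)
        ogRows[[ogi]] <<- data.frame(og_id = sprintf("OG%07d", ogi), row,
                                     stringsAsFactors = FALSE)
    }
    ## klepto-specific orthogroups holding the spiked candidate DEGs
    for (g in kleptoCandidates) addOG(g, c("Ecla", "Echl", "Pocc", "Emar"))
    ## klepto-specific orthogroups with non-DEG members (class != candidate)
    otherKlepto <- sample(setdiff(nuc, c(degGenes, silent)), 5)
    for (g in otherKlepto) addOG(g, c("Ecla", "Echl", "Pocc", "Emar"))
    ## conserved orthogroups over a fat slice of the remaining genes
    conservedPool <- setdiff(nuc, c(kleptoCandidates, otherKlepto))
    conserved <- sample(conservedPool,
                        round(0.45 * length(conservedPool)))
    for (g in conserved) addOG(g, species)
    ## a few partial-presence and non-focal orthogroups
    partial <- sample(setdiff(conservedPool, conserved),
                      min(5L, length(setdiff(conservedPool, conserved))))
    for (g in partial) addOG(g, c("Ecla", "Echl", "Acal"))
    addOG(character(0), c("Echl", "Pocc"))
    orthogroups <- do.call(rbind, ogRows)

    ## ---- functional annotations ---------------------------------------
    set.seed(.subSeed(cfg$seed, 111L))
    goPool <- sprintf("GO:%07d", 1:20)
    annotated <- sample(nuc, round(0.4 * length(nuc)))
    annotations <- do.call(rbind, lapply(annotated, function(g)
        data.frame(gene_id = g,
                   term = sample(goPool, sample(1:3, 1)),
                   stringsAsFactors = FALSE)))
    ## spike one immune-like term into the klepto candidates so the
    ## enrichment stage has genuine signal
    annotations <- rbind(annotations,
                         data.frame(gene_id = kleptoCandidates,
                                    term = "GO:0002376",
                                    stringsAsFactors = FALSE))
    annotations <- unique(annotations[order(annotations$gene_id,
                                            annotations$term), ])
    rownames(annotations) <- NULL

    ## ---- candidate phylogenies ---------------------------------------
    trees <- list(); treeClasses <- list()
    for (g in hgtGenes) {
        nwk <- sprintf(paste0(
            "(((%s:0.05,virA:0.02,slugrel:0.01)99:0.03,virB:0.03)",
            "98:0.1,((metA:0.02,metB:0.02)97:0.05,metC:0.04)96:0.08,",
            "bact1:0.3);"), g)
        trees[[g]] <- readSupportTree(nwk)
        treeClasses[[g]] <- c(slugrel = "skip", virA = "other",
                              virB = "other", metA = "recipient",
                              metB = "recipient", metC = "recipient",
                              bact1 = "other")
    }
    ## a decoy candidate whose tree nests it among recipients
    decoy <- setdiff(nuc, c(hgtGenes, silent))[1]
    trees[[decoy]] <- readSupportTree(sprintf(
        "((%s:0.02,metA:0.02)99:0.05,(metB:0.03,virA:0.2)96:0.04,virB:0.3);",
        decoy))
    treeClasses[[decoy]] <- c(metA = "recipient", metB = "recipient",
                              virA = "other", virB = "other")

    truth <- list(contaminant_contig_ids = sort(contaminantContigs),
                  hgt_gene_ids = sort(hgtGenes),
                  organelle_contig_ids = sort(organelleContigs),
                  deg_gene_ids = degGenes,
                  klepto_candidate_gene_ids = kleptoCandidates,
                  rescued_gene_ids = "Uresc1",
                  silent_gene_ids = sort(silent),
                  true_means = trueMeans)

    fx <- new("SlugFixture", genome = genome, models = sort(models),
              modelsUnmasked = sort(unmasked), repeats = sort(repeats),
              hits = hits, organelleHits = organelleHits, counts = counts,
              orthogroups = orthogroups, annotations = annotations,
              trees = trees, treeClasses = treeClasses, truth = truth,
              config = unclass(cfg))
    if (!is.null(dir)) writeFixture(fx, dir)
    fx
}

# attach the rescue-support blast table (derived, not stored in a slot)
#' Homology support table for the unmasked-run gene models of a fixture
#' @param fx a [SlugFixture-class].
#' @return data.frame \code{query_id}, \code{evalue}.
#' @export
rescueBlastHits <- function(fx) {
    stopifnot(is(fx, "SlugFixture"))
    data.frame(query_id = c("Uresc1", "Uovl1", "Uweak1", "Usimp1"),
               evalue = c(1e-6, 1e-8, 1e-2, 1e-9),
               stringsAsFactors = FALSE)
}
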